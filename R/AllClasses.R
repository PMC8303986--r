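#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

.scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' MachineModel: accelerator and nozzle calibration
#'
#' Encodes the machine model of a cyclotron-based PBS system operated in
#' FLASH (transmission) mode: the proton content of one monitor unit (MU),
#' the plan-level minimum MU per spot (which fixes the cyclotron beam current
#' of an energy layer and therefore the deliverable dose rate), the dwell
#' time of a minimum-MU spot, the lateral scanning speed, and a calibration
#' anchor tying a nozzle current to a spot peak dose rate (SPDR).
#'
#' All conversions among MU, proton flux, current and SPDR derive from these
#' constants; see [muRate()], [spdrFromMinMu()], [currentFromMinMu()] and
#' [dwellTime()].
#'
#' @slot protonsPerMu protons contained in one MU (default 5.17e6).
#' @slot minMuPerSpot minimum MU deliverable per spot; a plan-level setting
#'   (e.g. 100 or 400 MU).
#' @slot dwellTimeMinMu delivery time of a minimum-MU spot, in seconds
#'   (default 2e-3).
#' @slot scanSpeed lateral scanning speed between spots, in mm per ms
#'   (default 10).
#' @slot calibrationCurrent nozzle current of the calibration anchor, in
#'   ampere (default 640e-9).
#' @slot calibrationSpdr spot peak dose rate at the calibration current, in
#'   Gy/s (default 2600).
#' @slot elementaryCharge elementary charge in coulomb.
#'
#' @seealso [machineModel()]
#' @export
setClass("MachineModel",
    representation(
        protonsPerMu = "numeric",
        minMuPerSpot = "numeric",
        dwellTimeMinMu = "numeric",
        scanSpeed = "numeric",
        calibrationCurrent = "numeric",
        calibrationSpdr = "numeric",
        elementaryCharge = "numeric"
    )
)

setValidity("MachineModel", function(object) {
    vals <- c(
        protonsPerMu = object@protonsPerMu,
        minMuPerSpot = object@minMuPerSpot,
        dwellTimeMinMu = object@dwellTimeMinMu,
        scanSpeed = object@scanSpeed,
        calibrationCurrent = object@calibrationCurrent,
        calibrationSpdr = object@calibrationSpdr,
        elementaryCharge = object@elementaryCharge
    )
    if (length(vals) != 7L || !all(vapply(
        slotNames(object),
        function(s) .scalar(slot(object, s)), logical(1)
    ))) {
        return("all machine parameters must be finite numeric scalars")
    }
    if (any(vals <= 0)) {
        bad <- names(vals)[vals <= 0]
        return(paste0(
            "machine parameters must be strictly positive: ",
            paste(bad, collapse = ", ")
        ))
    }
    TRUE
})

#' Construct a machine model
#'
#' Defaults reflect a ProBeam-class system in FLASH mode: ~5.17e6 protons per
#' MU for a high-energy transmission beam, a 2 ms minimum-MU spot dwell,
#' 10 mm/ms scanning speed, and a (640 nA, 2600 Gy/s) current-to-SPDR
#' calibration anchor at the machine's highest transmission.
#'
#' @param protonsPerMu protons per MU.
#' @param minMuPerSpot minimum MU per spot (plan-level setting).
#' @param dwellTimeMinMu seconds needed to deliver a minimum-MU spot.
#' @param scanSpeed lateral scan speed, mm per ms.
#' @param calibrationCurrent ampere.
#' @param calibrationSpdr Gy/s at `calibrationCurrent`.
#' @return A [MachineModel-class] object.
#' @examples
#' m <- machineModel(minMuPerSpot = 100)
#' spdrFromMinMu(m) # ~168 Gy/s
#' @export
machineModel <- function(protonsPerMu = 5.17e6,
                         minMuPerSpot = 100,
                         dwellTimeMinMu = 2e-3,
                         scanSpeed = 10,
                         calibrationCurrent = 640e-9,
                         calibrationSpdr = 2600) {
    new("MachineModel",
        protonsPerMu = protonsPerMu,
        minMuPerSpot = minMuPerSpot,
        dwellTimeMinMu = dwellTimeMinMu,
        scanSpeed = scanSpeed,
        calibrationCurrent = calibrationCurrent,
        calibrationSpdr = calibrationSpdr,
        elementaryCharge = 1.602176634e-19
    )
}

#' SpotMap: one scanned field's spot positions and weights
#'
#' An ordered list of pencil-beam spots for a single field, each with a
#' lateral position (mm, in the field's beam's-eye-view frame: x/y lateral,
#' beam along +z) and an MU weight. Row order is delivery order.
#'
#' @slot fieldId character label of the field.
#' @slot spots data.frame with numeric columns `x`, `y` (mm) and `mu` (MU),
#'   one row per spot, in delivery order.
#' @slot gantryAngle gantry angle in degrees (metadata for multi-field
#'   fixtures; the dose engine works in the field-local frame).
#' @seealso [spotMap()], [serpentineOrder()], [buildTimeline()]
#' @export
setClass("SpotMap",
    representation(
        fieldId = "character",
        spots = "data.frame",
        gantryAngle = "numeric"
    )
)

setValidity("SpotMap", function(object) {
    sp <- object@spots
    if (!all(c("x", "y", "mu") %in% names(sp))) {
        return("spots must have columns x, y, mu")
    }
    if (nrow(sp) < 1L) {
        return("a spot map must contain at least one spot")
    }
    if (!all(vapply(sp[c("x", "y", "mu")], is.numeric, logical(1)))) {
        return("spot columns x, y, mu must be numeric")
    }
    if (!all(is.finite(sp$x)) || !all(is.finite(sp$y))) {
        return("spot positions must be finite")
    }
    if (!all(is.finite(sp$mu)) || any(sp$mu <= 0)) {
        return("spot MU weights must be finite and positive")
    }
    if (length(object@fieldId) != 1L) {
        return("fieldId must be a single label")
    }
    TRUE
})

#' Construct a spot map
#'
#' @param x,y spot center coordinates in mm (beam's-eye-view frame).
#' @param mu MU weight per spot; recycled if scalar.
#' @param fieldId field label.
#' @param gantryAngle gantry angle in degrees (metadata).
#' @return A [SpotMap-class] object.
#' @examples
#' sm <- spotMap(x = c(0, 5), y = c(0, 0), mu = 100)
#' nSpots(sm)
#' @export
spotMap <- function(x, y, mu, fieldId = "field1", gantryAngle = 0) {
    n <- max(length(x), length(y))
    new("SpotMap",
        fieldId = as.character(fieldId),
        spots = data.frame(
            x = as.numeric(x), y = as.numeric(y),
            mu = rep_len(as.numeric(mu), n)
        ),
        gantryAngle = as.numeric(gantryAngle)
    )
}

#' DeliveryTimeline: per-spot start and end times
#'
#' The explicit delivery schedule of one field under raster scanning: each
#' spot occupies the interval `[tStart, tEnd]` (its dwell), consecutive spots
#' are separated by the lateral transit time (Euclidean distance divided by
#' the scan speed), and the first spot starts at t = 0. Fields are temporally
#' disjoint: each field carries its own time origin.
#'
#' @slot tStart,tEnd numeric vectors of per-spot interval bounds (seconds).
#' @slot totalTime total field delivery time in seconds (beam-on plus
#'   transit).
#' @seealso [buildTimeline()]
#' @export
setClass("DeliveryTimeline",
    representation(
        tStart = "numeric",
        tEnd = "numeric",
        totalTime = "numeric"
    )
)

setValidity("DeliveryTimeline", function(object) {
    ts <- object@tStart
    te <- object@tEnd
    if (length(ts) != length(te) || length(ts) < 1L) {
        return("tStart and tEnd must be non-empty and of equal length")
    }
    tol <- 1e-12
    if (any(te - ts <= 0)) {
        return("every dwell interval must have positive duration")
    }
    if (length(ts) > 1L && any(ts[-1L] - te[-length(te)] < -tol)) {
        return("spot intervals must be ordered and non-overlapping")
    }
    if (abs(ts[1L]) > tol) {
        return("the first spot must start at t = 0")
    }
    if (object@totalTime < te[length(te)] - tol) {
        return("totalTime must cover the last spot interval")
    }
    TRUE
})

#' GridGeometry: regular voxel lattice
#'
#' A regular, axis-aligned voxel grid in the field-local frame: x/y lateral,
#' z depth along the beam. `origin` is the center of voxel `[1,1,1]` in mm;
#' voxel centers are `origin + (index - 1) * spacing`. Linear voxel indices
#' follow R's column-major array order with axis order (x, y, z).
#'
#' @slot origin mm position of the first voxel center (3-vector).
#' @slot spacing mm per axis (3-vector; default 2 mm isotropic).
#' @slot shape voxel counts per axis (3 integers).
#' @seealso [gridGeometry()], [voxelCenters()]
#' @export
setClass("GridGeometry",
    representation(
        origin = "numeric",
        spacing = "numeric",
        shape = "integer"
    )
)

setValidity("GridGeometry", function(object) {
    if (length(object@origin) != 3L || !all(is.finite(object@origin))) {
        return("origin must be a finite 3-vector (mm)")
    }
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0)) {
        return("spacing must be a positive finite 3-vector (mm)")
    }
    if (length(object@shape) != 3L || any(object@shape < 1L)) {
        return("shape must contain at least one voxel per axis")
    }
    TRUE
})

#' Construct a voxel-grid geometry
#'
#' @param origin center of the first voxel, mm (3-vector).
#' @param spacing voxel spacing per axis, mm; a scalar is recycled.
#' @param shape number of voxels per axis (3 integers).
#' @return A [GridGeometry-class] object.
#' @examples
#' g <- gridGeometry(origin = c(-25, -25, 40), spacing = 2, shape = c(26, 26, 1))
#' nVoxels(g)
#' @export
gridGeometry <- function(origin, spacing = 2, shape) {
    new("GridGeometry",
        origin = as.numeric(origin),
        spacing = rep_len(as.numeric(spacing), 3L),
        shape = as.integer(shape)
    )
}

#' SpotKernel: lateral Gaussian and depth model of a transmission spot
#'
#' The single-spot dose-rate kernel: a lateral Gaussian of width sigma(z)
#' around the spot axis, multiplied by a slowly varying depth factor along
#' the beam. The kernel is normalized so that the on-axis rate at the
#' reference depth equals the layer's spot peak dose rate (SPDR); the
#' reference depth (default 40 mm) is where the SPDR of a transmission spot
#' is defined in water. sigma grows linearly with depth (multiple Coulomb
#' scattering); the depth factor decays linearly (protons scattered out of
#' the beam), both deliberate plateau-region simplifications for a
#' shoot-through beam whose Bragg peak lies beyond the phantom.
#'
#' @slot sigma0 lateral sigma at the surface, mm (default 4).
#' @slot sigmaGrowth sigma growth per mm depth (default 0.02).
#' @slot depthAttenuation fractional loss per mm depth (default 5e-4).
#' @slot peakDepthRef reference depth at which the on-axis rate equals the
#'   SPDR, mm (default 40).
#' @seealso [spotKernel()], [spotRateAt()]
#' @export
setClass("SpotKernel",
    representation(
        sigma0 = "numeric",
        sigmaGrowth = "numeric",
        depthAttenuation = "numeric",
        peakDepthRef = "numeric"
    )
)

setValidity("SpotKernel", function(object) {
    ok <- .scalar(object@sigma0) && .scalar(object@sigmaGrowth) &&
        .scalar(object@depthAttenuation) && .scalar(object@peakDepthRef)
    if (!ok) return("kernel parameters must be finite numeric scalars")
    if (object@sigma0 <= 0) return("sigma0 must be positive")
    if (object@sigmaGrowth < 0) return("sigmaGrowth must be non-negative")
    if (object@depthAttenuation < 0 || object@depthAttenuation >= 1) {
        return("depthAttenuation must lie in [0, 1) per mm")
    }
    if (object@peakDepthRef < 0) return("peakDepthRef must be non-negative")
    if (1 - object@depthAttenuation * object@peakDepthRef <= 0) {
        return("depth model must be positive at the reference depth")
    }
    TRUE
})

#' Construct a spot kernel
#'
#' @param sigma0 surface sigma, mm. The spot sigma of a ~240-250 MeV
#'   transmission beam typically lies in 3-6 mm; 4 mm is the default.
#' @param sigmaGrowth mm of sigma per mm of depth.
#' @param depthAttenuation fractional on-axis loss per mm of depth.
#' @param peakDepthRef mm; depth where the on-axis rate equals the SPDR.
#' @return A [SpotKernel-class] object.
#' @examples
#' k <- spotKernel()
#' spotRateAt(k, spdr = 1300, spotCenter = c(0, 0), voxelPos = c(0, 0, 40))
#' @export
spotKernel <- function(sigma0 = 4, sigmaGrowth = 0.02,
                       depthAttenuation = 5e-4, peakDepthRef = 40) {
    new("SpotKernel",
        sigma0 = sigma0, sigmaGrowth = sigmaGrowth,
        depthAttenuation = depthAttenuation, peakDepthRef = peakDepthRef
    )
}

#' InfluenceMatrix: sparse per-voxel spot contributions
#'
#' Houses, for every voxel j and spot i within the lateral cutoff, the
#' deposited dose D[j,i] (Gy) in a sparse voxel-by-spot matrix. Because a
#' spot delivers at a constant instantaneous rate during its dwell, the
#' instantaneous rate is recovered exactly as Ddot[j,i] = D[j,i] / dwell[i];
#' the consistency D = Ddot * dwell is an invariant of the discrete-spot
#' model, not an approximation.
#'
#' @slot dose sparse `dgCMatrix`, voxels (rows, linear grid index) by spots
#'   (columns, delivery order), entries in Gy.
#' @slot dwell per-spot dwell time, seconds.
#' @slot spdr the layer's spot peak dose rate (Ddot_max of the Gaussian
#'   kernel), Gy/s.
#' @slot geometry the [GridGeometry-class] the rows refer to.
#' @slot cutoffRadius lateral cutoff in multiples of sigma beyond which
#'   contributions are dropped.
#' @slot fieldId label of the originating field.
#' @seealso [buildInfluence()], [influenceEntries()], [totalDose()]
#' @export
setClass("InfluenceMatrix",
    representation(
        dose = "dgCMatrix",
        dwell = "numeric",
        spdr = "numeric",
        geometry = "GridGeometry",
        cutoffRadius = "numeric",
        fieldId = "character"
    )
)

setValidity("InfluenceMatrix", function(object) {
    if (ncol(object@dose) != length(object@dwell)) {
        return("dwell must have one entry per spot column")
    }
    if (any(object@dwell <= 0)) return("dwell times must be positive")
    if (nrow(object@dose) != prod(object@geometry@shape)) {
        return("dose rows must match the voxel count of the geometry")
    }
    if (any(object@dose@x < 0)) return("dose entries must be non-negative")
    if (!.scalar(object@cutoffRadius) || object@cutoffRadius <= 0) {
        return("cutoffRadius must be a positive scalar")
    }
    TRUE
})

#' VoxelGrid, DoseGrid and DoseRateGrid: scalar fields on a voxel lattice
#'
#' `DoseGrid` holds doses in Gy, `DoseRateGrid` dose rates in Gy/s, both as
#' 3D arrays on a [GridGeometry-class]. Voxels where a dose-rate metric is
#' undefined (zero dose; total dose not exceeding twice the ADR threshold;
#' no spot above the DTDR threshold) are `NA` under the default
#' "exclude" policy so they never enter a histogram.
#'
#' @slot values 3D numeric array, axis order (x, y, z).
#' @slot geometry the grid geometry.
#' @slot metric for `DoseRateGrid`: which metric produced it
#'   ("dadr", "adr", "dtdr" or "").
#' @aliases DoseGrid-class DoseRateGrid-class
#' @export
setClass("VoxelGrid",
    representation(
        values = "array",
        geometry = "GridGeometry",
        "VIRTUAL"
    )
)

setValidity("VoxelGrid", function(object) {
    if (!identical(dim(object@values), as.integer(object@geometry@shape))) {
        return("values array must have the geometry's shape")
    }
    TRUE
})

#' @rdname VoxelGrid-class
#' @export
setClass("DoseGrid", contains = "VoxelGrid")

#' @rdname VoxelGrid-class
#' @export
setClass("DoseRateGrid", contains = "VoxelGrid",
    representation(metric = "character")
)

.doseGrid <- function(values, geometry) {
    new("DoseGrid", values = values, geometry = geometry)
}

.doseRateGrid <- function(values, geometry, metric = "") {
    new("DoseRateGrid", values = values, geometry = geometry, metric = metric)
}

#' MetricConfig: thresholds of the dose-rate metrics
#'
#' @slot adrDoseThreshold d* in Gy trimming the ADR irradiation window
#'   (default 0.1 Gy).
#' @slot dtdrDoseThreshold d* in Gy qualifying spots for DTDR (default
#'   0.1 Gy). The two thresholds default to the same value but are
#'   independent settings.
#' @slot flashRateThreshold Gy/s; the conventional FLASH threshold used for
#'   V40Gy/s-type coverage statistics (default 40).
#' @slot undefinedPolicy "exclude" (undefined voxels become `NA` and are
#'   dropped from histograms) or "zero" (assigned 0 Gy/s).
#' @seealso [metricConfig()]
#' @export
setClass("MetricConfig",
    representation(
        adrDoseThreshold = "numeric",
        dtdrDoseThreshold = "numeric",
        flashRateThreshold = "numeric",
        undefinedPolicy = "character"
    )
)

setValidity("MetricConfig", function(object) {
    if (object@adrDoseThreshold < 0 || object@dtdrDoseThreshold < 0 ||
        object@flashRateThreshold < 0) {
        return("thresholds must be non-negative")
    }
    if (!object@undefinedPolicy %in% c("exclude", "zero")) {
        return('undefinedPolicy must be "exclude" or "zero"')
    }
    TRUE
})

#' Construct a metric configuration
#'
#' @param adrDoseThreshold Gy; dose threshold d* trimming the ADR window.
#' @param dtdrDoseThreshold Gy; per-spot dose threshold d* for DTDR.
#' @param flashRateThreshold Gy/s; coverage threshold for V40Gy/s-type
#'   statistics.
#' @param undefinedPolicy "exclude" or "zero"; what to do with voxels where
#'   a metric is undefined.
#' @return A [MetricConfig-class] object.
#' @export
metricConfig <- function(adrDoseThreshold = 0.1, dtdrDoseThreshold = 0.1,
                         flashRateThreshold = 40,
                         undefinedPolicy = c("exclude", "zero")) {
    new("MetricConfig",
        adrDoseThreshold = adrDoseThreshold,
        dtdrDoseThreshold = dtdrDoseThreshold,
        flashRateThreshold = flashRateThreshold,
        undefinedPolicy = match.arg(undefinedPolicy)
    )
}

#' VolumeHistogram: cumulative DVH or DRVH
#'
#' A cumulative volume histogram over a structure's voxels: for each bin
#' edge v, the fraction of evaluated voxels whose value is >= v. Summary
#' statistics (V40Gy/s, D2%, Dmax) are computed from the raw voxel values
#' retained in the object, not from the rebinned curve, to avoid binning
#' bias. Only voxels where the underlying metric is defined enter the
#' histogram.
#'
#' @slot kind "dose" (Gy) or "dose-rate" (Gy/s).
#' @slot breaks bin edges (Gy or Gy/s), starting at 0.
#' @slot cumFraction cumulative volume fraction at each bin edge, in [0, 1],
#'   non-increasing.
#' @slot values raw voxel values backing the curve.
#' @slot nVoxels number of evaluated voxels.
#' @slot label structure / metric label.
#' @seealso [buildHistogram()], [vAtRate()], [dAtVolume()], [poolFields()]
#' @export
setClass("VolumeHistogram",
    representation(
        kind = "character",
        breaks = "numeric",
        cumFraction = "numeric",
        values = "numeric",
        nVoxels = "integer",
        label = "character"
    )
)

setValidity("VolumeHistogram", function(object) {
    if (!object@kind %in% c("dose", "dose-rate")) {
        return('kind must be "dose" or "dose-rate"')
    }
    if (length(object@breaks) != length(object@cumFraction)) {
        return("breaks and cumFraction must align")
    }
    cf <- object@cumFraction
    if (length(cf)) {
        if (any(diff(cf) > 1e-12)) {
            return("cumulative curve must be non-increasing")
        }
        if (any(cf < -1e-12 | cf > 1 + 1e-12)) {
            return("cumulative fractions must lie in [0, 1]")
        }
    }
    if (object@nVoxels < 1L) {
        return("a histogram needs at least one evaluated voxel")
    }
    TRUE
})
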