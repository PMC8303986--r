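#' @include histograms.R
#' @importFrom stats runif
NULL

# run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

# centered 1D lattice covering `extent` mm at `spacing` mm
.latticeAxis <- function(extent, spacing) {
    n <- floor(extent / spacing + 1e-9) + 1L
    (seq_len(n) - 1L) * spacing - (n - 1L) * spacing / 2
}

#' Uniform minimum-MU benchmark field
#'
#' A regular lattice of minimum-MU spots covering a rectangular field,
#' serpentine-ordered. The default reproduces the water-phantom benchmark:
#' a 5 x 5 cm^2 field at 5 mm spot spacing, i.e. an 11 x 11 lattice of 121
#' spots centered on the beam axis. Uniform minimum-MU weights are the
#' configuration in which the layer's SPDR and the spot dwell are both
#' machine-determined.
#'
#' @param model a [MachineModel-class]; spots carry its minimum MU.
#' @param fieldSize field extent (x, y) in mm (default c(50, 50)).
#' @param spacing spot spacing in mm (default 5).
#' @param fieldId field label.
#' @param gantryAngle degrees (metadata).
#' @return A serpentine-ordered [SpotMap-class].
#' @examples
#' nSpots(makeUniformField(machineModel())) # 121
#' @export
makeUniformField <- function(model, fieldSize = c(50, 50), spacing = 5,
                             fieldId = "benchmark", gantryAngle = 0) {
    stopifnot(is(model, "MachineModel"), spacing > 0, all(fieldSize >= 0))
    fieldSize <- rep_len(fieldSize, 2L)
    g <- expand.grid(
        x = .latticeAxis(fieldSize[1L], spacing),
        y = .latticeAxis(fieldSize[2L], spacing)
    )
    ord <- serpentineOrder(g)
    spotMap(g$x[ord], g$y[ord],
        mu = model@minMuPerSpot,
        fieldId = fieldId, gantryAngle = gantryAngle
    )
}

#' Single-spot field
#'
#' One spot at the lateral origin — the configuration used to define the
#' spot peak dose rate (the on-axis maximum near the reference depth in
#' water).
#'
#' @param mu MU weight; must be at least the machine minimum.
#' @param model a [MachineModel-class].
#' @param fieldId field label.
#' @return A [SpotMap-class] with one spot.
#' @export
makeSingleSpot <- function(mu, model, fieldId = "single-spot") {
    stopifnot(is(model, "MachineModel"))
    if (mu < model@minMuPerSpot) {
        stop(
            "undeliverable spot: ", mu, " MU is below the minimum of ",
            model@minMuPerSpot, " MU per spot"
        )
    }
    spotMap(0, 0, mu = mu, fieldId = fieldId)
}

#' Synthetic multi-field cylinder phantom
#'
#' A stand-in for patient anatomy: `nFields` transmission fields at equally
#' spaced gantry angles (72 degrees apart for the default five-field
#' arrangement), each covering the beam's-eye-view footprint of a cylinder
#' (radius x length, axis along the couch) with minimum-MU spots. Each
#' field's spot map lives in its own beam's-eye-view frame; the gantry angle
#' is carried as metadata. Optional multiplicative MU jitter (always >= the
#' minimum MU) produces randomized variants, deterministic for a given
#' seed. This phantom is synthetic and illustrative: it makes no claim of
#' reproducing any patient geometry.
#'
#' @param model a [MachineModel-class].
#' @param nFields number of fields (default 5).
#' @param radius cylinder radius in mm (default 40).
#' @param length cylinder length in mm (default 60).
#' @param spacing spot spacing in mm (default 5).
#' @param muJitter non-negative fraction: spot MU is drawn uniformly from
#'   `[minMU, minMU * (1 + muJitter)]` (default 0 = uniform minimum MU).
#' @param seed RNG seed for the jitter.
#' @return list of [SpotMap-class] objects, one per field.
#' @examples
#' maps <- makeMultifieldCylinder(machineModel())
#' vapply(maps, function(m) m@gantryAngle, numeric(1)) # 0 72 144 216 288
#' @export
makeMultifieldCylinder <- function(model, nFields = 5, radius = 40,
                                   length = 60, spacing = 5,
                                   muJitter = 0, seed = 1) {
    stopifnot(
        is(model, "MachineModel"), nFields >= 1, radius > 0, length > 0,
        spacing > 0, muJitter >= 0
    )
    angles <- (seq_len(nFields) - 1L) * 360 / nFields
    .withSeed(seed, lapply(seq_len(nFields), function(f) {
        g <- expand.grid(
            x = .latticeAxis(2 * radius, spacing),
            y = .latticeAxis(length, spacing)
        )
        ord <- serpentineOrder(g)
        mu <- model@minMuPerSpot *
            (1 + runif(nrow(g), 0, muJitter))
        spotMap(g$x[ord], g$y[ord],
            mu = mu[ord],
            fieldId = sprintf("field%02d", f),
            gantryAngle = angles[f]
        )
    }))
}

#' Default voxel geometry for the water-phantom benchmark
#'
#' A 2 mm isotropic grid covering the benchmark field laterally with an
#' 8 mm margin beyond the spot lattice (enough for the 3.5-sigma influence
#' cutoff to decay) and a depth range bracketing the SPDR reference depth,
#' with a voxel plane centered exactly at that depth.
#'
#' @param fieldSize lateral field extent (x, y) in mm.
#' @param margin lateral margin beyond the field edge, mm.
#' @param depthRange depth interval (z) covered in mm.
#' @param spacing voxel spacing, mm.
#' @return A [GridGeometry-class].
#' @export
benchmarkGeometry <- function(fieldSize = c(50, 50), margin = 8,
                              depthRange = c(32, 48), spacing = 2) {
    fieldSize <- rep_len(fieldSize, 2L)
    half <- fieldSize / 2 + margin
    nx <- 2L * floor(half[1L] / spacing) + 1L
    ny <- 2L * floor(half[2L] / spacing) + 1L
    nz <- floor((depthRange[2L] - depthRange[1L]) / spacing) + 1L
    gridGeometry(
        origin = c(
            -(nx - 1L) / 2 * spacing,
            -(ny - 1L) / 2 * spacing,
            depthRange[1L]
        ),
        spacing = spacing,
        shape = c(nx, ny, nz)
    )
}

#' Run the water-phantom benchmark end to end
#'
#' Builds the 5 x 5 cm^2, 5 mm-spacing uniform minimum-MU field, pins the
#' layer SPDR (1300 Gy/s by default, the benchmark's setting), constructs
#' the serpentine delivery timeline, computes DADR, ADR and DTDR on a 2 mm
#' grid, and evaluates the FLASH coverage V40Gy/s of each metric over the
#' field-footprint mask at the reference-depth slab.
#'
#' @param model a [MachineModel-class].
#' @param kernel a [SpotKernel-class].
#' @param cfg a [MetricConfig-class].
#' @param spdr layer SPDR override in Gy/s (default 1300).
#' @param geom optional [GridGeometry-class]; default [benchmarkGeometry()].
#' @return list with elements `map`, `timeline`, `influence`, `dose`,
#'   `metrics` (list of three [DoseRateGrid-class]), `mask`, `histograms`
#'   (per-metric DRVHs over the footprint) and `v40` (named vector of
#'   V40Gy/s percentages).
#' @examples
#' \donttest{
#' bm <- runBenchmark(machineModel())
#' bm$v40 # 100 100 100
#' }
#' @export
runBenchmark <- function(model = machineModel(), kernel = spotKernel(),
                         cfg = metricConfig(), spdr = 1300, geom = NULL) {
    map <- makeUniformField(model)
    if (is.null(geom)) geom <- benchmarkGeometry()
    timeline <- buildTimeline(map, model)
    infl <- buildInfluence(map, model, kernel, geom, spdrOverride = spdr)
    mets <- doseRateMetrics(infl, timeline, cfg)
    mask <- footprintMask(geom, map, depth = kernel@peakDepthRef)
    histos <- lapply(mets, buildHistogram, mask = mask)
    v40 <- vapply(histos, vAtRate, numeric(1),
        rate = cfg@flashRateThreshold
    )
    list(
        map = map, timeline = timeline, influence = infl,
        dose = totalDose(infl), metrics = mets, mask = mask,
        histograms = histos, v40 = v40
    )
}
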