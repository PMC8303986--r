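#' @include AllClasses.R
NULL

#' MU delivery rate of an energy layer
#'
#' The cyclotron beam current of a layer is fixed by the plan's minimum MU
#' per spot: a minimum-MU spot must be deliverable in the machine's
#' minimum-MU dwell time, so the layer delivers
#' `minMuPerSpot / dwellTimeMinMu` MU per second.
#'
#' @param model a [MachineModel-class].
#' @return MU per second.
#' @examples
#' muRate(machineModel(minMuPerSpot = 100)) # 5e4 MU/s
#' @export
setGeneric("muRate", function(model) standardGeneric("muRate"))

#' Spot peak dose rate implied by the minimum MU setting
#'
#' Converts the layer's MU rate into the spot peak dose rate (SPDR) through
#' the dose-per-MU constant k derived from the machine's calibration anchor
#' (the nozzle current at highest transmission and its SPDR). SPDR is the
#' layer's maximum instantaneous rate at a spot's axis at the reference
#' depth, and is linear in the minimum MU per spot.
#'
#' @param model a [MachineModel-class].
#' @return Gy/s.
#' @examples
#' spdrFromMinMu(machineModel(minMuPerSpot = 100)) # ~168 Gy/s
#' spdrFromMinMu(machineModel(minMuPerSpot = 400)) # ~673 Gy/s
#' @export
setGeneric("spdrFromMinMu", function(model) standardGeneric("spdrFromMinMu"))

#' Nozzle current implied by the minimum MU setting
#'
#' @param model a [MachineModel-class].
#' @return current in ampere.
#' @seealso [minMuFromCurrent()] for the inverse map.
#' @export
setGeneric("currentFromMinMu",
    function(model) standardGeneric("currentFromMinMu"))

#' Minimum MU per spot implied by a nozzle current
#'
#' Inverse of [currentFromMinMu()]: the minimum MU setting whose layer MU
#' rate corresponds to the given current.
#'
#' @param model a [MachineModel-class].
#' @param current nozzle current in ampere.
#' @return MU.
#' @export
setGeneric("minMuFromCurrent",
    function(model, current) standardGeneric("minMuFromCurrent"))

#' Dwell time of a spot
#'
#' At the layer's fixed beam current, delivery time scales linearly with the
#' spot's MU weight; a minimum-MU spot takes exactly the machine's
#' minimum-MU dwell time. Spots below the minimum MU are undeliverable.
#'
#' @param model a [MachineModel-class].
#' @param spotMu MU weight(s) of the spot(s); vectorized.
#' @return seconds.
#' @export
setGeneric("dwellTime", function(model, spotMu) standardGeneric("dwellTime"))

#' Build the delivery timeline of a field
#'
#' @param map a [SpotMap-class].
#' @param model a [MachineModel-class].
#' @return A [DeliveryTimeline-class].
#' @export
setGeneric("buildTimeline",
    function(map, model) standardGeneric("buildTimeline"))

#' @rdname accessors
#' @export
setGeneric("totalTime", function(x) standardGeneric("totalTime"))

#' Accessors for pbsflash objects
#'
#' `nSpots`, `spots`, `fieldId` inspect spot maps and influence matrices;
#' `totalTime`, `spotIntervals` inspect timelines; `gridValues`, `geometry`,
#' `nVoxels`, `voxelCenters` inspect grids and geometries; `histValues`,
#' `histCurve` inspect volume histograms.
#'
#' @param x,object the object to inspect.
#' @name accessors
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))

#' @rdname accessors
#' @export
setGeneric("spots", function(x) standardGeneric("spots"))

#' @rdname accessors
#' @export
setGeneric("fieldId", function(x) standardGeneric("fieldId"))

#' @rdname accessors
#' @export
setGeneric("spotIntervals", function(x) standardGeneric("spotIntervals"))

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname accessors
#' @export
setGeneric("voxelCenters", function(x) standardGeneric("voxelCenters"))

#' @rdname accessors
#' @export
setGeneric("histValues", function(x) standardGeneric("histValues"))

#' @rdname accessors
#' @export
setGeneric("histCurve", function(x) standardGeneric("histCurve"))

#' Total dose grid from an influence matrix
#'
#' Sums each voxel's spot contributions into the field's physical dose.
#'
#' @param x an [InfluenceMatrix-class].
#' @return A [DoseGrid-class] (Gy).
#' @export
setGeneric("totalDose", function(x) standardGeneric("totalDose"))

#' Dose-averaged dose rate (DADR)
#'
#' Per voxel, the dose-weighted mean of the instantaneous rates of all
#' contributing spots: sum_i(D[j,i] * Ddot[j,i]) / sum_i(D[j,i]). DADR
#' ignores delivery timing entirely — the same spots give the same DADR no
#' matter how long the delivery takes. Voxels with zero dose are undefined.
#'
#' @param x an [InfluenceMatrix-class].
#' @param cfg a [MetricConfig-class] (controls the undefined-voxel policy).
#' @return A [DoseRateGrid-class].
#' @export
setGeneric("dadr", function(x, cfg = metricConfig()) standardGeneric("dadr"))

#' Averaged dose rate (ADR)
#'
#' Per voxel, the dose-threshold-trimmed average rate
#' `(D_j - 2 d*) / (t1 - t0)`, where the cumulative dose d_j(t) — built from
#' the delivery timeline, accruing linearly during each contributing spot's
#' dwell and flat during scan transits — satisfies d_j(t0) = d* and
#' d_j(t1) = D_j - d*. ADR is the only one of the three metrics sensitive to
#' spot dwell and scanning time. Voxels with D_j <= 2 d* are undefined.
#'
#' @param x an [InfluenceMatrix-class].
#' @param timeline the field's [DeliveryTimeline-class].
#' @param cfg a [MetricConfig-class]; `adrDoseThreshold` is d*.
#' @return A [DoseRateGrid-class].
#' @export
setGeneric("adr",
    function(x, timeline, cfg = metricConfig()) standardGeneric("adr"))

#' Dose-threshold dose rate (DTDR)
#'
#' Per voxel, the minimum instantaneous rate among spots whose individual
#' dose contribution to the voxel exceeds d*; spots depositing no more than
#' d* (the Gaussian low-dose tails) are excluded. Timing-independent.
#' Voxels with no qualifying spot are undefined.
#'
#' @param x an [InfluenceMatrix-class].
#' @param cfg a [MetricConfig-class]; `dtdrDoseThreshold` is d*.
#' @return A [DoseRateGrid-class].
#' @export
setGeneric("dtdr", function(x, cfg = metricConfig()) standardGeneric("dtdr"))

#' Per-voxel influence entries
#'
#' @param x an [InfluenceMatrix-class].
#' @param voxel linear voxel index (single integer).
#' @return data.frame with columns `spot`, `dose` (Gy), `rate` (Gy/s) for
#'   the spots contributing to that voxel.
#' @export
setGeneric("influenceEntries",
    function(x, voxel) standardGeneric("influenceEntries"))

#' Build a cumulative volume histogram (DVH / DRVH)
#'
#' @param x a [DoseGrid-class] or [DoseRateGrid-class].
#' @param mask logical array or vector selecting the evaluated voxels
#'   (default: all). Voxels where the metric is undefined (`NA`) are always
#'   excluded.
#' @param binWidth bin width; defaults to 0.1 Gy for dose and 1 Gy/s for
#'   dose-rate histograms.
#' @param label structure / metric label carried into the object.
#' @return A [VolumeHistogram-class].
#' @export
setGeneric("buildHistogram",
    function(x, mask = NULL, binWidth = NULL, label = "") {
        standardGeneric("buildHistogram")
    })

#' Volume fraction at or above a dose rate
#'
#' The coverage statistic V_rate: the percentage of the evaluated volume
#' receiving at least the queried dose rate; V40Gy/s is the conventional
#' FLASH coverage index.
#'
#' @param h a dose-rate [VolumeHistogram-class].
#' @param rate Gy/s.
#' @return percent in [0, 100].
#' @export
setGeneric("vAtRate", function(h, rate) standardGeneric("vAtRate"))

#' Dose at a volume fraction
#'
#' The DVH statistic D_v%: the minimum dose received by the hottest v% of
#' the structure (D2% is the conventional hot-spot indicator). Computed from
#' raw voxel values with linear interpolation.
#'
#' @param h a dose [VolumeHistogram-class].
#' @param volumePercent percent in (0, 100].
#' @return Gy.
#' @export
setGeneric("dAtVolume",
    function(h, volumePercent) standardGeneric("dAtVolume"))

#' Pool per-field histograms into a plan-level curve
#'
#' Plan-level DRVHs are sampled from all fields with multiplicity: a voxel
#' irradiated by k fields contributes k samples (voxel-count-weighted union
#' of the per-field samples), matching per-field dose-rate reporting. This
#' differs from conventions that combine fields per-voxel before
#' histogramming.
#'
#' @param histos list of [VolumeHistogram-class] objects of the same kind.
#' @param label label for the pooled histogram.
#' @return A [VolumeHistogram-class].
#' @export
setGeneric("poolFields",
    function(histos, label = "plan") standardGeneric("poolFields"))
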