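#' @include io.R
NULL

setMethod("show", "MachineModel", function(object) {
    cat("MachineModel\n")
    cat(sprintf("  protons per MU : %.3g\n", object@protonsPerMu))
    cat(sprintf("  min MU / spot  : %g MU\n", object@minMuPerSpot))
    cat(sprintf(
        "  min-MU dwell   : %g ms\n", object@dwellTimeMinMu * 1e3
    ))
    cat(sprintf("  scan speed     : %g mm/ms\n", object@scanSpeed))
    cat(sprintf(
        "  calibration    : %.3g nA <-> %g Gy/s\n",
        object@calibrationCurrent * 1e9, object@calibrationSpdr
    ))
    cat(sprintf(
        "  derived        : %.4g Gy/MU, SPDR %.4g Gy/s, current %.4g nA\n",
        dosePerMu(object), spdrFromMinMu(object),
        currentFromMinMu(object) * 1e9
    ))
})

setMethod("show", "SpotMap", function(object) {
    cat(sprintf(
        "SpotMap '%s': %d spots, gantry %g deg, %.4g MU total\n",
        object@fieldId, nrow(object@spots), object@gantryAngle,
        sum(object@spots$mu)
    ))
    cat(sprintf(
        "  x in [%g, %g] mm, y in [%g, %g] mm\n",
        min(object@spots$x), max(object@spots$x),
        min(object@spots$y), max(object@spots$y)
    ))
})

setMethod("show", "DeliveryTimeline", function(object) {
    cat(sprintf(
        "DeliveryTimeline: %d spots, total %.4g ms (beam-on %.4g ms)\n",
        length(object@tStart), object@totalTime * 1e3,
        sum(object@tEnd - object@tStart) * 1e3
    ))
})

setMethod("show", "GridGeometry", function(object) {
    cat(sprintf(
        "GridGeometry: %d x %d x %d voxels, %g x %g x %g mm spacing\n",
        object@shape[1L], object@shape[2L], object@shape[3L],
        object@spacing[1L], object@spacing[2L], object@spacing[3L]
    ))
    cat(sprintf(
        "  first voxel center at (%g, %g, %g) mm\n",
        object@origin[1L], object@origin[2L], object@origin[3L]
    ))
})

setMethod("show", "SpotKernel", function(object) {
    cat(sprintf(
        paste0(
            "SpotKernel: sigma %g mm + %g mm/mm depth, ",
            "attenuation %g /mm, reference depth %g mm\n"
        ),
        object@sigma0, object@sigmaGrowth, object@depthAttenuation,
        object@peakDepthRef
    ))
})

setMethod("show", "InfluenceMatrix", function(object) {
    cat(sprintf(
        paste0(
            "InfluenceMatrix '%s': %d voxels x %d spots, ",
            "%d entries, SPDR %.4g Gy/s, cutoff %.2g sigma\n"
        ),
        object@fieldId, nrow(object@dose), ncol(object@dose),
        length(object@dose@x), object@spdr, object@cutoffRadius
    ))
})

setMethod("show", "DoseGrid", function(object) {
    v <- object@values
    cat(sprintf(
        "DoseGrid: %s voxels, dose [%.4g, %.4g] Gy\n",
        paste(dim(v), collapse = " x "),
        min(v, na.rm = TRUE), max(v, na.rm = TRUE)
    ))
})

setMethod("show", "DoseRateGrid", function(object) {
    v <- object@values
    lab <- if (nzchar(object@metric)) toupper(object@metric) else "dose rate"
    cat(sprintf(
        "DoseRateGrid (%s): %s voxels, %d defined, rate [%.4g, %.4g] Gy/s\n",
        lab, paste(dim(v), collapse = " x "), sum(!is.na(v)),
        min(v, na.rm = TRUE), max(v, na.rm = TRUE)
    ))
})

setMethod("show", "MetricConfig", function(object) {
    cat(sprintf(
        paste0(
            "MetricConfig: ADR d* = %g Gy, DTDR d* = %g Gy, ",
            "FLASH threshold %g Gy/s, undefined -> %s\n"
        ),
        object@adrDoseThreshold, object@dtdrDoseThreshold,
        object@flashRateThreshold, object@undefinedPolicy
    ))
})

setMethod("show", "VolumeHistogram", function(object) {
    cat(sprintf(
        "VolumeHistogram (%s%s): %d voxels, values [%.4g, %.4g]\n",
        object@kind,
        if (nzchar(object@label)) paste0(", ", object@label) else "",
        object@nVoxels, min(object@values), max(object@values)
    ))
})
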