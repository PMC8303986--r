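#' @include dose-engine.R
NULL

# fill value for voxels where a metric is undefined
.undefinedFill <- function(cfg) {
    if (cfg@undefinedPolicy == "zero") 0 else NA_real_
}

# triplet view of the sparse dose matrix: voxel / spot / dose vectors
.influenceTriplets <- function(x) {
    tm <- as(x@dose, "TsparseMatrix")
    list(vox = tm@i + 1L, spot = tm@j + 1L, dose = tm@x)
}

#' @rdname dadr
setMethod("dadr", "InfluenceMatrix", function(x, cfg = metricConfig()) {
    stopifnot(is(cfg, "MetricConfig"))
    rateM <- x@dose %*% Diagonal(x = 1 / x@dwell)
    num <- rowSums(x@dose * rateM)
    den <- rowSums(x@dose)
    vals <- rep(.undefinedFill(cfg), length(den))
    ok <- den > 0
    vals[ok] <- num[ok] / den[ok]
    .doseRateGrid(array(vals, dim = x@geometry@shape), x@geometry, "dadr")
})

#' @rdname adr
setMethod("adr", signature("InfluenceMatrix", "DeliveryTimeline"),
    function(x, timeline, cfg = metricConfig()) {
        stopifnot(is(cfg, "MetricConfig"))
        if (length(timeline@tStart) != ncol(x@dose)) {
            stop("timeline and influence matrix refer to different spot counts")
        }
        dstar <- cfg@adrDoseThreshold
        tr <- .influenceTriplets(x)
        Dj <- rowSums(x@dose)
        vals <- rep(.undefinedFill(cfg), length(Dj))

        definedVox <- which(Dj > 2 * dstar)
        if (length(definedVox)) {
            # per-voxel entry lists, grouped in ascending voxel order
            uvox <- sort(unique(tr$vox))
            groups <- split(
                seq_along(tr$vox),
                factor(tr$vox, levels = uvox)
            )
            pos <- match(definedVox, uvox)
            ts <- timeline@tStart
            te <- timeline@tEnd
            for (g in seq_along(definedVox)) {
                j <- definedVox[g]
                k <- groups[[pos[g]]]
                s <- tr$spot[k]
                o <- order(ts[s], method = "radix")
                s <- s[o]
                ds <- tr$dose[k][o]
                cumEnd <- cumsum(ds)
                total <- cumEnd[length(cumEnd)]
                if (any(ds < 0) || total <= 2 * dstar) {
                    stop("non-monotone cumulative dose function at voxel ", j)
                }
                cumBefore <- cumEnd - ds
                rate <- ds / (te[s] - ts[s])
                t0 <- .crossingTime(dstar, ts[s], cumBefore, cumEnd, rate)
                t1 <- .crossingTime(
                    total - dstar, ts[s], cumBefore, cumEnd, rate
                )
                vals[j] <- (total - 2 * dstar) / (t1 - t0)
            }
        }
        .doseRateGrid(array(vals, dim = x@geometry@shape), x@geometry, "adr")
    })

# earliest time at which the piecewise-linear cumulative dose reaches
# `target`: linear interpolation within the active dwell segment
.crossingTime <- function(target, tStart, cumBefore, cumEnd, rate) {
    n <- length(cumEnd)
    k <- findInterval(target, cumEnd, left.open = TRUE) + 1L
    if (k > n) k <- n # guard against float round-off at the total dose
    tStart[k] + max(0, target - cumBefore[k]) / rate[k]
}

#' @rdname dtdr
setMethod("dtdr", "InfluenceMatrix", function(x, cfg = metricConfig()) {
    stopifnot(is(cfg, "MetricConfig"))
    dstar <- cfg@dtdrDoseThreshold
    tr <- .influenceTriplets(x)
    qual <- tr$dose > dstar
    vals <- rep(.undefinedFill(cfg), nrow(x@dose))
    if (any(qual)) {
        vq <- tr$vox[qual]
        rq <- tr$dose[qual] / x@dwell[tr$spot[qual]]
        o <- order(vq, rq, method = "radix")
        first <- !duplicated(vq[o])
        vals[vq[o][first]] <- rq[o][first]
    }
    .doseRateGrid(array(vals, dim = x@geometry@shape), x@geometry, "dtdr")
})

#' Compute all three dose-rate metrics of a field
#'
#' Convenience wrapper running [dadr()], [adr()] and [dtdr()] on one
#' influence matrix.
#'
#' @param x an [InfluenceMatrix-class].
#' @param timeline the field's [DeliveryTimeline-class].
#' @param cfg a [MetricConfig-class].
#' @return named list of [DoseRateGrid-class] objects
#'   (`dadr`, `adr`, `dtdr`).
#' @export
doseRateMetrics <- function(x, timeline, cfg = metricConfig()) {
    list(
        dadr = dadr(x, cfg),
        adr = adr(x, timeline, cfg),
        dtdr = dtdr(x, cfg)
    )
}
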