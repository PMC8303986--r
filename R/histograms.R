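#' @include metrics.R
#' @importFrom stats quantile
#' @importFrom grDevices chull
NULL

.gridKind <- function(x) if (is(x, "DoseRateGrid")) "dose-rate" else "dose"

.makeHistogram <- function(values, kind, binWidth, label) {
    if (is.null(binWidth)) binWidth <- if (kind == "dose") 0.1 else 1
    stopifnot(binWidth > 0)
    top <- max(values, 0)
    breaks <- seq(0, top + binWidth, by = binWidth)
    # cumulative: fraction of voxels at or above each bin edge
    cf <- 1 - (stats::ecdf(values)(breaks - binWidth * 1e-9))
    new("VolumeHistogram",
        kind = kind, breaks = breaks, cumFraction = cf,
        values = as.numeric(values), nVoxels = length(values),
        label = label
    )
}

#' @rdname buildHistogram
setMethod("buildHistogram", "VoxelGrid",
    function(x, mask = NULL, binWidth = NULL, label = "") {
        vals <- as.vector(x@values)
        keep <- !is.na(vals)
        if (!is.null(mask)) {
            mask <- as.vector(mask)
            if (length(mask) != length(vals)) {
                stop("mask must match the grid's voxel count")
            }
            keep <- keep & mask
        }
        if (!any(keep)) stop("mask selects no defined voxel")
        if (label == "" && is(x, "DoseRateGrid")) label <- x@metric
        .makeHistogram(vals[keep], .gridKind(x), binWidth, label)
    })

#' @rdname vAtRate
setMethod("vAtRate", "VolumeHistogram", function(h, rate) {
    if (h@kind != "dose-rate") {
        stop("vAtRate requires a dose-rate histogram")
    }
    stopifnot(rate >= 0)
    100 * mean(h@values >= rate)
})

#' @rdname dAtVolume
setMethod("dAtVolume", "VolumeHistogram", function(h, volumePercent) {
    if (h@kind != "dose") stop("dAtVolume requires a dose histogram")
    if (volumePercent <= 0 || volumePercent > 100) {
        stop("volumePercent must lie in (0, 100]")
    }
    quantile(h@values, probs = 1 - volumePercent / 100, names = FALSE)
})

#' @rdname poolFields
setMethod("poolFields", "list", function(histos, label = "plan") {
    stopifnot(length(histos) >= 1L)
    if (!all(vapply(histos, is, logical(1), "VolumeHistogram"))) {
        stop("poolFields expects a list of VolumeHistogram objects")
    }
    kinds <- vapply(histos, function(h) h@kind, character(1))
    if (length(unique(kinds)) != 1L) {
        stop("cannot pool histograms of mixed kinds")
    }
    bw <- diff(histos[[1L]]@breaks[1:2])
    .makeHistogram(
        unlist(lapply(histos, function(h) h@values), use.names = FALSE),
        kinds[1L], bw, label
    )
})

#' @rdname accessors
setMethod("histValues", "VolumeHistogram", function(x) x@values)

#' @rdname accessors
#' @details `histCurve` returns the cumulative curve as a data.frame with
#'   columns `bin_edge` and `cumulative_fraction`.
setMethod("histCurve", "VolumeHistogram", function(x) {
    data.frame(bin_edge = x@breaks, cumulative_fraction = x@cumFraction)
})

#' Summary statistics of a volume histogram
#'
#' For dose-rate histograms: the FLASH coverage V at `rateThreshold`
#' (percent of volume at or above the threshold, by default V40Gy/s), plus
#' mean, min and max rate. For dose histograms: D2% (hot-spot dose), Dmax
#' and mean dose. All statistics come from the raw voxel values.
#'
#' @param h a [VolumeHistogram-class].
#' @param rateThreshold Gy/s for the coverage index (default 40).
#' @param hotVolumePercent percent for the hot-spot dose (default 2).
#' @return named numeric vector.
#' @export
histStats <- function(h, rateThreshold = 40, hotVolumePercent = 2) {
    stopifnot(is(h, "VolumeHistogram"))
    if (h@kind == "dose-rate") {
        c(
            V = vAtRate(h, rateThreshold),
            mean = mean(h@values),
            min = min(h@values),
            max = max(h@values)
        )
    } else {
        c(
            D2 = dAtVolume(h, hotVolumePercent),
            Dmax = max(h@values),
            mean = mean(h@values)
        )
    }
}

#' Field-footprint voxel mask
#'
#' Selects the voxels whose lateral (x, y) center lies inside the convex
#' hull of the field's spot centers, within a depth slab around the
#' evaluation depth. This is the region over which benchmark coverage
#' statistics such as V40Gy/s are evaluated: the Gaussian tails extend
#' laterally without bound, so "percent of the volume" is only meaningful
#' over a defined footprint.
#'
#' @param geom a [GridGeometry-class].
#' @param map a [SpotMap-class] (or list of maps; the union of spots is
#'   used).
#' @param depth evaluation depth in mm (default 40, the SPDR reference
#'   depth).
#' @param halfWidth half-thickness of the depth slab in mm; defaults to half
#'   the z spacing (a single voxel plane when `depth` falls on a plane).
#' @return logical array of the geometry's shape.
#' @export
footprintMask <- function(geom, map, depth = 40, halfWidth = NULL) {
    stopifnot(is(geom, "GridGeometry"))
    maps <- if (is(map, "SpotMap")) list(map) else map
    sx <- unlist(lapply(maps, function(m) m@spots$x), use.names = FALSE)
    sy <- unlist(lapply(maps, function(m) m@spots$y), use.names = FALSE)
    if (is.null(halfWidth)) halfWidth <- geom@spacing[3L] / 2
    zc <- .axisCenters(geom, 3L)
    zin <- abs(zc - depth) <= halfWidth + 1e-9

    xs <- .axisCenters(geom, 1L)
    ys <- .axisCenters(geom, 2L)
    pts <- cbind(
        rep(xs, times = length(ys)),
        rep(ys, each = length(xs))
    )
    uxy <- unique(cbind(sx, sy))
    hullIdx <- chull(uxy)
    lateral <- if (length(hullIdx) >= 3L) {
        # grow the hull by a sliver so lattice points on the boundary count
        hull <- uxy[hullIdx, , drop = FALSE]
        ctr <- colMeans(hull)
        hull <- sweep(sweep(hull, 2, ctr, "-") * (1 + 1e-9), 2, ctr, "+")
        bnd <- rbind(hull, hull[1L, ])
        mgcv::in.out(bnd, pts)
    } else {
        # degenerate footprint (single spot or collinear row): bounding box
        pts[, 1L] >= min(sx) - 1e-9 & pts[, 1L] <= max(sx) + 1e-9 &
            pts[, 2L] >= min(sy) - 1e-9 & pts[, 2L] <= max(sy) + 1e-9
    }
    mask <- array(FALSE, dim = geom@shape)
    for (kz in which(zin)) {
        mask[, , kz] <- matrix(lateral, nrow = geom@shape[1L])
    }
    mask
}
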