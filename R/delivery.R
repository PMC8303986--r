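#' @include machine.R
NULL

#' Order spot positions for row-serpentine raster scanning
#'
#' Groups spots into rows of equal y, sorts rows by increasing y, and
#' traverses alternate rows in opposite x directions (first row
#' left-to-right). On a square lattice this minimizes lateral travel: every
#' hop is one spot spacing. Deterministic for tied coordinates: ties are
#' broken by x, then by input index.
#'
#' The scan pattern matters only for the ADR metric (which is scanning
#' direction-dependent); DADR and DTDR ignore timing.
#'
#' @param positions two-column matrix or data.frame of (x, y) in mm.
#' @param tol positions whose y differ by no more than `tol` mm belong to
#'   the same row (default 1e-6).
#' @return integer permutation such that `positions[order, ]` is in
#'   serpentine delivery order.
#' @examples
#' p <- expand.grid(x = c(0, 5), y = c(0, 5))
#' p[serpentineOrder(p), ]
#' @export
serpentineOrder <- function(positions, tol = 1e-6) {
    positions <- as.data.frame(positions)
    x <- as.numeric(positions[[1L]])
    y <- as.numeric(positions[[2L]])
    n <- length(x)
    if (n == 0L) return(integer(0))
    # row id: group y values within tol of each other
    oy <- order(y, method = "radix")
    rowId <- integer(n)
    rid <- 1L
    rowId[oy[1L]] <- rid
    if (n > 1L) {
        for (k in 2L:n) {
            if (y[oy[k]] - y[oy[k - 1L]] > tol) rid <- rid + 1L
            rowId[oy[k]] <- rid
        }
    }
    ord <- integer(0)
    for (r in seq_len(rid)) {
        idx <- which(rowId == r)
        idx <- idx[order(x[idx], idx, method = "radix")]
        if (r %% 2L == 0L) idx <- rev(idx)
        ord <- c(ord, idx)
    }
    ord
}

#' @rdname buildTimeline
#' @details The first spot starts at t = 0. Each spot dwells for
#'   `dwellTime(model, mu)`; consecutive spots are separated by the lateral
#'   Euclidean distance divided by the scan speed (inter-row repositioning
#'   uses the same speed). No dose is delivered during transits. Spots below
#'   the machine's minimum MU raise an undeliverable-spot error.
#' @examples
#' m <- machineModel(minMuPerSpot = 100)
#' tl <- buildTimeline(spotMap(c(0, 5), c(0, 0), 100), m)
#' totalTime(tl) # 4.5 ms
setMethod("buildTimeline", signature("SpotMap", "MachineModel"),
    function(map, model) {
        sp <- map@spots
        dw <- dwellTime(model, sp$mu)
        n <- nrow(sp)
        transit <- if (n > 1L) {
            hop <- sqrt(diff(sp$x)^2 + diff(sp$y)^2) # mm
            hop / model@scanSpeed / 1000 # mm / (mm/ms) -> s
        } else {
            numeric(0)
        }
        starts <- cumsum(c(0, dw[-n] + transit))
        new("DeliveryTimeline",
            tStart = starts,
            tEnd = starts + dw,
            totalTime = starts[n] + dw[n]
        )
    })

#' @rdname accessors
setMethod("totalTime", "DeliveryTimeline", function(x) x@totalTime)

#' @rdname accessors
setMethod("spotIntervals", "DeliveryTimeline", function(x) {
    data.frame(tStart = x@tStart, tEnd = x@tEnd)
})

#' @rdname accessors
setMethod("nSpots", "SpotMap", function(x) nrow(x@spots))

#' @rdname accessors
setMethod("spots", "SpotMap", function(x) x@spots)

#' @rdname accessors
setMethod("fieldId", "SpotMap", function(x) x@fieldId)

#' Reorder a spot map
#'
#' @param map a [SpotMap-class].
#' @param order integer permutation of the spots (e.g. from
#'   [serpentineOrder()]).
#' @return the reordered [SpotMap-class].
#' @export
reorderSpots <- function(map, order) {
    stopifnot(is(map, "SpotMap"))
    if (!setequal(order, seq_len(nSpots(map)))) {
        stop("order must be a permutation of the spot indices")
    }
    sp <- map@spots[order, , drop = FALSE]
    rownames(sp) <- NULL
    initialize(map, spots = sp)
}
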