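#' @include delivery.R
#' @importFrom Matrix sparseMatrix rowSums Diagonal drop0
NULL

#' @rdname accessors
setMethod("nVoxels", "GridGeometry", function(x) prod(x@shape))

#' @rdname accessors
setMethod("geometry", "VoxelGrid", function(x) x@geometry)

#' @rdname accessors
setMethod("geometry", "InfluenceMatrix", function(x) x@geometry)

#' @rdname accessors
setMethod("gridValues", "VoxelGrid", function(x) x@values)

#' @rdname accessors
setMethod("fieldId", "InfluenceMatrix", function(x) x@fieldId)

#' @rdname accessors
setMethod("nSpots", "InfluenceMatrix", function(x) ncol(x@dose))

# per-axis voxel center coordinates
.axisCenters <- function(geom, axis) {
    geom@origin[axis] + (seq_len(geom@shape[axis]) - 1) * geom@spacing[axis]
}

#' @rdname accessors
#' @details `voxelCenters` returns an `nVoxels x 3` matrix of voxel-center
#'   positions in mm, rows in linear (column-major, x fastest) index order.
setMethod("voxelCenters", "GridGeometry", function(x) {
    xs <- .axisCenters(x, 1L)
    ys <- .axisCenters(x, 2L)
    zs <- .axisCenters(x, 3L)
    cbind(
        x = rep(xs, times = length(ys) * length(zs)),
        y = rep(rep(ys, each = length(xs)), times = length(zs)),
        z = rep(zs, each = length(xs) * length(ys))
    )
})

# lateral sigma and on-axis depth factor of the kernel at depth z (mm);
# the depth factor is normalized to 1 at the reference depth
.sigmaAt <- function(kernel, z) kernel@sigma0 + kernel@sigmaGrowth * z

.depthFactorAt <- function(kernel, z) {
    raw <- pmax(0, 1 - kernel@depthAttenuation * z)
    raw / (1 - kernel@depthAttenuation * kernel@peakDepthRef)
}

#' Instantaneous dose rate of a single spot at a point
#'
#' Evaluates the pencil-beam kernel: the layer's spot peak dose rate (SPDR)
#' times a lateral Gaussian `exp(-r^2 / (2 sigma(z)^2))` around the spot
#' axis, times a depth factor normalized to 1 at the kernel's reference
#' depth. At the spot axis and reference depth the value is the SPDR
#' exactly; at r = 3 sigma the lateral factor is `exp(-4.5)`, about 1%.
#'
#' @param kernel a [SpotKernel-class].
#' @param spdr the layer's spot peak dose rate, Gy/s.
#' @param spotCenter lateral spot center (x, y) in mm.
#' @param voxelPos point(s) (x, y, z) in mm; a 3-vector or an n-by-3 matrix.
#' @return Gy/s (vectorized over rows of `voxelPos`).
#' @examples
#' k <- spotKernel()
#' spotRateAt(k, 1300, c(0, 0), c(3 * 4.8, 0, 40)) / 1300 # ~0.011
#' @export
spotRateAt <- function(kernel, spdr, spotCenter, voxelPos) {
    stopifnot(is(kernel, "SpotKernel"), spdr >= 0)
    p <- if (is.matrix(voxelPos)) voxelPos else matrix(voxelPos, ncol = 3L)
    r2 <- (p[, 1L] - spotCenter[1L])^2 + (p[, 2L] - spotCenter[2L])^2
    sig <- .sigmaAt(kernel, p[, 3L])
    spdr * .depthFactorAt(kernel, p[, 3L]) * exp(-r2 / (2 * sig^2))
}

#' Build the sparse influence matrix of a field
#'
#' Superposes the Gaussian pencil-beam kernel of every spot onto the voxel
#' grid and records, per voxel and spot, the deposited dose
#' `D[j,i] = Ddot[j,i] * dwell[i]`, with `Ddot[j,i]` the kernel rate at the
#' voxel center. All spots of a (single-energy) field share the layer's
#' SPDR, fixed by the machine's minimum-MU setting; a heavier spot delivers
#' more dose by dwelling longer at the same instantaneous rate.
#' Contributions beyond `cutoffRadius` sigma laterally are dropped (3.5
#' sigma keeps > 99.8% of the lateral integral).
#'
#' @param map a [SpotMap-class].
#' @param model a [MachineModel-class].
#' @param kernel a [SpotKernel-class].
#' @param geom a [GridGeometry-class] in the field-local frame (beam along
#'   +z).
#' @param spdrOverride optional Gy/s pinning the layer SPDR, bypassing the
#'   machine calibration (e.g. 1300 Gy/s for the water-phantom benchmark).
#' @param cutoffRadius lateral cutoff in multiples of sigma (default 3.5).
#' @return An [InfluenceMatrix-class].
#' @examples
#' m <- machineModel()
#' geom <- gridGeometry(c(0, 0, 40), 2, c(1, 1, 1))
#' infl <- buildInfluence(makeSingleSpot(100, m), m, spotKernel(), geom,
#'     spdrOverride = 1300)
#' influenceEntries(infl, 1) # rate 1300 Gy/s, dose 2.6 Gy
#' @export
buildInfluence <- function(map, model, kernel, geom,
                           spdrOverride = NULL, cutoffRadius = 3.5) {
    stopifnot(
        is(map, "SpotMap"), is(model, "MachineModel"),
        is(kernel, "SpotKernel"), is(geom, "GridGeometry")
    )
    sp <- map@spots
    if (nrow(sp) == 0L) stop("empty spot map")
    dw <- dwellTime(model, sp$mu)
    spdr <- if (is.null(spdrOverride)) spdrFromMinMu(model) else spdrOverride
    stopifnot(length(spdr) == 1L, spdr > 0)

    xs <- .axisCenters(geom, 1L)
    ys <- .axisCenters(geom, 2L)
    zs <- .axisCenters(geom, 3L)
    nx <- geom@shape[1L]
    nxy <- nx * geom@shape[2L]
    sig <- .sigmaAt(kernel, zs)
    dfz <- .depthFactorAt(kernel, zs)
    cut <- cutoffRadius * sig # lateral cutoff in mm, per z plane

    ii <- vector("list", nrow(sp))
    jj <- vector("list", nrow(sp))
    xx <- vector("list", nrow(sp))
    for (i in seq_len(nrow(sp))) {
        dx2 <- (xs - sp$x[i])^2
        dy2 <- (ys - sp$y[i])^2
        pieces <- vector("list", length(zs))
        for (kz in seq_along(zs)) {
            if (dfz[kz] <= 0) next
            c2 <- cut[kz]^2
            ix <- which(dx2 <= c2)
            iy <- which(dy2 <= c2)
            if (!length(ix) || !length(iy)) next
            r2 <- outer(dx2[ix], dy2[iy], "+")
            keep <- r2 <= c2
            if (!any(keep)) next
            rate <- spdr * dfz[kz] * exp(-r2[keep] / (2 * sig[kz]^2))
            lin <- outer(ix, (iy - 1L) * nx, "+")[keep] + (kz - 1L) * nxy
            pieces[[kz]] <- list(lin = lin, dose = rate * dw[i])
        }
        pieces <- pieces[!vapply(pieces, is.null, logical(1))]
        if (length(pieces)) {
            lin <- unlist(lapply(pieces, `[[`, "lin"), use.names = FALSE)
            ii[[i]] <- lin
            jj[[i]] <- rep.int(i, length(lin))
            xx[[i]] <- unlist(lapply(pieces, `[[`, "dose"), use.names = FALSE)
        }
    }
    iAll <- unlist(ii, use.names = FALSE)
    dose <- if (length(iAll)) {
        sparseMatrix(
            i = iAll,
            j = unlist(jj, use.names = FALSE),
            x = unlist(xx, use.names = FALSE),
            dims = c(prod(geom@shape), nrow(sp))
        )
    } else {
        new("dgCMatrix",
            Dim = as.integer(c(prod(geom@shape), nrow(sp))),
            p = rep(0L, nrow(sp) + 1L)
        )
    }
    new("InfluenceMatrix",
        dose = drop0(dose), dwell = dw, spdr = spdr,
        geometry = geom, cutoffRadius = cutoffRadius,
        fieldId = map@fieldId
    )
}

#' @rdname influenceEntries
setMethod("influenceEntries", "InfluenceMatrix", function(x, voxel) {
    stopifnot(length(voxel) == 1L, voxel >= 1L, voxel <= nrow(x@dose))
    row <- x@dose[voxel, ]
    idx <- which(row > 0)
    data.frame(
        spot = idx,
        dose = row[idx],
        rate = row[idx] / x@dwell[idx]
    )
})

#' @rdname totalDose
setMethod("totalDose", "InfluenceMatrix", function(x) {
    vals <- array(rowSums(x@dose), dim = x@geometry@shape)
    .doseGrid(vals, x@geometry)
})
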