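# shared objects and small builders for the test suite

mm100 <- machineModel(minMuPerSpot = 100)
mm400 <- machineModel(minMuPerSpot = 400)

# flat kernel (no depth variation): lateral Gaussian only, sigma constant,
# so hand-computed expectations need no depth bookkeeping
flatKernel <- function(sigma = 4) {
    spotKernel(
        sigma0 = sigma, sigmaGrowth = 0, depthAttenuation = 0,
        peakDepthRef = 40
    )
}

# single-plane lateral grid at the reference depth
planeGeometry <- function(xs, ys, z = 40, spacing = 2) {
    gridGeometry(
        origin = c(xs[1L], ys[1L], z),
        spacing = c(
            if (length(xs) > 1) diff(xs[1:2]) else spacing,
            if (length(ys) > 1) diff(ys[1:2]) else spacing,
            spacing
        ),
        shape = c(length(xs), length(ys), 1L)
    )
}

# hand-built influence matrix: `doses` is a dense voxels-by-spots matrix,
# `dwell` the per-spot dwell (s). Geometry is a dummy 1D voxel line.
tinyInfluence <- function(doses, dwell, spdr = 1000) {
    doses <- as.matrix(doses)
    geom <- gridGeometry(
        origin = c(0, 0, 40), spacing = 2,
        shape = c(nrow(doses), 1L, 1L)
    )
    idx <- which(doses != 0, arr.ind = TRUE)
    new("InfluenceMatrix",
        dose = Matrix::sparseMatrix(
            i = idx[, 1L], j = idx[, 2L], x = doses[idx],
            dims = dim(doses)
        ),
        dwell = dwell, spdr = spdr, geometry = geom,
        cutoffRadius = 3.5, fieldId = "tiny"
    )
}

# timeline from explicit intervals (seconds)
tinyTimeline <- function(tStart, tEnd) {
    new("DeliveryTimeline",
        tStart = tStart, tEnd = tEnd, totalTime = max(tEnd)
    )
}

# random small field for property tests: nSpots spots scattered over a
# 30 x 30 mm area with MU weights in [minMU, 3 minMU]
randomSpotMap <- function(nSpots = 20, model = mm100) {
    spotMap(
        x = runif(nSpots, -15, 15),
        y = runif(nSpots, -15, 15),
        mu = model@minMuPerSpot * (1 + 2 * runif(nSpots)),
        fieldId = "random"
    )
}

# small evaluation grid used with randomSpotMap: 3 x 3 voxels around the
# field center at the reference depth
randomMapGeometry <- function() {
    gridGeometry(origin = c(-8, -8, 40), spacing = 8, shape = c(3, 3, 1))
}
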