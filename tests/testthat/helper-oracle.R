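# independent oracles, deliberately naive: plain summation and fixed-step
# time integration, sharing no code with the package's computation paths

# brute-force ADR: accumulate each voxel's cumulative dose on a fixed time
# grid (default 1 us) and read the threshold crossings off the samples
bruteForceAdr <- function(entryDose, tStart, tEnd, dstar = 0.1, dt = 1e-6) {
    total <- sum(entryDose)
    if (total <= 2 * dstar) return(NA_real_)
    times <- seq(0, max(tEnd) + dt, by = dt)
    cum <- numeric(length(times))
    for (k in seq_along(entryDose)) {
        rate <- entryDose[k] / (tEnd[k] - tStart[k])
        cum <- cum + rate * pmin(pmax(times - tStart[k], 0), tEnd[k] - tStart[k])
    }
    t0 <- times[which(cum >= dstar)[1L]]
    t1 <- times[which(cum >= total - dstar)[1L]]
    (total - 2 * dstar) / (t1 - t0)
}

# brute-force single-field dose at a point: direct Gaussian summation over
# every spot, no cutoff, no sparse machinery
bruteForceDose <- function(map, model, kernel, spdr, point) {
    sp <- spots(map)
    dose <- 0
    for (i in seq_len(nrow(sp))) {
        sig <- kernel@sigma0 + kernel@sigmaGrowth * point[3L]
        depth <- (1 - kernel@depthAttenuation * point[3L]) /
            (1 - kernel@depthAttenuation * kernel@peakDepthRef)
        r2 <- (point[1L] - sp$x[i])^2 + (point[2L] - sp$y[i])^2
        rate <- spdr * depth * exp(-r2 / (2 * sig^2))
        dose <- dose + rate * sp$mu[i] /
            (model@minMuPerSpot / model@dwellTimeMinMu)
    }
    dose
}

# interpolated D-at-volume oracle from the sorted values, independent of
# stats::quantile
interpDoseAtVolume <- function(values, volumePercent) {
    v <- sort(values)
    n <- length(v)
    # position of the (1 - p/100) quantile on the sorted sample
    h <- (n - 1) * (1 - volumePercent / 100) + 1
    lo <- floor(h)
    hi <- ceiling(h)
    v[lo] + (h - lo) * (v[hi] - v[lo])
}
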