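test_that("spot kernel peaks at the axis and falls off as a Gaussian", {
    k <- flatKernel(sigma = 4)
    expect_equal(spotRateAt(k, 1300, c(0, 0), c(0, 0, 40)), 1300)
    # 1% of the peak at 3 sigma, exp(-2) at 2 sigma
    expect_equal(
        spotRateAt(k, 1300, c(0, 0), c(12, 0, 40)) / 1300,
        exp(-4.5)
    )
    expect_equal(round(spotRateAt(k, 1300, c(0, 0), c(12, 0, 40)) / 13, 1), 1.1)
    expect_equal(
        spotRateAt(k, 1300, c(0, 0), c(0, 8, 40)) / 1300,
        exp(-2)
    )
    # depth-aware kernel: on-axis rate at the reference depth is the SPDR
    kd <- spotKernel()
    expect_equal(spotRateAt(kd, 2600, c(0, 0), c(0, 0, 40)), 2600)
})

test_that("single-spot influence reproduces the SPDR and its dwell dose", {
    geom <- planeGeometry(xs = 0, ys = 0)
    infl <- buildInfluence(
        makeSingleSpot(100, mm100), mm100, flatKernel(), geom,
        spdrOverride = 1300
    )
    e <- influenceEntries(infl, 1)
    expect_equal(nrow(e), 1L)
    expect_equal(e$rate, 1300)
    expect_equal(e$dose, 2.6) # SPDR x 2 ms, the per-spot center dose
})

test_that("influence entries honor symmetry and the lateral cutoff", {
    # two identical spots 5 mm apart; voxel midway sees two equal entries
    map <- spotMap(c(-2.5, 2.5), c(0, 0), 100)
    geom <- planeGeometry(xs = 0, ys = 0)
    infl <- buildInfluence(map, mm100, flatKernel(4), geom,
        spdrOverride = 1300)
    e <- influenceEntries(infl, 1)
    expect_equal(nrow(e), 2L)
    expect_equal(e$rate[1], e$rate[2])
    expect_equal(e$rate[1], 1300 * exp(-2.5^2 / (2 * 16)))
    # a voxel 4 sigma from the only spot is outside the 3.5 sigma cutoff
    geomFar <- planeGeometry(xs = 16, ys = 0)
    inflFar <- buildInfluence(
        makeSingleSpot(100, mm100), mm100, flatKernel(4), geomFar,
        spdrOverride = 1300, cutoffRadius = 3.5
    )
    expect_equal(nrow(influenceEntries(inflFar, 1)), 0L)
    # a spot map cannot even be constructed empty
    expect_error(spotMap(numeric(0), numeric(0), numeric(0)), "at least one")
})

test_that("every influence entry satisfies dose = rate x dwell", {
    set.seed(3)
    map <- randomSpotMap(15)
    infl <- buildInfluence(map, mm100, spotKernel(), randomMapGeometry(),
        spdrOverride = 1300)
    dw <- dwellTime(mm100, spots(map)$mu)
    for (j in seq_len(nVoxels(geometry(infl)))) {
        e <- influenceEntries(infl, j)
        if (nrow(e)) expect_equal(e$dose, e$rate * dw[e$spot])
    }
})

test_that("total dose is linear in MU and additive over spots", {
    geom <- randomMapGeometry()
    set.seed(5)
    map <- randomSpotMap(10)
    d1 <- gridValues(totalDose(
        buildInfluence(map, mm100, spotKernel(), geom, spdrOverride = 1300)
    ))
    sp <- spots(map)
    doubled <- spotMap(sp$x, sp$y, 2 * sp$mu)
    d2 <- gridValues(totalDose(
        buildInfluence(doubled, mm100, spotKernel(), geom,
            spdrOverride = 1300)
    ))
    expect_equal(d2, 2 * d1)
    # additivity: splitting the map in two and summing reproduces the total
    a <- spotMap(sp$x[1:5], sp$y[1:5], sp$mu[1:5])
    b <- spotMap(sp$x[6:10], sp$y[6:10], sp$mu[6:10])
    da <- gridValues(totalDose(
        buildInfluence(a, mm100, spotKernel(), geom, spdrOverride = 1300)
    ))
    db <- gridValues(totalDose(
        buildInfluence(b, mm100, spotKernel(), geom, spdrOverride = 1300)
    ))
    expect_equal(da + db, d1)
})

test_that("benchmark dose agrees with brute-force Gaussian summation", {
    map <- makeUniformField(mm100)
    kernel <- spotKernel()
    geom <- planeGeometry(xs = c(-2, 0, 2), ys = c(-2, 0, 2))
    infl <- buildInfluence(map, mm100, kernel, geom, spdrOverride = 1300)
    dose <- gridValues(totalDose(infl))
    for (ij in list(c(1, 1), c(2, 2), c(3, 2))) {
        pt <- c((ij[1] - 2) * 2, (ij[2] - 2) * 2, 40)
        expect_equal(
            dose[ij[1], ij[2], 1],
            bruteForceDose(map, mm100, kernel, 1300, pt),
            tolerance = 5e-3 # oracle has no lateral cutoff
        )
    }
    # center dose is the 2.6 Gy per-spot peak times the lattice Gaussian sum
    expect_gt(dose[2, 2, 1], 2.6)
})

test_that("a symmetric spot map yields a laterally symmetric dose grid", {
    map <- makeUniformField(mm100)
    geom <- benchmarkGeometry(depthRange = c(38, 42))
    infl <- buildInfluence(map, mm100, spotKernel(), geom,
        spdrOverride = 1300)
    d <- gridValues(totalDose(infl))[, , 2]
    expect_equal(d, d[rev(seq_len(nrow(d))), ], tolerance = 1e-10)
    expect_equal(d, d[, rev(seq_len(ncol(d)))], tolerance = 1e-10)
})

test_that("on-axis dose rate attenuates monotonically beyond the
           reference depth", {
    geom <- gridGeometry(origin = c(0, 0, 40), spacing = c(2, 2, 4),
        shape = c(1, 1, 11))
    infl <- buildInfluence(makeSingleSpot(100, mm100), mm100, spotKernel(),
        geom, spdrOverride = 1300)
    prof <- as.vector(gridValues(totalDose(infl)))
    expect_true(all(diff(prof) < 0))
    expect_equal(prof[1], 2.6) # normalized at the reference depth
})
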