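test_that("DADR is the dose-weighted mean of contributing spot rates", {
    # (D = 2 Gy at 100 Gy/s) and (D = 1 Gy at 50 Gy/s):
    # (2*100 + 1*50) / 3 = 83.33 Gy/s
    infl <- tinyInfluence(
        doses = matrix(c(2, 1), nrow = 1),
        dwell = c(2 / 100, 1 / 50)
    )
    expect_equal(as.vector(gridValues(dadr(infl)))[1], 250 / 3)
    # a single contributing spot gives its own rate
    single <- tinyInfluence(matrix(2.6, 1, 1), dwell = 2e-3)
    expect_equal(as.vector(gridValues(dadr(single)))[1], 1300)
    # equal rates collapse to that rate regardless of dose weights
    eq <- tinyInfluence(matrix(c(0.4, 1.7, 0.02), 1), dwell = c(0.4, 1.7, 0.02) / 75)
    expect_equal(as.vector(gridValues(dadr(eq)))[1], 75)
    # zero-dose voxel is undefined (NA) or zero under the "zero" policy
    two <- tinyInfluence(matrix(c(2.6, 0), 2, 1), dwell = 2e-3)
    expect_true(is.na(as.vector(gridValues(dadr(two)))[2]))
    z <- dadr(two, metricConfig(undefinedPolicy = "zero"))
    expect_equal(as.vector(gridValues(z))[2], 0)
})

test_that("ADR equals the slope for a single uninterrupted linear ramp", {
    # 2.6 Gy at 1300 Gy/s over 2 ms, d* = 0.1:
    # t0 = 0.0769 ms, t1 = 1.923 ms, ADR = 2.4 / 1.846 ms = 1300 Gy/s
    infl <- tinyInfluence(matrix(2.6, 1, 1), dwell = 2e-3)
    tl <- tinyTimeline(0, 2e-3)
    expect_equal(as.vector(gridValues(adr(infl, tl)))[1], 1300)
})

test_that("ADR trims the irradiation window at the dose thresholds", {
    # 2 Gy at 1000 Gy/s (0-2 ms), nothing (2-3 ms), 2 Gy at 1000 Gy/s
    # (3-5 ms): t0 = 0.1 ms, t1 = 4.9 ms, ADR = 3.8 / 4.8 ms = 791.7 Gy/s
    infl <- tinyInfluence(matrix(c(2, 2), nrow = 1), dwell = c(2e-3, 2e-3))
    tl <- tinyTimeline(c(0, 3e-3), c(2e-3, 5e-3))
    got <- as.vector(gridValues(adr(infl, tl)))[1]
    expect_equal(got, 3.8 / 4.8e-3)
    # and the brute-force 1 us integration agrees
    expect_equal(got, bruteForceAdr(c(2, 2), c(0, 3e-3), c(2e-3, 5e-3)),
        tolerance = 1e-3)
})

test_that("ADR is undefined when the dose does not exceed both thresholds", {
    infl <- tinyInfluence(matrix(0.15, 1, 1), dwell = 2e-3)
    tl <- tinyTimeline(0, 2e-3)
    expect_true(is.na(as.vector(gridValues(adr(infl, tl)))[1]))
    z <- adr(infl, tl, metricConfig(undefinedPolicy = "zero"))
    expect_equal(as.vector(gridValues(z))[1], 0)
})

test_that("DTDR is the minimum rate among spots above the dose threshold", {
    # (D = 0.5 at 100 Gy/s) qualifies, (D = 0.05 at 500 Gy/s) does not
    infl <- tinyInfluence(matrix(c(0.5, 0.05), nrow = 1),
        dwell = c(0.5 / 100, 0.05 / 500))
    expect_equal(as.vector(gridValues(dtdr(infl)))[1], 100)
    # single qualifying spot gives its rate; none gives NA
    one <- tinyInfluence(matrix(c(0.5, 0.08), 2, 1), dwell = 5e-3)
    v <- as.vector(gridValues(dtdr(one)))
    expect_equal(v[1], 100)
    expect_true(is.na(v[2]))
})

test_that("interpolated ADR matches 1 us brute-force integration", {
    set.seed(101)
    cfg <- metricConfig()
    for (rep in 1:10) {
        map <- randomSpotMap(20)
        tl <- buildTimeline(map, mm100)
        infl <- buildInfluence(map, mm100, spotKernel(), randomMapGeometry(),
            spdrOverride = 1300)
        grid <- gridValues(adr(infl, tl, cfg))
        iv <- spotIntervals(tl)
        for (j in seq_len(length(grid))) {
            e <- influenceEntries(infl, j)
            if (nrow(e) == 0) next
            want <- bruteForceAdr(e$dose, iv$tStart[e$spot], iv$tEnd[e$spot])
            if (is.na(want)) {
                expect_true(is.na(as.vector(grid)[j]))
            } else {
                expect_equal(as.vector(grid)[j], want, tolerance = 1e-3)
            }
        }
    }
})

test_that("DADR lies within the contributing rate bounds; DTDR and ADR
           respect their bounds", {
    set.seed(202)
    cfg <- metricConfig()
    for (rep in 1:5) {
        map <- randomSpotMap(20)
        tl <- buildTimeline(map, mm100)
        infl <- buildInfluence(map, mm100, spotKernel(), randomMapGeometry(),
            spdrOverride = 1300)
        da <- as.vector(gridValues(dadr(infl, cfg)))
        dt <- as.vector(gridValues(dtdr(infl, cfg)))
        ad <- as.vector(gridValues(adr(infl, tl, cfg)))
        dw <- dwellTime(mm100, spots(map)$mu)
        for (j in seq_along(da)) {
            e <- influenceEntries(infl, j)
            if (nrow(e) == 0) next
            expect_gte(da[j], min(e$rate) - 1e-9)
            expect_lte(da[j], max(e$rate) + 1e-9)
            qual <- e$dose > cfg@dtdrDoseThreshold
            if (any(qual)) {
                # DTDR exceeds d* over the longest qualifying dwell
                expect_gt(dt[j], cfg@dtdrDoseThreshold / max(dw[e$spot[qual]]))
            } else {
                expect_true(is.na(dt[j]))
            }
            if (!is.na(ad[j])) {
                # ADR cannot exceed the largest instantaneous total rate
                expect_lte(ad[j], sum(e$rate) + 1e-9)
            }
        }
    }
})

test_that("reversing delivery order changes no metric field", {
    set.seed(303)
    map <- randomSpotMap(20)
    geom <- randomMapGeometry()
    rmap <- reorderSpots(map, rev(seq_len(nSpots(map))))
    cfg <- metricConfig()
    i1 <- buildInfluence(map, mm100, spotKernel(), geom, spdrOverride = 1300)
    i2 <- buildInfluence(rmap, mm100, spotKernel(), geom, spdrOverride = 1300)
    t1 <- buildTimeline(map, mm100)
    t2 <- buildTimeline(rmap, mm100)
    expect_equal(gridValues(adr(i1, t1, cfg)), gridValues(adr(i2, t2, cfg)))
    expect_equal(gridValues(dadr(i1)), gridValues(dadr(i2)))
    expect_equal(gridValues(dtdr(i1)), gridValues(dtdr(i2)))
})

test_that("scaling the beam current scales all three metrics linearly", {
    set.seed(404)
    base <- randomSpotMap(15, mm100)
    sp <- spots(base)
    f <- 4
    scaled <- spotMap(sp$x, sp$y, f * sp$mu)
    geom <- randomMapGeometry()
    # d* scaled along with dose keeps the window geometry identical
    cfgB <- metricConfig(adrDoseThreshold = 0.1, dtdrDoseThreshold = 0.1)
    cfgS <- metricConfig(adrDoseThreshold = 0.1 * f, dtdrDoseThreshold = 0.1 * f)
    iB <- buildInfluence(base, mm100, spotKernel(), geom)
    iS <- buildInfluence(scaled, mm400, spotKernel(), geom)
    tB <- buildTimeline(base, mm100)
    tS <- buildTimeline(scaled, mm400)
    expect_equal(gridValues(dadr(iS)), f * gridValues(dadr(iB)))
    expect_equal(gridValues(dtdr(iS, cfgS)), f * gridValues(dtdr(iB, cfgB)))
    expect_equal(gridValues(adr(iS, tS, cfgS)), f * gridValues(adr(iB, tB, cfgB)))
})

test_that("metric means order as ADR <= DTDR <= DADR at patient-like
           field scale", {
    # at patient-scale delivery times (> 1.5 s for a 12 x 12 cm field) the
    # time-aware ADR drops below the instantaneous-rate metrics
    map <- makeUniformField(mm100, fieldSize = c(120, 120))
    geom <- benchmarkGeometry(fieldSize = c(120, 120), spacing = 4,
        depthRange = c(36, 44))
    tl <- buildTimeline(map, mm100)
    infl <- buildInfluence(map, mm100, spotKernel(), geom,
        spdrOverride = 1300)
    mask <- footprintMask(geom, map)
    mets <- doseRateMetrics(infl, tl)
    mu <- vapply(mets, function(g) mean(gridValues(g)[mask], na.rm = TRUE),
        numeric(1))
    expect_lte(mu[["adr"]], mu[["dtdr"]])
    expect_lte(mu[["dtdr"]], mu[["dadr"]])
})
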