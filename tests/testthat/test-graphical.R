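test_that("Logan slope equals V_T on noiseless reversible data", {
    ip <- defaultInputParams()
    sched <- defaultFrameSchedule()
    # one-tissue with K1 = k2 = 0.1: V_T = 1 analytically
    tac1 <- simulateTAC(kineticParams(0.1, 0.1), ip, sched)
    g1 <- loganVT(tac1, ip, tStar = 10)
    expect_equal(g1@slope, 1, tolerance = 0.02)
    # two-tissue (0.2, 0.4, 0.3, 0.15): V_T = 1.5
    tac2 <- simulateTAC(kineticParams(0.2, 0.4, 0.3, 0.15), ip, sched)
    g2 <- loganVT(tac2, ip, tStar = 10)
    expect_equal(g2@slope, 1.5, tolerance = 0.02)
    expect_gt(g2@r2, 0.99)
    expect_gte(g2@nPoints, 3L)
    # t* beyond the scan is an error
    expect_error(loganVT(tac2, ip, tStar = 70), "insufficient")
})

test_that("the Logan bias shrinks monotonically as t* grows", {
    ip <- defaultInputParams()
    tac <- ctrlTac()
    bias <- vapply(c(10, 15, 20, 25),
                   function(ts) abs(loganVT(tac, ip, tStar = ts)@slope - 0.87),
                   numeric(1))
    expect_true(all(diff(bias) <= 1e-10))
    expect_lt(bias[1L] / 0.87, 0.02)  # within 2% at the default t* = 10
})

test_that("Patlak recovers the net influx rate for irreversible kinetics", {
    ip <- defaultInputParams()
    sched <- defaultFrameSchedule()
    tac <- simulateTAC(kineticParams(0.2, 0.4, 0.2, 0), ip, sched)
    g <- patlakKi(tac, ip, tStar = 20)
    expect_equal(g@slope, 0.2 * 0.2 / 0.6, tolerance = 0.02)  # K1 k3/(k2+k3)
    expect_gt(g@r2, 0.99)
})

test_that("Patlak is visibly nonlinear on reversible kinetics while Logan is linear", {
    ip <- defaultInputParams()
    tac <- ctrlTac()
    lg <- loganVT(tac, ip, tStar = 10)
    pk <- patlakKi(tac, ip, tStar = 20)
    expect_gt(lg@r2, 0.99)
    expect_lt(pk@r2, lg@r2)
})

test_that("graphical slopes are invariant to joint rescaling", {
    ip <- defaultInputParams()
    tac <- ctrlTac()
    lg <- loganVT(tac, ip, tStar = 10)
    ip3 <- inputFunctionParams(ip@A1 * 5, ip@A2 * 5, ip@A3 * 5,
                               ip@lambda[1], ip@lambda[2], ip@lambda[3],
                               ip@wbRatio)
    tac3 <- timeActivityCurve(tac@schedule, activity(tac) * 5)
    lg3 <- loganVT(tac3, ip3, tStar = 10)
    expect_equal(lg3@slope, lg@slope, tolerance = 1e-10)
})

test_that("degenerate graphical inputs raise errors", {
    sched <- defaultFrameSchedule()
    tac <- timeActivityCurve(sched, rep(1, 21))
    zero <- bloodSeries(defaultBloodTimes(), rep(0, 15), rep(0, 15))
    zero@plasmaParent <- rep(0, 15); zero@corrected <- TRUE
    expect_error(patlakKi(tac, zero), "identically zero")
})

test_that("Logan accepts a sampled parent-corrected blood series", {
    ip <- defaultInputParams(); pm <- defaultParentModel()
    tac <- simulateTAC(ctrlParams(), ip, defaultFrameSchedule(), parent = pm)
    blood <- correctPlasma(generateInput(ip), pm)
    g <- loganVT(tac, blood, tStar = 10)
    expect_equal(g@slope, 0.87, tolerance = 0.05)
})

test_that("noise biases the Logan slope downward", {
    ip <- defaultInputParams()
    sched <- defaultFrameSchedule()
    p <- ctrlParams()
    big <- noiseModel(alpha = 4)   # deliberately harsh noise
    slopes <- vapply(1:40, function(i) {
        tac <- simulateTAC(p, ip, sched, big, seed = 5000 + i)
        a <- activity(tac)
        tac@activity <- pmax(a, 1e-6)   # keep log-free estimator defined
        loganVT(tac, ip, tStar = 10)@slope
    }, numeric(1))
    expect_lt(mean(slopes), 0.87)
})
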