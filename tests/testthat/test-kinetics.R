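test_that("the impulse response has the correct limits, roots and integral", {
    # one-tissue limit: k3 = 0 gives K1 exp(-k2 t) exactly
    h1 <- impulseResponse2TCM(kineticParams(0.3, 0.5))
    expect_equal(h1$phi, 0.3)
    expect_equal(h1$theta, 0.5)
    # hand-checked quadratic roots for (0.2, 0.4, 0.3, 0.15):
    # theta^2 - 0.85 theta + 0.06 = 0 -> 0.77231, 0.07769
    h <- impulseResponse2TCM(kineticParams(0.2, 0.4, 0.3, 0.15))
    expect_equal(h$theta, c(0.7723111, 0.0776889), tolerance = 1e-6)
    expect_equal(sum(h$phi), 0.2)
    # integral of h equals V_T for random valid parameters (numeric quadrature)
    set.seed(42)
    for (i in 1:25) {
        p <- kineticParams(runif(1, 0.05, 0.5), runif(1, 0.1, 1),
                           runif(1, 0.05, 0.6), runif(1, 0.05, 0.4))
        h <- impulseResponse2TCM(p)
        num <- stats::integrate(function(t)
            h$phi[1] * exp(-h$theta[1] * t) + h$phi[2] * exp(-h$theta[2] * t),
            0, Inf)$value
        expect_equal(num, unname(deriveMacro(p)["VT"]), tolerance = 1e-5)
    }
    expect_error(impulseResponse2TCM(kineticParams(0.1, 0)), "k2")
})

test_that("macro-parameters follow V_T = (K1/k2)(1 + k3/k4)", {
    m <- deriveMacro(kineticParams(0.2, 0.4, 0.3, 0.15))
    expect_equal(unname(m["BPND"]), 2)
    expect_equal(unname(m["VT"]), 1.5)
    m1 <- deriveMacro(kineticParams(0.2, 0.4))
    expect_equal(unname(m1["BPND"]), 0)
    expect_equal(unname(m1["VT"]), 0.5)
    # Table-2-style controls: V_T 0.87 with BP 1.85 imply K1/k2 = 0.87/2.85
    mc <- deriveMacro(ctrlParams())
    expect_equal(unname(mc["VT"]), 0.87, tolerance = 1e-12)
    expect_equal(0.4 * 0.87 / 2.85 / 0.4, 0.87 / 2.85)
    expect_error(deriveMacro(kineticParams(0.2, 0)), "k2 = 0")
    expect_error(deriveMacro(kineticParams(0.2, 0.4, 0.3, 0)), "k4 = 0")
})

test_that("the closed-form forward model matches an independent ODE oracle", {
    ip <- defaultInputParams()
    mids <- frameMid(defaultFrameSchedule())
    set.seed(7)
    for (i in 1:20) {
        p <- kineticParams(runif(1, 0.05, 0.5), runif(1, 0.1, 1),
                           runif(1, 0.05, 0.6), runif(1, 0.05, 0.4),
                           runif(1, 0, 0.15))
        analytic <- occuPET:::.modelCurveValues(p, ip, mids)
        oracle <- odeModelCurve(p, ip, mids)
        expect_lt(max(abs(analytic / oracle - 1)), 1e-3)
    }
})

test_that("noiseless fits recover the generating parameters", {
    ip <- defaultInputParams()
    truth <- ctrlParams(Vb = 0.07)
    tac <- simulateTAC(truth, ip, defaultFrameSchedule())
    fit <- fitCompartment(tac, ip, "2TCM")
    expect_true(fit@converged)
    est <- coef(fit); tru <- coef(truth)
    rates <- c("K1", "k2", "k3", "k4")
    expect_true(all(abs(est[rates] / tru[rates] - 1) < 0.01))
    expect_lt(abs(est["Vb"] - tru["Vb"]), 0.005)
    expect_equal(fit@vt, 0.87, tolerance = 0.01)
    expect_equal(fit@bpnd, 1.85, tolerance = 0.01)
    expect_gt(fit@r2, 0.9999)
    # one-tissue data refit by the one-tissue model
    t1 <- kineticParams(0.15, 0.3, Vb = 0.05)
    tac1 <- simulateTAC(t1, ip, defaultFrameSchedule())
    f1 <- fitCompartment(tac1, ip, "1TCM")
    expect_true(all(abs(coef(f1)[c("K1", "k2")] /
                        coef(t1)[c("K1", "k2")] - 1) < 0.01))
})

test_that("rate constants are invariant to joint rescaling of input and TAC", {
    ip <- defaultInputParams()
    truth <- ctrlParams(Vb = 0.05)
    tac <- simulateTAC(truth, ip, defaultFrameSchedule())
    f <- fitCompartment(tac, ip, "2TCM")
    ip2 <- inputFunctionParams(ip@A1 * 3, ip@A2 * 3, ip@A3 * 3,
                               ip@lambda[1], ip@lambda[2], ip@lambda[3],
                               ip@wbRatio)
    tac2 <- timeActivityCurve(tac@schedule, activity(tac) * 3, tac@weights)
    f2 <- fitCompartment(tac2, ip2, "2TCM")
    expect_equal(coef(f2), coef(f), tolerance = 1e-4)
    expect_equal(f2@vt, f@vt, tolerance = 1e-4)
})

test_that("the AIC formula penalizes parameters and tracks WRSS", {
    tac <- ctrlTac(Vb = 0.07)
    fit <- fitCompartment(tac, defaultInputParams(), "2TCM")
    expect_equal(akaike(fit), fit@aic)
    expect_equal(fit@aic, 21 * log(fit@wrss / 21) + 10)
    # nested models with identical WRSS differ by 2 * deltaP
    expect_equal(occuPET:::.aic(0.5, 21, 5) - occuPET:::.aic(0.5, 21, 3), 4)
    # lower WRSS at equal P gives lower AIC
    expect_lt(occuPET:::.aic(0.4, 21, 5), occuPET:::.aic(0.5, 21, 5))
    expect_warning(occuPET:::.aic(0, 21, 5), "sentinel")
})

test_that("compartment fits use the fitted sampled-blood path too", {
    # fitting against a measured (sampled) blood series instead of the
    # analytic input must give nearly the same answer on noiseless data
    ip <- defaultInputParams()
    pm <- defaultParentModel()
    truth <- ctrlParams(Vb = 0.07)
    tac <- simulateTAC(truth, ip, defaultFrameSchedule(), parent = pm)
    blood <- correctPlasma(generateInput(ip), pm)
    fit <- fitCompartment(tac, blood, "2TCM")
    expect_equal(fit@vt, 0.87, tolerance = 0.05)
    expect_equal(fit@bpnd, 1.85, tolerance = 0.15)
})

test_that("bi-exponential clearance is recovered within 2%", {
    sched <- defaultFrameSchedule()
    mids <- frameMid(sched)
    rf <- log(2) / 10; rs <- log(2) / 129
    y <- 40 * (0.10 * exp(-rf * mids) + 0.90 * exp(-rs * mids))
    tac <- timeActivityCurve(sched, y)
    b <- fitBiexponential(tac, c(2, 60))
    expect_false(b@degenerate)
    expect_equal(b@halfLife[1L], 10, tolerance = 0.02)
    expect_equal(b@halfLife[2L], 129, tolerance = 0.02)
    expect_equal(b@fraction, c(10, 90), tolerance = 0.02)
    expect_lte(b@halfLife[1L], b@halfLife[2L])
    expect_equal(sum(b@fraction), 100)
})

test_that("bi-exponential recovery agrees with a coarse grid-search oracle", {
    sched <- defaultFrameSchedule()
    mids <- frameMid(sched)
    y <- 25 * (0.3 * exp(-log(2) / 6 * mids) + 0.7 * exp(-log(2) / 80 * mids))
    tac <- timeActivityCurve(sched, y)
    fit <- fitBiexponential(tac, c(2, 60))
    # oracle: lattice over the two rates, amplitudes by linear least squares
    t <- mids[mids >= 2 & mids <= 60]; yy <- activity(tac)[mids >= 2 & mids <= 60]
    grid <- expand.grid(r1 = exp(seq(log(0.02), log(0.5), length.out = 60)),
                        r2 = exp(seq(log(0.002), log(0.02), length.out = 60)))
    sse <- apply(grid, 1L, function(g) {
        X <- cbind(exp(-g[1L] * t), exp(-g[2L] * t))
        sum(stats::lm.fit(X, yy)$residuals^2)
    })
    bestRates <- sort(unlist(grid[which.min(sse), ]), decreasing = TRUE)
    expect_equal(unname(log(2) / bestRates), fit@halfLife, tolerance = 0.05)
})

test_that("degenerate clearance collapses to a mono-exponential", {
    sched <- defaultFrameSchedule()
    mids <- frameMid(sched)
    tac <- timeActivityCurve(sched, 30 * exp(-log(2) / 40 * mids))
    expect_warning(b <- fitBiexponential(tac, c(2, 60)), "mono-exponential")
    expect_true(b@degenerate)
    expect_equal(b@halfLife, 40, tolerance = 0.02)
    expect_equal(b@fraction, 100)
})

test_that("clearance fit preconditions are enforced", {
    sched <- defaultFrameSchedule()
    mids <- frameMid(sched)
    y <- 30 * exp(-0.05 * mids); y[3] <- 100   # peak at frame 3 (~25 s)
    tac <- timeActivityCurve(sched, y)
    expect_error(fitBiexponential(tac, c(0.2, 60)), "after the peak")
    expect_error(fitBiexponential(tac, c(50, 60)), "at least 5 frames")
})
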