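test_that("the analytic input is a valid bolus shape", {
    ip <- defaultInputParams()
    b <- generateInput(ip)
    expect_length(sampleTimes(b), 15L)
    expect_true(all(plasma(b) >= 0))
    # zero at injection (limit t -> 0+)
    expect_equal(occuPET:::.analyticCp(ip, 0), 0)
    # early bolus peak, well before 2 min
    tt <- seq(0, 10, by = 0.01)
    cp <- occuPET:::.analyticCp(ip, tt)
    expect_lt(tt[which.max(cp)], 2)
    # whole blood is plasma over the fixed ratio
    expect_equal(wholeBlood(b), plasma(b) / ip@wbRatio)
    # all amplitudes zero -> identically zero series
    z <- inputFunctionParams(0, 0, 0, 3.5, 0.35, 0.011)
    expect_equal(plasma(generateInput(z)), rep(0, 15))
    # invalid parameters are rejected
    expect_error(inputFunctionParams(1, 1, 1, 0.3, 0.35, 0.011), "decreasing")
    expect_error(inputFunctionParams(-1, 1, 1, 3.5, 0.35, 0.011), ">= 0")
})

test_that("a constant plasma input drives the tissue to c * V_T", {
    # steady-state limit of the convolution: integral of h equals V_T
    p <- ctrlParams()
    vt <- unname(deriveMacro(p)["VT"])
    cst <- 5
    dt <- 1 / 60
    cp <- rep(cst, 300 / dt + 1)             # 300 min of constant input
    h <- impulseResponse2TCM(p)
    tis <- 0
    for (j in seq_len(nrow(h)))
        tis <- tis + h$phi[j] * occuPET:::.convExpGrid(cp, dt, h$theta[j])
    expect_equal(tail(tis, 1), cst * vt, tolerance = 1e-4)
})

test_that("simulated TACs are reproducible by seed and noiseless ones non-negative", {
    ip <- defaultInputParams(); sched <- defaultFrameSchedule()
    p <- ctrlParams(Vb = 0.07)
    clean <- simulateTAC(p, ip, sched)
    expect_true(all(activity(clean) >= 0))
    a <- simulateTAC(p, ip, sched, noiseModel(0.4), seed = 11)
    b <- simulateTAC(p, ip, sched, noiseModel(0.4), seed = 11)
    c <- simulateTAC(p, ip, sched, noiseModel(0.4), seed = 12)
    expect_identical(activity(a), activity(b))
    expect_false(identical(activity(a), activity(c)))
    expect_error(simulateTAC(kineticParams(0.1, 0.2, Vb = 1.2), ip, sched),
                 "Vb")
})

test_that("empirical frame noise matches the variance model", {
    ip <- defaultInputParams(); sched <- defaultFrameSchedule()
    p <- ctrlParams(Vb = 0.07)
    nm <- noiseModel(alpha = 0.4)
    mu <- activity(simulateTAC(p, ip, sched))
    expectedSD <- noiseSD(nm, mu, frameMid(sched), frameDuration(sched))
    nrep <- 10000L
    draws <- vapply(seq_len(nrep), function(i)
        activity(simulateTAC(p, ip, sched, nm, seed = 100000L + i)),
        numeric(21))
    empSD <- apply(draws, 1L, sd)
    expect_true(all(abs(empSD^2 / expectedSD^2 - 1) < 0.10))
})

test_that("the synthetic cohort reproduces the study design with exact truth", {
    study <- generateStudy(seed = 4, noise = noiseModel(alpha = 0))
    tr <- study$truth
    expect_length(study$scans, 21L)
    expect_equal(as.vector(table(tr@scans$dose)), c(6L, rep(3L, 5)))
    # occupancy zero at dose 0; k3 scales by (1 - occupancy)
    expect_equal(tr@scans$occupancy[tr@scans$dose == 0], rep(0, 6))
    expect_equal(tr@scans$k3,
                 tr@baseline@k3 * (1 - tr@scans$occupancy))
    # recorded V_T obeys the macro identity exactly
    expect_equal(tr@scans$VT,
                 (tr@scans$K1 / tr@scans$k2) * (1 + tr@scans$k3 / tr@scans$k4))
    # baseline BP_ND equals the generating baseline value
    expect_equal(unique(tr@scans$BPND[tr@scans$dose == 0]),
                 tr@baseline@k3 / tr@baseline@k4)
    # plasma kinetics identical across dose groups
    pl <- vapply(study$scans, function(s) plasma(s@blood), numeric(15))
    expect_equal(pl, pl[, c(1, 1:20)], ignore_attr = TRUE)
    # saturating dose removes all specific binding: V_T -> K1/k2
    expect_equal(trueOccupancy(tr, 1e9), 1, tolerance = 1e-6)
    knd <- tr@baseline@K1 / tr@baseline@k2
    vtInf <- (tr@baseline@K1 / tr@baseline@k2) *
        (1 + tr@baseline@k3 * (1 - trueOccupancy(tr, 1e9)) / tr@baseline@k4)
    expect_equal(vtInf, knd, tolerance = 1e-5)
})
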