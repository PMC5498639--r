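test_that("occupancy formulas follow their definitions", {
    # Table-2/3 style values, hand-evaluated: (0.87-0.23)/(0.87-0.088)*100
    expect_equal(occupancyFromVT(0.87, 0.23, 0.088), 81.8, tolerance = 1e-3)
    expect_equal(occupancyFromVT(1, 1, 0.2), 0)
    expect_equal(occupancyFromVT(1, 0.2, 0.2), 100)
    expect_error(occupancyFromVT(0.5, 0.3, 0.6), "exceed")
    # (1.85 - 0.87)/1.85 * 100
    expect_equal(occupancyFromBP(1.85, 0.87), 52.973, tolerance = 1e-4)
    expect_equal(occupancyFromBP(1.85, 0), 100)
    expect_equal(occupancyFromBP(1.85, 1.85), 0)
    expect_error(occupancyFromBP(0, 0.5), "> 0")
    # no clipping: noise can push outside [0, 100]
    expect_gt(occupancyFromVT(0.87, 0.05, 0.088), 100)
    expect_lt(occupancyFromVT(0.87, 0.95, 0.088), 0)
    # invariance to joint rescaling of all volumes
    expect_equal(occupancyFromVT(8.7, 2.3, 0.88), occupancyFromVT(0.87, 0.23, 0.088))
    # monotone in the drug-condition estimate
    occ <- occupancyFromVT(0.87, seq(0.8, 0.1, by = -0.1), 0.088)
    expect_true(all(diff(occ) > 0))
})

test_that("V_ND extrapolation recovers exact saturation data and flags flat data", {
    d <- c(0, 0.5, 3, 10, 30, 60)
    vt <- 0.088 + 0.782 * 10 / (10 + d)
    f <- fitVND(d, vt)
    expect_equal(f@vnd, 0.088, tolerance = 0.01)
    expect_equal(f@vs, 0.782, tolerance = 0.01)
    expect_equal(f@id50, 10, tolerance = 0.01)
    expect_true(f@reliable)
    expect_gt(f@r2, 0.9999)
    # grid-search oracle over (vnd, id50) with vs by least squares at fixed pair
    grid <- expand.grid(vnd = seq(0.02, 0.2, by = 0.002),
                        id50 = seq(5, 20, by = 0.2))
    sse <- apply(grid, 1L, function(g) {
        x <- g[2L] / (g[2L] + d)
        vs <- sum(x * (vt - g[1L])) / sum(x * x)
        sum((g[1L] + vs * x - vt)^2)
    })
    best <- grid[which.min(sse), ]
    expect_equal(f@vnd, best$vnd, tolerance = 0.05)
    expect_equal(f@id50, best$id50, tolerance = 0.05)
    # constant V_T: no dose dependence -> unreliable flag
    flat <- fitVND(d, rep(0.5, 6) + c(0, 1e-6, -1e-6, 0, 1e-6, 0))
    expect_false(flat@reliable)
    expect_error(fitVND(c(0, 1, 2), c(1, 0.9, 0.8)), "insufficient")
    expect_error(fitVND(d, -vt), "positive")
})

test_that("ED50 fitting recovers exact Hill data and honors its identity", {
    d <- c(0.5, 3, 10, 30, 60)
    occ <- 100 * d / (10 + d)
    f <- fitED50(d, occ)
    expect_equal(f@ed50, 10, tolerance = 1e-3)
    expect_equal(f@hill, 1, tolerance = 1e-3)
    expect_true(f@converged)
    expect_lt(f@pValue, 0.05)
    # occupancy at D = ED50 is exactly 50% for any Hill slope
    for (h in c(0.5, 1, 2.7))
        expect_equal(100 * f@ed50^h / (f@ed50^h + f@ed50^h), 50)
    # steep Hill data
    occ2 <- 100 * d^2.5 / (8^2.5 + d^2.5)
    f2 <- fitED50(d, occ2)
    expect_equal(f2@ed50, 8, tolerance = 1e-3)
    expect_equal(f2@hill, 2.5, tolerance = 1e-3)
    # fixed-slope variant is the simple Emax model
    f3 <- fitED50(d, occ, hill = "fixed")
    expect_equal(f3@ed50, 10, tolerance = 1e-3)
    expect_equal(f3@hill, 1)
    # free-Emax variant recovers a sub-maximal plateau
    occ4 <- 80 * d / (10 + d)
    f4 <- fitED50(d, occ4, emax = "free")
    expect_equal(f4@ed50, 10, tolerance = 1e-2)
    expect_equal(f4@emax, 80, tolerance = 1e-2)
    expect_error(fitED50(c(1, 2), c(10, 20)), "insufficient")
    expect_error(fitED50(d, rep(-5, 5)), "no fit possible")
})

test_that("the group comparison is a classical equal-variance t-test", {
    # textbook case: pooled SD 1.58, t = -1 with 8 df
    r <- compareGroups(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
    expect_equal(r$t, -1, tolerance = 1e-12)
    expect_equal(r$p, 0.3466, tolerance = 1e-3)
    expect_equal(r$df, 8)
    # identical groups: t = 0, p = 1
    same <- compareGroups(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    # swapping groups negates t, p unchanged
    sw <- compareGroups(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
    expect_equal(sw$t, 1)
    expect_equal(sw$p, r$p)
    expect_error(compareGroups(1, c(1, 2)), "insufficient")
})
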