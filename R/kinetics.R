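## Compartment-model fitting, macro-parameters, AIC, bi-exponential clearance.

#' Macro-parameters from rate constants
#'
#' V_T = (K1/k2)(1 + BP_ND) with BP_ND = k3/k4. For the one-tissue model
#' (k3 = k4 = 0) BP_ND = 0 and V_T = K1/k2.
#'
#' @param params a [KineticParams-class].
#' @return named numeric c(VT, BPND).
#' @examples
#' deriveMacro(kineticParams(0.2, 0.4, 0.3, 0.15))  # VT 1.5, BPND 2
#' @export
deriveMacro <- function(params) {
    stopifnot(is(params, "KineticParams"))
    if (params@k2 <= 0)
        stop("macro-parameters undefined: k2 = 0")
    if (params@k3 > 0 && params@k4 <= 0)
        stop("macro-parameters undefined: k4 = 0 with k3 > 0 (irreversible)")
    bp <- if (params@k3 == 0) 0 else params@k3 / params@k4
    c(VT = (params@K1 / params@k2) * (1 + bp), BPND = bp)
}

.aic <- function(wrss, n, p) {
    if (wrss <= 0) {
        warning("WRSS is zero; returning large negative AIC sentinel")
        return(-1e10)
    }
    n * log(wrss / n) + 2 * p
}

#' Akaike information criterion of a compartment fit
#'
#' AIC = N log(WRSS/N) + 2P with N the number of frames and P the number of
#' fitted parameters (3 for the one-tissue model, 5 for the two-tissue model).
#'
#' @param fit a [KineticFit-class].
#' @return the AIC (recomputed from the stored WRSS).
#' @export
akaike <- function(fit) {
    stopifnot(is(fit, "KineticFit"))
    .aic(fit@wrss, fit@nFrames, if (fit@model == "1TCM") 3L else 5L)
}

.defaultStart <- c(K1 = 0.1, k2 = 0.3, k3 = 0.2, k4 = 0.1, Vb = 0.05)

#' Fit a compartment model to a time-activity curve
#'
#' Weighted nonlinear least squares of the frame-averaged model curve
#' C(t) = (1 - Vb) (h (x) Cp)(t) + Vb C_wb(t), with the blood-volume fraction
#' Vb estimated rather than fixed. The parent-corrected plasma drives the
#' compartments; whole blood enters only through the Vb term. Bounded
#' Levenberg-Marquardt with multistart: the first start is the package
#' default, the rest jitter the rates log-uniformly (x10^U(-0.5, 0.5)) under
#' a fixed seed; the best weighted RSS wins. Rates are bounded to
#' [1e-4, 5] min^-1 and Vb to [0, 0.3].
#'
#' Default weights are the inverse of the frame-noise variance up to a
#' constant: duration * exp(-lambda_phys t_mid) / C(t_mid), with the observed
#' frame value standing in for the expected concentration (floored at 5% of
#' the TAC maximum so near-empty frames cannot dominate). A TAC carrying its
#' own weights keeps them.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param input an [InputFunctionParams-class] (analytic) or a parent-corrected
#'   [BloodSeries-class] (interpolated piecewise-linearly with an exponential
#'   tail).
#' @param model "2TCM" (two-tissue reversible) or "1TCM".
#' @param parent optional [ParentFractionModel-class], applied when `input` is
#'   analytic.
#' @param weights optional per-frame weights overriding the defaults.
#' @param multistart number of optimizer starts (default 5).
#' @param seed seed of the multistart jitter (fixed by default so fits are
#'   reproducible).
#' @param halfLife isotope half-life (min) used for the default weights.
#' @param dt convolution grid step, minutes (default 1 s).
#' @return A [KineticFit-class]. Non-convergence after all starts is flagged
#'   (`@converged`, flag "not-converged"), not an error; a k4 estimate at its
#'   lower bound is flagged "near-irreversible".
#' @export
fitCompartment <- function(tac, input, model = c("2TCM", "1TCM"),
                           parent = NULL, weights = NULL, multistart = 5L,
                           seed = 101L, halfLife = 20.38, dt = 1 / 60) {
    model <- match.arg(model)
    stopifnot(is(tac, "TimeActivityCurve"))
    sched <- tac@schedule
    grid <- .makeFitGrid(input, sched, parent = parent, dt = dt)
    obs <- activity(tac)
    n <- length(obs)
    tMid <- frameMid(sched)
    w <- if (!is.null(weights)) weights
         else if (length(tac@weights)) tac@weights
         else {
             cRef <- pmax(obs, 0.05 * max(obs))
             w0 <- frameDuration(sched) *
                 exp(-log(2) / halfLife * tMid) / cRef
             w0 / mean(w0)
         }
    sw <- sqrt(w)

    free <- if (model == "2TCM") c("K1", "k2", "k3", "k4", "Vb")
            else c("K1", "k2", "Vb")
    lower <- c(K1 = 1e-4, k2 = 1e-4, k3 = 1e-4, k4 = 1e-4, Vb = 0)[free]
    upper <- c(K1 = 5, k2 = 5, k3 = 5, k4 = 5, Vb = 0.3)[free]

    resid <- function(par) {
        p <- as.list(par)
        if (model == "1TCM") p$k3 <- p$k4 <- 0
        sw * (obs - .modelFromGrid(p$K1, p$k2, p$k3, p$k4, p$Vb, grid))
    }

    starts <- .withSeed(seed, {
        s0 <- .defaultStart[free]
        out <- list(s0)
        for (i in seq_len(max(multistart - 1L, 0L))) {
            s <- s0
            rates <- setdiff(free, "Vb")
            s[rates] <- pmin(pmax(s0[rates] * 10^stats::runif(length(rates),
                                                              -0.5, 0.5),
                                  lower[rates]), upper[rates])
            s["Vb"] <- stats::runif(1, 0, 0.15)
            out[[i + 1L]] <- s
        }
        out
    })

    best <- NULL
    for (s in starts) {
        fit <- tryCatch(
            minpack.lm::nls.lm(par = s, fn = resid, lower = lower,
                               upper = upper,
                               control = minpack.lm::nls.lm.control(
                                   maxiter = 300, ftol = 1e-12,
                                   ptol = 1e-12)),
            error = function(e) NULL)
        if (is.null(fit)) next
        wrss <- sum(fit$fvec^2)
        if (is.null(best) || wrss < best$wrss)
            best <- list(fit = fit, wrss = wrss)
    }
    if (is.null(best))
        stop("optimizer failed at every start")
    fit <- best$fit
    ## info 1-4: convergence; 6/7: no further reduction possible at machine
    ## precision (the normal stop on zero-residual data); 5: maxiter exceeded
    converged <- fit$info %in% c(1:4, 6:7)
    est <- fit$par
    full <- c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, Vb = 0)
    full[free] <- est
    kp <- kineticParams(full["K1"], full["k2"], full["k3"], full["k4"],
                        full["Vb"])

    se <- rep(NA_real_, length(free)); names(se) <- free
    covm <- tryCatch({
        sigma2 <- best$wrss / max(n - length(free), 1L)
        solve(fit$hessian) * sigma2
    }, error = function(e) NULL)
    if (!is.null(covm)) {
        d <- diag(covm)
        se[d >= 0] <- sqrt(d[d >= 0])
    }

    flags <- character()
    if (!converged) flags <- c(flags, "not-converged")
    if (model == "2TCM" && est["k4"] <= 2 * lower["k4"])
        flags <- c(flags, "near-irreversible")

    macro <- tryCatch(deriveMacro(kp), error = function(e) {
        flags <<- c(flags, "macro-undefined")
        c(VT = NA_real_, BPND = NA_real_)
    })
    fittedVals <- obs - fit$fvec / sw
    wMean <- sum(w * obs) / sum(w)
    r2 <- 1 - best$wrss / sum(w * (obs - wMean)^2)
    p <- if (model == "1TCM") 3L else 5L

    new("KineticFit", model = model, params = kp, se = se,
        vt = unname(macro["VT"]),
        bpnd = if (model == "1TCM") NA_real_ else unname(macro["BPND"]),
        wrss = best$wrss, aic = .aic(best$wrss, n, p), r2 = r2,
        nFrames = as.integer(n), converged = converged,
        residuals = obs - fittedVals, fitted = fittedVals, flags = flags)
}

#' Fit a bi-exponential clearance to the washout of a TAC
#'
#' Fits C(t) = A_f exp(-r_f t) + A_s exp(-r_s t) to the frame values inside a
#' time window after the uptake peak; half-lives are ln(2)/rate and the
#' component fractions are amplitude shares in percent. When the two rates
#' come out within 5% of each other the fit collapses to a single exponential
#' with a warning.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param window c(start, end) minutes; must start after the peak frame and
#'   contain at least 5 frames.
#' @return A [BiExpClearance-class] (fast component first).
#' @export
fitBiexponential <- function(tac, window = c(2, 60)) {
    stopifnot(is(tac, "TimeActivityCurve"))
    tMid <- frameMid(tac)
    act <- activity(tac)
    peak <- tMid[which.max(act)]
    if (window[1L] <= peak)
        stop(sprintf("window must start after the peak frame (peak at %.3g min)",
                     peak))
    use <- tMid >= window[1L] & tMid <= window[2L]
    if (sum(use) < 5L)
        stop("insufficient data: at least 5 frames required in the window")
    t <- tMid[use]; y <- act[use]
    if (any(y <= 0))
        stop("clearance fit requires positive activities in the window")

    ## starting values by tail peeling: slow component from the last frames,
    ## fast component from the early residual
    nTail <- max(3L, ceiling(sum(use) / 3))
    iTail <- utils::tail(seq_along(t), nTail)
    cs <- stats::coef(stats::lm(log(y[iTail]) ~ t[iTail]))
    rSlow <- max(-cs[2L], 1e-5)
    aSlow <- exp(cs[1L])
    resEarly <- y - aSlow * exp(-rSlow * t)
    iHead <- which(resEarly > 0 & seq_along(t) <= nTail)
    if (length(iHead) >= 2L) {
        ch <- stats::coef(stats::lm(log(resEarly[iHead]) ~ t[iHead]))
        rFast <- max(-ch[2L], rSlow * 3)
        aFast <- max(exp(ch[1L]), 1e-8)
    } else {
        rFast <- rSlow * 10
        aFast <- y[1L] * 0.2
    }

    res2 <- function(p) p[1L] * exp(-p[2L] * t) + p[3L] * exp(-p[4L] * t) - y
    fit <- minpack.lm::nls.lm(par = c(aFast, rFast, aSlow, rSlow), fn = res2,
                              lower = c(0, 1e-6, 0, 1e-6),
                              upper = c(Inf, 20, Inf, 20),
                              control = minpack.lm::nls.lm.control(maxiter = 300))
    p <- unname(fit$par)
    ## order fast first
    if (p[2L] < p[4L]) p <- p[c(3L, 4L, 1L, 2L)]
    rates <- p[c(2L, 4L)]
    amps <- p[c(1L, 3L)]
    if (abs(rates[1L] - rates[2L]) / max(rates) < 0.05 ||
        min(amps) <= 0 || min(amps) / sum(amps) < 0.005) {
        warning("rates indistinguishable; collapsing to a mono-exponential")
        res1 <- function(q) q[1L] * exp(-q[2L] * t) - y
        f1 <- minpack.lm::nls.lm(par = c(max(y), rates[which.max(amps)]),
                                 fn = res1,
                                 lower = c(0, 1e-6), upper = c(Inf, 20))
        q <- unname(f1$par)
        return(new("BiExpClearance", halfLife = log(2) / q[2L],
                   fraction = 100, rate = q[2L], amplitude = q[1L],
                   degenerate = TRUE))
    }
    new("BiExpClearance", halfLife = log(2) / rates,
        fraction = 100 * amps / sum(amps), rate = rates, amplitude = amps,
        degenerate = FALSE)
}
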