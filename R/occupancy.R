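## Receptor occupancy, V_ND extrapolation, ED50 estimation, group comparison.

#' Receptor occupancy from distribution volumes
#'
#' Occupancy = (V_T(baseline) - V_T(drug)) / (V_T(baseline) - V_ND) * 100%.
#' Values are never clipped; estimates outside [0, 100] can arise from noise
#' and should be flagged downstream, not silently truncated.
#'
#' @param vtBaseline baseline V_T.
#' @param vtDrug V_T under drug.
#' @param vnd non-displaceable distribution volume (must be < vtBaseline).
#' @return occupancy in percent.
#' @examples
#' occupancyFromVT(0.87, 0.23, 0.088)  # 81.8
#' @export
occupancyFromVT <- function(vtBaseline, vtDrug, vnd) {
    if (any(vtBaseline <= vnd))
        stop("vtBaseline must exceed vnd (denominator would be <= 0)")
    100 * (vtBaseline - vtDrug) / (vtBaseline - vnd)
}

#' Receptor occupancy from binding potentials
#'
#' Occupancy = (BP_ND(baseline) - BP_ND(drug)) / BP_ND(baseline) * 100%.
#'
#' @param bpBaseline baseline BP_ND (> 0).
#' @param bpDrug BP_ND under drug.
#' @return occupancy in percent.
#' @examples
#' occupancyFromBP(1.85, 0.87)  # 53.0
#' @export
occupancyFromBP <- function(bpBaseline, bpDrug) {
    if (any(bpBaseline <= 0))
        stop("bpBaseline must be > 0")
    100 * (bpBaseline - bpDrug) / bpBaseline
}

#' Extrapolate V_ND from V_T across drug doses
#'
#' Least-squares fit of the one-site saturation model
#' V_T(D) = V_ND + V_S * ID50 / (ID50 + D); V_ND is the infinite-dose
#' asymptote. When the dose dependence is not detectable (the V_S confidence
#' interval spans 0) the result is flagged unreliable.
#'
#' @param dose doses in mg/kg (0 = baseline allowed).
#' @param vt per-scan V_T estimates (> 0).
#' @return A [VndFit-class].
#' @export
fitVND <- function(dose, vt) {
    if (length(dose) != length(vt))
        stop("dose and vt must have the same length")
    if (length(unique(dose)) < 4L)
        stop("insufficient data: at least 4 distinct dose levels required (baseline plus 3 doses)")
    if (any(vt <= 0)) stop("V_T values must be positive")
    res <- function(p) p[1L] + p[2L] * p[3L] / (p[3L] + dose) - vt
    start <- c(vnd = max(min(vt) * 0.5, 1e-4),
               vs = max(max(vt) - min(vt), 1e-3),
               id50 = stats::median(dose[dose > 0]))
    fit <- minpack.lm::nls.lm(par = start, fn = res,
                              lower = c(0, 0, 1e-3),
                              upper = c(Inf, Inf, 1e4),
                              control = minpack.lm::nls.lm.control(maxiter = 300))
    p <- fit$par
    rss <- sum(fit$fvec^2)
    se <- rep(NA_real_, 3); names(se) <- names(start)
    covm <- tryCatch(solve(fit$hessian) * rss / max(length(vt) - 3L, 1L),
                     error = function(e) NULL)
    if (!is.null(covm)) {
        d <- diag(covm)
        se[d >= 0] <- sqrt(d[d >= 0])
    }
    r2 <- 1 - rss / sum((vt - mean(vt))^2)
    reliable <- is.finite(se["vs"]) && p["vs"] - 1.96 * se["vs"] > 0
    new("VndFit", vnd = unname(p["vnd"]), vs = unname(p["vs"]),
        id50 = unname(p["id50"]), se = se, r2 = r2,
        reliable = isTRUE(reliable))
}

#' Fit the dose-occupancy curve for the in vivo ED50
#'
#' Least squares of Occ(D) = Emax D^h / (ED50^h + D^h). The default variant
#' fixes Emax at 100% with the Hill slope h free (`hill = "free"`); h can be
#' fixed at 1 (`hill = "fixed"`, simple Emax), and `emax = "free"` lets the
#' plateau float (the convention of common dose-response software, where the
#' fitted top may exceed 100%). Unweighted by default; supply per-point SDs
#' for 1/SD^2 weighting. The reported p-value tests dose dependence (Pearson
#' correlation of occupancy with log dose); fits with p >= 0.05 should be
#' treated as unreliable.
#'
#' @param dose positive doses, mg/kg (at least 3 distinct).
#' @param occupancy occupancies in percent (not clipped).
#' @param hill "free" or "fixed".
#' @param emax "fixed" (100%) or "free".
#' @param sd optional per-point SDs for inverse-variance weighting.
#' @return An [Ed50Fit-class].
#' @export
fitED50 <- function(dose, occupancy, hill = c("free", "fixed"),
                    emax = c("fixed", "free"), sd = NULL) {
    hill <- match.arg(hill)
    emax <- match.arg(emax)
    if (length(dose) != length(occupancy))
        stop("dose and occupancy must have the same length")
    keep <- dose > 0
    dose <- dose[keep]; occupancy <- occupancy[keep]
    if (!is.null(sd)) sd <- sd[keep]
    if (length(unique(dose)) < 3L)
        stop("insufficient data: at least 3 distinct positive doses required")
    if (all(occupancy <= 0))
        stop("no fit possible: all occupancies are <= 0")
    w <- if (is.null(sd)) rep(1, length(dose)) else 1 / pmax(sd, 1e-6)^2
    sw <- sqrt(w / mean(w))
    model <- function(ed50, h, top) top * dose^h / (ed50^h + dose^h)
    ## start near the dose bracketing 50% occupancy
    ed0 <- dose[which.min(abs(occupancy - 50))]
    start <- c(ed50 = ed0)
    lower <- 1e-3; upper <- 1e4
    if (hill == "free") {
        start <- c(start, h = 1); lower <- c(lower, 0.1); upper <- c(upper, 10)
    }
    if (emax == "free") {
        start <- c(start, emax = 100)
        lower <- c(lower, 0); upper <- c(upper, 200)
    }
    res <- function(p) {
        h <- if (hill == "free") p[["h"]] else 1
        top <- if (emax == "free") p[["emax"]] else 100
        sw * (model(p[["ed50"]], h, top) - occupancy)
    }
    fit <- minpack.lm::nls.lm(par = start, fn = res, lower = lower,
                              upper = upper,
                              control = minpack.lm::nls.lm.control(
                                  maxiter = 300, ftol = 1e-12, ptol = 1e-12))
    p <- fit$par
    rss <- sum(fit$fvec^2)
    nPar <- length(start)
    se <- rep(NA_real_, nPar); names(se) <- names(start)
    covm <- tryCatch(solve(fit$hessian) * rss / max(length(dose) - nPar, 1L),
                     error = function(e) NULL)
    if (!is.null(covm)) {
        d <- diag(covm)
        se[d >= 0] <- sqrt(d[d >= 0])
    }
    occW <- sw * occupancy
    r2 <- 1 - rss / sum((occW - mean(occW))^2)
    pv <- if (length(dose) >= 3L)
        tryCatch(stats::cor.test(occupancy, log(dose))$p.value,
                 error = function(e) NA_real_) else NA_real_
    new("Ed50Fit", ed50 = unname(p["ed50"]),
        hill = if (hill == "free") unname(p["h"]) else 1,
        emax = if (emax == "free") unname(p["emax"]) else 100,
        se = se, r2 = r2, converged = fit$info %in% c(1:4, 6:7),
        model = paste0("hill-", hill,
                       if (emax == "free") "/emax-free" else ""),
        weighted = !is.null(sd), pValue = pv)
}

#' Two-sided unpaired t-test between groups
#'
#' Classical equal-variance two-sample Student t-test.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `df`, and the group means.
#' @examples
#' compareGroups(1:5, 2:6)  # t = -1, p = 0.347
#' @export
compareGroups <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        stop("insufficient data: each group needs at least 2 values")
    df <- length(a) + length(b) - 2L
    pooled <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
    if (pooled == 0) {
        ## degenerate zero-variance groups: equal means are indistinguishable
        t <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
        return(list(t = t, p = if (t == 0) 1 else 0, df = df,
                    meanA = mean(a), meanB = mean(b)))
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), meanA = mean(a), meanB = mean(b))
}
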