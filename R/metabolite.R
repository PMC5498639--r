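## Population parent-fraction modelling and plasma metabolite correction.

#' Fit the population parent-fraction curve
#'
#' Least-squares fit of f(t) = c + (1 - c) exp(-k t) (so f(0) = 1, monotone
#' non-increasing to the plateau c) to pooled intact-fraction measurements
#' from all animals.
#'
#' @param time sample times, minutes (> 0).
#' @param fraction intact fractions in [0, 1], same length as `time`.
#' @return A [ParentFractionModel-class] with the residual SD recorded.
#' @examples
#' t <- c(5, 15, 30, 40, 60)
#' f <- 0.6 + 0.4 * exp(-0.05 * t)
#' fitParentFraction(t, f)
#' @export
fitParentFraction <- function(time, fraction) {
    if (length(time) != length(fraction))
        stop("time and fraction must have the same length")
    if (length(time) < 3L)
        stop("insufficient data: at least 3 parent-fraction samples required")
    if (any(!is.finite(time)) || any(time <= 0))
        stop("sample times must be finite and > 0")
    if (any(fraction < 0 | fraction > 1))
        stop("fractions must lie in [0, 1]")
    if (all(fraction == 1)) {
        warning("all fractions equal 1; returning k = 0 (no metabolism)")
        return(parentFractionModel(1, 0, residualSD = 0))
    }
    res <- function(p) p[1L] + (1 - p[1L]) * exp(-p[2L] * time) - fraction
    fit <- minpack.lm::nls.lm(par = c(c = max(min(fraction) - 0.05, 0),
                                      k = 0.05),
                              fn = res, lower = c(0, 0), upper = c(1, 10),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- fit$par
    parentFractionModel(p[1L], p[2L],
                        residualSD = sqrt(sum(fit$fvec^2) /
                                          max(length(time) - 2L, 1L)))
}

#' Apply the parent-fraction correction to a plasma curve
#'
#' Multiplies each plasma sample by the modelled intact fraction at its time,
#' filling the `plasmaParent` slot. Whole blood is untouched. Applying the
#' correction to an already-corrected series is refused.
#'
#' @param blood a [BloodSeries-class].
#' @param model a [ParentFractionModel-class].
#' @return The corrected [BloodSeries-class] with `isParentCorrected()` TRUE.
#' @export
correctPlasma <- function(blood, model) {
    stopifnot(is(blood, "BloodSeries"), is(model, "ParentFractionModel"))
    if (isParentCorrected(blood))
        stop("blood series is already parent-corrected; refusing to correct twice")
    blood@plasmaParent <- blood@plasma * parentFraction(model, blood@time)
    blood@corrected <- TRUE
    validObject(blood)
    blood
}
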