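## Logan and Patlak graphical estimators.

.graphicalCommon <- function(tac, input, tStar, parent) {
    stopifnot(is(tac, "TimeActivityCurve"))
    tMid <- frameMid(tac)
    ct <- activity(tac)
    ## frame values are frame averages, so the integral to a frame end is
    ## exactly sum(duration * activity); to the mid-time, half the frame's
    ## own contribution is excluded
    dur <- frameDuration(tac)
    cumCt <- cumsum(dur * ct) - dur * ct / 2
    cumCp <- .cumCp(input, tMid, parent)
    cp <- .cpAt(input, tMid, parent)
    list(tMid = tMid, ct = ct, cumCt = cumCt, cumCp = cumCp, cp = cp)
}

.graphicalFit <- function(x, y, method, tStar, nUsable) {
    if (length(x) < 3L)
        stop(sprintf("insufficient data: only %d usable frames beyond t* = %g min (>= 3 required)",
                     length(x), tStar))
    fit <- stats::lm(y ~ x)
    new("GraphicalFit", method = method,
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]), tStar = tStar,
        nPoints = length(x), r2 = summary(fit)$r.squared, x = x, y = y)
}

#' Logan graphical analysis
#'
#' Ordinary least squares of int_0^t C_T / C_T(t) on int_0^t C_p / C_T(t)
#' over frames with mid-time >= t*; for a reversible tracer the slope
#' estimates the total distribution volume V_T. Tissue integrals are
#' trapezoids on the frame mid-times; plasma integrals use the blood sample
#' times merged with the frame mid-times (closed-form for analytic inputs).
#'
#' @param tac a [TimeActivityCurve-class].
#' @param input an [InputFunctionParams-class] or parent-corrected
#'   [BloodSeries-class]; the (parent-corrected) plasma is the regression
#'   input.
#' @param tStar start of the linear segment, minutes (default 10).
#' @param parent optional [ParentFractionModel-class] for analytic inputs.
#' @return A [GraphicalFit-class] with `slope` = V_T.
#' @export
loganVT <- function(tac, input, tStar = 10, parent = NULL) {
    g <- .graphicalCommon(tac, input, tStar, parent)
    use <- g$tMid >= tStar
    drop <- use & g$ct <= 0
    if (any(drop)) {
        warning(sprintf("dropping %d frame(s) with zero tissue activity",
                        sum(drop)))
        use <- use & !drop
    }
    .graphicalFit(g$cumCp[use] / g$ct[use], g$cumCt[use] / g$ct[use],
                  "Logan", tStar, sum(use))
}

#' Patlak graphical analysis
#'
#' Ordinary least squares of C_T(t) / C_p(t) on int_0^t C_p / C_p(t) over
#' frames with mid-time >= t*; for an irreversibly trapped tracer the slope
#' estimates the net influx rate Ki (min^-1).
#'
#' @inheritParams loganVT
#' @param tStar start of the linear segment, minutes (default 20).
#' @return A [GraphicalFit-class] with `slope` = Ki.
#' @export
patlakKi <- function(tac, input, tStar = 20, parent = NULL) {
    g <- .graphicalCommon(tac, input, tStar, parent)
    if (all(g$cp <= 0)) stop("plasma input is identically zero")
    use <- g$tMid >= tStar
    drop <- use & g$cp <= 0
    if (any(drop)) {
        warning(sprintf("dropping %d frame(s) with zero plasma input",
                        sum(drop)))
        use <- use & !drop
    }
    .graphicalFit(g$cumCp[use] / g$cp[use], g$ct[use] / g$cp[use],
                  "Patlak", tStar, sum(use))
}
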