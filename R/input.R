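## Input-function handling shared by the kinetic and graphical fitters.
##
## Both accept either an analytic input (InputFunctionParams, optionally with
## a ParentFractionModel applied) or a sampled BloodSeries. Sampled series are
## interpolated piecewise-linearly from (0, 0) through the samples, with a
## single-exponential tail beyond the last sample.

#' Default analytic input-function parameters
#'
#' A bolus shape typical of a ~1 min intravenous rodent injection of ~30 MBq:
#' the plasma curve rises linearly, peaks near 0.3 min at roughly
#' 1000 kBq/ml and decays tri-exponentially to about 20 kBq/ml at 60 min.
#' With the default baseline kinetics this puts the 0-60 min tumor SUV near
#' 0.6 for a 300-350 g animal.
#'
#' @return An [InputFunctionParams-class].
#' @export
defaultInputParams <- function() {
    inputFunctionParams(A1 = 10000, A2 = 160, A3 = 36,
                        lambda1 = 3.5, lambda2 = 0.35, lambda3 = 0.011,
                        wbRatio = 1.25)
}

## Terms of the curve driving the tissue compartments (parent plasma).
.driveTerms <- function(input, parent = NULL) {
    terms <- .termsPlasma(input)
    if (!is.null(parent)) terms <- .termsTimesParent(terms, parent)
    terms
}

## Evaluate an analytic input at arbitrary times.
.analyticCp <- function(input, t, parent = NULL)
    .evalTerms(.driveTerms(input, parent), t)

.analyticCwb <- function(input, t)
    .evalTerms(.termsPlasma(input), t) / input@wbRatio

## Piecewise-linear interpolation through (0,0) and the samples, exponential
## tail beyond the last sample (rate from the last two samples when they are
## positive and decreasing, otherwise held constant).
.sampledCurve <- function(time, conc, t) {
    n <- length(time)
    out <- stats::approx(c(0, time), c(0, conc), xout = pmin(t, time[n]),
                         rule = 2)$y
    beyond <- t > time[n]
    if (any(beyond)) {
        if (n >= 2L && conc[n] > 0 && conc[n - 1L] > conc[n]) {
            rate <- log(conc[n - 1L] / conc[n]) / (time[n] - time[n - 1L])
            out[beyond] <- conc[n] * exp(-rate * (t[beyond] - time[n]))
        } else {
            out[beyond] <- conc[n]
        }
    }
    out
}

## Plasma curve used to drive the compartments for a BloodSeries.
.bloodDrive <- function(blood) {
    if (length(blood@plasmaParent)) blood@plasmaParent
    else {
        warning("blood series is not parent-corrected; using total plasma")
        blood@plasma
    }
}

## Parent-corrected plasma value at arbitrary times, for either input kind.
.cpAt <- function(input, t, parent = NULL) {
    if (is(input, "InputFunctionParams")) return(.analyticCp(input, t, parent))
    if (is(input, "BloodSeries"))
        return(.sampledCurve(input@time, .bloodDrive(input), t))
    stop("input must be an InputFunctionParams or a BloodSeries")
}

.cwbAt <- function(input, t) {
    if (is(input, "InputFunctionParams")) return(.analyticCwb(input, t))
    if (is(input, "BloodSeries"))
        return(.sampledCurve(input@time, input@wholeBlood, t))
    stop("input must be an InputFunctionParams or a BloodSeries")
}

## Cumulative integral of the parent plasma from 0 to each of `times`.
## Analytic inputs integrate in closed form; sampled inputs use a trapezoid
## on the sample times merged with the requested times.
.cumCp <- function(input, times, parent = NULL) {
    if (is(input, "InputFunctionParams"))
        return(.intTerms(.driveTerms(input, parent), 0, times))
    grid <- sort(unique(c(0, input@time, times)))
    cp <- .cpAt(input, grid)
    cum <- c(0, cumsum((cp[-1L] + cp[-length(cp)]) / 2 * diff(grid)))
    cum[match(times, grid)]
}

## Uniform-grid representation used by the compartment fitter.
.makeFitGrid <- function(input, schedule, parent = NULL, dt = 1 / 60) {
    tEnd <- max(schedule@end)
    n <- round(tEnd / dt) + 1L
    t <- (seq_len(n) - 1L) * dt
    grid <- list(t = t, dt = dt,
                 cp = .cpAt(input, t, parent),
                 cwb = .cwbAt(input, t),
                 duration = frameDuration(schedule))
    grid$idx <- .frameGridIndex(schedule, dt, n)
    grid
}
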