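#' @import methods
NULL

## ---------------------------------------------------------------------------
## Acquisition containers
## ---------------------------------------------------------------------------

#' Frame schedule of a dynamic PET acquisition
#'
#' Stores the frame boundaries of a dynamic scan. Times are held internally in
#' minutes post injection; on-disk files use seconds (see [readTAC()]).
#' Frames must be contiguous, non-overlapping and of positive duration.
#'
#' @slot start numeric, frame start times (min).
#' @slot end numeric, frame end times (min).
#' @export
setClass("FrameSchedule",
         representation(start = "numeric", end = "numeric"))

setValidity("FrameSchedule", function(object) {
    s <- object@start; e <- object@end
    if (length(s) != length(e)) return("start and end differ in length")
    if (length(s) == 0L) return("schedule has no frames")
    if (anyNA(s) || anyNA(e) || any(!is.finite(c(s, e))))
        return("frame times must be finite")
    if (s[1L] < 0) return("first frame starts before injection (t < 0)")
    bad <- which(e - s <= 0)
    if (length(bad))
        return(sprintf("frame %d has non-positive duration", bad[1L]))
    if (length(s) > 1L) {
        if (any(diff(s) <= 0)) return("frame starts must be strictly increasing")
        gap <- which(abs(s[-1L] - e[-length(e)]) > 1e-9 * max(1, max(e)))
        if (length(gap))
            return(sprintf("frames %d and %d are not contiguous",
                           gap[1L], gap[1L] + 1L))
    }
    TRUE
})

#' Construct a frame schedule
#'
#' @param start,end frame boundaries, in `unit` ("min" or "sec").
#' @param unit time unit of `start`/`end`; stored internally in minutes.
#' @return A [FrameSchedule-class] object.
#' @examples
#' frameSchedule(c(0, 10, 20), c(10, 20, 40), unit = "sec")
#' @export
frameSchedule <- function(start, end, unit = c("min", "sec")) {
    unit <- match.arg(unit)
    f <- if (unit == "sec") 1 / 60 else 1
    new("FrameSchedule", start = as.numeric(start) * f,
        end = as.numeric(end) * f)
}

#' @describeIn frameSchedule number of frames
#' @param x a `FrameSchedule` (or object holding one)
#' @export
nFrames <- function(x) {
    if (is(x, "TimeActivityCurve")) x <- x@schedule
    length(x@start)
}

#' Frame time accessors
#'
#' Frame start/end/mid-point times and durations, in minutes by default.
#'
#' @param x a `FrameSchedule` or `TimeActivityCurve`.
#' @param unit "min" or "sec".
#' @return numeric vector, one value per frame.
#' @export
frameStart <- function(x, unit = c("min", "sec")) {
    if (is(x, "TimeActivityCurve")) x <- x@schedule
    x@start * if (match.arg(unit) == "sec") 60 else 1
}

#' @rdname frameStart
#' @export
frameEnd <- function(x, unit = c("min", "sec")) {
    if (is(x, "TimeActivityCurve")) x <- x@schedule
    x@end * if (match.arg(unit) == "sec") 60 else 1
}

#' @rdname frameStart
#' @export
frameMid <- function(x, unit = c("min", "sec")) {
    (frameStart(x, unit) + frameEnd(x, unit)) / 2
}

#' @rdname frameStart
#' @export
frameDuration <- function(x, unit = c("min", "sec")) {
    frameEnd(x, unit) - frameStart(x, unit)
}

setMethod("show", "FrameSchedule", function(object) {
    cat(sprintf("FrameSchedule: %d frames, %.4g-%.4g min\n",
                nFrames(object), object@start[1L],
                object@end[nFrames(object)]))
})

#' Tissue time-activity curve
#'
#' Decay-corrected activity concentration (kBq/ml) per frame of a
#' [FrameSchedule-class]. Optional per-frame weights are carried along for
#' fitting.
#'
#' @slot schedule the acquisition [FrameSchedule-class].
#' @slot activity numeric, kBq/ml per frame, decay-corrected to injection.
#' @slot weights numeric, optional non-negative fit weights (length 0 or
#'   `nFrames`).
#' @export
setClass("TimeActivityCurve",
         representation(schedule = "FrameSchedule", activity = "numeric",
                        weights = "numeric"))

setValidity("TimeActivityCurve", function(object) {
    n <- nFrames(object@schedule)
    if (length(object@activity) != n)
        return(sprintf("activity has %d values but the schedule has %d frames",
                       length(object@activity), n))
    if (any(!is.finite(object@activity)))
        return("activity values must be finite")
    w <- object@weights
    if (length(w) && length(w) != n)
        return("weights must be empty or one per frame")
    if (length(w) && (any(!is.finite(w)) || any(w < 0)))
        return("weights must be finite and non-negative")
    TRUE
})

#' Construct a time-activity curve
#'
#' @param schedule a [FrameSchedule-class].
#' @param activity kBq/ml per frame, decay-corrected to injection time.
#' @param weights optional non-negative per-frame fit weights.
#' @return A [TimeActivityCurve-class].
#' @export
timeActivityCurve <- function(schedule, activity, weights = numeric()) {
    new("TimeActivityCurve", schedule = schedule,
        activity = as.numeric(activity), weights = as.numeric(weights))
}

#' @describeIn timeActivityCurve activity vector (kBq/ml per frame)
#' @param x a `TimeActivityCurve`
#' @export
activity <- function(x) x@activity

#' @describeIn timeActivityCurve the underlying frame schedule
#' @export
schedule <- function(x) x@schedule

setMethod("show", "TimeActivityCurve", function(object) {
    cat(sprintf("TimeActivityCurve: %d frames, activity %.3g-%.3g kBq/ml\n",
                nFrames(object), min(object@activity), max(object@activity)))
})

#' Arterial blood sample series
#'
#' Whole-blood and plasma activity concentrations at discrete sampling times.
#' `plasmaParent` holds the metabolite-corrected (parent-only) plasma curve
#' once [correctPlasma()] has been applied; `corrected` guards against
#' applying the correction twice.
#'
#' @slot time numeric, sample times in minutes (> 0, strictly increasing).
#' @slot wholeBlood numeric, kBq/ml.
#' @slot plasma numeric, total plasma activity, kBq/ml.
#' @slot plasmaParent numeric, parent-corrected plasma (length 0 until filled).
#' @slot corrected logical flag set by [correctPlasma()].
#' @export
setClass("BloodSeries",
         representation(time = "numeric", wholeBlood = "numeric",
                        plasma = "numeric", plasmaParent = "numeric",
                        corrected = "logical"),
         prototype(plasmaParent = numeric(), corrected = FALSE))

setValidity("BloodSeries", function(object) {
    t <- object@time
    if (length(t) == 0L) return("blood series is empty")
    if (any(!is.finite(t)) || any(t <= 0))
        return("sample times must be finite and > 0")
    if (is.unsorted(t, strictly = TRUE))
        return("sample times must be strictly increasing")
    for (sl in c("wholeBlood", "plasma")) {
        v <- slot(object, sl)
        if (length(v) != length(t))
            return(sprintf("%s must have one value per sample time", sl))
        if (any(!is.finite(v)) || any(v < 0))
            return(sprintf("%s concentrations must be finite and >= 0", sl))
    }
    p <- object@plasmaParent
    if (length(p) && (length(p) != length(t) || any(p < 0)))
        return("plasmaParent must be empty or non-negative, one per sample")
    TRUE
})

#' Construct a blood sample series
#'
#' @param time sample times (in `unit`), strictly increasing, > 0.
#' @param wholeBlood,plasma activity concentrations, kBq/ml.
#' @param unit time unit of `time`; stored internally in minutes.
#' @return A [BloodSeries-class].
#' @export
bloodSeries <- function(time, wholeBlood, plasma, unit = c("min", "sec")) {
    unit <- match.arg(unit)
    f <- if (unit == "sec") 1 / 60 else 1
    new("BloodSeries", time = as.numeric(time) * f,
        wholeBlood = as.numeric(wholeBlood), plasma = as.numeric(plasma))
}

#' Blood series accessors
#'
#' @param x a `BloodSeries`.
#' @param unit "min" or "sec".
#' @export
sampleTimes <- function(x, unit = c("min", "sec")) {
    x@time * if (match.arg(unit) == "sec") 60 else 1
}

#' @rdname sampleTimes
#' @export
wholeBlood <- function(x) x@wholeBlood

#' @rdname sampleTimes
#' @export
plasma <- function(x) x@plasma

#' @rdname sampleTimes
#' @export
plasmaParent <- function(x) {
    if (!length(x@plasmaParent))
        stop("plasma has not been parent-corrected yet; see correctPlasma()")
    x@plasmaParent
}

#' @rdname sampleTimes
#' @export
isParentCorrected <- function(x) isTRUE(x@corrected)

setMethod("show", "BloodSeries", function(object) {
    cat(sprintf("BloodSeries: %d samples, %.3g-%.3g min%s\n",
                length(object@time), min(object@time), max(object@time),
                if (object@corrected) " (parent-corrected)" else ""))
})

#' A single scan of a study
#'
#' One animal's dynamic scan: tumor TAC, arterial blood series, and the scan
#' metadata needed for SUV and dose-response analysis.
#'
#' @slot subjectId character label, unique within a study.
#' @slot group "baseline" or "drug".
#' @slot drugDose mg/kg (0 for baseline).
#' @slot injectedDose MBq.
#' @slot bodyWeight g.
#' @slot tac the tumor [TimeActivityCurve-class].
#' @slot blood the arterial [BloodSeries-class].
#' @export
setClass("ScanRecord",
         representation(subjectId = "character", group = "character",
                        drugDose = "numeric", injectedDose = "numeric",
                        bodyWeight = "numeric", tac = "TimeActivityCurve",
                        blood = "BloodSeries"))

setValidity("ScanRecord", function(object) {
    if (!object@group %in% c("baseline", "drug"))
        return(sprintf("unknown group label '%s'", object@group))
    if (object@drugDose < 0) return("drugDose must be >= 0")
    if (object@group == "baseline" && object@drugDose != 0)
        return("baseline scans must have drugDose 0")
    if (object@injectedDose <= 0) return("injectedDose must be > 0")
    if (object@bodyWeight <= 0) return("bodyWeight must be > 0")
    TRUE
})

#' Construct a scan record
#'
#' @param subjectId unique subject label.
#' @param group "baseline" or "drug".
#' @param drugDose drug dose, mg/kg (0 for baseline).
#' @param injectedDose injected tracer dose, MBq.
#' @param bodyWeight body weight, g.
#' @param tac a [TimeActivityCurve-class].
#' @param blood a [BloodSeries-class].
#' @export
scanRecord <- function(subjectId, group, drugDose, injectedDose, bodyWeight,
                       tac, blood) {
    new("ScanRecord", subjectId = as.character(subjectId),
        group = as.character(group), drugDose = as.numeric(drugDose),
        injectedDose = as.numeric(injectedDose),
        bodyWeight = as.numeric(bodyWeight), tac = tac, blood = blood)
}

setMethod("show", "ScanRecord", function(object) {
    cat(sprintf("ScanRecord '%s' [%s, %.3g mg/kg]: %d frames, %d blood samples\n",
                object@subjectId, object@group, object@drugDose,
                nFrames(object@tac), length(object@blood@time)))
})

## ---------------------------------------------------------------------------
## Model parameter containers
## ---------------------------------------------------------------------------

#' Compartment-model rate constants
#'
#' Rate constants of the one- or two-tissue reversible compartment model:
#' K1 (plasma to tissue, ml min^-1 ml^-1), k2 (tissue to plasma, min^-1),
#' k3/k4 (binding/dissociation, min^-1) and the fractional blood volume Vb.
#' The one-tissue model is the special case k3 = k4 = 0.
#'
#' @slot K1,k2,k3,k4 numeric rate constants (>= 0).
#' @slot Vb fractional blood volume in [0, 1).
#' @export
setClass("KineticParams",
         representation(K1 = "numeric", k2 = "numeric", k3 = "numeric",
                        k4 = "numeric", Vb = "numeric"))

setValidity("KineticParams", function(object) {
    v <- c(K1 = object@K1, k2 = object@k2, k3 = object@k3, k4 = object@k4)
    if (any(!is.finite(v)) || any(v < 0))
        return("rate constants must be finite and >= 0")
    if (!is.finite(object@Vb) || object@Vb < 0 || object@Vb >= 1)
        return("Vb must lie in [0, 1)")
    TRUE
})

#' Construct compartment-model parameters
#'
#' @param K1 influx rate, ml min^-1 ml^-1.
#' @param k2,k3,k4 tissue rate constants, min^-1 (k3 = k4 = 0 gives the
#'   one-tissue model; k4 = 0 with k3 > 0 is the irreversible trapping limit).
#' @param Vb fractional blood volume in [0, 1).
#' @examples
#' kineticParams(K1 = 0.2, k2 = 0.4, k3 = 0.3, k4 = 0.15)
#' @export
kineticParams <- function(K1, k2, k3 = 0, k4 = 0, Vb = 0) {
    new("KineticParams", K1 = as.numeric(K1), k2 = as.numeric(k2),
        k3 = as.numeric(k3), k4 = as.numeric(k4), Vb = as.numeric(Vb))
}

#' @export
setMethod("coef", "KineticParams", function(object, ...) {
    c(K1 = object@K1, k2 = object@k2, k3 = object@k3, k4 = object@k4,
      Vb = object@Vb)
})

setMethod("show", "KineticParams", function(object) {
    cat("KineticParams:",
        paste(names(coef(object)), signif(coef(object), 4), sep = "=",
              collapse = " "), "\n")
})

#' Result of a compartment-model fit
#'
#' @slot model "1TCM" or "2TCM".
#' @slot params fitted [KineticParams-class].
#' @slot se standard errors of the fitted parameters.
#' @slot vt total distribution volume V_T = (K1/k2)(1 + k3/k4).
#' @slot bpnd non-displaceable binding potential k3/k4 (NA for 1TCM).
#' @slot wrss weighted residual sum of squares.
#' @slot aic Akaike information criterion, N log(WRSS/N) + 2P.
#' @slot r2 weighted coefficient of determination.
#' @slot nFrames number of frames fitted.
#' @slot converged logical.
#' @slot residuals per-frame (unweighted) residuals, observed - fitted.
#' @slot fitted per-frame model values.
#' @slot flags character vector of diagnostic flags (e.g. "near-irreversible").
#' @export
setClass("KineticFit",
         representation(model = "character", params = "KineticParams",
                        se = "numeric", vt = "numeric", bpnd = "numeric",
                        wrss = "numeric", aic = "numeric", r2 = "numeric",
                        nFrames = "integer", converged = "logical",
                        residuals = "numeric", fitted = "numeric",
                        flags = "character"))

#' @describeIn KineticFit-class fitted macro-parameters c(VT, BPND)
#' @param x a `KineticFit`
#' @export
macroParams <- function(x) c(VT = x@vt, BPND = x@bpnd)

#' @export
setMethod("coef", "KineticFit", function(object, ...) coef(object@params))

setMethod("show", "KineticFit", function(object) {
    cat(sprintf("KineticFit [%s]%s: VT=%.4g BPND=%.4g AIC=%.5g R2=%.4f\n",
                object@model,
                if (object@converged) "" else " (NOT CONVERGED)",
                object@vt, object@bpnd, object@aic, object@r2))
    cat("  ", paste(names(coef(object)), signif(coef(object), 4), sep = "=",
                    collapse = " "), "\n")
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' Graphical (Logan/Patlak) fit result
#'
#' @slot method "Logan" or "Patlak".
#' @slot slope regression slope: V_T for Logan, Ki (min^-1) for Patlak.
#' @slot intercept regression intercept.
#' @slot tStar start time of the linear segment, minutes.
#' @slot nPoints number of frames in the regression.
#' @slot r2 coefficient of determination.
#' @slot x,y the regression coordinates (for plotting).
#' @export
setClass("GraphicalFit",
         representation(method = "character", slope = "numeric",
                        intercept = "numeric", tStar = "numeric",
                        nPoints = "integer", r2 = "numeric",
                        x = "numeric", y = "numeric"))

#' @describeIn GraphicalFit-class the regression slope (Logan V_T / Patlak Ki)
#' @param x a `GraphicalFit`
#' @export
slope <- function(x) x@slope

setMethod("show", "GraphicalFit", function(object) {
    cat(sprintf("GraphicalFit [%s, t*=%.3g min]: slope=%.4g intercept=%.4g R2=%.4f (n=%d)\n",
                object@method, object@tStar, object@slope, object@intercept,
                object@r2, object@nPoints))
})

#' Bi-exponential clearance fit
#'
#' @slot halfLife numeric c(fast, slow), minutes.
#' @slot fraction numeric c(fast, slow), percent of amplitude, summing to 100.
#' @slot rate numeric decay rates, min^-1.
#' @slot amplitude numeric fitted amplitudes, kBq/ml.
#' @slot degenerate TRUE when the two rates were indistinguishable and the fit
#'   collapsed to a single exponential.
#' @export
setClass("BiExpClearance",
         representation(halfLife = "numeric", fraction = "numeric",
                        rate = "numeric", amplitude = "numeric",
                        degenerate = "logical"))

setMethod("show", "BiExpClearance", function(object) {
    if (object@degenerate)
        cat(sprintf("BiExpClearance (mono-exponential): t1/2 = %.4g min\n",
                    object@halfLife[1L]))
    else
        cat(sprintf("BiExpClearance: t1/2 = %.4g min (%.3g%%) / %.4g min (%.3g%%)\n",
                    object@halfLife[1L], object@fraction[1L],
                    object@halfLife[2L], object@fraction[2L]))
})

#' Parent-fraction (metabolite) model
#'
#' Fraction of plasma activity that is intact (parent) tracer as a function of
#' time: f(t) = c + (1 - c) exp(-k t), so f(0) = 1 and f decays monotonically
#' to the plateau c.
#'
#' @slot plateau c, asymptotic intact fraction in [0, 1].
#' @slot rate k, min^-1, >= 0.
#' @slot residualSD residual standard deviation of the population fit (NA when
#'   constructed directly).
#' @export
setClass("ParentFractionModel",
         representation(plateau = "numeric", rate = "numeric",
                        residualSD = "numeric"),
         prototype(residualSD = NA_real_))

setValidity("ParentFractionModel", function(object) {
    if (!is.finite(object@plateau) || object@plateau < 0 || object@plateau > 1)
        return("plateau must lie in [0, 1]")
    if (!is.finite(object@rate) || object@rate < 0)
        return("rate must be >= 0")
    TRUE
})

#' Construct a parent-fraction model
#'
#' @param plateau asymptotic intact fraction c in [0, 1].
#' @param rate decay rate k, min^-1.
#' @param residualSD residual SD of the fit producing the model (optional).
#' @return A [ParentFractionModel-class].
#' @export
parentFractionModel <- function(plateau, rate, residualSD = NA_real_) {
    new("ParentFractionModel", plateau = as.numeric(plateau),
        rate = as.numeric(rate), residualSD = as.numeric(residualSD))
}

#' Evaluate the parent fraction f(t)
#'
#' @param model a [ParentFractionModel-class].
#' @param time minutes post injection.
#' @return intact fraction in [plateau, 1].
#' @export
parentFraction <- function(model, time) {
    stopifnot(is(model, "ParentFractionModel"))
    model@plateau + (1 - model@plateau) * exp(-model@rate * time)
}

setMethod("show", "ParentFractionModel", function(object) {
    cat(sprintf("ParentFractionModel: f(t) = %.4g + %.4g exp(-%.4g t)",
                object@plateau, 1 - object@plateau, object@rate))
    if (is.finite(object@residualSD))
        cat(sprintf("  [residual SD %.3g]", object@residualSD))
    cat("\n")
})

## ---------------------------------------------------------------------------
## Simulation containers
## ---------------------------------------------------------------------------

#' Analytic arterial input function parameters
#'
#' A tri-exponential bolus model with a linear rise (Feng-type):
#' Cp(t) = (A1 t - A2 - A3) exp(-l1 t) + A2 exp(-l2 t) + A3 exp(-l3 t),
#' which is 0 at t = 0, peaks early and decays tri-exponentially. Whole-blood
#' activity is plasma divided by a constant plasma-to-whole-blood ratio.
#'
#' @slot A1 kBq/ml/min; @slot A2,A3 kBq/ml.
#' @slot lambda numeric(3), decay rates min^-1, strictly decreasing, > 0.
#' @slot wbRatio plasma-to-whole-blood activity ratio (> 0).
#' @export
setClass("InputFunctionParams",
         representation(A1 = "numeric", A2 = "numeric", A3 = "numeric",
                        lambda = "numeric", wbRatio = "numeric"))

setValidity("InputFunctionParams", function(object) {
    l <- object@lambda
    if (length(l) != 3L || any(!is.finite(l)) || any(l <= 0))
        return("lambda must be three finite positive rates")
    if (!(l[1L] > l[2L] && l[2L] > l[3L]))
        return("lambda must be strictly decreasing (l1 > l2 > l3)")
    if (any(!is.finite(c(object@A1, object@A2, object@A3))) ||
        object@A1 < 0 || object@A2 < 0 || object@A3 < 0)
        return("amplitudes must be finite and >= 0")
    if (!is.finite(object@wbRatio) || object@wbRatio <= 0)
        return("wbRatio must be > 0")
    TRUE
})

#' Construct analytic input-function parameters
#'
#' @param A1 linear-rise coefficient, kBq/ml/min.
#' @param A2,A3 exponential amplitudes, kBq/ml.
#' @param lambda1,lambda2,lambda3 decay rates, min^-1 (strictly decreasing).
#' @param wbRatio plasma-to-whole-blood activity ratio.
#' @export
inputFunctionParams <- function(A1, A2, A3, lambda1, lambda2, lambda3,
                                wbRatio = 1.25) {
    new("InputFunctionParams", A1 = as.numeric(A1), A2 = as.numeric(A2),
        A3 = as.numeric(A3),
        lambda = as.numeric(c(lambda1, lambda2, lambda3)),
        wbRatio = as.numeric(wbRatio))
}

setMethod("show", "InputFunctionParams", function(object) {
    cat(sprintf("InputFunctionParams: A=(%.4g, %.4g, %.4g), lambda=(%.4g, %.4g, %.4g) /min, plasma:WB=%.3g\n",
                object@A1, object@A2, object@A3, object@lambda[1L],
                object@lambda[2L], object@lambda[3L], object@wbRatio))
})

#' Frame-noise model for simulated TACs
#'
#' Gaussian count-statistics heuristic: the variance of a frame value is
#' alpha * C(t_mid) * exp(lambda_phys * t_mid) / duration, so longer frames
#' and earlier frames (less decay) are less noisy. `alpha = 0` is noiseless.
#'
#' @slot alpha dimensionless scale, >= 0.
#' @slot lambdaPhys physical decay constant, min^-1.
#' @export
setClass("NoiseModel",
         representation(alpha = "numeric", lambdaPhys = "numeric"))

setValidity("NoiseModel", function(object) {
    if (!is.finite(object@alpha) || object@alpha < 0)
        return("alpha must be >= 0")
    if (!is.finite(object@lambdaPhys) || object@lambdaPhys < 0)
        return("lambdaPhys must be >= 0")
    TRUE
})

#' Construct a noise model
#'
#' @param alpha dimensionless noise scale (0 = noiseless; the default 0.4
#'   gives coefficients of variation around 5-10% in the mid-to-late 5-10 min
#'   frames at typical simulated tumor concentrations of 20-60 kBq/ml, rising
#'   toward 15-25% in the short early frames).
#' @param halfLife isotope half-life in minutes (default carbon-11, 20.38 min).
#' @export
noiseModel <- function(alpha = 0.4, halfLife = 20.38) {
    stopifnot(halfLife > 0)
    new("NoiseModel", alpha = as.numeric(alpha),
        lambdaPhys = log(2) / halfLife)
}

#' Per-frame noise standard deviation
#'
#' @param noise a [NoiseModel-class].
#' @param value noise-free frame value, kBq/ml.
#' @param tMid frame mid-time, minutes.
#' @param duration frame duration, minutes.
#' @export
noiseSD <- function(noise, value, tMid, duration) {
    sqrt(noise@alpha * pmax(value, 0) * exp(noise@lambdaPhys * tMid) / duration)
}

#' Ground truth of a synthetic occupancy study
#'
#' @slot baseline baseline [KineticParams-class] (dose 0).
#' @slot ed50 true ED50, mg/kg.
#' @slot hill true Hill slope.
#' @slot scans data.frame with one row per scan: subjectId, group, dose,
#'   occupancy (fraction), K1..k4, Vb, VT, BPND.
#' @export
setClass("GroundTruth",
         representation(baseline = "KineticParams", ed50 = "numeric",
                        hill = "numeric", scans = "data.frame"))

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: ED50=%.4g mg/kg, hill=%.3g, baseline VT=%.4g, BPND=%.4g; %d scans\n",
                object@ed50, object@hill,
                (object@baseline@K1 / object@baseline@k2) *
                    (1 + object@baseline@k3 / object@baseline@k4),
                object@baseline@k3 / object@baseline@k4,
                nrow(object@scans)))
})

## ---------------------------------------------------------------------------
## Dose-response containers
## ---------------------------------------------------------------------------

#' Non-displaceable volume extrapolation fit
#'
#' One-site saturation model V_T(D) = V_ND + V_S * ID50 / (ID50 + D) fitted to
#' per-scan V_T estimates across drug doses; V_ND is the infinite-dose
#' asymptote.
#'
#' @slot vnd the asymptote V_ND (>= 0).
#' @slot vs specific volume V_S = V_T(0) - V_ND.
#' @slot id50 dose halving the specific volume, mg/kg.
#' @slot se named standard errors.
#' @slot r2 coefficient of determination.
#' @slot reliable FALSE when no dose dependence is detectable (V_S CI spans 0).
#' @export
setClass("VndFit",
         representation(vnd = "numeric", vs = "numeric", id50 = "numeric",
                        se = "numeric", r2 = "numeric", reliable = "logical"))

setMethod("show", "VndFit", function(object) {
    cat(sprintf("VndFit: V_ND=%.4g, V_S=%.4g, ID50=%.4g mg/kg, R2=%.4f%s\n",
                object@vnd, object@vs, object@id50, object@r2,
                if (object@reliable) "" else "  [UNRELIABLE: no dose dependence]"))
})

#' ED50 dose-response fit
#'
#' Hill model Occ(D) = Emax D^h / (ED50^h + D^h); the default variant fixes
#' Emax at 100%.
#'
#' @slot ed50 mg/kg, > 0.
#' @slot hill Hill slope (1 when fitted with `hill = "fixed"`).
#' @slot emax fitted plateau (100 when fixed).
#' @slot se named standard errors.
#' @slot r2 coefficient of determination.
#' @slot converged logical.
#' @slot model label of the fitted variant (e.g. "hill-free",
#'   "hill-fixed/emax-free").
#' @slot weighted TRUE for 1/SD^2 weighting.
#' @slot pValue p-value of the dose dependence (correlation with log dose).
#' @export
setClass("Ed50Fit",
         representation(ed50 = "numeric", hill = "numeric", emax = "numeric",
                        se = "numeric", r2 = "numeric", converged = "logical",
                        model = "character", weighted = "logical",
                        pValue = "numeric"))

setMethod("show", "Ed50Fit", function(object) {
    cat(sprintf("Ed50Fit [%s%s]: ED50=%.4g mg/kg, hill=%.3g, Emax=%.4g%%, R2=%.4f, p=%.3g%s\n",
                object@model, if (object@weighted) ", weighted" else "",
                object@ed50, object@hill, object@emax, object@r2,
                object@pValue,
                if (object@converged) "" else "  [NOT CONVERGED]"))
})
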