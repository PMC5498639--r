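## Exponential-term algebra for the closed-form forward model.
##
## Curves are represented as sums of terms coef * t^pow * exp(-rate * t) with
## pow in {0, 1}. The Feng-type input, its product with the parent-fraction
## model, and its convolution with the compartmental impulse response all stay
## inside this family, so frame averages of the simulated model curve are
## exact analytic integrals rather than quadrature.

.terms <- function(coef, rate, pow) {
    data.frame(coef = coef, rate = rate, pow = as.integer(pow))
}

## Feng input: Cp(t) = (A1 t - A2 - A3) e^(-l1 t) + A2 e^(-l2 t) + A3 e^(-l3 t)
.termsPlasma <- function(p) {
    stopifnot(is(p, "InputFunctionParams"))
    l <- p@lambda
    .terms(coef = c(p@A1, -(p@A2 + p@A3), p@A2, p@A3),
           rate = c(l[1L], l[1L], l[2L], l[3L]),
           pow = c(1L, 0L, 0L, 0L))
}

## Multiply a term set by the parent fraction f(t) = c + (1-c) e^(-k t):
## still a sum of (t^pow) exponentials, with rates shifted by k.
.termsTimesParent <- function(terms, model) {
    cc <- model@plateau; k <- model@rate
    out <- terms
    out$coef <- out$coef * cc
    extra <- terms
    extra$coef <- extra$coef * (1 - cc)
    extra$rate <- extra$rate + k
    rbind(out, extra)
}

.evalTerms <- function(terms, t) {
    v <- numeric(length(t))
    for (i in seq_len(nrow(terms))) {
        tt <- if (terms$pow[i] == 1L) t else 1
        v <- v + terms$coef[i] * tt * exp(-terms$rate[i] * t)
    }
    v
}

## Definite integral of one term over [t1, t2] (vectorized over t1/t2).
.intTerm <- function(coef, rate, pow, t1, t2) {
    if (abs(rate) < 1e-12) {
        if (pow == 0L) return(coef * (t2 - t1))
        return(coef * (t2^2 - t1^2) / 2)
    }
    if (pow == 0L) {
        coef * (exp(-rate * t1) - exp(-rate * t2)) / rate
    } else {
        coef * ((1 + rate * t1) * exp(-rate * t1) -
                (1 + rate * t2) * exp(-rate * t2)) / rate^2
    }
}

.intTerms <- function(terms, t1, t2) {
    v <- numeric(length(t1))
    for (i in seq_len(nrow(terms)))
        v <- v + .intTerm(terms$coef[i], terms$rate[i], terms$pow[i], t1, t2)
    v
}

## Convolve a term set with phi * exp(-theta t).
## exp(-l t) (x) exp(-th t) = (e^(-l t) - e^(-th t)) / (th - l)
## t e^(-l t) (x) e^(-th t) = [e^(-th t) - (1 + d t) e^(-l t)] / d^2, d = l - th
.convTermsExp <- function(terms, phi, theta) {
    out <- vector("list", nrow(terms))
    for (i in seq_len(nrow(terms))) {
        a <- terms$coef[i] * phi; l <- terms$rate[i]
        d <- l - theta
        ## rates are nudged apart upstream; a residual collision falls back to
        ## the t-exponential limit for pow 0
        if (terms$pow[i] == 0L) {
            if (abs(d) < 1e-10) {
                out[[i]] <- .terms(a, l, 1L)
            } else {
                out[[i]] <- .terms(c(a, -a) / (-d), c(l, theta), c(0L, 0L))
            }
        } else {
            if (abs(d) < 1e-10)
                stop("degenerate convolution (t^2 term); rates coincide")
            out[[i]] <- .terms(c(a / d^2, -a / d^2, -a / d),
                               c(theta, l, l), c(0L, 0L, 1L))
        }
    }
    do.call(rbind, out)
}

#' Impulse response of the two-tissue reversible compartment model
#'
#' Returns the amplitudes and rates of the bi-exponential impulse response
#' h(t) = phi1 exp(-theta1 t) + phi2 exp(-theta2 t), where theta1,2 are the
#' roots of theta^2 - (k2+k3+k4) theta + k2 k4 = 0. The amplitudes sum to K1
#' and the integral of h equals V_T. With k3 = k4 = 0 the one-tissue response
#' K1 exp(-k2 t) is returned; with k4 = 0, k3 > 0 the second rate is 0
#' (irreversible trapping).
#'
#' @param params a [KineticParams-class] (Vb is ignored here).
#' @return data.frame with columns `phi` (amplitudes, ml min^-1 ml^-1) and
#'   `theta` (rates, min^-1), fast component first.
#' @examples
#' impulseResponse2TCM(kineticParams(0.2, 0.4, 0.3, 0.15))
#' @export
impulseResponse2TCM <- function(params) {
    stopifnot(is(params, "KineticParams"))
    K1 <- params@K1; k2 <- params@k2; k3 <- params@k3; k4 <- params@k4
    if (k2 <= 0) stop("k2 must be > 0 for the impulse response")
    if (k3 == 0 && k4 == 0)
        return(data.frame(phi = K1, theta = k2))
    s <- k2 + k3 + k4
    disc <- s^2 - 4 * k2 * k4
    ## disc = (k2+k3+k4)^2 - 4 k2 k4 >= (k2-k4)^2 + ... >= 0 always; guard
    sq <- sqrt(max(disc, 0))
    th1 <- (s + sq) / 2
    th2 <- (s - sq) / 2
    if (th1 - th2 < 1e-12)
        stop("degenerate impulse response: equal eigenvalues")
    data.frame(phi = c(K1 * (th1 - k3 - k4), K1 * (k3 + k4 - th2)) / (th1 - th2),
               theta = c(th1, th2))
}

## Nudge impulse rates minutely off the input rates so the closed-form
## convolution never degenerates (documented numerical tie-break).
.nudgeRates <- function(h, inputRates) {
    for (i in seq_len(nrow(h))) {
        while (any(abs(h$theta[i] - inputRates) < 1e-9) ||
               (nrow(h) > 1 && any(abs(h$theta[i] - h$theta[-i]) < 1e-9)))
            h$theta[i] <- h$theta[i] * (1 + 1e-8) + 1e-12
    }
    h
}

## Tissue curve terms: (h (x) Cp_parent)(t)
.termsTissue <- function(params, inputTerms) {
    h <- impulseResponse2TCM(params)
    h <- .nudgeRates(h, inputTerms$rate)
    out <- vector("list", nrow(h))
    for (j in seq_len(nrow(h)))
        out[[j]] <- .convTermsExp(inputTerms, h$phi[j], h$theta[j])
    do.call(rbind, out)
}

## Exact frame averages of the full model curve
## C(t) = (1 - Vb) * (h (x) Cp_parent)(t) + Vb * C_wb(t)
.modelFrameAverages <- function(params, input, schedule, parent = NULL) {
    cpTerms <- .termsPlasma(input)
    drive <- if (is.null(parent)) cpTerms else .termsTimesParent(cpTerms, parent)
    tis <- .termsTissue(params, drive)
    t1 <- schedule@start; t2 <- schedule@end
    dur <- t2 - t1
    avg <- (1 - params@Vb) * .intTerms(tis, t1, t2) / dur
    if (params@Vb > 0) {
        wb <- cpTerms
        wb$coef <- wb$coef / input@wbRatio
        avg <- avg + params@Vb * .intTerms(wb, t1, t2) / dur
    }
    avg
}

## Point values of the full model curve at arbitrary times (closed form).
.modelCurveValues <- function(params, input, t, parent = NULL) {
    cpTerms <- .termsPlasma(input)
    drive <- if (is.null(parent)) cpTerms else .termsTimesParent(cpTerms, parent)
    tis <- .termsTissue(params, drive)
    v <- (1 - params@Vb) * .evalTerms(tis, t)
    if (params@Vb > 0)
        v <- v + params@Vb * .evalTerms(cpTerms, t) / input@wbRatio
    v
}

## ---------------------------------------------------------------------------
## Numeric path: grid convolution used by the fitting routines
## ---------------------------------------------------------------------------

## Convolution of a sampled input cp (on a uniform grid, step dt) with
## exp(-theta t), exact for piecewise-linear cp: a first-order recursive
## filter with analytically integrated segment weights.
.convExpGrid <- function(cp, dt, theta) {
    n <- length(cp)
    if (theta <= 0) {            # plain cumulative trapezoid
        inc <- (cp[-n] + cp[-1L]) * dt / 2
        return(c(0, cumsum(inc)))
    }
    u <- theta * dt
    E <- exp(-u)
    if (u < 1e-4) {
        g2 <- dt * (0.5 - u / 6)
        g1 <- dt * (0.5 - u / 3)
    } else {
        g2 <- 1 / theta - (1 - E) / (theta^2 * dt)
        g1 <- (1 - E) / theta - g2
    }
    inc <- g1 * cp[-n] + g2 * cp[-1L]
    c(0, stats::filter(inc, E, method = "recursive"))
}

## Map a frame schedule onto a uniform grid (t = 0, dt, 2dt, ...): frame
## averages by trapezoid over the grid points inside each frame. Frame
## boundaries must sit on the grid.
.frameGridIndex <- function(schedule, dt, nGrid) {
    i1 <- round(schedule@start / dt)
    i2 <- round(schedule@end / dt)
    if (any(abs(i1 * dt - schedule@start) > 1e-8) ||
        any(abs(i2 * dt - schedule@end) > 1e-8))
        stop("frame boundaries do not align with the convolution grid")
    if (max(i2) + 1L > nGrid) stop("grid shorter than the frame schedule")
    list(i1 = i1 + 1L, i2 = i2 + 1L)    # 1-based
}

.frameAveragesFromGrid <- function(curve, dt, idx, duration) {
    vapply(seq_along(idx$i1), function(f) {
        i <- idx$i1[f]:idx$i2[f]
        v <- curve[i]
        (sum(v) - (v[1L] + v[length(v)]) / 2) * dt
    }, numeric(1)) / duration
}

## Model frame averages from gridded inputs (used inside the optimizer).
## grid: list(t, dt, cp, cwb, idx, duration) from .makeFitGrid().
.modelFromGrid <- function(K1, k2, k3, k4, Vb, grid) {
    p <- kineticParams(K1, k2, k3, k4, Vb = 0)
    h <- impulseResponse2TCM(p)
    tis <- 0
    for (j in seq_len(nrow(h)))
        tis <- tis + h$phi[j] * .convExpGrid(grid$cp, grid$dt, h$theta[j])
    curve <- (1 - Vb) * tis + Vb * grid$cwb
    .frameAveragesFromGrid(curve, grid$dt, grid$idx, grid$duration)
}
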