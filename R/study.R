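## End-to-end study pipeline: metabolite correction -> compartment fits with
## AIC selection -> Logan -> occupancy -> V_ND and ED50, with study-level
## summary tables.

#' Study report
#'
#' Container for the tables produced by [runStudy()].
#'
#' @slot perScan data.frame, one row per scan (fitted parameters, macro
#'   parameters, AICs, Logan V_T).
#' @slot groups data.frame, per-dose-group means and SDs (V_T, BP, Vb, Logan).
#' @slot ttests data.frame, baseline vs 30 mg/kg comparisons (when available).
#' @slot occupancy data.frame, per-dose occupancy (mean, SD) per method.
#' @slot ed50 data.frame, ED50/hill/R2/p per method.
#' @slot vnd data.frame, V_ND extrapolation per V_T method.
#' @slot parent the fitted [ParentFractionModel-class].
#' @slot failures character, per-scan failures collected (run continues).
#' @slot truthComparison data.frame comparing estimates with the generator's
#'   ground truth (synthetic studies only; otherwise empty).
#' @export
setClass("StudyReport",
         representation(perScan = "data.frame", groups = "data.frame",
                        ttests = "data.frame", occupancy = "data.frame",
                        ed50 = "data.frame", vnd = "data.frame",
                        parent = "ParentFractionModel",
                        failures = "character",
                        truthComparison = "data.frame"))

setMethod("show", "StudyReport", function(object) {
    cat("StudyReport\n===========\n")
    cat(sprintf("%d scans analysed, %d failures\n",
                nrow(object@perScan), length(object@failures)))
    show(object@parent)
    cat("\nGroup summary (mean +/- SD):\n")
    print(object@groups, digits = 3, row.names = FALSE)
    if (nrow(object@ttests)) {
        cat("\nBaseline vs 30 mg/kg (two-sided unpaired t):\n")
        print(object@ttests, digits = 3, row.names = FALSE)
    }
    cat("\nOccupancy by dose (%):\n")
    print(object@occupancy, digits = 3, row.names = FALSE)
    cat("\nV_ND extrapolation:\n")
    print(object@vnd, digits = 3, row.names = FALSE)
    cat("\nED50 fits:\n")
    print(object@ed50, digits = 3, row.names = FALSE)
    if (nrow(object@truthComparison)) {
        cat("\nGround-truth comparison:\n")
        print(object@truthComparison, digits = 3, row.names = FALSE)
    }
    if (length(object@failures))
        cat("\nFailures:\n", paste(" -", object@failures, collapse = "\n"),
            "\n")
})

.meanSD <- function(x) sprintf("%.3g +/- %.2g", mean(x), stats::sd(x))

#' Run the full occupancy pipeline on a study
#'
#' For every scan: fit the population parent-fraction model (pooled samples),
#' correct the plasma input, fit the one- and two-tissue compartment models
#' (AIC-compared), and run Logan graphical analysis. Then summarize by dose
#' group, extrapolate V_ND from the V_T-versus-dose curves (2TCM and Logan
#' separately), convert to per-scan occupancies against the baseline-mean
#' V_T (and BP_ND), and fit the dose-occupancy curves for ED50. Per-scan
#' failures are collected and the run continues.
#'
#' Per-dose occupancy uses the mean drug-condition estimate against the mean
#' baseline estimate; per-animal occupancies against the baseline mean provide
#' the SD columns. BP-based ED50 is tagged unreliable when its dose-dependence
#' p-value is >= 0.05. Occupancies are flagged, never clipped, when outside
#' [-10, 110].
#'
#' @param study a list as returned by [generateStudy()] or [readStudy()]:
#'   `scans` (list of [ScanRecord-class]), optionally `parentSamples`,
#'   `truth`, `input` (analytic [InputFunctionParams-class]; when present it
#'   drives the fits directly, otherwise the sampled blood series is
#'   interpolated).
#' @param tStarLogan Logan t*, minutes.
#' @param ed50Hill "free" or "fixed" Hill slope for the ED50 fits.
#' @param multistart optimizer starts per compartment fit.
#' @param seed seed for the multistart jitter.
#' @return A [StudyReport-class].
#' @export
runStudy <- function(study, tStarLogan = 10, ed50Hill = c("free", "fixed"),
                     multistart = 5L, seed = 101L) {
    ed50Hill <- match.arg(ed50Hill)
    scans <- study$scans
    stopifnot(length(scans) > 0)

    parentModel <- if (!is.null(study$parentSamples))
        fitParentFraction(study$parentSamples$time,
                          study$parentSamples$fraction)
    else parentFractionModel(1, 0)   # no metabolite data: f == 1

    analytic <- study$input
    failures <- character()
    rows <- list()
    for (s in scans) {
        rows[[s@subjectId]] <- tryCatch({
            if (!is.null(analytic)) {
                input <- analytic
                par <- parentModel
            } else {
                input <- correctPlasma(s@blood, parentModel)
                par <- NULL
            }
            f1 <- fitCompartment(s@tac, input, "1TCM", parent = par,
                                 multistart = multistart, seed = seed)
            f2 <- fitCompartment(s@tac, input, "2TCM", parent = par,
                                 multistart = multistart, seed = seed)
            lg <- loganVT(s@tac, input, tStar = tStarLogan, parent = par)
            data.frame(subjectId = s@subjectId, group = s@group,
                       dose = s@drugDose,
                       K1 = f2@params@K1, k2 = f2@params@k2,
                       k3 = f2@params@k3, k4 = f2@params@k4,
                       Vb = f2@params@Vb, VT = f2@vt, BPND = f2@bpnd,
                       aic1 = f1@aic, aic2 = f2@aic,
                       preferred = if (f2@aic < f1@aic) "2TCM" else "1TCM",
                       VTlogan = lg@slope, r2logan = lg@r2,
                       suv = suv(s@tac, s@injectedDose, s@bodyWeight)$mean,
                       ## flagged fits (k4 at its bound, non-convergence) give
                       ## unstable macro-parameters and are excluded from the
                       ## dose-response stage
                       usable = f2@converged && is.finite(f2@vt) &&
                           !length(f2@flags))
        }, error = function(e) {
            failures <<- c(failures,
                           sprintf("%s: %s", s@subjectId, conditionMessage(e)))
            NULL
        })
    }
    perScan <- do.call(rbind, rows)
    if (is.null(perScan) || nrow(perScan) == 0L)
        stop("every scan failed; nothing to report")
    rownames(perScan) <- NULL

    groups <- do.call(rbind, lapply(split(perScan, perScan$dose), function(g)
        data.frame(dose = g$dose[1L], n = nrow(g),
                   VT = .meanSD(g$VT), BP = .meanSD(g$BPND),
                   Vb = .meanSD(g$Vb), VTlogan = .meanSD(g$VTlogan),
                   SUV = .meanSD(g$suv))))
    rownames(groups) <- NULL

    base <- perScan[perScan$dose == 0, ]
    if (nrow(base) == 0L) stop("study has no baseline (dose 0) scans")
    ttests <- data.frame()
    d30 <- perScan[perScan$dose == 30, ]
    if (nrow(base) >= 2L && nrow(d30) >= 2L) {
        ttests <- do.call(rbind, lapply(
            c(VT = "VT", BP = "BPND", Vb = "Vb", VTlogan = "VTlogan"),
            function(v) {
                ct <- compareGroups(base[[v]], d30[[v]])
                data.frame(parameter = v, t = ct$t, p = ct$p)
            }))
        rownames(ttests) <- NULL
    }

    ok <- perScan[perScan$usable, ]
    if (sum(!perScan$usable))
        failures <- c(failures,
                      sprintf("%s: flagged 2TCM fit excluded from dose-response",
                              perScan$subjectId[!perScan$usable]))
    vnd2 <- fitVND(ok$dose, ok$VT)
    vndL <- fitVND(perScan$dose, perScan$VTlogan)
    vnd <- data.frame(method = c("VT-2TCM", "VT-Logan"),
                      vnd = c(vnd2@vnd, vndL@vnd),
                      id50 = c(vnd2@id50, vndL@id50),
                      r2 = c(vnd2@r2, vndL@r2),
                      reliable = c(vnd2@reliable, vndL@reliable))

    occRows <- list(); ed50Rows <- list()
    methods <- list(
        list(name = "VT-2TCM", col = "VT", vnd = vnd2@vnd, data = ok,
             fn = function(b, v, vn) occupancyFromVT(b, v, vn)),
        list(name = "BP-2TCM", col = "BPND", vnd = NA_real_, data = ok,
             fn = function(b, v, vn) occupancyFromBP(b, v)),
        list(name = "VT-Logan", col = "VTlogan", vnd = vndL@vnd,
             data = perScan,
             fn = function(b, v, vn) occupancyFromVT(b, v, vn)))
    for (m in methods) {
        dat <- m$data
        drugDoses <- sort(unique(dat$dose[dat$dose > 0]))
        bMean <- mean(dat[[m$col]][dat$dose == 0])
        perDose <- tryCatch(do.call(rbind, lapply(drugDoses, function(d) {
            g <- dat[dat$dose == d, ]
            occI <- m$fn(bMean, g[[m$col]], m$vnd)
            occMean <- m$fn(bMean, mean(g[[m$col]]), m$vnd)
            data.frame(method = m$name, dose = d, occupancy = occMean,
                       sd = stats::sd(occI),
                       flagged = occMean < -10 | occMean > 110)
        })), error = function(e) {
            failures <<- c(failures,
                           sprintf("occupancy (%s): %s", m$name,
                                   conditionMessage(e)))
            NULL
        })
        if (is.null(perDose)) next
        occRows[[m$name]] <- perDose
        ef <- tryCatch(fitED50(perDose$dose, perDose$occupancy,
                               hill = ed50Hill),
                       error = function(e) NULL)
        ed50Rows[[m$name]] <- if (is.null(ef))
            data.frame(method = m$name, ed50 = NA_real_, hill = NA_real_,
                       r2 = NA_real_, p = NA_real_, reliable = FALSE)
        else
            data.frame(method = m$name, ed50 = ef@ed50, hill = ef@hill,
                       r2 = ef@r2, p = ef@pValue,
                       reliable = is.finite(ef@pValue) && ef@pValue < 0.05)
    }
    occupancy <- do.call(rbind, occRows); rownames(occupancy) <- NULL
    ed50 <- do.call(rbind, ed50Rows); rownames(ed50) <- NULL

    truthComparison <- data.frame()
    if (!is.null(study$truth) && is(study$truth, "GroundTruth")) {
        tr <- study$truth
        baseTrue <- deriveMacro(tr@baseline)
        truthComparison <- data.frame(
            quantity = c("baseline VT", "baseline BPND", "VND (K1/k2)",
                         "ED50 (VT-2TCM)"),
            truth = c(unname(baseTrue["VT"]), unname(baseTrue["BPND"]),
                      tr@baseline@K1 / tr@baseline@k2, tr@ed50),
            estimate = c(mean(base$VT), mean(base$BPND), vnd2@vnd,
                         ed50$ed50[ed50$method == "VT-2TCM"]))
        truthComparison$relError <-
            truthComparison$estimate / truthComparison$truth - 1
    }

    new("StudyReport", perScan = perScan, groups = groups,
        ttests = ttests, occupancy = occupancy, ed50 = ed50, vnd = vnd,
        parent = parentModel, failures = failures,
        truthComparison = truthComparison)
}
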