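## Readers and writers for the package's tabular on-disk formats. All files
## are comma-separated with a mandatory header row and '.' decimals; times are
## stored in seconds (minutes for parent-fraction files, which are sampled on
## a minutes protocol) and converted to minutes on read. Values round-trip at
## 12+ significant digits.

.requireColumns <- function(df, cols, path) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop(sprintf("%s: missing column(s) %s", path,
                     paste(miss, collapse = ", ")))
}

.readCsv <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop(sprintf("%s: file has no data rows", path))
    df
}

## Re-raise a validity failure as a format error naming the file.
.validateOrFormatError <- function(expr, path) {
    tryCatch(expr, error = function(e)
        stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE))
}

#' Read / write a time-activity curve
#'
#' CSV dialect: columns `frame_start_s`, `frame_end_s`,
#' `activity_kBq_per_ml`; comma-separated, header row mandatory, '.' decimal.
#' Frames must be contiguous, non-overlapping and of positive duration; any
#' violation is reported as a format error naming the offending row.
#'
#' @param path file path.
#' @return [readTAC()] returns a [TimeActivityCurve-class].
#' @export
readTAC <- function(path) {
    df <- .readCsv(path)
    .requireColumns(df, c("frame_start_s", "frame_end_s",
                          "activity_kBq_per_ml"), path)
    bad <- which(df$frame_end_s - df$frame_start_s <= 0)
    if (length(bad))
        stop(sprintf("%s: row %d has non-positive frame duration", path,
                     bad[1L]))
    if (nrow(df) > 1L) {
        ov <- which(abs(df$frame_start_s[-1L] -
                        df$frame_end_s[-nrow(df)]) > 1e-6)
        if (length(ov))
            stop(sprintf("%s: rows %d-%d overlap or leave a gap", path,
                         ov[1L], ov[1L] + 1L))
    }
    .validateOrFormatError(
        timeActivityCurve(frameSchedule(df$frame_start_s, df$frame_end_s,
                                        unit = "sec"),
                          df$activity_kBq_per_ml),
        path)
}

#' @rdname readTAC
#' @param tac a [TimeActivityCurve-class] to write.
#' @export
writeTAC <- function(tac, path) {
    stopifnot(is(tac, "TimeActivityCurve"))
    df <- data.frame(frame_start_s = frameStart(tac, "sec"),
                     frame_end_s = frameEnd(tac, "sec"),
                     activity_kBq_per_ml = activity(tac))
    .writeCsv(df, path)
    invisible(path)
}

.writeCsv <- function(df, path) {
    df[] <- lapply(df, function(x) if (is.numeric(x)) format(x, digits = 15)
                                   else x)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read / write an arterial blood series
#'
#' CSV dialect: columns `time_s`, `whole_blood_kBq_per_ml`,
#' `plasma_kBq_per_ml`; an optional `plasma_parent_kBq_per_ml` column carries
#' the metabolite-corrected plasma.
#'
#' @param path file path.
#' @return [readBlood()] returns a [BloodSeries-class].
#' @export
readBlood <- function(path) {
    df <- .readCsv(path)
    .requireColumns(df, c("time_s", "whole_blood_kBq_per_ml",
                          "plasma_kBq_per_ml"), path)
    if (is.unsorted(df$time_s, strictly = TRUE)) {
        bad <- which(diff(df$time_s) <= 0)[1L] + 1L
        stop(sprintf("%s: row %d breaks strictly increasing sample times",
                     path, bad))
    }
    b <- .validateOrFormatError(
        bloodSeries(df$time_s, df$whole_blood_kBq_per_ml,
                    df$plasma_kBq_per_ml, unit = "sec"),
        path)
    if ("plasma_parent_kBq_per_ml" %in% names(df)) {
        b@plasmaParent <- df$plasma_parent_kBq_per_ml
        b@corrected <- TRUE
        validObject(b)
    }
    b
}

#' @rdname readBlood
#' @param blood a [BloodSeries-class] to write.
#' @export
writeBlood <- function(blood, path) {
    stopifnot(is(blood, "BloodSeries"))
    df <- data.frame(time_s = sampleTimes(blood, "sec"),
                     whole_blood_kBq_per_ml = wholeBlood(blood),
                     plasma_kBq_per_ml = plasma(blood))
    if (length(blood@plasmaParent))
        df$plasma_parent_kBq_per_ml <- blood@plasmaParent
    .writeCsv(df, path)
    invisible(path)
}

#' Read / write parent-fraction measurements
#'
#' CSV dialect: columns `time_min`, `fraction_intact` (0-1). Rows may pool
#' several animals; times need not be unique but must be positive.
#'
#' @param path file path.
#' @return [readParent()] returns a data.frame with columns `time` (min) and
#'   `fraction`.
#' @export
readParent <- function(path) {
    df <- .readCsv(path)
    .requireColumns(df, c("time_min", "fraction_intact"), path)
    bad <- which(df$time_min <= 0 | df$fraction_intact < 0 |
                 df$fraction_intact > 1)
    if (length(bad))
        stop(sprintf("%s: row %d has time <= 0 or fraction outside [0, 1]",
                     path, bad[1L]))
    data.frame(time = df$time_min, fraction = df$fraction_intact)
}

#' @rdname readParent
#' @param samples data.frame with columns `time` (min), `fraction`.
#' @export
writeParent <- function(samples, path) {
    .writeCsv(data.frame(time_min = samples$time,
                         fraction_intact = samples$fraction), path)
    invisible(path)
}

#' Read / write a study directory
#'
#' A study is a YAML file listing one entry per scan (subject_id, group,
#' dose_mg_per_kg, injected_dose_MBq, body_weight_g, tac, blood), optionally a
#' `parent` file and a `seed`, with all file paths relative to the YAML's
#' directory.
#'
#' @param path path to the study YAML.
#' @return [readStudy()] returns a list with `scans` (list of
#'   [ScanRecord-class]), `parentSamples` (data.frame or NULL) and `seed`.
#' @export
readStudy <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$subjects) || !length(cfg$subjects))
        stop(sprintf("%s: study lists no subjects", path))
    dir <- dirname(path)
    ids <- vapply(cfg$subjects, `[[`, "", "subject_id")
    if (anyDuplicated(ids))
        stop(sprintf("%s: duplicate subject_id '%s'", path,
                     ids[anyDuplicated(ids)]))
    scans <- lapply(cfg$subjects, function(s) {
        if (!s$group %in% c("baseline", "drug"))
            stop(sprintf("%s: unknown group label '%s' for subject %s", path,
                         s$group, s$subject_id))
        scanRecord(s$subject_id, s$group, s$dose_mg_per_kg,
                   s$injected_dose_MBq, s$body_weight_g,
                   tac = readTAC(file.path(dir, s$tac)),
                   blood = readBlood(file.path(dir, s$blood)))
    })
    parentSamples <- if (!is.null(cfg$parent))
        readParent(file.path(dir, cfg$parent)) else NULL
    list(scans = scans, parentSamples = parentSamples, seed = cfg$seed)
}

#' @rdname readStudy
#' @param study a list as returned by [generateStudy()] or [readStudy()].
#' @param dir directory to write into (created if absent).
#' @param seed optional seed recorded in the YAML.
#' @return [writeStudy()] returns the path of the written YAML, invisibly.
#' @export
writeStudy <- function(study, dir, seed = NULL) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    subjects <- lapply(study$scans, function(s) {
        tacFile <- sprintf("%s_tac.csv", s@subjectId)
        bloodFile <- sprintf("%s_blood.csv", s@subjectId)
        writeTAC(s@tac, file.path(dir, tacFile))
        writeBlood(s@blood, file.path(dir, bloodFile))
        list(subject_id = s@subjectId, group = s@group,
             dose_mg_per_kg = s@drugDose, injected_dose_MBq = s@injectedDose,
             body_weight_g = s@bodyWeight, tac = tacFile, blood = bloodFile)
    })
    cfg <- list(subjects = subjects)
    if (!is.null(study$parentSamples)) {
        writeParent(study$parentSamples, file.path(dir, "parent.csv"))
        cfg$parent <- "parent.csv"
    }
    if (!is.null(seed)) cfg$seed <- seed
    if (!is.null(study$truth) && is(study$truth, "GroundTruth"))
        utils::write.csv(study$truth@scans,
                         file.path(dir, "ground_truth.csv"),
                         row.names = FALSE)
    out <- file.path(dir, "study.yaml")
    yaml::write_yaml(cfg, out)
    invisible(out)
}

#' Standardized uptake value
#'
#' SUV(t) = C(t) [kBq/ml] * bodyWeight [g] / injectedDose [kBq], assuming unit
#' tissue density. Also returns the duration-weighted mean SUV over a time
#' window (default 0-60 min).
#'
#' @param tac a [TimeActivityCurve-class] (decay-corrected).
#' @param injectedDose injected dose, MBq.
#' @param bodyWeight body weight, g.
#' @param window c(start, end) in minutes for the interval mean.
#' @return list with `curve` (SUV per frame) and `mean` (window mean).
#' @export
suv <- function(tac, injectedDose, bodyWeight, window = c(0, 60)) {
    stopifnot(is(tac, "TimeActivityCurve"))
    if (!is.finite(injectedDose) || injectedDose <= 0)
        stop("injectedDose must be > 0")
    if (!is.finite(bodyWeight) || bodyWeight <= 0)
        stop("bodyWeight must be > 0")
    curve <- activity(tac) * bodyWeight / (injectedDose * 1000)
    s <- frameStart(tac); e <- frameEnd(tac)
    overlap <- pmax(0, pmin(e, window[2L]) - pmax(s, window[1L]))
    if (sum(overlap) == 0) stop("window does not overlap the schedule")
    list(curve = curve, mean = sum(curve * overlap) / sum(overlap))
}
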