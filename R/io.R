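#' Read a long-format table of raw qPCR Ct measurements
#'
#' One well per row. Required columns: `sample_id`, `mirna_id`, `replicate`,
#' `ct`. Ct values equal to any of `undeterminedTokens` (case-insensitive) or
#' left blank are parsed as undetermined (censored at the PCR ceiling); all
#' other values must be numeric in (0, 40].
#'
#' @param path path to a UTF-8, comma-separated file with a header row.
#' @param undeterminedTokens character values treated as the undetermined
#'   sentinel (matched case-insensitively after trimming).
#' @return A data.frame with columns `sample_id`, `mirna_id`, `replicate`
#'   (integer), `ct` (numeric, `NA` when undetermined), `undetermined`
#'   (logical) and `imputed` (logical, all `FALSE` on read).
#' @details Duplicate (sample, miRNA, replicate) keys and malformed rows are
#'   rejected with an error naming the offending line.
#' @seealso [readSampleMeta()], [imputeUndetermined()]
#' @export
readCtTable <- function(path, undeterminedTokens = c("undetermined", "na")) {
    stopifnot(file.exists(path))
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = character(0))
    need <- c("sample_id", "mirna_id", "replicate", "ct")
    if (!all(need %in% colnames(raw)))
        stop("Ct table must have columns: ", paste(need, collapse = ", "))
    line <- seq_len(nrow(raw)) + 1L   # header is line 1
    rep_num <- suppressWarnings(as.integer(raw$replicate))
    bad <- which(is.na(rep_num) | rep_num < 1L)
    if (length(bad))
        stop("malformed replicate index at line ", bad[1] + 1L)
    ct_chr <- trimws(raw$ct)
    undet <- tolower(ct_chr) %in% tolower(undeterminedTokens) | ct_chr == ""
    ct <- suppressWarnings(as.numeric(ct_chr))
    ct[undet] <- NA_real_
    bad <- which(!undet & (is.na(ct) | !is.finite(ct) | ct <= 0 | ct > 40))
    if (length(bad))
        stop("malformed Ct value '", ct_chr[bad[1]], "' at line ",
             line[bad[1]], " (must be numeric in (0, 40] or undetermined)")
    key <- paste(raw$sample_id, raw$mirna_id, rep_num, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup))
        stop("duplicate (sample, miRNA, replicate) key at line ", line[dup[1]],
             ": ", raw$sample_id[dup[1]], " / ", raw$mirna_id[dup[1]],
             " / ", rep_num[dup[1]])
    data.frame(sample_id = raw$sample_id,
               mirna_id = raw$mirna_id,
               replicate = rep_num,
               ct = ct,
               undetermined = undet,
               imputed = FALSE,
               stringsAsFactors = FALSE)
}

#' Write a collection of Ct records back to CSV
#'
#' Full-precision serialisation: a write/read round trip reproduces the
#' records exactly. Undetermined wells are written as `Undetermined`.
#'
#' @param records data.frame as returned by [readCtTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCtTable <- function(records, path) {
    ct_chr <- vapply(records$ct, function(x)
        if (is.na(x)) "Undetermined" else format(x, digits = 17L),
        character(1))
    out <- data.frame(sample_id = records$sample_id,
                      mirna_id = records$mirna_id,
                      replicate = records$replicate,
                      ct = ct_chr)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Read the sample metadata table
#'
#' Required columns: `sample_id`, `subject_id`, `cohort` (one of `HC`,
#' `PROGRESSOR`, `NON_PROGRESSOR`), `timepoint` (`BASELINE`, `FOLLOW_UP`),
#' `age` (years, > 0). Any further columns are carried along as clinical
#' variables (e.g. `VAS`, `TJC28`, `DAS28_ESR`).
#'
#' Healthy controls may only have baseline samples; patient subjects have at
#' most one sample per timepoint. A `paired` column marks subjects with both
#' a baseline and a follow-up sample.
#'
#' @param path path to a CSV file.
#' @return A data.frame of samples with an added logical `paired` column.
#' @seealso [matchedPairs()]
#' @export
readSampleMeta <- function(path) {
    stopifnot(file.exists(path))
    meta <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "subject_id", "cohort", "timepoint", "age")
    if (!all(need %in% colnames(meta)))
        stop("sample metadata must have columns: ",
             paste(need, collapse = ", "))
    validateSampleMeta(meta)
}

#' Validate an in-memory sample metadata table
#'
#' Applies the same vocabulary and pairing checks as [readSampleMeta()].
#'
#' @param meta data.frame of sample metadata.
#' @return `meta` with a recomputed logical `paired` column.
#' @export
validateSampleMeta <- function(meta) {
    bad <- setdiff(unique(meta$cohort), .COHORTS)
    if (length(bad))
        stop("unknown cohort label(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(meta$timepoint), .TIMEPOINTS)
    if (length(bad))
        stop("unknown timepoint label(s): ", paste(bad, collapse = ", "))
    if (any(!is.finite(meta$age) | meta$age <= 0))
        stop("age must be a positive number of years")
    if (any(meta$cohort == "HC" & meta$timepoint == "FOLLOW_UP"))
        stop("healthy-control subjects cannot have FOLLOW_UP samples")
    if (anyDuplicated(meta$sample_id))
        stop("duplicate sample_id in metadata")
    key <- paste(meta$subject_id, meta$timepoint)
    if (anyDuplicated(key))
        stop("a subject may have at most one sample per timepoint")
    bl <- meta$subject_id[meta$timepoint == "BASELINE"]
    fu <- meta$subject_id[meta$timepoint == "FOLLOW_UP"]
    meta$paired <- meta$subject_id %in% intersect(bl, fu)
    meta
}

#' Matched baseline/follow-up pair index
#'
#' @param meta validated sample metadata.
#' @param cohort optional cohort filter.
#' @return data.frame with one row per paired subject: `subject_id`,
#'   `cohort`, `baseline_sample`, `followup_sample`. The map between the two
#'   sample columns is a bijection.
#' @export
matchedPairs <- function(meta, cohort = NULL) {
    if (!is.null(cohort)) meta <- meta[meta$cohort %in% cohort, , drop = FALSE]
    bl <- meta[meta$timepoint == "BASELINE", c("subject_id", "cohort",
                                               "sample_id")]
    fu <- meta[meta$timepoint == "FOLLOW_UP", c("subject_id", "sample_id")]
    m <- merge(bl, fu, by = "subject_id",
               suffixes = c("_baseline", "_followup"))
    data.frame(subject_id = m$subject_id,
               cohort = m$cohort,
               baseline_sample = m$sample_id_baseline,
               followup_sample = m$sample_id_followup,
               stringsAsFactors = FALSE)
}

#' Write a per-miRNA report table, rounded as published
#'
#' Fold and dCt columns are rounded to 1 decimal and AUC-scale columns to 2
#' decimals (the reporting precision of the study tables); a full-precision
#' companion file (`*_full.csv`) is always written alongside.
#'
#' @param tab data.frame (e.g. from [withinPatientFC()], [betweenGroupFD()],
#'   [rocTable()] or `as.data.frame` of a [SelectionReport-class]).
#' @param path output CSV path.
#' @param foldDigits,aucDigits decimals for fold/dCt columns and for
#'   proportion-scale columns.
#' @return `path`, invisibly.
#' @export
writeReportTable <- function(tab, path, foldDigits = 1L, aucDigits = 2L) {
    stopifnot(is.data.frame(tab))
    full <- sub("\\.csv$", "_full.csv", path)
    if (identical(full, path)) full <- paste0(path, "_full")
    utils::write.csv(tab, full, row.names = FALSE)
    out <- tab
    auc_cols <- grepl("^(auc|ci_low|ci_high|sensitivity|specificity|youden|rho|consistency_fraction)$",
                      colnames(out))
    for (j in seq_along(out)) {
        if (!is.numeric(out[[j]])) next
        out[[j]] <- round(out[[j]], if (auc_cols[j]) aucDigits else foldDigits)
    }
    utils::write.csv(out, path, row.names = FALSE)
    invisible(path)
}

#' Serialise a SelectionReport to JSON
#'
#' @param report a [SelectionReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSelectionReport <- function(report, path) {
    stopifnot(is(report, "SelectionReport"))
    jsonlite::write_json(
        list(panel = report@panel,
             table = selectionTable(report),
             params = report@params),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    invisible(path)
}

#' Published phase-summary reference tables
#'
#' Per-miRNA summary statistics of the two study phases as printed in the
#' original serum miRNA progression study (medians and IQRs of dCt/ddCt,
#' fold differences and changes, consistency counts, reliability and
#' provenance flags). These are the desk-checkable inputs used by the test
#' suite and the acceptance script; they are reference data, not outputs of
#' this package.
#'
#' @return data.frame of the pilot (31 miRNAs) or validation phase summary.
#' @name referenceSummaries
#' @aliases referencePilotSummary referenceValidationSummary
NULL

#' @rdname referenceSummaries
#' @export
referencePilotSummary <- function() {
    utils::read.csv(system.file("extdata", "pilot_phase_summary.csv",
                                package = "miRprog", mustWork = TRUE),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname referenceSummaries
#' @export
referenceValidationSummary <- function() {
    utils::read.csv(system.file("extdata", "validation_phase_summary.csv",
                                package = "miRprog", mustWork = TRUE),
                    stringsAsFactors = FALSE, check.names = FALSE)
}
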