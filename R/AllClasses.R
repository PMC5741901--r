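#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
NULL

.COHORTS <- c("HC", "PROGRESSOR", "NON_PROGRESSOR")
.TIMEPOINTS <- c("BASELINE", "FOLLOW_UP")

#' DctExperiment: normalised delta-Ct values with per-cell QC provenance
#'
#' A \linkS4class{SummarizedExperiment} subclass holding the per-sample,
#' per-miRNA normalised dCt grid produced by [computeDct()]. Rows are miRNAs,
#' columns are samples (one physical serum sample, i.e. one subject at one
#' timepoint). dCt is on the log2 scale relative to the endogenous control;
#' lower dCt means higher expression.
#'
#' Assays (all miRNA x sample):
#' \describe{
#'   \item{`dct`}{numeric mean delta-Ct; `NA` where the cell is missing.}
#'   \item{`imputed`}{logical; any contributing well was an undetermined Ct
#'     replaced by the detection-limit imputation value.}
#'   \item{`lowExpression`}{logical; any contributing raw Ct exceeded the
#'     low-expression cutoff (default 32 cycles). Sticky: it propagates to
#'     every fold statistic that touches the cell.}
#'   \item{`missing`}{logical; no retained replicate supports the cell.}
#' }
#'
#' `colData` carries the sample metadata (`sample_id`, `subject_id`,
#' `cohort`, `timepoint`, `age`, optional clinical scores).
#'
#' @seealso [computeDct()], [dctValues()], [flagImputed()],
#'   [flagLowExpression()], [flagMissing()]
#' @export
setClass("DctExperiment", contains = "SummarizedExperiment")

setValidity("DctExperiment", function(object) {
    msg <- character()
    needed <- c("dct", "imputed", "lowExpression", "missing")
    if (!all(needed %in% assayNames(object)))
        msg <- c(msg, paste("assays must include:",
                            paste(needed, collapse = ", ")))
    cd <- colData(object)
    for (col in c("sample_id", "subject_id", "cohort", "timepoint", "age"))
        if (!col %in% colnames(cd))
            msg <- c(msg, paste("colData lacks column", col))
    if ("cohort" %in% colnames(cd) &&
        !all(cd$cohort %in% .COHORTS))
        msg <- c(msg, "cohort labels must be HC, PROGRESSOR or NON_PROGRESSOR")
    if ("timepoint" %in% colnames(cd) &&
        !all(cd$timepoint %in% .TIMEPOINTS))
        msg <- c(msg, "timepoint labels must be BASELINE or FOLLOW_UP")
    if (all(needed %in% assayNames(object))) {
        dct <- assay(object, "dct")
        mis <- assay(object, "missing")
        if (any(is.na(dct) & !mis))
            msg <- c(msg, "NA dct cells must carry the missing flag")
    }
    if (length(msg)) msg else TRUE
})

#' Build a DctExperiment from an existing dCt matrix
#'
#' Constructor for workflows that start from already-normalised dCt values
#' (e.g. published summary reconstructions or external normalisation):
#' wraps a miRNA x sample matrix and sample metadata into the class used by
#' every downstream operation. Flag matrices default to all-`FALSE`
#' (`missing` defaults to `is.na(dct)`).
#'
#' @param dct numeric matrix, miRNAs x samples; column names must match
#'   `meta$sample_id`.
#' @param meta sample metadata (see [readSampleMeta()] for the contract).
#' @param imputed,lowExpression,missing optional logical matrices with the
#'   dimensions of `dct`.
#' @return A [DctExperiment-class].
#' @export
dctExperimentFromMatrix <- function(dct, meta, imputed = NULL,
                                    lowExpression = NULL, missing = NULL) {
    stopifnot(is.matrix(dct), !is.null(colnames(dct)))
    meta <- validateSampleMeta(meta)
    if (!identical(colnames(dct), meta$sample_id))
        stop("column names of dct must equal meta$sample_id (same order)")
    blank <- matrix(FALSE, nrow(dct), ncol(dct), dimnames = dimnames(dct))
    if (is.null(imputed)) imputed <- blank
    if (is.null(lowExpression)) lowExpression <- blank
    if (is.null(missing)) missing <- is.na(dct)
    se <- SummarizedExperiment(
        assays = list(dct = dct, imputed = imputed,
                      lowExpression = lowExpression, missing = missing),
        colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
    new("DctExperiment", se)
}

#' SelectionReport: per-miRNA criteria evaluation and the assembled panel
#'
#' Produced by [assemblePanel()]. `selectionTable()` returns the per-miRNA
#' evaluation (threshold passes, consistency fraction, rescue /
#' newly-expressed / literature / keep-list provenance, tier) and `panel()`
#' the final ordered miRNA id list.
#'
#' @slot table data.frame, one row per miRNA considered.
#' @slot panel character, ordered final candidate list.
#' @slot params list, the selection configuration used.
#' @seealso [assemblePanel()], [selectionConfig()]
#' @export
setClass("SelectionReport",
         representation(table = "data.frame",
                        panel = "character",
                        params = "list"))

setValidity("SelectionReport", function(object) {
    tab <- object@table
    msg <- character()
    need <- c("mirna", "passes_fd", "passes_fc", "consistency_fraction",
              "rescued_by_mean_fc", "newly_expressed", "literature_panel",
              "selected")
    if (!all(need %in% colnames(tab)))
        msg <- c(msg, paste("table lacks columns:",
                            paste(setdiff(need, colnames(tab)),
                                  collapse = ", ")))
    else {
        kept <- if ("kept_by_config" %in% colnames(tab))
            tab$kept_by_config else FALSE
        bad <- tab$selected & !(tab$passes_fd | tab$passes_fc |
                                tab$rescued_by_mean_fc | tab$newly_expressed |
                                tab$literature_panel | kept)
        if (any(bad))
            msg <- c(msg, "selected miRNAs must satisfy at least one rule")
        if (!all(object@panel %in% tab$mirna))
            msg <- c(msg, "panel members must appear in the table")
    }
    if (length(msg)) msg else TRUE
})
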