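#' Pipeline configuration
#'
#' Bundles the stage configurations and the reporting conventions shared by
#' [runPilot()] and [runValidation()].
#'
#' @param preprocess a [preprocessConfig()].
#' @param selection a [selectionConfig()].
#' @param referenceAge age at which adjusted medians are evaluated
#'   (`NULL` = pooled mean of the compared samples; the study reports at its
#'   pooled mean age of 52).
#' @param rocLevel,rocB,rocSeed bootstrap CI settings for the ROC stage.
#' @param clinicalVars clinical columns tested for Spearman association
#'   (skipped when absent from the metadata).
#' @return classed parameter list.
#' @export
pipelineConfig <- function(preprocess = preprocessConfig(),
                           selection = selectionConfig(),
                           referenceAge = NULL,
                           rocLevel = 0.90, rocB = 2000L, rocSeed = 1L,
                           clinicalVars = c("VAS", "TJC28", "DAS28_ESR")) {
    structure(list(preprocess = preprocess, selection = selection,
                   referenceAge = referenceAge, rocLevel = rocLevel,
                   rocB = as.integer(rocB), rocSeed = as.integer(rocSeed),
                   clinicalVars = clinicalVars),
              class = "pipelineConfig")
}

#' Run the pilot screening phase
#'
#' Preprocesses raw Ct records, computes raw and age-adjusted fold
#' differences of the progressors' baseline ("CCP") and follow-up ("VERA")
#' samples against healthy controls, the within-progressor fold changes,
#' applies the selection rules (threshold + consistency, mean-fold rescue,
#' newly-expressed detection) and assembles the candidate panel.
#'
#' @param ct Ct records ([readCtTable()] format).
#' @param meta sample metadata ([readSampleMeta()] format).
#' @param config a [pipelineConfig()].
#' @param outDir optional directory for report CSVs/JSON.
#' @return list: `experiment`, `fd_ccp_hc`, `fd_vera_hc` (age-adjusted fold
#'   tables; `*_raw` unadjusted), `fc` (selection-annotated within-patient
#'   table), `rescue`, `newly_expressed`, `report` (a
#'   [SelectionReport-class]), `table1` (the combined per-miRNA summary),
#'   `qc`.
#' @export
runPilot <- function(ct, meta, config = pipelineConfig(), outDir = NULL) {
    meta <- validateSampleMeta(meta)
    for (needed in c("HC", "PROGRESSOR"))
        if (!any(meta$cohort == needed))
            stop("pilot phase requires cohort ", needed)
    prep <- preprocessCt(ct, meta, config$preprocess)
    x <- prep$experiment
    if (nrow(x) == 0) stop("no miRNA assays present after preprocessing")

    fd_ccp_raw <- betweenGroupFD(x, "PROGRESSOR", "HC",
                                 "BASELINE", "BASELINE")
    fd_vera_raw <- betweenGroupFD(x, "PROGRESSOR", "HC",
                                  "FOLLOW_UP", "BASELINE")
    fd_ccp <- betweenGroupFD(x, "PROGRESSOR", "HC", "BASELINE", "BASELINE",
                             adjustAge = TRUE,
                             referenceAge = config$referenceAge)
    fd_vera <- betweenGroupFD(x, "PROGRESSOR", "HC", "FOLLOW_UP", "BASELINE",
                              adjustAge = TRUE,
                              referenceAge = config$referenceAge)
    fc <- selectProgressionCandidates(withinPatientFC(x, "PROGRESSOR"),
                                      config$selection)
    pd <- patientDdct(x, "PROGRESSOR")
    rescue <- rescueByMeanFC(pd$ddct, config$selection)
    newly <- detectNewlyExpressed(x, "PROGRESSOR", config$selection)

    dys <- unique(c(countDysregulated(fd_ccp, config$selection)$mirnas,
                    countDysregulated(fd_vera, config$selection)$mirnas))
    mags <- pmax(abs(fd_ccp$signed_value[match(rownames(dctValues(x)),
                                               fd_ccp$mirna)]),
                 abs(fd_vera$signed_value[match(rownames(dctValues(x)),
                                                fd_vera$mirna)]),
                 abs(fc$signed_value[match(rownames(dctValues(x)),
                                           fc$mirna)]), na.rm = TRUE)
    names(mags) <- rownames(dctValues(x))
    report <- assemblePanel(
        dysregulated = dys, candidates = fc,
        rescued = rescue$mirna[rescue$rescued_by_mean_fc],
        newlyExpressed = newly$mirna[newly$newly_expressed],
        config = config$selection, foldMagnitudes = mags)

    table1 <- .pilotSummaryTable(fd_ccp, fd_vera, fc)
    out <- list(experiment = x,
                fd_ccp_hc_raw = fd_ccp_raw, fd_vera_hc_raw = fd_vera_raw,
                fd_ccp_hc = fd_ccp, fd_vera_hc = fd_vera,
                fc = fc, rescue = rescue, newly_expressed = newly,
                report = report, table1 = table1, qc = prep$qc)
    if (!is.null(outDir)) .writePilotOutputs(out, outDir)
    out
}

#' @noRd
.pilotSummaryTable <- function(fd_ccp, fd_vera, fc) {
    ids <- union(union(fd_ccp$mirna, fd_vera$mirna), fc$mirna)
    i1 <- match(ids, fd_ccp$mirna); i2 <- match(ids, fd_vera$mirna)
    i3 <- match(ids, fc$mirna)
    data.frame(
        mirna = ids,
        hc_median = fd_ccp$median_b[i1],
        hc_q1 = fd_ccp$q1_b[i1], hc_q3 = fd_ccp$q3_b[i1],
        ccp_median = fd_ccp$median_a[i1],
        ccp_q1 = fd_ccp$q1_a[i1], ccp_q3 = fd_ccp$q3_a[i1],
        vera_median = fd_vera$median_a[i2],
        vera_q1 = fd_vera$q1_a[i2], vera_q3 = fd_vera$q3_a[i2],
        fd_ccp_hc = fd_ccp$signed_value[i1],
        fd_vera_hc = fd_vera$signed_value[i2],
        ddct_median = fc$ddct_median[i3],
        ddct_q1 = fc$ddct_q1[i3], ddct_q3 = fc$ddct_q3[i3],
        fc_median = fc$signed_value[i3],
        n_up = fc$n_consistent[i3], n_evaluable = fc$n_evaluable[i3],
        reliable = fd_ccp$reliable[i1] & fd_vera$reliable[i2] &
            fc$reliable[i3],
        stringsAsFactors = FALSE)
}

#' @noRd
.writePilotOutputs <- function(res, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeReportTable(res$table1, file.path(outDir, "pilot_summary.csv"))
    writeReportTable(res$fc, file.path(outDir, "pilot_fc.csv"))
    writeReportTable(res$fd_ccp_hc, file.path(outDir, "pilot_fd_ccp_hc.csv"))
    writeReportTable(res$fd_vera_hc,
                     file.path(outDir, "pilot_fd_vera_hc.csv"))
    writeReportTable(selectionTable(res$report),
                     file.path(outDir, "pilot_selection.csv"))
    writeSelectionReport(res$report,
                         file.path(outDir, "pilot_selection.json"))
    writeLines(res$qc, file.path(outDir, "pilot_qc.log"))
    invisible(outDir)
}

#' Run the validation phase
#'
#' For a panel of candidate miRNAs: within-patient fold changes in
#' progressors and non-progressors, baseline progressor-vs-non-progressor
#' fold differences (raw and age-adjusted), per-miRNA baseline ROC with
#' Youden operating point and stratified bootstrap CI, Spearman clinical
#' associations (when clinical columns are present), and re-testing of the
#' dysregulation criterion against healthy controls (`validated` flag).
#'
#' @param ct,meta,config as in [runPilot()].
#' @param panel character vector of candidate miRNA ids (e.g. from the
#'   pilot [SelectionReport-class]).
#' @param outDir optional output directory.
#' @return list: `experiment`, `fc_prog`, `fc_nonprog`, `fd_baseline`
#'   (+`_raw`), `roc`, `clinical`, `validated`, `table2`, `qc`.
#' @export
runValidation <- function(ct, meta, config = pipelineConfig(), panel,
                          outDir = NULL) {
    if (missing(panel) || !length(panel))
        stop("validation requires a non-empty candidate panel")
    meta <- validateSampleMeta(meta)
    for (needed in c("PROGRESSOR", "NON_PROGRESSOR"))
        if (!any(meta$cohort == needed))
            stop("validation phase requires cohort ", needed)
    prep <- preprocessCt(ct, meta, config$preprocess)
    x <- prep$experiment
    keep <- intersect(panel, rownames(dctValues(x)))
    if (!length(keep)) stop("none of the panel miRNAs are present")
    x <- x[keep, ]

    fc_prog <- selectProgressionCandidates(withinPatientFC(x, "PROGRESSOR"),
                                           config$selection)
    fc_nonprog <- withinPatientFC(x, "NON_PROGRESSOR")
    fd_raw <- betweenGroupFD(x, "PROGRESSOR", "NON_PROGRESSOR",
                             "BASELINE", "BASELINE")
    fd_adj <- betweenGroupFD(x, "PROGRESSOR", "NON_PROGRESSOR",
                             "BASELINE", "BASELINE", adjustAge = TRUE,
                             referenceAge = config$referenceAge)
    roc <- rocTable(x, level = config$rocLevel, B = config$rocB,
                    seed = config$rocSeed)
    clin <- NULL
    have <- intersect(config$clinicalVars, colnames(colData(x)))
    if (length(have)) {
        cl <- as.data.frame(colData(x))[have]
        if (any(!vapply(cl, function(v) all(is.na(v)), logical(1))))
            clin <- clinicalAssociations(x, have)
    }
    validated <- character()
    if (any(meta$cohort == "HC")) {
        fd_vera_hc <- betweenGroupFD(x, "PROGRESSOR", "HC",
                                     "FOLLOW_UP", "BASELINE",
                                     adjustAge = TRUE,
                                     referenceAge = config$referenceAge)
        validated <- countDysregulated(fd_vera_hc,
                                       config$selection)$mirnas
    }

    ids <- rownames(dctValues(x))
    i1 <- match(ids, fc_prog$mirna); i2 <- match(ids, fc_nonprog$mirna)
    i3 <- match(ids, fd_raw$mirna); i4 <- match(ids, roc$mirna)
    table2 <- data.frame(
        mirna = ids,
        fc_prog_median = fc_prog$signed_value[i1],
        fc_prog_q1 = signedFold(fc_prog$ddct_q3[i1]),
        fc_prog_q3 = signedFold(fc_prog$ddct_q1[i1]),
        fc_nonprog_median = fc_nonprog$signed_value[i2],
        bl_nonprog_median = fd_raw$median_b[i3],
        bl_nonprog_q1 = fd_raw$q1_b[i3], bl_nonprog_q3 = fd_raw$q3_b[i3],
        bl_prog_median = fd_raw$median_a[i3],
        bl_prog_q1 = fd_raw$q1_a[i3], bl_prog_q3 = fd_raw$q3_a[i3],
        fd_baseline = fd_raw$signed_value[i3],
        auc = roc$auc[i4], ci_low = roc$ci_low[i4],
        ci_high = roc$ci_high[i4],
        sensitivity = roc$sensitivity[i4],
        specificity = roc$specificity[i4],
        validated = ids %in% validated,
        stringsAsFactors = FALSE)
    out <- list(experiment = x, fc_prog = fc_prog, fc_nonprog = fc_nonprog,
                fd_baseline_raw = fd_raw, fd_baseline = fd_adj, roc = roc,
                clinical = clin, validated = validated, table2 = table2,
                qc = prep$qc)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeReportTable(table2, file.path(outDir, "validation_summary.csv"))
        writeReportTable(roc, file.path(outDir, "validation_roc.csv"))
        if (!is.null(clin))
            writeReportTable(clin,
                             file.path(outDir, "validation_clinical.csv"))
        writeLines(out$qc, file.path(outDir, "validation_qc.log"))
    }
    out
}
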