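#' Preprocessing configuration
#'
#' Parameters governing the raw-Ct to dCt stage.
#'
#' @param controlName endogenous control assay name (default `"RNU6B"`).
#' @param imputeCt cycles substituted for undetermined wells. The detection
#'   ceiling convention (default 35, below the 40-cycle PCR limit).
#' @param plausibilityFloor raw Ct strictly below this is treated as an
#'   implausible well (non-specific amplification) and excluded (default 8).
#' @param lowExpressionCt any contributing raw Ct above this flags the cell
#'   as low-expression / unreliable (default 32).
#' @param controlValidRange expected control Ct window (default c(23, 26));
#'   violations warn but do not fail.
#' @return A classed list of validated parameters.
#' @export
preprocessConfig <- function(controlName = "RNU6B",
                             imputeCt = 35,
                             plausibilityFloor = 8,
                             lowExpressionCt = 32,
                             controlValidRange = c(23, 26)) {
    stopifnot(plausibilityFloor < lowExpressionCt, lowExpressionCt < 40,
              imputeCt <= 40, length(controlValidRange) == 2L,
              controlValidRange[1] < controlValidRange[2])
    structure(list(controlName = controlName, imputeCt = imputeCt,
                   plausibilityFloor = plausibilityFloor,
                   lowExpressionCt = lowExpressionCt,
                   controlValidRange = controlValidRange),
              class = "preprocessConfig")
}

#' Impute undetermined Ct values at the detection ceiling
#'
#' Every undetermined well receives `config$imputeCt` cycles and is marked
#' imputed; the mark is sticky and propagates through dCt aggregation into
#' the reliability flag of any downstream fold statistic.
#'
#' @param records Ct records from [readCtTable()].
#' @param config a [preprocessConfig()].
#' @param quiet suppress the imputation-count message.
#' @return The records with `ct` filled in and `imputed` set.
#' @export
imputeUndetermined <- function(records, config = preprocessConfig(),
                               quiet = FALSE) {
    idx <- records$undetermined & !records$imputed
    records$ct[idx] <- config$imputeCt
    records$imputed[idx] <- TRUE
    if (!quiet && any(idx))
        message(sum(idx), " undetermined Ct value(s) imputed at ",
                config$imputeCt, " cycles")
    records
}

#' Exclude implausibly low raw Ct wells
#'
#' Non-imputed wells with raw Ct strictly below `config$plausibilityFloor`
#' are removed (a conservative guard against spurious very-early
#' amplification); remaining replicates still support the cell. Imputed
#' wells are never implausible. Idempotent.
#'
#' @inheritParams imputeUndetermined
#' @return list with elements `records` (retained wells) and `exclusions`
#'   (removed wells with a `reason` column).
#' @export
excludeImplausible <- function(records, config = preprocessConfig(),
                               quiet = FALSE) {
    idx <- !records$imputed & !is.na(records$ct) &
        records$ct < config$plausibilityFloor
    excl <- records[idx, , drop = FALSE]
    if (nrow(excl)) {
        excl$reason <- sprintf("raw Ct %.2f below plausibility floor %.2f",
                               excl$ct, config$plausibilityFloor)
        if (!quiet)
            message(nrow(excl), " implausible well(s) excluded")
    } else excl$reason <- character(0)
    list(records = records[!idx, , drop = FALSE], exclusions = excl)
}

#' Normalise Ct records to a dCt matrix with QC flags
#'
#' For each sample the mean of the retained endogenous-control replicates is
#' subtracted from each retained miRNA replicate, and the replicate mean is
#' taken:
#' \deqn{dCt = mean_r(Ct_r) - mean(Ct_{control})}
#' Cells flag `imputed` if any contributing well was imputed,
#' `lowExpression` if any contributing Ct (imputed value included) exceeds
#' the low-expression cutoff, and `missing` if no retained well supports
#' them. A sample whose control mean falls outside `controlValidRange`
#' triggers a warning (the control is expected to be stable, Ct 23-26).
#'
#' @param records imputed/filtered Ct records.
#' @param meta validated sample metadata covering every sample in `records`.
#' @param config a [preprocessConfig()].
#' @param mirnas assay names the matrix must cover (default: those present
#'   in `records`); assays whose every well was excluded appear as MISSING
#'   rows rather than vanishing.
#' @return A [DctExperiment-class].
#' @export
computeDct <- function(records, meta, config = preprocessConfig(),
                       mirnas = NULL) {
    meta <- validateSampleMeta(meta)
    if (!all(records$sample_id %in% meta$sample_id))
        stop("Ct records reference samples absent from the metadata: ",
             paste(utils::head(setdiff(records$sample_id, meta$sample_id)),
                   collapse = ", "))
    samples <- meta$sample_id
    is_ctrl <- records$mirna_id == config$controlName
    ctrl <- records[is_ctrl & !is.na(records$ct), , drop = FALSE]
    no_ctrl <- setdiff(samples, unique(ctrl$sample_id))
    if (length(no_ctrl))
        stop("no retained control (", config$controlName,
             ") replicates for sample(s): ",
             paste(no_ctrl, collapse = ", "))
    ctrl_mean <- vapply(split(ctrl$ct, ctrl$sample_id), mean, numeric(1))
    out_rng <- ctrl_mean < config$controlValidRange[1] |
        ctrl_mean > config$controlValidRange[2]
    if (any(out_rng))
        warning("control mean Ct outside [",
                config$controlValidRange[1], ", ",
                config$controlValidRange[2], "] for sample(s): ",
                paste(names(ctrl_mean)[out_rng], collapse = ", "))

    targ <- records[!is_ctrl & !is.na(records$ct), , drop = FALSE]
    if (is.null(mirnas))
        mirnas <- unique(records$mirna_id[!is_ctrl])
    mirnas <- sort(setdiff(mirnas, config$controlName))
    targ <- targ[targ$mirna_id %in% mirnas, , drop = FALSE]
    ns <- length(samples); nm <- length(mirnas)
    i <- match(targ$sample_id, samples)
    j <- match(targ$mirna_id, mirnas)
    li <- (j - 1L) * ns + i                        # linear sample x miRNA cell
    nmat <- matrix(tabulate(li, nbins = ns * nm), ns, nm,
                   dimnames = list(samples, mirnas))
    ctsum <- matrix(0, ns, nm, dimnames = list(samples, mirnas))
    s <- rowsum(targ$ct, group = li)
    ctsum[as.integer(rownames(s))] <- s[, 1]
    dct_sm <- ctsum / nmat - ctrl_mean[samples]    # sample x miRNA
    dct_sm[nmat == 0L] <- NA_real_

    flagAny <- function(cond) {
        m <- matrix(FALSE, length(samples), length(mirnas),
                    dimnames = list(samples, mirnas))
        sub <- targ[cond, , drop = FALSE]
        if (nrow(sub))
            m[cbind(match(sub$sample_id, samples),
                    match(sub$mirna_id, mirnas))] <- TRUE
        m
    }
    imput <- flagAny(targ$imputed)
    lowex <- flagAny(targ$ct > config$lowExpressionCt)
    miss <- nmat == 0L

    cd <- S4Vectors::DataFrame(meta, row.names = meta$sample_id)
    se <- SummarizedExperiment(
        assays = list(dct = t(dct_sm), imputed = t(imput),
                      lowExpression = t(lowex), missing = t(miss)),
        colData = cd)
    obj <- new("DctExperiment", se)
    metadata(obj)$preprocess <- unclass(config)
    obj
}

#' Run the full preprocessing stage
#'
#' Imputation, implausibility exclusion and control normalisation in one
#' call, returning the [DctExperiment-class] plus a QC log.
#'
#' @inheritParams computeDct
#' @param quiet suppress QC messages.
#' @return list with `experiment` (a `DctExperiment`), `exclusions`
#'   (data.frame of removed wells) and `qc` (character log lines).
#' @export
preprocessCt <- function(records, meta, config = preprocessConfig(),
                         quiet = TRUE) {
    n_undet <- sum(records$undetermined & !records$imputed)
    assayed <- unique(records$mirna_id)
    records <- imputeUndetermined(records, config, quiet = quiet)
    filtered <- excludeImplausible(records, config, quiet = quiet)
    exper <- computeDct(filtered$records, meta, config, mirnas = assayed)
    qc <- c(sprintf("imputed %d undetermined well(s) at Ct %.1f",
                    n_undet, config$imputeCt),
            sprintf("excluded %d implausible well(s) below Ct %.1f",
                    nrow(filtered$exclusions), config$plausibilityFloor),
            sprintf("low-expression cells (any raw Ct > %.0f): %d",
                    config$lowExpressionCt,
                    sum(assay(exper, "lowExpression"))))
    list(experiment = exper, exclusions = filtered$exclusions, qc = qc)
}
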