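#' Candidate-selection configuration
#'
#' @param foldThreshold minimum |signed fold| for dysregulation (default 4,
#'   inclusive).
#' @param consistencyThreshold minimum fraction of patients changing in the
#'   median's direction (default 0.75, inclusive).
#' @param literaturePanel miRNA ids always carried on the panel because of
#'   prior disease evidence (default: the nine established RA-associated
#'   miRNAs).
#' @param keepList miRNA ids retained on the panel by explicit decision even
#'   if they lose criteria status (e.g. after age adjustment).
#' @param enableMeanFcRescue,enableNewlyExpressed toggles for the two
#'   auxiliary panel-entry routes.
#' @param meanFcMode how the rescue-rule "mean FC" is computed:
#'   `"per_patient"` (mean of per-patient signed folds, default) or
#'   `"mean_ddct"` (signed fold of the mean ddCt).
#' @param newlyExpressedBaseline minimum fraction of progressors with an
#'   undetected/low baseline cell (default 0.5).
#' @param newlyExpressedFollowup minimum fraction with a cleanly detected
#'   follow-up cell (default 0.75).
#' @param panelCapacity assay capacity of a custom card (default 31); a
#'   larger panel warns.
#' @return A classed parameter list.
#' @export
selectionConfig <- function(foldThreshold = 4,
                            consistencyThreshold = 0.75,
                            literaturePanel = c("miR-21", "miR-146a",
                                                "miR-155", "miR-18a",
                                                "miR-34a", "miR-203",
                                                "miR-223", "miR-16",
                                                "miR-132"),
                            keepList = character(),
                            enableMeanFcRescue = TRUE,
                            enableNewlyExpressed = TRUE,
                            meanFcMode = c("per_patient", "mean_ddct"),
                            newlyExpressedBaseline = 0.5,
                            newlyExpressedFollowup = 0.75,
                            panelCapacity = 31L) {
    stopifnot(foldThreshold >= 1, consistencyThreshold > 0,
              consistencyThreshold <= 1)
    structure(list(foldThreshold = foldThreshold,
                   consistencyThreshold = consistencyThreshold,
                   literaturePanel = literaturePanel,
                   keepList = keepList,
                   enableMeanFcRescue = enableMeanFcRescue,
                   enableNewlyExpressed = enableNewlyExpressed,
                   meanFcMode = match.arg(meanFcMode),
                   newlyExpressedBaseline = newlyExpressedBaseline,
                   newlyExpressedFollowup = newlyExpressedFollowup,
                   panelCapacity = as.integer(panelCapacity)),
              class = "selectionConfig")
}

#' Count dysregulated miRNAs in a fold table
#'
#' A miRNA is dysregulated when |signed fold| meets the threshold
#' (inclusive) and its fold is reliable (no imputed or low-expression cell
#' contributed).
#'
#' @param foldTable data.frame from [betweenGroupFD()] or
#'   [withinPatientFC()] (columns `mirna`, `signed_value`, `reliable`).
#' @param config a [selectionConfig()].
#' @return list: `mirnas` (ids), `up` (positive folds), `down` (negative),
#'   `n_up`, `n_down`.
#' @export
countDysregulated <- function(foldTable, config = selectionConfig()) {
    hit <- abs(foldTable$signed_value) >= config$foldThreshold &
        foldTable$reliable
    up <- foldTable$mirna[hit & foldTable$signed_value > 0]
    down <- foldTable$mirna[hit & foldTable$signed_value < 0]
    list(mirnas = foldTable$mirna[hit], up = up, down = down,
         n_up = length(up), n_down = length(down))
}

#' Select progression candidates from within-patient fold changes
#'
#' The stringent pilot rule: |median FC| >= `foldThreshold` AND the change
#' direction consistent in >= `consistencyThreshold` of evaluable patients
#' AND a reliable fold (no imputed / low-expression contribution). Both
#' thresholds are inclusive (9/12 = 0.75 passes).
#'
#' @param fcTable data.frame from [withinPatientFC()].
#' @param config a [selectionConfig()].
#' @return `fcTable` with added `consistency_fraction`, `passes_fc` (the
#'   threshold conjunction ignoring reliability) and `selected`.
#' @export
selectProgressionCandidates <- function(fcTable, config = selectionConfig()) {
    out <- fcTable
    out$consistency_fraction <- out$n_consistent / out$n_evaluable
    out$passes_fc <- abs(out$signed_value) >= config$foldThreshold &
        out$consistency_fraction >= config$consistencyThreshold
    out$selected <- out$passes_fc & out$reliable
    out
}

#' Mean-fold rescue of near-threshold miRNAs
#'
#' A miRNA whose median FC misses the threshold may still enter the panel if
#' its mean fold change meets it and dysregulation is consistent: the study
#' retained one candidate this way (mean FC 4.27, consistent in 11/12).
#' The mean fold is either the mean of per-patient signed folds (default) or
#' the signed fold of the mean ddCt, per `config$meanFcMode`.
#'
#' @param ddct miRNA x patient matrix of per-patient ddCt values (`NA`
#'   allowed), e.g. `patientDdct(x)$ddct`.
#' @param config a [selectionConfig()].
#' @return data.frame: `mirna`, `mean_fc`, `consistency_fraction`,
#'   `rescued_by_mean_fc`.
#' @export
rescueByMeanFC <- function(ddct, config = selectionConfig()) {
    rows <- lapply(rownames(ddct), function(m) {
        v <- ddct[m, ]; v <- v[!is.na(v)]
        if (!length(v)) return(NULL)
        mean_fc <- if (config$meanFcMode == "per_patient")
            mean(signedFold(v)) else signedFold(mean(v))
        med <- stats::median(v)
        n_cons <- if (med < 0) sum(v < 0)
                  else if (med > 0) sum(v > 0)
                  else max(sum(v < 0), sum(v > 0))
        frac <- n_cons / length(v)
        data.frame(mirna = m, mean_fc = mean_fc,
                   consistency_fraction = frac,
                   rescued_by_mean_fc = config$enableMeanFcRescue &&
                       abs(mean_fc) >= config$foldThreshold &&
                       frac >= config$consistencyThreshold,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Detect miRNAs that start to be expressed upon progression
#'
#' Directional rule: undetected (imputed) or low-expression at baseline in
#' at least `newlyExpressedBaseline` of progressors AND cleanly detected
#' (present, not imputed, Ct at or below the low-expression cutoff) at
#' follow-up in at least `newlyExpressedFollowup`.
#'
#' @param x a [DctExperiment-class].
#' @param cohort cohort scanned (default `"PROGRESSOR"`).
#' @param config a [selectionConfig()].
#' @return data.frame: `mirna`, `frac_baseline_undetected`,
#'   `frac_followup_detected`, `newly_expressed`.
#' @export
detectNewlyExpressed <- function(x, cohort = "PROGRESSOR",
                                 config = selectionConfig()) {
    meta <- as.data.frame(colData(x))
    pairs <- matchedPairs(meta, cohort)
    und <- flagImputed(x) | flagLowExpression(x) | flagMissing(x)
    det <- !und
    frac_bl <- rowMeans(und[, pairs$baseline_sample, drop = FALSE])
    frac_fu <- rowMeans(det[, pairs$followup_sample, drop = FALSE])
    data.frame(mirna = rownames(und),
               frac_baseline_undetected = unname(frac_bl),
               frac_followup_detected = unname(frac_fu),
               newly_expressed = config$enableNewlyExpressed &
                   frac_bl >= config$newlyExpressedBaseline &
                   frac_fu >= config$newlyExpressedFollowup,
               stringsAsFactors = FALSE)
}

#' Assemble the final miRNA panel
#'
#' Union of (i) miRNAs dysregulated in any between-group comparison,
#' (ii) within-patient progression candidates, (iii) the literature panel,
#' (iv) mean-fold rescues and newly-expressed miRNAs, and (v) the explicit
#' keep-list. Deduplicated and deterministically ordered: criteria-passing
#' miRNAs first (by |fold| descending, then lexicographic), then literature,
#' then rescued / newly-expressed / kept. Exceeding the card capacity warns.
#'
#' @param dysregulated character ids from [countDysregulated()] (pooled over
#'   comparisons).
#' @param candidates data.frame from [selectProgressionCandidates()] (or a
#'   character vector of selected ids).
#' @param rescued character ids flagged by [rescueByMeanFC()].
#' @param newlyExpressed character ids from [detectNewlyExpressed()].
#' @param config a [selectionConfig()].
#' @param foldMagnitudes optional named numeric |fold| used to order the
#'   criteria tier.
#' @return A [SelectionReport-class].
#' @export
assemblePanel <- function(dysregulated, candidates,
                          rescued = character(),
                          newlyExpressed = character(),
                          config = selectionConfig(),
                          foldMagnitudes = NULL) {
    if (is.data.frame(candidates)) {
        cand_tab <- candidates
        cand <- candidates$mirna[candidates$selected]
        if (is.null(foldMagnitudes))
            foldMagnitudes <- stats::setNames(abs(cand_tab$signed_value),
                                              cand_tab$mirna)
    } else {
        cand_tab <- NULL
        cand <- as.character(candidates)
    }
    dysregulated <- unique(as.character(dysregulated))
    rescued <- unique(as.character(rescued))
    newlyExpressed <- unique(as.character(newlyExpressed))
    if (!config$enableMeanFcRescue) rescued <- character()
    if (!config$enableNewlyExpressed) newlyExpressed <- character()

    tier1 <- unique(c(dysregulated, cand))
    mag <- rep(0, length(tier1))
    if (!is.null(foldMagnitudes)) {
        hit <- match(tier1, names(foldMagnitudes))
        mag[!is.na(hit)] <- foldMagnitudes[hit[!is.na(hit)]]
    }
    tier1 <- tier1[order(-mag, tier1)]
    tier2 <- sort(setdiff(config$literaturePanel, tier1))
    tier3 <- sort(setdiff(unique(c(config$keepList, rescued, newlyExpressed)),
                          c(tier1, tier2)))
    panel <- c(tier1, tier2, tier3)
    if (length(panel) > config$panelCapacity)
        warning("panel of ", length(panel),
                " exceeds the card capacity of ", config$panelCapacity)

    all_ids <- unique(c(panel,
                        if (!is.null(cand_tab)) cand_tab$mirna))
    tab <- data.frame(
        mirna = all_ids,
        passes_fd = all_ids %in% dysregulated,
        passes_fc = all_ids %in% cand,
        consistency_fraction = if (!is.null(cand_tab))
            cand_tab$consistency_fraction[match(all_ids, cand_tab$mirna)]
            else NA_real_,
        rescued_by_mean_fc = all_ids %in% rescued,
        newly_expressed = all_ids %in% newlyExpressed,
        literature_panel = all_ids %in% config$literaturePanel,
        kept_by_config = all_ids %in% config$keepList,
        selected = all_ids %in% panel,
        tier = ifelse(all_ids %in% tier1, 1L,
                      ifelse(all_ids %in% tier2, 2L,
                             ifelse(all_ids %in% tier3, 3L, NA_integer_))),
        stringsAsFactors = FALSE)
    new("SelectionReport", table = tab, panel = panel,
        params = unclass(config))
}
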