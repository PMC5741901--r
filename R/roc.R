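#' ROC curve and Youden-optimal operating point for one miRNA
#'
#' Scores are oriented as expression = -dCt (lower dCt means higher
#' expression), fixed for all miRNAs so that discrimination worse than
#' chance is reported as AUC < 0.5 rather than silently rectified. The AUC
#' is the rank (trapezoid) statistic, equal to P(case expression > control
#' expression) + 0.5 P(tie). The operating point maximises the Youden index
#' (sensitivity + specificity - 1); ties are broken toward higher
#' sensitivity, then toward the lower threshold.
#'
#' @param dct numeric per-subject baseline dCt values.
#' @param isCase logical (or 0/1): `TRUE` for progressors.
#' @return list of class `rocResult`: `auc`, `threshold` (a dCt cutoff;
#'   subjects with dCt <= threshold are called progressors), `sensitivity`,
#'   `specificity`, `youden`, `n_case`, `n_control` and `curve` (data.frame
#'   of all candidate operating points).
#' @export
rocCurve <- function(dct, isCase) {
    isCase <- as.logical(isCase)
    ok <- !is.na(dct) & !is.na(isCase)
    dct <- dct[ok]; isCase <- isCase[ok]
    n1 <- sum(isCase); n0 <- sum(!isCase)
    if (n1 < 2 || n0 < 2)
        stop("need at least 2 subjects in each class")
    score <- -dct
    r <- rank(score, ties.method = "average")
    auc <- (sum(r[isCase]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    # candidate cutoffs on the dCt scale: call case when dct <= c
    cand <- sort(unique(c(-Inf, dct)))
    sens <- vapply(cand, function(cc) mean(dct[isCase] <= cc), numeric(1))
    spec <- vapply(cand, function(cc) mean(dct[!isCase] > cc), numeric(1))
    youden <- sens + spec - 1
    best <- order(-youden, -sens, cand)[1]
    structure(list(auc = auc,
                   threshold = cand[best],
                   sensitivity = sens[best],
                   specificity = spec[best],
                   youden = youden[best],
                   n_case = n1, n_control = n0,
                   curve = data.frame(threshold = cand, sensitivity = sens,
                                      specificity = spec, youden = youden)),
              class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
    cat(sprintf(
        "ROC: AUC %.3f | Youden %.2f at dCt <= %.3g (sens %.0f%%, spec %.0f%%) | %d cases vs %d controls\n",
        x$auc, x$youden, x$threshold, 100 * x$sensitivity,
        100 * x$specificity, x$n_case, x$n_control))
    invisible(x)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples cases and controls separately (so every resample keeps both
#' classes), recomputes the rank AUC, and returns the percentile interval.
#' Deterministic given `seed`.
#'
#' @inheritParams rocCurve
#' @param level confidence level (default 0.90, the study's reporting
#'   convention).
#' @param B bootstrap resamples (default 2000).
#' @param seed integer seed for the resampling stream.
#' @return numeric `c(low, high)`.
#' @export
bootstrapAucCI <- function(dct, isCase, level = 0.90, B = 2000L,
                           seed = 1L) {
    isCase <- as.logical(isCase)
    ok <- !is.na(dct) & !is.na(isCase)
    dct <- dct[ok]; isCase <- isCase[ok]
    s1 <- -dct[isCase]; s0 <- -dct[!isCase]
    n1 <- length(s1); n0 <- length(s0)
    if (n1 < 2 || n0 < 2) stop("need at least 2 subjects in each class")
    aucs <- withSeed(seed, {
        vapply(seq_len(B), function(b) {
            x1 <- s1[sample.int(n1, n1, replace = TRUE)]
            x0 <- s0[sample.int(n0, n0, replace = TRUE)]
            r <- rank(c(x1, x0), ties.method = "average")
            (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
        }, numeric(1))
    })
    alpha <- (1 - level) / 2
    ci <- stats::quantile(aucs, c(alpha, 1 - alpha), type = 7, names = FALSE)
    c(low = ci[1], high = ci[2])
}

#' Per-miRNA ROC table at baseline
#'
#' Evaluates every miRNA's baseline dCt as a classifier of progression
#' (progressors vs non-progressors), with the Youden operating point and a
#' stratified bootstrap CI on the AUC.
#'
#' @param x a [DctExperiment-class].
#' @param level,B,seed see [bootstrapAucCI()].
#' @param mirnas optional subset of miRNA ids.
#' @return data.frame: `mirna`, `auc`, `ci_low`, `ci_high`, `threshold_dct`,
#'   `sensitivity`, `specificity`, `youden`, `n_case`, `n_control`.
#' @export
rocTable <- function(x, level = 0.90, B = 2000L, seed = 1L, mirnas = NULL) {
    meta <- as.data.frame(colData(x))
    sel <- meta$timepoint == "BASELINE" &
        meta$cohort %in% c("PROGRESSOR", "NON_PROGRESSOR")
    if (!any(sel)) stop("no baseline progressor/non-progressor samples")
    isCase <- meta$cohort[sel] == "PROGRESSOR"
    d <- dctValues(x)[, sel, drop = FALSE]
    if (is.null(mirnas)) mirnas <- rownames(d)
    rows <- lapply(seq_along(mirnas), function(k) {
        m <- mirnas[k]
        v <- d[m, ]
        ok <- !is.na(v)
        if (sum(ok & isCase) < 2 || sum(ok & !isCase) < 2) return(NULL)
        roc <- rocCurve(v[ok], isCase[ok])
        ci <- bootstrapAucCI(v[ok], isCase[ok], level = level, B = B,
                             seed = seed + k)
        data.frame(mirna = m, auc = roc$auc, ci_low = ci[1], ci_high = ci[2],
                   threshold_dct = roc$threshold,
                   sensitivity = roc$sensitivity,
                   specificity = roc$specificity, youden = roc$youden,
                   n_case = roc$n_case, n_control = roc$n_control,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Spearman associations between baseline dCt and clinical variables
#'
#' Pairwise-complete Spearman rank correlations (average ranks for ties)
#' between each miRNA's baseline dCt and each clinical column of the sample
#' metadata, flagged substantive when |rho| > 0.3 (strict).
#'
#' @param x a [DctExperiment-class].
#' @param clinicalVars character names of colData columns (e.g. `"VAS"`,
#'   `"TJC28"`, `"DAS28_ESR"`).
#' @param cohorts cohorts included (default both patient groups).
#' @param minPairs minimum paired observations (default 3).
#' @return data.frame: `mirna`, `variable`, `rho`, `n`, `substantive`.
#' @export
clinicalAssociations <- function(x, clinicalVars,
                                 cohorts = c("PROGRESSOR",
                                             "NON_PROGRESSOR"),
                                 minPairs = 3L) {
    meta <- as.data.frame(colData(x))
    sel <- meta$timepoint == "BASELINE" & meta$cohort %in% cohorts
    d <- dctValues(x)[, sel, drop = FALSE]
    meta <- meta[sel, , drop = FALSE]
    missing_vars <- setdiff(clinicalVars, colnames(meta))
    if (length(missing_vars))
        stop("clinical variable(s) absent from metadata: ",
             paste(missing_vars, collapse = ", "))
    grid <- expand.grid(mirna = rownames(d), variable = clinicalVars,
                        stringsAsFactors = FALSE)
    res <- lapply(seq_len(nrow(grid)), function(k) {
        v <- d[grid$mirna[k], ]
        cl <- meta[[grid$variable[k]]]
        ok <- !is.na(v) & !is.na(cl)
        if (sum(ok) < minPairs)
            return(data.frame(grid[k, ], rho = NA_real_, n = sum(ok),
                              substantive = NA))
        rho <- stats::cor(v[ok], cl[ok], method = "spearman")
        data.frame(grid[k, ], rho = rho, n = sum(ok),
                   substantive = abs(rho) > 0.3)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
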