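#' Signed fold from a dCt-scale exponent
#'
#' Converts a ddCt (or a difference of group median dCt values) to the
#' signed fold convention used throughout the pipeline:
#' raw ratio \eqn{r = 2^{-x}}; if \eqn{r \ge 1} the fold is \eqn{r},
#' otherwise \eqn{-1/r}. Signed folds therefore never fall inside the open
#' interval (-1, 1); a fold of -2 means half the expression.
#'
#' @param x numeric vector of ddCt-scale exponents (finite).
#' @return numeric vector of signed folds.
#' @examples
#' signedFold(-2.1)  # 4.29: four-fold upregulation
#' signedFold(1)     # -2: two-fold downregulation
#' @export
signedFold <- function(x) {
    stopifnot(is.numeric(x), all(is.finite(x)))
    raw <- 2^(-x)
    ifelse(raw >= 1, raw, -1 / raw)
}

#' Signed fold from a raw expression ratio
#'
#' @param ratio positive raw ratios.
#' @return `ratio` where `>= 1`, else `-1/ratio`.
#' @export
signedFoldFromRatio <- function(ratio) {
    stopifnot(all(ratio > 0))
    ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Type-7 median and quartiles
#' @noRd
.medianIqr <- function(x) {
    x <- x[!is.na(x)]
    stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
}

#' Per-patient ddCt matrix for a matched cohort
#'
#' ddCt = dCt(follow-up) - dCt(baseline) per subject; negative values mean
#' upregulation at follow-up. Cells where either timepoint is missing are
#' `NA`.
#'
#' @param x a [DctExperiment-class].
#' @param cohort cohort whose matched pairs are used.
#' @return list: `ddct` (miRNA x subject matrix), `unreliable` (logical
#'   matrix, contributing cell imputed or low-expression), `pairs` (the
#'   matched-pair index).
#' @export
patientDdct <- function(x, cohort = "PROGRESSOR") {
    meta <- as.data.frame(colData(x))
    pairs <- matchedPairs(meta, cohort)
    if (!nrow(pairs))
        stop("no matched baseline/follow-up pairs in cohort ", cohort)
    d <- dctValues(x)
    bl <- d[, pairs$baseline_sample, drop = FALSE]
    fu <- d[, pairs$followup_sample, drop = FALSE]
    ddct <- fu - bl
    colnames(ddct) <- pairs$subject_id
    unrel <- (flagImputed(x) | flagLowExpression(x))
    unreliable <- unrel[, pairs$baseline_sample, drop = FALSE] |
        unrel[, pairs$followup_sample, drop = FALSE]
    colnames(unreliable) <- pairs$subject_id
    list(ddct = ddct, unreliable = unreliable, pairs = pairs)
}

#' Within-patient fold change per miRNA
#'
#' For every miRNA the per-patient ddCt (follow-up minus baseline) is
#' computed over a cohort's matched pairs, the group median ddCt is
#' converted to a signed fold change, and the number of patients whose
#' individual change points in the same direction as the median is counted
#' (a strict inequality; ddCt = 0 is inconsistent). A result is unreliable
#' when any contributing cell was imputed or low-expression.
#'
#' @param x a [DctExperiment-class].
#' @param cohort cohort with matched pairs (default `"PROGRESSOR"`).
#' @return data.frame, one row per evaluable miRNA: `mirna`, `comparison`,
#'   `n_evaluable`, `n_consistent`, `ddct_median`, `ddct_q1`, `ddct_q3`,
#'   `raw_ratio`, `signed_value`, `reliable`.
#' @export
withinPatientFC <- function(x, cohort = "PROGRESSOR") {
    pd <- patientDdct(x, cohort)
    rows <- lapply(rownames(pd$ddct), function(m) {
        v <- pd$ddct[m, ]
        ok <- !is.na(v)
        if (!any(ok)) return(NULL)
        v <- v[ok]
        q <- .medianIqr(v)
        med <- q[1]
        n_cons <- if (med < 0) sum(v < 0)
                  else if (med > 0) sum(v > 0)
                  else max(sum(v < 0), sum(v > 0))
        data.frame(mirna = m, comparison = "FC_WITHIN_PATIENTS",
                   n_evaluable = length(v), n_consistent = n_cons,
                   ddct_median = med, ddct_q1 = q[2], ddct_q3 = q[3],
                   raw_ratio = 2^(-med), signed_value = signedFold(med),
                   reliable = !any(pd$unreliable[m, ok]),
                   stringsAsFactors = FALSE)
    })
    dropped <- rownames(pd$ddct)[vapply(rows, is.null, logical(1))]
    if (length(dropped))
        message("no evaluable pairs for: ", paste(dropped, collapse = ", "))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Between-group fold difference per miRNA
#'
#' Raw mode: FD = signedFold(median dCt(group A) - median dCt(group B)).
#' Adjusted mode: the dCt of each miRNA is regressed on a group indicator
#' and age by median (quantile, tau = 0.5) regression; the group coefficient
#' is the age-adjusted difference in median dCt and per-cohort adjusted
#' medians are evaluated at `referenceAge`. Group A supplies the numerator
#' exponent, so positive FD means higher expression (lower dCt) in group A.
#'
#' @param x a [DctExperiment-class].
#' @param groupA,groupB cohort labels for the two groups.
#' @param timepointA,timepointB timepoint used for each group.
#' @param adjustAge fit the age-adjusted median regression instead of raw
#'   medians.
#' @param referenceAge age (years) at which adjusted medians are reported;
#'   defaults to the pooled mean age of the compared samples (the study
#'   convention is its pooled mean of 52).
#' @return data.frame, one row per miRNA: group medians/IQRs (raw and, when
#'   adjusted, the model-based medians at `referenceAge`), `diff_median`
#'   (the dCt-scale exponent), `raw_ratio`, `signed_value`, `reliable`,
#'   `n_a`, `n_b` and in adjusted mode `age_coefficient`, `reference_age`.
#' @details With fewer than 3 samples in a group, or a constant age column,
#'   the adjusted fit reduces to the raw difference of medians with
#'   `age_coefficient = 0` (warning in the degenerate one-sample case).
#' @export
betweenGroupFD <- function(x, groupA = "PROGRESSOR",
                           groupB = "NON_PROGRESSOR",
                           timepointA = "BASELINE", timepointB = "BASELINE",
                           adjustAge = FALSE, referenceAge = NULL) {
    meta <- as.data.frame(colData(x))
    selA <- meta$cohort == groupA & meta$timepoint == timepointA
    selB <- meta$cohort == groupB & meta$timepoint == timepointB
    if (!any(selA)) stop("no samples for group ", groupA, "/", timepointA)
    if (!any(selB)) stop("no samples for group ", groupB, "/", timepointB)
    d <- dctValues(x)
    unrel <- flagImputed(x) | flagLowExpression(x)
    ages <- c(meta$age[selA], meta$age[selB])
    grp <- c(rep(1, sum(selA)), rep(0, sum(selB)))   # A = 1, B = reference
    if (is.null(referenceAge)) referenceAge <- mean(ages)
    rows <- lapply(rownames(d), function(m) {
        ya <- d[m, selA]; yb <- d[m, selB]
        oka <- !is.na(ya); okb <- !is.na(yb)
        if (!any(oka) || !any(okb)) return(NULL)
        qa <- .medianIqr(ya[oka]); qb <- .medianIqr(yb[okb])
        out <- data.frame(mirna = m, comparison = "FD_BETWEEN_GROUPS",
                          median_a = qa[1], q1_a = qa[2], q3_a = qa[3],
                          median_b = qb[1], q1_b = qb[2], q3_b = qb[3],
                          n_a = sum(oka), n_b = sum(okb),
                          stringsAsFactors = FALSE)
        if (adjustAge) {
            y <- c(ya, yb); ok <- c(oka, okb)
            fit <- medianRegressionFD(y[ok], grp[ok], ages[ok], referenceAge)
            out$diff_median <- fit$group_coefficient
            out$age_coefficient <- fit$age_coefficient
            out$reference_age <- referenceAge
            out$adj_median_a <- fit$median_a
            out$adj_median_b <- fit$median_b
        } else {
            out$diff_median <- qa[1] - qb[1]
        }
        out$raw_ratio <- 2^(-out$diff_median)
        out$signed_value <- signedFold(out$diff_median)
        out$reliable <- !(any(unrel[m, selA][oka]) || any(unrel[m, selB][okb]))
        out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Median (tau = 0.5) regression of dCt on group + age
#'
#' The age-adjusted between-group difference in median dCt. Fitted by
#' minimising the tau = 0.5 check loss (`quantreg::rq`, Barrodale-Roberts).
#' When the age column is constant the age term is unidentifiable and the
#' fit reduces, by convention, to the plain difference of group medians with
#' a zero age coefficient; the same fallback (with a warning) applies to a
#' degenerate design with a single-observation group.
#'
#' @param y dCt values.
#' @param group 0/1 indicator (1 = group A, the numerator group).
#' @param age ages in years.
#' @param referenceAge age at which adjusted group medians are evaluated.
#' @return list: `intercept`, `group_coefficient` (dCt difference A - B),
#'   `age_coefficient`, `reference_age`, `median_a`, `median_b` (adjusted
#'   medians at `referenceAge`).
#' @export
medianRegressionFD <- function(y, group, age, referenceAge = mean(age)) {
    stopifnot(length(y) == length(group), length(y) == length(age))
    degenerate <- min(sum(group == 1), sum(group == 0)) < 2
    if (degenerate)
        warning("degenerate design: falling back to raw median difference")
    sa <- stats::sd(age)
    reduced <- function() {
        ma <- stats::median(y[group == 1])
        mb <- stats::median(y[group == 0])
        list(intercept = mb, group_coefficient = ma - mb,
             age_coefficient = 0, reference_age = referenceAge,
             median_a = ma, median_b = mb)
    }
    if (degenerate || !is.finite(sa) ||
        sa < 1e-8 * max(1, abs(mean(age))))
        return(reduced())
    fit <- tryCatch(
        suppressWarnings(
            quantreg::rq(y ~ group + age, tau = 0.5, method = "br")),
        error = function(e) NULL)
    if (is.null(fit)) {
        warning("median regression failed (singular design); ",
                "falling back to raw median difference")
        return(reduced())
    }
    cf <- stats::coef(fit)
    mb <- unname(cf[1] + cf["age"] * referenceAge)
    list(intercept = unname(cf[1]),
         group_coefficient = unname(cf["group"]),
         age_coefficient = unname(cf["age"]),
         reference_age = referenceAge,
         median_a = mb + unname(cf["group"]),
         median_b = mb)
}
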