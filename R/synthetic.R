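#' Per-miRNA simulation specification
#'
#' @param mirna_id assay name.
#' @param base_dct healthy-control level dCt (cycles; lower = higher
#'   expression).
#' @param progression_ddct dCt shift at follow-up in progressors (cycles;
#'   e.g. -2.1 emulates the strongest study candidate).
#' @param group_offset_dct baseline progressor-vs-non-progressor shift.
#' @param nonprog_ddct follow-up drift in non-progressors.
#' @param newly_expressed if `TRUE` the assay is below the detection limit
#'   in healthy controls and at patient baselines and only appears at
#'   progressor follow-up.
#' @return one-row data.frame; rbind rows to build a panel.
#' @export
mirnaSpec <- function(mirna_id, base_dct, progression_ddct = 0,
                      group_offset_dct = 0, nonprog_ddct = 0,
                      newly_expressed = FALSE) {
    stopifnot(is.finite(base_dct), is.finite(progression_ddct),
              is.finite(group_offset_dct), is.finite(nonprog_ddct))
    data.frame(mirna_id = mirna_id, base_dct = base_dct,
               progression_ddct = progression_ddct,
               group_offset_dct = group_offset_dct,
               nonprog_ddct = nonprog_ddct,
               newly_expressed = newly_expressed,
               stringsAsFactors = FALSE)
}

#' Study-shaped default miRNA panel
#'
#' Thirty-one assays emulating the study's custom card: three planted
#' progression candidates (miR-22, miR-382, miR-486-3p) whose effect sizes
#' (progression ddCt -2.1, -2.0, -2.0; baseline group offsets -4.3, -1.3,
#' +0.5; non-progressor drifts -1.77, -1.26, 0) are back-derived from the
#' published median dCt/ddCt/fold tables, and 28 null assays whose base dCt
#' are the published healthy-control medians.
#'
#' @param newlyExpressed also plant the two detection-onset assays
#'   (`miR-15b#`, `miR-335#` switch from undetected to expressed upon
#'   progression); off by default, which leaves exactly 3 planted effects
#'   among 28 nulls.
#' @return data.frame of [mirnaSpec()] rows.
#' @export
defaultMirnaSpecs <- function(newlyExpressed = FALSE) {
    ref <- referencePilotSummary()
    planted <- rbind(
        mirnaSpec("miR-22", base_dct = 4.2, progression_ddct = -2.1,
                  group_offset_dct = -4.3, nonprog_ddct = -log2(3.4)),
        mirnaSpec("miR-382", base_dct = -0.7, progression_ddct = -2.0,
                  group_offset_dct = -1.3, nonprog_ddct = -log2(2.4)),
        mirnaSpec("miR-486-3p", base_dct = 4.3, progression_ddct = -2.0,
                  group_offset_dct = 0.5, nonprog_ddct = 0))
    nulls <- ref[!ref$mirna %in% planted$mirna_id, c("mirna", "hc_median")]
    nulls <- do.call(rbind, lapply(seq_len(nrow(nulls)), function(k)
        mirnaSpec(nulls$mirna[k], base_dct = nulls$hc_median[k])))
    specs <- rbind(planted, nulls)
    if (newlyExpressed) {
        # onset assays: undetected before progression, then expressed at
        # the published follow-up level
        for (id in c("miR-15b#", "miR-335#")) {
            k <- specs$mirna_id == id
            specs$newly_expressed[k] <- TRUE
            specs$progression_ddct[k] <-
                ref$vera_median[ref$mirna == id] -
                ref$hc_median[ref$mirna == id]
        }
    }
    rownames(specs) <- NULL
    specs
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: 12 subjects per cohort,
#' triplicate wells, an endogenous control drawn uniformly in Ct 23-26,
#' technical replicate noise sd 0.2 cycles, between-subject sd 1.0 cycle,
#' age 52 +/- 10 years, detection limit Ct 35.
#'
#' @param nHc,nProg,nNonprog subjects per cohort (>= 2).
#' @param mirnas data.frame of [mirnaSpec()] rows.
#' @param controlCtRange uniform range of the per-sample control Ct.
#' @param techNoiseSd technical (replicate) noise sd, cycles.
#' @param subjectSd between-subject sd, cycles: a persistent random
#'   intercept per subject x miRNA, constant across the two timepoints (the
#'   matched design cancels it in within-patient ddCt).
#' @param detectionLimitCt wells beyond this Ct are undetermined.
#' @param ageMean,ageSd age distribution, years.
#' @param ageSlope planted dCt change per year of age (default 0).
#' @param replicates technical replicates per well group.
#' @param controlName endogenous control assay name.
#' @return classed parameter list.
#' @export
synthConfig <- function(nHc = 12L, nProg = 12L, nNonprog = 12L,
                        mirnas = defaultMirnaSpecs(),
                        controlCtRange = c(23, 26),
                        techNoiseSd = 0.2, subjectSd = 1.0,
                        detectionLimitCt = 35,
                        ageMean = 52, ageSd = 10, ageSlope = 0,
                        replicates = 3L, controlName = "RNU6B") {
    stopifnot(nHc >= 2, nProg >= 2, nNonprog >= 2,
              techNoiseSd >= 0, subjectSd >= 0, ageSd >= 0,
              detectionLimitCt <= 40, nrow(mirnas) >= 1)
    structure(list(nHc = as.integer(nHc), nProg = as.integer(nProg),
                   nNonprog = as.integer(nNonprog), mirnas = mirnas,
                   controlCtRange = controlCtRange,
                   techNoiseSd = techNoiseSd, subjectSd = subjectSd,
                   detectionLimitCt = detectionLimitCt,
                   ageMean = ageMean, ageSd = ageSd, ageSlope = ageSlope,
                   replicates = as.integer(replicates),
                   controlName = controlName),
              class = "synthConfig")
}

#' Simulate a study-shaped cohort with known ground truth
#'
#' Generates the raw long-format Ct table and sample metadata for three
#' cohorts: healthy controls (baseline only), progressors and
#' non-progressors (matched baseline/follow-up pairs). Per subject and
#' miRNA the true dCt is
#' `base_dct + cohort/timepoint effect + ageSlope * (age - ageMean) +
#' subject intercept`; each well's Ct is the sample's true control Ct plus
#' the true dCt plus technical noise, and wells beyond the detection limit
#' are censored to undetermined. Deterministic given `seed`.
#'
#' @param config a [synthConfig()].
#' @param seed integer seed.
#' @return list: `ct` (long Ct records as from [readCtTable()]), `meta`
#'   (sample metadata), `truth` (list with the assay-specification table,
#'   planted
#'   candidates — assays whose |signed fold| of the progression ddCt meets
#'   4 —, per-sample true dCt matrix, ages).
#' @export
simulateStudy <- function(config = synthConfig(), seed = 1L) {
    withSeed(seed, .simulateStudy(config))
}

.simulateStudy <- function(config) {
    sp <- config$mirnas
    subj <- data.frame(
        subject_id = c(sprintf("HC_%02d", seq_len(config$nHc)),
                       sprintf("P_%02d", seq_len(config$nProg)),
                       sprintf("NP_%02d", seq_len(config$nNonprog))),
        cohort = rep(c("HC", "PROGRESSOR", "NON_PROGRESSOR"),
                     c(config$nHc, config$nProg, config$nNonprog)),
        stringsAsFactors = FALSE)
    subj$age <- pmax(18, stats::rnorm(nrow(subj), config$ageMean,
                                      config$ageSd))
    meta <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i) {
        tps <- if (subj$cohort[i] == "HC") "BASELINE"
               else c("BASELINE", "FOLLOW_UP")
        data.frame(sample_id = paste0(subj$subject_id[i], "_",
                                      ifelse(tps == "BASELINE", "BL", "FU")),
                   subject_id = subj$subject_id[i],
                   cohort = subj$cohort[i], timepoint = tps,
                   age = subj$age[i], stringsAsFactors = FALSE)
    }))
    nm <- nrow(sp); nsub <- nrow(subj)
    # persistent subject x miRNA intercept
    bsub <- matrix(stats::rnorm(nsub * nm, 0, config$subjectSd), nsub, nm,
                   dimnames = list(subj$subject_id, sp$mirna_id))
    si <- match(meta$subject_id, subj$subject_id)
    effect <- matrix(0, nrow(meta), nm)   # cohort/timepoint effect
    isP <- meta$cohort == "PROGRESSOR"
    isNP <- meta$cohort == "NON_PROGRESSOR"
    isFU <- meta$timepoint == "FOLLOW_UP"
    for (j in seq_len(nm)) {
        effect[isP, j] <- sp$group_offset_dct[j]
        effect[isP & isFU, j] <- sp$group_offset_dct[j] +
            sp$progression_ddct[j]
        effect[isNP & isFU, j] <- sp$nonprog_ddct[j]
    }
    true_dct <- matrix(rep(sp$base_dct, each = nrow(meta)), nrow(meta), nm) +
        effect + config$ageSlope * (meta$age - config$ageMean) +
        bsub[si, , drop = FALSE]
    dimnames(true_dct) <- list(meta$sample_id, sp$mirna_id)
    # detection-onset assays: absent everywhere except progressor follow-up
    if (any(sp$newly_expressed)) {
        off <- which(sp$newly_expressed)
        absent <- !(isP & isFU)
        true_dct[absent, off] <- Inf
    }

    ctrl_true <- stats::runif(nrow(meta), config$controlCtRange[1],
                              config$controlCtRange[2])
    names(ctrl_true) <- meta$sample_id
    R <- config$replicates
    nwell <- nrow(meta) * (nm + 1L) * R
    well_sample <- rep(meta$sample_id, each = (nm + 1L) * R)
    well_mirna <- rep(rep(c(sp$mirna_id, config$controlName), each = R),
                      times = nrow(meta))
    well_rep <- rep(seq_len(R), times = nrow(meta) * (nm + 1L))
    true_ct_grid <- cbind(true_dct + ctrl_true, ctrl = ctrl_true)
    colnames(true_ct_grid) <- c(sp$mirna_id, config$controlName)
    mu <- true_ct_grid[cbind(match(well_sample, meta$sample_id),
                             match(well_mirna, colnames(true_ct_grid)))]
    ct <- mu + stats::rnorm(nwell, 0, config$techNoiseSd)
    undet <- !is.finite(ct) | ct > config$detectionLimitCt
    ct[undet] <- NA_real_
    records <- data.frame(sample_id = well_sample, mirna_id = well_mirna,
                          replicate = well_rep, ct = ct,
                          undetermined = undet, imputed = FALSE,
                          stringsAsFactors = FALSE)
    planted <- sp$mirna_id[abs(signedFold(sp$progression_ddct)) >= 4 |
                           sp$newly_expressed]
    list(ct = records,
         meta = validateSampleMeta(meta),
         truth = list(specs = sp,
                      planted_candidates = planted,
                      true_dct = true_dct,
                      control_ct = ctrl_true,
                      ages = stats::setNames(subj$age, subj$subject_id),
                      config = unclass(config)))
}

#' Attach simulated clinical scores to a cohort
#'
#' Adds VAS (0-100), TJC28 (0-28) and DAS28_ESR (~0-10) columns to the
#' patient samples. In `"linked"` mode each score is a monotone transform of
#' a latent variable correlated with a designated miRNA's true baseline dCt
#' so that the Spearman correlation targets `targetRho` (bivariate-normal
#' rank mapping: Pearson rho = 2 sin(pi * rho_s / 6)); in `"independent"`
#' mode the scores are pure noise.
#'
#' @param sim result of [simulateStudy()].
#' @param linkMirna miRNA whose true dCt drives the scores.
#' @param targetRho target Spearman correlation between the scores and the
#'   linked miRNA's dCt (sign included).
#' @param mode `"linked"` or `"independent"`.
#' @param seed integer seed.
#' @return `sim` with clinical columns added to `$meta` and the targets
#'   recorded in `$truth$clinical`.
#' @export
simulateClinical <- function(sim, linkMirna = "miR-22", targetRho = 0.5,
                             mode = c("linked", "independent"), seed = 1L) {
    mode <- match.arg(mode)
    withSeed(seed + 7919L, {
        meta <- sim$meta
        pat <- meta$cohort %in% c("PROGRESSOR", "NON_PROGRESSOR")
        n <- sum(pat)
        if (mode == "linked") {
            stopifnot(linkMirna %in% colnames(sim$truth$true_dct))
            z <- sim$truth$true_dct[meta$sample_id[pat], linkMirna]
            z <- scale(z)[, 1]
            rho_p <- 2 * sin(pi * targetRho / 6)
            lat <- rho_p * z + sqrt(1 - rho_p^2) * stats::rnorm(n)
        } else lat <- stats::rnorm(n)
        u <- stats::pnorm(lat)
        meta$VAS <- NA_real_; meta$TJC28 <- NA_real_
        meta$DAS28_ESR <- NA_real_
        meta$VAS[pat] <- round(100 * u, 1)
        meta$TJC28[pat] <- stats::qbinom(u, 28, 0.15)
        meta$DAS28_ESR[pat] <- round(1 + 7 * u, 2)
        sim$meta <- meta
        sim$truth$clinical <- list(mode = mode, link_mirna = linkMirna,
                                   target_rho = targetRho)
        sim
    })
}

#' Write a simulated study to disk
#'
#' Emits the long Ct table, the sample metadata and a machine-readable
#' ground-truth JSON.
#'
#' @param sim result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCtTable(sim$ct, file.path(dir, "ct_table.csv"))
    utils::write.csv(sim$meta, file.path(dir, "sample_meta.csv"),
                     row.names = FALSE)
    truth <- sim$truth
    truth$true_dct <- NULL  # large; regenerable from the seed
    truth$control_ct <- NULL
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    invisible(dir)
}
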