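# Shared fixtures and independent oracles, built in code at test time.

# Write a Ct CSV from header + row strings and return its path.
writeCtCsv <- function(rows, header = "sample_id,mirna_id,replicate,ct") {
    path <- tempfile(fileext = ".csv")
    writeLines(c(header, rows), path)
    path
}

# Minimal sample metadata table.
makeMeta <- function(sample_id, subject_id, cohort, timepoint, age = 50) {
    data.frame(sample_id = sample_id, subject_id = subject_id,
               cohort = cohort, timepoint = timepoint, age = age,
               stringsAsFactors = FALSE)
}

# Build a DctExperiment directly from a dCt matrix (miRNA x sample).
makeDctExperiment <- function(dct, meta, imputed = NULL, lowExpression = NULL,
                              missing = NULL) {
    dctExperimentFromMatrix(dct, meta, imputed = imputed,
                            lowExpression = lowExpression, missing = missing)
}

# A matched-pair experiment: one row per miRNA, ddct[m, i] planted between
# baseline (0) and follow-up for progressor i.
makePairedExperiment <- function(ddct) {
    n <- ncol(ddct)
    subj <- sprintf("P_%02d", seq_len(n))
    meta <- makeMeta(c(paste0(subj, "_BL"), paste0(subj, "_FU")),
                     rep(subj, 2), "PROGRESSOR",
                     rep(c("BASELINE", "FOLLOW_UP"), each = n))
    dct <- cbind(matrix(0, nrow(ddct), n), ddct)
    dimnames(dct) <- list(rownames(ddct), meta$sample_id)
    makeDctExperiment(dct, meta)
}

# Independent AUC oracle: exhaustive pair counting over cases x controls.
pairCountAuc <- function(caseScores, controlScores) {
    tot <- 0
    for (a in caseScores) for (b in controlScores)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(caseScores) * length(controlScores))
}

# Independent complete-linkage oracle: naive agglomeration, returns the
# sorted merge heights.
naiveCompleteHeights <- function(points) {
    clusters <- lapply(seq_len(nrow(points)), identity)
    d <- as.matrix(stats::dist(points))
    heights <- numeric(0)
    while (length(clusters) > 1) {
        best <- c(Inf, NA, NA)
        for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
            h <- max(d[clusters[[i]], clusters[[j]]])
            if (h < best[1]) best <- c(h, j, i)
        }
        heights <- c(heights, best[1])
        clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
        clusters[[best[3]]] <- NULL
    }
    heights
}

# Study-shaped simulation with quiet preprocessing for pipeline tests.
quietPilot <- function(sim, config = pipelineConfig()) {
    suppressWarnings(runPilot(sim$ct, sim$meta, config))
}
quietValidation <- function(sim, panel,
                            config = pipelineConfig(rocB = 200L)) {
    suppressWarnings(runValidation(sim$ct, sim$meta, config, panel))
}
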