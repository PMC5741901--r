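test_that("signed fold transform matches closed forms and published values", {
    expect_equal(signedFold(0), 1)
    expect_equal(signedFold(1), -2)      # 2^-1 = 0.5 -> -1/0.5
    expect_equal(round(signedFold(-2.1), 1), 4.3)
    expect_equal(round(signedFold(-4.3), 2), 19.70)
    expect_equal(signedFoldFromRatio(c(2, 0.25)), c(2, -4))
})

test_that("signed fold never lands in (-1, 1), is decreasing and antisymmetric", {
    set.seed(202)
    x <- c(runif(500, -8, 8), 0)
    f <- signedFold(x)
    expect_true(all(abs(f) >= 1))
    xs <- sort(unique(x))
    expect_true(all(diff(signedFold(xs)) < 0))
    xs <- x[abs(x) > 1e-9]
    expect_equal(signedFold(-xs), -signedFold(xs))
})

test_that("within-patient fold change counts direction consistency strictly", {
    x <- makePairedExperiment(
        rbind("miR-a" = c(1, -1, -1),
              "miR-b" = c(-2.1, -2.1, -2.1),
              "miR-c" = c(0.5, 1, 0)))
    fc <- withinPatientFC(x)
    a <- fc[fc$mirna == "miR-a", ]
    expect_equal(a$ddct_median, -1)
    expect_equal(a$n_consistent, 2L)      # the +1 patient is inconsistent
    expect_equal(a$n_evaluable, 3L)
    b <- fc[fc$mirna == "miR-b", ]
    expect_equal(b$signed_value, 2^2.1)
    expect_equal(b$n_consistent, 3L)
    cc <- fc[fc$mirna == "miR-c", ]       # ddCt = 0 is inconsistent
    expect_equal(cc$n_consistent, 2L)
})

test_that("missing pairs reduce n_evaluable; unreliable cells poison the fold", {
    dd <- rbind("miR-a" = c(-2, -2, NA, -2))
    x <- makePairedExperiment(dd)
    fc <- withinPatientFC(x)
    expect_equal(fc$n_evaluable, 3L)
    imp <- flagImputed(x); imp["miR-a", "P_01_BL"] <- TRUE
    SummarizedExperiment::assay(x, "imputed") <- imp
    expect_false(withinPatientFC(x)$reliable)
})

test_that("between-group fold difference is antisymmetric and identity at equality", {
    set.seed(7)
    meta <- makeMeta(sprintf("S%02d", 1:14), sprintf("X%02d", 1:14),
                     rep(c("PROGRESSOR", "NON_PROGRESSOR"), each = 7),
                     "BASELINE", age = rnorm(14, 52, 8))
    dct <- matrix(rnorm(2 * 14), 2, 14,
                  dimnames = list(c("m1", "m2"), meta$sample_id))
    x <- makeDctExperiment(dct, meta)
    ab <- betweenGroupFD(x, "PROGRESSOR", "NON_PROGRESSOR")
    ba <- betweenGroupFD(x, "NON_PROGRESSOR", "PROGRESSOR")
    expect_equal(ab$raw_ratio, 1 / ba$raw_ratio)
    off <- abs(ab$signed_value) > 1
    expect_equal(ab$signed_value[off], -ba$signed_value[off])
    d2 <- dct[, c(1:7, 1:7)]
    colnames(d2) <- meta$sample_id
    same <- makeDctExperiment(d2, meta)
    expect_equal(betweenGroupFD(same, "PROGRESSOR",
                                "NON_PROGRESSOR")$signed_value, c(1, 1))
})

test_that("published baseline medians reproduce the printed fold differences", {
    ref <- referenceValidationSummary()
    val <- ref[ref$phase == "validation", ]
    for (k in seq_len(nrow(val))) {
        fd <- signedFold(val$bl_prog_median[k] - val$bl_nonprog_median[k])
        expect_equal(round(fd, 1), val$fd_baseline[k], info = val$mirna[k])
    }
})

test_that("median regression reduces to median difference with constant age", {
    set.seed(31)
    y <- rnorm(22); g <- rep(c(1, 0), each = 11)
    fit <- medianRegressionFD(y, g, age = rep(52, 22))
    expect_equal(fit$group_coefficient,
                 median(y[g == 1]) - median(y[g == 0]))
    expect_equal(fit$age_coefficient, 0)
    # a numerically constant age column takes the same reduction
    fit2 <- medianRegressionFD(y, g, age = rep(52, 22) + 1e-12)
    expect_equal(fit2$group_coefficient,
                 median(y[g == 1]) - median(y[g == 0]))
})

test_that("age-adjusted fit recovers a planted slope and group offset", {
    spec <- mirnaSpec("m", base_dct = 2, group_offset_dct = -2)
    cfg <- synthConfig(nHc = 2, nProg = 200, nNonprog = 200, mirnas = spec,
                       subjectSd = 0.5, techNoiseSd = 0, ageSlope = 0.05)
    sim <- simulateStudy(cfg, seed = 91)
    x <- suppressWarnings(preprocessCt(sim$ct, sim$meta))$experiment
    fd <- betweenGroupFD(x, "PROGRESSOR", "NON_PROGRESSOR",
                         adjustAge = TRUE, referenceAge = 52)
    expect_equal(fd$diff_median, -2, tolerance = 0.1)
    expect_equal(fd$age_coefficient, 0.05, tolerance = 0.02)
    expect_equal(fd$reference_age, 52)
    # predicted cohort medians at the reference age stay consistent
    expect_equal(fd$adj_median_a - fd$adj_median_b, fd$diff_median)
})

test_that("adjusted fold difference is near 1 under the null", {
    hits <- 0L
    for (s in 1:100) {
        sim <- simulateStudy(
            synthConfig(nHc = 2, nProg = 200, nNonprog = 200,
                        mirnas = mirnaSpec("m", 2), subjectSd = 1,
                        techNoiseSd = 0), seed = 1000 + s)
        x <- suppressWarnings(preprocessCt(sim$ct, sim$meta))$experiment
        fd <- betweenGroupFD(x, "PROGRESSOR", "NON_PROGRESSOR",
                             adjustAge = TRUE)
        if (abs(fd$signed_value) < 1.3) hits <- hits + 1L
    }
    expect_gte(hits, 90L)
})

test_that("degenerate designs fall back to the raw median difference", {
    y <- c(5, 1, 2, 3)
    expect_warning(
        fit <- medianRegressionFD(y, c(1, 0, 0, 0), age = c(40, 50, 60, 70)),
        "degenerate")
    expect_equal(fit$group_coefficient, 5 - 2)
})
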