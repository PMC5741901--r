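test_that("generation is deterministic given a seed", {
    a <- simulateStudy(synthConfig(), seed = 21)
    b <- simulateStudy(synthConfig(), seed = 21)
    expect_identical(a$ct, b$ct)
    expect_identical(a$meta, b$meta)
    expect_identical(a$truth$true_dct, b$truth$true_dct)
    c <- simulateStudy(synthConfig(), seed = 22)
    expect_false(identical(a$ct$ct, c$ct$ct))
})

test_that("noise-free generation is exact and planted effects are recovered in closed form", {
    spec <- rbind(mirnaSpec("planted", base_dct = 2,
                            progression_ddct = -2.1),
                  mirnaSpec("null", base_dct = 1))
    cfg <- synthConfig(mirnas = spec, techNoiseSd = 0, subjectSd = 0)
    sim <- simulateStudy(cfg, seed = 1)
    x <- suppressWarnings(preprocessCt(sim$ct, sim$meta))$experiment
    fc <- withinPatientFC(x, "PROGRESSOR")
    expect_equal(fc$signed_value[fc$mirna == "planted"], 2^2.1)
    expect_equal(fc$signed_value[fc$mirna == "null"], 1)
    expect_equal(fc$n_consistent[fc$mirna == "planted"], 12L)
    hc <- sim$meta$sample_id[sim$meta$cohort == "HC"]
    expect_equal(unname(dctValues(x)["null", hc]), rep(1, 12))
})

test_that("ground truth lists exactly the assays planted at the fold threshold", {
    sim <- simulateStudy(synthConfig(), seed = 2)
    expect_setequal(sim$truth$planted_candidates,
                    c("miR-22", "miR-382", "miR-486-3p"))
    specs <- sim$truth$specs
    expect_equal(nrow(specs), 31L)
    expect_equal(sum(specs$progression_ddct != 0), 3L)
})

test_that("detection-onset assays are censored at baseline and seen at follow-up", {
    cfg <- synthConfig(mirnas = defaultMirnaSpecs(newlyExpressed = TRUE))
    sim <- simulateStudy(cfg, seed = 4)
    ct <- sim$ct
    meta <- sim$meta
    onset <- ct[ct$mirna_id == "miR-335#", ]
    fu_p <- meta$sample_id[meta$cohort == "PROGRESSOR" &
                           meta$timepoint == "FOLLOW_UP"]
    expect_true(all(onset$undetermined[!onset$sample_id %in% fu_p]))
    expect_true(mean(onset$undetermined[onset$sample_id %in% fu_p]) < 0.5)
    x <- suppressWarnings(preprocessCt(ct, meta))$experiment
    newly <- detectNewlyExpressed(x)
    expect_true(all(newly$newly_expressed[newly$mirna %in%
                                          c("miR-15b#", "miR-335#")]))
})

test_that("the censored fraction matches the normal tail beyond the detection limit", {
    spec <- mirnaSpec("edge", base_dct = 10.5)
    cfg <- synthConfig(nHc = 300, nProg = 2, nNonprog = 2, mirnas = spec,
                       controlCtRange = c(24, 24), subjectSd = 1,
                       techNoiseSd = 0.2)
    sim <- simulateStudy(cfg, seed = 17)
    wells <- sim$ct[sim$ct$mirna_id == "edge", ]
    hc <- sim$meta$sample_id[sim$meta$cohort == "HC"]
    wells <- wells[wells$sample_id %in% hc, ]
    p_true <- pnorm(35, mean = 24 + 10.5, sd = sqrt(1 + 0.2^2),
                    lower.tail = FALSE)
    p_obs <- mean(wells$undetermined)
    se <- sqrt(p_true * (1 - p_true) / nrow(wells))
    # wells within a subject share the intercept; allow a generous margin
    expect_lt(abs(p_obs - p_true), 6 * se)
})

test_that("clinical scores hit the target Spearman correlation", {
    cfg <- synthConfig(nHc = 2, nProg = 100, nNonprog = 100)
    sim <- simulateStudy(cfg, seed = 30)
    sim <- simulateClinical(sim, linkMirna = "miR-22", targetRho = 0.5,
                            seed = 30)
    meta <- sim$meta
    pat <- meta$cohort != "HC"
    rho <- cor(sim$truth$true_dct[meta$sample_id[pat], "miR-22"],
               meta$VAS[pat], method = "spearman")
    expect_equal(rho, 0.5, tolerance = 0.1)
    # perfect link: monotone transform of the same latent variable
    perf <- simulateClinical(sim, targetRho = 1, seed = 31)
    rho1 <- cor(sim$truth$true_dct[meta$sample_id[pat], "miR-22"],
                perf$meta$VAS[pat], method = "spearman")
    expect_gt(rho1, 0.999)
})

test_that("independent clinical mode stays below the substantive cutoff", {
    hits <- 0L
    for (s in 1:100) {
        sim <- simulateStudy(synthConfig(nHc = 2, nProg = 12,
                                         nNonprog = 12), seed = 4000 + s)
        sim <- simulateClinical(sim, mode = "independent", seed = 4000 + s)
        meta <- sim$meta
        pat <- meta$cohort != "HC"   # 24 subjects, both timepoints
        rho <- cor(sim$truth$true_dct[meta$sample_id[pat], "miR-22"],
                   meta$VAS[pat], method = "spearman")
        if (abs(rho) < 0.3) hits <- hits + 1L
    }
    expect_gte(hits, 90L)
})

test_that("a study is written to disk in the package's own CSV contracts", {
    sim <- simulateStudy(synthConfig(), seed = 6)
    dir <- file.path(tempdir(), "simstudy")
    writeStudy(sim, dir)
    ct <- readCtTable(file.path(dir, "ct_table.csv"))
    expect_identical(ct$ct, sim$ct$ct)
    meta <- readSampleMeta(file.path(dir, "sample_meta.csv"))
    expect_equal(nrow(meta), 60L)
    truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                 simplifyVector = TRUE)
    expect_setequal(truth$planted_candidates,
                    c("miR-22", "miR-382", "miR-486-3p"))
})
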