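refFoldTable <- function(ref, column) {
    data.frame(mirna = ref$mirna, signed_value = ref[[column]],
               reliable = !ref$low_expression, stringsAsFactors = FALSE)
}

test_that("dysregulation counts on the published pilot columns", {
    ref <- referencePilotSummary()
    vera <- countDysregulated(refFoldTable(ref, "fd_vera_hc"))
    expect_length(vera$mirnas, 13L)
    expect_equal(vera$n_up, 12L)
    expect_equal(vera$down, "miR-197")
    ccp <- countDysregulated(refFoldTable(ref, "fd_ccp_hc"))
    expect_length(ccp$mirnas, 7L)
    expect_equal(ccp$n_down, 4L)
    expect_equal(ccp$n_up, 3L)
    expect_setequal(ccp$down, c("miR-195", "miR-197", "miR-361", "miR-382"))
})

test_that("threshold boundary is inclusive and empty results are empty", {
    tab <- data.frame(mirna = c("a", "b"), signed_value = c(4.0, 3.99),
                      reliable = TRUE)
    expect_equal(countDysregulated(tab)$mirnas, "a")
    none <- data.frame(mirna = "a", signed_value = 2, reliable = TRUE)
    expect_length(countDysregulated(none)$mirnas, 0L)
})

test_that("the stringent FC + consistency rule picks the three study candidates", {
    ref <- referencePilotSummary()
    fc <- data.frame(mirna = ref$mirna, signed_value = ref$fc_median,
                     n_consistent = ref$n_up, n_evaluable = ref$n_evaluable,
                     reliable = !ref$low_expression,
                     stringsAsFactors = FALSE)
    sel <- selectProgressionCandidates(fc)
    expect_setequal(sel$mirna[sel$selected],
                    c("miR-22", "miR-382", "miR-486-3p"))
    m486 <- sel[sel$mirna == "miR-486-3p", ]
    expect_equal(m486$consistency_fraction, 0.75)   # 9/12, inclusive
    # near-threshold but unreliable: passes the numbers, not the selection
    m15 <- sel[sel$mirna == "miR-15b#", ]
    expect_true(m15$passes_fc)
    expect_false(m15$selected)
})

test_that("mean-FC rescue follows the conjunction of mean fold and consistency", {
    # 11 patients at ddCt -2.2 (fold 2^2.2) and one at +1 (fold -2):
    # mean signed fold = (11 * 2^2.2 - 2) / 12
    dd <- rbind(m = c(rep(-2.2, 11), 1))
    res <- rescueByMeanFC(dd)
    expect_equal(res$mean_fc, (11 * 2^2.2 - 2) / 12)
    expect_gte(res$mean_fc, 4)
    expect_equal(res$consistency_fraction, 11 / 12)
    expect_true(res$rescued_by_mean_fc)
    # mean fold below threshold
    low <- rescueByMeanFC(rbind(m = rep(-log2(3), 12)))
    expect_equal(low$mean_fc, 3)
    expect_false(low$rescued_by_mean_fc)
    # mean fold high but inconsistent (8/12)
    mix <- rescueByMeanFC(rbind(m = c(rep(-3.5, 8), rep(0.5, 4))))
    expect_gte(abs(mix$mean_fc), 4)
    expect_false(mix$rescued_by_mean_fc)
    # alternative mode: signed fold of the mean ddCt
    alt <- rescueByMeanFC(dd, selectionConfig(meanFcMode = "mean_ddct"))
    expect_equal(alt$mean_fc, signedFold(mean(dd[1, ])))
})

test_that("newly-expressed detection is directional", {
    n <- 12L
    subj <- sprintf("P_%02d", 1:n)
    meta <- makeMeta(c(paste0(subj, "_BL"), paste0(subj, "_FU")),
                     rep(subj, 2), "PROGRESSOR",
                     rep(c("BASELINE", "FOLLOW_UP"), each = n))
    dct <- matrix(5, 3, 2 * n,
                  dimnames = list(c("onset", "steady", "lost"),
                                  meta$sample_id))
    imp <- dct == Inf  # all FALSE
    imp["onset", paste0(subj[1:8], "_BL")] <- TRUE     # 8/12 baselines
    imp["lost", paste0(subj, "_FU")] <- TRUE
    x <- makeDctExperiment(dct, meta, imputed = imp)
    res <- detectNewlyExpressed(x)
    expect_true(res$newly_expressed[res$mirna == "onset"])
    expect_false(res$newly_expressed[res$mirna == "steady"])
    expect_false(res$newly_expressed[res$mirna == "lost"])
})

test_that("panel assembly reproduces the 31-member study panel", {
    ref <- referencePilotSummary()
    cfg <- selectionConfig(keepList = ref$mirna[ref$age_adjust_drop])
    dys <- unique(c(countDysregulated(refFoldTable(ref, "fd_ccp_hc"),
                                      cfg)$mirnas,
                    countDysregulated(refFoldTable(ref, "fd_vera_hc"),
                                      cfg)$mirnas))
    fc <- selectProgressionCandidates(
        data.frame(mirna = ref$mirna, signed_value = ref$fc_median,
                   n_consistent = ref$n_up, n_evaluable = ref$n_evaluable,
                   reliable = !ref$low_expression, stringsAsFactors = FALSE),
        cfg)
    rep <- assemblePanel(dys, fc,
                         rescued = ref$mirna[ref$mean_fc_rescue],
                         newlyExpressed = ref$mirna[ref$newly_expressed],
                         config = cfg)
    expect_length(panel(rep), 31L)
    expect_setequal(panel(rep), ref$mirna)
    tab <- selectionTable(rep)
    expect_true(all(tab$selected))
    expect_true(validObject(rep))
})

test_that("panel assembly is idempotent, deduplicating and order-invariant", {
    cfg <- selectionConfig(literaturePanel = c("lit1", "lit2"))
    p1 <- assemblePanel(c("a", "b"), c("b", "c"), rescued = "lit1",
                        config = cfg)
    p2 <- assemblePanel(c("b", "a"), c("c", "b"), rescued = "lit1",
                        config = cfg)
    expect_identical(panel(p1), panel(p2))
    expect_equal(anyDuplicated(panel(p1)), 0L)
    expect_setequal(panel(p1), c("a", "b", "c", "lit1", "lit2"))
    empty <- assemblePanel(character(), character(),
                           config = selectionConfig())
    expect_length(panel(empty), 9L)   # literature panel only
    expect_warning(
        assemblePanel(sprintf("m%02d", 1:40), character(),
                      config = selectionConfig(literaturePanel = character())),
        "capacity")
})

test_that("selection is monotone in both thresholds", {
    set.seed(99)
    for (rep in 1:20) {
        n <- 10L
        fc <- data.frame(mirna = sprintf("m%02d", 1:n),
                         signed_value = signedFold(runif(n, -3, 3)),
                         n_evaluable = 12L,
                         n_consistent = sample(0:12, n, replace = TRUE),
                         reliable = TRUE)
        loose <- selectProgressionCandidates(
            fc, selectionConfig(foldThreshold = 2,
                                consistencyThreshold = 0.5))
        strict <- selectProgressionCandidates(
            fc, selectionConfig(foldThreshold = 4,
                                consistencyThreshold = 0.75))
        expect_true(all(strict$mirna[strict$selected] %in%
                        loose$mirna[loose$selected]))
    }
})
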