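test_that("prevalence matches direct counting", {
    set.seed(3)
    m <- matrix(rbinom(80, 3, 0.4), 8, 10,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
    g <- rep(c("case", "control"), each = 5)
    prev <- taxonPrevalence(m, g)
    for (tx in rownames(m)) {
        expect_equal(prev[tx, "case"], mean(m[tx, 1:5] > 0))
        expect_equal(prev[tx, "control"], mean(m[tx, 6:10] > 0))
    }
    zero <- m; zero["g1", ] <- 0
    expect_true(all(taxonPrevalence(zero, g)["g1", ] == 0))
    expect_error(taxonPrevalence(m, factor(g, levels = c("case",
        "control", "ghost"))), "at least one sample")
})

test_that("prevalence filter keeps any-group cores at the threshold", {
    m <- rbind(g1 = c(1, 1, 1, 1, 0, 0, 0, 0),  # 100% case, 0% control
               g2 = c(1, 0, 0, 0, 1, 1, 1, 1),  # 25% / 100%
               g3 = c(1, 1, 0, 0, 1, 1, 0, 0),  # 50% / 50%
               g4 = c(1, 1, 1, 1, 1, 1, 1, 1))  # everywhere
    colnames(m) <- paste0("s", 1:8)
    g <- rep(c("case", "control"), each = 4)
    expect_identical(rownames(filterByPrevalence(m, g, 0)), rownames(m))
    expect_identical(rownames(filterByPrevalence(m, g, 100)),
                     c("g1", "g2", "g4"))
    expect_identical(rownames(filterByPrevalence(m, g, 60)),
                     c("g1", "g2", "g4"))
    expect_identical(rownames(filterByPrevalence(m, g, 60,
                                                 require_all = TRUE)),
                     "g4")
})

test_that("OOB curve is monotone in retention and anchored at zero", {
    cfg <- simConfig(n_subjects = 60, n_taxa = 20, case_rate = 0.4,
                     n_prev_taxa = 4, prevalence_delta = 0.6,
                     base_prevalence = 0.95, seed = 19)
    coh <- simulateCohort(cfg)
    g <- sampleStatus(coh)
    m <- relativeAbundance(coh)
    curve <- oobCurve(m, g, thresholds = seq(0, 100, 20), ntree = 100,
                      seed = 1)
    expect_true(all(diff(curve$n_taxa_retained) <= 0))
    expect_true(all(diff(curve$n_reads_retained) <= 0))
    expect_equal(curve$n_taxa_retained[1], nrow(m))
    # threshold-0 row equals a forest on the unfiltered table
    set.seed(1)
    rf0 <- randomForest::randomForest(x = t(m), y = g, ntree = 100)
    expect_equal(curve$oob_error[1],
                 unname(rf0$err.rate[100, "OOB"]) * 100)
})

test_that("forests detect planted signal and stay at chance under null", {
    cfg <- simConfig(n_subjects = 90, n_taxa = 20, case_rate = 0.5,
                     n_lfc_taxa = 4, effect_lfc_magnitude = 4, seed = 23)
    coh <- simulateCohort(cfg)
    g <- sampleStatus(coh)
    m <- relativeAbundance(coh)
    strong <- oobCurve(m, g, thresholds = 0, ntree = 300, seed = 2)
    expect_lt(strong$oob_error[1], 15)
    set.seed(6)
    null_err <- oobCurve(m, sample(g), thresholds = 0, ntree = 300,
                         seed = 3)$oob_error[1]
    maj <- 100 * min(mean(g == "case"), mean(g == "control"))
    expect_gt(null_err, maj - 20)
})

test_that("core taxa ranking recovers planted prevalence effects", {
    hits <- 0L
    for (r in 1:5) {
        cfg <- simConfig(n_subjects = 80, n_taxa = 25, case_rate = 0.33,
                         n_prev_taxa = 2, prevalence_delta = 0.7,
                         base_prevalence = 0.95, seed = 30 + r)
        coh <- simulateCohort(cfg)
        res <- coreTaxa(relativeAbundance(coh), sampleStatus(coh),
                        threshold = 20, top_k = 5, ntree = 300,
                        seed = 100 + r)
        gt <- groundTruth(coh)
        planted <- gt$taxon_id[gt$planted_effect == "prevalence"]
        hit <- planted %in% res$taxon
        dir_ok <- res$direction[match(planted, res$taxon)] ==
            gt$enriched_group[match(planted, gt$taxon_id)]
        hits <- hits + sum(hit & (is.na(dir_ok) | dir_ok))
    }
    expect_gte(hits, 9)  # >= 90% of 10 planted taxa across replicates
})

test_that("top-k selection is deterministic with lexicographic ties", {
    cfg <- simConfig(n_subjects = 50, n_taxa = 12, case_rate = 0.4,
                     n_lfc_taxa = 2, effect_lfc_magnitude = 4, seed = 44)
    coh <- simulateCohort(cfg)
    r1 <- coreTaxa(counts(coh), sampleStatus(coh), threshold = 0,
                   top_k = 1, ntree = 200, seed = 5)
    expect_lte(nrow(r1), 1)
    full <- coreTaxa(counts(coh), sampleStatus(coh), threshold = 0,
                     top_k = 50, ntree = 200, seed = 5)
    if (nrow(r1) == 1)
        expect_identical(r1$taxon, full$taxon[1])
    expect_true(all(full$mda > 0))
    expect_true(all(diff(full$mda) <= 0))
})

test_that("the core branch runs once per design, order-independently", {
    coh <- toyCohort(n_subjects = 80, n_taxa = 15, case_rate = 0.1,
                     seed = 26)
    meta <- as.data.frame(SummarizedExperiment::colData(coh))
    designs <- iterateDesigns(buildControlPools(meta, "region"), 2, 4, 9)
    res <- runCoreBranch(coh, designs, mode = "relative", threshold = 20,
                         top_k = 5, ntree = 100)
    expect_length(res, 4)
    res_rev <- runCoreBranch(coh, rev(designs), mode = "relative",
                             threshold = 20, top_k = 5, ntree = 100)
    expect_identical(res[[1]], res_rev[[4]])
    expect_length(runCoreBranch(coh, designs[1], mode = "relative",
                                threshold = 20, top_k = 5,
                                ntree = 100), 1)
})
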