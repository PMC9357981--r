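fakeDiff <- function(taxa, padj, lfc) {
    data.frame(taxon = taxa, base_mean = 1, log2_fold_change = lfc,
               se = 1, stat = lfc, pvalue = padj, padj = padj,
               stringsAsFactors = FALSE)
}

test_that("consensus tallies match direct counting on a hand-built list", {
    # taxon A significant in 2 of 3 iterations (case direction),
    # taxon B in 1 (control), taxon C never
    res <- list(
        fakeDiff(c("A", "B", "C"), c(0.01, 0.20, 0.9), c(1, -1, 0)),
        fakeDiff(c("A", "B", "C"), c(0.04, 0.01, 0.9), c(2, -2, 0)),
        fakeDiff(c("A", "B", "C"), c(0.30, 0.30, 0.9), c(1, -1, 0)))
    rep <- aggregateConsensus(list(diffabund = list(relative = res)),
                              n_iterations = 3, cut = 2)
    a <- rep[rep$taxon == "A", ]
    expect_equal(a$n_significant, 2)
    expect_true(a$consensus)
    expect_identical(a$direction, "case")
    b <- rep[rep$taxon == "B", ]
    expect_equal(b$n_significant, 1)
    expect_false(b$consensus)
    expect_false("C" %in% rep$taxon)

    expect_error(aggregateConsensus(list(diffabund = list(relative = res)),
                                    n_iterations = 3, cut = 5),
                 "cannot exceed")
    # cut = 0 flags every taxon that was ever tested significant
    rep0 <- aggregateConsensus(list(diffabund = list(relative = res)),
                               n_iterations = 3, cut = 0)
    expect_true(all(rep0$consensus))
})

test_that("aggregation is order-invariant and mode intersection works", {
    r1 <- fakeDiff("A", 0.01, 1.5)
    r2 <- fakeDiff("A", 0.02, 1.0)
    both <- list(diffabund = list(relative = list(r1, r2),
                                  total = list(r2, r1)))
    rep <- aggregateConsensus(both, n_iterations = 2, cut = 2)
    expect_true(all(rep$in_both_modes))
    shuffled <- aggregateConsensus(
        list(diffabund = list(relative = list(r2, r1),
                              total = list(r1, r2))),
        n_iterations = 2, cut = 2)
    expect_identical(rep, shuffled)
    # consensus in one mode only is not "both modes"
    one <- aggregateConsensus(
        list(diffabund = list(relative = list(r1, r2),
                              total = list(fakeDiff("A", 0.5, 1), r1))),
        n_iterations = 2, cut = 2)
    expect_false(any(one$in_both_modes))
})

test_that("direction ties are broken toward control with a warning", {
    res <- list(fakeDiff("A", 0.01, 1), fakeDiff("A", 0.01, -1))
    expect_warning(
        rep <- aggregateConsensus(list(diffabund = list(relative = res)),
                                  n_iterations = 2, cut = 2),
        "tie")
    expect_identical(rep$direction, "control")
})

test_that("cohort summary matches the closed-form oracle exactly", {
    tbl <- fcdCaseTable()
    expect_equal(nrow(tbl), 26)
    s <- summarizeCohort(tbl)
    age <- tbl$age_of_diagnosis
    expect_equal(s$age_mean, round(sum(age) / 26, 2))
    expect_equal(s$age_sd,
                 round(sqrt(sum((age - mean(age))^2) / 25), 2))
    # substring carriage: DR3-DQ2 without the allele suffix or a
    # different DR arm must not count as DR3-DQ2.5
    expect_equal(s$pct_hla_carriers,
                 round(100 * sum(grepl("DR3-DQ2.5", tbl$hla,
                                       fixed = TRUE), na.rm = TRUE) / 26))
    expect_false(grepl("DR3-DQ2.5", "DR3-DQ2", fixed = TRUE))
    expect_false(grepl("DR3-DQ2.5", "DR5-DQ7/DR7-DQ2.5", fixed = TRUE))

    one <- data.frame(age_of_diagnosis = 10, sex = "Female", hla = NA)
    s1 <- summarizeCohort(one, n_controls = 99)
    expect_equal(s1$age_mean, 10)
    expect_true(is.na(s1$age_sd))
    expect_error(summarizeCohort(data.frame(status = "control",
                                            age_of_diagnosis = 1,
                                            sex = "Male", hla = NA)),
                 "no cases")
})

test_that("covariate associations require both abundance modes", {
    cfg <- simConfig(n_subjects = 200, n_taxa = 12, case_rate = 0.1,
                     seed = 61)
    coh <- simulateCohort(cfg)
    # build a factor equal to a median split of one taxon's relative
    # abundance: must be significant in both modes at n = 200
    rel <- relativeAbundance(coh)
    split_var <- ifelse(rel["Genus005", ] > median(rel["Genus005", ]),
                        "hi", "lo")
    cd <- as.data.frame(SummarizedExperiment::colData(coh))
    cd$split <- split_var
    coh2 <- MicrobiomeCohort(counts(coh), metadata = cd,
                             qpcr = qpcrLoads(coh))
    res <- covariateAssociations(coh2, "Genus005", c("split", "sex"))
    hit <- res[res$factor == "split", ]
    expect_true(hit$significant_both)
    expect_lt(hit$padj_relative, 0.05)
    expect_lt(hit$padj_total, 0.05)
    # the both-modes rule never reports a factor missing from one mode
    expect_true(all(res$significant_both ==
        (res$padj_relative < 0.05 & res$padj_total < 0.05 &
         !is.na(res$padj_relative) & !is.na(res$padj_total))))
    expect_identical(nrow(covariateAssociations(coh2, character(),
                                                "sex")), 0L)
})

test_that("Monte-Carlo chi-square reproduces analytic extremes", {
    meta_eq <- data.frame(status = rep(c("case", "control"), each = 20),
                          f = rep(c("a", "b", "a", "b"), each = 10))
    r <- earlyLifeChisq(meta_eq, "f", n_sim = 500, seed = 1)
    expect_equal(r$statistic, 0)
    expect_equal(r$p_mc, 1)

    meta_sep <- data.frame(status = rep(c("case", "control"), each = 20),
                           f = rep(c("a", "b"), each = 20))
    r2 <- earlyLifeChisq(meta_sep, "f", n_sim = 500, seed = 1)
    expect_equal(r2$p_mc, 1 / 501)

    # large balanced table: Monte-Carlo p tracks the asymptotic p
    set.seed(9)
    meta_big <- data.frame(
        status = sample(c("case", "control"), 1000, TRUE),
        f = sample(c("a", "b", "c"), 1000, TRUE))
    r3 <- earlyLifeChisq(meta_big, "f", n_sim = 4000, seed = 2)
    asym <- stats::chisq.test(table(meta_big$f, meta_big$status))$p.value
    expect_lt(abs(r3$p_mc - asym), 0.02)

    degenerate <- data.frame(status = rep("case", 10), f = rep("a", 10))
    expect_error(earlyLifeChisq(degenerate, "f"), "degenerate")
})
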