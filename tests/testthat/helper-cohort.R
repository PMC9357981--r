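# small deterministic fixtures built in code

toyCounts <- function() {
    m <- matrix(c(5, 0, 3,
                  5, 2, 3,
                  0, 0, 0,
                  1, 8, 4), nrow = 4, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), c("s1", "s2", "s3")))
    m
}

toyCohort <- function(n_subjects = 120, n_taxa = 30, case_rate = 0.3,
                      seed = 7, ...) {
    simulateCohort(simConfig(n_subjects = n_subjects, n_taxa = n_taxa,
                             case_rate = case_rate, seed = seed, ...))
}

toyMeta <- function() {
    # 3 cases, 10 controls with hand-checkable pools
    data.frame(
        subject_id = c(paste0("case", 1:3), paste0("ctl", 1:10)),
        status = c(rep("case", 3), rep("control", 10)),
        region = c("N", "S", "N",
                   "N", "N", "N", "S", "S", "N", "S", "N", "S", "N"),
        siblings = c("Yes", "No", NA,
                     "Yes", "Yes", "No", "No", "Yes", "Yes", "No",
                     "No", NA, "Yes"),
        stringsAsFactors = FALSE)
}
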