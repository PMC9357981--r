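.tallyBranch <- function(results, branch = c("core", "diffabund"),
                         alpha = 0.05) {
    branch <- match.arg(branch)
    hits <- lapply(results, function(res) {
        if (branch == "diffabund") {
            sig <- res[!is.na(res$padj) & res$padj < alpha, , drop = FALSE]
            data.frame(taxon = sig$taxon,
                       direction = ifelse(sig$log2_fold_change >= 0,
                                          "case", "control"),
                       stringsAsFactors = FALSE)
        } else {
            res[, c("taxon", "direction"), drop = FALSE]
        }
    })
    all_hits <- do.call(rbind, hits)
    if (is.null(all_hits) || nrow(all_hits) == 0)
        return(data.frame(taxon = character(), n_significant = integer(),
                          n_case = integer(), n_control = integer(),
                          stringsAsFactors = FALSE))
    tab <- table(all_hits$taxon, factor(all_hits$direction,
                                        levels = c("case", "control")))
    data.frame(taxon = rownames(tab),
               n_significant = as.integer(rowSums(tab)),
               n_case = as.integer(tab[, "case"]),
               n_control = as.integer(tab[, "control"]),
               stringsAsFactors = FALSE)
}

#' Aggregate per-iteration results into a consensus report
#'
#' Counts, per taxon, the iterations in which it was significant
#' (differential-abundance branch: \code{padj < alpha}; core branch:
#' membership in the positive-MDA top-k), flags consensus taxa reaching
#' at least \code{cut} of the iterations, calls the direction by majority
#' vote across the counted iterations (ties broken toward
#' \code{"control"} with a warning), and marks taxa whose consensus holds
#' in both abundance modes of a branch.
#'
#' @param results nested named list:
#'   \code{results[[branch]][[mode]]} is the per-iteration result list of
#'   \code{\link{runCoreBranch}} or \code{\link{runDiffAbundBranch}},
#'   e.g. \code{list(core = list(relative = ..., total = ...),
#'   diffabund = list(relative = ...))}.
#' @param n_iterations number of iterations each branch was run for.
#' @param cut consensus cut: minimum number of significant iterations
#'   (50 of 100 in the reference protocol).
#' @param alpha adjusted-significance threshold for the
#'   differential-abundance branch.
#' @return \code{data.frame}, one row per taxon x branch x mode:
#'   \code{n_significant}, \code{consensus}, \code{direction},
#'   \code{in_both_modes}.
#' @examples
#' # see the package vignette for an end-to-end example
#' @export
aggregateConsensus <- function(results, n_iterations, cut = 50,
                               alpha = 0.05) {
    if (cut > n_iterations)
        stop("cut (", cut, ") cannot exceed n_iterations (",
             n_iterations, ")")
    rows <- list()
    for (branch in names(results)) {
        for (mode in names(results[[branch]])) {
            tl <- .tallyBranch(results[[branch]][[mode]], branch = branch,
                               alpha = alpha)
            if (nrow(tl) == 0) next
            tie <- tl$n_case == tl$n_control
            if (any(tie & tl$n_significant > 0))
                warning("direction tie for taxa ",
                        paste(tl$taxon[tie], collapse = ", "),
                        "; broken toward 'control'")
            rows[[paste(branch, mode)]] <- data.frame(
                taxon = tl$taxon, branch = branch, mode = mode,
                n_significant = tl$n_significant,
                consensus = tl$n_significant >= cut,
                direction = ifelse(tl$n_case > tl$n_control,
                                   "case", "control"),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(taxon = character(), branch = character(),
                          mode = character(), n_significant = integer(),
                          consensus = logical(), direction = character(),
                          in_both_modes = logical()))
    rownames(out) <- NULL
    # a taxon is "in both modes" if its consensus holds in >= 2 modes of
    # the same branch
    key <- paste(out$taxon, out$branch)
    cons_modes <- tapply(out$consensus, key, sum)
    out$in_both_modes <- out$consensus & cons_modes[key] >= 2
    out <- out[order(out$branch, out$mode, -out$n_significant, out$taxon), ]
    rownames(out) <- NULL
    out
}

#' Characteristics of the ABIS infants with future celiac disease
#'
#' The per-case characteristics table distributed with the package: age
#' of diagnosis (years), compound HLA-DR-DQ genotype, sex, mode of
#' delivery, geographic region, siblings at birth, breastfeeding and
#' gluten-introduction bins, and the size of each case's matched control
#' pool in the source cohort (1452 eligible controls overall, carried in
#' attribute \code{n_controls}).
#'
#' @return \code{data.frame} of 26 rows with attribute \code{n_controls}.
#' @examples
#' head(fcdCaseTable())
#' @export
fcdCaseTable <- function() {
    path <- system.file("extdata", "abis_fcd_cases.tsv",
                        package = "micomatch", mustWork = TRUE)
    tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = "NA")
    attr(tbl, "n_controls") <- 1452L
    tbl
}

#' Cohort summary statistics
#'
#' Mean and sample (n-1) standard deviation of the age of diagnosis,
#' overall and by sex; percent female among cases; percent of cases
#' carrying a named HLA haplotype (exact substring match on the genotype
#' string, missing genotypes counted as non-carriers); and cohort
#' incidence.  Values are rounded for display the way clinical cohort
#' tables print them: means/SDs to 2 decimals, percentages to whole
#' numbers, incidence to 1 decimal.
#'
#' @param meta \code{data.frame} of case rows (or a full cohort with a
#'   \code{status} column, from which cases are taken).  Needs columns
#'   \code{age_of_diagnosis}, \code{sex}, \code{hla}.
#' @param haplotype_query HLA substring whose carriage frequency is
#'   reported (e.g. \code{"DR3-DQ2.5"}).
#' @param n_controls number of controls (taken from
#'   \code{meta$status == "control"} when present, else from an
#'   \code{n_controls} attribute as in \code{\link{fcdCaseTable}}).
#' @return named list: \code{n_cases}, \code{n_controls},
#'   \code{incidence_pct}, \code{age_mean}, \code{age_sd},
#'   \code{age_mean_female}, \code{age_sd_female}, \code{age_mean_male},
#'   \code{age_sd_male}, \code{pct_female}, \code{pct_hla_carriers}.
#' @examples
#' summarizeCohort(fcdCaseTable())
#' @export
summarizeCohort <- function(meta, haplotype_query = "DR3-DQ2.5",
                            n_controls = NULL) {
    if (!is.null(meta$status)) {
        if (is.null(n_controls))
            n_controls <- sum(meta$status == "control")
        cases <- meta[meta$status == "case", , drop = FALSE]
    } else {
        cases <- meta
        if (is.null(n_controls))
            n_controls <- attr(meta, "n_controls")
    }
    if (nrow(cases) == 0) stop("no cases to summarize")
    sdev <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)
    age <- cases$age_of_diagnosis
    fem <- cases$sex == "Female"
    carrier <- !is.na(cases$hla) & grepl(haplotype_query, cases$hla,
                                         fixed = TRUE)
    inc <- if (is.null(n_controls)) NA_real_ else
        round(100 * nrow(cases) / (nrow(cases) + n_controls), 1)
    list(n_cases = nrow(cases),
         n_controls = n_controls %||% NA_integer_,
         incidence_pct = inc,
         age_mean = round(mean(age), 2),
         age_sd = round(sdev(age), 2),
         age_mean_female = round(mean(age[fem]), 2),
         age_sd_female = round(sdev(age[fem]), 2),
         age_mean_male = round(mean(age[!fem]), 2),
         age_sd_male = round(sdev(age[!fem]), 2),
         pct_female = round(100 * mean(fem)),
         pct_hla_carriers = round(100 * mean(carrier)))
}

#' Associate host factors with abundance of the consensus taxa
#'
#' For every consensus taxon and candidate factor, tests whether the
#' taxon's abundance differs across factor levels on the full cohort:
#' Mann-Whitney (Wilcoxon rank-sum) for two-level factors,
#' Kruskal-Wallis for more levels; missing factor values are dropped.
#' P values are BH-adjusted globally across the taxon x factor grid
#' within each abundance mode, and a factor is reported as significant
#' for a taxon only when it passes \code{alpha} in \emph{both} abundance
#' modes.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param taxa character, taxa to test (e.g. consensus taxa).
#' @param factors character, categorical columns of \code{colData(x)}.
#' @param alpha adjusted-significance threshold.
#' @param modes abundance modes tested (both by default).
#' @return \code{data.frame} per taxon x factor with per-mode \code{padj}
#'   columns and logical \code{significant_both}.
#' @export
covariateAssociations <- function(x, taxa, factors, alpha = 0.05,
                                  modes = c("relative", "total")) {
    taxa <- intersect(taxa, rownames(x))
    if (length(taxa) == 0 || length(factors) == 0)
        return(data.frame(taxon = character(), factor = character()))
    grid <- expand.grid(taxon = taxa, factor = factors,
                        stringsAsFactors = FALSE)
    for (mode in modes) {
        ab <- abundanceMatrix(x, mode)
        pv <- vapply(seq_len(nrow(grid)), function(i) {
            f <- colData(x)[[grid$factor[i]]]
            y <- ab[grid$taxon[i], ]
            ok <- !is.na(f)
            g <- factor(f[ok])
            if (nlevels(g) < 2) {
                warning("factor ", grid$factor[i],
                        " has a single level; skipped")
                return(NA_real_)
            }
            if (nlevels(g) == 2)
                stats::wilcox.test(y[ok] ~ g, exact = FALSE)$p.value
            else
                stats::kruskal.test(y[ok], g)$p.value
        }, numeric(1))
        grid[[paste0("pvalue_", mode)]] <- pv
        grid[[paste0("padj_", mode)]] <- bhAdjust(pv)
    }
    padj_cols <- paste0("padj_", modes)
    sig <- rep(TRUE, nrow(grid))
    for (cl in padj_cols) sig <- sig & !is.na(grid[[cl]]) & grid[[cl]] < alpha
    grid$significant_both <- sig
    grid
}

#' Monte-Carlo chi-square test of an early-life factor against status
#'
#' Pearson chi-square statistic of the factor x status contingency table
#' with a Monte-Carlo p value,
#' \eqn{p = (1 + \#\{\chi^2_{sim} \ge \chi^2_{obs}\})/(B + 1)}, from
#' tables simulated with both margins fixed
#' (\code{stats::chisq.test(simulate.p.value = TRUE)}).
#'
#' @param meta cohort metadata with a \code{status} column.
#' @param factor_name column of \code{meta} to cross-tabulate.
#' @param n_sim number of simulated tables.
#' @param seed RNG seed.
#' @return named list: \code{statistic}, \code{p_mc}, \code{table}.
#' @export
earlyLifeChisq <- function(meta, factor_name, n_sim = 2000, seed = 1L) {
    f <- droplevels(factor(meta[[factor_name]]))
    s <- droplevels(factor(meta$status))
    ok <- !is.na(f) & !is.na(s)
    tab <- table(f[ok], s[ok])
    if (any(dim(tab) < 2) || any(rowSums(tab) == 0) ||
        any(colSums(tab) == 0))
        stop("degenerate contingency table for ", factor_name)
    set.seed(seed)
    ct <- stats::chisq.test(tab, simulate.p.value = TRUE, B = n_sim)
    list(statistic = unname(ct$statistic), p_mc = ct$p.value, table = tab)
}
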