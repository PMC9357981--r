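#' Zero-tolerant ("poscounts") size factors
#'
#' Median-of-ratios normalization that stays defined when every taxon has
#' at least one zero.  The per-taxon reference is the geometric mean over
#' the *positive* counts only, but divided by the total number of samples
#' \eqn{m}: \eqn{r_i = (\prod_{j: c_{ij}>0} c_{ij})^{1/m}}.  The size
#' factor of sample \eqn{j} is the median of \eqn{c_{ij}/r_i} over taxa
#' with \eqn{r_i > 0} and \eqn{c_{ij} > 0}, and the factors are rescaled
#' to geometric mean 1.
#'
#' @param m taxa x samples count matrix.
#' @return named positive numeric vector of size factors, one per sample.
#' @examples
#' m <- matrix(c(4, 0, 8, 2, 6, 1, 0, 3, 12, 0, 16, 4), 4, 3,
#'     dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' sizeFactorsPoscounts(m)
#' @export
sizeFactorsPoscounts <- function(m) {
    m <- as.matrix(m)
    if (any(colSums(m) == 0))
        stop("sample(s) with all-zero counts: ",
             paste(colnames(m)[colSums(m) == 0], collapse = ", "))
    nsamp <- ncol(m)
    logref <- apply(m, 1, function(row) {
        pos <- row[row > 0]
        if (length(pos) == 0) -Inf else sum(log(pos)) / nsamp
    })
    sf <- vapply(seq_len(nsamp), function(j) {
        use <- is.finite(logref) & m[, j] > 0
        if (!any(use))
            stop("sample ", colnames(m)[j],
                 " shares no positive taxon with the reference")
        stats::median(exp(log(m[use, j]) - logref[use]))
    }, numeric(1))
    sf <- sf / exp(mean(log(sf)))
    stats::setNames(sf, colnames(m))
}

#' Method-of-moments negative-binomial dispersion per taxon
#'
#' \eqn{\hat\alpha_i = \max((v_i - \bar\mu_i)/\bar\mu_i^2,\ \alpha_{floor})}
#' from the mean \eqn{\bar\mu_i} and sample variance \eqn{v_i} of the
#' size-factor-normalized counts of taxon \eqn{i}.  A deliberately simple
#' estimator: no trend fitting or empirical-Bayes shrinkage, which keeps
#' the Wald test's operating characteristics transparent at matched-subset
#' sample sizes (see the package vignette for the fidelity discussion).
#'
#' @param m taxa x samples count matrix.
#' @param sf size factors from \code{\link{sizeFactorsPoscounts}}.
#' @param floor lower bound on the dispersion estimate.
#' @return named numeric vector of dispersions; attribute
#'   \code{untestable} marks all-zero taxa (held at the floor).
#' @export
estimateTaxonDispersion <- function(m, sf = sizeFactorsPoscounts(m),
                                    floor = 1e-8) {
    k <- sweep(as.matrix(m), 2, sf, "/")
    mu <- rowMeans(k)
    n <- ncol(k)
    v <- rowSums((k - mu)^2) / (n - 1)
    alpha <- ifelse(mu > 0, (v - mu) / mu^2, 0)
    alpha <- pmax(alpha, floor)
    names(alpha) <- rownames(m)
    attr(alpha, "untestable") <- rownames(m)[mu == 0]
    alpha
}

#' Per-taxon negative-binomial Wald test, cases vs controls
#'
#' Two-group NB test on size-factor-normalized counts.  The effect is
#' \eqn{LFC_i = \log_2\frac{\bar k_{i,case} + c}{\bar k_{i,control} + c}}
#' with a pseudo-mean shift \eqn{c} (default 0.5) applied symmetrically to
#' both group means so taxa absent from one group keep a finite LFC.  The
#' standard error comes from the expected information of the NB model
#' with plug-in group means and dispersion \eqn{\alpha_i}:
#' \eqn{\mathrm{Var}(\ln \bar k_{g}) \approx n_g^{-2} \sum_{j \in g}
#' (1/(\bar k_g s_j) + \alpha_i)}.  The Wald statistic \eqn{z = LFC/SE}
#' is referred to the standard normal (two-sided), and p values are
#' Benjamini-Hochberg adjusted across taxa.  No outlier (Cook's distance)
#' filtering is applied.
#'
#' @param m taxa x samples count matrix (integer; real-valued abundances
#'   must be scaled and rounded first, see \code{\link{runDiffAbundBranch}}).
#' @param groups case/control labels, one per sample.
#' @param sf size factors (poscounts by default).
#' @param dispersion per-taxon dispersions (method-of-moments by default).
#' @param pseudo pseudo-mean shift added to both group means.
#' @param iteration iteration index carried into the result.
#' @return \code{data.frame}: \code{taxon}, \code{base_mean},
#'   \code{log2_fold_change}, \code{se}, \code{stat}, \code{pvalue},
#'   \code{padj}.
#' @export
nbWaldTest <- function(m, groups, sf = sizeFactorsPoscounts(m),
                       dispersion = estimateTaxonDispersion(m, sf),
                       pseudo = 0.5, iteration = NA_integer_) {
    m <- as.matrix(m)
    g <- factor(groups, levels = c("control", "case"))
    if (nlevels(droplevels(g)) != 2 || any(table(g) < 2))
        stop("need two groups ('case', 'control') with >= 2 samples each")
    k <- sweep(m, 2, sf, "/")
    case <- g == "case"
    n1 <- sum(case); n0 <- sum(!case)
    m1 <- rowMeans(k[, case, drop = FALSE]) + pseudo
    m0 <- rowMeans(k[, !case, drop = FALSE]) + pseudo
    lfc <- log2(m1 / m0)
    inv_s1 <- sum(1 / sf[case]); inv_s0 <- sum(1 / sf[!case])
    v1 <- (inv_s1 / m1 + n1 * dispersion) / n1^2
    v0 <- (inv_s0 / m0 + n0 * dispersion) / n0^2
    se <- sqrt(v1 + v0) / log(2)
    stat <- lfc / se
    p <- 2 * stats::pnorm(-abs(stat))
    out <- data.frame(taxon = rownames(m),
                      base_mean = rowMeans(k),
                      log2_fold_change = unname(lfc), se = unname(se),
                      stat = unname(stat), pvalue = unname(p),
                      padj = bhAdjust(unname(p)),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "iteration") <- iteration
    out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")} with input
#' validation: monotone step-up FDR adjustment capped at 1.
#'
#' @param p numeric vector of p values in [0, 1].
#' @return adjusted p values, same length and order as \code{p}.
#' @export
bhAdjust <- function(p) {
    if (any(!is.na(p) & (p < 0 | p > 1)))
        stop("p values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Run the differential-abundance branch over all matched designs
#'
#' Applies the NB Wald test to each matched case-control subset without
#' any prevalence pre-filter.  In \code{"relative"} mode the raw counts
#' are fed to the test: the median-of-ratios size factors normalize
#' library size away, so the test is of relative composition while the
#' counts keep their true sampling granularity (see the vignette for why
#' fractions are not scaled to pseudo-counts).  In \code{"total"} mode
#' the qPCR-scaled absolute abundances (copies per gram) are rounded to
#' integers before fitting.  P values are BH-adjusted within each
#' iteration, across taxa.
#'
#' @inheritParams runCoreBranch
#' @param pseudo pseudo-mean shift of \code{\link{nbWaldTest}}.
#' @return List of per-iteration \code{\link{nbWaldTest}} result frames.
#' @export
runDiffAbundBranch <- function(x, designs, mode = "relative",
                               pseudo = 0.5) {
    lapply(designs, function(d) {
        sub <- subsetDesign(x, d)
        m <- if (mode == "total") round(abundanceMatrix(sub, "total"))
             else counts(sub)
        nbWaldTest(m, sampleStatus(sub), pseudo = pseudo,
                   iteration = d@iteration)
    })
}
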