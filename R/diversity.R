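#' Binomial deviance dissimilarity between samples
#'
#' For samples \eqn{j,k} and taxon counts \eqn{x_i, y_i} with
#' \eqn{n_i = x_i + y_i > 0}, the distance is
#' \deqn{d_{jk} = \sum_i \frac{1}{n_i}\left[x_i\ln\frac{x_i}{n_i} +
#'   y_i\ln\frac{y_i}{n_i} + n_i\ln 2\right]}
#' with \eqn{0\ln 0 \equiv 0}: the scaled deviance of the per-taxon
#' binomial null that reads split evenly between the two samples.  A
#' taxon present in only one of the two samples contributes exactly
#' \eqn{\ln 2}.  Computed with \code{\link[vegan]{vegdist}}.
#'
#' @param x a \linkS4class{MicrobiomeCohort} or a taxa x samples matrix.
#' @return A \code{dist} over samples.
#' @examples
#' m <- matrix(c(5, 0, 3, 5, 2, 3), 3, 2,
#'     dimnames = list(paste0("g", 1:3), c("a", "b")))
#' binomialDistance(m)
#' @export
binomialDistance <- function(x) {
    m <- if (is(x, "MicrobiomeCohort")) counts(x) else as.matrix(x)
    if (any(m < 0)) stop("negative entries are not allowed")
    if (ncol(m) < 2) stop("need at least two samples")
    vegan::vegdist(t(m), method = "binomial")
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' One-variable PERMANOVA: the pseudo-F statistic
#' \eqn{F = (SS_B/(a-1)) / (SS_W/(N-a))} from the Gower-centred distance
#' decomposition, with significance from whole-row label permutations,
#' \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (B + 1)}.  Samples with a
#' missing label are dropped before testing.  Backed by
#' \code{\link[vegan]{adonis2}}.
#'
#' @param d a \code{dist} (e.g. from \code{\link{binomialDistance}}).
#' @param labels factor-like group labels, one per sample in \code{d}.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations (optional).
#' @param variable name to report for the tested variable.
#' @return one-row \code{data.frame}: \code{variable}, \code{pseudo_F},
#'   \code{r_squared}, \code{p_value}, \code{n_permutations}, \code{n_used}.
#' @export
permanovaTest <- function(d, labels, n_perm = 999, seed = NULL,
                          variable = "group") {
    dm <- as.matrix(d)
    labels <- as.character(labels)
    if (length(labels) != nrow(dm))
        stop("one label per sample is required")
    keep <- !is.na(labels)
    dm <- dm[keep, keep, drop = FALSE]
    g <- factor(labels[keep])
    if (nlevels(g) < 2)
        stop("need at least two groups with observed labels")
    if (!is.null(seed)) set.seed(seed)
    df <- data.frame(g = g)
    fit <- vegan::adonis2(stats::as.dist(dm) ~ g, data = df,
                          permutations = n_perm)
    data.frame(variable = variable,
               pseudo_F = fit$F[1],
               r_squared = fit$R2[1],
               p_value = fit$`Pr(>F)`[1],
               n_permutations = n_perm,
               n_used = sum(keep),
               stringsAsFactors = FALSE)
}

#' Screen metadata variables for association with community composition
#'
#' Tests each candidate variable against the binomial-deviance distance
#' matrix of the cohort with a single-variable PERMANOVA (missing values
#' excluded per variable), adjusts p values across the screened set by
#' Benjamini-Hochberg, and flags variables with \code{padj < alpha} as
#' confounders to be used as matching covariates.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param variables character, column names of \code{colData(x)} to screen.
#' @param alpha FDR threshold for flagging a confounder.
#' @param n_perm permutations per test.
#' @param seed base RNG seed; test \eqn{k} uses \code{seed + k}.
#' @param mode abundance mode for the distance matrix (counts by default).
#' @return \code{data.frame}, one row per variable, with \code{padj} and
#'   logical \code{confounder}.
#' @examples
#' coh <- simulateCohort(simConfig(n_subjects = 60, n_taxa = 40, seed = 9))
#' screenConfounders(coh, c("region", "sex"), n_perm = 99, seed = 1)
#' @export
screenConfounders <- function(x, variables, alpha = 0.05, n_perm = 999,
                              seed = 1, mode = "counts") {
    if (length(variables) == 0)
        return(data.frame(variable = character(), pseudo_F = numeric(),
                          r_squared = numeric(), p_value = numeric(),
                          n_permutations = integer(), n_used = integer(),
                          padj = numeric(), confounder = logical()))
    missing_vars <- setdiff(variables, colnames(colData(x)))
    if (length(missing_vars))
        stop("variable(s) not in metadata: ",
             paste(missing_vars, collapse = ", "))
    d <- binomialDistance(abundanceMatrix(x, mode))
    res <- do.call(rbind, lapply(seq_along(variables), function(k) {
        permanovaTest(d, colData(x)[[variables[k]]], n_perm = n_perm,
                      seed = seed + k, variable = variables[k])
    }))
    res$padj <- stats::p.adjust(res$p_value, method = "BH")
    res$confounder <- res$padj < alpha
    res
}
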