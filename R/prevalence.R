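#' Per-taxon, per-group prevalence
#'
#' Prevalence of a taxon in a group is the fraction of that group's
#' samples in which the taxon is observed at all (any value > 0),
#' irrespective of abundance.
#'
#' @param m taxa x samples numeric matrix (counts or abundances).
#' @param groups factor-like group labels, one per sample.
#' @return numeric matrix, taxa x groups, of fractions in [0, 1].
#' @examples
#' m <- matrix(c(0, 2, 1, 0, 3, 0), 2, 3,
#'     dimnames = list(c("g1", "g2"), c("a", "b", "c")))
#' taxonPrevalence(m, c("x", "x", "y"))
#' @export
taxonPrevalence <- function(m, groups) {
    g <- if (is.factor(groups)) groups else factor(groups)
    if (nlevels(g) < 1 || any(table(g) == 0))
        stop("every group must contain at least one sample")
    out <- vapply(levels(g), function(lv) {
        rowMeans(m[, g == lv, drop = FALSE] > 0)
    }, numeric(nrow(m)))
    out <- matrix(out, nrow = nrow(m),
                  dimnames = list(rownames(m), levels(g)))
    out
}

#' Prevalence-interval filter
#'
#' Retains taxa whose prevalence reaches \code{threshold} percent in at
#' least one group (the per-group cores are merged); with
#' \code{require_all = TRUE} a taxon must reach the threshold in every
#' group instead.
#'
#' @inheritParams taxonPrevalence
#' @param threshold prevalence threshold in percent, in [0, 100].
#' @param require_all require the threshold in all groups rather than any.
#' @return The filtered matrix (possibly with zero rows).
#' @export
filterByPrevalence <- function(m, groups, threshold = 60,
                               require_all = FALSE) {
    stopifnot(threshold >= 0, threshold <= 100)
    prev <- taxonPrevalence(m, groups)
    hit <- prev * 100 >= threshold
    keep <- if (require_all) rowSums(hit) == ncol(hit) else rowSums(hit) > 0
    m[keep, , drop = FALSE]
}

.fitForest <- function(m, groups, ntree, seed, importance = FALSE) {
    set.seed(seed)
    randomForest::randomForest(x = t(m), y = factor(groups),
                               ntree = ntree, importance = importance)
}

#' Out-of-bag error across the prevalence interval
#'
#' At each prevalence threshold (0, 5, ..., 100 percent) the table is
#' filtered with \code{\link{filterByPrevalence}} and a random forest
#' (bagged trees, \eqn{\sqrt{p}} candidate features per split) is fit to
#' predict the group; the out-of-bag misclassification rate, the number
#' of taxa retained and the number of reads retained are recorded.  The
#' curve lets the analyst pick a threshold balancing OOB error against
#' taxon representation.
#'
#' @inheritParams filterByPrevalence
#' @param thresholds percent thresholds to scan.
#' @param ntree trees per forest.
#' @param seed base RNG seed (one derived seed per threshold).
#' @return \code{data.frame}: \code{threshold}, \code{oob_error} (percent,
#'   \code{NA} where no taxon survives), \code{n_taxa_retained},
#'   \code{n_reads_retained}.
#' @export
oobCurve <- function(m, groups, thresholds = seq(0, 100, by = 5),
                     ntree = 500, seed = 1L) {
    g <- factor(groups)
    if (nlevels(g) < 2) stop("need at least two groups")
    res <- lapply(seq_along(thresholds), function(k) {
        mf <- filterByPrevalence(m, g, thresholds[k])
        if (nrow(mf) == 0)
            return(data.frame(threshold = thresholds[k], oob_error = NA_real_,
                              n_taxa_retained = 0L, n_reads_retained = 0))
        rf <- .fitForest(mf, g, ntree, seed + k - 1L)
        oob <- rf$err.rate[ntree, "OOB"] * 100
        data.frame(threshold = thresholds[k], oob_error = unname(oob),
                   n_taxa_retained = nrow(mf),
                   n_reads_retained = sum(mf))
    })
    do.call(rbind, res)
}

#' Core taxa of one matched design by permutation importance
#'
#' Filters the table at the chosen prevalence threshold, fits a random
#' forest predicting group membership, ranks taxa by mean decrease in
#' out-of-bag accuracy (MDA, in percentage points) under per-taxon value
#' permutation, keeps the \code{top_k} taxa (ties broken by taxon label),
#' drops taxa with non-positive MDA, and calls the direction of each
#' survivor as the group with the larger mean abundance.
#'
#' @inheritParams filterByPrevalence
#' @param top_k maximum number of taxa reported.
#' @param ntree trees in the forest.
#' @param seed RNG seed.
#' @param iteration iteration index carried into the result.
#' @return \code{data.frame}: \code{taxon}, \code{mda},
#'   \code{direction} (\code{"case"}/\code{"control"}),
#'   \code{mean_case}, \code{mean_control}; attributes \code{iteration},
#'   \code{threshold}, \code{oob_error}.
#' @export
coreTaxa <- function(m, groups, threshold = 60, top_k = 30, ntree = 500,
                     seed = 1L, iteration = NA_integer_) {
    g <- factor(groups, levels = c("control", "case"))
    mf <- filterByPrevalence(m, g, threshold)
    if (nrow(mf) == 0)
        stop("no taxon passes the ", threshold, "% prevalence threshold")
    rf <- .fitForest(mf, g, ntree, seed, importance = TRUE)
    # unscaled mean decrease in OOB accuracy, as percentage points
    mda <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1] * 100
    ord <- order(-mda, names(mda))
    top <- names(mda)[ord][seq_len(min(top_k, length(mda)))]
    top <- top[mda[top] > 0]
    mc <- rowMeans(mf[top, g == "case", drop = FALSE])
    m0 <- rowMeans(mf[top, g == "control", drop = FALSE])
    out <- data.frame(taxon = top, mda = unname(mda[top]),
                      direction = ifelse(mc >= m0, "case", "control"),
                      mean_case = unname(mc), mean_control = unname(m0),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "iteration") <- iteration
    attr(out, "threshold") <- threshold
    attr(out, "oob_error") <- unname(rf$err.rate[ntree, "OOB"] * 100)
    out
}

#' Run the prevalence/core branch over all matched designs
#'
#' Applies \code{\link{coreTaxa}} to each matched case-control subset in
#' the chosen abundance mode, seeding each forest with that design's
#' stored seed so the whole branch replays exactly.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param designs list of \linkS4class{MatchedDesign}.
#' @param mode abundance mode (\code{"relative"}, \code{"total"} or
#'   \code{"counts"}).
#' @param threshold,top_k,ntree see \code{\link{coreTaxa}}.
#' @return List of per-iteration \code{coreTaxa} result frames.
#' @export
runCoreBranch <- function(x, designs, mode = "relative", threshold = 60,
                          top_k = 30, ntree = 500) {
    lapply(designs, function(d) {
        sub <- subsetDesign(x, d)
        m <- abundanceMatrix(sub, mode)
        coreTaxa(m, sampleStatus(sub), threshold = threshold,
                 top_k = top_k, ntree = ntree, seed = designSeed(d),
                 iteration = d@iteration)
    })
}
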