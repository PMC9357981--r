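#' Build per-case pools of eligible matched controls
#'
#' For every case, the eligible controls are those equal to the case on
#' every matching covariate where the case's value is observed; a
#' covariate missing on the case side is skipped for that case (region-only
#' matching, say, for a case with unknown siblings status), while a
#' control missing a required covariate is excluded from that case's pool.
#'
#' @param meta \code{data.frame} with columns \code{subject_id},
#'   \code{status} (\code{"case"}/\code{"control"}) and the covariates.
#' @param covariates character, matching covariate column names.
#' @return Named list (one element per case id) of eligible control id
#'   vectors, with attribute \code{covariates}.
#' @examples
#' cfg <- simConfig(n_subjects = 400, seed = 4)
#' meta <- simulateMetadata(cfg)
#' pools <- buildControlPools(meta, c("region", "siblings"))
#' lengths(pools)
#' @export
buildControlPools <- function(meta, covariates = c("region", "siblings")) {
    stopifnot(all(c("subject_id", "status") %in% names(meta)))
    missing_cov <- setdiff(covariates, names(meta))
    if (length(missing_cov))
        stop("covariate(s) not in metadata: ",
             paste(missing_cov, collapse = ", "))
    cases <- meta[meta$status == "case", , drop = FALSE]
    ctrls <- meta[meta$status == "control", , drop = FALSE]
    if (nrow(cases) == 0) stop("metadata contains no cases")
    pools <- lapply(seq_len(nrow(cases)), function(i) {
        ok <- rep(TRUE, nrow(ctrls))
        for (cv in covariates) {
            v <- cases[[cv]][i]
            if (is.na(v)) next  # covariate relaxed for this case
            ok <- ok & !is.na(ctrls[[cv]]) & ctrls[[cv]] == v
        }
        ctrls$subject_id[ok]
    })
    names(pools) <- cases$subject_id
    empty <- names(pools)[lengths(pools) == 0]
    if (length(empty))
        stop("no eligible controls for case(s): ",
             paste(empty, collapse = ", "))
    attr(pools, "covariates") <- covariates
    pools
}

#' Draw one seeded matched case-control design
#'
#' Cases are processed from scarcest pool to largest (ties broken by case
#' id) and \code{ratio} controls are drawn uniformly without replacement
#' from each case's remaining eligible pool.  By default a control serves
#' at most one case within an iteration; set \code{allow_reuse = TRUE} to
#' lift that restriction.  Deterministic given \code{seed}.
#'
#' @param pools output of \code{\link{buildControlPools}}.
#' @param ratio controls per case.
#' @param seed integer RNG seed for this draw.
#' @param iteration iteration index stored in the design.
#' @param allow_reuse may one control match several cases in the same
#'   iteration?
#' @return A \linkS4class{MatchedDesign}.
#' @export
drawDesign <- function(pools, ratio = 2, seed = 1L, iteration = 1L,
                       allow_reuse = FALSE) {
    stopifnot(ratio >= 0)
    set.seed(seed)
    ord <- order(lengths(pools), names(pools))
    used <- character()
    rows <- vector("list", length(pools))
    for (i in ord) {
        avail <- if (allow_reuse) pools[[i]] else setdiff(pools[[i]], used)
        if (length(avail) < ratio)
            stop("pool exhausted for case ", names(pools)[i],
                 " (", length(avail), " controls left, ", ratio,
                 " needed); reduce ratio, relax covariates, or set ",
                 "allow_reuse = TRUE")
        picked <- if (ratio == 0) character() else
            sample(avail, ratio, replace = FALSE)
        used <- c(used, picked)
        rows[[i]] <- data.frame(case_id = rep(names(pools)[i],
                                              length(picked)),
                                control_id = picked,
                                stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, rows)
    if (is.null(pairs))
        pairs <- data.frame(case_id = character(),
                            control_id = character())
    rownames(pairs) <- NULL
    new("MatchedDesign", iteration = as.integer(iteration),
        seed = as.integer(seed), pairs = pairs,
        covariates = as.character(attr(pools, "covariates") %||% character()),
        ratio = as.integer(ratio))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a series of independently seeded matched designs
#'
#' Iteration \eqn{i} (starting at 1) is drawn with seed
#' \code{base_seed + i - 1}; controls may recur across iterations since
#' iterations are independent draws.
#'
#' @inheritParams drawDesign
#' @param n_iterations number of designs (100 in the reference protocol).
#' @param base_seed seed of the first iteration.
#' @return List of \linkS4class{MatchedDesign}.
#' @examples
#' cfg <- simConfig(n_subjects = 400, seed = 4)
#' pools <- buildControlPools(simulateMetadata(cfg))
#' designs <- iterateDesigns(pools, ratio = 2, n_iterations = 5,
#'                           base_seed = 42)
#' @export
iterateDesigns <- function(pools, ratio = 2, n_iterations = 100,
                           base_seed = 42L, allow_reuse = FALSE) {
    lapply(seq_len(n_iterations), function(i) {
        drawDesign(pools, ratio = ratio, seed = base_seed + i - 1L,
                   iteration = i, allow_reuse = allow_reuse)
    })
}

#' Subset a cohort to one matched design
#'
#' Returns the cohort restricted to the design's cases and controls, in
#' case-then-control order.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param design a \linkS4class{MatchedDesign}.
#' @return A \linkS4class{MicrobiomeCohort}.
#' @export
subsetDesign <- function(x, design) {
    ids <- c(designCases(design), designControls(design))
    missing <- setdiff(ids, colnames(x))
    if (length(missing))
        stop("design subject(s) absent from cohort: ",
             paste(utils::head(missing, 5), collapse = ", "))
    x[, ids]
}
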