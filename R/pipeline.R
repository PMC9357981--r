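.config_defaults <- function() {
    list(min_reads = 1000, min_samples = 5, min_count = 5,
         n_iterations = 100, ratio = 2, threshold = 60, top_k = 30,
         cut = 50, alpha = 0.05, n_perm = 999, n_sim = 2000, trees = 500,
         seed = 42, covariates = c("region", "siblings"),
         modes = c("relative", "total"), allow_reuse = FALSE)
}

.config_ranges <- list(
    min_reads = c(0, Inf), min_samples = c(0, Inf), min_count = c(0, Inf),
    n_iterations = c(1, Inf), ratio = c(0, Inf), threshold = c(0, 100),
    top_k = c(1, Inf), cut = c(0, Inf), alpha = c(0, 1),
    n_perm = c(1, Inf), n_sim = c(1, Inf), trees = c(1, Inf))

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or starts from nothing), fills unset keys with the
#' reference protocol defaults (1000-read sample floor; taxa kept at
#' five or more reads in at least five samples; 100 matching iterations
#' at a 1:2 case:control ratio; 60 percent prevalence threshold; top 30
#' taxa by MDA; consensus at 50 iterations; alpha 0.05; 999 PERMANOVA
#' permutations; 2000 Monte-Carlo tables; 500 trees) and validates every
#' numeric against its documented range.  Unknown keys are rejected.
#'
#' @param path optional path to a YAML config file.
#' @param overrides named list applied on top of the file values.
#' @return validated named list of class \code{"PipelineConfig"}.
#' @examples
#' cfg <- loadPipelineConfig()
#' cfg$threshold
#' @export
loadPipelineConfig <- function(path = NULL, overrides = list()) {
    cfg <- .config_defaults()
    user <- list()
    if (!is.null(path)) {
        user <- yaml::read_yaml(path)
        if (is.null(user)) user <- list()
    }
    user[names(overrides)] <- overrides
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
    for (key in names(.config_ranges)) {
        r <- .config_ranges[[key]]
        v <- cfg[[key]]
        if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
            v < r[1] || v > r[2])
            stop("configuration key '", key, "' must be a number in [",
                 r[1], ", ", r[2], "]")
    }
    if (cfg$cut > cfg$n_iterations)
        stop("configuration key 'cut' must not exceed 'n_iterations'")
    if (!all(cfg$modes %in% c("relative", "total", "counts")))
        stop("configuration key 'modes' must be a subset of ",
             "relative/total/counts")
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Write a configuration back to YAML
#'
#' @param cfg a \code{\link{loadPipelineConfig}} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePipelineConfig <- function(cfg, path) {
    yaml::write_yaml(unclass(cfg), path)
    invisible(path)
}

#' Run the full iterative matched case-control consensus pipeline
#'
#' Filters the cohort (sample read floor, then rare-taxon filter, then
#' genus agglomeration when the input is at ASV rank), builds matched
#' control pools on the configured covariates, draws the seeded matching
#' iterations, runs the prevalence/core branch and the
#' differential-abundance branch on every iteration in each configured
#' abundance mode, and aggregates the consensus report.
#'
#' @param x a \linkS4class{MicrobiomeCohort} with \code{status} and the
#'   matching covariates in \code{colData()}.
#' @param config a \code{\link{loadPipelineConfig}} list.
#' @param outdir optional directory; when given, the consensus report,
#'   per-case pool sizes and design pairs are written as TSV.
#' @param verbose log stage timings to \code{stderr}.
#' @return named list: \code{cohort} (filtered), \code{pools},
#'   \code{designs}, \code{core}, \code{diffabund} (per-mode lists),
#'   \code{consensus}, \code{config}.
#' @examples
#' cfg <- loadPipelineConfig(overrides = list(
#'     n_iterations = 4, cut = 2, trees = 50, min_samples = 2))
#' coh <- simulateCohort(simConfig(n_subjects = 150, n_taxa = 30,
#'                                 case_rate = 0.05, seed = 8))
#' res <- runPipeline(coh, cfg)
#' head(res$consensus)
#' @export
runPipeline <- function(x, config = loadPipelineConfig(), outdir = NULL,
                        verbose = FALSE) {
    say <- function(...) if (verbose)
        message(format(Sys.time(), "%H:%M:%S"), " [micomatch] ", ...)
    say("filtering: ", ncol(x), " samples, ", nrow(x), " taxa")
    x <- filterSamples(x, config$min_reads)
    x <- filterTaxa(x, config$min_samples, config$min_count)
    if (taxonRank(x) == "asv") x <- agglomerateTaxa(x)
    say("retained ", ncol(x), " samples, ", nrow(x), " taxa")

    meta <- as.data.frame(colData(x))
    if (is.null(meta$subject_id)) meta$subject_id <- colnames(x)
    pools <- buildControlPools(meta, config$covariates)
    designs <- iterateDesigns(pools, ratio = config$ratio,
                              n_iterations = config$n_iterations,
                              base_seed = as.integer(config$seed),
                              allow_reuse = config$allow_reuse)
    say(length(designs), " matched designs drawn")

    core <- list(); diffab <- list()
    for (mode in config$modes) {
        say("core branch, ", mode, " abundance")
        core[[mode]] <- runCoreBranch(x, designs, mode = mode,
                                      threshold = config$threshold,
                                      top_k = config$top_k,
                                      ntree = config$trees)
        say("differential-abundance branch, ", mode, " abundance")
        diffab[[mode]] <- runDiffAbundBranch(x, designs, mode = mode)
    }
    consensus <- aggregateConsensus(
        list(core = core, diffabund = diffab),
        n_iterations = config$n_iterations,
        cut = config$cut, alpha = config$alpha)
    say("consensus: ", sum(consensus$consensus), " taxon/branch/mode hits")

    if (!is.null(outdir)) {
        if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
        utils::write.table(consensus, file.path(outdir, "consensus.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
            data.frame(case_id = names(pools), pool_size = lengths(pools)),
            file.path(outdir, "pools.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        allpairs <- do.call(rbind, lapply(designs, function(d)
            cbind(iteration = d@iteration, designPairs(d))))
        utils::write.table(allpairs, file.path(outdir, "designs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(cohort = x, pools = pools, designs = designs, core = core,
         diffabund = diffab, consensus = consensus, config = config)
}
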