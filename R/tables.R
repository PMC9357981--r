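#' Remove samples with too few reads
#'
#' Drops every sample whose total read count is below \code{min_reads}
#' (default 1000), preserving the order of the survivors.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param min_reads minimum column sum to retain a sample.
#' @return The filtered cohort.
#' @examples
#' coh <- simulateCohort(simConfig(n_subjects = 100, seed = 2))
#' filterSamples(coh, min_reads = 1000)
#' @export
filterSamples <- function(x, min_reads = 1000) {
    keep <- colSums(counts(x)) >= min_reads
    if (!any(keep))
        stop("no sample has at least ", min_reads, " reads")
    x[, keep]
}

#' Remove rare taxa
#'
#' Retains taxa observed at \code{min_count} or more reads in at least
#' \code{min_samples} samples (default: five or more reads in at least
#' five samples).
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param min_samples minimum number of samples meeting \code{min_count}.
#' @param min_count minimum per-sample read count.
#' @return The filtered cohort (warns if no taxon survives).
#' @export
filterTaxa <- function(x, min_samples = 5, min_count = 5) {
    keep <- rowSums(counts(x) >= min_count) >= min_samples
    if (!any(keep))
        warning("no taxon present in at least ", min_samples,
                " samples at ", min_count, " or more reads")
    x[keep, ]
}

#' Agglomerate ASV counts to genus level
#'
#' Sums counts of all members of each genus.  Taxa without a genus
#' assignment are binned into a pseudo-genus named after their own
#' highest resolved label, so no reads are discarded.  The grand total
#' of the table is conserved exactly.
#'
#' @param x a \linkS4class{MicrobiomeCohort} at ASV rank.
#' @param taxonomy named character vector mapping taxon labels to genus;
#'   defaults to \code{rowData(x)$genus}.
#' @return A genus-rank \linkS4class{MicrobiomeCohort}.
#' @export
agglomerateTaxa <- function(x, taxonomy = NULL) {
    if (is.null(taxonomy)) {
        if (is.null(rowData(x)$genus))
            stop("no taxonomy: supply 'taxonomy' or set rowData(x)$genus")
        taxonomy <- stats::setNames(rowData(x)$genus, rownames(x))
    }
    if (length(taxonomy) == 0)
        stop("empty taxonomy map")
    genus <- taxonomy[rownames(x)]
    unmapped <- is.na(genus) | genus == ""
    genus[unmapped] <- rownames(x)[unmapped]
    agg <- rowsum(counts(x), group = genus, reorder = TRUE)
    meta_cols <- colData(x)
    out <- MicrobiomeCohort(agg,
        metadata = as.data.frame(meta_cols), rank = "genus")
    metadata(out) <- metadata(x)
    out
}

#' Relative and total abundance transforms
#'
#' \code{relativeAbundance()} divides each sample (column) by its total so
#' columns sum to one; all-zero columns stay zero with a warning.
#' \code{totalAbundance()} scales relative abundances by the sample's
#' qPCR-measured total 16S rRNA copies per gram of stool, yielding
#' absolute abundances in copies per gram; each column then sums to that
#' sample's load.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param loads named positive numeric vector of 16S copies per gram;
#'   defaults to \code{qpcrLoads(x)}.
#' @return A numeric matrix (taxa x samples) with attribute
#'   \code{abundance_mode} set to \code{"relative"} or \code{"total"}.
#' @examples
#' coh <- simulateCohort(simConfig(n_subjects = 50, seed = 5))
#' rel <- relativeAbundance(coh)
#' stopifnot(all(abs(colSums(rel) - 1) < 1e-9))
#' @export
relativeAbundance <- function(x) {
    m <- counts(x)
    tot <- colSums(m)
    if (any(tot == 0))
        warning("all-zero sample(s) left at zero relative abundance: ",
                paste(colnames(m)[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
    rel <- sweep(m, 2, tot, "/")
    attr(rel, "abundance_mode") <- "relative"
    rel
}

#' @rdname relativeAbundance
#' @export
totalAbundance <- function(x, loads = qpcrLoads(x)) {
    if (is.null(loads))
        stop("no qPCR loads available; supply 'loads'")
    rel <- relativeAbundance(x)
    missing <- colnames(rel)[!colnames(rel) %in% names(loads) |
                             is.na(loads[colnames(rel)])]
    if (length(missing))
        stop("qPCR load missing for sample(s): ",
             paste(missing, collapse = ", "))
    l <- loads[colnames(rel)]
    if (any(l <= 0))
        stop("qPCR loads must be strictly positive")
    tot <- sweep(rel, 2, l, "*")
    attr(tot, "abundance_mode") <- "total"
    tot
}

#' Abundance matrix in a chosen mode
#'
#' Dispatch helper used by the per-iteration branches: returns raw counts,
#' relative abundances, or qPCR-scaled total abundances.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param mode one of \code{"counts"}, \code{"relative"}, \code{"total"}.
#' @return numeric matrix, taxa x samples.
#' @export
abundanceMatrix <- function(x, mode = c("relative", "total", "counts")) {
    mode <- match.arg(mode)
    switch(mode,
           counts = counts(x),
           relative = relativeAbundance(x),
           total = totalAbundance(x))
}

#' Read and write cohort tables as TSV
#'
#' \code{writeCohort()} writes \code{counts.tsv} (taxa rows, sample
#' columns), \code{metadata.tsv}, and, when present, \code{qpcr.tsv} and
#' \code{truth.tsv} into \code{dir}.  \code{readCohort()} rebuilds a
#' \linkS4class{MicrobiomeCohort} from such files.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param dir directory for the TSV files (created if needed).
#' @return \code{writeCohort()} returns \code{dir} invisibly;
#'   \code{readCohort()} returns a \linkS4class{MicrobiomeCohort}.
#' @export
writeCohort <- function(x, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    cnt <- data.frame(taxon = rownames(x), counts(x), check.names = FALSE)
    utils::write.table(cnt, file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(colData(x)),
                       file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    q <- qpcrLoads(x)
    if (!is.null(q))
        utils::write.table(data.frame(subject_id = names(q), qpcr_load = q),
                           file.path(dir, "qpcr.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    gt <- groundTruth(x)
    if (!is.null(gt))
        utils::write.table(gt, file.path(dir, "truth.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' @rdname writeCohort
#' @param counts_file,metadata_file,qpcr_file paths to the TSV files
#'   (qPCR optional).
#' @param rank taxonomic rank tag of the rows.
#' @export
readCohort <- function(counts_file, metadata_file, qpcr_file = NULL,
                       rank = c("genus", "asv")) {
    rank <- match.arg(rank)
    cnt <- utils::read.delim(counts_file, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(cnt[, -1, drop = FALSE])
    rownames(m) <- cnt[[1]]
    meta <- utils::read.delim(metadata_file, stringsAsFactors = FALSE)
    qpcr <- NULL
    if (!is.null(qpcr_file)) {
        qt <- utils::read.delim(qpcr_file, stringsAsFactors = FALSE)
        qpcr <- stats::setNames(qt[[2]], qt[[1]])
    }
    MicrobiomeCohort(m, metadata = meta, qpcr = qpcr, rank = rank)
}
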