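#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   colData colData<- rowData rowData<-
#' @importFrom BiocGenerics counts
NULL

#' MicrobiomeCohort: counts plus per-subject metadata for one cohort
#'
#' The central container of the package: a taxa-by-samples integer count
#' matrix (amplicon sequence variants or genera) together with per-subject
#' metadata (case/control status, matching covariates, HLA genotype,
#' environmental covariates) and, optionally, per-sample total 16S rRNA
#' copies per gram of stool from qPCR.  It extends
#' \linkS4class{SummarizedExperiment}: counts live in the \code{"counts"}
#' assay, subject metadata in \code{colData()}, taxonomy in \code{rowData()}.
#'
#' @slot rank character scalar, the taxonomic rank of the rows
#'   (\code{"asv"} or \code{"genus"}).
#'
#' @seealso \code{\link{simulateCohort}}, \code{\link{filterSamples}},
#'   \code{\link{agglomerateTaxa}}
#' @export
setClass("MicrobiomeCohort",
    contains = "SummarizedExperiment",
    slots = c(rank = "character"),
    prototype = prototype(rank = "genus"))

setValidity("MicrobiomeCohort", function(object) {
    msg <- NULL
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(abs(m - round(m)) > 1e-8))
            msg <- c(msg, "counts must be integer-valued")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "taxon labels must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (length(object@rank) != 1L || !object@rank %in% c("asv", "genus"))
        msg <- c(msg, "rank must be 'asv' or 'genus'")
    if ("qpcr_load" %in% colnames(colData(object))) {
        q <- object$qpcr_load
        if (any(!is.na(q) & q <= 0))
            msg <- c(msg, "qpcr_load must be strictly positive")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a MicrobiomeCohort
#'
#' @param counts numeric matrix, taxa in rows and samples in columns, with
#'   unique dimnames; entries must be non-negative integers.
#' @param metadata \code{data.frame} or \code{DataFrame} of per-subject
#'   metadata, one row per sample (matched to columns of \code{counts} by
#'   rownames or a \code{subject_id} column).  Typically contains
#'   \code{status} (\code{"case"}/\code{"control"}) and matching covariates.
#' @param qpcr optional named numeric vector of total 16S rRNA copies per
#'   gram of stool; stored as \code{colData()$qpcr_load}.
#' @param taxonomy optional named character vector mapping taxon labels to
#'   genus; stored as \code{rowData()$genus}.
#' @param rank taxonomic rank of the rows, \code{"asv"} or \code{"genus"}.
#'
#' @return A \linkS4class{MicrobiomeCohort}.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'     dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' MicrobiomeCohort(m, rank = "genus")
#' @export
MicrobiomeCohort <- function(counts, metadata = NULL, qpcr = NULL,
                             taxonomy = NULL, rank = c("genus", "asv")) {
    rank <- match.arg(rank)
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' must have taxon rownames and sample colnames")
    storage.mode(counts) <- "double"
    if (is.null(metadata)) {
        cd <- DataFrame(row.names = colnames(counts))
    } else {
        cd <- as(metadata, "DataFrame")
        if (!is.null(cd$subject_id) &&
            (is.null(rownames(cd)) || all(rownames(cd) == seq_len(nrow(cd)))))
            rownames(cd) <- cd$subject_id
        if (!setequal(rownames(cd), colnames(counts)))
            stop("metadata rows do not match count columns")
        cd <- cd[colnames(counts), , drop = FALSE]
    }
    if (!is.null(qpcr)) {
        missing <- setdiff(colnames(counts), names(qpcr))
        if (length(missing))
            stop("qPCR load missing for sample(s): ",
                 paste(missing, collapse = ", "))
        cd$qpcr_load <- unname(qpcr[colnames(counts)])
    }
    rd <- DataFrame(row.names = rownames(counts))
    if (!is.null(taxonomy))
        rd$genus <- unname(taxonomy[rownames(counts)])
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = cd, rowData = rd)
    new("MicrobiomeCohort", se, rank = rank)
}

#' @describeIn MicrobiomeCohort the count matrix (taxa x samples).
#' @param object a \code{MicrobiomeCohort}.
#' @export
setMethod("counts", "MicrobiomeCohort", function(object) {
    assay(object, "counts")
})

#' Accessors for MicrobiomeCohort components
#'
#' \code{qpcrLoads()} returns the per-sample 16S copies per gram of stool
#' (or \code{NULL}); \code{sampleStatus()} the case/control factor;
#' \code{taxonRank()} the rank tag of the rows.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @return see individual descriptions.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
qpcrLoads <- function(x) {
    if (!"qpcr_load" %in% colnames(colData(x))) return(NULL)
    stats::setNames(x$qpcr_load, colnames(x))
}

#' @rdname cohort-accessors
#' @export
sampleStatus <- function(x) {
    if (is.null(x$status)) stop("cohort has no 'status' column")
    factor(as.character(x$status), levels = c("control", "case"))
}

#' @rdname cohort-accessors
#' @export
taxonRank <- function(x) x@rank

#' @rdname cohort-accessors
#' @export
groundTruth <- function(x) metadata(x)$ground_truth

setMethod("show", "MicrobiomeCohort", function(object) {
    cat("MicrobiomeCohort (", object@rank, " level): ",
        nrow(object), " taxa x ", ncol(object), " samples\n", sep = "")
    if (!is.null(object$status)) {
        st <- table(factor(object$status, levels = c("case", "control")))
        cat("  status: ", st[["case"]], " cases, ",
            st[["control"]], " controls\n", sep = "")
    }
    if ("qpcr_load" %in% colnames(colData(object)))
        cat("  qPCR 16S loads available\n")
    if (!is.null(metadata(object)$ground_truth))
        cat("  synthetic cohort with ground-truth record\n")
    cat("  colData: ", paste(utils::head(colnames(colData(object)), 8),
                             collapse = ", "), "\n", sep = "")
})

#' MatchedDesign: one seeded matched case-control draw
#'
#' One iteration of the matching algorithm: for every case, \code{ratio}
#' controls drawn uniformly without replacement from that case's eligible
#' pool (controls sharing every non-missing matching covariate value with
#' the case).  The seed that produced the draw is stored so any iteration
#' can be replayed exactly.
#'
#' @slot iteration integer iteration index.
#' @slot seed integer RNG seed used for the draw.
#' @slot pairs \code{data.frame} with columns \code{case_id},
#'   \code{control_id}; each case appears exactly \code{ratio} times.
#' @slot covariates character, the matching covariates used.
#' @slot ratio integer, controls per case.
#'
#' @seealso \code{\link{drawDesign}}, \code{\link{iterateDesigns}}
#' @export
setClass("MatchedDesign",
    slots = c(iteration = "integer", seed = "integer",
              pairs = "data.frame", covariates = "character",
              ratio = "integer"))

setValidity("MatchedDesign", function(object) {
    msg <- NULL
    p <- object@pairs
    if (!all(c("case_id", "control_id") %in% names(p)))
        msg <- c(msg, "pairs needs case_id and control_id columns")
    else {
        per <- table(p$case_id)
        if (length(per) && object@ratio > 0 && any(per != object@ratio))
            msg <- c(msg, "every case must have exactly 'ratio' controls")
        if (anyDuplicated(p$control_id))
            msg <- c(msg, "a control may not be reused within one iteration")
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn MatchedDesign case ids in the design.
#' @param x a \code{MatchedDesign}.
#' @export
designCases <- function(x) unique(x@pairs$case_id)

#' @describeIn MatchedDesign control ids in the design.
#' @export
designControls <- function(x) unique(x@pairs$control_id)

#' @describeIn MatchedDesign the (case_id, control_id) pair table.
#' @export
designPairs <- function(x) x@pairs

#' @describeIn MatchedDesign seed used for the draw.
#' @export
designSeed <- function(x) x@seed

setMethod("show", "MatchedDesign", function(object) {
    cat("MatchedDesign iteration ", object@iteration,
        " (seed ", object@seed, "): ",
        length(designCases(object)), " cases x ", object@ratio,
        " matched controls on {",
        paste(object@covariates, collapse = ", "), "}\n", sep = "")
})
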