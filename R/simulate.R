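#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator with defaults that emulate a
#' general-population infant stool 16S cohort of roughly 1478 subjects,
#' about 1.8\% of whom are future cases, with four geographic regions,
#' a binary siblings-at-birth covariate with occasional missing values,
#' negative-binomially distributed genus counts under heterogeneous
#' library sizes, and log-normal per-sample total 16S qPCR loads.
#'
#' @param n_subjects number of subjects.
#' @param case_rate Bernoulli probability that a subject is a future case.
#' @param n_taxa number of genera simulated.
#' @param n_lfc_taxa number of taxa carrying a planted log2 fold change
#'   between cases and controls.
#' @param n_prev_taxa number of taxa carrying a planted prevalence
#'   difference between cases and controls.
#' @param region_probs named probability vector over geographic regions
#'   (must sum to 1).
#' @param sibling_prob probability of siblings at birth.
#' @param sibling_missing_prob probability the siblings value is missing.
#' @param hla_missing_prob probability the HLA genotype is missing.
#' @param female_prob probability a subject is female.
#' @param nb_dispersion negative-binomial dispersion alpha (variance =
#'   mu + alpha * mu^2).
#' @param taxon_logmean,taxon_logsd log-normal parameters of baseline
#'   per-taxon mean counts.
#' @param library_size_logmean,library_size_logsd log-normal parameters of
#'   the per-sample library-size factor.
#' @param qpcr_logmean,qpcr_logsd log-normal parameters of the 16S copies
#'   per gram of stool.
#' @param prevalence_shape1,prevalence_shape2 optional Beta parameters of
#'   a per-taxon presence probability applied to background taxa.  Off
#'   (\code{NA}) by default, which gives the plain negative-binomial
#'   model; set (e.g. to 0.7 and 1.3) to emulate the sparsity of real
#'   infant genus tables, where most genera fall below a 60-percent
#'   prevalence core.  See the vignette for what each regime exercises.
#' @param effect_lfc_magnitude absolute planted log2 fold change.
#' @param prevalence_delta planted prevalence difference (enriched minus
#'   deficient group) for prevalence-effect taxa.
#' @param base_prevalence presence probability in the enriched group for
#'   prevalence-effect taxa.
#' @param diag_age_mean,diag_age_sd mean/SD of the age of diagnosis (years)
#'   drawn for cases, truncated to [2, 20] and rounded to whole years.
#' @param seed integer RNG seed.
#'
#' @return A named list of class \code{"SimConfig"}.
#' @examples
#' cfg <- simConfig(n_subjects = 200, seed = 1)
#' @export
simConfig <- function(n_subjects = 1478, case_rate = 0.0176,
                      n_taxa = 150, n_lfc_taxa = 0, n_prev_taxa = 0,
                      region_probs = c(North = 0.29, East = 0.18,
                                       South = 0.26, West = 0.27),
                      sibling_prob = 0.6, sibling_missing_prob = 0.015,
                      hla_missing_prob = 0.05, female_prob = 0.49,
                      nb_dispersion = 0.5,
                      taxon_logmean = log(20), taxon_logsd = 1.3,
                      library_size_logmean = 0, library_size_logsd = 0.5,
                      qpcr_logmean = log(1e10), qpcr_logsd = 1,
                      prevalence_shape1 = NA, prevalence_shape2 = NA,
                      effect_lfc_magnitude = 2, prevalence_delta = 0.4,
                      base_prevalence = 0.9,
                      diag_age_mean = 11, diag_age_sd = 5.6,
                      seed = 1L) {
    cfg <- list(n_subjects = n_subjects, case_rate = case_rate,
                n_taxa = n_taxa, n_lfc_taxa = n_lfc_taxa,
                n_prev_taxa = n_prev_taxa, region_probs = region_probs,
                sibling_prob = sibling_prob,
                sibling_missing_prob = sibling_missing_prob,
                hla_missing_prob = hla_missing_prob,
                female_prob = female_prob,
                nb_dispersion = nb_dispersion,
                taxon_logmean = taxon_logmean, taxon_logsd = taxon_logsd,
                library_size_logmean = library_size_logmean,
                library_size_logsd = library_size_logsd,
                qpcr_logmean = qpcr_logmean, qpcr_logsd = qpcr_logsd,
                prevalence_shape1 = prevalence_shape1,
                prevalence_shape2 = prevalence_shape2,
                effect_lfc_magnitude = effect_lfc_magnitude,
                prevalence_delta = prevalence_delta,
                base_prevalence = base_prevalence,
                diag_age_mean = diag_age_mean, diag_age_sd = diag_age_sd,
                seed = as.integer(seed))
    stopifnot(n_subjects >= 2, n_taxa >= 1,
              case_rate >= 0, case_rate <= 1,
              n_lfc_taxa + n_prev_taxa <= n_taxa,
              sibling_prob >= 0, sibling_prob <= 1,
              sibling_missing_prob >= 0, sibling_missing_prob <= 1,
              nb_dispersion > 0,
              is.na(prevalence_shape1) || prevalence_shape1 > 0,
              is.na(prevalence_shape2) || prevalence_shape2 > 0,
              prevalence_delta >= 0, prevalence_delta <= 1,
              base_prevalence >= 0, base_prevalence <= 1,
              prevalence_delta <= base_prevalence,
              all(region_probs >= 0),
              abs(sum(region_probs) - 1) < 1e-8)
    class(cfg) <- "SimConfig"
    cfg
}

# compound HLA-DR-DQ genotypes sampled for synthetic subjects; weights chosen
# so roughly a fifth of subjects carry the DR3-DQ2.5 risk haplotype
.hla_pool <- c(
    "DR3-DQ2.5/DR4-DQ8"    = 0.06,
    "DR3-DQ2.5/DR3-DQ2.5"  = 0.03,
    "DR3-DQ2.5/DR15-DQ602" = 0.07,
    "DR3-DQ2.5/DR7-DQ2.2"  = 0.05,
    "DR4-DQ8/DR7-DQ2.2"    = 0.07,
    "DR4-DQ8/DR4-DQ8"      = 0.03,
    "DR4-DQ8/DR15-DQ602"   = 0.07,
    "DR5-DQ7/DR7-DQ2.5"    = 0.03,
    "DR1-DQ5/DR15-DQ602"   = 0.10,
    "DR3-DQ2"              = 0.04,
    "DR13-DQ603/DR14-DQ503" = 0.10,
    "DQX/DQX"              = 0.35)

#' Generate synthetic per-subject cohort metadata
#'
#' Draws case/control status, geographic region, siblings at birth (with
#' occasional missing values), sex, a compound HLA-DR-DQ genotype string,
#' diet covariates and, for cases, an age of diagnosis.  Covariates are
#' drawn independently of each other and of the count model, so the
#' cohort carries no confounding unless planted downstream.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @return \code{data.frame} with one row per subject: \code{subject_id},
#'   \code{status}, \code{region}, \code{siblings}, \code{sex}, \code{hla},
#'   \code{mode_of_delivery}, \code{total_breastfeeding},
#'   \code{gluten_introduction}, \code{age_of_diagnosis}.
#' @examples
#' meta <- simulateMetadata(simConfig(n_subjects = 300, seed = 7))
#' table(meta$status)
#' @export
simulateMetadata <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    n <- cfg$n_subjects
    status <- ifelse(stats::rbinom(n, 1L, cfg$case_rate) == 1L,
                     "case", "control")
    if (!any(status == "case"))
        stop("no cases drawn; raise case_rate or n_subjects")
    region <- sample(names(cfg$region_probs), n, replace = TRUE,
                     prob = cfg$region_probs)
    siblings <- ifelse(stats::runif(n) < cfg$sibling_prob, "Yes", "No")
    siblings[stats::runif(n) < cfg$sibling_missing_prob] <- NA
    sex <- ifelse(stats::runif(n) < cfg$female_prob, "Female", "Male")
    hla <- sample(names(.hla_pool), n, replace = TRUE, prob = .hla_pool)
    hla[stats::runif(n) < cfg$hla_missing_prob] <- NA
    mode_of_delivery <- sample(c("Vaginal", "Cesarean"), n, replace = TRUE,
                               prob = c(0.88, 0.12))
    total_breastfeeding <- sample(c("1 to 3", "4 to 7", "8 to 9"), n,
                                  replace = TRUE, prob = c(0.25, 0.3, 0.45))
    gluten_introduction <- sample(c("4 to 7", "8 to 9"), n,
                                  replace = TRUE, prob = c(0.75, 0.25))
    age <- rep(NA_real_, n)
    ncase <- sum(status == "case")
    age[status == "case"] <- pmin(pmax(round(
        stats::rnorm(ncase, cfg$diag_age_mean, cfg$diag_age_sd)), 2), 20)
    data.frame(subject_id = sprintf("S%04d", seq_len(n)),
               status = status, region = region, siblings = siblings,
               sex = sex, hla = hla, mode_of_delivery = mode_of_delivery,
               total_breastfeeding = total_breastfeeding,
               gluten_introduction = gluten_introduction,
               age_of_diagnosis = age,
               stringsAsFactors = FALSE)
}

#' Simulate genus counts, qPCR loads and ground truth for a cohort
#'
#' Counts are zero-inflated negative binomial: taxon \eqn{i} in sample
#' \eqn{j} has NB mean \eqn{s_j q_i 2^{b_i I[j\ \mathrm{case}]}} with
#' dispersion \code{nb_dispersion}, where \eqn{s_j} are log-normal
#' library-size factors, \eqn{q_i} log-normal baseline means, and
#' \eqn{b_i} the planted log2 fold change (zero except for the
#' \code{n_lfc_taxa} effect taxa); each taxon is then thinned by an
#' independent Bernoulli presence mask.  The per-taxon presence
#' probability \eqn{\pi_i} is Beta-distributed (so most taxa are rare,
#' as in real infant genus tables), except that LFC-effect taxa keep
#' \eqn{\pi = 1} (a pure abundance effect) and prevalence-effect taxa
#' use group-specific probabilities: \code{base_prevalence} in the
#' enriched group, \code{base_prevalence - prevalence_delta} in the
#' deficient group, with boosted baseline means so presence before
#' thinning is near-certain.  qPCR loads are log-normal and independent
#' of counts.
#'
#' @param meta metadata from \code{\link{simulateMetadata}}.
#' @param cfg the same \code{\link{simConfig}} used for the metadata.
#' @return A \linkS4class{MicrobiomeCohort} at genus rank; the ground-truth
#'   table (one row per taxon: \code{planted_effect}, \code{true_lfc},
#'   \code{true_prevalence_case}, \code{true_prevalence_control},
#'   \code{enriched_group}) and true library-size factors are stored in
#'   \code{metadata()}.
#' @examples
#' cfg <- simConfig(n_subjects = 120, n_lfc_taxa = 5, seed = 3)
#' coh <- simulateCounts(simulateMetadata(cfg), cfg)
#' @export
simulateCounts <- function(meta, cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (anyDuplicated(meta$subject_id))
        stop("duplicated subject ids in metadata")
    set.seed(cfg$seed + 1L)
    n <- nrow(meta)
    p <- cfg$n_taxa
    taxa <- sprintf("Genus%03d", seq_len(p))
    is_case <- meta$status == "case"

    planted <- sample(taxa, cfg$n_lfc_taxa + cfg$n_prev_taxa)
    lfc_taxa <- planted[seq_len(cfg$n_lfc_taxa)]
    prev_taxa <- setdiff(planted, lfc_taxa)

    q <- stats::rlnorm(p, cfg$taxon_logmean, cfg$taxon_logsd)
    names(q) <- taxa
    # effect taxa get a floor on the baseline mean so the planted signal is
    # identifiable at matched-subset sample sizes
    q[lfc_taxa] <- pmax(q[lfc_taxa], 20)
    q[prev_taxa] <- pmax(q[prev_taxa], 50)
    s <- stats::rlnorm(n, cfg$library_size_logmean, cfg$library_size_logsd)
    names(s) <- meta$subject_id

    # alternate the enriched group across effect taxa
    lfc_sign <- rep(c(1, -1), length.out = length(lfc_taxa))
    b <- stats::setNames(rep(0, p), taxa)
    b[lfc_taxa] <- lfc_sign * cfg$effect_lfc_magnitude

    mu <- q %o% s
    mu[, is_case] <- mu[, is_case] * 2^b

    counts <- matrix(stats::rnbinom(p * n, mu = mu,
                                    size = 1 / cfg$nb_dispersion),
                     nrow = p, dimnames = list(taxa, meta$subject_id))

    # optional sparsity: Beta-distributed presence probability per
    # background taxon (effect taxa are never masked here)
    if (!is.na(cfg$prevalence_shape1) && !is.na(cfg$prevalence_shape2)) {
        pi_taxon <- stats::rbeta(p, cfg$prevalence_shape1,
                                 cfg$prevalence_shape2)
        names(pi_taxon) <- taxa
        bg <- setdiff(taxa, c(lfc_taxa, prev_taxa))
        for (tx in bg)
            if (pi_taxon[tx] < 1)
                counts[tx, ] <- counts[tx, ] * stats::rbinom(n, 1L,
                                                             pi_taxon[tx])
    }

    prev_enriched <- rep(c("control", "case"), length.out = length(prev_taxa))
    prev_case <- prev_ctrl <- stats::setNames(rep(NA_real_, p), taxa)
    for (k in seq_along(prev_taxa)) {
        tx <- prev_taxa[k]
        hi <- cfg$base_prevalence
        lo <- cfg$base_prevalence - cfg$prevalence_delta
        pc <- if (prev_enriched[k] == "case") hi else lo
        p0 <- if (prev_enriched[k] == "case") lo else hi
        keep_prob <- ifelse(is_case, pc, p0)
        counts[tx, ] <- counts[tx, ] * stats::rbinom(n, 1L, keep_prob)
        prev_case[tx] <- pc
        prev_ctrl[tx] <- p0
    }

    qpcr <- stats::rlnorm(n, cfg$qpcr_logmean, cfg$qpcr_logsd)
    names(qpcr) <- meta$subject_id

    effect <- rep("none", p)
    names(effect) <- taxa
    effect[lfc_taxa] <- "lfc"
    effect[prev_taxa] <- "prevalence"
    enriched <- rep("none", p)
    names(enriched) <- taxa
    enriched[lfc_taxa] <- ifelse(b[lfc_taxa] > 0, "case", "control")
    enriched[prev_taxa] <- prev_enriched
    truth <- data.frame(taxon_id = taxa, planted_effect = unname(effect),
                        true_lfc = unname(b),
                        true_prevalence_case = unname(prev_case),
                        true_prevalence_control = unname(prev_ctrl),
                        enriched_group = unname(enriched),
                        stringsAsFactors = FALSE)

    coh <- MicrobiomeCohort(counts, metadata = meta, qpcr = qpcr,
                            rank = "genus")
    metadata(coh)$ground_truth <- truth
    metadata(coh)$library_factors <- s
    metadata(coh)$sim_config <- cfg
    coh
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: \code{\link{simulateMetadata}} followed by
#' \code{\link{simulateCounts}}.  Fully deterministic given
#' \code{cfg$seed}.
#'
#' @inheritParams simulateCounts
#' @return A \linkS4class{MicrobiomeCohort}.
#' @examples
#' coh <- simulateCohort(simConfig(n_subjects = 150, seed = 11))
#' @export
simulateCohort <- function(cfg = simConfig()) {
    simulateCounts(simulateMetadata(cfg), cfg)
}
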