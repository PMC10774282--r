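# Semi-synthetic benchmark generator.
#
# Emulates the published validation protocol: a pool of healthy-control-like
# ROI-volume vectors with covariate effects; pseudo-patients constructed by
# multiplying predefined ROI sets by (1 - r), r ~ Uniform(0, 0.3), one
# pattern per ground-truth subtype; one or two confounding imaging patterns
# on random participant subsets crossing subtype boundaries; fully simulated
# SNP vectors whose minor-allele frequency is elevated by +0.15 over a 0.33
# background within each subtype for its associated SNPs (and within random
# carrier subsets for confounding SNPs); optional entrywise missing-genotype
# masking.  Full ground truth is retained.

#' Simulation configuration
#'
#' Defaults reproduce the published semi-synthetic study conditions:
#' 539 reference participants, 1200 pseudo-patients in three equal subtypes,
#' 144 ROIs, uniform 0-30% volume reductions, 4 associated SNPs per subtype
#' at +0.15 minor-allele frequency over a 0.33 background, and two
#' genetic confounder subsets.
#'
#' @param n_ref reference (healthy) participants.
#' @param n_pt pseudo-patients.
#' @param n_roi phenotypic features (ROI volumes).
#' @param M_true ground-truth subtype count.
#' @param subtype_roi_sets list of `M_true` integer ROI index sets (defaults
#'   to disjoint blocks of `roi_set_size`).
#' @param roi_set_size ROIs per subtype pattern when defaulting.
#' @param change_ratio_range range of the uniform volume-reduction ratio.
#' @param n_confound_imaging number of confounding imaging patterns (0-2).
#' @param confound_roi_sets list of ROI index sets for the confounders.
#' @param confound_fraction fraction of pseudo-patients carrying each
#'   confounding imaging pattern.
#' @param n_genetic number of simulated SNPs.
#' @param snps_per_subtype associated SNPs per subtype.
#' @param background_maf background minor-allele frequency.
#' @param delta_maf additive MAF elevation in carriers.
#' @param n_confound_genetic number of confounding SNP sets.
#' @param confound_carrier_fraction fraction of pseudo-patients in each
#'   confounding-SNP carrier subset.
#' @param missing_rate entrywise missing-genotype probability.
#' @param cov_model covariate-effect specification for the base population:
#'   list with `age` (per-year log-volume slope), `sex`, `icv` (per-mm^3),
#'   `noise_sd` (lognormal residual sd), optional `baseline` (per-ROI mean
#'   volumes, mm^3).
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_ref = 539L, n_pt = 1200L, n_roi = 144L,
                       M_true = 3L, subtype_roi_sets = NULL,
                       roi_set_size = 15L,
                       change_ratio_range = c(0, 0.3),
                       n_confound_imaging = 1L, confound_roi_sets = NULL,
                       confound_fraction = 1 / 3,
                       n_genetic = 100L, snps_per_subtype = 4L,
                       background_maf = 0.33, delta_maf = 0.15,
                       n_confound_genetic = 2L,
                       confound_carrier_fraction = 1 / 3,
                       missing_rate = 0,
                       cov_model = list(age = -0.005, sex = 0.05,
                                        icv = 5e-7, noise_sd = 0.12),
                       seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (background_maf + delta_maf >= 1)
    stop("background_maf + delta_maf must be < 1")
  if (is.null(subtype_roi_sets)) {
    subtype_roi_sets <- split(seq_len(roi_set_size * M_true),
                              rep(seq_len(M_true), each = roi_set_size))
    names(subtype_roi_sets) <- NULL
  }
  if (is.null(confound_roi_sets) && n_confound_imaging > 0L) {
    start <- max(unlist(subtype_roi_sets))
    confound_roi_sets <- lapply(seq_len(n_confound_imaging), function(j)
      start + (j - 1L) * roi_set_size + seq_len(roi_set_size))
  }
  all_sets <- c(subtype_roi_sets, confound_roi_sets)
  if (length(all_sets) && max(unlist(all_sets)) > n_roi)
    stop("ROI index sets exceed n_roi")
  if (snps_per_subtype * M_true > n_genetic)
    stop("snps_per_subtype * M_true exceeds n_genetic")
  structure(list(n_ref = as.integer(n_ref), n_pt = as.integer(n_pt),
                 n_roi = as.integer(n_roi), M_true = as.integer(M_true),
                 subtype_roi_sets = subtype_roi_sets,
                 change_ratio_range = change_ratio_range,
                 n_confound_imaging = as.integer(n_confound_imaging),
                 confound_roi_sets = confound_roi_sets,
                 confound_fraction = confound_fraction,
                 n_genetic = as.integer(n_genetic),
                 snps_per_subtype = as.integer(snps_per_subtype),
                 background_maf = background_maf, delta_maf = delta_maf,
                 n_confound_genetic = as.integer(n_confound_genetic),
                 confound_carrier_fraction = confound_carrier_fraction,
                 missing_rate = missing_rate, cov_model = cov_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a healthy-control-like base population
#'
#' ROI volumes are `baseline * exp(age effect + sex effect + ICV effect +
#' lognormal noise)`, strictly positive.  Age is uniform on [55, 75], sex
#' Bernoulli(0.5), intracranial volume normal (mean 1.5e6 mm^3, sd 1.5e5).
#' Covariate effects are centred at the population means so baselines stay
#' interpretable as typical volumes.
#'
#' @param n participants (>= 2).
#' @param n_roi number of ROI features.
#' @param cov_model see [sim_config()].
#' @param seed integer seed.
#' @return a [cohort_table()] with every row labelled REF.
#' @export
generate_base_population <- function(n, n_roi,
                                     cov_model = list(age = -0.005, sex = 0.05,
                                                      icv = 5e-7, noise_sd = 0.12),
                                     seed = 1L) {
  stopifnot(n >= 2)
  baseline <- cov_model$baseline
  if (is.null(baseline))
    baseline <- exp(seq(log(3e3), log(3e4), length.out = n_roi))
  if (length(baseline) != n_roi) stop("baseline length must equal n_roi")
  if (any(baseline <= 0)) stop("per-ROI baseline means must be positive")
  set.seed(seed)
  age <- stats::runif(n, 55, 75)
  sex <- stats::rbinom(n, 1L, 0.5)
  icv <- stats::rnorm(n, 1.5e6, 1.5e5)
  lin <- cov_model$age * (age - 65) + cov_model$sex * (sex - 0.5) +
    cov_model$icv * (icv - 1.5e6)
  noise <- matrix(stats::rnorm(n * n_roi, 0, cov_model$noise_sd), n, n_roi)
  feats <- exp(sweep(noise, 1L, lin, "+"))
  feats <- sweep(feats, 2L, baseline, "*")
  colnames(feats) <- sprintf("roi_%03d", seq_len(n_roi))
  cohort_table(sprintf("P%05d", seq_len(n)), rep("REF", n),
               data.frame(age = age, sex = sex, icv = icv), feats)
}

#' Impose subtype and confounding imaging patterns on a base population
#'
#' The first `n_ref` (shuffled) participants stay untouched as the REF
#' group; the next `n_pt` become pseudo-patients (TAR), divided into
#' `M_true` subtypes of equal size (+/- 1).  Every ROI in a pseudo-patient's
#' subtype set is multiplied by `(1 - r)` with `r ~ Uniform(change_ratio
#' range)` drawn independently per participant-ROI pair; confounding
#' patterns are imposed the same way on random subsets crossing subtype
#' boundaries.
#'
#' @param base a [cohort_table()] with at least `n_ref + n_pt` rows.
#' @param cfg a [sim_config()].
#' @return list of class `semi_synthetic_cohort` with elements `phenotypes`
#'   (a [cohort_table()]) and `truth` (ground-truth record).
#' @export
build_semi_synthetic <- function(base, cfg) {
  n_total <- cfg$n_ref + cfg$n_pt
  if (length(base$participant_id) < n_total)
    stop("base population smaller than n_ref + n_pt")
  set.seed(derive_seed(cfg$seed, 101L))
  ord <- sample.int(length(base$participant_id))[seq_len(n_total)]
  tab <- cohort_subset(base, ord)
  group <- c(rep("REF", cfg$n_ref), rep("TAR", cfg$n_pt))

  subtype <- rep(seq_len(cfg$M_true), length.out = cfg$n_pt)
  subtype <- sample(subtype)

  feats <- tab$features
  imposed <- matrix(0, cfg$n_pt, ncol(feats))
  lo <- cfg$change_ratio_range[1]; hi <- cfg$change_ratio_range[2]
  if (hi >= 1) stop("change ratios must stay below 1")
  for (m in seq_len(cfg$M_true)) {
    rows <- which(subtype == m)
    cols <- cfg$subtype_roi_sets[[m]]
    r <- matrix(stats::runif(length(rows) * length(cols), lo, hi),
                length(rows), length(cols))
    imposed[rows, cols] <- r
  }
  confound_membership <- list()
  if (cfg$n_confound_imaging > 0L) {
    for (j in seq_len(cfg$n_confound_imaging)) {
      members <- stats::runif(cfg$n_pt) < cfg$confound_fraction
      cols <- cfg$confound_roi_sets[[j]]
      rows <- which(members)
      r <- matrix(stats::runif(length(rows) * length(cols), lo, hi),
                  length(rows), length(cols))
      # patterns compose multiplicatively; record the total imposed ratio
      imposed[rows, cols] <- 1 - (1 - imposed[rows, cols]) * (1 - r)
      confound_membership[[j]] <- members
    }
  }
  tar_rows <- cfg$n_ref + seq_len(cfg$n_pt)
  feats[tar_rows, ] <- tab$features[tar_rows, ] * (1 - imposed)

  phenotypes <- cohort_table(tab$participant_id, group, tab$covariates, feats)
  truth <- list(true_subtype = subtype,
                participant_id = tab$participant_id[tar_rows],
                imposed_ratio = imposed,
                confound_membership = confound_membership,
                subtype_roi_sets = cfg$subtype_roi_sets,
                confound_roi_sets = cfg$confound_roi_sets)
  structure(list(phenotypes = phenotypes, truth = truth, config = cfg),
            class = "semi_synthetic_cohort")
}

#' Simulate subtype-associated genotypes for the pseudo-patients
#'
#' Each SNP is drawn per participant as Binomial(2, p) under Hardy-Weinberg
#' equilibrium; p equals the background MAF except for subtype-associated
#' SNPs inside their subtype and confounding SNPs inside their random
#' carrier subset, where it is elevated by `delta_maf`.
#'
#' @param truth the `truth` element of [build_semi_synthetic()].
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] for the pseudo-patients, with the
#'   associated/confounding SNP index sets attached as attributes
#'   `assoc_snps` and `confound_snps`.
#' @export
simulate_genotypes <- function(truth, cfg) {
  n_pt <- length(truth$true_subtype)
  set.seed(derive_seed(cfg$seed, 202L))
  assoc <- split(sample.int(cfg$n_genetic, cfg$snps_per_subtype * cfg$M_true),
                 rep(seq_len(cfg$M_true), each = cfg$snps_per_subtype))
  names(assoc) <- NULL
  p <- matrix(cfg$background_maf, n_pt, cfg$n_genetic)
  for (m in seq_len(cfg$M_true)) {
    rows <- truth$true_subtype == m
    p[rows, assoc[[m]]] <- cfg$background_maf + cfg$delta_maf
  }
  confound_snps <- list()
  confound_carriers <- list()
  if (cfg$n_confound_genetic > 0L) {
    for (j in seq_len(cfg$n_confound_genetic)) {
      snps <- sample.int(cfg$n_genetic, cfg$snps_per_subtype)
      carriers <- stats::runif(n_pt) < cfg$confound_carrier_fraction
      p[carriers, snps] <- cfg$background_maf + cfg$delta_maf
      confound_snps[[j]] <- snps
      confound_carriers[[j]] <- carriers
    }
  }
  counts <- matrix(stats::rbinom(n_pt * cfg$n_genetic, 2L, as.vector(p)),
                   n_pt, cfg$n_genetic)
  G <- genotype_matrix(truth$participant_id, counts,
                       sprintf("snp_%04d", seq_len(cfg$n_genetic)))
  attr(G, "assoc_snps") <- assoc
  attr(G, "confound_snps") <- confound_snps
  attr(G, "confound_carriers") <- confound_carriers
  attr(G, "maf_matrix") <- p
  G
}

#' Mask genotype entries as missing at a given rate
#'
#' Entries are set missing independently with probability `rate`;
#' everything else is preserved.  Deterministic given the seed.
#'
#' @param G a [genotype_matrix()].
#' @param rate missing probability in [0, 1).
#' @param seed integer seed.
#' @return a [genotype_matrix()].
#' @export
mask_missing <- function(G, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(G)
  set.seed(seed)
  mask <- matrix(stats::runif(length(G$counts)) < rate,
                 nrow(G$counts), ncol(G$counts))
  counts <- G$counts
  counts[mask] <- NA
  out <- genotype_matrix(G$participant_id, counts, G$snp_ids)
  for (a in c("assoc_snps", "confound_snps", "confound_carriers", "maf_matrix"))
    attr(out, a) <- attr(G, a)
  out
}

#' Generate a complete semi-synthetic cohort
#'
#' Convenience wrapper: base population, imposed patterns, simulated
#' genotypes and missing-masking in one call, all deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list of class `semi_synthetic_cohort` with `phenotypes`,
#'   `genotypes`, `truth`, `config`.
#' @export
semi_synthetic_cohort <- function(cfg = sim_config()) {
  base <- generate_base_population(cfg$n_ref + cfg$n_pt, cfg$n_roi,
                                   cfg$cov_model,
                                   seed = derive_seed(cfg$seed, 7L))
  cohort <- build_semi_synthetic(base, cfg)
  G <- simulate_genotypes(cohort$truth, cfg)
  if (cfg$missing_rate > 0)
    G <- mask_missing(G, cfg$missing_rate, seed = derive_seed(cfg$seed, 303L))
  cohort$genotypes <- G
  cohort$truth$assoc_snps <- attr(G, "assoc_snps")
  cohort$truth$confound_snps <- attr(G, "confound_snps")
  cohort
}
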