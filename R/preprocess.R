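# Feature conditioning: covariate residualization estimated on the REF
# group only, standardization of every feature to REF mean 1 / sd 0.1,
# genotype recoding and mean-imputation of missing genotypes for the
# variational encoder input.

#' Fit the covariate residualizer and standardization parameters on REF
#'
#' Per-feature ordinary-least-squares coefficients of the covariates are
#' estimated on the REF rows only; the stored adjustment removes covariate
#' effects around the REF covariate means (`f - beta (c - mean_REF(c))`), so
#' REF keeps its location.  The REF mean and sd of the adjusted features are
#' stored for standardization to mean 1 / sd 0.1.
#'
#' @param table a [cohort_table()] with at least one REF row.
#' @param covariate_names covariates to residualize on (default all).
#' @return object of class `standardization_params`.
#' @export
fit_residualizer <- function(table, covariate_names = names(table$covariates)) {
  ref <- table$group == "REF"
  n_ref <- sum(ref)
  if (n_ref < length(covariate_names) + 2L)
    stop("need at least |covariates| + 2 REF rows")
  C <- as.matrix(table$covariates[ref, covariate_names, drop = FALSE])
  X <- cbind(1, C)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("collinear covariates on REF (rank-deficient design)")
  F_ref <- table$features[ref, , drop = FALSE]
  beta <- qr.coef(qr_x, F_ref)            # (1 + n_cov) x n_feat
  cov_means <- colMeans(C)
  slope <- beta[-1L, , drop = FALSE]
  adj_ref <- F_ref - (C - matrix(cov_means, n_ref, length(cov_means),
                                 byrow = TRUE)) %*% slope
  mu <- colMeans(adj_ref)
  sd_ <- apply(adj_ref, 2L, stats::sd)
  if (any(sd_ <= 0))
    stop("constant feature on REF: ",
         paste(colnames(F_ref)[sd_ <= 0], collapse = ", "))
  structure(list(covariate_names = covariate_names,
                 slope = slope, cov_means = cov_means,
                 ref_mean = mu, ref_sd = sd_,
                 feature_names = colnames(table$features),
                 target_mean = 1.0, target_sd = 0.1),
            class = "standardization_params")
}

#' Apply covariate adjustment and REF-anchored standardization
#'
#' Output feature `f' = 1 + 0.1 (f_adj - mean_REF) / sd_REF`, applied to REF
#' and TAR rows alike with the REF-estimated parameters.
#'
#' @param table a [cohort_table()] with the training feature set.
#' @param params a [fit_residualizer()] result.
#' @return a [cohort_table()] with standardized features.
#' @export
apply_standardization <- function(table, params) {
  if (!identical(colnames(table$features), params$feature_names))
    stop("feature names do not match the fitted standardization parameters")
  C <- as.matrix(table$covariates[, params$covariate_names, drop = FALSE])
  n <- nrow(C)
  adj <- table$features -
    (C - matrix(params$cov_means, n, length(params$cov_means),
                byrow = TRUE)) %*% params$slope
  std <- sweep(sweep(adj, 2L, params$ref_mean, "-"), 2L, params$ref_sd, "/")
  std <- params$target_mean + params$target_sd * std
  cohort_table(table$participant_id, table$group, table$covariates, std)
}

#' Invert the standardization (per feature, affine)
#'
#' Maps standardized features back to adjusted (covariate-residualized)
#' values.
#'
#' @param features standardized feature matrix.
#' @param params a [fit_residualizer()] result.
#' @return adjusted feature matrix.
#' @export
invert_standardization <- function(features, params) {
  adj <- (features - params$target_mean) / params$target_sd
  sweep(sweep(adj, 2L, params$ref_sd, "*"), 2L, params$ref_mean, "+")
}

#' Recode genotypes and mean-impute missing entries
#'
#' Observed entries pass through as allele counts in {0,1,2}; missing
#' entries are replaced by the per-SNP mean over the observed entries of the
#' target participants (equal to twice the observed minor-allele frequency).
#' SNPs with no observed entry among the targets are dropped with a warning.
#' The observed mask is returned unchanged for the likelihood computation.
#'
#' @param G a [genotype_matrix()].
#' @param tar_ids participant ids to keep, in order (default: all rows).
#' @return list with `imputed` (numeric matrix), `observed` (logical
#'   matrix), `snp_ids`, `participant_id`, and `snp_means` (imputation
#'   values used).
#' @export
recode_and_impute <- function(G, tar_ids = G$participant_id) {
  idx <- match(tar_ids, G$participant_id)
  if (anyNA(idx)) stop("tar_ids absent from the genotype matrix")
  counts <- G$counts[idx, , drop = FALSE]
  observed <- !is.na(counts)
  n_obs <- colSums(observed)
  drop <- n_obs == 0L
  if (any(drop)) {
    gpgan_log("warn", sprintf(
      "dropping %d SNP(s) with no observed genotype among targets: %s",
      sum(drop), paste(utils::head(G$snp_ids[drop], 5L), collapse = ", ")))
    counts <- counts[, !drop, drop = FALSE]
    observed <- observed[, !drop, drop = FALSE]
  }
  snp_ids <- colnames(counts)
  means <- colSums(counts * observed, na.rm = TRUE) / colSums(observed)
  imputed <- counts
  for (j in seq_len(ncol(imputed))) {
    miss <- !observed[, j]
    if (any(miss)) imputed[miss, j] <- means[j]
  }
  list(imputed = imputed, observed = observed, snp_ids = snp_ids,
       participant_id = tar_ids, snp_means = means)
}
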