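# Read-outs of a trained model: subtype probabilities via the inverse
# mapping, per-subtype phenotype change-ratio maps via the transformation
# function, and per-subtype inferred SNP allele frequencies via the genetic
# decoder.

#' Assign subtype probabilities to target participants
#'
#' Applies the categorical head of the inverse mapping to the (standardized)
#' phenotypic features only; genotypes are never consulted, so the trained
#' model applies to participants without genetic data.  Dominant label =
#' argmax probability, exact ties going to the lowest subtype index.
#'
#' @param model a `gpgan_model`.
#' @param phenotypes standardized [cohort_table()]; TAR rows are assigned
#'   (all rows if no TAR row is present).
#' @return data.frame: participant_id, P_1..P_M, dominant (integer in
#'   `1..M`).
#' @export
assign_subtypes <- function(model, phenotypes) {
  idx <- if (any(phenotypes$group == "TAR"))
    which(phenotypes$group == "TAR") else seq_along(phenotypes$participant_id)
  feats <- phenotypes$features[idx, , drop = FALSE]
  if (!identical(colnames(feats), model$feature_names))
    stop("feature names do not match the trained model")
  probs <- ad_value(net_g(model$par, ad_const(feats))$z1)
  dominant <- max.col(probs, ties.method = "first")
  out <- data.frame(participant_id = phenotypes$participant_id[idx],
                    probs, dominant = dominant, stringsAsFactors = FALSE)
  names(out)[1L + seq_len(ncol(probs))] <- sprintf("P_%d", seq_len(ncol(probs)))
  out
}

#' Per-subtype phenotype change-ratio map
#'
#' For each subtype m the categorical latent is fixed to the one-hot vector
#' of m; one `z2 ~ U[0,1]^n_z2` draw is paired with each reference feature
#' vector (rows sampled without replacement), and the entrywise ratio
#' `(f(x, z1, z2) - x) / x` is averaged over the reference rows.  Negative
#' ratios indicate volume loss (atrophy) attributed to the subtype.
#'
#' @param model a `gpgan_model`.
#' @param reference a standardized [cohort_table()]; its REF rows supply
#'   the x vectors.
#' @param n_draws number of (x, z2) pairs per subtype (default: all REF
#'   rows).
#' @return matrix M x n_features of mean signed change ratios.
#' @export
pattern_map <- function(model, reference, n_draws = NULL) {
  ref_idx <- which(reference$group == "REF")
  if (!length(ref_idx)) ref_idx <- seq_along(reference$participant_id)
  x <- reference$features[ref_idx, , drop = FALSE]
  if (is.null(n_draws)) n_draws <- nrow(x)
  n_draws <- min(n_draws, nrow(x))
  M <- model$spec$M
  out <- matrix(0, M, ncol(x), dimnames = list(NULL, colnames(x)))
  for (m in seq_len(M)) {
    rows <- sample.int(nrow(x), n_draws, replace = FALSE)
    xs <- x[rows, , drop = FALSE]
    z1 <- matrix(0, n_draws, M); z1[, m] <- 1
    z2 <- matrix(stats::runif(n_draws * model$spec$n_z2), n_draws,
                 model$spec$n_z2)
    y_syn <- transform_ref(model$par, xs, z1, z2)
    nonzero <- xs != 0
    if (!all(nonzero))
      gpgan_log("warn", "excluding zero-valued reference entries from ratios")
    ratio <- ifelse(nonzero, (y_syn - xs) / xs, NA_real_)
    out[m, ] <- colMeans(ratio, na.rm = TRUE)
  }
  out
}

#' Per-subtype inferred SNP minor-allele frequencies
#'
#' For each subtype the genetic decoder is evaluated at the exact one-hot
#' categorical vector with `n_draws` standard-normal draws of the
#' genetic-specific latent; the outputs (sigmoid, hence in (0,1)) are
#' averaged.
#'
#' @param model a `gpgan_model` trained with genetic features.
#' @param n_draws number of latent draws per subtype.
#' @return matrix M x n_snps of inferred allele frequencies.
#' @export
inferred_maf <- function(model, n_draws = 100L) {
  if (n_draws < 1L) stop("n_draws must be >= 1")
  if (model$par$n_snps == 0L) stop("model was trained without genetic features")
  M <- model$spec$M
  out <- matrix(0, M, model$par$n_snps,
                dimnames = list(NULL, model$snp_ids))
  for (m in seq_len(M)) {
    z1 <- matrix(0, n_draws, M); z1[, m] <- 1
    z3 <- matrix(stats::rnorm(n_draws * model$spec$n_z3), n_draws,
                 model$spec$n_z3)
    p <- ad_value(net_h(model$par, ad_const(z1), ad_const(z3)))
    out[m, ] <- colMeans(p)
  }
  out
}
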