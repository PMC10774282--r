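# Small fixtures built in code for the unit tests.

tiny_cohort <- function(n_ref = 30, n_tar = 30, n_feat = 6, seed = 42) {
  set.seed(seed)
  n <- n_ref + n_tar
  feats <- matrix(stats::rlnorm(n * n_feat, log(1000), 0.1), n, n_feat)
  colnames(feats) <- sprintf("roi_%03d", seq_len(n_feat))
  cohort_table(sprintf("S%03d", seq_len(n)),
               c(rep("REF", n_ref), rep("TAR", n_tar)),
               data.frame(age = runif(n, 55, 75),
                          sex = rbinom(n, 1, 0.5),
                          icv = rnorm(n, 1.5e6, 1e5)),
               feats)
}

tiny_genotypes <- function(n = 30, n_snp = 5, missing = 0, seed = 7,
                           ids = sprintf("S%03d", 30 + seq_len(n))) {
  set.seed(seed)
  counts <- matrix(rbinom(n * n_snp, 2, 0.3), n, n_snp)
  if (missing > 0) counts[runif(n * n_snp) < missing] <- NA
  genotype_matrix(ids, counts, sprintf("rs%03d", seq_len(n_snp)))
}

# standardized cohort with a clean 2-subtype signal, for small model runs
signal_cohort <- function(n_ref = 120, n_tar = 120, n_feat = 12, seed = 1,
                          shift = 0.4) {
  set.seed(seed)
  n <- n_ref + n_tar
  feats <- matrix(rnorm(n * n_feat, 1, 0.1), n, n_feat)
  subtype <- rep(1:2, length.out = n_tar)
  tar_rows <- n_ref + seq_len(n_tar)
  k <- max(2L, n_feat %/% 3L)
  set1 <- seq_len(k)
  set2 <- k + seq_len(k)
  feats[tar_rows[subtype == 1], set1] <-
    feats[tar_rows[subtype == 1], set1] - shift * 0.1
  feats[tar_rows[subtype == 2], set2] <-
    feats[tar_rows[subtype == 2], set2] - shift * 0.1
  colnames(feats) <- sprintf("f%02d", seq_len(n_feat))
  tab <- cohort_table(sprintf("Q%03d", seq_len(n)),
                      c(rep("REF", n_ref), rep("TAR", n_tar)),
                      data.frame(age = rep(65, n), sex = rep(0, n),
                                 icv = rep(1.5e6, n)),
                      feats)
  list(table = tab, subtype = subtype)
}

numeric_grad <- function(fun, p, i, eps = 1e-6) {
  v0 <- p$value
  p$value[i] <- v0[i] + eps
  up <- ad_value(fun())[1]
  p$value[i] <- v0[i] - eps
  dn <- ad_value(fun())[1]
  p$value <- v0
  (up - dn) / (2 * eps)
}
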