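# Loss terms of the two optimization steps.
#
# Phenotype step: a GAN maps reference (REF) phenotype vectors x onto
# synthesized target (TAR) vectors y' = f(x, z1, z2).  The categorical latent
# z1 is sampled from a discrete uniform distribution but every sample is
# re-weighted by M * p_theta(z1), so that gradients flow into the learned
# categorical prior; a KL penalty keeps that prior near uniform.  A change
# (l1) loss encourages sparse transformations and a reconstruction loss makes
# (z1, z2) recoverable from y' via the inverse mapping g.
#
# Gene step: a variational posterior q(z3 | v, y) (Gaussian, encoder r) and a
# decoder h that maps (g1(y), z3) to per-SNP allele frequencies maximize the
# evidence lower bound of a binomial genotype likelihood with two trials per
# SNP; missing genotypes contribute nothing to the likelihood.

.EPS_D  <- 1e-7   # discriminator log clamp
.EPS_CE <- 1e-12  # categorical cross-entropy clamp

#' Sample a latent batch for the Phenotype step
#'
#' `z1` is drawn from the discrete uniform distribution over the M one-hot
#' vectors and `z2` from uniform `[0,1]^n_z2`.  Each draw carries an
#' importance weight `w = M * softmax(theta_z1)[category]` as a graph node so
#' that the weighted losses are differentiable in the prior logits.
#'
#' @param theta_z1 the categorical-prior logit parameter node (or a 1 x M
#'   numeric matrix).
#' @param batch number of draws.
#' @param spec a [latent_spec()].
#' @return list with `z1` (one-hot matrix), `z2` (matrix), `category`
#'   (integer vector), and `w` (batch x 1 `ad_node` of weights).
#' @export
sample_latents <- function(theta_z1, batch, spec) {
  stopifnot(batch >= 1)
  M <- spec$M
  k <- sample.int(M, batch, replace = TRUE)
  z1 <- matrix(0, batch, M)
  z1[cbind(seq_len(batch), k)] <- 1
  z2 <- matrix(stats::runif(batch * spec$n_z2), batch, spec$n_z2)
  node <- if (is_ad(theta_z1)) theta_z1 else ad_const(theta_z1)
  probs <- ad_softmax_rows(node)                       # 1 x M
  w <- ad_scale(ad_matmul(ad_const(z1), ad_node(t(probs$value), list(probs),
         function(g) list(t(g)))), M)                  # batch x 1
  list(z1 = z1, z2 = z2, category = k, w = w)
}

#' KL divergence from the uniform categorical to the learned prior
#' @keywords internal
kl_uniform_prior <- function(theta_z1) {
  node <- if (is_ad(theta_z1)) theta_z1 else ad_const(theta_z1)
  M <- ncol(node$value)
  probs <- ad_softmax_rows(node)
  # sum_m (1/M) * log((1/M) / p_m) = -log(M) - (1/M) sum_m log p_m
  ad_sub(ad_scale(ad_sum(ad_log(ad_clamp(probs, .EPS_CE, 1))), -1 / M),
         log(M))
}

#' Transformation function f applied to a REF batch
#'
#' @param par a [gpgan_params()] object.
#' @param x REF feature matrix (batch x n_features).
#' @param z1 one-hot (or probability) matrix, batch x M.
#' @param z2 matrix in `[0,1]`, batch x n_z2.
#' @return synthesized TAR matrix y' (plain matrix).
#' @export
transform_ref <- function(par, x, z1, z2) {
  x <- as.matrix(x)
  if (ncol(x) != par$n_features) stop("feature dimension mismatch")
  ad_value(net_transform(par, ad_const(x), ad_const(z1), ad_const(z2)))
}

#' Adversarial losses of the Phenotype step
#'
#' The discriminator loss is the negated weighted cross-entropy
#' `-(E_y log D(y) + E_y' w log(1 - D(y')))`; the generator side uses the
#' non-saturating form `E_y' w (-log D(y'))` plus the KL penalty
#' `kappa * KL(U || p_theta)` on the categorical prior.
#'
#' @param par a [gpgan_params()] object.
#' @param x REF batch, `y` TAR batch (matrices).
#' @param y real TAR feature batch.
#' @param lat a latent batch from [sample_latents()] (drawn fresh if NULL).
#' @param kappa weight of the categorical-prior KL penalty.
#' @return list of scalar `ad_node`s: `loss_D` (minimize over discriminator
#'   weights), `loss_gen` (minimize over generator-side weights), plus the
#'   `kl` node and the synthesized batch `y_syn`.
#' @export
gan_losses <- function(par, x, y, lat = NULL, kappa = 1) {
  if (is.null(lat)) lat <- sample_latents(par$theta_z1, nrow(x), par$spec)
  y_syn <- net_transform(par, ad_const(x), ad_const(lat$z1), ad_const(lat$z2))

  # discriminator update: treat y' and w as constants
  d_real <- ad_clamp(net_discriminate(par, ad_const(y)), .EPS_D, 1 - .EPS_D)
  d_fake <- ad_clamp(net_discriminate(par, ad_const(ad_value(y_syn))),
                     .EPS_D, 1 - .EPS_D)
  w_const <- ad_const(ad_value(lat$w))
  loss_D <- ad_scale(ad_add(ad_mean(ad_log(d_real)),
                            ad_mean(ad_mul(ad_log(ad_sub(1, d_fake)),
                                           w_const))), -1)

  # generator side: gradient flows through f and theta_z1 (via w), not D
  d_syn <- ad_clamp(net_discriminate(par, y_syn), .EPS_D, 1 - .EPS_D)
  kl <- kl_uniform_prior(par$theta_z1)
  loss_gen <- ad_add(ad_mean(ad_mul(ad_scale(ad_log(d_syn), -1), lat$w)),
                     ad_scale(kl, kappa))
  list(loss_D = loss_D, loss_gen = loss_gen, kl = kl, y_syn = y_syn)
}

#' Sparse-transformation (change) loss
#'
#' Mean absolute difference between synthesized and reference features,
#' i.e. the batch-mean per-participant l1 distance divided by the number of
#' features.
#'
#' @param x REF batch (matrix or node).
#' @param y_syn synthesized batch (matrix or node).
#' @return scalar `ad_node`.
#' @export
change_loss <- function(x, y_syn) {
  ad_mean(ad_abs(ad_sub(.wrap(y_syn), .wrap(x))))
}

#' Inverse-consistency reconstruction loss
#'
#' Cross-entropy for the categorical latent and dimension-scaled squared
#' error for the continuous latent.
#'
#' @param z1 true one-hot matrix.
#' @param z1_hat_probs estimated probability matrix (rows sum to 1).
#' @param z2 true `z2` matrix.
#' @param z2_hat estimated `z2` matrix.
#' @return list of scalar `ad_node`s `ce` and `l2`.
#' @export
reconstruction_loss <- function(z1, z1_hat_probs, z2, z2_hat) {
  p <- ad_clamp(.wrap(z1_hat_probs), .EPS_CE, 1)
  ce <- ad_scale(ad_mean(ad_rowsums(ad_mul(ad_const(z1), ad_log(p)))), -1)
  l2 <- ad_mean(ad_square(ad_sub(.wrap(z2_hat), ad_const(z2))))
  list(ce = ce, l2 = l2)
}

#' Full generator-side Phenotype-step objective
#'
#' `loss_gen + mu * change + lambda * (ce + l2)`.
#'
#' @param components list with nodes `loss_gen`, `change`, `ce`, `l2`.
#' @param mu,lambda loss weights.
#' @return scalar `ad_node`.
#' @export
phenotype_objective <- function(components, mu = 5, lambda = 1) {
  ad_add(ad_add(components$loss_gen, ad_scale(components$change, mu)),
         ad_scale(ad_add(components$ce, components$l2), lambda))
}

#' Binomial genotype log-likelihood matrix (log pmf per entry)
#'
#' `log C(2, v) + v log p + (2 - v) log(1 - p)` for allele counts v in
#' {0,1,2}; entries where `mask` is FALSE contribute 0.
#' @keywords internal
binomial_loglik <- function(v, p_node, mask) {
  mask_num <- mask * 1
  lchoose_term <- (v == 1) * mask_num * log(2)
  p <- ad_clamp(p_node, 1e-7, 1 - 1e-7)
  vm <- v * mask_num
  cm <- (2 - v) * mask_num
  ll <- ad_add(ad_mul(ad_log(p), ad_const(vm)),
               ad_mul(ad_log(ad_sub(1, p)), ad_const(cm)))
  ad_add(ll, ad_const(lchoose_term))
}

#' Gene-step loss (negative ELBO)
#'
#' Encodes `(v_imputed, y)` into the Gaussian posterior of `z3`, draws one
#' reparametrized sample, decodes per-SNP allele frequencies from
#' `(g1(y), z3)`, and evaluates the binomial likelihood over observed
#' genotypes only plus the closed-form KL to the standard-normal prior.
#'
#' @param par a [gpgan_params()] object with genetic networks.
#' @param v_imputed imputed genotype matrix (batch x n_snps), observed
#'   entries are the raw counts.
#' @param observed_mask logical matrix, TRUE where the genotype was observed.
#' @param y TAR phenotype batch.
#' @param eps optional pre-drawn standard-normal matrix (batch x n_z3) for
#'   the reparametrization (drawn internally if NULL).
#' @return list of scalar `ad_node`s `nll` and `kl` (total gene loss is
#'   their sum) plus the posterior nodes `mu` and `sigma`.
#' @export
gene_step_loss <- function(par, v_imputed, observed_mask, y, eps = NULL) {
  batch <- nrow(y)
  post <- net_r(par, ad_const(v_imputed), ad_const(y))
  if (is.null(eps))
    eps <- matrix(stats::rnorm(batch * par$spec$n_z3), batch, par$spec$n_z3)
  z3 <- ad_add(post$mu, ad_mul(post$sigma, ad_const(eps)))
  z1_probs <- net_g(par, ad_const(y))$z1
  p <- net_h(par, z1_probs, z3)
  ll <- binomial_loglik(v_imputed, p, observed_mask)
  nll <- ad_scale(ad_mean(ad_rowsums(ll)), -1)
  sig <- ad_clamp(post$sigma, 1e-7, Inf)
  kl_mat <- ad_sub(ad_scale(ad_sub(ad_add(ad_square(post$mu),
                                          ad_square(sig)), 1), 0.5),
                   ad_log(sig))
  kl <- ad_mean(ad_rowsums(kl_mat))
  list(nll = nll, kl = kl, mu = post$mu, sigma = post$sigma)
}
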