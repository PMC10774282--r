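# Multilayer perceptrons used by the five parametrized functions of the
# model (transformation f, discriminator D, inverse mapping g with a
# categorical head g1 and a continuous head g2, genetic decoder h, and the
# variational encoder r).  All are 2-hidden-layer perceptrons with
# leaky-rectifier activations (width `hidden`, default 64).

#' Latent-space specification
#'
#' @param M number of subtypes (categorical latent dimension), `M >= 2`.
#' @param n_z2 dimension of the phenotype-specific latent `z2` (uniform on
#'   `[0,1]^n_z2`).
#' @param n_z3 dimension of the genetic-specific latent `z3` (standard-normal
#'   prior).
#' @return object of class `latent_spec`.
#' @export
latent_spec <- function(M = 3L, n_z2 = 5L, n_z3 = 5L) {
  M <- as.integer(M); n_z2 <- as.integer(n_z2); n_z3 <- as.integer(n_z3)
  if (M < 2L) stop("M must be >= 2")
  if (n_z2 < 1L || n_z3 < 1L) stop("n_z2 and n_z3 must be >= 1")
  structure(list(M = M, n_z2 = n_z2, n_z3 = n_z3), class = "latent_spec")
}

# He-style initialization; `zero_out` zero-initializes the output layer so a
# residual generator starts at the identity.
mlp_new <- function(sizes, zero_out = FALSE) {
  L <- length(sizes) - 1L
  layers <- vector("list", L)
  for (i in seq_len(L)) {
    fan_in <- sizes[i]
    sd <- sqrt(2 / fan_in)
    W <- matrix(stats::rnorm(fan_in * sizes[i + 1L], sd = sd), fan_in, sizes[i + 1L])
    if (zero_out && i == L) W[] <- 0
    layers[[i]] <- list(W = ad_param(W), b = ad_param(matrix(0, 1L, sizes[i + 1L])))
  }
  layers
}

# Forward pass through all layers; hidden activations are leaky ReLU, the
# output layer is linear (callers attach softmax/sigmoid/softplus heads).
mlp_forward <- function(layers, x, slope = 0.2) {
  h <- if (is_ad(x)) x else ad_const(x)
  L <- length(layers)
  for (i in seq_len(L)) {
    h <- ad_add(ad_matmul(h, layers[[i]]$W), layers[[i]]$b)
    if (i < L) h <- ad_leaky_relu(h, slope)
  }
  h
}

mlp_params <- function(layers) {
  unlist(lapply(layers, function(l) list(l$W, l$b)), recursive = FALSE)
}

#' Initialize all model parameters
#'
#' Creates the five networks and the categorical-prior logits.  `f` maps
#' `(x, z1, z2)` to an additive residual on `x`; `D` scores phenotype vectors;
#' `g` is a shared encoder with a softmax head `g1` (subtype probabilities)
#' and a sigmoid head `g2` (reconstruction of `z2`); `h` maps
#' `(z1 probabilities, z3)` to per-SNP allele frequencies through a sigmoid;
#' `r` maps `(v, y)` to the variational posterior mean and (softplus) sd of
#' `z3`.
#'
#' @param n_features number of phenotypic features.
#' @param n_snps number of genetic features (SNPs); 0 allowed for a
#'   phenotype-only model.
#' @param spec a [latent_spec()].
#' @param hidden hidden width of every perceptron.
#' @return object of class `gpgan_params`.
#' @export
gpgan_params <- function(n_features, n_snps, spec, hidden = 64L) {
  stopifnot(inherits(spec, "latent_spec"))
  M <- spec$M
  par <- list(
    f = mlp_new(c(n_features + M + spec$n_z2, hidden, hidden, n_features),
                zero_out = TRUE),
    D = mlp_new(c(n_features, hidden, hidden, 1L)),
    g_trunk = mlp_new(c(n_features, hidden, hidden)),
    g1_head = mlp_new(c(hidden, M)),
    g2_head = mlp_new(c(hidden, spec$n_z2)),
    theta_z1 = ad_param(matrix(0, 1L, M)),
    spec = spec,
    n_features = as.integer(n_features),
    n_snps = as.integer(n_snps),
    hidden = as.integer(hidden)
  )
  if (n_snps > 0L) {
    par$h <- mlp_new(c(M + spec$n_z3, hidden, hidden, n_snps))
    par$r_trunk <- mlp_new(c(n_snps + n_features, hidden, hidden))
    par$r_mu <- mlp_new(c(hidden, spec$n_z3))
    par$r_sigma <- mlp_new(c(hidden, spec$n_z3))
  }
  class(par) <- "gpgan_params"
  par
}

# Networks pass through the shared g trunk; forward helpers ------------------

net_transform <- function(par, x, z1, z2) {
  inp <- ad_cbind(x, z1, z2)
  delta <- mlp_forward(par$f, inp)
  ad_add(.wrap(x), delta)
}

net_discriminate <- function(par, y) {
  ad_sigmoid(mlp_forward(par$D, y))
}

net_g <- function(par, y) {
  trunk <- mlp_forward(par$g_trunk, y)
  trunk <- ad_leaky_relu(trunk, 0.2)
  list(z1 = ad_softmax_rows(mlp_forward(par$g1_head, trunk)),
       z2 = ad_sigmoid(mlp_forward(par$g2_head, trunk)))
}

net_h <- function(par, z1_probs, z3) {
  ad_sigmoid(mlp_forward(par$h, ad_cbind(z1_probs, z3)))
}

net_r <- function(par, v, y) {
  trunk <- mlp_forward(par$r_trunk, ad_cbind(v, y))
  trunk <- ad_leaky_relu(trunk, 0.2)
  list(mu = mlp_forward(par$r_mu, trunk),
       sigma = ad_softplus(mlp_forward(par$r_sigma, trunk)))
}

# Parameter groups for the three optimization steps --------------------------

params_discriminator <- function(par) mlp_params(par$D)

params_generator <- function(par) {
  c(mlp_params(par$f), mlp_params(par$g_trunk), mlp_params(par$g1_head),
    mlp_params(par$g2_head), list(par$theta_z1))
}

params_gene <- function(par) {
  c(mlp_params(par$h), mlp_params(par$r_trunk), mlp_params(par$r_mu),
    mlp_params(par$r_sigma), mlp_params(par$g_trunk), mlp_params(par$g1_head))
}

#' Project the Lipschitz-constrained networks onto the weight-clipping ball
#'
#' Every weight of `f`, the shared `g` trunk, and the `g1`/`g2` heads is
#' clipped to `[-c, c]`; the discriminator and the `h`/`r` networks are left
#' unclipped by default.
#'
#' @param par a [gpgan_params()] object (modified in place, also returned).
#' @param c positive clip bound.
#' @param include extra network names to clip (subset of
#'   `c("D", "h", "r")`).
#' @return `par`, invisibly.
#' @export
clip_parameters <- function(par, c = 1.0, include = character(),
                            which_nets = NULL) {
  if (c <= 0) stop("clip bound must be positive")
  nets <- if (is.null(which_nets))
    list(par$f, par$g_trunk, par$g1_head, par$g2_head)
  else par[which_nets]
  if ("D" %in% include) nets <- c(nets, list(par$D))
  if ("h" %in% include && !is.null(par$h)) nets <- c(nets, list(par$h))
  if ("r" %in% include && !is.null(par$r_trunk))
    nets <- c(nets, list(par$r_trunk, par$r_mu, par$r_sigma))
  for (net in nets) {
    for (p in mlp_params(net)) {
      p$value <- pmin(pmax(p$value, -c), c)
    }
  }
  invisible(par)
}

#' Categorical prior over subtypes implied by the trained logits
#' @param par a [gpgan_params()] object.
#' @return probability vector of length `M` (sums to 1).
#' @export
subtype_prior <- function(par) {
  as.vector(ad_value(ad_softmax_rows(ad_const(par$theta_z1$value))))
}

# Serialize parameter values to plain lists (text-friendly checkpointing).
params_to_list <- function(par) {
  take <- function(layers) lapply(layers, function(l)
    list(W = l$W$value, b = l$b$value))
  out <- list(f = take(par$f), D = take(par$D), g_trunk = take(par$g_trunk),
              g1_head = take(par$g1_head), g2_head = take(par$g2_head),
              theta_z1 = par$theta_z1$value,
              spec = unclass(par$spec), n_features = par$n_features,
              n_snps = par$n_snps, hidden = par$hidden, version = 1L)
  if (par$n_snps > 0L) {
    out$h <- take(par$h); out$r_trunk <- take(par$r_trunk)
    out$r_mu <- take(par$r_mu); out$r_sigma <- take(par$r_sigma)
  }
  out
}

# Rebuild from the compiled engine's output (already matrix-valued lists).
params_from_list_cpp <- function(x) {
  params_from_list(x)
}

params_from_list <- function(x) {
  spec <- latent_spec(x$spec$M, x$spec$n_z2, x$spec$n_z3)
  par <- gpgan_params(x$n_features, x$n_snps, spec, hidden = x$hidden)
  put <- function(layers, saved) {
    for (i in seq_along(layers)) {
      layers[[i]]$W$value <- .as_mat(saved[[i]]$W)
      layers[[i]]$b$value <- .as_mat(saved[[i]]$b)
    }
  }
  put(par$f, x$f); put(par$D, x$D); put(par$g_trunk, x$g_trunk)
  put(par$g1_head, x$g1_head); put(par$g2_head, x$g2_head)
  par$theta_z1$value <- .as_mat(x$theta_z1)
  if (x$n_snps > 0L) {
    put(par$h, x$h); put(par$r_trunk, x$r_trunk)
    put(par$r_mu, x$r_mu); put(par$r_sigma, x$r_sigma)
  }
  par
}
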