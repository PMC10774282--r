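# Training loop (alternating Phenotype / Gene optimization), assignment
# stopping rule, stratified hold-out cross-validation with gene-lr
# selection, and the consensus (ensemble) subtyping.

#' Train the subtype model
#'
#' Alternates, per iteration: (i) a discriminator update maximizing the
#' adversarial loss; (ii) a generator-side update of the transformation
#' network, the inverse mapping and the categorical-prior logits on the
#' full Phenotype-step objective; (iii) weight clipping of the
#' Lipschitz-constrained networks; (iv) a Gene-step update of the decoder,
#' inverse-mapping and variational-encoder weights at `gene_lr`.  Training
#' stops at `max_iterations` or when the dominant subtype assignment is
#' stable across checkpoints (see [stopping_rule()]).  Deterministic given
#' `config$seed`.
#'
#' @param phenotypes a standardized [cohort_table()] with REF and TAR rows.
#' @param genotypes NULL for a phenotype-only model, or the result of
#'   [recode_and_impute()] aligned to the TAR rows.
#' @param config a [gpgan_config()].
#' @param engine "cpp" (compiled, default) or "r" (reference
#'   implementation via the in-package autodiff; identical losses, used for
#'   cross-checking).
#' @return object of class `gpgan_model`: parameters, loss history,
#'   stopping diagnostics, and the config snapshot.
#' @export
train_gpgan <- function(phenotypes, genotypes = NULL, config = gpgan_config(),
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  spec <- latent_spec(config$M, config$n_z2, config$n_z3)
  x_all <- phenotypes$features[phenotypes$group == "REF", , drop = FALSE]
  y_all <- phenotypes$features[phenotypes$group == "TAR", , drop = FALSE]
  tar_ids <- phenotypes$participant_id[phenotypes$group == "TAR"]
  n_ref <- nrow(x_all); n_tar <- nrow(y_all)
  if (n_ref < 1L || n_tar < config$batch_size)
    stop("need at least one REF row and batch_size TAR rows")
  use_gene <- !is.null(genotypes)
  if (use_gene) {
    if (!identical(genotypes$participant_id, tar_ids))
      stop("genotypes must be aligned to the TAR participants")
    v <- genotypes$imputed
    vmask <- genotypes$observed
  }
  set.seed(config$seed)
  par <- gpgan_params(ncol(x_all), if (use_gene) ncol(v) else 0L, spec,
                      hidden = config$hidden)
  if (engine == "cpp") {
    cfg_cpp <- c(unclass(config), list(stop_threshold = 0.99,
                                       stop_window = 3L))
    res <- .cpp_train_core(params_to_list(par), x_all, y_all,
                           if (use_gene) v else matrix(0, 0, 0),
                           if (use_gene) vmask * 1 else matrix(0, 0, 0),
                           cfg_cpp)
    par_out <- params_from_list_cpp(res$par)
    return(structure(list(par = par_out, history = res$history,
                          assign_history = lapply(res$assign_history,
                                                  as.integer),
                          stopped_at = res$stopped_at,
                          feature_names = colnames(x_all),
                          snp_ids = if (use_gene) genotypes$snp_ids
                                    else character(0),
                          config = config, spec = spec),
                     class = "gpgan_model"))
  }
  opt_D <- adam_new(params_discriminator(par), config$phenotype_lr)
  opt_G <- adam_new(params_generator(par), config$phenotype_lr)
  if (use_gene) opt_E <- adam_new(params_gene(par), config$gene_lr)

  bs <- config$batch_size
  hist_len <- config$max_iterations %/% config$checkpoint_every + 1L
  history <- data.frame(iteration = integer(0), loss_D = numeric(0),
                        loss_gen = numeric(0), change = numeric(0),
                        recons = numeric(0), gene_nll = numeric(0),
                        gene_kl = numeric(0))
  assign_history <- list()
  stopped_at <- config$max_iterations
  acc_D <- acc_G <- acc_ch <- acc_rc <- acc_nll <- acc_kl <- 0
  n_acc <- 0L

  for (d in seq_len(config$d_warmup)) {
    xd <- x_all[sample.int(n_ref, bs, replace = n_ref < bs), , drop = FALSE]
    yd <- y_all[sample.int(n_tar, bs, replace = FALSE), , drop = FALSE]
    lat_d <- sample_latents(par$theta_z1, bs, spec)
    gl_d <- gan_losses(par, xd, yd, lat = lat_d, kappa = config$kappa)
    zero_grads(opt_D$params)
    ad_backward(gl_d$loss_D)
    opt_D <- adam_step(opt_D, lr = config$d_lr)
  }
  for (it in seq_len(config$max_iterations)) {
    loss_D_val <- NA_real_
    for (d in seq_len(config$d_steps)) {
      xd <- x_all[sample.int(n_ref, bs, replace = n_ref < bs), , drop = FALSE]
      yd <- y_all[sample.int(n_tar, bs, replace = FALSE), , drop = FALSE]
      lat_d <- sample_latents(par$theta_z1, bs, spec)
      gl_d <- gan_losses(par, xd, yd, lat = lat_d, kappa = config$kappa)
      zero_grads(opt_D$params)
      ad_backward(gl_d$loss_D)
      opt_D <- adam_step(opt_D, lr = config$d_lr)
      loss_D_val <- ad_value(gl_d$loss_D)[1]
    }
    xb <- x_all[sample.int(n_ref, bs, replace = n_ref < bs), , drop = FALSE]
    yi <- sample.int(n_tar, bs, replace = FALSE)
    yb <- y_all[yi, , drop = FALSE]

    lat <- sample_latents(par$theta_z1, bs, spec)
    gl <- gan_losses(par, xb, yb, lat = lat, kappa = config$kappa)

    gz <- net_g(par, gl$y_syn)
    rec <- reconstruction_loss(lat$z1, gz$z1, lat$z2, gz$z2)
    ch <- change_loss(xb, gl$y_syn)
    total <- phenotype_objective(list(loss_gen = gl$loss_gen, change = ch,
                                      ce = rec$ce, l2 = rec$l2),
                                 mu = config$mu, lambda = config$lambda)
    if (!is.finite(ad_value(total)[1]))
      stop(sprintf(
        "non-finite generator loss at iteration %d (gan=%.3g change=%.3g ce=%.3g l2=%.3g)",
        it, ad_value(gl$loss_gen)[1], ad_value(ch)[1],
        ad_value(rec$ce)[1], ad_value(rec$l2)[1]))
    zero_grads(opt_G$params)
    ad_backward(total)
    opt_G <- adam_step(opt_G)
    clip_parameters(par, config$clip_c)

    if (use_gene) {
      gn <- gene_step_loss(par, v[yi, , drop = FALSE],
                           vmask[yi, , drop = FALSE], yb)
      gene_total <- ad_add(gn$nll, gn$kl)
      if (!is.finite(ad_value(gene_total)[1]))
        stop(sprintf("non-finite gene loss at iteration %d", it))
      zero_grads(opt_E$params)
      ad_backward(gene_total)
      opt_E <- adam_step(opt_E)
      clip_parameters(par, config$clip_c,
                      which_nets = c("g_trunk", "g1_head"))
      acc_nll <- acc_nll + ad_value(gn$nll)[1]
      acc_kl <- acc_kl + ad_value(gn$kl)[1]
    }

    acc_D <- acc_D + loss_D_val
    acc_G <- acc_G + ad_value(gl$loss_gen)[1]
    acc_ch <- acc_ch + ad_value(ch)[1]
    acc_rc <- acc_rc + ad_value(rec$ce)[1] + ad_value(rec$l2)[1]
    n_acc <- n_acc + 1L

    if (it %% config$checkpoint_every == 0L || it == config$max_iterations) {
      probs <- ad_value(net_g(par, ad_const(y_all))$z1)
      dominant <- max.col(probs, ties.method = "first")
      assign_history[[length(assign_history) + 1L]] <- dominant
      history <- rbind(history, data.frame(
        iteration = it, loss_D = acc_D / n_acc, loss_gen = acc_G / n_acc,
        change = acc_ch / n_acc, recons = acc_rc / n_acc,
        gene_nll = if (use_gene) acc_nll / n_acc else NA_real_,
        gene_kl = if (use_gene) acc_kl / n_acc else NA_real_))
      acc_D <- acc_G <- acc_ch <- acc_rc <- acc_nll <- acc_kl <- 0
      n_acc <- 0L
      if (it >= config$min_iterations && stopping_rule(assign_history)) {
        stopped_at <- it
        gpgan_log("debug", "assignment-stability stopping rule fired at ",
                  it)
        break
      }
    }
  }
  structure(list(par = par, history = history,
                 assign_history = assign_history,
                 stopped_at = stopped_at,
                 feature_names = colnames(x_all),
                 snp_ids = if (use_gene) genotypes$snp_ids else character(0),
                 config = config, spec = spec),
            class = "gpgan_model")
}

#' @export
print.gpgan_model <- function(x, ...) {
  cat(sprintf(
    "<gpgan_model> M=%d, %d features, %d SNPs; stopped at iteration %d\n",
    x$spec$M, length(x$feature_names), length(x$snp_ids), x$stopped_at))
  invisible(x)
}

#' Assignment-stability stopping rule
#'
#' TRUE when the fraction of target participants whose dominant subtype is
#' unchanged between consecutive checkpoints strictly exceeds `threshold`
#' for `window` consecutive checkpoint pairs.
#'
#' @param assign_history list of dominant-label vectors, one per checkpoint.
#' @param threshold agreement fraction (strict).
#' @param window number of consecutive stable pairs required.
#' @return logical.
#' @export
stopping_rule <- function(assign_history, threshold = 0.99, window = 3L) {
  k <- length(assign_history)
  if (k < window + 1L) return(FALSE)
  for (j in (k - window + 1L):k) {
    agree <- mean(assign_history[[j]] == assign_history[[j - 1L]])
    if (!(agree > threshold)) return(FALSE)
  }
  TRUE
}

#' Save / load a model checkpoint (JSON text)
#'
#' @param model a `gpgan_model`.
#' @param path file path.
#' @export
write_checkpoint <- function(model, path) {
  payload <- list(format = "gpgan_checkpoint", version = 1L,
                  params = params_to_list(model$par),
                  feature_names = model$feature_names,
                  snp_ids = model$snp_ids,
                  config = unclass(model$config),
                  stopped_at = model$stopped_at)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @return for `read_checkpoint`, a `gpgan_model` (without training
#'   history).
#' @export
read_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "gpgan_checkpoint"))
    stop("not a model checkpoint: ", path)
  x$params$f <- .relist_layers(x$params$f)
  x$params$D <- .relist_layers(x$params$D)
  x$params$g_trunk <- .relist_layers(x$params$g_trunk)
  x$params$g1_head <- .relist_layers(x$params$g1_head)
  x$params$g2_head <- .relist_layers(x$params$g2_head)
  if (x$params$n_snps > 0) {
    x$params$h <- .relist_layers(x$params$h)
    x$params$r_trunk <- .relist_layers(x$params$r_trunk)
    x$params$r_mu <- .relist_layers(x$params$r_mu)
    x$params$r_sigma <- .relist_layers(x$params$r_sigma)
  }
  par <- params_from_list(x$params)
  cfg <- do.call(gpgan_config, x$config[names(x$config) %in%
                                          names(formals(gpgan_config))])
  structure(list(par = par, history = NULL, assign_history = NULL,
                 stopped_at = x$stopped_at,
                 feature_names = x$feature_names,
                 snp_ids = as.character(x$snp_ids), config = cfg,
                 spec = par$spec),
            class = "gpgan_model")
}

.relist_layers <- function(saved) {
  if (is.data.frame(saved)) saved <- split(saved, seq_len(nrow(saved)))
  lapply(saved, function(l) list(W = .as_mat(do.call(rbind, l$W)),
                                 b = .as_mat(unlist(l$b))))
}

#' Stratified hold-out cross-validation over the gene-lr grid
#'
#' For each repeat, the TAR rows are split into train/test (REF rows are
#' always fully reused as the reference distribution), stratified on the
#' `strata` labels when given.  Every grid value is trained on the same
#' split (paired comparison), test subtypes are assigned with the inverse
#' mapping, and the test association count (N-Asso-SNPs) is computed; the
#' selected gene-lr maximizes the mean test count, ties going to the
#' smaller value.
#'
#' @param phenotypes standardized [cohort_table()].
#' @param genotypes a [genotype_matrix()] over the TAR participants (raw
#'   counts with NA for missing; imputation is fit per training run).
#' @param config a [gpgan_config()]; `config$gene_lr_grid`,
#'   `config$n_repeats` and `config$test_fraction` drive the harness.
#' @param strata optional stratification labels for the TAR rows.
#' @param truth optional true subtype labels for the TAR rows; when given,
#'   train/test clustering accuracies are recorded.
#' @param covariates optional covariate matrix for the association test
#'   (defaults to the cohort covariates of the TAR rows).
#' @return list of class `gpgan_cv`: `records` (one row per repeat x grid
#'   value), `selected_gene_lr`, `summary`.
#' @export
holdout_cv <- function(phenotypes, genotypes, config = gpgan_config(),
                       strata = NULL, truth = NULL, covariates = NULL) {
  grid <- config$gene_lr_grid
  if (!length(grid)) stop("gene_lr_grid must be non-empty")
  tar_idx <- which(phenotypes$group == "TAR")
  n_tar <- length(tar_idx)
  tar_ids <- phenotypes$participant_id[tar_idx]
  if (is.null(covariates))
    covariates <- as.matrix(phenotypes$covariates[tar_idx, , drop = FALSE])
  if (is.null(strata)) strata <- rep(1L, n_tar)
  counts_all <- genotype_matrix(genotypes$participant_id,
                                genotypes$counts,
                                genotypes$snp_ids)
  ord <- match(tar_ids, counts_all$participant_id)
  if (anyNA(ord)) stop("genotypes missing for some TAR participants")
  counts <- counts_all$counts[ord, , drop = FALSE]

  records <- list()
  for (rep_i in seq_len(config$n_repeats)) {
    split_seed <- derive_seed(config$seed, 1000L + rep_i)
    set.seed(split_seed)
    test_idx <- unlist(lapply(split(seq_len(n_tar), strata), function(ix)
      sample(ix, max(1L, round(length(ix) * config$test_fraction)))))
    train_mask <- !(seq_len(n_tar) %in% test_idx)
    ph_train <- cohort_subset(phenotypes,
                              phenotypes$group == "REF" |
                                phenotypes$participant_id %in%
                                tar_ids[train_mask])
    for (g in seq_along(grid)) {
      cfg_g <- config
      cfg_g$gene_lr <- grid[g]
      cfg_g$seed <- derive_seed(split_seed, g)
      G_train <- genotype_matrix(tar_ids[train_mask],
                                 counts[train_mask, , drop = FALSE],
                                 colnames(counts))
      imp <- recode_and_impute(G_train)
      model <- train_gpgan(ph_train, imp, cfg_g)
      asg_train <- assign_subtypes(model, cohort_subset(
        phenotypes, phenotypes$participant_id %in% tar_ids[train_mask]))
      asg_test <- assign_subtypes(model, cohort_subset(
        phenotypes, phenotypes$participant_id %in% tar_ids[!train_mask]))
      llr_train <- lrt_table(asg_train$dominant,
                             counts[train_mask, , drop = FALSE],
                             covariates[train_mask, , drop = FALSE])$llr
      llr_test <- lrt_table(asg_test$dominant,
                            counts[!train_mask, , drop = FALSE],
                            covariates[!train_mask, , drop = FALSE])$llr
      rec <- data.frame(repeat_i = rep_i, gene_lr = grid[g],
                        n_asso_train = n_asso_snps(llr_train,
                                                   config$llr_threshold),
                        n_asso_test = n_asso_snps(llr_test,
                                                  config$llr_threshold))
      if (!is.null(truth)) {
        rec$acc_train <- clustering_accuracy(asg_train$dominant,
                                             truth[train_mask])$accuracy
        rec$acc_test <- clustering_accuracy(asg_test$dominant,
                                            truth[!train_mask])$accuracy
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  records <- do.call(rbind, records)
  means <- tapply(records$n_asso_test, records$gene_lr, mean)
  grid_sorted <- sort(grid)
  means <- means[as.character(grid_sorted)]
  selected <- grid_sorted[which.max(means)]   # which.max takes first = smallest on ties
  structure(list(records = records, selected_gene_lr = selected,
                 summary = data.frame(gene_lr = grid_sorted,
                                      mean_n_asso_test = as.vector(means))),
            class = "gpgan_cv")
}

#' Consensus (ensemble) subtype assignment
#'
#' Builds the participant co-assignment frequency matrix over the models'
#' dominant labels, cuts it into M groups by average-linkage agglomerative
#' clustering on (1 - frequency), and maps consensus groups to subtype
#' indices by majority alignment against the first model.  Deterministic
#' and invariant to label permutations of individual members.
#'
#' @param models list of `gpgan_model`s with identical latent spec.
#' @param phenotypes standardized [cohort_table()] of participants to
#'   assign (TAR rows are used).
#' @return data.frame: participant_id, consensus label `dominant`, and the
#'   fraction of models agreeing with the consensus (`support`).
#' @export
consensus_assign <- function(models, phenotypes) {
  if (!length(models)) stop("need at least one model")
  M <- models[[1L]]$spec$M
  for (m in models) if (m$spec$M != M) stop("models disagree on M")
  labels <- vapply(models, function(m)
    assign_subtypes(m, phenotypes)$dominant, integer(sum(phenotypes$group == "TAR")))
  labels <- matrix(labels, ncol = length(models))
  n <- nrow(labels)
  co <- matrix(0, n, n)
  for (k in seq_len(ncol(labels))) {
    lk <- labels[, k]
    co <- co + outer(lk, lk, "==")
  }
  co <- co / ncol(labels)
  if (length(models) == 1L || n <= M) {
    groups <- labels[, 1L]
  } else {
    hc <- stats::hclust(stats::as.dist(1 - co), method = "average")
    groups <- stats::cutree(hc, k = M)
    # merge spurious splits of perfectly co-assigned participants (arises
    # when the ensemble distinguishes fewer than M groups)
    repeat {
      gl <- sort(unique(groups))
      if (length(gl) < 2L) break
      merged <- FALSE
      for (a in seq_along(gl)) {
        for (b in seq_along(gl)) {
          if (b <= a) next
          between <- mean(co[groups == gl[a], groups == gl[b], drop = FALSE])
          if (between >= 0.999) {
            groups[groups == gl[b]] <- gl[a]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  # align consensus group indices to the first model's labels; groups that
  # cannot be matched (degenerate members) take the unused labels in order
  mapping <- clustering_accuracy(groups, labels[, 1L])$mapping
  dominant <- as.integer(mapping[as.character(groups)])
  if (anyNA(dominant)) {
    unmatched <- sort(unique(groups[is.na(dominant)]))
    free <- setdiff(seq_len(M), stats::na.omit(unique(dominant)))
    for (i in seq_along(unmatched)) {
      lbl <- if (i <= length(free)) free[i] else unmatched[i]
      dominant[groups == unmatched[i]] <- lbl
    }
  }
  ids <- phenotypes$participant_id[phenotypes$group == "TAR"]
  support <- vapply(seq_len(n), function(i) {
    same <- groups == groups[i]
    mean(co[i, same])
  }, 0)
  data.frame(participant_id = ids, dominant = dominant, support = support,
             stringsAsFactors = FALSE)
}
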