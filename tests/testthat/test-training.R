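small_cfg <- function(...) {
  gpgan_config(M = 2, n_z2 = 2, n_z3 = 2, batch_size = 16,
               max_iterations = 60, min_iterations = 60, d_warmup = 10,
               checkpoint_every = 30, hidden = 8, ...)
}

test_that("training returns finite loss history and respects max_iterations", {
  sc <- signal_cohort()
  G <- tiny_genotypes(n = 120, n_snp = 6, seed = 2,
                      ids = sc$table$participant_id[121:240])
  imp <- recode_and_impute(G)
  m <- train_gpgan(sc$table, imp, small_cfg(seed = 1))
  expect_s3_class(m, "gpgan_model")
  expect_lte(max(m$history$iteration), 60)
  expect_true(all(is.finite(m$history$loss_D)))
  expect_true(all(is.finite(m$history$loss_gen)))
  expect_true(all(is.finite(m$history$gene_nll)))
  expect_equal(length(m$assign_history[[1]]), 120L)
})

test_that("identical seeds give identical trained parameters", {
  sc <- signal_cohort()
  m1 <- train_gpgan(sc$table, NULL, small_cfg(seed = 7))
  m2 <- train_gpgan(sc$table, NULL, small_cfg(seed = 7))
  expect_identical(params_to_list(m1$par), params_to_list(m2$par))
  m3 <- train_gpgan(sc$table, NULL, small_cfg(seed = 8))
  expect_false(identical(params_to_list(m1$par)$f, params_to_list(m3$par)$f))
})

test_that("compiled and reference engines both run the same protocol", {
  sc <- signal_cohort(n_ref = 40, n_tar = 40, n_feat = 6)
  cfg <- small_cfg(seed = 3)
  cfg$max_iterations <- 20L
  cfg$min_iterations <- 20L
  cfg$checkpoint_every <- 10L
  cfg$d_warmup <- 5L
  m_cpp <- train_gpgan(sc$table, NULL, cfg, engine = "cpp")
  m_r <- train_gpgan(sc$table, NULL, cfg, engine = "r")
  # same shapes and finite losses from both engines (stochastic paths differ)
  expect_equal(dim(m_cpp$history), dim(m_r$history))
  expect_true(all(is.finite(m_r$history$loss_D)))
  expect_true(all(is.finite(m_cpp$history$loss_D)))
})

test_that("stopping rule requires strict stability over the window", {
  a <- rep(1L, 100)
  b <- a; b[1] <- 2L   # 99% agreement, not > 99%
  expect_true(stopping_rule(list(a, a, a, a)))
  expect_false(stopping_rule(list(a, b, a, b)))
  expect_false(stopping_rule(list(a, a, a)))          # too few checkpoints
  expect_false(stopping_rule(list(b, b, b, a)))
  c985 <- a; c985[1:2] <- 2L
  expect_false(stopping_rule(list(a, c985, a, c985))) # 98% twice
})

test_that("consensus of a single model equals its own assignment; duplication is a no-op", {
  sc <- signal_cohort(n_ref = 40, n_tar = 40, n_feat = 6)
  cfg <- small_cfg(seed = 4)
  cfg$max_iterations <- 30L
  m <- train_gpgan(sc$table, NULL, cfg)
  single <- consensus_assign(list(m), sc$table)
  own <- assign_subtypes(m, sc$table)
  expect_equal(single$dominant, own$dominant)
  dup <- consensus_assign(list(m, m, m), sc$table)
  expect_equal(dup$dominant, own$dominant)
})

test_that("consensus is invariant to label permutations of members", {
  sc <- signal_cohort(n_ref = 40, n_tar = 40, n_feat = 6)
  cfg <- small_cfg(seed = 5)
  cfg$max_iterations <- 30L
  m <- train_gpgan(sc$table, NULL, cfg)
  # permute subtype labels of a copy by swapping the g1 head outputs
  tmp <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(m, tmp)
  m_perm <- read_checkpoint(tmp)
  W <- m_perm$par$g1_head[[1]]$W$value
  b <- m_perm$par$g1_head[[1]]$b$value
  m_perm$par$g1_head[[1]]$W$value <- W[, c(2, 1)]
  m_perm$par$g1_head[[1]]$b$value <- b[, c(2, 1), drop = FALSE]
  a1 <- assign_subtypes(m, sc$table)$dominant
  a2 <- assign_subtypes(m_perm, sc$table)$dominant
  expect_equal(a2, c(2L, 1L)[a1])   # pure relabel
  cons <- consensus_assign(list(m, m_perm), sc$table)
  expect_equal(clustering_accuracy(cons$dominant, a1)$accuracy, 1)
  expect_error(consensus_assign(list(), sc$table), "at least one")
})

test_that("co-assignment support is a valid frequency", {
  sc <- signal_cohort(n_ref = 40, n_tar = 40, n_feat = 6)
  cfg <- small_cfg(seed = 6)
  cfg$max_iterations <- 30L
  models <- lapply(1:3, function(s) {
    cfg$seed <- s
    train_gpgan(sc$table, NULL, cfg)
  })
  cons <- consensus_assign(models, sc$table)
  expect_true(all(cons$support >= 0 & cons$support <= 1))
  expect_equal(nrow(cons), 40L)
})

test_that("hold-out CV produces repeats x grid records and selects by mean test count", {
  set.seed(10)
  sc <- signal_cohort(n_ref = 60, n_tar = 60, n_feat = 8, shift = 0.6)
  # genotypes with subtype-linked SNPs so the metric is informative
  counts <- matrix(rbinom(60 * 8, 2, 0.3), 60, 8)
  counts[sc$subtype == 1, 1:2] <- matrix(rbinom(sum(sc$subtype == 1) * 2, 2, 0.6),
                                         ncol = 2)
  G <- genotype_matrix(sc$table$participant_id[61:120], counts,
                       sprintf("rs%02d", 1:8))
  cfg <- small_cfg(seed = 11)
  cfg$max_iterations <- 40L
  cfg$min_iterations <- 40L
  cfg$n_repeats <- 1L
  cfg$gene_lr_grid <- c(1e-4, 2e-4)
  cv <- holdout_cv(sc$table, G, cfg, truth = sc$subtype)
  expect_equal(nrow(cv$records), 2L)
  expect_true(all(c("n_asso_train", "n_asso_test", "acc_train", "acc_test")
                  %in% names(cv$records)))
  means <- tapply(cv$records$n_asso_test, cv$records$gene_lr, mean)
  expect_equal(cv$selected_gene_lr,
               as.numeric(names(means))[which.max(means)])
  cfg$gene_lr_grid <- 5e-5
  cv1 <- holdout_cv(sc$table, G, cfg)
  expect_equal(cv1$selected_gene_lr, 5e-5)
})

test_that("strong-signal micro-cohort: held-out accuracy above 0.9 in most seeds", {
  hits <- vapply(1:5, function(s) {
    sim <- sim_config(n_ref = 200, n_pt = 400, n_roi = 30, M_true = 2,
                      roi_set_size = 10, n_confound_imaging = 0,
                      n_genetic = 20, n_confound_genetic = 0, seed = 700 + s)
    cohort <- semi_synthetic_cohort(sim)
    std <- apply_standardization(cohort$phenotypes,
                                 fit_residualizer(cohort$phenotypes))
    truth <- cohort$truth$true_subtype
    set.seed(900 + s)
    test_mask <- seq_along(truth) %in% sample(length(truth), 80)
    tar_ids <- cohort$truth$participant_id
    keep_train <- std$group == "REF" |
      std$participant_id %in% tar_ids[!test_mask]
    G_train <- genotype_matrix(tar_ids[!test_mask],
                               cohort$genotypes$counts[!test_mask, ,
                                                       drop = FALSE],
                               cohort$genotypes$snp_ids)
    model <- train_gpgan(cohort_subset(std, keep_train),
                         recode_and_impute(G_train),
                         validation_config(seed = 800 + s, M = 2L,
                                           max_iterations = 2500L,
                                           min_iterations = 1500L))
    test_tab <- cohort_subset(std, std$participant_id %in% tar_ids[test_mask])
    acc <- clustering_accuracy(assign_subtypes(model, test_tab)$dominant,
                               truth[test_mask])$accuracy
    acc > 0.9
  }, NA)
  expect_gte(sum(hits), 4L)
})
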