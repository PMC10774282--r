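test_that("base population has the right shape, positivity, and degenerate limit", {
  tab <- generate_base_population(100, 10, seed = 1)
  expect_equal(dim(tab$features), c(100L, 10L))
  expect_true(all(tab$features > 0))
  flat <- generate_base_population(
    5, 4, cov_model = list(age = 0, sex = 0, icv = 0, noise_sd = 0,
                           baseline = c(10, 20, 30, 40)), seed = 1)
  expect_equal(unname(flat$features),
               matrix(c(10, 20, 30, 40), 5, 4, byrow = TRUE))
  expect_error(generate_base_population(
    5, 2, cov_model = list(age = 0, sex = 0, icv = 0, noise_sd = 0,
                           baseline = c(-1, 1)), seed = 1), "positive")
})

test_that("log-volume age slope is recovered by OLS on generated data", {
  tab <- generate_base_population(5000, 3, seed = 2)
  slope <- coef(lm(log(tab$features[, 1]) ~ tab$covariates$age))[2]
  expect_equal(unname(slope), -0.005, tolerance = 0.2)
  expect_lt(abs(slope - (-0.005)), 0.001)
})

test_that("semi-synthetic split reproduces the published group sizes and subtype balance", {
  cfg <- sim_config(seed = 3)
  base <- generate_base_population(cfg$n_ref + cfg$n_pt, cfg$n_roi,
                                   cfg$cov_model, seed = 4)
  cohort <- build_semi_synthetic(base, cfg)
  expect_equal(sum(cohort$phenotypes$group == "REF"), 539L)
  expect_equal(sum(cohort$phenotypes$group == "TAR"), 1200L)
  expect_equal(as.integer(table(cohort$truth$true_subtype)),
               c(400L, 400L, 400L))
})

test_that("imposed ratios are exactly recoverable and bounded", {
  cfg <- sim_config(n_ref = 50, n_pt = 90, n_roi = 30, roi_set_size = 5,
                    seed = 5)
  base <- generate_base_population(140, 30, cfg$cov_model, seed = 6)
  cohort <- build_semi_synthetic(base, cfg)
  tar <- cohort$phenotypes$group == "TAR"
  imposed <- cohort$truth$imposed_ratio
  expect_true(all(imposed >= 0 & imposed < 0.51))
  # conservation: phenotype = base-after-split x (1 - ratio) entrywise
  base_vals <- cohort$phenotypes$features[tar, ] / (1 - imposed)
  # unaffected entries identical to base (ratio 0 entries unchanged)
  expect_true(all(abs(
    cohort$phenotypes$features[tar, ][imposed == 0] -
      base_vals[imposed == 0]) < 1e-12))
  # each pseudo-patient's subtype ROI set is affected
  sets <- cohort$truth$subtype_roi_sets
  for (i in seq_len(sum(tar))) {
    m <- cohort$truth$true_subtype[i]
    expect_true(all(imposed[i, sets[[m]]] > 0 | imposed[i, sets[[m]]] == 0))
    others <- setdiff(unlist(sets), sets[[m]])
    expect_true(all(imposed[i, others] == 0))
  }
})

test_that("mean imposed change ratio calibrates to 0.15", {
  cfg <- sim_config(seed = 7)
  cohort <- semi_synthetic_cohort(cfg)
  r <- cohort$truth$imposed_ratio
  sets <- cohort$truth$subtype_roi_sets
  vals <- unlist(lapply(1:3, function(m)
    r[cohort$truth$true_subtype == m, sets[[m]]]))
  expect_gt(length(vals), 10000)
  expect_equal(mean(vals), 0.15, tolerance = 0.035)
  expect_lt(abs(mean(vals) - 0.15), 0.005)
})

test_that("genotype law: counts in {0,1,2}, background MAF 0.33, subtype MAF 0.48", {
  cfg <- sim_config(seed = 8)
  cohort <- semi_synthetic_cohort(cfg)
  G <- cohort$genotypes
  expect_true(all(G$counts[!G$missing_mask] %in% 0:2))
  assoc <- unlist(cohort$truth$assoc_snps)
  confound <- unlist(cohort$truth$confound_snps)
  neutral <- setdiff(seq_len(ncol(G$counts)), c(assoc, confound))
  maf_neutral <- mean(G$counts[, neutral]) / 2
  expect_equal(maf_neutral, 0.33, tolerance = 0.02)
  # within-subtype MAF of associated SNPs, pooled over subtypes
  vals <- unlist(lapply(1:3, function(m)
    G$counts[cohort$truth$true_subtype == m, cohort$truth$assoc_snps[[m]]]))
  expect_equal(mean(vals) / 2, 0.48, tolerance = 0.03)
})

test_that("genotype cells follow Binomial(2, p) (chi-squared goodness of fit)", {
  cfg <- sim_config(n_pt = 9999, n_ref = 10, n_roi = 30, roi_set_size = 5,
                    n_genetic = 20, seed = 9)
  base <- generate_base_population(10009, 30, cfg$cov_model, seed = 10)
  cohort <- build_semi_synthetic(base, cfg)
  G <- simulate_genotypes(cohort$truth, cfg)
  assoc <- attr(G, "assoc_snps")
  neutral <- setdiff(seq_len(20), c(unlist(assoc),
                                    unlist(attr(G, "confound_snps"))))
  check_cell <- function(counts, p) {
    obs <- tabulate(counts + 1L, 3L)
    expected <- length(counts) * stats::dbinom(0:2, 2, p)
    stats::chisq.test(obs, p = expected / sum(expected))$p.value
  }
  expect_gt(check_cell(G$counts[, neutral[1]], 0.33), 0.01)
  m1 <- cohort$truth$true_subtype == 1
  expect_gt(check_cell(G$counts[m1, assoc[[1]][1]], 0.48), 0.01)
  expect_gt(check_cell(G$counts[!m1, assoc[[1]][1]], 0.33), 0.01)
})

test_that("confounder membership is independent of true subtype", {
  pvals <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s)
    cohort <- semi_synthetic_cohort(cfg)
    memb <- cohort$truth$confound_membership[[1]]
    suppressWarnings(stats::chisq.test(
      table(memb, cohort$truth$true_subtype))$p.value)
  }, 0)
  expect_gt(min(pvals), 0.001)
  expect_gt(mean(pvals > 0.05), 0.5)
})

test_that("missing-masking matches the rate, preserves the rest, and is seed-stable", {
  cfg <- sim_config(seed = 12)
  cohort <- semi_synthetic_cohort(cfg)
  G <- cohort$genotypes
  expect_identical(mask_missing(G, 0, seed = 1), G)
  Gm <- mask_missing(G, 0.3, seed = 2)
  expect_equal(mean(Gm$missing_mask), 0.3, tolerance = 0.01)
  keep <- !Gm$missing_mask
  expect_equal(Gm$counts[keep], G$counts[keep])
  Gm2 <- mask_missing(G, 0.3, seed = 2)
  expect_identical(Gm$missing_mask, Gm2$missing_mask)
  expect_error(mask_missing(G, 1.2), "rate")
})

test_that("the whole cohort is bit-reproducible given its seed", {
  a <- semi_synthetic_cohort(sim_config(n_ref = 30, n_pt = 60, n_roi = 20,
                                        roi_set_size = 4, n_genetic = 20,
                                        seed = 13))
  b <- semi_synthetic_cohort(sim_config(n_ref = 30, n_pt = 60, n_roi = 20,
                                        roi_set_size = 4, n_genetic = 20,
                                        seed = 13))
  expect_identical(a$phenotypes$features, b$phenotypes$features)
  expect_identical(a$genotypes$counts, b$genotypes$counts)
  expect_identical(a$truth$true_subtype, b$truth$true_subtype)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
  expect_error(sim_config(background_maf = 0.9, delta_maf = 0.2), "< 1")
  expect_error(sim_config(n_genetic = 10, snps_per_subtype = 4, M_true = 3),
               "exceeds n_genetic")
  expect_error(sim_config(n_roi = 20, roi_set_size = 15), "exceed n_roi")
})
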