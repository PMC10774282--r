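test_that("intercept-only multinomial loglik equals the closed form", {
  set.seed(1)
  labels <- sample(1:3, 200, TRUE, prob = c(0.5, 0.3, 0.2))
  fit <- fit_multinomial_logistic(labels)
  n_m <- table(labels)
  expected <- sum(n_m * log(n_m / length(labels)))
  expect_equal(fit$loglik, expected, tolerance = 1e-8)
})

test_that("two-class multinomial fit matches binary logistic regression", {
  set.seed(2)
  n <- 300
  x <- cbind(a = rnorm(n), b = rnorm(n))
  eta <- 0.5 + 1.2 * x[, 1] - 0.7 * x[, 2]
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  fit <- fit_multinomial_logistic(y + 1L, x)
  ref <- stats::glm(y ~ x, family = binomial())
  expect_equal(as.vector(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("multinomial loglik agrees with a derivative-free oracle on a tiny instance", {
  set.seed(3)
  n <- 30
  x <- rnorm(n)
  labels <- sample(1:3, n, TRUE)
  fit <- fit_multinomial_logistic(labels, cbind(x = x))
  nll <- function(theta) {
    B <- matrix(theta, 2, 2)
    eta <- cbind(0, cbind(1, x) %*% B)
    -sum(eta[cbind(seq_len(n), labels)] - log(rowSums(exp(eta))))
  }
  oracle <- stats::optim(rep(0, 4), nll, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(fit$loglik, -oracle$value, tolerance = 1e-4)
})

test_that("multinomial fit matches nnet::multinom on a random 3-class problem", {
  skip_if_not_installed("nnet")
  set.seed(4)
  n <- 250
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  labels <- sample(1:3, n, TRUE)
  fit <- fit_multinomial_logistic(labels, X)
  ref <- nnet::multinom(factor(labels) ~ X, trace = FALSE, reltol = 1e-12)
  expect_equal(fit$loglik, -ref$value, tolerance = 1e-5)
})

test_that("categorical-SNP LRT without covariates equals the contingency G-statistic", {
  set.seed(5)
  for (rep_i in 1:5) {
    n <- 150
    labels <- sample(1:3, n, TRUE)
    snp <- sample(0:2, n, TRUE, prob = c(0.45, 0.4, 0.15))
    # SNP entered as two indicator columns = fully categorical model
    ind <- cbind(het = as.numeric(snp == 1), hom = as.numeric(snp == 2))
    full <- fit_multinomial_logistic(labels, ind)
    red <- fit_multinomial_logistic(labels)
    llr <- 2 * (full$loglik - red$loglik)
    O <- table(factor(labels, 1:3), factor(snp, 0:2))
    O <- O[rowSums(O) > 0, colSums(O) > 0, drop = FALSE]
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    G <- 2 * sum(O * log(O / E), na.rm = TRUE)
    expect_equal(llr, G, tolerance = 1e-6)
  }
})

test_that("lrt_snp: deviance is non-negative, constant SNP gives p = 1, missing dropped pairwise", {
  set.seed(6)
  labels <- sample(1:3, 120, TRUE)
  snp <- sample(0:2, 120, TRUE)
  res <- lrt_snp(labels, snp)
  expect_gte(res$llr, 0)
  expect_equal(res$df, 2L)
  expect_equal(lrt_snp(labels, rep(1, 120))$p, 1)
  snp_na <- snp
  snp_na[1:20] <- NA
  expect_equal(lrt_snp(labels, snp_na)$n_used, 100L)
})

test_that("permutation null of lrt_snp yields uniform p-values", {
  set.seed(7)
  n <- 400
  labels <- sample(1:3, n, TRUE)
  covs <- cbind(age = rnorm(n, 65, 5))
  p <- replicate(200, {
    snp <- sample(0:2, n, TRUE, prob = c(0.45, 0.44, 0.11))
    lrt_snp(labels, snp, covs)$p
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("n_asso_snps counts strictly above the threshold", {
  expect_equal(n_asso_snps(rep(0, 5)), 0L)
  expect_equal(n_asso_snps(c(4.0, 3.8, 10.2)), 2L)
  expect_equal(n_asso_snps(c(3.841, 3.8411)), 1L)
})

test_that("p-value adjustment matches the published Bonferroni threshold and the BH step-up formula", {
  res <- adjust_pvalues(runif(178), "bonferroni")
  expect_equal(res$threshold, 0.05 / 178)
  expect_equal(signif(res$threshold, 3), 2.81e-4)
  expect_equal(adjust_pvalues(0.03, "bonferroni")$adjusted, 0.03)
  bh <- adjust_pvalues(c(0.01, 0.02, 0.03), "bh")
  expect_equal(bh$adjusted, c(0.03, 0.03, 0.03))
  set.seed(8)
  p <- runif(50)
  both <- cbind(adjust_pvalues(p, "bonferroni")$adjusted,
                adjust_pvalues(p, "bh")$adjusted)
  expect_true(all(both[, 1] >= both[, 2]))
})

test_that("clustering accuracy is bijection-aligned and matches exhaustive search", {
  truth <- c(1, 1, 2, 2, 3, 3)
  expect_equal(clustering_accuracy(truth, truth)$accuracy, 1)
  perm <- c(3, 3, 1, 1, 2, 2)
  expect_equal(clustering_accuracy(perm, truth)$accuracy, 1)
  pred <- c(1, 2, 2, 3, 3, 1)
  expect_equal(clustering_accuracy(pred, truth)$accuracy, 0.5)
  set.seed(9)
  pred2 <- sample(1:3, 40, TRUE)
  truth2 <- sample(1:3, 40, TRUE)
  brute <- max(apply(.permutations(3), 1, function(pm)
    mean(pm[pred2] == truth2)))
  expect_equal(clustering_accuracy(pred2, truth2)$accuracy, brute)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(10)
  x <- rnorm(20)
  y <- rnorm(25, 0.5)
  res <- anova_across_groups(c(x, y), rep(1:2, c(20, 25)))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(anova_across_groups(c(1, 2, 3, 1, 2, 3),
                                   rep(1:2, each = 3))$F, 0)
})

test_that("ANOVA type-I error is calibrated at the nominal level", {
  set.seed(11)
  rejections <- mean(replicate(1000, {
    v <- rnorm(60)
    anova_across_groups(v, rep(1:3, each = 20))$p < 0.05
  }))
  expect_gte(rejections, 0.03)
  expect_lte(rejections, 0.07)
})
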