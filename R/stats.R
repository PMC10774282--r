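# Association and evaluation statistics: multinomial-logistic
# likelihood-ratio SNP-subtype tests with covariates, the association-count
# model-selection metric, multiple-testing corrections, bijection-aligned
# clustering accuracy, and one-way ANOVA across subtypes.

#' Fit a multinomial logistic regression by Newton iterations
#'
#' Baseline-category parametrization (category 1 is the baseline); the full
#' Newton step uses the exact Hessian with a small ridge jitter for
#' stability.  Convergence is declared when the relative log-likelihood
#' change falls below `tol`.
#'
#' @param labels integer vector of class labels in `1..M`.
#' @param X design matrix (an intercept column is added internally).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @param ridge Hessian jitter.
#' @return list with `loglik`, `coefficients` (p x (M-1) matrix including
#'   the intercept row), `iterations`, `converged`.
#' @export
fit_multinomial_logistic <- function(labels, X = NULL, tol = 1e-8,
                                     max_iter = 200L, ridge = 1e-8) {
  labels <- as.integer(labels)
  M <- max(labels)
  n <- length(labels)
  if (min(labels) < 1L) stop("labels must be positive integers 1..M")
  Xd <- if (is.null(X)) matrix(1, n, 1L) else cbind(1, as.matrix(X))
  cn <- if (is.null(X)) character(0) else colnames(as.matrix(X))
  if (is.null(cn) || length(cn) != ncol(Xd) - 1L)
    cn <- sprintf("x%d", seq_len(ncol(Xd) - 1L))
  colnames(Xd) <- c("(intercept)", cn)
  p <- ncol(Xd)
  if (n <= p * (M - 1L)) stop("more parameters than observations")
  Y <- matrix(0, n, M)
  Y[cbind(seq_len(n), labels)] <- 1
  B <- matrix(0, p, M - 1L)                 # baseline category = 1
  loglik <- function(B) {
    eta <- cbind(0, Xd %*% B)
    eta <- eta - apply(eta, 1L, max)
    sum(eta[cbind(seq_len(n), labels)]) - sum(log(rowSums(exp(eta))))
  }
  ll_old <- loglik(B)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    eta <- cbind(0, Xd %*% B)
    eta <- eta - apply(eta, 1L, max)
    P <- exp(eta) / rowSums(exp(eta))       # n x M
    grad <- as.vector(t(Xd) %*% (Y[, -1L, drop = FALSE] -
                                   P[, -1L, drop = FALSE]))
    H <- matrix(0, p * (M - 1L), p * (M - 1L))
    for (j in seq_len(M - 1L)) {
      for (k in j:(M - 1L)) {
        w <- if (j == k) P[, j + 1L] * (1 - P[, j + 1L]) else
          -P[, j + 1L] * P[, k + 1L]
        block <- t(Xd) %*% (Xd * w)
        rj <- (j - 1L) * p + seq_len(p)
        rk <- (k - 1L) * p + seq_len(p)
        H[rj, rk] <- block
        if (j != k) H[rk, rj] <- t(block)
      }
    }
    diag(H) <- diag(H) + ridge
    step <- NULL
    jitter <- ridge
    while (is.null(step) && jitter <= 1) {
      step <- tryCatch(solve(H + diag(jitter, nrow(H)), grad),
                       error = function(e) NULL)
      jitter <- jitter * 100
    }
    if (is.null(step))
      step <- MASS::ginv(H) %*% grad
    # damped Newton: halve until the log-likelihood does not decrease
    alpha <- 1
    repeat {
      B_new <- B + alpha * matrix(step, p, M - 1L)
      ll_new <- loglik(B_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-10) break
      alpha <- alpha / 2
      if (alpha < 1e-8) { B_new <- B; ll_new <- ll_old; break }
    }
    B <- B_new
    if (abs(ll_new - ll_old) < tol * (abs(ll_old) + 1e-10)) {
      ll_old <- ll_new
      converged <- TRUE
      break
    }
    ll_old <- ll_new
  }
  if (!converged && it >= max_iter)
    warning("multinomial logistic fit did not converge in ", max_iter,
            " iterations")
  list(loglik = ll_old, coefficients = B, iterations = it,
       converged = converged)
}

#' Likelihood-ratio SNP-subtype association test
#'
#' Twice the log-likelihood difference between multinomial-logistic models
#' of the subtype labels fitted with and without the SNP (additive allele
#' coding), adjusting for covariates; df = M - 1; p from the upper
#' chi-squared tail.  Participants missing the SNP are dropped pairwise.
#'
#' @param labels subtype labels in `1..M`.
#' @param snp additive dosage vector (0/1/2, NA allowed).
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @return list with `llr`, `df`, `p`, `n_used`.
#' @export
lrt_snp <- function(labels, snp, covariates = NULL) {
  labels <- as.integer(labels)
  keep <- !is.na(snp)
  n_dropped <- sum(!keep)
  if (n_dropped)
    gpgan_log("debug", sprintf("lrt_snp: dropped %d missing genotype(s)",
                               n_dropped))
  labels <- labels[keep]
  snp <- as.numeric(snp[keep])
  C <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[keep, , drop = FALSE]
  M <- max(labels)
  if (M < 2L || length(unique(labels)) < 2L)
    return(list(llr = 0, df = 0L, p = 1, n_used = length(labels)))
  if (stats::var(snp) == 0)
    return(list(llr = 0, df = M - 1L, p = 1, n_used = length(labels)))
  reduced <- fit_multinomial_logistic(labels, C)
  full <- fit_multinomial_logistic(labels, cbind(C, snp = snp))
  llr <- 2 * (full$loglik - reduced$loglik)
  if (llr < 0) {
    if (llr < -1e-8) warning("negative deviance clipped to 0")
    llr <- 0
  }
  df <- M - 1L
  list(llr = llr, df = df, p = stats::pchisq(llr, df, lower.tail = FALSE),
       n_used = length(labels))
}

#' Per-SNP association table
#'
#' Runs [lrt_snp()] for every SNP column and attaches Bonferroni and
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param labels subtype labels in `1..M`.
#' @param G a [genotype_matrix()] or a counts matrix (NA = missing).
#' @param covariates optional covariate matrix/data.frame.
#' @return data.frame with snp_id, llr, df, p, p_bonf, p_bh.
#' @export
lrt_table <- function(labels, G, covariates = NULL) {
  counts <- if (inherits(G, "genotype_matrix")) G$counts else as.matrix(G)
  snp_ids <- colnames(counts)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%04d", seq_len(ncol(counts)))
  res <- lapply(seq_len(ncol(counts)), function(j)
    lrt_snp(labels, counts[, j], covariates))
  out <- data.frame(snp_id = snp_ids,
                    llr = vapply(res, `[[`, 0, "llr"),
                    df = vapply(res, function(r) as.integer(r$df), 0L),
                    p = vapply(res, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  out$p_bonf <- adjust_pvalues(out$p, "bonferroni")$adjusted
  out$p_bh <- adjust_pvalues(out$p, "bh")$adjusted
  out
}

#' Count of significantly associated SNPs
#'
#' Strict count of log-likelihood-ratio statistics exceeding the threshold
#' (default 3.841, the 0.95 quantile of chi-squared with 1 df).
#'
#' @param llr_values numeric vector of llr statistics.
#' @param threshold strict threshold.
#' @return integer count.
#' @export
n_asso_snps <- function(llr_values, threshold = 3.841) {
  stopifnot(all(is.finite(llr_values)))
  sum(llr_values > threshold)
}

#' Multiple-testing correction
#'
#' @param p vector of p-values in [0, 1].
#' @param method "bonferroni" or "bh" (Benjamini-Hochberg step-up).
#' @param alpha family-wise / FDR level for the reported threshold.
#' @return list with `adjusted` (same length as `p`) and `threshold`: the
#'   per-test p-value cutoff at `alpha` (for BH, the largest ordered p-value
#'   passing the step-up rule; NA if none).
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh"), alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (method == "bonferroni") {
    list(adjusted = stats::p.adjust(p, "bonferroni"), threshold = alpha / m)
  } else {
    adjusted <- stats::p.adjust(p, "BH")
    ord <- sort(p)
    pass <- which(ord <= seq_len(m) / m * alpha)
    list(adjusted = adjusted,
         threshold = if (length(pass)) ord[max(pass)] else NA_real_)
  }
}

#' Permutation-aligned clustering accuracy
#'
#' Maximum over label bijections of the mean agreement between predicted
#' and true labels (exhaustive search over bijections; exact for the small
#' M used here).
#'
#' @param predicted,truth label vectors of equal length.
#' @return list with `accuracy` and `mapping` (named vector: predicted
#'   level -> truth level).
#' @export
clustering_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  pl <- sort(unique(predicted))
  tl <- sort(unique(truth))
  if (length(pl) > 8L || length(tl) > 8L)
    stop("exhaustive bijection search supports at most 8 labels")
  # pad the smaller label set so bijections are total
  k <- max(length(pl), length(tl))
  conf <- matrix(0, k, k)
  for (i in seq_along(pl)) for (j in seq_along(tl))
    conf[i, j] <- sum(predicted == pl[i] & truth == tl[j])
  perms <- .permutations(k)
  best <- -1; best_perm <- NULL
  for (rowi in seq_len(nrow(perms))) {
    pm <- perms[rowi, ]
    agree <- sum(conf[cbind(seq_len(k), pm)])
    if (agree > best) { best <- agree; best_perm <- pm }
  }
  mapping <- tl[best_perm[seq_along(pl)]]
  names(mapping) <- as.character(pl)
  list(accuracy = best / length(truth), mapping = mapping)
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, 0L, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  out
}

#' One-way fixed-effects ANOVA across subtype groups
#'
#' @param values numeric response vector.
#' @param labels group labels (>= 2 groups, each with >= 2 members).
#' @return list with `F` and `p`.
#' @export
anova_across_groups <- function(values, labels) {
  labels <- as.factor(labels)
  sizes <- table(labels)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need >= 2 groups with >= 2 members each")
  fit <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value))
}
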