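# Tabular I/O (phenotype and genotype tables), run configuration, logging
# and seed plumbing.  All on-disk formats are tab-separated text with a
# header; genotype tables are also readable in a PLINK-.raw-style dosage
# dialect.

# ---- logging ---------------------------------------------------------------

.log_state <- new.env(parent = emptyenv())
.log_state$level <- "info"

.LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log level
#' @param level one of "debug", "info", "warn", "error".
#' @export
gpgan_log_level <- function(level = c("info", "debug", "warn", "error")) {
  .log_state$level <- match.arg(level)
  invisible(.log_state$level)
}

gpgan_log <- function(level, ...) {
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[.log_state$level]])
    message(sprintf("[gpgan %s] %s", level, paste0(...)))
  invisible(NULL)
}

# ---- cohort table ----------------------------------------------------------

#' Construct a cohort table
#'
#' One row per participant: an id, a group label (`REF` for the healthy
#' reference population, `TAR` for the target/patient population), named
#' covariates, and real-valued phenotypic features.
#'
#' @param participant_id character vector, unique.
#' @param group character vector of "REF"/"TAR".
#' @param covariates data.frame of numeric covariates (e.g. age, sex, icv).
#' @param features numeric matrix with column names.
#' @return object of class `cohort_table`.
#' @export
cohort_table <- function(participant_id, group, covariates, features) {
  participant_id <- as.character(participant_id)
  group <- as.character(group)
  features <- as.matrix(features)
  covariates <- as.data.frame(covariates)
  if (anyDuplicated(participant_id))
    stop("duplicate participant_id in cohort table")
  if (!all(group %in% c("REF", "TAR")))
    stop("group labels must be 'REF' or 'TAR'")
  if (length(group) != length(participant_id) ||
      nrow(features) != length(participant_id) ||
      nrow(covariates) != length(participant_id))
    stop("cohort table components have inconsistent lengths")
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("feat_%03d", seq_len(ncol(features)))
  structure(list(participant_id = participant_id, group = group,
                 covariates = covariates, features = features),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d participants (%d REF, %d TAR), %d features, covariates: %s\n",
              length(x$participant_id), sum(x$group == "REF"),
              sum(x$group == "TAR"), ncol(x$features),
              paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

#' Subset a cohort table by row index or group
#' @param table a `cohort_table`.
#' @param idx integer/logical row index.
#' @return a `cohort_table`.
#' @export
cohort_subset <- function(table, idx) {
  cohort_table(table$participant_id[idx], table$group[idx],
               table$covariates[idx, , drop = FALSE],
               table$features[idx, , drop = FALSE])
}

#' Read a phenotype table from tab-separated text
#'
#' Expected columns: `participant_id`, `group`, the declared covariates,
#' then one column per feature.
#'
#' @param path file path.
#' @param covariate_names covariate column names to expect.
#' @return a [cohort_table()].
#' @export
read_phenotype_table <- function(path, covariate_names = c("age", "sex", "icv")) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("participant_id", "group", covariate_names)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("phenotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  feat_names <- setdiff(names(df), required)
  if (!length(feat_names)) stop("phenotype table has no feature columns")
  feats <- df[, feat_names, drop = FALSE]
  for (j in seq_along(feats)) {
    v <- feats[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric feature value in column '%s', row %d",
                     feat_names[j], bad[1L]))
      feats[[j]] <- vn
    }
  }
  cohort_table(df$participant_id, df$group,
               df[, covariate_names, drop = FALSE],
               as.matrix(feats))
}

#' Write a phenotype table as tab-separated text
#' @param table a [cohort_table()].
#' @param path file path.
#' @export
write_phenotype_table <- function(table, path) {
  df <- data.frame(participant_id = table$participant_id,
                   group = table$group,
                   table$covariates,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$features, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- genotype matrix -------------------------------------------------------

#' Construct a genotype matrix
#'
#' Minor-allele counts in {0,1,2}; `NA` entries are missing genotypes (the
#' missing mask is derived from them).
#'
#' @param participant_id character vector.
#' @param counts integer matrix, participants x SNPs, entries 0/1/2 or NA.
#' @param snp_ids SNP identifiers (unique).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(participant_id, counts, snp_ids = colnames(counts)) {
  participant_id <- as.character(participant_id)
  counts <- as.matrix(counts)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%04d", seq_len(ncol(counts)))
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (nrow(counts) != length(participant_id))
    stop("counts rows must match participant_id length")
  obs <- counts[!is.na(counts)]
  if (length(obs) && !all(obs %in% c(0, 1, 2)))
    stop("genotype counts must be 0, 1 or 2 where observed")
  colnames(counts) <- snp_ids
  structure(list(participant_id = participant_id, snp_ids = snp_ids,
                 counts = counts, missing_mask = is.na(counts)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d participants x %d SNPs, %.1f%% missing\n",
              nrow(x$counts), ncol(x$counts), 100 * mean(x$missing_mask)))
  invisible(x)
}

#' Read a genotype table
#'
#' The `tsv` dialect has a `participant_id` column followed by one column
#' per SNP with entries 0/1/2 or a missing sentinel ("NA", empty, "NaN").
#' The `plink_raw` dialect is the PLINK `.raw` additive-dosage layout:
#' whitespace-separated columns FID IID PAT MAT SEX PHENOTYPE followed by
#' per-SNP allele dosages; IID is used as the participant id.
#'
#' @param path file path.
#' @param dialect "tsv" or "plink_raw".
#' @return a [genotype_matrix()].
#' @export
read_genotype_table <- function(path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  na_strings <- c("NA", "", "NaN", "nan")
  if (dialect == "tsv") {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            check.names = FALSE, na.strings = na_strings,
                            stringsAsFactors = FALSE)
    if (!"participant_id" %in% names(df))
      stop("genotype table is missing required column: participant_id")
    ids <- as.character(df$participant_id)
    counts <- as.matrix(df[, setdiff(names(df), "participant_id"), drop = FALSE])
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            na.strings = na_strings, stringsAsFactors = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(df)))
      stop("plink_raw file is missing header column(s): ",
           paste(setdiff(meta, names(df)), collapse = ", "))
    ids <- as.character(df$IID)
    counts <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  }
  storage.mode(counts) <- "double"
  genotype_matrix(ids, counts)
}

#' Write a genotype matrix as tab-separated text (canonical "NA" for missing)
#' @param G a [genotype_matrix()].
#' @param path file path.
#' @export
write_genotype_table <- function(G, path) {
  df <- data.frame(participant_id = G$participant_id, G$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Inner-join phenotype and genotype tables on participant id
#'
#' Participants present in only one table are dropped with a logged count.
#'
#' @param phenotypes a [cohort_table()].
#' @param genotypes a [genotype_matrix()]; genotype rows are expected for
#'   TAR participants.
#' @return list with the aligned `phenotypes` and `genotypes`.
#' @export
join_cohort <- function(phenotypes, genotypes) {
  tar_ids <- phenotypes$participant_id[phenotypes$group == "TAR"]
  common <- intersect(tar_ids, genotypes$participant_id)
  dropped_ph <- length(tar_ids) - length(common)
  dropped_gt <- length(genotypes$participant_id) - length(common)
  if (dropped_ph || dropped_gt)
    gpgan_log("info", sprintf(
      "inner join dropped %d TAR phenotype row(s) and %d genotype row(s)",
      dropped_ph, dropped_gt))
  keep <- phenotypes$group == "REF" | phenotypes$participant_id %in% common
  ph <- cohort_subset(phenotypes, keep)
  ord <- match(ph$participant_id[ph$group == "TAR"], genotypes$participant_id)
  gt <- genotype_matrix(genotypes$participant_id[ord],
                        genotypes$counts[ord, , drop = FALSE],
                        genotypes$snp_ids)
  list(phenotypes = ph, genotypes = gt)
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' All hyperparameters of the model and of the cross-validation / ensemble
#' machinery, with validated defaults.  The gene-step learning-rate grid,
#' hold-out repetition count, test fraction, ensemble size and the
#' association-count threshold default to the published protocol values.
#'
#' @param M number of subtypes.
#' @param n_z2,n_z3 ancillary latent dimensions.
#' @param kappa weight of the categorical-prior KL penalty.
#' @param mu weight of the sparse-change (l1) loss.
#' @param lambda weight of the latent reconstruction loss.
#' @param phenotype_lr Adam learning rate of the Phenotype step.
#' @param d_steps discriminator updates per iteration.
#' @param d_warmup discriminator-only updates before adversarial training
#'   starts (the untrained transformation is the identity, so warmup teaches
#'   the discriminator the REF-to-TAR contrast first).
#' @param d_lr discriminator learning rate (defaults to `phenotype_lr`).
#' @param gene_lr Adam learning rate of the Gene step (the hyperparameter
#'   selected by cross-validation).
#' @param clip_c weight-clipping bound for the Lipschitz-constrained
#'   networks.
#' @param batch_size minibatch size.
#' @param max_iterations training-iteration cap.
#' @param min_iterations iterations before the assignment-stability stopping
#'   rule may fire (burn-in).
#' @param hidden hidden width of all perceptrons.
#' @param checkpoint_every iterations between assignment checkpoints used by
#'   the stopping rule.
#' @param n_repeats,test_fraction,gene_lr_grid hold-out CV settings.
#' @param ensemble_size number of models in the consensus ensemble.
#' @param llr_threshold log-likelihood-ratio threshold defining the
#'   association count (N-Asso-SNPs).
#' @param seed master seed.
#' @return object of class `gpgan_config` (a named list).
#' @export
gpgan_config <- function(M = 3L, n_z2 = 5L, n_z3 = 5L,
                         kappa = 1, mu = 5, lambda = 1,
                         phenotype_lr = 2e-4, d_steps = 1L, d_lr = NULL,
                         d_warmup = 500L,
                         gene_lr = 1e-4,
                         clip_c = 1.0, batch_size = 64L,
                         max_iterations = 4000L, min_iterations = 2000L,
                         hidden = 64L,
                         checkpoint_every = 200L,
                         n_repeats = 50L, test_fraction = 0.2,
                         gene_lr_grid = c(5e-5, 1e-4, 2e-4, 4e-4),
                         ensemble_size = 50L, llr_threshold = 3.841,
                         seed = 1L) {
  cfg <- list(M = as.integer(M), n_z2 = as.integer(n_z2),
              n_z3 = as.integer(n_z3),
              kappa = kappa, mu = mu, lambda = lambda,
              phenotype_lr = phenotype_lr,
              d_steps = as.integer(d_steps),
              d_warmup = as.integer(d_warmup),
              d_lr = if (is.null(d_lr)) phenotype_lr else d_lr,
              gene_lr = gene_lr,
              clip_c = clip_c, batch_size = as.integer(batch_size),
              max_iterations = as.integer(max_iterations),
              min_iterations = as.integer(min_iterations),
              hidden = as.integer(hidden),
              checkpoint_every = as.integer(checkpoint_every),
              n_repeats = as.integer(n_repeats),
              test_fraction = test_fraction,
              gene_lr_grid = gene_lr_grid,
              ensemble_size = as.integer(ensemble_size),
              llr_threshold = llr_threshold,
              seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$M < 2L) stop("M must be >= 2")
  for (nm in c("kappa", "mu", "lambda"))
    if (cfg[[nm]] < 0) stop(nm, " must be non-negative")
  if (cfg$phenotype_lr <= 0 || cfg$gene_lr <= 0)
    stop("learning rates must be positive")
  if (cfg$test_fraction <= 0 || cfg$test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  if (any(cfg$gene_lr_grid <= 0))
    stop("gene_lr_grid values must be positive")
  if (cfg$clip_c <= 0) stop("clip_c must be positive")
  structure(cfg, class = "gpgan_config")
}

#' Load a run configuration from a YAML file
#'
#' Absent keys take the [gpgan_config()] defaults; unknown keys error.
#'
#' @param path file path (YAML key-value file; may be empty).
#' @return a `gpgan_config`.
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(gpgan_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- do.call(gpgan_config, raw)
  gpgan_log("debug", "resolved config: ",
            paste(names(cfg), vapply(cfg, function(x)
              paste(format(x), collapse = ","), ""), sep = "=", collapse = " "))
  cfg
}

#' Derive a child seed from a master seed
#'
#' Deterministic, keeps results reproducible across the CV/ensemble harness
#' while staying inside the 32-bit integer range.
#' @param seed master seed (integer).
#' @param k child index.
#' @return an integer seed in [1, 2^31).
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 10007) %% 2147483587) + 1L
}
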