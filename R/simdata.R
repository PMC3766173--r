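#' Draw a block compound-symmetric Gaussian expression matrix
#'
#' Each block shares a single latent factor: a variable in a block with
#' correlation `rho` is \eqn{\sqrt{\rho}\, f + \sqrt{1-\rho}\, e} with
#' standard-normal factor and idiosyncratic terms, giving mean 0, variance 1
#' and within-block correlation exactly `rho` by construction. Blocks are
#' mutually independent.
#'
#' @param n_samples number of samples (columns).
#' @param block_sizes integer vector of genes per block.
#' @param rho within-block correlation in \[0, 1).
#' @param gene_prefix prefix for generated gene identifiers.
#' @return A list: `matrix` (genes x samples), `block` (per-gene block id).
#' @export
rcs_expression <- function(n_samples, block_sizes, rho, gene_prefix = "g") {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  G <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  vals <- matrix(NA_real_, G, n_samples)
  for (b in seq_along(block_sizes)) {
    gb <- block_sizes[b]
    f <- matrix(stats::rnorm(n_samples), 1, n_samples)
    e <- matrix(stats::rnorm(gb * n_samples), gb, n_samples)
    vals[block == b, ] <- sqrt(rho) * f[rep(1, gb), , drop = FALSE] +
      sqrt(1 - rho) * e
  }
  rownames(vals) <- sprintf("%s%0*d", gene_prefix, nchar(G), seq_len(G))
  colnames(vals) <- sprintf("s%0*d", nchar(n_samples), seq_len(n_samples))
  list(matrix = vals, block = block)
}

#' Simulate the correlated-predictor regression study
#'
#' Generates the single-outcome benchmark for the equalization property of
#' the over-shrinkage estimator: two independent compound-symmetric
#' predictor blocks whose members all carry the same true coefficient, one
#' positive and one negative, plus Gaussian noise on the outcome. Defaults
#' are the study conditions: 201 samples, two blocks of 100 predictors,
#' within-block correlation 0.9, unit predictor variance, coefficients +1
#' and -1, unit noise standard deviation.
#'
#' @param n_samples number of samples.
#' @param genes_per_block predictors per block (two blocks).
#' @param rho within-block correlation.
#' @param coef_pos,coef_neg shared true coefficient of blocks 1 and 2.
#' @param noise_sd standard deviation of the outcome noise.
#' @param seed integer seed.
#' @return A list: `X` (samples x predictors), `y` (outcome vector),
#'   `truth` (true coefficient per predictor), `block` (block id per
#'   predictor), `config` (echo of the parameters).
#' @export
simulate_study1 <- function(n_samples = 201, genes_per_block = 100, rho = 0.9,
                            coef_pos = 1, coef_neg = -1, noise_sd = 1,
                            seed = 1L) {
  set.seed(as.integer(seed))
  gen <- rcs_expression(n_samples, c(genes_per_block, genes_per_block), rho,
                        gene_prefix = "x")
  X <- t(gen$matrix)                               # samples x predictors
  truth <- c(rep(coef_pos, genes_per_block), rep(-abs(coef_neg), genes_per_block))
  y <- as.vector(X %*% truth) + stats::rnorm(n_samples, sd = noise_sd)
  list(X = X, y = y, truth = truth, block = gen$block,
       config = list(n_samples = n_samples, genes_per_block = genes_per_block,
                     rho = rho, coef_pos = coef_pos, coef_neg = -abs(coef_neg),
                     noise_sd = noise_sd, seed = seed))
}

#' Over-shrinkage ridge fit of a single outcome
#'
#' The two-stage estimator applied outside the network setting: a ridge fit
#' of one outcome on a predictor matrix, followed by one least-squares
#' rescaling coefficient on the fitted values. Large penalties equalize the
#' coefficients of correlated predictors; the rescaling removes the
#' attendant shrinkage bias of the fitted values. Columns of `X` and `y` are
#' centered internally.
#'
#' @param X samples-by-predictors matrix.
#' @param y outcome vector.
#' @param lambda positive ridge penalty.
#' @return A list: `coefficients` (rescaled, length = ncol(X)), `nu`
#'   (rescaling factor), `ridge` (unrescaled ridge coefficients).
#' @export
osrr_fit_single <- function(X, y, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0)
    stop("lambda must be a positive scalar")
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  y <- as.numeric(y) - mean(y)
  n <- nrow(X)
  A <- tcrossprod(X)                               # n x n dual system
  diag(A) <- diag(A) + lambda
  beta <- as.vector(crossprod(X, solve(A, y)))
  yhat <- as.vector(X %*% beta)
  nu <- estimate_nu(y, yhat)$nu
  list(coefficients = stats::setNames(beta * nu, colnames(X)), nu = nu,
       ridge = beta)
}

#' Simulate a database plus small two-condition experiment
#'
#' Generates the differential-expression benchmark: a large training
#' database and a small experiment drawn from the same block
#' compound-symmetric co-expression structure, with condition effects added
#' to a random subset of genes in the treated samples only. Defaults are the
#' study conditions: database of 200 genes by 100 samples, two blocks of
#' 100 with correlation 0.8 and unit variance; experiment of 20 samples
#' split 10 control / 10 treated; each gene differentially expressed with
#' probability 0.2, effect size 1.0 with an independent random sign.
#'
#' @param n_genes total genes.
#' @param block_sizes genes per block (must sum to `n_genes`).
#' @param rho within-block correlation.
#' @param n_db database samples.
#' @param n_expt experiment samples.
#' @param n_treated treated samples (the rest are controls).
#' @param de_prob per-gene probability of a true condition effect.
#' @param de_effect absolute effect size added to treated samples.
#' @param expt_rho experiment correlation; defaults to `rho` (same
#'   structure), set to 0 for an experiment unrelated to the trained
#'   network.
#' @param seed integer seed.
#' @return An object of class `simulated_study`: list with `database` and
#'   `experiment` ([expression_matrix()], uncentered), `covariates`
#'   ([covariate_table()]), `truth` (`data.frame`: `gene_id`, `is_de`,
#'   `true_delta`, `block`), and `config`.
#' @export
simulate_de_study <- function(n_genes = 200, block_sizes = c(100, 100),
                              rho = 0.8, n_db = 100, n_expt = 20,
                              n_treated = 10, de_prob = 0.2, de_effect = 1.0,
                              expt_rho = rho, seed = 1L) {
  if (sum(block_sizes) != n_genes) stop("block sizes must sum to n_genes")
  if (n_treated >= n_expt) stop("need at least one control sample")
  if (de_prob < 0 || de_prob > 1) stop("de_prob must lie in [0, 1]")
  set.seed(as.integer(seed))
  db <- rcs_expression(n_db, block_sizes, rho)
  ex <- rcs_expression(n_expt, block_sizes, expt_rho)
  condition <- c(rep(0, n_expt - n_treated), rep(1, n_treated))
  is_de <- stats::rbinom(n_genes, 1, de_prob) == 1
  sign_de <- ifelse(stats::rbinom(n_genes, 1, 0.5) == 1, 1, -1)
  true_delta <- ifelse(is_de, sign_de * de_effect, 0)
  vals <- ex$matrix
  vals[, condition == 1] <- vals[, condition == 1] + true_delta
  colnames(vals) <- sprintf("e%0*d", nchar(n_expt), seq_len(n_expt))
  database <- expression_matrix(db$matrix)
  experiment <- expression_matrix(vals)
  structure(list(
    database = database,
    experiment = experiment,
    covariates = covariate_table(condition, sample_ids = colnames(vals)),
    truth = data.frame(gene_id = experiment$gene_ids, is_de = is_de,
                       true_delta = true_delta, block = ex$block,
                       stringsAsFactors = FALSE),
    config = list(n_genes = n_genes, block_sizes = block_sizes, rho = rho,
                  n_db = n_db, n_expt = n_expt, n_treated = n_treated,
                  de_prob = de_prob, de_effect = de_effect,
                  expt_rho = expt_rho, seed = seed)),
    class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(paste0("simulated_study: database %d x %d, experiment %d x %d ",
                     "(%d treated), %d true-DE genes\n"),
              nrow(x$database$values), ncol(x$database$values),
              nrow(x$experiment$values), ncol(x$experiment$values),
              sum(x$covariates$condition), sum(x$truth$is_de)))
  invisible(x)
}

#' Write a simulated study to plain-text files
#'
#' Emits `database.tsv`, `experiment.tsv`, `covariates.tsv`, `truth.tsv`
#' and `config.json` into a directory so the whole pipeline can run from
#' files alone.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(study$database, file.path(dir, "database.tsv"))
  write_expression(study$experiment, file.path(dir, "experiment.tsv"))
  write_covariates(study$covariates, file.path(dir, "covariates.tsv"))
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Score methods' results against simulation ground truth
#'
#' For each method's results table, computes power (rejection rate among
#' truly differentially expressed genes) and empirical type-I error
#' (rejection rate among null genes) at each cutoff, plus the
#' Kolmogorov–Smirnov distance of the null genes' p-values from uniform.
#'
#' @param results_list named list of results tables (each with `gene_id` and
#'   a p-value column).
#' @param truth the `truth` table of a [simulate_de_study()] result.
#' @param cutoffs p-value cutoffs to evaluate.
#' @param p_column p-value column name.
#' @return A `data.frame`, one row per method and cutoff: `method`,
#'   `cutoff`, `power`, `type1`, plus per-method `ks_stat`/`ks_p` (repeated
#'   across cutoffs).
#' @export
evaluate_methods <- function(results_list, truth,
                             cutoffs = c(0.05, 0.01, 0.001, 0.0001),
                             p_column = "p_delta") {
  stopifnot(is.list(results_list), length(results_list) > 0)
  if (is.null(names(results_list)) || any(names(results_list) == ""))
    stop("results_list must be a named list")
  out <- lapply(names(results_list), function(m) {
    res <- results_list[[m]]
    if (!identical(res$gene_id, truth$gene_id))
      stop("gene identifiers of method '", m, "' do not match the truth table")
    p <- res[[p_column]]
    p_null <- p[!truth$is_de]
    ks <- suppressWarnings(stats::ks.test(p_null, "punif"))
    df <- data.frame(method = m, cutoff = cutoffs,
                     power = vapply(cutoffs, function(co)
                       mean(p[truth$is_de] < co), numeric(1)),
                     type1 = vapply(cutoffs, function(co)
                       mean(p_null < co), numeric(1)),
                     stringsAsFactors = FALSE)
    df$ks_stat <- unname(ks$statistic)
    df$ks_p <- ks$p.value
    df
  })
  do.call(rbind, out)
}
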