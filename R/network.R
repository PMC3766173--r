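#' Fit a single gene's penalized regression on all other genes
#'
#' Minimizes \eqn{\|y_g - \beta Y_{-g}\|^2 + \lambda \|\beta\|^2} where
#' \eqn{Y_{-g}} is the centered database matrix with gene \eqn{g} removed, so
#' a gene never predicts itself. The self-coefficient is fixed at zero in the
#' returned length-G vector. The system is solved in its dual (sample-space)
#' form, an \eqn{N_D \times N_D} solve, because the number of genes typically
#' dwarfs the number of arrays.
#'
#' @param db a centered [expression_matrix()] (the training database).
#' @param gene_index integer row index of the outcome gene.
#' @param lambda positive ridge penalty; identifiability requires
#'   `lambda > 0`.
#' @return Numeric length-G coefficient vector named by gene, with entry
#'   `gene_index` exactly zero.
#' @export
fit_gene_ridge <- function(db, gene_index, lambda) {
  stopifnot(inherits(db, "expression_matrix"))
  if (!db$centered) stop("database must be centered (see center_genes)")
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0)
    stop("lambda must be a positive scalar")
  G <- nrow(db$values)
  if (G < 2) stop("need at least 2 genes")
  if (gene_index < 1 || gene_index > G) stop("gene_index out of range")
  y <- db$values[gene_index, ]
  M <- db$values[-gene_index, , drop = FALSE]      # (G-1) x N predictors
  A <- crossprod(M)                                # N x N dual Gram matrix
  diag(A) <- diag(A) + lambda
  alpha <- solve(A, y)
  beta <- numeric(G)
  beta[-gene_index] <- as.vector(M %*% alpha)
  stats::setNames(beta, db$gene_ids)
}

#' Estimate the global co-expression network
#'
#' Fits [fit_gene_ridge()] for every gene with one shared penalty. Rather
#' than rebuilding the Gram matrix G times, the full dual Gram
#' \eqn{S = Y^\top Y} is factorized once and each gene's self-exclusion is
#' applied as a rank-one Sherman–Morrison downdate, giving
#' \eqn{O(G N_D^2 + G^2 N_D)} total cost. The result is numerically
#' identical to refitting with the gene physically deleted.
#'
#' @param db a centered [expression_matrix()].
#' @param lambda positive ridge penalty shared by all genes.
#' @return An object of class `network_model`: list with `coefficients`
#'   (G x G matrix, row g = coefficients predicting gene g, zero diagonal),
#'   `lambda`, `gene_ids`, and `training_meta` (number of training samples).
#' @export
fit_network <- function(db, lambda) {
  stopifnot(inherits(db, "expression_matrix"))
  if (!db$centered) stop("database must be centered (see center_genes)")
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0)
    stop("lambda must be a positive scalar")
  Y <- db$values                        # G x N
  G <- nrow(Y); N <- ncol(Y)
  if (G < 2) stop("need at least 2 genes")
  S <- crossprod(Y)                     # N x N, sum over ALL genes
  diag(S) <- diag(S) + lambda
  U <- solve(S, t(Y))                   # N x G, column g = (S+lambda I)^-1 y_g
  # downdate: alpha_g = (S + lambda I - y_g y_g')^-1 y_g = u_g / (1 - y_g' u_g)
  cg <- colSums(t(Y) * U)
  if (any(cg >= 1 - 1e-12))
    stop("rank-one downdate degenerate; lambda too small for this matrix")
  Alpha <- sweep(U, 2, 1 - cg, "/")
  B <- t(Y %*% Alpha)                   # B[g, g'] = y_g' . alpha_g
  diag(B) <- 0
  dimnames(B) <- list(db$gene_ids, db$gene_ids)
  structure(list(coefficients = B, lambda = lambda, gene_ids = db$gene_ids,
                 training_meta = list(n_train = N)),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("network_model: %d genes, lambda = %g (trained on %d samples)\n",
              length(x$gene_ids), x$lambda, x$training_meta$n_train))
  invisible(x)
}

#' Predict each gene's expression in a new experiment
#'
#' Applies the database-trained coefficient rows to a centered experiment:
#' prediction row g is the weighted sum of all other genes of the same
#' sample. The raw prediction is deliberately over-shrunk; downstream models
#' rescale it per gene (see [estimate_nu()]).
#'
#' @param model a `network_model` from [fit_network()].
#' @param expt a centered [expression_matrix()] with the same genes in the
#'   same order as the model.
#' @return An object of class `network_prediction`: list with `values`
#'   (G x N matrix), `gene_ids`, `sample_ids`.
#' @export
predict_network <- function(model, expt) {
  stopifnot(inherits(model, "network_model"), inherits(expt, "expression_matrix"))
  if (!expt$centered) stop("experiment must be centered (see center_genes)")
  if (!identical(model$gene_ids, expt$gene_ids))
    stop("gene identifiers of model and experiment do not match (use intersect_genes)")
  vals <- model$coefficients %*% expt$values
  dimnames(vals) <- list(expt$gene_ids, expt$sample_ids)
  structure(list(values = vals, gene_ids = expt$gene_ids,
                 sample_ids = expt$sample_ids),
            class = "network_prediction")
}

#' @export
print.network_prediction <- function(x, ...) {
  cat(sprintf("network_prediction: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Over-shrinkage correction coefficient for one gene
#'
#' Second stage of the estimator: regresses the observed (centered)
#' expression of a gene on its network prediction without an intercept,
#' \eqn{\hat\nu = \langle y, \hat y\rangle / \langle\hat y, \hat y\rangle}.
#' A heavily penalized first stage biases predictions toward zero by a
#' roughly common factor; \eqn{\nu} undoes that bias, and converges to zero
#' when the trained network carries no information about the new data.
#'
#' @param y_g observed centered expression (length N).
#' @param yhat_g network prediction for the same gene (length N).
#' @return List with `nu` (estimate), `se` (standard error from linear-model
#'   theory with N - 1 residual degrees of freedom), and `df`.
#' @export
estimate_nu <- function(y_g, yhat_g) {
  y_g <- as.numeric(y_g); yhat_g <- as.numeric(yhat_g)
  if (length(y_g) != length(yhat_g)) stop("length mismatch")
  ss <- sum(yhat_g^2)
  if (ss <= 0) stop("network prediction is identically zero; nu is undefined")
  nu <- sum(y_g * yhat_g) / ss
  n <- length(y_g)
  rss <- sum((y_g - nu * yhat_g)^2)
  df <- n - 1L
  list(nu = nu, se = sqrt(rss / df / ss), df = df)
}

#' Select the shared ridge penalty by split-sample criteria
#'
#' Splits the database samples into two seeded random halves and scores each
#' candidate penalty on three aspects of goodness of fit: (i) out-sample
#' prediction — the median across genes of the correlation between
#' predictions trained on one half and observations in the other half
#' (both directions, averaged per gene); (ii) coefficient stability — the
#' mean across genes of the correlation between the two half-fits'
#' coefficient rows (self-entries excluded); and (iii), when a target
#' experiment is supplied, the median across genes of the correlation of the
#' full-database prediction with the target. The penalty is chosen by
#' criterion (i); (ii) and (iii) are reported for inspection. Ties prefer the
#' smallest penalty (less bias).
#'
#' @param db an [expression_matrix()] (centering is applied per half).
#' @param grid numeric vector of candidate penalties; the conventional
#'   default is `10^(2:6)`.
#' @param target optional [expression_matrix()] with the same genes as `db`.
#' @param seed integer seed for the half-split.
#' @param aggregate how per-gene out-sample correlations are pooled for
#'   criterion (i): `"median"` (default), `"mean"`, or `"max"`.
#' @param choose_by criterion used for the selection; `"prediction"`
#'   (criterion i, default) or `"target"` (criterion iii, requires `target`).
#' @return An object of class `lambda_report`: list with `grid`,
#'   `pred_cor`, `coef_stability`, `target_cor`, `chosen`, `seed`, `split`.
#' @export
select_lambda <- function(db, grid = 10^(2:6), target = NULL, seed = 1L,
                          aggregate = c("median", "mean", "max"),
                          choose_by = c("prediction", "target")) {
  stopifnot(inherits(db, "expression_matrix"))
  aggregate <- match.arg(aggregate)
  choose_by <- match.arg(choose_by)
  if (length(grid) == 0) stop("penalty grid is empty")
  if (any(grid <= 0)) stop("all penalties must be positive")
  N <- ncol(db$values)
  if (N < 4) stop("need at least 4 samples to split")
  set.seed(as.integer(seed))
  idx1 <- sort(sample.int(N, N %/% 2))
  idx2 <- setdiff(seq_len(N), idx1)
  if (length(idx1) < 2 || length(idx2) < 2) stop("split half has fewer than 2 samples")
  half <- function(idx) center_genes(
    expression_matrix(db$values[, idx, drop = FALSE], db$gene_ids,
                      db$sample_ids[idx]))
  h1 <- half(idx1); h2 <- half(idx2)
  db_c <- center_genes(db)
  target_c <- if (!is.null(target)) center_genes(target)
  agg <- switch(aggregate, median = stats::median, mean = mean, max = max)

  pred_cor <- coef_stab <- target_cor <- rep(NA_real_, length(grid))
  for (k in seq_along(grid)) {
    f1 <- fit_network(h1, grid[k])
    f2 <- fit_network(h2, grid[k])
    c12 <- gene_prediction_cor(f1, h2)
    c21 <- gene_prediction_cor(f2, h1)
    per_gene <- rowMeans(cbind(c12, c21), na.rm = TRUE)
    pred_cor[k] <- agg(per_gene[is.finite(per_gene)])
    coef_stab[k] <- mean(vapply(seq_along(db$gene_ids), function(g)
      stats::cor(f1$coefficients[g, -g], f2$coefficients[g, -g]),
      numeric(1)), na.rm = TRUE)
    if (!is.null(target)) {
      ffull <- fit_network(db_c, grid[k])
      ct <- gene_prediction_cor(ffull, target_c)
      target_cor[k] <- stats::median(ct[is.finite(ct)])
    }
  }
  score <- if (choose_by == "target") {
    if (is.null(target)) stop("choose_by = 'target' requires a target matrix")
    target_cor
  } else pred_cor
  best <- which(score == max(score))
  chosen <- grid[best[which.min(grid[best])]]
  structure(list(grid = grid, pred_cor = pred_cor, coef_stability = coef_stab,
                 target_cor = target_cor, chosen = chosen, seed = seed,
                 aggregate = aggregate,
                 split = list(half1 = idx1, half2 = idx2)),
            class = "lambda_report")
}

#' @export
print.lambda_report <- function(x, ...) {
  df <- data.frame(lambda = x$grid, pred_cor = x$pred_cor,
                   coef_stability = x$coef_stability,
                   target_cor = x$target_cor)
  print(df, row.names = FALSE)
  cat("chosen lambda:", x$chosen, "\n")
  invisible(x)
}

# per-gene Pearson correlation between a model's predictions on a centered
# matrix and the observed values; NA for genes with zero variance either side
gene_prediction_cor <- function(model, expt) {
  pred <- predict_network(model, expt)$values
  obs <- expt$values
  vapply(seq_len(nrow(obs)), function(g) {
    if (stats::sd(obs[g, ]) == 0 || stats::sd(pred[g, ]) == 0) return(NA_real_)
    stats::cor(obs[g, ], pred[g, ])
  }, numeric(1))
}

#' Write a network model to delimited text plus a JSON sidecar
#'
#' The coefficient matrix goes to a gene-by-gene TSV; the penalty and
#' training metadata go to `<path>.meta.json`.
#'
#' @param model a `network_model`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(model, path) {
  stopifnot(inherits(model, "network_model"))
  df <- data.frame(gene_id = model$gene_ids, model$coefficients,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(lambda = model$lambda, n_train = model$training_meta$n_train,
               n_genes = length(model$gene_ids))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a network model written by [write_network()]
#'
#' @param path TSV path; `<path>.meta.json` must exist alongside.
#' @return A `network_model`.
#' @export
read_network <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  genes <- trimws(as.character(tab[[1]]))
  B <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(B) <- list(genes, trimws(colnames(tab)[-1]))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(list(coefficients = B,
                 lambda = if (!is.null(meta$lambda)) as.numeric(meta$lambda) else NA_real_,
                 gene_ids = genes,
                 training_meta = list(n_train = if (!is.null(meta$n_train))
                   as.integer(meta$n_train) else NA_integer_)),
            class = "network_model")
}
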