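#' Network-adjusted differential expression test for one gene
#'
#' Fits the per-gene linear model
#' \eqn{y_g = \nu_g \hat y_g + \delta_g x + \epsilon} (plus an intercept),
#' where \eqn{\hat y_g} is the database-trained network prediction and
#' \eqn{x} the 0/1 condition indicator. The condition effect \eqn{\delta_g}
#' is jointly estimated with the over-shrinkage correction \eqn{\nu_g};
#' its two-sided Wald t-test is the network-adjusted test of differential
#' expression. Paired designs add per-pair intercepts, either fixed or as a
#' random effect fitted by REML.
#'
#' When the prediction is absent or constant the network term is dropped and
#' the model collapses to the naive comparator, which with `pairing = "none"`
#' is exactly the pooled-variance two-sample t-test.
#'
#' @param y_g observed expression for one gene (length N).
#' @param yhat_g network prediction (length N), or `NULL` for the naive
#'   model.
#' @param cov a [covariate_table()].
#' @param pairing `"none"`, `"fixed"` (per-pair fixed intercepts), or
#'   `"random"` (per-pair random intercept; requires `cov$pair_id`).
#' @return A one-row `data.frame` with columns `nu_hat`, `delta_hat`,
#'   `se_delta`, `df_delta`, `p_delta`, `direction`, `model_tag`,
#'   `degenerate`.
#' @export
fit_de_gene <- function(y_g, yhat_g = NULL, cov, pairing = c("none", "fixed", "random")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(cov, "covariate_table"))
  y_g <- as.numeric(y_g)
  n <- length(y_g)
  if (n != cov$n) stop("expression length != covariate table length")
  if (n < 4) stop("need at least 4 samples")
  x <- cov$condition
  if (length(unique(x)) < 2) stop("condition has a single level; no contrast to test")
  if (pairing != "none" && is.null(cov$pair_id))
    stop("pairing requested but covariate table has no pair_id")

  degenerate <- FALSE
  use_net <- !is.null(yhat_g)
  if (use_net) {
    yhat_g <- as.numeric(yhat_g)
    if (length(yhat_g) != n) stop("prediction length != expression length")
    if (stats::sd(yhat_g) < 1e-12) { use_net <- FALSE; degenerate <- TRUE }
  }

  dat <- data.frame(y = y_g, x = x)
  if (use_net) dat$yhat <- yhat_g
  if (!is.null(cov$pair_id)) dat$pair <- factor(cov$pair_id)
  rhs <- c(if (use_net) "yhat", "x", if (pairing == "fixed") "pair")
  form <- stats::reformulate(rhs, response = "y")

  if (pairing == "random") {
    res <- .fit_random_intercept(form, dat, term = "x")
    out <- data.frame(nu_hat = if (use_net) res$coefs[["yhat"]] else NA_real_,
                      delta_hat = res$est, se_delta = res$se,
                      df_delta = res$df, p_delta = res$p)
  } else {
    fit <- stats::lm(form, data = dat)
    ct <- summary(fit)$coefficients
    if (!"x" %in% rownames(ct)) stop("condition aliased in design")
    out <- data.frame(
      nu_hat = if (use_net && "yhat" %in% rownames(ct)) ct["yhat", 1] else NA_real_,
      delta_hat = ct["x", 1], se_delta = ct["x", 2],
      df_delta = fit$df.residual, p_delta = ct["x", 4])
  }
  out$direction <- ifelse(out$delta_hat > 0, "up",
                          ifelse(out$delta_hat < 0, "down", "none"))
  out$model_tag <- if (use_net) "osrr" else "naive"
  out$degenerate <- degenerate
  out
}

# Random-intercept fit with Wald t-tests on residual degrees of freedom
# n - (#fixed effects) - (#pairs); if the pair variance component is
# estimated at the zero boundary the model is refit as plain OLS.
.fit_random_intercept <- function(form, dat, term) {
  rform <- stats::update.formula(form, . ~ . + (1 | pair))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(rform, data = dat, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pair_var <- vc$vcov[vc$grp == "pair"][1]
  if (!is.finite(pair_var) || pair_var < 1e-10) {
    ols <- stats::lm(form, data = dat)
    ct <- summary(ols)$coefficients
    return(list(est = ct[term, 1], se = ct[term, 2], df = ols$df.residual,
                p = ct[term, 4], coefs = stats::coef(ols)))
  }
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  df <- nrow(dat) - length(b) - length(unique(dat$pair))
  if (df < 1) df <- 1
  tval <- b[[term]] / se[[term]]
  list(est = b[[term]], se = se[[term]], df = df,
       p = 2 * stats::pt(-abs(tval), df), coefs = b)
}

#' Network-disruption (interaction) test for one gene
#'
#' Extends the network-adjusted model with the elementwise product of the
#' network prediction and the condition indicator:
#' \eqn{y_g = \nu_g \hat y_g + \delta_g x + \gamma_g (\hat y_g x) + \epsilon}.
#' A nonzero \eqn{\gamma_g} means the gene's dependence on its trained
#' network differs between conditions — a condition-dependent rewiring of
#' regulatory relationships. Returns a two-sided Wald t-test of
#' \eqn{\gamma_g = 0}.
#'
#' @inheritParams fit_de_gene
#' @return A one-row `data.frame` with the [fit_de_gene()] columns plus
#'   `gamma_hat`, `se_gamma`, `p_gamma`.
#' @export
fit_interaction_gene <- function(y_g, yhat_g, cov,
                                 pairing = c("none", "fixed", "random")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(cov, "covariate_table"))
  y_g <- as.numeric(y_g); yhat_g <- as.numeric(yhat_g)
  n <- length(y_g)
  if (n != cov$n || length(yhat_g) != n) stop("length mismatch")
  x <- cov$condition
  if (length(unique(x)) < 2) stop("condition has a single level")

  base <- fit_de_gene(y_g, yhat_g, cov, pairing)
  # the interaction needs the prediction to vary within each condition group
  within_sd <- vapply(split(yhat_g, x), stats::sd, numeric(1))
  degenerate <- base$degenerate || any(within_sd < 1e-12)
  if (degenerate) {
    base$gamma_hat <- NA_real_; base$se_gamma <- NA_real_
    base$p_gamma <- NA_real_
    base$model_tag <- "osrr-interaction"
    base$degenerate <- TRUE
    return(base)
  }
  dat <- data.frame(y = y_g, yhat = yhat_g, x = x, xint = yhat_g * x)
  if (!is.null(cov$pair_id)) dat$pair <- factor(cov$pair_id)
  rhs <- c("yhat", "x", "xint", if (pairing == "fixed") "pair")
  form <- stats::reformulate(rhs, response = "y")
  if (pairing == "random") {
    res <- .fit_random_intercept(form, dat, term = "xint")
    resd <- .fit_random_intercept(form, dat, term = "x")
    out <- data.frame(nu_hat = res$coefs[["yhat"]], delta_hat = resd$est,
                      se_delta = resd$se, df_delta = resd$df, p_delta = resd$p,
                      gamma_hat = res$est, se_gamma = res$se, p_gamma = res$p)
  } else {
    fit <- stats::lm(form, data = dat)
    ct <- summary(fit)$coefficients
    if (anyNA(stats::coef(fit)) || !"xint" %in% rownames(ct)) {
      base$gamma_hat <- NA_real_; base$se_gamma <- NA_real_
      base$p_gamma <- NA_real_
      base$model_tag <- "osrr-interaction"; base$degenerate <- TRUE
      return(base)
    }
    out <- data.frame(nu_hat = ct["yhat", 1], delta_hat = ct["x", 1],
                      se_delta = ct["x", 2], df_delta = fit$df.residual,
                      p_delta = ct["x", 4], gamma_hat = ct["xint", 1],
                      se_gamma = ct["xint", 2], p_gamma = ct["xint", 4])
  }
  out$direction <- ifelse(out$delta_hat > 0, "up",
                          ifelse(out$delta_hat < 0, "down", "none"))
  out$model_tag <- "osrr-interaction"
  out$degenerate <- FALSE
  out
}

#' Residual-based direct-effect estimate (fixed-network comparator)
#'
#' The earlier compendium approach keeps the trained network fixed (no
#' rescaling) and reads the direct effect of a perturbation from the
#' residual \eqn{r = y - B y} of each sample, summarized per condition.
#' Provided as a comparator to the jointly-estimated model.
#'
#' @param expt a centered [expression_matrix()].
#' @param model a `network_model` with matching genes.
#' @param cov optional [covariate_table()]; when given, residual means are
#'   reported per condition.
#' @return An object of class `residual_effects`: list with `residuals`
#'   (G x N matrix) and `phi_hat` (G x conditions matrix of residual means,
#'   or overall means when `cov` is absent).
#' @export
cosgrove_residual <- function(expt, model, cov = NULL) {
  stopifnot(inherits(expt, "expression_matrix"), inherits(model, "network_model"))
  if (!identical(model$gene_ids, expt$gene_ids))
    stop("gene identifiers of model and experiment do not match")
  if (!expt$centered) stop("experiment must be centered")
  R <- expt$values - model$coefficients %*% expt$values
  dimnames(R) <- dimnames(expt$values)
  if (!is.null(cov)) {
    stopifnot(inherits(cov, "covariate_table"))
    if (cov$n != ncol(R)) stop("covariate length != sample count")
    phi <- cbind(control = rowMeans(R[, cov$condition == 0, drop = FALSE]),
                 perturbed = rowMeans(R[, cov$condition == 1, drop = FALSE]))
  } else {
    phi <- cbind(overall = rowMeans(R))
  }
  structure(list(residuals = R, phi_hat = phi), class = "residual_effects")
}

#' Multiple-testing adjustment
#'
#' Benjamini–Hochberg step-up by default; optionally Storey-style q-values
#' with the null proportion estimated at a fixed 0.5 threshold,
#' \eqn{\hat\pi_0 = \min(1, \overline{I(p > 0.5)}/0.5)}.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param method `"bh"` or `"storey"`.
#' @return Vector of adjusted values (same length and order as `p`).
#' @export
adjust_pvalues <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > 0.5) / 0.5)
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Run the differential-expression analysis over all genes
#'
#' Applies [fit_de_gene()] (and optionally [fit_interaction_gene()]) to every
#' gene of a centered experiment, with BH adjustment of the condition
#' p-values. Passing `prediction = NULL` runs the naive comparator for every
#' gene.
#'
#' @param expt a centered [expression_matrix()].
#' @param prediction a `network_prediction` aligned with `expt`, or `NULL`.
#' @param cov a [covariate_table()].
#' @param pairing passed to [fit_de_gene()].
#' @param with_interaction logical; also fit the network-disruption model.
#' @param adjust_method passed to [adjust_pvalues()].
#' @return A `data.frame`, one row per gene in the experiment's gene order,
#'   with a leading `gene_id` column and a `q_delta` column.
#' @export
run_de_analysis <- function(expt, prediction = NULL, cov,
                            pairing = c("none", "fixed", "random"),
                            with_interaction = FALSE,
                            adjust_method = c("bh", "storey")) {
  pairing <- match.arg(pairing)
  adjust_method <- match.arg(adjust_method)
  stopifnot(inherits(expt, "expression_matrix"))
  if (!is.null(prediction)) {
    stopifnot(inherits(prediction, "network_prediction"))
    if (!identical(prediction$gene_ids, expt$gene_ids))
      stop("prediction and experiment gene identifiers do not match")
  }
  rows <- lapply(seq_along(expt$gene_ids), function(g) {
    yhat <- if (!is.null(prediction)) prediction$values[g, ]
    if (with_interaction && !is.null(yhat))
      fit_interaction_gene(expt$values[g, ], yhat, cov, pairing)
    else
      fit_de_gene(expt$values[g, ], yhat, cov, pairing)
  })
  res <- do.call(rbind, rows)
  res <- cbind(data.frame(gene_id = expt$gene_ids, stringsAsFactors = FALSE), res)
  res$q_delta <- adjust_pvalues(res$p_delta, adjust_method)
  if (with_interaction && "p_gamma" %in% colnames(res)) {
    ok <- is.finite(res$p_gamma)
    res$q_gamma <- NA_real_
    if (any(ok)) res$q_gamma[ok] <- adjust_pvalues(res$p_gamma[ok], adjust_method)
  }
  rownames(res) <- NULL
  res
}

#' Count significant genes at conventional p-value cutoffs
#'
#' Tabulates, separately for up- and down-regulated genes, how many reach
#' each cutoff — the usual layout for comparing methods' yields.
#'
#' @param results a results table from [run_de_analysis()].
#' @param cutoffs numeric vector of p-value cutoffs.
#' @param p_column which p-value column to threshold.
#' @return A `data.frame` with columns `direction`, `cutoff`, `n`.
#' @export
summarize_de <- function(results, cutoffs = c(0.05, 0.01, 0.001, 0.0001),
                         p_column = "p_delta") {
  stopifnot(p_column %in% colnames(results))
  grid <- expand.grid(direction = c("down", "up"), cutoff = cutoffs,
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(d, co)
    sum(results$direction == d & results[[p_column]] < co, na.rm = TRUE),
    grid$direction, grid$cutoff)
  grid[order(grid$direction, -grid$cutoff), , drop = FALSE]
}
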