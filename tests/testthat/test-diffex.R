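test_that("the naive model reproduces the pooled-variance t-test exactly", {
  set.seed(1)
  cov <- two_group_cov(6)
  for (i in 1:5) {
    y <- rnorm(12) + 0.5 * cov$condition
    fit <- fit_de_gene(y, NULL, cov, pairing = "none")
    tt <- t.test(y[cov$condition == 1], y[cov$condition == 0],
                 var.equal = TRUE)
    expect_equal(fit$p_delta, tt$p.value, tolerance = 1e-12)
    expect_equal(fit$delta_hat, unname(tt$estimate[1] - tt$estimate[2]),
                 tolerance = 1e-12)
    expect_identical(fit$model_tag, "naive")
  }
  # a constant prediction falls back to the naive model with a flag
  y <- rnorm(12)
  fit2 <- fit_de_gene(y, rep(3, 12), cov)
  tt2 <- t.test(y[cov$condition == 1], y[cov$condition == 0], var.equal = TRUE)
  expect_equal(fit2$p_delta, tt2$p.value, tolerance = 1e-12)
  expect_true(fit2$degenerate)
})

test_that("equal group means give a zero condition effect", {
  set.seed(2)
  cov <- two_group_cov(5)
  y <- rep(c(1, 2, 3, 4, 5), 2)  # identical in both groups
  fit <- fit_de_gene(y, NULL, cov)
  expect_lt(abs(fit$delta_hat), 1e-10)
  # with a group-balanced prediction the adjusted effect is also exactly zero
  yhat <- rep(c(0.4, -1, 2, 0.1, -1.5), 2)
  fit2 <- fit_de_gene(y, yhat, cov)
  expect_lt(abs(fit2$delta_hat), 1e-10)
})

test_that("the generative model's condition effect is recovered", {
  deltas <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 200
    cov <- covariate_table(rep(c(0, 1), each = n / 2))
    yhat <- rnorm(n)
    y <- 0.8 * yhat + 1.5 * cov$condition + rnorm(n)
    fit <- fit_de_gene(y, yhat, cov)
    expect_lt(abs(fit$delta_hat - 1.5), 3 * fit$se_delta)
    fit$delta_hat
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 1.5), 0.05)
})

test_that("condition inference is invariant to rescaling the prediction", {
  set.seed(3)
  cov <- two_group_cov(8)
  yhat <- rnorm(16)
  y <- yhat + cov$condition + rnorm(16)
  base <- fit_de_gene(y, yhat, cov)
  basei <- fit_interaction_gene(y, yhat, cov)
  for (c_scale in c(0.01, 100)) {
    f <- fit_de_gene(y, c_scale * yhat, cov)
    expect_equal(f$delta_hat, base$delta_hat, tolerance = 1e-10)
    expect_equal(f$p_delta, base$p_delta, tolerance = 1e-10)
    expect_equal(f$nu_hat * c_scale, base$nu_hat, tolerance = 1e-10)
    fi <- fit_interaction_gene(y, c_scale * yhat, cov)
    expect_equal(fi$gamma_hat * c_scale, basei$gamma_hat, tolerance = 1e-10)
    expect_equal(fi$p_gamma, basei$p_gamma, tolerance = 1e-10)
  }
})

test_that("paired designs are handled with fixed and random intercepts", {
  set.seed(4)
  n_pairs <- 10
  pair <- rep(paste0("p", 1:n_pairs), each = 2)
  cov <- covariate_table(rep(c(0, 1), n_pairs), pair_id = pair)
  pair_eff <- rep(rnorm(n_pairs, sd = 2), each = 2)
  y <- pair_eff + 1 * cov$condition + rnorm(2 * n_pairs, sd = 0.5)
  ffix <- fit_de_gene(y, NULL, cov, pairing = "fixed")
  fran <- fit_de_gene(y, NULL, cov, pairing = "random")
  funp <- fit_de_gene(y, NULL, cov, pairing = "none")
  expect_lt(abs(ffix$delta_hat - 1), 0.6)
  expect_lt(abs(fran$delta_hat - 1), 0.6)
  # strong pair effects: accounting for pairing must sharpen the test
  expect_lt(ffix$p_delta, funp$p_delta)
  expect_lt(fran$p_delta, funp$p_delta)
  expect_error(fit_de_gene(y, NULL, covariate_table(rep(c(0, 1), n_pairs)),
                           pairing = "random"), "pair_id")
})

test_that("a boundary pair variance falls back to ordinary least squares", {
  set.seed(5)
  pair <- rep(paste0("p", 1:8), each = 2)
  cov <- covariate_table(rep(c(0, 1), 8), pair_id = pair)
  y <- rnorm(16)  # no pair structure at all
  fran <- fit_de_gene(y, NULL, cov, pairing = "random")
  fols <- fit_de_gene(y, NULL, cov, pairing = "none")
  expect_equal(fran$p_delta, fols$p_delta, tolerance = 1e-8)
})

test_that("interaction effects are recovered and the null is calibrated", {
  gammas <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    n <- 40
    cov <- covariate_table(rep(c(0, 1), each = n / 2))
    yhat <- rnorm(n)
    y <- 1 * yhat - 0.5 * yhat * cov$condition + 0.3 * cov$condition + rnorm(n)
    fit_interaction_gene(y, yhat, cov)$gamma_hat
  }, numeric(1))
  expect_lt(abs(mean(gammas) + 0.5), 0.1)

  # type-I error of the gamma test under gamma = 0
  set.seed(6)
  n <- 30
  cov <- covariate_table(rep(c(0, 1), each = n / 2))
  p <- vapply(1:1000, function(i) {
    yhat <- rnorm(n)
    y <- 0.7 * yhat + rnorm(n)
    fit_interaction_gene(y, yhat, cov)$p_gamma
  }, numeric(1))
  rate <- mean(p < 0.05)
  half_width <- 2.576 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rate - 0.05), half_width)

  # prediction constant within cases: flagged, not crashed
  yhat_c <- c(rnorm(15), rep(2, 15))
  fit_d <- fit_interaction_gene(rnorm(30), yhat_c, cov)
  expect_true(fit_d$degenerate)
  expect_true(is.na(fit_d$p_gamma))
})

test_that("fixed-network residuals match the definition", {
  db <- center_genes(random_expression(6, 10, seed = 7))
  net <- fit_network(db, 2)
  ex <- center_genes(random_expression(6, 5, seed = 8))
  r <- cosgrove_residual(ex, net)
  oracle <- matrix(NA_real_, 6, 5)
  for (g in 1:6) for (j in 1:5)
    oracle[g, j] <- ex$values[g, j] - sum(net$coefficients[g, ] * ex$values[, j])
  expect_equal(unname(r$residuals), oracle, tolerance = 1e-12)

  # zero network: residual is the data itself
  net0 <- net; net0$coefficients[] <- 0
  expect_equal(cosgrove_residual(ex, net0)$residuals, ex$values)

  # fixed-point construction: build B with zero diagonal so that Bv = v,
  # then any matrix whose columns are multiples of v has zero residual
  v <- c(1.3, -0.7, 2.1, 0.5)
  B <- outer(v, v) / (sum(v^2) - v^2)  # row g: v_g * v_h / sum_{h != g} v_h^2
  diag(B) <- 0
  expect_equal(as.vector(B %*% v), v, tolerance = 1e-12)
  Yfix <- v %o% c(1.5, -0.5, -1)       # column weights sum to 0: rows centered
  exf <- expression_matrix(Yfix, paste0("g", 1:4), paste0("s", 1:3),
                           centered = TRUE)
  netf <- structure(list(coefficients = B, lambda = 1,
                         gene_ids = exf$gene_ids,
                         training_meta = list(n_train = 3)),
                    class = "network_model")
  expect_lt(max(abs(cosgrove_residual(exf, netf)$residuals)), 1e-10)

  # per-condition residual means
  cov <- two_group_cov(2)  # 4 samples
  ex4 <- center_genes(random_expression(6, 4, seed = 10))
  rc <- cosgrove_residual(ex4, net, cov)
  expect_equal(dim(rc$phi_hat), c(6L, 2L))
  expect_equal(rc$phi_hat[, "control"],
               rowMeans(rc$residuals[, 1:2]), tolerance = 1e-12)
})

test_that("p-value adjustment follows the BH step-up", {
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_pvalues(0.031), 0.031)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.2, 0.8, 0.04)
  expect_true(all(adjust_pvalues(p) >= p))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  # Storey variant shrinks BH by the estimated null proportion
  set.seed(11)
  p2 <- c(runif(50, 0, 0.01), runif(50))
  expect_true(all(adjust_pvalues(p2, "storey") <= adjust_pvalues(p2) + 1e-12))
})

test_that("the full-table analysis composes the per-gene fits", {
  st <- simulate_de_study(n_genes = 10, block_sizes = c(5, 5), n_db = 30,
                          de_prob = 0, seed = 12)
  ex <- center_genes(st$experiment)
  net <- fit_network(center_genes(st$database), 1e3)
  pred <- predict_network(net, ex)
  res <- run_de_analysis(ex, pred, st$covariates, with_interaction = TRUE)
  expect_equal(nrow(res), 10)
  expect_identical(res$gene_id, ex$gene_ids)
  manual <- fit_interaction_gene(ex$values[4, ], pred$values[4, ],
                                 st$covariates)
  expect_equal(res$p_delta[4], manual$p_delta, tolerance = 1e-12)
  expect_equal(res$gamma_hat[4], manual$gamma_hat, tolerance = 1e-12)
  expect_true(all(res$q_delta >= res$p_delta - 1e-15))

  counts <- summarize_de(res)
  expect_equal(sum(counts$n[counts$cutoff == 0.05]),
               sum(res$p_delta < 0.05 & res$direction != "none"))
})

test_that("no-effect experiments rarely yield extreme p-values", {
  extreme <- vapply(1:20, function(s) {
    st <- simulate_de_study(n_genes = 10, block_sizes = c(5, 5), n_db = 30,
                            de_prob = 0, seed = 200 + s)
    res <- run_de_analysis(center_genes(st$experiment), NULL, st$covariates)
    any(res$p_delta < 1e-4)
  }, logical(1))
  expect_lte(sum(extreme), 1)
})
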