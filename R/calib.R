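#' Fit a beta-uniform mixture to a p-value histogram
#'
#' Models p-values as a mixture of a uniform component (null genes) and a
#' Beta(a, 1) spike near zero (signal), with density
#' \deqn{f(p) = \pi + (1-\pi)\, a\, p^{a-1}, \qquad 0 < a < 1,}
#' which integrates to one on (0, 1]. Parameters are fit by maximum
#' likelihood on logit-transformed scales with multiple restarts. Exact
#' zeros are clamped to the smallest positive double with a warning (the
#' density is unbounded at zero).
#'
#' The family is not identified at the uniform boundary: as `a` approaches 1
#' the beta component itself becomes uniform and the mixture weight is
#' arbitrary. When the fitted mixture does not improve on the pure-uniform
#' model by more than the usual 2-df likelihood-ratio cutoff, the fit is
#' collapsed to the uniform solution (`mix_uniform = 1`, `collapsed = TRUE`)
#' — the canonical representative of that ridge of equivalent solutions.
#'
#' @param p vector of p-values in (0, 1\]; at least 50 recommended.
#' @param n_restarts number of optimizer starts.
#' @return An object of class `bum_fit`: list with `mix_uniform` (weight of
#'   the uniform component), `shape_a`, `loglik`, `converged`, `collapsed`,
#'   `n`.
#' @export
fit_bum <- function(p, n_restarts = 5) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-values equal to 0 clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  if (length(p) < 2) stop("need at least 2 p-values")
  lp <- log(p)
  nll <- function(par) {
    pi0 <- stats::plogis(par[1]); a <- stats::plogis(par[2])
    -sum(log(pi0 + (1 - pi0) * a * exp((a - 1) * lp)))
  }
  starts <- list(c(0, 0), c(2, -1), c(-2, -1), c(2, 1), c(-1, -2))
  best <- NULL
  for (s in starts[seq_len(min(n_restarts, length(starts)))]) {
    fit <- try(stats::optim(s, nll, method = "BFGS",
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("beta-uniform mixture optimization failed")
  ll <- -best$value
  if (2 * ll < stats::qchisq(0.95, df = 2)) {
    # no real spike: report the canonical pure-uniform member of the ridge
    return(structure(list(mix_uniform = 1, shape_a = stats::plogis(best$par[2]),
                          loglik = 0, converged = best$convergence == 0,
                          collapsed = TRUE, n = length(p)),
                     class = "bum_fit"))
  }
  structure(list(mix_uniform = stats::plogis(best$par[1]),
                 shape_a = stats::plogis(best$par[2]),
                 loglik = ll,
                 converged = best$convergence == 0,
                 collapsed = FALSE,
                 n = length(p)),
            class = "bum_fit")
}

#' @export
print.bum_fit <- function(x, ...) {
  cat(sprintf("bum_fit: uniform weight %.3f, beta shape %.3f (loglik %.2f)\n",
              x$mix_uniform, x$shape_a, x$loglik))
  invisible(x)
}

#' Beta-uniform mixture density
#'
#' @param fit a `bum_fit` (or list with `mix_uniform` and `shape_a`).
#' @param p points in (0, 1\].
#' @return Density values.
#' @export
bum_density <- function(fit, p) {
  fit$mix_uniform + (1 - fit$mix_uniform) * fit$shape_a * p^(fit$shape_a - 1)
}

#' Empirical-Bayes false-positive rate at a p-value
#'
#' The ratio of the uniform (null) component over the full mixture density,
#' \eqn{\pi / f(p)}, clipped to \[0, 1\] — the estimated probability that a
#' gene with this p-value is a false positive.
#'
#' @param fit a `bum_fit`.
#' @param p scalar or vector of p-values in (0, 1\].
#' @return Values in \[0, 1\], non-decreasing in `p` when `shape_a < 1`.
#' @export
fpr_at <- function(fit, p) {
  pmin(1, pmax(0, fit$mix_uniform / bum_density(fit, p)))
}

#' Permutation null distribution of the per-gene tests
#'
#' Re-assigns the condition labels and recomputes the full per-gene analysis
#' for each permutation. In a paired design the case/control labels are
#' swapped within each pair (the exchangeable relabelings of a paired
#' experiment); when the number of requested permutations exceeds the
#' 2^(#pairs) distinct relabelings, all distinct ones are used exactly once.
#' Unpaired designs permute the label vector.
#'
#' @param expt a centered [expression_matrix()].
#' @param prediction a `network_prediction` or `NULL`.
#' @param cov a [covariate_table()].
#' @param method `"osrr"` (uses the prediction) or `"naive"`.
#' @param n_perm number of permutations (conventional default 100).
#' @param seed integer seed.
#' @param pairing passed to [run_de_analysis()].
#' @param perms optional list of explicit 0/1 condition vectors overriding
#'   random generation (e.g. the identity relabeling for checks).
#' @return An object of class `permutation_null`: list with `n_perm`,
#'   `seed`, and `pvalues` — a long `data.frame` (`perm`, `gene_id`, `p`).
#' @export
permutation_null <- function(expt, prediction = NULL, cov,
                             method = c("osrr", "naive"), n_perm = 100,
                             seed = 1L, pairing = c("none", "fixed", "random"),
                             perms = NULL) {
  method <- match.arg(method)
  pairing <- match.arg(pairing)
  stopifnot(inherits(cov, "covariate_table"))
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (method == "naive") prediction <- NULL

  if (is.null(perms)) {
    set.seed(as.integer(seed))
    if (!is.null(cov$pair_id)) {
      pairs <- unique(cov$pair_id)
      k <- length(pairs)
      # within-pair swaps; enumerate when the space is small enough
      if (k <= 25 && 2^k <= n_perm) {
        signs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), k)))
        n_perm <- nrow(signs)
      } else {
        signs <- matrix(sample(c(0L, 1L), n_perm * k, replace = TRUE),
                        nrow = n_perm)
        if (k <= 25) {  # drop duplicate relabelings, top up if needed
          signs <- unique(signs)
          while (nrow(signs) < n_perm) {
            extra <- matrix(sample(c(0L, 1L), n_perm * k, replace = TRUE),
                            nrow = n_perm)
            signs <- utils::head(unique(rbind(signs, extra)), n_perm)
          }
        }
      }
      if (all(vapply(split(cov$condition, cov$pair_id),
                     function(z) length(unique(z)) < 2, logical(1))))
        stop("no valid within-pair permutations: every pair has a single condition")
      perms <- lapply(seq_len(nrow(signs)), function(b) {
        cond <- cov$condition
        for (j in seq_len(k)) if (signs[b, j] == 1L) {
          idx <- which(cov$pair_id == pairs[j])
          cond[idx] <- 1 - cond[idx]
        }
        cond
      })
    } else {
      perms <- lapply(seq_len(n_perm), function(b) sample(cov$condition))
    }
  }
  out <- lapply(seq_along(perms), function(b) {
    cov_b <- covariate_table(perms[[b]], pair_id = cov$pair_id,
                             time_radians = cov$time_radians,
                             sample_ids = cov$sample_ids)
    res <- run_de_analysis(expt, prediction, cov_b, pairing = pairing)
    data.frame(perm = b, gene_id = res$gene_id, p = res$p_delta,
               stringsAsFactors = FALSE)
  })
  structure(list(n_perm = length(perms), seed = seed,
                 pvalues = do.call(rbind, out)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: %d permutations x %d genes (seed %s)\n",
              x$n_perm, length(unique(x$pvalues$gene_id)), format(x$seed)))
  invisible(x)
}

#' Fixed-width histogram summary of p-values
#'
#' Bin counts on \[0, 1\] with a fixed bin width, the usual display for
#' comparing observed and permuted p-value distributions.
#'
#' @param p vector of p-values.
#' @param width bin width (default 0.05).
#' @return A `data.frame` with `bin_lower`, `bin_upper`, `count`.
#' @export
pvalue_histogram <- function(p, width = 0.05) {
  breaks <- seq(0, 1, by = width)
  cts <- as.vector(table(cut(p, breaks = breaks, include.lowest = TRUE)))
  data.frame(bin_lower = utils::head(breaks, -1), bin_upper = breaks[-1],
             count = cts)
}
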