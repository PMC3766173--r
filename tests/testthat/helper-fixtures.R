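# fixtures built in code, shared across test files

random_expression <- function(G, N, seed = 1, prefix = "g") {
  set.seed(seed)
  expression_matrix(matrix(rnorm(G * N), G, N,
                           dimnames = list(sprintf("%s%02d", prefix, seq_len(G)),
                                           sprintf("s%02d", seq_len(N)))))
}

# primal closed-form ridge solve with gene g physically deleted
primal_ridge_oracle <- function(db, g, lambda) {
  X <- t(db$values[-g, , drop = FALSE])
  y <- db$values[g, ]
  beta <- solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, y))
  full <- numeric(nrow(db$values))
  full[-g] <- beta
  full
}

two_group_cov <- function(n_per_group) {
  covariate_table(rep(c(0, 1), each = n_per_group))
}
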