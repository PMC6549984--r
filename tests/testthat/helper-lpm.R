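# Fixture builders shared across the suite.  Everything is generated in code;
# no stored data files.

# Construct an lpm_data object directly from y and a design matrix.
make_data <- function(y, X, kinds = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(kinds)) {
    kinds <- vapply(seq_len(ncol(X)), function(j) {
      col <- X[, j]
      if (all(col == 1)) "constant"
      else if (all(col %in% c(-1, 1))) "binary_pm1"
      else "continuous"
    }, character(1))
    names(kinds) <- colnames(X)
  }
  structure(list(y = as.numeric(y), X = X,
                 missing_mask = matrix(FALSE, nrow(X), ncol(X),
                                       dimnames = dimnames(X)),
                 column_meta = kinds, n_dropped_outcome = 0L),
            class = "lpm_data")
}

# Random feasible design + outcomes under the model (fixed seed supplied by
# the caller).  Intercept plus (p - 1) uniform covariates on [-1, 1].
random_lpm <- function(n, beta, seed) {
  set.seed(seed)
  p <- length(beta)
  X <- cbind(1, matrix(runif(n * (p - 1), -1, 1), n, p - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  delta <- drop(X %*% beta)
  stopifnot(all(abs(delta) < 1))
  y <- ifelse(runif(n) < (1 + delta) / 2, 1, -1)
  make_data(y, X)
}

# A fit object at arbitrary (beta, Sigma): the diagnostics only read fields.
fit_at <- function(data, beta, sigma) {
  delta <- drop(data$X %*% beta)
  structure(list(beta_hat = beta, cov_hat = sigma, delta_hat = delta,
                 method = "ols", n = nrow(data$X),
                 n_out_of_range = sum(abs(delta) > 1)),
            class = "lpm_fit")
}

# Shared acceptance design: intercept + two +/-1 binaries + one uniform
# covariate, study-like kinds, worst support corner |b'x| = 0.6.
acceptance_covariates <- function() {
  list(covariate_spec("b1", "binary_pm1", prob = 0.5),
       covariate_spec("b2", "binary_pm1", prob = 0.25),
       covariate_spec("u1", "continuous", lower = -1, upper = 1))
}
acceptance_beta <- c(0.1, 0.2, 0.15, 0.15)
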