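# Out-of-range diagnostic for the linear-in-probability model.
#
# Even when the model holds, estimation noise in beta_hat pushes some fitted
# values x_i' beta_hat outside [-1, 1].  The expected number of such rows is
# lambda = sum_i p_i with
#   p_i = Phi{(-1 + b'x_i)/s_i} + Phi{(-1 - b'x_i)/s_i},  s_i^2 = x_i' Sigma x_i,
# by the asymptotic normality of the OLS estimator.  An observed count R
# appreciably larger than lambda casts doubt on the model.  The variance of R
# exceeds the Poisson bound lambda because the indicator summands share the
# same beta_hat; the full expression adds pairwise terms built from
# bivariate-normal quadrant probabilities.

#' Probability that one fitted value falls outside \[-1, 1\]
#'
#' Two-tailed normal probability \eqn{\Phi\{(-1+\delta_i)/\sqrt{s_i}\} +
#' \Phi\{(-1-\delta_i)/\sqrt{s_i}\}} that estimation noise carries the fitted
#' linear predictor for a row with true predictor `delta_i` and predictor
#' variance `s_i` past \eqn{\pm 1}.  Vectorized; symmetric in the sign of
#' `delta_i`.
#'
#' @param delta_i Linear predictor(s) \eqn{x_i'\beta}.
#' @param s_i Variance(s) \eqn{x_i'\Sigma_\beta x_i} of the fitted predictor;
#'   must be positive.
#' @return Out-of-range probabilities in \eqn{[0, 1]}.
#' @export
out_of_range_probability <- function(delta_i, s_i) {
  if (any(s_i <= 0)) {
    stop("out_of_range_probability: degenerate variance, s_i <= 0")
  }
  sd <- sqrt(s_i)
  pnorm((-1 + delta_i) / sd) + pnorm((-1 - delta_i) / sd)
}

new_range_diagnostic <- function(r_observed, lambda_hat, p_i,
                                 var_independent = NA_real_,
                                 var_full = NA_real_,
                                 method_note = "pairwise terms not computed",
                                 out_rows = integer()) {
  structure(list(
    r_observed = r_observed,
    lambda_hat = lambda_hat,
    p_i = p_i,
    var_r_independent = var_independent,
    var_r_full = var_full,
    var_r_poisson_bound = lambda_hat,
    method_note = method_note,
    out_of_range_rows = out_rows
  ), class = "lpm_range")
}

#' Predicted number of out-of-range fitted values
#'
#' Counts the fitted values outside \eqn{[-1, 1]} and computes the predicted
#' expected count \eqn{\hat\lambda = \sum_i \hat p_i}, plugging the estimated
#' coefficients and covariance into the per-row out-of-range probability.
#'
#' @param fit An `lpm_fit` carrying a valid covariance estimate.
#' @param data The [lpm_data()] object the fit was computed from.
#' @return An object of class `lpm_range` with `r_observed`, `lambda_hat`,
#'   `p_i`, the Poisson lower bound on `var(R)`, and the out-of-range row
#'   indices; the pairwise variance fields are `NA` until
#'   [variance_out_of_range()] fills them.
#' @export
predicted_out_of_range <- function(fit, data) {
  stopifnot(inherits(fit, "lpm_fit"), inherits(data, "lpm_data"))
  require_complete(data, "predicted_out_of_range")
  if (any(is.na(fit$cov_hat))) {
    stop("predicted_out_of_range: fit carries no valid covariance estimate")
  }
  X <- data$X
  s <- rowSums((X %*% fit$cov_hat) * X)     # x_i' Sigma x_i
  if (any(s <= 0)) {
    stop("predicted_out_of_range: degenerate variance x_i' Sigma x_i <= 0 ",
         "at row(s) ", paste(head(which(s <= 0), 5), collapse = ", "))
  }
  p <- out_of_range_probability(fit$delta_hat, s)
  new_range_diagnostic(
    r_observed = sum(abs(fit$delta_hat) > 1),
    lambda_hat = sum(p),
    p_i = p,
    out_rows = which(abs(fit$delta_hat) > 1)
  )
}

# pr(|bhat'x_i| > 1, |bhat'x_j| > 1) as the sum of four quadrant
# probabilities; vectorized over pairs.  zp = (1 - delta)/s is the upper
# exceedance threshold, zm = (1 + delta)/s the lower one; the lower-tail
# events flip the sign of Z and hence of the correlation.
pair_both_out <- function(zp_i, zm_i, zp_j, zm_j, rho, mode) {
  quadrant_probability(zp_i, zp_j, rho, mode) +
    quadrant_probability(zm_i, zm_j, rho, mode) +
    quadrant_probability(zp_i, zm_j, -rho, mode) +
    quadrant_probability(zm_i, zp_j, -rho, mode)
}

#' Variance of the out-of-range count
#'
#' Fills the variance fields of the out-of-range diagnostic:
#' \deqn{\mathrm{var}(R) = \sum_i p_i(1-p_i) + \sum_{i \ne j}
#' \{\mathrm{pr}(\text{both out of range}) - p_i p_j\},} where the joint
#' probability sums four bivariate-normal quadrant probabilities with
#' correlation \eqn{\rho_{ij} = x_i'\Sigma x_j / (s_i s_j)} (sign-flipped for
#' the lower-tail events).  When the number of ordered pairs exceeds
#' `max_pairs`, the pairwise sum is estimated from a simple random subsample
#' of pairs and scaled up; the note field records the subsample size.
#'
#' @param fit An `lpm_fit` with a valid covariance estimate.
#' @param data The [lpm_data()] object the fit was computed from.
#' @param pair_mode `"numeric"` (quadrature) or `"approx"`
#'   (conditional-expectation approximation) for the quadrant probabilities.
#' @param max_pairs Largest number of ordered pairs summed exactly
#'   (default `1e6`); beyond this a random subsample of `max_pairs` ordered
#'   pairs is used.
#' @return An `lpm_range` object with all variance fields filled.
#' @export
variance_out_of_range <- function(fit, data,
                                  pair_mode = c("numeric", "approx"),
                                  max_pairs = 1e6) {
  pair_mode <- match.arg(pair_mode)
  diag0 <- predicted_out_of_range(fit, data)
  X <- data$X
  Sig <- fit$cov_hat
  XS <- X %*% Sig
  s2 <- rowSums(XS * X)
  s <- sqrt(s2)
  delta <- fit$delta_hat
  zp <- (1 - delta) / s
  zm <- (1 + delta) / s
  p <- diag0$p_i
  n <- nrow(X)

  var_ind <- sum(p * (1 - p))

  n_ordered <- as.numeric(n) * (n - 1)
  exact <- n_ordered <= max_pairs
  if (exact) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    scale <- 2                                   # unordered -> ordered
    note <- sprintf("exact pairwise sum over %d unordered pairs (%s mode)",
                    length(i), pair_mode)
  } else {
    m <- ceiling(max_pairs / 2)
    i <- sample.int(n, m, replace = TRUE)
    j <- sample.int(n - 1L, m, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)               # j != i, uniform over ordered pairs
    scale <- n_ordered / m
    note <- sprintf(
      "pairwise sum estimated from %d random ordered pairs scaled by %.4g (%s mode)",
      m, scale, pair_mode)
  }
  rho <- rowSums(XS[i, , drop = FALSE] * X[j, , drop = FALSE]) / (s[i] * s[j])
  rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  both <- pair_both_out(zp[i], zm[i], zp[j], zm[j], rho, pair_mode)
  pair_sum <- scale * sum(both - p[i] * p[j])

  diag0$var_r_independent <- var_ind
  diag0$var_r_full <- var_ind + pair_sum
  diag0$method_note <- note
  diag0
}

#' @export
print.lpm_range <- function(x, ...) {
  cat("Out-of-range diagnostic\n")
  cat(sprintf("  observed count R          : %d\n", x$r_observed))
  cat(sprintf("  predicted count lambda    : %.2f\n", x$lambda_hat))
  cat(sprintf("  Poisson lower bound var(R): %.2f\n", x$var_r_poisson_bound))
  if (!is.na(x$var_r_independent)) {
    cat(sprintf("  var(R), independent terms : %.2f\n", x$var_r_independent))
  }
  if (!is.na(x$var_r_full)) {
    cat(sprintf("  var(R), with pairwise     : %.2f\n", x$var_r_full))
    cat(sprintf("  (%s)\n", x$method_note))
    flag <- abs(x$r_observed - x$lambda_hat) > 2 * sqrt(max(x$var_r_full, 0))
    cat(sprintf("  adequacy: %s\n",
                if (flag) "observed count differs from prediction by more than 2 SD; doubt cast on the model"
                else "observed count consistent with the model"))
  }
  invisible(x)
}
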