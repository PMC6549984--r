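# Coefficient interpretation in expected-count units, and the
# coefficient-ratio comparison with logistic regression.

#' Expected-count effect of a coefficient
#'
#' With outcomes coded \eqn{\pm 1}, the number of positive outcomes among n
#' individuals is \eqn{S = \sum_i Z_i} with \eqn{Z_i = (Y_i+1)/2}.  Replacing
#' `m` individuals by counterparts differing by one unit in covariate j
#' changes \eqn{E(S)} by \eqn{m\beta_j/2}.  For a binary covariate coded
#' \{-1, +1\} a level change spans two units, so the division by two is not
#' needed and the change is \eqn{m\beta_j}.
#'
#' @param fit An `lpm_fit`.
#' @param covariate Name of the covariate (must match a coefficient name).
#' @param m Hypothetical number of individuals replaced (positive integer).
#' @param kind `"continuous"` (unit change, effect \eqn{m\beta_j/2}) or
#'   `"binary_pm1"` (level change, effect \eqn{m\beta_j}).
#' @return An object of class `lpm_effect` with the coefficient, the kind,
#'   `m`, and `expected_change`.
#' @examples
#' \donttest{
#' sim <- simulate_lpm(nlsy_like_spec(2000, seed = 8))
#' fit <- fit_ols(lpm_complete(sim$data))
#' effect_statement(fit, "gender", m = 100, kind = "binary_pm1")
#' }
#' @export
effect_statement <- function(fit, covariate, m,
                             kind = c("continuous", "binary_pm1")) {
  kind <- match.arg(kind)
  stopifnot(inherits(fit, "lpm_fit"), m > 0)
  if (!covariate %in% names(fit$beta_hat)) {
    stop("unknown covariate '", covariate, "'; fit has: ",
         paste(names(fit$beta_hat), collapse = ", "))
  }
  b <- unname(fit$beta_hat[covariate])
  change <- if (kind == "continuous") m * b / 2 else m * b
  structure(list(covariate_name = covariate, coefficient = b,
                 covariate_kind = kind, m = m, expected_change = change),
            class = "lpm_effect")
}

#' @export
print.lpm_effect <- function(x, ...) {
  unit <- if (x$covariate_kind == "continuous") "one unit"
          else "one level (-1 to +1)"
  cat(sprintf(
    "Hypothetically replacing %d individuals by counterparts differing by %s\nin '%s' (all else equal) changes the expected number of positive outcomes\nby %+.4g (coefficient %.4g).\n",
    x$m, unit, x$covariate_name, x$expected_change, x$coefficient))
  invisible(x)
}

#' Logistic regression via iteratively reweighted least squares
#'
#' Fits the linear-logistic model to the \eqn{Z = (Y+1)/2} recode of the
#' outcome by Newton–Raphson on the Bernoulli log likelihood, implemented
#' in-package so the ratio comparison has no external model dependency.
#'
#' @param data An [lpm_data()] object with no missing covariate cells.
#' @param tol Score sup-norm convergence tolerance (default `1e-8`).
#' @param max_iter Maximum iterations (default 50).
#' @return A list with `beta_hat`, `cov_hat` (inverse observed information),
#'   `iterations`, and `logLik`.
#' @export
fit_logistic <- function(data, tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(data, "lpm_data"))
  require_complete(data, "fit_logistic")
  X <- data$X
  check_full_rank(X, "fit_logistic")
  z <- (data$y + 1) / 2
  beta <- numeric(ncol(X))
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    if (max(abs(eta)) > 30 && sqrt(sum(beta^2)) > 15) {
      stop("fit_logistic: separation detected (fitted probabilities ",
           "degenerate, coefficient norm diverging)")
    }
    mu <- 1 / (1 + exp(-eta))
    score <- drop(crossprod(X, z - mu))
    if (max(abs(score)) < tol) break
    w <- mu * (1 - mu)
    H <- crossprod(X * w, X)
    beta <- beta + drop(solve(H, score))
    if (iter == max_iter) {
      stop("fit_logistic: no convergence after ", max_iter, " iterations")
    }
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  cov <- solve(crossprod(X * (mu * (1 - mu)), X))
  names(beta) <- colnames(X)
  dimnames(cov) <- list(colnames(X), colnames(X))
  list(beta_hat = beta, cov_hat = (cov + t(cov)) / 2,
       iterations = iter,
       logLik = sum(z * log(mu) + (1 - z) * log1p(-mu)))
}

#' Compare coefficient ratios between the linear and logistic fits
#'
#' Coefficient magnitudes from the two models are on different scales, but
#' their pairwise ratios \eqn{\beta_j/\beta_k} are directly comparable and in
#' practice remarkably similar; in the small-signal limit the logistic linear
#' predictor is approximately twice the linear-in-probability one, so the
#' ratios agree.
#'
#' @param lpm An `lpm_fit`.
#' @param logit_beta Logistic coefficient vector in the same covariate order
#'   (e.g. `fit_logistic(data)$beta_hat`).
#' @param exclude_intercept Drop the leading intercept from the comparison
#'   (default `TRUE`; the comparison concerns effect coefficients).
#' @return An object of class `lpm_ratio_comparison`: both coefficient
#'   vectors, the two ratio matrices (`NA` where the denominator magnitude is
#'   below `1e-12`), and `max_relative_discrepancy`.
#' @export
compare_ratios <- function(lpm, logit_beta, exclude_intercept = TRUE) {
  stopifnot(inherits(lpm, "lpm_fit"))
  b1 <- lpm$beta_hat
  b2 <- logit_beta
  if (length(b1) != length(b2)) {
    stop("compare_ratios: coefficient vectors have different lengths (",
         length(b1), " vs ", length(b2), ")")
  }
  if (exclude_intercept) {
    drop_idx <- which(names(b1) == "(Intercept)")
    if (length(drop_idx) == 0L) drop_idx <- 1L
    b1 <- b1[-drop_idx[1]]
    b2 <- b2[-drop_idx[1]]
  }
  ratio_mat <- function(b) {
    r <- outer(b, b, "/")
    r[abs(rep(b, each = length(b))) <= 1e-12] <- NA_real_  # denominator ~ 0
    diag(r) <- 1
    r
  }
  r1 <- ratio_mat(b1)
  r2 <- ratio_mat(b2)
  ok <- !is.na(r1) & !is.na(r2) & row(r1) != col(r1)
  disc <- if (any(ok)) {
    max(abs(r1[ok] - r2[ok]) / pmax(abs(r2[ok]), 1e-12))
  } else NA_real_
  structure(list(lpm_coefficients = b1, logit_coefficients = b2,
                 ratio_matrix_lpm = r1, ratio_matrix_logit = r2,
                 max_relative_discrepancy = disc),
            class = "lpm_ratio_comparison")
}

#' @export
print.lpm_ratio_comparison <- function(x, ...) {
  cat("Coefficient-ratio comparison: linear-in-probability vs logistic\n")
  tab <- rbind(lpm = x$lpm_coefficients, logistic = x$logit_coefficients)
  print(signif(tab, 4))
  cat("ratio matrix (linear-in-probability):\n")
  print(signif(x$ratio_matrix_lpm, 3))
  cat("ratio matrix (logistic):\n")
  print(signif(x$ratio_matrix_logit, 3))
  cat(sprintf("max relative discrepancy between ratio matrices: %.4g\n",
              x$max_relative_discrepancy))
  invisible(x)
}
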