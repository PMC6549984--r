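# Constrained maximum likelihood for the linear-in-probability model.
#
# The log likelihood l(b) = sum_i log(1 + y_i x_i'b) is concave and finite
# only while |x_i'b| <= 1 for every row; a single row with |x_i'b| > 1 sends
# l(b) to -Inf, which is the fragility that makes OLS preferable in practice.
# Maximization is damped Newton ascent kept strictly inside the box
# |x_i'b| <= 1 - boundary_margin by an exact ratio test on the step length.

#' Log likelihood of the linear-in-probability model
#'
#' Returns \eqn{\ell(\beta) = \sum_i \log(1 + y_i x_i'\beta)}, or `-Inf` when
#' any row has \eqn{|x_i'\beta| > 1} (outside the parameter space the
#' likelihood of some observed outcome is non-positive).
#'
#' @param data An [lpm_data()] object with no missing covariate cells.
#' @param beta Coefficient vector.
#' @return A scalar log likelihood.
#' @export
lpm_loglik <- function(data, beta) {
  stopifnot(inherits(data, "lpm_data"))
  require_complete(data, "lpm_loglik")
  a <- 1 + data$y * drop(data$X %*% beta)
  if (any(a <= 0)) return(-Inf)
  sum(log(a))
}

#' Constrained maximum-likelihood fit
#'
#' Maximizes the concave log likelihood subject to
#' \eqn{|x_i'\beta| \le 1 - \epsilon} for every sample row, where
#' \eqn{\epsilon} is `boundary_margin`.  The default start is the OLS
#' estimate shrunk toward zero until feasible.  Convergence is declared when
#' the score sup-norm falls below `tol` or when a boundary constraint is
#' active and no feasible ascent step remains (then `boundary_active` is set
#' and no covariance is reported).  The covariance estimate at an interior
#' optimum is the inverse observed information.
#'
#' @param data An [lpm_data()] object with no missing covariate cells.
#' @param boundary_margin Interior offset \eqn{\epsilon > 0} (default `1e-6`).
#' @param start Optional starting coefficient vector; it is shrunk toward
#'   zero if infeasible.
#' @param tol Score sup-norm convergence tolerance (default `1e-8`).
#' @param max_iter Maximum Newton iterations (default 200).
#' @return An `lpm_fit` with `method = "ml"`, plus `boundary_active`,
#'   `score_norm`, `iterations` and `logLik`.
#' @export
fit_ml <- function(data, boundary_margin = 1e-6, start = NULL,
                   tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(data, "lpm_data"),
            boundary_margin > 0, boundary_margin < 0.5)
  require_complete(data, "fit_ml")
  X <- data$X
  y <- data$y
  check_full_rank(X, "fit_ml")
  p <- ncol(X)
  eps <- boundary_margin
  cap <- 1 - eps

  feasible_shrink <- function(b, margin) {
    d <- drop(X %*% b)
    m <- max(abs(d))
    if (m <= margin) return(b)
    b * (margin / m)
  }
  beta <- if (is.null(start)) {
    ols <- drop(solve(crossprod(X), crossprod(X, y)))
    feasible_shrink(ols, 1 - 2 * eps)
  } else {
    feasible_shrink(as.numeric(start), 1 - 2 * eps)
  }
  if (max(abs(drop(X %*% beta))) > cap + 1e-12) {
    stop("fit_ml internal invariant violation: shrunken start infeasible")
  }

  loglik <- function(d) sum(log(1 + y * d))
  delta <- drop(X %*% beta)
  ll <- loglik(delta)
  boundary_active <- FALSE
  score <- NULL

  iter <- 0L
  stalled <- FALSE
  for (iter in seq_len(max_iter)) {
    a <- 1 + y * delta
    score <- drop(crossprod(X, y / a))
    if (max(abs(score)) < tol) break
    H <- crossprod(X / a, X / a)            # observed information (positive definite)
    dir <- drop(solve(H, score))
    dd <- drop(X %*% dir)

    # largest t >= 0 with |delta + t * dd| <= cap rowwise (ratio test)
    pos <- dd > 0
    neg <- dd < 0
    t_max <- min(c(Inf,
                   (cap - delta[pos]) / dd[pos],
                   (-cap - delta[neg]) / dd[neg]))
    t_max <- max(t_max, 0)

    t <- min(1, t_max)
    accepted <- FALSE
    while (t > 1e-14) {
      cand <- delta + t * dd
      llc <- loglik(cand)
      if (is.finite(llc) && llc > ll) {
        beta <- beta + t * dir
        delta <- cand
        ll <- llc
        accepted <- TRUE
        break
      }
      t <- t / 2
    }
    if (!accepted) {
      if (max(abs(delta)) >= cap - 1e-8) {
        boundary_active <- TRUE               # pinned to the feasibility box
        break
      }
      if (sum(score * dir) < 1e-10) {         # ascent below rounding: converged
        stalled <- TRUE
        break
      }
      stop("fit_ml: no feasible ascent step at an interior iterate ",
           "(score sup-norm ", format(max(abs(score))), "); last iterate: ",
           paste(signif(beta, 6), collapse = ", "))
    }
  }
  a <- 1 + y * delta
  score <- drop(crossprod(X, y / a))
  if (max(abs(score)) >= tol && !boundary_active && !stalled) {
    if (max(abs(delta)) >= cap - 1e-8) {
      boundary_active <- TRUE
    } else {
      stop("fit_ml: no convergence after ", max_iter,
           " iterations (score sup-norm ", format(max(abs(score))),
           "); last iterate: ", paste(signif(beta, 6), collapse = ", "))
    }
  }

  if (boundary_active) {
    cov <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
    warning("fit_ml: solution on the feasibility boundary; ",
            "observed-information covariance not reported")
  } else {
    H <- crossprod(X / a, X / a)
    cov <- solve(H)
    cov <- (cov + t(cov)) / 2
    dimnames(cov) <- list(colnames(X), colnames(X))
  }
  names(beta) <- colnames(X)
  new_lpm_fit(beta, cov, delta, "ml", nrow(X),
              extra = list(boundary_active = boundary_active,
                           score_norm = max(abs(score)),
                           iterations = iter,
                           logLik = ll))
}

#' Analytic OLS-versus-ML variance comparison
#'
#' Computes, at a feasible coefficient vector, the corrected OLS covariance
#' \eqn{(X'X)^{-1} - (X'X)^{-1} X'\Delta X (X'X)^{-1}} and the
#' maximum-likelihood large-sample approximation
#' \eqn{\{X'(I-\Delta)^{-1}X\}^{-1}} (a lower bound on
#' \eqn{\{X'(I+\Delta)X\}^{-1}}), together with their difference.  The
#' difference is of order \eqn{n^{-1}\max_i \delta_i^4/(1-\delta_i^2)}:
#' writing \eqn{\Upsilon = (I-\Delta)^{-1} - I}, the geometric series gives
#' \eqn{\Upsilon - \Delta = \mathrm{diag}\{\delta_i^4/(1-\delta_i^2)\}},
#' which the function verifies internally, so the efficiency loss from using
#' least squares is typically negligible.
#'
#' @param data An [lpm_data()] object with no missing covariate cells.
#' @param beta Coefficient vector with \eqn{|x_i'\beta| < 1} for all rows.
#' @return An object of class `lpm_efficiency`: list with `var_ols`,
#'   `var_ml_approx`, `inflation` (their difference), `bound_scalar`
#'   (\eqn{n^{-1}\max_i \delta_i^4/(1-\delta_i^2)}) and `max_abs_delta`.
#' @export
efficiency_gap <- function(data, beta) {
  stopifnot(inherits(data, "lpm_data"))
  require_complete(data, "efficiency_gap")
  X <- data$X
  stopifnot(length(beta) == ncol(X))
  delta <- drop(X %*% beta)
  if (any(abs(delta) >= 1)) {
    stop("efficiency_gap: infeasible beta, |x_i'beta| >= 1 for row(s) ",
         paste(head(which(abs(delta) >= 1), 5), collapse = ", "))
  }
  d2 <- delta^2
  XtX_inv <- solve(crossprod(X))
  var_ols <- XtX_inv - XtX_inv %*% crossprod(X * d2, X) %*% XtX_inv
  var_ml <- solve(crossprod(X * (1 / (1 - d2)), X))  # {X'(I-Delta)^{-1}X}^{-1}
  inflation <- var_ols - var_ml

  # internal identity check: Upsilon - Delta = diag(d^4 / (1 - d^2))
  ups_minus_delta <- 1 / (1 - d2) - 1 - d2
  stopifnot(max(abs(ups_minus_delta - d2^2 / (1 - d2))) < 1e-10)

  structure(list(
    var_ols = (var_ols + t(var_ols)) / 2,
    var_ml_approx = (var_ml + t(var_ml)) / 2,
    inflation = (inflation + t(inflation)) / 2,
    bound_scalar = max(d2^2 / (1 - d2)) / nrow(X),
    max_abs_delta = max(abs(delta))
  ), class = "lpm_efficiency")
}

#' @export
print.lpm_efficiency <- function(x, ...) {
  cat("OLS vs ML variance comparison\n")
  cat(sprintf("  max |delta_i| = %.4f\n", x$max_abs_delta))
  cat(sprintf("  bound scalar max(delta^4/(1-delta^2))/n = %.3e\n",
              x$bound_scalar))
  rel <- diag(x$inflation) / diag(x$var_ml_approx)
  cat("  relative variance inflation of OLS (diagonal):\n")
  print(signif(rel, 4))
  invisible(x)
}
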