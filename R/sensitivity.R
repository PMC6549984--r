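# Extreme-assignment sensitivity analysis for missing covariates.
#
# Rather than imputing under an untestable missing-at-random assumption,
# every missing cell of each partially observed covariate is set to a "low"
# or a "high" level (lower/upper quartile of observed values for continuous
# covariates, -1/+1 for binary ones) and the model refit under every
# high/low pattern — the full 2^k two-level factorial for k such covariates,
# or a half fraction when k is large.  If the coefficient estimates barely
# move across patterns, the conclusions do not rest on the missing values.

#' Build the high/low assignment design for partially missing covariates
#'
#' Determines which covariates have missing cells, assigns each a (low, high)
#' pair — the lower and upper quartile of the observed values
#' (linear-interpolation definition, `quantile` type 7) for continuous
#' covariates, \eqn{(-1, +1)} for binary ones — and enumerates the assignment
#' patterns: the full \eqn{2^k} factorial when `k <= max_full_factorial`,
#' otherwise a resolution-k half fraction defined by aliasing the
#' highest-order interaction (patterns whose \eqn{\pm 1} codes multiply to
#' +1).
#'
#' @param data An [lpm_data()] object.
#' @param user_levels Optional named list of `c(low, high)` overrides per
#'   covariate.
#' @param max_full_factorial Largest k for which the full factorial is used
#'   (default 8).
#' @return An object of class `lpm_sensitivity_design`: `variables`, `levels`
#'   (named list of low/high pairs), `patterns` (character matrix of
#'   `"L"`/`"H"`, one row per pattern, rownames like `"LHH"`), `design_kind`,
#'   and `defining_contrast` (for a half fraction).
#' @export
build_design <- function(data, user_levels = NULL, max_full_factorial = 8L) {
  stopifnot(inherits(data, "lpm_data"))
  vars <- colnames(data$X)[colSums(data$missing_mask) > 0L]
  if (length(vars) == 0L) {
    return(structure(list(variables = character(), levels = list(),
                          patterns = matrix(character(), nrow = 1L, ncol = 0L,
                                            dimnames = list("", NULL)),
                          design_kind = "full_factorial",
                          defining_contrast = NULL),
                     class = "lpm_sensitivity_design"))
  }
  levels <- lapply(vars, function(v) {
    if (!is.null(user_levels) && v %in% names(user_levels)) {
      lv <- as.numeric(user_levels[[v]])
      stopifnot(length(lv) == 2L, lv[1] < lv[2])
      return(lv)
    }
    obs <- data$X[!data$missing_mask[, v], v]
    if (length(obs) == 0L) {
      stop("build_design: covariate '", v, "' is entirely missing; ",
           "cannot set levels")
    }
    if (data$column_meta[[v]] == "binary_pm1") return(c(-1, 1))
    lv <- unname(quantile(obs, c(0.25, 0.75), type = 7))
    if (lv[1] >= lv[2]) {
      stop("build_design: degenerate quartile levels for '", v, "'")
    }
    lv
  })
  names(levels) <- vars
  k <- length(vars)

  grid <- as.matrix(expand.grid(rep(list(c("L", "H")), k),
                                stringsAsFactors = FALSE))[, k:1, drop = FALSE]
  colnames(grid) <- vars
  kind <- "full_factorial"
  contrast <- NULL
  if (k > max_full_factorial) {
    code <- ifelse(grid == "H", 1, -1)
    keep <- apply(code, 1L, prod) == 1       # alias the k-way interaction
    grid <- grid[keep, , drop = FALSE]
    kind <- "half_fraction"
    contrast <- paste0("I = ", paste(vars, collapse = ":"))
  }
  rownames(grid) <- apply(grid, 1L, paste, collapse = "")
  structure(list(variables = vars, levels = levels, patterns = grid,
                 design_kind = kind, defining_contrast = contrast),
            class = "lpm_sensitivity_design")
}

#' @export
print.lpm_sensitivity_design <- function(x, ...) {
  k <- length(x$variables)
  cat(sprintf("Sensitivity design: %s, %d variable(s), %d pattern(s)\n",
              x$design_kind, k, nrow(x$patterns)))
  for (v in x$variables) {
    cat(sprintf("  %s: low = %.4g, high = %.4g\n",
                v, x$levels[[v]][1], x$levels[[v]][2]))
  }
  if (!is.null(x$defining_contrast)) {
    cat("  defining contrast:", x$defining_contrast, "\n")
  }
  invisible(x)
}

# Fill missing cells per one assignment pattern and return the completed data.
fill_pattern <- function(data, design, pattern_row) {
  out <- data
  for (v in design$variables) {
    lv <- design$levels[[v]]
    val <- if (pattern_row[[v]] == "H") lv[2] else lv[1]
    miss <- data$missing_mask[, v]
    out$X[miss, v] <- val
    out$missing_mask[miss, v] <- FALSE
  }
  # covariates outside the design may still be missing; the refit will error
  out
}

#' Refit the model under every high/low missingness pattern
#'
#' For each pattern in the design, fills every missing cell of each design
#' variable with that pattern's level, refits by ordinary least squares with
#' the corrected covariance, attaches the out-of-range diagnostic, and
#' summarizes the spread of the coefficient estimates across patterns.
#'
#' @param data An [lpm_data()] object.
#' @param design An [build_design()] result consistent with `data`.
#' @param fitter Only `"ols"` is supported (maximum likelihood would inherit
#'   its fragility to aberrant filled-in rows).
#' @return An object of class `lpm_sensitivity`: `per_pattern` (data frame,
#'   one row per pattern: coefficients, standard errors, observed and
#'   predicted out-of-range counts), `coefficients` and `ses` (matrices,
#'   patterns x p), `max_abs_difference` (per coefficient), and `fits`.
#' @export
run_sensitivity <- function(data, design, fitter = "ols") {
  stopifnot(inherits(data, "lpm_data"),
            inherits(design, "lpm_sensitivity_design"))
  fitter <- match.arg(fitter, "ols")
  outside <- setdiff(colnames(data$X)[colSums(data$missing_mask) > 0L],
                     design$variables)
  if (length(outside) > 0L) {
    stop("run_sensitivity: covariate(s) with missing cells not in the ",
         "design: ", paste(outside, collapse = ", "))
  }
  pat <- design$patterns
  labels <- rownames(pat)
  fits <- vector("list", nrow(pat))
  names(fits) <- labels
  for (r in seq_len(nrow(pat))) {
    filled <- fill_pattern(data, design, as.list(setNames(as.character(pat[r, ]), design$variables)))
    fits[[r]] <- tryCatch(fit_ols(filled), error = function(e) {
      stop("run_sensitivity: fit failed for pattern '", labels[r], "': ",
           conditionMessage(e))
    })
  }
  coefs <- t(vapply(fits, function(f) f$beta_hat,
                    numeric(length(fits[[1]]$beta_hat))))
  ses <- t(vapply(fits, function(f) sqrt(pmax(diag(f$cov_hat), 0)),
                  numeric(ncol(coefs))))
  r_obs <- vapply(fits, function(f) f$n_out_of_range, integer(1))
  lam <- vapply(seq_along(fits), function(r) {
    filled <- fill_pattern(data, design, as.list(setNames(as.character(pat[r, ]), design$variables)))
    predicted_out_of_range(fits[[r]], filled)$lambda_hat
  }, numeric(1))
  max_abs_diff <- apply(coefs, 2L, function(col) diff(range(col)))

  per_pattern <- data.frame(pattern = labels, coefs, se = ses,
                            n_out_of_range = r_obs,
                            lambda_hat = lam,
                            check.names = FALSE, row.names = NULL)
  structure(list(per_pattern = per_pattern,
                 coefficients = coefs, ses = ses,
                 max_abs_difference = max_abs_diff,
                 design = design, fits = fits),
            class = "lpm_sensitivity")
}

#' @export
print.lpm_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity analysis over %d missingness pattern(s)\n",
              nrow(x$coefficients)))
  tab <- cbind(x$coefficients,
               n_out = x$per_pattern$n_out_of_range,
               lambda = round(x$per_pattern$lambda_hat, 1))
  print(signif(tab, 4))
  cat("max absolute difference per coefficient:\n")
  print(signif(x$max_abs_difference, 3))
  invisible(x)
}

#' Main effects of missingness assignments on the estimates
#'
#' Codes each pattern entry as \eqn{\pm 1} (L = -1, H = +1) and computes, for
#' every model coefficient, the least-squares main effect of each design
#' variable's assignment: in an orthogonal (full factorial or regular half
#' fraction) design this is half the difference between the mean estimate
#' over high patterns and over low patterns.
#'
#' @param report A [run_sensitivity()] result.
#' @param design The design the report was computed from.
#' @return A matrix (design variables x model coefficients) of main effects.
#' @export
missingness_main_effects <- function(report, design) {
  stopifnot(inherits(report, "lpm_sensitivity"),
            inherits(design, "lpm_sensitivity_design"))
  pat <- design$patterns
  if (length(design$variables) == 0L) {
    return(matrix(numeric(), 0L, ncol(report$coefficients)))
  }
  code <- ifelse(pat == "H", 1, -1)
  # orthogonality check: columns must be balanced and mutually orthogonal
  G <- crossprod(code) / nrow(code)
  if (any(colSums(code) != 0) || max(abs(G - diag(ncol(code)))) > 1e-12) {
    stop("missingness_main_effects: pattern set is not an orthogonal ",
         "two-level design; main effects are not estimable by contrasts")
  }
  eff <- crossprod(code, report$coefficients) / nrow(code)  # = half (mean H - mean L)
  rownames(eff) <- design$variables
  eff
}
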