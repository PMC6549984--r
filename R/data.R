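#' Assemble a binary-outcome dataset in the model's canonical coding
#'
#' Builds the container used by every fitting routine: an outcome vector in
#' \{-1, +1\} coding, a design matrix (with a leading column of ones unless
#' `intercept = FALSE`), a logical mask marking missing covariate cells, and a
#' per-column kind flag.  Rows whose *outcome* is missing are dropped (they
#' carry no information about the dependence of outcome on covariates); rows
#' with missing *covariate* cells are kept and flagged in the mask, so that
#' the extreme-assignment sensitivity analysis can later fill them.
#'
#' @param table A data frame with one row per individual.
#' @param outcome Name of the binary outcome column.
#' @param covariates Character vector of covariate column names (all numeric).
#' @param coding Either `"zero_one"` (outcome coded \{0, 1\}; 0 is recoded to
#'   -1) or `"pm1"` (already \{-1, +1\}).
#' @param intercept Prepend a constant column of ones (default `TRUE`).
#' @return An object of class `lpm_data`: a list with elements `y` (numeric,
#'   entries -1/+1), `X` (numeric matrix, n x p), `missing_mask` (logical
#'   matrix, same shape as `X`), `column_meta` (character vector, one of
#'   `"constant"`, `"binary_pm1"`, `"continuous"` per column), and
#'   `n_dropped_outcome` (rows removed because the outcome was missing).
#' @examples
#' d <- data.frame(y = c(0, 1, 1, 0), x = c(-1, 1, 1, -1))
#' lpm_data(d, "y", "x")
#' @export
lpm_data <- function(table, outcome, covariates,
                     coding = c("zero_one", "pm1"), intercept = TRUE) {
  coding <- match.arg(coding)
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(c(outcome, covariates), names(table))
  if (length(missing_cols) > 0L) {
    stop("columns not found in input: ", paste(missing_cols, collapse = ", "))
  }
  y_raw <- table[[outcome]]
  if (!is.numeric(y_raw)) stop("outcome column '", outcome, "' must be numeric")

  keep <- !is.na(y_raw)
  n_dropped <- sum(!keep)
  y_raw <- y_raw[keep]

  levels_obs <- sort(unique(y_raw))
  if (length(levels_obs) != 2L) {
    stop("invalid outcome: expected exactly two observed levels, found ",
         length(levels_obs), " (", paste(levels_obs, collapse = ", "), ")")
  }
  expected <- if (coding == "zero_one") c(0, 1) else c(-1, 1)
  if (!isTRUE(all.equal(levels_obs, expected))) {
    stop("invalid outcome: levels (", paste(levels_obs, collapse = ", "),
         ") do not match coding '", coding, "'")
  }
  y <- if (coding == "zero_one") 2 * y_raw - 1 else y_raw

  for (v in covariates) {
    if (!is.numeric(table[[v]])) {
      stop("covariate '", v, "' is not numeric")
    }
  }
  Xcov <- as.matrix(table[keep, covariates, drop = FALSE])
  storage.mode(Xcov) <- "double"

  kind <- vapply(covariates, function(v) {
    obs <- Xcov[, v][!is.na(Xcov[, v])]
    if (length(obs) > 0L && all(obs %in% c(-1, 1))) "binary_pm1" else "continuous"
  }, character(1))

  if (intercept) {
    X <- cbind("(Intercept)" = 1, Xcov)
    kind <- c("(Intercept)" = "constant", kind)
  } else {
    X <- Xcov
  }
  mask <- is.na(X)
  if (nrow(X) < ncol(X)) {
    stop("fewer rows than columns after dropping missing outcomes (n = ",
         nrow(X), ", p = ", ncol(X), ")")
  }

  structure(
    list(y = as.numeric(y), X = X, missing_mask = mask,
         column_meta = kind, n_dropped_outcome = n_dropped),
    class = "lpm_data"
  )
}

#' @export
print.lpm_data <- function(x, ...) {
  cat("Linear-in-probability dataset\n")
  cat(sprintf("  n = %d, p = %d (outcome coded -1/+1)\n",
              nrow(x$X), ncol(x$X)))
  cat(sprintf("  positive outcomes: %d (%.1f%%)\n",
              sum(x$y == 1), 100 * mean(x$y == 1)))
  if (x$n_dropped_outcome > 0L) {
    cat(sprintf("  rows dropped for missing outcome: %d\n", x$n_dropped_outcome))
  }
  n_miss <- colSums(x$missing_mask)
  if (any(n_miss > 0L)) {
    cat("  missing covariate cells:\n")
    for (j in which(n_miss > 0L)) {
      cat(sprintf("    %s: %d (%.1f%%)\n", colnames(x$X)[j], n_miss[j],
                  100 * n_miss[j] / nrow(x$X)))
    }
  } else {
    cat("  no missing covariate cells\n")
  }
  invisible(x)
}

# Rows with no missing covariate cell.
complete_rows <- function(data) !apply(data$missing_mask, 1L, any)

# Design matrix restricted to complete rows; errors if any missingness would
# silently be used by a fitter.
require_complete <- function(data, caller) {
  if (any(data$missing_mask)) {
    stop(caller, ": design matrix contains missing covariate cells; ",
         "resolve missingness first (e.g. via the sensitivity analysis or ",
         "by subsetting to complete rows with lpm_complete())")
  }
  invisible(data)
}

#' Restrict a dataset to rows with fully observed covariates
#'
#' @param data An `lpm_data` object.
#' @return An `lpm_data` object containing only complete rows.
#' @export
lpm_complete <- function(data) {
  stopifnot(inherits(data, "lpm_data"))
  keep <- complete_rows(data)
  out <- data
  out$y <- data$y[keep]
  out$X <- data$X[keep, , drop = FALSE]
  out$missing_mask <- data$missing_mask[keep, , drop = FALSE]
  out
}

# Subset helper used by sensitivity refits and the CLI's exclusion refit.
lpm_subset <- function(data, rows) {
  out <- data
  out$y <- data$y[rows]
  out$X <- data$X[rows, , drop = FALSE]
  out$missing_mask <- data$missing_mask[rows, , drop = FALSE]
  out
}
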