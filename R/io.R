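# Delimited-text input and report rendering.

#' Read a delimited text file into an analysis dataset
#'
#' Thin wrapper over [utils::read.csv()] that applies the configurable
#' missing-value tokens and hands the result to [lpm_data()].
#'
#' @param path CSV/TSV file with a header row.
#' @param outcome,covariates,coding,intercept Passed to [lpm_data()].
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @param na_tokens Strings treated as missing (default `c("", "NA", ".")`).
#' @return An [lpm_data()] object.
#' @export
read_lpm_csv <- function(path, outcome, covariates,
                         coding = c("zero_one", "pm1"), intercept = TRUE,
                         sep = ",", na_tokens = c("", "NA", ".")) {
  tab <- read.csv(path, sep = sep, na.strings = na_tokens,
                  check.names = FALSE)
  lpm_data(tab, outcome, covariates, coding = coding, intercept = intercept)
}

# Machine-readable fit summary (the text rendering derives from this).
fit_summary_list <- function(fit, level = 0.95) {
  ct <- coef_table(fit, level)
  list(
    method = fit$method,
    n = fit$n,
    coefficients = as.list(setNames(ct$estimate, rownames(ct))),
    se = as.list(setNames(ct$se, rownames(ct))),
    z = as.list(setNames(ct$z, rownames(ct))),
    ci_lower = as.list(setNames(ct$lower, rownames(ct))),
    ci_upper = as.list(setNames(ct$upper, rownames(ct))),
    ci_level = level,
    n_out_of_range = fit$n_out_of_range
  )
}

range_summary_list <- function(rng) {
  list(
    r_observed = rng$r_observed,
    lambda_hat = rng$lambda_hat,
    var_r_independent = rng$var_r_independent,
    var_r_full = rng$var_r_full,
    var_r_poisson_bound = rng$var_r_poisson_bound,
    method_note = rng$method_note,
    adequacy_doubt = if (is.na(rng$var_r_full)) NA else
      abs(rng$r_observed - rng$lambda_hat) > 2 * sqrt(max(rng$var_r_full, 0)),
    out_of_range_rows = rng$out_of_range_rows
  )
}

sensitivity_summary_list <- function(sens) {
  list(
    design_kind = sens$design$design_kind,
    variables = sens$design$variables,
    levels = sens$design$levels,
    per_pattern = sens$per_pattern,
    max_abs_difference = as.list(sens$max_abs_difference)
  )
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# Sensitivity report as CSV: rows = patterns, final row = max abs difference.
write_sensitivity_csv <- function(sens, path) {
  tab <- sens$per_pattern
  extra <- tab[1, , drop = FALSE]
  extra[1, ] <- NA
  extra$pattern <- "max_abs_difference"
  p <- ncol(sens$coefficients)
  extra[1, 1 + seq_len(p)] <- sens$max_abs_difference
  out <- rbind(tab, extra)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

render_fit_text <- function(fit, level = 0.95) {
  ct <- coef_table(fit, level)
  lines <- c(
    sprintf("Linear-in-probability model fit (%s), n = %d", toupper(fit$method), fit$n),
    sprintf("%-14s %10s %10s %8s %10s %10s",
            "coefficient", "estimate", "se", "z",
            sprintf("%.0f%% lo", 100 * level), sprintf("%.0f%% hi", 100 * level)))
  for (i in seq_len(nrow(ct))) {
    lines <- c(lines, sprintf("%-14s %10.4g %10.4g %8.2f %10.4g %10.4g",
                              rownames(ct)[i], ct$estimate[i], ct$se[i],
                              ct$z[i], ct$lower[i], ct$upper[i]))
  }
  c(lines, sprintf("fitted values outside [-1, 1]: %d", fit$n_out_of_range))
}
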