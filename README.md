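# lpmbin — linear-in-probability models for binary outcomes

`lpmbin` estimates and stress-tests the **linear-in-probability model**
(LPM) for binary data: with outcomes coded $Y_i \in \{-1,+1\}$ and
covariates $x_i$ (intercept included),

$$\mathrm{pr}(Y_i = y \mid x_i) = \tfrac12\,(1 + y\,\beta^T x_i),
\qquad\text{so}\qquad E(Y_i \mid x_i) = \beta^T x_i,$$

subject to the parameter-space restriction $|\beta^T x| \le 1$.  The model
is attractive to epidemiologists and social scientists because $\beta_j$
reads directly in expected *counts of individuals*: replacing $m$
individuals by counterparts one unit higher in covariate $j$ changes the
expected number of positive outcomes by $m\beta_j/2$ (no division by 2 for
±1-coded binary covariates).  The package provides:

* **`fit_ols`** — least squares with the corrected covariance
  $\Sigma_\beta = (x^Tx)^{-1} - (x^Tx)^{-1}x^T\Delta x(x^Tx)^{-1}$,
  $\Delta = \mathrm{diag}\{(\beta^Tx_i)^2\}$, plugged in at
  $\hat\beta_{OLS}$ (plus a cautious one-step **`fit_wls`**);
* **`fit_ml`** — concave log likelihood
  $\sum_i\log(1+y_i x_i^T\beta)$ maximised under the row constraints
  $|x_i^T\beta|\le 1-\epsilon$, and **`efficiency_gap`**, the analytic
  OLS-vs-ML variance comparison showing the efficiency loss is
  $O(n^{-1}\max_i\delta_i^4/(1-\delta_i^2))$ — while a single row with
  $|\beta^Tx|>1$ destroys the likelihood but moves OLS by $O(1/n)$;
* **`predicted_out_of_range` / `variance_out_of_range`** — the model
  diagnostic: observed count $R$ of fitted values outside $[-1,1]$, its
  predicted value $\hat\lambda=\sum_i\hat p_i$, and $\mathrm{var}(R)$
  including pairwise dependence via bivariate-normal **quadrant
  probabilities** (`quadrant_probability`, quadrature and closed-form
  approximation);
* **`build_design` / `run_sensitivity` / `missingness_main_effects`** — the
  extreme-assignment sensitivity analysis for missing covariates: refit
  under all $2^k$ high/low fill patterns (quartile levels for continuous
  covariates), summarise the spread, estimate main effects of missingness;
* **`effect_statement` / `fit_logistic` / `compare_ratios`** —
  expected-count interpretation and the LPM-vs-logistic coefficient-ratio
  comparison;
* **`simulate_lpm` / `nlsy_like_spec`** — a seeded synthetic-data generator
  (mixed ±1 binary / bounded continuous / clamped-normal covariates,
  feasibility enforcement, MCAR missingness, optional contaminated rows)
  so everything above is testable without external data;
* a **CLI** (`inst/cli/lpmbin`) with subcommands `fit`, `diagnose`,
  `sensitivity`, `compare`, `simulate`, `full`.

## Worked example

```r
library(lpmbin)

# a study-like synthetic dataset: 5 covariates, 3 partially missing
sim <- simulate_lpm(nlsy_like_spec(n = 5000, seed = 42))
dat <- lpm_complete(sim$data)      # complete rows for the headline fit
fit <- fit_ols(dat)
print(fit)
```

```
Linear-in-probability model fit (OLS), n = 2241
            estimate        se        z    lower     upper
(Intercept) -0.92713 0.0701700 -13.2126 -1.06466 -0.789601
gender      -0.04662 0.0193781  -2.4058 -0.08460 -0.008639
afqt         0.01214 0.0006307  19.2547  0.01091  0.013381
log_income   0.03872 0.0080863   4.7886  0.02287  0.054571
race         0.13519 0.0224351   6.0260  0.09122  0.179166
with_parent  0.02070 0.0315623   0.6559 -0.04116  0.082562
Fitted values outside [-1, 1]: 0
```

Each coefficient is an expected-count effect; the corrected standard errors
account for the outcome variance $1-(\beta^Tx_i)^2$ varying across rows.
The model-adequacy diagnostic compares the observed out-of-range count with
its model-based prediction and variance:

```r
set.seed(42)
print(variance_out_of_range(fit, dat, pair_mode = "approx"))
```

```
Out-of-range diagnostic
  observed count R          : 0
  predicted count lambda    : 1.76
  Poisson lower bound var(R): 1.76
  var(R), independent terms : 1.42
  var(R), with pairwise     : 11.66
  (pairwise sum estimated from 500000 random ordered pairs scaled by 10.04 (approx mode))
  adequacy: observed count consistent with the model
```

Observing 0 out-of-range fitted values when ~1.8 were expected (with
standard deviation $\sqrt{11.7}\approx3.4$ — far above the naive Poisson
bound, because all the indicators share the same $\hat\beta$) raises no
doubt about the model.  Interpretation and the logistic comparison:

```r
effect_statement(fit, "race", m = 100, kind = "binary_pm1")
#> ... changes the expected number of positive outcomes by +13.52

cmp <- compare_ratios(fit, fit_logistic(dat)$beta_hat)
cmp$max_relative_discrepancy
#> 0.1561
```

Because three covariates have missing cells, their influence is bounded by
refitting under all 8 extreme fill patterns:

```r
des  <- build_design(sim$data)    # quartile levels: afqt (23.88, 74.5), ...
sens <- run_sensitivity(sim$data, des)
signif(sens$max_abs_difference, 2)
#> (Intercept)      gender        afqt  log_income        race with_parent
#>     0.04900     0.00170     0.00015     0.00530     0.00750     0.01100
```

Every coefficient moves by well under two standard errors across patterns:
the conclusions do not rest on the missing values.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lpmbin", package = "lpmbin"))')
Rscript "$CLI" simulate --n 2000 --seed 7 --out_csv demo.csv
Rscript "$CLI" full --input demo.csv --outcome y \
        --covariates gender,afqt,log_income,race,with_parent \
        --output_dir reports
```

`full` runs ingest → OLS with corrected covariance → out-of-range
diagnostic → sensitivity analysis (if any covariate has missing cells) →
logistic ratio comparison, writing `report.json`, `report.txt` and
`sensitivity.csv`.  Configuration can also come from a JSON file
(`--config cfg.json`; flags override).  Exit codes: 0 success, 2 validation
error, 3 computation error.

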