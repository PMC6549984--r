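---
title: "Methods: the linear-in-probability model for binary outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the linear-in-probability model for binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

For independent individuals $i = 1, \dots, n$ with binary outcome
$Y_i \in \{-1, +1\}$ and covariate vector $x_i \in \mathbb{R}^p$ (first
entry 1 for the intercept), the linear-in-probability model specifies

$$\mathrm{pr}(Y_i = y \mid x_i) = \tfrac12 (1 + y\,\beta^T x_i),
\qquad y \in \{-1, +1\},$$

so that $E(Y_i \mid x_i) = \beta^T x_i$.  The parameter space is implicitly
restricted: $|\beta^T x| \le 1$ must hold for every covariate vector the
model is asked about.  Compared with the linear-logistic model, the linear
form buys a direct operational reading of the coefficients — in expected
*numbers of individuals* affected by a covariate change — at the price of
that boundedness constraint, which is also the source of everything
interesting in this package: the heteroskedasticity correction, the
fragility of maximum likelihood, and the out-of-range diagnostic.

`lpmbin` canonicalises outcomes to $\{-1, +1\}$ at ingestion ($\{0,1\}$
input is recoded $0 \mapsto -1$); every formula below assumes that coding.
Binary covariates are likewise expected in $\pm 1$ coding, under which a
level change spans two units.

## Estimation

**Ordinary least squares.** $\hat\beta_{OLS} = (x^Tx)^{-1}x^TY$ is unbiased,
but $\mathrm{var}(Y_i) = 1 - (\beta^Tx_i)^2$ is not constant, so the naive
covariance $(x^Tx)^{-1}$ is wrong unless $\beta = 0$.  The corrected form is

$$\Sigma_\beta = (x^Tx)^{-1} - (x^Tx)^{-1} x^T \Delta x (x^Tx)^{-1},
\qquad \Delta = \mathrm{diag}\{(\beta^Tx_i)^2\},$$

estimated by plugging $\hat\beta_{OLS}$ into $\Delta$.  The plug-in can
produce $\hat\delta_i^2 = (x_i^T\hat\beta)^2 > 1$ (a negative implied
outcome variance); such entries are clipped at 1 and the clip count is
surfaced as a diagnostic, since the model itself gives no guidance there.
The correction always *shrinks* the naive variances, strictly so in any
coordinate with a nonzero sandwich term.

**Weighted least squares.** A single reweighting step with weights
$1/\max\{1-\hat\delta_i^2,\ v_0\}$ is provided (`fit_wls`).  Because the
outcome variance is not bounded away from zero, WLS is *not* a sound
general-purpose method: near-boundary rows get unbounded weight.  The floor
$v_0 = 0.05$ caps that influence, any floored weight raises a caution flag,
and the step is deliberately not iterated to convergence — iterating would
chase exactly the degenerate weights the floor exists to contain.

**Constrained maximum likelihood.** The log likelihood
$\ell(\beta) = \sum_i \log(1 + y_i\,x_i^T\beta)$ is concave and finite only
while $|x_i^T\beta| \le 1$ for every row.  `fit_ml` maximises it by damped
Newton ascent constrained to $|x_i^T\beta| \le 1-\epsilon$ (default
$\epsilon = 10^{-6}$), with an exact ratio test on the step length so
iterates stay feasible, starting from the OLS estimate shrunk toward zero
until feasible (the origin is always feasible, so the start exists).
Convergence is a score sup-norm below $10^{-8}$; when the remaining Newton
increment falls below floating-point resolution of the log likelihood the
iterate is accepted as converged at numerical precision.  A solution pinned
to the constraint is flagged `boundary_active` and carries no covariance; at
an interior optimum the covariance is the inverse observed information.

**Why OLS anyway?** Two results make OLS the recommended default.  First,
the efficiency loss is negligible: with
$\Upsilon = (I-\Delta)^{-1} - I$, the geometric series gives
$\Upsilon - \Delta = \mathrm{diag}\{\delta_i^4/(1-\delta_i^2)\}$ and the
variance inflation of OLS over the large-sample ML approximation
$\{x^T(I-\Delta)^{-1}x\}^{-1}$ is
$O(n^{-1}\max_i \delta_i^4/(1-\delta_i^2))$ — fourth order in the signal.
`efficiency_gap` computes both matrices, their difference, and this bound
scalar, verifying the diagonal identity internally.  (The large-sample ML
variance can be stated two ways, $\{x^T(I+\Delta)x\}^{-1}$ or the bound
$\{x^T(I-\Delta)^{-1}x\}^{-1}$; the report uses the latter, which is the
form the comparison is cleanest in.  The reported covariance of an actual
`fit_ml` is the inverse observed information instead — a deliberate
asymmetry.)  Second, ML is fragile: a single observation with
$|\beta^Tx_i| > 1$ — a measurement error, or a row from a slightly
different model — makes $\ell(\beta) = -\infty$ at the true parameter,
formally refuting it, while the OLS estimate moves by $O(1/n)$.  The
synthetic-data generator can manufacture exactly this contamination (see
below), and the test suite demonstrates both halves.

## Interpreting coefficients

With $Z_i = (Y_i+1)/2$ counting positive outcomes, replacing $m$
individuals by counterparts one unit higher in covariate $j$ changes the
expected count by $m\beta_j/2$; for a $\pm1$-coded binary covariate a level
change is two units and the division by two disappears.
`effect_statement` renders this arithmetic.  Although linear and logistic
coefficient *magnitudes* are not comparable, their pairwise ratios are, and
in the small-signal limit the logistic linear predictor is approximately
twice the linear one, so the ratio matrices converge.  `compare_ratios`
computes both matrices (intercept excluded by default; ratios with
denominator magnitude below $10^{-12}$ are reported as undefined rather
than infinite) and their maximum relative discrepancy.  The logistic fit is
an in-package Newton–Raphson/IRLS so the comparison has no external model
dependency; separation is detected by a diverging coefficient norm with
degenerate fitted probabilities.

## The out-of-range diagnostic

Even under a valid model, estimation noise pushes some fitted values
$x_i^T\hat\beta$ outside $[-1,1]$.  By asymptotic normality of
$\hat\beta$, row $i$ falls out of range with probability

$$p_i \simeq \Phi\!\left(\frac{-1+\beta^Tx_i}{\sqrt{x_i^T\Sigma_\beta x_i}}\right)
      + \Phi\!\left(\frac{-1-\beta^Tx_i}{\sqrt{x_i^T\Sigma_\beta x_i}}\right),$$

and $\lambda = \sum_i p_i$ is the expected out-of-range count.  An observed
count $R$ appreciably larger than $\hat\lambda$ casts doubt on the model;
reports flag "doubt" when $|R-\hat\lambda| > 2\sqrt{\widehat{\mathrm{var}}(R)}$
(the factor 2 is a package convention, not a derived constant).

Because all the indicator summands share the same $\hat\beta$, $R$ is far
from Poisson: $\lambda$ is only a crude lower bound for its variance.  The
full expression adds pairwise terms,
$\mathrm{var}(R) = \sum_i p_i(1-p_i) + \sum_{i\ne j}\{\mathrm{pr}(\text{both
out}) - p_ip_j\}$, where the joint probability decomposes into four standard
bivariate-normal quadrant probabilities with correlation
$\rho_{ij} = x_i^T\Sigma x_j/(s_is_j)$ — both tails of each row, with the
correlation sign flipped for opposite tails.

**Quadrant probabilities.** $\mathrm{pr}(Z_1 > z_1, Z_2 > z_2)$ is reduced
to the one-dimensional integral
$\int_{z_1}^\infty \Phi\{(\rho s - z_2)/\sqrt{1-\rho^2}\}\,\phi(s)\,ds$
(this is the only reading of the classical display that integrates to the
correct total probability: the weight must be the normal *density*).  The
production path is a vectorised 128-point Gauss–Legendre rule on
$[z_1, \max(z_1+14, 9)]$, whose truncated tail is below
$\Phi(-9) \approx 10^{-19}$; an adaptive `stats::integrate` refinement
backs the test oracles, and the two agree to about $10^{-13}$ on a wide
grid, comfortably inside the $10^{-10}$ working tolerance.  A cheap
closed-form approximation replaces the conditioning variable by its
truncated mean: $\Phi(-z_1)\,\Phi\{(\rho\,\phi(z_1)/\Phi(-z_1) -
z_2)/\sqrt{1-\rho^2}\}$.  Where the two thresholds' roles could be
interchanged, the rule is deterministic: condition on the variable with the
larger exceedance probability $\Phi(-z)$, i.e. the better-conditioned
truncated mean.  $\rho = \pm1$ is answered by the comonotone closed forms
in approximate mode and refused in numeric mode.  The $O(n^2)$ pairwise sum
is exact up to $10^6$ ordered pairs and estimated from a scaled uniform
random subsample of pairs beyond that, with the subsample size recorded in
the result.

**When does the predicted count match the observed one?**  A subtlety worth
stating because it shaped the synthetic-data generator: the plug-in
$\hat p_i$ evaluates the normal tail at
$\hat z_i = (1-\hat\delta_i)/\hat s_i$, and since
$\mathrm{var}(\hat\delta_i) = s_i^2$ by construction, $\hat z_i$ carries
noise of standard deviation $\approx 1$ *regardless of $n$*.  Averaged over
replicates this flattens the tail: $E[\hat\lambda] \approx \sum_i
\Phi(-z_i/\sqrt2)$, versus $E[R] = \sum_i \Phi(-z_i)$.  The two agree
exactly at $z = 0$ and diverge in the tail, so observed and predicted
counts calibrate *only when the out-of-range probability mass sits at the
range boundary* — fitted values clumped near $\pm1$.  That is precisely the
regime real bounded instruments produce (floor/ceiling clumping of
percentile scores), and the calibration test operates there; in a design
whose linear predictors stay comfortably inside $(-1, 1)$, both $R$ and
$\lambda$ are tiny and the plug-in overpredicts by a factor approaching
$\Phi(-z/\sqrt2)/\Phi(-z)$.  The diagnostic remains conservative in that
direction: it overstates the expected count, so a *large observed excess*
over $\hat\lambda$ is still evidence against the model.

## Sensitivity analysis for missing covariates

Rather than imputing under an untestable missing-at-random assumption, the
package refits the model under extreme assignments: every missing cell of
each partially observed covariate is set to a low or high level — the lower
and upper quartiles of the observed values for continuous covariates
(linear-interpolation quantile definition, R type 7), $\mp1$ for binary
ones — over all $2^k$ high/low patterns for the $k$ such covariates
(labels like `LHH`, letters in declared variable order).  Rows with missing
*outcome* are dropped before any filling: they carry no information about
the outcome–covariate dependence.  Beyond `max_full_factorial` (default 8)
variables, a regular half fraction aliasing the $k$-way interaction is used
and its defining contrast recorded; fancier fractions are out of scope.
Standard errors are recomputed per pattern with that pattern's plug-in
$\hat\Delta$ (the alternative — freezing the base fit's — was rejected as
inconsistent with each pattern being a complete analysis).  The per-pattern
table, the per-coefficient maximum absolute difference, and — the patterns
being an orthogonal two-level design — least-squares main effects of each
variable's assignment on each coefficient are reported.  Only the OLS
fitter is wired in: filling cells at extreme levels is exactly the
perturbation maximum likelihood is fragile to.

## The synthetic-data generator

`simulate_lpm` draws covariates per spec (binary $\pm1$ with a success
probability; continuous uniform on a bounded support; or clamped normal —
a normal draw clamped to the support, putting probability atoms at the
bounds, emulating the floor/ceiling clumping of bounded instruments such as
percentile test scores), then outcomes with
$\mathrm{pr}(Y=+1) = (1+\beta^Tx)/2$, then completely-at-random missingness
cell by cell.  Feasibility of the linear predictor is enforced either by
redrawing offending rows (`reject`, capped) or by shrinking $\beta$ once so
the worst corner of the covariate support satisfies
$|\beta^Tx| \le 1-\mathrm{margin}$ (`rescale`).  The margin defaults to
0.02 so estimation noise rarely produces out-of-range fitted values beyond
what the model itself predicts.  Contaminated rows — covariates scaled 1.5
times beyond the support until $|\beta^Tx| > 1$ — are appended last and
flagged; their outcome is set to the value the postulated model deems
impossible there, which is the one choice that guarantees the documented
contract $\ell(\beta_{true}) = -\infty$ (drawing from a clamped probability
would yield the possible outcome almost surely and keep the likelihood
finite).  MAR/MNAR missingness mechanisms are deliberately absent: the
extreme-assignment sensitivity analysis is agnostic to the mechanism, which
is its point.

`nlsy_like_spec` is an illustrative fixture shaped like a large
youth-cohort educational-attainment study: five covariates (gender $\pm1$;
a 0–100 ability percentile; log family income on roughly 3–11.2; race
$\pm1$; lives-with-parent $\pm1$) with missingness rates 4.3%, 51.2% and
5.1% on the ability, income and parent variables.  Coefficient magnitudes
are of the order such studies report; since those magnitudes with these
supports put the worst support corner outside the parameter space (as in
the real data, where a few percent of fitted values leave the range), the
spec uses `rescale`, and the emitted coefficients are a single feasible
shrinkage of the illustrative values.  None of these numbers estimate any
real population; they exist so every module is testable without a download.

**What a green test establishes.**  The generator produces exactly the
model the estimators assume, with independent rows, exact MCAR, and
covariate distributions chosen by the tester.  Passing tests therefore
establish the internal correctness and calibration of the machinery — not
robustness to dependent sampling, informative missingness, misspecified
link, or measurement error, none of which the generator emulates (except
the one-row contamination used to demonstrate ML fragility).

## Numerical conventions

* Rank-deficient designs are a hard error naming the aliased columns — no
  pseudo-inverse fallback, because silent aliasing corrupts the
  expected-count interpretation of coefficients.
* Score tolerance $10^{-8}$ (sup-norm), 200 Newton iterations, ML boundary
  margin $10^{-6}$; logistic IRLS uses the same tolerance with 50
  iterations.
* Quadrature: 128-node Gauss–Legendre, truncation below $\Phi(-9)$;
  adaptive refinement to absolute tolerance $10^{-10}$ available for
  scalar oracles.  $|\rho|$ is clipped to $1 - 10^{-12}$ inside the
  pairwise variance to keep near-comonotone pairs integrable.
* Confidence intervals are normal-approximation at a configurable level
  (default 95%); no multiple-testing adjustment is applied across
  coefficients.
* All randomness flows through explicit integer seeds; identical seeds
  reproduce datasets byte for byte.

## Limitations

No general GLM framework, no Bayesian estimation or regularisation, no
multiple imputation, no exact bivariate-normal CDF beyond the 1-D
reduction, no joint corrections for triples of out-of-range indicators, and
no attempt to match the joint covariate distribution of any real study —
only kinds, supports, and missingness pattern.
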