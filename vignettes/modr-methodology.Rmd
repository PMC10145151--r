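---
title: "Response-surface models and Monte Carlo design regions for gradient LC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface models and Monte Carlo design regions for gradient LC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromodr)
```

## The problem

Analytical Quality by Design (AQbD) asks a chromatographic method developer
to demonstrate, before routine use, a region of instrument settings — the
Method Operable Design Region (MODR) — inside which the method meets its
quality requirements with stated probability. `chromodr` implements the
computational side of that workflow for a gradient LC separation: design the
experiments, model the critical method attributes (CMAs) as response
surfaces over the critical method parameters (CMPs), and propagate the model
uncertainty by Monte Carlo to map the probability of joint criterion
satisfaction over a dense grid of settings.

The packaged study (`fa_ccd_data()`) is a separation of eight non-volatile
fatty acids with charged aerosol detection. Its CMPs are flow rate
$x_1 \in [0.5, 0.7]$ mL/min, gradient time $x_2 \in [8, 15]$ min and column
temperature $x_3 \in [30, 40]$ °C. Its CMAs are the baseline separation of
the two critical peak pairs and the retention factor of the last peak.

## Separation criterion and indirect modeling

Baseline separation of a critical pair is measured by
$$S = t_{2,\mathrm{start}} - t_{1,\mathrm{end}},$$
the start time of the later peak minus the end time of the earlier one
(`separation_criterion()`). $S > 0$ means the peaks are baseline-resolved;
$S \le 0$ means touching or overlap, which is a legitimate measured value,
not an error.

$S$ itself is modeled *indirectly*: the four peak-boundary times are each
given their own response surface, and $S$ is formed from the back-transformed
predictions (`predict_cmas()`). Direct surfaces for $S$ fare poorly because
$S$ is a small difference of two large, strongly correlated times; modeling
the boundaries separately keeps each response smooth and well-behaved. The
retention factor of the last peak, which bounds the run time, is modeled
directly.

A small piece of gradient arithmetic supports range-finding before the
designed experiments: under a linear gradient from $\varphi_i$ to
$\varphi_f$ percent organic over $t_{grad}$ minutes with dwell time $t_D$,
the organic content experienced by an analyte eluting at $t_r$ is
$$\varphi_e = \varphi_i + \frac{\varphi_f - \varphi_i}{t_{grad}}\,(t_r - t_D)$$
(`gradient_composition()`). Retention times outside $[t_D, t_D + t_{grad}]$
raise an error rather than clamping: the formula is meaningless there. The
dwell time is treated as a constant of the configuration at its quoted flow
rate; `rescale_dwell_time()` converts it between flows (dwell volume is a
property of the plumbing) but is not applied implicitly.

## Design and models

`build_ccd()` constructs the three-factor face-centered central composite
design: 8 factorial corners, 6 axial face points and `n_center` center
replicates (default 4, giving the study's 18 runs). All modeling happens on
the coded scale, where each factor's range maps linearly onto $[-1, +1]$;
coded levels are stored alongside natural units in the design table so that
fixtures can be compared without floating-point drift. The canonical
systematic run order is emitted by default, with an optional seeded shuffle
for instrument use — run order does not affect least squares.

Each CMA model is a reduced quadratic polynomial
$$y = b_0 + \sum_i b_i x_i + \sum_{i<j} b_{ij} x_i x_j + \sum_i b_{ii} x_i^2$$
fitted by ordinary least squares (`fit_rsm()`) to a *transformed* response.
Transforms come from the Box-Cox family restricted to its three interpretable
members — identity, reciprocal, log10. `suggest_transform()` profiles the
Box-Cox log-likelihood over $\lambda \in [-2, 2]$ and picks reciprocal when
the 95% interval supports $-1$ but neither 0 nor 1, log10 when it supports 0
but not 1, and identity otherwise; flat likelihoods (e.g. a constant
response) resolve to identity. The log is base 10 by design: the packaged
study's log-model intercept back-transforms to $10^{0.88} \approx 7.6$ min,
which matches the measured center-point retention, whereas $e^{0.88}$ does
not.

The packaged model structures (`fa_model_specs()`) are fixed reduced term
sets rather than the output of automatic selection: reproducing a published
model requires the published structure, and no selection rule recovers a
historical choice exactly. `backward_eliminate()` is provided for new
studies; it removes the weakest term above `alpha` step by step while
honoring hierarchy (a linear term survives while any surviving interaction
or quadratic contains its factor). On pure-noise responses it collapses to
the intercept in the large majority of replicates, but hierarchy can freeze
a chance-significant higher-order term together with its parents — a known
property of hierarchical stepwise schemes, and one reason the packaged
reproduction does not rely on it.

### Diagnostics

`glance()` on a fit reports $R^2$, adjusted $R^2$, PRESS-predicted $R^2$
(from leave-one-out residuals $e_i/(1-h_{ii})$), and the lack-of-fit F-test
p-value with pure error taken from replicated runs. Runs count as replicates
iff their coded settings are identical — in a CCD that is the center block.
Without replicates the lack-of-fit p-value is reported as `NA`, never
silently as 1.

One reproduction limit is worth stating precisely. The packaged responses
carry two printed decimals. Coefficients are insensitive to that rounding
and reproduce the published values at printed precision, but the
fourth-decimal diagnostics are not: perturbing each response within its
half-ulp ($\pm 0.005$) moves $R^2$-type statistics by a few units in the
fourth decimal and the lack-of-fit p-value by a few units in the third. The
published diagnostics (computed from unrounded instrument data) sit inside
exactly that band, and the suite contains a simulation test demonstrating
it. Diagnostic agreement beyond that precision is unattainable from printed
data, and the package does not pretend otherwise.

## Monte Carlo MODR

`build_grid()` discretizes the factor space into the inclusive grid defined
by each factor's `grid_step` — for the packaged study
$21 \times 21 \times 11 = 4851$ points. `modr_probability()` then runs the
error-propagation simulation: each iteration draws one perturbed coefficient
vector per model, evaluates all five surfaces at every grid point, forms the
CMAs, and records whether *all* rules hold jointly in that iteration's
perturbed world. Sharing one draw across the grid within an iteration is
both cheaper and the correct reading of propagating model error: an
iteration represents a plausible true model, not independent noise per
setting. The per-point probability is the fraction of passing iterations;
5000 iterations put the Monte Carlo standard error near 0.004 at $p = 0.9$.

### Perturbation choice

Two perturbation schemes are available. The default,
`method = "covariance"`, draws coefficient vectors from the multivariate
normal with the full estimated covariance $\hat\sigma^2 (X'X)^{-1}$ of the
least-squares fit — the actual sampling distribution of the estimates.
`method = "independent"` perturbs each coefficient independently by its
standard error. The independent scheme looks like the natural reading of
"add the standard error to each coefficient", but it ignores the strong
correlations a face-centered design induces between the intercept and the
quadratic terms, and therefore overstates prediction uncertainty: for the
packaged study it depresses the working point's joint probability from
about 0.92 to about 0.88 and would, inconsistently with the study's own
conclusion, place the chosen operating point outside the 90% region. The
covariance draw is the package default for that reason; the independent
scheme remains available for sensitivity analysis.

Determinism is strict: all draws are generated up front from one seed, model
by model and term by term, so identical settings give bit-identical maps and
the evaluation chunk size is a pure memory/speed knob. Fits with exactly
zero residual variance (e.g. noise-free synthetic data) are treated as
degenerate: their coefficients are not perturbed, and probabilities are
exactly 0 or 1.

### Extraction, zones, working point

`extract_modr()` thresholds the probability map (default: the rule set's
0.90) into the MODR mask, and labels an in-mask point *interior* when every
existing face neighbor (up to six) is also in the mask, *edge* otherwise.
Edge points meet the criteria but border settings that do not; boundary
cells of the grid are labeled conservatively using only their existing
neighbors. Masks nest monotonically in the threshold by construction.

`select_working_point()` picks the mask's erosion-depth center: repeatedly
peel the mask's surface (6-neighbor connectivity, outside-the-grid counts as
failing) and return the deepest surviving point — the setting farthest, in
grid steps, from any failing condition. Ties resolve to the highest joint
probability, then the lowest first-axis value (flow rate in the packaged
study: solvent economy), then the remaining axes, making the choice total
and reproducible. For the packaged study the algorithmic center lands near
(0.56 mL/min, 12.9 min, 32 °C), about 1.3 min of gradient time away from the
historically chosen (0.575, 14.2, 33): that point was picked from the
central region by inspection, and it is inside the computed MODR, but it is
not the distance-transform center. The package asserts membership and interior depth, not coincidence
with a manual choice.

Two geometric facts about the packaged map deserve mention. The probability
surface varies smoothly along the finely stepped flow and gradient-time axes
(maximum face-adjacent jump well below 0.5), but the temperature axis is
discretized twice as coarsely in coded units (step 0.2), and the first
pair's separation collapses sharply between 30 and 31 °C — adjacent
temperature levels can differ by more than 0.8 in probability. That is a
genuine cliff in the criterion, not Monte Carlo noise. And because the
chosen working point's probability (~0.92) lies close to the 0.90 cutoff,
its strict MODR membership is not stable across replicate studies (see
below); its *operability* — meeting all criteria at the estimated surfaces —
is.

## The synthetic-data generator

`generate_responses()` produces response tables with exactly the statistical
structure the analysis assumes: each response is a polynomial in the coded
factors on its transformed scale plus homoscedastic Gaussian noise,
back-transformed to the measurement scale. Noise lives on the transformed
scale because that is where the linear model and the Box-Cox argument place
it. Truths with a `half_width` emit boundary pairs (apex ± half-width) so
peak-pair machinery can be exercised; any non-positive generated value
aborts with the offending run named. An optional `round_digits` emulates the
two-decimal precision of a printed results table, which is how the package
studies reporting-precision effects.

`fa_truth()` returns the packaged study's five surfaces as generative
truths, with `noise = "matched"` defaulting each noise level to the residual
standard deviation of the corresponding refit. Two coefficient sources are
offered, and the difference is instructive: the `"published"` source uses
the printed coefficients, but each separation criterion is a small contrast
between two nearly identical models, and printing to 2–3 decimals erases
much of it (the printed intercepts of each paired model are identical).
The `"published"` truth therefore carries roughly half the first pair's true
separation margin at the working point. Pipeline self-consistency checks use
the `"refit"` source; the `"published"` source is what reproduces the
printed tables.

What the generator does *not* emulate: peak shapes and integration
conventions (how start/end times are read off a real chromatogram), drift
and carry-over between runs, heteroscedastic or correlated errors, and
detector response. Passing tests on synthetic data therefore demonstrate the
statistical pipeline, not the chromatography.

## Numerical choices and problem sizes

Fits use a QR solve with explicit rank checking — a rank-deficient model
matrix is an error naming the collinear terms, not a silent drop. Grid steps
must divide the factor range to within $10^{-9}$ so inclusive grids are well
formed. Coding round-trips are exact to $10^{-12}$; transform round-trips to
$10^{-12}$.

The test suite sizes its simulations to stay fast while keeping the
statistics sharp: the closed-form oracle comparison uses 50,000 draws at one
point (3-binomial-SE agreement), parameter recovery uses 200 seeded
refits of the 18-run design, the replicate-stability check uses 25
regenerated studies at 1000 draws each, and full-grid maps in tests use
2000–5000 draws. These are the package's chosen study sizes; the reported
tolerances are calibrated to them.

## Known limitations

* Only three-factor face-centered CCDs are constructed; rotatable or
  optimal designs, and more factors, are out of scope.
* OLS with homoscedastic errors only — no weighted or robust fits.
* Diagnostics reproduce printed references only to the precision the
  printed input data supports (see above).
* The MODR is evaluated on the grid; no continuous optimization over the
  factor space is attempted, and sub-grid-step geometry (the packaged
  working point lies between flow grid lines) is handled by
  nearest-grid-cell membership.
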