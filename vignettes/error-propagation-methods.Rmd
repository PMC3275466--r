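---
title: "Propagating measurement error through a centroid-based expression classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating measurement error through a centroid-based expression classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(classirep)
library(dplyr)
```

## The problem

Multivariate expression assays report a single categorical call — here, an
intrinsic breast-cancer subtype — computed from dozens of measured gene
expression values. Each of those measurements carries intrinsic laboratory
error (sample preparation, assay preparation, instrument noise). A sample
that lies close to one reference profile will receive the same call every
time it is measured; a sample in the "gray area" between two profiles may
flip its call from run to run, and the clinician reading a single report has
no way to know. `classirep` quantifies that risk: it characterizes the
per-gene measurement error, propagates it through the classifier by Monte
Carlo simulation, and reports how often a re-measurement of the same sample
would reproduce the original call.

## The classifier

The classifier is nearest-centroid with Spearman's rank correlation as the
similarity: a sample's profile $x$ over $G$ genes is compared with each
subtype centroid $c_k$ and assigned
$\hat{k} = \arg\max_k \rho(x, c_k)$, where $\rho$ is the Pearson correlation
of the average-rank transforms. Rho is a similarity, not a distance, so the
package maximizes it; rank transformation makes the call invariant to any
strictly monotone rescaling of the sample. Ties in values receive average
(fractional) ranks — the standard definition with ties. Exact ties in the
argmax (to $10^{-12}$) are resolved deterministically in favor of the
earlier subtype in the centroid set's declared column order and flagged
(`is_tie`); determinism here is what makes simulation tallies reproducible.
A vector with zero rank variance has no defined correlation and is an
error, collected per sample in non-strict batch mode.

Reference centroids are user-supplied data: the package ships no real
centroid values or gene lists, only a generator of synthetic ones.

## Error characterization

Repeated measures of archetypal samples — one stable, centroid-adjacent
sample per subtype, measured as twelve independent replicates — give, for
each gene in each archetype, a sample mean $\mu$ and sample standard
deviation $\sigma$ (with the $n-1$ denominator; the unbiased-variance
convention for small $n$). Twelve points are too few to judge a
distribution's *shape*, so for that purpose each archetype's replicates are
centered by the archetype's per-gene median and pooled across archetypes
(`pool_median_centered()`); with four archetypes of 12/12/12/11 usable
replicates this yields 47 points per gene. `normality_summary()` reports
skewness, excess kurtosis and a Shapiro–Wilk p-value per gene, but these
diagnostics never gate the pipeline: approximate Gaussianity is accepted by
inspection, and everything downstream assumes a Gaussian error model.

## The sigma model

The replicate data show the error magnitude is not constant: $\sigma$
depends on the expression level (weakly expressed genes are harder to
quantify) and on the subtype (subtypes differ in which genes they express
weakly). `fit_sigma_model()` therefore fits one curve per subtype to the
per-gene $(\mu, \sigma)$ points — 50 points per archetype, one per gene —
using locally weighted linear regression via `stats::loess` with
`span = 0.75`, `degree = 1`, `family = "symmetric"` (robust Tukey-bisquare
reweighting) and `surface = "direct"`, so queries beyond the training range
extrapolate the boundary's local linear fit rather than erroring.

The 95% confidence band around each fitted curve defines three scenarios:

* **best** — the lower band (least error),
* **average** — the fitted curve,
* **worst** — the upper band (most error).

The band is computed by a seeded nonparametric bootstrap: `n_boot = 500`
resamples of the training points, refit, evaluated on a 100-point grid per
subtype, with the percentile band interpolated linearly between grid points
and held constant beyond the training range. A closed-form loess band would
depend on unstated smoothing internals; the bootstrap is method-agnostic
and exactly reproducible under its seed. Bands are reordered pointwise so
that lower $\le$ fit $\le$ upper holds everywhere, and every predicted
$\sigma$ is clipped below at a hard floor (`sigma_floor = 1e-6` expression
units) because a direct-surface local linear extrapolation can go negative,
and Gaussian sampling needs $\sigma \ge 0$.

Whether to fit one surface with subtype as a factor or one curve per
subtype was an open choice; per-subtype curves were chosen because the
subtypes' error profiles differ in shape, not just level, and a shared
surface would smooth those differences away. A pooled across-subtypes curve
is still fit and kept as an explicit, opt-in fallback (`fallback = TRUE`)
for parents whose subtype has no archetype — typically the normal-tissue
class, which has no archetypal sample; by default such parents are skipped
with a warning and recorded in the run manifest.

## Monte Carlo simulation

A simulated sample draws each gene independently from
$\mathcal{N}(x_g, \sigma_g)$ centered on the parent's own value
(`simulate_profile()`). Centering on the parent preserves the co-regulation
present in the parent — genes that are high stay generally high — while the
*error* is independent across genes, which is the model's central
assumption. Values are not clipped to the parent's expression range.

Two sigma sources correspond to the two study designs:

* **archetype mode** — each gene uses its own $(\mu, \sigma)$ from the
  repeated measures, and the parent profile is the vector of $\mu$ values;
* **cohort mode** — the parent is first classified, its original subtype
  selects the error curve, and each gene's $\sigma$ is predicted from its
  expression value under the requested scenario.

`run_reproducibility()` classifies `n_sims` perturbed copies and tallies
assignments; `prop_identical` is the fraction assigned the parent's
subtype. The default `n_sims = 100000` makes the Monte Carlo error
negligible: by the normal-approximation half-width
$W = z\sqrt{\theta(1-\theta)/n}$ (`ci_width()`), a 2% misclassification
proportion estimated from 100,000 simulations carries a 95% interval of
± 0.00087. The package's tests and acceptance runs use 10,000 simulations
per parent (half-width ± 0.0027 at the same $\theta$), which keeps the full
suite under a minute of simulation time while remaining far finer than any
tolerance asserted.

Each (parent, scenario) pair draws from its own random substream whose seed
is a deterministic hash of the master seed and the parent's identity
(`derive_seed()`). Results are therefore bit-identical whatever the batch
composition, processing order, or parallel split — a property the test
suite checks by reversing the cohort and re-running single parents alone.

## Reporting

* `confusion_table()` aggregates tallies by the parents' original subtype;
  each cell is $100 \times$ (simulated samples with that original/assigned
  pair) / (all simulated samples of that original subtype), rendered to 2
  decimals. Rows sum to 100 within rounding.
* `change_histogram()` buckets parents by the percentage of their
  simulations that changed subtype (default bucket width 5 points, first
  bucket closed on the left, last bucket closed on both sides).
* `never_change_summary()` counts parents for which every simulation
  reproduced the original call.
* `scorecard()` renders one parent's tally as subtype probabilities (1
  decimal, sorted descending) — the clinician-facing uncertainty report —
  with Markdown and JSON serializations and an `autoplot()` method.

Rounding happens only at the rendering step; internal arithmetic is full
precision.

## The synthetic data generator

Real centroids, repeated measures and cohorts are user-supplied; the
`synthetic_spec()` family generates stand-ins with the statistical
structure the method assumes, so every stage is testable without external
data:

* **centroids** — 50 genes, five subtypes, values uniform over a log-scale
  range of $[0, 10]$ (matching the magnitude of qPCR-style relative
  expression), rejection-sampled until all pairwise $|\rho| \le 0.3$;
* **archetypes** — a centroid plus Gaussian jitter of SD 0.1 (1% of the
  dynamic range), so each classifies to its own subtype with $\rho$ near 1;
* **repeated measures** — 12 replicates per archetype with heteroscedastic
  noise $\sigma(e)$, affine and decreasing in expression with
  subtype-specific intercepts between 0.35 and 0.15 (floored at 0.05), the
  HER2-like subtype noisiest at low expression — emulating the observed
  dependence of error on expression level and subtype;
* **borderline samples** — convex combinations of two centroids plus
  jitter. Because Spearman's rho is computed on ranks, the *value* midpoint
  of two centroids generally is not on the decision boundary (the rank
  transform is nonlinear, leaving a rho gap of order 0.1 that measurement
  noise cannot bridge). `make_borderline()` therefore remaps the mixing
  weight monotonically so that $\lambda = 0.5$ lands on the empirical
  equal-rho point (found by bisection on the rho gap), while
  $\lambda \in \{0, 1\}$ still return the pure centroids. Set
  `balance = FALSE` for the raw value mixture.
* **cohorts** — labeled mixtures of archetypal and borderline samples with
  a truth manifest for parameter-recovery tests.

What passing tests on these fixtures shows is that the pipeline's
machinery — estimation, fitting, simulation, tallying — is correct under
the model's own assumptions. What it cannot show is fidelity to any real
assay: the generator draws genuinely Gaussian, genuinely independent
per-gene errors, its centroids are random rather than biologically
structured, and its expression values are uniform rather than bimodal or
skewed as real panels are. Conclusions about a particular assay require
that assay's own repeated measures.

## Numerical choices and degenerate inputs

* Missing values are errors everywhere; no imputation is attempted.
* Gene matching is exact and case-sensitive; silently fuzzy matching would
  hide assay mismatches. Alignment uses the sorted gene intersection, so
  results are invariant to input row order; dropping more than half the
  sample's genes warns, an empty intersection errors.
* All-tied vectors (zero rank variance) error rather than returning 0.
* The confidence-interval half-width uses the standard
  $z\sqrt{\theta(1-\theta)/n}$ form.
* TSVs are written with 15 significant digits; round trips preserve values
  to at least 10.
* Histogram bucket width must divide 100; a parent that changes in exactly
  100% of simulations falls in the closed last bucket.

## Limitations

* The error model is Gaussian and independent across genes by assumption;
  correlated technical error (e.g. plate effects) and non-Gaussian tails
  are out of scope.
* Only measurement error is propagated — tumor heterogeneity, sampling and
  pre-analytic variation are not modeled.
* A subtype with no archetypal sample has no error curve of its own;
  the pooled fallback borrows strength across subtypes and should be read
  as an approximation.
* The bootstrap band quantifies uncertainty in the fitted mean curve, not
  the spread of individual genes around it.
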