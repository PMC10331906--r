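---
title: "Methods: quantifying and explaining intraspecific variation in nest morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and explaining intraspecific variation in nest morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestvar)
```

# The scientific question

Nest building leaves a measurable record: a species whose members build
nests of very uniform dimensions is behaviourally rigid in that trait, while
large nest-to-nest differences indicate flexible building behaviour. This
package implements a comparative pipeline around that idea: quantify
within-species variability of four nest dimensions from repeated specimen
measurements, estimate how strongly that variability tracks phylogeny, and
regress it on ecological predictors while accounting for shared ancestry
and for uncertainty in the phylogeny itself.

# From caliper to coefficient of variation

Each nest is measured several times (three by default). The repeats are
averaged **on the raw centimetre scale** and the per-nest mean is natural-log
transformed; per species and trait we then take the mean and the sample
(n − 1) standard deviation of the per-nest log values, and report

$$\mathrm{CV} = \frac{\mathrm{sd}(\log x)}{\mathrm{mean}(\log x)}.$$

Dividing by the mean removes the coupling between absolute nest size and
absolute spread, so species of very different sizes are comparable. Two
choices here were genuinely open and are worth stating:

* *Natural log.* The transformation base is a free choice; natural log is
  the comparative-methods default and is what `summarize_species()` uses.
* *Reduce repeats before transforming.* One value per nest is needed; we
  average the repeats on the raw scale first (so measurement error shrinks
  by $1/\sqrt{k}$ before the nonlinearity), rather than averaging logs or
  pooling all $3n$ raw values into the CV. Pooling raw values would mix
  measurement error into the biological signal; the per-nest-mean route
  keeps the CV an estimate of between-nest variability.

Because the CV of log-values is **not unit invariant** (log 1 cm = 0), all
measurements must be in centimetres; `summarize_species()` aborts when a
species' mean log value is non-positive, which in practice means a unit
error, rather than attempting detection heuristics.

Measurement quality is summarized per trait by the one-way ANOVA intraclass
correlation $\mathrm{ICC} = (MS_A - MS_W)/(MS_A + (k-1) MS_W)$ with $k$ the
repeat count (harmonic mean when unbalanced). No threshold is enforced; the
ICC is reported and the analyst judges it.

# Phylogenetic signal: Pagel's λ

Under Brownian trait evolution, tip values are multivariate normal with
covariance $\sigma^2 V$, where $V_{ij}$ is the branch length shared from the
root to the most recent common ancestor of species $i$ and $j$. Pagel's λ
rescales only the off-diagonal of $V$: λ = 1 is full Brownian structure,
λ = 0 is phylogenetic independence. `bm_profile_loglik()` profiles the root
state and rate analytically,

$$\hat z_0 = \frac{\mathbf{1}^\top W^{-1} x}{\mathbf{1}^\top W^{-1}
\mathbf{1}}, \qquad
\hat\sigma^2 = \frac{(x-\hat z_0)^\top W^{-1} (x-\hat z_0)}{n},$$

with $W$ the λ-transformed covariance, leaving a one-dimensional likelihood
in λ that `fit_lambda()` maximizes by Brent search on each half of
[0, λ_max] plus the endpoints (tolerance 1e-8) — the profile can be
multimodal near the boundaries, so a single interior search is not trusted.
Significance is a likelihood-ratio test against λ = 0 referred to χ²₁. At
the λ = 0 boundary this reference is conservative (the true null is a
50:50 mixture of χ²₀ and χ²₁); the plain χ²₁ convention is kept because it
is what the standard comparative implementations report, and the test
suite verifies the resulting type-I error stays below nominal + 2 points.
Estimation is ML, not REML, so likelihoods are comparable across the
λ-restricted and free fits.

Defaults that matter:

* `lambda_max = 1` — estimates are kept in [0, 1] where λ is interpretable
  as a signal fraction; the bound is configurable up to values keeping the
  transformed covariance positive definite.
* All solves use the Cholesky factor of $W$; no explicit inverse is formed
  anywhere in the package, and the tests compare every quadratic form
  against an independent whitening oracle.

Star phylogenies are rejected explicitly ("λ has no effect on the
likelihood"): with no shared branch lengths the parameter is
unidentifiable, and silently returning an arbitrary value would poison
downstream HDP summaries.

# PGLS

`gls_fit()` implements generalized least squares
$\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y$ with standard errors
from $\hat\sigma^2 (X^\top V^{-1}X)^{-1}$, $\hat\sigma^2 = e^\top V^{-1}
e/(n-p)$, and two-tailed t-tests on $n - p$ degrees of freedom.
`pgls_fit()` builds the design from a species table, list-wise deletes
species with missing model variables (the per-model sample sizes are
reported, since covariate coverage differs between model families), prunes
the tree accordingly, and either fixes λ on the residual covariance
(default 1, full Brownian residuals — the default of the common PGLS
implementations) or profiles it by ML over [0, 1]. Body mass enters in
grams untransformed by default, with a `log_body_mass` switch, since either
convention is defensible and the choice is visible in the model frame.

Binary covariates are coded 0/1 with fixed reference levels — open-cup
nest, non-innovative, both-parent builder — so intercepts are interpretable
and signs comparable across traits. Clutch-size range is
`clutch_max − clutch_min`, a non-negative integer. No multiple-testing
correction is applied across the per-trait models; each model is reported
on its own, and readers should treat marginal p-values across twelve
tables accordingly.

# Uncertainty across a set of phylogenies

Point estimates alone hide the dependence of comparative statistics on the
tree. Every statistic (λ, each PGLS coefficient's β, t and p) is therefore
re-estimated on every member of a tree set and summarized by the **95%
highest-density interval**: the shortest contiguous window of the sorted
per-tree values containing ⌈0.95 N⌉ of them, ties broken toward the
smallest lower endpoint. The same window rule is applied uniformly to every
quantity, including p-values, since nothing suggests treating them
differently. Point estimates come from the **maximum clade credibility
tree**, the member maximizing the sum over its clades of log clade
frequency in the set (the usual tree-annotator convention; which software
produced any particular published MCC tree is rarely stated, so convention
had to be chosen once).

An important caveat the package makes explicit rather than hiding: the HDP
interval summarizes **phylogenetic uncertainty only**. All trees see the
same data, so the across-tree spread of a coefficient is typically much
smaller than its sampling standard error, and an HDP interval excluding
zero is *not* evidence of a nonzero effect — the per-fit t-test carries
that burden. The calibration experiments in the test suite quantify
exactly this: under a null effect the MCC-tree p-values are approximately
uniform (well-calibrated), while the β HDP across branch-length-perturbed
trees straddles zero only rarely, because it is a narrow interval centred
on the (noisy) point estimate. Interpreting these intervals as confidence
intervals would be a mistake in any analysis of this design, not a
property of this implementation.

Per-tree numerical failures are dropped with a logged count; more than 10%
failures aborts the aggregation, since an HDP over a biased surviving
subset would be misleading.

# The synthetic-study generator

`simulate_study()` produces complete studies with recorded truth. Its
defaults are the conditions of the motivating museum-collection design:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 55 | tips of the generator tree |
| `nests_min`–`nests_max` | 8–25 | nests per species (uniform) |
| `n_repeats` | 3 | caliper repeats per nest |
| `n_trees` | 1000 | posterior-like tree set size |
| `trait_means_z0` | 1.6–2.3 log-cm | root states; chosen so species means span ~2.5–21 cm across the four dimensions |
| `trait_sigma2` | 0.10–0.16 | Brownian rates per unit tree height, giving realistic across-species spread |
| `trait_cor` | 0.5 | correlation between the four dimensions' mean processes |
| `lambda_means`, `lambda_cv` | 1, 1 | signal of species means and of the CV latent |
| `cv_base`, `cv_spread` | 0.05, 0.03 | CV process centre and spread; realized CVs span roughly 1–30% |
| `measurement_error_sd` | 0.05 cm | additive caliper noise per repeat |
| effects (`clutch`, `builder`, `nesttype`, `innovation`) | 0.005, 0.01, 0.02, 0 | additive CV shifts per predictor unit, at the magnitudes a real museum study reports for its significant predictors |
| `tree_jitter_sdlog` | 0.1 | lognormal branch-length jitter emulating posterior spread |

Mechanics worth knowing when interpreting test results:

* The per-species CV is a latent Brownian variable (signal `lambda_cv`),
  standardized and passed through the positive link
  $\mathrm{cv} = \mathrm{cv\_base}\,e^{s u}$ with
  $s = \log((\mathrm{cv\_base}+\mathrm{cv\_spread})/\mathrm{cv\_base})$,
  then shifted by the covariate effects and truncated to [0.005, 0.35].
  The truncation keeps degenerate species out; configurations with
  `cv_spread >= cv_base` are rejected.
* Binary covariates are threshold-dichotomized Brownian liabilities, so
  dome-nesting, innovation and single-building are phylogenetically
  clumped, as they are in real clades (a property the tests verify by
  comparing λ of the observed coding against shuffled codings).
* Tree uncertainty is **branch-length jitter at fixed topology**
  (multiplicative lognormal, σ = 0.1). Real pseudo-posterior tree sets also
  vary in topology; this emulation keeps HDP machinery exercised while
  deliberately not modelling topological variation, so across-tree spreads
  here are, if anything, narrower than with real tree sets.
* The designated MCC tree of a synthetic study is the generator tree
  itself; all jittered members share its topology, so any clade-frequency
  convention selects that topology.
* One `set.seed()` call per study; component sub-seeds are drawn from that
  stream, so a study is a pure function of its configuration.

What the generator does **not** emulate: topology uncertainty (above),
spatial or temporal autocorrelation in sampling (years and latitudes are
uniform within species-specific windows), nest material or climate
covariates, and correlated within-species deviations across traits (only
the species means are correlated). Passing tests therefore demonstrate
correctness of the estimators and calibration under the stated generative
model — not robustness to every pathology of museum data.

# Numerical choices and degenerate inputs

* Branch lengths of exactly zero are accepted (they occur in published
  trees); negative lengths are errors. Polytomies are accepted everywhere —
  the Brownian covariance is well-defined — and never arbitrarily resolved.
* Pruning preserves root-to-tip distances exactly: a basal path collapsed
  by pruning is retained as a root edge and added to the covariance as
  history shared by all retained tips. The tests verify prune-then-vcv
  equals subsetting the full vcv to 1e-12.
* Tip labels are matched across files after converting spaces to
  underscores (the convention of underscored binomials in distributed bird
  trees); matching is otherwise exact and case-sensitive. Species present
  in the data but absent from a tree are dropped with a warning, not an
  error, mirroring how covariate coverage shrinks subset analyses.
* Constant traits, rank-deficient designs, star trees for λ, non-PD
  covariances, and exact-fit regressions are all explicit, named errors or
  flags rather than silent numerics.
* Newick serialization uses 9 significant digits, enough for parse →
  serialize → parse round-trips to preserve branch lengths to 1e-9.

# Problem sizes used by the test suite

The calibration experiments run at sizes chosen to make their Monte-Carlo
error small relative to the tolerance being asserted while keeping the
default suite quick: λ recovery at 200 tips × 200 replicates per generating
value, LRT calibration at 100 tips × 1000 replicates, null-effect study
calibration at 100 species × 50 trees × 20 studies, power at 150 species ×
40 studies, and oracle-equivalence sweeps of 100–1000 random instances.
The full-scale acceptance run uses the generator defaults (55 species,
1000 trees).

# Known limitations

* λ estimation at interior values is intrinsically noisy: even at 200 tips
  the ML estimate of λ = 0.5 has a median absolute error near 0.08 (the
  suite documents this; an independent implementation agrees to 1e-4).
  HDP intervals for λ from tree sets do not capture this sampling noise.
* The χ²₁ LRT is conservative at the boundary; reported p-values near 0.05
  understate significance slightly.
* `lambda_mode = "ml"` PGLS profiles a single λ shared by all residuals;
  no measurement-error (within-species variance) model is provided, so
  species with few nests carry the same weight as well-sampled ones.
* The CV link truncation bounds synthetic CVs away from the extremes;
  effect estimates in studies generated near the truncation boundary are
  mildly attenuated.
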