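# nestvar

Comparative analysis of **intraspecific variation in bird nest morphology**.

Nests are extended phenotypes: repeated builds by the members of a species
record how flexible its nest-building behaviour is. Given specimen-level
repeated measurements of nest dimensions (cup depth, nest height, internal
and external cup diameter, in cm), this package quantifies how variable each
species' nests are, asks whether that variability is phylogenetically
conserved, and tests which ecological factors predict it. It is written for
comparative biologists working from museum nest collections (or any
repeated-measures trait table) together with a posterior sample of
phylogenies such as the pseudo-posterior sets distributed for birds.

## What it computes

* **Intraspecific variation.** Per nest, repeated caliper measurements are
  averaged and log-transformed; per species and trait the coefficient of
  variation CV = sd(log x) / mean(log x) measures building variability on a
  size-free scale. Measurement quality is checked with the one-way ANOVA
  intraclass correlation ICC = (MS_A − MS_W) / (MS_A + (k − 1) MS_W).
* **Phylogenetic signal.** Pagel's λ, the scalar in [0, 1] multiplying the
  off-diagonal (shared-history) entries of the Brownian-motion covariance
  C(i, j) = σ² t_MRCA(i,j), is estimated by maximum likelihood with the root
  state and rate profiled analytically, and tested against λ = 0 with a
  likelihood-ratio test on χ²₁.
* **PGLS.** Generalized least squares β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y with
  phylogenetic residual covariance V (optionally λ-transformed or with λ
  profiled by ML), for three model families per trait: CV ~ sampling spans;
  CV ~ innovation + body mass + nest type; CV ~ clutch-size range + builder.
* **Phylogenetic uncertainty.** Every statistic is re-estimated across a set
  of phylogenies and summarized by the 95% highest-density (shortest-window)
  interval; point estimates come from the maximum clade credibility tree
  (sum of log clade frequencies).
* **Synthetic studies.** A generator produces complete studies — tree sets,
  correlated species means, phylogenetically structured within-species CVs,
  covariates with configurable effects, specimen tables with repeats — with
  the generating truth recorded, so calibration and power are testable
  end-to-end without any external data.

## Worked example

```r
library(nestvar)

study   <- simulate_study(simulation_config(n_species = 30, n_trees = 100, seed = 7))
summary <- summarize_species(study$specimens)
round(100 * head(summary$cv_cup_depth), 1)
#> [1] 7.2 5.2 7.0 5.8 8.9 6.0

cv  <- setNames(summary$cv_cup_depth, summary$species)
fit <- fit_lambda(cv, study$mcc)
fit
#> Pagel's lambda fit (n = 30)
#>   lambda = 0.7926  sigma2 = 0.0008736  logL = 69.9510
#>   LRT vs lambda = 0: stat = 15.1002, p = 0.000102

lambda_across_trees(cv, study$trees)$hdp
#> 95% HDP [0.769, 0.813]

mf <- prepare_model_frame(summary, study$covariates)
pgls_fit(mf, model_spec("cv_cup_depth",
                        c("innovation", "body_mass_g", "nest_type_dome")),
         study$mcc)
#> GLS fit: n = 30, df = 26, sigma2 = 0.003681, logL = 58.3711
#>                estimate        se      t      p
#> (Intercept)    0.041626 0.0330207 1.2606 0.2187
#> innovation     0.004088 0.0132458 0.3086 0.7601
#> body_mass_g    0.000338 0.0002156 1.5673 0.1291
#> nest_type_dome 0.043002 0.0282088 1.5244 0.1395
```

The first block shows per-species cup-depth CVs of 5–9%: these species vary
their cup depth by several percent of the (log) species mean. The λ fit says
that variability itself is phylogenetically conserved (λ ≈ 0.79, LRT
p ≈ 1e-4), and the narrow HDP shows the estimate is stable across the tree
set. In the PGLS table, dome-nesting species have a +0.043 higher CV than
open-cup nesters (the generator's built-in nest-type effect plus sampling
noise), while innovation has essentially none — each row reporting the
coefficient, its standard error, and a two-tailed t-test on n − p degrees
of freedom.

## Analysis workflow

The `analysis/` scripts run the complete study in order, writing tables
under `results/`:

```sh
Rscript analysis/01_simulate.R            # synthetic museum study + truth
Rscript analysis/02_trait_variation.R     # ICCs, per-species CVs, spans
Rscript analysis/03_phylogenetic_signal.R # lambda per quantity, HDPs
Rscript analysis/04_pgls.R                # three model families per trait
Rscript analysis/05_recovery.R            # estimates vs generating truth
```

Real data can be substituted for stage 1's output: a specimen CSV
(`species, specimen_id, repeat_id, cup_depth_cm, nest_height_cm,
internal_diameter_cm, external_diameter_cm, year, latitude`), a covariate
CSV (`species, body_mass_g, nest_type, innovation, clutch_min, clutch_max,
builder`), and Newick tree files; `run_analysis()` is the one-call
equivalent.

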