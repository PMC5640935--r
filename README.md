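# organotrope

Where does breast cancer first metastasize — bone, viscera, or both
within a short window — and which features of the primary tumour shift
that risk? `organotrope` implements the complete analysis chain for
studying *organotropic first metastasis* with a nested case-control
design on a clinical cohort:

- **Pattern classification.** Each patient's distant-recurrence timeline
  is classified as `bone_only`, `visceral_only`, `bone_and_visceral`
  (both categories within a 183-day metasynchronicity window) or
  `none`. Bone events cover bone/bone-marrow metastasis, spinal cord
  compression, pathological fracture and hypercalcaemia; visceral
  events cover lung, liver, brain and malignant ascites.
- **Incidence-density (risk-set) sampling.** For each case's calendar
  event time *T*, controls are drawn uniformly from cohort members
  still at risk at *T* (diagnosed, under follow-up, metastasis-free).
  A patient may be a control many times and later become a case. Odds
  ratios estimated from such matched data approximate hazard ratios.
- **Gene-module scoring.** Directional weighted-sum scores
  (`score_s = Σ_g w_g x_{g,s}` with `w_g ∈ {+1, −1}`), most-variable
  probe resolution, per-series scaling so 95 % of scores lie in
  `[−1, 1]`, Spearman nearest-centroid subtyping, and a NanoString-style
  normalization chain (mean + 2·SD background, housekeeping geometric
  mean, log2, per-sample centring).
- **A self-implemented statistical core.** Unconditional logistic
  regression by IRLS and conditional logistic regression on matched
  sets by Newton-Raphson, maximizing
  `L(β) = Π_s exp(βᵀx_case) / Σ_{j∈s} exp(βᵀx_j)`,
  with Wald ORs/CIs and explicit separation handling; Pearson χ²;
  Mann-Whitney U and Wilcoxon signed-rank with exact small-sample
  enumeration; Benjamini-Hochberg FDR; rank-formula ROC/AUC (the
  identity `AUC·n₁·n₂ = U` holds exactly); quartile OR analysis.
- **Signature discovery.** ER-concordant pair filtering, per-gene
  Mann-Whitney screening with BH control at FDR < 0.2, ±1 direction
  assignment, and ROC evaluation of the derived metasynchronous-spread
  ("BV") module.
- **A synthetic-cohort generator** with exponential cause-specific
  bone/visceral hazards `λ_site·exp(Σ β z)`, a post-first-event
  coupling factor that induces metasynchronous spread, and expression
  in which module member genes co-vary with the latent scores — so
  every stage is validated against known ground truth without any
  external data.

## Worked example

Simulate a 3000-patient cohort in which one 20-gene module doubles both
the bone and the visceral hazard per unit latent score, then run the
whole design — classification, risk-set sampling of 80 cases per
series with 3 matched controls reduced to 1:1 pairs, module scoring
with per-series scaling, and both regression families:

```r
library(organotrope)

sim <- sim_config(
  n_patients = 3000, n_genes = 200,
  modules = default_modules(), tau = c(M1 = 2),
  beta_bone = c(score_M1 = log(2)), beta_visc = c(score_M1 = log(2))
)
cfg <- study_config(sim = sim, series = c("V", "BV", "B"),
                    n_cases = 80, m = 3, seed = 42)
report <- run_full_study(cfg)

report$pattern_counts
#> # A tibble: 4 × 2
#>   pattern               n
#>   <fct>             <int>
#> 1 bone_only           208
#> 2 visceral_only       459
#> 3 bone_and_visceral   365
#> 4 none               1968

report$or_table[, c("series", "module", "model", "or",
                    "conf.low", "conf.high", "adj.p.value")]
#> # A tibble: 6 × 7
#>   series module model            or conf.low conf.high adj.p.value
#>   <chr>  <chr>  <chr>         <dbl>    <dbl>     <dbl>       <dbl>
#> 1 V      M1     conditional    3.28    1.61       6.68  0.00108
#> 2 V      M1     unconditional  3.11    1.62       5.99  0.000665
#> 3 BV     M1     conditional   11.8     4.07      34.3   0.00000555
#> 4 BV     M1     unconditional  7.36    3.27      16.6   0.00000147
#> 5 B      M1     conditional    1.29    0.721      2.29  0.395
#> 6 B      M1     unconditional  1.33    0.719      2.47  0.362
```

The odds ratios are per unit of the *scaled* module score (95 % of each
series' scores span `[−1, 1]`), so `or = 3.28` reads: moving across
roughly half the observed score range multiplies the odds of being a
visceral-only case by ~3.3. A module that raises both site hazards
raises the metasynchronous (BV) odds most — the case definition
requires both events — and leaves the bone-only series near null here
because high-score patients tend to present a visceral event within
the window. `plot_or_forest(report$or_table)` draws the panel;
`autoplot()` methods exist for ROC curves, module-score densities and
pattern-by-subtype crosstabs.

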