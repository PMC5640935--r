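---
title: "Methods: organotropic first metastasis as a nested case-control study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organotropic first metastasis as a nested case-control study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organotrope)
```

## The question and the design

Breast cancer metastasizes with strong organ preference: some primaries
recur first in bone, some in viscera (lung, liver, brain, ascites), and
some in both sites within months of each other — *metasynchronous*
bone-and-visceral spread, the pattern with the most aggressive clinical
course. The analysis implemented here asks whether tumour gene-module
expression measured in the primary at diagnosis shifts the risk of each
of these three first-metastasis patterns.

Because any cohort contains a mixture of patterns, follow-up times and
censoring, the design is a *nested case-control study with
incidence-density sampling*: at the calendar time $T$ a case presents
its event, controls are drawn at random from cohort members still at
risk at $T$. Conditional logistic regression on the matched sets then
estimates odds ratios that, under this sampling scheme, consistently
estimate hazard ratios — this is the headline statistical property the
package's validation targets.

## Pattern classification

A patient's timeline of organ-site events (days since histological
diagnosis) is reduced to the earliest bone-category time $t_b$ and
earliest visceral-category time $t_v$. With window $w$ (183 days by
default, a six-month window; the boundary is inclusive):

* both exist and $|t_b - t_v| \le w$ → `bone_and_visceral`;
* only $t_b$ (or $t_v - t_b > w$) → `bone_only`, and symmetrically
  `visceral_only`;
* neither → `none`.

Bone category: bone or bone-marrow metastasis, spinal cord compression,
pathological fracture, hypercalcaemia. Visceral: lung, liver, brain,
ascites. Distant sites outside both lists are carried as `ignored` and
never influence classification — the site vocabulary defines only these
two categories, and a timeline containing nothing else is `none`.
Simultaneous bone and visceral events (gap 0) are metasynchronous. Six
months is fixed as 183 days because no day count is canonical; it is a
configurable parameter, and classification is monotone in it (widening
the window can only merge single-site labels into `bone_and_visceral`,
never the reverse — a property the test suite asserts).

## Risk-set sampling conventions

The at-risk predicate at calendar day $T$ is half-open: diagnosis on or
before $T$, exit strictly after $T$, own metastasis strictly after $T$.
Consequently a patient whose event falls on exactly the case's event day
is *not* eligible, and every case is eligible as a control for earlier
cases — the re-use rule that makes incidence-density sampling efficient.
Controls are drawn uniformly without replacement within a set and
independently across sets; the default draws $m = 3$ candidate controls
per case and reduces to 1:1 pairs by a uniform choice, mirroring a
design in which tissue availability, not the sampling frame, limits the
final pair count. Sets with deficient or empty risk sets are flagged
rather than silently dropped.

## The synthetic cohort: what it emulates and what it does not

No patient data ships with the package; every validation runs on a
generator whose structure matches the assumptions of the analysis:

* **Accrual and censoring.** Diagnoses uniform over a 30-year calendar
  window; follow-up ends at the earlier of an exponential dropout
  (default rate $5\times10^{-5}$/day) and an administrative end five
  years after accrual closes.
* **Event model.** First bone and first visceral metastasis have
  independent exponential cause-specific hazards
  $\lambda_{site}\exp(\sum_k \beta_{site,k} z_k)$, where $z$ contains
  ER status and latent standard-normal module scores. After the earlier
  event, the later site's time is redrawn with its hazard multiplied by
  a coupling factor $\rho$ (valid by memorylessness). $\rho > 1$
  induces metasynchronicity; $\rho \to \infty$ makes every
  metastasizing patient `bone_and_visceral`.
* **Expression.** Member gene $g$ of module $j$ is
  $w_g \tau_j s_j + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$,
  on the log scale; non-members are pure noise. An optional probe
  expansion duplicates genes into probes of differing noisiness to
  exercise most-variable-probe resolution.

Default rates ($\lambda_{0,bone} = 2.6\times10^{-5}$,
$\lambda_{0,visc} = 4.6\times10^{-5}$/day, $\rho = 50$) were calibrated
once so that roughly a third of patients metastasize during follow-up
and the pattern split among metastasizers is roughly a quarter
bone-only, half visceral-only, a quarter bone-and-visceral — the regime
of the archival breast-cancer cohorts this design emulates. ER
prevalence defaults to 0.68. Exponential hazards were chosen over
Weibull because they admit closed-form checks (the first-event time is
$\text{Exp}(\lambda_b + \lambda_v)$ at $\beta = 0$) and make the
calendar/entry-time structure ignorable, which keeps the estimator
validity check clean.

The generator does **not** emulate treatment effects and their
confounding with pattern (hormone-treated patients differ by series in
real tables), competing mortality, copy-number-defined subtypes, or
probe-level assay artefacts. Passing tests therefore demonstrate the
correctness and calibration of the *machinery* on data satisfying the
model's assumptions, not robustness to these real-data violations.

Ground truth (latent scores, uncensored times, true $\beta$) is
returned in a separate `truth` element consumed only by tests; a test
asserts the study report is invariant to its removal.

## Scoring and scaling

Module scores are directional weighted sums over member genes present
in the matrix. Before regression, scores are scaled *within each
case-control series* by the affine map $x \mapsto (x - c)/h$, with $c$
and $h$ the midpoint and half-width of the series' central 95 %
interval (2.5th/97.5th linear-interpolation — type 7 — quantiles; the
quantile dialect matters and is therefore pinned). The reference is all
values in the series, cases and controls together (a controls-only
reference is available); "95 % of values" reads most naturally as all
values. Scaling is affine and order-preserving, so rank-based
quantities are untouched and per-unit odds ratios acquire a
range-relative interpretation. Scores are computed on raw log
expression and scaled afterwards, rather than on per-gene standardized
values; the NanoString-style scorer (`bv_nanostring_score`), which
standardizes genes across ER-positive samples first, is the documented
exception.

In the normalization chain for count data, background is
mean + 2·SD of the negative controls truncated at zero; content
normalization equalizes per-sample housekeeping geometric means;
`log2(x + 1)` admits zero counts after background subtraction; and
per-sample "geometric-mean standardization" is implemented as
subtracting the sample's mean log2 endogenous value — the identical
operation in the log domain, stated explicitly so it is not applied
twice.

## The statistical core: numerical choices

All estimators and tests are implemented in the package (standard-tool
fits appear only as cross-check oracles in the test suite):

* **Logistic (IRLS) and conditional logistic (Newton-Raphson).**
  Convergence is declared when the largest score component is below
  $10^{-8}$ or the relative log-likelihood change is below $10^{-10}$;
  iteration continues to a step-size floor of $10^{-12}$ so the
  returned optimum is machine-precision accurate (the 1:1 conditional
  fit must agree with the paired-difference logistic fit to
  $10^{-10}$, two routes to one contract). Separation is flagged when
  any coefficient exceeds 15 on the standardized-covariate scale, with
  a 50-iteration cap: deterministic failure, never silent divergence.
  Standard errors come from the inverse observed information; intervals
  are Wald, the standard epidemiological output. Strata with no
  within-stratum covariate variation are counted as uninformative;
  all-uninformative input is an error.
* **Rank tests.** Mann-Whitney U uses exact enumeration up to 12
  pooled observations without ties; the Wilcoxon signed-rank uses the
  exact rank-sum distribution (dynamic programming over sign
  assignments) up to 25 nonzero differences without ties. Beyond those
  limits both use normal approximations with tie-corrected variance
  and a 0.5 continuity correction. Zero differences are dropped;
  fully degenerate inputs return $p = 1$ with a flag.
* **BH adjustment** is the step-up formula, applied across the module
  panel within each series-by-model block ("within each test").
* **ROC/AUC** is defined through the rank U statistic with ties
  counted one half, so $AUC \cdot n_1 n_2 = U$ holds exactly by
  construction on every input, including ties.
* **Quartile analysis** bins all subjects by the control series'
  quartile thresholds and contrasts Q2-Q4 against Q1 in the
  conditional model; inestimable contrasts surface through the
  separation/convergence flags.
* **Chi-square** is Pearson's statistic without continuity correction;
  "Unknown" levels are retained as categories where the source tables
  print them.

## Module discovery

Discovery runs within an ER stratum after removing ER-discordant pairs
(confounding between ER status and pattern is the motivation). The
comparison is unpaired Mann-Whitney between metasynchronous cases and a
no-metastasis reference, even though the data arise from pairs — the
test choice is part of the procedure being implemented. The reference
defaults to concordant-pair controls with no distant event during their
entire follow-up; `all_controls` is available because the narrower
definition is not the only defensible reading. Genes with BH-adjusted
$p < 0.2$ enter the module with weight $+1$ (up) or $-1$ (down), the
direction taken from the difference of group medians with means
breaking ties. Evaluation on the derivation samples is labelled
*resubstitution* and flagged as optimistically biased; no
cross-validation is applied by default because the procedure under
study did not cross-validate.

## Validation problem sizes

The acceptance layer (test suite and `scripts/acceptance.R`) uses these
sizes, chosen as the package's own validation design: estimator
validity over 200 replicates of a 2000-patient cohort with true hazard
ratio 2 on both sites and 100 1:1 BV pairs (strong site coupling
$\rho = 10^6$, so the metasynchronous case series coincides with the
first-metastasis series and the estimand is exactly the per-unit
hazard ratio — under moderate coupling the window probability itself
depends on the score and the BV odds ratio exceeds the per-site
value); Mann-Whitney type-I error over $10^4$ null draws at
$n = 30/30$; FDR calibration over 200 screens of 1000 genes with 20
planted effects at $n = 30/30$; and signature recovery over 100 screens
of 5000 genes with a planted 21-gene module (19 up, 2 down, one
noise-SD shift) at $n = 50/50$, evaluated on an independent draw. At
that effect size the expected recovery is about 19.5 of 21 with about
4-5 false selections per screen — individual-gene power ≈ 0.87 at the
BH-adjusted threshold — so near-complete recovery with few false
positives is frequent but not guaranteed in any single screen, while
held-out discrimination of the derived module is essentially certain
(AUC far above 0.7).

## Known limitations

* Calendar-time matching only; no additional matching on age or
  follow-up duration, and no countermatching.
* Exponential baseline hazards; time-varying or Weibull baselines are
  not exercised by the default validation.
* Wald intervals can undercover at very small informative-pair counts
  or near-separation; profile-likelihood and Firth corrections are out
  of scope.
* The discovery stage reports resubstitution performance prominently;
  treat it as descriptive, not as an estimate of external validity.

## A compact end-to-end run

```{r example, eval = FALSE}
sim <- sim_config(
  n_patients = 3000, n_genes = 200,
  modules = default_modules(), tau = c(M1 = 2),
  beta_bone = c(score_M1 = log(2)), beta_visc = c(score_M1 = log(2))
)
cfg <- study_config(sim = sim, n_cases = 80, m = 3, seed = 42)
report <- run_full_study(cfg)
report$or_table
plot_or_forest(report$or_table)
```
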