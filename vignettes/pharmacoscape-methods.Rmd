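---
title: "Models and methods behind pharmacoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pharmacoscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmacoscape)
```

# The analysis problem

Large pharmacogenomic screens ask a simple question at an awkward scale:
which of the recurrent molecular alterations seen in patient tumors predict
how a cancer cell line responds to a drug? pharmacoscape implements the full
chain of that analysis. The unit of molecular information is the *cancer
functional event* (CFE): a binarized, clinically relevant alteration — a
driver-gene mutation (CG), a recurrently amplified or deleted copy-number
segment (RACS), a hypermethylated promoter CpG island (iCpG), a gene fusion,
or a binarized pathway-activity call. CFE catalogs are derived from tumor
cohorts and then *imposed* on cell lines (`filter_by_catalog()`), so the cell
line analysis only ever sees events with clinical provenance. Drug response
is summarized as the natural-log IC50 in ln(µM) (and AUC in [0, 1], where 1
means no effect over the tested range).

Everything downstream is organized around four statistical engines:

1. a covariate-adjusted ANOVA scan for single-CFE markers with explicit
   effect-size gating,
2. exhaustive inference of small AND/OR logic formulas over CFEs
   (binary-input, continuous-output logic optimization),
3. a data-type-combination scan with penalized linear and random-forest
   predictors under a mixture-derived predictiveness threshold, and
4. tumor/cell-line concordance summaries (frequency profiles,
   nearest-neighbor tissue matching, pathway frequencies, global CFE
   classes) plus a patient-stratification landscape.

A seeded synthetic-data generator with planted ground truth stands in for
the (portal-hosted) real data and is itself first-class, tested code.

# The synthetic cohorts: what they emulate and what they do not

`sim_config()` describes paired tumor/cell-line cohorts. Within each cancer
type every CFE is an independent Bernoulli draw at its configured tumor
frequency, *identical* for tumors and cell lines — this shared frequency is
exactly the recoverable signal the concordance analyses assume. Drug
response is built additively on the ln-IC50 scale:

$$\ln \mathrm{IC50}_{i,d} = \mu_d + \sum_j \beta_{jd}\, x_{ij}
  + \sum_r \beta_{rd}\, \phi_r(x_i) + \varepsilon_{i,d},\qquad
  \varepsilon \sim N(0, \sigma^2),$$

with $x_{ij}$ the binary CFE status, $\phi_r$ planted AND/OR rules evaluated
on the binary row, and $\sigma$ defaulting to 0.5 ln units — a noise level
at which an effect of $2\sigma$ (one natural-log unit, roughly a 2.7-fold
IC50 shift) carried by 30 of 300 lines is comfortably but not trivially
recoverable. The default study conditions (`default_sim_config()`) use six
cancer types with 120 tumors and 50 cell lines each, 40 CFEs with
deterministic per-type frequency profiles (0.05–0.20 background, one
enriched type per CFE at 0.45), eight drugs with baseline ln IC50 3.5 ln µM
against a 10 µM maximum tested concentration (so unaltered lines sit above
the screening range and read as resistant), and a handful of planted
additive and OR effects.

The concordance benchmark (`concordance_sim_config()`) instead gives every
cancer type one *dominant* CFE class (cycling CG, iCpG, deleted RACS,
amplified RACS at 0.45 versus 0.05 background; types sharing a class enrich
disjoint halves of its CFEs). Without a planted dominant class the
"predominant class per type" is a coin flip and its concordance between
cohorts is not a recoverable quantity; with it, both the nearest-neighbor
fingerprint and the modal global class are well defined.

What the generator does **not** emulate: linkage and mutual exclusivity
between CFEs (draws are independent), cohort-level batch structure,
missingness mechanisms beyond missing-at-random, heteroskedastic assay
noise, and any relation between gene expression and the binary events.
Passing tests therefore demonstrate the *statistical machinery* — calibration,
power at stated effect sizes, exactness of the optimizers — not robustness
to the correlation structure of real screens.

Dose–response curves are generated from a two-parameter logistic with a
lognormal slope (meanlog 0, sdlog 0.2), a dilution series
`max_conc / dilution^k`, and Gaussian viability noise clipped to
[−0.1, 1.2] to mimic plate-reader artifacts without producing pathological
fits. Methylation signal is a logit-normal mixture: informative islands mix
a low mode at beta 0.1 and a high mode at beta 0.8 (logit-scale sd 0.5,
high-mode weight uniform in [0.3, 0.7]); uninformative islands are unimodal
at beta 0.15.

# Curve summarization

`fit_curve()` replaces a multilevel, information-sharing curve model with
the minimal per-curve summary: least squares on
$v = 1/(1 + e^{s(\ln c - m)})$ with asymptotes fixed at 1 and 0. With 5–9
point curves the asymptotes are not identifiable and fixing them is what
makes $m = \ln \mathrm{IC50}$ and the slope $s$ estimable. Optimization
starts from a fixed grid (slope ∈ {0.5, 1, 2, 4} × ln IC50 at the
tested-range quartiles) and takes the best `nlminb()` refinement, so fits
are deterministic without a global optimizer. IC50s beyond the top tested
concentration are *kept* and flagged `extrapolated` rather than capped:
capping is a sensitivity analysis, not a default, because it destroys
dynamic range exactly where resistance biology lives. AUC is the analytic
mean of the fitted logistic over the tested log-concentration interval,
clipped to [0, 1]. Replicate concordance uses the screening convention that
a line is *sensitive* when IC50 ≤ the maximum tested concentration
(inclusive), and reports the Pearson correlation plus a one-sided Fisher
exact test of the 2×2 sensitive/resistant table.

# The ANOVA scan and its gates

For each (drug, CFE) pair with at least 3 carriers and 3 non-carriers of
complete data, `fit_association()` fits OLS of ln IC50 on covariates plus
the CFE and reports the F-test of the CFE term added last. Pan-cancer scans
adjust for cancer type and MSI status; cancer-specific scans (restricted to
types with more than 15 screened lines) adjust for MSI only. The minimum
group size of 3 is the smallest with a defined group variance; the choice is
ours, as is treating unknown MSI as its own factor level. FDR is controlled
by Benjamini–Hochberg *within each scan* — one pan-cancer family, one family
per cancer type — matching how pan-cancer and cancer-specific hit counts are
reported separately.

A pair is **significant** when p < 10⁻³ and FDR < 25%, and a
**large-effect** interaction when additionally both Glass deltas exceed 1:

$$\Delta_{\mathrm{pos}} = \frac{|\bar y_{\mathrm{pos}} - \bar y_{\mathrm{neg}}|}{s_{\mathrm{pos}}},\quad
  \Delta_{\mathrm{neg}} = \frac{|\bar y_{\mathrm{pos}} - \bar y_{\mathrm{neg}}|}{s_{\mathrm{neg}}},\quad
  d = \frac{\bar y_{\mathrm{pos}} - \bar y_{\mathrm{neg}}}{s_{\mathrm{pooled}}}.$$

Requiring both deltas > 1 means the mean shift must stand out against the
spread of *each* population, not just the pooled one. Direction is defined
on the mean difference: negative (carriers more sensitive) = *sensitizing*.

## A calibration caveat worth stating plainly

Under a global null with continuous, independent p-values, the BH procedure
at level q makes at least one rejection with probability exactly q. At
q = 0.25 roughly a quarter of pure-noise scans will therefore flag at least
one "significant" pair, whatever the number of tests — the p < 10⁻³ conjunct
stops binding once the scan exceeds a few thousand tests. The package's own
null simulations reproduce this: raw p-values are uniform (the fraction
below 0.05 sits at the nominal rate), per-scan counts of p < 10⁻³ follow
the binomial expectation, but the fraction of null scans with *zero* gated
hits plateaus around 70–80%, not higher. A pipeline that needs strict
null silence should lower q or add an effect-size gate — which is precisely
the role the large-effect (Glass Δ > 1 twice) filter plays.

`downsample_experiment()` reruns the scan on random subsets (by default the
500/300/150/60 ladder) and reports retention of full-cohort hits and the
effect-size shift of retained hits. `cross_study_validate()` compares two
scans on shared (drug, CFE) pairs via the correlation of signed −log₁₀ p
and per-direction validation rates (validated: p < 0.05 with the same
direction in the second study).

# Logic models

`lobico_cv()` implements binary-input, continuous-output logic optimization.
IC50s are binarized at θ (by convention the log maximum tested
concentration; configurable), and each sample is weighted by its distance
|ln IC50 − θ| from the threshold, normalized so each class carries total
weight 0.5. The weights let the continuous IC50s speak inside a
classification objective: clearly-sensitive and clearly-resistant lines
dominate, borderline lines barely matter, and the 0.5/0.5 normalization
balances the classes regardless of prevalence.

The hypothesis class is deliberately tiny: two-level AND/OR formulas over at
most four CFE literals, negation allowed. The eight candidate complexities
are the single literal, AND models of up to 2–4 literals, OR models of up to
2–4 literals, and the 2×2 OR-of-ANDs — the only symmetric eight-member
family spanning "single predictor" to "four inputs". Each complexity is
defined with *up to* semantics (up to K clauses of up to M distinct-feature
literals), which makes the classes nested, so the optimal training objective
is provably non-increasing in complexity and cross-validation is what
arbitrates.

The optimizer is exhaustive enumeration, not integer programming: every
candidate formula's prediction vector is materialized once per feature set
into a library matrix, and each fit (each CV fold, each permutation) reduces
to two crossproducts against it. This is exact — a brute-force
truth-table enumerator verifies objective-optimality on hundreds of random
instances in the test suite — and has no solver dependency. The cost is
quadratic in the clause count for the 2×2 class, so the exhaustive search is
restricted to the top `prefilter = 12` features ranked by single-feature
weighted accuracy when more are offered (at 25 features the 2×2 class alone
exceeds 700,000 candidate formulas and several gigabytes of prediction
vectors; 12 keeps the same exact optimizer at desk scale). Solutions must
have training specificity ≥ 80% — a model that calls resistant lines
sensitive is clinically useless however good its recall — and the constraint
is enforced on training data (enforcing it on held-out folds would make
feasibility stochastic). When no formula is feasible the null model
(all-resistant) is returned, flagged. Ties are broken toward fewer distinct
features, then lexicographically, so fits are deterministic.

Complexity is selected by stratified 5-fold CV on the weighted held-out
misclassification, averaged over folds (and repeats), with ties to the
simpler model; the selected complexity is refit on all data. Significance is
by permutation: the ln-IC50 vector is permuted, the whole CV pipeline rerun,
and p = (1 + #{permuted CV error ≤ observed}) / (n_perm + 1).
`lobico_scan()` applies BH across drugs and calls a model *predictive* at
p < 0.05 and FDR < 5%. Drugs need at least five sensitive lines to be
modeled at all. `feature_importance()` counts how often each CFE appears in
the per-fold winning formulas at the selected complexity, normalized to
sum 1, and aggregates into CFE-class categories.

# Multi-omic prediction

`scan_combinations()` fits one model per non-empty combination of feature
views (CG, RACS, iCpG, expression, and — pan-cancer only — one-hot tissue).
Binary views pass through; expression is standardized per gene. Performance
is the Pearson correlation of observed versus strictly out-of-fold predicted
ln IC50 under nested CV (5 outer folds; the elastic-net penalty tuned by
inner 5-fold CV at α = 0.5, the random-forest `mtry` by out-of-bag error).
Each fold's predictions are centered on their training mean before pooling:
an intercept-only fit then contributes a constant (scored r = 0) rather
than the training-fold means, whose anticorrelation with held-out means
would otherwise bias null correlations to about −0.08.

The predictiveness threshold can be fixed (defaults 0.21 pan-cancer, 0.25
cancer-specific) or derived from scratch by
`derive_predictive_threshold()`: fit a two-component Gaussian mixture to all
model correlations, call the higher-mean component informative, and take the
smallest r at which the posterior odds of being informative reach 9:1 —
evaluated on a dense grid and taking the first *sustained* crossing so a
heavy-tailed null cannot produce a spurious low crossing. If BIC prefers a
single component the mixture has collapsed and the threshold is +∞ with a
warning. Per drug and mode, the *lead model* is the best predictive
combination, ties to fewer data types.

# Concordance and stratification

Frequency profiles are per-type, per-cohort column means over observed
entries. Nearest-neighbor tissue matching ranks the other cohort's profiles
by correlation distance (1 − Pearson over shared CFEs) and scores whether
the same cancer type appears within the top k, pooling both directions
(cell→tumor and tumor→cell) into one accuracy. Pathway concordance maps
CFEs to pathways (a user table; `toy_pathway_map()` ships a 13-pathway
stand-in) and correlates the per-type fraction of samples with ≥ 1 altered
pathway member across cohorts.

Global classes reduce each sample to the argmax of its cohort-normalized
class burden — counts of altered CG (→ M), iCpG (→ H), deleted RACS (→ CD),
amplified RACS (→ CA) events, each divided by the cohort mean for that
class — with ties broken M > H > CD > CA. This burden-argmax rule is a
documented stand-in for a full enrichment clustering: it preserves the
testable contract (each class is dominated by its CFE type; concordance of
the predominant class per cancer type is well defined) without reproducing
an unpublished clustering. `stratification_landscape()` finally reports, per
cancer type and compound, the percentage of tumor samples carrying ≥ 1
sensitizing marker or satisfying a sensitivity logic rule, plus an
accumulated all-compound row — the population a stratified trial could
enroll.

# Methylation binarization

`detect_informative_cpg()` decides whether an island's beta values are
multimodal by comparing 1- and 2-component Gaussian mixtures (unequal
variances) on logit-transformed betas by BIC, requiring mean separation
≥ 1 logit unit and both weights ≥ 0.05. The logit transform is the natural
scale for beta values (it unbounds them and symmetrizes the modes); betas
are clipped to [10⁻³, 1 − 10⁻³] first. The discretization threshold is the
beta value between the two means where posterior membership is equal,
solved by `uniroot` on the log-posterior difference (dense-grid fallback
for degenerate fits); hypermethylated means strictly above the threshold.
One caveat is inherited from the scale choice: the equal-posterior point is
invariant under monotone transforms only for the *true* mixture. If the
data were truly Gaussian on the beta scale, the logit-normal fit recovers a
crossing systematically above the beta-scale one (≈ 0.59 versus 0.45 for
modes 0.1/0.8 with beta-scale sd 0.05); under its own generating model —
logit-normal components, as `simulate_methylation()` draws — recovery is
within ±0.05 of the analytic crossing in ≥ 95% of runs. Since real
methylation distributions are bounded and skewed (much closer to
logit-normal than to truncated Gaussians), we consider the logit scale the
right default and document the bias rather than hide it.

# Numerical and design choices, in one place

- Missing alteration entries propagate as `NA` and are excluded
  complete-case per test; they never silently become 0.
- CFE ids are opaque strings; RACS coordinates are labels, never parsed.
- Strict ">" at the hypermethylation threshold; "≤" for sensitivity at the
  maximum tested concentration (both deterministic boundary rules).
- `run_scan()` enumerates tests in sorted (drug, CFE) order, so results are
  invariant to input row/column order.
- All generators restore the caller's RNG state; every stochastic routine
  takes an explicit seed and is bitwise reproducible.
- Logic-model tie-breaks: fewer distinct features, then the lexicographic
  formula string. Complexity-selection ties go to the simpler model.
- Floating-point ties in the logic objective are merged at 10⁻⁹; weight
  conservation in `binarize_and_weight()` is exact to 10⁻¹².
- Problem sizes in the test suite and acceptance script (300-line cohorts,
  10,000-test null scans, 50-instance oracle sweeps, 20-permutation
  significance at recovery scale) were chosen as the smallest sizes at
  which each property is statistically decisive.

# Known limitations

- Independent-Bernoulli CFEs ignore co-occurrence/exclusivity structure;
  power estimates on real screens will differ.
- The per-curve logistic fit shares no information across cell lines; IC50s
  far above the tested range are extrapolations and should be treated as
  censored in sensitive analyses.
- The exhaustive logic optimizer is exact only within the top-`prefilter`
  features; with hundreds of CFEs the prefilter is a greedy screen and can
  in principle exclude a member of the optimal formula.
- The permutation test reruns CV with one repeat per permutation by
  default; p-values below 1/(n_perm + 1) are unattainable by construction.
- Gene expression enters as an already-summarized numeric matrix; no
  probe-level processing is attempted.
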