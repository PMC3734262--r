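---
title: "Reference-gene stability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrstab)
```

## The problem

A Cq value is the PCR cycle at which a reaction's fluorescence crosses a
threshold; it is logarithmic in starting template amount, with one cycle
corresponding to a factor E (the per-cycle amplification efficiency,
E = 2 for perfect doubling). Relative quantification divides a target
gene's efficiency-corrected quantity by that of one or more reference
genes; any instability in the references propagates into every reported
fold change. This package scores candidate references with five
established algorithms, merges their rankings into a consensus, and
validates the choice by quantifying a known-responsive target under
alternative reference sets.

## Data model and conventions

A `cq_matrix` holds genes × reactions Cq values with per-reaction
annotations (panel, condition, treatment group, biological and technical
replicate, mock flag). Each reaction is one observation: technical
replicates are **not** pre-averaged for stability analysis, so replicate
scatter counts against a candidate — this matches how per-experiment
sample sizes are usually reported (n = conditions × 2 × 2). The single
deliberate exception is quantification (below), where technical
replicates are averaged on the Cq scale first, which is standard practice
for fold-change reporting.

Relative quantities use the gene's minimum observed Cq (its most abundant
reaction) as calibrator: `rq = E^(minCq − Cq) ∈ (0, 1]`. The calibrator
is a per-gene multiplicative constant, and every downstream statistic
(log-ratio SDs, CVs of normalised values, correlations, fold changes) is
invariant to it, so the choice is consequence-free; min-Cq keeps values
in a fixed, interpretable range. Log base 2 is used everywhere ratios are
logged, so one unit is one perfect PCR cycle; NormFinder's ρ is therefore
in log₂ units.

Missing wells are `NA`, never zero. Pairwise statistics use
pairwise-complete observations; genes with fewer than 3 present values in
an analysis scope are dropped from that scope with a warning.

## The five methods

**Stability index.** Per gene: CV (%) of Cq and the OLS slope of the
gene's Cq on the per-reaction mean Cq across genes; SI = CV × |slope|.
The absolute value matters: a regression can return a negative slope, and
negative sensitivity to global expression drive is no virtue in a
reference. SI is the only method that depends on the absolute Cq level
(through the CV denominator), a documented asymmetry: adding a constant
to a gene's Cq changes its CV but leaves geNorm M, ΔCt, NormFinder ρ and
BestKeeper dispersion untouched.

**geNorm.** M is the mean SD of pairwise log₂ ratios; iterative exclusion
removes the highest-M gene, recording its M~A~, until two genes remain
(which share the final M~A~ — pairwise comparison cannot separate them).
Ties in M are broken by gene label order (the alphabetically last of the
tied genes is excluded first, so a fully degenerate panel ranks in label
order) with a warning. M~A~ ≤ 1 is flagged as the acceptability bound for
heterogeneous sample sets. The pairwise-variation series
V~n/n+1~ = SD[log₂(NF~n~/NF~n+1~)] (NF = geometric mean of the top n
genes) determines the minimal number of references: the smallest n with
V below the 0.15 cutoff, falling back to the panel size with a warning
when no V passes.

**NormFinder.** On column-centred log₂ quantities. Without groups, ρ is
the SD of a gene's centred values scaled by √(K/(K−1)): centring over K
genes contracts each gene's variance by (K−1)/K, and the correction
undoes it. With groups, per-gene-per-group intragroup variances s² and
intergroup deviations d are combined as
ρ = mean over groups of (|d̃| + √(s²/n)), where d̃ shrinks d by
γ²/(γ² + s²/n) and γ² is the across-genes, across-groups mean of d² — a
simple moment estimator of the between-group variance. Which mode a
published analysis used is often unstated; the pipeline default is
no-group mode (it needs no design assumptions), with grouped mode exposed
through the `groups` argument.

**BestKeeper.** Dispersion is the **mean absolute deviation** of Cq about
the gene's geometric mean Cq — the published BestKeeper convention,
worth flagging because result tables conventionally label this column
"SD". The per-reaction geometric mean of all genes' Cq forms the
BestKeeper index; each gene's Pearson r with the index is reported
descriptively but excluded from the ranking key (a constant gene has
undefined r, reported as `NA`, yet ranks first on zero dispersion).

**Comparative ΔCt.** Mean over partners of SD(Cq~g~ − Cq~h~). With all
efficiencies equal to 2 this equals geNorm's M gene for gene, because
log₂(rq~g~/rq~h~) = (Cq~h~ − Cq~g~) + constant; the test suite checks
this identity to 10 significant digits, which pins both implementations
at once.

## Consensus aggregation

The five rankings are merged by minimising the mean Spearman footrule
distance (sum of absolute rank displacements). The Cross-Entropy
Monte-Carlo optimiser keeps an n × n probability matrix over
(gene, position); each iteration samples 500 orderings (per-position
categorical draws without replacement, via Gumbel-max), keeps the top 10
% elite, and re-estimates the matrix as 0.7 × elite frequencies + 0.3 ×
previous matrix. Columns are floored at 1e-12 and renormalised to guard
against collapse. Iteration stops when the elite objective is unchanged
(within 1e-8) for 5 consecutive iterations, or at 200 iterations; the
best-ever ordering is returned, so the incumbent objective is monotone by
construction. The hyperparameters (500 / 0.1 / 0.7) are common
Cross-Entropy practice; all are exposed as arguments, and a seed is
mandatory. For ≤ 8 genes `aggregate_bruteforce()` enumerates all n!
orderings exactly (lexicographically smallest on ties) and serves as the
oracle in the tests: on random 5-list × 6-gene instances the CE optimiser
is required to attain the exact optimum in ≥ 98 of 100 instances and may
never undercut it.

A weighted footrule variant (positions replaced by each list's scores
rescaled onto [1, n]) is available but off by default: published
aggregations rarely state whether weighting was used, and the unweighted
distance is the named convention.

## Efficiency from raw curves

Real-time fluorescence is modelled (and simulated) as logistic:
exponential at F ≪ plateau, saturating above. The estimator scans all
windows of 4–6 consecutive cycles whose readings sit strictly above a
noise floor and below a plateau threshold, fits log₁₀ F on cycle by OLS,
and keeps the window with maximal r² (ties within 1e-9: steeper slope,
then earlier window); E = 10^slope. The floor is median + 10 × SD of the
first eight readings — generous enough to exclude baseline chatter — and
the plateau threshold is 90 % of the curve maximum; both simply restrict
the fit to the exponential phase, which is the point of the
window-of-linearity approach. Estimates with r² < 0.99 are dropped before
per-amplicon aggregation (mean ± n−1 SD), and means outside (1, 2.2] are
flagged. On noiseless exponentials every eligible window recovers E to
machine precision; on noisy logistic curves a small downward bias
(~0.03 at E = 1.8 with the generator defaults) remains because even
early-window fluorescence carries some plateau bend — the acceptance
band of ±0.05 reflects that.

## Quantification and the bias contrast

Technical replicates are averaged on the Cq scale; quantities are
normalised by the geometric mean of the reference set; each condition's
fold change is the mean normalised quantity over its biological
replicates divided by that of its calibrator, with SD over biological
replicates. The default calibrator rule matches a condition to the mock
condition in the same panel sharing its time-point prefix (e.g.
`d3.inf → d3.mock`), else to the panel's single mock condition; panels
without mocks need an explicit calibrator. Fold changes across
biological replicates are combined by arithmetic mean on the linear
scale. `bias_contrast()` repeats the quantification under a deliberately
poor reference and reports log₂(fold~worst~/fold~best~) per condition: a
reference with a +1-cycle treatment artefact produces exactly +1 log₂
unit of bias at E = 2.

## What the generator emulates — and what it does not

`sim_config()` defaults encode the emulated study design: 13 candidate
genes, 7 panels totalling 48 experimental cells (ripening series,
mock/infected time courses in three tissues and two cultivars, two
hormone-elicitation courses), 2 biological × 2 technical replicates — 192
reactions per gene. On the Cq scale:

- baselines b~g~ ~ U[8, 30] cycles (the span of abundances seen in real
  panels, from rRNA to low-copy transcription factors);
- a shared per-condition load L~c~ ~ N(0, 1) with per-gene sensitivity
  s~g~ ramping 0 → 0.6 — the "general expression-promoting conditions"
  signal that the stability-index slope is designed to detect;
- Gaussian biological noise per biological replicate and technical noise
  per reaction, with combined SD ramping 0.2 → 1.7 cycles so that
  realised per-gene total SDs span roughly 0.2–1.9 cycles, matching the
  dispersion range of real panels;
- group effects default to zero (they are available via `group_effect`
  for quantification and NormFinder-grouped scenarios).

Gene 1 is thus a designed true reference (s = 0, minimal σ), and the
ground-truth stability order is by
τ~g~ = √(σ²~bio~ + σ²~tech~) + s~g~·SD(L) + SD(δ~g,·~). Noise is Gaussian
on the Cq scale because Cq is already logarithmic in template amount —
consistent with all five methods operating on Cq or log ratios.

What passing parameter-recovery tests show is that the implementations
rank genes correctly when the generative model holds. Real data deviate
in ways the generator does not emulate: co-regulated candidate genes
(which bias geNorm toward correlated pairs), non-Gaussian outliers,
plate/run batch effects, missingness correlated with expression level,
and inhibition or efficiency drift across samples. The recovery rates
are therefore evidence of implementation correctness, not a guarantee
about any particular real panel.

Amplification curves are simulated with F₀ = 1e-6, plateau = 10
(relative units), read noise SD 2e-3 and 40 cycles: baseline noise at
0.02 % of plateau and an exponential phase of roughly ten cycles between
detection floor and plateau bend, typical of real-time instruments.
Baseline drift is deliberately not modelled — baseline handling is the
estimator's job, and the floor rule absorbs it.

## Numerical choices and degenerate inputs

- Sample SDs use the n−1 denominator throughout.
- Zero-variance predictors in the SI regression yield slope 0 with a
  warning rather than an error (a constant panel is a legitimate
  degenerate input, and SI = 0 is its correct limit).
- Exact-zero assertions on ratio statistics are tested at 1e-12: log/exp
  round-trips leave O(1e-16) residue even on exactly proportional
  profiles.
- geNorm exclusion ties are resolved at 1e-12 resolution by label order,
  with a warning.
- The Cq reader accepts decimal commas (common in exported tables) and
  records empty/`NA`/`ND` cells as missing; non-numeric cells are hard
  errors naming gene and reaction.
- All simulation and optimisation randomness flows through explicit
  integer seeds; the pipeline refuses to run its stochastic aggregation
  stage without one, and identical seeds give byte-identical JSON
  bundles.

## Problem sizes in the test suite

The suite exercises full-size simulated studies (13 × 192) across 100
seeds for method recovery and 50 seeds for end-to-end consensus recovery,
100 random aggregation instances against the exhaustive oracle, 100
simulated amplification curves for efficiency recovery, and a
10,000-reaction panel for the noise-SD convergence check — sizes chosen
so the whole suite completes in well under a minute while keeping the
Monte-Carlo margins (e.g. ≥ 90 of 100 seeds) statistically comfortable.

## Known limitations

- geNorm's final two genes are inseparable by construction; their shared
  M~A~ and the label-order tie-break are conventions, not measurements.
- BestKeeper's Pearson r is sensitive to heterogeneous variance across
  expression levels; it is reported but never ranked on.
- NormFinder's grouped mode uses the simple moment shrinkage above;
  results can differ in the third decimal from other implementations,
  which is why correctness is established by parameter recovery rather
  than by matching any particular software's output.
- The efficiency estimator reproduces the window-of-linearity idea, not
  any specific software's version-by-version windowing heuristics, and
  it does not call Cq values from curves.
- The consensus optimiser guarantees optimality only empirically (via
  the brute-force oracle at small n); at 13 genes the footrule optimum
  is not verified exhaustively.
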