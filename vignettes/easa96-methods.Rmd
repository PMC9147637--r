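---
title: "Probe-depletion analysis for a 96-well electrophilic screening assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe-depletion analysis for a 96-well electrophilic screening assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(easa96)
```

## The assay and its model

Skin sensitization by covalent protein binding is screened *in chemico* by
measuring how much of a reactive probe a test compound (TC) consumes. Two
probes stand in for nucleophilic protein side chains: a thiol
(4-nitrobenzenethiol, absorbance at 412 nm) and an amine (pyridoxylamine,
absorbance at 324 nm and fluorescence at ex 324 / em 398 nm). Reaction with
an electrophilic TC depletes the probe and lowers the signal.

Each 96-well plate carries its own controls: a solvent-only blank column,
15 negative-control (NC) wells (probe in solvent), a seven-level 1:2
positive-control dilution series in triplicate, and for each of up to seven
TCs four probe wells plus three probe-free interference wells. From the
50-minute read the package computes, per chemical,

$$\mathrm{Depletion} = (\overline{NC}-\overline{blank}) -
  (\overline{TC}-\overline{TC_{blank}}),\qquad
  \%\,\mathrm{depletion} = 100\,\frac{\mathrm{Depletion}}
  {\overline{NC}-\overline{blank}}.$$

Subtracting the TC-blank mean corrects for intrinsic TC colour or
fluorescence (interference); dividing by the NC-minus-blank window makes
the result scale-free.

## Classification routes

Three routes decide binder/nonbinder; all are computed and reported, and a
configurable primary route (default: frequentist at $\alpha=0.005$) drives
run-level calls.

**Frequentist.** Under Gaussian well groups the statistic
$$T=\frac{(\overline{NC}-\overline{blank})-(\overline{TC}-\overline{TC_b})}
{\sqrt{s^2_{NC}/n_{NC}+s^2_{bl}/n_{bl}+s^2_{TC}/n_{TC}+s^2_{TCb}/n_{TCb}}}$$
is referred to a Student $t$ with Satterthwaite degrees of freedom (inner
terms $(s^2/n)^2/(n-1)$). Counts are the wells actually retained after QC,
nominally 15/8/4/3. The default test is one-sided (depletion $>0$),
matching the direction of the Bayesian lower-bound rule; a two-sided mode
is available. Because the dominant variance term often carries only ~3
degrees of freedom, the approximation is measurably liberal in the far
tail: simulations in the test suite put the true size near 0.008 at
nominal $\alpha=0.005$ (it is accurate at $\alpha=0.05$, and near-exact
when group variances are equal). This is a property of the printed
formulas, not of the implementation.

**Bayesian.** A Gibbs sampler gives each of the four groups its own
Gaussian mean and variance, with diffuse normal priors on means and
Gamma(0.001, 0.001) priors on precisions. The sampler runs on data
standardized by the pooled within-group SD: on a raw absorbance scale the
group variances (~1e-5) would be swamped by the prior rate 0.001, inflating
posterior variances roughly a thousandfold; standardization keeps the
prior vague on any instrument scale and makes the route scale-invariant.
The chemical is a binder when the lower bound of the equal-tailed
$1-\alpha$ credible interval on Depletion exceeds zero. Two chains are run
and split-$\hat R$ on the depletion draws above 1.05 attaches a
non-convergence warning (the call is still reported). Defaults are 20000
iterations with 5000 burn-in per chain; the paired-agreement and recovery
checks in the tests use shorter chains because these well-separated
posteriors mix within a few hundred sweeps.

**k × SD.** Binder when % depletion strictly exceeds `ksd_factor`
(default 5) times the SD of the per-well NC % depletions. Ties are
nonbinders. This rule ignores TC-well uncertainty and is retained for
comparison, not as the primary route.

Borderline flags mark binders under 10 % depletion (potential Type I) and
nonbinders over 3 % (potential Type II). A % depletion below −20 %
indicates signal gain (e.g. coloured reaction products) and forces an
inconclusive call.

A run calls a chemical binder if any voting modality does; a clean
nonbinder requires at least one conclusive negative and no inconclusive
modality. Across runs, the majority of conclusive run calls decides, with
exact ties inconclusive. The amine-probe absorbance modality is computed
but can be dropped from voting (`include_pda_abs = FALSE`), since it adds
no calls beyond the other two in the published panel.

## In-process QC

* **Bubble test**: all wells are read at 680 nm (outside both probes'
  spectra) within the first read window. Wells above 0.081 AU (absorbance
  assays) or 5300 instrument units (fluorescence) are excluded before any
  summarization. The absorbance threshold sits where ~1 % of wells fall in
  practice; a well just below it biases that well's % depletion by only
  1–2 %.
* **Interference**: a TC-blank mean offset from the plate blank by more
  than `interference_k` (default 3) blank SDs is flagged — advisory only.
  An offset beyond the instrument's dynamic range marks that chemical's
  modality result not-available rather than excluding wells.
* **Pipetting**: within-stroke CV from the column-2 NC wells, between-
  stroke CV from the row-A NC wells, and an OLS column-trend test on the
  row-A wells. A significant trend warns (the thiol assay shows a <1 %
  trend routinely) but never rejects a plate on its own.
* **Control charting**: blank mean, NC mean, NC CV and the positive-
  control IC50 are charted per modality over all previously accepted runs
  (expanding window, minimum 5 runs before limits activate — the source
  protocol charts without stating a minimum). A run outside mean ± 3 SD on
  any parameter is a plate outlier and its data excluded; outliers are not
  appended to the history.

## Assay quality

The positive-control series is fitted with a four-parameter log-logistic
curve; the reported IC50 is the fitted curve's 50 %-depletion crossing,
with log-linear interpolation between bracketing levels as fallback and an
explicit not-estimable state when the response never brackets 50 % (the
chart parameter is then simply missing). The Z-factor is
$1-3(s_{sample}+s_{PC})/(\overline{NC}-\overline{blank})$ with a two-stage
trim of $s_{sample}$: chemicals under 5 % depletion are dropped, then
chemicals whose SD exceeds three times the mean SD of the remainder are
dropped once (no iteration) — the single-pass reading reproduces the
removal counts reported for the published panels. $s_{PC}$ comes from the
run's maximal-depletion compound (~99 % depletion).

## Defined approaches and concordance

Binder/nonbinder (protein binding, KE1) combines with keratinocyte
activation (KE2) and dendritic-cell activation (KE3) calls. "2 out of 3"
requires two concordant calls; one positive, one negative and one missing
is inconclusive — the tie handling is pinned by the published D-glucose
case, which is negative with this assay as KE1 and inconclusive with the
peptide-reactivity comparator. KE 3/1 is a decision tree: KE3 positive is
positive; KE3 negative defers to KE1; a missing KE3 is inconclusive.
Cooper statistics (accuracy, false-positive rate over reference negatives,
false-negative rate over reference positives) are reported as explicit
fractions; scopes select the comparator (LLNA only, LLNA+GPMT, or the
peptide-reactivity assay head-to-head), with inconclusive predictions and
missing comparators excluded and counted.

The package ships a transcription of the published 92-chemical reference
panel. Recomputing concordance from it reproduces the published
LLNA-only panel exactly (49/64 agreement, 6/15 false positives, 9/49
false negatives) and the comparator panel exactly (34/44, 2/13, 8/31).
The published LLNA+GPMT agreement cell (49/67) is internally inconsistent
with the per-chemical table, which yields 50/67: the three GPMT-only
chemicals are all printed non-sensitizers and one of them (triphenyl
phosphate, a nonbinder) agrees. The package reports the honestly
recomputed value.

## The synthetic plate generator

`simulate_run()` emulates the instrument so the whole pipeline is testable
without laboratory data. Its defaults state the simulated world:

* Gaussian noise per well with SD proportional to the group mean
  (multiplicative), since small signals carry relatively larger instrument
  noise; a constant-SD mode exists. Default CVs put the NC %-depletion SD
  near the published scales: ~1.2 % (thiol absorbance), ~2.0 % (amine
  absorbance), ~2.4 % (amine fluorescence).
* Signal scales: blank 0.066 AU (the observed 680 nm background mode is
  reused as the absorbance blank), NC 1.0 / 0.5 AU for the two absorbance
  assays, 2000/50000 RFU for fluorescence — chosen so windows and CVs sit
  at realistic magnitudes.
* Depletion acts only on the probe-derived part of the TC signal (above
  the interference offset), so the depletion equations are exact in
  expectation and zero-noise runs round-trip exactly.
* Bubbles: 1 % of wells by default, drawn once per plate, visible as
  spikes on the 680 nm read and carried 1:1 into absorbance reads (weakly,
  factor 0.2, into fluorescence, mirroring the much weaker observed
  correlation).
* A 2 % total probe decay from the 5- to the 50-minute read (truth is
  defined at 50 min, the analysis read), and an optional NC column trend
  (~1 % total emulates the thiol assay's pipetting trend).
* Positive-control wells follow a log-logistic curve per modality with the
  50 %-point at roughly one tenth of the top concentration, giving a
  near-complete response at the top level as observed.

What a green test does **not** establish: the generator draws independent
Gaussian wells, so plate-position effects, condensation-driven variance
growth after 50 min, solvent chemistry, kinetics and real interference
spectra are outside its world; agreement with the published Z-factors or
interference prevalence cannot be (and is not) claimed from simulation.

## Numerical choices and edge cases

* Sample SDs use $n-1$; inference uses the post-QC well counts, not the
  nominal 15/8/4/3 (the source text's "(i.e., n − 1)" parenthetical
  conflicts with its printed denominators; the printed formulas win).
* $\overline{NC}\le\overline{blank}$ is a hard signal-window error; a
  group emptied by exclusions is a hard error naming the group.
* Negative % depletion is returned as computed; only the classifier maps
  anomalies (< −20 %) to inconclusive.
* The 4PL fit uses `nls` (port, bounded); a non-convergent fit falls back
  to interpolation, and the method used is always recorded.
* k × SD ties resolve to nonbinder (strict inequality).
* Monte-Carlo assertions over grids use simultaneous (Bonferroni) bounds;
  per-cell two-SE bounds would fail by multiplicity alone.
* All MCMC is seeded; the sampler restores the caller's RNG state.

## Known limitations

Potency (EC3 / GHS subcategory) is out of scope; EC3 values in the
reference panel are metadata only. No multiple-testing correction is
applied across chemicals, matching the source protocol. The far-tail size
inflation of the Satterthwaite route at $\alpha \le 0.005$ is inherent to
the printed formulas; users wanting exact small-sample control should
prefer the Bayesian route.
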