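---
title: "Deriving and validating cross-species miRNA signatures with mirsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating cross-species miRNA signatures with mirsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsig)
```

## The problem

Circulating microRNAs are attractive disease biomarkers, but candidate
panels discovered in preclinical models rarely survive the trip to human
cohorts: identifiers differ across species and platforms, discovery designs
are tiny and high-dimensional, and single-split performance estimates
overfit badly. `mirsig` implements one complete, testable version of the
translational workflow for this setting:

1. **Discovery** in a 2×2 mouse serum design (Control/MPTP × day 0/day 5,
   four replicates per cell, ~3,000 miRNA probes): per-feature linear
   modelling with empirical-Bayes variance moderation, a dataset-level
   permutation test, and stability selection of a compact day-0 panel.
2. **Harmonization** of mouse and human mature miRNA names and seed
   sequences into platform-agnostic "core" identifiers.
3. **Validation** of the panel in independent human case/control cohorts by
   composite z-score scoring and permutation-validated ROC analysis.

Because the package must be exercisable without any external data, a
first-class synthetic-data module generates every input the pipeline
consumes, with planted effects whose recovery the test suite measures.

## Models and procedures

### Differential expression in the 2×2 design

`fit_cell_means()` fits the saturated cell-means parameterization of the
group × time design (equivalent to group + time + interaction). For feature
$g$, the pooled within-cell variance $s_g^2$ has $d = N - 4$ residual
degrees of freedom. `ebayes_moderate()` treats the $s_g^2$ as scaled
chi-square draws around an inverse-chi-square prior with hyperparameters
$(d_0, s_0^2)$, estimated by the method of moments on
$e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$:

$$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d/2), \qquad
  s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\},$$

with $\psi$, $\psi'$ the digamma and trigamma functions, the first equation
solved by Newton iteration on the monotone trigamma function. When
$\mathrm{var}(e) \le \psi'(d/2)$ — log-variance spread at or below its pure
sampling floor — the prior is infinitely informative: $d_0 = \infty$ and all
posterior variances equal $s_0^2 = \exp(\bar e)$. Otherwise the posterior
variance is the usual precision-weighted compromise
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, and moderated
t-statistics gain $d_0$ degrees of freedom. The synthetic generator draws
homoscedastic noise, so on simulated data the infinite-prior branch is the
common (and correct) outcome; the parameter-recovery test plants a true
$(d_0 = 4, s_0^2 = 2)$ prior and requires both hyperparameters back within
25% at 3,000 features.

The primary contrast is the day-5 minus day-0 cell-mean difference within
the MPTP group — the change attributable to the neurotoxin — with two-sided
p-values on $d_0 + d$ degrees of freedom and Benjamini–Hochberg q-values
(`bh_fdr()`, a validating wrapper over `stats::p.adjust`). The same
contrast within the control group is available by argument.

### The global permutation test

With ~3,000 features and 16 samples, per-feature FDR control says little
about whether the dataset as a whole carries treatment-specific temporal
signal. `global_permutation_test()` addresses this with an omnibus
statistic: per feature, the ordinary pooled-variance two-sample t of day 5
vs day 0 within each group, and

$$T = \sum_g t_{g,\mathrm{MPTP}}^2 - \sum_g t_{g,\mathrm{Control}}^2 .$$

The difference form is the default because the claim at stake is that time
effects concentrate in the treated group; a within-MPTP-only sum
(`statistic = "mptp_only"`) is provided as the simpler omnibus alternative.
Time labels are permuted *within* each group, preserving group membership
and per-group label counts. With four replicates per cell only
$\binom{8}{4}^2 = 4{,}900$ distinct joint assignments exist, fewer than the
conventional $B = 5{,}000$: sampled mode therefore draws with replacement
and uses the add-one estimator $p = (1 + \#\{T^* \ge T\})/(B+1)$, while
exhaustive mode enumerates all distinct assignments (the observed one
included) and returns the exact $p = \#\{T^* \ge T\}/4{,}900$. Sampled and
exhaustive p agree within Monte-Carlo error by test, and the type-I error
of the sampled test over 200 null datasets is required to fall in
[0.03, 0.08] at $\alpha = 0.05$.

### Day-0 classifier and stability selection

The diagnostic question is whether treated and control animals separate
*before* the day-5 response — eight samples against thousands of features.
Two guards against overfitting are built in:

* `loocv_elastic_net()` re-applies the top-$k$ absolute-t univariate filter
  ($k = 20$ by default) *inside* every leave-one-out fold, fits elastic-net
  logistic models over the mixing grid $\alpha \in \{0.1, 0.5, 0.9\}$ with
  the penalty chosen by stratified internal cross-validation, and pools the
  held-out scores into a single AUC. A dedicated leakage test plants a
  feature informative only through the held-out sample and verifies the
  fold is unchanged. Performance is reported as pooled-held-out AUC: a
  literal "mean AUC across folds" is undefined when every fold holds out a
  single sample.
* `stability_selection()` repeats the filter + elastic-net fit on random
  subsamples of 2 animals per class (2,000 iterations by default). Internal
  cross-validation is impossible at $n = 4$, so the penalty is anchored at
  $\lambda = 0.1\,\lambda_{\max}$ of each subsample, with $\alpha$ fixed at
  0.5, the middle of the grid. A feature's selection probability
  $\hat\pi_g$ is the fraction of iterations with a nonzero coefficient;
  features with $\hat\pi \ge 0.6$ form the panel, directions assigned from
  the discovery logFC sign (`build_panel()`). With 2-of-4 subsampling only
  36 distinct subsamples exist; a test confirms that sampling statistics
  match exhaustive enumeration over the 36.
* `selection_permutation_test()` re-runs a reduced-iteration stability
  selection under permuted class labels and compares the observed count of
  threshold-passing features against that null (add-one p-value). The
  reduced per-permutation iteration count (default 200) is what keeps a
  2,000-permutation null tractable on a desktop; a full-fidelity run is a
  parameter change.

### Cross-species harmonization

`normalize_mirna_name()` lower-cases identifiers, converts the mouse
`mmu-` prefix to `hsa-`, assumes human when no species prefix is present,
strips `-3p`/`-5p` arm suffixes, and flags non-human/non-mouse (e.g. viral)
identifiers for exclusion. The canonical serialization is
`hsa-mir-92b`-style — lowercase with the species prefix retained — chosen so
core names remain valid miRNA identifiers; the mapping is idempotent by
property test. `collapse_probes()` averages multiple probes mapping to one
core name (arithmetic mean on the stored scale). The seed region is defined
as nucleotides 2–8 (1-based, 7 nt) of the mature sequence, the definition
under which the package's shipped six-miRNA reference table
(`mirna_ortholog_reference()`) reproduces its printed seed columns exactly;
`compare_orthologs()` recomputes seeds and identity flags from sequences
alone and finds five of six pairs fully identical, with miR-326 the sole
seed mismatch (mouse 5p vs human 3p-dominant arm).

### Signature scoring and validation

Per cohort: counts become $\log_2(\mathrm{CPM} + 1)$
(`cohort_preprocess()`; array data pass through), probes collapse to core
names, every feature is z-scored across samples ($n-1$ denominator), and
the composite score is

$$S_i = \mathrm{mean}_{g \in \mathrm{down}}(-z_{gi}) -
        \mathrm{mean}_{g \in \mathrm{up}}(z_{gi}),$$

so loss of down-regulated members drives the score *up* in cases. Because
orientation is not guaranteed to transfer across platforms, the headline
AUC is $\max(\mathrm{AUC}, 1-\mathrm{AUC})$ with the orientation recorded —
and, critically, the permutation null recomputes the *same* max-orientation
statistic, which keeps the p-value calibrated (verified by a 200-replicate
null simulation; a naive one-sided null would be anti-conservative under
the max rule). Confidence intervals are stratified percentile bootstrap
(2,000 resamples); the operating threshold maximizes Youden's
$J = \mathrm{sens} + \mathrm{spec} - 1$ over observed cut-points, ties
broken toward sensitivity. The permutation p uses add-one smoothing by
default; the literal proportion $\#\{AUC^* \ge AUC\}/B$ is available by
flag.

## The synthetic-data generators

`mouse_sim_spec()` emulates the discovery arm: 3,163 features × 16 samples,
per-feature baselines uniform on [4, 12] log2 units, i.i.d. Gaussian noise
with SD 0.5, fifteen down-regulated features at logFC −2.0 and two
up-regulated at +1.4 applied in the MPTP × D5 cell, and a panel of six
down-regulated features (the signature miRNAs, by name) additionally
shifted down 1.5 log2 units in *all* MPTP samples — making them day-0
discriminative without touching the within-group time contrast. The shift
is applied negatively because the panel is down-regulated; its magnitude is
three noise SDs per feature.

`cohort_sim_spec()` emulates validation cohorts on two platforms:
continuous array-like values (unit-SD Gaussian around uniform baselines)
and exosome-style counts (negative binomial, dispersion 0.3, per-sample
library sizes uniform on [2×10⁵, 10⁶], with the PD effect applied on the
log2 latent scale before sampling). The default planted effect is a
0.8-SD standardized shift on down-regulated members in PD samples. Column
headers follow either label dialect (`PD_01`/`Control_01` prefixes, or
`S001`–`S100` numbering with 1–50 cases) so the label parser is exercised
end to end. Neither platform model is a claim about the real data-generating
process — the source study does not state one — they are stress tests for
the count-preprocessing and scoring paths.

What the generators deliberately omit: probe-level array physics, batch
effects, and inter-feature correlation (background features are
exchangeable). Passing tests therefore demonstrate the *procedures* are
correct and calibrated, not that the signature generalizes in real cohorts.

## Numerical choices and degenerate inputs

* Zero pooled variance in a two-sample t: t = 0 when the mean difference is
  also zero, ±∞ otherwise (a constant separation is maximal evidence);
  never NaN. Filter ties break lexicographically by feature ID.
* `ebayes_moderate()` refuses all-zero variances, excludes isolated zero
  variances from hyperparameter estimation (with a warning), and needs ≥10
  features.
* Trigamma inversion: Newton iteration from the asymptotic start
  $x = 0.5 + 1/y$, relative tolerance 1e−10, with closed-form limits for
  extreme arguments.
* Z-scoring maps constant features to all-zero rows with a warning; scoring
  errors only when *no* panel member matches, otherwise reports coverage.
* Missing values at load are rejected by default; per-feature median
  imputation is an explicit flag. Duplicate feature IDs error by default or
  average by flag.
* All stochastic stages accept a `seed`; the pipeline derives per-stage
  sub-seeds deterministically from one master seed (default 20250912), so a
  configuration reproduces its artifacts byte-identically.

## Design decisions that were genuinely open

* **Global statistic form.** Only "sum of squared t-statistics comparing
  time effects between groups" is specified upstream; the difference of
  per-group sums is adopted as the default (it directly targets
  treatment-specific change) with the MPTP-only sum as an option. Ordinary,
  not moderated, t inside the statistic: moderation is a per-feature
  inference concern, and the permutation null must use the same statistic
  observed.
* **Selection-frequency null statistic.** The count of features at
  $\hat\pi \ge$ threshold, with the mean of the top-$m$ probabilities as an
  alternative flag.
* **CI method** (unstated upstream): stratified percentile bootstrap.
* **Threshold criterion** (unstated): Youden's J.
* **Hemolysis proxy**: the miR-23a minus miR-451 log2 difference with a
  configurable cutoff, default 5 — the proxy is standard, the threshold is
  not; both miR-451 and miR-451a are accepted as the denominator.
* **LOOCV AUC**: pooled over held-out scores (see above).

## Problem sizes used by the test suite

Simulation-backed tests run at sizes chosen to make each property sharply
testable: type-I error of the global test over 200 null datasets at 300
features; exhaustive-p uniformity at 60 features (the exact null is a
4,900-point grid); stability-selection recovery demonstrations at 26–46
features; LOOCV separation at 40 features; cohort validation power over 50
seeds at 100 features and n = 50 + 50; eBayes recovery at 3,000 features.
The full-scale acceptance check of panel recovery runs at the default
3,163 features.

## Known limitations

The most consequential one is quantitative and worth stating plainly: under
the default synthetic conditions, the day-0 signal (a 3-SD per-feature
shift) is **not** recoverable by a top-20 |t| filter computed on 2-per-class
subsamples against 3,157 background features — the null t with 2 degrees of
freedom is too heavy-tailed, so planted features pass the filter in only
~6% of iterations and no feature reaches $\hat\pi \ge 0.6$. The acceptance
suite runs this condition honestly and reports the failure rather than
shrinking the problem; recovery is demonstrated, and tested, at small
background sizes where the mathematics permits it. Relatedly, with a fixed
liberal penalty ($0.1\,\lambda_{\max}$) the *baseline* selection
probability of pure-noise features sits near 0.3, and individual
chance-correlated features can spike above the 0.6 threshold at $n = 8$ —
compact-panel claims from designs this small should always carry the
permutation null. Finally, the generators' independence assumptions make
power estimates optimistic relative to correlated real miRNA data.

## A worked end-to-end run

```{r, eval = FALSE}
library(mirsig)

cfg <- pipeline_config(
  mouse = mouse_sim_spec(),
  cohorts = default_cohort_specs(),
  B_global = 2000, B_auc = 2000, n_stability_iter = 500,
  seed = 20250912, output_dir = "pipeline_out"
)
result <- run_all(cfg, fallback_panel = signature_panel_reference())
result$validation$summary
```

The discovery artifacts (DE table, selection probabilities, panel, global
test JSON, manifest with every seed) land in `pipeline_out/`, and
`report.md` summarizes both arms. `scripts/acceptance.R` in the repository
runs this same computation from scratch and writes the headline numbers as
JSON.
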