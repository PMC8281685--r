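---
title: "Gene-pair prognostic signatures: model, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair prognostic signatures: model, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A gene-pair signature predicts survival from binary within-sample order
indicators rather than expression magnitudes. For an ordered pair p = (a, b)
and sample s, the feature is

$$x_{p,s} = \mathbf{1}\{\mathrm{expr}(a, s) > \mathrm{expr}(b, s)\},$$

with strict inequality: a tie scores 0. The risk score is the linear form

$$\eta_s = \sum_p \beta_p\, x_{p,s}$$

with coefficients from an L1-penalized Cox proportional-hazards fit, and a
sample is called high-risk when $\eta_s$ strictly exceeds a ROC-derived
cutoff. The modelling assumptions are those of the Cox model — proportional
hazards in the pair indicators, independent censoring — plus the implicit
claim that prognostic information survives the reduction of expression to
within-sample ranks.

The reduction buys a strong invariance: any strictly increasing
transformation applied per sample (scaling, log, quantile shifts — a
different function per sample is allowed) leaves every indicator, hence
every score and risk call, bit-identical. This is the precise, testable form
of the usual "robust to batch effects across platforms" claim, and the test
suite asserts it literally over random monotone distortions. What the
invariance does **not** give is robustness to anything that reorders genes
within a sample (probe-specific saturation, gene-length effects when
switching between counts and length-normalized units).

## Pipeline stages and their parameters

**Pairing** (`build_pair_matrix`). The expression matrix is restricted to an
immune-gene list; each unordered combination appears once, oriented by
gene-list position, giving G(G−1)/2 rows. Both orientations are redundant
(complementary up to ties), and a single canonical orientation avoids
perfectly collinear duplicate features downstream.

**Frequency filter** (`filter_pairs`, `min_minor_freq = 0.20`). A pair whose
minor orientation occurs in under 20% of samples is nearly constant and can
only overfit; exactly the pairs with frequency in [0.20, 0.80] — bounds
inclusive, since a pair at exactly 20% is not "less than 20%" — are kept.
The comparison is made on the count scale with a 1e-9 absolute guard so that
inclusive bounds are not lost to binary float representation (0.2·n is not
always representable). The filter is computed on the training cohort only;
validation cohorts are transformed with the training signature's pairs
regardless of their local frequencies, which is how a fixed published
signature is applied to external data.

**Univariate screen** (`univariate_screen`, `alpha = 0.05`). One Cox fit per
pair with the indicator as sole covariate; the candidate flag uses the Wald
p-value, matching the summaries of standard survival software. Pairs that
are constant among the survival-complete samples — or that separate the
risk sets perfectly, where the partial likelihood is monotone — are flagged
inestimable and dropped without aborting the screen.

**Penalized fit** (`fit_lasso_cox`, `n_folds = 10`). The penalty grid is the
glmnet default (100 log-spaced values down to 0.001 of the smallest
all-zero penalty); λ is the grid value minimizing cross-validated partial
likelihood deviance (lambda.min, not 1-SE, since the selection criterion is
the *lowest* deviance). Folds are stratified by event status — with
moderate event counts an unstratified split can starve a fold of events and
destabilize the deviance — and are a deterministic function of the seed.
Binary indicators are left unstandardized (they are already on a common
scale; standardizing would penalize pairs by their frequency), and the Cox
model has no intercept. The refit at the chosen λ uses an exact
coefficient evaluation rather than path interpolation.

**Cutoff** (`time_dependent_roc`, `select_cutoff`). The ROC at horizon t*
uses cumulative cases / dynamic controls with Kaplan–Meier conditioning:

$$\mathrm{sens}(c) = \frac{(1 - \hat S(t^* \mid X > c))\,\hat P(X > c)}{1 - \hat S(t^*)},
\qquad
\mathrm{spec}(c) = \frac{\hat S(t^* \mid X \le c)\,\hat P(X \le c)}{\hat S(t^*)},$$

the estimator of the classical survivalROC approach, evaluated at every
observed marker value. The cutoff maximizes Youden's J = sens + spec − 1 at
the 5-year horizon by default; the source analysis names neither the
horizon nor the criterion, so this package adopts the most common
convention and leaves both configurable (`cutoff_horizon` in the pipeline
config). Ties in J break toward the smallest threshold; a flat curve
returns the smallest threshold with a warning.

**Evaluation.** Kaplan–Meier estimation, the two-group log-rank test and
multivariable Cox fits are implemented in the package (see *Numerical
conventions*); AUCs are reported at 365/1095/1825 days by default.

**TMB** (`compute_tmb`, `exome_length_mb = 38`). Mutations per megabase over
a fixed 38 Mb exome, the conventional whole-exome size; the per-sample
capture size is rarely available in public MAFs, so a fixed denominator is
the default and is configurable. All coding classes count by default —
the quantity is "somatic mutations in the exon length", not
"nonsynonymous mutations" — with `maf_nonsynonymous_classes()` as the
stricter preset.

**Association statistics.** Fisher's 2×2 test sums hypergeometric
probabilities of all tables at most as likely as the observed one (standard
two-sided convention, not mid-p). Pearson correlations report the exact
t-based p. Group comparisons of immune-feature levels use the Wilcoxon
rank-sum test — the source analysis never names the test behind its group
asterisks, and rank-sum is the standard choice for deconvolved cell
fractions; this is an assumption, documented here. No multiple-testing
correction is applied by default, mirroring the reporting style the package
reproduces; `fdr = TRUE` adds Benjamini–Hochberg q-values.

## The packaged bladder-cancer signature

`blca_irgp30()` loads the published 30-pair model (TCGA-BLCA training,
cutoff 0.538, λ = 0.03253915). Its pair list spans 30 distinct gene
symbols. One coefficient is published only as "< 0.001"; the packaged file
stores 0.0005 — the midpoint of the printed rounding interval — and records
that convention in its provenance field. With it, the maximal attainable
score (every indicator 1) is 0.5355. The packaged cutoff is a constant of
the shipped model: the exact ROC variant and horizon behind it are not
re-derivable without the original training data.

## The synthetic world

`simulate_cohort()` generates the structure the analysis assumes, no more:

- expression is log-normal per gene (log2 locations uniform on [2, 8],
  scales on [0.5, 1.5]), a reasonable cartoon of bulk transcriptomes;
- k signal pairs are chosen with **disjoint genes** and orientation
  frequency inside [0.3, 0.7], so recovery tests are well-posed (the pairs
  carry real variation and survive the 20% filter by construction);
- survival is exponential-baseline proportional hazards,
  h(t|s) = h0 exp(Σ β_p x_{p,s}) with h0 = 1/1000 per day (median baseline
  survival ≈ 693 days, a realistic cancer-cohort scale);
- censoring is independent Uniform(0, c_max), with c_max solved numerically
  against the realized event times to hit the target censoring fraction
  (default 30%);
- defaults are n = 300 samples, 20 genes, 5 signal pairs at |β| = 0.8 with
  alternating signs.

What the generator does **not** emulate: count-level noise (negative
binomial), gene–gene correlation beyond what shared log-normal structure
induces, non-proportional hazards, informative censoring, and signature
pairs sharing genes (the published model's 30 pairs heavily share genes; the
generator keeps signals disjoint to make recovery unambiguous). A green
recovery test therefore establishes that the screen+LASSO machinery finds
planted proportional-hazards signals of realistic strength under clean
conditions — not that it would recover the published signature from real
data.

`simulate_mutations()` draws per-sample Poisson counts with log-mean linear
in the standardized true risk; the slope b = r/√(m(1−r²)) (intercept
log m − b²/2) yields approximately the requested count–risk correlation r at
mean count m, which the tests verify empirically.

## Numerical conventions

- **Ties in expression** score 0 by exact float equality — no tolerance —
  so binarization is deterministic.
- **Cox fits** maximize the Breslow partial likelihood by Newton–Raphson
  with step-halving, to gradient norm < 1e-8 (max 100 iterations). Breslow
  tie handling is used throughout: simple, deterministic, and adequate for
  day-resolution survival data where ties are rare. Monotone likelihoods
  (separation) are detected at |β| > 15 and reported as errors naming the
  covariate; the screen converts them to inestimable flags.
- **Confidence intervals** are exp(β ± 1.96 SE), the normal approximation
  on the log-hazard scale.
- **Log-rank** accumulates O − E with the hypergeometric variance over
  distinct event times; on tie-free data it equals the Cox score test for
  the group indicator, which the tests assert to 1e-8.
- **Time-dependent ROC** integrates the (1 − spec, sens) polyline by
  trapezoid in descending-threshold order; on uncensored data the AUC
  reduces exactly (1e-10) to the Mann–Whitney statistic of cases vs
  controls. Conditional KM curves within marker strata use right-continuous
  steps.
- **Classification** is strict: score > cutoff is high risk; equality is
  low.
- **Report tables** render floats at 10 significant digits; expression
  round-trip files at 17 (full double precision). Pipeline reruns with the
  same config and seed are byte-identical.

## Scaling of stochastic test suites

Stochastic acceptance suites (signal recovery, null calibration,
rank-invariance) run at the sizes stated above (20 seeds where a rate over
seeds is asserted). A few per-module property tests run the end-to-end
pipeline at 5–10 seeds with smaller cohorts to keep the default test run
fast; the assertions are unchanged, only the repetition count differs.

## Known limitations

- The univariate screen ignores correlation between pairs sharing a gene;
  its candidate set is marginal, as in the original procedure.
- The LASSO path is fit by coordinate descent (glmnet); coefficients at
  near-zero penalty agree with the unpenalized Newton fit to ~1e-4, which
  bounds the numerical agreement one should expect between the two routes.
- KM-conditioned ROC estimates are not guaranteed monotone in the
  threshold under heavy censoring; the signed trapezoid handles small
  non-monotonicities but confidence bands are out of scope.
- The Fisher test is the standard two-sided exact test. Published
  contingency p-values generated by chi-square approximations will differ
  from it at moderate sample sizes (the package's acceptance tests document
  one such discrepancy rather than silently switching tests).
- TMB uses a fixed exome denominator; per-sample capture sizes, when known,
  can be passed by calling `compute_tmb` per stratum.
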