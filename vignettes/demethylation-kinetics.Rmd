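---
title: "Methods: serial demethylation kinetics, the random-set null, and methylome–transcriptome integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial demethylation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery: the
models and their assumptions, the tunable parameters and their defaults, what
the synthetic cohort generator does and does not emulate, the numerical
choices made at genuinely open design points, and the known limitations.

## The measurement scale

A 450K-style array reports, per CpG and sample, a methylated fraction
β ∈ [0, 1]. Testing happens on the m-value scale, m = log2(β/(1−β)), which
decompresses the boundary regions where β differences are floored. Because
synthetic (and occasionally normalized) data can contain exact 0/1, β is
clamped into [ε, 1−ε] before the logit; the default ε = 0.001 maps β = 1 to
m ≈ 9.97 and perturbs any β in (ε, 1−ε) not at all. Effect sizes and call
thresholds, in contrast, stay on the β scale (Δβ), where they have a direct
biological reading: Δβ = −0.1 is ten percentage points of demethylation.

CpGs on chrX/chrY (sex-confounded) and CpGs on known SNPs (genotype, not
methylation, signal) are removed before any analysis. Coordinates are
1-based; the nearest gene is the one whose TSS is closest in absolute base
pairs on the same chromosome, with the signed distance `position − tss`
(strand is not used); exact ties resolve to the lexicographically smallest
gene id, which is deterministic and input-order-independent. A CpG may carry
several region categories (as on array manifests); `intergenic` is
exclusive.

## Paired moderated testing

The design is serial and matched — each patient is their own day-0 control —
so the group-level contrast is a one-sample test on per-patient differences
d_i = m(t1) − m(t0). With tens of patients at best and ~10⁴–10⁵ CpGs, the
per-CpG variance estimates are noisy; the package therefore shrinks them
with the standard empirical-Bayes scaled-F model: s² ~ s₀²·F(d, d₀), with
hyperparameters (d₀, s₀²) estimated by method-of-moments on log s² (mean and
variance matched through digamma/trigamma; the trigamma equation is solved
by a monotone Newton iteration). The posterior variance
s̃² = (d₀s₀² + d·s²)/(d₀ + d) yields t̃ = mean(d)/(s̃/√n) on d + d₀ df.

Numerical corner cases:

* If the log-variance dispersion does not exceed the χ² sampling floor
  (trigamma(d/2)), the moment equation has no positive solution; the fit
  degrades to the fully pooled variance (d₀ = ∞) with a warning. This is
  expected on data whose per-feature variances are genuinely homogeneous,
  e.g. the generator's expression matrices.
* `prior_df = 0` bypasses shrinkage and reproduces the ordinary paired t
  exactly — used by the test suite as a closed-form anchor.
* Zero-variance features are excluded from hyperparameter estimation and
  receive the prior-only posterior; an all-zero feature gets t = 0, p = 1.
  If *every* feature is zero-variance there is nothing to pool and the fit
  refuses.

Significance is BH-adjusted (`stats::p.adjust`); a demethylation call
requires adj-p < 0.05 **and** Δβ < −0.1, both strict, per the "below
0.05"/"above 0.1" convention; remethylation is the mirror image (Δβ >
+0.1). Both thresholds are arguments. An unpaired variant is not provided:
with matched serial samples the paired formulation dominates, and the
per-patient single-sample sets (below) provide the patient-resolution view.

Per-patient "single-sample" call sets use the raw per-patient difference
β(t1) − β(t0) < −0.1 only. A single pair has no variance estimate, so no
per-patient p-value is attached; the burden counts feed the magnitude
classes (strong > 100,000 / limited < 25,000 CpGs on the full array,
strict inequalities, scaled proportionally for smaller universes).

## The random-set null for common demethylation

The question "is the demethylation shared across patients non-random?" is
answered by intersecting the per-patient call sets (optionally also
requiring group-wise significance; requiring presence in *all* patients is
the default, `min_fraction = 1`) and comparing the intersection size with a
resampled null: per iteration, each patient receives a uniform random CpG
set of *their own observed call-set size*, and the across-patient
intersection is recorded. This is the minimal null that preserves each
patient's call burden while destroying shared structure. A simpler variant
(every patient at the mean size) is available behind `mode = "single_set"`
for comparison.

The tail probability is parametric: a normal fit to the null counts,
p = 1 − Φ((obs − mean)/sd). An empirical rank p cannot go below 1/1000 at
1000 iterations, while genuinely shared signatures sit astronomically far
above the null; the normal tail makes that resolvable. When the null is
degenerate (all counts equal, typically all zero), the p is 0 or 1 by the
side of the mean, with a `degenerate` flag — with ≥ 10 patients the null
intersection of large random sets is essentially always empty, so a planted
signature produces obs ≫ 0 against a zero null, and the flagged p = 0 is
the honest summary.

**Conditioning matters for remethylation.** Rebound calls are only possible
among a patient's day-8 demethylated CpGs. If the null drew random sets
from the whole array, any *shared day-8* structure (the signature is in
every patient's day-8 set, and each patient independently rebounds about
half of it) would inflate the observed common-rebound count relative to a
null that essentially never intersects — shared demethylation would
masquerade as non-random remethylation. The remethylation null therefore
draws each patient's random sets from that patient's own day-8 set
(`per_patient_universes`), under which independently drawn rebounds are
correctly non-significant.

## Quantifying the day-15 rebound

"At least partially remethylated" is operationalised per patient as
β(d15) − β(d8) > +0.05 within that patient's day-8 demethylated set. Two
deliberate choices:

* **Threshold 0.05, not 0.1.** A CpG whose entire day-8 deficit is barely
  above 0.1 can never rebound by more than ~0.1, so a full-sized threshold
  structurally under-counts *partial* rebound; half the call threshold
  registers it. The threshold is an argument (`partial_delta` in the
  pipeline) for users who prefer the stricter reading.
* **An empirical noise floor is subtracted.** A lenient threshold admits
  measurement-noise crossings. Read noise is symmetric while rebound only
  shifts β upward, so the rate of opposite-direction crossings
  (β(d15) − β(d8) < −0.05) within the same day-8 sets estimates the
  false-rebound rate; `fraction_remethylated` is the threshold-crossing
  rate minus this mirror estimate (floored at 0), and the uncorrected rate
  is reported alongside as `fraction_called`. On simulated cohorts the raw
  rate at threshold 0.05 carries roughly a +0.04 bias that the correction
  removes; with no rebound at all it reads ~0.08 raw and ~0 corrected.

A group-wise mode (significant positive d15-vs-d8 calls intersected with a
group-level day-8 set) is available; note that when rebound is independent
per patient, a CpG rebounding in half the patients has a group-mean rebound
of about half the per-patient rebound, so the group-wise route is
conservative by construction for partial, patient-independent rebound.

## Cycle concordance

Two complementary views: (i) overlap of the group-wise call sets of cycles
1 and 2, with the recurrence fraction |A∩B|/|A|; (ii) recurrence of the
cycle-1 signature among CpGs demethylated in *every* cycle-2 patient —
deliberately the same per-patient-intersection construction as the
signature itself. The second is the reported "signature recurrence": with
few cycle-2 patients and only ~10² true positives among ~2×10⁴ CpGs, the
group-wise route is limited by the BH cutoff (≈ 0.05·k/m, which sits at the
raw-p floor reachable with ~5 residual df) rather than by effect sizes, so
it under-reports recurrence for reasons of multiplicity, not biology.
Per-patient signature enrichment in cycle 2 uses a one-sided Fisher test on
the 2×2 classification (in signature × called in this sample) over the
universe, with the conventional star coding (p < 0.001 = `***`).

## Methylome–transcriptome integration

Expression arrays are collapsed probe→gene by keeping the probe with the
highest across-sample IQR (ties: lexicographically smallest probe id).
Gene-level paired differential expression reuses the moderated machinery on
log2 intensities. Per gene, promoter β is the unweighted mean over CpGs in
{TSS1500, TSS200, 5'UTR} and body β over {1stExon, ExonBnd, Body, 3'UTR};
CpGs carrying categories from both groups contribute to both; a gene with
no CpG in a region is absent from that region's screen rather than
imputed 0.

The anti-correlation screen works at patient resolution: for each gene and
region, x = per-patient log2 fold change, y = per-patient region Δβ,
ρ = Spearman with average ranks. "The p-value from the normal distribution"
is interpreted as the Fisher z normal approximation,
z = atanh(ρ)·√(n−3) with ρ clamped to ±(1−10⁻¹²), one-sided lower tail for
anti-correlation; a call additionally requires ρ < 0, and a two-sided
option exists. Zero-variance vectors leave ρ undefined — flagged, never
called. Promoter and body screens run and are reported separately. The
screen is performed on raw p (per the "selected the ones below 0.05"
convention), so among truly null genes it calls ≈ α of them; it controls
the per-gene false-positive rate, not the FDR of the call list — with many
null genes the call list necessarily contains ≈ α·(number of null genes)
false members, which is why the test suite's "false-call" check is a
false-positive-rate bound on non-planted genes rather than an FDR bound.

Context enrichment of a CpG set against its universe runs one two-sided
Fisher test per category (8 region categories, 4 island classes, repeat
overlap; multi-category CpGs count once per category — marginal tests, not
a partition) with BH across the 13 tests.

## The synthetic cohort generator

The generator emulates the *statistical structure* the analyses assume, at
desk scale, with a ground-truth record; it does not emulate array
chemistry, genotype effects or clonal evolution, and it is not fitted to
any deposited dataset.

Defaults (all `cohort_config()` arguments; chosen once as field-plausible
study conditions): 20,000 CpGs (≈ 4% of them chrX/Y or SNP-flagged, to
exercise filtering), 2,000 genes, 12 blast patients with cycle-1 days
0/8/15, 4 of them with cycle-2 days 0/8, 8 T-cell patients with days 0/8,
gene-level expression at days 0/8.

* **Baseline methylome:** two-mode mixture, modes β = 0.9/0.1 with
  hyper-mode weight 0.75 and Beta-concentration 50 — reproduces the ~0.9
  cohort median of blast methylomes.
* **Day-8 effects:** a 100-CpG signature at Δβ = −0.3 in *all* blast
  patients in both cycles, selected among heavily methylated CpGs with
  multiplicative preference for open-sea (×3), repeat (×3) and intergenic
  (×2) contexts; plus per-patient background demethylation of a uniform
  fraction r_i ~ U(0.02, 0.35) of CpGs (the desk-scale analogue of per-
  patient burdens spanning two orders of magnitude) at Δβ = −0.3, with
  selection weight proportional to baseline β so heavily methylated CpGs
  are hit preferentially.
* **Day 15:** exactly `remethylation_fraction` (default 0.5) of each
  patient's truly demethylated CpGs, drawn independently per patient,
  rebound by a uniform U(0.3, 1.0) fraction of their day-8 deficit.
* **T cells:** an independent baseline methylome and per-patient uniform
  (unweighted, structure-free) demethylation of 0.3% of CpGs.
* **Expression:** 50 anti-correlated genes whose per-patient promoter Δβ
  scales with the patient's global demethylation propensity
  (−0.35 · r_i/max(r) · gene-sensitivity U(0.7, 1.3), small jitter) and
  whose log2 fold change is −4 × Δβ plus N(0, 0.3) noise; all other genes
  are pure noise. Tying the planted promoter effect to r_i gives the
  patient-level spread a rank correlation needs while keeping weakly
  responding patients near Δβ ≈ 0, so planted promoters do not join the
  all-patient common set.
* **Measurement noise:** each emitted β is redrawn from a Beta distribution
  centred on the latent value with concentration 300 (sd ≈ 0.02 at β = 0.9,
  ≈ 0.03 at β = 0.5) — array-replicate-like dispersion that stays in [0, 1]
  without clipping artifacts. No quantitative noise model is claimed to
  match any particular instrument.
* **Design metadata:** half the patients are labelled responders; response
  carries *no* methylation effect, matching the in-vivo observation that
  demethylation degree did not separate response groups. Note that with
  only ~6 patients per group, chance imbalance in per-patient burdens can
  still produce nonempty 80/20 screens.

Reproducibility: one master seed, with one derived stream per logical
component (layout/baseline, blast effects, remethylation, T cells, read
noise, expression), so perturbing one component leaves the others'
draws unchanged. Identical config + seed ⇒ bit-identical output.

What passing tests on this generator does **not** show: robustness to
batch/plate effects, probe cross-reactivity, inter-patient baseline
methylome differences (the latent baseline is shared across patients; only
noise and effects differ), cell-composition drift between timepoints, or
any real-data normalization issue — those live upstream of this package's
scope (raw-array processing is out of scope by design).

## Problem sizes used by the test suite

Unit tests run on toy fixtures and small cohorts (≈ 3,000–5,000 CpGs, 6–8
patients). The statistical acceptance checks use: the full default cohort
(20,000 CpGs, 12 patients) for signature detection, the T-cell contrast and
cycle concordance; 20 cohorts of 5,000 CpGs / 8 patients with no planted
structure for null calibration; 20 cohorts of 6,000 CpGs / 8 patients for
rebound recovery; and 10 cohorts of 12,000 CpGs / 2,000 genes / 23 patients
for the anti-correlation screen (23 patients and the slope/noise settings
being the stated study conditions for that analysis). These sizes are the
package's chosen simulation scale; all scale-free quantities they estimate
(recall, calibration, recovered fractions) are size-stable well below the
full-array scale.

## Known limitations

* The moderated model assumes exchangeable per-CpG variances after the
  scaled-F prior; strong variance strata (e.g. probe-type mixtures on real
  arrays) would call for stratified priors.
* The normal tail of the resampling null extrapolates far beyond the 1000
  simulated counts; for observed counts *inside* the null range the
  empirical rank would be the safer statement.
* The Fisher-z p for Spearman's ρ is an approximation whose accuracy decays
  below n ≈ 10; the screen refuses n < 5 outright.
* Single-sample calls have no per-patient error control; they are burden
  descriptors and set-builders, not tests.
* The rebound noise-floor correction assumes symmetric read noise and
  strictly non-negative rebound shifts; systematic day-15 drift would bias
  it.
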