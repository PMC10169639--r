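# demkin

Analysis of serial in-vivo DNA demethylation kinetics in AML blasts under
hypomethylating-agent (decitabine) treatment.

Decitabine depletes DNA methylation in dividing cells. In patients, purified
blood blasts sampled at day 0, day 8 and day 15 of a treatment cycle show
massive but highly patient-variable demethylation at day 8 and a partial
methylation rebound by day 15. The scientific questions this package
operationalises are: is any of that demethylation *non-random* — a common CpG
signature hit in every patient, recurring across treatment cycles — or is it
all stochastic collateral of replication without maintenance methylation? Do
bystander T cells, which divide slowly, escape it? And does promoter
demethylation actually induce the corresponding transcripts?

`demkin` is aimed at analysts working with Illumina 450K-style beta-value
matrices plus matched expression arrays from serial designs. It is
tidyverse-native: matrices are tibbles (`cpg_id`/`feature_id` first column,
one column per sample), every analysis returns a tibble or an object with
`tidy()`/`glance()`/`autoplot()` methods, and a synthetic cohort generator
with a ground-truth record makes the whole pipeline testable end to end
without patient data.

## The statistics at the core

* **Paired moderated differential methylation.** Beta values are mapped to
  m-values, m = log2(β/(1−β)) (β clamped to [ε, 1−ε], ε = 0.001). For each
  CpG the per-patient paired differences d_i = m(t1) − m(t0) are tested with
  a one-sample empirical-Bayes moderated t: per-CpG variances s² are shrunk
  towards a prior s₀² fitted by method-of-moments on log s² (scaled-F model),
  giving the posterior s̃² = (d₀·s₀² + d·s²)/(d₀ + d), t̃ = mean(d)/(s̃/√n)
  on d + d₀ degrees of freedom. With the prior df forced to 0 this is
  exactly the ordinary paired t. Calls require BH-adjusted p < 0.05 **and**
  Δβ < −0.1 (both strict; thresholds are arguments).
* **Random-CpG-set resampling null.** The commonly demethylated set (CpGs in
  every patient's single-sample call set and group-wise significant) is
  compared against 1000 random draws in which each patient receives a
  uniform random CpG set of their observed call-set size; the intersection
  counts form the null, and the upper-tail p comes from a normal fit to it —
  the parametric tail is what lets p-values far below 1/1000 be resolved.
* **Cycle concordance and per-sample enrichment.** Overlap of group-wise
  call sets across cycles, recurrence of the signature among CpGs
  demethylated in every cycle-2 patient, and per-patient one-sided Fisher
  tests of signature over-representation.
* **Methylation–expression integration.** Probe-to-gene collapse by highest
  IQR, paired moderated differential expression, per-gene promoter
  (TSS1500/TSS200/5'UTR) and gene-body (1stExon/ExonBnd/Body/3'UTR) mean
  beta, and a gene-wise Spearman screen correlating per-patient promoter Δβ
  with per-patient log2 fold change; anti-correlation p from the Fisher
  z-transform, `p = Φ(atanh(ρ)·√(n−3))`, called at p < 0.05 with ρ < 0.
* **Context enrichment.** Two-sided Fisher tests of a CpG set against the
  array universe over region categories, island status and repeat overlap,
  BH-adjusted.

## Worked example

```r
library(demkin)

cohort <- simulate_cohort(cohort_config(), seed = 7)
beta   <- filter_cpgs(cohort$beta_blast, cohort$annot)   # drop chrX/Y + SNP CpGs

dm <- diff_methylation(beta, cohort$sheet, t1 = "d8", t0 = "d0")
dm
#> Paired differential methylation: d8 vs d0, cycle 1, blast (n = 12 patients)
#>   19400 features; 416 demethylated, 0 remethylated (adj p < 0.05, |delta beta| > 0.1)

sets <- single_sample_delta_sets(beta, cohort$sheet)     # per-patient calls
lengths(sets)[1:6]
#>  P01  P02  P03  P04  P05  P06
#> 1101 6718 3910 3276 2850 6328

sig <- signature_null_test(sets, beta$cpg_id,
                           groupwise_significant = call_demethylated(tidy(dm)),
                           seed = 7)
sig
#> Random-set null (1000 iterations, 12 patients, mode per_patient)
#>   observed common count 101 vs null 0.00 +/- 0.00; upper-tail p = 0 (degenerate null)

cohort_methylation_summary(beta, cohort$sheet)
#> # A tibble: 3 x 3
#>   timepoint n_samples median_beta
#>   <chr>         <int>       <dbl>
#> 1 d0               12       0.886
#> 2 d8               12       0.835
#> 3 d15              12       0.850
```

Reading the output: per-patient demethylation burdens vary several-fold
(1,101–6,718 CpGs) the way patients do in vivo, yet 101 CpGs are demethylated
in *every* patient, while matched random sets essentially never intersect —
the definition of a non-random demethylation signature. Median methylation
dips at day 8 and partially rebounds at day 15. `autoplot(sig)` draws the
null-count density with the observed count;
`plot_demethylation_counts(sets)` gives the per-patient bar chart.

The full orchestration — filtering, both contrasts, the signature null,
remethylation, cycle-2 concordance, the T-cell contrast, the responder
80/20 screen, expression integration and context enrichment, each stage
written as a provenance-stamped TSV plus a JSON manifest — is one call:

```r
run_pipeline(list(simulate = TRUE), out_dir = "out", seed = 7)
```

A thin CLI wrapper lives at `inst/scripts/demkin.R`
(`Rscript demkin.R run --out DIR --seed 7 [--config run.yaml]`).

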