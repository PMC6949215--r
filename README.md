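# cnaconcord

Cross-platform copy-number concordance analysis for SNP arrays and MLPA in
acute lymphoblastic leukaemia (ALL).

## The problem

Risk stratification of B-other ALL increasingly uses copy-number
abnormality (CNA) profiles over eight genes and the PAR1 region (*IKZF1*,
*CDKN2A/B*, *PAX5*, *EBF1*, *ETV6*, *BTG1*, *RB1*, PAR1), originally
defined from MLPA peak ratios. Diagnostic laboratories often run SNP arrays
instead, so the clinical question is whether array-derived calls reproduce
the MLPA-defined profiles — and, when they do not, why. This package
implements that comparison as a tested pipeline:

* **Segmentation** — from-scratch circular binary segmentation (CBS) of
  per-sample Log R Ratio (LRR) vectors. The change-point statistic for an
  arc of probes against its complement is the pooled two-sample *t*
  statistic
  `T(i,j) = |mean(arc) − mean(comp)| / (s·sqrt(1/k + 1/(n−k)))`,
  maximised over all arcs, with significance from a permutation null and
  recursive splitting; a five-marker detection cut-off filters emitted
  events. GC correction is a covariate regression on probe GC fraction.
* **Categorical calling** — LRR thresholds over segment means give
  normal / loss-deletion / gain-amplification gene calls; `focal_rescue()`
  automates the visual LRR review that recovers focal events segmentation
  misses, notably deletions flanking the probe-free "IKZF1 hole".
* **MLPA calling** — peak-ratio thresholds with the ≥2-adjacent-probe
  rule; single-probe genes are callable but flagged.
* **Concordance** — per-gene 2×2 contingency tables, concordance
  percentages, and a five-category discordance taxonomy
  (i: no array probes over the event; ii: single-MLPA-probe evidence;
  iii: segmentation miss rescued from the LRR data; iv: true
  disagreement; v: no MLPA probes over the event).
* **Risk classification** — a configurable rule engine mapping nine-region
  CNA profiles to good / intermediate-poor risk, with distinct-patient
  reclassification counting between calling modes.
* **Synthetic cohorts** — a generator with known truth reproducing the
  coverage geometry (probe holes, probe-free gene interiors, single-probe
  kits, uncovered exons) that drives every discordance category.

The published per-gene contingency tables and the 25 discordant-call
records ship as checksummed fixtures, so the cohort-level arithmetic is
reproducible without the (undeposited) raw patient data.

## Worked example

Table mode recomputes the headline numbers from the packaged fixtures:

```r
library(cnaconcord)
res <- run_from_tables()
str(res$summary)
#> $ total_calls        : int 1287
#> $ discordant_cbs     : int 25
#> $ discordant_manual  : int 16
#> $ concordance_cbs    : List of 2 (raw 98.06, rounded 98)
#> $ concordance_manual : List of 2 (raw 98.76, rounded 99)
#> $ category_counts    : i 5, ii 2, iii 9, iv 6, v 3
#> $ reclassified_manual: int 4
#> $ reclassified_cbs   : int 8
```

1,287 gene-level comparisons across 143 samples; 25 discordant under fully
automated CBS calling (98% concordance), dropping to 16 (99%) when focal
events are rescued from the LRR data; of 25 discordances, 9 are CBS misses
recoverable by LRR review, 8 reflect probe-design differences between
platforms (categories i and v), and risk classification moves 4 patients
(manual calling) or 8 (automated) out of 143.

Data mode runs the same pipeline on synthetic cohorts with known truth:

```r
coh <- generate_cohort(synthetic_cohort_spec(n_samples = 50, seed = 1))
res <- run_cna_pipeline(coh, segmentation_params(nperm = 2000, seed = 2))
pipeline_performance(res, coh)[c("sensitivity", "specificity")]
#> $sensitivity  [1] 1
#> $specificity  [1] 0.997...
```

The failure mode the analysis is about is reproducible deterministically:

```r
d <- ikzf1_hole_demo()
gene_call(cbs_segment(d$profile), d$region, d$probes)$state  # "NORMAL"
focal_rescue(d$profile, d$region)$state                      # "LOSS_DELETION"
call_gene_mlpa(d$mlpa)$state                                 # "LOSS_DELETION"
```

The numbered drivers under `analysis/` (`01_simulate.R` … `04_risk.R`) run
the workflow end to end, writing stage tables under `results/`.

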