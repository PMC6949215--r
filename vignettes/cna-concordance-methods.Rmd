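---
title: "Methods: cross-platform copy-number concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform copy-number concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`cnaconcord` reimplements, as a tested pipeline, a concordance analysis
between two ways of measuring somatic copy-number abnormalities (CNAs) in
B-cell precursor acute lymphoblastic leukaemia: genome-wide SNP-array Log R
Ratio (LRR) data segmented automatically, and the targeted MLPA assay whose
per-exon peak ratios defined the original CNA risk profiles. The unit of
comparison is the per-gene, per-sample categorical call over eight genes and
the PAR1 region (IKZF1, CDKN2A, CDKN2B, PAX5, EBF1, ETV6, BTG1, RB1, PAR1).

The original patient-level array data are not redistributable, so the
package validates its machinery two ways: *table mode* reruns the
tabulation, concordance, discordance-category and risk-reclassification
arithmetic on the published per-gene contingency cells and discordant-call
records (shipped as checksummed CSV fixtures), and *data mode* runs the full
pipeline on synthetic cohorts with known truth from `generate_cohort()`.

## Segmentation model

Segmentation is circular binary segmentation (CBS), written from scratch.
For a probe vector of length $n$, boundaries $0 \le i < j \le n$ define an
arc $x_{i+1..j}$ and its complement; the change-point statistic is the
pooled-variance two-sample $t$ statistic

$$T(i,j) = \frac{|\bar{x}_{arc} - \bar{x}_{comp}|}
               {s\sqrt{1/k + 1/(n-k)}}, \qquad k = j - i,$$

maximised over all arcs. Significance of $T_{\max}$ is assessed against a
permutation reference distribution — the vector is shuffled `nperm` times
and rescanned — with $p = (1 + \#\{T^{perm}_{\max} \ge T_{obs}\})/(nperm+1)$.
Accepted splits (at level `alpha`) are applied recursively to the
sub-vectors. The hybrid/tail approximations that production CBS
implementations use to speed up the permutation step are deliberately
omitted: at per-gene scale the full permutation null is affordable and
exact in distribution. There is no undo/merge step.

Numerical conventions worth knowing:

* An arc and its complement carry the same statistic, so boundary arcs
  $(i, n)$ duplicate $(0, i)$; the scan scores each partition once (the
  canonical $j < n$ parametrization), which makes the lexicographic
  tie-break (smallest $i$, then $j$) well defined in floating point.
* Zero pooled variance returns $T = 0$ when the two group means coincide
  (constant vector) and $+\infty$ for a perfect split — matching the
  limiting behaviour of the $t$ statistic.
* The minimum-marker rule is a *detection cut-off*, not a constraint inside
  the arc search: a significant arc leaving fewer than `min_markers` probes
  on either side of its split is simply not emitted, and any residual short
  segment is merged into the neighbour with the closer mean. A three-probe
  dip in an otherwise flat profile therefore yields one segment, exactly as
  a five-marker detection rule demands.
* One seeded generator per `cbs_segment()` call; permutation draws are
  index shuffles of the working sub-vector, so results are reproducible
  given `seed`.
* `copy_value = baseline_ploidy * 2^mean_lrr` with a diploid default; the
  baseline is configurable but nothing downstream assumes otherwise.

GC correction is an ordinary least-squares regression of LRR on the probe
GC fraction, keeping the residuals re-centred at the input median. A
zero-variance GC vector degenerates the fit; the input is then returned
unchanged with a warning.

## Categorical calling

Thresholds laid over segment means convert segmentation into calls:
`loss_max` (-0.2), `deletion_max` (-0.8), `gain_min` (+0.15), `amp_min`
(+0.7), log2 units, boundaries inclusive toward the abnormal state. The
analysis aggregates loss/deletion and gain/amplification into one direction
each, because no formal threshold separates the members of each pair and
the two assays differ in sensitivity; the sub-states are still reported.
The exact cut-offs are deliberately uninteresting: every cohort-level
number the package reproduces is threshold-free (table mode) or robust to
them (clonal synthetic events sit at full-copy LRR shifts).

A gene's call is the most extreme (by $|\bar{x}|$) non-normal state among
segments that overlap at least one array probe *inside the gene span* and
span at least `min_markers` probes; nested mixed-direction events resolve
to the larger $|\bar{x}|$. Note the probe-inside rule means a gene whose
interior the array never probes (the CDKN2A situation) is structurally
uncallable from the array — that is a design fact of the platform, and it
is what discordance category i describes.

MLPA calls use the kit convention: a probe is abnormal when its peak ratio
crosses `loss_max` 0.75 / `gain_min` 1.3 (`deletion_max` 0.25, `amp_min`
2.0), and a gene is abnormal when at least two *adjacent* kit probes (in
genomic order) agree in direction. Genes represented by a single kit probe
(CDKN2B here) are callable from that probe but flagged
(`single_probe_evidence`), which is what discordance category ii consumes.
The adjacency rule is applied to gains as well as losses; the cited calling
convention does not say whether gains were exempt, and symmetry is the
conservative choice.

## Focal rescue

The source analysis recovered nine segmentation misses by eye from LRR
plots. `focal_rescue()` is an explicit automation of that review, applied
only where segmentation returned NORMAL. It scans maximal runs of
consecutive probes inside the gene span, breaking runs at coverage gaps
wider than `gap_threshold` (default 10 kb — the motivating intra-IKZF1 hole
is ~42 kb), so an event flanking a hole is evaluated on its own side. A
rescue requires:

1. at least `window_k = 4` *consecutive* probes all crossing the same
   categorical threshold (4 sits below the five-marker segmentation
   cut-off and above the single-probe floor — a lone outlier probe,
   however extreme, can never drive a rescue);
2. the median LRR of that run to cross the threshold and to stand clear of
   the probe noise: $|\tilde{x}| \ge z_{\min}\,\hat\sigma/\sqrt{m}$ with
   $z_{\min} = 5$ and $\hat\sigma$ estimated robustly from successive probe
   differences.

The noise guard is the package's own design choice for the genuinely open
question of what "visible by eye" means operationally: a reviewer calls
shifts that are unmistakable against the local scatter, and a five-standard-
error median is that. Without it, a 4-probe window rule at `gain_min` one
noise-SD above baseline fires on a substantial fraction of null profiles;
with it, the false-rescue rate at noise sd 0.15 is below 1% per profile
while clonal single-copy events (LRR shift -1) are untouched. Rescue is
additive by construction: it can only turn NORMAL into abnormal.

## Discordance taxonomy

A pair is concordant when both platforms are NORMAL or both abnormal
(direction-aggregated). Discordant pairs are classified by a cascade,
evaluated in the order i, ii, iii, v, with iv the residual ("disagreed
despite sufficient coverage") — the source defines the categories but not a
precedence, and iv is residual by its own wording:

| category | meaning | decisive evidence |
|---|---|---|
| i | array cannot see the event | 0 array probes in the abnormality interval |
| ii | MLPA rests on one probe | single-probe flag + ≥5 normal array probes there |
| iii | segmentation missed, rescue agrees | automated NORMAL, rescued call concordant with MLPA |
| iv | genuine disagreement | none of the above |
| v | MLPA cannot see the event | 0 kit probes in the array event's segment span |

The abnormality interval for an MLPA-detected event spans its abnormal kit
probes, padded on each side by half the distance to the nearest flanking
kit probe (or to the gene-span boundary for terminal runs); for an
array-detected event it is the supporting segment's span. The ≥5
normal-probe requirement in category ii operationalises "numerous" array
probes and is configurable.

## Risk classification

The CNA risk classifier itself (UKALL-CNA) is configuration, not code: its
published rule content is not reconstructable from the concordance study,
so rules ship as an ordered-JSON rule set (first match wins, explicit
default) and the packaged `example_rules.json` is labelled illustrative.
All reclassification counts the package reproduces use the risk labels
printed in the discordance table, so no invented rules contaminate them.
Counting is per *distinct patient* — the one patient appearing under both
CDKN2A and CDKN2B (plausibly one deletion spanning both) counts once —
and reporting pools IR with PR, as the source cohort's outcomes justified.

## The synthetic generator

`generate_cohort()` emulates the study inputs on a nine-pseudo-chromosome
toy genome (~30-120 array probes per region at 1.5 kb spacing; an MLPA kit
with one probe per covered exon), with the coverage geometry that makes
every discordance category constructible by design: the IKZF1 analogue's
~42 kb intron-3 hole, a CDKN2A analogue with no interior array probes, a
single-kit-probe CDKN2B analogue, EBF1/PAX5 analogues with MLPA-uncovered
exons, and a PAR1 analogue whose recurrent event interval contains no array
probe. Signals follow the standard admixture model: an event of copy change
$\Delta$ in clonal fraction $f$ shifts covered probes by
$\log_2((2 + f\Delta)/2)$ and sets covered MLPA ratios to $(2+f\Delta)/2$,
plus Gaussian noise (LRR sd 0.15; MLPA sd 0.08 — a typical assay
variability, chosen once since the source states none).

Defaults are the study's conditions: 143 samples, clonal events
(`subclonal_prob = 0`; the cohort had >90% blasts), per-region event
frequencies matching the observed abnormality rates. Subclonal admixture is
available for sensitivity studies; at the assay's stated 20%-cell floor a
single-copy deletion shifts LRR by only $\log_2 0.9 \approx -0.152$, inside
the normal band — the package documents and tests that array detection
degrades exactly there, mirroring the platforms' differing sub-clonal
sensitivities.

What the generator does **not** emulate: B-allele frequencies, GC waves
beyond a linear covariate, batch effects, probe-specific variances, or the
correlated noise of real arrays. Passing the synthetic recovery tests
therefore demonstrates the pipeline's logic and calibration, not
performance on real intensity data.

## Validation design and problem sizes

The test suite checks every operation against an independent oracle where
one exists: the arc statistic against `t.test()` over all $O(n^2)$ arcs;
the permutation p-value against the exhaustive 720-permutation null at
$n = 6$; interval queries against brute-force scans; the tabulators against
direct counting. Calibration properties use the study's stated conditions:
a null false-split rate at most $2\alpha$ over 500 replicates of 200-probe
Gaussian profiles, and boundary recovery within ±2 probes for ≥95% of 200
simulated clonal deletions (LRR -1, 15 probes, noise sd 0.15).

Cohort-scale runs (the analysis scripts, the end-to-end recovery check) use
`nperm = 2000` — p-value granularity 1/2001, an order of magnitude below
`alpha = 0.01` — and a 50-sample cohort; the exported default remains the
conventional `nperm = 10000`. Sensitivity is measured over truth events
whose intersection with the gene span contains at least `min_markers` array
probes: events injected into probe-free geometry are invisible to the array
*by design*, are excluded from the detection denominator, and are instead
required to surface as category-i discordances.

## Known limitations

* The probe-inside-span gene-calling rule cannot credit a gene deleted as
  part of a larger event when the array has no probe inside the gene; such
  events are reported as discordance category i rather than as calls.
* Rescue evaluates run medians, so an event occupying less than half of a
  coverage-delimited run can escape it; this is the price of resisting
  outliers and is why rescue complements rather than replaces segmentation.
* Full-permutation CBS is quadratic per scan and linear in `nperm`; it is
  meant for targeted-region analysis, not whole-genome arrays.
* Table mode reconstructs call pairs from per-gene cells; patient identity
  across genes is not printed in the source tables, so pseudo-sample
  alignment is arbitrary (it provably does not affect any reproduced
  count, all of which are per-gene or taken from the per-patient records).
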