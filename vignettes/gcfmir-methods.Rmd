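---
title: "Methods: two-stage Cq analysis for biofluid miRNA panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage Cq analysis for biofluid miRNA panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcfmir)
```

## The measurement and its assumptions

A PCR miRNA panel reports, per miRNA $i$ and sample $s$, the quantitation
cycle $Cq_{is}$ at which amplification crosses threshold; each cycle is a
doubling, so $Cq$ is $-\log_2$ abundance up to an assay-specific constant.
Three assumptions shape everything downstream:

1. **Right-censoring at 40 cycles.** An assay that has not crossed
   threshold by cycle 40 carries no usable quantity. We mark it
   *undetected* and carry a detection mask beside the matrix; we never
   impute a Cq of 40, because a censored value is a bound, not a
   measurement. A value of exactly 40.0 counts as undetected (the
   threshold is configurable via `censor_at`).
2. **Additive per-sample offsets.** Unequal input amounts shift a whole
   sample's Cq column by a constant $o_s$. Both normalizations below are
   exactly invariant to such shifts (tested to $10^{-9}$).
3. **Additive group effects on the Cq scale.** A disease effect of
   $\delta$ cycles is multiplicative ($2^{\delta}$-fold) on abundance,
   which is the $\Delta\Delta Cq$ logic.

## Normalization: two stages, two estimators of $o_s$

**Global mean (discovery).** With hundreds of assays per sample the mean
Cq of a sample is a stable estimator of its offset:
$\Delta Cq_{is} = Cq_{is} - \overline{Cq}_{\cdot s}$, the mean taken over
that sample's own detected miRNAs. A stricter variant
(`common_only = TRUE`) restricts the mean to miRNAs detected in every
sample; the default follows the per-sample definition because detection
dropout in biofluid panels is informative and the per-sample mean is the
field's standard. The global mean is *not* appropriate for a 40-assay
validation panel, where the panel composition (mostly regulated miRNAs)
would bias the offset estimate — hence stage two.

**Multi-reference (validation).**
$\Delta Cq_{is} = Cq_{is} - r_s$ with $r_s$ the mean Cq of a fixed
reference set in sample $s$; by construction the reference average of
$\Delta Cq$ is zero in every sample. Every sample must detect every
reference; a missing reference is a hard error rather than a silent
average over fewer probes, because that would re-introduce a per-sample
bias.

**Reference selection.** The stability measure is the geNorm pairwise
scheme: for candidates $j, k$ let $V_{jk} = \mathrm{SD}_s(Cq_{js} -
Cq_{ks})$ (sample SD, $n-1$ denominator); a candidate's stability is
$M_j = \mathrm{mean}_{k \ne j} V_{jk}$, low $M$ = stable. The largest-$M$
candidate is removed and all $M$ recomputed, until $k = 5$ remain (five
references being the panel convention this pipeline targets). Because
$V_{jk}$ never changes as the candidate set shrinks, the implementation
precomputes the pairwise-SD matrix once via
$V_{jk}^2 = \sigma^2_j + \sigma^2_k - 2\sigma_{jk}$ and maintains running
row sums — $O(n^2)$ overall; the test suite proves equality with a
literal brute force that recomputes every $M$ at every step. Candidates
are miRNAs detected in *all* samples (no imputation). Ties at the maximum
are resolved by removing the lexicographically last canonical name, so
results are deterministic. $M$ is invariant to per-sample shifts, so
ranking on raw Cq or on $\Delta Cq$ is identical (also tested).

## Differential statistics

Effects are $\Delta\Delta Cq = \overline{\Delta Cq}_{perio} -
\overline{\Delta Cq}_{healthy}$, available-case over detected values; the
reported/plotted quantity is $-\Delta\Delta Cq$, positive when
up-regulated in disease. The subtraction order (periodontitis − healthy)
is fixed. Tests are two-sided two-sample $t$; Welch is the default
because equal group variances cannot be assumed between health and
disease, with Student available (`variant = "student"`). A miRNA with
fewer than 2 detected values in a group is reported descriptively (effect
only, no $p/q$). Zero variance in both groups with equal means is not
testable (`NA`); with unequal means the limiting $p = 0$ is reported with
a warning. Multiplicity is controlled by Benjamini–Hochberg over all
tested miRNAs; the step-up $q$ is implemented directly and tested against
both a literal $O(n^2)$ oracle of the definition and `stats::p.adjust`.
Candidate selection uses strict inequalities, $q < 0.05$ and
$|\Delta\Delta Cq| > 1.0$ (one cycle = two-fold), so boundary records are
excluded.

## Concordance between sample sets

Reproducibility across the discovery and validation cohorts is judged by
(a) per-miRNA sign agreement of $-\Delta\Delta Cq$ (a zero effect
disagrees with any nonzero sign and is tallied separately; miRNAs absent
from either table are excluded from the denominator) and (b) Spearman
correlation of the paired $-\Delta\Delta Cq$ vectors, computed as Pearson
on average ranks, with no attached $p$ value — a rank correlation on ~40
points is descriptive here. Matched-pair comparisons use the single-pair
analogue $\Delta Cq_{healthy} - \Delta Cq_{perio}$. List overlaps are
exact-name set algebra after canonicalization (lower-case, `hsa-`
prefix); star names (`miR-205*`) are matched only verbatim, because
cross-platform synonym mapping is a curation problem, not an algorithmic
one — callers supply their own synonym maps if needed.

## The synthetic generator: what it emulates, what it does not

`generate_cq_dataset()` draws
$Cq_{is} = B_i + o_s + \beta_i \mathbb{1}[s \in perio] + \varepsilon_{is}$,
then censors at 40. Defaults are the stated world of the validation-scale
experiments: 600 assays, 6 vs 6 subjects, baselines $B_i \sim U(20, 37)$
(so a tail of assays sits near the detection limit and missing-data paths
are exercised), loading offsets $o_s \sim N(0, 1)$ (about a two-fold
loading spread, typical of strip-collected GCF), replicate noise
$\sigma_\varepsilon = 0.5$ cycles, effects of 2 cycles on 20 up- and 20
down-regulated miRNAs, and 5 designed references with zero effect and
reduced noise (0.1 cycles), their baselines drawn from the middle half of
the range so they are never censored.

`effect_cycles` may also be a range $(low, high)$, giving per-miRNA
magnitudes drawn uniformly: real biomarker panels are heterogeneous, and
a rank correlation between two cohorts is only informative when effect
sizes vary. With a single magnitude, ranks within the up and the down
cluster are pure noise and the between-set Spearman $\rho$ is capped near
$100/133.25 \approx 0.75$ for a 40-miRNA panel regardless of noise level —
the cross-set concordance experiment therefore uses magnitudes on
$(1, 4)$ cycles, chosen once from the spread seen in validated panels.
Passing a previous run's `truth` reuses its baselines, spiked assignments
and effects while drawing fresh subjects, offsets and noise: two such
runs are independent sample sets from the same truth, the
discovery/validation situation.

The generator does **not** emulate: amplification-efficiency differences,
plate effects, correlated miRNA co-expression, or heavy-tailed noise. A
green recovery test therefore establishes that the pipeline's arithmetic
and decision rules are correct under the additive-Gaussian-censored
model, not that the thresholds are optimal for any particular real
cohort.

## Numerical and design choices

* Undetected = mask + `NA`, end to end; statistics are available-case.
* Detection filter: a miRNA is analyzable if detected in $\ge 1$ sample
  of *each* group; the filter is idempotent.
* PCA (`pca_samples`): samples as observations on mean-centered
  $-\Delta Cq$ of complete-case miRNAs only — imputation would
  manufacture cluster structure; the variance fractions come from the SVD.
* Clustering (`hierarchical_heatmap`): Euclidean distance, average
  linkage, no row scaling (colors are $-\Delta Cq$ directly); all-missing
  rows are dropped with a warning; `stats::dist` handles missing cells
  pairwise.
* Determinism: every simulated path is seeded; `run_pipeline` writes no
  timestamps, so identical config + seed gives byte-identical outputs.
* Orientation is never guessed: rows are miRNAs, with an explicit
  `transpose` flag.

## Known limitations

* No inter-plate calibration or efficiency correction; Cq values are
  assumed comparable across samples after offset removal.
* BH assumes independence/PRDS across miRNAs; global-mean normalization
  induces weak negative correlation (each value contains $-1/n$ of every
  other), negligible at panel scale but real.
* NormFinder/BestKeeper-style model-based reference selection is not
  implemented; the stability ranking is the pairwise scheme only.
* The cohort-metadata summary reproduces printed demographics; it is not
  a statistical comparison of cohorts.
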