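# gcfmir

Two-stage qPCR miRNA panel analysis for gingival crevicular fluid (GCF)
and other low-input biofluids.

## The problem

GCF — the exudate collected with paper strips from the gingival sulcus —
carries extracellular miRNAs whose levels shift in periodontitis, making it
an attractive non-invasive biomarker source. Profiling it with PCR panels
yields a matrix of quantitation cycles Cq(i, s) per miRNA *i* and sample
*s*, with three recurring complications:

* **censoring** — amplifications that do not cross threshold by cycle 40
  are discarded as undetected, not imputed;
* **loading variation** — per-sample offsets from unequal input amounts
  must be removed before groups can be compared;
* **two stages** — a dense discovery panel (hundreds of assays) is
  normalized to each sample's global mean Cq, while a small validation
  panel re-measuring the selected candidates needs a fixed set of stable
  reference miRNAs instead.

`gcfmir` implements this workflow end to end, with a seeded synthetic-data
generator so every stage is testable without any download.

## The model

* **Normalization.** Discovery: ΔCq(i, s) = Cq(i, s) − mean over the
  sample's detected Cq (global-mean normalization). Validation:
  ΔCq(i, s) = Cq(i, s) − r_s with r_s the mean Cq of the reference probes
  in sample *s*, so the reference average is identical across samples.
* **Reference selection.** geNorm-style pairwise stability: a candidate's
  M value is the mean, over other candidates *k*, of SD_s(Cq_j − Cq_k);
  the largest-M candidate is iteratively excluded until *k* = 5 remain.
* **Differential expression.** Per miRNA, ΔΔCq = mean ΔCq(periodontitis) −
  mean ΔCq(healthy); the plotted effect is −ΔΔCq (positive = up-regulated,
  since lower Cq means higher abundance). Two-sided Welch (or Student) *t*
  on detected ΔCq values, Benjamini–Hochberg FDR *q* values, candidates at
  *q* < 0.05 and |ΔΔCq| > 1.0 (strict).
* **Concordance.** Per-miRNA direction agreement between sample sets and
  Spearman rank correlation (average-rank ties) of the paired −ΔΔCq
  values; matched-pair differences; exact-name list overlaps.

## Worked example

```r
library(gcfmir)

sim  <- generate_cq_dataset(sim_config(seed = 20))   # 600 miRNAs, 6 vs 6
filt <- filter_detected(sim$table, sim$sheet)        # detected in both groups
rk   <- rank_stability(filt, k = 5)                  # stability-ranked refs
rk
#> <stability_ranking>
#>   selected: hsa-mir-sim-0003, hsa-mir-sim-0005, hsa-mir-sim-0001, hsa-mir-sim-0004, hsa-mir-sim-0002
#>   M range 0.127-1.532 over 597 candidates

norm <- multi_reference_normalize(filt, rk$selected_references)
tab  <- diff_exp(norm, sim$sheet)                    # Welch t + BH q
head(as.data.frame(tab)[, c("mirna_id", "neg_ddcq", "q_value", "direction")], 3)
#>           mirna_id  neg_ddcq      q_value direction
#> 1 hsa-miR-sim-0006  2.550176 5.931357e-05        up
#> 2 hsa-miR-sim-0030 -2.045398 5.931357e-05      down
#> 3 hsa-miR-sim-0038 -2.670499 7.082534e-05      down

cand <- select_candidates(tab)                       # q < 0.05, |ΔΔCq| > 1
str(score_recovery(sim$truth, cand$up, cand$down, refs = rk$selected_references))
#> List of 7
#>  $ up_sensitivity  : num 0.95
#>  $ up_precision    : num 1
#>  $ down_sensitivity: num 0.9
#>  $ down_precision  : num 1
#>  $ n_false_up      : int 0
#>  $ n_false_down    : int 0
#>  $ refs_recovered  : int 5
```

The five designed reference probes are recovered exactly; 37 of 40 spiked
miRNAs pass the selection thresholds with no false positives, and the
selected effects sit near their true ±2-cycle magnitudes.

A full two-stage run (discovery → candidate panel → validation →
concordance report, with CSV/JSON outputs and provenance) is one call:

```r
res <- run_pipeline(pipeline_config(
  discovery  = list(sim = list(n_mirna = 600)),
  validation = list(sim = list(n_mirna = 600)),
  seed = 1, out_dir = "run1"))
```

A command-line interface with subcommands `simulate`, `normalize`,
`select-refs`, `diff`, `concord`, `overlap` and `run` is exposed via
`gcfmir_main()` (wrapper script in `inst/cli/gcfmir.R`).

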