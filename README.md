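# dtubench

Benchmarking differential transcript usage (DTU) detection with
counting-bin models, entirely on synthetic data with known truth.

## The problem

Most multi-exon genes express several isoforms, and many biological
contrasts change the *proportions* of those isoforms without changing
the gene's total output. Detecting this — differential transcript
usage — from short-read RNA-seq is commonly done indirectly: the
catalog is cut into *counting bins*, fragments are counted per bin,
and each bin is tested for a change in its usage relative to the rest
of its gene. How well this works depends heavily on how the bins are
defined (sub-exonic bins, whole exons, junctions, or the transcripts
themselves), on how overlapping genes are handled, and on how bloated
the catalog is with unexpressed isoforms.

`dtubench` is a workbench for measuring those effects. It is aimed at
methodologists and pipeline builders who want controlled, reproducible
answers: it simulates two-condition RNA-seq experiments where the
truth is known, builds the competing bin representations from one
catalog, runs a shared inference engine, and reports stratified
TPR/FDR.

## What it implements

* **Synthetic data** — genes with realistic exon/isoform structure in
  two regimes (`fruitfly_like`: few isoforms, long exons;
  `human_like`: many isoforms, short exons); gene counts
  `NB(mu, phi)` with `phi = a0 + a1/mu`; per-sample isoform fractions
  `Dirichlet(100 * pi)`; 5% non-specific background; paired 101-bp
  reads projected through exon structures as coordinate blocks. DTU
  is planted in genes with at least two expressed isoforms (fraction
  > 10%) and expected count > 500 by swapping the two most abundant
  isoform fractions in condition 2 — no gene-level differential
  expression, by construction.
* **Counting bins** — flattened disjoint bins with three treatments
  of overlapping genes (aggregate into `+`-complexes, exclude shared
  parts same-strand, exclude both strands); original exons
  (multi-assigned); splice junctions (exact-match counting);
  transcript bins via equivalence classes and an abundance EM.
* **Inference** — per bin, "this bin vs the rest of the gene" NB GLM
  (log link, median-of-ratios offsets, design
  `sample + part + condition:part`), Cox-Reid dispersion estimation
  with trend shrinkage, 1-df likelihood-ratio test, independent
  filtering, and gene-level q-values via the Sidak family bound
  `1 - (1 - min p)^n` + Benjamini-Hochberg.
* **Evaluation** — TPR/FDR at q-thresholds 0.01/0.05/0.1, strata by
  isoform count, isoform dominance and expression; isoform
  prefiltering (drop isoforms below 5-25% in both conditions) and
  annotation degradation (remove 20% of transcripts) arms.

## A worked example

```r
library(dtubench)
p   <- sim_params(n_genes = 40, library_size = 4e4, n_dtu = 8, seed = 3)
sim <- simulate_experiment(p)
cm  <- count_flat_or_exon(
  dtubench:::combine_fragments(sim$fragments),
  flatten(sim$annotation, "exclude_same_strand"))
fit <- dtu_test(cm, sim$samples$condition)
fit
#> Differential bin-usage test (bin-vs-rest NB GLM)
#>   bins: 220 total, 1 filtered out, 219 tested
#>   features with a q-value: 40
#>   q <= 0.05: 5 features
performance(match_truth(fit, sim$truth))
#>   stratum threshold TP FP TN FN   TPR FDR  n n_ds
#> 1    <NA>      0.01  5  0 32  3 0.625   0 40    8
#> 2    <NA>      0.05  5  0 32  3 0.625   0 40    8
#> 3    <NA>      0.10  5  0 32  3 0.625   0 40    8
```

Of the 8 genes with a planted isoform switch, 5 are recovered at every
threshold with no false positives; the 3 misses are small-effect or
low-count switches. `run_study(dtu_config(...))` runs the full grid
(counting variants x prefilter thresholds x catalog completeness) with
plain-file handoff between stages and a merged `performance.tsv`.

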