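---
title: "Benchmarking differential transcript usage with counting-bin models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking differential transcript usage with counting-bin models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# The problem

Differential transcript usage (DTU) is a change, between experimental
conditions, in the *relative proportions* of the isoforms a gene
expresses, irrespective of the gene's total output. A widely used way
to detect it from short-read RNA-seq is indirect: divide the genome
(or the transcriptome) into *counting bins*, count the fragments
assigned to each bin, and test each bin for a change in its usage
relative to the rest of its gene. `dtubench` packages that whole
workflow as a controlled experiment: a synthetic-data generator with
known DTU, several counting-bin constructions, a bin-versus-rest
negative binomial (NB) GLM test, and a stratified TPR/FDR evaluation,
so that the operating characteristics of the counting choices can be
measured rather than guessed.

# The synthetic experiment

`sim_params()` fixes the study conditions. Two conditions with three
biological replicates each are simulated. Structural regimes emulate
two kinds of transcriptomes: `fruitfly_like` (mostly 2-3 isoforms per
gene, long exons, short introns) and `human_like` (up to a dozen
isoforms, short exons). The numerical values of those structural
distributions (log-normal exon/intron lengths, isoform-count weights)
are package choices tuned to the qualitative contrast between a simple
and a complex transcriptome, not estimates of any particular genome.

Expression follows a hierarchical model:

* Per gene, a baseline expected count $\mu_g$ is drawn from a
  long-tailed log-normal and rescaled so that the expected counts sum
  to `library_size * (1 - background_fraction)`; the default
  background share of non-specific fragments is 5%.
* A dispersion $\phi_g$ follows the mean-dispersion trend
  $\phi = a_0 + a_1/\mu$ (defaults $a_0 = 0.01$, $a_1 = 3$, log-normal
  jitter sd 0.3). The trend's form mirrors what is routinely estimated
  from real RNA-seq; the coefficients are package defaults exposed in
  the configuration.
* Baseline isoform fractions $\pi_{gi}$ come from a sparse symmetric
  Dirichlet (concentration 0.7), sorted decreasing, so most genes have
  a dominant isoform and some near-zero ("annotated but not
  expressed") isoforms.
* Per sample, the gene count is $K \sim \mathrm{NB}(\mu_g, \phi_g)$
  (variance $\mu + \phi\mu^2$), and sample-level fractions are drawn
  from $\mathrm{Dirichlet}(100\,\pi_g)$ — the scale 100 reproduces the
  replicate-to-replicate wobble of estimated isoform proportions.
  Fractions of exactly zero are excluded from the Dirichlet (undefined
  at $\alpha = 0$) and stay zero. Gene counts are converted to RPK
  with the effective gene length (the $\pi$-weighted mean of isoform
  effective lengths, $L_\mathrm{eff} = \max(1, L - \bar f + 1)$ with
  $\bar f$ the mean fragment length), split by the fractions, and
  rescaled to TPM.

DTU is introduced for `n_dtu` genes drawn uniformly from those with at
least two expressed isoforms (baseline fraction above 10%) and
expected count above 500: the fractions of the two most abundant
isoforms are exchanged in condition 2. Total gene output is untouched,
so there is *no* gene-level differential expression by construction,
and the gap between the two top fractions (the *dominance
difference*) is the effect size.

Fragments are simulated at the coordinate level: paired 101-bp reads
from a fragment of truncated-normal length (mean 250, sd 25 — chosen
to exceed the read length comfortably), started uniformly along the
transcript and projected through the exon structure to genomic blocks.
Reads are error-free and alignment is implicit; this removes the
aligner from the loop and lets the counting operate on true
coordinates. The default 2e5 fragments per sample is a desk-scale
stand-in for the tens of millions of read pairs of a real study; the
acceptance analyses in `scripts/acceptance.R` and the test suite use
120-300 genes with 1.5e5-4e5 fragments per sample so that the
expected per-gene counts match the eligibility rule above while whole
studies complete in minutes. What the generator does *not* emulate:
sequencing errors and base qualities, positional/GC bias, strand
protocols, multi-chromosome genes, unannotated transcription. Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated model, not robustness to real-data artifacts.

# Counting bins

From one catalog, five bin families are built (`flatten()`,
`exon_bins()`, `junction_set()`, `transcript_bins()`):

* **flat** — cut the exon union of a feature at *every* exon boundary
  of its transcripts; the resulting sub-exonic bins are disjoint and
  each is annotated with the transcripts that contain it. Overlapping
  genes are handled three ways: aggregated into a `+`-joined complex
  (genes are merged transitively when their exon unions overlap by at
  least 1 bp on the same strand — the aggregation trigger is an
  explicit package decision, exon-level overlap matching the
  flattening substrate); excluded on the same strand; or excluded on
  either strand.
* **exon** — the original exons, deduplicated per gene, overlapping
  freely; fragments are assigned to every bin they touch, so counts
  are multi-assigned (column sums can exceed the fragment count).
* **junction** — one bin per splice junction; only fragments with a
  mate whose consecutive blocks match the junction boundaries
  *exactly* count.
* **transcript** — the isoforms themselves; fragments are reduced to
  equivalence classes (the set of transcripts whose exon structure
  contains both mates and whose junctions match every internal block
  boundary) and expected per-transcript counts are obtained by the
  standard abundance EM (E-step shares each class among members
  proportionally to $\theta_t / L_{t,\mathrm{eff}}$; uniform
  initialization; convergence at $\max|\Delta\theta| < 10^{-8}$).
  Single-isoform genes yield a single bin and are untestable
  downstream — an inherent limitation of transcript-level bins.

# The inference engine

For each bin that survives independent filtering (mean normalized
count at least 5 by default; the fixed threshold keeps the analysis
deterministic, in place of a rejection-maximizing quantile search) and
has at least one sibling bin, the observations are the bin's counts
$y_s$ and the summed counts $o_s$ of the feature's other bins. A NB
GLM with log link and size-factor offsets (median-of-ratios factors,
rescaled to geometric mean one) is fitted with design

$$\mathrm{sample} + \mathrm{part} + \mathrm{condition{:}part},$$

where *part* distinguishes "this bin" from "the rest of the gene". A
single dispersion per bin is shared by all $2S$ observations and
estimated by maximizing the Cox-Reid adjusted profile likelihood
(bounded search on $\log\phi \in [\log 10^{-8}, \log 10]$); estimates
are moderated toward a $b_0 + b_1/\mu$ trend, fitted by iterative
gamma-weighted least squares on bins with interior estimates, with a
log-normal prior whose sd is the MAD of the log-ratios, floored at
0.25. Estimates more than $2\,\mathrm{sd}$ above the trend are treated
as outliers and kept unshrunken. The condition:part interaction is
then assessed by a likelihood-ratio test on one degree of freedom,
with the inner IRLS converging at a relative deviance change below
$10^{-8}$ (at most 100 iterations; a non-converged fit marks the bin
untested rather than contributing a doubtful p-value).

Gene-level significance aggregates the tested bins of a feature: with
$n$ bins and smallest bin p-value $\theta$, the gene p-value is the
Sidak-style family bound $1 - (1 - \theta)^n$, and Benjamini-Hochberg
across features yields q-values. The multiple-testing universe is the
set of features with at least one tested bin. This closed-form
aggregation was chosen over empirical expected-false-positive counting
for transparency and determinism; it is slightly conservative when a
gene's bins are strongly correlated (multi-assigned counting), which
shows up as type-I error below the nominal level in the null
calibration.

# Evaluation

Gene results are matched to the simulated truth. Identifiers that are
not truth genes — notably `+`-joined complexes — cannot be classified
and are excluded; truth genes that received no q-value (filtered out
or hidden inside a complex) can never be called and therefore count as
negatives, so truly differential ones become false negatives. (An
alternative subset evaluation that drops uncalled truth genes from
the denominators is available via `drop_uncalled = TRUE`.) Calls use
`q <= threshold` at 0.01 / 0.05 / 0.1; TPR is TP/(TP+FN) and FDR is
FP/(TP+FP), both defined as 0 on empty denominators. Results can be
stratified by isoform count (breaks 1, 2, 4, 8, Inf), dominance
difference (breaks 0, 1/3, 2/3, 1; left-closed right-open), or
expression level.

# A small study

```{r study, eval = FALSE}
library(dtubench)
cfg <- dtu_config(
  params = sim_params(n_genes = 60, library_size = 6e4, n_dtu = 12),
  variants = c("flat_noaggreg", "junction"),
  prefilter_thresholds = c(0, 0.05),
  degrade = TRUE,
  out_dir = "dtu_study")
perf <- run_study(cfg)
subset(perf, threshold == 0.05)
```

Every stage writes plain files (`annotation.gtf`, `truth.tsv`, BED12
fragments, count TSVs, result TSVs, `performance.tsv`, a manifest with
checksums), so each arm of the grid is auditable and each stage can be
rerun in isolation (`run_simulation()`, `run_counting()`,
`run_testing()`, `run_evaluation()`).

# Numerical and design notes

* Coordinates are 0-based half-open internally; GTF I/O converts to
  1-based inclusive. Bookended exon records are merged on input so
  that every internal boundary is a genuine splice site.
* Flat bins are by construction the maximal runs of bases with an
  identical set of covering transcripts; the test suite checks this
  against a brute-force per-base projection oracle on hundreds of
  random catalogs.
* Ties in the top-two swap (equal fractions) make the swap a no-op;
  the gene keeps dominance difference 0 and is, correctly, nearly
  undetectable.
* EM output is real-valued; counts are rounded to the nearest integer
  before GLM fitting and at TSV export (1e-6).
* Annotation degradation removes `round(f n)` transcripts (half-up)
  per stratum — the swapped pairs of DTU genes versus all other
  transcripts — making the removal proportional between the two
  classes, and is deterministic given its seed.
* The independence of the test from sample ordering, the invariance
  of p-values to rescaling the size factors, and the invariance of
  flattening to gene input order are all asserted as properties in
  the test suite.

# Known limitations

The Sidak/BH aggregation and the fixed-threshold independent filter
are deliberate simplifications of the adaptive procedures used by
production DEU tools; they match those tools qualitatively, not
q-value-for-q-value. The fragment model is error-free and unbiased,
so FDR excesses caused by misalignment or bias are out of scope. Gene
complexes are evaluated as unmatched (their member genes become
uncallable), which penalizes aggregation exactly as the evaluation
design intends but gives no partial credit for a correct call on a
complex containing a true DTU gene.
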