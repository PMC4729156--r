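#' Study configuration
#'
#' Bundles the whole experiment grid: the simulation parameters, the
#' counting variants to run, the isoform-prefilter sweep, the
#' annotation-degradation arm, and the inference/evaluation settings.
#' Each arm of the study is one combination (counting variant x
#' prefilter threshold x catalog completeness).
#'
#' @param params a [sim_params()] list.
#' @param variants counting variants, a subset of `"flat_aggregate"`,
#'   `"flat_noaggreg"`, `"flat_bothstrands"`, `"exon"`, `"junction"`,
#'   `"transcript_em"`.
#' @param prefilter_thresholds ascending thresholds starting at 0
#'   (0 = no filtering); the study default sweeps 0, 0.05, 0.10,
#'   0.15, 0.25.
#' @param prefilter_mode see [prefilter_isoforms()].
#' @param degrade if `TRUE`, every arm is additionally run with a
#'   degraded catalog ([degrade_annotation()]).
#' @param degrade_fraction fraction of transcripts removed.
#' @param thresholds q-value thresholds for the evaluation.
#' @param min_mean independent-filter threshold of [dtu_test()].
#' @param out_dir output directory for the staged files.
#' @return A `dtu_config` list.
#' @export
dtu_config <- function(params = sim_params(n_genes = 60,
                                           library_size = 6e4,
                                           n_dtu = 12),
                       variants = c("flat_noaggreg", "exon", "junction",
                                    "transcript_em"),
                       prefilter_thresholds = c(0, 0.05, 0.1, 0.15, 0.25),
                       prefilter_mode = "true_condition",
                       degrade = FALSE,
                       degrade_fraction = 0.2,
                       thresholds = c(0.01, 0.05, 0.1),
                       min_mean = 5,
                       out_dir = tempfile("dtu_study_")) {
  all_variants <- c("flat_aggregate", "flat_noaggreg", "flat_bothstrands",
                    "exon", "junction", "transcript_em")
  if (length(variants) < 1) stopf("at least one counting variant required")
  variants <- match.arg(variants, all_variants, several.ok = TRUE)
  if (is.unsorted(prefilter_thresholds) || prefilter_thresholds[1] != 0)
    stopf("prefilter thresholds must be ascending and start at 0")
  structure(list(params = params, variants = variants,
                 prefilter_thresholds = prefilter_thresholds,
                 prefilter_mode = prefilter_mode,
                 degrade = degrade, degrade_fraction = degrade_fraction,
                 thresholds = thresholds, min_mean = min_mean,
                 out_dir = out_dir), class = "dtu_config")
}

sim_dir <- function(config) file.path(config$out_dir, "simulation")

arm_label <- function(variant, threshold, complete) {
  sprintf("%s@t%g@%s", variant, threshold,
          if (complete) "complete" else "degraded")
}

#' Run the simulation stage
#'
#' Generates the catalog, expression model, truth table and per-sample
#' fragments, and writes them to `out_dir/simulation`: `annotation.gtf`,
#' `truth.tsv`, `abundances.tsv` (baseline isoform fractions per
#' condition, the input of true-abundance prefiltering), one
#' `<sample>.bed` BED12 file per sample, `samples.tsv`, and a
#' `manifest.json` with the parameters and file checksums.
#'
#' @param config a [dtu_config()].
#' @param force overwrite an existing non-empty output directory.
#' @return The in-memory simulation (invisibly), as from
#'   [simulate_experiment()].
#' @export
run_simulation <- function(config, force = FALSE) {
  dir <- sim_dir(config)
  if (dir.exists(dir) && length(dir(dir)) && !force)
    stopf("output directory %s is not empty (use force = TRUE)", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_experiment(config$params)
  write_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  write_truth(sim$truth, file.path(dir, "truth.tsv"))
  iso <- sim$model$isoforms
  write.table(iso[c("transcript_id", "gene_id", "pi_1", "pi_2")],
              file.path(dir, "abundances.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (s in sim$samples$sample_id)
    write_fragments_bed12(sim$fragments[[s]],
                          file.path(dir, paste0(s, ".bed")))
  files <- dir(dir)
  manifest <- list(
    params = config$params[setdiff(names(config$params), NULL)],
    files = setNames(lapply(file.path(dir, files), function(f)
      unname(tools::md5sum(f))), files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}

# catalog for one (threshold, completeness) cell
arm_annotation <- function(ann, abundances, truth, config, threshold,
                           complete) {
  out <- if (threshold > 0)
    prefilter_isoforms(ann, abundances, threshold,
                       config$prefilter_mode) else ann
  if (!complete)
    out <- degrade_annotation(out, config$degrade_fraction, truth,
                              seed = config$params$seed + 17L)
  out
}

variant_binset <- function(ann, variant) {
  switch(variant,
         flat_aggregate = flatten(ann, "aggregate"),
         flat_noaggreg = flatten(ann, "exclude_same_strand"),
         flat_bothstrands = flatten(ann, "exclude_both_strands"),
         exon = exon_bins(ann),
         junction = junction_set(ann),
         transcript_em = transcript_bins(ann),
         stopf("unknown counting variant '%s'", variant))
}

count_variant <- function(frags, ann, variant, params) {
  if (variant == "transcript_em") {
    ecs <- build_equivalence_classes(frags, ann)
    tt <- transcript_table(ann)
    eff <- setNames(effective_length(tt$length, params$fragment_length_mean),
                    tt$transcript_id)
    em_quantify(ecs, eff, ann)
  } else {
    bs <- variant_binset(ann, variant)
    if (variant == "junction") count_junctions(frags, bs)
    else count_flat_or_exon(frags, bs)
  }
}

#' Run the counting stage
#'
#' Reads the simulation stage's files back from disk and produces one
#' count matrix per arm under `out_dir/counts`
#' (`<variant>@t<threshold>@<completeness>.counts.tsv` plus the
#' bin-to-feature map).
#'
#' @param config a [dtu_config()].
#' @return Character vector of count-matrix paths, invisibly.
#' @export
run_counting <- function(config) {
  dir <- sim_dir(config)
  if (!file.exists(file.path(dir, "annotation.gtf")))
    stopf("simulation outputs not found in %s; run run_simulation() first",
          dir)
  ann <- read_gtf(file.path(dir, "annotation.gtf"))
  truth <- read_truth(file.path(dir, "truth.tsv"))
  abund <- read.table(file.path(dir, "abundances.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  samples <- read.table(file.path(dir, "samples.tsv"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
  frags <- combine_fragments(lapply(samples$sample_id, function(s)
    read_fragments_bed12(file.path(dir, paste0(s, ".bed")),
                         sample_id = s)))
  cdir <- file.path(config$out_dir, "counts")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (complete in if (config$degrade) c(TRUE, FALSE) else TRUE)
    for (t in config$prefilter_thresholds) {
      arm_ann <- arm_annotation(ann, abund, truth, config, t, complete)
      for (v in config$variants) {
        cm <- count_variant(frags, arm_ann, v, config$params)
        path <- file.path(cdir, paste0(arm_label(v, t, complete),
                                       ".counts.tsv"))
        write_counts(cm, path)
        paths <- c(paths, path)
      }
    }
  invisible(paths)
}

#' Run the testing stage
#'
#' Applies [dtu_test()] to every count matrix under `out_dir/counts`,
#' writing per-arm gene-result tables under `out_dir/results`.
#'
#' @param config a [dtu_config()].
#' @return Character vector of result paths, invisibly.
#' @export
run_testing <- function(config) {
  cdir <- file.path(config$out_dir, "counts")
  files <- dir(cdir, pattern = "\\.counts\\.tsv$", full.names = TRUE)
  if (!length(files))
    stopf("no count matrices in %s; run run_counting() first", cdir)
  samples <- read.table(file.path(sim_dir(config), "samples.tsv"),
                        sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  rdir <- file.path(config$out_dir, "results")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (f in files) {
    cm <- read_counts(f)
    cond <- samples$condition[match(colnames(cm$counts),
                                    samples$sample_id)]
    fit <- suppressWarnings(dtu_test(cm, cond, min_mean = config$min_mean))
    path <- file.path(rdir, sub("\\.counts\\.tsv$", ".genes.tsv",
                                basename(f)))
    write_gene_results(fit, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Run the evaluation stage
#'
#' Matches every arm's gene results against the truth and writes the
#' merged performance table (`out_dir/performance.tsv`).
#'
#' @param config a [dtu_config()].
#' @param stratify_by optional scheme passed to [stratify()].
#' @return The [compare_arms()] table.
#' @export
run_evaluation <- function(config, stratify_by = NULL) {
  rdir <- file.path(config$out_dir, "results")
  files <- dir(rdir, pattern = "\\.genes\\.tsv$", full.names = TRUE)
  if (!length(files))
    stopf("no result tables in %s; run run_testing() first", rdir)
  truth <- read_truth(file.path(sim_dir(config), "truth.tsv"))
  arms <- list()
  for (f in files) {
    lab <- match_truth(read_gene_results(f), truth)
    if (!is.null(stratify_by)) lab <- stratify(lab, stratify_by)
    arms[[sub("\\.genes\\.tsv$", "", basename(f))]] <-
      performance(lab, config$thresholds)
  }
  perf <- compare_arms(arms)
  write.table(perf, file.path(config$out_dir, "performance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  perf
}

#' Run the whole study
#'
#' `simulate -> count -> test -> evaluate` with plain-file handoff
#' between the stages.
#'
#' @param config a [dtu_config()].
#' @param force forwarded to [run_simulation()].
#' @return The merged performance table.
#' @export
run_study <- function(config, force = FALSE) {
  run_simulation(config, force = force)
  run_counting(config)
  run_testing(config)
  run_evaluation(config)
}
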