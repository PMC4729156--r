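#' Isoform prefiltering
#'
#' Removes lowly abundant isoforms from a catalog before counting bins
#' are built, the FDR-improving step of the study. Two modes:
#'
#' * `"true_condition"`: `abundances` holds one relative-abundance
#'   column per condition; an isoform is dropped iff its abundance is
#'   below `threshold` in *both* conditions.
#' * `"estimated_sample"`: `abundances` holds one estimate column per
#'   sample; an isoform is dropped iff its abundance does not exceed
#'   `threshold` in *any* sample.
#'
#' Genes whose isoforms are all dropped disappear from the catalog.
#'
#' @param ann a [dtu_annotation()].
#' @param abundances data frame with a `transcript_id` column and one
#'   numeric column per condition (or per sample).
#' @param threshold relative-abundance cutoff in `[0, 1)`; the study
#'   sweeps 0.05, 0.10, 0.15 and 0.25.
#' @param mode `"true_condition"` or `"estimated_sample"`.
#' @return The filtered [dtu_annotation()].
#' @export
prefilter_isoforms <- function(ann, abundances, threshold,
                               mode = c("true_condition",
                                        "estimated_sample")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold < 1)
  validate_annotation(ann)
  if (!"transcript_id" %in% names(abundances))
    stopf("abundance table needs a transcript_id column")
  tx <- unique(ann$transcript_id)
  missing <- setdiff(tx, abundances$transcript_id)
  if (length(missing))
    stopf("no abundance for isoform(s): %s",
          paste(head(missing, 5), collapse = ", "))
  vals <- abundances[match(tx, abundances$transcript_id),
                     vapply(abundances, is.numeric, TRUE), drop = FALSE]
  if (ncol(vals) < 1) stopf("abundance table has no numeric columns")
  m <- as.matrix(vals)
  drop <- if (mode == "true_condition") {
    apply(m < threshold, 1L, all)
  } else {
    apply(m <= threshold, 1L, all)
  }
  out <- subset_transcripts(ann, tx[!drop])
  attr(out, "provenance") <- sprintf("%s | prefilter %s t=%g",
    attr(ann, "provenance") %||% "?", mode, threshold)
  out
}

#' Annotation degradation
#'
#' Emulates an incomplete transcriptome catalog by removing a fixed
#' fraction of the transcripts, proportionally split between the
#' differentially used transcripts (the swapped pairs recorded in the
#' truth table) and all other transcripts: `round(f * n)` transcripts
#' are sampled without replacement from each stratum.
#'
#' @param ann a [dtu_annotation()].
#' @param fraction fraction of transcripts to remove, in `(0, 1)`; the
#'   study uses 0.2.
#' @param truth a truth table from [select_dtu_genes()] (or any data
#'   frame with `dtu_status`, `swapped_1`, `swapped_2` columns).
#' @param seed integer seed making the removal reproducible.
#' @return The degraded [dtu_annotation()].
#' @export
degrade_annotation <- function(ann, fraction, truth, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stopf("fraction must be in (0, 1)")
  validate_annotation(ann)
  tx <- unique(ann$transcript_id)
  dtu_tx <- character(0)
  if (!is.null(truth) && nrow(truth)) {
    sel <- truth$dtu_status %in% TRUE
    dtu_tx <- intersect(c(truth$swapped_1[sel], truth$swapped_2[sel]), tx)
  }
  other_tx <- setdiff(tx, dtu_tx)
  remove <- with_seed(seed, {
    c(sample(dtu_tx, round_half_up(fraction * length(dtu_tx))),
      sample(other_tx, round_half_up(fraction * length(other_tx))))
  })
  out <- subset_transcripts(ann, setdiff(tx, remove))
  attr(out, "provenance") <- sprintf("%s | degraded f=%g seed=%d",
    attr(ann, "provenance") %||% "?", fraction, as.integer(seed))
  out
}
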