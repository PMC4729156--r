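#' Match gene-level results to the simulated truth
#'
#' Feature identifiers that are not gene ids of the truth table
#' (gene complexes with `"+"`-joined ids, or anything unknown) are
#' labeled `unmatched` and excluded from the confusion counts. Truth
#' genes absent from the results (filtered out, or hidden inside a
#' complex) are retained with no q-value: they can never be called, so
#' truly differential ones become false negatives.
#'
#' @param gene_results a `dtu_test` object or its `gene_results` data
#'   frame.
#' @param truth a truth table ([select_dtu_genes()] / [read_truth()]).
#' @return A data frame with `feature_id`, `q_value`, `truth_status`
#'   (`dtu` / `non_dtu` / `unmatched`) and the truth's strata columns.
#' @export
match_truth <- function(gene_results, truth) {
  gr <- if (inherits(gene_results, "dtu_test"))
    gene_results$gene_results else gene_results
  if (anyDuplicated(gr$feature_id))
    stopf("duplicate feature_id in results")
  hit <- match(gr$feature_id, truth$gene_id)
  labeled <- data.frame(
    feature_id = gr$feature_id,
    q_value = gr$q_value,
    truth_status = ifelse(is.na(hit), "unmatched",
                          ifelse(truth$dtu_status[hit], "dtu", "non_dtu")),
    stringsAsFactors = FALSE)
  extra <- intersect(c("n_isoforms", "dominance_diff", "expected_count"),
                     names(truth))
  for (cl in extra) labeled[[cl]] <- truth[[cl]][hit]
  # truth genes with no result: uncalled, q = NA
  absent <- !(truth$gene_id %in% gr$feature_id)
  if (any(absent)) {
    add <- data.frame(
      feature_id = truth$gene_id[absent],
      q_value = NA_real_,
      truth_status = ifelse(truth$dtu_status[absent], "dtu", "non_dtu"),
      stringsAsFactors = FALSE)
    for (cl in extra) add[[cl]] <- truth[[cl]][absent]
    labeled <- rbind(labeled, add)
  }
  rownames(labeled) <- NULL
  labeled
}

#' Confusion counts at a q-value threshold
#'
#' A feature is called differential when its q-value exists and is at
#' most the threshold. TPR is the fraction of truly differential genes
#' called; FDR the fraction of calls that are not truly differential;
#' both are 0 when their denominator is empty. Unmatched features are
#' excluded; with `drop_uncalled = TRUE` truth genes without a q-value
#' are dropped from the denominators as well (the alternative
#' subset-style evaluation), instead of counting as negatives.
#'
#' @param labeled output of [match_truth()].
#' @param threshold q-value threshold in `(0, 1]`.
#' @param drop_uncalled drop truth genes that received no q-value.
#' @return One-row data frame: threshold, TP, FP, TN, FN, TPR, FDR,
#'   n, n_ds.
#' @export
confusion_at <- function(labeled, threshold, drop_uncalled = FALSE) {
  lab <- labeled[labeled$truth_status != "unmatched", , drop = FALSE]
  if (drop_uncalled) lab <- lab[!is.na(lab$q_value), , drop = FALSE]
  call <- !is.na(lab$q_value) & lab$q_value <= threshold
  dtu <- lab$truth_status == "dtu"
  tp <- sum(call & dtu); fp <- sum(call & !dtu)
  fn <- sum(!call & dtu); tn <- sum(!call & !dtu)
  data.frame(threshold = threshold, TP = tp, FP = fp, TN = tn, FN = fn,
             TPR = if (tp + fn > 0) tp / (tp + fn) else 0,
             FDR = if (tp + fp > 0) fp / (tp + fp) else 0,
             n = nrow(lab), n_ds = sum(dtu))
}

#' Stratify labeled results
#'
#' Assigns each matched feature to a left-closed, right-open interval
#' of one gene characteristic: number of isoforms, isoform dominance
#' difference, or expected expression. Values outside the break range
#' fall into the closest stratum with a warning.
#'
#' @param labeled output of [match_truth()].
#' @param scheme `"n_isoforms"`, `"dominance"` or `"expression"`.
#' @param breaks cut points; defaults: isoform count `(1, 2, 4, 8,
#'   Inf)`, dominance `(0, 1/3, 2/3, 1)`, expression quartiles.
#' @return `labeled` with a `stratum` factor column.
#' @export
stratify <- function(labeled, scheme = c("n_isoforms", "dominance",
                                         "expression"), breaks = NULL) {
  scheme <- match.arg(scheme)
  x <- switch(scheme,
    n_isoforms = labeled$n_isoforms,
    dominance = labeled$dominance_diff,
    expression = labeled$expected_count)
  if (is.null(x)) stopf("labeled results lack the '%s' column", scheme)
  breaks <- breaks %||% switch(scheme,
    n_isoforms = c(1, 2, 4, 8, Inf),
    dominance = c(0, 1 / 3, 2 / 3, 1),
    expression = unique(stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1),
                                        na.rm = TRUE)))
  rng <- range(x, na.rm = TRUE)
  if (rng[1] < breaks[1] || rng[2] > breaks[length(breaks)]) {
    warnf("values outside the break range are assigned to the end strata")
    x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)])
  }
  lab <- sprintf("[%.3g,%.3g)", breaks[-length(breaks)], breaks[-1])
  lab[length(lab)] <- sub("\\)$", "]", lab[length(lab)])
  labeled$stratum <- cut(x, breaks, labels = lab, right = FALSE,
                         include.lowest = TRUE)
  labeled
}

#' Per-stratum, per-threshold performance
#'
#' Tabulates TPR and FDR at each threshold, optionally within strata.
#'
#' @param labeled output of [match_truth()] (possibly after
#'   [stratify()]).
#' @param thresholds q-value thresholds (default 0.01, 0.05, 0.1).
#' @param drop_uncalled see [confusion_at()].
#' @return Data frame with one row per (stratum x) threshold.
#' @export
performance <- function(labeled, thresholds = c(0.01, 0.05, 0.1),
                        drop_uncalled = FALSE) {
  strata <- if ("stratum" %in% names(labeled))
    levels(labeled$stratum) else NA_character_
  rows <- list()
  for (st in strata) {
    lab <- if (is.na(st)) labeled else
      labeled[!is.na(labeled$stratum) & labeled$stratum == st, ,
              drop = FALSE]
    for (t in thresholds) {
      r <- confusion_at(lab, t, drop_uncalled)
      r <- cbind(stratum = st, r)
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare experimental arms
#'
#' Binds the per-arm performance tables into one long table and flags
#' whether each arm controls the FDR at its threshold (`controlled =
#' FDR <= threshold`). All arms must share thresholds and strata.
#'
#' @param arms named list of [performance()] tables.
#' @return A `dtu_performance` data frame (arm, stratum, threshold,
#'   confusion counts, TPR, FDR, controlled).
#' @export
compare_arms <- function(arms) {
  stopifnot(length(arms) >= 1, !is.null(names(arms)))
  ref <- arms[[1]][c("stratum", "threshold")]
  for (a in arms)
    if (!identical(a[c("stratum", "threshold")], ref))
      stopf("arms have mismatched strata or thresholds")
  out <- do.call(rbind, lapply(names(arms), function(nm)
    cbind(arm = nm, arms[[nm]], stringsAsFactors = FALSE)))
  out$controlled <- out$FDR <= out$threshold
  rownames(out) <- NULL
  class(out) <- c("dtu_performance", "data.frame")
  out
}

#' FDR/TPR scatter of a performance table
#'
#' One point per (arm, threshold) as in the study's headline figures:
#' observed FDR on the x axis, TPR on the y axis, vertical lines at
#' the imposed thresholds, filled points where the FDR is controlled.
#'
#' @param x a [compare_arms()] table.
#' @param ... forwarded to [graphics::plot()].
#' @export
plot.dtu_performance <- function(x, ...) {
  arms <- unique(x$arm)
  cols <- grDevices::hcl.colors(max(3L, length(arms)), "Dark 3")
  graphics::plot(NA, xlim = c(0, max(0.3, max(x$FDR))), ylim = c(0, 1),
                 xlab = "observed FDR", ylab = "TPR", ...)
  graphics::abline(v = unique(x$threshold), lty = 3, col = "grey50")
  for (i in seq_along(arms)) {
    xi <- x[x$arm == arms[i], ]
    graphics::points(xi$FDR, xi$TPR, col = cols[i],
                     pch = ifelse(xi$controlled, 16, 1), cex = 1.2)
  }
  graphics::legend("bottomright", legend = arms,
                   col = cols[seq_along(arms)], pch = 16, bty = "n")
  invisible(x)
}
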