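# end-to-end helpers shared by the acceptance-style tests

# count one variant on a simulated experiment (optionally with a
# modified catalog) and run the bin-usage test
pipeline_fit <- function(sim, params, ann = sim$annotation,
                         variant = "flat_noaggreg") {
  frags <- dtubench:::combine_fragments(sim$fragments)
  cm <- dtubench:::count_variant(frags, ann, variant, params)
  suppressWarnings(suppressMessages(
    dtu_test(cm, sim$samples$condition)))
}

pipeline_confusion <- function(fit, truth, threshold = 0.05) {
  confusion_at(match_truth(fit, truth), threshold)
}

# pooled TPR/FDR over a list of (fit, truth) pairs
pooled_rates <- function(fits, truths, threshold = 0.05) {
  tp <- fp <- fn <- 0
  for (i in seq_along(fits)) {
    r <- pipeline_confusion(fits[[i]], truths[[i]], threshold)
    tp <- tp + r$TP; fp <- fp + r$FP; fn <- fn + r$FN
  }
  c(TPR = if (tp + fn > 0) tp / (tp + fn) else 0,
    FDR = if (tp + fp > 0) fp / (tp + fp) else 0)
}
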