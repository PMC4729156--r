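#' Median-of-ratios size factors
#'
#' For each sample, the median over bins (positive in all samples) of
#' the ratio of the bin's count to its geometric mean across samples;
#' factors are rescaled to geometric mean 1. When no bin is positive
#' in every sample the total-count ratios are used instead (with a
#' message).
#'
#' @param counts a [dtu_counts] object or a numeric matrix.
#' @return Named vector of positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  m <- if (inherits(counts, "dtu_counts")) counts$counts else counts
  pos <- rowSums(m > 0) == ncol(m)
  if (any(pos)) {
    lg <- log(m[pos, , drop = FALSE])
    gm <- rowMeans(lg)
    sf <- exp(apply(lg - gm, 2L, median))
  } else {
    message("no bin positive in all samples; falling back to total-count ratios")
    tot <- colSums(m)
    sf <- tot / exp(mean(log(tot)))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

#' Per-bin test inputs
#'
#' For every bin, pairs the bin's counts `y` with `o`, the summed
#' counts of all *other* bins of the same feature, per sample. Bins of
#' single-bin features are marked untestable (there is no "rest of the
#' gene" to compare against).
#'
#' @param counts a [dtu_counts] or matrix.
#' @param feature named character vector mapping bin ids to features
#'   (taken from `counts` when missing).
#' @param conditions integer/factor vector of sample conditions
#'   (two levels).
#' @param size_factors per-sample size factors.
#' @return List with `y`, `o` (bins x samples matrices), `feature`,
#'   `testable`, `conditions`, `size_factors`.
#' @export
build_bin_inputs <- function(counts, feature = NULL, conditions,
                             size_factors = NULL) {
  m <- if (inherits(counts, "dtu_counts")) counts$counts else counts
  feature <- feature %||%
    (if (inherits(counts, "dtu_counts")) counts$feature else NULL)
  if (is.null(feature)) stopf("a bin-to-feature map is required")
  stopifnot(length(conditions) == ncol(m))
  m <- round(m)  # EM output is real-valued
  ftot <- rowsum(m, feature[rownames(m)])
  o <- ftot[match(feature[rownames(m)], rownames(ftot)), , drop = FALSE] - m
  rownames(o) <- rownames(m)
  nbins <- table(feature[rownames(m)])
  testable <- as.integer(nbins[feature[rownames(m)]]) > 1L
  list(y = m, o = o, feature = feature[rownames(m)],
       testable = setNames(testable, rownames(m)),
       conditions = as.integer(factor(conditions)),
       size_factors = size_factors %||% rep(1, ncol(m)))
}

# design matrices for one bin: rows = (sample, part) with part = rest/this,
# full-rank by construction: intercept + sample effects + this + this:cond2
bin_design <- function(conditions) {
  S <- length(conditions)
  part <- rep(c(0L, 1L), each = S)   # 0 = rest of gene, 1 = this bin
  smp <- factor(rep(seq_len(S), 2L))
  X_null <- cbind(1, stats::model.matrix(~smp)[, -1, drop = FALSE],
                  this = part)
  X_full <- cbind(X_null,
                  this_cond2 = part * rep(conditions == 2L, 2L))
  colnames(X_null)[1] <- colnames(X_full)[1] <- "(Intercept)"
  list(full = X_full, null = X_null)
}

bin_obs <- function(y_row, o_row, size_factors) {
  list(y = c(o_row, y_row),
       offset = rep(log(size_factors), 2L))
}

DISP_BOUNDS <- c(1e-8, 10)

#' Cox-Reid dispersion estimate for one bin
#'
#' Maximizes the Cox-Reid adjusted profile log-likelihood of the
#' bin-versus-rest NB GLM (full design: sample effects + bin part +
#' condition:part interaction; one dispersion shared by all 2S
#' observations), by bounded search on log dispersion in
#' `[log 1e-8, log 10]`.
#'
#' @param y,o per-sample counts of the bin and of the feature's other
#'   bins.
#' @param conditions integer conditions (1/2) per sample.
#' @param size_factors per-sample size factors.
#' @return The dispersion estimate (a boundary value flags a
#'   degenerate fit).
#' @export
estimate_dispersion <- function(y, o, conditions, size_factors) {
  des <- bin_design(conditions)
  obs <- bin_obs(y, o, size_factors)
  disp_mle(des$full, obs$y, obs$offset)
}

disp_mle <- function(X, yv, offset) {
  f <- function(lphi) .nb_cr_apl(X, yv, offset, exp(lphi))
  opt <- optimize(f, interval = log(DISP_BOUNDS), maximum = TRUE,
                  tol = 1e-4)
  # prefer a boundary if it beats the interior optimum
  lo <- f(log(DISP_BOUNDS[1])); hi <- f(log(DISP_BOUNDS[2]))
  best <- which.max(c(opt$objective, lo, hi))
  exp(c(opt$maximum, log(DISP_BOUNDS))[best])
}

#' Fit the dispersion trend
#'
#' Fits `phi_tr(mu) = b0 + b1 / mu` to the per-bin dispersion
#' estimates against their mean normalized counts by iterative
#' gamma-weighted least squares on bins whose estimates are interior
#' to the search bounds, with both coefficients constrained
#' non-negative. With fewer than 10 usable bins the trend degenerates
#' to the median dispersion (with a message).
#'
#' @param dispersions raw per-bin dispersion estimates.
#' @param base_means per-bin mean normalized counts.
#' @return `c(b0, b1)`.
#' @export
fit_dispersion_trend <- function(dispersions, base_means) {
  usable <- is.finite(dispersions) & is.finite(base_means) &
    dispersions > DISP_BOUNDS[1] * 1.5 & dispersions < DISP_BOUNDS[2] / 1.5 &
    base_means > 0
  if (sum(usable) < 10) {
    message("fewer than 10 usable bins; using a constant dispersion trend")
    return(c(b0 = max(median(dispersions[is.finite(dispersions)],
                             na.rm = TRUE), 1e-6), b1 = 0))
  }
  d <- dispersions[usable]; mu <- base_means[usable]
  x <- 1 / mu
  co <- coef(lm(d ~ x))
  for (it in 1:8) {
    fitted <- pmax(co[1] + co[2] * x, 1e-8)
    w <- 1 / fitted^2
    co <- coef(lm(d ~ x, weights = w))
  }
  co <- pmax(co, 0)
  if (co[1] == 0 && co[2] == 0) co[1] <- max(median(d), 1e-6)
  c(b0 = unname(co[1]), b1 = unname(co[2]))
}

eval_trend <- function(trend, mu) pmax(trend[1] + trend[2] / pmax(mu, 1e-8),
                                       1e-8)

#' Shrink a dispersion estimate toward the trend
#'
#' Maximum a posteriori estimate combining the Cox-Reid adjusted
#' profile likelihood with a log-normal prior centered at the trend
#' value, except that estimates more than `2 * prior_sd` above the
#' trend (on the log scale) are treated as outliers and kept as is.
#'
#' @param y,o,conditions,size_factors as in [estimate_dispersion()].
#' @param raw_dispersion the unshrunken estimate.
#' @param trend_dispersion the trend value at the bin's mean.
#' @param prior_sd log-scale prior standard deviation.
#' @return The final dispersion.
#' @export
shrink_dispersion <- function(y, o, conditions, size_factors,
                              raw_dispersion, trend_dispersion, prior_sd) {
  if (log(raw_dispersion) > log(trend_dispersion) + 2 * prior_sd)
    return(raw_dispersion)  # dispersion outlier: no shrinkage
  des <- bin_design(conditions)
  obs <- bin_obs(y, o, size_factors)
  f <- function(lphi) .nb_cr_apl(des$full, obs$y, obs$offset, exp(lphi)) +
    stats::dnorm(lphi, log(trend_dispersion), prior_sd, log = TRUE)
  opt <- optimize(f, interval = log(DISP_BOUNDS), maximum = TRUE,
                  tol = 1e-4)
  exp(opt$maximum)
}

#' Bin-versus-rest likelihood ratio test
#'
#' Fits the full (sample + part + condition:part) and null
#' (sample + part) NB GLMs at a fixed dispersion and compares them by
#' a likelihood ratio test on 1 degree of freedom (two conditions).
#' The statistic is floored at zero; a non-converged fit marks the bin
#' untested.
#'
#' @param y,o,conditions,size_factors as in [estimate_dispersion()].
#' @param dispersion the (final) dispersion to fit at.
#' @return List `p_value`, `lrt_stat`, `tested`.
#' @export
test_bin <- function(y, o, conditions, size_factors, dispersion) {
  des <- bin_design(conditions)
  obs <- bin_obs(y, o, size_factors)
  full <- .nb_glm_fit(des$full, obs$y, obs$offset, dispersion)
  null <- .nb_glm_fit(des$null, obs$y, obs$offset, dispersion)
  if (!isTRUE(full$converged) || !isTRUE(null$converged))
    return(list(p_value = NA_real_, lrt_stat = NA_real_, tested = FALSE))
  lrt <- max(0, 2 * (full$loglik - null$loglik))
  list(p_value = pchisq(lrt, df = 1L, lower.tail = FALSE),
       lrt_stat = lrt, tested = TRUE)
}

#' Independent filtering of low-count bins
#'
#' Keeps a bin iff its mean normalized count (count over size factor,
#' averaged across samples) reaches `min_mean`; the multiple-testing
#' universe downstream consists of the surviving bins only.
#'
#' @param counts a [dtu_counts] or matrix.
#' @param size_factors per-sample size factors.
#' @param min_mean threshold on the mean normalized count (default 5).
#' @return Named logical vector over bins.
#' @export
independent_filter <- function(counts, size_factors, min_mean = 5) {
  m <- if (inherits(counts, "dtu_counts")) counts$counts else counts
  keep <- rowMeans(sweep(m, 2L, size_factors, "/")) >= min_mean
  setNames(keep, rownames(m))
}

#' Gene-level q-values from bin-level p-values
#'
#' Per feature with `n` tested bins and smallest bin p-value `theta`,
#' the gene-level p-value is the Sidak-style family bound
#' `1 - (1 - theta)^n`; Benjamini-Hochberg across features turns these
#' into q-values.
#'
#' @param bin_results data frame with `bin_id`, `feature_id`,
#'   `p_value`, `tested`.
#' @return Data frame `feature_id`, `n_tested_bins`, `min_bin_p`,
#'   `gene_p`, `q_value` (features with zero tested bins are absent).
#' @export
per_gene_qvalues <- function(bin_results) {
  ok <- bin_results$tested & !is.na(bin_results$p_value)
  br <- bin_results[ok, , drop = FALSE]
  if (nrow(br) == 0)
    return(data.frame(feature_id = character(), n_tested_bins = integer(),
                      min_bin_p = numeric(), gene_p = numeric(),
                      q_value = numeric()))
  f <- factor(br$feature_id)
  n <- as.integer(table(f))
  theta <- as.numeric(tapply(br$p_value, f, min))
  gene_p <- -expm1(n * log1p(-pmin(theta, 1)))  # 1 - (1-theta)^n
  gene_p <- pmin(pmax(gene_p, 0), 1)
  data.frame(feature_id = levels(f), n_tested_bins = n,
             min_bin_p = theta, gene_p = gene_p,
             q_value = p.adjust(gene_p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Test a count matrix for differential bin usage
#'
#' The inference engine of the study. For every counting bin that
#' survives independent filtering and has at least one sibling bin in
#' its feature, the bin's counts are compared against the summed
#' counts of the feature's other bins with a negative binomial GLM
#' (log link, size-factor offsets; design: sample effects + bin part +
#' condition:part interaction). Dispersion is estimated per bin by
#' Cox-Reid adjusted profile likelihood, moderated toward a `b0 +
#' b1/mu` trend with a log-normal prior (outliers kept), and the
#' interaction is assessed by a 1-df likelihood ratio test. Bin
#' p-values are aggregated per gene (Sidak family bound +
#' Benjamini-Hochberg across genes).
#'
#' @param counts a [dtu_counts] object (or numeric matrix, with
#'   `feature` supplied).
#' @param conditions vector with one entry per sample, two levels;
#'   condition 2 is the "treatment".
#' @param feature optional bin-to-feature map (named character).
#' @param min_mean independent-filter threshold on mean normalized
#'   counts.
#' @param dispersions optional fixed per-bin dispersions (named);
#'   skips estimation and shrinkage, for calibration studies.
#' @param prior_sd_floor lower bound for the shrinkage prior sd.
#' @return A `dtu_test` object: list with `gene_results` (feature_id,
#'   n_tested_bins, min_bin_p, gene_p, q_value), `bin_results`,
#'   `size_factors`, `trend`, `prior_sd`, `n_filtered`, `conditions`.
#' @export
dtu_test <- function(counts, conditions, feature = NULL, min_mean = 5,
                     dispersions = NULL, prior_sd_floor = 0.25) {
  inp <- build_bin_inputs(counts, feature, conditions)
  cond <- inp$conditions
  if (length(unique(cond)) != 2L || min(table(cond)) < 2L)
    stopf("two conditions with >= 2 samples each are required")
  m <- inp$y
  sf <- estimate_size_factors(m)
  keep <- independent_filter(m, sf, min_mean)
  inp$size_factors <- sf
  bins <- rownames(m)
  run <- keep & inp$testable
  n_run <- sum(run)
  base_mean <- rowMeans(sweep(m, 2L, sf, "/"))
  disp_raw <- rep(NA_real_, length(bins))
  disp_final <- rep(NA_real_, length(bins))
  names(disp_raw) <- names(disp_final) <- bins
  trend <- c(b0 = NA_real_, b1 = NA_real_)
  prior_sd <- NA_real_
  if (n_run > 0) {
    if (is.null(dispersions)) {
      for (i in which(run))
        disp_raw[i] <- estimate_dispersion(m[i, ], inp$o[i, ], cond, sf)
      trend <- fit_dispersion_trend(disp_raw[run], base_mean[run])
      phi_tr <- eval_trend(trend, base_mean)
      slr <- log(disp_raw[run]) - log(phi_tr[run])
      interior <- disp_raw[run] > DISP_BOUNDS[1] * 1.5 &
        disp_raw[run] < DISP_BOUNDS[2] / 1.5
      prior_sd <- max(prior_sd_floor,
                      if (any(interior)) mad(slr[interior]) else 0)
      for (i in which(run))
        disp_final[i] <- shrink_dispersion(m[i, ], inp$o[i, ], cond, sf,
                                           disp_raw[i], phi_tr[i], prior_sd)
    } else {
      disp_raw[bins] <- dispersions[bins]
      disp_final[bins] <- dispersions[bins]
    }
  }
  p <- rep(NA_real_, length(bins)); lrt <- rep(NA_real_, length(bins))
  tested <- rep(FALSE, length(bins))
  for (i in which(run)) {
    res <- test_bin(m[i, ], inp$o[i, ], cond, sf, disp_final[i])
    p[i] <- res$p_value; lrt[i] <- res$lrt_stat; tested[i] <- res$tested
  }
  bin_results <- data.frame(
    bin_id = bins, feature_id = unname(inp$feature),
    base_mean = base_mean, dispersion_raw = disp_raw,
    dispersion = disp_final, lrt_stat = lrt, p_value = p,
    kept = unname(keep), tested = tested,
    stringsAsFactors = FALSE, row.names = NULL)
  gene_results <- per_gene_qvalues(bin_results)
  if (nrow(gene_results) == 0)
    warnf("no testable bins survived filtering")
  structure(list(gene_results = gene_results, bin_results = bin_results,
                 size_factors = sf, trend = trend, prior_sd = prior_sd,
                 n_filtered = sum(!keep), conditions = cond,
                 min_mean = min_mean,
                 call = match.call()),
            class = "dtu_test")
}

#' @export
print.dtu_test <- function(x, ...) {
  cat("Differential bin-usage test (bin-vs-rest NB GLM)\n")
  cat(sprintf("  bins: %d total, %d filtered out, %d tested\n",
              nrow(x$bin_results), x$n_filtered,
              sum(x$bin_results$tested)))
  cat(sprintf("  features with a q-value: %d\n", nrow(x$gene_results)))
  if (nrow(x$gene_results))
    cat(sprintf("  q <= 0.05: %d features\n",
                sum(x$gene_results$q_value <= 0.05)))
  invisible(x)
}

#' @export
summary.dtu_test <- function(object, thresholds = c(0.01, 0.05, 0.1), ...) {
  gr <- object$gene_results
  calls <- vapply(thresholds, function(t) sum(gr$q_value <= t), integer(1))
  out <- list(n_bins = nrow(object$bin_results),
              n_tested = sum(object$bin_results$tested),
              n_features = nrow(gr),
              size_factors = object$size_factors,
              trend = object$trend, prior_sd = object$prior_sd,
              calls = setNames(calls, paste0("q<=", thresholds)))
  class(out) <- "summary.dtu_test"
  out
}

#' @export
print.summary.dtu_test <- function(x, ...) {
  cat("Differential bin-usage test summary\n")
  cat(sprintf("  %d bins (%d tested), %d features\n",
              x$n_bins, x$n_tested, x$n_features))
  cat(sprintf("  dispersion trend: b0=%.4g b1=%.4g (prior sd %.3g)\n",
              x$trend[1], x$trend[2], x$prior_sd))
  cat("  size factors:", paste(sprintf("%.3f", x$size_factors),
                               collapse = " "), "\n")
  cat("  calls:", paste(names(x$calls), x$calls, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.dtu_test <- function(x, ...) {
  br <- x$bin_results[x$bin_results$tested, , drop = FALSE]
  graphics::plot(br$base_mean, br$dispersion_raw, log = "xy", pch = 16,
                 cex = 0.5, col = "grey40",
                 xlab = "mean normalized count", ylab = "dispersion", ...)
  graphics::points(br$base_mean, br$dispersion, pch = 16, cex = 0.5,
                   col = "dodgerblue3")
  if (all(is.finite(x$trend))) {
    mu <- exp(seq(log(max(min(br$base_mean), 0.1)),
                  log(max(br$base_mean)), length.out = 100))
    graphics::lines(mu, eval_trend(x$trend, mu), col = "red", lwd = 2)
  }
  invisible(x)
}

#' Gene-level results table I/O
#'
#' @param x a `dtu_test` or its `gene_results` data frame.
#' @param path TSV path.
#' @return `read_gene_results` returns the data frame; the writer
#'   `path`, invisibly.
#' @export
write_gene_results <- function(x, path) {
  gr <- if (inherits(x, "dtu_test")) x$gene_results else x
  write.table(gr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_results
#' @export
read_gene_results <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
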