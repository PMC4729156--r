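#' Simulation parameters
#'
#' Bundles every tunable of the synthetic study into one list. The
#' defaults encode the study conditions: two conditions with three
#' biological replicates each, a 5% non-specific background, 101-bp
#' paired reads, sample-level isoform fractions drawn from a Dirichlet
#' with the baseline fractions scaled by 100, and differential usage
#' introduced by swapping the two most abundant isoforms of genes with
#' at least two expressed isoforms (relative abundance above 10%) and
#' expected count above 500.
#'
#' Two regimes shift the structural distributions: `"fruitfly_like"`
#' (few isoforms per gene, long exons) and `"human_like"` (many
#' isoforms per gene, short exons). Any regime default can be
#' overridden explicitly.
#'
#' @param n_genes number of genes to simulate.
#' @param regime `"fruitfly_like"` or `"human_like"`.
#' @param n_replicates biological replicates per condition.
#' @param library_size expected total on-target fragment count per
#'   sample (also the scale of the gene-level expected counts). The
#'   default 2e5 is a desk-scale stand-in for the tens of millions of
#'   read pairs of a real experiment.
#' @param background_fraction fraction of fragments from non-specific
#'   background, not stemming from any transcript.
#' @param fragment_length_mean,fragment_length_sd fragment length (bp),
#'   normal, truncated to `[read_length, transcript length]`.
#' @param read_length read length in bp.
#' @param dirichlet_scale concentration multiplier applied to the
#'   baseline isoform fractions when drawing per-sample fractions.
#' @param n_dtu number of genes receiving the isoform switch.
#' @param dtu_min_fraction,dtu_min_count eligibility bounds for the
#'   switch: at least two isoforms with baseline fraction strictly
#'   above `dtu_min_fraction`, expected count strictly above
#'   `dtu_min_count`.
#' @param seed integer master seed; the whole simulation is a pure
#'   function of the parameter list including this seed.
#' @param overlap_rate probability that a gene is placed overlapping
#'   the previous gene's last exon on the same strand (exercises the
#'   gene-aggregation machinery; 0 by default).
#' @param mu_sdlog log-scale spread of the lognormal baseline
#'   expression distribution.
#' @param dispersion_coeffs `c(a0, a1)` of the mean-dispersion
#'   relationship `phi = a0 + a1 / mu`.
#' @param dispersion_jitter_sd lognormal jitter applied to the
#'   per-gene dispersion around the trend.
#' @param dirichlet_alpha symmetric concentration (< 1) of the sparse
#'   baseline isoform-fraction Dirichlet; small values produce a
#'   dominant isoform plus near-zero ones.
#' @param isoform_count_weights named numeric vector: probability of a
#'   gene having 1, 2, ... isoforms (regime default if `NULL`).
#' @param exon_count_weights named numeric vector for exon numbers of
#'   the primary transcript (regime default if `NULL`).
#' @param exon_length_meanlog,exon_length_sdlog,intron_length_meanlog,intron_length_sdlog
#'   lognormal structural distributions (regime defaults if `NULL`).
#' @param gene_gap_range range (bp) of the gap between consecutive
#'   non-overlapping genes.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_genes,
                       regime = c("fruitfly_like", "human_like"),
                       n_replicates = 3L,
                       library_size = 2e5,
                       background_fraction = 0.05,
                       fragment_length_mean = 250,
                       fragment_length_sd = 25,
                       read_length = 101L,
                       dirichlet_scale = 100,
                       n_dtu = round(0.2 * n_genes),
                       dtu_min_fraction = 0.10,
                       dtu_min_count = 500,
                       seed = 1L,
                       overlap_rate = 0,
                       mu_sdlog = 1.2,
                       dispersion_coeffs = c(a0 = 0.01, a1 = 3),
                       dispersion_jitter_sd = 0.3,
                       dirichlet_alpha = 0.7,
                       isoform_count_weights = NULL,
                       exon_count_weights = NULL,
                       exon_length_meanlog = NULL,
                       exon_length_sdlog = NULL,
                       intron_length_meanlog = NULL,
                       intron_length_sdlog = NULL,
                       gene_gap_range = c(1000, 5000)) {
  regime <- match.arg(regime)
  preset <- regime_preset(regime)
  p <- list(
    n_genes = as.integer(n_genes), regime = regime,
    n_replicates = as.integer(n_replicates),
    library_size = library_size,
    background_fraction = background_fraction,
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    read_length = as.integer(read_length),
    dirichlet_scale = dirichlet_scale,
    n_dtu = as.integer(n_dtu),
    dtu_min_fraction = dtu_min_fraction,
    dtu_min_count = dtu_min_count,
    seed = as.integer(seed),
    overlap_rate = overlap_rate,
    mu_sdlog = mu_sdlog,
    dispersion_coeffs = dispersion_coeffs,
    dispersion_jitter_sd = dispersion_jitter_sd,
    dirichlet_alpha = dirichlet_alpha,
    isoform_count_weights = isoform_count_weights %||%
      preset$isoform_count_weights,
    exon_count_weights = exon_count_weights %||% preset$exon_count_weights,
    exon_length_meanlog = exon_length_meanlog %||% preset$exon_length_meanlog,
    exon_length_sdlog = exon_length_sdlog %||% preset$exon_length_sdlog,
    intron_length_meanlog = intron_length_meanlog %||%
      preset$intron_length_meanlog,
    intron_length_sdlog = intron_length_sdlog %||% preset$intron_length_sdlog,
    gene_gap_range = gene_gap_range)
  stopifnot(p$n_genes >= 1, p$n_dtu <= p$n_genes,
            p$background_fraction >= 0, p$background_fraction <= 1,
            p$dtu_min_fraction >= 0, p$dtu_min_fraction <= 1,
            p$overlap_rate >= 0, p$overlap_rate <= 1,
            p$fragment_length_mean >= p$read_length)
  class(p) <- "sim_params"
  p
}

regime_preset <- function(regime) {
  if (regime == "fruitfly_like") {
    list(
      isoform_count_weights = c("1" = 0.15, "2" = 0.45, "3" = 0.30,
                                "4" = 0.10),
      exon_count_weights = setNames(c(0.10, 0.20, 0.22, 0.18, 0.12,
                                      0.10, 0.08), as.character(2:8)),
      exon_length_meanlog = log(400), exon_length_sdlog = 0.6,
      intron_length_meanlog = log(120), intron_length_sdlog = 0.7)
  } else {
    list(
      isoform_count_weights = setNames(
        c(0.05, 0.08, 0.10, 0.12, 0.13, 0.12, 0.11, 0.09, 0.08,
          0.05, 0.04, 0.03), as.character(1:12)),
      exon_count_weights = setNames(rep(1 / 9, 9), as.character(4:12)),
      exon_length_meanlog = log(150), exon_length_sdlog = 0.55,
      intron_length_meanlog = log(800), intron_length_sdlog = 0.9)
  }
}

sample_weighted <- function(weights, n = 1L) {
  as.integer(sample(names(weights), n, replace = TRUE, prob = weights))
}

#' Generate a synthetic transcript catalog
#'
#' Places `n_genes` genes on one synthetic chromosome (`chrS`), by
#' default without overlap. Each gene receives a primary transcript
#' whose exon count/lengths and intron lengths follow the regime's
#' distributions; further isoforms are derived from the primary by
#' random structural edits (internal exon skipping, alternative 5'/3'
#' exon boundaries, intron retention), with duplicate structures
#' rejected, so no two isoforms of a gene are identical.
#'
#' @param params a [sim_params()] list.
#' @return A [dtu_annotation()].
#' @export
generate_annotation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, generate_annotation_impl(params))
}

generate_annotation_impl <- function(params) {
  p <- params
  rows <- vector("list", p$n_genes)
  cursor <- 10000L
  prev <- NULL  # last exon of previous gene + its strand
  for (g in seq_len(p$n_genes)) {
    gid <- sprintf("g%04d", g)
    n_ex <- sample_weighted(p$exon_count_weights)
    ex_len <- pmax(25L, as.integer(round(rlnorm(n_ex,
      p$exon_length_meanlog, p$exon_length_sdlog))))
    in_len <- if (n_ex > 1)
      pmax(30L, as.integer(round(rlnorm(n_ex - 1L,
        p$intron_length_meanlog, p$intron_length_sdlog)))) else integer(0)
    overlap_here <- !is.null(prev) && runif(1) < p$overlap_rate
    if (overlap_here) {
      strand <- prev$strand
      # first exon overlaps the previous gene's last exon by >=10 bp
      start0 <- max(prev$start, prev$end - max(10L, ex_len[1] %/% 2))
    } else {
      strand <- sample(c("+", "-"), 1L)
      start0 <- cursor + as.integer(round(runif(1, p$gene_gap_range[1],
                                                p$gene_gap_range[2])))
    }
    starts <- start0 + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    primary <- data.frame(start = starts, end = ends)
    n_iso <- sample_weighted(p$isoform_count_weights)
    isoforms <- list(primary)
    sigs <- exon_signature(primary)
    for (i in seq_len(max(0L, n_iso - 1L))) {
      for (try in 1:25) {
        cand <- edit_transcript(primary)
        sg <- exon_signature(cand)
        if (!sg %in% sigs) { isoforms <- c(isoforms, list(cand));
                             sigs <- c(sigs, sg); break }
      }
    }
    rows[[g]] <- do.call(rbind, lapply(seq_along(isoforms), function(i) {
      iso <- isoforms[[i]]
      data.frame(gene_id = gid,
                 transcript_id = sprintf("%s_t%02d", gid, i),
                 chrom = "chrS", start = iso$start, end = iso$end,
                 strand = strand, stringsAsFactors = FALSE)
    }))
    cursor <- max(cursor, max(ends))
    prev <- list(start = starts[n_ex], end = ends[n_ex], strand = strand)
  }
  ann <- dtu_annotation(do.call(rbind, rows),
    provenance = sprintf("simulated %s n_genes=%d seed=%d",
                         p$regime, p$n_genes, p$seed))
  validate_annotation(ann)
}

exon_signature <- function(ex) paste(ex$start, ex$end, collapse = ";")

# size-safe single draw (sample() would expand a scalar to 1:x)
resample1 <- function(x) x[sample.int(length(x), 1L)]

# one random structural edit of an exon data.frame (start/end, 0-based)
edit_transcript <- function(ex) {
  n <- nrow(ex)
  moves <- c("alt_boundary",
             if (n >= 3) "skip",
             if (n >= 2) "retain_intron")
  move <- resample1(moves)
  if (move == "skip") {
    drop <- resample1(2:(n - 1))
    ex <- ex[-drop, , drop = FALSE]
  } else if (move == "retain_intron") {
    j <- if (n == 2) 1L else resample1(seq_len(n - 1L))
    ex$end[j] <- ex$end[j + 1L]
    ex <- ex[-(j + 1L), , drop = FALSE]
  } else {
    j <- resample1(seq_len(n))
    w <- ex$end[j] - ex$start[j]
    d <- resample1(10:max(10L, min(150L, w - 20L)))
    d <- min(d, w - 15L)
    if (d >= 5L) {
      if (runif(1) < 0.5) ex$start[j] <- ex$start[j] + d
      else ex$end[j] <- ex$end[j] - d
    }
  }
  rownames(ex) <- NULL
  ex
}

#' Mean-dispersion relationship
#'
#' Maps an expected count to a negative binomial dispersion via
#' `phi = a0 + a1 / mu` (so variance `mu + phi * mu^2`), optionally
#' jittered on the log scale to mimic gene-to-gene scatter around the
#' trend.
#'
#' @param mu positive expected count (vectorized).
#' @param coeffs `c(a0, a1)`, both non-negative.
#' @param jitter_sd standard deviation of lognormal jitter (0 = none).
#' @return Dispersion values, same length as `mu`.
#' @export
dispersion_from_mean <- function(mu, coeffs = c(a0 = 0.01, a1 = 3),
                                 jitter_sd = 0) {
  if (any(mu <= 0)) stopf("mu must be positive")
  phi <- coeffs[[1]] + coeffs[[2]] / mu
  if (jitter_sd > 0)
    phi <- exp(log(phi) + rnorm(length(phi), 0, jitter_sd))
  pmax(phi, 1e-8)
}

#' Fragment-level effective length
#'
#' Number of valid fragment start positions:
#' `max(1, L - fragment_mean + 1)`.
#'
#' @param L length in bp.
#' @param fragment_mean mean fragment length in bp.
#' @return Effective length, floored at 1.
#' @export
effective_length <- function(L, fragment_mean) {
  pmax(1, L - fragment_mean + 1)
}

#' Build the expression model for a catalog
#'
#' Draws a lognormal baseline expected count per gene, rescaled so the
#' expected counts sum to `library_size * (1 - background_fraction)`;
#' pairs it with a dispersion from the mean-dispersion trend; and draws
#' baseline isoform fractions from a sparse symmetric Dirichlet, sorted
#' decreasing so the primary transcript is the most abundant and the
#' smallest fractions are near zero (emulating annotated but
#' essentially non-expressed isoforms). Condition-2 fractions start
#' equal to condition-1; [apply_dtu_swap()] introduces the switch.
#' The effective gene length is the baseline-fraction-weighted mean of
#' the isoform effective lengths.
#'
#' @param ann a [dtu_annotation()].
#' @param params a [sim_params()] list.
#' @return A `dtu_expression_model`: list with `genes` (gene_id, mu,
#'   phi, eff_len) and `isoforms` (transcript_id, gene_id, length,
#'   eff_len, pi_1, pi_2).
#' @export
build_expression_model <- function(ann, params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed + 1L, build_expression_model_impl(ann, params))
}

build_expression_model_impl <- function(ann, params) {
  p <- params
  tt <- transcript_table(ann)
  tt <- tt[order(tt$gene_id, tt$transcript_id), , drop = FALSE]
  gids <- unique(tt$gene_id)
  mu <- rlnorm(length(gids), log(100), p$mu_sdlog)
  mu <- mu / sum(mu) * p$library_size * (1 - p$background_fraction)
  phi <- dispersion_from_mean(mu, p$dispersion_coeffs,
                              p$dispersion_jitter_sd)
  tt$eff_len <- effective_length(tt$length, p$fragment_length_mean)
  pis <- lapply(gids, function(g) {
    k <- sum(tt$gene_id == g)
    sort(rdirichlet1(rep(p$dirichlet_alpha, k)), decreasing = TRUE)
  })
  tt$pi_1 <- unlist(pis)
  tt$pi_2 <- tt$pi_1
  gene_eff <- vapply(seq_along(gids), function(i) {
    sel <- tt$gene_id == gids[i]
    sum(tt$pi_1[sel] * tt$eff_len[sel])
  }, numeric(1))
  structure(list(
    genes = data.frame(gene_id = gids, mu = mu, phi = phi,
                       eff_len = pmax(1, gene_eff),
                       stringsAsFactors = FALSE),
    isoforms = tt[c("transcript_id", "gene_id", "length", "eff_len",
                    "pi_1", "pi_2")],
    params = p), class = "dtu_expression_model")
}

#' @export
print.dtu_expression_model <- function(x, ...) {
  cat(sprintf(
    "dtu_expression_model: %d genes, %d isoforms, sum(mu)=%.0f\n",
    nrow(x$genes), nrow(x$isoforms), sum(x$genes$mu)))
  invisible(x)
}

#' Select genes for the isoform switch
#'
#' Eligible genes have at least two expressed isoforms (baseline
#' fraction strictly above `dtu_min_fraction`) and expected count
#' strictly above `dtu_min_count`; `n_dtu` of them are drawn uniformly.
#' The returned truth table covers *all* genes, recording the DTU
#' status, the swapped pair (the two most abundant isoforms), the
#' isoform count, the isoform dominance difference (gap between the
#' two largest baseline fractions; 1 for single-isoform genes), and the
#' expected count.
#'
#' @param model a [build_expression_model()] result.
#' @param params a [sim_params()] list.
#' @return A data frame (`dtu_truth`).
#' @export
select_dtu_genes <- function(model, params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed + 2L, select_dtu_genes_impl(model, params))
}

select_dtu_genes_impl <- function(model, params) {
  p <- params
  iso <- model$isoforms
  genes <- model$genes
  per_gene <- split(seq_len(nrow(iso)), iso$gene_id)[genes$gene_id]
  n_expr <- vapply(per_gene, function(idx)
    sum(iso$pi_1[idx] > p$dtu_min_fraction), integer(1))
  n_iso <- lengths(per_gene)
  top2 <- t(vapply(per_gene, function(idx) {
    ord <- idx[order(-iso$pi_1[idx], iso$transcript_id[idx])]
    if (length(ord) >= 2)
      c(iso$transcript_id[ord[1]], iso$transcript_id[ord[2]])
    else c(iso$transcript_id[ord[1]], NA_character_)
  }, character(2)))
  dom <- vapply(per_gene, function(idx) {
    pi_s <- sort(iso$pi_1[idx], decreasing = TRUE)
    if (length(pi_s) >= 2) pi_s[1] - pi_s[2] else 1
  }, numeric(1))
  eligible <- n_expr >= 2 & genes$mu > p$dtu_min_count
  if (sum(eligible) < p$n_dtu)
    stopf("only %d of %d genes eligible for DTU, need %d",
          sum(eligible), nrow(genes), p$n_dtu)
  chosen <- sample(genes$gene_id[eligible], p$n_dtu)
  dtu <- genes$gene_id %in% chosen
  truth <- data.frame(
    gene_id = genes$gene_id,
    dtu_status = dtu,
    swapped_1 = ifelse(dtu, top2[, 1], NA_character_),
    swapped_2 = ifelse(dtu, top2[, 2], NA_character_),
    n_isoforms = as.integer(n_iso),
    dominance_diff = dom,
    expected_count = genes$mu,
    stringsAsFactors = FALSE)
  class(truth) <- c("dtu_truth", "data.frame")
  truth
}

#' Introduce the isoform switch
#'
#' For each DTU gene the condition-2 fractions equal the condition-1
#' fractions with the values of the two most abundant isoforms
#' exchanged; every other gene, and every expected gene count, is left
#' untouched, so there is no gene-level differential expression by
#' construction.
#'
#' @param model a [build_expression_model()] result.
#' @param truth a truth table from [select_dtu_genes()].
#' @return The modified model.
#' @export
apply_dtu_swap <- function(model, truth) {
  iso <- model$isoforms
  for (i in which(truth$dtu_status)) {
    a <- match(truth$swapped_1[i], iso$transcript_id)
    b <- match(truth$swapped_2[i], iso$transcript_id)
    if (is.na(a) || is.na(b))
      stopf("gene %s has fewer than two isoforms to swap",
            truth$gene_id[i])
    iso$pi_2[c(a, b)] <- iso$pi_1[c(b, a)]
  }
  model$isoforms <- iso
  model
}

#' Realize one sample's expression
#'
#' Draws the gene count from a negative binomial with the gene's mean
#' and dispersion (variance `mu + phi mu^2`), converts it to reads per
#' kilobase of effective gene length (RPK), draws sample-level isoform
#' fractions from a Dirichlet with parameters
#' `dirichlet_scale * pi^(condition)` (isoforms with exactly-zero
#' baseline fraction are excluded and stay at zero), splits the gene
#' RPK by those fractions, rescales to TPM (summing to 1e6), and
#' derives the expected fragment weight of each isoform as
#' `TPM * effective length`, normalized over the transcriptome.
#'
#' @param model a (possibly swapped) expression model.
#' @param condition 1 or 2.
#' @param sample_id sample label.
#' @param params a [sim_params()] list.
#' @param seed RNG seed for this sample's draws.
#' @return A `dtu_sample_expression` list.
#' @export
simulate_sample_expression <- function(model, condition, sample_id, params,
                                       seed) {
  stopifnot(condition %in% c(1, 2))
  with_seed(seed,
    simulate_sample_expression_impl(model, condition, sample_id, params))
}

simulate_sample_expression_impl <- function(model, condition, sample_id,
                                            params) {
  p <- params
  genes <- model$genes
  iso <- model$isoforms
  k <- rnbinom(nrow(genes), mu = genes$mu, size = 1 / genes$phi)
  gene_rpk <- k / (genes$eff_len / 1000)
  pi_c <- if (condition == 1) iso$pi_1 else iso$pi_2
  frac <- numeric(nrow(iso))
  idx_by_gene <- split(seq_len(nrow(iso)), iso$gene_id)[genes$gene_id]
  for (gi in seq_along(idx_by_gene)) {
    idx <- idx_by_gene[[gi]]
    if (length(idx) == 1L) { frac[idx] <- 1; next }
    frac[idx] <- rdirichlet1(p$dirichlet_scale * pi_c[idx])
  }
  iso_rpk <- gene_rpk[match(iso$gene_id, genes$gene_id)] * frac
  tot <- sum(iso_rpk)
  tpm <- if (tot > 0) 1e6 * iso_rpk / tot else iso_rpk
  w <- tpm * iso$eff_len
  w <- if (sum(w) > 0) w / sum(w) else w
  structure(list(
    sample_id = sample_id, condition = condition,
    genes = data.frame(gene_id = genes$gene_id, count = k,
                       rpk = gene_rpk, stringsAsFactors = FALSE),
    isoforms = data.frame(transcript_id = iso$transcript_id,
                          gene_id = iso$gene_id, fraction = frac,
                          rpk = iso_rpk, tpm = tpm, weight = w,
                          stringsAsFactors = FALSE)),
    class = "dtu_sample_expression")
}

#' Simulate paired-end fragments for one sample
#'
#' Draws `library_size` fragments: a `background_fraction` share placed
#' uniformly on the synthetic chromosome (unspliced single-block
#' mates, not stemming from any transcript), the rest assigned to
#' transcripts multinomially by the sample's expected fragment weights.
#' Fragment length is normal (`fragment_length_mean`,
#' `fragment_length_sd`) truncated to `[read_length, transcript
#' length]`; the start is uniform over the valid positions; the two
#' mates are the genomic projections of the first and last
#' `read_length` transcript bases, split across exons as needed.
#' Transcripts shorter than the read length are excluded from sampling
#' with a warning if they carried weight.
#'
#' @param ann a [dtu_annotation()].
#' @param sample_expr a [simulate_sample_expression()] result.
#' @param params a [sim_params()] list.
#' @param seed RNG seed for this sample's fragment draws.
#' @return A `dtu_fragments` object: list with `fragments` (data frame
#'   `fragment_id`, `origin`, `sample_id`) and `blocks` (data frame
#'   `frag` (row index into `fragments`), `mate`, `chrom`, `start`,
#'   `end`).
#' @export
simulate_fragments <- function(ann, sample_expr, params, seed) {
  with_seed(seed, simulate_fragments_impl(ann, sample_expr, params))
}

simulate_fragments_impl <- function(ann, sample_expr, params) {
  p <- params
  iso <- sample_expr$isoforms
  tt <- transcript_table(ann)
  len <- tt$length[match(iso$transcript_id, tt$transcript_id)]
  w <- iso$weight
  short <- len < p$read_length
  if (any(short & w > 0)) {
    warnf("%d transcript(s) shorter than the read length excluded from fragment sampling",
          sum(short & w > 0))
    w[short] <- 0
    w <- w / sum(w)
  }
  n_total <- as.integer(round(p$library_size))
  n_bg <- as.integer(round(p$background_fraction * n_total))
  n_fg <- n_total - n_bg
  counts <- as.integer(rmultinom(1, n_fg, w))
  exons_by_tx <- split(seq_len(nrow(ann)), ann$transcript_id)
  blocks_l <- list()
  origin <- character(0)
  frag_off <- 0L
  for (ti in which(counts > 0)) {
    tx <- iso$transcript_id[ti]
    idx <- exons_by_tx[[tx]]
    ex_start <- ann$start[idx]; ex_width <- ann$end[idx] - ann$start[idx]
    L <- sum(ex_width)
    nf <- counts[ti]
    fl <- pmin(pmax(as.integer(round(rnorm(nf, p$fragment_length_mean,
      p$fragment_length_sd))), p$read_length), L)
    start <- floor(runif(nf, 0, L - fl + 1))
    b1 <- project_tx_range(ex_start, ex_width, start, start + p$read_length)
    b2 <- project_tx_range(ex_start, ex_width, start + fl - p$read_length,
                           start + fl)
    b1$mate <- 1L; b2$mate <- 2L
    bb <- rbind(b1, b2)
    bb$frag <- bb$row + frag_off
    blocks_l[[length(blocks_l) + 1L]] <- bb[c("frag", "mate", "start", "end")]
    origin <- c(origin, rep(tx, nf))
    frag_off <- frag_off + nf
  }
  if (n_bg > 0) {
    chrom_len <- max(ann$end) + 10000L
    fl <- pmax(as.integer(round(rnorm(n_bg, p$fragment_length_mean,
      p$fragment_length_sd))), p$read_length)
    start <- floor(runif(n_bg, 0, chrom_len - fl + 1))
    bb <- data.frame(
      frag = rep(frag_off + seq_len(n_bg), 2L),
      mate = rep(1:2, each = n_bg),
      start = c(start, start + fl - p$read_length),
      end = c(start + p$read_length, start + fl))
    blocks_l[[length(blocks_l) + 1L]] <- bb
    origin <- c(origin, rep("background", n_bg))
    frag_off <- frag_off + n_bg
  }
  blocks <- do.call(rbind, blocks_l) %||%
    data.frame(frag = integer(), mate = integer(),
               start = integer(), end = integer())
  blocks <- blocks[order(blocks$frag, blocks$mate, blocks$start), ,
                   drop = FALSE]
  rownames(blocks) <- NULL
  blocks$chrom <- if (nrow(ann)) ann$chrom[1] else "chrS"
  frags <- data.frame(
    fragment_id = sprintf("%s_f%07d", sample_expr$sample_id,
                          seq_len(frag_off)),
    origin = origin, sample_id = sample_expr$sample_id,
    stringsAsFactors = FALSE)
  structure(list(fragments = frags,
                 blocks = blocks[c("frag", "mate", "chrom", "start", "end")]),
            class = "dtu_fragments")
}

#' @export
print.dtu_fragments <- function(x, ...) {
  cat(sprintf("dtu_fragments: %d fragments (%d background), %d sample(s)\n",
              nrow(x$fragments), sum(x$fragments$origin == "background"),
              length(unique(x$fragments$sample_id))))
  invisible(x)
}

# genomic projection of transcript-coordinate ranges [a, b)
# (vectorized over fragments of one transcript); returns one row per
# genomic block with the originating fragment in `row`
project_tx_range <- function(ex_start, ex_width, a, b) {
  cum <- c(0L, cumsum(ex_width))
  i <- findInterval(a, cum, rightmost.closed = FALSE)        # first exon
  j <- findInterval(b - 1L, cum, rightmost.closed = FALSE)   # last exon
  n_blocks <- j - i + 1L
  row <- rep(seq_along(a), n_blocks)
  exon <- unlist(lapply(seq_along(a), function(k) i[k]:j[k]))
  gs <- ex_start[exon] + pmax(0, a[row] - cum[exon])
  ge <- ex_start[exon] + pmin(ex_width[exon], b[row] - cum[exon])
  data.frame(row = row, start = as.integer(gs), end = as.integer(ge))
}

# concatenate per-sample fragment objects into one
combine_fragments <- function(frag_list) {
  offs <- cumsum(c(0L, vapply(frag_list,
    function(f) nrow(f$fragments), integer(1))))
  frags <- do.call(rbind, lapply(frag_list, `[[`, "fragments"))
  blocks <- do.call(rbind, lapply(seq_along(frag_list), function(i) {
    b <- frag_list[[i]]$blocks
    b$frag <- b$frag + offs[i]
    b
  }))
  rownames(frags) <- rownames(blocks) <- NULL
  structure(list(fragments = frags, blocks = blocks),
            class = "dtu_fragments")
}

#' Simulate a complete two-condition experiment
#'
#' Convenience wrapper running the whole generative cascade: catalog,
#' expression model, DTU gene selection, isoform switch, and per-sample
#' expression and fragments for `n_replicates` samples per condition
#' (condition-2 samples come after condition-1 samples).
#'
#' @param params a [sim_params()] list.
#' @return List with `annotation`, `model` (post-swap), `truth`,
#'   `samples` (data frame `sample_id`, `condition`), `expression`
#'   (per-sample list) and `fragments` (per-sample list).
#' @export
simulate_experiment <- function(params) {
  ann <- generate_annotation(params)
  model <- build_expression_model(ann, params)
  truth <- select_dtu_genes(model, params)
  model <- apply_dtu_swap(model, truth)
  n_rep <- params$n_replicates
  samples <- data.frame(
    sample_id = sprintf("sample%d", seq_len(2 * n_rep)),
    condition = rep(1:2, each = n_rep), stringsAsFactors = FALSE)
  expr <- vector("list", nrow(samples))
  frags <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    expr[[s]] <- simulate_sample_expression(model, samples$condition[s],
      samples$sample_id[s], params, seed = params$seed + 100L + s)
    frags[[s]] <- simulate_fragments(ann, expr[[s]], params,
      seed = params$seed + 200L + s)
  }
  names(expr) <- names(frags) <- samples$sample_id
  list(annotation = ann, model = model, truth = truth, samples = samples,
       expression = expr, fragments = frags)
}

#' Truth-table I/O
#'
#' Plain TSV round trip of the simulated ground truth; extra columns
#' are preserved.
#'
#' @param truth a truth table.
#' @param path file path.
#' @return `read_truth` returns the table; `write_truth` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stopf("truth table not found: %s", path)
  truth <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  need <- c("gene_id", "dtu_status")
  miss <- setdiff(need, names(truth))
  if (length(miss))
    stopf("truth table missing column(s): %s", paste(miss, collapse = ", "))
  class(truth) <- c("dtu_truth", "data.frame")
  truth
}

#' Fragment I/O in BED12
#'
#' One BED12 line per mate; the name field encodes
#' `fragment_id|origin/mate` so that a round trip preserves the
#' fragment's originating transcript.
#'
#' @param frags a `dtu_fragments` object.
#' @param path file path.
#' @param sample_id sample label to attach on read.
#' @return `read_fragments_bed12` returns a `dtu_fragments` object;
#'   the writer returns `path` invisibly.
#' @export
write_fragments_bed12 <- function(frags, path) {
  b <- frags$blocks
  key <- paste(b$frag, b$mate)
  first <- !duplicated(key)
  grp <- match(key, key[first])
  cs <- tapply(b$start, grp, min)
  ce <- tapply(b$end, grp, max)
  sizes <- vapply(split(b$end - b$start, grp), paste, "", collapse = ",")
  rel <- vapply(split(b$start, grp),
                function(s) paste(s - min(s), collapse = ","), "")
  nb <- as.integer(table(grp))
  fr <- b$frag[first]; mt <- b$mate[first]
  lines <- sprintf("%s\t%d\t%d\t%s|%s/%d\t0\t.\t%d\t%d\t0\t%d\t%s\t%s",
    b$chrom[first], cs, ce,
    frags$fragments$fragment_id[fr], frags$fragments$origin[fr], mt,
    cs, ce, nb, sizes, rel)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fragments_bed12
#' @export
read_fragments_bed12 <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stopf("fragment file not found: %s", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  name <- tab$V4
  mate <- as.integer(sub(".*/", "", name))
  id_origin <- sub("/[0-9]+$", "", name)
  fragment_id <- sub("\\|.*", "", id_origin)
  origin <- sub(".*\\|", "", id_origin)
  uid <- unique(fragment_id)
  frag <- match(fragment_id, uid)
  sizes <- strsplit(tab$V11, ",")
  rel <- strsplit(tab$V12, ",")
  nb <- lengths(sizes)
  row <- rep(seq_len(nrow(tab)), nb)
  bstart <- tab$V2[row] + as.integer(unlist(rel))
  bend <- bstart + as.integer(unlist(sizes))
  blocks <- data.frame(frag = frag[row], mate = mate[row],
                       chrom = tab$V1[row], start = bstart, end = bend,
                       stringsAsFactors = FALSE)
  blocks <- blocks[order(blocks$frag, blocks$mate, blocks$start), ,
                   drop = FALSE]
  rownames(blocks) <- NULL
  frags <- data.frame(
    fragment_id = uid,
    origin = origin[match(uid, fragment_id)],
    sample_id = sample_id %||% sub("_f[0-9]+$", "", uid),
    stringsAsFactors = FALSE)
  structure(list(fragments = frags, blocks = blocks),
            class = "dtu_fragments")
}
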