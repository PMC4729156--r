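#' Count matrices
#'
#' A `dtu_counts` object holds the bins-by-samples count table produced
#' by one counting paradigm: a numeric matrix `counts` (rownames = bin
#' ids, colnames = sample ids), the parallel `feature` map (named
#' character vector, bin id to gene/complex id) and the `bin_type`.
#' Counts are integers except for EM output, which is real-valued and
#' rounded only on export / before model fitting.
#'
#' @name dtu_counts
NULL

new_counts <- function(counts, feature, bin_type) {
  stopifnot(is.matrix(counts), nrow(counts) == length(feature),
            all(names(feature) == rownames(counts)))
  structure(list(counts = counts, feature = feature, bin_type = bin_type),
            class = "dtu_counts")
}

#' @export
print.dtu_counts <- function(x, ...) {
  cat(sprintf("dtu_counts: %d bins x %d samples (%s), total %.0f\n",
              nrow(x$counts), ncol(x$counts), x$bin_type, sum(x$counts)))
  invisible(x)
}

frag_samples <- function(frags) sort(unique(frags$fragments$sample_id))

#' Count fragments into flat or exon bins
#'
#' A fragment adds one count to *every* bin overlapped (by at least
#' 1 bp) by the union of its two mates' blocks -- at most one count per
#' (fragment, bin) pair even when both mates hit the bin. Fragments
#' overlapping several bins are therefore multi-assigned, and column
#' sums can exceed the number of fragments. Background fragments are
#' counted wherever they happen to overlap.
#'
#' @param frags a `dtu_fragments` object (one or more samples).
#' @param binset a [dtu_binset] of type `flat` or `exon`.
#' @return A [dtu_counts] object.
#' @export
count_flat_or_exon <- function(frags, binset) {
  if (!all(binset$bins$bin_type %in% c("flat", "exon")))
    stopf("count_flat_or_exon needs a flat or exon bin set")
  samples <- frag_samples(frags)
  b <- frags$blocks
  iv <- binset$intervals
  hits_frag <- integer(0); hits_bin <- integer(0)
  for (ch in unique(iv$chrom)) {
    bi <- which(iv$chrom == ch)
    fi <- which(b$chrom == ch)
    if (!length(bi) || !length(fi)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(b$start[fi] + 1L, b$end[fi]),
      IRanges::IRanges(iv$start[bi] + 1L, iv$end[bi]))
    hits_frag <- c(hits_frag, b$frag[fi][S4Vectors::queryHits(ov)])
    hits_bin <- c(hits_bin, bi[S4Vectors::subjectHits(ov)])
  }
  bin_of_iv <- match(iv$bin_id, binset$bins$bin_id)
  tally_hits(hits_frag, bin_of_iv[hits_bin], frags, binset, samples)
}

#' Count junction-spanning fragments
#'
#' A fragment supports junction `(d, a)` iff either mate has two
#' consecutive blocks ending exactly at `d` and starting exactly at
#' `a`; fragments lying completely within exons contribute nothing.
#'
#' @param frags a `dtu_fragments` object.
#' @param binset a [dtu_binset] of type `junction`.
#' @return A [dtu_counts] object.
#' @export
count_junctions <- function(frags, binset) {
  if (!all(binset$bins$bin_type == "junction"))
    stopf("count_junctions needs a junction bin set")
  samples <- frag_samples(frags)
  b <- frags$blocks
  n <- nrow(b)
  jx_frag <- integer(0); jx_bin <- integer(0)
  if (n > 1) {
    same <- b$frag[-1] == b$frag[-n] & b$mate[-1] == b$mate[-n]
    i <- which(same)
    if (length(i)) {
      key <- paste(b$chrom[i], b$end[i], b$start[i + 1L])
      bkey <- paste(binset$intervals$chrom[match(binset$bins$bin_id,
                                                 binset$intervals$bin_id)],
                    binset$bins$donor, binset$bins$acceptor)
      lut <- split(seq_len(nrow(binset$bins)), bkey)
      hit <- lut[key]
      nh <- lengths(hit); nh[is.na(names(hit))] <- 0L
      jx_frag <- rep(b$frag[i], nh)
      jx_bin <- unlist(hit, use.names = FALSE)
    }
  }
  tally_hits(jx_frag, jx_bin, frags, binset, samples)
}

# de-duplicate (fragment, bin) pairs and tabulate per sample
tally_hits <- function(hit_frag, hit_bin, frags, binset, samples) {
  nb <- nrow(binset$bins)
  counts <- matrix(0L, nb, length(samples),
                   dimnames = list(binset$bins$bin_id, samples))
  if (length(hit_frag)) {
    # numeric pair key (exact below 2^53) is much faster than
    # row-wise duplicated() on a two-column matrix
    dup <- duplicated(as.numeric(hit_frag) * (nb + 1) + hit_bin)
    hit_frag <- hit_frag[!dup]; hit_bin <- hit_bin[!dup]
    smp <- factor(frags$fragments$sample_id[hit_frag], levels = samples)
    tab <- table(factor(hit_bin, levels = seq_len(nb)), smp)
    counts[] <- as.integer(tab)
  }
  new_counts(counts, setNames(binset$bins$feature_id, binset$bins$bin_id),
             binset$bins$bin_type[1] %||% "flat")
}

#' Build transcript equivalence classes
#'
#' A fragment is compatible with a transcript iff every block of both
#' mates lies within an exon of the transcript and every internal block
#' boundary coincides exactly with one of the transcript's splice
#' junctions. The equivalence class of a fragment is the set of
#' transcripts it is compatible with; fragments compatible with no
#' transcript (including most background fragments) are discarded and
#' tallied.
#'
#' @param frags a `dtu_fragments` object.
#' @param ann a [dtu_annotation()].
#' @return List with `transcripts` (list of transcript-id sets per
#'   class), `counts` (classes x samples integer matrix) and
#'   `n_incompatible` (named vector per sample).
#' @export
build_equivalence_classes <- function(frags, ann) {
  validate_annotation(ann)
  samples <- frag_samples(frags)
  b <- frags$blocks
  n <- nrow(b)
  tx_ids <- unique(ann$transcript_id)
  # containment: block fully inside an exon
  ov <- IRanges::findOverlaps(
    IRanges::IRanges(b$start + 1L, b$end),
    IRanges::IRanges(ann$start + 1L, ann$end), type = "within")
  # (chrom ignored inside: single synthetic chromosome is the common
  # case; guard anyway)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  keep <- b$chrom[qh] == ann$chrom[sh]
  qh <- qh[keep]; sh <- sh[keep]
  tx_hit <- match(ann$transcript_id[sh], tx_ids)
  # count contained blocks per (mate, transcript); a block fits at most
  # one exon of a transcript, so plain tallying is exact
  mate_key <- paste(b$frag, b$mate)
  mate_id <- match(mate_key, unique(mate_key))
  n_blocks <- tabulate(mate_id)
  ok_pairs <- compat_pairs(b, mate_id, n_blocks, mate_id[qh], tx_hit,
                           ann, tx_ids)
  # fragment compatible iff both mates are
  frag_of_mate <- b$frag[!duplicated(mate_id)]
  fkey <- paste(frag_of_mate[ok_pairs$mate], ok_pairs$tx)
  cnt <- tapply(rep(1L, length(fkey)), fkey, sum)
  both <- cnt[cnt == 2]  # both mates compatible
  if (length(both)) {
    parts <- strsplit(names(both), " ")
    cf <- as.integer(vapply(parts, `[`, "", 1L))
    ct <- as.integer(vapply(parts, `[`, "", 2L))
    o <- order(cf, ct)
    cf <- cf[o]; ct <- ct[o]
    ec_key <- vapply(split(ct, cf), paste, "", collapse = ",")
    ec_frag <- as.integer(names(ec_key))
  } else {
    ec_key <- character(0); ec_frag <- integer(0)
  }
  uniq <- sort(unique(ec_key))
  counts <- matrix(0L, length(uniq), length(samples),
                   dimnames = list(NULL, samples))
  if (length(ec_frag)) {
    tab <- table(factor(ec_key, levels = uniq),
                 factor(frags$fragments$sample_id[ec_frag],
                        levels = samples))
    counts[] <- as.integer(tab)
  }
  total <- table(factor(frags$fragments$sample_id, levels = samples))
  n_incomp <- as.integer(total) - colSums(counts)
  list(transcripts = lapply(strsplit(uniq, ","),
                            function(i) tx_ids[as.integer(i)]),
       counts = counts,
       n_incompatible = setNames(n_incomp, samples))
}

# mates compatible with transcripts: containment of all blocks +
# junction match of all internal block boundaries (vectorized)
compat_pairs <- function(b, mate_id, n_blocks, hit_mate, hit_tx,
                         ann, tx_ids) {
  if (!length(hit_mate))
    return(data.frame(mate = integer(), tx = integer()))
  agg <- rowsum(rep(1L, length(hit_mate)), paste(hit_mate, hit_tx))
  parts <- strsplit(rownames(agg), " ")
  mid <- as.integer(vapply(parts, `[`, "", 1L))
  tx <- as.integer(vapply(parts, `[`, "", 2L))
  full <- as.integer(agg) == n_blocks[mid]
  mid <- mid[full]; tx <- tx[full]
  if (!length(mid))
    return(data.frame(mate = integer(), tx = integer()))
  # internal boundaries per mate
  n <- nrow(b)
  same <- if (n > 1) mate_id[-1] == mate_id[-n] else logical(0)
  i <- which(same)
  if (!length(i)) return(data.frame(mate = mid, tx = tx))
  bkey <- paste(b$chrom[i], b$end[i], b$start[i + 1L])
  bnd_by_mate <- split(bkey, mate_id[i])
  jx <- transcript_junctions(ann)
  jx_set <- paste(match(jx$transcript_id, tx_ids),
                  paste(jx$chrom, jx$donor, jx$acceptor))
  has_bnd <- as.character(mid) %in% names(bnd_by_mate)
  ok <- rep(TRUE, length(mid))
  if (any(has_bnd)) {
    sel <- which(has_bnd)
    bl <- bnd_by_mate[as.character(mid[sel])]
    nl <- lengths(bl)
    pair <- rep(sel, nl)
    match_ok <- paste(tx[pair], unlist(bl, use.names = FALSE)) %in% jx_set
    bad <- rowsum(as.integer(!match_ok), pair)
    ok[as.integer(rownames(bad))] <- bad[, 1] == 0L
  }
  data.frame(mate = mid[ok], tx = tx[ok])
}

#' Quantify transcripts from equivalence classes by EM
#'
#' Standard abundance EM: the E-step splits each class's count among
#' its member transcripts proportionally to `theta_t / eff_len_t`, the
#' M-step renormalizes `theta`. Initialization is uniform; convergence
#' when `max |delta theta| < tol` or after `max_iter` iterations. The
#' output re-expresses the converged weights as expected fragment
#' counts per transcript (summing to the compatible-fragment total per
#' sample). The per-iteration log-likelihood trace of the last sample
#' processed is attached as attribute `loglik`.
#'
#' @param ecs result of [build_equivalence_classes()].
#' @param effective_lengths named vector of transcript effective
#'   lengths (>= 1).
#' @param ann optional [dtu_annotation()] supplying the
#'   transcript-to-gene map (features fall back to the transcript's own
#'   id when absent).
#' @param max_iter,tol EM controls.
#' @return A [dtu_counts] with `bin_type = "transcript"` and
#'   real-valued counts.
#' @export
em_quantify <- function(ecs, effective_lengths, ann = NULL,
                        max_iter = 1000L, tol = 1e-8) {
  tx <- sort(unique(unlist(ecs$transcripts)))
  samples <- colnames(ecs$counts)
  out <- matrix(0, length(tx), length(samples),
                dimnames = list(tx, samples))
  loglik <- numeric(0)
  if (length(tx)) {
    if (!all(tx %in% names(effective_lengths)))
      stopf("missing effective length for transcript(s): %s",
            paste(head(setdiff(tx, names(effective_lengths)), 3),
                  collapse = ", "))
    L <- pmax(1, effective_lengths[tx])
    memb <- lapply(ecs$transcripts, match, tx)
    ec_of <- rep(seq_along(memb), lengths(memb))
    tx_of <- unlist(memb)
    for (s in seq_along(samples)) {
      cts <- ecs$counts[, s]
      N <- sum(cts)
      if (N == 0) next
      theta <- rep(1 / length(tx), length(tx))
      ll <- numeric(0)
      for (it in seq_len(max_iter)) {
        alpha <- theta / L
        denom <- vapply(split(alpha[tx_of], ec_of), sum, numeric(1))
        ll <- c(ll, sum(cts[denom > 0] * log(denom[denom > 0])))
        share <- alpha[tx_of] / denom[ec_of] * cts[ec_of]
        n_t <- vapply(split(share, factor(tx_of,
          levels = seq_along(tx))), sum, numeric(1))
        theta_new <- n_t / N
        if (max(abs(theta_new - theta)) < tol) { theta <- theta_new; break }
        theta <- theta_new
      }
      out[, s] <- theta * N
      loglik <- ll
    }
  }
  feature <- setNames(tx, tx)
  if (!is.null(ann)) {
    tt <- transcript_table(ann)
    hit <- match(tx, tt$transcript_id)
    feature[!is.na(hit)] <- tt$gene_id[hit[!is.na(hit)]]
  }
  res <- new_counts(out, feature, "transcript")
  attr(res, "loglik") <- loglik
  attr(res, "n_incompatible") <- ecs$n_incompatible
  res
}

#' Count-matrix I/O
#'
#' Writes the count table as TSV (`bin_id` column + one column per
#' sample; EM output rounded to 1e-6) together with the two-column
#' bin-to-feature map consumed by the testing step, and reads the pair
#' back.
#'
#' @param counts a [dtu_counts] object.
#' @param path counts TSV path; the feature map lands next to it with
#'   suffix `.features.tsv`.
#' @return `read_counts` returns a [dtu_counts]; the writer `path`,
#'   invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(bin_id = rownames(counts$counts),
                   round(counts$counts, 6), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(bin_id = names(counts$feature),
                    feature_id = unname(counts$feature),
                    bin_type = counts$bin_type)
  write.table(map, feature_map_path(path), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  map <- read.table(feature_map_path(path), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$bin_id
  new_counts(m, setNames(map$feature_id, map$bin_id), map$bin_type[1])
}

feature_map_path <- function(path) sub("(\\.tsv)?$", ".features.tsv",
                                       path, perl = TRUE)
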