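# Independent oracles and toy-data builders shared across the tests.
# Everything here is deliberately brute-force: per-base projections,
# grid searches, direct enumeration -- never the package's own code path.

# --- toy annotation generator -------------------------------------------

# random catalog of <= n_genes small genes on chrS; gene starts may
# collide (uniform placement in a shared window), exercising overlap
# handling; callers control the RNG seed
random_toy_annotation <- function(n_genes = 3, max_iso = 4,
                                  window = 4000) {
  rows <- list()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("tg%02d", g)
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(2:4, 1)
    ex_len <- sample(20:150, n_ex, replace = TRUE)
    introns <- sample(20:120, max(n_ex - 1, 1), replace = TRUE)
    start0 <- sample.int(window, 1)
    starts <- start0 + c(0, cumsum(ex_len[-n_ex] + introns[seq_len(n_ex - 1)]))
    ends <- starts + ex_len
    n_iso <- sample(seq_len(max_iso), 1)
    for (i in seq_len(n_iso)) {
      keep <- sort(sample(n_ex, sample(n_ex, 1)))
      s <- starts[keep]; e <- ends[keep]
      # random inward trims, keeping >= 10 bp exons
      trim <- pmin(sample(0:8, length(keep), replace = TRUE),
                   (e - s - 10) %/% 2)
      s <- s + trim; e <- e - trim
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gid, transcript_id = sprintf("%s_i%02d", gid, i),
        chrom = "chrS", start = s, end = e, strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  dtu_annotation(do.call(rbind, rows), provenance = "toy")
}

# --- per-base projection oracle for flatten() ---------------------------

# covering transcript ids per base of one gene set
base_cover <- function(ex, positions) {
  lapply(positions, function(p)
    sort(unique(ex$transcript_id[ex$start <= p & p < ex$end])))
}

# per-base gene coverage over all genes; returns data.frame(pos, gene_id)
gene_base_table <- function(ann) {
  ex <- as.data.frame(ann)
  rows <- lapply(seq_len(nrow(ex)), function(i)
    data.frame(pos = seq(ex$start[i], ex$end[i] - 1L),
               gene_id = ex$gene_id[i], strand = ex$strand[i],
               stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}

# brute-force flatten: label every base with its covering transcript
# set, then run-length-encode maximal runs with identical sets
oracle_flatten <- function(ann, mode) {
  ex_all <- as.data.frame(ann)
  gb <- gene_base_table(ann)
  genes <- sort(unique(ex_all$gene_id))
  gene_strand <- vapply(genes, function(g)
    ex_all$strand[ex_all$gene_id == g][1], "")
  if (mode == "aggregate") {
    # same-strand base sharing links genes; transitive closure
    comp <- as.list(genes); names(comp) <- genes
    assign_of <- setNames(genes, genes)
    for (p in unique(gb$pos)) {
      here <- gb[gb$pos == p, ]
      for (s in unique(here$strand)) {
        gs <- unique(here$gene_id[here$strand == s])
        if (length(gs) >= 2) {
          roots <- unique(assign_of[gs])
          tgt <- min(roots)
          assign_of[assign_of %in% roots] <- tgt
        }
      }
    }
    features <- split(names(assign_of), assign_of)
    names(features) <- vapply(features, function(x)
      paste(sort(x), collapse = "+"), "")
  } else {
    # exclusion is decided per base inside the feature loop below
    features <- as.list(genes)
    names(features) <- genes
  }
  out <- list()
  for (fid in names(features)) {
    ex <- ex_all[ex_all$gene_id %in% features[[fid]], , drop = FALSE]
    positions <- sort(unique(unlist(lapply(seq_len(nrow(ex)), function(i)
      seq(ex$start[i], ex$end[i] - 1L)))))
    if (mode != "aggregate") {
      strand <- gene_strand[[fid]]
      shared <- vapply(positions, function(p) {
        here <- gb[gb$pos == p, ]
        if (mode == "exclude_same_strand")
          here <- here[here$strand == strand, , drop = FALSE]
        length(unique(here$gene_id)) >= 2
      }, logical(1))
      positions <- positions[!shared]
    }
    if (!length(positions)) next
    covers <- vapply(base_cover(ex, positions), paste, "", collapse = ",")
    brk <- c(TRUE, diff(positions) != 1 |
               covers[-1] != covers[-length(covers)])
    run <- cumsum(brk)
    out[[fid]] <- data.frame(
      feature_id = fid,
      start = as.integer(tapply(positions, run, min)),
      end = as.integer(tapply(positions, run, max)) + 1L,
      members = as.character(tapply(covers, run, `[`, 1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(feature_id = character(), start = integer(),
                      end = integer(), members = character())
  res <- res[order(res$feature_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# normalize a flatten() binset to the oracle's shape
binset_as_table <- function(bs) {
  iv <- bs$intervals
  mem <- vapply(bs$members[iv$bin_id], paste, "", collapse = ",")
  out <- data.frame(
    feature_id = bs$bins$feature_id[match(iv$bin_id, bs$bins$bin_id)],
    start = iv$start, end = iv$end, members = unname(mem),
    stringsAsFactors = FALSE)
  out <- out[order(out$feature_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

expect_flatten_matches_oracle <- function(ann, mode) {
  got <- binset_as_table(flatten(ann, mode))
  want <- oracle_flatten(ann, mode)
  expect_equal(got, want, info = paste("mode", mode))
}

# --- fragment construction and brute-force counting ---------------------

# hand-built fragment set: blocks_list is a list of fragments, each a
# list(mate1 = matrix(start, end), mate2 = ...)
make_fragments <- function(blocks_list, sample_ids = "s1",
                           origins = "tX") {
  n <- length(blocks_list)
  sample_ids <- rep_len(sample_ids, n)
  origins <- rep_len(origins, n)
  rows <- list()
  for (f in seq_len(n)) {
    for (m in 1:2) {
      blk <- blocks_list[[f]][[m]]
      rows[[length(rows) + 1]] <- data.frame(
        frag = f, mate = m, chrom = "chrS",
        start = blk[, 1], end = blk[, 2])
    }
  }
  blocks <- do.call(rbind, rows)
  blocks <- blocks[order(blocks$frag, blocks$mate, blocks$start), ]
  rownames(blocks) <- NULL
  structure(list(
    fragments = data.frame(fragment_id = sprintf("f%04d", seq_len(n)),
                           origin = origins, sample_id = sample_ids,
                           stringsAsFactors = FALSE),
    blocks = blocks), class = "dtu_fragments")
}

# brute-force overlap counting: one count per (fragment, bin) when any
# block of either mate shares >= 1 base with any interval of the bin
oracle_overlap_counts <- function(frags, binset) {
  samples <- sort(unique(frags$fragments$sample_id))
  m <- matrix(0L, nrow(binset$bins), length(samples),
              dimnames = list(binset$bins$bin_id, samples))
  for (f in seq_len(nrow(frags$fragments))) {
    blk <- frags$blocks[frags$blocks$frag == f, ]
    for (bi in seq_len(nrow(binset$bins))) {
      iv <- binset$intervals[
        binset$intervals$bin_id == binset$bins$bin_id[bi], ]
      hit <- FALSE
      for (i in seq_len(nrow(blk)))
        for (j in seq_len(nrow(iv)))
          if (blk$chrom[i] == iv$chrom[j] &&
              blk$start[i] < iv$end[j] && iv$start[j] < blk$end[i])
            hit <- TRUE
      if (hit)
        m[bi, frags$fragments$sample_id[f]] <-
          m[bi, frags$fragments$sample_id[f]] + 1L
    }
  }
  m
}

# --- EM grid-search oracle ----------------------------------------------

# maximum-likelihood expected counts by exhaustive simplex grid search
# for 2 or 3 transcripts
oracle_em_grid <- function(ec_tx, ec_counts, eff_len) {
  k <- length(eff_len)
  stopifnot(k %in% c(2, 3))
  N <- sum(ec_counts)
  ll <- function(theta) {
    alpha <- theta / eff_len
    sum(vapply(seq_along(ec_tx), function(i) {
      d <- sum(alpha[ec_tx[[i]]])
      if (d <= 0 && ec_counts[i] > 0) return(-Inf)
      if (ec_counts[i] == 0) return(0)
      ec_counts[i] * log(d)
    }, numeric(1)))
  }
  best <- NULL; best_ll <- -Inf
  if (k == 2) {
    for (t1 in seq(0, 1, by = 1e-4)) {
      v <- ll(c(t1, 1 - t1))
      if (v > best_ll) { best_ll <- v; best <- c(t1, 1 - t1) }
    }
  } else {
    step <- 0.005
    for (t1 in seq(0, 1, by = step))
      for (t2 in seq(0, 1 - t1, by = step)) {
        v <- ll(c(t1, t2, 1 - t1 - t2))
        if (v > best_ll) { best_ll <- v; best <- c(t1, t2, 1 - t1 - t2) }
      }
  }
  best * N
}

# --- direct NB bin-count simulator (known generative model) -------------

# counts for features of `bins_per_feature` bins with multinomial
# bin usage within a gene-level NB total; switch_first flips the first
# two bin proportions in condition 2
sim_bin_counts <- function(n_features, bins_per_feature = 3,
                           mu = 600, phi = 0.05, n_rep = 3,
                           switch_first = FALSE) {
  cond <- rep(1:2, each = n_rep)
  rows <- list(); feature <- character(0)
  for (f in seq_len(n_features)) {
    pr1 <- rdirichlet_oracle(rep(2, bins_per_feature))
    pr2 <- pr1
    if (switch_first) pr2[1:2] <- pr1[2:1]
    m <- sapply(seq_along(cond), function(s) {
      tot <- rnbinom(1, mu = mu, size = 1 / phi)
      pr <- if (cond[s] == 1) pr1 else pr2
      as.integer(rmultinom(1, tot, pr))
    })
    rownames(m) <- sprintf("f%03d:B%d", f, seq_len(bins_per_feature))
    rows[[f]] <- m
    feature <- c(feature, rep(sprintf("f%03d", f), bins_per_feature))
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- sprintf("s%d", seq_along(cond))
  list(counts = counts, feature = setNames(feature, rownames(counts)),
       conditions = cond)
}

rdirichlet_oracle <- function(alpha) {
  g <- rgamma(length(alpha), alpha, 1)
  g / sum(g)
}
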