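#' Counting-bin sets
#'
#' A `dtu_binset` holds the counting bins derived from a transcript
#' catalog under one of the supported paradigms:
#'
#' * `flat` - disjoint sub-exonic bins obtained by cutting the exon
#'   union of a feature at every exon boundary of its transcripts.
#'   Overlapping genes are handled according to `overlap_mode`:
#'   `"aggregate"` merges same-strand exon-overlapping genes
#'   (transitively) into complexes whose feature id joins the sorted
#'   member gene ids with `"+"`; `"exclude_same_strand"` drops
#'   sub-intervals shared by two or more genes on the same strand;
#'   `"exclude_both_strands"` drops sub-intervals shared by genes on
#'   either strand.
#' * `exon` - one bin per distinct exon per gene; bins may overlap.
#' * `junction` - one bin per distinct splice junction per gene; the
#'   two stored intervals are 1-bp anchors flanking the junction.
#' * `transcript` - one bin per transcript.
#'
#' The object is a list with elements `bins` (data frame: `bin_id`,
#' `feature_id`, `bin_type`, plus `donor`/`acceptor` for junctions),
#' `intervals` (data frame: `bin_id`, `chrom`, `start`, `end`,
#' `strand`), `members` (named list: bin id to the transcript ids that
#' fully contain the bin), `overlap_mode`, and `complex_map` (named
#' list: feature id to member gene ids).
#'
#' @name dtu_binset
NULL

new_binset <- function(bins, intervals, members, overlap_mode, complex_map) {
  stopifnot(!anyDuplicated(bins$bin_id))
  structure(list(bins = bins, intervals = intervals, members = members,
                 overlap_mode = overlap_mode, complex_map = complex_map),
            class = "dtu_binset")
}

#' @export
print.dtu_binset <- function(x, ...) {
  cat(sprintf("dtu_binset: %d bins (%s), %d features, overlap_mode=%s\n",
              nrow(x$bins), paste(unique(x$bins$bin_type), collapse = ","),
              length(unique(x$bins$feature_id)), x$overlap_mode))
  invisible(x)
}

# reduced exon union per gene: data.frame(gene_id, chrom, strand, start, end)
gene_exon_unions <- function(ann) {
  parts <- lapply(split(seq_len(nrow(ann)), ann$gene_id), function(idx) {
    ir <- IRanges::reduce(IRanges::IRanges(ann$start[idx] + 1L, ann$end[idx]))
    data.frame(gene_id = ann$gene_id[idx[1]], chrom = ann$chrom[idx[1]],
               strand = ann$strand[idx[1]],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# union-find over gene ids, edges = same-strand exon-union overlap (>=1 bp)
aggregate_components <- function(unions) {
  genes <- unique(unions$gene_id)
  parent <- setNames(seq_along(genes), genes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  join <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (key in unique(paste(unions$chrom, unions$strand))) {
    sel <- paste(unions$chrom, unions$strand) == key
    u <- unions[sel, , drop = FALSE]
    ir <- IRanges::IRanges(u$start + 1L, u$end)
    hit <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
    for (k in which(qh < sh))
      join(match(u$gene_id[qh[k]], genes), match(u$gene_id[sh[k]], genes))
  }
  roots <- vapply(seq_along(genes), find, integer(1))
  split(genes, roots)
}

# sub-intervals (0-based half-open) covered by >=2 distinct genes;
# strand column is "*" when strand is ignored
shared_regions <- function(unions, ignore_strand) {
  grp <- if (ignore_strand) unions$chrom else paste(unions$chrom, unions$strand)
  parts <- lapply(split(seq_len(nrow(unions)), grp), function(idx) {
    u <- unions[idx, , drop = FALSE]
    ir <- IRanges::IRanges(u$start + 1L, u$end)
    cov <- IRanges::coverage(ir)
    sl <- IRanges::slice(cov, lower = 2, rangesOnly = TRUE)
    if (length(sl) == 0) return(NULL)
    data.frame(chrom = u$chrom[1],
               strand = if (ignore_strand) "*" else u$strand[1],
               start = IRanges::start(sl) - 1L,
               end = IRanges::end(sl), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer())
  rownames(out) <- NULL
  out
}

# shared regions applicable to a gene on chrom/strand
applicable_shared <- function(shared, chrom, strand) {
  shared[shared$chrom == chrom &
           (shared$strand == "*" | shared$strand == strand), , drop = FALSE]
}

# cut [boundaries] into segments, keep those covered by >=1 exon of `ex`,
# attach covering transcripts; ex: exon data.frame of one feature
flat_segments <- function(ex, extra_cuts = integer(0)) {
  bounds <- sort(unique(c(ex$start, ex$end, extra_cuts)))
  if (length(bounds) < 2)
    return(data.frame(start = integer(), end = integer()))
  seg <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  seg_ir <- IRanges::IRanges(seg$start + 1L, seg$end)
  ex_ir <- IRanges::IRanges(ex$start + 1L, ex$end)
  hits <- IRanges::findOverlaps(seg_ir, ex_ir, type = "within")
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  seg <- seg[keep, , drop = FALSE]
  members <- lapply(keep, function(q)
    sort(unique(ex$transcript_id[S4Vectors::subjectHits(hits)[
      S4Vectors::queryHits(hits) == q]])))
  seg$members <- members
  rownames(seg) <- NULL
  seg
}

drop_shared <- function(seg, sh) {
  if (nrow(seg) == 0 || nrow(sh) == 0) return(seg)
  ov <- IRanges::overlapsAny(IRanges::IRanges(seg$start + 1L, seg$end),
                             IRanges::IRanges(sh$start + 1L, sh$end))
  seg[!ov, , drop = FALSE]
}

#' Flatten a catalog into disjoint counting bins
#'
#' Cuts each feature's exon union at every exon boundary of the
#' feature's transcripts, producing disjoint sub-exonic ("flat") bins
#' whose member transcripts are the transcripts containing the bin
#' entirely within one exon. See [dtu_binset] for the three ways of
#' handling genes with overlapping exons.
#'
#' @param ann a [dtu_annotation()].
#' @param overlap_mode `"aggregate"`, `"exclude_same_strand"` or
#'   `"exclude_both_strands"`.
#' @return A [dtu_binset].
#' @export
flatten <- function(ann, overlap_mode = c("aggregate", "exclude_same_strand",
                                          "exclude_both_strands")) {
  overlap_mode <- match.arg(overlap_mode)
  validate_annotation(ann)
  empty <- data.frame(bin_id = character(), feature_id = character(),
                      bin_type = character(), stringsAsFactors = FALSE)
  if (nrow(ann) == 0)
    return(new_binset(empty,
      data.frame(bin_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character()),
      list(), overlap_mode, list()))
  unions <- gene_exon_unions(ann)
  if (overlap_mode == "aggregate") {
    comps <- aggregate_components(unions)
    features <- lapply(comps, sort)
    names(features) <- vapply(features, paste, "", collapse = "+")
  } else {
    shared <- shared_regions(unions,
      ignore_strand = overlap_mode == "exclude_both_strands")
    features <- as.list(sort(unique(ann$gene_id)))
    names(features) <- unlist(features)
  }
  features <- features[order(names(features))]
  bins_l <- list(); ints_l <- list(); members <- list()
  for (fid in names(features)) {
    ex <- ann[ann$gene_id %in% features[[fid]], , drop = FALSE]
    # multi-chrom complexes cannot arise (overlap requires shared chrom)
    extra <- integer(0)
    sh <- NULL
    if (overlap_mode != "aggregate") {
      sh <- applicable_shared(shared, ex$chrom[1], ex$strand[1])
      extra <- c(sh$start, sh$end)
    }
    seg <- flat_segments(ex, extra)
    if (overlap_mode != "aggregate")
      seg <- drop_shared(seg, sh)
    if (nrow(seg) == 0) next
    ids <- sprintf("%s:E%03d", fid, seq_len(nrow(seg)))
    bins_l[[fid]] <- data.frame(bin_id = ids, feature_id = fid,
                                bin_type = "flat", stringsAsFactors = FALSE)
    ints_l[[fid]] <- data.frame(bin_id = ids, chrom = ex$chrom[1],
                                start = seg$start, end = seg$end,
                                strand = ex$strand[1],
                                stringsAsFactors = FALSE)
    members <- c(members, setNames(seg$members, ids))
  }
  bins <- do.call(rbind, c(bins_l, list(empty)))
  ints <- do.call(rbind, ints_l) %||%
    data.frame(bin_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character())
  rownames(bins) <- rownames(ints) <- NULL
  complex_map <- features[unique(bins$feature_id)]
  new_binset(bins, ints, members, overlap_mode, complex_map)
}

#' Original-exon counting bins
#'
#' One bin per distinct exon coordinate tuple per gene (identical exons
#' shared by several isoforms collapse to one bin); bins of a gene may
#' overlap each other.
#'
#' @param ann a [dtu_annotation()].
#' @return A [dtu_binset] with `bin_type = "exon"`.
#' @export
exon_bins <- function(ann) {
  validate_annotation(ann)
  bins_l <- list(); ints_l <- list(); members <- list()
  for (gid in sort(unique(ann$gene_id))) {
    ex <- ann[ann$gene_id == gid, , drop = FALSE]
    key <- paste(ex$start, ex$end)
    uniq <- ex[!duplicated(key), , drop = FALSE]
    uniq <- uniq[order(uniq$start, uniq$end), , drop = FALSE]
    ids <- sprintf("%s:E%03d", gid, seq_len(nrow(uniq)))
    bins_l[[gid]] <- data.frame(bin_id = ids, feature_id = gid,
                                bin_type = "exon", stringsAsFactors = FALSE)
    ints_l[[gid]] <- data.frame(bin_id = ids, chrom = uniq$chrom,
                                start = uniq$start, end = uniq$end,
                                strand = uniq$strand, stringsAsFactors = FALSE)
    mem <- lapply(seq_len(nrow(uniq)), function(i)
      sort(unique(ex$transcript_id[ex$start == uniq$start[i] &
                                   ex$end == uniq$end[i]])))
    members <- c(members, setNames(mem, ids))
  }
  finish_binset(bins_l, ints_l, members)
}

#' Splice-junction counting bins
#'
#' One bin per distinct (donor end, acceptor start) pair per gene,
#' taken from consecutive exons within each transcript. Single-exon
#' transcripts contribute no junctions. Each bin stores two 1-bp anchor
#' intervals flanking the junction, plus the junction coordinates in
#' the `donor`/`acceptor` columns of `bins`.
#'
#' @param ann a [dtu_annotation()].
#' @return A [dtu_binset] with `bin_type = "junction"`.
#' @export
junction_set <- function(ann) {
  validate_annotation(ann)
  jx <- transcript_junctions(ann)
  bins_l <- list(); ints_l <- list(); members <- list()
  for (gid in sort(unique(ann$gene_id))) {
    j <- jx[jx$gene_id == gid, , drop = FALSE]
    if (nrow(j) == 0) next
    key <- paste(j$donor, j$acceptor)
    uniq <- j[!duplicated(key), , drop = FALSE]
    uniq <- uniq[order(uniq$donor, uniq$acceptor), , drop = FALSE]
    ids <- sprintf("%s:J%03d", gid, seq_len(nrow(uniq)))
    bins_l[[gid]] <- data.frame(bin_id = ids, feature_id = gid,
                                bin_type = "junction",
                                donor = uniq$donor, acceptor = uniq$acceptor,
                                stringsAsFactors = FALSE)
    ints_l[[gid]] <- data.frame(
      bin_id = rep(ids, each = 2L), chrom = rep(uniq$chrom, each = 2L),
      start = as.vector(rbind(uniq$donor - 1L, uniq$acceptor)),
      end = as.vector(rbind(uniq$donor, uniq$acceptor + 1L)),
      strand = rep(uniq$strand, each = 2L), stringsAsFactors = FALSE)
    mem <- lapply(seq_len(nrow(uniq)), function(i)
      sort(unique(j$transcript_id[j$donor == uniq$donor[i] &
                                  j$acceptor == uniq$acceptor[i]])))
    members <- c(members, setNames(mem, ids))
  }
  finish_binset(bins_l, ints_l, members)
}

# all junctions, one row per (transcript, junction)
transcript_junctions <- function(ann) {
  n <- nrow(ann)
  if (n == 0)
    return(data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      donor = integer(), acceptor = integer()))
  same_tx <- ann$transcript_id[-1] == ann$transcript_id[-n]
  i <- which(same_tx)
  data.frame(gene_id = ann$gene_id[i], transcript_id = ann$transcript_id[i],
             chrom = ann$chrom[i], strand = ann$strand[i],
             donor = ann$end[i], acceptor = ann$start[i + 1L],
             stringsAsFactors = FALSE)
}

#' Transcript-level counting bins
#'
#' One bin per transcript (`bin_id = transcript_id`), grouped by gene;
#' genes with a single isoform yield a single bin, for which the
#' bin-versus-rest test is undefined downstream.
#'
#' @param ann a [dtu_annotation()].
#' @return A [dtu_binset] with `bin_type = "transcript"`.
#' @export
transcript_bins <- function(ann) {
  validate_annotation(ann)
  tt <- transcript_table(ann)
  tt <- tt[order(tt$gene_id, tt$transcript_id), , drop = FALSE]
  bins <- data.frame(bin_id = tt$transcript_id, feature_id = tt$gene_id,
                     bin_type = "transcript", stringsAsFactors = FALSE)
  ints <- data.frame(bin_id = ann$transcript_id, chrom = ann$chrom,
                     start = ann$start, end = ann$end, strand = ann$strand,
                     stringsAsFactors = FALSE)
  members <- setNames(as.list(tt$transcript_id), tt$transcript_id)
  complex_map <- setNames(as.list(unique(tt$gene_id)), unique(tt$gene_id))
  new_binset(bins, ints, members, "n/a", complex_map)
}

finish_binset <- function(bins_l, ints_l, members) {
  empty_b <- data.frame(bin_id = character(), feature_id = character(),
                        bin_type = character(), stringsAsFactors = FALSE)
  empty_i <- data.frame(bin_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character())
  bins <- if (length(bins_l)) do.call(rbind, bins_l) else empty_b
  ints <- if (length(ints_l)) do.call(rbind, ints_l) else empty_i
  rownames(bins) <- rownames(ints) <- NULL
  complex_map <- setNames(as.list(unique(bins$feature_id)),
                          unique(bins$feature_id))
  new_binset(bins, ints, members, "n/a", complex_map)
}

#' Export a bin set as BED6
#'
#' One line per stored interval (junction bins emit their two anchors),
#' `name` = bin id, `score` = 0.
#'
#' @param binset a [dtu_binset].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(binset, path) {
  iv <- binset$intervals
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   iv$chrom, iv$start, iv$end, iv$bin_id, iv$strand)
  writeLines(lines, path)
  invisible(path)
}
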