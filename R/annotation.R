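#' Transcript catalogs
#'
#' A `dtu_annotation` is the package's representation of a transcript
#' catalog: a data frame with one row per exon and columns `gene_id`,
#' `transcript_id`, `chrom`, `start`, `end`, `strand`. Coordinates are
#' 0-based, half-open (`start < end`); GTF input/output converts to and
#' from the 1-based inclusive convention of that format. Exons of a
#' transcript are non-overlapping, sorted by start, and share one
#' chromosome and strand; bookended (touching) exons are merged on
#' construction so that every internal exon boundary is a real splice
#' site.
#'
#' @param exons data frame with the six columns above.
#' @param provenance free-text label describing where the catalog came
#'   from (file path, simulation parameters, ...).
#' @return A `dtu_annotation` object (a data frame).
#' @export
dtu_annotation <- function(exons, provenance = "constructed") {
  need <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(exons))
  if (length(miss))
    stopf("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  exons <- as.data.frame(exons)[need]
  exons$gene_id <- as.character(exons$gene_id)
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ,
                 drop = FALSE]
  exons <- merge_bookended(exons)
  rownames(exons) <- NULL
  structure(exons,
            provenance = provenance,
            class = c("dtu_annotation", "data.frame"))
}

# merge touching/overlapping exon records within each transcript
merge_bookended <- function(exons) {
  if (nrow(exons) == 0) return(exons)
  tx <- exons$transcript_id
  new_run <- c(TRUE, tx[-1] != tx[-length(tx)] |
                     exons$start[-1] > exons$end[-nrow(exons)])
  grp <- cumsum(new_run)
  if (max(grp) == nrow(exons)) return(exons)
  first <- !duplicated(grp)
  out <- exons[first, , drop = FALSE]
  out$end <- as.integer(tapply(exons$end, grp, max))
  out
}

validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "dtu_annotation"))
  if (nrow(ann) == 0) return(invisible(ann))
  if (any(ann$start >= ann$end))
    stopf("annotation has exons with start >= end")
  if (!all(ann$strand %in% c("+", "-")))
    stopf("annotation strand must be '+' or '-'")
  by_tx <- split(seq_len(nrow(ann)), ann$transcript_id)
  for (idx in by_tx) {
    if (length(unique(ann$gene_id[idx])) != 1L)
      stopf("transcript '%s' maps to several genes", ann$transcript_id[idx[1]])
    if (length(unique(ann$chrom[idx])) != 1L ||
        length(unique(ann$strand[idx])) != 1L)
      stopf("transcript '%s' spans chromosomes or strands",
            ann$transcript_id[idx[1]])
    s <- ann$start[idx]; e <- ann$end[idx]
    if (is.unsorted(s) || any(s[-1] < e[-length(e)]))
      stopf("transcript '%s' has unsorted or overlapping exons",
            ann$transcript_id[idx[1]])
  }
  tx_gene <- unique(ann[c("transcript_id", "gene_id")])
  if (anyDuplicated(tx_gene$transcript_id))
    stopf("transcript ids are not unique across the catalog")
  invisible(ann)
}

#' @export
print.dtu_annotation <- function(x, ...) {
  n_tx <- length(unique(x$transcript_id))
  n_g <- length(unique(x$gene_id))
  cat(sprintf(
    "dtu_annotation: %d genes, %d transcripts, %d exons (%s)\n",
    n_g, n_tx, nrow(x), attr(x, "provenance") %||% "?"))
  invisible(x)
}

#' Summaries of a transcript catalog
#'
#' `transcript_table()` returns one row per transcript (gene, chrom,
#' strand, number of exons, summed exon length); `gene_table()` one row
#' per gene with its transcript count.
#'
#' @param ann a [dtu_annotation()].
#' @return A data frame.
#' @export
transcript_table <- function(ann) {
  if (nrow(ann) == 0)
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      n_exons = integer(), length = integer()))
  f <- factor(ann$transcript_id, levels = unique(ann$transcript_id))
  first <- !duplicated(f)
  data.frame(
    transcript_id = ann$transcript_id[first],
    gene_id = ann$gene_id[first],
    chrom = ann$chrom[first],
    strand = ann$strand[first],
    n_exons = as.integer(table(f)[as.character(ann$transcript_id[first])]),
    length = as.integer(tapply(ann$end - ann$start, f, sum)[
      as.character(ann$transcript_id[first])]),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname transcript_table
#' @export
gene_table <- function(ann) {
  tt <- transcript_table(ann)
  if (nrow(tt) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), n_transcripts = integer()))
  first <- !duplicated(tt$gene_id)
  data.frame(
    gene_id = tt$gene_id[first],
    chrom = tt$chrom[first],
    strand = tt$strand[first],
    n_transcripts = as.integer(table(factor(tt$gene_id,
      levels = tt$gene_id[first]))),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a transcript catalog from GTF
#'
#' Imports the `exon` features of a GTF file (1-based inclusive
#' coordinates) into a [dtu_annotation()] with 0-based half-open
#' coordinates. Every exon feature must carry `gene_id` and
#' `transcript_id` attributes.
#'
#' @param path path to a GTF file.
#' @return A [dtu_annotation()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stopf("GTF parse error in %s: %s",
                                           path, conditionMessage(e)))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0)
    return(dtu_annotation(data.frame(gene_id = character(),
      transcript_id = character(), chrom = character(),
      start = integer(), end = integer(), strand = character()),
      provenance = path))
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stopf("GTF exon feature without gene_id in %s", path)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stopf("GTF exon feature without transcript_id in %s", path)
  dtu_annotation(data.frame(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE), provenance = path)
}

#' Write a transcript catalog to GTF
#'
#' One `exon` row per exon, 1-based inclusive coordinates, deterministic
#' ordering by (gene_id, transcript_id, start), so that
#' `write_gtf(read_gtf(f))` is a fixed point.
#'
#' @param ann a [dtu_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  validate_annotation(ann)
  if (nrow(ann) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf(
    "%s\tdtubench\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    ann$chrom, ann$start + 1L, ann$end, ann$strand,
    ann$gene_id, ann$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

# keep only the named transcripts (drops empty genes implicitly)
subset_transcripts <- function(ann, keep_tx) {
  out <- ann[ann$transcript_id %in% keep_tx, , drop = FALSE]
  dtu_annotation(out, provenance = attr(ann, "provenance") %||% "subset")
}
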