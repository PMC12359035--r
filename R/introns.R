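## Intron interval construction, SAF emission and intronic read counting.
##
## Introns are defined per gene as the gene span minus the union of all
## exons across that gene's transcripts (interval subtraction via
## GenomicRanges, the same operation used to build the intron SAF for
## featureCounts). Internal coordinates 0-based half-open; SAF written
## 1-based inclusive.

#' Build intron intervals for a set of gene models
#'
#' @param genes gene model list from [read_annotation()] or the simulator.
#' @return data.frame (class `intron_set`) with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, sorted and disjoint per
#'   gene. Genes without gaps contribute no rows.
#' @export
build_introns <- function(genes) {
  rows <- lapply(genes, function(g) {
    ex <- do.call(rbind, lapply(g$transcripts, function(t) t$exons))
    chrom <- g$transcripts[[1L]]$chrom
    strand <- g$transcripts[[1L]]$strand
    span <- IRanges::IRanges(min(ex[, 1L]) + 1L, max(ex[, 2L]))
    exr <- IRanges::reduce(IRanges::IRanges(ex[, 1L] + 1L, ex[, 2L]))
    introns <- IRanges::setdiff(span, exr)
    if (!length(introns)) return(NULL)
    data.frame(gene_id = g$gene_id, chrom = chrom,
               start = IRanges::start(introns) - 1L,
               end = IRanges::end(introns), strand = strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("intron_set", "data.frame")
  out
}

#' Write an intron set as a Simplified Annotation File (SAF)
#'
#' Columns GeneID, Chr, Start, End, Strand with 1-based inclusive
#' coordinates, one row per intron interval, sorted by (Chr, Start).
#'
#' @param introns intron set from [build_introns()].
#' @param path output file.
#' @export
write_saf <- function(introns, path) {
  df <- data.frame(GeneID = introns$gene_id, Chr = introns$chrom,
                   Start = introns$start + 1L, End = introns$end,
                   Strand = introns$strand, stringsAsFactors = FALSE)
  df <- df[order(df$Chr, df$Start, df$GeneID), , drop = FALSE]
  write_tsv(df, path)
}

#' Read a SAF back into an intron set
#'
#' @param path SAF file.
#' @return intron set (0-based half-open), as from [build_introns()].
#' @export
read_saf <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  out <- data.frame(gene_id = as.character(df$GeneID),
                    chrom = as.character(df$Chr),
                    start = as.integer(df$Start) - 1L,
                    end = as.integer(df$End),
                    strand = as.character(df$Strand),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("intron_set", "data.frame")
  out
}

#' Read read intervals from BED
#'
#' @param path BED file (>= 3 columns; 0-based half-open, as BED is).
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name` and `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  if (ncol(df) >= 6L) names(df)[6L] <- "strand"
  df
}

#' Count reads overlapping introns, per gene
#'
#' A read is assigned to a gene when it overlaps any of that gene's introns
#' by at least `min_overlap` bases. A read overlapping introns of several
#' genes counts for each of them, or contributes 1/k per gene with
#' `fraction = TRUE` (mirroring fractional multi-locus counting).
#'
#' @param reads data.frame of read intervals (0-based half-open) as from
#'   [read_bed()].
#' @param introns intron set.
#' @param min_overlap minimum overlap in bases.
#' @param fraction split multi-gene reads 1/k instead of counting fully.
#' @param stranded require matching strand (reads must carry `strand`).
#' @return named numeric vector of counts over every gene in `introns`.
#' @export
count_intronic <- function(reads, introns, min_overlap = 1L,
                           fraction = FALSE, stranded = FALSE) {
  gene_ids <- sort(unique(introns$gene_id))
  counts <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  if (!nrow(reads) || !nrow(introns)) return(counts)
  rgr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$start + 1L, reads$end),
    strand = if (stranded) reads$strand else "*")
  igr <- GenomicRanges::GRanges(
    introns$chrom, IRanges::IRanges(introns$start + 1L, introns$end),
    strand = if (stranded) introns$strand else "*")
  ov <- GenomicRanges::findOverlaps(rgr, igr, minoverlap = min_overlap,
                                    ignore.strand = !stranded)
  if (!length(ov)) return(counts)
  pair <- unique(data.frame(read = S4Vectors::queryHits(ov),
                            gene = introns$gene_id[S4Vectors::subjectHits(ov)],
                            stringsAsFactors = FALSE))
  w <- if (fraction) {
    k <- table(pair$read)
    1 / as.numeric(k[as.character(pair$read)])
  } else rep(1, nrow(pair))
  agg <- tapply(w, pair$gene, sum)
  counts[names(agg)] <- as.numeric(agg)
  counts
}

#' Genes with at least one intronic read
#'
#' @param counts named counts from [count_intronic()].
#' @return character vector of flagged gene ids.
#' @export
flag_intronic_genes <- function(counts) {
  sort(names(counts)[counts >= 1])
}

## deterministic TSV writer (LF endings, no quoting)
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, format_tsv_col), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

format_tsv_col <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    out <- vapply(x, function(v)
      if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                     trim = TRUE), character(1))
    out
  } else as.character(x)
}
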