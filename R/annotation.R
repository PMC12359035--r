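## Transcript models from genome annotation.
##
## Internal coordinates are 0-based half-open throughout; GFF3/GTF files are
## read and written 1-based inclusive, BED 0-based half-open, SAF 1-based
## inclusive (the native convention of each format).

REGIONS <- c("utr5", "cds", "utr3", "noncoding")

#' Read genome (or transcript) sequences from FASTA
#'
#' Sequences are uppercased (soft-masking ignored) and converted to the
#' internal RNA alphabet (T read as U). Headers are tokenized on the first
#' whitespace.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1L], call. = FALSE)
  out <- normalize_rna(as.character(seqs))
  if (any(nchar(out) == 0L))
    stop("empty sequence for record ", nm[nchar(out) == 0L][1L], call. = FALSE)
  names(out) <- nm
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    lines <- substring(s, seq(1L, nchar(s), width),
                       pmin(nchar(s), seq(width, nchar(s) + width - 1L, width)))
    writeLines(c(paste0(">", names(seqs)[i]), lines), con, sep = "\n")
  }
  invisible(path)
}

new_transcript_model <- function(transcript_id, gene_id, gene_name = "",
                                 biotype = "", strand, chrom,
                                 exons, cds_start = NA_integer_,
                                 cds_end = NA_integer_, tags = character(0)) {
  storage.mode(exons) <- "integer"
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("overlapping exons in transcript ", transcript_id, call. = FALSE)
  len <- sum(exons[, 2L] - exons[, 1L])
  if (!is.na(cds_start) &&
      !(cds_start >= 0L && cds_start < cds_end && cds_end <= len))
    stop("CDS bounds outside transcript ", transcript_id, call. = FALSE)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 gene_name = gene_name, biotype = biotype, strand = strand,
                 chrom = chrom, exons = exons,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 tags = sort(tags), transcript_length = as.integer(len)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model>", x$transcript_id, "gene", x$gene_id,
      paste0("(", x$strand, ")"), x$transcript_length, "nt,",
      nrow(x$exons), "exon(s)")
  if (!is.na(x$cds_start)) cat(", CDS [", x$cds_start, ",", x$cds_end, ")")
  if (length(x$tags)) cat(", tags:", paste(x$tags, collapse = ","))
  cat("\n")
  invisible(x)
}

## genomic position (0-based) -> transcript coordinate (0-based)
genomic_to_transcript <- function(tm, gpos) {
  ex <- tm$exons
  widths <- ex[, 2L] - ex[, 1L]
  offs <- cumsum(c(0L, widths))[seq_len(nrow(ex))]
  idx <- findInterval(gpos, ex[, 1L])
  if (any(idx < 1L) || any(gpos >= ex[idx, 2L]))
    stop("position not exonic in ", tm$transcript_id, call. = FALSE)
  tplus <- offs[idx] + (gpos - ex[idx, 1L])
  if (tm$strand == "+") tplus else tm$transcript_length - 1L - tplus
}

#' Read genome annotation into gene models
#'
#' Parses GFF3 or GTF (via rtracklayer), converts 1-based inclusive file
#' coordinates to internal 0-based half-open intervals, projects CDS
#' genomic intervals into transcript coordinates, and captures
#' MANE/canonical transcript tags from attributes.
#'
#' @param path annotation file.
#' @param dialect `"auto"` (by file extension), `"gff3"` or `"gtf"`.
#' @param mane_values,canonical_values attribute values of the `tag`
#'   attribute marking the MANE and Ensembl-canonical transcripts.
#' @return named list of gene models, each a list with `gene_id`,
#'   `gene_name`, `transcripts` (list of transcript models) and
#'   `representative` (NA until [select_representative()] is applied).
#' @export
read_annotation <- function(path, dialect = c("auto", "gff3", "gtf"),
                            mane_values = "MANE_Select",
                            canonical_values = "Ensembl_canonical") {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(gtf)(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)

  get_attr <- function(col, default = "") {
    if (col %in% names(df)) {
      v <- df[[col]]
      if (is.list(v))
        v <- vapply(v, function(e) paste(as.character(e), collapse = ","),
                    character(1))
      v <- as.character(v)
      ifelse(is.na(v), default, v)
    } else rep(default, nrow(df))
  }

  if (dialect == "gff3") {
    ids <- get_attr("ID", NA_character_)
    parents <- get_attr("Parent", NA_character_)
    gene_rows <- which(df$type == "gene")
    tx_rows <- which(!is.na(parents) & parents %in% ids[gene_rows] &
                     !(df$type %in% c("exon", "CDS")))
    tx_id <- ids
    tx_parent <- parents
    gene_id_of <- ids
  } else {
    gid <- get_attr("gene_id", NA_character_)
    tid <- get_attr("transcript_id", NA_character_)
    gene_rows <- which(df$type == "gene")
    if (!length(gene_rows))
      gene_rows <- which(!duplicated(gid) & !is.na(gid))
    tx_rows <- which(df$type == "transcript" |
                     (df$type == "mRNA" & !is.na(tid)))
    if (!length(tx_rows))
      tx_rows <- which(!duplicated(tid) & !is.na(tid) &
                       df$type %in% c("exon"))
    tx_id <- tid
    tx_parent <- gid
    gene_id_of <- gid
  }

  gene_name_attr <- if (dialect == "gff3") "Name" else "gene_name"
  if (dialect == "gff3" && !"Name" %in% names(df))
    gene_name_attr <- "gene_name"
  gene_names <- get_attr(gene_name_attr)
  biotypes <- get_attr("biotype")
  if (!nzchar(biotypes[1L]) && "gene_biotype" %in% names(df))
    biotypes <- get_attr("gene_biotype")
  if ("transcript_biotype" %in% names(df)) {
    tb <- get_attr("transcript_biotype")
    biotypes <- ifelse(nzchar(tb), tb, biotypes)
  }
  tags_raw <- get_attr("tag")

  exon_rows <- which(df$type == "exon")
  cds_rows <- which(df$type == "CDS")
  exon_parent <- if (dialect == "gff3") tx_parent[exon_rows] else tx_id[exon_rows]
  cds_parent <- if (dialect == "gff3") tx_parent[cds_rows] else tx_id[cds_rows]

  genes <- list()
  for (gi in gene_rows) {
    g_id <- gene_id_of[gi]
    g_name <- gene_names[gi]
    this_tx <- tx_rows[if (dialect == "gff3") tx_parent[tx_rows] == ids[gi]
                       else tx_parent[tx_rows] == g_id]
    tms <- list()
    for (ti in this_tx) {
      t_id <- tx_id[ti]
      ex_i <- exon_rows[exon_parent == t_id]
      if (!length(ex_i))
        stop("transcript ", t_id, " has no exon rows", call. = FALSE)
      exons <- cbind(df$start[ex_i] - 1L, df$end[ex_i])
      tx_span <- c(df$start[ti] - 1L, df$end[ti])
      if (any(exons[, 1L] < tx_span[1L]) || any(exons[, 2L] > tx_span[2L]))
        stop("exon outside the span of transcript ", t_id, call. = FALSE)
      strand <- df$strand[ti]
      tags <- unlist(strsplit(tags_raw[ti], ",", fixed = TRUE))
      tag_set <- c(if (any(tags %in% mane_values)) "MANE",
                   if (any(tags %in% canonical_values)) "canonical")
      bt <- biotypes[ti]
      tm <- new_transcript_model(t_id, g_id, g_name, bt, strand,
                                 df$seqnames[ti], exons, tags = tag_set)
      cd_i <- cds_rows[cds_parent == t_id]
      if (length(cd_i)) {
        cds_g <- cbind(df$start[cd_i] - 1L, df$end[cd_i])
        five_most <- if (strand == "+") min(cds_g[, 1L]) else max(cds_g[, 2L]) - 1L
        three_most <- if (strand == "+") max(cds_g[, 2L]) - 1L else min(cds_g[, 1L])
        cs <- genomic_to_transcript(tm, five_most)
        ce <- genomic_to_transcript(tm, three_most) + 1L
        tm <- new_transcript_model(t_id, g_id, g_name, bt, strand,
                                   df$seqnames[ti], exons,
                                   cds_start = cs, cds_end = ce,
                                   tags = tag_set)
      }
      tms[[t_id]] <- tm
    }
    genes[[g_id]] <- list(gene_id = g_id, gene_name = g_name,
                          transcripts = tms, representative = NA_character_)
  }
  genes
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon and CDS rows with the attributes
#' [read_annotation()] consumes; writing and re-reading reproduces
#' identical models. Output is byte-deterministic.
#'
#' @param genes gene model list.
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes[order(names(genes))]) {
    span <- range(unlist(lapply(g$transcripts, function(t) t$exons)))
    chrom <- g$transcripts[[1L]]$chrom
    strand <- g$transcripts[[1L]]$strand
    lines <- c(lines, paste(chrom, "smsites", "gene",
                            min(vapply(g$transcripts,
                                       function(t) min(t$exons[, 1L]), numeric(1))) + 1L,
                            max(vapply(g$transcripts,
                                       function(t) max(t$exons[, 2L]), numeric(1))),
                            ".", strand, ".",
                            paste0("ID=", g$gene_id,
                                   ";Name=", g$gene_name), sep = "\t"))
    for (t in g$transcripts[order(names(g$transcripts))]) {
      attrs <- paste0("ID=", t$transcript_id, ";Parent=", g$gene_id,
                      ";biotype=", t$biotype)
      tagv <- c(if ("MANE" %in% t$tags) "MANE_Select",
                if ("canonical" %in% t$tags) "Ensembl_canonical")
      if (length(tagv)) attrs <- paste0(attrs, ";tag=", paste(tagv, collapse = ","))
      lines <- c(lines, paste(t$chrom, "smsites", "mRNA",
                              min(t$exons[, 1L]) + 1L, max(t$exons[, 2L]),
                              ".", t$strand, ".", attrs, sep = "\t"))
      for (e in seq_len(nrow(t$exons)))
        lines <- c(lines, paste(t$chrom, "smsites", "exon",
                                t$exons[e, 1L] + 1L, t$exons[e, 2L],
                                ".", t$strand, ".",
                                paste0("Parent=", t$transcript_id), sep = "\t"))
      if (!is.na(t$cds_start)) {
        for (iv in cds_genomic_intervals(t))
          lines <- c(lines, paste(t$chrom, "smsites", "CDS",
                                  iv[1L] + 1L, iv[2L], ".", t$strand, "0",
                                  paste0("Parent=", t$transcript_id), sep = "\t"))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

## transcript-coordinate CDS [cds_start, cds_end) -> list of genomic intervals
cds_genomic_intervals <- function(tm) {
  ex <- tm$exons
  widths <- ex[, 2L] - ex[, 1L]
  ## exon order in transcript orientation
  ord <- if (tm$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  t_off <- 0L
  ivs <- list()
  for (e in ord) {
    w <- widths[e]
    lo <- max(tm$cds_start, t_off)
    hi <- min(tm$cds_end, t_off + w)
    if (lo < hi) {
      if (tm$strand == "+") {
        ivs[[length(ivs) + 1L]] <- c(ex[e, 1L] + (lo - t_off),
                                     ex[e, 1L] + (hi - t_off))
      } else {
        ivs[[length(ivs) + 1L]] <- c(ex[e, 2L] - (hi - t_off),
                                     ex[e, 2L] - (lo - t_off))
      }
    }
    t_off <- t_off + w
  }
  ivs[order(vapply(ivs, `[`, numeric(1), 1L))]
}

#' Extract the spliced transcript sequence from genome sequences
#'
#' Exon sequences are concatenated 5' to 3' in transcript orientation
#' (minus-strand exons reverse-complemented) and returned in the RNA
#' alphabet.
#'
#' @param genome named character vector from [read_genome_fasta()].
#' @param tm a transcript model.
#' @return RNA string.
#' @export
extract_transcript_sequence <- function(genome, tm) {
  chrom_seq <- genome[[tm$chrom]]
  if (is.null(chrom_seq)) stop("chromosome ", tm$chrom, " not in genome",
                               call. = FALSE)
  if (any(tm$exons[, 2L] > nchar(chrom_seq)) || any(tm$exons[, 1L] < 0L))
    stop("exon out of chromosome bounds in ", tm$transcript_id, call. = FALSE)
  pieces <- normalize_rna(substring(chrom_seq, tm$exons[, 1L] + 1L,
                                    tm$exons[, 2L]))
  if (tm$strand == "+") paste(pieces, collapse = "")
  else paste(rev(reverse_complement(pieces)), collapse = "")
}

#' Map transcript positions to mRNA regions
#'
#' For coding transcripts positions before the CDS are `utr5`, within it
#' `cds`, after it `utr3`; transcripts without a CDS are `noncoding`
#' throughout. Out-of-bounds positions give `NA`.
#'
#' @param tm a transcript model.
#' @param pos integer vector of 0-based transcript coordinates.
#' @return character vector of region labels.
#' @export
map_region <- function(tm, pos) {
  stopifnot(all(pos >= 0L))
  out <- rep(NA_character_, length(pos))
  inb <- pos < tm$transcript_length
  if (is.na(tm$cds_start)) {
    out[inb] <- "noncoding"
  } else {
    out[inb & pos < tm$cds_start] <- "utr5"
    out[inb & pos >= tm$cds_start & pos < tm$cds_end] <- "cds"
    out[inb & pos >= tm$cds_end] <- "utr3"
  }
  out
}

#' Region lengths of a transcript
#'
#' @param tm a transcript model.
#' @return named integer vector `utr5`, `cds`, `utr3` (all zero with the
#'   full length under `noncoding` for transcripts without a CDS).
#' @export
region_lengths <- function(tm) {
  if (is.na(tm$cds_start))
    return(c(utr5 = 0L, cds = 0L, utr3 = 0L,
             noncoding = tm$transcript_length))
  c(utr5 = tm$cds_start, cds = tm$cds_end - tm$cds_start,
    utr3 = tm$transcript_length - tm$cds_end, noncoding = 0L)
}

#' Select one representative transcript per gene
#'
#' Priority: MANE tag, then Ensembl-canonical tag, then greatest spliced
#' length, then lexicographically smallest transcript id.
#'
#' @param gene one gene model (element of [read_annotation()] output).
#' @return transcript id of the representative.
#' @export
select_representative <- function(gene) {
  tms <- gene$transcripts
  if (!length(tms)) stop("gene ", gene$gene_id, " has no transcripts",
                         call. = FALSE)
  score <- vapply(tms, function(t) {
    2L * ("MANE" %in% t$tags) + ("canonical" %in% t$tags)
  }, integer(1))
  lens <- vapply(tms, function(t) t$transcript_length, integer(1))
  ids <- vapply(tms, function(t) t$transcript_id, character(1))
  ord <- order(-score, -lens, ids)
  unname(ids[ord[1L]])
}

#' Per-gene transcript/region length table
#'
#' One row per gene using its representative transcript.
#'
#' @param genes gene model list (representatives are selected when unset).
#' @return data.frame with gene_id, transcript_id, gene_name, biotype and
#'   transcript/5'UTR/CDS/3'UTR lengths.
#' @export
gene_length_table <- function(genes) {
  rows <- lapply(genes, function(g) {
    rep_id <- if (is.na(g$representative)) select_representative(g)
              else g$representative
    t <- g$transcripts[[rep_id]]
    rl <- region_lengths(t)
    data.frame(gene_id = g$gene_id, transcript_id = t$transcript_id,
               gene_name = g$gene_name, biotype = t$biotype,
               transcript_length = t$transcript_length,
               utr5_length = rl[["utr5"]], cds_length = rl[["cds"]],
               utr3_length = rl[["utr3"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}
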