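## End-to-end orchestration: annotation -> scan -> structure filter ->
## per-gene master table, with deterministic file emission.

#' Run the Sm-site discovery pipeline over a transcriptome
#'
#' Builds transcript models, selects one representative transcript per
#' gene, extracts spliced sequences, scans for the Sm-site motifs,
#' resolves the flanking-structure filter, assigns regions and assembles
#' the per-gene master table.
#'
#' @param genome named sequences from [read_genome_fasta()], or a FASTA
#'   path.
#' @param genes gene model list from [read_annotation()], or a GFF3/GTF
#'   path.
#' @param motifs motif table, see [sm_motifs()].
#' @param up_window,down_window structure-filter windows (nt 5' and 3' of
#'   the site).
#' @param backend,sidecar structure backend, see [resolve_structures()].
#' @param out_dir optional directory; when given, writes `sites.tsv`
#'   (per-hit) and `master.tsv` (per-gene) deterministically.
#' @return list of class `sm_scan` with `hits`, `master` and
#'   `gene_lengths`.
#' @export
run_sm_scan <- function(genome, genes, motifs = sm_motifs(),
                        up_window = 20L, down_window = 10L,
                        backend = c("builtin", "sidecar"), sidecar = NULL,
                        out_dir = NULL) {
  backend <- match.arg(backend)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome_fasta(genome)
  if (is.character(genes) && length(genes) == 1L && file.exists(genes))
    genes <- read_annotation(genes)

  all_hits <- list()
  summaries <- list()
  for (g in genes) {
    rep_id <- if (is.na(g$representative)) select_representative(g)
              else g$representative
    tm <- g$transcripts[[rep_id]]
    seq <- extract_transcript_sequence(genome, tm)
    hits <- scan_sm_sites(tm$transcript_id, seq, motifs)
    hits <- resolve_structures(hits, up_window, down_window,
                               backend = backend, sidecar = sidecar)
    hits$region <- map_region(tm, hits$start)
    hits$gene_id <- rep(g$gene_id, nrow(hits))
    hits$gene_name <- rep(g$gene_name, nrow(hits))
    all_hits[[g$gene_id]] <- hits
    summaries[[g$gene_id]] <- summarize_gene(hits, tm)
  }
  hits <- do.call(rbind, all_hits)
  if (is.null(hits)) hits <- empty_hits()
  rownames(hits) <- NULL
  res <- structure(list(hits = hits, master = master_table(summaries),
                        gene_lengths = gene_length_table(genes)),
                   class = "sm_scan")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cols <- c("transcript_id", "gene_id", "gene_name", "motif",
              "motif_class", "start", "region", "site_seq",
              "downstream_seq", "upstream_ok", "downstream_ok", "retained")
    write_tsv(hits[, intersect(cols, names(hits)), drop = FALSE],
              file.path(out_dir, "sites.tsv"))
    write_tsv(res$master, file.path(out_dir, "master.tsv"))
  }
  res
}

#' @export
print.sm_scan <- function(x, ...) {
  cat("<sm_scan>", nrow(x$master), "genes scanned;",
      sum(x$hits$retained), "of", nrow(x$hits),
      "motif hits retained by the structure filter\n")
  cat("  genes with canonical sites:",
      sum(x$master$canonical_total > 0), "\n")
  cat("  genes with true-noncanonical sites:",
      sum(x$master$nc_true > 0), "\n")
  invisible(x)
}

#' Scan a transcriptome for splice-site or branch-point mimics
#'
#' @param genome,genes as in [run_sm_scan()].
#' @param mode `"5ss"`, `"5ss-bulge"`, `"bpt-consensus"` or
#'   `"bpt-stringent"`.
#' @param out optional TSV path for deterministic emission.
#' @return data.frame of mimic hits with gene annotation.
#' @export
run_mimic_scan <- function(genome, genes,
                           mode = c("5ss", "5ss-bulge", "bpt-consensus",
                                    "bpt-stringent"),
                           out = NULL) {
  mode <- match.arg(mode)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome_fasta(genome)
  if (is.character(genes) && length(genes) == 1L && file.exists(genes))
    genes <- read_annotation(genes)
  rows <- lapply(genes, function(g) {
    rep_id <- if (is.na(g$representative)) select_representative(g)
              else g$representative
    tm <- g$transcripts[[rep_id]]
    seq <- extract_transcript_sequence(genome, tm)
    h <- switch(mode,
                "5ss" = scan_5ss(tm$transcript_id, seq, allow_bulge = FALSE),
                "5ss-bulge" = scan_5ss(tm$transcript_id, seq,
                                       allow_bulge = TRUE),
                "bpt-consensus" = scan_branchpoints(tm$transcript_id, seq,
                                                    "consensus"),
                "bpt-stringent" = scan_branchpoints(tm$transcript_id, seq,
                                                    "stringent"))
    if (nrow(h)) h$gene_id <- g$gene_id
    h
  })
  out_df <- do.call(rbind, rows[vapply(rows, nrow, integer(1)) > 0L])
  if (is.null(out_df))
    out_df <- cbind(mimic_frame(character(0), character(0), integer(0),
                                character(0)),
                    data.frame(gene_id = character(0)))
  rownames(out_df) <- NULL
  if (!is.null(out)) write_tsv(out_df, out)
  out_df
}

#' Classify genes by their detected Sm-site content
#'
#' The stratification used for the CDF comparisons: `Canonical` when the
#' gene has any retained U1/U2/U5-type site, else `Noncanonical` when it
#' has any retained true-noncanonical site, else `Absent`.
#'
#' @param master master table from [run_sm_scan()].
#' @return named character vector gene_id -> class.
#' @export
sm_site_classes <- function(master) {
  cls <- ifelse(master$canonical_total > 0, "Canonical",
                ifelse(master$nc_true > 0, "Noncanonical", "Absent"))
  stats::setNames(cls, master$gene_id)
}
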