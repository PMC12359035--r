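## Per-gene Sm-site summaries (the rows of the master tables).

#' Summarize Sm-site hits for one gene
#'
#' Counts structure-retained hits per motif and per mRNA region of the
#' representative transcript. The canonical total is the sum of U1-, U2-
#' and U5-type counts; because every canonical site also matches the
#' degenerate noncanonical pattern, the true-noncanonical count is the raw
#' noncanonical count minus the canonical total (and must be
#' non-negative). A site's region is the region of its first base.
#'
#' @param hits hit table for this transcript with resolved structure
#'   decisions (see [resolve_structures()]).
#' @param tm the transcript model the hits belong to.
#' @return one-row data.frame (gene site summary).
#' @export
summarize_gene <- function(hits, tm) {
  if (nrow(hits) && any(is.na(hits$retained)))
    stop("hits carry unresolved structure decisions", call. = FALSE)
  if (nrow(hits) && !all(hits$transcript_id == tm$transcript_id))
    stop("hits do not all belong to transcript ", tm$transcript_id,
         call. = FALSE)
  kept <- hits[which(hits$retained), , drop = FALSE]
  region <- map_region(tm, kept$start)

  n_of <- function(motif) sum(kept$motif == motif)
  n_u1 <- n_of("U1"); n_u2 <- n_of("U2"); n_u5 <- n_of("U5")
  n_u7 <- n_of("U7"); n_nc_raw <- n_of("NC")
  canonical_total <- n_u1 + n_u2 + n_u5
  nc_true <- n_nc_raw - canonical_total
  if (nc_true < 0L)
    stop("internal inconsistency: nc_true < 0 for ", tm$transcript_id,
         " (every canonical site must also match the noncanonical pattern)",
         call. = FALSE)

  reg_count <- function(cls, reg)
    sum(kept$motif_class == cls & region == reg, na.rm = TRUE)
  rl <- region_lengths(tm)
  out <- data.frame(
    gene_id = tm$gene_id, transcript_id = tm$transcript_id,
    gene_name = tm$gene_name,
    n_U1 = n_u1, n_U2 = n_u2, n_U5 = n_u5, n_U7 = n_u7,
    n_NC_raw = n_nc_raw,
    canonical_total = canonical_total, nc_true = nc_true,
    stringsAsFactors = FALSE
  )
  for (reg in REGIONS) {
    can <- reg_count("canonical", reg)
    u7 <- reg_count("u7", reg)
    ncr <- reg_count("noncanonical", reg)
    out[[paste0("canonical_", reg)]] <- can
    out[[paste0("u7_", reg)]] <- u7
    out[[paste0("nc_true_", reg)]] <- ncr - can
  }
  out$transcript_length <- tm$transcript_length
  out$utr5_length <- rl[["utr5"]]
  out$cds_length <- rl[["cds"]]
  out$utr3_length <- rl[["utr3"]]
  out
}

#' Combine per-gene summaries into a master table
#'
#' @param summaries list of one-row data.frames from [summarize_gene()].
#' @return master table ordered by gene_id.
#' @export
master_table <- function(summaries) {
  out <- do.call(rbind, summaries)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}
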