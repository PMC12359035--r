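## Enrichment layer: normalization, simplified log2 fold-changes,
## enriched/depleted classification, Sm-site-stratified CDF comparisons
## (one-sided Wilcoxon rank-sum + Benjamini-Hochberg), rank correlations
## with length, region site densities and the multi-comparison candidate
## intersection.
##
## The fidelity path for per-gene statistics is an externally computed
## (gene, lfc, padj) table (e.g. from DESeq2 Wald tests); the internal
## simple_lfc supports simulation-only workflows and carries no test.

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (positive in every sample) of
#' the ratio of its count to the gene's geometric mean across samples;
#' factors are rescaled to geometric mean 1.
#'
#' @param m gene x sample count matrix (non-negative).
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative counts", call. = FALSE)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no gene has positive counts in all samples; ",
         "consider adding a pseudocount to the matrix", call. = FALSE)
  lm <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lm)
  f <- exp(apply(lm - geo, 2L, stats::median))
  f / exp(mean(log(f)))
}

#' Simplified normalized log2 fold-change
#'
#' lfc = log2((mean normalized count in A + pc) / (mean in B + pc)).
#' Internal stand-in for externally computed fold-changes; `padj` is
#' absent (NA) because no test is performed.
#'
#' @param m gene x sample count matrix.
#' @param condition character vector of condition labels, one per column.
#' @param contrast length-2 character vector `c(A, B)`; positive lfc means
#'   higher in A.
#' @param pseudocount added to both mean normalized counts.
#' @param sf size factors (default: computed from `m`).
#' @return data.frame (lfc table) with `gene_id`, `lfc`, `padj` (NA).
#' @export
simple_lfc <- function(m, condition, contrast, pseudocount = 0.5,
                       sf = size_factors(m)) {
  m <- as.matrix(m)
  stopifnot(length(condition) == ncol(m), length(contrast) == 2L)
  if (!all(contrast %in% condition))
    stop("unknown condition in contrast: ",
         paste(setdiff(contrast, condition), collapse = ", "), call. = FALSE)
  norm <- sweep(m, 2L, sf, "/")
  a <- rowMeans(norm[, condition == contrast[1L], drop = FALSE])
  b <- rowMeans(norm[, condition == contrast[2L], drop = FALSE])
  data.frame(gene_id = rownames(m),
             lfc = log2((a + pseudocount) / (b + pseudocount)),
             padj = NA_real_, stringsAsFactors = FALSE)
}

#' Classify genes as enriched, depleted or neither
#'
#' A gene is enriched when lfc > `up` and padj < `alpha`; depleted when
#' lfc < `down` and padj < `alpha`; otherwise neither. The defaults are
#' the >1.5-fold (log2 0.6) and padj < .05 thresholds used throughout the
#' enrichment analyses.
#'
#' @param tbl lfc table with `gene_id`, `lfc`, `padj`.
#' @param up,down lfc thresholds.
#' @param alpha adjusted p-value threshold.
#' @return named character vector gene_id -> class.
#' @export
classify_enrichment <- function(tbl, up = 0.6, down = -0.6, alpha = 0.05) {
  if (is.null(tbl$padj) || all(is.na(tbl$padj)))
    stop("padj is missing: import an externally computed (gene, lfc, padj) ",
         "table; the internal simple_lfc carries no test", call. = FALSE)
  cls <- rep("neither", nrow(tbl))
  ok <- !is.na(tbl$padj) & tbl$padj < alpha
  cls[ok & tbl$lfc > up] <- "enriched"
  cls[ok & tbl$lfc < down] <- "depleted"
  stats::setNames(cls, tbl$gene_id)
}

#' Stratified CDF comparison of log2 fold-changes
#'
#' For each ordered stratum pair (left, right), a one-sided two-sample
#' Wilcoxon rank-sum test on the lfc values (normal approximation with
#' midranks, tie-corrected variance and continuity correction) tests
#' whether the left stratum's fold-changes are shifted `alternative` (the
#' "left curve greater than right curve" convention of CDF plots).
#' Benjamini-Hochberg correction is applied across all pairs in the call.
#'
#' @param tbl lfc table with `gene_id` and `lfc`.
#' @param strata named character vector gene_id -> stratum label.
#' @param pairs list of length-2 character vectors (or "L:R" strings)
#'   giving ordered (left, right) label pairs.
#' @param alternative `"greater"` or `"less"` (left relative to right).
#' @return data.frame (class `strata_test`) with one row per pair:
#'   `left`, `right`, `n_left`, `n_right`, `W`, `alternative`, `p`,
#'   `padj`; ECDF plotting coordinates in `attr(, "ecdf")`.
#' @export
stratified_cdf_test <- function(tbl, strata, pairs,
                                alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.character(pairs)) pairs <- strsplit(pairs, ":", fixed = TRUE)
  lab <- strata[tbl$gene_id]
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    x <- tbl$lfc[!is.na(lab) & lab == pr[1L]]
    y <- tbl$lfc[!is.na(lab) & lab == pr[2L]]
    for (side in 1:2) {
      n <- if (side == 1L) length(x) else length(y)
      if (n < 2L)
        stop("stratum '", pr[side], "' has fewer than 2 genes", call. = FALSE)
    }
    wt <- stats::wilcox.test(x, y, alternative = alternative,
                             exact = FALSE, correct = TRUE)
    data.frame(left = pr[1L], right = pr[2L],
               n_left = length(x), n_right = length(y),
               W = unname(wt$statistic), alternative = alternative,
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  used <- sort(unique(unlist(pairs)))
  ecdfs <- do.call(rbind, lapply(used, function(lv) {
    v <- sort(tbl$lfc[!is.na(lab) & lab == lv])
    if (!length(v)) return(NULL)
    data.frame(stratum = lv, lfc = v,
               ecdf = seq_along(v) / length(v), stringsAsFactors = FALSE)
  }))
  attr(out, "ecdf") <- ecdfs
  class(out) <- c("strata_test", "data.frame")
  out
}

#' @export
print.strata_test <- function(x, ...) {
  cat("Stratified Wilcoxon rank-sum comparisons (BH-corrected):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation with a normal-approximation p-value,
#' used for rank-order comparisons of site frequency against transcript or
#' region length.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @return list with `tau` and `p`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("tau undefined for a constant vector", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Sm-site density per region
#'
#' Sites per million bases, per mRNA region, pooled over genes:
#' density = (sum of region site counts) / (sum of region lengths) * 1e6.
#'
#' @param summaries master table from [master_table()] (or list of
#'   summaries).
#' @param motif_class `"canonical"`, `"u7"` or `"nc_true"`.
#' @param regions regions to report.
#' @return data.frame with `region`, `sites`, `length_nt`,
#'   `density_per_mb`.
#' @export
site_density <- function(summaries, motif_class = "canonical",
                         regions = c("utr5", "cds", "utr3")) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- master_table(summaries)
  rows <- lapply(regions, function(reg) {
    cnt_col <- paste0(motif_class, "_", reg)
    len_col <- paste0(reg, "_length")
    if (!cnt_col %in% names(summaries))
      stop("unknown motif class/region column ", cnt_col, call. = FALSE)
    total_len <- sum(summaries[[len_col]])
    if (total_len == 0)
      stop("zero total length for region ", reg, call. = FALSE)
    sites <- sum(summaries[[cnt_col]])
    data.frame(region = reg, sites = sites, length_nt = total_len,
               density_per_mb = sites / total_len * 1e6,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Candidate intersection across comparisons
#'
#' Genes classified "enriched" in every supplied comparison and not in the
#' genomically ambiguous set, ordered by descending minimum lfc across the
#' comparisons (the most consistently enriched first).
#'
#' @param tables named list; each element a list with `lfc` table (`tbl`)
#'   and its classification (`class`, as from [classify_enrichment()]), or
#'   simply an lfc table (then classified with default thresholds).
#' @param ambiguous character vector of gene ids to exclude.
#' @return data.frame with `gene_id` and `min_lfc`.
#' @export
candidate_intersection <- function(tables, ambiguous = character(0)) {
  norm <- lapply(tables, function(el) {
    if (is.data.frame(el)) list(tbl = el, class = classify_enrichment(el))
    else el
  })
  enriched_sets <- lapply(norm, function(el)
    names(el$class)[el$class == "enriched"])
  genes <- Reduce(intersect, enriched_sets)
  genes <- setdiff(genes, ambiguous)
  if (!length(genes))
    return(data.frame(gene_id = character(0), min_lfc = numeric(0),
                      stringsAsFactors = FALSE))
  min_lfc <- vapply(genes, function(g) {
    min(vapply(norm, function(el)
      el$tbl$lfc[match(g, el$tbl$gene_id)], numeric(1)))
  }, numeric(1))
  ord <- order(-min_lfc, genes)
  data.frame(gene_id = genes[ord], min_lfc = unname(min_lfc[ord]),
             stringsAsFactors = FALSE)
}

#' Read an external (gene, lfc, padj) table
#'
#' @param path TSV with columns gene_id, lfc, padj.
#' @return lfc table data.frame.
#' @export
read_lfc_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  stopifnot(all(c("gene_id", "lfc", "padj") %in% names(df)))
  if (any(!is.na(df$padj) & (df$padj < 0 | df$padj > 1)))
    stop("padj outside [0, 1]", call. = FALSE)
  df
}

#' Read a gene x sample count matrix with its design
#'
#' @param counts_path TSV with a `gene_id` column followed by one column
#'   per sample.
#' @param design_path TSV with columns `sample` and `condition`.
#' @return list with `counts` (matrix) and `design` (data.frame).
#' @export
read_counts_tsv <- function(counts_path, design_path) {
  df <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  design <- utils::read.table(design_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, quote = "",
                              comment.char = "")
  stopifnot(all(design$sample %in% colnames(m)))
  list(counts = m[, design$sample, drop = FALSE], design = design)
}

#' Run the enrichment layer and write its outputs
#'
#' Computes (or accepts) per-gene log2 fold-changes, classifies genes as
#' enriched/depleted, runs the stratified CDF comparisons, and writes
#' `classification.tsv`, `strata_test.tsv` and `ecdf.tsv`
#' deterministically.
#'
#' @param lfc_table lfc table (gene_id, lfc, padj); alternatively supply
#'   `counts`/`design`/`contrast` to use the internal [simple_lfc()]
#'   (classification then requires an external padj and is skipped).
#' @param strata named character vector gene_id -> stratum.
#' @param pairs ordered stratum pairs, see [stratified_cdf_test()].
#' @param counts,design,contrast internal-lfc route.
#' @param alternative test direction.
#' @param out_dir optional output directory.
#' @return list with `lfc`, `classes` (or NULL), `strata_test`.
#' @export
run_enrichment <- function(lfc_table = NULL, strata, pairs,
                           counts = NULL, design = NULL, contrast = NULL,
                           alternative = "greater", out_dir = NULL) {
  if (is.null(lfc_table)) {
    stopifnot(!is.null(counts), !is.null(design), !is.null(contrast))
    lfc_table <- simple_lfc(counts, design$condition, contrast)
  }
  classes <- if (!all(is.na(lfc_table$padj)))
    classify_enrichment(lfc_table) else NULL
  res <- stratified_cdf_test(lfc_table, strata, pairs,
                             alternative = alternative)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(classes))
      write_tsv(data.frame(gene_id = names(classes), class = unname(classes),
                           stringsAsFactors = FALSE),
                file.path(out_dir, "classification.tsv"))
    write_tsv(as.data.frame(res), file.path(out_dir, "strata_test.tsv"))
    write_tsv(attr(res, "ecdf"), file.path(out_dir, "ecdf.tsv"))
  }
  list(lfc = lfc_table, classes = classes, strata_test = res)
}
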