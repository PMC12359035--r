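## Synthetic transcriptome, read and count simulator with planted ground
## truth.
##
## Design goals (all provable by construction, not just probable):
##  * background sequence is rejection-sampled so no unplanted window
##    matches any Sm-site motif (the degenerate NC pattern subsumes the
##    U1/U2/U5/U7 starts, so excluding NC matches excludes them all);
##  * planted structured sites carry designed hairpins (poly-G arm, A loop,
##    poly-C arm) inside flank zones that contain no other pairable letters,
##    so every maximum-weight structure pairs the arms and the filter must
##    retain the site;
##  * planted unstructured sites sit in {C,A}-only flank zones (no AU/GC/GU
##    pair is possible), so the filter must reject them.

#' Simulation configuration
#'
#' The defaults are the conditions under which the count layer is
#' validated: 1000 genes, 150 with a structured canonical Sm-site planted
#' in the 3'UTR (true log2 fold-change +1 in the ATP+ condition), 150 with
#' a structured noncanonical site, 50 with an unstructured canonical site,
#' negative-binomial counts with dispersion 0.1, and 3 samples per
#' condition.
#'
#' @param seed integer seed; all randomness in the generator derives from
#'   it.
#' @param n_genes number of genes (one transcript each).
#' @param site_spec data.frame with columns `motif`, `region`,
#'   `structured` ("hairpin" or "none") and `n_genes` (how many genes get
#'   one such site); specs are assigned to consecutive genes.
#' @param hairpin list with `stem` (>= 6 bp), `loop` (>= 4 nt), `offset5`
#'   (nt between hairpin end and site start, <= 20 - stem) and `offset3`
#'   (nt between motif end and hairpin start, <= 10 - 1).
#' @param utr5_meanlog,utr5_sdlog,cds_meanlog,cds_sdlog,utr3_meanlog,utr3_sdlog
#'   lognormal region-length parameters (nt).
#' @param intron_meanlog,intron_sdlog lognormal intron length (every gene
#'   has one intron splitting its CDS).
#' @param max_region_length cap used to detect unsatisfiable site specs.
#' @param basemean_meanlog,basemean_sdlog lognormal base-mean expression.
#' @param dispersion negative-binomial dispersion (0 gives Poisson).
#' @param lfc_by_class planted log2 fold-change (ATP+ over ATP-) per gene
#'   class.
#' @param n_per_condition samples per condition.
#' @param reads_per_gene,intronic_fraction,read_length read simulation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L,
                       site_spec = default_site_spec(),
                       hairpin = list(stem = 8L, loop = 4L,
                                      offset5 = 2L, offset3 = 1L),
                       utr5_meanlog = log(150), utr5_sdlog = 0.2,
                       cds_meanlog = log(600), cds_sdlog = 0.2,
                       utr3_meanlog = log(900), utr3_sdlog = 0.3,
                       intron_meanlog = log(300), intron_sdlog = 0.2,
                       max_region_length = 100000L,
                       basemean_meanlog = log(200), basemean_sdlog = 1,
                       dispersion = 0.1,
                       lfc_by_class = c(Canonical = 1, Noncanonical = 0,
                                        Absent = 0),
                       n_per_condition = 3L,
                       reads_per_gene = 20L, intronic_fraction = 0.5,
                       read_length = 50L) {
  stopifnot(hairpin$stem >= 6L, hairpin$loop >= 4L,
            hairpin$offset5 + hairpin$stem <= 20L,
            hairpin$offset3 + 1L <= 10L)
  if (sum(site_spec$n_genes) > n_genes)
    stop("site spec assigns more genes than n_genes", call. = FALSE)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 site_spec = site_spec, hairpin = hairpin,
                 utr5_meanlog = utr5_meanlog, utr5_sdlog = utr5_sdlog,
                 cds_meanlog = cds_meanlog, cds_sdlog = cds_sdlog,
                 utr3_meanlog = utr3_meanlog, utr3_sdlog = utr3_sdlog,
                 intron_meanlog = intron_meanlog, intron_sdlog = intron_sdlog,
                 max_region_length = as.integer(max_region_length),
                 basemean_meanlog = basemean_meanlog,
                 basemean_sdlog = basemean_sdlog,
                 dispersion = dispersion, lfc_by_class = lfc_by_class,
                 n_per_condition = as.integer(n_per_condition),
                 reads_per_gene = as.integer(reads_per_gene),
                 intronic_fraction = intronic_fraction,
                 read_length = as.integer(read_length)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_site_spec <- function() {
  data.frame(
    motif = c("U1", "U2", "U5", "NC", "U2"),
    region = "utr3",
    structured = c("hairpin", "hairpin", "hairpin", "hairpin", "none"),
    n_genes = c(50L, 50L, 50L, 150L, 50L),
    stringsAsFactors = FALSE
  )
}

## planted sequence of each motif; the NC planting is a degenerate instance
## that matches no canonical motif
planted_site_seq <- function(motif) {
  switch(motif,
         U1 = "AUUUGUG", U2 = "AUUUUUG", U5 = "AUUUUUUG",
         U7 = "AUUUGUCUAG", NC = "AUCUGUA",
         stop("unknown motif ", motif, call. = FALSE))
}

#' Gene-level ground truth implied by a configuration
#'
#' Class labels: `Canonical` when a structured U1/U2/U5 site is planted,
#' else `Noncanonical` when a structured NC site is planted, else
#' `Absent` (genes with only unstructured sites are Absent: the structure
#' filter must reject their sites). Deterministic: no randomness is used.
#'
#' @param cfg a `sim_config`.
#' @return data.frame with `gene_id`, `transcript_id`, `spec_row`,
#'   `class`, `lfc`.
#' @export
make_truth <- function(cfg) {
  n <- cfg$n_genes
  spec_row <- rep(NA_integer_, n)
  idx <- 1L
  for (r in seq_len(nrow(cfg$site_spec))) {
    k <- cfg$site_spec$n_genes[r]
    if (k > 0L) {
      spec_row[idx:(idx + k - 1L)] <- r
      idx <- idx + k
    }
  }
  cls <- vapply(spec_row, function(r) {
    if (is.na(r)) return("Absent")
    s <- cfg$site_spec[r, ]
    if (s$structured != "hairpin") return("Absent")
    if (s$motif %in% c("U1", "U2", "U5")) "Canonical"
    else "Noncanonical"  # NC plantings, and U7 (whose NC-pattern hit is
                         # retained but not canonical, so nc_true = 1)
  }, character(1))
  lfc <- unname(cfg$lfc_by_class[cls])
  lfc[is.na(lfc)] <- 0
  data.frame(gene_id = sprintf("g%04d", seq_len(n)),
             transcript_id = sprintf("t%04d", seq_len(n)),
             spec_row = spec_row, class = cls, lfc = lfc,
             stringsAsFactors = FALSE)
}

## ---- motif-free background ---------------------------------------------

NC_EXCLUSION <- "AUNUKUN"  # its expansion contains the start of every motif

## random sequence with no NC-pattern match (naive random sequence collides
## roughly once per 512 nt): draw once, then mutate the first base of every
## match to C. A C can complete no motif (each motif needs A at its first
## position and the degenerate N positions matched any base already), so
## patching strictly removes matches and converges.
clean_background <- function(n) {
  if (n <= 0L) return("")
  raw <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
  repair_background(raw, integer(0))
}

ca_fill <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("C", "A"), n, replace = TRUE), collapse = "")
}

## hairpin: poly-G 5' arm, poly-A loop, poly-C 3' arm; inside an A-only
## zone the C arm is the only possible pairing partner of the G arm, so
## every maximum-weight structure pairs them
hairpin_seq <- function(stem, loop) {
  paste0(strrep("G", stem), strrep("A", loop), strrep("C", stem))
}

## ---- transcriptome assembly --------------------------------------------

#' Simulate a transcriptome with planted Sm-sites
#'
#' Builds one spliced transcript per gene (5'UTR + CDS + 3'UTR, CDS split
#' by one intron), plants Sm-sites with structured or unpairable flank
#' zones per the site spec, assembles a genome with alternating strands,
#' and records the full ground truth. Deterministic for a fixed seed.
#'
#' @param cfg a `sim_config`.
#' @return list (class `sm_sim`) with `genome` (named sequences), `genes`
#'   (gene model list), `transcript_seqs` (named spliced sequences),
#'   `truth` (list with `genes` and `sites` data.frames) and `cfg`.
#' @export
make_transcriptome <- function(cfg) {
  set.seed(cfg$seed)
  truth_genes <- make_truth(cfg)
  n <- cfg$n_genes
  hp <- cfg$hairpin
  site_stride <- 200L + 10L + 80L  # upstream zone + motif + downstream zone

  genome_parts <- character(0)
  genome_pos <- 0L
  genes <- list()
  transcript_seqs <- character(0)
  site_rows <- list()

  for (i in seq_len(n)) {
    g_id <- truth_genes$gene_id[i]
    t_id <- truth_genes$transcript_id[i]
    sr <- truth_genes$spec_row[i]
    spec <- if (!is.na(sr)) cfg$site_spec[sr, ] else NULL

    u5 <- max(30L, round(stats::rlnorm(1, cfg$utr5_meanlog, cfg$utr5_sdlog)))
    cds <- max(90L, round(stats::rlnorm(1, cfg$cds_meanlog, cfg$cds_sdlog)))
    u3 <- max(120L, round(stats::rlnorm(1, cfg$utr3_meanlog, cfg$utr3_sdlog)))
    if (!is.null(spec)) {
      need <- site_stride + 20L
      if (need > cfg$max_region_length)
        stop("site spec exceeds region capacity", call. = FALSE)
      if (spec$region == "utr5") u5 <- max(u5, need)
      if (spec$region == "cds") cds <- max(cds, need)
      if (spec$region == "utr3") u3 <- max(u3, need)
    }
    len <- u5 + cds + u3
    seq_chars <- strsplit(clean_background(len), "", fixed = TRUE)[[1L]]

    if (!is.null(spec)) {
      region_start <- switch(spec$region, utr5 = 0L, cds = u5,
                             utr3 = u5 + cds)
      site_start <- region_start + 200L       # 0-based transcript coord
      site <- planted_site_seq(spec$motif)
      mlen <- nchar(site)
      structured <- identical(spec$structured, "hairpin")

      up_zone_from <- max(0L, site_start - 200L)
      up_len <- site_start - up_zone_from
      down_len <- min(len - (site_start + mlen), 60L)
      if (down_len < 16L)
        stop("planted site lacks 16 nt of downstream sequence", call. = FALSE)

      if (structured) {
        hp_str <- hairpin_seq(hp$stem, hp$loop)
        hp_len <- nchar(hp_str)
        ## upstream zone: A-only except the hairpin ending offset5 before
        ## the site
        up <- strrep("A", up_len)
        hp_at <- up_len - hp$offset5 - hp_len  # 0-based within zone
        substr(up, hp_at + 1L, hp_at + hp_len) <- hp_str
        ## downstream zone: A-only except the hairpin starting offset3
        ## after the motif
        down <- strrep("A", down_len)
        substr(down, hp$offset3 + 1L, hp$offset3 + hp_len) <- hp_str
      } else {
        up <- ca_fill(up_len)
        down <- ca_fill(down_len)
      }
      patch <- paste0(up, site, down)
      from <- up_zone_from + 1L
      seq_chars[from:(from + nchar(patch) - 1L)] <-
        strsplit(patch, "", fixed = TRUE)[[1L]]

      site_rows[[length(site_rows) + 1L]] <- data.frame(
        gene_id = g_id, transcript_id = t_id, motif = spec$motif,
        start = site_start,
        region = switch(spec$region, utr5 = "utr5", cds = "cds",
                        utr3 = "utr3"),
        structured = structured, stringsAsFactors = FALSE)
    }

    tseq <- paste(seq_chars, collapse = "")
    tseq <- repair_background(tseq,
                              planted = if (!is.null(spec)) site_rows[[length(site_rows)]]$start
                                        else integer(0))
    transcript_seqs[[t_id]] <- tseq

    ## genome: split the CDS with one intron; alternate strands
    split_at <- u5 + (cds %/% 2L)
    intron_len <- max(60L, round(stats::rlnorm(1, cfg$intron_meanlog,
                                               cfg$intron_sdlog)))
    intron <- clean_background(intron_len)
    pre <- paste0(substr(tseq, 1L, split_at), intron,
                  substr(tseq, split_at + 1L, len))
    strand <- if (i %% 2L == 1L) "+" else "-"
    span_seq <- if (strand == "+") pre else reverse_complement(pre)
    s <- genome_pos
    e <- s + nchar(span_seq)
    if (strand == "+") {
      exons <- rbind(c(s, s + split_at),
                     c(s + split_at + intron_len, e))
    } else {
      len2 <- len - split_at
      exons <- rbind(c(s, s + len2),
                     c(e - split_at, e))
    }
    cs <- u5; ce <- u5 + cds
    genes[[g_id]] <- list(
      gene_id = g_id, gene_name = g_id,
      transcripts = stats::setNames(list(new_transcript_model(
        t_id, g_id, g_id, "protein_coding", strand, "chr1", exons,
        cds_start = cs, cds_end = ce, tags = "canonical")), t_id),
      representative = t_id)
    genome_parts <- c(genome_parts, span_seq, strrep("A", 100L))
    genome_pos <- e + 100L
  }

  genome <- c(chr1 = paste(genome_parts, collapse = ""))
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(gene_id = character(0), transcript_id = character(0),
               motif = character(0), start = integer(0),
               region = character(0), structured = logical(0),
               stringsAsFactors = FALSE)
  structure(list(genome = genome, genes = genes,
                 transcript_seqs = transcript_seqs,
                 truth = list(genes = truth_genes[, c("gene_id",
                                                      "transcript_id",
                                                      "class", "lfc")],
                              sites = sites),
                 cfg = cfg),
            class = "sm_sim")
}

## remove background motif matches created at zone/background junctions:
## mutate the first base of any non-planted NC match to C (C can complete
## no motif, so this converges)
repair_background <- function(seq, planted) {
  m <- compile_motif(NC_EXCLUSION)
  repeat {
    starts <- setdiff(motif_match_starts(m, seq), planted)
    if (!length(starts)) return(seq)
    for (s in starts) substr(seq, s + 1L, s + 1L) <- "C"
  }
}

#' @export
print.sm_sim <- function(x, ...) {
  cat("<sm_sim>", length(x$genes), "genes,",
      nrow(x$truth$sites), "planted sites, seed", x$cfg$seed, "\n")
  invisible(x)
}

## ---- counts -------------------------------------------------------------

#' Simulate an ATP+/ATP- RIP-style count matrix
#'
#' Counts ~ NB(mean = basemean * 2^(lfc * [ATP+]) * sizefactor, dispersion)
#' with per-sample size factors drawn log-uniform on [0.7, 1.4].
#' Deterministic per seed (a fixed offset of the configuration seed, so
#' the transcriptome and count draws are independent streams).
#'
#' @param truth gene-level truth (the `genes` element of an `sm_sim`
#'   truth, or [make_truth()] output).
#' @param cfg a `sim_config`.
#' @return list with `counts` (gene x sample integer matrix), `design`
#'   (sample/condition data.frame) and `true_lfc`.
#' @export
make_counts <- function(truth, cfg) {
  set.seed(cfg$seed + 1L)
  ng <- nrow(truth)
  npc <- cfg$n_per_condition
  samples <- c(paste0("ATPminus_", seq_len(npc)),
               paste0("ATPplus_", seq_len(npc)))
  condition <- rep(c("ATPminus", "ATPplus"), each = npc)
  basemean <- stats::rlnorm(ng, cfg$basemean_meanlog, cfg$basemean_sdlog)
  sf <- exp(stats::runif(2L * npc, log(0.7), log(1.4)))
  mu <- outer(basemean, sf) *
    2^(truth$lfc %o% as.numeric(condition == "ATPplus"))
  counts <- if (cfg$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
           nrow = ng)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = ng)
  }
  dimnames(counts) <- list(truth$gene_id, samples)
  list(counts = counts,
       design = data.frame(sample = samples, condition = condition,
                           stringsAsFactors = FALSE),
       true_lfc = stats::setNames(truth$lfc, truth$gene_id))
}

## ---- reads --------------------------------------------------------------

#' Simulate read intervals over a gene set
#'
#' Places a configured fraction of each gene's reads uniformly inside its
#' introns and the remainder inside exons; each read lies entirely within
#' its compartment, so intronic counting recovers the truth tally exactly.
#'
#' @param genes gene model list (e.g. from [make_transcriptome()]).
#' @param cfg a `sim_config`.
#' @return data.frame of BED-style intervals with a `compartment` column;
#'   per-gene intronic tallies in `attr(, "intronic_truth")`.
#' @export
make_reads <- function(genes, cfg) {
  set.seed(cfg$seed + 2L)
  introns <- build_introns(genes)
  rows <- list()
  tally <- stats::setNames(integer(length(genes)), names(genes))
  for (g in genes) {
    gid <- g$gene_id
    gi <- introns[introns$gene_id == gid, , drop = FALSE]
    n <- cfg$reads_per_gene
    n_int <- if (nrow(gi)) round(n * cfg$intronic_fraction) else 0L
    tally[gid] <- n_int
    ex <- do.call(rbind, lapply(g$transcripts, function(t) t$exons))
    place <- function(iv_tab, k, compartment) {
      if (k <= 0L) return(NULL)
      w <- iv_tab[, 2L] - iv_tab[, 1L]
      pick <- sample.int(nrow(iv_tab), k, replace = TRUE, prob = w)
      starts <- iv_tab[pick, 1L] +
        floor(stats::runif(k) * pmax(1L, w[pick] - cfg$read_length))
      ends <- pmin(iv_tab[pick, 2L], starts + cfg$read_length)
      data.frame(chrom = g$transcripts[[1L]]$chrom, start = starts,
                 end = ends,
                 name = paste0(gid, "_", compartment, "_", seq_len(k)),
                 score = 0L, strand = g$transcripts[[1L]]$strand,
                 compartment = compartment, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <-
      place(as.matrix(gi[, c("start", "end")]), n_int, "intron")
    rows[[length(rows) + 1L]] <- place(ex, n - n_int, "exon")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "intronic_truth") <- tally
  out
}

## ---- file emission ------------------------------------------------------

#' Run the simulator and write all outputs to a directory
#'
#' Writes genome.fa, annotation.gff3, reads.bed, counts.tsv, design.tsv,
#' truth.tsv and truth_sites.tsv. All outputs are byte-deterministic for a
#' fixed configuration.
#'
#' @param cfg a `sim_config`.
#' @param out_dir output directory (created if needed).
#' @return the `sm_sim` object, invisibly.
#' @export
sm_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- make_transcriptome(cfg)
  cm <- make_counts(sim$truth$genes, cfg)
  reads <- make_reads(sim$genes, cfg)

  write_fasta(sim$genome, file.path(out_dir, "genome.fa"))
  write_gff3(sim$genes, file.path(out_dir, "annotation.gff3"))
  bed <- reads[, c("chrom", "start", "end", "name", "score", "strand")]
  write_tsv_noheader(bed, file.path(out_dir, "reads.bed"))
  counts_df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(counts_df, file.path(out_dir, "counts.tsv"))
  write_tsv(cm$design, file.path(out_dir, "design.tsv"))
  write_tsv(sim$truth$genes, file.path(out_dir, "truth.tsv"))
  write_tsv(sim$truth$sites, file.path(out_dir, "truth_sites.tsv"))
  invisible(sim)
}

write_tsv_noheader <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, format_tsv_col), sep = "\t"))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}
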