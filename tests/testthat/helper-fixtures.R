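# Shared fixture builders (all fixtures are constructed in code).

# a minimal coding transcript model: one exon covering [0, len) on chr1
toy_tm <- function(len = 300L, cds_start = 50L, cds_end = 150L,
                   id = "t1", gene = "g1", strand = "+",
                   tags = character(0)) {
  smsites:::new_transcript_model(id, gene, gene, "protein_coding", strand,
                                 "chr1", cbind(0L, len),
                                 cds_start = cds_start, cds_end = cds_end,
                                 tags = tags)
}

# the toy two-exon gene used in the annotation contract examples:
# + strand, exons [101,200] and [301,400] (1-based), CDS [151,350]
toy_gff3_lines <- function() {
  c("##gff-version 3",
    "chr1\ttoy\tgene\t101\t400\t.\t+\t.\tID=g1;Name=G1",
    paste0("chr1\ttoy\tmRNA\t101\t400\t.\t+\t.\t",
           "ID=t1;Parent=g1;biotype=protein_coding"),
    "chr1\ttoy\texon\t101\t200\t.\t+\t.\tParent=t1",
    "chr1\ttoy\texon\t301\t400\t.\t+\t.\tParent=t1",
    "chr1\ttoy\tCDS\t151\t200\t.\t+\t0\tParent=t1",
    "chr1\ttoy\tCDS\t301\t350\t.\t+\t0\tParent=t1")
}

toy_gtf_lines <- function() {
  at <- function(extra = "")
    paste0("gene_id \"g1\"; transcript_id \"t1\"; gene_name \"G1\"; ",
           "transcript_biotype \"protein_coding\";", extra)
  c(paste("chr1\ttoy\tgene\t101\t400\t.\t+\t.", "gene_id \"g1\"; gene_name \"G1\";",
          sep = "\t"),
    paste("chr1\ttoy\ttranscript\t101\t400\t.\t+\t.", at(), sep = "\t"),
    paste("chr1\ttoy\texon\t101\t200\t.\t+\t.", at(), sep = "\t"),
    paste("chr1\ttoy\texon\t301\t400\t.\t+\t.", at(), sep = "\t"),
    paste("chr1\ttoy\tCDS\t151\t200\t.\t+\t0", at(), sep = "\t"),
    paste("chr1\ttoy\tCDS\t301\t350\t.\t+\t0", at(), sep = "\t"))
}

# small simulation config for fast end-to-end runs
small_sim_config <- function(seed = 1L, n_genes = 10L,
                             site_spec = data.frame(
                               motif = c("U1", "U2", "U5", "NC", "U2"),
                               region = "utr3",
                               structured = c("hairpin", "hairpin", "hairpin",
                                              "hairpin", "none"),
                               n_genes = c(1L, 1L, 1L, 1L, 1L),
                               stringsAsFactors = FALSE)) {
  sim_config(seed = seed, n_genes = n_genes, site_spec = site_spec,
             utr5_meanlog = log(40), utr5_sdlog = 0.2,
             cds_meanlog = log(120), cds_sdlog = 0.2,
             utr3_meanlog = log(340), utr3_sdlog = 0.1,
             intron_meanlog = log(80), intron_sdlog = 0.2)
}

# planted-vs-called comparison: the hit set expected from a simulated
# transcriptome is the planted sites plus the NC-pattern twin of every
# planted canonical/U7 site
expected_hit_keys <- function(truth_sites) {
  canon <- truth_sites$motif %in% c("U1", "U2", "U5", "U7")
  c(paste(truth_sites$transcript_id, truth_sites$motif, truth_sites$start),
    paste(truth_sites$transcript_id[canon], "NC", truth_sites$start[canon]))
}

# U-free padding: contains no Sm-site motif (every motif requires
# uridines) and cannot base-pair with itself
random_motif_free <- function(n) {
  paste(sample(c("C", "A"), n, replace = TRUE), collapse = "")
}
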