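test_that("FASTA reading normalizes case and alphabet, rejects duplicates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgt", ">chr2", "ACGTN"), fa)
  g <- read_genome_fasta(fa)
  expect_identical(g, c(chr1 = "ACGU", chr2 = "ACGUN"))

  writeLines(c(">chr1", "ACGT", ">chr1", "GGGG"), fa)
  expect_error(read_genome_fasta(fa), "duplicate")
})

test_that("GFF3 models project CDS through the exon chain", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(toy_gff3_lines(), gff)
  genes <- read_annotation(gff)
  tm <- genes$g1$transcripts$t1
  expect_identical(tm$transcript_length, 200L)
  expect_identical(tm$cds_start, 50L)
  expect_identical(tm$cds_end, 150L)
  expect_identical(tm$exons, cbind(c(100L, 300L), c(200L, 400L)))
  expect_identical(tm$biotype, "protein_coding")
})

test_that("GTF dialect of the same toy gene gives the identical model", {
  gff <- tempfile(fileext = ".gff3"); gtf <- tempfile(fileext = ".gtf")
  writeLines(toy_gff3_lines(), gff)
  writeLines(toy_gtf_lines(), gtf)
  a <- read_annotation(gff)$g1$transcripts$t1
  b <- read_annotation(gtf)$g1$transcripts$t1
  for (f in c("transcript_id", "gene_id", "strand", "cds_start", "cds_end",
              "transcript_length", "biotype"))
    expect_identical(a[[f]], b[[f]], info = f)
  expect_identical(a$exons, b$exons)
})

test_that("a transcript without CDS rows stays noncoding", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t1\t100\t.\t+\t.\tID=g1;Name=G1",
               "chr1\tt\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=g1;biotype=lncRNA",
               "chr1\tt\texon\t1\t100\t.\t+\t.\tParent=t1"), gff)
  tm <- read_annotation(gff)$g1$transcripts$t1
  expect_true(is.na(tm$cds_start))
  expect_identical(tm$biotype, "lncRNA")
  expect_identical(unique(map_region(tm, 0:99)), "noncoding")
})

test_that("an exon outside its transcript span is an error naming it", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tt\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tt\tmRNA\t1\t100\t.\t+\t.\tID=tx_bad;Parent=g1",
               "chr1\tt\texon\t1\t150\t.\t+\t.\tParent=tx_bad"), gff)
  expect_error(read_annotation(gff), "tx_bad")
})

test_that("extract_transcript_sequence splices, strands and transcribes", {
  genome <- c(chr1 = "ACGTTTTT")
  plus <- smsites:::new_transcript_model("t1", "g1", "", "", "+", "chr1",
                                         cbind(c(0L, 5L), c(3L, 7L)))
  expect_identical(extract_transcript_sequence(genome, plus), "ACGUU")
  minus <- smsites:::new_transcript_model("t2", "g1", "", "", "-", "chr1",
                                          cbind(0L, 4L))
  expect_identical(extract_transcript_sequence(genome, minus), "ACGU")
  beyond <- smsites:::new_transcript_model("t3", "g1", "", "", "+", "chr1",
                                           cbind(0L, 99L))
  expect_error(extract_transcript_sequence(genome, beyond), "bounds")
})

test_that("minus-strand extraction equals revcomp of the mirrored model", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(40:120, 1)
    chrom <- random_rna(n)
    genome <- c(chr1 = chrom)
    k <- sample(1:3, 1)
    cuts <- sort(sample(seq(2, n - 2), 2 * k))
    exons <- cbind(cuts[seq(1, 2 * k, 2)], cuts[seq(2, 2 * k, 2)])
    plus <- smsites:::new_transcript_model("p", "g", "", "", "+", "chr1", exons)
    minus <- smsites:::new_transcript_model("m", "g", "", "", "-", "chr1", exons)
    expect_identical(extract_transcript_sequence(genome, minus),
                     reverse_complement(extract_transcript_sequence(genome, plus)))
  }
})

test_that("map_region follows half-open CDS bounds", {
  tm <- toy_tm(len = 300L, cds_start = 50L, cds_end = 150L)
  expect_identical(map_region(tm, 10L), "utr5")
  expect_identical(map_region(tm, 49L), "utr5")
  expect_identical(map_region(tm, 50L), "cds")
  expect_identical(map_region(tm, 149L), "cds")
  expect_identical(map_region(tm, 150L), "utr3")
  expect_identical(map_region(tm, 299L), "utr3")
  expect_true(is.na(map_region(tm, 300L)))
})

test_that("region lengths partition every coding transcript", {
  set.seed(9)
  for (rep in 1:20) {
    len <- sample(100:500, 1)
    cs <- sample(0:(len - 2), 1)
    ce <- sample((cs + 1):len, 1)
    tm <- toy_tm(len = len, cds_start = cs, cds_end = ce)
    rl <- region_lengths(tm)
    regions <- map_region(tm, 0:(len - 1L))
    expect_identical(as.integer(table(factor(regions,
                                             c("utr5", "cds", "utr3")))),
                     as.integer(rl[c("utr5", "cds", "utr3")]))
    expect_identical(sum(rl), tm$transcript_length)
  }
})

test_that("representative selection honours MANE > canonical > length > id", {
  gene <- function(...) list(gene_id = "g", gene_name = "g",
                             transcripts = list(...),
                             representative = NA_character_)
  a_canon <- toy_tm(id = "A", tags = "canonical")
  b_mane <- toy_tm(id = "B", tags = "MANE")
  expect_identical(select_representative(
    gene(A = a_canon, B = b_mane)), "B")
  a_short <- toy_tm(id = "A", len = 500L)
  b_long <- toy_tm(id = "B", len = 900L)
  expect_identical(select_representative(gene(A = a_short, B = b_long)), "B")
  tx1 <- toy_tm(id = "tx1"); tx2 <- toy_tm(id = "tx2")
  expect_identical(select_representative(gene(tx2 = tx2, tx1 = tx1)), "tx1")
  expect_error(select_representative(list(gene_id = "g", transcripts = list())),
               "no transcripts")
})

test_that("GFF3 round-trip reproduces identical gene models", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(toy_gff3_lines(), gff)
  genes <- read_annotation(gff)
  out <- tempfile(fileext = ".gff3")
  write_gff3(genes, out)
  again <- read_annotation(out)
  expect_identical(unclass(genes$g1$transcripts$t1),
                   unclass(again$g1$transcripts$t1))
  # and for a simulated multi-gene annotation with both strands and tags
  sim <- make_transcriptome(small_sim_config(seed = 3, n_genes = 6))
  out2 <- tempfile(fileext = ".gff3")
  write_gff3(sim$genes, out2)
  back <- read_annotation(out2)
  expect_identical(names(back), names(sim$genes))
  for (g in names(sim$genes)) {
    t0 <- sim$genes[[g]]$transcripts[[1L]]
    t1 <- back[[g]]$transcripts[[t0$transcript_id]]
    expect_identical(unclass(t0), unclass(t1), info = g)
  }
})

test_that("gene length table uses the representative transcript", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(toy_gff3_lines(), gff)
  tab <- gene_length_table(read_annotation(gff))
  expect_identical(tab$transcript_length, 200L)
  expect_identical(tab$utr5_length, 50L)
  expect_identical(tab$cds_length, 100L)
  expect_identical(tab$utr3_length, 50L)
})
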