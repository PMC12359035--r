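test_that("compile_motif expands degenerate symbols exactly", {
  m1 <- compile_motif("AUUUGUG")
  all7 <- oracle_expand("NNNNNNN")
  accepted <- all7[vapply(all7, function(s)
    length(motif_match_starts(m1, s)) > 0, logical(1))]
  expect_identical(accepted, "AUUUGUG")

  mnc <- compile_motif("AUNUKUN")
  accepted_nc <- all7[vapply(all7, function(s)
    length(motif_match_starts(mnc, s)) > 0, logical(1))]
  expect_length(accepted_nc, 32L)           # 4 * 2 * 4 expansions
  expect_setequal(accepted_nc, oracle_expand("AUNUKUN"))

  expect_error(compile_motif(""), "non-empty")
  expect_error(compile_motif("AUX"), "illegal pattern symbol")
})

test_that("T matches wherever U does and subject N never matches", {
  m <- compile_motif("AUUUGUG")
  expect_identical(motif_match_starts(m, "ATTTGTG"), 0L)
  mn <- compile_motif("AUNUKUN")
  # N at a position the pattern's N would otherwise cover
  expect_length(motif_match_starts(mn, "AUNUGUA"), 0L)
})

test_that("scan_sm_sites reports independent per-motif hits with windows", {
  set.seed(101)
  seq <- paste0(random_motif_free(100), "AUUUUUG", random_motif_free(193))
  hits <- scan_sm_sites("tx", seq)
  expect_setequal(hits$motif, c("U2", "NC"))
  expect_true(all(hits$start == 100L))
  expect_true(all(nchar(hits$upstream_seq) == 100L))
  expect_true(all(nchar(hits$downstream_seq) == 50L))

  # a U5 site matches U5 and NC but not U2
  seq5 <- paste0(random_motif_free(150), "AUUUUUUG", random_motif_free(150))
  hits5 <- scan_sm_sites("tx", seq5)
  expect_setequal(hits5$motif, c("U5", "NC"))
  expect_false("U2" %in% hits5$motif)
})

test_that("hits with under 16 nt of downstream sequence are discarded", {
  set.seed(404)
  seq <- paste0(random_motif_free(100), "AUUUGUG", strrep("C", 10))
  expect_identical(nrow(scan_sm_sites("tx", seq)), 0L)
  seq_ok <- paste0(random_motif_free(100), "AUUUGUG", strrep("C", 16))
  hits <- scan_sm_sites("tx", seq_ok)
  expect_true(all(hits$start == 100L))
  expect_true(all(nchar(hits$downstream_seq) == 16L))
})

test_that("overlapping same-motif occurrences are all reported", {
  # AUUUUUG at 0 and AUUUUUG starting at 4? Use a U-run: AUUUUUUUG has
  # NC matches at several offsets; verify against the expansion oracle
  seq <- paste0("AUAUUUAUGUGUAUUUUUGUG", strrep("C", 30))
  hits <- scan_sm_sites("tx", seq, motifs = sm_motifs()[sm_motifs()$motif == "NC", ])
  expect_identical(sort(hits$start), sort(oracle_scan(seq, "AUNUKUN")))
})

test_that("scanner equals the expansion-set oracle on random sequences", {
  set.seed(42)
  motifs <- sm_motifs()
  for (rep in 1:25) {
    seq <- random_rna(sample(50:800, 1))
    for (k in seq_len(nrow(motifs))) {
      m <- compile_motif(motifs$pattern[k])
      expect_identical(motif_match_starts(m, seq),
                       oracle_scan(seq, motifs$pattern[k]),
                       info = paste(motifs$motif[k], "rep", rep))
    }
  }
})

test_that("the printed mutant sites are never called", {
  set.seed(303)
  for (mut in c("ACCCCCG", "ACUCUCG")) {
    seq <- paste0(random_motif_free(80), mut, random_motif_free(80))
    hits <- scan_sm_sites("tx", seq)
    expect_false(80L %in% hits$start, info = mut)
  }
})

test_that("merge_annotations is a keyed union: idempotent and symmetric", {
  set.seed(202)
  seq <- paste0(random_motif_free(60), "AUUUGUG", random_motif_free(60),
                "AUUUUUG", random_motif_free(60))
  a <- scan_sm_sites("tx", seq)
  expect_identical(merge_annotations(a, a), merge_annotations(a, a[0, ]))
  b <- a[a$motif != "U1", ]
  m1 <- merge_annotations(a, b)
  m2 <- merge_annotations(b, a)
  expect_identical(m1, m2)
  expect_identical(nrow(m1), nrow(a))

  # a one-base difference in the downstream sequence breaks sharing
  a2 <- a
  a2$downstream_seq[1] <- sub("^.", if (substr(a2$downstream_seq[1], 1, 1) == "A")
    "C" else "A", a2$downstream_seq[1])
  m3 <- merge_annotations(a, a2)
  expect_identical(nrow(m3), nrow(a) + 1L)
})

test_that("5'ss mimic scan handles exact, mismatch and deletion calls", {
  expect_identical(scan_5ss("tx", "CAGGUAAGU")$kind, "ss5_exact")
  expect_identical(scan_5ss("tx", "CAGGUAAGC", allow_bulge = TRUE)$kind,
                   "ss5_bulge_mismatch")
  expect_identical(scan_5ss("tx", "CAGGUAGU", allow_bulge = TRUE)$kind,
                   "ss5_bulge_deletion")
  # exact match keeps precedence at its start when bulges are allowed
  both <- scan_5ss("tx", "CAGGUAAGU", allow_bulge = TRUE)
  expect_identical(both$kind[both$start == 0L], "ss5_exact")
  # without allow_bulge, no mismatch/deletion calls at all
  expect_identical(nrow(scan_5ss("tx", "CAGGUAAGC")), 0L)
})

test_that("5'ss scan equals the neighbourhood-set oracle on random sequence", {
  set.seed(7)
  exact_set <- oracle_expand("MAGGURAGK")
  mism_set <- oracle_ss5_mismatch_set()
  del_set <- oracle_ss5_deletion_set()
  for (rep in 1:15) {
    seq <- random_rna(400)
    hits <- scan_5ss("tx", seq, allow_bulge = TRUE)
    k9 <- oracle_kmers(seq, 9L)
    k8 <- oracle_kmers(seq, 8L)
    exp_exact <- which(k9 %in% exact_set) - 1L
    exp_mism <- setdiff(which(k9 %in% mism_set) - 1L, exp_exact)
    exp_del <- setdiff(which(k8 %in% del_set) - 1L, c(exp_exact, exp_mism))
    expect_identical(sort(hits$start[hits$kind == "ss5_exact"]),
                     sort(exp_exact))
    expect_identical(sort(hits$start[hits$kind == "ss5_bulge_mismatch"]),
                     sort(exp_mism))
    expect_identical(sort(hits$start[hits$kind == "ss5_bulge_deletion"]),
                     sort(exp_del))
  }
})

test_that("branch-point scans match their degenerate definitions", {
  expect_identical(scan_branchpoints("tx", "CUGACCCC", "consensus")$kind,
                   "bpt_consensus")
  expect_identical(scan_branchpoints("tx", "CACUGACA", "stringent")$kind,
                   "bpt_stringent")
  expect_identical(nrow(scan_branchpoints("tx", "AAAAAAAA", "consensus")), 0L)
  expect_identical(nrow(scan_branchpoints("tx", "AAAAAAAA", "stringent")), 0L)
  set.seed(11)
  for (rep in 1:10) {
    seq <- random_rna(300)
    expect_identical(scan_branchpoints("tx", seq, "consensus")$start,
                     oracle_scan(seq, "YUNAYYYY"))
    expect_identical(scan_branchpoints("tx", seq, "stringent")$start,
                     oracle_scan(seq, "YMYUNACW"))
  }
})
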