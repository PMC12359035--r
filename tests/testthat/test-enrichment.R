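test_that("size factors follow median-of-ratios", {
  m <- matrix(c(10, 20, 30, 40, 50), ncol = 1)[, c(1, 1)]
  rownames(m) <- paste0("g", 1:5); colnames(m) <- c("s1", "s2")
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = c(10, 20, 30, 40, 50), s2 = 2 * c(10, 20, 30, 40, 50))
  rownames(m2) <- paste0("g", 1:5)
  f <- size_factors(m2)
  expect_equal(unname(f[2] / f[1]), 2)
  expect_equal(exp(mean(log(f))), 1)

  m3 <- cbind(s1 = c(5, 8), s2 = c(0, 0))
  expect_error(size_factors(m3), "pseudocount")
})

test_that("simple_lfc computes normalized log2 ratios", {
  m <- cbind(a1 = c(8, 4, 0), a2 = c(8, 4, 0),
             b1 = c(2, 4, 0), b2 = c(2, 4, 0))
  rownames(m) <- c("up", "flat", "zero")
  cond <- c("A", "A", "B", "B")
  t0 <- simple_lfc(m, cond, c("A", "B"), pseudocount = 0,
                   sf = rep(1, 4))
  expect_equal(t0$lfc[t0$gene_id == "up"], 2)
  expect_equal(t0$lfc[t0$gene_id == "flat"], 0)
  t1 <- simple_lfc(m, cond, c("A", "B"), pseudocount = 0.5, sf = rep(1, 4))
  expect_equal(t1$lfc[t1$gene_id == "zero"], 0)
  expect_true(all(is.na(t0$padj)))
  expect_error(simple_lfc(m, cond, c("A", "C")), "unknown condition")
})

test_that("enrichment classification uses the 0.6 / .05 thresholds", {
  tbl <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    lfc = c(1.2, 0.61, -0.7, 0.61, -0.59),
                    padj = c(0.01, 0.06, 0.001, 0.049, 0.001))
  cls <- classify_enrichment(tbl)
  expect_identical(unname(cls), c("enriched", "neither", "depleted",
                                  "enriched", "neither"))
  # partition: every gene gets exactly one class
  expect_true(all(cls %in% c("enriched", "depleted", "neither")))
  expect_error(classify_enrichment(data.frame(gene_id = "a", lfc = 1,
                                              padj = NA_real_)),
               "padj")
})

test_that("stratified test matches exhaustive permutation for small n", {
  set.seed(99)
  for (rep in 1:12) {
    x <- round(rnorm(sample(4:8, 1)), 1)  # rounding forces occasional ties
    y <- round(rnorm(sample(4:8, 1)), 1)
    tbl <- data.frame(gene_id = paste0("g", seq_along(c(x, y))),
                      lfc = c(x, y))
    strata <- setNames(rep(c("L", "R"), c(length(x), length(y))),
                       tbl$gene_id)
    res <- stratified_cdf_test(tbl, strata, list(c("L", "R")), "greater")
    expect_lt(abs(res$p - oracle_perm_wilcox(x, y, "greater")), 0.02)
  }
})

test_that("a strong shift is detected and BH is applied across pairs", {
  set.seed(17)
  x <- rnorm(200) + 1
  y <- rnorm(200)
  z <- rnorm(200)
  tbl <- data.frame(gene_id = paste0("g", 1:600), lfc = c(x, y, z))
  strata <- setNames(rep(c("Canonical", "Absent", "Other"), each = 200),
                     tbl$gene_id)
  res <- stratified_cdf_test(tbl, strata,
                             list(c("Canonical", "Absent"),
                                  c("Other", "Absent")), "greater")
  expect_lt(res$p[1], 1e-6)
  expect_identical(res$padj, p.adjust(res$p, "BH"))
  expect_true(all(res$padj >= res$p))
  ec <- attr(res, "ecdf")
  expect_setequal(unique(ec$stratum), c("Canonical", "Absent", "Other"))
  expect_true(all(diff(ec$ecdf[ec$stratum == "Absent"]) >= 0))
  expect_error(stratified_cdf_test(tbl, strata, list(c("Missing", "Absent"))),
               "Missing")
})

test_that("BH adjustment is monotone, conservative and order-invariant", {
  set.seed(31)
  for (rep in 1:50) {
    p <- runif(sample(3:40, 1))
    adj <- p.adjust(p, "BH")
    expect_true(all(adj >= p - 1e-12))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))
    perm <- sample(seq_along(p))
    expect_equal(p.adjust(p[perm], "BH"), adj[perm])
  }
})

test_that("kendall_tau is tau-b, matching pair enumeration under ties", {
  expect_equal(kendall_tau(1:5, 2 * (1:5))$tau, 1)
  expect_equal(kendall_tau(1:5, -(1:5))$tau, -1)

  brute_tau_b <- function(x, y) {
    n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) C <- C + 1 else D <- D + 1
    }
    n0 <- n * (n - 1) / 2
    (C - D) / sqrt((n0 - tx) * (n0 - ty))
  }
  x <- c(1, 2, 2, 3); y <- c(1, 2, 3, 3)
  expect_equal(kendall_tau(x, y)$tau, brute_tau_b(x, y))
  set.seed(3)
  for (rep in 1:10) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 12, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y)$tau, brute_tau_b(x, y), info = rep)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("site density is count per length, scaled to sites per Mb", {
  mk <- function(gene, canon3, len3, lenc = 1000L) {
    data.frame(gene_id = gene, canonical_utr3 = canon3,
               canonical_cds = 1L, canonical_utr5 = 0L,
               utr3_length = len3, cds_length = lenc, utr5_length = 100L)
  }
  tab <- rbind(mk("a", 2L, 5000L), mk("b", 1L, 5000L))
  d <- site_density(tab, "canonical")
  expect_equal(d$density_per_mb[d$region == "utr3"], 3 / 10000 * 1e6)

  # equal counts, 3'UTR a third of the CDS length: density ratio 3
  tab2 <- rbind(mk("a", 1L, 500L, 1500L))
  d2 <- site_density(tab2, "canonical")
  expect_equal(d2$density_per_mb[d2$region == "utr3"] /
                 d2$density_per_mb[d2$region == "cds"], 3)

  # invariant to gene order and to splitting totals across genes
  expect_equal(site_density(tab[2:1, ], "canonical"), d)
  split_tab <- rbind(mk("a", 2L, 5000L), mk("b1", 1L, 2500L),
                     mk("b2", 0L, 2500L))
  split_tab$cds_length[2:3] <- 500L
  tab_eq <- rbind(mk("a", 2L, 5000L), mk("b", 1L, 5000L))
  tab_eq$cds_length[2] <- 1000L
  expect_equal(site_density(split_tab, "canonical",
                            "utr3")$density_per_mb,
               site_density(tab_eq, "canonical", "utr3")$density_per_mb)

  zero <- mk("z", 0L, 0L)
  expect_error(site_density(zero, "canonical", "utr3"), "zero total length")

  none <- rbind(mk("a", 0L, 5000L))
  expect_equal(site_density(none, "canonical",
                            "utr3")$density_per_mb, 0)
})

test_that("candidate intersection needs every comparison and no ambiguity", {
  mk_tbl <- function(lfcs) data.frame(gene_id = names(lfcs),
                                      lfc = unname(lfcs),
                                      padj = 0.01)
  t1 <- mk_tbl(c(a = 2.0, b = 1.0, c = 1.5, d = 0.1))
  t2 <- mk_tbl(c(a = 1.2, b = 0.7, c = 1.4, d = 2.0))
  t3 <- mk_tbl(c(a = 0.9, b = 0.3, c = 2.0, d = 2.0))
  out <- candidate_intersection(list(x = t1, y = t2, z = t3))
  # b fails in t3 (0.3 < 0.6); d fails in t1
  expect_identical(out$gene_id, c("c", "a"))  # ordered by min lfc desc
  expect_equal(out$min_lfc, c(1.4, 0.9))
  out2 <- candidate_intersection(list(x = t1, y = t2, z = t3),
                                 ambiguous = "c")
  expect_identical(out2$gene_id, "a")
})

test_that("external lfc tables round-trip and are validated", {
  f <- tempfile()
  writeLines(c("gene_id\tlfc\tpadj", "g1\t1.5\t0.01", "g2\t-0.2\tNA"), f)
  tbl <- read_lfc_table(f)
  expect_identical(tbl$gene_id, c("g1", "g2"))
  expect_true(is.na(tbl$padj[2]))
  writeLines(c("gene_id\tlfc\tpadj", "g1\t1.5\t1.7"), f)
  expect_error(read_lfc_table(f), "padj")
})
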