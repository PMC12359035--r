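# Independent oracles used throughout the suite. These deliberately avoid
# the package's scanning/folding/interval code paths: motif oracles work by
# explicit expansion-set membership, the fold oracle by exhaustive
# enumeration of structures, the intron oracle by per-base membership, and
# the Wilcoxon oracle by exhaustive permutation.

ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", U = "U",
                     N = c("A", "C", "G", "U"),
                     K = c("G", "U"), M = c("A", "C"), R = c("A", "G"),
                     Y = c("C", "U"), W = c("A", "U"))

# full expansion set of a degenerate pattern (a character vector of k-mers)
oracle_expand <- function(pattern) {
  sets <- ORACLE_IUPAC[strsplit(pattern, "", fixed = TRUE)[[1L]]]
  g <- do.call(expand.grid, c(unname(sets), list(stringsAsFactors = FALSE)))
  unique(do.call(paste0, g))
}

# all k-mers of a sequence, as a character vector (index i = 0-based start i-1)
oracle_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# 0-based starts where the k-mers of seq lie in an expansion set
oracle_scan <- function(seq, pattern) {
  set <- oracle_expand(pattern)
  k <- nchar(pattern)
  which(oracle_kmers(seq, k) %in% set) - 1L
}

# Hamming distance between two equal-length strings
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

# 9-mers at Hamming distance exactly 1 from the 5'ss expansion set
oracle_ss5_mismatch_set <- function() {
  set <- oracle_expand("MAGGURAGK")
  nb <- unlist(lapply(set, function(w) {
    ch <- strsplit(w, "", fixed = TRUE)[[1L]]
    unlist(lapply(seq_along(ch), function(p) {
      vapply(setdiff(c("A", "C", "G", "U"), ch[p]), function(alt) {
        v <- ch; v[p] <- alt; paste(v, collapse = "")
      }, character(1))
    }))
  }))
  setdiff(unique(nb), set)
}

# 8-mers equal to the 5'ss pattern with exactly one position deleted
oracle_ss5_deletion_set <- function() {
  syms <- strsplit("MAGGURAGK", "", fixed = TRUE)[[1L]]
  pats <- unique(vapply(seq_along(syms), function(d)
    paste(syms[-d], collapse = ""), character(1)))
  unique(unlist(lapply(pats, oracle_expand)))
}

# ---- exhaustive fold enumeration ---------------------------------------

oracle_pair_weight <- function(a, b, weights = c(GC = 3, AU = 2, GU = 1)) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) weights[["GC"]]
  else if (key %in% c("AU", "UA")) weights[["AU"]]
  else if (key %in% c("GU", "UG")) weights[["GU"]]
  else 0
}

# enumerate every non-crossing pairing with loop >= min_loop (as lists of
# pair matrices); exponential, for short sequences only
oracle_enum_pairings <- function(wmat, lo, hi, min_loop = 3L) {
  if (lo >= hi) return(list(matrix(0L, 0L, 2L)))
  out <- oracle_enum_pairings(wmat, lo + 1L, hi, min_loop)
  js <- if (lo + min_loop + 1L <= hi) seq.int(lo + min_loop + 1L, hi)
        else integer(0)
  for (j in js) {
    if (wmat[lo, j] > 0) {
      inner <- oracle_enum_pairings(wmat, lo + 1L, j - 1L, min_loop)
      right <- oracle_enum_pairings(wmat, j + 1L, hi, min_loop)
      for (a in inner) for (b in right)
        out[[length(out) + 1L]] <- rbind(c(lo, j), a, b)
    }
  }
  out
}

# does every maximal helix (stack run) of a pairing have >= min_helix pairs?
oracle_helices_ok <- function(pairs, min_helix = 2L) {
  if (!nrow(pairs)) return(TRUE)
  key <- paste(pairs[, 1L], pairs[, 2L])
  has <- function(i, j) paste(i, j) %in% key
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    if (has(i - 1L, j + 1L)) next       # not the outer end of its helix
    run <- 1L
    while (has(i + run, j - run)) run <- run + 1L
    if (run < min_helix) return(FALSE)
  }
  TRUE
}

.oracle_fold_cache <- new.env(parent = emptyenv())

# maximum total pair weight over valid structures, by exhaustive enumeration
# (cached on the pair-weight fingerprint, which fully determines the answer)
oracle_fold_max <- function(seq, min_loop = 3L, min_helix = 2L,
                            weights = c(GC = 3, AU = 2, GU = 1)) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 2L) return(0)
  code <- match(ch, c("A", "C", "G", "U"))
  W <- matrix(0, 4L, 4L)
  W[2L, 3L] <- W[3L, 2L] <- weights[["GC"]]
  W[1L, 4L] <- W[4L, 1L] <- weights[["AU"]]
  W[3L, 4L] <- W[4L, 3L] <- weights[["GU"]]
  wmat <- matrix(W[cbind(rep(code, times = n), rep(code, each = n))], n, n)
  key <- paste(n, min_loop, min_helix, paste(wmat[upper.tri(wmat)],
                                             collapse = ""), sep = "|")
  hit <- .oracle_fold_cache[[key]]
  if (!is.null(hit)) return(hit)
  best <- 0
  for (p in oracle_enum_pairings(wmat, 1L, n, min_loop)) {
    if (!oracle_helices_ok(p, min_helix)) next
    sc <- if (nrow(p)) sum(wmat[p]) else 0
    if (sc > best) best <- sc
  }
  .oracle_fold_cache[[key]] <- best
  best
}

# score a dot-bracket string directly (for validating returned structures)
oracle_score_dotbracket <- function(seq, db,
                                    weights = c(GC = 3, AU = 2, GU = 1)) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  st <- integer(0)
  total <- 0
  for (i in seq_along(ch)) {
    c2 <- substr(db, i, i)
    if (c2 == "(") st <- c(st, i)
    else if (c2 == ")") {
      j <- st[length(st)]
      st <- st[-length(st)]
      total <- total + oracle_pair_weight(ch[j], ch[i], weights)
    }
  }
  total
}

# ---- per-base intron oracle --------------------------------------------

# introns of one gene by per-base membership over the gene span
oracle_introns <- function(exons_list, span = NULL) {
  ex <- do.call(rbind, exons_list)
  if (is.null(span)) span <- c(min(ex[, 1L]), max(ex[, 2L]))
  bases <- seq.int(span[1L], span[2L] - 1L)
  exonic <- rep(FALSE, length(bases))
  for (r in seq_len(nrow(ex)))
    exonic[bases >= ex[r, 1L] & bases < ex[r, 2L]] <- TRUE
  runs <- rle(!exonic)
  ends <- cumsum(runs$lengths)
  starts <- c(0L, ends[-length(ends)])
  keep <- runs$values
  cbind(bases[1L] + starts[keep], bases[1L] + ends[keep])
}

# ---- exhaustive permutation Wilcoxon -----------------------------------

# one-sided permutation p-value for the rank-sum of x against y
oracle_perm_wilcox <- function(x, y, alternative = "greater") {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(nx + ny, nx)
  stat <- apply(combs, 2L, function(idx) sum(r[idx]))
  if (alternative == "greater") mean(stat >= obs) else mean(stat <= obs)
}

# random RNA string helper
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")
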