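## Sm-site motif definitions and the degenerate motif scanner.
##
## All scan coordinates are 0-based transcript offsets of the first motif
## base; windows are captured directly from the scanned sequence.

#' Sm-site motif table
#'
#' The five motif classes: the canonical U1/U2/U5-type sites, the U7-type
#' site, and the degenerate noncanonical pattern AUNUKUN (K = G or U).
#' Every canonical site also satisfies the noncanonical pattern, which is
#' why per-gene "true noncanonical" counts subtract the canonical total.
#'
#' @return data.frame with columns `motif`, `pattern`, `motif_class`.
#' @export
sm_motifs <- function() {
  data.frame(
    motif = c("U1", "U2", "U5", "U7", "NC"),
    pattern = c("AUUUGUG", "AUUUUUG", "AUUUUUUG", "AUUUGUCUAG", "AUNUKUN"),
    motif_class = c("canonical", "canonical", "canonical", "u7", "noncanonical"),
    stringsAsFactors = FALSE
  )
}

#' Compile a degenerate RNA pattern into a matcher
#'
#' Supported symbols: A, C, G, U plus the degenerate classes N, K, M, R, Y,
#' W. T in a subject sequence is treated as U; an N in the subject never
#' matches any pattern symbol.
#'
#' @param pattern degenerate RNA string.
#' @return an object of class `sm_matcher`.
#' @export
compile_motif <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L)
    stop("pattern must be a non-empty string", call. = FALSE)
  pattern <- chartr("T", "U", toupper(pattern))
  classes <- iupac_classes()
  syms <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  unknown <- setdiff(syms, names(classes))
  if (length(unknown))
    stop("illegal pattern symbol '", unknown[1L], "'", call. = FALSE)
  sets <- classes[syms]
  regex <- paste0(vapply(sets, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
  structure(list(pattern = pattern, length = length(syms),
                 sets = sets, regex = regex),
            class = "sm_matcher")
}

#' @export
print.sm_matcher <- function(x, ...) {
  cat("<sm_matcher> pattern", x$pattern, "(", x$length, "nt )\n")
  invisible(x)
}

#' Find all (overlapping) match start positions of a compiled motif
#'
#' @param matcher an `sm_matcher` from [compile_motif()].
#' @param seq a single RNA/DNA string (normalized internally).
#' @return integer vector of 0-based start offsets, possibly empty.
#' @export
motif_match_starts <- function(matcher, seq) {
  stopifnot(inherits(matcher, "sm_matcher"))
  seq <- normalize_rna(seq)
  if (nchar(seq) < matcher$length) return(integer(0))
  hits <- gregexpr(paste0("(?=", matcher$regex, ")"), seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Scan one transcript sequence for Sm-site motifs
#'
#' Every motif is scanned independently, so one position can yield both a
#' canonical and a noncanonical hit. For each match the preceding up to
#' `max_upstream` nt and the following up to `max_downstream` nt are
#' captured; matches with fewer than `min_downstream` nt available 3' of
#' the motif are discarded (they cannot carry the required 3' structure).
#'
#' @param transcript_id identifier recorded on each hit.
#' @param seq transcript sequence (5' to 3').
#' @param motifs motif table as from [sm_motifs()] (subset to scan fewer).
#' @param max_upstream,min_downstream,max_downstream flanking-window capture
#'   lengths in nt.
#' @return data.frame of hits with columns `transcript_id`, `motif`,
#'   `motif_class`, `start` (0-based), `site_seq`, `upstream_seq`,
#'   `downstream_seq`, `region`, `upstream_ok`, `downstream_ok`, `retained`
#'   (the last four filled in later by region assignment and the structure
#'   filter).
#' @export
scan_sm_sites <- function(transcript_id, seq, motifs = sm_motifs(),
                          max_upstream = 200L, min_downstream = 16L,
                          max_downstream = 50L) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  out <- vector("list", nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    m <- compile_motif(motifs$pattern[i])
    starts <- motif_match_starts(m, seq)
    if (!length(starts)) next
    ends <- starts + m$length            # 0-based, one past the motif
    down_avail <- n - ends
    keep <- down_avail >= min_downstream
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) next
    up_from <- pmax(0L, starts - max_upstream)
    down_to <- pmin(n, ends + max_downstream)
    out[[i]] <- data.frame(
      transcript_id = transcript_id,
      motif = motifs$motif[i],
      motif_class = motifs$motif_class[i],
      start = starts,
      site_seq = substring(seq, starts + 1L, ends),
      upstream_seq = substring(seq, up_from + 1L, starts),
      downstream_seq = substring(seq, ends + 1L, down_to),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  hits <- if (length(out)) do.call(rbind, out) else empty_hits()
  hits <- hits[order(hits$transcript_id, hits$start, hits$motif), , drop = FALSE]
  rownames(hits) <- NULL
  hits$region <- rep(NA_character_, nrow(hits))
  hits$upstream_ok <- rep(NA, nrow(hits))
  hits$downstream_ok <- rep(NA, nrow(hits))
  hits$retained <- rep(NA, nrow(hits))
  hits
}

empty_hits <- function() {
  data.frame(transcript_id = character(0), motif = character(0),
             motif_class = character(0), start = integer(0),
             site_seq = character(0), upstream_seq = character(0),
             downstream_seq = character(0), region = character(0),
             upstream_ok = logical(0), downstream_ok = logical(0),
             retained = logical(0), stringsAsFactors = FALSE)
}

#' Merge Sm-site hits called under two annotations
#'
#' A hit is "shared" between the two call sets when its
#' (transcript_id, motif, downstream 3' sequence) key occurs in both;
#' shared hits are emitted once, and hits unique to either set are
#' appended. The result is ordered by (transcript_id, start, motif), is
#' idempotent, and does not depend on argument order.
#'
#' @param hits_a,hits_b hit tables from [scan_sm_sites()] over the same
#'   transcript universe (e.g. RefSeq and Gencode calls).
#' @return merged hit table.
#' @export
merge_annotations <- function(hits_a, hits_b) {
  combined <- rbind(hits_a, hits_b)
  if (!nrow(combined)) return(combined)
  ord <- order(combined$transcript_id, combined$start, combined$motif,
               combined$site_seq, combined$downstream_seq)
  combined <- combined[ord, , drop = FALSE]
  key <- paste(combined$transcript_id, combined$motif,
               combined$downstream_seq, sep = "\r")
  combined <- combined[!duplicated(key), , drop = FALSE]
  rownames(combined) <- NULL
  combined
}

## ---- splice-site and branch-point mimics -------------------------------

SS5_PATTERN <- "MAGGURAGK"

## per-position class membership matrix: rows = positions of `pattern`,
## entry [j, i] = does subject char at offset j match pattern position j
## for a window starting at i (computed by the callers below)
pattern_position_match <- function(chars, pattern) {
  classes <- iupac_classes()
  syms <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  vapply(seq_along(syms),
         function(j) chars %in% classes[[syms[j]]],
         logical(length(chars)))
}

#' Scan for 5' splice-site mimics
#'
#' The 5' splice-site consensus is MAGGURAGK (M: A/C, R: A/G, K: G/U).
#' With `allow_bulge`, windows matching the consensus at exactly 8 of 9
#' positions are reported as `ss5_bulge_mismatch`, and 8-mers equal to the
#' consensus with exactly one position deleted as `ss5_bulge_deletion`.
#' A start position is reported at most once, with precedence
#' exact > mismatch > deletion.
#'
#' @param transcript_id identifier recorded on each hit.
#' @param seq transcript sequence.
#' @param allow_bulge also report single-mismatch and single-deletion hits.
#' @return data.frame with columns `transcript_id`, `kind`, `start`
#'   (0-based), `matched_seq`.
#' @export
scan_5ss <- function(transcript_id, seq, allow_bulge = FALSE) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  plen <- nchar(SS5_PATTERN)
  res <- list()

  if (n >= plen) {
    pm <- pattern_position_match(chars, SS5_PATTERN)   # n x 9
    starts9 <- seq_len(n - plen + 1L)
    nmatch <- Reduce(`+`, lapply(seq_len(plen),
                                 function(j) pm[starts9 + j - 1L, j]))
    exact <- starts9[nmatch == plen]
    res$exact <- mimic_frame(transcript_id, "ss5_exact", exact - 1L,
                             substring(seq, exact, exact + plen - 1L))
    if (allow_bulge) {
      mism <- starts9[nmatch == plen - 1L]
      res$mism <- mimic_frame(transcript_id, "ss5_bulge_mismatch", mism - 1L,
                              substring(seq, mism, mism + plen - 1L))
    }
  }

  if (allow_bulge && n >= plen - 1L) {
    ## the 9 single-deletion variants of the pattern (each 8 nt)
    syms <- strsplit(SS5_PATTERN, "", fixed = TRUE)[[1L]]
    del_patterns <- unique(vapply(seq_along(syms), function(d)
      paste(syms[-d], collapse = ""), character(1)))
    del_start <- integer(0)
    for (dp in del_patterns) {
      m <- compile_motif(dp)
      del_start <- union(del_start, motif_match_starts(m, seq))
    }
    del_start <- sort(del_start)
    ## precedence: drop starts already called exact or mismatch
    taken <- c(res$exact$start, if (!is.null(res$mism)) res$mism$start)
    del_start <- setdiff(del_start, taken)
    res$del <- mimic_frame(transcript_id, "ss5_bulge_deletion", del_start,
                           substring(seq, del_start + 1L, del_start + plen - 1L))
  }

  out <- do.call(rbind, res)
  if (is.null(out)) out <- mimic_frame(character(0), character(0),
                                       integer(0), character(0))
  out <- out[order(out$start, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan for branch-point mimics
#'
#' Two definitions: the degenerate consensus YUNAYYYY and the more
#' stringent U1/U12 match YMYUNACW (Y: C/U, M: A/C, W: A/U).
#'
#' @param transcript_id identifier recorded on each hit.
#' @param seq transcript sequence.
#' @param mode `"consensus"` or `"stringent"`.
#' @return data.frame as in [scan_5ss()], with `kind` one of
#'   `bpt_consensus`, `bpt_stringent`.
#' @export
scan_branchpoints <- function(transcript_id, seq,
                              mode = c("consensus", "stringent")) {
  mode <- match.arg(mode)
  pattern <- if (mode == "consensus") "YUNAYYYY" else "YMYUNACW"
  kind <- paste0("bpt_", mode)
  seq <- normalize_rna(seq)
  starts <- motif_match_starts(compile_motif(pattern), seq)
  out <- mimic_frame(transcript_id, kind, starts,
                     substring(seq, starts + 1L, starts + nchar(pattern)))
  rownames(out) <- NULL
  out
}

mimic_frame <- function(transcript_id, kind, start, matched_seq) {
  if (!length(start))
    return(data.frame(transcript_id = character(0), kind = character(0),
                      start = integer(0), matched_seq = character(0),
                      stringsAsFactors = FALSE))
  data.frame(transcript_id = transcript_id, kind = kind,
             start = as.integer(start), matched_seq = matched_seq,
             stringsAsFactors = FALSE)
}
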