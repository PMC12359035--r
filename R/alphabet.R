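## Sequence alphabet utilities.
##
## Internal convention: all sequences are handled uppercase in the RNA
## alphabet (T is read as U everywhere); soft-masking is ignored.

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases, converts T to U, and (optionally) validates that only
#' A/C/G/U/N remain. `N` is kept as an explicit ambiguous base; degenerate
#' motif patterns never match it.
#'
#' @param x character vector of nucleotide strings (DNA or RNA, any case).
#' @param allow_n keep `N` (default) or raise an error when present.
#' @return character vector in the canonical RNA alphabet.
#' @export
normalize_rna <- function(x, allow_n = TRUE) {
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl(if (allow_n) "[^ACGUN]" else "[^ACGU]", out)
  if (any(bad)) {
    ch <- regmatches(out[bad][1L],
                     regexpr(if (allow_n) "[^ACGUN]" else "[^ACGU]", out[bad][1L]))
    stop("illegal character '", ch, "' in nucleotide sequence", call. = FALSE)
  }
  out
}

#' Reverse complement in the RNA alphabet
#'
#' @param x character vector of RNA strings (A/C/G/U/N).
#' @return reverse complement of each element.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

## IUPAC degenerate classes used by the motif patterns (subject N excluded:
## an ambiguous base in the scanned sequence never matches).
iupac_classes <- function() {
  list(A = "A", C = "C", G = "G", U = "U",
       N = c("A", "C", "G", "U"),
       K = c("G", "U"), M = c("A", "C"), R = c("A", "G"),
       Y = c("C", "U"), W = c("A", "U"))
}
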