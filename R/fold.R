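## RNA secondary-structure filter for Sm-site hits.
##
## The folder maximizes summed base-pair weights (GC > AU > GU) over
## non-crossing structures with a minimum hairpin loop and a minimum helix
## length; the consumed decision is binary (is any base within the flanking
## window paired), which this model supports and tests exactly. An external
## dot-bracket sidecar (e.g. RNAfold output) can be substituted per window.

#' Fold an RNA sequence by weighted base-pair maximization
#'
#' Finds the non-crossing structure maximizing total pair weight subject to
#' a minimum hairpin loop of `min_loop` unpaired bases and every helix
#' (maximal stack of adjacent pairs) being at least `min_helix` pairs long.
#' Allowed pairs: AU, GC and the GU wobble. The traceback is deterministic
#' (the 5'-most base pairs with its smallest admissible partner).
#'
#' @param seq RNA string (1 to 1000 nt; T read as U; N not allowed).
#' @param min_loop minimum unpaired bases inside a hairpin loop.
#' @param weights named pair weights for GC, AU and GU.
#' @param min_helix minimum helix length in pairs.
#' @return object of class `fold_result`: list with `sequence`,
#'   `dotbracket` and `score`.
#' @export
fold_rna <- function(seq, min_loop = 3L, weights = c(GC = 3, AU = 2, GU = 1),
                     min_helix = 2L) {
  seq <- normalize_rna(seq, allow_n = FALSE)
  if (nchar(seq) < 1L || nchar(seq) > 1000L)
    stop("sequence length must be between 1 and 1000 nt", call. = FALSE)
  wt <- pair_weight_matrix(weights)
  res <- .fold_nussinov_cpp(seq, as.integer(min_loop), as.integer(min_helix), wt)
  structure(list(sequence = seq, dotbracket = res$dotbracket,
                 score = res$score),
            class = "fold_result")
}

## 4x4 matrix indexed by A,C,G,U codes
pair_weight_matrix <- function(weights) {
  w <- matrix(0, 4L, 4L, dimnames = list(c("A", "C", "G", "U"),
                                         c("A", "C", "G", "U")))
  w["G", "C"] <- w["C", "G"] <- weights[["GC"]]
  w["A", "U"] <- w["U", "A"] <- weights[["AU"]]
  w["G", "U"] <- w["U", "G"] <- weights[["GU"]]
  w
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "  (score ", x$score, ")\n", sep = "")
  invisible(x)
}

#' Paired positions of a fold
#'
#' @param fold a `fold_result` or a bare dot-bracket string.
#' @return integer vector of 1-based paired positions.
#' @export
paired_positions <- function(fold) {
  db <- if (inherits(fold, "fold_result")) fold$dotbracket else fold
  which(strsplit(db, "", fixed = TRUE)[[1L]] != ".")
}

#' Is structure predicted within a flanking window?
#'
#' For the upstream flank the window is the last `window` positions of the
#' fold (the bases immediately 5' of the site); for the downstream flank it
#' is the first `window` positions (immediately 3' of the site). Returns
#' TRUE when at least one base in the window is paired.
#'
#' @param fold a `fold_result` or dot-bracket string.
#' @param side `"upstream"` or `"downstream"`.
#' @param window window size in nt (clipped to the fold length).
#' @return logical flag.
#' @export
flank_structured <- function(fold, side = c("upstream", "downstream"), window) {
  side <- match.arg(side)
  db <- if (inherits(fold, "fold_result")) fold$dotbracket else fold
  n <- nchar(db)
  if (n == 0L) return(FALSE)
  pp <- paired_positions(db)
  if (!length(pp)) return(FALSE)
  window <- min(window, n)
  if (side == "upstream") any(pp > n - window) else any(pp <= window)
}

#' Decide the structure filter for one Sm-site hit
#'
#' The captured upstream and downstream windows are folded independently
#' (the motif itself is excluded); the hit is retained only when structure
#' is predicted within `up_window` nt 5' AND `down_window` nt 3' of the
#' site.
#'
#' @param hit a list or one-row data.frame with `upstream_seq` and
#'   `downstream_seq`.
#' @param up_window,down_window flanking windows in nt.
#' @param min_loop,weights,min_helix folder parameters, see [fold_rna()].
#' @param dotbrackets optional named list/vector with elements `upstream`
#'   and `downstream` holding externally computed dot-brackets for the two
#'   windows (sidecar backend); when given the built-in folder is not used.
#' @return list with `upstream_ok`, `downstream_ok`, `retained`.
#' @export
decide_structure <- function(hit, up_window = 20L, down_window = 10L,
                             min_loop = 3L, weights = c(GC = 3, AU = 2, GU = 1),
                             min_helix = 2L, dotbrackets = NULL) {
  fold_db <- function(s, which_side) {
    if (!is.null(dotbrackets)) return(dotbrackets[[which_side]])
    if (!nzchar(s)) return("")
    fold_rna(s, min_loop = min_loop, weights = weights,
             min_helix = min_helix)$dotbracket
  }
  up_db <- fold_db(hit$upstream_seq, "upstream")
  down_db <- fold_db(hit$downstream_seq, "downstream")
  upstream_ok <- flank_structured(up_db, "upstream", up_window)
  downstream_ok <- flank_structured(down_db, "downstream", down_window)
  list(upstream_ok = upstream_ok, downstream_ok = downstream_ok,
       retained = upstream_ok && downstream_ok)
}

#' Resolve structure decisions for a table of hits
#'
#' Vectorized wrapper over [decide_structure()] filling the
#' `upstream_ok`/`downstream_ok`/`retained` columns of a hit table. With
#' `backend = "sidecar"`, dot-brackets are looked up per window id
#' `<transcript_id>:<motif>:<start>:up|down` in a table read with
#' [read_dotbracket_sidecar()].
#'
#' @param hits hit table from [scan_sm_sites()].
#' @param up_window,down_window flanking windows in nt.
#' @param backend `"builtin"` folder or `"sidecar"` dot-brackets.
#' @param sidecar named character vector of dot-brackets (window id ->
#'   structure), required for the sidecar backend.
#' @param min_loop,weights,min_helix folder parameters.
#' @return `hits` with the three decision columns filled.
#' @export
resolve_structures <- function(hits, up_window = 20L, down_window = 10L,
                               backend = c("builtin", "sidecar"),
                               sidecar = NULL, min_loop = 3L,
                               weights = c(GC = 3, AU = 2, GU = 1),
                               min_helix = 2L) {
  backend <- match.arg(backend)
  if (backend == "sidecar" && is.null(sidecar))
    stop("sidecar backend requires a dot-bracket table", call. = FALSE)
  n <- nrow(hits)
  up_ok <- logical(n); down_ok <- logical(n)
  ## identical windows (e.g. a canonical site and its noncanonical-pattern
  ## twin share the upstream window) are folded once
  fold_cache <- new.env(parent = emptyenv())
  cached_db <- function(s) {
    if (!nzchar(s)) return("")
    key <- paste0("s", s)
    db <- fold_cache[[key]]
    if (is.null(db)) {
      db <- fold_rna(s, min_loop = min_loop, weights = weights,
                     min_helix = min_helix)$dotbracket
      fold_cache[[key]] <- db
    }
    db
  }
  for (i in seq_len(n)) {
    if (backend == "sidecar") {
      key <- paste(hits$transcript_id[i], hits$motif[i], hits$start[i], sep = ":")
      db <- list(upstream = unname(sidecar[paste0(key, ":up")]),
                 downstream = unname(sidecar[paste0(key, ":down")]))
      if (is.na(db$upstream) || is.na(db$downstream))
        stop("sidecar missing dot-bracket for window ", key, call. = FALSE)
    } else {
      db <- list(upstream = cached_db(hits$upstream_seq[i]),
                 downstream = cached_db(hits$downstream_seq[i]))
    }
    d <- decide_structure(hits[i, ], up_window, down_window,
                          min_loop, weights, min_helix, dotbrackets = db)
    up_ok[i] <- d$upstream_ok
    down_ok[i] <- d$downstream_ok
  }
  hits$upstream_ok <- up_ok
  hits$downstream_ok <- down_ok
  hits$retained <- up_ok & down_ok
  hits
}

#' Read a dot-bracket sidecar file
#'
#' Two-column tab-separated file (window_id, dotbracket), as produced by an
#' external folding run (e.g. RNAfold) over the captured windows.
#'
#' @param path sidecar TSV.
#' @return named character vector of dot-brackets.
#' @export
read_dotbracket_sidecar <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("window_id", "dotbracket"),
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  stats::setNames(tab$dotbracket, tab$window_id)
}
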