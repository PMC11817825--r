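#' Scan a sequence for canonical G-quadruplex motifs
#'
#' Finds runs of at least `min_run` guanines chained by loops of
#' `loop_min`..`loop_max` arbitrary bases; four or more chained runs form a
#' canonical quadruplex motif. Hits are reported 5'-most-greedy and maximal:
#' scanning starts at the leftmost possible run, extends the chain with as
#' many further runs as the loop rule allows, and resumes after the hit, so
#' reported hits never overlap. Designed folds cannot contain pseudoknots
#' (the folding model is nested-only), so quadruplexes are the remaining
#' competing-structure hazard screened at the sequence level.
#'
#' @param seq a [dna_sequence()] or character scalar.
#' @param min_run minimum G-run length (default 3).
#' @param loop_min,loop_max allowed loop lengths between runs (default 1-7).
#' @return A data frame of class `g4_hits` with one row per hit: `start`,
#'   `end` (1-based, inclusive), `n_runs`, `run_lengths`, `loop_lengths`
#'   (comma-separated), `motif`.
#' @examples
#' g4_scan("GGGTGGGTGGGTGGG")
#' g4_scan("ATATATATAT")
#' @export
g4_scan <- function(seq, min_run = 3L, loop_min = 1L, loop_max = 7L) {
  seq <- as_dna(seq, id = if (is.character(seq)) "seq" else attr(seq, "id"))
  s <- unclass(seq)
  # all maximal G-runs of length >= min_run: start, end
  m <- gregexpr(sprintf("G{%d,}", min_run), s)[[1]]
  hits <- data.frame(start = integer(0), end = integer(0),
                     n_runs = integer(0), run_lengths = character(0),
                     loop_lengths = character(0), motif = character(0),
                     stringsAsFactors = FALSE)
  if (m[1] == -1L) return(structure(hits, id = attr(seq, "id"), class = c("g4_hits", "data.frame")))
  rs <- as.integer(m)
  re <- rs + attr(m, "match.length") - 1L

  k <- 1L
  while (k <= length(rs)) {
    chain <- k
    while (TRUE) {
      nxt <- chain[length(chain)]
      cand <- which(rs > re[nxt] & rs - re[nxt] - 1L >= loop_min &
                      rs - re[nxt] - 1L <= loop_max)
      cand <- cand[cand > nxt]
      if (!length(cand)) break
      chain <- c(chain, cand[1L])  # 5'-most continuation
    }
    if (length(chain) >= 4L) {
      a <- rs[chain[1L]]; b <- re[chain[length(chain)]]
      loops <- if (length(chain) > 1L)
        rs[chain[-1L]] - re[chain[-length(chain)]] - 1L else integer(0)
      hits <- rbind(hits, data.frame(
        start = a, end = b, n_runs = length(chain),
        run_lengths = paste(re[chain] - rs[chain] + 1L, collapse = ","),
        loop_lengths = paste(loops, collapse = ","),
        motif = substr(s, a, b), stringsAsFactors = FALSE))
      k <- chain[length(chain)] + 1L
    } else {
      k <- k + 1L
    }
  }
  structure(hits, id = attr(seq, "id"), class = c("g4_hits", "data.frame"))
}

#' Certify that a structure is pseudoknot-free
#'
#' All structures produced by this package are nested by construction; this
#' predicate exists as an explicit assertion for structures imported from
#' elsewhere. Accepts a raw integer partner vector (unvalidated) so that
#' crossing pair sets can be tested.
#'
#' @param pt integer partner vector (0 = unpaired) or `pair_table`.
#' @return `TRUE` when no two pairs cross, `FALSE` otherwise.
#' @examples
#' pseudoknot_free(parse_dotbracket("((...))"))
#' pseudoknot_free(c(3L, 4L, 1L, 2L))  # crossing: FALSE
#' @export
pseudoknot_free <- function(pt) {
  pt <- as.integer(pt)
  n <- length(pt)
  open <- integer(0)
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j == 0L) next
    if (j < 1L || j > n || j == i || pt[j] != i) return(FALSE)
    if (j > i) open <- c(open, j)
    else {
      if (!length(open) || open[length(open)] != i) return(FALSE)
      open <- open[-length(open)]
    }
  }
  TRUE
}

#' Export quadruplex hits as BED-like TSV
#'
#' Columns: sequence id, start, end (1-based inclusive), motif string.
#'
#' @param hits a [g4_scan()] result (or a list of them).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_g4_tsv <- function(hits, path) {
  if (inherits(hits, "g4_hits")) hits <- list(hits)
  rows <- do.call(rbind, lapply(hits, function(h) {
    if (!nrow(h)) return(NULL)
    data.frame(id = attr(h, "id"), start = h$start, end = h$end,
               motif = h$motif, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(id = character(0), start = integer(0),
                       end = integer(0), motif = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
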