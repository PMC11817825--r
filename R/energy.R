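#' Minimum free energy folding of single-stranded DNA
#'
#' Computes a minimum-free-energy pseudoknot-free secondary structure under
#' the nearest-neighbor model by Zuker-style dynamic programming. The whole
#' recursion runs in integer hundredths of kcal/mol; the energy is converted
#' to kcal/mol only at the boundary, so results are bit-identical across
#' runs. The dangle model is "d2" (both-side terminal mismatches on every
#' helix end in exterior and multi loops); isolated (lonely) pairs are
#' permitted; interior loops are capped at 30 unpaired bases in the search.
#' Tie-breaking in the traceback prefers the pairing branch, then the
#' smaller 5' index, so the returned structure is deterministic.
#'
#' @param seq a [dna_sequence()] or character scalar.
#' @param params an `nn_params` object (default: bundled DNA Mathews-2004,
#'   37 degrees C).
#' @param max_n maximum sequence length accepted (default 10000).
#' @return An object of class `fold_result` with fields `id`, `sequence`,
#'   `structure` (a `pair_table`), `dotbracket`, `energy` (kcal/mol),
#'   `energy_int` (hundredths of kcal/mol), `dangles`, and
#'   `params_checksum`.
#' @examples
#' mfe_fold("GGGGCCAAAAAGGCCCC")
#' @export
mfe_fold <- function(seq, params = dna_params(), max_n = 10000L) {
  seq <- as_dna(seq, id = if (is.character(seq)) "seq" else attr(seq, "id"))
  n <- attr(seq, "n")
  if (n > max_n) stop(sprintf("sequence longer than max_n = %d", max_n))
  res <- .fold_mfe_cpp(seq_codes(seq), params)
  new_fold_result(seq, new_pair_table(res$pt), res$energy, params)
}

new_fold_result <- function(seq, pt, energy_int, params) {
  structure(list(id = attr(seq, "id"), sequence = unclass(seq),
                 structure = pt, dotbracket = to_dotbracket(pt),
                 energy = energy_int / 100, energy_int = as.integer(energy_int),
                 dangles = "d2", params_checksum = params$checksum),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf(">%s\n%s\n%s (%.2f)\n", x$id, x$sequence, x$dotbracket,
              x$energy))
  invisible(x)
}

#' Evaluate the energy of a given structure
#'
#' Sums the nearest-neighbor loop-face terms over the unique loop
#' decomposition of `pt`, in integer hundredths of kcal/mol, and converts
#' to kcal/mol. `eval_structure_energy(seq, mfe_fold(seq)$structure)`
#' equals `mfe_fold(seq)$energy` exactly (same integer arithmetic).
#'
#' @param seq a [dna_sequence()] or character scalar.
#' @param pt a `pair_table` valid for `seq` under the allowed-pair matrix.
#' @param params an `nn_params` object.
#' @return Energy in kcal/mol.
#' @export
eval_structure_energy <- function(seq, pt, params = dna_params()) {
  seq <- as_dna(seq)
  pt <- as_pair_table(pt)
  .eval_energy_cpp(seq_codes(seq), pt, params) / 100
}

#' Energy of a single loop face
#'
#' Computes the nearest-neighbor contribution of one loop record from
#' [decompose()], in integer hundredths of kcal/mol: stacking term for
#' stacks; length + mismatch terms for hairpins; length + asymmetry +
#' mismatch terms for bulges and interior loops; `a + b*k + c*u` plus
#' per-helix terminal terms for multiloops; terminal terms only for the
#' exterior face.
#'
#' @param record one element of a [decompose()] result.
#' @param seq the [dna_sequence()] the structure belongs to.
#' @param params an `nn_params` object.
#' @return Integer energy in hundredths of kcal/mol.
#' @export
loop_energy <- function(record, seq, params = dna_params()) {
  seq <- as_dna(seq)
  s <- seq_codes(seq)
  n <- length(s)
  base_at <- function(k) if (k >= 1L && k <= n) s[k] else 0L
  ptype <- function(i, j) {
    t <- pair_type_of(substr(seq, i, i), substr(seq, j, j))
    if (t == 0L) stop(sprintf("disallowed base pair between positions %d and %d", i, j))
    t
  }
  type <- record$type
  if (type == "exterior") {
    e <- 0L
    for (br in record$branches) {
      i <- br[1]; j <- br[2]
      e <- e + .e_extstem_cpp(params, ptype(i, j), base_at(i - 1L),
                              base_at(j + 1L))
    }
    return(e)
  }
  i <- record$closing[1]; j <- record$closing[2]
  t <- ptype(i, j)
  if (type == "hairpin") {
    ctx <- substr(seq, i, j)
    return(.e_hairpin_cpp(params, j - i - 1L, t, s[i + 1L], s[j - 1L], ctx))
  }
  if (type %in% c("stack", "bulge", "internal")) {
    br <- record$branches[[1]]
    p <- br[1]; q <- br[2]
    t2 <- ptype(q, p)
    return(.e_intloop_cpp(params, p - i - 1L, j - q - 1L, t, t2,
                          s[i + 1L], s[j - 1L], s[p - 1L], s[q + 1L]))
  }
  if (type == "multiloop") {
    e <- params$ml[["closing"]] +
      .e_mlstem_cpp(params, ptype(j, i), s[j - 1L], s[i + 1L])
    for (br in record$branches) {
      p <- br[1]; q <- br[2]
      e <- e + .e_mlstem_cpp(params, ptype(p, q), s[p - 1L], s[q + 1L])
    }
    return(e + record$u * params$ml[["base"]])
  }
  stop("unknown loop record type: ", type)
}

#' Write fold results as Vienna-style plain text
#'
#' One block per result: a `>id` header line, the sequence, and the
#' dot-bracket with the energy in parentheses, e.g. `(-17.90)`.
#'
#' @param results a `fold_result` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(results, path) {
  if (inherits(results, "fold_result")) results <- list(results)
  out <- unlist(lapply(results, function(x)
    c(paste0(">", x$id), x$sequence,
      sprintf("%s (%.2f)", x$dotbracket, x$energy))))
  writeLines(out, path)
  invisible(path)
}

#' Write a fold result as a connectivity table (CT)
#'
#' Standard 6-column CT format: index, base, 5' connect, 3' connect,
#' pairing partner (0 if none), natural numbering.
#'
#' @param result a `fold_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ct <- function(result, path) {
  stopifnot(inherits(result, "fold_result"))
  n <- nchar(result$sequence)
  bases <- strsplit(result$sequence, "")[[1]]
  pt <- result$structure
  hdr <- sprintf("%d ENERGY = %.2f %s", n, result$energy, result$id)
  rows <- sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                  seq_len(n) - 1L, c(seq_len(n - 1L) + 1L, 0L), pt, seq_len(n))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
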