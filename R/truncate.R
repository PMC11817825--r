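#' Sliding-window truncation scan of a parent aptamer
#'
#' Enumerates all end-truncations of a parent sequence over a grid of 5'
#' and 3' trims, refolds every candidate, and tests each minimum-free-energy
#' structure against the designated motif. Re-folding every candidate is the
#' point: preserving a motif "on paper" by deleting positions from a drawn
#' structure does not guarantee the truncated sequence still folds into it.
#'
#' @param parent a [dna_sequence()] or character scalar.
#' @param spec a [motif_spec()] that the full-length parent must satisfy.
#' @param params an `nn_params` object.
#' @param max_trim5,max_trim3 largest number of bases removed from each end
#'   (defaults: half the parent length each).
#' @param min_len smallest candidate length retained (default 10).
#' @return An object of class `truncation_landscape`: a data frame with one
#'   row per candidate (`trim5`, `trim3`, `length`, `energy_kcal_mol`,
#'   `motif_preserved`, `dotbracket`), sorted by total trim then `trim5`,
#'   with attributes `parent_id`, `spec` and `selected` (the minimal
#'   motif-preserving candidate under the default criterion of
#'   [select_minimal()]).
#' @examples
#' fx <- make_synthetic_aptamer(synthetic_aptamer_spec(seed = 1))
#' land <- truncation_scan(fx$sequence, fx$motif, max_trim5 = 8, max_trim3 = 8)
#' attr(land, "selected")[, 1:4]
#' @export
truncation_scan <- function(parent, spec, params = dna_params(),
                            max_trim5 = NULL, max_trim3 = NULL,
                            min_len = 10L) {
  parent <- as_dna(parent, id = if (is.character(parent)) "parent" else attr(parent, "id"))
  stopifnot(inherits(spec, "motif_spec"))
  n <- attr(parent, "n")
  if (is.null(max_trim5)) max_trim5 <- n %/% 2L
  if (is.null(max_trim3)) max_trim3 <- n %/% 2L

  f0 <- mfe_fold(parent, params)
  if (!isTRUE(c(matches_motif(f0$structure, spec))))
    stop("parent lacks motif: full-length MFE structure does not match the spec")

  grid <- expand.grid(trim5 = 0:max_trim5, trim3 = 0:max_trim3)
  grid <- grid[n - grid$trim5 - grid$trim3 >= min_len, , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    t5 <- grid$trim5[r]; t3 <- grid$trim3[r]
    sub <- substr(unclass(parent), t5 + 1L, n - t3)
    f <- mfe_fold(dna_sequence(sub, id = sprintf("%s_t5=%d_t3=%d",
                                                 attr(parent, "id"), t5, t3)),
                  params)
    m <- matches_motif(f$structure, spec)
    data.frame(trim5 = t5, trim3 = t3, length = nchar(sub),
               energy_kcal_mol = f$energy, motif_preserved = c(m),
               dotbracket = f$dotbracket, stringsAsFactors = FALSE)
  })
  land <- do.call(rbind, rows)
  land <- land[order(land$trim5 + land$trim3, land$trim5), ]
  rownames(land) <- NULL
  attr(land, "parent_id") <- attr(parent, "id")
  attr(land, "parent") <- unclass(parent)
  attr(land, "spec") <- spec
  class(land) <- c("truncation_landscape", "data.frame")
  attr(land, "selected") <- select_minimal(land)
  land
}

#' Select the minimal motif-preserving truncation
#'
#' Default criterion: the maximal total trim among motif-preserving rows;
#' ties broken by lower folding energy, then by smaller 5' trim.
#'
#' @param landscape a [truncation_scan()] result.
#' @param criterion `"max_trim"` (default) or `"min_energy"` (most stable
#'   preserving candidate regardless of length).
#' @return The selected row of the landscape (single-row data frame).
#' @export
select_minimal <- function(landscape, criterion = c("max_trim", "min_energy")) {
  criterion <- match.arg(criterion)
  keep <- landscape[landscape$motif_preserved, , drop = FALSE]
  if (!nrow(keep)) stop("no motif-preserving truncation candidate")
  ord <- if (criterion == "max_trim") {
    order(-(keep$trim5 + keep$trim3), keep$energy_kcal_mol, keep$trim5)
  } else {
    order(keep$energy_kcal_mol, -(keep$trim5 + keep$trim3), keep$trim5)
  }
  out <- keep[ord[1L], , drop = FALSE]
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

#' @export
print.truncation_landscape <- function(x, ...) {
  sel <- attr(x, "selected")
  cat(sprintf("truncation landscape of '%s': %d candidates, %d preserve the motif\n",
              attr(x, "parent_id"), nrow(x), sum(x$motif_preserved)))
  cat(sprintf("selected: trim5=%d trim3=%d length=%d energy=%.2f kcal/mol\n",
              sel$trim5, sel$trim3, sel$length, sel$energy_kcal_mol))
  invisible(x)
}

#' Export a truncation landscape as TSV
#'
#' Columns: trim5, trim3, length, energy_kcal_mol, motif_preserved,
#' dotbracket — one row per candidate, for re-plotting energy landscapes.
#'
#' @param landscape a [truncation_scan()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_landscape_tsv <- function(landscape, path) {
  utils::write.table(as.data.frame(landscape), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
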