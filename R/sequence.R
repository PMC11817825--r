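#' DNA sequence objects
#'
#' A `dna_sequence` is an identified string over the alphabet `A`, `C`,
#' `G`, `T`. Input is normalized to uppercase; any other character
#' (including `U`) is rejected so RNA input cannot slip through silently.
#'
#' @param residues character scalar of bases.
#' @param id short label for the sequence.
#' @return An object of class `dna_sequence`: a character scalar with
#'   attributes `id` and `n` (length in nucleotides).
#' @examples
#' dna_sequence("gattaca", id = "probe")
#' @export
dna_sequence <- function(residues, id = "seq") {
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("'residues' must be a single character string")
  res <- toupper(residues)
  if (nchar(res) < 1L) stop("sequence must have length >= 1")
  bad <- regmatches(res, regexpr("[^ACGT]", res))
  if (length(bad) && nzchar(bad)) {
    hint <- if (bad == "U") " (found 'U': supply DNA, not RNA)" else ""
    stop(sprintf("illegal character '%s' in sequence '%s'%s", bad, id, hint))
  }
  structure(res, id = as.character(id), n = nchar(res), class = "dna_sequence")
}

#' @export
as.character.dna_sequence <- function(x, ...) {
  attributes(x) <- NULL
  x
}

#' @export
print.dna_sequence <- function(x, ...) {
  cat(sprintf(">%s (%d nt)\n%s\n", attr(x, "id"), attr(x, "n"),
              unclass(x)))
  invisible(x)
}

# coerce character input leniently; keeps existing dna_sequence untouched
as_dna <- function(x, id = "seq") {
  if (inherits(x, "dna_sequence")) return(x)
  dna_sequence(x, id = id)
}

# base codes A=1 C=2 G=3 T=4 (matches src/fold.cpp)
seq_codes <- function(x) {
  m <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  unname(m[strsplit(unclass(as_dna(x)), "")[[1]]])
}

codes_to_seq <- function(codes, id = "seq") {
  dna_sequence(paste(c("A", "C", "G", "T")[codes], collapse = ""), id = id)
}

# pair type codes CG=1 GC=2 GT=3 TG=4 AT=5 TA=6, 0 = disallowed
pair_type_of <- function(a, b) {
  key <- paste0(a, b)
  m <- c(CG = 1L, GC = 2L, GT = 3L, TG = 4L, AT = 5L, TA = 6L)
  out <- m[key]
  out[is.na(out)] <- 0L
  unname(out)
}
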