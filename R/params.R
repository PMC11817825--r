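#' Nearest-neighbor energy parameter sets
#'
#' Parses the plain-text section-tagged parameter dialect used by common
#' folding software (`.par` files, "RNAfold parameter file v2.0" header)
#' into the integer tables the folding engine consumes. All energies are
#' kept as integers in hundredths of kcal/mol. Only free-energy tables are
#' used: the model is evaluated at the parameter set's reference
#' temperature of 37 degrees C and no enthalpy rescaling is performed.
#'
#' @param path path to a `.par` parameter file.
#' @return An object of class `nn_params`: a list of integer tables
#'   (stacking, loop-length, mismatch, 1x1/2x1/2x2 interior, multiloop
#'   coefficients, dangles, asymmetry), the terminal non-GC penalty, the
#'   logarithmic loop extrapolation coefficient, and bookkeeping fields
#'   `checksum` (md5 of the parameter text) and `source`.
#' @seealso [dna_params()] for the bundled DNA Mathews-2004 set.
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  parse_par_lines(readLines(path, warn = FALSE), source = path)
}

#' Bundled DNA Mathews-2004 parameters
#'
#' Loads the DNA nearest-neighbor free-energy tables (Mathews 2004
#' parameterization, 37 degrees C) shipped with the package. The set allows
#' the pairs C-G, G-C, G-T, T-G, A-T and T-A. The result is cached for the
#' session.
#'
#' @return An `nn_params` object (see [load_parameter_set()]).
#' @examples
#' p <- dna_params()
#' p$ml  # multiloop coefficients a (closing), b (per branch), c (per base)
#' @export
dna_params <- function() {
  if (!is.null(.pkg_cache$dna_params)) return(.pkg_cache$dna_params)
  chunks <- sort(list.files(system.file("extdata", package = "aptamin"),
                            pattern = "^dna_mathews2004_dg\\.par\\.", full.names = TRUE))
  if (!length(chunks)) stop("bundled parameter chunks missing")
  lines <- unlist(lapply(chunks, readLines, warn = FALSE))
  p <- parse_par_lines(lines, source = "dna_mathews2004 (bundled)")
  .pkg_cache$dna_params <- p
  p
}

# expected token counts per section (free-energy tables only)
.par_sections <- c(
  stack = 49L,
  mismatch_hairpin = 175L, mismatch_internal = 175L,
  mismatch_internal_1n = 175L, mismatch_internal_23 = 175L,
  mismatch_multi = 175L, mismatch_exterior = 175L,
  dangle5 = 35L, dangle3 = 35L,
  int11 = 1225L, int21 = 6125L, int22 = 9216L,
  hairpin = 31L, bulge = 31L, internal = 31L,
  ML_params = 6L, NINIO = 3L, Misc = 4L
)

parse_par_lines <- function(lines, source = "unknown") {
  if (!length(lines) || !grepl("parameter file", lines[1], ignore.case = TRUE))
    stop("not a recognized parameter file (missing v2.0 header): ", source)

  # strip /* ... */ comments; an unterminated /* discards the line tail
  clean <- gsub("/\\*.*?\\*/", " ", lines)
  clean <- sub("/\\*.*$", "", clean)

  sections <- list()
  cur <- NULL
  for (ln in seq_along(clean)) {
    line <- trimws(clean[ln])
    if (!nzchar(line)) next
    if (grepl("^##", line)) next
    if (grepl("^#", line)) {
      cur <- trimws(sub("^#", "", line))
      if (identical(cur, "END")) break
      sections[[cur]] <- list(tokens = character(0), lines = integer(0))
      next
    }
    if (is.null(cur)) next
    toks <- strsplit(line, "[ \t]+")[[1]]
    sections[[cur]]$tokens <- c(sections[[cur]]$tokens, toks)
    sections[[cur]]$lines <- c(sections[[cur]]$lines,
                               rep(ln, length(toks)))
  }

  get_ints <- function(name) {
    if (is.null(sections[[name]]))
      stop("missing mandatory section '", name, "' in ", source)
    toks <- sections[[name]]$tokens
    want <- .par_sections[[name]]
    vals <- suppressWarnings(as.integer(toks))
    vals[toks == "INF"] <- .E_INF
    bad <- which(is.na(vals) & toks != "INF")
    if (length(bad))
      stop(sprintf("malformed entry '%s' in section '%s' (line %d)",
                   toks[bad[1]], name, sections[[name]]$lines[bad[1]]))
    if (length(vals) < want)
      stop(sprintf("section '%s' truncated: %d of %d values present",
                   name, length(vals), want))
    vals[seq_len(want)]
  }

  special <- function(name, loop_len) {
    sec <- sections[[name]]
    if (is.null(sec) || !length(sec$tokens))
      return(list(seq = character(0), e = integer(0)))
    toks <- sec$tokens
    # rows of "SEQ dG dH"
    idx <- seq(1L, length(toks), by = 3L)
    list(seq = toupper(toks[idx]),
         e = as.integer(toks[pmin(idx + 1L, length(toks))]))
  }

  ml <- get_ints("ML_params")       # cu cu_dH cc cc_dH ci ci_dH
  nin <- get_ints("NINIO")          # m m_dH max
  misc <- get_ints("Misc")          # DuplexInit dH TerminalAU dH

  p <- list(
    stack = get_ints("stack"),
    mm_hairpin = get_ints("mismatch_hairpin"),
    mm_interior = get_ints("mismatch_internal"),
    mm_interior_1n = get_ints("mismatch_internal_1n"),
    mm_interior_23 = get_ints("mismatch_internal_23"),
    mm_multi = get_ints("mismatch_multi"),
    mm_exterior = get_ints("mismatch_exterior"),
    dangle5 = get_ints("dangle5"),
    dangle3 = get_ints("dangle3"),
    int11 = get_ints("int11"),
    int21 = get_ints("int21"),
    int22 = get_ints("int22"),
    hairpin = get_ints("hairpin"),
    bulge = get_ints("bulge"),
    interior = get_ints("internal"),
    ml = c(base = ml[1], closing = ml[3], intern = ml[5]),
    ninio = c(m = nin[1], max = nin[3]),
    terminal_au = misc[3],
    lxc = 107.856,            # logarithmic loop extrapolation, dekacal
    temperature = 37,
    special_hairpins = list(tetra = special("Tetraloops", 4L),
                            tri = special("Triloops", 3L),
                            hexa = special("Hexaloops", 6L)),
    source = source
  )
  tf <- tempfile()
  writeLines(lines, tf)
  p$checksum <- unname(tools::md5sum(tf))
  unlink(tf)
  class(p) <- "nn_params"
  p
}

#' @export
print.nn_params <- function(x, ...) {
  cat("nearest-neighbor parameter set\n")
  cat("  source:      ", x$source, "\n")
  cat("  checksum:    md5:", x$checksum, "\n")
  cat("  temperature: ", x$temperature, "C\n")
  cat("  pair alphabet: CG GC GT TG AT TA\n")
  cat(sprintf("  multiloop: a=%d b=%d c=%d (hundredths kcal/mol)\n",
              x$ml["closing"], x$ml["intern"], x$ml["base"]))
  invisible(x)
}

#' Allowed base pairs of a parameter set
#'
#' @param params an `nn_params` object.
#' @return Character vector of allowed pair dimers (5' base, 3' base).
#' @export
allowed_pairs <- function(params) {
  c("CG", "GC", "GT", "TG", "AT", "TA")
}
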