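#' Parse dot-bracket notation into a pair table
#'
#' Converts a pseudoknot-free dot-bracket string (characters `(`, `)` and
#' `.`) into a 1-based pair table: an integer vector whose `i`-th entry is
#' the partner of position `i`, or 0 when unpaired. Hairpin loops of fewer
#' than 3 unpaired bases are rejected at parse time, matching the
#' nearest-neighbor model's minimum loop size.
#'
#' @param text dot-bracket string.
#' @return An integer vector of class `pair_table`.
#' @examples
#' parse_dotbracket("((((...))))")
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad))
    stop(sprintf("illegal character '%s' at position %d", chars[bad[1]], bad[1]))
  pt <- integer(n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      open <- c(open, i)
    } else if (chars[i] == ")") {
      if (!length(open))
        stop(sprintf("unbalanced at position %d", i))
      j <- open[length(open)]
      open <- open[-length(open)]
      pt[j] <- i
      pt[i] <- j
    }
  }
  if (length(open))
    stop(sprintf("unbalanced at position %d", open[1]))
  # minimum hairpin size is a model constraint, checked once balance holds
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j > i && j - i - 1L < 3L)
      stop(sprintf("hairpin loop shorter than 3 bases at pair (%d,%d)", i, j))
  }
  new_pair_table(pt)
}

new_pair_table <- function(pt) {
  structure(as.integer(pt), class = "pair_table")
}

#' Validate a pair table
#'
#' Checks symmetry, absence of self-pairs and of pseudoknots. The minimum
#' hairpin loop size is enforced where structures enter the system as text
#' ([parse_dotbracket()]) and by the energy model itself; tables built
#' programmatically may carry shorter loops so that structure arithmetic
#' (distances, rendering) stays total.
#'
#' @param pt integer vector (0 = unpaired, otherwise 1-based partner).
#' @return The validated `pair_table`.
#' @export
as_pair_table <- function(pt) {
  if (inherits(pt, "pair_table")) return(pt)
  pt <- as.integer(pt)
  n <- length(pt)
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j == 0L) next
    if (j < 1L || j > n || j == i || pt[j] != i)
      stop(sprintf("pair table not symmetric at position %d", i))
  }
  # pseudoknot check: opened pairs must close in LIFO order
  open <- integer(0)
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j > i) open <- c(open, j)
    else if (j != 0L) {
      if (!length(open) || open[length(open)] != i)
        stop(sprintf("pseudoknot: crossing pair at position %d", i))
      open <- open[-length(open)]
    }
  }
  new_pair_table(pt)
}

#' Render a pair table as dot-bracket notation
#'
#' @param pt a `pair_table` (see [parse_dotbracket()]).
#' @return Dot-bracket string; `parse_dotbracket(to_dotbracket(pt))`
#'   reproduces `pt`.
#' @examples
#' to_dotbracket(parse_dotbracket("((..((...))..))"))
#' @export
to_dotbracket <- function(pt) {
  pt <- as_pair_table(pt)
  out <- rep(".", length(pt))
  out[pt != 0 & pt > seq_along(pt)] <- "("
  out[pt != 0 & pt < seq_along(pt)] <- ")"
  paste(out, collapse = "")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("pair_table, %d nt, %d pairs\n%s\n",
              length(x), sum(x != 0) %/% 2L, to_dotbracket(x)))
  invisible(x)
}

# list of pairs as a 2-column matrix (i < j)
pair_list <- function(pt) {
  pt <- as_pair_table(pt)
  i <- which(pt > seq_along(pt))
  cbind(i = i, j = pt[i])
}

#' Base-pair distance between two structures
#'
#' Size of the symmetric difference of the two pair sets. Zero iff the
#' structures are identical; a metric on structures of equal length.
#'
#' @param a,b `pair_table`s of equal length.
#' @return Non-negative integer.
#' @export
base_pair_distance <- function(a, b) {
  a <- as_pair_table(a); b <- as_pair_table(b)
  if (length(a) != length(b))
    stop("structures have different lengths")
  pa <- paste(pair_list(a)[, 1], pair_list(a)[, 2])
  pb <- paste(pair_list(b)[, 1], pair_list(b)[, 2])
  length(setdiff(pa, pb)) + length(setdiff(pb, pa))
}

#' Decompose a structure into loop faces
#'
#' Splits a pseudoknot-free structure into its unique set of loop faces:
#' stacks, hairpin loops, bulges, interior loops, multiloops and the
#' exterior loop. Every position belongs to exactly one face as an interior
#' element; paired positions additionally border the face their helix
#' closes, so face sizes sum to `n + 2 * number_of_pairs`.
#'
#' @param pt a `pair_table`.
#' @return An object of class `loop_decomposition`: a list of loop records.
#'   Each record has `type` (one of `"stack"`, `"hairpin"`, `"bulge"`,
#'   `"internal"`, `"multiloop"`, `"exterior"`), `closing` (the closing pair
#'   `c(i, j)`, or `NULL` for the exterior face), `branches` (list of inner
#'   pairs `c(p, q)`), `unpaired` (positions of unpaired bases in the face),
#'   `k` (number of helices meeting the face, counting the closing helix)
#'   and `u` (number of unpaired bases in the face).
#' @examples
#' d <- decompose(parse_dotbracket("((..((...))..((...))..))"))
#' vapply(d, function(r) r$type, "")
#' @export
decompose <- function(pt) {
  pt <- as_pair_table(pt)
  n <- length(pt)
  faces <- list()

  face_of_pair <- function(i, j) {
    i <- unname(i); j <- unname(j)
    branches <- list()
    unpaired <- integer(0)
    k <- i + 1L
    while (k < j) {
      q <- pt[k]
      if (q == 0L) {
        unpaired <- c(unpaired, k)
        k <- k + 1L
      } else {
        branches[[length(branches) + 1L]] <- c(k, q)
        k <- q + 1L
      }
    }
    nb <- length(branches)
    type <-
      if (nb == 0L) "hairpin"
      else if (nb == 1L) {
        n1 <- branches[[1]][1] - i - 1L
        n2 <- j - branches[[1]][2] - 1L
        if (n1 == 0L && n2 == 0L) "stack"
        else if (n1 == 0L || n2 == 0L) "bulge"
        else "internal"
      } else "multiloop"
    list(type = type, closing = c(i, j), branches = branches,
         unpaired = unpaired, k = nb + 1L, u = length(unpaired))
  }

  # exterior face
  branches <- list()
  unpaired <- integer(0)
  k <- 1L
  while (k <= n) {
    q <- pt[k]
    if (q == 0L) { unpaired <- c(unpaired, k); k <- k + 1L }
    else { branches[[length(branches) + 1L]] <- c(k, q); k <- q + 1L }
  }
  faces[[1L]] <- list(type = "exterior", closing = NULL, branches = branches,
                      unpaired = unpaired, k = length(branches),
                      u = length(unpaired))
  pl <- pair_list(pt)
  if (nrow(pl))
    for (r in seq_len(nrow(pl)))
      faces[[length(faces) + 1L]] <- face_of_pair(pl[r, 1], pl[r, 2])
  structure(faces, n = n, class = "loop_decomposition")
}

#' @export
print.loop_decomposition <- function(x, ...) {
  tab <- table(vapply(x, function(r) r$type, ""))
  cat(sprintf("loop decomposition of %d nt structure: %s\n", attr(x, "n"),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

# face size under the n + 2*pairs accounting convention: interior unpaired
# positions + 2 per bordering helix end (closing pair + each branch pair)
face_size <- function(rec) {
  rec$u + 2L * length(rec$branches) + if (is.null(rec$closing)) 0L else 2L
}

#' Specify a structural motif to preserve
#'
#' The motif is a multiloop, optionally constrained by a minimum number of
#' helices meeting the junction, a dot-bracket fragment that must occur as
#' an exact substructure, designated sequence intervals that must remain
#' unpaired, and an optional anchor pinning the match near original
#' coordinates.
#'
#' @param min_branches minimum number of helices meeting the multiloop,
#'   counting the closing helix (default 3, a three-way junction). Zero
#'   disables the multiloop requirement: the spec then only enforces the
#'   fragment/segment conditions (useful for parents without a junction).
#' @param fragment optional dot-bracket string that must occur verbatim as
#'   a substructure (its paired positions paired identically, its dots
#'   unpaired).
#' @param segments optional list of integer intervals `c(start, end)`
#'   (1-based, in the coordinates of the structure being tested) that must
#'   be entirely unpaired.
#' @param near optional position: the multiloop's closing pair must start
#'   within `near_tol` of it.
#' @param near_tol tolerance in nucleotides for `near` (default 5).
#' @return An object of class `motif_spec`.
#' @export
motif_spec <- function(min_branches = 3L, fragment = NULL, segments = NULL,
                       near = NULL, near_tol = 5L) {
  if (!is.null(fragment)) parse_dotbracket(fragment)  # must itself be balanced
  structure(list(min_branches = as.integer(min_branches), fragment = fragment,
                 segments = segments, near = near,
                 near_tol = as.integer(near_tol)),
            class = "motif_spec")
}

# offsets (0-based) at which the dot-bracket fragment occurs as an exact
# substructure of pt
fragment_offsets <- function(pt, fragment) {
  fpt <- parse_dotbracket(fragment)
  m <- length(fpt)
  n <- length(pt)
  if (m > n) return(integer(0))
  hits <- integer(0)
  for (off in 0:(n - m)) {
    ok <- TRUE
    for (f in seq_len(m)) {
      want <- if (fpt[f] == 0L) 0L else fpt[f] + off
      if (pt[off + f] != want) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

#' Test a structure against a motif specification
#'
#' Returns `TRUE` when the structure contains a multiloop satisfying the
#' spec. By default any multiloop anywhere in the structure qualifies
#' (position drift is allowed); supply `near` in the spec to pin the match.
#'
#' @param pt a `pair_table`.
#' @param spec a [motif_spec()].
#' @return Logical scalar with attribute `match`: a list with the matched
#'   multiloop's closing pair, branch pairs, and (when a fragment was
#'   requested) the fragment offset. `NULL` when no match.
#' @export
matches_motif <- function(pt, spec) {
  pt <- as_pair_table(pt)
  stopifnot(inherits(spec, "motif_spec"))

  frag_off <- NULL
  if (!is.null(spec$fragment)) {
    offs <- fragment_offsets(pt, spec$fragment)
    if (!length(offs)) return(structure(FALSE, match = NULL))
    frag_off <- offs
  }
  if (!is.null(spec$segments)) {
    for (seg in spec$segments) {
      idx <- seg[1]:seg[2]
      if (any(idx < 1L | idx > length(pt)) || any(pt[idx] != 0L))
        return(structure(FALSE, match = NULL))
    }
  }
  if (spec$min_branches <= 0L) {
    m <- if (is.null(frag_off)) NULL else list(fragment_offset = frag_off)
    return(structure(TRUE, match = m))
  }
  dec <- decompose(pt)
  for (rec in dec) {
    if (rec$type != "multiloop") next
    if (rec$k < spec$min_branches) next
    if (!is.null(spec$near) &&
        abs(rec$closing[1] - spec$near) > spec$near_tol) next
    if (!is.null(frag_off)) {
      # the fragment, if given, must cover this multiloop's closing pair
      covered <- any(vapply(frag_off, function(o) {
        fl <- nchar(spec$fragment)
        rec$closing[1] > o && rec$closing[2] <= o + fl
      }, logical(1)))
      if (!covered) next
      return(structure(TRUE, match = list(closing = rec$closing,
                                          branches = rec$branches,
                                          fragment_offset = frag_off)))
    }
    return(structure(TRUE, match = list(closing = rec$closing,
                                        branches = rec$branches)))
  }
  structure(FALSE, match = NULL)
}
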