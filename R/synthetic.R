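#' Specification for a synthetic multiloop aptamer
#'
#' Describes a three-way-junction test aptamer: an outer stem closing a
#' multiloop from which two hairpin branches emerge, with designated loop
#' sequences, junction content, and unpaired 5'/3' padding. Synthetic
#' parents generated from such specs stand in for experimentally selected
#' multiloop aptamers, so every pipeline stage is testable with known
#' ground-truth coordinates.
#'
#' @param seed integer seed; the generated aptamer is deterministic per
#'   seed.
#' @param stems lengths (bp) of the outer stem and the two branch stems;
#'   all must be >= 4.
#' @param loops character vector of the two hairpin loop sequences (>= 3 nt
#'   each).
#' @param junction character vector of the three unpaired junction runs
#'   (after the outer stem, between the branches, before the outer stem
#'   closes).
#' @param pad5,pad3 unpaired padding lengths at the 5' and 3' ends.
#' @return An object of class `synthetic_aptamer_spec`.
#' @export
synthetic_aptamer_spec <- function(seed = 1L, stems = c(6L, 5L, 5L),
                                   loops = c("AATAA", "ATTTA"),
                                   junction = c("AA", "AA", "AA"),
                                   pad5 = 5L, pad3 = 7L) {
  if (length(stems) != 3L || any(stems < 4L))
    stop("infeasible geometry: three stems of >= 4 bp required")
  if (length(loops) != 2L || any(nchar(loops) < 3L))
    stop("infeasible geometry: two hairpin loops of >= 3 nt required")
  if (length(junction) != 3L)
    stop("three junction runs required (may be empty strings)")
  structure(list(seed = as.integer(seed), stems = as.integer(stems),
                 loops = toupper(loops), junction = toupper(junction),
                 pad5 = as.integer(pad5), pad3 = as.integer(pad3)),
            class = "synthetic_aptamer_spec")
}

# random G/C stem side of length len without triple repeats
draw_stem <- function(len) {
  repeat {
    s <- sample(c("G", "C"), len, replace = TRUE)
    r <- rle(s)
    if (max(r$lengths) <= 2L) return(paste(s, collapse = ""))
  }
}

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

#' Generate a synthetic multiloop aptamer
#'
#' Builds the sequence and designed structure described by a
#' [synthetic_aptamer_spec()]: GC-saturated stems (drawn per seed, avoiding
#' G-run triples so no quadruplex motif arises) and A/T loop, junction and
#' padding content, then verifies by refolding that the designed structure
#' is the minimum-free-energy structure. Stem draws that misfold are
#' redrawn (deterministically under the seed); generation fails if no draw
#' folds correctly.
#'
#' @param spec a [synthetic_aptamer_spec()].
#' @param params an `nn_params` object.
#' @return A list: `sequence` (a [dna_sequence()]), `structure` (the
#'   designed `pair_table`, equal to the MFE structure), `coords` (all
#'   coordinates the generator used: padding, stem intervals, loop and
#'   junction intervals, in 1-based full-sequence positions), and `motif`
#'   (a ready-made [motif_spec()] whose fragment is the designed core
#'   structure, suitable for [truncation_scan()]).
#' @examples
#' fx <- make_synthetic_aptamer(synthetic_aptamer_spec(seed = 7))
#' fx$coords$pad5
#' @export
make_synthetic_aptamer <- function(spec, params = dna_params()) {
  stopifnot(inherits(spec, "synthetic_aptamer_spec"))
  s0 <- spec$stems[1]; s1 <- spec$stems[2]; s2 <- spec$stems[3]
  l1 <- spec$loops[1]; l2 <- spec$loops[2]
  j <- spec$junction
  db <- paste0(strrep(".", spec$pad5),
               strrep("(", s0), strrep(".", nchar(j[1])),
               strrep("(", s1), strrep(".", nchar(l1)), strrep(")", s1),
               strrep(".", nchar(j[2])),
               strrep("(", s2), strrep(".", nchar(l2)), strrep(")", s2),
               strrep(".", nchar(j[3])),
               strrep(")", s0), strrep(".", spec$pad3))
  designed <- parse_dotbracket(db)

  pad_seq <- function(len) paste(rep("A", len), collapse = "")

  with_local_seed(spec$seed, {
    for (try in 1:200) {
      a0 <- draw_stem(s0); a1 <- draw_stem(s1); a2 <- draw_stem(s2)
      seqstr <- paste0(pad_seq(spec$pad5),
                       a0, j[1],
                       a1, l1, revcomp(a1),
                       j[2],
                       a2, l2, revcomp(a2),
                       j[3],
                       revcomp(a0), pad_seq(spec$pad3))
      cand <- dna_sequence(seqstr, id = sprintf("synthetic_seed%d", spec$seed))
      f <- mfe_fold(cand, params)
      if (base_pair_distance(f$structure, designed) == 0L) {
        # 1-based coordinates of every element
        p <- spec$pad5
        o5 <- c(p + 1L, p + s0); cur <- p + s0
        j1 <- if (nchar(j[1])) c(cur + 1L, cur + nchar(j[1])) else NULL
        cur <- cur + nchar(j[1])
        b1_5 <- c(cur + 1L, cur + s1); cur <- cur + s1
        loop1 <- c(cur + 1L, cur + nchar(l1)); cur <- cur + nchar(l1)
        b1_3 <- c(cur + 1L, cur + s1); cur <- cur + s1
        j2 <- if (nchar(j[2])) c(cur + 1L, cur + nchar(j[2])) else NULL
        cur <- cur + nchar(j[2])
        b2_5 <- c(cur + 1L, cur + s2); cur <- cur + s2
        loop2 <- c(cur + 1L, cur + nchar(l2)); cur <- cur + nchar(l2)
        b2_3 <- c(cur + 1L, cur + s2); cur <- cur + s2
        j3 <- if (nchar(j[3])) c(cur + 1L, cur + nchar(j[3])) else NULL
        cur <- cur + nchar(j[3])
        o3 <- c(cur + 1L, cur + s0)
        core <- substr(db, spec$pad5 + 1L, nchar(db) - spec$pad3)
        coords <- list(pad5 = spec$pad5, pad3 = spec$pad3,
                       outer_stem = list(five = o5, three = o3),
                       branch1 = list(five = b1_5, three = b1_3, loop = loop1),
                       branch2 = list(five = b2_5, three = b2_3, loop = loop2),
                       junction = list(j1 = j1, j2 = j2, j3 = j3),
                       core = c(spec$pad5 + 1L, nchar(db) - spec$pad3))
        return(list(sequence = cand, structure = designed, coords = coords,
                    motif = motif_spec(min_branches = 3L, fragment = core)))
      }
    }
    stop("infeasible geometry: no stem draw folds into the designed structure")
  })
}
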