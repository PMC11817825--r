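IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  "." = c("A", "C", "G", "T")  # dot-bracket-style "anything" convenience
)

#' Positional sequence constraints for inverse design
#'
#' One IUPAC code per position restricts the bases a design may place
#' there; fixed positions are singleton codes. Designated loop and junction
#' intervals can be carried along for later loop restoration and junction
#' editing.
#'
#' @param n target length, or an IUPAC string of length `n`.
#' @param iupac optional IUPAC string (defaults to all-`N` when `n` is a
#'   number).
#' @param fixed optional named character vector or list: positions (as
#'   integers) to pin to specific bases, e.g. `c("3" = "G")`, or a list of
#'   `list(at = c(start, end), bases = "...")` intervals.
#' @param loops optional list of intervals `c(start, end)` marking
#'   functional loops.
#' @param junction optional interval `c(start, end)` marking the multiloop
#'   junction.
#' @return An object of class `seq_constraint`.
#' @export
seq_constraint <- function(n, iupac = NULL, fixed = NULL, loops = NULL,
                           junction = NULL) {
  if (is.character(n) && length(n) == 1L) { iupac <- n; n <- nchar(iupac) }
  n <- as.integer(n)
  if (is.null(iupac)) iupac <- strrep("N", n)
  if (nchar(iupac) != n) stop("IUPAC string length does not match n")
  codes <- strsplit(toupper(iupac), "")[[1]]
  bad <- which(!codes %in% names(IUPAC))
  if (length(bad)) stop(sprintf("unknown IUPAC code '%s' at position %d",
                                codes[bad[1]], bad[1]))
  if (!is.null(fixed)) {
    if (is.list(fixed)) {
      for (f in fixed) {
        idx <- f$at[1]:f$at[2]
        if (nchar(f$bases) != length(idx))
          stop("fixed interval and replacement lengths differ")
        codes[idx] <- strsplit(toupper(f$bases), "")[[1]]
      }
    } else {
      at <- as.integer(names(fixed))
      if (any(at < 1L | at > n)) stop("fixed position beyond target length")
      codes[at] <- toupper(unname(unlist(fixed)))
    }
  }
  structure(list(n = n, codes = codes, loops = loops, junction = junction),
            class = "seq_constraint")
}

allowed_bases <- function(constraint, i) IUPAC[[constraint$codes[i]]]

# run a block of code under a private RNG stream, restoring the caller's
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# allowed (a, b) dimers for a paired position under the constraint, with
# sampling weights favoring the stable Watson-Crick G-C pair over A-T and
# the destabilizing G-T wobble (stems drawn this way start near the stable
# end of the design space, where A-T to G-C replacement is the obvious
# stabilizing move)
allowed_pair_dimers <- function(constraint, i, j) {
  a <- allowed_bases(constraint, i)
  b <- allowed_bases(constraint, j)
  grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
  grid <- grid[pair_type_of(grid$a, grid$b) > 0L, , drop = FALSE]
  if (nrow(grid)) {
    w <- c(4, 4, 0.25, 0.25, 1, 1)  # CG GC GT TG AT TA
    grid$w <- w[pair_type_of(grid$a, grid$b)]
  }
  grid
}

sample_dimer <- function(dimers) {
  dimers[sample.int(nrow(dimers), 1L, prob = dimers$w), c("a", "b")]
}

#' Seeded constrained inverse folding
#'
#' Searches sequence space for a sequence whose minimum-free-energy
#' structure equals the target, by a seeded adaptive walk: start from a
#' random constraint-compatible sequence whose paired positions hold
#' complementary bases, then repeatedly mutate positions lying in
#' mismatched loop faces (paired positions are mutated as complementary
#' dimers), accepting moves that do not increase the base-pair distance
#' between the candidate's MFE structure and the target. The walk is
#' deterministic for a fixed seed.
#'
#' @param target target structure: a `pair_table` or dot-bracket string.
#' @param constraints a [seq_constraint()], or `NULL` for unconstrained.
#' @param seed integer seed for this run.
#' @param max_steps mutation budget (default `50 * n`).
#' @param params an `nn_params` object.
#' @param stall_limit abort the run as failed after this many consecutive
#'   non-improving steps (default `8 * n`).
#' @return An object of class `design_run`: `seed`, `steps`, `success`,
#'   `sequence` (best candidate), `distance` (base-pair distance of its MFE
#'   structure to the target; 0 on success), `mfe` (its MFE structure).
#' @export
inverse_fold <- function(target, constraints = NULL, seed = 1L,
                         max_steps = NULL, params = dna_params(),
                         stall_limit = NULL) {
  if (is.character(target)) target <- parse_dotbracket(target)
  target <- as_pair_table(target)
  n <- length(target)
  if (is.null(constraints)) constraints <- seq_constraint(n)
  if (constraints$n != n) stop("constraint length does not match target")
  if (is.null(max_steps)) max_steps <- 50L * n
  if (is.null(stall_limit)) stall_limit <- 8L * n

  pairs <- pair_list(target)
  # feasibility before search
  if (nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      if (!nrow(allowed_pair_dimers(constraints, pairs[r, 1], pairs[r, 2])))
        stop(sprintf("infeasible constraints: no allowed pair at (%d,%d)",
                     pairs[r, 1], pairs[r, 2]))
    }

  partner <- as.integer(target)

  with_local_seed(seed, {
    # initial sequence
    cur <- character(n)
    for (i in seq_len(n)) {
      if (partner[i] == 0L) {
        ab <- allowed_bases(constraints, i)
        cur[i] <- ab[sample.int(length(ab), 1L)]
      }
    }
    if (nrow(pairs))
      for (r in seq_len(nrow(pairs))) {
        d <- allowed_pair_dimers(constraints, pairs[r, 1], pairs[r, 2])
        pick <- sample_dimer(d)
        cur[pairs[r, 1]] <- pick$a
        cur[pairs[r, 2]] <- pick$b
      }

    fold_of <- function(chars) mfe_fold(paste(chars, collapse = ""), params)
    f <- fold_of(cur)
    dist <- base_pair_distance(f$structure, target)
    best <- list(seq = cur, dist = dist, fold = f)
    steps <- 0L
    stall <- 0L

    while (dist > 0L && steps < max_steps && stall < stall_limit) {
      # positions in the symmetric difference of pair sets
      mism <- which((f$structure != partner))
      cand <- if (length(mism)) mism else seq_len(n)
      # keep only positions with freedom to change
      free <- cand[vapply(cand, function(i) {
        if (partner[i] > 0L)
          nrow(allowed_pair_dimers(constraints, min(i, partner[i]),
                                   max(i, partner[i]))) > 1L
        else length(allowed_bases(constraints, i)) > 1L
      }, logical(1))]
      if (!length(free)) break
      w <- free[sample.int(length(free), 1L)]
      prop <- cur
      if (partner[w] > 0L) {
        i <- min(w, partner[w]); j <- max(w, partner[w])
        d <- allowed_pair_dimers(constraints, i, j)
        d <- d[!(d$a == cur[i] & d$b == cur[j]), , drop = FALSE]
        pick <- sample_dimer(d)
        prop[i] <- pick$a; prop[j] <- pick$b
      } else {
        ab <- setdiff(allowed_bases(constraints, w), cur[w])
        prop[w] <- ab[sample.int(length(ab), 1L)]
      }
      steps <- steps + 1L
      fp <- fold_of(prop)
      dp <- base_pair_distance(fp$structure, target)
      if (dp <= dist) {
        stall <- if (dp < dist) 0L else stall + 1L
        cur <- prop; f <- fp; dist <- dp
        if (dist < best$dist) best <- list(seq = cur, dist = dist, fold = f)
      } else {
        stall <- stall + 1L
      }
    }

    structure(list(seed = as.integer(seed), steps = steps,
                   success = best$dist == 0L,
                   sequence = dna_sequence(paste(best$seq, collapse = ""),
                                           id = sprintf("design_seed%d", seed)),
                   distance = best$dist, mfe = best$fold),
              class = "design_run")
  })
}

#' @export
print.design_run <- function(x, ...) {
  cat(sprintf("design run (seed %d): %s after %d steps, distance %d\n",
              x$seed, if (x$success) "success" else "failure", x$steps,
              x$distance))
  print(x$sequence)
  invisible(x)
}

# reproducible per-run seed from a master seed (Lehmer-style mix, < 2^31)
derive_seed <- function(master_seed, i) {
  m <- 2147483647
  x <- (as.numeric(master_seed) %% m) * 48271 + as.numeric(i) * 104729
  as.integer(x %% m) + 1L
}

#' Run a batch of seeded inverse-folding designs
#'
#' Repeats [inverse_fold()] with per-run seeds derived reproducibly from a
#' master seed, collapses successful designs to unique sequences, scores
#' each unique design by its MFE, screens them for canonical G-quadruplex
#' motifs (flagged designs are excluded from the ranking), and ranks the
#' remainder by MFE ascending, ties broken lexicographically.
#'
#' @param target target structure (`pair_table` or dot-bracket string).
#' @param constraints a [seq_constraint()] or `NULL`.
#' @param n_runs number of independent runs (the study-scale default is
#'   1000; use fewer for quick scans).
#' @param master_seed integer master seed.
#' @param params an `nn_params` object.
#' @param ... passed to [inverse_fold()] (e.g. `max_steps`).
#' @return An object of class `design_batch`: `target` (dot-bracket),
#'   `n_runs`, `master_seed`, `runs` (data frame: seed, steps, success,
#'   distance, sequence), and `designs` (data frame of unique successful
#'   sequences: sequence, energy_kcal_mol, g4_flagged, rank with `NA` for
#'   flagged designs), plus `params_checksum`.
#' @export
run_design_batch <- function(target, constraints = NULL, n_runs = 100L,
                             master_seed = 1L, params = dna_params(), ...) {
  if (is.character(target)) target <- parse_dotbracket(target)
  target <- as_pair_table(target)
  stopifnot(n_runs >= 1L)

  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs))
    runs[[i]] <- inverse_fold(target, constraints,
                              seed = derive_seed(master_seed, i),
                              params = params, ...)

  run_df <- data.frame(
    run = seq_len(n_runs),
    seed = vapply(runs, function(r) r$seed, integer(1)),
    steps = vapply(runs, function(r) r$steps, integer(1)),
    success = vapply(runs, function(r) r$success, logical(1)),
    distance = vapply(runs, function(r) r$distance, integer(1)),
    sequence = vapply(runs, function(r) unclass(r$sequence), character(1)),
    stringsAsFactors = FALSE)

  uniq <- unique(run_df$sequence[run_df$success])
  designs <- data.frame(sequence = uniq, stringsAsFactors = FALSE)
  if (nrow(designs)) {
    designs$energy_kcal_mol <- vapply(uniq, function(s)
      mfe_fold(s, params)$energy, numeric(1), USE.NAMES = FALSE)
    designs$g4_flagged <- vapply(uniq, function(s) nrow(g4_scan(s)) > 0L,
                                 logical(1), USE.NAMES = FALSE)
    ord <- order(designs$energy_kcal_mol, designs$sequence)
    designs <- designs[ord, , drop = FALSE]
    rownames(designs) <- NULL
    designs$rank <- NA_integer_
    ok <- which(!designs$g4_flagged)
    designs$rank[ok] <- seq_along(ok)
  } else {
    designs$energy_kcal_mol <- numeric(0)
    designs$g4_flagged <- logical(0)
    designs$rank <- integer(0)
  }

  structure(list(target = to_dotbracket(target), n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed), runs = run_df,
                 designs = designs, params_checksum = params$checksum),
            class = "design_batch")
}

#' @export
print.design_batch <- function(x, ...) {
  cat(sprintf("design batch: %d runs (master seed %d), %d successes, %d unique designs\n",
              x$n_runs, x$master_seed, sum(x$runs$success), nrow(x$designs)))
  if (nrow(x$designs)) {
    best <- x$designs[!x$designs$g4_flagged, , drop = FALSE]
    if (nrow(best))
      cat(sprintf("best ranked design: %.2f kcal/mol\n%s\n",
                  best$energy_kcal_mol[1], best$sequence[1]))
  }
  invisible(x)
}

#' @export
summary.design_batch <- function(object, ...) {
  cat(sprintf("target:        %s\n", object$target))
  cat(sprintf("runs:          %d (master seed %d)\n", object$n_runs,
              object$master_seed))
  cat(sprintf("successes:     %d\n", sum(object$runs$success)))
  cat(sprintf("unique:        %d\n", nrow(object$designs)))
  cat(sprintf("G4-flagged:    %d\n", sum(object$designs$g4_flagged)))
  if (nrow(object$designs))
    cat(sprintf("energy range:  %.2f .. %.2f kcal/mol\n",
                min(object$designs$energy_kcal_mol),
                max(object$designs$energy_kcal_mol)))
  invisible(object)
}

#' Re-truncate a designed sequence
#'
#' Applies the motif-preserving truncation scan to a successful design and
#' returns its minimal candidate. When no non-trivial trim preserves the
#' motif the untrimmed row `(0, 0)` is returned, never an empty result.
#'
#' @param run a `design_run` (or any sequence accepted by
#'   [truncation_scan()]).
#' @param spec a [motif_spec()].
#' @param params an `nn_params` object.
#' @param ... passed to [truncation_scan()].
#' @return The selected minimal row of the design's truncation landscape,
#'   with the full landscape in attribute `landscape`.
#' @export
minimize_design <- function(run, spec, params = dna_params(), ...) {
  seqin <- if (inherits(run, "design_run")) {
    if (!run$success) stop("cannot minimize an unsuccessful design run")
    run$sequence
  } else as_dna(run)
  land <- truncation_scan(seqin, spec, params, ...)
  sel <- attr(land, "selected")
  attr(sel, "landscape") <- land
  sel
}

#' Restore functional loop sequences in a design
#'
#' Overwrites designated loop intervals of a designed sequence with the
#' parent's original loop bases, refolds, and reports whether the target
#' structure survived the edit. Edits must lie in unpaired regions of the
#' target structure.
#'
#' @param design a [dna_sequence()] or character scalar.
#' @param loop_edits list of edits `list(at = c(start, end), bases = "...")`.
#' @param target the target structure the design was built for
#'   (`pair_table` or dot-bracket string).
#' @param params an `nn_params` object.
#' @param spec optional [motif_spec()]; when given, motif survival is also
#'   reported against it.
#' @return A list: `sequence` (edited), `fold` (its new `fold_result`),
#'   `structure_unchanged` (`TRUE` iff the MFE structure still equals the
#'   target), and `motif_preserved` (when `spec` given).
#' @export
restore_loop_sequences <- function(design, loop_edits, target,
                                   params = dna_params(), spec = NULL) {
  design <- as_dna(design, id = if (is.character(design)) "design" else attr(design, "id"))
  if (is.character(target)) target <- parse_dotbracket(target)
  target <- as_pair_table(target)
  n <- attr(design, "n")
  if (length(target) != n) stop("target length does not match design")
  chars <- strsplit(unclass(design), "")[[1]]
  for (ed in loop_edits) {
    idx <- ed$at[1]:ed$at[2]
    if (any(idx < 1L | idx > n)) stop("edit interval outside sequence")
    if (nchar(ed$bases) != length(idx))
      stop(sprintf("edit interval (%d,%d) and replacement length %d differ",
                   ed$at[1], ed$at[2], nchar(ed$bases)))
    if (any(target[idx] != 0L))
      stop(sprintf("edit interval (%d,%d) overlaps a paired position of the target",
                   ed$at[1], ed$at[2]))
    chars[idx] <- strsplit(toupper(ed$bases), "")[[1]]
  }
  edited <- dna_sequence(paste(chars, collapse = ""),
                         id = paste0(attr(design, "id"), "_looped"))
  f <- mfe_fold(edited, params)
  out <- list(sequence = edited, fold = f,
              structure_unchanged =
                base_pair_distance(f$structure, target) == 0L)
  if (!is.null(spec)) out$motif_preserved <- isTRUE(c(matches_motif(f$structure, spec)))
  out
}

#' Junction composition variants
#'
#' Produces one sequence variant per junction composition (e.g. `AAAA`,
#' `TTTT`, `ATAT`), leaving all other positions untouched.
#'
#' @param seq a [dna_sequence()] or character scalar.
#' @param junction interval `c(start, end)` of the multiloop junction.
#' @param compositions character vector of replacement strings, each of the
#'   junction's length.
#' @return A list of `dna_sequence` objects, named by composition.
#' @examples
#' junction_variants("ACGTACGTACGT", c(5, 8), c("AAAA", "TTTT", "ATAT"))
#' @export
junction_variants <- function(seq, junction, compositions) {
  seq <- as_dna(seq, id = if (is.character(seq)) "seq" else attr(seq, "id"))
  idx <- junction[1]:junction[2]
  out <- lapply(compositions, function(comp) {
    if (nchar(comp) != length(idx))
      stop(sprintf("composition '%s' does not match junction length %d",
                   comp, length(idx)))
    chars <- strsplit(unclass(seq), "")[[1]]
    chars[idx] <- strsplit(toupper(comp), "")[[1]]
    dna_sequence(paste(chars, collapse = ""),
                 id = sprintf("%s_junction_%s", attr(seq, "id"), toupper(comp)))
  })
  names(out) <- toupper(compositions)
  out
}

#' Size of the design space of a target structure
#'
#' The number of sequences compatible with the stem regions, estimated as 4
#' raised to the number of base pairs.
#'
#' @param target a `pair_table` or dot-bracket string.
#' @return A numeric scalar (exact for up to 26 pairs).
#' @examples
#' design_space_size("((((...))))")  # 4^4 = 256
#' @export
design_space_size <- function(target) {
  if (is.character(target)) target <- parse_dotbracket(target)
  target <- as_pair_table(target)
  4^(sum(target != 0L) / 2)
}
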