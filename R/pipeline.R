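#' Pipeline configuration
#'
#' Resolved settings for the end-to-end minimization workflow. Every run
#' writes the resolved configuration (with the parameter-set checksum and
#' master seed) next to its results, so outputs can be reproduced from the
#' emitted file alone.
#'
#' @param parent path to a FASTA file (first record used) or a sequence
#'   string / [dna_sequence()].
#' @param outdir output directory (created if missing).
#' @param motif_min_branches minimum helices at the junction (default 3).
#' @param motif_fragment optional dot-bracket fragment for the motif.
#' @param max_trim5,max_trim3 truncation grid bounds (default: half the
#'   parent length each).
#' @param n_runs inverse-design runs (default 100; the study-scale value is
#'   1000).
#' @param master_seed master seed for all randomness.
#' @param junction_compositions junction variants to build from the best
#'   design (default `AAAA`, `TTTT`, `ATAT`).
#' @param restore_loops restore the parent's hairpin-loop sequences into the
#'   best design (default TRUE).
#' @param params_file optional path to an alternative `.par` parameter
#'   file; default uses the bundled DNA Mathews-2004 set.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(parent, outdir,
                            motif_min_branches = 3L, motif_fragment = NULL,
                            max_trim5 = NULL, max_trim3 = NULL,
                            n_runs = 100L, master_seed = 1L,
                            junction_compositions = c("AAAA", "TTTT", "ATAT"),
                            restore_loops = TRUE, params_file = NULL) {
  structure(list(parent = parent, outdir = outdir,
                 motif_min_branches = as.integer(motif_min_branches),
                 motif_fragment = motif_fragment,
                 max_trim5 = max_trim5, max_trim3 = max_trim3,
                 n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed),
                 junction_compositions = junction_compositions,
                 restore_loops = isTRUE(restore_loops),
                 params_file = params_file),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

# hairpin-loop intervals of the branches of the motif-matched multiloop
branch_loop_intervals <- function(pt, match) {
  out <- list()
  for (br in match$branches) {
    # descend the branch helix to its hairpin loop
    i <- br[1]; j <- br[2]
    repeat {
      dec_inner <- NULL
      k <- i + 1L
      kids <- list()
      while (k < j) {
        q <- pt[k]
        if (q == 0L) k <- k + 1L
        else { kids[[length(kids) + 1L]] <- c(k, q); k <- q + 1L }
      }
      if (!length(kids)) { out[[length(out) + 1L]] <- c(i + 1L, j - 1L); break }
      if (length(kids) > 1L) break  # nested multiloop: no single hairpin loop
      i <- kids[[1]][1]; j <- kids[[1]][2]
    }
  }
  out
}

#' Run the end-to-end minimization pipeline
#'
#' Stages: fold the parent; sliding-window truncation scan preserving the
#' motif; inverse-design batch against the minimal candidate's structure;
#' restoration of the parent's hairpin-loop sequences into the best ranked
#' design; junction composition variants; quadruplex screen; ranked output.
#' All randomness derives from the master seed, so two runs with the same
#' configuration produce byte-identical machine outputs.
#'
#' @param config a [pipeline_config()].
#' @param params optional pre-loaded `nn_params` (overrides
#'   `config$params_file`).
#' @return Invisibly, a list with the per-stage results (`parent_fold`,
#'   `landscape`, `selected`, `batch`, `restored`, `variants`, `screen`)
#'   and the paths written.
#' @export
run_pipeline <- function(config, params = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(params))
    params <- if (is.null(config$params_file)) dna_params()
              else load_parameter_set(config$params_file)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config$outdir, name)
  log_con <- file(outfile("pipeline.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(fmt, ...) writeLines(sprintf(fmt, ...), log_con)

  parent <- if (inherits(config$parent, "dna_sequence")) config$parent
            else if (file.exists(as.character(config$parent)[1]))
              read_fasta(config$parent)[[1]]
            else as_dna(config$parent, id = "parent")
  say("stage fold: parent '%s' (%d nt)", attr(parent, "id"), attr(parent, "n"))

  spec <- motif_spec(min_branches = config$motif_min_branches,
                     fragment = config$motif_fragment)
  pf <- mfe_fold(parent, params)
  write_vienna(pf, outfile("parent.vienna.txt"))
  say("stage fold: MFE %.2f kcal/mol", pf$energy)

  land <- tryCatch(
    truncation_scan(parent, spec, params,
                    max_trim5 = config$max_trim5, max_trim3 = config$max_trim3),
    error = function(e) stop("stage truncate: ", conditionMessage(e)))
  write_landscape_tsv(land, outfile("landscape.tsv"))
  sel <- attr(land, "selected")
  say("stage truncate: selected trim5=%d trim3=%d (%d nt, %.2f kcal/mol)",
      sel$trim5, sel$trim3, sel$length, sel$energy_kcal_mol)

  minimal <- dna_sequence(substr(unclass(parent), sel$trim5 + 1L,
                                 attr(parent, "n") - sel$trim3),
                          id = paste0(attr(parent, "id"), "_minimal"))
  target <- parse_dotbracket(sel$dotbracket)

  batch <- if (config$n_runs > 0L)
    tryCatch(run_design_batch(target, NULL, n_runs = config$n_runs,
                              master_seed = config$master_seed, params = params),
             error = function(e) stop("stage design: ", conditionMessage(e)))
  else NULL
  if (!is.null(batch)) {
    write_batch_json(batch, outfile("design_batch.json"))
    if (any(!is.na(batch$designs$rank)))
      write_ranked_fasta(batch, outfile("designs_ranked.fasta"))
    say("stage design: %d/%d successes, %d unique", sum(batch$runs$success),
        batch$n_runs, nrow(batch$designs))
  }

  finals <- list(minimal)
  restored <- NULL
  m <- matches_motif(target, spec)
  if (!is.null(batch) && any(!is.na(batch$designs$rank))) {
    best <- batch$designs$sequence[match(1L, batch$designs$rank)]
    best <- dna_sequence(best, id = "best_design")
    finals <- c(finals, list(best))
    if (config$restore_loops && isTRUE(c(m)) &&
        !is.null(attr(m, "match")$branches)) {
      loops <- branch_loop_intervals(target, attr(m, "match"))
      edits <- lapply(loops, function(iv)
        list(at = iv, bases = substr(unclass(minimal), iv[1], iv[2])))
      restored <- restore_loop_sequences(best, edits, target, params, spec = spec)
      say("stage restore: %d loop(s) restored, structure %s",
          length(edits),
          if (restored$structure_unchanged) "unchanged" else "CHANGED")
      finals <- c(finals, list(restored$sequence))
    }
  }

  variants <- list()
  if (!is.null(restored) && isTRUE(c(m))) {
    # junction = first unpaired run of the matched multiloop with the same
    # length as the requested compositions
    rec <- attr(m, "match")
    dec <- decompose(target)
    ml <- Filter(function(r) r$type == "multiloop" &&
                   identical(r$closing, rec$closing), dec)[[1]]
    runs <- split(ml$unpaired, cumsum(c(1, diff(ml$unpaired) != 1)))
    want <- nchar(config$junction_compositions[1])
    jrun <- Filter(function(r) length(r) == want, runs)
    if (length(jrun)) {
      iv <- c(min(jrun[[1]]), max(jrun[[1]]))
      variants <- junction_variants(restored$sequence, iv,
                                    config$junction_compositions)
      say("stage variants: %d junction variants at (%d,%d)",
          length(variants), iv[1], iv[2])
    } else {
      say("stage variants: no junction run of length %d; skipped", want)
    }
  }
  finals <- c(finals, unname(variants))

  folds <- lapply(finals, mfe_fold, params = params)
  write_vienna(folds, outfile("final_candidates.vienna.txt"))
  write_fasta(finals, outfile("final_candidates.fasta"))
  hits <- lapply(finals, g4_scan)
  write_g4_tsv(hits, outfile("screen.tsv"))
  say("stage screen: %d candidate(s), %d with quadruplex hits",
      length(finals), sum(vapply(hits, nrow, integer(1)) > 0L))

  resolved <- list(
    parent_id = attr(parent, "id"), parent_length = attr(parent, "n"),
    motif_min_branches = config$motif_min_branches,
    motif_fragment = config$motif_fragment,
    max_trim5 = config$max_trim5, max_trim3 = config$max_trim3,
    n_runs = config$n_runs, master_seed = config$master_seed,
    junction_compositions = config$junction_compositions,
    restore_loops = config$restore_loops,
    params_checksum = params$checksum, params_source = params$source)
  yaml::write_yaml(resolved, outfile("config_resolved.yaml"))

  invisible(list(parent_fold = pf, landscape = land, selected = sel,
                 batch = batch, restored = restored, variants = variants,
                 screen = hits, outdir = config$outdir))
}
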