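#' Read DNA sequences from FASTA
#'
#' Multi-record FASTA via Biostrings, with uppercase normalization and a
#' strict DNA alphabet: records containing `U` are rejected with a message
#' advising DNA input. Duplicate record ids and empty files are errors.
#'
#' @param path FASTA file.
#' @return A named list of [dna_sequence()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  ids <- sub("[ \t].*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
  out <- lapply(seq_along(set), function(i) {
    res <- toupper(as.character(set[[i]]))
    if (grepl("U", res))
      stop(sprintf("record '%s' contains 'U': sequences must use the DNA alphabet (A/C/G/T)",
                   ids[i]))
    dna_sequence(res, id = ids[i])
  })
  names(out) <- ids
  out
}

#' Write DNA sequences to FASTA
#'
#' @param seqs a [dna_sequence()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "dna_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, unclass, character(1)))
  names(set) <- vapply(seqs, function(s) attr(s, "id"), character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Export ranked designs as FASTA
#'
#' Writes the ranked (non-flagged) unique designs of a batch, best first,
#' with energies in the headers.
#'
#' @param batch a [run_design_batch()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ranked_fasta <- function(batch, path) {
  stopifnot(inherits(batch, "design_batch"))
  d <- batch$designs[!is.na(batch$designs$rank), , drop = FALSE]
  seqs <- lapply(seq_len(nrow(d)), function(i)
    dna_sequence(d$sequence[i],
                 id = sprintf("design_rank%d_%.2fkcal", d$rank[i],
                              d$energy_kcal_mol[i])))
  write_fasta(seqs, path)
}

#' Export a design batch as JSON
#'
#' Serializes runs (with per-run seeds), unique designs with energies and
#' quadruplex flags, the target, the master seed and the parameter-set
#' checksum, so a batch can be reproduced from its own report.
#'
#' @param batch a [run_design_batch()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_batch_json <- function(batch, path) {
  stopifnot(inherits(batch, "design_batch"))
  jsonlite::write_json(
    list(target = batch$target, n_runs = batch$n_runs,
         master_seed = batch$master_seed,
         params_checksum = batch$params_checksum,
         runs = batch$runs, designs = batch$designs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
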