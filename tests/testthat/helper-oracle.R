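# exhaustive-enumeration folding oracle, independent of the DP engine:
# enumerates every valid pseudoknot-free structure (allowed pairs, hairpin
# loops >= 3) and scores each with eval_structure_energy

can_pair <- function(a, b) {
  paste0(a, b) %in% c("CG", "GC", "GT", "TG", "AT", "TA")
}

# list of pair matrices (2-column) for region [i, j] of character vector ch
enum_region <- function(ch, i, j, memo = new.env(parent = emptyenv())) {
  if (i >= j) return(list(NULL))
  key <- paste(i, j)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  out <- enum_region(ch, i + 1L, j, memo)  # i unpaired
  ks <- if (j - i >= 4L) seq(i + 4L, j) else integer(0)
  for (k in ks[can_pair(ch[i], ch[ks])]) {
    left <- enum_region(ch, i + 1L, k - 1L, memo)
    right <- enum_region(ch, k + 1L, j, memo)
    for (L in left) for (R in right)
      out[[length(out) + 1L]] <- rbind(c(i, k), L, R)
  }
  memo[[key]] <- out
  out
}

# minimum energy over all valid structures, in kcal/mol, plus the count
exhaustive_min_energy <- function(seq, params = dna_params()) {
  ch <- strsplit(toupper(as.character(seq)), "")[[1]]
  n <- length(ch)
  structs <- enum_region(ch, 1L, n)
  best <- 0
  for (ps in structs) {
    pt <- integer(n)
    if (!is.null(ps)) { pt[ps[, 1]] <- ps[, 2]; pt[ps[, 2]] <- ps[, 1] }
    e <- eval_structure_energy(seq, pt, params)
    if (e < best) best <- e
  }
  list(energy = best, n_structures = length(structs))
}
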