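test_that("a fully constrained design returns the input sequence unchanged", {
  g <- gol1_seq()
  target <- mfe_fold(g)$structure
  cons <- seq_constraint(as.character(g))  # every position fixed
  r <- inverse_fold(target, cons, seed = 1)
  expect_true(r$success)
  expect_equal(as.character(r$sequence), as.character(g))
  expect_equal(r$steps, 0L)
})

test_that("identical seeds reproduce a run exactly", {
  target <- "((((((....)))))).(((...)))"
  r1 <- inverse_fold(target, seed = 42)
  r2 <- inverse_fold(target, seed = 42)
  expect_identical(as.character(r1$sequence), as.character(r2$sequence))
  expect_identical(r1$steps, r2$steps)
  expect_identical(r1$distance, r2$distance)
})

test_that("successful runs refold to the target, verified by exhaustive enumeration", {
  target <- "((((....))))"
  for (seed in 1:5) {
    r <- inverse_fold(target, seed = seed)
    expect_true(r$success)
    refold <- mfe_fold(r$sequence)
    expect_equal(base_pair_distance(refold$structure,
                                    parse_dotbracket(target)), 0)
    # the independent enumeration oracle confirms the refold energy is the
    # global minimum for the designed sequence
    oracle <- exhaustive_min_energy(r$sequence)
    expect_equal(refold$energy, oracle$energy)
  }
})

test_that("infeasible constraints are rejected before searching", {
  expect_error(
    inverse_fold("((((....))))",
                 seq_constraint("AAAA....AAAA")),  # A-A cannot pair
    "infeasible constraints.*\\(1,12\\)")
})

test_that("constraints hold in every successful design", {
  cons <- seq_constraint("NNNSSNNNNSSNNN....NNNN")
  target <- "((((((....))))))......"
  cons <- seq_constraint(paste0(strrep("N", 6), "GAAC", strrep("N", 6),
                                strrep("N", 6)))
  r <- inverse_fold(target, cons, seed = 3)
  expect_true(r$success)
  expect_equal(substr(as.character(r$sequence), 7, 10), "GAAC")
})

test_that("design batches deduplicate, rank by energy and stay reproducible", {
  target <- "(((((.....)))))"
  b1 <- run_design_batch(target, n_runs = 12, master_seed = 5)
  b2 <- run_design_batch(target, n_runs = 12, master_seed = 5)
  expect_identical(b1$runs, b2$runs)
  expect_identical(b1$designs, b2$designs)

  # pigeonhole: unique <= successes <= runs
  expect_lte(nrow(b1$designs), sum(b1$runs$success))
  expect_lte(sum(b1$runs$success), b1$n_runs)
  expect_false(any(duplicated(b1$designs$sequence)))

  # ranking is MFE-ascending over unflagged designs
  ranked <- b1$designs[!is.na(b1$designs$rank), ]
  ranked <- ranked[order(ranked$rank), ]
  expect_true(all(diff(ranked$energy_kcal_mol) >= 0))

  # every successful design refolds to the target with distance 0
  tpt <- parse_dotbracket(target)
  for (s in b1$designs$sequence)
    expect_equal(base_pair_distance(mfe_fold(s)$structure, tpt), 0)

  # forcing two runs through the same seed collapses to one unique design
  r <- inverse_fold(target, seed = 77)
  dup <- data.frame(sequence = rep(as.character(r$sequence), 2))
  expect_equal(length(unique(dup$sequence)), 1)
})

test_that("G-quadruplex-forming designs are excluded from the ranking", {
  b <- run_design_batch("(((((.....)))))", n_runs = 6, master_seed = 2)
  flagged <- b$designs$g4_flagged
  expect_true(all(is.na(b$designs$rank[flagged])))
  expect_true(all(!is.na(b$designs$rank[!flagged])))
  for (s in b$designs$sequence[!flagged])
    expect_equal(nrow(g4_scan(s)), 0)
})

test_that("per-design re-truncation recovers padding and never returns empty", {
  fx <- make_synthetic_aptamer(synthetic_aptamer_spec(seed = 4, pad5 = 3,
                                                      pad3 = 4))
  sel <- minimize_design(fx$sequence, fx$motif,
                         max_trim5 = 6, max_trim3 = 6)
  expect_equal(c(sel$trim5, sel$trim3), c(3L, 4L))

  # an already-minimal design trims (0, 0)
  core <- substr(as.character(fx$sequence), fx$coords$core[1], fx$coords$core[2])
  sel0 <- minimize_design(core, fx$motif, max_trim5 = 4, max_trim3 = 4)
  expect_equal(c(sel0$trim5, sel0$trim3), c(0L, 0L))
})

test_that("loop restoration edits unpaired intervals and refolds", {
  fx <- make_synthetic_aptamer(synthetic_aptamer_spec(seed = 6))
  target <- fx$structure
  loop1 <- fx$coords$branch1$loop
  seqstr <- as.character(fx$sequence)

  # identity edit: nothing changes
  same <- restore_loop_sequences(
    fx$sequence, list(list(at = loop1, bases = substr(seqstr, loop1[1], loop1[2]))),
    target, spec = fx$motif)
  expect_equal(as.character(same$sequence), seqstr)
  expect_true(same$structure_unchanged)
  expect_true(same$motif_preserved)

  # a real edit into loop 1 keeps the loop unpaired and the motif intact
  new_loop <- strrep("T", loop1[2] - loop1[1] + 1)
  ed <- restore_loop_sequences(fx$sequence,
                               list(list(at = loop1, bases = new_loop)),
                               target, spec = fx$motif)
  expect_equal(substr(as.character(ed$sequence), loop1[1], loop1[2]), new_loop)
  expect_true(ed$motif_preserved)

  # wrong-length replacement and paired-interval edits are errors
  expect_error(restore_loop_sequences(
    fx$sequence, list(list(at = loop1, bases = "A")), target),
    "length")
  paired <- fx$coords$outer_stem$five
  expect_error(restore_loop_sequences(
    fx$sequence, list(list(at = paired, bases = strrep("A", paired[2] - paired[1] + 1))),
    target), "overlaps a paired position")
})

test_that("junction variants replace exactly the junction interval", {
  v <- junction_variants("ACGTACGTACGT", c(5, 8), c("AAAA", "TTTT", "ATAT"))
  expect_length(v, 3)
  expect_equal(as.character(v$AAAA), "ACGTAAAAACGT")
  expect_equal(as.character(v$TTTT), "ACGTTTTTACGT")
  expect_equal(as.character(v$ATAT), "ACGTATATACGT")
  # composition equal to the current content is an identity
  same <- junction_variants("ACGTACGTACGT", c(5, 8), "ACGT")
  expect_equal(as.character(same$ACGT), "ACGTACGTACGT")
  expect_error(junction_variants("ACGTACGT", c(3, 6), "AAA"),
               "does not match junction length")
})

test_that("design space size is 4^pairs", {
  expect_equal(design_space_size("......"), 1)
  expect_equal(design_space_size(as_pair_table(c(6L, 5L, 0L, 0L, 2L, 1L))), 16)
  # 15 stem pairs give the ~1e9 sequence diversity scale
  db <- "((((((((((((((( ... )))))))))))))))"
  pt <- integer(35); for (k in 1:15) { pt[k] <- 36 - k; pt[36 - k] <- k }
  expect_equal(design_space_size(as_pair_table(pt)), 4^15)
  expect_equal(design_space_size(as_pair_table(pt)), 1073741824)
})
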