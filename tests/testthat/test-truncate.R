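test_that("the no-trim row reproduces the parent fold", {
  fx <- make_synthetic_aptamer(synthetic_aptamer_spec(seed = 2))
  land <- truncation_scan(fx$sequence, fx$motif, max_trim5 = 3, max_trim3 = 3)
  f0 <- mfe_fold(fx$sequence)
  row0 <- land[land$trim5 == 0 & land$trim3 == 0, ]
  expect_equal(row0$energy_kcal_mol, f0$energy)
  expect_equal(row0$dotbracket, f0$dotbracket)
  expect_true(row0$motif_preserved)
  # grid coverage: all feasible (t5, t3) combinations present
  expect_equal(nrow(land), 16)
  expect_equal(nrow(unique(land[, c("trim5", "trim3")])), nrow(land))
})

test_that("a parent without the motif is rejected up front", {
  expect_error(
    truncation_scan("GGGGAAAACCCC", motif_spec(min_branches = 3)),
    "parent lacks motif")
})

test_that("selection prefers maximal trim, then energy, then smaller 5' trim", {
  land <- data.frame(
    trim5 = c(0L, 2L, 3L, 1L, 4L),
    trim3 = c(0L, 3L, 2L, 4L, 1L),
    length = 20L - c(0L, 5L, 5L, 5L, 5L),
    energy_kcal_mol = c(-9, -4.5, -5, -5, -5),
    motif_preserved = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    dotbracket = "....................", stringsAsFactors = FALSE)

  sel <- select_minimal(land)
  # rows with total trim 5 win; among them energy -5 beats -4.5; among the
  # two at -5, trim5 = 1 beats trim5 = 3; the preserved = FALSE row never wins
  expect_equal(c(sel$trim5, sel$trim3), c(1L, 4L))

  expect_equal(select_minimal(land, "min_energy")$trim5, 0L)
  expect_error(select_minimal(land[!land$motif_preserved, , drop = FALSE]),
               "no motif-preserving")

  single <- land[2, , drop = FALSE]
  expect_equal(select_minimal(single)$trim5, 2L)
})

test_that("selection equals a brute-force re-scan of the landscape", {
  fx <- make_synthetic_aptamer(synthetic_aptamer_spec(seed = 5))
  land <- truncation_scan(fx$sequence, fx$motif,
                          max_trim5 = fx$coords$pad5 + 2,
                          max_trim3 = fx$coords$pad3 + 2)
  sel <- attr(land, "selected")
  keep <- land[land$motif_preserved, ]
  best_total <- max(keep$trim5 + keep$trim3)
  cand <- keep[keep$trim5 + keep$trim3 == best_total, ]
  cand <- cand[cand$energy_kcal_mol == min(cand$energy_kcal_mol), ]
  cand <- cand[which.min(cand$trim5), ]
  expect_equal(c(sel$trim5, sel$trim3), c(cand$trim5, cand$trim3))
})

test_that("the selected candidate independently refolds to the motif", {
  fx <- make_synthetic_aptamer(synthetic_aptamer_spec(seed = 8))
  land <- truncation_scan(fx$sequence, fx$motif,
                          max_trim5 = fx$coords$pad5 + 2,
                          max_trim3 = fx$coords$pad3 + 2)
  sel <- attr(land, "selected")
  n <- attr(fx$sequence, "n")
  sub <- substr(as.character(fx$sequence), sel$trim5 + 1, n - sel$trim3)
  refold <- mfe_fold(sub)
  expect_true(c(matches_motif(refold$structure, fx$motif)))
  expect_equal(refold$dotbracket, sel$dotbracket)
})

test_that("landscape TSV export round-trips", {
  fx <- make_synthetic_aptamer(synthetic_aptamer_spec(seed = 2))
  land <- truncation_scan(fx$sequence, fx$motif, max_trim5 = 2, max_trim3 = 2)
  tf <- tempfile(fileext = ".tsv")
  write_landscape_tsv(land, tf)
  back <- read.delim(tf)
  expect_equal(nrow(back), nrow(land))
  expect_equal(back$energy_kcal_mol, land$energy_kcal_mol)
})
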