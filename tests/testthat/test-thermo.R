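# reassemble the bundled tables into a single .par file usable by the
# reference folding engine (cross-validation oracle)
vienna_par_file <- local({
  path <- NULL
  function() {
    if (is.null(path)) {
      path <<- tempfile(fileext = ".par")
      writeLines(bundled_par_lines(), path)
    }
    path
  }
})

rnafold <- function(seq) {
  out <- system2("RNAfold", c("--noconv", "--noPS", "-P", vienna_par_file()),
                 input = as.character(seq), stdout = TRUE, stderr = FALSE)
  list(db = sub(" .*", "", out[2]),
       energy = as.numeric(sub(".*\\( *(-?[0-9.]+)\\)$", "\\1", out[2])))
}

test_that("sequences without allowed pairs fold to the open chain at 0.0", {
  f <- mfe_fold("AAAAAAAAAAAAAAAAAAAA")
  expect_equal(f$energy, 0)
  expect_equal(sum(f$structure != 0), 0)
  expect_error(mfe_fold("ACGU"), "illegal character")
})

test_that("folding is deterministic and self-consistent", {
  set.seed(11)
  for (rep in 1:10) {
    s <- rand_dna(sample(20:60, 1))
    f1 <- mfe_fold(s); f2 <- mfe_fold(s)
    expect_identical(f1$dotbracket, f2$dotbracket)
    expect_identical(f1$energy_int, f2$energy_int)
    # MFE <= 0 since the open chain is always available
    expect_lte(f1$energy, 0)
    # evaluation of the MFE structure reproduces the DP energy exactly
    expect_identical(as.integer(f1$energy_int),
                     as.integer(round(100 * eval_structure_energy(s, f1$structure))))
  }
})

test_that("hand-summed loop terms from the parameter file match the model", {
  p <- dna_params()
  lines <- bundled_par_lines()

  hp_len <- as.integer(sub("INF", "10000000",
                           section_tokens(lines, "hairpin")))
  mmh <- as.integer(section_tokens(lines, "mismatch_hairpin"))
  stack <- matrix(as.integer(section_tokens(lines, "stack")), 7, byrow = TRUE)

  # 4-nt hairpin GAAAAC closed by G-C: length-4 entry + GC,A,A mismatch
  mm_gc_a_a <- mmh[(2 - 1) * 25 + (1) * 5 + 2]  # pair GC, row A, col A
  d <- decompose(parse_dotbracket("(....)"))
  hp_rec <- Filter(function(r) r$type == "hairpin", d)[[1]]
  expect_equal(loop_energy(hp_rec, dna_sequence("GAAAAC"), p),
               hp_len[5] + mm_gc_a_a)

  # 12-nt GC hairpin: three GC/CG stacks + the hairpin term above
  e <- eval_structure_energy("GGGGAAAACCCC", parse_dotbracket("((((....))))"), p)
  expect_equal(round(100 * e), 3 * stack[2, 1] + hp_len[5] + mm_gc_a_a)
})

test_that("multiloop term is a + b*k + c*u and vanishes with zero coefficients", {
  p <- dna_params()
  db <- "((..((...))..((...))..))"
  sq <- "GCAAGGAAACCAAGGAAACCAAGC"
  d <- decompose(parse_dotbracket(db))
  ml <- Filter(function(r) r$type == "multiloop", d)[[1]]

  # with a = b = c = 0 and all dangle/mismatch/terminal terms zeroed the
  # multiloop face contributes nothing
  p0 <- p
  p0$ml[] <- 0L
  p0$mm_multi[] <- 0L
  p0$terminal_au <- 0L
  expect_equal(loop_energy(ml, dna_sequence(sq), p0), 0L)

  # with the real tables the a + b*k + c*u part is recovered after
  # subtracting the per-helix mismatch terms
  e_full <- loop_energy(ml, dna_sequence(sq), p)
  pml <- p
  pml$mm_multi[] <- 0L
  e_plain <- loop_energy(ml, dna_sequence(sq), pml)
  expect_equal(e_plain,
               p$ml[["closing"]] + 3L * p$ml[["intern"]] + ml$u * p$ml[["base"]])
  expect_true(e_full != e_plain)  # mismatch terms do contribute

  # exterior face of an all-unpaired structure has zero energy
  ext <- decompose(as_pair_table(integer(6)))[[1]]
  expect_equal(loop_energy(ext, dna_sequence("ACGTAC"), p), 0L)
  expect_equal(eval_structure_energy("ACGTAC", integer(6), p), 0)
})

test_that("evaluation rejects structures the model cannot score", {
  expect_error(eval_structure_energy("AAAAAC", c(6L, 0L, 0L, 0L, 0L, 1L)),
               "disallowed base pair between positions 1 and 6")
  expect_error(
    eval_structure_energy("AAAATTTT", c(0L, 0L, 0L, 5L, 4L, 0L, 0L, 0L)),
    "hairpin loop shorter than 3")
})

test_that("DP minimum equals the exhaustive-enumeration minimum on short sequences", {
  set.seed(404)
  for (rep in 1:30) {
    n <- sample(8:14, 1)
    s <- rand_dna(n, prob = c(.2, .3, .3, .2))
    oracle <- exhaustive_min_energy(s)
    f <- mfe_fold(s)
    expect_equal(f$energy, oracle$energy,
                 info = sprintf("sequence %s", s))
  }
})

test_that("energies agree exactly with the reference folding engine", {
  expect_true(nzchar(Sys.which("RNAfold")))
  g <- gol1_seq()
  ours <- mfe_fold(g)
  ref <- rnafold(g)
  expect_equal(ours$energy, ref$energy, tolerance = 1e-9)
  expect_identical(ours$dotbracket, ref$db)

  set.seed(505)
  for (rep in 1:20) {
    s <- rand_dna(sample(25:70, 1), prob = c(.2, .3, .3, .2))
    expect_equal(mfe_fold(s)$energy, rnafold(s)$energy, tolerance = 1e-9,
                 info = s)
  }
})

test_that("Vienna text and CT writers emit the standard layouts", {
  f <- mfe_fold(dna_sequence("GGGGAAAACCCC", id = "hp"))
  tf <- tempfile()
  write_vienna(f, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], ">hp")
  expect_equal(lines[2], "GGGGAAAACCCC")
  expect_match(lines[3], "^\\(\\(\\(\\(\\.\\.\\.\\.\\)\\)\\)\\) \\(-3\\.00\\)$")

  tc <- tempfile()
  write_ct(f, tc)
  ct <- read.table(tc, skip = 1)
  expect_equal(nrow(ct), 12)
  expect_equal(ct$V5[1], 12)   # position 1 pairs 12
  expect_equal(ct$V5[5], 0)    # loop position unpaired
})
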