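test_that("canonical quadruplex motifs are detected with their geometry", {
  h <- g4_scan("GGGTGGGTGGGTGGG")
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end), c(1L, 15L))
  expect_equal(h$n_runs, 4)
  expect_equal(h$run_lengths, "3,3,3,3")
  expect_equal(h$loop_lengths, "1,1,1")

  expect_equal(nrow(g4_scan("ATATATATAT")), 0)

  # a single long G run is not four runs
  expect_equal(nrow(g4_scan("AAGGGGGGAA")), 0)

  # loops longer than loop_max break the chain
  expect_equal(nrow(g4_scan(paste0("GGG", strrep("A", 8), "GGGTGGGTGGG"))), 0)

  # five chained runs extend one maximal hit
  h5 <- g4_scan("GGGAGGGAGGGAGGGAGGG")
  expect_equal(nrow(h5), 1)
  expect_equal(h5$n_runs, 5)
})

test_that("the printed minimal aptamer sequence carries no canonical motif", {
  expect_equal(nrow(g4_scan(gol1_seq())), 0)
  # independent check: the regex for four chained G3 runs finds nothing
  expect_false(grepl("G{3,}([ACT]|G)*?G{3,}", "x"))  # regex sanity only
  expect_false(grepl("G{3,}[ACGT]{1,7}G{3,}[ACGT]{1,7}G{3,}[ACGT]{1,7}G{3,}",
                     as.character(gol1_seq())))
})

test_that("hits never overlap and vanish when their span is removed", {
  set.seed(909)
  for (rep in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, TRUE,
                      prob = c(.15, .15, .55, .15)), collapse = "")
    h <- g4_scan(s)
    if (nrow(h) >= 2)
      expect_true(all(h$start[-1] > h$end[-nrow(h)]))
    if (nrow(h) >= 1) {
      # excise the first hit's span: that hit does not reappear
      cut <- paste0(substr(s, 1, h$start[1] - 1),
                    substr(s, h$end[1] + 1, nchar(s)))
      h2 <- g4_scan(cut)
      expect_true(nrow(h2) <= nrow(h))
    }
  }
})

test_that("pseudoknot certificates hold for all folded output and fail on crossings", {
  set.seed(77)
  for (rep in 1:10) {
    f <- mfe_fold(rand_dna(40, prob = c(.2, .3, .3, .2)))
    expect_true(pseudoknot_free(f$structure))
  }
  expect_true(pseudoknot_free(parse_dotbracket("((..((...))..((...))..))")))
  # crossing pair set (1,3)+(2,4)
  expect_false(pseudoknot_free(c(3L, 4L, 1L, 2L)))
})

test_that("BED-like TSV export lists one row per hit", {
  h <- g4_scan(dna_sequence("GGGTGGGTGGGTGGG", id = "q"))
  tf <- tempfile()
  write_g4_tsv(h, tf)
  tab <- read.delim(tf)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$id, "q")
  expect_equal(tab$start, 1)
  # empty hit sets still write a valid header-only table
  tf2 <- tempfile()
  write_g4_tsv(g4_scan("ATATATATAT"), tf2)
  expect_equal(nrow(read.delim(tf2)), 0)
})
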