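test_that("dot-bracket parsing matches hand-derived pair sets", {
  pt <- parse_dotbracket("((((...))))")
  expect_equal(sum(pt != 0) / 2, 4)
  expect_equal(unname(pt[1:4]), c(11L, 10L, 9L, 8L))
  expect_equal(unname(pt[8:11]), c(4L, 3L, 2L, 1L))

  expect_equal(sum(parse_dotbracket(".....") != 0), 0)
})

test_that("parse errors name the offending position", {
  expect_error(parse_dotbracket("(()"), "unbalanced at position 1")
  expect_error(parse_dotbracket("())"), "unbalanced at position 3")
  expect_error(parse_dotbracket("(.x.)"), "illegal character 'x' at position 3")
  expect_error(parse_dotbracket("(..)"), "hairpin loop shorter than 3")
})

test_that("parse/emit round-trips over random structures", {
  set.seed(101)
  for (rep in 1:50) {
    pt <- rand_structure(sample(10:60, 1))
    db <- to_dotbracket(pt)
    expect_equal(as.integer(parse_dotbracket(db)), as.integer(pt))
  }
  expect_equal(to_dotbracket(as_pair_table(integer(5))), ".....")
  # programmatic tables below the hairpin minimum still render
  expect_equal(to_dotbracket(as_pair_table(c(6L, 5L, 0L, 0L, 2L, 1L))),
               "((..))")
})

test_that("loop decomposition identifies faces and multiloop geometry", {
  d1 <- decompose(parse_dotbracket("((((...))))"))
  types1 <- vapply(d1, function(r) r$type, "")
  expect_equal(sum(types1 == "stack"), 3)
  expect_equal(sum(types1 == "hairpin"), 1)
  expect_false("multiloop" %in% types1)

  d2 <- decompose(parse_dotbracket("((..((...))..((...))..))"))
  ml <- Filter(function(r) r$type == "multiloop", d2)
  expect_length(ml, 1)
  expect_equal(ml[[1]]$k, 3)   # closing helix + 2 branches
  expect_equal(ml[[1]]$u, 6)
})

test_that("decomposition faces cover n + 2*pairs positions", {
  set.seed(202)
  for (rep in 1:25) {
    pt <- rand_structure(sample(15:70, 1))
    d <- decompose(pt)
    total <- sum(vapply(d, aptamin:::face_size, integer(1)))
    expect_equal(total, length(pt) + sum(pt != 0))
    # every position is interior to exactly one face
    interior <- sort(unlist(lapply(d, function(r) {
      closing <- if (is.null(r$closing)) integer(0) else r$closing
      c(r$unpaired, unlist(lapply(r$branches, function(b) b)), closing)
    })))
    expect_equal(sort(unique(interior)), seq_along(pt))
  }
})

test_that("base-pair distance equals the set symmetric difference and is a metric", {
  a <- parse_dotbracket("((...))")
  expect_equal(base_pair_distance(a, a), 0)
  expect_equal(base_pair_distance(as_pair_table(c(6L, 5L, 0L, 0L, 2L, 1L)),
                                  as_pair_table(integer(6))), 2)
  expect_error(base_pair_distance(a, parse_dotbracket("........")),
               "different length")

  set.seed(303)
  brute <- function(x, y) {
    px <- apply(pairs_of(x), 1, paste, collapse = ",")
    py <- apply(pairs_of(y), 1, paste, collapse = ",")
    length(setdiff(px, py)) + length(setdiff(py, px))
  }
  pairs_of <- function(pt) {
    i <- which(pt > seq_along(pt)); cbind(i, as.integer(pt)[i])
  }
  for (rep in 1:20) {
    n <- sample(12:40, 1)
    x <- rand_structure(n); y <- rand_structure(n); z <- rand_structure(n)
    expect_equal(base_pair_distance(x, y), brute(x, y))
    expect_equal(base_pair_distance(x, y), base_pair_distance(y, x))
    expect_lte(base_pair_distance(x, z),
               base_pair_distance(x, y) + base_pair_distance(y, z))
  }
})

test_that("motif matching finds qualifying multiloops", {
  spec3 <- motif_spec(min_branches = 3)
  expect_false(c(matches_motif(parse_dotbracket("((((...))))"), spec3)))
  m <- matches_motif(parse_dotbracket("((..((...))..((...))..))"), spec3)
  expect_true(c(m))
  expect_equal(attr(m, "match")$closing, c(2L, 23L))

  # synthetic fixture: the match must sit at the generator's junction; the
  # multiloop face is closed by the innermost pair of the outer stem
  fx <- make_synthetic_aptamer(synthetic_aptamer_spec(seed = 11))
  m2 <- matches_motif(fx$structure, fx$motif)
  expect_true(c(m2))
  expect_equal(attr(m2, "match")$closing,
               c(fx$coords$outer_stem$five[2], fx$coords$outer_stem$three[1]))

  # fragment matching pins the exact substructure
  frag_spec <- motif_spec(min_branches = 3, fragment = fx$motif$fragment)
  expect_true(c(matches_motif(fx$structure, frag_spec)))
  expect_false(c(matches_motif(parse_dotbracket(
    paste(rep(".", length(fx$structure)), collapse = "")), frag_spec)))

  # designated segments must be unpaired
  seg_spec <- motif_spec(min_branches = 3,
                         segments = list(fx$coords$branch1$loop))
  expect_true(c(matches_motif(fx$structure, seg_spec)))
  paired_iv <- fx$coords$outer_stem$five
  expect_false(c(matches_motif(fx$structure,
                               motif_spec(3, segments = list(paired_iv)))))
})
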