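test_that("item similarity follows the one-level band", {
  expect_true(items_similar(2L, 3L))
  expect_true(items_similar(-3L, -2L))
  expect_false(items_similar(0L, -2L))
  expect_true(items_negatively_similar(3L, -3L))
  expect_true(items_negatively_similar(-2L, 1L))
  expect_false(items_negatively_similar(0L, -3L))
  expect_error(items_similar(4L, 0L), "alphabet")

  grid <- expand.grid(a = -3:3, b = -3:3)
  # symmetry, reflexivity, and the mirror identity neg(a,b) = sim(a,-b)
  expect_identical(items_similar(grid$a, grid$b), items_similar(grid$b, grid$a))
  expect_true(all(items_similar(-3:3, -3:3)))
  expect_identical(items_negatively_similar(grid$a, grid$b),
                   items_negatively_similar(grid$b, grid$a))
  expect_identical(items_negatively_similar(grid$a, grid$b),
                   items_similar(grid$a, -grid$b))
})

test_that("positive pair match is exactly membership; strict implies weak", {
  for (lo in pair_item_alphabet()) {
    for (e in item_alphabet()) {
      expect_identical(item_matches_pair(e, lo, "positive"), e %in% c(lo, lo + 1L))
      if (item_matches_pair(e, lo, "negative", "strict")) {
        expect_true(item_matches_pair(e, lo, "negative", "weak"))
      }
    }
  }
  expect_true(item_matches_pair(1L, 1L, "positive"))
  expect_true(item_matches_pair(1L, 0L, "negative", "weak"))
  expect_false(item_matches_pair(1L, 0L, "negative", "strict"))
})

test_that("the worked matching example reproduces exactly", {
  expect_identical(match_offsets(example_pairs, example_s1, "positive"), 1L)
  expect_identical(match_offsets(example_pairs, example_s3, "negative", "weak"), 0L)
  expect_length(match_offsets(example_pairs, example_s2, "positive"), 0L)
  expect_length(match_offsets(example_pairs, example_s2, "negative", "weak"), 0L)
  # under the strict printed definition the s3 match disappears
  expect_length(match_offsets(example_pairs, example_s3, "negative", "strict"), 0L)
})

test_that("a pattern self-matches its own lo items at offset 0", {
  set.seed(3)
  for (i in 1:25) {
    pairs <- sample(pair_item_alphabet(), sample(1:6, 1), replace = TRUE)
    expect_true(0L %in% match_offsets(pairs, pairs, "positive"))
  }
  # a full-width pattern can match a whole sequence (inclusive offset bound)
  expect_identical(match_offsets(c(0L, 1L), c(0L, 2L), "positive"), 0L)
})

test_that("insignificant fraction counts -1::0 and 0::1 positions", {
  expect_equal(insignificant_fraction(c(-1L, 0L)), 1)
  expect_equal(insignificant_fraction(example_pairs), 0.25)
  expect_equal(insignificant_fraction(2L), 0)
})

test_that("canonicalization is idempotent and behaviour-preserving", {
  expect_identical(canonicalize(2L), 2L)
  set.seed(5)
  for (i in 1:20) {
    pairs <- sample(pair_item_alphabet(), sample(1:5, 1), replace = TRUE)
    can <- canonicalize(pairs)
    expect_identical(canonicalize(can), can)
    # identical match behaviour over the full alphabet, every polarity
    for (e in item_alphabet()) {
      for (j in seq_along(pairs)) {
        expect_identical(item_matches_pair(e, pairs[j], "positive"),
                         item_matches_pair(e, can[j], "positive"))
        expect_identical(item_matches_pair(e, pairs[j], "negative", "weak"),
                         item_matches_pair(e, can[j], "negative", "weak"))
      }
    }
  }
})

test_that("the alphabets have seven items and six pair-items", {
  expect_length(item_alphabet(), 7L)
  expect_length(pair_item_alphabet(), 6L)
  expect_identical(pair_item_labels(pair_item_alphabet())[c(1, 6)],
                   c("-3::-2", "2::3"))
  expect_error(pair_item_labels(3L), "pair-item")
})

test_that("pattern objects enforce side disjointness and report support", {
  p <- subseq_pattern(c(1L, 0L), p = data.frame(gene = "a", offset = 0L),
                      n = data.frame(gene = "b", offset = c(1L)))
  expect_equal(p$support, 2L)
  expect_error(
    subseq_pattern(1L, p = data.frame(gene = "a", offset = 0L),
                   n = data.frame(gene = "a", offset = 1L)),
    "both sides")
})
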