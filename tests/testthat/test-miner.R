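test_that("identical profiles yield an all-positive closed pattern", {
  tmpl <- c(0L, 3L, 2L, -2L, 0L)
  d <- make_dmat(matrix(rep(tmpl, each = 6), nrow = 6))
  cfg <- mining_config(sup = 5L, min_len = 4L, max0_fraction = 0.6)
  ps <- mine_closed_patterns(d, cfg)
  expect_gt(length(ps), 0L)
  expect_true(any(vapply(ps$patterns, function(p)
    length(unique(p$p$gene)) == 6L && nrow(p$n) == 0L, logical(1L))))
  # agrees with exhaustive enumeration
  bf <- brute_force_mine(d, cfg)
  expect_identical(pattern_signatures(ps), pattern_signatures(bf))
})

test_that("sign-flipped profiles land on the negative side", {
  tmpl <- c(0L, 3L, 2L, -2L, 0L)
  d <- make_dmat(rbind(matrix(rep(tmpl, each = 3), nrow = 3),
                       matrix(rep(-tmpl, each = 2), nrow = 2)))
  ps <- mine_closed_patterns(d, mining_config(sup = 5L, min_len = 4L))
  expect_true(any(vapply(ps$patterns, function(p)
    length(unique(p$p$gene)) == 3L && length(unique(p$n$gene)) == 2L,
    logical(1L))))
})

test_that("support threshold above the gene count empties the result", {
  d <- make_dmat(matrix(rep(c(0L, 3L, 2L, -2L, 0L), each = 3), nrow = 3))
  expect_length(mine_closed_patterns(d, mining_config(sup = 4L, min_len = 2L)), 0L)
  expect_error(mine_closed_patterns(d, mining_config(sup = 1L, min_len = 9L)),
               "min_len")
})

test_that("patterns absorbed by an extension are not closed", {
  # trailing all-zero column: every gene matching {2::3, 1::2} at offset 0
  # also matches it extended right by 0::1, so the short pattern is open
  d <- make_dmat(matrix(rep(c(2L, 1L, 0L), each = 5), nrow = 5))
  expect_false(is_closed(c(2L, 1L), d))
  expect_true(is_closed(c(2L, 1L, 0L), d))      # full width, nothing to add
  expect_true(is_closed(c(2L, 2L), make_dmat(matrix(-3L, 2, 4))))  # empty match set
  # the miner agrees: no emitted pattern fails the independent closedness check
  ps <- mine_closed_patterns(d, mining_config(sup = 2L, min_len = 2L))
  for (p in ps$patterns) expect_true(is_closed(p$pairs, d))
})

test_that("emitted match sets replay exactly through match_offsets", {
  set.seed(42)
  d <- random_item_matrix(6, 8)
  ps <- mine_closed_patterns(d, mining_config(sup = 3L, min_len = 2L))
  expect_gt(length(ps), 0L)
  for (p in ps$patterns) {
    ms <- compute_match_sets(p$pairs, d)
    expect_equal(dplyr::arrange(p$p, gene, offset),
                 dplyr::arrange(ms$p, gene, offset))
    expect_equal(dplyr::arrange(p$n, gene, offset),
                 dplyr::arrange(ms$n, gene, offset))
    # disjoint sides, support over distinct genes
    expect_length(intersect(unique(p$p$gene), unique(p$n$gene)), 0L)
    expect_equal(p$support, length(unique(p$p$gene)) + length(unique(p$n$gene)))
  }
})

test_that("extension never grows a match set (anti-monotonicity)", {
  set.seed(9)
  d <- random_item_matrix(5, 7)
  ps <- mine_closed_patterns(d, mining_config(sup = 2L, min_len = 2L))
  key <- function(ms) paste(ms$gene, ms$offset)
  for (p in head(ps$patterns, 10L)) {
    base <- compute_match_sets(p$pairs, d)
    for (lo in pair_item_alphabet()) {
      ext <- compute_match_sets(c(p$pairs, lo), d)
      expect_true(all(key(ext$p) %in% key(base$p)))
      expect_true(all(unique(ext$n$gene) %in%
                        unique(c(base$n$gene, base$p$gene))))
    }
  }
})

test_that("miner and brute-force oracle agree on random matrices", {
  set.seed(101)
  for (i in 1:6) {
    d <- random_item_matrix(sample(4:6, 1), sample(5:7, 1))
    for (mode in c("weak", "strict")) {
      cfg <- mining_config(sup = 2L, min_len = 2L, max0_fraction = 0.6,
                           neg_match_mode = mode)
      expect_identical(pattern_signatures(mine_closed_patterns(d, cfg)),
                       pattern_signatures(brute_force_mine(d, cfg)),
                       info = sprintf("matrix %d, mode %s", i, mode))
    }
  }
})

test_that("the brute-force guard refuses oversized enumerations", {
  d <- random_item_matrix(8, 10)
  expect_error(brute_force_mine(d, mining_config(sup = 2L, min_len = 2L),
                                max_candidates = 10),
               "candidate")
})
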