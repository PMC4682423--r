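test_that("imputation averages interior neighbours and copies at boundaries", {
  vals <- rbind(c(2, NA, 4), c(NA, 5, 6), c(7, 8, NA))
  x <- make_emat(vals)
  y <- impute_missing(x)
  expect_equal(unname(y$values[1, ]), c(2, 3, 4))
  expect_equal(unname(y$values[2, ]), c(5, 5, 6))
  expect_equal(unname(y$values[3, ]), c(7, 8, 8))
  expect_false(any(y$missing_mask))
})

test_that("imputation drops genes over the missing budget, keeps observed values", {
  vals <- rbind(a = c(1, NA, NA, 4), b = c(1, 2, NA, 4))
  x <- make_emat(vals)
  expect_warning(y <- impute_missing(x, max_missing_per_gene = 1L), "a")
  expect_identical(y$gene_ids, "b")
  # observed entries are untouched
  expect_equal(unname(y$values[1, c(1, 2, 4)]), c(1, 2, 4))
})

test_that("cycle splitting follows the floor(h/k)+1 window rule", {
  x2 <- make_emat(matrix(seq_len(2 * 18), nrow = 2), n_cycles = 2L)
  parts <- split_cell_cycles(x2)
  expect_length(parts, 2L)
  expect_equal(vapply(parts, function(p) ncol(p$values), 0L),
               c(10L, 10L), ignore_attr = TRUE)
  # windows cover the original columns and overlap by 2(h/2+1) - h
  got <- sort(unique(unlist(lapply(parts, function(p) p$values[1, ]))))
  expect_equal(got, as.numeric(seq(1, 35, by = 2)))
  overlap <- intersect(parts[[1]]$values[1, ], parts[[2]]$values[1, ])
  expect_length(overlap, 2 * (18 %/% 2 + 1) - 18)

  x3 <- make_emat(matrix(seq_len(24), nrow = 1), n_cycles = 3L)
  parts3 <- split_cell_cycles(x3)
  expect_equal(vapply(parts3, function(p) ncol(p$values), 0L),
               c(9L, 9L, 9L), ignore_attr = TRUE)
  expect_equal(parts3[[2]]$values[1, 1], 9)   # middle window anchored at floor(h/3)
  expect_setequal(unlist(lapply(parts3, function(p) p$values[1, ])), 1:24)

  x1 <- make_emat(matrix(seq_len(14), nrow = 1), n_cycles = 1L)
  expect_identical(split_cell_cycles(x1)[[1]]$values, x1$values)

  x4 <- make_emat(matrix(1:8, nrow = 1), n_cycles = 4L)
  expect_error(split_cell_cycles(x4), "n_cycles")
})

test_that("delta is the nearest-rank percentile of absolute values", {
  # independent oracle: exhaustive sort + 1-based rank
  nearest_rank <- function(v, p) sort(abs(v))[ceiling(p * length(v))]
  expect_equal(compute_delta(c(-1, 2, -3, 4, -5, 6, -7, 8, -9, 10), 0.8), 8)
  set.seed(7)
  for (i in 1:20) {
    v <- rnorm(sample(3:15, 1))
    p <- runif(1, 0.1, 1)
    expect_equal(compute_delta(v, p), nearest_rank(v, p))
  }
  expect_equal(compute_delta(-3.2), 3.2)
  expect_true(is.na(compute_delta(c(0, 0, 0))))
  # zero at the rank falls back to the smallest positive magnitude
  expect_equal(compute_delta(c(0, 0, 0, 0, 5), 0.5), 5)
  expect_error(compute_delta(numeric(0)), "empty")
})

test_that("discretization reproduces the half-open band rule", {
  expect_identical(discretize_value(2.49, 1), 2L)
  expect_identical(discretize_value(2.51, 1), 3L)
  expect_identical(discretize_value(0, 0.37), 0L)
  expect_identical(discretize_value(-100, 1), -3L)
  # band edges: [k - 0.5, k + 0.5) scaled by delta
  expect_identical(discretize_value(c(0.5, 1.5, -0.5, -1.5), 1), c(1L, 2L, 0L, -1L))
})

test_that("discretization is monotone and antisymmetric off band boundaries", {
  grid <- seq(-4, 4, by = 0.01)
  for (delta in c(0.5, 1, 2.3)) {
    items <- discretize_value(grid, delta)
    expect_true(all(diff(items) >= 0L))
    off <- grid[abs(grid / delta * 2 - round(grid / delta * 2)) > 1e-6]
    expect_identical(discretize_value(-off, delta), -discretize_value(off, delta))
    expect_true(all(items %in% -3:3))
  }
})

test_that("matrix discretization applies per-gene scales and drops zero genes", {
  vals <- rbind(sig = c(0, 3, 2, -2, 0) * 2, zero = c(0, 0, 0, 0, 0))
  x <- make_emat(vals)
  expect_warning(d <- discretize_matrix(x, percentile = 0.8), "zero")
  expect_identical(rownames(d$items), "sig")
  # delta = 80th-percentile of |(0,6,4,-4,0)| = 4 -> items round(v/4)
  expect_equal(unname(d$delta), 4)
  expect_identical(unname(d$items[1, ]), c(0L, 2L, 1L, -1L, 0L))

  set.seed(11)
  r <- make_emat(matrix(rnorm(60, sd = 2), nrow = 5))
  dr <- discretize_matrix(r)
  expect_true(all(dr$items %in% -3:3))
  # discretized TSV round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_discretized_tsv(dr, path)
  back <- read_discretized_tsv(path)
  expect_identical(back$items, dr$items)
  expect_equal(unname(back$delta), unname(dr$delta))
})
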