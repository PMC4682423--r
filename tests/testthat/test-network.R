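toy_pattern_set <- function(p, n = NULL, source = "toy") {
  empty <- data.frame(gene = character(), offset = integer())
  new_pattern_set(list(subseq_pattern(c(2L, 1L), p = p,
                                      n = if (is.null(n)) empty else n)),
                  source)
}

test_that("co-membership at matching offsets gives a complete labelled graph", {
  ps <- toy_pattern_set(data.frame(gene = c("a", "b", "c"), offset = 0L))
  g <- build_gin(ps, i_t = 0L)
  expect_equal(nrow(g), 3L)
  expect_true(all(g$label == "positive"))
  expect_setequal(gin_nodes(g), c("a", "b", "c"))
})

test_that("the time-lag rule bounds the offset delay", {
  ps <- toy_pattern_set(data.frame(gene = c("a", "b"), offset = c(0L, 2L)))
  expect_equal(nrow(build_gin(ps, i_t = 1L)), 0L)
  expect_equal(nrow(build_gin(ps, i_t = 2L)), 1L)
  expect_equal(lag_allowance(14L), 1L)
  expect_equal(lag_allowance(12L), 0L)
  expect_equal(lag_allowance(8L, min_timepoints = 8L), 1L)
})

test_that("cross-side co-membership is a negative interaction", {
  ps <- toy_pattern_set(p = data.frame(gene = "a", offset = 1L),
                        n = data.frame(gene = "b", offset = 1L))
  g <- build_gin(ps, i_t = 0L)
  expect_equal(nrow(g), 1L)
  expect_identical(g$label, "negative")
})

test_that("integration counts per-polarity occurrences independently", {
  mk <- function(label) new_gin(data.frame(gene_a = "a", gene_b = "b", label = label))
  gins <- c(replicate(11, mk("positive"), simplify = FALSE),
            replicate(2, mk("negative"), simplify = FALSE))
  ig <- integrate_gins(gins)
  expect_equal(ig$pos_weight, 11L)
  expect_equal(ig$neg_weight, 2L)
  # a 'both' edge counts toward both polarities
  ig2 <- integrate_gins(list(mk("both")))
  expect_equal(c(ig2$pos_weight, ig2$neg_weight), c(1L, 1L))
  # permutation invariance
  ig3 <- integrate_gins(rev(gins))
  expect_equal(as.data.frame(ig), as.data.frame(ig3), ignore_attr = TRUE)
  # single-input integration is the identity with unit weights
  ig4 <- integrate_gins(list(mk("positive")))
  expect_equal(nrow(ig4), 1L)
  expect_equal(ig4$pos_weight + ig4$neg_weight, 1L)
})

test_that("reliability filtering thresholds each polarity and is monotone", {
  ig <- new_integrative_gin(data.frame(
    gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
    pos_weight = c(11L, 10L, 12L), neg_weight = c(2L, 10L, 11L)))
  r11 <- filter_reliable(ig, 11L)
  expect_setequal(paste(r11$gene_a, r11$gene_b), c("a b", "e f"))
  expect_identical(r11$label[r11$gene_a == "a"], "positive")
  expect_identical(r11$label[r11$gene_a == "e"], "both")
  expect_equal(nrow(filter_reliable(ig, 1L)), nrow(ig))
  # nested edge sets as occ rises
  prev <- NULL
  for (occ in 1:12) {
    cur <- paste(filter_reliable(ig, occ)$gene_a, filter_reliable(ig, occ)$gene_b)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("PCC baseline connects by absolute correlation with signed labels", {
  t <- seq(0, 2 * pi, length.out = 10)
  vals <- rbind(a = sin(t), b = sin(t), c = -sin(t), flat = rep(1, 10))
  x <- make_emat(vals)
  expect_warning(g <- pcc_baseline(x, threshold = 0.8), "constant")
  key <- paste(g$gene_a, g$gene_b, g$label)
  expect_true("a b positive" %in% key)
  expect_true("a c negative" %in% key)
  expect_false(any(grepl("flat", key)))
  # threshold monotonicity
  g_lo <- pcc_baseline(make_emat(vals[1:3, ]), threshold = 0.5)
  g_hi <- pcc_baseline(make_emat(vals[1:3, ]), threshold = 0.95)
  expect_true(all(paste(g_hi$gene_a, g_hi$gene_b) %in% paste(g_lo$gene_a, g_lo$gene_b)))
  expect_error(pcc_baseline(make_emat(vals[, 1:2])), "3 time points")

  # independent noise rarely crosses a stringent threshold
  set.seed(2)
  noise <- make_emat(matrix(rnorm(20 * 100), nrow = 20))
  g_noise <- pcc_baseline(noise, threshold = 0.999)
  expect_lt(nrow(g_noise), 3L)
})

test_that("degree statistics recover a planted power law", {
  # star graph: hub with degree m, m leaves of degree 1
  m <- 7L
  star <- new_gin(data.frame(gene_a = "hub", gene_b = paste0("leaf", 1:m),
                             label = "positive"))
  h <- degree_stats(star)$histogram
  expect_equal(h$count[h$degree == 1L], m)
  expect_equal(h$count[h$degree == m], 1L)

  # construct a degree histogram with counts proportional to k^-2 and
  # check the closed-form log-log fit recovers the exponent
  ds <- structure(list(histogram = tibble::tibble(
    degree = 1:6, count = round(720 / (1:6)^2)), n_nodes = 0L), class = "degree_stats")
  ds$histogram$p <- ds$histogram$count / sum(ds$histogram$count)
  fit <- coef(lm(log(p) ~ log(degree), data = ds$histogram))[2]
  expect_equal(unname(fit), -2, tolerance = 0.05)
  expect_equal(degree_stats(star)$exponent,
               unname(coef(lm(log(p) ~ log(degree),
                              data = degree_stats(star)$histogram))[2]))

  # complete graph: a single degree, exponent undefined
  cg <- new_gin(data.frame(t(combn(paste0("g", 1:4), 2)),
                           label = "positive") |>
                  setNames(c("gene_a", "gene_b", "label")))
  expect_true(is.na(degree_stats(cg)$exponent))
})

test_that("network containers validate and order endpoints", {
  g <- new_gin(data.frame(gene_a = "b", gene_b = "a", label = "positive"))
  expect_identical(c(g$gene_a, g$gene_b), c("a", "b"))
  expect_error(new_gin(data.frame(gene_a = "a", gene_b = "a", label = "positive")))
  expect_error(new_gin(data.frame(gene_a = "a", gene_b = "b", label = "up")))
})
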