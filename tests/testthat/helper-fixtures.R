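# in-code fixtures shared across test files

# wrap an integer item matrix as a discretized_matrix (delta = 1 per gene)
make_dmat <- function(items, name = "fixture") {
  items <- as.matrix(items)
  storage.mode(items) <- "integer"
  if (is.null(rownames(items))) rownames(items) <- paste0("g", seq_len(nrow(items)))
  if (is.null(colnames(items))) colnames(items) <- paste0("t", seq_len(ncol(items)))
  structure(list(items = items, delta = setNames(rep(1, nrow(items)), rownames(items)),
                 gene_ids = rownames(items), name = name),
            class = "discretized_matrix")
}

# the four-pair worked-example pattern {2::3, 1::2, -3::-2, 0::1}
example_pairs <- c(2L, 1L, -3L, 0L)
example_s1 <- c(0L, 3L, 2L, -2L, 0L)
example_s2 <- c(0L, 0L, 2L, -2L, 0L)
example_s3 <- c(-3L, -2L, 2L, 1L, 0L)

make_emat <- function(values, n_cycles = 1L, name = "fixture") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- paste0("g", seq_len(nrow(values)))
  expression_matrix(values, n_cycles = n_cycles, name = name)
}

# canonical serialization of a pattern set for set-equality comparison
pattern_signatures <- function(ps) {
  sort(vapply(ps$patterns, function(pat) {
    paste(
      paste(pat$pairs, collapse = ","),
      paste(sort(paste(pat$p$gene, pat$p$offset)), collapse = ";"),
      paste(sort(paste(pat$n$gene, pat$n$offset)), collapse = ";"),
      sep = "|")
  }, character(1L)))
}

random_item_matrix <- function(nv, nt) {
  make_dmat(matrix(sample(-3:3, nv * nt, replace = TRUE), nrow = nv))
}
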