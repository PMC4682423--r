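#' Mining configuration
#'
#' @param sup minimum number of distinct genes a pattern must match
#'   (positively plus negatively). Default 5.
#' @param min_len minimum pattern length in pair-items. Usually derived
#'   from a length fraction via [run_config()]: `ceiling(len_fraction * N_T)`.
#' @param max0_fraction maximum fraction of insignificant pair-items
#'   (`-1::0`, `0::1`) in a pattern. Default 0.6.
#' @param neg_match_mode negative-match convention, see
#'   [item_matches_pair()]. Mining defaults to `"strict"` (two-sided
#'   negative similarity): under the one-sided `"weak"` rule near-zero
#'   profiles negatively match most pair-items, and the complete set of
#'   closed patterns grows combinatorially on noisy data.
#' @return A list of class `mining_config`.
#' @export
mining_config <- function(sup = 5L, min_len = 1L, max0_fraction = 0.6,
                          neg_match_mode = c("strict", "weak")) {
  neg_match_mode <- match.arg(neg_match_mode)
  sup <- as.integer(sup); min_len <- as.integer(min_len)
  stopifnot(sup >= 1L, min_len >= 1L,
            max0_fraction >= 0, max0_fraction <= 1)
  structure(list(sup = sup, min_len = min_len, max0_fraction = max0_fraction,
                 neg_match_mode = neg_match_mode),
            class = "mining_config")
}

new_pattern_set <- function(patterns, source) {
  structure(list(patterns = patterns, source = source), class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set '%s'> %d closed pattern(s)\n",
              x$source, length(x$patterns)))
  invisible(x)
}

#' @export
length.pattern_set <- function(x) length(x$patterns)

#' Tidy a pattern set
#'
#' @param x a `pattern_set` from [mine_closed_patterns()].
#' @param ... unused.
#' @return A tibble with one row per (pattern, matched gene, offset):
#'   columns `pattern_id`, `pattern` (the "lo::hi" rendering), `length`,
#'   `side` (`"p"`/`"n"`), `gene`, `offset` (0-based), `support`.
#' @export
tidy.pattern_set <- function(x, ...) {
  if (!length(x$patterns)) {
    return(tibble::tibble(pattern_id = integer(), pattern = character(),
                          length = integer(), side = character(),
                          gene = character(), offset = integer(),
                          support = integer()))
  }
  purrr::imap_dfr(x$patterns, function(pat, i) {
    lab <- paste(pair_item_labels(pat$pairs), collapse = ",")
    dplyr::bind_rows(
      dplyr::mutate(pat$p, side = "p"),
      dplyr::mutate(pat$n, side = "n")
    ) |>
      dplyr::mutate(pattern_id = i, pattern = lab,
                    length = length(pat$pairs), support = pat$support) |>
      dplyr::select("pattern_id", "pattern", "length", "side", "gene",
                    "offset", "support")
  })
}

#' Glance at a pattern set
#'
#' @param x a `pattern_set`.
#' @param ... unused.
#' @return One-row tibble: pattern count, length range, support range.
#' @export
glance.pattern_set <- function(x, ...) {
  lens <- vapply(x$patterns, function(p) length(p$pairs), integer(1L))
  sups <- vapply(x$patterns, `[[`, integer(1L), "support")
  tibble::tibble(
    source = x$source,
    n_patterns = length(x$patterns),
    min_length = if (length(lens)) min(lens) else NA_integer_,
    max_length = if (length(lens)) max(lens) else NA_integer_,
    min_support = if (length(sups)) min(sups) else NA_integer_,
    max_support = if (length(sups)) max(sups) else NA_integer_
  )
}

#' Full match sets of a pattern over a discretized matrix
#'
#' Replays [match_offsets()] for every gene under both polarities and
#' applies the reporting rule: a gene with any positive offset is
#' reported on the `p` side only.
#'
#' @param pairs integer vector of pair-item lower items.
#' @param dmat a `discretized_matrix`.
#' @param neg_match_mode negative-match convention.
#' @return List with tibbles `p` and `n` (`gene`, `offset`).
#' @export
compute_match_sets <- function(pairs, dmat, neg_match_mode = "strict") {
  stopifnot(inherits(dmat, "discretized_matrix"))
  genes <- dmat$gene_ids
  pairs <- check_pairs(pairs)
  weak <- neg_match_mode == "weak"
  pg <- character(0); po <- integer(0)
  ng <- character(0); no <- integer(0)
  for (g in genes) {
    seqg <- dmat$items[g, ]
    op <- fast_match_offsets(pairs, seqg, TRUE, weak)
    if (length(op)) {
      pg <- c(pg, rep(g, length(op))); po <- c(po, as.integer(op))
      next
    }
    on <- fast_match_offsets(pairs, seqg, FALSE, weak)
    if (length(on)) {
      ng <- c(ng, rep(g, length(on))); no <- c(no, as.integer(on))
    }
  }
  list(p = tibble::tibble(gene = pg, offset = po),
       n = tibble::tibble(gene = ng, offset = no))
}

#' Closedness of a pattern
#'
#' A pattern (with full match sets) is closed when no single pair-item
#' prepended or appended leaves both reported match sets identical
#' (offsets shifted by one for a prepended item). A full-width pattern
#' is closed by construction; an unmatched pattern is vacuously closed.
#'
#' @param pairs integer vector of pair-item lower items.
#' @param dmat a `discretized_matrix`.
#' @param neg_match_mode negative-match convention.
#' @return Logical scalar.
#' @export
is_closed <- function(pairs, dmat, neg_match_mode = "strict") {
  pairs <- check_pairs(pairs)
  nt <- ncol(dmat$items)
  if (length(pairs) >= nt) return(TRUE)
  base <- compute_match_sets(pairs, dmat, neg_match_mode)
  key <- function(ms, shift = 0L) {
    paste(
      paste(sort(paste(ms$p$gene, ms$p$offset + shift)), collapse = ";"),
      paste(sort(paste(ms$n$gene, ms$n$offset + shift)), collapse = ";"),
      sep = "|")
  }
  base_key <- key(base)
  for (lo in pair_item_alphabet()) {
    if (key(compute_match_sets(c(pairs, lo), dmat, neg_match_mode)) == base_key)
      return(FALSE)
    if (key(compute_match_sets(c(lo, pairs), dmat, neg_match_mode), 1L) == base_key)
      return(FALSE)
  }
  TRUE
}

#' Mine all closed subsequential patterns
#'
#' Depth-first Apriori-style search over pair-item extensions with full
#' match-set recomputation (implemented in C++). Returns exactly the
#' patterns of length at least `min_len` whose distinct matched genes
#' number at least `sup`, whose insignificant fraction is within
#' `max0_fraction`, that are closed, and that are unique up to
#' match-set equivalence (for identical reported `(p, n)` sets the
#' shortest, then lexicographically smallest, pair sequence is kept).
#'
#' @param dmat a `discretized_matrix`.
#' @param config a [mining_config()].
#' @return A `pattern_set` whose `patterns` are [subseq_pattern()]s.
#' @export
mine_closed_patterns <- function(dmat, config = mining_config()) {
  stopifnot(inherits(dmat, "discretized_matrix"), inherits(config, "mining_config"))
  nt <- ncol(dmat$items)
  if (config$min_len > nt) {
    stop(sprintf("min_len (%d) exceeds the number of time points (%d)",
                 config$min_len, nt), call. = FALSE)
  }
  raw <- cpp_mine(dmat$items, config$sup, config$min_len,
                  config$max0_fraction, config$neg_match_mode == "weak")
  genes <- dmat$gene_ids
  pats <- lapply(raw, function(r) {
    subseq_pattern(
      pairs = r$pairs,
      p = tibble::tibble(gene = genes[r$p[, 1L]], offset = as.integer(r$p[, 2L])),
      n = tibble::tibble(gene = genes[r$n[, 1L]], offset = as.integer(r$n[, 2L]))
    )
  })
  pats <- pats[order(vapply(pats, function(p) pattern_sort_key(p$pairs), character(1L)))]
  new_pattern_set(pats, dmat$name)
}

# deterministic ordering: by length then lexicographic on lo values
pattern_sort_key <- function(pairs) {
  paste(sprintf("%02d", length(pairs)),
        paste(sprintf("%d", pairs + 3L), collapse = ""), sep = "-")
}
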