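#' The pair-item alphabet
#'
#' Discretization items live in `-3..3` (seven levels). A pair-item is
#' an ordered couple of adjacent items `e :: e+1`; there are exactly six
#' of them, `-3::-2` through `2::3`. Throughout the package a pair-item
#' sequence is represented by the integer vector of its lower items
#' (`lo`), each in `-3..2`.
#'
#' @return `item_alphabet()` returns the integer vector `-3:3`;
#'   `pair_item_alphabet()` returns `-3:2` (the legal `lo` values).
#' @export
item_alphabet <- function() -3:3

#' @rdname item_alphabet
#' @export
pair_item_alphabet <- function() -3:2

check_items <- function(e) {
  if (!all(e %in% -3:3)) {
    stop("item(s) outside the alphabet -3..3: ",
         paste(unique(e[!e %in% -3:3]), collapse = ", "), call. = FALSE)
  }
  as.integer(e)
}

check_pairs <- function(lo) {
  if (!length(lo)) stop("empty pair-item sequence", call. = FALSE)
  if (!all(lo %in% -3:2)) {
    stop("illegal pair-item lower item(s): ",
         paste(unique(lo[!lo %in% -3:2]), collapse = ", "), call. = FALSE)
  }
  as.integer(lo)
}

#' Format pair-items as "lo::hi" labels
#'
#' @param lo integer vector of lower items in -3..2.
#' @return Character vector like `"2::3"`.
#' @export
pair_item_labels <- function(lo) {
  lo <- check_pairs(lo)
  paste0(lo, "::", lo + 1L)
}

#' Item similarity
#'
#' Two items are similar iff they differ by at most one level
#' (`|a - b| <= 1`), and negatively similar iff their mirrored levels do
#' (`|a + b| <= 1`). So 2 is similar to 1, 2 and 3; 3 is negatively
#' similar to -3 and -2; 0 is not similar to -3 or -2 in either sense.
#'
#' @param a,b integer items in -3..3 (vectorized).
#' @return Logical.
#' @export
items_similar <- function(a, b) {
  a <- check_items(a); b <- check_items(b)
  abs(a - b) <= 1L
}

#' @rdname items_similar
#' @export
items_negatively_similar <- function(a, b) {
  a <- check_items(a); b <- check_items(b)
  abs(a + b) <= 1L
}

#' Match an item against a pair-item
#'
#' Positive polarity requires the item to be similar to both ends of the
#' pair, which is exactly membership in `{lo, hi}`. For negative
#' polarity two conventions are supported: `strict` requires negative
#' similarity to both ends; `weak` (the default throughout the package)
#' requires it to at least one end. The weak convention is the one under
#' which sign-mirrored sequences of a matching profile themselves match
#' (see the vignette for the rationale).
#'
#' @param e integer item (vectorized).
#' @param lo lower item of the pair (scalar, in -3..2).
#' @param polarity `"positive"` or `"negative"`.
#' @param mode negative-match convention, `"weak"` or `"strict"`.
#' @return Logical.
#' @export
item_matches_pair <- function(e, lo, polarity = c("positive", "negative"),
                              mode = c("weak", "strict")) {
  polarity <- match.arg(polarity)
  mode <- match.arg(mode)
  e <- check_items(e)
  lo <- check_pairs(lo)
  stopifnot(length(lo) == 1L)
  if (polarity == "positive") {
    items_similar(e, lo) & items_similar(e, lo + 1L)
  } else if (mode == "strict") {
    items_negatively_similar(e, lo) & items_negatively_similar(e, lo + 1L)
  } else {
    items_negatively_similar(e, lo) | items_negatively_similar(e, lo + 1L)
  }
}

#' Offsets at which a pattern matches a discretized sequence
#'
#' A pattern of `l` pair-items matches a sequence of items at 0-based
#' offset `ii` when every position `jj` in `0..l-1` satisfies
#' [item_matches_pair()] for `sequence[ii + jj]` against pair `jj`.
#' Matches are over consecutive positions, no gaps; the offset range is
#' `0..N_T - l` inclusive, so a full-width pattern can match a whole
#' sequence.
#'
#' @param pairs integer vector of pair-item lower items.
#' @param sequence integer item vector.
#' @inheritParams item_matches_pair
#' @return Sorted integer vector of 0-based offsets (possibly empty).
#' @export
match_offsets <- function(pairs, sequence, polarity = c("positive", "negative"),
                          mode = c("weak", "strict")) {
  polarity <- match.arg(polarity)
  mode <- match.arg(mode)
  pairs <- check_pairs(pairs)
  sequence <- check_items(sequence)
  fast_match_offsets(pairs, sequence, polarity == "positive", mode == "weak")
}

# validation-free matcher shared by match set computation; vectorized
# over offsets, one pass per pattern position
fast_match_offsets <- function(pairs, s, positive, weak) {
  l <- length(pairs)
  nt <- length(s)
  if (l > nt) return(integer(0))
  offs <- 0:(nt - l)
  ok <- rep(TRUE, length(offs))
  for (jj in seq_len(l)) {
    e <- s[offs + jj]
    lo <- pairs[jj]
    m <- if (positive) {
      e == lo | e == lo + 1L
    } else if (weak) {
      abs(e + lo) <= 1L | abs(e + lo + 1L) <= 1L
    } else {
      abs(e + lo) <= 1L & abs(e + lo + 1L) <= 1L
    }
    ok <- ok & m
  }
  offs[ok]
}

#' Fraction of insignificant positions in a pattern
#'
#' The pair-items `-1::0` and `0::1` denote insignificant expression
#' levels (items hovering around zero); patterns are bounded to at most
#' a `max0` fraction of them.
#'
#' @param pairs integer vector of pair-item lower items.
#' @return Fraction in \[0, 1\].
#' @export
insignificant_fraction <- function(pairs) {
  pairs <- check_pairs(pairs)
  mean(pairs %in% c(-1L, 0L))
}

# per-pair behaviour signature over the full item alphabet:
# which items match positively / negatively-strict / negatively-weak
pair_behaviour_signature <- function(lo) {
  e <- item_alphabet()
  paste(
    paste(as.integer(item_matches_pair(e, lo, "positive")), collapse = ""),
    paste(as.integer(item_matches_pair(e, lo, "negative", "strict")), collapse = ""),
    paste(as.integer(item_matches_pair(e, lo, "negative", "weak")), collapse = ""),
    sep = "|"
  )
}

#' Canonical form of a pair-item sequence
#'
#' Positionwise matching means two pair sequences are match-equivalent
#' exactly when, at every position, the two pair-items accept the same
#' items under both polarities. Per position this routine picks the
#' smallest `lo` among pair-items with identical match behaviour over
#' the full alphabet. (Over the seven-item alphabet the six pair-items
#' have pairwise distinct behaviour, so the map is the identity; it is
#' kept explicit so the invariant is checked, not assumed.)
#'
#' @param pairs integer vector of pair-item lower items.
#' @return Canonical integer vector of the same length.
#' @export
canonicalize <- function(pairs) {
  pairs <- check_pairs(pairs)
  sigs <- vapply(pair_item_alphabet(), pair_behaviour_signature, character(1L))
  vapply(pairs, function(lo) {
    pair_item_alphabet()[match(sigs[match(lo, pair_item_alphabet())], sigs)]
  }, integer(1L))
}

#' Subsequential pattern object
#'
#' Bundles a pair-item sequence with its positive (`p`) and negative
#' (`n`) match sets: tibbles of `(gene, offset)` rows, offsets 0-based,
#' a gene appearing on one side only (positive takes precedence) but
#' possibly at several offsets. Support is the number of distinct
#' matched genes.
#'
#' @param pairs integer vector of pair-item lower items.
#' @param p,n tibbles/data frames with columns `gene` (character) and
#'   `offset` (integer, 0-based).
#' @return An object of class `subseq_pattern`.
#' @export
subseq_pattern <- function(pairs, p, n) {
  pairs <- check_pairs(pairs)
  p <- tibble::as_tibble(p)[, c("gene", "offset")]
  n <- tibble::as_tibble(n)[, c("gene", "offset")]
  both <- intersect(unique(p$gene), unique(n$gene))
  if (length(both)) {
    stop("gene(s) on both sides of a pattern: ", paste(both, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(pairs = pairs, p = p, n = n,
         support = length(unique(p$gene)) + length(unique(n$gene))),
    class = "subseq_pattern"
  )
}

#' @export
print.subseq_pattern <- function(x, ...) {
  cat(sprintf("<subseq_pattern> {%s}  |p|=%d gene(s), |n|=%d gene(s)\n",
              paste(pair_item_labels(x$pairs), collapse = ", "),
              length(unique(x$p$gene)), length(unique(x$n$gene))))
  invisible(x)
}

#' @export
length.subseq_pattern <- function(x) length(x$pairs)
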