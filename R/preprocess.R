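#' Impute missing expression values
#'
#' Genes with more than `max_missing_per_gene` missing measurements are
#' dropped (with a warning naming them). Each remaining missing entry is
#' replaced by the mean of the nearest non-missing neighbour on each
#' side along the time axis; at the series boundaries, where only one
#' side has a neighbour, that neighbour's value is copied.
#'
#' @param x an [expression_matrix()].
#' @param max_missing_per_gene maximum number of missing entries a gene
#'   may have and still be retained. The default 1 keeps genes with
#'   fewer than 2 missing values.
#' @return An [expression_matrix()] with an all-`FALSE` mask.
#' @export
impute_missing <- function(x, max_missing_per_gene = 1L) {
  stopifnot(inherits(x, "expression_matrix"))
  n_miss <- rowSums(x$missing_mask)
  drop <- n_miss > max_missing_per_gene
  if (all(drop)) {
    stop("all genes exceed the missing-value budget; nothing to impute",
         call. = FALSE)
  }
  if (any(drop)) {
    warning(sprintf("dropping %d gene(s) with > %d missing values: %s",
                    sum(drop), max_missing_per_gene,
                    paste(head(x$gene_ids[drop], 5L), collapse = ", ")),
            call. = FALSE)
  }
  vals <- x$values[!drop, , drop = FALSE]
  mask <- x$missing_mask[!drop, , drop = FALSE]
  vals[mask] <- NA_real_
  for (i in which(rowSums(mask) > 0L)) {
    vals[i, ] <- fill_gaps(vals[i, ])
  }
  expression_matrix(vals, n_cycles = x$n_cycles, name = x$name,
                    missing_mask = matrix(FALSE, nrow(vals), ncol(vals)))
}

# nearest-neighbour gap fill along one gene's time series
fill_gaps <- function(v) {
  obs <- which(!is.na(v))
  if (!length(obs)) stop("gene has no observed values", call. = FALSE)
  for (j in which(is.na(v))) {
    left <- obs[obs < j]
    right <- obs[obs > j]
    if (!length(left)) {
      v[j] <- v[min(right)]
    } else if (!length(right)) {
      v[j] <- v[max(left)]
    } else {
      v[j] <- (v[max(left)] + v[min(right)]) / 2
    }
  }
  v
}

#' Split a multi-cycle time series into single-cycle datasets
#'
#' A series covering two cell cycles over `h` time points is split into
#' the first and last `floor(h/2) + 1` columns; three cycles give three
#' windows of `floor(h/3) + 1` columns (first, middle anchored at
#' `floor(h/3)`, last). Adjacent windows share boundary time points, so
#' the split covers every original column.
#'
#' @param x an [expression_matrix()] with `n_cycles` in 1..3.
#' @return A list of single-cycle [expression_matrix()] objects
#'   (`n_cycles = 1`), named `<name>_cc1`, `<name>_cc2`, ...
#'   For `n_cycles = 1` the input is returned unchanged in a length-1 list.
#' @export
split_cell_cycles <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  h <- ncol(x$values)
  nc <- x$n_cycles
  if (!nc %in% 1:3) {
    stop("n_cycles must be 1, 2 or 3 (got ", nc, ")", call. = FALSE)
  }
  if (nc == 1L) return(setNames(list(x), x$name))
  windows <- if (nc == 2L) {
    w <- h %/% 2L + 1L
    list(1:w, (h - w + 1L):h)
  } else {
    q <- h %/% 3L
    list(1:(q + 1L), (q + 1L):(2L * q + 1L), (h - q):h)
  }
  out <- lapply(seq_along(windows), function(k) {
    cols <- windows[[k]]
    expression_matrix(x$values[, cols, drop = FALSE], n_cycles = 1L,
                      name = paste0(x$name, "_cc", k),
                      missing_mask = x$missing_mask[, cols, drop = FALSE])
  })
  setNames(out, vapply(out, `[[`, character(1L), "name"))
}

#' Per-gene discretization scale
#'
#' The scale `delta_i` of a gene is the nearest-rank percentile of its
#' absolute expression levels: sort `|v|` ascending and take the element
#' at 1-based rank `ceiling(percentile * length(v))`. With the default
#' 0.8 this is the "biggest 80%-th" absolute value, so the band
#' `[-2.5 delta, 2.5 delta]` covers most of the gene's dynamic range.
#' A zero result falls back to the smallest positive `|v|`; an all-zero
#' gene has no meaningful scale and yields `NA` (un-discretizable).
#'
#' @param v numeric vector of one gene's expression values (no missing).
#' @param percentile rank fraction in (0, 1].
#' @return A positive scalar, or `NA_real_` for an all-zero gene.
#' @export
compute_delta <- function(v, percentile = 0.8) {
  if (!length(v)) stop("empty expression vector", call. = FALSE)
  if (anyNA(v)) stop("missing values present; impute first", call. = FALSE)
  stopifnot(percentile > 0, percentile <= 1)
  a <- sort(abs(v))
  d <- a[ceiling(percentile * length(a))]
  if (d == 0) {
    pos <- a[a > 0]
    if (!length(pos)) return(NA_real_)
    d <- pos[1L]
  }
  d
}

#' Discretize one expression value into a seven-level item
#'
#' Items are integers in -3..3 assigned by uniform half-open bands of
#' width `delta` centred on multiples of `delta`:
#' `[k*delta - delta/2, k*delta + delta/2)` maps to `k` for `|k| <= 2`,
#' values at or above `2.5*delta` map to 3 and values below
#' `-2.5*delta` map to -3. Equivalently, round-half-up of `m/delta`
#' clipped to `[-3, 3]`; e.g. with `delta = 1`, 2.49 maps to 2 and
#' 2.51 to 3.
#'
#' @param m expression value (vectorized).
#' @param delta positive per-gene scale.
#' @return Integer item(s) in -3..3.
#' @export
discretize_value <- function(m, delta) {
  stopifnot(is.numeric(m), is.numeric(delta), all(delta > 0))
  as.integer(pmax(-3, pmin(3, floor(m / delta + 0.5))))
}

#' Discretize an expression matrix
#'
#' Applies [compute_delta()] then [discretize_value()] per gene.
#' Un-discretizable (all-zero) genes are dropped with a warning.
#'
#' @param x an [expression_matrix()] without missing values.
#' @param percentile passed to [compute_delta()].
#' @return An object of class `discretized_matrix` with fields `items`
#'   (integer matrix in -3..3, same dimnames), `delta` (named per-gene
#'   scales), `gene_ids`, `name`.
#' @export
discretize_matrix <- function(x, percentile = 0.8) {
  stopifnot(inherits(x, "expression_matrix"))
  if (any(x$missing_mask)) {
    stop("matrix has missing values; run impute_missing() first", call. = FALSE)
  }
  delta <- apply(x$values, 1L, compute_delta, percentile = percentile)
  bad <- is.na(delta)
  if (all(bad)) stop("no discretizable genes (all rows constant zero)", call. = FALSE)
  if (any(bad)) {
    warning(sprintf("dropping %d un-discretizable all-zero gene(s): %s",
                    sum(bad), paste(head(x$gene_ids[bad], 5L), collapse = ", ")),
            call. = FALSE)
  }
  vals <- x$values[!bad, , drop = FALSE]
  delta <- delta[!bad]
  items <- matrix(discretize_value(vals, rep(delta, times = ncol(vals))),
                  nrow = nrow(vals), dimnames = dimnames(vals))
  structure(
    list(items = items, delta = delta, gene_ids = rownames(vals), name = x$name),
    class = "discretized_matrix"
  )
}

#' @export
print.discretized_matrix <- function(x, ...) {
  cat(sprintf("<discretized_matrix '%s'> %d genes x %d time points, items in [%d, %d]\n",
              x$name, nrow(x$items), ncol(x$items), min(x$items), max(x$items)))
  invisible(x)
}

#' @rdname tidy.expression_matrix
#' @export
tidy.discretized_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(x$gene_ids, times = ncol(x$items)),
    timepoint = rep(seq_len(ncol(x$items)), each = nrow(x$items)),
    item = as.integer(x$items),
    delta = rep(unname(x$delta), times = ncol(x$items))
  )
}

#' Write / read a discretized matrix as TSV
#'
#' The layout mirrors the expression TSV (header of time labels, gene id
#' first column) with an extra final column `delta` holding the per-gene
#' scale, so the pair round-trips exactly.
#'
#' @param x a `discretized_matrix`.
#' @param path file path.
#' @return `path` (write) or a `discretized_matrix` (read).
#' @export
write_discretized_tsv <- function(x, path) {
  lines <- c(
    paste(c("gene", colnames(x$items), "delta"), collapse = "\t"),
    vapply(seq_len(nrow(x$items)), function(i) {
      paste(c(rownames(x$items)[i], x$items[i, ],
              format(x$delta[i], digits = 17, scientific = FALSE, trim = TRUE)),
            collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_discretized_tsv
#' @export
read_discretized_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  delta <- as.numeric(df[["delta"]])
  items <- as.matrix(df[, setdiff(colnames(df), c("gene", "delta")), drop = FALSE])
  storage.mode(items) <- "integer"
  rownames(items) <- df[["gene"]]
  structure(
    list(items = items, delta = setNames(delta, df[["gene"]]),
         gene_ids = df[["gene"]], name = sub("\\.[^.]*$", "", basename(path))),
    class = "discretized_matrix"
  )
}
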