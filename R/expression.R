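#' Expression matrix container
#'
#' A thin wrapper around a numeric genes x time-points matrix carrying a
#' missing-value mask, the number of cell cycles the series spans, and an
#' optional dataset name. Expression values are assumed to be normalized
#' log-ratios with per-gene mean close to zero; the package never
#' re-normalizes.
#'
#' @param values numeric matrix, genes in rows, time points in columns.
#'   Row names (gene ids) are required and must be unique; column names
#'   default to `t1..tN`.
#' @param n_cycles number of cell cycles covered by the time series.
#' @param name dataset name used in manifests and pattern provenance.
#' @param missing_mask logical matrix of the same shape; `TRUE` marks a
#'   missing measurement. Defaults to `is.na(values)`.
#'
#' @return An object of class `expression_matrix` with fields
#'   `gene_ids`, `values`, `missing_mask`, `n_cycles`, `name`.
#' @export
expression_matrix <- function(values, n_cycles = 1L, name = "dataset",
                              missing_mask = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 2L) {
    stop("an expression matrix needs at least 1 gene and 2 time points",
         call. = FALSE)
  }
  if (is.null(rownames(values))) {
    stop("gene ids (row names) are required", call. = FALSE)
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(colnames(values))) colnames(values) <- paste0("t", seq_len(ncol(values)))
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- missing_mask | is.na(values)
  stopifnot(identical(dim(missing_mask), dim(values)))
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  structure(
    list(gene_ids = rownames(values), values = values,
         missing_mask = missing_mask, n_cycles = n_cycles,
         name = as.character(name)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix '%s'> %d genes x %d time points, %d cycle(s), %d missing\n",
    x$name, nrow(x$values), ncol(x$values), x$n_cycles, sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Tidy an expression matrix into long form
#'
#' @param x an [expression_matrix()].
#' @param ... unused.
#' @return A tibble with one row per (gene, time point): columns `gene`,
#'   `time` (column label), `timepoint` (1-based index), `value`,
#'   `missing`.
#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(x$gene_ids, times = ncol(x$values)),
    time = rep(colnames(x$values), each = nrow(x$values)),
    timepoint = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    value = as.vector(x$values),
    missing = as.vector(x$missing_mask)
  )
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of time-point labels and a first column of gene
#' identifiers. Empty cells and the tokens `NA`/`NaN` (case-insensitive)
#' are treated as missing measurements. Gene ids are opaque,
#' case-sensitive strings.
#'
#' @param path path to a tab-separated file.
#' @param n_cycles number of cell cycles the series covers (metadata the
#'   file itself does not carry).
#' @param name dataset name; defaults to the file name without extension.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, n_cycles = 1L, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression TSV needs a header and at least one gene row",
                               call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expected <- length(fields[[1L]])
  widths <- lengths(fields)
  if (any(widths != ncol_expected)) {
    stop(sprintf("ragged TSV: row %d has %d fields, expected %d",
                 which(widths != ncol_expected)[1L],
                 widths[widths != ncol_expected][1L], ncol_expected),
         call. = FALSE)
  }
  time_labels <- fields[[1L]][-1L]
  body <- fields[-1L]
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  cells <- vapply(body, function(f) f[-1L], character(length(time_labels)))
  cells <- if (is.null(dim(cells))) matrix(cells, nrow = 1L) else t(cells)
  missing <- !nzchar(cells) | tolower(cells) %in% c("na", "nan")
  vals <- suppressWarnings(as.numeric(cells))
  bad <- !missing & is.na(vals)
  if (any(bad)) {
    stop("non-numeric cell(s), e.g. '", cells[which(bad)[1L]], "'", call. = FALSE)
  }
  vals[missing] <- NA_real_
  values <- matrix(vals, nrow = length(gene_ids),
                   dimnames = list(gene_ids, time_labels))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  expression_matrix(values, n_cycles = n_cycles, name = name)
}

#' Write an expression matrix to TSV
#'
#' Missing entries are written as empty cells, so `write` then
#' [read_expression_tsv()] round-trips both values and mask.
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  vals <- x$values
  out <- matrix(format_num(vals), nrow = nrow(vals))
  out[x$missing_mask] <- ""
  lines <- c(
    paste(c("gene", colnames(vals)), collapse = "\t"),
    vapply(seq_len(nrow(vals)), function(i) {
      paste(c(rownames(vals)[i], out[i, ]), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

# full-precision numeric formatting for round-trip-stable TSV output
format_num <- function(v) {
  s <- vapply(as.vector(v), function(z) {
    if (is.na(z)) "" else format(z, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1L))
  s
}
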