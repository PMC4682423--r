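#' Gene interaction network containers
#'
#' A `gin` is a tibble of undirected labelled edges (`gene_a`,
#' `gene_b`, `label` in positive/negative/both) with endpoints ordered
#' `gene_a < gene_b` and a `nodes` attribute carrying the gene universe
#' (which may include isolated genes). An `integrative_gin` carries
#' per-polarity integer weights (`pos_weight`, `neg_weight`) counting in
#' how many per-dataset GINs the pair occurred with that polarity.
#'
#' @param edges tibble/data frame with columns `gene_a`, `gene_b`,
#'   `label` (for `new_gin`) or `pos_weight`, `neg_weight` (for
#'   `new_integrative_gin`).
#' @param nodes character vector of gene ids; defaults to the edge
#'   endpoints.
#' @return A tibble subclass of class `gin` / `integrative_gin`.
#' @export
new_gin <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b", "label") %in% names(edges)))
  edges <- order_endpoints(edges)
  stopifnot(all(edges$label %in% c("positive", "negative", "both")),
            !any(edges$gene_a == edges$gene_b))
  if (is.null(nodes)) nodes <- union(edges$gene_a, edges$gene_b)
  edges <- dplyr::arrange(edges, .data$gene_a, .data$gene_b)
  structure(edges, nodes = sort(unique(as.character(nodes))),
            class = c("gin", class(tibble::tibble())))
}

#' @rdname new_gin
#' @export
new_integrative_gin <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b", "pos_weight", "neg_weight") %in% names(edges)))
  edges <- order_endpoints(edges)
  stopifnot(all(edges$pos_weight + edges$neg_weight >= 1L),
            !any(edges$gene_a == edges$gene_b))
  if (is.null(nodes)) nodes <- union(edges$gene_a, edges$gene_b)
  edges <- dplyr::arrange(edges, .data$gene_a, .data$gene_b)
  structure(edges, nodes = sort(unique(as.character(nodes))),
            class = c("integrative_gin", class(tibble::tibble())))
}

order_endpoints <- function(edges) {
  a <- as.character(edges$gene_a); b <- as.character(edges$gene_b)
  swap <- a > b
  edges$gene_a <- ifelse(swap, b, a)
  edges$gene_b <- ifelse(swap, a, b)
  edges
}

#' Gene universe of a network
#'
#' @param gin a `gin` or `integrative_gin`.
#' @return Character vector of gene ids.
#' @export
gin_nodes <- function(gin) attr(gin, "nodes")

#' Build a per-dataset GIN from mined patterns
#'
#' Two genes that occur in a same pattern (on either match side) are
#' connected when some pair of their match offsets differs by at most
#' `i_t` time points. Same-side co-occurrence (both `p` or both `n`)
#' yields a positive interaction, cross-side a negative one; a pair
#' seeing both situations across patterns is labelled `both`.
#'
#' @param patterns a `pattern_set` from [mine_closed_patterns()].
#' @param i_t maximum allowed start-offset delay between the two genes
#'   (0 disables time-lagged edges). See [lag_allowance()] for the
#'   per-dataset rule.
#' @return A `gin`; its node set is every gene matched by any pattern.
#' @export
build_gin <- function(patterns, i_t = 0L) {
  stopifnot(inherits(patterns, "pattern_set"), i_t >= 0)
  pos_acc <- list()
  neg_acc <- list()
  all_genes <- character(0)
  for (pat in patterns$patterns) {
    mem <- dplyr::bind_rows(dplyr::mutate(pat$p, side = "p"),
                            dplyr::mutate(pat$n, side = "n"))
    genes <- unique(mem$gene)
    all_genes <- union(all_genes, genes)
    if (length(genes) < 2L) next
    offs <- lapply(split(mem$offset, mem$gene), identity)[genes]
    side <- vapply(split(mem$side, mem$gene), `[[`, "", 1L)[genes]
    pk <- character(0); nk <- character(0)
    for (i in seq_len(length(genes) - 1L)) {
      for (j in (i + 1L):length(genes)) {
        if (min(abs(outer(offs[[i]], offs[[j]], "-"))) > i_t) next
        key <- paste(sort(c(genes[i], genes[j])), collapse = "\t")
        if (side[i] == side[j]) pk <- c(pk, key) else nk <- c(nk, key)
      }
    }
    pos_acc[[length(pos_acc) + 1L]] <- pk
    neg_acc[[length(neg_acc) + 1L]] <- nk
  }
  pos_keys <- unique(unlist(pos_acc))
  neg_keys <- unique(unlist(neg_acc))
  if (is.null(pos_keys)) pos_keys <- character(0)
  if (is.null(neg_keys)) neg_keys <- character(0)
  keys <- union(pos_keys, neg_keys)
  if (!length(keys)) {
    return(new_gin(tibble::tibble(gene_a = character(), gene_b = character(),
                                  label = character()), nodes = all_genes))
  }
  parts <- strsplit(keys, "\t", fixed = TRUE)
  label <- dplyr::case_when(
    keys %in% pos_keys & keys %in% neg_keys ~ "both",
    keys %in% pos_keys ~ "positive",
    TRUE ~ "negative")
  new_gin(tibble::tibble(gene_a = vapply(parts, `[[`, "", 1L),
                         gene_b = vapply(parts, `[[`, "", 2L),
                         label = label),
          nodes = all_genes)
}

#' Per-dataset time-lag allowance
#'
#' One time point of delay is allowed for single-cycle datasets with
#' more than 12 time points (at least `min_timepoints`); shorter series
#' allow none.
#'
#' @param n_timepoints number of time points in the single-cycle dataset.
#' @param min_timepoints smallest series length that earns the 1-point
#'   allowance (default 13).
#' @return 0 or 1.
#' @export
lag_allowance <- function(n_timepoints, min_timepoints = 13L) {
  if (n_timepoints >= min_timepoints) 1L else 0L
}

#' Integrate per-dataset GINs with per-polarity weights
#'
#' The positive weight of a pair is the number of input GINs containing
#' it with label positive or both; the negative weight counts
#' negative/both occurrences. The two polarities are counted
#' independently of each other.
#'
#' @param gins list of `gin` objects.
#' @return An `integrative_gin` over the union of the input node sets.
#' @export
integrate_gins <- function(gins) {
  stopifnot(length(gins) >= 1L, all(vapply(gins, inherits, logical(1L), "gin")))
  nodes <- sort(unique(unlist(lapply(gins, gin_nodes))))
  tallies <- purrr::map_dfr(gins, function(g) {
    tibble::tibble(gene_a = g$gene_a, gene_b = g$gene_b,
                   pos = as.integer(g$label %in% c("positive", "both")),
                   neg = as.integer(g$label %in% c("negative", "both")))
  })
  if (!nrow(tallies)) {
    return(new_integrative_gin(
      tibble::tibble(gene_a = character(), gene_b = character(),
                     pos_weight = integer(), neg_weight = integer()),
      nodes = nodes))
  }
  edges <- tallies |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(pos_weight = sum(.data$pos), neg_weight = sum(.data$neg),
                     .groups = "drop")
  new_integrative_gin(edges, nodes = nodes)
}

#' Keep edges conserved across datasets
#'
#' An edge enters the reliable GIN when either polarity weight reaches
#' `occ`; the label records which polarity (or both) passed. Nodes of
#' the result are the surviving edge endpoints (isolated genes are
#' dropped from the reported view).
#'
#' @param ig an `integrative_gin`.
#' @param occ conservation threshold (minimum per-polarity weight).
#' @return A `gin`.
#' @export
filter_reliable <- function(ig, occ) {
  stopifnot(inherits(ig, "integrative_gin"), occ >= 1)
  keep <- ig$pos_weight >= occ | ig$neg_weight >= occ
  edges <- ig[keep, , drop = FALSE]
  label <- dplyr::case_when(
    edges$pos_weight >= occ & edges$neg_weight >= occ ~ "both",
    edges$pos_weight >= occ ~ "positive",
    TRUE ~ "negative")
  new_gin(tibble::tibble(gene_a = edges$gene_a, gene_b = edges$gene_b,
                         label = label))
}

#' Pearson-correlation baseline network
#'
#' Connects two genes when the absolute Pearson correlation of their
#' expression profiles over all time points reaches `threshold`; the
#' edge label records the sign of the correlation. Constant genes are
#' excluded with a warning.
#'
#' @param x an [expression_matrix()] without missing values and with at
#'   least 3 time points.
#' @param threshold absolute-correlation cutoff in (0, 1].
#' @return A `gin` whose nodes are all non-constant genes.
#' @export
pcc_baseline <- function(x, threshold = 0.8) {
  stopifnot(inherits(x, "expression_matrix"),
            threshold > 0, threshold <= 1)
  if (ncol(x$values) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (any(x$missing_mask)) stop("missing values present; impute first", call. = FALSE)
  sds <- apply(x$values, 1L, sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d constant gene(s) from the PCC baseline",
                    sum(sds == 0)), call. = FALSE)
  }
  vals <- x$values[sds > 0, , drop = FALSE]
  r <- cor(t(vals))
  idx <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  new_gin(tibble::tibble(
    gene_a = rownames(r)[idx[, 1L]],
    gene_b = rownames(r)[idx[, 2L]],
    label = ifelse(r[idx] > 0, "positive", "negative")),
    nodes = rownames(vals))
}

#' Degree distribution and power-law fit
#'
#' Tabulates node degrees of a GIN and fits `log p(k) ~ log k` by least
#' squares over degrees with nonzero counts, where `p(k)` is the
#' fraction of nodes with degree `k`. The reported exponent is the
#' slope (about -1.8 for the scale-free networks this method tends to
#' produce at full scale). With fewer than 2 distinct positive degrees
#' the exponent is undefined (`NA`).
#'
#' @param gin a `gin`.
#' @return Object of class `degree_stats`: a list with `histogram`
#'   (tibble `degree`, `count`, `p`), `exponent`, and `n_nodes`. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
degree_stats <- function(gin) {
  stopifnot(inherits(gin, "gin"))
  deg <- table(factor(c(gin$gene_a, gin$gene_b), levels = gin_nodes(gin)))
  hist <- tibble::tibble(degree = as.integer(names(table(deg))),
                         count = as.integer(table(deg)))
  hist <- hist[hist$degree > 0L, , drop = FALSE]
  hist$p <- hist$count / sum(hist$count)
  exponent <- NA_real_
  if (nrow(hist) >= 2L) {
    exponent <- unname(coef(lm(log(p) ~ log(degree), data = hist))[2L])
  }
  structure(list(histogram = hist, exponent = exponent,
                 n_nodes = length(gin_nodes(gin))),
            class = "degree_stats")
}

#' @export
print.degree_stats <- function(x, ...) {
  cat(sprintf("<degree_stats> %d node(s), %d distinct degree(s), exponent %s\n",
              x$n_nodes, nrow(x$histogram),
              if (is.na(x$exponent)) "undefined" else sprintf("%.3f", x$exponent)))
  invisible(x)
}

#' @export
tidy.degree_stats <- function(x, ...) x$histogram

#' @export
glance.degree_stats <- function(x, ...) {
  tibble::tibble(n_nodes = x$n_nodes, n_degrees = nrow(x$histogram),
                 exponent = x$exponent)
}
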