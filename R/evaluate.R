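#' Reference edge set
#'
#' An unordered, deduplicated set of gene-id pairs used as validation
#' standard (protein-protein interactions, pathway co-membership,
#' regulatory interactions, or planted synthetic truth), optionally
#' with a set of genes flagged as transcription factors. Self-pairs are
#' dropped with a warning.
#'
#' @param edges tibble/data frame with character columns `gene_a`,
#'   `gene_b`.
#' @param tf_genes optional character vector of transcription-factor
#'   gene ids.
#' @return A tibble subclass of class `reference_edges` with a
#'   `tf_genes` attribute (possibly `NULL`).
#' @export
reference_edges <- function(edges, tf_genes = NULL) {
  edges <- tibble::as_tibble(edges)[, c("gene_a", "gene_b")]
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  self <- edges$gene_a == edges$gene_b
  if (any(self)) {
    warning(sprintf("dropping %d self-pair(s) from the reference", sum(self)),
            call. = FALSE)
    edges <- edges[!self, , drop = FALSE]
  }
  edges <- order_endpoints(edges)
  edges <- dplyr::distinct(edges)
  edges <- dplyr::arrange(edges, .data$gene_a, .data$gene_b)
  structure(edges,
            tf_genes = if (is.null(tf_genes)) NULL else sort(unique(as.character(tf_genes))),
            class = c("reference_edges", class(tibble::tibble())))
}

#' @rdname reference_edges
#' @param ref a `reference_edges` object.
#' @export
tf_genes <- function(ref) attr(ref, "tf_genes")

#' Restrict a network and a reference to their common gene universe
#'
#' Both sides are cut down to the intersection of their gene universes.
#' If the reference carries transcription-factor flags, predicted edges
#' are further restricted to pairs with at least one TF endpoint, the
#' regime in which TF-gene regulation references are meaningful.
#'
#' @param gin a `gin`.
#' @param reference a [reference_edges()] set.
#' @return List with elements `gin` and `reference`, both restricted.
#' @export
restrict_to_common_genes <- function(gin, reference) {
  stopifnot(inherits(gin, "gin"), inherits(reference, "reference_edges"))
  ref_genes <- union(reference$gene_a, reference$gene_b)
  common <- intersect(gin_nodes(gin), ref_genes)
  if (!length(common)) stop("no genes in common between network and reference",
                            call. = FALSE)
  keep_g <- gin$gene_a %in% common & gin$gene_b %in% common
  tf <- tf_genes(reference)
  if (!is.null(tf)) {
    keep_g <- keep_g & (gin$gene_a %in% tf | gin$gene_b %in% tf)
  }
  g2 <- new_gin(gin[keep_g, c("gene_a", "gene_b", "label")],
                nodes = intersect(gin_nodes(gin), common))
  keep_r <- reference$gene_a %in% common & reference$gene_b %in% common
  r2 <- reference_edges(reference[keep_r, c("gene_a", "gene_b")], tf_genes = tf)
  list(gin = g2, reference = r2)
}

#' Evaluate a network against a reference edge set
#'
#' Restricts both sides to their common gene universe (see
#' [restrict_to_common_genes()]) and reports precision
#' `N_cp / N_p` plus two recalls: global recall divides the correct
#' predictions by all reference edges in the common universe, local
#' recall only by reference edges both of whose endpoints are genes of
#' the evaluated network. Edge labels are ignored; with no predicted
#' edges precision is undefined (`NA`), not 0.
#'
#' @param gin a `gin`.
#' @param reference a [reference_edges()] set.
#' @param restrict apply the common-universe (and TF) restriction first;
#'   set `FALSE` if already applied.
#' @return One-row tibble of class `gin_eval`: `n_predicted`,
#'   `n_correct`, `precision`, `global_recall`, `local_recall`,
#'   `n_reference_global`, `n_reference_local`.
#' @export
evaluate_gin <- function(gin, reference, restrict = TRUE) {
  if (restrict) {
    r <- restrict_to_common_genes(gin, reference)
    gin <- r$gin; reference <- r$reference
  }
  pred <- paste(gin$gene_a, gin$gene_b, sep = "\t")
  ref <- paste(reference$gene_a, reference$gene_b, sep = "\t")
  n_p <- length(pred)
  n_cp <- sum(pred %in% ref)
  net_genes <- union(gin$gene_a, gin$gene_b)
  local_ref <- reference$gene_a %in% net_genes & reference$gene_b %in% net_genes
  out <- tibble::tibble(
    n_predicted = n_p,
    n_correct = n_cp,
    precision = if (n_p == 0L) NA_real_ else n_cp / n_p,
    global_recall = if (length(ref)) n_cp / length(ref) else NA_real_,
    local_recall = if (sum(local_ref)) n_cp / sum(local_ref) else NA_real_,
    n_reference_global = length(ref),
    n_reference_local = sum(local_ref)
  )
  class(out) <- c("gin_eval", class(out))
  out
}
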