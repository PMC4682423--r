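#' Dataset descriptor
#'
#' @param name unique dataset name.
#' @param path path to the expression TSV.
#' @param n_cycles number of cell cycles the series covers (1..3).
#' @param time_interval informational sampling-interval label.
#' @return One-row tibble.
#' @export
dataset_descriptor <- function(name, path, n_cycles, time_interval = NA_character_) {
  stopifnot(n_cycles >= 1L)
  tibble::tibble(name = as.character(name), path = as.character(path),
                 n_cycles = as.integer(n_cycles),
                 time_interval = as.character(time_interval))
}

#' Run the full inference pipeline
#'
#' Executes, per input dataset: missing-value imputation, cell-cycle
#' splitting, discretization, closed-pattern mining, and per-dataset
#' GIN construction (with the time-lag allowance assigned per
#' single-cycle dataset by the lag rule, unless `config$i_t` overrides
#' it); then integrates all per-dataset GINs with per-polarity weights
#' and keeps edges conserved in at least `occ` of them.
#'
#' @param datasets either a descriptor table (columns `name`, `path`,
#'   `n_cycles`; see [dataset_descriptor()]) or a list of in-memory
#'   [expression_matrix()] objects.
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, discretized matrices,
#'   pattern JSON, per-dataset / integrative / reliable edge lists and
#'   a manifest JSON are written there.
#' @return A list of class `gin_pipeline`: `reliable` (a `gin`),
#'   `integrative` (an `integrative_gin`), `gins` (per single-cycle
#'   dataset), and `manifest` (config echo, per-dataset counts,
#'   timings).
#' @export
run_pipeline <- function(datasets, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  if (is.data.frame(datasets)) {
    stopifnot(all(c("name", "path", "n_cycles") %in% names(datasets)),
              !anyDuplicated(datasets$name))
    datasets <- lapply(seq_len(nrow(datasets)), function(i) {
      read_expression_tsv(datasets$path[i], n_cycles = datasets$n_cycles[i],
                          name = datasets$name[i])
    })
  }
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1L), "expression_matrix")))

  # impute + split first so the occ precondition can be validated
  cc <- list()
  for (d in datasets) {
    imputed <- impute_missing(d, config$max_missing)
    cc <- c(cc, split_cell_cycles(imputed))
  }
  if (config$occ > length(cc)) {
    stop(sprintf("occ (%d) exceeds the number of single-cycle datasets (%d)",
                 config$occ, length(cc)), call. = FALSE)
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  gins <- list()
  rows <- list()
  for (m in cc) {
    nt <- ncol(m$values)
    dmat <- discretize_matrix(m, config$delta_percentile)
    mc <- mining_config(sup = config$sup,
                        min_len = ceiling(config$len_fraction * nt),
                        max0_fraction = config$max0_fraction,
                        neg_match_mode = config$neg_match_mode)
    pats <- mine_closed_patterns(dmat, mc)
    i_t <- if (is.null(config$i_t)) {
      lag_allowance(nt, config$lag_rule_min_timepoints)
    } else config$i_t
    g <- build_gin(pats, i_t = i_t)
    gins[[m$name]] <- g
    rows[[m$name]] <- tibble::tibble(
      dataset = m$name, n_genes = nrow(dmat$items), n_timepoints = nt,
      min_len = mc$min_len, i_t = i_t,
      n_patterns = length(pats), n_edges = nrow(g))
    if (!is.null(out_dir)) {
      write_discretized_tsv(dmat, file.path(out_dir, paste0(m$name, "_items.tsv")))
      write_patterns_json(pats, file.path(out_dir, paste0(m$name, "_patterns.json")))
      write_edge_list_tsv(g, file.path(out_dir, paste0(m$name, "_edges.tsv")))
    }
  }

  ig <- integrate_gins(gins)
  reliable <- filter_reliable(ig, config$occ)
  manifest <- list(
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1L))],
    n_input_datasets = length(datasets),
    n_cc_datasets = length(cc),
    datasets = dplyr::bind_rows(rows),
    n_integrative_edges = nrow(ig),
    n_reliable_edges = nrow(reliable),
    n_reliable_genes = length(gin_nodes(reliable)),
    elapsed_sec = round(proc.time()[["elapsed"]] - t0, 3)
  )
  if (!is.null(out_dir)) {
    write_edge_list_tsv(ig, file.path(out_dir, "integrative_edges.tsv"))
    write_edge_list_tsv(reliable, file.path(out_dir, "reliable_edges.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  structure(list(reliable = reliable, integrative = ig, gins = gins,
                 manifest = manifest),
            class = "gin_pipeline")
}

#' @export
print.gin_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0(
    "<gin_pipeline> %d dataset(s) -> %d single-cycle dataset(s)\n",
    "  integrative edges: %d | reliable edges (occ=%d): %d over %d gene(s)\n"),
    m$n_input_datasets, m$n_cc_datasets, m$n_integrative_edges,
    m$config$occ, m$n_reliable_edges, m$n_reliable_genes))
  invisible(x)
}
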