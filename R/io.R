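#' Read a reference edge list from TSV
#'
#' Two or three tab-separated columns, no header. An optional third
#' column equal to `"TF"` flags the first gene of that line as a
#' transcription factor. Pairs are unordered and deduplicated;
#' self-pairs are dropped with a warning.
#'
#' @param path path to the edge-list TSV.
#' @return A [reference_edges()] set.
#' @export
read_edge_list_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(reference_edges(tibble::tibble(gene_a = character(),
                                          gene_b = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop(sprintf("edge list row %d has fewer than two columns",
                 which(lengths(fields) < 2L)[1L]), call. = FALSE)
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  flag <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "",
                 character(1L))
  tf <- unique(a[flag == "TF"])
  reference_edges(tibble::tibble(gene_a = a, gene_b = b),
                  tf_genes = if (length(tf)) tf else NULL)
}

#' Write a network's edges to TSV
#'
#' Plain GINs are written as `gene_a  gene_b  label`; integrative GINs
#' as `gene_a  gene_b  pos_weight  neg_weight`. No header, rows sorted
#' by endpoints, so identical networks serialize byte-identically.
#'
#' @param gin a `gin` or `integrative_gin`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list_tsv <- function(gin, path) {
  df <- as.data.frame(gin)
  df <- df[order(df$gene_a, df$gene_b, method = "radix"), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read mined patterns as JSON
#'
#' The JSON document records, per pattern, the pair-item sequence (as
#' lower items), the positive and negative match sets as lists of
#' (gene id, 0-based offset) records, and the source dataset name.
#'
#' @param patterns a `pattern_set`.
#' @param path file path.
#' @return `path` (write) or a `pattern_set` (read).
#' @export
write_patterns_json <- function(patterns, path) {
  stopifnot(inherits(patterns, "pattern_set"))
  doc <- list(
    source = patterns$source,
    patterns = lapply(patterns$patterns, function(pat) {
      list(pairs = pat$pairs,
           p = lapply(seq_len(nrow(pat$p)),
                      function(i) list(gene = pat$p$gene[i], offset = pat$p$offset[i])),
           n = lapply(seq_len(nrow(pat$n)),
                      function(i) list(gene = pat$n$gene[i], offset = pat$n$offset[i])))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patterns_json
#' @export
read_patterns_json <- function(path) {
  doc <- jsonlite::read_json(path)
  pats <- lapply(doc$patterns, function(rec) {
    side <- function(rows) {
      tibble::tibble(
        gene = vapply(rows, function(r) as.character(r$gene), ""),
        offset = vapply(rows, function(r) as.integer(r$offset), 0L))
    }
    subseq_pattern(unlist(rec$pairs), side(rec$p), side(rec$n))
  })
  new_pattern_set(pats, as.character(doc$source))
}

#' Run configuration
#'
#' Bundles the tunable parameters of the whole pipeline with their
#' defaults: `sup = 5` (minimum genes per pattern), `len_fraction =
#' 0.25` (minimum pattern length as a fraction of the time points,
#' applied with ceiling), `max0_fraction = 0.6` (insignificant
#' pair-item budget), `occ = 11` (conservation threshold),
#' `delta_percentile = 0.8` (per-gene scale rank), `neg_match_mode =
#' "strict"` (two-sided negative matching; the one-sided `"weak"` rule
#' is available but makes complete mining combinatorially expensive on
#' noisy data), `lag_rule_min_timepoints = 13` (series length from which a
#' 1-time-point delay is allowed), `i_t = NULL` (per-dataset lag
#' allowance from the rule; set an integer to override), and
#' `max_missing = 1` (missing values a gene may have).
#'
#' @param sup,len_fraction,max0_fraction,i_t,occ,delta_percentile,neg_match_mode,lag_rule_min_timepoints,max_missing
#'   see Description.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sup = 5L, len_fraction = 0.25, max0_fraction = 0.6,
                       i_t = NULL, occ = 11L, delta_percentile = 0.8,
                       neg_match_mode = c("strict", "weak"),
                       lag_rule_min_timepoints = 13L, max_missing = 1L) {
  neg_match_mode <- match.arg(neg_match_mode)
  stopifnot(sup >= 1L, len_fraction > 0, len_fraction <= 1,
            max0_fraction >= 0, max0_fraction <= 1, occ >= 1L,
            delta_percentile > 0, delta_percentile <= 1,
            lag_rule_min_timepoints >= 1L, max_missing >= 0L,
            is.null(i_t) || i_t >= 0L)
  structure(list(sup = as.integer(sup), len_fraction = len_fraction,
                 max0_fraction = max0_fraction,
                 i_t = if (is.null(i_t)) NULL else as.integer(i_t),
                 occ = as.integer(occ), delta_percentile = delta_percentile,
                 neg_match_mode = neg_match_mode,
                 lag_rule_min_timepoints = as.integer(lag_rule_min_timepoints),
                 max_missing = as.integer(max_missing)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file mirroring the [run_config()] fields; absent
#'   fields take their defaults.
#' @param config a `run_config`.
#' @return A `run_config` (read) or `path` (write).
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "neg_match_mode")
  bad <- setdiff(names(vals), c(known, "neg_match_mode"))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- unclass(config)
  yaml::write_yaml(vals[!vapply(vals, is.null, logical(1L))], path)
  invisible(path)
}
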