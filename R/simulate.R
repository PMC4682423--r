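#' Specification for synthetic multi-replicate time-course data
#'
#' Describes planted co-expression structure modelled on cell-cycle
#' expression programs: `n_modules` gene modules, each following a
#' smooth activation pulse (a raised-Gaussian template spanning roughly
#' plus/minus 2.5 in expression units) over a `window_len`-point
#' sub-window. Module windows are stratified across the time axis —
#' modules peak in different phases, as pathway programs do — which is
#' what makes the planted ground truth identifiable: away from its
#' pulse a gene shows only noise, so genes of different modules never
#' share the significant (non-zero-level) positions a pattern must
#' anchor on. A module member is the template or its negation (with
#' probability `frac_negative`), shifted by a per-gene lag drawn
#' uniformly from `0..max_lag`, plus Gaussian noise of standard
#' deviation `noise_sd` (expression units). Background genes are pure
#' noise. All replicates share the module structure (template, signs,
#' lags) and differ only in noise.
#'
#' @param n_modules,genes_per_module,n_background,n_timepoints,n_replicates
#'   counts; defaults 3, 6, 30, 12, 12.
#' @param frac_negative probability a member is the negated template.
#' @param max_lag maximum per-gene time-point lag.
#' @param noise_sd Gaussian noise sd.
#' @param window_len pulse width in time points (odd values center
#'   nicely).
#' @param seed RNG seed making generation deterministic.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_modules = 3L, genes_per_module = 6L,
                           n_background = 30L, n_timepoints = 12L,
                           n_replicates = 12L, frac_negative = 0.3,
                           max_lag = 1L, noise_sd = 0.15,
                           window_len = 5L, seed = 1L) {
  stopifnot(n_modules >= 1L, genes_per_module >= 2L, n_background >= 0L,
            n_timepoints >= 2L, n_replicates >= 1L,
            frac_negative >= 0, frac_negative <= 1,
            max_lag >= 0L, noise_sd >= 0,
            window_len >= 2L, window_len + max_lag <= n_timepoints)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate synthetic time-course data with planted modules
#'
#' @param spec a [synthetic_spec()].
#' @return List with `matrices` (one [expression_matrix()] per
#'   replicate, named `rep01..`), `truth` (a [reference_edges()] set of
#'   all within-module pairs; the same pairs with their expected
#'   polarity are in `truth_polarity`), and `modules` (tibble `gene`,
#'   `module`, `sign`, `lag`, `window_start`).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  nt <- spec$n_timepoints
  w <- spec$window_len
  gene_ids <- c(
    sprintf("M%02dG%02d", rep(seq_len(spec$n_modules), each = spec$genes_per_module),
            rep(seq_len(spec$genes_per_module), spec$n_modules)),
    sprintf("BG%03d", seq_len(spec$n_background)))

  # stratified window starts: one module per phase of the series; pulses
  # of different modules need >= max_lag + 2 points of separation for
  # the planted truth to stay identifiable under the match tolerance
  last_start <- nt - w + 1L - spec$max_lag
  starts <- round(seq(1L, last_start, length.out = spec$n_modules))
  if (spec$n_modules > 1L && min(diff(starts)) < spec$max_lag + 2L) {
    warning("module windows are too close for the time axis; ",
            "cross-module coincidences may blur the planted truth",
            call. = FALSE)
  }

  # smooth activation pulse; heavier-tailed than its 80th-percentile
  # magnitude so the discretized items rise well above the zero band
  x <- seq_len(w)
  shape <- exp(-(((x - (w + 1) / 2)) / (w / 4))^2)

  modules <- lapply(seq_len(spec$n_modules), function(m) {
    amp <- runif(1L, 2.2, 2.6) * sample(c(-1, 1), 1L)
    list(start = starts[m],
         template = amp * shape,
         signs = ifelse(runif(spec$genes_per_module) < spec$frac_negative, -1, 1),
         lags = sample.int(spec$max_lag + 1L, spec$genes_per_module,
                           replace = TRUE) - 1L)
  })

  make_replicate <- function(r) {
    vals <- matrix(rnorm(length(gene_ids) * nt, sd = spec$noise_sd),
                   nrow = length(gene_ids), dimnames = list(gene_ids, NULL))
    row <- 0L
    for (m in seq_len(spec$n_modules)) {
      mod <- modules[[m]]
      for (g in seq_len(spec$genes_per_module)) {
        row <- row + 1L
        cols <- (mod$start + mod$lags[g]):(mod$start + mod$lags[g] + w - 1L)
        vals[row, cols] <- vals[row, cols] + mod$signs[g] * mod$template
      }
    }
    expression_matrix(vals, n_cycles = 1L, name = sprintf("rep%02d", r))
  }
  matrices <- lapply(seq_len(spec$n_replicates), make_replicate)
  names(matrices) <- vapply(matrices, `[[`, "", "name")

  module_tbl <- tibble::tibble(
    gene = gene_ids[seq_len(spec$n_modules * spec$genes_per_module)],
    module = rep(seq_len(spec$n_modules), each = spec$genes_per_module),
    sign = unlist(lapply(modules, `[[`, "signs")),
    lag = unlist(lapply(modules, `[[`, "lags")),
    window_start = rep(starts, each = spec$genes_per_module))

  truth_rows <- module_tbl |>
    dplyr::group_by(.data$module) |>
    dplyr::group_map(function(d, key) {
      idx <- utils::combn(nrow(d), 2L)
      tibble::tibble(
        gene_a = d$gene[idx[1L, ]], gene_b = d$gene[idx[2L, ]],
        polarity = ifelse(d$sign[idx[1L, ]] == d$sign[idx[2L, ]],
                          "positive", "negative"))
    }) |>
    dplyr::bind_rows()

  list(matrices = matrices,
       truth = reference_edges(truth_rows[, c("gene_a", "gene_b")]),
       truth_polarity = order_endpoints(truth_rows),
       modules = module_tbl,
       spec = spec)
}

#' Write synthetic data to a directory
#'
#' One expression TSV per replicate plus `truth.tsv` (planted edges
#' with polarity) and `modules.tsv`.
#'
#' @param sim result of [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in sim$matrices) {
    write_expression_tsv(m, file.path(dir, paste0(m$name, ".tsv")))
  }
  write.table(as.data.frame(sim$truth_polarity), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(as.data.frame(sim$modules), file.path(dir, "modules.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
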