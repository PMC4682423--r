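#' Exhaustive brute-force pattern mining oracle
#'
#' Independent reference implementation used to verify
#' [mine_closed_patterns()] on small inputs. For every gene window and
#' both polarities it enumerates the full product set of pair-items
#' consistent with each window position — an exhaustive enumeration of
#' every pattern that can attain support of at least one gene, with the
#' matching windows recorded alongside — then keeps candidates matched
#' by at least `sup` distinct genes, within the insignificant-fraction
#' bound, and closed; candidates with identical reported match sets are
#' collapsed to the shortest, then lexicographically smallest, pair
#' sequence, exactly as the miner defines its output.
#'
#' @param dmat a `discretized_matrix` (intended for desk scale, say up
#'   to ~10 time points).
#' @param config a [mining_config()].
#' @param max_candidates refuse (with a size estimate) if the expansion
#'   would exceed this many candidate windows.
#' @return A `pattern_set`, set-equal to [mine_closed_patterns()] by
#'   construction requirement.
#' @export
brute_force_mine <- function(dmat, config = mining_config(),
                             max_candidates = 2e7) {
  stopifnot(inherits(dmat, "discretized_matrix"), inherits(config, "mining_config"))
  S <- dmat$items
  nt <- ncol(S)
  nv <- nrow(S)
  if (config$min_len > nt) {
    stop(sprintf("min_len (%d) exceeds the number of time points (%d)",
                 config$min_len, nt), call. = FALSE)
  }
  weak <- config$neg_match_mode == "weak"
  chars <- letters[1:6]  # lo = -3..2 -> a..f

  # candidate lo-sets per item: positive is {e-1, e}; negative-weak is
  # [-e-2, -e+1]; negative-strict is {-e-1, -e}; all clipped to -3..2
  pos_sets <- lapply(-3:3, function(e) intersect(c(e - 1L, e), -3:2))
  neg_sets <- if (weak) {
    lapply(-3:3, function(e) intersect(seq(-e - 2L, -e + 1L), -3:2))
  } else {
    lapply(-3:3, function(e) intersect(c(-e - 1L, -e), -3:2))
  }

  # guard on total expansion volume before doing the work
  total <- 0
  for (g in seq_len(nv)) {
    for (l in config$min_len:nt) {
      for (o in 0:(nt - l)) {
        items <- S[g, (o + 1):(o + l)] + 4L
        total <- total + prod(lengths(pos_sets[items])) +
          prod(lengths(neg_sets[items]))
      }
    }
  }
  if (total > max_candidates) {
    stop(sprintf("brute force would expand ~%.3g candidate sequences (cap %g)",
                 total, max_candidates), call. = FALSE)
  }

  expand_window <- function(sets) {
    v <- ""
    for (s in sets) {
      if (!length(s)) return(character(0))
      v <- paste0(rep(v, each = length(s)), chars[s + 4L])
    }
    v
  }

  # expansion records: candidate string + the (gene, offset, polarity)
  # window it came from; these ARE the match sets, assembled per
  # candidate below
  rec_cand <- vector("list", 0L)
  rec_meta <- vector("list", 0L)
  for (g in seq_len(nv)) {
    for (l in config$min_len:nt) {
      for (o in 0:(nt - l)) {
        items <- S[g, (o + 1):(o + l)] + 4L
        wp <- expand_window(pos_sets[items])
        wn <- expand_window(neg_sets[items])
        k <- length(rec_cand)
        if (length(wp)) {
          rec_cand[[k + 1L]] <- wp
          rec_meta[[k + 1L]] <- c(g, o, 1L, length(wp))
          k <- k + 1L
        }
        if (length(wn)) {
          rec_cand[[k + 1L]] <- wn
          rec_meta[[k + 1L]] <- c(g, o, 0L, length(wn))
        }
      }
    }
  }
  if (!length(rec_cand)) return(new_pattern_set(list(), dmat$name))
  cand <- unlist(rec_cand, use.names = FALSE)
  meta <- do.call(rbind, rec_meta)
  gene <- rep(meta[, 1L], meta[, 4L])
  off <- rep(meta[, 2L], meta[, 4L])
  pol <- rep(meta[, 3L], meta[, 4L])

  # frequent pre-filter: distinct matched genes per candidate
  keep <- !duplicated(paste(cand, gene))
  f <- factor(cand[keep])
  counts <- tabulate(f, nbins = nlevels(f))
  frequent <- levels(f)[counts >= config$sup]

  # insignificant-fraction bound on the pattern itself (-1::0 is 'c',
  # 0::1 is 'd')
  n0 <- vapply(strsplit(frequent, "", fixed = TRUE),
               function(ch) sum(ch %in% c("c", "d")), integer(1L))
  frequent <- frequent[n0 <= config$max0_fraction * nchar(frequent) + 1e-9]
  if (!length(frequent)) return(new_pattern_set(list(), dmat$name))

  sel <- cand %in% frequent
  cand <- cand[sel]; gene <- gene[sel]; off <- off[sel]; pol <- pol[sel]
  by_cand <- split(seq_along(cand), cand)

  decode <- function(key) match(strsplit(key, "", fixed = TRUE)[[1L]], chars) - 4L

  # closedness from the candidate's own match windows: an extension
  # filters each window through the single boundary item, so extended
  # match sets are subsets and set equality reduces to count equality
  closed_from_sets <- function(l, Pg, Po, Ng, No) {
    p_cnt <- length(Pg)
    pos_genes <- unique(Pg)
    n_cnt <- sum(!(Ng %in% pos_genes))
    if (l >= nt) return(TRUE)
    for (e in -3:2) {
      for (left in c(FALSE, TRUE)) {
        if (left) {
          kp <- Po >= 1L
          kp[kp] <- S[cbind(Pg[kp], Po[kp])] %in% c(e, e + 1L)
          kn <- No >= 1L
          en <- S[cbind(Ng[kn], No[kn])]
          kn[kn] <- if (weak) abs(en + e) <= 1L | abs(en + e + 1L) <= 1L
                    else abs(en + e) <= 1L & abs(en + e + 1L) <= 1L
        } else {
          kp <- Po + l < nt
          kp[kp] <- S[cbind(Pg[kp], Po[kp] + l + 1L)] %in% c(e, e + 1L)
          kn <- No + l < nt
          en <- S[cbind(Ng[kn], No[kn] + l + 1L)]
          kn[kn] <- if (weak) abs(en + e) <= 1L | abs(en + e + 1L) <= 1L
                    else abs(en + e) <= 1L & abs(en + e + 1L) <= 1L
        }
        if (sum(kp) == p_cnt &&
            sum(!(Ng[kn] %in% unique(Pg[kp]))) == n_cnt) {
          return(FALSE)
        }
      }
    }
    TRUE
  }

  # one group per (reported match sets, length); closedness and the
  # canonical representative are group properties
  groups <- new.env(parent = emptyenv())
  genes_chr <- dmat$gene_ids
  for (key in names(by_cand)) {
    idx <- by_cand[[key]]
    is_p <- pol[idx] == 1L
    pd <- !duplicated(paste(gene[idx][is_p], off[idx][is_p]))
    Pg <- gene[idx][is_p][pd]; Po <- off[idx][is_p][pd]
    nd <- !duplicated(paste(gene[idx][!is_p], off[idx][!is_p]))
    Ng <- gene[idx][!is_p][nd]; No <- off[idx][!is_p][nd]
    rep_n <- !(Ng %in% unique(Pg))
    gkey <- paste(
      nchar(key),
      paste(sort(paste(Pg, Po)), collapse = ";"),
      paste(sort(paste(Ng[rep_n], No[rep_n])), collapse = ";"), sep = "|")
    lov <- decode(key)
    prev <- get0(gkey, envir = groups)
    if (is.null(prev)) {
      assign(gkey, list(lov = lov, Pg = Pg, Po = Po, Ng = Ng, No = No),
             envir = groups)
    } else if (pattern_sort_key(lov) < pattern_sort_key(prev$lov)) {
      prev$lov <- lov
      assign(gkey, prev, envir = groups)
    }
  }

  pats <- list()
  for (gkey in ls(groups)) {
    g <- get(gkey, envir = groups)
    if (!closed_from_sets(length(g$lov), g$Pg, g$Po, g$Ng, g$No)) next
    rep_n <- !(g$Ng %in% unique(g$Pg))
    pats[[length(pats) + 1L]] <- subseq_pattern(
      g$lov,
      p = tibble::tibble(gene = genes_chr[g$Pg], offset = g$Po),
      n = tibble::tibble(gene = genes_chr[g$Ng[rep_n]], offset = g$No[rep_n]))
  }
  pats <- pats[order(vapply(pats, function(p) pattern_sort_key(p$pairs),
                            character(1L)))]
  new_pattern_set(pats, dmat$name)
}
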