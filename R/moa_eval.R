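#' Rank reference treatments by similarity to a query treatment
#'
#' Candidates are all active treatments except every treatment of the
#' query's own compound (all its concentrations are excluded). Candidates
#' are sorted by the Pearson correlation between their imaging signature
#' and the query's, descending, and collapsed to one entry per compound by
#' keeping its highest-ranked (best-correlated) concentration. Candidates
#' with a degenerate (zero-variance) signature are excluded with a warning.
#' Correlation ties are broken by compound id for determinism.
#'
#' @param query_id Treatment id of the query (must be active).
#' @param activity An `activity_calls` object from [call_active()].
#' @return Tibble with `compound_id`, `treatment_id` (the kept
#'   concentration) and `r`, sorted by decreasing correlation.
#' @export
rank_neighbors <- function(query_id, activity) {
  calls <- activity$calls
  if (!query_id %in% calls$treatment_id[calls$active]) {
    abort(paste0("moa error: query ", query_id, " is not an active treatment"))
  }
  query_cmp <- calls$compound_id[match(query_id, calls$treatment_id)]
  active <- calls[calls$active & calls$compound_id != query_cmp, , drop = FALSE]
  sig <- activity$signatures
  q <- sig[query_id, ]
  cand <- sig[active$treatment_id, , drop = FALSE]
  r <- suppressWarnings(as.vector(cor(t(cand), q)))
  bad <- !is.finite(r)
  if (any(bad)) {
    warn(paste0(sum(bad), " candidate treatment(s) with degenerate signature excluded"))
  }
  out <- tibble::tibble(
    compound_id = active$compound_id[!bad],
    treatment_id = active$treatment_id[!bad],
    r = r[!bad]
  )
  out <- out[order(-out$r, out$compound_id), ]
  out[!duplicated(out$compound_id), ]
}

#' AUC-ROC of a ranked candidate list against MoA membership
#'
#' Rank-based (Mann-Whitney) AUC of the correlation scores for member
#' versus non-member candidates; tied correlations receive midrank credit.
#'
#' @param correlations Numeric similarity scores of the ranked candidates.
#' @param is_member Logical membership flags, same length.
#' @return The AUC-ROC, or `NA` when either class is empty.
#' @export
query_auc <- function(correlations, is_member) {
  .rank_auc(correlations[is_member], correlations[!is_member])
}

# precompute, per active treatment, the collapsed candidate list
# (compound ids + correlation midranks); everything the permutation loop
# needs, independent of MoA membership
.query_rankings <- function(activity) {
  calls <- activity$calls[activity$calls$active, , drop = FALSE]
  if (nrow(calls) == 0L) return(list())
  sig <- activity$signatures[calls$treatment_id, , drop = FALSE]
  cc <- suppressWarnings(cor(t(sig)))
  out <- vector("list", nrow(calls))
  names(out) <- calls$treatment_id
  for (i in seq_len(nrow(calls))) {
    keep <- calls$compound_id != calls$compound_id[i] & is.finite(cc[i, ])
    cand <- tibble::tibble(
      compound_id = calls$compound_id[keep],
      r = cc[i, keep]
    )
    cand <- cand[order(-cand$r, cand$compound_id), ]
    cand <- cand[!duplicated(cand$compound_id), ]
    out[[i]] <- list(
      compound_id = cand$compound_id,
      midrank = rank(cand$r)
    )
  }
  out
}

# aggregated AUC for one MoA given a member-compound set and the
# precomputed query rankings: per-compound max over its query AUCs,
# then the median across member compounds
.moa_aggregate <- function(members, query_compound, rankings) {
  qi <- which(query_compound %in% members)
  if (length(qi) == 0L) return(NA_real_)
  aucs <- vapply(qi, function(i) {
    rk <- rankings[[i]]
    pos <- rk$compound_id %in% members
    n1 <- sum(pos)
    n0 <- length(pos) - n1
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    (sum(rk$midrank[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  per_cmp <- tapply(aucs, query_compound[qi], max, na.rm = TRUE)
  per_cmp <- per_cmp[is.finite(per_cmp)]
  if (length(per_cmp) == 0L) return(NA_real_)
  stats::median(per_cmp)
}

#' Aggregated AUC-ROC per mechanism of action
#'
#' For every MoA with at least `min_compounds` active compounds, each
#' active treatment of a member compound is used once as a query against
#' the collapsed candidate ranking of [rank_neighbors()]; per compound the
#' maximum AUC over its concentrations is taken (so a compound similar to
#' its MoA at only one concentration is not penalized), and the MoA
#' aggregate is the median of the per-compound maxima. Multi-MoA compounds
#' are evaluated independently for each of their MoAs.
#'
#' @param activity An `activity_calls` object.
#' @param annotations Tibble with `compound_id` and `moa`.
#' @param cell_line Cell line label for the result rows.
#' @param min_compounds Minimum active member compounds (default 3).
#' @return Tibble `moa`, `cell_line`, `n_compounds`, `auc`,
#'   `distinguishable` (`auc >= 0.9`).
#' @export
moa_auc <- function(activity, annotations, cell_line = "CL1", min_compounds = 3) {
  rankings <- .query_rankings(activity)
  calls <- activity$calls[activity$calls$active, , drop = FALSE]
  query_compound <- calls$compound_id
  active_cmp <- unique(query_compound)
  ann <- annotations[annotations$compound_id %in% active_cmp, , drop = FALSE]
  counts <- table(ann$moa)
  tested <- names(counts)[counts >= min_compounds]
  rows <- lapply(tested, function(m) {
    members <- ann$compound_id[ann$moa == m]
    tibble::tibble(
      moa = m,
      cell_line = cell_line,
      n_compounds = length(members),
      auc = .moa_aggregate(members, query_compound, rankings)
    )
  })
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    tibble::tibble(moa = character(), cell_line = character(),
                   n_compounds = integer(), auc = numeric())
  }
  out$distinguishable <- !is.na(out$auc) & out$auc >= 0.9
  out
}

#' Permutation significance and FDR for MoA AUC-ROC values
#'
#' Each iteration permutes the compound-to-annotation-set mapping among the
#' active compounds of a cell line: annotation sets move as units, so the
#' multi-MoA structure and the MoA size spectrum are preserved. The
#' aggregated AUC of every tested MoA is recomputed under each permutation;
#' the empirical p-value is `(1 + #[null >= observed]) / (1 + n_perm)`, and
#' p-values are Benjamini-Hochberg adjusted jointly across all tested
#' (MoA, cell line) pairs.
#'
#' @param results Result tibble from [moa_auc()] (possibly several cell
#'   lines row-bound).
#' @param activity An `activity_calls` object, or a named list of them by
#'   cell line when `results` spans several.
#' @param annotations Tibble with `compound_id` and `moa`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutations.
#' @param alpha FDR level used for the significance flag (default 0.05).
#' @param min_compounds As in [moa_auc()].
#' @return `results` with `p_value`, `p_adj`, `significant` and the
#'   per-iteration null mean attached as attribute `"null_mean_auc"`.
#' @export
permutation_significance <- function(results, activity, annotations,
                                     n_perm = 10000, seed = 1, alpha = 0.05,
                                     min_compounds = 3) {
  if (n_perm < 100) warn("n_perm < 100: permutation p-values will be unstable")
  act_list <- if (inherits(activity, "activity_calls")) {
    stats::setNames(list(activity), unique(results$cell_line)[1] %||% "CL1")
  } else activity

  set.seed(seed)
  results$p_value <- NA_real_
  null_means <- c()
  for (cl in unique(results$cell_line)) {
    act <- act_list[[cl]]
    if (is.null(act)) abort(paste0("moa error: no activity object for cell line ", cl))
    rankings <- .query_rankings(act)
    calls <- act$calls[act$calls$active, , drop = FALSE]
    query_compound <- calls$compound_id
    active_cmp <- sort(unique(query_compound))
    ann <- annotations[annotations$compound_id %in% active_cmp, , drop = FALSE]
    sets <- split(ann$moa, factor(ann$compound_id, levels = active_cmp))

    rows <- which(results$cell_line == cl)
    moas <- results$moa[rows]
    exceed <- stats::setNames(numeric(length(moas)), moas)
    obs <- stats::setNames(results$auc[rows], moas)
    null_sum <- 0
    null_n <- 0
    for (it in seq_len(n_perm)) {
      perm_sets <- sets[sample.int(length(sets))]
      names(perm_sets) <- active_cmp
      perm_members <- split(
        rep(names(perm_sets), lengths(perm_sets)),
        unlist(perm_sets, use.names = FALSE)
      )
      for (m in moas) {
        members <- perm_members[[m]]
        if (is.null(members) || length(members) < min_compounds) next
        a <- .moa_aggregate(members, query_compound, rankings)
        if (!is.na(a)) {
          null_sum <- null_sum + a
          null_n <- null_n + 1
          if (!is.na(obs[m]) && a >= obs[m]) exceed[m] <- exceed[m] + 1
        }
      }
    }
    results$p_value[rows] <- (1 + exceed) / (1 + n_perm)
    null_means <- c(null_means, stats::setNames(null_sum / max(null_n, 1), cl))
  }
  results$p_adj <- p.adjust(results$p_value, method = "BH")
  results$significant <- results$p_adj < alpha
  attr(results, "null_mean_auc") <- null_means
  results
}

#' Greedy cell-line ranking by added distinguishable MoAs
#'
#' Greedy set cover over cell lines: at each step the cell line adding the
#' most not-yet-covered MoAs with AUC at or above `cutoff` is picked (ties
#' broken by cell line id), yielding the cumulative coverage curve.
#'
#' @param results Combined [moa_auc()] results across cell lines.
#' @param cutoff Distinguishability cutoff (default 0.9).
#' @return Tibble `rank`, `cell_line`, `n_added`, `cumulative`.
#' @export
greedy_cell_line_ranking <- function(results, cutoff = 0.9) {
  ok <- !is.na(results$auc) & results$auc >= cutoff
  sets <- split(results$moa[ok], results$cell_line[ok])
  lines <- sort(unique(results$cell_line))
  sets <- lapply(stats::setNames(lines, lines), function(cl) unique(sets[[cl]]))
  covered <- character(0)
  rows <- vector("list", length(lines))
  remaining <- lines
  for (i in seq_along(lines)) {
    gains <- vapply(remaining, function(cl) {
      length(setdiff(sets[[cl]] %||% character(0), covered))
    }, integer(1))
    pick <- remaining[order(-gains, remaining)][1]
    covered <- union(covered, sets[[pick]] %||% character(0))
    rows[[i]] <- tibble::tibble(
      rank = i, cell_line = pick,
      n_added = gains[[pick]], cumulative = length(covered)
    )
    remaining <- setdiff(remaining, pick)
  }
  do.call(rbind, rows)
}
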