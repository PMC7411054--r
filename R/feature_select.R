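#' Prefilter wells before feature selection
#'
#' Three steps precede the mRMR ranking: (1) wells highly similar to the
#' DMSO controls are removed, using the Euclidean distance between each
#' well's descriptor profile and the mean control profile with a cut-off at
#' the 95th percentile of the null distribution formed by the individual
#' control wells' distances to that mean (wells below the cut-off are
#' dropped); (2) wells with fewer than `min_cells` live cells are removed;
#' (3) each descriptor is winsorized at its 1st and 99th percentiles over
#' the remaining wells, so outliers are clipped without changing the
#' treatment class sizes the F-statistic sees.
#'
#' @param profiles Normalized well profiles.
#' @param min_cells Minimum live-cell count (default 100).
#' @param trim Winsorization tail fraction per side (default 0.01).
#' @return The filtered, winsorized profiles.
#' @export
prefilter_wells <- function(profiles, min_cells = 100, trim = 0.01) {
  desc <- descriptor_names(profiles)
  x <- .descriptor_matrix(profiles, desc)
  ctrl <- profiles$is_control
  if (sum(ctrl) < 2L) abort("prefilter error: need >= 2 control wells")

  mu <- colMeans(x[ctrl, , drop = FALSE], na.rm = TRUE)
  d <- sqrt(rowSums(sweep(x, 2, mu, `-`)^2))
  cutoff <- .quantile(d[ctrl], 0.95)

  keep <- !is.na(d) & d >= cutoff & profiles$n_live >= min_cells
  if (!any(keep)) {
    abort(paste0("empty-selection error: all wells removed by the prefilter ",
                 "(distance cut-off ", signif(cutoff, 4), ", min cells ",
                 min_cells, ")"))
  }
  out <- profiles[keep, , drop = FALSE]

  y <- .descriptor_matrix(out, desc)
  lo <- apply(y, 2, .quantile, p = trim)
  hi <- apply(y, 2, .quantile, p = 1 - trim)
  y <- pmin(pmax(y, matrix(lo, nrow(y), ncol(y), byrow = TRUE)),
            matrix(hi, nrow(y), ncol(y), byrow = TRUE))
  out[, desc] <- tibble::as_tibble(y)
  out
}

#' Relevance of each descriptor for discriminating treatments
#'
#' One-way ANOVA F-statistic per descriptor with the treatment identifier
#' (compound x concentration; `"DMSO"` for surviving controls) as the
#' grouping factor, scaled by the maximum F across descriptors so values
#' lie in (0, 1]. All-constant descriptors get relevance 0.
#'
#' @param profiles Prefiltered, normalized well profiles.
#' @param groups Optional grouping vector overriding `treatment_id`.
#' @return Named numeric vector of relevances in `[0, 1]`.
#' @export
compute_relevance <- function(profiles, groups = NULL) {
  desc <- descriptor_names(profiles)
  x <- .descriptor_matrix(profiles, desc)
  g <- factor(groups %||% profiles$treatment_id)
  if (nlevels(droplevels(g)) < 2L) {
    abort("relevance error: need >= 2 treatment groups")
  }
  f <- .anova_f(x, droplevels(g))
  mx <- max(f[is.finite(f)], 0)
  f[!is.finite(f)] <- mx
  if (mx == 0) return(stats::setNames(rep(0, length(f)), desc))
  stats::setNames(f / max(f), desc)
}

# vectorized one-way ANOVA F over the columns of x, NA-aware
.anova_f <- function(x, g) {
  obs <- !is.na(x)
  x0 <- ifelse(obs, x, 0)
  n_g <- rowsum(obs + 0, g)            # groups x features: per-group n
  s_g <- rowsum(x0, g)                 # per-group sums
  n <- colSums(n_g)
  grand <- colSums(s_g) / n
  m_g <- s_g / n_g                     # per-group means (NaN if empty)
  m_g[n_g == 0] <- 0
  ssb <- colSums(n_g * sweep(m_g, 2, grand, `-`)^2)
  sst <- colSums(x0^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  k <- colSums(n_g > 0)
  df1 <- pmax(k - 1, 1)
  df2 <- pmax(n - k, 1)
  f <- (ssb / df1) / (ssw / df2)
  f[ssb == 0] <- 0                     # constant feature: F = 0 by convention
  f
}

#' Rank descriptors by the modified mRMR rule
#'
#' Greedy minimum-redundancy maximum-relevance ranking: the first feature is
#' the most relevant; at every subsequent step the redundancy of each
#' candidate is the maximum absolute Pearson correlation between the
#' candidate and any already-selected feature, and the candidate maximizing
#' the trade-off score `relevance x (1 - redundancy)` is selected. Ties are
#' broken deterministically toward the lower feature index. The full ranking
#' of all candidates is returned.
#'
#' @param profiles Prefiltered, normalized well profiles.
#' @param relevance Named relevance vector from [compute_relevance()].
#' @return A `feature_ranking` object: tibble with `step`, `feature`,
#'   `relevance`, `redundancy` and `score` at the step of selection.
#' @export
mrmr_rank <- function(profiles, relevance) {
  feats <- names(relevance)
  x <- .descriptor_matrix(profiles, feats)
  cc <- abs(cor(x, use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0

  p <- length(feats)
  selected <- integer(p)
  red_at <- numeric(p)
  score_at <- numeric(p)
  red <- rep(0, p)
  taken <- rep(FALSE, p)
  for (step in seq_len(p)) {
    if (step > 1L) red <- pmax(red, cc[, selected[step - 1L]])
    score <- relevance * (1 - red)
    score[taken] <- -Inf
    pick <- which.max(score)           # which.max takes the lowest index on ties
    selected[step] <- pick
    red_at[step] <- if (step == 1L) 0 else red[pick]
    score_at[step] <- if (step == 1L) relevance[pick] else score[pick]
    taken[pick] <- TRUE
  }
  out <- tibble::tibble(
    step = seq_len(p),
    feature = feats[selected],
    relevance = unname(relevance[selected]),
    redundancy = red_at,
    score = unname(score_at)
  )
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Replicate-discrimination AUC of a feature subset
#'
#' Measures how well Pearson correlation over the given feature subset
#' separates pairs of replicate wells (same compound and concentration)
#' from pairs of non-replicate wells (different compound or different
#' concentration). Per repeat, up to `max_pairs` replicate and `max_pairs`
#' non-replicate pairs are sampled without replacement; the AUC is the
#' rank-based probability that a replicate pair's correlation outranks a
#' non-replicate pair's (ties at 0.5). Control wells are excluded.
#'
#' @param profiles Prefiltered, normalized well profiles.
#' @param features Character vector of descriptor names (>= 2).
#' @param max_pairs Pair cap per class per repeat (default 10000).
#' @param repeats Number of sampling repeats (default 10).
#' @param seed Seed for the pair sampling.
#' @return List with `mean`, `sd` and the per-repeat `aucs`.
#' @export
replicate_auc <- function(profiles, features, max_pairs = 10000, repeats = 10,
                          seed = 1) {
  if (length(features) < 2L) {
    abort("replicate_auc error: need >= 2 features for Pearson correlation")
  }
  wells <- profiles[!profiles$is_control, , drop = FALSE]
  x <- .descriptor_matrix(wells, features)
  g <- wells$treatment_id
  rep_pairs <- .replicate_pairs(g)
  if (nrow(rep_pairs) == 0L) {
    abort("replicate_auc error: no treatment has >= 2 replicate wells")
  }
  set.seed(seed)
  aucs <- vapply(seq_len(repeats), function(r) {
    rp <- .sample_rows(rep_pairs, max_pairs)
    np <- .sample_nonreplicate_pairs(g, max_pairs)
    pos <- .pair_cor(x, rp[, 1], rp[, 2])
    neg <- .pair_cor(x, np[, 1], np[, 2])
    .rank_auc(pos[is.finite(pos)], neg[is.finite(neg)])
  }, numeric(1))
  list(mean = mean(aucs), sd = sd(aucs), aucs = aucs)
}

.replicate_pairs <- function(g) {
  idx <- split(seq_along(g), g)
  pairs <- lapply(idx, function(i) {
    if (length(i) < 2L) return(NULL)
    t(utils::combn(i, 2L))
  })
  out <- do.call(rbind, pairs)
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

.sample_rows <- function(m, cap) {
  if (nrow(m) <= cap) return(m)
  m[sample.int(nrow(m), cap), , drop = FALSE]
}

# uniform sample of well pairs with different treatment ids
.sample_nonreplicate_pairs <- function(g, cap) {
  n <- length(g)
  total <- n * (n - 1) / 2
  if (total <= cap * 1.5) {
    all_pairs <- t(utils::combn(n, 2L))
    keep <- g[all_pairs[, 1]] != g[all_pairs[, 2]]
    return(.sample_rows(all_pairs[keep, , drop = FALSE], cap))
  }
  got <- matrix(integer(0), ncol = 2)
  while (nrow(got) < cap) {
    a <- sample.int(n, cap, replace = TRUE)
    b <- sample.int(n, cap, replace = TRUE)
    ok <- a != b & g[a] != g[b]
    cand <- cbind(pmin(a[ok], b[ok]), pmax(a[ok], b[ok]))
    got <- unique(rbind(got, cand))
  }
  got[seq_len(cap), , drop = FALSE]
}

#' Choose the signature size by the one-SD stopping rule
#'
#' Given a replicate-AUC curve over candidate sizes, returns the minimal
#' size whose mean AUC is at least the maximum mean AUC minus the SD
#' observed at the size achieving that maximum.
#'
#' @param curve Data frame with columns `size`, `mean_auc`, `sd_auc`.
#' @return The chosen size `k`.
#' @export
choose_signature_size <- function(curve) {
  stopifnot(all(c("size", "mean_auc", "sd_auc") %in% names(curve)))
  i_max <- which.max(curve$mean_auc)
  threshold <- curve$mean_auc[i_max] - curve$sd_auc[i_max]
  min(curve$size[curve$mean_auc >= threshold])
}

#' Select the imaging signature from a feature ranking
#'
#' Evaluates the replicate-discrimination AUC at increasing prefix sizes of
#' the mRMR ranking (every size up to 30, then a strided grid) and applies
#' the one-SD rule of [choose_signature_size()]. Pair samples are drawn once
#' per repeat and reused across sizes, so the curve is internally
#' consistent; correlations over prefixes are computed incrementally.
#'
#' @param ranking A `feature_ranking` from [mrmr_rank()].
#' @param profiles The prefiltered profiles the ranking was computed on.
#' @param sizes Candidate sizes (default: 2..30, then strided up to 250).
#' @param max_pairs,repeats,seed As in [replicate_auc()].
#' @param cell_line Label stored in the resulting signature.
#' @return A `signature_spec` list: `cell_line`, ordered `features`
#'   (length `k`), `k`, the AUC `curve`, and the full `ranking`.
#' @export
select_signature <- function(ranking, profiles, sizes = NULL,
                             max_pairs = 10000, repeats = 10, seed = 1,
                             cell_line = "CL1") {
  p <- nrow(ranking)
  sizes <- sizes %||% unique(pmin(c(2:30, seq(35, 100, 5), seq(110, 250, 10)), p))
  sizes <- sort(unique(sizes[sizes >= 2 & sizes <= p]))
  ordered <- ranking$feature

  wells <- profiles[!profiles$is_control, , drop = FALSE]
  x <- .descriptor_matrix(wells, ordered[seq_len(max(sizes))])
  g <- wells$treatment_id
  rep_pairs <- .replicate_pairs(g)
  if (nrow(rep_pairs) == 0L) {
    abort("signature error: no treatment has >= 2 replicate wells")
  }

  set.seed(seed)
  auc_mat <- matrix(NA_real_, nrow = repeats, ncol = length(sizes))
  for (r in seq_len(repeats)) {
    rp <- .sample_rows(rep_pairs, max_pairs)
    np <- .sample_nonreplicate_pairs(g, max_pairs)
    auc_mat[r, ] <- .prefix_aucs(x, rbind(rp, np),
                                 rep(c(TRUE, FALSE), c(nrow(rp), nrow(np))),
                                 sizes)
  }
  curve <- tibble::tibble(
    size = sizes,
    mean_auc = colMeans(auc_mat),
    sd_auc = apply(auc_mat, 2, sd)
  )
  k <- choose_signature_size(curve)
  structure(list(
    cell_line = cell_line,
    features = ordered[seq_len(k)],
    k = k,
    curve = curve,
    ranking = ranking,
    seed = seed
  ), class = "signature_spec")
}

#' @export
print.signature_spec <- function(x, ...) {
  cat("Imaging signature for", x$cell_line, "\n")
  cat("  k =", x$k, "of", nrow(x$ranking), "candidate descriptors\n")
  i <- which(x$curve$size == x$k)
  cat(sprintf("  replicate AUC at k: %.3f +/- %.3f\n",
              x$curve$mean_auc[i], x$curve$sd_auc[i]))
  cat("  first features:", paste(head(x$features, 5), collapse = ", "), "\n")
  invisible(x)
}

# AUCs of pair-correlation scores over growing feature prefixes, via
# running sums: r_k = (k*Sxy - Sx*Sy) / sqrt((k*Sxx - Sx^2)(k*Syy - Sy^2))
.prefix_aucs <- function(x, pairs, is_rep, sizes) {
  a <- pairs[, 1]
  b <- pairs[, 2]
  n <- nrow(pairs)
  sx <- sy <- sxx <- syy <- sxy <- numeric(n)
  out <- numeric(length(sizes))
  si <- 1L
  for (k in seq_len(max(sizes))) {
    xa <- x[a, k]
    xb <- x[b, k]
    sx <- sx + xa; sy <- sy + xb
    sxx <- sxx + xa^2; syy <- syy + xb^2
    sxy <- sxy + xa * xb
    if (k == sizes[si]) {
      num <- k * sxy - sx * sy
      den <- sqrt(pmax(k * sxx - sx^2, 0) * pmax(k * syy - sy^2, 0))
      r <- ifelse(den > 0, num / den, NA_real_)
      ok <- is.finite(r)
      out[si] <- .rank_auc(r[is_rep & ok], r[!is_rep & ok])
      si <- si + 1L
      if (si > length(sizes)) break
    }
  }
  out
}
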