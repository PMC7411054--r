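#' Re-evaluate MoA distinguishability on concentration or channel subsets
#'
#' Design-of-experiment analysis over a full pipeline run:
#'
#' * **Concentration subsets** restrict the active treatments to the
#'   included concentrations and recompute the aggregated MoA AUC-ROC on
#'   that reduced set, using the signature and active calls of the full
#'   run.
#' * **Channel subsets** re-run the mRMR feature selection from scratch on
#'   the descriptors of the included fluorescence channels (rather than
#'   just dropping excluded-channel features from the full signature, for
#'   an unbiased comparison), while keeping the exact active-treatment set
#'   of the full three-channel run; treatment signatures and MoA aggregates
#'   are then recomputed on the re-selected features.
#'
#' @param state A `screen_run` from [run_screen()].
#' @param concentrations Concentrations (uM) to keep, or `NULL` for all.
#' @param channels Channels (`"BFP"`, `"GFP"`, `"RFP"`) to keep, or `NULL`
#'   for all.
#' @param min_compounds Minimum active member compounds per MoA.
#' @return Tibble `moa`, `cell_line`, `n_compounds`, `auc_full`,
#'   `auc_subset`, `delta`, with a `"subset_summary"` attribute giving the
#'   fractions of (MoA, cell line) pairs with `delta <= -0.05` and
#'   `>= 0.05`.
#' @export
subset_analysis <- function(state, concentrations = NULL, channels = NULL,
                            min_compounds = 3) {
  if (!is.null(concentrations) && length(concentrations) == 0) {
    abort("configuration error: empty concentration subset")
  }
  if (!is.null(channels) && length(channels) == 0) {
    abort("configuration error: empty channel subset")
  }
  activity <- state$activity
  signature <- state$signature

  if (!is.null(channels)) {
    channels <- match.arg(channels, c("BFP", "GFP", "RFP"), several.ok = TRUE)
    chan_map <- state$channel_map
    keep_desc <- names(chan_map)[chan_map %in% channels]
    keep_desc <- intersect(descriptor_names(state$prefiltered), keep_desc)
    if (length(keep_desc) < 2L) {
      abort("configuration error: channel subset leaves < 2 descriptors")
    }
    sub_pre <- state$prefiltered[, c(intersect(c(.meta_cols), names(state$prefiltered)),
                                     keep_desc), drop = FALSE]
    rel <- compute_relevance(sub_pre)
    rk <- mrmr_rank(sub_pre, rel)
    signature <- select_signature(rk, sub_pre, seed = state$seeds$signature,
                                  max_pairs = state$params$max_pairs,
                                  repeats = state$params$repeats,
                                  cell_line = state$cell_line)
    activity <- .recall_signatures(state, signature)
  }

  if (!is.null(concentrations)) {
    keep <- activity$calls$concentration_uM %in% concentrations
    activity <- .restrict_activity(activity, activity$calls$treatment_id[keep])
  }

  sub <- moa_auc(activity, state$annotations, cell_line = state$cell_line,
                 min_compounds = min_compounds)
  full <- state$moa_results
  out <- merge(
    data.frame(moa = full$moa, cell_line = full$cell_line,
               n_compounds = full$n_compounds, auc_full = full$auc),
    data.frame(moa = sub$moa, cell_line = sub$cell_line, auc_subset = sub$auc),
    by = c("moa", "cell_line"), all.x = TRUE
  )
  out$delta <- out$auc_subset - out$auc_full
  out <- tibble::as_tibble(out[order(out$cell_line, out$moa), ])
  d <- out$delta[!is.na(out$delta)]
  attr(out, "subset_summary") <- c(
    frac_decreased = mean(d <= -0.05),
    frac_increased = mean(d >= 0.05)
  )
  out
}

# keep the full run's active set but recompute treatment signatures on a
# different feature set (used by channel subsets)
.recall_signatures <- function(state, signature) {
  activity <- state$activity
  features <- .signature_features(signature)
  wells <- state$profiles[!state$profiles$is_control &
                            state$profiles$n_live >= state$params$min_cells, ,
                          drop = FALSE]
  x <- .descriptor_matrix(wells, features)
  trts <- split(seq_len(nrow(wells)), wells$treatment_id)
  trts <- trts[intersect(names(trts), activity$calls$treatment_id)]
  sigs <- t(vapply(names(trts), function(t) {
    apply(x[trts[[t]], , drop = FALSE], 2, stats::median)
  }, numeric(length(features))))
  rownames(sigs) <- names(trts)
  out <- activity
  out$signatures <- sigs
  out$features <- features
  out
}

# restrict an activity_calls object to a subset of treatments
.restrict_activity <- function(activity, treatment_ids) {
  out <- activity
  out$calls <- activity$calls[activity$calls$treatment_id %in% treatment_ids, ,
                              drop = FALSE]
  out$signatures <- activity$signatures[
    intersect(rownames(activity$signatures), treatment_ids), , drop = FALSE]
  out$compounds <- dplyr::summarise(
    dplyr::group_by(out$calls, .data$compound_id),
    active = any(.data$active), .groups = "drop"
  )
  out
}
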