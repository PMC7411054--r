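#' Filter a cell table to live cells
#'
#' Drops cells labelled dead or mis-segmented by the upstream QC classifier
#' and reports how many were removed. Only the label is consulted; the
#' classifier itself is outside this package's scope.
#'
#' @param cells Cell table with a `qc_label` column
#'   (`live`/`dead`/`missegmented`).
#' @param quiet Suppress the removal-count message.
#' @return The cell table restricted to live rows.
#' @export
filter_live <- function(cells, quiet = FALSE) {
  if (!"qc_label" %in% names(cells)) {
    abort("schema error: cell table has no `qc_label` column")
  }
  counts <- table(factor(cells$qc_label, levels = c("live", "dead", "missegmented")))
  if (!quiet) {
    message(sprintf("retained %d live cells (removed %d dead, %d mis-segmented)",
                    counts[["live"]], counts[["dead"]], counts[["missegmented"]]))
  }
  cells[cells$qc_label == "live", , drop = FALSE]
}

#' Aggregate live cells to well-level profiles
#'
#' For every well of each plate present in `cells`, computes the mean and
#' the median of each raw feature over the well's (live) cells plus the
#' cell count, giving a descriptor vector of length 2 x n_features + 1.
#' Map wells without any live cell yield a profile with cell count 0 and
#' missing (`NA`) descriptors, which downstream stages exclude pairwise.
#'
#' @param cells Live-cell table (see [filter_live()]).
#' @param plate_maps Plate map tibble; every `(plate, well)` in `cells` must
#'   appear here.
#' @return A well-profile tibble: metadata columns (`plate_id`, `batch_id`,
#'   `well`, `compound_id`, `concentration_uM`, `is_control`,
#'   `treatment_id`, `n_live`) plus descriptors `<feature>_mean`,
#'   `<feature>_median` and `cell_count`.
#' @export
aggregate_wells <- function(cells, plate_maps) {
  cells <- data.table::as.data.table(cells)
  feat <- setdiff(names(cells),
                  c("plate_id", "batch_id", "well", "cell_id", "qc_label"))
  key_cells <- unique(paste(cells$plate_id, cells$well))
  key_map <- paste(plate_maps$plate_id, plate_maps$well)
  orphan <- setdiff(key_cells, key_map)
  if (length(orphan) > 0) {
    abort(paste0("consistency error: wells absent from plate map: ",
                 paste(head(orphan, 5), collapse = ", ")))
  }

  means <- cells[, lapply(.SD, mean), by = c("plate_id", "well"), .SDcols = feat]
  medians <- cells[, lapply(.SD, stats::median), by = c("plate_id", "well"),
                   .SDcols = feat]
  counts <- cells[, list(cell_count = .N), by = c("plate_id", "well")]
  data.table::setnames(means, feat, paste0(feat, "_mean"))
  data.table::setnames(medians, feat, paste0(feat, "_median"))

  map <- plate_maps[plate_maps$plate_id %in% unique(cells$plate_id), , drop = FALSE]
  out <- merge(data.table::as.data.table(map), means,
               by = c("plate_id", "well"), all.x = TRUE)
  out <- merge(out, medians, by = c("plate_id", "well"), all.x = TRUE)
  out <- merge(out, counts, by = c("plate_id", "well"), all.x = TRUE)
  out$cell_count[is.na(out$cell_count)] <- 0
  out$n_live <- as.integer(out$cell_count)
  out$cell_count <- as.numeric(out$cell_count)
  data.table::setorderv(out, c("plate_id", "well_row", "well_col"))
  out[, c("well_row", "well_col") := NULL]
  meta <- intersect(c(.meta_cols, "n_live"), names(out))
  data.table::setcolorder(out, meta)
  tibble::as_tibble(out)
}

#' Normalize well profiles against DMSO controls
#'
#' Each descriptor is z-scored against the vehicle wells: subtract the mean
#' of the control wells plate-wise, then divide by the standard deviation of
#' the (plate-centered) control wells batch-wise. The batch SD is the sample
#' SD (n-1 denominator) of the pooled, plate-centered control values, so the
#' result is a proper standardization. Descriptors whose batch control SD is
#' zero (or not estimable) in any batch carry no information relative to the
#' controls; they are flagged constant and dropped with a warning.
#'
#' @param profiles Well-profile tibble from [aggregate_wells()].
#' @return The profiles with descriptors replaced by z-scores; dropped
#'   descriptor names are attached as attribute `"dropped_descriptors"`.
#' @export
normalize_profiles <- function(profiles) {
  desc <- setdiff(descriptor_names(profiles), "n_live")
  x <- .descriptor_matrix(profiles, desc)
  ctrl <- profiles$is_control

  for (p in unique(profiles$plate_id)) {
    on_p <- profiles$plate_id == p
    if (sum(ctrl & on_p) < 2L) {
      abort(paste0("normalization error: plate ", p, " has < 2 control wells"))
    }
    mu <- colMeans(x[ctrl & on_p, , drop = FALSE], na.rm = TRUE)
    x[on_p, ] <- sweep(x[on_p, , drop = FALSE], 2, mu, `-`)
  }

  dropped <- character(0)
  for (b in unique(profiles$batch_id)) {
    in_b <- profiles$batch_id == b
    if (sum(ctrl & in_b) < 2L) {
      abort(paste0("normalization error: batch ", b, " has < 2 control wells"))
    }
    s <- apply(x[ctrl & in_b, , drop = FALSE], 2, sd, na.rm = TRUE)
    bad <- !is.finite(s) | s == 0
    dropped <- union(dropped, colnames(x)[bad])
    s[bad] <- NA_real_
    x[in_b, ] <- sweep(x[in_b, , drop = FALSE], 2, s, `/`)
  }

  if (length(dropped) > 0) {
    warn(paste0("dropping ", length(dropped),
                " constant descriptor(s) with zero control SD: ",
                paste(head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else ""))
    x <- x[, setdiff(colnames(x), dropped), drop = FALSE]
  }

  out <- cbind(
    profiles[, intersect(c(.meta_cols, "n_live"), names(profiles)), drop = FALSE],
    tibble::as_tibble(x)
  )
  attr(out, "dropped_descriptors") <- dropped
  tibble::as_tibble(out)
}
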