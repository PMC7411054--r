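#' Euclidean activity threshold from the control null
#'
#' Each control well's imaging signature is compared against the mean
#' control signature, which is the zero vector after z-score normalization;
#' tau is the empirical 95th percentile (linear-interpolation quantile) of
#' these control distances. By construction about 5% of individual control
#' wells exceed tau.
#'
#' @param profiles Normalized well profiles (controls included).
#' @param signature A `signature_spec` (or character vector of features).
#' @param min_controls Minimum number of control wells for a stable
#'   quantile (default 20).
#' @return The threshold tau.
#' @export
compute_tau <- function(profiles, signature, min_controls = 20) {
  features <- .signature_features(signature)
  ctrl <- profiles[profiles$is_control, , drop = FALSE]
  if (nrow(ctrl) < min_controls) {
    abort(paste0("activity error: only ", nrow(ctrl), " control wells; need >= ",
                 min_controls, " for the tau quantile"))
  }
  d <- .signature_distances(ctrl, features)
  .quantile(d[is.finite(d)], 0.95)
}

.signature_features <- function(signature) {
  if (inherits(signature, "signature_spec")) signature$features else signature
}

# Euclidean distance of each well's signature to the 0-vector (the mean
# control signature after normalization)
.signature_distances <- function(profiles, features) {
  x <- .descriptor_matrix(profiles, features)
  sqrt(rowSums(x^2))
}

#' Flag the replicate wells of one treatment by the Euclidean criterion
#'
#' A well is flagged when its signature's Euclidean distance to the control
#' mean exceeds tau; the treatment is Euclidean-active when strictly more
#' than 50% of its replicate wells are flagged (>= 3 of 4 in the standard
#' design; 2 of 3 when a well was lost upstream).
#'
#' @param treatment_wells Normalized profiles of one treatment's wells.
#' @param signature Signature (spec or feature names).
#' @param tau Threshold from [compute_tau()].
#' @return List with per-well `flags` and the treatment-level `active` flag.
#' @export
call_euclidean_active <- function(treatment_wells, signature, tau) {
  d <- .signature_distances(treatment_wells, .signature_features(signature))
  flags <- d > tau
  list(flags = flags, active = mean(flags) > 0.5)
}

#' Reproducibility threshold from the non-replicate correlation null
#'
#' Builds the null distribution of Pearson correlations between imaging
#' signatures of well pairs drawn from different compounds, restricted to
#' wells of Euclidean-active treatments (pairs of the same compound at
#' different concentrations are excluded). Pairs are enumerated exhaustively
#' when their number is at most `cap_pairs`, else a seeded uniform subsample
#' of `cap_pairs` pairs is used. The threshold is the 95th percentile.
#'
#' @param profiles Normalized well profiles.
#' @param signature Signature (spec or feature names).
#' @param active_treatments Treatment ids flagged Euclidean-active.
#' @param cap_pairs Maximum pairs used (default 2e6).
#' @param seed Seed for the subsample.
#' @return List with `rho_null` and `n_pairs_used`.
#' @export
compute_reproducibility_null <- function(profiles, signature, active_treatments,
                                         cap_pairs = 2e6, seed = 1) {
  features <- .signature_features(signature)
  wells <- profiles[profiles$treatment_id %in% setdiff(active_treatments, "DMSO"), ,
                    drop = FALSE]
  if (length(unique(wells$compound_id)) < 2L) {
    abort("activity error: need Euclidean-active treatments of >= 2 compounds for the reproducibility null")
  }
  x <- .descriptor_matrix(wells, features)
  cmp <- wells$compound_id
  n <- nrow(wells)
  total <- n * (n - 1) / 2
  set.seed(seed)
  if (total <= cap_pairs * 1.5) {
    pairs <- t(utils::combn(n, 2L))
    pairs <- pairs[cmp[pairs[, 1]] != cmp[pairs[, 2]], , drop = FALSE]
    pairs <- .sample_rows(pairs, cap_pairs)
  } else {
    pairs <- matrix(integer(0), ncol = 2)
    while (nrow(pairs) < cap_pairs) {
      a <- sample.int(n, cap_pairs, replace = TRUE)
      b <- sample.int(n, cap_pairs, replace = TRUE)
      ok <- a != b & cmp[a] != cmp[b]
      pairs <- unique(rbind(pairs, cbind(pmin(a[ok], b[ok]), pmax(a[ok], b[ok]))))
    }
    pairs <- pairs[seq_len(cap_pairs), , drop = FALSE]
  }
  if (nrow(pairs) == 0L) abort("activity error: no eligible non-replicate pairs")
  r <- .pair_cor(x, pairs[, 1], pairs[, 2])
  r <- r[is.finite(r)]
  list(rho_null = .quantile(r, 0.95), n_pairs_used = nrow(pairs))
}

#' Two-criterion phenotypic active calling
#'
#' A treatment is phenotypically active when (1) strictly more than 50% of
#' its replicate wells deviate from the DMSO controls by more than tau
#' (Euclidean criterion) and (2) the median Pearson correlation over all
#' replicate signature pairs (six pairs for four wells) exceeds the
#' non-replicate null threshold rho_null (reproducibility criterion).
#' Wells with fewer than `min_cells` live cells are excluded beforehand, so
#' the >50% rule applies to the remaining replicate count; treatments left
#' with fewer than two wells cannot demonstrate reproducibility and are
#' called inactive with a warning. Per treatment the component-wise median
#' signature over its replicate wells is stored; a compound is active when
#' at least one of its concentrations is.
#'
#' @param profiles Normalized well profiles.
#' @param signature Signature (spec or feature names).
#' @param tau Threshold from [compute_tau()].
#' @param rho_null Threshold from [compute_reproducibility_null()].
#' @param min_cells Minimum live cells per well (default 100).
#' @return An `activity_calls` list: `calls` (per-treatment tibble),
#'   `signatures` (treatment x feature matrix of median signatures),
#'   `compounds` (per-compound activity), and the thresholds used.
#' @export
call_active <- function(profiles, signature, tau, rho_null, min_cells = 100) {
  features <- .signature_features(signature)
  wells <- profiles[!profiles$is_control & profiles$n_live >= min_cells, ,
                    drop = FALSE]
  if (nrow(wells) == 0L) abort("activity error: no sample wells left after the cell-count filter")
  x <- .descriptor_matrix(wells, features)
  d <- sqrt(rowSums(x^2))
  trts <- split(seq_len(nrow(wells)), wells$treatment_id)

  n_low <- 0L
  rows <- lapply(names(trts), function(t) {
    i <- trts[[t]]
    flags <- d[i] > tau
    euclid <- mean(flags) > 0.5
    if (length(i) >= 2L) {
      pr <- t(utils::combn(i, 2L))
      med_r <- stats::median(.pair_cor(x, pr[, 1], pr[, 2]), na.rm = TRUE)
      repro <- is.finite(med_r) && med_r > rho_null
    } else {
      n_low <<- n_low + 1L
      med_r <- NA_real_
      repro <- FALSE
    }
    tibble::tibble(
      treatment_id = t,
      compound_id = wells$compound_id[i[1]],
      concentration_uM = wells$concentration_uM[i[1]],
      n_wells = length(i),
      n_flagged = sum(flags),
      euclidean_active = euclid,
      median_replicate_cor = med_r,
      reproducible = repro,
      active = euclid && repro
    )
  })
  calls <- do.call(rbind, rows)
  if (n_low > 0L) {
    warn(paste0(n_low, " treatment(s) with < 2 usable wells: reproducibility ",
                "undefined, called inactive"))
  }
  sigs <- t(vapply(names(trts), function(t) {
    apply(x[trts[[t]], , drop = FALSE], 2, stats::median)
  }, numeric(ncol(x))))
  rownames(sigs) <- names(trts)

  compounds <- dplyr::summarise(
    dplyr::group_by(calls, .data$compound_id),
    active = any(.data$active), .groups = "drop"
  )
  structure(list(
    calls = calls,
    signatures = sigs,
    compounds = compounds,
    tau = tau,
    rho_null = rho_null,
    features = features
  ), class = "activity_calls")
}

#' @export
print.activity_calls <- function(x, ...) {
  cat("Activity calls for", nrow(x$calls), "treatments\n")
  cat(sprintf("  tau = %.3f, rho_null = %.3f\n", x$tau, x$rho_null))
  cat(sprintf("  active treatments: %d (%.1f%%); active compounds: %d of %d\n",
              sum(x$calls$active), 100 * mean(x$calls$active),
              sum(x$compounds$active), nrow(x$compounds)))
  invisible(x)
}
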