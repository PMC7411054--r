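# small screen configurations used across the suite ------------------------

small_config <- function(...) {
  args <- list(
    n_compounds = 12, n_moas = 3, moa_size_distribution = rep(3, 3),
    frac_multi_moa = 0, frac_active_compounds = 1, frac_coherent_moas = 1,
    n_features = 30, n_redundant_blocks = 3, redundant_block_size = 2,
    n_noise_features = 6, cells_per_well_mean = 150, cells_per_well_size = 20,
    seed = 1
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(screen_config, args)
}

# the scaled-down recovery screen: 60 compounds, 8 MoAs of size 5 (half
# coherent, half with per-compound random directions), 4 concentrations,
# 2 technical replicates x 2 batches, ~200 raw features
recovery_config <- function(seed) {
  screen_config(
    n_compounds = 60, n_moas = 8, moa_size_distribution = rep(5, 8),
    frac_multi_moa = 0, frac_active_compounds = 1, frac_coherent_moas = 0.5,
    n_features = 200, n_redundant_blocks = 10, redundant_block_size = 3,
    n_noise_features = 40, effect_size_active = 3, seed = seed
  )
}

# cache expensive pipeline runs so acceptance blocks can share them
.run_cache <- new.env(parent = emptyenv())

cached_screen_run <- function(seed, n_perm = 1000) {
  key <- paste0("run_", seed, "_", n_perm)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- suppressWarnings(
      run_screen(recovery_config(seed), n_perm = n_perm)
    )
  }
  .run_cache[[key]]
}

# build a well-profile tibble from a descriptor matrix -----------------------

make_profiles <- function(x, plate_id = "B1_P01", batch_id = "B1",
                          compound_id = "C0001", concentration_uM = 1,
                          is_control = FALSE, n_live = 400L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("d%02d", seq_len(ncol(x)))
  n <- nrow(x)
  meta <- tibble::tibble(
    plate_id = rep_len(plate_id, n),
    batch_id = rep_len(batch_id, n),
    well = sprintf("A%d", seq_len(n)),
    compound_id = rep_len(compound_id, n),
    concentration_uM = rep_len(concentration_uM, n),
    is_control = rep_len(is_control, n),
    n_live = rep_len(as.integer(n_live), n)
  )
  meta$concentration_uM[meta$is_control] <- NA_real_
  meta$compound_id[meta$is_control] <- "DMSO"
  meta$treatment_id <- ifelse(meta$is_control, "DMSO",
                              paste0(meta$compound_id, "@", meta$concentration_uM))
  cbind(meta, tibble::as_tibble(x))
}

# minimal activity_calls object for MoA-level unit tests ---------------------

make_activity <- function(signatures, compound_id, concentration_uM,
                          active = TRUE) {
  treatment_id <- paste0(compound_id, "@", concentration_uM)
  rownames(signatures) <- treatment_id
  calls <- tibble::tibble(
    treatment_id = treatment_id,
    compound_id = compound_id,
    concentration_uM = concentration_uM,
    n_wells = 4L, n_flagged = 4L,
    euclidean_active = TRUE,
    median_replicate_cor = 0.9,
    reproducible = TRUE,
    active = rep_len(active, length(treatment_id))
  )
  structure(list(
    calls = calls, signatures = signatures,
    compounds = dplyr::summarise(dplyr::group_by(calls, compound_id),
                                 active = any(active), .groups = "drop"),
    tau = 1, rho_null = 0.5, features = colnames(signatures)
  ), class = "activity_calls")
}
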