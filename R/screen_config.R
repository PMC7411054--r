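#' Configuration of a synthetic phenomic screen
#'
#' Builds and validates the parameter set of the synthetic screen generator.
#' The defaults mirror the screening design the pipeline targets: 384-well
#' plates with 28 DMSO control wells and 280 sample wells, two technical
#' replicates in each of two imaging batches (four replicate wells per
#' treatment), compounds screened at 0.3, 1, 3 and 9 uM, roughly 500 raw
#' per-cell features, and a compound library in which about 18% of compounds
#' carry more than one mechanism-of-action (MoA) annotation and about 53%
#' of compounds are truly active.
#'
#' @param n_compounds Number of compounds in the library.
#' @param n_moas Number of distinct MoA descriptors.
#' @param moa_size_distribution Integer vector of MoA sizes (co-annotated
#'   compounds per MoA). `NULL` draws sizes from a shifted geometric with
#'   mean ~5 compounds per MoA, the scale typical of annotated reference
#'   libraries.
#' @param frac_multi_moa Fraction of annotated compounds carrying two MoA
#'   descriptors (multi-MoA compounds model poly-pharmacology).
#' @param frac_active_compounds Fraction of compounds that are truly active.
#' @param frac_coherent_moas Fraction of MoAs whose member compounds share a
#'   common effect direction (phenotypically coherent). The remaining MoAs
#'   get an independent random direction per member compound.
#' @param concentrations Screening concentrations in uM, strictly increasing.
#' @param n_tech_replicates Technical replicate wells per treatment per batch.
#' @param n_batches Number of imaging batches.
#' @param controls_per_plate DMSO control wells per full plate.
#' @param samples_per_plate Compound-treated wells per full plate.
#' @param n_features Number of raw per-cell features.
#' @param n_redundant_blocks Number of redundant feature blocks; each block
#'   consists of `redundant_block_size` near-copies of one informative parent
#'   feature.
#' @param redundant_block_size Redundant copies per block.
#' @param n_noise_features Features carrying no treatment effect.
#' @param frac_affected_features Fraction of informative features a MoA's
#'   effect direction loads on.
#' @param effect_size_active Standardized effect magnitude at saturating
#'   concentration, in units of the control well-level SD (so a value of 3
#'   plants z-scores of about 3 on affected descriptors).
#' @param magnitude_sdlog Lognormal sd of the per-compound potency jitter.
#' @param hill_coefficient,ec50_meanlog,ec50_sdlog Saturating potency model:
#'   the effect multiplier at concentration c is c^h / (c^h + EC50^h) with a
#'   per-compound EC50 drawn lognormally (uM scale).
#' @param plate_effect_sd,batch_effect_sd,well_effect_sd Per-feature nuisance
#'   SDs at plate, batch and well level.
#' @param cell_noise_sd Per-cell feature noise SD.
#' @param cells_per_well_mean,cells_per_well_size Negative-binomial cell
#'   count model (mean and dispersion size).
#' @param frac_dead,frac_missegmented Per-cell probabilities of a dead or
#'   mis-segmented QC label.
#' @param seed Master seed; all stage seeds derive from it deterministically.
#' @return A validated list of class `screen_config`.
#' @export
screen_config <- function(n_compounds = 1008,
                          n_moas = 218,
                          moa_size_distribution = NULL,
                          frac_multi_moa = 0.18,
                          frac_active_compounds = 0.53,
                          frac_coherent_moas = 1,
                          concentrations = c(0.3, 1, 3, 9),
                          n_tech_replicates = 2,
                          n_batches = 2,
                          controls_per_plate = 28,
                          samples_per_plate = 280,
                          n_features = 500,
                          n_redundant_blocks = 25,
                          redundant_block_size = 3,
                          n_noise_features = 100,
                          frac_affected_features = 0.3,
                          effect_size_active = 3,
                          magnitude_sdlog = 0.25,
                          hill_coefficient = 2,
                          ec50_meanlog = 0,
                          ec50_sdlog = 0.7,
                          plate_effect_sd = 0.2,
                          batch_effect_sd = 0.2,
                          well_effect_sd = 0.3,
                          cell_noise_sd = 1,
                          cells_per_well_mean = 400,
                          cells_per_well_size = 10,
                          frac_dead = 0.05,
                          frac_missegmented = 0.05,
                          seed = 1) {
  config <- list(
    n_compounds = as.integer(n_compounds),
    n_moas = as.integer(n_moas),
    moa_size_distribution = moa_size_distribution,
    frac_multi_moa = frac_multi_moa,
    frac_active_compounds = frac_active_compounds,
    frac_coherent_moas = frac_coherent_moas,
    concentrations = as.numeric(concentrations),
    n_tech_replicates = as.integer(n_tech_replicates),
    n_batches = as.integer(n_batches),
    controls_per_plate = as.integer(controls_per_plate),
    samples_per_plate = as.integer(samples_per_plate),
    n_features = as.integer(n_features),
    n_redundant_blocks = as.integer(n_redundant_blocks),
    redundant_block_size = as.integer(redundant_block_size),
    n_noise_features = as.integer(n_noise_features),
    frac_affected_features = frac_affected_features,
    effect_size_active = effect_size_active,
    magnitude_sdlog = magnitude_sdlog,
    hill_coefficient = hill_coefficient,
    ec50_meanlog = ec50_meanlog,
    ec50_sdlog = ec50_sdlog,
    plate_effect_sd = plate_effect_sd,
    batch_effect_sd = batch_effect_sd,
    well_effect_sd = well_effect_sd,
    cell_noise_sd = cell_noise_sd,
    cells_per_well_mean = cells_per_well_mean,
    cells_per_well_size = cells_per_well_size,
    frac_dead = frac_dead,
    frac_missegmented = frac_missegmented,
    seed = as.integer(seed)
  )
  class(config) <- "screen_config"
  validate_screen_config(config)
  config
}

#' Validate a screen configuration
#'
#' @param config A `screen_config` object (or plain list with its fields).
#' @return The config, invisibly; aborts with a configuration error otherwise.
#' @export
validate_screen_config <- function(config) {
  fracs <- c("frac_multi_moa", "frac_active_compounds", "frac_coherent_moas",
             "frac_affected_features", "frac_dead", "frac_missegmented")
  for (f in fracs) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      abort(paste0("configuration error: `", f, "` must be a fraction in [0, 1]"))
    }
  }
  sds <- c("plate_effect_sd", "batch_effect_sd", "well_effect_sd",
           "cell_noise_sd", "effect_size_active")
  for (s in sds) {
    if (config[[s]] < 0) {
      abort(paste0("configuration error: `", s, "` must be nonnegative"))
    }
  }
  if (config$frac_dead + config$frac_missegmented >= 1) {
    abort("configuration error: frac_dead + frac_missegmented must be < 1")
  }
  conc <- config$concentrations
  if (length(conc) < 1L || any(conc <= 0) || is.unsorted(conc, strictly = TRUE)) {
    abort("configuration error: concentrations must be positive and strictly increasing")
  }
  if (config$n_compounds < 0L || config$n_moas < 0L) {
    abort("configuration error: counts must be nonnegative")
  }
  n_derived <- config$n_redundant_blocks * config$redundant_block_size +
    config$n_noise_features
  if (config$n_features - n_derived < 1L) {
    abort("configuration error: redundant + noise features leave no informative features")
  }
  sizes <- config$moa_size_distribution
  if (!is.null(sizes)) {
    if (length(sizes) != config$n_moas || any(sizes < 1)) {
      abort("configuration error: moa_size_distribution must give a size >= 1 per MoA")
    }
    n_annot <- .n_annotated(sum(sizes), config$frac_multi_moa)
    if (n_annot > config$n_compounds) {
      abort("configuration error: infeasible moa_size_distribution for n_compounds")
    }
  }
  if (config$controls_per_plate < 2L) {
    abort("configuration error: need >= 2 control wells per plate")
  }
  if (config$controls_per_plate + config$samples_per_plate > 384L) {
    abort("configuration error: plate layout exceeds 384 wells")
  }
  invisible(config)
}

# number of distinct annotated compounds implied by total annotation slots
# and the multi-MoA fraction (multi-MoA compounds carry exactly 2 descriptors)
.n_annotated <- function(total_slots, frac_multi) {
  n_annot <- round(total_slots / (1 + frac_multi))
  n_multi <- total_slots - n_annot
  if (n_multi < 0 || n_multi > n_annot) {
    abort("configuration error: infeasible multi-MoA fraction for the size distribution")
  }
  n_annot
}

#' Channel tags of the raw features
#'
#' Each raw feature is tagged with the fluorescence channel it derives from
#' (BFP, GFP or RFP), assigned round-robin by feature index. Descriptors
#' inherit the channel of their parent feature; the cell-count descriptor is
#' tagged BFP because segmentation (and hence counting) uses the BFP marker.
#'
#' @param config A `screen_config`.
#' @return Named character vector: raw feature id -> channel.
#' @export
feature_channels <- function(config) {
  ids <- .feature_ids(config$n_features)
  stats::setNames(rep_len(c("BFP", "GFP", "RFP"), config$n_features), ids)
}

#' Channel tags of well-level descriptors
#'
#' @param channels Named vector from [feature_channels()].
#' @return Named character vector: descriptor name -> channel.
#' @export
descriptor_channels <- function(channels) {
  d <- c(
    stats::setNames(channels, paste0(names(channels), "_mean")),
    stats::setNames(channels, paste0(names(channels), "_median")),
    cell_count = "BFP"
  )
  d
}

.feature_ids <- function(n) {
  sprintf("f%03d", seq_len(n))
}
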