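#' Run the full phenomic-profiling pipeline on a synthetic screen
#'
#' End-to-end, in memory: library generation, plate layout, cell-level
#' simulation with live-cell filtering and well aggregation (plate by
#' plate), DMSO normalization, prefiltering + mRMR signature selection,
#' two-criterion active calling, and per-MoA AUC-ROC with permutation
#' significance. Every stage draws its randomness from a child seed of
#' `seed`, so identical configurations reproduce identical results.
#'
#' @param config A [screen_config()].
#' @param n_perm Permutations for the MoA significance (default 1000).
#' @param cell_line Label of the simulated reporter cell line.
#' @param seed Master seed (defaults to `config$seed`).
#' @param sizes Candidate signature sizes (see [select_signature()]).
#' @param max_pairs,repeats Replicate-AUC sampling parameters.
#' @param min_cells Minimum live cells per usable well.
#' @param cap_pairs Pair cap for the reproducibility null.
#' @param verbose Log stage progress.
#' @return A `screen_run` list with the config, ground truth, annotations,
#'   plate maps, normalized `profiles`, `prefiltered` wells, `signature`,
#'   `activity`, `moa_results` and the channel map of the descriptors.
#' @export
run_screen <- function(config, n_perm = 1000, cell_line = "CL1", seed = NULL,
                       sizes = NULL, max_pairs = 10000, repeats = 10,
                       min_cells = 100, cap_pairs = 2e6, verbose = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  say <- function(...) if (verbose) message(...)

  say("stage 1/6: library + plate maps")
  lib <- generate_library(config)
  maps <- generate_plate_maps(config)

  say("stage 2/6: simulating ", length(unique(maps$plate_id)), " plates")
  wells <- simulate_well_profiles(maps, lib$truth, config, verbose = verbose)

  say("stage 3/6: normalizing ", nrow(wells), " wells")
  norm <- normalize_profiles(wells)

  say("stage 4/6: feature selection")
  pre <- prefilter_wells(norm, min_cells = min_cells)
  rel <- compute_relevance(pre)
  rank <- mrmr_rank(pre, rel)
  seeds <- list(signature = .child_seed(config$seed, 41),
                null = .child_seed(config$seed, 42),
                perm = .child_seed(config$seed, 43))
  signature <- select_signature(rank, pre, sizes = sizes, max_pairs = max_pairs,
                                repeats = repeats, seed = seeds$signature,
                                cell_line = cell_line)

  say("stage 5/6: active calling (k = ", signature$k, ")")
  tau <- compute_tau(norm, signature)
  eu_flags <- .euclidean_active_treatments(norm, signature, tau, min_cells)
  null <- compute_reproducibility_null(norm, signature, eu_flags,
                                       cap_pairs = cap_pairs, seed = seeds$null)
  activity <- call_active(norm, signature, tau, null$rho_null,
                          min_cells = min_cells)

  say("stage 6/6: MoA AUC-ROC (", n_perm, " permutations)")
  results <- moa_auc(activity, lib$annotations, cell_line = cell_line)
  if (nrow(results) > 0 && n_perm > 0) {
    results <- permutation_significance(results, activity, lib$annotations,
                                        n_perm = n_perm, seed = seeds$perm)
  }

  structure(list(
    config = config,
    truth = lib$truth,
    annotations = lib$annotations,
    plate_maps = maps,
    profiles = norm,
    prefiltered = pre,
    relevance = rel,
    signature = signature,
    activity = activity,
    moa_results = results,
    channel_map = descriptor_channels(feature_channels(config)),
    cell_line = cell_line,
    seeds = seeds,
    params = list(max_pairs = max_pairs, repeats = repeats,
                  min_cells = min_cells, cap_pairs = cap_pairs,
                  n_perm = n_perm)
  ), class = "screen_run")
}

# treatment ids whose wells pass the Euclidean criterion (> 50% flagged)
.euclidean_active_treatments <- function(profiles, signature, tau, min_cells) {
  wells <- profiles[!profiles$is_control & profiles$n_live >= min_cells, ,
                    drop = FALSE]
  d <- .signature_distances(wells, .signature_features(signature))
  flagged <- tapply(d > tau, wells$treatment_id, mean)
  names(flagged)[flagged > 0.5]
}

#' @export
print.screen_run <- function(x, ...) {
  cat("Phenomic screen run (", x$cell_line, ")\n", sep = "")
  cat("  ", nrow(x$profiles), " wells, ",
      length(descriptor_names(x$profiles)), " descriptors\n", sep = "")
  cat("  signature size k =", x$signature$k, "\n")
  cat("  active treatments:", sum(x$activity$calls$active), "of",
      nrow(x$activity$calls), "\n")
  if (nrow(x$moa_results) > 0) {
    cat("  distinguishable MoAs:", sum(x$moa_results$distinguishable),
        "of", nrow(x$moa_results), "tested\n")
  }
  invisible(x)
}

#' Run the pipeline from a YAML configuration and write its artifacts
#'
#' Thin orchestration layer: reads a YAML file whose keys are
#' [screen_config()] arguments (plus optional `n_perm`, `cell_line`),
#' validates it, executes [run_screen()], and writes the stage outputs
#' (well profiles, signature, activity calls, MoA results) together with a
#' JSON run manifest recording the config hash, seeds, and file paths.
#'
#' @param config Path to a YAML config file, or a config list.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed override.
#' @param n_perm Permutation count override.
#' @param verbose Log stage progress.
#' @return The `screen_run`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, n_perm = NULL,
                         verbose = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("pipeline stage `config`: input file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  extra <- config[intersect(names(config), c("n_perm", "cell_line"))]
  cfg_args <- config[setdiff(names(config), c("n_perm", "cell_line"))]
  cfg <- do.call(screen_config, cfg_args)
  n_perm <- n_perm %||% extra$n_perm %||% 1000
  cell_line <- extra$cell_line %||% "CL1"

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- run_screen(cfg, n_perm = n_perm, cell_line = cell_line, seed = seed,
                    verbose = verbose)

  paths <- list(
    plate_maps = file.path(out_dir, "plate_maps.csv"),
    wells = file.path(out_dir, "well_profiles.csv"),
    signature = file.path(out_dir, "signature.json"),
    activity = file.path(out_dir, "activity_calls.csv"),
    moa_results = file.path(out_dir, "moa_results.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write.csv(run$plate_maps, paths$plate_maps, row.names = FALSE)
  write.csv(run$profiles, paths$wells, row.names = FALSE)
  jsonlite::write_json(list(
    cell_line = run$signature$cell_line,
    k = run$signature$k,
    features = run$signature$features,
    curve = run$signature$curve,
    seed = run$signature$seed,
    config_hash = rlang::hash(cfg)
  ), paths$signature, auto_unbox = TRUE, digits = NA)
  write.csv(run$activity$calls, paths$activity, row.names = FALSE)
  write.csv(run$moa_results, paths$moa_results, row.names = FALSE)
  jsonlite::write_json(list(
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("phenoprofiler")),
    seed = cfg$seed,
    stage_seeds = run$seeds,
    n_perm = n_perm,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = paths[setdiff(names(paths), "manifest")]
  ), paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(run)
}
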