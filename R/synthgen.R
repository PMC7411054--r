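#' Generate a synthetic compound library with ground-truth annotations
#'
#' Creates a compound library annotated with mechanism-of-action (MoA)
#' descriptors plus the hidden generative state the simulator needs:
#' which compounds are truly active, the per-MoA (or per-compound) effect
#' direction over the raw features, per-compound potency (EC50) and
#' magnitude jitter, and the role of every raw feature (informative,
#' redundant copy of a parent, or pure noise).
#'
#' Multi-MoA compounds (modelling poly-pharmacology) carry exactly two
#' descriptors; their expected fraction among annotated compounds is
#' `frac_multi_moa`. MoAs flagged coherent share one effect direction across
#' their member compounds; incoherent MoAs give each member an independent
#' random direction, so their members are active but phenotypically
#' unrelated.
#'
#' @param config A [screen_config()].
#' @return A list with `annotations` (tibble: `compound_id`, `moa`) and
#'   `truth`, a `screen_truth` list holding `compounds`, `moas`, `features`,
#'   and the `effect_directions` matrix (compound x raw feature).
#' @export
generate_library <- function(config) {
  validate_screen_config(config)
  set.seed(.child_seed(config$seed, 1))

  n_cmp <- config$n_compounds
  compound_ids <- sprintf("C%04d", seq_len(max(n_cmp, 1)))[seq_len(n_cmp)]
  moa_ids <- sprintf("MOA%03d", seq_len(max(config$n_moas, 1)))[seq_len(config$n_moas)]

  sizes <- config$moa_size_distribution %||% .draw_moa_sizes(config)
  sizes <- as.integer(sizes)

  annotations <- .assign_moas(compound_ids, moa_ids, sizes, config$frac_multi_moa)

  n_active <- round(config$frac_active_compounds * n_cmp)
  active_ids <- sample(compound_ids, n_active)

  n_coherent <- round(config$frac_coherent_moas * config$n_moas)
  coherent_ids <- sample(moa_ids, n_coherent)

  features <- .assign_feature_roles(config)
  informative <- features$feature[features$role == "informative"]

  # one direction per coherent MoA, shared by all member compounds
  moa_dirs <- matrix(0, nrow = length(moa_ids), ncol = config$n_features,
                     dimnames = list(moa_ids, features$feature))
  for (m in moa_ids) {
    if (m %in% coherent_ids) moa_dirs[m, ] <- .draw_direction(config, features)
  }

  # per-compound direction: mean over its MoAs' directions, with an
  # independent draw standing in for each incoherent MoA / missing annotation
  dirs <- matrix(0, nrow = n_cmp, ncol = config$n_features,
                 dimnames = list(compound_ids, features$feature))
  ann_split <- split(annotations$moa, annotations$compound_id)
  for (cmp in intersect(active_ids, compound_ids)) {
    moas <- ann_split[[cmp]]
    if (is.null(moas)) {
      dirs[cmp, ] <- .draw_direction(config, features)
    } else {
      comp_dirs <- lapply(moas, function(m) {
        if (m %in% coherent_ids) moa_dirs[m, ] else .draw_direction(config, features)
      })
      dirs[cmp, ] <- Reduce(`+`, comp_dirs) / length(comp_dirs)
    }
  }

  compounds <- tibble::tibble(
    compound_id = compound_ids,
    active = compound_ids %in% active_ids,
    magnitude = rlnorm(n_cmp, 0, config$magnitude_sdlog),
    ec50_uM = rlnorm(n_cmp, config$ec50_meanlog, config$ec50_sdlog)
  )
  compounds$magnitude[!compounds$active] <- 0

  moa_sizes <- table(annotations$moa)
  moas <- tibble::tibble(
    moa = moa_ids,
    coherent = moa_ids %in% coherent_ids,
    n_compounds = as.integer(moa_sizes[moa_ids])
  )
  moas$n_compounds[is.na(moas$n_compounds)] <- 0L

  truth <- structure(list(
    compounds = compounds,
    moas = moas,
    features = features,
    effect_directions = dirs,
    config = config
  ), class = "screen_truth")

  list(annotations = annotations, truth = truth)
}

# shifted-geometric MoA sizes with mean ~5 compounds per MoA, trimmed until
# the implied number of annotated compounds fits the library
.draw_moa_sizes <- function(config) {
  if (config$n_moas == 0L) return(integer(0))
  sizes <- 1L + stats::rgeom(config$n_moas, 1 / 5.4)
  repeat {
    n_annot <- round(sum(sizes) / (1 + config$frac_multi_moa))
    if (n_annot <= config$n_compounds || all(sizes == 1L)) break
    sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  }
  sizes
}

# distribute annotation slots over compounds: multi-MoA compounds receive two
# distinct descriptors, the rest one; greedy by remaining MoA capacity
.assign_moas <- function(compound_ids, moa_ids, sizes, frac_multi) {
  if (length(moa_ids) == 0L || sum(sizes) == 0L) {
    return(tibble::tibble(compound_id = character(), moa = character()))
  }
  total <- sum(sizes)
  n_annot <- .n_annotated(total, frac_multi)
  n_multi <- total - n_annot
  if (n_annot > length(compound_ids)) {
    abort("configuration error: infeasible size distribution (more annotated compounds than library size)")
  }
  annotated <- sample(compound_ids, n_annot)
  remaining <- stats::setNames(sizes, moa_ids)
  rows_cmp <- character(total)
  rows_moa <- character(total)
  k <- 0L
  for (i in seq_len(n_annot)) {
    want <- if (i <= n_multi) 2L else 1L
    open <- names(remaining)[remaining > 0]
    if (length(open) < want) {
      abort("configuration error: infeasible size distribution for the multi-MoA fraction")
    }
    pick <- open[order(-remaining[open], open)][seq_len(want)]
    for (m in pick) {
      k <- k + 1L
      rows_cmp[k] <- annotated[i]
      rows_moa[k] <- m
      remaining[m] <- remaining[m] - 1L
    }
  }
  out <- tibble::tibble(compound_id = rows_cmp, moa = rows_moa)
  out[order(out$compound_id, out$moa), ]
}

# feature roles: informative, redundant (slope * parent + noise), pure noise
.assign_feature_roles <- function(config) {
  ids <- .feature_ids(config$n_features)
  n_red <- config$n_redundant_blocks * config$redundant_block_size
  roles <- rep("informative", config$n_features)
  idx <- sample.int(config$n_features)
  red_idx <- idx[seq_len(n_red)]
  noise_idx <- idx[n_red + seq_len(config$n_noise_features)]
  roles[red_idx] <- "redundant"
  roles[noise_idx] <- "noise"
  informative <- ids[roles == "informative"]
  parent <- rep(NA_character_, config$n_features)
  slope <- rep(NA_real_, config$n_features)
  if (n_red > 0L) {
    parents <- sample(informative, config$n_redundant_blocks,
                      replace = config$n_redundant_blocks > length(informative))
    parent[red_idx] <- rep(parents, each = config$redundant_block_size)
    slope[red_idx] <- sample(c(-1, 1), n_red, replace = TRUE) * runif(n_red, 0.8, 1.2)
  }
  tibble::tibble(
    feature = ids,
    role = roles,
    parent = parent,
    slope = slope,
    channel = unname(feature_channels(config))
  )
}

# an effect direction: +/-1 on a random subset of informative features
.draw_direction <- function(config, features) {
  d <- numeric(config$n_features)
  informative_idx <- which(features$role == "informative")
  n_affected <- max(1L, round(config$frac_affected_features * length(informative_idx)))
  hit <- sample(informative_idx, n_affected)
  d[hit] <- sample(c(-1, 1), n_affected, replace = TRUE)
  d
}

#' Lay out treatments and DMSO controls on 384-well plates
#'
#' Every treatment (compound x concentration) is placed on
#' `n_tech_replicates` wells per batch in each batch; both technical
#' replicates of a treatment sit on the same plate. Each full plate carries
#' `controls_per_plate` DMSO wells (on the outer columns) and up to
#' `samples_per_plate` sample wells; treatment order is shuffled per batch.
#' With zero compounds each batch still gets one control-only plate so
#' downstream stages have a vehicle reference.
#'
#' @param config A [screen_config()].
#' @return A tibble with columns `plate_id`, `batch_id`, `well`, `well_row`,
#'   `well_col`, `compound_id` (`"DMSO"` for controls), `concentration_uM`
#'   (`NA` for controls), `is_control`, `treatment_id`.
#' @export
generate_plate_maps <- function(config) {
  validate_screen_config(config)
  reps <- config$n_tech_replicates
  if (reps > config$samples_per_plate) {
    abort("layout error: more technical replicates than sample wells per plate")
  }
  compound_ids <- sprintf("C%04d", seq_len(max(config$n_compounds, 1)))[seq_len(config$n_compounds)]
  treatments <- expand.grid(
    compound_id = compound_ids,
    concentration_uM = config$concentrations,
    stringsAsFactors = FALSE
  )
  trt_per_plate <- config$samples_per_plate %/% reps

  maps <- vector("list", config$n_batches)
  for (b in seq_len(config$n_batches)) {
    batch_id <- paste0("B", b)
    set.seed(.child_seed(config$seed, 10L + b))
    if (nrow(treatments) > 0L) {
      order_b <- sample.int(nrow(treatments))
      plate_of <- ceiling(seq_along(order_b) / trt_per_plate)
      n_plates <- max(plate_of)
    } else {
      order_b <- integer(0)
      plate_of <- integer(0)
      n_plates <- 1L
    }
    plates <- vector("list", n_plates)
    for (p in seq_len(n_plates)) {
      trt_idx <- order_b[plate_of == p]
      n_samples <- length(trt_idx) * reps
      pos <- .plate_positions(config$controls_per_plate, n_samples)
      plate_id <- sprintf("%s_P%02d", batch_id, p)
      sample_rows <- if (length(trt_idx) > 0L) {
        data.frame(
          compound_id = rep(treatments$compound_id[trt_idx], each = reps),
          concentration_uM = rep(treatments$concentration_uM[trt_idx], each = reps)
        )
      } else {
        data.frame(compound_id = character(), concentration_uM = numeric())
      }
      plates[[p]] <- tibble::tibble(
        plate_id = plate_id,
        batch_id = batch_id,
        well = c(pos$control$well, pos$sample$well),
        well_row = c(pos$control$row, pos$sample$row),
        well_col = c(pos$control$col, pos$sample$col),
        compound_id = c(rep("DMSO", nrow(pos$control)), sample_rows$compound_id),
        concentration_uM = c(rep(NA_real_, nrow(pos$control)),
                             sample_rows$concentration_uM),
        is_control = c(rep(TRUE, nrow(pos$control)),
                       rep(FALSE, nrow(sample_rows)))
      )
    }
    maps[[b]] <- do.call(rbind, plates)
  }
  out <- do.call(rbind, maps)
  out$treatment_id <- .treatment_id(out$compound_id, out$concentration_uM)
  out
}

# control wells on the outer columns (1, 24, then 2, 23, ...), samples fill
# the remaining 384-well grid row-major
.plate_positions <- function(n_controls, n_samples) {
  rows <- LETTERS[1:16]
  cols <- 1:24
  grid <- expand.grid(row = rows, col = cols, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$row, rows), grid$col), ]
  grid$well <- paste0(grid$row, grid$col)
  edge_cols <- as.vector(rbind(cols, rev(cols)))[seq_len(24)]  # 1,24,2,23,...
  edge <- do.call(rbind, lapply(edge_cols, function(cc) grid[grid$col == cc, ]))
  if (n_controls > nrow(grid)) abort("layout error: too many control wells")
  control <- edge[seq_len(n_controls), ]
  rest <- grid[!grid$well %in% control$well, ]
  if (n_samples > nrow(rest)) abort("layout error: overfull plate")
  list(control = control, sample = rest[seq_len(n_samples), , drop = FALSE])
}

# control well-level SD implied by the nuisance model; effect sizes are
# expressed in units of this SD so they read as z-score magnitudes
.implied_well_sd <- function(config) {
  sqrt(config$well_effect_sd^2 +
         config$cell_noise_sd^2 / max(config$cells_per_well_mean, 1))
}

# saturating (Hill) potency multiplier
.potency <- function(concentration, ec50, hill) {
  concentration^hill / (concentration^hill + ec50^hill)
}

#' Simulate per-cell feature tables for a set of plates
#'
#' Generative model per live cell: feature value = plate offset + batch
#' offset + well offset + treatment effect + per-cell noise. The treatment
#' effect is direction x `effect_size_active` x control well-level SD x
#' per-compound magnitude jitter x Hill potency at the well's concentration;
#' it is zero for DMSO and inactive compounds. Redundant features are a
#' linear transform of their parent feature plus small noise; dead and
#' mis-segmented cells are drawn with shifted/inflated distributions and
#' labelled accordingly. Per-well cell counts are negative-binomial.
#'
#' All randomness is seeded per plate from the master seed, so simulating a
#' subset of plates yields the same cells as simulating all of them.
#'
#' @param plate_maps Plate map tibble from [generate_plate_maps()].
#' @param truth `truth` element from [generate_library()].
#' @param config A [screen_config()].
#' @return A `data.table` with columns `plate_id`, `batch_id`, `well`,
#'   `cell_id`, `qc_label` (`live`/`dead`/`missegmented`) and one column per
#'   raw feature.
#' @export
simulate_cells <- function(plate_maps, truth, config) {
  plates <- unique(plate_maps$plate_id)
  out <- lapply(plates, function(p) {
    .simulate_plate(plate_maps[plate_maps$plate_id == p, , drop = FALSE],
                    truth, config)
  })
  data.table::rbindlist(out)
}

.plate_index <- function(plate_id) {
  b <- as.integer(sub("^B(\\d+)_P(\\d+)$", "\\1", plate_id))
  p <- as.integer(sub("^B(\\d+)_P(\\d+)$", "\\2", plate_id))
  c(batch = b, plate = p)
}

.simulate_plate <- function(map, truth, config) {
  idx <- .plate_index(map$plate_id[1])
  n_feat <- config$n_features
  feat_ids <- truth$features$feature

  # batch offsets depend only on the batch, plate offsets on the plate
  set.seed(.child_seed(config$seed, 1000L + idx[["batch"]]))
  batch_off <- rnorm(n_feat, 0, config$batch_effect_sd)
  set.seed(.child_seed(config$seed, 100000L + 1000L * idx[["batch"]] + idx[["plate"]]))
  plate_off <- rnorm(n_feat, 0, config$plate_effect_sd)

  n_wells <- nrow(map)
  well_off <- matrix(rnorm(n_wells * n_feat, 0, config$well_effect_sd),
                     nrow = n_wells)

  # per-well treatment effect on the raw features
  well_sd <- .implied_well_sd(config)
  effects <- matrix(0, nrow = n_wells, ncol = n_feat)
  cmp_tbl <- truth$compounds
  trt <- !map$is_control & map$compound_id %in% rownames(truth$effect_directions)
  if (any(trt)) {
    cmp <- map$compound_id[trt]
    mag <- cmp_tbl$magnitude[match(cmp, cmp_tbl$compound_id)]
    ec50 <- cmp_tbl$ec50_uM[match(cmp, cmp_tbl$compound_id)]
    pot <- .potency(map$concentration_uM[trt], ec50, config$hill_coefficient)
    effects[trt, ] <- truth$effect_directions[cmp, , drop = FALSE] *
      (config$effect_size_active * well_sd * mag * pot)
  }

  base <- sweep(well_off + effects, 2, plate_off + batch_off, `+`)

  n_cells <- rnbinom(n_wells, mu = config$cells_per_well_mean,
                     size = config$cells_per_well_size)
  total <- sum(n_cells)
  well_of_cell <- rep.int(seq_len(n_wells), n_cells)

  values <- base[well_of_cell, , drop = FALSE] +
    matrix(rnorm(total * n_feat, 0, config$cell_noise_sd), nrow = total)

  u <- runif(total)
  qc <- rep("live", total)
  qc[u < config$frac_dead] <- "dead"
  qc[u >= config$frac_dead &
       u < config$frac_dead + config$frac_missegmented] <- "missegmented"
  dead <- qc == "dead"
  mis <- qc == "missegmented"
  if (any(dead)) {
    values[dead, ] <- values[dead, , drop = FALSE] + 3 * config$cell_noise_sd
  }
  if (any(mis)) {
    values[mis, ] <- values[mis, , drop = FALSE] +
      matrix(rnorm(sum(mis) * n_feat, 2 * config$cell_noise_sd,
                   4 * config$cell_noise_sd), nrow = sum(mis))
  }

  # redundant features derive from their parent's final per-cell value
  red <- which(truth$features$role == "redundant")
  for (j in red) {
    pj <- match(truth$features$parent[j], feat_ids)
    values[, j] <- truth$features$slope[j] * values[, pj] +
      rnorm(total, 0, 0.3 * config$cell_noise_sd)
  }

  colnames(values) <- feat_ids
  dt <- data.table::data.table(
    plate_id = map$plate_id[well_of_cell],
    batch_id = map$batch_id[well_of_cell],
    well = map$well[well_of_cell],
    cell_id = sequence(n_cells),
    qc_label = qc
  )
  data.table::rbindlist(list(cbind(dt, data.table::as.data.table(values))))
}

#' Simulate a screen directly at the well-profile level
#'
#' Convenience wrapper that simulates cells plate by plate, filters to live
#' cells and aggregates to well profiles, never holding more than one
#' plate's cells in memory. Equivalent to
#' `aggregate_wells(filter_live(simulate_cells(...)), plate_maps)`.
#'
#' @inheritParams simulate_cells
#' @param verbose Log per-plate progress.
#' @return A well-profile tibble (see [aggregate_wells()]).
#' @export
simulate_well_profiles <- function(plate_maps, truth, config, verbose = FALSE) {
  plates <- unique(plate_maps$plate_id)
  profiles <- lapply(plates, function(p) {
    map_p <- plate_maps[plate_maps$plate_id == p, , drop = FALSE]
    cells <- .simulate_plate(map_p, truth, config)
    live <- filter_live(cells, quiet = TRUE)
    if (verbose) message("simulated plate ", p, ": ", nrow(cells), " cells")
    aggregate_wells(live, map_p)
  })
  do.call(rbind, profiles)
}
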