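#' Read a compound annotation table
#'
#' Parses a delimited annotation file with one row per compound and columns
#' `compound_id`, `moa` (one or more MoA descriptors separated by `|`) and
#' optionally `targets` (gene names, `|`-separated). Rows with an empty
#' `moa` field yield unannotated compounds.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default comma).
#' @return List with `annotations` (long tibble `compound_id`, `moa`) and
#'   `targets` (long tibble `compound_id`, `gene`).
#' @export
read_compound_annotations <- function(path, sep = ",") {
  if (!file.exists(path)) {
    abort(paste0("annotation parser: input file not found: ", path))
  }
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "moa") %in% names(raw))) {
    abort("annotation parser: need columns `compound_id` and `moa`")
  }
  split_field <- function(ids, field) {
    parts <- strsplit(ifelse(is.na(field), "", field), "|", fixed = TRUE)
    parts <- lapply(parts, function(p) unique(trimws(p[nzchar(trimws(p))])))
    tibble::tibble(
      compound_id = rep(ids, lengths(parts)),
      value = unlist(parts, use.names = FALSE)
    )
  }
  ann <- split_field(raw$compound_id, raw$moa)
  names(ann)[2] <- "moa"
  targets <- if ("targets" %in% names(raw)) {
    tg <- split_field(raw$compound_id, raw$targets)
    names(tg)[2] <- "gene"
    tg
  } else {
    tibble::tibble(compound_id = character(), gene = character())
  }
  list(annotations = ann, targets = targets,
       compound_ids = unique(raw$compound_id))
}

#' Composition summary of an annotated compound library
#'
#' @param library A list from [read_compound_annotations()], or a long
#'   annotation tibble (`compound_id`, `moa`).
#' @return Tibble of counts: compounds, unique MoAs, single-MoA compounds,
#'   MoAs with >= 3 and >= 5 co-annotated compounds, compounds with mapped
#'   targets and unique target genes.
#' @export
summarize_library <- function(library) {
  if (is.data.frame(library)) {
    library <- list(annotations = library,
                    targets = tibble::tibble(compound_id = character(),
                                             gene = character()),
                    compound_ids = unique(library$compound_id))
  }
  ann <- library$annotations
  per_cmp <- table(ann$compound_id)
  per_moa <- table(ann$moa)
  tibble::tibble(
    n_compounds = length(library$compound_ids),
    n_moas = length(per_moa),
    n_single_moa_compounds = sum(per_cmp == 1),
    n_multi_moa_compounds = sum(per_cmp > 1),
    n_moas_ge3 = sum(per_moa >= 3),
    n_moas_ge5 = sum(per_moa >= 5),
    n_compounds_with_targets = length(unique(library$targets$compound_id)),
    n_unique_targets = length(unique(library$targets$gene))
  )
}

#' Expression calls from a two-component Gaussian mixture
#'
#' Per replicate, a two-component Gaussian mixture (unequal variances) is
#' fitted to that replicate's probe-set log2 intensity distribution; the
#' replicate's expression threshold is the 95th percentile of the fitted
#' lower-mean ("first mode") component, `mu_1 + 1.645 sigma_1`. A gene is
#' called expressed only if the intensity exceeds the replicate threshold
#' for **all** replicates and **all** of the gene's probe sets.
#'
#' The mixture is fitted by EM (mclust, model `"V"`) initialized from a
#' deterministic quantile-spaced subset of the sorted intensities, so the
#' fit is reproducible without a random seed; on failure a one-variance
#' model is retried before erroring.
#'
#' @param intensities Numeric matrix, probe sets x replicates, log2 scale,
#'   rownames = probe set ids.
#' @param probe_map Data frame with `probe_set` and `gene`.
#' @param conf Percentile of the first component used as threshold
#'   (default 0.95).
#' @return List: `calls` (tibble `gene`, `expressed`), `thresholds` (per
#'   replicate), `mixtures` (per-replicate component parameters).
#' @export
call_expressed <- function(intensities, probe_map, conf = 0.95) {
  if (is.null(rownames(intensities))) {
    abort("expression calling: intensity matrix needs probe-set rownames")
  }
  if (ncol(intensities) < 1L) abort("expression calling: need >= 1 replicate")
  fits <- lapply(seq_len(ncol(intensities)), function(j) {
    .fit_gmm2(intensities[, j][!is.na(intensities[, j])])
  })
  thresholds <- vapply(fits, function(f) {
    qnorm(conf, f$mean[f$low], f$sd[f$low])
  }, numeric(1))

  above <- sweep(intensities, 2, thresholds, `>`)
  probe_ok <- rowSums(above, na.rm = FALSE) == ncol(intensities)
  pm <- probe_map[probe_map$probe_set %in% rownames(intensities), , drop = FALSE]
  ok_by_gene <- tapply(probe_ok[pm$probe_set], pm$gene, function(v) all(!is.na(v) & v))
  calls <- tibble::tibble(
    gene = names(ok_by_gene),
    expressed = as.vector(ok_by_gene)
  )
  list(calls = calls[order(calls$gene), ], thresholds = thresholds,
       mixtures = fits)
}

# 2-component 1-D Gaussian mixture with deterministic quantile-subset init
.fit_gmm2 <- function(x) {
  n <- length(x)
  sub <- order(x)[unique(round(seq(1, n, length.out = min(n, 1000))))]
  fit <- tryCatch(
    Mclust(x, G = 2, modelNames = "V", verbose = FALSE,
           initialization = list(subset = sub)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # retry with an equal-variance model and a coarser init subset
    fit <- tryCatch(
      Mclust(x, G = 2, modelNames = "E", verbose = FALSE,
             initialization = list(subset = order(x)[
               round(seq(1, length(x), length.out = min(length(x), 500)))])),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) abort("expression calling: mixture fit failed to converge")
  mean_ <- as.vector(fit$parameters$mean)
  var_ <- fit$parameters$variance$sigmasq
  if (length(var_) == 1L) var_ <- rep(var_, 2)
  list(mean = mean_, sd = sqrt(var_), weight = fit$parameters$pro,
       low = which.min(mean_))
}

#' Core-fitness gene calls
#'
#' A gene is core-fitness when it causes a proliferation/viability defect
#' in at least two thirds of the tested cell lines (six or more of nine in
#' the standard CRISPR panels).
#'
#' @param defect_matrix Binary (0/1 or logical) matrix, genes x cell lines,
#'   rownames = gene ids.
#' @return Tibble `gene`, `n_defect`, `n_tested`, `core`.
#' @export
call_core_fitness <- function(defect_matrix) {
  m <- defect_matrix * 1
  if (!all(m %in% c(0, 1) | is.na(m))) {
    abort("core-fitness calling: defect matrix must be binary")
  }
  n <- ncol(m)
  n_defect <- rowSums(m == 1, na.rm = TRUE)
  tibble::tibble(
    gene = rownames(m) %||% as.character(seq_len(nrow(m))),
    n_defect = as.integer(n_defect),
    n_tested = n,
    core = n_defect >= ceiling(2 * n / 3)
  )
}

#' Association of phenotypic activity with target expression and fitness
#'
#' Three tests linking compound activity to properties of the annotated
#' targets: (1) Fisher's exact test of active versus having at least one
#' expressed target; (2) Wilcoxon rank-sum comparison of the lowest active
#' concentration between active compounds with and without an expressed
#' target; (3) Fisher's exact test of active versus targeting a
#' core-fitness gene, among compounds with at least one expressed target.
#' Tests whose contingency margins are empty are skipped with a note.
#'
#' @param compound_activity Tibble `compound_id`, `active`, and (for the
#'   Wilcoxon test) `lowest_active_concentration`.
#' @param target_map Tibble `compound_id`, `gene`.
#' @param expression_calls Tibble `gene`, `expressed` (from
#'   [call_expressed()]).
#' @param fitness_calls Optional tibble `gene`, `core` (from
#'   [call_core_fitness()]).
#' @return Tibble `test`, `n`, `estimate`, `p_value`, `note`.
#' @export
activity_association <- function(compound_activity, target_map,
                                 expression_calls, fitness_calls = NULL) {
  tm <- target_map[target_map$compound_id %in% compound_activity$compound_id, ,
                   drop = FALSE]
  if (nrow(tm) == 0L) abort("association error: no compound maps to a target gene")
  expr_genes <- expression_calls$gene[expression_calls$expressed]
  has_expr <- tapply(tm$gene %in% expr_genes, tm$compound_id, any)
  ca <- compound_activity[compound_activity$compound_id %in% names(has_expr), ,
                          drop = FALSE]
  ca$expressed_target <- as.vector(has_expr[ca$compound_id])

  rows <- list()
  tab <- table(active = ca$active, expressed = ca$expressed_target)
  if (all(dim(tab) == c(2, 2))) {
    ft <- fisher.test(tab)
    rows$expr <- tibble::tibble(
      test = "active_vs_expressed_fisher", n = nrow(ca),
      estimate = unname(ft$estimate), p_value = ft$p.value, note = NA_character_)
  } else {
    rows$expr <- tibble::tibble(
      test = "active_vs_expressed_fisher", n = nrow(ca),
      estimate = NA_real_, p_value = NA_real_,
      note = "skipped: empty contingency margin")
  }

  act <- ca[ca$active & !is.na(ca$lowest_active_concentration), , drop = FALSE]
  if (length(unique(act$expressed_target)) == 2L) {
    wt <- wilcox.test(lowest_active_concentration ~ expressed_target, data = act)
    rows$conc <- tibble::tibble(
      test = "lowest_active_conc_vs_expressed_wilcoxon", n = nrow(act),
      estimate = unname(wt$statistic), p_value = wt$p.value, note = NA_character_)
  } else {
    rows$conc <- tibble::tibble(
      test = "lowest_active_conc_vs_expressed_wilcoxon", n = nrow(act),
      estimate = NA_real_, p_value = NA_real_,
      note = "skipped: only one expression group among active compounds")
  }

  if (!is.null(fitness_calls)) {
    core_genes <- fitness_calls$gene[fitness_calls$core]
    has_core <- tapply(tm$gene %in% core_genes, tm$compound_id, any)
    sub <- ca[ca$expressed_target, , drop = FALSE]
    sub$core_target <- as.vector(has_core[sub$compound_id])
    tab2 <- table(active = sub$active, core = sub$core_target)
    if (all(dim(tab2) == c(2, 2))) {
      ft2 <- fisher.test(tab2)
      rows$core <- tibble::tibble(
        test = "active_vs_core_fitness_fisher", n = nrow(sub),
        estimate = unname(ft2$estimate), p_value = ft2$p.value,
        note = NA_character_)
    } else {
      rows$core <- tibble::tibble(
        test = "active_vs_core_fitness_fisher", n = nrow(sub),
        estimate = NA_real_, p_value = NA_real_,
        note = "skipped: empty contingency margin")
    }
  }
  do.call(rbind, rows)
}
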