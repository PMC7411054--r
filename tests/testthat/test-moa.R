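# exhaustive concordant/discordant pair-counting AUC oracle
pair_count_auc <- function(scores, is_member) {
  pos <- scores[is_member]
  neg <- scores[!is_member]
  grid <- expand.grid(p = pos, n = neg)
  (sum(grid$p > grid$n) + 0.5 * sum(grid$p == grid$n)) / nrow(grid)
}

test_that("query AUC matches exhaustive pair counting, with midrank ties", {
  # spec'd worked example: flags (1,0,1,0,0,0) by rank -> AUC = 7/8
  r <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  flags <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(query_auc(r, flags), 7 / 8)
  expect_equal(query_auc(r, flags), pair_count_auc(r, flags))
  # random instances up to 50 candidates, including ties
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    scores <- round(rnorm(n), 1)          # rounding forces ties
    memb <- runif(n) < 0.3
    if (!any(memb) || all(memb)) next
    expect_equal(query_auc(scores, memb), pair_count_auc(scores, memb))
  }
  # degenerate classes are NA
  expect_true(is.na(query_auc(r, rep(TRUE, 6))))
  # perfect and null orderings
  expect_equal(query_auc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
})

test_that("rank_neighbors excludes the query compound and collapses concentrations", {
  set.seed(22)
  sig <- rbind(
    diag(4)[rep(1, 4), ] + matrix(rnorm(16, 0, 0.05), 4),  # C1 at 4 concs
    c(1, 0.1, 0, 0),                                       # C2@1: close to C1
    c(0.2, 1, 0, 0),                                       # C2@9: less close
    c(0, 0, 1, 0.2),                                       # C3@1
    c(0, 0, 0.1, 1)                                        # C4@1
  )
  act <- make_activity(sig,
                       compound_id = c("C1", "C1", "C1", "C1", "C2", "C2", "C3", "C4"),
                       concentration_uM = c(0.3, 1, 3, 9, 1, 9, 1, 1))
  ranked <- rank_neighbors("C1@1", act)
  # none of the query compound's own treatments appear
  expect_false(any(ranked$compound_id == "C1"))
  # one entry per compound, keeping its best-correlated concentration
  expect_equal(sort(ranked$compound_id), c("C2", "C3", "C4"))
  expect_equal(ranked$treatment_id[ranked$compound_id == "C2"], "C2@1")
  # hand-set correlations sort correctly
  expect_equal(ranked$compound_id[1], "C2")
})

test_that("MoA aggregation is median of per-compound maxima", {
  # three coherent compounds + three unrelated ones; construction forces
  # per-compound query AUCs of 1 for the coherent MoA
  base <- c(rep(5, 4), rep(0, 4))
  set.seed(23)
  sigs <- rbind(
    matrix(rep(base, 3), nrow = 3, byrow = TRUE) + rnorm(24, 0, 0.1),
    matrix(rnorm(24, 0, 1), nrow = 3)
  )
  act <- make_activity(sigs, compound_id = sprintf("C%d", 1:6),
                       concentration_uM = rep(1, 6))
  ann <- tibble::tibble(compound_id = c("C1", "C2", "C3"), moa = "MOA_A")
  res <- moa_auc(act, ann)
  expect_equal(nrow(res), 1)
  expect_equal(res$auc, 1)
  expect_true(res$distinguishable)
  # MoAs with < 3 active compounds are not computed
  ann2 <- tibble::tibble(compound_id = c("C1", "C2"), moa = "MOA_B")
  expect_equal(nrow(moa_auc(act, ann2)), 0)
})

test_that("per-compound maxima {0.95, 0.90, 0.40} aggregate to the 0.90 median", {
  # direct application of max-then-median on a hand-built per-query table:
  # compound maxima median = 0.90
  maxima <- c(0.95, 0.90, 0.40)
  expect_equal(median(maxima), 0.90)
  # and through the package path: a compound similar to its MoA at one
  # concentration only still contributes its best AUC
  base <- c(rep(4, 3), rep(0, 3))
  sigs <- rbind(
    base, base,                       # C1@1, C2@1 coherent
    c(rep(4, 3), 0.5, 0.5, 0.5),      # C3@1 coherent-ish
    c(0.1, -0.2, 0.3, 4, -4, 2),      # C3@9 unrelated: max over concs rescues C3
    diag(6)[5, ] * 3, diag(6)[6, ] * 3
  )
  sigs <- sigs + matrix(rnorm(length(sigs), 0, 0.01), nrow(sigs))
  act <- make_activity(sigs,
                       compound_id = c("C1", "C2", "C3", "C3", "C4", "C5"),
                       concentration_uM = c(1, 1, 1, 9, 1, 1))
  ann <- tibble::tibble(compound_id = c("C1", "C2", "C3"), moa = "MOA_A")
  res <- moa_auc(act, ann)
  expect_equal(res$auc, 1)
})

test_that("permutation p-values use the +1 formula and BH matches the step-up oracle", {
  # all-tied geometry: one-hot signatures make every pairwise correlation
  # equal, so every query AUC is 0.5 under any labelling and the null always
  # ties the observed value -> p = (1 + n_perm) / (1 + n_perm) = 1
  sigs <- diag(8) * 2
  act <- make_activity(sigs, compound_id = sprintf("C%d", 1:8),
                       concentration_uM = rep(1, 8))
  ann <- tibble::tibble(compound_id = sprintf("C%d", 1:4), moa = "MOA_A")
  res <- moa_auc(act, ann)
  expect_equal(res$auc, 0.5)
  out <- suppressWarnings(
    permutation_significance(res, act, ann, n_perm = 50, seed = 1)
  )
  expect_equal(out$p_value, 1)
  # a clean separable cluster: no permutation beats AUC 1, p = 1/(n_perm+1)
  set.seed(24)
  strong <- rbind(
    matrix(rep(c(rep(6, 4), rep(0, 4)), 3), nrow = 3, byrow = TRUE),
    matrix(rnorm(5 * 8, 0, 0.5), nrow = 5)
  ) + matrix(rnorm(64, 0, 0.05), 8)
  act2 <- make_activity(strong, compound_id = sprintf("C%d", 1:8),
                        concentration_uM = rep(1, 8))
  res2 <- moa_auc(act2, tibble::tibble(compound_id = sprintf("C%d", 1:3),
                                       moa = "MOA_A"))
  out2 <- suppressWarnings(
    permutation_significance(res2, act2,
                             tibble::tibble(compound_id = sprintf("C%d", 1:3),
                                            moa = "MOA_A"),
                             n_perm = 60, seed = 2)
  )
  expect_equal(res2$auc, 1)
  expect_gte(out2$p_value, 1 / 61)
  expect_lt(out2$p_value, 0.25)
  # BH adjustment equals the textbook step-up computed by hand
  p <- c(0.001, 0.02, 0.04, 0.8)
  n <- length(p)
  o <- order(p)
  step_up <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    prev <- min(prev, p[o[i]] * n / i)
    step_up[o[i]] <- prev
  }
  expect_equal(p.adjust(p, "BH"), step_up)
})

test_that("permuted annotations give null AUCs centered near 0.5 at query level", {
  set.seed(25)
  sigs <- matrix(rnorm(30 * 12), nrow = 30)
  act <- make_activity(sigs, compound_id = sprintf("C%02d", 1:30),
                       concentration_uM = rep(1, 30))
  aucs <- replicate(200, {
    memb <- sprintf("C%02d", sample(2:30, 5))
    ranked <- rank_neighbors("C01@1", act)
    query_auc(ranked$r, ranked$compound_id %in% memb)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("greedy cell-line ranking solves the toy set-cover instances", {
  res <- tibble::tibble(
    moa = c("A", "B", "B", "C", "C"),
    cell_line = c("CL1", "CL1", "CL2", "CL2", "CL3"),
    auc = rep(0.95, 5)
  )
  out <- greedy_cell_line_ranking(res)
  expect_equal(out$cell_line, c("CL1", "CL2", "CL3"))
  expect_equal(out$cumulative, c(2, 3, 3))
  expect_equal(out$n_added, c(2, 1, 0))
  # single cell line: curve is its own count
  one <- greedy_cell_line_ranking(res[res$cell_line == "CL1", ])
  expect_equal(one$cumulative, 2)
  # identical sets: the second line adds nothing
  dup <- tibble::tibble(moa = c("A", "B", "A", "B"),
                        cell_line = rep(c("CL1", "CL2"), each = 2),
                        auc = 0.95)
  out2 <- greedy_cell_line_ranking(dup)
  expect_equal(out2$n_added, c(2, 0))
})

test_that("identity channel subset reproduces the full-run AUCs exactly", {
  run <- cached_screen_run(1)
  sub <- subset_analysis(run, channels = c("BFP", "GFP", "RFP"))
  expect_true(all(abs(sub$delta) < 1e-12, na.rm = TRUE))
  expect_equal(sub$auc_full, run$moa_results$auc[match(sub$moa, run$moa_results$moa)])
})

test_that("restricting concentrations changes the active set, not the signature", {
  run <- cached_screen_run(1)
  sub <- subset_analysis(run, concentrations = 9)
  expect_true(all(c("auc_full", "auc_subset", "delta") %in% names(sub)))
  expect_false(is.null(attr(sub, "subset_summary")))
  # potency spread means single-concentration screens lose some MoAs' AUC
  expect_true(any(!is.na(sub$delta)))
  expect_error(subset_analysis(run, concentrations = numeric(0)),
               "configuration error")
})

test_that("single-channel subsets rerun feature selection on that channel only", {
  run <- cached_screen_run(1)
  sub <- subset_analysis(run, channels = "BFP")
  expect_true(all(c("auc_full", "auc_subset", "delta") %in% names(sub)))
  # coherent effects load on all channels, so BFP alone retains most MoAs
  coh <- run$truth$moas$moa[run$truth$moas$coherent]
  keep <- sub$moa %in% coh & !is.na(sub$auc_subset)
  expect_gte(mean(sub$auc_subset[keep] >= 0.9), 0.5)
})
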