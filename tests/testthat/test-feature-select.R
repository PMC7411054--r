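test_that("prefilter removes DMSO-like wells, low-count wells, and clips outliers", {
  set.seed(1)
  n_ctrl <- 40
  ctrl <- make_profiles(matrix(rnorm(n_ctrl * 3, 0, 1), ncol = 3),
                        is_control = TRUE)
  far <- make_profiles(matrix(rnorm(20 * 3, 8, 1), ncol = 3),
                       compound_id = "C0002")
  far$well <- sprintf("B%d", 1:20)
  near <- make_profiles(matrix(0, 1, 3), compound_id = "C0003")  # distance ~0
  near$well <- "C1"
  low <- make_profiles(matrix(rnorm(2 * 3, 8, 1), ncol = 3),
                       compound_id = "C0004", n_live = c(99L, 100L))
  low$well <- c("D1", "D2")
  prof <- rbind(ctrl, far, near, low)
  out <- prefilter_wells(prof)
  expect_false("C1" %in% out$well)          # identical to control mean
  expect_false("D1" %in% out$well)          # 99 cells: removed
  expect_true("D2" %in% out$well)           # 100 cells: retained
  expect_true(all(sprintf("B%d", 1:20) %in% out$well))
  # winsorization: the post-filter max equals the 99th percentile of the
  # retained wells' raw values (brute-force percentile oracle)
  kept_raw <- prof[prof$well %in% out$well, ][["d01"]]
  expect_equal(max(out$d01), unname(quantile(kept_raw, 0.99, type = 7)))
  expect_equal(min(out$d01), unname(quantile(kept_raw, 0.01, type = 7)))
})

test_that("prefilter errors when every well is removed", {
  ctrl <- make_profiles(matrix(rnorm(60), ncol = 3), is_control = TRUE,
                        n_live = 50L)
  expect_error(prefilter_wells(ctrl), "empty-selection")
})

test_that("relevance matches one-way ANOVA and is scaled to max 1", {
  set.seed(2)
  g <- rep(c("C0001@1", "C0002@1", "C0003@1"), each = 2)
  x <- cbind(
    d01 = rnorm(6),                                  # noise
    d02 = rep(c(0, 3, 6), each = 2) + rnorm(6, 0, 0.1),  # strong separation
    d03 = rep(1, 6)                                  # constant
  )
  prof <- make_profiles(x, compound_id = sub("@1", "", g))
  rel <- compute_relevance(prof)
  oracle <- aov_relevance(prof[, c(setdiff(names(prof), "d03"))])
  expect_equal(rel[["d02"]], 1)
  expect_equal(rel[["d03"]], 0)  # constant feature: F = 0
  expect_equal(unname(rel[c("d01", "d02")]), unname(oracle[c("d01", "d02")]),
               tolerance = 1e-8)
  expect_true(all(rel >= 0 & rel <= 1))
})

test_that("hand-computed three-treatment ANOVA F agrees", {
  # 3 treatments x 2 wells, values chosen for hand computation
  x <- matrix(c(1, 2, 4, 6, 9, 11), ncol = 1, dimnames = list(NULL, "d01"))
  prof <- make_profiles(x, compound_id = rep(c("C1", "C2", "C3"), each = 2))
  g <- factor(prof$treatment_id)
  f_oracle <- summary(stats::aov(x[, 1] ~ g))[[1]][["F value"]][1]
  # grand mean 5.5; group means 1.5, 5, 10; SSB = 2*(16+0.25+20.25) = 73
  # SSW = 0.5 + 2 + 2 = 4.5; F = (73/2)/(4.5/3)
  expect_equal(f_oracle, (73 / 2) / (4.5 / 3))
  rel <- compute_relevance(prof, groups = g)
  expect_equal(rel[["d01"]], 1)  # single feature attains the max
})

test_that("mRMR ranking equals the brute-force greedy oracle", {
  set.seed(3)
  n <- 40
  base1 <- rep(seq(0, 3, length.out = 8), each = 5)
  base2 <- rep(c(0, 2, 0, 2, 1, 3, 1, 3), each = 5)
  x <- cbind(
    d01 = base1 + rnorm(n, 0, 0.3),   # informative
    d02 = base2 + rnorm(n, 0, 0.3),   # informative, partly independent
    d03 = base1 + rnorm(n, 0, 0.3),   # near-duplicate of d01
    d04 = rnorm(n),                   # noise
    d05 = rnorm(n)                    # noise
  )
  prof <- make_profiles(x, compound_id = rep(sprintf("C%d", 1:8), each = 5))
  rel <- compute_relevance(prof)
  ranking <- mrmr_rank(prof, rel)
  expect_equal(ranking$feature, greedy_mrmr_oracle(prof, rel))
  # step 1 selects the relevance argmax with redundancy 0 and score = relevance
  expect_equal(ranking$feature[1], names(which.max(rel)))
  expect_equal(ranking$redundancy[1], 0)
  expect_equal(ranking$score, ranking$relevance * (1 - ranking$redundancy))
})

test_that("an exact duplicate has redundancy 1 and ranks after positive scores", {
  set.seed(4)
  g <- rep(sprintf("C%d", 1:5), each = 4)
  sig <- rep(1:5, each = 4)
  x <- cbind(d01 = sig + rnorm(20, 0, 0.1), d03 = rnorm(20))
  x <- cbind(x, d02 = x[, "d01"])  # exact duplicate of d01
  prof <- make_profiles(x[, c("d01", "d02", "d03")], compound_id = g)
  rel <- compute_relevance(prof)
  ranking <- mrmr_rank(prof, rel)
  dup_step <- which(ranking$feature == "d02")
  expect_equal(ranking$redundancy[dup_step], 1)
  expect_equal(ranking$score[dup_step], 0)
  expect_gt(dup_step, which(ranking$feature == "d03"))
})

test_that("replicate AUC separates perfect replicates and is 0.5 under shuffling", {
  set.seed(5)
  n_trt <- 10
  centers <- matrix(rnorm(n_trt * 12, 0, 3), nrow = n_trt)
  x <- centers[rep(1:n_trt, each = 2), ] + rnorm(2 * n_trt * 12, 0, 0.05)
  prof <- make_profiles(x, compound_id = rep(sprintf("C%d", 1:n_trt), each = 2))
  out <- replicate_auc(prof, descriptor_names(prof), seed = 1)
  expect_equal(out$mean, 1.0)
  # destroying the replicate structure pushes the AUC to ~0.5
  prof_shuffled <- prof
  set.seed(6)
  prof_shuffled$treatment_id <- sample(prof$treatment_id)
  prof_shuffled$compound_id <- sub("@.*", "", prof_shuffled$treatment_id)
  out0 <- replicate_auc(prof_shuffled, descriptor_names(prof), seed = 1)
  expect_lt(abs(out0$mean - 0.5), 0.15)
})

test_that("replicate AUC equals the exhaustive all-pairs Mann-Whitney on 20 wells", {
  set.seed(7)
  g <- rep(sprintf("C%d", 1:5), each = 4)
  x <- matrix(rnorm(20 * 6), nrow = 20) +
    matrix(rnorm(5 * 6, 0, 1.5), nrow = 5)[rep(1:5, each = 4), ]
  prof <- make_profiles(x, compound_id = g)
  out <- replicate_auc(prof, descriptor_names(prof), max_pairs = 1e6,
                       repeats = 2, seed = 1)
  # oracle: all pairs, Pearson r, Wilcoxon rank-sum statistic / (n1 n0)
  pairs <- t(combn(20, 2))
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    cor(x[pairs[i, 1], ], x[pairs[i, 2], ])
  }, numeric(1))
  is_rep <- g[pairs[, 1]] == g[pairs[, 2]]
  w <- stats::wilcox.test(r[is_rep], r[!is_rep], exact = FALSE)$statistic
  auc_oracle <- unname(w) / (sum(is_rep) * sum(!is_rep))
  expect_equal(out$mean, auc_oracle, tolerance = 1e-12)
  expect_equal(out$sd, 0)  # pair sets are exhaustive, hence identical per repeat
})

test_that("the one-SD stopping rule picks the minimal size within the band", {
  curve <- data.frame(size = c(5, 10, 20),
                      mean_auc = c(0.80, 0.90, 0.91),
                      sd_auc = c(0.01, 0.02, 0.02))
  expect_equal(choose_signature_size(curve), 10)
  # constant curve with zero SD: minimality forces the smallest size
  flat <- data.frame(size = c(2, 5, 10), mean_auc = 0.9, sd_auc = 0)
  expect_equal(choose_signature_size(flat), 2)
})

test_that("select_signature evaluates the curve consistently with replicate_auc", {
  set.seed(8)
  n_trt <- 12
  centers <- matrix(rnorm(n_trt * 10, 0, 2), nrow = n_trt)
  x <- centers[rep(1:n_trt, each = 4), ] + rnorm(4 * n_trt * 10, 0, 0.5)
  prof <- make_profiles(x, compound_id = rep(sprintf("C%d", 1:n_trt), each = 4))
  rel <- compute_relevance(prof)
  ranking <- mrmr_rank(prof, rel)
  # sizes >= 3: with two features the pair correlation is exactly +/-1 and
  # the AUC is then determined entirely by float-level tie breaking
  sig <- select_signature(ranking, prof, sizes = c(3, 5, 7, 10),
                          max_pairs = 1e6, repeats = 3, seed = 9)
  expect_s3_class(sig, "signature_spec")
  expect_equal(sig$features, ranking$feature[seq_len(sig$k)])
  expect_equal(sig$k, choose_signature_size(sig$curve))
  # exhaustive pairs: the curve point at each size matches replicate_auc
  for (i in seq_len(nrow(sig$curve))) {
    ra <- replicate_auc(prof, ranking$feature[seq_len(sig$curve$size[i])],
                        max_pairs = 1e6, repeats = 1, seed = 1)
    expect_equal(sig$curve$mean_auc[i], ra$mean, tolerance = 1e-10)
  }
})

test_that("mRMR recovers planted informative structure on synthetic screens", {
  cfg <- small_config(n_compounds = 16, n_moas = 4,
                      moa_size_distribution = rep(4, 4), seed = 21,
                      n_features = 40, n_redundant_blocks = 4,
                      redundant_block_size = 2, n_noise_features = 8,
                      cells_per_well_mean = 200)
  run <- suppressWarnings(run_screen(cfg, n_perm = 0))
  f <- run$truth$features
  top <- head(run$signature$ranking$feature, 15)
  raw <- sub("_(mean|median)$", "", top)
  raw <- raw[raw != "cell_count"]
  roles <- f$role[match(raw, f$feature)]
  expect_gte(mean(roles == "informative"), 0.8)
  # at most one member per redundant block among the top selections
  red <- f[f$role == "redundant", ]
  blocks <- c(stats::setNames(red$parent, red$feature),
              stats::setNames(unique(red$parent), unique(red$parent)))
  in_blocks <- blocks[raw[raw %in% names(blocks)]]
  expect_true(all(table(in_blocks) <= 1))
})
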