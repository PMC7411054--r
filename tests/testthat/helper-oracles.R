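# independent brute-force oracles used by several test files ---------------

# one-way ANOVA F per descriptor via stats::aov, scaled by the max
aov_relevance <- function(profiles) {
  desc <- descriptor_names(profiles)
  g <- factor(profiles$treatment_id)
  f <- vapply(desc, function(d) {
    summary(stats::aov(profiles[[d]] ~ g))[[1]][["F value"]][1]
  }, numeric(1))
  f / max(f)
}

# greedy mRMR recomputing redundancy from scratch at every step
greedy_mrmr_oracle <- function(profiles, relevance) {
  x <- as.matrix(as.data.frame(profiles)[, names(relevance)])
  feats <- names(relevance)
  selected <- character(0)
  remaining <- feats
  while (length(remaining) > 0) {
    scores <- vapply(remaining, function(f) {
      red <- if (length(selected) == 0) 0 else {
        max(vapply(selected, function(s) abs(cor(x[, f], x[, s])), numeric(1)))
      }
      relevance[[f]] * (1 - red)
    }, numeric(1))
    best <- remaining[order(-scores, match(remaining, feats))][1]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}
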