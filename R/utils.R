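#' @importFrom rlang %||% abort warn hash .data
#' @importFrom dplyr group_by summarise arrange
#' @importFrom mclust Mclust mclustBIC
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile cor median rnorm rbinom rnbinom rlnorm runif
#' @importFrom stats sd var pnorm qnorm p.adjust fisher.test wilcox.test
#' @importFrom utils head read.csv write.csv
#' @import data.table
NULL

# metadata columns of well-profile tables; every other column is a descriptor
.meta_cols <- c(
  "plate_id", "batch_id", "well", "well_row", "well_col", "compound_id",
  "concentration_uM", "is_control", "treatment_id", "n_live"
)

#' Descriptor column names of a well-profile table
#'
#' Well profiles are plain data frames whose non-metadata columns are the
#' numeric descriptors (per raw feature a mean and a median, plus the live
#' cell count). This helper returns the descriptor columns in table order.
#'
#' @param profiles A well-profile data frame.
#' @return Character vector of descriptor column names.
#' @export
descriptor_names <- function(profiles) {
  setdiff(names(profiles), .meta_cols)
}

# numeric matrix of descriptors, rows = wells
.descriptor_matrix <- function(profiles, features = NULL) {
  features <- features %||% descriptor_names(profiles)
  missing <- setdiff(features, names(profiles))
  if (length(missing) > 0) {
    abort(paste0("descriptors absent from profiles: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  as.matrix(as.data.frame(profiles)[, features, drop = FALSE])
}

# deterministic child seed for a pipeline stage; keeps seeds < 2^31
.child_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + 104729 * offset) %% 2147483647
}

# empirical quantile convention used for all thresholds (tau, rho_null,
# winsorization limits): linear interpolation between order statistics
.quantile <- function(x, p) {
  unname(quantile(x, p, type = 7, names = FALSE, na.rm = TRUE))
}

# treatment identifier: compound at a concentration; controls are "DMSO"
.treatment_id <- function(compound_id, concentration_uM) {
  ifelse(compound_id == "DMSO", "DMSO",
         paste0(compound_id, "@", concentration_uM))
}

# Pearson correlation between paired rows of a wells x features matrix,
# computed over the feature axis. `a`, `b` are row indices of equal length.
.pair_cor <- function(mat, a, b) {
  z <- mat - rowMeans(mat)
  ss <- sqrt(rowSums(z^2))
  num <- rowSums(z[a, , drop = FALSE] * z[b, , drop = FALSE])
  num / (ss[a] * ss[b])
}

# rank-based (Mann-Whitney) AUC: probability a positive score outranks a
# negative one, ties credited at 0.5 via midranks
.rank_auc <- function(pos, neg) {
  n1 <- length(pos)
  n0 <- length(neg)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
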