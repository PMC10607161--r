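# Gene-family (functional) analysis: zeroing against the 'all' fraction,
# renormalisation, prevalence filtering, CLR and PCA, plus coating
# probability ratios of gene families.

#' Zero gene families absent from a participant's 'all' fraction
#'
#' For each participant, any gene family with zero abundance in the 'all'
#' fraction is zeroed in that participant's antibody-positive and -negative
#' fraction columns. Presence is `value > 0` on the raw (RPK or abundance)
#' scale.
#'
#' @param tables Named list with family-by-samples matrices `all`,
#'   `igg_pos`, `igg_neg`, sharing identifiers.
#' @return The list with `igg_pos` and `igg_neg` zeroed where required.
#' @export
zero_families_absent_in_all <- function(tables) {
  missing <- setdiff(FRACTION_LABELS, names(tables))
  if (length(missing)) {
    stop("gene-family bundle is missing fraction(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_aligned(tables$igg_pos, tables$igg_neg, c("igg_pos", "igg_neg"))
  check_aligned(tables$igg_pos, tables$all, c("igg_pos", "all"))
  absent <- tables$all == 0
  tables$igg_pos[absent] <- 0
  tables$igg_neg[absent] <- 0
  tables
}

#' Renormalise gene-family columns to relative abundances
#'
#' Per-column total-sum scaling of community-level gene-family rows,
#' mirroring RPK-to-relative-abundance conversion. Columns with no signal
#' raise an error naming the sample.
#'
#' @param table Family-by-samples matrix.
#' @return Matrix with columns summing to 1.
#' @export
renormalise_families <- function(table) {
  total_sum_scale(table)
}

#' Discard gene families below threshold in too many samples
#'
#' A family is kept only if it falls at or below `threshold` in fewer than
#' `max_below` samples.
#'
#' @param table Family-by-samples abundance matrix.
#' @param threshold Detection threshold (default 1e-6).
#' @param max_below Families below threshold in at least this many samples
#'   are discarded (default 7).
#' @return Filtered matrix.
#' @export
prevalence_filter <- function(table, threshold = 1e-6, max_below = 7) {
  validate_abundance_matrix(table, "gene-family table")
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  n_below <- rowSums(table <= threshold)
  table[n_below < max_below, , drop = FALSE]
}

#' Centred log-ratio transform
#'
#' Per sample (column), `log(x_i) - mean(log(x))`. Compositions must be
#' strictly positive; if zeros are present and no pseudocount is supplied,
#' half the smallest non-zero value in the table is added to every cell
#' first.
#'
#' @param table Feature-by-samples matrix of positive abundances.
#' @param pseudocount Constant added before the transform; `NULL` (default)
#'   auto-selects half the minimum positive value when zeros exist, 0
#'   disables the adjustment.
#' @return CLR-transformed matrix; each column sums to zero.
#' @export
clr_transform <- function(table, pseudocount = NULL) {
  validate_abundance_matrix(table, "abundance table")
  if (is.null(pseudocount)) {
    pseudocount <- if (any(table <= 0)) min(table[table > 0]) / 2 else 0
  }
  x <- table + pseudocount
  if (any(x <= 0)) {
    stop("CLR requires strictly positive values; supply a pseudocount",
         call. = FALSE)
  }
  logs <- log(x)
  sweep(logs, 2, colMeans(logs), "-")
}

#' Principal component analysis of a feature table
#'
#' Centres samples internally and computes PCs ordered by decreasing
#' variance. Signs follow the convention that each component's
#' largest-magnitude loading is positive, making results deterministic.
#'
#' @param table Feature-by-samples matrix (samples become PCA observations).
#' @param n_components Number of components to return; defaults to all.
#' @return List with `scores` (samples x k), `loadings` (features x k) and
#'   `explained_variance` (fraction of total variance per component).
#' @export
pca <- function(table, n_components = NULL) {
  x <- t(table)                       # samples as observations
  if (nrow(x) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  max_k <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- max_k
  if (n_components > max_k) {
    stop("n_components exceeds the available dimensions (", max_k, ")",
         call. = FALSE)
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(fit$sdev^2)
  if (total_var == 0) {
    stop("all samples are identical: zero total variance", call. = FALSE)
  }
  k <- seq_len(n_components)
  scores <- fit$x[, k, drop = FALSE]
  loadings <- fit$rotation[, k, drop = FALSE]
  for (j in k) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings,
       explained_variance = (fit$sdev^2 / total_var)[k])
}

#' Coating probability ratios of gene families
#'
#' Delegates to [prob_ratio()] with the gene-family pseudocount, marking
#' families undetected in both fractions of a sample as undefined, then
#' keeps only the families with a defined ratio in every sample.
#'
#' @param pos,neg Processed (zeroed, renormalised, thresholded) gene-family
#'   relative-abundance matrices.
#' @param flow Flow summary with fraction sizes.
#' @param pseudocount Pseudocount (default 6e-10).
#' @param scale Scale fraction sizes by the per-sample maximum.
#' @return Probability-ratio matrix restricted to families scored in all
#'   samples.
#' @export
gene_family_prob_ratio <- function(pos, neg, flow, pseudocount = 6e-10,
                                   scale = TRUE) {
  ratios <- prob_ratio(pos, neg, flow, pseudocount = pseudocount,
                       scale = scale, na_when_absent = TRUE)
  select_common_features(ratios, rule = "defined")
}
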