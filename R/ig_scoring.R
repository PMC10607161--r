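# Probability-ratio scoring of antibody coating from sorted fractions.
#
# The score asks, for each taxon, how much more likely one of its cells is
# to be found in the antibody-bound fraction than the unbound one. A taxon's
# relative abundance within a sorted fraction times that fraction's size (as
# a proportion of all SYBR+ events) estimates the joint probability that a
# random cell belongs to the taxon AND lands in that fraction; the log2
# ratio of the two joint probabilities is therefore independent of the
# taxon's overall abundance and converges to log2(theta/(1-theta)) for
# coating probability theta.

#' Log2 antibody-coating probability ratio
#'
#' For taxon (or gene family) i in sample j,
#' `ratio_ij = log2((pos_ij * S+_j + c) / (neg_ij * S-_j + c))`
#' where `pos_ij`/`neg_ij` are relative abundances within the sorted
#' fractions, `S+_j`/`S-_j` are the fraction sizes and `c` is a pseudocount.
#' With `scale = TRUE` the two fraction sizes are first divided by the
#' larger of the two, which leaves the c -> 0 ratio unchanged while keeping
#' the pseudocount on a comparable scale across samples.
#'
#' @param pos,neg Aligned feature-by-sample relative-abundance matrices for
#'   the antibody-positive and antibody-negative fractions.
#' @param flow Flow summary providing `igg_pos_size` and `igg_neg_size` per
#'   sample (proportions of SYBR+ events).
#' @param pseudocount Pseudocount `c`; must be > 0 (default 1e-5, the value
#'   used for species tables; use 6e-10 for gene families).
#' @param scale Divide both fraction sizes by the larger of the two
#'   (default TRUE).
#' @param na_when_absent If TRUE, cells where both fractions are zero are
#'   reported as NA (score undefined for an undetected feature) instead of
#'   log2(c/c) = 0.
#' @return Matrix of log2 probability ratios with a `pseudocount` attribute.
#' @export
prob_ratio <- function(pos, neg, flow, pseudocount = 1e-5, scale = TRUE,
                       na_when_absent = FALSE) {
  validate_abundance_matrix(pos, "'positive' fraction table")
  check_aligned(pos, neg, c("positive", "negative"))
  if (pseudocount <= 0) {
    stop("pseudocount must be > 0 to keep ratios finite", call. = FALSE)
  }
  s_pos <- flow_lookup(flow, colnames(pos), "igg_pos_size")
  s_neg <- flow_lookup(flow, colnames(pos), "igg_neg_size")
  if (scale) {
    larger <- pmax(s_pos, s_neg)
    if (any(larger <= 0)) {
      stop("cannot scale fraction sizes: both are zero for sample(s) ",
           paste(colnames(pos)[larger <= 0], collapse = ", "), call. = FALSE)
    }
    s_pos <- s_pos / larger
    s_neg <- s_neg / larger
  }
  num <- sweep(pos, 2, s_pos, "*") + pseudocount
  den <- sweep(neg, 2, s_neg, "*") + pseudocount
  # log2(num) - log2(den), not log2(num/den): makes antisymmetry under a
  # pos/neg swap exact in floating point
  ratio <- log2(num) - log2(den)
  if (na_when_absent) ratio[pos == 0 & neg == 0] <- NA_real_
  structure(ratio, pseudocount = pseudocount, scaled = scale)
}

#' Classify taxa by sorted-fraction presence
#'
#' A taxon is present in a fraction when its relative abundance there
#' exceeds `threshold`. Detected taxa are partitioned per sample into
#' only-negative, only-positive and both; the proportion recognised by the
#' antibody is `(only_pos + both) / total detected`, reported to 3 decimals
#' (NA when nothing is detected).
#'
#' @param pos,neg Aligned sorted-fraction relative-abundance matrices.
#' @param threshold Detection threshold (default 1e-5).
#' @return Data frame with one row per sample: `sample_id`, `n_only_neg`,
#'   `n_only_pos`, `n_both`, `proportion_pos`.
#' @export
classify_fraction_presence <- function(pos, neg, threshold = 1e-5) {
  validate_abundance_matrix(pos, "'positive' fraction table")
  check_aligned(pos, neg, c("positive", "negative"))
  in_pos <- pos > threshold
  in_neg <- neg > threshold
  n_only_neg <- colSums(in_neg & !in_pos)
  n_only_pos <- colSums(in_pos & !in_neg)
  n_both <- colSums(in_pos & in_neg)
  data.frame(sample_id = colnames(pos),
             n_only_neg = n_only_neg,
             n_only_pos = n_only_pos,
             n_both = n_both,
             proportion_pos = presence_proportion(n_only_neg, n_only_pos,
                                                  n_both),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proportion of detected taxa recognised by the antibody
#'
#' Computes `(n_only_pos + n_both) / (n_only_neg + n_only_pos + n_both)`
#' from presence-count triples, rounded to 3 decimals; NA when no taxon is
#' detected in either fraction.
#'
#' @param n_only_neg,n_only_pos,n_both Presence counts per sample.
#' @return Numeric vector of proportions.
#' @export
presence_proportion <- function(n_only_neg, n_only_pos, n_both) {
  total <- n_only_neg + n_only_pos + n_both
  out <- ifelse(total > 0, round((n_only_pos + n_both) / total, 3),
                NA_real_)
  unname(out)
}

#' Features detected in every sample
#'
#' Restricts a feature-by-sample matrix to the features observed in all
#' samples: abundance above `threshold` everywhere, or — for a ratio matrix
#' with NA marking undefined scores — a defined value everywhere.
#'
#' @param x Feature-by-sample matrix (abundances or probability ratios).
#' @param threshold Detection threshold for the "detected" rule (default 0).
#' @param rule "detected" keeps features with abundance above `threshold` in
#'   every sample; "defined" keeps features with a non-NA value in every
#'   sample (for ratio matrices, where any real value is a valid score).
#' @return The subset of rows detected in every sample (may be empty, with a
#'   warning).
#' @export
select_common_features <- function(x, threshold = 0,
                                   rule = c("detected", "defined")) {
  rule <- match.arg(rule)
  if (ncol(x) < 1) stop("at least one sample is required", call. = FALSE)
  keep <- if (rule == "defined") {
    rowSums(is.na(x)) == 0
  } else {
    rowSums(!is.na(x) & x > threshold) == ncol(x)
  }
  if (!any(keep)) {
    warning("no feature is detected in every sample")
  }
  x[keep, , drop = FALSE]
}

#' Isotype-normalise sorted fraction sizes
#'
#' Subtracts the isotype-control background from the reported
#' antibody-positive fraction size (both as proportions of SYBR+ events),
#' flooring at zero. Applied before scoring so that non-specific staining
#' does not inflate coating estimates.
#'
#' @param flow Flow summary data frame.
#' @return Flow summary with corrected `igg_pos_size`.
#' @export
normalise_flow_isotype <- function(flow) {
  validate_flow(flow)
  flow$igg_pos_size <-
    isotype_normalise(100 * flow$igg_pos_size, flow$isotype_pct) / 100
  flow
}
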