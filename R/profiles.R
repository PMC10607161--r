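# Relative (RMP) and quantitative (QMP) microbiome profiles.

#' Relative microbiome profile from 'all'-fraction counts
#'
#' Total-sum scales the 'all'-fraction counts, then applies the detection
#' threshold and pseudocount used for community profiling.
#'
#' @param all_counts Taxa-by-samples count matrix from the 'all' fraction.
#' @param threshold Detection threshold (default 1e-6).
#' @param pseudocount Pseudocount added after thresholding (default 1e-7).
#' @return Relative-abundance matrix.
#' @export
rmp <- function(all_counts, threshold = 1e-6, pseudocount = 1e-7) {
  apply_threshold(total_sum_scale(all_counts), threshold, pseudocount)
}

#' Quantitative microbiome profile (cells per gram)
#'
#' Multiplies each sample's relative abundances by its flow-cytometric
#' microbial load: `absolute_ij = RA_ij * load_j`. Because the default input
#' is a thresholded, pseudocounted RMP, column sums deviate slightly from the
#' load; set `renormalise = TRUE` to rescale each column to sum to 1 first.
#'
#' @param rmp_table Relative-abundance matrix (typically from [rmp()]).
#' @param flow Flow summary data frame with `sample_id` and `microbial_load`.
#' @param renormalise Rescale columns to sum to 1 before conversion.
#' @return Matrix of absolute abundances in cells/gram.
#' @export
qmp <- function(rmp_table, flow, renormalise = FALSE) {
  validate_abundance_matrix(rmp_table, "relative-abundance table")
  loads <- flow_lookup(flow, colnames(rmp_table), "microbial_load")
  if (anyNA(loads)) {
    stop("missing microbial_load for sample(s): ",
         paste(colnames(rmp_table)[is.na(loads)], collapse = ", "),
         call. = FALSE)
  }
  if (renormalise) {
    rmp_table <- sweep(rmp_table, 2, colSums(rmp_table), "/")
  }
  sweep(rmp_table, 2, loads, "*")
}

#' Stool water content
#'
#' `100 * (wet - dry) / wet`, in percent.
#'
#' @param wet_weight,dry_weight Weights in grams; `0 < dry <= wet`.
#' @return Water content percentage(s).
#' @export
water_content <- function(wet_weight, dry_weight) {
  if (any(wet_weight <= 0)) stop("wet_weight must be > 0", call. = FALSE)
  if (any(dry_weight < 0)) stop("dry_weight must be >= 0", call. = FALSE)
  if (any(dry_weight > wet_weight)) {
    stop("dry_weight cannot exceed wet_weight", call. = FALSE)
  }
  100 * (wet_weight - dry_weight) / wet_weight
}
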