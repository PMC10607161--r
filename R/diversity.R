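# Alpha and beta diversity. Index computations are delegated to vegan, the
# standard community-ecology toolkit; this module fixes orientations
# (taxa x samples in, per-sample results out) and adds the analytic /
# Monte-Carlo rarefaction pair used in tests.

# Accept either a single abundance vector or a taxa-by-samples matrix.
per_sample <- function(x, f) {
  if (is.matrix(x)) {
    apply(x, 2, f)
  } else {
    f(x)
  }
}

check_positive_sum <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (sum(x) <= 0) stop("abundances sum to zero", call. = FALSE)
  invisible(x)
}

#' Shannon diversity index
#'
#' `-sum(p_i * log(p_i))` over taxa with positive abundance, in natural-log
#' units by default. Invariant to rescaling, so counts and proportions give
#' the same value.
#'
#' @param abundances Non-negative vector, or taxa-by-samples matrix for
#'   per-sample results.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index (nats by default), one value per sample.
#' @export
shannon <- function(abundances, base = exp(1)) {
  per_sample(abundances, function(x) {
    check_positive_sum(x)
    vegan::diversity(x, index = "shannon", base = base)
  })
}

#' Inverse Simpson index
#'
#' `1 / sum(p_i^2)`: the effective number of equally abundant taxa.
#'
#' @inheritParams shannon
#' @return Inverse Simpson index, one value per sample.
#' @export
inv_simpson <- function(abundances) {
  per_sample(abundances, function(x) {
    check_positive_sum(x)
    vegan::diversity(x, index = "invsimpson")
  })
}

#' Expected species richness after rarefaction
#'
#' The default analytic mode returns the hypergeometric expectation of the
#' number of species observed when `depth` reads are drawn without
#' replacement: `sum_i [1 - choose(N - N_i, depth) / choose(N, depth)]`.
#' The Monte-Carlo mode subsamples reads without replacement `n_rep` times
#' and averages the observed richness; it converges to the analytic value.
#'
#' @param counts Non-negative integer read counts (single sample), or a
#'   taxa-by-samples matrix.
#' @param depth Rarefaction depth; must not exceed any sample's total.
#' @param method "analytic" (default) or "montecarlo".
#' @param n_rep Monte-Carlo replicates (default 1000).
#' @param seed Seed for the Monte-Carlo mode.
#' @return Expected richness, one value per sample.
#' @export
rarefied_richness <- function(counts, depth, method = c("analytic",
                                                        "montecarlo"),
                              n_rep = 1000, seed = 1) {
  method <- match.arg(method)
  per_sample(counts, function(x) {
    check_positive_sum(x)
    if (depth > sum(x)) {
      stop("rarefaction depth ", depth, " exceeds sample total ", sum(x),
           call. = FALSE)
    }
    if (method == "analytic") {
      # vegan::rarefy warns when deep counts lack singletons; expected here
      withCallingHandlers(
        as.numeric(vegan::rarefy(round(x), depth)),
        warning = function(w) {
          if (grepl("observed count data", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      )
    } else {
      set.seed(seed)
      reads <- rep(seq_along(x), times = round(x))
      mean(vapply(seq_len(n_rep), function(i) {
        length(unique(sample(reads, depth)))
      }, numeric(1)))
    }
  })
}

#' Lowest sequencing depth across samples
#'
#' Convenience for rarefying a cohort to its minimum total read count.
#'
#' @param counts Taxa-by-samples count matrix, or a list of such matrices
#'   (e.g. one per fraction) for a cohort-wide minimum.
#' @return The smallest column total.
#' @export
min_depth <- function(counts) {
  if (is.list(counts)) {
    min(vapply(counts, function(m) min(colSums(m)), numeric(1)))
  } else {
    min(colSums(counts))
  }
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = 1 - 2 * sum(min(x_i, y_i)) / sum(x_i + y_i)` for every sample
#' pair.
#'
#' @param table Taxa-by-samples abundance matrix (>= 2 samples).
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  validate_abundance_matrix(table, "abundance table")
  if (ncol(table) < 2) stop("need at least 2 samples", call. = FALSE)
  as.matrix(vegan::vegdist(t(table), method = "bray"))
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Runs vegan's NMDS (monotone-regression stress minimisation) over
#' `n_starts` random initialisations and keeps the lowest-stress
#' configuration. Deterministic for a fixed seed.
#'
#' @param d Dissimilarity matrix or `dist` object.
#' @param k Embedding dimensions (>= 1, < number of samples).
#' @param n_starts Random starts (default 20).
#' @param seed Integer seed.
#' @return List with `coords` (samples x k), `stress` (Kruskal stress-1),
#'   `converged` flag and `seed`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k >= n) {
    stop("k must be smaller than the number of samples (", n, ")",
         call. = FALSE)
  }
  set.seed(seed)
  fit <- suppressWarnings(
    vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  )
  coords <- fit$points
  colnames(coords) <- paste0("NMDS", seq_len(k))
  list(coords = coords, stress = fit$stress,
       converged = isTRUE(fit$converged) ||
         (is.numeric(fit$converged) && fit$converged > 0),
       seed = seed)
}
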