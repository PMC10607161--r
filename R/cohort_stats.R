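# Paired patient-control statistics and flow-derived quantities.

#' Two-tailed paired t-test with optional log transform
#'
#' Runs a two-tailed paired t-test between pair-aligned patient and control
#' values. With `auto_log = TRUE` and all values positive, the differences
#' are first screened for non-normality (Shapiro-Wilk at alpha = 0.05) and
#' both vectors are log-transformed when it rejects; the decision is
#' recorded in the result. Zero-variance differences do not error: the
#' result is flagged degenerate, with t = 0 and p = 1 when the two vectors
#' are identical and an infinite t otherwise.
#'
#' @param patient_values,control_values Equal-length, pair-aligned numeric
#'   vectors (n >= 2).
#' @param auto_log Enable the non-normality screen and log transform.
#' @param measure Label carried into the result.
#' @return A `paired_comparison` list: `measure`, `n_pairs`, `transform`,
#'   `t_statistic`, `p_value`, `degenerate`.
#' @export
paired_t_test <- function(patient_values, control_values, auto_log = FALSE,
                          measure = "measure") {
  x <- patient_values
  y <- control_values
  if (length(x) != length(y)) {
    stop("patient and control vectors must be pair-aligned and of equal ",
         "length", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  transform <- "none"
  if (auto_log && all(x > 0) && all(y > 0)) {
    d0 <- x - y
    sw_p <- tryCatch(stats::shapiro.test(d0)$p.value,
                     error = function(e) NA_real_)
    if (!is.na(sw_p) && sw_p < 0.05) {
      x <- log(x)
      y <- log(y)
      transform <- "log"
    }
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- sign(mean(d)) * Inf
      p <- NA_real_
    }
    res <- list(measure = measure, n_pairs = length(x),
                transform = transform, t_statistic = t_stat, p_value = p,
                degenerate = TRUE)
  } else {
    fit <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
    res <- list(measure = measure, n_pairs = length(x),
                transform = transform,
                t_statistic = unname(fit$statistic),
                p_value = fit$p.value, degenerate = FALSE)
  }
  structure(res, class = "paired_comparison")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Equal-length numeric vectors, n >= 3, each with positive
#'   variance.
#' @return List with `r`, `p_value` and `df` (n - 2).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  fit <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(fit$estimate), p_value = fit$p.value,
       df = unname(fit$parameter))
}

#' Subtract isotype-control background from a bound-microbe percentage
#'
#' @param measured_pct Measured antibody-bound percentage, in [0, 100].
#' @param isotype_pct Isotype-control percentage, in [0, 100].
#' @return `max(measured - isotype, 0)`; warns when the floor engages.
#' @export
isotype_normalise <- function(measured_pct, isotype_pct) {
  if (any(measured_pct < 0 | measured_pct > 100) ||
      any(isotype_pct < 0 | isotype_pct > 100)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  out <- measured_pct - isotype_pct
  if (any(out < 0)) {
    warning("isotype background exceeds measured percentage; flooring at 0")
    out[out < 0] <- 0
  }
  out
}

#' Absolute abundance of antibody-bound microbes
#'
#' Converts a bound-cell percentage to cells per gram via the sample's
#' flow-cytometric microbial load.
#'
#' @param bound_pct Bound percentage in [0, 100].
#' @param microbial_load Total microbial load, cells/gram (> 0).
#' @return Bound microbes in cells/gram.
#' @export
absolute_bound_load <- function(bound_pct, microbial_load) {
  if (any(bound_pct < 0 | bound_pct > 100)) {
    stop("bound_pct must lie in [0, 100]", call. = FALSE)
  }
  if (any(microbial_load <= 0)) {
    stop("microbial_load must be > 0", call. = FALSE)
  }
  microbial_load * bound_pct / 100
}
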