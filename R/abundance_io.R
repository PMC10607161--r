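# Input/output and the abundance filtering rules applied before scoring.
#
# All taxonomic tables in this package are numeric matrices with taxa as rows
# and samples as columns; dimnames are mandatory and must be unique.

FRACTION_LABELS <- c("all", "igg_pos", "igg_neg")

#' Validate a taxa-by-samples abundance matrix
#'
#' Checks the contract shared by every count/abundance table in the package:
#' a numeric matrix with unique row (taxon) and column (sample) names and no
#' negative or missing values.
#'
#' @param x Numeric matrix, taxa in rows, samples in columns.
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid.
#' @export
validate_abundance_matrix <- function(x, what = "abundance table") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix (taxa x samples)", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(what, " must have taxon rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop(what, " has duplicated taxon identifiers", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop(what, " has duplicated sample identifiers", call. = FALSE)
  }
  if (anyNA(x)) stop(what, " contains missing values", call. = FALSE)
  if (any(x < 0)) stop(what, " contains negative values", call. = FALSE)
  invisible(x)
}

# Stop unless two fraction tables share identical taxa and samples.
check_aligned <- function(a, b, what = c("pos", "neg")) {
  if (!identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b))) {
    stop("'", what[1], "' and '", what[2],
         "' tables are not aligned: identical taxon and sample identifiers ",
         "in the same order are required", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a single-sample Bracken species report
#'
#' Parses the tab-separated Bracken report dialect (columns `name`,
#' `taxonomy_id`, `taxonomy_lvl`, `kraken_assigned_reads`, `added_reads`,
#' `new_est_reads`, `fraction_total_reads`) and returns the re-estimated
#' species read counts. Species are keyed by `name|taxonomy_id` so that name
#' collisions across report dialects cannot merge distinct taxa.
#'
#' @param path Path to the report file.
#' @return Named numeric vector of `new_est_reads`, one element per species.
#' @export
read_bracken_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(lines))) {
    warning("empty Bracken report: ", path)
    return(stats::setNames(numeric(0), character(0)))
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  required <- c("name", "taxonomy_id", "taxonomy_lvl",
                "kraken_assigned_reads", "added_reads", "new_est_reads",
                "fraction_total_reads")
  missing <- setdiff(required, header)
  if (length(missing)) {
    stop("Bracken report ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  counts <- numeric(length(body))
  keys <- character(length(body))
  for (i in seq_along(body)) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < length(header)) {
      stop("malformed row at line ", i + 1L, " of ", path, call. = FALSE)
    }
    row <- stats::setNames(fields[seq_along(header)], header)
    n <- suppressWarnings(as.numeric(row[["new_est_reads"]]))
    if (is.na(n)) {
      stop("non-numeric read count at line ", i + 1L, " of ", path,
           call. = FALSE)
    }
    if (n < 0) {
      stop("negative read count at line ", i + 1L, " of ", path,
           call. = FALSE)
    }
    counts[i] <- n
    keys[i] <- paste(row[["name"]], row[["taxonomy_id"]], sep = "|")
  }
  stats::setNames(counts, keys)
}

#' Total-sum scale counts to relative abundances
#'
#' Converts read counts to relative abundances by dividing each sample
#' (column) by its total, so every column sums to 1.
#'
#' @param counts Taxa-by-samples count matrix.
#' @return Matrix of the same shape with columns summing to 1.
#' @export
total_sum_scale <- function(counts) {
  validate_abundance_matrix(counts, "count table")
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2, totals, "/")
}

#' Apply a detection threshold and pseudocount to relative abundances
#'
#' Values less than or equal to `threshold` are set to zero (strict
#' greater-than detection: a value exactly at the threshold is removed), then
#' `pseudocount` is added to every cell, zeros included. The input is not
#' modified.
#'
#' @param ra Relative-abundance matrix.
#' @param threshold Detection threshold (default 1e-6).
#' @param pseudocount Constant added after thresholding (default 1e-7).
#' @return Thresholded matrix.
#' @export
apply_threshold <- function(ra, threshold = 1e-6, pseudocount = 1e-7) {
  validate_abundance_matrix(ra, "relative-abundance table")
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  out <- ra
  out[out <= threshold] <- 0
  out + pseudocount
}

#' Remove taxa undetected in the 'all' fraction from the sorted fractions
#'
#' For each sample independently, taxa whose 'all'-fraction relative
#' abundance is not above `threshold` are zeroed in the 'IgG positive' and
#' 'IgG negative' tables. Removal is per-sample: a taxon may survive in one
#' participant and be zeroed in another.
#'
#' @param pos,neg Sorted-fraction relative-abundance matrices.
#' @param all_fraction 'all'-fraction relative-abundance matrix.
#' @param threshold Detection threshold on the 'all' fraction (default 1e-5).
#' @return List with elements `pos` and `neg`.
#' @export
zero_absent_in_all <- function(pos, neg, all_fraction, threshold = 1e-5) {
  validate_abundance_matrix(pos, "'IgG positive' table")
  check_aligned(pos, neg, c("IgG positive", "IgG negative"))
  check_aligned(pos, all_fraction, c("IgG positive", "all"))
  absent <- all_fraction <= threshold
  pos[absent] <- 0
  neg[absent] <- 0
  list(pos = pos, neg = neg)
}

#' @rdname table_io
#' @export
write_table_tsv <- function(x, path) {
  df <- data.frame(taxon_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write taxa-by-samples matrices as TSV
#'
#' The on-disk format is tab-separated with a `taxon_id` first column and one
#' column per sample (or per sample_fraction). Values round-trip to at least
#' 12 significant digits.
#'
#' @param x Matrix to write.
#' @param path File path.
#' @return `write_table_tsv` returns `path` invisibly; `read_table_tsv`
#'   returns the matrix.
#' @name table_io
#' @export
read_table_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"taxon_id" %in% names(df)) {
    stop("expected a 'taxon_id' column in ", path, call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "taxon_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$taxon_id
  validate_abundance_matrix(m, basename(path))
}

#' Read and write per-sample flow-cytometry summaries
#'
#' A flow summary holds, per sample: the sorted fraction sizes as proportions
#' of SYBR+ events (`igg_pos_size`, `igg_neg_size`), the isotype-control
#' background percentage (`isotype_pct`), and the flow-cytometric microbial
#' load in cells per gram (`microbial_load`).
#'
#' @param flow Data frame with columns `sample_id`, `igg_pos_size`,
#'   `igg_neg_size`, `isotype_pct`, `microbial_load`.
#' @param path File path.
#' @name flow_io
#' @export
write_flow_tsv <- function(flow, path) {
  validate_flow(flow)
  utils::write.table(flow, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname flow_io
#' @export
read_flow_tsv <- function(path) {
  flow <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_flow(flow)
}

#' @rdname flow_io
#' @export
validate_flow <- function(flow) {
  required <- c("sample_id", "igg_pos_size", "igg_neg_size", "isotype_pct",
                "microbial_load")
  missing <- setdiff(required, names(flow))
  if (length(missing)) {
    stop("flow summary is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  with(flow, {
    if (any(igg_pos_size < 0 | igg_pos_size > 1) ||
        any(igg_neg_size < 0 | igg_neg_size > 1)) {
      stop("fraction sizes must be proportions in [0, 1]", call. = FALSE)
    }
    if (any(microbial_load <= 0)) {
      stop("microbial_load must be positive (cells/gram)", call. = FALSE)
    }
  })
  flow
}

# Look up per-sample values from a flow summary in table column order.
flow_lookup <- function(flow, sample_ids, column) {
  idx <- match(sample_ids, flow$sample_id)
  if (anyNA(idx)) {
    stop("flow summary is missing sample(s): ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  flow[[column]][idx]
}
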