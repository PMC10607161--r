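# End-to-end orchestration: simulate an input bundle to disk, or analyse a
# bundle through the fixed stage order
#   threshold -> zero-absent-in-all -> score -> diversity -> functional ->
#   paired statistics
# writing every result table plus a JSON manifest.

#' Build a run configuration
#'
#' Defaults mirror the analysis settings used throughout the package:
#' community profiling at threshold 1e-6 with pseudocount 1e-7, antibody
#' scoring at threshold 1e-5 with pseudocount 1e-5, gene families at
#' threshold 1e-6 with pseudocount 6e-10 and prevalence cut at 7 samples.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  config <- list(
    mode = "synthetic",
    input_dir = "iggseq_inputs",
    output_dir = "iggseq_results",
    seed = 1,
    rmp_threshold = 1e-6,
    rmp_pseudocount = 1e-7,
    igg_threshold = 1e-5,
    igg_pseudocount = 1e-5,
    gene_threshold = 1e-6,
    gene_pseudocount = 6e-10,
    prevalence_max_below = 7,
    scale_ratio = TRUE,
    nmds_k = 2,
    nmds_starts = 20,
    scenario = list(),
    sort = list()
  )
  overrides <- list(...)
  if (length(overrides)) config <- utils::modifyList(config, overrides)
  structure(config, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file of key/value overrides, same names as
#'   [run_config()] arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  do.call(run_config, yaml::read_yaml(path))
}

bundle_files <- function(dir) {
  file.path(dir, c(
    counts_all = "counts_all.tsv",
    counts_igg_pos = "counts_igg_pos.tsv",
    counts_igg_neg = "counts_igg_neg.tsv",
    gene_all = "gene_families_all.tsv",
    gene_igg_pos = "gene_families_igg_pos.tsv",
    gene_igg_neg = "gene_families_igg_neg.tsv",
    flow = "flow_summary.tsv",
    metadata = "metadata.tsv"
  ))
}

#' Simulate a cohort and write the full input bundle to disk
#'
#' Generates a synthetic cohort under the configured scenario and writes
#' merged count tables (one per fraction), gene-family tables, the flow
#' summary, sample metadata and the ground-truth coating/abundance matrices
#' (for recovery checks) as TSV files.
#'
#' @param config A [run_config()]; `scenario` and `sort` entries override
#'   [cohort_scenario()] / [sort_spec()] defaults.
#' @return Invisibly, the list of written file paths.
#' @export
run_simulate <- function(config = run_config()) {
  scenario <- do.call(cohort_scenario, config$scenario)
  spec <- do.call(sort_spec, config$sort)
  cohort <- generate_cohort(scenario, spec, seed = config$seed)
  dir.create(config$input_dir, recursive = TRUE, showWarnings = FALSE)
  files <- bundle_files(config$input_dir)
  names(files) <- c("counts_all", "counts_igg_pos", "counts_igg_neg",
                    "gene_all", "gene_igg_pos", "gene_igg_neg", "flow",
                    "metadata")
  write_table_tsv(cohort$counts$all, files[["counts_all"]])
  write_table_tsv(cohort$counts$igg_pos, files[["counts_igg_pos"]])
  write_table_tsv(cohort$counts$igg_neg, files[["counts_igg_neg"]])
  write_table_tsv(cohort$gene_families$all, files[["gene_all"]])
  write_table_tsv(cohort$gene_families$igg_pos, files[["gene_igg_pos"]])
  write_table_tsv(cohort$gene_families$igg_neg, files[["gene_igg_neg"]])
  write_flow_tsv(cohort$flow, files[["flow"]])
  utils::write.table(cohort$metadata, files[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_files <- file.path(config$input_dir,
                           c("truth_coating_prob.tsv",
                             "truth_rel_abundance.tsv"))
  write_table_tsv(cohort$truth$coating_prob, truth_files[[1]])
  write_table_tsv(cohort$truth$rel_abundance, truth_files[[2]])
  invisible(c(files, truth = truth_files))
}

#' Read an input bundle from disk
#'
#' @param dir Directory written by [run_simulate()] (or assembled from real
#'   per-fraction tables in the same layout).
#' @return List with `counts`, `gene_families`, `flow`, `metadata`.
#' @export
read_bundle <- function(dir) {
  files <- bundle_files(dir)
  absent <- files[!file.exists(files)]
  if (length(absent)) {
    stop("input bundle is incomplete; missing file(s): ",
         paste(basename(absent), collapse = ", "), call. = FALSE)
  }
  md <- utils::read.delim(files[[8]], stringsAsFactors = FALSE)
  list(
    counts = list(all = read_table_tsv(files[[1]]),
                  igg_pos = read_table_tsv(files[[2]]),
                  igg_neg = read_table_tsv(files[[3]])),
    gene_families = list(all = read_table_tsv(files[[4]]),
                         igg_pos = read_table_tsv(files[[5]]),
                         igg_neg = read_table_tsv(files[[6]])),
    flow = read_flow_tsv(files[[7]]),
    metadata = md
  )
}

# Split per-sample values into pair-aligned patient/control vectors.
pair_split <- function(values, metadata) {
  v <- values[metadata$sample_id]
  pairs <- sort(unique(metadata$pair))
  pat <- vapply(pairs, function(p) {
    v[metadata$sample_id[metadata$pair == p & metadata$role == "patient"]]
  }, numeric(1))
  con <- vapply(pairs, function(p) {
    v[metadata$sample_id[metadata$pair == p & metadata$role == "control"]]
  }, numeric(1))
  list(patient = pat, control = con)
}

#' Analyse an input bundle end to end
#'
#' Runs the full analysis on a bundle (from disk, or in-memory as returned
#' by [generate_cohort()]): relative and quantitative profiles, antibody
#' probability ratios of taxa and gene families, fraction-presence
#' classification, alpha/beta diversity with NMDS, CLR + PCA of gene
#' families, and paired patient-control statistics. All result tables and a
#' JSON manifest are written to `config$output_dir`.
#'
#' @param config A [run_config()].
#' @param bundle Optional in-memory bundle; defaults to reading
#'   `config$input_dir`.
#' @return Invisibly, a list of all computed results (also written to disk).
#' @export
run_analyse <- function(config = run_config(), bundle = NULL) {
  if (is.null(bundle)) bundle <- read_bundle(config$input_dir)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  md <- bundle$metadata

  ## Community profiling (RMP / QMP) from the 'all' fraction
  rmp_table <- rmp(bundle$counts$all, config$rmp_threshold,
                   config$rmp_pseudocount)
  qmp_table <- qmp(rmp_table, bundle$flow)

  ## Antibody scoring of taxa
  all_ra <- total_sum_scale(bundle$counts$all)
  pos_ra <- total_sum_scale(bundle$counts$igg_pos)
  neg_ra <- total_sum_scale(bundle$counts$igg_neg)
  zeroed <- zero_absent_in_all(pos_ra, neg_ra, all_ra,
                               config$igg_threshold)
  flow_norm <- normalise_flow_isotype(bundle$flow)
  ratios <- prob_ratio(zeroed$pos, zeroed$neg, flow_norm,
                       pseudocount = config$igg_pseudocount,
                       scale = config$scale_ratio)
  presence <- classify_fraction_presence(zeroed$pos, zeroed$neg,
                                         config$igg_threshold)
  presence <- merge(md, presence, by = "sample_id", sort = FALSE)
  common <- select_common_features(all_ra, config$igg_threshold)
  ratios_common <- ratios[rownames(common), , drop = FALSE]

  ## Diversity
  alpha <- data.frame(
    sample_id = colnames(bundle$counts$all),
    shannon = shannon(all_ra),
    inv_simpson = inv_simpson(all_ra),
    row.names = NULL, stringsAsFactors = FALSE
  )
  depth <- min_depth(bundle$counts[c("igg_pos", "igg_neg")])
  alpha$richness_igg_pos <- rarefied_richness(bundle$counts$igg_pos, depth)
  alpha$richness_igg_neg <- rarefied_richness(bundle$counts$igg_neg, depth)
  bc_all <- bray_curtis(all_ra)
  ord_all <- nmds(bc_all, k = config$nmds_k, n_starts = config$nmds_starts,
                  seed = config$seed)
  sorted_ra <- cbind(zeroed$pos, zeroed$neg)
  colnames(sorted_ra) <- c(paste0(colnames(zeroed$pos), "_pos"),
                           paste0(colnames(zeroed$neg), "_neg"))
  sorted_ra <- sorted_ra[, colSums(sorted_ra) > 0, drop = FALSE]
  bc_fractions <- bray_curtis(sorted_ra)
  ord_fractions <- nmds(bc_fractions, k = config$nmds_k,
                        n_starts = config$nmds_starts, seed = config$seed)

  ## Functional analysis of gene families
  genes <- zero_families_absent_in_all(bundle$gene_families)
  gene_all <- apply_threshold(renormalise_families(genes$all),
                              config$gene_threshold, 0)
  gene_pos <- apply_threshold(renormalise_families(genes$igg_pos),
                              config$gene_threshold, 0)
  gene_neg <- apply_threshold(renormalise_families(genes$igg_neg),
                              config$gene_threshold, 0)
  gene_kept <- prevalence_filter(gene_all, config$gene_threshold,
                                 config$prevalence_max_below)
  gene_pca <- pca(clr_transform(gene_kept))
  gene_ratios <- gene_family_prob_ratio(gene_pos, gene_neg, flow_norm,
                                        pseudocount =
                                          config$gene_pseudocount,
                                        scale = config$scale_ratio)
  gene_ratio_pca <- if (nrow(gene_ratios) >= 2) pca(gene_ratios) else NULL

  ## Paired patient-control statistics
  mean_ratio <- colMeans(ratios_common)
  tests <- list(
    mean_prob_ratio = pair_split(mean_ratio, md),
    shannon = pair_split(stats::setNames(alpha$shannon, alpha$sample_id),
                         md),
    igg_pos_fraction_size =
      pair_split(stats::setNames(flow_norm$igg_pos_size,
                                 flow_norm$sample_id), md)
  )
  stats_rows <- lapply(names(tests), function(nm) {
    res <- paired_t_test(tests[[nm]]$patient, tests[[nm]]$control,
                         measure = nm)
    data.frame(measure = nm, n_pairs = res$n_pairs,
               transform = res$transform, t_statistic = res$t_statistic,
               p_value = res$p_value, degenerate = res$degenerate,
               stringsAsFactors = FALSE)
  })
  stats_table <- do.call(rbind, stats_rows)

  ## Write everything + manifest
  files <- c(
    rmp = "rmp.tsv", qmp = "qmp.tsv",
    prob_ratio_taxa = "prob_ratio_taxa.tsv",
    prob_ratio_common = "prob_ratio_common_taxa.tsv",
    fraction_presence = "fraction_presence.tsv",
    alpha_diversity = "alpha_diversity.tsv",
    bray_curtis_all = "bray_curtis_all.tsv",
    nmds_all = "nmds_all_coords.tsv",
    bray_curtis_fractions = "bray_curtis_fractions.tsv",
    nmds_fractions = "nmds_fractions_coords.tsv",
    gene_pca_scores = "gene_pca_scores.tsv",
    gene_prob_ratio = "gene_prob_ratio.tsv",
    paired_stats = "paired_stats.tsv"
  )
  paths <- stats::setNames(file.path(out_dir, files), names(files))
  write_table_tsv(rmp_table, paths[["rmp"]])
  write_table_tsv(qmp_table, paths[["qmp"]])
  write_table_tsv(unclass_matrix(ratios), paths[["prob_ratio_taxa"]])
  write_table_tsv(unclass_matrix(ratios_common),
                  paths[["prob_ratio_common"]])
  utils::write.table(presence, paths[["fraction_presence"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(alpha, paths[["alpha_diversity"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_square_tsv(bc_all, paths[["bray_curtis_all"]])
  write_coords_tsv(ord_all, paths[["nmds_all"]])
  write_square_tsv(bc_fractions, paths[["bray_curtis_fractions"]])
  write_coords_tsv(ord_fractions, paths[["nmds_fractions"]])
  write_square_tsv(gene_pca$scores, paths[["gene_pca_scores"]])
  write_table_tsv(unclass_matrix(gene_ratios), paths[["gene_prob_ratio"]])
  utils::write.table(stats_table, paths[["paired_stats"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "iggseq",
    version = as.character(utils::packageVersion("iggseq")),
    seed = config$seed,
    config = unclass(config),
    nmds_stress = list(all = ord_all$stress,
                       fractions = ord_fractions$stress),
    gene_pca_explained_variance = gene_pca$explained_variance,
    gene_ratio_pca_explained_variance =
      if (is.null(gene_ratio_pca)) NULL else
        gene_ratio_pca$explained_variance,
    files = as.list(paths)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(rmp = rmp_table, qmp = qmp_table, ratios = ratios,
                 ratios_common = ratios_common, presence = presence,
                 alpha = alpha, bray_curtis = bc_all, nmds_all = ord_all,
                 nmds_fractions = ord_fractions, gene_pca = gene_pca,
                 gene_ratio_pca = gene_ratio_pca,
                 gene_ratios = gene_ratios, stats = stats_table,
                 manifest = manifest))
}

unclass_matrix <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

write_square_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_coords_tsv <- function(ord, path) {
  df <- data.frame(sample_id = rownames(ord$coords), ord$coords,
                   stress = ord$stress, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
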