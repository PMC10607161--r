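# Synthetic sorted-fraction cohort generator.
#
# The generator emulates the measurement process behind antibody-coating
# sequencing: a ground-truth community with per-taxon coating probabilities,
# a cell sorter splitting SYBR+ events into coated/uncoated fractions, and
# multinomial shotgun sequencing of each sorted fraction. It exists so every
# downstream stage can be tested against known truth without sequencing data.

#' Cohort simulation scenario
#'
#' Bundles the population-level knobs of the synthetic cohort: how many
#' household pairs, how similar the two microbiomes within a household are,
#' the spread of taxon abundances, the coating-probability distribution, and
#' the patient effect expressed as a multiplicative factor on coating odds.
#'
#' @param n_pairs Number of household pairs (patient + control each).
#' @param patient_theta_scale Multiplicative factor applied to patients'
#'   per-taxon coating odds; 1 = no effect, values < 1 model reduced IgG
#'   reactivity.
#' @param household_similarity Correlation of log-abundances between the two
#'   members of a household, in [0, 1].
#' @param abundance_sigma Lognormal shape parameter of taxon abundances.
#' @param theta_alpha,theta_beta Beta-distribution parameters for per-taxon
#'   coating probabilities.
#' @param n_taxa Number of taxa per community.
#' @param n_gene_families Number of gene families in the incidence map.
#' @param gene_prevalence Probability a gene family is carried by a taxon.
#' @param mean_log_load,sd_log_load Lognormal parameters of the per-sample
#'   microbial load (cells/gram); defaults centre on 1.5e11 cells/g, within
#'   the range observed by flow cytometry in human stool.
#' @return A `cohort_scenario` list.
#' @export
cohort_scenario <- function(n_pairs = 5,
                            patient_theta_scale = 1,
                            household_similarity = 0.9,
                            abundance_sigma = 1.5,
                            theta_alpha = 2,
                            theta_beta = 2,
                            n_taxa = 60,
                            n_gene_families = 200,
                            gene_prevalence = 0.3,
                            mean_log_load = log(1.5e11),
                            sd_log_load = 0.3) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (patient_theta_scale <= 0) {
    stop("patient_theta_scale must be > 0", call. = FALSE)
  }
  if (household_similarity < 0 || household_similarity > 1) {
    stop("household_similarity must lie in [0, 1]", call. = FALSE)
  }
  if (abundance_sigma < 0) stop("abundance_sigma must be >= 0", call. = FALSE)
  structure(list(n_pairs = n_pairs,
                 patient_theta_scale = patient_theta_scale,
                 household_similarity = household_similarity,
                 abundance_sigma = abundance_sigma,
                 theta_alpha = theta_alpha,
                 theta_beta = theta_beta,
                 n_taxa = n_taxa,
                 n_gene_families = n_gene_families,
                 gene_prevalence = gene_prevalence,
                 mean_log_load = mean_log_load,
                 sd_log_load = sd_log_load),
            class = "cohort_scenario")
}

#' Cell-sorting and sequencing specification
#'
#' @param n_cells_sorted Cells collected per fraction on the sorter.
#' @param read_depth Sequencing reads per fraction.
#' @param isotype_background Non-specific staining added to the reported
#'   'IgG positive' fraction size (proportion of SYBR+ events); removed
#'   downstream by isotype normalisation.
#' @param gating_gap Proportion of SYBR+ events assigned to neither sorted
#'   fraction; must lie in [0, 0.2].
#' @param seed Integer seed for the multinomial draws.
#' @return A `sort_spec` list.
#' @export
sort_spec <- function(n_cells_sorted = 1e6,
                      read_depth = 2e5,
                      isotype_background = 0.01,
                      gating_gap = 0.05,
                      seed = 1) {
  if (gating_gap < 0 || gating_gap > 0.2) {
    stop("gating_gap must lie in [0, 0.2]", call. = FALSE)
  }
  if (read_depth < 0) stop("read_depth must be >= 0", call. = FALSE)
  structure(list(n_cells_sorted = n_cells_sorted,
                 read_depth = read_depth,
                 isotype_background = isotype_background,
                 gating_gap = gating_gap,
                 seed = seed),
            class = "sort_spec")
}

#' Construct a ground-truth community explicitly
#'
#' Low-level constructor used by [generate_community()] and by tests that
#' need exact abundances and coating probabilities.
#'
#' @param rel_abundance Per-taxon relative abundances; must be non-negative
#'   and sum to 1.
#' @param coating_prob Per-taxon antibody-coating probabilities in [0, 1].
#' @param microbial_load Total cells per gram of stool; positive.
#' @param taxon_ids Taxon identifiers; defaults to `taxon_001` style names.
#' @param gene_incidence Optional binary taxa-by-gene-family matrix.
#' @return A `ground_truth_community` list.
#' @export
ground_truth_community <- function(rel_abundance, coating_prob,
                                   microbial_load = 1.5e11,
                                   taxon_ids = NULL,
                                   gene_incidence = NULL) {
  n <- length(rel_abundance)
  if (length(coating_prob) != n) {
    stop("rel_abundance and coating_prob lengths differ", call. = FALSE)
  }
  if (any(rel_abundance < 0) || abs(sum(rel_abundance) - 1) > 1e-12) {
    stop("rel_abundance must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(coating_prob < 0 | coating_prob > 1)) {
    stop("coating_prob must lie in [0, 1]", call. = FALSE)
  }
  if (microbial_load <= 0) stop("microbial_load must be > 0", call. = FALSE)
  if (is.null(taxon_ids)) {
    taxon_ids <- sprintf("taxon_%03d", seq_len(n))
  }
  if (!is.null(gene_incidence) && nrow(gene_incidence) != n) {
    stop("gene_incidence must have one row per taxon", call. = FALSE)
  }
  structure(list(taxon_ids = taxon_ids,
                 rel_abundance = stats::setNames(rel_abundance, taxon_ids),
                 coating_prob = stats::setNames(coating_prob, taxon_ids),
                 microbial_load = microbial_load,
                 gene_incidence = gene_incidence),
            class = "ground_truth_community")
}

#' Draw a random ground-truth community
#'
#' Abundances are lognormal(0, `abundance_sigma`) renormalised to sum to 1;
#' coating probabilities are Beta(`theta_alpha`, `theta_beta`); the microbial
#' load is lognormal. Deterministic for a fixed seed.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param scenario A [cohort_scenario()].
#' @param seed Integer seed.
#' @return A [ground_truth_community()].
#' @export
generate_community <- function(n_taxa, scenario = cohort_scenario(),
                               seed = 1) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  set.seed(seed)
  log_a <- stats::rnorm(n_taxa, 0, scenario$abundance_sigma)
  ra <- exp(log_a) / sum(exp(log_a))
  theta <- stats::rbeta(n_taxa, scenario$theta_alpha, scenario$theta_beta)
  load <- stats::rlnorm(1, scenario$mean_log_load, scenario$sd_log_load)
  incidence <- draw_gene_incidence(n_taxa, scenario)
  ground_truth_community(ra, theta, load, gene_incidence = incidence)
}

draw_gene_incidence <- function(n_taxa, scenario) {
  m <- matrix(stats::rbinom(n_taxa * scenario$n_gene_families, 1,
                            scenario$gene_prevalence),
              nrow = n_taxa,
              dimnames = list(sprintf("taxon_%03d", seq_len(n_taxa)),
                              sprintf("fam_%04d",
                                      seq_len(scenario$n_gene_families))))
  m
}

#' True sorted-fraction sizes of a community
#'
#' Under per-cell Bernoulli coating, the probability a random cell is coated
#' is the abundance-weighted mean coating probability; the two fraction sizes
#' therefore sum to 1 exactly before any gating gap is applied.
#'
#' @param community A [ground_truth_community()].
#' @return Named numeric vector `c(igg_pos = ..., igg_neg = ...)`.
#' @export
true_fraction_sizes <- function(community) {
  pos <- sum(community$rel_abundance * community$coating_prob)
  c(igg_pos = pos, igg_neg = 1 - pos)
}

#' Simulate sorting and sequencing of the three fractions
#'
#' Draws multinomial read counts at the specified depth for the 'all'
#' fraction (composition = true abundances), the 'IgG positive' fraction
#' (composition proportional to abundance x coating probability) and the
#' 'IgG negative' fraction (abundance x (1 - coating probability)). The
#' reported flow fraction sizes are the true sizes shrunk by the gating gap,
#' with the isotype background added to the positive fraction only — exactly
#' the non-ideality that isotype normalisation removes downstream.
#'
#' @param community A [ground_truth_community()].
#' @param spec A [sort_spec()].
#' @param sample_id Sample identifier used in the outputs.
#' @return List with `counts` (taxa x 3 matrix, columns `all`, `igg_pos`,
#'   `igg_neg`) and `flow` (one-row data frame).
#' @export
simulate_fractions <- function(community, spec = sort_spec(),
                               sample_id = "S1") {
  ra <- community$rel_abundance
  theta <- community$coating_prob
  w_pos <- ra * theta
  w_neg <- ra * (1 - theta)
  if (spec$read_depth > 0 && sum(w_pos) == 0) {
    stop("degenerate scenario: no taxon has positive coating probability, ",
         "the 'IgG positive' fraction is empty", call. = FALSE)
  }
  if (spec$read_depth > 0 && sum(w_neg) == 0) {
    stop("degenerate scenario: every cell is coated, the 'IgG negative' ",
         "fraction is empty", call. = FALSE)
  }
  set.seed(spec$seed)
  draw <- function(w) {
    if (spec$read_depth == 0) return(numeric(length(w)))
    as.numeric(stats::rmultinom(1, spec$read_depth, w / sum(w)))
  }
  counts <- cbind(all = draw(ra), igg_pos = draw(w_pos),
                  igg_neg = draw(w_neg))
  rownames(counts) <- community$taxon_ids
  sizes <- true_fraction_sizes(community)
  flow <- data.frame(
    sample_id = sample_id,
    igg_pos_size = unname(sizes["igg_pos"]) * (1 - spec$gating_gap) +
      spec$isotype_background,
    igg_neg_size = unname(sizes["igg_neg"]) * (1 - spec$gating_gap),
    isotype_pct = spec$isotype_background * 100,
    microbial_load = community$microbial_load,
    stringsAsFactors = FALSE
  )
  list(counts = counts, flow = flow)
}

# Deterministically derive n sub-seeds from a master seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

scale_odds <- function(theta, factor) {
  odds <- factor * theta / (1 - theta)
  out <- odds / (1 + odds)
  out[theta == 1] <- 1
  out
}

#' Generate a complete synthetic household cohort
#'
#' For each household pair, patient and control communities share correlated
#' log-abundances (`household_similarity`) and a common set of per-taxon
#' coating probabilities; the patient's coating odds are multiplied by
#' `patient_theta_scale`. Each sample is then sorted and sequenced with
#' [simulate_fractions()] under a per-sample seed derived from the cohort
#' seed. Gene-family tables are the taxon-by-family incidence map weighted by
#' each fraction's realised composition and renormalised per column.
#'
#' @param scenario A [cohort_scenario()].
#' @param spec A [sort_spec()]; its seed field is ignored in favour of
#'   per-sample seeds derived from `seed`.
#' @param seed Master seed for the whole cohort.
#' @return List with elements `counts` (list of three taxa x samples
#'   matrices named `all`, `igg_pos`, `igg_neg`), `flow`, `gene_families`
#'   (list of three family x samples matrices), `metadata` (sample_id, pair,
#'   role) and `truth` (true abundance/coating matrices and loads).
#' @export
generate_cohort <- function(scenario = cohort_scenario(),
                            spec = sort_spec(), seed = 1) {
  n_taxa <- scenario$n_taxa
  taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
  n_samples <- 2L * scenario$n_pairs
  seeds <- derive_seeds(seed, 2L + 3L * scenario$n_pairs)
  set.seed(seeds[1])
  incidence <- draw_gene_incidence(n_taxa, scenario)

  roles <- rep(c("patient", "control"), scenario$n_pairs)
  pairs <- rep(seq_len(scenario$n_pairs), each = 2)
  sample_ids <- sprintf("pair%d_%s", pairs, roles)

  counts <- lapply(FRACTION_LABELS, function(f) {
    matrix(0, n_taxa, n_samples, dimnames = list(taxa, sample_ids))
  })
  names(counts) <- FRACTION_LABELS
  theta_true <- matrix(NA_real_, n_taxa, n_samples,
                       dimnames = list(taxa, sample_ids))
  ra_true <- theta_true
  flow_rows <- vector("list", n_samples)

  rho <- scenario$household_similarity
  for (p in seq_len(scenario$n_pairs)) {
    set.seed(seeds[1L + p])
    z <- stats::rnorm(n_taxa)
    e_pat <- stats::rnorm(n_taxa)
    e_con <- stats::rnorm(n_taxa)
    theta_base <- stats::rbeta(n_taxa, scenario$theta_alpha,
                               scenario$theta_beta)
    loads <- stats::rlnorm(2, scenario$mean_log_load, scenario$sd_log_load)
    mix <- function(e) {
      scenario$abundance_sigma * (sqrt(rho) * z + sqrt(1 - rho) * e)
    }
    for (k in 1:2) {
      role <- c("patient", "control")[k]
      log_a <- mix(if (role == "patient") e_pat else e_con)
      ra <- exp(log_a) / sum(exp(log_a))
      theta <- if (role == "patient") {
        scale_odds(theta_base, scenario$patient_theta_scale)
      } else {
        theta_base
      }
      j <- 2L * (p - 1L) + k
      community <- ground_truth_community(ra, theta, loads[k],
                                          taxon_ids = taxa,
                                          gene_incidence = incidence)
      sample_spec <- spec
      sample_spec$seed <- seeds[1L + scenario$n_pairs + j]
      sim <- simulate_fractions(community, sample_spec,
                                sample_id = sample_ids[j])
      for (f in FRACTION_LABELS) counts[[f]][, j] <- sim$counts[, f]
      flow_rows[[j]] <- sim$flow
      theta_true[, j] <- theta
      ra_true[, j] <- ra
    }
  }
  flow <- do.call(rbind, flow_rows)

  gene_families <- lapply(counts, function(m) {
    fam <- t(incidence) %*% m            # family x sample weighted reads
    totals <- colSums(fam)
    nz <- totals > 0
    fam[, nz] <- sweep(fam[, nz, drop = FALSE], 2, totals[nz], "/")
    fam
  })

  list(counts = counts,
       flow = flow,
       gene_families = gene_families,
       metadata = data.frame(sample_id = sample_ids, pair = pairs,
                             role = roles, stringsAsFactors = FALSE),
       truth = list(rel_abundance = ra_true, coating_prob = theta_true,
                    gene_incidence = incidence,
                    microbial_load = stats::setNames(flow$microbial_load,
                                                     sample_ids)),
       scenario = scenario, sort_spec = spec, seed = seed)
}
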