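test_that("generate_community draws valid, seed-reproducible communities", {
  sc <- cohort_scenario()
  com <- generate_community(2, sc, seed = 7)
  expect_equal(sum(com$rel_abundance), 1, tolerance = 1e-12)
  expect_true(all(com$coating_prob >= 0 & com$coating_prob <= 1))
  expect_gt(com$microbial_load, 0)

  again <- generate_community(2, sc, seed = 7)
  expect_identical(com, again)

  flat <- generate_community(10, cohort_scenario(abundance_sigma = 0),
                             seed = 1)
  expect_equal(unname(flat$rel_abundance), rep(0.1, 10))

  expect_error(generate_community(1, sc, seed = 1), "n_taxa")
})

test_that("true fraction sizes follow the abundance-weighted coating mean", {
  com <- function(ra, theta) ground_truth_community(ra, theta)
  expect_equal(true_fraction_sizes(com(c(0.5, 0.5), c(1, 0))),
               c(igg_pos = 0.5, igg_neg = 0.5))
  expect_equal(true_fraction_sizes(com(c(0.3, 0.7), c(0, 0))),
               c(igg_pos = 0, igg_neg = 1))
  # theta symmetric about 0.5 at equal abundance splits evenly
  expect_equal(true_fraction_sizes(com(c(0.5, 0.5), c(0.8, 0.2))),
               c(igg_pos = 0.5, igg_neg = 0.5))
  # conservation before gating: sizes always sum to 1 exactly
  for (seed in 1:5) {
    c_r <- generate_community(20, cohort_scenario(), seed = seed)
    expect_equal(sum(true_fraction_sizes(c_r)), 1, tolerance = 1e-12)
  }
})

test_that("simulated fraction compositions match the sorting model", {
  # identical coating probabilities: sorted composition = 'all' composition
  com <- ground_truth_community(c(0.9, 0.1), c(0.5, 0.5))
  sim <- simulate_fractions(com, sort_spec(read_depth = 1e6, seed = 3))
  p_pos <- sim$counts[, "igg_pos"] / sum(sim$counts[, "igg_pos"])
  for (i in 1:2) {
    se <- sqrt(com$rel_abundance[i] * (1 - com$rel_abundance[i]) / 1e6)
    expect_lt(abs(p_pos[i] - com$rel_abundance[i]), 3 * se)
  }

  zero <- simulate_fractions(com, sort_spec(read_depth = 0))
  expect_true(all(zero$counts == 0))

  expect_error(
    simulate_fractions(ground_truth_community(c(0.5, 0.5), c(0, 0)),
                       sort_spec(read_depth = 10)),
    "IgG positive"
  )
  expect_identical(
    simulate_fractions(com, sort_spec(seed = 11))$counts,
    simulate_fractions(com, sort_spec(seed = 11))$counts
  )
})

test_that("reported flow sizes carry the gating gap and isotype background", {
  com <- ground_truth_community(c(0.5, 0.5), c(0.8, 0.2))
  sim <- simulate_fractions(com, sort_spec(gating_gap = 0.05,
                                           isotype_background = 0.01))
  expect_equal(sim$flow$igg_pos_size, 0.5 * 0.95 + 0.01)
  expect_equal(sim$flow$igg_neg_size, 0.5 * 0.95)
  expect_equal(sim$flow$isotype_pct, 1)
})

test_that("cohort generation respects household structure and bookkeeping", {
  co <- generate_cohort(cohort_scenario(n_pairs = 5), sort_spec(), seed = 2)
  expect_equal(nrow(co$metadata), 10)
  expect_equal(length(unique(co$metadata$pair)), 5)
  expect_equal(as.integer(table(co$metadata$role)), c(5L, 5L))
  expect_equal(dim(co$counts$all), c(60, 10))

  # perfect household correlation + null effect: identical pair members
  ident <- generate_cohort(
    cohort_scenario(n_pairs = 2, household_similarity = 1,
                    patient_theta_scale = 1),
    sort_spec(), seed = 5)
  expect_equal(ident$truth$rel_abundance[, "pair1_patient"],
               ident$truth$rel_abundance[, "pair1_control"])
  expect_equal(ident$truth$coating_prob[, "pair1_patient"],
               ident$truth$coating_prob[, "pair1_control"])

  expect_identical(
    generate_cohort(cohort_scenario(n_pairs = 2), sort_spec(), seed = 9),
    generate_cohort(cohort_scenario(n_pairs = 2), sort_spec(), seed = 9)
  )
})

test_that("null cohorts have balanced sorted-fraction sizes", {
  # Monte-Carlo under the null: with no patient effect the mean reported
  # 'IgG positive' fraction size is the same in patients and controls
  co <- generate_cohort(cohort_scenario(n_pairs = 100,
                                        patient_theta_scale = 1),
                        sort_spec(), seed = 31)
  pat <- co$flow$igg_pos_size[co$metadata$role == "patient"]
  con <- co$flow$igg_pos_size[co$metadata$role == "control"]
  d <- pat - con
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(length(d)))
})

test_that("patient coating odds are scaled multiplicatively", {
  co <- generate_cohort(
    cohort_scenario(n_pairs = 1, patient_theta_scale = 0.25,
                    household_similarity = 1),
    sort_spec(), seed = 4)
  th_c <- co$truth$coating_prob[, "pair1_control"]
  th_p <- co$truth$coating_prob[, "pair1_patient"]
  expect_equal(th_p / (1 - th_p), 0.25 * th_c / (1 - th_c),
               tolerance = 1e-12)
})
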