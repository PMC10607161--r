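test_that("probability ratios match the independent transcription", {
  for (seed in 1:5) {
    pos <- rand_ra_table(10, 4, seed)
    neg <- rand_ra_table(10, 4, seed + 100)
    set.seed(seed + 200)
    s_pos <- runif(4, 0.2, 0.6)
    s_neg <- 1 - s_pos - runif(4, 0, 0.1)
    flow <- make_flow(colnames(pos), s_pos, s_neg)
    for (scale in c(TRUE, FALSE)) {
      got <- prob_ratio(pos, neg, flow, pseudocount = 1e-5, scale = scale)
      want <- oracle_prob_ratio(pos, neg, s_pos, s_neg, 1e-5, scale)
      expect_equal(unclass(got)[, ], want, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("ratio symmetry and pseudocount-only cells behave as expected", {
  pos <- tbl(c(0.3, 0), 2, 1)
  neg <- tbl(c(0.3, 0), 2, 1)
  flow <- make_flow("s01", 0.5, 0.5)
  r <- prob_ratio(pos, neg, flow)
  expect_equal(r[1, 1], 0)   # equal joint probabilities
  expect_equal(r[2, 1], 0)   # log2(c/c) for a doubly-absent taxon

  expect_error(prob_ratio(pos, neg, flow, pseudocount = 0), "pseudocount")

  # undetected cells can be flagged undefined instead
  r_na <- prob_ratio(pos, neg, flow, na_when_absent = TRUE)
  expect_true(is.na(r_na[2, 1]))
  expect_equal(r_na[1, 1], 0)
})

test_that("swapping fractions negates every ratio exactly", {
  pos <- rand_ra_table(8, 3, 42)
  neg <- rand_ra_table(8, 3, 43)
  flow <- make_flow(colnames(pos), c(0.3, 0.5, 0.4), c(0.6, 0.4, 0.5))
  swapped <- make_flow(colnames(pos), c(0.6, 0.4, 0.5), c(0.3, 0.5, 0.4))
  a <- prob_ratio(pos, neg, flow)
  b <- prob_ratio(neg, pos, swapped)
  expect_equal(unclass(a)[, ], -unclass(b)[, ], tolerance = 0,
               ignore_attr = TRUE)
})

test_that("scaled ratios are invariant to rescaling both fraction sizes", {
  pos <- rand_ra_table(8, 3, 44)
  neg <- rand_ra_table(8, 3, 45)
  s_pos <- c(0.3, 0.5, 0.4)
  s_neg <- c(0.6, 0.4, 0.5)
  base <- prob_ratio(pos, neg, make_flow(colnames(pos), s_pos, s_neg))
  # proportions must stay in [0,1] for the flow contract; shrink instead of
  # inflate, the invariance is multiplicative either way. A power-of-two
  # factor is bit-exact; any other factor is exact to rounding error.
  shrunk <- prob_ratio(pos, neg,
                       make_flow(colnames(pos), s_pos / 4, s_neg / 4))
  expect_identical(unclass(base)[, ], unclass(shrunk)[, ])
  odd <- prob_ratio(pos, neg,
                    make_flow(colnames(pos), s_pos / 3, s_neg / 3))
  expect_equal(unclass(odd)[, ], unclass(base)[, ], tolerance = 1e-12)
})

test_that("ratios ignore a taxon's overall abundance as c -> 0", {
  pos <- rand_ra_table(6, 2, 46)
  neg <- rand_ra_table(6, 2, 47)
  flow <- make_flow(colnames(pos), c(0.45, 0.5), c(0.55, 0.5))
  tiny <- 1e-14
  base <- prob_ratio(pos, neg, flow, pseudocount = tiny)
  pos2 <- pos
  neg2 <- neg
  pos2[3, ] <- pos[3, ] * 50   # same factor on both fractions
  neg2[3, ] <- neg[3, ] * 50
  scaled <- prob_ratio(pos2, neg2, flow, pseudocount = tiny)
  expect_equal(scaled[3, ], base[3, ], tolerance = 1e-8)
})

test_that("a simulated taxon's ratio approaches its coating log-odds", {
  com <- ground_truth_community(c(0.6, 0.3, 0.1), c(0.8, 0.5, 0.3))
  sim <- simulate_fractions(com, sort_spec(read_depth = 1e6, seed = 12))
  pos <- sim$counts[, "igg_pos", drop = FALSE] /
    sum(sim$counts[, "igg_pos"])
  neg <- sim$counts[, "igg_neg", drop = FALSE] /
    sum(sim$counts[, "igg_neg"])
  colnames(pos) <- colnames(neg) <- "S1"
  flow <- normalise_flow_isotype(sim$flow)
  r <- prob_ratio(pos, neg, flow, pseudocount = 1e-8)
  expect_equal(r["taxon_001", 1], log2(0.8 / 0.2), tolerance = 0.1)
})

test_that("fraction presence counts partition detected taxa", {
  t2 <- presence_tables(7, 7, 201)
  res <- classify_fraction_presence(t2$pos, t2$neg)
  expect_equal(res$n_only_neg, 7)
  expect_equal(res$n_only_pos, 7)
  expect_equal(res$n_both, 201)
  expect_equal(res$proportion_pos, 0.967)

  none <- classify_fraction_presence(tbl(0, 1, 1), tbl(0, 1, 1))
  expect_equal(none$n_both, 0)
  expect_true(is.na(none$proportion_pos))
})

test_that("common-feature selection requires detection in every sample", {
  m <- rand_ra_table(5, 10, 48)
  m[2, 7] <- 0   # present in 9/10 samples only
  kept <- select_common_features(m, threshold = 0)
  expect_false("t02" %in% rownames(kept))
  expect_equal(nrow(kept), 4)

  all_in <- rand_ra_table(5, 4, 49)
  expect_equal(select_common_features(all_in, threshold = 0), all_in)

  sparse <- tbl(c(1, 0, 0, 1), 2, 2)
  expect_warning(res <- select_common_features(sparse, threshold = 0),
                 "no feature")
  expect_equal(nrow(res), 0)
})

test_that("isotype normalisation of flow summaries floors at zero", {
  flow <- make_flow(c("a", "b"), c(0.40, 0.005), c(0.5, 0.9),
                    isotype_pct = 1)
  expect_warning(norm <- normalise_flow_isotype(flow), "flooring")
  expect_equal(norm$igg_pos_size, c(0.39, 0))
  expect_equal(norm$igg_neg_size, flow$igg_neg_size)
})
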