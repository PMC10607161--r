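gene_bundle <- function() {
  fams <- c("famA", "famB")
  samples <- c("p1", "p2")
  make <- function(v) matrix(v, 2, 2, dimnames = list(fams, samples))
  list(all = make(c(10, 0, 10, 10)),
       igg_pos = make(c(4, 4, 4, 4)),
       igg_neg = make(c(6, 6, 6, 6)))
}

test_that("families absent from a participant's 'all' fraction are zeroed", {
  z <- zero_families_absent_in_all(gene_bundle())
  # famB absent in participant p1 only: zeroed there, untouched in p2
  expect_equal(unname(z$igg_pos[, "p1"]), c(4, 0))
  expect_equal(unname(z$igg_neg[, "p1"]), c(6, 0))
  expect_equal(unname(z$igg_pos[, "p2"]), c(4, 4))

  full <- gene_bundle()
  full$all[2, 1] <- 1
  expect_equal(zero_families_absent_in_all(full)$igg_pos,
               full$igg_pos)

  expect_error(zero_families_absent_in_all(gene_bundle()[c("all",
                                                           "igg_pos")]),
               "igg_neg")
})

test_that("prevalence filter drops families below threshold too often", {
  m <- tbl(0.1, 3, 10, taxa = c("keep", "drop8", "keep6"))
  m["drop8", 1:8] <- 1e-7    # below threshold in 8/10 samples
  m["keep6", 1:6] <- 1e-7    # below in 6/10: retained
  out <- prevalence_filter(m, threshold = 1e-6, max_below = 7)
  expect_equal(rownames(out), c("keep", "keep6"))

  # disabled filter is the identity
  expect_equal(prevalence_filter(m, max_below = 11), m)
})

test_that("CLR centres logs per sample", {
  unif <- tbl(rep(0.25, 4), 4, 1)
  expect_equal(unname(clr_transform(unif)[, 1]), rep(0, 4))

  v <- c(1, exp(2), 1)
  comp <- tbl(v / sum(v), 3, 1)
  expect_equal(unname(clr_transform(comp)[, 1]), c(-2 / 3, 4 / 3, -2 / 3),
               tolerance = 1e-12)

  m <- rand_ra_table(6, 4, 60)
  out <- clr_transform(m)
  expect_equal(unname(colSums(out)), rep(0, 4), tolerance = 1e-10)
  # invariance to per-sample rescaling
  expect_equal(clr_transform(m * 7), out, tolerance = 1e-12)

  zeros <- tbl(c(0, 1, 1, 1), 2, 2)
  expect_error(clr_transform(zeros, pseudocount = 0), "pseudocount")
  # automatic pseudocount keeps the transform defined
  expect_true(all(is.finite(clr_transform(zeros))))
})

test_that("PCA orders components and fixes signs deterministically", {
  set.seed(61)
  x <- rnorm(20)
  two <- rbind(a = x, b = 2 * x + 3)
  colnames(two) <- sprintf("s%02d", 1:20)
  fit <- pca(two)
  expect_equal(fit$explained_variance[1], 1, tolerance = 1e-12)

  m <- rand_ra_table(15, 8, 62)
  fit2 <- pca(m)
  expect_true(all(diff(fit2$explained_variance) <= 1e-12))
  expect_equal(sum(fit2$explained_variance), 1, tolerance = 1e-10)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_along(fit2$explained_variance)) {
    l <- fit2$loadings[, j]
    expect_gte(l[which.max(abs(l))], 0)
  }

  # isotropic noise spreads variance roughly evenly
  set.seed(63)
  iso <- matrix(rnorm(4 * 500), 4, 500,
                dimnames = list(letters[1:4], sprintf("s%03d", 1:500)))
  fit3 <- pca(iso)
  expect_true(all(abs(fit3$explained_variance - 0.25) < 0.1))

  dup <- tbl(rep(c(1, 2), 2), 2, 2)
  expect_error(pca(dup), "zero total variance")
  expect_error(pca(m, n_components = 100), "exceeds")
})

test_that("gene-family ratios keep only families scored in every sample", {
  fams <- c("same", "gone", "partial")
  samples <- c("s1", "s2")
  make <- function(v) matrix(v, 3, 2, dimnames = list(fams, samples))
  pos <- make(c(0.5, 0, 0.4, 0.5, 0, 0))
  neg <- make(c(0.5, 0, 0.2, 0.5, 0, 0.1))
  flow <- make_flow(samples, c(0.5, 0.5), c(0.5, 0.5))
  r <- gene_family_prob_ratio(pos, neg, flow)
  expect_equal(rownames(r), c("same", "partial"))  # absent-everywhere drops
  expect_equal(unname(r["same", ]), c(0, 0))       # identical behaviour
})

test_that("a family carried by a fully coated taxon scores positive", {
  # two taxa; famX only in the (strongly coated) first taxon
  theta <- c(0.99, 0.2)
  incidence <- matrix(c(1, 0, 1, 1), 2, 2,
                      dimnames = list(c("t1", "t2"), c("famX", "famY")))
  n_samples <- 4
  pos <- neg <- matrix(NA_real_, 2, n_samples,
                       dimnames = list(c("famX", "famY"),
                                       sprintf("s%d", 1:n_samples)))
  flows <- vector("list", n_samples)
  for (j in seq_len(n_samples)) {
    com <- ground_truth_community(c(0.5, 0.5), theta,
                                  taxon_ids = c("t1", "t2"),
                                  gene_incidence = incidence)
    sim <- simulate_fractions(com, sort_spec(read_depth = 1e5, seed = j,
                                             isotype_background = 0))
    fam_pos <- t(incidence) %*% sim$counts[, "igg_pos"]
    fam_neg <- t(incidence) %*% sim$counts[, "igg_neg"]
    pos[, j] <- fam_pos / sum(fam_pos)
    neg[, j] <- fam_neg / sum(fam_neg)
    flows[[j]] <- sim$flow
    flows[[j]]$sample_id <- sprintf("s%d", j)
  }
  flow <- do.call(rbind, flows)
  r <- gene_family_prob_ratio(pos, neg, flow, pseudocount = 6e-10)
  expect_true(all(r["famX", ] > 0))
})
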