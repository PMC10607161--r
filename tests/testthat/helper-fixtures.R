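# Shared fixtures and independent oracles, built in code at test time.

# Independent element-by-element transcription of the log2 coating
# probability-ratio formula. Deliberately loop-based and separate from the
# vectorised implementation it cross-checks.
oracle_prob_ratio <- function(pos, neg, s_pos, s_neg, c, scale = TRUE) {
  out <- matrix(NA_real_, nrow(pos), ncol(pos), dimnames = dimnames(pos))
  for (j in seq_len(ncol(pos))) {
    sp <- s_pos[j]
    sn <- s_neg[j]
    if (scale) {
      m <- max(sp, sn)
      sp <- sp / m
      sn <- sn / m
    }
    for (i in seq_len(nrow(pos))) {
      out[i, j] <- log2((pos[i, j] * sp + c) / (neg[i, j] * sn + c))
    }
  }
  out
}

# Random taxa-by-samples relative-abundance matrix (columns sum to 1).
rand_ra_table <- function(n_taxa, n_samples, seed,
                          taxa = sprintf("t%02d", seq_len(n_taxa)),
                          samples = sprintf("s%02d", seq_len(n_samples))) {
  set.seed(seed)
  m <- matrix(stats::rgamma(n_taxa * n_samples, shape = 0.5),
              n_taxa, n_samples, dimnames = list(taxa, samples))
  sweep(m, 2, colSums(m), "/")
}

make_flow <- function(sample_ids, pos_size, neg_size, isotype_pct = 0,
                      load = 1.5e11) {
  data.frame(sample_id = sample_ids,
             igg_pos_size = pos_size,
             igg_neg_size = neg_size,
             isotype_pct = isotype_pct,
             microbial_load = load,
             stringsAsFactors = FALSE)
}

# Matrix constructor with mandatory dimnames, for terse fixtures.
tbl <- function(values, n_taxa, n_samples,
                taxa = sprintf("t%02d", seq_len(n_taxa)),
                samples = sprintf("s%02d", seq_len(n_samples))) {
  matrix(values, n_taxa, n_samples, dimnames = list(taxa, samples))
}

# Score a generated cohort exactly as the pipeline does and return the mean
# probability ratio per sample split by role, plus the paired-test p-value.
score_cohort_means <- function(cohort, pseudocount = 1e-5,
                               threshold = 1e-5) {
  all_ra <- total_sum_scale(cohort$counts$all)
  pos_ra <- total_sum_scale(cohort$counts$igg_pos)
  neg_ra <- total_sum_scale(cohort$counts$igg_neg)
  z <- zero_absent_in_all(pos_ra, neg_ra, all_ra, threshold)
  flow <- normalise_flow_isotype(cohort$flow)
  r <- prob_ratio(z$pos, z$neg, flow, pseudocount = pseudocount)
  mean_r <- colMeans(r)
  md <- cohort$metadata
  pat <- mean_r[md$sample_id[md$role == "patient"]]
  con <- mean_r[md$sample_id[md$role == "control"]]
  list(patient = pat, control = con,
       p_value = paired_t_test(pat, con)$p_value)
}

# Build pos/neg abundance tables for one sample realising a presence-count
# triple (only-neg / only-pos / both) at detection threshold `thr`.
presence_tables <- function(n_only_neg, n_only_pos, n_both, thr = 1e-5) {
  n <- n_only_neg + n_only_pos + n_both
  taxa <- sprintf("t%03d", seq_len(n))
  pos <- rep(0, n)
  neg <- rep(0, n)
  hi <- 10 * thr
  if (n_only_neg > 0) neg[seq_len(n_only_neg)] <- hi
  if (n_only_pos > 0) pos[n_only_neg + seq_len(n_only_pos)] <- hi
  if (n_both > 0) {
    idx <- n_only_neg + n_only_pos + seq_len(n_both)
    pos[idx] <- hi
    neg[idx] <- hi
  }
  list(pos = tbl(pos, n, 1, taxa, "s1"), neg = tbl(neg, n, 1, taxa, "s1"))
}
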