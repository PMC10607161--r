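# iggseq

Antibody-coating analysis of the intestinal microbiome from flow-sorted
microbial fractions (IgG-Seq / IgA-seq style experiments).

## The problem

Host antibodies coat a subset of gut microbes. Sorting SYBR-stained stool
microbes into an antibody-bound ('IgG positive') and an unbound
('IgG negative') fraction and shotgun-sequencing each fraction, alongside
the unsorted ('all') community, reveals *which* taxa the host's
immunoglobulin repertoire recognises. `iggseq` implements the computational
half of that experiment for paired patient–control cohorts:

* **Probability-ratio scoring.** For taxon *i* in sample *j* with relative
  abundances `pos_ij` / `neg_ij` inside the sorted fractions and fraction
  sizes `S+_j` / `S-_j` (proportions of SYBR+ events),

  ```
  ratio_ij = log2( (pos_ij * S+_j + c) / (neg_ij * S-_j + c) )
  ```

  with pseudocount `c` (default 1e-5 for taxa, 6e-10 for gene families) and
  optional scaling of both fraction sizes by the larger of the two. The
  numerator and denominator estimate the joint probability that a random
  cell belongs to taxon *i* and lands in the bound / unbound fraction, so
  the score converges to the coating log-odds `log2(theta/(1-theta))`
  independently of the taxon's abundance.
* **Profiles.** Relative microbiome profiles (total-sum scaling, detection
  threshold 1e-6, pseudocount 1e-7) and quantitative profiles in cells/gram
  via flow-cytometric microbial loads.
* **Diversity.** Shannon and inverse Simpson indices, analytic
  (hypergeometric) rarefied richness, Bray–Curtis dissimilarity and NMDS
  (all via `vegan`).
* **Functional analysis.** Gene-family zeroing against the 'all' fraction,
  renormalisation, prevalence filtering, CLR transform and PCA; coating
  probability ratios of gene families.
* **Paired statistics.** Two-tailed paired t-tests (with a recorded
  log-transform rule), Pearson correlations, isotype-control normalisation
  and absolute bound-cell loads.
* **A synthetic cohort generator** with known per-taxon coating
  probabilities, household-correlated communities, sorter non-idealities
  (gating gap, isotype background) and multinomial sequencing noise — so
  the whole pipeline is testable against ground truth.

## Worked example

Simulate three household pairs in which patients' coating odds are scaled
by 0.25 (a strong IgG hyporeactivity effect), then analyse end to end:

```r
library(iggseq)
cfg <- run_config(input_dir = "inputs", output_dir = "results", seed = 42,
                  scenario = list(n_pairs = 3, patient_theta_scale = 0.25))
run_simulate(cfg)
res <- run_analyse(cfg)

round(colMeans(res$ratios_common), 2)
#> pair1_patient pair1_control pair2_patient pair2_control pair3_patient pair3_control
#>         -2.38         -0.43         -2.06         -0.06         -1.77          0.21

res$stats[, c("measure", "n_pairs", "t_statistic", "p_value")]
#>                 measure n_pairs t_statistic      p_value
#> 1       mean_prob_ratio       3 -163.717182 3.730673e-05
#> 2               shannon       3   -0.848304 4.856042e-01
#> 3 igg_pos_fraction_size       3  -18.369276 2.950466e-03
```

Each patient's mean probability ratio sits roughly `log2(0.25) = -2` below
their household control — the simulated coating deficit, recovered by the
score — while community diversity (Shannon) shows no difference, as
expected: the effect is immunological, not compositional. `results/`
contains every table (RMP/QMP, per-taxon and per-gene-family ratios,
fraction-presence counts, alpha/beta diversity, NMDS coordinates, PCA
scores, paired statistics) plus a JSON manifest.

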