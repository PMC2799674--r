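# cipkit

Tools for finding **expression level polymorphisms (ELPs)** — genes whose
transcript abundance differs heritably between two genotypes and responds
differently to a stress treatment — from probe-level oligonucleotide array
data, together with the downstream evidence that makes such a call
convincing: annotation-category enrichment, shared promoter motifs, and
insertion/deletion polymorphisms near the genes.

The package is aimed at analysts comparing two sequenced genotypes (the
motivating case is *japonica* vs *indica* rice under methyl-viologen
oxidative stress) on a single-genotype array design, where probe-level
sequence polymorphisms and genotype×treatment interactions both matter.

## The core statistic

For each 25-mer probe, a balanced two-way fixed-effects ANOVA on log2
quantile-normalized intensities tests genotype (G), treatment (T) and their
interaction (G×T):

    SS_G  = 2r Σ_g (ȳ_g − ȳ)²      SS_T = 2r Σ_t (ȳ_t − ȳ)²
    SS_GT = r Σ_gt (ȳ_gt − ȳ_g − ȳ_t + ȳ)²
    F     = SS_effect / (SSE / 4(r−1))   ~  F(1, 4(r−1))

with Benjamini–Hochberg q-values per effect. A probe set is called a
**Core Intersectional Probeset (CIP)** when at least 3 member probes are
significant (raw p ≤ 0.01) for *all three* effects, and each CIP is placed
in an expression quadrant by the signs of its genotype-preference and
treatment-response deltas on probe-set-level signals (20%-trimmed-mean
summaries, per-array scaled to a target mean of 500).

Around that core: a probe-vs-genome polymorphism screen (exact/≤k-mismatch,
both strands), hypergeometric category enrichment, a deterministic
MDscan-style seed-and-refine motif search with IUPAC element scanning, a
strand-aware InDel classifier (upstream/genic/downstream), and a seeded
synthetic-data generator that plants all of the above so the pipeline can be
validated end to end.

## Worked example

```r
library(cipkit)

sc  <- sim_scenario(rng_seed = 7)     # 2 genotypes x 2 treatments x 3 reps,
dat <- simulate_dataset(sc)           # 200 probe sets x 11 probes, 10% CIPs
res <- run_elp_pipeline(dat$intensities, dat$design, dat$map)

res$venn
#>        cultivar_only        treatment_only      interaction_only
#>                  168                    23                    20
#>   cultivar_treatment  cultivar_interaction treatment_interaction
#>                  153                     5                     3
#>               triple                  none
#>                   58                  1770

head(res$cips[, c(1, 3:6)], 4)
#>   probeset_id n_core_probes   quadrant cultivar_delta treatment_delta
#> 1      PS0008             3 prefB_down      -1.139778      -1.0272644
#> 2      PS0010             3 prefB_down      -1.426122      -0.7489571
#> 3      PS0037             5   prefA_up       2.217518       0.9818688
#> 4      PS0053             3   prefA_up       1.099964       1.4749759

evaluate_recovery(res$cips$probeset_id, dat$truth$sets)
#> $sensitivity  0.55      $fdr  0
```

Of the 2,200 probes, 58 are significant for all three effects; 11 probe
sets clear the ≥3-core-probe gate, all of them planted CIPs (FDR 0), and
their quadrants (e.g. `prefA_up`: preferred in genotype A and induced by the
treatment) match the planted truth. Downstream evidence on the same
scenario:

```r
enrich(dat$truth$sets$probeset_id[dat$truth$sets$is_cip], dat$annotations)[1, ]
#>   category_id query_count background_count      p_value      q_value
#> 1      CAT001          10               18 4.362664e-07 1.308799e-05

find_motifs(dat$promoters[dat$truth$sets$is_cip], w = 8)[[1]]$consensus
#> [1] "AGTCAAAC"          # the planted W-box
```

The planted enriched category ranks first, and the planted W-box is
recovered as the top motif consensus.

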