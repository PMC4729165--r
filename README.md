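# focaltc

Time-course expression analysis of focal high-dose lung irradiation.

Stereotactic body radiotherapy delivers an ablative dose to a small tissue
volume; the molecular question is what that does to the irradiated spot,
to the non-irradiated tissue next to it, and how either compares with a
conventional diffuse dose. focaltc is an R package for analyzing the
resulting study design — one pooled microarray per condition, two 90 Gy
lung regions (focally irradiated and neighboring) sampled over weeks, a
20 Gy whole-lung series over months, and a non-irradiated control — as a
reproducible pipeline rather than a chain of web tools. It is aimed at
computational biologists who need every stage scripted, seeded, and
testable.

The pipeline stages, each an exported function working on a gene x time
matrix of log2 expression ratios versus control:

1. **Preprocessing** — probe filtering (signal > 1.4x local background),
   quantile normalization, duplicate-spot averaging, log2 ratios,
   average-linkage hierarchical clustering under 1 - Pearson distance,
   and the 2^-ddCt qRT-PCR helper.
2. **Temporal patterns** — short time-series clustering against a library
   of integer model profiles (all `(2c+1)^(T-1)` candidates, greedy
   maximin selection of `m = 50`), assignment by Pearson correlation, and
   profile significance from `n` permutations of each gene's time-point
   order: expected counts `s_j`, a hypergeometric tail, per-profile
   permutation p (plus mid-p), and an empirical FDR
   `q_j = E[#{permuted count >= threshold}] / #{observed count >= threshold}`.
3. **Enrichment** — hypergeometric / EASE over-representation with
   Benjamini-Hochberg FDR, information-content semantic similarity
   (Resnik/Lin), REVIGO-style redundancy reduction with dispensability
   scores, term networks, and per-time-point enrichment tracks.
4. **Pathway impact** — the two-evidence topology analysis: P_NDE
   (hypergeometric membership), perturbation propagation
   `PF(i) = dE(i) + sum_j beta(i<-j) PF(j)/N_ds(j)` with net accumulation
   `t_A`, bootstrap P_PERT (3000 iterations, two-sided around the null
   median), and the combination `P_G = c - c ln c`, `c = P_NDE * P_PERT`.
5. **Pathway activity** — sign-weighted mean log2 ratio per pathway and
   sample (repressors weighted -1, normalized by pathway size) with a
   gene-label permutation FDR and clustering of significant activity
   profiles.
6. **Network modules** — co-expression filtering (Pearson r > 0.8) of
   differentially expressed genes, intersection with a functional
   interaction database, Markov clustering (inflation 2.0), module GO
   annotation, and cross-region module comparison.
7. **Synthetic data** — a seeded generator planting temporal patterns,
   enriched gene sets, a perturbed pathway topology, and network modules,
   with the ground truth serialized next to the data, so every stage above
   is testable end to end without downloads.

## Worked example

```r
library(focaltc)

cfg <- synthetic_config(seed = 1)          # 2000 genes, a = 2, sigma = 0.2
sim <- simulate_timecourse(cfg)
tc  <- synthetic_timecourse(sim)           # filter -> average -> log2 ratios
m   <- tc$focal_90Gy

sel <- select_variable_genes(m, fold = 2)  # 501 genes
lib <- generate_model_profiles(ncol(m), c = 2, m = 50)
asg <- assign_genes(m, sel, lib)
sig <- profile_significance(asg, n_perm = 1000, seed = 3)
sig[order(-sig$n), ][1:2, ]
#>    profile   n      s p_hyper p_perm p_mid     q
#> 15      15 385 54.581       0  0.001 5e-04 0.000
#> 1        1  58  7.268       0  0.001 5e-04 0.707
```

Profile 15 holds 385 genes against a permutation expectation of ~55 and an
empirical FDR of 0 — the planted down-at-mid-course pattern. The second
largest profile collects the monotone-up genes; its high `q` shows the
plug-in FDR being conservative once counts drop toward the permutation
background. Downstream:

```r
tp   <- simulate_topologies(sim$truth, cfg)
de   <- de_from_timecourse(m, fold = 2)
spia <- run_spia(de, rownames(m), tp$topologies, n_boot = 3000, seed = 2)
spia[1, c("pathway", "n_de", "t_a", "p_pert", "p_g", "status")]
#>   pathway n_de      t_a       p_pert          p_g    status
#> 1   PW001   15 203.9638 0.0003333333 0.0008900068 activated
```

The planted activation cascade ranks first with P_PERT at its bootstrap
floor (1/3000). A command-line front end wraps the same functions:

```sh
Rscript inst/cli/pipeline.R simulate --out sim --seed 1
Rscript inst/cli/pipeline.R normalize --probes sim/probes.tsv --design sim/design.csv --out norm
Rscript inst/cli/pipeline.R patterns --timecourse norm/focal_90Gy.tsv --n-perm 1000 --seed 1 --out patterns
```

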