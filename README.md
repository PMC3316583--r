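# conseg

Bayesian multiple change-point segmentation of cross-species sequence
conservation, for single genes and other short genomic windows.

## What it does

Comparative genomics tools usually classify conservation at
whole-genome scale; `conseg` brings the same style of analysis to a
single locus.  Starting from a reference-anchored multiple alignment
(human / mouse / rat in the motivating use case), each column is
encoded as a ternary conservation code — the number of distinct
symbols in the column, gaps counted as an extra character, minus one —
and the code sequence is segmented by a Bayesian multiple change-point
mixture model fitted by MCMC:

- changepoint indicators `b_j ~ Bernoulli(rho)` at each boundary, with
  `rho ~ Beta(1,1)`;
- segment class labels `z_s ~ Categorical(pi)` over `k` latent
  conservation classes, `pi ~ Dirichlet(1,...,1)`;
- segment code counts `(n0, n1, n2)` entering through the
  Dirichlet-multinomial marginal
  `log Γ(A)/Γ(A+n) + Σ_c log Γ(α_c+n_c)/Γ(α_c)` with class parameters
  `α_g` (per-segment proportions integrated out), each `α` component
  under a log-uniform prior on (1e-3, 1e6).

The fit yields per-position posterior class profiles (exported as UCSC
fixedStep wiggle tracks), AIC/BIC/DIC model selection over `k`, a
profile-threshold classifier for protein-coding sequence with
sensitivity/specificity evaluation, and conserved-feature interval
extraction.  Companion modules scan DNA for splicing-regulatory motifs
(G triplets, CA repeats, YCAY, the PTB motifs CUCUCU/UCUUC, the AAUAAA
polyadenylation signal) with cross-species conservation filtering,
scan proteins for PROSITE-style phosphorylation acceptor sites
(`[ST]XX[DE]`, `[ST]X[RK]`, `[RK]XX[ST]`), split intermediate-filament
isoforms into head+rod and tail domains, and compute Kyte-Doolittle
hydropathy profiles (window 9).  A synthetic-data generator mirrors
the model exactly, so every stage is testable against known ground
truth without downloads.

## Worked example

Simulate a 20 kb alignment window with four conservation classes and
known truth, fit the model, and evaluate the coding classifier:

```r
library(conseg)

sc  <- recovery_scenario()        # 4 classes, code-0 means .95/.75/.50/.25
sim <- simulate_codes(sc$length, sc$k, sc$pi, sc$alphas, sc$rho, seed = 1)
sim
#> <conseg_sim> 20000 positions, 4 classes, 99 changepoints, seed 1

fit <- conseg(sim$codes, k = 4, n_iter = 1000, burn_in = 500, seed = 1)
summary(fit)
#> Change-point mixture fit: N = 20000, k = 4, 1000 iterations (burn-in 500)
#> posterior mean changepoint count: 110.9 (rho = 0.005596)
#> posterior mean mixture weights (pi):
#> [1] 0.2971 0.3018 0.1784 0.2227
#> ...
#> implied mean code proportions per class:
#>         code0  code1  code2
#> class1 0.9506 0.0405 0.0088
#> class2 0.4874 0.4168 0.0958
#> class3 0.8019 0.1570 0.0412
#> class4 0.2497 0.5414 0.2088
```

Mixture classes are exchangeable, so fitted class 1 here is the
conserved (code-0 ≈ 0.95) class; `best_label_permutation()` aligns
fitted to true labels before scoring:

```r
profiles <- compute_profiles(fit)           # N x k, rows sum to 1
match <- best_label_permutation(max.col(profiles, ties.method = "first"),
                                sim$position_labels, 4)
round(match$accuracy, 3)
#> [1] 0.958

coding_col <- which(match$permutation == 2) # fitted column of true class 2
classifier_confusion(profiles[, coding_col], annotate_coding(sim, 2))
#> TP=5233 FN=121 TN=14611 FP=35
#> sensitivity=0.9774 specificity=0.9976

head(extract_features(profiles[, coding_col]), 3)
#>   start  end length      mean   max label
#> 1     0  899    899 0.9914727 1.000     A
#> 2  1073 1309    236 0.9974576 1.000     B
#> 3  1542 1596     54 0.9763333 0.998     C
```

96% of positions land in the right class, and thresholding the
conserved-class profile at 0.5 recovers the planted "coding" segments
with sensitivity 0.98 and specificity 1.00.  `write_wiggle()` exports
any profile column for the UCSC browser; `information_criteria()` plus
`select_k()` choose the class count from a scan over `k`.

Motif and protein tools work on plain strings and FASTA:

```r
find_g_runs("GCAAAGGGATCCAGCTCTCCCTGGGGGCCTTCGTGACAC")
#>   seq_id start length  text motif strand
#> 1    seq     5      3   GGG g_run  sense
#> 2    seq    22      5 GGGGG g_run  sense

scan_protein_pattern("TSLD", "CKII")$start   # [ST]XX[DE]
#> [1] 0
```

A thin command-line front end (`inst/scripts/conseg`) exposes the
pipeline as subcommands (`simulate`, `encode`, `segment`, `select`,
`evaluate`, `scan`, `protein`) for shell use.

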