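---
title: "Segmenting cross-species conservation with a Bayesian change-point mixture model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting cross-species conservation with a Bayesian change-point mixture model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conseg)
```

## The problem

A single gene's regulatory architecture — exons, untranslated regions,
splice-control elements, polyadenylation signals — leaves a footprint in
cross-species conservation.  Given a reference-anchored alignment of a
genomic window across a few species (here human against mouse and rat),
`conseg` asks: *which stretches of the sequence share the same level and
style of conservation, and what are those levels?*  It answers with a
Bayesian multiple change-point segmentation whose latent classes
correspond to conservation regimes (e.g. "exon-like highly conserved",
"reference-specific insertion", "rodent deletion", "background"), and
with per-position posterior probabilities of class membership that can
be thresholded into an annotation-free detector of protein-coding
sequence.

## From alignment to codes

Each alignment column is reduced to a ternary **conservation code**:
the number of distinct symbols among the aligned characters minus one,
with a gap counted as an extra character (a single change).  For three
species the codes are 0 (all identical), 1 (two distinct symbols — one
mismatch, or one/two gaps in the same state) and 2 (three distinct
symbols).  Runs of gaps are scored column by column, never compressed:
this keeps per-base conservation information at the cost of some Markov
dependence between adjacent characters that the model ignores.
Reference-gap columns are dropped during projection, so positions map
one-to-one onto reference coordinates.  `N` is treated as a distinct
symbol, with a warning and a count, which is conservative and
deterministic; soft-masked lowercase is uppercased.  Columns also carry
a 10-valued **pattern label** (`AAA`, `AAB`, `ABA`, `ABB`, `ABC`,
`AA-`, `A-A`, `AB-`, `A-B`, `A--`) used for per-class composition
tables; the code equals the number of distinct symbols in the label
minus one, an invariant the tests enforce.

## The model

Writing $x_1,\dots,x_N$ for the codes, the model places:

* independent Bernoulli($\rho$) changepoint indicators at each of the
  $N-1$ between-character boundaries, $\rho \sim \mathrm{Beta}(1,1)$;
* i.i.d. class labels $z_s \sim \mathrm{Cat}(\pi)$ for each segment,
  $\pi \sim \mathrm{Dirichlet}(1,\dots,1)$ over $k$ classes;
* per-segment code proportions $\theta_s \sim
  \mathrm{Dirichlet}(\alpha_{z_s})$, integrated out analytically, so a
  segment with code counts $(n_0,n_1,n_2)$ contributes the
  Dirichlet-multinomial marginal
  $\log\frac{\Gamma(A)}{\Gamma(A+n)} + \sum_c
  \log\frac{\Gamma(\alpha_c+n_c)}{\Gamma(\alpha_c)}$, $A=\sum_c\alpha_c$;
* independent log-uniform priors on $(10^{-3}, 10^{6})$ for every
  $\alpha$ component.  The wide upper bound matters: concentrations in
  the $10^5$ range do occur in real chains, and the flat upper region of
  the likelihood is a genuine feature of the posterior that the sampler
  must handle (see *Mixing* below).

$k$ is fixed per fit and scanned externally (default 1–10), as is usual
for this model family; there is no transdimensional sampling.

## The sampler

`conseg()` alternates five move groups per iteration:

1. an **exact Gibbs sweep over all $N-1$ boundaries** with the segment
   labels summed out (each flip compares the label-marginalized
   evidence of split vs merged segments, in log space with cached
   log-gamma tables).  Because every boundary is resampled every
   iteration, separate changepoint "shift" moves would be redundant —
   a misplaced boundary dies and is reborn at the right place within a
   sweep or two;
2. Gibbs resampling of each segment label from
   $\pi_g \times$ marginal;
3. a conjugate Dirichlet update of $\pi$ from label counts;
4. a conjugate Beta update of $\rho$ from the boundary count;
5. Metropolis updates of each class's $\alpha$ vector with the labels
   marginalized out again (partially collapsed, so segments can softly
   re-associate while $\alpha$ moves): a moment-anchored independence
   proposal of the whole vector, a joint scale move with a step-size
   mixture (0.3 / 3.0 in log space), and two random-walk sweeps over
   components (step adapted towards 0.44 acceptance during burn-in
   only).

All randomness flows through R's RNG, so a fit is bit-reproducible from
its seed.  Defaults are 1000 iterations with a burn-in of 500;
convergence of the log-likelihood, changepoint count, $\pi$ and
$\alpha$ traces is summarized by `convergence_diagnostics()`, which
flags a first-half/second-half log-likelihood difference above three
pooled standard errors.

**Initialization.**  Chains start from a method-of-moments state:
k-means on 50-column window code proportions gives class centers,
initial labels and boundaries; per-class concentrations come from a
Dirichlet-multinomial moment estimator, capped at 300 because k-means
cells truncate within-cluster variance and would otherwise inflate the
estimate into a rigid (huge-concentration) starting state.  With this
warm start, burn-in refines rather than finds the class structure,
which is what makes the 1000-iteration default adequate.

**Mixing.**  For heavily overlapping classes the posterior genuinely
contains configurations in which one class becomes near-rigid (very
large $A$) and the labels reorganize around it; chains can dwell there.
The marginalized $\alpha$ updates and the heavy-tailed scale move
mitigate this, and the validation suite pins the sampler to exact
enumeration on short sequences, but users fitting overlapping classes
should expect class-assignment uncertainty to be real rather than an
artifact (compare the two bundled scenarios below).

## Profiles, model selection, classification

`compute_profiles()` averages, over post-burn-in samples, the indicator
that a position lies in a segment of class $g$; rows sum to one by
construction.  Profiles export as fixedStep wiggle tracks (browser
1-based coordinates; internally everything is 0-based half-open).

`information_criteria()` reports, per $k$, approximations to AIC
($-2\max\ell + 2p$), BIC ($-2\max\ell + p\log N$) and DIC (mean
deviance $+ \tfrac12$ variance of deviance), with
$p = 3k + (k-1) + 1$ free parameters and $\ell$ the post-burn-in data
log-likelihood given the sampled segmentation.  Because the
segmentation itself absorbs most of the fit, the maximum-likelihood AIC
keeps creeping downward past the true class count (an extra class
always buys a little fit), so selection uses an **elbow rule**:
`select_k()` picks the smallest $k$ whose improvement to the next $k$
is below 20% of the largest single-step improvement in the scan.  BIC
(which favours one class here) and DIC (too variable) are reported but
not used to select.

`assign_unambiguous()` assigns a position to a class when that class's
profile strictly exceeds a threshold (≥ 0.5, so assignment is unique);
`pattern_composition()` tabulates column patterns per class;
`classifier_confusion()` scores the designated "coding" class profile
against a coding annotation with the standard definitions —
coding ∧ called = TP, coding ∧ uncalled = FN, non-coding ∧ called =
FP, non-coding ∧ uncalled = TN, UTRs counting as non-coding —
and `sensitivity_specificity()` returns TP/(TP+FN) and TN/(TN+FP).
(Some descriptions of this procedure swap the TN/FP wording; the
definitions here are the only ones consistent with those ratios.)
`extract_features()` turns a profile into conserved-feature intervals
(threshold 0.5, minimum length 10, merge gap 5 by default — chosen so
that features of a few tens of nucleotides survive extraction).

## The synthetic generator and what passing tests mean

`simulate_codes()` is the exact generative mirror of the model:
Bernoulli boundaries, categorical labels, Dirichlet proportions, i.i.d.
codes.  `emit_alignment()` inverts the code mapping into concrete
3-species columns (re-encoding reproduces the codes exactly), and
`annotate_coding()` exports the true class-2 runs as a coding
annotation.  Two scenarios are bundled:

* `recovery_scenario()` — mean code-0 proportions 0.95/0.75/0.50/0.25
  (class 2 the conserved, exon-like class), equal weights,
  concentration 100, $\rho = 0.005$, $N = 20{,}000$.  Classes are
  separated by 2–3 within-class standard deviations at the mean
  segment length of 200; this is the benchmark on which the package
  asserts ≥ 0.80 argmax-class accuracy, changepoint-count recovery
  within ±20%, ≥ 0.85 classifier sensitivity/specificity, and
  majority selection of $k=4$ by the AIC elbow over a 1–6 scan.
* `gfap_scenario()` — code-0 proportions 0.35/0.95/0.60/0.45 with
  weights (0.1, 0.3, 0.4, 0.2) and class-specific column-pattern
  signatures (a reference-insertion class dominated by `A--`, a
  conserved class, a background class, a rodent-deletion class
  dominated by `AA-`/`A-A`), emulating the qualitative structure of a
  real single-gene window.  Three of its classes are nearly collinear
  in code space, which is realistic and hard: the posterior itself is
  diffuse across them, so class accuracy is reported for this scenario
  rather than asserted.

Because generator and model coincide, recovery tests are exactly
calibrated — they validate the inference machinery, not the model's
fit to real alignments.  What they cannot show: robustness to gap-run
autocorrelation (real indels come in runs; an optional gap-run length
in the emitter exists for robustness exploration only), to
alignment errors, or to conservation structure outside the
Dirichlet-multinomial family.  The changepoint-count check deserves a
caveat: the posterior mean count is calibrated *on average* over data
realizations, but for an individual realization it can sit 25% or more
from the planted count (boundaries between same-class segments are
nearly invisible, and their posterior mass is replaced by the learned
prior rate); independent chains agree on such values, so this is the
posterior, not a sampler artifact.

## Problem sizes and runtime

The bundled checks run on one CPU: the exhaustive-enumeration
comparison uses 12 positions and 20,000 fixed-parameter iterations
(about 3 s); recovery, classifier and model-selection checks use
$N = 20{,}000$ with the default 1000 iterations (about 5 s per fit;
the 20-replicate $k=1..6$ selection scan is the long pole at roughly
eight minutes).  A 110 kb window at $k=4$ costs about 30 s per fit at
the default settings.

## Motif and protein companions

The motif scanner covers the splicing-regulatory elements relevant to
this kind of 3′-isoform analysis — maximal G runs (min 3), maximal
perfect CA tandem repeats (min 3 units), YCAY, the PTB-binding motifs
CUCUCU and UCUUC (scanned as DNA), and the AAUAAA polyadenylation
signal — plus arbitrary IUPAC patterns, all reporting every
overlapping occurrence.  Where a "cluster" of hits is wanted, the
package reports a sliding-window hit density (50 nt) rather than
inventing a cluster threshold.  `conserved_hits()` calls a
reference-coordinate hit conserved only if every species' gapless
subsequence over the hit's columns matches the motif at full length
(any gap breaks conservation — the simplest column-anchored
definition).  PROSITE-style phosphorylation patterns are matched
exactly (no mismatches): CKII `[ST]XX[DE]`, PKC `[ST]X[RK]`,
cAMP/cGMP-dependent kinase `[RK]XX[ST]` (acceptor at position 4), with
flank annotation of the N-terminal residue (acidic residues enhance
CKII phosphorylation) and of the residue at +5 from the acceptor.

Protein tools split isoforms into head+rod and tail domains from a
metadata table (the bundled GFAP table: head+rod 374 aa mouse, 377
human, 375 rat) and compute sliding-window hydropathy with the
Kyte-Doolittle scale, window 9, full windows only, value at the center
residue, positive = hydrophobic; any other named scale vector (e.g.
OMH) can be plugged in.  The bundled FASTA fixture contains
**synthetic stand-in sequences** at the published isoform lengths —
real accessions must be supplied by the user; tail-relative positions
are reported for tail profiles.

## Numerical choices and degenerate inputs

All likelihoods live in log space; log-gamma values for the boundary
sweep are cached per class up to segment count 2048 with direct
evaluation beyond; log-sum-exp drops terms more than 34 nats below the
maximum (relative error < 2e-15).  Ties in argmax class assignment go
to the lowest class index.  Empty segments contribute zero to the
marginal; an empty code sequence, `k = 0`, `burn_in >= n_iter`,
thresholds below 0.5 for unambiguous assignment, and annotations
outside the profiled region are errors.  `k = 1` is the degenerate
mixture: profiles are identically one.

## Known limitations

* Gap runs violate the i.i.d.-within-segment assumption; the model
  trades that bias for per-base resolution deliberately.
* Posterior class profiles for heavily overlapping classes are
  honestly uncertain; argmax accuracy there is bounded by the
  posterior, not the sampler.
* The AIC/BIC/DIC values are sampling-based approximations; their
  absolute values are not comparable across different data, only
  across $k$ on the same data.
* The MAF reader supports the multiz dialect with `+`-strand reference
  rows and non-overlapping, sorted blocks; uncovered reference
  positions are not invented.
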