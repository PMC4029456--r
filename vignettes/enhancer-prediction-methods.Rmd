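---
title: "Methods: predicting enhancer activity from chromatin marks and motif affinities"
author: "enhancerPred"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: predicting enhancer activity from chromatin marks and motif affinities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

A candidate genomic region is represented by two feature families and a
binary activity label.

**Chromatin (EPI) features.** ChIP signal for each mark is given on a fixed
grid of 50-bp windows (window $i$ covers $[50i, 50(i+1))$ in 0-based
coordinates). The feature for a region is the unweighted arithmetic mean of
every window the region overlaps — a window partially covered counts fully,
and windows beyond the recorded track extent count as 0. This deliberately
simple aggregation makes the feature invariant to how a region is split at
window boundaries (up to window-count weighting), which the test suite
checks.

**Motif (MOT) features.** For each transcription-factor motif, given as a
position weight matrix $p(j, b)$ ($m$ positions $\times$ 4 bases,
regularized with a pseudocount of 1 before taking log-ratios), every length-$m$
site $i$ of the region's sequence has a mismatch energy

$$E_i = \frac{1}{\lambda} \sum_{j=1}^{m} \ln \frac{p(j, b^*_j)}{p(j, b_{ij})},$$

where $b^*_j$ is the consensus base at position $j$. The TRAP occupancy
model converts energies into an expected bound-molecule count,

$$A = \sum_{\text{strands}} \sum_{i=1}^{L-m+1}
      \frac{R_0 e^{-E_i}}{1 + R_0 e^{-E_i}},$$

with $\lambda = 0.7$ and $R_0 = e^{0.584\,m - 5.66}$ by default. Both
strands are scanned and summed (the standard TRAP convention; affinity is
therefore strand-symmetric), sites containing N contribute zero occupancy,
and natural logarithms are used throughout — $\lambda = 0.7$ is calibrated
for that choice. $A$ is bounded by $2(L-m+1)$ and grows with region length;
because negative regions are length-matched to positives, length itself
carries no label information.

**Classifiers.** Three backends see identical feature matrices:

* `rf` — a random forest of 30 CART trees (gini splits, bootstrap
  resampling, $\sqrt{p}$ features per split, grown to purity), score =
  fraction of trees voting positive. Implemented natively (with OOB
  permutation importance) because no forest package is available in the
  target environment; 30 trees is the stated operating point.
* `svm` — an RBF-kernel C-SVM (Platt SMO) on features standardized to zero
  mean and unit variance *using training-fold statistics*; $C = 1$,
  $\gamma = 1/p$. These settings are conventional defaults — the analysis
  this package embodies does not pin them — and are recorded in the model
  object.
* `bde` — a discrete Bayesian classifier. Features are discretized into 3
  equal-frequency bins (edges from training rows; test rows clamp to the
  outer bins; constant features collapse to one bin with a warning). All
  parent sets of the class node up to cardinality 3 are scored exhaustively
  with the Bayesian-Dirichlet-equivalent marginal likelihood (uniform prior,
  equivalent sample size 1), ties broken toward smaller sets and then
  lexicographic order. This replaces full Bayesian-network structure
  learning: only the class node's parents affect classification, and the
  exhaustive-subset cost is the reason a search budget guards against large
  feature sets (125 motifs and parent cardinality 3 already means >300k
  subsets).

**Evaluation.** `crossValidate()` reports per-fold ROC AUC (Mann-Whitney
rank form, ties counted 1/2) and thresholded error (vote fraction 0.5 /
decision value 0 / posterior 0.5). Folds come from a seeded shuffle,
unstratified by default; a `reversed` flag trains on one fold and tests on
the remaining $k-1$, probing training-size sensitivity. Fold means are
reported (not pooled-prediction AUC). `externalValidate()` refuses region
sets overlapping the training regions — filter with `removeOverlapping()`
first.

**Feature importance.** `repeatedImportance()` wraps a native
shadow-variable procedure: each iteration appends a freshly row-permuted
copy ("shadow") of every feature, fits the forest with OOB permutation
importance, and records a hit for features beating the best shadow; a
two-sided binomial test at $\alpha = 0.01$ on hit counts confirms or
rejects features, and $Z = (\text{imp} - \bar{\text{imp}}_{\text{shadow}})
/ \text{sd}(\text{imp}_{\text{shadow}})$ is averaged over iterations. The
procedure is repeated 30 times (an extended-randomization option is the
`nRepetitions` knob) with fresh *contrast variables* — permuted copies of
real features added before each repetition — and the mean number of
confirmed contrasts per repetition estimates the expected number of false
discoveries among the real features. Decisions aggregate by majority over
repetitions. Rejected features are kept in the system across iterations
(rather than dropped) for determinism and simplicity.

**Ablations.** `ablationCurve()` removes single marks or the K most/least
important marks (K = 1..7) and re-cross-validates, reporting the accuracy
loss against the full model. `iterativeTfElimination()` repeatedly removes
the 80% least important transcription factors
($\lfloor 0.8\,n \rfloor$; a single TF once fewer than 5 remain),
re-ranking by repeated importance at each step — the wording "examined in
the previous step" is read as re-running the ranking on the reduced system,
not reusing the initial ranking.

# The synthetic world

`generateDataset()` emulates the statistical structure the analysis
assumes, not the biology of any particular genome:

* Genome: i.i.d. bases at GC 0.41 on 2 chromosomes of 400 kb; 5% of the
  genome is overwritten with 2-mer repeat runs (100-300 bp) that the
  negative sampler can optionally avoid, mimicking low-complexity
  annotation.
* Enhancers: 500 mutually non-overlapping regions with Gaussian lengths
  (mean 270.47 bp, sd 112 bp — the observed statistics of the real positive
  set this design scales down from, which held 8008 regions). A spacing of
  two signal windows (100 bp) is enforced between regions; without it, a
  50-bp window can span two nearby same-label regions and leak correlated
  noise between training and test rows, which measurably biased null AUC
  upward (+0.008) on this dense toy genome. Real genomes are orders of
  magnitude sparser, so the buffer removes an artifact rather than adding
  information.
* Motifs: 20 PWMs of length 8-12 with one dominant base per position
  (probability drawn from [0.8, 0.95], remainder split evenly). The first 2
  are "drivers": each enhancer receives Poisson(6) driver instances
  (bases sampled per position from the PWM, random strand, uniform
  non-overlapping offsets, never straddling the enhancer boundary).
  Non-driver motifs are redrawn while their consensus nearly matches a
  driver consensus (≥ 70% identity over ≥ 5 bp at any ungapped offset on
  either strand): without this, a driver-similar motif genuinely responds
  to the planted sequence and the generator's "uninformative" record would
  simply be wrong for some seeds.
* Tracks: window value = $\delta_m \cdot 1[\text{window overlaps an
  enhancer}] + \mathcal{N}(0, 1)$, with graded effects
  $\delta = (4, 2, 1)$ on H3K4me1, H3K36me3 and Mef2 and 0 elsewhere. The
  grading gives single-mark ablation a strict informativeness ordering.
  An optional non-additive pair routes the whole effect of two marks to
  exactly one of them per enhancer (fair coin) — the simplest mechanism
  with the exclusive-or character reported for enhancer chromatin
  signatures; each mark alone is then weakly informative while the pair
  separates the classes.
* The planted density (6 sites per ~270-bp enhancer, one per ~45 bp) was
  chosen so the per-driver affinity shift is a few times the background
  affinity spread — the dominant background noise is region-length
  variation, since TRAP affinity sums over sites. Sparser planting (3
  sites) drowns in that noise; much denser planting (8+) converts ~30% of
  each enhancer into motif-derived sequence whose composition shift makes
  unrelated motifs genuinely label-informative.

What a green test on this world does **not** establish: performance on real
ChIP-Seq (no read-count noise model, no mapping bias, no nucleosome
structure, flat background), realistic motif co-occurrence grammar, or the
absolute AUC levels of any real dataset. The synthetic world checks the
*machinery* — that signal present in the stated form is found, ranked and
ablated correctly, and that no signal is found when none is planted.

# Negative sampling

Negatives are drawn with chromosome probability proportional to length and
uniform starts; lengths follow the positive set's fitted Gaussian
(`fitLengthDistribution()`, $n-1$ denominator), rounded, redrawn below
20 bp (the Gaussian has mass below 1 bp; the cutoff is this package's
choice). Candidates overlapping an exclusion set, a previous draw (mutual
exclusion is on by default to prevent duplicate training rows), or
consisting of more than 50% N are rejected. Exactly `n` regions are
returned or the sampler errors, naming the exclusion set that rejected most
candidates. After 200 consecutive collisions with previously accepted draws
the accepted set is discarded and sampling restarts — without this escape,
tightly constrained configurations (two 50-bp draws into one 100-bp gap)
deadlock on an unlucky first placement.

# Numerical and design notes

* Coordinates are GRanges-native (1-based, closed) internally; BED and
  bedGraph I/O convert at the boundary and all half-open semantics
  (region length, overlap, abutment) are preserved. This follows the
  Bioconductor containers the package is built on rather than a 0-based
  internal convention.
* bedGraph windows absent from a file are 0; off-grid or overlapping
  windows are errors, and a short window is only legal as the last one of
  a chromosome.
* TRAP sites with scaled energy above 45 are skipped ($< 3\cdot10^{-20}$
  occupancy, far below the $10^{-9}$ oracle-agreement tolerance).
* The BDe score is computed entirely in log space; zero data scores 0.
* All stochastic stages take explicit seeds; `runPipeline()` fans one
  global seed into per-stage seeds (a fixed affine map modulo $2^{31}-2$),
  so every artifact is reproducible byte-for-byte from the manifest.
* The forest, SMO and TRAP scan are small purpose-written C++ routines;
  permutation importance skips features a tree never splits on (their
  permutation provably cannot change predictions).
* Heavy acceptance simulations (importance recovery, ablation ordering) run
  at 200+200 regions rather than 500+500 purely for run time; the criteria
  they check do not pin a problem size. The shadow-importance iteration cap
  is 15 in those runs (the binomial test at $\alpha = 0.01$ can confirm
  from 13/15 hits), against a package default of 100.

# Known limitations

* The SVM and BDe settings are conventional defaults, not tuned; no nested
  cross-validation or calibration is provided.
* The BDe backend is a class-parent-set classifier, not a full Bayesian
  network learner; with hundreds of features it deliberately refuses to
  search (budget guard) instead of running for hours.
* The importance procedure's decisions depend on forest size and iteration
  caps; with very weak effects "tentative" is a common and honest outcome.
* The synthetic generator gives no quantitative realism for signal
  magnitudes; effect sizes are free parameters of the stated world.
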