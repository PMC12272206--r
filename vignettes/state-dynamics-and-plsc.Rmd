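---
title: "Phase-coherence state dynamics and PLSC: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-coherence state dynamics and PLSC: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`leidaplsc` analyzes multi-region timeseries as a sequence of recurring
phase-locking states and relates per-subject state dynamics to behavior.

**Instantaneous phase coherence.** Each regional signal is demeaned and
converted to an analytic signal by the Hilbert transform (frequency-domain
construction: negative frequencies zeroed, positive doubled), giving an
instantaneous phase `theta(n, t)` per region. Functional connectivity at
timepoint `t` is the cosine of the phase difference,

```
dFC(i, j, t) = cos(theta(i, t) - theta(j, t))
```

which is `1` for synchronized regions, `0` at quadrature and `-1` in
anti-phase. The N x N coherence matrix is compressed to its leading
eigenvector `LE(t)` (unit norm); its sign pattern splits regions into a
coherent majority and an anticoherent minority. The first and last timepoint
of every run are dropped because the discrete Hilbert transform is unreliable
at run boundaries.

**State repertoire.** `LE(t)` rows pooled over all runs and subjects are
clustered by k-medians with Manhattan (L1) distance; the coordinate-wise
median of each cluster is the LE state, and the average of the member
coherence matrices is the dFC state. L1 is used throughout — clustering,
transition distances, idiosyncrasy — because coordinate medians are the
L1-optimal centers, keeping the objective coherent.

**Reconfiguration metrics.** Per run and subject, with k states:
occurrences (k), mean dwell times (k), transition number (1), transition
probabilities including self-transitions (k x k), mean L1 step distances per
switch type (k x k), and idiosyncrasy — the mean L1 distance from the
subject's `LE(t)` to the cohort median of the assigned state (k). Metrics are
averaged across runs; with k = 6 the canonical vector has 91 entries, 49 of
them frequency metrics.

**PLSC.** After regressing age and gender out of both the metric matrix X
and the behavior matrix Y and z-scoring columns, the cross-block matrix
`R = X'Y / (n - 1)` is decomposed by SVD. Each singular-vector pair defines a
latent dimension; inference uses block-aware resampling throughout:
permutation p-values per dimension, bootstrap ratios (BRs) for loadings,
split-half reproducibility Z-scores, and cross-validated out-of-sample
Spearman correlations.

# Tunable parameters that matter

* `k` (states): the elbow curve (`elbow_curve()`) is the supplied heuristic;
  the repertoire is a lower-order representation, not a claim that exactly k
  states exist. Scanning starts at k = 2 — a one-state solution has no
  switching structure to describe.
* `n_restarts` (default 500; 20 in the test profile): k-medians is a local
  search; restarts with L1-adapted k-means++ seeding escape local minima.
  On small instances 100 restarts reproducibly reach the exhaustive optimum.
* Resampling counts (`n_perm`, `n_boot`, `n_split`, `n_folds`): the full
  profile uses 10,000 / 10,000 / 10,000 / 10, the test profile 500 / 500 /
  500 / 5. The permutation p-value floor is `1 / (n_perm + 1)`.
* BR threshold 2.5 and split-half Z threshold 1.95 are the conventional
  cutoffs for stable loadings and reproducible dimensions; both are
  approximately two-tailed normal critical values.

# The synthetic cohort: what it emulates and what it does not

The generator plants every quantity the pipeline is supposed to recover:

* k phase-locking patterns with offsets in {0, pi}; pattern 1 is uniform
  (globally coherent), the others flag disjoint anticoherent minorities —
  the planted coherence matrix is exactly the +-1 outer product whose
  leading eigenvector marks the minority.
* A hidden Markov state sequence per run; region n emits
  `sin(2*pi*f*t + offset_state(t)[n] + perturbation[n]) + noise`. The pure
  sinusoid is chosen so Hilbert phases provably recover the planted offsets
  within a state; an integer number of carrier cycles per run (default
  f = 0.04, T = 150) makes that recovery exact to machine precision for
  switch-free runs.
* Subject heterogeneity on two axes: *stickiness* (a mixing weight `w` in
  `(1 - w) P + w I`, which moves dwell times and switch counts but provably
  not occurrences) and *idiosyncrasy* (a fixed per-region phase perturbation
  with per-subject scale), plus planted pure-noise parameters.
* Families sharing a Gaussian random effect on the true parameters — the
  simplest mechanism that breaks exchangeability, so block-aware permutation
  and bootstrap have something real to respect.
* Confounds (age, gender) entering both the parameters and the behaviors
  linearly, and ten behavioral scores built from a rank-1 weighting of
  stickiness and idiosyncrasy.

Default study conditions (200 subjects in families of two, four runs of 150
timepoints, 20 regions, four states on a sticky uniform chain with stay
probability 0.95, noise SD 0.2, idiosyncrasy scale 0.05-0.5 rad, behavior
noise SD 0.5) were chosen once as a desk-scale cohort in which the planted
association is strong and identifiable. A mean dwell of 20 samples
corresponds to roughly 14 s at a 0.72 s sampling interval, within the range
reported for resting-state phase-coherence states.

The generator does **not** emulate hemodynamics, realistic fMRI noise
spectra (no autocorrelation, no physiological artifacts), spatial geometry
of parcels, or amplitude dynamics. Passing recovery tests therefore shows the
pipeline is correct and well calibrated under its own assumptions — not that
real fMRI satisfies those assumptions.

**The switch transient.** An instantaneous pi offset jump makes the signal
discontinuous, and the (global) discrete Hilbert transform smooths the phase
over the 1-3 samples around the switch. The sample adjacent to a switch is
therefore intrinsically ambiguous and is misassigned a substantial fraction
of the time no matter how little noise is added. Consequences embraced by the
design: exact label recovery (ARI = 1) is demonstrated on switch-free runs
(identity transition matrix — each run dwells in one uniformly drawn state);
switching cohorts are held to ARI > 0.9; and the default chain is sticky
enough (stay probability 0.95) that transient samples are a small minority.
A faster-switching chain would bury the planted structure under transients —
that is a property of the signal model, not of the estimator.

**Per-state metric reliability.** At desk-scale run lengths, per-state dwell
times and self-transition probabilities are estimated from a handful of
visits, so their subject-level reliability is low even though their
population dependence on stickiness is real; the global transition number
and the idiosyncrasy metrics are the reliable readouts of the two planted
parameters. The end-to-end recovery test therefore checks bootstrap
stability on that direct-readout set; attenuated per-state BRs at short run
lengths are expected behavior, mirrored by their near-zero two-session ICCs,
and disappear as runs lengthen.

# Numerical and procedural choices

* **Analytic signal:** frequency-domain Hilbert transform per row; no
  bandpass filtering by default (a `filter_fun` hook exists) — filtering is
  a deliberate non-step, not an omission.
* **Sign convention:** if an eigenvector has strictly more positive than
  negative entries it is negated; on an exact tie the orientation with
  negative entry-sum is kept, and if the sum is also zero the solver's
  orientation stands. Every emitted vector has at most N/2 positive entries.
* **Lower median:** coordinate medians of even-sized clusters take the lower
  central order statistic, keeping medians on the data lattice and making
  tie-breaking deterministic.
* **Empty clusters:** reseeded with the point farthest (L1) from the empty
  cluster's previous median; first index wins ties.
* **Convergence:** assignment fixpoint (an integer criterion, no tolerance)
  or 200 iterations.
* **State numbering:** descending pooled occurrence by default, so state 1
  is the most frequent (typically the uniform pattern).
* **Masking and imputation:** a metric undefined in a run (state never
  visited, switch never observed) is excluded from that subject's run
  average; if undefined in all runs it is imputed at the cohort median
  before PLSC, with counts logged. Median imputation preserves rank
  structure; dwell visits truncated by run boundaries count as complete
  (no censoring correction).
* **Permutation scheme:** rows of Y are permuted within exchangeability
  blocks built as "the b-th member of every family", so no block mixes
  relatives; permuting one side is the covariance-equivalent canonical
  choice (row-coupled permutation of both sides would preserve the
  association), with a both-sides mode available. Per-dimension p-values
  compare each observed singular value to the null distribution of the
  same-ranked singular value, without Procrustes realignment.
* **Bootstrap:** whole families resampled with replacement until the cohort
  size is reached; each resample is re-standardized and its SVD aligned to
  the original by greedy sign-and-order matching on weight vectors; the BR
  denominator is the SD of the bootstrap loading distribution.
* **Split-half reproducibility:** preprocessing is fitted on the train half
  and applied to the test half (leakage guard); the test singular value is
  `u' R_test v` with train weights. "Similarity of latent variables" is
  computed on weight vectors, since subject scores of disjoint halves are
  not comparable entry-wise.
* **Covariance explained:** `SV_d^2 / sum(SV^2)` (squared-singular-value
  convention).
* **Cross-block scaling:** `R = X'Y/(n - 1)` on z-scored columns (SD with
  divisor n - 1), so R is the cross-correlation matrix.
* **ICC:** ICC(2,1) — two-way random effects, absolute agreement, single
  measurement — as the standard test-retest form; ICC(3,1) by flag. With
  four runs, runs are split into two sessions of two.
* **Determinism:** one master seed; every stochastic routine derives its own
  substream, so partial reruns reproduce exactly.

# Problem sizes used by the test suite

Unit and recovery tests run at 6-50 subjects, 12-20 regions, runs of 40-150
timepoints; the end-to-end recovery test uses the full default design (200
subjects, four runs); calibration suites use 200 null replicates (n = 150,
500 permutations), 50 bootstrap replicates (n = 300, 200 resamples), and 20
null split-half replicates. These sizes were selected so each suite completes
in minutes on a single core while leaving the tested contrasts far from
their thresholds.

# Known limitations

* The k-medians solution is a best-of-restarts local optimum; global
  optimality is only guaranteed (and tested) on small instances.
* Eigenvectors of near-degenerate coherence matrices (leading eigenvalue gap
  near zero) are numerically unstable; the eigenvalue share is exposed so
  such timepoints can be audited.
* The spec-level association between metrics and behavior is linear;
  PLSC will under-detect planted nonlinear links.
* With very sticky subjects some switch types are never observed; their
  transition metrics are imputed, which shrinks their apparent effects
  toward zero.
* Families are modeled as exchangeable blocks with a single shared random
  effect; real pedigree structure (half-siblings, twins) is out of scope.
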