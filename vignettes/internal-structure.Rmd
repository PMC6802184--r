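---
title: "Recovering internal representations from population activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering internal representations from population activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Classical tuning-curve analysis asks how a neuron's firing relates to an
externally measured variable — the animal's position, its head direction —
and therefore requires choosing that variable in advance. `popstates`
implements the complementary, unsupervised route: it characterizes each
neuron's activity *relative to the state of the network itself*. From a
binary neurons-by-time activity raster alone it recovers a low-dimensional
internal structure, discrete network states and their temporal ordering, a
latent encoded variable (a position-like coordinate on a line, or an angle
on a ring), and an "internal tuning curve" per neuron — all without ever
looking at behavior. Behavioral measurements enter only afterwards, to
validate what was recovered and to fix the residual symmetry (a line can be
read in two directions, a ring up to rotation and reflection).

## The pipeline

1. **Data points.** Activity is binarized per time bin. Imaging sessions
   keep bins with more than one active neuron; binned spike trains (100 ms
   bins) keep bins with at least 15 active cells. Each retained bin is a
   binary population vector.
2. **Two-stage spectral embedding.** A symmetrized k-nearest-neighbor graph
   with binary weights is built on the activity vectors
   (neighbor fraction `p1`, default 0.375% of the number of points — the
   midpoint of the 0.25–0.5% range appropriate across data sets) and the
   generalized eigenproblem `L f = lambda D f` is solved; the 10
   eigenvectors after the constant one embed the data in 10 dimensions.
   The same procedure is applied once more on the 10-d coordinates
   (`p2` default 11.25%, midpoint of 7.5–15%) and the three leading
   nontrivial eigenvectors give the final 3-d embedding. Eigensolving uses
   ARPACK on the symmetrically normalized Laplacian above 500 nodes and a
   dense solver below; a disconnected graph is restricted to its largest
   component, and the dropped frames are reported rather than silently
   mixed.
3. **Geometry.** The intrinsic dimension is the log–log slope of the mean
   neighbor count within a growing radius; the fit window keeps radii where
   the mean count lies between 3% and 20% of the points (floor of 10
   counts). The window was calibrated on reference manifolds — a uniform
   segment, a uniform disc, and thick noisy lines of the sizes the pipeline
   produces — so that each reads its true dimension: below ~3% the counts
   probe the transverse noise ball of an embedded manifold, above ~20% they
   saturate on its finite extent. Topology comes from Vietoris–Rips
   persistent homology (built in `src/rips.cpp`, computed per dimension
   from the coboundary matrix with clearing) on a landmark set: K-means
   centroids (K = 70) after discarding clusters with fewer than 50 members.
   A Betti vector counts as *stable* when constant over at least 25% of the
   filtration range — an explicit form of "persists over a wide range of
   radii"; the widest such plateau is reported. The maximum filtration radius
   defaults to the 99th percentile of pairwise landmark distances.
4. **Network states.** Topological clustering tracks single-linkage
   components (computed exactly from the Euclidean minimum spanning tree)
   across the radius threshold and chooses the radius capturing the largest
   number of *stable* large components (at least 250 points; at least 50
   for sub-clustering). Stability again means persistence across radii, measured
   multiplicatively because merge radii live on a log scale: a component
   count qualifies when it persists while the radius grows by at least a
   factor of 1.4 (`stable_ratio`), calibrated against both populations:
   genuine state regimes of intact sessions persist across at least a
   ~1.5× radius growth, while the marginal 2–3-component regimes that
   shuffled (structure-free) data produce flip within less than 1.25×. Remaining points join
   the cluster of their nearest assigned neighbor. For continuously
   distributed clouds (the head-direction ring) there is no natural
   separation, and K-means (K = 8) parameterizes the manifold instead.
5. **Segments, subtypes, ordering.** Per state, frames are merged into
   temporal segments (gap threshold chosen where the segment count is
   insensitive to ±1 frame; minimum length at the antimode of the clearly
   bimodal candidate-length distribution, with kernel-density valley
   detection). Segment-average activity vectors projected on their first
   principal component expose subtypes: two subtypes are declared only when
   the sorted projections contain an internal spacing of at least one
   Freedman–Diaconis histogram bin width — the alignment-free form of "two
   modes separated by an empty histogram bin". Transition matrices at frame and segment
   level feed the ordering objective — the permutation of states
   maximizing summed transition probability, searched exhaustively with
   the end states constrained by segment starts/ends ((M−2)! candidates,
   linear) or over (M−1)!/2 cyclic orders; more than 10 states are
   rejected rather than searched.
6. **Internal variable and tuning curves.** Ordered sub-clusters receive
   evenly spaced internal positions in [0, 1]; cyclically ordered clusters
   receive angles 2πk/M, temporally smoothed through their unit vectors
   (truncated Gaussian, σ = 2 frames, 5-frame support) to avoid wrap
   artifacts. Internal tuning curves divide per-state event counts by
   occupancy, after linear interpolation in ordered-state index to the
   common 20-bin grid and smoothing (σ = 1.5 bins, 5-bin support); circular
   curves use 40 bins of 9° without interpolation. Cells with 5 or fewer
   events in the relevant states are excluded. External curves follow the
   field conventions: 24 4-cm track bins minus two at each end, speed
   filter 1 cm/s, per-direction maps (or direction-pooled trajectory-phase
   maps after flipping one direction's indexing).
7. **Statistics and decoders.** Information per event uses the standard
   occupancy-weighted log-ratio sum on unsmoothed maps, with a shuffle null
   that redraws event locations from the occupancy distribution (the
   spatial-coverage statistics); significance requires exceeding strictly
   more than 95% of 1000 shuffles. Field width counts bins contiguous with
   the peak above half maximum; circular curves get a Rayleigh vector.
   Decoders: independent-Poisson maximum likelihood (rate floor 1e-3
   events/s — "maximum likelihood" needs a noise model and Poisson is the
   standard for binned events), across-structure matching of internal
   coordinates under the structure's symmetry group, nearest-neighbor
   trajectory-phase decoding across running directions, and 20-bin
   template correlation with odd/even-minute splits. Decoding significance
   permutes the decoded series and re-fits the gauge per shuffle (a
   conservative null); explained variance is one minus the ratio of data to
   label-shuffled mean squared error.

## The synthetic sessions

No public recordings accompany the method, so the package ships generators
whose defaults are the study conditions, with planted per-neuron ground
truth as the oracle for every recovery test.

* **Linear track** (96 cm, drink and turn pauses at both ends, ~45
  left-right cycles in a 900 s default session): traversals follow a
  trapezoid-like speed profile peaking near 40 cm/s with a 20% floor at the
  ends — mice start and stop briskly, and a profile that creeps to zero
  would pile frames up at the track ends. Peak speed varies by ±30% across
  traversals, which is what makes trajectory phase, elapsed time, and
  speed-by-acceleration dissociable at all. `ca1` mode plants
  direction-selective place cells (Gaussian fields, σ 8–14 cm, peak event
  rates 2–4 events/s, 30% of fields direction-independent as on real
  tracks) plus drink/turn cells tuned to one end; `acc` mode plants
  trajectory-phase cells whose tuning is identical for the two running
  directions, plus drink/turn cells responding at both ends. Drink cells
  switch on 0.5 s after arrival (licking latency); without it, run-to-drink
  transition frames bridge the two clusters and single-linkage merges
  them. Events are Bernoulli per frame at rate × Δt, and each event marks
  two consecutive frames active, mirroring the event detector's rise-time
  convention.
* **Head direction** (50 cells, 30 min, 100 ms bins): heading follows a
  bounded-speed angular random walk; REM episodes freeze the actual head
  direction while a virtual trajectory with the same law at twice the
  angular speed drives the same von Mises tuning curves (the factor 2 is a
  free default — no quantitative REM statistics exist to pin it). Peak
  rates 20–45 Hz with a 1 Hz floor keep a typical bin above the 15-active-
  cell retention filter, as in the original recordings.
* **Fluorescence**: events convolved with a rise (50 ms) + exponential
  decay kernel (600 ms GCaMP6s / 200 ms GCaMP6f), lognormal amplitudes,
  slow baseline drift, white noise. The event detector measures a
  transient's decay as the time to fall to half the peak and requires at
  least half the indicator's nominal decay constant: the half-life of an
  exponential with the nominal constant is ln 2 ≈ 0.69 of it, so the
  criterion accepts transients down to ~0.72 of nominal and rejects fast
  noise blips without sitting on a knife edge.
* **Multiday sessions** re-sample the active roster each day (inclusion
  probability drawn from 0.41–0.64 by default) while preserving the
  planted tuning of retained neurons.

What the generators do *not* emulate: attractor dynamics (tuning is
imposed, not emergent), theta rhythm and sequence phenomena, slow drifts in
tuning, correlated noise across neurons, or imaging artifacts beyond the
trace level. Passing tests therefore demonstrate that the pipeline recovers
planted structure under realistic firing statistics — not that it is robust
to every pathology of real data.

## Numerical choices and degenerate inputs

* k-nearest-neighbor ties break by the lower frame index; eigenvector
  signs are canonicalized (largest-magnitude entry positive); eigensolver
  tolerance 1e-10.
* Equal-objective orderings resolve to the lexicographically smallest
  permutation.
* Zero-occupancy bins yield `NA` rates and are excluded from statistics;
  all-zero frames decode to `NA` and leave error statistics; constant
  traces yield zero events; a degenerate (single-point) cloud flags its
  dimension estimate instead of fitting.
* All generator randomness flows from one session seed through
  `split_seed()`, so every run is reproducible bit for bit.

## Design choices where the method left room

* **Stage-2 fragmentation of continuous manifolds.** The final 3-d
  embedding can split a long one-dimensional manifold into a few dense
  lobes (Laplacian eigenvectors localize on dense regions). The pipeline
  therefore treats *all* locomotion states symmetrically: subtype splits
  are computed per state, subtypes are grouped by running direction (state
  sorting against behavior, exactly how the method labels states in
  practice), and each direction group is re-embedded as a whole for
  sub-clustering and parameterization. With a single locomotion cluster
  this reduces to the classical two-subtype picture.
* **Cluster-radius stability.** Choosing the radius by raw maximal
  component count always rewards fragmentation; requiring the count to
  persist across a radius interval is the minimal faithful reading of
  "stable components" and is exposed as `stable_frac`.
* **Internal/external comparison gauge.** Reflections (line) and
  rotations+reflections (ring) are fixed by global mean-squared-error
  minimization against the reference series; the gauge never changes the
  error magnitudes, only the frame they are read in.
* **Across-structure decoding** matches internal coordinates through a
  binned lookup (20 bins) under the best symmetry element; "similarity
  between internal structures" is otherwise unspecified, and coordinates
  are the structure's canonical parameterization.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run the full pipeline on 900-s
linear-track sessions (500 neurons, 20 Hz for `ca1`, 10 Hz for `acc`) and
30-min head-direction sessions (50 cells, 100 ms bins), with smaller
sessions for unit-level checks. These sizes were chosen to match the
recordings the method was developed on (five to seven 3-min trials, ~68
traversals, 450–600 cells; 41–62 head-direction cells) while keeping a
complete run reproducible on a laptop.

## Known limitations

* Betti numbers are computed on at most 250 landmarks (K-means centroids);
  fine topological features smaller than the landmark resolution are
  invisible, and fewer than 50 surviving landmarks flags the result as
  low-confidence rather than failing.
* The factorial ordering search is exact but capped at 10 states.
* The leave-one-out internal information re-embeds the population per
  neuron and is the most expensive statistic in the package; use it on
  selected cells, not entire populations, for large sessions.
* Topological clustering assumes the embedding separates states by
  density; on data where states blend continuously, K-means mode is the
  honest alternative.
* The across-day structure-stability permutation test has a p-value floor
  near 0.05 on linear-track data: the state geometry is close to symmetric
  under track reflection, so several state-identity permutations in the
  null score almost as well as the identity. Day-to-day variability of the
  spectral layout under 40–60% roster turnover further widens the spread of
  pairwise structure correlations; the shipped tests therefore assert
  above-chance preservation for every day pair rather than outright
  significance for each.
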