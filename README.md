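# popstates

Unsupervised recovery of internal representations from neural population
activity.

Most analyses of neural recordings start from an externally measured
variable — the animal's position, its head direction — and ask how each
neuron's firing relates to it. `popstates` takes the complementary route:
from a binary neurons × time activity raster **alone**, it recovers

* a low-dimensional **internal structure** of the population activity
  (two-stage Laplacian Eigenmaps on a k-nearest-neighbor graph of activity
  vectors, solving `L f = λ D f` with `L = D − W`),
* the **intrinsic dimension** (log–log slope of neighbor counts) and
  **topology** (radius-stable Betti numbers β₀, β₁, β₂ from Vietoris–Rips
  persistent homology on K-means landmarks) of that structure,
* discrete **network states** (topological or K-means clustering), their
  temporal segments, subtypes, transition matrices, and their linear or
  cyclic **ordering** `Î = argmax_I Σ P(I_i → I_{i+1})`,
* a reconstructed **latent variable** — a position-like coordinate in
  [0, 1] on a line, or an angle in [0, 2π) on a ring — and per-neuron
  **internal tuning curves** (event rate as a function of network state),
* the standard tuning statistics (information per event
  `Σ pᵢ (rᵢ/r̄) log₂(rᵢ/r̄)` with occupancy-resampled shuffle nulls, field
  width, Rayleigh vector, bidirectionality overlap), and
* a decoder suite: independent-Poisson maximum likelihood,
  across-session/across-animal decoding through the analogy of internal
  structures, nearest-neighbor trajectory-phase decoding, template
  correlation with explained variance `1 − MSE(data)/MSE(shuffle)`, and
  permutation shuffle tests, plus multiday code/structure stability.

Behavioral measurements are used only for validation and for fixing the
residual symmetry of the recovered variable (reflection for a line,
rotation + reflection for a ring).

Because no public recordings accompany the method, the package ships a
first-class synthetic-session generator with planted ground truth:
direction-selective hippocampal-style place cells with drink/turn cells on
a 96-cm linear track, cingulate-style trajectory-phase cells symmetric
across running directions, head-direction cells with wake and REM "virtual"
heading trajectories, GCaMP6-like fluorescence transients, and multiday
sessions with partial cell turnover.

## Worked example

A 30-minute synthetic head-direction session (50 cells, 100 ms bins, wake
plus REM episodes), analyzed end to end without the heading ever entering
the pipeline:

```r
library(popstates)

ses <- gen_hd_session(n_neurons = 50, duration = 1800, seed = 3)
ses$activity
#> <activity_matrix> 50 neurons x 18000 bins (0.1 s bins, ephys); 17385/18000 frames retained

res <- analyze_ring_session(ses$activity, ses$behavior)

persistent_betti(res$embedding)
#> <betti_result> stable (b0, b1, b2) = (1, 1, 0) over radii 0.0024-0.0208

estimate_intrinsic_dimension(res$embedding)
#> <dimension_estimate> slope = 0.986 (fit window 0.00138-0.00917)

median(abs(res$trajectory$error_series)) * 180 / pi
#> [1] 7.39
```

The stable Betti vector (1, 1, 0) — one component, one hole, no enclosed
spaces — and the dimension slope ≈ 1 say the population activity lives on a
ring, before anything is known about the animal. The reconstructed internal
angle, aligned to the measured head direction only through the ring's
rotation/reflection gauge, tracks it with a median error of ~7.4°. Internal
tuning curves of individual cells (`internal_tuning_curve()`) then
reproduce their head-direction tuning, and a maximum-likelihood decoder
trained purely on REM-sleep internal tuning curves decodes the awake head
direction (`ml_decode()`; see the acceptance script).

For linear-track imaging sessions, `analyze_linear_session()` runs the
corresponding pipeline: network states for drinking, turning, and
locomotion; the two locomotion subtypes (running directions) exposed by
segment-level PCA; ordered sub-clusters; and an internal position in [0, 1]
per locomotion frame.

## Layout

| Path | Contents |
| --- | --- |
| `R/synthio.R` | synthetic sessions and ground truth, CSV/JSON session I/O |
| `R/preprocess.R` | Ca²⁺ event detection from ΔF/F₀ traces |
| `R/activity.R` | binary activity matrices, modality filters, shuffle controls |
| `R/embedding.R` | kNN graph, spectral embedding, two-stage pipeline |
| `R/geometry.R` | intrinsic dimension, persistent Betti numbers |
| `R/states.R` | clustering, segmentation, subtypes, transitions, ordering |
| `R/tuning.R` | latent-variable reconstruction, tuning curves, statistics |
| `R/decode.R` | decoders, explained variance, shuffle tests |
| `R/stability.R` | multiday code and structure stability |
| `src/` | compiled kNN/MST/union-find helpers and Rips persistence |
| `inst/cli/popstates` | thin command-line wrapper (`simulate`, `decode`) |
| `vignettes/` | methods vignette: models, parameters, design choices |
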