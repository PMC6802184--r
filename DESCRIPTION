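Package: popstates
Title: Unsupervised Recovery of Internal Representations from Neural Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers internal representations -- network states, internal
    tuning curves, encoded-variable trajectories, and the topology of the
    underlying state space -- from binarized neural population activity
    alone, without reference to behavior. Implements a two-stage Laplacian
    Eigenmaps embedding of activity vectors, intrinsic-dimension and
    persistent-homology (Betti number) estimation, topological and K-means
    state clustering with temporal segmentation and cyclic/linear state
    ordering, reconstruction of latent position-like and angular variables,
    internal and external tuning curves with information and directionality
    statistics, a suite of population decoders (maximum likelihood,
    across-structure, nearest-neighbor phase, template correlation) with
    shuffle-based significance tests, and multiday code/structure stability
    analysis. Ships a synthetic-session generator (direction-selective place
    cells, trajectory-phase cells, head-direction cells, GCaMP6-like
    fluorescence transients, multiday cell turnover) with planted ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
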