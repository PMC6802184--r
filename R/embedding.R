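#' Symmetrized k-nearest-neighbor graph
#'
#' Nodes `i` and `j` are connected if `i` is among the k nearest neighbors of
#' `j` or vice versa (OR symmetrization), with `k = max(1, round(p * n))`.
#' Weights are binary ("simple-minded" choice); distance is Euclidean. Ties in
#' distance are broken by the lower point index, so the graph is deterministic.
#'
#' @param points numeric matrix (points x dimensions).
#' @param p neighbor fraction in (0, 1); ignored if `k` is given.
#' @param k neighbor count (overrides `p`).
#' @return a `neighbor_graph`: list with `edges` (2-column matrix of 1-based
#'   undirected edges), `n`, `k`, `p`.
#' @export
knn_graph <- function(points, p = NULL, k = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points")
  if (is.null(k)) {
    if (is.null(p) || p <= 0 || p >= 1) stop("p must be in (0, 1)")
    k <- max(1L, as.integer(round(p * n)))
  }
  k <- min(as.integer(k), n - 1L)
  edges <- if (ncol(points) >= 32 && n > 2000) {
    knn_edges_blas(points, k)
  } else {
    cpp_knn_edges(points, k)
  }
  structure(list(edges = edges, n = n, k = k, p = p),
            class = "neighbor_graph")
}

# BLAS-backed kNN for high-dimensional inputs (stage 1 on many neurons):
# squared distances blockwise via d^2 = |x|^2 + |y|^2 - 2 x.y, then per-row
# selection with the same lowest-index tie-break as the compiled path
knn_edges_blas <- function(X, k, block = 1024L) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  ei <- vector("list", ceiling(n / block))
  bi <- 0L
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    D2 <- sq[rows] - 2 * tcrossprod(X[rows, , drop = FALSE], X)
    D2 <- sweep(D2, 2, sq, "+")
    nb <- matrix(0L, length(rows), k)
    for (r in seq_along(rows)) {
      d <- D2[r, ]
      d[rows[r]] <- Inf
      thr <- sort.int(d, partial = k)[k]
      idx <- which(d <= thr)
      idx <- idx[order(d[idx], idx)][seq_len(k)]
      nb[r, ] <- idx
    }
    bi <- bi + 1L
    ei[[bi]] <- cbind(rep(rows, k), as.integer(nb))
  }
  e <- do.call(rbind, ei)
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# degree-normalized adjacency as a sparse Matrix (both edge directions)
graph_adjacency <- function(g) {
  e <- g$edges
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(g$n, g$n))
}

#' Laplacian Eigenmaps spectral embedding of a neighbor graph
#'
#' Solves the generalized eigenproblem `L f = lambda D f` with `L = D - W`
#' (`D` the diagonal degree matrix) and returns the eigenvectors of the
#' smallest `n_dims` nontrivial eigenvalues as coordinates, leaving out the
#' leading (constant) eigenvector. A disconnected graph is restricted to its
#' largest connected component and the dropped nodes are reported; components
#' are never silently mixed. Eigenvector signs are canonicalized so the
#' largest-magnitude entry of each coordinate is positive.
#'
#' @param g a [knn_graph()].
#' @param n_dims number of embedding coordinates.
#' @param method `"auto"` (dense below 500 nodes, ARPACK above), `"dense"`,
#'   or `"arpack"`.
#' @return an `embedding`: list with `coords` (kept nodes x `n_dims`),
#'   `eigenvalues` (ascending, including the leading ~0 eigenvalue),
#'   `node_index` (indices of kept nodes in the input graph), `dropped`
#'   (indices of nodes outside the largest component), `stage`.
#' @export
spectral_embed <- function(g, n_dims = 10,
                           method = c("auto", "dense", "arpack")) {
  method <- match.arg(method)
  comp <- cpp_components(g$n, g$edges)
  tab <- tabulate(comp)
  keep_comp <- which.max(tab)
  node_index <- which(comp == keep_comp)
  dropped <- which(comp != keep_comp)
  nc <- length(node_index)
  if (nc < n_dims + 2)
    stop("largest connected component too small for the requested dimensions")
  remap <- integer(g$n)
  remap[node_index] <- seq_len(nc)
  e <- g$edges
  in_comp <- comp[e[, 1]] == keep_comp
  e <- cbind(remap[e[in_comp, 1]], remap[e[in_comp, 2]])
  if (method == "auto") method <- if (nc <= 500) "dense" else "arpack"
  if (method == "dense") {
    W <- matrix(0, nc, nc)
    W[e] <- 1
    W[e[, c(2, 1), drop = FALSE]] <- 1
    deg <- rowSums(W)
    dh <- 1 / sqrt(deg)
    # symmetric normalized Laplacian; f = D^{-1/2} u solves L f = lambda D f
    Lsym <- diag(nc) - (dh * W) * rep(dh, each = nc)
    es <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
    ord <- nc:(nc - n_dims)
    lambda <- es$values[ord]
    vecs <- es$vectors[, ord, drop = FALSE] * dh
  } else {
    W <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(nc, nc))
    deg <- Matrix::rowSums(W)
    dh <- 1 / sqrt(deg)
    nev <- n_dims + 1
    fn <- function(x, extra) x + dh * as.numeric(W %*% (dh * x))
    opts <- igraph::arpack_defaults()
    opts$n <- nc
    opts$nev <- nev
    opts$ncv <- min(nc, max(3 * nev + 10, 40))
    opts$which <- "LA"
    opts$maxiter <- 10000
    opts$tol <- 1e-10
    ar <- igraph::arpack(fn, sym = TRUE, options = opts)
    mu <- ar$values
    ord <- order(-mu)[seq_len(nev)]
    lambda <- 2 - mu[ord]
    vecs <- ar$vectors[, ord, drop = FALSE] * dh
  }
  # normalize and canonicalize signs (largest-|entry| positive)
  for (j in seq_len(ncol(vecs))) {
    v <- vecs[, j]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    vecs[, j] <- v
  }
  structure(list(coords = vecs[, -1, drop = FALSE],
                 eigenvalues = lambda,
                 node_index = node_index, dropped = dropped, stage = 1L),
            class = "embedding")
}

#' Two-stage spectral embedding of an activity matrix
#'
#' Applies Laplacian Eigenmaps twice: first on the binary activity vectors of
#' the retained frames (neighbor fraction `p1`, 10 output dimensions), then on
#' the 10-dimensional coordinates (neighbor fraction `p2`, 3 output
#' dimensions). The defaults are the midpoints of the ranges used for all
#' data sets (`p1` in 0.25-0.5%, `p2` in 7.5-15%).
#'
#' @param m an [activity_matrix()].
#' @param p1,p2 neighbor fractions for the two stages.
#' @param d1,d2 output dimensions of the two stages (10 and 3).
#' @param method eigensolver passed to [spectral_embed()].
#' @return an `embedding` with `coords` (frames x `d2`), `frame_index`
#'   (original bin index of each row), `eigenvalues` (stage 2), `stage1` (the
#'   first-stage embedding), `dropped_frames` (original bins lost to
#'   disconnected components at either stage), `p1`, `p2`.
#' @export
embed_two_stage <- function(m, p1 = 0.00375, p2 = 0.1125, d1 = 10, d2 = 3,
                            method = "auto") {
  stopifnot(inherits(m, "activity_matrix"))
  frames <- m$retained_frames
  if (!length(frames)) stop("no retained frames to embed")
  X1 <- t(m$values[, frames, drop = FALSE]) * 1.0
  g1 <- knn_graph(X1, p = p1)
  e1 <- tryCatch(spectral_embed(g1, d1, method),
                 error = function(err) stop("stage 1: ",
                                            conditionMessage(err)))
  frames1 <- frames[e1$node_index]
  g2 <- knn_graph(e1$coords, p = p2)
  e2 <- tryCatch(spectral_embed(g2, d2, method),
                 error = function(err) stop("stage 2: ",
                                            conditionMessage(err)))
  frames2 <- frames1[e2$node_index]
  dropped <- setdiff(frames, frames2)
  structure(list(coords = e2$coords, frame_index = frames2,
                 eigenvalues = e2$eigenvalues, stage = 2L,
                 stage1 = list(coords = e1$coords, frame_index = frames1,
                               eigenvalues = e1$eigenvalues),
                 dropped_frames = dropped, p1 = p1, p2 = p2),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> stage %d: %d points x %d dims\n", x$stage,
              nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

#' Save an embedding as a tabular file plus JSON sidecar
#'
#' @param e an `embedding`.
#' @param file path of the coordinate table (CSV); the sidecar is written to
#'   `paste0(file, ".json")`.
#' @return `file`, invisibly.
#' @export
write_embedding <- function(e, file) {
  df <- data.frame(frame_index = e$frame_index %||% e$node_index, e$coords)
  names(df)[-1] <- paste0("x", seq_len(ncol(e$coords)))
  utils::write.csv(df, file, row.names = FALSE)
  side <- list(p1 = e$p1, p2 = e$p2, eigenvalues = e$eigenvalues,
               dropped_frames = e$dropped_frames %||% integer(0))
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}
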