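#' Intrinsic-dimension estimate from neighbor counting
#'
#' For every point, counts the neighbors within a sphere as a function of the
#' sphere's radius; the slope of the mean count versus radius on a log-log
#' scale estimates the intrinsic dimension of the point cloud.
#'
#' @param coords an `embedding` or a numeric matrix of coordinates.
#' @param radii optional radius grid (ascending); default is 50 log-spaced
#'   radii between the 1st and 99th percentile of pairwise distances.
#' @param fit_window optional `c(r_min, r_max)`; by default the fit uses
#'   radii where the mean count lies between 3% and 20% of the number of
#'   points (with a floor of 10 counts), trimming both the noise floor and
#'   saturation.
#' @return a `dimension_estimate`: list with `radii`, `mean_counts`, `slope`,
#'   `fit_window`, `degenerate` flag.
#' @export
estimate_intrinsic_dimension <- function(coords, radii = NULL,
                                         fit_window = NULL) {
  X <- if (inherits(coords, "embedding")) coords$coords else as.matrix(coords)
  n <- nrow(X)
  if (n < 50) stop("need at least 50 points")
  if (is.null(radii)) {
    sub <- if (n > 1500) X[sort(sample.int(n, 1500)), , drop = FALSE] else X
    dq <- quantile(dist(sub), c(0.01, 0.99))
    if (dq[2] <= 0) {
      return(structure(list(radii = numeric(0), mean_counts = numeric(0),
                            slope = NA_real_, fit_window = c(NA, NA),
                            degenerate = TRUE),
                       class = "dimension_estimate"))
    }
    radii <- exp(seq(log(max(dq[1], dq[2] / 1e4)), log(dq[2]),
                     length.out = 50))
  }
  counts <- cpp_radius_counts(X, radii)
  if (is.null(fit_window)) {
    # scale-free window calibrated on reference manifolds: below ~3% of the
    # points the counts probe the noise ball of an embedded manifold, above
    # ~20% they saturate on its finite extent
    in_fit <- counts >= max(10, 0.03 * n) & counts <= 0.2 * n
    if (sum(in_fit) < 3) in_fit <- counts >= 5 & counts <= 0.5 * n
    fit_window <- if (any(in_fit)) range(radii[in_fit]) else range(radii)
  } else {
    in_fit <- radii >= fit_window[1] & radii <= fit_window[2]
  }
  use <- in_fit & counts > 0
  slope <- if (sum(use) >= 2) {
    unname(coef(lm(log(counts[use]) ~ log(radii[use])))[2])
  } else NA_real_
  structure(list(radii = radii, mean_counts = counts, slope = slope,
                 fit_window = fit_window, degenerate = !is.finite(slope)),
            class = "dimension_estimate")
}

#' @export
print.dimension_estimate <- function(x, ...) {
  cat(sprintf("<dimension_estimate> slope = %.3f (fit window %.3g-%.3g)\n",
              x$slope, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' Radius-stable Betti numbers of an embedded point cloud
#'
#' Estimates the numbers of connected components (beta0), holes (beta1) and
#' enclosed spaces (beta2) as a function of the filtration radius, using
#' Vietoris-Rips persistent homology on a representative landmark set. The
#' landmarks are K-means centroids (default K = 70) after discarding sparse
#' clusters (< 50 members). The reported stable Betti vector is read from the
#' widest radius plateau: a constant Betti vector persisting over at least
#' `stable_frac` of the filtration range.
#'
#' @param coords an `embedding` or a coordinate matrix.
#' @param k_landmarks number of K-means clusters for the landmark set.
#' @param min_cluster minimum members for a cluster to contribute a landmark.
#' @param n_radii size of the radius grid for the Betti curves.
#' @param stable_frac minimum plateau width as a fraction of the filtration
#'   range.
#' @param r_max maximum filtration radius; default the 99th percentile of
#'   pairwise landmark distances.
#' @param maxdim highest homology dimension (2).
#' @param seed seed for the K-means restarts.
#' @return a `betti_result`: `radii`, `betti_curves` (radius x dimension),
#'   `stable_betti`, `plateau` (radius interval), `landmarks`, `intervals`
#'   (persistence intervals per dimension), `low_confidence` flag.
#' @export
persistent_betti <- function(coords, k_landmarks = 70, min_cluster = 50,
                             n_radii = 100, stable_frac = 0.25, r_max = NULL,
                             maxdim = 2, seed = 1) {
  X <- if (inherits(coords, "embedding")) coords$coords else as.matrix(coords)
  n <- nrow(X)
  if (n < k_landmarks) stop("fewer points than requested landmarks")
  set.seed(as.integer(seed))
  km <- kmeans(X, centers = k_landmarks, nstart = 10, iter.max = 200,
               algorithm = "MacQueen")
  keep <- which(km$size >= min_cluster)
  low_confidence <- FALSE
  if (length(keep) < 2) keep <- order(km$size, decreasing = TRUE)[1:2]
  landmarks <- km$centers[keep, , drop = FALSE]
  if (nrow(landmarks) < 50) {
    warning("fewer than 50 surviving landmarks; topology estimate is ",
            "low-confidence")
    low_confidence <- TRUE
  }
  D <- as.matrix(dist(landmarks))
  r_max <- r_max %||% unname(quantile(D[upper.tri(D)], 0.99))
  pairs <- cpp_rips_pairs(D, r_max, maxdim)
  radii <- seq(0, r_max, length.out = n_radii)
  curves <- sapply(seq_len(maxdim + 1), function(q) {
    iv <- pairs[[q]]
    vapply(radii, function(r) sum(iv[, 1] <= r & iv[, 2] > r), numeric(1))
  })
  colnames(curves) <- paste0("beta", 0:maxdim)
  # widest plateau of a constant Betti vector spanning >= stable_frac of range
  key <- apply(curves, 1, paste, collapse = ",")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  widths <- radii[ends] - radii[starts]
  ok <- widths >= stable_frac * (r_max - radii[1])
  if (any(ok)) {
    best <- which(ok)[which.max(widths[ok])]
  } else {
    best <- which.max(widths)
    low_confidence <- TRUE
  }
  stable <- curves[starts[best], ]
  structure(list(radii = radii, betti_curves = curves,
                 stable_betti = unname(stable),
                 plateau = c(radii[starts[best]], radii[ends[best]]),
                 landmarks = landmarks, intervals = pairs,
                 low_confidence = low_confidence),
            class = "betti_result")
}

#' @export
print.betti_result <- function(x, ...) {
  cat(sprintf(
    "<betti_result> stable (b0, b1, b2) = (%s) over radii %.3g-%.3g%s\n",
    paste(x$stable_betti, collapse = ", "), x$plateau[1], x$plateau[2],
    if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Export Betti curves and persistence intervals
#'
#' @param b a `betti_result`.
#' @param file CSV path for the Betti curves; intervals go to
#'   `paste0(file, "_intervals.csv")` and the plateau report to
#'   `paste0(file, ".json")`.
#' @return `file`, invisibly.
#' @export
write_betti <- function(b, file) {
  utils::write.csv(data.frame(radius = b$radii, b$betti_curves), file,
                   row.names = FALSE)
  iv <- do.call(rbind, lapply(seq_along(b$intervals), function(q) {
    m <- b$intervals[[q]]
    if (!nrow(m)) return(NULL)
    data.frame(dim = q - 1L, birth = m[, 1], death = m[, 2])
  }))
  utils::write.csv(iv, paste0(file, "_intervals.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(stable_betti = b$stable_betti, plateau = b$plateau,
         low_confidence = b$low_confidence),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}
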