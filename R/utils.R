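#' @useDynLib popstates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor density dist kmeans lm mad prcomp quantile
#'   rbinom rlnorm rnorm rpois runif sd var coef confint median setNames
#'   complete.cases
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed circular difference
#'
#' Difference `a - b` mapped to `(-pi, pi]`, the mismatch convention used for
#' all angular errors in the package.
#'
#' @param a,b angles in radians.
#' @return numeric vector of signed differences in `(-pi, pi]`.
#' @export
circ_diff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  # map -pi to pi so the range is (-pi, pi]
  d[d == -pi] <- pi
  d
}

circ_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  atan2(sum(w * sin(theta)), sum(w * cos(theta))) %% (2 * pi)
}

#' Circular correlation of two angle series
#'
#' Fisher-Lee circular correlation coefficient; used to compare recovered and
#' planted angular variables.
#'
#' @param a,b angles in radians.
#' @return correlation in `[-1, 1]`.
#' @export
circ_cor <- function(a, b) {
  am <- atan2(mean(sin(a)), mean(cos(a)))
  bm <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - am)
  sb <- sin(b - bm)
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

# Truncated Gaussian kernel of odd length `size`, normalized to sum 1.
gauss_kernel <- function(sigma, size) {
  half <- (size - 1) / 2
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Kernel smoothing of a series. Linear mode renormalizes the kernel at the
# edges (truncation); circular mode wraps. NAs are dropped from the local
# average.
smooth_series <- function(x, sigma = 1.5, size = 5, circular = FALSE) {
  n <- length(x)
  if (n == 0) return(x)
  k <- gauss_kernel(sigma, size)
  half <- (size - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- (i - half):(i + half)
    if (circular) {
      idx <- ((idx - 1) %% n) + 1
      w <- k
    } else {
      keep <- idx >= 1 & idx <= n
      w <- k[keep]
      idx <- idx[keep]
    }
    v <- x[idx]
    ok <- !is.na(v)
    out[i] <- if (any(ok)) sum(w[ok] * v[ok]) / sum(w[ok]) else NA_real_
  }
  out
}

# Smooth an angular series through its unit vectors to avoid wrap artifacts.
smooth_circular_series <- function(theta, sigma = 2, size = 5) {
  cs <- smooth_series(cos(theta), sigma, size)
  sn <- smooth_series(sin(theta), sigma, size)
  atan2(sn, cs) %% (2 * pi)
}

#' Derive child seeds from a session seed
#'
#' All randomness in the generators flows from a single session seed through
#' this splitting scheme, so that a run is reproducible bit for bit.
#'
#' @param seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds, each below 2^31.
#' @export
split_seed <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Enumerate all permutations of seq_len(n) as rows of a matrix (n <= 9).
all_perms <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

# Most frequent value of an integer vector (ties: smallest).
int_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}
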