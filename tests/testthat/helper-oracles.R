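# Independent oracle implementations used to cross-check the package.
# These deliberately use brute force / direct formula evaluation and share no
# code with the implementation paths they verify.

# brute-force OR-symmetrized kNN edge set (ties by lower index)
oracle_knn_edges <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i], seq_len(n)[-i])
    nb <- (seq_len(n)[-i])[ord[seq_len(k)]]
    edges <- rbind(edges, cbind(pmin(i, nb), pmax(i, nb)))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# union-find connected-component count at one radius
oracle_n_components <- function(D, r) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] <= r) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# direct evaluation of the information-per-event formula
oracle_information <- function(occupancy, counts) {
  ok <- occupancy > 0
  p <- occupancy[ok] / sum(occupancy[ok])
  r <- counts[ok] / occupancy[ok]
  rbar <- sum(counts[ok]) / sum(occupancy[ok])
  s <- 0
  for (i in seq_along(p)) {
    if (r[i] > 0) s <- s + p[i] * (r[i] / rbar) * log2(r[i] / rbar)
  }
  s
}

# direct evaluation of the bidirectionality overlap
oracle_bidirectionality <- function(r_right, r_left) {
  nb <- length(r_right)
  Pr <- nb * r_right / sum(r_right)
  Pl <- nb * r_left / sum(r_left)
  num <- 0; den <- 0
  for (i in seq_len(nb)) {
    num <- num + min(Pr[i], Pl[i])
    den <- den + Pr[i] + Pl[i]
  }
  2 * num / den
}

# exhaustive state-ordering search (all M! permutations, filtered)
oracle_order_linear <- function(P, first, last) {
  M <- nrow(P)
  perms <- popstates:::all_perms(M)
  best <- NULL; best_obj <- -Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (p[1] != first || p[M] != last) next
    obj <- sum(P[cbind(p[-M], p[-1])])
    if (obj > best_obj) { best_obj <- obj; best <- p }
  }
  list(ordering = best, objective = best_obj)
}

oracle_order_cyclic_objective <- function(P) {
  M <- nrow(P)
  perms <- popstates:::all_perms(M)
  best_obj <- -Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    pn <- c(p[-1], p[1])
    obj <- sum(P[cbind(p, pn)]) + sum(P[cbind(pn, p)])
    if (obj > best_obj) best_obj <- obj
  }
  best_obj
}

# dense generalized eigensolver oracle: eigen(D^{-1} L), smallest eigenpairs
oracle_lem <- function(edges, n, n_dims) {
  W <- matrix(0, n, n)
  W[edges] <- 1
  W[edges[, c(2, 1)]] <- 1
  deg <- rowSums(W)
  L <- diag(deg) - W
  es <- eigen(solve(diag(deg)) %*% L)
  ord <- order(Re(es$values))
  vals <- Re(es$values[ord])
  vecs <- Re(es$vectors[, ord, drop = FALSE])
  # D-normalize and canonicalize sign like the implementation
  out <- vecs[, 2:(n_dims + 1), drop = FALSE]
  for (j in seq_len(ncol(out))) {
    v <- out[, j]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    out[, j] <- v
  }
  list(values = vals[seq_len(n_dims + 1)], vectors = out)
}
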