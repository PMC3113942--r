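# Independent oracles used across the suite. These deliberately follow
# the defining formulas by direct summation / enumeration, not the
# package's computational routes.

# Total scatter about the global centroid, by direct summation.
oracle_total_scatter <- function(X) {
  xbar <- colMeans(X)
  S <- matrix(0, ncol(X), ncol(X))
  for (j in seq_len(nrow(X))) {
    d <- X[j, ] - xbar
    S <- S + tcrossprod(d)
  }
  S
}

# Scatter pair by direct summation over the defining sums.
oracle_scatter <- function(X, y) {
  y <- factor(y)
  xbar <- colMeans(X)
  Sb <- matrix(0, ncol(X), ncol(X))
  Sw <- matrix(0, ncol(X), ncol(X))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    ci <- colMeans(X[idx, , drop = FALSE])
    Sb <- Sb + length(idx) * tcrossprod(ci - xbar)
    for (j in idx) Sw <- Sw + tcrossprod(X[j, ] - ci)
  }
  list(Sb = Sb, Sw = Sw)
}

# Classical FLDA directions via a literal eigen-solution of Sw^{-1} Sb.
oracle_flda <- function(X, y, q) {
  sc <- oracle_scatter(X, y)
  e <- eigen(solve(sc$Sw) %*% sc$Sb)
  D <- Re(e$vectors[, order(-Re(e$values))[seq_len(q)], drop = FALSE])
  for (j in seq_len(q)) D[, j] <- D[, j] / sqrt(sum(D[, j]^2))
  D
}

# Kennard-Stone selection by brute-force max-min enumeration.
oracle_kennard_stone <- function(X, n_train) {
  D <- as.matrix(dist(X))
  m <- nrow(X)
  best <- c(NA, NA); bestd <- -Inf
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_train) {
    rem <- setdiff(seq_len(m), sel)
    md <- vapply(rem, function(i) min(D[i, sel]), numeric(1))
    sel <- c(sel, rem[which.max(md)])
  }
  sel
}

# Two well-separated Gaussian clouds: the class-mean shift is spread
# over several features so the signal survives auto-scaling and
# dominates the leading principal components. PCDA must classify these
# perfectly at any sane component count.
separable_clouds <- function(n_per_class = 10, n_features = 50, shift = 6,
                             seed = 42) {
  plantedSignalData(n_per_class, n_features, 5L, shift, seed)
}

abs_cos <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
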