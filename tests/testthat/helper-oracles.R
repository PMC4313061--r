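# Independent oracles: deliberately different algorithms from the package
# implementations they check.

# Brute-force displacement-vector Pearson correlation: double loop over
# bead pairs, explicit time averages.
oracle_pearson <- function(coords) {
  # coords: n_atoms x 3 x n_frames (already aligned/centered as desired)
  n <- dim(coords)[1L]; nf <- dim(coords)[3L]
  mu <- apply(coords, c(1, 2), mean)
  M <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      num <- 0; vi <- 0; vj <- 0
      for (f in seq_len(nf)) {
        di <- coords[i, , f] - mu[i, ]
        dj <- coords[j, , f] - mu[j, ]
        num <- num + sum(di * dj)
        vi <- vi + sum(di * di)
        vj <- vj + sum(dj * dj)
      }
      M[i, j] <- M[j, i] <- num / sqrt(vi * vj)
    }
  }
  M
}

# Horn (1987) closed-form quaternion superposition: minimal RMSD from the
# maximal eigenvalue of the 4x4 quaternion matrix -- no SVD, no rotation
# needed, so no convention can couple it to the Kabsch route.
oracle_rmsd_horn <- function(mobile, ref) {
  M <- scale(mobile, scale = FALSE)
  P <- scale(ref, scale = FALSE)
  S <- t(M) %*% P
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- sum(M^2) + sum(P^2) - 2 * lam
  sqrt(max(0, e2) / nrow(mobile))
}

# Pure-R KSG (variant 1) mutual information between two 3-D variables.
oracle_ksg_mi <- function(a, b, k = 6) {
  n <- nrow(a)
  cheb <- function(x) {
    d <- matrix(0, n, n)
    for (col in seq_len(ncol(x))) d <- pmax(d, abs(outer(x[, col], x[, col], "-")))
    d
  }
  da <- cheb(a); db <- cheb(b)
  dj <- pmax(da, db)
  diag(dj) <- Inf
  acc <- 0
  for (t in seq_len(n)) {
    eps <- sort(dj[t, ], partial = k)[k]
    nx <- sum(da[t, -t] < eps)
    ny <- sum(db[t, -t] < eps)
    acc <- acc + digamma(nx + 1) + digamma(ny + 1)
  }
  digamma(k) + digamma(n) - acc / n
}

# Central finite difference gradient of a scalar function of coordinates.
oracle_fd_gradient <- function(f, x, h = 1e-5) {
  g <- matrix(0, nrow(x), 3)
  for (i in seq_len(nrow(x))) {
    for (d in 1:3) {
      xp <- x; xp[i, d] <- xp[i, d] + h
      xm <- x; xm[i, d] <- xm[i, d] - h
      g[i, d] <- (f(xp) - f(xm)) / (2 * h)
    }
  }
  g
}

# Closed-form eigen decomposition of a symmetric 3x3 matrix (trigonometric
# method) -- independent of LAPACK's eigen().
oracle_eigen3_values <- function(A) {
  q <- sum(diag(A)) / 3
  B <- A - q * diag(3)
  p2 <- sum(B^2) / 6
  p <- sqrt(p2)
  if (p < 1e-14) return(rep(q, 3))
  r <- det(B / p) / 2
  r <- max(-1, min(1, r))
  phi <- acos(r) / 3
  ev <- q + 2 * p * cos(phi + 2 * pi * (0:2) / 3)
  sort(ev, decreasing = TRUE)
}

# Uniform-mass inertia tensor about the centroid.
inertia_tensor <- function(coords) {
  X <- scale(coords, scale = FALSE)
  diag(3) * sum(X^2) - t(X) %*% X
}
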