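# Internal numeric helpers.

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Otsu threshold on a 256-bin histogram (maximises between-class variance).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(as.integer((x - lo) / (hi - lo) * n_bins) + 1L, n_bins),
                nbins = n_bins)
  w <- cumsum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  m <- cumsum(h * mids)
  n <- w[n_bins]; mtot <- m[n_bins]
  w1 <- w[-n_bins]; m1 <- m[-n_bins]
  valid <- w1 > 0 & w1 < n
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (mtot * w1[valid] - n * m1[valid])^2 /
    (w1[valid] * (n - w1[valid]))
  k <- which.max(between)
  lo + k * (hi - lo) / n_bins
}

# Best-fit 3D line through points (rows of `p`): returns the direction, the
# maximum perpendicular residual and the chord length (max pairwise distance).
fit_line3 <- function(p) {
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  sv <- svd(q)
  dir <- sv$v[, 1]
  proj <- q %*% dir
  resid <- q - proj %*% t(dir)
  perp <- sqrt(rowSums(resid^2))
  dmat <- as.matrix(stats::dist(p))
  list(direction = dir, max_perp = max(perp), length = max(dmat))
}

# Nearest rotation matrix (orthogonal Procrustes projection) to an arbitrary
# 3 x 3 matrix, with positive determinant.
nearest_rotation <- function(m) {
  sv <- svd(m)
  r <- sv$u %*% t(sv$v)
  if (det(r) < 0) {
    u <- sv$u
    u[, 3] <- -u[, 3]
    r <- u %*% t(sv$v)
  }
  r
}

pairwise_mean_distance <- function(p) {
  mean(stats::dist(p))
}

# Seed helper: derive a bounded child seed from a base seed and a tag.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 104729) %% 2147483647)
}
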