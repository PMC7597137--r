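# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own code paths.

# per-node entropy profile by direct looping over hub nodes
oracle_profile <- function(points) {
  n <- nrow(points)
  sapply(seq_len(n), function(i) {
    d <- sqrt((points[, 1] - points[i, 1])^2 + (points[, 2] - points[i, 2])^2)[-i]
    p <- d / sum(d)
    -sum(p * log(p)) / log(n - 1)
  })
}

# least-squares slope from the normal equations via stats::cov
oracle_slope <- function(v) {
  x <- seq_along(v) - 1
  stats::cov(x, v) / stats::var(x)
}

# the similarity rule restated from scratch
oracle_similar <- function(w1, w2, c) {
  if (w1 * w2 <= 0) return(FALSE)
  min(abs(w1), abs(w2)) / max(abs(w1), abs(w2)) >= c
}

# Gamma by full enumeration: every offset row, every unordered window pair
oracle_gamma <- function(v, W, phi, c) {
  L <- length(v)
  theta <- (W * phi / gcd_oracle(W, phi)) / phi - 1
  K <- L / W
  gammas <- sapply(0:theta, function(j) {
    slopes <- sapply(0:(K - 1), function(k) {
      idx <- ((j * phi + k * W + 0:(W - 1)) %% L) + 1
      oracle_slope(v[idx])
    })
    pairs <- 0
    for (a in 1:(K - 1)) for (b in (a + 1):K)
      if (oracle_similar(slopes[a], slopes[b], c)) pairs <- pairs + 1
    pairs / (K * (K - 1) / 2) * 100
  })
  list(gamma = max(gammas), by_offset = gammas)
}

gcd_oracle <- function(a, b) if (b == 0) a else gcd_oracle(b, a %% b)

# max cyclic-shift Pearson correlation by direct scan over all shifts
oracle_Q <- function(p1, p2) {
  L <- length(p1)
  max(sapply(0:(L - 1), function(s)
    stats::cor(p1[((seq_len(L) - 1 + s) %% L) + 1], p2)))
}

# do two segments properly intersect? near-collinear configurations (cross
# products within rounding noise of zero) count as non-crossing
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  eps <- 1e-9 * max(abs(c(p1, p2, q1, q2)), 1)^2
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  if (min(abs(c(d1, d2, d3, d4))) < eps) return(FALSE)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# brute-force all-pairs simplicity check of a closed polygon
polygon_is_simple <- function(points) {
  n <- nrow(points)
  nxt <- c(2:n, 1)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || nxt[i] == j || nxt[j] == i) next  # adjacent edges share a vertex
      if (segments_cross(points[i, ], points[nxt[i], ],
                         points[j, ], points[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

# random blob mask: union of filled discs on a small grid (always 4-connected)
random_blob_mask <- function(size = 24, n_discs = 3) {
  m <- matrix(FALSE, size, size)
  # discs always pairwise overlapping, so the union is one 4-connected blob
  cx <- stats::runif(n_discs, size * 0.40, size * 0.60)
  cy <- stats::runif(n_discs, size * 0.40, size * 0.60)
  r <- stats::runif(n_discs, size * 0.18, size * 0.30)
  for (k in seq_len(n_discs)) {
    for (i in seq_len(size)) for (j in seq_len(size))
      if ((i - cy[k])^2 + (j - cx[k])^2 <= r[k]^2) m[i, j] <- TRUE
  }
  m
}

# rigid-motion + scale transform of contour points
transform_points <- function(points, angle = 0, scale = 1, shift = c(0, 0)) {
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  sweep(scale * points %*% t(rot), 2, shift, `+`)
}
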