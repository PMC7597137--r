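#' Parameters of the self-similarity statistic
#'
#' @param window_size number of profile values per regression window
#'   (default 20).
#' @param lag cyclic offset between successive rows of windows (default
#'   20; must satisfy 1 <= lag <= window_size).
#' @param c similarity threshold on the slope magnitude ratio, in (0, 1]
#'   (default 0.8).
#' @param flat_tol optional tolerance under which two near-zero slopes are
#'   declared similar; the default 0 is the strict rule, where a zero
#'   slope is similar to no other window.
#' @return an object of class `gamma_params`.
#' @examples
#' gamma_params()              # the defaults: W = 20, lag = 20, c = 0.8
#' gamma_params(lag = 5)
#' @export
gamma_params <- function(window_size = 20, lag = 20, c = 0.8, flat_tol = 0) {
  if (!is_count(window_size, 2L))
    abort2("window_size must be an integer >= 2", "blse_invalid_spec")
  if (!is_count(lag, 1L) || lag > window_size)
    abort2("lag must be an integer with 1 <= lag <= window_size",
           "blse_invalid_spec")
  if (!is.numeric(c) || length(c) != 1L || c <= 0 || c > 1)
    abort2("c must lie in (0, 1]", "blse_invalid_spec")
  if (!is.numeric(flat_tol) || flat_tol < 0)
    abort2("flat_tol must be >= 0", "blse_invalid_spec")
  structure(list(window_size = as.integer(window_size), lag = as.integer(lag),
                 c = c, flat_tol = flat_tol),
            class = "gamma_params")
}

#' @export
print.gamma_params <- function(x, ...) {
  cat(sprintf("<gamma_params: W=%d, lag=%d, c=%g%s>\n", x$window_size, x$lag,
              x$c, if (x$flat_tol > 0) sprintf(", flat_tol=%g", x$flat_tol) else ""))
  invisible(x)
}

#' Least-squares slope of a window
#'
#' Ordinary least squares slope of the values against equally spaced
#' abscissae 0..W-1 — the fixed point of gradient descent on the squared
#' error, computed in closed form.
#'
#' @param values numeric vector of at least 2 finite values.
#' @return scalar slope.
#' @export
window_slope <- function(values) {
  w <- length(values)
  if (w < 2L) abort2("window needs at least 2 values", "blse_invalid_spec")
  if (anyNA(values) || any(!is.finite(values)))
    abort2("window values must be finite", "blse_invalid_spec")
  x <- seq_len(w) - 1
  sum((x - mean(x)) * (values - mean(values))) / sum((x - mean(x))^2)
}

#' Window similarity criterion
#'
#' Two windows are similar when their slopes agree in sign
#' (`w1 * w2 > 0`) and the smaller magnitude is at least fraction `c` of
#' the larger: `min(|w1|, |w2|) / max(|w1|, |w2|) >= c`. For positive
#' slopes this is exactly the printed ratio rule; stating it on magnitudes
#' extends it symmetrically to negative slopes. With `flat_tol > 0`, two
#' slopes both within `flat_tol` of zero are also similar.
#'
#' Vectorised over `w1`, `w2`.
#'
#' @param w1,w2 finite slopes.
#' @param c threshold in (0, 1].
#' @param flat_tol near-zero tolerance (default 0 = strict).
#' @return logical.
#' @examples
#' is_similar(0.8, 1.0, c = 0.8)   # TRUE (ratio exactly at threshold)
#' is_similar(-0.5, 0.5, c = 0.8)  # FALSE (opposite signs)
#' @export
is_similar <- function(w1, w2, c = 0.8, flat_tol = 0) {
  a1 <- abs(w1); a2 <- abs(w2)
  sim <- (w1 * w2 > 0) & (pmin(a1, a2) / pmax(a1, a2) >= c)
  if (flat_tol > 0) sim <- sim | (a1 <= flat_tol & a2 <= flat_tol)
  sim
}

#' Cyclic window offsets for the count matrix rows
#'
#' Row `j` of the count matrix shifts all windows by `j * lag`; the number
#' of distinct rows before the tiling repeats is
#' `theta + 1 = LCM(window_size, lag) / lag`.
#'
#' @param params a `gamma_params`.
#' @return integer vector of offsets `j * lag`, `j = 0..theta`.
#' @examples
#' row_offsets(gamma_params(lag = 5))   # 0 5 10 15
#' row_offsets(gamma_params(lag = 20))  # 0
#' @export
row_offsets <- function(params) {
  stopifnot(inherits(params, "gamma_params"))
  theta <- lcm2(params$window_size, params$lag) / params$lag - 1L
  as.integer(params$lag * (0:theta))
}

# accept a bls_profile (normalized values; must be closed) or a bare
# numeric vector (assumed cyclic)
profile_values <- function(profile, params) {
  if (inherits(profile, "bls_profile")) {
    if (!profile$closed)
      abort2("self-similarity is defined for closed contours only (cyclic shifts need wraparound)",
             "blse_open_contour")
    v <- profile$normalized
  } else if (is.numeric(profile)) {
    v <- as.numeric(profile)
  } else {
    abort2("profile must be a bls_profile or a numeric vector", "blse_invalid_spec")
  }
  if (anyNA(v) || any(!is.finite(v)))
    abort2("profile values must be finite", "blse_invalid_spec")
  if (length(v) %% params$window_size != 0L)
    abort2(sprintf(
      "profile length %d is not divisible by window size %d; resample the contour first",
      length(v), params$window_size), "blse_length")
  v
}

#' Window slopes for one cyclic offset row
#'
#' Splits the profile into `K = L / W` consecutive non-overlapping windows
#' starting at offset `j * lag` (indices taken modulo `L`) and returns the
#' least-squares slope of each.
#'
#' @param profile `bls_profile` (closed) or numeric vector treated as
#'   cyclic; length must be divisible by the window size.
#' @param params a `gamma_params`.
#' @param j row index, `0 <= j <= theta`.
#' @return numeric vector of `K` slopes.
#' @export
slopes_for_row <- function(profile, params, j = 0) {
  v <- profile_values(profile, params)
  offs <- row_offsets(params)
  if (!is_count(j, 0L) || j > length(offs) - 1L)
    abort2(sprintf("row index j must lie in 0..%d", length(offs) - 1L),
           "blse_invalid_spec")
  row_slopes(v, params$window_size, offs[j + 1L])
}

# all K window slopes at a given cyclic offset, vectorised:
# slope_k = sum(xc * window_k) / sum(xc^2) with xc the centred abscissae
row_slopes <- function(v, w, offset) {
  L <- length(v)
  k <- L %/% w
  idx <- (offset + seq_len(L) - 1L) %% L + 1L
  m <- matrix(v[idx], nrow = w, ncol = k)  # one window per column
  xc <- (seq_len(w) - 1) - (w - 1) / 2
  as.numeric(crossprod(xc, m)) / sum(xc^2)
}

#' Similar-window count matrix
#'
#' Entry `(j, k)` counts the windows in row `j` (cyclic offset `j * lag`)
#' that are similar to window `k` under the slope criterion, including the
#' trivial self-comparison, so every entry is at least 1. Rows are
#' computed independently.
#'
#' @inheritParams slopes_for_row
#' @return integer matrix of dimension `(theta + 1) x K` with the slope
#'   rows attached as attribute `"slopes"`.
#' @export
count_matrix <- function(profile, params = gamma_params()) {
  v <- profile_values(profile, params)
  offs <- row_offsets(params)
  k <- length(v) %/% params$window_size
  slopes <- t(vapply(offs, function(o) row_slopes(v, params$window_size, o),
                     numeric(k)))
  counts <- t(apply(slopes, 1L, function(w) {
    sim <- outer(w, w, is_similar, c = params$c, flat_tol = params$flat_tol)
    diag(sim) <- TRUE  # a window is trivially similar to itself
    as.integer(rowSums(sim))
  }))
  dimnames(counts) <- list(offset = offs, window = seq_len(k))
  attr(counts, "slopes") <- slopes
  counts
}

#' Similar-pair ratio of one count-matrix row
#'
#' `h_j = sum_k (M_jk - 1) / 2` counts the similar unordered window pairs
#' (the self-comparison is removed and each pair is counted once);
#' `gamma_j = 2 h_j / (K (K - 1)) * 100` is that count as a percentage of
#' all `K (K - 1) / 2` pairs.
#'
#' @param row integer vector of similar-window counts (one count-matrix
#'   row).
#' @param K number of windows (>= 2); defaults to `length(row)`.
#' @return percentage in \[0, 100\].
#' @examples
#' gamma_from_row(c(3, 3, 3))  # 100
#' gamma_from_row(c(2, 2, 1))  # 33.33...
#' @export
gamma_from_row <- function(row, K = length(row)) {
  if (!is_count(K, 2L)) abort2("K must be an integer >= 2", "blse_invalid_spec")
  h <- sum(row - 1) / 2
  200 * h / (K * (K - 1))
}

#' Self-similarity statistic of an entropy profile
#'
#' Builds the count matrix over all cyclic offset rows `j = 0..theta`,
#' converts each row to its similar-pair percentage `gamma_j`, and reports
#' the maximum as the self-similarity `Gamma` (in percent).
#'
#' @inheritParams slopes_for_row
#' @return an object of class `gamma_result`: list with `gamma` (the
#'   maximum, percent), `gamma_by_offset`, `counts`, `K`, `theta`,
#'   `offsets`, `params`.
#' @examples
#' saw <- rep(seq(0, 1, length.out = 20), 50)  # sawtooth, period = window
#' self_similarity(saw)$gamma                  # 100
#' @export
self_similarity <- function(profile, params = gamma_params()) {
  counts <- count_matrix(profile, params)
  k <- ncol(counts)
  gam <- apply(counts, 1L, gamma_from_row, K = k)
  structure(list(gamma = max(gam), gamma_by_offset = unname(gam),
                 counts = counts, K = k, theta = nrow(counts) - 1L,
                 offsets = as.integer(rownames(counts)), params = params),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result: Gamma = %.4g%% (K = %d windows, theta = %d)>\n",
              x$gamma, x$K, x$theta))
  cat("  gamma by offset:", paste(sprintf("%.4g", x$gamma_by_offset),
                                  collapse = " "), "\n")
  invisible(x)
}

#' End-to-end self-similarity of a contour
#'
#' Convenience wrapper: resample the closed contour to `nodes` nodes,
#' compute its entropy profile, and evaluate `Gamma`.
#'
#' @param contour a closed `bls_contour`.
#' @param params a `gamma_params`.
#' @param nodes profile length (default 1000; must be divisible by the
#'   window size).
#' @return a `gamma_result`.
#' @export
contour_gamma <- function(contour, params = gamma_params(), nodes = 1000) {
  if (!is_contour(contour)) abort2("not a bls_contour", "blse_invalid_spec")
  if (!contour$closed)
    abort2("Gamma is defined for closed contours only", "blse_open_contour")
  self_similarity(entropy_profile(resample_contour(contour, nodes)), params)
}
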