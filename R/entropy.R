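#' Branch length probabilities of a star network
#'
#' A star network has one hub and `n` branches of positive lengths
#' `L_1..L_n`; each branch carries probability `p_j = L_j / sum(L)`.
#'
#' @param lengths numeric vector of branch lengths (n >= 2, all > 0).
#' @return numeric vector of probabilities summing to 1.
#' @examples
#' branch_probabilities(c(1, 3))  # 0.25 0.75
#' @export
branch_probabilities <- function(lengths) {
  check_branch_lengths(lengths)
  lengths / sum(lengths)
}

check_branch_lengths <- function(lengths) {
  if (!is.numeric(lengths) || length(lengths) < 2L)
    abort2("need at least 2 branch lengths", "blse_too_few_branches")
  if (anyNA(lengths) || any(!is.finite(lengths)))
    abort2("branch lengths must be finite", "blse_invalid_length")
  if (any(lengths <= 0))
    abort2("branch lengths must be strictly positive", "blse_invalid_length")
  invisible(lengths)
}

#' Branch length similarity (BLS) entropy
#'
#' Shannon entropy of the branch length probabilities, normalised by
#' `log(n)` so the value lies in (0, 1]:
#' `S = -sum(p_j * log(p_j)) / log(n)`. S equals 1 exactly when all branch
#' lengths are equal, and decreases as the lengths become more dissimilar.
#' The normalisation makes S independent of the logarithm base.
#'
#' @inheritParams branch_probabilities
#' @return scalar entropy in (0, 1].
#' @examples
#' bls_entropy(rep(2.5, 7))  # 1
#' bls_entropy(c(1, 3))      # ~0.811
#' @export
bls_entropy <- function(lengths) {
  p <- branch_probabilities(lengths)
  -sum(p * log(p)) / log(length(p))
}

#' Star network branch lengths for one contour node
#'
#' Euclidean distances from node `i` to every other node of the contour,
#' in node order. These are the branch lengths of the star network whose
#' hub is node `i`.
#'
#' @param contour a `bls_contour` with >= 3 nodes.
#' @param i hub node index (1-based).
#' @return numeric vector of length `n_nodes(contour) - 1`.
#' @export
star_distances <- function(contour, i) {
  if (!is_contour(contour)) abort2("not a bls_contour", "blse_invalid_spec")
  n <- n_nodes(contour)
  if (n < 3L) abort2("contour must have at least 3 nodes", "blse_too_small")
  if (!is_count(i, 1L) || i > n) abort2("node index out of range", "blse_invalid_spec")
  p <- contour$points
  d <- sqrt((p[, 1L] - p[i, 1L])^2 + (p[, 2L] - p[i, 2L])^2)[-i]
  if (any(d == 0))
    abort2(sprintf("node %d coincides with another node (zero branch length)", i),
           "blse_zero_branch")
  d
}

#' BLS entropy profile of a contour
#'
#' Makes each boundary node in turn the hub of a star network connecting it
#' to all other nodes, and records the BLS entropy of that network, in
#' boundary order. The raw profile is accompanied by a min-max normalised
#' copy rescaled to attain exactly 0 and 1 (constant profiles are flagged
#' and normalised to all zeros instead of dividing by zero).
#'
#' The raw profile depends only on distance ratios, so it is invariant
#' under translation, rotation and uniform scaling of the contour.
#' Computation is O(N^2) in the node count.
#'
#' @param contour a `bls_contour` with >= 3 nodes and no coincident nodes.
#' @return an object of class `bls_profile`: list with `raw`,
#'   `normalized`, `closed`, `constant`.
#' @examples
#' pr <- entropy_profile(make_regular_polygon(5, 40))
#' range(pr$normalized)
#' @export
entropy_profile <- function(contour) {
  if (!is_contour(contour)) abort2("not a bls_contour", "blse_invalid_spec")
  n <- n_nodes(contour)
  if (n < 3L) abort2("contour must have at least 3 nodes", "blse_too_small")
  D <- as.matrix(stats::dist(contour$points))
  off_zero <- which(D == 0 & row(D) != col(D), arr.ind = TRUE)
  if (nrow(off_zero) > 0L)
    abort2(sprintf("nodes %d and %d coincide (zero branch length)",
                   off_zero[1L, 2L], off_zero[1L, 1L]), "blse_zero_branch")
  P <- D / rowSums(D)
  PL <- P * log(P)
  diag(PL) <- 0  # excluded branch: p log p -> 0
  raw <- unname(-rowSums(PL) / log(n - 1L))
  new_profile(raw, closed = contour$closed)
}

new_profile <- function(raw, closed) {
  rng <- range(raw)
  # profiles flat to within 1e-12 (relative) are treated as constant rather
  # than min-max scaled, which would only amplify rounding noise
  constant <- (rng[2L] - rng[1L]) <= 1e-12 * max(abs(rng), 1)
  normalized <- if (constant) rep(0, length(raw))
                else (raw - rng[1L]) / (rng[2L] - rng[1L])
  structure(list(raw = raw, normalized = normalized, closed = closed,
                 constant = constant),
            class = "bls_profile")
}

#' @export
print.bls_profile <- function(x, ...) {
  cat(sprintf("<bls_profile: %d nodes, %s%s; raw range [%.6g, %.6g]>\n",
              length(x$raw), if (x$closed) "closed" else "open",
              if (x$constant) ", constant" else "",
              min(x$raw), max(x$raw)))
  invisible(x)
}

#' Read and write entropy profile CSV files
#'
#' Columns `index`, `raw_entropy`, `normalized_entropy`; values written
#' with 17 significant digits so round trips are lossless.
#'
#' @param profile a `bls_profile`.
#' @param path file path.
#' @param closed closed flag attached on read (not stored in the CSV).
#' @return `read_profile_csv` returns a `bls_profile`;
#'   `write_profile_csv` returns `path` invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  if (!inherits(profile, "bls_profile"))
    abort2("not a bls_profile", "blse_invalid_spec")
  txt <- c("index,raw_entropy,normalized_entropy",
           sprintf("%d,%.17g,%.17g", seq_along(profile$raw), profile$raw,
                   profile$normalized))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path, closed = TRUE) {
  if (!file.exists(path))
    abort2(sprintf("profile file not found: %s", path), "blse_io")
  df <- utils::read.csv(path)
  need <- c("raw_entropy", "normalized_entropy")
  if (!all(need %in% names(df)))
    abort2(sprintf("profile CSV %s lacks columns %s", path,
                   paste(setdiff(need, names(df)), collapse = ", ")),
           "blse_parse")
  if (anyNA(df$raw_entropy))
    abort2(sprintf("non-numeric entropy value in %s", path), "blse_parse")
  new_profile(df$raw_entropy, closed = closed)
}
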