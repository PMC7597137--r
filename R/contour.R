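#' Planar contour objects
#'
#' A `bls_contour` is an ordered sequence of planar nodes (real-valued
#' coordinates, pixel units or abstract units) together with a flag saying
#' whether the node sequence wraps around. For closed contours the first and
#' last nodes are *not* duplicated: the wrap is implicit.
#'
#' @param points two-column numeric matrix (or data frame) of x, y
#'   coordinates in boundary order.
#' @param closed logical; does the node sequence wrap?
#' @return An object of class `bls_contour`: a list with elements `points`
#'   (n x 2 matrix, columns `x`, `y`) and `closed`.
#' @examples
#' sq <- contour_points(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), closed = TRUE)
#' n_nodes(sq)
#' @export
contour_points <- function(points, closed = TRUE) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2L)
    abort2("contour points must be a two-column numeric matrix", "blse_invalid_spec")
  if (anyNA(pts) || any(!is.finite(pts)))
    abort2("contour points must be finite", "blse_invalid_spec")
  if (nrow(pts) < 2L)
    abort2("a contour needs at least 2 points", "blse_too_small")
  dup <- rowSums(abs(pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])) == 0
  if (any(dup))
    abort2(sprintf("consecutive duplicate point at row %d", which(dup)[1L] + 1L),
           "blse_invalid_spec")
  if (closed && nrow(pts) >= 2L &&
      all(pts[1L, ] == pts[nrow(pts), ]))
    abort2("closed contours must not repeat the first point at the end",
           "blse_invalid_spec")
  dimnames(pts) <- list(NULL, c("x", "y"))
  structure(list(points = pts, closed = isTRUE(closed)), class = "bls_contour")
}

#' @export
print.bls_contour <- function(x, ...) {
  cat(sprintf("<bls_contour: %d nodes, %s>\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' @rdname contour_points
#' @param x a `bls_contour`.
#' @export
n_nodes <- function(x) nrow(x$points)

is_contour <- function(x) inherits(x, "bls_contour")

#' Signed polygon area (shoelace)
#'
#' Positive for counterclockwise node order in a right-handed x-y plane.
#'
#' @param contour a closed `bls_contour`.
#' @return signed area (numeric scalar).
#' @export
signed_area <- function(contour) {
  p <- contour$points
  xs <- p[, 1L]; ys <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  sum(xs * ys[j] - xs[j] * ys) / 2
}

# edge lengths including the closing edge when closed
edge_lengths <- function(contour) {
  p <- contour$points
  d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (contour$closed) d <- c(d, sqrt(sum((p[1L, ] - p[nrow(p), ])^2)))
  d
}

#' Total arc length of a contour
#'
#' Includes the implicit closing edge for closed contours.
#' @param contour a `bls_contour`.
#' @return numeric scalar.
#' @export
arc_length <- function(contour) sum(edge_lengths(contour))

#' Resample a contour uniformly in arc length
#'
#' Places `n` nodes equally spaced in cumulative arc length along the
#' polyline (wrapping across the implicit closing edge when the contour is
#' closed). The first output node coincides with the input's first node, so
#' resampling never changes the profile's phase origin.
#'
#' @param contour a `bls_contour` with at least 3 points.
#' @param n target node count (>= 3).
#' @return a `bls_contour` with `n` nodes and the same `closed` flag.
#' @examples
#' sq <- make_regular_polygon(4, 2)
#' resample_contour(sq, 16)
#' @export
resample_contour <- function(contour, n) {
  if (!is_contour(contour)) abort2("not a bls_contour", "blse_invalid_spec")
  if (!is_count(n, 3L)) abort2("n must be an integer >= 3", "blse_invalid_spec")
  if (n_nodes(contour) < 3L)
    abort2("contour must have at least 3 points", "blse_too_small")
  el <- edge_lengths(contour)
  total <- sum(el)
  if (total <= 0) abort2("degenerate contour of zero length", "blse_degenerate")
  p <- contour$points
  if (contour$closed) {
    p_ext <- rbind(p, p[1L, , drop = FALSE])
    cum <- c(0, cumsum(el))
    t_out <- total * (seq_len(n) - 1L) / n
  } else {
    p_ext <- p
    cum <- c(0, cumsum(el))
    t_out <- total * (seq_len(n) - 1L) / (n - 1L)
  }
  x <- stats::approx(cum, p_ext[, 1L], xout = t_out, ties = "ordered")$y
  y <- stats::approx(cum, p_ext[, 2L], xout = t_out, ties = "ordered")$y
  x[1L] <- p[1L, 1L]; y[1L] <- p[1L, 2L]
  contour_points(cbind(x, y), closed = contour$closed)
}

#' Read and write contour CSV files
#'
#' The on-disk format is a plain CSV with two numeric columns `x`, `y`
#' (header optional on read, written on write), one node per row.
#' Coordinates are written with 17 significant digits so a write/read
#' round trip reproduces them exactly.
#'
#' @param path file path.
#' @param closed logical flag attached to the contour on read (the CSV
#'   stores coordinates only).
#' @return `read_contour_csv` returns a `bls_contour`;
#'   `write_contour_csv` returns `path` invisibly.
#' @export
read_contour_csv <- function(path, closed = TRUE) {
  if (!file.exists(path))
    abort2(sprintf("contour file not found: %s", path), "blse_io")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    abort2(sprintf("empty contour file: %s", path), "blse_parse")
  first <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  start <- if (has_header) 2L else 1L
  rows <- lines[seq.int(start, length(lines))]
  if (length(rows) < 3L)
    abort2(sprintf("contour file %s has %d data rows; need at least 3",
                   path, length(rows)), "blse_too_small")
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad_len <- which(lengths(parts) != 2L)
  if (length(bad_len))
    abort2(sprintf("line %d of %s: expected two comma-separated values",
                   bad_len[1L] + start - 1L, path), "blse_parse")
  m <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE))
  bad <- which(rowSums(is.na(m)) > 0L)
  if (length(bad))
    abort2(sprintf("line %d of %s: non-numeric coordinate",
                   bad[1L] + start - 1L, path), "blse_parse")
  contour_points(m, closed = closed)
}

#' @rdname read_contour_csv
#' @param contour a `bls_contour` to write.
#' @export
write_contour_csv <- function(contour, path) {
  if (!is_contour(contour)) abort2("not a bls_contour", "blse_invalid_spec")
  p <- contour$points
  txt <- c("x,y", sprintf("%.17g,%.17g", p[, 1L], p[, 2L]))
  writeLines(txt, path)
  invisible(path)
}
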