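#' Trace the outer boundary of a binary mask
#'
#' Moore-neighbour tracing with Jacob's stopping criterion. The mask must
#' contain exactly one 4-connected foreground component; holes are ignored
#' (outer boundary only). Pixel coordinates are reported as (x = column,
#' y = row) and the node order is normalised to counterclockwise, i.e.
#' positive signed area in the (x, y) plane. The start pixel is the
#' topmost-then-leftmost foreground pixel (smallest row, then smallest
#' column).
#'
#' @param mask logical or 0/1 numeric matrix; `TRUE`/nonzero = foreground.
#' @return a closed `bls_contour` of boundary pixel coordinates.
#' @examples
#' m <- matrix(1, 3, 3)
#' trace_boundary(m)  # the 8-pixel ring
#' @export
trace_boundary <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.matrix(mask) || !is.numeric(mask))
    abort2("mask must be a logical or numeric matrix", "blse_invalid_spec")
  fg <- which(mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0L) abort2("mask contains no foreground pixels", "blse_no_shape")
  if (count_components4(mask != 0) > 1L)
    abort2("mask contains more than one 4-connected foreground component",
           "blse_ambiguous")

  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask != 0

  # start: topmost (min row) then leftmost (min col) foreground pixel
  start <- unname(fg[order(fg[, 1L], fg[, 2L])[1L], ]) + 1L  # padded coords

  b <- moore_trace(pad, start)
  if (nrow(b) < 3L)
    abort2("foreground component has fewer than 3 boundary pixels",
           "blse_too_small")
  # back to unpadded coordinates; x = column, y = row
  xy <- cbind(x = b[, 2L] - 1L, y = b[, 1L] - 1L)
  ct <- contour_points(xy, closed = TRUE)
  if (signed_area(ct) < 0)
    ct <- contour_points(xy[c(1L, nrow(xy):2L), , drop = FALSE], closed = TRUE)
  ct
}

# Moore-neighbour walk on a padded logical matrix; Jacob's stopping
# criterion (revisit the start pixel with the original backtrack pixel)
moore_trace <- function(pad, start) {
  # clockwise Moore neighbourhood starting from W, offsets as (row, col)
  nbr <- rbind(
    c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
    c(0L, 1L),  c(1L, 1L),   c(1L, 0L),  c(1L, -1L)
  )
  b0 <- start + nbr[1L, ]  # west neighbour: background by the start rule
  p <- start
  b <- b0
  pts <- vector("list", 64L)
  pts[[1L]] <- start
  np <- 1L
  maxit <- 8L * sum(pad) + 8L
  for (it in seq_len(maxit)) {
    diffd <- b - p
    bdir <- which(nbr[, 1L] == diffd[1L] & nbr[, 2L] == diffd[2L])
    d <- bdir
    found <- FALSE
    for (step in seq_len(8L)) {
      d <- d %% 8L + 1L  # rotate clockwise
      cand <- p + nbr[d, ]
      if (pad[cand[1L], cand[2L]]) { found <- TRUE; break }
      b <- cand  # last background pixel examined
    }
    if (!found) break  # isolated pixel
    cnew <- p + nbr[d, ]
    if (all(cnew == start) && all(b == b0)) break  # Jacob's criterion
    np <- np + 1L
    if (np > length(pts)) pts <- c(pts, vector("list", length(pts)))
    pts[[np]] <- cnew
    p <- cnew
  }
  do.call(rbind, pts[seq_len(np)])
}

# number of 4-connected foreground components (flood fill)
count_components4 <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  comp <- 0L
  idx <- which(bin)
  for (p in idx) {
    if (lab[p] != 0L) next
    comp <- comp + 1L
    queue <- p
    lab[p] <- comp
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (q - 1L) %% nr + 1L
      cc <- (q - 1L) %/% nr + 1L
      for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + off[1L]; c2 <- cc + off[2L]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc &&
            bin[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- comp
          queue <- c(queue, (c2 - 1L) * nr + r2)
        }
      }
    }
  }
  comp
}

#' Read a binary mask image
#'
#' Accepts PNG (via the `png` package, if installed), ASCII PGM/PBM
#' (`P1`/`P2` magic), or a plain CSV of 0/1 values. Any pixel value
#' strictly greater than half the maximum is foreground for grayscale
#' inputs; nonzero is foreground for CSV and PBM.
#'
#' @param path image path; format chosen by extension
#'   (`.png`, `.pgm`, `.pbm`, `.csv`).
#' @return logical matrix, `TRUE` = foreground.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort2(sprintf("mask not found: %s", path), "blse_io")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      abort2("reading PNG masks requires the 'png' package", "blse_io")
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(img > 0.5)
  }
  if (ext %in% c("pgm", "pbm")) return(read_pnm_ascii(path))
  if (ext == "csv") {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    storage.mode(m) <- "numeric"
    dimnames(m) <- NULL
    if (anyNA(m)) abort2(sprintf("non-numeric cell in mask CSV %s", path), "blse_parse")
    return(m != 0)
  }
  abort2(sprintf("unsupported mask format: .%s", ext), "blse_io")
}

# minimal ASCII netpbm reader (P1 bitmap / P2 graymap)
read_pnm_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  tok <- scan(text = paste(lines, collapse = " "), what = character(),
              quiet = TRUE)
  magic <- tok[1L]
  if (!magic %in% c("P1", "P2"))
    abort2(sprintf("unsupported netpbm magic '%s' (need ASCII P1/P2)", magic),
           "blse_parse")
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L])
  off <- if (magic == "P2") 5L else 4L
  maxval <- if (magic == "P2") as.numeric(tok[4L]) else 1
  vals <- as.numeric(tok[seq.int(off, length.out = w * h)])
  if (anyNA(vals)) abort2(sprintf("malformed pixel data in %s", path), "blse_parse")
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (magic == "P1") m != 0 else m > maxval / 2
}

#' Write an ASCII PGM mask
#'
#' @param mask logical or 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mask, path) {
  m <- (mask != 0) * 1L
  header <- c("P2", sprintf("%d %d", ncol(m), nrow(m)), "1")
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Rasterise a contour to a binary mask
#'
#' Point-in-polygon fill on a pixel grid, used to turn synthetic contours
#' into mask fixtures. The contour is scaled to fit the requested image
#' size with a 2-pixel margin.
#'
#' @param contour a closed `bls_contour`.
#' @param size image side length in pixels (default 64).
#' @return logical matrix of `size` x `size`.
#' @export
rasterize_contour <- function(contour, size = 64) {
  if (!is_contour(contour) || !contour$closed)
    abort2("rasterisation needs a closed contour", "blse_invalid_spec")
  p <- contour$points
  rng <- apply(p, 2L, range)
  span <- max(rng[2L, ] - rng[1L, ])
  if (span <= 0) abort2("degenerate contour", "blse_degenerate")
  s <- (size - 5L) / span
  px <- (p[, 1L] - rng[1L, 1L]) * s + 2.5
  py <- (p[, 2L] - rng[1L, 2L]) * s + 2.5
  grid_x <- matrix(rep(seq_len(size) - 0.5, each = size), size)
  grid_y <- matrix(rep(seq_len(size) - 0.5, times = size), size)
  inside <- point_in_polygon(as.vector(grid_x), as.vector(grid_y), px, py)
  matrix(inside, size, size)
}

# even-odd ray casting, vectorised over query points
point_in_polygon <- function(qx, qy, px, py) {
  n <- length(px)
  inside <- logical(length(qx))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > qy) != (py[j] > qy)) &
      (qx < (px[j] - px[i]) * (qy - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
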