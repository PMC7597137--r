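#' Two-segment straight line with controlled node densities
#'
#' Builds a single straight (collinear, open) contour by joining two
#' segments of equal length carrying `n1` and `n2` uniformly spaced nodes.
#' The junction node is shared, so the contour has `n1 + n2 - 1` nodes.
#' Unequal node counts give unequal node densities on the two halves, which
#' is the canonical probe for the node-density effect on the entropy
#' profile: the sparser half develops higher entropy values.
#'
#' @param n1,n2 node counts of the first and second segment (each >= 2,
#'   endpoints included).
#' @param segment_length length of each segment (default 1).
#' @return an open `bls_contour` with `n1 + n2 - 1` collinear nodes.
#' @examples
#' n_nodes(make_segmented_line(120, 100))  # 219
#' @export
make_segmented_line <- function(n1, n2, segment_length = 1) {
  if (!is_count(n1, 2L) || !is_count(n2, 2L))
    abort2("segment node counts must be integers >= 2", "blse_invalid_spec")
  if (!is.numeric(segment_length) || segment_length <= 0)
    abort2("segment_length must be positive", "blse_invalid_spec")
  x1 <- seq(0, segment_length, length.out = n1)
  # second segment built as the exact mirror of a 0..length grid so that
  # equal node counts give bitwise mirror-symmetric spacing
  x2 <- 2 * segment_length - rev(seq(0, segment_length, length.out = n2))
  x <- c(x1, x2[-1L])  # junction counted once
  contour_points(cbind(x, 0), closed = FALSE)
}

#' Equilateral triangle with per-side node counts
#'
#' Vertices a, b, c of a unit-side equilateral triangle in counterclockwise
#' order starting at a = (0, 0). Side a-b carries `n_ab` uniformly spaced
#' nodes (endpoints included), sides b-c and c-a carry `n_bc` and `n_ca`.
#' Shared vertices are counted once, so the closed contour has
#' `n_ab + n_bc + n_ca - 3` nodes.
#'
#' @param n_ab,n_bc,n_ca node counts per side (each >= 2).
#' @return a closed `bls_contour`.
#' @examples
#' n_nodes(make_triangle(100, 120, 120))  # 337
#' @export
make_triangle <- function(n_ab, n_bc, n_ca) {
  if (!is_count(n_ab, 2L) || !is_count(n_bc, 2L) || !is_count(n_ca, 2L))
    abort2("side node counts must be integers >= 2", "blse_invalid_spec")
  a <- c(0, 0); b <- c(1, 0); c_ <- c(0.5, sqrt(3) / 2)
  side <- function(p, q, n) {
    t <- seq(0, 1, length.out = n)[-n]  # drop far endpoint; next side supplies it
    cbind(p[1L] + t * (q[1L] - p[1L]), p[2L] + t * (q[2L] - p[2L]))
  }
  pts <- rbind(side(a, b, n_ab), side(b, c_, n_bc), side(c_, a, n_ca))
  contour_points(pts, closed = TRUE)
}

#' Regular polygon contour
#'
#' Unit-circumradius regular polygon, counterclockwise, with
#' `nodes_per_side` uniformly spaced nodes per side and shared vertices
#' counted once: `n_sides * (nodes_per_side - 1)` nodes in total.
#'
#' @param n_sides number of sides (>= 3).
#' @param nodes_per_side nodes per side including both vertices (>= 2).
#' @return a closed `bls_contour`.
#' @examples
#' n_nodes(make_regular_polygon(4, 250))  # 996
#' @export
make_regular_polygon <- function(n_sides, nodes_per_side) {
  if (!is_count(n_sides, 3L))
    abort2("n_sides must be an integer >= 3", "blse_invalid_spec")
  if (!is_count(nodes_per_side, 2L))
    abort2("nodes_per_side must be an integer >= 2", "blse_invalid_spec")
  ang <- 2 * pi * (seq_len(n_sides) - 1L) / n_sides
  v <- cbind(cos(ang), sin(ang))  # counterclockwise vertices
  pts <- do.call(rbind, lapply(seq_len(n_sides), function(i) {
    p <- v[i, ]; q <- v[if (i == n_sides) 1L else i + 1L, ]
    t <- seq(0, 1, length.out = nodes_per_side)[-nodes_per_side]
    cbind(p[1L] + t * (q[1L] - p[1L]), p[2L] + t * (q[2L] - p[2L]))
  }))
  contour_points(pts, closed = TRUE)
}

# raw vertex set of a seeded star-shaped random polygon (counterclockwise)
random_polygon_vertices <- function(n_vertices, seed,
                                    radius_range = c(0.5, 1)) {
  with_local_seed(seed, {
    repeat {
      ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
      # distinct angles guarantee a simple star-shaped polygon
      if (min(diff(c(ang, ang[1L] + 2 * pi))) > 1e-6) break
    }
    r <- stats::runif(n_vertices, radius_range[1L], radius_range[2L])
    cbind(r * cos(ang), r * sin(ang))
  })
}

#' Seeded random simple polygon
#'
#' Draws `n_vertices` angles uniformly on the circle, sorts them, and
#' assigns each a uniform radius in \[0.5, 1\] about the origin. The
#' angular-sort construction makes the polygon star-shaped, hence simple
#' (no self-intersections). The polygon is then resampled to `nodes_total`
#' nodes uniform in arc length. Fully deterministic given `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param n_vertices number of polygon vertices (>= 3).
#' @param seed integer seed.
#' @param nodes_total node count after arc-length resampling (default 1000).
#' @return a closed `bls_contour` with `nodes_total` nodes.
#' @examples
#' p <- make_random_polygon(10, seed = 42)
#' n_nodes(p)
#' @export
make_random_polygon <- function(n_vertices, seed, nodes_total = 1000) {
  if (!is_count(n_vertices, 3L))
    abort2("n_vertices must be an integer >= 3", "blse_invalid_spec")
  if (!is_count(nodes_total, 3L))
    abort2("nodes_total must be an integer >= 3", "blse_invalid_spec")
  v <- random_polygon_vertices(n_vertices, seed)
  resample_contour(contour_points(v, closed = TRUE), nodes_total)
}

#' Template-plus-noise shape groups
#'
#' Emulates a multi-class silhouette dataset (e.g. finger-gesture groups):
#' each group has a distinct random-polygon template and members are the
#' template with Gaussian displacement of its vertices, resampled to a
#' common profile length. Noise amplitude is expressed as a fraction of the
#' template scale (mean vertex radius).
#'
#' @param n_groups number of groups (default 10).
#' @param n_members shapes per group (default 10).
#' @param noise vertex displacement standard deviation as a fraction of
#'   the mean vertex radius (default 0.01, i.e. 1 percent of scale).
#' @param nodes_total nodes per contour after resampling (default 1000).
#' @param seed integer master seed; templates and members derive their own
#'   sub-seeds from it deterministically.
#' @param vertex_range range of template vertex counts, sampled uniformly
#'   (default 10:17, matching the random-polygon experiments).
#' @return a named list of `n_groups` lists of `bls_contour`s; names are
#'   `"g01"`, `"g02"`, ...
#' @export
make_shape_groups <- function(n_groups = 10, n_members = 10, noise = 0.01,
                              nodes_total = 1000, seed = 1,
                              vertex_range = 10:17) {
  if (!is_count(n_groups, 2L) || !is_count(n_members, 2L))
    abort2("need at least 2 groups of at least 2 members", "blse_invalid_spec")
  if (!is.numeric(noise) || noise < 0)
    abort2("noise must be non-negative", "blse_invalid_spec")
  nv <- with_local_seed(seed, sample(vertex_range, n_groups, replace = TRUE))
  groups <- lapply(seq_len(n_groups), function(g) {
    tpl_seed <- (seed * 1000L + g) %% .Machine$integer.max
    tpl <- random_polygon_vertices(nv[g], tpl_seed)
    scale <- mean(sqrt(rowSums(tpl^2)))
    lapply(seq_len(n_members), function(m) {
      mem_seed <- (seed * 1000L + g * 100L + m) %% .Machine$integer.max
      v <- with_local_seed(mem_seed,
        tpl + matrix(stats::rnorm(length(tpl), sd = noise * scale),
                     ncol = 2L))
      resample_contour(contour_points(v, closed = TRUE), nodes_total)
    })
  })
  names(groups) <- sprintf("g%02d", seq_len(n_groups))
  groups
}
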