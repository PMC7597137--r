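test_that("segmented line generator: counts, symmetry, density, errors", {
  ln <- make_segmented_line(100, 100, 1.0)
  expect_equal(n_nodes(ln), 199)
  expect_false(ln$closed)
  # collinear on the x axis
  expect_true(all(ln$points[, "y"] == 0))
  # equal densities force node positions exactly mirror-symmetric about the
  # midpoint; gap differences agree to one ulp
  x <- ln$points[, "x"]
  expect_identical(max(abs(x + rev(x) - 2)), 0)
  gaps <- diff(x)
  expect_lt(max(abs(gaps - rev(gaps))), 1e-15)

  # unequal counts: denser spacing on the first half
  ln2 <- make_segmented_line(120, 100, 1.0)
  expect_equal(n_nodes(ln2), 219)
  g <- diff(ln2$points[, "x"])
  expect_lt(mean(g[1:119]), mean(g[120:218]))

  expect_error(make_segmented_line(1, 100), class = "blse_invalid_spec")
  expect_error(make_segmented_line(10, 10, segment_length = 0),
               class = "blse_invalid_spec")
})

test_that("triangle and regular polygon generators: counts and orientation", {
  tri <- make_triangle(100, 120, 120)
  expect_equal(n_nodes(tri), 337)  # 100 + 120 + 120 minus 3 shared vertices
  expect_true(tri$closed)
  expect_gt(signed_area(tri), 0)  # counterclockwise

  expect_equal(n_nodes(make_triangle(2, 2, 2)), 3)
  expect_error(make_triangle(1, 2, 2), class = "blse_invalid_spec")

  sq <- make_regular_polygon(4, 250)
  expect_equal(n_nodes(sq), 996)
  expect_gt(signed_area(sq), 0)
  expect_equal(n_nodes(make_regular_polygon(5, 200)), 995)
  expect_equal(n_nodes(make_regular_polygon(3, 2)), 3)
  expect_error(make_regular_polygon(2, 10), class = "blse_invalid_spec")
  # unit circumradius
  expect_equal(max(sqrt(rowSums(sq$points^2))), 1, tolerance = 1e-12)
})

test_that("random polygons are deterministic, simple, and resampled", {
  p1 <- make_random_polygon(10, seed = 42, nodes_total = 1000)
  p2 <- make_random_polygon(10, seed = 42, nodes_total = 1000)
  expect_identical(p1$points, p2$points)  # bit-identical under one seed
  expect_false(identical(p1$points,
                         make_random_polygon(10, seed = 43, 1000)$points))
  expect_equal(n_nodes(p1), 1000)

  # simplicity via the brute-force all-pairs segment-intersection oracle
  for (spec in list(c(3, 7, 300), c(15, 1, 1000), c(17, 5, 500))) {
    poly <- make_random_polygon(spec[1], seed = spec[2], nodes_total = spec[3])
    expect_true(polygon_is_simple(poly$points))
  }
  expect_error(make_random_polygon(2, seed = 1), class = "blse_invalid_spec")
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(make_random_polygon(12, seed = 5))
  invisible(make_shape_groups(n_groups = 2, n_members = 2, nodes_total = 100,
                              seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("boundary tracing: 3x3 ring, orientation suite, errors", {
  tb <- trace_boundary(matrix(1, 3, 3))
  expect_equal(n_nodes(tb), 8)  # manual enumeration of the 3x3 ring
  expect_setequal(paste(tb$points[, 1], tb$points[, 2]),
                  c("1 1", "2 1", "3 1", "3 2", "3 3", "2 3", "1 3", "1 2"))
  expect_gt(signed_area(tb), 0)
  # start pixel: topmost-then-leftmost
  expect_equal(unname(tb$points[1, ]), c(1, 1))

  expect_error(trace_boundary(matrix(0, 4, 4)), class = "blse_no_shape")
  expect_error(trace_boundary(matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 1), 3)),
               class = "blse_ambiguous")
  m1 <- matrix(0, 4, 4); m1[2, 2] <- 1
  expect_error(trace_boundary(m1), class = "blse_too_small")

  # randomized suite: every traced boundary is counterclockwise
  set.seed(7)
  for (i in 1:25) {
    ct <- trace_boundary(random_blob_mask())
    expect_gt(signed_area(ct), 0)
  }
})

# independent stand-in construction so the resampling test does not depend
# on the seeded generator under test
random_polygon_vertices_test <- function(n, seed) {
  set.seed(seed)
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 0.5, 1)
  cbind(r * cos(ang), r * sin(ang))
}

test_that("resampling is uniform in arc length and phase preserving", {
  corners <- contour_points(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), closed = TRUE)
  r8 <- resample_contour(corners, 8)
  expect_equal(r8$points,
               cbind(x = c(0, .5, 1, 1, 1, .5, 0, 0),
                     y = c(0, 0, 0, .5, 1, 1, 1, .5)),
               tolerance = 1e-12)

  # identity: already uniform spacing, same node count
  hexa <- make_regular_polygon(6, 10)
  expect_equal(resample_contour(hexa, n_nodes(hexa))$points, hexa$points,
               tolerance = 1e-9)

  # circle sampled at 100 points, resampled to 1000: all points near the circle
  t100 <- 2 * pi * (0:99) / 100
  circ <- contour_points(cbind(cos(t100), sin(t100)), closed = TRUE)
  r1000 <- resample_contour(circ, 1000)
  radial <- abs(sqrt(rowSums(r1000$points^2)) - 1)
  expect_lt(max(radial), 1e-3)

  # arc length preserved within 1% for n >= 10x the vertex count (regular
  # polygons, node count chosen so samples straddle the corners); corner
  # cutting can only shrink the length, never grow it
  for (k in 6:10) {
    poly <- make_regular_polygon(k, 2)
    rs <- resample_contour(poly, 10 * k + 3)
    expect_lte(arc_length(rs), arc_length(poly) * (1 + 1e-12))
    expect_equal(arc_length(rs), arc_length(poly), tolerance = 0.01)
  }
  # spikier random polygons: monotonicity still holds even when the sharp
  # corners make the 1% bound unattainable at 10x sampling
  set.seed(11)
  for (i in 1:5) {
    poly <- contour_points(random_polygon_vertices_test(8, i), closed = TRUE)
    rs <- resample_contour(poly, 80)
    expect_lte(arc_length(rs), arc_length(poly) * (1 + 1e-12))
  }

  # open contours keep both endpoints
  ln <- make_segmented_line(10, 10)
  rl <- resample_contour(ln, 21)
  expect_equal(unname(rl$points[1, ]), c(0, 0))
  expect_equal(unname(rl$points[21, ]), c(2, 0))

  expect_error(resample_contour(corners, 2), class = "blse_invalid_spec")
})

test_that("contour CSV round trip and parse errors", {
  withr_like_tmp <- tempfile(fileext = ".csv")
  poly <- make_random_polygon(9, seed = 2, nodes_total = 50)
  write_contour_csv(poly, withr_like_tmp)
  back <- read_contour_csv(withr_like_tmp, closed = TRUE)
  expect_identical(back$points, poly$points)  # lossless at 17 digits

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2", "3,4"), f2)
  expect_error(read_contour_csv(f2), class = "blse_too_small")

  f3 <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2", "3,abc", "5,6"), f3)
  expect_error(read_contour_csv(f3), "line 3", class = "blse_parse")

  expect_error(read_contour_csv(tempfile()), class = "blse_io")
})

test_that("contour constructor enforces its invariants", {
  expect_error(contour_points(cbind(c(0, 0, 1), c(0, 0, 1))),
               class = "blse_invalid_spec")
  expect_error(contour_points(cbind(c(0, 1, 0), c(0, 1, 0)), closed = TRUE),
               class = "blse_invalid_spec")  # wrap must be implicit
  expect_error(contour_points(matrix(1:9, 3)), class = "blse_invalid_spec")
})

test_that("shape groups: structure, determinism, noise scale", {
  gs <- make_shape_groups(n_groups = 3, n_members = 4, noise = 0.01,
                          nodes_total = 200, seed = 5)
  expect_named(gs, c("g01", "g02", "g03"))
  expect_true(all(vapply(gs, length, 1L) == 4))
  expect_true(all(unlist(lapply(gs, function(g)
    vapply(g, n_nodes, 1L))) == 200))
  gs2 <- make_shape_groups(n_groups = 3, n_members = 4, noise = 0.01,
                           nodes_total = 200, seed = 5)
  expect_identical(gs, gs2)
  # members of one group are close to each other (1% noise), groups differ
  d_within <- mean(abs(gs[[1]][[1]]$points - gs[[1]][[2]]$points))
  d_between <- mean(abs(gs[[1]][[1]]$points - gs[[2]][[1]]$points))
  expect_lt(d_within, d_between / 5)
})
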