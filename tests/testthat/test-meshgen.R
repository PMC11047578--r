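test_that("frames on a straight segment are constant and axis-aligned", {
  seg <- straight_segment(c(0, 0, 0), c(0, 0, 40), 2, dl = 2)
  fr <- transport_frames(seg)
  n <- nrow(fr$dir)
  expect_equal(fr$dir, matrix(rep(c(0, 0, 1), each = n), n, 3),
               tolerance = 1e-12)
  expect_lt(max(abs(sweep(fr$nx, 2, fr$nx[1, ]))), 1e-12)
  expect_lt(max(abs(sweep(fr$ny, 2, fr$ny[1, ]))), 1e-12)
})

test_that("transported frames are right-handed orthonormal triads", {
  h <- make_noisy_centerline(turns = 1.5, noise_amplitude = 0, seed = 1)
  seg <- centerline_segment(h$points, dl = 1)
  fr <- transport_frames(seg)
  for (i in seq_len(nrow(fr$dir))) {
    expect_lt(abs(sum(fr$dir[i, ]^2) - 1), 1e-10)
    expect_lt(abs(sum(fr$nx[i, ]^2) - 1), 1e-10)
    expect_lt(abs(sum(fr$ny[i, ]^2) - 1), 1e-10)
    expect_lt(abs(sum(fr$dir[i, ] * fr$nx[i, ])), 1e-10)
    expect_lt(abs(sum(fr$dir[i, ] * fr$ny[i, ])), 1e-10)
    expect_lt(abs(sum(fr$nx[i, ] * fr$ny[i, ])), 1e-10)
    det3 <- sum(vasculate:::cross3(fr$nx[i, ], fr$ny[i, ]) * fr$dir[i, ])
    expect_equal(det3, 1, tolerance = 1e-10)
  }
})

test_that("parallel transport on a planar arc carries zero twist", {
  tt <- seq(0, pi / 2, length.out = 60)
  pts <- data.frame(x = 30 * cos(tt), y = 30 * sin(tt), z = 0, r = 1)
  fr <- transport_frames(centerline_segment(pts, dl = 1))
  # the plane normal (0,0,1) is perpendicular to every tangent: the
  # transported frame must keep a constant angle to it (no twist)
  ang <- acos(pmin(pmax(fr$nx %*% c(0, 0, 1), -1), 1))
  expect_lt(diff(range(ang)), 1e-8)
})

test_that("closed planar loops have vanishing holonomy", {
  tt <- seq(0, 2 * pi, length.out = 721)
  pts <- data.frame(x = 20 * cos(tt), y = 20 * sin(tt), z = 0, r = 1)
  fr <- transport_frames(pts)
  # planar curve: zero holonomy means the transported normal keeps a constant
  # out-of-plane component all the way around the loop
  expect_lt(diff(range(fr$nx[, 3])), 1e-6)
  expect_lt(diff(range(fr$ny[, 3])), 1e-6)
})

test_that("ring vertices realise the area-to-radius relation exactly", {
  p <- c(1, 2, 3)
  nx <- c(1, 0, 0); ny <- c(0, 1, 0)
  # A = pi -> r = 1
  ring <- ring_vertices(p, nx, ny, pi, k = 4)
  expect_equal(ring[1, ], p + c(1, 0, 0), tolerance = 1e-12)
  expect_equal(ring[2, ], p + c(0, 1, 0), tolerance = 1e-12)
  expect_equal(ring[3, ], p - c(1, 0, 0), tolerance = 1e-12)
  expect_equal(ring[4, ], p - c(0, 1, 0), tolerance = 1e-12)
  for (k in c(3, 5, 16)) {
    A <- 7.3
    rg <- ring_vertices(p, nx, ny, A, k = k)
    d <- sqrt(rowSums(sweep(rg, 2, p)^2))
    expect_lt(max(abs(d - sqrt(A / pi))), 1e-12)
    expect_lt(max(abs(colMeans(rg) - p)), 1e-12)  # sum of roots of unity = 0
  }
  expect_error(ring_vertices(p, nx, ny, 1, k = 2), "k must be")
  expect_error(ring_vertices(p, nx, ny, -1, k = 8), "non-positive")
})

test_that("tube triangulation has the band structure and Euler count", {
  seg <- straight_segment(c(0, 0, 0), c(0, 0, 10), 1.5, dl = 2)
  N <- nrow(seg$points)
  k <- 8L
  m <- segment_mesh(seg, k = k)
  expect_identical(nrow(m$vertices), k * N)
  expect_identical(nrow(m$faces), 2L * k * (N - 1L))
  census <- mesh_edge_census(m)
  # interior edges shared by exactly 2 faces; the 2k boundary-ring edges by 1
  expect_identical(sum(census$count == 1), 2L * k)
  expect_true(all(census$count %in% c(1, 2)))
  E <- nrow(census)
  expect_identical(E, 3L * k * N - 2L * k)
  expect_identical(nrow(m$vertices) - E + nrow(m$faces), 0L)  # V - E + F = 0

  # every vertex sits at distance sqrt(A/pi) from its centerline point
  A <- pi * seg$points$r^2
  P <- as.matrix(seg$points[, c("x", "y", "z")])
  d <- sqrt(rowSums((m$vertices - P[m$ring_index$point, ])^2))
  expect_lt(max(abs(d - sqrt(A[m$ring_index$point] / pi))), 1e-12)
})

test_that("two-ring band and half-slot rotation are triangulated watertight", {
  k <- 8L
  r1 <- ring_vertices(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), pi, k)
  r2 <- ring_vertices(c(0, 0, 2), c(1, 0, 0), c(0, 1, 0), pi, k)
  m <- triangulate_tube(list(r1, r2))
  expect_identical(nrow(m$faces), 16L)
  expect_identical(nrow(m$vertices), 16L)
  census <- mesh_edge_census(m)
  expect_identical(sum(census$count == 2), nrow(census) - 2L * k)

  # second ring rotated by exactly half a slot: tie resolved, still watertight
  ang <- pi / k
  rot <- cbind(cos(ang) * r2[, 1] - sin(ang) * r2[, 2],
               sin(ang) * r2[, 1] + cos(ang) * r2[, 2], r2[, 3])
  expect_warning(m2 <- triangulate_tube(list(r1, rot)), "constant offset")
  census2 <- mesh_edge_census(m2)
  expect_true(all(census2$count %in% c(1, 2)))
  expect_identical(sum(census2$count == 1), 2L * k)

  expect_error(triangulate_tube(list(r1)), "at least 2")
  expect_error(triangulate_tube(list(r1, r2[1:5, ])), "unequal")
})

test_that("face winding is outward-consistent", {
  seg <- straight_segment(c(0, 0, 0), c(0, 0, 10), 2, dl = 2)
  m <- segment_mesh(seg, k = 12)
  P <- as.matrix(seg$points[, c("x", "y", "z")])
  v <- m$vertices; f <- m$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fc <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  outward <- fc - P[m$ring_index$point[f[, 1]], ]
  expect_true(all(rowSums(nrm * outward) > 0))
})

test_that("baked scalar series carries fields and dynamic radii", {
  s <- seq(0, 20, 1)
  times <- seq(0, 1, length.out = 5)
  Q <- outer(rep(1, 5), 1 + 0.5 * s)           # linear in s
  A <- matrix(12, 5, length(s))
  A[3, ] <- 24                                  # doubled area at one instant
  sol <- structure(list(
    times = times, period = 1,
    segments = list("1" = list(s = s, A = A, P = A * 100, Q = Q, index = 1L,
                               wall = wall_model(E = 4e5, r0 = 2, h0 = 0.2))),
    fluid = fluid_props(), converged = TRUE), class = "solution_field")
  seg <- straight_segment(c(0, 0, 0), c(0, 0, 20), 2, dl = 2)
  mp <- map_solution_to_centerline(sol, seg)
  dyn <- bake_scalar_series(seg, mp, field = "Q", k = 8, frame_times = times)
  expect_length(dyn$frames, 5)
  # constant-in-t field: all frames carry identical scalars; ring scalars
  # strictly monotone along the tube for a linear-in-s field
  sc <- dyn$frames[[1]]$scalars
  ring_vals <- sc[seq(1, length(sc), by = 8)]
  expect_true(all(diff(ring_vals) > 0))
  expect_equal(dyn$frames[[2]]$scalars, dyn$frames[[1]]$scalars)
  # doubled area at frame 3: radius scales by sqrt(2) in that frame only
  ctr <- as.matrix(seg$points[, c("x", "y", "z")])[dyn$ring_index$point, ]
  rad <- function(fr) sqrt(rowSums((fr$vertices - ctr)^2))
  expect_equal(rad(dyn$frames[[3]]) / rad(dyn$frames[[1]]),
               rep(sqrt(2), nrow(ctr)), tolerance = 1e-12)
  expect_error(bake_scalar_series(seg, mp, field = "nope"), "unknown field")
})

test_that("mesh exports are deterministic and well-formed", {
  seg <- straight_segment(c(0, 0, 0), c(0, 0, 10), 2, dl = 2)
  m <- segment_mesh(seg, k = 8)
  f1 <- tempfile(fileext = ".vtk"); f2 <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f1, scalars = seq_len(nrow(m$vertices)))
  write_mesh_vtk(m, f2, scalars = seq_len(nrow(m$vertices)))
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(f1)[4], "DATASET POLYDATA")

  p1 <- tempfile(fileext = ".ply")
  write_mesh_ply(m, p1)
  hdr <- readLines(p1, n = 10)
  expect_identical(hdr[1], "ply")
  expect_true(any(grepl(sprintf("element vertex %d", nrow(m$vertices)), hdr)))

  # dynamic series writes frames + index + sidecar
  s <- seq(0, 10, 1)
  sol <- structure(list(
    times = c(0, 0.5, 1), period = 1,
    segments = list("1" = list(s = s, A = matrix(12, 3, 11),
                               P = matrix(1e4, 3, 11), Q = matrix(2, 3, 11),
                               index = 1L,
                               wall = wall_model(E = 4e5, r0 = 2, h0 = 0.2))),
    fluid = fluid_props(), converged = TRUE), class = "solution_field")
  mp <- map_solution_to_centerline(sol, seg)
  dyn <- bake_scalar_series(seg, mp, field = "Q", k = 8)
  d <- tempfile()
  write_dynamic_mesh(dyn, d)
  expect_true(file.exists(file.path(d, "series.pvd")))
  expect_true(file.exists(file.path(d, "color_range.json")))
  expect_length(list.files(d, pattern = "^frame_.*vtk$"), 3)
})
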