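test_that("mean velocity follows Q/A with unit consistency", {
  # 5 ml/s through 0.25 cm^2 = 25 mm^2 -> 20 cm/s
  expect_equal(mean_velocity(5, 25), 0.2)
  expect_equal(mean_velocity(0, 10), 0)
  expect_equal(mean_velocity(5, 50), mean_velocity(5, 25) / 2)
  expect_error(mean_velocity(1, 0), "non-positive")
})

test_that("the Poiseuille profile has the stated wall and centerline values", {
  V <- 0.3; R <- 2
  expect_equal(velocity_profile(V, R, 0), 2 * V)
  expect_equal(velocity_profile(V, R, R), 0)
  expect_error(velocity_profile(V, R, R + 0.1), "r <= R")
  # disc average of the profile equals the mean velocity
  f <- function(r) velocity_profile(V, R, r) * 2 * pi * r
  disc_mean <- stats::integrate(f, 0, R, rel.tol = 1e-12)$value / (pi * R^2)
  expect_equal(disc_mean, V, tolerance = 1e-10)
})

test_that("wall shear stress equals the wall derivative of the profile", {
  expect_equal(wss(0.2, 2, 0.004), 1.6)
  expect_equal(wss(0, 2), 0)
  expect_error(wss(1, 0), "non-positive")
  # mu |dU/dr| at r = R by central differences, randomized (V, R, mu)
  set.seed(11)
  for (i in 1:20) {
    V <- runif(1, 0.05, 1); R <- runif(1, 0.5, 5); mu <- runif(1, 0.002, 0.01)
    h <- 1e-6 * R
    dUdr <- (velocity_profile(V, R, R) - velocity_profile(V, R, R - h)) / h
    tau_fd <- mu * abs(dUdr) / 1e-3  # per-mm derivative to per-m
    expect_equal(wss(V, R, mu), tau_fd, tolerance = 1e-6)
  }
})

test_that("TAWSS is the rectified cycle average", {
  tt <- seq(0, 1, length.out = 1001)
  expect_equal(tawss(rep(2.5, 1001), tt, 1), 2.5, tolerance = 1e-12)
  expect_equal(tawss(sin(2 * pi * tt), tt, 1), 2 / pi, tolerance = 1e-3)
  expect_equal(tawss(-sin(2 * pi * tt), tt, 1), tawss(sin(2 * pi * tt), tt, 1))
  expect_equal(tawss(sin(2 * pi * tt), tt, 1, signed = TRUE), 0,
               tolerance = 1e-12)
  expect_error(tawss(sin(2 * pi * tt[1:400]), tt[1:400], 1), "one period")
})

# minimal hand-built solution container for the mapping tests
fake_solution <- function(s, times, A, P, Q, index = 1L) {
  wall <- wall_model(E = 4e5, r0 = mean(sqrt(A / pi)), h0 = 0.3)
  structure(list(
    times = times, period = diff(range(times)),
    segments = stats::setNames(
      list(list(s = s, A = A, P = P, Q = Q, index = index, wall = wall)),
      as.character(index)),
    fluid = fluid_props(), converged = TRUE), class = "solution_field")
}

test_that("mapping reproduces nested-grid and linear fields exactly", {
  s <- seq(0, 20, 1)                       # solver grid, ds = 1 mm
  times <- seq(0, 1, length.out = 5)
  lin <- outer(rep(1, 5), 2 + 3 * s)       # linear in s, constant in t
  sol <- fake_solution(s, times, A = lin * 0 + 12, P = lin * 100, Q = lin)
  seg <- straight_segment(c(0, 0, 0), c(0, 0, 20), radius = 2, dl = 2)  # dl = 2 mm
  mp <- map_solution_to_centerline(sol, seg)
  # nested grids: mapped values equal solver values at coincident nodes
  expect_equal(mp$Q[1, ], 2 + 3 * seq(0, 20, 2), tolerance = 1e-12)
  expect_equal(mp$P[1, ], 100 * (2 + 3 * seq(0, 20, 2)), tolerance = 1e-12)
  # constant field maps to constant
  expect_true(all(abs(mp$A - 12) < 1e-12))
  # endpoints map exactly
  expect_equal(mp$Q[, 1], sol$segments[["1"]]$Q[, 1])
  expect_equal(mp$Q[, ncol(mp$Q)], sol$segments[["1"]]$Q[, ncol(lin)])
})

test_that("mapping validates index and arc-length agreement", {
  s <- seq(0, 20, 1)
  times <- seq(0, 1, length.out = 3)
  M <- matrix(1, 3, 21)
  sol <- fake_solution(s, times, A = M * 10, P = M * 1e4, Q = M)
  wrong_index <- straight_segment(c(0, 0, 0), c(0, 0, 20), 2, index = 9)
  expect_error(map_solution_to_centerline(sol, wrong_index), "arterial index")
  too_long <- straight_segment(c(0, 0, 0), c(0, 0, 30), 2, index = 1)
  expect_error(map_solution_to_centerline(sol, too_long), "mismatch")
})

test_that("mapping conserves the segment-integrated flow between grids", {
  s <- seq(0, 40, 1)
  times <- c(0, 1)
  Q <- outer(c(1, 1), 3 + sin(s / 5) + 0.2 * s)
  sol <- fake_solution(s, times, A = Q * 0 + 10, P = Q * 1e3, Q = Q)
  seg <- straight_segment(c(0, 0, 0), c(0, 0, 40), 2, dl = 2)
  mp <- map_solution_to_centerline(sol, seg)
  arc <- c(0, cumsum(sqrt(rowSums(diff(as.matrix(seg$points[, 1:3]))^2))))
  int_sol <- pracma::trapz(s, Q[1, ])
  int_map <- pracma::trapz(arc, mp$Q[1, ])
  expect_equal(int_map, int_sol, tolerance = 5e-3)
})

test_that("solution_wss derives nodewise shear and per-segment TAWSS", {
  cow <- make_toy_cow(0)
  cfg <- cow$config
  cfg$solver$max_cycles <- 4
  cfg$solver$tol_cycle <- 5e-3
  sol <- suppressWarnings(simulate_network(cow$network, cfg))
  w <- solution_wss(sol)
  expect_named(w$segment_tawss, names(sol$segments))
  expect_true(all(w$segment_tawss > 0))
  # tau sign follows V sign everywhere
  sg <- w$segments[["2"]]
  expect_true(all(sign(sg$tau) == sign(sg$V) | sg$V == 0))
  # reference-radius option changes R but not the sign structure
  w0 <- solution_wss(sol, use_reference_radius = TRUE)
  expect_equal(dim(w0$segments[["2"]]$tau), dim(sg$tau))
})
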