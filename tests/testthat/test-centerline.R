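test_that("exactly collinear nodes fit to a straight line", {
  nodes <- data.frame(x = seq(0, 20, 1), y = 0, z = 0, r = 1.5)
  cv <- fit_spline_sfm(nodes)
  dev <- abs(curve_eval(cv, seq(0, cv$chord_length, length.out = 201))[, c("y", "z")])
  expect_lt(max(dev), 1e-9)
  expect_lt(max(curve_curvature(cv, seq(0, cv$chord_length, length.out = 201))),
            1e-9)
})

test_that("AIC selection picks the grid minimum; single-entry grid degenerates", {
  h <- make_noisy_centerline(turns = 1.5, seed = 3)
  cv <- fit_spline_sfm(h$points)
  expect_equal(cv$aic, min(cv$aic_table$aic))
  expect_true(cv$lambda3 %in% cv$aic_table$l3)
  one <- fit_spline_sfm(h$points, lambda_grid = 0.01)
  expect_identical(one$lambda3, 0.01)
  expect_identical(one$lambda4, 0.01)
  # full grid contains the diagonal optimum or better
  full <- fit_spline_sfm(h$points, lambda_grid = 10^seq(-2, 2), full_grid = TRUE)
  expect_lte(full$aic, cv$aic + 1e-6)
})

test_that("smoothing the quantization-noise helix halves the curvature error", {
  h <- make_noisy_centerline(R = 10, pitch = 5, turns = 2.5, arc_step = 1,
                             noise_amplitude = 0.5, seed = 42)
  cv <- fit_spline_sfm(h$points)
  interior <- 2:(nrow(h$points) - 1)
  raw_k <- polyline_curvature(h$points)[interior]
  fit_k <- curve_curvature(cv, cv$u)[interior]
  rms <- function(x) sqrt(mean(x^2))
  e_raw <- rms(raw_k - h$curvature)
  e_fit <- rms(fit_k - h$curvature)
  expect_lt(e_fit, 0.5 * e_raw)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_spline_sfm(data.frame(x = 1:5, y = 0, z = 0)), "at least 7")
  expect_error(fit_spline_sfm(data.frame(x = 1:10, y = 0, z = 0),
                              lambda_grid = c(-1, 1)), "positive")
})

test_that("resampling places points on the stated arc grid", {
  nodes <- data.frame(x = seq(0, 20, 0.5), y = 0, z = 0, r = 2)
  cv <- fit_spline_sfm(nodes)
  seg <- resample_curve(cv, dl = 2)
  expect_identical(nrow(seg$points), 11L)       # floor(20/2) + 1
  d <- sqrt(rowSums(diff(as.matrix(seg$points[, 1:3]))^2))
  expect_equal(d, rep(2, 10), tolerance = 1e-6)  # straight: chord == arc
  expect_equal(unlist(seg$points[1, 1:3], use.names = FALSE), c(0, 0, 0),
               tolerance = 1e-9)
  expect_equal(seg$points$x[11], 20, tolerance = 1e-6)
  # total arc length conserved within 0.1%
  expect_equal(segment_arclength(seg), curve_length(cv), tolerance = 1e-3)
  expect_error(resample_curve(cv, dl = -1), "positive")
  expect_warning(two <- resample_curve(cv, dl = 50), "2-point")
  expect_identical(nrow(two$points), 2L)
})

test_that("quarter-circle resampling matches the closed-form arc length", {
  R <- 10
  tt <- seq(0, pi / 2, length.out = 200)
  nodes <- data.frame(x = R * cos(tt), y = R * sin(tt), z = 0, r = 1)
  cv <- fit_spline_sfm(nodes, lambda_grid = 1e-8)
  L <- curve_length(cv)
  expect_equal(L, pi * R / 2, tolerance = 1e-4)
  seg <- resample_curve(cv, dl = 2)
  # chords are shorter than the 2 mm arc spacing on a curved path
  d <- sqrt(rowSums(diff(as.matrix(seg$points[, 1:3]))^2))
  expect_true(all(d < 2 + 1e-9))
  # arc positions of the resampled points are multiples of dl within 1e-4
  arcs <- vapply(seq_len(nrow(seg$points) - 1), function(i) {
    u <- stats::uniroot(function(uu)
      curve_eval(cv, uu)[, "x"] - seg$points$x[i], c(0, cv$chord_length),
      tol = 1e-12)$root
    curve_length(cv, 0, u)
  }, numeric(1))
  expect_equal(arcs, 2 * (seq_along(arcs) - 1), tolerance = 1e-4)
})

test_that("interpolation limit: tiny penalties reproduce the data", {
  h <- make_noisy_centerline(turns = 1, noise_amplitude = 0, seed = 1)
  cv <- fit_spline_sfm(h$points, lambda_grid = 1e-10)
  fit <- curve_eval(cv, cv$u)
  expect_lt(max(abs(fit[, "x"] - h$points$x)), 1e-3)
  expect_lt(max(abs(fit[, "y"] - h$points$y)), 1e-3)
})

test_that("smooth_skeleton produces labelled centerline segments", {
  ph <- make_tube_phantom("Y", length_vox = 30, radius_vox = 3)
  sk <- skeleton_from_volume(ph$volume, min_branch_mm = 6)
  segs <- smooth_skeleton(sk, dl = 2)
  expect_length(segs, 3)
  for (sg in segs) {
    expect_s3_class(sg, "centerline_segment")
    expect_true(all(sg$points$r > 0))
    d <- sqrt(rowSums(diff(as.matrix(sg$points[, 1:3]))^2))
    # spacing within 10% of dl except the final interval
    if (length(d) > 1) expect_true(all(abs(d[-length(d)] - 2) < 0.2 + 1e-9))
  }
})
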