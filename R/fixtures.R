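#' Voxelized tube phantoms
#'
#' Generates binary voxel volumes of simple vessels together with their
#' analytic ground truth, for skeletonization and smoothing oracles:
#' `"straight"` (cylinder along z), `"helix"` (tube around a helical axis,
#' ground-truth curvature `R/(R^2 + c^2)` attached) and `"Y"` (one stem
#' splitting into two straight branches).
#'
#' @param kind phantom type.
#' @param length_vox axis length in voxels (straight / stem+branches for Y).
#' @param radius_vox tube radius in voxels, >= 2 (thinning is unreliable
#'   below).
#' @param spacing voxel spacing (mm), scalar or length 3.
#' @param helix_radius,helix_pitch,helix_turns helix geometry (voxel units).
#' @param branch_angle_deg half-angle between the Y branches.
#' @return list with `volume` (a [voxel_volume()]), `centerline` (data frame
#'   of the analytic axis in world mm), `radius_mm`, and for the helix
#'   `curvature` (1/mm).
#' @export
make_tube_phantom <- function(kind = c("straight", "helix", "Y"),
                              length_vox = 40, radius_vox = 3,
                              spacing = 1,
                              helix_radius = 10, helix_pitch = 5,
                              helix_turns = 1.5,
                              branch_angle_deg = 35) {
  kind <- match.arg(kind)
  if (length_vox <= 0) stop("length must be positive")
  if (radius_vox < 2) stop("radius must be >= 2 voxels (thinning unreliable)")
  spacing <- rep_len(spacing, 3)

  axis_pts <- switch(kind,
    straight = {
      z <- seq(0, length_vox, by = 0.25)
      cbind(0, 0, z)
    },
    helix = {
      tt <- seq(0, 2 * pi * helix_turns, length.out = 60 * helix_turns * 4)
      cbind(helix_radius * cos(tt), helix_radius * sin(tt),
            helix_pitch * tt / (2 * pi))
    },
    Y = {
      a <- branch_angle_deg * pi / 180
      stem <- cbind(0, 0, seq(0, length_vox, by = 0.25))
      bl <- length_vox * 0.8
      s <- seq(0.25, bl, by = 0.25)
      b1 <- cbind(s * sin(a), 0, length_vox + s * cos(a))
      b2 <- cbind(-s * sin(a), 0, length_vox + s * cos(a))
      rbind(stem, b1, b2)
    })

  if (kind == "straight") {
    # exact cylinder voxelization: length_vox slices, no end caps
    pad <- radius_vox + 3L
    nxy <- 2L * pad + 1L
    dims <- c(nxy, nxy, as.integer(length_vox))
    xy <- expand.grid(i = seq_len(nxy), j = seq_len(nxy))
    disc <- (xy$i - pad - 1L)^2 + (xy$j - pad - 1L)^2 <= radius_vox^2
    vol <- array(FALSE, dims)
    vol[cbind(xy$i[disc], xy$j[disc], rep(seq_len(dims[3]), each = sum(disc)))] <- TRUE
    volume <- voxel_volume(vol, spacing = spacing)
    zc <- seq(0, length_vox - 1, by = 0.25)
    cl <- cbind(pad, pad, zc)  # 0-based index coordinates of the axis
    cl <- sweep(cl * rep(spacing, each = nrow(cl)), 2, volume$origin, "+")
    return(list(volume = volume,
                centerline = data.frame(x = cl[, 1], y = cl[, 2], z = cl[, 3]),
                radius_mm = radius_vox * spacing[1], kind = kind))
  }

  pad <- radius_vox + 3
  mins <- apply(axis_pts, 2, min) - pad
  maxs <- apply(axis_pts, 2, max) + pad
  dims <- as.integer(ceiling(maxs - mins) + 1)
  vol <- array(FALSE, dims)

  # paint spheres along the axis (axis sampled at <= 0.25 voxel steps)
  ctr <- sweep(axis_pts, 2, mins)
  rv <- radius_vox
  ball <- as.matrix(expand.grid(dx = -ceiling(rv):ceiling(rv),
                                dy = -ceiling(rv):ceiling(rv),
                                dz = -ceiling(rv):ceiling(rv)))
  ball <- ball[rowSums(ball^2) <= rv^2 + 1e-9, , drop = FALSE]
  filled <- new.env(hash = TRUE)
  for (i in seq_len(nrow(ctr))) {
    base <- round(ctr[i, ])
    key <- paste(base, collapse = ",")
    if (exists(key, envir = filled)) next
    assign(key, TRUE, envir = filled)
    vox <- sweep(ball, 2, base + 1, "+")  # 1-based indices
    ok <- vox[, 1] >= 1 & vox[, 2] >= 1 & vox[, 3] >= 1 &
      vox[, 1] <= dims[1] & vox[, 2] <= dims[2] & vox[, 3] <= dims[3]
    vol[vox[ok, , drop = FALSE]] <- TRUE
  }

  volume <- voxel_volume(vol, spacing = spacing)
  cl <- sweep(sweep(ctr, 2, spacing, "*"), 2, volume$origin, "+")
  out <- list(volume = volume,
              centerline = data.frame(x = cl[, 1], y = cl[, 2], z = cl[, 3]),
              radius_mm = radius_vox * spacing[1], kind = kind)
  if (kind == "helix") {
    c_par <- helix_pitch / (2 * pi)
    out$curvature <- helix_radius /
      (helix_radius^2 + c_par^2) / spacing[1]  # 1/mm after scaling
    out$helix <- list(R = helix_radius * spacing[1],
                      c = c_par * spacing[1], turns = helix_turns)
  }
  out
}

#' Analytic helix centerline with quantization noise
#'
#' Samples the helix `(R cos t, R sin t, c t)` at uniform arc steps and
#' corrupts the samples with voxel-style quantization noise: optional
#' rounding to a grid plus uniform jitter of the given amplitude per axis.
#' Ground-truth curvature is `R / (R^2 + c^2)`.
#'
#' @param R helix radius (mm).
#' @param pitch helix pitch (mm per turn); `c = pitch / (2 pi)`.
#' @param turns number of turns.
#' @param arc_step arc-length sampling step (mm).
#' @param noise_amplitude half-width of the uniform jitter (mm) per axis.
#' @param grid_mm round the clean samples to this grid first (0 disables).
#' @param radius constant tube radius attached to the points (mm).
#' @param seed RNG seed (fixes all randomness).
#' @return list with `points` (noisy x, y, z, r), `clean` (noise-free),
#'   `curvature` (true curvature, 1/mm).
#' @export
make_noisy_centerline <- function(R = 10, pitch = 5, turns = 2.5,
                                  arc_step = 1, noise_amplitude = 0.5,
                                  grid_mm = 0, radius = 1.5, seed = 1) {
  stopifnot(noise_amplitude >= 0)
  c_par <- pitch / (2 * pi)
  speed <- sqrt(R^2 + c_par^2)  # |dC/dt|
  t_end <- 2 * pi * turns
  tt <- seq(0, t_end, by = arc_step / speed)
  clean <- data.frame(x = R * cos(tt), y = R * sin(tt), z = c_par * tt,
                      r = radius)
  pts <- clean
  if (grid_mm > 0)
    pts[, c("x", "y", "z")] <- round(pts[, c("x", "y", "z")] / grid_mm) * grid_mm
  if (noise_amplitude > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    n <- nrow(pts)
    pts$x <- pts$x + stats::runif(n, -noise_amplitude, noise_amplitude)
    pts$y <- pts$y + stats::runif(n, -noise_amplitude, noise_amplitude)
    pts$z <- pts$z + stats::runif(n, -noise_amplitude, noise_amplitude)
  }
  list(points = pts, clean = clean, curvature = R / (R^2 + c_par^2),
       t = tt)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Convert NASCET (diameter) severity to area severity
#'
#' NASCET grades stenosis by diameter reduction; an area severity follows as
#' `1 - (1 - nascet)^2`.
#'
#' @param nascet diameter severity in `[0, 1)`.
#' @return area severity.
#' @export
severity_from_nascet <- function(nascet) {
  stopifnot(all(nascet >= 0), all(nascet < 1))
  1 - (1 - nascet)^2
}

#' Default inflow waveform
#'
#' Half-sine systolic pulse over `0.35 T` followed by zero diastolic flow,
#' normalised (trapezoidally, 200 intervals) so that the integral over one
#' period equals the stroke volume exactly.
#'
#' @param T_period cardiac period (s), positive.
#' @param stroke_volume ejected volume per beat (ml), positive.
#' @param n_samples number of table intervals.
#' @return data frame with `t` (s) and `Q` (ml/s) spanning `[0, T]`.
#' @export
default_inflow_waveform <- function(T_period = 1, stroke_volume = 12,
                                    n_samples = 200) {
  if (T_period <= 0) stop("period must be positive")
  if (stroke_volume <= 0) stop("stroke volume must be positive")
  t <- seq(0, T_period, length.out = n_samples + 1)
  ts <- 0.35 * T_period
  Q <- ifelse(t < ts, sin(pi * t / ts), 0)
  Q <- Q * stroke_volume / pracma::trapz(t, Q)
  data.frame(t = t, Q = Q)
}

#' Toy looped (Circle-of-Willis-like) network
#'
#' A planar looped network standing in for the cerebral collateral circle:
#' one root feeds left and right inlet branches; each inlet junction carries a
#' lateral terminal branch and a narrow communicating segment; the two
#' communicating segments meet at an anterior junction that feeds two distal
#' terminal branches.  The single loop lets a severe stenosis on the left
#' inlet branch drive compensatory (reversed) flow through the left
#' communicating segment, and its removal restores the symmetric
#' distribution.  All geometry and parameters are fixed constants chosen for
#' solver robustness; they are not patient values.
#'
#' Segment indices: 1 root, 2 left inlet, 3 right inlet, 4 left lateral
#' terminal branch, 5 right lateral terminal branch, 6 left communicating,
#' 7 right communicating, 8/9 anterior terminal branches.
#'
#' Severity presets: `"CS"` (70% NASCET, area severity 0.91) and `"VRCA"`
#' (area severity 0.9).
#'
#' @param severity area severity of the left-inlet stenosis in `[0, 1)`;
#'   0 builds the healthy network.
#' @param preset `"CS"` or `"VRCA"` overrides `severity`.
#' @param nascet interpret `severity` as a NASCET diameter ratio and convert
#'   to area severity.
#' @param dl centerline grid width (mm).
#' @return list with `network` (a `vascular_network`) and `config` (a
#'   [sim_config()]), plus bookkeeping ids: `left_com = 6`, `right_com = 7`,
#'   `left_inlet = 2`, `right_inlet = 3`.
#' @export
make_toy_cow <- function(severity = 0, preset = NULL, nascet = FALSE, dl = 2) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("CS", "VRCA"))
    severity <- switch(preset, CS = severity_from_nascet(0.7), VRCA = 0.9)
  } else if (nascet) severity <- severity_from_nascet(severity)
  if (severity < 0 || severity >= 1) stop("severity must be in [0, 1)")

  J0 <- c(0, 0, 0); JL <- c(-25, 30, 0); JR <- c(25, 30, 0); JA <- c(0, 55, 0)
  segs <- list(
    straight_segment(c(0, -30, 0), J0, radius = 4.0, dl = dl, index = 1),
    straight_segment(J0, JL, radius = 3.0, dl = dl, index = 2),
    straight_segment(J0, JR, radius = 3.0, dl = dl, index = 3),
    straight_segment(JL, c(-55, 30, 0), radius = 2.5, dl = dl, index = 4),
    straight_segment(JR, c(55, 30, 0), radius = 2.5, dl = dl, index = 5),
    straight_segment(JL, JA, radius = 1.0, dl = dl, index = 6),
    straight_segment(JR, JA, radius = 1.0, dl = dl, index = 7),
    straight_segment(JA, c(-12, 75, 0), radius = 2.0, dl = dl, index = 8),
    straight_segment(JA, c(12, 75, 0), radius = 2.0, dl = dl, index = 9))

  att <- function(seg, end) list(segment = seg, end = end)
  junctions <- list(
    list(att(1, "end"), att(2, "start"), att(3, "start")),   # J0
    list(att(2, "end"), att(4, "start"), att(6, "start")),   # JL
    list(att(3, "end"), att(5, "start"), att(7, "start")),   # JR
    list(att(6, "end"), att(7, "end"), att(8, "start"), att(9, "start")))  # JA

  # terminal RCR parameters: mean inflow 12 ml/s shared 5/5/1/1 between the
  # lateral (4, 5) and anterior (8, 9) beds at ~90 mmHg mean, 5 mmHg venous
  P_mean <- mmHg_to_Pa(90); P_out <- mmHg_to_Pa(5)
  term <- function(seg, Q_ml, r_feed_mm) {
    Rtot <- (P_mean - P_out) / ml_to_m3(Q_ml)
    c0 <- sqrt(4e5 * 0.1 / (2 * 1060 * (1 - 0.5^2)))  # wall defaults below
    R1 <- 1060 * c0 / mm2_to_m2(pi * r_feed_mm^2)
    R1 <- min(R1, 0.2 * Rtot)
    R2 <- Rtot - R1
    list(segment = seg, end = "end", R1 = R1, R2 = R2, C = 0.6 / R2,
         Pout = P_out)
  }
  terminals <- list(term(4, 5, 2.5), term(5, 5, 2.5),
                    term(8, 1, 2.0), term(9, 1, 2.0))

  stenoses <- if (severity > 0)
    list(list(segment = 2, position_mm = segment_arclength(segs[[2]]) / 2,
              severity = severity, length_mm = 10))
  else list()

  network <- assemble_network(
    segs, junctions = junctions, inlet = att(1, "start"),
    terminals = terminals, stenoses = stenoses,
    wall = list(E = 4e5, h0_ratio = 0.1, sigma = 0.5, P0 = mmHg_to_Pa(85)))

  config <- sim_config(default_inflow_waveform(T_period = 1, stroke_volume = 12),
                       period = 1, fluid = fluid_props(),
                       solver = solver_config())
  list(network = network, config = config, severity = severity,
       left_inlet = 2L, right_inlet = 3L, left_com = 6L, right_com = 7L)
}
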