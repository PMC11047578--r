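#' Cross-sectional mean velocity
#'
#' `V = Q / A`.  With `Q` in ml/s and `A` in mm^2 the result is directly in
#' m/s (1 ml/s / 1 mm^2 = 1 m/s).
#'
#' @param Q flow rate (ml/s).
#' @param A area (mm^2), positive.
#' @return mean velocity (m/s).
#' @export
mean_velocity <- function(Q, A) {
  if (any(A <= 0)) stop("non-positive area")
  Q / A
}

#' Poiseuille velocity profile
#'
#' `U(r) = 2 V (1 - r^2/R^2)` for a cylindrical cross-section (laminar,
#' axisymmetric Hagen-Poiseuille flow).
#'
#' @param V mean velocity (m/s).
#' @param R vessel radius (mm).
#' @param r radial offset(s) from the centerline (mm), `0 <= r <= R`.
#' @return velocity at offset `r` (m/s).
#' @export
velocity_profile <- function(V, R, r) {
  if (any(r < 0) || any(r > R)) stop("require 0 <= r <= R")
  2 * V * (1 - r^2 / R^2)
}

#' Wall shear stress (Poiseuille)
#'
#' `tau_w = 4 mu V / R`, the wall value of the Poiseuille profile gradient.
#' The sign of `tau_w` follows the sign of `V`.
#'
#' @param V mean velocity (m/s).
#' @param R vessel radius (mm), positive.
#' @param mu dynamic viscosity (Pa s).
#' @return wall shear stress (Pa).
#' @export
wss <- function(V, R, mu = 0.004) {
  if (any(R <= 0)) stop("non-positive radius")
  4 * mu * V / mm_to_m(R)
}

#' Time-averaged wall shear stress
#'
#' `TAWSS = (1/T) int |tau_w| dt` over exactly one period (trapezoidal).
#' The magnitude convention (nonnegative TAWSS) is the default; set
#' `signed = TRUE` for the signed mean.
#'
#' @param tau wall shear stress samples: vector, or a time-by-node matrix.
#' @param times sample times spanning exactly one period (s).
#' @param period the period T (s).
#' @param signed average the signed stress instead of its magnitude.
#' @return TAWSS (Pa); one value per column when `tau` is a matrix.
#' @export
tawss <- function(tau, times, period = diff(range(times)), signed = FALSE) {
  if (diff(range(times)) < period * (1 - 1e-6))
    stop("series spans less than one period")
  f <- function(y) pracma::trapz(times, if (signed) y else abs(y)) / period
  if (is.matrix(tau)) apply(tau, 2, f) else f(tau)
}

#' Derive velocity and wall shear stress fields from a solution
#'
#' For every segment and node: mean velocity `V = Q/A` (m/s), instantaneous
#' radius `R = sqrt(A/pi)` (mm; set `use_reference_radius = TRUE` to use the
#' segment reference radius instead), wall shear stress `tau_w = 4 mu V / R`
#' (Pa) and nodewise TAWSS over the converged cycle.
#'
#' @param solution a `solution_field` from [simulate_network()].
#' @param mu dynamic viscosity (Pa s); defaults to the solution's fluid.
#' @param use_reference_radius use `r0` instead of the instantaneous radius.
#' @return object of class `wss_field`: named list per segment with `s`, `V`,
#'   `R`, `tau` (time-by-node) and `tawss` (per node), plus `segment_tawss`
#'   (spatial mean per segment).
#' @export
solution_wss <- function(solution, mu = NULL,
                         use_reference_radius = FALSE) {
  stopifnot(inherits(solution, "solution_field"))
  if (is.null(mu)) mu <- solution$fluid$mu
  out <- lapply(solution$segments, function(sg) {
    V <- mean_velocity(sg$Q, sg$A)
    R <- if (use_reference_radius)
      matrix(sg$wall$r0, nrow(sg$A), ncol(sg$A))
    else sqrt(sg$A / pi)
    tau <- wss(V, R, mu)
    list(s = sg$s, V = V, R = R, tau = tau,
         tawss = tawss(tau, solution$times, solution$period))
  })
  seg_tawss <- vapply(out, function(w) mean(w$tawss), numeric(1))
  structure(list(segments = out, segment_tawss = seg_tawss,
                 times = solution$times, period = solution$period),
            class = "wss_field")
}

#' Map solver fields onto centerline coordinates
#'
#' Interpolates the solver's `Delta-s` grid values linearly in arc length to
#' the points of a centerline segment (`Delta-l` grid), producing the 3D
#' fields `A(x,y,z,t)`, `P(x,y,z,t)`, `Q(x,y,z,t)` plus derived `V` and
#' `tau_w`.  Endpoints map exactly; the solver tube length and centerline
#' length must agree within 5% (arc positions are scaled affinely between the
#' two parameterizations).
#'
#' @param solution a `solution_field`.
#' @param segment a [centerline_segment()] with the same arterial index.
#' @param mu viscosity for the shear-stress channel (Pa s).
#' @return object of class `mapped_field`: `points` (x, y, z, r), `times`,
#'   and time-by-point matrices `A`, `P`, `Q`, `V`, `tau`.
#' @export
map_solution_to_centerline <- function(solution, segment, mu = NULL) {
  stopifnot(inherits(solution, "solution_field"),
            inherits(segment, "centerline_segment"))
  if (is.null(mu)) mu <- solution$fluid$mu
  id <- as.character(segment$index)
  if (!(id %in% names(solution$segments)))
    stop("solution has no segment with arterial index ", segment$index)
  sg <- solution$segments[[id]]
  L_sol <- max(sg$s)
  arc <- segment_arcpos(segment)
  L_ctr <- max(arc)
  if (abs(L_sol - L_ctr) / L_ctr > 0.05)
    stop(sprintf("arc-length mismatch: solver %.3g mm vs centerline %.3g mm (> 5%%)",
                 L_sol, L_ctr))
  s_scaled <- sg$s * (L_ctr / L_sol)
  interp_rows <- function(M) {
    t(apply(M, 1, function(row) stats::approx(s_scaled, row, xout = arc,
                                              rule = 2)$y))
  }
  A <- interp_rows(sg$A); P <- interp_rows(sg$P); Q <- interp_rows(sg$Q)
  V <- mean_velocity(Q, A)
  tau <- wss(V, sqrt(A / pi), mu)
  structure(list(points = segment$points, times = solution$times,
                 A = A, P = P, Q = Q, V = V, tau = tau,
                 index = segment$index), class = "mapped_field")
}

#' Mapped field as a long data frame
#'
#' @param x a `mapped_field`.
#' @param ... unused.
#' @return data frame with columns `point`, `x`, `y`, `z`, `t`, `A`, `P`
#'   (mmHg), `Q`, `V`, `tau_w`.
#' @export
as.data.frame.mapped_field <- function(x, ...) {
  np <- nrow(x$points); nt <- length(x$times)
  data.frame(
    point = rep(seq_len(np), times = nt),
    x = rep(x$points$x, nt), y = rep(x$points$y, nt), z = rep(x$points$z, nt),
    t = rep(x$times, each = np),
    A = as.vector(t(x$A)), P = Pa_to_mmHg(as.vector(t(x$P))),
    Q = as.vector(t(x$Q)), V = as.vector(t(x$V)),
    tau_w = as.vector(t(x$tau)))
}
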