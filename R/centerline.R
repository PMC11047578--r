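#' Penalized quintic-spline smoothing of a centerline segment
#'
#' Fits, for each coordinate and for the radius, a degree-5 (order-6) B-spline
#' penalized least-squares smoother in a chord-length parameter, with the
#' roughness penalty `lambda3 * int (f''')^2 + lambda4 * int (f'''')^2`.
#' The penalty weights are selected from `lambda_grid` by minimising the
#' penalized-regression AIC
#' `sum_coords [ n log(RSS/n) + 2 edf ]`, where `edf` is the trace of the
#' smoother matrix.  By default the grid is searched on the diagonal
#' `lambda3 = lambda4`; set `full_grid = TRUE` for the full 2D search.
#' Interior knots are placed at every `knot_every`-th data site.
#'
#' This restores smooth vessel geometry from voxelized centerlines whose
#' quantization noise would otherwise corrupt local radius and curvature
#' estimates.
#'
#' @param nodes data frame with ordered columns `x`, `y`, `z` (mm) and
#'   optionally `r` (mm); at least 7 rows.
#' @param lambda_grid positive penalty values (default `10^seq(-4, 2)` with
#'   13 points).
#' @param full_grid search all `(lambda3, lambda4)` pairs instead of the
#'   diagonal.
#' @param knot_every interior-knot spacing in data points.
#' @return an object of class `smooth_curve` with elements `knots`, `coef`
#'   (basis x channels), `lambda3`, `lambda4`, `aic`, `edf`, `u` (chord
#'   parameters of the data) and `aic_table`.
#' @export
fit_spline_sfm <- function(nodes, lambda_grid = 10^seq(-4, 2, length.out = 13),
                           full_grid = FALSE, knot_every = 3) {
  nodes <- as.data.frame(nodes)
  stopifnot(all(c("x", "y", "z") %in% names(nodes)))
  has_r <- !is.null(nodes$r) && !all(is.na(nodes$r))
  chans <- if (has_r) c("x", "y", "z", "r") else c("x", "y", "z")
  n <- nrow(nodes)
  if (n < 7) stop("need at least 7 nodes for a degree-5 fit")
  if (any(lambda_grid <= 0)) stop("lambda_grid must be positive")

  P <- as.matrix(nodes[, c("x", "y", "z")])
  chord <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  if (any(diff(chord) <= 0)) stop("coincident consecutive nodes")
  u <- chord  # chord-length parameter in mm (penalties act per mm)
  L <- chord[n]

  ord <- 6L
  interior_idx <- seq(1 + knot_every, n - knot_every, by = knot_every)
  interior <- if (length(interior_idx)) u[interior_idx] else numeric(0)
  knots <- c(rep(0, ord), interior, rep(L, ord))

  B <- splines::splineDesign(knots, u, ord = ord)
  P3 <- penalty_matrix(knots, ord, 3L)
  P4 <- penalty_matrix(knots, ord, 4L)
  BtB <- crossprod(B)
  Y <- as.matrix(nodes[, chans])
  BtY <- crossprod(B, Y)

  pairs <- if (full_grid)
    expand.grid(l3 = lambda_grid, l4 = lambda_grid)
  else data.frame(l3 = lambda_grid, l4 = lambda_grid)

  eval_pair <- function(l3, l4) {
    M <- BtB + l3 * P3 + l4 * P4
    Mi <- tryCatch(solve(M), error = function(e)
      stop(sprintf("singular fit at lambda3 = %g, lambda4 = %g", l3, l4)))
    coef <- Mi %*% BtY
    fit <- B %*% coef
    rss <- colSums((Y - fit)^2)
    edf <- sum(diag(Mi %*% BtB))
    aic <- sum(n * log(pmax(rss, n * 1e-24) / n) + 2 * edf)
    list(coef = coef, aic = aic, edf = edf, rss = rss)
  }

  fits <- Map(eval_pair, pairs$l3, pairs$l4)
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- which.min(aics)
  f <- fits[[best]]

  structure(list(
    knots = knots, ord = ord, coef = f$coef, channels = chans,
    lambda3 = pairs$l3[best], lambda4 = pairs$l4[best],
    aic = f$aic, edf = f$edf, rss = f$rss, u = u, chord_length = L,
    aic_table = cbind(pairs, aic = aics)), class = "smooth_curve")
}

# integral penalty matrix int B^(d)(u) B^(d)(u)' du by Gauss-Legendre
# quadrature on each inter-knot span (exact: integrand is piecewise
# polynomial of degree <= 2*(5-d) <= 4)
penalty_matrix <- function(knots, ord, deriv) {
  uk <- unique(knots)
  nb <- length(knots) - ord
  P <- matrix(0, nb, nb)
  for (i in seq_len(length(uk) - 1)) {
    gl <- pracma::gaussLegendre(5, uk[i], uk[i + 1])
    Bd <- splines::splineDesign(knots, gl$x, ord = ord,
                                derivs = rep(deriv, length(gl$x)))
    P <- P + crossprod(Bd * sqrt(gl$w))
  }
  (P + t(P)) / 2
}

#' Evaluate a smooth curve (or its derivatives)
#'
#' @param curve a `smooth_curve` from [fit_spline_sfm()].
#' @param u chord-length parameter values in `[0, chord_length]` (mm).
#' @param deriv derivative order (0-4) with respect to the chord parameter.
#' @return matrix with one column per fitted channel (x, y, z, and r when
#'   fitted).
#' @export
curve_eval <- function(curve, u, deriv = 0) {
  stopifnot(inherits(curve, "smooth_curve"))
  u <- pmin(pmax(u, 0), curve$chord_length)
  B <- splines::splineDesign(curve$knots, u, ord = curve$ord,
                             derivs = rep(as.integer(deriv), length(u)))
  out <- B %*% curve$coef
  colnames(out) <- curve$channels
  out
}

#' Curvature of a smooth curve
#'
#' Geometric curvature `|C' x C''| / |C'|^3` (1/mm), invariant to the
#' parameterization.
#'
#' @inheritParams curve_eval
#' @return numeric vector of curvatures.
#' @export
curve_curvature <- function(curve, u) {
  d1 <- curve_eval(curve, u, 1)[, c("x", "y", "z"), drop = FALSE]
  d2 <- curve_eval(curve, u, 2)[, c("x", "y", "z"), drop = FALSE]
  cr <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
              d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
              d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  sqrt(rowSums(cr^2)) / pmax(sqrt(rowSums(d1^2))^3, .Machine$double.eps)
}

#' Discrete curvature of a polyline
#'
#' Three-point (circumscribed-circle) curvature estimate at interior vertices;
#' the first and last vertex get `NA`.  Used as the raw baseline against
#' which spline smoothing is judged.
#'
#' @param points matrix or data frame with columns `x`, `y`, `z` (mm).
#' @return numeric vector (1/mm) of length `nrow(points)`.
#' @export
polyline_curvature <- function(points) {
  P <- as.matrix(as.data.frame(points)[, c("x", "y", "z")])
  n <- nrow(P)
  kap <- rep(NA_real_, n)
  for (i in seq_len(n - 2) + 1) {
    a <- P[i - 1, ]; b <- P[i, ]; c <- P[i + 1, ]
    ab <- b - a; ac <- c - a; bc <- c - b
    cross <- c(ab[2] * ac[3] - ab[3] * ac[2],
               ab[3] * ac[1] - ab[1] * ac[3],
               ab[1] * ac[2] - ab[2] * ac[1])
    area2 <- sqrt(sum(cross^2))  # twice the triangle area
    denom <- sqrt(sum(ab^2)) * sqrt(sum(ac^2)) * sqrt(sum(bc^2))
    kap[i] <- if (denom > 0) 2 * area2 / denom else 0
  }
  kap
}

#' Arc length of a smooth curve
#'
#' Adaptive quadrature of the parametric speed with relative tolerance 1e-6.
#'
#' @param curve a `smooth_curve`.
#' @param u0,u1 parameter bounds.
#' @return arc length in mm.
#' @export
curve_length <- function(curve, u0 = 0, u1 = NULL) {
  if (is.null(u1)) u1 <- curve$chord_length
  speed <- function(uu) {
    d1 <- curve_eval(curve, uu, 1)[, c("x", "y", "z"), drop = FALSE]
    sqrt(rowSums(d1^2))
  }
  stats::integrate(speed, u0, u1, rel.tol = 1e-6, subdivisions = 500L)$value
}

#' Resample a smooth curve on a fixed arc-length grid
#'
#' Places points at arc lengths `0, dl, 2 dl, ...` and always includes the
#' final endpoint; radii are evaluated from the radius spline.  The default
#' grid width is 2 mm.
#'
#' @param curve a `smooth_curve` (fitted with a radius channel, or supply
#'   `radius` to use a constant).
#' @param dl grid width Delta-l in mm (default 2).
#' @param index arterial index to attach to the segment.
#' @param radius constant radius fallback (mm) when the curve has no `r`
#'   channel.
#' @return a `centerline_segment`: list with `points` (data frame x, y, z, r),
#'   `dl`, `index`, `length`.
#' @export
resample_curve <- function(curve, dl = 2, index = 1L, radius = NULL) {
  stopifnot(inherits(curve, "smooth_curve"))
  if (dl <= 0) stop("dl must be positive")
  L <- curve_length(curve)
  if (L <= 0) stop("curve has zero length")
  s_targets <- seq(0, L, by = dl)
  if (utils::tail(s_targets, 1) < L - 1e-9 * L) s_targets <- c(s_targets, L)
  if (dl >= L) {
    warning("dl >= curve length: returning a 2-point segment")
    s_targets <- c(0, L)
  }
  u <- vapply(s_targets, function(s) {
    if (s <= 0) return(0)
    if (s >= L) return(curve$chord_length)
    stats::uniroot(function(uu) curve_length(curve, 0, uu) - s,
                   lower = 0, upper = curve$chord_length, tol = 1e-10)$root
  }, numeric(1))
  XYZ <- curve_eval(curve, u)
  r <- if ("r" %in% curve$channels) XYZ[, "r"] else {
    if (is.null(radius)) stop("curve has no radius channel; supply `radius`")
    rep(radius, length(u))
  }
  points <- data.frame(x = XYZ[, "x"], y = XYZ[, "y"], z = XYZ[, "z"], r = r)
  if (any(points$r <= 0)) stop("non-positive radius after resampling")
  centerline_segment(points, dl = dl, index = index)
}

#' Centerline segment container
#'
#' An ordered polyline with radii on an approximately uniform arc-length grid.
#'
#' @param points data frame with columns `x`, `y`, `z`, `r` (mm), >= 2 rows.
#' @param dl nominal grid width (mm).
#' @param index integer arterial index.
#' @return object of class `centerline_segment`.
#' @export
centerline_segment <- function(points, dl, index = 1L) {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y", "z", "r") %in% names(points)), nrow(points) >= 2)
  if (any(points$r <= 0)) stop("radii must be positive")
  structure(list(points = points[, c("x", "y", "z", "r")], dl = dl,
                 index = as.integer(index)),
            class = "centerline_segment")
}

#' @export
print.centerline_segment <- function(x, ...) {
  cat("centerline_segment #", x$index, ": ", nrow(x$points), " points, dl = ",
      x$dl, " mm, length ", signif(segment_arclength(x), 5), " mm\n", sep = "")
  invisible(x)
}

#' Arc length of a centerline segment (sum of chords, mm)
#' @param segment a `centerline_segment`.
#' @return numeric length in mm.
#' @export
segment_arclength <- function(segment) {
  P <- as.matrix(segment$points[, c("x", "y", "z")])
  sum(sqrt(rowSums(diff(P)^2)))
}

# cumulative arc positions of the segment points (mm)
segment_arcpos <- function(segment) {
  P <- as.matrix(segment$points[, c("x", "y", "z")])
  c(0, cumsum(sqrt(rowSums(diff(P)^2))))
}

#' Build a centerline segment from a straight line
#'
#' Convenience constructor used by fixtures and examples.
#'
#' @param from,to endpoints (mm).
#' @param radius vessel radius (mm), recycled or interpolated linearly.
#' @param dl grid width (mm).
#' @param index arterial index.
#' @return a `centerline_segment`.
#' @export
straight_segment <- function(from, to, radius, dl = 2, index = 1L) {
  L <- sqrt(sum((to - from)^2))
  s <- seq(0, L, by = dl)
  if (utils::tail(s, 1) < L - 1e-9) s <- c(s, L)
  tpar <- s / L
  r <- if (length(radius) == 2) radius[1] + tpar * (radius[2] - radius[1])
  else rep(radius[1], length(tpar))
  pts <- data.frame(x = from[1] + tpar * (to[1] - from[1]),
                    y = from[2] + tpar * (to[2] - from[2]),
                    z = from[3] + tpar * (to[3] - from[3]), r = r)
  centerline_segment(pts, dl = dl, index = index)
}

#' Smooth and resample a labelled skeleton into centerline segments
#'
#' Applies [fit_spline_sfm()] and [resample_curve()] to every labelled path of
#' a split skeleton.  Paths shorter than 7 nodes are resampled linearly
#' without smoothing.
#'
#' @param sk a split skeleton with radii (see [skeleton_from_volume()]).
#' @param dl resampling grid width (mm).
#' @param ... passed to [fit_spline_sfm()].
#' @return list of `centerline_segment`s (named by arterial index).
#' @export
smooth_skeleton <- function(sk, dl = 2, ...) {
  stopifnot(inherits(sk, "skeleton"), !is.null(sk$segments))
  out <- lapply(seq_along(sk$segments), function(i) {
    p <- sk$segments[[i]]
    nodes <- sk$nodes[p, c("x", "y", "z", "r")]
    idx <- as.integer(names(sk$segments)[i])
    if (length(p) >= 7) {
      cv <- fit_spline_sfm(nodes, ...)
      resample_curve(cv, dl = dl, index = idx)
    } else {
      P <- as.matrix(nodes[, c("x", "y", "z")])
      arc <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
      s <- unique(c(seq(0, max(arc), by = dl), max(arc)))
      pts <- data.frame(
        x = stats::approx(arc, nodes$x, s)$y,
        y = stats::approx(arc, nodes$y, s)$y,
        z = stats::approx(arc, nodes$z, s)$y,
        r = stats::approx(arc, nodes$r, s)$y)
      centerline_segment(pts, dl = dl, index = idx)
    }
  })
  names(out) <- names(sk$segments)
  out
}
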