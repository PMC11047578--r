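#' Rotation-minimizing frames along a centerline segment
#'
#' Computes unit tangents by central differences (one-sided at the ends) and
#' propagates a pair of unit normals `(nx, ny)` by rotation-minimizing
#' parallel transport (the double-reflection method), so that
#' `(nx, ny, dir)` is a right-handed orthonormal triad at every point with no
#' spurious twist.
#'
#' @param segment a [centerline_segment()] (or a matrix/data frame of points
#'   with columns x, y, z), at least 2 points.
#' @return object of class `frame_field`: matrices `dir`, `nx`, `ny`
#'   (n x 3).
#' @export
transport_frames <- function(segment) {
  P <- if (inherits(segment, "centerline_segment"))
    as.matrix(segment$points[, c("x", "y", "z")])
  else as.matrix(as.data.frame(segment)[, c("x", "y", "z")])
  n <- nrow(P)
  if (n < 2) stop("need at least 2 points")
  d <- diff(P)
  if (any(rowSums(d^2) == 0))
    stop("coincident consecutive points at index ",
         which(rowSums(d^2) == 0)[1])

  normalize <- function(v) v / sqrt(sum(v^2))
  dir <- matrix(0, n, 3)
  dir[1, ] <- normalize(P[2, ] - P[1, ])
  dir[n, ] <- normalize(P[n, ] - P[n - 1, ])
  if (n > 2)
    for (i in 2:(n - 1)) dir[i, ] <- normalize(P[i + 1, ] - P[i - 1, ])

  # initial normal: any unit vector perpendicular to the first tangent
  seed <- c(1, 0, 0)
  if (abs(sum(seed * dir[1, ])) > 0.9) seed <- c(0, 1, 0)
  nx <- matrix(0, n, 3)
  ny <- matrix(0, n, 3)
  nx[1, ] <- normalize(seed - sum(seed * dir[1, ]) * dir[1, ])
  ny[1, ] <- cross3(dir[1, ], nx[1, ])

  # double-reflection rotation-minimizing transport
  for (i in seq_len(n - 1)) {
    v1 <- P[i + 1, ] - P[i, ]
    c1 <- sum(v1 * v1)
    rL <- nx[i, ] - (2 / c1) * sum(v1 * nx[i, ]) * v1
    tL <- dir[i, ] - (2 / c1) * sum(v1 * dir[i, ]) * v1
    v2 <- dir[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    nx[i + 1, ] <- if (c2 > 1e-300) rL - (2 / c2) * sum(v2 * rL) * v2 else rL
    nx[i + 1, ] <- normalize(nx[i + 1, ] -
                               sum(nx[i + 1, ] * dir[i + 1, ]) * dir[i + 1, ])
    ny[i + 1, ] <- cross3(dir[i + 1, ], nx[i + 1, ])
  }
  structure(list(dir = dir, nx = nx, ny = ny), class = "frame_field")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Ring vertices of a circular cross-section
#'
#' Places `k` vertices on the circle of area `A` centred at `p` in the plane
#' spanned by the frame normals:
#' `Q_l = p + sqrt(A/pi) * (nx cos(2 pi l / k) + ny sin(2 pi l / k))` for
#' `l = 0..k-1`.
#'
#' @param p centre point (length-3, mm).
#' @param nx,ny unit normals of the cross-sectional plane.
#' @param A cross-sectional area (mm^2), positive.
#' @param k circumferential resolution, >= 3.
#' @return k x 3 matrix of vertices.
#' @export
ring_vertices <- function(p, nx, ny, A, k = 16) {
  if (k < 3) stop("k must be >= 3")
  if (A <= 0) stop("non-positive area")
  r <- sqrt(A / pi)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  outer(rep(1, k), p) + r * (outer(cos(ang), nx) + outer(sin(ang), ny))
}

#' Triangulate a tube from vertex rings
#'
#' Connects consecutive rings of equal resolution `k` into a watertight band
#' of `2k` triangles each: every vertex pairs with the Euclidean-nearest
#' vertex of the adjacent ring (ties resolved to the lower index), with
#' wraparound at `l = k-1`.  If the nearest-vertex pairing is not a constant
#' circular offset (twist beyond half a slot), a warning is issued and the
#' constant-offset pairing derived from vertex 0 is used.  Faces are wound
#' consistently outward.
#'
#' @param rings list of k x 3 vertex matrices (>= 2 rings, equal k).
#' @param centers optional matrix of ring centre points (used for outward
#'   orientation; defaults to ring centroids).
#' @return object of class `tube_mesh`: `vertices` (kN x 3), `faces`
#'   (2k(N-1) x 3, 1-based), `ring_index` (data frame point/slot per vertex),
#'   `k`, `n_rings`.
#' @export
triangulate_tube <- function(rings, centers = NULL) {
  N <- length(rings)
  if (N < 2) stop("need at least 2 rings")
  k <- nrow(rings[[1]])
  if (any(vapply(rings, nrow, integer(1)) != k))
    stop("rings of unequal resolution")
  if (is.null(centers))
    centers <- t(vapply(rings, colMeans, numeric(3)))

  vertices <- do.call(rbind, rings)
  vid <- function(i, l) (i - 1) * k + (l %% k) + 1  # ring i (1-based), slot l (0-based)

  faces <- matrix(0L, 2 * k * (N - 1), 3)
  fi <- 0L
  for (i in seq_len(N - 1)) {
    A <- rings[[i]]; B <- rings[[i + 1]]
    # nearest vertex in ring i+1 for each vertex of ring i
    nearest <- vapply(seq_len(k), function(l) {
      dd <- rowSums(sweep(B, 2, A[l, ])^2)
      which.min(dd)  # first minimum = lower index tie-break
    }, integer(1))
    off <- (nearest[1] - 1) %% k
    consistent <- all((nearest - 1L) == (off + seq_len(k) - 1L) %% k)
    if (!consistent) {
      warning(sprintf("ring %d: nearest-vertex pairing non-monotonic; using constant offset %d",
                      i, off))
    }
    for (l in 0:(k - 1)) {
      v1 <- vid(i, l); v2 <- vid(i, l + 1)
      w1 <- vid(i + 1, l + off); w2 <- vid(i + 1, l + 1 + off)
      faces[fi + 1L, ] <- c(v1, w1, w2)
      faces[fi + 2L, ] <- c(v1, w2, v2)
      fi <- fi + 2L
    }
  }

  # consistent outward winding: check against outward directions
  ctr_of_vertex <- centers[rep(seq_len(N), each = k), , drop = FALSE]
  fc <- (vertices[faces[, 1], ] + vertices[faces[, 2], ] + vertices[faces[, 3], ]) / 3
  e1 <- vertices[faces[, 2], ] - vertices[faces[, 1], ]
  e2 <- vertices[faces[, 3], ] - vertices[faces[, 1], ]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  outward <- fc - ctr_of_vertex[faces[, 1], ]
  if (median(rowSums(nrm * outward)) < 0) faces[, 2:3] <- faces[, 3:2]

  structure(list(
    vertices = vertices, faces = faces,
    ring_index = data.frame(point = rep(seq_len(N), each = k),
                            slot = rep(0:(k - 1), N)),
    k = k, n_rings = N, scalars = list()), class = "tube_mesh")
}

#' @export
print.tube_mesh <- function(x, ...) {
  cat("tube_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces (k =", x$k, ",", x$n_rings, "rings)\n")
  invisible(x)
}

#' Edge census of a triangle mesh
#'
#' @param mesh a `tube_mesh`.
#' @return data frame of unique edges with their incident-face counts.
#' @export
mesh_edge_census <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  data.frame(edge = names(tab), count = as.integer(tab), row.names = NULL)
}

#' Build the lumen mesh of one segment at one instant
#'
#' @param segment a [centerline_segment()].
#' @param A areas at the segment points (mm^2); defaults to `pi r^2` from the
#'   point radii.
#' @param k circumferential resolution.
#' @param frames optional precomputed [transport_frames()] result.
#' @return a `tube_mesh`.
#' @export
segment_mesh <- function(segment, A = NULL, k = 16, frames = NULL) {
  P <- as.matrix(segment$points[, c("x", "y", "z")])
  if (is.null(A)) A <- pi * segment$points$r^2
  if (is.null(frames)) frames <- transport_frames(segment)
  rings <- lapply(seq_len(nrow(P)), function(i)
    ring_vertices(P[i, ], frames$nx[i, ], frames$ny[i, ], A[i], k))
  triangulate_tube(rings, centers = P)
}

#' Bake a time-varying scalar field onto a dynamic lumen mesh
#'
#' For every output time, ring radii are recomputed from the instantaneous
#' area `A(s, t)` (ring radius `sqrt(A(s,t)/pi)`)
#' and each ring's vertices carry the mapped scalar of their centerline point
#' at that time.  Connectivity is built once from the reference geometry and
#' shared by all frames.
#'
#' @param segment a [centerline_segment()].
#' @param mapped a [map_solution_to_centerline()] result for the segment.
#' @param field scalar channel to bake: one of `"A"`, `"P"`, `"Q"`, `"V"`,
#'   `"tau"`.
#' @param k circumferential resolution.
#' @param frame_times times at which to emit frames (default: all mapped
#'   times).
#' @param dynamic_radius recompute radii from `A(s,t)` per frame (default);
#'   `FALSE` keeps the static reference lumen.
#' @return object of class `dynamic_mesh`: shared `faces`, `ring_index`,
#'   `k`, and per-frame `vertices` + `scalars`, plus the color-range metadata
#'   `range` and `field`.
#' @export
bake_scalar_series <- function(segment, mapped, field = "Q", k = 16,
                               frame_times = NULL, dynamic_radius = TRUE) {
  stopifnot(inherits(mapped, "mapped_field"))
  if (!(field %in% c("A", "P", "Q", "V", "tau")))
    stop("unknown field ", field)
  vals <- mapped[[field]]
  if (is.null(vals)) stop("mapped field has no channel ", field)
  times <- mapped$times
  if (is.null(frame_times)) frame_times <- times
  ti <- vapply(frame_times, function(tt) which.min(abs(times - tt)), integer(1))

  frames <- transport_frames(segment)
  ref <- segment_mesh(segment, k = k, frames = frames)
  P <- as.matrix(segment$points[, c("x", "y", "z")])

  frames_out <- lapply(ti, function(row) {
    A_t <- if (dynamic_radius) mapped$A[row, ] else pi * segment$points$r^2
    rings <- lapply(seq_len(nrow(P)), function(i)
      ring_vertices(P[i, ], frames$nx[i, ], frames$ny[i, ], A_t[i], k))
    list(vertices = do.call(rbind, rings),
         scalars = rep(vals[row, ], each = k),
         time = times[row])
  })
  structure(list(
    faces = ref$faces, ring_index = ref$ring_index, k = k,
    n_rings = nrow(P), frames = frames_out, field = field,
    range = range(vals[ti, ]), colormap = "viridis"),
    class = "dynamic_mesh")
}

fmt_num <- function(x) formatC(x, format = "g", digits = 9)

#' Export a mesh as legacy VTK PolyData (ASCII)
#'
#' @param mesh a `tube_mesh`, or a list with `vertices`, `faces` and optional
#'   `scalars` (numeric per-vertex) plus `scalar_name`.
#' @param path output `.vtk` file.
#' @param scalars optional per-vertex scalar vector.
#' @param scalar_name name of the scalar array.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, scalars = NULL, scalar_name = "value") {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vasculate lumen mesh", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  writeLines(apply(v, 1, function(p) paste(fmt_num(p), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
  writeLines(apply(f, 1, function(tr)
    paste(c(3, tr - 1), collapse = " ")), con)
  if (!is.null(scalars)) {
    writeLines(c(sprintf("POINT_DATA %d", nrow(v)),
                 sprintf("SCALARS %s float 1", scalar_name),
                 "LOOKUP_TABLE default"), con)
    writeLines(fmt_num(scalars), con)
  }
  invisible(path)
}

#' Export a mesh as ASCII PLY
#'
#' @inheritParams write_mesh_vtk
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, scalars = NULL, scalar_name = "value") {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z")
  if (!is.null(scalars)) hdr <- c(hdr, sprintf("property float %s", scalar_name))
  hdr <- c(hdr, sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vm <- if (is.null(scalars)) v else cbind(v, scalars)
  writeLines(apply(vm, 1, function(p) paste(fmt_num(p), collapse = " ")), con)
  writeLines(apply(f, 1, function(tr)
    paste(c(3, tr - 1), collapse = " ")), con)
  invisible(path)
}

#' Export a dynamic mesh as a frame series
#'
#' Writes `frame_####.vtk` (or `.ply`) per time sample, a ParaView-style
#' `series.pvd` collection index, and a JSON sidecar with the scalar name,
#' range and colormap.
#'
#' @param dyn a `dynamic_mesh` from [bake_scalar_series()].
#' @param dir output directory (created if needed).
#' @param format `"vtk"` or `"ply"`.
#' @return the directory, invisibly.
#' @export
write_dynamic_mesh <- function(dyn, dir, format = c("vtk", "ply")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writer <- if (format == "vtk") write_mesh_vtk else write_mesh_ply
  files <- character(length(dyn$frames))
  for (i in seq_along(dyn$frames)) {
    fr <- dyn$frames[[i]]
    files[i] <- sprintf("frame_%04d.%s", i - 1, format)
    writer(list(vertices = fr$vertices, faces = dyn$faces),
           file.path(dir, files[i]), scalars = fr$scalars,
           scalar_name = dyn$field)
  }
  pvd <- c('<?xml version="1.0"?>',
           '<VTKFile type="Collection" version="0.1" byte_order="LittleEndian">',
           "  <Collection>",
           sprintf('    <DataSet timestep="%s" group="" part="0" file="%s"/>',
                   fmt_num(vapply(dyn$frames, `[[`, numeric(1), "time")), files),
           "  </Collection>", "</VTKFile>")
  writeLines(pvd, file.path(dir, "series.pvd"))
  jsonlite::write_json(list(field = dyn$field, range = dyn$range,
                            colormap = dyn$colormap),
                       file.path(dir, "color_range.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
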