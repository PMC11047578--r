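#' Assemble a simulation-ready vascular network
#'
#' Validates and packages centerline segments with their junction topology,
#' inlet, 0D terminal models and stenosis elements.  Every segment end must be
#' attached to exactly one junction, the inlet, or a terminal; junctions need
#' at least two incident ends; the network graph must be connected.  Segment
#' endpoints declared to meet at a junction are snapped to their common
#' centroid when all lie within `1.5 * dl` of it, otherwise assembly fails.
#'
#' Attachment records are lists `list(segment = <arterial index>, end =
#' "start"|"end")`.
#'
#' @param segments list of [centerline_segment()]s with unique arterial
#'   indices.
#' @param junctions list of junctions, each a list of >= 2 attachment records.
#' @param inlet one attachment record.
#' @param terminals list of attachment records each extended with Windkessel
#'   parameters `R1`, `R2`, `C` (SI: Pa s/m^3, m^3/Pa) and `Pout` (Pa).
#' @param stenoses optional list of records `list(segment =, position_mm =,
#'   severity =, length_mm =, Kv = NULL, Kt = 1.52, Ku = 1.2)`; `severity` is
#'   the area severity `1 - As/A0`.
#' @param wall default wall model parameters: list with `E` (Pa), `h0_ratio`
#'   (wall thickness as a fraction of radius) or `h0` (mm), `sigma`, `P0`
#'   (Pa).  Per-segment overrides may be supplied via `segment_wall`.
#' @param segment_wall optional named list (by arterial index) of per-segment
#'   wall overrides.
#' @return an object of class `vascular_network`.
#' @export
assemble_network <- function(segments, junctions = list(), inlet, terminals,
                             stenoses = list(),
                             wall = list(E = 4e5, h0_ratio = 0.1, sigma = 0.5,
                                         P0 = mmHg_to_Pa(85)),
                             segment_wall = list()) {
  stopifnot(is.list(segments), length(segments) >= 1)
  for (s in segments) stopifnot(inherits(s, "centerline_segment"))
  ids <- vapply(segments, `[[`, integer(1), "index")
  if (anyDuplicated(ids)) stop("duplicate arterial indices in segments")
  names(segments) <- ids

  att_key <- function(a) paste0(a$segment, ":", a$end)
  check_att <- function(a, what) {
    if (!is.list(a) || is.null(a$segment) || is.null(a$end) ||
        !(a$end %in% c("start", "end")))
      stop(what, ": attachment must be list(segment=, end='start'|'end')")
    if (!(as.character(a$segment) %in% names(segments)))
      stop(what, ": unknown segment ", a$segment)
    a$segment <- as.integer(a$segment)
    a
  }

  inlet <- check_att(inlet, "inlet")
  terminals <- lapply(terminals, function(tm) {
    tm2 <- check_att(tm, "terminal")
    for (f in c("R1", "R2", "C", "Pout"))
      if (is.null(tm[[f]])) stop("terminal missing field ", f)
    list(segment = tm2$segment, end = tm2$end, R1 = tm$R1, R2 = tm$R2,
         C = tm$C, Pout = tm$Pout)
  })
  junctions <- lapply(junctions, function(j) lapply(j, check_att, "junction"))
  for (j in junctions)
    if (length(j) < 2) stop("junction must join at least two segment ends")

  # every end attached exactly once
  all_att <- c(list(inlet), terminals, unlist(junctions, recursive = FALSE))
  keys <- vapply(all_att, att_key, character(1))
  if (anyDuplicated(keys))
    stop("segment end attached more than once: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  want <- as.vector(outer(ids, c("start", "end"), paste, sep = ":"))
  missing <- setdiff(want, keys)
  if (length(missing))
    stop("dangling segment end(s): ", paste(missing, collapse = ", "))
  if (sum(vapply(list(inlet), function(a) 1L, integer(1))) != 1L)
    stop("exactly one inlet required")

  end_point <- function(a) {
    p <- segments[[as.character(a$segment)]]$points
    unlist(p[if (a$end == "start") 1 else nrow(p), c("x", "y", "z")])
  }

  # snap junction endpoints to their centroid
  for (ji in seq_along(junctions)) {
    pts <- t(vapply(junctions[[ji]], end_point, numeric(3)))
    ctr <- colMeans(pts)
    dl_max <- max(vapply(junctions[[ji]], function(a)
      segments[[as.character(a$segment)]]$dl, numeric(1)))
    dist <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
    if (any(dist > 1.5 * dl_max))
      stop(sprintf("junction %d: segment end(s) %s exceed the snap tolerance %.3g mm",
                   ji, paste(which(dist > 1.5 * dl_max), collapse = ", "),
                   1.5 * dl_max))
    for (a in junctions[[ji]]) {
      seg <- segments[[as.character(a$segment)]]
      row <- if (a$end == "start") 1 else nrow(seg$points)
      seg$points[row, c("x", "y", "z")] <- as.list(ctr)
      segments[[as.character(a$segment)]] <- seg
    }
  }

  # connectivity: contract segments to edges between attachment sites
  site_of <- function(a) {
    k <- att_key(a)
    for (ji in seq_along(junctions))
      for (b in junctions[[ji]]) if (att_key(b) == k) return(paste0("J", ji))
    if (att_key(inlet) == k) return("INLET")
    for (ti in seq_along(terminals))
      if (att_key(terminals[[ti]]) == k) return(paste0("T", ti))
    stop("unattached end ", k)
  }
  ends <- lapply(ids, function(i) list(
    start = site_of(list(segment = i, end = "start")),
    end = site_of(list(segment = i, end = "end"))))
  el <- do.call(rbind, lapply(ends, function(e) c(e$start, e$end)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::components(g)$no != 1) stop("network graph is disconnected")
  n_cycles <- igraph::ecount(g) - igraph::vcount(g) + 1

  stenoses <- lapply(stenoses, function(st) {
    if (is.null(st$segment) || !(as.character(st$segment) %in% names(segments)))
      stop("stenosis references unknown segment")
    seg <- segments[[as.character(st$segment)]]
    L <- segment_arclength(seg)
    if (is.null(st$position_mm)) st$position_mm <- L / 2
    if (st$position_mm <= 0 || st$position_mm >= L)
      stop("stenosis position outside segment")
    if (is.null(st$severity)) stop("stenosis needs `severity` (area severity)")
    if (st$severity < 0 || st$severity >= 1) stop("severity must be in [0, 1)")
    if (is.null(st$length_mm)) st$length_mm <- 10
    if (is.null(st$Kt)) st$Kt <- 1.52
    if (is.null(st$Ku)) st$Ku <- 1.2
    st$segment <- as.integer(st$segment)
    st
  })

  structure(list(segments = segments, junctions = junctions, inlet = inlet,
                 terminals = terminals, stenoses = stenoses, wall = wall,
                 segment_wall = segment_wall, n_cycles = n_cycles),
            class = "vascular_network")
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("vascular_network:", length(x$segments), "segments,",
      length(x$junctions), "junctions,", length(x$terminals), "terminals,",
      length(x$stenoses), "stenoses;", x$n_cycles, "independent cycle(s)\n")
  invisible(x)
}

#' Write / read a vascular network as JSON
#'
#' The file stores segments with full point lists (x, y, z, r), the junction
#' table, boundary attachments, stenosis elements and wall defaults; reading
#' re-validates through [assemble_network()], so the round trip reproduces the
#' structure exactly.
#'
#' @param network a `vascular_network`.
#' @param path output file.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   the network.
#' @export
write_network <- function(network, path) {
  obj <- list(
    segments = lapply(network$segments, function(s)
      list(index = s$index, dl = s$dl, points = s$points)),
    junctions = network$junctions,
    inlet = network$inlet,
    terminals = network$terminals,
    stenoses = network$stenoses,
    wall = network$wall,
    segment_wall = network$segment_wall)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- lapply(obj$segments, function(s) {
    pts <- do.call(rbind, lapply(s$points, function(p)
      data.frame(x = p$x, y = p$y, z = p$z, r = p$r)))
    centerline_segment(pts, dl = s$dl, index = s$index)
  })
  assemble_network(
    segments = segs,
    junctions = obj$junctions,
    inlet = obj$inlet,
    terminals = obj$terminals,
    stenoses = if (is.null(obj$stenoses)) list() else obj$stenoses,
    wall = obj$wall,
    segment_wall = if (is.null(obj$segment_wall)) list() else obj$segment_wall)
}

#' Scale the radii of selected network segments
#'
#' Multiplies every point radius of the named segments by the given factors
#' (used by the remodeling loop; reference area follows as `A0 = pi r^2`).
#'
#' @param network a `vascular_network`.
#' @param factors named numeric vector: names are arterial indices.
#' @return the modified network.
#' @export
scale_segment_radii <- function(network, factors) {
  for (nm in names(factors)) {
    if (!(nm %in% names(network$segments))) stop("unknown segment ", nm)
    if (!is.finite(factors[[nm]]) || factors[[nm]] <= 0)
      stop("radius scale factor must be positive")
    network$segments[[nm]]$points$r <- network$segments[[nm]]$points$r * factors[[nm]]
  }
  network
}

#' Remove all stenosis elements from a network
#'
#' @param network a `vascular_network`.
#' @return the network without stenoses (the virtual-surgery configuration).
#' @export
remove_stenoses <- function(network) {
  network$stenoses <- list()
  network
}
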