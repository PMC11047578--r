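#' Vascular skeleton
#'
#' A skeleton is a spatial graph extracted from a binary vessel volume: nodes
#' carry world-mm positions, a local radius and a classification (`terminal`
#' if degree 1 — or 0 for an isolated voxel —, `plain` if degree 2,
#' `bifurcation` if degree >= 3); edges connect 26-adjacent skeleton voxels.
#' After [classify_and_split()], maximal bifurcation-free paths are labelled
#' with integer arterial indices and stored as ordered node-id paths in
#' `$segments`.
#'
#' @param nodes data frame with columns `x`, `y`, `z` (mm) and optionally `r`
#'   (mm, default `NA`).
#' @param edges data frame / matrix with columns `from`, `to` (row indices
#'   into `nodes`); self-loops are rejected.
#' @param meta named list of provenance metadata.
#' @return object of class `skeleton`.
#' @export
skeleton <- function(nodes, edges, meta = list()) {
  nodes <- as.data.frame(nodes)
  stopifnot(all(c("x", "y", "z") %in% names(nodes)))
  if (is.null(nodes$r)) nodes$r <- NA_real_
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    names(edges)[1:2] <- c("from", "to")
    if (any(edges$from == edges$to)) stop("skeleton graph has a self-loop")
    if (any(edges$from < 1 | edges$to < 1 | edges$from > nrow(nodes) |
              edges$to > nrow(nodes)))
      stop("edge references a missing node")
    # canonical undirected order, unique
    swp <- edges$from > edges$to
    tmp <- edges$from[swp]; edges$from[swp] <- edges$to[swp]; edges$to[swp] <- tmp
    edges <- unique(edges[, c("from", "to")])
  } else {
    edges <- data.frame(from = integer(), to = integer())
  }
  nodes$id <- seq_len(nrow(nodes))
  sk <- structure(list(nodes = nodes, edges = edges, segments = NULL,
                       meta = meta), class = "skeleton")
  recompute_kinds(sk)
}

recompute_kinds <- function(sk) {
  deg <- integer(nrow(sk$nodes))
  if (nrow(sk$edges)) {
    tab <- table(factor(c(sk$edges$from, sk$edges$to),
                        levels = seq_len(nrow(sk$nodes))))
    deg <- as.integer(tab)
  }
  sk$nodes$degree <- deg
  sk$nodes$kind <- ifelse(deg >= 3, "bifurcation",
                          ifelse(deg == 2, "plain", "terminal"))
  sk
}

#' @export
print.skeleton <- function(x, ...) {
  k <- table(factor(x$nodes$kind, levels = c("terminal", "bifurcation", "plain")))
  cat("skeleton:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (",
      k[["terminal"]], "terminal,", k[["bifurcation"]], "bifurcation,",
      k[["plain"]], "plain )\n")
  if (!is.null(x$segments))
    cat("  split into", length(x$segments), "labelled segments\n")
  invisible(x)
}

skeleton_graph <- function(sk) {
  igraph::graph_from_data_frame(
    sk$edges, directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(sk$nodes))))
}

#' Extract a voxel skeleton from a binary volume
#'
#' Shrinks the segmented vessel volume to one-voxel-wide centerlines using
#' sequential topology-preserving thinning (simple-point deletion in six
#' directional subcycles, 26-connected foreground / 6-connected background,
#' curve endpoints preserved).  Thinning operates in index space; a warning is
#' issued for anisotropic spacing.  Skeleton voxels become nodes at voxel
#' centres in world mm; 26-adjacent skeleton voxels are joined by edges.
#' The connected-component count of the input foreground is preserved.
#'
#' @param volume a [voxel_volume()] with at least one foreground voxel.
#' @return a [skeleton()] with radii unset (see [assign_radii()]).
#' @seealso [classify_and_split()], [prune_skeleton()], [skeleton_from_volume()]
#' @export
skeletonize <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!any(volume$data)) stop("no foreground")
  if (diff(range(volume$spacing)) > 1e-9)
    warning("anisotropic spacing: thinning is performed in index space")
  thin <- .thin_voxels_cpp(volume$data, dim(volume$data))
  idx <- which(thin, arr.ind = TRUE)
  pos <- voxel_to_world(idx, volume)
  nodes <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], r = NA_real_)
  edges <- voxel_adjacency(idx)
  sk <- skeleton(nodes, edges,
                 meta = list(algorithm = "sequential simple-point thinning (6 subcycles, 26/6 connectivity)",
                             spacing = volume$spacing, origin = volume$origin,
                             voxel_index = unname(idx)))
  sk
}

# edges between 26-adjacent voxel index rows
voxel_adjacency <- function(idx) {
  n <- nrow(idx)
  if (n < 2) return(data.frame(from = integer(), to = integer()))
  key <- function(i, j, k, d) (i - 1) + d[1] * ((j - 1) + d[2] * (k - 1))
  d <- apply(idx, 2, max) + 2L
  lookup <- new.env(hash = TRUE, size = n)
  for (v in seq_len(n))
    assign(as.character(key(idx[v, 1], idx[v, 2], idx[v, 3], d)), v, envir = lookup)
  from <- integer(0); to <- integer(0)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (v in seq_len(n)) {
    for (o in seq_len(nrow(offs))) {
      i <- idx[v, 1] + offs[o, 1]; j <- idx[v, 2] + offs[o, 2]
      k <- idx[v, 3] + offs[o, 3]
      if (i < 1 || j < 1 || k < 1) next
      w <- mget(as.character(key(i, j, k, d)), envir = lookup,
                ifnotfound = list(NULL))[[1]]
      if (!is.null(w) && w > v) {
        from <- c(from, v); to <- c(to, w)
      }
    }
  }
  data.frame(from = from, to = to)
}

#' Classify skeleton nodes and split into labelled segments
#'
#' Recomputes node kinds, collapses each connected cluster of adjacent
#' bifurcation nodes to a single centroid node (thinning can leave small
#' degree->=3 cliques at branch points), then partitions the skeleton into
#' maximal bifurcation-free paths.  Each path receives a distinct integer
#' arterial index; plain and terminal nodes carry the label of their (unique)
#' segment, bifurcation nodes belong to every incident segment as endpoints
#' and keep label `NA`.  A pure cycle without bifurcations becomes one closed
#' segment (a message is emitted).
#'
#' @param sk a [skeleton()].
#' @return the skeleton with `$segments` (named list of node-id paths) and a
#'   `label` column on nodes.
#' @export
classify_and_split <- function(sk) {
  stopifnot(inherits(sk, "skeleton"))
  if (nrow(sk$nodes) < 1) stop("skeleton has no nodes")
  sk <- recompute_kinds(sk)
  sk <- collapse_bifurcation_cliques(sk)
  split_segments(sk)
}

collapse_bifurcation_cliques <- function(sk) {
  bif <- which(sk$nodes$degree >= 3)
  if (length(bif) < 2) return(sk)
  sub <- sk$edges[sk$edges$from %in% bif & sk$edges$to %in% bif, , drop = FALSE]
  if (!nrow(sub)) return(sk)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(sub$from), to = as.character(sub$to)),
    directed = FALSE, vertices = data.frame(name = as.character(bif)))
  comp <- igraph::components(g)
  member <- split(as.integer(igraph::V(g)$name), comp$membership)
  member <- Filter(function(m) length(m) > 1, member)
  if (!length(member)) return(sk)

  nodes <- sk$nodes
  edges <- sk$edges
  remap <- seq_len(nrow(nodes))
  drop <- logical(nrow(nodes))
  for (m in member) {
    keep <- m[1]
    nodes$x[keep] <- mean(nodes$x[m]); nodes$y[keep] <- mean(nodes$y[m])
    nodes$z[keep] <- mean(nodes$z[m])
    nodes$r[keep] <- if (all(is.na(nodes$r[m]))) NA_real_ else max(nodes$r[m], na.rm = TRUE)
    remap[m] <- keep
    drop[setdiff(m, keep)] <- TRUE
  }
  edges$from <- remap[edges$from]
  edges$to <- remap[edges$to]
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  keep_ids <- which(!drop)
  new_id <- integer(nrow(nodes)); new_id[keep_ids] <- seq_along(keep_ids)
  nodes <- nodes[keep_ids, , drop = FALSE]
  edges$from <- new_id[edges$from]; edges$to <- new_id[edges$to]
  sk2 <- skeleton(nodes[, c("x", "y", "z", "r")], edges, meta = sk$meta)
  sk2
}

split_segments <- function(sk) {
  n <- nrow(sk$nodes)
  deg <- sk$nodes$degree
  adj <- vector("list", n)
  for (e in seq_len(nrow(sk$edges))) {
    a <- sk$edges$from[e]; b <- sk$edges$to[e]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  breaks <- which(deg != 2)
  used <- matrix(FALSE, 0, 0)  # edge-used bookkeeping via env keys
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  used_env <- new.env(hash = TRUE)
  segs <- list()

  walk <- function(start, nxt) {
    path <- c(start, nxt)
    assign(ekey(start, nxt), TRUE, envir = used_env)
    prev <- start; cur <- nxt
    while (deg[cur] == 2) {
      nbrs <- adj[[cur]]
      nxt2 <- nbrs[nbrs != prev]
      if (length(nxt2) == 0) break
      nxt2 <- nxt2[1]
      if (exists(ekey(cur, nxt2), envir = used_env)) break
      assign(ekey(cur, nxt2), TRUE, envir = used_env)
      path <- c(path, nxt2)
      prev <- cur; cur <- nxt2
    }
    path
  }

  for (b in breaks) {
    for (nb in adj[[b]]) {
      if (!exists(ekey(b, nb), envir = used_env))
        segs[[length(segs) + 1]] <- walk(b, nb)
    }
  }
  # pure cycles: remaining unused edges among degree-2 nodes
  for (e in seq_len(nrow(sk$edges))) {
    a <- sk$edges$from[e]; b <- sk$edges$to[e]
    if (!exists(ekey(a, b), envir = used_env)) {
      path <- walk(a, b)
      # close the loop if it returned to start
      message("closed segment: cycle without bifurcation nodes")
      segs[[length(segs) + 1]] <- path
    }
  }
  # isolated nodes become single-node segments
  for (v in which(deg == 0)) segs[[length(segs) + 1]] <- v

  names(segs) <- seq_along(segs)
  sk$segments <- segs
  sk$nodes$label <- NA_integer_
  for (lab in seq_along(segs)) {
    p <- segs[[lab]]
    inner <- p[sk$nodes$degree[p] <= 2]
    sk$nodes$label[inner] <- lab
  }
  sk
}

#' Prune short or unwanted skeleton branches
#'
#' Removes labelled segments that either have a terminal endpoint and an arc
#' length below `min_length_mm`, or whose label is not in `keep_labels`.
#' Degrees and kinds are recomputed and the skeleton re-split; a surviving
#' segment keeps the smallest label it previously carried (labels are stable
#' under pruning; segments merged across a vanished bifurcation take the
#' smaller of the merged labels).
#'
#' @param sk a split skeleton (see [classify_and_split()]).
#' @param min_length_mm drop terminal-ended segments shorter than this (mm).
#' @param keep_labels integer labels to keep (alternative to `min_length_mm`).
#' @return the pruned, re-split skeleton.
#' @export
prune_skeleton <- function(sk, min_length_mm = NULL, keep_labels = NULL) {
  stopifnot(inherits(sk, "skeleton"))
  if (is.null(sk$segments)) stop("skeleton must be split first (classify_and_split)")
  if (is.null(min_length_mm) && is.null(keep_labels))
    stop("supply min_length_mm or keep_labels")

  seg_len <- vapply(sk$segments, function(p) {
    if (length(p) < 2) return(0)
    pts <- as.matrix(sk$nodes[p, c("x", "y", "z")])
    sum(sqrt(rowSums(diff(pts)^2)))
  }, numeric(1))

  drop_seg <- rep(FALSE, length(sk$segments))
  if (!is.null(min_length_mm)) {
    has_term <- vapply(sk$segments, function(p)
      any(sk$nodes$degree[c(p[1], p[length(p)])] <= 1), logical(1))
    drop_seg <- drop_seg | (has_term & seg_len < min_length_mm)
  }
  if (!is.null(keep_labels))
    drop_seg <- drop_seg | !(seq_along(sk$segments) %in% keep_labels)

  if (!any(drop_seg)) return(sk)
  keep_paths <- sk$segments[!drop_seg]
  if (!length(keep_paths)) stop("pruning would remove the whole skeleton")

  old_label <- sk$nodes$label
  keep_nodes <- sort(unique(unlist(keep_paths)))
  new_id <- integer(nrow(sk$nodes)); new_id[keep_nodes] <- seq_along(keep_nodes)
  edges <- sk$edges
  # keep only edges used by surviving paths
  ekeep <- logical(nrow(edges))
  ekey <- paste0(pmin(edges$from, edges$to), "_", pmax(edges$from, edges$to))
  keys <- unlist(lapply(keep_paths, function(p) {
    if (length(p) < 2) return(character())
    paste0(pmin(p[-length(p)], p[-1]), "_", pmax(p[-length(p)], p[-1]))
  }))
  ekeep <- ekey %in% keys
  edges <- edges[ekeep, , drop = FALSE]
  edges$from <- new_id[edges$from]; edges$to <- new_id[edges$to]
  nodes <- sk$nodes[keep_nodes, c("x", "y", "z", "r"), drop = FALSE]

  sk2 <- skeleton(nodes, edges, meta = sk$meta)
  sk2 <- classify_and_split(sk2)
  # stable relabel: each new segment inherits the smallest old label present
  old_for_new <- old_label[keep_nodes]
  inherited <- vapply(sk2$segments, function(p) {
    labs <- old_for_new[p]
    labs <- labs[!is.na(labs)]
    if (!length(labs)) NA_integer_ else min(labs)
  }, integer(1))
  ord <- order(inherited, na.last = TRUE)
  sk2$segments <- sk2$segments[ord]
  names(sk2$segments) <- ifelse(is.na(inherited[ord]),
                                seq_along(ord), inherited[ord])
  lab_of <- as.integer(names(sk2$segments))
  sk2$nodes$label <- NA_integer_
  for (i in seq_along(sk2$segments)) {
    p <- sk2$segments[[i]]
    inner <- p[sk2$nodes$degree[p] <= 2]
    sk2$nodes$label[inner] <- lab_of[i]
  }
  sk2
}

#' Assign distance-transform radii to skeleton nodes
#'
#' Sets each node's radius to the Euclidean distance (mm, spacing-aware) from
#' the node position to the nearest background voxel centre of `volume`.  The
#' nearest background voxel to an interior point always lies in the background
#' shell 26-adjacent to the foreground, so the search is restricted to that
#' shell.
#'
#' @param sk a [skeleton()] whose nodes lie inside the foreground of `volume`.
#' @param volume the originating [voxel_volume()].
#' @return the skeleton with radii filled in (all > 0).
#' @export
assign_radii <- function(sk, volume) {
  stopifnot(inherits(sk, "skeleton"), inherits(volume, "voxel_volume"))
  pos <- as.matrix(sk$nodes[, c("x", "y", "z")])
  idx <- world_to_voxel(pos, volume)
  d <- dim(volume$data)
  inside <- idx[, 1] >= 1 & idx[, 2] >= 1 & idx[, 3] >= 1 &
    idx[, 1] <= d[1] & idx[, 2] <= d[2] & idx[, 3] <= d[3]
  fg <- inside
  fg[inside] <- volume$data[idx[inside, , drop = FALSE]]
  if (!all(fg))
    stop("node(s) outside foreground: ", paste(which(!fg), collapse = ", "))

  shell <- background_shell(volume)
  if (!nrow(shell)) {  # volume entirely foreground: bound by domain walls
    sk$nodes$r <- pmin(
      (idx[, 1] - 0.5) * volume$spacing[1], (d[1] - idx[, 1] + 0.5) * volume$spacing[1],
      (idx[, 2] - 0.5) * volume$spacing[2], (d[2] - idx[, 2] + 0.5) * volume$spacing[2],
      (idx[, 3] - 0.5) * volume$spacing[3], (d[3] - idx[, 3] + 0.5) * volume$spacing[3])
    return(sk)
  }
  shell_pos <- voxel_to_world(shell, volume)
  r <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    dd <- sweep(shell_pos, 2, pos[i, ], "-")
    r[i] <- sqrt(min(rowSums(dd * dd)))
  }
  sk$nodes$r <- r
  sk
}

# background voxels 26-adjacent to foreground (as index rows); voxels outside
# the array are treated as background, so boundary-adjacent foreground also
# contributes virtual shell voxels just outside the domain
background_shell <- function(volume) {
  v <- volume$data
  d <- dim(v)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  # dilate foreground by one (26-neighbourhood) inside padded array
  dil <- pad
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sx <- (2 + dx):(d[1] + 1 + dx); sy <- (2 + dy):(d[2] + 1 + dy)
    sz <- (2 + dz):(d[3] + 1 + dz)
    dil[sx, sy, sz] <- dil[sx, sy, sz] | pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  }
  shell <- dil & !pad
  idx <- which(shell, arr.ind = TRUE)
  idx - 1L  # back to unpadded 1-based coordinates (may be 0 or d+1: virtual)
}

#' One-call skeleton pipeline
#'
#' [skeletonize()] + [classify_and_split()] + optional [prune_skeleton()] +
#' [assign_radii()].
#'
#' @param volume a [voxel_volume()].
#' @param min_branch_mm prune terminal branches shorter than this (mm);
#'   `NULL` disables pruning.
#' @return a split, labelled skeleton with radii.
#' @export
skeleton_from_volume <- function(volume, min_branch_mm = NULL) {
  sk <- skeletonize(volume)
  sk <- classify_and_split(sk)
  if (!is.null(min_branch_mm) && min_branch_mm > 0) {
    pruned <- try(prune_skeleton(sk, min_length_mm = min_branch_mm), silent = TRUE)
    if (!inherits(pruned, "try-error")) sk <- pruned
  }
  assign_radii(sk, volume)
}

#' Write / read a skeleton as JSON
#'
#' One record per node (id, x, y, z, r, kind, label) and one per edge, plus
#' the segment paths and metadata.
#'
#' @param sk a [skeleton()].
#' @param path output file.
#' @return `write_skeleton` returns `path` invisibly; `read_skeleton` returns
#'   the skeleton.
#' @export
write_skeleton <- function(sk, path) {
  obj <- list(nodes = sk$nodes, edges = sk$edges,
              segments = lapply(sk$segments, as.integer),
              meta = sk$meta[setdiff(names(sk$meta), "voxel_index")])
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_skeleton
#' @export
read_skeleton <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sk <- skeleton(obj$nodes[, c("x", "y", "z", "r")], obj$edges,
                 meta = as.list(obj$meta))
  if (!is.null(obj$segments) && length(obj$segments)) {
    sk$segments <- lapply(obj$segments, as.integer)
    names(sk$segments) <- names(obj$segments)
    sk$nodes$label <- obj$nodes$label
  }
  sk
}
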