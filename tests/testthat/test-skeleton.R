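test_that("straight cylinder phantom thins to a single two-terminal path", {
  ph <- make_tube_phantom("straight", length_vox = 40, radius_vox = 3)
  sk <- skeletonize(ph$volume)
  sk <- classify_and_split(sk)
  sk <- prune_skeleton(sk, min_length_mm = 5)
  kinds <- table(factor(sk$nodes$kind,
                        levels = c("terminal", "bifurcation", "plain")))
  expect_identical(as.integer(kinds[["terminal"]]), 2L)
  expect_identical(as.integer(kinds[["bifurcation"]]), 0L)
  expect_length(sk$segments, 1)
  # skeleton voxels are a subset of the foreground
  sk_all <- skeletonize(ph$volume)
  idx <- sk_all$meta$voxel_index
  expect_true(all(ph$volume$data[idx]))
  # one-voxel thickness: no 2x2x2 solid block of skeleton voxels
  thin <- array(FALSE, dim(ph$volume$data))
  thin[idx] <- TRUE
  d <- dim(thin)
  blocks <- thin[-d[1], -d[2], -d[3]] & thin[-1, -d[2], -d[3]] &
    thin[-d[1], -1, -d[3]] & thin[-1, -1, -d[3]] &
    thin[-d[1], -d[2], -1] & thin[-1, -d[2], -1] &
    thin[-d[1], -1, -1] & thin[-1, -1, -1]
  expect_false(any(blocks))
})

test_that("thinning preserves connected components and is idempotent", {
  ph1 <- make_tube_phantom("straight", length_vox = 20, radius_vox = 2)
  # two disjoint copies in one volume
  d <- dim(ph1$volume$data)
  two <- array(FALSE, d + c(d[1] + 4L, 0L, 0L))
  two[seq_len(d[1]), , ] <- ph1$volume$data
  two[d[1] + 4L + seq_len(d[1]), , ] <- ph1$volume$data
  vol2 <- voxel_volume(two)
  expect_identical(count_components(vol2), 2L)
  thin <- .thin_voxels_cpp(vol2$data, dim(vol2$data))
  expect_identical(.count_components_cpp(thin, dim(thin), 26L), 2L)
  # idempotence: thinning an already-thin volume changes nothing
  thin2 <- .thin_voxels_cpp(thin, dim(thin))
  expect_identical(thin, thin2)
})

test_that("degenerate volumes are handled", {
  v <- array(FALSE, c(3, 3, 3))
  expect_error(skeletonize(voxel_volume(v)), "no foreground")
  v[2, 2, 2] <- TRUE
  sk <- classify_and_split(skeletonize(voxel_volume(v)))
  expect_identical(nrow(sk$nodes), 1L)
  expect_identical(sk$nodes$kind, "terminal")
  expect_identical(sk$nodes$degree, 0L)
})

test_that("Y phantom yields 3 terminals and a single bifurcation", {
  ph <- make_tube_phantom("Y", length_vox = 30, radius_vox = 3)
  sk <- classify_and_split(skeletonize(ph$volume))
  sk <- prune_skeleton(sk, min_length_mm = 6)
  kinds <- table(factor(sk$nodes$kind,
                        levels = c("terminal", "bifurcation", "plain")))
  expect_identical(as.integer(kinds[["terminal"]]), 3L)
  expect_identical(as.integer(kinds[["bifurcation"]]), 1L)
  expect_length(sk$segments, 3)
  # the bifurcation node is an endpoint of all three segments
  bif <- sk$nodes$id[sk$nodes$kind == "bifurcation"]
  ends <- vapply(sk$segments, function(p) bif %in% c(p[1], p[length(p)]),
                 logical(1))
  expect_true(all(ends))
})

test_that("abstract skeleton splitting matches path enumeration", {
  # path of 10 plain-degree nodes -> 1 segment, 2 terminals
  path <- skeleton(data.frame(x = 1:10, y = 0, z = 0),
                   data.frame(from = 1:9, to = 2:10))
  path <- classify_and_split(path)
  expect_length(path$segments, 1)
  expect_identical(sum(path$nodes$kind == "terminal"), 2L)

  # H-shaped skeleton: two non-adjacent bifurcations joined by a crossbar
  # of plain nodes, two arms each -> 5 segments
  nodes <- data.frame(
    x = c(-1, 1, 0, 0, 0, 0, -1, 1),
    y = c(2, 2, 1, 0, -1, -2, -3, -3),
    z = 0)
  edges <- data.frame(from = c(1, 2, 3, 4, 5, 6, 6),
                      to = c(3, 3, 4, 5, 6, 7, 8))
  h <- classify_and_split(skeleton(nodes, edges))
  expect_length(h$segments, 5)
  expect_identical(sum(h$nodes$kind == "bifurcation"), 2L)

  # oracle on random small trees: #segments equals the edge count of the
  # bifurcation-contracted graph.  Every tree edge is subdivided once so no
  # two branch nodes are adjacent (adjacent branch clusters are collapsed by
  # design, which would change the contracted graph itself).
  set.seed(7)
  for (rep in 1:5) {
    n <- 12
    parent <- vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))
    from <- c(parent, (n + 1):(2 * n - 1))
    to <- c((n + 1):(2 * n - 1), 2:n)  # midpoint node on every edge
    m <- 2L * n - 1L
    nodes <- data.frame(x = runif(m), y = runif(m), z = runif(m))
    sk <- classify_and_split(skeleton(nodes, data.frame(from = from, to = to)))
    deg <- tabulate(c(from, to), m)
    # each maximal chain ends at two nodes of degree != 2 (tree: no cycles)
    n_expected <- sum(deg[deg != 2]) / 2
    expect_length(sk$segments, n_expected)
  }
})

test_that("pruning removes short terminal branches and relabels stably", {
  # Y with one short (1 mm) branch: prune at 2 mm -> one straight segment
  nodes <- data.frame(x = c(0, 0, 0, 0, 0, 1, 0, 0),
                      y = c(0, 1, 2, 3, 4, 4, 5, 6), z = 0)
  edges <- data.frame(from = c(1, 2, 3, 4, 5, 5, 7),
                      to = c(2, 3, 4, 5, 6, 7, 8))
  y <- classify_and_split(skeleton(nodes, edges))
  expect_length(y$segments, 3)
  pruned <- prune_skeleton(y, min_length_mm = 2)
  expect_length(pruned$segments, 1)
  expect_identical(sum(pruned$nodes$kind == "bifurcation"), 0L)
  # min_length 0 and keep_labels = all are identities
  expect_identical(prune_skeleton(y, min_length_mm = 0)$segments, y$segments)
  expect_identical(prune_skeleton(y, keep_labels = seq_along(y$segments))$segments,
                   y$segments)
  # pruning everything errors
  expect_error(prune_skeleton(y, keep_labels = integer(0)), "whole skeleton")
})

test_that("distance-transform radii match the brute-force oracle", {
  ph <- make_tube_phantom("straight", length_vox = 20, radius_vox = 3)
  expect_true(all(dim(ph$volume$data) <= 32))
  sk <- classify_and_split(skeletonize(ph$volume))
  sk <- assign_radii(sk, ph$volume)
  expect_equal(sk$nodes$r, brute_force_radii(sk, ph$volume), tolerance = 1e-12)
  expect_true(all(sk$nodes$r > 0))
  interior <- sk$nodes$degree == 2
  expect_true(all(sk$nodes$r[interior] >= 2.5 & sk$nodes$r[interior] <= 3.5))

  # spacing scaling: halving the spacing halves the metric radii
  vol_half <- voxel_volume(ph$volume$data, spacing = c(0.5, 0.5, 0.5))
  sk_half <- assign_radii(classify_and_split(skeletonize(vol_half)), vol_half)
  expect_equal(sk_half$nodes$r[sk_half$nodes$degree == 2],
               sk$nodes$r[interior] / 2, tolerance = 1e-12)

  # node on a 1-voxel-thick plate: radius bounded by one spacing
  plate <- array(FALSE, c(9, 9, 3))
  plate[2:8, 2:8, 2] <- TRUE
  pv <- voxel_volume(plate)
  psk <- skeleton(data.frame(x = 4, y = 4, z = 1), data.frame())
  psk <- assign_radii(psk, pv)
  expect_lte(psk$nodes$r, 1)

  # a node outside the foreground is reported by index
  bad <- skeleton(data.frame(x = 0, y = 0, z = 0), data.frame())
  expect_error(assign_radii(bad, ph$volume), "outside foreground")
})

test_that("skeleton JSON round trip preserves the structure", {
  ph <- make_tube_phantom("Y", length_vox = 20, radius_vox = 2)
  sk <- assign_radii(classify_and_split(skeletonize(ph$volume)), ph$volume)
  f <- tempfile(fileext = ".json")
  write_skeleton(sk, f)
  sk2 <- read_skeleton(f)
  expect_equal(sk2$nodes[, c("x", "y", "z", "r", "degree", "kind", "label")],
               sk$nodes[, c("x", "y", "z", "r", "degree", "kind", "label")],
               tolerance = 0)
  expect_identical(lapply(sk2$segments, as.integer),
                   lapply(sk$segments, as.integer))
})
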