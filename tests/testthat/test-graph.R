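test_that("build_graph classifies lines, Ys and rings correctly", {
  # straight 50-voxel line: 2 endpoints, 1 segment, 0 junctions
  sk <- skeleton_from_voxels(line_voxels(50), c(10, 10, 60))
  g <- build_graph(sk)
  expect_identical(nrow(g$nodes), 2L)
  expect_identical(length(g$segments), 1L)
  expect_identical(sum(g$nodes$degree >= 3), 0L)
  expect_identical(sort(g$nodes$kind), c("endpoint", "endpoint"))
  expect_euler(g)

  # Y: 1 junction node, 3 endpoint nodes, 3 segments
  gy <- build_graph(y_skeleton(arm = 30))
  expect_identical(nrow(gy$nodes), 4L)
  expect_identical(length(gy$segments), 3L)
  expect_identical(sum(gy$nodes$kind == "junction"), 1L)
  expect_identical(gy$nodes$degree[gy$nodes$kind == "junction"], 3L)
  expect_euler(gy)

  # 40-voxel ring: 1 anchor node, 1 self-loop, cycle count 1
  gr <- build_graph(skeleton_from_voxels(ring_voxels(10), c(6, 40, 40)))
  expect_identical(nrow(gr$nodes), 1L)
  expect_identical(length(gr$segments), 1L)
  expect_identical(gr$segments[[1]]$from, gr$segments[[1]]$to)
  expect_identical(cycle_count(gr), 1L)
  expect_euler(gr)

  # every skeleton voxel is used exactly once (paths + nodes tile the skeleton)
  used <- do.call(rbind, lapply(gy$segments, function(s) s$path_vox))
  # 3 arms of 30 voxels each appear in paths; the centre voxel belongs to the
  # junction node only
  expect_identical(nrow(unique(used)), 90L)

  # empty skeleton -> empty graph
  ge <- build_graph(skeleton_from_voxels(matrix(0L, 0, 3), c(4, 4, 4)))
  expect_identical(nrow(ge$nodes), 0L)
  expect_identical(length(ge$segments), 0L)
})

test_that("segment lengths are exact on forced-arithmetic paths", {
  # 10-step axis-aligned path at 2 um voxels -> 20 um
  g <- build_graph(skeleton_from_voxels(line_voxels(11), c(10, 10, 20)))
  g <- measure_lengths(g, c(2, 2, 2))
  expect_equal(g$segments[[1]]$length_um, 20)

  # 10-step 26-diagonal at 1 um voxels -> 10 * sqrt(3)
  vox <- cbind(1:11, 1:11, 1:11)
  gd <- build_graph(skeleton_from_voxels(vox, c(12, 12, 12)))
  gd <- measure_lengths(gd, c(1, 1, 1))
  expect_equal(gd$segments[[1]]$length_um, 10 * sqrt(3))

  # anisotropic voxels scale each axis independently
  ga <- measure_lengths(build_graph(skeleton_from_voxels(line_voxels(11), c(10, 10, 20))),
                        c(5, 3, 2))
  expect_equal(ga$segments[[1]]$length_um, 20)  # path runs along x (2 um steps)
})

test_that("a sampled helix matches its closed-form arc length within 2%", {
  r <- 20; pitch <- 4; tmax <- 4 * pi
  tt <- seq(0, tmax, length.out = 200)
  pts <- cbind(r * cos(tt), r * sin(tt), pitch * tt)
  nodes <- data.frame(id = 1:2, x = pts[c(1, 200), 1], y = pts[c(1, 200), 2],
                      z = pts[c(1, 200), 3])
  seg <- list(list(id = 1L, from = 1L, to = 2L, points = pts))
  g <- hevquant:::new_vessel_graph(nodes, seg, c(1, 1, 1))
  g <- measure_lengths(g)
  analytic <- sqrt(r^2 + pitch^2) * tmax
  expect_lt(abs(g$segments[[1]]$length_um - analytic) / analytic, 0.02)
})

test_that("distance-transform widths recover tube diameters", {
  tube_graph <- function(radius_um) {
    spec <- phantom_spec(shape = c(60, 24, 24), voxel_size = c(2, 2, 2),
                         topology = list(nodes = rbind(c(24, 24, 10), c(24, 24, 110)),
                                         edges = data.frame(from = 1, to = 2,
                                                            radius_um = radius_um)),
                         domain_semiaxes_um = c(200, 200, 200))
    phantom_pipeline(generate_phantom(spec))$graph
  }
  g8 <- tube_graph(8)                       # radius 4 voxels -> width 16 um
  expect_lte(abs(g8$segments[[1]]$width_um - 16), 2)

  g2 <- tube_graph(2)                       # minimal 1-voxel tube
  expect_lte(abs(g2$segments[[1]]$width_um - 4), 2)

  # two tubes, radii 5 and 10 voxels: widths ordered, ratio 2 +- 10%
  spec <- phantom_spec(shape = c(60, 60, 60), voxel_size = c(2, 2, 2),
                       topology = list(
                         nodes = rbind(c(30, 30, 10), c(30, 30, 110),
                                       c(90, 90, 10), c(90, 90, 110)),
                         edges = data.frame(from = c(1, 3), to = c(2, 4),
                                            radius_um = c(10, 20))),
                       domain_semiaxes_um = c(300, 300, 300))
  g <- phantom_pipeline(generate_phantom(spec))$graph
  w <- sort(vapply(g$segments, function(s) s$width_um, 0))
  expect_identical(length(w), 2L)
  expect_lt(abs(w[2] / w[1] - 2), 0.2)

  # a path outside its mask is an error
  gm <- measure_lengths(build_graph(skeleton_from_voxels(line_voxels(5), c(10, 10, 10))))
  off <- binary_mask(array(FALSE, c(10, 10, 10)), c(1, 1, 1))
  expect_error(measure_widths(gm, off), "exits the vessel mask")
})

test_that("pruning removes short spurs, merges through degree-2 nodes, and is idempotent", {
  # Y with one 3-voxel arm (3 um), threshold 10 um -> single merged segment
  c0 <- c(5, 40, 40)
  vox <- rbind(c0,
               t(vapply(1:30, function(i) c0 + c(0, 0, i), numeric(3))),
               t(vapply(1:30, function(i) c0 + c(0, 0, -i), numeric(3))),
               t(vapply(1:3, function(i) c0 + c(0, i, 0), numeric(3))))
  g <- measure_lengths(build_graph(skeleton_from_voxels(vox, c(10, 80, 80))), c(1, 1, 1))
  expect_identical(length(g$segments), 3L)
  p <- prune_spurs(g, 10)
  expect_identical(length(p$segments), 1L)
  expect_identical(sum(p$nodes$degree >= 3), 0L)
  expect_equal(p$segments[[1]]$length_um, 60, tolerance = 0.05)
  expect_euler(p)

  expect_identical(length(prune_spurs(g, 0)$segments), 3L)      # threshold 0: identity
  p2 <- prune_spurs(p, 10)
  expect_identical(segment_table(p2), segment_table(p))          # idempotent
  expect_error(prune_spurs(g, -1), "non-negative")
})

test_that("networks are ranked by total length and labelled on segments", {
  big <- y_skeleton(arm = 30, c0 = c(5, 40, 40), shape = c(10, 200, 200))
  small <- y_skeleton(arm = 12, c0 = c(5, 150, 150), shape = c(10, 200, 200))
  sk <- skeleton_from_voxels(rbind(big$voxels, small$voxels), c(10, 200, 200))
  g <- identify_networks(measure_lengths(build_graph(sk), c(1, 1, 1)))
  expect_identical(nrow(g$networks), 2L)
  expect_true(all(diff(g$networks$total_length_um) <= 0))        # descending
  expect_identical(g$networks$n_segments, c(3L, 3L))
  expect_identical(g$networks$n_branch_points, c(1L, 1L))
  nets <- vapply(g$segments, function(s) s$network, 0L)
  expect_setequal(unique(nets), c(1L, 2L))
  expect_euler(g)

  single <- identify_networks(measure_lengths(build_graph(big), c(1, 1, 1)))
  expect_identical(nrow(single$networks), 1L)
  empty <- identify_networks(build_graph(skeleton_from_voxels(matrix(0L, 0, 3), c(4, 4, 4))))
  expect_identical(nrow(empty$networks), 0L)
})

test_that("graph metrics are invariant under 90-degree rotations of the volume", {
  ph <- generate_phantom(phantom_spec(shape = c(64, 64, 64), seed = 21, max_segments = 8))
  mask <- clean_mask(binarize(ph$volume, "fixed", 125), 27)
  rot <- function(a) {                      # rotate about z: (z, y, x) -> (z, x, -y)
    b <- aperm(a, c(1, 3, 2))
    b[, , rev(seq_len(dim(b)[3]))]
  }
  m2 <- binary_mask(rot(mask$data), mask$voxel_size, "vessel")
  g1 <- phantom_pipeline(ph)$graph
  g2 <- build_graph(skeletonize(m2))
  g2 <- measure_widths(measure_lengths(g2), m2)
  g2 <- identify_networks(prune_spurs(g2, 10))
  expect_identical(length(g2$segments), length(g1$segments))
  expect_identical(sum(g2$nodes$degree >= 3), sum(g1$nodes$degree >= 3))
  # counts are exact under rotation; totals agree to ~2% (the thinning
  # tie-break follows raster order, so the skeleton can shift by single
  # voxels near junctions when the volume is rotated)
  l1 <- vapply(g1$segments, function(s) s$length_um, 0)
  l2 <- vapply(g2$segments, function(s) s$length_um, 0)
  expect_equal(sum(l2), sum(l1), tolerance = 0.02)
  w1 <- vapply(g1$segments, function(s) s$width_um, 0)
  w2 <- vapply(g2$segments, function(s) s$width_um, 0)
  expect_equal(mean(w2), mean(w1), tolerance = 0.02)
})
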