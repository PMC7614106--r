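test_that("an explicit Y spec yields exact ground truth", {
  ctr <- c(128, 128, 128)
  dirs <- rbind(c(0, 0, 1), c(0, 0.94, -0.342), c(0, -0.94, -0.342))
  nodes <- rbind(ctr, ctr + 60 * dirs[1, ], ctr + 60 * dirs[2, ], ctr + 60 * dirs[3, ])
  spec <- phantom_spec(topology = list(nodes = nodes,
                                       edges = data.frame(from = 1, to = 2:4,
                                                          radius_um = 8)))
  ph <- generate_phantom(spec)
  tg <- ph$truth$graph
  expect_identical(length(tg$segments), 3L)
  expect_identical(sum(tg$nodes$degree >= 3), 1L)
  expect_equal(total_truth_length(ph$truth), 3 * 60, tolerance = 0.01)
  expect_euler(tg)
  # analytic lengths equal polyline arc lengths
  for (s in tg$segments)
    expect_equal(s$length_um, sum(sqrt(rowSums(diff(s$points)^2))), tolerance = 1e-9)
})

test_that("identical spec and seed give identical volumes; different seeds differ", {
  a <- generate_phantom(phantom_spec(shape = c(48, 48, 48), seed = 42, noise_sd = 5))
  b <- generate_phantom(phantom_spec(shape = c(48, 48, 48), seed = 42, noise_sd = 5))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(segment_table(a$truth$graph), segment_table(b$truth$graph))
  c3 <- generate_phantom(phantom_spec(shape = c(48, 48, 48), seed = 43, noise_sd = 5))
  expect_false(identical(a$volume$data, c3$volume$data))
})

test_that("a background-only spec yields an empty truth graph", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24, 24), topology = list()))
  expect_identical(length(ph$truth$graph$segments), 0L)
  expect_true(all(ph$volume$data == 50))
})

test_that("rasterization is faithful to the capsule geometry", {
  spec <- phantom_spec(shape = c(48, 48, 48), seed = 5, max_segments = 5)
  ph <- generate_phantom(spec)
  mask <- ph$truth$vessel_mask$data
  segs <- do.call(rbind, lapply(ph$truth$graph$segments, function(s) {
    p <- s$points
    cbind(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE], s$radius_um)
  }))
  dist_to_caps <- function(pt) {
    min(apply(segs, 1, function(e) {
      a <- e[1:3]; b <- e[4:6]
      ab <- b - a; t <- sum((pt - a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      sqrt(sum((pt - (a + t * ab))^2)) - e[7]
    }))
  }
  idx <- which(mask); set.seed(1)
  pick <- sample(idx, 200)
  d <- dim(mask)
  for (i in pick) {
    i1 <- (i - 1) %% d[1]; i2 <- ((i - 1) %/% d[1]) %% d[2]
    i3 <- (i - 1) %/% (d[1] * d[2])
    pt <- c((i3 + 0.5) * 2, (i2 + 0.5) * 2, (i1 + 0.5) * 2)
    expect_lte(dist_to_caps(pt), 1e-9)   # centre of a true voxel is inside a capsule
  }
  # and background voxel centres near the tubes are strictly outside
  off <- sample(which(!mask), 200)
  for (i in off) {
    i1 <- (i - 1) %% d[1]; i2 <- ((i - 1) %/% d[1]) %% d[2]
    i3 <- (i - 1) %/% (d[1] * d[2])
    pt <- c((i3 + 0.5) * 2, (i2 + 0.5) * 2, (i1 + 0.5) * 2)
    expect_gt(dist_to_caps(pt), 0)
  }
})

test_that("sectioning a perpendicular tube yields one disc of analytic area", {
  spec <- phantom_spec(shape = c(64, 48, 48), voxel_size = c(2, 2, 2),
                       topology = list(nodes = rbind(c(48, 48, 30), c(48, 48, 118)),
                                       edges = data.frame(from = 1, to = 2, radius_um = 8)),
                       domain_semiaxes_um = c(200, 200, 200))
  ph <- generate_phantom(spec)   # tube along z through (x,y) = (48,48)
  sec <- section_phantom(ph$volume, ph$truth, z_index = 32, thickness_um = 4)
  expect_identical(sec$truth$n_vessels, 1L)
  expect_identical(max(sec$labels), 1L)
  area <- sum(sec$labels > 0) * prod(sec$pixel_size)
  ring <- 2 * pi * 8 * max(sec$pixel_size)   # +- one pixel ring around the disc
  expect_lt(abs(area - pi * 64), ring)

  m <- measure_section(sec$labels, sec$outline, sec$pixel_size)
  expect_identical(m$n_vessels, 1L)

  none <- section_phantom(ph$volume, ph$truth, z_index = 1, thickness_um = 4)
  expect_identical(max(none$labels), 0L)
  expect_identical(none$truth$n_vessels, 0L)
  expect_error(section_phantom(ph$volume, ph$truth, 2, thickness_um = 1),
               "below one z-step")
})
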