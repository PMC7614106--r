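test_that("bin_distribution follows the printed upper-inclusive convention", {
  h <- bin_distribution(c(5, 15, 15, 25))
  expect_identical(h$bin[1:3], c("1-10", "11-20", "21-30"))
  expect_equal(h$pct[1:3], c(25, 50, 25))
  expect_equal(sum(h$pct), 100)

  # a value of exactly 20 lands in "11-20"
  h20 <- bin_distribution(20)
  expect_equal(h20$pct[h20$bin == "11-20"], 100)

  # open-ended trailing bin beyond the cap
  hc <- bin_distribution(c(5, 250), cap = 100)
  expect_identical(hc$bin[nrow(hc)], "> 100")
  expect_equal(hc$pct[nrow(hc)], 50)

  he <- bin_distribution(numeric(0))
  expect_identical(nrow(he), 0L)
  expect_true(attr(he, "empty"))
  expect_error(bin_distribution(c(-1, 5)), "positive")
  expect_error(bin_distribution(5, bin_width = 0), "positive")
})

test_that("summarize_network reproduces hand arithmetic on a Y graph", {
  # three 60 um segments meeting at one junction
  gy <- measure_lengths(build_graph(y_skeleton(arm = 30)), c(2, 2, 2))
  gy <- identify_networks(gy)
  # tissue of exactly 10^6 um^3 = 1e-3 mm^3: 125000 voxels of 8 um^3
  tis <- binary_mask(array(TRUE, c(50, 50, 50)), c(2, 2, 2), "tissue")
  m <- summarize_network(gy, tis)
  expect_equal(m$ln_volume, 1e6)
  expect_gt(m$total_length, 3 * 55); expect_lt(m$total_length, 3 * 65)
  expect_identical(m$n_segments, 3L)
  expect_identical(m$n_branch_points, 1L)
  expect_identical(m$n_networks, 1L)
  expect_equal(m$density_length, m$total_length / 1e-3)
  expect_equal(m$density_count, 3 / 1e-3)
  expect_equal(sum(m$length_histogram$pct), 100, tolerance = 1e-12)

  # doubling the tissue volume halves both densities exactly
  tis2 <- binary_mask(array(TRUE, c(100, 50, 50)), c(2, 2, 2), "tissue")
  m2 <- summarize_network(gy, tis2)
  expect_identical(m2$density_length, m$density_length / 2)
  expect_identical(m2$density_count, m$density_count / 2)

  # empty graph -> all-zero counts
  ge <- identify_networks(build_graph(skeleton_from_voxels(matrix(0L, 0, 3), c(4, 4, 4))))
  me <- summarize_network(ge, tis)
  expect_identical(me$n_segments, 0L)
  expect_equal(me$total_length, 0)
  expect_identical(nrow(me$length_histogram), 0L)
  expect_error(summarize_network(gy, binary_mask(array(FALSE, c(2, 2, 2)),
                                                 c(1, 1, 1), "tissue")), "zero")
})

test_that("compare_conditions reports pairwise fold changes without testing", {
  gy <- identify_networks(measure_lengths(build_graph(y_skeleton(30)), c(2, 2, 2)))
  t1 <- binary_mask(array(TRUE, c(50, 50, 50)), c(2, 2, 2), "tissue")
  t8 <- binary_mask(array(TRUE, c(100, 100, 100)), c(2, 2, 2), "tissue")
  a <- summarize_network(gy, t1)
  b <- summarize_network(gy, t8)

  self <- compare_conditions(list(x = a, y = a))
  expect_equal(unlist(self[, 3:6]), rep(1, 4), ignore_attr = TRUE)

  fc <- compare_conditions(list(small = a, big = b))
  expect_equal(fc$fold_ln_volume, 8, tolerance = 0.02)

  three <- compare_conditions(list(a = a, b = b, c = a))
  expect_identical(nrow(three), 3L)
  expect_error(compare_conditions(list(a)), "at least two")
})

test_that("scaling the voxel size rescales lengths, widths, volumes and densities exactly", {
  ph <- generate_phantom(phantom_spec(shape = c(64, 64, 64), seed = 13, max_segments = 8))
  mask1 <- clean_mask(binarize(ph$volume, "fixed", 125), 27)
  sk <- skeletonize(mask1)
  g1 <- build_graph(sk)
  g1 <- measure_widths(measure_lengths(g1, c(2, 2, 2)), mask1)
  mask2 <- binary_mask(mask1$data, c(4, 4, 4), "vessel")
  sk2 <- sk; sk2$voxel_size <- c(4, 4, 4)
  g2 <- build_graph(sk2)
  g2 <- measure_widths(measure_lengths(g2, c(4, 4, 4)), mask2)

  l1 <- vapply(g1$segments, function(s) s$length_um, 0)
  l2 <- vapply(g2$segments, function(s) s$length_um, 0)
  expect_identical(l2, 2 * l1)
  w1 <- vapply(g1$segments, function(s) s$width_um, 0)
  w2 <- vapply(g2$segments, function(s) s$width_um, 0)
  expect_identical(w2, 2 * w1)

  t1 <- binary_mask(array(TRUE, c(20, 20, 20)), c(2, 2, 2), "tissue")
  t2 <- binary_mask(array(TRUE, c(20, 20, 20)), c(4, 4, 4), "tissue")
  m1 <- summarize_network(identify_networks(g1), t1)
  m2 <- summarize_network(identify_networks(g2), t2)
  expect_identical(m2$ln_volume, 8 * m1$ln_volume)
  expect_identical(m2$density_length, m1$density_length / 4)
})

test_that("constant-density phantom families show the volume/length and branch/length couplings", {
  fams <- lapply(seq(1, 2, length.out = 20), function(f) {
    side <- 2L * as.integer(round(32 * f))
    ph <- generate_phantom(phantom_spec(
      shape = rep(side, 3), voxel_size = c(2, 2, 2),
      n_roots = 2L, branch_prob = 0.7,
      max_segments = as.integer(round(10 * f^3)),
      seed = 300 + as.integer(round(100 * f))))
    tl <- total_truth_length(ph$truth)
    list(volume = ph$truth$tissue_volume_um3, length = tl,
         branch = sum(ph$truth$graph$nodes$degree >= 3))
  })
  vol <- vapply(fams, `[[`, 0, "volume")
  len <- vapply(fams, `[[`, 0, "length")
  br <- vapply(fams, `[[`, 0, "branch")
  expect_gte(max(vol) / min(vol), 7.5)                    # family spans ~8x volume
  fit <- stats::lm(len ~ vol)
  expect_gte(summary(fit)$r.squared, 0.95)
  expect_gte(stats::cor(br, len), 0.9)
})
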