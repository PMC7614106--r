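test_that("TIFF stacks round-trip bit-exactly with voxel metadata", {
  f <- withr::local_tempfile(fileext = ".tif")

  zeros <- volume_image(array(0, c(4, 8, 8)), c(5, 2, 2))
  write_stack(zeros, f)
  back <- read_stack(f)
  expect_identical(dim(back), c(4L, 8L, 8L))
  expect_true(all(back$data == 0))
  expect_identical(back$voxel_size, c(5, 2, 2))

  set.seed(11)
  v <- volume_image(array(sample(0:65535, 2 * 6 * 7, TRUE), c(2, 6, 7)),
                    c(1, 1, 1), "PNAd")
  write_stack(v, f)
  v2 <- read_stack(f)
  expect_identical(v2$data, v$data)          # 16-bit path, bit exact
  expect_identical(v2$channel_label, "PNAd")

  v8 <- volume_image(array(sample(0:255, 3 * 4 * 4, TRUE), c(3, 4, 4)), c(2, 2, 2))
  write_stack(v8, f)
  expect_identical(read_stack(f)$data, v8$data)  # 8-bit path
})

test_that("a paper-scale 600-slice stack reads back with the right shape", {
  f <- withr::local_tempfile(fileext = ".tif")
  a <- array(0L, c(600, 64, 64))
  a[, 32, 32] <- 200L
  write_stack(volume_image(a, c(5, 2, 2)), f)
  v <- read_stack(f)
  expect_identical(dim(v), c(600L, 64L, 64L))
  expect_equal(sum(v$data), sum(a))
})

test_that("the TIFF writer agrees with an independent reader and vice versa", {
  f <- withr::local_tempfile(fileext = ".tif")
  set.seed(3)
  v <- volume_image(array(sample(0:60000, 3 * 5 * 9, TRUE), c(3, 5, 9)), c(1, 1, 1))
  write_stack(v, f)
  py <- sprintf(
    "import tifffile; a = tifffile.imread(%s); print(a.shape[0], a.shape[1], a.shape[2], int(a.sum()))",
    shQuote(f))
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  expect_identical(out, sprintf("3 5 9 %d", sum(v$data)))

  # and read a file written by the independent implementation
  f2 <- withr::local_tempfile(fileext = ".tif")
  py2 <- sprintf(
    "import tifffile, numpy as np; rng = np.random.default_rng(5); a = rng.integers(0, 65535, (4, 6, 6), dtype=np.uint16); tifffile.imwrite(%s, a, photometric='minisblack', compression=None); print(int(a.sum()))",
    shQuote(f2))
  s <- as.numeric(system2("python", c("-c", shQuote(py2)), stdout = TRUE))
  v2 <- read_stack(f2, c(1, 1, 1))
  expect_identical(dim(v2), c(4L, 6L, 6L))
  expect_equal(sum(v2$data), s)
})

test_that("malformed TIFF input fails with descriptive errors", {
  expect_error(read_stack(file.path(tempdir(), "nope.tif")), "not found")
  f <- withr::local_tempfile(fileext = ".tif")
  writeBin(as.raw(c(0x49, 0x49, 42, 0)), f)
  expect_error(read_stack(f), "truncated|TIFF")
  writeBin(charToRaw("not a tiff at all, just text"), f)
  expect_error(read_stack(f), "byte-order")
})

test_that("SpatialGraph files round-trip a hand-built Y graph", {
  sk <- y_skeleton(arm = 10)
  g <- measure_lengths(build_graph(sk), c(1, 1, 1))
  f <- withr::local_tempfile(fileext = ".am")
  write_spatial_graph(g, f)
  txt <- readLines(f)
  expect_identical(txt[1], "# AmiraMesh 3D ASCII 2.0")
  expect_true(any(grepl("define VERTEX 4", txt)))
  expect_true(any(grepl("define EDGE 3", txt)))

  g2 <- parse_spatial_graph(f)
  expect_identical(nrow(g2$nodes), nrow(g$nodes))
  expect_identical(length(g2$segments), length(g$segments))
  expect_identical(vapply(g2$segments, function(s) nrow(s$points), 0L),
                   vapply(g$segments, function(s) nrow(s$points), 0L))
  for (i in seq_along(g$segments))
    expect_lt(max(abs(g2$segments[[i]]$points - g$segments[[i]]$points)), 1e-4)
  expect_identical(sort(g2$nodes$degree), sort(g$nodes$degree))
  expect_euler(g2)
})

test_that("SpatialGraph export rejects empty graphs and truncated files", {
  empty <- build_graph(skeleton_from_voxels(matrix(0L, 0, 3), c(4, 4, 4)))
  expect_error(write_spatial_graph(empty, tempfile()), "nothing to write")

  sk <- y_skeleton(arm = 5)
  g <- measure_lengths(build_graph(sk), c(1, 1, 1))
  f <- withr::local_tempfile(fileext = ".am")
  write_spatial_graph(g, f)
  txt <- readLines(f)
  writeLines(txt[seq_len(which(trimws(txt) == "@4")[1] - 1)], f)
  expect_error(parse_spatial_graph(f), "@4")
})

test_that("metrics serialise losslessly to JSON and tabulate to CSV", {
  sk <- y_skeleton(arm = 10)
  g <- identify_networks(measure_lengths(build_graph(sk), c(2, 2, 2)))
  tissue <- binary_mask(array(TRUE, c(10, 20, 20)), c(2, 2, 2), "tissue")
  m <- summarize_network(g, tissue)

  fj <- withr::local_tempfile(fileext = ".json")
  write_metrics(m, fj, "json")
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$total_length, m$total_length)
  expect_equal(back$n_segments, m$n_segments)
  expect_equal(back$density_length, m$density_length)
  expect_equal(as.data.frame(back$length_histogram)$pct, m$length_histogram$pct)

  fc <- withr::local_tempfile(fileext = ".csv")
  write_metrics(list(a = m, b = m), fc, "csv")
  tab <- utils::read.csv(fc, check.names = FALSE)
  expect_identical(nrow(tab), 2L)
  expect_true(any(grepl("^length_pct\\[", names(tab))))

  expect_error(write_metrics(m, fc, "parquet"), "unknown format")

  zero <- hevquant:::.zero_network_metrics()
  write_metrics(zero, fc, "csv")
  tz <- utils::read.csv(fc)
  expect_equal(tz$total_length, 0)
  expect_equal(tz$n_segments, 0)
})
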