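test_that("preprocess smooths without creating or destroying signal", {
  v <- volume_image(array(runif(6 * 6 * 6), c(6, 6, 6)), c(2, 2, 2))
  expect_identical(preprocess(v, 0), v)                       # sigma 0: identity
  expect_error(preprocess(v, -1), "non-negative")

  cst <- volume_image(array(7, c(8, 8, 8)), c(1, 1, 1))
  expect_equal(preprocess(cst, 2)$data, cst$data)             # constant invariant

  imp <- array(0, c(21, 21, 21)); imp[11, 11, 11] <- 1
  sm <- preprocess(volume_image(imp, c(1, 1, 1)), 1)          # sigma = 1 voxel
  expect_lt(max(sm$data), 1)                                  # peak reduced
  expect_lt(abs(sum(sm$data) - 1), 1e-6)                      # mass conserved
  expect_equal(which.max(sm$data), which.max(imp))            # peak stays put
})

test_that("Otsu separates a bimodal phantom to >= 99% agreement with truth", {
  spec <- phantom_spec(shape = c(64, 64, 64), voxel_size = c(2, 2, 2),
                       topology = list(nodes = rbind(c(20, 64, 64), c(108, 64, 64)),
                                       edges = data.frame(from = 1, to = 2, radius_um = 10)),
                       noise_sd = 5, seed = 42)
  ph <- generate_phantom(spec)     # background N(50,5), vessel N(200,5)
  m <- binarize(ph$volume, "otsu")
  thr <- attr(m, "threshold")
  expect_true(thr > 60 && thr < 190)
  agree <- mean(m$data == ph$truth$vessel_mask$data)
  expect_gte(agree, 0.99)
})

test_that("fixed thresholds behave at the extremes and are monotone", {
  v <- volume_image(array(runif(10^3, 0, 100), c(10, 10, 10)), c(1, 1, 1))
  expect_false(any(binarize(v, "fixed", max(v$data))$data))   # empty mask
  expect_true(all(binarize(v, "fixed", min(v$data) - 1)$data))# full mask
  t1 <- sort(runif(5, 10, 90))
  counts <- vapply(t1, function(t) sum(binarize(v, "fixed", t)$data), 0)
  expect_true(all(diff(counts) <= 0))                         # raising removes only
  expect_error(binarize(v, "percentile", 120), "strictly in")
  expect_error(binarize(v, "banana"), "unknown")
})

test_that("clean_mask removes speckle, fills cavities, and is idempotent", {
  a <- array(FALSE, c(10, 10, 10)); a[5, 5, 5] <- TRUE
  m <- binary_mask(a, c(1, 1, 1))
  expect_false(any(clean_mask(m, 2)$data))                    # lone speck gone
  expect_identical(clean_mask(m, 0, FALSE)$data, a)           # floor 0, fill off

  # hollow sealed box -> solid after filling
  b <- array(FALSE, c(12, 12, 12)); b[3:10, 3:10, 3:10] <- TRUE
  hollow <- b; hollow[5:8, 5:8, 5:8] <- FALSE
  filled <- clean_mask(binary_mask(hollow, c(1, 1, 1)), 0, fill_holes = TRUE)
  expect_identical(filled$data, b)

  spec <- phantom_spec(shape = c(48, 48, 48), seed = 9, max_segments = 6)
  ph <- generate_phantom(spec)
  m2 <- binarize(ph$volume, "fixed", 125)
  once <- clean_mask(m2, 27, TRUE)
  twice <- clean_mask(once, 27, TRUE)
  expect_identical(once$data, twice$data)                     # idempotent
})

test_that("tissue volume from an autofluorescence ellipsoid is within 2% of analytic", {
  d <- c(100, 80, 100)
  vol <- array(50, d)
  el <- array(hevquant:::cpp_ellipsoid_mask(d, c(2, 2, 2),
                                            c(100, 80, 100), c(80, 60, 40)), d)
  vol[el] <- 200
  tm <- tissue_mask(volume_image(vol, c(2, 2, 2)), "autofluorescence")
  analytic <- 4 / 3 * pi * 80 * 60 * 40
  expect_lt(abs(mask_volume(tm) - analytic) / analytic, 0.02)
})

test_that("the convex hull envelope contains the vessels it is built from", {
  spec <- phantom_spec(shape = c(48, 48, 48), seed = 4, max_segments = 5)
  ph <- generate_phantom(spec)
  vm <- ph$truth$vessel_mask
  tm <- tissue_mask(vm, "convex_hull")
  expect_true(all(tm$data[vm$data]))                          # vessel subset tissue
  expect_gte(mask_volume(tm), mask_volume(vm))
  expect_error(tissue_mask(binary_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))),
               "empty")
})
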