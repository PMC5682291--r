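test_that("foliage height diversity matches hand-computed Shannon values", {
  mk <- function(props) {
    a <- array(props, c(length(props), 1, 1))
    vertical_profile_stack(a, layer_thickness = 5, pixel_size = 6)
  }
  expect_equal(compute_fhd(mk(c(1)))$values[1, 1], 0)
  expect_equal(compute_fhd(mk(c(0.5, 0.5)))$values[1, 1], log(2))
  expect_equal(compute_fhd(mk(c(0.5, 0.25, 0.25)))$values[1, 1],
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(compute_fhd(mk(c(0.5, 0.25, 0.25)))$values[1, 1], 1.0397,
               tolerance = 1e-4)
  # zero layers contribute nothing; all-zero profile is nodata
  expect_equal(compute_fhd(mk(c(0.5, 0, 0.5)))$values[1, 1], log(2))
  expect_true(is.na(compute_fhd(mk(c(0, 0)))$values[1, 1]))
})

test_that("FHD equals log(n) for uniform profiles and ignores scaling", {
  for (n in 1:10) {
    a <- array(1 / n, c(n, 2, 2))
    fhd <- compute_fhd(vertical_profile_stack(a, 5, 6))
    expect_equal(fhd$values, matrix(log(n), 2, 2), tolerance = 1e-12)
    # proportions are scale free: multiplying the profile changes nothing
    fhd2 <- compute_fhd(vertical_profile_stack(a * 37.5, 5, 6))
    expect_equal(fhd2$values, fhd$values)
  }
})

test_that("band_mean averages the closed wavelength interval", {
  cube <- constant_cube(0.3)
  expect_equal(band_mean(cube, 760, 800), matrix(0.3, 4, 5))
  # single band inside the range is the identity
  v <- array(0.2, c(2, 1, 1)); v[2, , ] <- 0.4
  cb <- reflectance_cube(v, c(700, 750), 2)
  expect_equal(band_mean(cb, 690, 710)[1], 0.2)
  expect_equal(band_mean(cb, 690, 760)[1], 0.3)
  expect_error(band_mean(cb, 900, 950), "900-950")
})

test_that("spectral indices reproduce hand evaluations and flat-cube zeros", {
  cube <- constant_cube(0.3)
  expect_equal(chl_index(cube)$values, matrix(0, 4, 5))
  expect_equal(car_index(cube)$values, matrix(0, 4, 5))
  expect_equal(ewt_index(cube)$values, matrix(0, 4, 5))

  wl <- c(550, 700, 780, 1126, 1193)
  v <- array(NA_real_, c(5, 1, 1))
  v[, 1, 1] <- c(0.1, 0.1, 0.5, 0.5, 0.25)
  cb <- reflectance_cube(v, wl, 2)
  expect_equal(chl_index(cb)$values[1, 1], (10 - 2) * 0.5)
  expect_equal(ewt_index(cb)$values[1, 1], 0.5)

  cb2 <- reflectance_cube(array(c(0.05, 0.1, 0.5, 0.5, 0.6), c(5, 1, 1)),
                          c(515, 700, 780, 1126, 1193), 2)
  expect_equal(car_index(cb2)$values[1, 1], (20 - 10) * 0.5)
  # water band above the reference: negative index retained
  expect_lt(ewt_index(cb2)$values[1, 1], 0)
})

test_that("ewt_index requires bands near its target wavelengths", {
  cb <- constant_cube(0.3, wl = c(550, 700, 780))
  expect_error(ewt_index(cb), "no band within")
})

test_that("zero reflectance in a required window becomes nodata", {
  wl <- c(550, 700, 780, 1126, 1193)
  v <- array(0.3, c(5, 2, 1))
  v[1, 1, 1] <- 0    # zero green reflectance at pixel (1,1)
  v[4, 2, 1] <- 0    # zero 1126 reference at pixel (2,1)
  cb <- reflectance_cube(v, wl, 2)
  expect_true(is.na(chl_index(cb)$values[1, 1]))
  expect_false(is.na(chl_index(cb)$values[2, 1]))
  expect_true(is.na(ewt_index(cb)$values[2, 1]))
})

test_that("aggregate_brightest picks the brightest pixels per block", {
  tr <- trait_raster(matrix(1:9, 3, 3, byrow = TRUE), "CHL", 2)
  # brightness ranks make 7, 8, 9 the brightest
  br <- matrix(0, 3, 3); br[3, ] <- 1
  out <- aggregate_brightest(tr, br, factor = 3)
  expect_equal(out$values[1, 1], 8)
  expect_equal(out$pixel_size, 6)

  # constant block stays constant whatever the brightness
  trc <- trait_raster(matrix(0.7, 3, 3), "CHL", 2)
  expect_equal(aggregate_brightest(trc, matrix(runif(9), 3, 3), 3)$values,
               matrix(0.7, 1, 1))

  # exactly 3 valid pixels: their mean regardless of brightness
  v <- matrix(NA_real_, 3, 3); v[1, 1:3] <- c(1, 2, 6)
  tr3 <- trait_raster(v, "CHL", 2)
  expect_equal(aggregate_brightest(tr3, matrix(9:1, 3, 3), 3)$values[1, 1],
               3)

  # all-nodata block -> nodata; misaligned brightness errors
  trn <- trait_raster(matrix(NA_real_, 3, 3), "CHL", 2)
  expect_true(is.na(aggregate_brightest(trn, br, 3)$values[1, 1]))
  expect_error(aggregate_brightest(tr, matrix(0, 2, 2), 3), "aligned")
})

test_that("aggregate_brightest equals the block mean under uniform brightness",
{
  set.seed(42)
  v <- matrix(runif(36), 6, 6)
  tr <- trait_raster(v, "CHL", 2)
  out <- aggregate_brightest(tr, matrix(1, 6, 6), factor = 3,
                             n_brightest = 9)
  brute <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2)
    brute[i, j] <- mean(v[(i * 3 - 2):(i * 3), (j * 3 - 2):(j * 3)])
  expect_equal(out$values, brute)
})

test_that("normalize_trait min-max scales, clips, and is idempotent", {
  tr <- trait_raster(matrix(c(2, 4, 6), 1, 3), "CH", 6)
  nt <- normalize_trait(tr)
  expect_equal(nt$values, matrix(c(0, 0.5, 1), 1, 3))
  expect_equal(attr(nt, "range_low"), 2)
  expect_equal(attr(nt, "range_high"), 6)

  tr2 <- trait_raster(matrix(c(-1, 0, 3), 1, 3), "CH", 6)
  expect_equal(normalize_trait(tr2)$values, matrix(c(0, 0.25, 1), 1, 3))

  # idempotent on its own output (bounds 0 and 1 are attained)
  expect_equal(normalize_trait(nt)$values, nt$values)

  expect_error(normalize_trait(trait_raster(matrix(5, 2, 2), "CH", 6)),
               "zero range")

  # percentile clip winsorizes the tails
  set.seed(7)
  v <- matrix(c(runif(98), -100, 100), 10, 10)
  ntc <- normalize_trait(trait_raster(v, "CH", 6), clip = c(0.05, 0.95))
  expect_true(all(ntc$values >= 0 & ntc$values <= 1))
  expect_lt(attr(ntc, "range_high"), 100)
})

test_that("forest mask applies threshold, gap fill, and tree threshold", {
  chm <- function(m) canopy_height_model(m, 6)
  # uniform mature canopy: all forest
  expect_true(all(forest_mask(chm(matrix(20, 5, 5)))))

  # tall ring enclosing a 6 m juvenile patch: patch is gap-filled and kept
  m <- matrix(30, 7, 7)
  m[4, 4] <- 6
  fm <- forest_mask(chm(m))
  expect_true(fm[4, 4])

  # enclosed true gap below 4 m: filled by step 2, removed by step 3
  m[4, 4] <- 2
  expect_false(forest_mask(chm(m))[4, 4])

  # isolated low pixels outside any mature region stay excluded
  m2 <- matrix(0, 7, 7)
  m2[2, 2] <- 6
  expect_false(any(forest_mask(chm(m2))))

  # open bay touching the border is not a hole and is not filled
  m3 <- matrix(30, 7, 7)
  m3[1:4, 4] <- 6
  fm3 <- forest_mask(chm(m3))
  expect_false(any(fm3[1:4, 4]))
})

test_that("forest mask is stable when mature canopies grow taller", {
  set.seed(11)
  h <- matrix(runif(400, 0, 30), 20, 20)
  base <- forest_mask(canopy_height_model(h, 6))
  h2 <- ifelse(h >= 10, h + 25, h)
  expect_identical(forest_mask(canopy_height_model(h2, 6)), base)
})

test_that("rgb composite maps traits to channels and paints background", {
  v <- function(x) matrix(x, 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  st <- stack_from_matrices(v(1), v(0), v(0), mask = mask)
  img <- rgb_composite(st, background = c(0.5, 0.5, 0.5))
  expect_equal(img[1, 1, ], c(1, 0, 0))          # pure red = max CH
  expect_equal(img[2, 2, ], c(0.5, 0.5, 0.5))    # masked pixel
  stg <- stack_from_matrices(v(0.5), v(0.5), v(0.5))
  expect_equal(rgb_composite(stg)[1, 1, ], rep(0.5, 3))  # mid grey
  expect_error(rgb_composite(st, channels = c(R = "XX", G = "FHD",
                                              B = "PAI")),
               "unknown trait")
})

test_that("physiological composite uses the CAR/CHL/EWT convention", {
  st <- stack_from_matrices(matrix(1, 2, 2), matrix(0, 2, 2),
                            matrix(0, 2, 2),
                            names = c("CHL", "CAR", "EWT"))
  img <- rgb_composite(st)
  # CHL = 1 drives the green channel
  expect_equal(img[1, 1, ], c(0, 1, 0))
})

test_that("bilinear resampling preserves linear ramps", {
  v <- outer(seq_len(12), rep(1, 12)) * 1.0   # ramp down the rows
  tr <- trait_raster(v, "CH", 2)
  out <- resample_bilinear(tr, 3)
  expect_equal(dim(out$values), c(4, 4))
  expect_equal(out$pixel_size, 6)
  # coarse centres sit at fine rows 2, 5, 8, 11 of the ramp
  expect_equal(out$values[, 1], c(2, 5, 8, 11))
  # constant raster is unchanged
  trc <- trait_raster(matrix(3.3, 12, 12), "CH", 2)
  expect_equal(resample_bilinear(trc, 3)$values, matrix(3.3, 4, 4))
})
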