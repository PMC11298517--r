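test_that("ERD profile samples a line at unit steps", {
  # 46-wide ramp: axis-aligned line reproduces pixel values 0..45
  ramp <- array(rep(0:45, each = 4), dim = c(2, 2, 46))
  p <- extract_erd_profile(ramp, 1, c(1, 1), c(1, 46))
  expect_length(p$positions_px, 46)
  expect_equal(p$intensities[, 1], as.numeric(0:45))
  # zero-length line: single sample at the start voxel
  p0 <- extract_erd_profile(ramp, 1, c(2, 5), c(2, 5))
  expect_equal(p0$intensities[, 1], 4)
  # constant image gives a constant profile
  cst <- array(3, dim = c(1, 8, 8))
  expect_true(all(extract_erd_profile(cst, 1, c(1, 1), c(8, 8))$intensities == 3))
  expect_error(extract_erd_profile(ramp, 1, c(1, 1), c(1, 50)), "out of bounds")
  expect_error(extract_erd_profile(ramp, 9, c(1, 1), c(1, 5)), "out of bounds")
})

test_that("oblique profiles use bilinear interpolation", {
  sl <- outer(1:8, 1:8, function(y, x) as.double(x))  # value = x coordinate
  vol <- array(0, c(1, 8, 8)); vol[1, , ] <- sl
  p <- extract_erd_profile(vol, 1, c(1, 1), c(8, 8))
  # along the diagonal the x coordinate advances by 1/sqrt(2) per step
  expected <- 1 + (p$positions_px) / sqrt(2)
  expect_equal(p$intensities[, 1], expected, tolerance = 1e-9)
})

test_that("profile aggregation gives the t-based 95% CI", {
  mk <- function(vals) {
    v <- array(rep(vals, each = 1), dim = c(1, 1, length(vals)))
    extract_erd_profile(v, 1, c(1, 1), c(1, length(vals)))
  }
  # identical replicates: zero-width CI
  agg0 <- aggregate_profiles(list(mk(c(1, 2, 3)), mk(c(1, 2, 3))))
  expect_equal(agg0$summary$ci95_low, agg0$summary$mean)
  # two replicates 0 and 2 -> mean 1
  agg1 <- aggregate_profiles(list(mk(c(0, 0, 0)), mk(c(2, 2, 2))))
  expect_equal(agg1$summary$mean, rep(1, 3))
  # n = 4 with per-position sd 1 -> half width qt(.975, 3)/2
  vals <- c(0, 2, 1 - sqrt(1 / 2), 1 + sqrt(1 / 2))  # sd exactly 1
  agg2 <- aggregate_profiles(lapply(vals, function(v) mk(rep(v, 5))))
  half <- agg2$summary$mean - agg2$summary$ci95_low
  expect_equal(half, rep(qt(0.975, 3) / 2, 5), tolerance = 1e-9)
  expect_equal(half[1], 1.5912, tolerance = 1e-4)
  expect_error(aggregate_profiles(list(mk(1:3))), "at least 2")
  expect_error(aggregate_profiles(list(mk(1:3), mk(1:4))), "mismatched")
})

test_that("rise distance matches the Gaussian closed form", {
  # 10-90% rise of a Gaussian-blurred step is 2 * qnorm(0.9) * sigma
  for (sg in c(2, 3, 4)) {
    e <- generate_edge_phantom(sg, shape = c(1, 2, 96))
    p <- extract_erd_profile(e, 1, c(1, 1), c(1, 96))
    expect_equal(rise_distance(p), 2 * qnorm(0.9) * sg,
                 tolerance = 0.02 * 2 * qnorm(0.9) * sg)
  }
  # ideal step: distance below one pixel
  st <- generate_edge_phantom(0, shape = c(1, 2, 32))
  expect_lte(rise_distance(extract_erd_profile(st, 1, c(1, 1), c(1, 32))), 1)
  # doubling sigma doubles the distance
  r1 <- rise_distance(extract_erd_profile(generate_edge_phantom(3, shape = c(1, 2, 128)),
                                          1, c(1, 1), c(1, 128)))
  r2 <- rise_distance(extract_erd_profile(generate_edge_phantom(6, shape = c(1, 2, 128)),
                                          1, c(1, 1), c(1, 128)))
  expect_equal(r2 / r1, 2, tolerance = 0.03)
  expect_error(rise_distance(rep(1, 10)), "flat")
})

test_that("region signatures recover the phantom signature table", {
  ph <- generate_liver_phantom(noiseless_spec(seed = 8))
  sig <- region_signature(ph$clean, ph$truth)
  S_true <- ph$spec$class_signature
  corrected <- pmax(sweep(S_true, 2, S_true["background", ], "-"), 0)
  expected <- sweep(corrected, 2, apply(corrected, 2, max), "/")
  expect_equal(sig$S, expected[rownames(sig$S), colnames(sig$S)],
               tolerance = 1e-6)
  # per-channel ranking matches the generator in every channel
  for (ch in colnames(sig$S))
    expect_equal(order(sig$S[, ch]), order(expected[, ch]))
})

test_that("signature normalization and background rules hold", {
  # single nonbackground region scores 1 in every channel with signal
  lab <- array(c(rep(1L, 8), rep(2L, 8)), dim = c(2, 2, 4))
  rlv <- region_label_volume(lab, c("1" = "background", "2" = "liver"))
  ch <- array(c(rep(0.1, 8), rep(0.8, 8)), dim = c(2, 2, 4))
  mcv <- multichannel_volume(list("405" = ch, "785" = 2 * ch))
  sig <- region_signature(mcv, rlv)
  expect_equal(unname(sig$S["liver", ]), c(1, 1))
  expect_equal(unname(sig$raw_means["liver", "405"]), 0.7)
  # background-only means are zero after correction
  expect_equal(unname(sig$raw_means["background", ]), c(0, 0))
  # empty region and missing background produce errors
  expect_error(region_signature(mcv, region_label_volume(lab, c("1" = "a", "2" = "b", "3" = "c"))),
               "empty region")
  expect_error(region_signature(mcv, rlv, background_class = "nope"),
               "not present")
})

test_that("channel subtraction clips at zero and honors normalization", {
  a <- array(c(1, 0.25, 0.5, 0), dim = c(1, 2, 2))
  b <- array(c(0.25, 1, 0.5, 0.1), dim = c(1, 2, 2))
  s <- subtract_channels(a, b)
  expect_equal(as.vector(s), c(0.75, 0, 0, 0))
  expect_true(all(subtract_channels(b, a) >= 0))
  # where both directions are considered, they partition |a - b|
  expect_equal(subtract_channels(a, b) + subtract_channels(b, a),
               abs(a - b))
  expect_equal(subtract_channels(a, a), array(0, dim(a)))
  expect_error(subtract_channels(a, array(0, c(1, 2, 3))), "shape")
  # normalize_first maps both inputs through the percentile rescale
  set.seed(7)
  x <- array(runif(64, 0, 100), c(4, 4, 4)); y <- array(runif(64, 0, 50), c(4, 4, 4))
  sn <- subtract_channels(x, y, normalize_first = TRUE, p_low = 0, p_high = 100)
  expect_true(max(sn) <= 1 && min(sn) >= 0)
})

test_that("inversion is an involution on [0,1] volumes", {
  set.seed(8)
  v <- array(runif(27), dim = c(3, 3, 3))
  expect_equal(invert_volume(invert_volume(v)), v)
  expect_equal(invert_volume(array(0, c(1, 1, 1)))[1], 1)
  expect_equal(mean(invert_volume(v)), 1 - mean(v))
  expect_error(invert_volume(v * 2), "\\[0, 1\\]")
})

test_that("sharpness is zero for constant slices and falls with blur", {
  expect_equal(sharpness_power_spectrum(matrix(5, 32, 32)), 0)
  set.seed(9)
  img <- matrix(runif(96 * 96), 96, 96)
  vals <- vapply(c(0, 1, 2, 4), function(sg) {
    sl <- if (sg == 0) img else as.matrix(EBImage::gblur(img, sg))
    sharpness_power_spectrum(sl)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("sharpness is invariant to affine intensity rescaling", {
  set.seed(10)
  img <- matrix(runif(64 * 64), 64, 64)
  s0 <- sharpness_power_spectrum(img)
  expect_equal(sharpness_power_spectrum(3.7 * img + 11), s0,
               tolerance = 1e-6 * s0)
  # volumes are processed slice-wise
  vol <- array(runif(4 * 32 * 32), dim = c(4, 32, 32))
  expect_length(sharpness_power_spectrum(vol), 4)
})

test_that("dice matches hand counts and a brute-force oracle", {
  m <- function(v) array(v, dim = c(2, 2, 2))
  a <- m(c(1, 1, 1, 1, 0, 0, 0, 0)); b <- m(c(1, 1, 0, 0, 1, 1, 0, 0))
  expect_equal(dice(a, b), 0.5)  # |A|=4, |B|=4, |A^B|=2
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, m(c(0, 0, 0, 0, 1, 1, 1, 1))), 0)
  expect_warning(d0 <- dice(m(rep(0, 8)), m(rep(0, 8))), "empty")
  expect_equal(d0, 1)
  expect_error(dice(a, array(0, c(2, 2, 3))), "shape")
  # symmetry + brute-force voxel counting on random 8^3 masks
  set.seed(11)
  for (i in 1:20) {
    x <- array(runif(512) < 0.3, dim = c(8, 8, 8))
    y <- array(runif(512) < 0.3, dim = c(8, 8, 8))
    inter <- 0; sx <- 0; sy <- 0
    for (j in 1:512) {
      inter <- inter + (x[j] && y[j]); sx <- sx + x[j]; sy <- sy + y[j]
    }
    oracle <- 2 * inter / (sx + sy)
    expect_equal(dice(x, y), oracle)
    expect_equal(dice(y, x), oracle)
    expect_gte(dice(x, y), 0); expect_lte(dice(x, y), 1)
  }
})
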