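test_that("bilateral fusion is plain float addition with diagnostics", {
  set.seed(1)
  l <- array(sample.int(40000, 24, replace = TRUE), dim = c(2, 3, 4))
  r <- array(sample.int(40000, 24, replace = TRUE), dim = c(2, 3, 4))
  f <- fuse_bilateral(l, r)
  expect_s3_class(f, "fusion_result")
  expect_equal(f$fused, array(as.double(l) + as.double(r), dim = dim(l)))
  # additive identity and commutativity
  z <- array(0L, dim = dim(r))
  expect_equal(fuse_bilateral(z, r)$fused, array(as.double(r), dim = dim(r)))
  expect_equal(fuse_bilateral(l, r)$fused, fuse_bilateral(r, l)$fused)
})

test_that("fusion reports (but never applies) 16-bit saturation", {
  l <- array(c(40000L, 10L, 0L, 0L), dim = c(1, 2, 2))
  r <- array(c(40000L, 10L, 0L, 0L), dim = c(1, 2, 2))
  f <- fuse_bilateral(l, r)
  expect_equal(f$fused[1, 1, 1], 80000)
  expect_equal(f$clipped_fraction, 1 / 4)
  expect_equal(fuse_bilateral(l * 0L, r)$clipped_fraction, 0)
})

test_that("fusion rejects mismatched shapes and mixed channels", {
  expect_error(fuse_bilateral(array(0, c(1, 2, 2)), array(0, c(1, 2, 3))),
               "shape mismatch")
  a <- array(1, c(1, 2, 2)); b <- array(1, c(1, 2, 2))
  attr(a, "metadata") <- acquisition_metadata(405, side = "left")
  attr(b, "metadata") <- acquisition_metadata(640, side = "right")
  expect_error(fuse_bilateral(a, b), "different excitation")
})

test_that("fusion is linear in scalar intensity scaling", {
  set.seed(2)
  l <- array(runif(60), dim = c(3, 4, 5)); r <- array(runif(60), dim = c(3, 4, 5))
  a <- 2.7
  expect_equal(fuse_bilateral(a * l, a * r)$fused,
               a * fuse_bilateral(l, r)$fused, tolerance = 1e-12)
})

test_that("trilinear downsampling averages blocks and scales voxel size", {
  v <- array(as.double(0:63), dim = c(4, 4, 4))  # raster order 0..63
  out <- downsample_trilinear(v, 4)
  expect_equal(as.vector(out), 31.5)
  cst <- downsample_trilinear(array(7, c(6, 6, 6)), c(2, 3, 1))
  expect_true(all(cst == 7))
  expect_identical(dim(cst), c(3L, 2L, 6L))
  x <- array(runif(4 * 8 * 8), dim = c(4, 8, 8))
  attr(x, "metadata") <- acquisition_metadata(488, voxel_size_um = c(5, 5, 5))
  y <- downsample_trilinear(x, 4)
  expect_equal(attr(y, "metadata")$voxel_size_um, c(20, 20, 20))
  expect_error(downsample_trilinear(v, 0), "positive")
})

test_that("downsampling conserves the mean; partial blocks averaged as-is", {
  set.seed(3)
  v <- array(runif(8 * 12 * 16), dim = c(8, 12, 16))
  expect_equal(mean(downsample_trilinear(v, c(2, 4, 4))), mean(v),
               tolerance = 1e-12)
  # trailing partial block: 5 columns at factor 2 -> last block is 1 wide
  w <- array(as.double(1:5), dim = c(1, 1, 5))
  out <- downsample_trilinear(w, c(1, 1, 2))
  expect_equal(as.vector(out), c(1.5, 3.5, 5))
})

test_that("block downsampling agrees with a brute-force loop oracle", {
  set.seed(4)
  v <- array(runif(5 * 7 * 6), dim = c(5, 7, 6))
  f <- c(2, 3, 2)
  oracle <- array(0, dim = ceiling(dim(v) / f))
  for (i in seq_len(dim(oracle)[1]))
    for (j in seq_len(dim(oracle)[2]))
      for (k in seq_len(dim(oracle)[3])) {
        zi <- ((i - 1) * f[1] + 1):min(i * f[1], dim(v)[1])
        yi <- ((j - 1) * f[2] + 1):min(j * f[2], dim(v)[2])
        xi <- ((k - 1) * f[3] + 1):min(k * f[3], dim(v)[3])
        oracle[i, j, k] <- mean(v[zi, yi, xi])
      }
  expect_equal(downsample_trilinear(v, f), oracle, tolerance = 1e-12)
})

test_that("exposure normalization divides once and only once", {
  md <- acquisition_metadata(785, exposure_ms = 1040)
  v <- array(1040, dim = c(2, 3, 3))
  out <- normalize_exposure(v, md)
  expect_true(all(out == 1))
  expect_true(attr(out, "metadata")$normalized)
  expect_error(normalize_exposure(out), "already")
  # exposure 1 ms is the identity; ratios are unchanged
  md1 <- acquisition_metadata(405, exposure_ms = 1)
  w <- array(runif(18), dim = c(2, 3, 3))
  expect_equal(normalize_exposure(w, md1)[seq_along(w)], w[seq_along(w)])
  out2 <- normalize_exposure(w, md)
  expect_equal(out2[2] / out2[5], w[2] / w[5])
})

test_that("histogram normalization maps percentiles linearly to [0,1]", {
  ramp <- array(seq(0, 100, length.out = 101), dim = c(1, 1, 101))
  out <- normalize_histogram(ramp, 0, 100)
  expect_equal(out[1, 1, 26], 0.25, tolerance = 1e-12)
  expect_equal(range(out), c(0, 1))
  set.seed(5)
  v <- array(rnorm(4000), dim = c(10, 20, 20))
  n <- normalize_histogram(v)
  expect_equal(min(n), 0); expect_equal(max(n), 1)
  expect_warning(z <- normalize_histogram(array(3, c(2, 2, 2))), "zero dynamic")
  expect_true(all(z == 0))
  expect_error(normalize_histogram(v, 50, 10), "p_low")
})

test_that("histogram normalization is idempotent up to the clip mass", {
  set.seed(6)
  v <- array(rnorm(8000), dim = c(20, 20, 20))
  once <- normalize_histogram(v, 1, 99)
  twice <- normalize_histogram(once, 1, 99)
  # re-normalizing only drifts by the clipped-tail quantile offsets
  expect_lt(max(abs(twice - once)), 0.01)
})
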