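test_that("to_grayscale averages channels and keeps achromatic pixels", {
  img <- array(0, dim = c(2, 2, 3))
  img[1, 1, ] <- c(30, 60, 90)
  img[1, 2, ] <- c(7, 7, 7)
  img[2, 1, ] <- c(0, 0, 0)
  g <- to_grayscale(img)
  expect_equal(g[1, 1], 60)
  expect_equal(g[1, 2], 7)
  expect_equal(g[2, 1], 0)
  expect_error(to_grayscale(array(0, dim = c(2, 2, 2))), "H x W x 3")
  ## Rec. 601 weights behind the flag
  expect_equal(to_grayscale(img, weights = "rec601")[1, 1],
               0.299 * 30 + 0.587 * 60 + 0.114 * 90)
})

test_that("quantization maps the source range to [0,255] with clipping", {
  expect_equal(as.vector(quantize_8bit(16383, bit_depth = 14)), 255)
  v <- matrix(c(0, 1, 30, 254, 255), 1)
  expect_equal(as.vector(quantize_8bit(v, bit_depth = 8)), as.vector(v))
  expect_equal(as.vector(quantize_8bit(-3, bit_depth = 8)), 0)
  expect_equal(as.vector(quantize_8bit(300, bit_depth = 8)), 255)
  expect_error(quantize_8bit(matrix(c(1, NaN), 1)), "NaN")
  expect_error(quantize_8bit(matrix(c(1, Inf), 1)), "NaN|infinite")
})

test_that("decimate output dims are floor(dim/factor) for all small sizes", {
  for (f in 1:4) {
    for (W in seq(16L, 64L, by = 7L)) {
      img <- matrix(runif(32 * W, 0, 255), 32, W)
      out <- decimate(img, f)
      expect_identical(dim(out), c(32L %/% f, W %/% f))
    }
  }
  expect_error(decimate(matrix(0, 32, 32), 0), "positive integer")
  expect_error(decimate(matrix(0, 4, 4), 4), "at least 2")
})

test_that("decimation preserves constants up to passband ripple", {
  img <- matrix(128, 64, 64)
  out <- decimate(img, 2)
  ## four zero-phase passes (two per axis), each bounded by the 0.05 dB
  ## design ripple (10% slack for coefficient roundoff)
  expect_true(all(abs(out - 128) < 1.1 * 128 * (1 - 10^(-4 * 0.05 / 20))))
  ## and the output is spatially flat
  expect_lt(diff(range(out)), 1e-8)
})

test_that("zero-phase filtering preserves even symmetry", {
  x <- exp(-((1:64) - 32.5)^2 / 50) * 100      # even-symmetric about 32.5
  flt <- signal::cheby1(8, 0.05, 0.4)
  y <- viscomplex:::zero_phase_filter(x, flt)
  expect_lt(max(abs(y - rev(y))), 1e-9)
})

test_that("the order-8 Chebyshev design attenuates Nyquist by over 40 dB", {
  flt <- signal::cheby1(8, 0.05, 0.4)
  ## evaluate |H| at the Nyquist frequency (z = -1)
  hny <- abs(sum(flt$b * (-1)^(seq_along(flt$b) - 1)) /
             sum(flt$a * (-1)^(seq_along(flt$a) - 1)))
  expect_lt(20 * log10(hny), -40)
  ## a pure Nyquist checkerboard is essentially annihilated: the residual
  ## alternating amplitude of the filtered field is under 1% of the input
  cb <- 127.5 + 127.5 * outer(1:64, 1:64, function(i, j) (-1)^(i + j))
  filt <- viscomplex:::zero_phase_cols(cb, flt)
  filt <- t(viscomplex:::zero_phase_cols(t(filt), flt))
  resid <- mean(filt * outer(1:64, 1:64, function(i, j) (-1)^(i + j)))
  expect_lt(abs(resid), 0.01 * 127.5)
})

test_that("raster round-trips preserve pixel values and bit depth", {
  tmp <- withr::local_tempfile(fileext = ".png")
  m <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  png::writePNG(m / 255, tmp)
  got <- load_image(tmp)
  expect_equal(unclass(got), m, ignore_attr = TRUE)
  expect_identical(attr(got, "bit_depth"), 8L)

  ## 16-bit TIFF keeps its native scale until quantization
  tmp16 <- withr::local_tempfile(fileext = ".tif")
  m16 <- matrix(c(0L, 1000L, 30000L, 65535L), 2, 2)
  tiff::writeTIFF(m16 / 65535, tmp16, bits.per.sample = 16L)
  got16 <- load_image(tmp16)
  expect_equal(unclass(got16), m16, ignore_attr = TRUE)
  expect_identical(attr(got16, "bit_depth"), 16L)
  expect_equal(as.vector(quantize_8bit(got16)),
               as.vector(round(m16 / 65535 * 255)))

  ## colour PNG comes back as H x W x 3
  tmpc <- withr::local_tempfile(fileext = ".png")
  arr <- array(runif(2 * 2 * 3), dim = c(2, 2, 3))
  png::writePNG(arr, tmpc)
  gotc <- load_image(tmpc)
  expect_identical(dim(gotc), c(2L, 2L, 3L))

  ## black image reads as all zeros
  tmpb <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0, 2, 2), tmpb)
  expect_true(all(unclass(load_image(tmpb)) == 0))
})

test_that("unreadable or missing files raise format errors naming the path", {
  expect_error(load_image("no/such/file.png"), "no/such/file.png")
  tmp <- withr::local_tempfile(fileext = ".png")
  writeBin(as.raw(c(137, 80, 78, 71, 1, 2, 3)), tmp)  # truncated PNG
  expect_error(load_image(tmp), "cannot read image file")
  tmpu <- withr::local_tempfile(fileext = ".bmp")
  writeBin(raw(10), tmpu)
  expect_error(load_image(tmpu), "unsupported")
})

test_that("display geometry reproduces the presentation parameters", {
  ## 2144 x 1424 image at 37 x 25.12 degrees of visual angle
  expect_equal(nyquist_cpd(2144, 37), 28.97, tolerance = 0.005)
  expect_equal(nyquist_cpd(1424, 25.12), 28.34, tolerance = 0.005)
  ## 0.2505 mm pixel pitch viewed from 80 cm
  expect_equal(visual_angle_deg(1424, 0.2505, 80), 25.12, tolerance = 0.005)
})
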