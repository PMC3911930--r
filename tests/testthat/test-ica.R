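test_that("patch sampling respects the non-overlapping grid", {
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  ## a 32x32 image holds at most (32/16)^2 = 4 non-overlapping 16x16 patches
  P <- sample_patches(list(img), 4, 16, seed = 1)
  expect_identical(dim(P), c(4L, 256L))
  expect_error(sample_patches(list(img), 5, 16, seed = 1), "4")
  ## patches are actual grid cells, vectorised column-major
  P1 <- sample_patches(list(img), 4, 16, seed = 9)
  cells <- list(img[1:16, 1:16], img[17:32, 1:16],
                img[1:16, 17:32], img[17:32, 17:32])
  for (k in 1:4) {
    hit <- any(vapply(cells, function(cc)
      isTRUE(all.equal(as.vector(cc), P1[k, ])), logical(1)))
    expect_true(hit)
  }
  expect_identical(dim(sample_patches(list(img), 0, 16, seed = 1)),
                   c(0L, 256L))
  expect_identical(sample_patches(list(img), 3, 16, seed = 5),
                   sample_patches(list(img), 3, 16, seed = 5))
  expect_error(sample_patches(list(matrix(0, 8, 8)), 1, 16, seed = 1),
               "at least patch_size")
})

test_that("the learned bank has one filter per dimension and exactly one DC", {
  bank <- vx_bank8()
  expect_identical(dim(bank$filters), c(64L, 64L))
  expect_length(bank$dc_index, 1L)
  ## all non-DC filters are unit-norm and zero-mean
  nondc <- bank$filters[-bank$dc_index, ]
  expect_lt(max(abs(rowMeans(nondc))), 1e-6)
  expect_equal(unname(rowSums(nondc^2)), rep(1, 63), tolerance = 1e-9)
  ## the DC filter's spectrum is concentrated at zero frequency
  dc <- matrix(bank$filters[bank$dc_index, ], 8, 8)
  Fm <- Mod(stats::fft(dc))
  expect_identical(which.max(Fm), 1L)
})

test_that("learning is deterministic given seed and data", {
  P <- sample_patches(vx_corpus()[1:4], 300, 8, seed = 7)
  b1 <- learn_filters(P, iterations = 30, seed = 99)
  b2 <- learn_filters(P, iterations = 30, seed = 99)
  expect_identical(b1$filters, b2$filters)
  expect_identical(b1$dc_index, b2$dc_index)
})

test_that("degenerate patch sets are rejected", {
  P <- matrix(5, 300, 64)                      # rank-deficient covariance
  attr(P, "patch_size") <- 8L
  expect_error(learn_filters(P), "rank deficient")
  Pfew <- matrix(runif(10 * 64), 10, 64)
  attr(Pfew, "patch_size") <- 8L
  expect_error(learn_filters(Pfew), "at least as many patches")
})

test_that("Gabor fitting recovers known parameters", {
  ## single exact case: f = 0.25 cpp at 45 degrees
  g <- viscomplex:::gabor_patch(16, 1, 0, 0, 3, 3, 0.25, pi / 4, 0)
  fit <- fit_gabor(as.vector(g), 16)
  expect_lt(abs(fit$center_frequency - 0.25) / 0.25, 0.10)
  dth <- abs(fit$orientation - 45) %% 180
  expect_lt(min(dth, 180 - dth), 5)
  expect_lt(fit$fit_residual, 0.05)
  ## closed-form half-amplitude bandwidth of the Gaussian envelope
  sigma_f <- 1 / (2 * pi * 3)
  a <- sigma_f * sqrt(2 * log(2))
  bw_true <- log2((0.25 + a) / (0.25 - a))
  expect_lt(abs(fit$bandwidth - bw_true) / bw_true, 0.10)
  expect_error(fit_gabor(rep(1, 256), 16), "constant")
})

test_that("Gabor recovery holds across 20 random synthetic filters", {
  set.seed(51)
  ferr <- oerr <- berr <- numeric(20)
  for (i in 1:20) {
    f0 <- runif(1, 0.12, 0.42)
    th <- runif(1, 0, pi)
    sg <- runif(1, 2, 4.5)
    ph <- runif(1, 0, 2 * pi)
    g <- viscomplex:::gabor_patch(16, 1, runif(1, -2, 2), runif(1, -2, 2),
                                  sg, sg * runif(1, 0.7, 1.3), f0, th, ph)
    fit <- fit_gabor(as.vector(g), 16)
    ferr[i] <- abs(fit$center_frequency - f0) / f0
    d <- abs(fit$orientation - th * 180 / pi) %% 180
    oerr[i] <- min(d, 180 - d)
    sigma_f <- 1 / (2 * pi * sg)
    a <- sigma_f * sqrt(2 * log(2))
    bw_true <- if (f0 > a) log2((f0 + a) / (f0 - a)) else Inf
    berr[i] <- abs(fit$bandwidth - bw_true) / bw_true
  }
  expect_lt(median(ferr), 0.10)
  expect_lt(median(oerr), 5)
  expect_lt(median(berr), 0.10)
})

test_that("bank characterisation summarises frequency content", {
  ## hand-built low-frequency bank reports a low-frequency majority
  set.seed(52)
  lows <- t(sapply(1:15, function(i) {
    as.vector(viscomplex:::gabor_patch(8, 1, 0, 0, 2.5, 2.5,
                                       runif(1, 0.06, 0.15),
                                       runif(1, 0, pi), 0))
  }))
  fake <- structure(list(filters = rbind(lows, rep(1 / 8, 64)),
                         dc_index = 16L, patch_size = 8L, dc_constant = 0),
                    class = "ic_filter_bank")
  ch <- characterize_bank(fake)
  expect_identical(nrow(ch), 15L)
  expect_lt(attr(ch, "frac_high_frequency"), 0.5)
  ## empty bank yields an empty table
  empty <- structure(list(filters = matrix(1 / 8, 1, 64), dc_index = 1L,
                          patch_size = 8L, dc_constant = 0),
                     class = "ic_filter_bank")
  expect_identical(nrow(characterize_bank(empty)), 0L)
})

test_that("filter banks survive a JSON round trip", {
  bank <- vx_bank8()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_filter_bank(bank, tmp)
  back <- read_filter_bank(tmp)
  expect_equal(back$filters, bank$filters, tolerance = 1e-12)
  expect_identical(back$dc_index, bank$dc_index)
  expect_identical(back$patch_size, bank$patch_size)
})
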