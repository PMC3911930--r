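## Separable convolution with mirror-reflect borders.
conv_sep <- function(img, kernel) {
  k <- length(kernel)
  p <- (k - 1L) %/% 2L
  pad_filter <- function(x) {
    n <- length(x)
    xp <- c(x[(p + 1L):2L], x, x[(n - 1L):(n - p)])
    as.vector(stats::filter(xp, kernel, sides = 2L))[(p + 1L):(p + n)]
  }
  out <- apply(img, 2L, pad_filter)
  t(apply(out, 1L, pad_filter))
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Edge-perimeter length
#'
#' Counts edge pixels in a Canny edge map — the perimeter-detection baseline
#' for visual complexity. Pipeline: Gaussian smoothing, Sobel gradients,
#' non-maximum suppression along the quantised gradient direction, then
#' hysteresis thresholding (weak-edge components are kept only if they
#' contain a strong-edge pixel; 8-connectivity via [EBImage::bwlabel()]).
#'
#' Thresholds are fixed fractions (`low`/`high`, defaults 0.10/0.20 — the
#' classic Canny convention) of the maximal Sobel magnitude attainable on
#' the image's `[0, 255]` scale, so edge counts are comparable across
#' images. Quantile-based thresholds (`threshold_mode = "quantile"`, with
#' `low`/`high` read as quantiles of the image's own gradient magnitudes)
#' are available but adapt to each image and therefore measure edge
#' *salience relative to the scene*, not absolute edge content.
#'
#' @param img Grayscale matrix on the 8-bit `[0, 255]` scale.
#' @param sigma Gaussian smoothing s.d. in pixels (default 1.0).
#' @param low,high Hysteresis thresholds: fractions of the maximal gradient
#'   (`"absolute"`, defaults 0.10 / 0.20) or quantiles of the observed
#'   gradient magnitudes (`"quantile"`).
#' @param threshold_mode `"absolute"` (default) or `"quantile"`.
#' @return Number of edge pixels (nonnegative integer).
#' @export
perimeter_length <- function(img, sigma = 1.0, low = 0.10, high = 0.20,
                             threshold_mode = c("absolute", "quantile")) {
  threshold_mode <- match.arg(threshold_mode)
  img <- as.matrix(img)
  sm <- conv_sep(img, gaussian_kernel(sigma))
  H <- nrow(sm); W <- ncol(sm)
  if (H < 3L || W < 3L) return(0L)
  ## Sobel gradients on the interior (replicated border)
  pad <- rbind(sm[1, , drop = FALSE], sm, sm[H, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, W, drop = FALSE])
  i <- 2:(H + 1L); j <- 2:(W + 1L)
  gx <- (pad[i - 1, j + 1] + 2 * pad[i, j + 1] + pad[i + 1, j + 1]) -
        (pad[i - 1, j - 1] + 2 * pad[i, j - 1] + pad[i + 1, j - 1])
  gy <- (pad[i + 1, j - 1] + 2 * pad[i + 1, j] + pad[i + 1, j + 1]) -
        (pad[i - 1, j - 1] + 2 * pad[i - 1, j] + pad[i - 1, j + 1])
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(0L)
  ## non-maximum suppression in 4 quantised directions
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  dir <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
         ifelse(ang < 67.5, 45L, ifelse(ang < 112.5, 90L, 135L)))
  magp <- matrix(0, H + 2L, W + 2L)
  magp[i, j] <- mag
  n1 <- matrix(0, H, W); n2 <- matrix(0, H, W)
  sel <- dir == 0L                       # horizontal gradient -> compare left/right
  n1[sel] <- magp[i, j + 1][sel]; n2[sel] <- magp[i, j - 1][sel]
  sel <- dir == 90L
  n1[sel] <- magp[i + 1, j][sel]; n2[sel] <- magp[i - 1, j][sel]
  sel <- dir == 45L
  n1[sel] <- magp[i + 1, j + 1][sel]; n2[sel] <- magp[i - 1, j - 1][sel]
  sel <- dir == 135L
  n1[sel] <- magp[i + 1, j - 1][sel]; n2[sel] <- magp[i - 1, j + 1][sel]
  nms <- ifelse(mag >= n1 & mag >= n2, mag, 0)
  if (threshold_mode == "absolute") {
    ## maximal Sobel response on the 8-bit scale: 4 * 255 per axis
    scale_max <- 4 * 255 * sqrt(2)
    t_lo <- low * scale_max
    t_hi <- high * scale_max
  } else {
    t_lo <- stats::quantile(mag, low, names = FALSE)
    t_hi <- stats::quantile(mag, high, names = FALSE)
  }
  strong <- nms > t_hi
  weak <- nms > t_lo
  if (!any(strong)) return(0L)
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  sum(lab %in% keep[keep > 0])
}

#' JPEG-encoded file size
#'
#' Encodes the (8-bit grayscale) image as JPEG in memory at the given quality
#' and returns the byte count — the information-theoretic file-size baseline.
#' No metadata beyond the minimal JFIF header is written, so the count is
#' deterministic.
#'
#' @param img Grayscale matrix with values in `[0, 255]`.
#' @param quality Integer JPEG quality in `[1, 100]` (default 75).
#' @return Encoded size in bytes.
#' @export
jpeg_size <- function(img, quality = 75L) {
  if (!is.numeric(quality) || length(quality) != 1L || quality < 1 ||
      quality > 100) {
    stop("`quality` must be in [1, 100]", call. = FALSE)
  }
  img <- as.matrix(img)
  if (min(img) < 0 || max(img) > 255) {
    stop("`img` must be on the 8-bit [0, 255] scale", call. = FALSE)
  }
  length(jpeg::writeJPEG(img / 255, raw(), quality = quality / 100))
}

## One 2-D orthogonal Haar analysis step: returns LL, LH, HL, HH.
haar_step <- function(m) {
  od <- seq(1L, nrow(m), 2L); ev <- od + 1L
  lo <- (m[od, , drop = FALSE] + m[ev, , drop = FALSE]) / sqrt(2)
  hi <- (m[od, , drop = FALSE] - m[ev, , drop = FALSE]) / sqrt(2)
  odc <- seq(1L, ncol(m), 2L); evc <- odc + 1L
  list(
    LL = (lo[, odc, drop = FALSE] + lo[, evc, drop = FALSE]) / sqrt(2),
    LH = (lo[, odc, drop = FALSE] - lo[, evc, drop = FALSE]) / sqrt(2),
    HL = (hi[, odc, drop = FALSE] + hi[, evc, drop = FALSE]) / sqrt(2),
    HH = (hi[, odc, drop = FALSE] - hi[, evc, drop = FALSE]) / sqrt(2)
  )
}

shannon_entropy_bits <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  cnt <- tabulate(pmin(bins, 1L + floor((x - rng[1]) / diff(rng) * bins)),
                  nbins = bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

#' Subband entropy
#'
#' Mean Shannon entropy (bits) of histogram-binned coefficients over the
#' subbands of an orthogonal 2-D Haar wavelet decomposition of the luminance
#' image — the wavelet-coding baseline for visual clutter. Subbands are the
#' three detail bands at each level plus the final approximation band. The
#' image is cropped to the largest dimensions divisible by `2^levels`.
#'
#' @param img Grayscale matrix.
#' @param levels Decomposition depth (default 3).
#' @param bins Histogram bins per subband (default 255).
#' @return Mean subband entropy in bits (0 for a constant image; each
#'   subband's entropy is at most `log2(bins)`).
#' @export
subband_entropy <- function(img, levels = 3L, bins = 255L) {
  img <- as.matrix(img)
  blk <- 2L^levels
  H <- (nrow(img) %/% blk) * blk
  W <- (ncol(img) %/% blk) * blk
  if (H < blk || W < blk) {
    stop("image too small for a ", levels, "-level decomposition",
         call. = FALSE)
  }
  m <- img[seq_len(H), seq_len(W), drop = FALSE]
  ents <- numeric(0)
  for (lv in seq_len(levels)) {
    s <- haar_step(m)
    ents <- c(ents, vapply(s[c("LH", "HL", "HH")], shannon_entropy_bits,
                           numeric(1), bins = bins))
    m <- s$LL
  }
  ents <- c(ents, shannon_entropy_bits(m, bins))
  mean(ents)
}

#' Nasanen's area-frequency complexity measure
#'
#' The product of the effective image area and the median radial frequency of
#' the Fourier amplitude spectrum. The effective area is defined here as the
#' product of `4 * s.d.` of the marginal spatial distributions of
#' `|I - mean(I)|` along x and y (a second-moment spread); the median
#' frequency is the radial frequency (cycles/pixel) that splits the
#' DC-excluded amplitude-spectrum mass in half. A zero-variance image scores
#' 0.
#'
#' @param img Grayscale matrix.
#' @return `nasanen_measure()`: nonnegative scalar
#'   (pixel^2 * cycles/pixel); `nasanen_effective_area()`: pixel^2;
#'   `nasanen_median_frequency()`: cycles/pixel.
#' @export
nasanen_measure <- function(img) {
  img <- as.matrix(img)
  if (sum(abs(img - mean(img))) == 0) return(0)
  nasanen_effective_area(img) * nasanen_median_frequency(img)
}

#' @rdname nasanen_measure
#' @export
nasanen_effective_area <- function(img) {
  img <- as.matrix(img)
  w <- abs(img - mean(img))
  tot <- sum(w)
  if (tot == 0) return(0)
  py <- rowSums(w) / tot
  px <- colSums(w) / tot
  wvar <- function(p, idx) sum(p * (idx - sum(p * idx))^2)
  (4 * sqrt(wvar(py, seq_along(py)))) * (4 * sqrt(wvar(px, seq_along(px))))
}

#' @rdname nasanen_measure
#' @export
nasanen_median_frequency <- function(img) {
  img <- as.matrix(img)
  if (sum(abs(img - mean(img))) == 0) return(0)
  H <- nrow(img); W <- ncol(img)
  amp <- Mod(stats::fft(img - mean(img)))
  fy <- c(0:(H %/% 2), -((H - H %/% 2 - 1L):1)) / H
  fx <- c(0:(W %/% 2), -((W - W %/% 2 - 1L):1)) / W
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  ord <- order(as.vector(fr))
  cum <- cumsum(as.vector(amp)[ord])
  as.vector(fr)[ord][which(cum >= cum[length(cum)] / 2)[1]]
}

#' All baseline scores for one image
#'
#' @param img Grayscale matrix on the 8-bit scale.
#' @param quality JPEG quality for [jpeg_size()].
#' @param levels,bins Parameters for [subband_entropy()].
#' @param sigma,low,high Parameters for [perimeter_length()].
#' @return Named list: `perimeter`, `jpeg_bytes`, `subband_entropy`,
#'   `nasanen` (and `feature_congestion = NA`, reserved).
#' @export
baseline_scores <- function(img, quality = 75L, levels = 3L, bins = 255L,
                            sigma = 1.0, low = 0.10, high = 0.20) {
  list(
    perimeter = perimeter_length(img, sigma, low, high),
    jpeg_bytes = jpeg_size(img, quality),
    subband_entropy = subband_entropy(img, levels, bins),
    nasanen = nasanen_measure(img),
    feature_congestion = NA_real_
  )
}
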