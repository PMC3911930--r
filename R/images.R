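#' Read a raster image
#'
#' Reads a PNG, TIFF or JPEG file into a numeric array on its native intensity
#' scale: an `H x W` matrix for single-channel files, an `H x W x 3` array for
#' colour files (an alpha channel, if present, is dropped). The source bit
#' depth is recorded in the `"bit_depth"` attribute; values are returned on
#' the `[0, 2^bit_depth - 1]` scale so that, e.g., a 16-bit TIFF keeps its
#' 16-bit values until [quantize_8bit()] is applied.
#'
#' @param path Path to a `.png`, `.tif(f)`, `.jpg` or `.jpeg` file.
#' @return A numeric matrix (grayscale) or `H x W x 3` array (colour) with a
#'   `"bit_depth"` attribute.
#' @seealso [to_grayscale()], [quantize_8bit()], [decimate()]
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("image file not found: '", path, "'", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  res <- tryCatch(
    switch(ext,
      png = {
        img <- png::readPNG(path, info = TRUE)
        depth <- attr(img, "info")$bit.depth
        if (is.null(depth)) depth <- 8L
        list(pix = img * (2^depth - 1), depth = depth)
      },
      tif = ,
      tiff = {
        img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
        depth <- attr(img, "bits.per.sample")
        if (is.null(depth)) depth <- attr(img, "info")$bits.per.sample
        if (is.null(depth)) depth <- if (max(img) > 255) 16L else 8L
        list(pix = img + 0, depth = depth)
      },
      jpg = ,
      jpeg = list(pix = jpeg::readJPEG(path) * 255, depth = 8L),
      stop("unsupported raster format '", ext, "'")
    ),
    error = function(e) {
      stop("cannot read image file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  pix <- res$pix
  if (length(dim(pix)) == 3L) {
    if (dim(pix)[3] >= 3L) {
      pix <- pix[, , 1:3, drop = FALSE]
    } else {
      pix <- pix[, , 1L]
    }
  }
  structure(pix, bit_depth = as.integer(res$depth))
}

#' Collapse colour channels to grayscale
#'
#' Collapses an `H x W x 3` colour array to a single luminance channel. The
#' default is the unweighted mean of the three channels; Rec. 601 luminance
#' weights (0.299, 0.587, 0.114) are available via `weights = "rec601"`.
#'
#' @param img An `H x W x 3` numeric array.
#' @param weights `"mean"` (default) or `"rec601"`.
#' @return An `H x W` numeric matrix; the `"bit_depth"` attribute, if any, is
#'   preserved.
#' @export
to_grayscale <- function(img, weights = c("mean", "rec601")) {
  weights <- match.arg(weights)
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) {
    stop("`img` must be an H x W x 3 array, got dims [",
         paste(d, collapse = ", "), "]", call. = FALSE)
  }
  w <- if (weights == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
  out <- img[, , 1L] * w[1] + img[, , 2L] * w[2] + img[, , 3L] * w[3]
  attr(out, "bit_depth") <- attr(img, "bit_depth")
  out
}

## Squared magnitude response of an Arma filter at the N DFT frequencies.
zp_mag2 <- function(flt, N) {
  z <- exp(-2i * pi * (0:(N - 1)) / N)
  B <- as.vector(outer(z, seq_along(flt$b) - 1, "^") %*% flt$b)
  A <- as.vector(outer(z, seq_along(flt$a) - 1, "^") %*% flt$a)
  Mod(B / A)^2
}

## Zero-phase filtering along columns: the filter's squared magnitude
## response (the exact frequency response of a forward-backward pass) is
## applied with zero phase under symmetric (mirror-reflect) extension, which
## removes boundary transients entirely.
## Whole-sample symmetric extension (x_1..x_n, x_{n-1}..x_2) keeps both a
## constant and a pure Nyquist tone exactly periodic across the seam.
zero_phase_cols <- function(m, flt) {
  n <- nrow(m)
  xe <- rbind(m, m[(n - 1L):2L, , drop = FALSE])
  N <- nrow(xe)
  H <- zp_mag2(flt, N)
  out <- Re(stats::mvfft(stats::mvfft(xe) * H, inverse = TRUE)) / N
  out[seq_len(n), , drop = FALSE]
}

zero_phase_filter <- function(x, flt) {
  as.vector(zero_phase_cols(matrix(x, length(x), 1L), flt))
}

#' Anti-aliased decimation
#'
#' Low-pass filters an image with a zero-phase eighth-order Chebyshev Type I
#' filter and then subsamples it by an integer factor, the standard guard
#' against aliasing before downsampling. Filtering is separable (columns then
#' rows) and zero-phase: the filter's squared magnitude response — exactly
#' the response of a forward-backward pass — is applied with zero phase
#' under mirror-reflect symmetric extension, so no boundary transients are
#' introduced. Output dimensions are `floor(dim / factor)`.
#'
#' @param img Numeric matrix (grayscale image).
#' @param factor Positive integer downsampling factor.
#' @param cutoff Normalised low-pass cutoff (fraction of Nyquist). Default is
#'   the classic decimation convention `0.8 / factor`.
#' @param ripple_db Passband ripple of the Chebyshev design in dB
#'   (default 0.05).
#' @param order Filter order (default 8).
#' @return Filtered, subsampled matrix of dimension `floor(dim(img) / factor)`.
#' @examples
#' img <- matrix(runif(64 * 48, 0, 255), 64, 48)
#' dim(decimate(img, 2))  # 32 x 24
#' @export
decimate <- function(img, factor, cutoff = 0.8 / factor, ripple_db = 0.05,
                     order = 8L) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor < 1 || factor != round(factor)) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  img <- as.matrix(img)
  if (factor == 1L) return(img)
  if (any(dim(img) < 2L * factor)) {
    stop("image dimensions must be at least 2 * factor", call. = FALSE)
  }
  flt <- signal::cheby1(order, ripple_db, cutoff)
  out <- zero_phase_cols(img, flt)
  out <- t(zero_phase_cols(t(out), flt))
  ri <- seq(1L, by = factor, length.out = nrow(img) %/% factor)
  ci <- seq(1L, by = factor, length.out = ncol(img) %/% factor)
  structure(out[ri, ci, drop = FALSE], bit_depth = attr(img, "bit_depth"))
}

#' Quantize to 8-bit luminance
#'
#' Linearly maps intensities from their source bit-depth range
#' `[0, 2^bit_depth - 1]` to `[0, 255]`, rounds half-to-even and clips to
#' `[0, 255]`, yielding bit-exact results across platforms.
#'
#' @param img Numeric matrix or array of finite intensities.
#' @param bit_depth Source bit depth; defaults to the image's `"bit_depth"`
#'   attribute, else 8.
#' @return Matrix/array of integers (stored as numeric) in `[0, 255]` with
#'   `bit_depth` attribute 8.
#' @export
quantize_8bit <- function(img, bit_depth = NULL) {
  if (any(!is.finite(img))) {
    stop("`img` contains NaN or infinite values", call. = FALSE)
  }
  if (is.null(bit_depth)) bit_depth <- attr(img, "bit_depth")
  if (is.null(bit_depth)) bit_depth <- 8L
  out <- round(img / (2^bit_depth - 1) * 255)
  out[] <- pmin(pmax(out, 0), 255)
  attr(out, "bit_depth") <- 8L
  out
}

#' Display geometry helpers
#'
#' `nyquist_cpd()` converts an image extent in pixels and its subtended visual
#' angle into the maximum representable spatial frequency (Nyquist) in
#' cycles/degree. `visual_angle_deg()` gives the visual angle subtended by a
#' run of pixels of known pitch viewed from a given distance.
#'
#' @param n_pixels Number of pixels along the dimension.
#' @param angle_deg Visual angle subtended by those pixels, in degrees.
#' @param pixel_pitch_mm Physical pixel pitch in millimetres.
#' @param distance_cm Viewing distance in centimetres.
#' @return A frequency in cycles/degree, or an angle in degrees.
#' @examples
#' nyquist_cpd(2144, 37)          # ~29 cycles/degree
#' visual_angle_deg(1424, 0.2505, 80)
#' @export
nyquist_cpd <- function(n_pixels, angle_deg) {
  stopifnot(n_pixels > 0, angle_deg > 0)
  n_pixels / 2 / angle_deg
}

#' @rdname nyquist_cpd
#' @export
visual_angle_deg <- function(n_pixels, pixel_pitch_mm, distance_cm) {
  stopifnot(n_pixels > 0, pixel_pitch_mm > 0, distance_cm > 0)
  extent_mm <- n_pixels * pixel_pitch_mm
  2 * atan(extent_mm / 2 / (distance_cm * 10)) * 180 / pi
}
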