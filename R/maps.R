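#' Vectorise a square neighborhood
#'
#' Reads an `s x s` patch into a column vector in column-major order
#' (top-to-bottom, then left-to-right).
#'
#' @param N Square numeric matrix.
#' @return Numeric vector of length `s^2`.
#' @export
vectorize_neighborhood <- function(N) {
  if (!is.matrix(N) || nrow(N) != ncol(N)) {
    stop("neighborhood must be a square matrix", call. = FALSE)
  }
  as.vector(N)
}

#' RMS contrast of a neighborhood vector
#'
#' The root-mean-square contrast: the population standard deviation
#' (divisor `n`) of the luminance values.
#'
#' @param x Numeric vector, length at least 2.
#' @param population Use population moments (divisor `n`, default) or sample
#'   moments (divisor `n - 1`).
#' @return Nonnegative scalar, in luminance levels.
#' @export
rms_contrast <- function(x, population = TRUE) {
  stopifnot(length(x) >= 2L)
  v <- mean((x - mean(x))^2)
  if (!population) v <- v * length(x) / (length(x) - 1L)
  sqrt(v)
}

## All sliding size x size neighborhoods at the given stride, one per row,
## vectorised column-major, in column-major order of map positions.
im2col <- function(img, size, stride) {
  H <- nrow(img); W <- ncol(img)
  i0 <- seq(1L, H - size + 1L, by = stride)
  j0 <- seq(1L, W - size + 1L, by = stride)
  start <- rep((j0 - 1L) * H, each = length(i0)) + rep(i0, times = length(j0))
  off <- as.vector(outer(0:(size - 1L), (0:(size - 1L)) * H, "+"))
  P <- matrix(img[outer(start, off, "+")], length(start), size^2)
  attr(P, "map_dim") <- c(length(i0), length(j0))
  P
}

check_map_args <- function(img, size, stride) {
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1 ||
      stride != round(stride)) {
    stop("`stride` must be a positive integer", call. = FALSE)
  }
  if (!is.matrix(img)) stop("`img` must be a grayscale matrix", call. = FALSE)
  if (any(dim(img) < size)) {
    stop("neighborhood size ", size, " exceeds image dimensions [",
         paste(dim(img), collapse = ", "), "]", call. = FALSE)
  }
}

#' Dense local RMS-contrast map
#'
#' Computes `C(i, j)`, the RMS contrast of the `size x size` neighborhood
#' anchored at every valid position (no padding), at the given stride. The
#' result is numerically identical to computing [rms_contrast()] on each
#' neighborhood directly.
#'
#' @param img Grayscale matrix.
#' @param size Neighborhood side length (default 16).
#' @param stride Step between neighborhood anchors (default 1, i.e. around
#'   every pixel of the valid region).
#' @return A `contrast_map`: numeric matrix of dimension
#'   `floor((dim - size) / stride) + 1` with attributes `size` and `stride`.
#' @export
contrast_map <- function(img, size = 16L, stride = 1L) {
  check_map_args(img, size, stride)
  P <- im2col(img, size, stride)
  mu <- rowMeans(P)
  v <- pmax(rowMeans(P^2) - mu^2, 0)
  out <- matrix(sqrt(v), attr(P, "map_dim")[1], attr(P, "map_dim")[2])
  structure(out, size = as.integer(size), stride = as.integer(stride),
            class = c("contrast_map", "matrix", "array"))
}

#' Log-transform of luminance values
#'
#' Elementwise piecewise logarithm used to normalise luminance before filter
#' responses: `l(v) = ln(v)` for `v > 0` and `l(0) = 0`, so the output is
#' always finite. Negative input is an error.
#'
#' @param x Nonnegative numeric vector/matrix of luminance values.
#' @return Transformed values of the same shape.
#' @export
log_transform <- function(x) {
  if (any(x < 0)) stop("luminance values must be nonnegative", call. = FALSE)
  out <- x
  pos <- x > 0
  out[pos] <- log(x[pos])
  out[!pos] <- 0
  out
}

#' Filter responses of a neighborhood
#'
#' Inner products of every filter in the bank with the (log-transformed)
#' neighborhood vector; the DC filter's response is pinned to the bank's
#' constant `dc_constant` regardless of the input.
#'
#' @param xt Numeric vector of length `patch_size^2`.
#' @param bank An `ic_filter_bank`.
#' @return Numeric response vector, one entry per filter.
#' @export
filter_responses <- function(xt, bank) {
  stopifnot(inherits(bank, "ic_filter_bank"))
  if (length(xt) != ncol(bank$filters)) {
    stop("input length ", length(xt), " does not match bank dimensionality ",
         ncol(bank$filters), call. = FALSE)
  }
  a <- as.vector(bank$filters %*% xt)
  a[bank$dc_index] <- bank$dc_constant
  a
}

#' Pearson kurtosis of a response vector
#'
#' Non-excess kurtosis with population moments: fourth central moment divided
#' by the squared second central moment. Returns `NA` (undefined, to be
#' masked) when the response variance is below `1e-12`.
#'
#' @param a Numeric vector, length at least 4.
#' @return Scalar kurtosis (at least 1 when defined), or `NA`.
#' @export
response_kurtosis <- function(a) {
  stopifnot(length(a) >= 4L)
  mu <- mean(a)
  m2 <- mean((a - mu)^2)
  if (m2 < 1e-12) return(NA_real_)
  mean((a - mu)^4) / m2^2
}

#' Dense filter-response kurtosis map
#'
#' For every valid `size x size` neighborhood: vectorise (column-major),
#' log-transform, take the IC-filter responses (DC pinned to the bank
#' constant), and record the Pearson kurtosis of the response vector.
#' High kurtosis marks sparse filter activity (low local spatial frequency);
#' low kurtosis marks dense activity (high local spatial frequency).
#' Neighborhoods with (numerically) zero response variance yield `NA` and are
#' excluded from downstream statistics.
#'
#' @param img Grayscale matrix with nonnegative values.
#' @param bank An `ic_filter_bank` whose `patch_size` equals `size`.
#' @param size Neighborhood side length (defaults to the bank's patch size).
#' @param stride Step between neighborhood anchors (default 1).
#' @return A `kurtosis_map`: numeric matrix (with `NA` for undefined entries)
#'   with attributes `size` and `stride`.
#' @export
kurtosis_map <- function(img, bank, size = bank$patch_size, stride = 1L) {
  stopifnot(inherits(bank, "ic_filter_bank"))
  if (size != bank$patch_size) {
    stop("neighborhood size ", size, " does not match the bank's patch size ",
         bank$patch_size, call. = FALSE)
  }
  check_map_args(img, size, stride)
  P <- im2col(img, size, stride)
  XT <- log_transform(P)
  A <- XT %*% t(bank$filters)           # n_pos x d responses
  A[, bank$dc_index] <- bank$dc_constant
  mu <- rowMeans(A)
  Ac <- A - mu
  m2 <- rowMeans(Ac^2)
  m4 <- rowMeans(Ac^4)
  K <- ifelse(m2 < 1e-12, NA_real_, m4 / m2^2)
  out <- matrix(K, attr(P, "map_dim")[1], attr(P, "map_dim")[2])
  structure(out, size = as.integer(size), stride = as.integer(stride),
            class = c("kurtosis_map", "matrix", "array"))
}
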