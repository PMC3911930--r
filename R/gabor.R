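## Evaluate a 2-D Gabor on the patch grid. Coordinates are (row, col) with
## origin at the patch centre; theta (radians) is the direction of the carrier
## wave vector, so the carrier is cos(2*pi*f*xr + phase) with xr the
## coordinate along theta.
gabor_patch <- function(patch_size, amp, r0, c0, sigma_par, sigma_perp,
                        freq, theta, phase) {
  ctr <- (patch_size + 1) / 2
  r <- matrix(seq_len(patch_size) - ctr, patch_size, patch_size) - r0
  cc <- matrix(rep(seq_len(patch_size) - ctr, each = patch_size),
               patch_size, patch_size) - c0
  xr <- cc * cos(theta) + r * sin(theta)
  yr <- -cc * sin(theta) + r * cos(theta)
  amp * exp(-(xr^2 / (2 * sigma_par^2) + yr^2 / (2 * sigma_perp^2))) *
    cos(2 * pi * freq * xr + phase)
}

#' Fit a 2-D Gabor function to a filter
#'
#' Least-squares fit of a Gaussian-envelope cosine carrier to a (non-DC)
#' filter, used to characterise learned IC filters. Initialisation takes the
#' carrier frequency and orientation from the peak of the filter's discrete
#' amplitude spectrum and the envelope from the centroid/spread of the
#' absolute filter weights; refinement uses Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]).
#'
#' The reported half-amplitude spatial-frequency bandwidth in octaves follows
#' from the fitted parameters in closed form: a Gaussian envelope of s.d.
#' `sigma` along the carrier direction has spectral s.d.
#' `sigma_f = 1 / (2 pi sigma)`, so the amplitude response falls to half its
#' peak at `f +/- sigma_f sqrt(2 log 2)` and
#' `bandwidth = log2(f_hi / f_lo)`. When the half-amplitude band reaches zero
#' frequency (`f <= sigma_f sqrt(2 log 2)`) the bandwidth is infinite.
#'
#' @param filter Numeric vector of length `patch_size^2` (column-major
#'   filter weights); must not be constant (DC).
#' @param patch_size Patch side length.
#' @return A list of class `gabor_params`: `center_frequency` (cycles/pixel),
#'   `orientation` (degrees in `[0, 180)`), `bandwidth` (octaves),
#'   `fit_residual` (relative RMS residual; `Inf` on fit failure, with the
#'   other parameters `NA`), plus the raw fitted parameters in `$par`.
#' @export
fit_gabor <- function(filter, patch_size = as.integer(round(sqrt(length(filter))))) {
  if (length(filter) != patch_size^2) {
    stop("filter length does not match patch_size^2", call. = FALSE)
  }
  if (stats::sd(filter) == 0) {
    stop("cannot fit a Gabor to a constant (DC) filter", call. = FALSE)
  }
  w <- matrix(filter, patch_size, patch_size)
  ## spectral peak (DC excluded) -> carrier init
  Fm <- Mod(stats::fft(w))
  fr <- c(0:(patch_size %/% 2), -((patch_size - patch_size %/% 2 - 1L):1)) /
    patch_size
  Fm[1, 1] <- 0
  pk <- arrayInd(which.max(Fm), dim(Fm))
  f_row <- fr[pk[1]]                    # cycles/pixel along rows
  f_col <- fr[pk[2]]                    # cycles/pixel along cols
  f0 <- sqrt(f_row^2 + f_col^2)
  theta0 <- atan2(f_row, f_col)
  ## envelope init from |w|
  ctr <- (patch_size + 1) / 2
  aw <- abs(w) / sum(abs(w))
  rows <- matrix(seq_len(patch_size) - ctr, patch_size, patch_size)
  cols <- matrix(rep(seq_len(patch_size) - ctr, each = patch_size),
                 patch_size, patch_size)
  r0 <- sum(aw * rows)
  c0 <- sum(aw * cols)
  s0 <- sqrt(max(sum(aw * ((rows - r0)^2 + (cols - c0)^2)) / 2, 0.25))
  amp0 <- max(abs(w))
  resid_fn <- function(p) {
    as.vector(w - gabor_patch(patch_size, p[1], p[2], p[3],
                              exp(p[4]), exp(p[5]), p[6], p[7], p[8]))
  }
  lower <- c(-10 * amp0, -patch_size, -patch_size, log(0.3), log(0.3),
             0.01, theta0 - pi, -2 * pi)
  upper <- c(10 * amp0, patch_size, patch_size, log(2 * patch_size),
             log(2 * patch_size), 0.5 * sqrt(2), theta0 + pi, 2 * pi)
  ## carrier phase is unknown a priori: try cosine and sine starts, keep the
  ## better converged fit
  fits <- lapply(c(0, pi / 2), function(ph0) {
    tryCatch(
      minpack.lm::nls.lm(
        par = c(amp0, r0, c0, log(s0), log(s0), f0, theta0, ph0),
        fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  })
  fits <- Filter(function(f) !is.null(f) && all(is.finite(f$par)), fits)
  fit <- if (length(fits) > 0L) {
    fits[[which.min(vapply(fits, function(f) f$deviance, numeric(1)))]]
  } else NULL
  if (is.null(fit)) {
    return(structure(list(center_frequency = NA_real_,
                          orientation = NA_real_, bandwidth = NA_real_,
                          fit_residual = Inf, par = NULL),
                     class = "gabor_params"))
  }
  p <- fit$par
  freq <- abs(p[6])
  theta <- (p[7] * 180 / pi) %% 180
  sigma_par <- exp(p[4])
  sigma_f <- 1 / (2 * pi * sigma_par)
  a <- sigma_f * sqrt(2 * log(2))
  bandwidth <- if (freq > a) log2((freq + a) / (freq - a)) else Inf
  rel_res <- sqrt(mean(resid_fn(p)^2)) / sqrt(mean(w^2))
  structure(list(center_frequency = freq, orientation = theta,
                 bandwidth = bandwidth, fit_residual = rel_res, par = p),
            class = "gabor_params")
}

#' Characterise every non-DC filter of a bank by fitted Gabor parameters
#'
#' @param bank An `ic_filter_bank`.
#' @return A data frame with one row per non-DC filter: `filter` (index in
#'   the bank), `center_frequency` (cycles/pixel), `orientation` (degrees),
#'   `bandwidth` (octaves), `fit_residual`. The fraction of filters with
#'   centre frequency above 0.25 cycles/pixel is attached as attribute
#'   `"frac_high_frequency"`.
#' @export
characterize_bank <- function(bank) {
  stopifnot(inherits(bank, "ic_filter_bank"))
  idx <- setdiff(seq_len(nrow(bank$filters)), bank$dc_index)
  if (length(idx) == 0L) {
    return(data.frame(filter = integer(0), center_frequency = numeric(0),
                      orientation = numeric(0), bandwidth = numeric(0),
                      fit_residual = numeric(0)))
  }
  rows <- lapply(idx, function(k) {
    g <- fit_gabor(bank$filters[k, ], bank$patch_size)
    data.frame(filter = k, center_frequency = g$center_frequency,
               orientation = g$orientation, bandwidth = g$bandwidth,
               fit_residual = g$fit_residual)
  })
  out <- do.call(rbind, rows)
  attr(out, "frac_high_frequency") <-
    mean(out$center_frequency > 0.25, na.rm = TRUE)
  out
}

#' Mode of the half-amplitude bandwidth histogram
#'
#' Bins the finite bandwidths of a characterisation table into fixed-width
#' bins and returns the centre of the most populated bin.
#'
#' @param characterization Data frame from [characterize_bank()].
#' @param binwidth Histogram bin width in octaves (default 0.1).
#' @return The bandwidth-histogram mode (bin centre), in octaves.
#' @export
bandwidth_mode <- function(characterization, binwidth = 0.1) {
  bw <- characterization$bandwidth
  bw <- bw[is.finite(bw)]
  if (length(bw) == 0L) return(NA_real_)
  bin <- floor(bw / binwidth)
  tb <- table(bin)
  (as.numeric(names(tb))[which.max(tb)] + 0.5) * binwidth
}
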