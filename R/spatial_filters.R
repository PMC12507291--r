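#' Spatial-frequency bandwidth of a channel
#'
#' Full bandwidth at half maximum (FWHM) in octaves. Bandwidth is constant
#' (`w0`) at spatial frequencies at or above the critical frequency `theta0`
#' and grows by 0.26 octaves per octave of SF below it.
#'
#' @param theta spatial frequency in cpd (> 0), vectorized.
#' @param theta0 critical SF in cpd (default 2).
#' @param w0 asymptotic FWHM in octaves (default 1.5).
#' @return FWHM in octaves.
#' @export
sf_bandwidth <- function(theta, theta0 = 2, w0 = 1.5) {
  if (any(theta <= 0)) stop_param("theta must be positive")
  ifelse(theta >= theta0, w0, w0 - 0.26 * log2(theta / theta0))
}

#' Convert a Gaussian FWHM to a standard deviation
#'
#' @param w full width at half maximum (>= 0), any units.
#' @return SD in the same units: `w / (2 sqrt(2 log 2))`.
#' @export
fwhm_to_sigma <- function(w) {
  if (any(w < 0)) stop_param("FWHM must be non-negative")
  w / (2 * sqrt(2 * log(2)))
}

#' Receptive-field spatial constant
#'
#' Gaussian SD of the RF envelope (RF width is defined as two SDs). Width
#' follows 1/SF above 1 cpd and SF^-0.5 below 1 cpd, anchored at `beta0`
#' dva at 1 cpd.
#'
#' @param theta spatial frequency in cpd (> 0), vectorized.
#' @param beta0 RF width at 1 cpd, in dva (default 1).
#' @return sigma_RF in dva.
#' @export
rf_sigma <- function(theta, beta0 = 1) {
  if (any(theta <= 0)) stop_param("theta must be positive")
  0.5 * beta0 * ifelse(theta >= 1, theta^-1, theta^-0.5)
}

#' Orientation bandwidth of a channel
#'
#' FWHM of the orientation tuning implied by a Gabor of SF `theta` with
#' spatial envelope SD `rf_sigma(theta)`:
#' `w = 2 atan( sqrt(2 log 2) / (2 pi sigma_RF theta) )`.
#' Because `sigma_RF * theta` is constant above 1 cpd, the bandwidth is a
#' constant ~41 deg there and widens as SF decreases (to ~100 deg at 0.1 cpd).
#'
#' @inheritParams rf_sigma
#' @return FWHM in degrees.
#' @export
orientation_bandwidth <- function(theta, beta0 = 1) {
  if (any(theta <= 0)) stop_param("theta must be positive")
  s <- rf_sigma(theta, beta0)
  2 * atan(sqrt(2 * log(2)) / (2 * pi * s * theta)) * 180 / pi
}

#' Filter-bank specification
#'
#' Seven spatial frequencies by eight orientations, with SF and orientation
#' bandwidths scaled physiologically via [sf_bandwidth()] and
#' [orientation_bandwidth()].
#'
#' @param sf_set spatial frequencies in cpd (strictly increasing).
#' @param ori_set orientations in deg, spanning 180 deg; the value is the
#'   stripe (preferred edge) orientation, anticlockwise from horizontal.
#' @param theta0,w0 see [sf_bandwidth()].
#' @param beta0 see [rf_sigma()].
#' @export
bank_spec <- function(sf_set = c(0.25, 0.4, 0.63, 1.0, 1.59, 2.52, 4.0),
                      ori_set = c(-67.5, -45, -22.5, 0, 22.5, 45, 67.5, 90),
                      theta0 = 2, w0 = 1.5, beta0 = 1) {
  if (is.unsorted(sf_set, strictly = TRUE))
    stop_param("sf_set must be strictly increasing")
  structure(list(sf_set = sf_set, ori_set = ori_set, theta0 = theta0,
                 w0 = w0, beta0 = beta0),
            class = "bank_spec")
}

# frequency-domain log-Gabor magnitude on a grid of fx, fy (cpd);
# single-sided: one angular lobe centered on the wave-vector direction
log_gabor_transfer <- function(fx, fy, theta, omega, sigma_ln, sigma_om_rad) {
  f <- sqrt(outer(fy^2, fx^2, `+`))
  ang <- atan2(outer(fy, rep(1, length(fx))), outer(rep(1, length(fy)), fx))
  phi_w <- (omega + 90) * pi / 180  # wave-vector angle
  dang <- atan2(sin(ang - phi_w), cos(ang - phi_w))
  G <- exp(-(log(pmax(f, .Machine$double.xmin) / theta))^2 / (2 * sigma_ln^2)) *
    exp(-dang^2 / (2 * sigma_om_rad^2))
  G[f == 0] <- 0
  G
}

#' Build the log-Gabor filter bank
#'
#' Kernels are constructed in the frequency domain (Gaussian in log radial
#' frequency and in orientation, single-sided) and transformed to space.
#' Each kernel is stored as a complex matrix: the real part is the
#' even-phase (symmetric) kernel, the imaginary part the odd-phase
#' (antisymmetric) kernel. Spatial support is cropped to a side of
#' `8 * rf_sigma(theta, 1)` dva, rounded up to an odd pixel count, and the
#' even kernel's residual DC (from cropping) is removed.
#'
#' @param spec a [bank_spec()].
#' @param pitch pixel pitch in dva/px; must resolve the highest SF with at
#'   least two samples per cycle.
#' @return `"log_gabor_bank"`: list with `kernels` (list indexed
#'   `[[i_theta]][[i_omega]]`), `spec`, `pitch`, and per-SF `sigma_ln`,
#'   `sigma_om`, `extent_px`.
#' @export
build_bank <- function(spec = bank_spec(), pitch = 3.36 / 51) {
  if (pitch > 1 / (2 * max(spec$sf_set)))
    stop_param("pitch ", signif(pitch, 4), " dva/px cannot resolve ",
               max(spec$sf_set), " cpd (need <= ",
               signif(1 / (2 * max(spec$sf_set)), 4), ")")
  sigma_ln <- fwhm_to_sigma(sf_bandwidth(spec$sf_set, spec$theta0, spec$w0)) * log(2)
  sigma_om <- fwhm_to_sigma(orientation_bandwidth(spec$sf_set, spec$beta0))
  extent_px <- vapply(spec$sf_set, function(th) {
    side <- ceiling(8 * rf_sigma(th, 1) / pitch)
    as.integer(side + (side + 1) %% 2)
  }, integer(1))
  kernels <- vector("list", length(spec$sf_set))
  for (i in seq_along(spec$sf_set)) {
    side <- extent_px[i]
    L <- good_fft_size(2L * side)
    fgrid <- fft_freqs(L, pitch)
    kernels[[i]] <- lapply(seq_along(spec$ori_set), function(j) {
      G <- log_gabor_transfer(fgrid, fgrid, spec$sf_set[i], spec$ori_set[j],
                              sigma_ln[i], sigma_om[i] * pi / 180)
      h <- ifft2(G)
      # crop the spatial kernel (centered at the origin with wraparound)
      idx <- ((seq_len(side) - (side + 1L) / 2L) %% L) + 1L
      h <- h[idx, idx]
      re <- Re(h); im <- Im(h)
      re <- re - mean(re)  # remove residual DC from cropping
      matrix(complex(real = re, imaginary = im), side, side)
    })
  }
  structure(list(kernels = kernels, spec = spec, pitch = pitch,
                 sigma_ln = sigma_ln, sigma_om = sigma_om,
                 extent_px = extent_px),
            class = "log_gabor_bank")
}

#' @export
print.log_gabor_bank <- function(x, ...) {
  cat(sprintf("<log_gabor_bank> %d SFs x %d orientations, pitch %.4f dva/px, kernel sides %s px\n",
              length(x$spec$sf_set), length(x$spec$ori_set), x$pitch,
              paste(x$extent_px, collapse = "/")))
  invisible(x)
}

#' Apply the spatial filter bank to a retinal movie
#'
#' Convolves every frame with every kernel (same-size output, zero-padded
#' boundaries, i.e. mean-luminance surround). The result is complex: real
#' part = even-phase response, imaginary part = odd-phase response.
#'
#' @param bank a `log_gabor_bank` whose pitch matches the movie.
#' @param movie a `retinal_movie`.
#' @return `"spatial_response"`: complex array with dimensions
#'   (theta, omega, t, y, x) and attributes `sf_set`, `ori_set`, `rate`,
#'   `pitch`.
#' @export
apply_spatial <- function(bank, movie) {
  if (abs(bank$pitch - movie$pitch) > 1e-9 * movie$pitch)
    stop_param("bank pitch (", signif(bank$pitch, 5),
               ") does not match movie pitch (", signif(movie$pitch, 5), ")")
  d <- dim(movie$frames)
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  if (max(bank$extent_px) > max(ny, nx))
    warning("largest kernel (", max(bank$extent_px),
            ") exceeds the canvas (", ny, " x ", nx,
            " px); responses are dominated by boundary padding",
            call. = FALSE)
  nth <- length(bank$spec$sf_set); nom <- length(bank$spec$ori_set)
  pad <- max(bank$extent_px)
  PY <- good_fft_size(ny + pad); PX <- good_fft_size(nx + pad)
  TF <- bank_transfers(bank, PY, PX)
  out <- array(0i, c(nth, nom, nt, ny, nx))
  for (t in seq_len(nt)) {
    Fr <- fft(pad_matrix(movie$frames[, , t], PY, PX))
    for (i in seq_len(nth)) for (j in seq_len(nom)) {
      r <- fft(Fr * TF[[i]][[j]], inverse = TRUE) / (PY * PX)
      out[i, j, t, , ] <- r[seq_len(ny), seq_len(nx)]
    }
  }
  structure(out, class = "spatial_response", sf_set = bank$spec$sf_set,
            ori_set = bank$spec$ori_set, rate = movie$rate,
            pitch = movie$pitch)
}

# padded-grid transfer functions of the bank's (cropped) spatial kernels,
# with the kernel center shifted to the origin so that convolution output
# is spatially aligned with the input
bank_transfers <- function(bank, PY, PX) {
  lapply(seq_along(bank$spec$sf_set), function(i) {
    lapply(bank$kernels[[i]], function(k) {
      side <- nrow(k)
      ctr <- (side + 1L) / 2L
      p <- pad_matrix(k, PY, PX)
      fft(shift_to_origin(p, ctr, ctr))
    })
  })
}
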