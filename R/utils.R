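# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_param <- function(...) stop(..., call. = FALSE)

# smallest "FFT-friendly" integer >= n (factors 2, 3, 5, 7 only)
good_fft_size <- function(n) {
  is_good <- function(m) {
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    m == 1L
  }
  m <- as.integer(n)
  while (!is_good(m)) m <- m + 1L
  m
}

# unnormalized inverse 2-D FFT convenience (R's fft() leaves ifft unscaled)
ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)

# FFT frequencies (cycles per unit) for n samples at spacing d
fft_freqs <- function(n, d) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / (n * d)
}

# wrap angles (deg) into (-180, 180]
wrap180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# wrap orientation (deg, period 180) into (-90, 90]
wrap_ori <- function(a) {
  a <- (a + 90) %% 180 - 90
  a[a == -90] <- 90
  a
}

# circular mean / SD of orientations (deg, period 180) via angle doubling
ori_circ_mean <- function(a) {
  z <- mean(exp(2i * a * pi / 180))
  wrap_ori(Arg(z) * 180 / pi / 2)
}

ori_circ_sd <- function(a) {
  z <- mean(exp(2i * a * pi / 180))
  r <- min(max(Mod(z), .Machine$double.eps), 1)
  sqrt(-2 * log(r)) * 180 / pi / 2
}

# zero-pad a matrix into the top-left corner of a (py x px) matrix
pad_matrix <- function(m, py, px) {
  out <- matrix(0, py, px)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

# circularly shift a matrix so that element (cy, cx) moves to (1, 1)
shift_to_origin <- function(m, cy, cx) {
  ny <- nrow(m); nx <- ncol(m)
  iy <- ((seq_len(ny) - 1 + (cy - 1)) %% ny) + 1
  ix <- ((seq_len(nx) - 1 + (cx - 1)) %% nx) + 1
  m[iy, ix]
}

# causal convolution of the columns of x (time along rows) with kernel h,
# scaled by dt; output has the same number of rows as x
causal_conv_cols <- function(x, h, dt) {
  nt <- nrow(x)
  if (length(h) > nt) {
    warning("temporal kernel longer than series; tail beyond the series is dropped",
            call. = FALSE)
    h <- h[seq_len(nt)]
  }
  # banded lower-triangular Toeplitz multiply via BLAS
  H <- matrix(0, nt, nt)
  for (j in seq_along(h)) {
    idx <- seq_len(nt - j + 1)
    H[cbind(idx + j - 1, idx)] <- h[j]
  }
  (H %*% x) * dt
}

# first-order IIR exponential lowpass along columns' rows (time along rows),
# unit DC gain: y_t = a y_{t-1} + (1 - a) x_t
iir_exp_lowpass <- function(x, a) {
  out <- x
  out[1, ] <- (1 - a) * x[1, ]
  for (t in 2:nrow(x)) out[t, ] <- a * out[t - 1, ] + (1 - a) * x[t, ]
  out
}

# separable unit-sum Gaussian blur over the first two dims of a (y, x, ...) array
gaussian_blur_yx <- function(arr, sd_px) {
  d <- dim(arr)
  if (sd_px <= 0) return(arr)
  r <- max(1L, ceiling(3 * sd_px))
  g <- exp(-(-r:r)^2 / (2 * sd_px^2))
  g <- g / sum(g)
  conv_dim <- function(a, dlen, glen_half, gv, along) {
    # build banded convolution matrix (truncated at edges, kernel unit-sum;
    # zero padding outside)
    C <- matrix(0, dlen, dlen)
    for (j in -glen_half:glen_half) {
      idx <- seq_len(dlen)
      src <- idx + j
      ok <- src >= 1 & src <= dlen
      C[cbind(idx[ok], src[ok])] <- gv[j + glen_half + 1]
    }
    if (along == 1L) {
      m <- matrix(a, d[1], prod(d[-1]))
      array(C %*% m, d)
    } else {
      perm <- c(2L, 1L, seq_along(d)[-(1:2)])
      ap <- aperm(a, perm)
      m <- matrix(ap, d[2], prod(d[-2]))
      aperm(array(C %*% m, dim(ap)), order(perm))
    }
  }
  arr <- conv_dim(arr, d[1], r, g, 1L)
  conv_dim(arr, d[2], r, g, 2L)
}
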