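#' Spatial aggregate of model output
#'
#' Sums a (theta, omega, t, y, x) response tensor over channels and time,
#' yielding a retinotopic (y, x) map.
#'
#' @param rn a response tensor (typically a `normalized_response`).
#' @return numeric matrix (y, x).
#' @export
aggregate_space <- function(rn) {
  d <- dim(rn)
  apply(unclass(rn), c(4, 5), sum)
}

#' Engagement of SF and orientation channels
#'
#' Sums a response tensor over space and time per (theta, omega) channel.
#'
#' @param rn a response tensor (theta, omega, t, y, x).
#' @return `"channel_engagement"`: non-negative matrix (theta x omega) with
#'   `sf_set` / `ori_set` attributes when present on the input.
#' @export
channel_engagement <- function(rn) {
  out <- apply(unclass(rn), c(1, 2), sum)
  structure(out, sf_set = attr(rn, "sf_set"), ori_set = attr(rn, "ori_set"),
            class = "channel_engagement")
}

#' Present-minus-absent engagement contrast
#'
#' @param engagement_present,engagement_absent matched (theta x omega)
#'   engagement matrices.
#' @return elementwise difference (present - absent).
#' @export
condition_difference <- function(engagement_present, engagement_absent) {
  if (!identical(dim(engagement_present), dim(engagement_absent)))
    stop_param("engagement shapes do not match")
  out <- unclass(engagement_present) - unclass(engagement_absent)
  structure(out, sf_set = attr(engagement_present, "sf_set"),
            ori_set = attr(engagement_present, "ori_set"))
}

#' Peak channel and mean retinal trajectory direction
#'
#' Summarizes an engagement contrast by its maximum-power channel and the
#' trials' retinal trajectory directions: circular mean orientation
#' (period 180 deg) with a +/-2 SD dispersion, plus the SF at the contrast
#' maximum.
#'
#' @param contrast (theta x omega) contrast with `sf_set` / `ori_set`
#'   attributes (e.g. from [condition_difference()]).
#' @param trajectory_dirs per-trial mean retinal trajectory orientations in
#'   degrees (period 180).
#' @return `"peak_channel"`: `peak_orientation` (deg), `peak_sf` (cpd),
#'   `trajectory_orientation` (circular mean, deg), `dispersion` (2 SD, deg).
#' @export
peak_channel <- function(contrast, trajectory_dirs) {
  if (length(trajectory_dirs) < 1) stop_param("need at least one trial")
  if (all(contrast == 0))
    stop_param("all-zero contrast: peak channel undefined")
  idx <- which(contrast == max(contrast), arr.ind = TRUE)[1, ]
  structure(list(
    peak_orientation = attr(contrast, "ori_set")[idx[2]],
    peak_sf = attr(contrast, "sf_set")[idx[1]],
    trajectory_orientation = ori_circ_mean(trajectory_dirs),
    dispersion = 2 * ori_circ_sd(trajectory_dirs)),
    class = "peak_channel")
}

#' @export
print.peak_channel <- function(x, ...) {
  cat(sprintf("<peak_channel> peak at %.3g cpd / %g deg; trajectory %.1f deg (+/- %.1f)\n",
              x$peak_sf, x$peak_orientation, x$trajectory_orientation,
              x$dispersion))
  invisible(x)
}

# principal-axis orientation (deg) of the region of `map` above
# `threshold` * max, from the second moments of the thresholded mass
principal_axis <- function(map, threshold = 0.5) {
  m <- map
  m[m < threshold * max(m)] <- 0
  ys <- row(m); xs <- col(m)
  tot <- sum(m)
  cy <- sum(ys * m) / tot; cx <- sum(xs * m) / tot
  # y axis points up in retinal coordinates, but row index grows downward
  # only if the map were image-ordered; our maps are (y, x) with y ascending
  sxx <- sum((xs - cx)^2 * m) / tot
  syy <- sum((ys - cy)^2 * m) / tot
  sxy <- sum((xs - cx) * (ys - cy) * m) / tot
  wrap_ori(0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi)
}

#' Single-receptive-field pass demonstration
#'
#' A small Gaussian blob crosses a single log-Gabor receptive field at
#' constant speed, with the RF's stripes oriented either parallel or
#' orthogonal to the motion direction. Returns the stagewise response
#' traces at the RF location: spatial response (even/odd), temporally
#' filtered response, quadrature energy, its delayed lowpass, and the
#' normalized output.
#'
#' @param speed stimulus speed in dva/s (> 0).
#' @param rf_orientation `"orthogonal"` or `"parallel"` to the (horizontal)
#'   motion direction.
#' @param surface a `trf_surface` for the temporal kernel.
#' @param theta RF spatial frequency in cpd; the default 0.63 is the
#'   center channel of the study target's frequency band.
#' @param rate simulation rate in Hz.
#' @param pitch spatial sampling in dva/px.
#' @param blob_sd blob SD in dva.
#' @param span half-extent of the traversed path in dva.
#' @param spec a [normalization_spec()]; the normalization pool of this
#'   single isolated unit is the unit itself (temporal lowpass only).
#' @return list of stage traces (`t`, `rs_even`, `rs_odd`, `rst_even`,
#'   `rst_odd`, `re`, `rl`, `rn`).
#' @export
rf_pass_demo <- function(speed, rf_orientation = c("orthogonal", "parallel"),
                         surface, theta = 0.63, rate = 480, pitch = 3.36 / 51,
                         blob_sd = 0.08, span = 4, spec = normalization_spec()) {
  rf_orientation <- match.arg(rf_orientation)
  if (speed <= 0) stop_param("speed must be positive")
  # stripes parallel to (horizontal) motion: omega = 0; orthogonal: 90
  omega <- if (rf_orientation == "parallel") 0 else 90
  bank <- build_bank(bank_spec(sf_set = theta, ori_set = omega), pitch)
  k <- bank$kernels[[1]][[1]]
  side <- nrow(k)
  # cross-correlation of kernel and blob along the horizontal center line
  L <- good_fft_size(2L * side + ceiling(2 * span / pitch))
  half <- (side - 1L) / 2L
  g <- seq(0, L - 1) * pitch
  g <- pmin(g, (L * pitch) - g)  # circular distance from origin
  blob <- exp(-outer(g^2, g^2, `+`) / (2 * blob_sd^2))
  K <- fft(shift_to_origin(pad_matrix(k, L, L), half + 1L, half + 1L))
  C <- fft(Conj(fft(blob)) * K, inverse = TRUE) / L^2
  prof <- C[1, ]  # correlation along x at y = 0
  # sample along the path; the trace continues 0.3 s past the pass so the
  # lagged temporal response is captured in full
  t <- seq(0, 2 * span / speed + 0.3, by = 1 / rate)
  xpos <- -span + speed * t
  xi <- (xpos / pitch) %% L
  i0 <- floor(xi); wfrac <- xi - i0
  idx <- function(i) (i %% L) + 1L
  rs <- (1 - wfrac) * prof[idx(i0)] + wfrac * prof[idx(i0 + 1)]
  rs[abs(xpos) > span] <- 0i   # blob outside the simulated region
  h <- calibrated_kernel(surface, theta, rate)
  if (length(h) > length(t)) h <- h[seq_along(t)]
  rstm <- causal_conv_cols(cbind(Re(rs), Im(rs)), h, 1 / rate)
  re <- rstm[, 1]^2 + rstm[, 2]^2
  a <- exp(-1 / (rate * tau_seconds(spec)))
  rl <- as.vector(iir_exp_lowpass(matrix(re, ncol = 1), a))
  rn <- re^spec$n / (spec$sigma^spec$n + rl^spec$n)
  list(t = t, rs_even = Re(rs), rs_odd = Im(rs),
       rst_even = rstm[, 1], rst_odd = rstm[, 2],
       re = re, rl = rl, rn = rn, speed = speed,
       rf_orientation = rf_orientation)
}
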