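#' Normalization model specification
#'
#' Parameters of the delayed divisive normalization stage.
#'
#' @param tau_n time constant of the temporal lowpass (0.75; interpreted in
#'   the units given by `tau_units`).
#' @param tau_units `"s"` (default) or `"ms"`.
#' @param gl_sd SD of the spatial lowpass Gaussian in dva (0.5).
#' @param sigma semisaturation constant (0.07).
#' @param n normalization exponent (1.4).
#' @param pool_radius channel pooling radius in cells (2 each way).
#' @param sigma_p_theta pooling SD over SF distance, octaves (1).
#' @param sigma_p_omega pooling SD over orientation distance, deg (11.5).
#' @export
normalization_spec <- function(tau_n = 0.75, tau_units = c("s", "ms"),
                               gl_sd = 0.5, sigma = 0.07, n = 1.4,
                               pool_radius = 2L, sigma_p_theta = 1,
                               sigma_p_omega = 11.5) {
  tau_units <- match.arg(tau_units)
  if (any(c(tau_n, gl_sd, sigma, n, sigma_p_theta, sigma_p_omega) <= 0))
    stop_param("all normalization parameters must be positive")
  if (pool_radius < 0 || pool_radius != round(pool_radius))
    stop_param("pool_radius must be a non-negative integer")
  structure(list(tau_n = tau_n, tau_units = tau_units, gl_sd = gl_sd,
                 sigma = sigma, n = n, pool_radius = as.integer(pool_radius),
                 sigma_p_theta = sigma_p_theta, sigma_p_omega = sigma_p_omega),
            class = "normalization_spec")
}

tau_seconds <- function(spec) {
  if (spec$tau_units == "ms") spec$tau_n / 1000 else spec$tau_n
}

#' Quadrature energy of spatiotemporal responses
#'
#' Squares and sums even- and odd-phase responses, dropping the phase
#' dimension: `R_E = R_even^2 + R_odd^2`.
#'
#' @param rst a complex `spatial_response` (Re = even, Im = odd).
#' @return `"energy_response"`: non-negative array (theta, omega, t, y, x).
#' @export
energy <- function(rst) {
  if (!is.complex(rst))
    stop_param("both quadrature phases are required (complex input: Re = even, Im = odd)")
  out <- Re(rst)^2 + Im(rst)^2
  attributes(out) <- attributes(rst)
  class(out) <- "energy_response"
  out
}

# Gaussian channel-pooling weights for (d_theta octaves, d_omega deg)
pool_weight <- function(d_theta, d_omega, spec) {
  exp(-(d_theta^2 / (2 * spec$sigma_p_theta^2) +
          d_omega^2 / (2 * spec$sigma_p_omega^2)))
}

# neighbor index offsets and weights for channel pooling at (i, j)
pool_neighbors <- function(sf_set, ori_set, i, j, spec) {
  r <- spec$pool_radius
  nth <- length(sf_set); nom <- length(ori_set)
  it <- (i - r):(i + r)
  it <- it[it >= 1 & it <= nth]  # SF edge: truncate, weights renormalized
  jo <- (((j - 1) + (-r):r) %% nom) + 1  # orientation wraps (period 180 deg)
  grid <- expand.grid(a = seq_along(it), b = seq_along(jo))
  dth <- log2(sf_set[it[grid$a]] / sf_set[i])
  dom <- abs((ori_set[jo[grid$b]] - ori_set[j] + 90) %% 180 - 90)
  w <- pool_weight(dth, dom, spec)
  list(it = it[grid$a], jo = jo[grid$b], w = w / sum(w))
}

#' Lowpass-filtered, channel-pooled normalization signal
#'
#' Computes `R_L` by convolving the energy response with a unit-gain
#' exponential temporal lowpass (time constant `tau_n`) and a unit-sum
#' spatial Gaussian (`gl_sd`), then pools `R_L` over the +/-`pool_radius`
#' SF/orientation neighborhood with Gaussian distance weights (octaves,
#' degrees; orientation distance wrapped at 180 deg, SF edges truncated
#' with renormalized weights).
#'
#' @param re an `energy_response`.
#' @param spec a [normalization_spec()].
#' @param return_rl also return the intermediate `R_L`.
#' @return `R_LP` array like `re` (list with `rlp` and `rl` when
#'   `return_rl = TRUE`).
#' @export
lowpass_pool <- function(re, spec = normalization_spec(), return_rl = FALSE) {
  d <- dim(re)
  rate <- attr(re, "rate"); pitch <- attr(re, "pitch")
  sf_set <- attr(re, "sf_set"); ori_set <- attr(re, "ori_set")
  a <- exp(-1 / (rate * tau_seconds(spec)))
  rl <- re
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    x <- array(re[i, j, , , ], d[3:5])                   # t, y, x
    xm <- matrix(x, d[3], d[4] * d[5])
    xm <- iir_exp_lowpass(xm, a)
    x <- aperm(array(xm, d[3:5]), c(2, 3, 1))            # y, x, t
    x <- gaussian_blur_yx(x, spec$gl_sd / pitch)
    rl[i, j, , , ] <- aperm(x, c(3, 1, 2))
  }
  rlp <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    nb <- pool_neighbors(sf_set, ori_set, i, j, spec)
    acc <- array(0, d[3:5])
    for (q in seq_along(nb$w))
      acc <- acc + nb$w[q] * array(rl[nb$it[q], nb$jo[q], , , ], d[3:5])
    rlp[i, j, , , ] <- acc
  }
  attributes(rlp) <- attributes(re)
  class(rlp) <- "array"
  if (return_rl) {
    attributes(rl) <- attributes(re); class(rl) <- "array"
    list(rlp = rlp, rl = rl)
  } else rlp
}

#' Delayed divisive normalization
#'
#' `R_N = R_E^n / (sigma^n + R_LP^n)`, elementwise. Because the denominator
#' is a delayed (lowpass) copy of the response, onsets produce a transient
#' that settles to a lower sustained level, while brief transients pass
#' largely unaffected.
#'
#' @param re an `energy_response`.
#' @param rlp the pooled lowpass signal from [lowpass_pool()].
#' @param spec a [normalization_spec()].
#' @return `"normalized_response"` array (theta, omega, t, y, x).
#' @export
delayed_normalize <- function(re, rlp, spec = normalization_spec()) {
  if (!identical(dim(re), dim(rlp))) stop_param("shape mismatch")
  if (any(re < 0) || any(rlp < 0))
    stop_param("negative inputs: energy() must precede normalization")
  out <- unclass(re)^spec$n / (spec$sigma^spec$n + unclass(rlp)^spec$n)
  attributes(out) <- attributes(re)
  class(out) <- "normalized_response"
  out
}

#' Run the full early-vision model on a retinal movie
#'
#' Composition of [apply_spatial()], [apply_temporal()], [energy()],
#' [lowpass_pool()] and [delayed_normalize()].
#'
#' @param movie a `retinal_movie`.
#' @param bank a `log_gabor_bank` (pitch must match).
#' @param surface a `trf_surface`.
#' @param spec a [normalization_spec()].
#' @return a `normalized_response` array (theta, omega, t, y, x).
#' @export
run_model <- function(movie, bank, surface, spec = normalization_spec()) {
  rs <- apply_spatial(bank, movie)
  rst <- apply_temporal(rs, surface)
  re <- energy(rst)
  rlp <- lowpass_pool(re, spec)
  delayed_normalize(re, rlp, spec)
}
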