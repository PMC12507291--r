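#' Collapse a response tensor across channels
#'
#' Mean over the (theta, omega) dimensions, yielding a (t, y, x) array.
#'
#' @param rn a response tensor (theta, omega, t, y, x).
#' @return array (t, y, x) with `rate` attribute when present on the input.
#' @export
collapse_channels <- function(rn) {
  d <- dim(rn)
  out <- apply(unclass(rn), 3:5, mean)
  attr(out, "rate") <- attr(rn, "rate")
  out
}

# spatial max of the positive part of the instantaneous temporal difference,
# per sample; first sample has no predecessor and yields 0
pos_change_series <- function(a_tyx) {
  d <- dim(a_tyx)
  m <- matrix(a_tyx, d[1], d[2] * d[3])
  dm <- rbind(0, diff(m))
  dm[dm < 0] <- 0
  apply(dm, 1, max)
}

#' Build the sensorimotor contingency from static-condition responses
#'
#' Averages channel-collapsed normalized responses over static-condition
#' trials into the time-resolved map `xbar`, and derives the switch
#' threshold `lambda` from the positive temporal differences of `xbar`
#' within the saccade window: `lambda = median(d+) + c * 1.4826 * MAD(d+)`.
#'
#' @param static_trials list of collapsed (t, y, x) arrays (see
#'   [collapse_channels()]), or 5-D response tensors (collapsed on the fly).
#' @param wi integration half-window in samples (15 ms at the response
#'   rate).
#' @param lambda_scale the factor `c` (default 3).
#' @param saccade_window sample range used for the threshold statistic;
#'   defaults to the whole series.
#' @return `"contingency"`: `xbar`, `lambda`, `wi`, `saccade_window`,
#'   `pred` (the windowed prediction series), `d_series`.
#' @export
build_contingency <- function(static_trials, wi, lambda_scale = 3,
                              saccade_window = NULL) {
  if (length(static_trials) < 1) stop_param("need at least one static trial")
  coll <- lapply(static_trials, function(x)
    if (length(dim(x)) == 5) collapse_channels(x) else x)
  xbar <- Reduce(`+`, coll) / length(coll)
  if (is.null(saccade_window)) saccade_window <- seq_len(dim(xbar)[1])
  d <- pos_change_series(xbar)
  dw <- d[saccade_window]
  lambda <- stats::median(dw) + lambda_scale * stats::mad(dw)
  pred <- running_max(d, wi)
  structure(list(xbar = xbar, lambda = lambda, wi = as.integer(wi),
                 lambda_scale = lambda_scale, saccade_window = saccade_window,
                 d_series = d, pred = pred),
            class = "contingency")
}

running_max <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n), function(k)
    max(x[max(1, k - w):min(n, k + w)]), numeric(1))
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("<contingency> %d samples, lambda = %.4g, wi = %d samples\n",
              dim(x$xbar)[1], x$lambda, x$wi))
  invisible(x)
}

#' Predicted visual change at sample k
#'
#' Maximum, over space and over the temporal integration window
#' `[k - wi, k + wi]` (clipped at the series ends), of the positive part of
#' the temporal difference of the contingency map `xbar`.
#'
#' @param contingency a `contingency`.
#' @param k sample index (vectorized).
#' @return numeric.
#' @export
predicted_change <- function(contingency, k) {
  contingency$pred[k]
}

#' Measured visual change at sample k
#'
#' Spatial maximum of the positive part of the instantaneous (single
#' sample) temporal difference of a trial's collapsed response.
#'
#' @param trial_collapsed (t, y, x) array.
#' @param k sample index (vectorized).
#' @return numeric.
#' @export
measured_change <- function(trial_collapsed, k) {
  pos_change_series(trial_collapsed)[k]
}

#' Run the switch model on one trial
#'
#' Computes the prediction-error series `y_k = measured - predicted`, the
#' switch indicator `K_k = 1(y_k > lambda)`, the accumulated position
#' estimate `x_{k+1} = x_k + predicted_k + K_k y_k`, and the first switch
#' time.
#'
#' @param trial either a collapsed (t, y, x) array, a 5-D response tensor,
#'   or a precomputed measured-change series (numeric vector).
#' @param contingency a `contingency` of matching length.
#' @return `"switch_trace"`: `pred_change`, `meas_change`, `y`, `K`,
#'   `x_est`, `switch_idx` (NA when the threshold is never exceeded),
#'   `lambda`.
#' @export
run_switch <- function(trial, contingency) {
  meas <- if (is.numeric(trial) && is.null(dim(trial))) {
    trial
  } else {
    x <- if (length(dim(trial)) == 5) collapse_channels(trial) else trial
    pos_change_series(x)
  }
  pred <- contingency$pred
  if (length(meas) != length(pred))
    stop_param("trial length (", length(meas),
               ") does not match contingency (", length(pred), ")")
  y <- meas - pred
  K <- as.integer(y > contingency$lambda)
  x_est <- cumsum(pred + K * y)
  sw <- which(K == 1L)
  # sub-sample switch time: linear interpolation of the first upward
  # crossing of lambda (the integer switch_idx is the first sample above)
  switch_time <- NA_real_
  if (length(sw)) {
    k <- sw[1]
    switch_time <- if (k == 1) 1 else
      k - 1 + (contingency$lambda - y[k - 1]) / (y[k] - y[k - 1])
  }
  structure(list(pred_change = pred, meas_change = meas, y = y, K = K,
                 x_est = x_est,
                 switch_idx = if (length(sw)) sw[1] else NA_integer_,
                 switch_time = switch_time,
                 lambda = contingency$lambda),
            class = "switch_trace")
}

#' @export
print.switch_trace <- function(x, ...) {
  cat(sprintf("<switch_trace> %d samples, lambda %.4g, switch at %s\n",
              length(x$y), x$lambda,
              if (is.na(x$switch_idx)) "none" else paste0("sample ", x$switch_idx)))
  invisible(x)
}

#' Positive sum of differences between two prediction-error series
#'
#' @param y_present,y_absent aligned series.
#' @param time_resolved return the per-sample positive differences instead
#'   of their sum.
#' @return scalar (or vector when `time_resolved = TRUE`).
#' @export
pos_sum_diff <- function(y_present, y_absent, time_resolved = FALSE) {
  if (length(y_present) != length(y_absent))
    stop_param("series are not aligned (lengths ", length(y_present), " vs ",
               length(y_absent), ")")
  d <- pmax(y_present - y_absent, 0)
  if (time_resolved) d else sum(d)
}
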