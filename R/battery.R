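# Trial simulation at study scale and the streaming model pipeline used for
# multi-trial batteries.

#' Canvas presets
#'
#' `full_scale()` is the native study resolution (pitch 3.36/51 dva/px,
#' 1440 Hz). `battery_scale()` is the reduced resolution used for
#' multi-trial simulations: pitch 0.122 dva/px (the coarsest that still
#' resolves the 4 cpd channel at two samples per cycle) at 240 Hz, with
#' 6x temporal supersampling in the renderer so that continuous motion is
#' integrated within each frame rather than point-sampled. Switch times
#' are interpolated across the threshold crossing, so their resolution is
#' not limited to the frame interval.
#'
#' @param window total movie duration in seconds (saccade onset sits
#'   `pre` seconds after movie start).
#' @param pre pre-saccadic padding in seconds.
#' @return list with `canvas` (a [canvas_spec()]), `supersample`, `pre`,
#'   `window`.
#' @export
battery_scale <- function(window = 0.185, pre = 0.025) {
  list(canvas = canvas_spec(xlim = c(-10.2, 20.4), ylim = c(-8.6, 8.6),
                            pitch = 0.122, rate = 240),
       supersample = 6L, pre = pre, window = window)
}

#' @rdname battery_scale
#' @export
full_scale <- function(window = 0.185, pre = 0.025) {
  list(canvas = canvas_spec(xlim = c(-10.2, 20.4), ylim = c(-8.6, 8.6),
                            pitch = 3.36 / 51, rate = 1440),
       supersample = 1L, pre = pre, window = window)
}

#' Simulate a single experimental trial
#'
#' Generates saccade and target trajectories under the study conditions
#' (17.6 dva mean amplitude, 53.6 ms mean duration, 6.6 dva target step
#' over 25 ms strictly inside the saccade, 0.15 dva mean upward saccade
#' bias) and renders the retinotopic movie.
#'
#' @param direction target motion direction (see
#'   [schedule_target_motion()]).
#' @param streak `"present"` or `"absent"`.
#' @param patch a `stimulus_patch` (resampled to the canvas pitch if
#'   needed).
#' @param scale a scale preset (see [battery_scale()]).
#' @param params optional list overriding the per-trial draws: `amplitude`,
#'   `duration`, `vertical_bias`, `start_latency`.
#' @param seed optional seed for the per-trial parameter draws (ignored
#'   when `params` is given).
#' @return a `retinal_movie` with `params` attached.
#' @export
simulate_trial <- function(direction, streak, patch,
                           scale = battery_scale(), params = NULL,
                           seed = NULL) {
  if (is.null(params)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    params <- draw_trial_params(1)[[1]]
  }
  rate <- scale$canvas$rate
  sac <- synthesize_saccade(amplitude = params$amplitude,
                            duration = params$duration,
                            vertical_bias = params$vertical_bias,
                            rate = rate, pre = scale$pre,
                            post = (round(scale$window * rate) -
                                    round(scale$pre * rate) -
                                    round(params$duration * rate)) / rate)
  tgt <- schedule_target_motion(direction, streak, sac,
                                start_latency = params$start_latency)
  movie <- render_retinal_movie(patch, sac, tgt, scale$canvas,
                                supersample = scale$supersample)
  movie$params <- params
  movie
}

rtrunc <- function(n, mean, sd, lo, hi)
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

# per-trial parameter draws matching the study's saccade statistics
draw_trial_params <- function(n) {
  amplitude <- rtrunc(n, 17.6, 0.8, 15.5, 19.6)
  duration <- rtrunc(n, 0.0536, 0.003, 0.0455, 0.0678)
  vertical_bias <- stats::rnorm(n, 0.15, 0.10)
  # measured stimulus-onset latency ~17.5 ms; motion must end (25 ms plus
  # a margin) before the saccade offset
  start_latency <- pmin(rtrunc(n, 0.0175, 0.002, 0.012, 0.0205),
                        duration - 0.0255)
  lapply(seq_len(n), function(i)
    list(amplitude = amplitude[i], duration = duration[i],
         vertical_bias = vertical_bias[i], start_latency = start_latency[i]))
}

# block ("participant") level kinematic means
draw_block_means <- function(n) {
  amplitude <- rtrunc(n, 17.6, 0.7, 15.8, 19.3)
  duration <- rtrunc(n, 0.0536, 0.0025, 0.047, 0.066)
  vertical_bias <- stats::rnorm(n, 0.15, 0.07)
  start_latency <- rtrunc(n, 0.0175, 0.001, 0.014, 0.020)
  lapply(seq_len(n), function(i)
    list(amplitude = amplitude[i], duration = duration[i],
         vertical_bias = vertical_bias[i], start_latency = start_latency[i]))
}

# trial-level jitter around a block's means
draw_trial_jitter <- function(bm) {
  duration <- rtrunc(1, bm$duration, 0.002, 0.0455, 0.0678)
  list(amplitude = rtrunc(1, bm$amplitude, 0.5, 15.5, 19.6),
       duration = duration,
       vertical_bias = stats::rnorm(1, bm$vertical_bias, 0.05),
       start_latency = min(rtrunc(1, bm$start_latency, 0.0015, 0.012, 0.0205),
                           duration - 0.0255))
}

# Direction-specific retinotopic canvas: covers the target's retinal
# excursion for that condition plus the patch footprint and most of the
# filter spill, without carrying the full union canvas for every trial.
direction_canvas <- function(direction, pitch, rate) {
  ylim <- switch(direction,
                 upward = c(-4.6, 10.8),
                 downward = c(-11.2, 4.2),
                 c(-4.6, 4.2))
  xlim <- if (direction == "inward") c(-10.2, 20.4) else c(-5.4, 20.4)
  canvas_spec(xlim, ylim, pitch, rate)
}

# mean retinal trajectory orientation (deg, period 180) over the motion
# window (or the saccade window for static trials)
trajectory_orientation <- function(saccade, target) {
  retinal <- target$position - saccade$gaze
  idx <- if (is.na(target$motion_onset_idx))
    saccade$onset_idx:(saccade$offset_idx - 1L)
  else target$motion_onset_idx:(target$motion_offset_idx - 1L)
  dx <- sum(retinal[idx + 1L, 1] - retinal[idx, 1])
  dy <- sum(retinal[idx + 1L, 2] - retinal[idx, 2])
  wrap_ori(atan2(dy, dx) * 180 / pi)
}

# Streaming pipeline for one movie (compiled core): spatial filtering with
# shared padded-grid transfer functions, temporal filtering, energy, and
# delayed normalization with channel pooling, reduced on the fly to the
# quantities the battery needs.
stream_trial_model <- function(movie, bank, transfers, hts, spec,
                               return_collapsed = FALSE) {
  d <- dim(movie$frames)
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  nth <- length(bank$spec$sf_set); nom <- length(bank$spec$ori_set)
  a <- exp(-1 / (movie$rate * tau_seconds(spec)))
  sd_px <- spec$gl_sd / movie$pitch
  r_bl <- max(1L, ceiling(3 * sd_px))
  gk <- exp(-(-r_bl:r_bl)^2 / (2 * sd_px^2)); gk <- gk / sum(gk)
  pool_idx <- vector("list", nth * nom)
  pool_w <- vector("list", nth * nom)
  for (i in seq_len(nth)) for (j in seq_len(nom)) {
    nb <- pool_neighbors(bank$spec$sf_set, bank$spec$ori_set, i, j, spec)
    pool_idx[[(i - 1) * nom + j]] <- as.integer((nb$it - 1) * nom + nb$jo - 1)
    pool_w[[(i - 1) * nom + j]] <- nb$w
  }
  flat_transfers <- unlist(transfers, recursive = FALSE)
  res <- cpp_stream_model(movie$frames, flat_transfers, hts,
                          nth, nom, pool_idx, pool_w, a, gk,
                          spec$sigma, spec$n, return_collapsed)
  out <- list(meas = as.vector(res$meas), engagement = res$engagement,
              spatial_map = res$spatial_map)
  if (return_collapsed) {
    collapsed <- aperm(array(res$collapsed, c(ny, nx, nt)), c(3, 1, 2))
    attr(collapsed, "rate") <- movie$rate
    out$collapsed <- collapsed
  }
  out
}

# banded convolution matrix (truncated at edges) for a unit-sum kernel
band_conv_matrix <- function(n, g) {
  r <- (length(g) - 1L) / 2L
  C <- matrix(0, n, n)
  for (j in -r:r) {
    idx <- seq_len(n); src <- idx + j
    ok <- src >= 1 & src <= n
    C[cbind(idx[ok], src[ok])] <- g[j + r + 1]
  }
  C
}

# nt x nt matrix implementing causal convolution with kernel h (times dt)
# as a right-multiply: out = m %*% HT, m is (pix x t)
temporal_conv_matrix <- function(h, nt, dt) {
  if (length(h) > nt) h <- h[seq_len(nt)]
  HT <- matrix(0, nt, nt)
  for (j in seq_along(h)) {
    idx <- seq_len(nt - j + 1)
    HT[cbind(idx, idx + j - 1)] <- h[j]
  }
  HT * dt
}

#' Run a synthetic trial battery through the model and the switch stage
#'
#' Generates `n_per_cell` parameter draws per target direction, renders
#' each as a matched present/absent pair (same saccade, same patch; only
#' the motion interval differs), runs the early-vision model, builds the
#' sensorimotor contingency from the static trials, and computes
#' prediction-error (switch) times for every trial.
#'
#' @param seed master seed; the battery is fully reproducible.
#' @param surface a `trf_surface` for the temporal kernels.
#' @param n_per_cell parameter draws per direction (default 4, i.e.
#'   5 directions x 2 streak conditions x 4 = 40 trials).
#' @param directions condition set.
#' @param scale a scale preset (see [battery_scale()]).
#' @param spec a [normalization_spec()].
#' @param bank optional prebuilt `log_gabor_bank` at the canvas pitch.
#' @param lambda_scale threshold scale factor `c` (see
#'   [build_contingency()]).
#' @param wi_ms prediction integration half-window in ms (15).
#' @param n_contingency extra static-condition trials per block, used only
#'   to build that block's sensorimotor contingency (the contingency
#'   stands for accumulated experience with target-capturing saccades, so
#'   it is estimated from more static trials than the battery itself
#'   evaluates).
#' @param progress print per-trial progress to stderr.
#' @return `"switch_battery"`: `table` (one row per trial: direction,
#'   streak, pair id, switch sample/ms relative to saccade offset and to
#'   motion offset, trajectory orientation, minimum retinal speed),
#'   `engagement` (theta x omega x trial), `y` (prediction-error series x
#'   trial), `spatial_maps`, `contingency`, `bank_spec`, `scale`, `seed`.
#' @export
run_battery <- function(seed, surface, n_per_cell = 4,
                        directions = c("static", "inward", "outward",
                                       "upward", "downward"),
                        scale = battery_scale(),
                        spec = normalization_spec(), bank = NULL,
                        lambda_scale = 3, wi_ms = 15, n_contingency = 6,
                        progress = FALSE) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  rate <- scale$canvas$rate
  # one patch per parameter block (as each participant saw their own
  # patch); anisotropies of individual noise draws average out across
  # blocks in condition summaries
  patch_seeds <- sample.int(2^30, n_per_cell)
  patches <- lapply(patch_seeds, function(s)
    resample_patch(make_noise_patch(seed = s), scale$canvas$pitch))
  if (is.null(bank)) bank <- build_bank(bank_spec(), scale$canvas$pitch)
  nt <- round(scale$window * rate) + 1L
  pad <- max(bank$extent_px)
  transfer_cache <- new.env(parent = emptyenv())
  transfers_for <- function(canvas) {
    PY <- good_fft_size(length(canvas$ygrid) + pad)
    PX <- good_fft_size(length(canvas$xgrid) + pad)
    key <- paste(PY, PX)
    if (is.null(transfer_cache[[key]]))
      transfer_cache[[key]] <- bank_transfers(bank, PY, PX)
    transfer_cache[[key]]
  }
  hts <- lapply(bank$spec$sf_set, function(th)
    temporal_conv_matrix(calibrated_kernel(surface, th, rate), nt, 1 / rate))
  # Two-level design: each block plays the role of a participant, with its
  # own noise patch, its own mean saccade kinematics, and its own
  # sensorimotor contingency built from its static trials. Within a block,
  # moving-condition present/absent pairs share the trial-level draw
  # (matched pairs for streak contrasts); the two static trials are
  # independent draws so the block contingency has within-block variance.
  block_means <- draw_block_means(n_per_cell)
  grid <- expand.grid(rep = seq_len(n_per_cell), direction = directions,
                      stringsAsFactors = FALSE)
  grid$pair <- seq_len(nrow(grid))
  # all series are aligned at saccade offset (the reference point of the
  # offset-locked analyses); k0 is the common offset sample
  onset <- round(scale$pre * rate) + 1L
  k0 <- onset + round(0.0678 * rate)
  shift_right <- function(x, s) {
    if (s <= 0) return(x)
    c(rep(0, s), x[seq_len(length(x) - s)])
  }
  rows <- list(); eng <- list(); ys <- list(); maps <- list()
  meas_list <- list()
  static_coll <- lapply(seq_len(n_per_cell), function(b) list())
  trial_meta <- list()
  tid <- 0L
  for (g in seq_len(nrow(grid))) {
    blk <- grid$rep[g]
    pair_draw <- draw_trial_jitter(block_means[[blk]])
    for (streak in c("present", "absent")) {
      tid <- tid + 1L
      p <- if (grid$direction[g] == "static")
        draw_trial_jitter(block_means[[blk]]) else pair_draw
      sac <- synthesize_saccade(amplitude = p$amplitude,
                                duration = p$duration,
                                vertical_bias = p$vertical_bias,
                                rate = rate, pre = scale$pre,
                                post = (round(scale$window * rate) -
                                        round(scale$pre * rate) -
                                        round(p$duration * rate)) / rate)
      tgt <- schedule_target_motion(grid$direction[g], streak, sac,
                                    start_latency = p$start_latency)
      canvas <- direction_canvas(grid$direction[g], scale$canvas$pitch, rate)
      movie <- render_retinal_movie(patches[[grid$rep[g]]], sac, tgt, canvas,
                                    supersample = scale$supersample)
      res <- stream_trial_model(movie, bank, transfers_for(canvas), hts, spec,
                                return_collapsed =
                                  grid$direction[g] == "static")
      s_k <- k0 - sac$offset_idx
      if (grid$direction[g] == "static") {
        coll <- res$collapsed
        if (s_k > 0) {
          shifted <- array(0, dim(coll))
          shifted[(s_k + 1):nt, , ] <- coll[seq_len(nt - s_k), , ]
          attr(shifted, "rate") <- attr(coll, "rate")
          coll <- shifted
        }
        static_coll[[blk]][[length(static_coll[[blk]]) + 1L]] <- coll
      }
      meas_list[[tid]] <- shift_right(res$meas, s_k)
      eng[[tid]] <- res$engagement
      maps[[tid]] <- res$spatial_map
      trial_meta[[tid]] <- list(
        direction = grid$direction[g], streak = streak, pair = grid$pair[g],
        block = blk,
        onset_idx = sac$onset_idx + s_k, offset_idx = k0,
        motion_offset_idx = tgt$motion_offset_idx + s_k,
        traj_dir = trajectory_orientation(sac, tgt),
        min_retinal_speed = min_retinal_speed(sac, tgt))
      if (progress)
        message(sprintf("trial %d/%d: %s/%s", tid,
                        2L * nrow(grid), grid$direction[g], streak))
    }
  }
  # extra static trials per block for contingency estimation only
  if (n_contingency > 0) {
    for (blk in seq_len(n_per_cell)) {
      canvas <- direction_canvas("static", scale$canvas$pitch, rate)
      for (q in seq_len(n_contingency)) {
        p <- draw_trial_jitter(block_means[[blk]])
        sac <- synthesize_saccade(amplitude = p$amplitude,
                                  duration = p$duration,
                                  vertical_bias = p$vertical_bias,
                                  rate = rate, pre = scale$pre,
                                  post = (round(scale$window * rate) -
                                          round(scale$pre * rate) -
                                          round(p$duration * rate)) / rate)
        tgt <- schedule_target_motion("static", "present", sac,
                                      start_latency = p$start_latency)
        movie <- render_retinal_movie(patches[[blk]], sac, tgt, canvas,
                                      supersample = scale$supersample)
        res <- stream_trial_model(movie, bank, transfers_for(canvas), hts,
                                  spec, return_collapsed = TRUE)
        s_k <- k0 - sac$offset_idx
        coll <- res$collapsed
        if (s_k > 0) {
          shifted <- array(0, dim(coll))
          shifted[(s_k + 1):nt, , ] <- coll[seq_len(nt - s_k), , ]
          attr(shifted, "rate") <- attr(coll, "rate")
          coll <- shifted
        }
        static_coll[[blk]][[length(static_coll[[blk]]) + 1L]] <- coll
        if (progress)
          message(sprintf("contingency trial %d/%d (block %d)", q,
                          n_contingency, blk))
      }
    }
  }
  wi <- round(wi_ms / 1000 * rate)
  sacc_win <- onset:k0
  contingencies <- lapply(static_coll, function(sc)
    build_contingency(sc, wi = wi, lambda_scale = lambda_scale,
                      saccade_window = sacc_win))
  tab <- do.call(rbind, lapply(seq_len(tid), function(k) {
    m <- trial_meta[[k]]
    tr <- run_switch(meas_list[[k]], contingencies[[m$block]])
    ys[[k]] <<- tr$y
    data.frame(trial = k, direction = m$direction, streak = m$streak,
               pair = m$pair, block = m$block,
               lambda = contingencies[[m$block]]$lambda,
               switch_idx = tr$switch_idx,
               switch_ms_offset = (tr$switch_time - m$offset_idx) / rate * 1000,
               switch_ms_motion = if (!is.na(m$motion_offset_idx))
                 (tr$switch_time - m$motion_offset_idx) / rate * 1000
               else NA_real_,
               traj_dir = m$traj_dir,
               min_retinal_speed = m$min_retinal_speed,
               onset_idx = m$onset_idx, offset_idx = m$offset_idx,
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab,
                 engagement = array(unlist(eng),
                                    c(length(bank$spec$sf_set),
                                      length(bank$spec$ori_set), tid)),
                 y = do.call(cbind, ys),
                 spatial_maps = maps,
                 contingencies = contingencies,
                 contingency = contingencies[[1]],
                 bank_spec = bank$spec, scale = scale, seed = seed,
                 rate = rate),
            class = "switch_battery")
}

#' @export
print.switch_battery <- function(x, ...) {
  cat(sprintf("<switch_battery> %d trials, seed %d, lambda %.4g\n",
              nrow(x$table), x$seed, x$contingency$lambda))
  agg <- stats::aggregate(switch_ms_offset ~ direction + streak,
                          data = x$table, FUN = function(v)
                            round(mean(v, na.rm = TRUE), 1))
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Mean engagement contrast per direction from a battery
#'
#' Averages present and absent engagement across a battery's trials for
#' one direction and returns their difference.
#'
#' @param battery a `switch_battery`.
#' @param direction condition label.
#' @return (theta x omega) contrast with channel attributes.
#' @export
battery_engagement_contrast <- function(battery, direction) {
  tab <- battery$table
  sel <- function(s) which(tab$direction == direction & tab$streak == s)
  mean_eng <- function(idx) {
    m <- apply(battery$engagement[, , idx, drop = FALSE], c(1, 2), mean)
    structure(m, sf_set = battery$bank_spec$sf_set,
              ori_set = battery$bank_spec$ori_set,
              class = "channel_engagement")
  }
  condition_difference(mean_eng(sel("present")), mean_eng(sel("absent")))
}
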