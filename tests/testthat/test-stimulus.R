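test_that("noise patches are reproducible, bounded, and band-limited", {
  p1 <- make_noise_patch(7)
  p2 <- make_noise_patch(7)
  expect_identical(p1$pixels, p2$pixels)
  p3 <- make_noise_patch(8)
  expect_lt(cor(as.vector(p1$pixels), as.vector(p3$pixels)), 0.5)
  expect_true(all(abs(p1$pixels) <= 1))
  expect_equal(nrow(p1$pixels), 51)
  # peak contrast is normalized to 1 before the aperture
  pna <- make_noise_patch(7, aperture_sd = Inf)
  expect_equal(max(abs(pna$pixels)), 1)
  # -3 dB points of the radially averaged power spectrum: a single 51-px
  # realization is noise-limited, so pool spectra over independent seeds
  pool <- lapply(1:16, function(s) make_noise_patch(s, aperture_sd = Inf))
  cuts <- measure_band_cutoffs(pool)
  expect_lt(abs(cuts["lo"] - 0.33) / 0.33, 0.2)
  expect_lt(abs(cuts["hi"] - 1.02) / 1.02, 0.2)
})

test_that("noise patch edge cases and parameter validation", {
  z <- make_noise_patch(1, amplitude = 0, aperture_sd = Inf)
  expect_true(all(z$pixels == 0))
  expect_error(make_noise_patch(1, size_px = 50), "odd")
  expect_error(make_noise_patch(1, cutoff_hi = 10), "Nyquist")
  # Gaussian aperture acts multiplicatively
  pa <- make_noise_patch(7)
  pn <- make_noise_patch(7, aperture_sd = Inf)
  half <- 25
  ap <- exp(-outer(((-half:half) * pa$pitch)^2,
                   ((-half:half) * pa$pitch)^2, `+`) / (2 * 0.56^2))
  expect_equal(pa$pixels, pn$pixels * ap, tolerance = 1e-12)
})

test_that("synthesized saccades have realistic, consistent kinematics", {
  s <- synthesize_saccade(amplitude = 17.6, duration = 0.0536)
  expect_gt(s$peak_velocity, 400)
  expect_lt(s$peak_velocity, 650)
  # displacement equals amplitude
  disp <- unname(s$gaze[s$offset_idx, 1] - s$gaze[s$onset_idx, 1])
  expect_equal(disp, 17.6, tolerance = 1e-6)
  # velocity identically zero outside the saccade
  v <- sqrt(diff(s$gaze[, 1])^2 + diff(s$gaze[, 2])^2) * s$rate
  expect_true(all(v[seq_len(s$onset_idx - 1)] == 0))
  expect_true(all(v[s$offset_idx:length(v)] == 0))
  # zero-amplitude saccade: constant gaze
  s0 <- synthesize_saccade(amplitude = 0)
  expect_true(all(s0$gaze[, 1] == s0$gaze[1, 1]))
  expect_equal(s0$peak_velocity, 0)
  # vertical bias reaches its full value at offset
  sb <- synthesize_saccade(vertical_bias = 0.15)
  expect_equal(unname(sb$gaze[sb$offset_idx, 2] - sb$gaze[sb$onset_idx, 2]),
               0.15, tolerance = 1e-9)
  # leftward saccades mirror horizontally
  sl <- synthesize_saccade(direction = "left")
  expect_equal(unname(sl$gaze[sl$offset_idx, 1]), -17.6, tolerance = 1e-6)
})

test_that("target motion scheduling matches the trial design", {
  s <- synthesize_saccade(rate = 1440)
  tg <- schedule_target_motion("upward", "present", s)
  # 25 ms at 1440 fps spans exactly 36 frames
  expect_equal(tg$motion_offset_idx - tg$motion_onset_idx + 1L, 36L)
  expect_true(all(tg$visible))
  # constant velocity: equal per-frame steps summing to 6.6 dva
  seg <- tg$position[tg$motion_onset_idx:tg$motion_offset_idx, 2]
  expect_equal(diff(range(seg)), 6.6)
  expect_equal(diff(seg), rep(6.6 / 35, 35), tolerance = 1e-12)
  expect_lte(tg$motion_offset_idx, s$offset_idx)
  # static: constant position, visible throughout
  tgs <- schedule_target_motion("static", "present", s)
  expect_true(all(tgs$position[, 1] == 18.25) && all(tgs$visible))
  # absent: invisible during the motion frames, endpoint afterwards
  tga <- schedule_target_motion("upward", "absent", s)
  expect_true(all(!tga$visible[tga$motion_onset_idx:tga$motion_offset_idx]))
  expect_equal(tga$position[tga$motion_onset_idx + 35L, 2], 6.6)
  expect_true(all(tga$visible[(tga$motion_offset_idx + 1L):nrow(tga$position)]))
  # motion that would outlast the saccade is rejected
  expect_error(schedule_target_motion("upward", "present", s,
                                      start_latency = 0.04),
               "offset")
})

test_that("renderer places the patch at target-minus-gaze and conserves energy", {
  patch <- make_noise_patch(3, size_px = 25)
  canvas <- canvas_spec(xlim = c(-3, 3), ylim = c(-3, 3), rate = 480)
  # stationary gaze, static target at the fovea: identical frames
  s0 <- synthesize_saccade(amplitude = 0, rate = 480, pre = 0.002,
                           post = 0.004)
  t0 <- schedule_target_motion("static", "present", s0, origin = c(0.4, -0.3))
  mv <- render_retinal_movie(patch, s0, t0, canvas)
  expect_true(all(apply(mv$frames, 3, function(f) identical(f, mv$frames[, , 1]))))
  # the rendered frame equals a direct insertion at target minus gaze
  expected <- streakvision:::insert_patch(
    matrix(0, length(canvas$ygrid), length(canvas$xgrid)), patch$pixels,
    (-0.3 - canvas$ylim[1]) / canvas$pitch + 1,
    (0.4 - canvas$xlim[1]) / canvas$pitch + 1)
  expect_equal(mv$frames[, , 1], expected, tolerance = 1e-12)
  # moving gaze: retinal position tracks -gaze; |contrast| mass is conserved
  s1 <- synthesize_saccade(amplitude = 1.5, duration = 0.03, rate = 480,
                           pre = 0.004, post = 0.004)
  t1 <- schedule_target_motion("static", "present", s1, origin = c(0.5, 0))
  mv1 <- render_retinal_movie(patch, s1, t1, canvas)
  masses <- apply(mv1$frames, 3, function(f) sum(abs(f)))
  expect_lt(diff(range(masses)) / mean(masses), 0.05)
  for (k in c(1L, s1$onset_idx + 5L, nrow(s1$gaze))) {
    pos <- t1$position[k, ] - s1$gaze[k, ]
    expected <- streakvision:::insert_patch(
      matrix(0, length(canvas$ygrid), length(canvas$xgrid)), patch$pixels,
      (pos[2] - canvas$ylim[1]) / canvas$pitch + 1,
      (pos[1] - canvas$xlim[1]) / canvas$pitch + 1)
    expect_equal(mv1$frames[, , k], expected, tolerance = 1e-12)
  }
  # default pitch ties 51 px to 3.36 dva
  expect_equal(canvas_spec()$pitch, 3.36 / 51)
  # leaving the canvas raises an error naming the first bad frame
  t2 <- schedule_target_motion("static", "present", s0, origin = c(5, 0))
  expect_error(render_retinal_movie(patch, s0, t2, canvas), "frame 1")
})

test_that("retinal rotation labels follow the cross-product rule", {
  expect_equal(retinal_rotation_label("right", "upward"), "CW")
  expect_equal(retinal_rotation_label("left", "downward"), "CW")
  expect_equal(retinal_rotation_label("right", "downward"), "CCW")
  expect_equal(retinal_rotation_label("left", "upward"), "CCW")
  expect_equal(retinal_rotation_label("right", "static"), "undefined")
  expect_equal(retinal_rotation_label("right", "outward"), "undefined")
})

test_that("outward motion strongly reduces the target's minimum retinal speed", {
  s <- synthesize_saccade()
  out <- schedule_target_motion("outward", "present", s)
  sta <- schedule_target_motion("static", "present", s)
  v_out <- streakvision:::min_retinal_speed(s, out)
  v_sta <- streakvision:::min_retinal_speed(
    s, sta, window = out$motion_onset_idx:(out$motion_offset_idx - 1L))
  expect_lt(v_out, 60)
  expect_gt(v_sta, 200)
})
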