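test_that("the sensitivity surface is bandpass at low SF and lowpass at high SF", {
  # low SF: mid temporal frequencies beat the lowest
  expect_gt(kelly_sensitivity(0.25, 8), kelly_sensitivity(0.25, 0.5))
  # high SF: sensitivity falls with temporal frequency
  expect_gt(kelly_sensitivity(4, 0.5), kelly_sensitivity(4, 30))
  expect_error(kelly_sensitivity(0.01, 1), "range")
  expect_error(kelly_sensitivity(1, 100), "range")
  # frozen full-grid maximum (regression fixture computed by brute-force
  # evaluation of the implemented closed form over the 31 x 33 grid)
  g <- kelly_grid()
  S <- outer(g$sf_grid, g$tf_grid, kelly_sensitivity)
  pk <- which(S == max(S), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(22, 14))   # ~2.0 cpd, ~3.2 Hz
  expect_equal(max(S), 109.9765, tolerance = 1e-3)
})

test_that("flicker envelopes are Gaussian-ramped sinusoids", {
  fl <- flicker_envelope(4)
  expect_equal(fl$ramp_sd, 7.5 / 8)
  expect_equal(fl$ramp_sd, 0.9375)
  # Gaussian factor peaks (=1) at delta/2; at a sine peak nearest delta/2
  # the envelope is close to +/-1
  g <- exp(-(fl$t - 7.5 / 2)^2 / (2 * 0.9375^2))
  expect_equal(max(g), 1, tolerance = 1e-9)
  expect_equal(fl$envelope, sin(2 * pi * 4 * fl$t) * g, tolerance = 1e-12)
  # RMS over the stimulus versus quadrature oracle:
  # mean(sin^2) * integral of Gaussian^2 via direct numerical quadrature
  rms <- sqrt(mean(fl$envelope^2))
  oracle <- sqrt(sum(sin(2 * pi * 4 * fl$t)^2 * g^2) / length(fl$t))
  expect_equal(rms, oracle, tolerance = 1e-12)
  expect_error(flicker_envelope(300, rate = 500), "alias")
})

test_that("the two-stage kernel has the expected lobe structure", {
  t <- seq(0, 0.6, by = 1 / 500)
  p0 <- list(A = 1, tau = 0.007, n = 9, B = 0, k = 1)
  h <- trf_kernel(p0, t)
  expect_equal(h[1], 0)
  expect_true(all(h >= 0))
  # monophasic kernel peaks at t = n * tau (within one sample)
  expect_lt(abs(t[which.max(h)] - 9 * 0.007), 1.01 / 500)
  # sufficiently strong transience: exactly one sign change
  p1 <- list(A = 1, tau = 0.007, n = 9, B = 1, k = 1)
  h1 <- trf_kernel(p1, t)
  signs <- sign(h1[abs(h1) > 1e-9 * max(abs(h1))])
  expect_equal(sum(diff(signs) != 0), 1)
  expect_equal(kernel_phasity(p1), "biphasic")
  expect_equal(kernel_phasity(p0), "monophasic")
  expect_error(trf_kernel(list(A = 1, tau = 0.007, n = 2.5, B = 0, k = 1), t),
               "integer")
})

test_that("probability summation behaves like a power-law norm", {
  p <- list(A = 2, tau = 0.008, n = 7, B = 0.6, k = 1)
  f <- c(1, 4, 16)
  s1 <- predicted_sensitivity(p, f)
  # degree-1 homogeneity in A
  p2 <- p; p2$A <- 4
  expect_equal(predicted_sensitivity(p2, f), 2 * s1, tolerance = 1e-9)
  # large beta approaches the response maximum
  fl <- flicker_envelope(4)
  h <- trf_kernel(p, seq(0, 0.6, by = 1 / 500))
  r <- convolve(fl$envelope, rev(h), type = "open") / 500
  s100 <- predicted_sensitivity(p, 4, beta_ps = 100)
  expect_lt(abs(s100 - max(abs(r))) / max(abs(r)), 0.05)
  # direct-summation oracle at beta = 3
  oracle <- (sum(abs(r)^3) / 500)^(1 / 3)
  expect_equal(s1[2], oracle, tolerance = 1e-6 * oracle)
  expect_error(predicted_sensitivity(p, 4, beta_ps = -1), "positive")
})

test_that("TRF fitting recovers known parameters from synthetic sensitivities", {
  truth <- list(A = 5, tau = 0.0065, n = 10, B = 0.9, k = 1, theta = 1)
  targets <- predicted_sensitivity(truth, kelly_grid()$tf_grid)
  fit <- fit_trf_for_sf(1, targets = targets)
  expect_equal(fit$n, truth$n)
  expect_equal(fit$k, truth$k)
  expect_lt(abs(fit$tau - truth$tau) / truth$tau, 0.05)
  expect_lt(abs(fit$B - truth$B) / truth$B, 0.05)
  expect_lt(abs(fit$A - truth$A) / truth$A, 0.05)
  expect_true(fit$converged)
})

test_that("fitted kernels transition from biphasic to monophasic with SF", {
  fits <- cached_bank_fits()
  phas <- vapply(fits, kernel_phasity, character(1))
  sf <- bank_spec()$sf_set
  expect_true(all(phas[sf < 2] == "biphasic"))
  expect_true(all(phas[sf > 2] == "monophasic"))
})

test_that("the time-by-SF surface interpolates its training kernels", {
  surf <- cached_surface()
  # interpolation fidelity at training SFs
  expect_lt(max(surf$rel_rmse), 0.05)
  # kernel at an intermediate SF is bracketed by neighbors where they agree
  h10 <- surface_kernel(surf, 1.0, 500)
  h16 <- surface_kernel(surf, 1.59, 500)
  h12 <- surface_kernel(surf, 1.2, 500)
  n <- min(length(h10), length(h12), length(h16))
  agree <- sign(h10[1:n]) == sign(h16[1:n]) &
    abs(h10[1:n]) > 0.05 * max(abs(h10)) &
    abs(h16[1:n]) > 0.05 * max(abs(h16))
  lohi <- cbind(pmin(h10[1:n], h16[1:n]), pmax(h10[1:n], h16[1:n]))
  tol <- 0.1 * max(abs(h10))
  expect_true(all(h12[1:n][agree] >= lohi[agree, 1] - tol &
                    h12[1:n][agree] <= lohi[agree, 2] + tol))
  expect_error(surface_kernel(surf, 20, 500), "range")
  expect_error(fit_trf_surface(cached_trf_fits()[1]), "at least 2")
})

test_that("temporal filtering is causal and matches the double-sum oracle", {
  surf <- cached_surface()
  set.seed(5)
  rate <- 480
  nth <- 2; nom <- 2; nt <- 20; ny <- 3; nx <- 3
  rs <- array(complex(real = rnorm(nth * nom * nt * ny * nx),
                      imaginary = rnorm(nth * nom * nt * ny * nx)),
              c(nth, nom, nt, ny, nx))
  rs <- structure(rs, class = "spatial_response",
                  sf_set = c(1.0, 2.52), ori_set = c(0, 90),
                  rate = rate, pitch = 0.1)
  out <- suppressWarnings(apply_temporal(rs, surf))
  h <- calibrated_kernel(surf, 1.0, rate)
  # direct double-sum convolution at one site
  for (t in c(1, 7, 20)) {
    acc <- 0 + 0i
    for (j in seq_len(min(t, length(h))))
      acc <- acc + h[j] * rs[1, 2, t - j + 1, 2, 3] / rate
    expect_equal(out[1, 2, t, 2, 3], acc, tolerance = 1e-10)
  }
  # causality: changing future inputs leaves earlier outputs unchanged
  rs2 <- rs
  rs2[, , 15:20, , ] <- 0
  out2 <- suppressWarnings(apply_temporal(rs2, surf))
  expect_equal(out2[, , 1:14, , ], out[, , 1:14, , ], tolerance = 1e-12)
  # zero input
  z <- rs; z[] <- 0i
  expect_true(all(suppressWarnings(apply_temporal(z, surf)) == 0))
  # a kernel longer than the series warns
  expect_warning(apply_temporal(rs, surf), "longer")
})
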