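make_response <- function(arr, sf_set, ori_set, rate = 480, pitch = 0.1) {
  structure(arr, class = if (is.complex(arr)) "spatial_response" else
    "energy_response", sf_set = sf_set, ori_set = ori_set,
    rate = rate, pitch = pitch)
}

test_that("quadrature energy squares and sums the two phases", {
  arr <- array(complex(real = 3, imaginary = 4), c(1, 1, 1, 1, 1))
  re <- energy(make_response(arr, 1, 0))
  expect_equal(as.vector(re), 25)
  set.seed(1)
  arr2 <- array(complex(real = rnorm(8), imaginary = rnorm(8)), c(1, 2, 2, 1, 2))
  expect_true(all(energy(make_response(arr2, 1, c(0, 90))) >= 0))
  expect_error(energy(array(1, c(1, 1, 1, 1, 1))), "phase")
})

test_that("a quadrature pair responds to a drifting grating with low ripple", {
  pitch <- 3.36 / 51
  bank <- build_bank(bank_spec(sf_set = 1.59, ori_set = 0), pitch)
  n <- 48; nt <- 24; rate <- 480
  xy <- (seq_len(n) - (n + 1) / 2) * pitch
  tf <- 6
  frames <- array(0, c(n, n, nt))
  for (t in seq_len(nt))
    frames[, , t] <- outer(xy, xy, function(y, x)
      cos(2 * pi * (1.59 * y - tf * (t - 1) / rate)))
  rs <- apply_spatial(bank, tiny_movie(frames, pitch, rate))
  re <- energy(rs)
  trace <- re[1, 1, , n / 2, n / 2]
  expect_lt((max(trace) - min(trace)) / mean(trace), 0.1)
})

test_that("lowpass pooling has unit steady-state gain and Gaussian weights", {
  sf_set <- c(0.5, 1, 2); ori_set <- c(0, 45, 90)
  spec <- normalization_spec(pool_radius = 1)
  # long series (4+ s) so the tau = 0.75 s lowpass settles; interior
  # pixel so the truncated unit-sum spatial kernel is complete
  nt <- 1500; rate <- 360
  arr <- array(2, c(3, 3, nt, 9, 9))
  re <- make_response(arr, sf_set, ori_set, rate = rate, pitch = 0.5)
  rlp <- lowpass_pool(re, spec)
  # constant input: unit-gain temporal and spatial kernels recover the input
  expect_equal(rlp[2, 2, nt, 5, 5], 2, tolerance = 5e-3)
  # hand-computed Gaussian channel weights on a 3-channel toy
  arr2 <- arr
  arr2[1, , , , ] <- 1; arr2[2, , , , ] <- 2; arr2[3, , , , ] <- 5
  re2 <- make_response(arr2, sf_set, ori_set, rate = rate, pitch = 0.5)
  rlp2 <- lowpass_pool(re2, spec)
  w_sf <- exp(-(log2(c(0.5, 1, 2) / 1))^2 / 2)           # sigma 1 octave
  w_or <- exp(-(c(-45, 0, 45))^2 / (2 * 11.5^2))         # sigma 11.5 deg
  W <- outer(w_sf, w_or)
  expect_equal(rlp2[2, 2, nt, 5, 5] / rlp[2, 2, nt, 5, 5] * 2,
               sum(W * c(1, 2, 5)) / sum(W), tolerance = 1e-3)
  # weights peak at zero distance and decay monotonically
  nb <- streakvision:::pool_neighbors(sf_set, ori_set, 2, 2,
                                      normalization_spec(pool_radius = 1))
  self <- which(nb$it == 2 & nb$jo == 2)
  expect_true(all(nb$w[self] >= nb$w))
})

test_that("delayed normalization is bounded, sign-preserving and transient-friendly", {
  sf_set <- 1; ori_set <- 0
  spec <- normalization_spec()
  # closed-form steady state: R_E = R_LP = 1
  arr <- array(1, c(1, 1, 1, 1, 1))
  re <- make_response(arr, sf_set, ori_set)
  rn <- delayed_normalize(re, arr, spec)
  expect_equal(as.vector(rn), 1 / (1 + 0.07^1.4), tolerance = 1e-9)
  expect_equal(as.vector(rn), 0.9758, tolerance = 1e-3)
  # zero energy stays zero; negative input rejected
  z <- make_response(array(0, c(1, 1, 1, 1, 1)), 1, 0)
  expect_equal(as.vector(delayed_normalize(z, array(0, dim(z)), spec)), 0)
  expect_error(delayed_normalize(make_response(array(-1, c(1, 1, 1, 1, 1)), 1, 0),
                                 array(1, c(1, 1, 1, 1, 1)), spec), "negative")
  expect_error(delayed_normalize(re, array(1, c(1, 1, 2, 1, 1)), spec), "shape")
  # step input: onset transient exceeds the sustained plateau
  nt <- 600
  step <- array(0, c(1, 1, nt, 1, 1)); step[, , 51:nt, , ] <- 1
  res <- make_response(step, sf_set, ori_set, rate = 480, pitch = 0.5)
  rlp <- lowpass_pool(res, spec)
  rn2 <- delayed_normalize(res, rlp, spec)
  trace <- rn2[1, 1, , 1, 1]
  expect_gt(max(trace), 1.5 * trace[nt])
  # doubling the semisaturation constant weakly decreases the output
  rn3 <- delayed_normalize(res, rlp, normalization_spec(sigma = 0.14))
  expect_true(all(rn3 <= rn2 + 1e-12))
  # normalization preserves the zero set
  expect_true(all((rn2 == 0) == (step == 0)))
})

test_that("the full model matches a straight-line reimplementation of all stages", {
  surf <- cached_surface()
  set.seed(11)
  pitch <- 3.36 / 51
  spec_b <- bank_spec(sf_set = c(2.52, 4.0), ori_set = c(0, 90))
  bank <- build_bank(spec_b, pitch)
  nspec <- normalization_spec(pool_radius = 1)
  ny <- 32; nx <- 32; nt <- 10; rate <- 480
  frames <- array(rnorm(ny * nx * nt, sd = 0.3), c(ny, nx, nt))
  mov <- tiny_movie(frames, pitch, rate)
  rn <- suppressWarnings(run_model(mov, bank, surf, nspec))
  expect_true(all(rn >= 0))
  # --- independent straight-line reimplementation ---
  kernels_t <- lapply(spec_b$sf_set, function(th)
    calibrated_kernel(surf, th, rate))
  pad_conv <- function(fr, k) {
    side <- nrow(k); half <- (side - 1) / 2
    out <- matrix(0 + 0i, ny, nx)
    kc <- k[side:1, side:1]
    for (y in seq_len(ny)) for (x in seq_len(nx)) {
      ys <- (y - half):(y + half); xs <- (x - half):(x + half)
      ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
      out[y, x] <- sum(kc[ok_y, ok_x] * fr[ys[ok_y], xs[ok_x]])
    }
    out
  }
  a <- exp(-1 / (rate * nspec$tau_n))
  sdpx <- nspec$gl_sd / pitch
  rbl <- ceiling(3 * sdpx)
  g1 <- exp(-(-rbl:rbl)^2 / (2 * sdpx^2)); g1 <- g1 / sum(g1)
  blur1 <- function(v) {   # 1-D truncated unit-sum conv, zero padded
    n <- length(v)
    vapply(seq_len(n), function(i) {
      idx <- (i - rbl):(i + rbl); ok <- idx >= 1 & idx <= n
      sum(v[idx[ok]] * g1[ok])
    }, numeric(1))
  }
  RE <- array(0, c(2, 2, nt, ny, nx))
  RL <- array(0, c(2, 2, nt, ny, nx))
  for (i in 1:2) for (j in 1:2) {
    k <- bank$kernels[[i]][[j]]
    rs <- array(0 + 0i, c(nt, ny, nx))
    for (t in seq_len(nt)) rs[t, , ] <- pad_conv(frames[, , t], k)
    h <- kernels_t[[i]]
    rst <- array(0 + 0i, c(nt, ny, nx))
    for (t in seq_len(nt)) for (q in seq_len(min(t, length(h))))
      rst[t, , ] <- rst[t, , ] + h[q] * rs[t - q + 1, , ] / rate
    RE[i, j, , , ] <- Re(rst)^2 + Im(rst)^2
    for (y in seq_len(ny)) for (x in seq_len(nx)) {
      v <- RE[i, j, , y, x]
      l <- numeric(nt); l[1] <- (1 - a) * v[1]
      for (t in 2:nt) l[t] <- a * l[t - 1] + (1 - a) * v[t]
      RL[i, j, , y, x] <- l
    }
    for (t in seq_len(nt)) {
      m <- RL[i, j, t, , ]
      m <- apply(m, 2, blur1)
      m <- t(apply(m, 1, blur1))
      RL[i, j, t, , ] <- m
    }
  }
  RN <- array(0, c(2, 2, nt, ny, nx))
  for (i in 1:2) for (j in 1:2) {
    num <- 0; den <- 0
    acc <- array(0, c(nt, ny, nx)); wsum <- 0
    for (i2 in 1:2) for (j2 in 1:2) {
      if (abs(i2 - i) > 1) next  # pool radius 1 in SF
      dth <- log2(spec_b$sf_set[i2] / spec_b$sf_set[i])
      dom <- abs((spec_b$ori_set[j2] - spec_b$ori_set[j] + 90) %% 180 - 90)
      w <- exp(-(dth^2 / 2 + dom^2 / (2 * 11.5^2)))
      acc <- acc + w * RL[i2, j2, , , ]
      wsum <- wsum + w
    }
    rlp <- acc / wsum
    RN[i, j, , , ] <- RE[i, j, , , ]^1.4 / (0.07^1.4 + rlp^1.4)
  }
  expect_equal(unclass(rn), RN, tolerance = 1e-8, ignore_attr = TRUE)
})
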