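test_that("sequential model occupancies satisfy the chain invariants", {
  set.seed(101)
  for (i in 1:25) {
    k1 <- 10^runif(1, -3, 0)
    k2 <- 10^runif(1, -3, 0)
    m <- photocycle_model(k1, k2)
    tt <- seq(0, 20 / min(k1, k2), length.out = 400)
    oc <- occupancies(m, tt)
    expect_equal(unname(oc[1, "M"]), 1)
    expect_equal(unname(oc[1, "O"]), 0)
    expect_true(all(oc[, "O"] >= -1e-12))
    total <- rowSums(oc)
    expect_true(all(diff(total) <= 1e-12))
    expect_true(all(total <= 1 + 1e-12))
  }
})

test_that("equal rates use the analytic limit c_O = k t exp(-k t)", {
  k <- 0.02
  m <- photocycle_model(k, k * (1 + 1e-12))
  tt <- c(1, 10, 50, 200)
  expect_equal(occupancies(m, tt)[, "O"], k * tt * exp(-k * tt),
               tolerance = 1e-8)
})

test_that("crossover time matches closed forms and a dense-grid scan", {
  # k1 = k2 = k: c_O = k t e^{-kt} crosses c_M at k t = 1
  k <- 1 / 50
  expect_equal(crossover_time(photocycle_model(k, k)), 50, tolerance = 1e-5)
  # k2 = 0: c_O = 1 - c_M, crossing at tau ln 2
  expect_equal(crossover_time(photocycle_model(1 / 100, 0)), 100 * log(2),
               tolerance = 1e-5)
  # the studied system: tau1 = 81, tau2 = 220 ms -> ~63 ms
  m <- photocycle_model(1 / 81, 1 / 220)
  tstar <- crossover_time(m)
  expect_equal(tstar, 63, tolerance = 0.02)
  # brute-force dense scan oracle (1e-3 ms step)
  tt <- seq(1e-3, 500, by = 1e-3)
  oc <- occupancies(m, tt)
  scan <- tt[which(diff(sign(oc[, "M"] - oc[, "O"])) != 0)[1]]
  expect_lt(abs(tstar - scan), 1e-3 + 1e-6)
})

test_that("half-decay time matches closed forms and a dense-grid scan", {
  # conserved total when O never decays
  expect_true(is.na(half_decay_time(photocycle_model(1 / 50, 0))))
  # fast-M limit: total ~ exp(-k2 t)
  expect_equal(half_decay_time(photocycle_model(1000, 1 / 100)),
               100 * log(2), tolerance = 1e-4)
  m <- photocycle_model(1 / 81, 1 / 220)
  Th <- half_decay_time(m)
  expect_equal(Th, 240.76, tolerance = 1e-3)
  tt <- seq(1e-3, 1000, by = 1e-3)
  scan <- tt[which(rowSums(occupancies(m, tt)) < 0.5)[1]]
  expect_lt(abs(Th - scan), 1e-3 + 1e-6)
})

test_that("rate solver inverts the crossover/half-decay observables", {
  m <- solve_rates_from_times(63, 240)
  expect_equal(crossover_time(m), 63, tolerance = 1e-5)
  expect_equal(half_decay_time(m), 240, tolerance = 1e-5)
  # the solved lifetimes for the printed timing pair
  expect_equal(1 / m$k1, 81, tolerance = 0.01)
  expect_equal(1 / m$k2, 220, tolerance = 0.01)
})

test_that("repeat averaging rejects gross outliers and keeps clean repeats", {
  wl <- seq(350, 650, by = 5); dl <- seq(0, 100, by = 10)
  clean <- outer(sin(wl / 40), exp(-dl / 60)) * 0.05
  # identity case: identical repeats, all retained
  stack <- array(rep(clean, 10), dim = c(length(wl), length(dl), 10))
  av <- average_repeats(stack, 3, wavelengths = wl, delays = dl)
  expect_equal(av$D, clean, ignore_attr = TRUE)
  expect_equal(attr(av, "n_retained"), 10)
  # 9 clean + 1 offset by 10x the noise level
  set.seed(7)
  noise_sd <- 0.002
  stack <- array(clean, dim = c(length(wl), length(dl), 10)) +
    array(rnorm(length(clean) * 10, sd = noise_sd),
          dim = c(length(wl), length(dl), 10))
  stack[, , 10] <- stack[, , 10] + 10 * noise_sd
  # oracle: direct computation of RMS deviations from the median matrix
  med <- apply(stack, c(1, 2), median)
  rms <- vapply(1:10, function(i) sqrt(mean((stack[, , i] - med)^2)),
                numeric(1))
  expect_identical(which(rms > 3 * median(rms)), 10L)
  av <- average_repeats(stack, 3, wavelengths = wl, delays = dl)
  expect_equal(attr(av, "n_retained"), 9)
  expect_false(attr(av, "retained")[10])
})

test_that("45-repeat averaging recovers the truth to the noise floor", {
  g <- make_spectral_series(n_repeats = 45, noise_sd = 0.003, seed = 21)
  truth <- cbind(g$truth$S_M, g$truth$S_O) %*% t(g$truth$traces)
  av <- average_repeats(g$series, 3)
  n <- attr(av, "n_retained")
  expect_gte(n, 40)
  expect_lt(sqrt(mean((av$D - truth)^2)), 3 * 0.003 / sqrt(45))
})

test_that("all-repeats-rejected is an error naming the threshold", {
  stack <- array(rnorm(2 * 4 * 2), dim = c(2, 4, 2))
  expect_error(average_repeats(stack, 1e-12, wavelengths = c(1, 2),
                               delays = 1:4),
               "rejected at threshold")
})

test_that("truncated SVD is the Eckart-Young optimal low-rank approximation", {
  # rank-1 outer product reconstructs exactly
  u <- sin(1:30 / 5); v <- exp(-(1:8) / 3)
  M <- outer(u, v)
  s <- svd_truncate(M, 1)
  expect_equal(s$u %*% diag(s$d[1], 1) %*% t(s$v), M, tolerance = 1e-12)
  expect_lt(s$d[2] / s$d[1], 1e-12)
  # noise-free two-state series is rank 2
  g <- make_spectral_series(noise_sd = 0)
  s <- svd_truncate(g$series, 2)
  expect_lt(s$d[3] / s$d[2], 1e-10)
  # random matrix: rank-2 squared error equals sum of trailing singular values
  set.seed(5)
  M <- matrix(rnorm(40 * 9), 40, 9)
  s <- svd_truncate(M, 2)
  rec <- s$u %*% diag(s$d[1:2]) %*% t(s$v)
  expect_equal(sum((M - rec)^2), sum(svd(M)$d[-(1:2)]^2), tolerance = 1e-10)
  expect_error(svd_truncate(matrix(c(1, NA, 1, 1), 2)), "non-finite")
})

test_that("noise-free decomposition recovers rates, traces and spectra exactly", {
  g <- make_spectral_series(noise_sd = 0, k1 = 1 / 81, k2 = 1 / 220)
  f <- fit_photocycle(g$series)
  expect_lt(f$residual_rms, 1e-10)
  expect_equal(f$model$k1, 1 / 81, tolerance = 1e-3)
  expect_equal(f$model$k2, 1 / 220, tolerance = 1e-3)
  expect_equal(unname(f$traces), unname(g$truth$traces), tolerance = 1e-6)
  expect_equal(max(abs(f$basis[, "M"] - g$truth$S_M)), 0, tolerance = 1e-8)
  expect_equal(max(abs(f$basis[, "O"] - g$truth$S_O)), 0, tolerance = 1e-8)
})

test_that("decomposition recovers rates within 5 percent at SNR 20 (Monte Carlo)", {
  errs <- t(vapply(1:50, function(s) {
    g <- make_spectral_series(snr = 20, seed = 1000 + s)
    f <- fit_photocycle(g$series)
    abs(coef(f) / c(1 / 81, 1 / 220) - 1)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.05)
})

test_that("fit refuses non-identifiable (rank-deficient) series", {
  wl <- seq(350, 650, by = 10); dl <- seq(0, 100, by = 10)
  rank1 <- outer(sin(wl / 40), exp(-dl / 60))
  s <- spectral_series(wl, dl, rank1)
  expect_error(fit_photocycle(s), "not identifiable")
})

test_that("fitted object methods are consistent with the stored fit", {
  g <- make_spectral_series(snr = 30, seed = 3)
  f <- fit_photocycle(g$series)
  expect_s3_class(f, "photocycle_fit")
  expect_named(coef(f), c("k1", "k2"))
  expect_equal(predict(f), f$fitted)
  expect_equal(residuals(f), g$series$D - f$fitted)
  oc <- predict(f, delays = c(0, 63), type = "occupancy")
  expect_equal(unname(oc[1, "M"]), 1)
  expect_output(print(f), "crossover")
  expect_output(print(summary(f)), "tau1")
  sims <- simulate(f, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "spectral_series")
})

test_that("photostationary spectra decompose onto the basis by least squares", {
  g <- make_spectral_series(noise_sd = 0)
  B <- cbind(g$truth$S_M, g$truth$S_O)
  # pure scaled M
  d <- photostationary_decompose(0.4 * g$truth$S_M, B)
  expect_equal(d$occ_M, 0.4, tolerance = 1e-10)
  expect_equal(d$occ_O, 0, tolerance = 1e-10)
  # noisy mixture recovered within 3 standard errors (lm oracle)
  set.seed(13)
  spec <- 0.25 * B[, 1] + 0.35 * B[, 2] + rnorm(nrow(B), sd = 1e-3)
  d <- photostationary_decompose(spec, B)
  se <- summary(lm(spec ~ B - 1))$coefficients[, "Std. Error"]
  expect_lt(abs(d$occ_M - 0.25), 3 * se[1])
  expect_lt(abs(d$occ_O - 0.35), 3 * se[2])
  # orthogonal spectrum: zero coefficients, residual rms equals spectrum rms
  Q <- qr.Q(qr(cbind(B, rnorm(nrow(B)))))
  orth <- Q[, 3]
  d <- photostationary_decompose(orth, B)
  expect_equal(d$occ_M, 0, tolerance = 1e-10)
  expect_equal(d$occ_O, 0, tolerance = 1e-10)
  expect_equal(d$residual_rms, sqrt(mean(orth^2)), tolerance = 1e-10)
  # collinear basis refused
  expect_error(photostationary_decompose(B[, 1], cbind(B[, 1], B[, 1] * 2)),
               "collinear")
})

test_that("beam-overlap correction follows the linear geometric model", {
  expect_equal(occupancy_beam_correction(0, 760, 91.2, 5), 1)
  expect_equal(occupancy_beam_correction(1000, 760, 91.2, 5), 0)
  # hand evaluation: (96.2 - 45.6) / 96.2
  expect_equal(occupancy_beam_correction(60, 760, 91.2, 5),
               (91.2 + 5 - 760 * 0.06) / (91.2 + 5), tolerance = 1e-12)
  expect_equal(occupancy_beam_correction(60, 760, 91.2, 5), 0.526,
               tolerance = 1e-3)
})

test_that("frame binning pools 10 ms frames into 30 ms windows", {
  tms <- seq(0, 230, by = 10)       # 24 frames of 10 ms
  vals <- seq_along(tms)
  b <- bin_frames(tms, vals, 30)
  expect_equal(nrow(b), 8)
  expect_true(all(b$n == 3))
  expect_equal(b$bin_start_ms, seq(0, 210, by = 30))
  # single frame
  b1 <- bin_frames(5, 2.5, 30)
  expect_equal(b1$n, 1L)
  expect_equal(b1$mean, 2.5)
  # constant values
  bc <- bin_frames(tms, rep(7, 24), 30)
  expect_true(all(bc$mean == 7))
  expect_error(bin_frames(-5, 1, 30), "outside")
})
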