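test_that("bandpass filter kills DC and passes the 10 Hz band per the analytic response", {
  fs <- 1000
  cfg <- detector_config()
  dc <- rep(1, 5000)
  y <- bandpass_filter(dc, fs, cfg)
  expect_lt(max(abs(y[1000:4000])), 1e-6)

  # analytic |H(f)|^2 of the order-3 Butterworth bandpass applied twice
  # (forward-backward), from direct evaluation of the transfer function
  butter_mag <- function(f) {
    bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
    w <- 2 * pi * f / fs
    H <- sum(bf$b * exp(-1i * w * (seq_along(bf$b) - 1))) /
      sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
    Mod(H)^2
  }
  t <- seq(0, 10, by = 1 / fs)
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_filter(x10, fs, cfg)
  core <- 3000:7000
  amp10 <- (max(y10[core]) - min(y10[core])) / 2
  expect_equal(amp10, butter_mag(10), tolerance = 0.01)

  # 0.5 Hz drift attenuated >= 20 dB relative to 10 Hz content
  x05 <- sin(2 * pi * 0.5 * t)
  y05 <- bandpass_filter(x05, fs, cfg)
  amp05 <- (max(y05[core]) - min(y05[core])) / 2
  expect_gt(20 * log10(amp10 / amp05), 20)
  expect_gt(20 * log10(butter_mag(10) / butter_mag(0.5)), 20)
})

test_that("band edges at or above Nyquist are rejected", {
  expect_error(bandpass_filter(rnorm(100), 25,
                               detector_config(band_high = 15)), "Nyquist")
})

test_that("energy envelope is zero for silence, unimodal for one pulse, and scales quadratically", {
  fs <- 1000
  cfg <- detector_config()
  expect_true(all(pan_tompkins_stages(rep(0, 2000), fs, cfg) == 0))

  tpl <- hrvogtt:::ricker_template(0.02, fs)
  x <- c(rep(0, 1000), tpl, rep(0, 1000))
  env <- pan_tompkins_stages(x, fs, cfg)
  expect_true(all(env >= 0))
  expect_equal(length(env), length(x))
  win <- round(0.150 * fs)
  dominant <- hrvogtt:::local_maxima(env, min_halfwidth = win %/% 2L)
  big <- dominant[env[dominant] > max(env) / 2]
  expect_equal(length(big), 1L)

  env3 <- pan_tompkins_stages(3 * x, fs, cfg)
  expect_equal(env3, 9 * env, tolerance = 1e-12)
})

test_that("single-lead detection finds clean beats within 10 ms and respects the refractory period", {
  rr <- generate_rr_series(quiet_profile(1000), 0, 60, 1)
  ecg <- render_multilead_ecg(rr$beat_times, ecg_render_spec(noise_sd = 0),
                              seed = 1)
  cand <- detect_rpeaks_single_lead(ecg$signal[, 1], ecg$fs)
  expect_equal(length(cand), length(ecg$true_r_indices))
  expect_true(all(abs(cand - ecg$true_r_indices) <= 10))
  expect_true(all(diff(cand) >= 0.2 * ecg$fs))

  expect_identical(detect_rpeaks_single_lead(rep(0, 5000), 1000), integer(0))
})

test_that("two pulses 150 ms apart yield one detection (refractory suppression)", {
  fs <- 1000
  tpl <- hrvogtt:::ricker_template(0.02, fs)
  x <- rep(0, 4000)
  # a few warm-up beats so the adaptive threshold settles, then the pair
  put <- function(x, at) {
    h <- (length(tpl) - 1) / 2
    x[(at - h):(at + h)] <- x[(at - h):(at + h)] + tpl
    x
  }
  for (at in c(500, 1500, 2500)) x <- put(x, at)
  x <- put(x, 3300); x <- put(x, 3450)
  cand <- detect_rpeaks_single_lead(x, fs)
  expect_equal(sum(cand > 3200), 1L)
})

test_that("fusion takes the median of clustered times and honours lead support", {
  fs <- 1000
  cfg <- detector_config(min_lead_support = 3)
  # identical candidates in 12 leads
  same <- replicate(12, c(1000L, 2000L, 3000L), simplify = FALSE)
  fp <- fuse_rpeaks(same, fs, cfg)
  expect_equal(fp$fused_indices, c(1000L, 2000L, 3000L))
  expect_equal(fp$support_counts, c(12L, 12L, 12L))

  # median of three
  three <- list(c(1000L), c(1010L), c(1020L))
  fp3 <- fuse_rpeaks(three, fs, detector_config(min_lead_support = 1))
  expect_equal(fp3$fused_indices, 1010L)

  # spike in one lead only is dropped under min support 3
  leads <- replicate(12, c(1000L, 2000L), simplify = FALSE)
  leads[[4]] <- c(1000L, 1500L, 2000L)
  fps <- fuse_rpeaks(leads, fs, cfg)
  expect_false(any(fps$fused_indices == 1500L))
})

test_that("fusion is invariant to lead order and keeps fused gaps above the refractory period", {
  set.seed(42)
  base <- sort(sample(seq(500L, 59000L, by = 800L)))
  leads <- lapply(1:8, function(i) base + sample(-20:20, length(base), TRUE))
  cfg <- detector_config(min_lead_support = 2)
  a <- fuse_rpeaks(leads, 1000, cfg)
  b <- fuse_rpeaks(rev(leads), 1000, cfg)
  expect_equal(a$fused_indices, b$fused_indices)
  expect_true(all(diff(a$fused_indices) >= 200))
})

test_that("empty and flat leads produce empty candidate sets, and all-empty fusion is empty", {
  cfg <- detector_config()
  fp <- fuse_rpeaks(replicate(12, integer(0), simplify = FALSE), 1000, cfg)
  expect_length(fp$fused_indices, 0)
})
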