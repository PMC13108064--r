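test_that("time-domain statistics match hand-evaluated values", {
  v <- c(800, 810, 790, 805, 795)
  td <- time_domain(v)
  expect_equal(td$mean_rr, 800)
  expect_equal(td$pnn50, 0)
  expect_equal(td$rmssd, sqrt((10^2 + 20^2 + 15^2 + 10^2) / 4),
               tolerance = 1e-12)

  const <- time_domain(rep(700, 10))
  expect_equal(const$sdnn, 0)
  expect_equal(const$rmssd, 0)
  expect_equal(const$sdsd, 0)
  expect_equal(const$pnn50, 0)

  expect_error(time_domain(c(800, 810)), "at least 3")
})

test_that("Welch band powers localize single-tone RR modulation", {
  t <- seq(0, 300, by = 0.25)  # ~4 Hz virtual beats
  mk <- function(f) 900 + 40 * sin(2 * pi * f * t)
  hf <- spectral_features(mk(0.25), t)
  expect_gte(hf$hf / (hf$lf + hf$hf), 0.9)
  lf <- spectral_features(mk(0.10), t)
  expect_gte(lf$lf / (lf$lf + lf$hf), 0.9)
  expect_lt(abs(hf$hf_peak - 0.25), 0.02)
  expect_lt(abs(lf$lf_peak - 0.10), 0.02)

  # constant series: negligible power everywhere, LF/HF reported missing
  cst <- spectral_features(rep(900, length(t)), t)
  expect_lt(cst$total_power, 1e-10 * hf$total_power)
  expect_true(is.na(cst$lf_hf))
})

test_that("band powers are additive within total power", {
  for (s in 1:5) {
    rr <- generate_rr_series(default_group_profiles()$C, 0, 300, s)
    fd <- spectral_features(rr$rr, rr$beat_times)
    expect_lte(fd$vlf + fd$lf + fd$hf, fd$total_power * (1 + 1e-6))
  }
})

test_that("Poincare indices satisfy the SD1-SDSD identity and hand values", {
  set.seed(1)
  for (i in 1:20) {
    v <- 800 + rnorm(100, 0, 30)
    pc <- poincare_features(v)
    td <- time_domain(v)
    expect_equal(pc$sd1, td$sdsd / sqrt(2), tolerance = 1e-9)
    expect_equal(pc$poincare_area_s, pi * pc$sd1 * pc$sd2, tolerance = 1e-12)
  }
  alt <- rep(c(800, 900), 50)
  expect_equal(poincare_features(alt)$sd1, 100 / sqrt(2), tolerance = 1e-3)
  cst <- poincare_features(rep(800, 50))
  expect_equal(cst$sd1, 0)
  expect_equal(cst$sd2, 0)
  expect_equal(cst$poincare_area_s, 0)
})

test_that("sample and approximate entropy equal the brute-force counting oracle", {
  expect_equal(sample_entropy(rep(5, 30)), 0)
  expect_equal(approximate_entropy(rep(5, 30)), 0)

  x <- rep(c(1, 2), 5)
  expect_equal(as.numeric(sample_entropy(x)), sampen_oracle(x))

  set.seed(7)
  for (i in 1:50) {
    n <- sample(20:80, 1)
    x <- round(rnorm(n), 2)
    expect_equal(as.numeric(sample_entropy(x)), sampen_oracle(x),
                 tolerance = 1e-12)
    expect_equal(approximate_entropy(x), apen_oracle(x), tolerance = 1e-12)
  }
})

test_that("entropy orders noise above regular rhythms", {
  set.seed(2)
  wins_s <- 0; wins_a <- 0
  for (i in 1:20) {
    noise <- rnorm(300)
    sine <- sin(2 * pi * (1:300) / 25) * sd(noise) / sqrt(0.5)
    if (as.numeric(sample_entropy(noise)) >
        as.numeric(sample_entropy(sine))) wins_s <- wins_s + 1
    if (approximate_entropy(noise) > approximate_entropy(sine))
      wins_a <- wins_a + 1
  }
  expect_gte(wins_s, 18)
  expect_gte(wins_a, 18)
})

test_that("DFA recovers the theoretical exponents of white and Brownian noise", {
  set.seed(4)
  a1_white <- a1_brown <- numeric(20)
  for (i in 1:20) {
    w <- rnorm(1000)
    a1_white[i] <- dfa(w)$dfa_alpha1
    a1_brown[i] <- dfa(cumsum(rnorm(1000)))$dfa_alpha1
  }
  expect_lt(abs(mean(a1_white) - 0.5), 0.1)
  expect_lt(abs(mean(a1_brown) - 1.5), 0.1)
})

test_that("DFA recovers alpha for synthesized 1/f^beta noise and is scale invariant", {
  set.seed(5)
  for (beta in c(0, 1, 2)) {
    target <- (beta + 1) / 2
    vals <- vapply(1:20, function(i)
      dfa(hrvogtt:::fractal_noise(1000, beta))$dfa_alpha1, numeric(1))
    expect_lt(abs(mean(vals) - target), 0.1,
              label = sprintf("alpha for beta=%g", beta))
  }
  x <- rnorm(600)
  expect_equal(dfa(x)$dfa_alpha1, dfa(7.3 * x)$dfa_alpha1, tolerance = 1e-9)
  expect_true(is.na(dfa(rnorm(100))$dfa_alpha2))
})

test_that("assembled feature vector has the canonical 32 entries and is deterministic", {
  rr <- generate_rr_series(default_group_profiles()$MetS, 0, 400, 6)
  seg <- condition_rr(rr)
  fv1 <- hrv_features(seg)
  fv2 <- hrv_features(seg)
  expect_length(fv1, 32L)
  expect_identical(names(fv1), hrv_feature_names())
  expect_identical(fv1, fv2)
  expect_true(all(is.finite(fv1)))
})

test_that("feature extraction is invariant to a constant beat-time offset", {
  rr <- generate_rr_series(default_group_profiles()$C, 0, 400, 8)
  seg <- condition_rr(rr)
  seg2 <- seg
  seg2$beat_times <- seg$beat_times + 1000
  expect_equal(hrv_features(seg), hrv_features(seg2), tolerance = 1e-9)
})

test_that("z-score scaler learns from training rows only", {
  tr <- matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  st <- fit_scaler(tr)
  expect_equal(unname(st$center), c(2, 3))
  z <- apply_scaler(st, tr)
  expect_equal(unname(z), matrix(c(-1, 1, -1, 1), 2, 2), tolerance = 1e-12)

  big <- matrix(rnorm(200), 20, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
  st2 <- fit_scaler(big)
  ztr <- apply_scaler(st2, big)
  expect_true(all(abs(colMeans(ztr)) < 1e-9))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_true(all(abs(apply(ztr, 2, pop_sd) - 1) < 1e-9))

  far <- matrix(1e6, 1, 10, dimnames = list(NULL, paste0("f", 1:10)))
  expect_true(all(is.finite(apply_scaler(st2, far))))

  const <- cbind(big, k = rep(5, 20))
  expect_warning(st3 <- fit_scaler(const), "zero-variance")
  expect_identical(st3$dropped, "k")
  expect_equal(ncol(apply_scaler(st3, const)), 10L)
})
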