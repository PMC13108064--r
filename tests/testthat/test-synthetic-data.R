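test_that("degenerate constant generator yields exact metronome beats", {
  rr <- generate_rr_series(quiet_profile(1000), stage = 0, duration = 10,
                           seed = 1)
  expect_equal(rr$rr, rep(1000, length(rr$rr)))
  expect_equal(rr$beat_times, seq_along(rr$rr) * 1.0)
})

test_that("generated series recover the profile mean RR and SDNN", {
  profs <- default_group_profiles()
  for (g in names(profs)) {
    stats <- vapply(1:20, function(s) {
      r <- generate_rr_series(profs[[g]], 0, 300, seed = s)
      c(mean(r$rr), sd(r$rr))
    }, numeric(2))
    expect_lt(abs(mean(stats[1, ]) / profs[[g]]$mean_rr - 1), 0.02,
              label = paste("mean RR recovery", g))
    expect_lt(abs(mean(stats[2, ]) / profs[[g]]$sdnn_target - 1), 0.15,
              label = paste("SDNN recovery", g))
  }
})

test_that("variability ordering between marathoner and MetS profiles holds", {
  profs <- default_group_profiles()
  wins <- vapply(1:20, function(s) {
    sd(generate_rr_series(profs$M, 0, 300, s)$rr) >
      sd(generate_rr_series(profs$MetS, 0, 300, s)$rr)
  }, logical(1))
  expect_true(all(wins))
})

test_that("default profiles are ordered MetS < C < M in mean RR", {
  profs <- default_group_profiles()
  expect_lt(profs$MetS$mean_rr, profs$C$mean_rr)
  expect_lt(profs$C$mean_rr, profs$M$mean_rr)
})

test_that("generator is deterministic and seed-sensitive", {
  p <- default_group_profiles()$C
  a <- generate_rr_series(p, 30, 120, seed = 5)
  b <- generate_rr_series(p, 30, 120, seed = 5)
  c <- generate_rr_series(p, 30, 120, seed = 6)
  expect_identical(a$rr, b$rr)
  expect_false(identical(a$rr, c$rr))
})

test_that("profile validation rejects bad parameters", {
  expect_error(group_profile("C", -100, 50, 10, 10), "mean_rr")
  expect_error(group_profile("C", 900, 50, 10, 10, lf_freq = 0.3,
                             hf_freq = 0.2), "frequencies")
  expect_error(generate_rr_series(quiet_profile(), duration = -5),
               "duration")
})

test_that("hf-only modulation concentrates Welch power in the HF band", {
  p <- group_profile("C", 1000, sdnn_target = 0, lf_amplitude = 0,
                     hf_amplitude = 30)
  p$sdnn_target <- 30 / sqrt(2)  # oscillation supplies all the variance
  rr <- generate_rr_series(p, 0, 300, seed = 3)
  fd <- spectral_features(rr$rr, rr$beat_times)
  expect_gte(fd$hf / (fd$lf + fd$hf), 0.90)
})

test_that("rendered ECG places the template apex on the annotated sample", {
  ecg <- render_multilead_ecg(1.0, ecg_render_spec(noise_sd = 0), seed = 1)
  for (j in seq_len(ncol(ecg$signal)))
    expect_equal(which.max(abs(ecg$signal[, j])), 1001L)
  expect_identical(ecg$true_r_indices, 1001L)
})

test_that("artifacts are rendered but never annotated as beats", {
  art <- data.frame(lead = 4, time_s = 7.2, amplitude = 2.0)
  p <- quiet_profile(1000)
  rr <- generate_rr_series(p, 0, 20, 1)
  ecg <- render_multilead_ecg(rr$beat_times,
                              ecg_render_spec(noise_sd = 0,
                                              artifact_spec = art), seed = 1)
  expect_false(any(abs(ecg$true_r_indices - 7201L) < 100))
  # the spike is present in lead 4 only
  base <- render_multilead_ecg(rr$beat_times,
                               ecg_render_spec(noise_sd = 0), seed = 1)
  dif <- abs(ecg$signal - base$signal)
  expect_gt(max(dif[, 4]), 1)
  expect_equal(max(dif[, -4]), 0)
})

test_that("rendering is bit-identical for identical spec and seed", {
  rr <- generate_rr_series(default_group_profiles()$M, 0, 30, 2)
  a <- render_multilead_ecg(rr$beat_times, ecg_render_spec(), seed = 9)
  b <- render_multilead_ecg(rr$beat_times, ecg_render_spec(), seed = 9)
  expect_identical(a$signal, b$signal)
})

test_that("cohort has the right size, balance and determinism", {
  spec <- synthetic_cohort_spec(seed = 4, duration_s = 60,
                                profiles = lapply(default_group_profiles(),
                                                  function(p) p))
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh$manifest), 200L)
  expect_equal(length(unique(coh$manifest$subject_id)), 40L)
  expect_true(all(table(coh$manifest$subject_id) == 5L))
  expect_equal(as.numeric(table(coh$manifest$group)[c("MetS", "C", "M")]),
               c(75, 50, 75))

  tiny <- synthetic_cohort_spec(n_per_group = c(MetS = 1, C = 1, M = 1),
                                stages = 0, seed = 4, duration_s = 60)
  expect_equal(nrow(generate_cohort(tiny)$manifest), 3L)

  a <- generate_cohort(tiny); b <- generate_cohort(tiny)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$records[[1]]$rr_series$rr, b$records[[1]]$rr_series$rr)
})

test_that("cohort round-trips through CSV export", {
  tiny <- synthetic_cohort_spec(n_per_group = c(MetS = 1, C = 1, M = 1),
                                stages = c(0, 30), seed = 8, duration_s = 60)
  coh <- generate_cohort(tiny)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 6L)
  back <- read_rr_csv(file.path(dir, man$file[1]))
  expect_equal(back$rr, coh$records[[1]]$rr_series$rr)
})
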