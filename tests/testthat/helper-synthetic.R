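# Shared fixtures built in code.

quiet_profile <- function(mean_rr = 1000) {
  group_profile("C", mean_rr = mean_rr, sdnn_target = 0,
                lf_amplitude = 0, hf_amplitude = 0)
}

# small rendered ECG used by several detector tests (cached per session)
small_ecg <- local({
  cache <- NULL
  function(duration = 60, seed = 7, noise_sd = 0.02, artifact_spec = NULL,
           n_leads = 12L) {
    key <- paste(duration, seed, noise_sd, n_leads,
                 is.null(artifact_spec))
    if (!is.null(cache) && identical(cache$key, key)) return(cache$ecg)
    p <- default_group_profiles()$C
    rr <- generate_rr_series(p, 0, duration, seed)
    ecg <- render_multilead_ecg(
      rr$beat_times,
      ecg_render_spec(noise_sd = noise_sd, artifact_spec = artifact_spec,
                      n_leads = n_leads),
      seed = seed + 1)
    cache <<- list(key = key, ecg = ecg)
    ecg
  }
})

# brute-force O(n^2) sample entropy oracle (explicit loops, independent of
# the package implementation)
sampen_oracle <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * sqrt(mean((x - mean(x))^2))
  count_matches <- function(mm) {
    cnt <- 0L
    for (i in 1:(n - m)) {
      for (j in 1:(n - m)) {
        if (i == j) next
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) cnt <- cnt + 1L
      }
    }
    cnt
  }
  B <- count_matches(m)
  A <- count_matches(m + 1L)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

apen_oracle <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * sqrt(mean((x - mean(x))^2))
  phi <- function(mm) {
    nt <- n - mm + 1L
    total <- 0
    for (i in 1:nt) {
      cnt <- 0L
      for (j in 1:nt) {
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) cnt <- cnt + 1L
      }
      total <- total + log(cnt / nt)
    }
    total / nt
  }
  phi(m) - phi(m + 1L)
}

# brute-force pairwise-concordance AUC oracle
auc_oracle <- function(labels01, scores) {
  pos <- scores[labels01 == 1]; neg <- scores[labels01 == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
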