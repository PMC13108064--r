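# RR-interval generator: two sinusoidal modulators (LF, HF) on top of a mean
# level plus spectrally shaped (1/f^beta) noise whose exponent is mapped to
# the target DFA alpha-1 via beta = 2*alpha - 1.

#' Spectrally synthesized 1/f^beta noise
#'
#' Generates standardized correlated noise by assigning random phases to a
#' half-spectrum with amplitude f^(-beta/2) and inverse-transforming.
#' `beta = 0` gives white noise, `beta = 2` Brownian-like noise.
#'
#' @param n length of the series.
#' @param beta spectral exponent (>= 0).
#' @return numeric vector of length `n`, mean 0, SD 1.
#' @keywords internal
fractal_noise <- function(n, beta) {
  if (n < 2) return(rep(0, n))
  nfft <- 2^ceiling(log2(max(n, 4)))
  half <- nfft / 2
  amp <- seq_len(half)^(-beta / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- c(0 + 0i, spec[seq_len(half - 1)], complex(modulus = amp[half]),
            Conj(rev(spec[seq_len(half - 1)])))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  s <- stats::sd(x)
  if (s == 0) rep(0, n) else (x - mean(x)) / s
}

#' Generate a synthetic RR-interval series with ground-truth beat times
#'
#' RR at beat time t is `mean_rr * stage_adj + lf_amplitude * sin(2*pi*
#' lf_freq*t) + hf_amplitude * sin(2*pi*hf_freq*t + phi) + noise`, where the
#' noise term is 1/f^beta-shaped so that its scaling exponent approximates
#' the profile's `fractal_exponent`, and its SD is set so the total series
#' SD approximates the profile's `sdnn_target`. Beat times are the
#' cumulative sum of the RR intervals. Deterministic for a fixed seed.
#'
#' @param profile a [group_profile()].
#' @param stage OGTT stage in minutes (selects the profile's stage
#'   modulation).
#' @param duration recording duration in seconds (>= 60).
#' @param seed integer seed controlling all randomness of this call.
#' @return an object of class `RRSeries` with fields `beat_times` (s),
#'   `rr` (ms), `artifact_mask`, `corrected`, and metadata fields.
#' @export
generate_rr_series <- function(profile, stage = 0, duration = 300, seed = 1L) {
  if (!inherits(profile, "GroupProfile")) stop("profile must be a GroupProfile")
  if (duration <= 0) stop("duration must be positive")
  set.seed(as.integer(seed))
  mod <- stage_mod(profile, stage)
  mu <- profile$mean_rr * mod$mean_rr
  lf_a <- profile$lf_amplitude * mod$amplitude
  hf_a <- profile$hf_amplitude * mod$amplitude
  # residual noise SD so that total variance tracks sdnn_target
  target_sd <- profile$sdnn_target * mod$amplitude
  osc_var <- lf_a^2 / 2 + hf_a^2 / 2
  noise_sd <- sqrt(max(target_sd^2 - osc_var, 0))
  phi <- stats::runif(1, 0, 2 * pi)
  beta <- 2 * profile$fractal_exponent - 1
  n_exp <- max(2L, round(duration * 1000 / mu))
  n_max <- ceiling(duration * 1000 / (mu * 0.5)) + 16L
  noise <- rep(0, n_max)
  if (noise_sd > 0) {
    raw <- fractal_noise(n_max, beta)
    # standardize over the expected beat count so the realized mean and SD
    # track the profile targets (long-memory noise subsegments drift)
    mu_n <- mean(raw[seq_len(n_exp)])
    sd_n <- stats::sd(raw[seq_len(n_exp)])
    if (sd_n > 0) noise <- noise_sd * (raw - mu_n) / sd_n
  }

  rr <- numeric(n_max)
  bt <- numeric(n_max)
  t <- 0
  i <- 0L
  while (t < duration && i < n_max) {
    i <- i + 1L
    val <- mu + lf_a * sin(2 * pi * profile$lf_freq * t) +
      hf_a * sin(2 * pi * profile$hf_freq * t + phi) + noise[i]
    val <- max(val, 300)  # physiological floor
    t <- t + val / 1000
    rr[i] <- val
    bt[i] <- t
  }
  keep <- seq_len(i)
  bt <- bt[keep]
  rr <- rr[keep]
  inside <- bt <= duration + 1e-9
  bt <- bt[inside]
  rr <- rr[inside]
  new_rr_series(beat_times = bt, rr = rr,
                group_label = profile$group_label, stage = stage)
}

new_rr_series <- function(beat_times, rr,
                          artifact_mask = rep(FALSE, length(rr)),
                          corrected = rep(FALSE, length(rr)),
                          group_label = NA_character_, stage = NA_real_,
                          subject_id = NA_character_) {
  stopifnot(length(rr) == length(artifact_mask),
            length(rr) == length(corrected))
  structure(list(beat_times = beat_times, rr = rr,
                 artifact_mask = artifact_mask, corrected = corrected,
                 group_label = group_label, stage = stage,
                 subject_id = subject_id),
            class = "RRSeries")
}

#' @export
print.RRSeries <- function(x, ...) {
  cat(sprintf("RRSeries: %d intervals, mean RR %.1f ms, %d flagged, %d corrected\n",
              length(x$rr), mean(x$rr), sum(x$artifact_mask), sum(x$corrected)))
  invisible(x)
}
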