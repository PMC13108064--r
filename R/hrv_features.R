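# Multidomain HRV descriptors for a five-minute RR segment: time domain,
# Welch spectral band powers, and nonlinear indices (Poincare, sample and
# approximate entropy, detrended fluctuation analysis), assembled into the
# canonical 32-descriptor feature vector.
#
# SD-type statistics use the population (1/n) convention throughout.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Canonical names of the 32 HRV descriptors, in order
#'
#' The roster comprises the named time-domain (mean RR, SDNN, RMSSD, SDSD,
#' pNN50), spectral (VLF, LF, HF, LF/HF) and nonlinear (SD1, SD2, SampEn,
#' ApEn, DFA alpha-1/alpha-2) descriptors, completed to 32 with their
#' standard companions: pNN20, mean heart rate, median RR, RR coefficient
#' of variation, SDNN index, total power, normalized and relative band
#' powers, per-band peak frequencies, the SD1/SD2 ratio, the Poincare
#' ellipse area S, and the entropies at a second tolerance (r = 0.15 SD).
#'
#' @return character vector of length 32.
#' @export
hrv_feature_names <- function() {
  c("mean_rr", "sdnn", "rmssd", "sdsd", "pnn50", "pnn20", "mean_hr",
    "median_rr", "cv_rr", "sdnn_index",
    "vlf", "lf", "hf", "total_power", "lf_hf", "lf_nu", "hf_nu",
    "lf_rel", "hf_rel", "vlf_peak", "lf_peak", "hf_peak",
    "sd1", "sd2", "sd1_sd2", "poincare_area_s",
    "sampen", "apen", "sampen_r15", "apen_r15",
    "dfa_alpha1", "dfa_alpha2")
}

#' Time-domain HRV statistics
#'
#' @param rr RR intervals in ms (>= 3 values).
#' @return named list: `mean_rr`, `sdnn`, `rmssd`, `sdsd`, `pnn50` (%),
#'   plus companions `pnn20`, `mean_hr` (bpm), `median_rr`, `cv_rr` (%).
#' @export
time_domain <- function(rr) {
  if (length(rr) < 3) stop("need at least 3 intervals")
  d <- diff(rr)
  list(mean_rr = mean(rr), sdnn = pop_sd(rr),
       rmssd = sqrt(mean(d^2)), sdsd = pop_sd(d),
       pnn50 = 100 * mean(abs(d) > 50), pnn20 = 100 * mean(abs(d) > 20),
       mean_hr = 60000 / mean(rr), median_rr = stats::median(rr),
       cv_rr = 100 * pop_sd(rr) / mean(rr))
}

sdnn_index <- function(rr, beat_times, window_s = 60) {
  bins <- floor((beat_times - beat_times[1]) / window_s)
  vals <- tapply(rr, bins, function(v) if (length(v) >= 3) pop_sd(v) else NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Spectral analysis configuration
#'
#' Task Force standard bands: VLF 0.0033-0.04, LF 0.04-0.15,
#' HF 0.15-0.40 Hz; 4 Hz cubic-spline resampling of the tachogram; Welch
#' estimation with 120 s Hann segments at 50% overlap and linear detrend.
#'
#' @param resample_rate even-sampling rate in Hz.
#' @param vlf_band,lf_band,hf_band band edges in Hz.
#' @param welch_segment segment length in seconds.
#' @param welch_overlap fractional overlap.
#' @return object of class `SpectralConfig`.
#' @export
spectral_config <- function(resample_rate = 4,
                            vlf_band = c(0.0033, 0.04),
                            lf_band = c(0.04, 0.15),
                            hf_band = c(0.15, 0.40),
                            welch_segment = 120, welch_overlap = 0.5) {
  if (resample_rate <= 2 * hf_band[2]) stop("resample_rate must exceed twice the HF upper edge")
  structure(list(resample_rate = resample_rate, vlf_band = vlf_band,
                 lf_band = lf_band, hf_band = hf_band,
                 welch_segment = welch_segment, welch_overlap = welch_overlap),
            class = "SpectralConfig")
}

# Welch one-sided PSD with Hann window; returns freq (Hz) and psd (ms^2/Hz)
welch_psd <- function(x, fs, seg_len, overlap) {
  n <- length(x)
  L <- min(n, seg_len)
  step <- max(1L, floor(L * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  starts <- seq(1L, n - L + 1L, by = step)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    P <- Mod(X)^2 / (fs * sum(w^2))
    half <- P[seq_len(nf)]
    if (L %% 2 == 0) half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    else half[2:nf] <- 2 * half[2:nf]
    acc <- acc + half
  }
  list(freq = (seq_len(nf) - 1) * fs / L, psd = acc / length(starts))
}

band_power <- function(freq, psd, band) {
  sel <- freq >= band[1] & freq <= band[2]
  if (sum(sel) < 2) return(0)
  f <- freq[sel]; p <- psd[sel]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

band_peak <- function(freq, psd, band) {
  sel <- freq >= band[1] & freq <= band[2]
  if (!any(sel)) return(NA_real_)
  freq[sel][which.max(psd[sel])]
}

#' Frequency-domain HRV features via Welch estimation
#'
#' The tachogram is resampled evenly by cubic spline, linearly detrended,
#' and its one-sided Welch periodogram integrated (trapezoid) over the
#' VLF, LF and HF bands.
#'
#' @param rr RR intervals in ms.
#' @param beat_times beat times in s (cumulative RR when `NULL`).
#' @param cfg a [spectral_config()].
#' @return named list: `vlf`, `lf`, `hf`, `total_power` (ms^2), `lf_hf`,
#'   `lf_nu`, `hf_nu`, `lf_rel`, `hf_rel` (%), `vlf_peak`, `lf_peak`,
#'   `hf_peak` (Hz). `lf_hf` is `NA` when HF power is zero.
#' @export
spectral_features <- function(rr, beat_times = NULL, cfg = spectral_config()) {
  if (is.null(beat_times)) beat_times <- cumsum(rr) / 1000
  fs <- cfg$resample_rate
  grid <- seq(beat_times[1], beat_times[length(beat_times)], by = 1 / fs)
  x <- stats::spline(beat_times, rr, xout = grid)$y
  # linear detrend
  tt <- seq_along(x)
  x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
  ps <- welch_psd(x, fs, seg_len = round(cfg$welch_segment * fs),
                  overlap = cfg$welch_overlap)
  vlf <- band_power(ps$freq, ps$psd, cfg$vlf_band)
  lf <- band_power(ps$freq, ps$psd, cfg$lf_band)
  hf <- band_power(ps$freq, ps$psd, cfg$hf_band)
  total <- band_power(ps$freq, ps$psd, c(cfg$vlf_band[1], cfg$hf_band[2]))
  # powers below 1e-12 ms^2 are numerically zero (a flat tachogram)
  eps <- 1e-12
  list(vlf = vlf, lf = lf, hf = hf, total_power = total,
       lf_hf = if (hf > eps) lf / hf else NA_real_,
       lf_nu = if (lf + hf > eps) 100 * lf / (lf + hf) else NA_real_,
       hf_nu = if (lf + hf > eps) 100 * hf / (lf + hf) else NA_real_,
       lf_rel = if (total > eps) 100 * lf / total else NA_real_,
       hf_rel = if (total > eps) 100 * hf / total else NA_real_,
       vlf_peak = band_peak(ps$freq, ps$psd, cfg$vlf_band),
       lf_peak = band_peak(ps$freq, ps$psd, cfg$lf_band),
       hf_peak = band_peak(ps$freq, ps$psd, cfg$hf_band))
}

#' Poincare-plot descriptors
#'
#' `sd1` is the dispersion of the lag-1 return map perpendicular to the
#' identity line, `sd2` along it; `S = pi * sd1 * sd2` is the fitted
#' ellipse area.
#'
#' @param rr RR intervals in ms (>= 3).
#' @return named list: `sd1`, `sd2`, `sd1_sd2`, `poincare_area_s`.
#' @export
poincare_features <- function(rr) {
  if (length(rr) < 3) stop("need at least 3 intervals")
  a <- rr[-length(rr)]; b <- rr[-1]
  sd1 <- pop_sd((b - a) / sqrt(2))
  sd2 <- pop_sd((b + a) / sqrt(2))
  list(sd1 = sd1, sd2 = sd2,
       sd1_sd2 = if (sd2 > 0) sd1 / sd2 else NA_real_,
       poincare_area_s = pi * sd1 * sd2)
}

#' Entropy configuration
#' @param m embedding (template) length; @param r tolerance as a fraction
#'   of the series SD (Chebyshev distance).
#' @return object of class `EntropyConfig`.
#' @export
entropy_config <- function(m = 2L, r = 0.2) {
  if (m < 1 || r <= 0) stop("need m >= 1 and r > 0")
  structure(list(m = as.integer(m), r = r), class = "EntropyConfig")
}

# Chebyshev distance matrix between all templates of length m
cheb_template_dist <- function(x, m) {
  N <- length(x)
  nt <- N - m + 1L
  D <- abs(outer(x, x, "-"))
  M <- D[seq_len(nt), seq_len(nt), drop = FALSE]
  if (m > 1) for (k in seq_len(m - 1L))
    M <- pmax(M, D[seq_len(nt) + k, seq_len(nt) + k, drop = FALSE])
  M
}

#' Sample entropy
#'
#' `-ln(A/B)` with B the count of ordered template pairs of length `m`
#' within Chebyshev distance `r * SD` (self-matches excluded, templates
#' `1..N-m`) and A the same for length `m + 1`.
#'
#' @param rr numeric series; @param cfg an [entropy_config()].
#' @return scalar; `NA` with a `reason` attribute when A or B is zero, `0`
#'   for a constant series (all templates match at both lengths).
#' @export
sample_entropy <- function(rr, cfg = entropy_config()) {
  N <- length(rr)
  m <- cfg$m
  if (N <= m + 1) stop("series too short for the template length")
  r_abs <- cfg$r * pop_sd(rr)
  n_use <- N - m
  Mm <- cheb_template_dist(rr, m)[seq_len(n_use), seq_len(n_use), drop = FALSE]
  Mm1 <- cheb_template_dist(rr, m + 1L)
  B <- sum(Mm <= r_abs) - n_use
  A <- sum(Mm1 <= r_abs) - nrow(Mm1)
  if (B == 0 || A == 0) {
    out <- NA_real_
    attr(out, "reason") <- if (B == 0) "no length-m template matches" else
      "no length-(m+1) template matches"
    return(out)
  }
  -log(A / B)
}

#' Approximate entropy
#'
#' `Phi_m(r) - Phi_{m+1}(r)` with self-matches included, per the standard
#' definition.
#'
#' @inheritParams sample_entropy
#' @return scalar ApEn; 0 for a constant series.
#' @export
approximate_entropy <- function(rr, cfg = entropy_config()) {
  N <- length(rr)
  m <- cfg$m
  if (N <= m + 1) stop("series too short for the template length")
  r_abs <- cfg$r * pop_sd(rr)
  phi <- function(mm) {
    M <- cheb_template_dist(rr, mm)
    C <- rowSums(M <= r_abs) / ncol(M)
    mean(log(C))
  }
  phi(m) - phi(m + 1L)
}

#' Detrended fluctuation analysis
#'
#' The mean-centred series is integrated; for each box size the profile is
#' split into non-overlapping boxes, a least-squares line removed per box,
#' and `F(n)` taken as the RMS residual. `alpha` is the slope of
#' `log F(n)` vs `log n` over each range (all integer boxes over 4-16
#' beats for the short range; log2-spaced boxes over 16-64 for the long
#' range).
#'
#' @param rr numeric series.
#' @param short_range,long_range integer box sizes for alpha-1 (all
#'   integers 4-16, the common short-range convention) and alpha-2
#'   (log2-spaced 16-64).
#' @return named list `dfa_alpha1`, `dfa_alpha2` (`NA` when the series is
#'   too short for the long-range boxes).
#' @export
dfa <- function(rr, short_range = 4:16,
                long_range = c(16L, 23L, 32L, 45L, 64L)) {
  y <- cumsum(rr - mean(rr))
  N <- length(y)
  fluct <- function(n) {
    k <- N %/% n
    if (k < 2) return(NA_real_)
    res2 <- 0
    tt <- seq_len(n)
    X <- cbind(1, tt)
    for (b in seq_len(k)) {
      seg <- y[((b - 1) * n + 1):(b * n)]
      res2 <- res2 + sum(stats::lm.fit(X, seg)$residuals^2)
    }
    sqrt(res2 / (k * n))
  }
  slope <- function(sizes) {
    # the range is reported only when the series covers its largest box
    if (N < 4 * max(sizes)) return(NA_real_)
    Fv <- vapply(sizes, fluct, numeric(1))
    ok <- is.finite(Fv) & Fv > 0
    if (sum(ok) < 2) return(NA_real_)
    stats::coef(stats::lm(log(Fv[ok]) ~ log(sizes[ok])))[[2]]
  }
  list(dfa_alpha1 = slope(short_range), dfa_alpha2 = slope(long_range))
}

#' Assemble the canonical 32-descriptor HRV feature vector
#'
#' Runs all three domains on a conditioned segment and returns the fixed
#' 32-value named vector ([hrv_feature_names()] order). Missing values
#' (e.g. LF/HF with zero HF power) are encoded as `NA`.
#'
#' @param segment an `RRSegment` (or numeric RR vector in ms).
#' @param spec_cfg a [spectral_config()].
#' @param ent_cfg an [entropy_config()] for the primary entropies; the
#'   secondary pair uses tolerance `r = 0.15`.
#' @return named numeric vector of length 32.
#' @export
hrv_features <- function(segment, spec_cfg = spectral_config(),
                         ent_cfg = entropy_config()) {
  if (inherits(segment, "RRSegment")) {
    rr <- segment$rr
    bt <- segment$beat_times
  } else {
    rr <- as.numeric(segment)
    bt <- cumsum(rr) / 1000
  }
  td <- time_domain(rr)
  td$sdnn_index <- sdnn_index(rr, bt)
  fd <- spectral_features(rr, bt, spec_cfg)
  pc <- poincare_features(rr)
  ent2 <- entropy_config(ent_cfg$m, 0.15)
  nl <- c(pc, list(sampen = as.numeric(sample_entropy(rr, ent_cfg)),
                   apen = approximate_entropy(rr, ent_cfg),
                   sampen_r15 = as.numeric(sample_entropy(rr, ent2)),
                   apen_r15 = approximate_entropy(rr, ent2)),
          dfa(rr))
  all <- c(td, fd, nl)
  out <- vapply(hrv_feature_names(), function(nm) {
    v <- all[[nm]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  stopifnot(length(out) == 32L)
  out
}

#' Fit a z-score scaler on training feature vectors
#'
#' Means and SDs are learned from the training rows only (population 1/n
#' SD, consistent with the package's SD convention); missing values are
#' imputed with training medians before standardization. Zero-variance
#' features are dropped with a warning and recorded.
#'
#' @param x numeric matrix (rows = samples, named columns).
#' @return object of class `ScalerState` (`center`, `scale`, `medians`,
#'   `dropped`).
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 training vectors")
  medians <- apply(x, 2, stats::median, na.rm = TRUE)
  medians[!is.finite(medians)] <- 0
  for (j in seq_len(ncol(x))) x[!is.finite(x[, j]), j] <- medians[j]
  ctr <- colMeans(x)
  scl <- apply(x, 2, pop_sd)
  dropped <- colnames(x)[scl == 0 | !is.finite(scl)]
  if (length(dropped))
    warning("dropping zero-variance features: ", paste(dropped, collapse = ", "))
  structure(list(center = ctr, scale = scl, medians = medians,
                 dropped = dropped), class = "ScalerState")
}

#' Apply a fitted scaler
#'
#' @param state a `ScalerState` from [fit_scaler()].
#' @param x matrix with the same columns as the training data.
#' @return standardized matrix; dropped features removed.
#' @export
apply_scaler <- function(state, x) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) x[!is.finite(x[, j]), j] <- state$medians[j]
  out <- sweep(sweep(x, 2, state$center), 2, state$scale, "/")
  if (is.null(colnames(out)) || length(state$dropped) == 0)
    return(out[, !is.na(state$scale), drop = FALSE])
  out[, !(colnames(out) %in% state$dropped), drop = FALSE]
}
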