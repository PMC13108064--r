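# Per-lead modified Pan-Tompkins R-peak detection and multichannel fusion.
#
# Stages per lead: zero-phase 5-15 Hz Butterworth bandpass -> five-point
# derivative -> squaring -> moving-window integration -> adaptive dual
# thresholds with a 200 ms refractory period -> +/-50 ms refinement on the
# filtered signal. Per-lead candidates are then clustered across leads with
# a 50 ms tolerance and each cluster is fused at the median timing.

#' Detector configuration
#'
#' @param band_low,band_high bandpass edges in Hz (defaults 5 and 15).
#' @param filter_order Butterworth order (default 3).
#' @param integration_window moving-window integrator length in ms
#'   (default 150).
#' @param refractory minimum admissible gap between detections in ms
#'   (default 200).
#' @param refine_window half-width in ms of the local-maximum refinement on
#'   the filtered signal (default 50).
#' @param fusion_tolerance clustering tolerance across leads in ms
#'   (default 50).
#' @param min_lead_support minimum number of leads that must contribute to
#'   keep a fused peak; `NULL` means `ceiling(n_leads / 3)` at fusion time.
#' @param refine_on `"filtered"` (default) or `"raw"` signal for the
#'   refinement search.
#' @return object of class `DetectorConfig`.
#' @export
detector_config <- function(band_low = 5, band_high = 15, filter_order = 3,
                            integration_window = 150, refractory = 200,
                            refine_window = 50, fusion_tolerance = 50,
                            min_lead_support = NULL,
                            refine_on = c("filtered", "raw")) {
  if (!(band_low > 0 && band_low < band_high)) stop("need 0 < band_low < band_high")
  if (refractory <= 0 || fusion_tolerance <= 0) stop("refractory and fusion_tolerance must be > 0")
  structure(list(band_low = band_low, band_high = band_high,
                 filter_order = filter_order,
                 integration_window = integration_window,
                 refractory = refractory, refine_window = refine_window,
                 fusion_tolerance = fusion_tolerance,
                 min_lead_support = min_lead_support,
                 refine_on = match.arg(refine_on)),
            class = "DetectorConfig")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applied forward-backward (`signal::filtfilt`) so detected peak times are
#' not systematically lagged, which matters because timings are fused
#' across leads.
#'
#' @param x numeric signal (one lead).
#' @param fs sampling rate in Hz.
#' @param config a [detector_config()].
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, config = detector_config()) {
  if (config$band_high >= fs / 2) stop("band_high must be below Nyquist")
  if (length(x) <= 3 * config$filter_order) stop("signal too short for filter order")
  bf <- signal::butter(config$filter_order,
                       c(config$band_low, config$band_high) / (fs / 2),
                       type = "pass")
  # demean first: keeps the forward-backward pass free of the slowly
  # decaying DC transient
  signal::filtfilt(bf, x - mean(x))
}

#' Derivative, squaring and moving-window integration
#'
#' The classic energy-envelope cascade: five-point derivative, pointwise
#' squaring, and a centred moving-average integrator of
#' `integration_window` ms. Output is non-negative and length-preserving
#' (edges zero-padded).
#'
#' @inheritParams bandpass_filter
#' @param filtered bandpass-filtered lead.
#' @return integrated energy envelope.
#' @export
pan_tompkins_stages <- function(filtered, fs, config = detector_config()) {
  n <- length(filtered)
  # five-point derivative (1/8)(-x[n-2] - 2x[n-1] + 2x[n+1] + x[n+2])
  d <- numeric(n)
  if (n >= 5) {
    core <- 3:(n - 2)
    d[core] <- (-filtered[core - 2] - 2 * filtered[core - 1] +
                  2 * filtered[core + 1] + filtered[core + 2]) / 8
  }
  sq <- d^2
  win <- max(1L, round(config$integration_window / 1000 * fs))
  env <- stats::filter(sq, rep(1 / win, win), sides = 2)
  env[is.na(env)] <- 0
  as.numeric(env)
}

local_maxima <- function(x, min_halfwidth = 1L) {
  # local maxima dominating a +/- min_halfwidth neighbourhood, so broad or
  # flat-topped envelope bumps yield one candidate at their apex
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (min_halfwidth <= 1L) return(cand)
  keep <- vapply(cand, function(p) {
    lo <- max(1L, p - min_halfwidth); hi <- min(n, p + min_halfwidth)
    x[p] >= max(x[lo:hi])
  }, logical(1))
  cand[keep]
}

#' Detect R-peak candidates in a single lead
#'
#' Adaptive dual-threshold detection on the integrated envelope in the
#' style of the original Pan-Tompkins method: running signal (SPK) and
#' noise (NPK) level estimates initialised from the first two seconds,
#' threshold `NPK + 0.25 (SPK - NPK)`, a refractory period, and final
#' refinement to the local maximum of the filtered (or raw) signal within
#' `refine_window` ms.
#'
#' @param x one lead of raw ECG.
#' @param fs sampling rate Hz.
#' @param config a [detector_config()].
#' @return integer vector of candidate sample indices (1-based), strictly
#'   increasing, gaps >= refractory; empty for flat or too-short leads.
#' @export
detect_rpeaks_single_lead <- function(x, fs, config = detector_config()) {
  win <- max(1L, round(config$integration_window / 1000 * fs))
  if (length(x) <= max(3 * config$filter_order + 1, win) || stats::sd(x) == 0)
    return(integer(0))
  filt <- bandpass_filter(x, fs, config)
  env <- pan_tompkins_stages(filt, fs, config)
  if (max(env) <= 0) return(integer(0))
  peaks <- local_maxima(env, min_halfwidth = as.integer(win %/% 2L))
  if (length(peaks) == 0) return(integer(0))

  init <- env[seq_len(min(length(env), round(2 * fs)))]
  spk <- max(init)
  npk <- mean(init) * 0.5
  refr <- config$refractory / 1000 * fs
  qrs <- integer(0)
  last <- -Inf
  for (p in peaks) {
    thr <- npk + 0.25 * (spk - npk)
    if (env[p] > thr && (p - last) >= refr) {
      qrs <- c(qrs, p)
      last <- p
      spk <- 0.125 * env[p] + 0.875 * spk
    } else {
      npk <- 0.125 * env[p] + 0.875 * npk
    }
  }
  if (length(qrs) == 0) return(integer(0))

  search <- if (config$refine_on == "filtered") filt else x
  rw <- as.integer(round(config$refine_window / 1000 * fs))
  refined <- vapply(qrs, function(p) {
    lo <- max(1L, p - rw); hi <- min(length(search), p + rw)
    lo + which.max(search[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # re-enforce refractory after refinement
  keep <- integer(0)
  last <- -Inf
  for (p in refined) {
    if (p - last >= refr) { keep <- c(keep, p); last <- p }
  }
  keep
}

#' Fuse per-lead R-peak candidates across channels
#'
#' All candidate times are pooled and sorted; a candidate starts a new
#' cluster when it lies more than `fusion_tolerance` ms from the running
#' median of the current cluster. Each retained cluster (support >=
#' `min_lead_support` leads) is fused at the median of its member sample
#' indices (lower median for even sizes, keeping fused indices on the
#' sampling grid). The refractory period is enforced again on the fused
#' sequence, dropping the later of two close peaks (keeping the higher
#' support).
#'
#' @param per_lead_candidates list (one element per lead) of candidate
#'   sample indices.
#' @param fs sampling rate Hz.
#' @param config a [detector_config()].
#' @return object of class `FusedRPeaks`: `per_lead_candidates`,
#'   `fused_indices`, `fused_times` (s), `support_counts`.
#' @export
fuse_rpeaks <- function(per_lead_candidates, fs, config = detector_config()) {
  n_leads <- length(per_lead_candidates)
  min_support <- config$min_lead_support
  if (is.null(min_support)) min_support <- ceiling(n_leads / 3)
  all_idx <- unlist(per_lead_candidates, use.names = FALSE)
  all_lead <- rep(seq_len(n_leads), vapply(per_lead_candidates, length, integer(1)))
  out <- list(per_lead_candidates = per_lead_candidates,
              fused_indices = integer(0), fused_times = numeric(0),
              support_counts = integer(0))
  class(out) <- "FusedRPeaks"
  if (length(all_idx) == 0) return(out)
  ord <- order(all_idx)
  all_idx <- all_idx[ord]; all_lead <- all_lead[ord]
  tol <- config$fusion_tolerance / 1000 * fs

  fused <- integer(0); support <- integer(0)
  cl_idx <- all_idx[1]; cl_lead <- all_lead[1]
  lower_median <- function(v) sort(v)[ceiling(length(v) / 2)]
  flush <- function() {
    sup <- length(unique(cl_lead))
    if (sup >= min_support) {
      fused <<- c(fused, lower_median(cl_idx))
      support <<- c(support, sup)
    }
  }
  for (i in seq_along(all_idx)[-1]) {
    if (abs(all_idx[i] - stats::median(cl_idx)) > tol) {
      flush()
      cl_idx <- all_idx[i]; cl_lead <- all_lead[i]
    } else {
      cl_idx <- c(cl_idx, all_idx[i]); cl_lead <- c(cl_lead, all_lead[i])
    }
  }
  flush()
  if (length(fused) == 0) return(out)

  # refractory on the fused sequence: drop the lower-support of close pairs
  refr <- config$refractory / 1000 * fs
  keep <- rep(TRUE, length(fused))
  last <- 1L
  for (i in seq_along(fused)[-1]) {
    if (fused[i] - fused[last] < refr) {
      if (support[i] > support[last]) { keep[last] <- FALSE; last <- i }
      else keep[i] <- FALSE
    } else last <- i
  }
  out$fused_indices <- fused[keep]
  out$fused_times <- (fused[keep] - 1) / fs
  out$support_counts <- support[keep]
  out
}

#' Full multilead detection: per-lead Pan-Tompkins + fusion
#'
#' @param ecg a `MultileadECG`.
#' @param config a [detector_config()].
#' @return a `FusedRPeaks` object.
#' @export
detect_rpeaks <- function(ecg, config = detector_config()) {
  cands <- lapply(seq_len(ncol(ecg$signal)), function(j)
    detect_rpeaks_single_lead(ecg$signal[, j], ecg$fs, config))
  names(cands) <- ecg$lead_names
  fuse_rpeaks(cands, ecg$fs, config)
}

#' @export
print.FusedRPeaks <- function(x, ...) {
  cat(sprintf("FusedRPeaks: %d fused peaks from %d leads (support %s)\n",
              length(x$fused_indices), length(x$per_lead_candidates),
              if (length(x$support_counts)) paste0(min(x$support_counts), "-",
                                                   max(x$support_counts)) else "-"))
  invisible(x)
}

#' Detection performance against ground-truth annotations
#'
#' Greedy one-to-one matching of detections to annotated beats within a
#' tolerance window; returns sensitivity and positive predictivity.
#'
#' @param detected sample indices of detections.
#' @param truth annotated true R-peak sample indices.
#' @param fs sampling rate Hz.
#' @param tol_ms match window in ms (default 50).
#' @return list with `sensitivity`, `ppv`, `tp`, `fp`, `fn`.
#' @export
detection_performance <- function(detected, truth, fs, tol_ms = 50) {
  tol <- tol_ms / 1000 * fs
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol)
    if (length(j)) { used[j[which.min(abs(truth[j] - d))]] <- TRUE; tp <- tp + 1L }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  list(sensitivity = if (length(truth)) tp / (tp + fn) else NA_real_,
       ppv = if (length(detected)) tp / (tp + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}
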