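# RR-series construction from fused peaks, artifact flagging/correction,
# five-minute segment selection, and fixed-length 256-interval sequences.

#' Build an RR series from fused R peaks
#'
#' @param fused a `FusedRPeaks` (or numeric vector of beat times in s).
#' @return an `RRSeries` with `rr[i] = 1000 * (t[i+1] - t[i])`.
#' @export
build_rr <- function(fused) {
  bt <- if (inherits(fused, "FusedRPeaks")) fused$fused_times else fused
  if (length(bt) < 2) stop("need at least 2 fused peaks to build an RR series")
  rr <- diff(bt) * 1000
  new_rr_series(beat_times = bt[-1], rr = rr)
}

moving_median_excl <- function(rr, window = 5L) {
  # centred moving median, window shrinking at the boundaries, computed
  # excluding the candidate interval itself so an artifact cannot drag its
  # own reference
  n <- length(rr)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::median(rr[setdiff(lo:hi, i)])
  }, numeric(1))
}

#' Flag RR artifacts against a local moving median
#'
#' An interval is flagged when it deviates strictly more than `threshold`
#' (default 20%) from the median of a centred `window`-beat neighbourhood
#' (default 5), the candidate itself excluded from its reference.
#'
#' @param rr an `RRSeries`.
#' @param window beats in the moving-median window.
#' @param threshold relative deviation above which an interval is flagged.
#' @return the `RRSeries` with `artifact_mask` updated.
#' @export
flag_artifacts <- function(rr, window = 5L, threshold = 0.20) {
  if (length(rr$rr) < window) stop("series shorter than the median window")
  ref <- moving_median_excl(rr$rr, window)
  rr$artifact_mask <- abs(rr$rr - ref) / ref > threshold
  rr
}

#' Correct flagged intervals by linear interpolation
#'
#' Flagged values are replaced by linear interpolation between the nearest
#' unflagged neighbours (in beat index); unflagged values are untouched.
#' Flagged runs at the series edges take the nearest unflagged value.
#'
#' @param rr an `RRSeries` with a populated `artifact_mask`.
#' @return corrected `RRSeries`; `corrected` marks replaced intervals.
#' @export
correct_artifacts <- function(rr) {
  m <- rr$artifact_mask
  if (all(m)) stop("all intervals flagged; nothing to interpolate from")
  if (any(m)) {
    idx <- seq_along(rr$rr)
    rr$rr[m] <- stats::approx(idx[!m], rr$rr[!m], xout = idx[m],
                              rule = 2)$y
    rr$corrected <- rr$corrected | m
    rr$artifact_mask[m] <- FALSE
  }
  rr
}

#' Select the cleanest five-minute analysis window
#'
#' Scans contiguous windows of `duration` seconds and returns the one with
#' the fewest flagged intervals (earliest on ties).
#'
#' @param rr an `RRSeries` (flag before correcting to use artifact counts).
#' @param duration window length in seconds (default 300).
#' @return object of class `RRSegment`: `rr` (ms), `start_time` (s),
#'   `duration`, `n_flagged`, plus the parent series index range.
#' @export
select_segment <- function(rr, duration = 300) {
  bt <- rr$beat_times
  span <- bt[length(bt)] - (bt[1] - rr$rr[1] / 1000)
  if (span < duration) stop("recording shorter than the requested segment")
  starts <- bt - rr$rr / 1000  # interval start times
  n <- length(bt)
  best_i <- NA_integer_; best_flags <- Inf; best_hi <- NA_integer_
  for (i in seq_len(n)) {
    if (starts[i] + duration > bt[n] + 1e-9) break
    hi <- findInterval(starts[i] + duration + 1e-9, bt)
    flags <- sum(rr$artifact_mask[i:hi])
    if (flags < best_flags) { best_flags <- flags; best_i <- i; best_hi <- hi }
  }
  if (is.na(best_i)) stop("recording shorter than the requested segment")
  structure(list(rr = rr$rr[best_i:best_hi],
                 artifact_mask = rr$artifact_mask[best_i:best_hi],
                 beat_times = bt[best_i:best_hi],
                 start_time = starts[best_i], duration = duration,
                 n_flagged = best_flags, index_range = c(best_i, best_hi)),
            class = "RRSegment")
}

#' Extract a fixed 256-interval RR sequence from a segment
#'
#' Takes the first 256 intervals (a configurable offset is available). A
#' segment holding fewer than 256 intervals is padded by repeating its
#' final value, with `padded` set on the result.
#'
#' @param segment an `RRSegment` (or numeric RR vector in ms).
#' @param offset 0-based start offset within the segment.
#' @return numeric vector of exactly 256 RR values (ms) with attributes
#'   `padded` (logical) and `n_pad`.
#' @export
extract_sequence256 <- function(segment, offset = 0L) {
  rr <- if (inherits(segment, "RRSegment")) segment$rr else as.numeric(segment)
  if (length(rr) < 2) stop("segment too short")
  if (offset > 0) rr <- rr[-seq_len(min(offset, length(rr) - 2L))]
  n <- length(rr)
  if (n >= 256L) {
    out <- rr[1:256]
    attr(out, "padded") <- FALSE
    attr(out, "n_pad") <- 0L
  } else {
    out <- c(rr, rep(rr[n], 256L - n))
    attr(out, "padded") <- TRUE
    attr(out, "n_pad") <- 256L - n
  }
  stopifnot(length(out) == 256L)
  out
}

#' Full RR conditioning: flag, select segment, correct
#'
#' Convenience wrapper running the standard conditioning chain on a raw
#' `RRSeries`: artifact flagging, cleanest-window selection, then linear
#' interpolation of remaining flags inside the segment.
#'
#' @param rr an `RRSeries`.
#' @param duration analysis window in seconds.
#' @return the selected `RRSegment` with corrected `rr` values.
#' @export
condition_rr <- function(rr, duration = 300) {
  rr <- flag_artifacts(rr)
  seg <- select_segment(rr, duration)
  if (any(seg$artifact_mask)) {
    tmp <- new_rr_series(beat_times = seg$beat_times, rr = seg$rr,
                         artifact_mask = seg$artifact_mask)
    tmp <- correct_artifacts(tmp)
    seg$rr <- tmp$rr
    seg$corrected <- tmp$corrected
  }
  seg
}
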