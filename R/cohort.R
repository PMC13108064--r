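# Cohort-level synthetic data generation and on-disk export.

derive_seed <- function(master, subject_idx, stage_idx) {
  as.integer((as.numeric(master) * 7919 + subject_idx * 131 + stage_idx * 7) %%
               2147483629)
}

#' Generate a synthetic cohort
#'
#' Produces one record per subject and OGTT stage, each holding a
#' ground-truth RR series (and optionally rendered multilead ECG when the
#' spec carries an `ecg_render` section). Two calls with the same spec are
#' identical.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return object of class `SyntheticCohort` with a `manifest` data.frame
#'   (`subject_id`, `group`, `stage`) and a parallel list `records`, each
#'   record containing `rr_series` (class `RRSeries`) and optionally `ecg`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "SyntheticCohortSpec")) stop("spec must be a SyntheticCohortSpec")
  groups <- names(spec$n_per_group)
  manifest <- NULL
  records <- list()
  sub_global <- 0L
  for (g in groups) {
    prof <- spec$profiles[[g]]
    for (s in seq_len(spec$n_per_group[[g]])) {
      sub_global <- sub_global + 1L
      sid <- sprintf("%s%02d", g, s)
      # stable subject-level trait so subjects differ within a group and
      # subject-wise partitioning is meaningful
      sseed <- derive_seed(spec$seed, sub_global, 0L)
      set.seed(sseed)
      prof_s <- prof
      ts <- spec$trait_sd
      if (is.null(ts)) ts <- c(mean_rr = 0.04, sdnn = 0.10)
      prof_s$mean_rr <- prof$mean_rr * stats::rnorm(1, 1, ts[["mean_rr"]])
      prof_s$sdnn_target <- prof$sdnn_target *
        max(stats::rnorm(1, 1, ts[["sdnn"]]), 0.3)
      for (k in seq_along(spec$stages)) {
        st <- spec$stages[k]
        rseed <- derive_seed(spec$seed, sub_global, k)
        rr <- generate_rr_series(prof_s, stage = st,
                                 duration = spec$duration_s, seed = rseed)
        rr$subject_id <- sid
        rec <- list(subject_id = sid, group = g, stage = st, rr_series = rr)
        if (!is.null(spec$ecg_render)) {
          rec$ecg <- render_multilead_ecg(rr$beat_times, spec$ecg_render,
                                          seed = rseed + 1L, subject_id = sid,
                                          group_label = g, stage = st)
        }
        records[[length(records) + 1L]] <- rec
        manifest <- rbind(manifest,
                          data.frame(subject_id = sid, group = g, stage = st,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(manifest = manifest, records = records, spec = spec),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d records (%d subjects x %d stages)\n",
              nrow(x$manifest), length(unique(x$manifest$subject_id)),
              length(unique(x$manifest$stage))))
  invisible(x)
}

#' Write an RR series to a two-column CSV (beat_time_s, rr_ms)
#'
#' Also writes the artifact and correction provenance columns.
#' @param rr an `RRSeries`; @param path output file.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(rr, path) {
  utils::write.csv(data.frame(beat_time_s = rr$beat_times, rr_ms = rr$rr,
                              artifact = rr$artifact_mask,
                              corrected = rr$corrected),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an RR series from a CSV written by [write_rr_csv()]
#' @param path input file.
#' @return an `RRSeries`.
#' @export
read_rr_csv <- function(path) {
  d <- utils::read.csv(path)
  new_rr_series(beat_times = d$beat_time_s, rr = d$rr_ms,
                artifact_mask = if (!is.null(d$artifact)) as.logical(d$artifact)
                                else rep(FALSE, nrow(d)),
                corrected = if (!is.null(d$corrected)) as.logical(d$corrected)
                            else rep(FALSE, nrow(d)))
}

#' Write a multilead ECG as a wide CSV (time + one column per lead)
#' @param ecg a `MultileadECG`; @param path output file.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(ecg, path) {
  d <- data.frame(time_s = (seq_len(nrow(ecg$signal)) - 1) / ecg$fs)
  for (j in seq_along(ecg$lead_names)) d[[ecg$lead_names[j]]] <- ecg$signal[, j]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a wide-CSV multilead ECG
#' @param path file with a `time_s` column plus one column per lead.
#' @param fs sampling rate; inferred from `time_s` when `NULL`.
#' @return a `MultileadECG` (without ground-truth annotation).
#' @export
read_ecg_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(d)) stop("expected a time_s column")
  if (is.null(fs)) fs <- round(1 / stats::median(diff(d$time_s)))
  leads <- setdiff(names(d), "time_s")
  structure(list(signal = as.matrix(d[leads]), fs = fs, lead_names = leads,
                 true_r_indices = NULL, subject_id = NA_character_,
                 group_label = NA_character_, stage = NA_real_),
            class = "MultileadECG")
}

#' Write a cohort to disk (manifest CSV + one RR CSV per record)
#'
#' @param cohort a `SyntheticCohort`; @param dir output directory.
#' @param write_ecg also write rendered ECG CSVs when present.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_ecg = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$file <- sprintf("%s_stage%03d_rr.csv", man$subject_id, man$stage)
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    write_rr_csv(rec$rr_series, file.path(dir, man$file[i]))
    if (write_ecg && !is.null(rec$ecg)) {
      write_ecg_csv(rec$ecg, file.path(
        dir, sprintf("%s_stage%03d_ecg.csv", rec$subject_id, rec$stage)))
    }
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}
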