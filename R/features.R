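# The twelve physiological tidal-breathing features.
#
# All per-cycle quantities are averaged over the accepted cycles of a trial:
# inspiratory/expiratory times, times to peak flow, peak flows, tidal volumes,
# the duty cycle TI/(TI+TE), and the inspiratory/expiratory "velocity" (mean
# rate of flow rise from phase onset to phase peak, peak flow / time-to-peak,
# in L/s^2). Breathing rate uses the segmented span, not the nominal record
# length, so discarded partial breaths do not bias it.

#' Extract the 12-feature vector from one segmented record
#'
#' @param cycles Cycle tibble with tidal volumes, from [derive_volume()] or
#'   [segment_record()].
#' @param fs Sampling rate, Hz.
#' @param peak_summary `"mean"` (default) averages per-cycle peak flows;
#'   `"max"` takes the trial-wide maximum instead.
#' @param velocity `"slope"` (default) computes per-cycle peak flow divided by
#'   time-to-peak; `"mean_flow"` averages the flow samples between phase onset
#'   and peak (requires `flow`).
#' @param flow Conditioned flow tibble; only needed for
#'   `velocity = "mean_flow"`.
#' @return One-row tibble with the columns of [feature_names()].
#' @export
extract_features <- function(cycles, fs, peak_summary = c("mean", "max"),
                             velocity = c("slope", "mean_flow"), flow = NULL) {
  peak_summary <- match.arg(peak_summary)
  velocity <- match.arg(velocity)
  if (is.null(cycles) || nrow(cycles) == 0) {
    abort("no breath cycles to extract features from",
          class = "tidybreathe_no_breaths")
  }
  span_s <- (max(cycles$cycle_end) - min(cycles$insp_onset)) / fs

  vel_pair <- function(pk, tpk, onset_col) {
    ok <- tpk > 0
    if (!all(ok)) {
      warn(sprintf("%d cycle(s) with zero time-to-peak excluded from velocity features",
                   sum(!ok)))
    }
    if (velocity == "slope" || is.null(flow)) {
      mean(pk[ok] / tpk[ok])
    } else {
      x <- abs(flow$flow_lps)
      mean(purrr::map_dbl(which(ok), function(j) {
        s <- cycles[[onset_col]][j]
        mean(x[s:(s + round(tpk[j] * fs))])
      }))
    }
  }

  tibble::tibble(
    ti_s = mean(cycles$ti_s),
    te_s = mean(cycles$te_s),
    br_bpm = nrow(cycles) / span_s * 60,
    dcy = mean(cycles$ti_s / (cycles$ti_s + cycles$te_s)),
    pif_lps = if (peak_summary == "mean") mean(cycles$pif_lps) else max(cycles$pif_lps),
    pef_lps = if (peak_summary == "mean") mean(cycles$pef_lps) else max(cycles$pef_lps),
    tpif_s = mean(cycles$tpif_s),
    tpef_s = mean(cycles$tpef_s),
    tv_ins_L = mean(cycles$tv_ins_L),
    tv_exp_L = mean(cycles$tv_exp_L),
    vel_ins = vel_pair(cycles$pif_lps, cycles$tpif_s, "insp_onset"),
    vel_exp = vel_pair(cycles$pef_lps, cycles$tpef_s, "exp_onset")
  )
}

#' Build the cohort feature table
#'
#' Runs conditioning, segmentation, volume derivation and feature extraction
#' over every record of a cohort. Records in which no complete breath cycle is
#' found are dropped with a warning and listed in the `dropped` attribute.
#'
#' @param cohort A `breath_cohort` (see [synth_cohort()], [read_cohort()]).
#' @param smooth_window_s,hysteresis_frac,min_phase_s Preprocessing settings,
#'   see [segment_record()].
#' @param peak_summary,velocity Feature conventions, see [extract_features()].
#' @return Tibble with `subject_id`, `trial`, `label` and the 12 feature
#'   columns, one row per surviving subject-trial, in manifest order.
#' @export
build_feature_table <- function(cohort, smooth_window_s = 0.05,
                                hysteresis_frac = 0.05, min_phase_s = 0.25,
                                peak_summary = "mean", velocity = "slope") {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    id <- sprintf("%s trial %d", cohort$subject_id[i], cohort$trial[i])
    tryCatch({
      seg <- segment_record(cohort$flow[[i]], cohort$fs_hz[i],
                            smooth_window_s, hysteresis_frac, min_phase_s,
                            record_id = id)
      dplyr::bind_cols(
        tibble::tibble(subject_id = cohort$subject_id[i],
                       trial = cohort$trial[i],
                       label = cohort$label[i]),
        extract_features(seg$cycles, cohort$fs_hz[i],
                         peak_summary = peak_summary, velocity = velocity,
                         flow = seg$flow)
      )
    }, tidybreathe_no_breaths = function(e) {
      warn(paste0("dropping ", id, ": ", conditionMessage(e)))
      NULL
    })
  })
  dropped <- purrr::map_lgl(rows, is.null)
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    abort("no record yielded any breath cycles; feature table is empty",
          class = "tidybreathe_empty_table")
  }
  attr(out, "dropped") <- sprintf("%s trial %d", cohort$subject_id,
                                  cohort$trial)[dropped]
  out
}
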