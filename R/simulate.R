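# Synthetic tidal-breathing cohorts.
#
# The generator emulates a restful-breathing acquisition protocol: 60-second
# flow traces sampled at 100 Hz, three trials per subject on different days,
# two groups (smokers vs non-smokers) whose breathing differs in timing and
# expiratory shape, riding on a subject-level lung-capacity (FRC-like)
# amplitude that is deliberately *not* class-informative.

#' Default group-conditional simulator parameters
#'
#' Returns the configuration used by [sample_subject()] and [synth_cohort()].
#' At full class separation, non-smokers breathe with a 4.0 s period, duty
#' cycle 0.50 and an expiratory peak at 45% of expiration; smokers with a
#' 4.5 s period, duty cycle 0.40 and an early expiratory peak at 25% —
#' the flow-limited, skewed expiration that obstruction produces. The
#' FRC-proxy amplitude `frc_scale` is uniform on \[0.8, 1.3\] for both groups,
#' so lung capacity is a nuisance dimension, never a class signal.
#'
#' @return A named list of distribution settings.
#' @export
simulate_defaults <- function() {
  list(
    # group means at separation = 1
    nonsmoker = list(period_s = 4.0, duty = 0.50, exp_peak_frac = 0.45),
    smoker    = list(period_s = 4.5, duty = 0.40, exp_peak_frac = 0.25),
    # common between-subject standard deviations
    sd = list(period_s = 0.35, duty = 0.04, exp_peak_frac = 0.05, tv_L = 0.07),
    tv_L = 0.5,                 # nominal tidal volume mean, litres
    frc_range = c(0.8, 1.3),    # subject-level amplitude multiplier
    noise_sd = 0.05,            # additive flow noise, L/s
    drift_amp = 0.03,           # slow baseline drift amplitude, L/s
    drift_period_s = 45,        # drift period, seconds (>= 30 s)
    trial_jitter = 0.05         # per-trial uniform jitter on period and tv
  )
}

#' Draw per-subject breathing parameters
#'
#' Draws one subject's timing/shape/amplitude parameters from the
#' group-conditional distributions. Group means are linearly interpolated in
#' `separation`: at 0 both groups share the midpoint distribution (the classes
#' collapse); at 1 they sit at the full group means of [simulate_defaults()].
#' Uses the current R random stream; seed with [withr::with_seed()] or
#' `set.seed()` for reproducibility.
#'
#' @param group 0 (non-smoker) or 1 (smoker).
#' @param separation Class separation in \[0, 1\].
#' @param defaults Parameter configuration, see [simulate_defaults()].
#' @return One-row tibble with columns `group`, `period_s`, `duty`, `tv_L`,
#'   `frc_scale`, `exp_peak_frac`, `noise_sd`, `drift_amp`.
#' @export
#' @examples
#' withr::with_seed(1, sample_subject(1, separation = 1))
sample_subject <- function(group, separation = 1, defaults = simulate_defaults()) {
  if (!group %in% c(0, 1)) {
    abort("`group` must be 0 or 1", class = "tidybreathe_domain")
  }
  if (!is.numeric(separation) || separation < 0 || separation > 1) {
    abort("`separation` must lie in [0, 1]", class = "tidybreathe_domain")
  }
  mid <- purrr::map2(defaults$nonsmoker, defaults$smoker, ~ (.x + .y) / 2)
  full <- if (group == 1) defaults$smoker else defaults$nonsmoker
  mu <- purrr::map2(mid, full, ~ (1 - separation) * .x + separation * .y)

  tibble::tibble(
    group = as.integer(group),
    period_s = clamp(rnorm(1, mu$period_s, defaults$sd$period_s), 2.0, 8.0),
    duty = clamp(rnorm(1, mu$duty, defaults$sd$duty), 0.2, 0.8),
    tv_L = clamp(rnorm(1, defaults$tv_L, defaults$sd$tv_L), 0.15, 1.5),
    frc_scale = runif(1, defaults$frc_range[1], defaults$frc_range[2]),
    exp_peak_frac = clamp(rnorm(1, mu$exp_peak_frac, defaults$sd$exp_peak_frac),
                          0.05, 0.90),
    noise_sd = defaults$noise_sd,
    drift_amp = defaults$drift_amp
  )
}

#' Synthesize one tidal-breathing flow trace
#'
#' Builds a periodic flow waveform from subject parameters: inspiration is a
#' half-sine of duration `duty * period_s`; expiration is a two-piece
#' half-cosine that rises to its peak at `exp_peak_frac` of the expiratory
#' duration and then decays, with amplitude chosen so the noise-free per-cycle
#' net volume is zero. Inspiration is positive flow, expiration negative. All
#' amplitudes are multiplied by `frc_scale`; Gaussian noise (`noise_sd`) and a
#' slow sinusoidal baseline drift (`drift_amp`, period `drift_period_s`) are
#' then added.
#'
#' @param params One-row tibble or list of subject parameters, as produced by
#'   [sample_subject()].
#' @param duration_s Trace duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param drift_period_s Baseline drift period, seconds.
#' @return Tibble with columns `time_s`, `flow_lps` and
#'   `round(duration_s * fs)` rows.
#' @export
#' @examples
#' p <- withr::with_seed(1, sample_subject(0))
#' flow <- synth_flow(p, duration_s = 10, fs = 100)
synth_flow <- function(params, duration_s = 60, fs = 100, drift_period_s = 45) {
  if (duration_s <= 0 || fs <= 0) {
    abort("`duration_s` and `fs` must be positive", class = "tidybreathe_domain")
  }
  p <- as.list(params)
  stopifnot(p$period_s > 0, p$duty > 0, p$duty < 1, p$tv_L > 0,
            p$frc_scale > 0, p$exp_peak_frac > 0, p$exp_peak_frac < 1)

  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  ti <- p$duty * p$period_s
  te <- p$period_s - ti
  tp <- p$exp_peak_frac * te
  # amplitudes balancing inspired and expired volume: each phase integrates to
  # amp * 2 * phase_duration / pi
  a_ins <- p$tv_L * pi / (2 * ti)
  a_exp <- p$tv_L * pi / (2 * te)

  tau <- t %% p$period_s
  flow <- numeric(n)
  insp <- tau < ti
  flow[insp] <- a_ins * sin(pi * tau[insp] / ti)
  tau_e <- tau[!insp] - ti
  rise <- tau_e < tp
  fe <- numeric(sum(!insp))
  fe[rise] <- sin(pi * tau_e[rise] / (2 * tp))
  fe[!rise] <- cos(pi * (tau_e[!rise] - tp) / (2 * (te - tp)))
  flow[!insp] <- -a_exp * fe

  flow <- flow * p$frc_scale
  if (p$drift_amp > 0) {
    phase <- runif(1, 0, 2 * pi)
    flow <- flow + p$drift_amp * sin(2 * pi * t / drift_period_s + phase)
  }
  if (p$noise_sd > 0) {
    flow <- flow + rnorm(n, 0, p$noise_sd)
  }
  tibble::tibble(time_s = t, flow_lps = flow)
}

#' Generate a synthetic tidal-breathing cohort
#'
#' Draws `2 * n_per_class` subjects (labels: 1 = smoker, 0 = non-smoker) and
#' synthesizes `trials` flow traces per subject. Trials of one subject share
#' the subject's parameters up to a small per-trial jitter (uniform within
#' +/-5% on breath period and tidal volume), modelling day-to-day variation.
#'
#' @param n_per_class Subjects per class.
#' @param trials Trials (traces) per subject.
#' @param duration_s Trace duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param separation Class separation in \[0, 1\].
#' @param seed Integer seed; fully determines the cohort.
#' @param defaults Simulator configuration, see [simulate_defaults()].
#' @return A `breath_cohort`: a tibble with one row per subject-trial, columns
#'   `subject_id`, `trial`, `label`, `fs_hz`, the subject parameters, and a
#'   `flow` list-column of `time_s`/`flow_lps` tibbles. The subject manifest
#'   is available via [cohort_manifest()].
#' @export
#' @examples
#' cohort <- synth_cohort(n_per_class = 2, trials = 1, duration_s = 10, seed = 1)
synth_cohort <- function(n_per_class = 10, trials = 3, duration_s = 60, fs = 100,
                         separation = 1, seed = 1,
                         defaults = simulate_defaults()) {
  if (n_per_class < 1 || trials < 1) {
    abort("`n_per_class` and `trials` must be >= 1", class = "tidybreathe_domain")
  }
  withr::with_seed(as.integer(seed), {
    subjects <- purrr::map_dfr(seq_len(2 * n_per_class), function(i) {
      group <- as.integer(i > n_per_class)
      dplyr::mutate(
        sample_subject(group, separation, defaults),
        subject_id = sprintf("S%02d", i), .before = 1
      )
    })
    jit <- defaults$trial_jitter
    records <- tidyr::expand_grid(subjects, trial = seq_len(trials))
    records <- dplyr::mutate(
      records,
      period_s = .data$period_s * runif(dplyr::n(), 1 - jit, 1 + jit),
      tv_L = .data$tv_L * runif(dplyr::n(), 1 - jit, 1 + jit),
      fs_hz = fs
    )
    records$flow <- purrr::pmap(
      list(records$period_s, records$duty, records$tv_L, records$frc_scale,
           records$exp_peak_frac, records$noise_sd, records$drift_amp),
      function(period_s, duty, tv_L, frc_scale, exp_peak_frac, noise_sd, drift_amp) {
        synth_flow(
          list(period_s = period_s, duty = duty, tv_L = tv_L,
               frc_scale = frc_scale, exp_peak_frac = exp_peak_frac,
               noise_sd = noise_sd, drift_amp = drift_amp),
          duration_s = duration_s, fs = fs,
          drift_period_s = defaults$drift_period_s
        )
      }
    )
    out <- dplyr::relocate(
      dplyr::rename(records, label = "group"),
      "subject_id", "trial", "label", "fs_hz"
    )
    out <- tibble::new_tibble(out, class = "breath_cohort",
                              seed = as.integer(seed), separation = separation)
    out
  })
}

#' Subject-trial manifest of a cohort
#'
#' @param cohort A `breath_cohort` from [synth_cohort()] or [read_cohort()].
#' @return Tibble without the `flow` list-column.
#' @export
cohort_manifest <- function(cohort) {
  tibble::as_tibble(cohort[, setdiff(names(cohort), "flow")])
}

#' Write a cohort to per-trial CSV files plus a manifest
#'
#' Each flow record is written as `<subject_id>_t<trial>.csv` with columns
#' `time_s,flow_lps`; the manifest `manifest.csv` records
#' `subject_id,trial,label,fs_hz,file` plus the generating parameters.
#'
#' @param cohort A `breath_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest file path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_t%d.csv", cohort$subject_id, cohort$trial)
  purrr::walk2(cohort$flow, files, function(flow, file) {
    write.csv(flow, file.path(dir, file), row.names = FALSE)
  })
  manifest <- dplyr::mutate(cohort_manifest(cohort), file = files)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A `breath_cohort` tibble with a `flow` list-column.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- tibble::as_tibble(read.csv(manifest_path))
  dir <- dirname(manifest_path)
  manifest$flow <- purrr::map(manifest$file, function(f) {
    tibble::as_tibble(read.csv(file.path(dir, f)))
  })
  out <- manifest[, setdiff(names(manifest), "file")]
  tibble::new_tibble(out, class = "breath_cohort")
}
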