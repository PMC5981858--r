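# Flow-trace conditioning, breath segmentation and drift-free volume.
#
# Segmentation follows the usual zero-crossing scheme with an amplitude
# hysteresis and a minimum phase duration, so noise blips around the baseline
# do not split a phase. Indexing is 1-based with half-open cycles
# [insp_onset, cycle_end); times are derived as (index difference) / fs.

#' Condition a flow trace by centered moving-average smoothing
#'
#' The window is `round(smooth_window_s * fs)` samples, forced odd (minimum 1);
#' edges use shrinking windows so the output has the input's length.
#' `smooth_window_s = 0` is the identity.
#'
#' @param flow Tibble with columns `time_s`, `flow_lps`.
#' @param fs Sampling rate, Hz.
#' @param smooth_window_s Smoothing window, seconds.
#' @return Tibble of the same shape with smoothed `flow_lps`.
#' @export
condition_signal <- function(flow, fs, smooth_window_s = 0.05) {
  x <- flow$flow_lps
  n <- length(x)
  if (smooth_window_s < 0) {
    abort("`smooth_window_s` must be >= 0", class = "tidybreathe_domain")
  }
  w <- round(smooth_window_s * fs)
  if (w %% 2 == 0) w <- w + 1
  w <- max(w, 1)
  if (w >= n) {
    abort("smoothing window must be shorter than the record",
          class = "tidybreathe_domain")
  }
  if (w == 1) return(flow)
  r <- (w - 1) %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - r, 1)
  hi <- pmin(i + r, n)
  flow$flow_lps <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  flow
}

# Sign runs of a flow trace; zeros inherit the preceding sign.
flow_sign_runs <- function(x) {
  s <- sign(x)
  nz <- which(s != 0)
  if (length(nz) == 0) return(NULL)
  # propagate last non-zero sign forward, and the first one backward
  s_filled <- s
  s_filled[s_filled == 0] <- NA
  s_filled <- c(NA, s_filled)
  for (i in which(is.na(s_filled))) if (i > 1) s_filled[i] <- s_filled[i - 1]
  s_filled <- s_filled[-1]
  s_filled[is.na(s_filled)] <- s[nz[1]]
  r <- rle(s_filled)
  ends <- cumsum(r$lengths)
  tibble::tibble(sign = r$values,
                 start = c(1L, head(ends, -1) + 1L),
                 end = ends)
}

#' Segment a conditioned flow trace into breath cycles
#'
#' Phases begin at zero crossings. A candidate phase is accepted only if its
#' peak absolute flow exceeds `hysteresis_frac` times the trial-wide maximum
#' absolute flow and it lasts at least `min_phase_s`; rejected runs (noise
#' blips) are merged into the preceding phase. A cycle is an inspiration
#' (positive flow) followed by its expiration; `cycle_end` is the onset of the
#' next inspiration, half-open convention. Phases cut by the record boundary
#' are kept only if the boundary sample has essentially returned to baseline
#' (|flow| at the boundary below the hysteresis level); otherwise the partial
#' cycle is discarded.
#'
#' @param flow Conditioned flow tibble (`time_s`, `flow_lps`).
#' @param fs Sampling rate, Hz.
#' @param hysteresis_frac Amplitude acceptance threshold, fraction of the
#'   trial-wide max absolute flow, in \[0, 0.5).
#' @param min_phase_s Minimum accepted phase duration, seconds.
#' @param record_id Identifier used in error messages.
#' @return Tibble of cycles: `cycle_idx`, `insp_onset`, `exp_onset`,
#'   `cycle_end` (1-based sample indices), `ti_s`, `te_s`, `pif_lps`,
#'   `pef_lps`, `tpif_s`, `tpef_s`.
#' @export
segment_breaths <- function(flow, fs, hysteresis_frac = 0.05,
                            min_phase_s = 0.25, record_id = "record") {
  if (hysteresis_frac < 0 || hysteresis_frac >= 0.5) {
    abort("`hysteresis_frac` must lie in [0, 0.5)", class = "tidybreathe_domain")
  }
  if (min_phase_s <= 0) {
    abort("`min_phase_s` must be positive", class = "tidybreathe_domain")
  }
  x <- flow$flow_lps
  n <- length(x)
  m <- max(abs(x))
  no_breaths <- function() {
    abort(paste0("no complete breath cycle found in ", record_id),
          class = "tidybreathe_no_breaths", record_id = record_id)
  }
  if (m == 0) no_breaths()

  runs <- flow_sign_runs(x)
  if (is.null(runs) || nrow(runs) < 2) no_breaths()

  peak_of <- function(s, e) max(abs(x[s:e]))
  min_len <- min_phase_s * fs

  # accept/merge pass: minor runs (too small or too short) extend the
  # previous accepted phase; adjacent same-sign phases merge
  acc <- list()
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]
    major <- peak_of(s, e) > hysteresis_frac * m && (e - s + 1) >= min_len
    if (major) {
      k <- length(acc)
      if (k > 0 && acc[[k]]$sign == runs$sign[i]) {
        acc[[k]]$end <- e
      } else {
        acc[[length(acc) + 1]] <- list(sign = runs$sign[i], start = s, end = e)
      }
    } else if (length(acc) > 0) {
      acc[[length(acc)]]$end <- e
    }
    # minor runs before the first accepted phase are dropped (leading partial)
  }
  if (length(acc) < 2) no_breaths()
  ph <- dplyr::bind_rows(purrr::map(acc, tibble::as_tibble))

  # boundary policy: first/last phases touching the record edge are kept only
  # if flow at the edge is within the hysteresis band
  keep_first <- ph$sign[1] > 0 &&
    (ph$start[1] > 1 || abs(x[1]) <= hysteresis_frac * m)
  if (!keep_first) ph <- ph[-1, , drop = FALSE]
  if (nrow(ph) >= 1 && ph$end[nrow(ph)] == n &&
      abs(x[n]) > hysteresis_frac * m) {
    ph <- ph[-nrow(ph), , drop = FALSE]
  }
  # a cycle needs a completed expiration: last phase must be an expiration
  while (nrow(ph) >= 1 && ph$sign[nrow(ph)] > 0) ph <- ph[-nrow(ph), , drop = FALSE]
  if (nrow(ph) < 2) no_breaths()

  ins_idx <- which(ph$sign > 0 & dplyr::lead(ph$sign) < 0)
  if (length(ins_idx) == 0) no_breaths()

  cycles <- purrr::map_dfr(seq_along(ins_idx), function(j) {
    i <- ins_idx[j]
    insp_onset <- ph$start[i]
    exp_onset <- ph$start[i + 1]
    cycle_end <- ph$end[i + 1] + 1L    # one past the expiration = next onset
    irange <- insp_onset:(exp_onset - 1L)
    erange <- exp_onset:(cycle_end - 1L)
    ipk <- which.max(x[irange])
    epk <- which.max(-x[erange])
    tibble::tibble(
      cycle_idx = j,
      insp_onset = insp_onset, exp_onset = exp_onset, cycle_end = cycle_end,
      ti_s = (exp_onset - insp_onset) / fs,
      te_s = (cycle_end - exp_onset) / fs,
      pif_lps = x[irange][ipk],
      pef_lps = -x[erange][epk],
      tpif_s = (ipk - 1) / fs,
      tpef_s = (epk - 1) / fs
    )
  })
  cycles
}

#' Derive a drift-free volume signal and per-cycle tidal volumes
#'
#' Integrates flow by the cumulative trapezoidal rule, then removes drift
#' within each cycle by subtracting the straight line that returns the
#' cycle-end volume to the cycle-start volume (per-cycle linear detrend).
#' Inspired volume is the maximum intra-cycle excursion above the cycle
#' baseline; expired volume is the fall from that maximum back to the
#' corrected end-expiratory level.
#'
#' @param flow Conditioned flow tibble.
#' @param cycles Cycle tibble from [segment_breaths()] on the same record.
#' @param fs Sampling rate, Hz.
#' @return List with `volume` (tibble `time_s`, `vol_L`: the drift-corrected
#'   volume signal) and `cycles` (input cycles plus `tv_ins_L`, `tv_exp_L`).
#' @export
derive_volume <- function(flow, cycles, fs) {
  x <- flow$flow_lps
  n <- length(x)
  if (nrow(cycles) == 0 || max(cycles$cycle_end) > n + 1L) {
    abort("cycles do not match the flow record", class = "tidybreathe_domain")
  }
  v <- as.numeric(pracma::cumtrapz(flow$time_s, x))
  v_corr <- v
  tv_ins <- tv_exp <- numeric(nrow(cycles))
  anchor <- v[cycles$insp_onset[1]]   # common end-expiratory level
  for (j in seq_len(nrow(cycles))) {
    s <- cycles$insp_onset[j]
    e <- min(cycles$cycle_end[j], n)     # last sample inside the cycle span
    idx <- s:e
    ramp <- (v[e] - v[s]) * (idx - s) / max(e - s, 1L)
    v_corr[idx] <- v[idx] - ramp - (v[s] - anchor)
    peak <- max(v_corr[idx])
    tv_ins[j] <- peak - anchor
    tv_exp[j] <- peak - v_corr[e]
  }
  cycles$tv_ins_L <- tv_ins
  cycles$tv_exp_L <- tv_exp
  list(volume = tibble::tibble(time_s = flow$time_s, vol_L = v_corr),
       cycles = cycles)
}

#' Condition, segment and integrate one flow record
#'
#' Convenience wrapper chaining [condition_signal()], [segment_breaths()] and
#' [derive_volume()].
#'
#' @inheritParams segment_breaths
#' @inheritParams condition_signal
#' @return List with `flow` (conditioned), `cycles` (with tidal volumes) and
#'   `volume`.
#' @export
segment_record <- function(flow, fs, smooth_window_s = 0.05,
                           hysteresis_frac = 0.05, min_phase_s = 0.25,
                           record_id = "record") {
  cond <- condition_signal(flow, fs, smooth_window_s)
  cycles <- segment_breaths(cond, fs, hysteresis_frac, min_phase_s, record_id)
  vol <- derive_volume(cond, cycles, fs)
  list(flow = cond, cycles = vol$cycles, volume = vol$volume)
}
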