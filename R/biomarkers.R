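#' Action-potential biomarkers of a single beat
#'
#' Extracts the standard human atrial AP biomarkers from a voltage trace:
#' durations at 20/50/90% repolarization (APD20/50/90), amplitude (APA),
#' resting membrane potential (RMP) and the plateau potential at 20% of
#' APD90 (V20).
#'
#' Definitions: RMP is the voltage immediately before the stimulus; APA is
#' peak minus RMP; the take-off point is the time of maximum dV/dt during the
#' upstroke; APDx is the time from take-off to the repolarizing crossing of
#' `RMP + (1 - x/100) * APA`, linearly interpolated between samples; V20 is
#' the voltage at `take-off + 0.2 * APD90`.
#'
#' @param trace A `voltage_trace` (or any data frame with `time`/`V`).
#' @param beat_window Optional numeric length-2 time window (ms) containing
#'   exactly one stimulated beat; defaults to the last stimulus onward.
#' @param stim_time Stimulus onset within the window; defaults to the last
#'   recorded stimulus time (or the window start).
#' @return One-row tibble with `apd20`, `apd50`, `apd90`, `apa`, `rmp`,
#'   `v20`, `t_takeoff` plus flags `excited` (APA >= 10 mV) and
#'   `repolarized` (the 90% level was crossed). Biomarkers are `NA` when the
#'   corresponding flag fails.
#' @export
compute_ap_biomarkers <- function(trace, beat_window = NULL, stim_time = NULL) {
  t <- trace$time; V <- trace$V
  stims <- attr(trace, "stim_times")
  if (is.null(stim_time)) {
    stim_time <- if (!is.null(stims) && length(stims)) {
      if (is.null(beat_window)) max(stims) else max(stims[stims < max(beat_window) &
                                                          stims >= min(beat_window)], -Inf)
    } else if (!is.null(beat_window)) min(beat_window) else t[1]
    if (!is.finite(stim_time)) stim_time <- min(beat_window)
  }
  if (is.null(beat_window)) beat_window <- c(stim_time, max(t))
  keep <- t >= beat_window[1] & t <= beat_window[2]
  t <- t[keep]; V <- V[keep]
  if (length(t) < 5) abort("beat window contains too few samples")

  na_row <- function(excited, repolarized, rmp = NA_real_, apa = NA_real_) {
    tibble(apd20 = NA_real_, apd50 = NA_real_, apd90 = NA_real_,
           apa = apa, rmp = rmp, v20 = NA_real_, t_takeoff = NA_real_,
           excited = excited, repolarized = repolarized)
  }

  pre <- which(t <= stim_time)
  rmp <- if (length(pre)) V[max(pre)] else V[1]
  peak_i <- which.max(V)
  apa <- V[peak_i] - rmp
  if (!is.finite(apa) || apa < 10) return(na_row(FALSE, FALSE, rmp, apa))

  # take-off: max dV/dt on the upstroke, searched from the stimulus to the
  # first sample reaching 95% of APA (not the global peak, which noise can
  # push deep into the plateau)
  rise_end <- which(V >= rmp + 0.95 * apa)[1]
  up <- which(t >= stim_time & seq_along(t) <= rise_end)
  if (length(up) < 2) return(na_row(FALSE, FALSE, rmp, apa))
  dv <- diff(V[up]) / diff(t[up])
  k <- which.max(dv)
  # take-off = centre of the steepest segment (unbiased for a rise that
  # happens between two samples)
  t0 <- (t[up[k]] + t[up[k + 1]]) / 2

  # linearly interpolated down-crossing of level after the peak; a crossing
  # must persist (median over the following ~1 ms stays below the level), so
  # isolated noise dips are not mistaken for repolarization
  dt_samp <- stats::median(diff(t))
  persist <- max(1L, ceiling(1 / dt_samp))
  down_cross <- function(level) {
    idx <- which(V[-seq_len(peak_i)] <= level) + peak_i
    for (i2 in idx) {
      w <- V[i2:min(i2 + persist, length(V))]
      if (median(w) <= level) {
        i1 <- i2 - 1
        if (V[i1] == V[i2]) return(t[i2])
        return(t[i1] + (level - V[i1]) / (V[i2] - V[i1]) * (t[i2] - t[i1]))
      }
    }
    NA_real_
  }
  apd_at <- function(x) {
    tc <- down_cross(rmp + (1 - x / 100) * apa)
    if (is.na(tc)) NA_real_ else tc - t0
  }
  apd90 <- apd_at(90)
  if (is.na(apd90)) return(na_row(TRUE, FALSE, rmp, apa))
  apd50 <- apd_at(50); apd20 <- apd_at(20)
  v20 <- approx(t, V, xout = t0 + 0.2 * apd90)$y

  tibble(apd20 = apd20, apd50 = apd50, apd90 = apd90, apa = apa, rmp = rmp,
         v20 = v20, t_takeoff = t0, excited = TRUE, repolarized = TRUE)
}

#' Rate-dependence ratios of APD
#'
#' Forms the rate-adaptation ratios `APD(f) / APD(1 Hz)` for APD50 and APD90
#' at 2, 3 and 4 Hz from a per-frequency biomarker table.
#'
#' @param bm_by_freq Tibble with a `frequency` column (Hz) and columns
#'   `apd50`, `apd90`; must contain 1 Hz plus at least one of 2/3/4 Hz.
#' @return One-row tibble with columns `apd50_ratio_2hz` ...
#'   `apd90_ratio_4hz` (only for the frequencies present).
#' @export
compute_rate_ratios <- function(bm_by_freq) {
  if (!all(c("frequency", "apd50", "apd90") %in% names(bm_by_freq)))
    abort("bm_by_freq needs columns frequency, apd50, apd90")
  ref <- dplyr::filter(bm_by_freq, .data$frequency == 1)
  if (nrow(ref) != 1) abort("exactly one 1 Hz row is required")
  if (!is.finite(ref$apd50) || !is.finite(ref$apd90) ||
      ref$apd50 <= 0 || ref$apd90 <= 0)
    abort("1 Hz APDs must be positive and finite")
  hi <- dplyr::filter(bm_by_freq, .data$frequency %in% c(2, 3, 4))
  if (!nrow(hi)) abort("at least one of 2, 3 or 4 Hz is required")
  out <- list()
  for (k in seq_len(nrow(hi))) {
    f <- hi$frequency[k]
    out[[paste0("apd50_ratio_", f, "hz")]] <- hi$apd50[k] / ref$apd50
    out[[paste0("apd90_ratio_", f, "hz")]] <- hi$apd90[k] / ref$apd90
  }
  as_tibble(out)
}

# multi-frequency phenotype of one parameter set: 1 Hz biomarkers plus rate
# ratios. Frequencies are paced in sequence (warm continuation), `beats`
# stimuli each; the element-wise median over the last `analyze_beats` beats
# is reported, which damps beat-to-beat alternans at fast rates.
phenotype_at_frequencies <- function(params, freqs = c(1, 2, 3, 4), beats = 30,
                                     dt = 0.02, amplitude = NULL,
                                     analyze_beats = 3) {
  amp <- amplitude %||% default_stim_amplitude(dt)
  state <- cell_steady_state(af_cell_params(), dt = dt)
  rows <- vector("list", length(freqs))
  nb <- min(analyze_beats, 3)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    pr <- pacing_protocol(f, beats = beats, amplitude = amp)
    tr <- simulate_cell(params, pr, dt = dt, init = state)
    state <- attr(tr, "final_state")
    cl <- 1000 / f
    per_beat <- dplyr::bind_rows(lapply(seq(beats - nb, beats - 1), function(b)
      compute_ap_biomarkers(tr, beat_window = c(b * cl, (b + 1) * cl))))
    bm <- dplyr::summarise(per_beat,
      dplyr::across(dplyr::where(is.numeric), ~ median(.x)),
      dplyr::across(dplyr::where(is.logical), ~ all(.x)))
    rows[[i]] <- dplyr::mutate(bm, frequency = f, .before = 1)
  }
  bm <- dplyr::bind_rows(rows)
  ratios <- if (all(bm$excited) && all(bm$repolarized) && 1 %in% freqs &&
                length(freqs) > 1) compute_rate_ratios(bm) else NULL
  list(biomarkers = bm, ratios = ratios)
}

#' Phenotype of the baseline chronic-AF model
#'
#' Simulates the unscaled remodeled model at the calibration frequencies and
#' returns its 1-Hz biomarkers and rate-dependence ratios as a single row.
#' Cached within a session.
#'
#' @param beats Stimuli per frequency (last beat analyzed).
#' @param dt Integration step (ms).
#' @param freqs Pacing frequencies (Hz).
#' @return One-row tibble of the 12 calibration quantities: `apd20`, `apd50`,
#'   `apd90`, `apa`, `rmp`, `v20` at 1 Hz and the APD50/APD90 ratios at
#'   2/3/4 Hz.
#' @export
baseline_phenotype <- function(beats = 30, dt = 0.02, freqs = c(1, 2, 3, 4)) {
  key <- param_key("base_phen", beats, dt, freqs)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  ph <- phenotype_at_frequencies(af_cell_params(), freqs, beats, dt)
  one <- dplyr::select(dplyr::filter(ph$biomarkers, .data$frequency == 1),
                       "apd20", "apd50", "apd90", "apa", "rmp", "v20")
  cache_set(key, dplyr::bind_cols(one, ph$ratios))
}
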