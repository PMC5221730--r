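# Stand-in generator for the unavailable patient recordings: biomarker
# acceptance envelopes with configurable center and spread, and synthetic AP
# traces whose true biomarkers are known in closed form.

#' Generate a biomarker acceptance envelope
#'
#' Builds per-biomarker `[min, max]` acceptance bounds around a center
#' phenotype: `center -+ spread * |center|`, optionally jittered with seeded
#' uniform noise on the half-widths. This emulates the experimental
#' physiologic envelope used for population calibration; measured ranges can
#' be substituted by editing the returned table (the calibration stage
#' consumes exactly this schema).
#'
#' Half-widths are `spread` times a per-biomarker scale. The scale is
#' `|center|`, floored at a quarter of the biomarker family's characteristic
#' magnitude (the APD90 center for duration biomarkers, the APA center for
#' potential biomarkers, 1 for dimensionless ratios): a purely
#' `|center|`-proportional window degenerates for biomarkers whose center
#' sits near zero on its natural scale (APD20, the plateau potential V20),
#' which would reject essentially every candidate. Set `scale_floor = 0` for
#' strictly proportional bounds.
#'
#' @param center One-row data frame (or named vector) of biomarker centers,
#'   e.g. [baseline_phenotype()].
#' @param spread Half-width as a fraction of the biomarker scale, in
#'   `(0, 1]`.
#' @param jitter Relative jitter applied to each half-width (0 = none).
#' @param seed Seed for the jitter; required when `jitter > 0`.
#' @param scale_floor Family-scale floor fraction (default 0.25).
#' @return A `biomarker_ranges` tibble with columns `biomarker`, `center`,
#'   `min`, `max`.
#' @export
generate_biomarker_ranges <- function(center, spread = 0.3, jitter = 0,
                                      seed = NULL, scale_floor = 0.25) {
  if (!is.numeric(spread) || length(spread) != 1 || spread <= 0 || spread > 1)
    abort("spread must be a single value in (0, 1]")
  if (is.data.frame(center)) {
    stopifnot(nrow(center) == 1)
    center <- unlist(center[1, vapply(center, is.numeric, logical(1))])
  }
  if (is.null(names(center))) abort("center must be named")
  dur <- grepl("^apd[0-9]+$", names(center))
  volt <- names(center) %in% c("apa", "rmp", "v20")
  fam <- rep(1, length(center)) # dimensionless ratios
  if (any(dur) && "apd90" %in% names(center))
    fam[dur] <- abs(center[["apd90"]])
  if (any(volt) && "apa" %in% names(center))
    fam[volt] <- abs(center[["apa"]])
  scale <- pmax(abs(center), scale_floor * fam)
  half <- spread * scale
  if (jitter > 0) {
    if (is.null(seed)) abort("a seed is required when jitter > 0")
    set.seed(seed)
    lo_j <- 1 + jitter * stats::runif(length(half), -1, 1)
    hi_j <- 1 + jitter * stats::runif(length(half), -1, 1)
  } else {
    lo_j <- hi_j <- rep(1, length(half))
  }
  out <- tibble(biomarker = names(center), center = unname(center),
                min = unname(center - half * lo_j),
                max = unname(center + half * hi_j))
  bad <- out$min >= out$max
  if (any(bad))
    abort(paste0("degenerate range (min >= max) for: ",
                 paste(out$biomarker[bad], collapse = ", ")))
  class(out) <- c("biomarker_ranges", class(out))
  out
}

#' Default calibration envelope
#'
#' Acceptance ranges centered on the baseline chronic-AF model phenotype.
#' The default spread of 0.3 stands in for the unpublished experimental
#' envelope; see `generate_biomarker_ranges()` to supply measured bounds.
#'
#' @inheritParams generate_biomarker_ranges
#' @inheritParams baseline_phenotype
#' @return A `biomarker_ranges` tibble.
#' @export
default_biomarker_ranges <- function(spread = 0.3, beats = 30, dt = 0.02) {
  generate_biomarker_ranges(baseline_phenotype(beats = beats, dt = dt),
                            spread = spread)
}

#' Generate a synthetic action potential with known biomarkers
#'
#' Produces an idealized AP trace whose true biomarkers follow in closed form
#' from the shape parameters, for exercising the biomarker extractor. The
#' trapezoid shape rests at `rmp`, rises to `peak` in one sample at
#' `pre_ms`, holds a plateau for `plateau_ms`, then falls linearly back over
#' `fall_ms`; its true APDx is `plateau_ms + fall_ms * x/100`. The
#' exponential shape holds the same plateau and then repolarizes as
#' `rmp + APA * exp(-t/tau_ms)`, so APDx is
#' `plateau_ms - tau_ms * log(1 - x/100)`.
#'
#' @param shape `"trapezoid"` or `"exponential"`.
#' @param rmp,peak Resting and peak voltage (mV).
#' @param plateau_ms,fall_ms Trapezoid plateau and linear-fall durations (ms).
#' @param tau_ms Exponential repolarization time constant (ms).
#' @param pre_ms,post_ms Rest padding before the upstroke / after the fall.
#' @param dt Sample interval (ms).
#' @param noise_sd Gaussian noise standard deviation (mV).
#' @param seed Seed used when `noise_sd > 0`; a fixed seed gives a
#'   bit-identical trace.
#' @return A `voltage_trace` tibble with attribute `"truth"`: the closed-form
#'   biomarker row.
#' @export
generate_synthetic_ap <- function(shape = c("trapezoid", "exponential"),
                                  rmp = -80, peak = 20, plateau_ms = 100,
                                  fall_ms = 200, tau_ms = 80, pre_ms = 50,
                                  post_ms = 100, dt = 0.1, noise_sd = 0,
                                  seed = NULL) {
  shape <- match.arg(shape)
  if (dt <= 0) abort("dt must be positive")
  apa <- peak - rmp
  if (apa <= 0) abort("peak must exceed rmp")
  # the instantaneous rise is placed midway between two samples
  # (pre_ms + dt/2), where the take-off estimator's segment-centre
  # convention recovers it without bias
  rise_at <- pre_ms + dt / 2
  if (shape == "trapezoid") {
    dur <- pre_ms + plateau_ms + fall_ms + post_ms
    t <- seq(0, dur, by = dt)
    tr <- t - rise_at # time from take-off
    V <- ifelse(tr < 0, rmp,
         ifelse(tr <= plateau_ms, peak,
         ifelse(tr <= plateau_ms + fall_ms,
                peak - apa * (tr - plateau_ms) / fall_ms, rmp)))
    apd90_true <- plateau_ms + 0.90 * fall_ms
    v20_t <- 0.2 * apd90_true
    truth <- tibble(apd20 = plateau_ms + 0.20 * fall_ms,
                    apd50 = plateau_ms + 0.50 * fall_ms,
                    apd90 = apd90_true, apa = apa, rmp = rmp,
                    v20 = if (v20_t <= plateau_ms) peak
                          else peak - apa * (v20_t - plateau_ms) / fall_ms)
  } else {
    # peak plateau followed by exponential repolarization
    apd90_true <- plateau_ms - tau_ms * log(1 - 0.9)
    dur <- pre_ms + apd90_true * 1.5 + post_ms
    t <- seq(0, dur, by = dt)
    tr <- t - rise_at
    V <- ifelse(tr < 0, rmp,
         ifelse(tr <= plateau_ms, peak,
                rmp + apa * exp(-(tr - plateau_ms) / tau_ms)))
    apd_of <- function(x) plateau_ms - tau_ms * log(1 - x / 100)
    v20_t <- 0.2 * apd90_true
    truth <- tibble(apd20 = apd_of(20), apd50 = apd_of(50),
                    apd90 = apd90_true, apa = apa, rmp = rmp,
                    v20 = if (v20_t <= plateau_ms) peak else
                      rmp + apa * exp(-(v20_t - plateau_ms) / tau_ms))
  }
  if (noise_sd > 0) {
    if (is.null(seed)) abort("a seed is required when noise_sd > 0")
    set.seed(seed)
    V <- V + stats::rnorm(length(V), 0, noise_sd)
  }
  out <- tibble(time = t, V = V)
  attr(out, "stim_times") <- pre_ms
  attr(out, "sample_dt") <- dt
  attr(out, "truth") <- truth
  class(out) <- c("voltage_trace", class(out))
  out
}
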