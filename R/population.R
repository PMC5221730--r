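#' Latin hypercube sample of conductance scale vectors
#'
#' Draws `n` scale vectors by Latin hypercube sampling: for each of the
#' `dims` conductances, exactly one sample falls in each of the `n`
#' equal-width strata of `[lo, hi]`. The default range 0 to 3 spans -100% to
#' +200% of the nominal conductance.
#'
#' @param n Number of candidate models (the full study uses 16384; desk-scale
#'   runs use a few hundred).
#' @param dims Number of sampled conductances.
#' @param lo,hi Scale-factor range.
#' @param seed Integer seed; the sample is reproducible given the seed.
#' @param names Column names, by default [conductance_names()].
#' @return Tibble with `model_id` and one column per conductance.
#' @export
latin_hypercube_sample <- function(n, dims = 11, lo = 0, hi = 3, seed = NULL,
                                   names = conductance_names()) {
  if (n < 1) abort("n must be at least 1")
  if (length(names) != dims) abort("`names` must have length `dims`")
  if (!is.null(seed)) set.seed(seed)
  m <- lhs::randomLHS(n, dims)
  m <- lo + (hi - lo) * m
  colnames(m) <- names
  dplyr::bind_cols(tibble(model_id = seq_len(n)), as_tibble(m))
}

#' Evaluate the multi-frequency phenotype of one candidate
#'
#' Applies a scale vector to the baseline AF model, paces it at the
#' calibration frequencies and extracts the calibration quantities. Solver
#' failures and non-excitable candidates are recorded as flags, never raised.
#'
#' @param scale Named (or ordered length-11) numeric scale vector.
#' @param freqs Pacing frequencies in Hz.
#' @param beats Stimuli per frequency; the last beat is analyzed.
#' @param dt Integration step (ms).
#' @return One-row tibble: the 12 calibration quantities plus `excited`,
#'   `repolarized` and `failure` (NA, `"not_excited"`,
#'   `"repolarization_failure"` or `"solver_failure"`).
#' @export
evaluate_candidate <- function(scale, freqs = c(1, 2, 3, 4), beats = 30,
                               dt = 0.02) {
  params <- af_cell_params(scale = scale)
  quantities <- c("apd20", "apd50", "apd90", "apa", "rmp", "v20",
                  paste0("apd50_ratio_", c(2, 3, 4), "hz"),
                  paste0("apd90_ratio_", c(2, 3, 4), "hz"))
  empty <- as_tibble(setNames(as.list(rep(NA_real_, length(quantities))),
                              quantities))
  ph <- tryCatch(phenotype_at_frequencies(params, freqs, beats, dt),
                 error = function(e) NULL)
  if (is.null(ph))
    return(dplyr::mutate(empty, excited = FALSE, repolarized = FALSE,
                         failure = "solver_failure"))
  bm1 <- dplyr::filter(ph$biomarkers, .data$frequency == 1)
  if (!all(ph$biomarkers$excited))
    return(dplyr::mutate(empty, excited = FALSE, repolarized = FALSE,
                         failure = "not_excited"))
  if (!all(ph$biomarkers$repolarized) || is.null(ph$ratios))
    return(dplyr::mutate(empty, excited = TRUE, repolarized = FALSE,
                         failure = "repolarization_failure"))
  out <- dplyr::bind_cols(
    dplyr::select(bm1, "apd20", "apd50", "apd90", "apa", "rmp", "v20"),
    ph$ratios)
  miss <- setdiff(quantities, names(out))
  for (m in miss) out[[m]] <- NA_real_
  dplyr::mutate(out[, quantities], excited = TRUE, repolarized = TRUE,
                failure = NA_character_)
}

#' Evaluate every candidate of a sample
#'
#' @param samples Tibble from [latin_hypercube_sample()].
#' @param ... Passed to [evaluate_candidate()].
#' @param progress Print a dot every 25 candidates.
#' @return `samples` with the phenotype columns bound on.
#' @export
evaluate_population <- function(samples, ..., progress = FALSE) {
  sc_cols <- setdiff(names(samples), "model_id")
  rows <- purrr::map(seq_len(nrow(samples)), function(i) {
    if (progress && i %% 25 == 0) cat(".")
    s <- unlist(samples[i, sc_cols])
    evaluate_candidate(s, ...)
  })
  if (progress) cat("\n")
  dplyr::bind_cols(samples, dplyr::bind_rows(rows))
}

#' Calibrate a population against a biomarker envelope
#'
#' Flags each candidate as accepted when every calibration quantity lies
#' inside its acceptance range (and the candidate excited and repolarized at
#' all frequencies); the first violated biomarker is recorded as the
#' rejection reason.
#'
#' @param table Tibble from [evaluate_population()].
#' @param ranges A `biomarker_ranges` table ([generate_biomarker_ranges()]).
#' @return An `af_population` tibble: `table` plus `accepted` and
#'   `rejection_reason`, with the envelope attached as attribute `"ranges"`.
#' @export
calibrate_population <- function(table, ranges) {
  if (!all(c("biomarker", "min", "max") %in% names(ranges)))
    abort("ranges must have columns biomarker, min, max")
  if (any(ranges$min >= ranges$max))
    abort("invalid envelope: min must be below max for every biomarker")
  missing_q <- setdiff(ranges$biomarker, names(table))
  if (length(missing_q))
    abort(paste0("table lacks biomarker column(s): ",
                 paste(missing_q, collapse = ", ")))
  lo <- setNames(ranges$min, ranges$biomarker)
  hi <- setNames(ranges$max, ranges$biomarker)
  reason <- rep(NA_character_, nrow(table))
  ok <- rep(TRUE, nrow(table))
  if ("failure" %in% names(table)) {
    f <- !is.na(table$failure)
    ok[f] <- FALSE
    reason[f] <- table$failure[f]
  }
  for (q in ranges$biomarker) {
    v <- table[[q]]
    out_of_range <- ok & (!is.finite(v) | v < lo[q] | v > hi[q])
    reason[out_of_range] <- q
    ok[out_of_range] <- FALSE
  }
  out <- dplyr::mutate(table, accepted = ok, rejection_reason = reason)
  attr(out, "ranges") <- ranges
  class(out) <- c("af_population", class(out))
  out
}

#' @export
print.af_population <- function(x, ...) {
  cat(sprintf("<af_population> %d candidates, %d accepted (%.1f%%)\n",
              nrow(x), sum(x$accepted), 100 * mean(x$accepted)))
  NextMethod()
}

#' @importFrom generics glance
#' @export
glance.af_population <- function(x, ...) {
  tibble(n_candidates = nrow(x), n_accepted = sum(x$accepted),
         acceptance_rate = mean(x$accepted),
         n_not_excited = sum(x$rejection_reason %in% "not_excited"),
         n_solver_failure = sum(x$rejection_reason %in% "solver_failure"))
}
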