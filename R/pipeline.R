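#' Configure an in-silico reentry experiment
#'
#' Bundles every knob of the two experiments (reentry maintenance across the
#' calibrated population; L-type calcium block on the sustained models) into
#' one reproducible configuration. The `"desk"` preset runs a 2D sheet at
#' sizes chosen for a single workstation; `"study"` mirrors the full-scale
#' protocol (16384 candidates, multi-second spherical simulations) and is
#' intended for cluster hardware.
#'
#' @param n_candidates Latin-hypercube candidates to draw and calibrate.
#' @param seed Integer seed controlling sampling (and therefore the whole
#'   pipeline; all downstream solvers are deterministic).
#' @param spread Calibration envelope half-width (fraction of the baseline
#'   phenotype).
#' @param max_models Cap on the number of accepted models carried into
#'   tissue simulation (problem-size control; `Inf` = all accepted).
#' @param mesh_kind,sheet_cm,dx,sphere_radius,subdivisions Mesh preset.
#' @param D Diffusion coefficient (cm^2/ms).
#' @param dt Tissue integration step (ms). The desk default (0.04) trades a
#'   small, population-uniform integration bias for runtime; use 0.02-0.025
#'   for convergence studies.
#' @param frame_dt Voltage frame interval (ms).
#' @param basal_ms Basal observation window (ms); sustained/unsustained
#'   classification and basal DF/RM use `[0, basal_ms]`.
#' @param obs_ms Post-intervention observation window (ms). The full-scale
#'   protocol observes 7 s under block.
#' @param beats Stimuli per frequency during calibration.
#' @param cell_dt Single-cell integration step (ms).
#' @param freqs Calibration pacing frequencies (Hz).
#' @param block_target,block_factor The intervention (default: 50% gCaL
#'   block).
#' @param init_window_ms Phase-seed beat window (ms).
#' @return An `af_config` list.
#' @export
experiment_config <- function(n_candidates = 1024, seed = 101, spread = 0.3,
                              max_models = 22,
                              mesh_kind = c("sheet", "sphere"),
                              sheet_cm = 2.5, dx = 0.05, sphere_radius = 2.5,
                              subdivisions = 5, D = 1.2e-3, dt = 0.04,
                              frame_dt = 2, basal_ms = 1200, obs_ms = 1200,
                              beats = 16, cell_dt = 0.025,
                              freqs = c(1, 2, 3, 4),
                              block_target = "gCaL", block_factor = 0.5,
                              init_window_ms = 300) {
  mesh_kind <- match.arg(mesh_kind)
  structure(list(n_candidates = n_candidates, seed = seed, spread = spread,
                 max_models = max_models, mesh_kind = mesh_kind,
                 sheet_cm = sheet_cm, dx = dx, sphere_radius = sphere_radius,
                 subdivisions = subdivisions, D = D, dt = dt,
                 frame_dt = frame_dt, basal_ms = basal_ms, obs_ms = obs_ms, beats = beats,
                 cell_dt = cell_dt, freqs = freqs,
                 block_target = block_target, block_factor = block_factor,
                 init_window_ms = init_window_ms),
            class = "af_config")
}

#' Full-scale configuration preset
#'
#' The study-scale protocol: 16384 candidates, spherical tissue, 7-s
#' observation under block. Cluster-scale; not intended for a single
#' workstation.
#'
#' @param seed Integer seed.
#' @return An `af_config`.
#' @export
study_config <- function(seed = 101) {
  experiment_config(n_candidates = 16384, seed = seed, max_models = Inf,
                    mesh_kind = "sphere", subdivisions = 6, dt = 0.02,
                    frame_dt = 1, beats = 30, cell_dt = 0.02,
                    basal_ms = 7000, obs_ms = 7000)
}

config_mesh <- function(cfg) {
  if (cfg$mesh_kind == "sheet")
    build_mesh("sheet", size = cfg$sheet_cm, dx = cfg$dx)
  else
    build_mesh("sphere", radius = cfg$sphere_radius,
               subdivisions = cfg$subdivisions)
}

#' Run the reentry-maintenance experiment
#'
#' End-to-end first experiment: sample candidates, calibrate against the
#' biomarker envelope, simulate functional reentry once per accepted model
#' (the basal window plus the continuation window that later serves as the
#' no-intervention reference), analyze rotor dynamics, and relate the
#' sampled conductances to reentry maintenance (group comparison) and to
#' DF/RM among sustained models (partial correlations).
#'
#' @param cfg An [experiment_config()].
#' @param ranges Optional calibration envelope; defaults to
#'   [default_biomarker_ranges()] at `cfg$spread`.
#' @param progress Print progress marks.
#' @return An `af_maintenance` object: list with `population`, `reentry`
#'   (per-model conductances + reentry biomarkers), `comparison`
#'   (sustained vs unsustained), `pcr_df`, `pcr_rm`, `r2_df_rm`, `config`,
#'   and per-model branch states for the block experiment.
#' @export
run_maintenance_experiment <- function(cfg = experiment_config(),
                                       ranges = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "af_config"))
  if (is.null(ranges))
    ranges <- default_biomarker_ranges(spread = cfg$spread, beats = cfg$beats,
                                       dt = cfg$cell_dt)
  samples <- latin_hypercube_sample(cfg$n_candidates, seed = cfg$seed)
  evaluated <- evaluate_population(samples, freqs = cfg$freqs,
                                   beats = cfg$beats, dt = cfg$cell_dt,
                                   progress = progress)
  pop <- calibrate_population(evaluated, ranges)
  acc <- dplyr::filter(pop, .data$accepted)
  if (!nrow(acc)) abort("calibration accepted no models; nothing to simulate")
  if (nrow(acc) > cfg$max_models) acc <- acc[seq_len(cfg$max_models), ]
  mesh <- config_mesh(cfg)
  total <- cfg$basal_ms + cfg$obs_ms
  rows <- vector("list", nrow(acc))
  snapshots <- vector("list", nrow(acc))
  cont_rows <- vector("list", nrow(acc))
  for (i in seq_len(nrow(acc))) {
    if (progress) cat("model", acc$model_id[i], "\n")
    sc <- unlist(acc[i, conductance_names()])
    params <- af_cell_params(scale = sc)
    init <- initiate_reentry(mesh, params, "phase_seed",
                             window_ms = cfg$init_window_ms)
    mv <- run_tissue(mesh, params, init, duration = total, D = cfg$D,
                     dt = cfg$dt, frame_dt = cfg$frame_dt,
                     snapshot_t = cfg$basal_ms)
    basal <- reentry_biomarkers(windowed_movie(mv, 0, cfg$basal_ms))
    cont <- if (basal$sustained)
      reentry_biomarkers(windowed_movie(mv, cfg$basal_ms, total))
    else dplyr::mutate(basal, df = NA_real_, rm = NA_real_)
    rows[[i]] <- dplyr::bind_cols(tibble(model_id = acc$model_id[i]),
                                  as_tibble(as.list(sc)), basal)
    cont_rows[[i]] <- dplyr::mutate(cont, model_id = acc$model_id[i],
                                    .before = 1)
    snapshots[[i]] <- mv$snapshot
  }
  reentry <- dplyr::bind_rows(rows)
  continuation <- dplyr::bind_rows(cont_rows)
  names(snapshots) <- reentry$model_id
  comparison <- NULL
  if (any(reentry$sustained) && any(!reentry$sustained))
    comparison <- build_group_comparison(reentry, "sustained")
  sust <- dplyr::filter(reentry, .data$sustained)
  pcr_df <- pcr_rm <- NULL
  if (nrow(sust) >= 13 && sd(sust$df, na.rm = TRUE) > 0) {
    pcr_df <- partial_correlation(sust, "df")
    pcr_rm <- partial_correlation(sust, "rm")
  }
  r2 <- if (nrow(sust) >= 3) signed_r2(sust$df, sust$rm) else NA_real_
  structure(list(population = pop, reentry = reentry,
                 continuation = continuation, comparison = comparison,
                 pcr_df = pcr_df, pcr_rm = pcr_rm, r2_df_rm = r2,
                 snapshots = snapshots, mesh = mesh, config = cfg,
                 ranges = ranges),
            class = "af_maintenance")
}

# view of a movie restricted to a time window (frames are shared, not copied
# lazily; fine at desk scale)
windowed_movie <- function(movie, from, to) {
  keep <- movie$time >= from & movie$time <= to
  out <- movie
  out$V <- movie$V[, keep, drop = FALSE]
  out$time <- movie$time[keep] - from
  out
}

#' Run the calcium-block experiment
#'
#' Applies the configured conductance block (by default a 50% reduction of
#' gCaL) to every model that sustained reentry at baseline, restarting
#' bit-exactly from the end of the basal window. Changes in DF and RM are
#' measured against the matched no-block continuation over the same
#' observation window, and block-induced termination is related to the
#' sampled conductances.
#'
#' @param baseline An `af_maintenance` result.
#' @param block_factor Remaining gCaL fraction; defaults to the configured
#'   value (0.5). `1` is the null intervention.
#' @param progress Print progress marks.
#' @return An `af_block` result: list with `effects` (per-model `d_df`,
#'   `d_rm`, `terminated`), `comparison` (terminated vs persisting),
#'   `pcr_d_df`, `pcr_d_rm`, `r2_d_df_d_rm`, `config`.
#' @export
run_ical_block_experiment <- function(baseline, block_factor = NULL,
                                      progress = FALSE) {
  stopifnot(inherits(baseline, "af_maintenance"))
  cfg <- baseline$config
  if (is.null(block_factor)) block_factor <- cfg$block_factor
  sust <- dplyr::filter(baseline$reentry, .data$sustained)
  if (!nrow(sust)) abort("no sustained baseline models to block")
  blk <- block_spec(cfg$block_target, block_factor, onset = 0)
  rows <- vector("list", nrow(sust))
  for (i in seq_len(nrow(sust))) {
    mid <- as.character(sust$model_id[i])
    if (progress) cat("block model", mid, "\n")
    sc <- unlist(sust[i, conductance_names()])
    params <- af_cell_params(scale = sc)
    mv <- run_tissue(baseline$mesh, params, baseline$snapshots[[mid]],
                     duration = cfg$obs_ms, D = cfg$D, dt = cfg$dt,
                     frame_dt = cfg$frame_dt, block = blk)
    rb <- reentry_biomarkers(mv)
    ref <- dplyr::filter(baseline$continuation,
                         .data$model_id == sust$model_id[i])
    rows[[i]] <- dplyr::bind_cols(
      tibble(model_id = sust$model_id[i]), as_tibble(as.list(sc)),
      tibble(df_block = rb$df, rm_block = rb$rm,
             d_df = rb$df - ref$df, d_rm = rb$rm - ref$rm,
             terminated = !rb$sustained,
             t_term = rb$t_term, mechanism = rb$mechanism,
             sustained_ref = ref$sustained))
  }
  effects <- dplyr::bind_rows(rows)
  comparison <- NULL
  if (any(effects$terminated) && any(!effects$terminated))
    comparison <- build_group_comparison(effects, "terminated")
  still <- dplyr::filter(effects, !.data$terminated)
  pcr_d_df <- pcr_d_rm <- NULL
  if (nrow(still) >= 13 && sd(still$d_rm, na.rm = TRUE) > 0) {
    pcr_d_df <- partial_correlation(still, "d_df")
    pcr_d_rm <- partial_correlation(still, "d_rm")
  }
  r2 <- if (nrow(still) >= 3) signed_r2(still$d_df, still$d_rm) else NA_real_
  structure(list(effects = effects, comparison = comparison,
                 pcr_d_df = pcr_d_df, pcr_d_rm = pcr_d_rm,
                 r2_d_df_d_rm = r2, block_factor = block_factor,
                 config = cfg),
            class = "af_block_result")
}

#' @export
print.af_maintenance <- function(x, ...) {
  cat(sprintf("<af_maintenance> %d/%d candidates calibrated; %d simulated; %d sustained (%.0f%%)\n",
              sum(x$population$accepted), nrow(x$population),
              nrow(x$reentry), sum(x$reentry$sustained),
              100 * mean(x$reentry$sustained)))
  invisible(x)
}

#' @export
print.af_block_result <- function(x, ...) {
  cat(sprintf("<af_block_result> %s x %.2f: %d/%d terminated (%.0f%%)\n",
              x$config$block_target, x$block_factor,
              sum(x$effects$terminated), nrow(x$effects),
              100 * mean(x$effects$terminated)))
  invisible(x)
}
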