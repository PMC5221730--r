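#' Specify a conductance block intervention
#'
#' @param target Conductance name (e.g. `"gCaL"` for L-type calcium block).
#' @param factor Remaining fraction of the conductance in `[0, 1]` (0.5 =
#'   50% block).
#' @param onset Time (ms) from which the block applies.
#' @return An `af_block` list.
#' @export
block_spec <- function(target = "gCaL", factor = 0.5, onset = 0) {
  if (!target %in% names(crn_nominal()))
    abort(paste0("unknown block target: ", target))
  if (!is.numeric(factor) || factor < 0 || factor > 1)
    abort("block factor must lie in [0, 1]")
  structure(list(target = target, factor = factor, onset = onset),
            class = "af_block")
}

#' Run a monodomain tissue simulation
#'
#' Integrates the monodomain reaction-diffusion system on a mesh with
#' homogeneous membrane kinetics: Godunov operator splitting at a shared
#' fixed step (reaction via the cell model, then diffusion through the mesh
#' Laplacian). Deterministic: identical inputs give bit-identical movies.
#'
#' @param mesh An [build_mesh()] mesh.
#' @param params A `cell_params` object applied at every node.
#' @param init Initial state: an `n x 21` or `21 x n` matrix (e.g. from
#'   [initiate_reentry()]), or a single length-21 state recycled to all
#'   nodes.
#' @param duration Simulated time in ms.
#' @param D Diffusion coefficient in cm^2/ms.
#' @param dt Shared reaction/diffusion step in ms.
#' @param frame_dt Voltage frame output interval in ms.
#' @param stims Optional list of stimuli, each
#'   `list(nodes =, start =, dur =, amp =)` with node indices and pA/pF
#'   amplitude.
#' @param block Optional [block_spec()] applied from its onset.
#' @param snapshot_t Optional time at which the full state is additionally
#'   recorded (attribute `"snapshot"`), so a run can be branched bit-exactly.
#' @return A `voltage_movie`: list with `V` (nodes x frames, mV), `time`
#'   (ms), `mesh`, `frame_dt`, `final_state`, `interventions` (log of the
#'   applied block, if any) and optionally `snapshot`.
#' @export
run_tissue <- function(mesh, params, init, duration, D = 1.2e-3, dt = 0.025,
                       frame_dt = 1, stims = list(), block = NULL,
                       snapshot_t = -1) {
  stopifnot(inherits(mesh, "af_mesh"), inherits(params, "cell_params"))
  n <- nrow(mesh$points)
  if (is.null(dim(init))) init <- matrix(init, 21, n)
  if (nrow(init) == n && ncol(init) == 21L && n != 21L) init <- t(init)
  if (nrow(init) != 21L || ncol(init) != n)
    abort("init must be 21 state variables by n mesh nodes")
  # explicit-diffusion stability (CFL-type): dt * D * max|L_ii| < 1
  cfl <- dt * D * max(abs(Matrix::diag(mesh$L)))
  if (cfl >= 1)
    abort(sprintf("unstable diffusion step: dt * D * max|L_ii| = %.2f >= 1", cfl))
  if (mesh$spacing > 0.06 && D > 0)
    warn(sprintf("mesh spacing %.3f cm is coarse for wavefront propagation",
                 mesh$spacing))
  Lc <- methods::as(mesh$L, "CsparseMatrix")
  bi <- -1L; bf <- 1; bo <- 0
  if (!is.null(block)) {
    stopifnot(inherits(block, "af_block"))
    bi <- match(block$target, names(crn_nominal())) - 1L
    bf <- block$factor; bo <- block$onset
  }
  r <- crn_tissue_run(param_vector(params), init, Lc@p, Lc@i, Lc@x, D, dt,
                      duration, frame_dt, stims, bi, bf, bo, snapshot_t)
  interventions <- NULL
  if (!is.null(block))
    interventions <- tibble(target = block$target, factor = block$factor,
                            onset = block$onset, applied = r$block_applied)
  out <- list(V = r$V, time = r$time, mesh = mesh, frame_dt = frame_dt,
              final_state = r$final_state, interventions = interventions,
              D = D, dt = dt)
  if (snapshot_t >= 0) out$snapshot <- r$snapshot
  structure(out, class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  cat(sprintf("<voltage_movie> %d nodes x %d frames (%.0f ms at %.1f ms/frame, %s mesh)\n",
              nrow(x$V), ncol(x$V), max(x$time), x$frame_dt, x$mesh$kind))
  if (!is.null(x$interventions)) {
    iv <- x$interventions
    cat(sprintf("  block: %s x %.2f from %.0f ms (applied: %s)\n",
                iv$target, iv$factor, iv$onset, iv$applied))
  }
  invisible(x)
}

#' Build an initial state that triggers functional reentry
#'
#' Two initiation methods are provided. `"phase_seed"` distributes the
#' states of one paced beat around the mesh center so that activation phase
#' advances by one full cycle per turn (a one-armed spiral seed on sheets;
#' an azimuthal winding with two opposite poles on spheres). `"cross_field"`
#' runs a classic S1-S2 protocol (planar wave, then a quadrant stimulus
#' timed to the vulnerable window) and returns the resulting state field.
#'
#' @param mesh An `af_mesh`.
#' @param params A `cell_params` object.
#' @param method `"phase_seed"` or `"cross_field"`.
#' @param window_ms Length of the beat-state window wrapped around the
#'   circle (phase seed).
#' @param center Rotation center in cm; defaults to the mesh centroid.
#' @param D,dt Conduction settings used by the S1-S2 run (cross-field only).
#' @param s2_delay_ms S2 timing offset added to the single-cell APD90
#'   (cross-field only).
#' @return A `21 x n` state matrix.
#' @export
initiate_reentry <- function(mesh, params, method = c("phase_seed", "cross_field"),
                             window_ms = 300, center = NULL, D = 1.2e-3,
                             dt = 0.025, s2_delay_ms = 15) {
  method <- match.arg(method)
  if (method == "phase_seed")
    phase_seed_state(mesh, params, window_ms, center)
  else
    cross_field_state(mesh, params, D, dt, s2_delay_ms)
}

# one paced-beat state trajectory sampled at 1 ms, from the upstroke
beat_state_trajectory <- function(params, window_ms, dt = 0.02) {
  key <- param_key("beat_traj", param_vector(params), window_ms, dt)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  pr <- pacing_protocol(1, beats = 4)
  tr <- simulate_cell(params, pr, dt = dt, sample_dt = 1, keep_states = TRUE)
  st <- attr(tr, "states") # 21 x samples at 1 ms
  i0 <- 3001L # onset of the 4th beat (t = 3000 ms)
  idx <- i0 + seq(0, window_ms - 1)
  idx[idx > ncol(st)] <- ncol(st)
  cache_set(key, st[, idx, drop = FALSE])
}

phase_seed_state <- function(mesh, params, window_ms, center) {
  traj <- beat_state_trajectory(params, window_ms)
  p <- mesh$points
  if (mesh$kind == "sphere") {
    theta <- atan2(p[, 2], p[, 1])
  } else {
    if (is.null(center)) center <- c(mean(range(p[, 1])), mean(range(p[, 2])))
    theta <- atan2(p[, 2] - center[2], p[, 1] - center[1])
  }
  frac <- (theta + pi) / (2 * pi) # in [0, 1)
  k <- pmin(1L + as.integer(floor(frac * window_ms)), ncol(traj))
  traj[, k, drop = FALSE]
}

cross_field_state <- function(mesh, params, D, dt, s2_delay_ms) {
  if (mesh$kind != "sheet") abort("cross-field initiation requires a sheet mesh")
  bm <- compute_ap_biomarkers(simulate_cell(params, pacing_protocol(1, beats = 3)),
                              beat_window = c(2000, 3000))
  if (!isTRUE(bm$excited)) abort("initiation failed: tissue is not excitable")
  p <- mesh$points
  xr <- range(p[, 1]); yr <- range(p[, 2])
  s1 <- which(p[, 1] <= xr[1] + 2.5 * mesh$spacing)
  s2 <- which(p[, 1] <= mean(xr) & p[, 2] <= mean(yr))
  t2 <- 5 + bm$apd90 + s2_delay_ms
  amp <- 2 * default_stim_amplitude()
  mv <- run_tissue(mesh, params,
                   init = unname(cell_steady_state(params)),
                   duration = t2 + 30, D = D, dt = dt, frame_dt = 5,
                   stims = list(list(nodes = s1, start = 5, dur = 2, amp = amp),
                                list(nodes = s2, start = t2, dur = 2, amp = amp)))
  st <- mv$final_state
  dimnames(st) <- NULL
  st
}

#' Measure planar conduction velocity on a strip
#'
#' Paces one end of a 1D strip and reports the conduction velocity between
#' 25% and 75% of its length from -40 mV upstroke crossing times (linearly
#' interpolated between frames).
#'
#' @param params A `cell_params` object.
#' @param D Diffusion coefficient (cm^2/ms).
#' @param dx Node spacing (cm).
#' @param length_cm Strip length (cm).
#' @param dt Integration step (ms).
#' @return Conduction velocity in cm/s (`NA` if the wave fails to traverse).
#' @export
measure_cv <- function(params = af_cell_params(), D = 1.2e-3, dx = 0.05,
                       length_cm = 2, dt = 0.025) {
  mesh <- build_mesh("strip", size = length_cm, dx = dx)
  n <- nrow(mesh$points)
  stim <- list(nodes = seq_len(max(3L, round(0.05 / dx))), start = 2, dur = 2,
               amp = 2 * default_stim_amplitude())
  mv <- run_tissue(mesh, params, init = unname(cell_steady_state(params)),
                   duration = 20 + length_cm / 0.02, D = D, dt = dt,
                   frame_dt = 0.25, stims = list(stim))
  act <- activation_times(mv$V, mv$time, threshold = -40)
  x <- mesh$points[, 1]
  i1 <- which.min(abs(x - 0.25 * length_cm))
  i2 <- which.min(abs(x - 0.75 * length_cm))
  if (!is.finite(act[i1]) || !is.finite(act[i2]) || act[i2] <= act[i1])
    return(NA_real_)
  1000 * (x[i2] - x[i1]) / (act[i2] - act[i1])
}

activation_times <- function(V, time, threshold = -40) {
  n <- nrow(V)
  out <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    above <- which(V[j, ] >= threshold)
    if (!length(above) || above[1] == 1L) next
    i2 <- above[1]; i1 <- i2 - 1L
    out[j] <- time[i1] + (threshold - V[j, i1]) / (V[j, i2] - V[j, i1]) *
      (time[i2] - time[i1])
  }
  out
}
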