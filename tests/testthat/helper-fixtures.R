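# lazily computed, session-memoized fixtures shared across test files
.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# baseline paced trace at 1 Hz (3 beats), 0.5 ms sampling
fx_baseline_trace <- function() fx("baseline_trace", function()
  simulate_cell(af_cell_params(), pacing_protocol(1, beats = 3)))

# small evaluated candidate table for calibration-property tests
fx_evaluated <- function() fx("evaluated", function() {
  s <- latin_hypercube_sample(32, seed = 11)
  evaluate_population(s)
})

# full desk-scale trend experiment shared between the acceptance checks;
# sized so the suite stays within a workstation run
fx_experiment <- function() fx("experiment", function() {
  cfg <- experiment_config(seed = 101)
  base <- run_maintenance_experiment(cfg)
  blk <- run_ical_block_experiment(base)
  list(base = base, blk = blk)
})

# brute-force winding-number integrator: independent oracle for
# phase-singularity detection (loops over faces, accumulates the argument of
# the unit phasor rotation along the boundary)
oracle_winding <- function(phase_frame, mesh) {
  f <- mesh$faces
  k <- ncol(f)
  out <- integer(nrow(f))
  for (t in seq_len(nrow(f))) {
    tot <- 0
    for (s in seq_len(k)) {
      a <- f[t, s]; b <- f[t, if (s == k) 1L else s + 1L]
      tot <- tot + Arg(exp(1i * (phase_frame[b] - phase_frame[a])))
    }
    out[t] <- as.integer(round(tot / (2 * pi)))
  }
  out
}

# random smooth phase field on a grid mesh from a few Fourier modes
random_smooth_phase <- function(mesh, seed) {
  set.seed(seed)
  p <- mesh$points
  z <- 0
  for (k in 1:4) {
    kx <- stats::runif(1, -3, 3); ky <- stats::runif(1, -3, 3)
    amp <- stats::runif(1, 0.3, 1); phs <- stats::runif(1, 0, 2 * pi)
    z <- z + amp * exp(1i * (kx * p[, 1] + ky * p[, 2] + phs))
  }
  Arg(z)
}

# independent oracle: exact two-sided Mann-Whitney p by full enumeration of
# the C(n1 + n2, n1) group assignments
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

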