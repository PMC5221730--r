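#' Names of the sampled maximal conductances
#'
#' The eleven ionic parameters that are scaled to build the population:
#' fast sodium (gNa), L-type calcium (gCaL), transient outward (gto),
#' ultrarapid delayed rectifier (gKur), rapid and slow delayed rectifiers
#' (gKr, gKs), inward rectifier (gK1), the Na/K pump and Na/Ca exchanger
#' maxima (INaK_max, INaCa_max), the SERCA uptake maximum (Iup_max) and the
#' sarcolemmal Ca pump maximum (IpCa_max). The set is configurable wherever a
#' scale vector is accepted; this is the package default.
#'
#' @return Character vector of length 11.
#' @export
conductance_names <- function() {
  c("gNa", "gCaL", "gto", "gKur", "gKr", "gKs", "gK1",
    "INaK_max", "INaCa_max", "Iup_max", "IpCa_max")
}

# full parameter vector handed to the compiled kernel; order is a contract
# with src/crn_kernel.cpp. gKur is a multiplier on the voltage-dependent
# conductance expression (nominal 1).
crn_nominal <- function() {
  c(gNa = 7.8, gCaL = 0.12375, gto = 0.1652, gKur = 1.0,
    gKr = 0.029411765, gKs = 0.12941176, gK1 = 0.09,
    INaK_max = 0.59933874, INaCa_max = 1600, Iup_max = 0.005,
    IpCa_max = 0.275, gbNa = 0.0006744375, gbCa = 0.001131, Krel = 30)
}

# chronic-AF electrical remodeling of the baseline atrial model:
# ICaL -70%, Ito -50%, IKur -50%, IK1 +100%
af_remodeling_factors <- function() {
  c(gCaL = 0.3, gto = 0.5, gKur = 0.5, gK1 = 2.0)
}

#' Construct a remodeled human atrial cell parameter set
#'
#' Builds the parameter vector of the human atrial membrane model
#' (Courtemanche-Ramirez-Nattel formulation) with chronic-AF electrical
#' remodeling applied by default, optionally rescaled by a conductance scale
#' vector. Scaling is multiplicative on the remodeled values, so
#' `scale = 1` reproduces the baseline AF model exactly.
#'
#' @param scale Optional named numeric vector of multipliers in `[0, 3]` for a
#'   subset of [conductance_names()] (or any of the model maxima).
#' @param remodeling `"chronic_af"` (default) applies the AF remodeling
#'   factors; `"none"` gives the original, non-remodeled model.
#' @return An object of class `cell_params`.
#' @examples
#' p <- af_cell_params()
#' p_block <- af_cell_params(scale = c(gCaL = 0.5))
#' @export
af_cell_params <- function(scale = NULL, remodeling = c("chronic_af", "none")) {
  remodeling <- match.arg(remodeling)
  g <- crn_nominal()
  if (remodeling == "chronic_af") {
    f <- af_remodeling_factors()
    g[names(f)] <- g[names(f)] * f
  }
  out <- structure(list(g = g, remodeling = remodeling,
                        scale = setNames(rep(1, 11), conductance_names())),
                   class = "cell_params")
  if (!is.null(scale)) out <- scale_conductances(out, scale)
  out
}

#' Apply a conductance scale vector to a parameter set
#'
#' Multiplies the targeted maximal conductances of `base` elementwise by
#' `scale`; every other parameter is left untouched and `base` itself is not
#' modified. A scale of all ones is the identity.
#'
#' @param base A `cell_params` object.
#' @param scale Named numeric vector of multipliers in `[0, 3]`, names drawn
#'   from the model parameters (by default the eleven sampled conductances),
#'   or an unnamed length-11 vector taken in [conductance_names()] order.
#' @return A new `cell_params` object.
#' @export
scale_conductances <- function(base, scale) {
  stopifnot(inherits(base, "cell_params"))
  if (is.null(names(scale))) {
    if (length(scale) != 11L)
      abort("unnamed scale vectors must have length 11 (one per sampled conductance)")
    names(scale) <- conductance_names()
  }
  unknown <- setdiff(names(scale), names(base$g))
  if (length(unknown))
    abort(paste0("unknown conductance name(s): ", paste(unknown, collapse = ", ")))
  if (any(!is.finite(scale)) || any(scale < 0))
    abort("scale factors must be finite and non-negative")
  if (any(scale > 3))
    abort("scale factors must lie in [0, 3] (-100% to +200% of nominal)")
  out <- base
  out$g[names(scale)] <- out$g[names(scale)] * scale
  keep <- intersect(names(scale), names(out$scale))
  out$scale[keep] <- out$scale[keep] * scale[keep]
  out
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> human atrial membrane model (",
      if (x$remodeling == "chronic_af") "chronic-AF remodeled" else "non-remodeled",
      ")\n", sep = "")
  scaled <- x$scale[x$scale != 1]
  if (length(scaled)) {
    cat("  scaled conductances:\n")
    for (nm in names(scaled)) cat(sprintf("    %-10s x %.3f\n", nm, scaled[nm]))
  } else cat("  all sampled conductances at baseline (scale = 1)\n")
  invisible(x)
}

# numeric vector for the kernel
param_vector <- function(params) {
  stopifnot(inherits(params, "cell_params"))
  unname(params$g)
}

# published initial conditions of the membrane model (resting, 1 Hz history)
crn_initial_state <- function() {
  c(V = -81.18, m = 0.002908, h = 0.9649, j = 0.9775,
    oa = 0.03043, oi = 0.9992, ua = 0.004966, ui = 0.9986,
    xr = 3.296e-5, xs = 0.01869, d = 1.367e-4, f = 0.9996, fca = 0.7755,
    u = 0, v = 1, w = 0.9992,
    Nai = 11.17, Ki = 139.0, Cai = 1.013e-4, Caup = 1.488, Carel = 1.488)
}

state_names <- function() names(crn_initial_state())

validate_state <- function(state) {
  if (length(state) != 21L) abort("cell state must have 21 entries")
  if (any(!is.finite(state))) {
    bad <- state_names()[which(!is.finite(state))[1]]
    abort(paste0("non-finite state variable: ", bad))
  }
  gates <- state[2:16]
  if (any(gates < 0 | gates > 1)) {
    bad <- state_names()[1 + which(gates < 0 | gates > 1)[1]]
    abort(paste0("gating variable outside [0, 1]: ", bad))
  }
  conc <- state[17:21]
  if (any(conc <= 0)) {
    bad <- state_names()[16 + which(conc <= 0)[1]]
    abort(paste0("non-positive ionic concentration: ", bad))
  }
  invisible(state)
}

#' Time derivative of the cell state
#'
#' Evaluates the right-hand side of the membrane model at a given state: a
#' deterministic, pure function of `(state, params, stim)`. Used for
#' steady-state diagnostics and numerical checks; the simulators use the same
#' current formulation internally.
#'
#' @param state Numeric length-21 state vector (`V` in mV, gates in `[0,1]`,
#'   concentrations in mM).
#' @param params A `cell_params` object.
#' @param stim Stimulus current density in pA/pF (positive depolarizes).
#' @return Named numeric vector `d(state)/dt` (mV/ms, 1/ms, mM/ms).
#' @export
cell_derivatives <- function(state, params = af_cell_params(), stim = 0) {
  validate_state(state)
  d <- crn_derivatives(param_vector(params), as.numeric(state), stim)
  setNames(d, state_names())
}

#' Quiescent steady state of a parameter set
#'
#' Relaxes the model without stimulation from the published initial
#' conditions and returns the final state. Results are cached per parameter
#' set within a session.
#'
#' @param params A `cell_params` object.
#' @param relax_ms Relaxation horizon in ms (default 60 s).
#' @param dt Integration step in ms.
#' @return Named numeric state vector.
#' @export
cell_steady_state <- function(params = af_cell_params(), relax_ms = 60000,
                              dt = 0.02) {
  key <- param_key("ss", param_vector(params), relax_ms, dt)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  r <- crn_cell_run(param_vector(params), unname(crn_initial_state()), dt,
                    relax_ms, numeric(0), 2, 0, relax_ms, FALSE)
  cache_set(key, setNames(r$final_state, state_names()))
}
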