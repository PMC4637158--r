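# Membrane kinetics behind a uniform interface: the Bondarenko et al. (2004)
# mouse ventricular model and a two-variable excitable surrogate.
#
# Both models expose: n_states, V_rest (mV), init_state (eta0), and are
# integrated by the explicit-Euler kernels in src/. Currents are
# per-capacitance (pA/pF), so reaction dynamics are dV/dt = -I_ion + I_stim
# in mV/ms.

#' Membrane kinetics models
#'
#' `bondarenko_model()` is a port of the Bondarenko et al. (2004) mouse left
#' ventricular (apex) action potential model: 15 transmembrane currents, with
#' the fast Na+ channel, the L-type Ca2+ channel, the rapid delayed rectifier
#' and the ryanodine receptor represented as Markov chains, plus full
#' intracellular Ca2+ handling. All 44 chain/gate/concentration states are
#' integrated explicitly (41 are independent; the published formulation eliminates
#' one state per chain), so each Markov chain conserves occupancy to rounding
#' error. The frozen initial state is the model's own quiescent steady state
#' (5 s of stimulus-free integration at `dt = 1e-4` ms).
#'
#' `surrogate_model()` is a lightweight two-variable excitable model
#' (Mitchell--Schaeffer form mapped onto the physiological voltage range)
#' used for fast solver tests and large Monte-Carlo ensembles. Its
#' parameters are fixed so that upstroke, action-potential duration and
#' tissue conduction velocity are on the murine scale of the Bondarenko
#' tissue model.
#'
#' @param stim_default,stim_default_micro Stimulus amplitudes (pA/pF) used
#'   by protocol presets for discrete (whole-cell) and microscopic
#'   (2-volume edge band) runs; frozen at twice the respective diastolic
#'   plane-stimulus thresholds, found once by bisection on a homogeneous
#'   template strip (the microscopic band drives far less membrane per
#'   stimulated element, hence the larger value).
#' @return Object of class `ionic_model`.
#' @examples
#' m <- surrogate_model()
#' s <- cell_state(m)
#' s <- reaction_step(m, s, I_stim = 0, dt_o = 0.01)
#' @name ionic_models
NULL

.new_ionic_model <- function(name, model_id, n_states, V_rest, init_state,
                             state_names, pars, stim_default,
                             stim_default_micro, dt_o_default,
                             quiescence_tol) {
  structure(list(name = name, model_id = model_id,
                 n_states = as.integer(n_states),
                 V_rest = V_rest, init_state = init_state,
                 state_names = state_names, pars = pars,
                 stim_default = stim_default,
                 stim_default_micro = stim_default_micro,
                 dt_o_default = dt_o_default,
                 quiescence_tol = quiescence_tol),
            class = "ionic_model")
}

#' @rdname ionic_models
#' @export
bondarenko_model <- function(stim_default = .bdk_stim_default,
                             stim_default_micro = .bdk_stim_default_micro) {
  .new_ionic_model(
    name = "bondarenko2004-apex",
    model_id = 2L,
    n_states = .bdk_n_states(),
    V_rest = .bdk_rest_V,
    init_state = .bdk_rest_state,
    state_names = .bdk_state_names(),
    pars = numeric(0),
    stim_default = stim_default,
    stim_default_micro = stim_default_micro,
    dt_o_default = 1e-4,
    quiescence_tol = 0.01)
}

#' @rdname ionic_models
#' @export
surrogate_model <- function(stim_default = .sur_stim_default,
                            stim_default_micro = .sur_stim_default_micro) {
  pars <- c(tau_in = 0.32, tau_out = 6, tau_open = 30, tau_close = 9,
            u_gate = 0.13, V_rest = -82, V_amp = 120)
  .new_ionic_model(
    name = "surrogate2v",
    model_id = 1L,
    n_states = 1L,
    V_rest = -82,
    init_state = c(h = 1),
    state_names = "h",
    pars = pars,
    stim_default = stim_default,
    stim_default_micro = stim_default_micro,
    dt_o_default = 0.01,
    quiescence_tol = 1e-9)
}

#' Cell state of an ionic model
#'
#' @param model An [ionic_model][ionic_models].
#' @param V Initial transmembrane voltage (mV), default the model's rest.
#' @return Object of class `cell_state`: list with `V` (mV) and `eta` (the
#'   model's state vector).
#' @export
cell_state <- function(model, V = model$V_rest) {
  structure(list(V = V, eta = model$init_state), class = "cell_state")
}

# dispatch to the compiled stepper; V and eta are modified in place, so pass
# fresh copies
.ionic_step <- function(model, V, eta, stim, n_sub, dt) {
  if (model$model_id == 1L) {
    .surrogate_step(V, eta, stim, n_sub, dt, model$pars)
  } else {
    .bdk_step(V, eta, stim, n_sub, dt)
  }
  invisible(NULL)
}

#' One explicit-Euler reaction step
#'
#' Advances a single-cell state by one explicit-Euler step of the reaction
#' (ODE) stage: `dV/dt = -I_ion(V, eta) + I_stim`, `d eta/dt = f(V, eta)`.
#'
#' @param model An [ionic_model][ionic_models].
#' @param state A [cell_state()].
#' @param I_stim Stimulus current, per-capacitance (pA/pF).
#' @param dt_o Reaction time step in ms (default `1e-4` for the Bondarenko
#'   model, chosen for explicit-Euler stability).
#' @return The advanced `cell_state`.
#' @export
reaction_step <- function(model, state, I_stim = 0,
                          dt_o = model$dt_o_default) {
  integrate_reaction(model, state, I_stim, N_o = 1L, dt_o = dt_o)
}

#' Integrate the reaction stage over N_o substeps
#'
#' `N_o` successive [reaction_step()]s, spanning `N_o * dt_o` ms (one
#' diffusion step of the operator-split scheme).
#'
#' @inheritParams reaction_step
#' @param N_o Number of substeps (>= 1).
#' @return The advanced `cell_state`.
#' @export
integrate_reaction <- function(model, state, I_stim = 0, N_o = 1L,
                               dt_o = model$dt_o_default) {
  stopifnot(inherits(model, "ionic_model"), inherits(state, "cell_state"))
  if (dt_o <= 0) stop("dt_o must be positive", call. = FALSE)
  N_o <- as.integer(N_o)
  if (N_o < 1L) stop("N_o must be >= 1", call. = FALSE)
  V <- state$V + 0 # fresh allocation: the kernel updates V in place
  eta <- matrix(as.numeric(state$eta), ncol = 1L)
  .ionic_step(model, V, eta, as.numeric(I_stim), N_o, dt_o)
  structure(list(V = V, eta = stats::setNames(eta[, 1L], model$state_names)),
            class = "cell_state")
}

#' Single-cell pulse protocol
#'
#' Integrates one cell with rectangular stimulus pulses and records
#' `(t, V)` (plus selected states) at `record_dt` resolution. Used for
#' threshold finding, calibration and the single-cell CLI.
#'
#' @param model An [ionic_model][ionic_models].
#' @param T_end End time, ms.
#' @param pulses data.frame with columns `start`, `duration`, `amplitude`
#'   (ms, ms, pA/pF); default a single 2 ms pulse at `model$stim_default`.
#' @param dt_o Reaction step, ms.
#' @param record_dt Recording interval, ms.
#' @param record_states Names of states to record alongside V.
#' @return data.frame with columns `t`, `V`, and any recorded states.
#' @export
simulate_cell <- function(model, T_end = 100,
                          pulses = data.frame(start = 1, duration = 2,
                                              amplitude = model$stim_default),
                          dt_o = model$dt_o_default,
                          record_dt = 0.1,
                          record_states = character(0)) {
  stopifnot(inherits(model, "ionic_model"))
  n_rec <- floor(T_end / record_dt)
  n_sub <- max(1L, as.integer(round(record_dt / dt_o)))
  dt <- record_dt / n_sub
  V <- model$V_rest + 0 # fresh allocation: updated in place by the kernel
  eta <- matrix(as.numeric(model$init_state), ncol = 1L)
  sidx <- match(record_states, model$state_names)
  if (anyNA(sidx)) stop("unknown state name", call. = FALSE)
  out <- matrix(NA_real_, n_rec + 1L, 2L + length(sidx))
  out[1L, ] <- c(0, V, eta[sidx, 1L])
  t <- 0
  for (k in seq_len(n_rec)) {
    # stimulus constant within a recording interval
    amp <- 0
    if (nrow(pulses))
      for (p in seq_len(nrow(pulses)))
        if (t >= pulses$start[p] &&
            t < pulses$start[p] + pulses$duration[p])
          amp <- amp + pulses$amplitude[p]
    .ionic_step(model, V, eta, amp, n_sub, dt)
    t <- k * record_dt
    out[k + 1L, ] <- c(t, V, eta[sidx, 1L])
  }
  out <- as.data.frame(out)
  names(out) <- c("t", "V", record_states)
  out
}

#' Diastolic threshold of a 2 ms stimulus pulse
#'
#' Bisects the minimal pulse amplitude (pA/pF) that elicits an action
#' potential (V crossing 0 mV) in a single resting cell.
#'
#' @param model An [ionic_model][ionic_models].
#' @param duration Pulse duration, ms.
#' @param lo,hi Initial bracket, pA/pF.
#' @param tol Bisection tolerance, pA/pF.
#' @return Threshold amplitude, pA/pF.
#' @export
find_threshold <- function(model, duration = 2, lo = 0, hi = 80, tol = 0.25) {
  fires <- function(amp) {
    tr <- simulate_cell(model, T_end = 20,
                        pulses = data.frame(start = 1, duration = duration,
                                            amplitude = amp),
                        record_dt = 0.5)
    any(tr$V > 0)
  }
  if (!fires(hi)) stop("upper bracket does not elicit an AP", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' @export
print.ionic_model <- function(x, ...) {
  cat("ionic_model '", x$name, "': ", x$n_states,
      " state variables, V_rest = ", signif(x$V_rest, 6), " mV\n", sep = "")
  cat("  default stimulus ", signif(x$stim_default, 4),
      " pA/pF, reaction step ", x$dt_o_default, " ms\n", sep = "")
  invisible(x)
}

#' @export
print.cell_state <- function(x, ...) {
  cat("cell_state: V =", signif(x$V, 6), "mV,", length(x$eta),
      "state variables\n")
  invisible(x)
}
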