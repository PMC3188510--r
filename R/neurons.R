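# Exponential integrate-and-fire membrane dynamics.

#' Spike-initiation nonlinearity
#'
#' The exponential term `Psi(V) = slope * exp((V - v_thresh) / slope)` that
#' drives the finite-time divergence of the membrane potential identified
#' with a spike.  `slope` (mV) sets how sharp spike initiation is and
#' `v_thresh` the voltage around which it occurs.
#'
#' @param v membrane potential, mV.
#' @param v_thresh threshold potential, mV.
#' @param slope slope factor, mV (> 0).
#' @return mV.
#' @export
spike_nonlinearity <- function(v, v_thresh, slope) {
  stopifnot(slope > 0)
  slope * exp((v - v_thresh) / slope)
}

#' Default neuron state at a given potential
#'
#' Effective parameters start at their baselines; the post-spike offsets of
#' [post_spike_update()] relax back toward these values.
#'
#' @param params a neuron parameter list (see [default_spec()]`$neurons`).
#' @param v initial membrane potential, mV.
#' @return a `neuron_state` list.
#' @export
neuron_state <- function(params, v = params$e_leak) {
  structure(list(
    v = v,
    inv_tau_m = 1 / params$tau_m,
    v_thresh = params$v_thresh,
    slope = params$slope,
    time_since_spike = Inf,
    refractory_until = -Inf), class = "neuron_state")
}

#' Membrane equation right-hand side
#'
#' `dV/dt = (1/tau_m) (E_L - V + Psi(V)) + I_syn / C`, evaluated with the
#' state's instantaneous effective parameters.
#'
#' @param state a `neuron_state`.
#' @param i_syn total synaptic current, nA.
#' @param params neuron parameters.
#' @return mV/ms.
#' @export
membrane_rhs <- function(state, i_syn, params) {
  state$inv_tau_m *
    (params$e_leak - state$v +
       spike_nonlinearity(state$v, state$v_thresh, state$slope)) +
    i_syn / params$capacitance
}

#' Sub-threshold resting potential
#'
#' The lower (stable) root of `E_L - V + Psi(V) = 0`.  With the reference
#' parameters the exponential term is negligible at `E_L`, so the rest point
#' sits within microvolts of the leak potential.
#'
#' @param params neuron parameters.
#' @param tol root tolerance, mV.
#' @return mV.
#' @export
resting_potential <- function(params, tol = 1e-9) {
  f <- function(v) params$e_leak - v +
    spike_nonlinearity(v, params$v_thresh, params$slope)
  lo <- params$e_leak - 20
  # the unstable root sits below v_thresh; bracket the stable one from below
  hi <- params$v_thresh
  # find a sign change: f(lo) < 0 would mean no sub-threshold fixed point
  if (f(lo) <= 0) stop("no stable sub-threshold fixed point", call. = FALSE)
  while (f(hi) > 0) {
    hi <- hi - 0.5
    if (hi < lo) stop("no stable sub-threshold fixed point", call. = FALSE)
  }
  uniroot(f, c(lo, hi), tol = tol)$root
}

#' Post-spike state update
#'
#' Soft mode (excitatory): the potential is reset and the effective
#' threshold, slope factor and inverse time constant acquire additive
#' offsets (two components for the threshold) that decay exponentially back
#' to baseline with their own time constants.  Offsets from successive
#' spikes accumulate on top of any remaining offset, so rapid firing builds
#' up spike-frequency adaptation that self-limits runaway excitation.  Hard
#' mode (inhibitory): the potential is reset and integration is suspended
#' for the refractory period.
#'
#' @param state a `neuron_state`.
#' @param params neuron parameters.
#' @param refractory refractory parameter list (see [default_spec()]).
#' @param spike_time spike time, ms.
#' @return the updated `neuron_state`.
#' @export
post_spike_update <- function(state, params, refractory, spike_time) {
  state$v <- params$v_reset
  state$time_since_spike <- 0
  if (refractory$mode == "soft") {
    state$v_thresh <- state$v_thresh + sum(refractory$v_thresh$amplitude)
    state$slope <- state$slope + refractory$slope$amplitude
    state$inv_tau_m <- state$inv_tau_m + refractory$inv_tau_m$amplitude
  } else {
    state$refractory_until <- spike_time + refractory$refractory_period
  }
  state
}

#' Relax effective parameters over an interval
#'
#' Closed-form exponential decay of the post-spike offsets over `dt` ms.
#'
#' @param state a `neuron_state`.
#' @param params neuron parameters.
#' @param refractory soft refractory parameters.
#' @param dt elapsed time, ms.
#' @return the relaxed `neuron_state`.
#' @export
relax_effective_params <- function(state, params, refractory, dt) {
  if (refractory$mode != "soft") return(state)
  o_vt <- (state$v_thresh - params$v_thresh)
  # split proportionally across the two stored components is not needed at
  # the state level used here; the simulator core tracks components
  # separately.  For single-component use, decay with the slowest constant.
  amps <- refractory$v_thresh$amplitude
  taus <- refractory$v_thresh$tau
  if (is.finite(state$time_since_spike)) {
    t1 <- state$time_since_spike + dt
    state$v_thresh <- params$v_thresh + sum(amps * exp(-t1 / taus))
    state$slope <- params$slope +
      refractory$slope$amplitude * exp(-t1 / refractory$slope$tau)
    state$inv_tau_m <- 1 / params$tau_m +
      refractory$inv_tau_m$amplitude * exp(-t1 / refractory$inv_tau_m$tau)
    state$time_since_spike <- t1
  } else {
    state$v_thresh <- params$v_thresh + o_vt * exp(-dt / max(taus))
  }
  state
}

#' Analytic time to divergence at the integration cutoff
#'
#' Once the potential reaches the cutoff the exponential term dominates and
#' the remaining trajectory integrates in closed form:
#' `t_div = tau_m * exp(-(V - v_thresh) / slope)`.  The precondition (the
#' nonlinearity exceeding ten times the leak term) is checked.
#'
#' @param v_now current membrane potential, mV (at or above the cutoff).
#' @param params neuron parameters.
#' @param check enforce the dominance precondition (default TRUE).
#' @return remaining time to the spike, ms.
#' @export
time_to_divergence <- function(v_now, params, check = TRUE) {
  if (check) {
    leak <- abs(params$e_leak - v_now)
    if (any(spike_nonlinearity(v_now, params$v_thresh, params$slope) <
              10 * leak))
      stop("potential not in the divergence-dominated region", call. = FALSE)
  }
  params$tau_m * exp(-(v_now - params$v_thresh) / params$slope)
}

# ---- single-neuron reference integrator ----------------------------------

#' One classical Runge-Kutta step
#'
#' Fourth-order step for `dy/dt = f(t, y)`; used by the single-neuron
#' reference integrator and exposed for convergence testing.
#'
#' @param f function of `(t, y)`.
#' @param t,y current time and state.
#' @param h step size.
#' @return the state at `t + h`.
#' @export
rk4_step <- function(f, t, y, h) {
  k1 <- f(t, y)
  k2 <- f(t + h / 2, y + h / 2 * k1)
  k3 <- f(t + h / 2, y + h / 2 * k2)
  k4 <- f(t + h, y + h * k3)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Integrate a single neuron under a prescribed current
#'
#' Fixed-step RK4 with cutoff-and-extrapolate spike handling, for one
#' isolated neuron driven by an arbitrary current waveform.  Serves as a
#' slow, transparent reference for the network core and for PSP
#' calibration.
#'
#' @param params neuron parameters.
#' @param current function of time (ms) returning nA, or a constant.
#' @param duration total time, ms.
#' @param dt step, ms.
#' @param refractory optional refractory parameters; `NULL` disables the
#'   post-spike parameter dynamics (voltage is still reset).
#' @param v0 initial potential, mV.
#' @return list with `times`, `v` (trace, reset-valued after spikes) and
#'   `spikes` (precise spike times, ms).
#' @export
integrate_single_neuron <- function(params, current, duration, dt = 0.2,
                                    refractory = NULL, v0 = params$e_leak) {
  ifun <- if (is.function(current)) current else function(t) current
  n <- ceiling(duration / dt)
  times <- (0:n) * dt
  v <- numeric(n + 1)
  v[1] <- v0
  spikes <- numeric(0)
  # effective parameter offsets
  off <- c(vt1 = 0, vt2 = 0, dl = 0, itm = 0)
  soft <- !is.null(refractory) && refractory$mode == "soft"
  rhs <- function(t, y, o) {
    vt <- params$v_thresh + o[1] + o[2]
    dl <- params$slope + o[3]
    itm <- 1 / params$tau_m + o[4]
    x <- min((y - vt) / dl, 30)
    itm * (params$e_leak - y + dl * exp(x)) + ifun(t) / params$capacitance
  }
  decay <- function(o, h) {
    if (!soft) return(o)
    taus <- c(refractory$v_thresh$tau, refractory$slope$tau,
              refractory$inv_tau_m$tau)
    o * exp(-h / taus)
  }
  for (k in seq_len(n)) {
    t <- times[k]
    y <- v[k]
    f <- function(tt, yy) rhs(tt, yy, decay(off, tt - t))
    yn <- rk4_step(f, t, y, dt)
    if (!is.finite(yn) || yn >= params$v_thresh + off[1] + off[2]) {
      # sub-step through the upswing; after a reset the remainder of the
      # step is still integrated so spike timing carries no step bias
      m <- 40L
      h <- dt / m
      yy <- y
      o_loc <- off
      for (s in seq_len(m)) {
        ts <- t + (s - 1) * h
        f <- function(tt, yv) rhs(tt, yv, decay(o_loc, tt - ts))
        yy2 <- rk4_step(f, ts, yy, h)
        o_loc <- decay(o_loc, h)
        vt <- params$v_thresh + o_loc[1] + o_loc[2]
        dl <- params$slope + o_loc[3]
        itm <- 1 / params$tau_m + o_loc[4]
        cut <- max(params$v_cut, vt + 10 * dl)
        if (!is.finite(yy2)) yy2 <- cut + 20 * dl
        if (yy2 >= cut) {
          t_sp <- ts + h + exp(-min((yy2 - vt) / dl, 60)) / itm
          spikes <- c(spikes, t_sp)
          yy2 <- params$v_reset
          if (soft) {
            o_loc <- o_loc + c(refractory$v_thresh$amplitude,
                               refractory$slope$amplitude,
                               refractory$inv_tau_m$amplitude)
          }
        }
        yy <- yy2
      }
      yn <- yy
      off <- o_loc
    } else {
      off <- decay(off, dt)
    }
    v[k + 1] <- yn
  }
  list(times = times, v = v, spikes = spikes)
}
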