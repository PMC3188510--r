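# Conductance-based synapses: peak-normalized difference-of-exponentials
# kernels realized as two exponential state variables.

#' Kernel peak time and normalization
#'
#' The unit-peak kernel is `N (exp(-t/tau_d) - exp(-t/tau_r))`; its maximum
#' sits at `t* = tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)` and `N`
#' is chosen so the value there is 1.
#'
#' @param tau_r,tau_d rise and decay times, ms (`tau_r < tau_d`).
#' @return `kernel_peak_time()`: ms; `kernel_norm()`: dimensionless.
#' @export
kernel_peak_time <- function(tau_r, tau_d) {
  stopifnot(tau_r > 0, tau_r < tau_d)
  tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}

#' @rdname kernel_peak_time
#' @export
kernel_norm <- function(tau_r, tau_d) {
  tp <- kernel_peak_time(tau_r, tau_d)
  1 / (exp(-tp / tau_d) - exp(-tp / tau_r))
}

#' Unit-peak synaptic kernel
#'
#' Zero before the arrival, then the peak-normalized difference of
#' exponentials.
#'
#' @param t time since arrival, ms (vectorized).
#' @param tau_r,tau_d rise and decay times, ms.
#' @return dimensionless activation in `[0, 1]`.
#' @export
kernel_value <- function(t, tau_r, tau_d) {
  if (tau_r >= tau_d) stop("requires tau_r < tau_d", call. = FALSE)
  n <- kernel_norm(tau_r, tau_d)
  ifelse(t < 0, 0, n * (exp(-t / tau_d) - exp(-t / tau_r)))
}

#' Synaptic current
#'
#' `I = g * s * (E_syn - V)`: depolarizing for excitatory classes
#' (reversal above rest) and hyperpolarizing for GABA.
#'
#' @param v membrane potential, mV.
#' @param class_params a synapse-class list (fields `g`, `e_rev`).
#' @param activation kernel activation `s >= 0`.
#' @return nA (g in nS, potentials in mV: nS * mV = pA, reported in nA).
#' @export
synaptic_current <- function(v, class_params, activation) {
  stopifnot(all(activation >= 0))
  class_params$g * activation * (class_params$e_rev - v) * 1e-3
}

#' Step the two-exponential synaptic state
#'
#' Exact exponential decay of the rise and decay components over `dt`;
#' queued arrivals whose time falls inside the step are applied at their
#' (sub-step-accurate) offset.  The reconstructed conductance
#' `g * (decay - rise)` reproduces the superposition of [kernel_value()]
#' kernels.
#'
#' @param state list with components `rise`, `decay` (values at the current
#'   time) and `queue` (data.frame `time`, `increment` of pending arrivals).
#' @param t current time, ms.
#' @param dt step, ms.
#' @param tau_r,tau_d kinetics, ms.
#' @return the state advanced to `t + dt`.
#' @export
step_synaptic_state <- function(state, t, dt, tau_r, tau_d) {
  stopifnot(dt > 0)
  due <- state$queue$time >= t & state$queue$time < t + dt
  ev <- state$queue[due, , drop = FALSE]
  r <- state$rise * exp(-dt / tau_r)
  d <- state$decay * exp(-dt / tau_d)
  if (nrow(ev)) {
    rem <- t + dt - ev$time
    r <- r + sum(ev$increment * exp(-rem / tau_r))
    d <- d + sum(ev$increment * exp(-rem / tau_d))
  }
  list(rise = r, decay = d, queue = state$queue[!due, , drop = FALSE])
}

#' Single-event postsynaptic potential amplitude
#'
#' Integrates one isolated neuron at rest through a single synaptic event
#' of the given class (unit kernel peak, peak conductance `g`) and returns
#' the absolute peak voltage deflection from rest - the calibration
#' quantity of the synaptic efficacy table.
#'
#' @param neuron neuron parameters (see [default_spec()]`$neurons`).
#' @param class_params synapse-class parameters.
#' @param dt integration step, ms.
#' @param horizon simulated time, ms (long enough to catch slow-decay peaks).
#' @return absolute peak deflection, mV.
#' @export
psp_peak <- function(neuron, class_params, dt = 0.02,
                     horizon = max(40, 6 * class_params$tau_d)) {
  if (class_params$g == 0) return(0)
  v_rest <- resting_potential(neuron)
  nrm <- kernel_norm(class_params$tau_r, class_params$tau_d)
  t_on <- 1
  current <- function(t, v) {
    s <- if (t < t_on) 0 else
      nrm * (exp(-(t - t_on) / class_params$tau_d) -
               exp(-(t - t_on) / class_params$tau_r))
    class_params$g * s * (class_params$e_rev - v) * 1e-3
  }
  # conductance-based drive depends on V: integrate the coupled equation
  n <- ceiling(horizon / dt)
  v <- v_rest
  peak <- 0
  f <- function(t, y) {
    (1 / neuron$tau_m) *
      (neuron$e_leak - y + spike_nonlinearity(y, neuron$v_thresh, neuron$slope)) +
      current(t, y) / neuron$capacitance
  }
  for (k in seq_len(n)) {
    v <- rk4_step(f, (k - 1) * dt, v, dt)
    peak <- max(peak, abs(v - v_rest))
  }
  peak
}

#' All reference PSP amplitudes of a spec
#'
#' @param spec a `network_spec`.
#' @return data.frame with class, target, simulated and reference PSP (mV).
#' @export
psp_table <- function(spec) {
  rows <- lapply(names(spec$synapses), function(nm) {
    sy <- spec$synapses[[nm]]
    if (is.na(sy$reference_psp)) return(NULL)
    data.frame(synapse = nm, class = sy$class, target = sy$target,
               psp = psp_peak(spec$neurons[[sy$target]], sy),
               reference_psp = sy$reference_psp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Calibrate the GABA reversal potential against the reference PSPs
#'
#' The inhibitory reversal is not fixed by the efficacy table; this routine
#' adjusts the single scalar `E_GABA` to minimize the squared error of the
#' two GABA reference PSP amplitudes and returns the fitted value along
#' with a spec carrying it.
#'
#' @param spec a `network_spec`.
#' @param interval search interval for `E_GABA`, mV.
#' @return list with `e_gaba` (fitted value, mV) and `spec` (updated).
#' @export
calibrate_gaba_reversal <- function(spec, interval = c(-90, -62)) {
  target <- function(eg) {
    s <- spec
    s$synapses$gaba_on_excitatory$e_rev <- eg
    s$synapses$gaba_on_inhibitory$e_rev <- eg
    err <- 0
    for (nm in c("gaba_on_excitatory", "gaba_on_inhibitory")) {
      sy <- s$synapses[[nm]]
      err <- err + (psp_peak(s$neurons[[sy$target]], sy) - sy$reference_psp)^2
    }
    err
  }
  opt <- optimize(target, interval)
  out <- spec
  out$synapses$gaba_on_excitatory$e_rev <- opt$minimum
  out$synapses$gaba_on_inhibitory$e_rev <- opt$minimum
  list(e_gaba = opt$minimum, spec = out)
}
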