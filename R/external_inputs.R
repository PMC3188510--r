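# Thalamic (LGN) contrast-tuned Poisson drive and shared-rate
# Ornstein-Uhlenbeck background input.

#' Stimulus description
#'
#' Constant-contrast stimuli (`mode = "constant"`) or the flashed-grating
#' square wave (`mode = "flash"`): 0.5 s at `contrast` followed by 1 s at
#' zero contrast, repeated; transitions are instantaneous.
#'
#' @param contrast contrast in `[0, 1]` (the `on` value for flashes).
#' @param orientation stimulus orientation, degrees.
#' @param mode `"constant"` or `"flash"`.
#' @param on_ms,off_ms flash on/off phase durations, ms.
#' @return a `stimulus` object.
#' @export
stimulus <- function(contrast, orientation = 0,
                     mode = c("constant", "flash"),
                     on_ms = 500, off_ms = 1000) {
  mode <- match.arg(mode)
  if (contrast < 0 || contrast > 1)
    stop("contrast must lie in [0, 1]", call. = FALSE)
  structure(list(contrast = contrast, orientation = orientation,
                 mode = mode, on_ms = on_ms, off_ms = off_ms),
            class = "stimulus")
}

#' Contrast waveform of a stimulus
#'
#' @param stim a [stimulus()].
#' @param t times, ms (negative times are pre-stimulus: zero contrast for
#'   flashed stimuli, the constant value otherwise).
#' @return contrast value(s) at `t`.
#' @export
contrast_waveform <- function(stim, t) {
  if (stim$mode == "constant") return(rep(stim$contrast, length(t)))
  period <- stim$on_ms + stim$off_ms
  phase <- t %% period
  ifelse(t >= 0 & phase < stim$on_ms, stim$contrast, 0)
}

#' Single LGN cell firing rate versus contrast
#'
#' The two-decade logarithmic contrast map of the classical thalamic-drive
#' parameterization this model builds on: the rate rises linearly in
#' log-contrast over `C` in `[0.01, 1]`, from the dark rate to the maximal
#' rate, `R(C) = R_dark + (R_max - R_dark) (2 + log10 C)/2`, clamped at
#' `R_dark` for contrasts below 1%.
#'
#' @param contrast contrast in `[0, 1]` (vectorized).
#' @param params LGN parameter list (see [default_spec()]`$lgn`).
#' @return firing rate, Hz.
#' @export
lgn_single_cell_rate <- function(contrast, params = .default_lgn()) {
  if (any(contrast < 0 | contrast > 1))
    stop("contrast must lie in [0, 1]", call. = FALSE)
  x <- pmax(0, (2 + log10(pmax(contrast, 1e-12))) / 2)
  params$single_cell_dark_rate +
    (params$single_cell_max_rate - params$single_cell_dark_rate) * x
}

#' Poisson rate of the LGN synapse of a cortical neuron
#'
#' The aggregate thalamic drive at ring coordinate `theta`:
#' an untuned offset plus a contrast- and orientation-tuned gain,
#' `nu(theta) = nu0 + nu1 * x(C) * A(theta - theta0)`, where
#' `x(C) = (R(C) - R_dark) / (R_max - R_dark)` is the normalized single-cell
#' contrast response and
#' `A(phi) = (1 - eps) + eps * [cos(2 phi)]_+` the tuning profile with
#' broadness `eps` (`eps = 1`: pure rectified cosine).  At zero contrast the
#' rate is the untuned dark drive.  The lower layer receives the rate scaled
#' by `lower_layer_attenuation`.
#'
#' @param theta neuron coordinate(s), degrees.
#' @param stim a [stimulus()] (its constant/on contrast is used).
#' @param params LGN parameter list.
#' @param layer `"upper"` or `"lower"`.
#' @param contrast optional contrast overriding the stimulus value.
#' @return rate, Hz.
#' @export
lgn_population_rate <- function(theta, stim, params = .default_lgn(),
                                layer = "upper", contrast = stim$contrast) {
  eps <- params$tuning_broadness
  x <- (lgn_single_cell_rate(contrast, params) - params$single_cell_dark_rate) /
    (params$single_cell_max_rate - params$single_cell_dark_rate)
  tuning <- (1 - eps) +
    eps * pmax(cos(2 * wrap_angle(theta - stim$orientation) * pi / 180), 0)
  rate <- params$rate_offset + params$rate_gain * x * tuning
  if (layer == "lower") rate <- rate * params$lower_layer_attenuation
  rate
}

#' Exact Ornstein-Uhlenbeck rate update
#'
#' Shared background rate with mean `mu`, stationary standard deviation
#' `sd` and correlation time `tau`, advanced by `dt` with the exact
#' discretization `R' = mu + (R - mu) e^(-dt/tau) + sd sqrt(1 - e^(-2dt/tau)) z`.
#' The latent state is Gaussian; rectification at zero happens only when
#' spikes are generated from it.
#'
#' @param rate current rate, Hz.
#' @param dt step, ms.
#' @param z standard-normal draw(s).
#' @param params background parameter list (`mean_rate`, `volatility`
#'   interpreted as stationary SD, `filter_time`).
#' @return updated rate, Hz.
#' @export
ou_rate_step <- function(rate, dt, z, params = .default_background()) {
  stopifnot(dt > 0)
  e <- exp(-dt / params$filter_time)
  params$mean_rate + (rate - params$mean_rate) * e +
    params$volatility * sqrt(1 - e^2) * z
}

#' Generate input spike times from a rate trace
#'
#' Per-step Poisson thinning of a (possibly time-varying) rate: the number
#' of events in each step is Poisson with mean `rate * dt`, placed
#' uniformly within the step.  Rates are rectified at zero.  A warning is
#' issued when `rate * dt` exceeds 0.2 events per step, where a Bernoulli
#' reading of the count would be inaccurate.
#'
#' @param rate_trace rate per step, Hz (recycled if scalar).
#' @param dt step, ms.
#' @param duration total time, ms (required if `rate_trace` is scalar).
#' @return event times, ms.
#' @export
generate_input_spikes <- function(rate_trace, dt, duration = NULL) {
  if (length(rate_trace) == 1) {
    if (is.null(duration)) stop("duration required for scalar rate")
    rate_trace <- rep(rate_trace, ceiling(duration / dt))
  }
  rate_trace <- pmax(rate_trace, 0)
  lambda <- rate_trace * dt * 1e-3
  if (any(lambda > 0.2))
    warning("rate * dt exceeds 0.2 events/step; consider a smaller step")
  counts <- rpois(length(lambda), lambda)
  idx <- rep(seq_along(counts), counts)
  sort((idx - 1) * dt + runif(length(idx)) * dt)
}
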