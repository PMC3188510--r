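# Network integration: fixed-step RK4 with latency-queued spike delivery,
# cutoff-and-extrapolate spike timing, recorders and paired-run protocols.

.channel_kinetics <- function(spec) {
  syn <- spec$synapses
  # channels: 1 recurrent AMPA, 2 NMDA, 3 GABA, 4 LGN (AMPA), 5 background
  # (AMPA); rows: excitatory / inhibitory target
  tr <- matrix(0, 2, 5); td <- matrix(0, 2, 5); er <- matrix(0, 2, 5)
  pops <- c("excitatory", "inhibitory")
  for (p in 1:2) {
    a <- syn[[paste0("ampa_on_", pops[p])]]
    nm <- syn[[paste0("nmda_on_", pops[p])]]
    gb <- syn[[paste0("gaba_on_", pops[p])]]
    tr[p, ] <- c(a$tau_r, nm$tau_r, gb$tau_r, a$tau_r, a$tau_r)
    td[p, ] <- c(a$tau_d, nm$tau_d, gb$tau_d, a$tau_d, a$tau_d)
    er[p, ] <- c(a$e_rev, nm$e_rev, gb$e_rev, a$e_rev, a$e_rev)
  }
  nrm <- matrix(mapply(function(r, d) kernel_norm(r, d), tr, td), 2, 5)
  list(tau_r = tr, tau_d = td, e_rev = er, norm = nrm)
}

.lfp_membership <- function(layout, sectors) {
  if (is.null(sectors) || nrow(sectors) == 0)
    return(list(off = 0L, idx = integer(0), sectors = sectors))
  idx <- integer(0); off <- 0L
  for (k in seq_len(nrow(sectors))) {
    sc <- sectors[k, ]
    layer <- if (!is.null(sc$layer)) sc$layer else "upper"
    members <- which(layout$layer == layer &
                       abs(wrap_angle(layout$theta - sc$center)) <= sc$width / 2)
    if (length(members) == 0)
      stop("empty LFP sector at center ", sc$center, call. = FALSE)
    idx <- c(idx, members - 1L)
    off <- c(off, length(idx))
  }
  list(off = as.integer(off), idx = as.integer(idx), sectors = sectors)
}

#' Simulate the hypercolumn
#'
#' Integrates the full network with the fixed-step fourth-order
#' Runge-Kutta scheme (default 0.2 ms step), analytic extrapolation of
#' spike times past the integration cutoff, latency-aligned delivery of
#' spikes, tuned LGN Poisson drive and shared-rate background noise.  The
#' run is deterministic given `(spec, net, stim, seed)`.  Initial membrane
#' potentials are drawn uniformly within 5 mV of the leak potential and a
#' warm-up period precedes the recorded window.
#'
#' @param spec a `network_spec`.
#' @param stim a [stimulus()].
#' @param duration recorded duration, ms.
#' @param seed integer seed (noise streams and initial conditions).
#' @param net optional prebuilt [build_network()] wiring (for fixed-wiring
#'   protocols); built from the spec otherwise.
#' @param warmup warm-up time, ms, simulated before recording starts.
#' @param record_v indices of neurons whose membrane potential is recorded.
#' @param v_stride_ms voltage sampling interval, ms.
#' @param lfp_sectors data.frame (`center`, `width`, optional `layer`) of
#'   LFP recording sites: per-site mean total synaptic input current.
#' @param comp_rate optional per-neuron Poisson compensation rate, Hz,
#'   delivered through a unit AMPA-kinetics synapse of conductance `comp_g`.
#' @param comp_g compensation synapse conductance, nS.
#' @param perturb optional `list(neuron =, spike =)`: suppress delivery of
#'   that neuron's k-th spike (the emitting neuron is still reset).
#' @param n_sub sub-steps used while a membrane is in the spike-initiation
#'   zone.
#' @return a `sim_result`: `spikes` (data.frame `neuron`, `time` in ms,
#'   warm-up spikes carry negative times), `v`/`v_times`/`v_neurons`,
#'   `lfp` (channels x samples, nA), `bg_rate`, `currents` (per-neuron mean
#'   absolute LGN/recurrent/background current, nA), `g_exc_mean`
#'   (per-neuron mean recurrent excitatory conductance, nS), `meta`.
#' @export
run_simulation <- function(spec, stim, duration, seed = spec$master_seed,
                           net = NULL, warmup = 500,
                           record_v = integer(0), v_stride_ms = 2,
                           lfp_sectors = NULL,
                           comp_rate = NULL, comp_g = 1,
                           perturb = NULL, n_sub = 20) {
  stopifnot(duration >= spec$dt)
  if (is.null(net)) net <- build_network(spec, seed = spec$master_seed)
  spec <- net$spec
  layout <- net$layout
  n <- nrow(layout)
  dt <- spec$dt

  exc <- as.integer(layout$pop == "excitatory")
  np_e <- spec$neurons$excitatory
  np_i <- spec$neurons$inhibitory
  pick <- function(field) ifelse(exc == 1L, np_e[[field]], np_i[[field]])
  kin <- .channel_kinetics(spec)

  # edges in CSR order by presynaptic index
  ord <- order(net$src)
  src <- net$src[ord]
  edge_off <- c(0L, cumsum(tabulate(src, nbins = n)))
  tpop_row <- ifelse(layout$pop[net$tgt[ord]] == "excitatory", 1L, 2L)
  fast_ch <- ifelse(net$fast_class[ord] == "AMPA", 0L, 2L)
  norm_fast <- kin$norm[cbind(tpop_row, fast_ch + 1L)]
  norm_nmda <- kin$norm[cbind(tpop_row, 2L)]
  lat <- net$latency[ord]
  delay_steps <- as.integer(round(lat / dt))
  if (any(abs(delay_steps * dt - lat) > 1e-9))
    warning("latencies rounded to the nearest integration step")

  rf <- spec$refractory$excitatory
  refr_steps <- as.integer(round(spec$refractory$inhibitory$refractory_period / dt))

  # external drives
  atten <- ifelse(layout$layer == "lower", spec$lgn$lower_layer_attenuation, 1)
  rate_on <- lgn_population_rate(layout$theta, stim, spec$lgn, "upper") * atten
  rate_off <- lgn_population_rate(layout$theta, stim, spec$lgn, "upper",
                                  contrast = 0) * atten
  norm_ampa <- kin$norm[cbind(ifelse(exc == 1L, 1L, 2L), 4L)]
  lgn_w <- spec$lgn$g_lgn * atten * norm_ampa
  bg_w <- spec$background$g_bg * norm_ampa
  has_comp <- !is.null(comp_rate)
  if (!has_comp) comp_rate <- numeric(n)
  comp_w <- comp_g * kin$norm[cbind(ifelse(exc == 1L, 1L, 2L), 1L)]

  n_warm <- as.integer(round(warmup / dt))
  n_rec <- as.integer(round(duration / dt))
  tsteps <- (seq_len(n_warm + n_rec) - 1L) * dt - n_warm * dt
  cstate <- as.integer(contrast_waveform(stim, tsteps) > 0)

  lfp_m <- .lfp_membership(layout, lfp_sectors)
  v_stride <- max(1L, as.integer(round(v_stride_ms / dt)))

  set.seed(seed)
  v_init <- runif(n, pick("e_leak") - 5, pick("e_leak") + 5)
  pn <- if (is.null(perturb)) -1L else as.integer(perturb$neuron - 1L)
  pk <- if (is.null(perturb)) -1L else as.integer(perturb$spike)

  res <- .sim_core(
    n, dt, n_warm, n_rec, exc,
    1 / pick("tau_m"), pick("capacitance") * 1e3,
    pick("e_leak"), pick("v_thresh"), pick("slope"),
    pick("v_reset"), pick("v_cut"),
    rf$v_thresh$amplitude[1], rf$v_thresh$tau[1],
    rf$v_thresh$amplitude[2], rf$v_thresh$tau[2],
    rf$slope$amplitude, rf$slope$tau,
    rf$inv_tau_m$amplitude, rf$inv_tau_m$tau,
    refr_steps,
    kin$tau_r, kin$tau_d, kin$e_rev,
    edge_off, as.integer(net$tgt[ord] - 1L),
    net$w_fast[ord] * norm_fast, net$w_nmda[ord] * norm_nmda,
    fast_ch, delay_steps,
    rate_on, rate_off, cstate, lgn_w, bg_w,
    comp_rate, comp_w, has_comp,
    spec$background$mean_rate, spec$background$volatility,
    spec$background$filter_time,
    v_init,
    as.integer(record_v - 1L), v_stride,
    lfp_m$off, lfp_m$idx,
    pn, pk, as.integer(n_sub))

  ns <- res$n_rec_steps
  structure(list(
    spikes = data.frame(neuron = as.integer(res$spike_id),
                        time = res$spike_t),
    n_spikes = res$n_spikes,
    v = res$v, v_times = res$v_times, v_neurons = as.integer(record_v),
    lfp = res$lfp * 1e-3, lfp_sectors = lfp_m$sectors,
    lfp_times = seq_len(ns) * dt,
    bg_rate = res$bg_rate,
    currents = list(lgn = res$acc_lgn / ns * 1e-3,
                    recurrent = res$acc_rec / ns * 1e-3,
                    background = res$acc_bg / ns * 1e-3),
    g_exc_mean = res$acc_gexc / ns,
    meta = list(spec = spec, stim = stim, seed = seed, dt = dt,
                duration = duration, warmup = warmup,
                wiring_checksum = wiring_checksum(net),
                n_neurons = n, layout = layout)),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %d neurons, %g ms recorded, %d spikes, seed %d\n",
    x$meta$n_neurons, x$meta$duration, nrow(x$spikes), x$meta$seed))
  invisible(x)
}

#' Deterministic checksum of a wiring realization
#'
#' @param net a `connectivity`.
#' @return integer checksum (stable across sessions).
#' @export
wiring_checksum <- function(net) {
  v <- c(net$src, net$tgt, round(net$w_fast * 1e6))
  as.integer(sum((v %% 7919) * (seq_along(v) %% 101)) %% 2147483647)
}

#' Repeated stimulus trials over fixed wiring
#'
#' Independent noise realizations (one per seed) over a single quenched
#' wiring draw; the protocol behind trial-averaged statistics such as the
#' PSTH.
#'
#' @param spec a `network_spec`.
#' @param stim a [stimulus()].
#' @param duration recorded duration per trial, ms.
#' @param seeds integer vector, one seed per trial.
#' @param ... passed to [run_simulation()].
#' @return list of `sim_result`.
#' @export
run_trials <- function(spec, stim, duration, seeds, ...) {
  if (length(seeds) < 1) stop("at least one trial required", call. = FALSE)
  net <- build_network(spec, seed = spec$master_seed)
  lapply(seeds, function(s)
    run_simulation(spec, stim, duration, seed = s, net = net, ...))
}

#' Single-spike perturbation experiment
#'
#' Runs the network twice with identical wiring and identical noise
#' realizations; in the perturbed run the indexed spike of the target
#' neuron is not delivered to any postsynaptic target, while the emitting
#' neuron's own post-spike reset still takes place.  The pair of runs is
#' bit-identical before the omitted spike.
#'
#' @param spec a `network_spec`.
#' @param stim a [stimulus()].
#' @param duration recorded duration, ms.
#' @param seed noise seed shared by both runs.
#' @param target_neuron index of the neuron whose spike is omitted.
#' @param target_spike which spike of that neuron (1-based, counted from
#'   the start of the warm-up).
#' @param ... passed to [run_simulation()].
#' @return list with `unperturbed` and `perturbed` `sim_result`s.
#' @export
perturb_single_spike <- function(spec, stim, duration, seed,
                                 target_neuron, target_spike = 1L, ...) {
  net <- build_network(spec, seed = spec$master_seed)
  ref <- run_simulation(spec, stim, duration, seed = seed, net = net, ...)
  if (ref$n_spikes[target_neuron] < target_spike)
    stop("target neuron emitted fewer spikes than requested", call. = FALSE)
  pert <- run_simulation(spec, stim, duration, seed = seed, net = net,
                         perturb = list(neuron = target_neuron,
                                        spike = target_spike), ...)
  list(unperturbed = ref, perturbed = pert)
}

#' Remove excitation of interneurons with compensated drive
#'
#' Tests the interneuron-gamma mechanism: all recurrent excitatory
#' synapses onto inhibitory neurons are removed and each interneuron
#' instead receives an independent Poisson drive through an AMPA-kinetics
#' synapse whose rate is calibrated, from an intact reference run, to
#' reproduce that neuron's time-averaged recurrent excitatory conductance.
#'
#' @param spec a `network_spec`.
#' @param stim a [stimulus()].
#' @param duration recorded duration, ms.
#' @param seed noise seed.
#' @param comp_g compensation synapse conductance, nS.
#' @param ... passed to [run_simulation()].
#' @return list with `intact` and `no_ei` `sim_result`s.
#' @export
run_ei_removed <- function(spec, stim, duration, seed, comp_g = 1, ...) {
  net <- build_network(spec, seed = spec$master_seed)
  intact <- run_simulation(spec, stim, duration, seed = seed, net = net, ...)
  layout <- net$layout
  is_i <- layout$pop == "inhibitory"
  # calibrate compensation rate from mean excitatory conductance (nS):
  # a Poisson stream of rate r through a unit-peak kernel of weight g and
  # area A contributes g * A * r to the mean conductance
  syn_i <- spec$synapses$ampa_on_inhibitory
  area <- kernel_norm(syn_i$tau_r, syn_i$tau_d) * (syn_i$tau_d - syn_i$tau_r)
  comp_rate <- numeric(nrow(layout))
  comp_rate[is_i] <- intact$g_exc_mean[is_i] / (comp_g * area) * 1e3
  # remove E -> I synapses
  net2 <- net
  cut <- layout$pop[net2$src] == "excitatory" &
    layout$pop[net2$tgt] == "inhibitory"
  net2$w_fast_base[cut] <- 0
  net2$w_nmda_base[cut] <- 0
  net2 <- apply_interlayer_scale(net2, spec$gamma)
  no_ei <- run_simulation(spec, stim, duration, seed = seed, net = net2,
                          comp_rate = comp_rate, comp_g = comp_g, ...)
  list(intact = intact, no_ei = no_ei)
}
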