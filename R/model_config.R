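#' @useDynLib hypercolumn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats integrate uniroot rnorm runif rpois sd var fft nextn
#'   coef nls median quantile approx optimize
#' @importFrom utils modifyList read.csv write.csv head tail
NULL

# ---- built-in parameter tables -------------------------------------------
# All values are the model's reference parameterization for a network of
# N_E = 4000 excitatory and N_I = 1000 inhibitory neurons per ring.

.default_neuron <- function(kind) {
  if (kind == "excitatory") {
    list(kind = "excitatory",
         tau_m = 23.30, capacitance = 0.26, e_leak = -57.8,
         v_thresh = -45.2, slope = 1.2,
         v_reset = -57.8, v_cut = -45.2 + 10 * 1.2)
  } else {
    list(kind = "inhibitory",
         tau_m = 11.65, capacitance = 0.13, e_leak = -57.8,
         v_thresh = -45.2, slope = 1.2,
         v_reset = -57.8, v_cut = -45.2 + 10 * 1.2)
  }
}

# Post-spike relaxation of the effective excitatory-neuron parameters:
# additive offsets that decay exponentially toward baseline.  Two components
# act on the threshold V_T, one on the slope factor Delta_T and one on the
# inverse membrane time constant.
.default_soft_refractory <- function() {
  list(mode = "soft",
       v_thresh = list(amplitude = c(22.9, 13.5), tau = c(14.7, 76.2)),
       slope = list(amplitude = 10.0, tau = 17.7),
       inv_tau_m = list(amplitude = 0.14, tau = 14.3))
}

.default_hard_refractory <- function() {
  list(mode = "hard", refractory_period = 2.0)
}

# Synapse classes keyed by class x target population.  Peak conductances are
# the reference-size values; rise/decay in ms, conductance in nS, reversal in
# mV, reference_psp the calibrated unitary PSP amplitude in mV.
.default_synapses <- function() {
  list(
    ampa_on_excitatory = list(class = "AMPA", target = "excitatory",
      tau_r = 1, tau_d = 3, g = 1.0, e_rev = 0, reference_psp = 0.84),
    ampa_on_inhibitory = list(class = "AMPA", target = "inhibitory",
      tau_r = 1, tau_d = 3, g = 1.5, e_rev = 0, reference_psp = 2.07),
    # the GABA reversal is not tabulated; the shipped default is the value
    # recovered by calibrating the unitary IPSP amplitudes against the
    # efficacy table (see calibrate_gaba_reversal); the conventional -70 mV
    # underestimates both reference IPSPs by ~30%
    gaba_on_excitatory = list(class = "GABA", target = "excitatory",
      tau_r = 1, tau_d = 4, g = 4.0, e_rev = -75.1, reference_psp = 1.13),
    gaba_on_inhibitory = list(class = "GABA", target = "inhibitory",
      tau_r = 1, tau_d = 2, g = 4.0, e_rev = -75.1, reference_psp = 1.36),
    nmda_on_excitatory = list(class = "NMDA", target = "excitatory",
      tau_r = 3, tau_d = 80, g = 0.14, e_rev = 0, reference_psp = 0.50),
    # the efficacy table prints no NMDA-on-inhibitory row, but excitatory
    # spikes evoke composite AMPA+NMDA responses in all targets; the
    # conductance is reconstructed at the AMPA-on-inhibitory proportion
    nmda_on_inhibitory = list(class = "NMDA", target = "inhibitory",
      tau_r = 3, tau_d = 80, g = 0.21, e_rev = 0, reference_psp = NA_real_))
}

# Connection-probability profiles p(dtheta) = [p0 + p1 cos(2 dtheta)]_+ and
# latencies by pathway.  Inter-layer pathways are subject to the coupling
# scale Gamma.  source_layer "both" expands to one pathway per layer.
.default_pathways <- function() {
  path <- function(sl, sp, tl, tp, p0, p1, latency, inter) {
    list(source_layer = sl, source_pop = sp, target_layer = tl,
         target_pop = tp, p0 = p0, p1 = p1, latency = latency,
         interlayer = inter)
  }
  list(
    # intra-layer (identical in both layers)
    path("both", "excitatory", "same", "excitatory", 0.06, 0.06, 1.0, FALSE),
    path("both", "excitatory", "same", "inhibitory", 0.06, 0.06, 1.0, FALSE),
    path("both", "inhibitory", "same", "excitatory", 0.24, 0.12, 1.0, FALSE),
    path("both", "inhibitory", "same", "inhibitory", 0.24, 0.12, 1.0, FALSE),
    # inter-layer excitation
    path("upper", "excitatory", "lower", "excitatory", 0.06, 0.18, 3.0, TRUE),
    path("upper", "excitatory", "lower", "inhibitory", 0.06, 0.18, 3.0, TRUE),
    path("lower", "excitatory", "upper", "excitatory", 0.06, 0.18, 1.0, TRUE),
    path("lower", "excitatory", "upper", "inhibitory", 0.07, 0.16, 1.0, TRUE),
    # inter-layer inhibition (symmetric, unmodulated)
    path("upper", "inhibitory", "lower", "excitatory", 0.12, 0.00, 3.0, TRUE),
    path("upper", "inhibitory", "lower", "inhibitory", 0.12, 0.00, 3.0, TRUE),
    path("lower", "inhibitory", "upper", "excitatory", 0.12, 0.00, 1.0, TRUE),
    path("lower", "inhibitory", "upper", "inhibitory", 0.12, 0.00, 1.0, TRUE))
}

.default_lgn <- function() {
  list(g_lgn = 1.0, rate_offset = 150, rate_gain = 2850,
       single_cell_dark_rate = 5, single_cell_max_rate = 48,
       tuning_broadness = 1, lower_layer_attenuation = 0.5)
}

.default_background <- function() {
  list(g_bg = 10, mean_rate = 10, volatility = 1, filter_time = 10)
}

# ---- NetworkSpec ----------------------------------------------------------

#' Default hypercolumn specification
#'
#' Builds the complete parameterization of a two-ring hypercolumn: neuron
#' parameters for both populations, refractoriness, synapse classes,
#' connection-probability profiles and latencies, thalamic (LGN) input,
#' shared-rate background noise, the inter-layer coupling scale `gamma`, and
#' integration settings.  Defaults are the model's reference values for
#' `n_exc = 4000`, `n_inh = 1000` neurons per layer; smaller or larger
#' networks are derived with [scale_network()], which preserves the mean and
#' the quenched fluctuations of the recurrent input.
#'
#' @param n_exc,n_inh excitatory/inhibitory neurons per layer.
#' @param gamma inter-layer coupling scale in `[0, 1]` (1 = fully coupled).
#' @param dt integration step, ms.
#' @param master_seed integer seed controlling wiring and noise streams.
#' @return an object of class `network_spec`.
#' @export
default_spec <- function(n_exc = 4000, n_inh = 1000, gamma = 1,
                         dt = 0.2, master_seed = 1L) {
  spec <- structure(list(
    n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
    n_exc_ref = 4000L, n_inh_ref = 1000L,
    neurons = list(excitatory = .default_neuron("excitatory"),
                   inhibitory = .default_neuron("inhibitory")),
    refractory = list(excitatory = .default_soft_refractory(),
                      inhibitory = .default_hard_refractory()),
    synapses = .default_synapses(),
    pathways = .default_pathways(),
    lgn = .default_lgn(),
    background = .default_background(),
    gamma = gamma,
    gamma_scope = "both",
    dt = dt,
    master_seed = as.integer(master_seed)),
    class = "network_spec")
  validate_spec(spec)
  spec
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> 2 layers x (%d E + %d I) = %d neurons, gamma = %g, dt = %g ms\n",
    x$n_exc, x$n_inh, 2L * (x$n_exc + x$n_inh), x$gamma, x$dt))
  invisible(x)
}

#' Validate a network specification
#'
#' Checks every invariant of the parameterization (positivity of time
#' constants, rise < decay, reversal-potential ordering, probability profiles
#' bounded by 1, `gamma` in `[0,1]`, ...) and stops with a message naming the
#' offending field on the first violation.
#'
#' @param spec a `network_spec`.
#' @return the spec, invisibly.
#' @export
validate_spec <- function(spec) {
  fail <- function(field, msg) {
    stop(sprintf("invalid spec: %s (%s)", field, msg), call. = FALSE)
  }
  if (spec$n_exc < 1 || spec$n_inh < 1) fail("n_exc/n_inh", "sizes must be >= 1")
  if (spec$dt <= 0) fail("dt", "integration step must be > 0")
  if (spec$gamma < 0 || spec$gamma > 1) fail("gamma", "must lie in [0, 1]")
  if (!spec$gamma_scope %in% c("both", "lower_to_upper"))
    fail("gamma_scope", "must be 'both' or 'lower_to_upper'")
  for (kind in c("excitatory", "inhibitory")) {
    np <- spec$neurons[[kind]]
    if (np$tau_m <= 0) fail(paste0(kind, "$tau_m"), "must be > 0")
    if (np$capacitance <= 0) fail(paste0(kind, "$capacitance"), "must be > 0")
    if (np$slope <= 0) fail(paste0(kind, "$slope"), "must be > 0")
    if (np$v_reset >= np$v_cut) fail(paste0(kind, "$v_reset"), "must be < v_cut")
    # the spike nonlinearity must dominate the leak at the cutoff
    leak <- abs(np$e_leak - np$v_cut)
    if (spike_nonlinearity(np$v_cut, np$v_thresh, np$slope) < 10 * leak)
      fail(paste0(kind, "$v_cut"),
           "exponential term must exceed 10x the leak term at the cutoff")
  }
  rf <- spec$refractory
  if (rf$excitatory$mode != "soft" || rf$inhibitory$mode != "hard")
    fail("refractory$mode", "soft for excitatory, hard for inhibitory")
  if (any(c(rf$excitatory$v_thresh$tau, rf$excitatory$slope$tau,
            rf$excitatory$inv_tau_m$tau) <= 0))
    fail("refractory$excitatory", "relaxation times must be > 0")
  if (rf$inhibitory$refractory_period < 0)
    fail("refractory$inhibitory$refractory_period", "must be >= 0")
  el <- spec$neurons$excitatory$e_leak
  for (nm in names(spec$synapses)) {
    sy <- spec$synapses[[nm]]
    if (sy$tau_r <= 0 || sy$tau_r >= sy$tau_d)
      fail(paste0("synapses$", nm), "requires 0 < rise time < decay time")
    if (sy$g < 0) fail(paste0("synapses$", nm, "$g"), "must be >= 0")
    if (sy$class %in% c("AMPA", "NMDA") && sy$e_rev <= el)
      fail(paste0("synapses$", nm, "$e_rev"),
           "excitatory reversal must exceed the leak potential")
    if (sy$class == "GABA" && sy$e_rev >= el)
      fail(paste0("synapses$", nm, "$e_rev"),
           "inhibitory reversal must be below the leak potential")
  }
  for (k in seq_along(spec$pathways)) {
    pw <- spec$pathways[[k]]
    if (pw$p0 < 0) fail(sprintf("pathways[[%d]]$p0", k), "must be >= 0")
    if (pw$p0 + pw$p1 > 1)
      fail(sprintf("pathways[[%d]]", k),
           "peak connection probability p0 + p1 exceeds 1")
    if (pw$latency < 0) fail(sprintf("pathways[[%d]]$latency", k), "must be >= 0")
  }
  lg <- spec$lgn
  if (any(c(lg$g_lgn, lg$rate_offset, lg$rate_gain,
            lg$single_cell_dark_rate, lg$single_cell_max_rate) < 0))
    fail("lgn", "rates and conductances must be >= 0")
  if (lg$tuning_broadness < 0 || lg$tuning_broadness > 1)
    fail("lgn$tuning_broadness", "must lie in [0, 1]")
  if (lg$lower_layer_attenuation <= 0 || lg$lower_layer_attenuation > 1)
    fail("lgn$lower_layer_attenuation", "must lie in (0, 1]")
  bg <- spec$background
  if (bg$mean_rate <= 0) fail("background$mean_rate", "must be > 0")
  if (bg$filter_time <= 0) fail("background$filter_time", "must be > 0")
  if (bg$volatility < 0) fail("background$volatility", "must be >= 0")
  invisible(spec)
}

# ---- configuration files --------------------------------------------------

.spec_known_keys <- c(
  "n_exc", "n_inh", "gamma", "gamma_scope", "dt", "master_seed",
  "neurons", "refractory", "synapses", "pathways", "lgn", "background")

#' Load a network specification from a YAML document
#'
#' Unknown top-level keys are rejected; keys absent from the document keep
#' their built-in defaults.  Units follow the parameter tables throughout
#' (ms, nF, mV, nS, Hz, degrees); no unit conversion is performed.
#'
#' @param path path to a YAML file, or a YAML string.
#' @return a validated `network_spec`.
#' @export
load_spec <- function(path) {
  doc <- if (file.exists(path)) yaml::read_yaml(path)
         else yaml::yaml.load(path)
  if (is.null(doc)) doc <- list()
  unknown <- setdiff(names(doc), .spec_known_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  spec <- default_spec()
  for (key in intersect(names(doc), .spec_known_keys)) {
    spec[[key]] <- if (is.list(spec[[key]]) && is.list(doc[[key]]))
      modifyList(spec[[key]], doc[[key]]) else doc[[key]]
  }
  spec$n_exc <- as.integer(spec$n_exc)
  spec$n_inh <- as.integer(spec$n_inh)
  spec$master_seed <- as.integer(spec$master_seed)
  validate_spec(spec)
  spec
}

#' Save a network specification to YAML
#'
#' `load_spec(save_spec(spec, path))` restores the spec field-for-field.
#'
#' @param spec a `network_spec`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_spec <- function(spec, path) {
  validate_spec(spec)
  yaml::write_yaml(unclass(spec)[.spec_known_keys], path)
  invisible(path)
}

# ---- size scaling ---------------------------------------------------------

# ring average of the raw rectified profile [p0 + p1 cos(2 theta)]_+ over
# theta in [-90, 90)
.mean_rectified <- function(p0, p1) {
  if (p1 == 0) return(max(p0, 0))
  f <- function(u) pmax(p0 + p1 * cos(u), 0)
  integrate(f, -pi, pi, rel.tol = 1e-10)$value / (2 * pi)
}

# The connectivity table's mean target counts equal p0 x (population size)
# for every pathway, including those where rectification is active, so the
# profile actually wired is the rectified cosine renormalized to ring mean
# p0.  (For profiles with p1 <= p0 the renormalization is the identity.)
.reference_profile <- function(dtheta, p0, p1) {
  p <- pmax(p0 + p1 * cos(2 * dtheta * pi / 180), 0)
  mr <- .mean_rectified(p0, p1)
  if (mr > 0) p * (p0 / mr) else p
}

.mean_probability <- function(p0, p1) {
  max(p0, 0)
}

# Size scaling.  Each reference probability p maps to
#   p(N) = p N_ref / (p N_ref + (1 - p) N)
# (the in-degree-statistics-preserving map; identity at N = N_ref, bounded
# by 1 at any size), applied pointwise to the rectified profile.  The peak
# conductance is then rescaled so the product (expected in-degree K) x g is
# exactly invariant for every pathway:
#   g(N) = g_ref * (pbar_ref N_ref) / (pbar(N) N),
# which also preserves the quenched across-neuron variance K (1 - p) g^2
# in the uniform-profile approximation.
.prob_map <- function(p, n_src_ref, n_src) {
  ifelse(p <= 0, 0, p * n_src_ref / (p * n_src_ref + (1 - p) * n_src))
}

.scaled_profile <- function(dtheta, p0_ref, p1_ref, n_src_ref, n_src) {
  .prob_map(.reference_profile(dtheta, p0_ref, p1_ref), n_src_ref, n_src)
}

.scaled_mean_probability <- function(p0_ref, p1_ref, n_src_ref, n_src) {
  f <- function(u) .prob_map(
    .reference_profile(u * 90 / pi, p0_ref, p1_ref), n_src_ref, n_src)
  integrate(f, -pi, pi, rel.tol = 1e-10)$value / (2 * pi)
}

.scale_factors <- function(p0_ref, p1_ref, n_src_ref, n_src) {
  pbar_ref <- .mean_probability(p0_ref, p1_ref)
  if (pbar_ref <= 0) return(list(pbar = 0, fg = 1))
  pbar <- .scaled_mean_probability(p0_ref, p1_ref, n_src_ref, n_src)
  list(pbar = pbar, fg = (pbar_ref * n_src_ref) / (pbar * n_src))
}

#' Rescale a specification to a different network size
#'
#' Adjusts every recurrent pathway's connection-probability profile and peak
#' conductance so that the spatial mean and the quenched spatial fluctuations
#' of the time-averaged recurrent synaptic input are preserved relative to
#' the reference network (4000 excitatory + 1000 inhibitory per layer).
#' External (LGN and background) synapses are per-neuron drives and are not
#' rescaled.  Scaled values are always derived from the stored reference
#' values, so the operation is idempotent at the reference size and
#' composes: `scale_network(scale_network(s, a), b)` equals
#' `scale_network(s, b)`.
#'
#' @param spec a `network_spec`.
#' @param n_exc,n_inh target per-layer population sizes.
#' @return a rescaled `network_spec` (sizes updated, reference values kept).
#' @export
scale_network <- function(spec, n_exc, n_inh = round(n_exc / 4)) {
  if (n_exc < 1 || n_inh < 1) stop("target sizes must be >= 1", call. = FALSE)
  out <- spec
  out$n_exc <- as.integer(n_exc)
  out$n_inh <- as.integer(n_inh)
  out
}

#' Resolved pathway table at the spec's current size
#'
#' Expands the pathway list to concrete (source layer, population) ->
#' (target layer, population) rows carrying the reference profile
#' parameters (`p0_ref`, `p1_ref`), the source sizes, the size-scaled ring
#' mean probability `pbar`, the conductance scale factor `g_scale` relative
#' to the reference tables (chosen so expected in-degree x conductance is
#' invariant under size scaling), latency and inter-layer flag.  The scaled
#' probability at a given angular distance is
#' [scaled_connection_probability()].
#'
#' @param spec a `network_spec`.
#' @return a data.frame with one row per concrete pathway.
#' @export
pathway_table <- function(spec) {
  rows <- list()
  for (pw in spec$pathways) {
    layers <- if (pw$source_layer == "both") c("upper", "lower")
              else pw$source_layer
    for (sl in layers) {
      tl <- if (pw$target_layer == "same") sl else pw$target_layer
      n_src_ref <- if (pw$source_pop == "excitatory") spec$n_exc_ref
                   else spec$n_inh_ref
      n_src <- if (pw$source_pop == "excitatory") spec$n_exc else spec$n_inh
      sf <- .scale_factors(pw$p0, pw$p1, n_src_ref, n_src)
      rows[[length(rows) + 1L]] <- data.frame(
        source_layer = sl, source_pop = pw$source_pop,
        target_layer = tl, target_pop = pw$target_pop,
        p0_ref = pw$p0, p1_ref = pw$p1,
        n_src = n_src, n_src_ref = n_src_ref,
        pbar = sf$pbar, g_scale = sf$fg, latency = pw$latency,
        interlayer = pw$interlayer, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Size-scaled connection probability of a pathway
#'
#' Applies the size map pointwise to the rectified reference profile of a
#' [pathway_table()] row.
#'
#' @param dtheta angular distance(s), degrees.
#' @param pathway one row of [pathway_table()].
#' @return probability in `[0, 1]`.
#' @export
scaled_connection_probability <- function(dtheta, pathway) {
  .scaled_profile(dtheta, pathway$p0_ref, pathway$p1_ref,
                  pathway$n_src_ref, pathway$n_src)
}

# ---- presets --------------------------------------------------------------

#' Built-in experiment presets
#'
#' * `baseline` - the reference parameterization.
#' * `symmetric_drive` - equal LGN drive to both layers and equal
#'   inter-layer latencies in both directions.
#' * `densified_inhibition` - inhibitory connection probabilities raised to a
#'   1:10 excitatory:inhibitory density ratio (intra-layer I: p0 = 0.6,
#'   p1 = 0.3; inter-layer I: p0 = 0.3, p1 = 0).
#' * `large_variance_noise` - fewer, stronger thalamic afferents
#'   (synthetic stand-in values), saturating at 32 Hz per afferent.
#' * `unmodulated_interlayer_excitation` - the spatial modulation of
#'   inter-layer excitation replaced by its ring-averaged unmodulated
#'   equivalent (p1 = 0, p0 = mean of the rectified profile).
#'
#' @param name preset name; see above.
#' @return a validated `network_spec`.
#' @export
preset_spec <- function(name = c("baseline", "symmetric_drive",
                                 "densified_inhibition",
                                 "large_variance_noise",
                                 "unmodulated_interlayer_excitation")) {
  name <- match.arg(name)
  spec <- default_spec()
  if (name == "symmetric_drive") {
    spec$lgn$lower_layer_attenuation <- 1
    for (k in seq_along(spec$pathways))
      if (spec$pathways[[k]]$interlayer) spec$pathways[[k]]$latency <- 1.0
  } else if (name == "densified_inhibition") {
    for (k in seq_along(spec$pathways)) {
      pw <- spec$pathways[[k]]
      if (pw$source_pop != "inhibitory") next
      if (pw$interlayer) {
        spec$pathways[[k]]$p0 <- 0.3; spec$pathways[[k]]$p1 <- 0.0
      } else {
        spec$pathways[[k]]$p0 <- 0.6; spec$pathways[[k]]$p1 <- 0.3
      }
    }
  } else if (name == "large_variance_noise") {
    spec$lgn$g_lgn <- 3.0
    spec$lgn$rate_offset <- 50
    spec$lgn$rate_gain <- 950
    spec$lgn$single_cell_max_rate <- 32
  } else if (name == "unmodulated_interlayer_excitation") {
    for (k in seq_along(spec$pathways)) {
      pw <- spec$pathways[[k]]
      if (pw$interlayer && pw$source_pop == "excitatory") {
        spec$pathways[[k]]$p0 <- .mean_probability(pw$p0, pw$p1)
        spec$pathways[[k]]$p1 <- 0.0
      }
    }
  }
  validate_spec(spec)
  spec
}

#' @rdname preset_spec
#' @export
list_presets <- function() {
  c("baseline", "symmetric_drive", "densified_inhibition",
    "large_variance_noise", "unmodulated_interlayer_excitation")
}
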