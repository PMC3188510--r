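# Quenched two-ring random wiring.

#' Evenly spaced ring coordinates
#'
#' Angular positions (degrees in `[-90, 90)`) for `n` neurons on a ring with
#' orientation periodicity 180 degrees.
#'
#' @param n number of neurons.
#' @return numeric vector of angles, degrees.
#' @export
ring_angles <- function(n) {
  seq(-90, 90, length.out = n + 1)[seq_len(n)]
}

#' Wrap an angular difference to `[-90, 90)`
#'
#' Orientation space has period 180 degrees.
#'
#' @param dtheta angular difference(s), degrees.
#' @return wrapped difference(s), degrees.
#' @export
wrap_angle <- function(dtheta) {
  ((dtheta + 90) %% 180) - 90
}

#' Spatially modulated connection probability
#'
#' `p(dtheta) = [p0 + p1 cos(2 dtheta)]_+` (rectified at zero), the ring
#' profile used for every pathway.
#'
#' @param dtheta angular distance, degrees.
#' @param p0 mean (offset) component.
#' @param p1 modulation amplitude.
#' @return probability in `[0, 1]`.
#' @export
connection_probability <- function(dtheta, p0, p1) {
  if (p0 + p1 > 1)
    stop("invalid profile: p0 + p1 exceeds 1", call. = FALSE)
  pmax(p0 + p1 * cos(2 * dtheta * pi / 180), 0)
}

#' Expected out-degree of a pathway
#'
#' Target-population size times the ring average (numerical integration) of
#' the wired probability profile: the rectified cosine renormalized to ring
#' mean `p0`, matching the connectivity table's mean target counts for
#' every pathway including those where rectification is active.
#'
#' @param p0,p1 profile parameters.
#' @param n_target target population size.
#' @return expected number of targets.
#' @export
expected_out_degree <- function(p0, p1, n_target) {
  f <- function(u) .reference_profile(u * 90 / pi, p0, p1)
  n_target * integrate(f, -pi, pi, rel.tol = 1e-10)$value / (2 * pi)
}

#' Draw the quenched synaptic wiring of a hypercolumn
#'
#' Neuron indexing: `1..n_exc` upper-layer excitatory, then upper
#' inhibitory, lower excitatory, lower inhibitory.  For every pathway each
#' ordered neuron pair is connected independently with the size-scaled
#' rectified-cosine probability of its angular distance; autapses are
#' excluded.  Per-connection latencies come from the pathway table and peak
#' conductances from the synapse classes, size scaling, and (for
#' inter-layer pathways in scope of `gamma_scope`) the coupling scale
#' `gamma`.
#'
#' @param spec a `network_spec`.
#' @param seed integer seed for the wiring draw (defaults to the spec's
#'   master seed).
#' @return a `connectivity` object: flat edge vectors (`src`, `tgt`,
#'   `w_fast`, `w_nmda`, `fast_class`, `latency`, `interlayer_scaled`) plus
#'   neuron coordinate/population tables.
#' @export
build_network <- function(spec, seed = spec$master_seed) {
  layout <- network_layout(spec)
  tab <- pathway_table(spec)
  syn <- spec$synapses
  g_of <- function(class, target) {
    key <- paste0(tolower(class), "_on_", target)
    syn[[key]]$g
  }
  set.seed(seed)
  src_l <- list(); tgt_l <- list(); path_l <- list()
  for (k in seq_len(nrow(tab))) {
    pw <- tab[k, ]
    si <- which(layout$layer == pw$source_layer & layout$pop == pw$source_pop)
    ti <- which(layout$layer == pw$target_layer & layout$pop == pw$target_pop)
    # probability matrix via outer angular distance; Bernoulli per pair
    dth <- wrap_angle(outer(layout$theta[si], layout$theta[ti], "-"))
    p <- scaled_connection_probability(dth, pw)
    hit <- which(matrix(runif(length(p)) < p, nrow = length(si)),
                 arr.ind = TRUE)
    s <- si[hit[, 1]]
    t <- ti[hit[, 2]]
    keep <- s != t
    src_l[[k]] <- s[keep]
    tgt_l[[k]] <- t[keep]
    path_l[[k]] <- rep.int(k, sum(keep))
  }
  src <- unlist(src_l, use.names = FALSE)
  tgt <- unlist(tgt_l, use.names = FALSE)
  pid <- unlist(path_l, use.names = FALSE)
  tpop <- layout$pop[tgt]
  spop <- layout$pop[src]
  g_fast <- ifelse(spop == "excitatory",
                   ifelse(tpop == "excitatory", g_of("AMPA", "excitatory"),
                          g_of("AMPA", "inhibitory")),
                   ifelse(tpop == "excitatory", g_of("GABA", "excitatory"),
                          g_of("GABA", "inhibitory")))
  g_nmda <- ifelse(spop == "excitatory",
                   ifelse(tpop == "excitatory", g_of("NMDA", "excitatory"),
                          g_of("NMDA", "inhibitory")), 0)
  gsc <- tab$g_scale[pid]
  net <- structure(list(
    spec = spec, layout = layout, pathway_id = pid, pathways = tab,
    src = src, tgt = tgt,
    w_fast_base = g_fast * gsc, w_nmda_base = g_nmda * gsc,
    fast_class = ifelse(spop == "excitatory", "AMPA", "GABA"),
    latency = tab$latency[pid],
    gamma_scaled = .gamma_scaled_edges(tab, pid, spec$gamma_scope),
    seed = seed), class = "connectivity")
  apply_interlayer_scale(net, spec$gamma)
}

.gamma_scaled_edges <- function(tab, pid, scope) {
  inter <- tab$interlayer[pid]
  if (scope == "lower_to_upper")
    inter & tab$source_layer[pid] == "lower"
  else inter
}

#' Neuron layout of a spec
#'
#' @param spec a `network_spec`.
#' @return data.frame with `layer`, `pop`, `theta` per neuron.
#' @export
network_layout <- function(spec) {
  data.frame(
    layer = rep(c("upper", "upper", "lower", "lower"),
                times = c(spec$n_exc, spec$n_inh, spec$n_exc, spec$n_inh)),
    pop = rep(c("excitatory", "inhibitory", "excitatory", "inhibitory"),
              times = c(spec$n_exc, spec$n_inh, spec$n_exc, spec$n_inh)),
    theta = c(ring_angles(spec$n_exc), ring_angles(spec$n_inh),
              ring_angles(spec$n_exc), ring_angles(spec$n_inh)),
    stringsAsFactors = FALSE)
}

#' Rescale inter-layer conductances
#'
#' Sets the effective conductances of the inter-layer pathways (per the
#' spec's `gamma_scope`) to `gamma` times their fully coupled values.  The
#' rescaling is absolute - applying 0.5 twice still gives 0.5, not 0.25 -
#' because the gamma = 1 base weights are retained.  Intra-layer weights are
#' untouched and adjacency is never redrawn.
#'
#' @param net a `connectivity` object.
#' @param gamma inter-layer coupling scale in `[0, 1]`.
#' @return the rescaled `connectivity`.
#' @export
apply_interlayer_scale <- function(net, gamma) {
  if (gamma < 0 || gamma > 1)
    stop("gamma must lie in [0, 1]", call. = FALSE)
  fac <- ifelse(net$gamma_scaled, gamma, 1)
  net$w_fast <- net$w_fast_base * fac
  net$w_nmda <- net$w_nmda_base * fac
  net$gamma <- gamma
  net$spec$gamma <- gamma
  net
}

#' Realized out-degrees of one pathway
#'
#' @param net a `connectivity`.
#' @param pathway row index into `net$pathways`.
#' @return integer vector, one out-degree per source neuron of the pathway.
#' @export
realized_out_degrees <- function(net, pathway) {
  tabrow <- net$pathways[pathway, ]
  si <- which(net$layout$layer == tabrow$source_layer &
                net$layout$pop == tabrow$source_pop)
  sel <- net$pathway_id == pathway
  tabulate(match(net$src[sel], si), nbins = length(si))
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("<connectivity> %d neurons, %d connections, gamma = %g, seed = %d\n",
              nrow(x$layout), length(x$src), x$gamma, x$seed))
  invisible(x)
}
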