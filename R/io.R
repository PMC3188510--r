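# Artifact readers/writers and experiment presets.
#
# The canonical on-disk container is R's native serialization (RDS) with an
# explicit schema version; spike rasters and scalar series additionally
# round-trip through plain CSV, and experiment manifests are JSON.

.RESULT_SCHEMA <- 1L

#' Write / read a simulation result
#'
#' Lossless round trip of a `sim_result` (or any package object) with a
#' schema version check on read.
#'
#' @param result object to store.
#' @param path file path.
#' @return `write_result()`: the path, invisibly; `read_result()`: the
#'   restored object.
#' @export
write_result <- function(result, path) {
  saveRDS(list(schema = .RESULT_SCHEMA, payload = result), path)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupted or unreadable result file: ", path, call. = FALSE))
  if (!is.list(obj) || is.null(obj$schema))
    stop("corrupted result file (no schema marker): ", path, call. = FALSE)
  if (obj$schema != .RESULT_SCHEMA)
    stop(sprintf("schema version mismatch: file %s has v%d, expected v%d",
                 path, obj$schema, .RESULT_SCHEMA), call. = FALSE)
  obj$payload
}

#' Spike-raster CSV export / import
#'
#' Two-column CSV (`neuron_id`, `time_ms`); times are written with
#' microsecond precision.
#'
#' @param result a `sim_result` (or data.frame `neuron`, `time`).
#' @param path file path.
#' @return `write_raster_csv()`: the path; `read_raster_csv()`: a
#'   data.frame `neuron`, `time`.
#' @export
write_raster_csv <- function(result, path) {
  sp <- if (inherits(result, "sim_result")) result$spikes else result
  df <- data.frame(neuron_id = sp$neuron, time_ms = round(sp$time, 6))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  df <- read.csv(path)
  data.frame(neuron = as.integer(df$neuron_id), time = df$time_ms)
}

#' Run a named experiment preset
#'
#' Executes a simulate-and-analyze chain at a reduced network scale and
#' writes its artifacts (CSV tables, JSON manifest) to `outdir`.  Presets:
#'
#' * `chi-vs-contrast`: synchrony measure over a contrast set.
#' * `lfp-spectrum`: LFP power spectra at 0%, low and high contrast,
#'   normalized to the zero-contrast 0 Hz power.
#' * `tuning`: orientation tuning of the upper-layer excitatory
#'   population at one contrast (circular variance, preferred orientation).
#' * `perturbation`: single-spike perturbation pair and the RMS divergence
#'   of the population rate.
#'
#' @param name preset name.
#' @param scale_factor network scale relative to the reference size
#'   (0.05 = 250 neurons total).
#' @param seed master seed.
#' @param outdir output directory (created if needed).
#' @param duration recorded duration per run, ms.
#' @return the manifest list, invisibly.
#' @export
run_preset <- function(name = c("chi-vs-contrast", "lfp-spectrum",
                                "tuning", "perturbation"),
                       scale_factor = 0.05, seed = 1, outdir = tempdir(),
                       duration = 2000) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset '", name[1], "'; available: ",
         paste(eval(formals(run_preset)$name), collapse = ", "),
         call. = FALSE))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- scale_network(default_spec(master_seed = seed),
                        n_exc = max(8, round(4000 * scale_factor)),
                        n_inh = max(2, round(1000 * scale_factor)))
  files <- character(0)
  add <- function(df, fname) {
    p <- file.path(outdir, fname)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }
  n_up_e <- seq_len(spec$n_exc)
  if (name == "chi-vs-contrast") {
    contrasts <- c(0.02, 0.3, 0.95)
    chi <- vapply(contrasts, function(C) {
      r <- run_simulation(spec, stimulus(C, 0), duration, seed = seed,
                          record_v = n_up_e, v_stride_ms = 2)
      chi_of_result(r)
    }, numeric(1))
    add(data.frame(contrast = contrasts, chi = chi), "chi_vs_contrast.csv")
  } else if (name == "lfp-spectrum") {
    sect <- data.frame(center = 0, width = 18)
    runs <- lapply(c(0, 0.02, 0.95), function(C)
      run_simulation(spec, stimulus(C, 0), duration, seed = seed,
                     lfp_sectors = sect))
    ref <- lfp_signal(runs[[1]])
    for (k in 2:3) {
      ps <- power_spectrum(lfp_signal(runs[[k]]), reference = ref)
      add(data.frame(freq = ps$freq, power = ps$power),
          sprintf("lfp_spectrum_C%g.csv", runs[[k]]$meta$stim$contrast))
    }
  } else if (name == "tuning") {
    oris <- ring_angles(12)
    rates <- vapply(oris, function(o) {
      r <- run_simulation(spec, stimulus(0.95, o), duration, seed = seed)
      sel <- which(abs(wrap_angle(r$meta$layout$theta[n_up_e] - o)) <= 5)
      sp <- r$spikes[r$spikes$time >= 0 & r$spikes$neuron %in% n_up_e[sel], ]
      nrow(sp) / length(sel) / (duration / 1000)
    }, numeric(1))
    tc <- tuning_statistics(rates, oris)
    add(data.frame(orientation = oris, rate = rates), "tuning_curve.csv")
    add(data.frame(circular_variance = tc$circular_variance,
                   preferred = tc$preferred, peak_rate = tc$peak_rate),
        "tuning_stats.csv")
  } else if (name == "perturbation") {
    pre <- run_simulation(spec, stimulus(0.95, 0), 200, seed = seed)
    cand <- pre$spikes$neuron[pre$spikes$time >= 0][1]
    k <- sum(pre$spikes$neuron == cand &
               pre$spikes$time <= pre$spikes$time[pre$spikes$neuron == cand &
                                                    pre$spikes$time >= 0][1])
    pair <- perturb_single_spike(spec, stimulus(0.95, 0), duration,
                                 seed = seed, target_neuron = cand,
                                 target_spike = k)
    h1 <- population_rate(pair$unperturbed)
    h2 <- population_rate(pair$perturbed)
    add(data.frame(t = h1$t, unperturbed = h1$fraction,
                   perturbed = h2$fraction), "perturbation_rates.csv")
  }
  manifest <- list(preset = name, seed = seed, scale_factor = scale_factor,
                   n_exc = spec$n_exc, n_inh = spec$n_inh,
                   duration_ms = duration,
                   package_version = as.character(utils::packageVersion("hypercolumn")),
                   files = basename(files))
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
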