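# Steady-state and trial-based statistics: tuning, contrast response,
# synchrony, correlograms, LFP/MUA spectra and coherence, PSTH.

#' Uniformly sampled scalar signal
#'
#' @param samples numeric vector.
#' @param fs sampling rate, Hz.
#' @param units unit label.
#' @param t0 time of the first sample, ms.
#' @param meta optional metadata list.
#' @return a `signal_series`.
#' @export
signal_series <- function(samples, fs, units = "", t0 = 0, meta = list()) {
  stopifnot(is.numeric(samples), fs > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), fs = fs, units = units,
                 t0 = t0, meta = meta), class = "signal_series")
}

.as_samples <- function(x) if (inherits(x, "signal_series")) x$samples else x

# ---- tuning and contrast response ----------------------------------------

#' Tuning-curve statistics
#'
#' From mean rates over an orientation grid, computes the
#' orientation-doubled resultant `m = sum(r e^{2 i theta}) / sum(r)`, the
#' circular variance `CV = 1 - |m|`, the preferred orientation
#' `psi = arg(m)/2`, the peak rate, and a circular skewness: the
#' rate-weighted first sine moment of the doubled angles about the mean
#' direction, normalized by `(1 - |m|)^{3/2}` (zero for symmetric curves,
#' signed by the direction of the asymmetry).
#'
#' @param rates mean firing rate per orientation, Hz.
#' @param orientations orientation grid, degrees (default 12 orientations
#'   spanning `[-90, 90)`).
#' @return a `tuning_curve` list with `rates`, `orientations`, `peak_rate`,
#'   `preferred`, `circular_variance`, `skewness`, `resultant`.
#' @export
tuning_statistics <- function(rates, orientations = ring_angles(length(rates))) {
  stopifnot(length(rates) == length(orientations), length(rates) >= 3)
  if (all(rates == 0)) stop("all-zero tuning curve", call. = FALSE)
  if (any(rates < 0)) stop("negative rates", call. = FALSE)
  phi <- 2 * orientations * pi / 180
  m <- sum(rates * exp(1i * phi)) / sum(rates)
  R <- Mod(m)
  psi <- wrap_angle(Arg(m) / 2 * 180 / pi)
  w <- rates / sum(rates)
  skew <- if (R > 1 - 1e-12) 0 else
    sum(w * sin(2 * (phi - Arg(m)))) / (1 - R)^1.5
  structure(list(rates = rates, orientations = orientations,
                 peak_rate = max(rates), preferred = psi,
                 circular_variance = 1 - R, skewness = skew,
                 resultant = m), class = "tuning_curve")
}

#' Hyperbolic-ratio contrast-response fit
#'
#' Least-squares fit of `R(C) = baseline + R_max C^n / (C^n + C50^n)`
#' (Naka-Rushton form) to peak rates across contrasts.
#'
#' @param contrasts contrast levels in `[0, 1]` (at least 5).
#' @param rates peak firing rate at each contrast, Hz.
#' @return list with `r_max`, `c50`, `exponent`, `baseline`, `residual`
#'   (RMS), `fitted`, and `degenerate` (TRUE when the response range is too
#'   small to identify `C50`).
#' @export
fit_crf <- function(contrasts, rates) {
  stopifnot(length(contrasts) == length(rates), length(contrasts) >= 5)
  rng <- diff(range(rates))
  if (rng < 1e-8 || rng < 0.02 * max(abs(rates), 1e-12)) {
    return(list(r_max = 0, c50 = NA_real_, exponent = NA_real_,
                baseline = mean(rates), residual = sd(rates),
                fitted = rep(mean(rates), length(rates)), degenerate = TRUE))
  }
  start <- list(rmax = rng, c50 = max(median(contrasts), 0.05),
                n = 1.5, base = min(rates))
  fit <- minpack.lm::nlsLM(
    rates ~ base + rmax * contrasts^n / (contrasts^n + c50^n),
    start = start,
    lower = c(rmax = 0, c50 = 1e-4, n = 0.1, base = -Inf),
    upper = c(rmax = Inf, c50 = 10, n = 10, base = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  fitted <- cf["base"] + cf["rmax"] * contrasts^cf["n"] /
    (contrasts^cf["n"] + cf["c50"]^cf["n"])
  list(r_max = unname(cf["rmax"]), c50 = unname(cf["c50"]),
       exponent = unname(cf["n"]), baseline = unname(cf["base"]),
       residual = sqrt(mean((rates - fitted)^2)), fitted = fitted,
       degenerate = FALSE)
}

# ---- synchrony ------------------------------------------------------------

#' Population synchrony measure chi
#'
#' Ratio-of-variances synchrony of a set of membrane-potential traces:
#' `chi = sqrt( Var_t[mean_i V_i(t)] / mean_i Var_t[V_i(t)] )`.  Equals 1
#' for identical traces and decays as `1/sqrt(N)` for independent ones;
#' invariant under common affine transforms.  Spike excursions are clipped
#' at `clip` (the spike-initiation threshold) by default so the statistic
#' reflects sub-threshold synchrony.
#'
#' @param v matrix of traces, samples x neurons (or a list of equal-length
#'   vectors).
#' @param clip clip level, mV (`NULL` to disable).
#' @return chi in `[0, 1]`.
#' @export
synchrony_chi <- function(v, clip = NULL) {
  if (is.list(v)) v <- do.call(cbind, v)
  stopifnot(is.matrix(v), ncol(v) >= 2)
  if (!is.null(clip)) v <- pmin(v, clip)
  vars <- apply(v, 2, var)
  if (any(vars == 0)) stop("zero-variance trace", call. = FALSE)
  sqrt(var(rowMeans(v)) / mean(vars))
}

#' Finite-size scaling of the synchrony measure
#'
#' Fits `chi(N)^2 = a + b / N` by linear least squares and reports the
#' asymptote `sqrt(a)` together with the log-log slope of chi versus N
#' (which approaches -0.5 for asynchronous states, where `a = 0`).
#'
#' @param sizes network sizes (at least 3).
#' @param chi synchrony values at each size.
#' @param n_boot bootstrap replicates for the slope confidence interval
#'   (0 disables).
#' @return list with `slope`, `asymptote`, `a`, `b`, optional `slope_ci`.
#' @export
chi_scaling <- function(sizes, chi, n_boot = 0) {
  stopifnot(length(sizes) == length(chi))
  if (length(unique(sizes)) < 3) stop("need at least 3 sizes", call. = FALSE)
  fit <- stats::lm(I(chi^2) ~ I(1 / sizes))
  a <- max(coef(fit)[1], 0)
  b <- coef(fit)[2]
  slope <- unname(coef(stats::lm(log(chi) ~ log(sizes)))[2])
  out <- list(slope = slope, asymptote = sqrt(a), a = unname(a),
              b = unname(b))
  if (n_boot > 0) {
    us <- sort(unique(sizes))
    sl <- replicate(n_boot, {
      idx <- unlist(lapply(us, function(s) {
        k <- which(sizes == s); sample(k, length(k), replace = TRUE)
      }))
      unname(coef(stats::lm(log(chi[idx]) ~ log(sizes[idx])))[2])
    })
    out$slope_ci <- quantile(sl, c(0.025, 0.975), names = FALSE)
  }
  out
}

# ---- correlograms ---------------------------------------------------------

#' Cross-correlogram of two signals
#'
#' Cross-covariance of the mean-subtracted signals over lags up to
#' `max_lag`; the normalized variant divides by the geometric mean of the
#' variances, so the zero-lag value of an autocorrelogram is 1 (or the
#' variance `AC(0)` when unnormalized).
#'
#' @param x,y equal-rate [signal_series()] or numeric vectors.
#' @param max_lag maximal lag, ms.
#' @param fs sampling rate, Hz (taken from `x` when it is a series).
#' @param normalized divide by the geometric mean of the variances.
#' @return list with `lag_ms` and `value`.
#' @export
correlogram <- function(x, y = x, max_lag = 100, fs = NULL,
                        normalized = TRUE) {
  if (inherits(x, "signal_series")) fs <- x$fs
  if (is.null(fs)) stop("fs required for plain vectors", call. = FALSE)
  xs <- .as_samples(x); ys <- .as_samples(y)
  stopifnot(length(xs) == length(ys))
  n <- length(xs)
  lag_n <- round(max_lag * fs / 1000)
  if (lag_n >= n) stop("max_lag must be below the series length", call. = FALSE)
  xs <- xs - mean(xs); ys <- ys - mean(ys)
  lags <- -lag_n:lag_n
  val <- vapply(lags, function(l) {
    if (l >= 0) sum(xs[1:(n - l)] * ys[(1 + l):n]) / n
    else sum(xs[(1 - l):n] * ys[1:(n + l)]) / n
  }, numeric(1))
  if (normalized) {
    denom <- sqrt((sum(xs^2) / n) * (sum(ys^2) / n))
    if (denom == 0) stop("zero-variance signal", call. = FALSE)
    val <- val / denom
  }
  list(lag_ms = lags / fs * 1000, value = val)
}

#' Smooth a spike train into a spike-count signal
#'
#' Convolution with a square window (width `window_ms`) sampled at `fs`.
#'
#' @param times spike times, ms.
#' @param window_ms square window width, ms.
#' @param fs sampling rate, Hz.
#' @param t_range `c(start, end)` of the output, ms.
#' @return a [signal_series()] of windowed spike counts.
#' @export
smooth_spike_train <- function(times, window_ms = 10, fs = 1000,
                               t_range) {
  dt <- 1000 / fs
  grid <- seq(t_range[1], t_range[2], by = dt)
  counts <- vapply(grid, function(t)
    sum(times > t - window_ms / 2 & times <= t + window_ms / 2), numeric(1))
  signal_series(counts, fs, units = "count")
}

#' Zero-lag pairwise cross-correlation coefficients
#'
#' Coefficients for all pairs of columns of a signal matrix (voltage
#' traces used raw, spike trains first smoothed with [smooth_spike_train()]
#' by the caller).
#'
#' @param x matrix, samples x units.
#' @return numeric vector of coefficients, one per unordered pair.
#' @export
pairwise_cco <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  cm <- stats::cor(x)
  cm[upper.tri(cm)]
}

#' CCo histogram of a simulation
#'
#' Selects neurons of the recorded voltage set (or the spike raster) whose
#' coordinate lies within a sector centered on the stimulus orientation,
#' applies the admissibility rules (at least `min_spikes` spikes per train
#' for spike-based pairs), and returns the zero-lag coefficients.
#'
#' @param result a `sim_result` (voltages recorded for the voltage type).
#' @param type `"voltage"` or `"spikes"`.
#' @param sector_width selection sector width, degrees.
#' @param window_ms square smoothing window for spike trains, ms.
#' @param min_spikes minimal spike count per admissible train.
#' @param clip clip voltages at the spike-initiation threshold.
#' @return numeric vector of pairwise coefficients.
#' @export
cco_histogram <- function(result, type = c("voltage", "spikes"),
                          sector_width = 18, window_ms = 10,
                          min_spikes = 100, clip = TRUE) {
  type <- match.arg(type)
  layout <- result$meta$layout
  center <- result$meta$stim$orientation
  sel <- which(layout$layer == "upper" & layout$pop == "excitatory" &
                 abs(wrap_angle(layout$theta - center)) <= sector_width / 2)
  if (type == "voltage") {
    keep <- which(result$v_neurons %in% sel)
    if (length(keep) < 2) stop("no admissible pairs", call. = FALSE)
    v <- t(result$v[keep, , drop = FALSE])
    if (clip) v <- pmin(v, result$meta$spec$neurons$excitatory$v_thresh)
    pairwise_cco(v)
  } else {
    sp <- result$spikes[result$spikes$time >= 0, ]
    counts <- tabulate(sp$neuron, nbins = result$meta$n_neurons)
    sel <- sel[counts[sel] >= min_spikes]
    if (length(sel) < 2) stop("no admissible pairs", call. = FALSE)
    dur <- result$meta$duration
    sm <- vapply(sel, function(i) {
      smooth_spike_train(sp$time[sp$neuron == i], window_ms, fs = 1000,
                         t_range = c(0, dur))$samples
    }, numeric(floor(dur) + 1))
    pairwise_cco(sm)
  }
}

# ---- LFP / MUA / spectra --------------------------------------------------

#' Extract a recorded LFP channel
#'
#' The simulated LFP is the mean total synaptic input current over the
#' upper-layer neurons of a small angular sector, recorded at the
#' integration rate (5 kHz at the default step).  The sector must have been
#' requested via `lfp_sectors` in [run_simulation()].
#'
#' @param result a `sim_result`.
#' @param sector_center sector center, degrees.
#' @param sector_width sector width, degrees.
#' @return a [signal_series()] in nA.
#' @export
lfp_signal <- function(result, sector_center = 0, sector_width = 18) {
  sc <- result$lfp_sectors
  if (is.null(sc) || nrow(result$lfp) == 0)
    stop("no LFP sector recorded; pass lfp_sectors to run_simulation()",
         call. = FALSE)
  k <- which(abs(sc$center - sector_center) < 1e-9 &
               abs(sc$width - sector_width) < 1e-9)
  if (length(k) == 0)
    stop("requested sector was not recorded", call. = FALSE)
  signal_series(result$lfp[k[1], ], fs = 1000 / result$meta$dt, units = "nA",
                meta = list(center = sector_center, width = sector_width))
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

.welch_xspec <- function(x, y, fs, segment_s = 1, overlap = 0.5) {
  n <- length(x)
  L <- min(round(segment_s * fs), n)
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  w <- .hann(L)
  wnorm <- sum(w^2)
  acc <- complex(real = numeric(floor(L / 2) + 1))
  for (s in starts) {
    xs <- fft(x[s:(s + L - 1)] * w)
    ys <- fft(y[s:(s + L - 1)] * w)
    acc <- acc + (xs * Conj(ys))[seq_along(acc)]
  }
  list(freq = (seq_along(acc) - 1) * fs / L,
       spec = acc / (length(starts) * wnorm * fs),
       n_segments = length(starts))
}

#' Welch power spectrum
#'
#' Hann-tapered, segment-averaged periodogram (1 s segments, 50% overlap
#' by default).  The series mean is removed before estimation.  When a
#' zero-contrast reference series is supplied the spectrum is normalized so
#' the reference's 0 Hz power equals 1; spectra of a given regime are then
#' directly comparable on the model's logarithmic power scale.
#'
#' @param x a [signal_series()] (or vector with `fs`).
#' @param reference optional zero-contrast reference series for the
#'   normalization.
#' @param fs sampling rate, Hz, for plain vectors.
#' @param segment_s Welch segment length, s.
#' @param overlap segment overlap fraction.
#' @param smooth_bins moving-average display smoothing (1 = none).
#' @return a `spectral_estimate` list: `freq` (Hz), `power`, `kind`,
#'   `n_segments`, `normalization`.
#' @export
power_spectrum <- function(x, reference = NULL, fs = NULL, segment_s = 1,
                           overlap = 0.5, smooth_bins = 1) {
  if (inherits(x, "signal_series")) fs <- x$fs
  xs <- .as_samples(x); xs <- xs - mean(xs)
  if (length(xs) < 4 * round(segment_s * fs) / 2)
    stop("series too short for the requested Welch segments", call. = FALSE)
  px <- .welch_xspec(xs, xs, fs, segment_s, overlap)
  power <- Re(px$spec)
  norm <- "none"
  if (!is.null(reference)) {
    rs <- .as_samples(reference); rs <- rs - mean(rs)
    pr <- .welch_xspec(rs, rs, fs, segment_s, overlap)
    p0 <- Re(pr$spec)[1]
    if (p0 <= 0) p0 <- Re(pr$spec)[2]
    power <- power / p0
    norm <- "unit power at 0 Hz of the zero-contrast reference"
  }
  if (smooth_bins > 1) {
    k <- rep(1 / smooth_bins, smooth_bins)
    power <- as.numeric(stats::filter(power, k, sides = 2))
  }
  structure(list(freq = px$freq, power = power, kind = "power",
                 n_segments = px$n_segments, normalization = norm),
            class = "spectral_estimate")
}

#' Frequency of the spectral peak in a band
#'
#' @param x a [signal_series()].
#' @param band `c(fmin, fmax)`, Hz.
#' @param ... passed to [power_spectrum()].
#' @return peak frequency, Hz.
#' @export
oscillation_peak_frequency <- function(x, band = c(20, 100), ...) {
  ps <- power_spectrum(x, ...)
  sel <- which(ps$freq >= band[1] & ps$freq <= band[2])
  ps$freq[sel[which.max(ps$power[sel])]]
}

#' Multi-unit activity signal
#'
#' Sum of the spike trains of a few randomly selected cells of an angular
#' sector (upper layer), convolved with a Gaussian window of 1 ms variance
#' and sampled at the LFP rate.  The integral of the signal equals the
#' summed spike count.
#'
#' @param result a `sim_result`.
#' @param sector_center,sector_width sector, degrees.
#' @param n_units number of cells summed.
#' @param units optional explicit neuron indices (overrides the random
#'   draw).
#' @param sd_ms Gaussian kernel standard deviation, ms.
#' @param fs output sampling rate, Hz.
#' @return a [signal_series()] (events/ms).
#' @export
mua_signal <- function(result, sector_center = 0, sector_width = 18,
                       n_units = 3, units = NULL, sd_ms = 1, fs = 5000) {
  layout <- result$meta$layout
  if (is.null(units)) {
    pool <- which(layout$layer == "upper" &
                    abs(wrap_angle(layout$theta - sector_center)) <=
                    sector_width / 2)
    if (length(pool) < n_units)
      stop("fewer cells than requested units in the sector", call. = FALSE)
    units <- sample(pool, n_units)
  }
  dur <- result$meta$duration
  dt <- 1000 / fs
  grid <- seq(0, dur, by = dt)
  out <- numeric(length(grid))
  sp <- result$spikes
  times <- sp$time[sp$neuron %in% units & sp$time >= 0 & sp$time <= dur]
  for (t in times) {
    lo <- max(1, floor((t - 6 * sd_ms) / dt) + 1)
    hi <- min(length(grid), ceiling((t + 6 * sd_ms) / dt) + 1)
    out[lo:hi] <- out[lo:hi] + stats::dnorm(grid[lo:hi], t, sd_ms)
  }
  signal_series(out, fs, units = "events/ms",
                meta = list(units = units, n_spikes = length(times)))
}

#' MUA-LFP coherence
#'
#' Magnitude coherence `|S_xy| / sqrt(S_xx S_yy)` between the sector LFP
#' and the MUA of randomly chosen cell triplets, from Welch-averaged
#' cross-spectra, averaged over triplets.  Values lie in `[0, 1]`.
#'
#' @param result a `sim_result` with the sector's LFP recorded.
#' @param sector_center,sector_width sector, degrees.
#' @param n_triplets number of random triplets averaged.
#' @param n_units cells per triplet.
#' @param segment_s,overlap Welch parameters.
#' @return a `spectral_estimate` with `kind = "coherence"`.
#' @export
mua_lfp_coherence <- function(result, sector_center = 0, sector_width = 18,
                              n_triplets = 20, n_units = 3,
                              segment_s = 1, overlap = 0.5) {
  lfp <- lfp_signal(result, sector_center, sector_width)
  fs <- lfp$fs
  x <- lfp$samples - mean(lfp$samples)
  acc <- NULL
  for (k in seq_len(n_triplets)) {
    mua <- mua_signal(result, sector_center, sector_width,
                      n_units = n_units, fs = fs)
    y <- mua$samples[seq_along(x)]
    y <- y - mean(y)
    sxy <- .welch_xspec(x, y, fs, segment_s, overlap)
    sxx <- .welch_xspec(x, x, fs, segment_s, overlap)
    syy <- .welch_xspec(y, y, fs, segment_s, overlap)
    coh <- Mod(sxy$spec) / sqrt(pmax(Re(sxx$spec) * Re(syy$spec), 1e-300))
    acc <- if (is.null(acc)) coh else acc + coh
    freq <- sxy$freq
    nseg <- sxy$n_segments
  }
  structure(list(freq = freq, power = pmin(acc / n_triplets, 1),
                 kind = "coherence", n_segments = nseg,
                 normalization = "magnitude coherence"),
            class = "spectral_estimate")
}

# ---- population rate and PSTH ---------------------------------------------

#' Population spike-rate histogram
#'
#' Fraction of the selected neurons firing per time bin.
#'
#' @param result a `sim_result`.
#' @param bin_ms bin width, ms.
#' @param neurons neuron indices (default: upper-layer excitatory).
#' @return list with `t` (bin centers, ms) and `fraction`.
#' @export
population_rate <- function(result, bin_ms = 2, neurons = NULL) {
  layout <- result$meta$layout
  if (is.null(neurons))
    neurons <- which(layout$layer == "upper" & layout$pop == "excitatory")
  sp <- result$spikes
  sp <- sp[sp$neuron %in% neurons & sp$time >= 0 &
             sp$time <= result$meta$duration, ]
  breaks <- seq(0, result$meta$duration, by = bin_ms)
  h <- graphics::hist(sp$time, breaks = breaks, plot = FALSE)
  list(t = h$mids, fraction = h$counts / length(neurons))
}

#' Peristimulus time histogram
#'
#' Pools spikes of cells preferring the stimulus orientation (within
#' `half_width` degrees) across repeated flash presentations and trials;
#' each bar is (spikes in bin) / (number of presentations) / (number of
#' sampled cells).
#'
#' @param trials list of `sim_result` sharing a flashed-stimulus schedule.
#' @param bin_ms bin width, ms (must divide the stimulus period).
#' @param half_width selection half-width around the stimulus orientation,
#'   degrees.
#' @return list with `t` (time from stimulus onset, bin centers, ms),
#'   `probability`, `n_cells`, `n_presentations`.
#' @export
psth <- function(trials, bin_ms = 2, half_width = 5) {
  stim <- trials[[1]]$meta$stim
  if (stim$mode != "flash")
    stop("PSTH requires a flashed stimulus", call. = FALSE)
  period <- stim$on_ms + stim$off_ms
  if (abs(period / bin_ms - round(period / bin_ms)) > 1e-9)
    stop("bin width must divide the stimulus period", call. = FALSE)
  layout <- trials[[1]]$meta$layout
  cells <- which(layout$layer == "upper" & layout$pop == "excitatory" &
                   abs(wrap_angle(layout$theta - stim$orientation)) <=
                   half_width)
  breaks <- seq(0, period, by = bin_ms)
  counts <- numeric(length(breaks) - 1)
  n_pres <- 0
  for (tr in trials) {
    n_rep <- floor(tr$meta$duration / period)
    if (n_rep < 1) stop("trial shorter than one stimulus period", call. = FALSE)
    n_pres <- n_pres + n_rep
    sp <- tr$spikes
    sp <- sp[sp$neuron %in% cells & sp$time >= 0 &
               sp$time < n_rep * period, ]
    rel <- sp$time %% period
    counts <- counts + graphics::hist(rel, breaks = breaks,
                                      plot = FALSE)$counts
  }
  list(t = breaks[-1] - bin_ms / 2,
       probability = counts / n_pres / length(cells),
       n_cells = length(cells), n_presentations = n_pres)
}

#' Synchrony of a simulation's recorded voltages
#'
#' Convenience wrapper: chi over the recorded membrane potentials of the
#' upper-layer excitatory population (clipped at the spike-initiation
#' threshold).
#'
#' @param result a `sim_result` with voltages recorded.
#' @param clip clip at the excitatory threshold (default TRUE).
#' @return chi.
#' @export
chi_of_result <- function(result, clip = TRUE) {
  layout <- result$meta$layout
  keep <- which(layout$pop[result$v_neurons] == "excitatory" &
                  layout$layer[result$v_neurons] == "upper")
  v <- t(result$v[keep, , drop = FALSE])
  synchrony_chi(v, clip = if (clip)
    result$meta$spec$neurons$excitatory$v_thresh else NULL)
}
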