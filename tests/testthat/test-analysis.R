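test_that("tuning statistics match closed-form and quadrature oracles", {
  oris <- ring_angles(12)
  # flat curve: complete cancellation
  flat <- tuning_statistics(rep(3, 12), oris)
  expect_equal(flat$circular_variance, 1, tolerance = 1e-12)
  # single-orientation response: perfect tuning
  one <- rep(0, 12); one[4] <- 5
  expect_equal(tuning_statistics(one, oris)$circular_variance, 0)
  expect_equal(tuning_statistics(one, oris)$preferred, oris[4])
  # rectified cosine: independent complex-sum oracle on the same grid
  psi <- 15
  r <- pmax(cos(2 * (oris - psi) * pi / 180), 0)
  tc <- tuning_statistics(r, oris)
  m_oracle <- sum(r * exp(2i * oris * pi / 180)) / sum(r)
  expect_equal(1 - Mod(m_oracle), tc$circular_variance, tolerance = 1e-9)
  expect_equal(tc$preferred, psi, tolerance = 1e-6)
  expect_equal(tc$skewness, 0, tolerance = 1e-9)
  expect_error(tuning_statistics(rep(0, 12), oris), "all-zero")
})

test_that("contrast-response fits recover known parameters", {
  set.seed(3)
  cs <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.7, 1)
  truth <- function(C) 2 + 30 * C^1.2 / (C^1.2 + 0.1^1.2)
  rates <- truth(cs) * (1 + rnorm(length(cs), 0, 0.01))
  fit <- fit_crf(cs, rates)
  expect_false(fit$degenerate)
  expect_equal(fit$r_max, 30, tolerance = 0.05 * 30)
  expect_equal(fit$c50, 0.1, tolerance = 0.06)
  expect_equal(fit$exponent, 1.2, tolerance = 0.15)
  expect_equal(fit$baseline, 2, tolerance = 0.5)
  # fitted curve within the noise envelope at every sample
  expect_true(all(abs(fit$fitted - truth(cs)) < 0.05 * truth(cs) + 0.5))
  # constant data: degenerate flag
  expect_true(fit_crf(cs, rep(7, 8))$degenerate)
})

test_that("the synchrony measure has its analytic limiting values", {
  set.seed(5)
  base <- rnorm(4000)
  ident <- matrix(base, 4000, 12)
  expect_equal(synchrony_chi(ident), 1)
  # independent white noise: chi ~ N^{-1/2}
  for (N in c(8, 32)) {
    chis <- replicate(30, synchrony_chi(matrix(rnorm(3000 * N), 3000, N)))
    se <- sd(chis) / sqrt(30)
    expect_lt(abs(mean(chis) - 1 / sqrt(N)), 3 * se + 0.003)
  }
  # shared sinusoid + equal-power noise: chi^2 -> 1/2 + 1/(2N)
  N <- 16; L <- 20000
  shared <- sqrt(2) * sin(2 * pi * (1:L) / 80)  # unit variance
  chis <- replicate(20, {
    synchrony_chi(matrix(shared, L, N) + matrix(rnorm(L * N), L, N))
  })
  expect_equal(mean(chis), sqrt(1 / 2 + 1 / (2 * N)),
               tolerance = 3 * sd(chis) / sqrt(20) + 0.01)
  # invariance under common affine transforms
  x <- matrix(rnorm(1000 * 6), 1000, 6)
  expect_equal(synchrony_chi(3.2 * x - 40), synchrony_chi(x))
  expect_error(synchrony_chi(cbind(rnorm(100), rep(1, 100))), "zero-variance")
})

test_that("finite-size scaling fits recover closed forms", {
  sizes <- c(250, 500, 1000, 2000, 4000)
  exact <- chi_scaling(sizes, sizes^-0.5)
  expect_equal(exact$slope, -0.5, tolerance = 1e-9)
  expect_equal(exact$asymptote, 0, tolerance = 1e-6)
  sat <- chi_scaling(sizes, sqrt(0.25 + 1 / sizes))
  expect_equal(sat$asymptote, 0.5, tolerance = 0.01 * 0.5)
  set.seed(9)
  noisy <- chi_scaling(rep(sizes, each = 6),
                       rep(sizes, each = 6)^-0.5 * exp(rnorm(30, 0, 0.05)),
                       n_boot = 400)
  expect_true(noisy$slope_ci[1] < -0.5 && -0.5 < noisy$slope_ci[2])
  expect_error(chi_scaling(c(100, 100, 200), c(1, 1, 2)), "3 sizes")
})

test_that("correlograms satisfy their normalization contracts", {
  set.seed(2)
  x <- as.numeric(arima.sim(list(ar = 0.9), 5000))
  cg <- correlogram(x, x, max_lag = 50, fs = 1000)
  expect_equal(cg$value[cg$lag_ms == 0], 1)
  expect_equal(max(cg$value), 1)
  neg <- correlogram(x, -x, max_lag = 50, fs = 1000)
  expect_equal(neg$value[neg$lag_ms == 0], -1)
  raw <- correlogram(x, x, max_lag = 10, fs = 1000, normalized = FALSE)
  expect_equal(raw$value[raw$lag_ms == 0], mean((x - mean(x))^2))
  # independent OU-like traces: zero-lag value within the null band
  y <- as.numeric(arima.sim(list(ar = 0.9), 5000))
  n_eff <- 5000 * (1 - 0.9^2) / (1 + 0.9^2)  # effective samples for AR(1)
  cxy <- correlogram(x, y, max_lag = 5, fs = 1000)
  expect_lt(abs(cxy$value[cxy$lag_ms == 0]), 4 / sqrt(n_eff))
  expect_error(correlogram(x, x, max_lag = 6000, fs = 1000), "max_lag")
})

test_that("pairwise coefficients behave under null and common-rate models", {
  set.seed(11)
  # a train with itself
  tr <- sort(runif(400, 0, 1e4))
  sm <- smooth_spike_train(tr, 10, 1000, c(0, 1e4))$samples
  expect_equal(pairwise_cco(cbind(sm, sm))[1], 1)
  # independent Poisson trains: mean coefficient near zero
  mats <- vapply(1:8, function(k)
    smooth_spike_train(sort(runif(1000, 0, 1e5)), 10, 200,
                       c(0, 1e5))$samples, numeric(20001))
  ccos <- pairwise_cco(mats)
  expect_lt(abs(mean(ccos)), 3 * sd(ccos) / sqrt(length(ccos)) + 0.01)
  # common-rate-modulated pairs: positive mean matching the Cox oracle
  L <- 2e5
  rate <- 10 + 8 * sin(2 * pi * (1:L) / 5000)   # Hz, 1 ms steps
  lam <- rate * 1e-3
  cnt <- vapply(1:6, function(k) rpois(L, lam), numeric(L))
  w <- 25
  bins <- vapply(1:6, function(k) colSums(matrix(cnt[, k], nrow = w)),
                 numeric(L / w))
  obs <- mean(pairwise_cco(bins))
  rw <- colMeans(matrix(rate, nrow = w))
  covan <- var(rw) * (w * 1e-3)^2
  oracle <- covan / (mean(bins[, 1]) + covan)
  expect_equal(obs, oracle, tolerance = 0.25)
})

test_that("welch spectra identify lines, flatness and Lorentzian shapes", {
  fs <- 1000
  t <- (1:16000) / fs
  line <- signal_series(sin(2 * pi * 40 * t), fs)
  ps <- power_spectrum(line, segment_s = 1)
  expect_equal(ps$freq[which.max(ps$power)], 40, tolerance = 1)
  # white noise: flat within sampling fluctuation
  set.seed(13)
  wn <- power_spectrum(signal_series(rnorm(64000), fs), segment_s = 0.512)
  band <- wn$power[wn$freq > 20 & wn$freq < 480]
  expect_lt(sd(band) / mean(band), 3 / sqrt(wn$n_segments))
  # OU process: half-power near 1/(2 pi tau)
  tau <- 10e-3
  a <- exp(-1 / (fs * tau))
  ou <- as.numeric(arima.sim(list(ar = a), 2e5)) * sqrt(1 - a^2)
  po <- power_spectrum(signal_series(ou, fs), segment_s = 1, smooth_bins = 5)
  p0 <- mean(po$power[po$freq > 0.5 & po$freq < 4], na.rm = TRUE)
  fc <- 1 / (2 * pi * tau)
  half_band <- mean(po$power[abs(po$freq - fc) < 2], na.rm = TRUE)
  expect_equal(half_band / p0, 0.5, tolerance = 0.15)
  expect_error(power_spectrum(signal_series(rnorm(100), fs), segment_s = 1),
               "too short")
})

test_that("spectrum and autocorrelogram are Wiener-Khinchin consistent", {
  set.seed(17)
  fs <- 1000
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 2^12))
  xc <- x - mean(x)
  n <- length(xc)
  per <- Mod(fft(xc))^2 / n
  # time-domain autocovariance (no FFT involved)
  ac <- correlogram(xc, xc, max_lag = (n - 1) / fs * 1000, fs = fs,
                    normalized = FALSE)
  acv <- ac$value[ac$lag_ms >= 0]
  # the DTFT of the biased autocovariance over all lags equals the
  # periodogram exactly at the Fourier frequencies
  lags <- 0:(n - 1)
  for (k in c(5, 17, 60, 150, 400)) {
    s <- acv[1] + 2 * sum(acv[-1] * cos(2 * pi * k * lags[-1] / n))
    expect_equal(s, per[k + 1], tolerance = 1e-6 * max(per))
  }
})

test_that("MUA signals integrate to their spike count", {
  spec <- mini_spec()
  r <- run_simulation(spec, stimulus(0.95, 0), duration = 500, seed = 2,
                      warmup = 300)
  set.seed(1)
  mua <- mua_signal(r, 0, 18, n_units = 3)
  dt_s <- 1000 / mua$fs
  # edge spikes lose the Gaussian mass outside the recording window
  lay <- r$meta$layout
  times <- r$spikes$time[r$spikes$neuron %in% mua$meta$units &
                           r$spikes$time >= 0 &
                           r$spikes$time <= r$meta$duration]
  mass <- sum(pnorm((r$meta$duration - times) / 1) - pnorm(-times / 1))
  # rectangle-rule quadrature at the signal edges limits agreement
  expect_equal(sum(mua$samples) * dt_s, mass, tolerance = 1e-4)
  silent <- mua_signal(r, 0, 18, units = which(tabulate(r$spikes$neuron,
    nbins = r$meta$n_neurons) == 0)[1:3])
  expect_true(all(silent$samples == 0))
})

test_that("coherence is bounded and detects shared structure", {
  fs <- 1000
  set.seed(19)
  x <- as.numeric(arima.sim(list(ar = 0.8), 32000))
  # y = x: coherence 1 at every frequency
  cxy <- .welch_xspec(x, x, fs)
  coh <- Mod(cxy$spec) / sqrt(Re(cxy$spec) * Re(cxy$spec))
  expect_true(all(abs(coh - 1) < 1e-9))
  # independent signals: coherence below the Welch bias floor
  y <- as.numeric(arima.sim(list(ar = 0.8), 32000))
  sxy <- .welch_xspec(x, y, fs); sxx <- .welch_xspec(x, x, fs)
  syy <- .welch_xspec(y, y, fs)
  c2 <- Mod(sxy$spec) / sqrt(Re(sxx$spec) * Re(syy$spec))
  bias <- 1 / sqrt(sxy$n_segments)   # expected magnitude under independence
  expect_lt(mean(c2[5:400]), 3 * bias)
  # band-limited relation: filtered x + noise is coherent only in the band
  b <- signal::butter(4, c(0.1, 0.2))
  yf <- as.numeric(signal::filtfilt(b, x)) + rnorm(32000, 0, 0.05)
  sxy <- .welch_xspec(x, yf, fs); syy <- .welch_xspec(yf, yf, fs)
  c3 <- Mod(sxy$spec) / sqrt(pmax(Re(sxx$spec) * Re(syy$spec), 1e-300))
  inband <- mean(c3[sxy$freq > 55 & sxy$freq < 95])
  outband <- mean(c3[sxy$freq > 150 & sxy$freq < 400])
  expect_gt(inband, 0.8)
  expect_lt(outband, 0.35)
})

test_that("simulation-level coherence stays in the unit interval", {
  spec <- mini_spec()
  r <- run_simulation(spec, stimulus(0.95, 0), duration = 2000, seed = 4,
                      warmup = 300,
                      lfp_sectors = data.frame(center = 0, width = 18))
  set.seed(2)
  est <- mua_lfp_coherence(r, 0, 18, n_triplets = 4, segment_s = 0.5)
  expect_true(all(est$power >= 0 & est$power <= 1))
  expect_equal(est$kind, "coherence")
})

test_that("PSTH normalization matches the Poisson expectation", {
  # synthetic trials: homogeneous Poisson spiking in the selected cells
  spec <- tiny_spec(n_exc = 40, n_inh = 10)
  stim <- stimulus(0.8, 0, mode = "flash")
  lay <- network_layout(spec)
  cells <- which(lay$layer == "upper" & lay$pop == "excitatory" &
                   abs(wrap_angle(lay$theta)) <= 5)
  rate <- 10  # Hz
  dur <- 6000
  set.seed(23)
  mk_trial <- function(seed) {
    sp <- do.call(rbind, lapply(cells, function(i) {
      n <- rpois(1, rate * dur / 1000)
      data.frame(neuron = i, time = sort(runif(n, 0, dur)))
    }))
    structure(list(spikes = sp,
                   meta = list(stim = stim, layout = lay, duration = dur,
                               n_neurons = nrow(lay))),
              class = "sim_result")
  }
  trials <- lapply(1:40, mk_trial)
  h <- psth(trials, bin_ms = 2, half_width = 5)
  expected <- rate * 0.002
  se <- sqrt(expected / (h$n_presentations * h$n_cells))
  expect_lt(max(abs(h$probability - expected)), 5 * se)
  # variance scaling: doubling trials halves the bar SE
  se1 <- sd(psth(trials[1:10], 2)$probability)
  se2 <- sd(psth(trials[1:40], 2)$probability)
  expect_equal(log(se2 / se1) / log(4), -0.5, tolerance = 0.3)
  # empty input
  silent <- mk_trial(1); silent$spikes <- silent$spikes[0, ]
  expect_true(all(psth(list(silent), 2)$probability == 0))
  expect_error(psth(trials, bin_ms = 7), "divide")
})
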