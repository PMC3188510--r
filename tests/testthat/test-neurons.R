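exc <- default_spec()$neurons$excitatory
inh <- default_spec()$neurons$inhibitory
soft <- default_spec()$refractory$excitatory
hard <- default_spec()$refractory$inhibitory

test_that("spike nonlinearity matches its closed form", {
  expect_equal(spike_nonlinearity(-45.2, -45.2, 1.2), 1.2)
  expect_equal(spike_nonlinearity(-45.2 + 1.2, -45.2, 1.2), 1.2 * exp(1))
  expect_lt(spike_nonlinearity(-45.2 - 50 * 1.2, -45.2, 1.2), 1e-20)
  # derivative of the integrated trajectory reproduces the nonlinearity:
  # dV/dt at V with zero input is (E_L - V + Psi(V)) / tau_m
  v0 <- -44
  st <- neuron_state(exc, v0)
  num <- (rk4_step(function(t, y) {
    s <- st; s$v <- y
    membrane_rhs(s, 0, exc)
  }, 0, v0, 1e-4) - v0) / 1e-4
  expect_equal(num, (exc$e_leak - v0 + spike_nonlinearity(v0, exc$v_thresh,
                                                          exc$slope)) / exc$tau_m,
               tolerance = 1e-4)
})

test_that("membrane right-hand side combines leak, spike term and current", {
  st <- neuron_state(exc, exc$e_leak)
  expect_equal(membrane_rhs(st, 0, exc),
               spike_nonlinearity(exc$e_leak, exc$v_thresh, exc$slope) /
                 exc$tau_m)
  expect_lt(membrane_rhs(st, 0, exc), 1e-5)  # rest sits at the leak potential
  expect_equal(membrane_rhs(st, 0.26, exc) - membrane_rhs(st, 0, exc), 1.0)
  # increasing the slope factor well above V_T weakens the exponential drive
  v_grid <- seq(exc$v_thresh + 2, exc$v_thresh + 6, by = 0.5)
  expect_true(all(spike_nonlinearity(v_grid, exc$v_thresh, 2 * exc$slope) <
                    spike_nonlinearity(v_grid, exc$v_thresh, exc$slope)))
})

test_that("resting potential is the stable sub-threshold root", {
  # bisection oracle, independent of uniroot
  f <- function(v) exc$e_leak - v + spike_nonlinearity(v, exc$v_thresh, exc$slope)
  lo <- -70; hi <- exc$v_thresh - 2
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(resting_potential(exc), (lo + hi) / 2, tolerance = 1e-6)
  expect_equal(resting_potential(exc), -57.8, tolerance = 1e-3)
  # vanishing slope factor limit: rest -> leak potential
  small <- exc; small$slope <- 1e-6
  expect_equal(resting_potential(small), exc$e_leak, tolerance = 1e-5)
  degen <- exc; degen$e_leak <- exc$v_thresh + 5
  expect_error(resting_potential(degen), "no stable")
})

test_that("post-spike update applies the tabulated offsets", {
  st <- post_spike_update(neuron_state(exc), exc, soft, spike_time = 100)
  expect_equal(st$v, exc$v_reset)
  expect_equal(st$v_thresh - exc$v_thresh, 22.9 + 13.5)
  expect_equal(st$slope - exc$slope, 10.0)
  expect_equal(st$inv_tau_m - 1 / exc$tau_m, 0.14)
  # all offsets back within 1% of their amplitude after 10 relaxation times
  relaxed <- relax_effective_params(st, exc, soft, 10 * 76.2)
  expect_lt(abs(relaxed$v_thresh - exc$v_thresh), 0.01 * 36.4)
  expect_lt(abs(relaxed$slope - exc$slope), 0.01 * 10)
  # hard mode: reset plus suspension window, no parameter change
  sti <- post_spike_update(neuron_state(inh), inh, hard, spike_time = 100)
  expect_equal(sti$v, inh$v_reset)
  expect_equal(sti$refractory_until, 100 + 2)
  expect_equal(sti$v_thresh, inh$v_thresh)
})

test_that("divergence-time extrapolation matches fine-grained integration", {
  expect_equal(time_to_divergence(exc$v_thresh, exc, check = FALSE),
               exc$tau_m)
  v0 <- exc$v_thresh + 10 * exc$slope  # the cutoff
  t_ana <- time_to_divergence(v0, exc)
  expect_equal(t_ana, exc$tau_m * exp(-10), tolerance = 1e-12)
  # brute-force sub-microsecond integration of the full equation with leak
  v <- v0; t <- 0; h <- t_ana / 5000
  while (v < v0 + 400 && t < 10 * t_ana) {
    v <- v + h * (exc$e_leak - v +
                    spike_nonlinearity(v, exc$v_thresh, exc$slope)) / exc$tau_m
    t <- t + h
  }
  expect_equal(t_ana, t, tolerance = 0.02)
  # monotone decrease with depolarization
  vg <- seq(v0, v0 + 5, by = 0.5)
  expect_true(all(diff(time_to_divergence(vg, exc)) < 0))
  expect_error(time_to_divergence(-50, exc), "divergence-dominated")
})

test_that("a quiescent neuron converges to rest from any sub-threshold start", {
  vr <- resting_potential(exc)
  for (v0 in c(-75, -65, -57, -50, -46.5)) {
    out <- integrate_single_neuron(exc, 0, duration = 600, dt = 0.2, v0 = v0)
    expect_length(out$spikes, 0)
    expect_equal(tail(out$v, 1), vr, tolerance = 1e-3)
  }
})

test_that("cutoff-and-extrapolation spike times match a fine reference", {
  # constant supra-threshold current; reference at a 1000x finer step
  i_const <- 0.4
  coarse <- integrate_single_neuron(exc, i_const, duration = 120, dt = 0.2)
  fine <- integrate_single_neuron(exc, i_const, duration = 120, dt = 0.0002)
  expect_gte(length(coarse$spikes), 3)
  expect_lt(max(abs(coarse$spikes[1:3] - fine$spikes[1:3])), 0.02)
})

test_that("RK4 exhibits fourth-order convergence on a linear system", {
  f <- function(t, y) -0.7 * y + sin(3 * t)
  exact <- function(h) {
    y <- 1
    for (k in seq_len(round(4 / h))) y <- rk4_step(f, (k - 1) * h, y, h)
    y
  }
  # reference via very small step
  ref <- exact(1e-4)
  errs <- vapply(c(0.4, 0.2, 0.1), function(h) abs(exact(h) - ref),
                 numeric(1))
  order <- log(errs[1] / errs[3]) / log(4)
  expect_gt(order, 3.6)
})
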