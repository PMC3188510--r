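test_that("angular wrap and ring placement respect orientation periodicity", {
  expect_equal(wrap_angle(95), -85)
  expect_equal(wrap_angle(-95), 85)
  expect_equal(wrap_angle(0), 0)
  th <- ring_angles(8)
  expect_equal(th[1], -90)
  expect_equal(diff(th), rep(180 / 8, 7))
})

test_that("connection probability is the rectified tuned profile", {
  expect_equal(connection_probability(0, 0.24, 0.12), 0.36)
  expect_equal(connection_probability(90, 0.06, 0.18), 0)
  expect_equal(connection_probability(-90, 0.06, 0.18), 0)
  # ring average without rectification equals p0 (numerical integration)
  avg <- integrate(function(x) connection_probability(x, 0.24, 0.12),
                   -90, 90)$value / 180
  expect_equal(avg, 0.24, tolerance = 1e-8)
  expect_error(connection_probability(0, 0.9, 0.2), "exceeds 1")
})

test_that("expected out-degrees reproduce the connectivity table", {
  # intra-layer I -> E at reference size
  expect_equal(expected_out_degree(0.24, 0.12, 4000), 960, tolerance = 1e-6)
  # lower E -> upper I: rectification active since p1 > p0; the wired
  # profile is renormalized so the mean target count stays p0 x size
  deg <- expected_out_degree(0.07, 0.16, 1000)
  expect_equal(deg, 70, tolerance = 0.02)
  # independent quadrature oracle: normalized rectified profile
  raw_mean <- integrate(function(x)
    pmax(0.07 + 0.16 * cos(2 * x * pi / 180), 0), -90, 90,
    rel.tol = 1e-10)$value / 180
  oracle <- 1000 * integrate(function(x)
    pmax(0.07 + 0.16 * cos(2 * x * pi / 180), 0) * 0.07 / raw_mean,
    -90, 90, rel.tol = 1e-10)$value / 180
  expect_equal(deg, oracle, tolerance = 1e-8)
})

test_that("wiring draws are reproducible and respect the pathway structure", {
  spec <- tiny_spec(n_exc = 60, n_inh = 15)
  n1 <- build_network(spec, seed = 5)
  n2 <- build_network(spec, seed = 5)
  expect_identical(n1$src, n2$src)
  expect_identical(n1$tgt, n2$tgt)
  expect_identical(wiring_checksum(n1), wiring_checksum(n2))
  n3 <- build_network(spec, seed = 6)
  expect_false(identical(n1$src, n3$src))
  expect_true(all(n1$src != n1$tgt))  # no autapses
})

test_that("realized out-degrees match the binomial expectation", {
  spec <- tiny_spec(n_exc = 120, n_inh = 30)
  tab <- pathway_table(spec)
  k <- which(tab$source_pop == "inhibitory" & !tab$interlayer &
               tab$source_layer == "upper")[1]
  # expectation of the scaled profile summed over excitatory targets
  th_s <- ring_angles(spec$n_inh)
  th_t <- ring_angles(spec$n_exc)
  pmat <- scaled_connection_probability(
    wrap_angle(outer(th_s, th_t, "-")), tab[k, ])
  expected <- mean(rowSums(pmat))
  degs <- unlist(lapply(1:50, function(s)
    realized_out_degrees(build_network(spec, seed = s), k)))
  se <- sd(degs) / sqrt(length(degs))
  expect_lt(abs(mean(degs) - expected), 3 * se + 1e-9)
  # per-seed totals within 5 SD of the binomial expectation
  tot <- vapply(1:10, function(s)
    sum(realized_out_degrees(build_network(spec, seed = s), k)), numeric(1))
  sd_bin <- sqrt(sum(pmat * (1 - pmat)))
  expect_true(all(abs(tot - sum(pmat)) < 5 * sd_bin))
})

test_that("expected degree profile is translation invariant", {
  spec <- tiny_spec(n_exc = 120, n_inh = 30)
  k <- which(pathway_table(spec)$source_pop == "inhibitory" &
               pathway_table(spec)$source_layer == "upper" &
               !pathway_table(spec)$interlayer)[1]
  degs <- sapply(1:40, function(s)
    realized_out_degrees(build_network(spec, seed = s), k))
  per_neuron <- rowMeans(degs)
  # compare three source angles: all should share the same expectation
  picks <- round(c(1, spec$n_inh / 2, spec$n_inh - 1))
  se <- sd(degs) / sqrt(ncol(degs))
  expect_lt(diff(range(per_neuron[picks])), 6 * se)
})

test_that("intra-layer inhibition dominates excitation at all distances", {
  tab <- pathway_table(default_spec())
  ie <- tab[tab$source_pop == "inhibitory" & !tab$interlayer &
              tab$target_pop == "excitatory" & tab$source_layer == "upper", ]
  ee <- tab[tab$source_pop == "excitatory" & !tab$interlayer &
              tab$target_pop == "excitatory" & tab$source_layer == "upper", ]
  dth <- seq(-89, 89, by = 1)
  expect_true(all(scaled_connection_probability(dth, ie[1, ]) >
                    scaled_connection_probability(dth, ee[1, ])))
})

test_that("the inter-layer scale acts only on inter-layer conductances", {
  spec <- tiny_spec(n_exc = 60, n_inh = 15)
  net <- build_network(spec, seed = 2)
  inter <- net$gamma_scaled
  w1 <- net$w_fast
  half <- apply_interlayer_scale(net, 0.5)
  expect_equal(half$w_fast[inter], 0.5 * w1[inter])
  expect_equal(half$w_fast[!inter], w1[!inter])
  # absolute rescaling: applying 0.5 twice is still 0.5, not 0.25
  again <- apply_interlayer_scale(half, 0.5)
  expect_equal(again$w_fast, half$w_fast)
  # gamma = 0 zeroes inter-layer conductances but adjacency remains drawn
  zero <- apply_interlayer_scale(net, 0)
  expect_true(all(zero$w_fast[inter] == 0))
  expect_equal(length(zero$src), length(net$src))
  expect_error(apply_interlayer_scale(net, 1.2), "gamma")
  # identity at gamma = 1
  one <- apply_interlayer_scale(net, 1)
  expect_equal(one$w_fast, w1)
})
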