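# Miniature deterministic network specs used across the suite.  All fixtures
# are generated in code; nothing is read from disk.

tiny_spec <- function(n_exc = 40, n_inh = 10, seed = 11L, ...) {
  spec <- scale_network(default_spec(master_seed = seed), n_exc, n_inh)
  mods <- list(...)
  for (nm in names(mods)) spec[[nm]] <- mods[[nm]]
  spec
}

# the miniature fixture size used for end-to-end runs (500 neurons total)
mini_spec <- function(seed = 11L) {
  scale_network(default_spec(master_seed = seed), 200, 50)
}

quiet_spec <- function(...) {
  # all external drives silenced: only wiring remains
  spec <- tiny_spec(...)
  spec$lgn$rate_offset <- 0
  spec$lgn$rate_gain <- 0
  spec$background$mean_rate <- 1e-9
  spec$background$volatility <- 0
  spec
}
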