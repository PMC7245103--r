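# Small networks used across tests, built in code.

# monomer + a single corner-dimer channel: A + A <-> A2
dimer_network <- function(params = rate_params(), channels = c("both", "corner")) {
  channels <- match.arg(channels)
  sp <- enumerate_species(2)
  if (channels == "corner") sp <- sp[sp$id != "M2e", ]
  net <- enumerate_reactions(sp, 2)
  assign_base_constants(net, params)
}

# parameters that make the corner dimerization channel have an effective
# forward constant of exactly 1 (mu = 1/2 for two monomers)
unit_dimer_params <- function(...) {
  rate_params(D = 1, k_nano = 0, temperature = 0.5, volume = 1, ...)
}

# the full default assembly network, built once per test session
giant_network_cache <- new.env(parent = emptyenv())
giant_network <- function(params = rate_params()) {
  if (is.null(giant_network_cache$net)) {
    giant_network_cache$net <- mob_network(154, params)
  }
  assign_base_constants(giant_network_cache$net, params)
}

# exact stationary mean dimer count of the A + A <-> A2 birth-death chain
# with N0 monomers, forward constant kf (propensity kf * n (n-1) / 2) and
# reverse constant kr (propensity kr * d), by exhaustive state enumeration
dimer_equilibrium_mean <- function(N0, kf = 1, kr = 1) {
  dmax <- N0 %/% 2L
  log_pi <- numeric(dmax + 1L)
  for (d in seq_len(dmax)) {
    n_before <- N0 - 2L * (d - 1L)
    a_f <- kf * n_before * (n_before - 1) / 2
    a_r <- kr * d
    log_pi[d + 1L] <- log_pi[d] + log(a_f) - log(a_r)
  }
  w <- exp(log_pi - max(log_pi))
  sum((0:dmax) * w) / sum(w)
}
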