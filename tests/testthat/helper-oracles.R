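# Shared fixtures and independent oracles, built in code at test time.

# Vectorized ensemble Monte Carlo of the scalar synapse dynamics: n_syn
# independent synapses, each receiving `burn + record` presentation cycles
# (jump from the rule's class mixture + Gaussian noise, then one unit of
# decay). Returns the pooled samples recorded at the pre-presentation phase
# after burn-in: draws from the stationary distribution g_inf.
single_synapse_mc <- function(params, n_syn = 2e4, burn = NULL, record = 5,
                              seed = 42) {
  if (is.null(burn)) burn <- max(200, ceiling(20 * tau(params)))
  cls <- dwsyn:::rule_classes(params)
  withr::with_seed(seed, {
    J <- numeric(n_syn)
    out <- vector("list", record)
    k <- exp(-2 * params$r1)
    for (t in seq_len(burn + record)) {
      I <- sample(cls$I, n_syn, replace = TRUE, prob = cls$prob)
      jump <- params$r2 * I
      if (params$r3 > 0) jump <- jump + params$r3 * rnorm(n_syn)
      J <- J + jump
      pos <- J > 0
      J[pos] <- params$C + (J[pos] - params$C) * k
      J[!pos & J < 0] <- -params$C + (J[!pos & J < 0] + params$C) * k
      if (t > burn) out[[t - burn]] <- J
    }
    unlist(out)
  })
}

# Kolmogorov-Smirnov distance between a sample and a gridded density.
ks_to_density <- function(samples, dens) {
  cdf_grid <- cumsum(dens$density) * dens$dx
  emp <- ecdf(samples)
  # evaluate at cell right edges
  max(abs(emp(dens$grid + dens$dx / 2) - cdf_grid))
}

# A priori KS bound: half-cell discretization shift plus 3x the sampling
# fluctuation scale (both computable without looking at the comparison).
ks_bound <- function(dens, n_samples) {
  dens$dx * max(dens$density) / 2 + 3 * 1.36 / sqrt(n_samples)
}

# Small balanced parameter set used across tests (modest tau so stationary
# distributions converge quickly).
params_small <- function(...) {
  dwsyn::dw_params(C = 2, r1 = 0.2, r2 = 1, r3 = 0, theta = 0,
                   f = 0.5, c = 0.1, N = 2000, ...)
}
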