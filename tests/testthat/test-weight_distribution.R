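# Master-equation solver for the synaptic weight distribution.

delta_density <- function(at, n = 801, lo = -4, hi = 4, phase = 0) {
  grid <- seq(lo, hi, length.out = n)
  dx <- (hi - lo) / (n - 1)
  g <- numeric(n)
  g[which.min(abs(grid - at))] <- 1 / dx
  weight_density(grid, g, phase = phase)
}

test_that("moments integrate point masses, mixtures and uniform densities", {
  p <- params_small()
  d1 <- delta_density(2)
  expect_equal(moments(d1)$mean, 2, tolerance = 1e-9)
  expect_equal(moments(d1)$rms, 2, tolerance = 1e-9)
  # half at +C, half at -C
  grid <- seq(-4, 4, length.out = 801)
  g <- numeric(801)
  g[which.min(abs(grid - 2))] <- 0.5
  g[which.min(abs(grid + 2))] <- 0.5
  d2 <- weight_density(grid, g / (sum(g) * 0.01), phase = 1)
  expect_equal(moments(d2)$mean, 0, tolerance = 1e-9)
  expect_equal(moments(d2)$rms, 2, tolerance = 1e-9)
  # uniform on [-1, 1]: rms = 1/sqrt(3) (up to cell-edge quadrature)
  gu <- as.numeric(abs(grid) <= 1)
  du <- weight_density(grid, gu / (sum(gu) * 0.01), phase = 1)
  expect_equal(moments(du)$mean, 0, tolerance = 1e-9)
  expect_equal(moments(du)$rms, 1 / sqrt(3), tolerance = 1e-2)
})

test_that("decay transport fixes the wells, contracts single wells, keeps symmetry", {
  p <- params_small() # C = 2
  dC <- delta_density(2)
  out <- evolve_decay(dC, p, dt = 1)
  expect_equal(moments(out)$mean, 2, tolerance = 1e-6)
  expect_equal(sum(out$density) * out$dx, 1, tolerance = 1e-9)
  # C = 0: a centered Gaussian contracts by e^{-2 r1 dt} in std
  p0 <- dw_params(C = 0, r1 = 0.3)
  grid <- seq(-6, 6, length.out = 2401)
  dx <- grid[2] - grid[1]
  g <- dnorm(grid, 0, 1)
  d0 <- weight_density(grid, g / (sum(g) * dx), phase = 0)
  out0 <- evolve_decay(d0, p0, dt = 1)
  expect_equal(moments(out0)$rms, exp(-0.6), tolerance = 1e-2)
  # mirror symmetry is preserved exactly by the transport
  gs <- dnorm(grid, 2, 0.7) + dnorm(grid, -2, 0.7)
  ds <- weight_density(grid, gs / (sum(gs) * (grid[2] - grid[1])), phase = 0)
  outs <- evolve_decay(ds, params_small(), dt = 0.7)
  expect_equal(outs$density, rev(outs$density), tolerance = 1e-12)
  # dead zone is empty after decay (the exact center is excluded: this test
  # grid has a point at J = 0, the unstable equilibrium, which maps to
  # itself by convention)
  k <- exp(-2 * params_small()$r1 * 0.7)
  dead <- abs(outs$grid) < 2 * (1 - k) - outs$dx & outs$grid != 0
  expect_true(all(outs$density[dead] == 0))
})

test_that("a presentation splits a balanced point mass into two half masses", {
  p <- dw_params(C = 2, r1 = 0.2, r2 = 1)
  d0 <- delta_density(0)
  out <- apply_presentation(d0, p)
  expect_equal(sum(out$density) * out$dx, 1, tolerance = 1e-9)
  m <- moments(out)
  expect_equal(m$mean, 0, tolerance = 1e-9)
  expect_equal(m$rms, 1, tolerance = 1e-6) # half at -r2, half at +r2
  mass_near <- function(d, at) {
    sum(d$density[abs(d$grid - at) <= d$dx]) * d$dx
  }
  expect_gt(mass_near(out, 1), 0.49)
  expect_gt(mass_near(out, -1), 0.49)
})

test_that("zero input leaves the density unchanged and noise adds variance", {
  p_null <- dw_params(C = 2, r1 = 0.2, r2 = 0, r3 = 0)
  d <- delta_density(1.5)
  expect_equal(apply_presentation(d, p_null)$density, d$density,
               tolerance = 1e-12)
  p_noise <- dw_params(C = 2, r1 = 0.2, r2 = 1, r3 = 0.4)
  out <- apply_presentation(d, p_noise)
  expect_equal(sum(out$density) * out$dx, 1, tolerance = 1e-9)
  # variance = jump-mixture variance + r3^2
  expect_equal(moments(out)$rms^2, 1.5^2 + 1 + 0.4^2, tolerance = 1e-3)
})

test_that("asymptotic distribution is symmetric, normalized and stationary", {
  p <- params_small()
  g <- asymptotic_distribution(p)
  expect_equal(sum(g$density) * g$dx, 1, tolerance = 1e-9)
  expect_equal(moments(g)$mean, 0, tolerance = 1e-8) # balanced symmetry
  expect_equal(g$density, rev(g$density), tolerance = 1e-6)
  # fixed point of one full cycle
  g2 <- evolve_decay(apply_presentation(g, p), p, dt = 1)
  expect_equal(g2$density, g$density, tolerance = 1e-6)
  expect_error(asymptotic_distribution(dw_params(C = 0, r1 = 0)),
               "no stationary density")
})

test_that("single-well stationary variance matches the AR(1) closed forms", {
  for (r1 in c(0.1, 0.3)) {
    p <- dw_params(C = 0, r1 = r1, r2 = 1, r3 = 0)
    g <- asymptotic_distribution(p)
    v_pre <- 1 * exp(-4 * r1) / (1 - exp(-4 * r1))
    expect_equal(moments(g)$rms^2, v_pre, tolerance = 1e-3)
    # just after the presentation jump the variance gains r2^2
    g_post <- apply_presentation(g, p)
    expect_equal(moments(g_post)$rms^2, 1 / (1 - exp(-4 * r1)),
                 tolerance = 1e-3)
  }
})

test_that("deep wells concentrate the stationary mass onto +/- C", {
  p <- dw_params(C = 2, r1 = 5, r2 = 1)
  g <- asymptotic_distribution(p)
  near <- function(at) sum(g$density[abs(g$grid - at) <= g$dx]) * g$dx
  expect_gte(near(2), 0.49)
  expect_gte(near(-2), 0.49)
})

test_that("the stationary density matches single-synapse Monte Carlo", {
  p <- dw_params(C = 2, r1 = 0.1, r2 = 1, r3 = 0)
  g <- asymptotic_distribution(p)
  samples <- single_synapse_mc(p, n_syn = 4e4, record = 5)
  expect_gte(length(samples), 2e5)
  expect_lt(ks_to_density(samples, g), ks_bound(g, length(samples)))
  # with plasticity noise as well
  pn <- dw_params(C = 2, r1 = 0.2, r2 = 1, r3 = 0.5)
  gn <- asymptotic_distribution(pn)
  sn <- single_synapse_mc(pn, n_syn = 4e4, record = 5)
  expect_lt(ks_to_density(sn, gn), ks_bound(gn, length(sn)))
})

test_that("conditional distributions shift, relax and mirror correctly", {
  p <- params_small()
  g <- asymptotic_distribution(p)
  cond <- conditional_distributions(g, p, ages = c(0, 1, 5, 200))
  # age 0, potentiated class: the stationary density shifted by +r2
  m0 <- cond$mean[cond$sigma == 1 & cond$age == 0]
  expect_equal(m0, p$r2, tolerance = 1e-6)
  # balanced mirror identity g_{sigma}(J, t) = g_{-sigma}(-J, t) at all ages
  for (a in c(0, 1, 5)) {
    gp <- cond$density[cond$sigma == 1 & cond$age == a][[1]]
    gm <- cond$density[cond$sigma == -1 & cond$age == a][[1]]
    expect_equal(gp$density, rev(gm$density), tolerance = 1e-9)
  }
  # old tags relax back to the symmetric stationary density (the inter-well
  # component decays on the slow 1/(2q) timescale, hence the loose bound)
  m_old <- cond$mean[cond$sigma == 1 & cond$age == 200]
  expect_equal(m_old, 0, tolerance = 1e-4)
  # re-mixing the conditional densities with their priors restores g_inf
  for (a in c(1, 5)) {
    sub <- cond[cond$age == a, ]
    mix <- Reduce(`+`, Map(function(d, w) w * d$density, sub$density,
                           sub$prob))
    expect_equal(mix, g$density, tolerance = 1e-6)
  }
})

test_that("conditional moment curve decays exponentially for a single well", {
  p <- dw_params(C = 0, r1 = 0.25, r2 = 1, N = 1000)
  g <- asymptotic_distribution(p)
  cm <- conditional_moments(g, p, max_age = 12)
  expect_equal(cm$mean, exp(-2 * 0.25 * cm$age), tolerance = 1e-2)
  expect_equal(cm$rms, rep(sqrt(exp(-1) / (1 - exp(-1))), 12),
               tolerance = 1e-2)
})
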