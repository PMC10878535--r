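# Binarized SNR and the matched two-state Markov synapse.

test_that("binarize takes the sign and resolves zeros randomly", {
  expect_equal(binarize(c(2.7, -0.3, 0.01)), c(1L, -1L, 1L))
  set.seed(1)
  z <- binarize(rep(0, 2000))
  expect_true(all(z %in% c(-1L, 1L)))
  expect_lt(abs(mean(z)), 0.1)
})

test_that("double-well SNR vanishes without learning and relaxes to zero", {
  p0 <- dw_params(C = 2, r1 = 0.2, r2 = 0)
  expect_equal(snr_double_well(p0, 0:5, cN = 1000)$snr, rep(0, 6))
  p <- params_small()
  curve <- meanfield_curve(p)
  # the inter-well occupancy relaxes on the slow 1/(2q) timescale, so the
  # age must be deep into that regime before the SNR is gone
  s <- snr_double_well(p, c(0, 1, 2, 2000), cN = 1000, curve = curve)
  expect_gt(s$snr[1], 0)
  expect_equal(s$snr[4], 0, tolerance = 1e-4)
})

test_that("matched Markov transitions reflect the well-switching probabilities", {
  # no input, no noise: nothing ever switches
  p0 <- dw_params(C = 2, r1 = 0.2, r2 = 0, r3 = 0)
  ms0 <- matched_markov(p0)
  expect_equal(ms0$M_pot, diag(2), ignore_attr = TRUE)
  expect_equal(ms0$M_dep, diag(2), ignore_attr = TRUE)
  # balanced mirror symmetry: potentiation and depression are mirror images
  p <- dw_params(C = 1.5, r1 = 0.3, r2 = 1)
  ms <- matched_markov(p)
  expect_equal(ms$M_pot[2, 1], ms$M_dep[1, 2], tolerance = 1e-9)
  expect_equal(ms$M_pot[1, 2], ms$M_dep[2, 1], tolerance = 1e-9)
  expect_equal(colSums(ms$M_pot), c(1, 1), ignore_attr = TRUE)
  # deep narrow wells: a potentiation always lifts the low well across
  pd <- dw_params(C = 0.4, r1 = 20, r2 = 1)
  msd <- matched_markov(pd)
  expect_gt(msd$M_pot[2, 1], 0.999)
  mc <- single_synapse_mc(pd, n_syn = 2e4, record = 1)
  flips <- mean(sign(decay_map(mc[mc < 0] + 1, pd, 1)) > 0)
  expect_equal(msd$M_pot[2, 1], flips, tolerance = 1e-3)
})

test_that("Markov SNR has its structural identities", {
  q <- 0.12
  M_pot <- matrix(c(1 - q, q, 0, 1), 2, 2)
  M_dep <- matrix(c(1, 0, q, 1 - q), 2, 2)
  ms <- list(M_pot = M_pot, M_dep = M_dep,
             W = (M_pot + M_dep) / 2 - diag(2), w = c(-1, 1),
             p_inf = c(0.5, 0.5))
  expect_equal(snr_markov(ms, 0, cN = 2000), sqrt(2000) * q)
  # identical matrices carry no signal
  ms_null <- ms
  ms_null$M_dep <- M_pot
  ms_null$W <- M_pot - diag(2)
  expect_equal(snr_markov(ms_null, 0:5, cN = 2000), rep(0, 6))
  bad <- ms
  bad$M_pot <- matrix(c(0.5, 0.1, 0, 1), 2, 2)
  expect_error(snr_markov(bad, 1, 100), "stochastic")
})

test_that("Markov SNR agrees with a brute-force two-state chain", {
  q_pot <- 0.1
  q_dep <- 0.08
  M_pot <- matrix(c(1 - q_pot, q_pot, 0, 1), 2, 2)
  M_dep <- matrix(c(1, 0, q_dep, 1 - q_dep), 2, 2)
  # stationary distribution of the averaged chain
  flip_up <- q_pot / 2
  flip_dn <- q_dep / 2
  p_lo <- flip_dn / (flip_up + flip_dn)
  ms <- list(M_pot = M_pot, M_dep = M_dep,
             W = (M_pot + M_dep) / 2 - diag(2), w = c(-1, 1),
             p_inf = c(p_lo, 1 - p_lo))
  cN <- 2000
  ages <- c(0, 1, 2, 5, 10)
  sn_disc <- snr_markov(ms, ages, cN, method = "discrete")
  # Monte Carlo: chains at stationarity receive a potentiation, then t
  # random events; the signal is the mean efficacy of the potentiated pool
  n <- 2e5
  set.seed(8)
  w <- ifelse(runif(n) < p_lo, -1, 1)
  flip <- function(w, q_up, q_dn) {
    u <- runif(n)
    ifelse(w < 0 & u < q_up, 1, ifelse(w > 0 & u < q_dn, -1, w))
  }
  w <- flip(w, q_pot, 0) # the tagged potentiation event
  mc <- numeric(length(ages))
  t_now <- 0
  for (i in seq_along(ages)) {
    while (t_now < ages[i]) {
      pot <- runif(n) < 0.5
      w_new <- flip(w, q_pot, 0)
      w_alt <- flip(w, 0, q_dep)
      w <- ifelse(pot, w_new, w_alt)
      t_now <- t_now + 1
    }
    mc[i] <- mean(w)
  }
  # E[w|pot] - E[w|dep] = 2 (E[w|pot] - stationary mean), since the mean
  # operator leaves the stationary distribution invariant
  mc_snr <- sqrt(cN) * (mc - (1 - 2 * p_lo))
  se <- sqrt(cN) * 3 / sqrt(n)
  expect_true(all(abs(mc_snr - sn_disc) < pmax(3 * se, 0.02 * abs(sn_disc))))
  # the matrix-exponential form tracks the discrete chain at small q
  sn_exp <- snr_markov(ms, ages, cN, method = "exponential")
  expect_true(all(abs(sn_exp - sn_disc) <=
                    0.05 * pmax(abs(sn_disc), max(abs(sn_disc)) * 0.05)))
})

test_that("matched model and double-well model share the initial SNR", {
  p <- dw_params(C = 1.5, r1 = 0.3, r2 = 1, r3 = 0)
  g <- asymptotic_distribution(p)
  ms <- matched_markov(p, g_inf = g)
  s_dw <- snr_double_well(p, 0, cN = 2000, g_inf = g)$snr
  s_mk <- snr_markov(ms, 0, cN = 2000)
  expect_equal(s_dw, s_mk, tolerance = 1e-9)
})

test_that("the envelope bound dominates two-state chains and is continuous", {
  cN <- 2000
  expect_equal(snr_markov_bound(0, cN), sqrt(cN))
  expect_equal(snr_markov_bound(1 - 1e-12, cN), snr_markov_bound(1 + 1e-12, cN),
               tolerance = 1e-9)
  expect_error(snr_markov_bound(-0.1, cN), "non-negative")
  # brute-force scan over symmetric and asymmetric chains
  ts <- c(0, 0.5, 1, 2, 5, 10, 20)
  bound <- snr_markov_bound(ts, cN)
  qs <- c(0.001, 0.005, 0.02, 0.05, 0.1, 0.2, 0.4, 0.7, 1)
  worst <- -Inf
  for (qp in qs) for (qd in qs) {
    M_pot <- matrix(c(1 - qp, qp, 0, 1), 2, 2)
    M_dep <- matrix(c(1, 0, qd, 1 - qd), 2, 2)
    p_lo <- (qd / 2) / (qp / 2 + qd / 2)
    ms <- list(M_pot = M_pot, M_dep = M_dep,
               W = (M_pot + M_dep) / 2 - diag(2), w = c(-1, 1),
               p_inf = c(p_lo, 1 - p_lo))
    s <- snr_markov(ms, ts, cN)
    worst <- max(worst, max(s - bound))
  }
  expect_lte(worst, 1e-8)
})
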