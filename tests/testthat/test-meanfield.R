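# Mean-field retrieval theory (balanced coding).

test_that("conditional field moments vanish without overlap and have the closed form", {
  p <- dw_params(C = 2, r1 = 0.2, N = 5000, c = 0.1)
  fm0 <- conditional_field_moments(list(m_v = 0, m_u = 0), p, M = 0.5,
                                   Omega = 2)
  expect_equal(as.numeric(fm0$mu), rep(0, 4))
  expect_equal(fm0$d, 2 * sqrt(0.1 * 0.5 / 5000))
  # closed form mu^{s_v s_u} = (c/2) (+/- A m_v +/- r2 m_u)
  st <- list(m_v = 0.8, m_u = 0.1)
  fm <- conditional_field_moments(st, p, M = 0.5, Omega = 2)
  A <- 0.5
  expect_equal(fm$mu["1", "1"], 0.1 / 2 * (A * 0.8 + 1 * 0.1))
  expect_equal(fm$mu["1", "0"], 0.1 / 2 * (A * 0.8 - 1 * 0.1))
  expect_equal(fm$mu["0", "0"], -fm$mu["1", "1"]) # balanced symmetry
  expect_equal(fm$mu["0", "1"], -fm$mu["1", "0"])
  # at full retrieval the mean equals the direct expectation c A / 2
  fm1 <- conditional_field_moments(list(m_v = 1, m_u = 0), p, M = 0.5,
                                   Omega = 2)
  expect_equal(fm1$mu["1", "1"], 0.1 * 0.5 / 2)
})

test_that("overlap update has the Gaussian tail limits", {
  mk <- function(mu11, mu10, d) {
    list(mu = matrix(c(0, mu10, 0, mu11), 2, 2,
                     dimnames = list(s_v = 0:1, s_u = 0:1)), d = d)
  }
  # mu11 = mu10: the two terms cancel in m_u
  s <- overlap_update(list(m_v = 0.5, m_u = 0), mk(0.3, 0.3, 0.1))
  expect_equal(s$m_u, 0)
  # strong signal: m_v -> 1, m_u -> 0
  s2 <- overlap_update(list(m_v = 0.5, m_u = 0), mk(50, 50, 0.1))
  expect_equal(s2$m_v, 1, tolerance = 1e-9)
  expect_equal(s2$m_u, 0, tolerance = 1e-9)
  # overwhelming noise: both overlaps vanish
  s3 <- overlap_update(list(m_v = 0.5, m_u = 0), mk(0.3, 0.2, 1e6))
  expect_equal(s3$m_v, 0, tolerance = 1e-5)
  expect_equal(s3$m_u, 0, tolerance = 1e-5)
  expect_error(overlap_update(list(m_v = 0, m_u = 0), mk(1, 1, 0)), "positive")
})

test_that("the retrieval iteration matches the general field-moment path", {
  p <- dw_params(C = 2, r1 = 0.2, N = 5000, c = 0.1)
  cur <- meanfield_curve(p)
  for (age in c(1, 3)) {
    fast <- solve_retrieval(age, p, cur)
    # reference: iterate via the exported general functions
    A <- cur$M[age]
    Om <- sqrt(cur$Omega[age]^2 + p$r2^2 + p$r3^2)
    st <- list(m_v = 1, m_u = 0.05)
    for (i in 1:5000) {
      new <- overlap_update(st, conditional_field_moments(st, p, A, Om))
      if (abs(new$m_v - st$m_v) < 1e-8 && abs(new$m_u - st$m_u) < 1e-8) {
        st <- new
        break
      }
      st <- new
    }
    expect_equal(fast$m_v, st$m_v, tolerance = 1e-6)
    expect_equal(fast$m_u, st$m_u, tolerance = 1e-6)
  }
})

test_that("retrieval succeeds at small age and fails beyond capacity", {
  p <- dw_params(C = 0, r1 = 0.1, N = 1e4, c = 0.05)
  cur <- meanfield_curve(p)
  s1 <- solve_retrieval(1, p, cur)
  expect_true(s1$stable)
  expect_gt(s1$m_v, 0.9)
  cap <- capacity_meanfield(p, curve = cur)
  expect_gt(cap$p, 0)
  s_beyond <- solve_retrieval(cap$p + 1, p, cur)
  expect_false(s_beyond$stable)
  # the overlap curve is non-increasing up to the collapse
  tab <- tidy(cap)
  expect_true(all(diff(tab$m_v[seq_len(cap$p)]) < 1e-6))
})

test_that("capacity is zero without learning and decreases with well depth", {
  expect_equal(capacity_meanfield(dw_params(C = 1, r1 = 0.2, r2 = 0))$p, 0)
  caps <- vapply(c(0.05, 0.1, 0.2), function(r1) {
    optimize_C(dw_params(r1 = r1, N = 5000, c = 0.05),
               C_grid = seq(0, 6, by = 0.5), refine = 1)$p_star
  }, numeric(1))
  expect_true(all(diff(caps) < 0))
})

test_that("single-well capacity grows logarithmically with N, faster for shallower wells", {
  Ns <- c(2e3, 2e4, 2e5)
  caps <- sapply(c(0.05, 0.1), function(r1) {
    cur <- meanfield_curve(dw_params(C = 0, r1 = r1))
    sapply(Ns, function(N) {
      dwsyn:::mf_capacity_int(dw_params(C = 0, r1 = r1, N = N, c = 0.05), cur)
    })
  })
  # increments per decade roughly constant (log growth), not accelerating
  for (j in 1:2) {
    inc <- diff(caps[, j])
    expect_true(all(inc > 0))
    expect_lt(inc[2], 2.5 * inc[1])
    expect_gt(inc[2], inc[1] / 2.5)
  }
  # the shallower well stores more at every size
  expect_true(all(caps[, 1] > caps[, 2]))
})

test_that("mean-field capacity is invariant under the dynamical rescaling", {
  p <- dw_params(C = 2, r1 = 0.2, r2 = 1, N = 4000, c = 0.1)
  x <- 3
  q <- rescale_params(p, x, r1_scaling = "dynamical")
  gs <- dwsyn:::resolve_grid(p)
  p_cap <- capacity_meanfield(p, curve = meanfield_curve(
    p, n_grid = gs$n_grid, J_min = gs$J_min, J_max = gs$J_max))$p
  # scale the grid with the weights so the discretization is identical
  q_cap <- capacity_meanfield(q, curve = meanfield_curve(
    q, n_grid = gs$n_grid, J_min = x * gs$J_min, J_max = x * gs$J_max))$p
  expect_equal(q_cap, p_cap)
})

test_that("optimize_C returns grid argmax with ties toward smaller C", {
  p <- dw_params(r1 = 0.2, N = 2000, c = 0.1)
  opt <- optimize_C(p, C_grid = c(1.5), refine = 0)
  expect_equal(opt$C_star, 1.5) # degenerate single-point grid
  expect_error(optimize_C(p, C_grid = numeric(0)), "empty")
  opt2 <- optimize_C(p, C_grid = seq(0, 4, by = 1), refine = 0)
  best <- min(opt2$table$C[opt2$table$p == max(opt2$table$p)])
  expect_equal(opt2$C_star, best)
})

test_that("scaling fits recover exact power laws and log forms", {
  N <- c(1e3, 1e4, 1e5, 1e6)
  fit_lin <- fit_scaling_exponent(N, 0.02 * N)
  expect_equal(fit_lin$exponent, 1, tolerance = 1e-10)
  fit_sqrt <- fit_scaling_exponent(N, 3 * sqrt(N))
  expect_equal(fit_sqrt$exponent, 0.5, tolerance = 1e-10)
  fit_log <- fit_scaling_exponent(N, 40 * log(N / 200))
  expect_equal(fit_log$a_log, 40, tolerance = 1e-8)
  expect_equal(fit_log$b_log, 200, tolerance = 1e-6)
  expect_error(fit_scaling_exponent(N, c(0, 1, 2, 3)), "positive")
  expect_equal(nrow(tidy(fit_sqrt)), 2)
  expect_equal(glance(fit_sqrt)$r_squared_power, 1, tolerance = 1e-10)
})
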