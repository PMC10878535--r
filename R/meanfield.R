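# Mean-field theory of retrieval for the balanced case (f = 1/2, theta = 0).
#
# The local field of a neuron, conditioned on its states (s_v, s_u) in the
# probed pattern (age u - v) and the most recent pattern, is Gaussian with
# mean mu^{s_v s_u} and std d. The means are built from the conditional
# weight-distribution moments; iterating the resulting overlap map to a fixed
# point decides whether the probed pattern is still a stable attractor.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Phi(x) = (1/sqrt(pi)) int_0^x e^{-t^2} dt = erf(x) / 2, an odd function
# saturating at +/- 1/2.
mf_phi <- function(x) erf(x) / 2

#' Conditional local-field moments
#'
#' Given the current overlaps `(m_v, m_u)` with the probed and the most
#' recent pattern, and the conditional weight moments at the probed age
#' (mean `M` of the potentiated-class distribution and RMS `Omega`), returns
#' the mean local field `mu^{s_v s_u}` for each combination of the neuron's
#' states in the two patterns, and the common field standard deviation `d`.
#'
#' The mean sums over the presynaptic states `(s, s')` in the two patterns
#' with their prior probability (1/4 each at balance), weighting the
#' conditional weight mean `M_{sigma_v sigma_u}` — where
#' `sigma = (2 a - 1)(2 b - 1)` pairs the postsynaptic with the presynaptic
#' state — by the probability `P(s, s')` that the presynaptic neuron is
#' active. The std is `d = Omega sqrt(c f / N)` with mean activity
#' `f = 1/2`, the central-limit std of the field sum.
#'
#' @param state List or vector with elements `m_v`, `m_u`, both in `[-1, 1]`.
#' @param params A [dw_params()] object (balanced rule, `f = 0.5`,
#'   `theta = 0`).
#' @param M Mean of the potentiated-class conditional distribution at the
#'   probed age, pre-presentation (the depressed class is its mirror image).
#' @param Omega RMS of the conditional weight distribution at retrieval
#'   time, i.e. after the most recent presentation (the presentation adds
#'   `r2^2 + r3^2` to the pre-presentation variance; only the average of
#'   the field depends on which jump the synapse received).
#' @return A list with `mu` (2 x 2 matrix indexed by `s_v + 1`, `s_u + 1`)
#'   and `d`.
#' @export
conditional_field_moments <- function(state, params, M, Omega) {
  stopifnot(params$rule == "balanced", abs(params$f - 0.5) < 1e-12,
            abs(params$theta) < 1e-12)
  m_v <- state$m_v
  m_u <- state$m_u
  r2 <- params$r2
  # P(presynaptic neuron active | eta^v = s, eta^u = s'): Bayes combination
  # of the two single-pattern conditionals, normalized by the baseline
  # activity 1/2 so that the table averages to the balanced mean activity
  # (P = 2 * p_v(s) * p_u(s'); the bare product would average to 1/4).
  p_act <- function(s, sp) {
    2 * (s * m_v + (1 - m_v) / 2) * (sp * m_u + (1 - m_u) / 2)
  }
  mu <- matrix(0, 2, 2, dimnames = list(s_v = 0:1, s_u = 0:1))
  for (s_v in 0:1) {
    for (s_u in 0:1) {
      acc <- 0
      for (s in 0:1) {
        for (sp in 0:1) {
          sig_v <- (2 * s_v - 1) * (2 * s - 1)
          sig_u <- (2 * s_u - 1) * (2 * sp - 1)
          M_cond <- sig_v * M + sig_u * r2 # conditional mean at u+
          acc <- acc + 0.25 * M_cond * p_act(s, sp)
        }
      }
      mu[s_v + 1, s_u + 1] <- params$c * acc
    }
  }
  d <- Omega * sqrt(params$c * 0.5 / params$N)
  if (!is.finite(d) || d <= 0) stop("field std must be positive", call. = FALSE)
  list(mu = mu, d = d)
}

#' One step of the overlap self-consistency map
#'
#' Updates the overlaps from the Gaussian conditional field moments:
#' `m_v <- Phi(mu10 / (sqrt(2) d)) - Phi(-mu11 / (sqrt(2) d))` and
#' `m_u <- Phi(-mu10 / (sqrt(2) d)) - Phi(-mu11 / (sqrt(2) d))`, with
#' `Phi(x) = erf(x)/2`. The `sqrt(2) d` denominator makes the two terms
#' exactly the Gaussian probabilities `P(h_{11} > 0)` and `P(h_{10} <> 0)`
#' of a field with std `d`.
#'
#' @param state List with current `m_v`, `m_u`.
#' @param fm Field moments as returned by [conditional_field_moments()].
#' @return A list with updated `m_v`, `m_u`.
#' @export
overlap_update <- function(state, fm) {
  d <- fm$d
  if (d <= 0) stop("`d` must be positive", call. = FALSE)
  mu11 <- fm$mu["1", "1"]
  mu10 <- fm$mu["1", "0"]
  s2d <- sqrt(2) * d
  list(
    m_v = mf_phi(mu10 / s2d) - mf_phi(-mu11 / s2d),
    m_u = mf_phi(-mu10 / s2d) - mf_phi(-mu11 / s2d)
  )
}

# --- cached conditional-moment curve -----------------------------------------
# The mean-field inputs at age t are the conditional moments M(t), Omega(t)
# (and, for the SNR, the signed mass) of the potentiated-class distribution,
# which do not depend on N or c. They are computed once per (C, r1, r2, r3)
# and extended lazily in age, so capacity searches and N-sweeps reuse them.

#' Conditional moment curve engine
#'
#' Computes the stationary distribution `g_inf` and prepares a lazily
#' extended record of the potentiated-class conditional moments
#' (`M(t)`, `Omega(t)`) and signed mass over age. Used internally by
#' [capacity_meanfield()], [optimize_C()] and [snr_double_well()]; exposed so
#' that sweeps over `N` can share one curve per potential shape.
#'
#' @inheritParams asymptotic_distribution
#' @param g_inf Optionally a precomputed [asymptotic_distribution()].
#' @return An environment of class `dw_mf_curve` with fields `M`, `Omega`,
#'   `S` (signed mass), `T` (ages computed so far) and `g_inf`.
#' @export
meanfield_curve <- function(params, g_inf = NULL, n_grid = NULL,
                            J_min = NULL, J_max = NULL,
                            tol = 1e-10, max_iter = 1e5, seed = 1) {
  stopifnot(params$rule == "balanced")
  if (is.null(g_inf)) {
    g_inf <- asymptotic_distribution(params, n_grid, J_min, J_max,
                                     tol = tol, max_iter = max_iter,
                                     seed = seed)
  }
  eng <- density_engine(params, length(g_inf$grid), min(g_inf$grid),
                        max(g_inf$grid))
  shift_pot <- push_matrix(eng$grid, eng$grid + params$r2)
  g0 <- as.numeric(shift_pot %*% g_inf$density)
  if (!is.null(eng$kernel)) g0 <- convolve_fold(g0, eng$kernel)
  g <- engine_decay(eng, g0) # age 1, pre-presentation
  cur <- new.env(parent = emptyenv())
  cur$params <- params
  cur$eng <- eng
  cur$g_inf <- g_inf
  cur$state <- g
  cur$T <- 1L
  cur$M <- sum(g * eng$grid) * eng$dx
  cur$Omega <- sqrt(sum(g * eng$grid^2) * eng$dx)
  cur$S <- sum(g * sign(eng$grid)) * eng$dx
  class(cur) <- "dw_mf_curve"
  cur
}

# Extend the curve in place up to age T.
extend_curve <- function(cur, T) {
  T <- as.integer(T)
  if (cur$T >= T) return(invisible(cur))
  eng <- cur$eng
  g <- cur$state
  n_new <- T - cur$T
  M <- numeric(n_new); Om <- numeric(n_new); S <- numeric(n_new)
  for (i in seq_len(n_new)) {
    g <- engine_cycle(eng, g)
    M[i] <- sum(g * eng$grid) * eng$dx
    Om[i] <- sqrt(sum(g * eng$grid^2) * eng$dx)
    S[i] <- sum(g * sign(eng$grid)) * eng$dx
  }
  cur$state <- g
  cur$M <- c(cur$M, M)
  cur$Omega <- c(cur$Omega, Om)
  cur$S <- c(cur$S, S)
  cur$T <- T
  invisible(cur)
}

#' Solve the retrieval fixed point at a given age
#'
#' Iterates the overlap self-consistency map from the stability-protocol
#' initial condition `(m_v, m_u) = (1, 0.05)` — a retrieval state perturbed
#' toward the most recent pattern — until both overlaps change by less than
#' `tol`. The probed pattern is classed as retrievable when the iteration
#' settles at `m_v > 0` with `m_u` near 0; flows to the recent pattern or to
#' the zero state are classed unstable.
#'
#' @param age Pattern age (integer >= 1).
#' @param params A [dw_params()] object (balanced scope).
#' @param curve A [meanfield_curve()] for these parameters (built on the fly
#'   when `NULL`).
#' @param eps Initial perturbation toward the most recent pattern.
#' @param tol Convergence tolerance on both overlaps.
#' @param max_iter Iteration cap.
#' @return A list with `m_v`, `m_u`, `stable`, `converged`, `iterations`.
#' @export
solve_retrieval <- function(age, params, curve = NULL, eps = 0.05,
                            tol = 1e-8, max_iter = 1e4) {
  if (is.null(curve)) curve <- meanfield_curve(params)
  extend_curve(curve, age)
  A <- curve$M[age]
  # post-presentation RMS at retrieval time
  Omega <- sqrt(curve$Omega[age]^2 + params$r2^2 + params$r3^2)
  d <- Omega * sqrt(params$c * 0.5 / params$N)
  # hot loop: closed form of conditional_field_moments() at balance,
  # mu^{11,10} = (c/2)(A m_v +/- r2 m_u) (equivalence asserted in tests)
  k <- params$c / 2
  r2 <- params$r2
  s2d <- sqrt(2) * d
  m_v <- 1
  m_u <- eps
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    z11 <- k * (A * m_v + r2 * m_u) / s2d
    z10 <- k * (A * m_v - r2 * m_u) / s2d
    e11 <- 2 * stats::pnorm(z11 * sqrt(2)) - 1
    e10 <- 2 * stats::pnorm(z10 * sqrt(2)) - 1
    m_v_new <- (e10 + e11) / 2
    m_u_new <- (e11 - e10) / 2
    done <- abs(m_v_new - m_v) < tol && abs(m_u_new - m_u) < tol
    m_v <- m_v_new
    m_u <- m_u_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  stable <- converged && m_v > 1e-2 && abs(m_u) < 1e-2
  list(m_v = m_v, m_u = m_u, stable = stable,
       converged = converged, iterations = iter)
}

# Internal integer capacity: largest stable age. Exponential bracketing and
# bisection (retrievability is monotone in age over most of parameter
# space), followed by a forward verification scan: the conditional mean
# M(t) of deep-well synapses can be non-monotone at small ages (probability
# flux between wells lags the tagged jump, the same mechanism that makes
# the binarized SNR non-monotone), so stable ages can reappear beyond the
# first unstable one.
mf_capacity_int <- function(params, curve, max_age = 1e6) {
  if (params$r2 == 0) return(0L)
  stable_at <- function(a) solve_retrieval(a, params, curve)$stable
  p <- 0L
  if (stable_at(1L)) {
    lo <- 1L
    hi <- 2L
    while (hi <= max_age && stable_at(hi)) {
      lo <- hi
      hi <- hi * 2L
    }
    if (hi > max_age) return(lo)
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (stable_at(mid)) lo <- mid else hi <- mid
    }
    p <- lo
  }
  # forward scan past the bisection result for re-entrant stable ages
  repeat {
    win <- max(20L, p %/% 4L)
    ages <- (p + 1L):min(p + win, max_age)
    found <- 0L
    for (a in ages) if (stable_at(a)) found <- a
    if (found == 0L || found >= max_age) break
    p <- found
  }
  p
}

#' Mean-field storage capacity
#'
#' The storage capacity `p` is the largest age at which the retrieval fixed
#' point survives the stability protocol of [solve_retrieval()]. Found by
#' exponential bracketing then bisection over age.
#'
#' @inheritParams solve_retrieval
#' @param max_age Safety cap on the age search.
#' @return An object of class `dw_capacity`: a list with `p`, `params` and
#'   the moment `curve` used. `tidy()` returns the overlap-vs-age table.
#' @examples
#' p <- dw_params(C = 0, r1 = 0.2, N = 2000, c = 0.1)
#' capacity_meanfield(p)$p
#' @export
capacity_meanfield <- function(params, curve = NULL, max_age = 1e6) {
  stopifnot(inherits(params, "dw_params"), params$rule == "balanced")
  if (is.null(curve)) curve <- meanfield_curve(params)
  p <- mf_capacity_int(params, curve, max_age)
  structure(list(p = p, params = params, curve = curve, method = "meanfield"),
            class = "dw_capacity")
}

#' @export
print.dw_capacity <- function(x, ...) {
  cat(sprintf("<dw_capacity> p = %d (%s; C = %g, r1 = %g, N = %d)\n",
              x$p, x$method, x$params$C, x$params$r1, x$params$N))
  invisible(x)
}

#' Overlap-vs-age table for a capacity result
#'
#' @param x A `dw_capacity` object.
#' @param ages Ages to tabulate (default `1..p+1`).
#' @param ... Unused.
#' @return A tibble with columns `age`, `m_v`, `m_u`, `stable`.
#' @importFrom generics tidy
#' @export
tidy.dw_capacity <- function(x, ages = NULL, ...) {
  if (is.null(ages)) ages <- seq_len(max(x$p + 1L, 1L))
  if (x$method != "meanfield") return(x$probes)
  rows <- lapply(ages, function(a) {
    s <- solve_retrieval(a, x$params, x$curve)
    tibble::tibble(age = a, m_v = s$m_v, m_u = s$m_u, stable = s$stable)
  })
  dplyr::bind_rows(rows)
}

#' @importFrom generics glance
#' @export
glance.dw_capacity <- function(x, ...) {
  tibble::tibble(p = x$p, method = x$method, C = x$params$C,
                 r1 = x$params$r1, r2 = x$params$r2, r3 = x$params$r3,
                 N = x$params$N, c = x$params$c)
}

#' Mean-field capacity over a grid of potential widths and network sizes
#'
#' Sweeps `capacity_meanfield()` over `C` and `N`, reusing the conditional
#' moment curve of each `C` across all `N` (the curve does not depend on
#' `N`).
#'
#' @param params Template [dw_params()] (balanced).
#' @param C Vector of potential half-widths.
#' @param N Vector of network sizes (default: the template's `N`).
#' @param curves Optional environment used to cache curves across calls.
#' @inheritParams asymptotic_distribution
#' @return A tibble with columns `C`, `N`, `p`.
#' @export
capacity_sweep_meanfield <- function(params, C, N = params$N, curves = NULL,
                                     n_grid = NULL, J_min = NULL,
                                     J_max = NULL, seed = 1) {
  if (is.null(curves)) curves <- new.env(parent = emptyenv())
  grid <- tidyr::expand_grid(C = C, N = N)
  grid$p <- NA_integer_
  for (cc in unique(grid$C)) {
    pc <- modify_params(params, C = cc)
    gs <- resolve_grid(pc, n_grid, J_min, J_max)
    key <- sprintf("C=%.10g|r1=%.10g|r2=%.10g|r3=%.10g|n=%d|%.6g",
                   cc, params$r1, params$r2, params$r3, gs$n_grid, gs$J_max)
    if (is.null(curves[[key]])) {
      curves[[key]] <- meanfield_curve(pc, n_grid = gs$n_grid,
                                       J_min = gs$J_min, J_max = gs$J_max,
                                       seed = seed)
    }
    cur <- curves[[key]]
    for (nn in unique(grid$N)) {
      pn <- modify_params(params, C = cc, N = nn)
      idx <- grid$C == cc & grid$N == nn
      grid$p[idx] <- mf_capacity_int(pn, cur)
    }
  }
  grid
}

# Copy a dw_params with some fields replaced.
modify_params <- function(params, ...) {
  upd <- list(...)
  args <- unclass(params)
  # keep amit_fusi defaults tied to C/f unless explicitly overridden
  retie_I1 <- !("I1" %in% names(upd)) && abs(args$I1 - 2 * args$C) < 1e-12
  retie_I2 <- !("I2" %in% names(upd)) &&
    abs(args$I2 + args$f * (1 - args$f)) < 1e-12
  args[names(upd)] <- upd
  if (retie_I1) args$I1 <- 2 * args$C
  if (retie_I2) args$I2 <- -args$f * (1 - args$f)
  do.call(dw_params, args)
}

#' Capacity-optimal potential width
#'
#' Maximizes the mean-field storage capacity over a grid of potential
#' half-widths `C`, optionally refining the grid around the coarse argmax.
#' Ties are broken toward smaller `C`.
#'
#' @param params Template [dw_params()] (balanced).
#' @param C_grid Candidate half-widths (default 41 points on
#'   `[0, 8 r2]`).
#' @param refine Number of local grid-refinement rounds around the argmax
#'   (each shrinks the bracket to the two neighboring grid cells).
#' @param refine_points Points per refinement round.
#' @param curves Optional cache environment (see
#'   [capacity_sweep_meanfield()]).
#' @inheritParams asymptotic_distribution
#' @return An object of class `dw_copt`: list with `C_star`, `p_star` and
#'   the search `table` (tibble of `C`, `N`, `p`).
#' @export
optimize_C <- function(params, C_grid = NULL, refine = 2, refine_points = 11,
                       curves = NULL, n_grid = NULL, J_min = NULL,
                       J_max = NULL, seed = 1) {
  if (is.null(C_grid)) C_grid <- seq(0, 8 * params$r2, length.out = 41)
  if (length(C_grid) == 0) stop("`C_grid` is empty", call. = FALSE)
  stopifnot(all(C_grid >= 0))
  if (is.null(curves)) curves <- new.env(parent = emptyenv())
  C_grid <- sort(unique(C_grid))
  tab <- capacity_sweep_meanfield(params, C = C_grid, N = params$N,
                                  curves = curves, n_grid = n_grid,
                                  J_min = J_min, J_max = J_max, seed = seed)
  best <- function(t) {
    i <- which(t$p == max(t$p))
    i[which.min(t$C[i])] # ties toward smaller C
  }
  for (r in seq_len(refine)) {
    if (length(C_grid) < 2) break
    i <- best(tab)
    Cb <- tab$C[i]
    neighb <- sort(tab$C)
    j <- match(Cb, neighb)
    lo <- if (j > 1) neighb[j - 1] else Cb
    hi <- if (j < length(neighb)) neighb[j + 1] else Cb
    if (hi - lo < 1e-6) break
    C_new <- setdiff(seq(lo, hi, length.out = refine_points), tab$C)
    if (length(C_new) == 0) break
    tab <- dplyr::bind_rows(
      tab,
      capacity_sweep_meanfield(params, C = C_new, N = params$N,
                               curves = curves, n_grid = n_grid,
                               J_min = J_min, J_max = J_max, seed = seed)
    )
  }
  tab <- dplyr::arrange(tab, .data$C)
  i <- best(tab)
  structure(list(C_star = tab$C[i], p_star = tab$p[i], table = tab,
                 params = params),
            class = "dw_copt")
}

#' @export
print.dw_copt <- function(x, ...) {
  cat(sprintf("<dw_copt> C* = %g, p* = %d (r1 = %g, N = %d; %d grid points)\n",
              x$C_star, x$p_star, x$params$r1, x$params$N, nrow(x$table)))
  invisible(x)
}

#' @export
tidy.dw_copt <- function(x, ...) x$table

#' Fit the capacity scaling with network size
#'
#' Fits both functional forms used for capacity-vs-size curves: the power
#' law `p = k N^a` (least squares on `log p` vs `log N`) and the logarithmic
#' form `p = a log(N / b)` (least squares of `p` on `log N`).
#'
#' @param N Network sizes (at least 3).
#' @param p Capacities, all `> 0`.
#' @return An object of class `dw_scaling`; `tidy()` gives one row per form
#'   with the fitted parameters, `glance()` gives the residual standard
#'   errors and R-squared of both fits.
#' @examples
#' fit <- fit_scaling_exponent(c(1e3, 1e4, 1e5), c(30, 95, 300))
#' tidy(fit)
#' @export
fit_scaling_exponent <- function(N, p) {
  stopifnot(length(N) == length(p), length(N) >= 3)
  if (any(p <= 0)) stop("all capacities must be positive", call. = FALSE)
  pow <- stats::lm(log(p) ~ log(N))
  logf <- stats::lm(p ~ log(N))
  a_log <- unname(stats::coef(logf)[2])
  b_log <- unname(exp(-stats::coef(logf)[1] / a_log))
  structure(list(
    exponent = unname(stats::coef(pow)[2]),
    prefactor = unname(exp(stats::coef(pow)[1])),
    a_log = a_log, b_log = b_log,
    power_fit = pow, log_fit = logf,
    data = tibble::tibble(N = N, p = p)
  ), class = "dw_scaling")
}

#' @export
print.dw_scaling <- function(x, ...) {
  cat(sprintf("<dw_scaling> power law: p = %.3g * N^%.4g | log form: p = %.4g * log(N / %.4g)\n",
              x$prefactor, x$exponent, x$a_log, x$b_log))
  invisible(x)
}

#' @export
tidy.dw_scaling <- function(x, ...) {
  tibble::tibble(
    form = c("power", "log"),
    term = c("exponent", "prefactor"),
    estimate = c(x$exponent, x$a_log),
    companion = c(x$prefactor, x$b_log)
  )
}

#' @export
glance.dw_scaling <- function(x, ...) {
  tibble::tibble(
    r_squared_power = summary(x$power_fit)$r.squared,
    r_squared_log = summary(x$log_fit)$r.squared,
    sigma_power = summary(x$power_fit)$sigma,
    sigma_log = summary(x$log_fit)$sigma,
    n = nrow(x$data)
  )
}

#' Critical potential depth for the single-to-double-well transition
#'
#' Estimates `r1*`, the smallest decay rate at which the capacity-optimal
#' potential half-width becomes nonzero: below `r1*` a single-well potential
#' (`C* = 0`) maximizes capacity, above it a double well wins. Scans the
#' supplied `r1` grid for the first supercritical point, then bisects the
#' bracketing interval to the requested resolution.
#'
#' @param params Template [dw_params()] (balanced).
#' @param r1_grid Sorted grid of candidate `r1` values spanning the
#'   transition.
#' @param C_grid Candidate half-widths passed to [optimize_C()].
#' @param N_ref Reference network size.
#' @param resolution Bisection stops when the bracket is narrower than this.
#' @param refine Refinement rounds for [optimize_C()].
#' @param verbose Print progress to stderr.
#' @return The estimated `r1*` (bracket midpoint) with attributes `bracket`
#'   and `evaluations` (tibble of `r1`, `C_star`, `p_star`).
#' @export
estimate_r1_star <- function(params, r1_grid = c(0.004, 0.012),
                             C_grid = seq(0, 8, length.out = 41),
                             N_ref = 2e4, resolution = 5e-4, refine = 1,
                             verbose = FALSE) {
  stopifnot(length(r1_grid) >= 2, !is.unsorted(r1_grid))
  evals <- list()
  supercritical <- function(r1) {
    pr <- modify_params(params, r1 = r1, N = N_ref)
    opt <- optimize_C(pr, C_grid = C_grid, refine = refine)
    evals[[length(evals) + 1L]] <<-
      tibble::tibble(r1 = r1, C_star = opt$C_star, p_star = opt$p_star)
    if (verbose) {
      message(sprintf("  r1 = %.5f: C* = %.3f, p* = %d",
                      r1, opt$C_star, opt$p_star))
    }
    opt$C_star > 0
  }
  status <- vapply(r1_grid, supercritical, logical(1))
  if (all(status) || !any(status)) {
    stop("the single-to-double-well transition is outside `r1_grid`",
         call. = FALSE)
  }
  i <- which(status)[1]
  if (i == 1) stop("smallest grid r1 is already supercritical", call. = FALSE)
  lo <- r1_grid[i - 1]
  hi <- r1_grid[i]
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (supercritical(mid)) hi <- mid else lo <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "bracket") <- c(lo, hi)
  attr(out, "evaluations") <- dplyr::bind_rows(evals)
  out
}
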