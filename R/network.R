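# Direct simulation of the binary attractor network with online double-well
# synaptic learning. Learning is driven by clamped external patterns; the
# neuronal dynamics only enter at retrieval time, which is read-only for the
# weights.

#' Generate random binary patterns
#'
#' I.i.d. Bernoulli(`f`) binary patterns, reproducible from a seed. For the
#' sparse-coding protocol use `f = 4 * log(N) / N`.
#'
#' @param N Number of neurons.
#' @param f Coding level in (0, 1).
#' @param count Number of patterns.
#' @param seed RNG seed.
#' @return An `N x count` integer matrix of class `dw_patterns` with
#'   attributes `f` and `seed`.
#' @examples
#' eta <- generate_patterns(100, 0.5, count = 10, seed = 1)
#' colMeans(eta)
#' @export
generate_patterns <- function(N, f, count, seed = 1) {
  stopifnot(f > 0, f < 1, N >= 2, count >= 1)
  pats <- withr_seed(seed, matrix(
    as.integer(stats::runif(N * count) < f), nrow = N, ncol = count))
  structure(pats, f = f, seed = seed, class = c("dw_patterns", "matrix"))
}

#' Coding level for the sparse protocol
#'
#' The sparse-coding scaling `f = 4 log(N) / N` used in the sparse-coding
#' experiments.
#'
#' @param N Network size.
#' @return The coding level.
#' @export
sparse_coding_level <- function(N) 4 * log(N) / N

#' Construct a network with random sparse connectivity
#'
#' Samples the fixed connectivity mask (`c_ij` i.i.d. Bernoulli(`c`),
#' asymmetric, zero diagonal) and initializes the synaptic weights, either at
#' zero or by i.i.d. draws from the master-equation stationary distribution
#' `g_inf` (which removes the need for a long burn-in at small `r1`).
#'
#' @param params A [dw_params()] object.
#' @param seed Seed for the connectivity mask (and equilibrium weight draw).
#' @param init `"zero"` starts all weights at 0; `"equilibrium"` draws them
#'   from [asymptotic_distribution()].
#' @param g_inf Optional precomputed stationary density for
#'   `init = "equilibrium"`.
#' @return An object of class `dw_network`.
#' @export
dw_network <- function(params, seed = 1, init = c("zero", "equilibrium"),
                       g_inf = NULL) {
  stopifnot(inherits(params, "dw_params"))
  init <- match.arg(init)
  N <- params$N
  mask <- withr_seed(seed, {
    cols <- lapply(seq_len(N), function(j) {
      k <- stats::rbinom(1L, N - 1L, params$c)
      if (k == 0L) return(integer(0))
      rows <- sample.int(N - 1L, k)
      rows + (rows >= j) # skip the diagonal
    })
    cols
  })
  jj <- rep.int(seq_len(N), lengths(mask))
  ii <- unlist(mask, use.names = FALSE)
  Jx <- numeric(length(ii))
  if (init == "equilibrium") {
    if (is.null(g_inf)) g_inf <- asymptotic_distribution(params)
    Jx <- withr_seed(seed + 1L, {
      idx <- sample.int(length(g_inf$grid), length(ii), replace = TRUE,
                        prob = g_inf$density)
      g_inf$grid[idx] + stats::runif(length(ii), -g_inf$dx / 2, g_inf$dx / 2)
    })
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = Jx, dims = c(N, N))
  # align (ii, jj) with the internal column-compressed ordering of M@x
  ord <- order(jj, ii)
  structure(list(params = params, M = M, ii = ii[ord], jj = jj[ord],
                 Jx = Jx[ord], n_presented = 0L, seed = seed),
            class = "dw_network")
}

#' @export
print.dw_network <- function(x, ...) {
  cat(sprintf("<dw_network> N = %d, %d synapses (c = %g), %d patterns presented\n",
              x$params$N, length(x$Jx), x$params$c, x$n_presented))
  invisible(x)
}

#' Present one pattern to the network
#'
#' Applies the learning dynamics for one pattern interval: every masked
#' synapse receives the instantaneous jump
#' `r2 * I(eta_i, eta_j) + r3 * epsilon_ij` (with standard Gaussian
#' `epsilon`), then decays toward its well minimum for one full unit
#' interval. Neuron states are not involved: learning is driven by the
#' clamped external pattern.
#'
#' @param net A [dw_network()].
#' @param pattern Binary vector of length `N`.
#' @return The updated network.
#' @export
present_pattern <- function(net, pattern) {
  stopifnot(inherits(net, "dw_network"), length(pattern) == net$params$N)
  p <- net$params
  jump <- p$r2 * input_amplitude(pattern[net$ii], pattern[net$jj], p)
  if (p$r3 > 0) jump <- jump + p$r3 * stats::rnorm(length(jump))
  net$Jx <- decay_map(net$Jx + jump, p, dt = 1)
  net$n_presented <- net$n_presented + 1L
  net
}

#' Run the neuronal dynamics to a fixed point
#'
#' Synchronous threshold updates `V <- Theta(h - theta)` with local field
#' `h_i = (1/N) sum_j c_ij J_ij V_j`, iterated until the state repeats
#' (fixed point), enters a 2-cycle, or an iteration cap is hit. Retrieval is
#' read-only: the weights are not modified.
#'
#' @param net A [dw_network()].
#' @param init_state Binary initial state of length `N`.
#' @param max_sweeps Iteration cap.
#' @return A list with `state` (the last state), `status` (`"fixed_point"`,
#'   `"cycle"` or `"max_sweeps"`), and `sweeps`.
#' @export
run_to_fixed_point <- function(net, init_state, max_sweeps = 200L) {
  stopifnot(inherits(net, "dw_network"),
            length(init_state) == net$params$N)
  p <- net$params
  M <- net$M
  M@x <- net$Jx
  V <- as.numeric(init_state)
  V_prev <- NULL
  for (s in seq_len(max_sweeps)) {
    h <- as.numeric(M %*% V) / p$N
    V_new <- as.numeric(h - p$theta >= 0)
    if (identical(V_new, V)) {
      return(list(state = as.integer(V_new), status = "fixed_point",
                  sweeps = s))
    }
    if (!is.null(V_prev) && identical(V_new, V_prev)) {
      return(list(state = as.integer(V_new), status = "cycle", sweeps = s))
    }
    V_prev <- V
    V <- V_new
  }
  list(state = as.integer(V), status = "max_sweeps", sweeps = max_sweeps)
}

#' Overlap between a network state and a pattern
#'
#' The normalized correlation
#' `m = 1 / (N f (1 - f)) * sum_i (eta_i - f) V_i`, which is 1 when the
#' state equals the pattern and 0 in expectation for an unrelated state (at
#' `f = 1/2` it reduces to the `4/N sum (eta - 1/2) V` form).
#'
#' @param state Binary state vector.
#' @param pattern Binary pattern vector of the same length.
#' @param f Coding level of the pattern ensemble.
#' @return The overlap.
#' @export
overlap <- function(state, pattern, f = 0.5) {
  stopifnot(length(state) == length(pattern))
  sum((pattern - f) * state) / (length(pattern) * f * (1 - f))
}

# Present `count` new patterns (appending to `history`), returning updated
# net and pattern matrix.
present_stream <- function(net, count, f, history = NULL) {
  N <- net$params$N
  new_pats <- matrix(as.integer(stats::runif(N * count) < f), N, count)
  for (k in seq_len(count)) net <- present_pattern(net, new_pats[, k])
  list(net = net, patterns = cbind(history, new_pats))
}

# Probe retrieval of the pattern at a given age: initialize at it, run to a
# fixed point, measure overlaps with it and with the most recent pattern.
probe_age <- function(net, patterns, age, criterion = 0.5) {
  T_ <- ncol(patterns)
  stopifnot(age >= 1, age <= T_ - 1)
  f <- net$params$f
  target <- patterns[, T_ - age]
  res <- run_to_fixed_point(net, target)
  m_v <- overlap(res$state, target, f)
  m_u <- overlap(res$state, patterns[, T_], f)
  tibble::tibble(age = age, m_v = m_v, m_u = m_u, status = res$status,
                 sweeps = res$sweeps,
                 retrieved = m_v >= criterion & m_v > m_u)
}

#' Storage capacity by direct network simulation
#'
#' Presents a stream of random patterns to the network (after burn-in or
#' from an equilibrium weight draw), then searches for the maximal age at
#' which a stored pattern is still retrieved: the network is initialized at
#' the probe pattern, run to a fixed point, and the pattern counts as
#' retrieved when the final overlap satisfies `m_v >= criterion` and
#' `m_v > m_u` (the overlap with the most recent pattern, to which the
#' network sometimes falls instead). The age search doubles a probe window
#' and bisects inside it; probing never modifies the weights, so all ages
#' are tested on the same realized weight history.
#'
#' @param params A [dw_params()] object.
#' @param seed Seed for connectivity, weights, patterns and noise.
#' @param burn_in Presentations before the probe window; default
#'   `max(200, ceiling(20 * tau))` for `init = "zero"`, 0 for
#'   `init = "equilibrium"` (weights start from the master-equation
#'   stationary distribution).
#' @param init Weight initialization, see [dw_network()].
#' @param criterion Retrieval threshold on `m_v`.
#' @param window Initial probe-window width (doubled as needed).
#' @param max_age Cap on the age search.
#' @param probe_ages Optionally, probe exactly these ages instead of
#'   searching for the capacity.
#' @param g_inf Optional precomputed stationary density (for
#'   `init = "equilibrium"`).
#' @return An object of class `dw_capacity` with `p`, the probe log
#'   (`probes`), `params` and `seed`. When `probe_ages` is given, `p` is
#'   the largest probed age that was retrieved (0 if none).
#' @export
simulate_capacity <- function(params, seed = 1, burn_in = NULL,
                              init = c("zero", "equilibrium"),
                              criterion = 0.5, window = 32L, max_age = 1e5,
                              probe_ages = NULL, g_inf = NULL) {
  stopifnot(inherits(params, "dw_params"))
  init <- match.arg(init)
  if (is.null(burn_in)) {
    burn_in <- if (init == "zero") max(200L, ceiling(20 * tau(params))) else 0L
  }
  net <- dw_network(params, seed = seed, init = init, g_inf = g_inf)
  set.seed(seed + 2L)
  # burn-in, monitoring weight-moment drift over its two halves
  if (burn_in > 0) {
    half <- burn_in %/% 2L
    st <- present_stream(net, half, params$f)
    rms1 <- sqrt(mean(st$net$Jx^2))
    st <- present_stream(st$net, burn_in - half, params$f)
    rms2 <- sqrt(mean(st$net$Jx^2))
    net <- st$net
    if (rms1 > 0 && abs(rms2 - rms1) / rms2 > 0.05) {
      warning("weight RMS still drifting after burn-in (",
              signif(rms1, 4), " -> ", signif(rms2, 4),
              "); consider a longer burn-in", call. = FALSE)
    }
  }
  if (params$r2 == 0 && is.null(probe_ages)) {
    return(structure(list(p = 0L, probes = tibble::tibble(), params = params,
                          seed = seed, method = "simulation"),
                     class = "dw_capacity"))
  }
  window <- as.integer(window)
  st <- present_stream(net, window + 1L, params$f)
  net <- st$net
  patterns <- st$patterns
  probes <- list()
  test_age <- function(age) {
    while (age > ncol(patterns) - 1L) { # grow the probe window as needed
      st <- present_stream(net, window, params$f, history = patterns)
      net <<- st$net
      patterns <<- st$patterns
      window <<- window * 2L
    }
    row <- probe_age(net, patterns, age, criterion)
    probes[[length(probes) + 1L]] <<- row
    row$retrieved
  }
  if (!is.null(probe_ages)) {
    for (a in sort(probe_ages)) test_age(a)
    probes <- dplyr::bind_rows(probes)
    p <- if (any(probes$retrieved)) max(probes$age[probes$retrieved]) else 0L
  } else {
    p <- 0L
    if (test_age(1L)) {
      lo <- 1L
      hi <- 2L
      while (hi <= max_age && test_age(hi)) {
        lo <- hi
        hi <- hi * 2L
      }
      if (hi > max_age) {
        p <- lo
      } else {
        while (hi - lo > 1L) {
          mid <- (lo + hi) %/% 2L
          if (test_age(mid)) lo <- mid else hi <- mid
        }
        p <- lo
      }
    }
    # retrieval can be re-entrant in age (deep wells); scan past the
    # bisection result
    repeat {
      win <- max(10L, p %/% 4L)
      ages <- (p + 1L):min(p + win, max_age)
      found <- 0L
      for (a in ages) if (test_age(a)) found <- a
      if (found == 0L || found >= max_age) break
      p <- found
    }
    probes <- dplyr::bind_rows(probes)
  }
  structure(list(p = as.integer(p), probes = probes, params = params,
                 seed = seed, method = "simulation"),
            class = "dw_capacity")
}

#' Simulated overlap-vs-age curve
#'
#' Probes a fixed set of ages in independent network realizations and
#' summarizes the final overlap with the probed pattern, for comparison with
#' the mean-field overlap curve.
#'
#' @inheritParams simulate_capacity
#' @param ages Ages to probe.
#' @param realizations Number of independent realizations.
#' @return A tibble with one row per (realization, age): columns
#'   `realization`, `age`, `m_v`, `m_u`, `status`.
#' @export
simulate_overlap_curve <- function(params, ages, realizations = 5, seed = 1,
                                   burn_in = NULL,
                                   init = c("zero", "equilibrium"),
                                   g_inf = NULL) {
  init <- match.arg(init)
  rows <- lapply(seq_len(realizations), function(r) {
    cap <- simulate_capacity(params, seed = seed + 1000L * r,
                             burn_in = burn_in, init = init,
                             probe_ages = ages, g_inf = g_inf)
    dplyr::mutate(cap$probes, realization = r, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Optimize sparse-coding capacity over potential width and threshold
#'
#' Grid search of [simulate_capacity()] over `(C, theta)`, as used in the
#' sparse-coding protocol where both the neuronal threshold and the
#' potential width are tuned for capacity. Ties are broken toward smaller
#' `C`, then smaller `theta`.
#'
#' @param params Template [dw_params()].
#' @param C_grid,theta_grid Non-empty candidate grids.
#' @inheritParams simulate_capacity
#' @return A list of class `dw_copt_sim` with `C_star`, `theta_star`,
#'   `p_star` and the search `table`.
#' @export
optimize_capacity_sparse <- function(params, C_grid, theta_grid, seed = 1,
                                     init = "equilibrium", burn_in = NULL,
                                     window = 32L) {
  if (length(C_grid) == 0 || length(theta_grid) == 0) {
    stop("`C_grid` and `theta_grid` must be non-empty", call. = FALSE)
  }
  grid <- tidyr::expand_grid(C = sort(C_grid), theta = sort(theta_grid))
  grid$p <- vapply(seq_len(nrow(grid)), function(k) {
    pk <- modify_params(params, C = grid$C[k], theta = grid$theta[k])
    simulate_capacity(pk, seed = seed, init = init, burn_in = burn_in,
                      window = window)$p
  }, integer(1))
  i <- which(grid$p == max(grid$p))
  i <- i[order(grid$C[i], grid$theta[i])][1]
  structure(list(C_star = grid$C[i], theta_star = grid$theta[i],
                 p_star = grid$p[i], table = grid, params = params),
            class = "dw_copt_sim")
}

#' @export
print.dw_copt_sim <- function(x, ...) {
  cat(sprintf("<dw_copt_sim> C* = %g, theta* = %g, p* = %d\n",
              x$C_star, x$theta_star, x$p_star))
  invisible(x)
}

#' @export
tidy.dw_copt_sim <- function(x, ...) x$table

#' Weight histogram of a simulated network
#'
#' Empirical distribution of the masked synaptic weights, binned on the
#' master-equation grid, for direct comparison with
#' [asymptotic_distribution()].
#'
#' @param net A [dw_network()].
#' @param n_grid,J_min,J_max Grid specification (defaults match
#'   [asymptotic_distribution()]).
#' @return A [weight_density()] object.
#' @export
network_weight_density <- function(net, n_grid = 4000, J_min = -20,
                                   J_max = 20) {
  grid <- weight_grid(n_grid, J_min, J_max)
  dx <- (J_max - J_min) / (n_grid - 1)
  idx <- pmin(pmax(round((net$Jx - J_min) / dx) + 1, 1), n_grid)
  counts <- tabulate(idx, nbins = n_grid)
  weight_density(grid, counts / (sum(counts) * dx), phase = 1)
}
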