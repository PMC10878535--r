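# Experiment harness: robustness statistic, parameter sweeps, seeded tabular
# outputs.

# Flatten a dw_params into a one-row tibble (carried on every result row).
params_to_tibble <- function(params) {
  tibble::tibble(C = params$C, r1 = params$r1, r2 = params$r2, r3 = params$r3,
                 theta = params$theta, f = params$f, c = params$c,
                 N = params$N, rule = params$rule)
}

#' Robustness of storage to synaptic noise
#'
#' Measures how quickly the storage capacity degrades with plasticity noise.
#' With the potential width fixed at its noiseless optimum `C*(r3 = 0)`, the
#' capacity `p(r3)` is computed over a noise grid; the noise is normalized
#' by the weight scale, `r3_tilde = r3 / Omega` with `Omega` the RMS of the
#' noiseless stationary weight distribution; and the robustness is the
#' reciprocal absolute slope `R = |dp / d r3_tilde|^{-1}`, estimated by
#' least squares over the small-noise window where `p` has dropped by at
#' most `window_drop` of `p(0)`.
#'
#' @param params Template [dw_params()] (balanced: capacities are computed
#'   by mean-field theory; other rules by direct simulation).
#' @param r3_grid Noise strengths; must include 0.
#' @param C_grid Grid for the noiseless `C` optimization (default as in
#'   [optimize_C()]); ignored when `C_fixed` is given.
#' @param C_fixed Optionally skip the optimization and use this width.
#' @param window_drop Fraction of `p0` defining the small-noise fitting
#'   window (default 0.2).
#' @param seed Seed (used for the simulation path).
#' @param ... Passed to [simulate_capacity()] for non-balanced rules.
#' @return An object of class `dw_robustness`: list with `R`, `p0`, `C0`,
#'   `Omega0` and the `table` (tibble of `r3`, `r3_tilde`, `p`). `R` is
#'   `Inf` (flagged by `flat = TRUE`) when the capacity does not change
#'   over the window.
#' @export
robustness_R <- function(params, r3_grid, C_grid = NULL, C_fixed = NULL,
                         window_drop = 0.2, seed = 1, ...) {
  stopifnot(any(r3_grid == 0))
  r3_grid <- sort(unique(r3_grid))
  balanced <- params$rule == "balanced"
  p0_params <- modify_params(params, r3 = 0)
  if (is.null(C_fixed)) {
    if (!balanced) {
      stop("supply `C_fixed` for non-balanced rules", call. = FALSE)
    }
    opt <- optimize_C(p0_params, C_grid = C_grid)
    C0 <- opt$C_star
  } else {
    C0 <- C_fixed
  }
  g0 <- asymptotic_distribution(modify_params(p0_params, C = C0))
  Omega0 <- moments(g0)$rms
  p_of_r3 <- vapply(r3_grid, function(r3) {
    pk <- modify_params(params, C = C0, r3 = r3)
    if (balanced) {
      mf_capacity_int(pk, meanfield_curve(pk))
    } else {
      simulate_capacity(pk, seed = seed, ...)$p
    }
  }, numeric(1))
  tab <- tibble::tibble(r3 = r3_grid, r3_tilde = r3_grid / Omega0,
                        p = p_of_r3)
  p0 <- tab$p[tab$r3 == 0]
  win <- tab$p >= (1 - window_drop) * p0
  # contiguous small-noise window from r3 = 0
  win <- cumprod(win) == 1
  flat <- FALSE
  if (sum(win) < 2 || length(unique(tab$p[win])) == 1) {
    # no measurable drop inside the window: take the first drop if any
    if (any(tab$p < p0)) {
      k <- which(tab$p < p0)[1]
      slope <- (tab$p[k] - p0) / (tab$r3_tilde[k] - 0)
    } else {
      slope <- 0
    }
  } else {
    slope <- unname(stats::coef(stats::lm(p ~ r3_tilde,
                                          data = tab[win, ]))[2])
  }
  if (slope == 0) {
    flat <- TRUE
    R <- Inf
  } else {
    R <- 1 / abs(slope)
  }
  structure(list(R = R, p0 = p0, C0 = C0, Omega0 = Omega0, table = tab,
                 flat = flat, params = params),
            class = "dw_robustness")
}

#' @export
print.dw_robustness <- function(x, ...) {
  cat(sprintf("<dw_robustness> R = %.4g, p0 = %d at C0 = %g (Omega0 = %.4g)%s\n",
              x$R, x$p0, x$C0, x$Omega0,
              if (x$flat) " [flat capacity: R undefined/infinite]" else ""))
  invisible(x)
}

#' @export
tidy.dw_robustness <- function(x, ...) x$table

#' @export
glance.dw_robustness <- function(x, ...) {
  tibble::tibble(R = x$R, p0 = x$p0, C0 = x$C0, Omega0 = x$Omega0,
                 flat = x$flat)
}

#' Read an experiment configuration
#'
#' Flat key-value text format (`key = value`, `#` comments). Scalar keys set
#' [dw_params()] fields; `experiment` selects the pipeline; keys of the form
#' `sweep_<param> = v1,v2,...` define sweep axes; `seeds = s1,s2,...` lists
#' realization seeds; `ages = a1,a2,...` gives probe ages for the SNR and
#' overlap experiments; `output` optionally names a CSV file.
#'
#' @param path Path to the config file.
#' @return A list with elements `experiment`, `params`, `sweep`, `seeds`,
#'   `ages`, `output`.
#' @export
read_experiment_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  cfg <- list(sweep = list(), seeds = 1L, ages = NULL, output = NULL)
  par_args <- list()
  num <- function(v) as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
  for (k in seq_along(keys)) {
    key <- keys[k]; val <- vals[k]
    if (key == "experiment") {
      cfg$experiment <- val
    } else if (key == "output") {
      cfg$output <- val
    } else if (key == "seeds") {
      cfg$seeds <- as.integer(num(val))
    } else if (key == "ages") {
      cfg$ages <- as.integer(num(val))
    } else if (startsWith(key, "sweep_")) {
      cfg$sweep[[sub("^sweep_", "", key)]] <- num(val)
    } else if (key == "rule") {
      par_args$rule <- val
    } else {
      par_args[[key]] <- as.numeric(val)
    }
  }
  if (is.null(cfg$experiment)) stop("config lacks `experiment`", call. = FALSE)
  cfg$params <- do.call(dw_params, par_args)
  cfg
}

#' Run a configured experiment sweep
#'
#' Executes one of the package pipelines over the cross product of the
#' configured sweep axes (and seeds, for stochastic pipelines), one result
#' row per combination, each row carrying the fully resolved parameter set.
#' Deterministic given the configuration. Available experiments:
#'
#' * `"capacity_meanfield"`: mean-field storage capacity.
#' * `"capacity_sim"`: storage capacity by direct simulation (one row per
#'   seed).
#' * `"optimize_C"`: capacity-optimal potential width.
#' * `"snr"`: SNR comparison curve (double-well, matched Markov, bound) at
#'   the configured ages.
#' * `"robustness"`: capacity-vs-noise table and robustness `R` (sweep axis
#'   `r3` is the noise grid).
#'
#' @param config A list as returned by [read_experiment_config()], or a
#'   path to a config file.
#' @return A tibble of results. If `config$output` is set the table is also
#'   written there as CSV (partial results are flushed after every sweep
#'   point, so a failed sweep leaves the completed rows on disk).
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  exp_id <- config$experiment
  sweep <- config$sweep
  grid <- if (length(sweep) > 0) {
    do.call(tidyr::expand_grid, sweep)
  } else {
    tibble::tibble(.rows = 1)
  }
  stochastic <- exp_id %in% c("capacity_sim")
  if (stochastic) {
    grid <- tidyr::expand_grid(grid, .seed = config$seeds)
  }
  out <- list()
  flush <- function() {
    res <- dplyr::bind_rows(out)
    if (!is.null(config$output)) {
      utils::write.csv(res, config$output, row.names = FALSE)
    }
    res
  }
  for (k in seq_len(nrow(grid))) {
    row <- grid[k, , drop = FALSE]
    upd <- as.list(row[setdiff(names(row), ".seed")])
    pk <- do.call(modify_params, c(list(config$params), upd))
    base <- params_to_tibble(pk)
    res_k <- switch(exp_id,
      capacity_meanfield = {
        dplyr::bind_cols(base, tibble::tibble(
          p = mf_capacity_int(pk, meanfield_curve(pk))))
      },
      capacity_sim = {
        cap <- simulate_capacity(pk, seed = row$.seed)
        dplyr::bind_cols(base, tibble::tibble(seed = row$.seed, p = cap$p))
      },
      optimize_C = {
        opt <- optimize_C(pk)
        dplyr::bind_cols(base, tibble::tibble(C_star = opt$C_star,
                                              p_star = opt$p_star))
      },
      snr = {
        ages <- if (is.null(config$ages)) 0:20 else config$ages
        dplyr::bind_cols(base[rep(1, length(ages)), ],
                         snr_comparison(pk, ages))
      },
      robustness = {
        r3_grid <- config$sweep$r3
        if (is.null(r3_grid)) stop("robustness needs `sweep_r3`",
                                   call. = FALSE)
        rob <- robustness_R(pk, r3_grid)
        dplyr::bind_cols(base[rep(1, nrow(rob$table)), ],
                         rob$table, tibble::tibble(R = rob$R))
      },
      stop("unknown experiment id: ", exp_id, call. = FALSE)
    )
    out[[k]] <- res_k
    flush()
    if (exp_id == "robustness") break # the sweep axis is consumed internally
  }
  flush()
}
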