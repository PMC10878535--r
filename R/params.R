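#' Model parameters for the double-well synapse network
#'
#' Bundles every parameter of the synapse and network model: the potential
#' half-width `C`, the decay rate `r1` (depth of the potential; synapses relax
#' toward the well minima with time constant `1/(2 r1)` in units of the
#' pattern-presentation interval), the input strength `r2`, the plasticity
#' noise strength `r3` (standard deviation of the Gaussian jump added at every
#' presentation), the neuronal threshold `theta`, the coding level `f`, the
#' connection probability `c`, the network size `N`, and the plasticity rule.
#'
#' Three rules are supported for the activity-dependent jump `I(eta_i, eta_j)`:
#' * `"balanced"` (requires `f = 0.5`): `I = +1` when pre and post states
#'   agree, `-1` otherwise.
#' * `"tsodyks_feigelman"`: covariance rule `I = (eta_i - f)(eta_j - f)`.
#' * `"amit_fusi"`: `I = I1` when both neurons are active, `I2` when exactly
#'   one is active, `0` when both are silent. Defaults are `I1 = 2 C`,
#'   `I2 = -f (1 - f)`.
#'
#' @param C Potential half-width (distance of each well minimum from zero),
#'   `C >= 0`, in weight units.
#' @param r1 Potential depth / weight decay rate per pattern interval,
#'   `r1 >= 0`.
#' @param r2 Input (learning) strength, `r2 >= 0`.
#' @param r3 Noise strength (per-presentation Gaussian std), `r3 >= 0`.
#' @param theta Neuronal firing threshold.
#' @param f Coding level, probability a neuron is active in a pattern,
#'   `0 < f < 1`.
#' @param c Connection probability, `0 < c <= 1`.
#' @param N Number of neurons, integer `>= 2`.
#' @param rule Plasticity rule, one of `"balanced"`, `"tsodyks_feigelman"`,
#'   `"amit_fusi"`.
#' @param I1,I2 Potentiation/depression amplitudes for the `"amit_fusi"` rule;
#'   defaults `2 * C` and `-f * (1 - f)`.
#'
#' @return An object of class `dw_params` (a named list).
#' @examples
#' p <- dw_params(C = 2, r1 = 0.1, N = 1e4)
#' tau(p) # decay time constant 1/(2 r1)
#' @export
dw_params <- function(C = 1, r1 = 0.1, r2 = 1, r3 = 0, theta = 0,
                      f = 0.5, c = 0.05, N = 10000,
                      rule = c("balanced", "tsodyks_feigelman", "amit_fusi"),
                      I1 = 2 * C, I2 = -f * (1 - f)) {
  rule <- match.arg(rule)
  stopifnot(
    is.numeric(C), length(C) == 1, C >= 0,
    is.numeric(r1), length(r1) == 1, r1 >= 0,
    is.numeric(r2), length(r2) == 1, r2 >= 0,
    is.numeric(r3), length(r3) == 1, r3 >= 0,
    is.numeric(theta), length(theta) == 1,
    is.numeric(f), length(f) == 1, f > 0, f < 1,
    is.numeric(c), length(c) == 1, c > 0, c <= 1,
    is.numeric(N), length(N) == 1, N >= 2
  )
  if (rule == "balanced" && abs(f - 0.5) > 1e-12) {
    stop("the balanced rule is defined for f = 0.5", call. = FALSE)
  }
  structure(
    list(C = C, r1 = r1, r2 = r2, r3 = r3, theta = theta,
         f = f, c = c, N = as.integer(round(N)), rule = rule,
         I1 = I1, I2 = I2),
    class = "dw_params"
  )
}

#' @export
print.dw_params <- function(x, ...) {
  cat("<dw_params> rule =", x$rule, "\n")
  cat(sprintf("  C = %g, r1 = %g (tau = %g), r2 = %g, r3 = %g, theta = %g\n",
              x$C, x$r1, tau(x), x$r2, x$r3, x$theta))
  cat(sprintf("  f = %g, c = %g, N = %d", x$f, x$c, x$N))
  if (x$rule == "amit_fusi") cat(sprintf(", I1 = %g, I2 = %g", x$I1, x$I2))
  cat("\n")
  invisible(x)
}

#' Synaptic decay time constant
#'
#' Read-only accessor for `tau = 1 / (2 r1)`, the exponential relaxation time
#' of a synapse toward its well minimum, in pattern-presentation intervals.
#'
#' @param params A [dw_params()] object.
#' @return A scalar (`Inf` when `r1 = 0`).
#' @export
tau <- function(params) {
  stopifnot(inherits(params, "dw_params"))
  if (params$r1 == 0) Inf else 1 / (2 * params$r1)
}

#' Rescale the model parameters
#'
#' Applies the scale transformation
#' `(r2, C, J, r1, r3, theta) -> (x r2, x C, x J, r1/x, x r3, x theta)`
#' in its printed form (`r1_scaling = "printed"`). Because the decay flow
#' `dJ/dt = -2 r1 (J -/+ C)` is linear in `(J, C)`, the variant that leaves
#' the dynamics (and hence storage capacity) exactly invariant keeps `r1`
#' unchanged while scaling the other quantities; this is available as
#' `r1_scaling = "dynamical"`. See the methods vignette for the derivation.
#'
#' @param params A [dw_params()] object.
#' @param x Positive scale factor.
#' @param r1_scaling `"printed"` divides `r1` by `x`; `"dynamical"` leaves
#'   `r1` unchanged (the exact symmetry of the weight dynamics).
#' @return A transformed [dw_params()] object. For the `"amit_fusi"` rule the
#'   potentiation amplitude `I1` scales with `C`; `I2` scales with `x` like
#'   the other weight-dimensioned quantities.
#' @examples
#' p <- dw_params(C = 2, r1 = 0.1)
#' rescale_params(p, 2)
#' @export
rescale_params <- function(params, x, r1_scaling = c("printed", "dynamical")) {
  stopifnot(inherits(params, "dw_params"))
  r1_scaling <- match.arg(r1_scaling)
  if (!is.numeric(x) || length(x) != 1 || x <= 0) {
    stop("`x` must be a positive scalar", call. = FALSE)
  }
  dw_params(
    C = x * params$C,
    r1 = if (r1_scaling == "printed") params$r1 / x else params$r1,
    r2 = x * params$r2,
    r3 = x * params$r3,
    theta = x * params$theta,
    f = params$f, c = params$c, N = params$N, rule = params$rule,
    I1 = x * params$I1, I2 = x * params$I2
  )
}

#' Read model parameters from a flat key-value config file
#'
#' Parses a plain-text configuration with one `key = value` pair per line
#' (`#` starts a comment). Recognized keys are the fields of [dw_params()]
#' (`C, r1, r2, r3, theta, f, c, N, rule, I1, I2`) plus an optional `seed`,
#' returned as the `"seed"` attribute.
#'
#' @param path Path to the config file.
#' @return A [dw_params()] object (with attribute `seed` if present).
#' @export
read_params_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  known <- c("C", "r1", "r2", "r3", "theta", "f", "c", "N", "rule",
             "I1", "I2", "seed")
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- stats::setNames(as.list(vals), keys)
  for (k in setdiff(names(args), "rule")) args[[k]] <- as.numeric(args[[k]])
  seed <- args$seed
  args$seed <- NULL
  p <- do.call(dw_params, args)
  if (!is.null(seed)) attr(p, "seed") <- as.integer(seed)
  p
}
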