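# Signal-to-noise analysis of the binarized double-well synapse and the
# matched two-state Markov synapse.

#' Binarize synaptic weights
#'
#' `w = sign(J)`: which well the synapse occupies. An exactly zero weight (a
#' measure-zero event) is assigned +1 or -1 with equal probability from the
#' current RNG stream.
#'
#' @param J Numeric weights.
#' @return Integer vector of -1 / +1.
#' @export
binarize <- function(J) {
  w <- sign(J)
  z <- w == 0
  if (any(z)) w[z] <- sample(c(-1, 1), sum(z), replace = TRUE)
  as.integer(w)
}

#' SNR curve of the binarized double-well model
#'
#' Signal-to-noise ratio of the binarized connectivity with respect to the
#' ideal trace of a pattern stored `t` presentations ago:
#' `SNR(t) = sqrt(cN) * int g_{sigma=+1}(J, t) sign(J) dJ`, using the
#' potentiated-class conditional density from the master equation (the
#' depressed class is its mirror image at balance, so it contributes the
#' same amount). The `sqrt(cN)` normalization is the standard deviation of
#' the null overlap of a `cN`-term sum of independent `+/-1` weights. Since
#' decay never changes the sign of a weight, the curve is constant within
#' each presentation interval; it is reported at integer ages with age 0
#' immediately after the tagged potentiation.
#'
#' @param params A [dw_params()] object (balanced rule).
#' @param ages Integer ages `>= 0`.
#' @param cN Effective number of synapses per neuron (default
#'   `params$c * params$N`).
#' @param curve Optional precomputed [meanfield_curve()].
#' @param g_inf Optional precomputed [asymptotic_distribution()].
#' @return A tibble of class `dw_snr` with columns `age` and `snr`.
#' @export
snr_double_well <- function(params, ages, cN = params$c * params$N,
                            curve = NULL, g_inf = NULL) {
  stopifnot(params$rule == "balanced", all(ages >= 0),
            all(ages == round(ages)))
  ages <- sort(unique(as.integer(ages)))
  if (params$r2 == 0) {
    out <- tibble::tibble(age = ages, snr = 0)
    class(out) <- c("dw_snr", class(out))
    return(out)
  }
  if (is.null(curve)) curve <- meanfield_curve(params, g_inf = g_inf)
  s <- numeric(length(ages))
  pos <- ages > 0
  if (any(pos)) {
    extend_curve(curve, max(ages))
    s[pos] <- curve$S[ages[pos]]
  }
  if (any(!pos)) { # age 0: g_inf shifted by +r2 (plus noise), before any decay
    g0 <- curve$g_inf
    shifted <- as.numeric(push_matrix(g0$grid, g0$grid + params$r2) %*%
                            g0$density)
    kern <- noise_kernel(g0$dx, params$r3)
    if (!is.null(kern)) shifted <- convolve_fold(shifted, kern)
    s[!pos] <- sum(shifted * sign(g0$grid)) * g0$dx
  }
  out <- tibble::tibble(age = ages, snr = sqrt(cN) * s)
  class(out) <- c("dw_snr", class(out))
  out
}

#' Two-state Markov synapse matched to the double-well model
#'
#' Builds the 2x2 column-stochastic potentiation and depression transition
#' matrices whose switching probabilities equal the probabilities that a
#' double-well synapse, drawn from the stationary ensemble `g_inf` and
#' restricted to one well, ends in the other well after one presentation
#' (jump plus noise plus one unit of decay — decay itself never switches the
#' well, so the jump decides).
#'
#' @param params A [dw_params()] object (balanced rule).
#' @param g_inf Optional precomputed [asymptotic_distribution()].
#' @return An object of class `dw_markov`: list with `M_pot`, `M_dep`
#'   (column-stochastic, states ordered (-1, +1)), the relaxation generator
#'   `W = (M_pot + M_dep)/2 - I`, efficacies `w = c(-1, 1)` and stationary
#'   distribution `p_inf = c(1/2, 1/2)`.
#' @export
matched_markov <- function(params, g_inf = NULL) {
  stopifnot(params$rule == "balanced")
  if (is.null(g_inf)) g_inf <- asymptotic_distribution(params)
  g <- g_inf$density * g_inf$dx # cell masses, pre-presentation
  grid <- g_inf$grid
  kern <- noise_kernel(g_inf$dx, params$r3)
  switch_prob <- function(from_neg, jump) {
    m0 <- g
    if (from_neg) m0[grid > 0] <- 0 else m0[grid < 0] <- 0
    tot <- sum(m0)
    if (tot <= 0) stop("empty well in g_inf", call. = FALSE)
    m1 <- as.numeric(push_matrix(grid, grid + jump) %*% m0)
    if (!is.null(kern)) m1 <- convolve_fold(m1, kern)
    ended <- if (from_neg) sum(m1[grid > 0]) else sum(m1[grid < 0])
    ended / tot
  }
  r2 <- params$r2
  q_pot_up <- switch_prob(TRUE, +r2) # - -> + under potentiation
  q_pot_dn <- switch_prob(FALSE, +r2) # + -> - under potentiation (noise only)
  q_dep_dn <- switch_prob(FALSE, -r2) # + -> - under depression
  q_dep_up <- switch_prob(TRUE, -r2) # - -> + under depression (noise only)
  M_pot <- matrix(c(1 - q_pot_up, q_pot_up, q_pot_dn, 1 - q_pot_dn), 2, 2,
                  dimnames = list(to = c("-1", "+1"), from = c("-1", "+1")))
  M_dep <- matrix(c(1 - q_dep_up, q_dep_up, q_dep_dn, 1 - q_dep_dn), 2, 2,
                  dimnames = dimnames(M_pot))
  structure(list(M_pot = M_pot, M_dep = M_dep,
                 W = (M_pot + M_dep) / 2 - diag(2),
                 w = c(-1, 1), p_inf = c(0.5, 0.5)),
            class = "dw_markov")
}

#' @export
print.dw_markov <- function(x, ...) {
  cat(sprintf("<dw_markov> P(-1 -> +1 | pot) = %.4g, P(+1 -> -1 | dep) = %.4g\n",
              x$M_pot[2, 1], x$M_dep[1, 2]))
  invisible(x)
}

#' SNR of a two-state Markov synapse
#'
#' `SNR_b(t) = (sqrt(cN) / 2) * w' e^{tW} (M_pot - M_dep) p_inf`, with
#' relaxation generator `W = (M_pot + M_dep)/2 - I`. The default
#' `"exponential"` method uses the continuous-time matrix exponential
#' interpolation; `"discrete"` replaces `e^{tW}` by
#' `((M_pot + M_dep)/2)^t` at integer ages, which is the exact mean
#' operator of the discrete chain (the two agree to second order in the
#' switching probabilities).
#'
#' @param ms A [matched_markov()] object (or any list with the same
#'   fields).
#' @param t Ages (vector, `>= 0`; integers required for `"discrete"`).
#' @param cN Effective number of synapses per neuron.
#' @param method `"exponential"` or `"discrete"`.
#' @return Numeric vector of SNR values.
#' @export
snr_markov <- function(ms, t, cN, method = c("exponential", "discrete")) {
  method <- match.arg(method)
  stopifnot(all(t >= 0))
  check_stochastic <- function(M) {
    all(abs(colSums(M) - 1) < 1e-9) && all(M >= -1e-12) && all(M <= 1 + 1e-12)
  }
  if (!check_stochastic(ms$M_pot) || !check_stochastic(ms$M_dep)) {
    stop("transition matrices must be column-stochastic", call. = FALSE)
  }
  signal0 <- (ms$M_pot - ms$M_dep) %*% ms$p_inf
  vapply(t, function(tt) {
    prop <- if (method == "exponential") {
      as.matrix(Matrix::expm(tt * ms$W))
    } else {
      stopifnot(tt == round(tt))
      mp <- diag(2)
      Mbar <- (ms$M_pot + ms$M_dep) / 2
      if (tt > 0) for (k in seq_len(tt)) mp <- Mbar %*% mp
      mp
    }
    sqrt(cN) / 2 * as.numeric(ms$w %*% prop %*% signal0)
  }, numeric(1))
}

#' Envelope bound on the SNR of two-state Markov synapses
#'
#' The upper bound over all two-state Markov models:
#' `sqrt(cN) e^{-t}` for `t <= 1` and `sqrt(cN) / (e t)` for `t > 1`
#' (continuous at `t = 1`).
#'
#' @param t Ages (`>= 0`).
#' @param cN Effective number of synapses per neuron.
#' @return Numeric vector of bound values.
#' @export
snr_markov_bound <- function(t, cN) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  ifelse(t <= 1, sqrt(cN) * exp(-t), sqrt(cN) / (exp(1) * t))
}

#' SNR comparison table
#'
#' Tabulates, over a grid of ages, the binarized double-well SNR, the
#' matched Markov SNR and the two-state Markov envelope bound.
#'
#' @inheritParams snr_double_well
#' @return A tibble with columns `age`, `snr_double_well`, `snr_markov`,
#'   `bound`.
#' @export
snr_comparison <- function(params, ages, cN = params$c * params$N,
                           g_inf = NULL) {
  if (is.null(g_inf)) g_inf <- asymptotic_distribution(params)
  curve <- meanfield_curve(params, g_inf = g_inf)
  dw <- snr_double_well(params, ages, cN = cN, curve = curve)
  ms <- matched_markov(params, g_inf = g_inf)
  tibble::tibble(
    age = dw$age,
    snr_double_well = dw$snr,
    snr_markov = snr_markov(ms, dw$age, cN),
    bound = snr_markov_bound(dw$age, cN)
  )
}
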