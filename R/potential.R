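#' Double-well potential energy
#'
#' The piecewise-quadratic potential with minima at `+C` and `-C`:
#' `U(J) = (J - C)^2` for `J > 0` and `U(J) = (J + C)^2` for `J < 0`.
#' At `J = 0` both branches agree in the limit and `U(0) = C^2`, the height
#' of the barrier separating the wells.
#'
#' @param J Synaptic weight(s), any real value; vectorized.
#' @param C Potential half-width, `C >= 0`.
#' @return The potential energy, same length as `J`.
#' @examples
#' dw_potential(c(-2, 0, 2), C = 2) # 0, 4, 0
#' @export
dw_potential <- function(J, C) {
  stopifnot(is.numeric(J), is.numeric(C), length(C) == 1, C >= 0)
  ifelse(J > 0, (J - C)^2, (J + C)^2)
}

#' Deterministic decay toward the well minima
#'
#' In the absence of inputs a synapse relaxes exponentially toward the
#' minimum of the well it currently occupies, with time constant
#' `1/(2 r1)`: for `J > 0`, `J(t + dt) = C + (J - C) exp(-2 r1 dt)`, and the
#' mirror image for `J < 0`. The sign of `J` never changes under decay (the
#' flow cannot cross the barrier at 0); `J = 0` is an unstable equilibrium
#' and is mapped to itself.
#'
#' @param J Synaptic weight(s); vectorized.
#' @param params A [dw_params()] object (uses `C` and `r1`).
#' @param dt Decay duration as a fraction of the pattern interval,
#'   `0 <= dt <= 1`.
#' @return Decayed weight(s).
#' @examples
#' p <- dw_params(C = 0, r1 = 0.5)
#' decay_map(5, p, dt = 1) # 5 * exp(-1)
#' @export
decay_map <- function(J, params, dt = 1) {
  stopifnot(inherits(params, "dw_params"),
            is.numeric(dt), length(dt) == 1, dt >= 0, dt <= 1)
  k <- exp(-2 * params$r1 * dt)
  C <- params$C
  out <- J
  pos <- J > 0
  neg <- J < 0
  out[pos] <- C + (J[pos] - C) * k
  out[neg] <- -C + (J[neg] + C) * k
  out
}

# Jump amplitude I(eta_post, eta_pre) for one rule; vectorized over states.
# eta_post is the state imposed on the postsynaptic neuron i, eta_pre on the
# presynaptic neuron j.
input_amplitude <- function(eta_post, eta_pre, params) {
  switch(params$rule,
    balanced = (2 * eta_post - 1) * (2 * eta_pre - 1),
    tsodyks_feigelman = (eta_post - params$f) * (eta_pre - params$f),
    amit_fusi = params$I1 * eta_post * eta_pre +
      params$I2 * (eta_post + eta_pre - 2 * eta_post * eta_pre)
  )
}

#' Deterministic input-driven weight increment
#'
#' The jump `r2 * I(eta_post, eta_pre)` applied to a synapse when a pattern
#' is presented, for the rule selected in `params`. The full stochastic
#' update adds an independent Gaussian term of standard deviation `r3` on
#' top of this deterministic part.
#'
#' @param eta_post,eta_pre Imposed binary states (0 or 1) of the post- and
#'   presynaptic neurons; vectorized.
#' @param params A [dw_params()] object.
#' @return The deterministic weight increment(s).
#' @examples
#' p <- dw_params(rule = "balanced")
#' input_jump(1, 1, p) # +1
#' input_jump(1, 0, p) # -1
#' @export
input_jump <- function(eta_post, eta_pre, params) {
  stopifnot(inherits(params, "dw_params"),
            all(eta_post %in% c(0, 1)), all(eta_pre %in% c(0, 1)))
  params$r2 * input_amplitude(eta_post, eta_pre, params)
}

# Plasticity event classes of a rule: the distinct values of I together with
# their prior probabilities under i.i.d. Bernoulli(f) pre/post states.
# Returns a data.frame with columns I (amplitude) and prob.
rule_classes <- function(params) {
  f <- params$f
  combos <- expand.grid(post = c(0, 1), pre = c(0, 1))
  amp <- input_amplitude(combos$post, combos$pre, params)
  prob <- ifelse(combos$post == 1, f, 1 - f) * ifelse(combos$pre == 1, f, 1 - f)
  agg <- tapply(prob, factor(amp, levels = sort(unique(amp))), sum)
  data.frame(I = as.numeric(names(agg)), prob = as.numeric(agg))
}
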