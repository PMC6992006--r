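#' Model parameters for the evolutionary dynamics
#'
#' @param delta resource-management intensity applied to every agent in
#'   fixed mode, in `[0, 1]`. Ignored when coevolution is on (`s > 0`),
#'   where each agent carries its own `delta_i`.
#' @param mu exploration rate: probability that an updating agent adopts a
#'   fresh norm drawn uniformly on `[0, 0.5]^2` instead of imitating.
#' @param K selection noise of the Fermi rule, `> 0`. Small `K` means
#'   nearly deterministic imitation of richer neighbors.
#' @param eps learning-error half-range: an imitated norm is perturbed
#'   component-wise by i.i.d. uniform draws on `[-eps, eps]`, then clipped
#'   back to `[0, 0.5]`.
#' @param s time-scale ratio of norm evolution to resource-management
#'   evolution. `s > 0` enables coevolution: after each norm-update phase,
#'   `round(s * N)` sequential micro-steps update individual `delta_i` by
#'   pairwise comparison. `s = 0` disables coevolution.
#' @param delta_perturb half-range of the uniform perturbation added when a
#'   `delta` value is copied during coevolution (default 0.025).
#' @return an object of class `ug_params`.
#' @examples
#' ug_params(delta = 1, K = 0.1, eps = 5e-3)
#' @export
ug_params <- function(delta = 1, mu = 0, K = 0.1, eps = 5e-3, s = 0,
                      delta_perturb = 0.025) {
  stopifnot(delta >= 0, delta <= 1, mu >= 0, mu <= 1, K > 0, eps >= 0,
            s >= 0, delta_perturb >= 0)
  structure(list(delta = delta, mu = mu, K = K, eps = eps, s = s,
                 delta_perturb = delta_perturb),
            class = "ug_params")
}

#' Fermi (pairwise-comparison) imitation probability
#'
#' Probability that a focal agent with payoff `payoff_self` adopts the
#' strategy of a role model with payoff `payoff_target`:
#' `1 / (1 + exp(-(payoff_target - payoff_self) / K))`. Strictly increasing
#' in the payoff difference; equals 1/2 at equal payoffs; satisfies
#' `T(x) + T(-x) = 1`.
#'
#' @param payoff_target role model's payoff.
#' @param payoff_self focal agent's payoff.
#' @param K selection noise, `> 0`.
#' @return probability in `(0, 1)`.
#' @examples
#' fermi_probability(0.6, 0.5, K = 0.1)  # 1 / (1 + exp(-1))
#' @export
fermi_probability <- function(payoff_target, payoff_self, K) {
  if (any(K <= 0) || anyNA(K)) stop("`K` must be > 0", call. = FALSE)
  1 / (1 + exp(-(payoff_target - payoff_self) / K))
}

## Draw a uniform neighbor of agent i (1-based), consuming exactly one
## uniform variate; mirrors the C++ engine bit-for-bit.
draw_neighbor <- function(state, i) {
  if (is.null(state$adj)) {
    idx0 <- floor(runif(1) * (state$n - 1L))
    j <- idx0 + 1L
    if (j >= i) j <- j + 1L
    j
  } else {
    nb <- state$adj[[i]]
    nb[floor(runif(1) * length(nb)) + 1L]
  }
}

#' Synchronous norm-updating phase
#'
#' Every agent updates independently, all role-model norms being read from
#' the pre-update generation:
#' * with probability `mu` it explores: a fresh norm uniform on
#'   `[0, 0.5]^2`;
#' * otherwise it picks one neighbor uniformly at random and, with the
#'   Fermi probability of the payoff difference, adopts that neighbor's
#'   norm perturbed component-wise by uniform draws on `[-eps, eps]` and
#'   clipped to `[0, 0.5]`; else it keeps its norm.
#'
#' Payoffs must come from the interaction phase of the same time step.
#' Agents without neighbors keep their norm in the imitation branch.
#'
#' @param state a [ug_state()] whose `payoff` field is current.
#' @param params a [ug_params()].
#' @return the state with updated norms.
#' @export
norm_update_phase <- function(state, params) {
  stopifnot(inherits(state, "ug_state"), inherits(params, "ug_params"))
  n <- state$n
  deg <- degrees(state)
  p_new <- state$p
  q_new <- state$q
  for (i in seq_len(n)) {
    u <- runif(1)
    if (u < params$mu) {
      p_new[i] <- runif(1, 0, 0.5)
      q_new[i] <- runif(1, 0, 0.5)
    } else if (deg[i] > 0L) {
      j <- draw_neighbor(state, i)
      if (runif(1) < fermi_probability(state$payoff[j], state$payoff[i],
                                       params$K)) {
        e1 <- runif(1, -params$eps, params$eps)
        e2 <- runif(1, -params$eps, params$eps)
        p_new[i] <- min(max(state$p[j] + e1, 0), 0.5)
        q_new[i] <- min(max(state$q[j] + e2, 0), 0.5)
      }
    }
  }
  state$p <- p_new
  state$q <- q_new
  state
}

#' Coevolutionary update of the resource-management intensities
#'
#' Runs `round(s * N)` sequential micro-steps. Each micro-step picks a
#' uniform-random agent i and a uniform-random neighbor j, and with the
#' Fermi probability of their payoff difference sets
#' `delta_i <- clip(delta_j + xi, 0, 1)` where `xi` is uniform on
#' `[-delta_perturb, delta_perturb]`. Payoffs are those of the last
#' interaction phase and are not recomputed between micro-steps; `delta`
#' values updated earlier in the phase are visible to later micro-steps.
#'
#' @inheritParams norm_update_phase
#' @return the state with updated `delta`.
#' @export
coevolution_phase <- function(state, params) {
  stopifnot(inherits(state, "ug_state"), inherits(params, "ug_params"))
  n_micro <- as.integer(round(params$s * state$n))
  deg <- degrees(state)
  for (k in seq_len(n_micro)) {
    i <- floor(runif(1) * state$n) + 1L
    if (deg[i] == 0L) next
    j <- draw_neighbor(state, i)
    if (runif(1) < fermi_probability(state$payoff[j], state$payoff[i],
                                     params$K)) {
      xi <- runif(1, -params$delta_perturb, params$delta_perturb)
      state$delta[i] <- min(max(state$delta[j] + xi, 0), 1)
    }
  }
  state
}
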