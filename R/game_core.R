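#' Individual norms in the continuous Ultimatum Game
#'
#' An individual norm is a pair `[p, q]`: `p` is the fraction of the
#' resource offered when acting as proposer, `q` the minimum fraction
#' accepted when acting as responder. Both components are constrained to
#' `[0, 0.5]` (a rational agent never offers, nor demands, more than half).
#' A norm is *self-compatible* when `p >= q`, i.e. the agent would accept
#' its own offer.
#'
#' @param p offer level(s), in `[0, 0.5]`.
#' @param q acceptance threshold(s), in `[0, 0.5]`.
#' @return `ug_norm()` returns a named numeric vector `c(p = , q = )`.
#' @examples
#' ug_norm(0.4, 0.3)
#' @export
ug_norm <- function(p, q) {
  stopifnot(length(p) == 1L, length(q) == 1L)
  check_norms(p, q)
  c(p = as.numeric(p), q = as.numeric(q))
}

## internal: vectorized validity check for norm components
check_norms <- function(p, q) {
  if (!is.numeric(p) || !is.numeric(q) || length(p) != length(q)) {
    stop("`p` and `q` must be numeric vectors of equal length", call. = FALSE)
  }
  if (anyNA(p) || anyNA(q)) stop("norm components must not be NA", call. = FALSE)
  if (any(p < 0 | p > 0.5) || any(q < 0 | q > 0.5)) {
    stop("norm components must lie in [0, 0.5]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Resolve a single Ultimatum deal
#'
#' The proposer offers fraction `p`; the responder accepts iff the offer
#' meets its threshold, i.e. iff `p - q >= 0` (the Heaviside convention
#' `H(0) = 1`: **ties are accepted**, which matters on the boundary where an
#' agent's offer exactly matches a threshold).
#'
#' @param p_offer proposer offer level(s).
#' @param q_threshold responder acceptance threshold(s).
#' @return logical vector, `TRUE` where the deal succeeds.
#' @examples
#' resolve_deal(0.3, 0.3)  # tie -> accepted
#' resolve_deal(0.2, 0.3)  # rejected
#' @export
resolve_deal <- function(p_offer, q_threshold) {
  check_norms(p_offer, pmin(q_threshold, 0.5))
  p_offer >= q_threshold
}

#' Allocate resources to a pair's two deals from last round's outcomes
#'
#' Each connected pair (i, j) plays two deals per round: one with i
#' proposing (resource `R_i`) and one with j proposing (resource `R_j`).
#' Both parties shift resources towards the deal that succeeded last round,
#' with intensity `delta`:
#'
#' * both succeeded or both failed: `R_i = R_j = 1`;
#' * only i's deal succeeded: `R_i = 1 + delta`, `R_j = 1 - delta`;
#' * only j's deal succeeded: `R_i = 1 - delta`, `R_j = 1 + delta`.
#'
#' Equivalently `R_i = 1 + delta * (S_ij - S_ji)` with success indicators
#' `S` in `{0, 1}`. The pair total `R_i + R_j = 2` is conserved exactly, so
#' the maximal payoff available to the population does not depend on
#' `delta`.
#'
#' @param prev_success_ij logical: did last round's deal with i proposing
#'   to j succeed?
#' @param prev_success_ji logical: did last round's deal with j proposing
#'   to i succeed?
#' @param delta resource-management intensity, in `[0, 1]`.
#' @return list with numeric components `R_i` and `R_j`.
#' @examples
#' allocate_resources(TRUE, FALSE, delta = 1)   # (2, 0)
#' allocate_resources(FALSE, FALSE, delta = 0.5) # (1, 1)
#' @export
allocate_resources <- function(prev_success_ij, prev_success_ji, delta) {
  if (any(delta < 0 | delta > 1) || anyNA(delta)) {
    stop("`delta` must lie in [0, 1]", call. = FALSE)
  }
  s_ij <- as.numeric(prev_success_ij)
  s_ji <- as.numeric(prev_success_ji)
  R_i <- 1 + delta * (s_ij - s_ji)
  list(R_i = R_i, R_j = 2 - R_i)
}

#' Payoff of one agent from its two deals with a neighbor
#'
#' Agent i's payoff from the pair (i, j) in one round is
#' `(1 - p_i) H(p_i - q_j) R_i + p_j H(p_j - q_i) R_j`: as proposer it keeps
#' `1 - p_i` of resource `R_i` if its offer is accepted, and as responder
#' it receives share `p_j` of resource `R_j` if it accepts j's offer.
#'
#' @param p_i,q_i norm of the focal agent i.
#' @param p_j,q_j norm of the neighbor j.
#' @param R_i resource of the deal where i proposes.
#' @param R_j resource of the deal where j proposes.
#' @return numeric payoff(s) of agent i, in `[0, R_i + R_j]`.
#' @examples
#' pair_payoff(0.4, 0.3, 0.2, 0.1, 1, 1)  # 0.6
#' pair_payoff(0.2, 0.1, 0.4, 0.3, 1, 1)  # 0.4
#' @export
pair_payoff <- function(p_i, q_i, p_j, q_j, R_i, R_j) {
  if (any(R_i < 0) || any(R_j < 0)) {
    stop("resources must be non-negative", call. = FALSE)
  }
  (1 - p_i) * (p_i >= q_j) * R_i + p_j * (p_j >= q_i) * R_j
}

#' Population state for the agent-based model
#'
#' Bundles everything the per-step phases read and write: the agents'
#' norms, their per-agent resource-management intensities, the deal ledger
#' (one-step memory of deal outcomes, one boolean per ordered neighbor
#' pair), the network, and the payoffs from the last interaction phase.
#'
#' The ledger starts all-`TRUE`, the unique state under which every deal of
#' the first round is played over a unit resource. It is stored as a dense
#' `N x N` logical matrix for all network types; at the population sizes
#' this model targets the dense form is small and uniform.
#'
#' @param p,q numeric vectors of norm components, in `[0, 0.5]`.
#' @param delta per-agent resource-management intensity; recycled to length
#'   `N`; in `[0, 1]`. The intensity applied on an edge (i, j) is
#'   `min(delta[i], delta[j])`.
#' @param adj `NULL` for a complete graph, else a list of integer vectors:
#'   `adj[[i]]` holds the (1-based, sorted) neighbors of agent i.
#' @param ledger optional `N x N` logical matrix of previous deal outcomes
#'   (`ledger[i, j]` = did the deal with i proposing to j succeed);
#'   defaults to all-`TRUE`.
#' @return an object of class `ug_state`.
#' @examples
#' st <- ug_state(p = c(0.4, 0.2), q = c(0.3, 0.1), delta = 1)
#' @export
ug_state <- function(p, q, delta = 0, adj = NULL, ledger = NULL) {
  check_norms(p, q)
  n <- length(p)
  if (n < 1L) stop("population must be non-empty", call. = FALSE)
  delta <- rep_len(as.numeric(delta), n)
  if (any(delta < 0 | delta > 1)) stop("`delta` must lie in [0, 1]", call. = FALSE)
  if (!is.null(adj)) {
    stopifnot(is.list(adj), length(adj) == n)
    adj <- lapply(adj, function(v) sort(as.integer(v)))
    if (any(vapply(adj, function(v) any(v < 1L | v > n), logical(1)))) {
      stop("adjacency indices out of range", call. = FALSE)
    }
  }
  if (is.null(ledger)) {
    ledger <- matrix(TRUE, n, n)
  } else {
    stopifnot(is.logical(ledger), all(dim(ledger) == c(n, n)))
  }
  structure(
    list(p = as.numeric(p), q = as.numeric(q), delta = delta,
         adj = adj, ledger = ledger, payoff = rep(0, n), n = n),
    class = "ug_state"
  )
}

#' @export
print.ug_state <- function(x, ...) {
  net <- if (is.null(x$adj)) "complete graph" else "edge-list network"
  cat(sprintf("<ug_state> %d agents on a %s\n", x$n, net))
  cat(sprintf("  mean norm [%.3f, %.3f], mean delta %.3f\n",
              mean(x$p), mean(x$q), mean(x$delta)))
  invisible(x)
}

## neighbor count per agent
degrees <- function(state) {
  if (is.null(state$adj)) rep(state$n - 1L, state$n)
  else lengths(state$adj)
}

#' Individual interaction phase
#'
#' Every agent plays the Ultimatum Game with each neighbor, once as
#' proposer and once as responder. Resources for each deal come from
#' [allocate_resources()] applied to the previous round's ledger with the
#' edge intensity `min(delta[i], delta[j])`; the payoff of an agent is the
#' *mean* of its pairwise payoffs over its `M_i` neighbors. The ledger is
#' replaced by the current round's deal outcomes. Isolated agents receive
#' payoff 0.
#'
#' @param state a [ug_state()].
#' @return the state with updated `payoff` and `ledger`.
#' @export
interaction_phase <- function(state) {
  stopifnot(inherits(state, "ug_state"))
  n <- state$n
  p <- state$p
  q <- state$q
  if (is.null(state$adj)) {
    ## complete-graph vectorized path
    S <- outer(p, q, ">=")                     # S[i, j]: i's offer meets j's bar
    Dm <- outer(state$delta, state$delta, pmin)
    Rm <- 1 + Dm * (state$ledger - t(state$ledger))  # resource of deal (i -> j)
    ## the partner deal's resource is the exact complement 2 - R, as in
    ## allocate_resources(); row i collects agent i's two terms per pair
    Pm <- (1 - p) * S * Rm + t(p * S) * (2 - Rm)
    diag(Pm) <- 0
    state$payoff <- if (n > 1L) rowSums(Pm) / (n - 1L) else rep(0, n)
    diag(S) <- FALSE   # no self-edge; keep the ledger diagonal inert
    state$ledger <- S
  } else {
    S <- matrix(FALSE, n, n)
    pay <- rep(0, n)
    for (i in seq_len(n)) {
      for (j in state$adj[[i]]) {
        if (j <= i) next
        s_ij <- p[i] >= q[j]
        s_ji <- p[j] >= q[i]
        r <- allocate_resources(state$ledger[i, j], state$ledger[j, i],
                                min(state$delta[i], state$delta[j]))
        pay[i] <- pay[i] + ((1 - p[i]) * s_ij * r$R_i + p[j] * s_ji * r$R_j)
        pay[j] <- pay[j] + ((1 - p[j]) * s_ji * r$R_j + p[i] * s_ij * r$R_i)
        S[i, j] <- s_ij
        S[j, i] <- s_ji
      }
    }
    deg <- degrees(state)
    state$payoff <- ifelse(deg > 0L, pay / pmax(deg, 1L), 0)
    state$ledger <- S
  }
  state
}
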