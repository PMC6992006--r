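#' Empathy level of a norm
#'
#' `e_i = 1 - |p_i - q_i| / 0.5`: how close an agent's offer is to its own
#' acceptance threshold. 1 for fully empathetic norms (`p = q`), 0 at the
#' maximal discrepancy `|p - q| = 0.5`.
#'
#' @param p,q norm components, vectorized.
#' @return empathy level(s) in `[0, 1]`.
#' @examples
#' empathy_of(0.3, 0.3)   # 1
#' empathy_of(0.5, 0)     # 0
#' @export
empathy_of <- function(p, q) {
  check_norms(p, q)
  1 - abs(p - q) / 0.5
}

#' Conformity level of a norm relative to the population mean norm
#'
#' `c_i = 1 - dist([p_i, q_i], [p_bar, q_bar]) / (sqrt(2) / 2)`: Euclidean
#' closeness of an individual norm to the social norm (the concurrent
#' population mean), normalized by the diameter `sqrt(2)/2` of the norm
#' square so that `c_i` lies in `[0, 1]`.
#'
#' @param p,q norm components, vectorized.
#' @param p_bar,q_bar population mean offer and acceptance levels.
#' @return conformity level(s) in `[0, 1]`.
#' @examples
#' conformity_of(0.25, 0.25, 0.25, 0.25)  # 1
#' conformity_of(0, 0, 0.5, 0.5)          # 0
#' @export
conformity_of <- function(p, q, p_bar, q_bar) {
  check_norms(p, q)
  1 - sqrt((p - p_bar)^2 + (q - q_bar)^2) / (sqrt(2) / 2)
}

#' Summarize a population state
#'
#' Computes the population variables at one time step: mean offer `p_bar`,
#' mean acceptance `q_bar` (fairness), mean empathy `e_bar`, collective
#' conformity `c_bar` (computed against the same-step means), and mean
#' resource-management intensity `delta_bar`.
#'
#' @param state a [ug_state()], or any list with numeric `p`, `q`, `delta`.
#' @param t time step to record (default `NA`).
#' @return a one-row `data.frame` with columns
#'   `t, p_bar, q_bar, e_bar, c_bar, delta_bar`.
#' @export
summarize_population <- function(state, t = NA_integer_) {
  p <- state$p
  q <- state$q
  if (length(p) == 0L) stop("population must be non-empty", call. = FALSE)
  p_bar <- mean(p)
  q_bar <- mean(q)
  data.frame(
    t = as.integer(t),
    p_bar = p_bar,
    q_bar = q_bar,
    e_bar = mean(empathy_of(p, q)),
    c_bar = mean(conformity_of(p, q, p_bar, q_bar)),
    delta_bar = mean(state$delta)
  )
}

#' Average a time series over an equilibrium window
#'
#' Field-wise arithmetic mean of the recorded summaries with
#' `transient < t <= transient + window`, the standard way to report the
#' stationary (oscillatory) state of a long run.
#'
#' @param series a `data.frame` as produced by [run_simulation()], with a
#'   `t` column.
#' @param transient number of initial time steps to discard.
#' @param window number of time steps to average over.
#' @return a one-row `data.frame` of window means (with `t` set to the
#'   window end).
#' @export
equilibrium_average <- function(series, transient, window) {
  stopifnot(is.data.frame(series), "t" %in% names(series),
            transient >= 0, window > 0)
  keep <- series$t > transient & series$t <= transient + window
  if (!any(keep)) {
    stop("series too short: no recorded steps fall in (transient, transient + window]",
         call. = FALSE)
  }
  out <- as.data.frame(lapply(series[keep, , drop = FALSE], mean))
  out$t <- transient + window
  out
}

#' 2-D histogram of the norm distribution
#'
#' Bins the agents' norms on a regular grid over `[0, 0.5]^2`, the raw
#' material for norm-distribution snapshots of the initial and stationary
#' states.
#'
#' @param state a [ug_state()] (or list with `p`, `q`).
#' @param bins number of bins per axis (default 50).
#' @return a `bins x bins` integer matrix of counts; rows index `p` bins,
#'   columns `q` bins, with bin breaks attached as attributes.
#' @export
norm_histogram <- function(state, bins = 50L) {
  stopifnot(bins >= 1L)
  breaks <- seq(0, 0.5, length.out = bins + 1L)
  ip <- findInterval(state$p, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  iq <- findInterval(state$q, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- matrix(0L, bins, bins)
  for (k in seq_along(ip)) h[ip[k], iq[k]] <- h[ip[k], iq[k]] + 1L
  attr(h, "breaks") <- breaks
  h
}
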