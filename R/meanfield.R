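#' Build the 2x2 mini Ultimatum Game between two discrete norms
#'
#' Reduces the full model to two self-compatible norms: a generous
#' (egalitarian) norm `IN2 = [p2, q2]` and a less generous norm
#' `IN1 = [p1, q1]`, with `p2 > p1` and `p2 >= q1`. Three orderings arise:
#'
#' 1. `q1 <= q2 <= p1 < p2`: both cross-deals succeed;
#' 2. `q2 < q1 <= p1 < p2`: both cross-deals succeed;
#' 3. `q1 <= p1 < q2 <= p2`: IN1's offer to IN2 is rejected.
#'
#' Matrix entries are the stationary per-round pair payoffs after the deal
#' ledger has settled (one round of burn-in): in cases 1-2 every deal
#' succeeds, all resources stay at 1 and the matrix is independent of
#' `delta`; in case 3 the persistent conflict shifts resources, giving
#' `(a, b, c, d) = (1, (1 - p2)(1 + delta), p2 (1 + delta), 1)` where `a`
#' (`d`) is the payoff of an IN2 (IN1) player against its own kind and `b`
#' (`c`) the payoff of an IN2 (IN1) player in a mixed pair.
#'
#' @param norm1 less generous norm, a length-2 numeric `c(p, q)`.
#' @param norm2 more generous norm, a length-2 numeric `c(p, q)`.
#' @param delta resource-management intensity in `[0, 1]`.
#' @return an object of class `ug_minigame` with fields `a, b, c, d`,
#'   `case_id`, `norm1`, `norm2`, `delta`.
#' @examples
#' build_minigame(c(0.2, 0.1), c(0.4, 0.3), delta = 0)  # (1, 0.6, 0.4, 1)
#' @export
build_minigame <- function(norm1, norm2, delta) {
  stopifnot(length(norm1) == 2L, length(norm2) == 2L,
            delta >= 0, delta <= 1)
  p1 <- norm1[[1]]; q1 <- norm1[[2]]
  p2 <- norm2[[1]]; q2 <- norm2[[2]]
  check_norms(c(p1, p2), c(q1, q2))
  if (p1 < q1 || p2 < q2) {
    stop("both norms must be self-compatible (p >= q)", call. = FALSE)
  }
  if (!(p2 > p1 && p2 >= q1)) {
    stop("`norm2` must be more generous than `norm1` (p2 > p1 and p2 >= q1)",
         call. = FALSE)
  }
  ## stationary cross-deal outcomes (static, since the norms are fixed)
  s21 <- p2 >= q1   # IN2 proposes to IN1; TRUE by the generosity premise
  s12 <- p1 >= q2   # IN1 proposes to IN2
  case_id <- if (s12) (if (q1 <= q2) 1L else 2L) else 3L
  ## settled resources for the mixed pair
  r21 <- 1 + delta * (s21 - s12)   # deal where IN2 proposes
  r12 <- 2 - r21
  b <- (1 - p2) * s21 * r21 + p1 * s12 * r12   # IN2 player vs IN1 player
  cc <- (1 - p1) * s12 * r12 + p2 * s21 * r21  # IN1 player vs IN2 player
  structure(
    list(a = 1, b = b, c = cc, d = 1, case_id = case_id,
         norm1 = c(p = p1, q = q1), norm2 = c(p = p2, q = q2),
         delta = delta),
    class = "ug_minigame"
  )
}

#' @export
print.ug_minigame <- function(x, ...) {
  cat(sprintf("<ug_minigame> case %d, delta = %g\n", x$case_id, x$delta))
  cat(sprintf("  IN2 = [%.3f, %.3f], IN1 = [%.3f, %.3f]\n",
              x$norm2[1], x$norm2[2], x$norm1[1], x$norm1[2]))
  cat(sprintf("  payoff matrix (a b / c d): %.4f %.4f / %.4f %.4f\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Replicator-dynamics analysis of a 2x2 mini-game
#'
#' For the frequency `x` of IN2 players, the replicator equation is
#' `dx/dt = x (1 - x) [(a - c) x + (b - d)(1 - x)]`. The interior fixed
#' point, when it lies in (0, 1), is `x* = (d - b) / (a - b - c + d)`.
#' Regimes for the games built here (`a = d = 1`):
#' * `bistable` (`a > c`, `b < d`): both norms are best replies to
#'   themselves; `x*` is unstable and the basin of all-IN2 is `1 - x*`;
#' * `IN2-dominant` (`a >= c`, `b >= d`, not neutral): IN2 fixates from any
#'   interior frequency, basin 1;
#' * `IN1-dominant` (mirror case), basin 0;
#' * `neutral` (`a = c`, `b = d`): no basin claim (basin `NA`).
#'
#' @param game a [build_minigame()] result (or any list with `a,b,c,d`).
#' @return an object of class `ug_replicator`: fields `x_star` (interior
#'   fixed point or `NA`), `regime`, `basin_IN2`.
#' @examples
#' replicator_analyze(build_minigame(c(0.2, 0.1), c(0.4, 0.3), 0))
#' @export
replicator_analyze <- function(game) {
  a <- game$a; b <- game$b; cc <- game$c; d <- game$d
  stopifnot(is.finite(a + b + cc + d))
  x_star <- NA_real_
  denom <- a - b - cc + d
  if (a == cc && b == d) {
    regime <- "neutral"
    basin <- NA_real_
  } else if (a > cc && b < d) {
    regime <- "bistable"
    x_star <- (d - b) / denom
    basin <- 1 - x_star
  } else if (a >= cc && b >= d) {
    regime <- "IN2-dominant"
    basin <- 1
  } else if (a <= cc && b <= d) {
    regime <- "IN1-dominant"
    basin <- 0
  } else {
    ## a < c and b > d: stable interior coexistence (not reachable from
    ## the mini-game construction, handled for completeness)
    regime <- "coexistence"
    x_star <- (d - b) / denom
    basin <- NA_real_
  }
  structure(list(x_star = x_star, regime = regime, basin_IN2 = basin,
                 game = game[c("a", "b", "c", "d")]),
            class = "ug_replicator")
}

#' @export
print.ug_replicator <- function(x, ...) {
  cat(sprintf("<ug_replicator> regime %s, x* = %s, basin(IN2) = %s\n",
              x$regime, format(x$x_star), format(x$basin_IN2)))
  invisible(x)
}

## replicator vector field for deSolve
replicator_rhs <- function(t, x, parms) {
  fdiff <- (parms$a - parms$c) * x + (parms$b - parms$d) * (1 - x)
  list(x * (1 - x) * fdiff)
}

#' Fate of an initial IN2 frequency under forward integration
#'
#' Numerically integrates the replicator ODE from `x0` with
#' [deSolve::ode()] until the trajectory is absorbed near 0 or 1 (within
#' `tol`), and reports the absorbing end.
#'
#' @param game a [build_minigame()] result or list with `a,b,c,d`.
#' @param x0 initial frequency of IN2 in (0, 1).
#' @param t_max integration horizon.
#' @param tol absorbing tolerance near the boundaries.
#' @return `1` if the trajectory is absorbed at all-IN2, `0` at all-IN1,
#'   `NA` if neither within `t_max` (slow/neutral dynamics).
#' @export
replicator_fate <- function(game, x0, t_max = 20000, tol = 1e-9) {
  stopifnot(x0 > 0, x0 < 1)
  parms <- game[c("a", "b", "c", "d")]
  root <- function(t, x, parms) min(x - tol, 1 - tol - x)
  sol <- deSolve::ode(y = c(x = x0), times = c(0, t_max),
                      func = replicator_rhs, parms = parms,
                      rootfun = root, method = "lsodar",
                      rtol = 1e-10, atol = 1e-12)
  x_end <- sol[nrow(sol), "x"]
  if (x_end >= 1 - 2 * tol) 1
  else if (x_end <= 2 * tol) 0
  else NA_real_
}

#' Basin boundary of a bistable mini-game by forward integration
#'
#' Independent numerical check of the closed-form interior fixed point:
#' bisects on the initial frequency between a point absorbed at all-IN1
#' and one absorbed at all-IN2.
#'
#' @inheritParams replicator_fate
#' @param tol bisection tolerance on the boundary location.
#' @return the basin boundary (the unstable fixed point) to within `tol`.
#' @export
basin_boundary_ode <- function(game, tol = 1e-7) {
  lo <- 1e-6
  hi <- 1 - 1e-6
  if (!identical(replicator_fate(game, lo), 0) ||
      !identical(replicator_fate(game, hi), 1)) {
    stop("game is not bistable with IN1 stable at 0 and IN2 stable at 1",
         call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f <- replicator_fate(game, mid)
    if (is.na(f)) stop("integration did not absorb; increase t_max", call. = FALSE)
    if (f == 1) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Minimal resource-management intensity for IN2 dominance
#'
#' In a case-3 mini-game the IN2-vs-IN1 payoff is
#' `b' = (1 - p2)(1 + delta)`; IN2 dominates once `b' >= d' = 1`, i.e. at
#' `delta* = p2 / (1 - p2)`. The gap `b' - c' = (1 - 2 p2)(1 + delta)`
#' grows with `delta` for `p2 < 1/2`, which is the mechanism enlarging the
#' egalitarian basin. At `p2 = 1/2` the mixed-pair payoffs are equal for
#' every `delta` (a draw at best), so dominance is unattainable.
#'
#' @param p2 offer level of the egalitarian norm, in (0, 0.5].
#' @return `delta*` in `(0, 1]`; `NA` (with a message attribute) when
#'   `p2 >= 0.5` or when `delta*` would exceed 1.
#' @examples
#' dominance_threshold(0.4)  # 2/3
#' @export
dominance_threshold <- function(p2) {
  stopifnot(p2 > 0, p2 <= 0.5)
  if (p2 >= 0.5) {
    return(structure(NA_real_, reason = "no dominance for any delta"))
  }
  dstar <- p2 / (1 - p2)
  if (dstar > 1) {
    return(structure(NA_real_,
                     reason = "dominance unreachable within delta <= 1"))
  }
  dstar
}

#' Replicator phase grid over (p2, delta)
#'
#' Sweeps the egalitarian offer level `p2` and the management intensity
#' `delta` for the canonical case-3 pairing of an egalitarian norm
#' `IN2 = [p2, p2]` against the selfish norm `IN1 = [0, 0]`, classifying
#' each cell's replicator regime.
#'
#' @param p2_values grid of egalitarian offer levels in (0, 0.5].
#' @param delta_values grid of intensities in `[0, 1]`.
#' @return a `data.frame` with columns `p2, delta, regime, x_star,
#'   basin_IN2`.
#' @export
meanfield_grid <- function(p2_values = seq(0.05, 0.5, length.out = 50),
                           delta_values = seq(0, 1, length.out = 50)) {
  grid <- expand.grid(p2 = p2_values, delta = delta_values,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    g <- build_minigame(c(0, 0), c(grid$p2[k], grid$p2[k]), grid$delta[k])
    r <- replicator_analyze(g)
    data.frame(p2 = grid$p2[k], delta = grid$delta[k], regime = r$regime,
               x_star = r$x_star, basin_IN2 = r$basin_IN2)
  })
  do.call(rbind, res)
}
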