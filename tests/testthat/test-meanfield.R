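test_that("mini-game matrices reproduce the conflict-case entries exactly", {
  # case 3 pairing (stingy proposals rejected), no resource management
  g0 <- build_minigame(c(0.2, 0.1), c(0.4, 0.3), delta = 0)
  expect_identical(g0$case_id, 3L)
  expect_identical(c(g0$a, g0$b, g0$c, g0$d), c(1, 0.6, 0.4, 1))
  # full resource management doubles the surviving deal's resource
  g1 <- build_minigame(c(0.2, 0.1), c(0.4, 0.3), delta = 1)
  expect_identical(c(g1$a, g1$b, g1$c, g1$d), c(1, 1.2, 0.8, 1))
  # generic delta: b = (1 - p2)(1 + delta), c = p2 (1 + delta)
  for (d in seq(0, 1, by = 0.25)) {
    g <- build_minigame(c(0.2, 0.1), c(0.4, 0.3), delta = d)
    expect_equal(g$b, 0.6 * (1 + d))
    expect_equal(g$c, 0.4 * (1 + d))
  }
})

test_that("cases 1 and 2 are classified correctly and are delta-invariant", {
  # case 1: q1 <= q2 <= p1 < p2
  m0 <- build_minigame(c(0.3, 0.05), c(0.4, 0.1), delta = 0)
  m1 <- build_minigame(c(0.3, 0.05), c(0.4, 0.1), delta = 1)
  expect_identical(m0$case_id, 1L)
  expect_identical(c(m0$a, m0$b, m0$c, m0$d), c(m1$a, m1$b, m1$c, m1$d))
  # case 2: q2 < q1 <= p1 < p2
  m2 <- build_minigame(c(0.3, 0.2), c(0.4, 0.1), delta = 0.7)
  expect_identical(m2$case_id, 2L)
  expect_identical(c(m2$a, m2$b, m2$c, m2$d),
                   with(build_minigame(c(0.3, 0.2), c(0.4, 0.1), 0),
                        c(a, b, c, d)))
  # both cross-deals succeed: entries from unit resources
  expect_equal(m0$b, (1 - 0.4) + 0.3)
  expect_equal(m0$c, (1 - 0.3) + 0.4)
})

test_that("mini-game construction rejects invalid norm pairs", {
  expect_error(build_minigame(c(0.1, 0.3), c(0.4, 0.3), 0), "self-compatible")
  expect_error(build_minigame(c(0.4, 0.3), c(0.2, 0.1), 0), "more generous")
})

test_that("replicator analysis finds the bistable fixed point and the dominance regimes", {
  r <- replicator_analyze(list(a = 1, b = 0.6, c = 0.4, d = 1))
  expect_equal(r$regime, "bistable")
  expect_equal(r$x_star, 0.4)
  expect_equal(r$basin_IN2, 0.6)

  r <- replicator_analyze(list(a = 1, b = 1.2, c = 0.8, d = 1))
  expect_equal(r$regime, "IN2-dominant")
  expect_equal(r$basin_IN2, 1)

  r <- replicator_analyze(list(a = 1, b = 1, c = 1, d = 1))
  expect_equal(r$regime, "neutral")
  expect_true(is.na(r$basin_IN2))
})

test_that("risk dominance of the generous norm at delta = 0: basin exceeds one half", {
  for (p2 in c(0.1, 0.25, 0.4, 0.49)) {
    g <- build_minigame(c(0, 0), c(p2, p2), delta = 0)
    r <- replicator_analyze(g)
    expect_equal(r$regime, "bistable")
    expect_equal(r$basin_IN2, 1 - p2)
    expect_gt(r$basin_IN2, 0.5)
  }
})

test_that("the mixed-pair payoff gap grows linearly in delta below p2 = 1/2", {
  for (p2 in c(0.2, 0.35, 0.45)) {
    gaps <- sapply(seq(0, 1, by = 0.1), function(d) {
      g <- build_minigame(c(0, 0), c(p2, p2), d)
      g$b - g$c
    })
    expect_equal(gaps, (1 - 2 * p2) * (1 + seq(0, 1, by = 0.1)))
    expect_true(all(diff(gaps) > 0))
  }
  # at p2 = 1/2 the gap vanishes for every delta: a draw at best
  gaps <- sapply(c(0, 0.5, 1), function(d) {
    g <- build_minigame(c(0, 0), c(0.5, 0.5), d)
    g$b - g$c
  })
  expect_equal(gaps, rep(0, 3))
})

test_that("dominance threshold solves (1 - p2)(1 + delta) = 1", {
  expect_equal(dominance_threshold(0.4), 2 / 3)
  expect_equal(dominance_threshold(0.25), 1 / 3)
  expect_lt(dominance_threshold(1e-4), 2e-4)  # vanishes with p2
  expect_true(is.na(dominance_threshold(0.5)))
  # the regime flips exactly at the threshold
  p2 <- 0.4
  dstar <- dominance_threshold(p2)
  below <- replicator_analyze(build_minigame(c(0, 0), c(p2, p2), dstar - 1e-9))
  above <- replicator_analyze(build_minigame(c(0, 0), c(p2, p2),
                                             min(dstar + 1e-9, 1)))
  expect_equal(below$regime, "bistable")
  expect_equal(above$regime, "IN2-dominant")
})

test_that("basin of the egalitarian norm is nondecreasing in delta across the phase grid", {
  grid <- meanfield_grid(p2_values = seq(0.05, 0.5, length.out = 50),
                         delta_values = seq(0, 1, length.out = 50))
  expect_equal(nrow(grid), 2500L)
  for (p2 in unique(grid$p2)) {
    sub <- grid[grid$p2 == p2, ]
    sub <- sub[order(sub$delta), ]
    b <- sub$basin_IN2
    b[is.na(b)] <- 1  # neutral cells only arise at p2 = 1/2, delta = 1
    expect_true(all(diff(b) >= -1e-12))
  }
})

test_that("closed-form fixed points agree with replicator forward integration", {
  for (p2 in c(0.2, 0.3, 0.4)) {
    for (frac in c(0.15, 0.6)) {
      d <- frac * dominance_threshold(p2)
      g <- build_minigame(c(0, 0), c(p2, p2), d)
      r <- replicator_analyze(g)
      expect_equal(r$regime, "bistable")
      expect_equal(basin_boundary_ode(g, tol = 1e-8), r$x_star,
                   tolerance = 1e-6)
    }
  }
  # dominant game: every interior start is absorbed at all-IN2
  g <- build_minigame(c(0, 0), c(0.3, 0.3), delta = 0.9)
  expect_equal(replicator_analyze(g)$regime, "IN2-dominant")
  for (x0 in c(0.01, 0.2, 0.9)) expect_equal(replicator_fate(g, x0), 1)
})

test_that("two-norm agent simulations are absorbed on the side the replicator analysis predicts", {
  # IN1 = [0.2, 0.1], IN2 = [0.4, 0.3]: at delta = 0 bistable with
  # x* = 0.4; at delta = 1 the generous norm dominates
  two_norm_fate <- function(x0, delta, seed, n = 200, horizon = 3000) {
    set.seed(seed)
    n2 <- round(x0 * n)
    idx <- sample.int(n, n2)
    p <- rep(0.2, n); q <- rep(0.1, n)
    p[idx] <- 0.4; q[idx] <- 0.3
    st <- ug_state(p, q, delta = delta)
    pars <- ug_params(delta = delta, mu = 0, K = 0.1, eps = 0)
    for (t in seq_len(horizon)) {
      st <- interaction_phase(st)
      st <- norm_update_phase(st, pars)
      x <- mean(st$p == 0.4)
      if (x == 0 || x == 1) return(x)
    }
    mean(st$p == 0.4)
  }
  expect_equal(two_norm_fate(0.70, delta = 0, seed = 21), 1)
  expect_equal(two_norm_fate(0.15, delta = 0, seed = 22), 0)
  # under dominance the generous norm wins even from below the delta = 0
  # unstable point (noise at K = 0.1 still eliminates tiny minorities,
  # whose first-round payoffs predate the resource shift)
  for (seed in 21:23) expect_equal(two_norm_fate(0.30, delta = 1, seed), 1)
})
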