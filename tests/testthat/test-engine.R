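test_that("identical seed and configuration give identical runs", {
  cfg <- run_config(n = 60, horizon = 80, seed = 99,
                    params = ug_params(delta = 1, mu = 0.02, K = 0.1,
                                       eps = 5e-3, s = 0.2))
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$state$p, r2$state$p)
  expect_identical(r1$state$delta, r2$state$delta)
  # and CSV outputs are byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  write_run(r1, d1); write_run(r2, d2)
  expect_identical(readLines(file.path(d1, "series.csv")),
                   readLines(file.path(d2, "series.csv")))
})

test_that("the C++ and reference R engines produce identical trajectories", {
  base <- list(n = 35L, horizon = 50L, seed = 4L)
  cases <- list(
    ug_params(delta = 1, mu = 0, K = 0.1, eps = 5e-3, s = 0),
    ug_params(delta = 0.4, mu = 0.1, K = 0.05, eps = 0.01, s = 0.7)
  )
  for (pars in cases) {
    for (net in list(NULL, ring_adj(35L))) {
      cfg_c <- run_config(n = base$n, horizon = base$horizon,
                          seed = base$seed, params = pars, network = net,
                          engine = "cpp")
      cfg_r <- cfg_c; cfg_r$engine <- "r"
      rc <- run_simulation(cfg_c)
      rr <- run_simulation(cfg_r)
      expect_identical(rc$state$p, rr$state$p)
      expect_identical(rc$state$q, rr$state$q)
      expect_identical(rc$state$delta, rr$state$delta)
      expect_identical(rc$state$payoff, rr$state$payoff)
      expect_true(all(rc$state$ledger == rr$state$ledger))
      expect_equal(rc$series, rr$series, tolerance = 1e-12)
    }
  }
})

test_that("initialization modes set up the documented populations", {
  set.seed(1)
  cfg <- run_config(n = 10000, init_mode = "uniform", seed = 123)
  st <- initialize_population(cfg)
  s <- summarize_population(st, 1)
  expect_lt(abs(s$p_bar - 0.25), 0.01)
  expect_lt(abs(s$q_bar - 0.25), 0.01)
  expect_lt(abs(s$e_bar - 2 / 3), 0.01)
  expect_lt(abs(s$c_bar - 0.7294), 0.01)
  expect_true(all(st$ledger))

  st <- initialize_population(run_config(n = 50, init_mode = "selfish"))
  s <- summarize_population(st)
  expect_equal(c(s$p_bar, s$q_bar, s$e_bar, s$c_bar), c(0, 0, 1, 1))

  st <- initialize_population(
    run_config(n = 50, init_mode = "homogeneous", init_p0 = 0.4,
               init_q0 = 0.4, violator_frac = 0))
  expect_equal(summarize_population(st)$c_bar, 1)

  set.seed(2)
  st <- initialize_population(
    run_config(n = 200, init_mode = "homogeneous", init_p0 = 0.4,
               init_q0 = 0.4, violator_frac = 0.1))
  expect_equal(sum(st$p != 0.4 | st$q != 0.4), 20L, tolerance = 1)

  # coevolution runs start without any resource management
  st <- initialize_population(
    run_config(n = 20, params = ug_params(delta = 1, s = 0.1)))
  expect_identical(st$delta, rep(0, 20))
})

test_that("fixed-delta runs conserve total payoff when every deal succeeds", {
  # all norms self-compatible and mutually acceptable: each pair splits
  # its full resource 2, so summed payoffs equal N independent of delta
  set.seed(3)
  q <- runif(30, 0, 0.2)
  p <- runif(30, 0.25, 0.5)  # every p exceeds every q
  for (d in c(0, 0.6, 1)) {
    st <- ug_state(p, q, delta = d)
    for (t in 1:3) {
      st <- interaction_phase(st)
      expect_equal(sum(st$payoff), 30)
    }
  }
})

test_that("a homogeneous population yields a constant time series", {
  cfg <- run_config(n = 40, horizon = 100, seed = 5,
                    init_mode = "homogeneous", init_p0 = 0.3,
                    init_q0 = 0.25,
                    params = ug_params(delta = 1, mu = 0, K = 0.1, eps = 0))
  r <- run_simulation(cfg)
  expect_equal(unique(r$series$p_bar), 0.3)
  expect_equal(unique(r$series$q_bar), 0.25)
  expect_equal(unique(r$series$c_bar), 1)
})

test_that("with near-deterministic imitation the less generous agent adopts the generous norm", {
  # two agents, conflict pairing, delta = 1: the generous agent earns more
  # in every round, so at tiny K the selfish agent converts
  cfg <- run_config(n = 2, horizon = 10, seed = 8,
                    params = ug_params(delta = 1, mu = 0, K = 1e-4, eps = 0))
  st <- ug_state(p = c(0.4, 0.2), q = c(0.3, 0.1), delta = 1)
  pars <- cfg$params
  set.seed(cfg$seed)
  st <- interaction_phase(st)
  expect_equal(st$payoff, c(0.6, 0.4))
  st <- norm_update_phase(st, pars)
  expect_equal(c(st$p[2], st$q[2]), c(0.4, 0.3))
  expect_equal(c(st$p[1], st$q[1]), c(0.4, 0.3))
})

test_that("edge-list networks round-trip and isolated nodes are tolerated", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("0 1", "1 2", "2 0", "3 4"), f)
  adj <- read_edgelist(f, n = 6)
  expect_length(adj, 6)
  expect_equal(adj[[1]], c(2L, 3L))
  expect_equal(adj[[6]], integer(0))
  expect_message(
    r <- run_simulation(run_config(n = 6, horizon = 30, seed = 3,
                                   network = f, params = ug_params())),
    "isolated")
  expect_true(all(is.finite(r$state$payoff)))
})

test_that("snapshots record the population at the requested steps", {
  cfg <- run_config(n = 25, horizon = 40, seed = 17,
                    snapshot_times = c(1L, 20L),
                    params = ug_params(delta = 1))
  r <- run_simulation(cfg)
  expect_named(r$snapshots, c("1", "20"))
  snap1 <- r$snapshots[["1"]]
  expect_equal(nrow(snap1), 25)
  # the t = 1 snapshot is the initial population
  set.seed(17)
  st0 <- initialize_population(cfg)
  expect_equal(snap1$p, st0$p)
  # snapshotting does not perturb the trajectory
  cfg2 <- cfg; cfg2$snapshot_times <- integer(0)
  expect_identical(run_simulation(cfg2)$state$p, r$state$p)
})

test_that("run configuration validates its spans and supports key-value files", {
  expect_error(run_config(n = 10, horizon = 100, transient = 80, window = 40),
               "horizon")
  f <- tempfile(fileext = ".cfg")
  writeLines(c("n = 30", "horizon = 50", "delta = 0.5", "mu: 0.1",
               "seed = 12", "# comment", "record_every = 5"), f)
  cfg <- parse_config(f)
  expect_equal(cfg$n, 30L)
  expect_equal(cfg$params$delta, 0.5)
  expect_equal(cfg$params$mu, 0.1)
  expect_equal(cfg$record_every, 5L)
  cfg <- parse_config(f, overrides = list(seed = "77"))
  expect_equal(cfg$seed, 77L)
  r <- run_simulation(cfg)
  expect_equal(max(r$series$t), 46)
})
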