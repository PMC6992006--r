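#' Read a plain-text edge list
#'
#' One undirected edge per line: two whitespace-separated 0-based integer
#' node ids. Self-loops and duplicate edges are dropped.
#'
#' @param path path to the edge-list file.
#' @param n number of nodes; defaults to `max(id) + 1`. Nodes without
#'   edges are kept as isolated agents (they receive payoff 0 and never
#'   imitate).
#' @return adjacency list: `adj[[i]]` holds the sorted 1-based neighbors
#'   of node i.
#' @export
read_edgelist <- function(path, n = NULL) {
  el <- read.table(path, header = FALSE,
                   colClasses = c("integer", "integer"))
  if (ncol(el) < 2L) stop("edge list needs two columns of node ids", call. = FALSE)
  a <- el[[1]] + 1L
  b <- el[[2]] + 1L
  if (any(a < 1L) || any(b < 1L)) stop("node ids must be >= 0", call. = FALSE)
  if (is.null(n)) n <- max(a, b)
  if (max(a, b) > n) stop("edge list references node id >= n", call. = FALSE)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (k in seq_along(a)) {
    adj[[a[k]]] <- c(adj[[a[k]]], b[k])
    adj[[b[k]]] <- c(adj[[b[k]]], a[k])
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Run configuration
#'
#' Collects everything a reproducible run needs. Defaults give the
#' desk-scale profile (complete graph of 500 agents, 5000 steps); the
#' published-scale protocol (10^4 agents, 10^7 steps) is obtained by
#' setting `n` and `horizon` explicitly.
#'
#' @param n population size (ignored if `network` is given and covers more
#'   nodes).
#' @param params a [ug_params()].
#' @param horizon number of time steps.
#' @param seed RNG seed; every stochastic choice of the run draws from the
#'   single generator this seeds, so a run is bit-reproducible.
#' @param init_mode `"uniform"` (norm components i.i.d. uniform on
#'   `[0, 0.5]`), `"selfish"` (all agents at `[0, 0]`), or
#'   `"homogeneous"` (all agents at `c(init_p0, init_q0)` with a fraction
#'   `violator_frac` replaced by uniform-random norms).
#' @param init_p0,init_q0 homogeneous-mode norm.
#' @param violator_frac fraction of uniform-random violators injected in
#'   homogeneous mode.
#' @param network `NULL` for a complete graph of `n` nodes, a path to an
#'   edge-list file, or an adjacency list as from [read_edgelist()].
#' @param record_every record the population summary every this many steps.
#' @param transient,window equilibrium-averaging spans (defaults: final
#'   half of the run). Must satisfy `transient + window <= horizon`.
#' @param snapshot_times steps at which to snapshot all agents' norms.
#' @param output_dir if non-`NULL`, CSV outputs and a run manifest are
#'   written there.
#' @param engine `"cpp"` (default) or `"r"`; both implement the identical
#'   update contract and RNG draw order, so they produce identical
#'   trajectories for the same seed.
#' @return an object of class `ug_config`.
#' @export
run_config <- function(n = 500L, params = ug_params(), horizon = 5000L,
                       seed = 1L, init_mode = c("uniform", "selfish",
                                                "homogeneous"),
                       init_p0 = 0.4, init_q0 = 0.4, violator_frac = 0,
                       network = NULL, record_every = 1L,
                       transient = NULL, window = NULL,
                       snapshot_times = integer(0), output_dir = NULL,
                       engine = c("cpp", "r")) {
  init_mode <- match.arg(init_mode)
  engine <- match.arg(engine)
  stopifnot(n >= 1L, horizon >= 1L, record_every >= 1L,
            violator_frac >= 0, violator_frac <= 1)
  stopifnot(inherits(params, "ug_params"))
  if (is.character(network)) network <- read_edgelist(network)
  if (!is.null(network)) {
    n <- max(n, length(network))
    if (length(network) < n) {   # pad trailing edge-free nodes
      network <- c(network, rep(list(integer(0)), n - length(network)))
    }
  }
  if (is.null(transient)) transient <- floor(horizon / 2)
  if (is.null(window)) window <- horizon - transient
  if (transient + window > horizon) {
    stop("`transient + window` must not exceed `horizon`", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), params = params, horizon = as.integer(horizon),
         seed = as.integer(seed), init_mode = init_mode,
         init_p0 = init_p0, init_q0 = init_q0,
         violator_frac = violator_frac, network = network,
         record_every = as.integer(record_every),
         transient = as.integer(transient), window = as.integer(window),
         snapshot_times = as.integer(snapshot_times),
         output_dir = output_dir, engine = engine),
    class = "ug_config"
  )
}

#' Initialize a population from a run configuration
#'
#' Norms per `init_mode`; the deal ledger all-`TRUE` (every first-round
#' resource equals 1); `delta_i` set to the fixed intensity
#' `params$delta` when coevolution is off, and to 0 when it is on
#' (`s > 0`), matching the protocol where resource management must evolve
#' from absence.
#'
#' @param config a [run_config()].
#' @return a [ug_state()].
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "ug_config"))
  n <- config$n
  mode <- config$init_mode
  if (mode == "uniform") {
    p <- runif(n, 0, 0.5)
    q <- runif(n, 0, 0.5)
  } else if (mode == "selfish") {
    p <- rep(0, n)
    q <- rep(0, n)
  } else {
    p <- rep(config$init_p0, n)
    q <- rep(config$init_q0, n)
    n_viol <- round(config$violator_frac * n)
    if (n_viol > 0) {
      idx <- sample.int(n, n_viol)
      p[idx] <- runif(n_viol, 0, 0.5)
      q[idx] <- runif(n_viol, 0, 0.5)
    }
  }
  coevo <- config$params$s > 0
  delta0 <- if (coevo) 0 else config$params$delta
  st <- ug_state(p, q, delta = delta0, adj = config$network)
  if (!is.null(st$adj) && any(lengths(st$adj) == 0L)) {
    message("network contains isolated nodes; they receive payoff 0")
  }
  st
}

## adjacency list -> 0-based CSR for the C++ engine
adj_to_csr <- function(adj) {
  deg <- lengths(adj)
  list(neighbors = as.integer(unlist(adj, use.names = FALSE) - 1L),
       offsets = as.integer(c(0L, cumsum(deg))))
}

#' Run the agent-based simulation
#'
#' Executes `horizon` time steps of interaction phase, synchronous norm
#' updating, and (when `s > 0`) the coevolutionary `delta` update, on the
#' configured network. The population summary is recorded at the *start*
#' of every `record_every`-th step, so `t = 1` describes the initial
#' state. Identical seed and configuration give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return an object of class `ug_run`: list with `series` (data.frame of
#'   recorded summaries), `equilibrium` (window average per
#'   [equilibrium_average()]), `state` (final [ug_state()]), `snapshots`
#'   (named list of per-agent data.frames at `snapshot_times`), and
#'   `config`.
#' @examples
#' cfg <- run_config(n = 30, horizon = 50, seed = 42)
#' run <- run_simulation(cfg)
#' run$equilibrium
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "ug_config"))
  set.seed(config$seed)
  state <- initialize_population(config)
  pars <- config$params
  if (pars$s > 0 && abs(pars$s * state$n - round(pars$s * state$n)) > 1e-9) {
    message(sprintf("s * N = %g is not an integer; using %d micro-steps per phase",
                    pars$s * state$n, as.integer(round(pars$s * state$n))))
  }
  snaps <- list()
  snap_times <- sort(unique(config$snapshot_times))
  take_snapshot <- function(state, t) {
    data.frame(agent_id = seq_len(state$n) - 1L, p = state$p, q = state$q,
               delta = state$delta)
  }
  ## run in segments so snapshots can be taken mid-run without disturbing
  ## the RNG stream (the engines consume draws identically per step)
  boundaries <- sort(unique(c(snap_times[snap_times >= 1 &
                                           snap_times <= config$horizon],
                              config$horizon + 1L)))
  series_chunks <- list()
  t_now <- 1L
  for (b in boundaries) {
    if (b %in% snap_times) {
      ## snapshot describes the state at step start
    }
    steps <- b - t_now
    if (steps > 0) {
      out <- run_engine(state, pars, steps, t_offset = t_now,
                        record_every = config$record_every,
                        engine = config$engine)
      state <- out$state
      series_chunks[[length(series_chunks) + 1L]] <- out$series
      t_now <- b
    }
    if (b <= config$horizon && b %in% snap_times) {
      snaps[[as.character(b)]] <- take_snapshot(state, b)
    }
  }
  series <- do.call(rbind, series_chunks)
  rownames(series) <- NULL
  eq <- equilibrium_average(series, config$transient, config$window)
  run <- structure(list(series = series, equilibrium = eq, state = state,
                        snapshots = snaps, config = config),
                   class = "ug_run")
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

## dispatch one contiguous block of steps to the chosen engine
run_engine <- function(state, pars, steps, t_offset, record_every, engine) {
  if (engine == "cpp") {
    csr <- if (is.null(state$adj)) list(neighbors = integer(0),
                                        offsets = integer(0))
           else adj_to_csr(state$adj)
    res <- run_engine_cpp(state$p, state$q, state$delta, state$ledger,
                          csr$neighbors, csr$offsets,
                          is.null(state$adj),
                          pars$mu, pars$K, pars$eps, pars$s,
                          pars$delta_perturb,
                          as.integer(steps), as.integer(t_offset),
                          as.integer(record_every))
    state$p <- res$p
    state$q <- res$q
    state$delta <- res$delta
    state$payoff <- res$payoff
    state$ledger <- res$ledger
    series <- as.data.frame(res$series)
    names(series) <- c("t", "p_bar", "q_bar", "e_bar", "c_bar", "delta_bar")
    series$t <- as.integer(series$t)
    list(state = state, series = series)
  } else {
    rows <- vector("list", steps)
    n_rec <- 0L
    for (k in seq_len(steps)) {
      t <- t_offset + k - 1L
      if ((t - 1L) %% record_every == 0L) {
        n_rec <- n_rec + 1L
        rows[[n_rec]] <- summarize_population(state, t)
      }
      state <- interaction_phase(state)
      state <- norm_update_phase(state, pars)
      if (pars$s > 0) state <- coevolution_phase(state, pars)
    }
    list(state = state, series = do.call(rbind, rows[seq_len(n_rec)]))
  }
}

#' @export
print.ug_run <- function(x, ...) {
  cat(sprintf("<ug_run> %d agents, %d steps (seed %d, engine %s)\n",
              x$config$n, x$config$horizon, x$config$seed, x$config$engine))
  cat("equilibrium window means:\n")
  print(x$equilibrium, row.names = FALSE)
  invisible(x)
}

#' Write run outputs as CSV plus a plain-text manifest
#'
#' Time series as `series.csv` (`t,p_bar,q_bar,e_bar,c_bar,delta_bar`),
#' snapshots as `snapshot_<t>.csv` (`agent_id,p,q,delta`), the equilibrium
#' summary as `equilibrium.csv`, and a `manifest.txt` with the full
#' configuration and seed.
#'
#' @param run a `ug_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$series, file.path(dir, "series.csv"), row.names = FALSE)
  write.csv(run$equilibrium, file.path(dir, "equilibrium.csv"),
            row.names = FALSE)
  for (tt in names(run$snapshots)) {
    write.csv(run$snapshots[[tt]],
              file.path(dir, sprintf("snapshot_%s.csv", tt)),
              row.names = FALSE)
  }
  cfg <- run$config
  pars <- cfg$params
  manifest <- c(
    sprintf("package: ugnorm %s", as.character(utils::packageVersion("ugnorm"))),
    sprintf("n: %d", cfg$n),
    sprintf("network: %s", if (is.null(cfg$network)) "complete" else "edge-list"),
    sprintf("horizon: %d", cfg$horizon),
    sprintf("seed: %d", cfg$seed),
    sprintf("init_mode: %s", cfg$init_mode),
    sprintf("engine: %s", cfg$engine),
    sprintf("delta: %g", pars$delta), sprintf("mu: %g", pars$mu),
    sprintf("K: %g", pars$K), sprintf("eps: %g", pars$eps),
    sprintf("s: %g", pars$s),
    sprintf("delta_perturb: %g", pars$delta_perturb),
    sprintf("record_every: %d", cfg$record_every),
    sprintf("transient: %d", cfg$transient),
    sprintf("window: %d", cfg$window)
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Parse a flat key-value configuration file
#'
#' One `key = value` (or `key: value`) pair per line; `#` starts a
#' comment. Keys match the arguments of [run_config()] and [ug_params()].
#'
#' @param path configuration file.
#' @param overrides named list of values taking precedence over the file.
#' @return a [run_config()].
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L) stop("cannot parse config line: ", ln, call. = FALSE)
      kv[[m[2]]] <- m[3]
    }
  }
  kv[names(overrides)] <- overrides
  num <- function(key, default) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  chr <- function(key, default) {
    if (is.null(kv[[key]])) default else as.character(kv[[key]])
  }
  pars <- ug_params(delta = num("delta", 1), mu = num("mu", 0),
                    K = num("K", 0.1), eps = num("eps", 5e-3),
                    s = num("s", 0),
                    delta_perturb = num("delta_perturb", 0.025))
  snap <- chr("snapshot_times", "")
  snap <- if (nzchar(snap)) as.integer(strsplit(snap, "[,; ]+")[[1]]) else integer(0)
  horizon <- as.integer(num("horizon", 5000))
  tr <- num("transient", NA)
  wd <- num("window", NA)
  run_config(
    n = as.integer(num("n", 500)), params = pars, horizon = horizon,
    seed = as.integer(num("seed", 1)),
    init_mode = chr("init_mode", "uniform"),
    init_p0 = num("init_p0", 0.4), init_q0 = num("init_q0", 0.4),
    violator_frac = num("violator_frac", 0),
    network = if (!is.null(kv[["network"]])) chr("network", NULL) else NULL,
    record_every = as.integer(num("record_every", 1)),
    transient = if (is.na(tr)) NULL else as.integer(tr),
    window = if (is.na(wd)) NULL else as.integer(wd),
    snapshot_times = snap,
    output_dir = chr("output_dir", NULL),
    engine = chr("engine", "cpp")
  )
}
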