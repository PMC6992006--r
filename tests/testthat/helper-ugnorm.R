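# Shared fixtures built in code.

# A small random population state on a complete graph.
random_state <- function(n, delta = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ug_state(p = runif(n, 0, 0.5), q = runif(n, 0, 0.5), delta = delta)
}

# A ring network adjacency list of n nodes.
ring_adj <- function(n) {
  lapply(seq_len(n), function(i) {
    sort(unique(c(i %% n + 1L, (i - 2L) %% n + 1L)))
  })
}

# Independent scalar oracle for the four-case resource-allocation table.
allocation_table_oracle <- function(s_ij, s_ji, delta) {
  if (s_ij && s_ji) c(1, 1)
  else if (s_ij && !s_ji) c(1 + delta, 1 - delta)
  else if (!s_ij && s_ji) c(1 - delta, 1 + delta)
  else c(1, 1)
}
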