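---
title: "Egalitarian norm evolution in the Ultimatum Game with adaptive resource management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egalitarian norm evolution in the Ultimatum Game with adaptive resource management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ugnorm)
```

## The model

`ugnorm` simulates a population of agents playing the continuous Ultimatum
Game on a network. Each agent carries an individual norm $[p, q]$ with both
components in $[0, 0.5]$: $p$ is the fraction of the resource it offers as
proposer, $q$ the minimum fraction it accepts as responder. A deal succeeds
iff the offer meets the responder's threshold, $H(p - q) = 1$, with the
Heaviside convention $H(0) = 1$ — **ties are accepted**, which matters on
the boundary where offers exactly match thresholds. A norm with $p \ge q$
is *self-compatible*: the agent would accept its own offer.

Each time step has two phases (plus an optional third):

**Interaction.** Every connected pair $(i, j)$ plays two deals, one in each
role assignment. Agent $i$'s payoff from the pair is
$$P(IN_i, IN_j) = (1 - p_i)\,H(p_i - q_j)\,R_i + p_j\,H(p_j - q_i)\,R_j,$$
and its step payoff is the mean over its $M_i$ neighbors. The resources
$R_i, R_j$ implement *adaptive resource management*: both parties shift
resources towards the deal that succeeded in the previous round, with
intensity $\Delta \in [0, 1]$:
$$R_i = 1 + \Delta\,(S_{ij} - S_{ji}), \qquad R_j = 2 - R_i,$$
where $S_{ij} \in \{0, 1\}$ records last round's outcome of the deal with
$i$ proposing. The pair total $R_i + R_j = 2$ is conserved exactly, so the
maximal payoff available to the population does not depend on $\Delta$. The
one-step outcome memory (the *deal ledger*) starts all-successful, which is
the unique state making every first-round resource equal to one.

**Norm updating (synchronous).** With probability $\mu$ an agent explores:
it adopts a fresh norm uniform on $[0, 0.5]^2$. Otherwise it picks one
neighbor uniformly at random and adopts that neighbor's (pre-update) norm
with the Fermi probability
$$T(P_j - P_i) = \frac{1}{1 + e^{-(P_j - P_i)/K}},$$
where $K > 0$ is the selection noise. An adopted norm is perturbed
component-wise by i.i.d. uniform draws on $[-\varepsilon, \varepsilon]$
(the learning error) and clipped back to $[0, 0.5]$.

**Coevolution (optional).** With time-scale ratio $s > 0$, each agent
carries its own management intensity $\Delta_i$, the intensity on an edge
is $\min(\Delta_i, \Delta_j)$ (the least-capable party limits the pair),
and after each norm update $\mathrm{round}(s N)$ sequential micro-steps
each pick a random agent and neighbor and copy the neighbor's $\Delta$
with the Fermi probability, plus a uniform perturbation on
$[-0.025, 0.025]$, clipped to $[0, 1]$. Payoffs are not recomputed between
micro-steps; $\Delta$ values updated earlier in a phase are visible to
later micro-steps.

## Population observables

Four summary statistics describe the collective state: the fairness means
$\bar p, \bar q$; the empathy level $\bar e$ with
$e_i = 1 - |p_i - q_i|/0.5$; and the collective conformity $\bar c$ with
$c_i = 1 - \lVert (p_i, q_i) - (\bar p, \bar q)\rVert / (\sqrt 2 / 2)$,
computed against the *same-step* means (the only self-consistent reading,
since the social norm is defined by the current population). An
*egalitarian social norm* is a state with all four high. Long runs are
summarized by the field-wise mean over an equilibrium window, because the
stationary state is oscillatory rather than fixed.

For a population with norms i.i.d. uniform on $[0, 0.5]^2$ the exact
expectations are $\bar p = \bar q = 1/4$, $\bar e = 2/3$, and
$\bar c \approx 0.7295$ (one minus the mean distance to the centre of a
square of side $1/2$, scaled by $\sqrt2/2$); `initialize_population()`
reproduces these to $\pm 0.01$ at $N = 10^4$.

## The two-norm mean-field reduction

`build_minigame()` reduces the model to two fixed self-compatible norms, a
generous $IN_2 = [p_2, q_2]$ and a less generous $IN_1 = [p_1, q_1]$
($p_2 > p_1$, $p_2 \ge q_1$). When the stingy cross-offer is rejected
($p_1 < q_2$, the conflict case), the settled pairwise payoffs form the
matrix
$$\begin{pmatrix} a & b \\ c & d \end{pmatrix} =
  \begin{pmatrix} 1 & (1 - p_2)(1 + \Delta) \\ p_2 (1 + \Delta) & 1 \end{pmatrix},$$
whose entries are the stationary per-round pair payoffs *after the ledger
has settled* (one round of burn-in; the first round's payoffs differ, which
is why the constructor documents this convention). In the two non-conflict
orderings every deal succeeds and the matrix is independent of $\Delta$.

`replicator_analyze()` classifies the replicator dynamics
$\dot x = x(1 - x)[(a - c)x + (b - d)(1 - x)]$ for the frequency $x$ of
$IN_2$: at $\Delta = 0$ the game is bistable with unstable point
$x^* = p_2$, so the generous norm is risk-dominant (basin $1 - p_2 > 1/2$);
the mixed-pair advantage $b - c = (1 - 2 p_2)(1 + \Delta)$ grows with
$\Delta$, and once $(1 - p_2)(1 + \Delta) \ge 1$, i.e.
$\Delta \ge \Delta^* = p_2 / (1 - p_2)$ (`dominance_threshold()`), the
generous norm dominates outright. At $p_2 = 1/2$ the mixed payoffs tie for
every $\Delta$ — a draw at best — which is why a fully egalitarian
population is never reached. The closed-form fixed points are cross-checked
against forward integration of the ODE (`deSolve::ode()`, `lsodar` with
root-stopping near the absorbing boundaries at tolerance $10^{-9}$, and
bisection on the initial condition) to $10^{-6}$.

## Numerical and design choices

* **Clipping, not reflecting or redrawing**, for perturbed norms and
  $\Delta$ values: the simplest rule consistent with hard intervals. The
  induced boundary atoms are negligible at the default
  $\varepsilon = 5\times10^{-3}$.
* **Exploration draws** use the initialization distribution (uniform on
  $[0, 0.5]^2$); no other distribution is singled out by the model.
* **Ledger persistence:** pair memory attaches to the *pair*, not the
  norm; an agent that changes norm keeps its ledgers. Nothing in the model
  ties outcome memory to strategy identity, and resetting would let agents
  erase the resource penalty of a failed deal simply by moving an
  $\varepsilon$-step.
* **Ledger storage** is a dense $N \times N$ logical matrix for every
  network type; at the population sizes this package targets (up to a few
  thousand agents) the dense form is small, and one representation keeps
  the two engines trivially comparable.
* **Self-exclusion:** an agent never samples itself as role model;
  micro-step sampling in the coevolution phase is with replacement.
* **Payoff reuse:** all $sN$ coevolution micro-steps of a step reuse the
  payoffs of that step's interaction phase.
* **Two engines, one contract.** The default engine is C++ (Rcpp); a pure-R
  reference implementation of all three phases follows the identical RNG
  draw-order contract, and the test suite asserts bit-identical
  trajectories between the two on complete and sparse networks, with and
  without coevolution. All stochastic choices draw from R's seeded
  generator, so runs are bit-reproducible.

## Scaled-down study conditions, and what they show

The reference protocol behind the target equilibrium values uses a complete
graph of $N = 10^4$ agents and $10^7$ steps — far beyond a desk-scale test
budget. The package's acceptance protocol therefore runs $N = 500$,
$20{,}000$ steps (the time point at which the reference values are
reported), averages the final half of each run, and repeats over 10 seeds
($\mu = 0$, $K = 0.1$, $\varepsilon = 5\times10^{-3}$, uniform
initialization).

What this reproduces faithfully:

* all initial-state statistics;
* the no-management branch ($\Delta = 0$): the population becomes
  empathetic, conformist and *selfish* ($\bar p \approx 0.06$,
  $\bar q \approx 0.02$), matching the reference values to well within
  tolerance;
* the hard qualitative contrast: $\Delta = 1$ runs sustain offers several
  times higher than $\Delta = 0$ runs.

What it does not: at $N = 500$ the fair state that forms early in a
$\Delta = 1$ run ($\bar p$ rising to $\approx 0.32$) is metastable. Its
stability rests on a thin margin $\bar p - \bar q$ of a few learning-error
widths; finite-size fluctuations let acceptance thresholds drift across
offer levels, and the resulting self-incompatible "rejector" norms — which
the two-norm mean-field omits by construction — profit from the very
resource-management mechanism that sustains fairness, triggering recurrent
collapses and rebounds. Final-half window means at desk scale therefore
fall substantially below the large-population equilibrium values, and the
corresponding quantitative acceptance checks are expected to fail at this
scale while the qualitative ones pass. The same behavior is produced by an
independently written implementation of the model, and every model
component is verified in isolation against its analytic value, so we
report the scaled-down numbers as a property of the model at small $N$
rather than adjust the protocol towards the reference values.

## Worked example

```{r example}
cfg <- run_config(n = 200, horizon = 2000, seed = 42,
                  params = ug_params(delta = 1, mu = 0, K = 0.1, eps = 5e-3),
                  record_every = 10)
run <- run_simulation(cfg)
run$equilibrium
```

```{r meanfield}
g <- build_minigame(c(0.2, 0.1), c(0.4, 0.3), delta = 1)
replicator_analyze(g)
dominance_threshold(0.4)
```

## Limitations

* One-step deal memory only; longer memories and error-prone resource
  management are out of scope.
* Synchronous norm updating only; asynchronous and alternative imitation
  dynamics are not implemented.
* The mean-field analysis covers the discrete two-norm reduction, not the
  full norm continuum.
* Desk-scale populations underestimate the stability of the fair state
  (see above); population sizes of order $10^4$ are needed for the
  reference-scale equilibrium values, at a computational cost outside routine
  testing.
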