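#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fermi (pairwise-comparison) imitation probability.
static inline double fermi(double pay_target, double pay_self, double K) {
  return 1.0 / (1.0 + std::exp(-(pay_target - pay_self) / K));
}

static inline double clip(double x, double lo, double hi) {
  return std::min(std::max(x, lo), hi);
}

// One contiguous block of time steps of the full model:
//   interaction phase -> synchronous norm update -> (optional) coevolution.
//
// The RNG draw order per step is a fixed contract shared with the pure-R
// reference engine (norm_update_phase / coevolution_phase), so both
// engines produce identical trajectories from the same seed:
//   per agent i (ascending): u_explore; [p,q] if exploring, else
//   neighbor index, u_imitate, and on success two learning-error draws;
//   then per coevolution micro-step: agent, neighbor, u, perturbation.
//
// Networks: complete graph (complete = true) or CSR adjacency with sorted
// neighbor lists (0-based `neighbors`, per-agent `offsets`).
// [[Rcpp::export]]
List run_engine_cpp(NumericVector p0, NumericVector q0,
                    NumericVector delta0, LogicalMatrix ledger0,
                    IntegerVector neighbors, IntegerVector offsets,
                    bool complete,
                    double mu, double K, double eps, double s,
                    double delta_perturb,
                    int steps, int t_offset, int record_every) {
  const int n = p0.size();
  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> q(q0.begin(), q0.end());
  std::vector<double> delta(delta0.begin(), delta0.end());
  std::vector<double> pn(n), qn(n), payoff(n, 0.0);
  // ledger[i*n + j]: previous deal outcome with i proposing to j
  std::vector<char> led(n * (size_t)n, 1), led_new(n * (size_t)n, 0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      led[(size_t)i * n + j] = (char)(ledger0(i, j) != 0);

  std::vector<int> deg(n);
  if (complete) {
    for (int i = 0; i < n; ++i) deg[i] = n - 1;
  } else {
    for (int i = 0; i < n; ++i) deg[i] = offsets[i + 1] - offsets[i];
  }

  const int n_micro = (s > 0.0) ? (int)::Rf_fround(s * n, 0.0) : 0;
  int n_rec = 0;
  for (int k = 0; k < steps; ++k)
    if ((t_offset + k - 1) % record_every == 0) ++n_rec;
  NumericMatrix series(n_rec, 6);
  int rec = 0;

  for (int k = 0; k < steps; ++k) {
    const int t = t_offset + k;

    // record the population summary at step start (t = 1 is the initial
    // state)
    if ((t - 1) % record_every == 0) {
      double sp = 0, sq = 0, se = 0, sd = 0;
      for (int i = 0; i < n; ++i) {
        sp += p[i]; sq += q[i];
        se += 1.0 - std::fabs(p[i] - q[i]) / 0.5;
        sd += delta[i];
      }
      const double p_bar = sp / n, q_bar = sq / n;
      double sc = 0;
      const double cnorm = std::sqrt(2.0) / 2.0;
      for (int i = 0; i < n; ++i) {
        const double dp = p[i] - p_bar, dq = q[i] - q_bar;
        sc += 1.0 - std::sqrt(dp * dp + dq * dq) / cnorm;
      }
      series(rec, 0) = t;
      series(rec, 1) = p_bar;
      series(rec, 2) = q_bar;
      series(rec, 3) = se / n;
      series(rec, 4) = sc / n;
      series(rec, 5) = sd / n;
      ++rec;
    }

    // ---- interaction phase ----------------------------------------
    std::fill(payoff.begin(), payoff.end(), 0.0);
    std::fill(led_new.begin(), led_new.end(), 0);
    if (complete) {
      // long-double accumulators match the reference engine, whose
      // complete-graph path sums payoff terms via rowSums()
      std::vector<long double> acc(n, 0.0L);
      for (int i = 0; i < n; ++i) {
        const double pi = p[i], qi = q[i], di = delta[i];
        for (int j = i + 1; j < n; ++j) {
          const double sij = (pi >= q[j]) ? 1.0 : 0.0;
          const double sji = (p[j] >= qi) ? 1.0 : 0.0;
          const double dmin = std::min(di, delta[j]);
          const double lij = (double)led[(size_t)i * n + j];
          const double lji = (double)led[(size_t)j * n + i];
          const double rij = 1.0 + dmin * (lij - lji);
          const double rji = 2.0 - rij;
          acc[i] += (1.0 - pi) * sij * rij + p[j] * sji * rji;
          acc[j] += (1.0 - p[j]) * sji * rji + pi * sij * rij;
          led_new[(size_t)i * n + j] = (char)(sij != 0.0);
          led_new[(size_t)j * n + i] = (char)(sji != 0.0);
        }
      }
      for (int i = 0; i < n; ++i)
        payoff[i] = (n > 1) ? (double)acc[i] / (n - 1) : 0.0;
    } else {
      for (int i = 0; i < n; ++i) {
        for (int a = offsets[i]; a < offsets[i + 1]; ++a) {
          const int j = neighbors[a];
          if (j <= i) continue;
          const double sij = (p[i] >= q[j]) ? 1.0 : 0.0;
          const double sji = (p[j] >= q[i]) ? 1.0 : 0.0;
          const double dmin = std::min(delta[i], delta[j]);
          const double lij = (double)led[(size_t)i * n + j];
          const double lji = (double)led[(size_t)j * n + i];
          const double rij = 1.0 + dmin * (lij - lji);
          const double rji = 2.0 - rij;
          payoff[i] += (1.0 - p[i]) * sij * rij + p[j] * sji * rji;
          payoff[j] += (1.0 - p[j]) * sji * rji + p[i] * sij * rij;
          led_new[(size_t)i * n + j] = (char)(sij != 0.0);
          led_new[(size_t)j * n + i] = (char)(sji != 0.0);
        }
      }
      for (int i = 0; i < n; ++i)
        payoff[i] = (deg[i] > 0) ? payoff[i] / deg[i] : 0.0;
    }
    led.swap(led_new);

    // ---- synchronous norm-updating phase --------------------------
    for (int i = 0; i < n; ++i) { pn[i] = p[i]; qn[i] = q[i]; }
    for (int i = 0; i < n; ++i) {
      const double u = unif_rand();
      if (u < mu) {
        pn[i] = 0.5 * unif_rand();
        qn[i] = 0.5 * unif_rand();
      } else if (deg[i] > 0) {
        int j;
        if (complete) {
          int idx = (int)(unif_rand() * (n - 1));
          j = idx + (idx >= i ? 1 : 0);
        } else {
          j = neighbors[offsets[i] + (int)(unif_rand() * deg[i])];
        }
        if (unif_rand() < fermi(payoff[j], payoff[i], K)) {
          const double e1 = -eps + (eps - (-eps)) * unif_rand();
          const double e2 = -eps + (eps - (-eps)) * unif_rand();
          pn[i] = clip(p[j] + e1, 0.0, 0.5);
          qn[i] = clip(q[j] + e2, 0.0, 0.5);
        }
      }
    }
    p.swap(pn);
    q.swap(qn);

    // ---- coevolution of the management intensities ----------------
    for (int m = 0; m < n_micro; ++m) {
      const int i = (int)(unif_rand() * n);
      if (deg[i] == 0) continue;
      int j;
      if (complete) {
        int idx = (int)(unif_rand() * (n - 1));
        j = idx + (idx >= i ? 1 : 0);
      } else {
        j = neighbors[offsets[i] + (int)(unif_rand() * deg[i])];
      }
      if (unif_rand() < fermi(payoff[j], payoff[i], K)) {
        const double xi = -delta_perturb +
          (delta_perturb - (-delta_perturb)) * unif_rand();
        delta[i] = clip(delta[j] + xi, 0.0, 1.0);
      }
    }
  }

  LogicalMatrix ledger_out(n, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      ledger_out(i, j) = (led[(size_t)i * n + j] != 0);

  return List::create(
    _["p"] = NumericVector(p.begin(), p.end()),
    _["q"] = NumericVector(q.begin(), q.end()),
    _["delta"] = NumericVector(delta.begin(), delta.end()),
    _["payoff"] = NumericVector(payoff.begin(), payoff.end()),
    _["ledger"] = ledger_out,
    _["series"] = series);
}
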