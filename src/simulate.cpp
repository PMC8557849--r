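#include <Rcpp.h>
using namespace Rcpp;

// Jump-chain (Gillespie) simulation of the k-allele Moran process from a
// given state over a time window.  Rates match the sparse generator:
// state-changing birth/death pairs only; self-replacements advance no
// state and are integrated out of the exponential clocks.  Uses R's RNG.
//
// x: mutant haplotype counts (length k), modified in place conceptually;
// returns the state at time t_end (absorbing states persist).
// [[Rcpp::export]]
IntegerVector cpp_sim_k_allele(IntegerVector x0, NumericVector fstar,
                               int N, double t_len) {
  int k = x0.size();
  std::vector<int> x(x0.begin(), x0.end());
  double t = 0.0;
  // event buffers: up to k*(k+1) state-changing transitions
  int maxev = k * (k + 1);
  std::vector<double> rate(maxev);
  std::vector<int> ev_l(maxev), ev_u(maxev); // u = -1: wt death; u = -2: wt birth

  for (;;) {
    int W = N;
    double D = 0.0;
    for (int j = 0; j < k; ++j) { W -= x[j]; D += x[j] * fstar[j]; }
    D += W;
    int ne = 0;
    double tot = 0.0;
    for (int l = 0; l < k; ++l) {
      if (x[l] > 0 && W > 0) {
        // wild-type birth, death of l-carrier: x -> x - e_l
        double r = ((double)W / D) * ((double)x[l] / N);
        rate[ne] = r; ev_l[ne] = l; ev_u[ne] = -2; tot += r; ++ne;
        // birth of l-carrier, wild-type death: x -> x + e_l
        r = (x[l] * fstar[l] / D) * ((double)W / N);
        rate[ne] = r; ev_l[ne] = l; ev_u[ne] = -1; tot += r; ++ne;
      }
      for (int u = 0; u < k; ++u) {
        if (u == l || x[l] == 0 || x[u] == 0) continue;
        double r = (x[l] * fstar[l] / D) * ((double)x[u] / N);
        rate[ne] = r; ev_l[ne] = l; ev_u[ne] = u; tot += r; ++ne;
      }
    }
    if (tot <= 0.0) break;                  // absorbing
    t += R::exp_rand() / tot;
    if (t > t_len) break;
    double pick = unif_rand() * tot;
    int e = 0;
    for (; e < ne - 1; ++e) { pick -= rate[e]; if (pick <= 0) break; }
    int l = ev_l[e], u = ev_u[e];
    if (u == -2) { x[l] -= 1; }
    else if (u == -1) { x[l] += 1; }
    else { x[l] += 1; x[u] -= 1; }
  }
  return IntegerVector(x.begin(), x.end());
}

// Tracked infinite-sites replicates for general K: conditional on K
// mutation arrivals (sorted uniforms on [0, tb]), simulate the nested
// k-allele intervals; each new mutation must land on a carrier of the
// most-derived haplotype (probability x_k/N) for all K mutations to be
// able to fix under complete linkage.  Returns, per replicate class,
// counts indexed by history (binary digits, "0" = fixed together with the
// next) plus a trailing "failed" count.
// [[Rcpp::export]]
IntegerVector cpp_tracked_k_replicates(int N, NumericVector f, double tb,
                                       int n_reps) {
  int K = f.size();
  int n_hist = 1 << (K - 1);
  IntegerVector counts(n_hist + 1);        // last slot = failed
  std::vector<double> tt(K);

  for (int rep = 0; rep < n_reps; ++rep) {
    for (int i = 0; i < K; ++i) tt[i] = unif_rand() * tb;
    std::sort(tt.begin(), tt.end());

    std::vector<int> x(1, 1);
    std::vector<double> fstar(1, f[0]);
    int hist = 0;
    bool failed = false;

    for (int i = 0; i < K; ++i) {
      double t_end = (i + 1 < K) ? tt[i + 1] : tb;
      IntegerVector xs = cpp_sim_k_allele(
        IntegerVector(x.begin(), x.end()),
        NumericVector(fstar.begin(), fstar.end()), N, t_end - tt[i]);
      x.assign(xs.begin(), xs.end());
      int k = (int)x.size();
      if (i + 1 < K) {
        int xk = x[k - 1];
        if (unif_rand() * N >= xk) { failed = true; break; }
        if (xk == N) {
          // intervening fixation: digit 1, wild type redefined
          hist |= (1 << (K - 2 - i));
          x.assign(1, 1);
          fstar.assign(1, f[i + 1]);
        } else {
          // same lineage, no fixation yet: digit 0, dimension grows
          x[k - 1] -= 1;
          x.push_back(1);
          fstar.push_back(fstar[k - 1] * f[i + 1]);
        }
      } else {
        // end of branch: success iff fully fixed for the derived stack
        bool fixed = (x[k - 1] == N);
        for (int j = 0; j + 1 < k; ++j) if (x[j] != 0) fixed = false;
        if (!fixed) failed = true;
      }
    }
    if (failed) counts[n_hist] += 1; else counts[hist] += 1;
  }
  return counts;
}

// Exact Gillespie realization of the finite-sites Moran model.
// pop: N x M integer matrix of character indices (0-based, alphabet size
// A); fit: M x A sitewise fitness table; mu: A x A mutation-rate matrix
// (zero diagonal).  Replacement events (individual i replaced by a copy
// of individual j) occur at rate f(X_j) / (N * sum_k f(X_k)) per ordered
// pair, so the total replacement event rate -- self-replacements
// included -- is exactly 1 per unit time; mutations A->B at each site of
// each individual occur at rate mu(A,B).  Self-replacements advance time
// but change no state.  Events are recorded (up to max_events);
// substitutions are logged whenever a site becomes monomorphic for a
// character differing from its current reference character.
// [[Rcpp::export]]
List cpp_finite_sites(IntegerMatrix pop0, NumericMatrix fit, NumericMatrix mu,
                      double tb, bool record_events, int max_events) {
  int N = pop0.nrow(), M = pop0.ncol(), A = fit.ncol();
  IntegerMatrix pop = clone(pop0);

  // per-individual fitness (multiplicative across sites)
  std::vector<double> find(N);
  for (int i = 0; i < N; ++i) {
    double p = 1.0;
    for (int s = 0; s < M; ++s) p *= fit(s, pop(i, s));
    find[i] = p;
  }
  // per-character total mutation out-rate
  std::vector<double> mu_out(A, 0.0);
  double mu_max_out = 0.0;
  for (int a = 0; a < A; ++a) {
    for (int b = 0; b < A; ++b) mu_out[a] += mu(a, b);
    mu_max_out = std::max(mu_max_out, mu_out[a]);
  }
  // reference (currently fixed) character per site, from t = 0 state;
  // requires monomorphic start for substitution bookkeeping, else takes
  // the majority character as reference
  std::vector<int> ref(M);
  for (int s = 0; s < M; ++s) {
    std::vector<int> cnt(A, 0);
    for (int i = 0; i < N; ++i) cnt[pop(i, s)] += 1;
    ref[s] = (int)(std::max_element(cnt.begin(), cnt.end()) - cnt.begin());
  }

  std::vector<double> ev_time; std::vector<int> ev_kind, ev_i, ev_j, ev_site,
    ev_from, ev_to;
  std::vector<double> sub_time; std::vector<int> sub_site, sub_from, sub_to;

  double t = 0.0;
  long long n_events = 0;
  bool truncated = false;

  auto check_substitution = [&](int s, double when) {
    int c0 = pop(0, s);
    for (int i = 1; i < N; ++i) if (pop(i, s) != c0) return;
    if (c0 != ref[s]) {
      sub_time.push_back(when); sub_site.push_back(s);
      sub_from.push_back(ref[s]); sub_to.push_back(c0);
      ref[s] = c0;
    }
  };

  for (;;) {
    // total rates: replacements 1 (by time scaling), mutations state-dep.
    double fsum = 0.0, rmut = 0.0;
    for (int i = 0; i < N; ++i) fsum += find[i];
    for (int i = 0; i < N; ++i)
      for (int s = 0; s < M; ++s) rmut += mu_out[pop(i, s)];
    double tot = 1.0 + rmut;

    // absorption shortcut: no mutation possible and population monomorphic
    if (rmut == 0.0) {
      bool mono = true;
      for (int i = 1; i < N && mono; ++i)
        for (int s = 0; s < M; ++s)
          if (pop(i, s) != pop(0, s)) { mono = false; break; }
      if (mono) break;
    }

    t += R::exp_rand() / tot;
    if (t > tb) { t = tb; break; }
    ++n_events;
    if (record_events && (int)ev_time.size() >= max_events) truncated = true;

    if (unif_rand() * tot < 1.0) {
      // replacement: parent j with probability f(X_j)/sum f, victim i uniform
      double pick = unif_rand() * fsum;
      int j = 0;
      for (; j < N - 1; ++j) { pick -= find[j]; if (pick <= 0) break; }
      int i = (int)(unif_rand() * N); if (i == N) i = N - 1;
      if (record_events && !truncated) {
        ev_time.push_back(t); ev_kind.push_back(0);
        ev_i.push_back(i); ev_j.push_back(j);
        ev_site.push_back(NA_INTEGER); ev_from.push_back(NA_INTEGER);
        ev_to.push_back(NA_INTEGER);
      }
      if (i != j) {
        std::vector<int> changed;
        for (int s = 0; s < M; ++s)
          if (pop(i, s) != pop(j, s)) { pop(i, s) = pop(j, s); changed.push_back(s); }
        if (!changed.empty()) {
          find[i] = find[j];
          for (int c : changed) check_substitution(c, t);
        }
      }
    } else {
      // mutation: cell (i, s) with probability proportional to mu_out
      double pick = unif_rand() * rmut;
      int i = 0, s = 0; bool done = false;
      for (i = 0; i < N && !done; ++i)
        for (s = 0; s < M; ++s) {
          pick -= mu_out[pop(i, s)];
          if (pick <= 0) { done = true; break; }
        }
      if (done) --i; else { i = N - 1; s = M - 1; }
      int a = pop(i, s);
      double pb = unif_rand() * mu_out[a];
      int b = -1;
      for (int c = 0; c < A; ++c) {
        if (c == a || mu(a, c) <= 0.0) continue;
        b = c; pb -= mu(a, c);
        if (pb <= 0) break;
      }
      if (b < 0) continue;                 // no admissible target (mu row ~ 0)
      pop(i, s) = b;
      find[i] = find[i] / fit(s, a) * fit(s, b);
      if (record_events && !truncated) {
        ev_time.push_back(t); ev_kind.push_back(1);
        ev_i.push_back(i); ev_j.push_back(NA_INTEGER);
        ev_site.push_back(s); ev_from.push_back(a); ev_to.push_back(b);
      }
      check_substitution(s, t);
    }
  }

  return List::create(
    _["population"] = pop,
    _["t_end"] = t,
    _["n_events"] = (double)n_events,
    _["events"] = DataFrame::create(
      _["time"] = NumericVector(ev_time.begin(), ev_time.end()),
      _["kind"] = IntegerVector(ev_kind.begin(), ev_kind.end()),
      _["individual"] = IntegerVector(ev_i.begin(), ev_i.end()),
      _["parent"] = IntegerVector(ev_j.begin(), ev_j.end()),
      _["site"] = IntegerVector(ev_site.begin(), ev_site.end()),
      _["from"] = IntegerVector(ev_from.begin(), ev_from.end()),
      _["to"] = IntegerVector(ev_to.begin(), ev_to.end())
    ),
    _["events_truncated"] = truncated,
    _["substitutions"] = DataFrame::create(
      _["time"] = NumericVector(sub_time.begin(), sub_time.end()),
      _["site"] = IntegerVector(sub_site.begin(), sub_site.end()),
      _["from"] = IntegerVector(sub_from.begin(), sub_from.end()),
      _["to"] = IntegerVector(sub_to.begin(), sub_to.end())
    )
  );
}

// Two-allele jump-chain replicates run to absorption: each row is
// (fixed 0/1, absorption time).  Used to validate conditional
// fixation-time moments against direct simulation.
// [[Rcpp::export]]
NumericMatrix cpp_two_allele_absorption_samples(int N, double f, int n_reps,
                                                int x0) {
  NumericMatrix out(n_reps, 2);
  for (int rep = 0; rep < n_reps; ++rep) {
    int x = x0;
    double t = 0.0;
    while (x > 0 && x < N) {
      double D = (double)(N - x) + x * f;
      double up = (x * f / D) * ((double)(N - x) / N);
      double dn = ((double)(N - x) / D) * ((double)x / N);
      t += R::exp_rand() / (up + dn);
      if (unif_rand() * (up + dn) < up) ++x; else --x;
    }
    out(rep, 0) = (x == N) ? 1.0 : 0.0;
    out(rep, 1) = t;
  }
  return out;
}
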