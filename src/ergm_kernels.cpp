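#include <Rcpp.h>
using namespace Rcpp;

// Term codes, kept in sync with TERM_NAMES on the R side:
// 1 edge, 2 GGG_triad, 3 GGS_triad, 4 GSS_triad, 5 GGG_chain, 6 GGS_chain,
// 7 SGS_chain, 8 two_path, 9 alt_two_paths, 10 alt_stars, 11 activity,
// 12 match, 13 mismatch, 14 dyadic_cov.

// Change statistic of one term for ADDING edge {i, j}; A(i, j) must be 0
// and deg must match A. All quantities are exact: the value equals
// g(A + ij) - g(A) for the global statistic g.
static double delta_add_one(const IntegerMatrix &A, const IntegerVector &deg,
                            const IntegerVector &role, int code, double lambda,
                            const IntegerVector &av, const NumericMatrix &cm,
                            int i, int j) {
  const int n = A.nrow();
  switch (code) {
  case 1: // edge
    return 1.0;
  case 2: case 3: case 4: { // role-attributed triangles
    int want = (code == 2) ? 3 : (code == 3) ? 2 : 1; // GP count in triangle
    int cnt = 0;
    for (int k = 0; k < n; ++k)
      if (A(i, k) && A(j, k) && role[i] + role[j] + role[k] == want) ++cnt;
    return (double)cnt;
  }
  case 5: case 6: case 7: { // open chains, center GP
    // endpoint role sum: GGG 2, GGS 1, SGS 0
    int want = (code == 5) ? 2 : (code == 6) ? 1 : 0;
    double d = 0.0;
    // new two-paths centered at i: endpoints {j, m}, open iff A(j, m) == 0
    if (role[i] == 1) {
      for (int m = 0; m < n; ++m)
        if (A(i, m) && m != j && !A(j, m) && role[j] + role[m] == want) d += 1.0;
    }
    // new two-paths centered at j
    if (role[j] == 1) {
      for (int m = 0; m < n; ++m)
        if (A(j, m) && m != i && !A(i, m) && role[i] + role[m] == want) d += 1.0;
    }
    // previously open two-paths i--k--j close
    for (int k = 0; k < n; ++k)
      if (A(i, k) && A(j, k) && role[k] == 1 && role[i] + role[j] == want)
        d -= 1.0;
    return d;
  }
  case 8: // two_path: sum choose(d, 2)
    return (double)(deg[i] + deg[j]);
  case 9: { // alt_two_paths
    const double q = 1.0 - 1.0 / lambda;
    double d = 0.0;
    for (int m = 0; m < n; ++m) {
      if (A(j, m) && m != i) { // pair {i, m} gains common neighbour j
        int L2 = 0;
        for (int k = 0; k < n; ++k) L2 += (A(i, k) && A(k, m)) ? 1 : 0;
        d += std::pow(q, (double)L2);
      }
      if (A(i, m) && m != j) { // pair {j, m} gains common neighbour i
        int L2 = 0;
        for (int k = 0; k < n; ++k) L2 += (A(j, k) && A(k, m)) ? 1 : 0;
        d += std::pow(q, (double)L2);
      }
    }
    return d;
  }
  case 10: { // alt_stars
    const double q = 1.0 - 1.0 / lambda;
    return lambda * (1.0 - std::pow(q, (double)deg[i])) +
           lambda * (1.0 - std::pow(q, (double)deg[j]));
  }
  case 11: // activity (binary attribute)
    return (double)(av[i] + av[j]);
  case 12: // match
    return av[i] == av[j] ? 1.0 : 0.0;
  case 13: // mismatch
    return av[i] != av[j] ? 1.0 : 0.0;
  case 14: // dyadic covariate
    return cm(i, j);
  default:
    stop("unknown term code");
  }
}

// Pre-extracted per-term data: pulling vectors/matrices out of the R List
// once keeps the per-proposal cost free of R API overhead.
struct TermSet {
  IntegerVector code;
  NumericVector lambda;
  std::vector<IntegerVector> av;
  std::vector<NumericMatrix> cm;
  TermSet(const IntegerVector &code_, const NumericVector &lambda_,
          const List &avec, const List &cmat)
      : code(code_), lambda(lambda_) {
    for (int t = 0; t < code.size(); ++t) {
      av.push_back(as<IntegerVector>(avec[t]));
      cm.push_back(as<NumericMatrix>(cmat[t]));
    }
  }
  int size() const { return code.size(); }
};

static void delta_add_vec(const IntegerMatrix &A, const IntegerVector &deg,
                          const IntegerVector &role, const TermSet &ts,
                          int i, int j, double *out) {
  for (int t = 0; t < ts.size(); ++t) {
    out[t] = delta_add_one(A, deg, role, ts.code[t], ts.lambda[t],
                           ts.av[t], ts.cm[t], i, j);
  }
}

// [[Rcpp::export]]
NumericVector cpp_change_stats(IntegerMatrix A, int i, int j,
                               IntegerVector code, NumericVector lambda,
                               List avec, List cmat, IntegerVector role) {
  IntegerMatrix B = clone(A);
  const int n = B.nrow();
  IntegerVector deg(n);
  if (B(i, j) == 1) { B(i, j) = 0; B(j, i) = 0; } // force the 0 state
  for (int a = 0; a < n; ++a) {
    int d = 0;
    for (int b = 0; b < n; ++b) d += B(a, b);
    deg[a] = d;
  }
  TermSet ts(code, lambda, avec, cmat);
  NumericVector out(code.size());
  delta_add_vec(B, deg, role, ts, i, j, REAL(out));
  return out;
}

// Design matrix of change statistics for all dyads i < j (row order:
// column-major over the upper triangle), plus the response y = x_ij.
// [[Rcpp::export]]
List cpp_mple_design(IntegerMatrix A, IntegerVector code, NumericVector lambda,
                     List avec, List cmat, IntegerVector role) {
  IntegerMatrix B = clone(A);
  const int n = B.nrow(), p = code.size();
  const int nd = n * (n - 1) / 2;
  IntegerVector deg(n);
  for (int a = 0; a < n; ++a) {
    int d = 0;
    for (int b = 0; b < n; ++b) d += B(a, b);
    deg[a] = d;
  }
  TermSet ts(code, lambda, avec, cmat);
  NumericMatrix X(nd, p);
  IntegerVector y(nd);
  std::vector<double> buf(p);
  int r = 0;
  for (int j = 1; j < n; ++j) {
    for (int i = 0; i < j; ++i, ++r) {
      y[r] = B(i, j);
      if (B(i, j)) { // evaluate on the 0 state
        B(i, j) = 0; B(j, i) = 0; deg[i]--; deg[j]--;
        delta_add_vec(B, deg, role, ts, i, j, buf.data());
        B(i, j) = 1; B(j, i) = 1; deg[i]++; deg[j]++;
      } else {
        delta_add_vec(B, deg, role, ts, i, j, buf.data());
      }
      for (int t = 0; t < p; ++t) X(r, t) = buf[t];
    }
  }
  return List::create(_["X"] = X, _["y"] = y);
}

struct EdgeList {
  std::vector<int> ei, ej;      // endpoints of present edges, i < j
  std::vector<int> pos;         // dyad -> position + 1 (0 = absent), i < j
  int n;
  int dyad_index(int i, int j) const {
    if (i > j) std::swap(i, j);
    return j * (j - 1) / 2 + i;
  }
  void init(const IntegerMatrix &A) {
    n = A.nrow();
    pos.assign(n * (n - 1) / 2, 0);
    for (int j = 1; j < n; ++j)
      for (int i = 0; i < j; ++i)
        if (A(i, j)) {
          ei.push_back(i); ej.push_back(j);
          pos[dyad_index(i, j)] = (int)ei.size();
        }
  }
  int size() const { return (int)ei.size(); }
  void add(int i, int j) {
    if (i > j) std::swap(i, j);
    ei.push_back(i); ej.push_back(j);
    pos[dyad_index(i, j)] = (int)ei.size();
  }
  void remove(int i, int j) {
    int d = dyad_index(i, j);
    int k = pos[d] - 1;
    int last = (int)ei.size() - 1;
    if (k != last) {
      ei[k] = ei[last]; ej[k] = ej[last];
      pos[dyad_index(ei[k], ej[k])] = k + 1;
    }
    ei.pop_back(); ej.pop_back();
    pos[d] = 0;
  }
};

static inline void set_edge(IntegerMatrix &A, IntegerVector &deg,
                            EdgeList &el, int i, int j, int v) {
  if (A(i, j) == v) return;
  A(i, j) = v; A(j, i) = v;
  if (v) { deg[i]++; deg[j]++; el.add(i, j); }
  else   { deg[i]--; deg[j]--; el.remove(i, j); }
}

// Metropolis sampler over binary undirected networks.
//
// proposal 0 (single_toggle): flip one uniformly chosen dyad, accepted with
// min(1, exp(s * theta . delta)) where delta is the add-direction change
// vector and s = +1 (add) or -1 (delete).
// proposal 1 (tie_swap): delete a uniform present edge and add a uniform
// absent dyad simultaneously, preserving the edge count exactly.
//
// Runs burn_in proposals, then records n_samples statistic vectors spaced
// thinning proposals apart (the first sample is taken thinning proposals
// after burn-in; with thinning = 0 a single state is recorded right after
// burn_in, which callers use to advance a chain). Uses R's RNG, so results
// are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_sample_ergm(IntegerMatrix A0, NumericVector z0, NumericVector theta,
                     IntegerVector code, NumericVector lambda, List avec,
                     List cmat, IntegerVector role, double burn_in,
                     double thinning, int n_samples, int proposal,
                     bool collect_nets) {
  IntegerMatrix A = clone(A0);
  const int n = A.nrow(), p = code.size();
  const long nd = (long)n * (n - 1) / 2;
  IntegerVector deg(n);
  for (int a = 0; a < n; ++a) {
    int d = 0;
    for (int b = 0; b < n; ++b) d += A(a, b);
    deg[a] = d;
  }
  EdgeList el;
  el.init(A);
  if (proposal == 1 && (el.size() == 0 || (long)el.size() == nd))
    stop("tie_swap requires a start network that is neither empty nor complete");

  TermSet ts(code, lambda, avec, cmat);
  std::vector<double> z(z0.begin(), z0.end());
  std::vector<double> d1(p), d2(p);
  NumericMatrix stats(n_samples, p);
  List nets(collect_nets ? n_samples : 0);
  long accepted = 0, proposed = 0;

  auto propose = [&]() {
    ++proposed;
    if (proposal == 0) {
      int i = (int)(R::unif_rand() * n);
      int j;
      do { j = (int)(R::unif_rand() * n); } while (j == i);
      if (i >= n) i = n - 1;
      if (j >= n) j = n - 1;
      if (i == j) return;
      bool present = A(i, j) == 1;
      if (present) set_edge(A, deg, el, i, j, 0);
      delta_add_vec(A, deg, role, ts, i, j, d1.data());
      double lp = 0.0;
      for (int t = 0; t < p; ++t) lp += theta[t] * d1[t];
      if (present) lp = -lp;
      if (lp >= 0 || R::unif_rand() < std::exp(lp)) {
        ++accepted;
        if (present) { for (int t = 0; t < p; ++t) z[t] -= d1[t]; }
        else { set_edge(A, deg, el, i, j, 1);
               for (int t = 0; t < p; ++t) z[t] += d1[t]; }
      } else if (present) {
        set_edge(A, deg, el, i, j, 1); // reject: restore
      }
    } else {
      // tie swap
      int e = (int)(R::unif_rand() * el.size());
      if (e >= el.size()) e = el.size() - 1;
      int a = el.ei[e], b = el.ej[e];
      set_edge(A, deg, el, a, b, 0);
      delta_add_vec(A, deg, role, ts, a, b, d1.data());
      // uniform absent dyad (the removed dyad itself is eligible)
      int ci, cj;
      do {
        ci = (int)(R::unif_rand() * n);
        do { cj = (int)(R::unif_rand() * n); } while (cj == ci);
        if (ci >= n) ci = n - 1;
        if (cj >= n) cj = n - 1;
      } while (A(ci, cj) == 1);
      delta_add_vec(A, deg, role, ts, ci, cj, d2.data());
      double lp = 0.0;
      for (int t = 0; t < p; ++t) lp += theta[t] * (d2[t] - d1[t]);
      if (lp >= 0 || R::unif_rand() < std::exp(lp)) {
        ++accepted;
        set_edge(A, deg, el, ci, cj, 1);
        for (int t = 0; t < p; ++t) z[t] += d2[t] - d1[t];
      } else {
        set_edge(A, deg, el, a, b, 1); // restore
      }
    }
  };

  for (long s = 0; s < (long)burn_in; ++s) propose();
  for (int smp = 0; smp < n_samples; ++smp) {
    for (long s = 0; s < (long)thinning; ++s) propose();
    for (int t = 0; t < p; ++t) stats(smp, t) = z[t];
    if (collect_nets) nets[smp] = clone(A);
    if (smp % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["stats"] = stats, _["nets"] = nets,
                      _["final"] = A, _["z_final"] = NumericVector(z.begin(), z.end()),
                      _["edges"] = el.size(),
                      _["acc_rate"] = proposed ? (double)accepted / proposed : 0.0);
}
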