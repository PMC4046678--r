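#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Multipoint machinery for ordered linkage groups under a no-interference
// (Markov) crossover model. Gametes contribute, for every pair of
// consecutive observed markers along the order, a Bernoulli observation
// whose success probability is the composed recombination fraction of the
// spanned intervals r(span) = 0.5 * (1 - prod(1 - 2 theta_t)). Interval
// fractions are profiled by EM with a closed-form E-step.
//
// Parents whose grandparental phase is unresolved at some heterozygous
// markers get a deterministic anchored phase: each unresolved column is
// flipped, or not, to minimise mismatches against the nearest previously
// anchored column (majority vote over co-observed offspring, ties kept
// unflipped). The likelihood is invariant to whole-parent flips.

static void anchor_parent(const IntegerMatrix &tr, const IntegerVector &ph,
                          const IntegerVector &order, IntegerMatrix &orig,
                          int row0, bool resolved_only) {
  const int no = tr.nrow(), m = order.size();
  for (int t = 0; t < m; ++t) {
    const int j = order[t];
    const bool known = ph[j] != NA_INTEGER;
    bool any_obs = false;
    for (int i = 0; i < no; ++i)
      if (tr(i, j) != NA_INTEGER) { any_obs = true; break; }
    if (!any_obs) {
      for (int i = 0; i < no; ++i) orig(row0 + i, t) = NA_INTEGER;
      continue;
    }
    if (known) {
      for (int i = 0; i < no; ++i) {
        const int v = tr(i, j);
        orig(row0 + i, t) = (v == NA_INTEGER) ? NA_INTEGER : (v + ph[j]) % 2;
      }
      continue;
    }
    if (resolved_only) {
      // order-search mode: unresolved columns carry no origin, so the
      // likelihood cannot be inflated by re-anchoring per candidate order
      for (int i = 0; i < no; ++i) orig(row0 + i, t) = NA_INTEGER;
      continue;
    }
    // pooled majority vote against the nearest anchored columns; a thin
    // or tied vote would flip whole columns on a coin toss and flood the
    // map with false double recombinants, so such columns stay unanchored
    int d = 0, n = 0, used = 0;
    for (int tp = t - 1; tp >= 0 && used < 5 && n < 12; --tp) {
      int dd = 0, nn = 0;
      for (int i = 0; i < no; ++i) {
        const int v = tr(i, j), o = orig(row0 + i, tp);
        if (v != NA_INTEGER && o != NA_INTEGER) {
          ++nn;
          if (v != o) ++dd;
        }
      }
      if (nn > 0) {
        ++used;
        n += nn;
        d += dd;
      }
    }
    if (n < 4 || 2 * d == n) {
      for (int i = 0; i < no; ++i) orig(row0 + i, t) = NA_INTEGER;
      continue;
    }
    const int flip = (2 * d > n) ? 1 : 0;
    for (int i = 0; i < no; ++i) {
      const int v = tr(i, j);
      orig(row0 + i, t) = (v == NA_INTEGER) ? NA_INTEGER : (v + flip) % 2;
    }
  }
}

// [[Rcpp::export(name = ".mp_origins")]]
List mp_origins(List trans, List phase, IntegerVector order,
                bool resolved_only = false) {
  const int np = trans.size(), m = order.size();
  int total = 0;
  for (int p = 0; p < np; ++p) total += as<IntegerMatrix>(trans[p]).nrow();
  IntegerMatrix orig(total, m);
  IntegerVector parent(total);
  int row0 = 0;
  for (int p = 0; p < np; ++p) {
    IntegerMatrix tr = trans[p];
    IntegerVector ph = phase[p];
    anchor_parent(tr, ph, order, orig, row0, resolved_only);
    for (int i = 0; i < tr.nrow(); ++i) parent[row0 + i] = p + 1;
    row0 += tr.nrow();
  }
  return List::create(_["origins"] = orig, _["parent"] = parent);
}

struct SpanData {
  std::vector<int> j1, j2;
  std::vector<double> N, R;
};

static SpanData count_spans(const IntegerMatrix &orig) {
  const int n = orig.nrow(), m = orig.ncol();
  std::unordered_map<long long, std::pair<double, double> > acc;
  for (int i = 0; i < n; ++i) {
    int tp = -1, op = 0;
    for (int t = 0; t < m; ++t) {
      const int o = orig(i, t);
      if (o == NA_INTEGER) continue;
      if (tp >= 0) {
        const long long key = (long long)tp * m + t;
        std::pair<double, double> &e = acc[key];
        e.first += 1.0;
        if (o != op) e.second += 1.0;
      }
      tp = t;
      op = o;
    }
  }
  SpanData s;
  for (std::unordered_map<long long, std::pair<double, double> >::iterator it = acc.begin();
       it != acc.end(); ++it) {
    s.j1.push_back((int)(it->first / m));
    s.j2.push_back((int)(it->first % m));
    s.N.push_back(it->second.first);
    s.R.push_back(it->second.second);
  }
  return s;
}

static double span_loglik(const SpanData &s, const std::vector<double> &theta) {
  double ll = 0.0;
  for (size_t k = 0; k < s.j1.size(); ++k) {
    double q = 1.0;
    for (int t = s.j1[k]; t < s.j2[k]; ++t) q *= (1.0 - 2.0 * theta[t]);
    double r = 0.5 * (1.0 - q);
    if (r < 1e-12) r = 1e-12;
    if (r > 0.5) r = 0.5;
    ll += s.R[k] * std::log(r) + (s.N[k] - s.R[k]) * std::log(1.0 - r);
  }
  return ll;
}

// [[Rcpp::export(name = ".mp_profile")]]
List mp_profile(List trans, List phase, IntegerVector parent_sex,
                IntegerVector order, int sex, NumericVector thetas0,
                double tol, int maxit, bool resolved_only = false) {
  const int np = trans.size(), m = order.size();
  // stack anchored origins for the selected parents
  int total = 0;
  for (int p = 0; p < np; ++p)
    if (sex < 0 || parent_sex[p] == sex) total += as<IntegerMatrix>(trans[p]).nrow();
  IntegerMatrix orig(total, m);
  int row0 = 0;
  for (int p = 0; p < np; ++p) {
    if (!(sex < 0 || parent_sex[p] == sex)) continue;
    IntegerMatrix tr = trans[p];
    IntegerVector ph = phase[p];
    anchor_parent(tr, ph, order, orig, row0, resolved_only);
    row0 += tr.nrow();
  }
  SpanData s = count_spans(orig);
  const int ni = m > 1 ? m - 1 : 0;
  std::vector<double> theta(ni, 0.05), E(ni), C(ni), cover(ni, 0.0);
  for (size_t k = 0; k < s.j1.size(); ++k)
    for (int t = s.j1[k]; t < s.j2[k]; ++t) cover[t] += s.N[k];
  bool fixed = thetas0.size() > 0;
  if (fixed) {
    for (int t = 0; t < ni; ++t) {
      theta[t] = thetas0[t];
      if (theta[t] > 0.49999) theta[t] = 0.49999;
    }
  } else {
    // initialise from purely adjacent spans where available
    std::vector<double> aN(ni, 0.0), aR(ni, 0.0);
    for (size_t k = 0; k < s.j1.size(); ++k)
      if (s.j2[k] == s.j1[k] + 1) { aN[s.j1[k]] += s.N[k]; aR[s.j1[k]] += s.R[k]; }
    for (int t = 0; t < ni; ++t)
      if (aN[t] > 0) {
        theta[t] = aR[t] / aN[t];
        if (theta[t] > 0.49) theta[t] = 0.49;
        if (theta[t] < 1e-4) theta[t] = 1e-4;
      }
  }
  double ll = span_loglik(s, theta);
  if (!fixed && ni > 0) {
    for (int it = 0; it < maxit; ++it) {
      std::fill(E.begin(), E.end(), 0.0);
      std::fill(C.begin(), C.end(), 0.0);
      for (size_t k = 0; k < s.j1.size(); ++k) {
        double q = 1.0;
        for (int t = s.j1[k]; t < s.j2[k]; ++t) q *= (1.0 - 2.0 * theta[t]);
        double r = 0.5 * (1.0 - q);
        if (r < 1e-12) r = 1e-12;
        for (int t = s.j1[k]; t < s.j2[k]; ++t) {
          const double om = 1.0 - 2.0 * theta[t];
          const double qm = (std::fabs(om) > 1e-12) ? q / om : 0.0;
          const double p1 = (r > 0) ? theta[t] * 0.5 * (1.0 + qm) / r : 0.0;
          const double p0 = (1.0 - r > 0) ? theta[t] * 0.5 * (1.0 - qm) / (1.0 - r) : 0.0;
          E[t] += s.R[k] * p1 + (s.N[k] - s.R[k]) * p0;
          C[t] += s.N[k];
        }
      }
      for (int t = 0; t < ni; ++t) {
        theta[t] = (C[t] > 0) ? E[t] / C[t] : 0.0;
        if (theta[t] > 0.49999) theta[t] = 0.49999;
        // zero is absorbing in EM; keep covered intervals off the
        // boundary so recombinants seen only in long spans can migrate in
        if (C[t] > 0 && theta[t] < 1e-4) theta[t] = 1e-4;
      }
      const double ll_new = span_loglik(s, theta);
      const bool done = std::fabs(ll_new - ll) < tol * std::log(10.0);
      ll = ll_new;
      if (done) break;
    }
  }
  return List::create(
    _["loglik10"] = ll / std::log(10.0),
    _["thetas"] = NumericVector(theta.begin(), theta.end()),
    _["cover"] = NumericVector(cover.begin(), cover.end()),
    _["n_gametes"] = total
  );
}

// Profiled log10-likelihood for column subset `order` of a precomputed
// origin matrix (grandparent-resolved origins; order-independent), the
// hot loop of BUILD/FLIPS order search.
// [[Rcpp::export(name = ".mp_score")]]
double mp_score(IntegerMatrix origins, IntegerVector order, double tol,
                int maxit) {
  const int n = origins.nrow(), m = order.size();
  if (m < 2) return 0.0;
  std::unordered_map<long long, std::pair<double, double> > acc;
  for (int i = 0; i < n; ++i) {
    int tp = -1, op = 0;
    for (int t = 0; t < m; ++t) {
      const int o = origins(i, order[t]);
      if (o == NA_INTEGER) continue;
      if (tp >= 0) {
        std::pair<double, double> &e = acc[(long long)tp * m + t];
        e.first += 1.0;
        if (o != op) e.second += 1.0;
      }
      tp = t;
      op = o;
    }
  }
  SpanData s;
  for (std::unordered_map<long long, std::pair<double, double> >::iterator it = acc.begin();
       it != acc.end(); ++it) {
    s.j1.push_back((int)(it->first / m));
    s.j2.push_back((int)(it->first % m));
    s.N.push_back(it->second.first);
    s.R.push_back(it->second.second);
  }
  const int ni = m - 1;
  std::vector<double> theta(ni, 0.05), E(ni), C(ni);
  std::vector<double> aN(ni, 0.0), aR(ni, 0.0);
  for (size_t k = 0; k < s.j1.size(); ++k)
    if (s.j2[k] == s.j1[k] + 1) { aN[s.j1[k]] += s.N[k]; aR[s.j1[k]] += s.R[k]; }
  for (int t = 0; t < ni; ++t)
    if (aN[t] > 0) {
      theta[t] = aR[t] / aN[t];
      if (theta[t] > 0.49) theta[t] = 0.49;
      if (theta[t] < 1e-4) theta[t] = 1e-4;
    }
  double ll = span_loglik(s, theta);
  for (int it = 0; it < maxit; ++it) {
    std::fill(E.begin(), E.end(), 0.0);
    std::fill(C.begin(), C.end(), 0.0);
    for (size_t k = 0; k < s.j1.size(); ++k) {
      double q = 1.0;
      for (int t = s.j1[k]; t < s.j2[k]; ++t) q *= (1.0 - 2.0 * theta[t]);
      double r = 0.5 * (1.0 - q);
      if (r < 1e-12) r = 1e-12;
      for (int t = s.j1[k]; t < s.j2[k]; ++t) {
        const double om = 1.0 - 2.0 * theta[t];
        const double qm = (std::fabs(om) > 1e-12) ? q / om : 0.0;
        const double p1 = (r > 0) ? theta[t] * 0.5 * (1.0 + qm) / r : 0.0;
        const double p0 = (1.0 - r > 0) ? theta[t] * 0.5 * (1.0 - qm) / (1.0 - r) : 0.0;
        E[t] += s.R[k] * p1 + (s.N[k] - s.R[k]) * p0;
        C[t] += s.N[k];
      }
    }
    for (int t = 0; t < ni; ++t) {
      theta[t] = (C[t] > 0) ? E[t] / C[t] : 0.0;
      if (theta[t] > 0.49999) theta[t] = 0.49999;
      if (C[t] > 0 && theta[t] < 1e-4) theta[t] = 1e-4;
    }
    const double ll_new = span_loglik(s, theta);
    const bool done = std::fabs(ll_new - ll) < tol * std::log(10.0);
    ll = ll_new;
    if (done) break;
  }
  return ll / std::log(10.0);
}

// Full-information profiled likelihood: pooled spans where both endpoint
// phases are grandparent-resolved, plus per-parent phase-mixture span
// classes elsewhere. Summing a parent's phase vector out is equivalent to
// independent interval-flip bits, so each (parent, span) class carries a
// two-component mixture over its reference-phase mismatch count k:
//   L = 0.5 * [ r^k (1-r)^(n-k) + r^(n-k) (1-r)^k ],
// r the composed fraction over the span. Overlapping span classes of one
// parent share flip bits; treating them as independent is a composite
// approximation that is exact for completely observed gametes.
//
// ref: reference-phase origin matrix (gametes x markers; resolved columns
// hold true origins, unresolved ones transmissions under flip 0).
// parent: 1-based parent index per gamete row. resolved: parents x
// markers logical. rows: 1-based gamete rows to use (sex filtering).
// [[Rcpp::export(name = ".mp_fit")]]
List mp_fit(IntegerMatrix ref, IntegerVector parent, LogicalMatrix resolved,
            IntegerVector rows, IntegerVector order, NumericVector thetas0,
            double tol, int maxit, int max_mix_span = 1) {
  const int m = order.size();
  const int ni = m > 1 ? m - 1 : 0;
  // pooled resolved spans keyed j1*m+j2; mixture classes keyed
  // ((p*m)+j1)*m+j2 -> (n, k)
  std::unordered_map<long long, std::pair<double, double> > pool, mixm;
  for (int ri = 0; ri < rows.size(); ++ri) {
    const int i = rows[ri] - 1;
    const int p = parent[i] - 1;
    int tp = -1, op = 0;
    bool rp = false;
    for (int t = 0; t < m; ++t) {
      const int j = order[t];
      const int o = ref(i, j);
      if (o == NA_INTEGER) continue;
      const bool rs = resolved(p, j);
      if (tp >= 0) {
        if (rs && rp) {
          std::pair<double, double> &e = pool[(long long)tp * m + t];
          e.first += 1.0;
          if (o != op) e.second += 1.0;
        } else {
          std::pair<double, double> &e =
            mixm[((long long)p * m + tp) * m + t];
          e.first += 1.0;
          if (o != op) e.second += 1.0;
        }
      }
      tp = t;
      op = o;
      rp = rs;
    }
  }
  struct Cls { int j1, j2; double N, R; bool mix; };
  std::vector<Cls> cls;
  for (std::unordered_map<long long, std::pair<double, double> >::iterator it = pool.begin();
       it != pool.end(); ++it) {
    Cls c; c.j1 = (int)(it->first / m); c.j2 = (int)(it->first % m);
    c.N = it->second.first; c.R = it->second.second; c.mix = false;
    cls.push_back(c);
  }
  for (std::unordered_map<long long, std::pair<double, double> >::iterator it = mixm.begin();
       it != mixm.end(); ++it) {
    Cls c; c.j2 = (int)(it->first % m);
    c.j1 = (int)((it->first / m) % m);
    c.N = it->second.first; c.R = it->second.second; c.mix = true;
    // long-span mixture classes have composed fractions far from zero,
    // where the free flip bit absorbs recombinant excess and deflates
    // theta; short spans at small r are essentially clean, so keep spans
    // up to max_mix_span intervals with at least two gametes
    if (c.j2 - c.j1 > max_mix_span || c.N < 2) continue;
    cls.push_back(c);
  }
  std::vector<double> theta(ni, 0.05), E(ni), C(ni), cover(ni, 0.0);
  for (size_t k = 0; k < cls.size(); ++k)
    for (int t = cls[k].j1; t < cls[k].j2; ++t) cover[t] += cls[k].N;
  const bool fixed = thetas0.size() > 0;
  if (fixed) {
    for (int t = 0; t < ni; ++t) {
      theta[t] = thetas0[t];
      if (theta[t] > 0.49999) theta[t] = 0.49999;
    }
  }
  double ll = 0.0;
  for (int it = 0; it <= maxit; ++it) {
    std::fill(E.begin(), E.end(), 0.0);
    std::fill(C.begin(), C.end(), 0.0);
    double ll_new = 0.0;
    for (size_t k = 0; k < cls.size(); ++k) {
      const Cls &c = cls[k];
      double q = 1.0;
      for (int t = c.j1; t < c.j2; ++t) q *= (1.0 - 2.0 * theta[t]);
      double r = 0.5 * (1.0 - q);
      if (r < 1e-12) r = 1e-12;
      if (r > 0.5) r = 0.5;
      double keff, llc;
      if (!c.mix) {
        keff = c.R;
        llc = c.R * std::log(r) + (c.N - c.R) * std::log(1.0 - r);
      } else {
        // mixture over the span flip bit
        const double la = c.R * std::log(r) + (c.N - c.R) * std::log(1.0 - r);
        const double lb = (c.N - c.R) * std::log(r) + c.R * std::log(1.0 - r);
        const double mx = la > lb ? la : lb;
        llc = mx + std::log(0.5 * (std::exp(la - mx) + std::exp(lb - mx)));
        const double w = 1.0 / (1.0 + std::exp(lb - la));
        keff = w * c.R + (1.0 - w) * (c.N - c.R);
      }
      ll_new += llc;
      // distribute expected flips over the span's intervals
      for (int t = c.j1; t < c.j2; ++t) {
        const double om = 1.0 - 2.0 * theta[t];
        const double qm = (std::fabs(om) > 1e-12) ? q / om : 0.0;
        const double p1 = theta[t] * 0.5 * (1.0 + qm) / r;
        const double p0 = (1.0 - r > 0) ? theta[t] * 0.5 * (1.0 - qm) / (1.0 - r) : 0.0;
        E[t] += keff * p1 + (c.N - keff) * p0;
        C[t] += c.N;
      }
    }
    const bool done = it > 0 && std::fabs(ll_new - ll) < tol * std::log(10.0);
    ll = ll_new;
    if (fixed || done || it == maxit) break;
    for (int t = 0; t < ni; ++t) {
      theta[t] = (C[t] > 0) ? E[t] / C[t] : 0.0;
      if (theta[t] > 0.49999) theta[t] = 0.49999;
      if (C[t] > 0 && theta[t] < 1e-4) theta[t] = 1e-4;
    }
  }
  return List::create(
    _["loglik10"] = ll / std::log(10.0),
    _["thetas"] = NumericVector(theta.begin(), theta.end()),
    _["cover"] = NumericVector(cover.begin(), cover.end()));
}
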