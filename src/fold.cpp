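// Hairpin-restricted minimum-free-energy folding.
//
// Dynamic programming over nested single-hairpin structures: a closed span
// (i,j) is either a hairpin loop or contains exactly one inner pair (k,l)
// reached through a stack, bulge or interior loop (sizes capped at 30).
// Multiloops and pseudoknots are deliberately outside the model: every
// cis-signal handled by this package is a simple stem loop.
//
// Energies in kcal/mol; sequence encoded 1..4 = A,C,G,U.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

const double INF = 1e9;

struct Par {
  NumericMatrix stack;            // 6 x 6, [type1-1, type2rev-1]
  NumericVector mmh, mmi, mm1n, mm23;  // 6 x 4 x 4 arrays, flattened
  NumericVector hairpin_init, bulge_init, internal_init;  // index = size
  double terminal_au, ninio, ninio_max;
  bool terminal_mismatch;
  int max_loop;
};

Par unpack(const List& par) {
  Par p;
  p.stack = as<NumericMatrix>(par["stack"]);
  p.mmh = as<NumericVector>(par["mismatch_hairpin"]);
  p.mmi = as<NumericVector>(par["mismatch_internal"]);
  p.mm1n = as<NumericVector>(par["mismatch_internal_1n"]);
  p.mm23 = as<NumericVector>(par["mismatch_internal_23"]);
  p.hairpin_init = as<NumericVector>(par["hairpin_init"]);
  p.bulge_init = as<NumericVector>(par["bulge_init"]);
  p.internal_init = as<NumericVector>(par["internal_init"]);
  p.terminal_au = as<double>(par["terminal_au"]);
  p.ninio = as<double>(par["ninio"]);
  p.ninio_max = as<double>(par["ninio_max"]);
  p.terminal_mismatch = as<bool>(par["terminal_mismatch"]);
  p.max_loop = as<int>(par["max_loop"]);
  return p;
}

inline int pair_type(int a, int b) {
  // 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA (A=1 C=2 G=3 U=4)
  if (a == 2 && b == 3) return 1;
  if (a == 3 && b == 2) return 2;
  if (a == 3 && b == 4) return 3;
  if (a == 4 && b == 3) return 4;
  if (a == 1 && b == 4) return 5;
  if (a == 4 && b == 1) return 6;
  return 0;
}

inline double mm(const NumericVector& tab, int type, int x, int y) {
  // dims 6 x 4 x 4
  return tab[(type - 1) + 6 * ((x - 1) + 4 * (y - 1))];
}

inline double au_pen(const Par& p, int type) {
  return type >= 3 ? p.terminal_au : 0.0;
}

// s is 0-based int array of codes; i < j are 0-based.
double hairpin_energy(const Par& p, const IntegerVector& s, int i, int j,
                      int type) {
  int u = j - i - 1;
  if (u < 3 || u > 30) return INF;
  double e = p.hairpin_init[u];
  if (!R_finite(e)) return INF;
  if (u == 3) {
    e += au_pen(p, type);
  } else if (p.terminal_mismatch) {
    e += mm(p.mmh, type, s[i + 1], s[j - 1]);
  } else {
    e += au_pen(p, type);
  }
  return e;
}

double interior_energy(const Par& p, const IntegerVector& s, int i, int j,
                       int k, int l, int type1, int type2r) {
  int u1 = k - i - 1, u2 = j - l - 1;
  if (u1 == 0 && u2 == 0) return p.stack(type1 - 1, type2r - 1);
  if (u1 == 0 || u2 == 0) {            // bulge
    int b = u1 + u2;
    if (b > p.max_loop) return INF;
    if (b == 1) return p.bulge_init[1] + p.stack(type1 - 1, type2r - 1);
    return p.bulge_init[b] + au_pen(p, type1) + au_pen(p, type2r);
  }
  int n = u1 + u2;                     // interior loop
  if (n > p.max_loop) return INF;
  double e = p.internal_init[n] +
    std::min(p.ninio * std::abs(u1 - u2), p.ninio_max);
  if (p.terminal_mismatch) {
    const NumericVector* tab = &p.mmi;
    int mn = std::min(u1, u2), mx = std::max(u1, u2);
    if (mn == 1) tab = &p.mm1n;
    else if (mn == 2 && mx == 3) tab = &p.mm23;
    e += mm(*tab, type1, s[i + 1], s[j - 1]) +
         mm(*tab, type2r, s[l + 1], s[k - 1]);
  } else {
    e += au_pen(p, type1) + au_pen(p, type2r);
  }
  return e;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_fold_matrix(IntegerVector seq, List par) {
  const Par p = unpack(par);
  const int n = seq.size();
  NumericMatrix V(n, n);
  std::fill(V.begin(), V.end(), INF);
  for (int span = 4; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int t = pair_type(seq[i], seq[j]);
      if (t == 0) continue;
      double best = hairpin_energy(p, seq, i, j, t);
      int kmax = std::min(i + p.max_loop + 1, j - 4);
      for (int k = i + 1; k <= kmax; ++k) {
        int lmin = std::max(k + 4, j - p.max_loop - 1 + (k - i - 1));
        for (int l = j - 1; l >= lmin; --l) {
          int t2r = pair_type(seq[l], seq[k]);
          if (t2r == 0) continue;
          double inner = V(k, l);
          if (inner >= INF) continue;
          double e = interior_energy(p, seq, i, j, k, l, t, t2r) + inner;
          if (e < best) best = e;
        }
      }
      V(i, j) = best;
    }
  }
  return V;
}

// [[Rcpp::export]]
IntegerMatrix cpp_traceback(IntegerVector seq, List par, NumericMatrix V,
                            int i1, int j1) {
  const Par p = unpack(par);
  const double eps = 1e-7;
  std::vector<int> pi, pj;
  int i = i1 - 1, j = j1 - 1;
  for (;;) {
    pi.push_back(i + 1);
    pj.push_back(j + 1);
    int t = pair_type(seq[i], seq[j]);
    double v = V(i, j);
    if (std::fabs(hairpin_energy(p, seq, i, j, t) - v) < eps) break;
    bool found = false;
    int kmax = std::min(i + p.max_loop + 1, j - 4);
    for (int k = i + 1; k <= kmax && !found; ++k) {
      for (int l = j - 1; l >= k + 4; --l) {
        int t2r = pair_type(seq[l], seq[k]);
        if (t2r == 0 || V(k, l) >= INF) continue;
        double e = interior_energy(p, seq, i, j, k, l, t, t2r) + V(k, l);
        if (std::fabs(e - v) < eps) {
          i = k; j = l; found = true; break;
        }
      }
    }
    if (!found) stop("traceback failed");  // should not happen
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    out(r, 0) = pi[r];
    out(r, 1) = pj[r];
  }
  return out;
}
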