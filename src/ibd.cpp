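#include <Rcpp.h>
using namespace Rcpp;

// Single-marker IBD engine.
//
// A pedigree is encoded by parent indices (0-based, -1 = founder), ordered so
// that parents precede children.  Each founder carries two uniquely labelled
// alleles; an inheritance vector assigns, for every non-founder, which
// paternal and which maternal allele was transmitted.  Conditional on an
// inheritance vector the marker genotype constraints reduce to a 2-colouring
// problem over founder alleles (hom constraints force an allele's type,
// het constraints are XOR edges), so P(genotypes | vector) factorises over
// connected components of that constraint graph.  The engine sums (exact) or
// samples (Monte Carlo) inheritance vectors and returns the posterior mean
// pairwise sharing pi_ij = (1/2) * #{(k,l): allele k of i IBD allele l of j}.

namespace {

struct IbdWork {
  int n;                       // members
  std::vector<int> fa, mo;     // parent indices, -1 founder
  std::vector<int> geno;       // dosage 0/1/2, -1 missing
  std::vector<int> nonf;       // non-founder member indices, pedigree order
  double p, q;                 // minor / major allele frequency
  int nAll;                    // number of founder alleles (2 * founders)
  std::vector<int> L0, L1;     // current allele labels per member
  std::vector<int> forced;     // -1 unknown, else forced type 0/1
  std::vector<int> head, nxt, to;
  int nedge;
  std::vector<int> color, comp, stk;

  void init(const IntegerVector &fa_, const IntegerVector &mo_,
            const IntegerVector &geno_, double p_) {
    n = fa_.size();
    fa.assign(n, -1); mo.assign(n, -1); geno.assign(n, -1);
    nonf.clear();
    for (int i = 0; i < n; i++) {
      fa[i] = fa_[i]; mo[i] = mo_[i];
      geno[i] = (geno_[i] == NA_INTEGER) ? -1 : geno_[i];
      if (fa[i] >= 0) nonf.push_back(i);
    }
    p = p_; q = 1.0 - p_;
    L0.assign(n, 0); L1.assign(n, 0);
    nAll = 0;
    for (int i = 0; i < n; i++)
      if (fa[i] < 0) { L0[i] = nAll++; L1[i] = nAll++; }
    forced.assign(nAll, -1);
    head.assign(nAll, -1);
    nxt.assign(2 * n + 2, 0); to.assign(2 * n + 2, 0);
    color.assign(nAll, -1);
  }

  // fill labels from transmission choices (one pair of bits per non-founder)
  void setLabels(const std::vector<int> &cp, const std::vector<int> &cm) {
    for (size_t k = 0; k < nonf.size(); k++) {
      int i = nonf[k];
      L0[i] = cp[k] ? L1[fa[i]] : L0[fa[i]];
      L1[i] = cm[k] ? L1[mo[i]] : L0[mo[i]];
    }
  }

  void addEdge(int a, int b) {
    to[nedge] = b; nxt[nedge] = head[a]; head[a] = nedge; nedge++;
  }

  bool force(int a, int t) {
    if (forced[a] < 0) { forced[a] = t; return true; }
    return forced[a] == t;
  }

  // P(observed genotypes | current labels); 0 if inconsistent
  double weight() {
    std::fill(forced.begin(), forced.end(), -1);
    std::fill(head.begin(), head.end(), -1);
    nedge = 0;
    for (int i = 0; i < n; i++) {
      int g = geno[i];
      if (g < 0) continue;
      int a = L0[i], b = L1[i];
      if (g == 1) {
        if (a == b) return 0.0;      // autozygous allele cannot be het
        addEdge(a, b); addEdge(b, a);
      } else {
        int t = (g == 2) ? 1 : 0;
        if (!force(a, t)) return 0.0;
        if (!force(b, t)) return 0.0;
      }
    }
    std::fill(color.begin(), color.end(), -1);
    double w = 1.0;
    for (int s = 0; s < nAll; s++) {
      if (color[s] >= 0) continue;
      if (head[s] < 0 && forced[s] < 0) continue;  // unconstrained: factor 1
      comp.clear(); stk.clear();
      stk.push_back(s); color[s] = 0;
      int anchor = -1;
      while (!stk.empty()) {
        int u = stk.back(); stk.pop_back();
        comp.push_back(u);
        if (forced[u] >= 0 && anchor < 0) anchor = u;
        for (int e = head[u]; e >= 0; e = nxt[e]) {
          int v = to[e];
          if (color[v] < 0) { color[v] = 1 - color[u]; stk.push_back(v); }
          else if (color[v] == color[u]) return 0.0;  // odd het cycle
        }
      }
      if (anchor >= 0) {
        int base = forced[anchor] ^ color[anchor];
        double cw = 1.0;
        for (int u : comp) {
          int t = base ^ color[u];
          if (forced[u] >= 0 && forced[u] != t) return 0.0;
          cw *= t ? p : q;
        }
        w *= cw;
      } else {
        double w0 = 1.0, w1 = 1.0;
        for (int u : comp) {
          if (color[u]) { w0 *= p; w1 *= q; }
          else          { w0 *= q; w1 *= p; }
        }
        w *= w0 + w1;
      }
    }
    return w;
  }

  double pairShare(int i, int j) const {
    int c = 0;
    c += (L0[i] == L0[j]); c += (L0[i] == L1[j]);
    c += (L1[i] == L0[j]); c += (L1[i] == L1[j]);
    return 0.5 * c;
  }
};

} // namespace

// [[Rcpp::export]]
List ibd_exact_cpp(IntegerVector fa, IntegerVector mo, IntegerVector geno,
                   double p) {
  IbdWork W;
  W.init(fa, mo, geno, p);
  int NF = W.nonf.size();
  if (2 * NF > 62) stop("inheritance space too large for exact enumeration");
  long long total = 1LL << (2 * NF);
  int n = W.n;
  NumericMatrix num(n, n);
  double Wsum = 0.0;
  std::vector<int> cp(NF), cm(NF);
  for (long long v = 0; v < total; v++) {
    long long x = v;
    for (int k = 0; k < NF; k++) {
      cp[k] = x & 1; x >>= 1;
      cm[k] = x & 1; x >>= 1;
    }
    W.setLabels(cp, cm);
    double w = W.weight();
    if (w <= 0.0) continue;
    Wsum += w;
    for (int i = 0; i < n; i++)
      for (int j = i; j < n; j++)
        num(i, j) += w * W.pairShare(i, j);
  }
  NumericMatrix pi(n, n);
  if (Wsum > 0.0) {
    for (int i = 0; i < n; i++)
      for (int j = i; j < n; j++) {
        pi(i, j) = num(i, j) / Wsum;
        pi(j, i) = pi(i, j);
      }
  }
  double prior = std::pow(0.5, 2.0 * NF);
  return List::create(_["pi"] = pi, _["weight"] = Wsum * prior,
                      _["states"] = (double)total);
}

// [[Rcpp::export]]
List ibd_mc_cpp(IntegerVector fa, IntegerVector mo, IntegerVector geno,
                double p, int n_samples) {
  IbdWork W;
  W.init(fa, mo, geno, p);
  int NF = W.nonf.size();
  int n = W.n;
  NumericMatrix Swx(n, n), Sw2x(n, n), Sw2x2(n, n);
  double Sw = 0.0, Sw2 = 0.0;
  long long nacc = 0;
  std::vector<int> cp(NF), cm(NF);
  for (int it = 0; it < n_samples; it++) {
    for (int k = 0; k < NF; k++) {
      cp[k] = unif_rand() < 0.5;
      cm[k] = unif_rand() < 0.5;
    }
    W.setLabels(cp, cm);
    double w = W.weight();
    if (w <= 0.0) continue;
    nacc++;
    Sw += w; Sw2 += w * w;
    for (int i = 0; i < n; i++)
      for (int j = i; j < n; j++) {
        double x = W.pairShare(i, j);
        Swx(i, j)  += w * x;
        Sw2x(i, j) += w * w * x;
        Sw2x2(i, j) += w * w * x * x;
      }
  }
  NumericMatrix pi(n, n), se(n, n);
  if (Sw > 0.0) {
    for (int i = 0; i < n; i++)
      for (int j = i; j < n; j++) {
        double r = Swx(i, j) / Sw;
        // self-normalised importance-sampling variance (delta method)
        double v = (Sw2x2(i, j) - 2.0 * r * Sw2x(i, j) + r * r * Sw2) /
                   (Sw * Sw);
        pi(i, j) = r; pi(j, i) = r;
        se(i, j) = std::sqrt(std::max(v, 0.0)); se(j, i) = se(i, j);
      }
  }
  return List::create(_["pi"] = pi, _["se"] = se, _["weight"] = Sw,
                      _["n_accepted"] = (double)nacc);
}
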