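#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Layout conventions shared with the R side:
//  - nodes are 0-based ids 0..n_nodes-1, root = 0
//  - parent, childL, childR, leafcol: length n_nodes; -1 where absent
//  - states: P x S integer matrix, entries 0/1/NA (NA = '*')
//  - leafcol[v] gives the 0-based column of leaf v in `states`
//  - Tarr: 4 * n_nodes * ncat flat array; entry (2*i + j) of the branch
//    into node v under category c sits at (c*n_nodes + v)*4 + 2*i + j
//  - postorder/preorder: node ids in traversal order

// Upward (Felsenstein) pass for one pattern under one category.
// Fills L (2 per node, scaled so the max entry per node is 1) and
// returns the log pattern likelihood, or -Inf if impossible.  Scaling
// factors are accumulated multiplicatively and only flushed into the
// log when they risk underflow, which keeps log() calls rare.
static double up_pass(const int *pat, int P, int p,
                      const int *postorder, int n,
                      const int *childL, const int *childR,
                      const int *leafcol,
                      const double *Tc, double pi0, double *L) {
  double logscale = 0.0, scale = 1.0;
  for (int k = 0; k < n; ++k) {
    int v = postorder[k];
    double *Lv = L + 2 * v;
    int cl = childL[v];
    if (cl < 0) {                       // leaf
      int s = pat[(size_t)leafcol[v] * P + p];
      if (s == NA_INTEGER) { Lv[0] = 1.0; Lv[1] = 1.0; }
      else if (s == 0)     { Lv[0] = 1.0; Lv[1] = 0.0; }
      else                 { Lv[0] = 0.0; Lv[1] = 1.0; }
      continue;
    }
    int cr = childR[v];
    const double *Ll = L + 2 * cl, *Lr = L + 2 * cr;
    const double *Tl = Tc + 4 * cl, *Tr = Tc + 4 * cr;
    double a = (Tl[0] * Ll[0] + Tl[1] * Ll[1]) *
               (Tr[0] * Lr[0] + Tr[1] * Lr[1]);
    double b = (Tl[2] * Ll[0] + Tl[3] * Ll[1]) *
               (Tr[2] * Lr[0] + Tr[3] * Lr[1]);
    double m = a > b ? a : b;
    if (m <= 0.0) return R_NegInf;
    Lv[0] = a / m; Lv[1] = b / m;
    scale *= m;
    if (scale < 1e-280) { logscale += std::log(scale); scale = 1.0; }
  }
  double lik = pi0 * L[0] + (1.0 - pi0) * L[1];
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik * scale) + logscale;
}

// [[Rcpp::export(name = ".cpp_loglik_cats")]]
NumericMatrix cpp_loglik_cats(IntegerMatrix states, IntegerVector postorder,
                              IntegerVector childL, IntegerVector childR,
                              IntegerVector leafcol, NumericVector Tarr,
                              int n_nodes, double pi0, int ncat) {
  int P = states.nrow();
  NumericMatrix out(P, ncat);
  const int *pat = INTEGER(states);
  const double *T = REAL(Tarr);
  const int *po = INTEGER(postorder), *cL = INTEGER(childL),
            *cR = INTEGER(childR), *lc = INTEGER(leafcol);
  int n = postorder.size();
  std::vector<double> L(2 * n_nodes);
  for (int c = 0; c < ncat; ++c) {
    const double *Tc = T + (size_t)c * n_nodes * 4;
    for (int p = 0; p < P; ++p)
      out(p, c) = up_pass(pat, P, p, po, n, cL, cR, lc, Tc, pi0, L.data());
  }
  return out;
}

// Full expectation pass.  W is a P x ncat matrix of per-pattern,
// per-category site weights (count * posterior category probability);
// entries of 0 are skipped.  Accumulates
//   trans[2*i+j, v, c]  = expected (i -> j) transitions on the branch
//                         into node v under category c,
//   node_post[v, s]     = expected number of sites in state s at node v,
//   cat_tot[c]          = expected number of sites in category c.
// [[Rcpp::export(name = ".cpp_estep_stats")]]
List cpp_estep_stats(IntegerMatrix states, IntegerVector postorder,
                     IntegerVector preorder, IntegerVector parent,
                     IntegerVector childL, IntegerVector childR,
                     IntegerVector leafcol, NumericVector Tarr,
                     int n_nodes, double pi0, NumericMatrix W) {
  int P = states.nrow();
  int ncat = W.ncol();
  const int *pat = INTEGER(states);
  const double *T = REAL(Tarr);
  const int *po = INTEGER(postorder), *pre = INTEGER(preorder),
            *cLv = INTEGER(childL), *cRv = INTEGER(childR),
            *lc = INTEGER(leafcol);
  NumericVector trans(4 * (size_t)n_nodes * ncat);
  NumericMatrix node_post(n_nodes, 2);
  NumericVector cat_tot(ncat);
  double *tr = REAL(trans);
  double *np = REAL(node_post);
  std::vector<double> L(2 * n_nodes), A(2 * n_nodes);
  int n = preorder.size();

  for (int c = 0; c < ncat; ++c) {
    const double *Tc = T + (size_t)c * n_nodes * 4;
    double *trc = tr + (size_t)c * n_nodes * 4;
    for (int p = 0; p < P; ++p) {
      double w = W(p, c);
      if (w <= 0.0) continue;
      double ll = up_pass(pat, P, p, po, n, cLv, cRv, lc, Tc, pi0,
                          L.data());
      if (!R_finite(ll)) continue;      // impossible pattern, no mass
      cat_tot[c] += w;
      // outside pass; A is renormalized per node, joints per branch
      A[0] = pi0; A[1] = 1.0 - pi0;
      for (int k = 0; k < n; ++k) {
        int v = pre[k];
        double *Av = A.data() + 2 * v;
        double *Lv = L.data() + 2 * v;
        double p0 = Av[0] * Lv[0], p1 = Av[1] * Lv[1];
        double tot = p0 + p1;
        if (tot > 0.0) {
          np[v] += w * p0 / tot;
          np[n_nodes + v] += w * p1 / tot;
        }
        int cl = cLv[v];
        if (cl < 0) continue;
        int cr = cRv[v];
        const double *Ll = L.data() + 2 * cl, *Lr = L.data() + 2 * cr;
        const double *Tl = Tc + 4 * cl, *Tr = Tc + 4 * cr;
        double msgL0 = Tl[0] * Ll[0] + Tl[1] * Ll[1];
        double msgL1 = Tl[2] * Ll[0] + Tl[3] * Ll[1];
        double msgR0 = Tr[0] * Lr[0] + Tr[1] * Lr[1];
        double msgR1 = Tr[2] * Lr[0] + Tr[3] * Lr[1];
        // branch into the left child
        {
          double F0 = Av[0] * msgR0, F1 = Av[1] * msgR1;
          double J0 = F0 * Tl[0] * Ll[0], J1 = F0 * Tl[1] * Ll[1];
          double J2 = F1 * Tl[2] * Ll[0], J3 = F1 * Tl[3] * Ll[1];
          double s = J0 + J1 + J2 + J3;
          if (s > 0.0) {
            double ws = w / s;
            double *acc = trc + 4 * cl;
            acc[0] += ws * J0; acc[1] += ws * J1;
            acc[2] += ws * J2; acc[3] += ws * J3;
          }
          // outside message excludes the child's own subtree
          double a0 = F0 * Tl[0] + F1 * Tl[2];
          double a1 = F0 * Tl[1] + F1 * Tl[3];
          double at = a0 + a1;
          if (at > 0.0) { A[2 * cl] = a0 / at; A[2 * cl + 1] = a1 / at; }
          else          { A[2 * cl] = 0.5;     A[2 * cl + 1] = 0.5; }
        }
        // branch into the right child
        {
          double F0 = Av[0] * msgL0, F1 = Av[1] * msgL1;
          double J0 = F0 * Tr[0] * Lr[0], J1 = F0 * Tr[1] * Lr[1];
          double J2 = F1 * Tr[2] * Lr[0], J3 = F1 * Tr[3] * Lr[1];
          double s = J0 + J1 + J2 + J3;
          if (s > 0.0) {
            double ws = w / s;
            double *acc = trc + 4 * cr;
            acc[0] += ws * J0; acc[1] += ws * J1;
            acc[2] += ws * J2; acc[3] += ws * J3;
          }
          double a0 = F0 * Tr[0] + F1 * Tr[2];
          double a1 = F0 * Tr[1] + F1 * Tr[3];
          double at = a0 + a1;
          if (at > 0.0) { A[2 * cr] = a0 / at; A[2 * cr + 1] = a1 / at; }
          else          { A[2 * cr] = 0.5;     A[2 * cr + 1] = 0.5; }
        }
      }
    }
  }
  trans.attr("dim") = IntegerVector::create(4, n_nodes, ncat);
  return List::create(_["trans"] = trans, _["node_post"] = node_post,
                      _["cat_tot"] = cat_tot);
}
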