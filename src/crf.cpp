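#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Scaled-linear-space forward-backward over the CRF state graph.
//
// States are 1..K (emitting). Virtual anchors: 0 = start, K+1 = end.
// Every edge (including start->state and state->end) carries its own
// transition weight. Labels constrain which states may emit at each
// position (0 = unconstrained). Per-position emission scores are
// max-shifted before exponentiation and alphas are renormalized at each
// step, so the recursion is safe for sequences of arbitrary length; the
// log partition function is reassembled from the accumulated scales.
//
// Emission weight layout: W[(k-1)*35 + off[d] + (s-1)] where off are the
// cumulative alphabet offsets of the 7 dimensions (sizes 5,5,5,5,5,6,4).

static const int OFFS[7] = {0, 5, 10, 15, 20, 25, 31};
static const int NEM = 35;

// [[Rcpp::export(name = ".crf_fb_cpp")]]
List crf_fb_cpp(IntegerMatrix symbols, IntegerVector labels,
                IntegerVector state_labels, NumericVector W,
                IntegerVector ef, IntegerVector et, NumericVector tr,
                bool want_grad, bool want_post) {
  const int T = symbols.nrow();
  const int K = state_labels.size();
  const int E = ef.size();
  if (T == 0)
    return List::create(_["log_z"] = NA_REAL, _["feasible"] = false,
                        _["first_infeasible"] = 0);

  std::vector<double> we(E);
  std::vector<double> startw(K, 0.0), endw(K, 0.0);
  std::vector<int> ia, ib, ie; // interior edges
  for (int e = 0; e < E; ++e) {
    we[e] = std::exp(tr[e]);
    if (ef[e] == 0) {
      startw[et[e] - 1] += we[e];
    } else if (et[e] == K + 1) {
      endw[ef[e] - 1] += we[e];
    } else {
      ia.push_back(ef[e] - 1);
      ib.push_back(et[e] - 1);
      ie.push_back(e);
    }
  }
  const int EI = ia.size();

  // emission potentials psi(t,k), max-shifted per position over allowed
  std::vector<double> psi(static_cast<size_t>(T) * K);
  std::vector<char> allow(static_cast<size_t>(T) * K);
  double mx_sum = 0.0;
  for (int t = 0; t < T; ++t) {
    double mx = R_NegInf;
    std::vector<double> sc(K);
    for (int k = 0; k < K; ++k) {
      bool ok = (labels[t] == 0) || (state_labels[k] == labels[t]);
      allow[static_cast<size_t>(t) * K + k] = ok;
      if (!ok) { sc[k] = R_NegInf; continue; }
      const double* w = &W[static_cast<size_t>(k) * NEM];
      double s = 0.0;
      for (int d = 0; d < 7; ++d) s += w[OFFS[d] + symbols(t, d) - 1];
      sc[k] = s;
      if (s > mx) mx = s;
    }
    if (mx == R_NegInf) mx = 0.0; // no allowed state: all psi 0
    mx_sum += mx;
    for (int k = 0; k < K; ++k)
      psi[static_cast<size_t>(t) * K + k] =
        (sc[k] == R_NegInf) ? 0.0 : std::exp(sc[k] - mx);
  }

  // forward
  std::vector<double> alpha(static_cast<size_t>(T) * K, 0.0);
  double log_scale = 0.0;
  bool feasible = true;
  int first_bad = 0;
  {
    double c = 0.0;
    for (int k = 0; k < K; ++k) {
      double v = startw[k] * psi[k];
      alpha[k] = v;
      c += v;
    }
    if (c <= 0.0) { feasible = false; first_bad = 1; }
    else {
      log_scale += std::log(c);
      for (int k = 0; k < K; ++k) alpha[k] /= c;
    }
  }
  std::vector<double> acc(K);
  for (int t = 1; t < T && feasible; ++t) {
    std::fill(acc.begin(), acc.end(), 0.0);
    const double* ap = &alpha[static_cast<size_t>(t - 1) * K];
    for (int e = 0; e < EI; ++e) acc[ib[e]] += ap[ia[e]] * we[ie[e]];
    double c = 0.0;
    double* an = &alpha[static_cast<size_t>(t) * K];
    const double* ps = &psi[static_cast<size_t>(t) * K];
    for (int k = 0; k < K; ++k) {
      double v = acc[k] * ps[k];
      an[k] = v;
      c += v;
    }
    if (c <= 0.0) { feasible = false; first_bad = t + 1; }
    else {
      log_scale += std::log(c);
      for (int k = 0; k < K; ++k) an[k] /= c;
    }
  }
  double zt = 0.0;
  if (feasible) {
    const double* aT = &alpha[static_cast<size_t>(T - 1) * K];
    for (int k = 0; k < K; ++k) zt += aT[k] * endw[k];
    if (zt <= 0.0) { feasible = false; first_bad = T; }
  }
  if (!feasible)
    return List::create(_["log_z"] = R_NegInf, _["feasible"] = false,
                        _["first_infeasible"] = first_bad);
  const double log_z = log_scale + mx_sum + std::log(zt);

  if (!want_grad && !want_post)
    return List::create(_["log_z"] = log_z, _["feasible"] = true,
                        _["first_infeasible"] = 0);

  // backward (renormalized each step; posteriors normalized per position)
  std::vector<double> beta(static_cast<size_t>(T) * K, 0.0);
  {
    double s = 0.0;
    double* bT = &beta[static_cast<size_t>(T - 1) * K];
    for (int k = 0; k < K; ++k) { bT[k] = endw[k]; s += endw[k]; }
    for (int k = 0; k < K; ++k) bT[k] /= s;
  }
  for (int t = T - 2; t >= 0; --t) {
    std::fill(acc.begin(), acc.end(), 0.0);
    const double* bn = &beta[static_cast<size_t>(t + 1) * K];
    const double* ps = &psi[static_cast<size_t>(t + 1) * K];
    for (int e = 0; e < EI; ++e)
      acc[ia[e]] += we[ie[e]] * ps[ib[e]] * bn[ib[e]];
    double s = 0.0;
    double* bt = &beta[static_cast<size_t>(t) * K];
    for (int k = 0; k < K; ++k) { bt[k] = acc[k]; s += acc[k]; }
    if (s > 0) for (int k = 0; k < K; ++k) bt[k] /= s;
  }

  NumericMatrix post(want_post ? T : 0, want_post ? K : 0);
  NumericVector gw(want_grad ? W.size() : 0);
  NumericVector gt(want_grad ? E : 0);

  std::vector<double> gamma(K);
  for (int t = 0; t < T; ++t) {
    const double* at = &alpha[static_cast<size_t>(t) * K];
    const double* bt = &beta[static_cast<size_t>(t) * K];
    double s = 0.0;
    for (int k = 0; k < K; ++k) { gamma[k] = at[k] * bt[k]; s += gamma[k]; }
    for (int k = 0; k < K; ++k) gamma[k] /= s;
    if (want_post)
      for (int k = 0; k < K; ++k) post(t, k) = gamma[k];
    if (want_grad) {
      for (int k = 0; k < K; ++k) {
        if (gamma[k] == 0.0) continue;
        double* g = &gw[static_cast<size_t>(k) * NEM];
        for (int d = 0; d < 7; ++d)
          g[OFFS[d] + symbols(t, d) - 1] += gamma[k];
      }
    }
  }

  if (want_grad) {
    std::vector<double> xi(E);
    // start edges
    {
      double s = 0.0;
      const double* b1 = &beta[0];
      for (int e = 0; e < E; ++e) {
        if (ef[e] != 0) { xi[e] = 0.0; continue; }
        int b = et[e] - 1;
        xi[e] = we[e] * psi[b] * b1[b];
        s += xi[e];
      }
      if (s > 0) for (int e = 0; e < E; ++e) if (ef[e] == 0) gt[e] += xi[e] / s;
    }
    // end edges
    {
      double s = 0.0;
      const double* aT = &alpha[static_cast<size_t>(T - 1) * K];
      for (int e = 0; e < E; ++e) {
        if (et[e] != K + 1) { xi[e] = 0.0; continue; }
        xi[e] = aT[ef[e] - 1] * we[e];
        s += xi[e];
      }
      if (s > 0)
        for (int e = 0; e < E; ++e) if (et[e] == K + 1) gt[e] += xi[e] / s;
    }
    // interior edges
    std::vector<double> v(EI);
    for (int t = 0; t + 1 < T; ++t) {
      const double* at = &alpha[static_cast<size_t>(t) * K];
      const double* bn = &beta[static_cast<size_t>(t + 1) * K];
      const double* ps = &psi[static_cast<size_t>(t + 1) * K];
      double s = 0.0;
      for (int e = 0; e < EI; ++e) {
        v[e] = at[ia[e]] * we[ie[e]] * ps[ib[e]] * bn[ib[e]];
        s += v[e];
      }
      if (s > 0) for (int e = 0; e < EI; ++e) gt[ie[e]] += v[e] / s;
    }
  }

  List out = List::create(_["log_z"] = log_z, _["feasible"] = true,
                          _["first_infeasible"] = 0);
  if (want_post) out["posteriors"] = post;
  if (want_grad) { out["grad_w"] = gw; out["grad_tr"] = gt; }
  return out;
}
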