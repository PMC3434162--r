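#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Windowed McCaskill-style partition function over a pair-additive energy
// model.  Nested (intra-pair) partition functions are banded: only
// subsequences that can sit inside a pair of span <= max_span are needed,
// so tables are n x (max_span+1).  Exterior prefix/suffix partition
// functions are kept in log space so arbitrarily long sequences do not
// overflow; the outside band is normalised by the total partition function
// and therefore stays on probability scale.

namespace {

inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// nucleotide codes: 0=A 1=C 2=G 3=U 4=N (never pairs)
inline double pair_energy(int a, int b, double eGC, double eAU, double eGU) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return eGC;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return eAU;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return eGU;
  return NA_REAL;
}

} // namespace

// [[Rcpp::export(name = ".fold_bpp_cpp")]]
List fold_bpp_cpp(IntegerVector codes, int max_span, int min_loop,
                  double temperature_scale,
                  double eGC, double eAU, double eGU, double prune) {
  const int n = codes.size();
  if (n == 0) {
    return List::create(_["i"] = IntegerVector(0), _["j"] = IntegerVector(0),
                        _["p"] = NumericVector(0), _["log_z"] = 0.0);
  }
  const int B = max_span; // max nested subsequence length we ever query
  const double ts = temperature_scale;

  // pair Boltzmann weights, 0 when pairing is illegal by type
  std::vector<double> lw(static_cast<size_t>(n + 1) * (B + 1), R_NegInf);
  auto LW = [&](int k, int j) -> double& { // k < j, j - k <= B
    return lw[static_cast<size_t>(k) * (B + 1) + (j - k)];
  };
  auto legal = [&](int k, int j) -> bool {
    if (j - k > max_span || j - k - 1 < min_loop) return false;
    double e = pair_energy(codes[k - 1], codes[j - 1], eGC, eAU, eGU);
    return !ISNA(e);
  };
  for (int k = 1; k <= n; ++k)
    for (int j = k + 1; j <= n && j - k <= B; ++j)
      if (legal(k, j)) {
        double e = pair_energy(codes[k - 1], codes[j - 1], eGC, eAU, eGU);
        LW(k, j) = -e / ts;
      }

  // nested inside: ZIN(i, len) = Z of [i, i+len-1], len 0..B
  std::vector<double> zin(static_cast<size_t>(n + 2) * (B + 1), 0.0);
  auto ZIN = [&](int i, int len) -> double& {
    return zin[static_cast<size_t>(i) * (B + 1) + len];
  };
  for (int i = 1; i <= n + 1; ++i) ZIN(i, 0) = 1.0;
  for (int len = 1; len <= B; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      const int j = i + len - 1;
      double z = ZIN(i, len - 1); // j unpaired
      for (int k = (j - max_span > i) ? j - max_span : i; k < j; ++k) {
        double l = LW(k, j);
        if (l == R_NegInf) continue;
        z += ZIN(i, k - i) * std::exp(l) * ZIN(k + 1, j - k - 1);
      }
      ZIN(i, len) = z;
    }
  }

  // exterior prefix/suffix in log space
  std::vector<double> lzf(n + 2, 0.0), lzr(n + 2, 0.0);
  for (int j = 1; j <= n; ++j) {
    double acc = lzf[j - 1];
    for (int k = (j - max_span > 1) ? j - max_span : 1; k < j; ++k) {
      double l = LW(k, j);
      if (l == R_NegInf) continue;
      acc = logsumexp2(acc, lzf[k - 1] + l + std::log(ZIN(k + 1, j - k - 1)));
    }
    lzf[j] = acc;
  }
  lzr[n + 1] = 0.0;
  for (int i = n; i >= 1; --i) {
    double acc = lzr[i + 1];
    for (int l = i + 1; l <= n && l - i <= max_span; ++l) {
      double w = LW(i, l);
      if (w == R_NegInf) continue;
      acc = logsumexp2(acc, w + std::log(ZIN(i + 1, l - i - 1)) + lzr[l + 1]);
    }
    lzr[i] = acc;
  }
  const double lztot = lzf[n];

  // outside of nested items, normalised by Ztot; pair probabilities
  std::vector<double> bn(static_cast<size_t>(n + 2) * (B + 1), 0.0);
  auto BN = [&](int i, int len) -> double& {
    return bn[static_cast<size_t>(i) * (B + 1) + len];
  };
  std::vector<double> pp(static_cast<size_t>(n + 1) * (B + 1), 0.0);
  auto PP = [&](int k, int j) -> double& {
    return pp[static_cast<size_t>(k) * (B + 1) + (j - k)];
  };

  // prefix-level rules: F(j) -> F(k-1) (k,j) N(k+1, j-1)
  for (int j = 1; j <= n; ++j) {
    const double lbf = lzr[j + 1] - lztot; // log outside of prefix [1..j]
    for (int k = (j - max_span > 1) ? j - max_span : 1; k < j; ++k) {
      double l = LW(k, j);
      if (l == R_NegInf) continue;
      double base = lbf + lzf[k - 1] + l;
      BN(k + 1, j - k - 1) += std::exp(base);
      PP(k, j) += std::exp(base + std::log(ZIN(k + 1, j - k - 1)));
    }
  }
  // nested rules, decreasing length
  for (int len = B; len >= 1; --len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      const double b = BN(i, len);
      if (b == 0.0) continue;
      const int j = i + len - 1;
      BN(i, len - 1) += b; // j unpaired
      for (int k = (j - max_span > i) ? j - max_span : i; k < j; ++k) {
        double l = LW(k, j);
        if (l == R_NegInf) continue;
        double w = std::exp(l);
        double zi = ZIN(k + 1, j - k - 1);
        BN(i, k - i) += b * w * zi;
        BN(k + 1, j - k - 1) += b * ZIN(i, k - i) * w;
        PP(k, j) += b * ZIN(i, k - i) * w * zi;
      }
    }
  }

  std::vector<int> oi, oj;
  std::vector<double> op;
  for (int k = 1; k <= n; ++k)
    for (int j = k + 1; j <= n && j - k <= B; ++j) {
      double p = PP(k, j);
      if (p > prune) {
        if (p > 1.0) p = 1.0; // clip roundoff
        oi.push_back(k);
        oj.push_back(j);
        op.push_back(p);
      }
    }
  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj),
                      _["p"] = wrap(op), _["log_z"] = lztot);
}
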