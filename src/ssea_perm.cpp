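#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One-sided one-sample Kolmogorov-Smirnov upper tail P(D+ >= d).
// Mirrors the R implementation in R/ks.R: exact Birnbaum-Tingey for
// n <= 140, conservative asymptotic exp(-2 n d^2) otherwise.
// log-factorial table for the exact small-n branch (n <= 140)
static const double *lfact_table() {
  static std::vector<double> lf;
  if (lf.empty()) {
    lf.resize(141);
    lf[0] = 0.0;
    for (int i = 1; i <= 140; ++i) lf[i] = lf[i - 1] + std::log((double)i);
  }
  return lf.data();
}

static double ks_p_upper_c(double d, int n) {
  if (d <= 0.0) return 1.0;
  if (d >= 1.0) return 0.0;
  if (n > 140) {
    double p = std::exp(-2.0 * n * d * d);
    return p > 1.0 ? 1.0 : p;
  }
  const double *lf = lfact_table();
  int tmax = (int)std::floor(n * (1.0 - d) + 1e-12);
  double s = 0.0;
  for (int j = 0; j <= tmax; ++j) {
    double q = d + (double)j / n;
    if (q < 1.0) {
      s += std::exp(lf[n] - lf[j] - lf[n - j] + (j - 1) * std::log(q) +
                    (n - j) * std::log1p(-q));
    } else if (n - j == 0) {
      s += 1.0;
    }
  }
  double p = d * s;
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export]]
double cpp_ks_p_upper(double d, int n) { return ks_p_upper_c(d, n); }

// Permutation engine for SNP-set enrichment scores.
//
// rank_avg: average-tie ranks of the background GWAS p-values (length N).
// pos:      position of each background SNP in the (p, snp_id) order;
//           membership in the top fraction is pos <= n_top.
// set_idx:  0-based background indices of all set members, concatenated.
// set_len:  number of members per set.
//
// Per permutation, the assignment of GWAS p-values to background eSNPs is
// shuffled (Fisher-Yates on R's RNG stream, so results are reproducible
// under set.seed) while set memberships stay intact; each set's score
// (mean of -log10 KS and Fisher p-values) is recomputed. shuffle = false
// gives the identity assignment, i.e. the observed scores.
// [[Rcpp::export]]
NumericMatrix cpp_perm_scores(NumericVector rank_avg, IntegerVector pos,
                              IntegerVector set_idx, IntegerVector set_len,
                              int n_top, int n_perm, bool shuffle) {
  const int N = rank_avg.size();
  const int S = set_len.size();
  NumericMatrix out(n_perm, S);
  std::vector<int> perm(N);
  std::vector<double> buf;
  // lazy per-set cache of Fisher tail p-values indexed by hit count
  std::vector<std::vector<double> > fisher_cache(S);
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    for (int i = 0; i < N; ++i) perm[i] = i;
    if (shuffle) {
      for (int i = N - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
    }
    int off = 0;
    for (int s = 0; s < S; ++s) {
      const int k = set_len[s];
      double score = 0.0;
      if (k >= 2) {
        buf.resize(k);
        int hits = 0;
        for (int m = 0; m < k; ++m) {
          const int asg = perm[set_idx[off + m]];
          buf[m] = rank_avg[asg] / N;
          if (pos[asg] <= n_top) ++hits;
        }
        std::sort(buf.begin(), buf.end());
        double dplus = R_NegInf;
        for (int m = 0; m < k; ++m) {
          const double v = (double)(m + 1) / k - buf[m];
          if (v > dplus) dplus = v;
        }
        double pks = ks_p_upper_c(dplus, k);
        std::vector<double> &fc = fisher_cache[s];
        if (fc.empty()) fc.assign(k + 1, -1.0);
        if (fc[hits] < 0.0)
          fc[hits] = R::phyper(hits - 1, n_top, N - n_top, k, 0, 0);
        double pf = fc[hits];
        if (pks < 1e-300) pks = 1e-300;
        if (pf < 1e-300) pf = 1e-300;
        score = 0.5 * (-std::log10(pks) - std::log10(pf));
      }
      out(p, s) = score;
      off += k;
    }
  }
  return out;
}
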