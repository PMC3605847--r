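#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Summary statistics (mean alleles/locus, unbiased expected heterozygosity,
// mean M-ratio, mean squared Burrows correlation) for complete two-allele
// matrices; mirrors the R implementations for missing-free data and is the
// fast path of the ABC simulator. pcrit < 0 means 1/(2S).
static bool geno_stats(const std::vector<int> &A, const std::vector<int> &B,
                       int S, int L, double pcrit,
                       const std::vector<int> &unit, double *out) {
  double sum_k = 0.0, sum_he = 0.0, sum_m = 0.0;
  if (pcrit < 0) pcrit = 1.0 / (2.0 * S);
  std::vector<double> dose;          // S x ncol, column-major
  std::vector<int> locus_of;
  int n_poly = 0;

  for (int l = 0; l < L; ++l) {
    const int *pa = &A[l * S], *pb = &B[l * S];
    int lo = pa[0], hi = pa[0];
    for (int i = 0; i < S; ++i) {
      lo = std::min(lo, std::min(pa[i], pb[i]));
      hi = std::max(hi, std::max(pa[i], pb[i]));
    }
    const int w = hi - lo + 1;
    std::vector<int> cnt(w, 0);
    for (int i = 0; i < S; ++i) { ++cnt[pa[i] - lo]; ++cnt[pb[i] - lo]; }
    const double m2 = 2.0 * S;
    int k = 0;
    double ss = 0.0;
    for (int c = 0; c < w; ++c)
      if (cnt[c]) { ++k; double f = cnt[c] / m2; ss += f * f; }
    sum_k += k;
    sum_he += (1.0 - ss) * m2 / (m2 - 1.0);
    // M-ratio on the repeat ladder
    if (k == 1) sum_m += 1.0;
    else {
      int rmax = (int)std::lround((double)(hi - lo) / unit[l]);
      // distinct rungs
      std::vector<char> rung(rmax + 1, 0);
      for (int c = 0; c < w; ++c)
        if (cnt[c]) rung[(int)std::lround((double)c / unit[l])] = 1;
      int kr = 0;
      for (int c = 0; c <= rmax; ++c) kr += rung[c];
      sum_m += (double)kr / (rmax + 1);
    }
    if (k < 2) continue;
    ++n_poly;
    // retained alleles for the disequilibrium statistic
    std::vector<int> keep;
    for (int c = 0; c < w; ++c) {
      if (!cnt[c]) continue;
      double f = cnt[c] / m2;
      if (f >= pcrit && f <= 1.0 - pcrit) keep.push_back(c);
    }
    if (keep.empty()) continue;
    if (k == 2 && (int)keep.size() == 2) keep.resize(1);
    for (size_t ci = 0; ci < keep.size(); ++ci) {
      const int u = keep[ci] + lo;
      size_t base = dose.size();
      dose.resize(base + S);
      for (int i = 0; i < S; ++i)
        dose[base + i] = (pa[i] == u) + (pb[i] == u);
      locus_of.push_back(l);
    }
  }
  out[0] = sum_k / L;
  out[1] = sum_he / L;
  out[2] = sum_m / L;
  out[3] = NA_REAL;
  if (n_poly < 2) return false;

  const int K = locus_of.size();
  std::vector<double> mean(K), sd(K);
  for (int c = 0; c < K; ++c) {
    double s1 = 0, s2 = 0;
    const double *d = &dose[(size_t)c * S];
    for (int i = 0; i < S; ++i) { s1 += d[i]; s2 += d[i] * d[i]; }
    mean[c] = s1 / S;
    sd[c] = std::sqrt(std::max(s2 / S - mean[c] * mean[c], 0.0));
  }
  double sum_r2 = 0.0;
  long n_cmp = 0;
  const double fac = (double)S / (S - 1.0);
  for (int c1 = 0; c1 < K; ++c1)
    for (int c2 = c1 + 1; c2 < K; ++c2) {
      if (locus_of[c1] == locus_of[c2]) continue;
      if (sd[c1] <= 0 || sd[c2] <= 0) continue;
      const double *d1 = &dose[(size_t)c1 * S], *d2 = &dose[(size_t)c2 * S];
      double sxy = 0.0;
      for (int i = 0; i < S; ++i) sxy += d1[i] * d2[i];
      double r = (sxy / S - mean[c1] * mean[c2]) / (sd[c1] * sd[c2]);
      sum_r2 += r * r * fac * fac;
      ++n_cmp;
    }
  if (n_cmp == 0) return false;
  out[3] = sum_r2 / n_cmp;
  return true;
}

// [[Rcpp::export]]
NumericVector geno_stats_cpp(IntegerMatrix a1, IntegerMatrix a2,
                             double pcrit, IntegerVector repeat_unit) {
  const int S = a1.nrow(), L = a1.ncol();
  std::vector<int> A(S * L), B(S * L), unit(L);
  for (int l = 0; l < L; ++l) {
    unit[l] = repeat_unit[l];
    for (int i = 0; i < S; ++i) {
      A[l * S + i] = a1(i, l);
      B[l * S + i] = a2(i, l);
    }
  }
  NumericVector out(4);
  out.attr("names") = CharacterVector::create("mean_alleles", "he",
                                              "m_ratio", "mean_r2");
  geno_stats(A, B, S, L, pcrit, unit, REAL(out));
  return out;
}

// One ABC draw: found a Wright-Fisher population of size N from the given
// per-locus allele frequencies (Hardy-Weinberg), drift `gens` generations,
// sample S individuals, return the summary statistics.
// [[Rcpp::export]]
NumericMatrix abc_sim_stats_cpp(List freq_codes, List freq_probs,
                                NumericVector ne_draws, int S, int gens,
                                IntegerVector repeat_unit) {
  const int L = freq_codes.size();
  const int ndraw = ne_draws.size();
  NumericMatrix out(ndraw, 4);
  colnames(out) = CharacterVector::create("mean_alleles", "he", "m_ratio",
                                          "mean_r2");
  std::vector<std::vector<int> > codes(L);
  std::vector<std::vector<double> > cum(L);
  for (int l = 0; l < L; ++l) {
    IntegerVector cd = freq_codes[l];
    NumericVector pr = freq_probs[l];
    codes[l] = as<std::vector<int> >(cd);
    cum[l].resize(pr.size());
    double acc = 0.0;
    for (int j = 0; j < pr.size(); ++j) { acc += pr[j]; cum[l][j] = acc; }
    cum[l][pr.size() - 1] = 1.0;
  }
  std::vector<int> unit = as<std::vector<int> >(repeat_unit);

  for (int d = 0; d < ndraw; ++d) {
    const int N = std::max(2, (int)std::lround(ne_draws[d]));
    std::vector<int> A((size_t)N * L), B((size_t)N * L),
                     A2((size_t)N * L), B2((size_t)N * L);
    for (int l = 0; l < L; ++l) {
      const std::vector<double> &cl = cum[l];
      const std::vector<int> &cdl = codes[l];
      for (int i = 0; i < N; ++i) {
        double u = unif_rand();
        size_t j = std::lower_bound(cl.begin(), cl.end(), u) - cl.begin();
        A[(size_t)l * N + i] = cdl[j];
        u = unif_rand();
        j = std::lower_bound(cl.begin(), cl.end(), u) - cl.begin();
        B[(size_t)l * N + i] = cdl[j];
      }
    }
    for (int g = 0; g < gens; ++g) {
      for (int i = 0; i < N; ++i) {
        const int p1 = (int)(unif_rand() * N);
        const int p2 = (int)(unif_rand() * N);
        for (int l = 0; l < L; ++l) {
          const size_t base = (size_t)l * N;
          A2[base + i] = (unif_rand() < 0.5) ? A[base + p1] : B[base + p1];
          B2[base + i] = (unif_rand() < 0.5) ? A[base + p2] : B[base + p2];
        }
      }
      std::swap(A, A2);
      std::swap(B, B2);
    }
    // sample S individuals (partial Fisher-Yates; with replacement if N < S)
    std::vector<int> idx(S);
    if (N >= S) {
      std::vector<int> perm(N);
      for (int i = 0; i < N; ++i) perm[i] = i;
      for (int i = 0; i < S; ++i) {
        int j = i + (int)(unif_rand() * (N - i));
        std::swap(perm[i], perm[j]);
        idx[i] = perm[i];
      }
    } else
      for (int i = 0; i < S; ++i) idx[i] = (int)(unif_rand() * N);
    std::vector<int> SA((size_t)S * L), SB((size_t)S * L);
    for (int l = 0; l < L; ++l)
      for (int i = 0; i < S; ++i) {
        SA[(size_t)l * S + i] = A[(size_t)l * N + idx[i]];
        SB[(size_t)l * S + i] = B[(size_t)l * N + idx[i]];
      }
    double st[4];
    if (geno_stats(SA, SB, S, L, -1.0, unit, st)) {
      for (int c = 0; c < 4; ++c) out(d, c) = st[c];
    } else
      for (int c = 0; c < 4; ++c) out(d, c) = NA_REAL;
  }
  return out;
}
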