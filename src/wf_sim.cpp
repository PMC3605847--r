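#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Forward-time Wright-Fisher metapopulation simulator.
//
// Individuals are stored contiguously by deme (deme_sizes gives the block
// sizes, constant over time). Each generation, every offspring in deme i
// draws one parental deme from row i of the backward migration matrix, then
// two parents uniformly with replacement from that deme; each parent
// transmits one of its two alleles, mutating +/-1 step with probability mu
// (reflecting at allele code 1). Uses R's RNG so results are reproducible
// under set.seed().
//
// Returns final allele matrices and, when track = true, the pooled and
// per-deme mean expected heterozygosity after each generation (element 1 is
// the initial state).
// [[Rcpp::export]]
List wf_metapop_cpp(IntegerMatrix a1_, IntegerMatrix a2_,
                    IntegerVector deme_sizes, NumericMatrix mig,
                    int generations, double mu, bool track) {
  const int n = a1_.nrow(), L = a1_.ncol(), s = deme_sizes.size();
  if (mig.nrow() != s || mig.ncol() != s)
    stop("migration matrix dimension must match deme count");
  int tot = 0;
  std::vector<int> offset(s);
  for (int i = 0; i < s; ++i) { offset[i] = tot; tot += deme_sizes[i]; }
  if (tot != n) stop("deme sizes must sum to the number of individuals");

  // cumulative migration rows for inverse-cdf deme sampling
  std::vector<double> cum(s * s);
  for (int i = 0; i < s; ++i) {
    double acc = 0.0;
    for (int k = 0; k < s; ++k) { acc += mig(i, k); cum[i * s + k] = acc; }
    if (std::abs(acc - 1.0) > 1e-8) stop("migration matrix rows must sum to 1");
    cum[i * s + s - 1] = 1.0;
  }

  std::vector<int> A(n * L), B(n * L), A2(n * L), B2(n * L);
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < n; ++i) {
      A[l * n + i] = a1_(i, l);
      B[l * n + i] = a2_(i, l);
    }

  const int T = track ? generations + 1 : 0;
  NumericVector het_pool(T);
  NumericMatrix het_sub(T, s);
  std::vector<int> counts;          // per-locus window counts, pooled
  std::vector<int> dcounts;         // per-locus window counts, one deme

  auto record = [&](int t, std::vector<int> &Av, std::vector<int> &Bv) {
    double hp = 0.0;
    std::vector<double> hs(s, 0.0);
    for (int l = 0; l < L; ++l) {
      const int *pa = &Av[l * n], *pb = &Bv[l * n];
      int lo = pa[0], hi = pa[0];
      for (int i = 0; i < n; ++i) {
        lo = std::min(lo, std::min(pa[i], pb[i]));
        hi = std::max(hi, std::max(pa[i], pb[i]));
      }
      const int w = hi - lo + 1;
      counts.assign(w, 0);
      for (int d = 0; d < s; ++d) {
        dcounts.assign(w, 0);
        const int o = offset[d], m2 = 2 * deme_sizes[d];
        for (int i = o; i < o + deme_sizes[d]; ++i) {
          ++dcounts[pa[i] - lo];
          ++dcounts[pb[i] - lo];
        }
        double ss = 0.0;
        for (int c = 0; c < w; ++c) {
          counts[c] += dcounts[c];
          double f = (double)dcounts[c] / m2;
          ss += f * f;
        }
        hs[d] += 1.0 - ss;
      }
      double ss = 0.0;
      for (int c = 0; c < w; ++c) {
        double f = (double)counts[c] / (2.0 * n);
        ss += f * f;
      }
      hp += 1.0 - ss;
    }
    het_pool[t] = hp / L;
    for (int d = 0; d < s; ++d) het_sub(t, d) = hs[d] / L;
  };

  if (track) record(0, A, B);

  for (int g = 1; g <= generations; ++g) {
    for (int d = 0; d < s; ++d) {
      const double *crow = &cum[d * s];
      for (int j = offset[d]; j < offset[d] + deme_sizes[d]; ++j) {
        const double u = unif_rand();
        int k = 0;
        while (crow[k] < u) ++k;
        const int p1 = offset[k] + (int)(unif_rand() * deme_sizes[k]);
        const int p2 = offset[k] + (int)(unif_rand() * deme_sizes[k]);
        for (int l = 0; l < L; ++l) {
          const int base = l * n;
          int g1 = (unif_rand() < 0.5) ? A[base + p1] : B[base + p1];
          int g2 = (unif_rand() < 0.5) ? A[base + p2] : B[base + p2];
          if (mu > 0.0) {
            if (unif_rand() < mu)
              g1 += (g1 <= 1) ? 1 : ((unif_rand() < 0.5) ? 1 : -1);
            if (unif_rand() < mu)
              g2 += (g2 <= 1) ? 1 : ((unif_rand() < 0.5) ? 1 : -1);
          }
          A2[base + j] = g1;
          B2[base + j] = g2;
        }
      }
    }
    std::swap(A, A2);
    std::swap(B, B2);
    if (track) record(g, A, B);
  }

  IntegerMatrix out1(n, L), out2(n, L);
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < n; ++i) {
      out1(i, l) = A[l * n + i];
      out2(i, l) = B[l * n + i];
    }
  return List::create(_["a1"] = out1, _["a2"] = out2,
                      _["het_pooled"] = het_pool, _["het_sub"] = het_sub);
}
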