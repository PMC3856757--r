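#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Soft-selection reproduction across all occupied demes.
//
// Survivors are grouped by deme; every occupied deme is refilled to
// `capacity` newborns. Each newborn's parents are drawn uniformly with
// replacement from the deme's survivors (self-pairing allowed). At every
// locus (column pair 2l, 2l+1) the newborn receives one allelic value
// chosen at random from each parent, with free recombination across loci;
// each of the 20 allelic values then mutates with probability `mu` by a
// Normal(0, msd) step (mutation slots located by geometric skipping).
// Parent genomes are gathered through a transposed scratch buffer so each
// parent's alleles are cache-contiguous. Uses the R random number stream.
// [[Rcpp::export(name = ".repro_cpp")]]
List repro_cpp(NumericMatrix A, IntegerVector deme, int n_demes,
               int capacity, double mu, double msd) {
  const int n = A.nrow();
  const int ncol = A.ncol(); // 20: 10 diploid loci
  const int pairs = ncol / 2;
  std::vector<int> cnt(n_demes, 0);
  for (int i = 0; i < n; ++i) cnt[deme[i] - 1]++;
  std::vector<int> first(n_demes + 1, 0);
  for (int d = 0; d < n_demes; ++d) first[d + 1] = first[d] + cnt[d];
  // counting sort: survivor row indices grouped by deme
  std::vector<int> idx(n);
  {
    std::vector<int> cursor(first.begin(), first.end() - 1);
    for (int i = 0; i < n; ++i) idx[cursor[deme[i] - 1]++] = i;
  }
  int n_occ = 0;
  for (int d = 0; d < n_demes; ++d) if (cnt[d] > 0) ++n_occ;
  const int M = n_occ * capacity;

  // transpose survivors: At[i * ncol + c]
  std::vector<double> At((size_t)n * ncol);
  for (int c = 0; c < ncol; ++c) {
    const double *col = &A(0, c);
    for (int i = 0; i < n; ++i) At[(size_t)i * ncol + c] = col[i];
  }
  std::vector<double> Kt((size_t)M * ncol);
  IntegerVector off_deme(M);
  const bool mutate = mu > 0.0 && msd > 0.0;
  const double skip_scale = mutate ? 1.0 / std::log1p(-mu) : 0.0;

  int row = 0;
  for (int d = 0; d < n_demes; ++d) {
    if (cnt[d] == 0) continue;
    const int base = first[d], size = cnt[d];
    for (int j = 0; j < capacity; ++j, ++row) {
      int ka = (int)(unif_rand() * size); if (ka == size) --ka;
      int kb = (int)(unif_rand() * size); if (kb == size) --kb;
      const double *pa = &At[(size_t)idx[base + ka] * ncol];
      const double *pb = &At[(size_t)idx[base + kb] * ncol];
      double *kid = &Kt[(size_t)row * ncol];
      for (int l = 0; l < pairs; ++l) {
        const int c = 2 * l;
        kid[c] = pa[c + (unif_rand() < 0.5)];
        kid[c + 1] = pb[c + (unif_rand() < 0.5)];
      }
      if (mutate) {
        int pos = (int)(std::log(unif_rand()) * skip_scale);
        while (pos < ncol) {
          kid[pos] += norm_rand() * msd;
          pos += 1 + (int)(std::log(unif_rand()) * skip_scale);
        }
      }
      off_deme[row] = d + 1;
    }
  }

  NumericMatrix kids(M, ncol);
  for (int c = 0; c < ncol; ++c) {
    double *col = M > 0 ? &kids(0, c) : nullptr;
    for (int i = 0; i < M; ++i) col[i] = Kt[(size_t)i * ncol + c];
  }
  return List::create(_["alleles"] = kids, _["deme"] = off_deme);
}
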