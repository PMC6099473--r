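#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Pedigree arrays are 0-based parent indices with -1 for a missing parent.
// `rank` is a topological depth (founders 0, otherwise 1 + max parental rank),
// which guarantees that when rank[j] >= rank[i] (and j != i), j is not an
// ancestor of i, so the Malecot recursion may decompose j onto its parents.

typedef std::unordered_map<uint64_t, double> KinMemo;

static inline uint64_t pair_key(int a, int b) {
  if (a > b) std::swap(a, b);
  return (static_cast<uint64_t>(a) << 32) | static_cast<uint64_t>(static_cast<uint32_t>(b));
}

static double kin(int i, int j, const int* sire, const int* dam,
                  const int* rank, KinMemo& memo) {
  if (i < 0 || j < 0) return 0.0;
  uint64_t key = pair_key(i, j);
  KinMemo::iterator it = memo.find(key);
  if (it != memo.end()) return it->second;
  double val;
  if (i == j) {
    // k(i,i) = 0.5 * (1 + f_i), f_i = k(sire_i, dam_i)
    double f = (sire[i] >= 0 && dam[i] >= 0)
      ? kin(sire[i], dam[i], sire, dam, rank, memo) : 0.0;
    val = 0.5 * (1.0 + f);
  } else {
    // decompose the individual that cannot be an ancestor of the other
    int a = i, b = j;  // decompose b
    if (rank[a] > rank[b] || (rank[a] == rank[b] && a > b)) std::swap(a, b);
    double ks = (sire[b] >= 0) ? kin(a, sire[b], sire, dam, rank, memo) : 0.0;
    double kd = (dam[b]  >= 0) ? kin(a, dam[b],  sire, dam, rank, memo) : 0.0;
    val = 0.5 * (ks + kd);
  }
  memo[key] = val;
  return val;
}

// [[Rcpp::export(name = ".kinship_pairs_cpp")]]
NumericVector kinship_pairs_cpp(IntegerVector sire, IntegerVector dam,
                                IntegerVector rank,
                                IntegerVector ii, IntegerVector jj) {
  int m = ii.size();
  NumericVector out(m);
  KinMemo memo;
  const int* s = sire.begin();
  const int* d = dam.begin();
  const int* r = rank.begin();
  for (int k = 0; k < m; ++k) {
    out[k] = kin(ii[k], jj[k], s, d, r, memo);
  }
  return out;
}

// [[Rcpp::export(name = ".inbreeding_all_cpp")]]
NumericVector inbreeding_all_cpp(IntegerVector sire, IntegerVector dam,
                                 IntegerVector rank) {
  int n = sire.size();
  NumericVector out(n);
  KinMemo memo;
  const int* s = sire.begin();
  const int* d = dam.begin();
  const int* r = rank.begin();
  for (int i = 0; i < n; ++i) {
    out[i] = (s[i] >= 0 && d[i] >= 0) ? kin(s[i], d[i], s, d, r, memo) : 0.0;
  }
  return out;
}

// Tabular (Henderson) additive relationship matrix. Rows must already be in
// topological order (parents before offspring); parent indices refer to rows
// of this ordering.
// [[Rcpp::export(name = ".amatrix_cpp")]]
NumericMatrix amatrix_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    double Asd = (s >= 0 && d >= 0) ? A(s, d) : 0.0;
    A(i, i) = 1.0 + 0.5 * Asd;
    for (int j = 0; j < i; ++j) {
      double as = (s >= 0) ? A(s, j) : 0.0;
      double ad = (d >= 0) ? A(d, j) : 0.0;
      double v = 0.5 * (as + ad);
      A(i, j) = v;
      A(j, i) = v;
    }
  }
  return A;
}

// Gene dropping: founder-unique alleles transmitted by Mendelian sampling.
// Rows must be in topological order; returns the count of replicates in which
// one allele sampled from i and one from j are identical by descent.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".gene_drop_cpp")]]
int gene_drop_cpp(IntegerVector sire, IntegerVector dam,
                  int i, int j, int n_reps) {
  int n = sire.size();
  std::vector<int> a1(n), a2(n);
  int hits = 0;
  for (int rep = 0; rep < n_reps; ++rep) {
    int next_allele = 0;
    for (int k = 0; k < n; ++k) {
      if (sire[k] < 0) a1[k] = next_allele++;
      else a1[k] = (unif_rand() < 0.5) ? a1[sire[k]] : a2[sire[k]];
      if (dam[k] < 0) a2[k] = next_allele++;
      else a2[k] = (unif_rand() < 0.5) ? a1[dam[k]] : a2[dam[k]];
    }
    int gi = (unif_rand() < 0.5) ? a1[i] : a2[i];
    int gj = (unif_rand() < 0.5) ? a1[j] : a2[j];
    if (gi == gj) ++hits;
  }
  return hits;
}
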