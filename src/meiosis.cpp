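#include <Rcpp.h>
using namespace Rcpp;

// Marsaglia-Tsang gamma sampler using R's RNG stream; valid for shape >= 1
// (all callers boost shapes below 1).
static inline double rgamma_mt(double d, double c) {
  for (;;) {
    double x = norm_rand();
    double v = 1.0 + c * x;
    if (v <= 0.0) continue;
    v = v * v * v;
    double u = unif_rand();
    double x2 = x * x;
    if (u < 1.0 - 0.0331 * x2 * x2) return d * v;
    if (std::log(u) < 0.5 * x2 + d * (1.0 - v + std::log(v))) return d * v;
  }
}

// Chiasma positions on the four-strand bundle from a stationary gamma renewal
// process (rate 2 per Morgan, i.e. mean inter-event distance 50 cM), thinned
// to the gamete with probability 1/2 per event (no chromatid interference).
// The first event distance is drawn from the equilibrium residual
// distribution: U * length-biased interval, where length-biasing
// Gamma(nu, scale) gives Gamma(nu + 1, scale).
static void sample_crossovers(double length_cm, double nu, bool obligate,
                              std::vector<double> &out) {
  out.clear();
  const double scale = 50.0 / nu;
  const double d1 = (nu + 1.0) - 1.0 / 3.0;        // shape nu + 1 (>= 1)
  const double c1 = 1.0 / std::sqrt(9.0 * d1);
  double x;
  if (nu >= 1.0) {
    const double d0 = nu - 1.0 / 3.0;
    const double c0 = 1.0 / std::sqrt(9.0 * d0);
    x = unif_rand() * rgamma_mt(d1, c1) * scale;
    while (x < length_cm) {
      if (unif_rand() < 0.5) out.push_back(x);
      x += rgamma_mt(d0, c0) * scale;
    }
  } else {
    // shape below 1: draw Gamma(nu + 1) and boost by U^(1/nu)
    x = unif_rand() * rgamma_mt(d1, c1) * scale;
    while (x < length_cm) {
      if (unif_rand() < 0.5) out.push_back(x);
      x += rgamma_mt(d1, c1) *
        std::pow(unif_rand(), 1.0 / nu) * scale;
    }
  }
  if (obligate && out.empty())
    out.push_back(unif_rand() * length_cm);
}

// [[Rcpp::export]]
List cpp_crossover_positions(double length_cm, double nu, bool obligate,
                             int n) {
  List res(n);
  std::vector<double> buf;
  for (int i = 0; i < n; ++i) {
    sample_crossovers(length_cm, nu, obligate, buf);
    res[i] = NumericVector(buf.begin(), buf.end());
  }
  return res;
}

// One gamete per entry of `parents` (1-based column indices into h1/h2).
// Haplotype matrices are loci x individuals; `pos` holds within-chromosome
// cM positions, chromosomes delimited by chr_start (0-based) / chr_len.
// A crossover at x switches strands for loci with position > x.
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix &h1, const IntegerMatrix &h2,
                          const IntegerVector &parents,
                          const NumericVector &pos,
                          const IntegerVector &chr_start,
                          const IntegerVector &chr_len,
                          const NumericVector &chr_length_cm,
                          double nu, bool obligate) {
  const int L = h1.nrow();
  const int ng = parents.size();
  const int nchr = chr_start.size();
  IntegerMatrix out(L, ng);
  std::vector<double> cos_;
  const int *p1 = INTEGER(h1);
  const int *p2 = INTEGER(h2);
  int *po = INTEGER(out);
  const double *pp = REAL(pos);

  for (int g = 0; g < ng; ++g) {
    const int par = parents[g] - 1;
    const int *a = p1 + (R_xlen_t)par * L;
    const int *b = p2 + (R_xlen_t)par * L;
    int *dst = po + (R_xlen_t)g * L;
    for (int c = 0; c < nchr; ++c) {
      const int s = chr_start[c], n = chr_len[c];
      sample_crossovers(chr_length_cm[c], nu, obligate, cos_);
      int strand = (unif_rand() < 0.5) ? 0 : 1;
      size_t k = 0;
      const size_t nco = cos_.size();
      for (int j = s; j < s + n; ++j) {
        const double pj = pp[j];
        while (k < nco && cos_[k] < pj) {
          strand ^= 1;
          ++k;
        }
        dst[j] = strand ? b[j] : a[j];
      }
    }
  }
  return out;
}

// Raw Gram matrix of DH dosages at the selected loci, computed exactly with
// packed-bit popcounts: dosage = 2 * haplotype allele for fully inbred
// individuals, so (M M')_{ij} = 4 * |loci where both carry allele 1|.
// [[Rcpp::export]]
NumericMatrix cpp_gram_dh(const IntegerMatrix &h1,
                          const IntegerVector &loci) {
  const int L = h1.nrow();
  const int n = h1.ncol();
  const int m = loci.size();
  const int words = (m + 63) / 64;
  std::vector<uint64_t> packed((size_t)n * words, 0ull);
  const int *p1 = INTEGER(h1);
  for (int i = 0; i < n; ++i) {
    const int *col = p1 + (R_xlen_t)i * L;
    uint64_t *dst = packed.data() + (size_t)i * words;
    for (int j = 0; j < m; ++j)
      if (col[loci[j] - 1])
        dst[j >> 6] |= (1ull << (j & 63));
  }
  NumericMatrix G(n, n);
  double *pg = REAL(G);
  for (int i = 0; i < n; ++i) {
    const uint64_t *xi = packed.data() + (size_t)i * words;
    for (int j = i; j < n; ++j) {
      const uint64_t *xj = packed.data() + (size_t)j * words;
      long long c0 = 0, c1 = 0, c2 = 0, c3 = 0;
      int w = 0;
      for (; w + 4 <= words; w += 4) {
        c0 += __builtin_popcountll(xi[w] & xj[w]);
        c1 += __builtin_popcountll(xi[w + 1] & xj[w + 1]);
        c2 += __builtin_popcountll(xi[w + 2] & xj[w + 2]);
        c3 += __builtin_popcountll(xi[w + 3] & xj[w + 3]);
      }
      for (; w < words; ++w)
        c0 += __builtin_popcountll(xi[w] & xj[w]);
      const double v = 4.0 * (double)(c0 + c1 + c2 + c3);
      pg[(R_xlen_t)j * n + i] = v;
      pg[(R_xlen_t)i * n + j] = v;
    }
  }
  return G;
}

// Dosage-matrix product M v for a set of loci, straight from haplotypes
// (v has one entry per selected locus). Returns one value per individual.
// [[Rcpp::export]]
NumericVector cpp_dosage_mult(const IntegerMatrix &h1,
                              const IntegerMatrix &h2,
                              const IntegerVector &loci,
                              const NumericVector &v) {
  const int L = h1.nrow();
  const int n = h1.ncol();
  const int m = loci.size();
  NumericVector out(n);
  const int *p1 = INTEGER(h1);
  const int *p2 = INTEGER(h2);
  for (int i = 0; i < n; ++i) {
    const int *a = p1 + (R_xlen_t)i * L;
    const int *b = p2 + (R_xlen_t)i * L;
    double s = 0.0;
    for (int j = 0; j < m; ++j) {
      const double vj = v[j];
      if (vj == 0.0) continue;
      const int row = loci[j] - 1;
      s += vj * (double)(a[row] + b[row]);
    }
    out[i] = s;
  }
  return out;
}

// Transposed product M' w from haplotypes: one value per selected locus.
// [[Rcpp::export]]
NumericVector cpp_dosage_tmult(const IntegerMatrix &h1,
                               const IntegerMatrix &h2,
                               const IntegerVector &loci,
                               const NumericVector &w) {
  const int L = h1.nrow();
  const int n = h1.ncol();
  const int m = loci.size();
  NumericVector out(m);
  const int *p1 = INTEGER(h1);
  const int *p2 = INTEGER(h2);
  std::vector<double> acc(m, 0.0);
  for (int i = 0; i < n; ++i) {
    const int *a = p1 + (R_xlen_t)i * L;
    const int *b = p2 + (R_xlen_t)i * L;
    const double wi = w[i];
    if (wi == 0.0) continue;
    for (int j = 0; j < m; ++j) {
      const int row = loci[j] - 1;
      acc[j] += wi * (double)(a[row] + b[row]);
    }
  }
  std::copy(acc.begin(), acc.end(), out.begin());
  return out;
}

// In-place double-centring helper for a Gram matrix:
// G <- G - a 1' - 1 a' + cc.
// [[Rcpp::export]]
void cpp_center_gram(NumericMatrix G, const NumericVector &a, double cc) {
  const int n = G.nrow();
  double *pg = REAL(G);
  for (int j = 0; j < n; ++j) {
    const double aj = a[j] - cc;
    double *col = pg + (R_xlen_t)j * n;
    for (int i = 0; i < n; ++i)
      col[i] -= a[i] + aj;
  }
}

// In-place addition of a scalar to the diagonal.
// [[Rcpp::export]]
void cpp_add_diag(NumericMatrix G, double lambda) {
  const int n = G.nrow();
  double *pg = REAL(G);
  for (int i = 0; i < n; ++i)
    pg[(R_xlen_t)i * n + i] += lambda;
}

// Genotype dosage matrix, individuals x selected loci, as double
// (ready for RRBLUP linear algebra).
// [[Rcpp::export]]
NumericMatrix cpp_dosage(const IntegerMatrix &h1, const IntegerMatrix &h2,
                         const IntegerVector &loci) {
  const int L = h1.nrow();
  const int n = h1.ncol();
  const int m = loci.size();
  NumericMatrix out(n, m);
  const int *p1 = INTEGER(h1);
  const int *p2 = INTEGER(h2);
  double *po = REAL(out);
  for (int j = 0; j < m; ++j) {
    const int row = loci[j] - 1;
    const int *a = p1 + row;
    const int *b = p2 + row;
    double *dst = po + (R_xlen_t)j * n;
    for (int i = 0; i < n; ++i)
      dst[i] = (double)(a[(R_xlen_t)i * L] + b[(R_xlen_t)i * L]);
  }
  return out;
}
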