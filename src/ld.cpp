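#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-locus haplotype frequency EM and likelihood-based D' confidence
// intervals from unphased diploid dosage data.  Genotype pairs are reduced
// to a 3x3 count table n[a][b] (a = dosage at locus A, b = dosage at locus
// B).  Under HWE every cell determines its two haplotypes except the double
// heterozygote, which the EM resolves.

static const double EPS_P = 1e-300;

// log-likelihood of a 3x3 genotype count table given haplotype frequencies
static double loglik_counts(const double n[3][3], double pAB, double pAb,
                            double paB, double pab) {
  double P[3][3];
  P[0][0] = pab * pab;
  P[0][1] = 2.0 * pab * paB;
  P[0][2] = paB * paB;
  P[1][0] = 2.0 * pab * pAb;
  P[1][1] = 2.0 * pAB * pab + 2.0 * pAb * paB;
  P[1][2] = 2.0 * paB * pAB;
  P[2][0] = pAb * pAb;
  P[2][1] = 2.0 * pAb * pAB;
  P[2][2] = pAB * pAB;
  double ll = 0.0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      if (n[a][b] > 0.0) ll += n[a][b] * std::log(std::max(P[a][b], EPS_P));
  return ll;
}

struct EMResult {
  double p[4];  // pAB, pAb, paB, pab
  int niter;
  bool converged;
};

static EMResult em_counts(const double n[3][3], double tol, int max_iter,
                          std::vector<double> *trace) {
  double N = 0.0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) N += n[a][b];
  EMResult res;
  res.p[0] = res.p[1] = res.p[2] = res.p[3] = 0.25;  // uniform start
  res.niter = 0;
  res.converged = false;
  if (N <= 0.0) return res;
  double H = 2.0 * N;
  for (int it = 0; it < max_iter; ++it) {
    double pAB = res.p[0], pAb = res.p[1], paB = res.p[2], pab = res.p[3];
    if (trace) trace->push_back(loglik_counts(n, pAB, pAb, paB, pab));
    double denom = pAB * pab + pAb * paB;
    double E = denom > 0.0 ? (pAB * pab) / denom : 0.5;
    double cAB = 2.0 * n[2][2] + n[2][1] + n[1][2] + E * n[1][1];
    double cAb = 2.0 * n[2][0] + n[2][1] + n[1][0] + (1.0 - E) * n[1][1];
    double caB = 2.0 * n[0][2] + n[1][2] + n[0][1] + (1.0 - E) * n[1][1];
    double cab = 2.0 * n[0][0] + n[0][1] + n[1][0] + E * n[1][1];
    double q[4] = {cAB / H, cAb / H, caB / H, cab / H};
    double delta = 0.0;
    for (int k = 0; k < 4; ++k)
      delta = std::max(delta, std::fabs(q[k] - res.p[k]));
    for (int k = 0; k < 4; ++k) res.p[k] = q[k];
    res.niter = it + 1;
    if (delta < tol) { res.converged = true; break; }
  }
  if (trace)
    trace->push_back(loglik_counts(n, res.p[0], res.p[1], res.p[2], res.p[3]));
  return res;
}

static void ld_from_freqs(const double p[4], double *D, double *Dprime,
                          double *r2) {
  double pAB = p[0], pAb = p[1], paB = p[2];
  double pA = pAB + pAb, pB = pAB + paB;
  double d = pAB - pA * pB;
  double dmax;
  if (d > 0.0)
    dmax = std::min(pA * (1.0 - pB), (1.0 - pA) * pB);
  else
    dmax = std::min(pA * pB, (1.0 - pA) * (1.0 - pB));
  *D = d;
  *Dprime = dmax > 0.0 ? std::fabs(d) / dmax : 0.0;
  if (*Dprime > 1.0) *Dprime = 1.0;
  double denom = pA * (1.0 - pA) * pB * (1.0 - pB);
  *r2 = denom > 0.0 ? d * d / denom : 0.0;
  if (*r2 > 1.0) *r2 = 1.0;
}

// Profile the two-locus likelihood over |D'| on a grid, allele frequencies
// fixed; return equal-tail bounds of the normalized likelihood mass.
static void dprime_ci_counts(const double n[3][3], double pA, double pB,
                             double sgn, double confidence, int grid_n,
                             double *ci_low, double *ci_high) {
  std::vector<double> ll(grid_n);
  double dmax = sgn >= 0.0
    ? std::min(pA * (1.0 - pB), (1.0 - pA) * pB)
    : std::min(pA * pB, (1.0 - pA) * (1.0 - pB));
  double llmax = -1e308;
  for (int k = 0; k < grid_n; ++k) {
    double dprime = (double)k / (double)(grid_n - 1);
    double D = (sgn >= 0.0 ? 1.0 : -1.0) * dprime * dmax;
    double pAB = pA * pB + D;
    double pAb = pA * (1.0 - pB) - D;
    double paB = (1.0 - pA) * pB - D;
    double pab = (1.0 - pA) * (1.0 - pB) + D;
    pAB = std::max(pAB, 0.0); pAb = std::max(pAb, 0.0);
    paB = std::max(paB, 0.0); pab = std::max(pab, 0.0);
    ll[k] = loglik_counts(n, pAB, pAb, paB, pab);
    if (ll[k] > llmax) llmax = ll[k];
  }
  double total = 0.0;
  std::vector<double> mass(grid_n);
  for (int k = 0; k < grid_n; ++k) {
    mass[k] = std::exp(ll[k] - llmax);
    total += mass[k];
  }
  double alpha2 = (1.0 - confidence) / 2.0;
  double cum = 0.0;
  int lo = grid_n - 1;
  for (int k = 0; k < grid_n; ++k) {
    cum += mass[k] / total;
    if (cum >= alpha2) { lo = k; break; }
  }
  double tail = 0.0;
  int hi = 0;
  for (int k = grid_n - 1; k >= 0; --k) {
    tail += mass[k] / total;
    if (tail >= alpha2) { hi = k; break; }
  }
  *ci_low = (double)lo / (double)(grid_n - 1);
  *ci_high = (double)hi / (double)(grid_n - 1);
}

static void tabulate_pair(const IntegerMatrix &geno, int i, int j,
                          double n[3][3]) {
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) n[a][b] = 0.0;
  int ns = geno.nrow();
  for (int s = 0; s < ns; ++s) {
    int a = geno(s, i), b = geno(s, j);
    if (a == NA_INTEGER || b == NA_INTEGER) continue;
    n[a][b] += 1.0;
  }
}

// [[Rcpp::export(name = ".em_counts_cpp")]]
List em_counts_cpp(NumericMatrix counts, double tol = 1e-7,
                   int max_iter = 1000, bool trace = false) {
  if (counts.nrow() != 3 || counts.ncol() != 3)
    stop("counts must be a 3x3 genotype table");
  double n[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) n[a][b] = counts(a, b);
  std::vector<double> tr;
  EMResult res = em_counts(n, tol, max_iter, trace ? &tr : (std::vector<double> *)0);
  double D, Dp, r2;
  ld_from_freqs(res.p, &D, &Dp, &r2);
  List out = List::create(
    _["freqs"] = NumericVector::create(_["pAB"] = res.p[0], _["pAb"] = res.p[1],
                                       _["paB"] = res.p[2], _["pab"] = res.p[3]),
    _["D"] = D, _["Dprime"] = Dp, _["r2"] = r2,
    _["niter"] = res.niter, _["converged"] = res.converged);
  if (trace) out["loglik"] = NumericVector(tr.begin(), tr.end());
  return out;
}

// [[Rcpp::export(name = ".dprime_ci_cpp")]]
NumericVector dprime_ci_cpp(NumericMatrix counts, double confidence = 0.90,
                            int grid_n = 101) {
  double n[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) n[a][b] = counts(a, b);
  double N = 0.0, sumA = 0.0, sumB = 0.0;
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      N += n[a][b];
      sumA += a * n[a][b];
      sumB += b * n[a][b];
    }
  if (N <= 0.0) stop("empty count table");
  double pA = sumA / (2.0 * N), pB = sumB / (2.0 * N);
  EMResult res = em_counts(n, 1e-7, 1000, 0);
  double D, Dp, r2;
  ld_from_freqs(res.p, &D, &Dp, &r2);
  double lo = NA_REAL, hi = NA_REAL;
  bool degenerate = (pA <= 0.0 || pA >= 1.0 || pB <= 0.0 || pB >= 1.0);
  if (!degenerate)
    dprime_ci_counts(n, pA, pB, D >= 0.0 ? 1.0 : -1.0, confidence, grid_n,
                     &lo, &hi);
  return NumericVector::create(_["ci_low"] = lo, _["ci_high"] = hi);
}

// Bulk pairwise LD: for each (ii[k], jj[k]) 0-based column pair of the
// dosage matrix, run the EM, compute D/D'/r2 and the D' likelihood CI.
// [[Rcpp::export(name = ".ld_pairs_cpp")]]
NumericMatrix ld_pairs_cpp(IntegerMatrix geno, IntegerVector ii,
                           IntegerVector jj, double confidence = 0.90,
                           int grid_n = 101) {
  int np = ii.size();
  if (jj.size() != np) stop("ii and jj must have equal length");
  NumericMatrix out(np, 6);
  colnames(out) = CharacterVector::create("D", "Dprime", "r2", "ci_low",
                                          "ci_high", "degenerate");
  double n[3][3];
  for (int k = 0; k < np; ++k) {
    tabulate_pair(geno, ii[k], jj[k], n);
    double N = 0.0, sumA = 0.0, sumB = 0.0;
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        N += n[a][b];
        sumA += a * n[a][b];
        sumB += b * n[a][b];
      }
    double pA = N > 0.0 ? sumA / (2.0 * N) : 0.0;
    double pB = N > 0.0 ? sumB / (2.0 * N) : 0.0;
    bool degenerate = (pA <= 0.0 || pA >= 1.0 || pB <= 0.0 || pB >= 1.0);
    if (degenerate) {
      out(k, 0) = 0.0; out(k, 1) = 0.0; out(k, 2) = 0.0;
      out(k, 3) = NA_REAL; out(k, 4) = NA_REAL; out(k, 5) = 1.0;
      continue;
    }
    EMResult res = em_counts(n, 1e-7, 1000, 0);
    double D, Dp, r2;
    ld_from_freqs(res.p, &D, &Dp, &r2);
    double lo, hi;
    dprime_ci_counts(n, pA, pB, D >= 0.0 ? 1.0 : -1.0, confidence, grid_n,
                     &lo, &hi);
    out(k, 0) = D; out(k, 1) = Dp; out(k, 2) = r2;
    out(k, 3) = lo; out(k, 4) = hi; out(k, 5) = 0.0;
  }
  return out;
}
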