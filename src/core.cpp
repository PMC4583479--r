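#include <limits>
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Assemble an N x M dosage matrix from panel haplotypes and per-individual
// block-mosaic source indices. H is the (n_hap x M) 0/1 panel matrix,
// s1/s2 are (N x B) 1-based panel-haplotype indices for the two haplotypes
// of each individual, vb maps each variant to its (1-based) block.
// [[Rcpp::export]]
IntegerMatrix assemble_dosage(const IntegerMatrix& H,
                              const IntegerMatrix& s1,
                              const IntegerMatrix& s2,
                              const IntegerVector& vb) {
  const int N = s1.nrow(), M = H.ncol();
  IntegerMatrix out(N, M);
  for (int m = 0; m < M; ++m) {
    const int b = vb[m] - 1;
    const int* hcol = &H(0, m);
    const int* c1 = &s1(0, b);
    const int* c2 = &s2(0, b);
    int* o = &out(0, m);
    for (int i = 0; i < N; ++i)
      o[i] = hcol[c1[i] - 1] + hcol[c2[i] - 1];
  }
  return out;
}


// Cephes-style double-precision exp (|rel err| ~ 2e-16 on (-700, 700));
// the scalar libm exp dominates the Newton loops on this SSE baseline.
static inline double fexp(double x) {
  if (x > 708.0) return std::numeric_limits<double>::infinity();
  if (x < -708.0) return 0.0;
  static const double LOG2E = 1.44269504088896341;
  static const double C1 = 6.93145751953125e-1;
  static const double C2 = 1.42860682030941723212e-6;
  double n = std::floor(x * LOG2E + 0.5);
  x -= n * C1;
  x -= n * C2;
  const double xx = x * x;
  double px = x * (((1.26177193074810590878e-4 * xx +
                     3.02994407707441961300e-2) * xx) +
                   9.99999999999999999910e-1);
  const double qx = ((3.00198505138664455042e-6 * xx +
                      2.52448340349684104192e-3) * xx +
                     2.27265548208155028766e-1) * xx +
                    2.00000000000000000005e0;
  double e = 1.0 + 2.0 * px / (qx - px);
  // scale by 2^n via direct exponent assembly (ldexp is a libm call)
  union { double d; unsigned long long u; } sc;
  sc.u = (unsigned long long)(1023 + (long long)n) << 52;
  return e * sc.d;
}

// Two-parameter (intercept + dosage) logistic Newton-Raphson on grouped
// data: xs[g] is the dosage value of group g, n1/n0 the case/control counts.
// Returns 0 on convergence. beta/se/niter written in place.
static int newton_logistic(const std::vector<double>& xs,
                           const std::vector<double>& n1,
                           const std::vector<double>& n0,
                           double tol, int maxit,
                           double& b0_io, double& b1_io, double& se,
                           bool warm) {
  const int G = (int)xs.size();
  double t1 = 0, t0 = 0, sx = 0, sxx = 0, sn = 0, s1x = 0;
  for (int g = 0; g < G; ++g) {
    const double n = n1[g] + n0[g];
    t1 += n1[g]; t0 += n0[g];
    sn += n; sx += n * xs[g]; sxx += n * xs[g] * xs[g];
    s1x += n1[g] * xs[g];
  }
  const double pbar = t1 / sn;
  double b0 = std::log(t1 / t0), b1 = 0.0;
  if (warm) {
    b0 = b0_io; b1 = b1_io;
  } else {
    // one score step from the null for a good start
    const double xbar = sx / sn;
    const double U = s1x - pbar * sx;
    const double I = pbar * (1 - pbar) * (sxx - sn * xbar * xbar);
    if (I > 0) { b1 = U / I; b0 -= b1 * xbar; }
  }
  double i00 = 0, i01 = 0, i11 = 0;
  bool conv = false;
  for (int it = 0; it < maxit; ++it) {
    double g0 = 0, g1 = 0;
    i00 = i01 = i11 = 0;
    for (int g = 0; g < G; ++g) {
      const double eta = b0 + b1 * xs[g];
      const double p = 1.0 / (1.0 + fexp(-eta));
      const double n = n1[g] + n0[g];
      const double r = n1[g] - n * p;
      const double w = n * p * (1 - p);
      g0 += r; g1 += r * xs[g];
      i00 += w; i01 += w * xs[g]; i11 += w * xs[g] * xs[g];
    }
    const double det = i00 * i11 - i01 * i01;
    if (det <= 0 || !std::isfinite(det)) return 2;
    double d0 = (i11 * g0 - i01 * g1) / det;
    double d1 = (i00 * g1 - i01 * g0) / det;
    const double step = std::max(std::fabs(d0), std::fabs(d1));
    if (step > 5.0) { d0 *= 5.0 / step; d1 *= 5.0 / step; }
    b0 += d0; b1 += d1;
    if (std::max(std::fabs(d0), std::fabs(d1)) < tol) { conv = true; break; }
  }
  const double det = i00 * i11 - i01 * i01;
  if (!conv || det <= 0) return 2;
  b0_io = b0;
  b1_io = b1;
  se = std::sqrt(i00 / det);
  if (!std::isfinite(b1) || !std::isfinite(se) || std::fabs(b1) > 15)
    return 2;
  return 0;
}

// Exact per-individual Newton iterations on a dosage column (NA skipped),
// starting from (b0, b1). Returns 0 on convergence.
static int newton_exact_col(const double* x, const int* y, int N,
                            double tol, int maxit, bool has_na,
                            double& b0, double& b1, double& se) {
  double i00 = 0, i01 = 0, i11 = 0;
  bool conv = false;
  for (int it = 0; it < maxit; ++it) {
    double g0 = 0, g1 = 0;
    i00 = i01 = i11 = 0;
    for (int i = 0; i < N; ++i) {
      const double xi = x[i];
      if (has_na && ISNAN(xi)) continue;
      const double p = 1.0 / (1.0 + fexp(-(b0 + b1 * xi)));
      const double r = (y[i] == 1 ? 1.0 : 0.0) - p;
      const double w = p * (1 - p);
      g0 += r; g1 += r * xi;
      i00 += w; i01 += w * xi; i11 += w * xi * xi;
    }
    const double det = i00 * i11 - i01 * i01;
    if (det <= 0 || !std::isfinite(det)) return 2;
    double d0 = (i11 * g0 - i01 * g1) / det;
    double d1 = (i00 * g1 - i01 * g0) / det;
    const double step = std::max(std::fabs(d0), std::fabs(d1));
    if (step > 5.0) { d0 *= 5.0 / step; d1 *= 5.0 / step; }
    b0 += d0; b1 += d1;
    if (std::max(std::fabs(d0), std::fabs(d1)) < tol) { conv = true; break; }
  }
  const double det = i00 * i11 - i01 * i01;
  if (!conv || det <= 0) return 2;
  se = std::sqrt(i00 / det);
  if (!std::isfinite(b1) || !std::isfinite(se) || std::fabs(b1) > 15)
    return 2;
  return 0;
}

// Per-variant logistic association scan. X is N x M dosage (NA = missing),
// y is 0/1 phenotype. Every column is first aggregated onto a dosage grid
// of 1/64 (hard calls land exactly on grid points, so for them the
// aggregated fit IS the exact fit); columns with off-grid (imputed)
// dosages then finish with exact per-individual Newton iterations from
// the aggregated optimum -- the fixed point of the exact iterations is
// the exact-data MLE, the aggregation only shortens the path to it.
// Status: 0 ok, 1 monomorphic, 2 unstable.
// [[Rcpp::export]]
List logit_scan_cpp(const NumericMatrix& X, const IntegerVector& y,
                    double tol = 1e-8, int maxit = 25) {
  const int N = X.nrow(), M = X.ncol();
  NumericVector beta(M, NA_REAL), se(M, NA_REAL), eaf(M, NA_REAL);
  IntegerVector status(M), ncase(M), nctrl(M);
  const int NB = 129;                      // dosage grid 0, 1/64, ..., 2
  std::vector<double> bn1(NB), bn0(NB);
  const int* yp = &y[0];
  for (int m = 0; m < M; ++m) {
    const double* x = &X(0, m);
    int nca = 0, nco = 0;
    bool on_grid = true, mono = true;
    double first = NA_REAL, sum = 0;
    std::fill(bn1.begin(), bn1.end(), 0.0);
    std::fill(bn0.begin(), bn0.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      const double xi = x[i];
      if (ISNAN(xi)) continue;
      if (yp[i] == 1) ++nca; else ++nco;
      sum += xi;
      if (ISNAN(first)) first = xi;
      else if (xi != first) mono = false;
      const double bpos = xi * (NB - 1) / 2.0;
      int bi = (int)(bpos + 0.5);
      if (bi < 0) bi = 0; else if (bi >= NB) bi = NB - 1;
      if (bpos != (double)bi) on_grid = false;
      if (yp[i] == 1) bn1[bi] += 1; else bn0[bi] += 1;
    }
    ncase[m] = nca; nctrl[m] = nco;
    const int nn = nca + nco;
    if (nn == 0) { status[m] = 1; continue; }
    eaf[m] = sum / (2.0 * nn);
    if (mono || nca == 0 || nco == 0) { status[m] = 1; continue; }
    std::vector<double> cx, c1, c0;
    for (int g = 0; g < NB; ++g)
      if (bn1[g] + bn0[g] > 0) {
        cx.push_back(2.0 * g / (NB - 1));
        c1.push_back(bn1[g]); c0.push_back(bn0[g]);
      }
    double b0 = NA_REAL, b1 = NA_REAL, s = NA_REAL;
    int st = newton_logistic(cx, c1, c0, on_grid ? tol : 1e-9, maxit,
                             b0, b1, s, false);
    if (!on_grid) {
      if (st != 0) { b0 = std::log((double)nca / nco); b1 = 0; }
      st = newton_exact_col(x, yp, N, tol, maxit, nn < N, b0, b1, s);
    }
    status[m] = st;
    if (st == 0) { beta[m] = b1; se[m] = s; }
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["eaf"] = eaf,
                      _["status"] = status, _["n_case"] = ncase,
                      _["n_ctrl"] = nctrl);
}

// Fill untyped/failed variant columns with expected dosages from the
// panel-LD linear predictor and compute the empirical (dosage-variance
// ratio) INFO score per imputed variant. Returns a filled copy of D.
// [[Rcpp::export]]
List impute_fill_cpp(const NumericMatrix& D, const IntegerVector& untyped,
                     const IntegerMatrix& nbr, const NumericMatrix& coef,
                     const NumericVector& icept,
                     const LogicalVector& unimputable,
                     const NumericVector& fallback) {
  const int N = D.nrow(), U = untyped.size(), k = nbr.nrow();
  NumericMatrix out = clone(D);
  NumericVector info(U);
  std::vector<double> pred(N);
  for (int u = 0; u < U; ++u) {
    const int col = untyped[u] - 1;
    double s1 = 0, s2 = 0;
    if (unimputable[u]) {
      const double d = fallback[u];
      for (int i = 0; i < N; ++i) out(i, col) = d;
      info[u] = 0.0;
      continue;
    }
    for (int i = 0; i < N; ++i) pred[i] = 2.0 * icept[u];
    for (int j = 0; j < k; ++j) {
      const double b = coef(j, u);
      const double* src = &out(0, nbr(j, u) - 1);
      for (int i = 0; i < N; ++i) pred[i] += b * src[i];
    }
    for (int i = 0; i < N; ++i) {
      double d = pred[i];
      if (d < 0) d = 0; else if (d > 2) d = 2;
      out(i, col) = d;
      s1 += d; s2 += d * d;
    }
    const double mean = s1 / N;
    const double v = (s2 - N * mean * mean) / (N - 1);
    const double p = mean / 2.0;
    const double denom = 2.0 * p * (1 - p);
    info[u] = denom > 0 ? std::min(1.0, v / denom) : 0.0;
  }
  return List::create(_["dosages"] = out, _["info"] = info);
}

// Block-mosaic source chain, anchored at `anchor_b` (1-based), switching
// to a uniformly random panel haplotype at each crossed boundary.
// [[Rcpp::export]]
IntegerMatrix mosaic_states_cpp(int H_n, int B, int anchor_b,
                                const IntegerVector& init,
                                const NumericVector& sw) {
  const int n = init.size();
  IntegerMatrix S(n, B);
  const int a = anchor_b - 1;
  for (int i = 0; i < n; ++i) S(i, a) = init[i];
  for (int b = a + 1; b < B; ++b) {
    const double p = sw[b - 1];
    for (int i = 0; i < n; ++i)
      S(i, b) = (unif_rand() < p) ?
        (int)(unif_rand() * H_n) + 1 : S(i, b - 1);
  }
  for (int b = a - 1; b >= 0; --b) {
    const double p = sw[b];
    for (int i = 0; i < n; ++i)
      S(i, b) = (unif_rand() < p) ?
        (int)(unif_rand() * H_n) + 1 : S(i, b + 1);
  }
  return S;
}


// Convert an integer dosage matrix to double with the columns of
// `mask_out` (1-based indices) set entirely to NA -- the array
// downsampling transform, done in one pass.
// [[Rcpp::export]]
NumericMatrix mask_untyped_cpp(const IntegerMatrix& D,
                               const IntegerVector& mask_out) {
  const int N = D.nrow(), M = D.ncol();
  NumericMatrix out(N, M);
  std::vector<char> drop(M, 0);
  for (int j = 0; j < mask_out.size(); ++j) drop[mask_out[j] - 1] = 1;
  for (int m = 0; m < M; ++m) {
    double* o = &out(0, m);
    if (drop[m]) {
      for (int i = 0; i < N; ++i) o[i] = NA_REAL;
    } else {
      const int* d = &D(0, m);
      for (int i = 0; i < N; ++i)
        o[i] = d[i] == NA_INTEGER ? NA_REAL : (double)d[i];
    }
  }
  return out;
}


// Hard-call scan on an integer dosage matrix (values 0/1/2 or NA): the
// genotype-count sufficient statistics make each fit O(1) after one
// counting pass, with no double conversion of the matrix.
// [[Rcpp::export]]
List logit_scan_int_cpp(const IntegerMatrix& X, const IntegerVector& y,
                        double tol = 1e-8, int maxit = 25) {
  const int N = X.nrow(), M = X.ncol();
  NumericVector beta(M, NA_REAL), se(M, NA_REAL), eaf(M, NA_REAL);
  IntegerVector status(M), ncase(M), nctrl(M);
  const int* yp = &y[0];
  for (int m = 0; m < M; ++m) {
    const int* x = &X(0, m);
    double cnt[2][3] = {{0, 0, 0}, {0, 0, 0}};
    int nca = 0, nco = 0;
    long sum = 0;
    for (int i = 0; i < N; ++i) {
      const int xi = x[i];
      if (xi == NA_INTEGER) continue;
      if (yp[i] == 1) ++nca; else ++nco;
      sum += xi;
      cnt[yp[i]][xi] += 1;
    }
    ncase[m] = nca; nctrl[m] = nco;
    const int nn = nca + nco;
    if (nn == 0) { status[m] = 1; continue; }
    eaf[m] = sum / (2.0 * nn);
    int nlev = 0;
    std::vector<double> cx, c1, c0;
    for (int g = 0; g < 3; ++g)
      if (cnt[0][g] + cnt[1][g] > 0) {
        ++nlev;
        cx.push_back((double)g);
        c1.push_back(cnt[1][g]); c0.push_back(cnt[0][g]);
      }
    if (nlev < 2 || nca == 0 || nco == 0) { status[m] = 1; continue; }
    double b0 = NA_REAL, b1 = NA_REAL, s_ = NA_REAL;
    const int st = newton_logistic(cx, c1, c0, tol, maxit, b0, b1, s_,
                                   false);
    status[m] = st;
    if (st == 0) { beta[m] = b1; se[m] = s_; }
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["eaf"] = eaf,
                      _["status"] = status, _["n_case"] = ncase,
                      _["n_ctrl"] = nctrl);
}
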