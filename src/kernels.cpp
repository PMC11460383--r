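#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise-distance kernels for the three PDDF/XS engines.  All histograms
// use the shared bin rule: distance r belongs to bin round(r / dr), i.e. bins
// are centred on m * dr with edges (m +/- 1/2) * dr.

static inline double dist3(const double* x, const double* y, const double* z,
                           int j, int k) {
  double dx = x[j] - x[k], dy = y[j] - y[k], dz = z[j] - z[k];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export]]
double cpp_max_pair_dist(NumericVector x, NumericVector y, NumericVector z) {
  int n = x.size();
  double best = 0.0;
  for (int j = 0; j < n - 1; ++j)
    for (int k = j + 1; k < n; ++k) {
      double dx = x[j] - x[k], dy = y[j] - y[k], dz = z[j] - z[k];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}

// Point-charge PDDF: accumulated pair weights dz_j * dz_k per bin (ordered
// pairs, so off-diagonal contributions count twice); self pairs returned
// separately as a mass at r = 0.
// [[Rcpp::export]]
List cpp_weighted_hist(NumericVector x, NumericVector y, NumericVector z,
                       NumericVector w, double dr, int nbins) {
  int n = x.size();
  NumericVector bins(nbins);
  double self = 0.0;
  for (int j = 0; j < n; ++j) self += w[j] * w[j];
  for (int j = 0; j < n - 1; ++j)
    for (int k = j + 1; k < n; ++k) {
      double r = dist3(REAL(x), REAL(y), REAL(z), j, k);
      int b = (int)std::lround(r / dr);
      if (b >= nbins) b = nbins - 1;
      bins[b] += 2.0 * w[j] * w[k];
    }
  return List::create(_["bins"] = bins, _["self_mass"] = self);
}

// Cross-pair weighted histogram (both ordered directions) between two sets.
// [[Rcpp::export]]
NumericVector cpp_cross_weighted_hist(NumericVector xa, NumericVector ya,
                                      NumericVector za, NumericVector wa,
                                      NumericVector xb, NumericVector yb,
                                      NumericVector zb, NumericVector wb,
                                      double dr, int nbins) {
  NumericVector bins(nbins);
  int na = xa.size(), nb = xb.size();
  for (int j = 0; j < na; ++j)
    for (int k = 0; k < nb; ++k) {
      double dx = xa[j] - xb[k], dy = ya[j] - yb[k], dz = za[j] - zb[k];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)std::lround(r / dr);
      if (b >= nbins) b = nbins - 1;
      bins[b] += 2.0 * wa[j] * wb[k];
    }
  return bins;
}

// Typed pair-distance histograms H_jk(r_m): ordered-pair counts per type
// pair per bin, self pairs (j == k atoms) tallied per type at r = 0.
// Layout: cube[m + nbins * (s + ntypes * t)] with the symmetric entries
// (s,t) and (t,s) both filled.
// [[Rcpp::export]]
List cpp_typed_hist(NumericVector x, NumericVector y, NumericVector z,
                    IntegerVector type0, int ntypes, double dr, int nbins) {
  int n = x.size();
  NumericVector cube((R_xlen_t)nbins * ntypes * ntypes);
  NumericVector selfc(ntypes);
  for (int j = 0; j < n; ++j) selfc[type0[j]] += 1.0;
  for (int j = 0; j < n - 1; ++j) {
    int tj = type0[j];
    for (int k = j + 1; k < n; ++k) {
      int tk = type0[k];
      double r = dist3(REAL(x), REAL(y), REAL(z), j, k);
      int b = (int)std::lround(r / dr);
      if (b >= nbins) b = nbins - 1;
      cube[b + (R_xlen_t)nbins * (tj + ntypes * tk)] += 1.0;
      cube[b + (R_xlen_t)nbins * (tk + ntypes * tj)] += 1.0;
    }
  }
  return List::create(_["cube"] = cube, _["self_counts"] = selfc);
}

// Typed cross histogram between two atom sets (ordered pairs, both
// directions), for inter-subunit correlation terms.
// [[Rcpp::export]]
NumericVector cpp_cross_typed_hist(NumericVector xa, NumericVector ya,
                                   NumericVector za, IntegerVector ta,
                                   NumericVector xb, NumericVector yb,
                                   NumericVector zb, IntegerVector tb,
                                   int ntypes, double dr, int nbins) {
  NumericVector cube((R_xlen_t)nbins * ntypes * ntypes);
  int na = xa.size(), nb = xb.size();
  for (int j = 0; j < na; ++j)
    for (int k = 0; k < nb; ++k) {
      double dx = xa[j] - xb[k], dy = ya[j] - yb[k], dz = za[j] - zb[k];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)std::lround(r / dr);
      if (b >= nbins) b = nbins - 1;
      cube[b + (R_xlen_t)nbins * (ta[j] + ntypes * tb[k])] += 1.0;
      cube[b + (R_xlen_t)nbins * (tb[k] + ntypes * ta[j])] += 1.0;
    }
  return cube;
}

// Direct Debye sum: I(q) = sum_jk A_j(q) A_k(q) sinc(q r_jk).
// Amat is nq x ntypes with per-type combined form factors A_t(q).
// [[Rcpp::export]]
NumericVector cpp_dd_xs(NumericVector x, NumericVector y, NumericVector z,
                        IntegerVector type0, NumericMatrix Amat,
                        NumericVector q) {
  int n = x.size(), nq = q.size();
  NumericVector I(nq);
  // diagonal j == k
  for (int j = 0; j < n; ++j) {
    int t = type0[j];
    for (int iq = 0; iq < nq; ++iq) I[iq] += Amat(iq, t) * Amat(iq, t);
  }
  for (int j = 0; j < n - 1; ++j) {
    int tj = type0[j];
    for (int k = j + 1; k < n; ++k) {
      int tk = type0[k];
      double r = dist3(REAL(x), REAL(y), REAL(z), j, k);
      for (int iq = 0; iq < nq; ++iq) {
        double xq = q[iq] * r;
        double s = (xq == 0.0) ? 1.0 : std::sin(xq) / xq;
        I[iq] += 2.0 * Amat(iq, tj) * Amat(iq, tk) * s;
      }
    }
  }
  return I;
}

// ---- analytic Gaussian PDDF kernel ----------------------------------------
// One Gaussian form-factor product term c * exp(-d q^2) on a pair at
// distance a contributes the exact density
//   K(r; a, d) = r / (2 a sqrt(pi d)) [exp(-(r-a)^2/4d) - exp(-(r+a)^2/4d)]
// whose cumulative integral has the closed form
//   M(r) = { -2d [G(r-a) - G(r+a)] + a sqrt(pi d) [erf((r-a)/2 sqrt(d)) +
//            erf((r+a)/2 sqrt(d))] } / (2 a sqrt(pi d)),  G(x)=exp(-x^2/4d),
// with M(0) = 0 and M(inf) = 1.  Bin masses are exact cumulative
// differences, so total weight is conserved for any Gaussian width.
// The a -> 0 (self pair) limit is
//   M_self(r) = erf(r / 2 sqrt(d)) - r exp(-r^2/4d) / sqrt(pi d).

static inline double cum_pair(double r, double a, double d, double sqd,
                              double sqpd) {
  if (r <= 0.0) return 0.0;
  double u = (r - a), v = (r + a);
  double G = std::exp(-u * u / (4.0 * d)) - std::exp(-v * v / (4.0 * d));
  double E = std::erf(u / (2.0 * sqd)) + std::erf(v / (2.0 * sqd));
  return (-2.0 * d * G + a * sqpd * E) / (2.0 * a * sqpd);
}

static inline double cum_self(double r, double d, double sqd, double sqpd) {
  if (r <= 0.0) return 0.0;
  return std::erf(r / (2.0 * sqd)) - r * std::exp(-r * r / (4.0 * d)) / sqpd;
}

// Accumulate bin masses (uniform grid, centres m * dr, m = 0..nr-1) for
// centres a[] with weights w[] and one Gaussian exponent d.  d == 0 is the
// point-charge (delta) limit.  Window of 14 Gaussian sigmas around each
// centre; truncation error < 1e-21 of the term weight.
// [[Rcpp::export]]
void cpp_accum_gauss_bins(NumericVector acc, NumericVector a, NumericVector w,
                          double d, double dr, bool self) {
  int nr = acc.size(), n = a.size();
  if (d <= 0.0) {
    for (int i = 0; i < n; ++i) {
      int b = (int)std::lround(a[i] / dr);
      if (b >= nr) b = nr - 1;
      acc[b] += w[i];
    }
    return;
  }
  double sqd = std::sqrt(d), sqpd = std::sqrt(M_PI * d);
  double W = 14.0 * std::sqrt(2.0 * d);
  for (int i = 0; i < n; ++i) {
    double ai = self ? 0.0 : a[i];
    if (!self && ai < 1e-9) ai = 0.0;
    double lo = ai - W - 0.5 * dr, hi = ai + W;
    int m0 = (int)std::floor(lo / dr + 0.5); if (m0 < 0) m0 = 0;
    int m1 = (int)std::ceil(hi / dr + 0.5);  if (m1 > nr - 1) m1 = nr - 1;
    double eprev = (m0 == 0) ? 0.0 : (m0 - 0.5) * dr;
    double cprev = (ai == 0.0) ? cum_self(eprev, d, sqd, sqpd)
                               : cum_pair(eprev, ai, d, sqd, sqpd);
    for (int m = m0; m <= m1; ++m) {
      double e2 = (m + 0.5) * dr;
      double c2 = (ai == 0.0) ? cum_self(e2, d, sqd, sqpd)
                                : cum_pair(e2, ai, d, sqd, sqpd);
      acc[m] += w[i] * (c2 - cprev);
      cprev = c2;
    }
  }
}

// Direct-Debye analytical PDDF: for every atom pair, the Gaussian terms of
// the type-pair form-factor product spread the pair weight around r_jk.
// prod_c / prod_d: (ntypes*ntypes) x maxterms matrices of product terms,
// nterms[s + ntypes*t] valid columns.  Returns bin masses on the r grid.
// [[Rcpp::export]]
NumericVector cpp_dd_pddf(NumericVector x, NumericVector y, NumericVector z,
                          IntegerVector type0, int ntypes,
                          NumericMatrix prod_c, NumericMatrix prod_d,
                          IntegerVector nterms, double dr, int nr) {
  NumericVector acc(nr);
  int n = x.size();
  double sqd, sqpd;
  // self pairs
  for (int j = 0; j < n; ++j) {
    int tp = type0[j] + ntypes * type0[j];
    for (int l = 0; l < nterms[tp]; ++l) {
      double c = prod_c(tp, l), d = prod_d(tp, l);
      if (d <= 0.0) { acc[0] += c; continue; }
      sqd = std::sqrt(d); sqpd = std::sqrt(M_PI * d);
      double W = 14.0 * std::sqrt(2.0 * d);
      int m1 = (int)std::ceil((W / dr) + 0.5); if (m1 > nr - 1) m1 = nr - 1;
      double cprev = 0.0;
      for (int m = 0; m <= m1; ++m) {
        double c2 = cum_self((m + 0.5) * dr, d, sqd, sqpd);
        acc[m] += c * (c2 - cprev);
        cprev = c2;
      }
    }
  }
  for (int j = 0; j < n - 1; ++j) {
    int tj = type0[j];
    for (int k = j + 1; k < n; ++k) {
      int tk = type0[k];
      int tp = tj + ntypes * tk;
      double a = dist3(REAL(x), REAL(y), REAL(z), j, k);
      for (int l = 0; l < nterms[tp]; ++l) {
        double c = 2.0 * prod_c(tp, l), d = prod_d(tp, l);
        if (d <= 0.0) {
          int b = (int)std::lround(a / dr);
          if (b >= nr) b = nr - 1;
          acc[b] += c;
          continue;
        }
        sqd = std::sqrt(d); sqpd = std::sqrt(M_PI * d);
        double W = 14.0 * std::sqrt(2.0 * d);
        double lo = a - W - 0.5 * dr, hi = a + W;
        int m0 = (int)std::floor(lo / dr + 0.5); if (m0 < 0) m0 = 0;
        int m1 = (int)std::ceil(hi / dr + 0.5);  if (m1 > nr - 1) m1 = nr - 1;
        double eprev = (m0 == 0) ? 0.0 : (m0 - 0.5) * dr;
        bool slf = (a < 1e-9);
        double cprev = slf ? cum_self(eprev, d, sqd, sqpd)
                           : cum_pair(eprev, a, d, sqd, sqpd);
        for (int m = m0; m <= m1; ++m) {
          double e2 = (m + 0.5) * dr;
          double c2 = slf ? cum_self(e2, d, sqd, sqpd)
                          : cum_pair(e2, a, d, sqd, sqpd);
          acc[m] += c * (c2 - cprev);
          cprev = c2;
        }
      }
    }
  }
  return acc;
}

// Distance-histogram XS (typed histogram in, intensities out).
// cube layout as cpp_typed_hist; Amat nq x ntypes.
// [[Rcpp::export]]
NumericVector cpp_dh_xs(NumericVector cube, NumericVector selfc, int ntypes,
                        int nbins, double dr, NumericMatrix Amat,
                        NumericVector q) {
  int nq = q.size();
  NumericVector I(nq);
  for (int t = 0; t < ntypes; ++t)
    if (selfc[t] > 0)
      for (int iq = 0; iq < nq; ++iq)
        I[iq] += selfc[t] * Amat(iq, t) * Amat(iq, t);
  for (int s = 0; s < ntypes; ++s)
    for (int t = s; t < ntypes; ++t) {
      double fac = (s == t) ? 1.0 : 2.0;  // cube holds both (s,t) and (t,s)
      R_xlen_t off = (R_xlen_t)nbins * (s + ntypes * t);
      for (int m = 0; m < nbins; ++m) {
        double h = cube[off + m];
        if (h == 0.0) continue;
        double rm = m * dr, hw = fac * h;
        for (int iq = 0; iq < nq; ++iq) {
          double xq = q[iq] * rm;
          double sc = (xq == 0.0) ? 1.0 : std::sin(xq) / xq;
          I[iq] += hw * Amat(iq, s) * Amat(iq, t) * sc;
        }
      }
    }
  return I;
}

// Distance-histogram analytical PDDF: Gaussian kernel per (type pair, bin).
// [[Rcpp::export]]
NumericVector cpp_dh_pddf(NumericVector cube, NumericVector selfc, int ntypes,
                          int nbins, double dr_hist,
                          NumericMatrix prod_c, NumericMatrix prod_d,
                          IntegerVector nterms, double dr, int nr) {
  NumericVector acc(nr);
  for (int t = 0; t < ntypes; ++t) {
    if (selfc[t] == 0.0) continue;
    int tp = t + ntypes * t;
    for (int l = 0; l < nterms[tp]; ++l) {
      double c = selfc[t] * prod_c(tp, l), d = prod_d(tp, l);
      NumericVector a(1); a[0] = 0.0;
      NumericVector w(1); w[0] = c;
      cpp_accum_gauss_bins(acc, a, w, d, dr, true);
    }
  }
  for (int s = 0; s < ntypes; ++s)
    for (int t = s; t < ntypes; ++t) {
      double fac = (s == t) ? 1.0 : 2.0;
      int tp = s + ntypes * t;
      R_xlen_t off = (R_xlen_t)nbins * (s + ntypes * t);
      // gather non-empty bins once per type pair
      std::vector<double> ctr, wt;
      for (int m = 0; m < nbins; ++m) {
        double h = cube[off + m];
        if (h != 0.0) { ctr.push_back(m * dr_hist); wt.push_back(fac * h); }
      }
      if (ctr.empty()) continue;
      NumericVector a(ctr.begin(), ctr.end());
      for (int l = 0; l < nterms[tp]; ++l) {
        double cl = prod_c(tp, l), d = prod_d(tp, l);
        NumericVector w(wt.size());
        for (size_t i = 0; i < wt.size(); ++i) w[i] = wt[i] * cl;
        cpp_accum_gauss_bins(acc, a, w, d, dr, false);
      }
    }
  return acc;
}

// Cross-pair analytical PDDF between two atom sets (both ordered
// directions): the inter-subunit correlation term of the Debye PDDF.
// [[Rcpp::export]]
NumericVector cpp_cross_dd_pddf(NumericVector xa, NumericVector ya,
                                NumericVector za, IntegerVector ta,
                                NumericVector xb, NumericVector yb,
                                NumericVector zb, IntegerVector tb,
                                int ntypes,
                                NumericMatrix prod_c, NumericMatrix prod_d,
                                IntegerVector nterms, double dr, int nr) {
  NumericVector acc(nr);
  int na = xa.size(), nb = xb.size();
  for (int j = 0; j < na; ++j) {
    int tj = ta[j];
    for (int k = 0; k < nb; ++k) {
      int tp = tj + ntypes * tb[k];
      double dx = xa[j] - xb[k], dy = ya[j] - yb[k], dz = za[j] - zb[k];
      double a = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int l = 0; l < nterms[tp]; ++l) {
        double c = 2.0 * prod_c(tp, l), d = prod_d(tp, l);
        if (d <= 0.0) {
          int b = (int)std::lround(a / dr);
          if (b >= nr) b = nr - 1;
          acc[b] += c;
          continue;
        }
        double sqd = std::sqrt(d), sqpd = std::sqrt(M_PI * d);
        double W = 14.0 * std::sqrt(2.0 * d);
        double lo = a - W - 0.5 * dr, hi = a + W;
        int m0 = (int)std::floor(lo / dr + 0.5); if (m0 < 0) m0 = 0;
        int m1 = (int)std::ceil(hi / dr + 0.5);  if (m1 > nr - 1) m1 = nr - 1;
        double eprev = (m0 == 0) ? 0.0 : (m0 - 0.5) * dr;
        bool slf = (a < 1e-9);
        double cprev = slf ? cum_self(eprev, d, sqd, sqpd)
                           : cum_pair(eprev, a, d, sqd, sqpd);
        for (int m = m0; m <= m1; ++m) {
          double e2 = (m + 0.5) * dr;
          double c2 = slf ? cum_self(e2, d, sqd, sqpd)
                          : cum_pair(e2, a, d, sqd, sqpd);
          acc[m] += c * (c2 - cprev);
          cprev = c2;
        }
      }
    }
  }
  return acc;
}
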