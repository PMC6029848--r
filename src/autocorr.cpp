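#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pearson spatial autocorrelogram of a (possibly NaN-masked) rate map at all
// integer offsets up to max_lag. The correlogram is point-symmetric, so only
// half the offsets are computed. Fully finite maps take a prefix-sum fast
// path in which only the cross term needs an explicit loop; this is what
// makes 1000-shuffle gridness nulls affordable.

static inline double rect_sum(const std::vector<double>& S, int nx,
                              int i0, int i1, int j0, int j1) {
  // inclusive bin ranges, prefix array is (nx+1) wide
  int W = nx + 1;
  return S[(j1 + 1) * W + (i1 + 1)] - S[j0 * W + (i1 + 1)]
       - S[(j1 + 1) * W + i0] + S[j0 * W + i0];
}

// fast path: Pearson correlogram table of a fully finite map
static void ac_table_finite(const double* rp, int nx, int ny, int L,
                            int min_overlap, double* ac) {
  int n1 = 2 * L + 1;
  std::fill(ac, ac + (size_t)n1 * n1, NA_REAL);
  int W = nx + 1, H = ny + 1;
  std::vector<double> S1((size_t)W * H, 0.0), S2((size_t)W * H, 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double v = rp[(size_t)j * nx + i];
      S1[(j + 1) * W + (i + 1)] = v + S1[j * W + (i + 1)]
        + S1[(j + 1) * W + i] - S1[j * W + i];
      S2[(j + 1) * W + (i + 1)] = v * v + S2[j * W + (i + 1)]
        + S2[(j + 1) * W + i] - S2[j * W + i];
    }
  for (int dx = 0; dx <= L; ++dx) {
    int dy0 = (dx == 0) ? 0 : -L;
    for (int dy = dy0; dy <= L; ++dy) {
      int i0 = std::max(0, -dx), i1 = std::min(nx - 1, nx - 1 - dx);
      int j0 = std::max(0, -dy), j1 = std::min(ny - 1, ny - 1 - dy);
      if (i0 > i1 || j0 > j1) continue;
      double n = (double)(i1 - i0 + 1) * (j1 - j0 + 1);
      if (n < min_overlap) continue;
      double s1 = rect_sum(S1, nx, i0, i1, j0, j1);
      double s11 = rect_sum(S2, nx, i0, i1, j0, j1);
      double s2 = rect_sum(S1, nx, i0 + dx, i1 + dx, j0 + dy, j1 + dy);
      double s22 = rect_sum(S2, nx, i0 + dx, i1 + dx, j0 + dy, j1 + dy);
      double s12 = 0.0;
      int len = i1 - i0 + 1;
      for (int j = j0; j <= j1; ++j) {
        const double* a = rp + (size_t)j * nx + i0;
        const double* b = rp + (size_t)(j + dy) * nx + i0 + dx;
        // independent accumulators so the reduction vectorises
        double c0 = 0, c1 = 0, c2 = 0, c3 = 0;
        int i = 0;
        for (; i + 3 < len; i += 4) {
          c0 += a[i] * b[i];
          c1 += a[i + 1] * b[i + 1];
          c2 += a[i + 2] * b[i + 2];
          c3 += a[i + 3] * b[i + 3];
        }
        for (; i < len; ++i) c0 += a[i] * b[i];
        s12 += (c0 + c1) + (c2 + c3);
      }
      double den = (n * s11 - s1 * s1) * (n * s22 - s2 * s2);
      double val = (den > 1e-24) ? (n * s12 - s1 * s2) / std::sqrt(den)
                                 : NA_REAL;
      ac[(size_t)(L + dy) * n1 + (L + dx)] = val;
      ac[(size_t)(L - dy) * n1 + (L - dx)] = val;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix autocorr_cpp(NumericMatrix r, int max_lag, int min_overlap) {
  int nx = r.nrow(), ny = r.ncol();
  int L = max_lag;
  NumericMatrix ac(2 * L + 1, 2 * L + 1);
  std::fill(ac.begin(), ac.end(), NA_REAL);

  bool has_na = false;
  for (int i = 0; i < nx * ny; ++i)
    if (!R_finite(r[i])) { has_na = true; break; }

  if (!has_na) {
    ac_table_finite(r.begin(), nx, ny, L, min_overlap, ac.begin());
  } else {
    for (int dx = 0; dx <= L; ++dx) {
      int dy0 = (dx == 0) ? 0 : -L;
      for (int dy = dy0; dy <= L; ++dy) {
        int i0 = std::max(0, -dx), i1 = std::min(nx - 1, nx - 1 - dx);
        int j0 = std::max(0, -dy), j1 = std::min(ny - 1, ny - 1 - dy);
        if (i0 > i1 || j0 > j1) continue;
        double n = 0, s1 = 0, s2 = 0, s11 = 0, s22 = 0, s12 = 0;
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            double a = r(i, j), b = r(i + dx, j + dy);
            if (!R_finite(a) || !R_finite(b)) continue;
            n += 1; s1 += a; s2 += b; s11 += a * a; s22 += b * b; s12 += a * b;
          }
        if (n < min_overlap) continue;
        double den = (n * s11 - s1 * s1) * (n * s22 - s2 * s2);
        double val = (den > 1e-24) ? (n * s12 - s1 * s2) / std::sqrt(den)
                                   : NA_REAL;
        ac(L + dx, L + dy) = val;
        ac(L - dx, L - dy) = val;
      }
    }
  }
  return ac;
}

// Batched gridness with the expanding-annulus-maximum rule, for shuffle
// nulls: one fully finite rate map per column of `maps`. Disc geometry and
// bilinear rotation operators (CSR over the correlogram table) are
// precomputed in R (see gridness_geom); results match gridness_core().
// [[Rcpp::export]]
NumericVector gridness_batch_cpp(NumericMatrix maps, int nx, int ny, int L,
                                 IntegerVector disc_dx, IntegerVector disc_dy,
                                 NumericVector disc_rr, IntegerVector ring_id,
                                 List rot_p, List rot_j, List rot_x,
                                 double inner_thresh, int min_annulus) {
  int nmap = maps.ncol();
  int m = disc_dx.size();
  int n1 = 2 * L + 1;
  const int NROT = 5; // 30, 60, 90, 120, 150 degrees
  std::vector<const int*> rp(NROT), rj(NROT);
  std::vector<const double*> rx(NROT);
  std::vector<IntegerVector> rpv, rjv;
  std::vector<NumericVector> rxv;
  for (int q = 0; q < NROT; ++q) {
    rpv.push_back(as<IntegerVector>(rot_p[q]));
    rjv.push_back(as<IntegerVector>(rot_j[q]));
    rxv.push_back(as<NumericVector>(rot_x[q]));
  }
  for (int q = 0; q < NROT; ++q) {
    rp[q] = rpv[q].begin(); rj[q] = rjv[q].begin(); rx[q] = rxv[q].begin();
  }
  std::vector<double> tab((size_t)n1 * n1);
  std::vector<double> v0(m);
  std::vector<std::vector<double> > vr(NROT, std::vector<double>(m));
  NumericVector out(nmap);

  for (int mm = 0; mm < nmap; ++mm) {
    ac_table_finite(&maps(0, mm), nx, ny, L, 20, tab.data());
    // disc values
    for (int i = 0; i < m; ++i)
      v0[i] = tab[(size_t)(disc_dy[i] + L) * n1 + (disc_dx[i] + L)];
    // inner radius: first integer ring whose azimuthal mean drops below
    // inner_thresh
    std::vector<double> rsum(L, 0.0); std::vector<int> rcnt(L, 0);
    for (int i = 0; i < m; ++i) {
      int k = ring_id[i];
      if (k >= 1 && k <= L - 1 && R_finite(v0[i])) {
        rsum[k] += v0[i]; rcnt[k] += 1;
      }
    }
    int inner = -1;
    for (int k = 1; k <= L - 1; ++k)
      if (rcnt[k] > 0 && rsum[k] / rcnt[k] < inner_thresh) { inner = k; break; }
    if (inner < 0) { out[mm] = NA_REAL; continue; }
    // rotated disc values by bilinear interpolation over the table
    for (int q = 0; q < NROT; ++q)
      for (int i = 0; i < m; ++i) {
        double acc = 0.0; bool ok = true;
        for (int e = rp[q][i]; e < rp[q][i + 1]; ++e) {
          double tv = tab[rj[q][e]];
          if (!R_finite(tv)) { ok = false; break; }
          acc += rx[q][e] * tv;
        }
        vr[q][i] = ok ? acc : NA_REAL;
      }
    // expanding annuli: cumulative Pearson over radius-sorted disc cells
    double s1[NROT], s2[NROT], s11[NROT], s22[NROT], s12[NROT];
    double cnt[NROT];
    for (int q = 0; q < NROT; ++q)
      s1[q] = s2[q] = s11[q] = s22[q] = s12[q] = cnt[q] = 0.0;
    double best = NA_REAL;
    for (int i = 0; i < m; ++i) {
      if (disc_rr[i] <= inner) continue;
      double a = v0[i];
      for (int q = 0; q < NROT; ++q) {
        double b = vr[q][i];
        if (R_finite(a) && R_finite(b)) {
          cnt[q] += 1; s1[q] += a; s2[q] += b;
          s11[q] += a * a; s22[q] += b * b; s12[q] += a * b;
        }
      }
      if (disc_rr[i] < inner + 2) continue;
      double cc[NROT]; bool ok = true;
      for (int q = 0; q < NROT; ++q) {
        double den = (cnt[q] * s11[q] - s1[q] * s1[q]) *
                     (cnt[q] * s22[q] - s2[q] * s2[q]);
        if (cnt[q] < min_annulus || den <= 1e-24) { ok = false; break; }
        cc[q] = (cnt[q] * s12[q] - s1[q] * s2[q]) / std::sqrt(den);
      }
      if (!ok) continue;
      double g = std::min(cc[1], cc[3]) -
                 std::max(cc[0], std::max(cc[2], cc[4]));
      if (!R_finite(best) || g > best) best = g;
    }
    out[mm] = best;
  }
  return out;
}
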