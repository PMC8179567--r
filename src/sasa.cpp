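#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Golden-spiral unit sphere points: deterministic, near-uniform.
static std::vector<double> spiral_dots(int n) {
  std::vector<double> pts(3 * n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * i;
    pts[3 * i] = r * std::cos(th);
    pts[3 * i + 1] = r * std::sin(th);
    pts[3 * i + 2] = z;
  }
  return pts;
}

// Shrake-Rupley solvent accessible surface area.
// Returns per-atom areas; optionally the exposed dot positions, outward
// normals, owning atom (1-based) and per-dot area, for surface statistics.
// [[Rcpp::export(name = ".sasa_cpp")]]
List sasa_cpp(NumericMatrix xyz, NumericVector radius, double probe,
              int ndots, bool return_dots) {
  int n = xyz.nrow();
  std::vector<double> dots = spiral_dots(ndots);
  NumericVector area(n);
  std::vector<double> dx(n), dy(n), dz(n), rr(n);
  for (int i = 0; i < n; ++i) {
    dx[i] = xyz(i, 0); dy[i] = xyz(i, 1); dz[i] = xyz(i, 2);
    rr[i] = radius[i] + probe;
  }
  std::vector<double> outp, outn;
  std::vector<int> owner;
  std::vector<double> dotarea;
  std::vector<int> nb; nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    double ri = rr[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double ddx = dx[j] - dx[i], ddy = dy[j] - dy[i], ddz = dz[j] - dz[i];
      double lim = ri + rr[j];
      if (ddx * ddx + ddy * ddy + ddz * ddz < lim * lim) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < ndots; ++k) {
      double px = dx[i] + ri * dots[3 * k];
      double py = dy[i] + ri * dots[3 * k + 1];
      double pz = dz[i] + ri * dots[3 * k + 2];
      bool burial = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double ddx = px - dx[j], ddy = py - dy[j], ddz = pz - dz[j];
        if (ddx * ddx + ddy * ddy + ddz * ddz < rr[j] * rr[j]) {
          burial = true;
          break;
        }
      }
      if (!burial) {
        ++exposed;
        if (return_dots) {
          outp.push_back(px); outp.push_back(py); outp.push_back(pz);
          outn.push_back(dots[3 * k]); outn.push_back(dots[3 * k + 1]);
          outn.push_back(dots[3 * k + 2]);
          owner.push_back(i + 1);
          dotarea.push_back(4.0 * M_PI * ri * ri / ndots);
        }
      }
    }
    area[i] = 4.0 * M_PI * ri * ri * exposed / ndots;
  }
  if (!return_dots) return List::create(Named("area") = area);
  int m = owner.size();
  NumericMatrix P(m, 3), N(m, 3);
  IntegerVector ow(m);
  NumericVector da(m);
  for (int i = 0; i < m; ++i) {
    P(i, 0) = outp[3 * i]; P(i, 1) = outp[3 * i + 1];
    P(i, 2) = outp[3 * i + 2];
    N(i, 0) = outn[3 * i]; N(i, 1) = outn[3 * i + 1];
    N(i, 2) = outn[3 * i + 2];
    ow[i] = owner[i]; da[i] = dotarea[i];
  }
  return List::create(Named("area") = area, Named("dots") = P,
                      Named("normals") = N, Named("owner") = ow,
                      Named("dot_area") = da);
}

// For each row of A, distance to (and index of) the nearest row of B.
// [[Rcpp::export(name = ".nearest_cpp")]]
List nearest_cpp(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nbn = B.nrow();
  NumericVector d(na);
  IntegerVector idx(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    int bj = -1;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nbn; ++j) {
      double ddx = ax - B(j, 0), ddy = ay - B(j, 1), ddz = az - B(j, 2);
      double dd = ddx * ddx + ddy * ddy + ddz * ddz;
      if (dd < best) { best = dd; bj = j; }
    }
    d[i] = std::sqrt(best);
    idx[i] = bj + 1;
  }
  return List::create(Named("dist") = d, Named("index") = idx);
}

// Minimum pairwise distance ratio r / (r_i + r_j) between two atom sets;
// used for hard-sphere clash screening.
// [[Rcpp::export(name = ".min_contact_ratio_cpp")]]
double min_contact_ratio_cpp(NumericMatrix A, NumericVector ra,
                             NumericMatrix B, NumericVector rb) {
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < B.nrow(); ++j) {
      double ddx = ax - B(j, 0), ddy = ay - B(j, 1), ddz = az - B(j, 2);
      double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      double ratio = d / (ra[i] + rb[j]);
      if (ratio < best) best = ratio;
    }
  }
  return best;
}
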