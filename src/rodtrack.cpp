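#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- small helpers ----------------------------------------------------

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// double-well potential p(s) of the distance regularizer
static inline double pwell(double s) {
  if (s <= 1.0) {
    double c = 2.0 * M_PI;
    return (1.0 / (c * c)) * (1.0 - std::cos(c * s));
  }
  double d = s - 1.0;
  return 0.5 * d * d;
}

// d_p(s) = p'(s)/s, removable singularity at 0 filled with its limit 1
static inline double dpwell(double s) {
  if (s < 1e-12) return 1.0;
  if (s <= 1.0) return std::sin(2.0 * M_PI * s) / (2.0 * M_PI * s);
  return (s - 1.0) / s;
}

// smoothed Dirac delta, compact support |x| <= eps
static inline double dirac_eps(double x, double eps) {
  if (std::fabs(x) > eps) return 0.0;
  return (1.0 / (2.0 * eps)) * (1.0 + std::cos(M_PI * x / eps));
}

// smoothed Heaviside, H(-inf)=0, H(+inf)=1
static inline double heav_eps(double x, double eps) {
  if (x < -eps) return 0.0;
  if (x > eps) return 1.0;
  return 0.5 * (1.0 + x / eps + std::sin(M_PI * x / eps) / M_PI);
}

// central differences in the interior, one-sided at the borders
static void gradient(const NumericMatrix& f, NumericMatrix& fx,
                     NumericMatrix& fy) {
  int nr = f.nrow(), nc = f.ncol();
  for (int j = 0; j < nc; ++j) {
    int jm = clampi(j - 1, 0, nc - 1), jp = clampi(j + 1, 0, nc - 1);
    double wj = 1.0 / (jp - jm);
    for (int i = 0; i < nr; ++i) {
      int im = clampi(i - 1, 0, nr - 1), ip = clampi(i + 1, 0, nr - 1);
      fx(i, j) = wj * (f(i, jp) - f(i, jm));              // d/dcol
      fy(i, j) = (f(ip, j) - f(im, j)) / (ip - im);       // d/drow
    }
  }
}

// divergence of a vector field (ax: col component, ay: row component)
static void divergence(const NumericMatrix& ax, const NumericMatrix& ay,
                       NumericMatrix& out) {
  int nr = ax.nrow(), nc = ax.ncol();
  for (int j = 0; j < nc; ++j) {
    int jm = clampi(j - 1, 0, nc - 1), jp = clampi(j + 1, 0, nc - 1);
    for (int i = 0; i < nr; ++i) {
      int im = clampi(i - 1, 0, nr - 1), ip = clampi(i + 1, 0, nr - 1);
      out(i, j) = 0.5 * (ax(i, jp) - ax(i, jm)) +
                  0.5 * (ay(ip, j) - ay(im, j));
    }
  }
}

// ---- exported primitives ----------------------------------------------

// Separable convolution with a 1-D kernel (rows then columns), replicate
// padding. Kernel length must be odd.
// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(const NumericMatrix& img,
                           const NumericVector& kernel) {
  int nr = img.nrow(), nc = img.ncol(), k = kernel.size(), r = k / 2;
  if (k % 2 == 0) stop("kernel length must be odd");
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = 0; t < k; ++t)
        s += kernel[t] * img(clampi(i + t - r, 0, nr - 1), j);
      tmp(i, j) = s;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = 0; t < k; ++t)
        s += kernel[t] * tmp(i, clampi(j + t - r, 0, nc - 1));
      out(i, j) = s;
    }
  return out;
}

// Unweighted DRLSE energy integrals (Rp, Lg, Ag).
// [[Rcpp::export]]
NumericVector cpp_energy_terms(const NumericMatrix& phi,
                               const NumericMatrix& g, double eps) {
  int nr = phi.nrow(), nc = phi.ncol();
  if (g.nrow() != nr || g.ncol() != nc) stop("phi and g shapes differ");
  NumericMatrix fx(nr, nc), fy(nr, nc);
  gradient(phi, fx, fy);
  double Rp = 0.0, Lg = 0.0, Ag = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = std::sqrt(fx(i, j) * fx(i, j) + fy(i, j) * fy(i, j));
      Rp += pwell(s);
      Lg += g(i, j) * dirac_eps(phi(i, j), eps) * s;
      Ag += g(i, j) * heav_eps(-phi(i, j), eps);
    }
  return NumericVector::create(_["Rp"] = Rp, _["Lg"] = Lg, _["Ag"] = Ag);
}

// DRLSE gradient flow with the three-term stopping criterion.
// freeze: pixels where the level set must not change (integer 0/1 matrix,
// may be 0x0 for "none"). Returns final phi, iterations used, the energy
// trace (one row per evaluated state, initial state first) and the deltas.
// [[Rcpp::export]]
List cpp_drlse_evolve(NumericMatrix phi, const NumericMatrix& g,
                      double mu, double lam, double alpha, double dt,
                      double eps, double K, int max_iter,
                      const IntegerMatrix& freeze) {
  int nr = phi.nrow(), nc = phi.ncol();
  if (g.nrow() != nr || g.ncol() != nc) stop("phi and g shapes differ");
  bool use_freeze = freeze.nrow() == nr && freeze.ncol() == nc;
  NumericMatrix phi0 = clone(phi);

  NumericMatrix gx(nr, nc), gy(nr, nc);
  gradient(g, gx, gy);

  NumericMatrix fx(nr, nc), fy(nr, nc), nx(nr, nc), ny(nr, nc),
      ax(nr, nc), ay(nr, nc), curv(nr, nc), dreg(nr, nc);

  std::vector<double> eRp, eLg, eAg, deltas;
  NumericVector e0 = cpp_energy_terms(phi, g, eps);
  eRp.push_back(e0[0]); eLg.push_back(e0[1]); eAg.push_back(e0[2]);

  int iters = 0;
  const double floor_s = 1e-10;
  for (int it = 1; it <= max_iter; ++it) {
    gradient(phi, fx, fy);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double s = std::sqrt(fx(i, j) * fx(i, j) + fy(i, j) * fy(i, j));
        double inv = 1.0 / (s + floor_s);
        nx(i, j) = fx(i, j) * inv;
        ny(i, j) = fy(i, j) * inv;
        double dp = dpwell(s);
        ax(i, j) = dp * fx(i, j);
        ay(i, j) = dp * fy(i, j);
      }
    divergence(nx, ny, curv);
    divergence(ax, ay, dreg);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        if (use_freeze && freeze(i, j) != 0) continue;
        double del = dirac_eps(phi(i, j), eps);
        double edge = del * (gx(i, j) * nx(i, j) + gy(i, j) * ny(i, j) +
                             g(i, j) * curv(i, j));
        double area = g(i, j) * del;
        double upd = phi(i, j) +
                     dt * (mu * dreg(i, j) + lam * edge + alpha * area);
        if (!std::isfinite(upd))
          stop("non-finite level set value at iteration %d", it);
        phi(i, j) = upd;
      }
    NumericVector e = cpp_energy_terms(phi, g, eps);
    double d1 = e[0] - eRp.back(), d2 = e[1] - eLg.back(),
           d3 = e[2] - eAg.back();
    double delta = d1 * d1 + d2 * d2 + d3 * d3;
    eRp.push_back(e[0]); eLg.push_back(e[1]); eAg.push_back(e[2]);
    deltas.push_back(delta);
    iters = it;
    if (delta <= K) break;
  }

  int nrow_e = (int)eRp.size();
  NumericMatrix energies(nrow_e, 3);
  for (int i = 0; i < nrow_e; ++i) {
    energies(i, 0) = eRp[i];
    energies(i, 1) = eLg[i];
    energies(i, 2) = eAg[i];
  }
  colnames(energies) = CharacterVector::create("Rp", "Lg", "Ag");
  return List::create(_["phi"] = phi, _["iterations"] = iters,
                      _["energies"] = energies,
                      _["deltas"] = NumericVector(deltas.begin(),
                                                  deltas.end()));
}

// Connected-component labelling of a 0/1 mask, 4- or 8-connectivity.
// Labels are assigned in raster-scan discovery order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const IntegerMatrix& mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1}, dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  int ndir = connectivity == 4 ? 4 : 8;
  int* dx = connectivity == 4 ? dx4 : dx8;
  int* dy = connectivity == 4 ? dy4 : dy8;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int d = 0; d < ndir; ++d) {
          int qi = pi + dy[d], qj = pj + dx[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  return lab;
}
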