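#include <Rcpp.h>
using namespace Rcpp;

// Model G(r) = sum_p w2_p * N(r; d_p, sigma_p) / r on a uniform grid, with
// optional Jacobian wrt Cartesian coordinates. Gaussians truncated at
// +/- 8 sigma (relative error < 1e-14).

// [[Rcpp::export]]
List pdf_model_eval_cpp(NumericMatrix xyz, IntegerMatrix pairs,
                        NumericVector sigma, NumericVector w2,
                        double r0, double dr, int nr, bool want_jac) {
  const int npair = pairs.nrow(), natom = xyz.nrow();
  const double inv_sqrt2pi = 0.39894228040143267794;
  NumericVector g(nr);
  NumericMatrix J;
  if (want_jac) J = NumericMatrix(nr, 3 * natom);
  for (int p = 0; p < npair; ++p) {
    const int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    const double dx = xyz(i, 0) - xyz(j, 0);
    const double dy = xyz(i, 1) - xyz(j, 1);
    const double dz = xyz(i, 2) - xyz(j, 2);
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double s = sigma[p];
    int lo = (int)std::floor((d - 8.0 * s - r0) / dr);
    int hi = (int)std::ceil((d + 8.0 * s - r0) / dr);
    if (lo < 0) lo = 0;
    if (hi > nr - 1) hi = nr - 1;
    if (lo > hi) continue;
    const double ux = dx / d, uy = dy / d, uz = dz / d;
    const int ci = 3 * i, cj = 3 * j;
    const double amp = w2[p] * inv_sqrt2pi / s;
    for (int k = lo; k <= hi; ++k) {
      const double r = r0 + k * dr;
      if (r <= 0) continue;
      const double z = (r - d) / s;
      const double gval = amp * std::exp(-0.5 * z * z) / r;
      g[k] += gval;
      if (want_jac) {
        const double dNdd = gval * z / s;
        J(k, ci) += dNdd * ux;
        J(k, ci + 1) += dNdd * uy;
        J(k, ci + 2) += dNdd * uz;
        J(k, cj) -= dNdd * ux;
        J(k, cj + 1) -= dNdd * uy;
        J(k, cj + 2) -= dNdd * uz;
      }
    }
  }
  if (want_jac) return List::create(_["g"] = g, _["jac"] = J);
  return List::create(_["g"] = g);
}

// Full stage-1 residual and Jacobian: residual = [gobs - s*G(r); penalty],
// penalty_p = kpen * max(0, dmin - d_p). Jacobian includes the scale
// column when refine_scale.

// [[Rcpp::export]]
List pdf_resid_jac_cpp(NumericMatrix xyz, IntegerMatrix pairs,
                       NumericVector sigma, NumericVector w2,
                       double r0, double dr, NumericVector gobs,
                       double scale, bool refine_scale,
                       double dmin, double kpen, bool want_jac) {
  const int npair = pairs.nrow(), natom = xyz.nrow(), nr = gobs.size();
  const int ncol = 3 * natom + (refine_scale ? 1 : 0);
  const double inv_sqrt2pi = 0.39894228040143267794;
  std::vector<double> g(nr, 0.0);
  NumericVector resid(nr + npair);
  NumericMatrix J;
  if (want_jac) J = NumericMatrix(nr + npair, ncol);
  for (int p = 0; p < npair; ++p) {
    const int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    const double dx = xyz(i, 0) - xyz(j, 0);
    const double dy = xyz(i, 1) - xyz(j, 1);
    const double dz = xyz(i, 2) - xyz(j, 2);
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double ux = dx / d, uy = dy / d, uz = dz / d;
    const int ci = 3 * i, cj = 3 * j;
    // collision penalty row
    if (d < dmin) {
      resid[nr + p] = kpen * (dmin - d);
      if (want_jac) {
        J(nr + p, ci) = -kpen * ux;
        J(nr + p, ci + 1) = -kpen * uy;
        J(nr + p, ci + 2) = -kpen * uz;
        J(nr + p, cj) = kpen * ux;
        J(nr + p, cj + 1) = kpen * uy;
        J(nr + p, cj + 2) = kpen * uz;
      }
    }
    const double s = sigma[p];
    int lo = (int)std::floor((d - 8.0 * s - r0) / dr);
    int hi = (int)std::ceil((d + 8.0 * s - r0) / dr);
    if (lo < 0) lo = 0;
    if (hi > nr - 1) hi = nr - 1;
    if (lo > hi) continue;
    const double amp = w2[p] * inv_sqrt2pi / s;
    for (int k = lo; k <= hi; ++k) {
      const double r = r0 + k * dr;
      if (r <= 0) continue;
      const double z = (r - d) / s;
      const double gval = amp * std::exp(-0.5 * z * z) / r;
      g[k] += gval;
      if (want_jac) {
        const double dRdd = -scale * gval * z / s;   // d(resid)/dd
        J(k, ci) += dRdd * ux;
        J(k, ci + 1) += dRdd * uy;
        J(k, ci + 2) += dRdd * uz;
        J(k, cj) -= dRdd * ux;
        J(k, cj + 1) -= dRdd * uy;
        J(k, cj + 2) -= dRdd * uz;
      }
    }
  }
  for (int k = 0; k < nr; ++k) resid[k] = gobs[k] - scale * g[k];
  if (want_jac && refine_scale) {
    for (int k = 0; k < nr; ++k) J(k, ncol - 1) = -g[k];
  }
  if (want_jac) return List::create(_["resid"] = resid, _["jac"] = J,
                                    _["g"] = NumericVector(g.begin(), g.end()));
  return List::create(_["resid"] = resid,
                      _["g"] = NumericVector(g.begin(), g.end()));
}
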