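// Perspective-3-Point solver for the tetrahedron E-ABC.
//
// Given the side lengths (d_BC, d_CA, d_AB) of a triangle ABC and the three
// visual angles (theta_BC, theta_CA, theta_AB) its vertices subtend at the
// center of projection E, enumerate every positive-distance triple
// (l_A, l_B, l_C) satisfying the law-of-cosines system
//
//   l_i^2 + l_j^2 - 2 l_i l_j cos(theta_ij) = d_ij^2 ,   ij in {AB, BC, CA}.
//
// Reduction: with u = l_B/l_A, v = l_C/l_A the three equations collapse to
// two quadratics in u whose coefficients are polynomials in v; their
// resultant is a degree-4 polynomial in v.  Roots are extracted from the
// companion matrix (eigenvalue method), back-substituted, filtered for
// positivity, verified against the original system, and deduplicated.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

const double REAL_ROOT_TOL = 1e-9;   // |Im| < tol * max(1, |Re|)
const double POSITIVITY_TOL = 1e-9;  // l > tol required
const double DEDUP_TOL = 1e-6;       // max relative component difference

// polynomial arithmetic on coefficient vectors, ascending powers
inline arma::vec pmul(const arma::vec& a, const arma::vec& b) {
  arma::vec out(a.n_elem + b.n_elem - 1, arma::fill::zeros);
  for (arma::uword i = 0; i < a.n_elem; ++i)
    for (arma::uword j = 0; j < b.n_elem; ++j)
      out(i + j) += a(i) * b(j);
  return out;
}

inline arma::vec padd(const arma::vec& a, const arma::vec& b, double sb) {
  arma::uword n = std::max(a.n_elem, b.n_elem);
  arma::vec out(n, arma::fill::zeros);
  out.head(a.n_elem) += a;
  out.head(b.n_elem) += sb * b;
  return out;
}

// real roots of a polynomial (ascending coefficients) via the companion
// matrix of its monic normalization; near-zero leading terms are trimmed
std::vector<double> poly_real_roots(arma::vec coef) {
  double scale = arma::abs(coef).max();
  if (scale <= 0.0) return {};
  coef /= scale;
  arma::uword deg = coef.n_elem - 1;
  while (deg > 0 && std::abs(coef(deg)) < 1e-13) --deg;
  std::vector<double> roots;
  if (deg == 0) return roots;
  if (deg == 1) {
    roots.push_back(-coef(0) / coef(1));
    return roots;
  }
  arma::mat C(deg, deg, arma::fill::zeros);
  for (arma::uword i = 1; i < deg; ++i) C(i, i - 1) = 1.0;
  for (arma::uword i = 0; i < deg; ++i) C(i, deg - 1) = -coef(i) / coef(deg);
  arma::cx_vec ev;
  if (!arma::eig_gen(ev, C)) {
    stop("companion-matrix eigenvalue computation failed");
  }
  for (arma::uword i = 0; i < ev.n_elem; ++i) {
    double re = ev(i).real(), im = ev(i).imag();
    if (std::abs(im) < REAL_ROOT_TOL * std::max(1.0, std::abs(re)))
      roots.push_back(re);
  }
  return roots;
}

struct Sol { double lA, lB, lC; };

// Newton refinement of a candidate on the full law-of-cosines system.
// Quartic roots can be ill-conditioned when solutions cluster (small,
// near-orthographic images), so raw back-substitution may carry errors of
// ~1e-7; a few Newton steps restore full double precision before the
// residual gate is applied.
void polish_candidate(double& lA, double& lB, double& lC, double a2,
                      double b2, double c2, double ca, double cb,
                      double cg) {
  for (int it = 0; it < 25; ++it) {
    double F1 = lA * lA + lB * lB - 2.0 * lA * lB * cg - c2;
    double F2 = lB * lB + lC * lC - 2.0 * lB * lC * ca - a2;
    double F3 = lC * lC + lA * lA - 2.0 * lC * lA * cb - b2;
    double fmax = std::max(std::abs(F1), std::max(std::abs(F2),
                                                  std::abs(F3)));
    if (fmax < 1e-14) break;
    arma::mat J = {{2.0 * (lA - lB * cg), 2.0 * (lB - lA * cg), 0.0},
                   {0.0, 2.0 * (lB - lC * ca), 2.0 * (lC - lB * ca)},
                   {2.0 * (lA - lC * cb), 0.0, 2.0 * (lC - lA * cb)}};
    arma::vec F = {F1, F2, F3};
    arma::vec step;
    if (!arma::solve(step, J, -F, arma::solve_opts::no_approx)) break;
    double nA = lA + step(0), nB = lB + step(1), nC = lC + step(2);
    if (!(nA > 0.0 && nB > 0.0 && nC > 0.0)) break;
    lA = nA; lB = nB; lC = nC;
  }
}

// core solver; angles in radians, sides in the same units as the returned l
std::vector<Sol> p3p_solve_core(double dBC, double dCA, double dAB,
                                double thBC, double thCA, double thAB,
                                double resid_tol) {
  const double a2 = dBC * dBC, b2 = dCA * dCA, c2 = dAB * dAB;
  const double ca = std::cos(thBC);  // angle between rays to B and C
  const double cb = std::cos(thCA);  // rays to C and A
  const double cg = std::cos(thAB);  // rays to A and B

  // two quadratics in u with v-polynomial coefficients (ascending in v):
  //   p(u) = b2*u^2 + p1(v)*u + p0(v) = 0   (BC/CA ratio)
  //   q(u) = b2*u^2 + q1   *u + q0(v) = 0   (AB/CA ratio)
  arma::vec p0 = {-a2, 2.0 * a2 * cb, b2 - a2};
  arma::vec p1 = {0.0, -2.0 * b2 * ca};
  arma::vec q0 = {b2 - c2, 2.0 * c2 * cb, -c2};
  arma::vec q1 = {-2.0 * b2 * cg};

  // resultant of p and q in u (shared leading coefficient b2):
  //   R(v) = b2^2 (q0 - p0)^2 - b2 (q1 - p1) (p1 q0 - p0 q1)
  arma::vec diff0 = padd(q0, p0, -1.0);
  arma::vec term1 = pmul(diff0, diff0) * (b2 * b2);
  arma::vec diffq = padd(q1, p1, -1.0);
  arma::vec cross = padd(pmul(p1, q0), pmul(p0, q1), -1.0);
  arma::vec quart = padd(term1, pmul(diffq, cross), -b2);

  std::vector<double> vroots = poly_real_roots(quart);

  std::vector<Sol> sols;
  for (double v : vroots) {
    if (v <= POSITIVITY_TOL) continue;
    // candidate u values for this v.  A common root of p and q follows
    // from the linear combination p - q, but that elimination degenerates
    // when the two quadratics are (near-)proportional — which happens at
    // symmetric configurations where one v root carries two distinct u
    // solutions.  So all roots of p and of q are tried as candidates; the
    // polish + residual gate keeps exactly the common ones.
    std::vector<double> ucand;
    double lin = (p1(1) * v) - q1(0);               // p1(v) - q1
    double con = (p0(0) - q0(0)) + (p0(1) - q0(1)) * v +
                 (p0(2) - q0(2)) * v * v;           // p0(v) - q0(v)
    if (std::abs(lin) > 1e-10 * std::max(1.0, std::abs(con)))
      ucand.push_back(-con / lin);
    double Bp = p1(1) * v, Cp = p0(0) + p0(1) * v + p0(2) * v * v;
    double discp = Bp * Bp - 4.0 * b2 * Cp;
    if (discp >= 0.0) {
      ucand.push_back((-Bp + std::sqrt(discp)) / (2.0 * b2));
      ucand.push_back((-Bp - std::sqrt(discp)) / (2.0 * b2));
    }
    double Bq = q1(0), Cq = q0(0) + q0(1) * v + q0(2) * v * v;
    double discq = Bq * Bq - 4.0 * b2 * Cq;
    if (discq >= 0.0) {
      ucand.push_back((-Bq + std::sqrt(discq)) / (2.0 * b2));
      ucand.push_back((-Bq - std::sqrt(discq)) / (2.0 * b2));
    }
    // cheap pre-polish dedup: common roots appear once in p's and once in
    // q's root list, so most candidates are near-identical
    std::sort(ucand.begin(), ucand.end());
    ucand.erase(std::unique(ucand.begin(), ucand.end(),
                            [](double x, double y) {
                              return std::abs(x - y) <
                                     1e-7 * std::max(1.0, std::abs(x));
                            }),
                ucand.end());
    for (double u : ucand) {
      if (u <= POSITIVITY_TOL) continue;
      double den = 1.0 + u * u - 2.0 * u * cg;  // >= sin^2(theta_AB) > 0
      if (den <= 0.0) continue;
      double lA = dAB / std::sqrt(den);
      double lB = u * lA, lC = v * lA;
      if (lA <= POSITIVITY_TOL || lB <= POSITIVITY_TOL ||
          lC <= POSITIVITY_TOL)
        continue;
      polish_candidate(lA, lB, lC, a2, b2, c2, ca, cb, cg);
      if (lA <= POSITIVITY_TOL || lB <= POSITIVITY_TOL ||
          lC <= POSITIVITY_TOL)
        continue;
      // verify against the original system (rejects extraneous roots and
      // p/q roots that are not common roots)
      double rAB = std::abs(lA * lA + lB * lB - 2.0 * lA * lB * cg - c2);
      double rBC = std::abs(lB * lB + lC * lC - 2.0 * lB * lC * ca - a2);
      double rCA = std::abs(lC * lC + lA * lA - 2.0 * lC * lA * cb - b2);
      if (std::max(rAB, std::max(rBC, rCA)) >= resid_tol) continue;
      sols.push_back({lA, lB, lC});
    }
  }

  // deduplicate (repeated quartic roots count once), sort by lA then lB
  std::vector<Sol> uniq;
  for (const Sol& s : sols) {
    bool dup = false;
    for (const Sol& t : uniq) {
      double m = std::max(
          std::abs(s.lA - t.lA) / std::max(std::abs(s.lA), std::abs(t.lA)),
          std::max(
              std::abs(s.lB - t.lB) / std::max(std::abs(s.lB), std::abs(t.lB)),
              std::abs(s.lC - t.lC) / std::max(std::abs(s.lC), std::abs(t.lC))));
      if (m < DEDUP_TOL) { dup = true; break; }
    }
    if (!dup) uniq.push_back(s);
  }
  std::sort(uniq.begin(), uniq.end(), [](const Sol& x, const Sol& y) {
    if (x.lA != y.lA) return x.lA < y.lA;
    return x.lB < y.lB;
  });
  return uniq;
}

}  // namespace

// [[Rcpp::export(name = ".p3p_solve_raw")]]
NumericMatrix p3p_solve_raw(double d_bc, double d_ca, double d_ab,
                            double th_bc, double th_ca, double th_ab,
                            double resid_tol) {
  std::vector<Sol> s =
      p3p_solve_core(d_bc, d_ca, d_ab, th_bc, th_ca, th_ab, resid_tol);
  NumericMatrix out(s.size(), 3);
  for (size_t i = 0; i < s.size(); ++i) {
    out(i, 0) = s[i].lA;
    out(i, 1) = s[i].lB;
    out(i, 2) = s[i].lC;
  }
  colnames(out) = CharacterVector::create("l_A", "l_B", "l_C");
  return out;
}

// batch solution counting for Monte-Carlo sweeps and shape-space grids;
// all angles in radians, one instance per row position
// [[Rcpp::export(name = ".p3p_count_batch")]]
IntegerVector p3p_count_batch(NumericVector d_bc, NumericVector d_ca,
                              NumericVector d_ab, NumericVector th_bc,
                              NumericVector th_ca, NumericVector th_ab,
                              double resid_tol) {
  R_xlen_t n = d_bc.size();
  if (d_ca.size() != n || d_ab.size() != n || th_bc.size() != n ||
      th_ca.size() != n || th_ab.size() != n)
    stop("batch inputs must have equal length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = (int)p3p_solve_core(d_bc[i], d_ca[i], d_ab[i], th_bc[i],
                                 th_ca[i], th_ab[i], resid_tol)
                 .size();
  }
  return out;
}
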