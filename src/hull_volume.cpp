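// Exact convex-hull volume in low dimension by supporting-hyperplane facet
// enumeration. Intended for the small point sets (tens of species, <= ~6
// axes) that arise in functional trait spaces; complexity is C(n, d) facet
// candidates, each an O(d^3) solve, so it is exact but not suitable for
// large n or high d.
#include <RcppArmadillo.h>
#include <set>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

// (d-1)-volume of a simplex given its d vertices (rows of F, in d columns),
// via the Gram determinant of its edge matrix.
double simplex_facet_volume(const arma::mat& F) {
  const arma::uword d = F.n_cols;
  arma::mat E(d - 1, d);
  for (arma::uword i = 1; i < d; ++i) E.row(i - 1) = F.row(i) - F.row(0);
  arma::mat G = E * E.t();
  double det = arma::det(G);
  if (det < 0.0) det = 0.0;
  double vol = std::sqrt(det);
  for (arma::uword k = 2; k + 1 <= d; ++k) vol /= static_cast<double>(k);
  return vol;
}

arma::mat dedup_rows(const arma::mat& P, double tol) {
  std::vector<arma::uword> keep;
  for (arma::uword i = 0; i < P.n_rows; ++i) {
    bool dup = false;
    for (arma::uword j : keep) {
      if (arma::norm(P.row(i) - P.row(j), "inf") <= tol) { dup = true; break; }
    }
    if (!dup) keep.push_back(i);
  }
  arma::mat Q(keep.size(), P.n_cols);
  for (size_t i = 0; i < keep.size(); ++i) Q.row(i) = P.row(keep[i]);
  return Q;
}

double hull_volume_rec(const arma::mat& P0, double tol) {
  arma::mat P = dedup_rows(P0, tol);
  const arma::uword n = P.n_rows;
  const arma::uword d = P.n_cols;
  if (d == 0 || n == 0) return 0.0;
  if (d == 1) return P.col(0).max() - P.col(0).min();
  if (n <= d) return 0.0;  // at most d points span zero d-volume

  const arma::rowvec centroid = arma::mean(P, 0);
  std::set<std::vector<arma::uword> > seen;
  double vol = 0.0;

  // iterate over all d-subsets as facet candidates
  std::vector<arma::uword> idx(d);
  for (arma::uword i = 0; i < d; ++i) idx[i] = i;
  bool more = true;
  while (more) {
    arma::mat E(d - 1, d);
    for (arma::uword i = 1; i < d; ++i)
      E.row(i - 1) = P.row(idx[i]) - P.row(idx[0]);
    arma::mat U, V;
    arma::vec s;
    if (arma::svd(U, s, V, E)) {
      // the subset must affinely span a (d-1)-flat, else skip it
      if (s(d - 2) > tol) {
        arma::vec w = V.col(d - 1);  // unit normal of the candidate plane
        const double b = arma::dot(w, P.row(idx[0]).t());
        arma::vec side = P * w - b;
        const bool below = arma::all(side <= tol);
        const bool above = arma::all(side >= -tol);
        if (below || above) {
          std::vector<arma::uword> facet;
          for (arma::uword j = 0; j < n; ++j)
            if (std::abs(side(j)) <= tol) facet.push_back(j);
          if (seen.insert(facet).second) {
            double fvol;
            if (facet.size() == d) {
              arma::mat F(d, d);
              for (arma::uword i = 0; i < d; ++i) F.row(i) = P.row(facet[i]);
              fvol = simplex_facet_volume(F);
            } else {
              // coplanar facet with > d vertices: project into the plane
              // and take its (d-1)-volume recursively
              arma::mat F(facet.size(), d);
              for (size_t i = 0; i < facet.size(); ++i)
                F.row(i) = P.row(facet[i]);
              arma::rowvec fc = arma::mean(F, 0);
              arma::mat C = F.each_row() - fc;
              arma::mat Uf, Vf;
              arma::vec sf;
              arma::svd_econ(Uf, sf, Vf, C);
              arma::mat Q = C * Vf.cols(0, d - 2);
              fvol = hull_volume_rec(Q, tol);
            }
            const double h = std::abs(arma::dot(w, centroid.t()) - b);
            vol += fvol * h / static_cast<double>(d);
          }
        }
      }
    }
    // next combination
    more = false;
    for (arma::sword i = d - 1; i >= 0; --i) {
      if (idx[i] < n - d + i) {
        ++idx[i];
        for (arma::uword j = i + 1; j < d; ++j) idx[j] = idx[j - 1] + 1;
        more = true;
        break;
      }
    }
  }
  return vol;
}

}  // namespace

// [[Rcpp::export(name = ".hull_volume_cpp")]]
double hull_volume_cpp(const arma::mat& pts, double rel_tol = 1e-9) {
  if (pts.n_rows == 0 || pts.n_cols == 0) return 0.0;
  double scale = 0.0;
  for (arma::uword j = 0; j < pts.n_cols; ++j) {
    const double r = pts.col(j).max() - pts.col(j).min();
    if (r > scale) scale = r;
  }
  const double tol = rel_tol * std::max(1.0, scale);
  return hull_volume_rec(pts, tol);
}
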