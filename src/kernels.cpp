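// Fast kernels for framework-fitted loop RMSD.
//
// Every pairwise comparison performs its own least-squares (Kabsch)
// superposition on the fit (framework) atoms and evaluates the RMSD over
// the calc (loop) atoms only; nothing is routed through a common
// reference frame.  Rotations are constrained to be proper (det +1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Proper rotation mapping centred rows of A onto centred rows of B.
// H = A' B (3x3). Returns R with det(R) = +1.
static inline mat kabsch_rotation(const mat& H) {
  mat U, V;
  vec s;
  if (!svd(U, s, V, H)) Rcpp::stop("SVD failed in superposition");
  double sgn = det(V * U.t()) < 0 ? -1.0 : 1.0;
  mat D = eye(3, 3);
  D(2, 2) = sgn;
  return V * D * U.t();
}

// Centre rows of X at the centroid of its fit-atom subset; also return
// the fit centroid.
static inline void centre_on_fit(const mat& X, const uvec& fit, mat& Xc,
                                 rowvec& cen) {
  cen = mean(X.rows(fit), 0);
  Xc = X.each_row() - cen;
}

// coords: cube n_atoms x 3 x n_frames (nm)
// fit0, calc0: 0-based atom indices
// Returns the symmetric n_frames x n_frames loop-RMSD matrix.
// [[Rcpp::export]]
arma::mat cpp_pairwise_loop_rmsd(const arma::cube& coords,
                                 const arma::uvec& fit0,
                                 const arma::uvec& calc0) {
  const uword nf = coords.n_slices;
  const uword nfit = fit0.n_elem;
  const uword ncalc = calc0.n_elem;
  if (nfit < 3) Rcpp::stop("need at least 3 fit atoms");
  if (ncalc < 1) Rcpp::stop("need at least 1 calc atom");

  // Precompute per frame: centred fit coords and calc coords relative to
  // the fit centroid.
  cube F(nfit, 3, nf), C(ncalc, 3, nf);
  vec c2(nf);
  for (uword f = 0; f < nf; ++f) {
    mat X = coords.slice(f);
    rowvec cen = mean(X.rows(fit0), 0);
    F.slice(f) = X.rows(fit0);
    F.slice(f).each_row() -= cen;
    C.slice(f) = X.rows(calc0);
    C.slice(f).each_row() -= cen;
    c2(f) = accu(square(C.slice(f)));
  }

  mat out(nf, nf, fill::zeros);
  for (uword i = 0; i < nf; ++i) {
    const mat& Fi = F.slice(i);
    const mat& Ci = C.slice(i);
    for (uword j = i + 1; j < nf; ++j) {
      mat H = Fi.t() * F.slice(j);
      mat R = kabsch_rotation(H);
      // sum_k || R a_k - b_k ||^2 = |A|^2 + |B|^2 - 2 sum_k b_k . (R a_k)
      double cross = accu((Ci * R.t()) % C.slice(j));
      double ss = (c2(i) + c2(j) - 2.0 * cross) / double(ncalc);
      out(i, j) = out(j, i) = ss > 0 ? std::sqrt(ss) : 0.0;
    }
  }
  return out;
}

// Superpose every frame onto `ref` using the fit atoms; returns the cube
// of fitted full frames.
// [[Rcpp::export]]
arma::cube cpp_fit_frames(const arma::cube& coords, const arma::mat& ref,
                          const arma::uvec& fit0) {
  const uword nf = coords.n_slices;
  if (fit0.n_elem < 3) Rcpp::stop("need at least 3 fit atoms");
  rowvec cref = mean(ref.rows(fit0), 0);
  mat Bc = ref.rows(fit0);
  Bc.each_row() -= cref;
  cube out(coords.n_rows, 3, nf);
  for (uword f = 0; f < nf; ++f) {
    mat X = coords.slice(f);
    rowvec cen = mean(X.rows(fit0), 0);
    mat Ac = X.rows(fit0);
    Ac.each_row() -= cen;
    mat R = kabsch_rotation(Ac.t() * Bc);
    mat Xc = X.each_row() - cen;
    mat Y = Xc * R.t();
    Y.each_row() += cref;
    out.slice(f) = Y;
  }
  return out;
}

// Framework-fitted loop RMSD of every frame against one reference frame.
// [[Rcpp::export]]
arma::vec cpp_rmsd_to_reference(const arma::cube& coords, const arma::mat& ref,
                                const arma::uvec& fit0,
                                const arma::uvec& calc0) {
  const uword nf = coords.n_slices;
  if (fit0.n_elem < 3) Rcpp::stop("need at least 3 fit atoms");
  rowvec cref = mean(ref.rows(fit0), 0);
  mat Bfit = ref.rows(fit0);
  Bfit.each_row() -= cref;
  mat Bcalc = ref.rows(calc0);
  Bcalc.each_row() -= cref;
  vec out(nf);
  for (uword f = 0; f < nf; ++f) {
    mat X = coords.slice(f);
    rowvec cen = mean(X.rows(fit0), 0);
    mat Ac = X.rows(fit0);
    Ac.each_row() -= cen;
    mat R = kabsch_rotation(Ac.t() * Bfit);
    mat Acalc = X.rows(calc0);
    Acalc.each_row() -= cen;
    mat D = Acalc * R.t() - Bcalc;
    out(f) = std::sqrt(accu(square(D)) / double(calc0.n_elem));
  }
  return out;
}
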