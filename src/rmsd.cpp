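// Kabsch superposition kernels.
//
// Frames are stored frame-major: one row per conformation, 3N columns
// ordered (x1, y1, z1, x2, ...). All RMSDs are minimal RMSDs over rigid
// rotation + translation, computed in closed form via the SVD of the 3x3
// cross-covariance matrix with the usual reflection correction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Reshape one frame-major row into an N x 3 coordinate matrix.
static mat row_to_coords(const rowvec& r) {
  const uword n = r.n_elem / 3;
  mat x(n, 3);
  for (uword i = 0; i < n; ++i) {
    x(i, 0) = r[3 * i];
    x(i, 1) = r[3 * i + 1];
    x(i, 2) = r[3 * i + 2];
  }
  return x;
}

// Minimal RMSD between two centered coordinate sets with
// cross-covariance C = X^T Y. The optimal rotation is applied and the
// residual evaluated explicitly: the trace shortcut
// (gx + gy - 2*sum(s)) loses half the significant digits to
// cancellation when the two structures nearly coincide.
static double rmsd_centered(const mat& xc, const mat& yc, const mat& C) {
  mat U, V;
  vec s;
  if (!svd(U, s, V, C)) Rcpp::stop("SVD failed in RMSD computation");
  mat D = eye(3, 3);
  if (det(U * V.t()) < 0) D(2, 2) = -1.0;
  mat R = U * D * V.t();
  return std::sqrt(accu(square(xc * R - yc)) /
                   static_cast<double>(xc.n_rows));
}

// [[Rcpp::export]]
double cpp_rmsd_pair(const arma::mat& x, const arma::mat& y) {
  if (x.n_rows != y.n_rows || x.n_cols != 3 || y.n_cols != 3)
    Rcpp::stop("coordinate matrices must be N x 3 with equal N");
  mat xc = x.each_row() - mean(x, 0);
  mat yc = y.each_row() - mean(y, 0);
  return rmsd_centered(xc, yc, xc.t() * yc);
}

// All pairwise minimal RMSDs between rows of A (Ka x 3N) and rows of
// B (Kb x 3N); returns a Ka x Kb matrix.
// [[Rcpp::export]]
arma::mat cpp_rmsd_matrix(const arma::mat& A, const arma::mat& B) {
  if (A.n_cols != B.n_cols) Rcpp::stop("frame dimension mismatch");
  const uword n = A.n_cols / 3;
  const uword ka = A.n_rows, kb = B.n_rows;

  std::vector<mat> ac(ka), bc(kb);
  for (uword i = 0; i < ka; ++i) {
    ac[i] = row_to_coords(A.row(i));
    ac[i].each_row() -= mean(ac[i], 0);
  }
  for (uword j = 0; j < kb; ++j) {
    bc[j] = row_to_coords(B.row(j));
    bc[j].each_row() -= mean(bc[j], 0);
  }

  mat out(ka, kb);
  for (uword i = 0; i < ka; ++i) {
    for (uword j = 0; j < kb; ++j) {
      out(i, j) = rmsd_centered(ac[i], bc[j], ac[i].t() * bc[j]);
    }
  }
  return out;
}

// For each row of A, the minimum RMSD over rows of B and its 1-based
// index; ties broken by the lowest index. Streams over B so the full
// Ka x Kb matrix is never materialised.
// [[Rcpp::export]]
Rcpp::List cpp_best_match(const arma::mat& A, const arma::mat& B) {
  if (A.n_cols != B.n_cols) Rcpp::stop("frame dimension mismatch");
  const uword n = A.n_cols / 3;
  const uword ka = A.n_rows, kb = B.n_rows;

  std::vector<mat> ac(ka);
  for (uword i = 0; i < ka; ++i) {
    ac[i] = row_to_coords(A.row(i));
    ac[i].each_row() -= mean(ac[i], 0);
  }

  vec best(ka);
  best.fill(datum::inf);
  uvec idx(ka, fill::zeros);
  for (uword j = 0; j < kb; ++j) {
    mat yc = row_to_coords(B.row(j));
    yc.each_row() -= mean(yc, 0);
    for (uword i = 0; i < ka; ++i) {
      double r = rmsd_centered(ac[i], yc, ac[i].t() * yc);
      if (r < best(i)) {
        best(i) = r;
        idx(i) = j + 1;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("rmsd") = best,
                            Rcpp::Named("index") = idx);
}

// Superpose every frame of X (K x 3N) onto the reference frame (1-based
// row index); returns the aligned K x 3N matrix. The reference frame is
// returned unchanged. Degenerate cross-covariances (rank < 2, e.g.
// all-collinear coordinates) fall back to a pure translation.
// [[Rcpp::export]]
arma::mat cpp_align_frames(const arma::mat& X, int ref_index) {
  const uword k = X.n_rows, n = X.n_cols / 3;
  if (ref_index < 1 || static_cast<uword>(ref_index) > k)
    Rcpp::stop("reference index out of range");
  mat ref = row_to_coords(X.row(ref_index - 1));
  rowvec ref_cen = mean(ref, 0);
  mat refc = ref.each_row() - ref_cen;

  mat out(k, X.n_cols);
  for (uword f = 0; f < k; ++f) {
    if (f == static_cast<uword>(ref_index - 1)) {
      out.row(f) = X.row(f);
      continue;
    }
    mat x = row_to_coords(X.row(f));
    rowvec cen = mean(x, 0);
    mat xc = x.each_row() - cen;
    mat C = xc.t() * refc;
    mat U, V;
    vec s;
    mat R;
    if (svd(U, s, V, C) && s(1) > 1e-10 * std::max(s(0), 1.0)) {
      mat D = eye(3, 3);
      if (det(V * U.t()) < 0) D(2, 2) = -1.0;
      R = U * D * V.t();
    } else {
      R = eye(3, 3);  // ill-conditioned rotation: translation only
    }
    mat moved = xc * R;
    moved.each_row() += ref_cen;
    for (uword i = 0; i < n; ++i) {
      out(f, 3 * i) = moved(i, 0);
      out(f, 3 * i + 1) = moved(i, 1);
      out(f, 3 * i + 2) = moved(i, 2);
    }
  }
  return out;
}
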