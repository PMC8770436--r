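// Trilinear (8-node) hexahedral element kernels for small-strain linear
// elasticity: element stiffness with B-bar mean-dilatation treatment of the
// volumetric term (near-incompressible tissue, nu = 0.45), global triplet
// assembly, Dirichlet reduction, and centroid strain recovery.
//
// Voigt order used throughout: (xx, yy, zz, xy, yz, zx) with ENGINEERING
// shear in B (gamma = 2*eps), tensor shear in recovered strain output.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

// 2x2x2 Gauss points in the reference cube [-1,1]^3 (weights all 1)
const double GP = 0.5773502691896257645091488;

// reference-node signs of the standard hex8 ordering
const int XI[8]  = {-1,  1,  1, -1, -1,  1,  1, -1};
const int ETA[8] = {-1, -1,  1,  1, -1, -1,  1,  1};
const int ZET[8] = {-1, -1, -1, -1,  1,  1,  1,  1};

// shape-function derivatives wrt (xi,eta,zeta) at a point; dN is 8x3
inline void shape_deriv(double xi, double eta, double zeta, double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    dN[a][0] = 0.125 * XI[a] * (1 + ETA[a] * eta) * (1 + ZET[a] * zeta);
    dN[a][1] = 0.125 * ETA[a] * (1 + XI[a] * xi) * (1 + ZET[a] * zeta);
    dN[a][2] = 0.125 * ZET[a] * (1 + XI[a] * xi) * (1 + ETA[a] * eta);
  }
}

// physical gradients dN/dx (8x3) and detJ at (xi,eta,zeta); coords is 8x3
inline double grad_phys(const double* cx, const double* cy, const double* cz,
                        double xi, double eta, double zeta, double dNdx[8][3]) {
  double dN[8][3];
  shape_deriv(xi, eta, zeta, dN);
  double J[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  for (int a = 0; a < 8; ++a) {
    J[0][0] += dN[a][0] * cx[a]; J[0][1] += dN[a][0] * cy[a]; J[0][2] += dN[a][0] * cz[a];
    J[1][0] += dN[a][1] * cx[a]; J[1][1] += dN[a][1] * cy[a]; J[1][2] += dN[a][1] * cz[a];
    J[2][0] += dN[a][2] * cx[a]; J[2][1] += dN[a][2] * cy[a]; J[2][2] += dN[a][2] * cz[a];
  }
  double det = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
             - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
             + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
  if (det <= 0) return det;
  double inv[3][3];
  inv[0][0] =  (J[1][1] * J[2][2] - J[1][2] * J[2][1]) / det;
  inv[0][1] = -(J[0][1] * J[2][2] - J[0][2] * J[2][1]) / det;
  inv[0][2] =  (J[0][1] * J[1][2] - J[0][2] * J[1][1]) / det;
  inv[1][0] = -(J[1][0] * J[2][2] - J[1][2] * J[2][0]) / det;
  inv[1][1] =  (J[0][0] * J[2][2] - J[0][2] * J[2][0]) / det;
  inv[1][2] = -(J[0][0] * J[1][2] - J[0][2] * J[1][0]) / det;
  inv[2][0] =  (J[1][0] * J[2][1] - J[1][1] * J[2][0]) / det;
  inv[2][1] = -(J[0][0] * J[2][1] - J[0][1] * J[2][0]) / det;
  inv[2][2] =  (J[0][0] * J[1][1] - J[0][1] * J[1][0]) / det;
  for (int a = 0; a < 8; ++a) {
    // chain rule: dN/dxi = J * dN/dx with J_ij = dx_j/dxi_i,
    // hence dN/dx_j = sum_i inv[j][i] * dN/dxi_i
    double gx = inv[0][0] * dN[a][0] + inv[0][1] * dN[a][1] + inv[0][2] * dN[a][2];
    double gy = inv[1][0] * dN[a][0] + inv[1][1] * dN[a][1] + inv[1][2] * dN[a][2];
    double gz = inv[2][0] * dN[a][0] + inv[2][1] * dN[a][1] + inv[2][2] * dN[a][2];
    dNdx[a][0] = gx; dNdx[a][1] = gy; dNdx[a][2] = gz;
  }
  return det;
}

// B (6x24, engineering shear) from physical gradients
inline void fill_B(const double dNdx[8][3], double B[6][24]) {
  for (int r = 0; r < 6; ++r)
    for (int c = 0; c < 24; ++c) B[r][c] = 0.0;
  for (int a = 0; a < 8; ++a) {
    int c = 3 * a;
    double gx = dNdx[a][0], gy = dNdx[a][1], gz = dNdx[a][2];
    B[0][c]     = gx;
    B[1][c + 1] = gy;
    B[2][c + 2] = gz;
    B[3][c]     = gy; B[3][c + 1] = gx;   // gamma_xy
    B[4][c + 1] = gz; B[4][c + 2] = gy;   // gamma_yz
    B[5][c]     = gz; B[5][c + 2] = gx;   // gamma_zx
  }
}

// Ke for one element; bbar selects mean-dilatation volumetric treatment.
// Returns false on non-positive Jacobian.
bool hex8_ke(const double* cx, const double* cy, const double* cz,
             double lambda, double mu, bool bbar, double Ke[24][24]) {
  double Ball[8][6][24];
  double detall[8];
  double vol = 0.0;
  double bvol_bar[24];
  for (int c = 0; c < 24; ++c) bvol_bar[c] = 0.0;
  int g = 0;
  for (int k = 0; k < 2; ++k)
    for (int j = 0; j < 2; ++j)
      for (int i = 0; i < 2; ++i, ++g) {
        double xi = (2 * i - 1) * GP, eta = (2 * j - 1) * GP, zeta = (2 * k - 1) * GP;
        double dNdx[8][3];
        double det = grad_phys(cx, cy, cz, xi, eta, zeta, dNdx);
        if (det <= 0) return false;
        detall[g] = det;
        fill_B(dNdx, Ball[g]);
        vol += det;
        for (int a = 0; a < 8; ++a) {
          bvol_bar[3 * a]     += det * dNdx[a][0];
          bvol_bar[3 * a + 1] += det * dNdx[a][1];
          bvol_bar[3 * a + 2] += det * dNdx[a][2];
        }
      }
  for (int c = 0; c < 24; ++c) bvol_bar[c] /= vol;

  for (int r = 0; r < 24; ++r)
    for (int c = 0; c < 24; ++c) Ke[r][c] = 0.0;

  double Bg[6][24];
  for (g = 0; g < 8; ++g) {
    double w = detall[g];
    for (int r = 0; r < 6; ++r)
      for (int c = 0; c < 24; ++c) Bg[r][c] = Ball[g][r][c];
    if (bbar) {
      // replace pointwise dilatation rows with the element average:
      // B_bar = B_dev + (1/3) m (m^T B)_bar  on the normal-strain rows
      double dil[24];
      for (int c = 0; c < 24; ++c)
        dil[c] = Bg[0][c] + Bg[1][c] + Bg[2][c];
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 24; ++c)
          Bg[r][c] += (bvol_bar[c] - dil[c]) / 3.0;
    }
    // D*B with isotropic D (lambda, mu), engineering shear rows
    double DB[6][24];
    for (int c = 0; c < 24; ++c) {
      double tr = Bg[0][c] + Bg[1][c] + Bg[2][c];
      DB[0][c] = lambda * tr + 2.0 * mu * Bg[0][c];
      DB[1][c] = lambda * tr + 2.0 * mu * Bg[1][c];
      DB[2][c] = lambda * tr + 2.0 * mu * Bg[2][c];
      DB[3][c] = mu * Bg[3][c];
      DB[4][c] = mu * Bg[4][c];
      DB[5][c] = mu * Bg[5][c];
    }
    for (int r = 0; r < 24; ++r)
      for (int c = r; c < 24; ++c) {
        double s = 0.0;
        for (int q = 0; q < 6; ++q) s += Bg[q][r] * DB[q][c];
        Ke[r][c] += w * s;
      }
  }
  for (int r = 0; r < 24; ++r)
    for (int c = 0; c < r; ++c) Ke[r][c] = Ke[c][r];
  return true;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
NumericMatrix hex8_stiffness_cpp(NumericMatrix coords, double lambda,
                                 double mu, bool bbar) {
  if (coords.nrow() != 8 || coords.ncol() != 3)
    stop("coords must be 8x3");
  double cx[8], cy[8], cz[8];
  for (int a = 0; a < 8; ++a) {
    cx[a] = coords(a, 0); cy[a] = coords(a, 1); cz[a] = coords(a, 2);
  }
  double Ke[24][24];
  if (!hex8_ke(cx, cy, cz, lambda, mu, bbar, Ke))
    stop("element has non-positive Jacobian");
  NumericMatrix out(24, 24);
  for (int r = 0; r < 24; ++r)
    for (int c = 0; c < 24; ++c) out(r, c) = Ke[r][c];
  return out;
}

// Assemble lower-triangle triplets (global dof i >= j) of the stiffness
// matrix. elems is Mx8 1-based node indices; lambda/mu per element.
// [[Rcpp::export]]
List assemble_triplets_cpp(NumericMatrix nodes, IntegerMatrix elems,
                           NumericVector lambda, NumericVector mu,
                           bool bbar) {
  const int M = elems.nrow();
  if (elems.ncol() != 8) stop("elems must be Mx8");
  if (lambda.size() != M || mu.size() != M)
    stop("lambda/mu must have one value per element");
  const R_xlen_t per = 24 * 25 / 2; // 300 lower-tri entries per element
  IntegerVector I((R_xlen_t)M * per), Jv((R_xlen_t)M * per);
  NumericVector X((R_xlen_t)M * per);
  double cx[8], cy[8], cz[8], Ke[24][24];
  int gdof[24];
  R_xlen_t p = 0;
  for (int e = 0; e < M; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      cx[a] = nodes(n, 0); cy[a] = nodes(n, 1); cz[a] = nodes(n, 2);
      gdof[3 * a] = 3 * n; gdof[3 * a + 1] = 3 * n + 1; gdof[3 * a + 2] = 3 * n + 2;
    }
    if (!hex8_ke(cx, cy, cz, lambda[e], mu[e], bbar, Ke))
      stop("element %d has non-positive Jacobian", e + 1);
    for (int r = 0; r < 24; ++r)
      for (int c = 0; c <= r; ++c) {
        int gi = gdof[r], gj = gdof[c];
        if (gi >= gj) { I[p] = gi + 1; Jv[p] = gj + 1; }
        else          { I[p] = gj + 1; Jv[p] = gi + 1; }
        X[p] = Ke[r][c];
        ++p;
      }
  }
  return List::create(_["i"] = I, _["j"] = Jv, _["x"] = X);
}

// Reduce lower-triangle triplets to the free-free block and accumulate the
// Dirichlet right-hand side: rhs_f = -K_fc * u_c.
// map[dof] = 1-based free index, or 0 if constrained; uc = prescribed value
// per global dof (0 where free).
// [[Rcpp::export]]
List reduce_system_cpp(IntegerVector I, IntegerVector Jv, NumericVector X,
                       IntegerVector map, NumericVector uc) {
  const R_xlen_t nnz = X.size();
  const int ndof = map.size();
  int nfree = 0;
  for (int d = 0; d < ndof; ++d) if (map[d] > 0) ++nfree;
  NumericVector rhs(nfree);
  R_xlen_t keep = 0;
  for (R_xlen_t p = 0; p < nnz; ++p)
    if (map[I[p] - 1] > 0 && map[Jv[p] - 1] > 0) ++keep;
  IntegerVector Io(keep), Jo(keep);
  NumericVector Xo(keep);
  R_xlen_t q = 0;
  for (R_xlen_t p = 0; p < nnz; ++p) {
    int gi = I[p] - 1, gj = Jv[p] - 1;
    int mi = map[gi], mj = map[gj];
    double x = X[p];
    if (mi > 0 && mj > 0) {
      Io[q] = mi; Jo[q] = mj; Xo[q] = x; ++q;
    } else if (mi > 0 && mj == 0) {
      rhs[mi - 1] -= x * uc[gj];
    } else if (mi == 0 && mj > 0) {
      rhs[mj - 1] -= x * uc[gi];
    }
  }
  return List::create(_["i"] = Io, _["j"] = Jo, _["x"] = Xo,
                      _["rhs"] = rhs, _["nfree"] = nfree);
}

// f = K u from lower-triangle triplets (symmetric expansion)
// [[Rcpp::export]]
NumericVector triplet_symm_matvec_cpp(IntegerVector I, IntegerVector Jv,
                                      NumericVector X, NumericVector u,
                                      int ndof) {
  NumericVector f(ndof);
  const R_xlen_t nnz = X.size();
  for (R_xlen_t p = 0; p < nnz; ++p) {
    int gi = I[p] - 1, gj = Jv[p] - 1;
    double x = X[p];
    f[gi] += x * u[gj];
    if (gi != gj) f[gj] += x * u[gi];
  }
  return f;
}

// Centroid small-strain tensors: Mx6 (xx, yy, zz, xy, yz, zx), TENSOR shear.
// U is Nx3 nodal displacements.
// [[Rcpp::export]]
NumericMatrix centroid_strains_cpp(NumericMatrix nodes, IntegerMatrix elems,
                                   NumericMatrix U) {
  const int M = elems.nrow();
  NumericMatrix out(M, 6);
  double cx[8], cy[8], cz[8], ux[8], uy[8], uz[8];
  for (int e = 0; e < M; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      cx[a] = nodes(n, 0); cy[a] = nodes(n, 1); cz[a] = nodes(n, 2);
      ux[a] = U(n, 0); uy[a] = U(n, 1); uz[a] = U(n, 2);
    }
    double dNdx[8][3];
    double det = grad_phys(cx, cy, cz, 0.0, 0.0, 0.0, dNdx);
    if (det <= 0) stop("element %d has non-positive centroid Jacobian", e + 1);
    double g[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int a = 0; a < 8; ++a) {
      g[0][0] += ux[a] * dNdx[a][0]; g[0][1] += ux[a] * dNdx[a][1]; g[0][2] += ux[a] * dNdx[a][2];
      g[1][0] += uy[a] * dNdx[a][0]; g[1][1] += uy[a] * dNdx[a][1]; g[1][2] += uy[a] * dNdx[a][2];
      g[2][0] += uz[a] * dNdx[a][0]; g[2][1] += uz[a] * dNdx[a][1]; g[2][2] += uz[a] * dNdx[a][2];
    }
    out(e, 0) = g[0][0];
    out(e, 1) = g[1][1];
    out(e, 2) = g[2][2];
    out(e, 3) = 0.5 * (g[0][1] + g[1][0]);
    out(e, 4) = 0.5 * (g[1][2] + g[2][1]);
    out(e, 5) = 0.5 * (g[2][0] + g[0][2]);
  }
  return out;
}

// Element volumes by 2x2x2 quadrature.
// [[Rcpp::export]]
NumericVector element_volumes_cpp(NumericMatrix nodes, IntegerMatrix elems) {
  const int M = elems.nrow();
  NumericVector out(M);
  double cx[8], cy[8], cz[8];
  for (int e = 0; e < M; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      cx[a] = nodes(n, 0); cy[a] = nodes(n, 1); cz[a] = nodes(n, 2);
    }
    double v = 0.0;
    for (int k = 0; k < 2; ++k)
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i) {
          double dNdx[8][3];
          double det = grad_phys(cx, cy, cz, (2 * i - 1) * GP, (2 * j - 1) * GP,
                                 (2 * k - 1) * GP, dNdx);
          if (det <= 0) stop("element %d has non-positive Jacobian", e + 1);
          v += det;
        }
    out[e] = v;
  }
  return out;
}

// Minimum Jacobian determinant over the 2x2x2 quadrature points, per element.
// [[Rcpp::export]]
NumericVector min_jacobians_cpp(NumericMatrix nodes, IntegerMatrix elems) {
  const int M = elems.nrow();
  NumericVector out(M);
  double cx[8], cy[8], cz[8];
  for (int e = 0; e < M; ++e) {
    for (int a = 0; a < 8; ++a) {
      int n = elems(e, a) - 1;
      cx[a] = nodes(n, 0); cy[a] = nodes(n, 1); cz[a] = nodes(n, 2);
    }
    double mn = R_PosInf;
    for (int k = 0; k < 2; ++k)
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i) {
          double dNdx[8][3];
          double det = grad_phys(cx, cy, cz, (2 * i - 1) * GP, (2 * j - 1) * GP,
                                 (2 * k - 1) * GP, dNdx);
          if (det < mn) mn = det;
        }
    out[e] = mn;
  }
  return out;
}
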