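// Low-level element kernels for the mixed u-p poroelastic solver.
// Hex8 (trilinear) elements, 2x2x2 Gauss quadrature throughout.
// Quadrature points of element e occupy slots (e-1)*8 + q, q = 1..8.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GP = 0.5773502691896258;  // 1/sqrt(3)

// local node coordinates, VTK hex ordering (bottom CCW, then top)
static const double XI[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
static const double ET[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
static const double ZE[8] = {-1, -1, -1, -1, 1, 1, 1, 1};

static void shape_hex8(double xi, double et, double ze,
                       double *N, double *dN /* 8 x 3, col-major */) {
  for (int a = 0; a < 8; ++a) {
    const double sx = XI[a], sy = ET[a], sz = ZE[a];
    N[a] = 0.125 * (1 + sx * xi) * (1 + sy * et) * (1 + sz * ze);
    dN[a + 0]  = 0.125 * sx * (1 + sy * et) * (1 + sz * ze);
    dN[a + 8]  = 0.125 * sy * (1 + sx * xi) * (1 + sz * ze);
    dN[a + 16] = 0.125 * sz * (1 + sx * xi) * (1 + sy * et);
  }
}

// Gauss point local coordinates (q = 0..7, same tensor ordering as nodes)
static inline void gauss_pt(int q, double *xi, double *et, double *ze) {
  *xi = GP * XI[q]; *et = GP * ET[q]; *ze = GP * ZE[q];
}

// [[Rcpp::export]]
List fe_quadrature(const NumericMatrix &nodes, const IntegerMatrix &elems) {
  const int E = elems.nrow();
  const int EQ = E * 8;
  NumericVector dNdx(Dimension(8, 3, EQ));
  NumericVector wdet(EQ);
  NumericMatrix xq(3, EQ);
  NumericMatrix Nshape(8, 8);  // [a, q]
  double mindet = R_PosInf;

  double N[8], dN[24];
  for (int q = 0; q < 8; ++q) {
    double xi, et, ze;
    gauss_pt(q, &xi, &et, &ze);
    shape_hex8(xi, et, ze, N, dN);
    for (int a = 0; a < 8; ++a) Nshape(a, q) = N[a];
  }

  for (int e = 0; e < E; ++e) {
    double X[8][3];
    for (int a = 0; a < 8; ++a) {
      const int n = elems(e, a) - 1;
      X[a][0] = nodes(n, 0); X[a][1] = nodes(n, 1); X[a][2] = nodes(n, 2);
    }
    for (int q = 0; q < 8; ++q) {
      const int pt = e * 8 + q;
      double xi, et, ze;
      gauss_pt(q, &xi, &et, &ze);
      shape_hex8(xi, et, ze, N, dN);
      // J[i][j] = d x_j / d xi_i
      double J[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            J[i][j] += dN[a + 8 * i] * X[a][j];
      const double det =
          J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
          J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
          J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      if (det < mindet) mindet = det;
      double Ji[3][3];
      const double id = 1.0 / det;
      Ji[0][0] =  (J[1][1] * J[2][2] - J[1][2] * J[2][1]) * id;
      Ji[0][1] = -(J[0][1] * J[2][2] - J[0][2] * J[2][1]) * id;
      Ji[0][2] =  (J[0][1] * J[1][2] - J[0][2] * J[1][1]) * id;
      Ji[1][0] = -(J[1][0] * J[2][2] - J[1][2] * J[2][0]) * id;
      Ji[1][1] =  (J[0][0] * J[2][2] - J[0][2] * J[2][0]) * id;
      Ji[1][2] = -(J[0][0] * J[1][2] - J[0][2] * J[1][0]) * id;
      Ji[2][0] =  (J[1][0] * J[2][1] - J[1][1] * J[2][0]) * id;
      Ji[2][1] = -(J[0][0] * J[2][1] - J[0][1] * J[2][0]) * id;
      Ji[2][2] =  (J[0][0] * J[1][1] - J[0][1] * J[1][0]) * id;
      // dN/dx_i = sum_j Ji[j][i] dN/dxi_j   (since J[i][j] = dx_j/dxi_i)
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double v = 0;
          for (int j = 0; j < 3; ++j) v += Ji[i][j] * dN[a + 8 * j];
          dNdx[a + 8 * i + 24 * pt] = v;
        }
      wdet[pt] = det;  // all Gauss weights are 1
      double xw = 0, yw = 0, zw = 0;
      for (int a = 0; a < 8; ++a) {
        xw += N[a] * X[a][0]; yw += N[a] * X[a][1]; zw += N[a] * X[a][2];
      }
      xq(0, pt) = xw; xq(1, pt) = yw; xq(2, pt) = zw;
    }
  }
  return List::create(_["dNdx"] = dNdx, _["wdet"] = wdet, _["xq"] = xq,
                      _["Nshape"] = Nshape, _["min_detJ"] = mindet);
}

// displacement gradient g[i][j] = du_i/dx_j at every quadrature point
// [[Rcpp::export]]
NumericVector fe_gradu(const IntegerMatrix &elems, const NumericVector &dNdx,
                       const NumericVector &U) {
  const int E = elems.nrow();
  NumericVector g(Dimension(3, 3, E * 8));
  for (int e = 0; e < E; ++e) {
    double u[8][3];
    for (int a = 0; a < 8; ++a) {
      const int n = elems(e, a) - 1;
      u[a][0] = U[3 * n]; u[a][1] = U[3 * n + 1]; u[a][2] = U[3 * n + 2];
    }
    for (int q = 0; q < 8; ++q) {
      const int pt = e * 8 + q;
      double gg[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
      for (int a = 0; a < 8; ++a) {
        const double dx = dNdx[a + 24 * pt], dy = dNdx[a + 8 + 24 * pt],
                     dz = dNdx[a + 16 + 24 * pt];
        for (int i = 0; i < 3; ++i) {
          gg[i + 0] += u[a][i] * dx;
          gg[i + 3] += u[a][i] * dy;
          gg[i + 6] += u[a][i] * dz;
        }
      }
      for (int k = 0; k < 9; ++k) g[k + 9 * pt] = gg[k];
    }
  }
  return g;
}

// internal force from Cauchy stress (Voigt xx,yy,zz,xy,yz,xz), length-3N vector
// [[Rcpp::export]]
NumericVector fe_fint(const IntegerMatrix &elems, const NumericVector &dNdx,
                      const NumericVector &wdet, const NumericMatrix &sigma,
                      int nnode) {
  const int E = elems.nrow();
  NumericVector f(3 * nnode);
  for (int e = 0; e < E; ++e) {
    for (int q = 0; q < 8; ++q) {
      const int pt = e * 8 + q;
      const double w = wdet[pt];
      const double sxx = sigma(0, pt), syy = sigma(1, pt), szz = sigma(2, pt),
                   sxy = sigma(3, pt), syz = sigma(4, pt), sxz = sigma(5, pt);
      for (int a = 0; a < 8; ++a) {
        const double dx = dNdx[a + 24 * pt], dy = dNdx[a + 8 + 24 * pt],
                     dz = dNdx[a + 16 + 24 * pt];
        const int n = elems(e, a) - 1;
        f[3 * n]     += w * (sxx * dx + sxy * dy + sxz * dz);
        f[3 * n + 1] += w * (sxy * dx + syy * dy + syz * dz);
        f[3 * n + 2] += w * (sxz * dx + syz * dy + szz * dz);
      }
    }
  }
  return f;
}

// stiffness triplets for per-point 6x6 tangent D (Voigt, engineering shear)
// [[Rcpp::export]]
List fe_stiff_triplets(const IntegerMatrix &elems, const NumericVector &dNdx,
                       const NumericVector &wdet, const NumericVector &D) {
  const int E = elems.nrow();
  IntegerVector I(E * 576), Jv(E * 576);
  NumericVector X(E * 576);
  // row index (Voigt) layout of B for dof direction i: rows[i][k], grads[i][k]
  // dir x -> rows xx(0), xy(3), xz(5) with grads x,y,z
  // dir y -> rows yy(1), xy(3), yz(4) with grads y,x,z
  // dir z -> rows zz(2), yz(4), xz(5) with grads z,y,x
  static const int rows[3][3] = {{0, 3, 5}, {1, 3, 4}, {2, 4, 5}};
  static const int grds[3][3] = {{0, 1, 2}, {1, 0, 2}, {2, 1, 0}};
  std::size_t out = 0;
  for (int e = 0; e < E; ++e) {
    double Ke[24][24];
    for (int r = 0; r < 24; ++r)
      for (int c = 0; c < 24; ++c) Ke[r][c] = 0;
    for (int q = 0; q < 8; ++q) {
      const int pt = e * 8 + q;
      const double w = wdet[pt];
      const double *Dp = &D[36 * pt];  // column-major 6x6
      double g[8][3];
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) g[a][i] = dNdx[a + 8 * i + 24 * pt];
      // Bc[I][dof] sparse: build dense 6x24 then BtDB
      double B[6][24];
      for (int r = 0; r < 6; ++r)
        for (int c = 0; c < 24; ++c) B[r][c] = 0;
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          const int dof = 3 * a + i;
          for (int k = 0; k < 3; ++k) B[rows[i][k]][dof] += g[a][grds[i][k]];
        }
      double T[6][24];
      for (int r = 0; r < 6; ++r)
        for (int c = 0; c < 24; ++c) {
          double v = 0;
          for (int s = 0; s < 6; ++s) v += Dp[r + 6 * s] * B[s][c];
          T[r][c] = v;
        }
      for (int r = 0; r < 24; ++r)
        for (int c = 0; c < 24; ++c) {
          double v = 0;
          for (int s = 0; s < 6; ++s) v += B[s][r] * T[s][c];
          Ke[r][c] += w * v;
        }
    }
    int dof[24];
    for (int a = 0; a < 8; ++a) {
      const int n = elems(e, a) - 1;
      dof[3 * a] = 3 * n + 1; dof[3 * a + 1] = 3 * n + 2; dof[3 * a + 2] = 3 * n + 3;
    }
    for (int r = 0; r < 24; ++r)
      for (int c = 0; c < 24; ++c) {
        I[out] = dof[r]; Jv[out] = dof[c]; X[out] = Ke[r][c]; ++out;
      }
  }
  return List::create(_["i"] = I, _["j"] = Jv, _["x"] = X);
}

// coupling Q (u-dof rows, pressure-node cols), permeability H, and
// pressure-projection stabilization S triplets.
// kperm, alpha are per-element. Q_{(a,i),b} = int dNa/dx_i Nb dV
// H_{ab} = int k grad Na . grad Nb dV
// S_e = alpha * (Me - ve ve^T / V), Me = int Na Nb dV, ve = int Na dV
// [[Rcpp::export]]
List fe_qhs_triplets(const IntegerMatrix &elems, const NumericVector &dNdx,
                     const NumericVector &wdet, const NumericMatrix &Nshape,
                     const NumericVector &kperm, const NumericVector &alpha) {
  const int E = elems.nrow();
  IntegerVector Qi(E * 192), Qj(E * 192);
  NumericVector Qx(E * 192);
  IntegerVector Hi(E * 64), Hj(E * 64);
  NumericVector Hx(E * 64), Sx(E * 64);
  std::size_t oq = 0, oh = 0;
  for (int e = 0; e < E; ++e) {
    double Qe[24][8], He[8][8], Me[8][8], ve[8], V = 0;
    for (int r = 0; r < 24; ++r)
      for (int c = 0; c < 8; ++c) Qe[r][c] = 0;
    for (int r = 0; r < 8; ++r) {
      ve[r] = 0;
      for (int c = 0; c < 8; ++c) { He[r][c] = 0; Me[r][c] = 0; }
    }
    for (int q = 0; q < 8; ++q) {
      const int pt = e * 8 + q;
      const double w = wdet[pt];
      for (int a = 0; a < 8; ++a) {
        const double Na = Nshape(a, q);
        ve[a] += w * Na;
        for (int i = 0; i < 3; ++i) {
          const double da = dNdx[a + 8 * i + 24 * pt];
          for (int b = 0; b < 8; ++b) Qe[3 * a + i][b] += w * da * Nshape(b, q);
        }
        for (int b = 0; b < 8; ++b) {
          double gg = 0;
          for (int i = 0; i < 3; ++i)
            gg += dNdx[a + 8 * i + 24 * pt] * dNdx[b + 8 * i + 24 * pt];
          He[a][b] += w * kperm[e] * gg;
          Me[a][b] += w * Na * Nshape(b, q);
        }
      }
      V += w;
    }
    int nd[8];
    for (int a = 0; a < 8; ++a) nd[a] = elems(e, a);
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        for (int b = 0; b < 8; ++b) {
          Qi[oq] = 3 * (nd[a] - 1) + i + 1; Qj[oq] = nd[b];
          Qx[oq] = Qe[3 * a + i][b]; ++oq;
        }
    for (int a = 0; a < 8; ++a)
      for (int b = 0; b < 8; ++b) {
        Hi[oh] = nd[a]; Hj[oh] = nd[b];
        Hx[oh] = He[a][b];
        Sx[oh] = alpha[e] * (Me[a][b] - ve[a] * ve[b] / V);
        ++oh;
      }
  }
  return List::create(_["qi"] = Qi, _["qj"] = Qj, _["qx"] = Qx,
                      _["hi"] = Hi, _["hj"] = Hj, _["hx"] = Hx,
                      _["sx"] = Sx);
}

// interpolate nodal scalar fields to quadrature points: vals is N x m
// [[Rcpp::export]]
NumericMatrix fe_interp_qp(const IntegerMatrix &elems, const NumericMatrix &Nshape,
                           const NumericMatrix &vals) {
  const int E = elems.nrow(), m = vals.ncol();
  NumericMatrix out(E * 8, m);
  for (int e = 0; e < E; ++e)
    for (int q = 0; q < 8; ++q) {
      const int pt = e * 8 + q;
      for (int c = 0; c < m; ++c) {
        double v = 0;
        for (int a = 0; a < 8; ++a) v += Nshape(a, q) * vals(elems(e, a) - 1, c);
        out(pt, c) = v;
      }
    }
  return out;
}

// volume-weighted scatter of per-point scalars to nodes (returns sums and weights)
// [[Rcpp::export]]
List fe_qp_to_nodes(const IntegerMatrix &elems, const NumericMatrix &Nshape,
                    const NumericVector &wdet, const NumericMatrix &vals,
                    int nnode) {
  const int E = elems.nrow(), m = vals.ncol();
  NumericMatrix acc(nnode, m);
  NumericVector wt(nnode);
  for (int e = 0; e < E; ++e)
    for (int q = 0; q < 8; ++q) {
      const int pt = e * 8 + q;
      for (int a = 0; a < 8; ++a) {
        const int n = elems(e, a) - 1;
        const double w = Nshape(a, q) * wdet[pt];
        wt[n] += w;
        for (int c = 0; c < m; ++c) acc(n, c) += w * vals(pt, c);
      }
    }
  return List::create(_["acc"] = acc, _["wt"] = wt);
}
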