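// Finite-element core: transversely isotropic Veronda-Westmann material,
// trilinear hexahedra with mean-dilatation volumetric treatment, follower
// pressure facets, and global assembly.  Units: um, MPa, uN.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

typedef arma::mat::fixed<3, 3> mat33;
typedef arma::vec::fixed<3> vec3;
typedef arma::mat::fixed<8, 3> mat83;

struct MatPar { double C1, C2, C5, K; };

// 2x2x2 Gauss points on [-1,1]^3 and trilinear shape gradients
static const double GP = 0.5773502691896257645091488;
static double gp_xi[8][3];
static mat83 dNdxi_tab[8];
static bool tables_ready = false;

static void init_tables() {
  if (tables_ready) return;
  static const int sg[8][3] = {{-1,-1,-1},{1,-1,-1},{1,1,-1},{-1,1,-1},
                               {-1,-1,1},{1,-1,1},{1,1,1},{-1,1,1}};
  int g = 0;
  for (int c = 0; c < 8; ++c) {
    gp_xi[g][0] = sg[c][0] * GP; gp_xi[g][1] = sg[c][1] * GP; gp_xi[g][2] = sg[c][2] * GP;
    ++g;
  }
  for (int q = 0; q < 8; ++q) {
    double xi = gp_xi[q][0], eta = gp_xi[q][1], ze = gp_xi[q][2];
    for (int a = 0; a < 8; ++a) {
      double sx = sg[a][0], sy = sg[a][1], sz = sg[a][2];
      dNdxi_tab[q](a, 0) = 0.125 * sx * (1 + sy * eta) * (1 + sz * ze);
      dNdxi_tab[q](a, 1) = 0.125 * sy * (1 + sx * xi) * (1 + sz * ze);
      dNdxi_tab[q](a, 2) = 0.125 * sz * (1 + sx * xi) * (1 + sy * eta);
    }
  }
  tables_ready = true;
}

// isochoric (matrix + fiber) energy and deviatoric Cauchy stress; the
// volumetric pressure is added at element level from the mean dilatation
static inline void vw_iso(const mat33 &F, double J, const vec3 &a0,
                          const MatPar &mp, double &W, mat33 &sig, bool wantS) {
  double Jm23 = std::pow(J, -2.0 / 3.0);
  mat33 B = F * F.t();
  mat33 Bb = Jm23 * B;
  double I1 = arma::trace(Bb);
  mat33 Bb2 = Bb * Bb;
  double I2 = 0.5 * (I1 * I1 - arma::trace(Bb2));
  double ex = std::exp(mp.C2 * (I1 - 3.0));
  W = mp.C1 * (ex - 1.0) - 0.5 * mp.C1 * mp.C2 * (I2 - 3.0);

  vec3 w = F * a0;
  double lam2 = arma::dot(w, w);
  double lb = std::cbrt(1.0 / J) * std::sqrt(lam2);
  if (lb > 1.0) W += 0.5 * mp.C5 * (lb - 1.0) * (lb - 1.0);

  if (!wantS) return;
  double W1 = mp.C1 * mp.C2 * ex;
  double W2 = -0.5 * mp.C1 * mp.C2;
  mat33 S = (W1 + I1 * W2) * Bb - W2 * Bb2;
  sig = (2.0 / J) * S;
  double tr3 = arma::trace(sig) / 3.0;
  sig.diag() -= tr3;
  if (mp.C5 > 0.0 && lb > 1.0) {
    double cf = (lb / J) * (mp.C5 * (lb - 1.0));
    sig += (cf / lam2) * (w * w.t());
    sig.diag() -= cf / 3.0;
  }
}

// element internal force (8x3) and energy with mean-dilatation volumetric term
static void element_force(const mat83 &Xe, const mat83 &Ue, const vec3 &a0,
                          const MatPar &mp, const mat83 dNdX[8],
                          const double wgp[8], mat83 &fe, double &energy) {
  mat33 Fs[8];
  double Js[8], Vel = 0.0, Jbar = 0.0;
  for (int q = 0; q < 8; ++q) {
    // F_{mn} = delta_{mn} + sum_a U(a,m) dNdX(a,n)
    Fs[q] = arma::eye<arma::mat>(3, 3);
    Fs[q] += Ue.t() * dNdX[q];
    double J = arma::det(Fs[q]);
    if (!(J > 0.0)) throw std::runtime_error("element inversion: det(F) <= 0");
    Js[q] = J;
    Vel += wgp[q];
    Jbar += wgp[q] * J;
  }
  Jbar /= Vel;
  double lnJb = std::log(Jbar);
  double Up = mp.K * lnJb / Jbar;               // U'(Jbar)
  fe.zeros();
  energy = Vel * 0.5 * mp.K * lnJb * lnJb;
  for (int q = 0; q < 8; ++q) {
    double W;
    mat33 sig;
    vw_iso(Fs[q], Js[q], a0, mp, W, sig, true);
    sig.diag() += Up;
    mat33 P = (Js[q] * sig) * arma::inv(Fs[q]).t();
    fe += wgp[q] * (dNdX[q] * P.t());
    energy += wgp[q] * W;
  }
}

static void precompute_grad(const mat83 &Xe, mat83 dNdX[8], double wgp[8]) {
  for (int q = 0; q < 8; ++q) {
    mat33 J0 = Xe.t() * dNdxi_tab[q];        // d x / d xi
    double dj = arma::det(J0);
    if (!(dj > 0.0)) throw std::runtime_error("non-positive reference Jacobian");
    dNdX[q] = dNdxi_tab[q] * arma::inv(J0);   // dN/dx = dN/dxi * (dx/dxi)^-1
    wgp[q] = dj;                              // unit gauss weights
  }
}

// [[Rcpp::export]]
NumericVector hex_jacobians(NumericMatrix nodes, IntegerMatrix hexes) {
  init_tables();
  int ne = hexes.nrow();
  NumericVector out(ne);
  for (int e = 0; e < ne; ++e) {
    mat83 Xe;
    for (int a = 0; a < 8; ++a)
      for (int d = 0; d < 3; ++d) Xe(a, d) = nodes(hexes(e, a) - 1, d);
    double mn = arma::datum::inf;
    for (int q = 0; q < 8; ++q) {
      mat33 J0 = Xe.t() * dNdxi_tab[q];
      mn = std::min(mn, arma::det(J0));
    }
    out[e] = mn;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector hex_volumes(NumericMatrix nodes, IntegerMatrix hexes) {
  init_tables();
  int ne = hexes.nrow();
  NumericVector out(ne);
  for (int e = 0; e < ne; ++e) {
    mat83 Xe;
    for (int a = 0; a < 8; ++a)
      for (int d = 0; d < 3; ++d) Xe(a, d) = nodes(hexes(e, a) - 1, d);
    double V = 0.0;
    for (int q = 0; q < 8; ++q) V += arma::det(Xe.t() * dNdxi_tab[q]);
    out[e] = V;
  }
  return out;
}

// signed enclosed volume of a facet surface (quads 2x2 Gauss, flat triangles)
// [[Rcpp::export]]
double surface_volume(NumericMatrix nodes, Nullable<IntegerMatrix> quads,
                      Nullable<IntegerMatrix> tris) {
  double V = 0.0;
  if (quads.isNotNull()) {
    IntegerMatrix Q(quads);
    for (int f = 0; f < Q.nrow(); ++f) {
      vec3 x[4];
      for (int a = 0; a < 4; ++a)
        for (int d = 0; d < 3; ++d) x[a](d) = nodes(Q(f, a) - 1, d);
      for (int gx = -1; gx <= 1; gx += 2) for (int gy = -1; gy <= 1; gy += 2) {
        double xi = gx * GP, eta = gy * GP;
        double N[4] = {0.25 * (1 - xi) * (1 - eta), 0.25 * (1 + xi) * (1 - eta),
                       0.25 * (1 + xi) * (1 + eta), 0.25 * (1 - xi) * (1 + eta)};
        double dNxi[4] = {-0.25 * (1 - eta), 0.25 * (1 - eta),
                          0.25 * (1 + eta), -0.25 * (1 + eta)};
        double dNeta[4] = {-0.25 * (1 - xi), -0.25 * (1 + xi),
                           0.25 * (1 + xi), 0.25 * (1 - xi)};
        vec3 xg = arma::zeros(3), xx = arma::zeros(3), xe = arma::zeros(3);
        for (int a = 0; a < 4; ++a) {
          xg += N[a] * x[a]; xx += dNxi[a] * x[a]; xe += dNeta[a] * x[a];
        }
        V += arma::dot(xg, arma::cross(xx, xe)) / 3.0;
      }
    }
  }
  if (tris.isNotNull()) {
    IntegerMatrix T(tris);
    for (int f = 0; f < T.nrow(); ++f) {
      vec3 x[3];
      for (int a = 0; a < 3; ++a)
        for (int d = 0; d < 3; ++d) x[a](d) = nodes(T(f, a) - 1, d);
      V += arma::dot(x[0], arma::cross(x[1], x[2])) / 6.0;
    }
  }
  return V;
}

// follower-pressure nodal forces on one quad facet (deformed coords xc, 4x3)
static void quad_force(const double xc[4][3], double P, double f[12]) {
  for (int i = 0; i < 12; ++i) f[i] = 0.0;
  for (int gx = -1; gx <= 1; gx += 2) for (int gy = -1; gy <= 1; gy += 2) {
    double xi = gx * GP, eta = gy * GP;
    double N[4] = {0.25 * (1 - xi) * (1 - eta), 0.25 * (1 + xi) * (1 - eta),
                   0.25 * (1 + xi) * (1 + eta), 0.25 * (1 - xi) * (1 + eta)};
    double dNxi[4] = {-0.25 * (1 - eta), 0.25 * (1 - eta),
                      0.25 * (1 + eta), -0.25 * (1 + eta)};
    double dNeta[4] = {-0.25 * (1 - xi), -0.25 * (1 + xi),
                       0.25 * (1 + xi), 0.25 * (1 - xi)};
    double tx[3] = {0, 0, 0}, te[3] = {0, 0, 0};
    for (int a = 0; a < 4; ++a) for (int d = 0; d < 3; ++d) {
      tx[d] += dNxi[a] * xc[a][d];
      te[d] += dNeta[a] * xc[a][d];
    }
    double n[3] = {tx[1] * te[2] - tx[2] * te[1],
                   tx[2] * te[0] - tx[0] * te[2],
                   tx[0] * te[1] - tx[1] * te[0]};
    for (int a = 0; a < 4; ++a) for (int d = 0; d < 3; ++d)
      f[3 * a + d] += P * N[a] * n[d];
  }
}

static void tri_force(const double xc[3][3], double P, double f[9]) {
  double e1[3], e2[3];
  for (int d = 0; d < 3; ++d) { e1[d] = xc[1][d] - xc[0][d]; e2[d] = xc[2][d] - xc[0][d]; }
  double n[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                 e1[2] * e2[0] - e1[0] * e2[2],
                 e1[0] * e2[1] - e1[1] * e2[0]};
  for (int a = 0; a < 3; ++a) for (int d = 0; d < 3; ++d)
    f[3 * a + d] = P * n[d] / 6.0;
}

// Global assembly.  Returns internal/external force vectors (length 3*n),
// internal strain energy, enclosed volumes, per-element mean dilatation, and
// (optionally) tangent triplets for K = d(f_int - f_ext)/dU by central
// differences at element/facet level.
// [[Rcpp::export]]
List fe_assemble(NumericMatrix nodes, IntegerMatrix hexes, NumericMatrix fibers,
                 NumericVector matpar, NumericMatrix U,
                 Nullable<IntegerMatrix> quads, Nullable<IntegerMatrix> tris,
                 double P, bool want_tangent) {
  init_tables();
  MatPar mp = {matpar[0], matpar[1], matpar[2], matpar[3]};
  int nn = nodes.nrow(), ne = hexes.nrow();
  int ndof = 3 * nn;
  NumericVector fint(ndof), fext(ndof);
  double energy = 0.0;
  const double h = 1e-6;

  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    ti.reserve((size_t)ne * 576 + 4096);
    tj.reserve((size_t)ne * 576 + 4096);
    tx.reserve((size_t)ne * 576 + 4096);
  }

  mat83 dNdX[8];
  double wgp[8];
  for (int e = 0; e < ne; ++e) {
    mat83 Xe, Ue;
    int ids[8];
    for (int a = 0; a < 8; ++a) {
      ids[a] = hexes(e, a) - 1;
      for (int d = 0; d < 3; ++d) {
        Xe(a, d) = nodes(ids[a], d);
        Ue(a, d) = U(ids[a], d);
      }
    }
    vec3 a0;
    for (int d = 0; d < 3; ++d) a0(d) = fibers(e, d);
    try {
      precompute_grad(Xe, dNdX, wgp);
      mat83 fe;
      double We;
      element_force(Xe, Ue, a0, mp, dNdX, wgp, fe, We);
      energy += We;
      for (int a = 0; a < 8; ++a) for (int d = 0; d < 3; ++d)
        fint[3 * ids[a] + d] += fe(a, d);
      if (want_tangent) {
        double Ke[24][24];
        mat83 Up = Ue, Um = Ue, fp, fm;
        double dummy;
        for (int c = 0; c < 24; ++c) {
          int ca = c / 3, cd = c % 3;
          Up(ca, cd) += h; Um(ca, cd) -= h;
          element_force(Xe, Up, a0, mp, dNdX, wgp, fp, dummy);
          element_force(Xe, Um, a0, mp, dNdX, wgp, fm, dummy);
          for (int r = 0; r < 24; ++r)
            Ke[r][c] = (fp(r / 3, r % 3) - fm(r / 3, r % 3)) / (2 * h);
          Up(ca, cd) = Ue(ca, cd); Um(ca, cd) = Ue(ca, cd);
        }
        for (int r = 0; r < 24; ++r) for (int c = 0; c < 24; ++c) {
          ti.push_back(3 * ids[r / 3] + r % 3 + 1);
          tj.push_back(3 * ids[c / 3] + c % 3 + 1);
          tx.push_back(Ke[r][c]);
        }
      }
    } catch (std::exception &ex) {
      stop("element %d: %s", e + 1, ex.what());
    }
  }

  // follower pressure on facets (deformed configuration)
  if (P != 0.0 && quads.isNotNull()) {
    IntegerMatrix Q(quads);
    for (int f = 0; f < Q.nrow(); ++f) {
      int ids[4];
      double xc[4][3];
      for (int a = 0; a < 4; ++a) {
        ids[a] = Q(f, a) - 1;
        for (int d = 0; d < 3; ++d) xc[a][d] = nodes(ids[a], d) + U(ids[a], d);
      }
      double fq[12];
      quad_force(xc, P, fq);
      for (int a = 0; a < 4; ++a) for (int d = 0; d < 3; ++d)
        fext[3 * ids[a] + d] += fq[3 * a + d];
      if (want_tangent) {
        double fp[12], fm[12];
        for (int c = 0; c < 12; ++c) {
          int ca = c / 3, cd = c % 3;
          xc[ca][cd] += h; quad_force(xc, P, fp);
          xc[ca][cd] -= 2 * h; quad_force(xc, P, fm);
          xc[ca][cd] += h;
          for (int r = 0; r < 12; ++r) {
            double kv = -(fp[r] - fm[r]) / (2 * h);   // K = -d f_ext / dU
            if (kv != 0.0) {
              ti.push_back(3 * ids[r / 3] + r % 3 + 1);
              tj.push_back(3 * ids[c / 3] + c % 3 + 1);
              tx.push_back(kv);
            }
          }
        }
      }
    }
  }
  if (P != 0.0 && tris.isNotNull()) {
    IntegerMatrix T(tris);
    for (int f = 0; f < T.nrow(); ++f) {
      int ids[3];
      double xc[3][3];
      for (int a = 0; a < 3; ++a) {
        ids[a] = T(f, a) - 1;
        for (int d = 0; d < 3; ++d) xc[a][d] = nodes(ids[a], d) + U(ids[a], d);
      }
      double ft[9];
      tri_force(xc, P, ft);
      for (int a = 0; a < 3; ++a) for (int d = 0; d < 3; ++d)
        fext[3 * ids[a] + d] += ft[3 * a + d];
      if (want_tangent) {
        double fp[9], fm[9];
        for (int c = 0; c < 9; ++c) {
          int ca = c / 3, cd = c % 3;
          xc[ca][cd] += h; tri_force(xc, P, fp);
          xc[ca][cd] -= 2 * h; tri_force(xc, P, fm);
          xc[ca][cd] += h;
          for (int r = 0; r < 9; ++r) {
            double kv = -(fp[r] - fm[r]) / (2 * h);
            if (kv != 0.0) {
              ti.push_back(3 * ids[r / 3] + r % 3 + 1);
              tj.push_back(3 * ids[c / 3] + c % 3 + 1);
              tx.push_back(kv);
            }
          }
        }
      }
    }
  }

  List out = List::create(_["f_int"] = fint, _["f_ext"] = fext,
                          _["energy"] = energy);
  if (want_tangent) {
    out["Ki"] = wrap(ti);
    out["Kj"] = wrap(tj);
    out["Kx"] = wrap(tx);
  }
  return out;
}

// per-element averaged fields at a solution state
// [[Rcpp::export]]
List fe_fields(NumericMatrix nodes, IntegerMatrix hexes, NumericMatrix fibers,
               NumericVector matpar, NumericMatrix U) {
  init_tables();
  MatPar mp = {matpar[0], matpar[1], matpar[2], matpar[3]};
  int ne = hexes.nrow();
  NumericMatrix sig(ne, 6), egl(ne, 6);
  NumericVector Jbar(ne), Jmin(ne), Jmax(ne);
  mat83 dNdX[8];
  double wgp[8];
  for (int e = 0; e < ne; ++e) {
    mat83 Xe, Ue;
    for (int a = 0; a < 8; ++a) {
      int id = hexes(e, a) - 1;
      for (int d = 0; d < 3; ++d) { Xe(a, d) = nodes(id, d); Ue(a, d) = U(id, d); }
    }
    vec3 a0;
    for (int d = 0; d < 3; ++d) a0(d) = fibers(e, d);
    precompute_grad(Xe, dNdX, wgp);
    mat33 Fs[8];
    double Js[8], Vel = 0.0, Jb = 0.0, jmn = arma::datum::inf, jmx = 0.0;
    for (int q = 0; q < 8; ++q) {
      Fs[q] = arma::eye<arma::mat>(3, 3);
      Fs[q] += Ue.t() * dNdX[q];
      Js[q] = arma::det(Fs[q]);
      Vel += wgp[q]; Jb += wgp[q] * Js[q];
      jmn = std::min(jmn, Js[q]); jmx = std::max(jmx, Js[q]);
    }
    Jb /= Vel;
    double Up = mp.K * std::log(Jb) / Jb;
    mat33 sAvg = arma::zeros(3, 3), eAvg = arma::zeros(3, 3);
    for (int q = 0; q < 8; ++q) {
      double W;
      mat33 s;
      vw_iso(Fs[q], Js[q], a0, mp, W, s, true);
      s.diag() += Up;                            // volumetric pressure
      mat33 E = 0.5 * (Fs[q].t() * Fs[q] - arma::eye<arma::mat>(3, 3));
      sAvg += (wgp[q] / Vel) * s;
      eAvg += (wgp[q] / Vel) * E;
    }
    sAvg = 0.5 * (sAvg + sAvg.t());
    int m1[6] = {0, 1, 2, 0, 1, 0}, m2[6] = {0, 1, 2, 1, 2, 2};
    for (int c = 0; c < 6; ++c) {
      sig(e, c) = sAvg(m1[c], m2[c]);
      egl(e, c) = eAvg(m1[c], m2[c]);
    }
    Jbar[e] = Jb; Jmin[e] = jmn; Jmax[e] = jmx;
  }
  return List::create(_["sigma"] = sig, _["E_GL"] = egl, _["J_bar"] = Jbar,
                      _["J_min"] = Jmin, _["J_max"] = Jmax);
}
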