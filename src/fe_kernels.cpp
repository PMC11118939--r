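// Element kernels for the total-Lagrangian segment solver.
// Units: N - mm - MPa. All connectivity passed 0-based from R.
//
// Global dof layout (0-based): node i translations at 3*i + {0,1,2};
// rotation triplets (bending-shell nodes only) appended after 3*n, their
// base index per node supplied by R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double GP = 0.5773502691896258;  // 1/sqrt(3)

// ---------------------------------------------------------------------------
// Hexahedral solids: 8-node trilinear, total Lagrangian (Green-Lagrange).
// mat_type 0: orthotropic St.Venant-Kirchhoff, full 2x2x2 integration
//          1: isotropic StVK, selective reduced integration of the bulk
//             (volumetric) term (params: K, mu, beta_stab)
//          2: Neo-Hookean, SRI of the volumetric (J-1)^2/D term
//             (params: C10, D, beta_stab)
//
// SRI types carry a volumetric hourglass stabilization: the single-point
// bulk rule leaves non-uniform dilatation modes restrained only by the shear
// modulus, which for nearly incompressible soft tissue (K/mu >> 1) admits
// spurious low-energy modes. W_stab = beta K / 2 sum_g w_g (trE_g - trE_c)^2
// vanishes for uniform dilatation and for isochoric deformation, so neither
// the patch test nor locking relief is affected.
// ---------------------------------------------------------------------------

template <typename MAT>
static void hex_shape_deriv(double xi, double eta, double ze, MAT &dN) {
  // dN: 8 x 3 in parent coords
  const double s[8][3] = {{-1,-1,-1},{1,-1,-1},{1,1,-1},{-1,1,-1},
                          {-1,-1,1},{1,-1,1},{1,1,1},{-1,1,1}};
  for (int a = 0; a < 8; ++a) {
    double px = s[a][0], py = s[a][1], pz = s[a][2];
    dN(a,0) = 0.125 * px * (1+py*eta) * (1+pz*ze);
    dN(a,1) = 0.125 * py * (1+px*xi) * (1+pz*ze);
    dN(a,2) = 0.125 * pz * (1+px*xi) * (1+py*eta);
  }
}

// Voigt: (11,22,33,12,23,13) with engineering shear strain.
typedef vec::fixed<6> vec6;
typedef mat::fixed<6,24> mat624;
typedef mat::fixed<8,3> mat83;

static void gl_strain_voigt(const mat33 &F, vec6 &Ev) {
  mat33 E = 0.5 * (F.t() * F - eye(3,3));
  Ev = {E(0,0), E(1,1), E(2,2), 2*E(0,1), 2*E(1,2), 2*E(0,2)};
}

static void voigt_to_mat(const vec6 &Sv, mat33 &S) {
  S(0,0)=Sv(0); S(1,1)=Sv(1); S(2,2)=Sv(2);
  S(0,1)=S(1,0)=Sv(3); S(1,2)=S(2,1)=Sv(4); S(0,2)=S(2,0)=Sv(5);
}

// B_nl (6 x 24): delta E_voigt = B * delta u
static void build_B(const mat83 &dNdX, const mat33 &F, mat624 &B) {
  B.zeros();
  for (int a = 0; a < 8; ++a) {
    double g0 = dNdX(a,0), g1 = dNdX(a,1), g2 = dNdX(a,2);
    for (int k = 0; k < 3; ++k) {
      int c = 3*a + k;
      B(0,c) = F(k,0)*g0;
      B(1,c) = F(k,1)*g1;
      B(2,c) = F(k,2)*g2;
      B(3,c) = F(k,0)*g1 + F(k,1)*g0;
      B(4,c) = F(k,1)*g2 + F(k,2)*g1;
      B(5,c) = F(k,0)*g2 + F(k,2)*g0;
    }
  }
}

// Cauchy von Mises from 2nd PK (Voigt) at deformation F.
static double vm_cauchy(const mat33 &F, const vec &Sv) {
  mat33 S;
  voigt_to_mat(Sv, S);
  double J = det(F);
  mat33 sig = (F * S * F.t()) / J;
  double m = (sig(0,0)+sig(1,1)+sig(2,2))/3.0;
  mat33 dev = sig - m*eye(3,3);
  return std::sqrt(1.5 * accu(dev % dev));
}

// [[Rcpp::export]]
Rcpp::List hex_asm_cpp(const arma::mat &X, const arma::imat &conn,
                       const arma::ivec &mat_type, const arma::mat &params,
                       const arma::vec &u, bool want_kg, bool want_energy,
                       bool clamp_geo = false) {
  // clamp_geo: for the SRI soft-tissue types (1, 2), keep only the tensile
  // principal part of the stress in the geometric stiffness. Soft solids
  // near p ~ mu destabilize the iteration matrix long before the structure
  // fails; the internal force (hence every converged equilibrium) is exact
  // either way, so this only stabilizes the Newton path. Buckling analyses
  // request the full operator.
  const int m = conn.n_rows;
  const int ntrans = 3 * X.n_rows;
  vec Km_val(576 * (size_t)m, fill::zeros);
  vec Kg_val(want_kg ? 576 * (size_t)m : 0, fill::zeros);
  vec fint(ntrans, fill::zeros);
  vec vm(m, fill::zeros), vol(m, fill::zeros);
  double energy = 0.0, min_detJ = datum::inf, min_detF = datum::inf;

  mat83 dN, dNdX;
  mat624 B;
  mat33 Jm, Jinv, F;

  for (int e = 0; e < m; ++e) {
    mat Xe(8,3), Ue(8,3);
    for (int a = 0; a < 8; ++a) {
      int n = conn(e,a);
      for (int d = 0; d < 3; ++d) {
        Xe(a,d) = X(n,d);
        Ue(a,d) = u(3*n + d);
      }
    }
    int type = mat_type(e);
    mat66 Cel;
    double Kb = 0, mu = 0, C10 = 0, Dnh = 0, beta = 0, Kstab = 0;
    if (type == 0) {
      Cel = reshape(params.row(e).cols(0,35).t(), 6, 6);
    } else if (type == 1) {
      Kb = params(e,0); mu = params(e,1); beta = params(e,2);
      Kstab = std::min(beta * Kb, 50.0 * mu);
    } else {
      C10 = params(e,0); Dnh = params(e,1); beta = params(e,2);
      Kstab = std::min(beta * 2.0 / Dnh, 50.0 * 2.0 * C10);
    }

    mat Ke(24,24,fill::zeros), Kg(24,24,fill::zeros);
    vec fe(24, fill::zeros);
    double Ve = 0.0, We = 0.0, vme = 0.0;
    // centroid dilatation and its derivatives, for the stabilization
    double trE_c = 0.0;
    vec bvec_c(24, fill::zeros);
    mat Gc(8, 8, fill::zeros);

    // volumetric/SRI point data (centroid)
    auto gp_contrib = [&](double xi, double eta, double ze, double wq,
                          int mode /*0 full/dev part, 1 SRI vol part*/) {
      hex_shape_deriv(xi, eta, ze, dN);
      Jm = Xe.t() * dN;               // 3x3: dx/dxi
      double dJ = det(Jm);
      if (dJ < min_detJ) min_detJ = dJ;
      Jinv = inv(Jm);
      dNdX = dN * Jinv;               // 8x3
      F = eye(3,3) + (Ue.t() * dNdX); // 3x3
      double dF = det(F);
      if (dF < min_detF) min_detF = dF;
      mat33 C = F.t() * F;
      vec6 Ev; gl_strain_voigt(F, Ev);
      build_B(dNdX, F, B);
      double w = wq * dJ;
      if (mode == 0) Ve += w;

      vec6 Sv; Sv.zeros();
      mat66 Ct; Ct.zeros();
      double Wgp = 0.0;
      if (type == 0) {
        Sv = Cel * Ev;
        Ct = Cel;
        Wgp = 0.5 * dot(Ev, Sv);
      } else if (type == 1) {
        double trE = Ev(0)+Ev(1)+Ev(2);
        if (mode == 0) {   // deviatoric part: mu * dev(E):dev(E) at 8 gp
          vec Ct_diag = {2*mu, 2*mu, 2*mu, mu, mu, mu};
          Ct = diagmat(Ct_diag);
          for (int a=0;a<3;++a) for (int b=0;b<3;++b) Ct(a,b) -= (2.0*mu/3.0);
          Sv = Ct * Ev;
          double devEE = (Ev(0)*Ev(0)+Ev(1)*Ev(1)+Ev(2)*Ev(2)
                          + 0.5*(Ev(3)*Ev(3)+Ev(4)*Ev(4)+Ev(5)*Ev(5)))
                         - trE*trE/3.0;
          Wgp = mu * devEE;
        } else {           // bulk K (trE)^2 / 2 at centroid
          Sv.zeros(); Sv(0)=Sv(1)=Sv(2)=Kb*trE;
          Ct.zeros();
          for (int a=0;a<3;++a) for (int b=0;b<3;++b) Ct(a,b)=Kb;
          Wgp = 0.5 * Kb * trE * trE;
        }
      } else {  // Neo-Hookean (analytic convected tangents)
        double J2 = std::max(det(C), 1e-12);
        double J = std::sqrt(J2);
        mat33 Ci = inv(C);
        auto voigt_pair = [](int a, int &i, int &j) {
          switch (a) { case 0: i=0;j=0; break; case 1: i=1;j=1; break;
                       case 2: i=2;j=2; break; case 3: i=0;j=1; break;
                       case 4: i=1;j=2; break; default: i=0;j=2; }
        };
        auto fill_tangent = [&](double cCC, double cIC, double cCI,
                                double cII, double cSym) {
          // Ct = cCC Ci x Ci + cIC I x Ci + cCI Ci x I + cII I x I
          //      + cSym * sym(Ci_ik Ci_jl)
          for (int a = 0; a < 6; ++a) for (int b = 0; b < 6; ++b) {
            int i,jq,k,l;
            voigt_pair(a, i, jq); voigt_pair(b, k, l);
            double I_ij = (i==jq) ? 1.0 : 0.0, I_kl = (k==l) ? 1.0 : 0.0;
            double v = cCC * Ci(i,jq) * Ci(k,l)
                     + cIC * I_ij * Ci(k,l) + cCI * Ci(i,jq) * I_kl
                     + cII * I_ij * I_kl
                     + cSym * 0.5 * (Ci(i,k)*Ci(jq,l) + Ci(i,l)*Ci(jq,k));
            Ct(a,b) = v;
          }
        };
        if (mode == 0) {
          double I1 = trace(C), Jm23 = std::pow(J, -2.0/3.0);
          mat33 S = 2.0 * C10 * Jm23 * (eye(3,3) - (I1/3.0) * Ci);
          Sv = {S(0,0), S(1,1), S(2,2), S(0,1), S(1,2), S(0,2)};
          Wgp = C10 * (Jm23 * I1 - 3.0);
          double c = (4.0/3.0) * C10 * Jm23;
          fill_tangent(c * I1 / 3.0, -c, -c, 0.0, c * I1);
        } else {
          mat33 S = (2.0/Dnh) * (J - 1.0) * J * Ci;
          Sv = {S(0,0), S(1,1), S(2,2), S(0,1), S(1,2), S(0,2)};
          Wgp = (1.0/Dnh) * (J - 1.0) * (J - 1.0);
          double f = J2 - J;
          fill_tangent((2.0/Dnh) * (2.0*J - 1.0) * J, 0.0, 0.0, 0.0,
                       -(2.0/Dnh) * 2.0 * f);
        }
      }

      fe += w * (B.t() * Sv);
      Ke += w * (B.t() * Ct * B);
      We += w * Wgp;
      if (type != 0) {
        double trE = Ev(0) + Ev(1) + Ev(2);
        vec ones6 = {1, 1, 1, 0, 0, 0};
        vec bvec = B.t() * ones6;
        if (mode == 1) {         // centroid pass: record reference values
          trE_c = trE;
          bvec_c = bvec;
          Gc = dNdX * dNdX.t();
        } else if (Kstab > 0) {  // volumetric hourglass stabilization
          vec db = bvec - bvec_c;
          double dv = trE - trE_c;
          fe += (Kstab * w * dv) * db;
          Ke += (Kstab * w) * (db * db.t());
          We += 0.5 * Kstab * w * dv * dv;
          // Hessian of trE (geometric part of the stabilization tangent):
          // d2(trE)/du_Ik du_Jl = delta_kl grad(N_I) . grad(N_J)
          mat Gs = (dNdX * dNdX.t()) - Gc;   // 8x8
          double cgeo = Kstab * w * dv;
          for (int a = 0; a < 8; ++a)
            for (int b = 0; b < 8; ++b) {
              double g = cgeo * Gs(a,b);
              Kg(3*a,3*b) += g; Kg(3*a+1,3*b+1) += g; Kg(3*a+2,3*b+2) += g;
            }
        }
      }
      // geometric part (initial stress)
      mat33 S3; voigt_to_mat(Sv, S3);
      if (clamp_geo && type != 0) {
        vec3 sev; mat33 svec;
        eig_sym(sev, svec, S3);
        for (int q = 0; q < 3; ++q) sev(q) = std::max(sev(q), 0.0);
        S3 = svec * diagmat(sev) * svec.t();
      }
      mat G = dNdX * S3 * dNdX.t();   // 8x8
      for (int a = 0; a < 8; ++a)
        for (int b = 0; b < 8; ++b) {
          double g = w * G(a,b);
          Kg(3*a,3*b) += g; Kg(3*a+1,3*b+1) += g; Kg(3*a+2,3*b+2) += g;
        }
      if (mode == 0) {
        double v = vm_cauchy(F, Sv);
        if (v > vme) vme = v;
      }
    };

    // SRI volumetric pass first: single centroid point, weight 8 (also
    // records the centroid dilatation for the stabilization term)
    if (type != 0) gp_contrib(0.0, 0.0, 0.0, 8.0, 1);
    // full / deviatoric pass: 2x2x2
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j)
        for (int k = 0; k < 2; ++k)
          gp_contrib(i ? GP : -GP, j ? GP : -GP, k ? GP : -GP, 1.0, 0);

    vol(e) = Ve;
    vm(e) = vme;
    energy += We;
    // scatter
    for (int a = 0; a < 8; ++a)
      for (int d = 0; d < 3; ++d)
        fint(3*conn(e,a) + d) += fe(3*a + d);
    size_t off = 576 * (size_t)e;
    for (int c = 0; c < 24; ++c)
      for (int r = 0; r < 24; ++r) {
        Km_val(off + 24*c + r) = Ke(r,c);
        if (want_kg) Kg_val(off + 24*c + r) = Kg(r,c);
      }
  }

  return Rcpp::List::create(
    Rcpp::Named("Km") = Km_val, Rcpp::Named("Kg") = Kg_val,
    Rcpp::Named("fint") = fint, Rcpp::Named("vm") = vm,
    Rcpp::Named("vol") = vol, Rcpp::Named("energy") = energy,
    Rcpp::Named("min_detJ") = min_detJ, Rcpp::Named("min_detF") = min_detF);
}

// ---------------------------------------------------------------------------
// Plane-stress von Mises return mapping (backward Euler), anisotropic elastic
// D allowed. Voigt (11, 22, 12eng). Returns stress, updated plastic strain
// and equivalent plastic strain.
// ---------------------------------------------------------------------------

static const mat33 Pps = {{1.0,-0.5,0.0},{-0.5,1.0,0.0},{0.0,0.0,3.0}};

static void ps_return_map(const mat33 &D, const vec3 &eps, const vec3 &epsp_old,
                          double alpha_old, double sy0, double H,
                          vec3 &sig, vec3 &epsp_new, double &alpha_new) {
  vec3 sig_tr = D * (eps - epsp_old);
  double se_tr = std::sqrt(std::max(0.0, dot(sig_tr, Pps * sig_tr)));
  double ycur = sy0 + H * alpha_old;
  if (se_tr <= ycur + 1e-12 * sy0) {
    sig = sig_tr; epsp_new = epsp_old; alpha_new = alpha_old;
    return;
  }
  // Newton on (sig, dgamma)
  vec3 s = sig_tr;
  double dg = 0.0;
  for (int it = 0; it < 40; ++it) {
    double se = std::sqrt(std::max(1e-300, dot(s, Pps * s)));
    vec3 n = (Pps * s) / se;
    vec3 Rs = s - D * (eps - epsp_old - dg * n);
    double Rf = se - (sy0 + H * (alpha_old + dg));
    if (norm(Rs) < 1e-10 * sy0 && std::abs(Rf) < 1e-10 * sy0) break;
    mat33 dn = (Pps - (Pps * s) * (Pps * s).t() / (se * se)) / se;
    mat44 J(fill::zeros);
    J.submat(0,0,2,2) = eye(3,3) + dg * D * dn;
    J.submat(0,3,2,3) = D * n;
    J.submat(3,0,3,2) = n.t();
    J(3,3) = -H;
    vec4 R = {Rs(0), Rs(1), Rs(2), Rf};
    vec4 dz = solve(J, -R);
    s += dz.subvec(0,2);
    dg += dz(3);
    if (dg < 0) dg = 0.0;
  }
  double se = std::sqrt(std::max(1e-300, dot(s, Pps * s)));
  vec3 n = (Pps * s) / se;
  sig = s;
  epsp_new = epsp_old + dg * n;
  alpha_new = alpha_old + dg;
}

// Exposed for unit testing of the plane-stress map.
// [[Rcpp::export]]
Rcpp::List ps_return_map_cpp(const arma::mat &D, const arma::vec &eps,
                             const arma::vec &epsp, double alpha,
                             double sy0, double H) {
  vec3 sig, ep;
  double an;
  ps_return_map(D, eps, epsp, alpha, sy0, H, sig, ep, an);
  return Rcpp::List::create(Rcpp::Named("sigma") = sig,
                            Rcpp::Named("epsp") = ep,
                            Rcpp::Named("alpha") = an);
}

// ---------------------------------------------------------------------------
// Quadrilateral shells. Flat reference geometry, local frame from the
// element; membrane with full Green-Lagrange in-plane strain (all three
// local displacement components) + MITC4 Mindlin bending; small rotation
// penalty ties the drilling rotation to the in-plane spin.
//
// Cortical variant: 6 dof/node (translations + rotations), plane-stress
// elastoplastic membrane, elastic bending.
// Fibre variant (membrane_asm_cpp): 3 dof/node, rank-one fibre stiffness,
// no bending.
// ---------------------------------------------------------------------------

struct ShellFrame {
  mat33 T;       // rows are local axes e1,e2,e3 (global components)
  mat xy;        // 4x2 local in-plane coords
};

static ShellFrame shell_frame(const mat &Xe /*4x3*/) {
  ShellFrame fr;
  rowvec3 d1 = (Xe.row(1) + Xe.row(2) - Xe.row(0) - Xe.row(3));
  rowvec3 d2 = (Xe.row(2) + Xe.row(3) - Xe.row(0) - Xe.row(1));
  rowvec3 e3 = cross(d1, d2);
  e3 /= norm(e3);
  rowvec3 e1 = d1 / norm(d1);
  // orthogonalize
  e1 = e1 - dot(e1, e3) * e3;
  e1 /= norm(e1);
  rowvec3 e2 = cross(e3, e1);
  fr.T.row(0) = e1; fr.T.row(1) = e2; fr.T.row(2) = e3;
  rowvec3 c = mean(Xe, 0);
  fr.xy.set_size(4,2);
  for (int a = 0; a < 4; ++a) {
    rowvec3 r = Xe.row(a) - c;
    fr.xy(a,0) = dot(r, e1);
    fr.xy(a,1) = dot(r, e2);
  }
  return fr;
}

static void quad_shape(double xi, double eta, vec &N, mat &dN) {
  const double s[4][2] = {{-1,-1},{1,-1},{1,1},{-1,1}};
  N.set_size(4); dN.set_size(4,2);
  for (int a = 0; a < 4; ++a) {
    N(a)   = 0.25 * (1 + s[a][0]*xi) * (1 + s[a][1]*eta);
    dN(a,0) = 0.25 * s[a][0] * (1 + s[a][1]*eta);
    dN(a,1) = 0.25 * s[a][1] * (1 + s[a][0]*xi);
  }
}

// Membrane contribution at one gauss point for a shell/membrane element with
// local nodal displacements ul (4x3). Fills B (3 x 12, local trans dofs),
// strain, and in-plane displacement-gradient a-matrix.
static void membrane_kinematics(const mat &dNdx /*4x2*/, const mat &ul /*4x3*/,
                                vec3 &epsv, mat &B /*3x12*/, mat &Hgrad /*3x2*/) {
  Hgrad = ul.t() * dNdx;             // 3x2
  // deformed covariant vectors a_alpha = e_alpha + du/dx_alpha (local comps)
  mat a = Hgrad;
  a(0,0) += 1.0;
  a(1,1) += 1.0;
  // strain: eps_ab = 0.5 * (a_a . a_b - delta_ab)
  double e11 = 0.5 * (dot(a.col(0), a.col(0)) - 1.0);
  double e22 = 0.5 * (dot(a.col(1), a.col(1)) - 1.0);
  double g12 = dot(a.col(0), a.col(1));
  epsv = {e11, e22, g12};
  B.zeros(3, 12);
  for (int I = 0; I < 4; ++I) {
    double g1 = dNdx(I,0), g2 = dNdx(I,1);
    for (int k = 0; k < 3; ++k) {
      int c = 3*I + k;
      B(0,c) = a(k,0) * g1;
      B(1,c) = a(k,1) * g2;
      B(2,c) = a(k,0) * g2 + a(k,1) * g1;
    }
  }
}

// Cortical shell assembly: flat quad with Green-Lagrange membrane strain,
// MITC4 Mindlin bending, drilling penalty, and LAYERED elastoplasticity:
// five Gauss points through the thickness, each with its own plane-stress
// von Mises return map, so yielding starts at the bending faces and couples
// membrane and bending stiffness consistently. With sy0 <= 0 the element is
// elastic and the classic decoupled membrane/bending split is used.
// Plastic state per element: 4 gp x 5 layers x (eps_p(3), alpha) = 80.
static const int NLAY = 5;
static const double LXI[NLAY] = {-0.9061798459386640, -0.5384693101056831, 0.0,
                                  0.5384693101056831,  0.9061798459386640};
static const double LWT[NLAY] = {0.2369268850561891, 0.4786286704993665,
                                 0.5688888888888889, 0.4786286704993665,
                                 0.2369268850561891};

static void one_shell(const mat &Xe, const mat &ue /*4x3 global trans*/,
                      const mat &re /*4x3 global rot*/,
                      const mat33 &Dps, double t, double G13, double G23,
                      double sy0, double H, double drill_coef, bool bending,
                      const vec &pstate_in /*80*/, vec &pstate_out,
                      mat &Ke, mat &Kg, vec &fe, double &We, double &vme,
                      double &area) {
  ShellFrame fr = shell_frame(Xe);
  const int nde = 24;
  Ke.zeros(nde, nde); Kg.zeros(nde, nde); fe.zeros(nde);
  We = 0.0; vme = 0.0; area = 0.0;
  pstate_out = pstate_in;

  mat ul = ue * fr.T.t();            // 4x3 local translations
  mat rl = re * fr.T.t();            // 4x3 local rotations

  vec N; mat dN, dNdx;
  mat22 Jm;
  mat Bm(3,12), Hg;

  // bending-block dof map: (w, th1, th2) per node -> local element dofs
  uvec bmap(12);
  for (int a = 0; a < 4; ++a) {
    bmap(3*a)   = 3*a + 2;
    bmap(3*a+1) = 12 + 3*a;
    bmap(3*a+2) = 12 + 3*a + 1;
  }
  vec wb(12);
  for (int a = 0; a < 4; ++a) {
    wb(3*a)   = ul(a,2);
    wb(3*a+1) = rl(a,0);
    wb(3*a+2) = rl(a,1);
  }

  int gp_id = 0;
  for (int i = 0; i < 2; ++i) for (int j = 0; j < 2; ++j, ++gp_id) {
    double xi = i ? GP : -GP, eta = j ? GP : -GP;
    quad_shape(xi, eta, N, dN);
    Jm = fr.xy.t() * dN;
    double dJ = det(Jm);
    dNdx = dN * inv(Jm);
    area += dJ;
    vec3 epsv;
    membrane_kinematics(dNdx, ul, epsv, Bm, Hg);
    // bending curvature operator at this gp
    mat Bb(3,12,fill::zeros);
    for (int a = 0; a < 4; ++a) {
      double g1 = dNdx(a,0), g2 = dNdx(a,1);
      Bb(0, 3*a+2) += g1;
      Bb(1, 3*a+1) += -g2;
      Bb(2, 3*a+2) += g2;
      Bb(2, 3*a+1) += -g1;
    }
    vec3 kap = Bb * wb;

    // expanded operators on the 24 local dofs
    mat Bm24(3,24,fill::zeros), Bb24(3,24,fill::zeros);
    Bm24.cols(0,11) = Bm;
    for (int r = 0; r < 12; ++r) Bb24.col(bmap(r)) = Bb.col(r);

    vec3 Nres(fill::zeros), Mres(fill::zeros);
    mat33 D00(fill::zeros), D01(fill::zeros), D11(fill::zeros);
    if (sy0 > 0) {
      for (int l = 0; l < NLAY; ++l) {
        double zl = 0.5 * t * LXI[l];
        double tw = 0.5 * t * LWT[l];
        vec3 eps_l = epsv + zl * kap;
        int off = (gp_id * NLAY + l) * 4;
        vec3 epsp_old = pstate_in.subvec(off, off + 2);
        double alpha_old = pstate_in(off + 3);
        vec3 sig, epsp_new; double alpha_new;
        ps_return_map(Dps, eps_l, epsp_old, alpha_old, sy0, H,
                      sig, epsp_new, alpha_new);
        pstate_out.subvec(off, off + 2) = epsp_new;
        pstate_out(off + 3) = alpha_new;
        mat33 Dtan = Dps;
        if (alpha_new > alpha_old + 1e-14) {
          double h = 1e-8 * std::max(1.0, norm(eps_l, "inf"));
          for (int c = 0; c < 3; ++c) {
            vec3 ep = eps_l, em = eps_l;
            ep(c) += h; em(c) -= h;
            vec3 sp, sm, dum; double da;
            ps_return_map(Dps, ep, epsp_old, alpha_old, sy0, H, sp, dum, da);
            ps_return_map(Dps, em, epsp_old, alpha_old, sy0, H, sm, dum, da);
            Dtan.col(c) = (sp - sm) / (2*h);
          }
          Dtan = 0.5 * (Dtan + Dtan.t());
        }
        Nres += tw * sig;
        Mres += tw * zl * sig;
        D00 += tw * Dtan;
        D01 += (tw * zl) * Dtan;
        D11 += (tw * zl * zl) * Dtan;
        We += dJ * tw * 0.5 * dot(eps_l - epsp_new, Dps * (eps_l - epsp_new));
        double se = std::sqrt(std::max(0.0, dot(sig, Pps * sig)));
        if (se > vme) vme = se;
      }
    } else {
      // elastic: decoupled closed-form integration through the thickness
      vec3 sigm = Dps * epsv;
      vec3 mom = (t*t*t/12.0) * (Dps * kap);
      Nres = t * sigm;
      Mres = mom;
      D00 = t * Dps;
      D11 = (t*t*t/12.0) * Dps;
      We += dJ * (0.5 * t * dot(epsv, sigm) + 0.5 * dot(kap, mom));
      vec3 sb = (6.0/(t*t)) * mom;
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        vec3 sf = sigm + sgn * sb;
        double se = std::sqrt(std::max(0.0, dot(sf, Pps * sf)));
        if (se > vme) vme = se;
      }
    }

    fe += dJ * (Bm24.t() * Nres + Bb24.t() * Mres);
    Ke += dJ * (Bm24.t() * D00 * Bm24 + Bm24.t() * D01 * Bb24
                + Bb24.t() * D01 * Bm24 + Bb24.t() * D11 * Bb24);
    // geometric stiffness from the membrane stress resultant
    mat22 S2 = {{Nres(0), Nres(2)},{Nres(2), Nres(1)}};
    mat Gm = dNdx * S2 * dNdx.t();
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        double g = dJ * Gm(a,b);
        Kg(3*a,3*b) += g; Kg(3*a+1,3*b+1) += g; Kg(3*a+2,3*b+2) += g;
      }
  }

  // ---- MITC4 assumed transverse shear (elastic) ----------------------------
  {
    mat22 Ds = {{G13,0.0},{0.0,G23}};
    Ds *= (5.0/6.0) * t;
    auto cov_shear_row = [&](double xi, double eta, int comp, rowvec &row) {
      quad_shape(xi, eta, N, dN);
      mat Jl = fr.xy.t() * dN;
      row.zeros(12);
      for (int a = 0; a < 4; ++a) {
        row(3*a) += dN(a,comp);
        row(3*a+2) += -N(a) * Jl(0,comp);
        row(3*a+1) += +N(a) * Jl(1,comp);
      }
    };
    rowvec gA(12), gB(12), gC(12), gD(12);
    cov_shear_row(0,-1, 0, gA);
    cov_shear_row(0, 1, 0, gB);
    cov_shear_row(-1,0, 1, gC);
    cov_shear_row(1, 0, 1, gD);
    for (int i = 0; i < 2; ++i) for (int j = 0; j < 2; ++j) {
      double xi = i ? GP : -GP, eta = j ? GP : -GP;
      quad_shape(xi, eta, N, dN);
      Jm = fr.xy.t() * dN;
      double dJ = det(Jm);
      mat22 Jinv2 = inv(Jm);
      mat Bs_cov(2,12);
      Bs_cov.row(0) = 0.5*(1-eta)*gA + 0.5*(1+eta)*gB;
      Bs_cov.row(1) = 0.5*(1-xi)*gC + 0.5*(1+xi)*gD;
      mat Bs = Jinv2.t() * Bs_cov;
      mat Bs24(2,24,fill::zeros);
      for (int r = 0; r < 12; ++r) Bs24.col(bmap(r)) = Bs.col(r);
      vec2 gam = Bs * wb;
      vec2 q = Ds * gam;
      fe += dJ * (Bs24.t() * q);
      Ke += dJ * (Bs24.t() * Ds * Bs24);
      We += dJ * 0.5 * dot(gam, q);
    }
  }

  // ---- drilling penalty -----------------------------------------------------
  {
    quad_shape(0,0,N,dN);
    Jm = fr.xy.t() * dN;
    dNdx = dN * inv(Jm);
    // per-node penalty on (theta3_I - in-plane spin at centroid); the spin
    // omega = 0.5*(d u2/d x1 - d u1/d x2) makes the term invariant under
    // rigid rotation, and per-node application leaves no null modes
    double kd = 0.25 * drill_coef * Dps(2,2) * t * area;
    vec uloc = join_cols(vectorise(ul.t()), vectorise(rl.t()));
    for (int I = 0; I < 4; ++I) {
      rowvec rr(24, fill::zeros);
      rr(12 + 3*I + 2) = 1.0;
      for (int a = 0; a < 4; ++a) {
        rr(3*a + 1) -= 0.5 * dNdx(a,0);
        rr(3*a)     += 0.5 * dNdx(a,1);
      }
      double val = dot(rr, uloc);
      fe += kd * val * rr.t();
      Ke += kd * (rr.t() * rr);
      We += 0.5 * kd * val * val;
    }
  }

  // transform local -> global (local = blockdiag(T) * global)
  mat R(nde, nde, fill::zeros);
  for (int bq = 0; bq < 8; ++bq)
    R.submat(3*bq, 3*bq, 3*bq+2, 3*bq+2) = fr.T;
  Ke = R.t() * Ke * R;
  Kg = R.t() * Kg * R;
  fe = R.t() * fe;
}

// [[Rcpp::export]]
Rcpp::List shell_asm_cpp(const arma::mat &X, const arma::imat &conn,
                         const arma::imat &rotbase,
                         const arma::mat &params,
                         const arma::vec &u, const arma::mat &pstate,
                         int ndof, bool want_kg) {
  // rotbase: m x 4 (0-based rotation dof base per node); params: m x 13;
  // pstate: m x 80 (4 gp x 5 layers x [eps_p(3), alpha])
  const int m = conn.n_rows;
  vec Km_val(576 * (size_t)m, fill::zeros);
  vec Kg_val(want_kg ? 576 * (size_t)m : 0, fill::zeros);
  vec fint(ndof, fill::zeros);
  vec vm(m, fill::zeros);
  mat pstate_out(m, 80, fill::zeros);
  double energy = 0.0;

  for (int e = 0; e < m; ++e) {
    mat Xe(4,3), ue(4,3), re(4,3);
    ivec dofs(24);
    for (int a = 0; a < 4; ++a) {
      int nno = conn(e,a);
      int rb = rotbase(e,a);
      for (int d = 0; d < 3; ++d) {
        Xe(a,d) = X(nno,d);
        ue(a,d) = u(3*nno + d);
        re(a,d) = u(rb + d);
        dofs(3*a + d) = 3*nno + d;
        dofs(12 + 3*a + d) = rb + d;
      }
    }
    double t = params(e,1);
    mat33 Dps = {{params(e,2), params(e,3), params(e,4)},
                 {params(e,3), params(e,5), params(e,6)},
                 {params(e,4), params(e,6), params(e,7)}};
    double G13 = params(e,8), G23 = params(e,9);
    double sy0 = params(e,10), H = params(e,11), drill = params(e,12);

    mat Ke, Kg; vec fe; double We, vme, area;
    vec pout;
    one_shell(Xe, ue, re, Dps, t, G13, G23, sy0, H, drill, true,
              pstate.row(e).t(), pout, Ke, Kg, fe, We, vme, area);
    pstate_out.row(e) = pout.t();
    vm(e) = vme;
    energy += We;
    for (int r = 0; r < 24; ++r) fint(dofs(r)) += fe(r);
    size_t off = 576 * (size_t)e;
    for (int c = 0; c < 24; ++c)
      for (int r = 0; r < 24; ++r) {
        Km_val(off + 24*c + r) = Ke(r,c);
        if (want_kg) Kg_val(off + 24*c + r) = Kg(r,c);
      }
  }
  return Rcpp::List::create(
    Rcpp::Named("Km") = Km_val, Rcpp::Named("Kg") = Kg_val,
    Rcpp::Named("fint") = fint, Rcpp::Named("vm") = vm,
    Rcpp::Named("pstate") = pstate_out, Rcpp::Named("energy") = energy);
}

// Fibre membranes: a balanced laminate of two fibre families at +/- angle
// from the local circumferential axis, each at half the layer thickness.
// By default the families are bidirectional (resist compression too, like
// the composite shells they represent) and only the geometric stiffness is
// clamped to the tensile principal part (bending-free membranes otherwise
// carry zero-energy wrinkling modes). With tension_only = 1 the families
// themselves go slack in compression (W = sum_f E_f/2 max(eps_f, 0)^2).
// params: m x 4 columns [t, E, angle_deg, tension_only]
// [[Rcpp::export]]
Rcpp::List membrane_asm_cpp(const arma::mat &X, const arma::imat &conn,
                            const arma::mat &params,
                            const arma::vec &u, int ndof, bool want_kg) {
  const int m = conn.n_rows;
  vec Km_val(144 * (size_t)m, fill::zeros);
  vec Kg_val(want_kg ? 144 * (size_t)m : 0, fill::zeros);
  vec fint(ndof, fill::zeros);
  double energy = 0.0;

  vec N; mat dN, dNdx;
  mat22 Jm;
  mat Bm(3,12), Hg;

  for (int e = 0; e < m; ++e) {
    mat Xe(4,3), ue(4,3);
    ivec dofs(12);
    for (int a = 0; a < 4; ++a) {
      int nno = conn(e,a);
      for (int d = 0; d < 3; ++d) {
        Xe(a,d) = X(nno,d);
        ue(a,d) = u(3*nno + d);
        dofs(3*a + d) = 3*nno + d;
      }
    }
    double t = params(e,0), Ef = params(e,1);
    double ang = params(e,2) * datum::pi / 180.0;
    bool tension_only = params.n_cols > 3 && params(e,3) > 0.5;
    vec3 vplus = {std::cos(ang)*std::cos(ang), std::sin(ang)*std::sin(ang),
                  std::cos(ang)*std::sin(ang)};
    vec3 vminus = {vplus(0), vplus(1), -vplus(2)};
    ShellFrame fr = shell_frame(Xe);
    mat ul = ue * fr.T.t();

    mat Ke(12,12,fill::zeros), Kg(12,12,fill::zeros);
    vec fe(12, fill::zeros);
    double We = 0.0;
    for (int i = 0; i < 2; ++i) for (int j = 0; j < 2; ++j) {
      double xi = i ? GP : -GP, eta = j ? GP : -GP;
      quad_shape(xi, eta, N, dN);
      Jm = fr.xy.t() * dN;
      double dJ = det(Jm);
      dNdx = dN * inv(Jm);
      double w = dJ * t;
      vec3 epsv;
      membrane_kinematics(dNdx, ul, epsv, Bm, Hg);
      vec3 sig(fill::zeros);
      mat33 Dtan(fill::zeros);
      for (int f = 0; f < 2; ++f) {
        const vec3 &v = f ? vminus : vplus;
        double ef = dot(v, epsv);
        if (!tension_only || ef > 0) {
          sig += 0.5 * Ef * ef * v;      // half thickness per family
          Dtan += 0.5 * Ef * (v * v.t());
          We += w * 0.25 * Ef * ef * ef;
        }
      }
      fe += w * (Bm.t() * sig);
      Ke += w * (Bm.t() * Dtan * Bm);
      // tensile principal part only: no wrinkling modes in K_sigma
      mat22 S2 = {{sig(0), sig(2)},{sig(2), sig(1)}};
      {
        vec2 sev; mat22 svec;
        eig_sym(sev, svec, S2);
        sev(0) = std::max(sev(0), 0.0);
        sev(1) = std::max(sev(1), 0.0);
        S2 = svec * diagmat(sev) * svec.t();
      }
      mat Gm = dNdx * S2 * dNdx.t();
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) {
          double g = w * Gm(a,b);
          Kg(3*a,3*b) += g; Kg(3*a+1,3*b+1) += g; Kg(3*a+2,3*b+2) += g;
        }
    }
    // transform to global
    mat R(12, 12, fill::zeros);
    for (int bq = 0; bq < 4; ++bq)
      R.submat(3*bq, 3*bq, 3*bq+2, 3*bq+2) = fr.T;
    Ke = R.t() * Ke * R;
    Kg = R.t() * Kg * R;
    fe = R.t() * fe;
    energy += We;
    for (int r = 0; r < 12; ++r) fint(dofs(r)) += fe(r);
    size_t off = 144 * (size_t)e;
    for (int c = 0; c < 12; ++c)
      for (int r = 0; r < 12; ++r) {
        Km_val(off + 12*c + r) = Ke(r,c);
        if (want_kg) Kg_val(off + 12*c + r) = Kg(r,c);
      }
  }
  return Rcpp::List::create(
    Rcpp::Named("Km") = Km_val, Rcpp::Named("Kg") = Kg_val,
    Rcpp::Named("fint") = fint, Rcpp::Named("energy") = energy);
}

// ---------------------------------------------------------------------------
// Tension-only two-node links (ligaments). Engineering strain on the current
// length (F = EA (L - L0)/L0 along the current axis), zero force and zero
// tangent in compression; energy-consistent with W = EA L0 eps^2 / 2.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List link_asm_cpp(const arma::mat &X, const arma::imat &conn,
                        const arma::vec &EA, const arma::vec &u, bool want_kg) {
  const int m = conn.n_rows;
  vec Km_val(36 * (size_t)m, fill::zeros);
  vec Kg_val(want_kg ? 36 * (size_t)m : 0, fill::zeros);
  vec fint(3 * X.n_rows, fill::zeros);
  vec force(m, fill::zeros), elong(m, fill::zeros);
  double energy = 0.0;

  for (int e = 0; e < m; ++e) {
    int n1 = conn(e,0), n2 = conn(e,1);
    vec3 X1 = X.row(n1).t(), X2 = X.row(n2).t();
    vec3 u1 = {u(3*n1), u(3*n1+1), u(3*n1+2)};
    vec3 u2 = {u(3*n2), u(3*n2+1), u(3*n2+2)};
    vec3 d0 = X2 - X1;
    double L0 = norm(d0);
    vec3 x = d0 + u2 - u1;
    double L = norm(x);
    double eps = (L - L0) / L0;
    elong(e) = L - L0;
    if (eps <= 0) continue;   // tension-only
    double N = EA(e) * eps;
    force(e) = N;
    energy += 0.5 * EA(e) * L0 * eps * eps;
    vec3 xh = x / L;
    vec3 f2 = N * xh;
    for (int d = 0; d < 3; ++d) {
      fint(3*n2 + d) += f2(d);
      fint(3*n1 + d) -= f2(d);
    }
    mat33 km = (EA(e) / L) * (xh * xh.t());
    mat33 kg = (N / L) * (eye(3,3) - xh * xh.t());
    size_t off = 36 * (size_t)e;
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) {
        double vmat = km(r,c), vg = kg(r,c);
        // 6x6 block [[k,-k],[-k,k]] column-major
        Km_val(off + 6*c + r)            = vmat;
        Km_val(off + 6*c + (r+3))        = -vmat;
        Km_val(off + 6*(c+3) + r)        = -vmat;
        Km_val(off + 6*(c+3) + (r+3))    = vmat;
        if (want_kg) {
          Kg_val(off + 6*c + r)         = vg;
          Kg_val(off + 6*c + (r+3))     = -vg;
          Kg_val(off + 6*(c+3) + r)     = -vg;
          Kg_val(off + 6*(c+3) + (r+3)) = vg;
        }
      }
  }
  return Rcpp::List::create(
    Rcpp::Named("Km") = Km_val, Rcpp::Named("Kg") = Kg_val,
    Rcpp::Named("fint") = fint, Rcpp::Named("force") = force,
    Rcpp::Named("elong") = elong, Rcpp::Named("energy") = energy);
}

// ---------------------------------------------------------------------------
// Helpers: triplet value accumulation into a fixed CSC slot map, and
// reference-geometry checks.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::vec accumulate_cpp(const arma::ivec &slot,
                         const arma::vec &vals, int n) {
  // slot: 1-based target position per value, 0 = drop
  vec out(n, fill::zeros);
  for (size_t i = 0; i < slot.n_elem; ++i) {
    int s = slot(i);
    if (s > 0) out(s - 1) += vals(i);
  }
  return out;
}

// accumulate a list of value vectors laid end to end against one slot map
// (avoids concatenating multi-million-entry vectors every assembly)
// [[Rcpp::export]]
arma::vec accumulate_list_cpp(const arma::ivec &slot, Rcpp::List pieces, int n) {
  vec out(n, fill::zeros);
  size_t off = 0;
  for (int p = 0; p < pieces.size(); ++p) {
    Rcpp::NumericVector v(pieces[p]);
    for (int i = 0; i < v.size(); ++i) {
      int s = slot(off + i);
      if (s > 0) out(s - 1) += v[i];
    }
    off += v.size();
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List hex_geometry_cpp(const arma::mat &X, const arma::imat &conn) {
  const int m = conn.n_rows;
  vec vol(m), minJ(m);
  mat dN(8,3);
  for (int e = 0; e < m; ++e) {
    mat Xe(8,3);
    for (int a = 0; a < 8; ++a)
      for (int d = 0; d < 3; ++d) Xe(a,d) = X(conn(e,a),d);
    double V = 0.0, mJ = datum::inf;
    for (int i = 0; i < 2; ++i) for (int j = 0; j < 2; ++j) for (int k = 0; k < 2; ++k) {
      hex_shape_deriv(i?GP:-GP, j?GP:-GP, k?GP:-GP, dN);
      double dJ = det(Xe.t() * dN);
      V += dJ;
      if (dJ < mJ) mJ = dJ;
    }
    vol(e) = V; minJ(e) = mJ;
  }
  return Rcpp::List::create(Rcpp::Named("vol") = vol, Rcpp::Named("min_detJ") = minJ);
}
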