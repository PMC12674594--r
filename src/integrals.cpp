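// Gaussian integral engine (McMurchie-Davidson scheme).
//
// Shells are contracted Cartesian Gaussians built from raw monomials
// x^i y^j z^k exp(-a r^2); primitive normalisation factors are folded into the
// contraction coefficients on the R side.  Two-electron integrals are
// transformed to real solid-harmonic (spherical) AOs inside the quartet loop
// using per-angular-momentum transform matrices supplied by R.  One-electron
// matrices are returned in the raw Cartesian basis and transformed in R.
//
// Conventions: chemist notation (ab|cd); Cartesian components of a shell are
// ordered ix = l..0, iy = l-ix..0, iz = l-ix-iy.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const int LMAX = 5;          // highest angular momentum supported
static const int MMAX = 4 * LMAX + 4; // highest Boys order needed

struct Shell {
  int l;
  double A[3];
  std::vector<double> exps;
  std::vector<double> coefs; // includes primitive norms
};

static int ncart(int l) { return (l + 1) * (l + 2) / 2; }

// ---------------------------------------------------------------- Boys F_m(T)
static void boys(int mmax, double T, double *F) {
  if (T < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T > 35.0) {
    // asymptotic F_0 then stable upward recursion
    F[0] = 0.5 * std::sqrt(M_PI / T);
    double expT = (T > 700.0) ? 0.0 : std::exp(-T);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - expT) / (2.0 * T);
    return;
  }
  // series at mmax, then downward recursion
  double expT = std::exp(-T);
  double sum = 1.0 / (2.0 * mmax + 1.0), term = sum;
  for (int i = 1; i < 200; ++i) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * i + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = expT * sum;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2.0 * T * F[m] + expT) / (2.0 * m - 1.0);
}

// ------------------------------------------------- Hermite expansion E_t^{ij}
// E[i][j][t] for one Cartesian direction; dimension limits small, use fixed
// stride buffers.
struct Etab {
  // E[(i*(jmax+1)+j)*(tmax+1)+t]
  std::vector<double> v;
  int jdim, tdim;
  double &at(int i, int j, int t) { return v[(i * jdim + j) * tdim + t]; }
  double get(int i, int j, int t) const {
    if (t < 0 || t >= tdim) return 0.0;
    return v[(i * jdim + j) * tdim + t];
  }
};

static void build_E(int imax, int jmax, double a, double b, double AB,
                    Etab &E) {
  double p = a + b, mu = a * b / p;
  E.jdim = jmax + 1;
  E.tdim = imax + jmax + 1;
  E.v.assign((imax + 1) * E.jdim * E.tdim, 0.0);
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  double PA = -b * AB / p; // P - A where A - B = AB
  double PB = a * AB / p;  // P - B
  for (int i = 1; i <= imax; ++i)
    for (int t = 0; t <= i; ++t) {
      double val = 0.0;
      if (t > 0) val += E.get(i - 1, 0, t - 1) / (2.0 * p);
      val += PA * E.get(i - 1, 0, t);
      val += (t + 1) * E.get(i - 1, 0, t + 1);
      E.at(i, 0, t) = val;
    }
  for (int j = 1; j <= jmax; ++j)
    for (int i = 0; i <= imax; ++i)
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (t > 0) val += E.get(i, j - 1, t - 1) / (2.0 * p);
        val += PB * E.get(i, j - 1, t);
        val += (t + 1) * E.get(i, j - 1, t + 1);
        E.at(i, j, t) = val;
      }
}

// --------------------------------------------- Hermite Coulomb tensor R_{tuv}
// R[n][t][u][v] with t+u+v <= Ntot - n; returns R^0.
struct Rtab {
  std::vector<double> v;
  int dim; // Ntot+1
  double &at(int n, int t, int u, int w) {
    return v[((n * dim + t) * dim + u) * dim + w];
  }
};

static void build_R(int Ntot, double p, double X, double Y, double Z,
                    Rtab &R) {
  double T = p * (X * X + Y * Y + Z * Z);
  double F[MMAX + 1];
  boys(Ntot, T, F);
  R.dim = Ntot + 1;
  R.v.assign((size_t)(Ntot + 1) * R.dim * R.dim * R.dim, 0.0);
  double m2p = 1.0;
  for (int n = 0; n <= Ntot; ++n) {
    R.at(n, 0, 0, 0) = m2p * F[n];
    m2p *= -2.0 * p;
  }
  for (int n = Ntot - 1; n >= 0; --n) {
    int rem = Ntot - n;
    for (int t = 0; t <= rem; ++t)
      for (int u = 0; u <= rem - t; ++u)
        for (int w = 0; w <= rem - t - u; ++w) {
          if (t + u + w == 0) continue;
          double val;
          if (t > 0) {
            val = X * R.at(n + 1, t - 1, u, w);
            if (t > 1) val += (t - 1) * R.at(n + 1, t - 2, u, w);
          } else if (u > 0) {
            val = Y * R.at(n + 1, t, u - 1, w);
            if (u > 1) val += (u - 1) * R.at(n + 1, t, u - 2, w);
          } else {
            val = Z * R.at(n + 1, t, u, w - 1);
            if (w > 1) val += (w - 1) * R.at(n + 1, t, u, w - 2);
          }
          R.at(n, t, u, w) = val;
        }
  }
}

// ------------------------------------------------------------- shell parsing
static std::vector<Shell> parse_shells(List shells) {
  IntegerVector l = shells["l"];
  NumericMatrix cen = shells["centers"]; // 3 x nsh
  List ex = shells["exps"], co = shells["coefs"];
  int nsh = l.size();
  std::vector<Shell> out(nsh);
  for (int s = 0; s < nsh; ++s) {
    out[s].l = l[s];
    for (int k = 0; k < 3; ++k) out[s].A[k] = cen(k, s);
    NumericVector e = ex[s], c = co[s];
    out[s].exps.assign(e.begin(), e.end());
    out[s].coefs.assign(c.begin(), c.end());
  }
  return out;
}

static void cart_comps(int l, std::vector<std::array<int,3>> &comp) {
  comp.clear();
  for (int ix = l; ix >= 0; --ix)
    for (int iy = l - ix; iy >= 0; --iy)
      comp.push_back({ix, iy, l - ix - iy});
}

// ---------------------------------------------------- one-electron integrals
// [[Rcpp::export]]
List cpp_one_ints(List shells) {
  std::vector<Shell> sh = parse_shells(shells);
  int nsh = sh.size(), nbf = 0;
  std::vector<int> off(nsh);
  for (int s = 0; s < nsh; ++s) { off[s] = nbf; nbf += ncart(sh[s].l); }
  NumericMatrix S(nbf, nbf), K(nbf, nbf);
  std::vector<std::array<int,3>> ca, cb;
  Etab Ex, Ey, Ez;
  for (int sa = 0; sa < nsh; ++sa)
    for (int sb = 0; sb <= sa; ++sb) {
      const Shell &A = sh[sa], &B = sh[sb];
      cart_comps(A.l, ca); cart_comps(B.l, cb);
      int na = ca.size(), nb = cb.size();
      std::vector<double> sblk(na * nb, 0.0), tblk(na * nb, 0.0);
      for (size_t pa = 0; pa < A.exps.size(); ++pa)
        for (size_t pb = 0; pb < B.exps.size(); ++pb) {
          double a = A.exps[pa], b = B.exps[pb];
          double cc = A.coefs[pa] * B.coefs[pb];
          double p = a + b, pref = std::pow(M_PI / p, 1.5);
          // need j up to B.l + 2 for kinetic
          build_E(A.l, B.l + 2, a, b, A.A[0] - B.A[0], Ex);
          build_E(A.l, B.l + 2, a, b, A.A[1] - B.A[1], Ey);
          build_E(A.l, B.l + 2, a, b, A.A[2] - B.A[2], Ez);
          for (int ia = 0; ia < na; ++ia)
            for (int ib = 0; ib < nb; ++ib) {
              int i = ca[ia][0], j = ca[ia][1], k = ca[ia][2];
              int m = cb[ib][0], n = cb[ib][1], o = cb[ib][2];
              double sx = Ex.get(i, m, 0), sy = Ey.get(j, n, 0),
                     sz = Ez.get(k, o, 0);
              double s0 = sx * sy * sz;
              sblk[ia * nb + ib] += cc * pref * s0;
              // kinetic via monomial raising/lowering on ket
              double tx = b * (2 * (m + n + o) + 3) * s0;
              tx -= 2.0 * b * b *
                    (Ex.get(i, m + 2, 0) * sy * sz +
                     sx * Ey.get(j, n + 2, 0) * sz +
                     sx * sy * Ez.get(k, o + 2, 0));
              double low = 0.0;
              if (m > 1) low += m * (m - 1) * Ex.get(i, m - 2, 0) * sy * sz;
              if (n > 1) low += n * (n - 1) * sx * Ey.get(j, n - 2, 0) * sz;
              if (o > 1) low += o * (o - 1) * sx * sy * Ez.get(k, o - 2, 0);
              tx -= 0.5 * low;
              tblk[ia * nb + ib] += cc * pref * tx;
            }
        }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          S(off[sa] + ia, off[sb] + ib) = sblk[ia * nb + ib];
          S(off[sb] + ib, off[sa] + ia) = sblk[ia * nb + ib];
          K(off[sa] + ia, off[sb] + ib) = tblk[ia * nb + ib];
          K(off[sb] + ib, off[sa] + ia) = tblk[ia * nb + ib];
        }
    }
  return List::create(_["S"] = S, _["T"] = K);
}

// V_{mu nu} = sum_A q_A int chi_mu chi_nu / |r - R_A|  (positive kernel)
// [[Rcpp::export]]
NumericMatrix cpp_nuclear(List shells, NumericMatrix qcen, NumericVector q) {
  std::vector<Shell> sh = parse_shells(shells);
  int nsh = sh.size(), nbf = 0, nq = q.size();
  std::vector<int> off(nsh);
  for (int s = 0; s < nsh; ++s) { off[s] = nbf; nbf += ncart(sh[s].l); }
  NumericMatrix V(nbf, nbf);
  std::vector<std::array<int,3>> ca, cb;
  Etab Ex, Ey, Ez; Rtab R;
  for (int sa = 0; sa < nsh; ++sa)
    for (int sb = 0; sb <= sa; ++sb) {
      const Shell &A = sh[sa], &B = sh[sb];
      cart_comps(A.l, ca); cart_comps(B.l, cb);
      int na = ca.size(), nb = cb.size();
      int Ntot = A.l + B.l;
      std::vector<double> blk(na * nb, 0.0);
      for (size_t pa = 0; pa < A.exps.size(); ++pa)
        for (size_t pb = 0; pb < B.exps.size(); ++pb) {
          double a = A.exps[pa], b = B.exps[pb];
          double cc = A.coefs[pa] * B.coefs[pb];
          double p = a + b;
          double P[3];
          for (int k = 0; k < 3; ++k) P[k] = (a * A.A[k] + b * B.A[k]) / p;
          build_E(A.l, B.l, a, b, A.A[0] - B.A[0], Ex);
          build_E(A.l, B.l, a, b, A.A[1] - B.A[1], Ey);
          build_E(A.l, B.l, a, b, A.A[2] - B.A[2], Ez);
          for (int iq = 0; iq < nq; ++iq) {
            build_R(Ntot, p, P[0] - qcen(0, iq), P[1] - qcen(1, iq),
                    P[2] - qcen(2, iq), R);
            double pref = 2.0 * M_PI / p * q[iq] * cc;
            for (int ia = 0; ia < na; ++ia)
              for (int ib = 0; ib < nb; ++ib) {
                double acc = 0.0;
                for (int t = 0; t <= ca[ia][0] + cb[ib][0]; ++t) {
                  double ex = Ex.get(ca[ia][0], cb[ib][0], t);
                  if (ex == 0.0) continue;
                  for (int u = 0; u <= ca[ia][1] + cb[ib][1]; ++u) {
                    double ey = Ey.get(ca[ia][1], cb[ib][1], u);
                    if (ey == 0.0) continue;
                    for (int w = 0; w <= ca[ia][2] + cb[ib][2]; ++w) {
                      double ez = Ez.get(ca[ia][2], cb[ib][2], w);
                      if (ez == 0.0) continue;
                      acc += ex * ey * ez * R.at(0, t, u, w);
                    }
                  }
                }
                blk[ia * nb + ib] += pref * acc;
              }
          }
        }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          V(off[sa] + ia, off[sb] + ib) = blk[ia * nb + ib];
          V(off[sb] + ib, off[sa] + ia) = blk[ia * nb + ib];
        }
    }
  return V;
}

// ------------------------------------------------------------- ERI machinery
// Primitive-pair data reused across quartets.
struct PairPrim {
  double p, P[3], cc;
  Etab Ex, Ey, Ez;
};
struct ShellPair {
  int sa, sb;
  std::vector<PairPrim> prims;
  double schwarz; // sqrt((ab|ab)) upper bound, filled later
};

static void make_pairs(const std::vector<Shell> &sh, bool triangular,
                       std::vector<ShellPair> &pairs) {
  int nsh = sh.size();
  pairs.clear();
  for (int sa = 0; sa < nsh; ++sa)
    for (int sb = 0; sb <= (triangular ? sa : nsh - 1); ++sb) {
      ShellPair sp;
      sp.sa = sa; sp.sb = sb; sp.schwarz = 1.0;
      const Shell &A = sh[sa], &B = sh[sb];
      for (size_t pa = 0; pa < A.exps.size(); ++pa)
        for (size_t pb = 0; pb < B.exps.size(); ++pb) {
          PairPrim pp;
          double a = A.exps[pa], b = B.exps[pb];
          pp.p = a + b;
          for (int k = 0; k < 3; ++k)
            pp.P[k] = (a * A.A[k] + b * B.A[k]) / pp.p;
          pp.cc = A.coefs[pa] * B.coefs[pb];
          // screen negligible primitive pairs
          double mu = a * b / pp.p, ab2 = 0.0;
          for (int k = 0; k < 3; ++k) {
            double d = A.A[k] - B.A[k];
            ab2 += d * d;
          }
          if (mu * ab2 > 46.0 && std::fabs(pp.cc) * std::exp(-mu * ab2) < 1e-16)
            continue;
          build_E(A.l, B.l, a, b, A.A[0] - B.A[0], pp.Ex);
          build_E(A.l, B.l, a, b, A.A[1] - B.A[1], pp.Ey);
          build_E(A.l, B.l, a, b, A.A[2] - B.A[2], pp.Ez);
          sp.prims.push_back(std::move(pp));
        }
      pairs.push_back(std::move(sp));
    }
}

// compute Cartesian quartet block (ab|cd) for shell pairs spAB (basis 1) and
// spCD (basis 2); result in blk[(ia*nb+ib)*nc*nd + ic*nd+id]
static void quartet(const Shell &A, const Shell &B, const Shell &C,
                    const Shell &D, const ShellPair &spAB,
                    const ShellPair &spCD, Rtab &R,
                    std::vector<double> &blk) {
  std::vector<std::array<int,3>> ca, cb, cc_, cd;
  cart_comps(A.l, ca); cart_comps(B.l, cb);
  cart_comps(C.l, cc_); cart_comps(D.l, cd);
  int na = ca.size(), nb = cb.size(), nc = cc_.size(), nd = cd.size();
  int L1 = A.l + B.l, L2 = C.l + D.l, Ntot = L1 + L2;
  blk.assign((size_t)na * nb * nc * nd, 0.0);
  int d2 = L2 + 1;
  std::vector<double> ket((size_t)nc * nd * d2 * d2 * d2);
  std::vector<double> mid; // [cdpair][t,u,v]
  int d1 = L1 + 1;
  mid.resize((size_t)nc * nd * d1 * d1 * d1);
  for (size_t i1 = 0; i1 < spAB.prims.size(); ++i1) {
    const PairPrim &pp1 = spAB.prims[i1];
    for (size_t i2 = 0; i2 < spCD.prims.size(); ++i2) {
      const PairPrim &pp2 = spCD.prims[i2];
      double p = pp1.p, qq = pp2.p;
      double theta = p * qq / (p + qq);
      build_R(Ntot, theta, pp1.P[0] - pp2.P[0], pp1.P[1] - pp2.P[1],
              pp1.P[2] - pp2.P[2], R);
      double pref = 2.0 * std::pow(M_PI, 2.5) /
                    (p * qq * std::sqrt(p + qq)) * pp1.cc * pp2.cc;
      // ket Hermite coefficients
      std::fill(ket.begin(), ket.end(), 0.0);
      for (int ic = 0; ic < nc; ++ic)
        for (int id = 0; id < nd; ++id) {
          int cx = cc_[ic][0], cy = cc_[ic][1], cz = cc_[ic][2];
          int dx = cd[id][0], dy = cd[id][1], dz = cd[id][2];
          size_t base = ((size_t)ic * nd + id) * d2 * d2 * d2;
          for (int t = 0; t <= cx + dx; ++t) {
            double ex = pp2.Ex.get(cx, dx, t);
            if (ex == 0.0) continue;
            for (int u = 0; u <= cy + dy; ++u) {
              double ey = pp2.Ey.get(cy, dy, u);
              if (ey == 0.0) continue;
              for (int w = 0; w <= cz + dz; ++w) {
                double ez = pp2.Ez.get(cz, dz, w);
                if (ez == 0.0) continue;
                double sgn = ((t + u + w) % 2) ? -1.0 : 1.0;
                ket[base + ((size_t)t * d2 + u) * d2 + w] = sgn * ex * ey * ez;
              }
            }
          }
        }
      // mid[cd][tuv] = sum_{TUV} ket[cd][TUV] * R[t+T,u+U,v+V]
      for (int ic = 0; ic < nc; ++ic)
        for (int id = 0; id < nd; ++id) {
          size_t kb = ((size_t)ic * nd + id) * d2 * d2 * d2;
          size_t mb = ((size_t)ic * nd + id) * d1 * d1 * d1;
          int cx = cc_[ic][0] + cd[id][0], cy = cc_[ic][1] + cd[id][1],
              cz = cc_[ic][2] + cd[id][2];
          for (int t = 0; t <= L1; ++t)
            for (int u = 0; u <= L1 - t; ++u)
              for (int w = 0; w <= L1 - t - u; ++w) {
                double acc = 0.0;
                for (int T = 0; T <= cx; ++T)
                  for (int U = 0; U <= cy; ++U)
                    for (int W = 0; W <= cz; ++W) {
                      double kv = ket[kb + ((size_t)T * d2 + U) * d2 + W];
                      if (kv == 0.0) continue;
                      acc += kv * R.at(0, t + T, u + U, w + W);
                    }
                mid[mb + ((size_t)t * d1 + u) * d1 + w] = acc;
              }
        }
      // bra contraction
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          int ax = ca[ia][0], ay = ca[ia][1], az = ca[ia][2];
          int bx = cb[ib][0], by = cb[ib][1], bz = cb[ib][2];
          size_t ob = ((size_t)ia * nb + ib) * nc * nd;
          for (int t = 0; t <= ax + bx; ++t) {
            double ex = pp1.Ex.get(ax, bx, t);
            if (ex == 0.0) continue;
            for (int u = 0; u <= ay + by; ++u) {
              double ey = pp1.Ey.get(ay, by, u);
              if (ey == 0.0) continue;
              for (int w = 0; w <= az + bz; ++w) {
                double ez = pp1.Ez.get(az, bz, w);
                if (ez == 0.0) continue;
                double e3 = pref * ex * ey * ez;
                size_t mi = ((size_t)t * d1 + u) * d1 + w;
                for (int icd = 0; icd < nc * nd; ++icd)
                  blk[ob + icd] +=
                      e3 * mid[(size_t)icd * d1 * d1 * d1 + mi];
              }
            }
          }
        }
    }
  }
}

// transform cart quartet block to spherical using T matrices (nsph x ncart)
static void sph_quartet(const std::vector<double> &cart, int na, int nb,
                        int nc, int nd, const NumericMatrix &Ta,
                        const NumericMatrix &Tb, const NumericMatrix &Tc,
                        const NumericMatrix &Td, std::vector<double> &out,
                        std::vector<double> &tmp1, std::vector<double> &tmp2) {
  int sa = Ta.nrow(), sb = Tb.nrow(), sc = Tc.nrow(), sd = Td.nrow();
  // index (ia,ib,ic,id) row-major
  tmp1.assign((size_t)sa * nb * nc * nd, 0.0);
  for (int a2 = 0; a2 < sa; ++a2)
    for (int a1 = 0; a1 < na; ++a1) {
      double t = Ta(a2, a1);
      if (t == 0.0) continue;
      const double *src = &cart[(size_t)a1 * nb * nc * nd];
      double *dst = &tmp1[(size_t)a2 * nb * nc * nd];
      for (int r = 0; r < nb * nc * nd; ++r) dst[r] += t * src[r];
    }
  tmp2.assign((size_t)sa * sb * nc * nd, 0.0);
  for (int b2 = 0; b2 < sb; ++b2)
    for (int b1 = 0; b1 < nb; ++b1) {
      double t = Tb(b2, b1);
      if (t == 0.0) continue;
      for (int a2 = 0; a2 < sa; ++a2) {
        const double *src = &tmp1[((size_t)a2 * nb + b1) * nc * nd];
        double *dst = &tmp2[((size_t)a2 * sb + b2) * nc * nd];
        for (int r = 0; r < nc * nd; ++r) dst[r] += t * src[r];
      }
    }
  tmp1.assign((size_t)sa * sb * sc * nd, 0.0);
  for (int c2 = 0; c2 < sc; ++c2)
    for (int c1 = 0; c1 < nc; ++c1) {
      double t = Tc(c2, c1);
      if (t == 0.0) continue;
      for (int ab = 0; ab < sa * sb; ++ab) {
        const double *src = &tmp2[((size_t)ab * nc + c1) * nd];
        double *dst = &tmp1[((size_t)ab * sc + c2) * nd];
        for (int r = 0; r < nd; ++r) dst[r] += t * src[r];
      }
    }
  out.assign((size_t)sa * sb * sc * sd, 0.0);
  for (int d2_ = 0; d2_ < sd; ++d2_)
    for (int d1_ = 0; d1_ < nd; ++d1_) {
      double t = Td(d2_, d1_);
      if (t == 0.0) continue;
      for (int abc = 0; abc < sa * sb * sc; ++abc)
        out[(size_t)abc * sd + d2_] += t * tmp1[(size_t)abc * nd + d1_];
    }
}

static double schwarz_bound(const Shell &A, const Shell &B,
                            const ShellPair &sp, Rtab &R,
                            std::vector<double> &blk) {
  quartet(A, B, A, B, sp, sp, R, blk);
  std::vector<std::array<int,3>> ca, cb;
  cart_comps(A.l, ca); cart_comps(B.l, cb);
  int na = ca.size(), nb = cb.size();
  double mx = 0.0;
  for (int ia = 0; ia < na; ++ia)
    for (int ib = 0; ib < nb; ++ib) {
      size_t idx = (((size_t)ia * nb + ib) * na + ia) * nb + ib;
      double v = std::fabs(blk[idx]);
      if (v > mx) mx = v;
    }
  return std::sqrt(mx);
}

// Full two-electron integral tensor in the spherical AO basis, chemist
// notation (ab|cd); basis 2 may differ from basis 1 (electron-proton blocks).
// tmats[[l+1]] : (2l+1) x ncart(l) solid-harmonic transform, rows scaled so
// the final AOs are normalised (scaling applied on the R side via coefs).
// [[Rcpp::export]]
NumericVector cpp_eri(List shells1, List shells2, List tmats, bool same,
                      double screen_tol) {
  std::vector<Shell> sh1 = parse_shells(shells1);
  std::vector<Shell> sh2 = same ? sh1 : parse_shells(shells2);
  int n1 = 0, n2 = 0;
  std::vector<int> soff1(sh1.size()), soff2(sh2.size());
  for (size_t s = 0; s < sh1.size(); ++s) {
    soff1[s] = n1; n1 += 2 * sh1[s].l + 1;
  }
  for (size_t s = 0; s < sh2.size(); ++s) {
    soff2[s] = n2; n2 += 2 * sh2[s].l + 1;
  }
  std::vector<ShellPair> pr1, pr2;
  make_pairs(sh1, true, pr1);
  if (same) pr2 = pr1; else make_pairs(sh2, true, pr2);
  Rtab R;
  std::vector<double> blk, sph, tmp1, tmp2;
  // Schwarz bounds
  for (auto &sp : pr1)
    sp.schwarz = schwarz_bound(sh1[sp.sa], sh1[sp.sb], sp, R, blk);
  if (same) {
    for (size_t i = 0; i < pr1.size(); ++i) pr2[i].schwarz = pr1[i].schwarz;
  } else {
    for (auto &sp : pr2)
      sp.schwarz = schwarz_bound(sh2[sp.sa], sh2[sp.sb], sp, R, blk);
  }
  NumericVector out((size_t)n1 * n1 * n2 * n2); // zero-initialised
  double *O = out.begin();
  size_t N1 = n1, N2 = n2;
  // helper to write value at (a,b,c,d) with symmetry images
  auto store = [&](int a, int b, int c, int d, double v) {
    O[((size_t)d * N2 + c) * N1 * N1 + (size_t)b * N1 + a] = v;
  };
  for (size_t ip = 0; ip < pr1.size(); ++ip) {
    const ShellPair &spAB = pr1[ip];
    const Shell &A = sh1[spAB.sa], &B = sh1[spAB.sb];
    int sA = 2 * A.l + 1, sB = 2 * B.l + 1;
    size_t jmax = same ? ip + 1 : pr2.size();
    for (size_t jp = 0; jp < jmax; ++jp) {
      const ShellPair &spCD = pr2[jp];
      if (spAB.schwarz * spCD.schwarz < screen_tol) continue;
      const Shell &C = sh2[spCD.sa], &D = sh2[spCD.sb];
      int sC = 2 * C.l + 1, sD = 2 * D.l + 1;
      quartet(A, B, C, D, spAB, spCD, R, blk);
      std::vector<std::array<int,3>> dum;
      int na = ncart(A.l), nb = ncart(B.l), nc = ncart(C.l), nd = ncart(D.l);
      sph_quartet(blk, na, nb, nc, nd, tmats[A.l], tmats[B.l], tmats[C.l],
                  tmats[D.l], sph, tmp1, tmp2);
      for (int ia = 0; ia < sA; ++ia)
        for (int ib = 0; ib < sB; ++ib)
          for (int ic = 0; ic < sC; ++ic)
            for (int id = 0; id < sD; ++id) {
              double v = sph[(((size_t)ia * sB + ib) * sC + ic) * sD + id];
              int a = soff1[spAB.sa] + ia, b = soff1[spAB.sb] + ib;
              int c = soff2[spCD.sa] + ic, d = soff2[spCD.sb] + id;
              store(a, b, c, d, v);
              store(b, a, c, d, v);
              store(a, b, d, c, v);
              store(b, a, d, c, v);
              if (same) {
                store(c, d, a, b, v);
                store(d, c, a, b, v);
                store(c, d, b, a, v);
                store(d, c, b, a, v);
              }
            }
    }
  }
  out.attr("dim") =
      IntegerVector::create(n1, n1, n2, n2);
  return out;
}

// 3-center (mu nu | P) and 2-center (P|Q) Coulomb integrals for density
// fitting: each auxiliary function is paired with a dummy zero-exponent unit
// s "function" (a constant), which turns the 4-index kernel into the desired
// 3-/2-index one.
static void make_aux_pairs(const std::vector<Shell> &aux,
                           std::vector<ShellPair> &pairs,
                           std::vector<Shell> &shwithdummy) {
  // pair i couples aux shell i with a dummy s at the same center
  pairs.clear();
  shwithdummy = aux;
  Shell dummy;
  dummy.l = 0;
  dummy.exps.assign(1, 0.0);
  dummy.coefs.assign(1, 1.0);
  for (size_t s = 0; s < aux.size(); ++s) {
    ShellPair sp;
    sp.sa = (int)s;
    sp.sb = (int)shwithdummy.size(); // the shared dummy appended below
    for (size_t p = 0; p < aux[s].exps.size(); ++p) {
      PairPrim q;
      q.p = aux[s].exps[p];
      for (int k = 0; k < 3; ++k) q.P[k] = aux[s].A[k];
      q.cc = aux[s].coefs[p];
      build_E(aux[s].l, 0, aux[s].exps[p], 0.0, 0.0, q.Ex);
      build_E(aux[s].l, 0, aux[s].exps[p], 0.0, 0.0, q.Ey);
      build_E(aux[s].l, 0, aux[s].exps[p], 0.0, 0.0, q.Ez);
      sp.prims.push_back(std::move(q));
    }
    sp.schwarz = 1.0;
    pairs.push_back(std::move(sp));
  }
  // one shared dummy shell at origin (center irrelevant: exponent 0)
  dummy.A[0] = dummy.A[1] = dummy.A[2] = 0.0;
  shwithdummy.push_back(dummy);
}

// [[Rcpp::export]]
NumericVector cpp_eri_3c(List shells, List shellsAux, List tmats) {
  std::vector<Shell> sh = parse_shells(shells);
  std::vector<Shell> aux = parse_shells(shellsAux);
  int n = 0, naux = 0;
  std::vector<int> soff(sh.size()), aoff(aux.size());
  for (size_t s = 0; s < sh.size(); ++s) { soff[s] = n; n += 2 * sh[s].l + 1; }
  for (size_t s = 0; s < aux.size(); ++s) {
    aoff[s] = naux; naux += 2 * aux[s].l + 1;
  }
  std::vector<ShellPair> pr;
  make_pairs(sh, true, pr);
  std::vector<ShellPair> apr;
  std::vector<Shell> auxd;
  make_aux_pairs(aux, apr, auxd);
  Rtab R;
  std::vector<double> blk, sph, tmp1, tmp2;
  NumericVector out((size_t)n * n * naux);
  double *O = out.begin();
  Shell dummy = auxd.back();
  for (size_t ip = 0; ip < pr.size(); ++ip) {
    const Shell &A = sh[pr[ip].sa], &B = sh[pr[ip].sb];
    int sA = 2 * A.l + 1, sB = 2 * B.l + 1;
    for (size_t jp = 0; jp < apr.size(); ++jp) {
      const Shell &C = aux[jp];
      int sC = 2 * C.l + 1;
      quartet(A, B, C, dummy, pr[ip], apr[jp], R, blk);
      sph_quartet(blk, ncart(A.l), ncart(B.l), ncart(C.l), 1, tmats[A.l],
                  tmats[B.l], tmats[C.l], tmats[0], sph, tmp1, tmp2);
      for (int ia = 0; ia < sA; ++ia)
        for (int ib = 0; ib < sB; ++ib)
          for (int ic = 0; ic < sC; ++ic) {
            double v = sph[((size_t)ia * sB + ib) * sC + ic];
            int a = soff[pr[ip].sa] + ia, b = soff[pr[ip].sb] + ib;
            int c = aoff[jp] + ic;
            O[(size_t)c * n * n + (size_t)b * n + a] = v;
            O[(size_t)c * n * n + (size_t)a * n + b] = v;
          }
    }
  }
  out.attr("dim") = IntegerVector::create(n, n, naux);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_eri_2c(List shellsAux, List tmats) {
  std::vector<Shell> aux = parse_shells(shellsAux);
  int naux = 0;
  std::vector<int> aoff(aux.size());
  for (size_t s = 0; s < aux.size(); ++s) {
    aoff[s] = naux; naux += 2 * aux[s].l + 1;
  }
  std::vector<ShellPair> apr;
  std::vector<Shell> auxd;
  make_aux_pairs(aux, apr, auxd);
  Shell dummy = auxd.back();
  Rtab R;
  std::vector<double> blk, sph, tmp1, tmp2;
  NumericMatrix out(naux, naux);
  for (size_t ip = 0; ip < apr.size(); ++ip) {
    const Shell &A = aux[ip];
    int sA = 2 * A.l + 1;
    for (size_t jp = 0; jp <= ip; ++jp) {
      const Shell &C = aux[jp];
      int sC = 2 * C.l + 1;
      quartet(A, dummy, C, dummy, apr[ip], apr[jp], R, blk);
      sph_quartet(blk, ncart(A.l), 1, ncart(C.l), 1, tmats[A.l], tmats[0],
                  tmats[C.l], tmats[0], sph, tmp1, tmp2);
      for (int ia = 0; ia < sA; ++ia)
        for (int ic = 0; ic < sC; ++ic) {
          double v = sph[(size_t)ia * sC + ic];
          out(aoff[ip] + ia, aoff[jp] + ic) = v;
          out(aoff[jp] + ic, aoff[ip] + ia) = v;
        }
    }
  }
  return out;
}

// J/K build from a full same-basis ERI tensor:
//   J_pq = sum_rs (pq|rs) D_rs ;  K_pq = sum_rs (pr|qs) D_rs
// [[Rcpp::export]]
List cpp_jk(NumericVector eri, int n, NumericMatrix D) {
  NumericMatrix J(n, n), K(n, n);
  const double *E = eri.begin();
  const double *d = D.begin();
  double *j = J.begin(), *k = K.begin();
  size_t N = n;
  for (size_t dd = 0; dd < N; ++dd)
    for (size_t cc = 0; cc < N; ++cc) {
      const double *Eb = E + (dd * N + cc) * N * N;
      double Dcd = d[dd * N + cc];
      for (size_t bb = 0; bb < N; ++bb) {
        const double *Er = Eb + bb * N;
        double Dbd = d[dd * N + bb];
        double *Kc = k + cc * N; // K(a, c) column-major: K[a + n*c]
        for (size_t aa = 0; aa < N; ++aa) {
          double v = Er[aa];
          j[bb * N + aa] += v * Dcd; // J(a,b) += v * D(c,d)
          Kc[aa] += v * Dbd;         // K(a,c) += v * D(b,d)
        }
      }
    }
  return List::create(_["J"] = J, _["K"] = K);
}

// Coulomb coupling from a cross ERI tensor (mu nu | mu' nu') with dims
// (n1,n1,n2,n2):  Ve_{mu nu} = sum (mu nu|m'n') Dp_{m'n'},
//                 Vp_{m'n'}  = sum De_{mu nu} (mu nu|m'n')
// [[Rcpp::export]]
List cpp_cross_j(NumericVector eri, int n1, int n2, NumericMatrix D1,
                 NumericMatrix D2) {
  NumericMatrix V1(n1, n1), V2(n2, n2);
  const double *E = eri.begin();
  const double *d1 = D1.begin(), *d2 = D2.begin();
  double *v1 = V1.begin(), *v2 = V2.begin();
  size_t N1 = n1, N2 = n2;
  for (size_t dd = 0; dd < N2; ++dd)
    for (size_t cc = 0; cc < N2; ++cc) {
      const double *Eb = E + (dd * N2 + cc) * N1 * N1;
      double Dp = d2[dd * N2 + cc];
      double acc = 0.0;
      for (size_t ab = 0; ab < N1 * N1; ++ab) {
        v1[ab] += Eb[ab] * Dp;
        acc += Eb[ab] * d1[ab];
      }
      v2[cc * N2 + dd] += acc; // note: filled at (c,d); tensor symmetric in cd
    }
  // symmetrise V2 (it was accumulated transposed-consistently)
  for (int i = 0; i < n2; ++i)
    for (int jj = 0; jj < i; ++jj) {
      double m = 0.5 * (V2(i, jj) + V2(jj, i));
      V2(i, jj) = m; V2(jj, i) = m;
    }
  return List::create(_["V1"] = V1, _["V2"] = V2);
}

// ---------------------------------------------------------- AO values on grid
// returns values and Cartesian gradients of spherical AOs at grid points
// [[Rcpp::export]]
List cpp_ao_grid(List shells, NumericMatrix pts, List tmats) {
  std::vector<Shell> sh = parse_shells(shells);
  int npt = pts.nrow(), nbf = 0;
  std::vector<int> off(sh.size());
  for (size_t s = 0; s < sh.size(); ++s) {
    off[s] = nbf; nbf += 2 * sh[s].l + 1;
  }
  NumericMatrix val(npt, nbf), gx(npt, nbf), gy(npt, nbf), gz(npt, nbf);
  std::vector<std::array<int,3>> cmp;
  for (size_t s = 0; s < sh.size(); ++s) {
    const Shell &A = sh[s];
    cart_comps(A.l, cmp);
    int nc = cmp.size(), ns = 2 * A.l + 1;
    NumericMatrix T = tmats[A.l];
    std::vector<double> cv(nc), cgx(nc), cgy(nc), cgz(nc);
    for (int ip = 0; ip < npt; ++ip) {
      double x = pts(ip, 0) - A.A[0], y = pts(ip, 1) - A.A[1],
             z = pts(ip, 2) - A.A[2];
      double r2 = x * x + y * y + z * z;
      std::fill(cv.begin(), cv.end(), 0.0);
      std::fill(cgx.begin(), cgx.end(), 0.0);
      std::fill(cgy.begin(), cgy.end(), 0.0);
      std::fill(cgz.begin(), cgz.end(), 0.0);
      for (size_t pp = 0; pp < A.exps.size(); ++pp) {
        double a = A.exps[pp];
        double e = A.coefs[pp] * std::exp(-a * r2);
        if (e == 0.0) continue;
        for (int ic = 0; ic < nc; ++ic) {
          int i = cmp[ic][0], jj = cmp[ic][1], kk = cmp[ic][2];
          double xi = 1.0, yj = 1.0, zk = 1.0;
          for (int t = 0; t < i; ++t) xi *= x;
          for (int t = 0; t < jj; ++t) yj *= y;
          for (int t = 0; t < kk; ++t) zk *= z;
          double mono = xi * yj * zk;
          cv[ic] += e * mono;
          double dx;
          if (i > 0) {
            double xim = 1.0;
            for (int t = 0; t < i - 1; ++t) xim *= x;
            dx = (i * xim - 2.0 * a * x * xi) * yj * zk;
          } else dx = -2.0 * a * x * mono;
          double dy;
          if (jj > 0) {
            double yjm = 1.0;
            for (int t = 0; t < jj - 1; ++t) yjm *= y;
            dy = (jj * yjm - 2.0 * a * y * yj) * xi * zk;
          } else dy = -2.0 * a * y * mono;
          double dz;
          if (kk > 0) {
            double zkm = 1.0;
            for (int t = 0; t < kk - 1; ++t) zkm *= z;
            dz = (kk * zkm - 2.0 * a * z * zk) * xi * yj;
          } else dz = -2.0 * a * z * mono;
          cgx[ic] += e * dx;
          cgy[ic] += e * dy;
          cgz[ic] += e * dz;
        }
      }
      for (int is = 0; is < ns; ++is) {
        double av = 0, ax = 0, ay = 0, az = 0;
        for (int ic = 0; ic < nc; ++ic) {
          double t = T(is, ic);
          if (t == 0.0) continue;
          av += t * cv[ic]; ax += t * cgx[ic];
          ay += t * cgy[ic]; az += t * cgz[ic];
        }
        val(ip, off[s] + is) = av;
        gx(ip, off[s] + is) = ax;
        gy(ip, off[s] + is) = ay;
        gz(ip, off[s] + is) = az;
      }
    }
  }
  return List::create(_["val"] = val, _["dx"] = gx, _["dy"] = gy,
                      _["dz"] = gz);
}

// -------------------------------------------------------------- Becke weights
// Standard Becke partition weights (k = 3 iterations of the cell function)
// with Bragg-radius size adjustment. pts: n x 3, owner: 0-based center index
// of each point, centers: m x 3, radii: m Bragg radii (bohr).
// [[Rcpp::export]]
NumericVector cpp_becke_weights(NumericMatrix pts, IntegerVector owner,
                                NumericMatrix centers, NumericVector radii) {
  int np = pts.nrow(), m = centers.nrow();
  NumericVector w(np);
  std::vector<double> P(m);
  // precompute inter-center distances and size-adjust parameters
  std::vector<double> Rij(m * m), aij(m * m);
  for (int i = 0; i < m; ++i)
    for (int jj = 0; jj < m; ++jj) {
      double s = 0;
      for (int k = 0; k < 3; ++k) {
        double d = centers(i, k) - centers(jj, k);
        s += d * d;
      }
      Rij[i * m + jj] = std::sqrt(s);
      double chi = radii[i] / radii[jj];
      double u = (chi - 1.0) / (chi + 1.0);
      double a = u / (u * u - 1.0);
      if (a > 0.45) a = 0.45;
      if (a < -0.45) a = -0.45;
      aij[i * m + jj] = a;
    }
  for (int ip = 0; ip < np; ++ip) {
    double px = pts(ip, 0), py = pts(ip, 1), pz = pts(ip, 2);
    std::vector<double> r(m);
    for (int i = 0; i < m; ++i) {
      double dx = px - centers(i, 0), dy = py - centers(i, 1),
             dz = pz - centers(i, 2);
      r[i] = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
    double tot = 0.0;
    for (int i = 0; i < m; ++i) {
      double p = 1.0;
      for (int jj = 0; jj < m; ++jj) {
        if (jj == i) continue;
        double mu = (r[i] - r[jj]) / Rij[i * m + jj];
        mu = mu + aij[i * m + jj] * (1.0 - mu * mu);
        for (int k = 0; k < 3; ++k) mu = 1.5 * mu - 0.5 * mu * mu * mu;
        p *= 0.5 * (1.0 - mu);
      }
      P[i] = p;
      tot += p;
    }
    w[ip] = (tot > 0.0) ? P[owner[ip]] / tot : 0.0;
  }
  return w;
}
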