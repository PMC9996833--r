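// McMurchie-Davidson evaluation of Gaussian integrals over contracted
// cartesian shells (l <= 2), assembled into spherical-harmonic AO matrices.
// Normalization of the contracted functions is finalized on the R side by
// scaling with 1/sqrt(diag(S)); within-shell component ratios are exact here.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double PI = 3.141592653589793238462643383279502884;

// ---------------------------------------------------------------------------
// Boys function F_m(x), m = 0..mmax
static void boys(int mmax, double x, std::vector<double> &F) {
  F.assign(mmax + 1, 0.0);
  if (x > 35.0) {
    // asymptotic + upward recursion (stable for large x)
    F[0] = 0.5 * std::sqrt(PI / x) * std::erf(std::sqrt(x));
    double ex = (x > 700.0) ? 0.0 : std::exp(-x);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - ex) / (2.0 * x);
  } else {
    // series for F_mmax, then downward recursion
    double ex = std::exp(-x);
    double term = 1.0 / (2.0 * mmax + 1.0);
    double sum = term;
    for (int k = 1; k < 300; ++k) {
      term *= 2.0 * x / (2.0 * mmax + 2.0 * k + 1.0);
      sum += term;
      if (term < 1e-17 * sum) break;
    }
    F[mmax] = ex * sum;
    for (int m = mmax; m > 0; --m)
      F[m - 1] = (2.0 * x * F[m] + ex) / (2.0 * m - 1.0);
  }
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficients E_t^{ij} for one cartesian dimension.
// Flattened table: E[(i*(jmax+1) + j)*(imax+jmax+1) + t]
struct ETab {
  int imax, jmax, tdim;
  std::vector<double> v;
  double at(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(size_t)(i * (jmax + 1) + j) * tdim + t];
  }
};

static ETab etable(int imax, int jmax, double a, double b, double A, double B) {
  ETab E;
  E.imax = imax; E.jmax = jmax; E.tdim = imax + jmax + 1;
  E.v.assign((size_t)(imax + 1) * (jmax + 1) * E.tdim, 0.0);
  double p = a + b;
  double q = a * b / p;
  double P = (a * A + b * B) / p;
  double PA = P - A, PB = P - B, AB = A - B;
  auto set = [&](int i, int j, int t, double val) {
    E.v[(size_t)(i * (jmax + 1) + j) * E.tdim + t] = val;
  };
  set(0, 0, 0, std::exp(-q * AB * AB));
  // build up i at j = 0
  for (int i = 1; i <= imax; ++i)
    for (int t = 0; t <= i; ++t) {
      double val = 0.0;
      if (t > 0)     val += E.at(i - 1, 0, t - 1) / (2.0 * p);
      val += PA * E.at(i - 1, 0, t);
      val += (t + 1.0) * E.at(i - 1, 0, t + 1);
      set(i, 0, t, val);
    }
  // build up j for each i
  for (int i = 0; i <= imax; ++i)
    for (int j = 1; j <= jmax; ++j)
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (t > 0)   val += E.at(i, j - 1, t - 1) / (2.0 * p);
        val += PB * E.at(i, j - 1, t);
        val += (t + 1.0) * E.at(i, j - 1, t + 1);
        set(i, j, t, val);
      }
  return E;
}

// ---------------------------------------------------------------------------
// Hermite Coulomb integrals R_{t,u,v} (n = 0) at argument (p, PC)
struct RTab {
  int tmax, umax, vmax;
  std::vector<double> v; // [t][u][v]
  double at(int t, int u, int w) const {
    return v[(size_t)(t * (umax + 1) + u) * (vmax + 1) + w];
  }
};

static RTab rtable(int tmax, int umax, int vmax, double p,
                   double X, double Y, double Z) {
  int nmax = tmax + umax + vmax;
  double T = p * (X * X + Y * Y + Z * Z);
  std::vector<double> F;
  boys(nmax, T, F);
  // R^n_{000} = (-2p)^n F_n
  // recursion on full 4D table [n][t][u][v]
  int td = tmax + 1, ud = umax + 1, vd = vmax + 1;
  std::vector<double> R((size_t)(nmax + 1) * td * ud * vd, 0.0);
  auto idx = [&](int n, int t, int u, int w) {
    return (((size_t)n * td + t) * ud + u) * vd + w;
  };
  double m2p = 1.0;
  for (int n = 0; n <= nmax; ++n) { R[idx(n, 0, 0, 0)] = m2p * F[n]; m2p *= -2.0 * p; }
  for (int n = nmax - 1; n >= 0; --n) {
    int lev = nmax - n; // max t+u+v we need at this n
    for (int t = 0; t <= std::min(tmax, lev); ++t)
      for (int u = 0; u <= std::min(umax, lev - t); ++u)
        for (int w = 0; w <= std::min(vmax, lev - t - u); ++w) {
          if (t + u + w == 0) continue;
          double val;
          if (t > 0) {
            val = X * R[idx(n + 1, t - 1, u, w)];
            if (t > 1) val += (t - 1.0) * R[idx(n + 1, t - 2, u, w)];
          } else if (u > 0) {
            val = Y * R[idx(n + 1, t, u - 1, w)];
            if (u > 1) val += (u - 1.0) * R[idx(n + 1, t, u - 2, w)];
          } else {
            val = Z * R[idx(n + 1, t, u, w - 1)];
            if (w > 1) val += (w - 1.0) * R[idx(n + 1, t, u, w - 2)];
          }
          R[idx(n, t, u, w)] = val;
        }
  }
  RTab out;
  out.tmax = tmax; out.umax = umax; out.vmax = vmax;
  out.v.assign((size_t)td * ud * vd, 0.0);
  for (int t = 0; t <= tmax; ++t)
    for (int u = 0; u <= umax; ++u)
      for (int w = 0; w <= vmax; ++w)
        out.v[(size_t)(t * ud + u) * vd + w] = R[idx(0, t, u, w)];
  return out;
}

// ---------------------------------------------------------------------------
// shell bookkeeping
struct Shell {
  int l;
  double x, y, z;
  std::vector<double> ex;  // primitive exponents
  std::vector<double> cf;  // contraction coefs * primitive (l,0,0) norms
  int cart0;               // offset in cartesian AO list
};

static int ncart(int l) { return (l + 1) * (l + 2) / 2; }

// cartesian component exponents, canonical order
static void cartcomp(int l, std::vector<int> &lx, std::vector<int> &ly,
                     std::vector<int> &lz) {
  lx.clear(); ly.clear(); lz.clear();
  for (int a = l; a >= 0; --a)
    for (int b = l - a; b >= 0; --b) {
      lx.push_back(a); ly.push_back(b); lz.push_back(l - a - b);
    }
}

static double dfact(int n) { // (2n-1)!!
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

static double primnorm(double a, int l) {
  return std::pow(2.0 * a / PI, 0.75) * std::pow(4.0 * a, 0.5 * l) /
         std::sqrt(dfact(l));
}

static std::vector<Shell> unpack_shells(List shells) {
  IntegerVector l = shells["l"];
  NumericMatrix xyz = shells["center"]; // nshell x 3, bohr
  List ex = shells["exponents"];
  List cf = shells["coefficients"];
  int ns = l.size();
  std::vector<Shell> out(ns);
  int off = 0;
  for (int i = 0; i < ns; ++i) {
    out[i].l = l[i];
    out[i].x = xyz(i, 0); out[i].y = xyz(i, 1); out[i].z = xyz(i, 2);
    NumericVector e = ex[i], c = cf[i];
    out[i].ex.assign(e.begin(), e.end());
    out[i].cf.resize(c.size());
    for (int k = 0; k < c.size(); ++k)
      out[i].cf[k] = c[k] * primnorm(e[k], l[i]);
    out[i].cart0 = off;
    off += ncart(l[i]);
  }
  return out;
}

static int ncart_total(const std::vector<Shell> &sh) {
  int n = 0;
  for (auto &s : sh) n += ncart(s.l);
  return n;
}

// ---------------------------------------------------------------------------
// one-electron integrals (cartesian basis)
// [[Rcpp::export(name = ".cpp_one_electron")]]
List cpp_one_electron(List shells, NumericMatrix atom_xyz, NumericVector Zval) {
  std::vector<Shell> sh = unpack_shells(shells);
  int ns = sh.size();
  int nb = ncart_total(sh);
  NumericMatrix S(nb, nb), T(nb, nb), V(nb, nb);
  std::vector<int> lxa, lya, lza, lxb, lyb, lzb;

  for (int is = 0; is < ns; ++is) {
    const Shell &A = sh[is];
    cartcomp(A.l, lxa, lya, lza);
    for (int js = 0; js <= is; ++js) {
      const Shell &B = sh[js];
      cartcomp(B.l, lxb, lyb, lzb);
      int na = ncart(A.l), nbb = ncart(B.l);
      std::vector<double> Sblk(na * nbb, 0.0), Tblk(na * nbb, 0.0),
          Vblk(na * nbb, 0.0);
      for (size_t ip = 0; ip < A.ex.size(); ++ip)
        for (size_t jp = 0; jp < B.ex.size(); ++jp) {
          double a = A.ex[ip], b = B.ex[jp];
          double cc = A.cf[ip] * B.cf[jp];
          double p = a + b;
          double Px = (a * A.x + b * B.x) / p;
          double Py = (a * A.y + b * B.y) / p;
          double Pz = (a * A.z + b * B.z) / p;
          // tables with +2 margin on j for the kinetic formula
          ETab Ex = etable(A.l, B.l + 2, a, b, A.x, B.x);
          ETab Ey = etable(A.l, B.l + 2, a, b, A.y, B.y);
          ETab Ez = etable(A.l, B.l + 2, a, b, A.z, B.z);
          double sqp = std::sqrt(PI / p);
          auto s1 = [&](const ETab &E, int i, int j) {
            if (i < 0 || j < 0) return 0.0;
            return E.at(i, j, 0) * sqp;
          };
          auto k1 = [&](const ETab &E, int i, int j) {
            double val = -2.0 * b * b * s1(E, i, j + 2) +
                         b * (2.0 * j + 1.0) * s1(E, i, j);
            if (j >= 2) val -= 0.5 * j * (j - 1.0) * s1(E, i, j - 2);
            return val;
          };
          for (int ia = 0; ia < na; ++ia)
            for (int ib = 0; ib < nbb; ++ib) {
              double sx = s1(Ex, lxa[ia], lxb[ib]);
              double sy = s1(Ey, lya[ia], lyb[ib]);
              double sz = s1(Ez, lza[ia], lzb[ib]);
              double tx = k1(Ex, lxa[ia], lxb[ib]);
              double ty = k1(Ey, lya[ia], lyb[ib]);
              double tz = k1(Ez, lza[ia], lzb[ib]);
              Sblk[ia * nbb + ib] += cc * sx * sy * sz;
              Tblk[ia * nbb + ib] += cc * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
              // nuclear attraction
              int tmax = lxa[ia] + lxb[ib], umax = lya[ia] + lyb[ib],
                  vmax = lza[ia] + lzb[ib];
              for (int ic = 0; ic < atom_xyz.nrow(); ++ic) {
                RTab R = rtable(tmax, umax, vmax, p, Px - atom_xyz(ic, 0),
                                Py - atom_xyz(ic, 1), Pz - atom_xyz(ic, 2));
                double acc = 0.0;
                for (int t = 0; t <= tmax; ++t)
                  for (int u = 0; u <= umax; ++u)
                    for (int w = 0; w <= vmax; ++w)
                      acc += Ex.at(lxa[ia], lxb[ib], t) *
                             Ey.at(lya[ia], lyb[ib], u) *
                             Ez.at(lza[ia], lzb[ib], w) * R.at(t, u, w);
                Vblk[ia * nbb + ib] += -Zval[ic] * cc * 2.0 * PI / p * acc;
              }
            }
        }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nbb; ++ib) {
          int r = A.cart0 + ia, cix = B.cart0 + ib;
          S(r, cix) = Sblk[ia * nbb + ib]; S(cix, r) = S(r, cix);
          T(r, cix) = Tblk[ia * nbb + ib]; T(cix, r) = T(r, cix);
          V(r, cix) = Vblk[ia * nbb + ib]; V(cix, r) = V(r, cix);
        }
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

// ---------------------------------------------------------------------------
// electron repulsion integrals, full cartesian N^4 array, chemist (pq|rs)
// [[Rcpp::export(name = ".cpp_eri")]]
NumericVector cpp_eri(List shells) {
  std::vector<Shell> sh = unpack_shells(shells);
  int ns = sh.size();
  int nb = ncart_total(sh);
  NumericVector out((R_xlen_t)nb * nb * nb * nb);
  auto O = [&](int p, int q, int r, int s) -> double & {
    return out[((R_xlen_t)((R_xlen_t)s * nb + r) * nb + q) * nb + p];
  };
  std::vector<int> lx1, ly1, lz1, lx2, ly2, lz2, lx3, ly3, lz3, lx4, ly4, lz4;

  for (int is = 0; is < ns; ++is) {
    const Shell &A = sh[is];
    cartcomp(A.l, lx1, ly1, lz1);
    for (int js = 0; js <= is; ++js) {
      const Shell &B = sh[js];
      cartcomp(B.l, lx2, ly2, lz2);
      for (int ks = 0; ks <= is; ++ks) {
        const Shell &Cs = sh[ks];
        cartcomp(Cs.l, lx3, ly3, lz3);
        int lmax = (ks == is) ? js : ks;
        for (int ls = 0; ls <= lmax; ++ls) {
          const Shell &D = sh[ls];
          cartcomp(D.l, lx4, ly4, lz4);
          int n1 = ncart(A.l), n2 = ncart(B.l), n3 = ncart(Cs.l), n4 = ncart(D.l);
          std::vector<double> blk((size_t)n1 * n2 * n3 * n4, 0.0);
          for (size_t ip = 0; ip < A.ex.size(); ++ip)
            for (size_t jp = 0; jp < B.ex.size(); ++jp) {
              double a = A.ex[ip], b = B.ex[jp];
              double p = a + b;
              double Px = (a * A.x + b * B.x) / p;
              double Py = (a * A.y + b * B.y) / p;
              double Pz = (a * A.z + b * B.z) / p;
              ETab Ex1 = etable(A.l, B.l, a, b, A.x, B.x);
              ETab Ey1 = etable(A.l, B.l, a, b, A.y, B.y);
              ETab Ez1 = etable(A.l, B.l, a, b, A.z, B.z);
              double cab = A.cf[ip] * B.cf[jp];
              for (size_t kp = 0; kp < Cs.ex.size(); ++kp)
                for (size_t lp = 0; lp < D.ex.size(); ++lp) {
                  double c = Cs.ex[kp], d = D.ex[lp];
                  double q = c + d;
                  double Qx = (c * Cs.x + d * D.x) / q;
                  double Qy = (c * Cs.y + d * D.y) / q;
                  double Qz = (c * Cs.z + d * D.z) / q;
                  ETab Ex2 = etable(Cs.l, D.l, c, d, Cs.x, D.x);
                  ETab Ey2 = etable(Cs.l, D.l, c, d, Cs.y, D.y);
                  ETab Ez2 = etable(Cs.l, D.l, c, d, Cs.z, D.z);
                  double ccd = Cs.cf[kp] * D.cf[lp];
                  double alpha = p * q / (p + q);
                  int tmax = A.l + B.l, umax = tmax, vmax = tmax;
                  int t2max = Cs.l + D.l;
                  RTab R = rtable(tmax + t2max, umax + t2max, vmax + t2max,
                                  alpha, Px - Qx, Py - Qy, Pz - Qz);
                  double pref = 2.0 * std::pow(PI, 2.5) /
                                (p * q * std::sqrt(p + q)) * cab * ccd;
                  for (int i1 = 0; i1 < n1; ++i1)
                    for (int i2 = 0; i2 < n2; ++i2)
                      for (int i3 = 0; i3 < n3; ++i3)
                        for (int i4 = 0; i4 < n4; ++i4) {
                          double acc = 0.0;
                          int tm = lx1[i1] + lx2[i2], um = ly1[i1] + ly2[i2],
                              vm = lz1[i1] + lz2[i2];
                          int tm2 = lx3[i3] + lx4[i4], um2 = ly3[i3] + ly4[i4],
                              vm2 = lz3[i3] + lz4[i4];
                          for (int t = 0; t <= tm; ++t) {
                            double ex1 = Ex1.at(lx1[i1], lx2[i2], t);
                            if (ex1 == 0.0) continue;
                            for (int u = 0; u <= um; ++u) {
                              double ey1 = Ey1.at(ly1[i1], ly2[i2], u);
                              if (ey1 == 0.0) continue;
                              for (int w = 0; w <= vm; ++w) {
                                double ez1 = Ez1.at(lz1[i1], lz2[i2], w);
                                if (ez1 == 0.0) continue;
                                double e1 = ex1 * ey1 * ez1;
                                for (int t2 = 0; t2 <= tm2; ++t2) {
                                  double ex2 = Ex2.at(lx3[i3], lx4[i4], t2);
                                  if (ex2 == 0.0) continue;
                                  for (int u2 = 0; u2 <= um2; ++u2) {
                                    double ey2 = Ey2.at(ly3[i3], ly4[i4], u2);
                                    if (ey2 == 0.0) continue;
                                    for (int w2 = 0; w2 <= vm2; ++w2) {
                                      double ez2 = Ez2.at(lz3[i3], lz4[i4], w2);
                                      if (ez2 == 0.0) continue;
                                      double sgn = ((t2 + u2 + w2) % 2) ? -1.0 : 1.0;
                                      acc += e1 * ex2 * ey2 * ez2 * sgn *
                                             R.at(t + t2, u + u2, w + w2);
                                    }
                                  }
                                }
                              }
                            }
                          }
                          blk[(((size_t)i1 * n2 + i2) * n3 + i3) * n4 + i4] +=
                              pref * acc;
                        }
                }
            }
          // scatter with 8-fold permutational symmetry
          for (int i1 = 0; i1 < n1; ++i1)
            for (int i2 = 0; i2 < n2; ++i2)
              for (int i3 = 0; i3 < n3; ++i3)
                for (int i4 = 0; i4 < n4; ++i4) {
                  double val = blk[(((size_t)i1 * n2 + i2) * n3 + i3) * n4 + i4];
                  int p = A.cart0 + i1, qq = B.cart0 + i2,
                      r = Cs.cart0 + i3, s = D.cart0 + i4;
                  O(p, qq, r, s) = val; O(qq, p, r, s) = val;
                  O(p, qq, s, r) = val; O(qq, p, s, r) = val;
                  O(r, s, p, qq) = val; O(s, r, p, qq) = val;
                  O(r, s, qq, p) = val; O(s, r, qq, p) = val;
                }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nb, nb, nb, nb);
  return out;
}
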