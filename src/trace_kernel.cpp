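// Pathline integration kernel: RK4 with mask-weight-normalised trilinear
// spatial and linear cyclic temporal interpolation, valve-disc crossing
// detection and dilated-mask truncation. Mirrors the documented semantics of
// trace_pathlines(); kept in C++ because per-particle interpolation
// dominates the cost of flow-component analysis.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Frames {
  int nx, ny, nz, nt;
  std::vector<const double*> vx, vy, vz, w;
  std::vector<const int*> dil;
  double hx, hy, hz;
  std::vector<double> times;
  double rr;
};

struct Bracket {
  int k, kp;
  double alpha;
};

inline double cyc(double t, double rr) {
  double r = t - std::floor(t / rr) * rr;
  if (r < 0) r += rr;
  if (r >= rr) r -= rr;
  return r;
}

inline Bracket bracket(const Frames& F, double tau) {
  double t = cyc(tau, F.rr);
  int k = F.nt - 1;
  for (int i = F.nt - 1; i >= 0; --i) {
    if (F.times[i] <= t + 1e-15) { k = i; break; }
  }
  int kp = (k == F.nt - 1) ? 0 : k + 1;
  double tk = F.times[k];
  double tn = (k == F.nt - 1) ? F.times[0] + F.rr : F.times[kp];
  Bracket b;
  b.k = k; b.kp = kp;
  b.alpha = (t - tk) / (tn - tk);
  return b;
}

// mask-normalised trilinear sample of one frame at voxel coords (ui,uj,uk)
inline void sample_frame(const Frames& F, int k, double ui, double uj, double uk,
                         double out[3]) {
  int i0 = (int)std::floor(ui), j0 = (int)std::floor(uj), k0 = (int)std::floor(uk);
  i0 = std::min(std::max(i0, 1), F.nx - 1);
  j0 = std::min(std::max(j0, 1), F.ny - 1);
  k0 = std::min(std::max(k0, 1), F.nz - 1);
  double fi = ui - i0, fj = uj - j0, fk = uk - k0;
  fi = std::min(std::max(fi, 0.0), 1.0);
  fj = std::min(std::max(fj, 0.0), 1.0);
  fk = std::min(std::max(fk, 0.0), 1.0);
  const double* vx = F.vx[k];
  const double* vy = F.vy[k];
  const double* vz = F.vz[k];
  const double* w3 = F.w[k];
  long nx = F.nx, nxy = (long)F.nx * F.ny;
  long base = (i0 - 1) + (long)(j0 - 1) * nx + (long)(k0 - 1) * nxy;
  double a1 = 0, a2 = 0, a3 = 0, wacc = 0;
  for (int di = 0; di <= 1; ++di) {
    double wi = di ? fi : 1 - fi;
    for (int dj = 0; dj <= 1; ++dj) {
      double wij = wi * (dj ? fj : 1 - fj);
      for (int dk = 0; dk <= 1; ++dk) {
        double wgt = wij * (dk ? fk : 1 - fk);
        long idx = base + di + (long)dj * nx + (long)dk * nxy;
        double wm = wgt * w3[idx];
        wacc += wm;
        a1 += wm * vx[idx];
        a2 += wm * vy[idx];
        a3 += wm * vz[idx];
      }
    }
  }
  if (wacc > 1e-12) {
    out[0] = a1 / wacc; out[1] = a2 / wacc; out[2] = a3 / wacc;
  } else {
    out[0] = out[1] = out[2] = 0;
  }
}

// velocity (m/s) at grid-frame position p (mm) and cyclic time tau
inline void vel_at(const Frames& F, const double p[3], double tau, double v[3]) {
  Bracket b = bracket(F, tau);
  double ui = p[0] / F.hx + 1, uj = p[1] / F.hy + 1, uk = p[2] / F.hz + 1;
  double v0[3], v1[3];
  sample_frame(F, b.k, ui, uj, uk, v0);
  sample_frame(F, b.kp, ui, uj, uk, v1);
  for (int c = 0; c < 3; ++c) v[c] = (1 - b.alpha) * v0[c] + b.alpha * v1[c];
}

struct Disc {
  double c[3], n[3], r;
};

inline Disc disc_at(const Frames& F, const NumericMatrix& centers,
                    const NumericMatrix& normals, const NumericVector& radii,
                    double tau) {
  Bracket b = bracket(F, tau);
  Disc d;
  double nn = 0;
  for (int c = 0; c < 3; ++c) {
    d.c[c] = (1 - b.alpha) * centers(b.k, c) + b.alpha * centers(b.kp, c);
    d.n[c] = (1 - b.alpha) * normals(b.k, c) + b.alpha * normals(b.kp, c);
    nn += d.n[c] * d.n[c];
  }
  nn = std::sqrt(nn);
  for (int c = 0; c < 3; ++c) d.n[c] /= nn;
  d.r = (1 - b.alpha) * radii[b.k] + b.alpha * radii[b.kp];
  return d;
}

}  // namespace

// [[Rcpp::export(name = ".trace_kernel")]]
List trace_kernel(List vel, List w3, List dil,
                  IntegerVector dims, NumericVector spacing,
                  NumericVector times, double rr, NumericVector vmax,
                  Nullable<List> discs_,
                  NumericMatrix seeds, double t_start, double duration,
                  int dirsgn, double substep_frac, int record_every) {
  Frames F;
  F.nx = dims[0]; F.ny = dims[1]; F.nz = dims[2]; F.nt = vel.size();
  F.hx = spacing[0]; F.hy = spacing[1]; F.hz = spacing[2];
  F.times = as<std::vector<double> >(times);
  F.rr = rr;
  for (int k = 0; k < F.nt; ++k) {
    List vk = vel[k];
    F.vx.push_back(REAL(as<NumericVector>(vk[0])));
    F.vy.push_back(REAL(as<NumericVector>(vk[1])));
    F.vz.push_back(REAL(as<NumericVector>(vk[2])));
    F.w.push_back(REAL(as<NumericVector>(w3[k])));
    F.dil.push_back(LOGICAL(as<LogicalVector>(dil[k])));
  }

  bool have_discs = discs_.isNotNull();
  NumericMatrix mc, mn, ac, an;
  NumericVector mr, ar;
  if (have_discs) {
    List discs(discs_);
    List m = discs["mitral"], a = discs["aortic"];
    mc = as<NumericMatrix>(m["centers"]); mn = as<NumericMatrix>(m["normals"]);
    mr = as<NumericVector>(m["radii"]);
    ac = as<NumericMatrix>(a["centers"]); an = as<NumericMatrix>(a["normals"]);
    ar = as<NumericVector>(a["radii"]);
  }

  int n = seeds.nrow();
  NumericMatrix pos(clone(seeds));
  IntegerVector status(n, 0);  // 0 complete, 1 mitral, 2 aortic, 3 truncated
  NumericVector event_time(n, NA_REAL);
  std::vector<char> active(n, 1);
  int n_active = n;

  double hmin = std::min(F.hx, std::min(F.hy, F.hz));
  double min_dt = F.rr;
  for (int k = 0; k < F.nt; ++k) {
    double next_t = (k == F.nt - 1) ? F.times[0] + F.rr : F.times[k + 1];
    min_dt = std::min(min_dt, next_t - F.times[k]);
  }

  std::vector<double> rec_pos, rec_t;
  int step = 0;
  double elapsed = 0;
  const double eps = 1e-9;

  while (elapsed < duration - 1e-12 && n_active > 0) {
    double tau = cyc(t_start + dirsgn * elapsed, F.rr);
    Bracket br = bracket(F, tau);
    double vm = std::max(std::max(vmax[br.k], vmax[br.kp]), 1e-6);
    double dt = std::min(substep_frac * hmin / (vm * 1e3),
                         std::min(min_dt / 2, duration - elapsed));
    double sd = dirsgn * dt;

    Disc dm, da;
    if (have_discs) {
      dm = disc_at(F, mc, mn, mr, tau + sd / 2);
      da = disc_at(F, ac, an, ar, tau + sd / 2);
    }
    Bracket brn = bracket(F, tau + sd);
    int knear = (brn.alpha < 0.5) ? brn.k : brn.kp;
    const int* diln = F.dil[knear];

    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      double p0[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
      double k1[3], k2[3], k3[3], k4[3], q[3], p1[3];
      vel_at(F, p0, tau, k1);
      for (int c = 0; c < 3; ++c) q[c] = p0[c] + 0.5 * sd * 1e3 * k1[c];
      vel_at(F, q, tau + sd / 2, k2);
      for (int c = 0; c < 3; ++c) q[c] = p0[c] + 0.5 * sd * 1e3 * k2[c];
      vel_at(F, q, tau + sd / 2, k3);
      for (int c = 0; c < 3; ++c) q[c] = p0[c] + sd * 1e3 * k3[c];
      vel_at(F, q, tau + sd, k4);
      for (int c = 0; c < 3; ++c) {
        p1[c] = p0[c] + sd * 1e3 * (k1[c] + 2 * k2[c] + 2 * k3[c] + k4[c]) / 6;
      }

      bool crossed = false;
      if (have_discs) {
        const Disc* dd[2] = {&dm, &da};
        for (int vvi = 0; vvi < 2; ++vvi) {
          const Disc& D = *dd[vvi];
          double cn = D.c[0] * D.n[0] + D.c[1] * D.n[1] + D.c[2] * D.n[2];
          double s0 = p0[0] * D.n[0] + p0[1] * D.n[1] + p0[2] * D.n[2] - cn;
          double s1 = p1[0] * D.n[0] + p1[1] * D.n[1] + p1[2] * D.n[2] - cn;
          bool hit = (s0 > eps && s1 <= -eps) || (s0 < -eps && s1 >= eps) ||
                     (std::fabs(s0) <= eps && s1 < -eps);
          if (!hit) continue;
          double f = std::fabs(s0) / std::max(std::fabs(s0) + std::fabs(s1), 1e-12);
          double qq[3], dc[3];
          for (int c = 0; c < 3; ++c) qq[c] = p0[c] + f * (p1[c] - p0[c]);
          for (int c = 0; c < 3; ++c) dc[c] = qq[c] - D.c[c];
          double d2 = dc[0] * dc[0] + dc[1] * dc[1] + dc[2] * dc[2];
          double dn = dc[0] * D.n[0] + dc[1] * D.n[1] + dc[2] * D.n[2];
          if (d2 - dn * dn <= D.r * D.r) {
            status[i] = vvi + 1;
            event_time[i] = tau + sd * f;
            for (int c = 0; c < 3; ++c) pos(i, c) = qq[c];
            crossed = true;
          }
        }
      }
      if (crossed) {
        active[i] = 0; --n_active;
        continue;
      }
      for (int c = 0; c < 3; ++c) pos(i, c) = p1[c];
      // truncation: outside the 1-voxel-dilated mask at the nearest frame
      int ii = (int)std::lround(p1[0] / F.hx);
      int jj = (int)std::lround(p1[1] / F.hy);
      int kk = (int)std::lround(p1[2] / F.hz);
      bool oob = p1[0] < -F.hx || p1[0] > F.nx * F.hx ||
                 p1[1] < -F.hy || p1[1] > F.ny * F.hy ||
                 p1[2] < -F.hz || p1[2] > F.nz * F.hz;
      ii = std::min(std::max(ii, 0), F.nx - 1);
      jj = std::min(std::max(jj, 0), F.ny - 1);
      kk = std::min(std::max(kk, 0), F.nz - 1);
      long lin = ii + (long)jj * F.nx + (long)kk * F.nx * F.ny;
      if (oob || !diln[lin]) {
        status[i] = 3;
        event_time[i] = tau + sd;
        active[i] = 0; --n_active;
      }
    }

    elapsed += dt;
    ++step;
    if (record_every > 0 && step % record_every == 0) {
      rec_t.push_back(elapsed);
      for (int c = 0; c < 3; ++c) {
        for (int i = 0; i < n; ++i) rec_pos.push_back(pos(i, c));
      }
    }
  }

  List out = List::create(_["positions"] = pos, _["status"] = status,
                          _["event_time"] = event_time);
  if (record_every > 0) {
    int nrec = rec_t.size();
    NumericVector arr(rec_pos.begin(), rec_pos.end());
    if (nrec > 0) arr.attr("dim") = IntegerVector::create(n, 3, nrec);
    out["record_positions"] = arr;
    out["record_elapsed"] = NumericVector(rec_t.begin(), rec_t.end());
  }
  return out;
}
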