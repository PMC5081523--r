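// Langevin dynamics engine for the coarse-grained chromatin bead-spring model.
//
// Internal units: length nm, energy eps (= kT at reference temperature),
// mass 1. With sigma = 30 nm and m = eps = 1 the intrinsic time unit
// tau_LJ = sigma * sqrt(m/eps) equals 30 internal time units; R wrappers
// convert durations expressed in tau_LJ accordingly.
//
// Force field (Kremer-Grest chain):
//   - FENE bonds between consecutive beads of a chain
//   - WCA excluded volume between all bead pairs (cell-list accelerated)
//   - Kratky-Porod bending U = kappa * (1 - cos theta)
//   - harmonic confining wall active beyond R_nuc - sigma/2, force capped
//     (the capped branch doubles as the radial compressive force that pulls
//     protruding beads back inside)
//   - attractive cut-shifted LJ between centromeric beads of the same chain
//   - harmonic centre-of-mass restraints with linearly ramped spring
//     constants, a piecewise-constant equilibrium-distance schedule and a
//     per-restraint force cap
//
// Integrator: BAOAB splitting of underdamped Langevin dynamics; with
// gamma = 0 and T = 0 noise it reduces to velocity Verlet (NVE).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Params {
  double sigma;
  double feneK, feneR0;
  double kappa;
  double rnuc, wallK, wallFcap;
  double cenEps, cenCut;
  double gamma, dt, temp;
  double pairFcap;  // cap on pair-force magnitude (0 = exact); soft push-off
  double maxStep;   // per-half-step displacement clamp in nm (0 = off)
};

Params read_params(const List& par) {
  Params p;
  p.sigma    = as<double>(par["sigma"]);
  p.feneK    = as<double>(par["fene_k"]);
  p.feneR0   = as<double>(par["fene_r0"]);
  p.kappa    = as<double>(par["kappa"]);
  p.rnuc     = as<double>(par["r_nuc"]);
  p.wallK    = as<double>(par["wall_k"]);
  p.wallFcap = as<double>(par["wall_fcap"]);
  p.cenEps   = as<double>(par["cen_eps"]);
  p.cenCut   = as<double>(par["cen_cut"]);
  p.gamma    = as<double>(par["gamma"]);
  p.dt       = as<double>(par["dt"]);
  p.temp     = as<double>(par["temp"]);
  p.pairFcap = par.containsElementNamed("pair_fcap") ?
    as<double>(par["pair_fcap"]) : 0.0;
  p.maxStep = par.containsElementNamed("max_step") ?
    as<double>(par["max_step"]) : 0.0;
  return p;
}

struct CellList {
  double x0[3];
  double cell;
  int dim[3];
  std::vector<int> head, nxt;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double cutoff) {
    const int n = (int)x.size();
    double lo[3] = {x[0], y[0], z[0]}, hi[3] = {x[0], y[0], z[0]};
    for (int i = 1; i < n; ++i) {
      lo[0] = std::min(lo[0], x[i]); hi[0] = std::max(hi[0], x[i]);
      lo[1] = std::min(lo[1], y[i]); hi[1] = std::max(hi[1], y[i]);
      lo[2] = std::min(lo[2], z[i]); hi[2] = std::max(hi[2], z[i]);
    }
    cell = cutoff;
    for (int d = 0; d < 3; ++d) {
      double ext = hi[d] - lo[d] + 1e-9;
      int nd = std::max(1, (int)std::floor(ext / cutoff));
      if (nd > 128) { nd = 128; }
      dim[d] = nd;
      x0[d] = lo[d];
      // widen cells if the box is larger than 128 cells along this axis
      double cd = ext / nd;
      if (cd > cell) cell = cd;
    }
    // recompute dims with the common (possibly widened) cell size
    for (int d = 0; d < 3; ++d) {
      double ext = hi[d] - lo[d] + 1e-9;
      dim[d] = std::max(1, (int)std::floor(ext / cell) + 1);
    }
    head.assign((size_t)dim[0] * dim[1] * dim[2], -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = index_of(x[i], y[i], z[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  int clampc(int v, int d) const {
    return std::max(0, std::min(v, dim[d] - 1));
  }
  int index_of(double xx, double yy, double zz) const {
    int cx = clampc((int)std::floor((xx - x0[0]) / cell), 0);
    int cy = clampc((int)std::floor((yy - x0[1]) / cell), 1);
    int cz = clampc((int)std::floor((zz - x0[2]) / cell), 2);
    return (cx * dim[1] + cy) * dim[2] + cz;
  }
};

struct Restraints {
  std::vector<int> a0, a1, b0, b1;     // half-open bead ranges, 0-based
  std::vector<double> kini, kmax;
  double fcap;
  long rampSteps;
  std::vector<long> schedStep;         // ascending, schedStep[0] == 0
  std::vector<double> schedD0;

  int size() const { return (int)a0.size(); }
  double d0_at(long step) const {
    double d0 = schedD0.empty() ? 0.0 : schedD0[0];
    for (size_t i = 0; i < schedStep.size(); ++i)
      if (step >= schedStep[i]) d0 = schedD0[i];
    return d0;
  }
  double ramp_at(long step) const {
    if (rampSteps <= 0) return 1.0;
    double f = (double)step / (double)rampSteps;
    return f > 1.0 ? 1.0 : f;
  }
};

Restraints read_restraints(const List& restr) {
  Restraints r;
  if (restr.size() == 0) { r.fcap = 0; r.rampSteps = 0; return r; }
  IntegerVector a0 = restr["a0"], a1 = restr["a1"], b0 = restr["b0"], b1 = restr["b1"];
  NumericVector ki = restr["k_init"], km = restr["k_max"];
  r.a0.assign(a0.begin(), a0.end());
  r.a1.assign(a1.begin(), a1.end());
  r.b0.assign(b0.begin(), b0.end());
  r.b1.assign(b1.begin(), b1.end());
  r.kini.assign(ki.begin(), ki.end());
  r.kmax.assign(km.begin(), km.end());
  r.fcap = as<double>(restr["fcap"]);
  r.rampSteps = (long)as<double>(restr["ramp_steps"]);
  IntegerVector ss = restr["sched_step"];
  NumericVector sd = restr["sched_d0"];
  r.schedStep.assign(ss.begin(), ss.end());
  r.schedD0.assign(sd.begin(), sd.end());
  return r;
}

class System {
public:
  int n;
  std::vector<double> x, y, z;
  std::vector<double> fx, fy, fz;
  std::vector<int> chain;     // chain id per bead
  std::vector<char> cen;      // centromere flag
  Params p;
  CellList cl;
  double pe;                  // potential energy of last force evaluation

  System(const NumericMatrix& coords, const IntegerVector& ch,
         const LogicalVector& cn, const Params& par) : p(par) {
    n = coords.nrow();
    x.resize(n); y.resize(n); z.resize(n);
    fx.resize(n); fy.resize(n); fz.resize(n);
    chain.resize(n); cen.resize(n);
    for (int i = 0; i < n; ++i) {
      x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
      chain[i] = ch[i];
      cen[i] = cn[i] ? 1 : 0;
    }
  }

  // forces for the conformational force field (no restraints)
  void forces() {
    const double sig = p.sigma;
    const double wcaCut2 = std::pow(2.0, 1.0 / 3.0) * sig * sig;  // (2^{1/6} s)^2
    const double cenCut2 = p.cenCut * p.cenCut;
    const double cutoff = std::max(std::sqrt(wcaCut2), p.cenCut);
    pe = 0.0;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);

    // --- FENE bonds (explicit, so overstretch is always detected) ---
    const double R02 = p.feneR0 * p.feneR0;
    for (int i = 0; i + 1 < n; ++i) {
      if (chain[i] != chain[i + 1]) continue;
      double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i], dz = z[i + 1] - z[i];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= R02)
        stop("FENE bond overstretched (bead %d-%d, r = %.2f nm >= R0 = %.2f nm): integration unstable",
             i + 1, i + 2, std::sqrt(r2), p.feneR0);
      double denom = 1.0 - r2 / R02;
      pe += -0.5 * p.feneK * R02 * std::log(denom);
      double fr = -p.feneK / denom;  // dU/dr / r  (attractive toward r=0)
      fx[i] -= fr * dx; fy[i] -= fr * dy; fz[i] -= fr * dz;
      fx[i + 1] += fr * dx; fy[i + 1] += fr * dy; fz[i + 1] += fr * dz;
    }

    // --- pair interactions: WCA + centromere attraction ---
    cl.build(x, y, z, cutoff);
    // with pairFcap > 0 (soft push-off) pair forces accumulate separately
    // and the NET pair force per bead is capped, so crowded beads cannot
    // out-pull a FENE bond no matter how many neighbours they overlap
    std::vector<double> pfx, pfy, pfz;
    double *tfx = fx.data(), *tfy = fy.data(), *tfz = fz.data();
    if (p.pairFcap > 0) {
      pfx.assign(n, 0.0); pfy.assign(n, 0.0); pfz.assign(n, 0.0);
      tfx = pfx.data(); tfy = pfy.data(); tfz = pfz.data();
    }
    const double sig2 = sig * sig;
    const double cenShift = [&]() {
      // cut-shifted LJ so U(cenCut) = 0
      double sr2 = sig2 / cenCut2, sr6 = sr2 * sr2 * sr2;
      return 4.0 * p.cenEps * (sr6 * sr6 - sr6);
    }();
    for (int i = 0; i < n; ++i) {
      int cx = cl.clampc((int)std::floor((x[i] - cl.x0[0]) / cl.cell), 0);
      int cy = cl.clampc((int)std::floor((y[i] - cl.x0[1]) / cl.cell), 1);
      int cz = cl.clampc((int)std::floor((z[i] - cl.x0[2]) / cl.cell), 2);
      for (int ox = -1; ox <= 1; ++ox) {
        int nx2 = cx + ox; if (nx2 < 0 || nx2 >= cl.dim[0]) continue;
        for (int oy = -1; oy <= 1; ++oy) {
          int ny2 = cy + oy; if (ny2 < 0 || ny2 >= cl.dim[1]) continue;
          for (int oz = -1; oz <= 1; ++oz) {
            int nz2 = cz + oz; if (nz2 < 0 || nz2 >= cl.dim[2]) continue;
            int c = (nx2 * cl.dim[1] + ny2) * cl.dim[2] + nz2;
            for (int j = cl.head[c]; j >= 0; j = cl.nxt[j]) {
              if (j <= i) continue;
              double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
              double r2 = dx * dx + dy * dy + dz * dz;
              bool bonded = (chain[i] == chain[j]) && (std::abs(i - j) == 1);
              bool cenPair = !bonded && cen[i] && cen[j] && chain[i] == chain[j];
              if (cenPair && r2 < cenCut2) {
                // full LJ, depth cenEps, cut & shifted at cenCut
                double sr2 = sig2 / r2, sr6 = sr2 * sr2 * sr2;
                pe += 4.0 * p.cenEps * (sr6 * sr6 - sr6) - cenShift;
                double fr = 24.0 * p.cenEps * (2.0 * sr6 * sr6 - sr6) / r2;
                if (p.pairFcap > 0) {
                  double fm = std::abs(fr) * std::sqrt(r2);
                  if (fm > p.pairFcap) fr *= p.pairFcap / fm;
                }
                tfx[i] -= fr * dx; tfy[i] -= fr * dy; tfz[i] -= fr * dz;
                tfx[j] += fr * dx; tfy[j] += fr * dy; tfz[j] += fr * dz;
              } else if (!cenPair && r2 < wcaCut2) {
                double sr2 = sig2 / r2, sr6 = sr2 * sr2 * sr2;
                pe += 4.0 * (sr6 * sr6 - sr6) + 1.0;  // eps = 1
                double fr = 24.0 * (2.0 * sr6 * sr6 - sr6) / r2;
                if (p.pairFcap > 0) {
                  double fm = std::abs(fr) * std::sqrt(r2);
                  if (fm > p.pairFcap) fr *= p.pairFcap / fm;
                }
                tfx[i] -= fr * dx; tfy[i] -= fr * dy; tfz[i] -= fr * dz;
                tfx[j] += fr * dx; tfy[j] += fr * dy; tfz[j] += fr * dz;
              }
            }
          }
        }
      }
    }

    if (p.pairFcap > 0) {
      for (int i = 0; i < n; ++i) {
        double fm = std::sqrt(pfx[i] * pfx[i] + pfy[i] * pfy[i] +
                              pfz[i] * pfz[i]);
        double sc = (fm > p.pairFcap) ? p.pairFcap / fm : 1.0;
        fx[i] += sc * pfx[i]; fy[i] += sc * pfy[i]; fz[i] += sc * pfz[i];
      }
    }

    // --- Kratky-Porod bending ---
    if (p.kappa > 0) {
      for (int i = 1; i + 1 < n; ++i) {
        if (chain[i - 1] != chain[i] || chain[i] != chain[i + 1]) continue;
        double b1x = x[i] - x[i - 1], b1y = y[i] - y[i - 1], b1z = z[i] - z[i - 1];
        double b2x = x[i + 1] - x[i], b2y = y[i + 1] - y[i], b2z = z[i + 1] - z[i];
        double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
        double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
        double u1x = b1x / n1, u1y = b1y / n1, u1z = b1z / n1;
        double u2x = b2x / n2, u2y = b2y / n2, u2z = b2z / n2;
        double c = u1x * u2x + u1y * u2y + u1z * u2z;
        pe += p.kappa * (1.0 - c);
        // dU/db1 = -kappa * (u2 - c u1)/n1 ; dU/db2 = -kappa * (u1 - c u2)/n2
        double g1x = -p.kappa * (u2x - c * u1x) / n1;
        double g1y = -p.kappa * (u2y - c * u1y) / n1;
        double g1z = -p.kappa * (u2z - c * u1z) / n1;
        double g2x = -p.kappa * (u1x - c * u2x) / n2;
        double g2y = -p.kappa * (u1y - c * u2y) / n2;
        double g2z = -p.kappa * (u1z - c * u2z) / n2;
        fx[i - 1] += g1x; fy[i - 1] += g1y; fz[i - 1] += g1z;
        fx[i]     += -g1x + g2x; fy[i] += -g1y + g2y; fz[i] += -g1z + g2z;
        fx[i + 1] += -g2x; fy[i + 1] += -g2y; fz[i + 1] += -g2z;
      }
    }

    // --- confining wall ---
    if (std::isfinite(p.rnuc)) {
      const double r0 = p.rnuc - 0.5 * p.sigma;
      const double dcap = (p.wallK > 0) ? p.wallFcap / p.wallK : 0.0;
      for (int i = 0; i < n; ++i) {
        double r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
        if (r <= r0 || r < 1e-12) continue;
        double d = r - r0;
        double fmag;
        if (d <= dcap) {
          pe += 0.5 * p.wallK * d * d;
          fmag = p.wallK * d;
        } else {
          pe += 0.5 * p.wallK * dcap * dcap + p.wallFcap * (d - dcap);
          fmag = p.wallFcap;
        }
        fx[i] -= fmag * x[i] / r;
        fy[i] -= fmag * y[i] / r;
        fz[i] -= fmag * z[i] / r;
      }
    }
  }

  // add COM restraint forces at ramp fraction `kf` and equilibrium d0
  void restraint_forces(const Restraints& r, double kf, double d0) {
    for (int q = 0; q < r.size(); ++q) {
      double k = r.kini[q] + (r.kmax[q] - r.kini[q]) * kf;
      if (k <= 0) continue;
      int nA = r.a1[q] - r.a0[q], nB = r.b1[q] - r.b0[q];
      double ax = 0, ay = 0, az = 0, bx = 0, by = 0, bz = 0;
      for (int i = r.a0[q]; i < r.a1[q]; ++i) { ax += x[i]; ay += y[i]; az += z[i]; }
      for (int i = r.b0[q]; i < r.b1[q]; ++i) { bx += x[i]; by += y[i]; bz += z[i]; }
      ax /= nA; ay /= nA; az /= nA; bx /= nB; by /= nB; bz /= nB;
      double dx = bx - ax, dy = by - ay, dz = bz - az;
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < 1e-12) continue;
      double fmag = k * (d - d0);               // >0 pulls together
      if (fmag > r.fcap) fmag = r.fcap;
      if (fmag < -r.fcap) fmag = -r.fcap;
      pe += 0.5 * k * (d - d0) * (d - d0);      // harmonic branch bookkeeping
      double ux = dx / d, uy = dy / d, uz = dz / d;
      double fa = fmag / nA, fb = fmag / nB;
      for (int i = r.a0[q]; i < r.a1[q]; ++i) {
        fx[i] += fa * ux; fy[i] += fa * uy; fz[i] += fa * uz;
      }
      for (int i = r.b0[q]; i < r.b1[q]; ++i) {
        fx[i] -= fb * ux; fy[i] -= fb * uy; fz[i] -= fb * uz;
      }
    }
  }

  NumericMatrix coords_matrix() const {
    NumericMatrix m(n, 3);
    for (int i = 0; i < n; ++i) { m(i, 0) = x[i]; m(i, 1) = y[i]; m(i, 2) = z[i]; }
    return m;
  }
};

}  // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_forces")]]
List cpp_forces(NumericMatrix coords, IntegerVector chain, LogicalVector cen,
                List par) {
  Params p = read_params(par);
  System s(coords, chain, cen, p);
  s.forces();
  NumericMatrix f(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    f(i, 0) = s.fx[i]; f(i, 1) = s.fy[i]; f(i, 2) = s.fz[i];
  }
  return List::create(_["forces"] = f, _["energy"] = s.pe);
}

//' @noRd
// [[Rcpp::export(name = "cpp_restraint_forces")]]
List cpp_restraint_forces(NumericMatrix coords, IntegerVector chain,
                          LogicalVector cen, List par, List restr,
                          double ramp_frac, double d0) {
  Params p = read_params(par);
  System s(coords, chain, cen, p);
  std::fill(s.fx.begin(), s.fx.end(), 0.0);
  std::fill(s.fy.begin(), s.fy.end(), 0.0);
  std::fill(s.fz.begin(), s.fz.end(), 0.0);
  s.pe = 0.0;
  Restraints r = read_restraints(restr);
  s.restraint_forces(r, ramp_frac, d0);
  NumericMatrix f(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    f(i, 0) = s.fx[i]; f(i, 1) = s.fy[i]; f(i, 2) = s.fz[i];
  }
  return List::create(_["forces"] = f, _["energy"] = s.pe);
}

//' @noRd
// [[Rcpp::export(name = "cpp_run")]]
List cpp_run(NumericMatrix coords, IntegerVector chain, LogicalVector cen,
             List par, List restr, int nsteps, int snap_every, int seed,
             Nullable<NumericMatrix> vel0 = R_NilValue) {
  Params p = read_params(par);
  System s(coords, chain, cen, p);
  Restraints r = read_restraints(restr);
  const int n = s.n;
  const double dt = p.dt;
  const double c1 = std::exp(-p.gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  const double sqkT = std::sqrt(p.temp);

  std::mt19937_64 rng((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> vx(n), vy(n), vz(n);
  if (vel0.isNotNull()) {
    NumericMatrix v(vel0);
    for (int i = 0; i < n; ++i) { vx[i] = v(i, 0); vy[i] = v(i, 1); vz[i] = v(i, 2); }
  } else if (p.temp > 0) {
    for (int i = 0; i < n; ++i) {
      vx[i] = sqkT * gauss(rng); vy[i] = sqkT * gauss(rng); vz[i] = sqkT * gauss(rng);
    }
  }

  auto eval_forces = [&](long step) {
    s.forces();
    if (r.size() > 0) s.restraint_forces(r, r.ramp_at(step), r.d0_at(step));
  };
  eval_forces(0);

  int nsnap = (snap_every > 0) ? nsteps / snap_every : 0;
  List snaps(nsnap + 1);
  IntegerVector snapStep(nsnap + 1);
  NumericVector peOut(nsnap + 1), keOut(nsnap + 1), kfOut(nsnap + 1), d0Out(nsnap + 1);
  auto record = [&](int idx, long step) {
    snaps[idx] = s.coords_matrix();
    snapStep[idx] = (int)step;
    peOut[idx] = s.pe;
    double ke = 0;
    for (int i = 0; i < n; ++i) ke += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    keOut[idx] = 0.5 * ke;
    kfOut[idx] = r.size() > 0 ? r.ramp_at(step) : 0.0;
    d0Out[idx] = r.size() > 0 ? r.d0_at(step) : 0.0;
  };
  record(0, 0);

  const double maxDisp = p.sigma;  // instability guard per half-drift
  int isnap = 1;
  for (long step = 1; step <= nsteps; ++step) {
    // B
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * s.fx[i];
      vy[i] += 0.5 * dt * s.fy[i];
      vz[i] += 0.5 * dt * s.fz[i];
    }
    // A
    for (int i = 0; i < n; ++i) {
      double ddx = 0.5 * dt * vx[i], ddy = 0.5 * dt * vy[i], ddz = 0.5 * dt * vz[i];
      double dn = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (p.maxStep > 0) {
        if (dn > p.maxStep) {
          double sc = p.maxStep / dn;
          ddx *= sc; ddy *= sc; ddz *= sc;
          vx[i] *= sc; vy[i] *= sc; vz[i] *= sc;
        }
      } else if (dn > maxDisp) {
        stop("integration unstable: bead displacement exceeds sigma in one step (step %ld)", step);
      }
      s.x[i] += ddx; s.y[i] += ddy; s.z[i] += ddz;
    }
    // O
    if (p.gamma > 0) {
      for (int i = 0; i < n; ++i) {
        vx[i] = c1 * vx[i] + c2 * sqkT * gauss(rng);
        vy[i] = c1 * vy[i] + c2 * sqkT * gauss(rng);
        vz[i] = c1 * vz[i] + c2 * sqkT * gauss(rng);
      }
    }
    // A
    for (int i = 0; i < n; ++i) {
      double ddx = 0.5 * dt * vx[i], ddy = 0.5 * dt * vy[i], ddz = 0.5 * dt * vz[i];
      double dn = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (p.maxStep > 0) {
        if (dn > p.maxStep) {
          double sc = p.maxStep / dn;
          ddx *= sc; ddy *= sc; ddz *= sc;
          vx[i] *= sc; vy[i] *= sc; vz[i] *= sc;
        }
      } else if (dn > maxDisp) {
        stop("integration unstable: bead displacement exceeds sigma in one step (step %ld)", step);
      }
      s.x[i] += ddx; s.y[i] += ddy; s.z[i] += ddz;
    }
    // B with fresh forces
    eval_forces(step);
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * s.fx[i];
      vy[i] += 0.5 * dt * s.fy[i];
      vz[i] += 0.5 * dt * s.fz[i];
    }
    if (snap_every > 0 && step % snap_every == 0 && isnap <= nsnap) {
      record(isnap, step);
      ++isnap;
    }
    if (step % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix vOut(n, 3);
  for (int i = 0; i < n; ++i) { vOut(i, 0) = vx[i]; vOut(i, 1) = vy[i]; vOut(i, 2) = vz[i]; }
  return List::create(
    _["coords"] = s.coords_matrix(),
    _["vel"] = vOut,
    _["snaps"] = snaps,
    _["snap_step"] = snapStep,
    _["pe"] = peOut,
    _["ke"] = keOut,
    _["ramp_frac"] = kfOut,
    _["d0"] = d0Out);
}

//' @noRd
// [[Rcpp::export(name = "cpp_has_clash")]]
bool cpp_has_clash(NumericMatrix existing, NumericMatrix candidate, double cutoff) {
  const int ne = existing.nrow(), nc = candidate.nrow();
  if (ne == 0 || nc == 0) return false;
  std::vector<double> x(ne), y(ne), z(ne);
  for (int i = 0; i < ne; ++i) { x[i] = existing(i, 0); y[i] = existing(i, 1); z[i] = existing(i, 2); }
  CellList cl;
  cl.build(x, y, z, cutoff);
  const double cut2 = cutoff * cutoff;
  for (int q = 0; q < nc; ++q) {
    double qx = candidate(q, 0), qy = candidate(q, 1), qz = candidate(q, 2);
    int cx = cl.clampc((int)std::floor((qx - cl.x0[0]) / cl.cell), 0);
    int cy = cl.clampc((int)std::floor((qy - cl.x0[1]) / cl.cell), 1);
    int cz = cl.clampc((int)std::floor((qz - cl.x0[2]) / cl.cell), 2);
    for (int ox = -1; ox <= 1; ++ox) {
      int nx2 = cx + ox; if (nx2 < 0 || nx2 >= cl.dim[0]) continue;
      for (int oy = -1; oy <= 1; ++oy) {
        int ny2 = cy + oy; if (ny2 < 0 || ny2 >= cl.dim[1]) continue;
        for (int oz = -1; oz <= 1; ++oz) {
          int nz2 = cz + oz; if (nz2 < 0 || nz2 >= cl.dim[2]) continue;
          int c = (nx2 * cl.dim[1] + ny2) * cl.dim[2] + nz2;
          for (int j = cl.head[c]; j >= 0; j = cl.nxt[j]) {
            double dx = x[j] - qx, dy = y[j] - qy, dz = z[j] - qz;
            if (dx * dx + dy * dy + dz * dz < cut2) return true;
          }
        }
      }
    }
  }
  return false;
}
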