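#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Shifted-force Lennard-Jones pair tables for the three species
// (0 = core c, 1 = segment s, 2 = fluid particle P).  The potential is
//   u(r) = u_LJ(r) - u_LJ(rc) - (r - rc) u'_LJ(rc),   r < rc
// which makes both the energy and the force vanish continuously at the
// cutoff rc.  Attractive pairs use rc = 2.5 sigma_ij, repulsive rc = sigma_ij.
struct PairTables {
  double sig2[3][3];   // sigma_ij^2
  double eps[3][3];
  double rc[3][3];
  double rc2[3][3];
  double ushift[3][3]; // u_LJ(rc)
  double fshift[3][3]; // u'_LJ(rc)
};

static PairTables build_tables(const NumericMatrix& sigma,
                               const NumericMatrix& eps,
                               const NumericMatrix& rcut) {
  PairTables t;
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b) {
      double s = sigma(a, b), e = eps(a, b), rc = rcut(a, b);
      t.sig2[a][b] = s * s;
      t.eps[a][b]  = e;
      t.rc[a][b]   = rc;
      t.rc2[a][b]  = rc * rc;
      double sr2  = (s * s) / (rc * rc);
      double sr6  = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      t.ushift[a][b] = 4.0 * e * (sr12 - sr6);
      t.fshift[a][b] = -24.0 * e * (2.0 * sr12 - sr6) / rc;
    }
  }
  return t;
}

// energy and scalar force magnitude (positive = repulsive) for one pair
static inline void pair_eval(const PairTables& t, int a, int b, double r2,
                             double& u, double& fmag_over_r) {
  if (r2 >= t.rc2[a][b]) { u = 0.0; fmag_over_r = 0.0; return; }
  double r = std::sqrt(r2);
  double sr2  = t.sig2[a][b] / r2;
  double sr6  = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  double e = t.eps[a][b];
  u = 4.0 * e * (sr12 - sr6) - t.ushift[a][b] - (r - t.rc[a][b]) * t.fshift[a][b];
  double fmag = 24.0 * e * (2.0 * sr12 - sr6) / r + t.fshift[a][b];
  fmag_over_r = fmag / r;
}

struct Box {
  double L[3];
  bool periodic[3];
};

static inline double min_image(double d, double L, bool per) {
  if (per) d -= L * std::nearbyint(d / L);
  return d;
}

// 1-2 exclusions: directly bonded beads do not interact through the
// non-bonded potential (harmonic bond only), as in standard bead-spring MD.
static std::vector< std::vector<int> > build_exclusions(const IntegerMatrix& bonds, int n) {
  std::vector< std::vector<int> > excl(n);
  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0), j = bonds(k, 1);
    excl[i].push_back(j);
    excl[j].push_back(i);
  }
  return excl;
}

static inline bool is_excluded(const std::vector< std::vector<int> >& excl, int i, int j) {
  const std::vector<int>& e = excl[i];
  for (size_t k = 0; k < e.size(); ++k) if (e[k] == j) return true;
  return false;
}

static void accumulate_pair(const PairTables& t, const Box& box,
                            const std::vector<double>& x, const std::vector<double>& y,
                            const std::vector<double>& z, const IntegerVector& species,
                            const std::vector< std::vector<int> >& excl,
                            int i, int j, std::vector<double>& fx, std::vector<double>& fy,
                            std::vector<double>& fz, double& epot) {
  if (is_excluded(excl, i, j)) return;
  double dx = min_image(x[i] - x[j], box.L[0], box.periodic[0]);
  double dy = min_image(y[i] - y[j], box.L[1], box.periodic[1]);
  double dz = min_image(z[i] - z[j], box.L[2], box.periodic[2]);
  double r2 = dx * dx + dy * dy + dz * dz;
  int a = species[i], b = species[j];
  if (r2 >= t.rc2[a][b]) return;
  if (r2 < 1e-12) stop("overlapping beads (r < 1e-6 sigma): singular pair interaction");
  double u, for_r;
  pair_eval(t, a, b, r2, u, for_r);
  epot += u;
  fx[i] += for_r * dx; fy[i] += for_r * dy; fz[i] += for_r * dz;
  fx[j] -= for_r * dx; fy[j] -= for_r * dy; fz[j] -= for_r * dz;
}

// Brute-force O(N^2) non-bonded loop
static double forces_brute(const PairTables& t, const Box& box,
                           const std::vector<double>& x, const std::vector<double>& y,
                           const std::vector<double>& z, const IntegerVector& species,
                           const std::vector< std::vector<int> >& excl,
                           std::vector<double>& fx, std::vector<double>& fy,
                           std::vector<double>& fz) {
  int n = (int)x.size();
  double epot = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      accumulate_pair(t, box, x, y, z, species, excl, i, j, fx, fy, fz, epot);
  return epot;
}

// Linked-cell O(N) non-bonded loop; falls back to brute force when the box
// holds fewer than three cells along any periodic direction.
struct CellGrid {
  int nc[3];
  double inv_w[3];
  std::vector<int> head;   // first particle in cell, -1 terminated lists
  std::vector<int> next;
  bool valid;
};

static void build_grid(CellGrid& g, const Box& box, double cutoff,
                       const std::vector<double>& x, const std::vector<double>& y,
                       const std::vector<double>& z) {
  g.valid = true;
  for (int d = 0; d < 3; ++d) {
    g.nc[d] = (int)std::floor(box.L[d] / cutoff);
    if (g.nc[d] < 1) g.nc[d] = 1;
    if (box.periodic[d] && g.nc[d] < 3) { g.valid = false; return; }
    g.inv_w[d] = g.nc[d] / box.L[d];
  }
  int n = (int)x.size();
  int ncell = g.nc[0] * g.nc[1] * g.nc[2];
  if (ncell < 27) { g.valid = false; return; }
  g.head.assign(ncell, -1);
  if ((int)g.next.size() != n) g.next.assign(n, -1);
  for (int i = 0; i < n; ++i) {
    double p[3] = { x[i], y[i], z[i] };
    int c[3];
    for (int d = 0; d < 3; ++d) {
      double s = p[d] / (g.nc[d] / g.inv_w[d]);  // fraction of box
      s -= std::floor(s);                        // wrap into [0,1)
      c[d] = (int)(s * g.nc[d]);
      if (c[d] >= g.nc[d]) c[d] = g.nc[d] - 1;
    }
    int ci = (c[2] * g.nc[1] + c[1]) * g.nc[0] + c[0];
    g.next[i] = g.head[ci];
    g.head[ci] = i;
  }
}

static double forces_cell(CellGrid& g, const PairTables& t, const Box& box,
                          double cutoff,
                          const std::vector<double>& x, const std::vector<double>& y,
                          const std::vector<double>& z, const IntegerVector& species,
                          const std::vector< std::vector<int> >& excl,
                          std::vector<double>& fx, std::vector<double>& fy,
                          std::vector<double>& fz, bool& used_cell) {
  build_grid(g, box, cutoff, x, y, z);
  if (!g.valid) {
    used_cell = false;
    return forces_brute(t, box, x, y, z, species, excl, fx, fy, fz);
  }
  used_cell = true;
  double epot = 0.0;
  // half shell of 13 neighbour offsets + same cell
  static const int off[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
    {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
  };
  for (int cz = 0; cz < g.nc[2]; ++cz)
    for (int cy = 0; cy < g.nc[1]; ++cy)
      for (int cx = 0; cx < g.nc[0]; ++cx) {
        int ci = (cz * g.nc[1] + cy) * g.nc[0] + cx;
        if (g.head[ci] < 0) continue;
        // pairs within the cell
        for (int i = g.head[ci]; i >= 0; i = g.next[i])
          for (int j = g.next[i]; j >= 0; j = g.next[j])
            accumulate_pair(t, box, x, y, z, species, excl, i, j, fx, fy, fz, epot);
        // pairs with the half shell
        for (int o = 0; o < 13; ++o) {
          int nx = cx + off[o][0], ny = cy + off[o][1], nz = cz + off[o][2];
          if (box.periodic[0]) nx = (nx + g.nc[0]) % g.nc[0];
          else if (nx < 0 || nx >= g.nc[0]) continue;
          if (box.periodic[1]) ny = (ny + g.nc[1]) % g.nc[1];
          else if (ny < 0 || ny >= g.nc[1]) continue;
          if (box.periodic[2]) nz = (nz + g.nc[2]) % g.nc[2];
          else if (nz < 0 || nz >= g.nc[2]) continue;
          int cj = (nz * g.nc[1] + ny) * g.nc[0] + nx;
          for (int i = g.head[ci]; i >= 0; i = g.next[i])
            for (int j = g.head[cj]; j >= 0; j = g.next[j])
              accumulate_pair(t, box, x, y, z, species, excl, i, j, fx, fy, fz, epot);
        }
      }
  return epot;
}

static double bond_forces(const IntegerMatrix& bonds, double kss, double b0,
                          const Box& box,
                          const std::vector<double>& x, const std::vector<double>& y,
                          const std::vector<double>& z,
                          std::vector<double>& fx, std::vector<double>& fy,
                          std::vector<double>& fz) {
  double epot = 0.0;
  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0), j = bonds(k, 1);
    double dx = min_image(x[i] - x[j], box.L[0], box.periodic[0]);
    double dy = min_image(y[i] - y[j], box.L[1], box.periodic[1]);
    double dz = min_image(z[i] - z[j], box.L[2], box.periodic[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) stop("zero-length bond");
    double dr = r - b0;
    epot += kss * dr * dr;
    double for_r = -2.0 * kss * dr / r;
    fx[i] += for_r * dx; fy[i] += for_r * dy; fz[i] += for_r * dz;
    fx[j] -= for_r * dx; fy[j] -= for_r * dy; fz[j] -= for_r * dz;
  }
  return epot;
}

static Box make_box(const NumericVector& L, const LogicalVector& periodic) {
  Box box;
  for (int d = 0; d < 3; ++d) { box.L[d] = L[d]; box.periodic[d] = periodic[d]; }
  return box;
}

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, IntegerVector species,
                        IntegerMatrix bonds, double kss, double bond_r0,
                        NumericMatrix sigma, NumericMatrix eps, NumericMatrix rcut,
                        NumericVector boxL, LogicalVector periodic,
                        double cutoff, std::string method) {
  int n = pos.nrow();
  PairTables t = build_tables(sigma, eps, rcut);
  Box box = make_box(boxL, periodic);
  std::vector<double> x(n), y(n), z(n), fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  std::vector< std::vector<int> > excl = build_exclusions(bonds, n);
  double epot;
  bool used_cell = false;
  if (method == "brute") {
    epot = forces_brute(t, box, x, y, z, species, excl, fx, fy, fz);
  } else {
    CellGrid g;
    epot = forces_cell(g, t, box, cutoff, x, y, z, species, excl, fx, fy, fz, used_cell);
  }
  epot += bond_forces(bonds, kss, bond_r0, box, x, y, z, fx, fy, fz);
  NumericMatrix f(n, 3);
  for (int i = 0; i < n; ++i) { f(i, 0) = fx[i]; f(i, 1) = fy[i]; f(i, 2) = fz[i]; }
  return List::create(_["forces"] = f, _["epot"] = epot,
                      _["used_cell"] = used_cell);
}

// Velocity-Verlet with (optional) Nose-Hoover thermostat.  Immobile beads
// keep their coordinates; forces on them are computed (Newton's third law)
// but never applied.  Kinetic energy and the thermostat couple to mobile
// beads only (g = 3 N_mobile degrees of freedom, Q = g T tdamp^2).
// Hard walls (slab geometry) act by specular reflection at z = r_i above the
// grafted wall and z = Lz - r_i below the bare wall, where r_i is the bead
// radius; beads listed in wall_exempt pass the grafted wall freely.
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                LogicalVector mobile, IntegerMatrix bonds, double kss, double bond_r0,
                NumericMatrix sigma, NumericMatrix eps, NumericMatrix rcut,
                NumericVector boxL, LogicalVector periodic, double cutoff,
                bool use_walls, NumericVector wall_radius, LogicalVector wall_exempt,
                double dt, int nsteps, bool nvt, double T_target, double tdamp,
                double xi0, int esample, int fsample, std::string method) {
  int n = pos.nrow();
  PairTables t = build_tables(sigma, eps, rcut);
  Box box = make_box(boxL, periodic);
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n),
                      fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  std::vector< std::vector<int> > excl = build_exclusions(bonds, n);
  std::vector<int> mob;
  for (int i = 0; i < n; ++i) if (mobile[i]) mob.push_back(i);
  int nmob = (int)mob.size();
  double g = 3.0 * nmob;
  double Q = (nvt && T_target > 0) ? g * T_target * tdamp * tdamp : 1.0;
  double xi = xi0;
  bool brute = (method == "brute");
  CellGrid grid;

  // initial forces
  double epot;
  {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    bool uc;
    epot = brute ? forces_brute(t, box, x, y, z, species, excl, fx, fy, fz)
                 : forces_cell(grid, t, box, cutoff, x, y, z, species, excl, fx, fy, fz, uc);
    epot += bond_forces(bonds, kss, bond_r0, box, x, y, z, fx, fy, fz);
  }

  std::vector<int> samp_step;
  std::vector<double> samp_epot, samp_ekin, samp_T;
  List frames;
  std::vector<int> frame_step;

  double max_disp = 0.5;

  for (int step = 1; step <= nsteps; ++step) {
    // kinetic energy at t (mobile beads)
    double K = 0.0;
    for (int m = 0; m < nmob; ++m) {
      int i = mob[m];
      K += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    }
    K *= 0.5;
    // half kick (with friction) and thermostat half update
    double h = 0.5 * dt;
    for (int m = 0; m < nmob; ++m) {
      int i = mob[m];
      vx[i] += h * (fx[i] - xi * vx[i]);
      vy[i] += h * (fy[i] - xi * vy[i]);
      vz[i] += h * (fz[i] - xi * vz[i]);
    }
    if (nvt) xi += h * (2.0 * K - g * T_target) / Q;
    // drift
    for (int m = 0; m < nmob; ++m) {
      int i = mob[m];
      double ddx = dt * vx[i], ddy = dt * vy[i], ddz = dt * vz[i];
      if (std::fabs(ddx) > max_disp || std::fabs(ddy) > max_disp || std::fabs(ddz) > max_disp)
        stop("integration instability: displacement > 0.5 sigma in one step (reduce dt)");
      x[i] += ddx; y[i] += ddy; z[i] += ddz;
      for (int d = 0; d < 3; ++d) {
        double* p = (d == 0 ? &x[i] : (d == 1 ? &y[i] : &z[i]));
        if (box.periodic[d]) {
          if (*p < 0) *p += box.L[d];
          else if (*p >= box.L[d]) *p -= box.L[d];
        }
      }
    }
    // hard walls (slab): specular reflection
    if (use_walls) {
      for (int m = 0; m < nmob; ++m) {
        int i = mob[m];
        double r = wall_radius[i];
        if (!wall_exempt[i] && z[i] < r) { z[i] = 2.0 * r - z[i]; vz[i] = -vz[i]; }
        double top = box.L[2] - r;
        if (z[i] > top) { z[i] = 2.0 * top - z[i]; vz[i] = -vz[i]; }
      }
    }
    // new forces
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    bool uc;
    epot = brute ? forces_brute(t, box, x, y, z, species, excl, fx, fy, fz)
                 : forces_cell(grid, t, box, cutoff, x, y, z, species, excl, fx, fy, fz, uc);
    epot += bond_forces(bonds, kss, bond_r0, box, x, y, z, fx, fy, fz);
    // thermostat second half update uses K at t+dt/2
    if (nvt) {
      double Kh = 0.0;
      for (int m = 0; m < nmob; ++m) {
        int i = mob[m];
        Kh += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      }
      Kh *= 0.5;
      xi += h * (2.0 * Kh - g * T_target) / Q;
    }
    double denom = nvt ? (1.0 + h * xi) : 1.0;
    for (int m = 0; m < nmob; ++m) {
      int i = mob[m];
      vx[i] = (vx[i] + h * fx[i]) / denom;
      vy[i] = (vy[i] + h * fy[i]) / denom;
      vz[i] = (vz[i] + h * fz[i]) / denom;
    }
    // sampling
    if (esample > 0 && step % esample == 0) {
      double Ks = 0.0;
      for (int m = 0; m < nmob; ++m) {
        int i = mob[m];
        Ks += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      }
      Ks *= 0.5;
      samp_step.push_back(step);
      samp_epot.push_back(epot);
      samp_ekin.push_back(Ks);
      samp_T.push_back(nmob > 0 ? 2.0 * Ks / g : 0.0);
    }
    if (fsample > 0 && step % fsample == 0) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) { fr(i, 0) = x[i]; fr(i, 1) = y[i]; fr(i, 2) = z[i]; }
      frames.push_back(fr);
      frame_step.push_back(step);
    }
    if (step % 10000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    pos_out(i, 0) = x[i]; pos_out(i, 1) = y[i]; pos_out(i, 2) = z[i];
    vel_out(i, 0) = vx[i]; vel_out(i, 1) = vy[i]; vel_out(i, 2) = vz[i];
  }
  return List::create(
    _["positions"] = pos_out, _["velocities"] = vel_out, _["xi"] = xi,
    _["series"] = DataFrame::create(_["step"] = samp_step, _["epot"] = samp_epot,
                                    _["ekin"] = samp_ekin, _["Tstar"] = samp_T),
    _["frames"] = frames, _["frame_step"] = frame_step);
}

// Random sequential insertion of fluid beads with an overlap criterion
// (candidate rejected if closer than min_frac * sigma_ij to any bead).
// Uses R's RNG so insertion is reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_insert_fluid(NumericMatrix existing, IntegerVector species_existing,
                               int n_insert, int species_new,
                               NumericMatrix sigma, NumericVector boxL,
                               LogicalVector periodic, double zlo, double zhi,
                               double min_frac, int max_tries) {
  Box box = make_box(boxL, periodic);
  int n0 = existing.nrow();
  std::vector<double> x, y, z;
  std::vector<int> sp;
  x.reserve(n0 + n_insert); y.reserve(n0 + n_insert); z.reserve(n0 + n_insert);
  for (int i = 0; i < n0; ++i) {
    x.push_back(existing(i, 0)); y.push_back(existing(i, 1)); z.push_back(existing(i, 2));
    sp.push_back(species_existing[i]);
  }
  NumericMatrix out(n_insert, 3);
  int placed = 0;
  long tries = 0;
  while (placed < n_insert) {
    if (++tries > (long)max_tries)
      stop("fluid insertion failed: retry budget exhausted (density too high; consider lattice pre-placement)");
    double cx = R::runif(0.0, box.L[0]);
    double cy = R::runif(0.0, box.L[1]);
    double cz = R::runif(zlo, zhi);
    bool ok = true;
    for (size_t j = 0; j < x.size(); ++j) {
      double dx = min_image(cx - x[j], box.L[0], box.periodic[0]);
      double dy = min_image(cy - y[j], box.L[1], box.periodic[1]);
      double dz = min_image(cz - z[j], box.L[2], box.periodic[2]);
      double dmin = min_frac * sigma(species_new, sp[j]);
      if (dx * dx + dy * dy + dz * dz < dmin * dmin) { ok = false; break; }
    }
    if (!ok) continue;
    out(placed, 0) = cx; out(placed, 1) = cy; out(placed, 2) = cz;
    x.push_back(cx); y.push_back(cy); z.push_back(cz); sp.push_back(species_new);
    ++placed;
  }
  return out;
}
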