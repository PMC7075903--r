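// Soft harmonic disk kernels: cell-list forces, FIRE relaxation, overdamped
// active-Brownian integration, and the O(N_contacts * N_q) correlation loops.
// Periodic rectangular box (Lx, Ly). All randomness is drawn from R's RNG so
// set.seed() controls these paths.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct CellList {
  int ncx, ncy;
  double cw_x, cw_y;
  std::vector<std::vector<int>> cells;
  bool all_pairs;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             double Lx, double Ly, double cutoff) {
    int n = (int)x.size();
    ncx = (int)std::floor(Lx / cutoff);
    ncy = (int)std::floor(Ly / cutoff);
    if (ncx < 3 || ncy < 3) { all_pairs = true; return; }
    all_pairs = false;
    cw_x = Lx / ncx; cw_y = Ly / ncy;
    cells.assign((size_t)ncx * ncy, {});
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor(x[i] / cw_x); if (cx >= ncx) cx = ncx - 1; if (cx < 0) cx = 0;
      int cy = (int)std::floor(y[i] / cw_y); if (cy >= ncy) cy = ncy - 1; if (cy < 0) cy = 0;
      cells[(size_t)cy * ncx + cx].push_back(i);
    }
  }
};

inline double wrap01(double v, double L) {
  v -= L * std::floor(v / L);
  if (v >= L) v -= L;
  return v;
}

// Pair potential: harmonic repulsion for r < s = sigma_i + sigma_j, optional
// piecewise-linear attractive tail out to (1+eps)s (zero energy at the cutoff).
inline void pair_ef(double r, double s, double k, double eps,
                    double& e, double& fmag /* >0 repulsive */) {
  if (eps <= 0.0) {
    if (r < s) { double d = s - r; e = 0.5 * k * d * d; fmag = k * d; }
    else { e = 0.0; fmag = 0.0; }
    return;
  }
  double rc = s * (1.0 + eps), rm = s * (1.0 + 0.5 * eps);
  double c0 = 0.25 * k * s * s * eps * eps;  // depth offset so V(rc)=0
  if (r < s) {
    double d = s - r; e = 0.5 * k * d * d - c0; fmag = k * d;
  } else if (r < rm) {
    double d = r - s; e = 0.5 * k * d * d - c0; fmag = -k * d;
  } else if (r < rc) {
    double d = rc - r; e = -0.5 * k * d * d; fmag = -k * d;
  } else { e = 0.0; fmag = 0.0; }
}

// Total energy and forces. Positions must be wrapped into [0,Lx) x [0,Ly).
void energy_forces(const std::vector<double>& x, const std::vector<double>& y,
                   const std::vector<double>& rad, double Lx, double Ly,
                   double k, double eps,
                   std::vector<double>& fx, std::vector<double>& fy, double& etot) {
  int n = (int)x.size();
  fx.assign(n, 0.0); fy.assign(n, 0.0); etot = 0.0;
  double smax = 0.0;
  for (int i = 0; i < n; ++i) if (rad[i] > smax) smax = rad[i];
  double cutoff = 2.0 * smax * (1.0 + (eps > 0 ? eps : 0.0)) + 1e-12;
  CellList cl; cl.build(x, y, Lx, Ly, cutoff);

  auto handle_pair = [&](int i, int j) {
    double dx = x[j] - x[i]; dx -= Lx * std::nearbyint(dx / Lx);
    double dy = y[j] - y[i]; dy -= Ly * std::nearbyint(dy / Ly);
    double s = rad[i] + rad[j];
    double rc = s * (1.0 + (eps > 0 ? eps : 0.0));
    double r2 = dx * dx + dy * dy;
    if (r2 >= rc * rc) return;
    double r = std::sqrt(r2);
    if (r < 1e-12) stop("coincident particle centers: contact normal undefined");
    double e, f;
    pair_ef(r, s, k, eps, e, f);
    etot += e;
    double ux = dx / r, uy = dy / r;       // unit vector i -> j
    fx[i] -= f * ux; fy[i] -= f * uy;      // repulsive: push i away from j
    fx[j] += f * ux; fy[j] += f * uy;
  };

  if (cl.all_pairs) {
    // Small boxes: explicit image sums. Pairs i < j over all image shifts in
    // range; self-image terms have constant separation, so they add energy
    // but no force.
    int mx = (int)std::ceil(cutoff / Lx), my = (int)std::ceil(cutoff / Ly);
    for (int i = 0; i < n; ++i) for (int j = i; j < n; ++j) {
      double s = rad[i] + rad[j];
      double rc = s * (1.0 + (eps > 0 ? eps : 0.0));
      for (int sx = -mx; sx <= mx; ++sx) for (int sy = -my; sy <= my; ++sy) {
        if (i == j && !(sx > 0 || (sx == 0 && sy > 0))) continue;
        double dx = x[j] - x[i] + sx * Lx;
        double dy = y[j] - y[i] + sy * Ly;
        double r2 = dx * dx + dy * dy;
        if (r2 >= rc * rc) continue;
        double r = std::sqrt(r2);
        if (r < 1e-12) stop("coincident particle centers: contact normal undefined");
        double e, f;
        pair_ef(r, s, k, eps, e, f);
        etot += e;
        if (i != j) {
          double ux = dx / r, uy = dy / r;
          fx[i] -= f * ux; fy[i] -= f * uy;
          fx[j] += f * ux; fy[j] += f * uy;
        }
      }
    }
  } else {
    for (int cy = 0; cy < cl.ncy; ++cy) for (int cx = 0; cx < cl.ncx; ++cx) {
      const std::vector<int>& me = cl.cells[(size_t)cy * cl.ncx + cx];
      for (int oy = -1; oy <= 1; ++oy) for (int ox = -1; ox <= 1; ++ox) {
        int jx = (cx + ox + cl.ncx) % cl.ncx, jy = (cy + oy + cl.ncy) % cl.ncy;
        int self = (jx == cx && jy == cy);
        int lin_me = cy * cl.ncx + cx, lin_o = jy * cl.ncx + jx;
        if (!self && lin_o < lin_me) continue;  // each cell pair once
        const std::vector<int>& other = cl.cells[(size_t)lin_o];
        for (size_t a = 0; a < me.size(); ++a) {
          size_t b0 = self ? a + 1 : 0;
          for (size_t b = b0; b < other.size(); ++b) handle_pair(me[a], other[b]);
        }
      }
    }
  }
}

double max_force(const std::vector<double>& fx, const std::vector<double>& fy) {
  double m = 0.0;
  for (size_t i = 0; i < fx.size(); ++i) {
    double f = std::sqrt(fx[i] * fx[i] + fy[i] * fy[i]);
    if (f > m) m = f;
  }
  return m;
}

} // namespace

// [[Rcpp::export(name = ".sd_energy_forces")]]
List sd_energy_forces_cpp(NumericVector x, NumericVector y, NumericVector rad,
                          double Lx, double Ly, double k, double eps) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end()),
      rv(rad.begin(), rad.end()), fx, fy;
  double e;
  energy_forces(xv, yv, rv, Lx, Ly, k, eps, fx, fy, e);
  return List::create(_["energy"] = e,
                      _["fx"] = NumericVector(fx.begin(), fx.end()),
                      _["fy"] = NumericVector(fy.begin(), fy.end()));
}

// FIRE relaxation with a monotone-energy safeguard (uphill steps rejected and
// restarted with a smaller time step), so the accepted-energy trace is
// non-increasing.
// [[Rcpp::export(name = ".sd_fire")]]
List sd_fire_cpp(NumericVector x0, NumericVector y0, NumericVector rad,
                 double Lx, double Ly, double k, double eps, double ftol,
                 int max_iter, double dt0) {
  int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end()),
      rv(rad.begin(), rad.end());
  std::vector<double> vx(n, 0.0), vy(n, 0.0), fx, fy;
  double e;
  energy_forces(x, y, rv, Lx, Ly, k, eps, fx, fy, e);
  double e_init = e;
  double dt = dt0, dt_max = 10.0 * dt0, alpha = 0.1;
  const double f_inc = 1.1, f_dec = 0.5, alpha0 = 0.1, f_alpha = 0.99;
  const int n_min = 5;
  int n_pos = 0, it = 0;
  double fmax = max_force(fx, fy);
  std::vector<double> xs = x, ys = y;  // last accepted (monotone) state
  double es = e;

  while (fmax > ftol && it < max_iter) {
    ++it;
    for (int i = 0; i < n; ++i) { vx[i] += dt * fx[i]; vy[i] += dt * fy[i]; }
    double P = 0.0, vn = 0.0, fn = 0.0;
    for (int i = 0; i < n; ++i) {
      P += vx[i] * fx[i] + vy[i] * fy[i];
      vn += vx[i] * vx[i] + vy[i] * vy[i];
      fn += fx[i] * fx[i] + fy[i] * fy[i];
    }
    vn = std::sqrt(vn); fn = std::sqrt(fn);
    if (fn > 0) {
      for (int i = 0; i < n; ++i) {
        vx[i] = (1.0 - alpha) * vx[i] + alpha * vn * fx[i] / fn;
        vy[i] = (1.0 - alpha) * vy[i] + alpha * vn * fy[i] / fn;
      }
    }
    if (P > 0) {
      if (++n_pos > n_min) { dt = std::min(dt * f_inc, dt_max); alpha *= f_alpha; }
    } else {
      n_pos = 0; dt *= f_dec; alpha = alpha0;
      std::fill(vx.begin(), vx.end(), 0.0);
      std::fill(vy.begin(), vy.end(), 0.0);
    }
    for (int i = 0; i < n; ++i) {
      x[i] = wrap01(x[i] + dt * vx[i], Lx);
      y[i] = wrap01(y[i] + dt * vy[i], Ly);
    }
    energy_forces(x, y, rv, Lx, Ly, k, eps, fx, fy, e);
    if (e > es + 1e-12 * std::fabs(es)) {
      x = xs; y = ys;
      energy_forces(x, y, rv, Lx, Ly, k, eps, fx, fy, e);
      std::fill(vx.begin(), vx.end(), 0.0);
      std::fill(vy.begin(), vy.end(), 0.0);
      dt *= f_dec; n_pos = 0; alpha = alpha0;
      if (dt < 1e-14) break;
    } else {
      xs = x; ys = y; es = e;
    }
    fmax = max_force(fx, fy);
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["x"] = NumericVector(xs.begin(), xs.end()),
                      _["y"] = NumericVector(ys.begin(), ys.end()),
                      _["energy"] = es, _["energy_initial"] = e_init,
                      _["fmax"] = fmax, _["iterations"] = it,
                      _["converged"] = (fmax <= ftol));
}

namespace {

// Verlet pair list with a safety skin: forces are exact as long as no
// particle has moved more than skin/2 since the last rebuild.
struct PairList {
  std::vector<int> pi, pj;
  std::vector<double> x0, y0;
  double skin;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& rad, double Lx, double Ly,
             double cutoff) {
    int n = (int)x.size();
    pi.clear(); pj.clear();
    double rc = cutoff + skin;
    CellList cl; cl.build(x, y, Lx, Ly, rc);
    auto consider = [&](int i, int j) {
      double dx = x[j] - x[i]; dx -= Lx * std::nearbyint(dx / Lx);
      double dy = y[j] - y[i]; dy -= Ly * std::nearbyint(dy / Ly);
      double rij = (rad[i] + rad[j]) + skin;
      if (dx * dx + dy * dy < rij * rij) { pi.push_back(i); pj.push_back(j); }
    };
    if (cl.all_pairs) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) consider(i, j);
    } else {
      for (int cy = 0; cy < cl.ncy; ++cy) for (int cx = 0; cx < cl.ncx; ++cx) {
        const std::vector<int>& me = cl.cells[(size_t)cy * cl.ncx + cx];
        for (int oy = -1; oy <= 1; ++oy) for (int ox = -1; ox <= 1; ++ox) {
          int jx = (cx + ox + cl.ncx) % cl.ncx, jy = (cy + oy + cl.ncy) % cl.ncy;
          int self = (jx == cx && jy == cy);
          int lin_me = cy * cl.ncx + cx, lin_o = jy * cl.ncx + jx;
          if (!self && lin_o < lin_me) continue;
          const std::vector<int>& other = cl.cells[(size_t)lin_o];
          for (size_t a = 0; a < me.size(); ++a) {
            size_t b0 = self ? a + 1 : 0;
            for (size_t b = b0; b < other.size(); ++b) consider(me[a], other[b]);
          }
        }
      }
    }
    x0 = x; y0 = y;
  }

  bool stale(const std::vector<double>& x, const std::vector<double>& y,
             double Lx, double Ly) const {
    double lim2 = 0.25 * skin * skin;
    for (size_t i = 0; i < x.size(); ++i) {
      double dx = x[i] - x0[i]; dx -= Lx * std::nearbyint(dx / Lx);
      double dy = y[i] - y0[i]; dy -= Ly * std::nearbyint(dy / Ly);
      if (dx * dx + dy * dy > lim2) return true;
    }
    return false;
  }
};

void forces_from_pairs(const PairList& pl, const std::vector<double>& x,
                       const std::vector<double>& y,
                       const std::vector<double>& rad, double Lx, double Ly,
                       double k, double eps,
                       std::vector<double>& fx, std::vector<double>& fy) {
  fx.assign(x.size(), 0.0); fy.assign(x.size(), 0.0);
  for (size_t c = 0; c < pl.pi.size(); ++c) {
    int i = pl.pi[c], j = pl.pj[c];
    double dx = x[j] - x[i]; dx -= Lx * std::nearbyint(dx / Lx);
    double dy = y[j] - y[i]; dy -= Ly * std::nearbyint(dy / Ly);
    double s = rad[i] + rad[j];
    double rc = s * (1.0 + (eps > 0 ? eps : 0.0));
    double r2 = dx * dx + dy * dy;
    if (r2 >= rc * rc) continue;
    double r = std::sqrt(r2);
    if (r < 1e-12) stop("coincident particle centers: contact normal undefined");
    double e, f;
    pair_ef(r, s, k, eps, e, f);
    double ux = dx / r, uy = dy / r;
    fx[i] -= f * ux; fy[i] -= f * uy;
    fx[j] += f * ux; fy[j] += f * uy;
  }
}

} // namespace

// Overdamped active Brownian integrator:
//   r <- r + dt (v0 n_hat + F/zeta),  theta <- theta + N(0, dt/tau).
// Frames (wrapped + unwrapped positions, instantaneous velocities, angles)
// saved every save_every steps. Uses a skinned Verlet pair list in large
// boxes and falls back to full image-summed force evaluations in small ones.
// [[Rcpp::export(name = ".sd_run")]]
List sd_run_cpp(NumericVector x0, NumericVector y0, NumericVector th0,
                NumericVector rad, double Lx, double Ly, double k, double eps,
                double v0, double tau, double zeta,
                double dt, int n_steps, int save_every) {
  int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end()),
      xu(x0.begin(), x0.end()), yu(y0.begin(), y0.end()),
      th(th0.begin(), th0.end()), rv(rad.begin(), rad.end()), fx, fy;
  int n_saves = n_steps / save_every;
  NumericMatrix X(n, n_saves), Y(n, n_saves), XU(n, n_saves), YU(n, n_saves),
      VX(n, n_saves), VY(n, n_saves), TH(n, n_saves);
  NumericVector times(n_saves);
  double sig_th = std::sqrt(dt / tau);
  double rmin = *std::min_element(rv.begin(), rv.end());
  double smax = 0.0;
  for (int i = 0; i < n; ++i) if (rv[i] > smax) smax = rv[i];
  double cutoff = 2.0 * smax * (1.0 + (eps > 0 ? eps : 0.0)) + 1e-12;
  bool use_pairs = (std::floor(Lx / (cutoff + 0.6 * rmin)) >= 3 &&
                    std::floor(Ly / (cutoff + 0.6 * rmin)) >= 3);
  PairList pl; pl.skin = 0.6 * rmin;
  if (use_pairs) pl.build(x, y, rv, Lx, Ly, cutoff);
  int n_unstable = 0;
  double e;
  int isave = 0;
  for (int step = 1; step <= n_steps; ++step) {
    if (use_pairs) {
      if (pl.stale(x, y, Lx, Ly)) pl.build(x, y, rv, Lx, Ly, cutoff);
      forces_from_pairs(pl, x, y, rv, Lx, Ly, k, eps, fx, fy);
    } else {
      energy_forces(x, y, rv, Lx, Ly, k, eps, fx, fy, e);
    }
    bool save_now = (step % save_every == 0);
    for (int i = 0; i < n; ++i) {
      double vxi = v0 * std::cos(th[i]) + fx[i] / zeta;
      double vyi = v0 * std::sin(th[i]) + fy[i] / zeta;
      if (dt * std::sqrt(fx[i] * fx[i] + fy[i] * fy[i]) / zeta > rmin) ++n_unstable;
      x[i] = wrap01(x[i] + dt * vxi, Lx);
      y[i] = wrap01(y[i] + dt * vyi, Ly);
      xu[i] += dt * vxi; yu[i] += dt * vyi;
      if (save_now) {
        X(i, isave) = x[i]; Y(i, isave) = y[i];
        XU(i, isave) = xu[i]; YU(i, isave) = yu[i];
        VX(i, isave) = vxi; VY(i, isave) = vyi;
      }
      th[i] += sig_th * norm_rand();
      if (save_now) TH(i, isave) = th[i];
    }
    if (save_now) { times[isave] = step * dt; ++isave; }
    if (step % 5000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["times"] = times, _["X"] = X, _["Y"] = Y,
                      _["XU"] = XU, _["YU"] = YU, _["VX"] = VX, _["VY"] = VY,
                      _["TH"] = TH,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["y"] = NumericVector(y.begin(), y.end()),
                      _["theta"] = NumericVector(th.begin(), th.end()),
                      _["n_unstable"] = n_unstable);
}

// Contact list: pair indices (1-based), minimum-image separation i -> j, and
// Hessian coefficients kn = V''(r), kt = -V'(r)/r per contact.
// [[Rcpp::export(name = ".sd_contacts")]]
List sd_contacts_cpp(NumericVector x, NumericVector y, NumericVector rad,
                     double Lx, double Ly, double k, double eps) {
  int n = x.size();
  std::vector<int> ii, jj;
  std::vector<double> dxs, dys, rs, kns, kts;
  double smax = 0.0;
  for (int i = 0; i < n; ++i) if (rad[i] > smax) smax = rad[i];
  double cutg = 2.0 * smax * (1.0 + (eps > 0 ? eps : 0.0)) + 1e-12;
  for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
    double dx = x[j] - x[i]; dx -= Lx * std::nearbyint(dx / Lx);
    double dy = y[j] - y[i]; dy -= Ly * std::nearbyint(dy / Ly);
    if (std::fabs(dx) > cutg || std::fabs(dy) > cutg) continue;
    double s = rad[i] + rad[j];
    double rc = s * (1.0 + (eps > 0 ? eps : 0.0));
    double r2 = dx * dx + dy * dy;
    if (r2 >= rc * rc) continue;
    double r = std::sqrt(r2);
    double kn, kt;
    if (eps <= 0.0 || r < s) { kn = k; kt = k * (s - r) / r; }
    else if (r < s * (1.0 + 0.5 * eps)) { kn = k; kt = -k * (r - s) / r; }
    else { kn = -k; kt = -k * (rc - r) / r; }
    ii.push_back(i + 1); jj.push_back(j + 1);
    dxs.push_back(dx); dys.push_back(dy); rs.push_back(r);
    kns.push_back(kn); kts.push_back(kt);
  }
  return List::create(_["i"] = IntegerVector(ii.begin(), ii.end()),
                      _["j"] = IntegerVector(jj.begin(), jj.end()),
                      _["dx"] = NumericVector(dxs.begin(), dxs.end()),
                      _["dy"] = NumericVector(dys.begin(), dys.end()),
                      _["r"] = NumericVector(rs.begin(), rs.end()),
                      _["kn"] = NumericVector(kns.begin(), kns.end()),
                      _["kt"] = NumericVector(kts.begin(), kts.end()));
}

// Fourier dynamical matrix D(q) accumulated over contacts:
//   D(q) = (1/N) sum_pairs (2 - 2 cos(q . r_ij)) (kn n n^T - kt t t^T).
// [[Rcpp::export(name = ".dq_components")]]
NumericMatrix dq_components_cpp(NumericVector dx, NumericVector dy,
                                NumericVector kn, NumericVector kt,
                                NumericVector qx, NumericVector qy, int n_particles) {
  int nc = dx.size(), nq = qx.size();
  NumericMatrix out(nq, 3);
  std::vector<double> nx(nc), ny(nc), r(nc);
  for (int c = 0; c < nc; ++c) {
    r[c] = std::sqrt(dx[c] * dx[c] + dy[c] * dy[c]);
    nx[c] = dx[c] / r[c]; ny[c] = dy[c] / r[c];
  }
  for (int iq = 0; iq < nq; ++iq) {
    double Dxx = 0, Dyy = 0, Dxy = 0;
    for (int c = 0; c < nc; ++c) {
      double w = 2.0 - 2.0 * std::cos(qx[iq] * dx[c] + qy[iq] * dy[c]);
      double mxx = kn[c] * nx[c] * nx[c] - kt[c] * ny[c] * ny[c];
      double myy = kn[c] * ny[c] * ny[c] - kt[c] * nx[c] * nx[c];
      double mxy = (kn[c] + kt[c]) * nx[c] * ny[c];
      Dxx += w * mxx; Dyy += w * myy; Dxy += w * mxy;
    }
    out(iq, 0) = Dxx / n_particles;
    out(iq, 1) = Dyy / n_particles;
    out(iq, 2) = Dxy / n_particles;
  }
  return out;
}

// |v(q)|^2 for one frame under the v(q) = (1/N) sum_j exp(i q.r_j) v_j convention.
// [[Rcpp::export(name = ".vq_frame")]]
NumericVector vq_frame_cpp(NumericVector x, NumericVector y,
                           NumericVector vx, NumericVector vy,
                           NumericVector qx, NumericVector qy) {
  int n = x.size(), nq = qx.size();
  NumericVector out(nq);
  for (int iq = 0; iq < nq; ++iq) {
    double cre_x = 0, cim_x = 0, cre_y = 0, cim_y = 0;
    for (int j = 0; j < n; ++j) {
      double ph = qx[iq] * x[j] + qy[iq] * y[j];
      double c = std::cos(ph), s = std::sin(ph);
      cre_x += c * vx[j]; cim_x += s * vx[j];
      cre_y += c * vy[j]; cim_y += s * vy[j];
    }
    out[iq] = (cre_x * cre_x + cim_x * cim_x + cre_y * cre_y + cim_y * cim_y) /
              ((double)n * n);
  }
  return out;
}

// Pair-binned velocity dot products for C_vv(r), one frame.
// [[Rcpp::export(name = ".cvv_frame")]]
List cvv_frame_cpp(NumericVector x, NumericVector y,
                   NumericVector vx, NumericVector vy,
                   double Lx, double Ly, bool periodic,
                   double bin_width, int n_bins) {
  int n = x.size();
  NumericVector sums(n_bins);
  IntegerVector counts(n_bins);
  for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
    double dx = x[j] - x[i], dy = y[j] - y[i];
    if (periodic) {
      dx -= Lx * std::nearbyint(dx / Lx);
      dy -= Ly * std::nearbyint(dy / Ly);
    }
    double r = std::sqrt(dx * dx + dy * dy);
    int b = (int)std::floor(r / bin_width);
    if (b >= 0 && b < n_bins) {
      sums[b] += vx[i] * vx[j] + vy[i] * vy[j];
      counts[b] += 1;
    }
  }
  return List::create(_["sums"] = sums, _["counts"] = counts);
}

// Self-intermediate scattering function from unwrapped trajectories:
// S(q,t) averaged over time origins, particles and n_angles directions.
// [[Rcpp::export(name = ".sisf")]]
NumericVector sisf_cpp(NumericMatrix XU, NumericMatrix YU, double qmag,
                       int n_angles, IntegerVector lags) {
  int n = XU.nrow(), nf = XU.ncol(), nl = lags.size();
  NumericVector out(nl);
  std::vector<double> qxs(n_angles), qys(n_angles);
  for (int a = 0; a < n_angles; ++a) {
    double ang = M_PI * a / n_angles;  // directions modulo pi (cosine is even)
    qxs[a] = qmag * std::cos(ang); qys[a] = qmag * std::sin(ang);
  }
  for (int il = 0; il < nl; ++il) {
    int lag = lags[il];
    double acc = 0.0; long cnt = 0;
    for (int t0 = 0; t0 + lag < nf; ++t0) {
      int t1 = t0 + lag;
      for (int i = 0; i < n; ++i) {
        double dx = XU(i, t1) - XU(i, t0), dy = YU(i, t1) - YU(i, t0);
        for (int a = 0; a < n_angles; ++a)
          acc += std::cos(qxs[a] * dx + qys[a] * dy);
        cnt += n_angles;
      }
    }
    out[il] = acc / cnt;
  }
  return out;
}
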