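#include <Rcpp.h>
using namespace Rcpp;

// Inner loop of the swarm simulation. Mirrors the R-level reference step
// (advance() + group_directions()) exactly, including the RNG draw order:
// per step, tumble deflections for tumbling live agents in ascending index
// order, then heading noise for all live agents in ascending index order.

static inline double wrap_angle(double a) {
  const double twopi = 2.0 * M_PI;
  double r = a - twopi * std::floor((a + M_PI) / twopi);
  if (r <= -M_PI) r += twopi;
  return r;
}

struct Terrain {
  double tx, ty, AK, kappa, Ap, kx, ky, eps;
  int form; // 0 product of sines, 1 sum of cosines
  double conc(double x, double y) const {
    double dx = x - tx, dy = y - ty;
    double r = std::sqrt(dx * dx + dy * dy);
    double rc = r > eps ? r : eps;
    double bess = AK > 0 ? AK * R::bessel_k(kappa * rc, 0.0, 1.0) : 0.0;
    double per = (form == 0)
      ? Ap * std::sin(kx * x) * std::sin(ky * y)
      : Ap * 0.5 * (std::cos(kx * x) + std::cos(ky * y));
    return bess + per;
  }
  void grad(double x, double y, double &gx, double &gy) const {
    double dx = x - tx, dy = y - ty;
    double r = std::sqrt(dx * dx + dy * dy);
    double rc = r > eps ? r : eps;
    gx = 0.0; gy = 0.0;
    if (AK > 0 && r > 0) {
      double mag = -AK * kappa * R::bessel_k(kappa * rc, 1.0, 1.0);
      gx += mag * dx / r;
      gy += mag * dy / r;
    }
    if (Ap > 0) {
      if (form == 0) {
        gx += Ap * kx * std::cos(kx * x) * std::sin(ky * y);
        gy += Ap * ky * std::sin(kx * x) * std::cos(ky * y);
      } else {
        gx -= Ap * 0.5 * kx * std::sin(kx * x);
        gy -= Ap * 0.5 * ky * std::sin(ky * y);
      }
    }
  }
};

// [[Rcpp::export]]
List sim_core(NumericVector x0, NumericVector y0, NumericVector theta0,
              NumericVector w0, IntegerVector ssc0, IntegerVector tau,
              NumericVector conc0, NumericVector ctum0, int run_length_nominal,
              NumericVector terrain, int periodic_form,
              NumericVector motion, int gradient_mode, int tumble_reference,
              NumericVector zones, int policy_mode, NumericVector policy,
              double goal_radius, int max_steps, bool record) {
  const int n = x0.size();
  Terrain tr{terrain[0], terrain[1], terrain[2], terrain[3], terrain[4],
             terrain[5], terrain[6], terrain[7], periodic_form};
  const double v0 = motion[0], dt = motion[1], sigma_eta = motion[2],
               smin = motion[3], smax = motion[4], g0 = motion[5];
  const double Rr = zones[0], Ro = zones[1], Ra = zones[2], ratio = zones[3];
  const double fixed_w = policy[0], w_low = policy[1], w_high = policy[2];
  const double step_len = v0 * dt;
  const double smin2 = smin * smin, smax2 = smax * smax;
  const double tiny = 1e-12;

  std::vector<double> x(n), y(n), th(n), w(n), lastc(n), ctum(n), g(n, 0.0);
  std::vector<int> ssc(n);
  std::vector<bool> arrived(n);
  IntegerVector arrival_step(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    x[i] = x0[i]; y[i] = y0[i]; th[i] = theta0[i]; w[i] = w0[i];
    ssc[i] = ssc0[i]; lastc[i] = conc0[i]; ctum[i] = ctum0[i];
    double dx = x[i] - tr.tx, dy = y[i] - tr.ty;
    arrived[i] = std::sqrt(dx * dx + dy * dy) <= goal_radius;
    if (arrived[i]) arrival_step[i] = 0;
  }

  NumericMatrix xr, yr, thr, wr;
  LogicalMatrix ar;
  if (record) {
    xr = NumericMatrix(max_steps + 1, n);
    yr = NumericMatrix(max_steps + 1, n);
    thr = NumericMatrix(max_steps + 1, n);
    wr = NumericMatrix(max_steps + 1, n);
    ar = LogicalMatrix(max_steps + 1, n);
    for (int i = 0; i < n; ++i) {
      xr(0, i) = x[i]; yr(0, i) = y[i]; thr(0, i) = th[i]; wr(0, i) = w[i];
      ar(0, i) = arrived[i];
    }
  }

  std::vector<double> gdx(n), gdy(n);
  std::vector<bool> has_gd(n), tumbling(n);
  std::vector<double> delta(n), eta(n);

  double align_sum = 0.0; int align_steps = 0;
  double wsum = 0.0; long wcount = 0;
  int n_steps = 0;

  for (int t = 1; t <= max_steps; ++t) {
    bool all_arrived = true;
    for (int i = 0; i < n; ++i) if (!arrived[i]) { all_arrived = false; break; }
    if (all_arrived) break;
    n_steps = t;

    // group directions from the time-t state
    if (policy_mode > 0) {
      for (int i = 0; i < n; ++i) {
        has_gd[i] = false;
        if (arrived[i]) continue;
        double rx = 0, ry = 0, ox = 0, oy = 0, ax = 0, ay = 0;
        int nr = 0, noa = 0;
        for (int j = 0; j < n; ++j) {
          if (j == i || arrived[j]) continue;
          double dx = x[j] - x[i], dy = y[j] - y[i];
          double d = std::sqrt(dx * dx + dy * dy);
          if (d == 0.0) { // coincident: random repulsion direction
            double a = unif_rand() * 2.0 * M_PI;
            rx += std::cos(a); ry += std::sin(a); ++nr;
          } else if (d < Rr) {
            rx += dx / d; ry += dy / d; ++nr;
          } else if (d < Ro) {
            ox += std::cos(th[j]); oy += std::sin(th[j]); ++noa;
          } else if (d < Ra) {
            ax += dx / d; ay += dy / d; ++noa;
          }
        }
        double sx, sy;
        if (nr > 0) { sx = -rx; sy = -ry; }
        else if (noa > 0) { sx = ratio * ox + ax; sy = ratio * oy + ay; }
        else continue;
        double ns = std::sqrt(sx * sx + sy * sy);
        if (ns < tiny) continue;
        gdx[i] = sx / ns; gdy[i] = sy / ns; has_gd[i] = true;
      }
    } else {
      for (int i = 0; i < n; ++i) has_gd[i] = false;
    }

    // RNG block 1: tumble deflections
    const double run_len_nom = step_len * run_length_nominal;
    for (int i = 0; i < n; ++i) {
      tumbling[i] = !arrived[i] && ssc[i] >= tau[i];
      if (tumbling[i]) {
        if (gradient_mode == 2) { // concentration change over the whole run
          g[i] = (lastc[i] - ctum[i]) / run_len_nom;
          ctum[i] = lastc[i];
        }
        double s2 = smin2 + (smax2 - smin2) / (1.0 + std::exp(g[i] / g0));
        delta[i] = R::rnorm(0.0, std::sqrt(s2));
      }
    }
    // RNG block 2: internal noise
    for (int i = 0; i < n; ++i)
      if (!arrived[i]) eta[i] = R::rnorm(0.0, sigma_eta);

    // synchronous update
    for (int i = 0; i < n; ++i) {
      if (arrived[i]) continue;
      double base = th[i];
      if (has_gd[i] && (!tumbling[i] || tumble_reference == 1)) {
        double ux = std::cos(th[i]), uy = std::sin(th[i]);
        double vx = w[i] * ux + (1.0 - w[i]) * gdx[i];
        double vy = w[i] * uy + (1.0 - w[i]) * gdy[i];
        double nv = std::sqrt(vx * vx + vy * vy);
        base = (nv < tiny) ? th[i] : std::atan2(vy / nv, vx / nv);
      }
      double ang = tumbling[i] ? base + delta[i] : base;
      ang = wrap_angle(ang + eta[i]);
      x[i] += step_len * std::cos(ang);
      y[i] += step_len * std::sin(ang);
      th[i] = ang;
      double newc = tr.conc(x[i], y[i]);
      double dC = newc - lastc[i];
      if (gradient_mode == 0) {
        g[i] = dC / step_len;
      } else if (gradient_mode == 1) {
        double gx, gy;
        tr.grad(x[i], y[i], gx, gy);
        g[i] = gx * std::cos(ang) + gy * std::sin(ang);
      }
      if (policy_mode == 2) w[i] = dC > 0 ? w_high : w_low;
      lastc[i] = newc;
      ssc[i] = tumbling[i] ? 1 : ssc[i] + 1;
      double dx = x[i] - tr.tx, dy = y[i] - tr.ty;
      if (std::sqrt(dx * dx + dy * dy) <= goal_radius) {
        arrived[i] = true;
        arrival_step[i] = t;
      }
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(th[i]))
        stop("non-finite agent state at step %d", t);
    }

    // online metrics over agents not yet absorbed at the end of the step
    double px = 0, py = 0; int nl = 0;
    for (int i = 0; i < n; ++i) {
      if (arrived[i]) continue;
      px += std::cos(th[i]); py += std::sin(th[i]);
      wsum += w[i]; ++wcount; ++nl;
    }
    if (nl > 0) {
      align_sum += std::sqrt(px * px + py * py) / nl;
      ++align_steps;
    }

    if (record) {
      for (int i = 0; i < n; ++i) {
        xr(t, i) = x[i]; yr(t, i) = y[i]; thr(t, i) = th[i]; wr(t, i) = w[i];
        ar(t, i) = arrived[i];
      }
    }
  }

  List out = List::create(
    _["n_steps"] = n_steps,
    _["arrival_step"] = arrival_step,
    _["alignment"] = align_steps > 0 ? align_sum / align_steps : NA_REAL,
    _["mean_weight"] = wcount > 0 ? wsum / wcount : NA_REAL,
    _["x_final"] = NumericVector(x.begin(), x.end()),
    _["y_final"] = NumericVector(y.begin(), y.end()),
    _["theta_final"] = NumericVector(th.begin(), th.end()),
    _["w_final"] = NumericVector(w.begin(), w.end()),
    _["arrived_final"] = LogicalVector(arrived.begin(), arrived.end()));
  if (record) {
    out["x"] = xr; out["y"] = yr; out["theta"] = thr; out["w"] = wr;
    out["arrived"] = ar;
  }
  return out;
}
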