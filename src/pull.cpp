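// Langevin (BAOAB) constant-velocity pulling of a bead-spring chain with
// permanently breakable cross-links. Units: nm, ps, amu, kJ/mol (so that
// k_B = 0.00831446 kJ/mol/K and no further conversion is needed).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.00831446262;

// [[Rcpp::export]]
List pull_cpp(NumericMatrix pos0, NumericVector mass,
              IntegerVector b_i, IntegerVector b_j,
              NumericVector b_k, NumericVector b_r0,
              IntegerVector x_i, IntegerVector x_j,
              NumericVector x_k, NumericVector x_r0, NumericVector x_break,
              IntegerVector groupA, IntegerVector groupB,
              double k_pull, double rate, double temperature,
              double dt, double gamma, int record_every,
              int max_steps, NumericVector axis, double max_xi,
              int o_stride, double grace) {
  const int n = pos0.nrow();
  const int nb = b_i.size(), nx = x_i.size();
  std::vector<double> x(3 * n), v(3 * n, 0.0), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = pos0(i, c);

  RNGScope scope;
  if (temperature > 0) {
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(KB * temperature / mass[i]);
      for (int c = 0; c < 3; ++c) v[3 * i + c] = s * norm_rand();
    }
  }

  std::vector<bool> alive(nx, true);
  double massA = 0, massB = 0;
  for (int k = 0; k < groupA.size(); ++k) massA += mass[groupA[k] - 1];
  for (int k = 0; k < groupB.size(); ++k) massB += mass[groupB[k] - 1];

  auto com_xi = [&](void) {
    double ca = 0, cb = 0;
    for (int c = 0; c < 3; ++c) {
      double sa = 0, sb = 0;
      for (int k = 0; k < groupA.size(); ++k) {
        int i = groupA[k] - 1; sa += mass[i] * x[3 * i + c];
      }
      for (int k = 0; k < groupB.size(); ++k) {
        int i = groupB[k] - 1; sb += mass[i] * x[3 * i + c];
      }
      ca += axis[c] * sa / massA;
      cb += axis[c] * sb / massB;
    }
    return cb - ca;
  };

  const double xi0 = com_xi();
  double pot = 0.0;

  std::vector<double> rec_t, rec_xi, rec_f, rec_e;
  std::vector<double> ev_t, ev_f; std::vector<int> ev_i, ev_j;

  auto forces = [&](double t, double &xi_out, double &fpull_out) {
    std::fill(f.begin(), f.end(), 0.0);
    pot = 0.0;
    for (int s = 0; s < nb; ++s) {
      int i = b_i[s] - 1, j = b_j[s] - 1;
      double d2 = 0, dv[3];
      for (int c = 0; c < 3; ++c) {
        dv[c] = x[3 * i + c] - x[3 * j + c]; d2 += dv[c] * dv[c];
      }
      double d = std::sqrt(d2), str = d - b_r0[s];
      double fac = -b_k[s] * str / (d > 1e-12 ? d : 1e-12);
      pot += 0.5 * b_k[s] * str * str;
      for (int c = 0; c < 3; ++c) {
        f[3 * i + c] += fac * dv[c]; f[3 * j + c] -= fac * dv[c];
      }
    }
    for (int s = 0; s < nx; ++s) {
      if (!alive[s]) continue;
      int i = x_i[s] - 1, j = x_j[s] - 1;
      double d2 = 0, dv[3];
      for (int c = 0; c < 3; ++c) {
        dv[c] = x[3 * i + c] - x[3 * j + c]; d2 += dv[c] * dv[c];
      }
      double d = std::sqrt(d2), str = d - x_r0[s];
      double fac = -x_k[s] * str / (d > 1e-12 ? d : 1e-12);
      pot += 0.5 * x_k[s] * str * str;
      for (int c = 0; c < 3; ++c) {
        f[3 * i + c] += fac * dv[c]; f[3 * j + c] -= fac * dv[c];
      }
    }
    double xi = com_xi();
    double target = xi0 + rate * t;
    double fpull = k_pull * (target - xi);   // force transmitted by the spring
    pot += 0.5 * k_pull * (target - xi) * (target - xi);
    for (int k = 0; k < groupB.size(); ++k) {
      int i = groupB[k] - 1;
      double w = mass[i] / massB;
      for (int c = 0; c < 3; ++c) f[3 * i + c] += fpull * w * axis[c];
    }
    for (int k = 0; k < groupA.size(); ++k) {
      int i = groupA[k] - 1;
      double w = mass[i] / massA;
      for (int c = 0; c < 3; ++c) f[3 * i + c] -= fpull * w * axis[c];
    }
    xi_out = xi; fpull_out = fpull;
    return;
  };

  double xi, fpull;
  forces(0.0, xi, fpull);
  // thermostat applied every o_stride steps with the exact OU update over
  // the stride interval (o_stride * dt remains far below 1/gamma)
  const double c1 = std::exp(-gamma * o_stride * dt);
  const double c2 = (gamma > 0 && temperature > 0)
    ? std::sqrt((1.0 - c1 * c1) * KB * temperature) : 0.0;

  int step = 0;
  bool blown = false;
  double last_t = 0;
  for (step = 0; step < max_steps; ++step) {
    double t = step * dt;
    // B: half kick
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) v[3 * i + c] += 0.5 * dt * f[3 * i + c] / mass[i];
    // A: half drift
    for (int k = 0; k < 3 * n; ++k) x[k] += 0.5 * dt * v[k];
    // O: thermostat
    if (gamma > 0 && (step % o_stride == 0)) {
      for (int i = 0; i < n; ++i) {
        double s = c2 / std::sqrt(mass[i]);
        for (int c = 0; c < 3; ++c) {
          v[3 * i + c] = c1 * v[3 * i + c] +
            (temperature > 0 ? s * norm_rand() : 0.0);
        }
      }
    }
    // A: half drift
    for (int k = 0; k < 3 * n; ++k) x[k] += 0.5 * dt * v[k];
    // forces at new positions, then B: half kick
    forces(t + dt, xi, fpull);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) v[3 * i + c] += 0.5 * dt * f[3 * i + c] / mass[i];

    if (!std::isfinite(xi) || !std::isfinite(fpull)) { blown = true; break; }
    last_t = t + dt;

    // rupture check: permanent removal past the extension threshold
    for (int s = 0; s < nx; ++s) {
      if (!alive[s]) continue;
      int i = x_i[s] - 1, j = x_j[s] - 1;
      double d2 = 0;
      for (int c = 0; c < 3; ++c) {
        double dc = x[3 * i + c] - x[3 * j + c]; d2 += dc * dc;
      }
      if (std::sqrt(d2) > x_r0[s] + x_break[s]) {
        alive[s] = false;
        ev_t.push_back(last_t); ev_f.push_back(fpull);
        ev_i.push_back(x_i[s]); ev_j.push_back(x_j[s]);
      }
    }

    if ((step + 1) % record_every == 0) {
      double kin = 0;
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          kin += 0.5 * mass[i] * v[3 * i + c] * v[3 * i + c];
      rec_t.push_back(last_t); rec_xi.push_back(xi);
      rec_f.push_back(fpull); rec_e.push_back(kin + pot);
    }
    if (xi >= max_xi) break;
    // once every cross-link has ruptured the unfolding story is over; run a
    // grace window to record the force decay, then stop
    if (nx > 0 && ev_t.size() == (size_t)nx &&
        last_t >= ev_t.back() + grace) break;
  }

  NumericMatrix fin(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) fin(i, c) = x[3 * i + c];
  LogicalVector alive_out(nx);
  for (int s = 0; s < nx; ++s) alive_out[s] = alive[s];

  return List::create(
    _["time"] = wrap(rec_t), _["separation"] = wrap(rec_xi),
    _["force"] = wrap(rec_f), _["energy"] = wrap(rec_e),
    _["event_time"] = wrap(ev_t), _["event_force"] = wrap(ev_f),
    _["event_i"] = wrap(ev_i), _["event_j"] = wrap(ev_j),
    _["final_pos"] = fin, _["alive"] = alive_out,
    _["blown"] = blown, _["last_time"] = last_t, _["xi0"] = xi0);
}
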