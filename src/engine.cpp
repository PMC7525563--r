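// Coarse-grained engine: WCA + truncated Coulomb + harmonic bonded terms,
// BAOAB Langevin integration.  All quantities in reduced units (sigma, kT,
// e); orthorhombic periodic box with the minimum-image convention.
// Desk-scale systems (<= a few hundred sites): the non-bonded loop is a
// direct O(n^2) pair sweep, which at these sizes beats a cell list because
// the Coulomb cutoff sphere covers most of the box.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Params {
  double sigma_s, sigma_o, epsilon;
  double ke;          // vacuum Bjerrum length in sigma units
  double eps_r;
  double r_cut;       // Coulomb cutoff (sigma)
  double k_bond_so, r0_so;
  double k_angle_oso, theta0_oso;   // theta0 in radians
  double k_bond_bb, r0_bb;
  double k_bend, theta0_bend;       // radians (pi)
};

inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

// pair exclusion: directly bonded pairs (S-O within a monomer, backbone
// S-S neighbours) and the two O sites of the same monomer
inline bool excluded(int ci, int cj, int mi, int mj, int si, int sj) {
  if (ci != cj) return false;
  if (mi == mj) return true;
  return si == 1 && sj == 1 && std::abs(mi - mj) == 1;
}

struct Breakdown { double wca = 0, coulomb = 0, bond = 0, angle = 0; };

void compute_forces(const std::vector<double>& x,
                    const std::vector<int>& chain,
                    const std::vector<int>& mono,
                    const std::vector<int>& isS,
                    const std::vector<double>& q,
                    const IntegerMatrix& bonds,
                    const IntegerMatrix& angles,
                    const double* box, bool periodic,
                    const Params& p,
                    std::vector<double>& f, Breakdown& e) {
  const int n = (int)chain.size();
  std::fill(f.begin(), f.end(), 0.0);
  e = Breakdown();

  const double rc2 = p.r_cut * p.r_cut;
  const double pref = p.ke / p.eps_r;
  const double wca_cut_ss = std::pow(2.0, 1.0 / 3.0) * p.sigma_s * p.sigma_s;
  const double sig_so = 0.5 * (p.sigma_s + p.sigma_o);
  const double wca_cut_so = std::pow(2.0, 1.0 / 3.0) * sig_so * sig_so;
  const double wca_cut_oo = std::pow(2.0, 1.0 / 3.0) * p.sigma_o * p.sigma_o;

  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
    for (int j = i + 1; j < n; ++j) {
      if (excluded(chain[i], chain[j], mono[i], mono[j], isS[i], isS[j]))
        continue;
      double dx = xi - x[3 * j], dy = yi - x[3 * j + 1],
             dz = zi - x[3 * j + 2];
      if (periodic) {
        dx = min_image(dx, box[0]);
        dy = min_image(dy, box[1]);
        dz = min_image(dz, box[2]);
      }
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rc2) continue;   // pairs at exactly r_c are included
      double f_over_r = 0.0;

      // WCA with per-pair diameter (S/S, S/O, O/O)
      double sig2, wcut2;
      if (isS[i] && isS[j])       { sig2 = p.sigma_s * p.sigma_s; wcut2 = wca_cut_ss; }
      else if (!isS[i] && !isS[j]){ sig2 = p.sigma_o * p.sigma_o; wcut2 = wca_cut_oo; }
      else                        { sig2 = sig_so * sig_so;       wcut2 = wca_cut_so; }
      if (r2 < wcut2) {
        const double sr2 = sig2 / r2;
        const double s6 = sr2 * sr2 * sr2, s12 = s6 * s6;
        e.wca += 4.0 * p.epsilon * (s12 - s6) + p.epsilon;
        f_over_r += 24.0 * p.epsilon * (2.0 * s12 - s6) / r2;
      }

      // sharply truncated Coulomb
      const double qq = q[i] * q[j];
      if (qq != 0.0) {
        const double inv_r = 1.0 / std::sqrt(r2);
        const double u = pref * qq * inv_r;
        e.coulomb += u;
        f_over_r += u * inv_r * inv_r;
      }

      f[3 * i] += f_over_r * dx; f[3 * j] -= f_over_r * dx;
      f[3 * i + 1] += f_over_r * dy; f[3 * j + 1] -= f_over_r * dy;
      f[3 * i + 2] += f_over_r * dz; f[3 * j + 2] -= f_over_r * dz;
    }
  }

  // bonds: kind 0 = S-O, 1 = backbone
  for (int b = 0; b < bonds.nrow(); ++b) {
    const int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    const double k = bonds(b, 2) == 0 ? p.k_bond_so : p.k_bond_bb;
    const double r0 = bonds(b, 2) == 0 ? p.r0_so : p.r0_bb;
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    if (periodic) {
      dx = min_image(dx, box[0]);
      dy = min_image(dy, box[1]);
      dz = min_image(dz, box[2]);
    }
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double dr = r - r0;
    e.bond += 0.5 * k * dr * dr;
    const double fr = -k * dr / r;
    f[3 * i] += fr * dx; f[3 * j] -= fr * dx;
    f[3 * i + 1] += fr * dy; f[3 * j + 1] -= fr * dy;
    f[3 * i + 2] += fr * dz; f[3 * j + 2] -= fr * dz;
  }

  // angles: kind 0 = O-S-O, 1 = backbone bend (theta0 = pi)
  for (int a = 0; a < angles.nrow(); ++a) {
    const int i = angles(a, 0) - 1, j = angles(a, 1) - 1,
              k3 = angles(a, 2) - 1;
    const double k = angles(a, 3) == 0 ? p.k_angle_oso : p.k_bend;
    const double th0 = angles(a, 3) == 0 ? p.theta0_oso : p.theta0_bend;
    double ax = x[3 * i] - x[3 * j], ay = x[3 * i + 1] - x[3 * j + 1],
           az = x[3 * i + 2] - x[3 * j + 2];
    double bx = x[3 * k3] - x[3 * j], by = x[3 * k3 + 1] - x[3 * j + 1],
           bz = x[3 * k3 + 2] - x[3 * j + 2];
    if (periodic) {
      ax = min_image(ax, box[0]); ay = min_image(ay, box[1]);
      az = min_image(az, box[2]);
      bx = min_image(bx, box[0]); by = min_image(by, box[1]);
      bz = min_image(bz, box[2]);
    }
    const double la = std::sqrt(ax * ax + ay * ay + az * az);
    const double lb = std::sqrt(bx * bx + by * by + bz * bz);
    double c = (ax * bx + ay * by + az * bz) / (la * lb);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    const double th = std::acos(c);
    const double dth = th - th0;
    e.angle += 0.5 * k * dth * dth;
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-6) s = 1e-6;
    const double coef = k * dth / s;   // dE/dtheta / sin(theta)
    // F_i = coef * d(cos)/d r_i ; d(cos)/d r_i = b/(la lb) - c a/la^2
    const double fia = coef * (bx / (la * lb) - c * ax / (la * la));
    const double fib = coef * (by / (la * lb) - c * ay / (la * la));
    const double fic = coef * (bz / (la * lb) - c * az / (la * la));
    const double fka = coef * (ax / (la * lb) - c * bx / (lb * lb));
    const double fkb = coef * (ay / (la * lb) - c * by / (lb * lb));
    const double fkc = coef * (az / (la * lb) - c * bz / (lb * lb));
    f[3 * i] += fia; f[3 * i + 1] += fib; f[3 * i + 2] += fic;
    f[3 * k3] += fka; f[3 * k3 + 1] += fkb; f[3 * k3 + 2] += fkc;
    f[3 * j] -= fia + fka; f[3 * j + 1] -= fib + fkb;
    f[3 * j + 2] -= fic + fkc;
  }
}

Params params_from_list(const List& prm) {
  Params p;
  p.sigma_s = as<double>(prm["sigma"]);
  p.sigma_o = as<double>(prm["sigma_o"]);
  p.epsilon = as<double>(prm["epsilon_wca"]);
  p.ke = as<double>(prm["coulomb_prefactor"]);
  p.eps_r = as<double>(prm["dielectric_eps_r"]);
  p.r_cut = as<double>(prm["r_cut_coulomb"]);
  p.k_bond_so = as<double>(prm["k_bond_SO"]);
  p.r0_so = as<double>(prm["r0_SO"]);
  p.k_angle_oso = as<double>(prm["k_angle_OSO"]);
  p.theta0_oso = as<double>(prm["theta0_OSO"]) * M_PI / 180.0;
  p.k_bond_bb = as<double>(prm["k_bond_backbone"]);
  p.r0_bb = as<double>(prm["r0_backbone"]);
  p.k_bend = as<double>(prm["k_bend_backbone"]);
  p.theta0_bend = M_PI;
  return p;
}

} // namespace

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector box, bool periodic,
                       IntegerVector chain, IntegerVector mono,
                       IntegerVector isS, NumericVector charge,
                       IntegerMatrix bonds, IntegerMatrix angles,
                       List prm) {
  const int n = pos.nrow();
  Params p = params_from_list(prm);
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = pos(i, d);
  std::vector<int> ch(chain.begin(), chain.end()),
      mo(mono.begin(), mono.end()), ss(isS.begin(), isS.end());
  std::vector<double> q(charge.begin(), charge.end());
  Breakdown e;
  compute_forces(x, ch, mo, ss, q, bonds, angles, box.begin(), periodic,
                 p, f, e);
  NumericMatrix fr(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fr(i, d) = f[3 * i + d];
  return List::create(_["wca"] = e.wca, _["coulomb"] = e.coulomb,
                      _["bond"] = e.bond, _["angle"] = e.angle,
                      _["forces"] = fr);
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericMatrix vel,
                      NumericVector box, bool periodic,
                      IntegerVector chain, IntegerVector mono,
                      IntegerVector isS, NumericVector charge,
                      IntegerMatrix bonds, IntegerMatrix angles,
                      List prm, NumericVector epsr_step,
                      NumericVector kT_step, double dt, double gamma,
                      int n_steps, int save_every, int seed,
                      int log_every) {
  const int n = pos.nrow();
  Params p = params_from_list(prm);
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = pos(i, d);
      v[3 * i + d] = vel(i, d);
    }
  std::vector<int> ch(chain.begin(), chain.end()),
      mo(mono.begin(), mono.end()), ss(isS.begin(), isS.end());
  std::vector<double> q(charge.begin(), charge.end());

  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double c1 = gamma > 0 ? std::exp(-gamma * dt) : 1.0;
  const double c2 = gamma > 0 ? std::sqrt(1.0 - c1 * c1) : 0.0;

  Breakdown e;
  if (epsr_step.size() > 0) p.eps_r = epsr_step[0];
  compute_forces(x, ch, mo, ss, q, bonds, angles, box.begin(), periodic,
                 p, f, e);

  std::vector<NumericMatrix> frames;
  std::vector<int> frame_steps;
  std::vector<double> frame_eps;
  std::vector<std::array<double, 8>> log;
  bool ok = true;
  int fail_step = -1;

  auto kinetic = [&]() {
    double ke = 0;
    for (int i = 0; i < 3 * n; ++i) ke += v[i] * v[i];
    return 0.5 * ke;
  };
  auto snapshot = [&](int step, double eps) {
    NumericMatrix fm(n, 3);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) fm(i, d) = x[3 * i + d];
    frames.push_back(fm);
    frame_steps.push_back(step);
    frame_eps.push_back(eps);
  };
  auto log_row = [&](int step) {
    const double ke = kinetic();
    log.push_back({(double)step, e.wca, e.coulomb, e.bond, e.angle,
                   e.wca + e.coulomb + e.bond + e.angle, ke,
                   2.0 * ke / (3.0 * n)});
  };

  snapshot(0, p.eps_r);
  log_row(0);

  for (int s = 1; s <= n_steps; ++s) {
    const double kT = kT_step.size() == 1 ? kT_step[0] : kT_step[s - 1];
    // BAOAB
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    if (c2 > 0.0) {
      const double amp = c2 * std::sqrt(kT);
      for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + amp * gauss(rng);
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // dielectric schedule applies before the force evaluation
    if (epsr_step.size() == 1) p.eps_r = epsr_step[0];
    else if (epsr_step.size() > 1) p.eps_r = epsr_step[s - 1];
    compute_forces(x, ch, mo, ss, q, bonds, angles, box.begin(), periodic,
                   p, f, e);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];

    bool finite = true;
    for (int i = 0; i < 3 * n && finite; ++i)
      if (!std::isfinite(x[i])) finite = false;
    if (!finite) { ok = false; fail_step = s; break; }
    if (save_every > 0 && s % save_every == 0) snapshot(s, p.eps_r);
    if (log_every > 0 && s % log_every == 0) log_row(s);
    if (s % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix xm(n, 3), vm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      xm(i, d) = x[3 * i + d];
      vm(i, d) = v[3 * i + d];
    }
  NumericMatrix lg(log.size(), 8);
  for (size_t r = 0; r < log.size(); ++r)
    for (int cidx = 0; cidx < 8; ++cidx) lg(r, cidx) = log[r][cidx];
  colnames(lg) = CharacterVector::create("step", "wca", "coulomb", "bond",
                                         "angle", "total", "kinetic",
                                         "temperature");
  return List::create(_["frames"] = wrap(frames),
                      _["frame_steps"] = wrap(frame_steps),
                      _["frame_eps"] = wrap(frame_eps),
                      _["positions"] = xm, _["velocities"] = vm,
                      _["log"] = lg, _["ok"] = ok,
                      _["fail_step"] = fail_step);
}
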