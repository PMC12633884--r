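#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Event-driven Euler--Maruyama integration of two coupled phase oscillators
// with discrete resets at each tap (phase crossing of 2*pi).
//
// Within a step of length dt the phase of player i moves linearly by
//   inc_i = omega_i * dt + sigma_i * sqrt(dt) * xi_i
// (xi_i a standard-normal draw from R's RNG, so set.seed() controls runs).
// A 2*pi crossing inside the step is located by linear interpolation on that
// path; the tapper's phase is set to exactly 0 at the crossing and the
// partner's phase/period reset is applied at the same instant, after which
// the remainder of the step is integrated with the updated angular velocity.

static const double TWO_PI = 6.283185307179586476925286766559;

// Built-in response functions; id 0 dispatches to a user R function.
enum RespId { RESP_RFUN = 0, RESP_NEG_SIN = 1, RESP_ZERO = 2 };

static inline double resp_eval(int id, const Function &f, double theta) {
  switch (id) {
  case RESP_NEG_SIN: return -std::sin(theta);
  case RESP_ZERO:    return 0.0;
  default:           return as<double>(f(theta));
  }
}

struct Player {
  double a, b, k, sigma, omega0;
  int z_id, y_id;
  Function zf, yf;
  Player(double a_, double b_, double k_, double sigma_, double omega0_,
         int z_id_, int y_id_, Function zf_, Function yf_)
    : a(a_), b(b_), k(k_), sigma(sigma_), omega0(omega0_),
      z_id(z_id_), y_id(y_id_), zf(zf_), yf(yf_) {}
};

// Apply the partner reset to player j at the instant player i taps.
// Returns the number of taps of j triggered by the reset itself (a phase
// jump across 2*pi counts as a tap of j).
static int partner_reset(double theta[], double omega[], int j,
                         const Player &pj) {
  double z = resp_eval(pj.z_id, pj.zf, theta[j]);
  double y = resp_eval(pj.y_id, pj.yf, theta[j]);
  theta[j] += pj.a * z;
  omega[j] += pj.b * y - pj.k * (omega[j] - pj.omega0);
  if (omega[j] <= 0.0)
    stop("degenerate run: angular velocity of player %d driven to %.6g <= 0 by a partner reset",
         j + 1, omega[j]);
  if (theta[j] >= TWO_PI) {
    theta[j] -= TWO_PI;
    if (theta[j] >= TWO_PI)
      stop("degenerate run: phase jump of player %d exceeded a full period", j + 1);
    return 1;
  }
  return 0;
}

// [[Rcpp::export]]
List simulate_pair_cpp(int n_taps, double dt,
                       NumericVector a, NumericVector b, NumericVector k,
                       NumericVector sigma, NumericVector omega0,
                       IntegerVector z_id, IntegerVector y_id,
                       Function z1, Function y1, Function z2, Function y2,
                       bool t0_is_tap, int tie_first, double max_time) {
  Player p1(a[0], b[0], k[0], sigma[0], omega0[0], z_id[0], y_id[0], z1, y1);
  Player p2(a[1], b[1], k[1], sigma[1], omega0[1], z_id[1], y_id[1], z2, y2);
  const Player *pl[2] = {&p1, &p2};

  double theta[2] = {0.0, 0.0};
  double omega[2] = {omega0[0], omega0[1]};
  std::vector<double> taps[2];
  taps[0].reserve(n_taps);
  taps[1].reserve(n_taps);
  int count[2] = {0, 0};
  if (t0_is_tap) {
    taps[0].push_back(0.0);
    taps[1].push_back(0.0);
    count[0] = count[1] = 1;
  }

  const double sqdt = std::sqrt(dt);
  double t = 0.0;
  RNGScope rng;

  while (count[0] < n_taps || count[1] < n_taps) {
    if (t > max_time)
      stop("simulation exceeded max_time = %.3f s before reaching %d taps", max_time, n_taps);
    double xi0 = norm_rand(), xi1 = norm_rand();
    if (!std::isfinite(xi0) || !std::isfinite(xi1))
      stop("non-finite noise draw");
    // total phase noise over the step, apportioned linearly in time
    double nu[2] = {pl[0]->sigma * sqdt * xi0, pl[1]->sigma * sqdt * xi1};

    double f = 0.0; // fraction of the step already integrated
    int guard = 0;
    while (f < 1.0) {
      if (++guard > 64)
        stop("degenerate run: more than 64 tap events inside one integration step");
      // phase slope per unit step-fraction (drift uses the current omega)
      double slope[2] = {omega[0] * dt + nu[0], omega[1] * dt + nu[1]};
      double fc[2] = {2.0, 2.0};
      for (int i = 0; i < 2; ++i)
        if (slope[i] > 0.0) {
          double fi = f + (TWO_PI - theta[i]) / slope[i];
          if (fi <= 1.0) fc[i] = fi;
        }
      if (fc[0] > 1.0 && fc[1] > 1.0) {
        theta[0] += (1.0 - f) * slope[0];
        theta[1] += (1.0 - f) * slope[1];
        break;
      }
      int i; // tapping player this event (ties go to tie_first)
      if (fc[0] == fc[1]) i = tie_first - 1;
      else i = (fc[0] < fc[1]) ? 0 : 1;
      double fstar = fc[i];
      if (fstar < f) fstar = f; // clamp numerical underrun
      theta[0] += (fstar - f) * slope[0];
      theta[1] += (fstar - f) * slope[1];
      f = fstar;
      double t_ev = t + f * dt;
      int j = 1 - i;

      theta[i] = 0.0;
      if (count[i] < n_taps) taps[i].push_back(t_ev);
      ++count[i];
      int extra = partner_reset(theta, omega, j, *pl[j]);
      if (extra) {
        // the reset pushed j across 2*pi: j taps at the same instant and
        // i receives a reset in turn (at theta[i] = 0)
        if (count[j] < n_taps) taps[j].push_back(t_ev);
        ++count[j];
        if (partner_reset(theta, omega, i, *pl[i]))
          stop("degenerate run: cascading resets at t = %.6f s", t_ev);
      }
      if (count[0] < n_taps && count[1] < n_taps &&
          std::abs(count[0] - count[1]) > 1)
        stop("runaway desynchronization: tap counts %d vs %d at t = %.6f s",
             count[0], count[1], t_ev);
    }
    t += dt;
  }

  return List::create(_["taps_p1"] = wrap(taps[0]),
                      _["taps_p2"] = wrap(taps[1]),
                      _["omega_final"] = NumericVector::create(omega[0], omega[1]));
}
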