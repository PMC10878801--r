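#include <Rcpp.h>
using namespace Rcpp;

// splitmix64 mixer; used to derive independent per-cell seeds from a master
// seed so that adding experiment cells never perturbs other cells' streams.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export]]
int hash_seed_cpp(std::string key) {
  uint64_t h = 0x853C49E6748FEA9BULL;
  for (size_t i = 0; i < key.size(); ++i) {
    h = splitmix64(h ^ (uint64_t)(unsigned char)key[i]);
  }
  // map into [1, 2^31 - 2]: a valid, strictly positive R integer seed
  return (int)(h % 2147483645ULL) + 1;
}

// Discrete-time closed-loop trial at a single clock (sensor rate == frame
// rate).  Per sample: bout transition -> emit noisy trackball increments ->
// leaky evidence update (gated by the *current* stimulus-active flag) ->
// hysteresis motion detector -> gate computes the active flag for the NEXT
// sample (one-sample sensor->controller->display latency).
//
// mode: 0 = OPEN_LOOP, 1 = IN_PHASE, 2 = OUT_OF_PHASE
// behaviour codes: 0 = PAUSE, 1 = WALK_FORWARD, 2 = WALK_TURN
// turn_sign_in: +1/-1 imposed (within-subject persistence), 0 = draw here.
//
// Uses R's RNG throughout; draw order is mirrored exactly by the R-level
// step_agent()/choose_bout_at_pause_end() so the two implementations can be
// compared sample-for-sample under a shared seed.
// [[Rcpp::export]]
List agent_trial_cpp(List par, int n, int mode, double signal_sign,
                     double threshold, int debounce_on, int debounce_off,
                     double turn_sign_in) {
  const double tau_w  = as<double>(par["tau_w"]);
  const double t_min  = as<double>(par["t_min"]);
  const double alpha  = as<double>(par["alpha"]);
  const double t_max  = as<double>(par["t_max"]);
  const double v_walk = as<double>(par["v_walk"]);
  const double omega  = as<double>(par["turn_yaw_rate"]);
  const double w_pause = as<double>(par["w_pause"]);
  const double w_walk  = as<double>(par["w_walk"]);
  const double tau_e   = as<double>(par["tau_e"]);
  const double beta    = as<double>(par["beta"]);
  const double k_turn  = as<double>(par["k_turn"]);
  const double b_turn  = as<double>(par["b_turn"]);
  const double sigma   = as<double>(par["sigma"]);
  const double rate    = as<double>(par["sample_rate"]);
  const double dt = 1.0 / rate;

  NumericVector fwd(n), yaw(n), lat(n), Ev(n), mag(n);
  IntegerVector behav(n);
  LogicalVector act(n), mov(n);

  double turn_sign = turn_sign_in;
  if (turn_sign == 0.0) turn_sign = (unif_rand() < 0.5) ? -1.0 : 1.0;

  int b = 0;                    // start paused: trial begins pre-locomotion
  double tib = 0.0;             // time in current bout (s)
  double walk_end = 0.0;        // scheduled walk-bout duration (s)
  double E = 0.0;               // evidence
  bool moving = false;          // detector state (initially NOT_MOVING)
  int cnt_on = 0, cnt_off = 0;  // debounce run-length counters
  bool active = (mode == 0) ? true : (mode == 1 ? moving : !moving);

  for (int t = 0; t < n; ++t) {
    if (b == 0) {
      bool term;
      if (tib >= t_max - 1e-12) {
        term = true;  // hard cap: hazard is infinite at t_max
      } else {
        double h = (alpha - 1.0) / (tib + t_min)
                   * (1.0 + beta * std::max(0.0, -E));
        term = (unif_rand() < std::min(1.0, h * dt));
      }
      if (term) {
        double p_turn = 1.0 / (1.0 + std::exp(-(k_turn * (-E) + b_turn)));
        b = (unif_rand() < p_turn) ? 2 : 1;
        walk_end = exp_rand() * tau_w;
        tib = 0.0;
      }
    } else if (tib >= walk_end - 1e-12) {
      b = 0;
      tib = 0.0;
    }

    double f0 = (b != 0) ? v_walk * dt : 0.0;
    double y0 = (b == 2) ? turn_sign * omega * dt : 0.0;
    // three noise draws every sample keeps the RNG stream aligned across
    // parameterisations (and with the R reference loop)
    double fz = f0 + sigma * norm_rand();
    double yz = y0 + sigma * norm_rand();
    double lz = sigma * norm_rand();

    double w = (b == 0) ? w_pause : w_walk;
    E += dt * (-E / tau_e + w * signal_sign * (active ? 1.0 : 0.0));

    fwd[t] = fz; yaw[t] = yz; lat[t] = lz;
    Ev[t] = E; behav[t] = b; act[t] = active;

    double m = std::sqrt(fz * fz + lz * lz);
    mag[t] = m;
    if (m > threshold) { cnt_on++; cnt_off = 0; } else { cnt_off++; cnt_on = 0; }
    if (!moving && cnt_on >= debounce_on) moving = true;
    else if (moving && cnt_off >= debounce_off) moving = false;
    mov[t] = moving;

    active = (mode == 0) ? true : (mode == 1 ? moving : !moving);
    tib += dt;
  }

  return List::create(_["d_forward_cm"] = fwd,
                      _["d_yaw_rad"] = yaw,
                      _["d_lateral_cm"] = lat,
                      _["evidence"] = Ev,
                      _["behaviour"] = behav,
                      _["stimulus_active"] = act,
                      _["moving"] = mov,
                      _["magnitude"] = mag,
                      _["turn_sign"] = turn_sign);
}

// Monte-Carlo permutation null for the Mann-Whitney U statistic.
// ranks: midranks of the pooled sample; na: size of group a.
// Returns counts of permuted U <= and >= the observed U (1e-9 tolerance).
// [[Rcpp::export]]
IntegerVector mw_perm_tail_cpp(NumericVector ranks, int na, int nperm,
                               double u_obs) {
  const int n = ranks.size();
  std::vector<double> r(ranks.begin(), ranks.end());
  const double shift = na * (na + 1.0) / 2.0;
  int n_le = 0, n_ge = 0;
  for (int p = 0; p < nperm; ++p) {
    // partial Fisher-Yates: random na-subset into positions [0, na)
    for (int i = 0; i < na; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(r[i], r[j]);
    }
    double s = 0.0;
    for (int i = 0; i < na; ++i) s += r[i];
    double u = s - shift;
    if (u <= u_obs + 1e-9) n_le++;
    if (u >= u_obs - 1e-9) n_ge++;
  }
  return IntegerVector::create(n_le, n_ge);
}
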