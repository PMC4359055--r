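// Discrete-time stepper for the HSC homeostasis agent-based model.
//
// Two agent compartments (LT-HSC, ST-HSC) feed a progenitor stock in a
// closed demand loop. Progenitors mature out of the system at a first-order
// rate; the resulting fractional deficit of the progenitor pool (plus,
// optionally, an ST deficit for LT cells) is the demand signal that
// activates quiescent HSCs. An activated cell traverses division and then
// exports one differentiating daughter downstream (with transit
// amplification) while the other daughter returns to quiescence, so HSC
// pool sizes are conserved and the yearly number of divisions is set by
// downstream consumption -- 24 exported cells/day at target pools.
//
// Hypotheses differ in when a cell commits to this program:
//   HYP1   -- commitment at signal reception; one total-division duration.
//   HYP2.x -- a G0-exit stage precedes commitment; cells still exiting when
//             the demand signal returns to zero abort back to quiescence.
//             HYP2.2 adds a fixed delay to the LT-HSC G0-exit mean.
//
// All stochastic draws use R's RNG, so set.seed() in R makes a run
// deterministic.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

// Gaussian truncated below at 0.1 hr (inverse-CDF), matching the R-side
// duration model.
double rtnorm_floor(double mean, double sd) {
  const double floor_h = 0.1;
  if (sd <= 0.0) return std::max(mean, floor_h);
  double lo = R::pnorm(floor_h, mean, sd, 1, 0);
  double u = R::runif(lo, 1.0);
  if (u >= 1.0) u = 1.0 - 1e-12;
  return R::qnorm(u, mean, sd, 1, 0);
}

inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

struct EventLog {
  std::vector<double> time;
  std::vector<int> compartment; // 0 = LT, 1 = ST
  std::vector<std::string> type;
  bool enabled = false;
  void add(double t, int c, const char* what) {
    if (enabled && time.size() < 100000) {
      time.push_back(t);
      compartment.push_back(c);
      type.push_back(what);
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".abm_kernel")]]
List abm_kernel(List par) {
  const int hypothesis = as<int>(par["hypothesis"]); // 1, 21, 22
  const double dt = as<double>(par["dt"]);
  const int n_steps = as<int>(par["n_steps"]);
  const int record_every = as<int>(par["record_every"]);

  const NumericVector target = par["target"]; // LT, ST, progenitor
  const NumericVector mean_exit = par["mean_exit"]; // LT (delay folded), ST
  const NumericVector sd_exit = par["sd_exit"];
  const NumericVector mean_transit = par["mean_transit"];
  const NumericVector sd_transit = par["sd_transit"];
  const NumericVector mean_total = par["mean_total"]; // HYP1
  const NumericVector sd_total = par["sd_total"];

  const NumericVector gain = par["gain"]; // LT, ST (per hour)
  const double w_down = as<double>(par["downstream_weight"]);
  const double noise = as<double>(par["noise"]);
  const double prog_amp = as<double>(par["prog_amplification"]);
  const double prog_efflux = as<double>(par["prog_efflux"]); // /day/cell

  const double injury_time = as<double>(par["injury_time"]); // hours, <0 none
  const double injury_fraction = as<double>(par["injury_fraction"]);

  const bool has_forced = !Rf_isNull(par["forced_signal"]);
  NumericMatrix forced;
  if (has_forced) forced = as<NumericMatrix>(par["forced_signal"]);

  EventLog events;
  events.enabled = as<bool>(par["record_events"]);

  // Pending-division buckets indexed by step; capacity covers the horizon
  // plus the longest plausible duration draw.
  double mx_mean = 0.0, mx_sd = 0.0;
  for (int c = 0; c < 2; ++c) {
    mx_mean = std::max(mx_mean, std::max(mean_total[c],
                                         mean_exit[c] + mean_transit[c]));
    mx_sd = std::max(mx_sd, std::max(sd_total[c],
                                     std::max(sd_exit[c], sd_transit[c])));
  }
  const int margin = (int)std::ceil((mx_mean + 12.0 * mx_sd + 24.0) / dt) + 2;
  const int cap = n_steps + margin;

  long n_q[2] = {(long)target[0], (long)target[1]};
  long n_cycling[2] = {0, 0};
  std::vector<std::vector<int> > exiting(2); // pending commit step per cell
  std::vector<std::vector<int> > div_due(2, std::vector<int>(cap, 0));

  double n_prog = target[2];

  long cum_div[2] = {0, 0};
  long aborts[2] = {0, 0};
  long activations[2] = {0, 0};
  long exported[2] = {0, 0};
  long prog_out_total = 0, injury_removed = 0;

  const int injury_step =
      injury_time < 0 ? -1 : (int)std::floor(injury_time / dt);

  const double prog_haz = prog_efflux / 24.0 * dt;

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix series(n_rec, 6);
  int rec_row = 0;
  series(0, 0) = 0.0;
  series(0, 1) = n_q[0];
  series(0, 2) = n_q[1];
  series(0, 3) = n_prog;
  series(0, 4) = 0;
  series(0, 5) = 0;
  ++rec_row;

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;

    if (s == injury_step) {
      long removed = (long)std::round(injury_fraction * n_prog);
      if (removed > n_prog) removed = (long)n_prog;
      n_prog -= removed;
      injury_removed = removed;
    }

    const double pool_lt = n_q[0] + (double)exiting[0].size() + n_cycling[0];
    const double pool_st = n_q[1] + (double)exiting[1].size() + n_cycling[1];
    const double d_lt = std::max(0.0, (target[0] - pool_lt) / target[0]);
    const double d_st = std::max(0.0, (target[1] - pool_st) / target[1]);
    const double d_p = std::max(0.0, (target[2] - n_prog) / target[2]);

    // Demand per compartment: own deficit plus (weighted) deficits of the
    // downstream compartments. With conservative divisions the own terms
    // vanish and the progenitor deficit is the pacemaker.
    double demand[2];
    demand[0] = d_lt + w_down * (d_st + d_p);
    demand[1] = d_st + w_down * d_p;

    double p_act[2];
    bool signal_zero[2];
    for (int c = 0; c < 2; ++c) {
      if (has_forced) {
        p_act[c] = clamp01(forced(s, c));
        signal_zero[c] = forced(s, c) <= 0.0;
      } else {
        const double eps = R::runif(-noise, noise);
        p_act[c] = clamp01(gain[c] * demand[c] * (1.0 + eps) * dt);
        signal_zero[c] = demand[c] <= 0.0;
      }
    }

    for (int c = 0; c < 2; ++c) {
      // Cells still traversing G0 exit have not committed: when the demand
      // signal has returned to zero they return to quiescence.
      if (hypothesis != 1 && signal_zero[c] && !exiting[c].empty()) {
        aborts[c] += (long)exiting[c].size();
        n_q[c] += (long)exiting[c].size();
        for (size_t i = 0; i < exiting[c].size(); ++i) {
          events.add(t, c, "abort");
        }
        exiting[c].clear();
      }

      // G0 exits completing this step: commit, draw a cycle-transit time.
      if (!exiting[c].empty()) {
        size_t keep = 0;
        for (size_t i = 0; i < exiting[c].size(); ++i) {
          if (exiting[c][i] == s) {
            double transit = rtnorm_floor(mean_transit[c], sd_transit[c]);
            int due = s + std::max(1, (int)std::lround(transit / dt));
            if (due >= cap) due = cap - 1;
            ++div_due[c][due];
            ++n_cycling[c];
            events.add(t, c, "commit");
          } else {
            exiting[c][keep++] = exiting[c][i];
          }
        }
        exiting[c].resize(keep);
      }

      // Divisions completing this step: one daughter returns to quiescence,
      // the other differentiates and joins the progenitor pool with
      // transit amplification.
      const int k = div_due[c][s];
      if (k > 0) {
        div_due[c][s] = 0;
        n_cycling[c] -= k;
        n_q[c] += k;
        cum_div[c] += k;
        exported[c] += k;
        n_prog += prog_amp * k;
        for (int i = 0; i < k; ++i) events.add(t, c, "division");
      }

      // Activation of quiescent cells by the demand signal.
      if (p_act[c] > 0.0 && n_q[c] > 0) {
        const long n_act = (long)R::rbinom((double)n_q[c], p_act[c]);
        if (n_act > 0) {
          n_q[c] -= n_act;
          activations[c] += n_act;
          for (long i = 0; i < n_act; ++i) {
            events.add(t, c, "activation");
            if (hypothesis == 1) {
              double total = rtnorm_floor(mean_total[c], sd_total[c]);
              int due = s + std::max(1, (int)std::lround(total / dt));
              if (due >= cap) due = cap - 1;
              ++div_due[c][due];
              ++n_cycling[c];
            } else {
              double g0 = rtnorm_floor(mean_exit[c], sd_exit[c]);
              int commit = s + std::max(1, (int)std::lround(g0 / dt));
              if (commit >= cap) commit = cap - 1;
              exiting[c].push_back(commit);
            }
          }
        }
      }
    }

    // Progenitor maturation out of the modelled system.
    if (prog_haz > 0.0 && n_prog > 0) {
      const long out = (long)R::rbinom(std::floor(n_prog), clamp01(prog_haz));
      n_prog -= out;
      prog_out_total += out;
    }

    if ((s + 1) % record_every == 0) {
      series(rec_row, 0) = (s + 1) * dt;
      series(rec_row, 1) = n_q[0] + (double)exiting[0].size() + n_cycling[0];
      series(rec_row, 2) = n_q[1] + (double)exiting[1].size() + n_cycling[1];
      series(rec_row, 3) = n_prog;
      series(rec_row, 4) = cum_div[0];
      series(rec_row, 5) = cum_div[1];
      ++rec_row;
    }
  }

  List counters = List::create(
      _["divisions"] = NumericVector::create(cum_div[0], cum_div[1]),
      _["activations"] = NumericVector::create(activations[0], activations[1]),
      _["aborts"] = NumericVector::create(aborts[0], aborts[1]),
      _["exported"] = NumericVector::create(exported[0], exported[1]),
      _["prog_influx"] = (double)(prog_amp * (cum_div[0] + cum_div[1])),
      _["prog_efflux"] = (double)prog_out_total,
      _["injury_removed"] = (double)injury_removed);

  List out = List::create(
      _["series"] = series(Range(0, rec_row - 1), _),
      _["counters"] = counters,
      _["final"] = List::create(
          _["n_quiescent"] = NumericVector::create(n_q[0], n_q[1]),
          _["n_exiting"] = NumericVector::create((double)exiting[0].size(),
                                                 (double)exiting[1].size()),
          _["n_cycling"] = NumericVector::create(n_cycling[0], n_cycling[1]),
          _["n_progenitor"] = n_prog));
  if (events.enabled) {
    out["events"] = DataFrame::create(
        _["time"] = events.time,
        _["compartment"] = events.compartment,
        _["type"] = events.type,
        _["stringsAsFactors"] = false);
  }
  return out;
}
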