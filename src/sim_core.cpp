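// Hourly individual-based simulation core: one lactating female (plus pup)
// foraging from a central island over a static prey landscape.
//
// The loop mirrors the R-level primitive functions (p_fishing, compute_th_t,
// p_return, p_death, fishing_gain, ...); the scalar formulas are factored
// into small functions that are also exported so the R and compiled routes
// can be cross-checked in the tests.

#include <Rcpp.h>
using namespace Rcpp;

static inline double clamp01(double x) {
  return x < 0 ? 0 : (x > 1 ? 1 : x);
}

static inline double logistic2(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// [[Rcpp::export(name = "cpp_p_fishing")]]
double cpp_p_fishing(double abundance, double th_t, bool is_night,
                     bool at_satiety, double min_fish_abund) {
  if (!is_night || at_satiety || abundance < min_fish_abund) return 0.0;
  return logistic2(2.0 * (abundance - th_t));
}

// [[Rcpp::export(name = "cpp_th_t")]]
double cpp_th_t(double avg_env, double e_ratio, double thr_ceiling,
                double min_fish_abund, double th_exponent = 0.25) {
  double frac = clamp01((e_ratio - 1.0) / (thr_ceiling - 1.0));
  frac = std::pow(frac, th_exponent);
  double th = min_fish_abund + frac * (avg_env - min_fish_abund);
  return th < min_fish_abund ? min_fish_abund : th;
}

// [[Rcpp::export(name = "cpp_p_return")]]
double cpp_p_return(double e_frac, double ewb_frac, double ts_frac,
                    double k, double gamma) {
  double margin = e_frac - ewb_frac;
  if (margin < 0) margin = 0;
  double ts = ts_frac > 1 ? 1 : ts_frac;
  double p = std::exp(-k * margin) + std::pow(ts, gamma);
  return p > 1 ? 1 : p;
}

// [[Rcpp::export(name = "cpp_p_death")]]
double cpp_p_death(double current, double reference, double lethal_pct,
                   double sd_pct) {
  double pct = 100.0 * current / reference;
  return R::pnorm((lethal_pct - pct) / sd_pct, 0.0, 1.0, 1, 0);
}

static inline double wrap_angle(double a) {
  a = (a + M_PI) / (2.0 * M_PI);
  a -= std::floor(a);
  return a * 2.0 * M_PI - M_PI;
}

static inline double dist2d(double dx, double dy) {
  return std::sqrt(dx * dx + dy * dy);
}

struct Pars {
  int n;                       // grid side
  double cell_km, step_km;
  double met_mj_kg, ashore_met_frac;
  double econtent_seal, econtent_pup;
  double drag_km;              // MJ per km for this female
  double e_init, e_min;
  double emax_factor, satiation_frac;
  double mj_per_unit, min_fish_abund, thr_ceiling, th_exponent;
  int night_start, night_len, departure_hour;
  double mta_h, prenatal_ashore_h, t_max_trip_h;
  double return_k, return_gamma, crw_turn_sd, outbound_turn_sd;
  double emergency_frac, satiety_return_frac, mem_dist_discount;
  double prospect_th_factor;
  double grad_weight, g_half, milk_rate;
  double pup_e0, pup_max_e, perinatal_gain_e, pup_loss;
  double lethal_f, lethal_p, mort_sd;
  int prenatal_h, t_rearing_h;
  int mem;
  double island_x, island_y;
};

static Pars read_pars(const List& pl) {
  Pars p;
  p.n = as<int>(pl["grid_n"]);
  p.cell_km = pl["cell_km"]; p.step_km = pl["step_km"];
  p.met_mj_kg = pl["met_mj_kg"]; p.ashore_met_frac = pl["ashore_met_frac"];
  p.econtent_seal = pl["econtent_seal"]; p.econtent_pup = pl["econtent_pup"];
  p.drag_km = pl["drag_km"];
  p.e_init = pl["e_init"]; p.e_min = pl["e_min"];
  p.emax_factor = pl["emax_factor"]; p.satiation_frac = pl["satiation_frac"];
  p.mj_per_unit = pl["mj_per_unit"]; p.min_fish_abund = pl["min_fish_abund"];
  p.thr_ceiling = pl["thr_ceiling"];
  p.th_exponent = pl["th_exponent"];
  p.night_start = as<int>(pl["night_start"]);
  p.night_len = as<int>(pl["night_len"]);
  p.departure_hour = as<int>(pl["departure_hour"]);
  p.mta_h = pl["mta_h"]; p.prenatal_ashore_h = pl["prenatal_ashore_h"];
  p.t_max_trip_h = pl["t_max_trip_h"];
  p.return_k = pl["return_k"]; p.return_gamma = pl["return_gamma"];
  p.emergency_frac = pl["emergency_frac"];
  p.satiety_return_frac = pl["satiety_return_frac"];
  p.mem_dist_discount = pl["mem_dist_discount"];
  p.prospect_th_factor = pl["prospect_th_factor"];
  p.crw_turn_sd = pl["crw_turn_sd"];
  p.outbound_turn_sd = pl["outbound_turn_sd"];
  p.grad_weight = pl["grad_weight"];
  p.g_half = pl["g_half"]; p.milk_rate = pl["milk_rate"];
  p.pup_e0 = pl["pup_e0"]; p.pup_max_e = pl["pup_max_e"];
  p.perinatal_gain_e = pl["perinatal_gain_e"]; p.pup_loss = pl["pup_loss"];
  p.lethal_f = pl["lethal_pct_female"]; p.lethal_p = pl["lethal_pct_pup"];
  p.mort_sd = pl["mort_sd_pct"];
  p.prenatal_h = as<int>(pl["prenatal_h"]);
  p.t_rearing_h = as<int>(pl["t_rearing_h"]);
  p.mem = as<int>(pl["mem"]);
  p.island_x = pl["island_x"]; p.island_y = pl["island_y"];
  return p;
}

// simulation state
struct Sim {
  // female
  double x, y, e_seal, e_max, e_dawn, heading;
  double ref_f, e_min_cur;  // mortality reference: energy at last departure
  bool alive_f, at_sea, homing, transit, outbound;
  double ts, t_ashore;
  // memory
  double best_x, best_y, best_ab, best_val, fidelity;
  double lastfish_x, lastfish_y, lastfish_ab; double h_since_fish;
  double naive_heading;
  int prev_r, prev_c; double prev_ab; bool have_grad; double grad_bearing;
  double target_x, target_y; bool have_target;
  // pup
  double e_pup, ref_pup; bool alive_p, pup_born;
  // trip accounting
  bool in_trip; double trip_start, trip_dist, trip_ewon, trip_e0;
  int trip_nfish, trip_mode;
  double best_gain_rate;
  // totals over the rearing phase
  double spent, dist_total; int nfish_total;
};

// [[Rcpp::export]]
List sim_run_cpp(NumericMatrix map, double avg_env, List pars_list,
                 bool trace = false) {
  Pars P = read_pars(pars_list);
  Sim s;
  s.x = P.island_x; s.y = P.island_y;
  s.e_seal = P.e_init; s.e_max = P.emax_factor * P.e_init; s.e_dawn = P.e_init;
  s.ref_f = P.e_init; s.e_min_cur = P.e_min;
  s.heading = 0; s.alive_f = true; s.at_sea = false; s.homing = false;
  s.transit = false; s.outbound = false; s.ts = 0; s.t_ashore = P.mta_h;
  s.best_x = 0; s.best_y = 0; s.best_ab = -1; s.best_val = -1e300;
  s.fidelity = 0;
  s.lastfish_x = 0; s.lastfish_y = 0; s.lastfish_ab = -1; s.h_since_fish = 0;
  s.naive_heading = R::runif(-M_PI, M_PI);
  s.prev_r = -1; s.prev_c = -1; s.prev_ab = 0;
  s.have_grad = false; s.grad_bearing = 0;
  s.target_x = 0; s.target_y = 0; s.have_target = false;
  s.e_pup = 0; s.ref_pup = 1; s.alive_p = false; s.pup_born = false;
  s.best_gain_rate = 0;
  s.in_trip = false; s.trip_start = 0; s.trip_dist = 0; s.trip_ewon = 0;
  s.trip_mode = 0;
  s.trip_nfish = 0;
  s.spent = 0; s.dist_total = 0; s.nfish_total = 0;

  const double domain = P.n * P.cell_km;
  int phase = 0;                 // 0 prenatal, 1 perinatal, 2 rearing
  int per_h = 0, per_count = 0;
  int t_rear = 0;
  long t_global = 0;
  const long t_guard = P.prenatal_h + 24L * 10 + 7 * 24 + P.t_rearing_h + 400;

  // trip log
  std::vector<double> tr_phase, tr_start, tr_end, tr_dist, tr_nfish, tr_ewon,
      tr_e0, tr_e1, tr_mode;
  // optional hourly trace
  std::vector<double> h_t, h_phase, h_x, h_y, h_es, h_ep, h_event,
      h_gain, h_met, h_drag, h_transfer;

  int death_hour_f = -1, death_hour_p = -1;

  while (phase < 3 && t_global < t_guard) {
    int hod = (int)(t_global % 24);
    bool night = (hod >= P.night_start) ||
                 (hod < (P.night_start + P.night_len) % 24);
    double ev = 0, gain = 0, met = 0, drag = 0, transfer = 0;

    if (phase == 1) {
      // perinatal shore fast: resting metabolism, linear transfer of the
      // perinatal mass gain to the pup, no pup fasting loss
      double w = s.e_seal / P.econtent_seal;
      met = P.ashore_met_frac * P.met_mj_kg * w;
      transfer = P.perinatal_gain_e / per_h;
      s.e_seal -= met + transfer;
      if (s.e_seal < 0) s.e_seal = 0;
      s.e_pup += transfer;
      per_count++;
      ev = 10;
      if (per_count >= per_h) {
        phase = 2;
        s.ref_pup = s.e_pup;
        s.t_ashore = P.mta_h;   // eligible to depart at the scheduled hour
        // the initial mass regression describes females weighed just before
        // their first provisioning departure: the rearing season starts here
        s.e_seal = P.e_init; s.e_dawn = P.e_init;
        double g = s.best_gain_rate;
        s.fidelity = g / (g + P.g_half);
      }
    } else if (s.alive_f && !s.at_sea) {
      // ---- ashore hour (prenatal or rearing) ----
      double w = s.e_seal / P.econtent_seal;
      met = P.ashore_met_frac * P.met_mj_kg * w;
      s.e_seal -= met;
      if (s.e_seal < 0) s.e_seal = 0;
      if (phase == 2 && s.alive_p) {
        double surplus = s.e_seal - s.e_min_cur;
        if (surplus > 0) {
          transfer = P.milk_rate * surplus;
          double room = P.pup_max_e - s.e_pup;
          if (transfer > room) transfer = room > 0 ? room : 0;
          if (transfer > s.e_seal) transfer = s.e_seal;
          s.e_seal -= transfer;
          s.e_pup += transfer;
        }
      }
      s.t_ashore += 1;
      ev = 0;
      // departure decision (shorter rests during prenatal prospection);
      // a female whose reserves run low while fasting ashore cuts her
      // visit short and goes back to sea to feed herself
      double stay_h = (phase == 0) ? P.prenatal_ashore_h : P.mta_h;
      bool emergency = s.e_seal < P.emergency_frac * s.ref_f &&
                       s.t_ashore >= P.prenatal_ashore_h;
      if (s.t_ashore >= stay_h || emergency) {
        int dep = P.departure_hour;
        bool usable = (P.mem == 1 && s.best_ab > 0);
        double tdist = 0;
        if (usable) {
          tdist = dist2d(s.best_x - s.x, s.best_y - s.y);
          int travel = (int)std::ceil(tdist / P.step_km);
          // feasible departure hour closest to the default, arriving at night
          int besth = -1; int bestd = 99;
          for (int h = 0; h < 24; h++) {
            int arr = (h + travel) % 24;
            bool okn = (arr >= P.night_start) ||
                       (arr < (P.night_start + P.night_len) % 24);
            if (!okn) continue;
            int dd = std::abs(h - P.departure_hour);
            if (24 - dd < dd) dd = 24 - dd;
            if (dd < bestd) { bestd = dd; besth = h; }
          }
          if (besth >= 0) dep = besth;
        }
        if (hod == dep) {
          // leave: seal the suckling bout, set mode and heading
          if (phase == 2 && s.alive_p && s.e_pup > s.ref_pup)
            s.ref_pup = s.e_pup;
          s.at_sea = true; s.homing = false;
          s.ts = 0; s.in_trip = true;
          s.trip_start = (phase == 2) ? (double)t_rear : (double)t_global;
          s.trip_dist = 0; s.trip_ewon = 0; s.trip_nfish = 0;
          s.trip_e0 = s.e_seal;
          s.prev_r = -1; s.prev_c = -1; s.have_grad = false;
          s.lastfish_ab = -1; s.h_since_fish = 0;
          bool go_transit = usable && (R::runif(0, 1) < s.fidelity);
          s.trip_mode = go_transit ? 1 : 0;
          if (go_transit) {
            s.transit = true; s.outbound = false; s.have_target = true;
            s.target_x = s.best_x; s.target_y = s.best_y;
            s.heading = std::atan2(s.target_y - s.y, s.target_x - s.x);
          } else {
            // commute along a systematically rotated heading until the
            // prey field is reached (naive departure): successive
            // prospecting trips cover new sectors
            s.transit = false; s.outbound = true; s.have_target = false;
            s.heading = s.naive_heading;
            s.naive_heading = wrap_angle(s.naive_heading + 2.399963);
          }
          ev = 5;
        }
      }
    } else if (s.alive_f && s.at_sea) {
      // ---- at-sea hour ----
      double w = s.e_seal / P.econtent_seal;
      met = P.met_mj_kg * w;
      s.e_seal -= met;
      if (s.e_seal < 0) s.e_seal = 0;
      s.ts += 1;
      int r = (int)(s.y / P.cell_km); if (r < 0) r = 0; if (r >= P.n) r = P.n - 1;
      int c = (int)(s.x / P.cell_km); if (c < 0) c = 0; if (c >= P.n) c = P.n - 1;
      double ab = map(r, c);
      if (night) {
        // the female can only estimate abundance at night
        if (s.outbound && ab >= P.min_fish_abund) s.outbound = false;
      } else if (s.outbound && s.ts >= (double)P.night_len + 2.0) {
        // dawn after a full night of empty water: stop commuting and search
        // the band reached
        s.outbound = false;
      }
      if (!night && hod == (P.night_start + P.night_len) % 24 && phase == 2 &&
          !s.homing && !s.transit && s.trip_nfish == 0 && s.lastfish_ab < 0 &&
          !(P.mem == 1 && s.best_ab >= 2.0 * P.min_fish_abund)) {
        // a provisioning female whose night yielded nothing and who knows
        // of no feeding area cuts her losses and returns to try a new sector
        s.homing = true; s.outbound = false;
      }
      if (night) {
        if (P.mem == 1) {
          // the reference cell maximises richness net of the travel cost of
          // reaching it from the colony: among equally rich cells the
          // closest is remembered
          double d_isl0 = dist2d(s.x - P.island_x, s.y - P.island_y);
          double val = ab - P.mem_dist_discount * d_isl0;
          if (ab >= P.min_fish_abund && val > s.best_val) {
            s.best_val = val;
            s.best_ab = ab;
            s.best_x = (c + 0.5) * P.cell_km;
            s.best_y = (r + 0.5) * P.cell_km;
          }
        }
        if (r != s.prev_r || c != s.prev_c) {
          if (s.prev_r >= 0 && ab != s.prev_ab) {
            // bearing towards the richer of the last two visited cells
            // (x runs along columns, y along rows)
            double to_cur = std::atan2((r - s.prev_r) * P.cell_km,
                                       (c - s.prev_c) * P.cell_km);
            s.grad_bearing = (ab > s.prev_ab) ? to_cur : wrap_angle(to_cur + M_PI);
            s.have_grad = true;
          } else {
            s.have_grad = false;
          }
          s.prev_r = r; s.prev_c = c; s.prev_ab = ab;
        }
        // a female on clearly poorer ground heads back to the best feeding
        // area she knows instead of searching blindly: her long-term
        // reference cell (Mem1) or the best cell fished on this trip
        if (!s.homing && !s.transit && !s.outbound) {
          // candidate known cells are valued net of the travel to reach
          // them from the current position
          double tx = 0, ty = 0; bool go = false; double bestv = ab + 2.0 * P.min_fish_abund;
          if (P.mem == 1 && s.best_ab >= 2.0 * P.min_fish_abund) {
            double v = s.best_ab -
              P.mem_dist_discount * dist2d(s.best_x - s.x, s.best_y - s.y);
            if (v > bestv) { bestv = v; tx = s.best_x; ty = s.best_y; go = true; }
          }
          if (s.lastfish_ab > 0) {
            double v = s.lastfish_ab -
              P.mem_dist_discount * dist2d(s.lastfish_x - s.x, s.lastfish_y - s.y);
            if (v > bestv) { bestv = v; tx = s.lastfish_x; ty = s.lastfish_y; go = true; }
          }
          if (go && dist2d(tx - s.x, ty - s.y) > P.cell_km) {
            s.transit = true; s.have_target = true;
            s.target_x = tx; s.target_y = ty;
          }
        }
      }
      // forced homing at the end of the prenatal period
      if (phase == 0 && t_global >= P.prenatal_h) s.homing = true;

      // arrival at the memorised target ends the commute
      if (s.transit) {
        double dt0 = dist2d(s.target_x - s.x, s.target_y - s.y);
        if (dt0 <= P.cell_km) s.transit = false;
      }
      // trip-length ceiling: overrides every other mode
      if (!s.homing && s.ts >= P.t_max_trip_h) {
        s.homing = true; s.transit = false; s.outbound = false;
      }
      // foraging-or-returning: a night decision taken while foraging (not
      // during the committed commute), ahead of the fish-or-move decision
      if (!s.homing && night && !s.outbound && !s.transit) {
        double d_isl = dist2d(s.x - P.island_x, s.y - P.island_y);
        double methere = P.met_mj_kg * (s.e_seal / P.econtent_seal);
        double ewb = s.e_min_cur + (d_isl / P.step_km) * methere +
                     d_isl * P.drag_km;
        if (phase == 2 && s.alive_p)
          ewb += 2.0 * 24.0 * P.ashore_met_frac * methere;
        double pr = cpp_p_return(s.e_seal / s.e_max, ewb / s.e_max,
                                 s.ts / P.t_max_trip_h,
                                 P.return_k, P.return_gamma);
        if (R::runif(0, 1) < pr) s.homing = true;
      }
      bool fished = false;
      {
        // fishing is possible on any night hour over a profitable cell,
        // including opportunistically on the way home
        if (night && ab >= P.min_fish_abund && s.e_seal < s.e_max - 1e-12) {
          double th = cpp_th_t(avg_env, s.e_seal / s.e_min_cur, P.thr_ceiling,
                               P.min_fish_abund, P.th_exponent);
          // prospecting females are after the rich cores worth memorising
          if (phase == 0) th = P.prospect_th_factor * avg_env;
          double pf = logistic2(2.0 * (ab - th));
          if (R::runif(0, 1) < pf) {
            gain = ab * P.mj_per_unit;
            double cap = P.satiation_frac * s.e_dawn;
            if (gain > cap) gain = cap;
            if (gain > s.e_max - s.e_seal) gain = s.e_max - s.e_seal;
            if (gain < 0) gain = 0;
            s.e_seal += gain;
            s.trip_ewon += gain; s.trip_nfish++;
            s.h_since_fish = 0;
            if (ab > s.lastfish_ab) {
              s.lastfish_ab = ab;
              s.lastfish_x = (c + 0.5) * P.cell_km;
              s.lastfish_y = (r + 0.5) * P.cell_km;
            }
            if (phase == 2) s.nfish_total++;
            fished = true; ev = 2;
          }
        }
        if (!fished) s.h_since_fish += 1;
        if (!fished && !s.homing && !night &&
            hod == (P.night_start + P.night_len) % 24 &&
            s.e_seal >= P.satiety_return_frac * s.e_max) {
          // a female near her storage ceiling at dawn gains nothing by
          // staying at sea: she heads home to provision the pup
          s.homing = true; s.transit = false; s.outbound = false;
        }
      }
      if (!fished && !s.homing) {
        // movement hour
        if (s.transit) {
          double dt = dist2d(s.target_x - s.x, s.target_y - s.y);
          if (dt <= P.step_km) {
            s.transit = false;  // reached the memorised cell, start searching
            s.heading = wrap_angle(s.heading + R::rnorm(0, P.crw_turn_sd));
          } else {
            s.heading = std::atan2(s.target_y - s.y, s.target_x - s.x);
          }
        } else if (s.outbound) {
          s.heading = wrap_angle(s.heading + R::rnorm(0, P.outbound_turn_sd));
        } else {
          s.heading = wrap_angle(s.heading + R::rnorm(0, P.crw_turn_sd));
          if (night && s.have_grad) {
            double wg = P.grad_weight;
            s.heading = std::atan2(
                (1 - wg) * std::sin(s.heading) + wg * std::sin(s.grad_bearing),
                (1 - wg) * std::cos(s.heading) + wg * std::cos(s.grad_bearing));
          }
        }
        double nx = s.x + P.step_km * std::cos(s.heading);
        double ny = s.y + P.step_km * std::sin(s.heading);
        // reflecting boundaries
        if (nx < 0) { nx = -nx; s.heading = wrap_angle(M_PI - s.heading); }
        if (nx > domain) { nx = 2 * domain - nx; s.heading = wrap_angle(M_PI - s.heading); }
        if (ny < 0) { ny = -ny; s.heading = -s.heading; }
        if (ny > domain) { ny = 2 * domain - ny; s.heading = -s.heading; }
        s.x = nx; s.y = ny;
        drag = P.drag_km * P.step_km;
        s.e_seal -= drag;
        if (s.e_seal < 0) s.e_seal = 0;
        s.trip_dist += P.step_km;
        if (phase == 2) s.dist_total += P.step_km;
        ev = 1;
      } else if (s.homing && !fished) {
        // move straight home; land when within one step
        double d_isl = dist2d(s.x - P.island_x, s.y - P.island_y);
        double stepd = d_isl <= P.step_km ? d_isl : P.step_km;
        if (stepd > 0) {
          s.heading = std::atan2(P.island_y - s.y, P.island_x - s.x);
          s.x += stepd * std::cos(s.heading);
          s.y += stepd * std::sin(s.heading);
          drag = P.drag_km * stepd;
          s.e_seal -= drag;
          if (s.e_seal < 0) s.e_seal = 0;
          s.trip_dist += stepd;
          if (phase == 2) s.dist_total += stepd;
        }
        ev = 3;
        if (d_isl <= P.step_km) {
          // landing: close the trip, update trip fidelity
          s.at_sea = false; s.homing = false; s.t_ashore = 0;
          double dur = s.ts > 0 ? s.ts : 1;
          double g = s.trip_ewon / dur;
          if (g > s.best_gain_rate) s.best_gain_rate = g;
          // fidelity saturates in the best gain rate achieved so far: one
          // failed trip does not erase trust in a proven feeding area
          s.fidelity = s.best_gain_rate / (s.best_gain_rate + P.g_half);
          tr_phase.push_back(phase);
          tr_start.push_back(s.trip_start);
          tr_end.push_back(phase == 2 ? (double)t_rear : (double)t_global);
          tr_dist.push_back(s.trip_dist);
          tr_nfish.push_back(s.trip_nfish);
          tr_ewon.push_back(s.trip_ewon);
          tr_e0.push_back(s.trip_e0);
          tr_e1.push_back(s.e_seal);
          tr_mode.push_back(s.trip_mode);
          s.in_trip = false;
          ev = 4;
          // prenatal landing after the forced return: give birth
          if (phase == 0 && t_global >= P.prenatal_h) {
            phase = 1;
            per_h = 24 * (5 + (int)std::floor(R::runif(0, 3)));
            if (per_h > 24 * 7) per_h = 24 * 7;
            per_count = 0;
            s.e_pup = P.pup_e0; s.ref_pup = P.pup_e0;
            s.alive_p = true; s.pup_born = true;
          }
        }
      }
    }

    // prenatal-to-perinatal transition when already ashore
    if (phase == 0 && !s.at_sea && t_global >= P.prenatal_h && s.alive_f) {
      phase = 1;
      per_h = 24 * (5 + (int)std::floor(R::runif(0, 3)));
      if (per_h > 24 * 7) per_h = 24 * 7;
      per_count = 0;
      s.e_pup = P.pup_e0; s.ref_pup = P.pup_e0;
      s.alive_p = true; s.pup_born = true;
    }

    // pup fasting during the rearing phase
    if (phase == 2 && s.alive_p) {
      bool nursed = s.alive_f && !s.at_sea;
      if (!nursed) s.e_pup *= (1.0 - P.pup_loss);
    }

    // mortality draws (hourly). The prospection pass and the fixed
    // perinatal fast are initialisation: the female's survival is accounted
    // over the rearing period, starting from her measured initial mass.
    if (s.alive_f && phase >= 2) {
      double pd = cpp_p_death(s.e_seal, s.ref_f, P.lethal_f, P.mort_sd);
      if (pd > 0 && R::runif(0, 1) < pd) {
        s.alive_f = false;
        death_hour_f = (int)t_global;
        if (phase == 0) phase = 3;  // died before birth: nothing to rear
        if (phase == 1) phase = 2;  // pup alone ashore from now on
      }
    }
    if (s.alive_p && phase >= 1) {
      double pd = cpp_p_death(s.e_pup, s.ref_pup, P.lethal_p, P.mort_sd);
      if (pd > 0 && R::runif(0, 1) < pd) {
        s.alive_p = false;
        death_hour_p = (int)t_global;
      }
    }

    // energy spent during the rearing phase (cost side of the ledger)
    if (phase == 2) s.spent += met + drag + transfer;

    if (trace) {
      h_t.push_back((double)t_global); h_phase.push_back(phase);
      h_x.push_back(s.x); h_y.push_back(s.y);
      h_es.push_back(s.e_seal); h_ep.push_back(s.pup_born ? s.e_pup : NA_REAL);
      h_event.push_back(ev); h_gain.push_back(gain); h_met.push_back(met);
      h_drag.push_back(drag); h_transfer.push_back(transfer);
    }

    // the prospection pass is behavioural initialisation: the female
    // explores and memorises at her initial condition, and the energy
    // clock starts at birth
    if (phase == 0) { s.e_seal = P.e_init; s.e_dawn = P.e_init; }

    // clock advance and dawn bookkeeping
    t_global++;
    hod = (int)(t_global % 24);
    if (hod == (P.night_start + P.night_len) % 24) {
      // dawn: reset the satiation reference (the storage ceiling e_max is a
      // fixed physiological property, 1.07 x the initial mass-energy)
      s.e_dawn = s.e_seal;
    }
    if (phase == 2) {
      t_rear++;
      if (t_rear >= P.t_rearing_h) phase = 3;
      else if (!s.alive_f && !s.alive_p) phase = 3;
    }
  }

  int nt = tr_phase.size();
  NumericMatrix trips(nt, 9);
  for (int i = 0; i < nt; i++) {
    trips(i, 0) = tr_phase[i]; trips(i, 1) = tr_start[i];
    trips(i, 2) = tr_end[i]; trips(i, 3) = tr_dist[i];
    trips(i, 4) = tr_nfish[i]; trips(i, 5) = tr_ewon[i];
    trips(i, 6) = tr_e0[i]; trips(i, 7) = tr_e1[i];
    trips(i, 8) = tr_mode[i];
  }
  colnames(trips) = CharacterVector::create("phase", "t_start", "t_end",
                                            "distance", "n_fishing", "e_won",
                                            "e_start", "e_end", "mode");
  List out = List::create(
      _["female_survived"] = s.alive_f,
      _["pup_survived"] = s.alive_p && s.pup_born,
      _["pup_born"] = s.pup_born,
      _["final_mass_female"] = s.e_seal / P.econtent_seal,
      _["final_mass_pup"] = s.pup_born ? s.e_pup / P.econtent_pup : NA_REAL,
      _["total_energy_spent"] = s.spent,
      _["total_distance"] = s.dist_total,
      _["n_fishing_total"] = s.nfish_total,
      _["hours_simulated"] = (double)t_global,
      _["rearing_hours"] = (double)t_rear,
      _["death_hour_female"] = death_hour_f,
      _["death_hour_pup"] = death_hour_p,
      _["memory"] = List::create(
          _["best_x"] = s.best_x, _["best_y"] = s.best_y,
          _["best_abundance"] = s.best_ab,
          _["last_trip_gain_rate"] = s.best_gain_rate,
          _["fidelity"] = s.fidelity),
      _["trips"] = trips);
  if (trace) {
    int nh = h_t.size();
    NumericMatrix tm(nh, 11);
    for (int i = 0; i < nh; i++) {
      tm(i, 0) = h_t[i]; tm(i, 1) = h_phase[i]; tm(i, 2) = h_x[i];
      tm(i, 3) = h_y[i]; tm(i, 4) = h_es[i]; tm(i, 5) = h_ep[i];
      tm(i, 6) = h_event[i]; tm(i, 7) = h_gain[i]; tm(i, 8) = h_met[i];
      tm(i, 9) = h_drag[i]; tm(i, 10) = h_transfer[i];
    }
    colnames(tm) = CharacterVector::create("t", "phase", "x", "y", "e_seal",
                                           "e_pup", "event", "gain", "met",
                                           "drag", "transfer");
    out["trace"] = tm;
  }
  return out;
}
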