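#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Three-trophic-level individual-based automata model on a toroidal square.
// Resources are grazed by primary consumers (PC) within radius_pc; PCs are
// taken by secondary consumers (SC) within radius_sc. PC survival and
// reproduction respond to consumption within one timestep; SC survival and
// reproduction respond to consumption summed over a rolling window, so the
// two consumer levels couple to their prey on very different timescales.
//
// All randomness goes through R's RNG (movement, consumer processing order,
// resource influx), so runs are reproducible from set.seed() and the
// spatial-index and exhaustive-search paths consume identical RNG streams.

namespace {

struct Torus {
  double L;
  double wrap(double x) const {
    x -= L * std::floor(x / L);
    if (x >= L) x = 0.0;  // guard against rounding at the boundary
    return x;
  }
  double d2(double x1, double y1, double x2, double y2) const {
    double dx = std::fabs(x1 - x2);
    if (dx > L / 2) dx = L - dx;
    double dy = std::fabs(y1 - y2);
    if (dy > L / 2) dy = L - dy;
    return dx * dx + dy * dy;
  }
};

// uniform-cell spatial index; cell width >= query radius so a 3x3
// neighborhood always covers the query disc
struct CellGrid {
  int nc;
  double width;
  const Torus &tor;
  std::vector<std::vector<int> > cells;
  CellGrid(const Torus &t, double radius, const std::vector<double> &x,
           const std::vector<double> &y)
      : tor(t) {
    nc = (int)std::floor(t.L / radius);
    if (nc < 1) nc = 1;
    if (nc > 3) {
      // nothing; 3x3 neighborhood valid whenever nc >= 3
    } else {
      nc = 1;  // degenerate: single cell = exhaustive within-cell scan
    }
    width = t.L / nc;
    cells.assign(nc * nc, std::vector<int>());
    for (size_t i = 0; i < x.size(); ++i) cells[cell_of(x[i], y[i])].push_back((int)i);
  }
  int cell_of(double x, double y) const {
    int cx = (int)(x / width), cy = (int)(y / width);
    if (cx >= nc) cx = nc - 1;
    if (cy >= nc) cy = nc - 1;
    return cy * nc + cx;
  }
  // visit candidate prey indices near (x, y)
  template <class F>
  void visit(double x, double y, F f) const {
    int cx = (int)(x / width), cy = (int)(y / width);
    if (cx >= nc) cx = nc - 1;
    if (cy >= nc) cy = nc - 1;
    if (nc == 1) {
      for (int i : cells[0]) f(i);
      return;
    }
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ax = (cx + dx + nc) % nc, ay = (cy + dy + nc) % nc;
        for (int i : cells[ay * nc + ax]) f(i);
      }
  }
};

int runif_int(int n) {  // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// uniform point in a disc of radius r around (x0, y0)
void disc_point(double x0, double y0, double r, const Torus &tor, double &x,
                double &y) {
  double rr = r * std::sqrt(unif_rand());
  double a = unif_rand() * 2.0 * M_PI;
  x = tor.wrap(x0 + rr * std::cos(a));
  y = tor.wrap(y0 + rr * std::sin(a));
}

void shuffle_idx(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) std::swap(v[i], v[runif_int(i + 1)]);
}

// movement modes: 0 = per-axis displacement uniform on [-s, s];
// 1 = fixed step of length s in a uniform random direction;
// 2 = displacement of exactly s in each axis, signs random;
// 3 = relocate uniformly on the grid (fast-mixing / mean-field limit)
void move_all(std::vector<double> &x, std::vector<double> &y, double speed,
              int mode, const Torus &tor) {
  for (size_t i = 0; i < x.size(); ++i) {
    if (mode == 3) {
      x[i] = R::runif(0.0, tor.L);
      y[i] = R::runif(0.0, tor.L);
      continue;
    }
    double dx, dy;
    if (mode == 1) {
      double a = unif_rand() * 2.0 * M_PI;
      dx = speed * std::cos(a);
      dy = speed * std::sin(a);
    } else if (mode == 2) {
      dx = (unif_rand() < 0.5) ? -speed : speed;
      dy = (unif_rand() < 0.5) ? -speed : speed;
    } else {
      dx = R::runif(-speed, speed);
      dy = R::runif(-speed, speed);
    }
    x[i] = tor.wrap(x[i] + dx);
    y[i] = tor.wrap(y[i] + dy);
  }
}

std::vector<double> as_vec(NumericVector v) {
  return std::vector<double>(v.begin(), v.end());
}

}  // namespace

// [[Rcpp::export(name = ".iba_run_cpp")]]
List iba_run_cpp(List state, List cfg, int n_steps) {
  Torus tor{as<double>(cfg["grid_size"])};
  const double speed_r = cfg["speed_r"], speed_pc = cfg["speed_pc"],
               speed_sc = cfg["speed_sc"];
  const double r2_pc = std::pow(as<double>(cfg["radius_pc"]), 2),
               r2_sc = std::pow(as<double>(cfg["radius_sc"]), 2);
  const double radius_pc = cfg["radius_pc"], radius_sc = cfg["radius_sc"];
  const int influx = cfg["resource_influx"], window = cfg["sc_window"],
            surv_thr = cfg["sc_survival_threshold"],
            repro_thr = cfg["sc_repro_threshold"],
            refractory = cfg["sc_repro_refractory"];
  auto mode_of = [](const std::string &m) {
    return m == "radial" ? 1 : m == "axis_fixed" ? 2 : m == "mix" ? 3 : 0;
  };
  const int move_mode = mode_of(as<std::string>(cfg["movement"]));
  const int move_mode_sc = mode_of(as<std::string>(cfg["movement_sc"]));
  const bool use_index = as<bool>(cfg["spatial_index"]);
  // shared grazing: a resource feeds every PC within radius this step and is
  // then removed; exclusive: first (randomly ordered) PC to reach it eats it
  const bool shared = as<bool>(cfg["resource_sharing"]);
  // a PC taken by an SC has already grazed this step; if true its offspring
  // (meals >= 2) still appears even though the parent is removed
  const bool posthumous = as<bool>(cfg["pc_posthumous_repro"]);
  // starvation rule before an SC has a full window of history:
  // "grace": no starvation until age >= window;
  // "prorated": die when the rolling sum falls below the threshold scaled
  //             to the history actually available, from the first step
  const bool prorated = as<std::string>(cfg["sc_starvation"]) == "prorated";
  // when true, SC predation is resolved before PC grazing within a step, so
  // SCs select from the full PC pool including PCs that would starve
  const bool predation_first = as<bool>(cfg["sc_predation_first"]);
  // satiation: an SC stops hunting after this many PCs in one step
  // (0 = unlimited)
  const int sc_max_meals = as<int>(cfg["sc_max_meals"]);
  // offspring location: uniformly on the grid ("random", like the resource
  // influx), at the parent's position ("parent"), or uniformly in a disc of
  // radius `offspring_dispersal` around the parent ("disc")
  const std::string op = as<std::string>(cfg["offspring_placement"]);
  const int offspring_mode = op == "random" ? 2 : op == "disc" ? 1 : 0;
  const double disp_r = as<double>(cfg["offspring_dispersal"]);

  std::vector<double> rx = as_vec(state["rx"]), ry = as_vec(state["ry"]);
  std::vector<double> px = as_vec(state["pcx"]), py = as_vec(state["pcy"]);
  std::vector<double> sx = as_vec(state["scx"]), sy = as_vec(state["scy"]);
  IntegerMatrix hist0 = state["sc_hist"];  // window x n_sc circular buffer
  std::vector<std::vector<int> > hist(sx.size(), std::vector<int>(window, 0));
  for (size_t j = 0; j < sx.size(); ++j)
    for (int r = 0; r < window; ++r) hist[j][r] = hist0(r, j);
  std::vector<long> hsum(sx.size(), 0);
  for (size_t j = 0; j < sx.size(); ++j)
    for (int r = 0; r < window; ++r) hsum[j] += hist[j][r];
  std::vector<int> age = as<std::vector<int> >(state["sc_age"]);
  std::vector<int> since = as<std::vector<int> >(state["sc_since_repro"]);
  int step = state["current_step"];

  IntegerVector rec_t(n_steps), rec_r(n_steps), rec_pc(n_steps), rec_sc(n_steps),
      rec_eaten_r(n_steps), rec_eaten_pc(n_steps), rec_pc_starved(n_steps),
      rec_pc_births(n_steps), rec_sc_deaths(n_steps), rec_sc_births(n_steps);

  RNGScope rng;

  for (int s = 0; s < n_steps; ++s) {
    const int n_r_before = (int)rx.size();

    // absorbing state: with no consumers of either class nothing can be
    // eaten or born, so abundances evolve deterministically (influx only)
    if (px.empty() && sx.empty()) {
      for (int i = 0; i < influx; ++i) {
        rx.push_back(R::runif(0.0, tor.L));
        ry.push_back(R::runif(0.0, tor.L));
      }
      ++step;
      rec_t[s] = step;
      rec_r[s] = (int)rx.size();
      rec_pc[s] = 0;
      rec_sc[s] = 0;
      rec_eaten_r[s] = 0;
      rec_eaten_pc[s] = 0;
      rec_pc_starved[s] = 0;
      rec_pc_births[s] = 0;
      rec_sc_deaths[s] = 0;
      rec_sc_births[s] = 0;
      continue;
    }

    // (1) movement, every individual
    move_all(rx, ry, speed_r, move_mode, tor);
    move_all(px, py, speed_pc, move_mode, tor);
    move_all(sx, sy, speed_sc, move_mode_sc, tor);

    // consumption phases; a step runs grazing-then-predation by default,
    // or predation-then-grazing when `sc_predation_first` (PCs already
    // taken do not graze in that case)
    std::vector<bool> r_eaten(rx.size(), false);
    std::vector<bool> pc_taken(px.size(), false);
    std::vector<int> pc_meals(px.size(), 0);
    std::vector<int> sc_meals(sx.size(), 0);
    int eaten_pc_total = 0, removed_r_total = 0;

    // PCs graze resources within radius_pc; each resource at most once
    // (every PC in reach when `resource_sharing`)
    auto graze = [&]() {
      std::vector<int> pc_order(px.size());
      for (size_t i = 0; i < pc_order.size(); ++i) pc_order[i] = (int)i;
      shuffle_idx(pc_order);
      CellGrid g(tor, radius_pc, rx, ry);
      for (int i : pc_order) {
        if (predation_first && pc_taken[i]) continue;
        int meals = 0;
        auto eat = [&](int j) {
          if ((shared || !r_eaten[j]) &&
              tor.d2(px[i], py[i], rx[j], ry[j]) <= r2_pc) {
            r_eaten[j] = true;
            ++meals;
          }
        };
        if (use_index) {
          g.visit(px[i], py[i], eat);
        } else {
          for (size_t j = 0; j < rx.size(); ++j) eat((int)j);
        }
        pc_meals[i] = meals;
      }
      for (size_t j = 0; j < rx.size(); ++j)
        if (r_eaten[j]) ++removed_r_total;
    };

    // SCs take PCs within radius_sc; each PC at most once
    auto predate = [&]() {
      std::vector<int> sc_order(sx.size());
      for (size_t i = 0; i < sc_order.size(); ++i) sc_order[i] = (int)i;
      shuffle_idx(sc_order);
      CellGrid g(tor, radius_sc, px, py);
      for (int i : sc_order) {
        int meals = 0;
        auto eat = [&](int j) {
          if ((sc_max_meals == 0 || meals < sc_max_meals) && !pc_taken[j] &&
              tor.d2(sx[i], sy[i], px[j], py[j]) <= r2_sc) {
            pc_taken[j] = true;
            ++meals;
          }
        };
        if (use_index) {
          g.visit(sx[i], sy[i], eat);
        } else {
          for (size_t j = 0; j < px.size(); ++j) eat((int)j);
        }
        sc_meals[i] = meals;
        eaten_pc_total += meals;
      }
    };

    if (predation_first) {
      predate();
      graze();
    } else {
      graze();
      predate();
    }

    // (4) PC survival/reproduction; predation removals first, then
    //     0 meals -> starves, >=1 -> survives, >=2 -> one offspring
    std::vector<double> npx, npy;
    npx.reserve(px.size());
    npy.reserve(px.size());
    int starved = 0, pc_births = 0;
    auto place_offspring = [&](double x0, double y0, std::vector<double> &ox,
                               std::vector<double> &oy) {
      double x, y;
      if (offspring_mode == 2) {
        x = R::runif(0.0, tor.L);
        y = R::runif(0.0, tor.L);
      } else if (offspring_mode == 1) {
        disc_point(x0, y0, disp_r, tor, x, y);
      } else {
        x = x0;
        y = y0;
      }
      ox.push_back(x);
      oy.push_back(y);
    };
    for (size_t i = 0; i < px.size(); ++i) {
      if (pc_taken[i]) {
        if (posthumous && pc_meals[i] >= 2) {
          place_offspring(px[i], py[i], npx, npy);
          ++pc_births;
        }
        continue;
      }
      if (pc_meals[i] == 0) {
        ++starved;
        continue;
      }
      npx.push_back(px[i]);
      npy.push_back(py[i]);
      if (pc_meals[i] >= 2) {
        place_offspring(px[i], py[i], npx, npy);
        ++pc_births;
      }
    }
    px.swap(npx);
    py.swap(npy);

    // (5) SC rolling-window update, survival and reproduction.
    //     Survival is only enforced once an SC has a full window of history
    //     (the rule is undefined before that); reproduction needs the rolling
    //     sum over the last `window` steps and a refractory gap.
    const int row = step % window;
    int sc_deaths = 0, sc_births = 0;
    std::vector<double> birth_x, birth_y;
    size_t j = 0;
    while (j < sx.size()) {
      hsum[j] += sc_meals[j] - hist[j][row];
      hist[j][row] = sc_meals[j];
      ++age[j];
      ++since[j];
      const double thr_j = prorated
          ? surv_thr * (double)std::min(age[j], window) / window
          : (age[j] >= window ? (double)surv_thr : -1.0);
      if (hsum[j] < thr_j) {
        sx.erase(sx.begin() + j);
        sy.erase(sy.begin() + j);
        hist.erase(hist.begin() + j);
        hsum.erase(hsum.begin() + j);
        age.erase(age.begin() + j);
        since.erase(since.begin() + j);
        ++sc_deaths;
        continue;
      }
      if (hsum[j] >= repro_thr && since[j] >= refractory) {
        place_offspring(sx[j], sy[j], birth_x, birth_y);
        since[j] = 0;
        ++sc_births;
      }
      ++j;
    }
    for (size_t b = 0; b < birth_x.size(); ++b) {
      sx.push_back(birth_x[b]);
      sy.push_back(birth_y[b]);
      hist.push_back(std::vector<int>(window, 0));
      hsum.push_back(0);
      age.push_back(0);
      since.push_back(0);
    }

    // (6) remove grazed resources, then influx of new resources
    std::vector<double> nrx, nry;
    nrx.reserve(rx.size() - removed_r_total + influx);
    nry.reserve(rx.size() - removed_r_total + influx);
    for (size_t i = 0; i < rx.size(); ++i)
      if (!r_eaten[i]) {
        nrx.push_back(rx[i]);
        nry.push_back(ry[i]);
      }
    for (int i = 0; i < influx; ++i) {
      nrx.push_back(R::runif(0.0, tor.L));
      nry.push_back(R::runif(0.0, tor.L));
    }
    rx.swap(nrx);
    ry.swap(nry);

    // (7) advance the clock and record end-of-step abundances
    ++step;
    rec_t[s] = step;
    rec_r[s] = (int)rx.size();
    rec_pc[s] = (int)px.size();
    rec_sc[s] = (int)sx.size();
    rec_eaten_r[s] = removed_r_total;
    rec_eaten_pc[s] = eaten_pc_total;
    rec_pc_starved[s] = starved;
    rec_pc_births[s] = pc_births;
    rec_sc_deaths[s] = sc_deaths;
    rec_sc_births[s] = sc_births;
    if (n_r_before - removed_r_total + influx != (int)rx.size())
      stop("resource ledger failed to balance at step %d", step);

    if (s % 2000 == 1999) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix hist_out(window, (int)sx.size());
  for (size_t c = 0; c < sx.size(); ++c)
    for (int r = 0; r < window; ++r) hist_out(r, c) = hist[c][r];

  List new_state = List::create(
      _["rx"] = NumericVector(rx.begin(), rx.end()),
      _["ry"] = NumericVector(ry.begin(), ry.end()),
      _["pcx"] = NumericVector(px.begin(), px.end()),
      _["pcy"] = NumericVector(py.begin(), py.end()),
      _["scx"] = NumericVector(sx.begin(), sx.end()),
      _["scy"] = NumericVector(sy.begin(), sy.end()),
      _["sc_hist"] = hist_out,
      _["sc_age"] = IntegerVector(age.begin(), age.end()),
      _["sc_since_repro"] = IntegerVector(since.begin(), since.end()),
      _["current_step"] = step);

  DataFrame rec = DataFrame::create(
      _["t"] = rec_t, _["resources"] = rec_r, _["primary_consumers"] = rec_pc,
      _["secondary_consumers"] = rec_sc, _["resources_eaten"] = rec_eaten_r,
      _["pc_eaten_by_sc"] = rec_eaten_pc, _["pc_starved"] = rec_pc_starved,
      _["pc_births"] = rec_pc_births, _["sc_deaths"] = rec_sc_deaths,
      _["sc_births"] = rec_sc_births);

  return List::create(_["state"] = new_state, _["records"] = rec);
}
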