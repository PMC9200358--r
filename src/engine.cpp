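// Agent-based germinal-centre reaction engine.
//
// The R layer builds the lattice, chemokine fields and stroma and passes
// flat arrays; this file owns the per-time-step loop: persistent-random-walk
// motility with site exclusion, the antigen-collection state machines of the
// three scenarios, Tfh help competition, and the B-cell lifecycle
// (proliferation + somatic hypermutation, the collection window, selection,
// recycling and asymmetric-division output). All stochastic draws flow from
// one xoshiro256++ stream seeded from the run seed, so runs are bit
// reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t out = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return out;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int n) {
    int v = (int)(unif() * n);
    return v >= n ? n - 1 : v;
  }
};

const int DX[6] = {1, -1, 0, 0, 0, 0};
const int DY[6] = {0, 0, 1, -1, 0, 0};
const int DZ6[6] = {0, 0, 0, 0, 1, -1};

enum Phase { CB = 0, CC_COLLECT = 1, CC_SEEK = 2 };
enum Coll { FREE = 0, BOUND = 1, EXTRACT = 2 };
const int MAXD = 8;

struct Cell {
  uint8_t alive, phase, coll, clone;
  uint8_t helped, attended, selected;
  uint8_t in_contact;
  int contact_idle, contact_refract;
  int8_t dir;
  int16_t persist;
  int16_t shape[MAXD];
  int x, y, z;
  double pa, pd, aff;
  int divleft;
  int div_timer;
  int window;      // -1 until the LZ search starts, then elapsed steps
  int refract, tfh_sig, seek_clock;
  int bound_site;
  double ag_ret, ag_col;
  int uid;
  int nc_contact, nc_assoc, nc_disno, nc_diswith;
};

struct Tfh {
  int x, y, z;
  int8_t dir;
  int16_t persist;
  int helping;
};

struct Engine {
  // geometry
  int nside, rmax;
  const int *inside, *zone, *fdc_map;
  const double *f12, *f13;
  std::vector<int> fdc_ag;
  // parameters
  int scenario, n_steps, sample_every;
  double dt;
  int n_clones, n_dims;
  std::vector<double> th_s2, th_c2;  // sin^2/cos^2 theta per clone
  double gamma2, aff_floor;
  std::vector<int> ag_pos;
  double p_finish, s_ag;
  int refract_steps, window_steps;
  bool rupture_first;
  int expansion_div, div_after_sel;
  double cycle_steps, jitter, mut_prob;
  int tfh_req_steps, seek_steps;
  int contact_patience_steps, contact_refract_steps;
  double asym_prob, asym_frac;
  double move_prob_b, move_prob_tfh, w_b, w_tfh;
  int persist_steps;

  Rng rng;
  std::vector<Cell> cells;
  std::vector<int> free_slots;
  std::vector<Tfh> tfh;
  std::vector<int> occ;  // -1 free, >=0 B-cell slot, <=-2 Tfh (-k-2)
  int uid_counter = 0;

  // ledgers and logs
  double init_ag = 0, lost_ag = 0, oc_ag = 0;
  long long founders_total = 0, divisions = 0, apoptosis = 0;
  std::vector<long long> capture_cum, oc_count;
  std::vector<double> oc_aff_sum;
  std::vector<int> ev_uid, ev_clone, ev_contact, ev_assoc, ev_disno,
      ev_diswith, ev_selected;
  std::vector<int> oc_clone;
  std::vector<double> oc_time_h, oc_aff, oc_units;

  explicit Engine(uint64_t seed) : rng(seed) {}

  inline int cube(int x, int y, int z) const {
    return (x + rmax) + nside * ((y + rmax) + nside * (z + rmax));
  }
  inline bool inBox(int x, int y, int z) const {
    return std::abs(x) <= rmax && std::abs(y) <= rmax && std::abs(z) <= rmax;
  }
  inline bool isInside(int x, int y, int z) const {
    return inBox(x, y, z) && inside[cube(x, y, z)];
  }

  void phenotype(Cell &c) {
    long d = 0;
    for (int k = 0; k < n_dims; ++k) d += std::labs(c.shape[k] - ag_pos[k]);
    double d2 = (double)d * d;
    c.pa = std::exp(-d2 * th_s2[c.clone] / gamma2);
    c.pd = 1.0 - std::exp(-d2 * th_c2[c.clone] / gamma2);
    c.aff = std::exp(-d2 / gamma2);
    if (c.aff < aff_floor) c.aff = 0.0;
  }

  int drawCycle() {
    double f = 1.0 - jitter + 2.0 * jitter * rng.unif();
    int t = (int)std::lround(cycle_steps * f);
    return t < 1 ? 1 : t;
  }

  int allocSlot() {
    if (!free_slots.empty()) {
      int i = free_slots.back();
      free_slots.pop_back();
      return i;
    }
    cells.push_back(Cell());
    return (int)cells.size() - 1;
  }

  int spawn(int clone, int x, int y, int z, const int16_t *shape,
            int divleft, double ag_ret) {
    int i = allocSlot();
    Cell &c = cells[i];
    c = Cell();
    c.alive = 1; c.phase = CB; c.coll = FREE; c.clone = (uint8_t)clone;
    c.helped = 0; c.attended = 0; c.selected = 0;
    c.dir = -1; c.persist = 0;
    for (int k = 0; k < n_dims; ++k) c.shape[k] = shape[k];
    c.x = x; c.y = y; c.z = z;
    c.divleft = divleft;
    c.div_timer = drawCycle();
    c.window = -1; c.refract = 0; c.tfh_sig = 0; c.seek_clock = 0;
    c.bound_site = -1;
    c.ag_ret = ag_ret; c.ag_col = 0;
    c.uid = ++uid_counter;
    c.nc_contact = c.nc_assoc = c.nc_disno = c.nc_diswith = 0;
    phenotype(c);
    occ[cube(x, y, z)] = i;
    return i;
  }

  void flushEvents(const Cell &c) {
    if (!c.attended) return;
    ev_uid.push_back(c.uid);
    ev_clone.push_back(c.clone);
    ev_contact.push_back(c.nc_contact);
    ev_assoc.push_back(c.nc_assoc);
    ev_disno.push_back(c.nc_disno);
    ev_diswith.push_back(c.nc_diswith);
    ev_selected.push_back(c.selected);
  }

  void die(int i) {
    Cell &c = cells[i];
    lost_ag += c.ag_ret + c.ag_col;
    ++apoptosis;
    flushEvents(c);
    occ[cube(c.x, c.y, c.z)] = -1;
    c.alive = 0;
    free_slots.push_back(i);
  }

  void makeOC(int i, double t_h) {
    Cell &c = cells[i];
    double units = c.ag_ret + c.ag_col;
    oc_ag += units;
    oc_count[c.clone]++;
    oc_aff_sum[c.clone] += c.aff;
    oc_clone.push_back(c.clone);
    oc_time_h.push_back(t_h);
    oc_aff.push_back(c.aff);
    oc_units.push_back(units);
    flushEvents(c);
    occ[cube(c.x, c.y, c.z)] = -1;
    c.alive = 0;
    free_slots.push_back(i);
  }

  void mutate(int i) {
    if (rng.unif() >= mut_prob) return;
    Cell &c = cells[i];
    int k = rng.below(n_dims);
    c.shape[k] += (rng.below(2) == 0) ? -1 : 1;
    phenotype(c);
  }

  void toCC(int i) {
    Cell &c = cells[i];
    c.phase = CC_COLLECT; c.coll = FREE;
    c.ag_col = 0; c.refract = 0; c.tfh_sig = 0; c.seek_clock = 0;
    c.in_contact = 0; c.contact_idle = 0; c.contact_refract = 0;
    c.bound_site = -1;
    c.window = (zone[cube(c.x, c.y, c.z)] == 1) ? 0 : -1;
  }

  // one persistent-random-walk attempt for an agent at (x,y,z)
  template <typename A>
  void walk(A &a, double move_prob, double w, const double *field) {
    if (a.persist <= 0 || a.dir < 0) {
      if (w > 0 && rng.unif() < w) {
        double best = -1.0;
        int pick = -1, nbest = 0;
        for (int d = 0; d < 6; ++d) {
          int nx = a.x + DX[d], ny = a.y + DY[d], nz = a.z + DZ6[d];
          if (!isInside(nx, ny, nz)) continue;
          double v = field[cube(nx, ny, nz)];
          if (v > best) { best = v; pick = d; nbest = 1; }
          else if (v == best) {
            ++nbest;
            if (rng.unif() * nbest < 1.0) pick = d;
          }
        }
        a.dir = (int8_t)(pick >= 0 ? pick : rng.below(6));
      } else {
        a.dir = (int8_t)rng.below(6);
      }
      a.persist = (int16_t)persist_steps;
    }
    a.persist--;
    if (rng.unif() < move_prob) {
      int d = a.dir;
      int nx = a.x + DX[d], ny = a.y + DY[d], nz = a.z + DZ6[d];
      if (isInside(nx, ny, nz) && occ[cube(nx, ny, nz)] == -1) {
        occ[cube(nx, ny, nz)] = occ[cube(a.x, a.y, a.z)];
        occ[cube(a.x, a.y, a.z)] = -1;
        a.x = nx; a.y = ny; a.z = nz;
      } else {
        a.dir = -1;  // blocked: re-orient next step
      }
    }
  }

  void collectionStep(int i) {
    Cell &c = cells[i];
    if (c.refract > 0) { c.refract--; return; }
    if (c.coll == FREE) {
      int site = fdc_map[cube(c.x, c.y, c.z)];
      if (site < 0) return;
      int cag = fdc_ag[site];
      double pC = cag >= s_ag ? 1.0 : (double)cag / s_ag;
      c.nc_contact++;
      double pb = (scenario == 0 ? c.aff : c.pa) * pC;
      if (pb > 0 && rng.unif() < pb) {
        c.nc_assoc++;
        c.bound_site = site;
        c.coll = (scenario == 0) ? EXTRACT : BOUND;
      }
      return;
    }
    if (c.coll == BOUND) {
      if (rng.unif() < c.pd) {
        c.nc_disno++;
        c.coll = FREE; c.bound_site = -1; c.refract = refract_steps;
      } else {
        c.coll = EXTRACT;
      }
      return;
    }
    // EXTRACT
    int site = c.bound_site;
    if (fdc_ag[site] < 1) {  // depleted mid-bond: rupture without antigen
      c.nc_disno++;
      c.coll = FREE; c.bound_site = -1; c.refract = refract_steps;
      return;
    }
    bool ruptured = false, finished = false;
    if (rupture_first) {
      if (scenario == 1 && rng.unif() < c.pd) ruptured = true;
      if (!ruptured) finished = rng.unif() < p_finish;
    } else {
      finished = rng.unif() < p_finish;
      if (!finished && scenario == 1 && rng.unif() < c.pd) ruptured = true;
    }
    if (ruptured) {
      c.nc_disno++;
      c.coll = FREE; c.bound_site = -1; c.refract = refract_steps;
    } else if (finished) {
      c.nc_diswith++;
      fdc_ag[site]--;
      c.ag_col += 1.0;
      capture_cum[c.clone]++;
      c.coll = FREE; c.bound_site = -1; c.refract = refract_steps;
    }
  }

  void divide(int i, double /*t_h*/, double t_h_now) {
    // find a free inside neighbour for the daughter
    int opts[6], nopt = 0;
    {
      const Cell &c = cells[i];
      for (int d = 0; d < 6; ++d) {
        int nx = c.x + DX[d], ny = c.y + DY[d], nz = c.z + DZ6[d];
        if (isInside(nx, ny, nz) && occ[cube(nx, ny, nz)] == -1)
          opts[nopt++] = d;
      }
    }
    if (nopt == 0) { cells[i].div_timer = 1; return; }  // crowded: retry
    int d = opts[rng.below(nopt)];
    double agr = cells[i].ag_ret;
    bool asym = false;
    int dominant = -1;
    double share0, share1;
    if (agr > 0 && rng.unif() < asym_prob) {
      asym = true;
      dominant = rng.below(2);
      double big = asym_frac * agr;
      share0 = (dominant == 0) ? big : agr - big;
      share1 = (dominant == 0) ? agr - big : big;
    } else {
      share0 = share1 = agr / 2.0;
    }
    int clone = cells[i].clone;
    int nx = cells[i].x + DX[d], ny = cells[i].y + DY[d],
        nz = cells[i].z + DZ6[d];
    int16_t shp[MAXD];
    for (int k = 0; k < n_dims; ++k) shp[k] = cells[i].shape[k];
    int newdiv = cells[i].divleft - 1;
    int j = spawn(clone, nx, ny, nz, shp, newdiv, share1);  // may realloc
    ++divisions;
    Cell &m = cells[i];
    m.divleft = newdiv;
    m.ag_ret = share0;
    m.div_timer = drawCycle();
    mutate(i);
    mutate(j);
    if (asym) {
      int dom = (dominant == 0) ? i : j;
      if (cells[dom].ag_ret > 0) makeOC(dom, t_h_now);
    }
    if (cells[i].alive && cells[i].divleft == 0) toCC(i);
    if (cells[j].alive && cells[j].divleft == 0) toCC(j);
  }

  void lifecycleStep(int i, double t_h_now) {
    Cell &c = cells[i];
    if (!c.alive) return;
    if (c.phase == CB) {
      c.div_timer--;
      if (c.div_timer <= 0) {
        if (c.divleft > 0) divide(i, t_h_now, t_h_now);
        else toCC(i);
      }
      return;
    }
    if (c.phase == CC_COLLECT) {
      if (c.window >= 0) {
        c.window++;
        if (c.window >= window_steps && c.coll == FREE) {
          if (c.ag_col <= 0) die(i);
          else {
            c.phase = CC_SEEK;
            c.seek_clock = 0;
            c.attended = 1;
          }
        }
      }
      return;
    }
    // CC_SEEK
    c.seek_clock++;
    if (c.contact_refract > 0) c.contact_refract--;
    if (c.in_contact) {
      if (c.helped) {
        c.contact_idle = 0;
      } else if (++c.contact_idle >= contact_patience_steps) {
        c.in_contact = 0;
        c.contact_idle = 0;
        c.contact_refract = contact_refract_steps;
      }
    }
    if (c.tfh_sig >= tfh_req_steps) {
      c.selected = 1;
      c.helped = 0;
      c.in_contact = 0;
      c.contact_idle = 0;
      c.contact_refract = 0;
      c.phase = CB;
      c.ag_ret += c.ag_col;
      c.ag_col = 0;
      c.divleft = div_after_sel;
      c.div_timer = drawCycle();
      c.tfh_sig = 0;
      c.window = -1;
      if (c.divleft == 0) toCC(i);
    } else if (c.seek_clock >= seek_steps) {
      die(i);
    }
  }

  void tfhPhase(std::vector<int> &torder) {
    for (size_t i = 0; i < cells.size(); ++i)
      if (cells[i].alive) cells[i].helped = 0;
    for (int oi : torder) {
      Tfh &t = tfh[oi];
      int best = -1, nbest = 0;
      double bestag = 0;
      for (int d = 0; d < 6; ++d) {
        int nx = t.x + DX[d], ny = t.y + DY[d], nz = t.z + DZ6[d];
        if (!inBox(nx, ny, nz)) continue;
        int o = occ[cube(nx, ny, nz)];
        if (o < 0) continue;
        const Cell &c = cells[o];
        if (!c.alive || c.phase != CC_SEEK || !c.in_contact ||
            c.ag_col <= 0)
          continue;
        if (c.ag_col > bestag) { bestag = c.ag_col; best = o; nbest = 1; }
        else if (c.ag_col == bestag) {
          ++nbest;
          if (rng.unif() * nbest < 1.0) best = o;
        }
      }
      t.helping = best;
      if (best >= 0) {
        cells[best].helped = 1;
        cells[best].tfh_sig++;
      }
    }
  }

  List run() {
    capture_cum.assign(n_clones, 0);
    oc_count.assign(n_clones, 0);
    oc_aff_sum.assign(n_clones, 0.0);

    int n_samples = n_steps / sample_every + 1;
    NumericVector ts_time(n_samples);
    NumericMatrix ts_cb(n_samples, n_clones), ts_cc(n_samples, n_clones),
        ts_oc(n_samples, n_clones), ts_ag(n_samples, n_clones),
        ts_aff(n_samples, n_clones), ts_affoc(n_samples, n_clones);
    int sample_row = 0;
    auto takeSample = [&](double t_h) {
      std::vector<int> cb(n_clones, 0), cc(n_clones, 0);
      std::vector<double> asum(n_clones, 0.0);
      std::vector<int> acount(n_clones, 0);
      for (const Cell &c : cells) {
        if (!c.alive) continue;
        if (c.phase == CB) cb[c.clone]++;
        else cc[c.clone]++;
        asum[c.clone] += c.aff;
        acount[c.clone]++;
      }
      ts_time[sample_row] = t_h;
      for (int k = 0; k < n_clones; ++k) {
        ts_cb(sample_row, k) = cb[k];
        ts_cc(sample_row, k) = cc[k];
        ts_oc(sample_row, k) = (double)oc_count[k];
        ts_ag(sample_row, k) = (double)capture_cum[k];
        ts_aff(sample_row, k) =
            acount[k] ? asum[k] / acount[k] : NA_REAL;
        ts_affoc(sample_row, k) =
            oc_count[k] ? oc_aff_sum[k] / oc_count[k] : NA_REAL;
      }
      sample_row++;
    };

    takeSample(0.0);
    std::vector<int> order, torder;
    for (int step = 0; step < n_steps; ++step) {
      double t_h_now = (step + 1) * dt / 3600.0;
      // shuffled agent order for this step
      order.clear();
      for (int i = 0; i < (int)cells.size(); ++i)
        if (cells[i].alive) order.push_back(i);
      for (int i = (int)order.size() - 1; i > 0; --i) {
        int j = rng.below(i + 1);
        std::swap(order[i], order[j]);
      }
      torder.clear();
      for (int i = 0; i < (int)tfh.size(); ++i) torder.push_back(i);
      for (int i = (int)torder.size() - 1; i > 0; --i) {
        int j = rng.below(i + 1);
        std::swap(torder[i], torder[j]);
      }

      // 1. motility; seekers engaged with a Tfh hold their position
      for (int i : order) {
        Cell &c = cells[i];
        if (!c.alive) continue;
        if (c.phase == CC_COLLECT && c.coll != FREE) continue;
        if (c.phase == CC_SEEK && c.in_contact) continue;
        const double *field = (c.phase == CB) ? f12 : f13;
        walk(c, move_prob_b, w_b, field);
        if (c.phase == CC_COLLECT && c.window < 0 &&
            zone[cube(c.x, c.y, c.z)] == 1)
          c.window = 0;
        // a free seeker arriving next to a Tfh binds it and competes in
        // place until helped, selected, or the contact goes stale
        if (c.phase == CC_SEEK && !c.in_contact && c.contact_refract == 0) {
          for (int d = 0; d < 6; ++d) {
            int nx = c.x + DX[d], ny = c.y + DY[d], nz = c.z + DZ6[d];
            if (inBox(nx, ny, nz) && occ[cube(nx, ny, nz)] <= -2) {
              c.in_contact = 1;
              c.contact_idle = 0;
              break;
            }
          }
        }
      }
      for (int k : torder) {
        Tfh &t = tfh[k];
        if (t.helping >= 0 && cells[t.helping].alive &&
            cells[t.helping].phase == CC_SEEK)
          continue;  // engaged: hold position
        walk(t, move_prob_tfh, w_tfh, f13);
      }

      // 2. antigen collection
      for (int i : order)
        if (cells[i].alive && cells[i].phase == CC_COLLECT)
          collectionStep(i);

      // 3. Tfh help competition
      tfhPhase(torder);

      // 4. lifecycle
      for (int i : order) lifecycleStep(i, t_h_now);

      if ((step + 1) % sample_every == 0) takeSample(t_h_now);
    }

    // flush event records of cells still alive
    for (const Cell &c : cells)
      if (c.alive) flushEvents(c);

    double cell_ag = 0;
    long long alive = 0, total_oc = 0;
    for (const Cell &c : cells)
      if (c.alive) { cell_ag += c.ag_ret + c.ag_col; ++alive; }
    double site_ag = 0;
    for (int a : fdc_ag) site_ag += a;
    for (int k = 0; k < n_clones; ++k) total_oc += oc_count[k];

    return List::create(
        _["time_h"] = ts_time, _["n_cb"] = ts_cb, _["n_cc"] = ts_cc,
        _["n_oc_cum"] = ts_oc, _["ag_collected_total"] = ts_ag,
        _["mean_affinity_alive"] = ts_aff,
        _["mean_affinity_oc_cum"] = ts_affoc,
        _["ev"] = List::create(
            _["cell_id"] = ev_uid, _["clone"] = ev_clone,
            _["n_fdc_contacts"] = ev_contact,
            _["n_associations"] = ev_assoc,
            _["n_dissoc_no_ag"] = ev_disno,
            _["n_dissoc_with_ag"] = ev_diswith,
            _["selected"] = ev_selected),
        _["oc"] = List::create(
            _["clone"] = oc_clone, _["time_h"] = oc_time_h,
            _["affinity"] = oc_aff, _["ag"] = oc_units),
        _["ledger"] = NumericVector::create(
            _["ag_initial"] = init_ag, _["ag_on_sites"] = site_ag,
            _["ag_in_cells"] = cell_ag, _["ag_in_oc"] = oc_ag,
            _["ag_lost_apoptosis"] = lost_ag,
            _["founders"] = (double)founders_total,
            _["divisions"] = (double)divisions,
            _["apoptosis"] = (double)apoptosis,
            _["n_oc"] = (double)total_oc, _["alive_final"] = (double)alive),
        _["site_ag_final"] = IntegerVector(fdc_ag.begin(), fdc_ag.end()));
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_run_gc(List a) {
  IntegerVector inside = a["inside"], zone = a["zone"],
      fdc_map = a["fdc_map"], fdc_ag = a["fdc_ag"],
      tfh_pos = a["tfh_pos"], dz_sites = a["dz_sites"],
      ag_pos = a["ag_pos"];
  NumericVector f12 = a["f12"], f13 = a["f13"], theta_deg = a["theta_deg"];
  IntegerMatrix founder_shape = a["founder_shape"];

  Engine e((uint64_t)(uint32_t)as<int>(a["seed"]));
  e.nside = as<int>(a["nside"]);
  e.rmax = (e.nside - 1) / 2;
  e.inside = INTEGER(inside);
  e.zone = INTEGER(zone);
  e.fdc_map = INTEGER(fdc_map);
  e.f12 = REAL(f12);
  e.f13 = REAL(f13);
  e.fdc_ag.assign(fdc_ag.begin(), fdc_ag.end());

  e.scenario = as<int>(a["scenario"]);
  e.n_steps = as<int>(a["n_steps"]);
  e.sample_every = as<int>(a["sample_every"]);
  e.dt = as<double>(a["dt"]);
  e.n_clones = theta_deg.size();
  e.n_dims = as<int>(a["n_dims"]);
  if (e.n_dims > MAXD) stop("at most %d shape-space dimensions", MAXD);
  double g = as<double>(a["gamma"]);
  e.gamma2 = g * g;
  e.aff_floor = as<double>(a["affinity_floor"]);
  e.ag_pos.assign(ag_pos.begin(), ag_pos.end());
  for (int k = 0; k < e.n_clones; ++k) {
    double th = theta_deg[k] * M_PI / 180.0;
    double s = std::sin(th), c = std::cos(th);
    e.th_s2.push_back(s * s);
    e.th_c2.push_back(c * c);
  }
  e.p_finish = as<double>(a["p_finish"]);
  e.s_ag = as<double>(a["s_ag"]);
  e.refract_steps = as<int>(a["refract_steps"]);
  e.window_steps = as<int>(a["window_steps"]);
  e.rupture_first = as<bool>(a["rupture_first"]);
  e.expansion_div = as<int>(a["expansion_div"]);
  e.div_after_sel = as<int>(a["div_after_sel"]);
  e.cycle_steps = as<double>(a["cycle_steps"]);
  e.jitter = as<double>(a["jitter"]);
  e.mut_prob = as<double>(a["mut_prob"]);
  e.tfh_req_steps = as<int>(a["tfh_req_steps"]);
  e.seek_steps = as<int>(a["seek_steps"]);
  e.contact_patience_steps = as<int>(a["contact_patience_steps"]);
  e.contact_refract_steps = as<int>(a["contact_refract_steps"]);
  e.asym_prob = as<double>(a["asym_prob"]);
  e.asym_frac = as<double>(a["asym_frac"]);
  e.move_prob_b = as<double>(a["move_prob_b"]);
  e.move_prob_tfh = as<double>(a["move_prob_tfh"]);
  e.w_b = as<double>(a["chemo_weight_b"]);
  e.w_tfh = as<double>(a["chemo_weight_tfh"]);
  e.persist_steps = as<int>(a["persist_steps"]);

  int n3 = e.nside * e.nside * e.nside;
  e.occ.assign(n3, -1);
  for (int a0 : e.fdc_ag) e.init_ag += a0;

  // Tfh seeding (R supplies distinct LZ cube indices, 0-based)
  for (int k = 0; k < tfh_pos.size(); ++k) {
    Tfh t;
    int idx = tfh_pos[k];
    t.z = idx / (e.nside * e.nside) - e.rmax;
    t.y = (idx / e.nside) % e.nside - e.rmax;
    t.x = idx % e.nside - e.rmax;
    t.dir = -1; t.persist = 0; t.helping = -1;
    e.occ[idx] = -k - 2;
    e.tfh.push_back(t);
  }

  // founder seeding in the dark zone
  int n_founders = as<int>(a["n_founders"]);
  for (int c = 0; c < e.n_clones; ++c) {
    int16_t shp[MAXD];
    for (int k = 0; k < e.n_dims; ++k)
      shp[k] = (int16_t)founder_shape(c, k);
    for (int f = 0; f < n_founders; ++f) {
      int idx = -1;
      for (int tries = 0; tries < 10000; ++tries) {
        int cand = dz_sites[e.rng.below(dz_sites.size())];
        if (e.occ[cand] == -1) { idx = cand; break; }
      }
      if (idx < 0) stop("could not place founder: dark zone full");
      int z = idx / (e.nside * e.nside) - e.rmax;
      int y = (idx / e.nside) % e.nside - e.rmax;
      int x = idx % e.nside - e.rmax;
      e.spawn(c, x, y, z, shp, e.expansion_div, 0.0);
      e.founders_total++;
    }
  }

  return e.run();
}

// [[Rcpp::export]]
int cpp_simulate_captures(int n, int scenario, double pa, double pd,
                          double pc, double aff, double pfinish, int seed) {
  Rng rng((uint64_t)(uint32_t)seed);
  int captures = 0;
  for (int i = 0; i < n; ++i) {
    double pbind = (scenario == 0 ? aff : pa) * pc;
    if (rng.unif() >= pbind) continue;        // no association
    if (scenario != 0) {
      if (rng.unif() < pd) continue;          // dissociation before extraction
    }
    if (pfinish <= 0) continue;               // extraction can never complete
    bool captured = false;
    for (;;) {
      if (scenario == 1 && rng.unif() < pd) break;  // rupture
      if (rng.unif() < pfinish) { captured = true; break; }
    }
    if (captured) ++captures;
  }
  return captures;
}
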