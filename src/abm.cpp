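// Deme-based spatial agent model of tumour growth under a dynamic selection
// landscape. Genotype-level bookkeeping (counts per genotype per deme) keeps
// the model equivalent in distribution to per-cell semantics while scaling to
// 1e7+ cells. All randomness goes through R's RNG so runs are reproducible
// under set.seed().

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Params {
  int deme_capacity;
  double final_size;
  double death_rate;
  double mutation_rate;   // expected mutations per division over the exome
  double s;               // global selection coefficient
  double driver_prob;
  double driver_mult;
  double event_prob;      // genomic-event probability per division (enabled lineages)
  double min_report_frac; // carrier-fraction floor for reported mutations
  int founder_mutations;  // truncal mutations carried by the founder cell
};

// DFE draw for a single mutation; side mass proportional to the side scale
// (negative Exp(mean s) with prob 2/3, positive Exp(mean s/2) with prob 1/3);
// drivers get a deterministic +driver_mult*s and enable rearrangements.
inline double mutation_effect(const Params& P, bool& is_driver) {
  is_driver = false;
  if (P.s <= 0.0) return 0.0;
  if (unif_rand() < P.driver_prob) {
    is_driver = true;
    return P.driver_mult * P.s;
  }
  if (unif_rand() < 2.0 / 3.0) return -R::rexp(P.s);
  return R::rexp(P.s / 2.0);
}

// genomic events: positive Exp(mean s) with prob 1/4, negative Exp(mean 3 s)
// with prob 3/4 (means 2x / 3x the mutation means)
inline double event_effect(const Params& P) {
  if (P.s <= 0.0) return 0.0;
  if (unif_rand() < 3.0 / 4.0) return -R::rexp(3.0 * P.s);
  return R::rexp(P.s);
}

struct Genotypes {
  std::vector<int> parent;        // -1 for the founder
  std::vector<double> fitness;
  std::vector<uint8_t> rearr;     // structural-rearrangement enabled lineage
  std::vector<int64_t> mut_off;
  std::vector<int> mut_n;
  std::vector<int> muts;          // flat new-mutation ids per genotype
  std::vector<int> mut_origin;    // mutation id -> genotype that introduced it

  int add(int par, double fit, bool rearr_flag, const std::vector<int>& newmuts) {
    parent.push_back(par);
    fitness.push_back(fit < 0.0 ? 0.0 : fit);
    rearr.push_back(rearr_flag ? 1 : 0);
    mut_off.push_back((int64_t)muts.size());
    mut_n.push_back((int)newmuts.size());
    int id = (int)parent.size() - 1;
    for (int m : newmuts) {
      muts.push_back(m);
      if ((int)mut_origin.size() <= m) mut_origin.resize(m + 1, -1);
      mut_origin[m] = id;
    }
    return id;
  }
};

struct Deme {
  std::vector<std::pair<int, int>> cnt; // (genotype, cells)
  int64_t total = 0;
  bool alive = true;
};

constexpr int64_t COORD_OFF = 1 << 20;
inline int64_t pos_key(int x, int y, int z) {
  return ((int64_t)(x + COORD_OFF)) |
         (((int64_t)(y + COORD_OFF)) << 21) |
         (((int64_t)(z + COORD_OFF)) << 42);
}
inline void key_pos(int64_t k, int& x, int& y, int& z) {
  x = (int)(k & ((1 << 21) - 1)) - COORD_OFF;
  y = (int)((k >> 21) & ((1 << 21) - 1)) - COORD_OFF;
  z = (int)((k >> 42) & ((1 << 21) - 1)) - COORD_OFF;
}
const int DX[6] = {1, -1, 0, 0, 0, 0};
const int DY[6] = {0, 0, 1, -1, 0, 0};
const int DZ[6] = {0, 0, 0, 0, 1, -1};

struct World {
  std::unordered_map<int64_t, int> pos2idx;
  std::vector<int64_t> keys;
  std::vector<Deme> demes;
  int64_t total_cells = 0;

  int add_deme(int64_t key) {
    demes.emplace_back();
    keys.push_back(key);
    int idx = (int)demes.size() - 1;
    pos2idx[key] = idx;
    return idx;
  }
  bool empty_at(int64_t key) const { return pos2idx.find(key) == pos2idx.end(); }
};

// one synchronous division+death sweep over a single deme
void sweep_deme(World& W, int di, Genotypes& G, const Params& P, int& next_mut) {
  Deme& d = W.demes[di];
  if (!d.alive || d.total == 0) return;
  double maxfit = 0.0;
  for (auto& e : d.cnt) maxfit = std::max(maxfit, G.fitness[e.first]);
  // division slows as the deme fills but must still outpace the death rate
  // at capacity, otherwise demes equilibrate below capacity and never split;
  // the factor is 1 at an empty deme and 1/2 at the capacity threshold
  double density = 1.0 - (double)d.total / (2.0 * P.deme_capacity);
  if (density < 0.0) density = 0.0;

  size_t n0 = d.cnt.size();
  int64_t delta = 0;
  std::vector<int> newmuts;
  for (size_t i = 0; i < n0; ++i) {
    int g = d.cnt[i].first;
    int c = d.cnt[i].second;
    if (c == 0) continue;
    double pdiv = (maxfit > 0.0 ? G.fitness[g] / maxfit : 0.0) * density;
    int nb = (pdiv > 0.0) ? (int)R::rbinom((double)c, pdiv) : 0;
    if (nb > 0) {
      bool enabled = G.rearr[g] != 0;
      // daughters with no mutation and no event stay in the parent genotype
      double p_plain = std::exp(-P.mutation_rate) * (enabled ? 1.0 - P.event_prob : 1.0);
      int n_plain = (int)R::rbinom((double)nb, p_plain);
      d.cnt[i].second += n_plain;
      delta += n_plain;
      for (int b = 0; b < nb - n_plain; ++b) {
        // rejection draw conditioned on (k > 0) || event
        int k = 0; bool ev = false;
        for (int tries = 0; tries < 1000; ++tries) {
          k = (int)R::rpois(P.mutation_rate);
          ev = enabled && (unif_rand() < P.event_prob);
          if (k > 0 || ev) break;
        }
        double fit = G.fitness[g];
        bool rearr_flag = enabled;
        newmuts.clear();
        for (int m = 0; m < k; ++m) {
          bool is_driver = false;
          double eff = mutation_effect(P, is_driver);
          if (is_driver && !rearr_flag) rearr_flag = true;
          fit *= (1.0 + eff);
          newmuts.push_back(next_mut++);
        }
        if (ev) fit *= (1.0 + event_effect(P));
        int ng = G.add(g, fit, rearr_flag, newmuts);
        d.cnt.push_back(std::make_pair(ng, 1));
        delta += 1;
      }
    }
  }
  // deaths apply to every cell present after the division phase
  for (size_t i = 0; i < d.cnt.size(); ++i) {
    int c = d.cnt[i].second;
    if (c == 0) continue;
    int nd = (int)R::rbinom((double)c, P.death_rate);
    d.cnt[i].second -= nd;
    delta -= nd;
  }
  // compact
  size_t w = 0;
  int64_t tot = 0;
  for (size_t i = 0; i < d.cnt.size(); ++i) {
    if (d.cnt[i].second > 0) {
      d.cnt[w++] = d.cnt[i];
      tot += d.cnt[i].second;
    }
  }
  d.cnt.resize(w);
  d.total = tot;
  W.total_cells += delta;
  if (tot == 0) {
    d.alive = false;
    W.pos2idx.erase(W.keys[di]);
  }
}

// split an over-capacity deme: ~half its cells move to a uniformly chosen
// empty neighbour, or the nearest empty position along a random direction
void split_deme(World& W, int di, const Params& P) {
  Deme& d = W.demes[di];
  if (!d.alive || d.total <= P.deme_capacity) return;
  int x, y, z;
  key_pos(W.keys[di], x, y, z);
  std::vector<int64_t> empties;
  for (int n = 0; n < 6; ++n) {
    int64_t k = pos_key(x + DX[n], y + DY[n], z + DZ[n]);
    if (W.empty_at(k)) empties.push_back(k);
  }
  int64_t target;
  if (!empties.empty()) {
    target = empties[(size_t)(unif_rand() * empties.size()) % empties.size()];
  } else {
    int dir = (int)(unif_rand() * 6) % 6;
    int step = 1;
    while (true) {
      int64_t k = pos_key(x + DX[dir] * step, y + DY[dir] * step, z + DZ[dir] * step);
      if (W.empty_at(k)) { target = k; break; }
      ++step;
      if (step > (1 << 19)) stop("deme split walked off the lattice");
    }
  }
  int nd = W.add_deme(target);
  Deme& dn = W.demes[nd];
  Deme& ds = W.demes[di]; // re-reference: add_deme may reallocate
  int64_t moved_tot = 0;
  for (auto& e : ds.cnt) {
    int moved = (int)R::rbinom((double)e.second, 0.5);
    if (moved > 0) {
      dn.cnt.push_back(std::make_pair(e.first, moved));
      e.second -= moved;
      moved_tot += moved;
    }
  }
  dn.total = moved_tot;
  ds.total -= moved_tot;
  if (ds.total == 0) { ds.alive = false; W.pos2idx.erase(W.keys[di]); }
  if (dn.total == 0) { dn.alive = false; W.pos2idx.erase(target); }
}

std::vector<int> surface_demes(const World& W) {
  std::vector<int> out;
  for (size_t i = 0; i < W.demes.size(); ++i) {
    if (!W.demes[i].alive) continue;
    int x, y, z;
    key_pos(W.keys[i], x, y, z);
    for (int n = 0; n < 6; ++n) {
      if (W.empty_at(pos_key(x + DX[n], y + DY[n], z + DZ[n]))) {
        out.push_back((int)i);
        break;
      }
    }
  }
  return out;
}

// sample n cells without replacement from a deme and remove them (founder
// cells are taken out of the primary tumour)
std::vector<int> take_cells(World& W, int di, int n) {
  Deme& d = W.demes[di];
  std::vector<int> out;
  if ((int64_t)n > d.total) n = (int)d.total;
  int64_t remaining = d.total;
  int need = n;
  for (auto& e : d.cnt) {
    if (need == 0) break;
    int take = (int)R::rhyper((double)e.second, (double)(remaining - e.second), (double)need);
    for (int i = 0; i < take; ++i) out.push_back(e.first);
    need -= take;
    remaining -= e.second;
    e.second -= take;
  }
  int64_t taken = (int64_t)out.size();
  d.total -= taken;
  W.total_cells -= taken;
  if (d.total == 0) { d.alive = false; W.pos2idx.erase(W.keys[di]); }
  return out;
}

// sample n cells without replacement from (genotype,count) pools
std::vector<int> sample_cells(const std::vector<std::pair<int, int>>& pool, int n) {
  int64_t N = 0;
  for (auto& e : pool) N += e.second;
  if (n > N) n = (int)N;
  std::vector<int> out;
  int64_t remaining = N;
  int need = n;
  for (auto& e : pool) {
    if (need == 0) break;
    int take = (int)R::rhyper((double)e.second, (double)(remaining - e.second), (double)need);
    for (int i = 0; i < take; ++i) out.push_back(e.first);
    need -= take;
    remaining -= e.second;
  }
  return out;
}

// grow a tumour from the given founder cells until final_size; returns false
// on extinction
bool grow(World& W, Genotypes& G, const Params& P, const std::vector<int>& founders,
          int& next_mut, std::vector<double>& size_history,
          double snapshot_size, std::vector<int>* snapshot_founders,
          int snap_n_cells, int snap_n_regions) {
  W.pos2idx.clear(); W.keys.clear(); W.demes.clear(); W.total_cells = 0;
  int d0 = W.add_deme(pos_key(0, 0, 0));
  std::map<int, int> fc; // ordered so the RNG stream is reproducible
  for (int g : founders) fc[g]++;
  for (auto& e : fc) W.demes[d0].cnt.push_back(e);
  W.demes[d0].total = (int64_t)founders.size();
  W.total_cells = (int64_t)founders.size();
  bool snapped = snapshot_size <= 0.0;

  int sweep = 0;
  while (W.total_cells < (int64_t)P.final_size) {
    ++sweep;
    size_t ndemes = W.demes.size();
    for (size_t i = 0; i < ndemes; ++i) sweep_deme(W, (int)i, G, P, next_mut);
    for (size_t i = 0; i < W.demes.size(); ++i) split_deme(W, (int)i, P);
    size_history.push_back((double)W.total_cells);
    if (W.total_cells == 0) return false;
    if (!snapped && (double)W.total_cells >= snapshot_size) {
      snapped = true;
      std::vector<int> surf = surface_demes(W);
      // founder cells drawn from the surface of distinct source localities
      int nsrc = std::min((size_t)snap_n_regions, surf.size());
      for (int j = (int)surf.size() - 1; j > 0; --j) {
        int k = (int)(unif_rand() * (j + 1)) % (j + 1);
        std::swap(surf[j], surf[k]);
      }
      for (int r = 0; r < nsrc; ++r) {
        int want = snap_n_cells / nsrc + (r < snap_n_cells % nsrc ? 1 : 0);
        std::vector<int> cells = take_cells(W, surf[r], want);
        snapshot_founders->insert(snapshot_founders->end(), cells.begin(), cells.end());
      }
      if (W.total_cells == 0) return false; // the seeding emptied the primary
    }
    if (sweep % 16 == 0) Rcpp::checkUserInterrupt();
    if (sweep > 2000000) stop("growth did not terminate");
  }
  return true;
}

// spatially contiguous disjoint regions of ~region_cells cells each
std::vector<std::vector<std::pair<int, int>>>
sample_regions_impl(World& W, int n_regions, int64_t region_cells) {
  if (W.total_cells < (int64_t)n_regions * region_cells)
    stop("tumour smaller than n_regions * region_cells");
  std::vector<int> surf = surface_demes(W);
  for (int j = (int)surf.size() - 1; j > 0; --j) {
    int k = (int)(unif_rand() * (j + 1)) % (j + 1);
    std::swap(surf[j], surf[k]);
  }
  std::vector<bool> claimed(W.demes.size(), false);
  std::vector<std::vector<std::pair<int, int>>> regions;
  size_t next_seed = 0;
  for (int r = 0; r < n_regions; ++r) {
    // seed: next unclaimed surface deme (or any unclaimed deme)
    int seed = -1;
    while (next_seed < surf.size()) {
      if (!claimed[surf[next_seed]]) { seed = surf[next_seed]; break; }
      ++next_seed;
    }
    if (seed < 0) {
      for (size_t i = 0; i < W.demes.size(); ++i)
        if (W.demes[i].alive && !claimed[i]) { seed = (int)i; break; }
    }
    if (seed < 0) stop("no unclaimed demes left for region sampling");

    std::vector<std::pair<int, int>> bulk;
    int64_t acc = 0;
    std::queue<int> q;
    q.push(seed);
    claimed[seed] = true;
    int sx, sy, sz;
    key_pos(W.keys[seed], sx, sy, sz);
    while (acc < region_cells) {
      int cur = -1;
      if (!q.empty()) {
        cur = q.front(); q.pop();
      } else {
        // frontier exhausted: continue from the nearest unclaimed deme
        int64_t best = -1;
        for (size_t i = 0; i < W.demes.size(); ++i) {
          if (!W.demes[i].alive || claimed[i]) continue;
          int x, y, z;
          key_pos(W.keys[i], x, y, z);
          int64_t dist = (int64_t)std::abs(x - sx) + std::abs(y - sy) + std::abs(z - sz);
          if (best < 0 || dist < best) { best = dist; cur = (int)i; }
        }
        if (cur < 0) break;
        claimed[cur] = true;
      }
      Deme& d = W.demes[cur];
      if (d.alive && d.total > 0) {
        if (acc + d.total <= region_cells) {
          for (auto& e : d.cnt) bulk.push_back(e);
          acc += d.total;
        } else {
          // partial deme: without-replacement subsample to hit the target
          int need = (int)(region_cells - acc);
          std::vector<int> cells = sample_cells(d.cnt, need);
          std::unordered_map<int, int> cc;
          for (int g : cells) cc[g]++;
          for (auto& e : cc) bulk.push_back(e);
          acc = region_cells;
        }
      }
      int x, y, z;
      key_pos(W.keys[cur], x, y, z);
      for (int n = 0; n < 6; ++n) {
        auto it = W.pos2idx.find(pos_key(x + DX[n], y + DY[n], z + DZ[n]));
        if (it != W.pos2idx.end() && !claimed[it->second]) {
          claimed[it->second] = true;
          q.push(it->second);
        }
      }
    }
    regions.push_back(bulk);
  }
  return regions;
}

// per-region carrier counts by ancestry accumulation, reported above a
// carrier-fraction floor
List region_tables(const std::vector<std::vector<std::pair<int, int>>>& regions,
                   const Genotypes& G, double min_frac,
                   std::unordered_set<int>& reported_union) {
  List out(regions.size());
  for (size_t r = 0; r < regions.size(); ++r) {
    std::unordered_map<int, int64_t> carriers;
    int64_t total = 0;
    std::unordered_map<int, int64_t> gcount;
    for (auto& e : regions[r]) { gcount[e.first] += e.second; total += e.second; }
    for (auto& e : gcount) {
      int g = e.first;
      while (g >= 0) {
        int64_t off = G.mut_off[g];
        for (int m = 0; m < G.mut_n[g]; ++m) carriers[G.muts[off + m]] += e.second;
        g = G.parent[g];
      }
    }
    int64_t floor_cells = (int64_t)std::ceil(min_frac * (double)total);
    std::vector<std::pair<int, int64_t>> keep;
    for (auto& e : carriers)
      if (e.second >= floor_cells) keep.push_back(e);
    std::sort(keep.begin(), keep.end());
    IntegerVector mid(keep.size());
    NumericVector car(keep.size());
    for (size_t i = 0; i < keep.size(); ++i) {
      mid[i] = keep[i].first;
      car[i] = (double)keep[i].second;
      reported_union.insert(keep[i].first);
    }
    out[r] = List::create(_["mutation_id"] = mid, _["carriers"] = car,
                          _["n_cells"] = (double)total);
  }
  return out;
}

Params read_params(List cfg) {
  Params P;
  P.deme_capacity = as<int>(cfg["deme_capacity"]);
  P.final_size = as<double>(cfg["final_size"]);
  P.death_rate = as<double>(cfg["death_rate"]);
  P.mutation_rate = as<double>(cfg["mutation_rate"]);
  P.s = as<double>(cfg["s"]);
  P.driver_prob = as<double>(cfg["driver_prob"]);
  P.driver_mult = as<double>(cfg["driver_mult"]);
  P.event_prob = as<double>(cfg["event_prob"]);
  P.min_report_frac = as<double>(cfg["min_report_frac"]);
  P.founder_mutations = as<int>(cfg["founder_mutations"]);
  return P;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_dfe_draws")]]
NumericVector cpp_dfe_draws(int n, double s, std::string kind,
                            double driver_prob = 0.0, double driver_mult = 10.0) {
  Params P;
  P.s = s; P.driver_prob = driver_prob; P.driver_mult = driver_mult;
  NumericVector out(n);
  bool is_event = (kind == "event");
  for (int i = 0; i < n; ++i) {
    if (is_event) {
      out[i] = event_effect(P);
    } else {
      bool drv = false;
      out[i] = mutation_effect(P, drv);
    }
  }
  return out;
}

// [[Rcpp::export(name = "cpp_simulate")]]
List cpp_simulate(List cfg) {
  Params P = read_params(cfg);
  int n_regions = as<int>(cfg["n_regions"]);
  double region_cells = as<double>(cfg["region_cells"]);
  double divergence_size = as<double>(cfg["divergence_size"]);
  int met_n_cells = as<int>(cfg["met_n_cells"]);
  int met_n_source_regions = as<int>(cfg["met_n_source_regions"]);
  int max_attempts = as<int>(cfg["max_attempts"]);

  // the founder cell carries the truncal mutations of tumour initiation
  std::vector<int> truncal(P.founder_mutations);
  for (int i = 0; i < P.founder_mutations; ++i) truncal[i] = i;

  Genotypes G;
  G.add(-1, 1.0, false, truncal);
  int next_mut = P.founder_mutations;

  World W;
  std::vector<double> size_history;
  std::vector<int> met_founders;
  std::vector<int> founder(1, 0);

  bool want_met = divergence_size > 0.0;
  double snap = want_met ? std::min(divergence_size, P.final_size) : 0.0;

  int attempts = 0;
  bool ok = false;
  while (attempts < max_attempts && !ok) {
    ++attempts;
    size_history.clear();
    met_founders.clear();
    // reset registry between attempts so failed runs leave no genotypes
    G = Genotypes();
    G.add(-1, 1.0, false, truncal);
    next_mut = P.founder_mutations;
    ok = grow(W, G, P, founder, next_mut, size_history, snap,
              &met_founders, met_n_cells, met_n_source_regions);
  }
  if (!ok) stop("primary tumour went extinct in every attempt");
  if (want_met && met_founders.empty() && (double)W.total_cells >= snap) {
    // divergence size above final size: seed from the final tumour surface
    std::vector<int> surf = surface_demes(W);
    int nsrc = std::min((size_t)met_n_source_regions, surf.size());
    for (int r = 0; r < nsrc; ++r) {
      int want = met_n_cells / nsrc + (r < met_n_cells % nsrc ? 1 : 0);
      std::vector<int> cells = take_cells(W, surf[r], want);
      met_founders.insert(met_founders.end(), cells.begin(), cells.end());
    }
  }

  std::unordered_set<int> reported;
  auto prim_regions = sample_regions_impl(W, n_regions, (int64_t)region_cells);
  List prim_tabs = region_tables(prim_regions, G, P.min_report_frac, reported);
  double primary_cells = (double)W.total_cells;

  List met_tabs = List(0);
  double met_cells = 0.0;
  int met_attempts = 0;
  if (want_met) {
    Params MP = P;
    MP.final_size = as<double>(cfg["met_final_size"]);
    MP.s = as<double>(cfg["met_s"]);
    int met_regions_n = as<int>(cfg["met_n_regions"]);
    double met_region_cells = as<double>(cfg["met_region_cells"]);
    World WM;
    std::vector<double> hist2;
    bool mok = false;
    while (met_attempts < max_attempts && !mok) {
      ++met_attempts;
      hist2.clear();
      mok = grow(WM, G, MP, met_founders, next_mut, hist2, 0.0, nullptr, 0, 0);
    }
    if (!mok) stop("metastasis went extinct in every attempt");
    auto met_regions = sample_regions_impl(WM, met_regions_n, (int64_t)met_region_cells);
    met_tabs = region_tables(met_regions, G, P.min_report_frac, reported);
    met_cells = (double)WM.total_cells;
  }

  // lineage bookkeeping for reported mutations: origin genotype per mutation
  // and, per origin genotype, the nearest ancestor that is itself an origin
  std::vector<int> rep(reported.begin(), reported.end());
  std::sort(rep.begin(), rep.end());
  IntegerVector mut_id(rep.size()), mut_origin(rep.size());
  std::unordered_set<int> origin_set;
  for (size_t i = 0; i < rep.size(); ++i) {
    mut_id[i] = rep[i];
    mut_origin[i] = G.mut_origin[rep[i]];
    origin_set.insert(G.mut_origin[rep[i]]);
  }
  std::vector<int> origins(origin_set.begin(), origin_set.end());
  std::sort(origins.begin(), origins.end());
  IntegerVector og(origins.size()), og_parent(origins.size());
  for (size_t i = 0; i < origins.size(); ++i) {
    og[i] = origins[i];
    int p = G.parent[origins[i]];
    while (p >= 0 && origin_set.find(p) == origin_set.end()) p = G.parent[p];
    og_parent[i] = p;
  }

  // founder genotype multiset of the metastasis
  IntegerVector fo(met_founders.size());
  for (size_t i = 0; i < met_founders.size(); ++i) fo[i] = met_founders[i];

  return List::create(
    _["primary_regions"] = prim_tabs,
    _["met_regions"] = met_tabs,
    _["mutations"] = DataFrame::create(_["mutation_id"] = mut_id,
                                       _["origin_genotype"] = mut_origin),
    _["genotype_edges"] = DataFrame::create(_["genotype_id"] = og,
                                            _["parent_genotype"] = og_parent),
    _["met_founders"] = fo,
    _["n_cells_primary"] = primary_cells,
    _["n_cells_met"] = met_cells,
    _["n_genotypes"] = (double)G.parent.size(),
    _["n_mutations"] = (double)next_mut,
    _["attempts_primary"] = attempts,
    _["attempts_met"] = met_attempts,
    _["n_sweeps"] = (double)size_history.size(),
    _["size_history"] = NumericVector(size_history.begin(), size_history.end())
  );
}
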