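#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Lattice conventions shared by the simulator:
//   site index = x + sx * (y + sy * z), 0-based; sz == 1 for 2-D.
//   occupancy codes: 0 empty, 1 wild-type, 2 mutant.
//   Neighbourhood is von Neumann (4 in 2-D, 6 in 3-D).

static inline int nbrs(int site, int sx, int sy, int sz, int* nb) {
  int x = site % sx, r = site / sx, y = r % sy, z = r / sy;
  int k = 0;
  if (x > 0)      nb[k++] = site - 1;
  if (x < sx - 1) nb[k++] = site + 1;
  if (y > 0)      nb[k++] = site - sx;
  if (y < sy - 1) nb[k++] = site + sx;
  if (sz > 1) {
    if (z > 0)      nb[k++] = site - sx * sy;
    if (z < sz - 1) nb[k++] = site + sx * sy;
  }
  return k;
}

static inline bool on_boundary(int site, int sx, int sy, int sz) {
  int x = site % sx, r = site / sx, y = r % sy, z = r / sy;
  if (x == 0 || x == sx - 1 || y == 0 || y == sy - 1) return true;
  if (sz > 1 && (z == 0 || z == sz - 1)) return true;
  return false;
}

// uniform integer in [0, n), driven by R's RNG
static inline int iunif(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Scratch space for the breadth-first push-path search.  Timestamped visit
// marks avoid clearing O(lattice) arrays on every division attempt.
struct PushScratch {
  std::vector<int> vid, vdist;
  std::vector<int> frontier, next, terminals;
  int counter;
  PushScratch() : counter(0) {}
  void ensure(size_t n) {
    if (vid.size() != n) { vid.assign(n, 0); vdist.assign(n, 0); counter = 0; }
  }
};

// Find a push chain for the dividing cell: the shortest sequence of <= q
// occupied sites ending adjacent to an empty site.  Chain length counts
// pushed cells, so length 0 means the divider itself touches an empty site.
// Among minimum-length chains, straight-line chains (all steps along one
// lattice direction) take strict priority; remaining ties are broken at
// random.  Fills `chain` (ordered from the divider outwards, divider
// excluded) and `empty_site`; returns false when no chain of length <= q
// exists.
static bool find_push(const std::vector<int>& occ, int sx, int sy, int sz,
                      int cell, int q, PushScratch& S,
                      std::vector<int>& chain, int& empty_site) {
  int nb[6], cand[6];
  chain.clear();
  S.ensure(occ.size());

  int k = nbrs(cell, sx, sy, sz, nb);
  int nempty = 0;
  for (int i = 0; i < k; ++i) if (occ[nb[i]] == 0) cand[nempty++] = nb[i];
  if (nempty > 0) { empty_site = cand[iunif(nempty)]; return true; }
  if (q <= 0) return false;

  // straight-line candidates: walk each lattice direction until the first
  // empty site or the q+1 limit
  int x = cell % sx, r = cell / sx, y = r % sy, z = r / sy;
  int offs[6], room[6], ndir = 0;
  offs[ndir] = -1;       room[ndir++] = x;
  offs[ndir] = +1;       room[ndir++] = sx - 1 - x;
  offs[ndir] = -sx;      room[ndir++] = y;
  offs[ndir] = +sx;      room[ndir++] = sy - 1 - y;
  if (sz > 1) {
    offs[ndir] = -sx * sy; room[ndir++] = z;
    offs[ndir] = +sx * sy; room[ndir++] = sz - 1 - z;
  }
  int best_straight = q + 1;  // sentinel: no straight chain found yet
  int sdir[6], nsd = 0;
  for (int d = 0; d < ndir; ++d) {
    int tmax = std::min(q + 1, room[d]);
    for (int t = 1; t <= tmax; ++t) {
      if (occ[cell + t * offs[d]] == 0) {
        int len = t - 1;
        if (len < best_straight) { best_straight = len; nsd = 0; }
        if (len == best_straight) sdir[nsd++] = d;
        break;
      }
    }
  }

  // breadth-first search over occupied sites for the minimal chain length
  int id = ++S.counter;
  S.frontier.clear(); S.terminals.clear();
  S.vid[cell] = id; S.vdist[cell] = 0;
  S.frontier.push_back(cell);
  int depth = 0, dmin = -1;
  while (!S.frontier.empty() && depth < q && dmin < 0) {
    ++depth;
    S.next.clear();
    for (size_t f = 0; f < S.frontier.size(); ++f) {
      int kk = nbrs(S.frontier[f], sx, sy, sz, nb);
      for (int i = 0; i < kk; ++i) {
        int s2 = nb[i];
        if (occ[s2] != 0 && S.vid[s2] != id) {
          S.vid[s2] = id; S.vdist[s2] = depth;
          S.next.push_back(s2);
        }
      }
    }
    for (size_t f = 0; f < S.next.size(); ++f) {
      int s2 = S.next[f];
      int kk = nbrs(s2, sx, sy, sz, nb);
      for (int i = 0; i < kk; ++i)
        if (occ[nb[i]] == 0) { S.terminals.push_back(s2); break; }
    }
    if (!S.terminals.empty()) dmin = depth;
    S.frontier.swap(S.next);
  }
  if (dmin < 0) return false;

  if (best_straight == dmin) {
    int d = sdir[iunif(nsd)];
    for (int t = 1; t <= dmin; ++t) chain.push_back(cell + t * offs[d]);
    empty_site = cell + (dmin + 1) * offs[d];
    return true;
  }

  // random minimal chain: uniform terminal, then backtrack through uniformly
  // chosen minimal predecessors
  int term = S.terminals[iunif((int)S.terminals.size())];
  int kk = nbrs(term, sx, sy, sz, nb);
  int ne = 0;
  for (int i = 0; i < kk; ++i) if (occ[nb[i]] == 0) cand[ne++] = nb[i];
  empty_site = cand[iunif(ne)];
  chain.assign(dmin, 0);
  int cur = term;
  for (int dd = dmin; dd >= 1; --dd) {
    chain[dd - 1] = cur;
    if (dd == 1) break;
    int kk2 = nbrs(cur, sx, sy, sz, nb);
    int np = 0;
    for (int i = 0; i < kk2; ++i) {
      int s2 = nb[i];
      if (S.vid[s2] == id && S.vdist[s2] == dd - 1) cand[np++] = s2;
    }
    cur = cand[iunif(np)];
  }
  return true;
}

// Occupied-cell bookkeeping: `cellsv` lists occupied sites, `where` maps a
// site to its position in `cellsv` (-1 when empty), enabling O(1) uniform
// selection, moves and swap-pop removals.
struct Pop {
  std::vector<int> occ, where, cellsv;
  int sx, sy, sz;
  bool boundary_hit;
  Pop(int sx_, int sy_, int sz_)
      : occ((size_t)sx_ * sy_ * sz_, 0), where((size_t)sx_ * sy_ * sz_, -1),
        sx(sx_), sy(sy_), sz(sz_), boundary_hit(false) {}
  void add(int s, int g) {
    if (on_boundary(s, sx, sy, sz)) boundary_hit = true;
    occ[s] = g; where[s] = (int)cellsv.size(); cellsv.push_back(s);
  }
  void move(int a, int b) {
    if (on_boundary(b, sx, sy, sz)) boundary_hit = true;
    int i = where[a];
    cellsv[i] = b; where[b] = i; where[a] = -1;
    occ[b] = occ[a]; occ[a] = 0;
  }
  void remove(int s) {
    int i = where[s], last = cellsv.back();
    cellsv[i] = last; where[last] = i;
    cellsv.pop_back(); where[s] = -1; occ[s] = 0;
  }
};

// Execute one division attempt: find a push chain, displace its cells one
// step toward the empty terminus, and place a daughter of the divider's
// genotype in the freed adjacent site.  Returns false (state unchanged) when
// no chain of length <= q exists.
static bool attempt_division_impl(Pop& P, int cell, int q, PushScratch& S,
                                  std::vector<int>& chain, int* daughter_site) {
  int empty_site;
  if (!find_push(P.occ, P.sx, P.sy, P.sz, cell, q, S, chain, empty_site))
    return false;
  int g = P.occ[cell];
  int d = (int)chain.size();
  int freed = empty_site;
  if (d > 0) {
    P.move(chain[d - 1], empty_site);
    for (int i = d - 1; i >= 1; --i) P.move(chain[i - 1], chain[i]);
    freed = chain[0];
  }
  P.add(freed, g);
  if (daughter_site) *daughter_site = freed;
  return true;
}

// [[Rcpp::export]]
List sim_tumour_cpp(int sx, int sy, int sz, double s, double psi,
                    int n_intro, int nmax, int q, double max_events) {
  Pop P(sx, sy, sz);
  PushScratch S;
  std::vector<int> chain;
  chain.reserve(q + 1);

  int cx = sx / 2, cy = sy / 2, cz = (sz > 1) ? sz / 2 : 0;
  P.add(cx + sx * (cy + sy * cz), 1);

  int nwt = 1, nmut = 0;
  bool mutated = false;
  int pop_at_mut = NA_INTEGER;
  double fires = 0, deaths = 0, failed = 0;
  double fires_wt = 0, fires_mut = 0;
  double wexpo_wt = 0, wexpo_mut = 0;
  const double bmut = 1.0 + s;
  int status = 0;  // 0 ok, 1 extinct, 2 mutant extinct, 3 stalled, 4 boundary

  // immediate introduction when the threshold equals the founder population
  if (!mutated && nwt + nmut >= n_intro) {
    int idx = iunif(nwt);
    P.occ[P.cellsv[idx]] = 2;
    nwt--; nmut++;
    mutated = true;
    pop_at_mut = nwt + nmut;
  }

  long long guard = 0;
  while (nwt + nmut < nmax) {
    int N = nwt + nmut;
    if (N == 0) { status = 1; break; }
    if (mutated && nmut == 0) { status = 2; break; }
    if (++guard % 4096 == 0) Rcpp::checkUserInterrupt();
    if (fires > max_events) { status = 3; break; }

    int site = P.cellsv[iunif(N)];
    int g = P.occ[site];
    if (s > 0.0 && g == 1 && unif_rand() * bmut >= 1.0) continue;  // rejection step

    // a firing event: the cell either dies or attempts a division
    fires += 1;
    double W = nwt + bmut * nmut;
    wexpo_wt += nwt / W;
    wexpo_mut += nmut / W;
    if (g == 2) fires_mut += 1; else fires_wt += 1;

    if (psi > 0.0 && unif_rand() < psi) {
      deaths += 1;
      P.remove(site);
      if (g == 2) nmut--; else nwt--;
    } else {
      if (attempt_division_impl(P, site, q, S, chain, (int*)0)) {
        if (g == 2) nmut++; else nwt++;
      } else {
        failed += 1;
      }
    }
    if (P.boundary_hit) { status = 4; break; }

    if (!mutated && nwt + nmut == n_intro) {
      int idx;
      do { idx = iunif(nwt + nmut); } while (P.occ[P.cellsv[idx]] != 1);
      P.occ[P.cellsv[idx]] = 2;
      nwt--; nmut++;
      mutated = true;
      pop_at_mut = nwt + nmut;
    }
  }

  IntegerVector occ_out(P.occ.begin(), P.occ.end());
  return List::create(
      _["status"] = status, _["occ"] = occ_out,
      _["n_wt"] = nwt, _["n_mut"] = nmut,
      _["pop_at_mutation"] = pop_at_mut,
      _["fires"] = fires, _["deaths"] = deaths, _["failed"] = failed,
      _["fires_wt"] = fires_wt, _["fires_mut"] = fires_mut,
      _["wexpo_wt"] = wexpo_wt, _["wexpo_mut"] = wexpo_mut);
}

// [[Rcpp::export]]
List choose_push_path_cpp(IntegerVector occ, int sx, int sy, int sz,
                          int cell0, int q) {
  std::vector<int> o(occ.begin(), occ.end());
  PushScratch S;
  std::vector<int> chain;
  int empty_site = -1;
  bool found = find_push(o, sx, sy, sz, cell0, q, S, chain, empty_site);
  return List::create(_["found"] = found,
                      _["chain"] = IntegerVector(chain.begin(), chain.end()),
                      _["empty_site"] = empty_site);
}

// [[Rcpp::export]]
List attempt_division_cpp(IntegerVector occ, int sx, int sy, int sz,
                          int cell0, int q) {
  Pop P(sx, sy, sz);
  for (int i = 0; i < occ.size(); ++i) if (occ[i] != 0) P.add(i, occ[i]);
  P.boundary_hit = false;  // pre-existing cells may legitimately sit anywhere
  PushScratch S;
  std::vector<int> chain;
  int daughter = -1;
  bool ok = attempt_division_impl(P, cell0, q, S, chain, &daughter);
  return List::create(_["success"] = ok,
                      _["occ"] = IntegerVector(P.occ.begin(), P.occ.end()),
                      _["daughter_site"] = daughter,
                      _["chain"] = IntegerVector(chain.begin(), chain.end()));
}
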