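// Cellular Potts kernel: membrane-ring kinetics, protrusion field,
// Metropolis sweeps. Mirrors the exported R reference operations; the R
// versions are the readable spec, this is the fast path for whole runs.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xorshift64* generator: seeded determinism independent of R's RNG
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n); }
};

struct Params {
  double n, L_rho, L_R, L_K, I_R, I_rho, I_K, delta_R, delta_rho, delta_P;
  double gamma, alpha_P, alpha_R, k_X, k_G, k_C, GIT, PIX, Pax_tot;
  double eps, eps_L, eps_B, eta, B_r, gamma_R, gamma_K, D_R, D_Ri;
};

Params readParams(const List& p) {
  Params q;
  q.n = p["n"]; q.L_rho = p["L_rho"]; q.L_R = p["L_R"]; q.L_K = p["L_K"];
  q.I_R = p["I_R"]; q.I_rho = p["I_rho"]; q.I_K = p["I_K"];
  q.delta_R = p["delta_R"]; q.delta_rho = p["delta_rho"]; q.delta_P = p["delta_P"];
  q.gamma = p["gamma"]; q.alpha_P = p["alpha_P"]; q.alpha_R = p["alpha_R"];
  q.k_X = p["k_X"]; q.k_G = p["k_G"]; q.k_C = p["k_C"];
  q.GIT = p["GIT"]; q.PIX = p["PIX"]; q.Pax_tot = p["Pax_tot"];
  q.eps = p["eps"]; q.eps_L = p["eps_L"]; q.eps_B = p["eps_B"]; q.eta = p["eta"];
  q.B_r = p["B_r"]; q.gamma_R = p["gamma_R"]; q.gamma_K = p["gamma_K"];
  q.D_R = p["D_R"]; q.D_Ri = p["D_Ri"];
  return q;
}

inline double Kfun(double R, const Params& p) {
  return p.alpha_R * R / ((1 + p.k_X * p.PIX) * (1 + p.alpha_R * R) +
    p.k_G * p.k_X * p.GIT * p.PIX / (1 + p.k_X * p.PIX + 3.0 / (1 + R)));
}

// 4V reaction derivatives at one ring site
inline void react4v(double R, double Ri, double B, double kB, const Params& p,
                    double& dR, double& dB, double& dkB) {
  double K = Kfun(R, p);
  double rho = p.I_rho * std::pow(p.L_R, p.n) /
    (p.I_rho * std::pow(p.L_R, p.n) +
     p.delta_rho * (std::pow(p.L_R, p.n) + std::pow(R + p.gamma * K, p.n)));
  double h = std::pow(K, p.n) / (std::pow(p.L_K, p.n) + std::pow(K, p.n));
  double P = B * h / (p.alpha_P * B * h + p.delta_P);
  double Iks = p.I_K * (1 - 1 / (1.5 + p.k_X * p.PIX +
    p.k_G * p.k_X * p.k_C * p.GIT * p.PIX * p.Pax_tot * P));
  double gate = std::pow(p.L_rho, p.n) /
    (std::pow(p.L_rho, p.n) + std::pow(rho, p.n));
  dR = (p.I_R + Iks) * gate * Ri - p.delta_R * R;
  dB = p.eps * (1 - p.gamma_R * R - kB * (B - p.B_r) +
                1 / (p.eta * (B + p.eps_B)));
  dkB = p.eps_L * (p.gamma_K - R);
}

struct Lattice {
  int W, H;
  std::vector<int> lab;  // column-major like R: idx = i + W*j
  int area;
  int perim;  // cell-medium 4-edges
  bool periodic;
  inline int wi(int i) const { return (i % W + W) % W; }
  inline int wj(int j) const { return (j % H + H) % H; }
  int at(int i, int j) const {
    if (periodic) return lab[wi(i) + W * wj(j)];
    if (i < 0 || i >= W || j < 0 || j >= H) return 0;
    return lab[i + W * j];
  }
  void recount() {
    area = 0; perim = 0;
    for (int j = 0; j < H; ++j) for (int i = 0; i < W; ++i) {
      if (at(i, j) > 0) {
        ++area;
        if (at(i - 1, j) == 0) ++perim;
        if (at(i + 1, j) == 0) ++perim;
        if (at(i, j - 1) == 0) ++perim;
        if (at(i, j + 1) == 0) ++perim;
      }
    }
  }
};

// solve (I - a*Lap) x = d on a periodic ring (backward-Euler diffusion)
// via the Sherman-Morrison cyclic tridiagonal reduction; overwrites d
void cyclicDiffuse(std::vector<double>& d, double a, size_t m,
                   std::vector<double>& c1, std::vector<double>& c2,
                   std::vector<double>& x1, std::vector<double>& x2) {
  if (a <= 0 || m < 3) return;
  // tridiagonal system: diag b0 = 1 + 2a, off-diagonals -a, with periodic
  // corner entries -a folded in by rank-one correction
  double b0 = 1 + 2 * a;
  double alpha = -a;  // corner value
  double gamma = -b0; // Sherman-Morrison gauge
  c1.resize(m); c2.resize(m); x1.resize(m); x2.resize(m);
  // modified diagonal
  for (size_t i = 0; i < m; ++i) c1[i] = b0;
  c1[0] = b0 - gamma;
  c1[m - 1] = b0 - alpha * alpha / gamma;
  // u vector: (gamma, 0, ..., 0, alpha)
  for (size_t i = 0; i < m; ++i) { x2[i] = 0; }
  x2[0] = gamma; x2[m - 1] = alpha;
  // Thomas solve for two right-hand sides (d and u), off-diagonal -a
  // forward sweep
  c2[0] = -a / c1[0];
  double d0 = d[0] / c1[0], u0 = x2[0] / c1[0];
  x1[0] = d0; std::vector<double>& usol = x2;
  double uprev = u0; usol[0] = u0;
  for (size_t i = 1; i < m; ++i) {
    double denom = c1[i] + a * c2[i - 1];
    c2[i] = -a / denom;
    x1[i] = (d[i] + a * x1[i - 1]) / denom;
    usol[i] = ((i == m - 1 ? alpha : 0.0) + a * usol[i - 1]) / denom;
  }
  (void)uprev;
  for (size_t i = m - 1; i-- > 0; ) {
    x1[i] -= c2[i] * x1[i + 1];
    usol[i] -= c2[i] * usol[i + 1];
  }
  double fact = (x1[0] + x1[m - 1] * alpha / gamma) /
                (1 + usol[0] + usol[m - 1] * alpha / gamma);
  for (size_t i = 0; i < m; ++i) d[i] = x1[i] - fact * usol[i];
}

inline double wrapDiff(double a, double b, int W) {
  double d = a - b;
  d -= W * std::floor(d / W + 0.5);
  return d;
}

const int DX8[8] = {0, -1, -1, -1, 0, 1, 1, 1};
const int DY8[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
const int DX4[4] = {1, -1, 0, 0};
const int DY4[4] = {0, 0, 1, -1};

// membrane test: cell site with a Moore-neighbour that is medium
inline bool isMembrane(const Lattice& L, int i, int j) {
  if (L.at(i, j) == 0) return false;
  for (int k = 0; k < 8; ++k)
    if (L.at(i + DX8[k], j + DY8[k]) == 0) return true;
  return false;
}

struct Stamp {
  std::vector<int> v;
  int cur;
  Stamp() : cur(0) {}
  void ensure(size_t n) { if (v.size() < n) v.assign(n, 0); }
  void fresh(size_t n) { ensure(n); ++cur; }
  bool test(int i) const { return v[i] == cur; }
  void set(int i) { v[i] = cur; }
};

// Moore-neighbour boundary trace; returns membrane sites in contour order
// (first occurrences). Mirrors boundary_walk() in R.
std::vector<std::pair<int,int> > walkBoundary(const Lattice& L, Stamp* ws = 0) {
  // start: first (column-major) cell site with a medium 4-neighbour; the
  // backtrack is its first medium neighbour in N, W, S, E order, so that a
  // cell away from the lattice edge traces identically to the R reference
  // (whose start always has a medium site to the north)
  int si = -1, sj = -1, bi = 0, bj = 0;
  for (int j = 0; j < L.H && si < 0; ++j) {
    for (int i = 0; i < L.W; ++i) {
      if (L.lab[i + L.W * j] > 0) {
        if (L.at(i - 1, j) == 0) { si = i; sj = j; bi = i - 1; bj = j; break; }
        if (L.at(i, j - 1) == 0) { si = i; sj = j; bi = i; bj = j - 1; break; }
        if (L.at(i + 1, j) == 0) { si = i; sj = j; bi = i + 1; bj = j; break; }
        if (L.at(i, j + 1) == 0) { si = i; sj = j; bi = i; bj = j + 1; break; }
      }
    }
  }
  std::vector<std::pair<int,int> > path;
  if (si < 0) {
    // no membrane at all (cell fills the torus) or empty lattice
    for (int j = 0; j < L.H && path.empty(); ++j)
      for (int i = 0; i < L.W; ++i)
        if (L.lab[i + L.W * j] > 0) { path.push_back(std::make_pair(i, j)); break; }
    if (L.area <= 1) return path;
    return std::vector<std::pair<int,int> >();
  }
  if (L.area == 1) { path.push_back(std::make_pair(si, sj)); return path; }
  // Moore moves in cyclic order (W, NW, N, NE, E, SE, S, SW), matching the
  // R reference; trace with backtrack bookkeeping (Jacob's criterion)
  const int MI[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int MJ[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  int ci = si, cj = sj;
  Stamp local;
  Stamp* seen = ws ? ws : &local;
  // states are (site, backtrack direction); the trace stops as soon as a
  // state recurs, which is robust even when the orbit never returns to the
  // exact initial state (rho-shaped orbits on pathological shapes)
  seen->fresh((size_t)L.W * L.H * 8);
  std::vector<std::pair<int,int> > order;
  std::vector<char> onPath(L.W * L.H, 0);
  long guard = 16L * L.W * L.H;
  while (guard-- > 0) {
    if (!onPath[ci + L.W * cj]) {
      onPath[ci + L.W * cj] = 1;
      order.push_back(std::make_pair(ci, cj));
    }
    int kb = -1;
    for (int k = 0; k < 8; ++k)
      if (L.wi(ci + MI[k]) == L.wi(bi) && L.wj(cj + MJ[k]) == L.wj(bj)) { kb = k; break; }
    if (kb < 0) break;
    long state = ((long)(ci + L.W * cj)) * 8 + kb;
    if (seen->test(state)) break;
    seen->set(state);
    bool found = false;
    for (int k = 1; k <= 8; ++k) {
      int d = (kb + k) % 8;
      int ni = ci + MI[d], nj = cj + MJ[d];
      if (L.at(ni, nj) > 0) {
        int dprev = (d + 7) % 8;
        bi = ci + MI[dprev]; bj = cj + MJ[dprev];
        ci = ni; cj = nj;
        if (L.periodic) {
          // keep coordinates canonical; the backtrack is relative to ci/cj
          int nci = L.wi(ci), ncj = L.wj(cj);
          bi += nci - ci; bj += ncj - cj;
          ci = nci; cj = ncj;
        }
        found = true;
        break;
      }
    }
    if (!found) break;
  }
  // filter to membrane sites
  for (size_t k = 0; k < order.size(); ++k) {
    if (isMembrane(L, order[k].first, order[k].second))
      path.push_back(order[k]);
  }
  return path;
}

// Act field: membrane sites carry membrane R; interior takes nearest
// membrane value (Euclidean, lowest walk index on ties); medium is 0.
// cellSites limits the interior scan (and the clearing of the previous
// field) to the cell, keeping the cost independent of the lattice size.
void actField(const Lattice& L,
              const std::vector<std::pair<int,int> >& walk,
              const std::vector<double>& memR, std::vector<double>& act,
              const std::vector<int>* cellSites = 0, Stamp* memStamp = 0) {
  if (cellSites) {
    if (act.empty()) act.assign(L.W * L.H, 0.0);
  } else {
    act.assign(L.W * L.H, 0.0);
  }
  Stamp local;
  Stamp* isMem = memStamp ? memStamp : &local;
  isMem->fresh(L.W * L.H);
  for (size_t k = 0; k < walk.size(); ++k) {
    int idx = walk[k].first + L.W * walk[k].second;
    isMem->set(idx);
  }
  std::vector<int> targets;
  if (cellSites) {
    targets = *cellSites;
  } else {
    for (int idx = 0; idx < L.W * L.H; ++idx)
      if (L.lab[idx] > 0) targets.push_back(idx);
  }
  for (size_t t = 0; t < targets.size(); ++t) {
    int idx = targets[t];
    if (L.lab[idx] == 0) { act[idx] = 0; continue; }
    int i = idx % L.W, j = idx / L.W;
    if (isMem->test(idx)) continue;  // filled from memR below
    long best = -1; double bd = 1e18;
    for (size_t k = 0; k < walk.size(); ++k) {
      double di = walk[k].first - i, dj = walk[k].second - j;
      if (L.periodic) {
        di = wrapDiff(walk[k].first, i, L.W);
        dj = wrapDiff(walk[k].second, j, L.H);
      }
      double d = di * di + dj * dj;
      if (d < bd - 1e-12) { bd = d; best = (long)k; }
    }
    act[idx] = memR[best];
  }
  for (size_t k = 0; k < walk.size(); ++k)
    act[walk[k].first + L.W * walk[k].second] = memR[k];
}

// geometric mean of act over Moore neighbourhood restricted to sites with
// the focal label; 0 for medium focal sites or if any included value is 0
double gmAct(const Lattice& L, const std::vector<double>& act, int i, int j) {
  int lab = L.at(i, j);
  if (lab == 0) return 0.0;
  double slog = 0; int cnt = 0;
  for (int di = -1; di <= 1; ++di) for (int dj = -1; dj <= 1; ++dj) {
    int ii = i + di, jj = j + dj;
    if (ii < 0 || ii >= L.W || jj < 0 || jj >= L.H) continue;
    if (L.at(ii, jj) == lab) {
      double v = act[ii + L.W * jj];
      if (v <= 0) return 0.0;
      slog += std::log(v); ++cnt;
    }
  }
  if (!cnt) return 0.0;
  return std::exp(slog / cnt);
}

// local connectivity check for removing cell site v (see R reference)
bool locallyConnectedWithout(const Lattice& L, int i, int j) {
  int nb[8][2]; int n = 0; int seed = -1;
  for (int k = 0; k < 8; ++k) {
    int di = DX8[k], dj = DY8[k];
    if (L.at(i + di, j + dj) > 0) {
      nb[n][0] = di; nb[n][1] = dj;
      if (seed < 0 && std::abs(di) + std::abs(dj) == 1) seed = n;
      ++n;
    }
  }
  if (n == 0 || seed < 0) return false;
  bool seen[8] = {false};
  int queue[8]; int qh = 0, qt = 0;
  queue[qt++] = seed; seen[seed] = true;
  while (qh < qt) {
    int c = queue[qh++];
    for (int k = 0; k < n; ++k) {
      if (!seen[k] &&
          std::abs(nb[c][0] - nb[k][0]) + std::abs(nb[c][1] - nb[k][1]) == 1) {
        seen[k] = true; queue[qt++] = k;
      }
    }
  }
  for (int k = 0; k < n; ++k) if (!seen[k]) return false;
  return true;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = "cpm_boundary_walk_cpp")]]
IntegerMatrix cpmBoundaryWalk(IntegerMatrix lattice) {
  Lattice L; L.W = lattice.nrow(); L.H = lattice.ncol();
  L.lab.assign(lattice.begin(), lattice.end());
  L.periodic = false;
  L.recount();
  std::vector<std::pair<int,int> > w = walkBoundary(L);
  IntegerMatrix out(w.size(), 2);
  for (size_t k = 0; k < w.size(); ++k) {
    out(k, 0) = w[k].first + 1; out(k, 1) = w[k].second + 1;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpm_act_field_cpp")]]
NumericMatrix cpmActField(IntegerMatrix lattice, NumericVector memR) {
  Lattice L; L.W = lattice.nrow(); L.H = lattice.ncol();
  L.lab.assign(lattice.begin(), lattice.end());
  L.periodic = false;
  L.recount();
  std::vector<std::pair<int,int> > w = walkBoundary(L);
  if ((int)w.size() != memR.size())
    stop("membrane_R length must match membrane size");
  std::vector<double> mem(memR.begin(), memR.end()), act;
  actField(L, w, mem, act);
  NumericMatrix out(L.W, L.H);
  std::copy(act.begin(), act.end(), out.begin());
  return out;
}

// [[Rcpp::export(name = "cpm_run_cpp")]]
List cpmRun(IntegerMatrix lattice, List cfg, List params,
            double Rlow, double Rhigh, double targetC, bool keepMasks) {
  Params p = readParams(params);
  Lattice L; L.W = lattice.nrow(); L.H = lattice.ncol();
  L.lab.assign(lattice.begin(), lattice.end());
  L.periodic = true;  // toroidal lattice: the cell never meets a border
  L.recount();

  const double lambda_P = cfg["lambda_P"], lambda_S = cfg["lambda_S"];
  const double P_t = cfg["P_target"], S_t = cfg["S_target"];
  const double lambda_Act = cfg["lambda_Act"], T = cfg["temperature"];
  const int mcs_total = cfg["mcs_total"];
  const double dt = cfg["dt"];
  const int pde_substeps = cfg["pde_substeps"];
  const int mcs_per_step = cfg["mcs_per_step"];
  const int record_every = cfg["record_every"];
  const double B0 = cfg["B0"];
  const int seed = cfg["seed"];
  Rng rng((uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);

  // membrane ring state; the ring is a fixed physical length L0 (the
  // initial membrane size) discretized by the current membrane sites, so
  // dx = L0 / m and conserved mass is sum(values) * dx
  Stamp wsWalk0;
  std::vector<std::pair<int,int> > walk = walkBoundary(L, &wsWalk0);
  size_t m = walk.size();
  const double L0 = (double)m;
  // initial membrane state: the homogeneous low-Rac state with a small
  // deterministic modulation that seeds the symmetry breaking; the
  // inactive pool is shifted uniformly so the conserved per-site total
  // matches the low steady state's value exactly
  (void)Rhigh;
  std::vector<double> R(m), Ri(m), Bv(m, B0), kB(m, 0.0);
  double massC = 0;
  for (size_t k = 0; k < m; ++k) {
    R[k] = Rlow * (1.0 + 0.02 * std::sin(2.0 * M_PI * k / m));
    Ri[k] = std::max(1.0 - R[k] - p.gamma * Kfun(R[k], p), 0.0);
    massC += R[k] + Ri[k];
  }
  double shift = (targetC * m - massC) / m;
  for (size_t k = 0; k < m; ++k) Ri[k] = std::max(Ri[k] + shift, 0.0);

  int n_track = mcs_total / mcs_per_step + 1;
  NumericMatrix trackOut(n_track, 2);
  NumericVector meanR(mcs_total), accepted(mcs_total);
  List masksOut;
  bool aborted = false; int abort_mcs = -1;

  double Dmax = std::max(p.D_R, p.D_Ri);

  std::vector<double> act;
  std::vector<double> dRv, dBv, dkBv, Rn, Rin;
  // explicit cell-site list: O(1) add/remove via position index
  std::vector<int> cellList;
  std::vector<int> posInList(L.W * L.H, -1);
  for (int idx = 0; idx < L.W * L.H; ++idx) {
    if (L.lab[idx] > 0) {
      posInList[idx] = (int)cellList.size();
      cellList.push_back(idx);
    }
  }
  std::vector<int> actPrev;  // sites whose act value must be cleared
  Stamp wsWalk, wsMem;
  std::vector<double> wsA, wsB, wsC, wsD;
  std::vector<long> oldAt(L.W * L.H, -1);
  std::vector<int> oldAtTouched;

  // centroid tracking
  double cx = 0, cy = 0;
  {
    long sx = 0, sy = 0;
    for (int j = 0; j < L.H; ++j) for (int i = 0; i < L.W; ++i)
      if (L.lab[i + L.W * j] > 0) { sx += i + 1; sy += j + 1; }
    cx = (double)sx / L.area; cy = (double)sy / L.area;
  }
  trackOut(0, 0) = cx; trackOut(0, 1) = cy;
  int track_row = 1;

  for (int mcs = 1; mcs <= mcs_total; ++mcs) {
    // --- kinetics on the membrane ring ---
    // operator splitting per substep: explicit reaction, implicit
    // (backward-Euler) diffusion, so the step size is limited only by the
    // reaction rates, not by dx
    m = walk.size();
    double dx = L0 / m;
    double dx2 = dx * dx;
    int nsub = std::max(pde_substeps, (int)std::ceil(dt / 0.5));
    double h = dt / nsub;
    dRv.resize(m); dBv.resize(m); dkBv.resize(m); Rn.resize(m); Rin.resize(m);
    for (int s = 0; s < nsub; ++s) {
      for (size_t k = 0; k < m; ++k) {
        double dR, dB, dkB;
        react4v(R[k], Ri[k], Bv[k], kB[k], p, dR, dB, dkB);
        Rn[k] = R[k] + h * dR;
        Rin[k] = Ri[k] - h * dR;
        dBv[k] = Bv[k] + h * dB;
        dkBv[k] = kB[k] + h * dkB;
      }
      cyclicDiffuse(Rn, h * p.D_R / dx2, m, wsA, wsB, wsC, wsD);
      cyclicDiffuse(Rin, h * p.D_Ri / dx2, m, wsA, wsB, wsC, wsD);
      R.swap(Rn); Ri.swap(Rin); Bv.swap(dBv); kB.swap(dkBv);
    }
    double mr = 0; for (size_t k = 0; k < m; ++k) mr += R[k];
    meanR[mcs - 1] = mr / m;

    // --- protrusion field ---
    for (size_t k = 0; k < actPrev.size(); ++k) act[actPrev[k]] = 0.0;
    actField(L, walk, R, act, &cellList, &wsMem);
    actPrev = cellList;

    // --- one sweep of Metropolis copy attempts over boundary pairs ---
    // candidate pairs: ordered (u, v), 4-adjacent, different labels; every
    // boundary edge has its cell end on the membrane walk
    std::vector<std::pair<int,int> > pairs;  // encoded site indices (u, v)
    for (size_t k = 0; k < walk.size(); ++k) {
      int i = walk[k].first, j = walk[k].second;
      for (int d = 0; d < 4; ++d) {
        int ni = L.wi(i + DX4[d]), nj = L.wj(j + DY4[d]);
        if (L.at(ni, nj) == 0) {
          pairs.push_back(std::make_pair(i + L.W * j, ni + L.W * nj));
          pairs.push_back(std::make_pair(ni + L.W * nj, i + L.W * j));
        }
      }
    }
    int n_att = (int)pairs.size();
    int n_acc = 0;
    for (int a = 0; a < n_att; ++a) {
      std::pair<int,int> pr = pairs[rng.below(n_att)];
      int ui = pr.first % L.W, uj = pr.first / L.W;
      int vi = pr.second % L.W, vj = pr.second / L.W;
      int lu = L.at(ui, uj), lv = L.at(vi, vj);
      if (lu == lv) continue;  // stale pair after earlier accepted copy
      bool gaining = lu > 0;
      if (!gaining) {
        if (L.area <= 1) continue;
        if (!locallyConnectedWithout(L, vi, vj)) continue;
      }
      // geometry delta
      int nCell = 0;
      for (int k = 0; k < 4; ++k)
        if (L.at(vi + DX4[k], vj + DY4[k]) > 0) ++nCell;
      int dPer, dArea;
      if (gaining) { dArea = 1; dPer = (4 - nCell) - nCell; }
      else { dArea = -1; dPer = nCell - (4 - nCell); }
      double dH = lambda_P * (std::pow(L.perim + dPer - P_t, 2) -
                              std::pow(L.perim - P_t, 2)) +
                  lambda_S * (std::pow(L.area + dArea - S_t, 2) -
                              std::pow(L.area - S_t, 2));
      dH += lambda_Act * (gmAct(L, act, vi, vj) - gmAct(L, act, ui, uj));
      bool acc = dH <= 0 || rng.unif() < std::exp(-dH / T);
      if (acc) {
        int vidx = vi + L.W * vj;
        if (dArea > 0) {
          posInList[vidx] = (int)cellList.size();
          cellList.push_back(vidx);
        } else {
          int pos = posInList[vidx];
          int last = cellList.back();
          cellList[pos] = last; posInList[last] = pos;
          cellList.pop_back(); posInList[vidx] = -1;
        }
        L.lab[vidx] = lu;
        L.area += dArea; L.perim += dPer;
        double cxw = cx - L.W * std::floor(cx / L.W);
        double cyw = cy - L.H * std::floor(cy / L.H);
        cx += dArea * wrapDiff(vi + 1, cxw, L.W) / L.area;
        cy += dArea * wrapDiff(vj + 1, cyw, L.H) / L.area;
        ++n_acc;
      }
    }
    accepted[mcs - 1] = n_acc;
    if (aborted) break;
    if (L.area < 9) { aborted = true; abort_mcs = mcs; break; }

    // --- remap ring onto the (possibly deformed) membrane ---
    if (n_acc > 0) {
      std::vector<std::pair<int,int> > nwalk = walkBoundary(L, &wsWalk);
      size_t m2 = nwalk.size();
      if (m2 < 4) { aborted = true; abort_mcs = mcs; break; }
      std::vector<double> R2(m2), Ri2(m2), B2(m2), kB2(m2);
      std::vector<long> pos(m2, -1);
      // index old walk by site (buffer reset via the touched list)
      for (size_t k = 0; k < oldAtTouched.size(); ++k) oldAt[oldAtTouched[k]] = -1;
      oldAtTouched.clear();
      for (size_t k = 0; k < walk.size(); ++k) {
        int idx = walk[k].first + L.W * walk[k].second;
        oldAt[idx] = (long)k;
        oldAtTouched.push_back(idx);
      }
      std::vector<size_t> gained;
      for (size_t k = 0; k < m2; ++k) {
        long o = oldAt[nwalk[k].first + L.W * nwalk[k].second];
        if (o >= 0) {
          pos[k] = o;
          R2[k] = R[o]; Ri2[k] = Ri[o]; B2[k] = Bv[o]; kB2[k] = kB[o];
        } else gained.push_back(k);
      }
      size_t n_surv = m2 - gained.size();
      if (n_surv == 0) { aborted = true; abort_mcs = mcs; break; }
      for (size_t g = 0; g < gained.size(); ++g) {
        size_t k = gained[g];
        // nearest surviving ring positions forwards and backwards
        size_t fwd = k, bwd = k;
        for (size_t stp = 1; stp <= m2; ++stp) {
          size_t cand = (k + stp) % m2;
          if (pos[cand] >= 0) { fwd = cand; break; }
        }
        for (size_t stp = 1; stp <= m2; ++stp) {
          size_t cand = (k + m2 - stp) % m2;
          if (pos[cand] >= 0) { bwd = cand; break; }
        }
        R2[k] = 0.5 * (R[pos[fwd]] + R[pos[bwd]]);
        Ri2[k] = 0.5 * (Ri[pos[fwd]] + Ri[pos[bwd]]);
        B2[k] = 0.5 * (Bv[pos[fwd]] + Bv[pos[bwd]]);
        kB2[k] = 0.5 * (kB[pos[fwd]] + kB[pos[bwd]]);
      }
      // conserve total Rac mass: sum * dx with dx = L0 / m on each grid
      double mass_old = 0, mass_new = 0;
      for (size_t k = 0; k < walk.size(); ++k) mass_old += R[k] + Ri[k];
      for (size_t k = 0; k < m2; ++k) mass_new += R2[k] + Ri2[k];
      mass_old *= L0 / walk.size();
      mass_new *= L0 / m2;
      if (mass_new > 0) {
        double fac = mass_old / mass_new;
        for (size_t k = 0; k < m2; ++k) { R2[k] *= fac; Ri2[k] *= fac; }
      }
      walk.swap(nwalk); R.swap(R2); Ri.swap(Ri2); Bv.swap(B2); kB.swap(kB2);
    }

    // --- recording ---
    if (mcs % mcs_per_step == 0 && track_row < n_track) {
      trackOut(track_row, 0) = cx; trackOut(track_row, 1) = cy;
      if (keepMasks && ((track_row - 1) % record_every == 0)) {
        LogicalMatrix mk(L.W, L.H);
        for (int idx = 0; idx < L.W * L.H; ++idx) mk[idx] = L.lab[idx] > 0;
        masksOut.push_back(mk);
      }
      ++track_row;
    }
  }

  IntegerMatrix latOut(L.W, L.H);
  std::copy(L.lab.begin(), L.lab.end(), latOut.begin());
  size_t mfin = walk.size();
  NumericMatrix ring(mfin, 4);
  for (size_t k = 0; k < mfin; ++k) {
    ring(k, 0) = R[k]; ring(k, 1) = Ri[k]; ring(k, 2) = Bv[k]; ring(k, 3) = kB[k];
  }
  colnames(ring) = CharacterVector::create("R", "Ri", "B", "kB");

  // truncate the track to recorded rows
  NumericMatrix trk(track_row, 2);
  for (int r = 0; r < track_row; ++r) {
    trk(r, 0) = trackOut(r, 0); trk(r, 1) = trackOut(r, 1);
  }
  return List::create(
    _["track"] = trk, _["masks"] = masksOut, _["mean_R"] = meanR,
    _["accepted"] = accepted, _["lattice"] = latOut, _["ring"] = ring,
    _["aborted"] = aborted, _["abort_mcs"] = abort_mcs);
}
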