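// Compiled core: overdamped Brownian dynamics of microtubules (MT),
// neurofilaments (NF) and transiting membranous organelles in a 2D axonal
// cross-section, with motor-spring coupling and discrete cargo kinetics.
//
// Everything here works in internal units: lengths in nm, time in s, forces
// in pN (drags in pN.s/nm, diffusivities in nm^2/s).  The parameter vector
// handed over from R (R/params.R, .par_vec) follows the ParIdx order below;
// the two files must stay in sync.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// parameter vector layout (synced with .par_names in R/params.R)
// ---------------------------------------------------------------------------
enum ParIdx {
  P_R_M = 0, P_R_N, P_R_B, P_KON_N, P_KOFF_N, P_KOUT_N,
  P_KON_O, P_KOFF_O, P_KIN_O, P_S_O, P_L_R, P_EPS,
  P_KAPPA_N, P_KAPPA_O, P_MU_M, P_MU_N, P_MU_O,
  P_D_M, P_D_N, P_D_O, P_M_MAX, P_H_SLOW, P_H_FAST,
  P_ORG_A, P_ORG_B, P_EPS_DOUBLE, P_NPAR
};

// surface gaps below this are rechecked after every accepted displacement;
// chosen to exceed any plausible one-step closing distance at h <= 1/50 s
static const double DANGER_GAP = 25.0;
// accepted configurations keep every close gap above this guard: the
// repulsion potential rises by tens of kT over the excluded band, so
// thermal states never visit it. The guard must sit BELOW every force
// balance the dynamics can produce (multi-spring organelle squeezes reach
// several hundred pN, balancing the diverging repulsion near 0.1-0.3 nm),
// or squeezed pairs would be rejected forever; step halving handles the
// stiffness at these gaps
static const double GAP_GUARD = 0.05;
static const int    PLACE_ATTEMPTS = 100;
static const int    NOISE_REDRAWS = 3;

// ---------------------------------------------------------------------------
// random stream: xoshiro256++ seeded via splitmix64, ziggurat normals
// ---------------------------------------------------------------------------
struct Zig {
  uint32_t kn[128];
  double wn[128], fn[128];
  Zig() {
    const double m1 = 2147483648.0; /* 2^31 */
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};
static const Zig ZIG;

struct RNG {
  uint64_t s[4];
  void seed(uint64_t x) {
    for (int i = 0; i < 4; i++) {
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
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  inline int randint(int n) { // uniform on {0, ..., n-1}
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
  double norm() {
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)next();
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < ZIG.kn[iz]) return hz * ZIG.wn[iz];
      if (iz == 0) { // tail beyond |x| = 3.4426...
        const double Rz = 3.442619855899;
        double x, y;
        do {
          x = -std::log(unif_pos()) / Rz;
          y = -std::log(unif_pos());
        } while (y + y < x * x);
        return hz > 0 ? Rz + x : -(Rz + x);
      }
      double x = hz * ZIG.wn[iz];
      if (ZIG.fn[iz] + unif() * (ZIG.fn[iz - 1] - ZIG.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// ---------------------------------------------------------------------------
// state
// ---------------------------------------------------------------------------
struct Domain { int kind; double size; }; // 0 = disk (R0), 1 = periodic square (L)

struct Org {
  double x, y, z, a, b;
  std::vector<int> mts; // bonded MT indices, 0-based
};

struct State {
  int nM = 0, nN = 0;
  std::vector<double> px, py; // MT block [0,nM), then NF block [nM,nM+nN)
  std::vector<int> nfb;       // per NF: bonded MT index or -1
  std::vector<Org> orgs;
  Domain dom;
};

static inline double orad(const Org &g) {
  double q = 1.0 - (g.z * g.z) / (g.a * g.a);
  return q > 0 ? g.b * q : 0.0;
}

static inline void sep(const Domain &dom, double x1, double y1, double x2,
                       double y2, double &dx, double &dy) {
  dx = x2 - x1;
  dy = y2 - y1;
  if (dom.kind == 1) {
    const double L = dom.size, H = 0.5 * dom.size;
    if (dx > H) dx -= L; else if (dx < -H) dx += L;
    if (dy > H) dy -= L; else if (dy < -H) dy += L;
  }
}

// parameter cache, reloaded whenever the schedule may have mutated the vector
struct PC {
  double rM, rN, Rb, konN, koffN, koutN, konO, koffO, kinO, sO;
  double Lr, eps, kapN, kapO, muM, muN, muO, DM, DN, DO;
  int mmax; // <= 0 means unlimited
  double h_slow, h_fast, org_a, org_b;
  bool epsdbl;
  void load(const std::vector<double> &p) {
    rM = p[P_R_M]; rN = p[P_R_N]; Rb = p[P_R_B];
    konN = p[P_KON_N]; koffN = p[P_KOFF_N]; koutN = p[P_KOUT_N];
    konO = p[P_KON_O]; koffO = p[P_KOFF_O]; kinO = p[P_KIN_O];
    sO = p[P_S_O]; Lr = p[P_L_R]; eps = p[P_EPS];
    kapN = p[P_KAPPA_N]; kapO = p[P_KAPPA_O];
    muM = p[P_MU_M]; muN = p[P_MU_N]; muO = p[P_MU_O];
    DM = p[P_D_M]; DN = p[P_D_N]; DO = p[P_D_O];
    mmax = (int)std::llround(p[P_M_MAX]);
    h_slow = p[P_H_SLOW]; h_fast = p[P_H_FAST];
    org_a = p[P_ORG_A]; org_b = p[P_ORG_B];
    epsdbl = p[P_EPS_DOUBLE] != 0.0;
  }
};

static inline double prad(const State &st, const PC &pc, int i) {
  return i < st.nM ? pc.rM : pc.rN;
}

// ---------------------------------------------------------------------------
// uniform grid for range queries / pair enumeration
// ---------------------------------------------------------------------------
struct Grid {
  bool brute = true;
  int nx = 0, ny = 0;
  double x0 = 0, y0 = 0, cs = 1;
  bool periodic = false;
  std::vector<int> head, nxt;
};

static void grid_build(Grid &g, const double *px, const double *py, int n,
                       const Domain &dom, double cutoff) {
  g.periodic = (dom.kind == 1);
  if (n < 16) { g.brute = true; return; } // not worth binning
  if (dom.kind == 1) {
    double L = dom.size;
    int nc = (int)std::floor(L / cutoff);
    if (nc < 3) { g.brute = true; return; }
    g.nx = g.ny = nc;
    g.cs = L / nc;
    g.x0 = 0; g.y0 = 0;
  } else {
    double ext = 2.0 * dom.size + 100.0;
    int nc = std::max(1, (int)std::floor(ext / cutoff));
    if (nc < 2) { g.brute = true; return; }
    g.nx = g.ny = nc;
    g.cs = ext / nc;
    g.x0 = -dom.size - 50.0;
    g.y0 = -dom.size - 50.0;
  }
  g.brute = false;
  g.head.assign((size_t)g.nx * g.ny, -1);
  g.nxt.assign(n, -1);
  for (int i = 0; i < n; i++) {
    int cx = (int)std::floor((px[i] - g.x0) / g.cs);
    int cy = (int)std::floor((py[i] - g.y0) / g.cs);
    if (g.periodic) {
      cx = ((cx % g.nx) + g.nx) % g.nx;
      cy = ((cy % g.ny) + g.ny) % g.ny;
    } else {
      cx = std::min(std::max(cx, 0), g.nx - 1);
      cy = std::min(std::max(cy, 0), g.ny - 1);
    }
    int c = cy * g.nx + cx;
    g.nxt[i] = g.head[c];
    g.head[c] = i;
  }
}

// visit all points of the grid within the 3x3 cell neighborhood of (x, y)
template <class F>
static void grid_query(const Grid &g, const double *px, const double *py,
                       int n, double x, double y, F fn) {
  if (g.brute) {
    for (int i = 0; i < n; i++) fn(i);
    return;
  }
  int cx = (int)std::floor((x - g.x0) / g.cs);
  int cy = (int)std::floor((y - g.y0) / g.cs);
  for (int oy = -1; oy <= 1; oy++) {
    for (int ox = -1; ox <= 1; ox++) {
      int ax = cx + ox, ay = cy + oy;
      if (g.periodic) {
        ax = ((ax % g.nx) + g.nx) % g.nx;
        ay = ((ay % g.ny) + g.ny) % g.ny;
      } else if (ax < 0 || ax >= g.nx || ay < 0 || ay >= g.ny) {
        continue;
      }
      for (int i = g.head[ay * g.nx + ax]; i >= 0; i = g.nxt[i]) fn(i);
    }
  }
}

// ---------------------------------------------------------------------------
// Verlet pair list for MT/NF repulsion (organelles handled directly)
// ---------------------------------------------------------------------------
struct PairList {
  std::vector<int> a, b;
  std::vector<double> sumr;
  double skin = 12.0;
  double travel = 1e18; // accumulated bound on max displacement since build
  bool valid = false;
  long rebuilds = 0;
};

struct Counters {
  long slow_steps = 0, fast_steps = 0, rejects = 0;
  long nf_binds = 0, nf_unbinds = 0, nf_departs = 0, nf_cancelled = 0;
  long org_arrivals = 0, org_deferred = 0, org_departs = 0;
  long rebuilds = 0;
};

struct Sim {
  State st;
  std::vector<double> par;
  PC pc;
  PairList pl;
  RNG rng;
  Counters cnt;
  // scratch
  std::vector<double> fx, fy, ofx, ofy;
  std::vector<int> d_a, d_b, d_bd; // danger pairs / boundary-danger ids
  std::vector<double> sx, sy, sox, soy, soz;
  void reload() { pc.load(par); }
};

static void pairs_build(Sim &S) {
  PairList &pl = S.pl;
  const State &st = S.st;
  const PC &pc = S.pc;
  pl.a.clear(); pl.b.clear(); pl.sumr.clear();
  pl.travel = 0;
  pl.valid = true;
  pl.rebuilds++;
  S.cnt.rebuilds++;
  int n = st.nM + st.nN;
  if (n < 2) return;
  double rmax = std::max(pc.rM, pc.rN);
  double cutoff = pc.Lr + 2.0 * rmax + pl.skin;
  auto consider = [&](int i, int j) {
    double dx, dy;
    sep(st.dom, st.px[i], st.py[i], st.px[j], st.py[j], dx, dy);
    double sr = prad(st, pc, i) + prad(st, pc, j);
    double cut = pc.Lr + sr + pl.skin;
    if (dx * dx + dy * dy <= cut * cut) {
      pl.a.push_back(i);
      pl.b.push_back(j);
      pl.sumr.push_back(sr);
    }
  };
  Grid g;
  grid_build(g, st.px.data(), st.py.data(), n, st.dom, cutoff);
  if (g.brute) {
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) consider(i, j);
    return;
  }
  // half stencil so each pair is enumerated once
  const int sten[4][2] = {{1, 0}, {-1, 1}, {0, 1}, {1, 1}};
  for (int cy = 0; cy < g.ny; cy++) {
    for (int cx = 0; cx < g.nx; cx++) {
      int c = cy * g.nx + cx;
      for (int i = g.head[c]; i >= 0; i = g.nxt[i])
        for (int j = g.nxt[i]; j >= 0; j = g.nxt[j]) consider(i, j);
      for (int s = 0; s < 4; s++) {
        int ax = cx + sten[s][0], ay = cy + sten[s][1];
        if (g.periodic) {
          ax = ((ax % g.nx) + g.nx) % g.nx;
          ay = ((ay % g.ny) + g.ny) % g.ny;
        } else if (ax < 0 || ax >= g.nx || ay < 0 || ay >= g.ny) {
          continue;
        }
        int c2 = ay * g.nx + ax;
        for (int i = g.head[c]; i >= 0; i = g.nxt[i])
          for (int j = g.head[c2]; j >= 0; j = g.nxt[j]) consider(i, j);
      }
    }
  }
}

// ---------------------------------------------------------------------------
// force field: pairwise soft repulsion (diverging at contact), boundary
// repulsion, motor springs; epsilon prefactors doubled for organelles whose
// cross-sectional radius is growing (z < 0), emulating the fluid they push
// ---------------------------------------------------------------------------
static bool forces_eval(Sim &S, bool collect_danger = true) {
  const PC &pc = S.pc;
  State &st = S.st;
  int nP = st.nM + st.nN;
  int nO = (int)st.orgs.size();
  S.fx.assign(nP, 0.0); S.fy.assign(nP, 0.0);
  S.ofx.assign(nO, 0.0); S.ofy.assign(nO, 0.0);
  S.d_a.clear(); S.d_b.clear(); S.d_bd.clear();
  bool contact = false;

  // MT/NF pairwise repulsion via the Verlet list
  const size_t np = S.pl.a.size();
  for (size_t k = 0; k < np; k++) {
    int i = S.pl.a[k], j = S.pl.b[k];
    double sr = S.pl.sumr[k];
    double dx, dy;
    sep(st.dom, st.px[i], st.py[i], st.px[j], st.py[j], dx, dy);
    double r2 = dx * dx + dy * dy;
    double cut = pc.Lr + sr;
    if (r2 > cut * cut) continue;
    double r = std::sqrt(r2);
    double d = r - sr;
    if (d <= 0) { contact = true; continue; }
    if (collect_danger && d < DANGER_GAP) {
      S.d_a.push_back(i);
      S.d_b.push_back(j);
    }
    double f_over_r = pc.eps * (pc.Lr - d) / (d * r); // eps*(Lr/d - 1)/r
    S.fx[i] -= f_over_r * dx; S.fy[i] -= f_over_r * dy;
    S.fx[j] += f_over_r * dx; S.fy[j] += f_over_r * dy;
  }

  // NF-MT motor springs (zero-rest-length, cutoff at the binding radius)
  for (int f = 0; f < st.nN; f++) {
    int m = st.nfb[f];
    if (m < 0) continue;
    int i = st.nM + f;
    double dx, dy;
    sep(st.dom, st.px[m], st.py[m], st.px[i], st.py[i], dx, dy);
    double r = std::sqrt(dx * dx + dy * dy);
    double d = r - pc.rM - pc.rN;
    if (d > 0 && d <= pc.Rb && r > 0) {
      double f_over_r = pc.kapN * d / r;
      S.fx[m] += f_over_r * dx; S.fy[m] += f_over_r * dy;
      S.fx[i] -= f_over_r * dx; S.fy[i] -= f_over_r * dy;
    }
  }

  // organelles: repulsion against every particle, springs to bonded MTs,
  // organelle-organelle repulsion
  for (int o = 0; o < nO; o++) {
    Org &G = st.orgs[o];
    double ro = orad(G);
    double fo = (pc.epsdbl && G.z < 0) ? 2.0 : 1.0;
    for (int i = 0; i < nP; i++) {
      double dx, dy;
      sep(st.dom, G.x, G.y, st.px[i], st.py[i], dx, dy);
      double sr = ro + prad(st, pc, i);
      double cut = pc.Lr + sr;
      double r2 = dx * dx + dy * dy;
      if (r2 > cut * cut) continue;
      double r = std::sqrt(r2);
      double d = r - sr;
      if (d <= 0) { contact = true; continue; }
      if (collect_danger && d < DANGER_GAP) {
        S.d_a.push_back(nP + o);
        S.d_b.push_back(i);
      }
      double f_over_r = fo * pc.eps * (pc.Lr - d) / (d * r);
      S.ofx[o] -= f_over_r * dx; S.ofy[o] -= f_over_r * dy;
      S.fx[i] += f_over_r * dx;  S.fy[i] += f_over_r * dy;
    }
    for (size_t q = 0; q < G.mts.size(); q++) {
      int m = G.mts[q];
      double dx, dy;
      sep(st.dom, G.x, G.y, st.px[m], st.py[m], dx, dy);
      double r = std::sqrt(dx * dx + dy * dy);
      double d = r - ro - pc.rM;
      if (d > 0 && d <= pc.Rb && r > 0) {
        double f_over_r = pc.kapO * d / r;
        S.ofx[o] += f_over_r * dx; S.ofy[o] += f_over_r * dy;
        S.fx[m] -= f_over_r * dx;  S.fy[m] -= f_over_r * dy;
      }
    }
    for (int o2 = o + 1; o2 < nO; o2++) {
      Org &G2 = st.orgs[o2];
      double ro2 = orad(G2);
      double fo2 = (pc.epsdbl && G2.z < 0) ? 2.0 : 1.0;
      double dx, dy;
      sep(st.dom, G.x, G.y, G2.x, G2.y, dx, dy);
      double sr = ro + ro2;
      double cut = pc.Lr + sr;
      double r2 = dx * dx + dy * dy;
      if (r2 > cut * cut) continue;
      double r = std::sqrt(r2);
      double d = r - sr;
      if (d <= 0) { contact = true; continue; }
      if (collect_danger && d < DANGER_GAP) {
        S.d_a.push_back(nP + o);
        S.d_b.push_back(nP + o2);
      }
      double f_over_r = fo * fo2 * pc.eps * (pc.Lr - d) / (d * r);
      S.ofx[o] -= f_over_r * dx;  S.ofy[o] -= f_over_r * dy;
      S.ofx[o2] += f_over_r * dx; S.ofy[o2] += f_over_r * dy;
    }
  }

  // boundary repulsion (disk domain only)
  if (st.dom.kind == 0) {
    double R0 = st.dom.size;
    for (int i = 0; i < nP; i++) {
      double ri = prad(st, pc, i);
      double inner = R0 - ri - pc.Lr;
      double r2 = st.px[i] * st.px[i] + st.py[i] * st.py[i];
      if (inner > 0 && r2 < inner * inner) continue;
      double rr = std::sqrt(r2);
      double db = R0 - rr - ri;
      if (db <= 0) { contact = true; continue; }
      if (db <= pc.Lr && rr > 0) {
        if (collect_danger && db < DANGER_GAP) S.d_bd.push_back(i);
        double f = pc.eps * (pc.Lr / db - 1.0);
        S.fx[i] -= f * st.px[i] / rr;
        S.fy[i] -= f * st.py[i] / rr;
      }
    }
    for (int o = 0; o < nO; o++) {
      Org &G = st.orgs[o];
      double ro = orad(G);
      double rr = std::sqrt(G.x * G.x + G.y * G.y);
      double db = R0 - rr - ro;
      if (db <= 0) { contact = true; continue; }
      if (db <= pc.Lr && rr > 0) {
        if (collect_danger && db < DANGER_GAP) S.d_bd.push_back(nP + o);
        double f = pc.eps * (pc.Lr / db - 1.0);
        S.ofx[o] -= f * G.x / rr;
        S.ofy[o] -= f * G.y / rr;
      }
    }
  }
  return contact;
}

// ---------------------------------------------------------------------------
// Euler-Maruyama update and contact-guarded stepping
// ---------------------------------------------------------------------------
static void save_positions(Sim &S) {
  S.sx = S.st.px;
  S.sy = S.st.py;
  int nO = (int)S.st.orgs.size();
  S.sox.resize(nO); S.soy.resize(nO); S.soz.resize(nO);
  for (int o = 0; o < nO; o++) {
    S.sox[o] = S.st.orgs[o].x;
    S.soy[o] = S.st.orgs[o].y;
    S.soz[o] = S.st.orgs[o].z;
  }
}

static void restore_positions(Sim &S) {
  S.st.px = S.sx;
  S.st.py = S.sy;
  for (size_t o = 0; o < S.st.orgs.size(); o++) {
    S.st.orgs[o].x = S.sox[o];
    S.st.orgs[o].y = S.soy[o];
    S.st.orgs[o].z = S.soz[o];
  }
}

// apply one EM displacement at step h; returns max MT/NF displacement
static double do_update(Sim &S, double h) {
  const PC &pc = S.pc;
  State &st = S.st;
  double sdM = std::sqrt(2.0 * pc.DM * h);
  double sdN = std::sqrt(2.0 * pc.DN * h);
  double sdO = std::sqrt(2.0 * pc.DO * h);
  double ivM = h / pc.muM, ivN = h / pc.muN, ivO = h / pc.muO;
  double maxd2 = 0;
  int nP = st.nM + st.nN;
  for (int i = 0; i < nP; i++) {
    bool mt = i < st.nM;
    double dx = S.fx[i] * (mt ? ivM : ivN) + (mt ? sdM : sdN) * S.rng.norm();
    double dy = S.fy[i] * (mt ? ivM : ivN) + (mt ? sdM : sdN) * S.rng.norm();
    st.px[i] += dx;
    st.py[i] += dy;
    double d2 = dx * dx + dy * dy;
    if (d2 > maxd2) maxd2 = d2;
  }
  if (st.dom.kind == 1) {
    double L = st.dom.size;
    for (int i = 0; i < nP; i++) {
      st.px[i] -= L * std::floor(st.px[i] / L);
      st.py[i] -= L * std::floor(st.py[i] / L);
    }
  }
  for (size_t o = 0; o < st.orgs.size(); o++) {
    Org &G = st.orgs[o];
    G.x += S.ofx[o] * ivO + sdO * S.rng.norm();
    G.y += S.ofy[o] * ivO + sdO * S.rng.norm();
    G.z += pc.sO * h;
  }
  return std::sqrt(maxd2);
}

// diagnostic: smallest current gap over the danger set (pair or boundary)
static std::string danger_report(Sim &S) {
  const PC &pc = S.pc;
  State &st = S.st;
  int nP = st.nM + st.nN;
  auto posrad = [&](int id, double &x, double &y, double &r) {
    if (id < nP) {
      x = st.px[id]; y = st.py[id]; r = prad(st, pc, id);
    } else {
      const Org &G = st.orgs[id - nP];
      x = G.x; y = G.y; r = orad(G);
    }
  };
  double worst = 1e18; int wa = -1, wb = -1;
  for (size_t k = 0; k < S.d_a.size(); k++) {
    double x1, y1, r1, x2, y2, r2v;
    posrad(S.d_a[k], x1, y1, r1);
    posrad(S.d_b[k], x2, y2, r2v);
    double dx, dy;
    sep(st.dom, x1, y1, x2, y2, dx, dy);
    double g = std::sqrt(dx * dx + dy * dy) - r1 - r2v;
    if (g < worst) { worst = g; wa = S.d_a[k]; wb = S.d_b[k]; }
  }
  for (size_t k = 0; k < S.d_bd.size(); k++) {
    double x, y, r;
    posrad(S.d_bd[k], x, y, r);
    double g = st.dom.size - std::sqrt(x * x + y * y) - r;
    if (g < worst) { worst = g; wa = S.d_bd[k]; wb = -99; }
  }
  char buf[160];
  snprintf(buf, sizeof(buf), "min gap %.4g nm (ids %d/%d, nP=%d, nO=%d)",
           worst, wa, wb, nP, (int)st.orgs.size());
  return std::string(buf);
}

// recheck the close-approach set after a displacement; false means overlap
static bool danger_ok(Sim &S) {
  const PC &pc = S.pc;
  State &st = S.st;
  int nP = st.nM + st.nN;
  auto posrad = [&](int id, double &x, double &y, double &r) {
    if (id < nP) {
      x = st.px[id]; y = st.py[id]; r = prad(st, pc, id);
    } else {
      const Org &G = st.orgs[id - nP];
      x = G.x; y = G.y; r = orad(G);
    }
  };
  for (size_t k = 0; k < S.d_a.size(); k++) {
    double x1, y1, r1, x2, y2, r2v;
    posrad(S.d_a[k], x1, y1, r1);
    posrad(S.d_b[k], x2, y2, r2v);
    double dx, dy;
    sep(st.dom, x1, y1, x2, y2, dx, dy);
    double sr = r1 + r2v + GAP_GUARD;
    if (dx * dx + dy * dy <= sr * sr) return false;
  }
  if (st.dom.kind == 0) {
    double R0 = st.dom.size;
    for (size_t k = 0; k < S.d_bd.size(); k++) {
      double x, y, r;
      posrad(S.d_bd[k], x, y, r);
      if (std::sqrt(x * x + y * y) + r >= R0 - GAP_GUARD) return false;
    }
  }
  return true;
}

static void org_departures(Sim &S);

// Advance the mechanics over `span` seconds. The nominal step follows the
// two-level policy (h_fast while organelles are present, h_slow otherwise),
// or `h_override` if positive. A step that would push a close pair below
// the gap guard is rejected: the noise is redrawn a few times, then the
// step is halved, and the reduced step is carried forward (doubling back
// towards nominal after successes) so stiff episodes do not restart the
// halving from scratch.
static void advance_mech(Sim &S, double span, double &t,
                         double h_override = -1.0) {
  double remaining = span;
  double ht_cur = -1.0;
  while (remaining > 1e-12) {
    bool fast = !S.st.orgs.empty();
    double hnom = h_override > 0 ? h_override
                                 : (fast ? S.pc.h_fast : S.pc.h_slow);
    double hmin = std::min(S.pc.h_fast, hnom) / 1024.0;
    if (ht_cur <= 0 || ht_cur > hnom) ht_cur = hnom;
    double h = std::min(ht_cur, remaining);
    if (!S.pl.valid || S.pl.travel > 0.5 * S.pl.skin) pairs_build(S);
    bool contact = forces_eval(S);
    // displacement cap: one step may move a particle by at most
    // DANGER_GAP * 0.4 (drift plus a 5-sigma noise allowance), so that no
    // unmonitored pair (gap >= DANGER_GAP) can reach contact in one step;
    // a squeezed particle with a large force simply takes smaller steps,
    // which is also where the explicit scheme needs them for accuracy
    if (!contact) {
      double maxv = 0;
      int nP = S.st.nM + S.st.nN;
      for (int i = 0; i < nP; i++) {
        double f = std::sqrt(S.fx[i] * S.fx[i] + S.fy[i] * S.fy[i]);
        double v = f / (i < S.st.nM ? S.pc.muM : S.pc.muN);
        if (v > maxv) maxv = v;
      }
      for (size_t o = 0; o < S.st.orgs.size(); o++) {
        double f = std::sqrt(S.ofx[o] * S.ofx[o] + S.ofy[o] * S.ofy[o]);
        double v = f / S.pc.muO;
        if (v > maxv) maxv = v;
      }
      double budget = 0.4 * DANGER_GAP; // nm per particle per step
      double Dmax = std::max(S.pc.DM, S.pc.DN);
      if (!S.st.orgs.empty()) Dmax = std::max(Dmax, S.pc.DO);
      double sdmax = std::sqrt(2.0 * Dmax);
      while (h > 1e-9 && maxv * h + 5.0 * sdmax * std::sqrt(h) > budget)
        h *= 0.5;
    }
    if (contact) {
      // full brute-force scan for the offending pair, for the diagnostic
      const State &st = S.st;
      int nP = st.nM + st.nN;
      double worst = 1e18; int wa = -1, wb = -1;
      for (int i = 0; i < nP; i++) {
        for (int j = i + 1; j < nP; j++) {
          double dx, dy;
          sep(st.dom, st.px[i], st.py[i], st.px[j], st.py[j], dx, dy);
          double g = std::sqrt(dx * dx + dy * dy) - prad(st, S.pc, i) -
                     prad(st, S.pc, j);
          if (g < worst) { worst = g; wa = i; wb = j; }
        }
        for (size_t o = 0; o < st.orgs.size(); o++) {
          double dx, dy;
          sep(st.dom, st.px[i], st.py[i], st.orgs[o].x, st.orgs[o].y, dx, dy);
          double g = std::sqrt(dx * dx + dy * dy) - prad(st, S.pc, i) -
                     orad(st.orgs[o]);
          if (g < worst) { worst = g; wa = i; wb = nP + (int)o; }
        }
        if (st.dom.kind == 0) {
          double g = st.dom.size -
                     std::sqrt(st.px[i] * st.px[i] + st.py[i] * st.py[i]) -
                     prad(st, S.pc, i);
          if (g < worst) { worst = g; wa = i; wb = -99; }
        }
      }
      stop("overlapping particles in the current state at t = %g s "
           "(min gap %g nm, ids %d/%d, nP=%d, nO=%d)",
           t, worst, wa, wb, nP, (int)S.st.orgs.size());
    }
    save_positions(S);
    bool ok = false;
    for (int att = 0; att < NOISE_REDRAWS && !ok; att++) {
      double md = do_update(S, h);
      if (danger_ok(S)) {
        ok = true;
        S.pl.travel += md;
      } else {
        restore_positions(S);
        S.cnt.rejects++;
      }
    }
    if (!ok) {
      ht_cur = h * 0.5;
      if (ht_cur < hmin)
        stop("contact could not be resolved by step halving at t = %g s (%s)",
             t, danger_report(S).c_str());
      continue;
    }
    t += h;
    remaining -= h;
    if (fast) S.cnt.fast_steps++; else S.cnt.slow_steps++;
    org_departures(S);
    ht_cur = std::min(hnom, ht_cur * 2.0);
  }
}

// ---------------------------------------------------------------------------
// cargo kinetics (discrete Bernoulli events per kinetics tick)
// ---------------------------------------------------------------------------
static bool placement_clear(const Sim &S, double x, double y, double r,
                            int exclude) {
  const State &st = S.st;
  const PC &pc = S.pc;
  int nP = st.nM + st.nN;
  for (int i = 0; i < nP; i++) {
    if (i == exclude) continue;
    double dx, dy;
    sep(st.dom, x, y, st.px[i], st.py[i], dx, dy);
    double sr = r + prad(st, pc, i) + GAP_GUARD;
    if (dx * dx + dy * dy <= sr * sr) return false;
  }
  for (size_t o = 0; o < st.orgs.size(); o++) {
    double dx, dy;
    sep(st.dom, x, y, st.orgs[o].x, st.orgs[o].y, dx, dy);
    double sr = r + orad(st.orgs[o]) + GAP_GUARD;
    if (dx * dx + dy * dy <= sr * sr) return false;
  }
  if (st.dom.kind == 0 &&
      std::sqrt(x * x + y * y) + r >= st.dom.size - GAP_GUARD)
    return false;
  return true;
}

// departure of a bound NF: teleport it next to an eligible MT (one having
// another NF within the binding radius), or cancel the event
static bool try_depart_replace(Sim &S, int f) {
  State &st = S.st;
  const PC &pc = S.pc;
  std::vector<int> elig;
  for (int m = 0; m < st.nM; m++) {
    for (int f2 = 0; f2 < st.nN; f2++) {
      if (f2 == f) continue;
      double dx, dy;
      sep(st.dom, st.px[m], st.py[m], st.px[st.nM + f2], st.py[st.nM + f2],
          dx, dy);
      double d = std::sqrt(dx * dx + dy * dy) - pc.rM - pc.rN;
      if (d <= pc.Rb) { elig.push_back(m); break; }
    }
  }
  if (elig.empty()) return false;
  double cd = pc.rM + pc.rN + pc.Rb; // center distance giving gap R_b
  for (int att = 0; att < PLACE_ATTEMPTS; att++) {
    int m = elig[S.rng.randint((int)elig.size())];
    double th = 2.0 * M_PI * S.rng.unif();
    double x = st.px[m] + cd * std::cos(th);
    double y = st.py[m] + cd * std::sin(th);
    if (st.dom.kind == 1) {
      double L = st.dom.size;
      x -= L * std::floor(x / L);
      y -= L * std::floor(y / L);
    }
    if (placement_clear(S, x, y, pc.rN, st.nM + f)) {
      st.px[st.nM + f] = x;
      st.py[st.nM + f] = y;
      st.nfb[f] = -1; // entrant starts unbound
      S.pl.valid = false;
      return true;
    }
  }
  return false;
}

static void nf_kinetics(Sim &S, double h) {
  const PC &pc = S.pc;
  State &st = S.st;
  if (st.nN == 0) return;
  double pbind = pc.konN * h;
  double punb = pc.koffN * h, pout = pc.koutN * h;
  Grid g;
  double qcut = pc.Rb + pc.rM + pc.rN;
  bool has_grid = false;
  if (pbind > 0 && st.nM > 0) {
    grid_build(g, st.px.data(), st.py.data(), st.nM, st.dom, qcut);
    has_grid = true;
  }
  std::vector<int> cand;
  for (int f = 0; f < st.nN; f++) {
    int i = st.nM + f;
    if (st.nfb[f] < 0) {
      if (!has_grid) continue;
      cand.clear();
      grid_query(g, st.px.data(), st.py.data(), st.nM, st.px[i], st.py[i],
                 [&](int m) {
                   double dx, dy;
                   sep(st.dom, st.px[i], st.py[i], st.px[m], st.py[m], dx, dy);
                   double d = std::sqrt(dx * dx + dy * dy) - pc.rM - pc.rN;
                   if (d <= pc.Rb) cand.push_back(m);
                 });
      if (cand.empty()) continue;
      if (S.rng.unif() < pbind) {
        st.nfb[f] = cand[S.rng.randint((int)cand.size())];
        S.cnt.nf_binds++;
      }
    } else {
      // at most one transition per NF per tick: one variate against the
      // cumulative probabilities [koff*h, (koff+kout)*h]
      double u = S.rng.unif();
      if (u < punb) {
        st.nfb[f] = -1;
        S.cnt.nf_unbinds++;
      } else if (u < punb + pout) {
        if (try_depart_replace(S, f))
          S.cnt.nf_departs++;
        else
          S.cnt.nf_cancelled++;
      }
    }
  }
}

static void org_arrival(Sim &S, double h) {
  const PC &pc = S.pc;
  State &st = S.st;
  if (pc.kinO <= 0 || st.nM == 0) return;
  if (S.rng.unif() >= pc.kinO * h) return;
  int m = S.rng.randint(st.nM);
  double cd = pc.rM + pc.Rb; // entry cross-sectional radius is 0
  for (int att = 0; att < PLACE_ATTEMPTS; att++) {
    double th = 2.0 * M_PI * S.rng.unif();
    double x = st.px[m] + cd * std::cos(th);
    double y = st.py[m] + cd * std::sin(th);
    if (st.dom.kind == 1) {
      double L = st.dom.size;
      x -= L * std::floor(x / L);
      y -= L * std::floor(y / L);
    }
    if (placement_clear(S, x, y, 0.0, -1)) {
      Org G;
      G.x = x; G.y = y;
      G.z = -pc.org_a;
      G.a = pc.org_a; G.b = pc.org_b;
      G.mts.push_back(m); // track engagement (any cap admits one bond)
      st.orgs.push_back(G);
      S.cnt.org_arrivals++;
      return;
    }
  }
  S.cnt.org_deferred++;
}

static void org_binding(Sim &S, double h) {
  const PC &pc = S.pc;
  State &st = S.st;
  double pon = pc.konO * h, poff = pc.koffO * h;
  for (size_t o = 0; o < st.orgs.size(); o++) {
    Org &G = st.orgs[o];
    // unbinding first, then new engagements
    for (size_t q = G.mts.size(); q-- > 0;) {
      if (S.rng.unif() < poff) G.mts.erase(G.mts.begin() + q);
    }
    if (pon <= 0 || st.nM == 0) continue;
    double ro = orad(G);
    int cap = pc.mmax <= 0 ? st.nM : pc.mmax;
    for (int m = 0; m < st.nM; m++) {
      if ((int)G.mts.size() >= cap) break;
      if (std::find(G.mts.begin(), G.mts.end(), m) != G.mts.end()) continue;
      double dx, dy;
      sep(st.dom, G.x, G.y, st.px[m], st.py[m], dx, dy);
      double d = std::sqrt(dx * dx + dy * dy) - ro - pc.rM;
      if (d <= pc.Rb && S.rng.unif() < pon) G.mts.push_back(m);
    }
  }
}

// drop organelles that have fully crossed the section (z >= a)
static void org_departures(Sim &S) {
  State &st = S.st;
  for (size_t o = st.orgs.size(); o-- > 0;) {
    if (st.orgs[o].z >= st.orgs[o].a) {
      st.orgs.erase(st.orgs.begin() + o);
      S.cnt.org_departs++;
    }
  }
}

// ---------------------------------------------------------------------------
// R <-> C++ conversion (lowered representations, see R/state.R)
// ---------------------------------------------------------------------------
static State state_from_R(List s) {
  State st;
  NumericMatrix mt = s["mt"], nf = s["nf"];
  st.nM = mt.nrow();
  st.nN = nf.nrow();
  st.px.resize(st.nM + st.nN);
  st.py.resize(st.nM + st.nN);
  for (int i = 0; i < st.nM; i++) { st.px[i] = mt(i, 0); st.py[i] = mt(i, 1); }
  for (int i = 0; i < st.nN; i++) {
    st.px[st.nM + i] = nf(i, 0);
    st.py[st.nM + i] = nf(i, 1);
  }
  NumericVector ox = s["org_x"], oy = s["org_y"], oz = s["org_z"],
                oa = s["org_a"], ob = s["org_b"];
  for (int o = 0; o < ox.size(); o++) {
    Org G;
    G.x = ox[o]; G.y = oy[o]; G.z = oz[o]; G.a = oa[o]; G.b = ob[o];
    st.orgs.push_back(G);
  }
  st.dom.kind = as<int>(s["dom_kind"]);
  st.dom.size = as<double>(s["dom_size"]);
  st.nfb.assign(st.nN, -1);
  return st;
}

static void bonds_from_R(State &st, List b) {
  IntegerVector nfb = b["nf"];
  for (int f = 0; f < st.nN && f < nfb.size(); f++) st.nfb[f] = nfb[f];
  List ob = b["org"];
  for (int o = 0; o < (int)st.orgs.size() && o < ob.size(); o++) {
    IntegerVector v = ob[o];
    st.orgs[o].mts.assign(v.begin(), v.end());
  }
}

static List state_to_R(const State &st) {
  NumericMatrix mt(st.nM, 2), nf(st.nN, 2);
  for (int i = 0; i < st.nM; i++) { mt(i, 0) = st.px[i]; mt(i, 1) = st.py[i]; }
  for (int i = 0; i < st.nN; i++) {
    nf(i, 0) = st.px[st.nM + i];
    nf(i, 1) = st.py[st.nM + i];
  }
  int nO = (int)st.orgs.size();
  NumericVector ox(nO), oy(nO), oz(nO), oa(nO), ob(nO);
  for (int o = 0; o < nO; o++) {
    ox[o] = st.orgs[o].x; oy[o] = st.orgs[o].y; oz[o] = st.orgs[o].z;
    oa[o] = st.orgs[o].a; ob[o] = st.orgs[o].b;
  }
  return List::create(
      _["mt"] = mt, _["nf"] = nf, _["org_x"] = ox, _["org_y"] = oy,
      _["org_z"] = oz, _["org_a"] = oa, _["org_b"] = ob,
      _["dom_kind"] = st.dom.kind, _["dom_size"] = st.dom.size);
}

static List bonds_to_R(const State &st) {
  IntegerVector nfb(st.nN);
  for (int f = 0; f < st.nN; f++) nfb[f] = st.nfb[f];
  List ob(st.orgs.size());
  for (size_t o = 0; o < st.orgs.size(); o++) {
    ob[o] = IntegerVector(st.orgs[o].mts.begin(), st.orgs[o].mts.end());
  }
  return List::create(_["nf"] = nfb, _["org"] = ob);
}

static Sim make_sim(List state, List bonds, NumericVector par, int seed) {
  Sim S;
  S.st = state_from_R(state);
  bonds_from_R(S.st, bonds);
  S.par.assign(par.begin(), par.end());
  if ((int)S.par.size() != P_NPAR) stop("parameter vector has wrong length");
  S.reload();
  S.rng.seed((uint64_t)(int64_t)seed);
  return S;
}

static double mean_pdmt(const State &st) {
  if (st.nM < 2) return NA_REAL;
  double s = 0;
  long n = 0;
  for (int i = 0; i < st.nM; i++) {
    for (int j = i + 1; j < st.nM; j++) {
      double dx, dy;
      sep(st.dom, st.px[i], st.py[i], st.px[j], st.py[j], dx, dy);
      s += std::sqrt(dx * dx + dy * dy);
      n++;
    }
  }
  return s / n;
}

// ---------------------------------------------------------------------------
// exported single-step operations (each call owns a stream seeded by `seed`)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_forces(List state, List bonds, NumericVector par) {
  Sim S = make_sim(state, bonds, par, 1);
  pairs_build(S);
  bool contact = forces_eval(S);
  int nM = S.st.nM, nN = S.st.nN, nO = (int)S.st.orgs.size();
  NumericMatrix fmt(nM, 2), fnf(nN, 2), forg(nO, 2);
  for (int i = 0; i < nM; i++) { fmt(i, 0) = S.fx[i]; fmt(i, 1) = S.fy[i]; }
  for (int i = 0; i < nN; i++) {
    fnf(i, 0) = S.fx[nM + i];
    fnf(i, 1) = S.fy[nM + i];
  }
  for (int o = 0; o < nO; o++) { forg(o, 0) = S.ofx[o]; forg(o, 1) = S.ofy[o]; }
  return List::create(_["mt"] = fmt, _["nf"] = fnf, _["org"] = forg,
                      _["contact"] = contact);
}

// [[Rcpp::export]]
List cpp_em_step(List state, List bonds, NumericVector par, double h,
                 int seed) {
  Sim S = make_sim(state, bonds, par, seed);
  double t = 0;
  advance_mech(S, h, t, h);
  return List::create(_["state"] = state_to_R(S.st),
                      _["bonds"] = bonds_to_R(S.st), _["h_used"] = h,
                      _["rejects"] = (double)S.cnt.rejects);
}

// [[Rcpp::export]]
List cpp_nf_kinetics(List state, List bonds, NumericVector par, double h,
                     int seed) {
  Sim S = make_sim(state, bonds, par, seed);
  nf_kinetics(S, h);
  return List::create(
      _["state"] = state_to_R(S.st), _["bonds"] = bonds_to_R(S.st),
      _["events"] = NumericVector::create(
          _["binds"] = (double)S.cnt.nf_binds,
          _["unbinds"] = (double)S.cnt.nf_unbinds,
          _["departs"] = (double)S.cnt.nf_departs,
          _["cancelled"] = (double)S.cnt.nf_cancelled));
}

// [[Rcpp::export]]
List cpp_org_arrival(List state, List bonds, NumericVector par, double h,
                     int seed) {
  Sim S = make_sim(state, bonds, par, seed);
  org_arrival(S, h);
  return List::create(_["state"] = state_to_R(S.st),
                      _["bonds"] = bonds_to_R(S.st),
                      _["arrived"] = (double)S.cnt.org_arrivals,
                      _["deferred"] = (double)S.cnt.org_deferred);
}

// [[Rcpp::export]]
List cpp_org_binding(List state, List bonds, NumericVector par, double h,
                     int seed) {
  Sim S = make_sim(state, bonds, par, seed);
  org_binding(S, h);
  return List::create(_["state"] = state_to_R(S.st),
                      _["bonds"] = bonds_to_R(S.st));
}

// ---------------------------------------------------------------------------
// fused simulation loop
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(List state, List bonds, NumericVector par, List schedule,
             double t_end, double series_dt, double snapshot_dt, int seed,
             bool strict_kinetics) {
  Sim S = make_sim(state, bonds, par, seed);
  NumericVector sc_time = schedule["time"];
  IntegerVector sc_idx = schedule["idx"];
  NumericVector sc_val = schedule["value"];
  int sp = 0, nsc = sc_time.size();

  std::vector<double> ser_t, ser_pdmt, ser_bound, ser_norg;
  List snapshots;
  auto record_series = [&](double t) {
    ser_t.push_back(t);
    ser_pdmt.push_back(mean_pdmt(S.st));
    double nb = 0;
    for (int f = 0; f < S.st.nN; f++)
      if (S.st.nfb[f] >= 0) nb++;
    ser_bound.push_back(S.st.nN > 0 ? nb / S.st.nN : NA_REAL);
    ser_norg.push_back((double)S.st.orgs.size());
  };
  auto take_snapshot = [&](double t) {
    snapshots.push_back(List::create(_["t"] = t, _["state"] = state_to_R(S.st),
                                     _["bonds"] = bonds_to_R(S.st)));
  };

  double t = 0;
  record_series(0.0);
  bool do_snap = snapshot_dt > 0;
  if (do_snap) take_snapshot(0.0);
  double next_series = series_dt > 0 ? series_dt : R_PosInf;
  double next_snap = do_snap ? snapshot_dt : R_PosInf;

  while (t < t_end - 1e-9) {
    while (sp < nsc && sc_time[sp] <= t + 1e-9) {
      S.par[sc_idx[sp]] = sc_val[sp];
      S.reload();
      sp++;
    }
    double tick = std::min(S.pc.h_slow, t_end - t);
    if (!strict_kinetics) {
      // NF replacement invalidates the pair list internally; organelles are
      // not part of the Verlet list, so arrivals/engagements need nothing
      nf_kinetics(S, tick);
      org_arrival(S, tick);
      org_binding(S, tick);
    }
    if (strict_kinetics) {
      double remaining = tick;
      while (remaining > 1e-12) {
        bool fast = !S.st.orgs.empty();
        double h = fast ? S.pc.h_fast : S.pc.h_slow;
        if (h > remaining) h = remaining;
        nf_kinetics(S, h);
        org_arrival(S, h);
        org_binding(S, h);
        advance_mech(S, h, t);
        remaining -= h;
      }
    } else {
      advance_mech(S, tick, t);
    }
    if (t + 1e-9 >= next_series) {
      record_series(t);
      while (next_series <= t + 1e-9) next_series += series_dt;
    }
    if (t + 1e-9 >= next_snap) {
      take_snapshot(t);
      while (next_snap <= t + 1e-9) next_snap += snapshot_dt;
    }
  }

  NumericVector counters = NumericVector::create(
      _["slow_steps"] = (double)S.cnt.slow_steps,
      _["fast_steps"] = (double)S.cnt.fast_steps,
      _["rejects"] = (double)S.cnt.rejects,
      _["nf_binds"] = (double)S.cnt.nf_binds,
      _["nf_unbinds"] = (double)S.cnt.nf_unbinds,
      _["nf_departs"] = (double)S.cnt.nf_departs,
      _["nf_cancelled"] = (double)S.cnt.nf_cancelled,
      _["org_arrivals"] = (double)S.cnt.org_arrivals,
      _["org_deferred"] = (double)S.cnt.org_deferred,
      _["org_departs"] = (double)S.cnt.org_departs,
      _["pairlist_rebuilds"] = (double)S.cnt.rebuilds);

  return List::create(
      _["series"] = List::create(
          _["t"] = NumericVector(ser_t.begin(), ser_t.end()),
          _["pdmt_mean"] = NumericVector(ser_pdmt.begin(), ser_pdmt.end()),
          _["bound_frac"] = NumericVector(ser_bound.begin(), ser_bound.end()),
          _["n_org"] = NumericVector(ser_norg.begin(), ser_norg.end())),
      _["snapshots"] = snapshots, _["final_state"] = state_to_R(S.st),
      _["final_bonds"] = bonds_to_R(S.st), _["t_final"] = t,
      _["counters"] = counters,
      _["params_final"] = NumericVector(S.par.begin(), S.par.end()));
}
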