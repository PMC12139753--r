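// Particle-based engine for flat clathrin lattice assembly/disassembly.
//
// Units: positions in nm, time in s, diffusion coefficients in nm^2/s
// (rotational in 1/s).  All stochastic draws use R's RNG so a single
// set.seed() on the R side makes runs reproducible.
//
// Body frame of a clathrin: center at origin, the three leg sites at
// angles 0/120/240 degrees in the xy-plane at distance `leg`, the AP-2
// binding arm along -z at distance `arm`.  A membrane-bound clathrin has
// its plane parallel to z = 0, arm pointing down, center at z = arm.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const double ANTIPAR_TOL_NM = 0.5; // ring-closure site mismatch tolerance

// Fast internal PRNG (xoshiro256++), seeded from R's RNG at engine entry so
// that set.seed() on the R side fully determines a run.  R's generators are
// too slow for the ~10^3 draws per 3-microsecond timestep.
struct FastRng {
  uint64_t s[4];
  double cachedNorm = 0;
  bool hasNorm = false;

  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seedFromR() {
    uint64_t x = (uint64_t)(unif_rand() * 9007199254740992.0);
    x ^= (uint64_t)(unif_rand() * 9007199254740992.0) << 11;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    hasNorm = false;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {              // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {              // Marsaglia polar
    if (hasNorm) { hasNorm = false; return cachedNorm; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cachedNorm = v * f;
    hasNorm = true;
    return u * f;
  }
};

// ---------------------------------------------------------------- quaternions

static inline void qnormalize(double* q) {
  double n = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  for (int d = 0; d < 4; ++d) q[d] /= n;
}

static inline void qmul(const double* a, const double* b, double* out) {
  out[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  out[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  out[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  out[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
}

// rotate vector v by unit quaternion q
static inline void qrot(const double* q, const double* v, double* out) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  double t0 = 2.0*(y*v[2] - z*v[1]);
  double t1 = 2.0*(z*v[0] - x*v[2]);
  double t2 = 2.0*(x*v[1] - y*v[0]);
  out[0] = v[0] + w*t0 + (y*t2 - z*t1);
  out[1] = v[1] + w*t1 + (z*t0 - x*t2);
  out[2] = v[2] + w*t2 + (x*t1 - y*t0);
}

// quaternion from rotation vector (axis * angle)
static inline void qfromrotvec(const double* w, double* q) {
  double a = std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
  if (a < 1e-14) { q[0] = 1; q[1] = q[2] = q[3] = 0; return; }
  double h = 0.5*a, s = std::sin(h)/a;
  q[0] = std::cos(h); q[1] = w[0]*s; q[2] = w[1]*s; q[3] = w[2]*s;
}

// quaternion from a rotation matrix (columns m[0..2], m[3..5], m[6..8])
static inline void qfrommat(const double* m, double* q) {
  // m is column-major 3x3
  double tr = m[0] + m[4] + m[8];
  if (tr > 0) {
    double s = std::sqrt(tr + 1.0) * 2.0;
    q[0] = 0.25*s;
    q[1] = (m[5] - m[7]) / s;
    q[2] = (m[6] - m[2]) / s;
    q[3] = (m[1] - m[3]) / s;
  } else if (m[0] > m[4] && m[0] > m[8]) {
    double s = std::sqrt(1.0 + m[0] - m[4] - m[8]) * 2.0;
    q[0] = (m[5] - m[7]) / s;
    q[1] = 0.25*s;
    q[2] = (m[3] + m[1]) / s;
    q[3] = (m[6] + m[2]) / s;
  } else if (m[4] > m[8]) {
    double s = std::sqrt(1.0 + m[4] - m[0] - m[8]) * 2.0;
    q[0] = (m[6] - m[2]) / s;
    q[1] = (m[3] + m[1]) / s;
    q[2] = 0.25*s;
    q[3] = (m[7] + m[5]) / s;
  } else {
    double s = std::sqrt(1.0 + m[8] - m[0] - m[4]) * 2.0;
    q[0] = (m[1] - m[3]) / s;
    q[1] = (m[6] + m[2]) / s;
    q[2] = (m[7] + m[5]) / s;
    q[3] = 0.25*s;
  }
  qnormalize(q);
}

static inline void matvec(const double* m, const double* v, double* out) {
  out[0] = m[0]*v[0] + m[3]*v[1] + m[6]*v[2];
  out[1] = m[1]*v[0] + m[4]*v[1] + m[7]*v[2];
  out[2] = m[2]*v[0] + m[5]*v[1] + m[8]*v[2];
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}

// ------------------------------------------------------------- site geometry

// site s (0..2 legs, 3 = AP-2 arm tip) of a clathrin with center c, quat q
static inline void siteOf(const double* c, const double* q, double leg,
                          double arm, int s, double* out) {
  static const double COS120 = -0.5, SIN120 = 0.8660254037844386;
  double body[3];
  if (s == 0)      { body[0] = leg;        body[1] = 0;            body[2] = 0; }
  else if (s == 1) { body[0] = leg*COS120; body[1] = leg*SIN120;   body[2] = 0; }
  else if (s == 2) { body[0] = leg*COS120; body[1] = -leg*SIN120;  body[2] = 0; }
  else             { body[0] = 0;          body[1] = 0;            body[2] = -arm; }
  double r[3];
  qrot(q, body, r);
  out[0] = c[0] + r[0]; out[1] = c[1] + r[1]; out[2] = c[2] + r[2];
}

static inline void normalOf(const double* q, double* out) {
  double ez[3] = {0, 0, 1};
  qrot(q, ez, out);
}

// rigid transform placing molecule B (leg site sb) head-to-head against the
// fixed molecule A (leg site sa): bound sites `bond` nm apart, collinear with
// the A-center/site axis, both molecule planes coplanar with consistent
// normals.  Returns rotation M (column-major) and pivot/target so that
//   x' = M (x - pivot) + target
// maps any point rigidly attached to B.
static void placeTransform(const double* cA, const double* qA, int sa,
                           const double* cB, const double* qB, int sb,
                           double leg, double arm, double bond,
                           double* M, double* pivot, double* target) {
  double pA[3], pB[3], nA[3], nB[3], uA[3], uB[3];
  siteOf(cA, qA, leg, arm, sa, pA);
  siteOf(cB, qB, leg, arm, sb, pB);
  normalOf(qA, nA);
  normalOf(qB, nB);
  for (int d = 0; d < 3; ++d) {
    uA[d] = (pA[d] - cA[d]) / leg;
    uB[d] = (pB[d] - cB[d]) / leg;
    target[d] = pA[d] + bond*uA[d];
    pivot[d] = pB[d];
  }
  // target triad: (-uA, nA x -uA, nA); source triad: (uB, nB x uB, nB)
  double a1[3] = {-uA[0], -uA[1], -uA[2]}, a2[3], b2[3];
  cross3(nA, a1, a2);
  cross3(nB, uB, b2);
  // M = TA * TB^T  with TA = [a1 a2 nA], TB = [uB b2 nB]
  double TA[9] = {a1[0],a1[1],a1[2], a2[0],a2[1],a2[2], nA[0],nA[1],nA[2]};
  double TB[9] = {uB[0],uB[1],uB[2], b2[0],b2[1],b2[2], nB[0],nB[1],nB[2]};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += TA[k*3+i] * TB[k*3+j];
      M[j*3+i] = s;
    }
}

// ------------------------------------------------------------------ exports

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_sites(NumericVector center, NumericVector quat,
                        double leg, double arm) {
  NumericMatrix out(4, 3);
  double c[3] = {center[0], center[1], center[2]};
  double q[4] = {quat[0], quat[1], quat[2], quat[3]};
  double p[3];
  for (int s = 0; s < 4; ++s) {
    siteOf(c, q, leg, arm, s, p);
    for (int d = 0; d < 3; ++d) out(s, d) = p[d];
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
List cpp_place_pair(NumericVector centerA, NumericVector quatA, int siteA,
                    NumericVector centerB, NumericVector quatB, int siteB,
                    double leg, double arm, double bond) {
  double cA[3] = {centerA[0], centerA[1], centerA[2]};
  double qA[4] = {quatA[0], quatA[1], quatA[2], quatA[3]};
  double cB[3] = {centerB[0], centerB[1], centerB[2]};
  double qB[4] = {quatB[0], quatB[1], quatB[2], quatB[3]};
  double M[9], pivot[3], target[3];
  placeTransform(cA, qA, siteA - 1, cB, qB, siteB - 1, leg, arm, bond,
                 M, pivot, target);
  double tmp[3], cNew[3];
  for (int d = 0; d < 3; ++d) tmp[d] = cB[d] - pivot[d];
  matvec(M, tmp, cNew);
  for (int d = 0; d < 3; ++d) cNew[d] += target[d];
  double qM[4], qNew[4];
  qfrommat(M, qM);
  qmul(qM, qB, qNew);
  qnormalize(qNew);
  return List::create(_["center"] = NumericVector::create(cNew[0], cNew[1], cNew[2]),
                      _["quat"] = NumericVector::create(qNew[0], qNew[1], qNew[2], qNew[3]));
}

// ------------------------------------------------------------------- engine

// uniform cell list over clathrin centers; cell size >= every interaction
// cutoff, so the 27-cell neighborhood is complete for any query
struct CellGrid {
  int nx = 0;
  double cell = 0, L = 0;
  bool per = false, active = false;
  std::vector<int> head, nxt, cellOf;

  void build(const std::vector<double>& pos, int n, double L_, double cutoff,
             bool periodic) {
    L = L_; per = periodic;
    nx = (int)std::floor(L / cutoff);
    if (nx > 16) nx = 16;     // keep the head array cache-resident
    active = nx >= 4 && n >= 64;
    if (!active) return;
    cell = L / nx;
    head.assign((size_t)nx * nx * nx, -1);
    nxt.assign(n, -1);
    cellOf.assign(n, -1);
    for (int i = 0; i < n; ++i) insert(i, &pos[i * 3]);
  }
  inline int clampc(int v) const { return v < 0 ? 0 : (v >= nx ? nx - 1 : v); }
  inline int idx(const double* p) const {
    int ix = clampc((int)(p[0] / cell));
    int iy = clampc((int)(p[1] / cell));
    int iz = clampc((int)(p[2] / cell));
    return (iz * nx + iy) * nx + ix;
  }
  void insert(int i, const double* p) {
    int c = idx(p);
    nxt[i] = head[c];
    head[c] = i;
    cellOf[i] = c;
  }
  void remove(int i) {
    int c = cellOf[i];
    if (c < 0) return;
    int j = head[c];
    if (j == i) head[c] = nxt[i];
    else {
      while (nxt[j] != i) j = nxt[j];
      nxt[j] = nxt[i];
    }
    cellOf[i] = -1;
  }
  void move(int i, const double* p) {
    if (!active) return;
    int c = idx(p);
    if (c == cellOf[i]) return;
    remove(i);
    insert(i, p);
  }
  // visit molecule indices in the 27-cell neighborhood of p; F returns
  // true to stop early
  template <class F> bool visit(const double* p, F f) const {
    int ix = clampc((int)(p[0] / cell));
    int iy = clampc((int)(p[1] / cell));
    int iz = clampc((int)(p[2] / cell));
    for (int dz = -1; dz <= 1; ++dz) {
      int z = iz + dz;
      if (z < 0 || z >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = iy + dy;
        if (per) y = (y + nx) % nx;
        else if (y < 0 || y >= nx) continue;
        for (int dxc = -1; dxc <= 1; ++dxc) {
          int x = ix + dxc;
          if (per) x = (x + nx) % nx;
          else if (x < 0 || x >= nx) continue;
          for (int j = head[(z * nx + y) * nx + x]; j >= 0; j = nxt[j])
            if (f(j)) return true;
        }
      }
    }
    return false;
  }

  // collect molecule indices in the 27-cell neighborhood of p
  void gather(const double* p, std::vector<int>& out) const {
    out.clear();
    int ix = clampc((int)(p[0] / cell));
    int iy = clampc((int)(p[1] / cell));
    int iz = clampc((int)(p[2] / cell));
    for (int dz = -1; dz <= 1; ++dz) {
      int z = iz + dz;
      if (z < 0 || z >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = iy + dy;
        if (per) y = (y + nx) % nx;
        else if (y < 0 || y >= nx) continue;
        for (int dxc = -1; dxc <= 1; ++dxc) {
          int x = ix + dxc;
          if (per) x = (x + nx) % nx;
          else if (x < 0 || x >= nx) continue;
          for (int j = head[(z * nx + y) * nx + x]; j >= 0; j = nxt[j])
            out.push_back(j);
        }
      }
    }
  }
};

struct Engine {
  int n;  // clathrins
  int m;  // AP-2s
  std::vector<double> pos, quat;       // n*3, n*4
  std::vector<int> comp;               // 0 cytosol, 1 membrane
  std::vector<int> legb, legbs;        // n*3 partner index / partner site (-1 free)
  std::vector<int> ap2b;               // n: AP-2 index or -1
  std::vector<double> apos;            // m*2
  std::vector<int> abond;              // m: clathrin index or -1
  std::vector<int> creact, areact;     // per-step reacted flags
  double time;

  // parameters
  double L, leg, arm, bondLen, excl, sigma, dt;
  double p3cc, p2cc, p3ca, p2ca, poffcc, poffca;
  double Dct, Dcr, Dat;                // nm^2/s, 1/s, nm^2/s
  bool periodic, allowSol, ccNeedsAnchor;
  int maxRetry;

  long skippedMoves = 0, placementRejects = 0;

  // event log
  std::vector<double> evTime;
  std::vector<int> evType, evId1, evS1, evId2, evS2;

  // scratch
  std::vector<int> parent, rankv;
  std::vector<double> sites;           // n*12 cache
  CellGrid grid;
  std::vector<int> nbuf;
  FastRng rng;
  std::vector<char> hasFree;            // clathrin has >= 1 free leg
  std::vector<int> propIdx;             // member -> row in proposal buffers
  std::vector<int> rootSlot, compOrder, compStart;
  std::vector<int> memBuf, apsBuf;
  std::vector<double> propP, propQb, propAb;

  double excl2, sigma2, cutcc2, cutmax;

  void derive() {
    excl2 = 4.0*excl*excl;
    sigma2 = sigma*sigma;
    double c = 2.0*leg + sigma;
    cutcc2 = c*c;
    cutmax = std::max(c, 2.0*excl);
  }

  inline double dx(double a, double b) const {  // minimal-image lateral delta
    double d = a - b;
    if (periodic) { if (d > 0.5*L) d -= L; else if (d < -0.5*L) d += L; }
    return d;
  }
  inline double dist2(const double* a, const double* b) const {
    double d0 = dx(a[0], b[0]), d1 = dx(a[1], b[1]), d2 = a[2] - b[2];
    return d0*d0 + d1*d1 + d2*d2;
  }

  // ---- union-find over clathrin-clathrin bonds
  int find(int i) { while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; } return i; }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (rankv[a] < rankv[b]) std::swap(a, b);
    parent[b] = a;
    if (rankv[a] == rankv[b]) rankv[a]++;
  }
  void buildComponents() {
    parent.resize(n); rankv.assign(n, 0);
    for (int i = 0; i < n; ++i) parent[i] = i;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        if (legb[i*3+k] > i) unite(i, legb[i*3+k]);
  }

  void cacheSites() {
    sites.resize(n*12);
    for (int i = 0; i < n; ++i)
      for (int s = 0; s < 4; ++s)
        siteOf(&pos[i*3], &quat[i*4], leg, arm, s, &sites[i*12 + s*3]);
  }

  // any membrane member -> whole component membrane; else cytosol
  void refreshCompartments() {
    buildComponents();
    std::vector<char> anchored(n, 0);
    for (int i = 0; i < n; ++i)
      if (ap2b[i] >= 0) anchored[find(i)] = 1;
    for (int i = 0; i < n; ++i)
      comp[i] = anchored[find(i)] ? 1 : 0;
  }

  // snap a membrane molecule to the exact manifold: center z = arm,
  // quaternion a pure z-rotation
  void snapMembrane(int i) {
    pos[i*3+2] = arm;
    double* q = &quat[i*4];
    double nrm = std::sqrt(q[0]*q[0] + q[3]*q[3]);
    if (nrm > 1e-9) { q[0] /= nrm; q[1] = 0; q[2] = 0; q[3] /= nrm; }
  }

  inline bool inBox(const double* p) const {
    if (p[2] < 0 || p[2] > L) return false;
    if (!periodic && (p[0] < 0 || p[0] > L || p[1] < 0 || p[1] > L)) return false;
    return true;
  }
  inline void wrapLateral(double* p) const {
    if (!periodic) return;
    p[0] -= L*std::floor(p[0]/L);
    p[1] -= L*std::floor(p[1]/L);
  }

  // overlap of proposed member positions against all non-member clathrins;
  // `exA`/`exB` is an optional about-to-be-bonded pair (exempt)
  bool overlaps(const std::vector<int>& members, const std::vector<double>& prop,
                const std::vector<char>& inSet, int exA = -1, int exB = -1) {
    for (size_t a = 0; a < members.size(); ++a) {
      const double* pa = &prop[a*3];
      int i = members[a];
      if (grid.active) {
        if (grid.visit(pa, [&](int j) {
              if (inSet[j]) return false;
              if ((i == exA && j == exB) || (i == exB && j == exA)) return false;
              return dist2(pa, &pos[j*3]) < excl2;
            })) return true;
      } else {
        for (int j = 0; j < n; ++j) {
          if (inSet[j]) continue;
          if ((i == exA && j == exB) || (i == exB && j == exA)) continue;
          if (dist2(pa, &pos[j*3]) < excl2) return true;
        }
      }
    }
    return false;
  }

  // overlap test for a moved rigid set, outsider-centric: cheap when the
  // set is large and dense (lattice) because only boundary cells contain
  // non-members.  propIdx must map member -> row of `prop`.
  bool overlapsBig(const std::vector<int>& mem, const std::vector<double>& prop,
                   const std::vector<char>& inSet) {
    double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
    for (size_t a = 0; a < mem.size(); ++a)
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], prop[a*3+d]);
        hi[d] = std::max(hi[d], prop[a*3+d]);
      }
    double margin = 2.0*excl + grid.cell;
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      c0[d] = (int)std::floor((lo[d] - margin) / grid.cell);
      c1[d] = (int)std::floor((hi[d] + margin) / grid.cell);
      if (!periodic || d == 2) {
        c0[d] = std::max(c0[d], 0);
        c1[d] = std::min(c1[d], grid.nx - 1);
      } else if (c1[d] - c0[d] >= grid.nx) {
        c0[d] = 0; c1[d] = grid.nx - 1;
      }
    }
    for (int cz = c0[2]; cz <= c1[2]; ++cz)
      for (int cy = c0[1]; cy <= c1[1]; ++cy)
        for (int cx = c0[0]; cx <= c1[0]; ++cx) {
          int x = periodic ? ((cx % grid.nx) + grid.nx) % grid.nx : cx;
          int y = periodic ? ((cy % grid.nx) + grid.nx) % grid.nx : cy;
          int cell = (cz * grid.nx + y) * grid.nx + x;
          for (int j = grid.head[cell]; j >= 0; j = grid.nxt[j]) {
            if (inSet[j]) continue;
            if (grid.visit(&pos[j*3], [&](int e) {
                  return inSet[e] &&
                         dist2(&prop[propIdx[e]*3], &pos[j*3]) < excl2;
                })) return true;
          }
        }
    return false;
  }

  void event(int type, int i1, int s1, int i2, int s2) {
    evTime.push_back(time); evType.push_back(type);
    evId1.push_back(i1 + 1); evS1.push_back(s1 + 1);
    evId2.push_back(i2 + 1); evS2.push_back(s2 + 1);
  }

  // -------------------------------------------------------- dissociation
  void dissociationSweep() {
    // bond list: (i, k) leg bonds with partner > i; (i, -1) AP-2 bonds
    static std::vector<std::pair<int,int> > bonds;
    bonds.clear();
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < 3; ++k)
        if (legb[i*3+k] > i) bonds.push_back(std::make_pair(i, k));
      if (ap2b[i] >= 0) bonds.push_back(std::make_pair(i, -1));
    }
    // Fisher-Yates shuffle (random sweep order)
    for (int b = (int)bonds.size() - 1; b > 0; --b) {
      int j = (int)(rng.unif() * (b + 1));
      if (j > b) j = b;
      std::swap(bonds[b], bonds[j]);
    }
    bool broke = false;
    for (size_t b = 0; b < bonds.size(); ++b) {
      int i = bonds[b].first, k = bonds[b].second;
      if (creact[i]) continue;
      if (k >= 0) {                       // clathrin-clathrin
        int j = legb[i*3+k];
        if (j < 0 || creact[j]) continue;
        if (rng.unif() < poffcc) {
          int ks = legbs[i*3+k];
          legb[i*3+k] = -1; legbs[i*3+k] = -1;
          legb[j*3+ks] = -1; legbs[j*3+ks] = -1;
          creact[i] = creact[j] = 1;
          event(1, i, k, j, ks);
          broke = true;
        }
      } else {                            // clathrin-AP-2
        int a = ap2b[i];
        if (areact[a]) continue;
        if (rng.unif() < poffca) {
          ap2b[i] = -1; abond[a] = -1;
          creact[i] = 1; areact[a] = 1;
          event(3, i, 3, a, -1);
          broke = true;
        }
      }
    }
    if (broke) refreshCompartments();
  }

  // --------------------------------------------------------- association
  struct Cand { int type; int i, ki, j, kj; double p; }; // type 0 cc, 1 ca

  void associationSweep() {
    if (p3cc <= 0 && p2cc <= 0 && p3ca <= 0 && p2ca <= 0) return;
    buildComponents();
    cacheSites();
    bool anyMembrane = false;
    for (int i = 0; i < n; ++i) if (comp[i] == 1) { anyMembrane = true; break; }
    bool scanCC = allowSol || anyMembrane;
    static std::vector<Cand> cands;
    cands.clear();
    // clathrin-clathrin leg pairs
    auto tryPair = [&](int i, int j) {
      bool memI = comp[i] == 1, memJ = comp[j] == 1;
      if (!memI && !memJ && !allowSol) return;
      if (ccNeedsAnchor && (memI || memJ)) {
        // recruitment happens at AP-2-bound clathrins; within one lattice
        // (ring closure) the geometry, not the anchor, gates the bond
        if (ap2b[i] < 0 && ap2b[j] < 0 && find(i) != find(j)) return;
      }
      if (dist2(&pos[i*3], &pos[j*3]) > cutcc2) return;
      for (int ki = 0; ki < 3; ++ki) {
        if (legb[i*3+ki] >= 0) continue;
        for (int kj = 0; kj < 3; ++kj) {
          if (legb[j*3+kj] >= 0) continue;
          if (dist2(&sites[i*12+ki*3], &sites[j*12+kj*3]) <= sigma2) {
            Cand c; c.type = 0; c.i = i; c.ki = ki; c.j = j; c.kj = kj;
            c.p = (memI && memJ) ? p2cc : p3cc;
            cands.push_back(c);
          }
        }
      }
    };
    hasFree.assign(n, 0);
    for (int i = 0; i < n; ++i)
      hasFree[i] = legb[i*3] < 0 || legb[i*3+1] < 0 || legb[i*3+2] < 0;
    double zmax_cc = arm + 2.0*leg + sigma;   // membrane partners live at z = arm
    if (scanCC && grid.active) {
      for (int i = 0; i < n; ++i) {
        if (!hasFree[i]) continue;
        if (!allowSol && comp[i] == 0 && pos[i*3+2] > zmax_cc) continue;
        grid.gather(&pos[i*3], nbuf);
        for (size_t b = 0; b < nbuf.size(); ++b) {
          int j = nbuf[b];
          if (j > i && hasFree[j]) tryPair(i, j);
        }
      }
    } else if (scanCC) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) tryPair(i, j);
    }
    for (int i = 0; i < n; ++i) {
      // clathrin arm + free AP-2
      if (ap2b[i] < 0) {
        const double* tip = &sites[i*12 + 9];
        bool memI = comp[i] == 1;
        if (tip[2] > sigma) continue;    // arm too far above the membrane
        for (int a = 0; a < m; ++a) {
          if (abond[a] >= 0) continue;
          double ap[3] = {apos[a*2], apos[a*2+1], 0.0};
          double d2 = memI
            ? dx(tip[0], ap[0])*dx(tip[0], ap[0]) + dx(tip[1], ap[1])*dx(tip[1], ap[1])
            : dist2(tip, ap);
          if (d2 <= sigma2) {
            Cand c; c.type = 1; c.i = i; c.ki = 3; c.j = a; c.kj = -1;
            c.p = memI ? p2ca : p3ca;
            cands.push_back(c);
          }
        }
      }
    }
    for (int b = (int)cands.size() - 1; b > 0; --b) {
      int j = (int)(rng.unif() * (b + 1));
      if (j > b) j = b;
      std::swap(cands[b], cands[j]);
    }
    for (size_t c = 0; c < cands.size(); ++c) {
      const Cand& cd = cands[c];
      if (cd.type == 0) attemptCC(cd);
      else attemptCA(cd);
    }
  }

  void componentOf(int i, std::vector<int>& members, std::vector<int>& ap2s,
                   std::vector<char>& inSet) {
    members.clear(); ap2s.clear();
    inSet.assign(n, 0);
    int r = find(i);
    for (int j = 0; j < n; ++j)
      if (find(j) == r) {
        members.push_back(j);
        inSet[j] = 1;
        if (ap2b[j] >= 0) ap2s.push_back(ap2b[j]);
      }
  }

  bool componentAnchored(const std::vector<int>& members) {
    for (size_t a = 0; a < members.size(); ++a)
      if (ap2b[members[a]] >= 0) return true;
    return false;
  }

  void attemptCC(const Cand& cd) {
    int i = cd.i, ki = cd.ki, j = cd.j, kj = cd.kj;
    if (creact[i] || creact[j]) return;
    if (legb[i*3+ki] >= 0 || legb[j*3+kj] >= 0) return;
    if (rng.unif() >= cd.p) return;

    if (find(i) == find(j)) {            // ring closure within one lattice
      double M[9], pivot[3], target[3], pB[3];
      placeTransform(&pos[i*3], &quat[i*4], ki, &pos[j*3], &quat[j*4], kj,
                     leg, arm, bondLen, M, pivot, target);
      siteOf(&pos[j*3], &quat[j*4], leg, arm, kj, pB);
      double miss = std::sqrt((pB[0]-target[0])*(pB[0]-target[0]) +
                              (pB[1]-target[1])*(pB[1]-target[1]) +
                              (pB[2]-target[2])*(pB[2]-target[2]));
      if (miss > ANTIPAR_TOL_NM) { placementRejects++; return; }
      legb[i*3+ki] = j; legbs[i*3+ki] = kj;
      legb[j*3+kj] = i; legbs[j*3+kj] = ki;
      creact[i] = creact[j] = 1;
      event(0, i, ki, j, kj);
      return;
    }

    // decide which component moves: unanchored one, else the smaller
    std::vector<int> memI, memJ, apI, apJ;
    std::vector<char> setI, setJ;
    componentOf(i, memI, apI, setI);
    componentOf(j, memJ, apJ, setJ);
    bool ancI = componentAnchored(memI), ancJ = componentAnchored(memJ);
    int ai = i, aki = ki, bi = j, bki = kj;         // a = fixed, b = moved
    std::vector<int>* memB = &memJ; std::vector<int>* apB = &apJ;
    std::vector<char>* setB = &setJ;
    bool moveI = false;
    if (ancI && !ancJ) moveI = false;
    else if (ancJ && !ancI) moveI = true;
    else moveI = memI.size() < memJ.size();
    if (moveI) {
      ai = j; aki = kj; bi = i; bki = ki;
      memB = &memI; apB = &apI; setB = &setI;
    }

    double M[9], pivot[3], target[3];
    placeTransform(&pos[ai*3], &quat[ai*4], aki, &pos[bi*3], &quat[bi*4], bki,
                   leg, arm, bondLen, M, pivot, target);
    std::vector<double> prop(memB->size()*3), propQ(memB->size()*4);
    double qM[4];
    qfrommat(M, qM);
    for (size_t a = 0; a < memB->size(); ++a) {
      int mol = (*memB)[a];
      double tmp[3];
      for (int d = 0; d < 3; ++d) tmp[d] = pos[mol*3+d] - pivot[d];
      matvec(M, tmp, &prop[a*3]);
      for (int d = 0; d < 3; ++d) prop[a*3+d] += target[d];
      wrapLateral(&prop[a*3]);
      if (!inBox(&prop[a*3])) { placementRejects++; return; }
      qmul(qM, &quat[mol*4], &propQ[a*4]);
      qnormalize(&propQ[a*4]);
    }
    // moved AP-2s follow rigidly (in-plane part of the transform)
    std::vector<double> propA(apB->size()*2);
    for (size_t a = 0; a < apB->size(); ++a) {
      int ap = (*apB)[a];
      double tmp[3] = {apos[ap*2] - pivot[0], apos[ap*2+1] - pivot[1], -pivot[2]};
      double r[3];
      matvec(M, tmp, r);
      propA[a*2] = r[0] + target[0];
      propA[a*2+1] = r[1] + target[1];
      double p2[3] = {propA[a*2], propA[a*2+1], 0};
      wrapLateral(p2);
      propA[a*2] = p2[0]; propA[a*2+1] = p2[1];
      if (!periodic && (p2[0] < 0 || p2[0] > L || p2[1] < 0 || p2[1] > L)) {
        placementRejects++; return;
      }
    }
    if (overlaps(*memB, prop, *setB, ai, bi)) { placementRejects++; return; }

    // commit
    for (size_t a = 0; a < memB->size(); ++a) {
      int mol = (*memB)[a];
      std::memcpy(&pos[mol*3], &prop[a*3], 3*sizeof(double));
      std::memcpy(&quat[mol*4], &propQ[a*4], 4*sizeof(double));
      grid.move(mol, &pos[mol*3]);
    }
    for (size_t a = 0; a < apB->size(); ++a) {
      int ap = (*apB)[a];
      apos[ap*2] = propA[a*2]; apos[ap*2+1] = propA[a*2+1];
    }
    legb[ai*3+aki] = bi; legbs[ai*3+aki] = bki;
    legb[bi*3+bki] = ai; legbs[bi*3+bki] = aki;
    unite(ai, bi);
    bool anchored = ancI || ancJ;
    // mark both whole components reacted (their geometry just changed)
    std::vector<int> all;
    all.insert(all.end(), memI.begin(), memI.end());
    all.insert(all.end(), memJ.begin(), memJ.end());
    for (size_t a = 0; a < all.size(); ++a) {
      creact[all[a]] = 1;
      if (anchored) { comp[all[a]] = 1; snapMembrane(all[a]); }
    }
    event(0, i, ki, j, kj);
  }

  void attemptCA(const Cand& cd) {
    int i = cd.i, a = cd.j;
    if (creact[i] || areact[a]) return;
    if (ap2b[i] >= 0 || abond[a] >= 0) return;
    if (rng.unif() >= cd.p) return;

    if (comp[i] == 1) {
      // lattice already membrane-bound: pull the AP-2 under the free arm
      double tip[3];
      siteOf(&pos[i*3], &quat[i*4], leg, arm, 3, tip);
      double p2[3] = {tip[0], tip[1], 0};
      wrapLateral(p2);
      apos[a*2] = p2[0]; apos[a*2+1] = p2[1];
      ap2b[i] = a; abond[a] = i;
      creact[i] = 1; areact[a] = 1;
      event(2, i, 3, a, -1);
      return;
    }

    // cytosolic component docks onto the membrane: rotate plane normal to +z
    // about the arm tip of molecule i, then translate the tip onto the AP-2
    std::vector<int> mem, aps;
    std::vector<char> inSet;
    buildComponents();
    componentOf(i, mem, aps, inSet);
    double nB[3], tip[3];
    normalOf(&quat[i*4], nB);
    siteOf(&pos[i*3], &quat[i*4], leg, arm, 3, tip);
    double axis[3] = {nB[1], -nB[0], 0};           // nB x ez
    double s = std::sqrt(axis[0]*axis[0] + axis[1]*axis[1]);
    double cth = nB[2];
    double qM[4];
    if (s < 1e-12) {
      if (cth > 0) { qM[0] = 1; qM[1] = qM[2] = qM[3] = 0; }
      else { qM[0] = 0; qM[1] = 1; qM[2] = 0; qM[3] = 0; }  // flip about x
    } else {
      double ang = std::atan2(s, cth);
      double w[3] = {axis[0]/s*ang, axis[1]/s*ang, 0};
      qfromrotvec(w, qM);
    }
    double targ[3] = {apos[a*2], apos[a*2+1], 0};
    std::vector<double> prop(mem.size()*3), propQ(mem.size()*4);
    for (size_t b = 0; b < mem.size(); ++b) {
      int mol = mem[b];
      double tmp[3] = {pos[mol*3] - tip[0], pos[mol*3+1] - tip[1], pos[mol*3+2] - tip[2]};
      double r[3];
      qrot(qM, tmp, r);
      prop[b*3] = r[0] + targ[0]; prop[b*3+1] = r[1] + targ[1]; prop[b*3+2] = r[2] + targ[2];
      wrapLateral(&prop[b*3]);
      if (!inBox(&prop[b*3])) { placementRejects++; return; }
      qmul(qM, &quat[mol*4], &propQ[b*4]);
      qnormalize(&propQ[b*4]);
    }
    if (overlaps(mem, prop, inSet)) { placementRejects++; return; }
    for (size_t b = 0; b < mem.size(); ++b) {
      int mol = mem[b];
      std::memcpy(&pos[mol*3], &prop[b*3], 3*sizeof(double));
      std::memcpy(&quat[mol*4], &propQ[b*4], 4*sizeof(double));
      comp[mol] = 1;
      snapMembrane(mol);
      grid.move(mol, &pos[mol*3]);
      creact[mol] = 1;
    }
    ap2b[i] = a; abond[a] = i;
    areact[a] = 1;
    event(2, i, 3, a, -1);
  }

  // ----------------------------------------------------------- diffusion
  std::vector<char> inSetBuf;
  void diffuseSweep() {
    buildComponents();
    // flat grouping of molecules by component root
    rootSlot.assign(n, -1);
    compStart.assign(n + 1, 0);
    int nslots = 0;
    for (int i = 0; i < n; ++i) {
      int r = find(i);
      if (rootSlot[r] < 0) rootSlot[r] = nslots++;
      compStart[rootSlot[r] + 1]++;
    }
    for (int s = 0; s < nslots; ++s) compStart[s + 1] += compStart[s];
    compOrder.resize(n);
    {
      std::vector<int>& fill = nbuf;
      fill.assign(nslots, 0);
      for (int i = 0; i < n; ++i) {
        int s = rootSlot[find(i)];
        compOrder[compStart[s] + fill[s]++] = i;
      }
    }
    if ((int)inSetBuf.size() != n) inSetBuf.assign(n, 0);
    std::vector<char>& inSet = inSetBuf;
    for (int s = 0; s < nslots; ++s) {
      memBuf.assign(compOrder.begin() + compStart[s],
                    compOrder.begin() + compStart[s + 1]);
      std::vector<int>& mem = memBuf;
      bool reacted = false;
      apsBuf.clear();
      std::vector<int>& aps = apsBuf;
      for (size_t a = 0; a < mem.size(); ++a) {
        if (creact[mem[a]]) reacted = true;
        if (ap2b[mem[a]] >= 0) {
          aps.push_back(ap2b[mem[a]]);
          if (areact[ap2b[mem[a]]]) reacted = true;
        }
      }
      if (reacted) continue;
      bool membrane = comp[mem[0]] == 1;
      int nc = (int)mem.size(), na = (int)aps.size();
      // cluster diffusion: translation harmonic-mean rule over all members,
      // rotation over clathrin members (n = 3 exponent rule)
      double Dt = 1.0 / (nc / Dct + (Dat > 0 ? na / Dat : 0));
      double Dr = Dcr / (double)((long)nc*nc*nc);
      double sdT = std::sqrt(2.0*Dt*dt), sdR = std::sqrt(2.0*Dr*dt);

      if (nc == 1 && na == 0 && !membrane) {  // free cytosolic monomer: cheap path
        moveMonomer(mem[0], sdT, sdR);
        continue;
      }
      if (nc == 1 && membrane) {              // anchored monomer (+ its AP-2)
        moveAnchoredMonomer(mem[0], na ? aps[0] : -1, sdT, sdR);
        continue;
      }
      moveComplex(mem, aps, membrane, sdT, sdR, inSet);
    }
    // free AP-2s
    double sdA = std::sqrt(2.0*Dat*dt);
    for (int a = 0; a < m; ++a) {
      if (abond[a] >= 0 || areact[a]) continue;
      double p[3] = {apos[a*2] + sdA*rng.norm(), apos[a*2+1] + sdA*rng.norm(), 0};
      foldOrWrap(p);
      apos[a*2] = p[0]; apos[a*2+1] = p[1];
    }
  }

  inline void foldOrWrap(double* p) const {
    if (periodic) {
      p[0] -= L*std::floor(p[0]/L);
      p[1] -= L*std::floor(p[1]/L);
    } else {
      for (int d = 0; d < 2; ++d) {
        while (p[d] < 0 || p[d] > L) { p[d] = p[d] < 0 ? -p[d] : 2*L - p[d]; }
      }
    }
  }

  // single membrane-bound clathrin: 2D displacement, in-plane rotation
  // about its own center; the AP-2 sits exactly under the center (the
  // adaptor arm points straight down) and follows rigidly.
  void moveAnchoredMonomer(int i, int ap, double sdT, double sdR) {
    if (sdT <= 0 && sdR <= 0) return;
    double* c = &pos[i*3];
    for (int attempt = 0; attempt < maxRetry; ++attempt) {
      double p[3] = {c[0] + sdT*rng.norm(), c[1] + sdT*rng.norm(), c[2]};
      foldOrWrap(p);
      bool ok = true;
      if (grid.active) {
        ok = !grid.visit(p, [&](int j) {
          return j != i && dist2(p, &pos[j*3]) < excl2;
        });
      } else {
        for (int j = 0; j < n && ok; ++j) {
          if (j == i) continue;
          if (dist2(p, &pos[j*3]) < excl2) ok = false;
        }
      }
      if (!ok) continue;
      std::memcpy(c, p, 3*sizeof(double));
      grid.move(i, c);
      if (ap >= 0) { apos[ap*2] = c[0]; apos[ap*2+1] = c[1]; }
      double w[3] = {0, 0, sdR*rng.norm()};
      double qR[4], qN[4];
      qfromrotvec(w, qR);
      qmul(qR, &quat[i*4], qN);
      qnormalize(qN);
      std::memcpy(&quat[i*4], qN, 4*sizeof(double));
      snapMembrane(i);
      return;
    }
    skippedMoves++;
  }

  void moveMonomer(int i, double sdT, double sdR) {
    if (sdT <= 0 && sdR <= 0) return;   // D = 0: position unchanged
    double* c = &pos[i*3];
    for (int attempt = 0; attempt < maxRetry; ++attempt) {
      double p[3] = {c[0] + sdT*rng.norm(), c[1] + sdT*rng.norm(), c[2] + sdT*rng.norm()};
      foldOrWrap(p);
      while (p[2] < 0 || p[2] > L) { p[2] = p[2] < 0 ? -p[2] : 2*L - p[2]; }
      bool ok = true;
      if (grid.active) {
        ok = !grid.visit(p, [&](int j) {
          return j != i && dist2(p, &pos[j*3]) < excl2;
        });
      } else {
        for (int j = 0; j < n && ok; ++j) {
          if (j == i) continue;
          if (dist2(p, &pos[j*3]) < excl2) ok = false;
        }
      }
      if (!ok) continue;
      std::memcpy(c, p, 3*sizeof(double));
      grid.move(i, c);
      double w[3] = {sdR*rng.norm(), sdR*rng.norm(), sdR*rng.norm()};
      double qR[4], qN[4];
      qfromrotvec(w, qR);
      qmul(qR, &quat[i*4], qN);
      qnormalize(qN);
      std::memcpy(&quat[i*4], qN, 4*sizeof(double));
      return;
    }
    skippedMoves++;
  }

  void moveComplex(const std::vector<int>& mem, const std::vector<int>& aps,
                   bool membrane, double sdT, double sdR, std::vector<char>& inSet) {
    if (sdT <= 0 && sdR <= 0) return;   // D = 0: nothing moves
    for (size_t a = 0; a < mem.size(); ++a) inSet[mem[a]] = 1;
    // centroid of clathrin centers
    double cx = 0, cy = 0, cz = 0;
    for (size_t a = 0; a < mem.size(); ++a) {
      cx += pos[mem[a]*3]; cy += pos[mem[a]*3+1]; cz += pos[mem[a]*3+2];
    }
    cx /= mem.size(); cy /= mem.size(); cz /= mem.size();

    propP.resize(mem.size()*3); propQb.resize(mem.size()*4);
    propAb.resize(aps.size()*2);
    std::vector<double>& prop = propP;
    std::vector<double>& propQ = propQb;
    std::vector<double>& propA = propAb;
    bool big = grid.active && mem.size() > 16;
    if (big) {
      if ((int)propIdx.size() != n) propIdx.assign(n, -1);
      for (size_t a = 0; a < mem.size(); ++a) propIdx[mem[a]] = (int)a;
    }
    bool done = false;
    for (int attempt = 0; attempt < maxRetry && !done; ++attempt) {
      double d0 = sdT*rng.norm(), d1 = sdT*rng.norm();
      double d2 = membrane ? 0.0 : sdT*rng.norm();
      double qR[4];
      if (membrane) {
        double w[3] = {0, 0, sdR*rng.norm()};
        qfromrotvec(w, qR);
      } else {
        double w[3] = {sdR*rng.norm(), sdR*rng.norm(), sdR*rng.norm()};
        qfromrotvec(w, qR);
      }
      for (int flip = 0; flip < 2 && !done; ++flip) {
        double t0 = flip ? -d0 : d0, t1 = flip ? -d1 : d1, t2 = flip ? -d2 : d2;
        bool ok = true;
        for (size_t a = 0; a < mem.size() && ok; ++a) {
          int mol = mem[a];
          double v[3] = {pos[mol*3] - cx, pos[mol*3+1] - cy, pos[mol*3+2] - cz};
          double rv[3];
          qrot(qR, v, rv);
          prop[a*3]   = cx + rv[0] + t0;
          prop[a*3+1] = cy + rv[1] + t1;
          prop[a*3+2] = cz + rv[2] + t2;
          wrapLateral(&prop[a*3]);
          if (!inBox(&prop[a*3])) ok = false;
        }
        for (size_t a = 0; a < aps.size() && ok; ++a) {
          int ap = aps[a];
          double v[3] = {apos[ap*2] - cx, apos[ap*2+1] - cy, -cz};
          double rv[3];
          qrot(qR, v, rv);
          double p2[3] = {cx + rv[0] + t0, cy + rv[1] + t1, 0};
          wrapLateral(p2);
          if (!periodic && (p2[0] < 0 || p2[0] > L || p2[1] < 0 || p2[1] > L)) ok = false;
          propA[a*2] = p2[0]; propA[a*2+1] = p2[1];
        }
        if (!ok) continue;
        if (big ? overlapsBig(mem, prop, inSet) : overlaps(mem, prop, inSet))
          continue;
        // commit
        for (size_t a = 0; a < mem.size(); ++a) {
          int mol = mem[a];
          std::memcpy(&pos[mol*3], &prop[a*3], 3*sizeof(double));
          double qN[4];
          qmul(qR, &quat[mol*4], qN);
          qnormalize(qN);
          std::memcpy(&quat[mol*4], qN, 4*sizeof(double));
          if (membrane) snapMembrane(mol);
          grid.move(mol, &pos[mol*3]);
        }
        for (size_t a = 0; a < aps.size(); ++a) {
          apos[aps[a]*2] = propA[a*2]; apos[aps[a]*2+1] = propA[a*2+1];
        }
        done = true;
      }
    }
    if (!done) skippedMoves++;
    for (size_t a = 0; a < mem.size(); ++a) inSet[mem[a]] = 0;
  }

  void step() {
    std::fill(creact.begin(), creact.end(), 0);
    std::fill(areact.begin(), areact.end(), 0);
    grid.build(pos, n, L, cutmax, periodic);
    dissociationSweep();
    associationSweep();
    diffuseSweep();
    time += dt;
  }
};

static Engine makeEngine(List state, List params) {
  Engine e;
  List clat = state["clat"], ap2 = state["ap2"];
  NumericMatrix cpos = clat["pos"], cquat = clat["quat"];
  IntegerVector ccomp = clat["comp"], ap2b = clat["ap2_bond"];
  IntegerMatrix legb = clat["leg_bond"], legbs = clat["leg_bond_site"];
  NumericMatrix apos = ap2["pos"];
  IntegerVector abond = ap2["bond"];
  e.n = cpos.nrow(); e.m = apos.nrow();
  e.pos.resize(e.n*3); e.quat.resize(e.n*4);
  e.comp.resize(e.n); e.legb.resize(e.n*3); e.legbs.resize(e.n*3); e.ap2b.resize(e.n);
  for (int i = 0; i < e.n; ++i) {
    for (int d = 0; d < 3; ++d) e.pos[i*3+d] = cpos(i, d);
    for (int d = 0; d < 4; ++d) e.quat[i*4+d] = cquat(i, d);
    e.comp[i] = ccomp[i];
    for (int k = 0; k < 3; ++k) {
      e.legb[i*3+k] = legb(i, k) - 1;      // 1-based -> 0-based, 0 -> -1
      e.legbs[i*3+k] = legbs(i, k) - 1;
    }
    e.ap2b[i] = ap2b[i] - 1;
  }
  e.apos.resize(e.m*2); e.abond.resize(e.m);
  for (int a = 0; a < e.m; ++a) {
    e.apos[a*2] = apos(a, 0); e.apos[a*2+1] = apos(a, 1);
    e.abond[a] = abond[a] - 1;
  }
  e.creact.assign(e.n, 0); e.areact.assign(e.m, 0);
  e.time = as<double>(state["time"]);

  e.L = as<double>(params["edge_length_nm"]);
  e.leg = as<double>(params["leg_length_nm"]);
  e.arm = as<double>(params["ap2_arm_length_nm"]);
  e.bondLen = as<double>(params["bond_length_nm"]);
  e.excl = as<double>(params["excluded_volume_radius_nm"]);
  e.sigma = as<double>(params["sigma_react_nm"]);
  e.dt = as<double>(params["dt_s"]);
  e.p3cc = as<double>(params["p3_cc"]);
  e.p2cc = as<double>(params["p2_cc"]);
  e.p3ca = as<double>(params["p3_ca"]);
  e.p2ca = as<double>(params["p2_ca"]);
  e.poffcc = as<double>(params["p_off_cc"]);
  e.poffca = as<double>(params["p_off_ca"]);
  e.Dct = as<double>(params["d_clat_trans_nm2_s"]);
  e.Dcr = as<double>(params["d_clat_rot_s"]);
  e.Dat = as<double>(params["d_ap2_trans_nm2_s"]);
  e.periodic = as<bool>(params["lateral_periodic"]);
  e.allowSol = as<bool>(params["allow_solution_dimerization"]);
  e.ccNeedsAnchor = as<bool>(params["cc_requires_ap2_bound"]);
  e.maxRetry = as<int>(params["max_move_retries"]);
  e.derive();
  e.rng.seedFromR();
  return e;
}

static List packState(const Engine& e) {
  NumericMatrix cpos(e.n, 3), cquat(e.n, 4);
  IntegerVector ccomp(e.n), ap2b(e.n);
  IntegerMatrix legb(e.n, 3), legbs(e.n, 3);
  for (int i = 0; i < e.n; ++i) {
    for (int d = 0; d < 3; ++d) cpos(i, d) = e.pos[i*3+d];
    for (int d = 0; d < 4; ++d) cquat(i, d) = e.quat[i*4+d];
    ccomp[i] = e.comp[i];
    for (int k = 0; k < 3; ++k) {
      legb(i, k) = e.legb[i*3+k] + 1;
      legbs(i, k) = e.legbs[i*3+k] + 1;
    }
    ap2b[i] = e.ap2b[i] + 1;
  }
  NumericMatrix apos(e.m, 2);
  IntegerVector abond(e.m);
  for (int a = 0; a < e.m; ++a) {
    apos(a, 0) = e.apos[a*2]; apos(a, 1) = e.apos[a*2+1];
    abond[a] = e.abond[a] + 1;
  }
  return List::create(
    _["time"] = e.time,
    _["clat"] = List::create(_["pos"] = cpos, _["quat"] = cquat, _["comp"] = ccomp,
                             _["leg_bond"] = legb, _["leg_bond_site"] = legbs,
                             _["ap2_bond"] = ap2b),
    _["ap2"] = List::create(_["pos"] = apos, _["bond"] = abond));
}

//' @noRd
// [[Rcpp::export]]
List cpp_run(List state, List params, int n_steps, int record_every) {
  Engine e = makeEngine(state, params);
  int n_frames = record_every > 0 ? n_steps / record_every : 0;
  List frames(n_frames);
  int fi = 0;
  for (int s = 0; s < n_steps; ++s) {
    e.step();
    if (record_every > 0 && (s + 1) % record_every == 0 && fi < n_frames) {
      frames[fi++] = packState(e);
    }
    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  DataFrame events = DataFrame::create(
    _["time_s"] = wrap(e.evTime),
    _["type"] = wrap(e.evType),
    _["id1"] = wrap(e.evId1), _["site1"] = wrap(e.evS1),
    _["id2"] = wrap(e.evId2), _["site2"] = wrap(e.evS2));
  return List::create(
    _["state"] = packState(e),
    _["frames"] = frames,
    _["events"] = events,
    _["skipped_moves"] = (double)e.skippedMoves,
    _["placement_rejects"] = (double)e.placementRejects);
}

// ------------------------------------------------- well-mixed A+B harness
//
// Point particles A and B in a closed cubic box, reversible A+B <-> AB with
// the same Doi acceptance / Poisson dissociation machinery as the lattice
// engine.  The complex diffuses with the harmonic-mean translational D.

//' @noRd
// [[Rcpp::export]]
List cpp_well_mixed(int nA, int nB, double L, double sigma,
                    double p_bind, double p_off,
                    double DA, double DB, double dt,
                    int n_steps, int record_every) {
  FastRng rng;
  rng.seedFromR();
  std::vector<double> pa(nA*3), pb(nB*3);
  std::vector<int> bondA(nA, -1), bondB(nB, -1);
  for (int i = 0; i < nA*3; ++i) pa[i] = rng.unif()*L;
  for (int i = 0; i < nB*3; ++i) pb[i] = rng.unif()*L;
  double sdA = std::sqrt(2*DA*dt), sdB = std::sqrt(2*DB*dt);
  double Dab = 1.0/(1.0/DA + 1.0/DB);
  double sdAB = std::sqrt(2*Dab*dt);
  double sigma2 = sigma*sigma;
  int nRec = record_every > 0 ? n_steps/record_every : 0;
  IntegerVector trace(nRec);
  std::vector<char> ra(nA), rb(nB);
  std::vector<std::pair<int,int> > cands;
  int fi = 0;
  for (int s = 0; s < n_steps; ++s) {
    std::fill(ra.begin(), ra.end(), 0);
    std::fill(rb.begin(), rb.end(), 0);
    // dissociation
    for (int i = 0; i < nA; ++i) {
      if (bondA[i] >= 0 && rng.unif() < p_off) {
        int j = bondA[i];
        bondA[i] = -1; bondB[j] = -1;
        ra[i] = 1; rb[j] = 1;
        // place B at contact in a random direction
        double u = 2*rng.unif() - 1, phi = 2*M_PI*rng.unif();
        double st = std::sqrt(1 - u*u);
        pb[j*3]   = pa[i*3]   + sigma*st*std::cos(phi);
        pb[j*3+1] = pa[i*3+1] + sigma*st*std::sin(phi);
        pb[j*3+2] = pa[i*3+2] + sigma*u;
        for (int d = 0; d < 3; ++d) {
          double v = pb[j*3+d];
          while (v < 0 || v > L) v = v < 0 ? -v : 2*L - v;
          pb[j*3+d] = v;
        }
      }
    }
    // association
    cands.clear();
    for (int i = 0; i < nA; ++i) {
      if (bondA[i] >= 0 || ra[i]) continue;
      for (int j = 0; j < nB; ++j) {
        if (bondB[j] >= 0 || rb[j]) continue;
        double d0 = pa[i*3]-pb[j*3], d1 = pa[i*3+1]-pb[j*3+1], d2 = pa[i*3+2]-pb[j*3+2];
        if (d0*d0 + d1*d1 + d2*d2 <= sigma2) cands.push_back(std::make_pair(i, j));
      }
    }
    for (int b = (int)cands.size() - 1; b > 0; --b) {
      int j = (int)(rng.unif()*(b+1));
      if (j > b) j = b;
      std::swap(cands[b], cands[j]);
    }
    for (size_t c = 0; c < cands.size(); ++c) {
      int i = cands[c].first, j = cands[c].second;
      if (bondA[i] >= 0 || bondB[j] >= 0 || ra[i] || rb[j]) continue;
      if (rng.unif() < p_bind) {
        bondA[i] = j; bondB[j] = i;
        for (int d = 0; d < 3; ++d) pb[j*3+d] = pa[i*3+d];
        ra[i] = 1; rb[j] = 1;
      }
    }
    // diffusion
    for (int i = 0; i < nA; ++i) {
      if (ra[i]) continue;
      double sd = bondA[i] >= 0 ? sdAB : sdA;
      for (int d = 0; d < 3; ++d) {
        double v = pa[i*3+d] + sd*rng.norm();
        while (v < 0 || v > L) v = v < 0 ? -v : 2*L - v;
        pa[i*3+d] = v;
        if (bondA[i] >= 0) pb[bondA[i]*3+d] = v;
      }
    }
    for (int j = 0; j < nB; ++j) {
      if (rb[j] || bondB[j] >= 0) continue;
      for (int d = 0; d < 3; ++d) {
        double v = pb[j*3+d] + sdB*rng.norm();
        while (v < 0 || v > L) v = v < 0 ? -v : 2*L - v;
        pb[j*3+d] = v;
      }
    }
    if (record_every > 0 && (s+1) % record_every == 0 && fi < nRec) {
      int nb = 0;
      for (int i = 0; i < nA; ++i) if (bondA[i] >= 0) nb++;
      trace[fi++] = nb;
    }
    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  int nb = 0;
  for (int i = 0; i < nA; ++i) if (bondA[i] >= 0) nb++;
  return List::create(_["trace"] = trace, _["final_bound"] = nb);
}
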