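// Brownian-dynamics kernel for rigid patchy bodies with dynamic bonding.
//
// Bodies are rigid assemblies of repulsion spheres plus (optionally) binding
// sites.  Propagation is overdamped Langevin: translational and rotational
// mobilities are supplied per species as diffusivities (length^2/time and
// rad^2/time); per-species temperature factors scale only the noise, which is
// how crowders get an effective temperature distinct from the synDrop
// components.  Pair repulsion is the soft quartic potential with XPLOR
// smoothing; bonded sites are held by a harmonic spring.  The bond updater
// runs every `updater_period` steps and adds/removes bonds with Metropolis
// acceptance so that the stationary ensemble is Boltzmann-consistent.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding; fast uniform and (polar) normal
// draws for the integrator's noise
struct FastRng {
  uint64_t s[4];
  double spare;
  bool has_spare;
  void seed(uint64_t x) {
    has_spare = false; spare = 0.0;
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
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

struct Vec3 {
  double x, y, z;
};
static inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }

struct Quat {
  double w, x, y, z;
};
static inline Quat qmul(Quat a, Quat b) {
  return {a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
          a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
          a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
          a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w};
}
static inline void qnormalize(Quat &q) {
  double n = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
  q.w /= n; q.x /= n; q.y /= n; q.z /= n;
}
static inline Vec3 qrot(Quat q, Vec3 v) {
  // rotate v by unit quaternion q
  Vec3 u = {q.x, q.y, q.z};
  Vec3 t = 2.0 * cross(u, v);
  return v + q.w * t + cross(u, t);
}
static inline Quat axis_angle_quat(Vec3 axis_times_angle) {
  double th = norm(axis_times_angle);
  if (th < 1e-14) return {1.0, 0.0, 0.0, 0.0};
  double s = std::sin(0.5 * th) / th;
  return {std::cos(0.5 * th), s * axis_times_angle.x, s * axis_times_angle.y,
          s * axis_times_angle.z};
}

struct SpeciesDef {
  std::vector<Vec3> body_off;
  std::vector<double> body_rad;
  std::vector<Vec3> site_off;
  double site_rad;
  int site_type;  // 0 = inert, 1 and 2 are complementary patch classes
  double Dt, Dr, Tfac;
  bool rotate;
};

// soft quartic pair potential with optional XPLOR smoothing window
struct SoftPair {
  double eps, r_on_frac;
  bool smooth;
  // returns energy; *fmag gets dU/dr with sign so that force on i along
  // r_ij-hat is -dU/dr (repulsive => positive -dU/dr)
  double eval(double r, double rcut, double *dudr) const {
    *dudr = 0.0;
    if (r >= rcut || eps <= 0.0) return 0.0;
    double rr = r / rcut;
    double r2 = rr * rr;
    double U = eps * (1.0 - r2 * r2);
    double dU = -4.0 * eps * r2 * rr / rcut;
    double ron = r_on_frac * rcut;
    if (!smooth || r < ron) {
      *dudr = dU;
      return U;
    }
    // XPLOR smoothing on [r_on, r_cut]
    double rc2 = rcut * rcut, ro2 = ron * ron, x2 = r * r;
    double denom = (rc2 - ro2) * (rc2 - ro2) * (rc2 - ro2);
    double a = rc2 - x2;
    double S = a * a * (rc2 + 2.0 * x2 - 3.0 * ro2) / denom;
    double dS = (2.0 * a * (-2.0 * r) * (rc2 + 2.0 * x2 - 3.0 * ro2) +
                 a * a * 4.0 * r) / denom;
    *dudr = dU * S + U * dS;
    return U * S;
  }
};

struct Engine {
  // definitions
  std::vector<SpeciesDef> spec;
  std::vector<int> sp;  // species of each body
  int nbody;
  // state
  std::vector<Vec3> pos;
  std::vector<Quat> quat;
  // bonds: parallel arrays; site_bond maps global site index -> bond slot (-1 free)
  std::vector<int> ba, bsa, bb, bsb;   // body a, site a, body b, site b
  std::vector<char> bond_alive;
  std::vector<int> site_bond;
  std::vector<int> site_base;          // global site index base per body
  int nsite_total;
  // box
  Vec3 box;
  bool periodic, walls;
  // params
  double dt;
  SoftPair pairpot;
  double lj_eps;
  double P_on, P_off, d_bind, spring_k, rest_len;
  bool bind_center, frustration, java_escape, metropolis;
  int updater_period;
  double max_step;  // instability guard, absolute length
  FastRng rng;

  // escape-before-rebind bookkeeping (java mode): blocked site pairs
  std::vector<std::pair<int, int>> blocked;

  // sphere scratch (world coordinates of repulsion spheres)
  std::vector<Vec3> sppos;
  std::vector<double> sprad;
  std::vector<int> spbody;
  // verlet list
  std::vector<int> vl_i, vl_j;
  std::vector<Vec3> vl_ref;
  double skin;
  double maxrad;

  double runif() { return rng.unif(); }
  double rnorm() { return rng.normal(); }

  Vec3 minimg(Vec3 d) const {
    if (!periodic) return d;
    // wrapped coordinates keep |d| < box, so one branchy correction per
    // axis replaces the nearbyint division in the hot loops
    double hx = 0.5 * box.x, hy = 0.5 * box.y, hz = 0.5 * box.z;
    if (d.x > hx) d.x -= box.x; else if (d.x < -hx) d.x += box.x;
    if (d.y > hy) d.y -= box.y; else if (d.y < -hy) d.y += box.y;
    if (d.z > hz) d.z -= box.z; else if (d.z < -hz) d.z += box.z;
    return d;
  }
  void wrap(Vec3 &p) const {
    if (!periodic) return;
    p.x -= box.x * std::floor(p.x / box.x + 0.5);
    p.y -= box.y * std::floor(p.y / box.y + 0.5);
    p.z -= box.z * std::floor(p.z / box.z + 0.5);
  }

  void build_spheres() {
    sppos.clear(); sprad.clear(); spbody.clear();
    for (int i = 0; i < nbody; ++i) {
      const SpeciesDef &s = spec[sp[i]];
      for (size_t k = 0; k < s.body_off.size(); ++k) {
        Vec3 off = s.rotate ? qrot(quat[i], s.body_off[k]) : s.body_off[k];
        sppos.push_back(pos[i] + off);
        sprad.push_back(s.body_rad[k]);
        spbody.push_back(i);
      }
    }
  }

  void update_sphere_positions() {
    int idx = 0;
    for (int i = 0; i < nbody; ++i) {
      const SpeciesDef &s = spec[sp[i]];
      for (size_t k = 0; k < s.body_off.size(); ++k) {
        Vec3 off = s.rotate ? qrot(quat[i], s.body_off[k]) : s.body_off[k];
        sppos[idx] = pos[i] + off;
        ++idx;
      }
    }
  }

  void build_verlet() {
    int n = (int)sppos.size();
    vl_i.clear(); vl_j.clear();
    vl_ref = sppos;
    double cut = 2.0 * maxrad + skin;
    int ncx = periodic ? std::max(1, (int)std::floor(box.x / cut)) : 0;
    int ncy = periodic ? std::max(1, (int)std::floor(box.y / cut)) : 0;
    int ncz = periodic ? std::max(1, (int)std::floor(box.z / cut)) : 0;
    bool use_cells = periodic && ncx >= 3 && ncy >= 3 && ncz >= 3 && n > 200;
    if (!use_cells) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          if (spbody[i] == spbody[j]) continue;
          double lim = sprad[i] + sprad[j] + skin;
          Vec3 d = minimg(sppos[i] - sppos[j]);
          if (dot(d, d) < lim * lim) { vl_i.push_back(i); vl_j.push_back(j); }
        }
      return;
    }
    int ncell = ncx * ncy * ncz;
    std::vector<int> head(ncell, -1), nxt(n, -1);
    auto cellof = [&](Vec3 p) {
      int cx = (int)std::floor((p.x / box.x + 0.5) * ncx); cx = ((cx % ncx) + ncx) % ncx;
      int cy = (int)std::floor((p.y / box.y + 0.5) * ncy); cy = ((cy % ncy) + ncy) % ncy;
      int cz = (int)std::floor((p.z / box.z + 0.5) * ncz); cz = ((cz % ncz) + ncz) % ncz;
      return (cz * ncy + cy) * ncx + cx;
    };
    for (int i = 0; i < n; ++i) {
      int c = cellof(sppos[i]);
      nxt[i] = head[c]; head[c] = i;
    }
    for (int cz = 0; cz < ncz; ++cz)
      for (int cy = 0; cy < ncy; ++cy)
        for (int cx = 0; cx < ncx; ++cx) {
          int c0 = (cz * ncy + cy) * ncx + cx;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int cx2 = (cx + dx + ncx) % ncx;
                int cy2 = (cy + dy + ncy) % ncy;
                int cz2 = (cz + dz + ncz) % ncz;
                int c1 = (cz2 * ncy + cy2) * ncx + cx2;
                if (c1 < c0) continue;
                for (int i = head[c0]; i >= 0; i = nxt[i])
                  for (int j = head[c1]; j >= 0; j = nxt[j]) {
                    if (c1 == c0 && j >= i) continue;
                    if (spbody[i] == spbody[j]) continue;
                    double lim = sprad[i] + sprad[j] + skin;
                    Vec3 d = minimg(sppos[i] - sppos[j]);
                    if (dot(d, d) < lim * lim) { vl_i.push_back(i); vl_j.push_back(j); }
                  }
              }
        }
  }

  bool verlet_stale() const {
    double lim2 = 0.25 * skin * skin;  // half-skin displacement triggers rebuild
    for (size_t i = 0; i < sppos.size(); ++i) {
      Vec3 d = minimg(sppos[i] - vl_ref[i]);
      if (dot(d, d) > lim2) return true;
    }
    return false;
  }

  Vec3 site_world(int body, int site) const {
    const SpeciesDef &s = spec[sp[body]];
    return pos[body] + qrot(quat[body], s.site_off[site]);
  }

  double spring_energy(double r) const {
    double e = r - rest_len;
    return 0.5 * spring_k * e * e;
  }

  // forces + torques on bodies; returns potential energy (unused, cheap)
  void compute_forces(std::vector<Vec3> &F, std::vector<Vec3> &T) {
    std::fill(F.begin(), F.end(), Vec3{0, 0, 0});
    std::fill(T.begin(), T.end(), Vec3{0, 0, 0});
    // pair repulsion over verlet list
    for (size_t k = 0; k < vl_i.size(); ++k) {
      int i = vl_i[k], j = vl_j[k];
      double rcut = sprad[i] + sprad[j];
      Vec3 d = minimg(sppos[i] - sppos[j]);
      double r2 = dot(d, d);
      if (r2 >= rcut * rcut) continue;
      double r = std::sqrt(r2);
      double dudr;
      pairpot.eval(r, rcut, &dudr);
      if (r < 1e-9) continue;  // coincident centers: no defined direction
      double fmag = -dudr;     // along d-hat on sphere i
      Vec3 f = (fmag / r) * d;
      int bi = spbody[i], bj = spbody[j];
      F[bi] = F[bi] + f;
      F[bj] = F[bj] - f;
      Vec3 ai = minimg(sppos[i] - pos[bi]);
      Vec3 aj = minimg(sppos[j] - pos[bj]);
      T[bi] = T[bi] + cross(ai, f);
      T[bj] = T[bj] - cross(aj, f);
    }
    // bond springs between site centers
    for (size_t b = 0; b < ba.size(); ++b) {
      if (!bond_alive[b]) continue;
      Vec3 pa = site_world(ba[b], bsa[b]);
      Vec3 pb = site_world(bb[b], bsb[b]);
      Vec3 d = minimg(pa - pb);
      double r = norm(d);
      double ext = r - rest_len;
      if (std::fabs(ext) < 1e-12 || r < 1e-9) continue;
      Vec3 f = (-spring_k * ext / r) * d;  // force on a
      F[ba[b]] = F[ba[b]] + f;
      F[bb[b]] = F[bb[b]] - f;
      Vec3 aa = minimg(pa - pos[ba[b]]);
      Vec3 ab = minimg(pb - pos[bb[b]]);
      T[ba[b]] = T[ba[b]] + cross(aa, f);
      T[bb[b]] = T[bb[b]] - cross(ab, f);
    }
    // walls: soft repulsion against the six faces of the closed box
    if (walls) {
      for (size_t i = 0; i < sppos.size(); ++i) {
        int bi = spbody[i];
        double rad = sprad[i];
        double half[3] = {0.5 * box.x, 0.5 * box.y, 0.5 * box.z};
        double p[3] = {sppos[i].x, sppos[i].y, sppos[i].z};
        Vec3 f = {0, 0, 0};
        for (int ax = 0; ax < 3; ++ax) {
          double dlo = p[ax] + half[ax];   // distance to low face
          double dhi = half[ax] - p[ax];   // distance to high face
          double dudr;
          if (dlo < rad) {
            pairpot.eval(std::max(dlo, 0.0), rad, &dudr);
            double fm = -dudr;
            if (ax == 0) f.x += fm; else if (ax == 1) f.y += fm; else f.z += fm;
          }
          if (dhi < rad) {
            pairpot.eval(std::max(dhi, 0.0), rad, &dudr);
            double fm = -dudr;
            if (ax == 0) f.x -= fm; else if (ax == 1) f.y -= fm; else f.z -= fm;
          }
        }
        F[bi] = F[bi] + f;
        Vec3 a = minimg(sppos[i] - pos[bi]);
        T[bi] = T[bi] + cross(a, f);
      }
    }
  }

  void step(std::vector<Vec3> &F, std::vector<Vec3> &T, int stepno) {
    compute_forces(F, T);
    for (int i = 0; i < nbody; ++i) {
      const SpeciesDef &s = spec[sp[i]];
      double c1 = s.Dt * dt;                       // mobility * kT=1 * dt
      double c2 = std::sqrt(2.0 * s.Dt * s.Tfac * dt);
      Vec3 dx = {c1 * F[i].x + c2 * rnorm(),
                 c1 * F[i].y + c2 * rnorm(),
                 c1 * F[i].z + c2 * rnorm()};
      double dn = norm(dx);
      if (dn > max_step)
        stop("integration instability: particle %d moved %f at step %d",
             i + 1, dn, stepno);
      pos[i] = pos[i] + dx;
      if (!periodic && walls) {
        // keep centers inside the closed box even under extreme kicks
        double hx = 0.5 * box.x, hy = 0.5 * box.y, hz = 0.5 * box.z;
        pos[i].x = std::min(std::max(pos[i].x, -hx), hx);
        pos[i].y = std::min(std::max(pos[i].y, -hy), hy);
        pos[i].z = std::min(std::max(pos[i].z, -hz), hz);
      } else {
        wrap(pos[i]);
      }
      if (s.rotate) {
        double r1 = s.Dr * dt;
        double r2 = std::sqrt(2.0 * s.Dr * s.Tfac * dt);
        Vec3 dth = {r1 * T[i].x + r2 * rnorm(),
                    r1 * T[i].y + r2 * rnorm(),
                    r1 * T[i].z + r2 * rnorm()};
        Quat dq = axis_angle_quat(dth);
        quat[i] = qmul(dq, quat[i]);
        qnormalize(quat[i]);
      }
    }
    update_sphere_positions();
    if (stepno % 4 == 0 && verlet_stale()) build_verlet();
  }

  // distance used by the binding criterion between two sites
  double bind_distance(Vec3 pa, Vec3 pb, double site_rad_a, double site_rad_b) const {
    double r = norm(minimg(pa - pb));
    if (bind_center) return r;
    return r - site_rad_a - site_rad_b;  // surface gap between site spheres
  }

  bool molecules_bonded(int b1, int b2) const {
    for (size_t b = 0; b < ba.size(); ++b) {
      if (!bond_alive[b]) continue;
      if ((ba[b] == b1 && bb[b] == b2) || (ba[b] == b2 && bb[b] == b1)) return true;
    }
    return false;
  }

  // all complementary free-site pairs within the binding distance
  void candidate_pairs(std::vector<std::array<int, 4>> &out) {
    out.clear();
    // gather free sites by patch class
    std::vector<int> s1b, s1s, s2b, s2s;
    for (int i = 0; i < nbody; ++i) {
      const SpeciesDef &s = spec[sp[i]];
      if (s.site_type == 0) continue;
      for (size_t k = 0; k < s.site_off.size(); ++k) {
        if (site_bond[site_base[i] + (int)k] >= 0) continue;
        if (s.site_type == 1) { s1b.push_back(i); s1s.push_back((int)k); }
        else { s2b.push_back(i); s2s.push_back((int)k); }
      }
    }
    std::vector<Vec3> p1(s1b.size()), p2(s2b.size());
    for (size_t a = 0; a < s1b.size(); ++a) p1[a] = site_world(s1b[a], s1s[a]);
    for (size_t b = 0; b < s2b.size(); ++b) p2[b] = site_world(s2b[b], s2s[b]);
    for (size_t a = 0; a < s1b.size(); ++a) {
      double ra = spec[sp[s1b[a]]].site_rad;
      for (size_t b = 0; b < s2b.size(); ++b) {
        double rb = spec[sp[s2b[b]]].site_rad;
        double reach = d_bind + (bind_center ? 0.0 : ra + rb);
        Vec3 d = minimg(p1[a] - p2[b]);
        if (dot(d, d) > reach * reach) continue;
        if (frustration && molecules_bonded(s1b[a], s2b[b])) continue;
        out.push_back({s1b[a], s1s[a], s2b[b], s2s[b]});
      }
    }
  }

  bool is_blocked(int ga, int gb) const {
    for (auto &pr : blocked)
      if (pr.first == ga && pr.second == gb) return true;
    return false;
  }

  void purge_blocked() {
    // a pair leaves the blocked list once it has escaped past the binding range
    std::vector<std::pair<int, int>> keep;
    for (auto &pr : blocked) {
      int ga = pr.first, gb = pr.second;
      // decode global site index
      int bodya = 0, bodyb = 0;
      while (bodya + 1 < nbody && site_base[bodya + 1] <= ga) ++bodya;
      while (bodyb + 1 < nbody && site_base[bodyb + 1] <= gb) ++bodyb;
      int sa = ga - site_base[bodya], sb = gb - site_base[bodyb];
      Vec3 pa = site_world(bodya, sa), pb = site_world(bodyb, sb);
      double gap = bind_distance(pa, pb, spec[sp[bodya]].site_rad,
                                 spec[sp[bodyb]].site_rad);
      if (gap <= d_bind) keep.push_back(pr);
    }
    blocked.swap(keep);
  }

  int add_bond(int b1, int s1, int b2, int s2) {
    ba.push_back(b1); bsa.push_back(s1); bb.push_back(b2); bsb.push_back(s2);
    bond_alive.push_back(1);
    int id = (int)ba.size() - 1;
    site_bond[site_base[b1] + s1] = id;
    site_bond[site_base[b2] + s2] = id;
    return id;
  }

  // one bond-updater invocation; returns (formed, broken)
  std::pair<int, int> bond_update(std::vector<std::array<int, 4>> &cand,
                                  std::vector<std::array<int, 6>> *events,
                                  int stepno) {
    int formed = 0, broken = 0;
    if (java_escape) purge_blocked();
    // sites freed during this invocation may not rebind until the next one,
    // so one call realises exactly one two-state transition attempt per pair
    std::vector<char> freed(nsite_total, 0);
    // removal sweep over existing bonds
    for (size_t b = 0; b < ba.size(); ++b) {
      if (!bond_alive[b]) continue;
      if (P_off <= 0.0) continue;
      if (runif() < P_off) {
        // Metropolis factor for release of spring energy: min(1, exp(+U)) = 1
        bond_alive[b] = 0;
        site_bond[site_base[ba[b]] + bsa[b]] = -1;
        site_bond[site_base[bb[b]] + bsb[b]] = -1;
        freed[site_base[ba[b]] + bsa[b]] = 1;
        freed[site_base[bb[b]] + bsb[b]] = 1;
        if (java_escape)
          blocked.push_back({site_base[ba[b]] + bsa[b], site_base[bb[b]] + bsb[b]});
        if (events) events->push_back({stepno, 0, ba[b], bsa[b], bb[b], bsb[b]});
        ++broken;
      }
    }
    if (P_on > 0.0) {
      candidate_pairs(cand);
      // random processing order resolves conflicts between candidates
      for (int k = (int)cand.size() - 1; k > 0; --k) {
        int j = (int)std::floor(runif() * (k + 1));
        std::swap(cand[k], cand[j]);
      }
      for (auto &c : cand) {
        int ga = site_base[c[0]] + c[1], gb = site_base[c[2]] + c[3];
        if (site_bond[ga] >= 0 || site_bond[gb] >= 0) continue;
        if (freed[ga] || freed[gb]) continue;
        if (frustration && molecules_bonded(c[0], c[2])) continue;
        if (java_escape && is_blocked(ga, gb)) continue;
        if (runif() >= P_on) continue;
        Vec3 pa = site_world(c[0], c[1]), pb = site_world(c[2], c[3]);
        double r = norm(minimg(pa - pb));
        double dU = spring_energy(r);
        if (metropolis && dU > 0.0 && runif() >= std::exp(-dU)) continue;
        add_bond(c[0], c[1], c[2], c[3]);
        if (events) events->push_back({stepno, 1, c[0], c[1], c[2], c[3]});
        ++formed;
      }
    }
    return {formed, broken};
  }

  int live_bond_count() const {
    int n = 0;
    for (char a : bond_alive) n += a;
    return n;
  }
};

SpeciesDef parse_species(List s) {
  SpeciesDef d;
  NumericMatrix boff = s["body_off"];
  NumericVector brad = s["body_rad"];
  for (int k = 0; k < boff.ncol(); ++k)
    d.body_off.push_back({boff(0, k), boff(1, k), boff(2, k)});
  for (int k = 0; k < brad.size(); ++k) d.body_rad.push_back(brad[k]);
  NumericMatrix soff = s["site_off"];
  for (int k = 0; k < soff.ncol(); ++k)
    d.site_off.push_back({soff(0, k), soff(1, k), soff(2, k)});
  d.site_rad = as<double>(s["site_rad"]);
  d.site_type = as<int>(s["site_type"]);
  d.Dt = as<double>(s["Dt"]);
  d.Dr = as<double>(s["Dr"]);
  d.Tfac = as<double>(s["Tfac"]);
  d.rotate = as<bool>(s["rotate"]);
  return d;
}

void setup_engine(Engine &E, List species, IntegerVector sp_of, NumericMatrix pos0,
                  NumericMatrix quat0, IntegerMatrix bonds0, NumericVector box,
                  bool periodic, bool walls, double dt, double eps_soft,
                  double r_on_frac, double P_on, double P_off, double d_bind,
                  bool bind_center, double spring_k, double rest_len,
                  bool frustration, bool java_escape, bool metropolis,
                  int updater_period, double max_step_frac, double seed) {
  for (int i = 0; i < species.size(); ++i)
    E.spec.push_back(parse_species(species[i]));
  E.nbody = sp_of.size();
  for (int i = 0; i < E.nbody; ++i) {
    E.sp.push_back(sp_of[i] - 1);
    E.pos.push_back({pos0(i, 0), pos0(i, 1), pos0(i, 2)});
    E.quat.push_back({quat0(i, 0), quat0(i, 1), quat0(i, 2), quat0(i, 3)});
  }
  E.box = {box[0], box[1], box[2]};
  E.periodic = periodic;
  E.walls = walls;
  E.dt = dt;
  E.pairpot = {eps_soft, r_on_frac, true};
  E.lj_eps = 0.0;
  E.P_on = P_on; E.P_off = P_off;
  E.d_bind = d_bind; E.bind_center = bind_center;
  E.spring_k = spring_k; E.rest_len = rest_len;
  E.frustration = frustration; E.java_escape = java_escape;
  E.metropolis = metropolis;
  E.updater_period = updater_period;
  E.rng.seed((uint64_t)seed);
  // site bookkeeping
  E.nsite_total = 0;
  double mind = 1e100;
  E.maxrad = 0.0;
  for (int i = 0; i < E.nbody; ++i) {
    E.site_base.push_back(E.nsite_total);
    E.nsite_total += (int)E.spec[E.sp[i]].site_off.size();
    for (double r : E.spec[E.sp[i]].body_rad) {
      mind = std::min(mind, 2.0 * r);
      E.maxrad = std::max(E.maxrad, r);
    }
  }
  E.site_bond.assign(E.nsite_total, -1);
  for (int b = 0; b < bonds0.nrow(); ++b)
    E.add_bond(bonds0(b, 0) - 1, bonds0(b, 1) - 1, bonds0(b, 2) - 1, bonds0(b, 3) - 1);
  E.max_step = max_step_frac * mind;
  E.skin = 0.3 * mind;
  E.build_spheres();
  E.build_verlet();
}

}  // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List species, IntegerVector sp_of, NumericMatrix pos0,
                NumericMatrix quat0, IntegerMatrix bonds0, NumericVector box,
                bool periodic, bool walls, double dt, int n_steps, int stride,
                double eps_soft, double r_on_frac, double P_on, double P_off,
                int updater_period, double d_bind, bool bind_center,
                double spring_k, double rest_len, bool frustration,
                bool java_escape, bool metropolis, bool integrate, double seed,
                NumericVector box_final, int compress_steps, bool log_events,
                double max_step_frac, int count_every) {
  Engine E;
  setup_engine(E, species, sp_of, pos0, quat0, bonds0, box, periodic, walls, dt,
               eps_soft, r_on_frac, P_on, P_off, d_bind, bind_center, spring_k,
               rest_len, frustration, java_escape, metropolis, updater_period,
               max_step_frac, seed);
  std::vector<Vec3> F(E.nbody), T(E.nbody);
  std::vector<std::array<int, 4>> cand;
  std::vector<std::array<int, 6>> events;
  Vec3 box_start = E.box;
  Vec3 box_end = {box_final[0], box_final[1], box_final[2]};
  bool compressing = compress_steps > 0;

  std::vector<NumericMatrix> frame_pos;
  std::vector<IntegerMatrix> frame_bonds;
  std::vector<int> frame_steps;
  std::vector<int> bc_step;
  std::vector<int> bc_count;

  auto snapshot = [&](int stepno) {
    NumericMatrix P(E.nbody, 3);
    for (int i = 0; i < E.nbody; ++i) {
      P(i, 0) = E.pos[i].x; P(i, 1) = E.pos[i].y; P(i, 2) = E.pos[i].z;
    }
    int nb = E.live_bond_count();
    IntegerMatrix B(nb, 4);
    int r = 0;
    for (size_t b = 0; b < E.ba.size(); ++b) {
      if (!E.bond_alive[b]) continue;
      B(r, 0) = E.ba[b] + 1; B(r, 1) = E.bsa[b] + 1;
      B(r, 2) = E.bb[b] + 1; B(r, 3) = E.bsb[b] + 1;
      ++r;
    }
    frame_pos.push_back(P);
    frame_bonds.push_back(B);
    frame_steps.push_back(stepno);
  };

  snapshot(0);
  bc_step.push_back(0);
  bc_count.push_back(E.live_bond_count());
  long updater_calls = 0;
  if (count_every < 1) count_every = 1;

  for (int s = 1; s <= n_steps; ++s) {
    if (compressing && s <= compress_steps) {
      double f = (double)s / compress_steps;
      Vec3 nb = {box_start.x + f * (box_end.x - box_start.x),
                 box_start.y + f * (box_end.y - box_start.y),
                 box_start.z + f * (box_end.z - box_start.z)};
      double sx = nb.x / E.box.x, sy = nb.y / E.box.y, sz = nb.z / E.box.z;
      for (int i = 0; i < E.nbody; ++i) {
        E.pos[i].x *= sx; E.pos[i].y *= sy; E.pos[i].z *= sz;
      }
      E.box = nb;
      E.update_sphere_positions();
      E.build_verlet();
    }
    if (integrate) E.step(F, T, s);
    if (E.updater_period > 0 && s % E.updater_period == 0) {
      E.bond_update(cand, log_events ? &events : nullptr, s);
      if (++updater_calls % count_every == 0) {
        bc_step.push_back(s);
        bc_count.push_back(E.live_bond_count());
      }
    }
    if (stride > 0 && s % stride == 0) snapshot(s);
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  if (n_steps > 0 && (stride == 0 || n_steps % stride != 0)) snapshot(n_steps);

  NumericMatrix fpos(E.nbody, 3);
  NumericMatrix fquat(E.nbody, 4);
  for (int i = 0; i < E.nbody; ++i) {
    fpos(i, 0) = E.pos[i].x; fpos(i, 1) = E.pos[i].y; fpos(i, 2) = E.pos[i].z;
    fquat(i, 0) = E.quat[i].w; fquat(i, 1) = E.quat[i].x;
    fquat(i, 2) = E.quat[i].y; fquat(i, 3) = E.quat[i].z;
  }
  IntegerMatrix ev(events.size(), 6);
  for (size_t k = 0; k < events.size(); ++k) {
    ev(k, 0) = events[k][0]; ev(k, 1) = events[k][1];
    ev(k, 2) = events[k][2] + 1; ev(k, 3) = events[k][3] + 1;
    ev(k, 4) = events[k][4] + 1; ev(k, 5) = events[k][5] + 1;
  }
  // live bonds at the end
  int nb = E.live_bond_count();
  IntegerMatrix B(nb, 4);
  int r = 0;
  for (size_t b = 0; b < E.ba.size(); ++b) {
    if (!E.bond_alive[b]) continue;
    B(r, 0) = E.ba[b] + 1; B(r, 1) = E.bsa[b] + 1;
    B(r, 2) = E.bb[b] + 1; B(r, 3) = E.bsb[b] + 1;
    ++r;
  }
  return List::create(
      _["frame_pos"] = wrap(frame_pos), _["frame_bonds"] = wrap(frame_bonds),
      _["frame_steps"] = wrap(frame_steps), _["bond_count_steps"] = wrap(bc_step),
      _["bond_counts"] = wrap(bc_count), _["final_pos"] = fpos,
      _["final_quat"] = fquat, _["final_bonds"] = B, _["events"] = ev,
      _["box"] = NumericVector::create(E.box.x, E.box.y, E.box.z));
}

// [[Rcpp::export(name = ".engine_soft_pair")]]
List engine_soft_pair(NumericVector r, double rcut, double eps, double r_on_frac,
                      bool smooth) {
  SoftPair p{eps, r_on_frac, smooth};
  int n = r.size();
  NumericVector U(n), Fv(n);
  for (int i = 0; i < n; ++i) {
    double dudr;
    U[i] = p.eval(r[i], rcut, &dudr);
    Fv[i] = -dudr;
  }
  return List::create(_["energy"] = U, _["force"] = Fv);
}

// [[Rcpp::export(name = ".engine_candidate_pairs")]]
IntegerMatrix engine_candidate_pairs(List species, IntegerVector sp_of,
                                     NumericMatrix pos0, NumericMatrix quat0,
                                     IntegerMatrix bonds0, NumericVector box,
                                     bool periodic, double d_bind,
                                     bool bind_center, bool frustration) {
  Engine E;
  setup_engine(E, species, sp_of, pos0, quat0, bonds0, box, periodic, false,
               0.001, 0.0, 0.95, 0.0, 0.0, d_bind, bind_center, 1.0, 0.0,
               frustration, false, true, 1, 1e9, 1.0);
  std::vector<std::array<int, 4>> cand;
  E.candidate_pairs(cand);
  IntegerMatrix out(cand.size(), 4);
  for (size_t k = 0; k < cand.size(); ++k) {
    out(k, 0) = cand[k][0] + 1; out(k, 1) = cand[k][1] + 1;
    out(k, 2) = cand[k][2] + 1; out(k, 3) = cand[k][3] + 1;
  }
  return out;
}

// [[Rcpp::export(name = ".engine_site_positions")]]
NumericMatrix engine_site_positions(List species, IntegerVector sp_of,
                                    NumericMatrix pos0, NumericMatrix quat0) {
  std::vector<SpeciesDef> spec;
  for (int i = 0; i < species.size(); ++i) spec.push_back(parse_species(species[i]));
  int n = sp_of.size();
  std::vector<std::array<double, 5>> rows;
  for (int i = 0; i < n; ++i) {
    const SpeciesDef &s = spec[sp_of[i] - 1];
    Quat q = {quat0(i, 0), quat0(i, 1), quat0(i, 2), quat0(i, 3)};
    Vec3 p = {pos0(i, 0), pos0(i, 1), pos0(i, 2)};
    for (size_t k = 0; k < s.site_off.size(); ++k) {
      Vec3 w = p + qrot(q, s.site_off[k]);
      rows.push_back({(double)(i + 1), (double)(k + 1), w.x, w.y, w.z});
    }
  }
  NumericMatrix out(rows.size(), 5);
  for (size_t r = 0; r < rows.size(); ++r)
    for (int c = 0; c < 5; ++c) out(r, c) = rows[r][c];
  colnames(out) = CharacterVector::create("molecule", "site", "x", "y", "z");
  return out;
}

// Random sequential insertion of n spheres of radius `rad` avoiding overlap
// with existing spheres and with each other.
// [[Rcpp::export(name = ".engine_rsi")]]
NumericMatrix engine_rsi(NumericMatrix existing, NumericVector exist_rad,
                         int n, double rad, NumericVector box, bool periodic,
                         double seed, double max_attempts) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  Vec3 bx = {box[0], box[1], box[2]};
  auto minimg = [&](Vec3 d) {
    if (periodic) {
      d.x -= bx.x * std::nearbyint(d.x / bx.x);
      d.y -= bx.y * std::nearbyint(d.y / bx.y);
      d.z -= bx.z * std::nearbyint(d.z / bx.z);
    }
    return d;
  };
  // cell grid for overlap queries
  double maxr = rad;
  for (int i = 0; i < exist_rad.size(); ++i) maxr = std::max(maxr, exist_rad[i]);
  double cut = rad + maxr;
  int ncx = std::max(1, (int)std::floor(bx.x / cut));
  int ncy = std::max(1, (int)std::floor(bx.y / cut));
  int ncz = std::max(1, (int)std::floor(bx.z / cut));
  int ncell = ncx * ncy * ncz;
  std::vector<std::vector<int>> cells(ncell);
  std::vector<Vec3> pts;
  std::vector<double> rads;
  auto cellof = [&](Vec3 p) {
    int cx = (int)std::floor((p.x / bx.x + 0.5) * ncx); cx = std::min(std::max(cx, 0), ncx - 1);
    int cy = (int)std::floor((p.y / bx.y + 0.5) * ncy); cy = std::min(std::max(cy, 0), ncy - 1);
    int cz = (int)std::floor((p.z / bx.z + 0.5) * ncz); cz = std::min(std::max(cz, 0), ncz - 1);
    return (cz * ncy + cy) * ncx + cx;
  };
  auto overlaps = [&](Vec3 p) {
    int c = cellof(p);
    int cz = c / (ncx * ncy), cy = (c / ncx) % ncy, cx = c % ncx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int x = (cx + dx + ncx) % ncx, y = (cy + dy + ncy) % ncy,
              z = (cz + dz + ncz) % ncz;
          for (int idx : cells[(z * ncy + y) * ncx + x]) {
            double lim = rad + rads[idx];
            Vec3 d = minimg(p - pts[idx]);
            if (dot(d, d) < lim * lim) return true;
          }
        }
    return false;
  };
  for (int i = 0; i < existing.nrow(); ++i) {
    Vec3 p = {existing(i, 0), existing(i, 1), existing(i, 2)};
    pts.push_back(p); rads.push_back(exist_rad[i]);
    cells[cellof(p)].push_back((int)pts.size() - 1);
  }
  NumericMatrix out(n, 3);
  double attempts = 0;
  // in a walled box keep whole spheres inside
  double mx = periodic ? 0.5 * bx.x : 0.5 * bx.x - rad;
  double my = periodic ? 0.5 * bx.y : 0.5 * bx.y - rad;
  double mz = periodic ? 0.5 * bx.z : 0.5 * bx.z - rad;
  for (int k = 0; k < n; ++k) {
    for (;;) {
      if (++attempts > max_attempts)
        stop("random sequential insertion failed after %.0f attempts (placed %d of %d); use the compression path for this volume fraction",
             attempts, k, n);
      Vec3 p = {(2.0 * U(rng) - 1.0) * mx, (2.0 * U(rng) - 1.0) * my,
                (2.0 * U(rng) - 1.0) * mz};
      if (!overlaps(p)) {
        pts.push_back(p); rads.push_back(rad);
        cells[cellof(p)].push_back((int)pts.size() - 1);
        out(k, 0) = p.x; out(k, 1) = p.y; out(k, 2) = p.z;
        break;
      }
    }
  }
  return out;
}
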