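// Particle engines: 3D cytosolic Brownian dynamics with periodic boundaries,
// collision-mediated membrane (retro)translocation on static axis-aligned
// rectangular mitochondria, lateral 2D membrane diffusion with face
// transitions (surface unfolding), and a mesoscopic binding-radius reaction
// engine for membrane-confined protein interaction networks.
//
// All randomness flows from a std::mt19937_64 seeded once per call; the
// engine output is bit-reproducible for a given seed and input state.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <cstdint>
#include <random>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct RngState {
  std::mt19937_64 eng;
  bool has_cached;
  double cached;
  explicit RngState(uint64_t seed) : eng(seed), has_cached(false), cached(0.0) {}
  double unif() {
    // 53-bit uniform strictly inside (0,1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_cached) {
      has_cached = false;
      return cached;
    }
    // Marsaglia polar method (trig-free Box-Muller)
    double v1, v2, s;
    do {
      v1 = 2.0 * unif() - 1.0;
      v2 = 2.0 * unif() - 1.0;
      s = v1 * v1 + v2 * v2;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    cached = v2 * f;
    has_cached = true;
    return v1 * f;
  }
  int randint(int n) {  // 0..n-1 (modulo bias negligible for n << 2^64)
    return static_cast<int>(eng() % static_cast<uint64_t>(n));
  }
};

struct Box {
  double c[3];
  double h[3];
};

inline void face_axes(int face, int &a, int &s, int &a1, int &a2) {
  a = face / 2;
  s = (face % 2 == 0) ? 1 : -1;
  a1 = (a + 1) % 3;
  a2 = (a + 2) % 3;
}

inline void face_to_xyz(const Box &b, int face, double u, double v, double *p) {
  int a, s, a1, a2;
  face_axes(face, a, s, a1, a2);
  p[a] = b.c[a] + s * b.h[a];
  p[a1] = b.c[a1] - b.h[a1] + u;
  p[a2] = b.c[a2] - b.h[a2] + v;
}

inline void xyz_to_face(const Box &b, int face, const double *p, double &u, double &v) {
  int a, s, a1, a2;
  face_axes(face, a, s, a1, a2);
  u = p[a1] - (b.c[a1] - b.h[a1]);
  v = p[a2] - (b.c[a2] - b.h[a2]);
}

inline void clamp_uv(const Box &b, int face, double &u, double &v) {
  int a, s, a1, a2;
  face_axes(face, a, s, a1, a2);
  double Lu = 2.0 * b.h[a1], Lv = 2.0 * b.h[a2];
  if (u < 0) u = 0;
  if (u > Lu) u = Lu;
  if (v < 0) v = 0;
  if (v > Lv) v = Lv;
}

// Lateral displacement (du, dv) on a box surface starting from (face, u, v).
// Steps crossing a face edge continue onto the adjacent face with path length
// preserved (unfolding). Corners route through the edge crossed first; exact
// ties are broken towards the lower destination face index.
inline void membrane_move(const Box &b, int &face, double &u, double &v,
                          double du, double dv) {
  for (int iter = 0; iter < 10; ++iter) {
    int a, s, a1, a2;
    face_axes(face, a, s, a1, a2);
    double Lu = 2.0 * b.h[a1], Lv = 2.0 * b.h[a2];
    double tbest = 2.0;
    int edge = -1, nfbest = 7;
    // candidate edges: 0:+u, 1:-u, 2:+v, 3:-v
    double tc[4] = {2, 2, 2, 2};
    int nf[4] = {2 * a1, 2 * a1 + 1, 2 * a2, 2 * a2 + 1};
    if (du > 0 && u + du > Lu) tc[0] = (Lu - u) / du;
    if (du < 0 && u + du < 0) tc[1] = -u / du;
    if (dv > 0 && v + dv > Lv) tc[2] = (Lv - v) / dv;
    if (dv < 0 && v + dv < 0) tc[3] = -v / dv;
    for (int e = 0; e < 4; ++e) {
      if (tc[e] <= 1.0) {
        if (tc[e] < tbest - 1e-15 ||
            (std::fabs(tc[e] - tbest) <= 1e-15 && nf[e] < nfbest)) {
          tbest = tc[e];
          edge = e;
          nfbest = nf[e];
        }
      }
    }
    if (edge < 0) {
      u += du;
      v += dv;
      break;
    }
    u += tbest * du;
    v += tbest * dv;
    double rem_u = (1.0 - tbest) * du, rem_v = (1.0 - tbest) * dv;
    double p[3];
    // snap onto the edge exactly before mapping
    if (edge == 0) u = Lu;
    if (edge == 1) u = 0;
    if (edge == 2) v = Lv;
    if (edge == 3) v = 0;
    face_to_xyz(b, face, u, v, p);
    // remaining displacement folded onto the adjacent face: the along-edge
    // component is preserved, the across-edge magnitude continues along the
    // inward direction of the new face, i.e. opposite the old outward normal.
    double r3[3] = {0, 0, 0};
    if (edge == 0) {
      r3[a2] += rem_v;
      r3[a] += -s * rem_u;  // rem_u > 0
    } else if (edge == 1) {
      r3[a2] += rem_v;
      r3[a] += s * rem_u;  // magnitude -rem_u > 0
    } else if (edge == 2) {
      r3[a1] += rem_u;
      r3[a] += -s * rem_v;
    } else {
      r3[a1] += rem_u;
      r3[a] += s * rem_v;
    }
    face = nfbest;
    xyz_to_face(b, face, p, u, v);
    int na, ns, na1, na2;
    face_axes(face, na, ns, na1, na2);
    du = r3[na1];
    dv = r3[na2];
    if (du == 0 && dv == 0) break;
  }
  clamp_uv(b, face, u, v);
}

// First intersection of segment p0 -> p0 + d with box b translated by shift.
// Start point assumed outside. Tangential grazing resolves as no-hit.
inline bool seg_box_hit(const double *p0, const double *d, const double *invd,
                        const Box &b, const double *shift, double &thit,
                        int &hit_face) {
  double tmin = 0.0, tmax = 1.0;
  int axis_enter = -1;
  for (int a = 0; a < 3; ++a) {
    double c = b.c[a] + shift[a];
    double lo = c - b.h[a], hi = c + b.h[a];
    double s0 = p0[a], dd = d[a];
    if (dd == 0.0) {
      if (s0 <= lo || s0 >= hi) return false;
    } else {
      double t1 = (lo - s0) * invd[a], t2 = (hi - s0) * invd[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) {
        tmin = t1;
        axis_enter = a;
      }
      if (t2 < tmax) tmax = t2;
      if (tmin >= tmax) return false;
    }
  }
  if (axis_enter < 0) return false;
  if (tmin <= 1e-12 || tmin > 1.0) return false;
  thit = tmin;
  // moving towards +a enters the -a face (index 2a+1), and vice versa
  hit_face = 2 * axis_enter + (d[axis_enter] > 0 ? 1 : 0);
  return true;
}

struct Grid {
  int n[3];
  double L[3];
  std::vector<std::vector<int>> cells;
  std::vector<char> wrapped;  // cell received a box through the periodic seam
  int idx(int i, int j, int k) const { return (i * n[1] + j) * n[2] + k; }
  int cell_of(const double *p) const {
    int ii[3];
    for (int a = 0; a < 3; ++a) {
      double x = p[a] / L[a] + 0.5;
      int i = static_cast<int>(std::floor(x * n[a]));
      i %= n[a];
      if (i < 0) i += n[a];
      ii[a] = i;
    }
    return idx(ii[0], ii[1], ii[2]);
  }
};

void build_grid(Grid &g, const std::vector<Box> &boxes, const double *L,
                double expand) {
  for (int a = 0; a < 3; ++a) {
    g.L[a] = L[a];
    g.n[a] = std::max(1, static_cast<int>(std::floor(L[a] / 0.5)));
  }
  g.cells.assign(g.n[0] * g.n[1] * g.n[2], {});
  g.wrapped.assign(g.cells.size(), 0);
  for (size_t bi = 0; bi < boxes.size(); ++bi) {
    int lo[3], hi[3];
    for (int a = 0; a < 3; ++a) {
      double l = boxes[bi].c[a] - boxes[bi].h[a] - expand;
      double hh = boxes[bi].c[a] + boxes[bi].h[a] + expand;
      lo[a] = static_cast<int>(std::floor((l / L[a] + 0.5) * g.n[a]));
      hi[a] = static_cast<int>(std::floor((hh / L[a] + 0.5) * g.n[a]));
      if (hi[a] - lo[a] + 1 >= g.n[a]) {
        lo[a] = 0;
        hi[a] = g.n[a] - 1;
      }
    }
    for (int i = lo[0]; i <= hi[0]; ++i)
      for (int j = lo[1]; j <= hi[1]; ++j)
        for (int k = lo[2]; k <= hi[2]; ++k) {
          bool wr = (i < 0 || i >= g.n[0] || j < 0 || j >= g.n[1] || k < 0 ||
                     k >= g.n[2]);
          int ii = ((i % g.n[0]) + g.n[0]) % g.n[0];
          int jj = ((j % g.n[1]) + g.n[1]) % g.n[1];
          int kk = ((k % g.n[2]) + g.n[2]) % g.n[2];
          int f = g.idx(ii, jj, kk);
          g.cells[f].push_back(static_cast<int>(bi));
          if (wr) g.wrapped[f] = 1;
        }
  }
}

inline void wrap3(double *p, const double *L) {
  for (int a = 0; a < 3; ++a) p[a] -= L[a] * std::nearbyint(p[a] / L[a]);
}

// Propagate one cytosolic particle along displacement d with specular
// reflection / probabilistic binding at mitochondrial surfaces.
// Returns -1 if the particle remains cytosolic (p updated), otherwise the
// index of the box it bound to (face/u/v set).
// The candidate boxes are gathered from the grid cells overlapped by the
// ball of radius |d| around the start point (reflections preserve path
// length, so the whole trajectory of the step stays inside that ball).
inline int move_cytosol(double *p, double *d, const std::vector<Box> &boxes,
                        const Grid &g, const double *L, double pbind,
                        RngState &rng, double *collcnt, int &face_out,
                        double &u_out, double &v_out) {
  // candidate boxes from the start-point cell: per-axis steps are clamped to
  // 4 sigma and reflections preserve path length, so the grid expansion
  // (4 sigma * sqrt(3) + margin) covers every box the step could reach
  int ci = g.cell_of(p);
  const std::vector<int> &cand = g.cells[ci];
  if (cand.empty()) {
    for (int a = 0; a < 3; ++a) p[a] += d[a];
    wrap3(p, L);
    return -1;
  }
  const bool need_wrap = g.wrapped[ci] != 0;
  static const double zero_shift[3] = {0, 0, 0};
  for (int iter = 0; iter < 8; ++iter) {
    double tbest = 2.0, shiftbest[3] = {0, 0, 0};
    int bbest = -1, fbest = -1;
    double invd[3];
    for (int a = 0; a < 3; ++a) invd[a] = (d[a] == 0.0) ? 0.0 : 1.0 / d[a];
    for (int bi : cand) {
      double shift_buf[3];
      const double *shift = zero_shift;
      if (need_wrap) {
        for (int a = 0; a < 3; ++a)
          shift_buf[a] = L[a] * std::nearbyint((p[a] - boxes[bi].c[a]) / L[a]);
        shift = shift_buf;
      }
      double t;
      int f;
      if (seg_box_hit(p, d, invd, boxes[bi], shift, t, f) && t < tbest) {
        tbest = t;
        bbest = bi;
        fbest = f;
        for (int a = 0; a < 3; ++a) shiftbest[a] = shift[a];
      }
    }
    if (bbest < 0) {
      for (int a = 0; a < 3; ++a) p[a] += d[a];
      wrap3(p, L);
      return -1;
    }
    if (collcnt) collcnt[bbest] += 1.0;
    double hp[3];
    for (int a = 0; a < 3; ++a) hp[a] = p[a] + tbest * d[a];
    int axis = fbest / 2;
    double outw = (fbest % 2 == 0) ? 1.0 : -1.0;
    if (rng.unif() < pbind) {
      double q[3];
      for (int a = 0; a < 3; ++a) q[a] = hp[a] - shiftbest[a];
      q[axis] = boxes[bbest].c[axis] + outw * boxes[bbest].h[axis];
      xyz_to_face(boxes[bbest], fbest, q, u_out, v_out);
      clamp_uv(boxes[bbest], fbest, u_out, v_out);
      face_out = fbest;
      return bbest;
    }
    // specular reflection, nudged off the face to avoid re-detection
    for (int a = 0; a < 3; ++a) {
      double rem = (1.0 - tbest) * d[a];
      d[a] = (a == axis) ? -rem : rem;
      p[a] = hp[a];
    }
    p[axis] += outw * 1e-7;
    if (iter == 7) {
      // reflection cap: stay at the last hit point, 1 nm outward
      p[axis] += outw * 1e-3;
      wrap3(p, L);
      return -1;
    }
  }
  return -1;  // unreachable
}

std::vector<Box> make_boxes(const NumericMatrix &centers,
                            const NumericMatrix &halfs) {
  int n = centers.nrow();
  std::vector<Box> boxes(n);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) {
      boxes[i].c[a] = centers(i, a);
      boxes[i].h[a] = halfs(i, a);
    }
  return boxes;
}

}  // namespace

// Whole-cell translocation run: multi-species Brownian dynamics with
// membrane binding, lateral membrane diffusion and retrotranslocation.
// comp: 0 = cytosol (xyz used), 1 = membrane (box/face/u/v used).
// [[Rcpp::export]]
List run_translocation_cpp(NumericVector cell_dims, NumericMatrix centers,
                           NumericMatrix halfs, IntegerVector sp,
                           IntegerVector comp, NumericMatrix xyz,
                           IntegerVector boxid, IntegerVector face,
                           NumericMatrix uv, NumericVector D_cyto,
                           NumericVector D_mem, NumericVector p_bind,
                           NumericVector k_off, double dt, int n_steps,
                           int record_every, double seed,
                           int collide_from_step = 0) {
  const int N = sp.size();
  const int K = D_cyto.size();
  double L[3] = {cell_dims[0], cell_dims[1], cell_dims[2]};
  std::vector<Box> boxes = make_boxes(centers, halfs);
  const int nb = static_cast<int>(boxes.size());

  std::vector<double> sig_c(K), sig_m(K), p_off(K);
  double sig_max = 0.0;
  for (int k = 0; k < K; ++k) {
    sig_c[k] = std::sqrt(2.0 * D_cyto[k] * dt);
    sig_m[k] = std::sqrt(2.0 * D_mem[k] * dt);
    p_off[k] = 1.0 - std::exp(-k_off[k] * dt);
    if (sig_c[k] > sig_max) sig_max = sig_c[k];
  }
  const double clamp4 = 4.0 * sig_max;
  Grid grid;
  build_grid(grid, boxes, L, clamp4 * 1.7320509 + 0.01);

  // working copies
  std::vector<int> P_sp(sp.begin(), sp.end()), P_comp(comp.begin(), comp.end()),
      P_box(boxid.begin(), boxid.end()), P_face(face.begin(), face.end());
  std::vector<double> X(N), Y(N), Z(N), U(N), V(N);
  for (int i = 0; i < N; ++i) {
    X[i] = xyz(i, 0);
    Y[i] = xyz(i, 1);
    Z[i] = xyz(i, 2);
    U[i] = uv(i, 0);
    V[i] = uv(i, 1);
  }

  RngState rng(static_cast<uint64_t>(seed));
  std::vector<double> coll(nb * K, 0.0);

  int n_rec = (record_every > 0) ? (n_steps / record_every + 1) : 2;
  NumericMatrix series(n_rec, 1 + 2 * K);
  int rec_i = 0;
  auto record = [&](int step) {
    if (rec_i >= n_rec) return;
    std::vector<int> nc(K, 0), nm(K, 0);
    for (int i = 0; i < N; ++i) {
      if (P_comp[i] == 0)
        nc[P_sp[i]]++;
      else
        nm[P_sp[i]]++;
    }
    series(rec_i, 0) = step * dt;
    for (int k = 0; k < K; ++k) {
      series(rec_i, 1 + k) = nc[k];
      series(rec_i, 1 + K + k) = nm[k];
    }
    rec_i++;
  };
  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    bool do_count = (step > collide_from_step);
    for (int i = 0; i < N; ++i) {
      int k = P_sp[i];
      if (P_comp[i] == 0) {
        if (sig_c[k] == 0.0) continue;
        double d[3];
        for (int a = 0; a < 3; ++a) {
          double z = sig_c[k] * rng.norm();
          if (z > clamp4) z = clamp4;
          if (z < -clamp4) z = -clamp4;
          d[a] = z;
        }
        double p[3] = {X[i], Y[i], Z[i]};
        int f;
        double uu, vv;
        int b = move_cytosol(p, d, boxes, grid, L, p_bind[k], rng,
                             do_count ? coll.data() + static_cast<size_t>(k) * nb
                                      : nullptr,
                             f, uu, vv);
        if (b >= 0) {
          P_comp[i] = 1;
          P_box[i] = b;
          P_face[i] = f;
          U[i] = uu;
          V[i] = vv;
        } else {
          X[i] = p[0];
          Y[i] = p[1];
          Z[i] = p[2];
        }
      } else {
        const Box &b = boxes[P_box[i]];
        if (sig_m[k] > 0.0) {
          double du = sig_m[k] * rng.norm(), dv = sig_m[k] * rng.norm();
          int f = P_face[i];
          double uu = U[i], vv = V[i];
          membrane_move(b, f, uu, vv, du, dv);
          P_face[i] = f;
          U[i] = uu;
          V[i] = vv;
        }
        if (p_off[k] > 0.0 && rng.unif() < p_off[k]) {
          double p[3];
          face_to_xyz(b, P_face[i], U[i], V[i], p);
          int a, s, a1, a2;
          face_axes(P_face[i], a, s, a1, a2);
          p[a] += s * 1e-3;  // release 1 nm along the outward normal
          wrap3(p, L);
          P_comp[i] = 0;
          X[i] = p[0];
          Y[i] = p[1];
          Z[i] = p[2];
          P_box[i] = -1;
          P_face[i] = -1;
        }
      }
    }
    if (record_every > 0 && step % record_every == 0) record(step);
  }
  if (rec_i == 0 || series(rec_i - 1, 0) < n_steps * dt) record(n_steps);

  // final membrane counts per box x species
  NumericMatrix memcnt(nb, K);
  for (int i = 0; i < N; ++i)
    if (P_comp[i] == 1) memcnt(P_box[i], P_sp[i]) += 1.0;

  NumericMatrix collm(nb, K);
  for (int k = 0; k < K; ++k)
    for (int b = 0; b < nb; ++b) collm(b, k) = coll[static_cast<size_t>(k) * nb + b];

  NumericMatrix xyz_out(N, 3), uv_out(N, 2);
  for (int i = 0; i < N; ++i) {
    if (P_comp[i] == 1) {
      double p[3];
      face_to_xyz(boxes[P_box[i]], P_face[i], U[i], V[i], p);
      xyz_out(i, 0) = p[0];
      xyz_out(i, 1) = p[1];
      xyz_out(i, 2) = p[2];
    } else {
      xyz_out(i, 0) = X[i];
      xyz_out(i, 1) = Y[i];
      xyz_out(i, 2) = Z[i];
    }
    uv_out(i, 0) = U[i];
    uv_out(i, 1) = V[i];
  }

  return List::create(
      _["species"] = IntegerVector(P_sp.begin(), P_sp.end()),
      _["compartment"] = IntegerVector(P_comp.begin(), P_comp.end()),
      _["box"] = IntegerVector(P_box.begin(), P_box.end()),
      _["face"] = IntegerVector(P_face.begin(), P_face.end()),
      _["xyz"] = xyz_out, _["uv"] = uv_out,
      _["series"] = series(Range(0, rec_i - 1), _),
      _["collisions"] = collm, _["mem_counts"] = memcnt);
}

// Single segment vs geometry: first-collision outcome used by unit tests.
// [[Rcpp::export]]
List collide_partition_cpp(NumericVector start, NumericVector end,
                           NumericVector cell_dims, NumericMatrix centers,
                           NumericMatrix halfs, double p_bind, double seed) {
  double L[3] = {cell_dims[0], cell_dims[1], cell_dims[2]};
  std::vector<Box> boxes = make_boxes(centers, halfs);
  Grid grid;
  double steplen = 1e-6;
  for (int a = 0; a < 3; ++a)
    steplen += std::fabs(end[a] - start[a]);
  build_grid(grid, boxes, L, 2.0 * steplen);
  RngState rng(static_cast<uint64_t>(seed));
  std::vector<double> coll(boxes.size(), 0.0);
  double p[3] = {start[0], start[1], start[2]};
  double d[3] = {end[0] - start[0], end[1] - start[1], end[2] - start[2]};
  int f = -1;
  double u = 0, v = 0;
  // single-species view: collision counts collapse over boxes
  int b = move_cytosol(p, d, boxes, grid, L, p_bind, rng, coll.data(), f, u, v);
  double ncoll = 0;
  for (double c : coll) ncoll += c;
  std::string outcome = (b >= 0) ? "bound" : (ncoll > 0 ? "reflected" : "no_hit");
  return List::create(_["outcome"] = outcome, _["mito"] = b, _["face"] = f,
                      _["u"] = u, _["v"] = v,
                      _["pos"] = NumericVector::create(p[0], p[1], p[2]),
                      _["n_collisions"] = ncoll);
}

// Deterministic single lateral displacement on a box surface (topology tests).
// [[Rcpp::export]]
List membrane_step_cpp(NumericVector center, NumericVector half, int face,
                       double u, double v, double du, double dv) {
  Box b;
  for (int a = 0; a < 3; ++a) {
    b.c[a] = center[a];
    b.h[a] = half[a];
  }
  membrane_move(b, face, u, v, du, dv);
  double p[3];
  face_to_xyz(b, face, u, v, p);
  return List::create(_["face"] = face, _["u"] = u, _["v"] = v,
                      _["pos"] = NumericVector::create(p[0], p[1], p[2]));
}

namespace {

// flat cell list over a bounded domain with lazy (stamped) clearing;
// rebuilt every step for the bimolecular pair search
struct CellList {
  double lo[3], cs;
  int n[3], dim;
  bool periodic;
  double Lx, Ly;
  std::vector<int> head, stamp, nxt;
  int epoch = 0;

  void init(const double *lo_, const double *hi_, double cell_size, int dim_,
            bool periodic_, double Lx_, double Ly_, int n_particles) {
    dim = dim_;
    periodic = periodic_;
    Lx = Lx_;
    Ly = Ly_;
    cs = cell_size;
    long total = 1;
    for (int a = 0; a < 3; ++a) {
      lo[a] = lo_[a];
      double span = std::max(hi_[a] - lo_[a], cs);
      n[a] = (a < dim) ? std::max(1, static_cast<int>(std::ceil(span / cs)))
                       : 1;
      total *= n[a];
    }
    head.assign(total, -1);
    stamp.assign(total, -1);
    nxt.assign(n_particles, -1);
  }
  inline int wrapi(int i, int a) const {
    if (!periodic) return (i < 0 || i >= n[a]) ? -1 : i;
    i %= n[a];
    return (i < 0) ? i + n[a] : i;
  }
  inline int flat(int i, int j, int k) const { return (i * n[1] + j) * n[2] + k; }
  inline void coords(const double *p, int *c) const {
    for (int a = 0; a < 3; ++a) {
      if (a >= dim) {
        c[a] = 0;
        continue;
      }
      int i = static_cast<int>(std::floor((p[a] - lo[a]) / cs));
      if (periodic) {
        i %= n[a];
        if (i < 0) i += n[a];
      } else {
        if (i < 0) i = 0;
        if (i >= n[a]) i = n[a] - 1;
      }
      c[a] = i;
    }
  }
  inline void insert(int i, const double *p) {
    int c[3];
    coords(p, c);
    int f = flat(c[0], c[1], c[2]);
    if (stamp[f] != epoch) {
      stamp[f] = epoch;
      head[f] = -1;
    }
    if (i >= static_cast<int>(nxt.size())) nxt.resize(i + 64, -1);
    nxt[i] = head[f];
    head[f] = i;
  }
};

}  // namespace

// Membrane reaction engine on a box surface or a periodic rectangular patch.
// surface_type: 0 = periodic patch (surf_par = Lx, Ly; face ignored, u/v are
// wrapped coordinates), 1 = box surface (surf_par = cx,cy,cz,hx,hy,hz).
// Bimolecular rules fire when an unordered pair sits within the rule's
// binding radius after the diffusion substep; candidate pairs are processed
// in randomized order and each particle reacts at most once per step.
// Catalytic rules convert the B-role reactant in place (A survives).
// Unimolecular dissociations fire with a per-step probability and place the
// two products an unbinding radius apart.
// [[Rcpp::export]]
List run_reactions_cpp(int surface_type, NumericVector surf_par, int n_species,
                       NumericVector D_mem, IntegerVector sp,
                       IntegerVector face, NumericVector u, NumericVector v,
                       IntegerVector bi_rA, IntegerVector bi_rB,
                       IntegerVector bi_prod, IntegerVector bi_cat,
                       NumericVector bi_rbind, IntegerVector un_re,
                       IntegerVector un_p1, IntegerVector un_p2,
                       NumericVector un_prob, NumericVector un_rd, double dt,
                       int n_steps, int record_every, double seed) {
  const int K = n_species;
  Box box;
  double Lx = 0, Ly = 0;
  const bool on_box = (surface_type == 1);
  if (on_box) {
    for (int a = 0; a < 3; ++a) {
      box.c[a] = surf_par[a];
      box.h[a] = surf_par[3 + a];
    }
  } else {
    Lx = surf_par[0];
    Ly = surf_par[1];
  }

  std::vector<int> P_sp(sp.begin(), sp.end()), P_face(face.begin(), face.end());
  std::vector<double> P_u(u.begin(), u.end()), P_v(v.begin(), v.end());
  std::vector<char> alive(P_sp.size(), 1);

  std::vector<double> sig(K);
  for (int k = 0; k < K; ++k) sig[k] = std::sqrt(2.0 * D_mem[k] * dt);

  const int nbi = bi_rA.size();
  std::vector<int> rule(K * K, -1);
  double rmax = 0.0;
  for (int r = 0; r < nbi; ++r) {
    rule[bi_rA[r] * K + bi_rB[r]] = r;
    rule[bi_rB[r] * K + bi_rA[r]] = r;
    if (bi_rbind[r] > rmax) rmax = bi_rbind[r];
  }
  std::vector<int> uni_of(K, -1);
  for (int r = 0; r < un_re.size(); ++r) uni_of[un_re[r]] = r;

  RngState rng(static_cast<uint64_t>(seed));

  auto pos3 = [&](int i, double *p) {
    if (on_box) {
      face_to_xyz(box, P_face[i], P_u[i], P_v[i], p);
    } else {
      p[0] = P_u[i];
      p[1] = P_v[i];
      p[2] = 0.0;
    }
  };
  auto wrap_patch = [&](int i) {
    P_u[i] -= Lx * std::floor(P_u[i] / Lx);
    P_v[i] -= Ly * std::floor(P_v[i] / Ly);
  };
  auto displace = [&](int i, double du, double dv) {
    if (on_box) {
      int f = P_face[i];
      double uu = P_u[i], vv = P_v[i];
      membrane_move(box, f, uu, vv, du, dv);
      P_face[i] = f;
      P_u[i] = uu;
      P_v[i] = vv;
    } else {
      P_u[i] += du;
      P_v[i] += dv;
      wrap_patch(i);
    }
  };

  int n_rec = (record_every > 0) ? (n_steps / record_every + 1) : 2;
  NumericMatrix series(n_rec, 1 + K);
  int rec_i = 0;
  auto record = [&](int step) {
    if (rec_i >= n_rec) return;
    std::vector<int> cnt(K, 0);
    for (size_t i = 0; i < P_sp.size(); ++i)
      if (alive[i]) cnt[P_sp[i]]++;
    series(rec_i, 0) = step * dt;
    for (int k = 0; k < K; ++k) series(rec_i, 1 + k) = cnt[k];
    rec_i++;
  };
  record(0);

  // species taking part in any bimolecular rule
  std::vector<char> reactive(K, 0);
  for (int r = 0; r < nbi; ++r) {
    reactive[bi_rA[r]] = 1;
    reactive[bi_rB[r]] = 1;
  }

  CellList cl;
  if (nbi > 0 && rmax > 0) {
    double lo[3], hi[3];
    if (on_box) {
      for (int a = 0; a < 3; ++a) {
        lo[a] = box.c[a] - box.h[a] - 1e-9;
        hi[a] = box.c[a] + box.h[a] + 1e-9;
      }
    } else {
      lo[0] = lo[1] = lo[2] = 0;
      hi[0] = Lx;
      hi[1] = Ly;
      hi[2] = 0;
    }
    // cell size targets ~1 particle per occupied cell (keeps both the
    // neighbor scan short and the head/stamp arrays cache-resident)
    double area = on_box ? 2.0 * ((2 * box.h[0]) * (2 * box.h[1]) +
                                  (2 * box.h[1]) * (2 * box.h[2]) +
                                  (2 * box.h[2]) * (2 * box.h[0]))
                         : Lx * Ly;
    double n0 = std::max(static_cast<double>(P_sp.size()), 1.0);
    double cs = std::max(2.5 * rmax, 0.7 * std::sqrt(area / n0));
    cl.init(lo, hi, cs, on_box ? 3 : 2, !on_box, Lx, Ly,
            static_cast<int>(P_sp.size()));
  }

  std::vector<std::array<double, 3>> pcache;
  struct Cand {
    int i, j, r;
  };
  std::vector<Cand> cands;

  for (int step = 1; step <= n_steps; ++step) {
    const int n0 = static_cast<int>(P_sp.size());
    // diffusion substep
    for (int i = 0; i < n0; ++i) {
      if (!alive[i]) continue;
      double s = sig[P_sp[i]];
      if (s > 0) displace(i, s * rng.norm(), s * rng.norm());
    }
    // bimolecular reactions
    if (nbi > 0 && rmax > 0) {
      cl.epoch++;
      pcache.assign(n0, {0, 0, 0});
      for (int i = 0; i < n0; ++i) {
        if (!alive[i] || !reactive[P_sp[i]]) continue;
        double p[3];
        pos3(i, p);
        pcache[i] = {p[0], p[1], p[2]};
        cl.insert(i, p);
      }
      cands.clear();
      const int kmax = on_box ? 1 : 0;
      for (int i = 0; i < n0; ++i) {
        if (!alive[i] || !reactive[P_sp[i]]) continue;
        const double *pi = pcache[i].data();
        int cc[3];
        cl.coords(pi, cc);
        for (int di = -1; di <= 1; ++di) {
          int ci = cl.wrapi(cc[0] + di, 0);
          if (ci < 0) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            int cj = cl.wrapi(cc[1] + dj, 1);
            if (cj < 0) continue;
            for (int dk = -kmax; dk <= kmax; ++dk) {
              int ck = cl.wrapi(cc[2] + dk, 2);
              if (ck < 0) continue;
              int f = cl.flat(ci, cj, ck);
              if (cl.stamp[f] != cl.epoch) continue;
              for (int j = cl.head[f]; j >= 0; j = cl.nxt[j]) {
                if (j <= i) continue;
                int r = rule[P_sp[i] * K + P_sp[j]];
                if (r < 0) continue;
                const double *pj = pcache[j].data();
                double ddx = pi[0] - pj[0], ddy = pi[1] - pj[1],
                       ddz = pi[2] - pj[2];
                if (!on_box) {
                  ddx -= Lx * std::nearbyint(ddx / Lx);
                  ddy -= Ly * std::nearbyint(ddy / Ly);
                }
                double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
                if (d2 <= bi_rbind[r] * bi_rbind[r]) cands.push_back({i, j, r});
              }
            }
          }
        }
      }
      // randomized processing order; a consumed particle is removed from
      // later pairs within the same step
      for (int m = static_cast<int>(cands.size()) - 1; m > 0; --m) {
        int pick = rng.randint(m + 1);
        std::swap(cands[m], cands[pick]);
      }
      std::vector<char> used(n0, 0);
      for (const Cand &cd : cands) {
        if (!alive[cd.i] || !alive[cd.j] || used[cd.i] || used[cd.j]) continue;
        used[cd.i] = used[cd.j] = 1;
        int ia = cd.i, ib = cd.j;
        if (P_sp[ia] != bi_rA[cd.r]) std::swap(ia, ib);
        if (bi_cat[cd.r] == 1) {
          P_sp[ib] = bi_prod[cd.r];  // B converted in place, A survives
        } else {
          P_sp[ia] = bi_prod[cd.r];  // complex at the A-role position
          alive[ib] = 0;
        }
      }
    }
    // unimolecular dissociations
    {
      const int n1 = static_cast<int>(P_sp.size());
      for (int i = 0; i < n1; ++i) {
        if (!alive[i]) continue;
        int r = uni_of[P_sp[i]];
        if (r < 0 || un_prob[r] <= 0) continue;
        if (rng.unif() < un_prob[r]) {
          double th = 6.283185307179586 * rng.unif();
          double ox = 0.5 * un_rd[r] * std::cos(th);
          double oy = 0.5 * un_rd[r] * std::sin(th);
          int f2 = P_face[i];
          double u2 = P_u[i], v2 = P_v[i];
          P_sp[i] = un_p1[r];
          displace(i, ox, oy);
          P_sp.push_back(un_p2[r]);
          P_face.push_back(f2);
          P_u.push_back(u2);
          P_v.push_back(v2);
          alive.push_back(1);
          int inew = static_cast<int>(P_sp.size()) - 1;
          displace(inew, -ox, -oy);
        }
      }
    }
    if (record_every > 0 && step % record_every == 0) record(step);
  }
  if (rec_i == 0 || series(rec_i - 1, 0) < n_steps * dt) record(n_steps);

  // compact final state
  std::vector<int> o_sp, o_face;
  std::vector<double> o_u, o_v;
  for (size_t i = 0; i < P_sp.size(); ++i) {
    if (!alive[i]) continue;
    o_sp.push_back(P_sp[i]);
    o_face.push_back(P_face[i]);
    o_u.push_back(P_u[i]);
    o_v.push_back(P_v[i]);
  }
  return List::create(_["species"] = IntegerVector(o_sp.begin(), o_sp.end()),
                      _["face"] = IntegerVector(o_face.begin(), o_face.end()),
                      _["u"] = NumericVector(o_u.begin(), o_u.end()),
                      _["v"] = NumericVector(o_v.begin(), o_v.end()),
                      _["series"] = series(Range(0, rec_i - 1), _));
}

// Connected-component labeling of a binary mask (4- or 8-connectivity).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (int q = 0; q < nnb; ++q) {
          int rr = r + dr8[q], cc = c + dc8[q];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  return lab;
}
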