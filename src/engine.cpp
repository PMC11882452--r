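// Monte Carlo engine for state-augmented Kern-Frenkel patchy discs.
//
// Particles are hard discs of diameter sigma carrying three patches at 120
// degrees. A patch binds only in its "closed" state (1); "open" (0) patches
// are inert. A pair is bonded (energy -eps) when sigma <= r < sigma + delta
// and one patch on each particle points at the partner within the half-width
// theta_pw, with both patches closed. Energies are in units of kT (beta = 1).
//
// All randomness comes from R's RNG so set.seed() gives bit-identical runs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925287;
static const double PATCH_SEP = TWO_PI / 3.0;

struct Pot {
  double L, sigma, delta, theta_pw, eps, p_open;
  double s2, rc2; // sigma^2, (sigma+delta)^2
};

static inline double wrap_d(double d, double L) {
  // minimum-image component in [-L/2, L/2)
  return d - L * std::floor(d / L + 0.5);
}

static inline double wrap_pos(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L || x < 0.0) x = 0.0; // guard against fp edge
  return x;
}

static inline double ang_wrap(double a) {
  // wrap to [-pi, pi)
  return a - TWO_PI * std::floor(a / TWO_PI + 0.5);
}

// Pair interaction code: -1 overlap, 0 nothing, 1 bonded (pa, pb filled with
// the bonding patch indices, smallest summed angular deviation wins ties).
static inline int pair_code(double xi, double yi, double thi, const int* si,
                            double xj, double yj, double thj, const int* sj,
                            const Pot& P, int& pa, int& pb) {
  double dx = wrap_d(xj - xi, P.L), dy = wrap_d(yj - yi, P.L);
  double r2 = dx * dx + dy * dy;
  if (r2 >= P.rc2) return 0;
  if (r2 < P.s2) return -1;
  double phi = std::atan2(dy, dx);
  double best = 1e300;
  pa = -1; pb = -1;
  for (int a = 0; a < 3; ++a) {
    if (!si[a]) continue;
    double da = std::fabs(ang_wrap(thi + a * PATCH_SEP - phi));
    if (da >= P.theta_pw) continue;
    for (int b = 0; b < 3; ++b) {
      if (!sj[b]) continue;
      double db = std::fabs(ang_wrap(thj + b * PATCH_SEP - phi - M_PI));
      if (db >= P.theta_pw) continue;
      if (da + db < best) { best = da + db; pa = a; pb = b; }
    }
  }
  return (pa >= 0) ? 1 : 0;
}

// --------------------------------------------------------------------------
// System with an incrementally maintained cell list.

struct Sys {
  Pot P;
  std::vector<double> x, y, th;
  std::vector<int> st; // 3 per particle
  int nc;              // cells per side (0 => brute force, small boxes)
  double cw;
  std::vector<int> head, nxt, prv, cellof;

  int n() const { return (int)x.size(); }

  void init_cells() {
    double rc = P.sigma + P.delta;
    nc = (int)std::floor(P.L / rc);
    if (nc < 4) { nc = 0; return; } // brute force below 4 cells per side
    cw = P.L / nc;
    head.assign(nc * nc, -1);
    nxt.assign(n(), -1);
    prv.assign(n(), -1);
    cellof.assign(n(), -1);
    for (int i = 0; i < n(); ++i) cell_insert(i);
  }

  int cell_index(double xi, double yi) const {
    int cx = (int)(xi / cw), cy = (int)(yi / cw);
    if (cx >= nc) cx = nc - 1;
    if (cy >= nc) cy = nc - 1;
    return cy * nc + cx;
  }

  void cell_insert(int i) {
    int c = cell_index(x[i], y[i]);
    cellof[i] = c;
    nxt[i] = head[c];
    prv[i] = -1;
    if (head[c] >= 0) prv[head[c]] = i;
    head[c] = i;
  }

  void cell_remove(int i) {
    int c = cellof[i];
    if (prv[i] >= 0) nxt[prv[i]] = nxt[i]; else head[c] = nxt[i];
    if (nxt[i] >= 0) prv[nxt[i]] = prv[i];
  }

  void cell_move(int i) {
    int c = cell_index(x[i], y[i]);
    if (c == cellof[i]) return;
    cell_remove(i);
    cell_insert(i);
  }

  void add_particle(double xi, double yi, double thi, int s0, int s1, int s2) {
    x.push_back(xi); y.push_back(yi); th.push_back(thi);
    st.push_back(s0); st.push_back(s1); st.push_back(s2);
    if (nc > 0) {
      nxt.push_back(-1); prv.push_back(-1); cellof.push_back(-1);
      cell_insert(n() - 1);
    }
  }

  // Energy of a trial particle (xi, yi, thi, si) interacting with everything
  // except index `skip`. Sets `overlap`; optionally records bonded partners.
  double energy_around(double xi, double yi, double thi, const int* si,
                       int skip, bool& overlap,
                       std::vector<int>* partners) const {
    overlap = false;
    double e = 0.0;
    int pa, pb;
    if (nc == 0) {
      for (int j = 0; j < n(); ++j) {
        if (j == skip) continue;
        int code = pair_code(xi, yi, thi, si, x[j], y[j], th[j], &st[3 * j], P, pa, pb);
        if (code < 0) { overlap = true; return 0.0; }
        if (code > 0) { e -= P.eps; if (partners) partners->push_back(j); }
      }
      return e;
    }
    int cx = (int)(xi / cw), cy = (int)(yi / cw);
    if (cx >= nc) cx = nc - 1;
    if (cy >= nc) cy = nc - 1;
    for (int oy = -1; oy <= 1; ++oy) {
      int gy = (cy + oy + nc) % nc;
      for (int ox = -1; ox <= 1; ++ox) {
        int gx = (cx + ox + nc) % nc;
        for (int j = head[gy * nc + gx]; j >= 0; j = nxt[j]) {
          if (j == skip) continue;
          int code = pair_code(xi, yi, thi, si, x[j], y[j], th[j], &st[3 * j], P, pa, pb);
          if (code < 0) { overlap = true; return 0.0; }
          if (code > 0) { e -= P.eps; if (partners) partners->push_back(j); }
        }
      }
    }
    return e;
  }

  double energy_of(int i, bool& overlap, std::vector<int>* partners) const {
    return energy_around(x[i], y[i], th[i], &st[3 * i], i, overlap, partners);
  }

  double total_energy(bool& overlap) const {
    double e = 0.0;
    overlap = false;
    for (int i = 0; i < n(); ++i) {
      bool ov = false;
      e += energy_of(i, ov, nullptr);
      if (ov) { overlap = true; return 0.0; }
    }
    return 0.5 * e;
  }
};

static Pot make_pot(double L, double sigma, double delta, double theta_pw,
                    double eps, double p_open) {
  Pot P;
  P.L = L; P.sigma = sigma; P.delta = delta; P.theta_pw = theta_pw;
  P.eps = eps; P.p_open = p_open;
  P.s2 = sigma * sigma;
  P.rc2 = (sigma + delta) * (sigma + delta);
  return P;
}

static Sys make_sys(NumericVector x, NumericVector y, NumericVector th,
                    IntegerMatrix st, const Pot& P) {
  Sys S;
  S.P = P;
  int n = x.size();
  S.x.assign(x.begin(), x.end());
  S.y.assign(y.begin(), y.end());
  S.th.assign(th.begin(), th.end());
  S.st.resize(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) S.st[3 * i + k] = st(i, k);
  S.init_cells();
  return S;
}

// --------------------------------------------------------------------------
// Exported primitives

// [[Rcpp::export]]
NumericVector minimum_image_cpp(NumericVector dx, NumericVector dy, double L) {
  int n = dx.size();
  NumericVector out(2 * n);
  for (int i = 0; i < n; ++i) {
    out[i] = wrap_d(dx[i], L);
    out[n + i] = wrap_d(dy[i], L);
  }
  return out;
}

// [[Rcpp::export]]
List pair_energy_cpp(double xi, double yi, double thi, IntegerVector si,
                     double xj, double yj, double thj, IntegerVector sj,
                     double L, double sigma, double delta, double theta_pw,
                     double eps) {
  Pot P = make_pot(L, sigma, delta, theta_pw, eps, 0.5);
  int pa, pb;
  int sa[3] = { si[0], si[1], si[2] }, sb[3] = { sj[0], sj[1], sj[2] };
  int code = pair_code(xi, yi, thi, sa, xj, yj, thj, sb, P, pa, pb);
  return List::create(_["code"] = code,
                      _["energy"] = (code > 0) ? -eps : 0.0,
                      _["patch_i"] = (code > 0) ? pa + 1 : NA_INTEGER,
                      _["patch_j"] = (code > 0) ? pb + 1 : NA_INTEGER);
}

// [[Rcpp::export]]
double total_energy_cpp(NumericVector x, NumericVector y, NumericVector th,
                        IntegerMatrix st, double L, double sigma, double delta,
                        double theta_pw, double eps) {
  Sys S = make_sys(x, y, th, st, make_pot(L, sigma, delta, theta_pw, eps, 0.5));
  // overlap reported with the offending pair
  int pa, pb;
  for (int i = 0; i < S.n(); ++i) {
    bool ov;
    std::vector<int> dummy;
    S.energy_of(i, ov, nullptr);
    if (ov) {
      for (int j = 0; j < S.n(); ++j) {
        if (j == i) continue;
        int code = pair_code(S.x[i], S.y[i], S.th[i], &S.st[3 * i],
                             S.x[j], S.y[j], S.th[j], &S.st[3 * j], S.P, pa, pb);
        if (code < 0)
          stop("hard-core overlap between particles %d and %d", i + 1, j + 1);
      }
    }
  }
  bool ov;
  return S.total_energy(ov);
}

// [[Rcpp::export]]
IntegerMatrix bond_list_cpp(NumericVector x, NumericVector y, NumericVector th,
                            IntegerMatrix st, double L, double sigma,
                            double delta, double theta_pw) {
  Sys S = make_sys(x, y, th, st, make_pot(L, sigma, delta, theta_pw, 1.0, 0.5));
  std::vector<int> bi, bj, bpa, bpb;
  int pa, pb;
  for (int i = 0; i < S.n(); ++i) {
    bool ov;
    std::vector<int> partners;
    S.energy_of(i, ov, &partners);
    if (ov) stop("hard-core overlap involving particle %d", i + 1);
    for (size_t k = 0; k < partners.size(); ++k) {
      int j = partners[k];
      if (j <= i) continue;
      pair_code(S.x[i], S.y[i], S.th[i], &S.st[3 * i],
                S.x[j], S.y[j], S.th[j], &S.st[3 * j], S.P, pa, pb);
      bi.push_back(i + 1); bj.push_back(j + 1);
      bpa.push_back(pa + 1); bpb.push_back(pb + 1);
    }
  }
  IntegerMatrix out(bi.size(), 4);
  for (size_t k = 0; k < bi.size(); ++k) {
    out(k, 0) = bi[k]; out(k, 1) = bj[k];
    out(k, 2) = bpa[k]; out(k, 3) = bpb[k];
  }
  colnames(out) = CharacterVector::create("i", "j", "patch_i", "patch_j");
  return out;
}

// --------------------------------------------------------------------------
// The sampler

static bool breaks_bond(const std::vector<int>& before,
                        const std::vector<int>& after) {
  for (size_t a = 0; a < before.size(); ++a) {
    bool kept = false;
    for (size_t b = 0; b < after.size(); ++b)
      if (after[b] == before[a]) { kept = true; break; }
    if (!kept) return true;
  }
  return false;
}

// [[Rcpp::export]]
List mc_run_cpp(NumericVector x0, NumericVector y0, NumericVector th0,
                IntegerMatrix st0, double L, double sigma, double delta,
                double theta_pw, double eps, double p_open,
                NumericVector fractions, double max_translate,
                double max_rotate, double deposition_rate,
                int n_sweeps, int record_every) {
  Pot P = make_pot(L, sigma, delta, theta_pw, eps, p_open);
  Sys S = make_sys(x0, y0, th0, st0, P);

  bool ov0;
  double E = S.total_energy(ov0);
  if (ov0) stop("initial configuration has a hard-core overlap");

  const double ft = fractions[0];
  const double fr = ft + fractions[1];
  const double ff = fr + fractions[2];

  int n_frames = n_sweeps / record_every;
  List frames(n_frames);
  NumericMatrix obs(n_frames, 9);
  colnames(obs) = CharacterVector::create(
    "step", "energy", "energy_recomputed", "acc_translate", "acc_rotate",
    "acc_flip", "acc_cluster", "bond_break_acc", "n_particles");

  long att[4] = {0, 0, 0, 0}, acc[4] = {0, 0, 0, 0};
  long bb_acc = 0, att_all = 0;
  int frame_idx = 0;
  int dep_skipped = 0;

  std::vector<int> part_before, part_after, cluster, stackv;
  std::vector<double> ux, uy;
  std::vector<char> inclu;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    // deposition (kinetics experiments only; rate 0 in equilibrium runs)
    if (deposition_rate > 0.0) {
      int k = (int)R::rpois(deposition_rate);
      for (int d = 0; d < k; ++d) {
        bool placed = false;
        for (int t = 0; t < 200 && !placed; ++t) {
          double nx = unif_rand() * L, ny = unif_rand() * L;
          double nth = unif_rand() * TWO_PI;
          int ns[3];
          for (int q = 0; q < 3; ++q) ns[q] = (unif_rand() < (1.0 - p_open)) ? 1 : 0;
          bool ovl;
          double de = S.energy_around(nx, ny, nth, ns, -1, ovl, nullptr);
          if (ovl) continue;
          S.add_particle(nx, ny, nth, ns[0], ns[1], ns[2]);
          E += de;
          placed = true;
        }
        if (!placed) ++dep_skipped;
      }
    }

    int N = S.n();
    for (int m = 0; m < N; ++m) {
      double u = unif_rand();
      int type = (u < ft) ? 0 : (u < fr) ? 1 : (u < ff) ? 2 : 3;
      ++att[type];
      ++att_all;
      if (N == 0) continue;
      int i = (int)(unif_rand() * N);
      if (i == N) i = N - 1;

      if (type == 0 || type == 1) {
        // single-particle translation / rotation
        double nx = S.x[i], ny = S.y[i], nth = S.th[i];
        if (type == 0) {
          nx = wrap_pos(nx + (unif_rand() * 2.0 - 1.0) * max_translate, L);
          ny = wrap_pos(ny + (unif_rand() * 2.0 - 1.0) * max_translate, L);
        } else {
          nth = nth + (unif_rand() * 2.0 - 1.0) * max_rotate;
          nth -= TWO_PI * std::floor(nth / TWO_PI);
        }
        bool ov_old, ov_new;
        part_before.clear(); part_after.clear();
        double e_old = S.energy_of(i, ov_old, &part_before);
        double e_new = S.energy_around(nx, ny, nth, &S.st[3 * i], i, ov_new, &part_after);
        if (ov_new) continue;
        double dE = e_new - e_old;
        if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
          S.x[i] = nx; S.y[i] = ny; S.th[i] = nth;
          if (type == 0 && S.nc > 0) S.cell_move(i);
          E += dE;
          ++acc[type];
          if (breaks_bond(part_before, part_after)) ++bb_acc;
        }
      } else if (type == 2) {
        // patch-state flip: Metropolis with intrinsic weights
        // w(open) = p_open, w(closed) = 1 - p_open
        int k = (int)(unif_rand() * 3);
        if (k == 3) k = 2;
        int cur = S.st[3 * i + k];
        double w_new = cur ? p_open : (1.0 - p_open); // weight of target state
        double w_old = cur ? (1.0 - p_open) : p_open;
        if (w_new <= 0.0) continue;
        bool ov_old, ov_new;
        part_before.clear(); part_after.clear();
        double e_old = S.energy_of(i, ov_old, &part_before);
        S.st[3 * i + k] = 1 - cur;
        double e_new = S.energy_of(i, ov_new, &part_after);
        double dE = e_new - e_old;
        double a = (w_old > 0.0 ? w_new / w_old : 1e300) * std::exp(-dE);
        if (a >= 1.0 || unif_rand() < a) {
          E += dE;
          ++acc[type];
          if (breaks_bond(part_before, part_after)) ++bb_acc;
        } else {
          S.st[3 * i + k] = cur; // revert
        }
      } else {
        // rigid cluster move over the bonded component of a random seed;
        // selection down-weighted by 1/size; proposals creating any new
        // cluster-outside bond or overlap are rejected (dE is exactly 0
        // for accepted moves, so acceptance is 1).
        cluster.clear(); stackv.clear();
        if (inclu.size() < (size_t)N) inclu.assign(N, 0); else std::fill(inclu.begin(), inclu.end(), 0);
        ux.clear(); uy.clear();
        stackv.push_back(i);
        inclu[i] = 1;
        std::vector<double> uxm(N), uym(N);
        uxm[i] = S.x[i]; uym[i] = S.y[i];
        bool wraps = false; // a cluster percolating the torus cannot be
                            // unwrapped consistently; such moves are skipped
        while (!stackv.empty()) {
          int v = stackv.back(); stackv.pop_back();
          cluster.push_back(v);
          bool ovv;
          part_after.clear();
          S.energy_of(v, ovv, &part_after);
          for (size_t q = 0; q < part_after.size(); ++q) {
            int w = part_after[q];
            if (!inclu[w]) {
              inclu[w] = 1;
              uxm[w] = uxm[v] + wrap_d(S.x[w] - uxm[v], L);
              uym[w] = uym[v] + wrap_d(S.y[w] - uym[v], L);
              stackv.push_back(w);
            } else {
              double ex = uxm[v] + wrap_d(S.x[w] - uxm[v], L) - uxm[w];
              double ey = uym[v] + wrap_d(S.y[w] - uym[v], L) - uym[w];
              if (std::fabs(ex) > 1e-9 || std::fabs(ey) > 1e-9) wraps = true;
            }
          }
        }
        if (wraps) continue;
        int s = (int)cluster.size();
        if (unif_rand() >= 1.0 / (double)s) continue; // size down-weighting
        bool rotate = unif_rand() < 0.5;
        double dx = 0.0, dy = 0.0, dphi = 0.0, cxm = 0.0, cym = 0.0;
        if (rotate) {
          dphi = (unif_rand() * 2.0 - 1.0) * max_rotate;
          for (int q = 0; q < s; ++q) { cxm += uxm[cluster[q]]; cym += uym[cluster[q]]; }
          cxm /= s; cym /= s;
        } else {
          dx = (unif_rand() * 2.0 - 1.0) * max_translate;
          dy = (unif_rand() * 2.0 - 1.0) * max_translate;
        }
        std::vector<double> nxv(s), nyv(s), nthv(s), nux(s), nuy(s);
        double cphi = std::cos(dphi), sphi = std::sin(dphi);
        for (int q = 0; q < s; ++q) {
          int v = cluster[q];
          double px = uxm[v], py = uym[v];
          if (rotate) {
            double rx = px - cxm, ry = py - cym;
            px = cxm + cphi * rx - sphi * ry;
            py = cym + sphi * rx + cphi * ry;
            nthv[q] = S.th[v] + dphi;
            nthv[q] -= TWO_PI * std::floor(nthv[q] / TWO_PI);
          } else {
            px += dx; py += dy;
            nthv[q] = S.th[v];
          }
          nux[q] = px; nuy[q] = py;
          nxv[q] = wrap_pos(px, L);
          nyv[q] = wrap_pos(py, L);
        }
        // reject on overlap or any new bond with the outside
        bool reject = false;
        int pa, pb;
        // rigid motion preserves unwrapped internal distances but not the
        // torus distance between far-apart members: a cluster spanning
        // more than half the box can fold onto itself through the
        // boundary, so such member pairs are re-checked explicitly
        {
          double rc = S.P.sigma + S.P.delta;
          double span2 = (L / 2 - rc) * (L / 2 - rc);
          double maxr2 = 0.0;
          double mx = 0.0, my = 0.0;
          for (int q = 0; q < s; ++q) { mx += nux[q]; my += nuy[q]; }
          mx /= s; my /= s;
          for (int q = 0; q < s; ++q) {
            double r2 = (nux[q] - mx) * (nux[q] - mx) +
                        (nuy[q] - my) * (nuy[q] - my);
            if (r2 > maxr2) maxr2 = r2;
          }
          if (4.0 * maxr2 > span2) {
            for (int q = 0; q < s && !reject; ++q) {
              for (int r2i = q + 1; r2i < s; ++r2i) {
                double du2 = (nux[q] - nux[r2i]) * (nux[q] - nux[r2i]) +
                             (nuy[q] - nuy[r2i]) * (nuy[q] - nuy[r2i]);
                if (du2 <= span2) continue;
                int code = pair_code(nxv[q], nyv[q], nthv[q],
                                     &S.st[3 * cluster[q]],
                                     nxv[r2i], nyv[r2i], nthv[r2i],
                                     &S.st[3 * cluster[r2i]], S.P, pa, pb);
                if (code != 0) { reject = true; break; }
              }
            }
          }
        }
        if (reject) continue;
        for (int q = 0; q < s && !reject; ++q) {
          int v = cluster[q];
          // scan potential partners of the moved particle
          if (S.nc == 0) {
            for (int j = 0; j < S.n() && !reject; ++j) {
              if (inclu[j]) continue;
              int code = pair_code(nxv[q], nyv[q], nthv[q], &S.st[3 * v],
                                   S.x[j], S.y[j], S.th[j], &S.st[3 * j], S.P, pa, pb);
              if (code != 0) reject = true;
            }
          } else {
            int cx = (int)(nxv[q] / S.cw), cy = (int)(nyv[q] / S.cw);
            if (cx >= S.nc) cx = S.nc - 1;
            if (cy >= S.nc) cy = S.nc - 1;
            for (int oy = -1; oy <= 1 && !reject; ++oy) {
              int gy = (cy + oy + S.nc) % S.nc;
              for (int ox = -1; ox <= 1 && !reject; ++ox) {
                int gx = (cx + ox + S.nc) % S.nc;
                for (int j = S.head[gy * S.nc + gx]; j >= 0; j = S.nxt[j]) {
                  if (inclu[j]) continue;
                  int code = pair_code(nxv[q], nyv[q], nthv[q], &S.st[3 * v],
                                       S.x[j], S.y[j], S.th[j], &S.st[3 * j], S.P, pa, pb);
                  if (code != 0) { reject = true; break; }
                }
              }
            }
          }
        }
        if (reject) continue;
        for (int q = 0; q < s; ++q) {
          int v = cluster[q];
          S.x[v] = nxv[q]; S.y[v] = nyv[q]; S.th[v] = nthv[q];
          if (S.nc > 0) S.cell_move(v);
        }
        ++acc[type];
      }
    }

    if (sweep % record_every == 0 && frame_idx < n_frames) {
      int N2 = S.n();
      NumericVector fx(N2), fy(N2), fth(N2);
      IntegerMatrix fst(N2, 3);
      for (int i2 = 0; i2 < N2; ++i2) {
        fx[i2] = S.x[i2]; fy[i2] = S.y[i2]; fth[i2] = S.th[i2];
        for (int k2 = 0; k2 < 3; ++k2) fst(i2, k2) = S.st[3 * i2 + k2];
      }
      frames[frame_idx] = List::create(
        _["step"] = sweep, _["x"] = fx, _["y"] = fy,
        _["orientation"] = fth, _["patch_states"] = fst);
      bool ovr;
      double E_full = S.total_energy(ovr);
      obs(frame_idx, 0) = sweep;
      obs(frame_idx, 1) = E;
      obs(frame_idx, 2) = E_full;
      for (int t = 0; t < 4; ++t)
        obs(frame_idx, 3 + t) = att[t] > 0 ? (double)acc[t] / (double)att[t] : NA_REAL;
      obs(frame_idx, 7) = att_all > 0 ? (double)bb_acc / (double)att_all : NA_REAL;
      obs(frame_idx, 8) = N2;
      for (int t = 0; t < 4; ++t) { att[t] = 0; acc[t] = 0; }
      bb_acc = 0; att_all = 0;
      ++frame_idx;
    }
    if (sweep % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["frames"] = frames, _["observables"] = obs,
                      _["final_energy"] = E,
                      _["deposition_skipped"] = dep_skipped);
}
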