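// Bond-fluctuation-method kernel: two (or one) self-avoiding ring polymers
// on a cubic lattice in a hard-walled box, single-monomer unit moves,
// transient membrane tethering fields, optional inter-polymer force coupling.
//
// Conventions (shared with the R layer):
//  - a monomer at integer position (x,y,z) occupies the 8 corner sites of
//    the unit cube [x,x+1]x[y,y+1]x[z,z+1]; positions range 0..L-1 per axis;
//  - one Monte-Carlo step (MCS) = M attempted moves, M = total monomers;
//  - the tether field is updated once after every MCS;
//  - all randomness comes from R's RNG (controlled by set.seed()).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const int DX[6] = {1, -1, 0, 0, 0, 0};
const int DY[6] = {0, 0, 1, -1, 0, 0};
const int DZ[6] = {0, 0, 0, 0, 1, -1};

enum FieldMode { MODE_NONE = 0, MODE_UNIFORM = 1, MODE_STATIC = 2,
                 MODE_OSC = 3, MODE_MIND = 4 };

// xoshiro256++ stream, seeded from R's RNG so that set.seed() controls the
// whole trajectory while the hot loop avoids per-draw R API calls.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(double u1, double u2) {
    // splitmix64 expansion of two 32-bit words drawn from R's RNG
    uint64_t seed = ((uint64_t)(u1 * 4294967296.0) << 32) ^
                    (uint64_t)(u2 * 4294967296.0);
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double uniform() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

// Allowed BFM bond set == all integer vectors with squared length in
// {4,5,6,9,10}; components never exceed 3 in magnitude.
inline bool bond_allowed_raw(int dx, int dy, int dz) {
  int q = dx * dx + dy * dy + dz * dz;
  return q == 4 || q == 5 || q == 6 || q == 9 || q == 10;
}

struct BondTable {
  bool ok[343];
  BondTable() {
    for (int dx = -3; dx <= 3; ++dx)
      for (int dy = -3; dy <= 3; ++dy)
        for (int dz = -3; dz <= 3; ++dz)
          ok[(dx + 3) * 49 + (dy + 3) * 7 + (dz + 3)] =
              bond_allowed_raw(dx, dy, dz);
  }
  inline bool operator()(int dx, int dy, int dz) const {
    if (dx < -3 || dx > 3 || dy < -3 || dy > 3 || dz < -3 || dz > 3)
      return false;
    return ok[(dx + 3) * 49 + (dy + 3) * 7 + (dz + 3)];
  }
};

// Evaluation of the tethering field p(x, t); x is the monomer position
// (lower corner), the field is evaluated at the cube centre x + 0.5.
struct FieldEval {
  int mode = MODE_NONE;
  double p_max = 0.0, steepness = 1.0, period = 1.0;
  int Lx = 0;
  std::vector<double> pstat;    // static/uniform profile per position
  // mind_profile mode
  std::vector<double> bins, times;
  std::vector<std::vector<double> > frames;  // per-frame intensities
  double mcs_per_second = 1.0, duration = 0.0, t0 = 0.0;
  int cached_frame = -1;
  std::vector<double> pmind;

  void init(const List& field, int Lx_) {
    Lx = Lx_;
    mode = as<int>(field["mode"]);
    p_max = as<double>(field["p_max"]);
    steepness = as<double>(field["steepness"]);
    period = as<double>(field["period"]);
    if (mode == MODE_STATIC || mode == MODE_OSC || mode == MODE_UNIFORM) {
      pstat.resize(Lx);
      for (int x = 0; x < Lx; ++x) {
        if (mode == MODE_UNIFORM) {
          pstat[x] = p_max;
        } else {
          double c = (x + 0.5) / Lx;
          pstat[x] = p_max * std::pow(2.0 * std::fabs(c - 0.5), steepness);
        }
      }
    }
    if (mode == MODE_MIND) {
      NumericMatrix prof = as<NumericMatrix>(field["prof_intensity"]);
      NumericVector b = as<NumericVector>(field["prof_bins"]);
      NumericVector tt = as<NumericVector>(field["prof_times"]);
      mcs_per_second = as<double>(field["mcs_per_second"]);
      int nf = prof.nrow(), nb = prof.ncol();
      bins.assign(b.begin(), b.end());
      times.assign(tt.begin(), tt.end());
      frames.resize(nf);
      for (int i = 0; i < nf; ++i) {
        frames[i].resize(nb);
        double mx = 0.0;
        for (int j = 0; j < nb; ++j) mx = std::max(mx, prof(i, j));
        if (mx <= 0.0) mx = 1.0;   // all-zero frame -> zero field
        for (int j = 0; j < nb; ++j) frames[i][j] = prof(i, j) / mx;
      }
      t0 = times[0];
      double dt = nf > 1 ? (times[nf - 1] - times[0]) / (nf - 1) : 1.0;
      duration = (times[nf - 1] - times[0]) + dt;
      pmind.assign(Lx, 0.0);
      cached_frame = -1;
    }
  }

  int frame_at(double clock) {
    double ts = clock / mcs_per_second;
    double v = ts - t0;
    double tau = v - std::floor(v / duration) * duration;
    // nearest frame under cyclic wrap
    int best = 0;
    double bestd = R_PosInf;
    int nf = (int)times.size();
    for (int i = 0; i < nf; ++i) {
      double d = std::fabs(times[i] - t0 - tau);
      d = std::min(d, duration - d);
      if (d < bestd) { bestd = d; best = i; }
    }
    return best;
  }

  void refresh_mind(double clock) {
    int f = frame_at(clock);
    if (f == cached_frame) return;
    cached_frame = f;
    const std::vector<double>& I = frames[f];
    int nb = (int)bins.size();
    for (int x = 0; x < Lx; ++x) {
      double u = (x + 0.5) / Lx;   // relative axial coordinate
      double v;
      if (u <= bins[0]) v = I[0];
      else if (u >= bins[nb - 1]) v = I[nb - 1];
      else {
        int j = 0;
        while (j + 1 < nb && bins[j + 1] < u) ++j;
        double w = (u - bins[j]) / (bins[j + 1] - bins[j]);
        v = (1.0 - w) * I[j] + w * I[j + 1];
      }
      pmind[x] = p_max * v;
    }
  }

  // probability for a monomer at position x at MCS clock (call
  // refresh_mind(clock) once per MCS beforehand in mind mode)
  inline double prob(int x, double clock) const {
    switch (mode) {
    case MODE_NONE: return 0.0;
    case MODE_UNIFORM: return pstat[x];
    case MODE_STATIC: return pstat[x];
    case MODE_OSC: {
      long long half = (long long)std::floor(clock / period);
      bool left_active = (half % 2) == 0;
      double c = x + 0.5;
      if (left_active ? (c < Lx / 2.0) : (c > Lx / 2.0)) return pstat[x];
      return 0.0;
    }
    case MODE_MIND: return pmind[x];
    }
    return 0.0;
  }
};

inline double geometric_dwell(double dwell_mean, Xoshiro& rng) {
  if (!R_FINITE(dwell_mean)) return R_PosInf;
  if (dwell_mean <= 1.0) return 1.0;
  double u = rng.uniform();
  return 1.0 + std::floor(std::log(u) / std::log1p(-1.0 / dwell_mean));
}

}  // namespace

// Evaluate the binding-probability field on a grid (cross-check interface;
// shares the evaluation path used inside the simulation loop).
// [[Rcpp::export(name = ".field_probability_cpp")]]
NumericMatrix field_probability_cpp(List field, IntegerVector box,
                                    IntegerVector x, NumericVector mcs) {
  FieldEval fe;
  fe.init(field, box[0]);
  NumericMatrix out(x.size(), mcs.size());
  for (int j = 0; j < mcs.size(); ++j) {
    if (fe.mode == MODE_MIND) fe.refresh_mind(mcs[j]);
    for (int i = 0; i < x.size(); ++i) out(i, j) = fe.prob(x[i], mcs[j]);
  }
  return out;
}

// Main simulation loop.  pos0 is an M x 3 integer matrix of monomer
// positions, polymers stored contiguously (monomer m belongs to polymer
// m / N, ring index m % N).  Returns the updated state plus requested logs.
// [[Rcpp::export(name = ".bfm_run_cpp")]]
List bfm_run_cpp(IntegerMatrix pos0, int n_polymers, int N,
                 IntegerVector box, LogicalVector bound0,
                 NumericVector release0, double mcs0, double n_mcs,
                 List field, double dwell_mean, double border_distance,
                 bool interchain, double force, double cm_window,
                 double record_every, double record_positions_every,
                 bool log_bindings, int max_bind_log, bool log_moves) {
  const int M = n_polymers * N;
  if (pos0.nrow() != M) stop("positions do not match n_polymers * N");
  const int Lx = box[0], Ly = box[1], Lz = box[2];
  const int sy = Ly + 1, sz = Lz + 1;
  const long long S = (long long)(Lx + 1) * sy * sz;

  std::vector<int> px(M), py(M), pz(M);
  std::vector<char> bound(M);
  std::vector<double> release(M);
  std::vector<double> sumx(n_polymers, 0.0);
  int n_bound = 0;
  for (int m = 0; m < M; ++m) {
    px[m] = pos0(m, 0); py[m] = pos0(m, 1); pz[m] = pos0(m, 2);
    if (px[m] < 0 || px[m] > Lx - 1 || py[m] < 0 || py[m] > Ly - 1 ||
        pz[m] < 0 || pz[m] > Lz - 1)
      stop("monomer %d outside the confinement box", m + 1);
    bound[m] = bound0[m];
    if (bound[m]) ++n_bound;
    release[m] = release0[m];
    sumx[m / N] += px[m];
  }

  static BondTable bond;
  // ring bond validity of the input state
  for (int m = 0; m < M; ++m) {
    int p = m / N, l = m % N;
    int nx = p * N + (l + 1) % N;
    if (!bond(px[nx] - px[m], py[nx] - py[m], pz[nx] - pz[m]))
      stop("invalid bond between monomers %d and %d in input state",
           m + 1, nx + 1);
  }

  // occupancy bitmap: bit k set if polymer k occupies the site
  std::vector<uint8_t> occ(S, 0);
  for (int m = 0; m < M; ++m) {
    uint8_t bit = (uint8_t)(1 << (m / N));
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j)
        for (int k = 0; k < 2; ++k) {
          long long idx =
              ((long long)(px[m] + i) * sy + (py[m] + j)) * sz + (pz[m] + k);
          if (occ[idx] & bit)
            stop("self-overlap within polymer %d in input state", m / N + 1);
          if (interchain && (occ[idx] & ~bit))
            stop("inter-polymer overlap in input state");
          occ[idx] |= bit;
        }
  }

  FieldEval fe;
  fe.init(field, Lx);

  // recording buffers
  const bool rec_cm = record_every > 0;
  const bool rec_pos = record_positions_every > 0;
  std::vector<double> cm_buf, cm_mcs;
  std::vector<int> pos_buf;
  std::vector<double> pos_mcs;
  std::vector<double> bind_log;          // rows: mcs, monomer, x, dwell
  std::vector<double> bind_events(log_bindings ? Lx : 0, 0.0);
  std::vector<double> bind_expected(log_bindings ? Lx : 0, 0.0);
  std::vector<int> move_log;             // rows: monomer, dir, accepted

  auto record_cm = [&](double clock) {
    cm_mcs.push_back(clock);
    for (int p = 0; p < n_polymers; ++p)
      cm_buf.push_back((sumx[p] / N + 0.5 - Lx / 2.0) / Lx);
  };
  auto record_pos = [&](double clock) {
    pos_mcs.push_back(clock);
    for (int m = 0; m < M; ++m) {
      pos_buf.push_back(px[m]); pos_buf.push_back(py[m]);
      pos_buf.push_back(pz[m]);
    }
  };
  if (rec_cm) record_cm(mcs0);
  if (rec_pos) record_pos(mcs0);

  const double half_x = Lx / 2.0;
  Xoshiro rng(unif_rand(), unif_rand());
  long long accepted = 0, attempted = 0;
  const long long n_steps = (long long)n_mcs;

  for (long long t = 1; t <= n_steps; ++t) {
    for (int a = 0; a < M; ++a) {
      double u = rng.uniform() * (6.0 * M);
      int m = (int)(u / 6.0); if (m >= M) m = M - 1;
      int d = (int)(u - 6.0 * m); if (d >= 6) d = 5; if (d < 0) d = 0;
      ++attempted;
      bool acc = false;
      do {
        if (bound[m]) break;
        int nx = px[m] + DX[d], ny = py[m] + DY[d], nz = pz[m] + DZ[d];
        if (nx < 0 || nx > Lx - 1 || ny < 0 || ny > Ly - 1 ||
            nz < 0 || nz > Lz - 1) break;
        int p = m / N, l = m % N;
        int mp = p * N + (l + N - 1) % N, mn = p * N + (l + 1) % N;
        if (!bond(px[mp] - nx, py[mp] - ny, pz[mp] - nz)) break;
        if (!bond(px[mn] - nx, py[mn] - ny, pz[mn] - nz)) break;
        // the 4 sites of the advancing face must be free
        uint8_t bit = (uint8_t)(1 << p);
        uint8_t mask = interchain ? 0xFF : bit;
        int fx = nx + (DX[d] > 0 ? 1 : 0);
        int fy = ny + (DY[d] > 0 ? 1 : 0);
        int fz = nz + (DZ[d] > 0 ? 1 : 0);
        bool blocked = false;
        if (DX[d] != 0) {
          for (int j = 0; j < 2 && !blocked; ++j)
            for (int k = 0; k < 2; ++k)
              if (occ[((long long)fx * sy + (ny + j)) * sz + (nz + k)] & mask)
                { blocked = true; break; }
        } else if (DY[d] != 0) {
          for (int i = 0; i < 2 && !blocked; ++i)
            for (int k = 0; k < 2; ++k)
              if (occ[((long long)(nx + i) * sy + fy) * sz + (nz + k)] & mask)
                { blocked = true; break; }
        } else {
          for (int i = 0; i < 2 && !blocked; ++i)
            for (int j = 0; j < 2; ++j)
              if (occ[((long long)(nx + i) * sy + (ny + j)) * sz + fz] & mask)
                { blocked = true; break; }
        }
        if (blocked) break;
        if (DX[d] != 0) {
          double new_sum = sumx[p] + DX[d];
          if (cm_window > 0 &&
              std::fabs(new_sum / N + 0.5 - half_x) > cm_window) break;
          if (force > 0 && n_polymers == 2) {
            double d_old = std::fabs(sumx[0] - sumx[1]) / N;
            double d_new = std::fabs((p == 0 ? new_sum : sumx[0]) -
                                     (p == 1 ? new_sum : sumx[1])) / N;
            double dU = force * (d_new - d_old);
            if (dU > 0 && rng.uniform() >= std::exp(-dU)) break;
          }
        }
        // accept: clear trailing face, set advancing face
        int ox = px[m] + (DX[d] > 0 ? 0 : 1);
        int oy = py[m] + (DY[d] > 0 ? 0 : 1);
        int oz = pz[m] + (DZ[d] > 0 ? 0 : 1);
        if (DX[d] != 0) {
          for (int j = 0; j < 2; ++j)
            for (int k = 0; k < 2; ++k) {
              occ[((long long)ox * sy + (py[m] + j)) * sz + (pz[m] + k)] &= ~bit;
              occ[((long long)fx * sy + (ny + j)) * sz + (nz + k)] |= bit;
            }
          sumx[p] += DX[d];
        } else if (DY[d] != 0) {
          for (int i = 0; i < 2; ++i)
            for (int k = 0; k < 2; ++k) {
              occ[((long long)(px[m] + i) * sy + oy) * sz + (pz[m] + k)] &= ~bit;
              occ[((long long)(nx + i) * sy + fy) * sz + (nz + k)] |= bit;
            }
        } else {
          for (int i = 0; i < 2; ++i)
            for (int j = 0; j < 2; ++j) {
              occ[((long long)(px[m] + i) * sy + (py[m] + j)) * sz + oz] &= ~bit;
              occ[((long long)(nx + i) * sy + (ny + j)) * sz + fz] |= bit;
            }
        }
        px[m] = nx; py[m] = ny; pz[m] = nz;
        acc = true; ++accepted;
      } while (false);
      if (log_moves) {
        move_log.push_back(m + 1); move_log.push_back(d + 1);
        move_log.push_back(acc ? 1 : 0);
      }
    }

    double clock = mcs0 + t;

    // tether update: releases first, then stochastic binding
    if (n_bound > 0)
      for (int m = 0; m < M; ++m)
        if (bound[m] && release[m] <= clock) { bound[m] = 0; --n_bound; }
    if (fe.mode != MODE_NONE) {
      if (fe.mode == MODE_MIND) fe.refresh_mind(clock);
      for (int m = 0; m < M; ++m) {
        if (bound[m]) continue;
        int dy = std::min(py[m], Ly - 1 - py[m]);
        int dz = std::min(pz[m], Lz - 1 - pz[m]);
        if (dy >= border_distance && dz >= border_distance) continue;
        double p = fe.prob(px[m], clock);
        if (log_bindings) bind_expected[px[m]] += p;
        if (p <= 0) continue;
        if (rng.uniform() < p) {
          bound[m] = 1; ++n_bound;
          double k = geometric_dwell(dwell_mean, rng);
          release[m] = clock + k;
          if (log_bindings) {
            bind_events[px[m]] += 1.0;
            if ((int)(bind_log.size() / 4) < max_bind_log) {
              bind_log.push_back(clock);
              bind_log.push_back(m + 1);
              bind_log.push_back(px[m]);
              bind_log.push_back(k);
            }
          }
        }
      }
    }

    if (rec_cm && t % (long long)record_every == 0) record_cm(clock);
    if (rec_pos && t % (long long)record_positions_every == 0)
      record_pos(clock);
    if ((t & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix pos_out(M, 3);
  LogicalVector bound_out(M);
  NumericVector release_out(M);
  for (int m = 0; m < M; ++m) {
    pos_out(m, 0) = px[m]; pos_out(m, 1) = py[m]; pos_out(m, 2) = pz[m];
    bound_out[m] = bound[m] != 0;
    release_out[m] = release[m];
  }

  List out = List::create(
      _["pos"] = pos_out, _["bound"] = bound_out, _["release"] = release_out,
      _["mcs"] = mcs0 + n_mcs, _["accepted"] = (double)accepted,
      _["attempted"] = (double)attempted);
  if (rec_cm) {
    int nr = (int)cm_mcs.size();
    NumericMatrix cm(nr, n_polymers);
    for (int i = 0; i < nr; ++i)
      for (int p = 0; p < n_polymers; ++p)
        cm(i, p) = cm_buf[(size_t)i * n_polymers + p];
    out["cm_mcs"] = NumericVector(cm_mcs.begin(), cm_mcs.end());
    out["cm_rel"] = cm;
  }
  if (rec_pos) {
    int ns = (int)pos_mcs.size();
    IntegerVector ps(pos_buf.begin(), pos_buf.end());
    ps.attr("dim") = IntegerVector::create(3, M, ns);
    out["pos_mcs"] = NumericVector(pos_mcs.begin(), pos_mcs.end());
    out["pos_samples"] = ps;
  }
  if (log_bindings) {
    int nr = (int)(bind_log.size() / 4);
    NumericMatrix bl(nr, 4);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < 4; ++j) bl(i, j) = bind_log[(size_t)i * 4 + j];
    colnames(bl) = CharacterVector::create("mcs", "monomer", "x", "dwell");
    out["bind_log"] = bl;
    out["bind_events"] = NumericVector(bind_events.begin(), bind_events.end());
    out["bind_expected"] =
        NumericVector(bind_expected.begin(), bind_expected.end());
  }
  if (log_moves) {
    int nr = (int)(move_log.size() / 3);
    IntegerMatrix ml(nr, 3);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < 3; ++j) ml(i, j) = move_log[(size_t)i * 3 + j];
    colnames(ml) = CharacterVector::create("monomer", "direction", "accepted");
    out["move_log"] = ml;
  }
  return out;
}
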