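// Simulation cores for epsilon-greedy Expected SARSA self-play in the
// memory-one iterated Prisoner's Dilemma, and the deterministic
// strategy-average dynamics iterated to convergence.
//
// Conventions (shared with the R level):
//   states  0..3 = cc, cd, dc, dd;  next state index = 2*a1 + a2
//   actions 0 = c, 1 = d; greedy ties fall to defection (strict '>' for c)
//   strategy code: defect bits over (cc, cd, dc, dd), cc most significant
#include <Rcpp.h>
#include <random>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// uniform in [0,1) from the raw engine stream; engine output is specified by
// the C++ standard, so trajectories are reproducible across platforms
static inline double runif01(std::mt19937_64 &eng) {
  return (eng() >> 11) * (1.0 / 9007199254740992.0); // 2^-53
}

static inline std::mt19937_64 traj_engine(int seed, int traj) {
  std::uint64_t s = static_cast<std::uint64_t>(static_cast<std::int64_t>(seed));
  s ^= 0x9E3779B97F4A7C15ULL * static_cast<std::uint64_t>(traj + 1);
  return std::mt19937_64(s);
}

static inline int greedy(const double q[4][2], int s) {
  return q[s][0] > q[s][1] ? 0 : 1;
}

static inline int strategy_code(const double q[4][2]) {
  int code = 0;
  for (int s = 0; s < 4; ++s) code |= greedy(q, s) << (3 - s);
  return code;
}

static inline int pair_code_of(const double q1[4][2], const double q2[4][2]) {
  return 16 * strategy_code(q1) + strategy_code(q2);
}

// epsilon-greedy draw given the greedy action
static inline int draw_action(std::mt19937_64 &eng, int agreedy, double eps) {
  double u = runif01(eng);
  if (u < eps) return runif01(eng) < 0.5 ? 0 : 1;
  return agreedy;
}

static void init_tables(std::mt19937_64 &eng, double lo, double hi,
                        const Nullable<NumericMatrix> &q1_init,
                        const Nullable<NumericMatrix> &q2_init,
                        double q1[4][2], double q2[4][2]) {
  if (q1_init.isNotNull() && q2_init.isNotNull()) {
    NumericMatrix m1(q1_init), m2(q2_init);
    for (int s = 0; s < 4; ++s)
      for (int a = 0; a < 2; ++a) { q1[s][a] = m1(s, a); q2[s][a] = m2(s, a); }
  } else {
    for (int s = 0; s < 4; ++s)
      for (int a = 0; a < 2; ++a) q1[s][a] = lo + runif01(eng) * (hi - lo);
    for (int s = 0; s < 4; ++s)
      for (int a = 0; a < 2; ++a) q2[s][a] = lo + runif01(eng) * (hi - lo);
  }
}

// recorded step indices: 0, every, 2*every, ..., and the final step
static std::vector<int> record_points(int horizon, int every) {
  std::vector<int> pts;
  pts.push_back(0);
  for (int t = every; t <= horizon; t += every) pts.push_back(t);
  if (pts.back() != horizon) pts.push_back(horizon);
  return pts;
}

// [[Rcpp::export]]
List cpp_run_online(double Tp, double Sp, double alpha, double eps,
                    double delta, int horizon, int record_every,
                    int coop_window, int n_samples, int seed,
                    double lo, double hi,
                    Nullable<NumericMatrix> q1_init,
                    Nullable<NumericMatrix> q2_init, int state0) {
  const double r1[4] = {1.0, Sp, Tp, 0.0};
  const double r2[4] = {1.0, Tp, Sp, 0.0};
  std::vector<int> pts = record_points(horizon, record_every);
  const int n_rec = static_cast<int>(pts.size());
  IntegerMatrix codes(n_rec, n_samples);
  NumericMatrix coop(n_rec, n_samples);
  NumericMatrix fq1(n_samples, 8), fq2(n_samples, 8); // final tables, s*2+a

  for (int i = 0; i < n_samples; ++i) {
    std::mt19937_64 eng = traj_engine(seed, i);
    double q1[4][2], q2[4][2];
    init_tables(eng, lo, hi, q1_init, q2_init, q1, q2);
    int s = state0 >= 0 ? state0 : static_cast<int>(runif01(eng) * 4.0);
    std::vector<unsigned char> buf(coop_window, 0);
    int ccount = 0, bpos = 0, rec = 0;
    codes(rec, i) = pair_code_of(q1, q2);
    coop(rec, i) = NA_REAL;
    ++rec;
    for (int t = 1; t <= horizon; ++t) {
      int a1 = draw_action(eng, greedy(q1, s), eps);
      int a2 = draw_action(eng, greedy(q2, s), eps);
      int sn = 2 * a1 + a2;
      // expected next-state value under each agent's own current frequencies
      int g1 = greedy(q1, sn), g2 = greedy(q2, sn);
      double v1 = (1 - eps / 2) * q1[sn][g1] + (eps / 2) * q1[sn][1 - g1];
      double v2 = (1 - eps / 2) * q2[sn][g2] + (eps / 2) * q2[sn][1 - g2];
      q1[s][a1] = (1 - alpha) * q1[s][a1] + alpha * (r1[sn] + delta * v1);
      q2[s][a2] = (1 - alpha) * q2[s][a2] + alpha * (r2[sn] + delta * v2);
      // trailing-window mutual-cooperation count
      ccount += (sn == 0) - buf[bpos];
      buf[bpos] = (sn == 0);
      bpos = (bpos + 1) % coop_window;
      s = sn;
      if (rec < n_rec && t == pts[rec]) {
        codes(rec, i) = pair_code_of(q1, q2);
        coop(rec, i) = static_cast<double>(ccount) /
                       std::min(t, coop_window);
        ++rec;
      }
    }
    for (int st = 0; st < 4; ++st)
      for (int a = 0; a < 2; ++a) {
        fq1(i, st * 2 + a) = q1[st][a];
        fq2(i, st * 2 + a) = q2[st][a];
      }
  }
  return List::create(_["times"] = NumericVector(pts.begin(), pts.end()),
                      _["codes"] = codes, _["coop"] = coop,
                      _["fq1"] = fq1, _["fq2"] = fq2);
}

// [[Rcpp::export]]
List cpp_run_batch(double Tp, double Sp, double alpha, double eps,
                   double delta, int K, int n_batches,
                   int record_every_batches, int n_samples, int seed,
                   double lo, double hi,
                   Nullable<NumericMatrix> q1_init,
                   Nullable<NumericMatrix> q2_init, int state0) {
  const double r1[4] = {1.0, Sp, Tp, 0.0};
  const double r2[4] = {1.0, Tp, Sp, 0.0};
  std::vector<int> pts = record_points(n_batches, record_every_batches);
  const int n_rec = static_cast<int>(pts.size());
  IntegerMatrix codes(n_rec, n_samples);
  NumericMatrix coop(n_rec, n_samples);
  NumericMatrix fq1(n_samples, 8), fq2(n_samples, 8); // final tables, s*2+a
  NumericVector times(n_rec);
  for (int r = 0; r < n_rec; ++r)
    times[r] = static_cast<double>(pts[r]) * K;

  for (int i = 0; i < n_samples; ++i) {
    std::mt19937_64 eng = traj_engine(seed, i);
    double q1[4][2], q2[4][2];
    init_tables(eng, lo, hi, q1_init, q2_init, q1, q2);
    int s = state0 >= 0 ? state0 : static_cast<int>(runif01(eng) * 4.0);
    int rec = 0;
    codes(rec, i) = pair_code_of(q1, q2);
    coop(rec, i) = NA_REAL;
    ++rec;
    for (int b = 1; b <= n_batches; ++b) {
      // interaction phase: strategies frozen at the acting values; the
      // valuation tables are iteratively refined, each sampled target
      // bootstrapping from the current q_val so that the within-batch
      // recursion performs value iteration for the frozen strategy
      int g1s[4], g2s[4];
      for (int st = 0; st < 4; ++st) {
        g1s[st] = greedy(q1, st);
        g2s[st] = greedy(q2, st);
      }
      double qv1[4][2], qv2[4][2];   // q_val, warm-started at q_act
      int t1c[4][2] = {}, t2c[4][2] = {};  // local update counters
      for (int st = 0; st < 4; ++st)
        for (int a = 0; a < 2; ++a) { qv1[st][a] = q1[st][a]; qv2[st][a] = q2[st][a]; }
      int cc = 0;
      for (int t = 0; t < K; ++t) {
        int a1 = draw_action(eng, g1s[s], eps);
        int a2 = draw_action(eng, g2s[s], eps);
        int sn = 2 * a1 + a2;
        // expected next-state value under the frozen acting strategy,
        // estimated from the current valuation table
        double v1 = (1 - eps / 2) * qv1[sn][g1s[sn]] + (eps / 2) * qv1[sn][1 - g1s[sn]];
        double v2 = (1 - eps / 2) * qv2[sn][g2s[sn]] + (eps / 2) * qv2[sn][1 - g2s[sn]];
        // local rate 1/(t+1): q_val ends the batch as the running mean of
        // the sampled targets for each (s, a)
        double rate1 = 1.0 / (t1c[s][a1] + 1);
        double rate2 = 1.0 / (t2c[s][a2] + 1);
        qv1[s][a1] += rate1 * (r1[sn] + delta * v1 - qv1[s][a1]);
        qv2[s][a2] += rate2 * (r2[sn] + delta * v2 - qv2[s][a2]);
        ++t1c[s][a1];
        ++t2c[s][a2];
        s = sn;
        cc += (s == 0);
      }
      // adaptation phase: visited entries move toward the batch estimate
      // with the global learning rate (unvisited entries are no-ops since
      // q_val was warm-started at q_act)
      for (int st = 0; st < 4; ++st)
        for (int a = 0; a < 2; ++a) {
          if (t1c[st][a] > 0) q1[st][a] += alpha * (qv1[st][a] - q1[st][a]);
          if (t2c[st][a] > 0) q2[st][a] += alpha * (qv2[st][a] - q2[st][a]);
        }
      if (rec < n_rec && b == pts[rec]) {
        codes(rec, i) = pair_code_of(q1, q2);
        coop(rec, i) = static_cast<double>(cc) / K;
        ++rec;
      }
    }
    for (int st = 0; st < 4; ++st)
      for (int a = 0; a < 2; ++a) {
        fq1(i, st * 2 + a) = q1[st][a];
        fq2(i, st * 2 + a) = q2[st][a];
      }
  }
  return List::create(_["times"] = times, _["codes"] = codes,
                      _["coop"] = coop, _["fq1"] = fq1, _["fq2"] = fq2);
}

// solve the 4x4 system A x = b (Gaussian elimination, partial pivoting);
// A and b are overwritten, the solution lands in x
static void solve4(double A[4][4], const double b1[4], const double b2[4],
                   double x1[4], double x2[4]) {
  double M[4][6];
  for (int r = 0; r < 4; ++r) {
    for (int c = 0; c < 4; ++c) M[r][c] = A[r][c];
    M[r][4] = b1[r];
    M[r][5] = b2[r];
  }
  for (int col = 0; col < 4; ++col) {
    int piv = col;
    for (int r = col + 1; r < 4; ++r)
      if (std::abs(M[r][col]) > std::abs(M[piv][col])) piv = r;
    if (piv != col)
      for (int c = col; c < 6; ++c) std::swap(M[col][c], M[piv][c]);
    double d = M[col][col];
    for (int r = col + 1; r < 4; ++r) {
      double f = M[r][col] / d;
      if (f != 0.0)
        for (int c = col; c < 6; ++c) M[r][c] -= f * M[col][c];
    }
  }
  for (int k = 0; k < 2; ++k) {
    double *x = (k == 0) ? x1 : x2;
    int rhs = 4 + k;
    for (int r = 3; r >= 0; --r) {
      double acc = M[r][rhs];
      for (int c = r + 1; c < 4; ++c) acc -= M[r][c] * x[c];
      x[r] = acc / M[r][r];
    }
  }
}

// one step of the deterministic strategy-average dynamics, in place;
// returns the max absolute change
static double det_step(double q1[4][2], double q2[4][2], const double r1[4],
                       const double r2[4], double alpha, double eps,
                       double delta) {
  double x1[4][2], x2[4][2];
  for (int s = 0; s < 4; ++s) {
    int g1 = greedy(q1, s), g2 = greedy(q2, s);
    x1[s][g1] = 1 - eps / 2; x1[s][1 - g1] = eps / 2;
    x2[s][g2] = 1 - eps / 2; x2[s][1 - g2] = eps / 2;
  }
  // joint state-transition matrix and per-state average rewards
  double A[4][4], rs1[4], rs2[4];
  for (int s = 0; s < 4; ++s) {
    double P[4] = {0, 0, 0, 0};
    rs1[s] = rs2[s] = 0;
    for (int a1 = 0; a1 < 2; ++a1)
      for (int a2 = 0; a2 < 2; ++a2) {
        double w = x1[s][a1] * x2[s][a2];
        int sn = 2 * a1 + a2;
        P[sn] += w;
        rs1[s] += w * r1[sn];
        rs2[s] += w * r2[sn];
      }
    for (int sn = 0; sn < 4; ++sn)
      A[s][sn] = (s == sn ? 1.0 : 0.0) - delta * P[sn];
  }
  double v1[4], v2[4];
  solve4(A, rs1, rs2, v1, v2);
  // strategy-average qualities and next-state expectations per agent
  double t1[4][2], t2[4][2];       // update targets rbar + delta * nextq
  double qb1[4][2], qb2[4][2];     // qbar
  for (int s = 0; s < 4; ++s) {
    for (int a1 = 0; a1 < 2; ++a1) {
      double rb = 0, pv = 0;
      for (int a2 = 0; a2 < 2; ++a2) {
        int sn = 2 * a1 + a2;
        rb += x2[s][a2] * r1[sn];
        pv += x2[s][a2] * v1[sn];
      }
      qb1[s][a1] = rb + delta * pv;
    }
    for (int a2 = 0; a2 < 2; ++a2) {
      double rb = 0, pv = 0;
      for (int a1 = 0; a1 < 2; ++a1) {
        int sn = 2 * a1 + a2;
        rb += x1[s][a1] * r2[sn];
        pv += x1[s][a1] * v2[sn];
      }
      qb2[s][a2] = rb + delta * pv;
    }
  }
  double vq1[4], vq2[4];           // own-strategy averages of qbar
  for (int s = 0; s < 4; ++s) {
    vq1[s] = x1[s][0] * qb1[s][0] + x1[s][1] * qb1[s][1];
    vq2[s] = x2[s][0] * qb2[s][0] + x2[s][1] * qb2[s][1];
  }
  for (int s = 0; s < 4; ++s) {
    for (int a1 = 0; a1 < 2; ++a1) {
      double rb = 0, nq = 0;
      for (int a2 = 0; a2 < 2; ++a2) {
        int sn = 2 * a1 + a2;
        rb += x2[s][a2] * r1[sn];
        nq += x2[s][a2] * vq1[sn];
      }
      t1[s][a1] = rb + delta * nq;
    }
    for (int a2 = 0; a2 < 2; ++a2) {
      double rb = 0, nq = 0;
      for (int a1 = 0; a1 < 2; ++a1) {
        int sn = 2 * a1 + a2;
        rb += x1[s][a1] * r2[sn];
        nq += x1[s][a1] * vq2[sn];
      }
      t2[s][a2] = rb + delta * nq;
    }
  }
  double dmax = 0;
  for (int s = 0; s < 4; ++s)
    for (int a = 0; a < 2; ++a) {
      double d1 = alpha * (t1[s][a] - q1[s][a]);
      double d2 = alpha * (t2[s][a] - q2[s][a]);
      q1[s][a] += d1;
      q2[s][a] += d2;
      dmax = std::max(dmax, std::max(std::abs(d1), std::abs(d2)));
    }
  return dmax;
}

// [[Rcpp::export]]
List cpp_converge_classify(NumericMatrix q1_init, NumericMatrix q2_init,
                           double Tp, double Sp, double alpha, double eps,
                           double delta, double tol, int max_iters,
                           int window) {
  const double r1[4] = {1.0, Sp, Tp, 0.0};
  const double r2[4] = {1.0, Tp, Sp, 0.0};
  double q1[4][2], q2[4][2];
  for (int s = 0; s < 4; ++s)
    for (int a = 0; a < 2; ++a) { q1[s][a] = q1_init(s, a); q2[s][a] = q2_init(s, a); }
  int prev_code = pair_code_of(q1, q2);
  int streak = 0, it = 0;
  bool converged = false;
  for (it = 1; it <= max_iters; ++it) {
    double dmax = det_step(q1, q2, r1, r2, alpha, eps, delta);
    int code = pair_code_of(q1, q2);
    streak = (dmax < tol && code == prev_code) ? streak + 1 : 0;
    prev_code = code;
    if (streak >= window) { converged = true; break; }
  }
  NumericMatrix o1(4, 2), o2(4, 2);
  for (int s = 0; s < 4; ++s)
    for (int a = 0; a < 2; ++a) { o1(s, a) = q1[s][a]; o2(s, a) = q2[s][a]; }
  return List::create(_["code"] = prev_code, _["converged"] = converged,
                      _["iterations"] = std::min(it, max_iters),
                      _["q1"] = o1, _["q2"] = o2);
}
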