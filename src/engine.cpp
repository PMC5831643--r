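// Deterministic shared-tree level-k I-POMDP engine for the 10-round trust
// game on the 5x5 action grid.
//
// One tree of depth H = min(P, rounds left) is built from the acting
// player's current decision. All embedded lower-level agents are evaluated
// inside the same tree (their horizons truncate at the tree boundary), and
// each level's policies are kept in memory for the next level up, so the
// cost is linear in the theory-of-mind level: one forward belief-filtering
// pass and one backward induction pass per level over a shared node set.
//
// Everything is closed-form/deterministic: no Monte Carlo in the planner.

#include <Rcpp.h>
#include <cstring>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

static const int INV_AMT[5] = {0, 5, 10, 15, 20};
static const int NRET[5] = {1, 5, 5, 5, 5};
// fraction * 3*aI rounded half away from zero
static const int RET_AMT[5][5] = {
    {0, 0, 0, 0, 0},
    {0, 3, 5, 8, 10},
    {0, 5, 10, 15, 20},
    {0, 8, 15, 23, 30},
    {0, 10, 20, 30, 40}};
static const double ALPHA[3] = {0.0, 0.4, 1.0};
static const double ZETAV[5] = {0.0, 0.25, 0.5, 0.75, 1.0};
// irritability prior rows by awareness q = 0..4
static const double QPRIOR[5][5] = {
    {400.0, 0.1, 0.1, 0.1, 0.1},
    {4.0, 0.5, 0.5, 0.5, 0.5},
    {0.4, 0.1, 0.1, 0.1, 0.1},
    {2.0, 1.0, 1.0, 1.0, 1.0},
    {0.1, 0.1, 0.1, 0.1, 400.0}};
static const int N_ROUNDS = 10;

// ---------------------------------------------------------------- utilities

static inline double uInv(int aI, int aT, double alpha, double omega) {
  double chiI = 20.0 - aI + aT, chiT = 3.0 * aI - aT;
  double g = chiI > chiT ? alpha * (chiI - chiT) : 0.0;
  return omega * (20.0 - aI) + aT - g;
}

static inline double uTru(int aI, int aT, double alpha) {
  double chiI = 20.0 - aI + aT, chiT = 3.0 * aI - aT;
  double g = chiT > chiI ? alpha * (chiT - chiI) : 0.0;
  return chiT - g;
}

static void softmax(const double *q, int n, double beta, double *out) {
  double m = q[0];
  for (int i = 1; i < n; ++i)
    if (q[i] > m) m = q[i];
  if (!R_finite(beta)) {  // argmax limit; ties uniform over maximizers
    int cnt = 0;
    for (int i = 0; i < n; ++i) cnt += (q[i] > m - 1e-10);
    for (int i = 0; i < n; ++i) out[i] = (q[i] > m - 1e-10) ? 1.0 / cnt : 0.0;
    return;
  }
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    out[i] = std::exp(beta * (q[i] - m));
    s += out[i];
  }
  for (int i = 0; i < n; ++i) out[i] /= s;
}

// ------------------------------------------------------------------ context

struct Ctx {
  int role;   // 0 investor, 1 trustee
  int k, P;
  double beta, omega, zeta;
  int q, alphaIdx;
  int irrMode;  // 0 = maximal distrust, 1 = uniform partner assumption
  long maxNodes;
};

struct Belief {
  double d[3];  // Dirichlet weights over partner guilt
  double w[5];  // Dirichlet weights over partner irritability
  double v[5];  // partner irritation weight per zeta hypothesis
};

// per-subject precomputed tables (level -1 policies, irritated policies)
struct Engine {
  Ctx c;
  double polT_m1[3][5][5];  // level -1 trustee policy [alpha][aI][ret]
  double polI_m1[3][5];     // level -1 investor policy [alpha][aI]
  double irrT[5][5];        // irritated trustee policy per aI
  double irrI[5];           // irritated investor policy
  double EunifT[5];         // mean return amount per aI (uniform bottom-out)
  double EunifI;            // mean investment amount
};

static int role_of_level(const Engine &E, int l) {
  return ((E.c.k - l) % 2 == 0) ? E.c.role : 1 - E.c.role;
}

static Engine make_engine(const List &ctx) {
  Engine E;
  E.c.role = as<int>(ctx["role"]);
  E.c.k = as<int>(ctx["k"]);
  E.c.P = as<int>(ctx["P"]);
  E.c.beta = as<double>(ctx["beta"]);
  E.c.omega = as<double>(ctx["omega"]);
  E.c.zeta = as<double>(ctx["zeta"]);
  E.c.q = as<int>(ctx["q"]);
  E.c.irrMode = as<int>(ctx["irr_mode"]);
  E.c.maxNodes = ctx.containsElementNamed("max_nodes")
                     ? (long)as<double>(ctx["max_nodes"])
                     : 2000000L;
  double alpha = as<double>(ctx["alpha"]);
  E.c.alphaIdx = -1;
  for (int i = 0; i < 3; ++i)
    if (std::abs(alpha - ALPHA[i]) < 1e-9) E.c.alphaIdx = i;
  if (E.c.alphaIdx < 0) stop("alpha must be one of 0, 0.4, 1");
  if (E.c.k < 0 || E.c.k > 4) stop("tom level must be in 0..4");
  if (E.c.P < 1 || E.c.P > 4) stop("plan must be in 1..4");
  if (E.c.q < 0 || E.c.q > 4) stop("awareness must be in 0..4");

  for (int aI = 0; aI < 5; ++aI) {
    double s = 0.0;
    for (int j = 0; j < NRET[aI]; ++j) s += RET_AMT[aI][j];
    E.EunifT[aI] = s / NRET[aI];
  }
  E.EunifI = 10.0;

  // level -1 trustee: myopic softmax of own-round utility
  for (int a = 0; a < 3; ++a)
    for (int aI = 0; aI < 5; ++aI) {
      double q[5];
      for (int j = 0; j < NRET[aI]; ++j) q[j] = uTru(INV_AMT[aI], RET_AMT[aI][j], ALPHA[a]);
      softmax(q, NRET[aI], E.c.beta, E.polT_m1[a][aI]);
      for (int j = NRET[aI]; j < 5; ++j) E.polT_m1[a][aI][j] = 0.0;
    }
  // level -1 investor: immediate expected utility, uniform partner guilt
  for (int a = 0; a < 3; ++a) {
    double q[5];
    for (int aI = 0; aI < 5; ++aI) {
      double acc = 0.0;
      for (int a2 = 0; a2 < 3; ++a2)
        for (int j = 0; j < NRET[aI]; ++j)
          acc += (1.0 / 3.0) * E.polT_m1[a2][aI][j] *
                 uInv(INV_AMT[aI], RET_AMT[aI][j], ALPHA[a], E.c.omega);
      q[aI] = acc;
    }
    softmax(q, 5, E.c.beta, E.polI_m1[a]);
  }
  // irritated policies: guilt-free, myopic, beta = 1/2
  for (int aI = 0; aI < 5; ++aI) {
    double q[5];
    for (int j = 0; j < NRET[aI]; ++j) q[j] = uTru(INV_AMT[aI], RET_AMT[aI][j], 0.0);
    softmax(q, NRET[aI], 0.5, E.irrT[aI]);
    for (int j = NRET[aI]; j < 5; ++j) E.irrT[aI][j] = 0.0;
  }
  {
    double wi = std::max(1.0, E.c.omega);
    double q[5];
    for (int aI = 0; aI < 5; ++aI) {
      q[aI] = wi * (20.0 - INV_AMT[aI]);
      if (E.c.irrMode == 1) q[aI] += E.EunifT[aI];
    }
    softmax(q, 5, 0.5, E.irrI);
  }
  return E;
}

static std::vector<Belief> init_beliefs(const Engine &E) {
  std::vector<Belief> B(E.c.k + 1);
  for (int l = 0; l <= E.c.k; ++l) {
    for (int i = 0; i < 3; ++i) B[l].d[i] = 1.0;
    for (int z = 0; z < 5; ++z) {
      B[l].w[z] = QPRIOR[E.c.q][z];
      B[l].v[z] = 0.0;
    }
  }
  return B;
}

// ------------------------------------------------- shared edge-update logic

static inline void norm3(const double *x, double *out) {
  double s = x[0] + x[1] + x[2];
  for (int i = 0; i < 3; ++i) out[i] = x[i] / s;
}
static inline void norm5(const double *x, double *out) {
  double s = 0.0;
  for (int i = 0; i < 5; ++i) s += x[i];
  for (int i = 0; i < 5; ++i) out[i] = x[i] / s;
}
static inline void track_step(const double *v, double diff, double *out) {
  for (int z = 0; z < 5; ++z) {
    double nv = v[z];
    if (diff < 0)
      nv = std::min(nv + ZETAV[z], 1.0);  // unfavorable: shortfall
    else if (diff > 0)
      nv = std::max(nv - ZETAV[z], 0.0);  // favorable: repair
    out[z] = nv;
  }
}

// investor-parity level: predictions of the trustee and the per-hypothesis
// trustee irritation track after each own hypothetical investment
struct InvCalc {
  double track[5][5];  // [aI][zeta]
  double predT[5][5];  // [aI][ret]
  double EretT[5];
  double pa[3], pz[5];
  double pibar[5][5];  // guilt-marginal non-irritated trustee policy [aI][ret]
};

static void calc_inv(const Engine &E, const Belief &B,
                     const double polTlm1[3][5][5], double Einv_lm1,
                     InvCalc &o) {
  norm3(B.d, o.pa);
  norm5(B.w, o.pz);
  for (int aI = 0; aI < 5; ++aI) {
    track_step(B.v, (double)INV_AMT[aI] - Einv_lm1, o.track[aI]);
    int nr = NRET[aI];
    double er = 0.0;
    for (int j = 0; j < nr; ++j) {
      o.pibar[aI][j] = o.pa[0] * polTlm1[0][aI][j] +
                       o.pa[1] * polTlm1[1][aI][j] +
                       o.pa[2] * polTlm1[2][aI][j];
      double p = 0.0;
      for (int z = 0; z < 5; ++z)
        p += o.pz[z] * ((1.0 - o.track[aI][z]) * o.pibar[aI][j] +
                        o.track[aI][z] * E.irrT[aI][j]);
      o.predT[aI][j] = p;
      er += RET_AMT[aI][j] * p;
    }
    for (int j = nr; j < 5; ++j) {
      o.predT[aI][j] = 0.0;
      o.pibar[aI][j] = 0.0;
    }
    o.EretT[aI] = er;
  }
}

static Belief edge_inv(const Engine &E, const Belief &B, const InvCalc &o,
                       const double polTlm1[3][5][5], int aI, int aTj) {
  Belief nb = B;
  for (int z = 0; z < 5; ++z) nb.v[z] = o.track[aI][z];
  if (aI > 0) {  // forced returns carry no information
    for (int i = 0; i < 3; ++i) {
      double li = 0.0;
      for (int z = 0; z < 5; ++z)
        li += o.pz[z] * ((1.0 - o.track[aI][z]) * polTlm1[i][aI][aTj] +
                         o.track[aI][z] * E.irrT[aI][aTj]);
      nb.d[i] += li;
    }
    for (int z = 0; z < 5; ++z)
      nb.w[z] += (1.0 - o.track[aI][z]) * o.pibar[aI][aTj] +
                 o.track[aI][z] * E.irrT[aI][aTj];
  }
  return nb;
}

// trustee-parity level: predictions of the investor
struct TruCalc {
  double pibar[5];
  double predI[5];
  double EinvI;
  double pa[3], pz[5];
};

static void calc_tru(const Engine &E, const Belief &B,
                     const double polIlm1[3][5], TruCalc &o) {
  norm3(B.d, o.pa);
  norm5(B.w, o.pz);
  double ei = 0.0;
  for (int aI = 0; aI < 5; ++aI) {
    o.pibar[aI] = o.pa[0] * polIlm1[0][aI] + o.pa[1] * polIlm1[1][aI] +
                  o.pa[2] * polIlm1[2][aI];
    double p = 0.0;
    for (int z = 0; z < 5; ++z)
      p += o.pz[z] * ((1.0 - B.v[z]) * o.pibar[aI] + B.v[z] * E.irrI[aI]);
    o.predI[aI] = p;
    ei += INV_AMT[aI] * p;
  }
  o.EinvI = ei;
}

static Belief edge_tru(const Engine &E, const Belief &B, const TruCalc &o,
                       const double polIlm1[3][5], const double *EretT_lm1,
                       int aI, int aTj) {
  Belief nb = B;
  for (int i = 0; i < 3; ++i) {
    double li = 0.0;
    for (int z = 0; z < 5; ++z)
      li += o.pz[z] * ((1.0 - B.v[z]) * polIlm1[i][aI] + B.v[z] * E.irrI[aI]);
    nb.d[i] += li;
  }
  for (int z = 0; z < 5; ++z)
    nb.w[z] += (1.0 - B.v[z]) * o.pibar[aI] + B.v[z] * E.irrI[aI];
  if (aI > 0) {  // own (trustee) forced move updates no track
    track_step(nb.v, (double)RET_AMT[aI][aTj] - EretT_lm1[aI], nb.v);
  }
  return nb;
}

// --------------------------------------------------------------- tree slots

struct Slot {
  int child[5][5];
  Belief B[5];
  // investor-parity per-level storage
  double QI[5][3][5], polI[5][3][5], VI[5][3];
  double predT[5][5][5], EretT[5][5], track[5][5][5];
  // trustee-parity per-level storage
  double QT[5][3][5][5], polT[5][3][5][5], VT[5][3];
  double predI[5][5], EinvI[5];
};

static std::vector<Slot> g_slots;  // reused buffer (single-threaded R)

static int build_structure(const Engine &E, int H) {
  long need = 1, lev = 1;
  for (int d = 1; d < H; ++d) {
    lev *= 21;
    need += lev;
  }
  if (need > E.c.maxNodes)
    stop("planning tree of %ld nodes exceeds the node budget (%ld)", need,
         E.c.maxNodes);
  if ((long)g_slots.size() < need) g_slots.resize(need);
  std::vector<Slot> &S = g_slots;
  // BFS: depth d occupies a contiguous block; children assigned in order
  long start = 0, count = 1, next = 1;
  for (int d = 0; d < H; ++d) {
    for (long s = start; s < start + count; ++s) {
      for (int aI = 0; aI < 5; ++aI)
        for (int j = 0; j < 5; ++j) S[s].child[aI][j] = -1;
      if (d < H - 1) {
        for (int aI = 0; aI < 5; ++aI)
          for (int j = 0; j < NRET[aI]; ++j) S[s].child[aI][j] = (int)next++;
      }
    }
    start += count;
    count *= 21;
  }
  return (int)next;
}

// build the shared tree from the current beliefs; fills g_slots[0..n)
static int run_tree(const Engine &E, const std::vector<Belief> &rootB, int H) {
  int n = build_structure(E, H);
  std::vector<Slot> &S = g_slots;
  for (int l = 0; l <= E.c.k; ++l) S[0].B[l] = rootB[l];

  for (int l = 0; l <= E.c.k; ++l) {
    int rl = role_of_level(E, l);
    // forward pass: predictions + belief filtering along edges
    for (int s = 0; s < n; ++s) {
      Slot &sl = S[s];
      if (rl == 0) {
        const double(*pT)[5][5] = (l == 0) ? E.polT_m1 : sl.polT[l - 1];
        double Einv = (l == 0) ? E.EunifI : sl.EinvI[l - 1];
        InvCalc o;
        calc_inv(E, sl.B[l], pT, Einv, o);
        std::memcpy(sl.track[l], o.track, sizeof(o.track));
        std::memcpy(sl.predT[l], o.predT, sizeof(o.predT));
        std::memcpy(sl.EretT[l], o.EretT, sizeof(o.EretT));
        for (int aI = 0; aI < 5; ++aI)
          for (int j = 0; j < NRET[aI]; ++j) {
            int ch = sl.child[aI][j];
            if (ch >= 0) S[ch].B[l] = edge_inv(E, sl.B[l], o, pT, aI, j);
          }
      } else {
        const double(*pI)[5] = (l == 0) ? E.polI_m1 : sl.polI[l - 1];
        const double *Eret = (l == 0) ? E.EunifT : sl.EretT[l - 1];
        TruCalc o;
        calc_tru(E, sl.B[l], pI, o);
        std::memcpy(sl.predI[l], o.predI, sizeof(o.predI));
        sl.EinvI[l] = o.EinvI;
        for (int aI = 0; aI < 5; ++aI)
          for (int j = 0; j < NRET[aI]; ++j) {
            int ch = sl.child[aI][j];
            if (ch >= 0) S[ch].B[l] = edge_tru(E, sl.B[l], o, pI, Eret, aI, j);
          }
      }
    }
    // backward pass: Q-values, policies, continuation values
    for (int s = n - 1; s >= 0; --s) {
      Slot &sl = S[s];
      if (rl == 0) {
        for (int a = 0; a < 3; ++a) {
          double Q[5];
          for (int aI = 0; aI < 5; ++aI) {
            double acc = 0.0;
            for (int j = 0; j < NRET[aI]; ++j) {
              int ch = sl.child[aI][j];
              double cont = (ch >= 0) ? S[ch].VI[l][a] : 0.0;
              acc += sl.predT[l][aI][j] *
                     (uInv(INV_AMT[aI], RET_AMT[aI][j], ALPHA[a], E.c.omega) + cont);
            }
            Q[aI] = acc;
          }
          std::memcpy(sl.QI[l][a], Q, sizeof(Q));
          softmax(Q, 5, E.c.beta, sl.polI[l][a]);
          double val = 0.0;
          for (int aI = 0; aI < 5; ++aI) val += sl.polI[l][a][aI] * Q[aI];
          sl.VI[l][a] = val;
        }
      } else {
        for (int a = 0; a < 3; ++a) {
          double V = 0.0;
          for (int aI = 0; aI < 5; ++aI) {
            int nr = NRET[aI];
            double Q[5];
            for (int j = 0; j < nr; ++j) {
              int ch = sl.child[aI][j];
              double cont = (ch >= 0) ? S[ch].VT[l][a] : 0.0;
              Q[j] = uTru(INV_AMT[aI], RET_AMT[aI][j], ALPHA[a]) + cont;
            }
            double pol[5];
            softmax(Q, nr, E.c.beta, pol);
            double ev = 0.0;
            for (int j = 0; j < nr; ++j) {
              sl.QT[l][a][aI][j] = Q[j];
              sl.polT[l][a][aI][j] = pol[j];
              ev += pol[j] * Q[j];
            }
            for (int j = nr; j < 5; ++j) {
              sl.QT[l][a][aI][j] = NA_REAL;
              sl.polT[l][a][aI][j] = 0.0;
            }
            V += sl.predI[l][aI] * ev;
          }
          sl.VT[l][a] = V;
        }
      }
    }
  }
  return n;
}

// ------------------------------------------------------- round assessments

// everything the caller (and the belief advance) needs from the root slot;
// index [level + 1], so 0 holds the level -1 tables
struct Summary {
  double polI[6][3][5];
  double polT[6][3][5][5];
  double EinvI[6];
  double EretT[6][5];
  double QIown[5];
  double QTown[5][5];
  double predTroot[5][5];
  double predIroot[5];
  int H;
};

struct Player {
  Engine E;
  std::vector<Belief> B;
  double own_v;
  int round;  // next round to play, 1-based
};

static Player make_player(const List &ctx) {
  Player P;
  P.E = make_engine(ctx);
  P.B = init_beliefs(P.E);
  P.own_v = 0.0;
  P.round = 1;
  return P;
}

static void assess(const Player &P, Summary &S) {
  const Engine &E = P.E;
  if (P.round > N_ROUNDS) stop("game over: no further rounds to assess");
  S.H = std::min(E.c.P, N_ROUNDS - P.round + 1);
  run_tree(E, P.B, S.H);
  const Slot &root = g_slots[0];
  std::memcpy(S.polI[0], E.polI_m1, sizeof(E.polI_m1));
  std::memcpy(S.polT[0], E.polT_m1, sizeof(E.polT_m1));
  S.EinvI[0] = E.EunifI;
  std::memcpy(S.EretT[0], E.EunifT, sizeof(E.EunifT));
  for (int l = 0; l <= E.c.k; ++l) {
    if (role_of_level(E, l) == 0) {
      std::memcpy(S.polI[l + 1], root.polI[l], sizeof(root.polI[l]));
      std::memcpy(S.EretT[l + 1], root.EretT[l], sizeof(root.EretT[l]));
    } else {
      std::memcpy(S.polT[l + 1], root.polT[l], sizeof(root.polT[l]));
      S.EinvI[l + 1] = root.EinvI[l];
    }
  }
  int k = E.c.k, a = E.c.alphaIdx;
  if (E.c.role == 0) {
    std::memcpy(S.QIown, root.QI[k][a], sizeof(S.QIown));
    std::memcpy(S.predTroot, root.predT[k], sizeof(S.predTroot));
  } else {
    std::memcpy(S.QTown, root.QT[k][a], sizeof(S.QTown));
    std::memcpy(S.predIroot, root.predI[k], sizeof(S.predIroot));
  }
}

// advance the real belief stack and own irritation with an observed round
static void advance(Player &P, const Summary &S, int aI, int aTj) {
  const Engine &E = P.E;
  int k = E.c.k;
  std::vector<Belief> nb(k + 1);
  for (int l = 0; l <= k; ++l) {
    if (role_of_level(E, l) == 0) {
      InvCalc o;
      calc_inv(E, P.B[l], S.polT[l], S.EinvI[l], o);
      nb[l] = edge_inv(E, P.B[l], o, S.polT[l], aI, aTj);
    } else {
      TruCalc o;
      calc_tru(E, P.B[l], S.polI[l], o);
      nb[l] = edge_tru(E, P.B[l], o, S.polI[l], S.EretT[l], aI, aTj);
    }
  }
  P.B = nb;
  if (E.c.role == 0) {
    if (aI > 0) {  // forced return: neutral, no own-irritation change
      double diff = (double)RET_AMT[aI][aTj] - S.EretT[k + 1][aI];
      if (diff < 0)
        P.own_v = std::min(P.own_v + E.c.zeta, 1.0);
      else if (diff > 0)
        P.own_v = std::max(P.own_v - E.c.zeta, 0.0);
    }
  } else {
    double diff = (double)INV_AMT[aI] - S.EinvI[k + 1];
    if (diff < 0)
      P.own_v = std::min(P.own_v + E.c.zeta, 1.0);
    else if (diff > 0)
      P.own_v = std::max(P.own_v - E.c.zeta, 0.0);
  }
  P.round += 1;
}

// trustee's own irritation at decision time (after observing this round's aI)
static double trustee_v_decision(const Player &P, const Summary &S, int aI) {
  double diff = (double)INV_AMT[aI] - S.EinvI[P.E.c.k + 1];
  double v = P.own_v;
  if (diff < 0)
    v = std::min(v + P.E.c.zeta, 1.0);
  else if (diff > 0)
    v = std::max(v - P.E.c.zeta, 0.0);
  return v;
}

static void behavior_inv(const Player &P, const Summary &S, double out[5]) {
  const Engine &E = P.E;
  for (int i = 0; i < 5; ++i)
    out[i] = (1.0 - P.own_v) * S.polI[E.c.k + 1][E.c.alphaIdx][i] +
             P.own_v * E.irrI[i];
}

static void behavior_tru(const Player &P, const Summary &S, int aI, double vdec,
                         double out[5]) {
  const Engine &E = P.E;
  for (int j = 0; j < 5; ++j)
    out[j] = (1.0 - vdec) * S.polT[E.c.k + 1][E.c.alphaIdx][aI][j] +
             vdec * E.irrT[aI][j];
}

// ------------------------------------------------------ index helpers / IO

static int inv_index(int amt) {
  for (int i = 0; i < 5; ++i)
    if (INV_AMT[i] == amt) return i;
  stop("investment %d is not on the grid {0,5,10,15,20}", amt);
  return -1;
}

static int ret_index(int aIidx, int amt) {
  for (int j = 0; j < NRET[aIidx]; ++j)
    if (RET_AMT[aIidx][j] == amt) return j;
  stop("repayment %d is not on the return grid for investment %d", amt,
       INV_AMT[aIidx]);
  return -1;
}

// ------------------------------------------------------------- entry points

// [[Rcpp::export]]
List cpp_assess(List ctx, IntegerVector invest, IntegerVector repay) {
  Player P = make_player(ctx);
  const Engine &E = P.E;
  int R = invest.size();
  if (repay.size() != R) stop("invest/repay length mismatch");
  if (R > N_ROUNDS) stop("history longer than %d rounds", N_ROUNDS);

  NumericMatrix planned(R, 5), irritated(R, 5), mixture(R, 5), predp(R, 5),
      qval(R, 5);
  NumericVector v(R), expectation(R), p_obs(R);
  LogicalVector forced(R);

  Summary S;
  for (int r = 0; r < R; ++r) {
    int aI = inv_index(invest[r]);
    int aTj = ret_index(aI, repay[r]);
    assess(P, S);
    if (E.c.role == 0) {
      double pol[5];
      behavior_inv(P, S, pol);
      for (int i = 0; i < 5; ++i) {
        planned(r, i) = S.polI[E.c.k + 1][E.c.alphaIdx][i];
        irritated(r, i) = E.irrI[i];
        mixture(r, i) = pol[i];
        predp(r, i) = S.predTroot[aI][i];
        qval(r, i) = S.QIown[i];
      }
      v[r] = P.own_v;
      expectation[r] = S.EretT[E.c.k + 1][aI];
      p_obs[r] = pol[aI];
      forced[r] = false;
    } else {
      forced[r] = (aI == 0);
      double vdec = trustee_v_decision(P, S, aI);
      double pol[5];
      behavior_tru(P, S, aI, vdec, pol);
      for (int j = 0; j < 5; ++j) {
        planned(r, j) = S.polT[E.c.k + 1][E.c.alphaIdx][aI][j];
        irritated(r, j) = E.irrT[aI][j];
        mixture(r, j) = pol[j];
        predp(r, j) = S.predIroot[j];
        qval(r, j) = S.QTown[aI][j];
      }
      v[r] = vdec;
      expectation[r] = S.EinvI[E.c.k + 1];
      p_obs[r] = (aI == 0) ? 1.0 : pol[aTj];
    }
    advance(P, S, aI, aTj);
  }
  return List::create(
      _["planned"] = planned, _["irritated"] = irritated,
      _["mixture"] = mixture, _["pred_partner"] = predp, _["q_values"] = qval,
      _["v"] = v, _["expectation"] = expectation, _["p_obs"] = p_obs,
      _["forced"] = forced, _["final_v"] = P.own_v);
}

// [[Rcpp::export]]
List cpp_policy(List ctx, IntegerVector invest, IntegerVector repay,
                int aI_now) {
  Player P = make_player(ctx);
  const Engine &E = P.E;
  int R = invest.size();
  Summary S;
  for (int r = 0; r < R; ++r) {
    int aI = inv_index(invest[r]);
    int aTj = ret_index(aI, repay[r]);
    assess(P, S);
    advance(P, S, aI, aTj);
  }
  assess(P, S);
  int k = E.c.k, a = E.c.alphaIdx;
  if (E.c.role == 0) {
    double pol[5];
    behavior_inv(P, S, pol);
    NumericMatrix predT(5, 5);
    NumericVector eret(5);
    for (int aI = 0; aI < 5; ++aI) {
      eret[aI] = S.EretT[k + 1][aI];
      for (int j = 0; j < 5; ++j) predT(aI, j) = S.predTroot[aI][j];
    }
    return List::create(
        _["planned"] = NumericVector(S.polI[k + 1][a], S.polI[k + 1][a] + 5),
        _["irritated"] = NumericVector(E.irrI, E.irrI + 5),
        _["mixture"] = NumericVector(pol, pol + 5),
        _["q_values"] = NumericVector(S.QIown, S.QIown + 5),
        _["v_decision"] = P.own_v, _["pred_partner"] = predT,
        _["expectation"] = eret, _["forced"] = false);
  } else {
    if (aI_now < 0) stop("trustee policy query requires the current investment");
    int aI = inv_index(aI_now);
    double vdec = trustee_v_decision(P, S, aI);
    double pol[5];
    behavior_tru(P, S, aI, vdec, pol);
    return List::create(
        _["planned"] = NumericVector(S.polT[k + 1][a][aI],
                                     S.polT[k + 1][a][aI] + 5),
        _["irritated"] = NumericVector(E.irrT[aI], E.irrT[aI] + 5),
        _["mixture"] = NumericVector(pol, pol + 5),
        _["q_values"] = NumericVector(S.QTown[aI], S.QTown[aI] + 5),
        _["v_decision"] = vdec,
        _["pred_partner"] = NumericVector(S.predIroot, S.predIroot + 5),
        _["expectation"] = S.EinvI[k + 1], _["forced"] = (aI == 0));
  }
}

// ----------------------------------------------------------------- simulate

struct SimNode {
  Player pI, pT;
  Summary SI, ST;
};

// [[Rcpp::export]]
List cpp_simulate(List ctxI, List ctxT, IntegerVector forcedI,
                  IntegerVector forcedT, int n_runs) {
  if (forcedI.size() != N_ROUNDS || forcedT.size() != N_ROUNDS)
    stop("forced-action vectors must have length 10");
  std::map<std::string, SimNode> cache;
  {
    SimNode root;
    root.pI = make_player(ctxI);
    root.pT = make_player(ctxT);
    if (root.pI.E.c.role != 0 || root.pT.E.c.role != 1)
      stop("ctxI must be an investor and ctxT a trustee");
    assess(root.pI, root.SI);
    assess(root.pT, root.ST);
    cache.emplace("", root);
  }
  IntegerMatrix inv(n_runs, N_ROUNDS), rep(n_runs, N_ROUNDS);
  NumericMatrix vI(n_runs, N_ROUNDS), vT(n_runs, N_ROUNDS);

  for (int run = 0; run < n_runs; ++run) {
    std::string key = "";
    SimNode *cur = &cache.at(key);
    for (int r = 0; r < N_ROUNDS; ++r) {
      // investor decision
      double polI[5];
      behavior_inv(cur->pI, cur->SI, polI);
      int aI;
      if (forcedI[r] >= 0) {
        aI = inv_index(forcedI[r]);
      } else {
        double u = unif_rand(), c = 0.0;
        aI = 4;
        for (int i = 0; i < 5; ++i) {
          c += polI[i];
          if (u <= c) {
            aI = i;
            break;
          }
        }
      }
      // trustee decision
      double vdec = trustee_v_decision(cur->pT, cur->ST, aI);
      int aTj = 0;
      if (aI > 0) {
        if (forcedT[r] >= 0) {
          aTj = ret_index(aI, forcedT[r]);
        } else {
          double polT[5];
          behavior_tru(cur->pT, cur->ST, aI, vdec, polT);
          double u = unif_rand(), c = 0.0;
          aTj = NRET[aI] - 1;
          for (int j = 0; j < NRET[aI]; ++j) {
            c += polT[j];
            if (u <= c) {
              aTj = j;
              break;
            }
          }
        }
      } else if (forcedT[r] > 0) {
        stop("scenario forces a nonzero return after a zero investment");
      }
      inv(run, r) = INV_AMT[aI];
      rep(run, r) = RET_AMT[aI][aTj];
      vI(run, r) = cur->pI.own_v;
      vT(run, r) = vdec;
      if (r < N_ROUNDS - 1) {
        key.push_back((char)('a' + aI));
        key.push_back((char)('a' + aTj));
        auto it = cache.find(key);
        if (it == cache.end()) {
          SimNode nxt;
          nxt.pI = cur->pI;
          nxt.pT = cur->pT;
          advance(nxt.pI, cur->SI, aI, aTj);
          advance(nxt.pT, cur->ST, aI, aTj);
          assess(nxt.pI, nxt.SI);
          assess(nxt.pT, nxt.ST);
          it = cache.emplace(key, nxt).first;
        }
        cur = &it->second;
      }
    }
  }
  return List::create(_["investments"] = inv, _["repayments"] = rep,
                      _["v_investor"] = vI, _["v_trustee"] = vT);
}

// ------------------------------------------------------------ introspection

// [[Rcpp::export]]
List cpp_tree_dump(List ctx, IntegerVector invest, IntegerVector repay) {
  Player P = make_player(ctx);
  const Engine &E = P.E;
  Summary S;
  int R = invest.size();
  for (int r = 0; r < R; ++r) {
    int aI = inv_index(invest[r]);
    int aTj = ret_index(aI, repay[r]);
    assess(P, S);
    advance(P, S, aI, aTj);
  }
  int H = std::min(E.c.P, N_ROUNDS - P.round + 1);
  int n = run_tree(E, P.B, H);
  std::vector<Slot> &T = g_slots;

  // reconstruct paths in BFS order
  std::vector<std::string> paths(n);
  {
    long start = 0, count = 1;
    for (int d = 0; d < H; ++d) {
      for (long s = start; s < start + count; ++s)
        for (int aI = 0; aI < 5; ++aI)
          for (int j = 0; j < NRET[aI]; ++j) {
            int ch = T[s].child[aI][j];
            if (ch >= 0)
              paths[ch] = paths[s] + (paths[s].empty() ? "" : "|") +
                          std::to_string(INV_AMT[aI]) + ":" +
                          std::to_string(RET_AMT[aI][j]);
          }
      start += count;
      count *= 21;
    }
  }

  List slots(n);
  for (int s = 0; s < n; ++s) {
    List levels(E.c.k + 1);
    for (int l = 0; l <= E.c.k; ++l) {
      int rl = role_of_level(E, l);
      List li;
      li["role"] = rl == 0 ? "investor" : "trustee";
      li["d"] = NumericVector(T[s].B[l].d, T[s].B[l].d + 3);
      li["w"] = NumericVector(T[s].B[l].w, T[s].B[l].w + 5);
      li["v"] = NumericVector(T[s].B[l].v, T[s].B[l].v + 5);
      if (rl == 0) {
        NumericMatrix Q(3, 5), pol(3, 5), predT(5, 5);
        for (int a = 0; a < 3; ++a)
          for (int i = 0; i < 5; ++i) {
            Q(a, i) = T[s].QI[l][a][i];
            pol(a, i) = T[s].polI[l][a][i];
          }
        for (int aI = 0; aI < 5; ++aI)
          for (int j = 0; j < 5; ++j) predT(aI, j) = T[s].predT[l][aI][j];
        li["Q"] = Q;
        li["pol"] = pol;
        li["V"] = NumericVector(T[s].VI[l], T[s].VI[l] + 3);
        li["pred"] = predT;
        li["Eret"] = NumericVector(T[s].EretT[l], T[s].EretT[l] + 5);
      } else {
        NumericVector Q(Dimension(3, 5, 5)), pol(Dimension(3, 5, 5));
        for (int a = 0; a < 3; ++a)
          for (int aI = 0; aI < 5; ++aI)
            for (int j = 0; j < 5; ++j) {
              Q[a + 3 * aI + 15 * j] = T[s].QT[l][a][aI][j];
              pol[a + 3 * aI + 15 * j] = T[s].polT[l][a][aI][j];
            }
        li["Q"] = Q;
        li["pol"] = pol;
        li["V"] = NumericVector(T[s].VT[l], T[s].VT[l] + 3);
        li["pred"] = NumericVector(T[s].predI[l], T[s].predI[l] + 5);
        li["Einv"] = T[s].EinvI[l];
      }
      levels[l] = li;
    }
    slots[s] = List::create(_["path"] = paths[s], _["levels"] = levels);
  }
  return List::create(_["n_slots"] = n, _["H"] = H, _["root_round"] = P.round,
                      _["slots"] = slots);
}

// [[Rcpp::export]]
List cpp_tree_stats(List ctx, int round) {
  Engine E = make_engine(ctx);
  int H = std::min(E.c.P, N_ROUNDS - round + 1);
  long need = 1, lev = 1;
  for (int d = 1; d < H; ++d) {
    lev *= 21;
    need += lev;
  }
  return List::create(_["n_slots"] = (double)need,
                      _["n_level_passes"] = E.c.k + 1, _["H"] = H);
}
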