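// XCS classifier engine and synchronous Boolean-network simulator.
//
// Everything stochastic draws from R's RNG (unif_rand), so a single
// set.seed() call in R fully determines a run.  Conditions are stored as
// (care, value) bit masks with node 1 in the most significant bit, which
// makes rule matching a single mask comparison; the guard N <= 24 is
// enforced on the R side.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

// ------------------------------------------------------------- network ----

struct Net {
  int n, k;
  std::vector<std::vector<int> > in;   // 0-based input indices, first = MSB
  std::vector<std::vector<int> > tab;  // per node, 2^k output bits
};

Net asNet(const List &net) {
  Net N;
  N.n = as<int>(net["n"]);
  N.k = as<int>(net["k"]);
  IntegerMatrix inputs = net["inputs"];
  IntegerMatrix tables = net["truthTables"];
  const int rows = 1 << N.k;
  N.in.resize(N.n);
  N.tab.resize(N.n);
  for (int i = 0; i < N.n; ++i) {
    N.in[i].resize(N.k);
    for (int j = 0; j < N.k; ++j) N.in[i][j] = inputs(i, j) - 1;
    N.tab[i].resize(rows);
    for (int r = 0; r < rows; ++r) N.tab[i][r] = tables(i, r);
  }
  return N;
}

// synchronous update: all outputs computed from the pre-step state
inline uint32_t stepState(const Net &N, uint32_t s) {
  uint32_t out = 0;
  for (int i = 0; i < N.n; ++i) {
    int idx = 0;
    for (int j = 0; j < N.k; ++j)
      idx = (idx << 1) | (int)((s >> (N.n - 1 - N.in[i][j])) & 1u);
    out = (out << 1) | (uint32_t)N.tab[i][idx];
  }
  return out;
}

uint32_t strToState(const std::string &s) {
  uint32_t v = 0;
  for (size_t i = 0; i < s.size(); ++i) v = (v << 1) | (s[i] == '1' ? 1u : 0u);
  return v;
}

std::string stateToStr(uint32_t v, int n) {
  std::string s(n, '0');
  for (int i = 0; i < n; ++i)
    if ((v >> (n - 1 - i)) & 1u) s[i] = '1';
  return s;
}

int rint(int m) {  // uniform integer in [0, m)
  int v = (int)(unif_rand() * m);
  return v >= m ? m - 1 : v;
}

// ------------------------------------------------------------ parameters --

struct Par {
  int R;
  double gamma;
  int thetaMna;
  double pHash, pI, epsI, fI, eps0, thetaGa, thetaDel;
  double beta, alpha, nu, chi, mu, delta, thetaSub;
  bool doAss, doGas;
};

Par asPar(const List &p) {
  Par q;
  q.R = as<int>(p["popSize"]);
  q.gamma = as<double>(p["gamma"]);
  q.thetaMna = as<int>(p["thetaMna"]);
  q.pHash = as<double>(p["pHash"]);
  q.pI = as<double>(p["predictionInit"]);
  q.epsI = as<double>(p["errorInit"]);
  q.fI = as<double>(p["fitnessInit"]);
  q.eps0 = as<double>(p["eps0"]);
  q.thetaGa = as<double>(p["thetaGa"]);
  q.thetaDel = as<double>(p["thetaDel"]);
  q.beta = as<double>(p["beta"]);
  q.alpha = as<double>(p["alpha"]);
  q.nu = as<double>(p["nu"]);
  q.chi = as<double>(p["chi"]);
  q.mu = as<double>(p["mu"]);
  q.delta = as<double>(p["delta"]);
  q.thetaSub = as<double>(p["thetaSub"]);
  q.doAss = as<bool>(p["doActionSetSubsumption"]);
  q.doGas = as<bool>(p["doGaSubsumption"]);
  return q;
}

// ------------------------------------------------------------ population --

struct Cl {
  uint32_t care, val;  // val bits are zero wherever care is zero
  int action;
  double p, eps, f;
  int num, exp;
  double as;
  int ts;
  long long id;
};

struct Pop {
  int n;  // condition length
  std::vector<Cl> v;
  std::unordered_map<long long, int> pos;
  long long nextId;
  long long micro;
  Pop() : n(0), nextId(1), micro(0) {}
  void reindex() {
    pos.clear();
    for (size_t i = 0; i < v.size(); ++i) pos[v[i].id] = (int)i;
  }
  int find(long long id) const {
    std::unordered_map<long long, int>::const_iterator it = pos.find(id);
    return it == pos.end() ? -1 : it->second;
  }
};

void condToMask(const std::string &c, uint32_t &care, uint32_t &val) {
  care = 0;
  val = 0;
  for (size_t i = 0; i < c.size(); ++i) {
    care <<= 1;
    val <<= 1;
    if (c[i] != '#') {
      care |= 1u;
      if (c[i] == '1') val |= 1u;
    }
  }
}

std::string maskToCond(uint32_t care, uint32_t val, int n) {
  std::string s(n, '#');
  for (int i = 0; i < n; ++i) {
    uint32_t b = 1u << (n - 1 - i);
    if (care & b) s[i] = (val & b) ? '1' : '0';
  }
  return s;
}

inline int nHash(const Cl &c, int n) {
  int bits = 0;
  uint32_t care = c.care;
  while (care) { bits += (int)(care & 1u); care >>= 1; }
  return n - bits;
}

inline bool condMatches(const Cl &c, uint32_t s) {
  return (s & c.care) == c.val;
}

// general strictly more general than specific, same action
inline bool moreGeneral(const Cl &g, const Cl &s, int n) {
  if (g.action != s.action) return false;
  if (nHash(g, n) <= nHash(s, n)) return false;
  if ((s.care & g.care) != g.care) return false;
  return (s.val & g.care) == g.val;
}

Pop popFromDf(DataFrame df, int n_hint) {
  Pop P;
  P.n = n_hint;
  CharacterVector cond = df["condition"];
  IntegerVector act = df["action"];
  NumericVector pr = df["prediction"], er = df["error"], fi = df["fitness"];
  IntegerVector nu = df["numerosity"], ex = df["experience"];
  NumericVector as_ = df["actionSetSize"];
  IntegerVector ts = df["timeStamp"];
  for (int i = 0; i < cond.size(); ++i) {
    Cl c;
    std::string cs = as<std::string>(cond[i]);
    if (P.n == 0) P.n = (int)cs.size();
    condToMask(cs, c.care, c.val);
    c.action = act[i];
    c.p = pr[i];
    c.eps = er[i];
    c.f = fi[i];
    c.num = nu[i];
    c.exp = ex[i];
    c.as = as_[i];
    c.ts = ts[i];
    c.id = P.nextId++;
    P.micro += c.num;
    P.v.push_back(c);
  }
  P.reindex();
  return P;
}

DataFrame popToDf(const Pop &P) {
  const int m = (int)P.v.size();
  CharacterVector cond(m);
  IntegerVector act(m), nu(m), ex(m), ts(m);
  NumericVector pr(m), er(m), fi(m), as_(m);
  for (int i = 0; i < m; ++i) {
    const Cl &c = P.v[i];
    cond[i] = maskToCond(c.care, c.val, P.n);
    act[i] = c.action;
    pr[i] = c.p;
    er[i] = c.eps;
    fi[i] = c.f;
    nu[i] = c.num;
    ex[i] = c.exp;
    as_[i] = c.as;
    ts[i] = c.ts;
  }
  DataFrame df = DataFrame::create(
      _["condition"] = cond, _["action"] = act, _["prediction"] = pr,
      _["error"] = er, _["fitness"] = fi, _["numerosity"] = nu,
      _["experience"] = ex, _["actionSetSize"] = as_, _["timeStamp"] = ts,
      _["stringsAsFactors"] = false);
  df.attr("class") = CharacterVector::create("xcs_population", "data.frame");
  df.attr("conditionLength") = P.n;
  return df;
}

// insert, merging with an identical (condition, action) macroclassifier
void insertCl(Pop &P, const Cl &c) {
  for (size_t i = 0; i < P.v.size(); ++i) {
    Cl &o = P.v[i];
    if (o.care == c.care && o.val == c.val && o.action == c.action) {
      o.num += c.num;
      P.micro += c.num;
      return;
    }
  }
  Cl c2 = c;
  c2.id = P.nextId++;
  P.v.push_back(c2);
  P.pos[c2.id] = (int)P.v.size() - 1;
  P.micro += c2.num;
}

void eraseAt(Pop &P, int i) {
  P.v.erase(P.v.begin() + i);
  P.reindex();
}

// roulette deletion down to the population capacity R
void deleteToCapacity(Pop &P, const Par &par) {
  while (P.micro > par.R && !P.v.empty()) {
    double totF = 0.0;
    for (size_t i = 0; i < P.v.size(); ++i) totF += P.v[i].f;
    const double meanF = totF / (double)P.micro;
    std::vector<double> vote(P.v.size());
    double sum = 0.0;
    for (size_t i = 0; i < P.v.size(); ++i) {
      const Cl &c = P.v[i];
      double w = c.as * c.num;
      const double fpm = c.f / c.num;
      if (c.exp > par.thetaDel && fpm < par.delta * meanF)
        w *= meanF / std::max(fpm, 1e-12);
      vote[i] = w;
      sum += w;
    }
    int pick = (int)P.v.size() - 1;
    if (sum > 0) {
      double u = unif_rand() * sum, acc = 0.0;
      for (size_t i = 0; i < P.v.size(); ++i) {
        acc += vote[i];
        if (u < acc) { pick = (int)i; break; }
      }
    } else {
      pick = rint((int)P.v.size());
    }
    P.v[pick].num -= 1;
    P.micro -= 1;
    if (P.v[pick].num == 0) eraseAt(P, pick);
  }
}

std::vector<long long> matchIds(const Pop &P, uint32_t s) {
  std::vector<long long> out;
  for (size_t i = 0; i < P.v.size(); ++i)
    if (condMatches(P.v[i], s)) out.push_back(P.v[i].id);
  return out;
}

Cl coverCl(uint32_t s, const std::vector<int> &absent, const Par &par, int n,
           int time) {
  Cl c;
  c.care = (n == 32) ? 0xffffffffu : ((1u << n) - 1u);
  c.val = s & c.care;
  for (int i = 0; i < n; ++i) {
    if (unif_rand() < par.pHash) {
      uint32_t b = 1u << (n - 1 - i);
      c.care &= ~b;
      c.val &= ~b;
    }
  }
  c.action = absent[rint((int)absent.size())];
  c.p = par.pI;
  c.eps = par.epsI;
  c.f = par.fI;
  c.num = 1;
  c.exp = 0;
  c.as = 1.0;
  c.ts = time;
  c.id = 0;  // assigned on insert
  return c;
}

// match set with covering until theta_mna DISTINCT actions are represented
std::vector<long long> buildMatch(Pop &P, uint32_t s, const Par &par,
                                  int nActions, int time, bool covering) {
  for (int guard = 0;; ++guard) {
    std::vector<long long> ids = matchIds(P, s);
    if (!covering) return ids;
    std::vector<bool> present(nActions, false);
    int distinct = 0;
    for (size_t i = 0; i < ids.size(); ++i) {
      int a = P.v[P.find(ids[i])].action;
      if (!present[a]) { present[a] = true; ++distinct; }
    }
    if (distinct >= par.thetaMna) return ids;
    if (guard > 100 * nActions)
      stop("covering failed to stabilise; population capacity too small");
    std::vector<int> absent;
    for (int a = 0; a < nActions; ++a)
      if (!present[a]) absent.push_back(a);
    if (absent.empty())
      stop("covering exhausted: thetaMna exceeds the number of actions");
    insertCl(P, coverCl(s, absent, par, P.n, time));
    deleteToCapacity(P, par);
  }
}

// prediction array: fitness-weighted mean prediction per advocated action
void predArray(const Pop &P, const std::vector<long long> &ids, int nActions,
               std::vector<double> &pa, std::vector<bool> &has) {
  std::vector<double> sPF(nActions, 0.0), sF(nActions, 0.0), sP(nActions, 0.0);
  std::vector<int> cnt(nActions, 0);
  pa.assign(nActions, 0.0);
  has.assign(nActions, false);
  for (size_t i = 0; i < ids.size(); ++i) {
    int j = P.find(ids[i]);
    if (j < 0) continue;
    const Cl &c = P.v[j];
    sPF[c.action] += c.p * c.f;
    sF[c.action] += c.f;
    sP[c.action] += c.p;
    cnt[c.action] += 1;
  }
  for (int a = 0; a < nActions; ++a) {
    if (cnt[a] == 0) continue;
    has[a] = true;
    pa[a] = (sF[a] > 0) ? sPF[a] / sF[a] : sP[a] / cnt[a];
  }
}

// deterministic action chooser: exploit when max prediction > 500,
// otherwise pick a random represented action; greedy mode always exploits
int chooseAction(const std::vector<double> &pa, const std::vector<bool> &has,
                 bool greedy) {
  int best = -1;
  std::vector<int> present;
  for (size_t a = 0; a < pa.size(); ++a) {
    if (!has[a]) continue;
    present.push_back((int)a);
    if (best < 0 || pa[a] > pa[best]) best = (int)a;
  }
  if (best < 0) stop("no action available in prediction array");
  if (greedy || pa[best] > 500.0) return best;
  return present[rint((int)present.size())];
}

double maxPrediction(const std::vector<double> &pa,
                     const std::vector<bool> &has) {
  double m = 0.0;
  bool any = false;
  for (size_t a = 0; a < pa.size(); ++a)
    if (has[a] && (!any || pa[a] > m)) { m = pa[a]; any = true; }
  return any ? m : 0.0;
}

// action-set subsumption: the most general experienced accurate member
// absorbs every strictly-less-general member
void assSubsume(Pop &P, std::vector<long long> &ids, const Par &par) {
  int subIdx = -1, subHash = -1;
  for (size_t i = 0; i < ids.size(); ++i) {
    int j = P.find(ids[i]);
    if (j < 0) continue;
    const Cl &c = P.v[j];
    if (c.exp > par.thetaSub && c.eps < par.eps0) {
      int h = nHash(c, P.n);
      if (h > subHash) { subHash = h; subIdx = (int)i; }
    }
  }
  if (subIdx < 0) return;
  long long subId = ids[subIdx];
  std::vector<long long> keep;
  for (size_t i = 0; i < ids.size(); ++i) {
    int j = P.find(ids[i]);
    if (j < 0) continue;
    if (ids[i] != subId) {
      int js = P.find(subId);
      if (moreGeneral(P.v[js], P.v[j], P.n)) {
        P.v[js].num += P.v[j].num;  // micro count conserved
        eraseAt(P, j);
        continue;
      }
    }
    keep.push_back(ids[i]);
  }
  ids.swap(keep);
}

// MAM update of prediction error, prediction and action-set-size estimate,
// then accuracy-based fitness; error is updated against the pre-update
// prediction
void updateSet(Pop &P, std::vector<long long> &ids, double Ptarget,
               const Par &par) {
  std::vector<int> idx;
  long long numSum = 0;
  for (size_t i = 0; i < ids.size(); ++i) {
    int j = P.find(ids[i]);
    if (j < 0) continue;
    idx.push_back(j);
    numSum += P.v[j].num;
  }
  if (idx.empty()) { ids.clear(); return; }
  for (size_t i = 0; i < idx.size(); ++i) {
    Cl &c = P.v[idx[i]];
    c.exp += 1;
    const double inv = (c.exp < 1.0 / par.beta) ? 1.0 / c.exp : par.beta;
    c.eps += inv * (std::abs(Ptarget - c.p) - c.eps);
    c.p += inv * (Ptarget - c.p);
    c.as += inv * ((double)numSum - c.as);
  }
  double denom = 0.0;
  std::vector<double> kap(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) {
    const Cl &c = P.v[idx[i]];
    kap[i] = (c.eps < par.eps0) ? 1.0
                                : par.alpha * std::pow(c.eps / par.eps0, -par.nu);
    denom += kap[i] * c.num;
  }
  for (size_t i = 0; i < idx.size(); ++i) {
    Cl &c = P.v[idx[i]];
    const double kprime = (denom > 0) ? kap[i] * c.num / denom : 0.0;
    c.f += par.beta * (kprime - c.f);
  }
  // keep only survivors in the caller's id list
  std::vector<long long> alive;
  for (size_t i = 0; i < ids.size(); ++i)
    if (P.find(ids[i]) >= 0) alive.push_back(ids[i]);
  ids.swap(alive);
  if (par.doAss) assSubsume(P, ids, par);
}

void crossoverMasks(Cl &a, Cl &b, int n) {
  int x = rint(n + 1), y = rint(n + 1);
  if (x > y) std::swap(x, y);
  if (x == y) return;
  const uint32_t span = (uint32_t)(y - x);
  const uint32_t mask =
      (span >= 32) ? 0xffffffffu : (((1u << span) - 1u) << (n - y));
  uint32_t ca = (a.care & ~mask) | (b.care & mask);
  uint32_t cb = (b.care & ~mask) | (a.care & mask);
  uint32_t va = (a.val & ~mask) | (b.val & mask);
  uint32_t vb = (b.val & ~mask) | (a.val & mask);
  a.care = ca; a.val = va;
  b.care = cb; b.val = vb;
}

// niche mutation: a # becomes the situation's bit, a literal becomes #
void mutateCl(Cl &c, uint32_t situation, const Par &par, int n, int nActions) {
  for (int i = 0; i < n; ++i) {
    if (unif_rand() < par.mu) {
      const uint32_t b = 1u << (n - 1 - i);
      if (c.care & b) {
        c.care &= ~b;
        c.val &= ~b;
      } else {
        c.care |= b;
        c.val = (c.val & ~b) | (situation & b);
      }
    }
  }
  if (unif_rand() < par.mu) {
    int a = rint(nActions - 1);
    if (a >= c.action) ++a;
    c.action = a;
  }
}

// GA on an action set; returns true when the theta_ga trigger fired
bool gaOnSet(Pop &P, std::vector<long long> &ids, uint32_t situation, int time,
             const Par &par, int nActions) {
  std::vector<int> idx;
  double tsNum = 0.0;
  long long numSum = 0;
  for (size_t i = 0; i < ids.size(); ++i) {
    int j = P.find(ids[i]);
    if (j < 0) continue;
    idx.push_back(j);
    tsNum += (double)P.v[j].ts * P.v[j].num;
    numSum += P.v[j].num;
  }
  if (idx.empty() || numSum == 0) return false;
  if ((double)time - tsNum / (double)numSum <= par.thetaGa) return false;
  for (size_t i = 0; i < idx.size(); ++i) P.v[idx[i]].ts = time;

  // fitness-proportionate roulette over the action set
  double fSum = 0.0;
  for (size_t i = 0; i < idx.size(); ++i) fSum += P.v[idx[i]].f;
  int psel[2];
  for (int t = 0; t < 2; ++t) {
    int pick = (int)idx.size() - 1;
    if (fSum > 0) {
      double u = unif_rand() * fSum, acc = 0.0;
      for (size_t i = 0; i < idx.size(); ++i) {
        acc += P.v[idx[i]].f;
        if (u < acc) { pick = (int)i; break; }
      }
    } else {
      pick = rint((int)idx.size());
    }
    psel[t] = idx[pick];
  }
  Cl par1 = P.v[psel[0]], par2 = P.v[psel[1]];
  Cl ch[2];
  ch[0] = par1;
  ch[1] = par2;
  for (int t = 0; t < 2; ++t) {
    ch[t].num = 1;
    ch[t].exp = 0;
    ch[t].ts = time;
  }
  if (unif_rand() < par.chi) crossoverMasks(ch[0], ch[1], P.n);
  // children inherit the parent averages of prediction, error and fitness
  const double mp = (par1.p + par2.p) / 2.0;
  const double me = (par1.eps + par2.eps) / 2.0;
  const double mf = (par1.f + par2.f) / 2.0;
  for (int t = 0; t < 2; ++t) {
    ch[t].p = mp;
    ch[t].eps = me;
    ch[t].f = mf;
    mutateCl(ch[t], situation, par, P.n, nActions);
  }
  const long long id1 = par1.id, id2 = par2.id;
  for (int t = 0; t < 2; ++t) {
    bool absorbed = false;
    if (par.doGas) {
      const long long pids[2] = {id1, id2};
      for (int w = 0; w < 2 && !absorbed; ++w) {
        int j = P.find(pids[w]);
        if (j < 0) continue;
        Cl &pc = P.v[j];
        if (pc.exp > par.thetaSub && pc.eps < par.eps0 &&
            moreGeneral(pc, ch[t], P.n)) {
          pc.num += 1;
          P.micro += 1;
          absorbed = true;
        }
      }
    }
    if (!absorbed) insertCl(P, ch[t]);
  }
  deleteToCapacity(P, par);
  // refresh caller's ids (members may have been deleted)
  std::vector<long long> alive;
  for (size_t i = 0; i < ids.size(); ++i)
    if (P.find(ids[i]) >= 0) alive.push_back(ids[i]);
  ids.swap(alive);
  return true;
}

// ------------------------------------------------------------------ task --

struct Task {
  int n, nActions;
  std::vector<uint32_t> succ;
  std::vector<char> inTarget;
  std::vector<uint32_t> starts;  // all states outside the target cycle
};

Task asTask(const List &net, const CharacterVector &target) {
  Net N = asNet(net);
  Task T;
  T.n = N.n;
  T.nActions = N.n + 1;
  const uint32_t S = 1u << N.n;
  T.succ.resize(S);
  T.inTarget.assign(S, 0);
  for (uint32_t s = 0; s < S; ++s) T.succ[s] = stepState(N, s);
  for (int i = 0; i < target.size(); ++i)
    T.inTarget[strToState(as<std::string>(target[i]))] = 1;
  for (uint32_t s = 0; s < S; ++s)
    if (!T.inTarget[s]) T.starts.push_back(s);
  return T;
}

struct TrialOut {
  long steps, interventions;
  bool reached;
  double reward;
  std::vector<uint32_t> traj;
};

// one trial: the nine-step sense-match-predict-act-reward cycle, with the
// previous action set updated from the current prediction array and a final
// update + GA trigger check on the terminal action set
TrialOut runTrialImpl(Pop &P, const Task &T, const Par &par, bool learning,
                      uint32_t start, long maxSteps, long &time, bool keepTraj) {
  TrialOut out;
  out.steps = 0;
  out.interventions = 0;
  out.reached = false;
  out.reward = 0.0;
  uint32_t state = start;
  if (keepTraj) out.traj.push_back(state);
  std::vector<long long> prevAS;
  double prevReward = 0.0;
  uint32_t prevSit = 0;
  bool havePrev = false;
  while (true) {
    if (learning) ++time;
    const uint32_t sit = state;
    std::vector<long long> M =
        buildMatch(P, sit, par, T.nActions, (int)time, learning);
    std::vector<double> pa;
    std::vector<bool> has;
    predArray(P, M, T.nActions, pa, has);
    bool anyAction = false;
    for (int a = 0; a < T.nActions; ++a)
      if (has[a]) { anyAction = true; break; }
    const int action = anyAction ? chooseAction(pa, has, !learning) : 0;
    std::vector<long long> AS;
    for (size_t i = 0; i < M.size(); ++i) {
      int j = P.find(M[i]);
      if (j >= 0 && P.v[j].action == action) AS.push_back(M[i]);
    }
    if (action != 0) {
      state ^= 1u << (T.n - action);
      out.steps += 1;
      out.interventions += 1;
    }
    state = T.succ[state];
    out.steps += 1;
    if (keepTraj) out.traj.push_back(state);
    const bool reached = T.inTarget[state] != 0;
    // the reinforcement program counts one step per reward calculation
    // (i.e. per decision cycle = per natural update); the trial ledger
    // above additionally counts interventions for the reported statistics
    const long cycles = out.steps - out.interventions;
    const double reward =
        reached ? 1000.0 * (double)(cycles - out.interventions) /
                      (double)cycles
                : 0.0;
    if (learning && havePrev) {
      const double Ptarget = prevReward + par.gamma * maxPrediction(pa, has);
      updateSet(P, prevAS, Ptarget, par);
      gaOnSet(P, prevAS, prevSit, (int)time, par, T.nActions);
    }
    if (reached) {
      if (learning && !AS.empty()) {
        updateSet(P, AS, reward, par);
        gaOnSet(P, AS, sit, (int)time, par, T.nActions);
      }
      out.reached = true;
      out.reward = reward;
      return out;
    }
    if (out.steps >= maxSteps) {
      if (learning && !AS.empty()) {
        updateSet(P, AS, 0.0, par);
        gaOnSet(P, AS, sit, (int)time, par, T.nActions);
      }
      out.reached = false;
      out.reward = 0.0;
      return out;
    }
    prevAS = AS;
    prevReward = reward;
    prevSit = sit;
    havePrev = true;
  }
}

struct EvalOut {
  std::vector<uint32_t> start;
  std::vector<bool> reached;
  std::vector<long> steps, interv;
  std::vector<std::string> traj;
  bool covered;
  double avgSteps, avgInterv;
};

// greedy, non-learning sweep over every start state outside the target
EvalOut evalAll(Pop &P, const Task &T, const Par &par, long maxSteps,
                bool keepTraj) {
  EvalOut E;
  E.covered = true;
  double ss = 0.0, si = 0.0;
  long dummyTime = 0;
  for (size_t i = 0; i < T.starts.size(); ++i) {
    TrialOut o =
        runTrialImpl(P, T, par, false, T.starts[i], maxSteps, dummyTime,
                     keepTraj);
    E.start.push_back(T.starts[i]);
    E.reached.push_back(o.reached);
    E.steps.push_back(o.steps);
    E.interv.push_back(o.interventions);
    if (keepTraj) {
      std::string t;
      for (size_t j = 0; j < o.traj.size(); ++j) {
        if (j) t += " ";
        t += stateToStr(o.traj[j], T.n);
      }
      E.traj.push_back(t);
    }
    if (!o.reached) E.covered = false;
    ss += (double)o.steps;
    si += (double)o.interventions;
  }
  const double m = std::max((double)T.starts.size(), 1.0);
  E.avgSteps = ss / m;
  E.avgInterv = si / m;
  return E;
}

DataFrame evalToDf(const EvalOut &E, int n, bool keepTraj) {
  const int m = (int)E.start.size();
  CharacterVector st(m);
  LogicalVector re(m);
  IntegerVector sp(m), iv(m);
  CharacterVector tj(m);
  for (int i = 0; i < m; ++i) {
    st[i] = stateToStr(E.start[i], n);
    re[i] = E.reached[i];
    sp[i] = (int)E.steps[i];
    iv[i] = (int)E.interv[i];
    if (keepTraj) tj[i] = E.traj[i];
  }
  if (keepTraj)
    return DataFrame::create(_["start"] = st, _["reached"] = re,
                             _["steps"] = sp, _["interventions"] = iv,
                             _["trajectory"] = tj,
                             _["stringsAsFactors"] = false);
  return DataFrame::create(_["start"] = st, _["reached"] = re, _["steps"] = sp,
                           _["interventions"] = iv,
                           _["stringsAsFactors"] = false);
}

}  // namespace

// ---------------------------------------------------------------------------
// exported: network simulation and state-space analysis
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
std::string cpp_network_step(List net, std::string state) {
  Net N = asNet(net);
  return stateToStr(stepState(N, strToState(state)), N.n);
}

// [[Rcpp::export]]
List cpp_map_state_space(List net) {
  Net N = asNet(net);
  const uint32_t S = 1u << N.n;
  std::vector<uint32_t> succ(S);
  for (uint32_t s = 0; s < S; ++s) succ[s] = stepState(N, s);
  std::vector<int> color(S, 0), basin(S, -1);
  std::vector<std::vector<uint32_t> > cycles;
  std::vector<uint32_t> path;
  for (uint32_t s0 = 0; s0 < S; ++s0) {
    if (color[s0] != 0) continue;
    path.clear();
    uint32_t s = s0;
    while (color[s] == 0) {
      color[s] = 1;
      path.push_back(s);
      s = succ[s];
    }
    int aid;
    if (color[s] == 1) {  // new cycle discovered on the current path
      size_t pos = 0;
      while (path[pos] != s) ++pos;
      std::vector<uint32_t> cyc(path.begin() + pos, path.end());
      size_t mi = 0;
      for (size_t i = 1; i < cyc.size(); ++i)
        if (cyc[i] < cyc[mi]) mi = i;
      std::vector<uint32_t> rot;
      for (size_t i = 0; i < cyc.size(); ++i)
        rot.push_back(cyc[(mi + i) % cyc.size()]);
      cycles.push_back(rot);
      aid = (int)cycles.size();
      for (size_t i = 0; i < cyc.size(); ++i) {
        basin[cyc[i]] = aid;
        color[cyc[i]] = 2;
      }
    } else {
      aid = basin[s];
    }
    for (size_t i = 0; i < path.size(); ++i) {
      if (color[path[i]] == 1) {
        basin[path[i]] = aid;
        color[path[i]] = 2;
      }
    }
  }
  IntegerVector successor(S), basinOut(S);
  for (uint32_t s = 0; s < S; ++s) {
    successor[s] = (int)succ[s] + 1;  // 1-based index into state order
    basinOut[s] = basin[s];
  }
  List att(cycles.size());
  for (size_t i = 0; i < cycles.size(); ++i) {
    IntegerVector cy(cycles[i].size());
    for (size_t j = 0; j < cycles[i].size(); ++j)
      cy[j] = (int)cycles[i][j] + 1;
    att[i] = cy;
  }
  return List::create(_["successor"] = successor, _["attractors"] = att,
                      _["basin"] = basinOut);
}

// ---------------------------------------------------------------------------
// exported: XCS operations (shared with the trainer)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_build_match_set(DataFrame pop, std::string state, List params,
                         int time, bool covering) {
  Par par = asPar(params);
  Pop P = popFromDf(pop, (int)state.size());
  const int nActions = (int)state.size() + 1;
  std::vector<long long> ids =
      buildMatch(P, strToState(state), par, nActions, time, covering);
  IntegerVector idx(ids.size());
  for (size_t i = 0; i < ids.size(); ++i) idx[i] = P.find(ids[i]) + 1;
  return List::create(_["population"] = popToDf(P), _["matchSet"] = idx);
}

// [[Rcpp::export]]
DataFrame cpp_cover(std::string state, IntegerVector presentActions,
                    List params, int time) {
  Par par = asPar(params);
  const int n = (int)state.size();
  const int nActions = n + 1;
  std::vector<bool> present(nActions, false);
  for (int i = 0; i < presentActions.size(); ++i)
    present[presentActions[i]] = true;
  std::vector<int> absent;
  for (int a = 0; a < nActions; ++a)
    if (!present[a]) absent.push_back(a);
  if (absent.empty())
    stop("covering exhausted: every action is already present");
  Pop P;
  P.n = n;
  Cl c = coverCl(strToState(state), absent, par, n, time);
  c.id = 1;
  P.v.push_back(c);
  P.micro = 1;
  P.reindex();
  return popToDf(P);
}

// [[Rcpp::export]]
List cpp_update_action_set(DataFrame pop, IntegerVector actionSet,
                           double Ptarget, List params) {
  Par par = asPar(params);
  Pop P = popFromDf(pop, 0);
  std::vector<long long> ids;
  for (int i = 0; i < actionSet.size(); ++i)
    ids.push_back(P.v[actionSet[i] - 1].id);
  updateSet(P, ids, Ptarget, par);
  IntegerVector idx(ids.size());
  for (size_t i = 0; i < ids.size(); ++i) idx[i] = P.find(ids[i]) + 1;
  return List::create(_["population"] = popToDf(P), _["actionSet"] = idx);
}

// [[Rcpp::export]]
List cpp_run_ga(DataFrame pop, IntegerVector actionSet, std::string situation,
                int time, List params) {
  Par par = asPar(params);
  Pop P = popFromDf(pop, (int)situation.size());
  std::vector<long long> ids;
  for (int i = 0; i < actionSet.size(); ++i)
    ids.push_back(P.v[actionSet[i] - 1].id);
  const int nActions = (int)situation.size() + 1;
  bool trig = gaOnSet(P, ids, strToState(situation), time, par, nActions);
  return List::create(_["population"] = popToDf(P), _["triggered"] = trig);
}

// [[Rcpp::export]]
List cpp_action_set_subsumption(DataFrame pop, IntegerVector actionSet,
                                List params) {
  Par par = asPar(params);
  Pop P = popFromDf(pop, 0);
  std::vector<long long> ids;
  for (int i = 0; i < actionSet.size(); ++i)
    ids.push_back(P.v[actionSet[i] - 1].id);
  assSubsume(P, ids, par);
  IntegerVector idx(ids.size());
  for (size_t i = 0; i < ids.size(); ++i) idx[i] = P.find(ids[i]) + 1;
  return List::create(_["population"] = popToDf(P), _["actionSet"] = idx);
}

// [[Rcpp::export]]
DataFrame cpp_delete_to_capacity(DataFrame pop, List params) {
  Par par = asPar(params);
  Pop P = popFromDf(pop, 0);
  deleteToCapacity(P, par);
  return popToDf(P);
}

// [[Rcpp::export]]
List cpp_crossover(std::string cond1, std::string cond2,
                   Nullable<IntegerVector> cuts) {
  const int n = (int)cond1.size();
  Cl a, b;
  condToMask(cond1, a.care, a.val);
  condToMask(cond2, b.care, b.val);
  if (cuts.isNotNull()) {
    IntegerVector cu(cuts);
    int x = cu[0], y = cu[1];
    if (x > y) std::swap(x, y);
    if (x != y) {
      const uint32_t span = (uint32_t)(y - x);
      const uint32_t mask =
          (span >= 32) ? 0xffffffffu : (((1u << span) - 1u) << (n - y));
      uint32_t ca = (a.care & ~mask) | (b.care & mask);
      uint32_t cb = (b.care & ~mask) | (a.care & mask);
      uint32_t va = (a.val & ~mask) | (b.val & mask);
      uint32_t vb = (b.val & ~mask) | (a.val & mask);
      a.care = ca; a.val = va;
      b.care = cb; b.val = vb;
    }
  } else {
    crossoverMasks(a, b, n);
  }
  return List::create(maskToCond(a.care, a.val, n), maskToCond(b.care, b.val, n));
}

// [[Rcpp::export]]
List cpp_mutate(std::string condition, int action, std::string situation,
                List params) {
  Par par = asPar(params);
  const int n = (int)condition.size();
  Cl c;
  condToMask(condition, c.care, c.val);
  c.action = action;
  mutateCl(c, strToState(situation), par, n, n + 1);
  return List::create(_["condition"] = maskToCond(c.care, c.val, n),
                      _["action"] = c.action);
}

// ---------------------------------------------------------------------------
// exported: trials, training, evaluation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_trial(List net, CharacterVector target, DataFrame pop, List params,
                   bool learning, std::string start, int maxSteps, int time) {
  Par par = asPar(params);
  Task T = asTask(net, target);
  Pop P = popFromDf(pop, T.n);
  P.n = T.n;
  long tm = time;
  TrialOut o = runTrialImpl(P, T, par, learning, strToState(start), maxSteps,
                            tm, true);
  CharacterVector traj(o.traj.size());
  for (size_t i = 0; i < o.traj.size(); ++i)
    traj[i] = stateToStr(o.traj[i], T.n);
  return List::create(_["population"] = popToDf(P), _["steps"] = (int)o.steps,
                      _["interventions"] = (int)o.interventions,
                      _["reached"] = o.reached, _["reward"] = o.reward,
                      _["time"] = (int)tm, _["trajectory"] = traj);
}

// [[Rcpp::export]]
DataFrame cpp_evaluate_all_states(List net, CharacterVector target,
                                  DataFrame pop, List params, int maxSteps) {
  Par par = asPar(params);
  Task T = asTask(net, target);
  Pop P = popFromDf(pop, T.n);
  P.n = T.n;
  EvalOut E = evalAll(P, T, par, maxSteps, true);
  return evalToDf(E, T.n, true);
}

// [[Rcpp::export]]
List cpp_run_training(List net, CharacterVector target, List params,
                      int minTrials, int evalInterval, int maxSteps,
                      int hardCeiling) {
  Par par = asPar(params);
  Task T = asTask(net, target);
  if (par.thetaMna > T.nActions)
    stop("thetaMna exceeds the number of available actions (N + 1)");
  if (T.starts.empty()) stop("target attractor covers the whole state space");
  Pop P;
  P.n = T.n;
  long time = 0;
  bool success = false;
  int trial = 0;
  std::vector<int> logTrial;
  std::vector<bool> logCovered;
  std::vector<double> logSteps, logInterv;
  std::vector<int> logMacro, logMicro;
  while (trial < hardCeiling) {
    ++trial;
    const uint32_t start = T.starts[rint((int)T.starts.size())];
    runTrialImpl(P, T, par, true, start, maxSteps, time, false);
    if (trial >= minTrials && (trial - minTrials) % evalInterval == 0) {
      EvalOut E = evalAll(P, T, par, maxSteps, false);
      logTrial.push_back(trial);
      logCovered.push_back(E.covered);
      logSteps.push_back(E.avgSteps);
      logInterv.push_back(E.avgInterv);
      logMacro.push_back((int)P.v.size());
      logMicro.push_back((int)P.micro);
      if (E.covered) { success = true; break; }
    }
  }
  const int m = (int)logTrial.size();
  IntegerVector lt(m), lm(m), lmi(m);
  LogicalVector lc(m);
  NumericVector ls(m), li(m);
  for (int i = 0; i < m; ++i) {
    lt[i] = logTrial[i];
    lc[i] = logCovered[i];
    ls[i] = logSteps[i];
    li[i] = logInterv[i];
    lm[i] = logMacro[i];
    lmi[i] = logMicro[i];
  }
  DataFrame log = DataFrame::create(
      _["trial"] = lt, _["covered"] = lc, _["avgSteps"] = ls,
      _["avgInterventions"] = li, _["macroRules"] = lm, _["microCount"] = lmi);
  return List::create(_["population"] = popToDf(P), _["log"] = log,
                      _["success"] = success, _["trials"] = trial,
                      _["time"] = (int)time);
}
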