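// Core simulation engine: IPD strategy rules, deception operators, the
// four-case encounter protocol, and the per-tick evolutionary loop
// (random pairing -> encounters -> cull two lowest -> score-weighted breeding
// with two-point crossover and probabilistic mutation).
//
// All randomness goes through R's RNG (unif_rand / norm_rand) so that
// set.seed() at the R level makes every exported entry point, and the full
// run, bit-reproducible across platforms.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Move encoding: 0 = Cooperate (C), 1 = Defect (D).
static const int MOVE_C = 0;
static const int MOVE_D = 1;

// Strategy encoding (order fixed; mirrored by strategy_levels() in R).
enum Strat { TFT = 0, TF2T, PAVLOV, ALLC, ALLD, RANDOM, PROB, N_STRAT };

// Deception encoding (order fixed; mirrored by deception_levels() in R).
enum Decep { NONE = 0, DEGRADATION, CORRUPTION, DENIAL, SUBVERSION, N_DECEP };

struct Agent {
  int strat;
  int dec;
  double mp;      // mutation probability locus
  double score;   // cumulative score
  std::vector<int> mem;  // opponent moves, oldest first, length <= depth
  int own_last;   // -1 = absent
};

static inline int runif_int(int n) {
  // uniform integer in 0..n-1
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// ---- strategy rules ---------------------------------------------------

static int select_move_agent(const Agent &a) {
  const std::vector<int> &m = a.mem;
  int len = (int)m.size();
  switch (a.strat) {
  case ALLC: return MOVE_C;
  case ALLD: return MOVE_D;
  case RANDOM: return unif_rand() < 0.5 ? MOVE_C : MOVE_D;
  case TFT:
    return len == 0 ? MOVE_C : m[len - 1];
  case TF2T:
    if (len < 2) return MOVE_C;
    return (m[len - 1] == MOVE_D && m[len - 2] == MOVE_D) ? MOVE_D : MOVE_C;
  case PAVLOV: {
    // win-stay / lose-shift: "win" = received T or R last round, i.e. the
    // opponent cooperated; needs both own last move and an observed move.
    if (a.own_last < 0 || len == 0) return MOVE_C;
    bool won = (m[len - 1] == MOVE_C);
    return won ? a.own_last : (1 - a.own_last);
  }
  case PROB: {
    if (len == 0) return unif_rand() < 0.5 ? MOVE_C : MOVE_D;
    int nc = 0;
    for (int i = 0; i < len; ++i) if (m[i] == MOVE_C) ++nc;
    return unif_rand() < (double)nc / len ? MOVE_C : MOVE_D;
  }
  default:
    stop("unknown strategy code");
  }
  return MOVE_C; // not reached
}

static inline void append_mem(Agent &a, int move, int depth) {
  if ((int)a.mem.size() >= depth && depth > 0) a.mem.erase(a.mem.begin());
  if (depth > 0) a.mem.push_back(move);
}

static inline void payoff_pair_int(int ma, int mb, const double *pay,
                                   double &pa, double &pb) {
  // pay = {T, R, P, S}
  if (ma == MOVE_D && mb == MOVE_C) { pa = pay[0]; pb = pay[3]; }
  else if (ma == MOVE_C && mb == MOVE_D) { pa = pay[3]; pb = pay[0]; }
  else if (ma == MOVE_C && mb == MOVE_C) { pa = pay[1]; pb = pay[1]; }
  else { pa = pay[2]; pb = pay[2]; }
}

// ---- deception operators ----------------------------------------------

// Applies the attacker's operator to the victim's pre-move state.
// Returns true if this round's memory append must be suppressed (Denial).
static bool apply_operator(int kind, Agent &victim) {
  switch (kind) {
  case DEGRADATION:
    for (size_t i = 0; i < victim.mem.size(); ++i)
      victim.mem[i] = unif_rand() < 0.5 ? MOVE_C : MOVE_D;
    return false;
  case CORRUPTION:
    for (size_t i = 0; i < victim.mem.size(); ++i)
      victim.mem[i] = MOVE_C;
    return false;
  case SUBVERSION:
    victim.strat = ALLC;
    return false;
  case DENIAL:
    return true;
  case NONE:
    return false;
  default:
    stop("unknown deception code");
  }
  return false;
}

struct EncOut {
  int move_a, move_b;
  double pay_a, pay_b;           // net (cost already subtracted for deceivers)
  double gross_a, gross_b;
  double base_a, base_b;         // counterfactual gross payoffs
  int success_a, success_b;      // 1 success, 0 failure, NA_INTEGER if not deceiving
};

// The four-case encounter protocol. Mutates both agents (memory edits
// persist, this round's opponent move appended unless denied, own_last and
// scores updated).
static EncOut play_encounter_core(Agent &a, Agent &b, const double *pay,
                                  double cost, int depth) {
  bool adec = a.dec != NONE;
  bool bdec = b.dec != NONE;
  EncOut out;
  out.success_a = NA_INTEGER;
  out.success_b = NA_INTEGER;
  bool suppress_a = false; // a does not observe b's move this round
  bool suppress_b = false;

  if (!adec && !bdec) {
    out.move_a = select_move_agent(a);
    out.move_b = select_move_agent(b);
    payoff_pair_int(out.move_a, out.move_b, pay, out.gross_a, out.gross_b);
    out.base_a = out.gross_a;
    out.base_b = out.gross_b;
    out.pay_a = out.gross_a;
    out.pay_b = out.gross_b;
  } else if (adec != bdec) {
    // single deceiver; relabel so x = attacker, y = victim
    Agent &att = adec ? a : b;
    Agent &vic = adec ? b : a;
    int m_att = select_move_agent(att);
    int m_vic0 = select_move_agent(vic);          // counterfactual victim move
    double b_att, b_vic;
    payoff_pair_int(m_att, m_vic0, pay, b_att, b_vic);
    bool denied = apply_operator(att.dec, vic);   // edits persist in vic
    // Denial leaves the pre-move state untouched, so the victim's move is
    // the counterfactual one; other operators alter the state the victim
    // selects from.
    int m_vic1 = denied ? m_vic0 : select_move_agent(vic);
    double g_att, g_vic;
    payoff_pair_int(m_att, m_vic1, pay, g_att, g_vic);
    int succ = g_att > b_att ? 1 : 0;
    if (adec) {
      out.move_a = m_att; out.move_b = m_vic1;
      out.gross_a = g_att; out.gross_b = g_vic;
      out.base_a = b_att; out.base_b = b_vic;
      out.pay_a = g_att - cost; out.pay_b = g_vic;
      out.success_a = succ;
      suppress_b = denied;
    } else {
      out.move_a = m_vic1; out.move_b = m_att;
      out.gross_a = g_vic; out.gross_b = g_att;
      out.base_a = b_vic; out.base_b = b_att;
      out.pay_a = g_vic; out.pay_b = g_att - cost;
      out.success_b = succ;
      suppress_a = denied;
    }
  } else {
    // mutual deception: baseline from unaltered states, then both operators
    // applied simultaneously, then both moves re-selected.
    int ma0 = select_move_agent(a);
    int mb0 = select_move_agent(b);
    payoff_pair_int(ma0, mb0, pay, out.base_a, out.base_b);
    bool denied_a = apply_operator(b.dec, a); // b's operator hits a
    bool denied_b = apply_operator(a.dec, b);
    out.move_a = denied_a ? ma0 : select_move_agent(a);
    out.move_b = denied_b ? mb0 : select_move_agent(b);
    payoff_pair_int(out.move_a, out.move_b, pay, out.gross_a, out.gross_b);
    out.pay_a = out.gross_a - cost;
    out.pay_b = out.gross_b - cost;
    out.success_a = out.gross_a > out.base_a ? 1 : 0;
    out.success_b = out.gross_b > out.base_b ? 1 : 0;
    suppress_a = denied_a;
    suppress_b = denied_b;
  }

  if (!suppress_a) append_mem(a, out.move_b, depth);
  if (!suppress_b) append_mem(b, out.move_a, depth);
  a.own_last = out.move_a;
  b.own_last = out.move_b;
  a.score += out.pay_a;
  b.score += out.pay_b;
  return out;
}

// ---- population <-> R conversion --------------------------------------

static std::vector<Agent> pop_from_list(const List &pop) {
  IntegerVector strat = pop["strategy"];
  IntegerVector dec = pop["deception"];
  NumericVector mp = pop["mutation_prob"];
  NumericVector score = pop["score"];
  IntegerMatrix mem = pop["mem"];
  IntegerVector mem_len = pop["mem_len"];
  IntegerVector own_last = pop["own_last"];
  int n = strat.size();
  std::vector<Agent> agents(n);
  for (int i = 0; i < n; ++i) {
    agents[i].strat = strat[i];
    agents[i].dec = dec[i];
    agents[i].mp = mp[i];
    agents[i].score = score[i];
    agents[i].own_last = own_last[i];
    agents[i].mem.clear();
    for (int j = 0; j < mem_len[i]; ++j) agents[i].mem.push_back(mem(i, j));
  }
  return agents;
}

static List pop_to_list(const std::vector<Agent> &agents, int depth) {
  int n = (int)agents.size();
  IntegerVector strat(n), dec(n), mem_len(n), own_last(n);
  NumericVector mp(n), score(n);
  IntegerMatrix mem(n, depth);
  std::fill(mem.begin(), mem.end(), -1);
  for (int i = 0; i < n; ++i) {
    strat[i] = agents[i].strat;
    dec[i] = agents[i].dec;
    mp[i] = agents[i].mp;
    score[i] = agents[i].score;
    own_last[i] = agents[i].own_last;
    mem_len[i] = (int)agents[i].mem.size();
    for (size_t j = 0; j < agents[i].mem.size(); ++j) mem(i, (int)j) = agents[i].mem[j];
  }
  return List::create(_["strategy"] = strat, _["deception"] = dec,
                      _["mutation_prob"] = mp, _["score"] = score,
                      _["mem"] = mem, _["mem_len"] = mem_len,
                      _["own_last"] = own_last);
}

static Agent agent_from_list(const List &al) {
  Agent a;
  a.strat = as<int>(al["strategy"]);
  a.dec = as<int>(al["deception"]);
  a.mp = as<double>(al["mutation_prob"]);
  a.score = as<double>(al["score"]);
  a.own_last = as<int>(al["own_last"]);
  IntegerVector m = al["memory"];
  a.mem.assign(m.begin(), m.end());
  return a;
}

static List agent_to_list(const Agent &a) {
  return List::create(_["strategy"] = a.strat, _["deception"] = a.dec,
                      _["mutation_prob"] = a.mp, _["score"] = a.score,
                      _["memory"] = IntegerVector(a.mem.begin(), a.mem.end()),
                      _["own_last"] = a.own_last);
}

// ---- evolutionary step ------------------------------------------------

static void pair_and_play_pop(std::vector<Agent> &agents, const double *pay,
                              double cost, int depth, int rounds,
                              int &succ, int &fail) {
  int n = (int)agents.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  // Fisher-Yates with R's RNG: uniformly random perfect matching
  for (int i = n - 1; i > 0; --i) {
    int j = runif_int(i + 1);
    std::swap(idx[i], idx[j]);
  }
  // each pair plays a match of `rounds` consecutive PD rounds; deceivers
  // deceive, pay the cost, and are success-scored on every round
  for (int k = 0; k + 1 < n; k += 2) {
    for (int r = 0; r < rounds; ++r) {
      EncOut e = play_encounter_core(agents[idx[k]], agents[idx[k + 1]], pay,
                                     cost, depth);
      if (e.success_a != NA_INTEGER) (e.success_a ? succ : fail)++;
      if (e.success_b != NA_INTEGER) (e.success_b ? succ : fail)++;
    }
  }
}

static void crossover_mutate_core(const Agent &p1, const Agent &p2,
                                  Agent &c1, Agent &c2,
                                  const std::vector<int> &allowed,
                                  double sigma) {
  // two-point crossover on the 3-locus genome (strategy, deception, mp):
  // cut points in {0,1,2,3}; loci in [min,max) swapped
  int cut1 = runif_int(4);
  int cut2 = runif_int(4);
  int lo = std::min(cut1, cut2), hi = std::max(cut1, cut2);
  double g1[3] = { (double)p1.strat, (double)p1.dec, p1.mp };
  double g2[3] = { (double)p2.strat, (double)p2.dec, p2.mp };
  for (int i = lo; i < hi; ++i) std::swap(g1[i], g2[i]);
  Agent *kids[2] = { &c1, &c2 };
  double *gen[2] = { g1, g2 };
  for (int k = 0; k < 2; ++k) {
    Agent &c = *kids[k];
    c.strat = (int)gen[k][0];
    c.dec = (int)gen[k][1];
    c.mp = gen[k][2];
    double mp0 = c.mp; // per-locus mutation probability of this offspring
    if (unif_rand() < mp0) c.strat = runif_int(N_STRAT);
    if (unif_rand() < mp0)
      c.dec = allowed.empty() ? NONE : allowed[runif_int((int)allowed.size())];
    if (unif_rand() < mp0) {
      c.mp = mp0 + norm_rand() * sigma;
      if (c.mp < 0) c.mp = 0;
      if (c.mp > 1) c.mp = 1;
    }
  }
}

// newborn_mode: 0 = offspring start at score 0, 1 = mean of parents' scores
static void cull_and_breed_pop(std::vector<Agent> &agents,
                               const std::vector<int> &allowed, double sigma,
                               int newborn_mode) {
  int n = (int)agents.size();
  if (n < 4) stop("population too small to cull and breed");
  std::vector<bool> dead(n, false);
  int slots[2];
  for (int r = 0; r < 2; ++r) {
    double lowest = R_PosInf;
    for (int i = 0; i < n; ++i)
      if (!dead[i] && agents[i].score < lowest) lowest = agents[i].score;
    // ties broken uniformly at random
    std::vector<int> ties;
    for (int i = 0; i < n; ++i)
      if (!dead[i] && agents[i].score == lowest) ties.push_back(i);
    int pick = ties[runif_int((int)ties.size())];
    dead[pick] = true;
    slots[r] = pick;
  }
  // parent 1: probability proportional to max(score, 0) among survivors
  std::vector<int> surv;
  for (int i = 0; i < n; ++i) if (!dead[i]) surv.push_back(i);
  double total = 0;
  for (size_t i = 0; i < surv.size(); ++i)
    total += std::max(agents[surv[i]].score, 0.0);
  int p1;
  if (total > 0) {
    double u = unif_rand() * total, acc = 0;
    p1 = surv.back();
    for (size_t i = 0; i < surv.size(); ++i) {
      acc += std::max(agents[surv[i]].score, 0.0);
      if (u < acc) { p1 = surv[i]; break; }
    }
  } else {
    p1 = surv[runif_int((int)surv.size())];
  }
  // parent 2: uniform among the other survivors
  int p2 = p1;
  while (p2 == p1) p2 = surv[runif_int((int)surv.size())];

  Agent c1, c2;
  crossover_mutate_core(agents[p1], agents[p2], c1, c2, allowed, sigma);
  double s0 = 0;
  if (newborn_mode == 1) s0 = 0.5 * (agents[p1].score + agents[p2].score);
  Agent *kids[2] = { &c1, &c2 };
  for (int k = 0; k < 2; ++k) {
    kids[k]->score = s0;
    kids[k]->mem.clear();
    kids[k]->own_last = -1;
    agents[slots[k]] = *kids[k];
  }
}

static void census_row(const std::vector<Agent> &agents, double *row,
                       int succ, int fail) {
  // row layout: 14 counts (strategy-major, plain then deceiving),
  // mean_score, successes, failures
  int n = (int)agents.size();
  for (int c = 0; c < 17; ++c) row[c] = 0;
  double tot = 0;
  for (int i = 0; i < n; ++i) {
    int col = 2 * agents[i].strat + (agents[i].dec != NONE ? 1 : 0);
    row[col] += 1;
    tot += agents[i].score;
  }
  row[14] = n > 0 ? tot / n : 0;
  row[15] = succ;
  row[16] = fail;
}

// ---- exported entry points --------------------------------------------

// [[Rcpp::export]]
int cpp_select_move(int strategy, IntegerVector memory, int own_last) {
  Agent a;
  a.strat = strategy;
  a.dec = NONE;
  a.mp = 0; a.score = 0;
  a.own_last = own_last;
  a.mem.assign(memory.begin(), memory.end());
  return select_move_agent(a);
}

// [[Rcpp::export]]
IntegerVector cpp_apply_corruption(IntegerVector memory) {
  IntegerVector out = clone(memory);
  for (int i = 0; i < out.size(); ++i) out[i] = MOVE_C;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_apply_degradation(IntegerVector memory) {
  IntegerVector out = clone(memory);
  for (int i = 0; i < out.size(); ++i)
    out[i] = unif_rand() < 0.5 ? MOVE_C : MOVE_D;
  return out;
}

// [[Rcpp::export]]
List cpp_play_encounter(List agent_a, List agent_b, NumericVector payoffs,
                        double cost, int memory_depth) {
  Agent a = agent_from_list(agent_a);
  Agent b = agent_from_list(agent_b);
  EncOut e = play_encounter_core(a, b, REAL(payoffs), cost, memory_depth);
  return List::create(
    _["move_a"] = e.move_a, _["move_b"] = e.move_b,
    _["payoff_a"] = e.pay_a, _["payoff_b"] = e.pay_b,
    _["gross_a"] = e.gross_a, _["gross_b"] = e.gross_b,
    _["baseline_a"] = e.base_a, _["baseline_b"] = e.base_b,
    _["success_a"] = e.success_a == NA_INTEGER ? LogicalVector::create(NA_LOGICAL)
                                               : LogicalVector::create(e.success_a == 1),
    _["success_b"] = e.success_b == NA_INTEGER ? LogicalVector::create(NA_LOGICAL)
                                               : LogicalVector::create(e.success_b == 1),
    _["agent_a"] = agent_to_list(a), _["agent_b"] = agent_to_list(b));
}

// [[Rcpp::export]]
List cpp_pair_and_play(List pop, NumericVector payoffs, double cost,
                       int memory_depth, int rounds) {
  std::vector<Agent> agents = pop_from_list(pop);
  if (agents.size() % 2 != 0)
    stop("population size must be even for random pairing");
  int succ = 0, fail = 0;
  pair_and_play_pop(agents, REAL(payoffs), cost, memory_depth, rounds,
                    succ, fail);
  return List::create(_["population"] = pop_to_list(agents, memory_depth),
                      _["successes"] = succ, _["failures"] = fail);
}

// [[Rcpp::export]]
List cpp_cull_and_breed(List pop, IntegerVector allowed, double sigma,
                        int newborn_mode, int memory_depth) {
  std::vector<Agent> agents = pop_from_list(pop);
  std::vector<int> allw(allowed.begin(), allowed.end());
  cull_and_breed_pop(agents, allw, sigma, newborn_mode);
  return pop_to_list(agents, memory_depth);
}

// [[Rcpp::export]]
List cpp_crossover_mutate(List g1, List g2, IntegerVector allowed,
                          double sigma) {
  Agent p1, p2, c1, c2;
  p1.strat = as<int>(g1["strategy"]); p1.dec = as<int>(g1["deception"]);
  p1.mp = as<double>(g1["mutation_prob"]);
  p2.strat = as<int>(g2["strategy"]); p2.dec = as<int>(g2["deception"]);
  p2.mp = as<double>(g2["mutation_prob"]);
  std::vector<int> allw(allowed.begin(), allowed.end());
  crossover_mutate_core(p1, p2, c1, c2, allw, sigma);
  return List::create(
    _["offspring1"] = List::create(_["strategy"] = c1.strat,
                                   _["deception"] = c1.dec,
                                   _["mutation_prob"] = c1.mp),
    _["offspring2"] = List::create(_["strategy"] = c2.strat,
                                   _["deception"] = c2.dec,
                                   _["mutation_prob"] = c2.mp));
}

// [[Rcpp::export]]
NumericMatrix cpp_run_simulation(List pop, int ticks, NumericVector payoffs,
                                 double cost, int memory_depth, int rounds,
                                 IntegerVector allowed, double sigma,
                                 int newborn_mode) {
  std::vector<Agent> agents = pop_from_list(pop);
  if (agents.size() % 2 != 0)
    stop("population size must be even for random pairing");
  std::vector<int> allw(allowed.begin(), allowed.end());
  const double *pay = REAL(payoffs);
  NumericMatrix out(ticks + 1, 18);
  std::vector<double> row(17);
  census_row(agents, row.data(), 0, 0);
  out(0, 0) = 0;
  for (int c = 0; c < 17; ++c) out(0, c + 1) = row[c];
  for (int t = 1; t <= ticks; ++t) {
    int succ = 0, fail = 0;
    pair_and_play_pop(agents, pay, cost, memory_depth, rounds, succ, fail);
    cull_and_breed_pop(agents, allw, sigma, newborn_mode);
    census_row(agents, row.data(), succ, fail);
    out(t, 0) = t;
    for (int c = 0; c < 17; ++c) out(t, c + 1) = row[c];
    if (t % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
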