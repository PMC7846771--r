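// Conflict-driven clause-learning (CDCL) satisfiability solver.
//
// A complete solver in the MiniSat lineage: two-literal watches, first-UIP
// conflict analysis, VSIDS-style variable activities with phase saving,
// Luby restarts, learned-clause database reduction, solving under
// assumptions, and incremental clause addition between solve calls.
// Assumptions are what make the support-set enumeration ansatz cheap:
// temporary exclusion clauses are passed as assumed unit literals instead
// of mutating the formula.
//
// Literal encoding: external literals are +v / -v (v >= 1); internally a
// literal is 2*(v-1) + (negative ? 1 : 0).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdlib>
#include <cmath>

namespace {

typedef int Lit;   // internal literal code
typedef int Var;   // 0-based variable index

inline Lit mklit(Var v, bool neg) { return 2 * v + (neg ? 1 : 0); }
inline Lit neglit(Lit l) { return l ^ 1; }
inline Var litvar(Lit l) { return l >> 1; }
inline bool litsign(Lit l) { return l & 1; }  // true = negated

const int VAL_UNDEF = -1;

struct Clause {
  std::vector<Lit> lits;
  bool learnt;
  bool deleted;
  double activity;
  Clause() : learnt(false), deleted(false), activity(0.0) {}
};

class Solver {
public:
  int nvars;
  bool ok;                       // false once the formula is globally UNSAT
  std::vector<Clause> clauses;   // problem + learnt clauses
  std::vector<int> n_problem_clauses_idx;  // indices of problem clauses (for model check)
  std::vector<std::vector<int> > watches;  // watches[lit] -> clause indices
  std::vector<signed char> assigns;        // per var: VAL_UNDEF/0/1
  std::vector<signed char> polarity;       // saved phase, 1 = last true
  std::vector<int> level;                  // decision level per var
  std::vector<int> reason;                 // clause index or -1
  std::vector<double> activity;
  std::vector<Lit> trail;
  std::vector<int> trail_lim;
  std::priority_queue<std::pair<double, Var> > order;  // lazy activity queue
  std::vector<signed char> seen;
  double var_inc;
  double cla_inc;
  long long n_conflicts_total;
  int n_learnt;

  explicit Solver(int n) : nvars(0), ok(true), var_inc(1.0), cla_inc(1.0),
                           n_conflicts_total(0), n_learnt(0) {
    grow(n);
  }

  void grow(int n_new) {
    for (int i = nvars; i < n_new; ++i) {
      assigns.push_back(VAL_UNDEF);
      polarity.push_back(0);
      level.push_back(0);
      reason.push_back(-1);
      activity.push_back(0.0);
      seen.push_back(0);
      watches.push_back(std::vector<int>());
      watches.push_back(std::vector<int>());
      order.push(std::make_pair(0.0, i));
    }
    nvars = n_new;
  }

  int decision_level() const { return (int)trail_lim.size(); }

  int value_var(Var v) const { return assigns[v]; }
  int value_lit(Lit l) const {
    signed char a = assigns[litvar(l)];
    if (a == VAL_UNDEF) return VAL_UNDEF;
    return litsign(l) ? 1 - a : a;
  }

  void var_bump(Var v) {
    activity[v] += var_inc;
    if (activity[v] > 1e100) {
      for (int i = 0; i < nvars; ++i) activity[i] *= 1e-100;
      var_inc *= 1e-100;
    }
    order.push(std::make_pair(activity[v], v));
  }
  void var_decay() { var_inc *= (1.0 / 0.95); }

  void cla_bump(Clause &c) {
    c.activity += cla_inc;
    if (c.activity > 1e20) {
      for (size_t i = 0; i < clauses.size(); ++i)
        if (clauses[i].learnt) clauses[i].activity *= 1e-20;
      cla_inc *= 1e-20;
    }
  }
  void cla_decay() { cla_inc *= (1.0 / 0.999); }

  void unchecked_enqueue(Lit p, int from) {
    Var v = litvar(p);
    assigns[v] = litsign(p) ? 0 : 1;
    level[v] = decision_level();
    reason[v] = from;
    trail.push_back(p);
  }

  void new_decision_level() { trail_lim.push_back((int)trail.size()); }

  void backtrack(int lvl) {
    if (decision_level() <= lvl) return;
    int lim = trail_lim[lvl];
    for (int i = (int)trail.size() - 1; i >= lim; --i) {
      Var v = litvar(trail[i]);
      polarity[v] = assigns[v];
      assigns[v] = VAL_UNDEF;
      reason[v] = -1;
      order.push(std::make_pair(activity[v], v));
    }
    trail.resize(lim);
    trail_lim.resize(lvl);
    qhead = lim;
  }

  int qhead = 0;

  // returns conflicting clause index or -1
  int propagate() {
    while (qhead < (int)trail.size()) {
      Lit p = trail[qhead++];
      Lit fl = neglit(p);  // literal that just became false
      std::vector<int> &ws = watches[fl];
      size_t i = 0, j = 0;
      while (i < ws.size()) {
        int ci = ws[i];
        Clause &c = clauses[ci];
        if (c.deleted) { ++i; continue; }  // lazily dropped
        std::vector<Lit> &ls = c.lits;
        if (ls[0] == fl) std::swap(ls[0], ls[1]);
        // invariant now: ls[1] == fl
        Lit first = ls[0];
        if (value_lit(first) == 1) { ws[j++] = ws[i++]; continue; }
        bool moved = false;
        for (size_t k = 2; k < ls.size(); ++k) {
          if (value_lit(ls[k]) != 0) {
            std::swap(ls[1], ls[k]);
            watches[ls[1]].push_back(ci);
            moved = true;
            break;
          }
        }
        if (moved) { ++i; continue; }
        ws[j++] = ws[i++];
        if (value_lit(first) == 0) {
          while (i < ws.size()) ws[j++] = ws[i++];
          ws.resize(j);
          qhead = (int)trail.size();
          return ci;
        }
        unchecked_enqueue(first, ci);
      }
      ws.resize(j);
    }
    return -1;
  }

  // First-UIP learning. Fills out_learnt (out_learnt[0] = asserting lit)
  // and returns the backtrack level.
  int analyze(int confl, std::vector<Lit> &out_learnt) {
    out_learnt.clear();
    out_learnt.push_back(-1);  // placeholder for asserting literal
    int pathC = 0;
    Lit p = -1;
    int index = (int)trail.size() - 1;
    int cur = decision_level();
    do {
      Clause &c = clauses[confl];
      if (c.learnt) cla_bump(c);
      for (size_t j = (p == -1 ? 0 : 1); j < c.lits.size(); ++j) {
        Lit q = c.lits[j];
        Var v = litvar(q);
        if (!seen[v] && level[v] > 0) {
          seen[v] = 1;
          var_bump(v);
          if (level[v] >= cur) ++pathC;
          else out_learnt.push_back(q);
        }
      }
      while (!seen[litvar(trail[index--])]) {}
      p = trail[index + 1];
      confl = reason[litvar(p)];
      seen[litvar(p)] = 0;
      --pathC;
    } while (pathC > 0);
    out_learnt[0] = neglit(p);

    int bt = 0;
    if (out_learnt.size() > 1) {
      size_t maxi = 1;
      for (size_t i = 2; i < out_learnt.size(); ++i)
        if (level[litvar(out_learnt[i])] > level[litvar(out_learnt[maxi])]) maxi = i;
      std::swap(out_learnt[1], out_learnt[maxi]);
      bt = level[litvar(out_learnt[1])];
    }
    for (size_t i = 0; i < out_learnt.size(); ++i) seen[litvar(out_learnt[i])] = 0;
    return bt;
  }

  void attach(int ci) {
    Clause &c = clauses[ci];
    watches[c.lits[0]].push_back(ci);
    watches[c.lits[1]].push_back(ci);
  }

  // Add a problem clause (external literal form); call at level 0 only.
  bool add_clause_external(const std::vector<int> &ext) {
    backtrack(0);
    if (!ok) return false;
    std::vector<Lit> ls;
    ls.reserve(ext.size());
    for (size_t i = 0; i < ext.size(); ++i) {
      int e = ext[i];
      Var v = std::abs(e) - 1;
      if (v >= nvars) grow(v + 1);
      Lit l = mklit(v, e < 0);
      int val = value_lit(l);
      if (val == 1) return true;      // satisfied at level 0
      if (val == 0) continue;         // falsified at level 0: drop literal
      bool dup = false, taut = false;
      for (size_t k = 0; k < ls.size(); ++k) {
        if (ls[k] == l) { dup = true; break; }
        if (ls[k] == neglit(l)) { taut = true; break; }
      }
      if (taut) return true;
      if (!dup) ls.push_back(l);
    }
    if (ls.empty()) { ok = false; return false; }
    if (ls.size() == 1) {
      unchecked_enqueue(ls[0], -1);
      if (propagate() != -1) { ok = false; return false; }
      return true;
    }
    Clause c;
    c.lits = ls;
    clauses.push_back(c);
    int ci = (int)clauses.size() - 1;
    n_problem_clauses_idx.push_back(ci);
    attach(ci);
    return true;
  }

  Lit pick_branch() {
    while (!order.empty()) {
      Var v = order.top().second;
      order.pop();
      if (assigns[v] == VAL_UNDEF)
        return mklit(v, polarity[v] != 1);  // saved phase (default false)
    }
    return -1;
  }

  void reduce_db() {
    // keep the more active half of learnt clauses; called at level 0 only
    std::vector<std::pair<double, int> > ls;
    for (size_t i = 0; i < clauses.size(); ++i)
      if (clauses[i].learnt && !clauses[i].deleted)
        ls.push_back(std::make_pair(clauses[i].activity, (int)i));
    if (ls.size() < 2) return;
    std::sort(ls.begin(), ls.end());
    size_t half = ls.size() / 2;
    for (size_t i = 0; i < half; ++i) {
      Clause &c = clauses[ls[i].second];
      if (c.lits.size() <= 2) continue;  // keep short clauses
      c.deleted = true;
      std::vector<Lit>().swap(c.lits);
      --n_learnt;
    }
  }

  static long long luby(long long i) {
    // Luby restart sequence 1 1 2 1 1 2 4 ...
    long long k = 1;
    while ((1LL << k) - 1 < i + 1) ++k;
    while ((1LL << k) - 1 != i + 1) {
      --k;
      i = i - ((1LL << k) - 1);
    }
    return 1LL << (k - 1);
  }

  // status: 1 SAT, 0 UNSAT (possibly under assumptions), -1 conflict budget hit
  int solve(const std::vector<Lit> &assumps, long long max_conflicts) {
    backtrack(0);
    if (!ok) return 0;
    if (propagate() != -1) { ok = false; return 0; }
    long long conflicts = 0;
    long long restart_no = 0;
    long long restart_lim = 64 * luby(restart_no);
    long long restart_cnt = 0;
    long long learnt_cap = 4000 + (long long)n_problem_clauses_idx.size();
    std::vector<Lit> learnt;
    for (;;) {
      int confl = propagate();
      if (confl != -1) {
        ++conflicts; ++restart_cnt; ++n_conflicts_total;
        if (decision_level() == 0) { ok = false; return 0; }
        int bt = analyze(confl, learnt);
        backtrack(bt);
        if (learnt.size() == 1) {
          unchecked_enqueue(learnt[0], -1);
        } else {
          Clause c;
          c.lits = learnt;
          c.learnt = true;
          c.activity = cla_inc;
          clauses.push_back(c);
          int ci = (int)clauses.size() - 1;
          attach(ci);
          ++n_learnt;
          unchecked_enqueue(learnt[0], ci);
        }
        var_decay();
        cla_decay();
        if (max_conflicts >= 0 && conflicts >= max_conflicts) {
          backtrack(0);
          return -1;
        }
      } else {
        if (restart_cnt >= restart_lim) {
          restart_cnt = 0;
          restart_lim = 64 * luby(++restart_no);
          backtrack(0);
          if (n_learnt > learnt_cap) reduce_db();
          continue;
        }
        Lit next = -1;
        bool assump_block = false;
        while (decision_level() < (int)assumps.size()) {
          Lit p = assumps[decision_level()];
          int val = value_lit(p);
          if (val == 1) {
            new_decision_level();  // already implied: dummy level
          } else if (val == 0) {
            return 0;  // assumptions inconsistent with formula
          } else {
            next = p;
            assump_block = true;
            break;
          }
        }
        if (next == -1 && !assump_block) next = pick_branch();
        if (next == -1) return 1;  // all variables assigned: model found
        new_decision_level();
        unchecked_enqueue(next, -1);
      }
    }
  }

  // re-evaluate every problem clause under the current full assignment
  bool verify_model() const {
    for (size_t i = 0; i < n_problem_clauses_idx.size(); ++i) {
      const Clause &c = clauses[n_problem_clauses_idx[i]];
      bool sat = false;
      for (size_t j = 0; j < c.lits.size(); ++j)
        if (value_lit(c.lits[j]) == 1) { sat = true; break; }
      if (!sat) return false;
    }
    return true;
  }
};

}  // namespace

using namespace Rcpp;

// ---- clause buffer: O(1) clause accumulation on the C++ side ------------

struct ClauseBuffer {
  std::vector<int> flat;   // literals, clauses separated by 0
  int n;
  ClauseBuffer() : n(0) {}
};

// [[Rcpp::export(name = ".cbuf_new")]]
SEXP cbuf_new() {
  XPtr<ClauseBuffer> p(new ClauseBuffer(), true);
  return p;
}

// [[Rcpp::export(name = ".cbuf_push")]]
void cbuf_push(SEXP ptr, IntegerVector lits) {
  XPtr<ClauseBuffer> b(ptr);
  b->flat.insert(b->flat.end(), lits.begin(), lits.end());
  b->flat.push_back(0);
  ++(b->n);
}

// [[Rcpp::export(name = ".cbuf_size")]]
int cbuf_size(SEXP ptr) {
  XPtr<ClauseBuffer> b(ptr);
  return b->n;
}

// [[Rcpp::export(name = ".cbuf_as_list")]]
List cbuf_as_list(SEXP ptr) {
  XPtr<ClauseBuffer> b(ptr);
  List out(b->n);
  std::vector<int> cur;
  int k = 0;
  for (size_t i = 0; i < b->flat.size(); ++i) {
    if (b->flat[i] == 0) {
      out[k++] = IntegerVector(cur.begin(), cur.end());
      cur.clear();
    } else cur.push_back(b->flat[i]);
  }
  return out;
}

// [[Rcpp::export(name = ".sat_new")]]
SEXP sat_new(int nvars) {
  XPtr<Solver> p(new Solver(nvars), true);
  return p;
}

// [[Rcpp::export(name = ".sat_add_buffer")]]
bool sat_add_buffer(SEXP ptr, SEXP bufptr) {
  XPtr<Solver> s(ptr);
  XPtr<ClauseBuffer> b(bufptr);
  std::vector<int> cur;
  bool ok = true;
  for (size_t i = 0; i < b->flat.size(); ++i) {
    if (b->flat[i] == 0) {
      ok = s->add_clause_external(cur) && ok;
      cur.clear();
    } else cur.push_back(b->flat[i]);
  }
  return ok;
}

// [[Rcpp::export(name = ".sat_add_clause")]]
bool sat_add_clause(SEXP ptr, IntegerVector lits) {
  XPtr<Solver> s(ptr);
  std::vector<int> v(lits.begin(), lits.end());
  return s->add_clause_external(v);
}

// [[Rcpp::export(name = ".sat_new_var")]]
int sat_new_var(SEXP ptr) {
  XPtr<Solver> s(ptr);
  s->grow(s->nvars + 1);
  return s->nvars;
}

// [[Rcpp::export(name = ".sat_nvars")]]
int sat_nvars(SEXP ptr) {
  XPtr<Solver> s(ptr);
  return s->nvars;
}

// [[Rcpp::export(name = ".sat_okay")]]
bool sat_okay(SEXP ptr) {
  XPtr<Solver> s(ptr);
  return s->ok;
}

// [[Rcpp::export(name = ".sat_solve")]]
List sat_solve(SEXP ptr, IntegerVector assumptions, double max_conflicts) {
  XPtr<Solver> s(ptr);
  std::vector<int> as;
  as.reserve(assumptions.size());
  for (int i = 0; i < assumptions.size(); ++i) {
    int e = assumptions[i];
    int v = std::abs(e) - 1;
    if (v >= s->nvars) s->grow(v + 1);
    as.push_back(mklit(v, e < 0));
  }
  long long budget = (max_conflicts < 0) ? -1 : (long long)max_conflicts;
  int st = s->solve(as, budget);
  if (st == 1) {
    if (!s->verify_model())
      stop("internal error: solver returned a model violating a clause");
    IntegerVector model(s->nvars);
    for (int v = 0; v < s->nvars; ++v) model[v] = s->assigns[v] == 1 ? 1 : 0;
    s->backtrack(0);
    return List::create(_["status"] = "sat", _["model"] = model);
  }
  s->backtrack(0);
  return List::create(
      _["status"] = (st == 0) ? "unsat" : "undetermined",
      _["model"] = R_NilValue);
}
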