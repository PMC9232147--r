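#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Iterative DPLL with unit propagation and chronological backtracking.
// Literals use DIMACS convention: +v / -v, variables 1..nvars. Instances
// produced by the bounded unfolding are small (hundreds to a few thousand
// variables) and almost fully determined by propagation once the boundary
// places at step 0 are decided, so a lean solver with deterministic
// branching (caller-supplied variable order, FALSE tried first) is both
// sufficient and reproducible.

// [[Rcpp::export(name = ".sat_solve_cpp")]]
List sat_solve_cpp(int nvars, List clauses_, IntegerVector assumptions,
                   IntegerVector var_order) {
  size_t nc = clauses_.size();
  std::vector< std::vector<int> > clauses(nc);
  for (size_t i = 0; i < nc; ++i) {
    IntegerVector cl = clauses_[i];
    if (cl.size() == 0) {
      return List::create(_["sat"] = false, _["model"] = R_NilValue);
    }
    clauses[i].assign(cl.begin(), cl.end());
    for (int lit : clauses[i]) {
      int v = std::abs(lit);
      if (v < 1 || v > nvars) stop("literal out of range: %d", lit);
    }
  }

  std::vector<signed char> val(nvars + 1, 0);
  std::vector<int> trail;
  trail.reserve(nvars);

  // occurrence lists: clauses containing each literal's negation are the
  // ones that can become unit/false when that literal is falsified; we use
  // a simple full-scan fixpoint instead (instances are tiny).
  auto assign = [&](int lit) {
    int v = std::abs(lit);
    val[v] = lit > 0 ? 1 : -1;
    trail.push_back(v);
  };
  auto undoTo = [&](size_t n) {
    while (trail.size() > n) {
      val[trail.back()] = 0;
      trail.pop_back();
    }
  };
  auto propagate = [&]() -> bool {
    bool changed = true;
    while (changed) {
      changed = false;
      for (size_t i = 0; i < nc; ++i) {
        const std::vector<int> &c = clauses[i];
        int nfree = 0, freeLit = 0;
        bool satisfied = false;
        for (int lit : c) {
          signed char s = val[std::abs(lit)];
          if (s == 0) {
            if (++nfree > 1) break;  // not unit, not false
            freeLit = lit;
          } else if ((s == 1) == (lit > 0)) {
            satisfied = true;
            break;
          }
        }
        if (satisfied || nfree > 1) continue;
        if (nfree == 0) return false;  // conflict
        assign(freeLit);
        changed = true;
      }
    }
    return true;
  };

  for (int lit : assumptions) {
    int v = std::abs(lit);
    if (v < 1 || v > nvars) stop("assumption literal out of range: %d", lit);
    signed char want = lit > 0 ? 1 : -1;
    if (val[v] == 0) assign(lit);
    else if (val[v] != want)
      return List::create(_["sat"] = false, _["model"] = R_NilValue);
  }
  if (!propagate())
    return List::create(_["sat"] = false, _["model"] = R_NilValue);

  // branch order: caller-specified variables first, then ascending index
  std::vector<int> order;
  order.reserve(nvars);
  std::vector<bool> seen(nvars + 1, false);
  for (int v : var_order) {
    if (v >= 1 && v <= nvars && !seen[v]) { order.push_back(v); seen[v] = true; }
  }
  for (int v = 1; v <= nvars; ++v)
    if (!seen[v]) order.push_back(v);

  struct Frame { int var; bool triedTrue; size_t trailSize; };
  std::vector<Frame> stack;

  for (;;) {
    int branch = 0;
    for (int v : order) if (val[v] == 0) { branch = v; break; }
    if (branch == 0) {  // all assigned, no conflict: SAT
      LogicalVector model(nvars);
      for (int v = 1; v <= nvars; ++v) model[v - 1] = val[v] == 1;
      return List::create(_["sat"] = true, _["model"] = model);
    }
    stack.push_back(Frame{branch, false, trail.size()});
    assign(-branch);  // FALSE first: favours small activation sets
    while (!propagate()) {
      while (!stack.empty() && stack.back().triedTrue) {
        undoTo(stack.back().trailSize);
        stack.pop_back();
      }
      if (stack.empty())
        return List::create(_["sat"] = false, _["model"] = R_NilValue);
      Frame &f = stack.back();
      undoTo(f.trailSize);
      f.triedTrue = true;
      assign(f.var);
    }
  }
}
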