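#include <Rcpp.h>
using namespace Rcpp;

// One competition sweep of the cellular automaton.
//
// Cells listed in `order` (0-based indices into the grid vectors) are
// visited sequentially. A cell whose current class is over-allocated
// (gap[cur] < 0, with gap = demand - allocated kept live during the sweep)
// competes for a new class: by roulette wheel (rule = 0) or argmax
// (rule = 1) over the combined probability
//   TProb[p] = sp(cell, p) * omega(cell, p) * inertia[p] * allow(current, p)
// restricted to classes whose demand is not yet met (gap[p] > 0). Each
// executed move transfers one cell from a surplus class to a deficit class,
// so the total absolute gap never increases. A cell with no positive score
// among receivable classes keeps its class.
//
// With relax = 1 a surplus cell may also move into a class exactly at its
// demand: that leaves the maximum absolute gap non-increasing while opening
// two-step transfer chains when the allowance matrix forbids the direct
// surplus-to-deficit conversion.
//
// `sp` and `omega` are n_cell x K matrices over the full grid; `codes`
// holds 1-based class indices.
// [[Rcpp::export]]
List allocation_sweep(NumericMatrix sp, NumericMatrix omega,
                      NumericVector inertia, IntegerMatrix allow,
                      IntegerVector codes, IntegerVector order,
                      IntegerVector gap, NumericVector u, int rule,
                      int relax) {
  int K = sp.ncol();
  IntegerVector newcodes = clone(codes);
  IntegerVector D = clone(gap);
  std::vector<double> tp(K);
  int moves = 0;

  for (int ii = 0; ii < order.size(); ++ii) {
    int cell = order[ii];
    int cur = newcodes[cell] - 1;
    if (D[cur] >= 0) continue;  // class not over-allocated: cell keeps it
    double tot = 0.0;
    for (int p = 0; p < K; ++p) {
      double v = 0.0;
      bool receivable = D[p] > 0 ||
        (relax == 1 && D[p] == 0 && p != cur);  // chain through balanced class
      if (receivable && allow(cur, p) == 1) {
        double s = sp(cell, p);
        double o = omega(cell, p);
        if (s > 0.0 && o > 0.0)
          v = s * o * inertia[p];
      }
      tp[p] = v;
      tot += v;
    }
    if (tot <= 0.0) continue;
    int chosen = -1;
    if (rule == 1) {
      double best = -1.0;
      for (int p = 0; p < K; ++p)
        if (tp[p] > best) { best = tp[p]; chosen = p; }
    } else {
      double target = u[ii] * tot, acc = 0.0;
      for (int p = 0; p < K; ++p) {
        acc += tp[p];
        if (acc >= target) { chosen = p; break; }
      }
      if (chosen < 0) chosen = K - 1;  // numeric guard
    }
    newcodes[cell] = chosen + 1;
    D[chosen] -= 1;
    D[cur] += 1;
    ++moves;
  }
  return List::create(_["codes"] = newcodes, _["gap"] = D,
                      _["moves"] = moves);
}
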