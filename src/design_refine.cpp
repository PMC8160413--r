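// Greedy pairwise-swap refinement of a choice design's slot matrix.
// M is (task x alternative) slots by attribute, level indices 1..L[a],
// 0 = attribute not shown; alternatives vary fastest within a task.
// Swaps exchange two slots of the same attribute (preserving level
// balance); a swap is kept when the weighted score (duplicate
// alternatives >> within-task overlap >> co-occurrence imbalance) does
// not get worse. Uses R's RNG for reproducibility under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static inline int ru(int n) { // uniform integer in [0, n)
  int k = (int)(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export(name = ".refine_design_cpp")]]
IntegerMatrix refine_design_cpp(IntegerMatrix M_, int n_tasks, int n_alts,
                                IntegerVector L, int n_sweeps) {
  IntegerMatrix M(clone(M_));
  const int n_attr = M.ncol();
  const int n_slots = n_tasks * n_alts;

  // profile hash per slot (double: exact for the integer magnitudes here)
  std::vector<double> pw(n_attr, 1.0);
  for (int a = 1; a < n_attr; ++a) pw[a] = pw[a - 1] * (L[a - 1] + 1);
  std::vector<double> h(n_slots, 0.0);
  for (int s = 0; s < n_slots; ++s)
    for (int a = 0; a < n_attr; ++a) h[s] += M(s, a) * pw[a];

  // co-occurrence counts per attribute pair (a < b)
  std::vector<std::vector<int>> counts(n_attr * n_attr);
  for (int a = 0; a < n_attr - 1; ++a)
    for (int b = a + 1; b < n_attr; ++b) {
      std::vector<int>& cv = counts[a * n_attr + b];
      cv.assign(L[a] * L[b], 0);
      for (int s = 0; s < n_slots; ++s)
        if (M(s, a) > 0 && M(s, b) > 0)
          cv[(M(s, a) - 1) * L[b] + M(s, b) - 1] += 1;
    }

  // candidate slots per attribute (the shown pattern never changes)
  std::vector<std::vector<int>> cand(n_attr);
  for (int a = 0; a < n_attr; ++a)
    for (int s = 0; s < n_slots; ++s)
      if (M(s, a) > 0) cand[a].push_back(s);

  auto dup_task = [&](int t) {
    int d = 0;
    for (int i = 0; i < n_alts; ++i)
      for (int j = i + 1; j < n_alts; ++j)
        if (h[t * n_alts + i] == h[t * n_alts + j]) { ++d; break; }
    return d;
  };
  auto ov_cell = [&](int t, int a) {
    int v0 = M(t * n_alts, a);
    if (v0 == 0) return 0;
    for (int i = 1; i < n_alts; ++i)
      if (M(t * n_alts + i, a) != v0) return 0;
    return 1;
  };

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    int a = ru(n_attr);
    int nc = (int)cand[a].size();
    if (nc < 2) continue;
    int i1 = ru(nc), i2 = ru(nc - 1);
    if (i2 >= i1) ++i2;
    int s1 = cand[a][i1], s2 = cand[a][i2];
    int v1 = M(s1, a), v2 = M(s2, a);
    if (v1 == v2) continue;
    int t1 = s1 / n_alts, t2 = s2 / n_alts;

    int old_dup = dup_task(t1) + (t2 != t1 ? dup_task(t2) : 0);
    int old_ov = ov_cell(t1, a) + (t2 != t1 ? ov_cell(t2, a) : 0);

    double delta_ss = 0.0;
    // apply co-occurrence updates, log them for undo
    std::vector<std::array<int, 3>> undo; // {pair key, old cell, new cell}
    for (int b = 0; b < n_attr; ++b) {
      if (b == a) continue;
      int k = (std::min(a, b)) * n_attr + std::max(a, b);
      std::vector<int>& cv = counts[k];
      const int ss[2] = {s1, s2};
      const int vold[2] = {v1, v2}, vnew[2] = {v2, v1};
      for (int j = 0; j < 2; ++j) {
        int w = M(ss[j], b);
        if (w == 0) continue;
        int ko, kn;
        if (a < b) {
          ko = (vold[j] - 1) * L[b] + w - 1;
          kn = (vnew[j] - 1) * L[b] + w - 1;
        } else {
          ko = (w - 1) * L[a] + vold[j] - 1;
          kn = (w - 1) * L[a] + vnew[j] - 1;
        }
        delta_ss += (-2.0 * cv[ko] + 1.0) + (2.0 * cv[kn] + 1.0);
        cv[ko] -= 1; cv[kn] += 1;
        undo.push_back({k, ko, kn});
      }
    }

    M(s1, a) = v2; M(s2, a) = v1;
    h[s1] += (v2 - v1) * pw[a];
    h[s2] += (v1 - v2) * pw[a];
    int new_dup = dup_task(t1) + (t2 != t1 ? dup_task(t2) : 0);
    int new_ov = ov_cell(t1, a) + (t2 != t1 ? ov_cell(t2, a) : 0);

    double delta = 1e6 * (new_dup - old_dup) + 10.0 * (new_ov - old_ov) + delta_ss;
    if (delta > 0) { // revert
      M(s1, a) = v1; M(s2, a) = v2;
      h[s1] += (v1 - v2) * pw[a];
      h[s2] += (v2 - v1) * pw[a];
      for (auto it = undo.rbegin(); it != undo.rend(); ++it) {
        counts[(*it)[0]][(*it)[1]] += 1;
        counts[(*it)[0]][(*it)[2]] -= 1;
      }
    }
  }
  return M;
}
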