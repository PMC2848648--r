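// Dynamic-programming engine for gene tiling.
//
// Nodes are candidate gene boundaries sorted by forward coordinate:
//   type 0 = forward start (5'F, gene left edge)
//   type 1 = forward stop  (3'F, gene right edge)
//   type 2 = reverse stop  (3'R, gene left edge)
//   type 3 = reverse start (5'R, gene right edge)
// Connections follow the nine legal pairings: gene (5'F->3'F, 3'R->5'R),
// intergenic (3'F->5'F, 3'F->3'R, 5'R->3'R, 5'R->5'F), same-strand overlap
// (3'F->3'F, 3'R->3'R, second gene's 5' implied, overlap <= 60 bp) and
// opposite-strand 3' overlap (3'F->5'R, second gene's 3' implied, overlap
// <= 200 bp, 5' ends may not overlap).
//
// Forward-stop nodes keep one DP state per incoming gene (keyed by that
// gene's 5' position) so the no-5'-overlap rule of the opposite-strand
// connection is enforced exactly.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Conn {
  int lnode;
  int gene;
  int kind;  // 0 gene, 1 fwd-fwd overlap, 2 rev-rev overlap, 3 opposite overlap
};

struct Entry {  // gene-bearing arrival at a forward-stop node
  int start;    // 5' (left edge) of the arriving gene
  double val;
  int prev;
  int gene;
  bool waived;
};

// [[Rcpp::export]]
List dp_engine_cpp(IntegerVector n_coord, IntegerVector n_type,
                   IntegerVector g_lnode, IntegerVector g_rnode,
                   IntegerVector g_left, IntegerVector g_right,
                   LogicalVector g_fwd,
                   NumericVector g_score, NumericVector g_score_w,
                   LogicalVector g_waiver_ok,
                   bool final_pass,
                   int max_gap, int bonus_dist, int penalty_dist,
                   double bonus, double penalty,
                   int sso_max, int opp_max) {
  const int n = n_coord.size();
  const int ng = g_lnode.size();

  auto dmod = [&](int gap) -> double {
    if (gap < bonus_dist) return bonus;
    if (gap > penalty_dist) return -penalty;
    return 0.0;
  };

  // nodes of each type, in index (= coordinate) order
  std::vector<std::vector<int>> by_type(4);
  for (int i = 0; i < n; i++) by_type[n_type[i]].push_back(i);
  std::vector<std::vector<int>> coord_by_type(4);
  for (int t = 0; t < 4; t++) {
    coord_by_type[t].reserve(by_type[t].size());
    for (int i : by_type[t]) coord_by_type[t].push_back(n_coord[i]);
  }
  auto nodes_in = [&](int t, int lo, int hi, std::vector<int> &out) {
    const std::vector<int> &cv = coord_by_type[t];
    const std::vector<int> &iv = by_type[t];
    size_t a = std::lower_bound(cv.begin(), cv.end(), lo) - cv.begin();
    for (size_t k = a; k < cv.size() && cv[k] <= hi; k++) out.push_back(iv[k]);
  };

  // incoming gene-bearing connections grouped by right node
  std::vector<std::vector<Conn>> incoming(n);
  std::vector<int> buf;
  for (int g = 0; g < ng; g++) {
    incoming[g_rnode[g]].push_back({g_lnode[g], g, 0});
    if (g_fwd[g]) {
      buf.clear();
      nodes_in(1, g_left[g], std::min(g_left[g] + sso_max - 1, g_right[g] - 1), buf);
      for (int u : buf) incoming[g_rnode[g]].push_back({u, g, 1});
      buf.clear();
      // this gene as first gene of an opposite-strand pair is handled from
      // the reverse gene's side below
    } else {
      // rev-rev overlap: this gene connects from its own 3' to a later 3'R
      buf.clear();
      nodes_in(2, std::max(g_left[g] + 1, g_right[g] - sso_max + 1), g_right[g], buf);
      for (int u : buf) if (u != g_lnode[g]) incoming[u].push_back({g_lnode[g], g, 2});
      // opposite-strand overlap: forward 3' inside this gene's 5'-distal part
      buf.clear();
      nodes_in(1, g_left[g], std::min(g_left[g] + opp_max - 1, g_right[g] - 1), buf);
      for (int u : buf) incoming[g_rnode[g]].push_back({u, g, 3});
    }
  }

  std::vector<double> val(n, 0.0);
  std::vector<int> bprev(n, -1), bgene(n, -1), bentry(n, -1);
  std::vector<char> bwaived(n, 0);
  std::vector<std::vector<Entry>> entries(n);  // only for type-1 nodes

  for (int j = 0; j < n; j++) {
    double best = 0.0;
    int pbest = -1, gbest = -1, ebest = -1;
    bool wbest = false;
    for (const Conn &c : incoming[j]) {
      int g = c.gene;
      double sc = g_score[g];
      bool waived = false;
      double cand;
      if (c.kind == 0) {
        cand = val[c.lnode] + sc;
      } else if (c.kind == 1 || c.kind == 2) {
        // overlap connections carry the second gene's score only
        int ovl = (c.kind == 1) ? (n_coord[c.lnode] - g_left[g] + 1)
                                : (g_right[g] - n_coord[j] + 1);
        if (final_pass && g_waiver_ok[g] && (ovl == 1 || ovl == 4)) {
          sc = g_score_w[g];
          waived = true;
        }
        cand = val[c.lnode] + sc;
      } else {  // opposite-strand overlap; need left gene's 5' < this gene's 3'
        double base = 0.0;  // virtual bare state at the forward stop
        int ent = -2;
        const std::vector<Entry> &es = entries[c.lnode];
        for (size_t k = 0; k < es.size(); k++) {
          if (es[k].start < g_left[g] && es[k].val > base) {
            base = es[k].val;
            ent = (int)k;
          }
        }
        cand = base + sc;
        if (cand > best) {
          best = cand; pbest = c.lnode; gbest = g; ebest = ent; wbest = false;
        }
        continue;
      }
      if (n_type[j] == 1) entries[j].push_back({g_left[g], cand, c.lnode, g, waived});
      if (cand > best) {
        best = cand; pbest = c.lnode; gbest = g; ebest = -1; wbest = waived;
      }
    }
    // intergenic connections into forward starts and reverse stops
    if (n_type[j] == 0 || n_type[j] == 2) {
      bool found = false;
      int i = j - 1;
      for (; i >= 0; i--) {
        if (n_coord[i] >= n_coord[j]) continue;
        int gap = n_coord[j] - n_coord[i] - 1;
        if (gap > max_gap) break;
        int t = n_type[i];
        if (t == 1 || t == 3) {
          found = true;
          double cand = val[i] + dmod(gap);
          if (cand > best) { best = cand; pbest = i; gbest = -1; ebest = -1; wbest = false; }
        }
      }
      if (!found) {
        // no allowed predecessor within the window: connect to the nearest
        // one beyond it so a sparse region cannot sever the path
        for (; i >= 0; i--) {
          int t = n_type[i];
          if ((t == 1 || t == 3) && n_coord[i] < n_coord[j]) {
            double cand = val[i] + dmod(n_coord[j] - n_coord[i] - 1);
            if (cand > best) { best = cand; pbest = i; gbest = -1; ebest = -1; wbest = false; }
            break;
          }
        }
      }
    }
    val[j] = best;
    bprev[j] = pbest; bgene[j] = gbest; bentry[j] = ebest; bwaived[j] = wbest;
  }

  // best path end
  int jbest = 0;
  for (int j = 1; j < n; j++) if (val[j] > val[jbest]) jbest = j;

  // traceback
  std::vector<int> sel;
  std::vector<char> selw;
  int cur = jbest;
  int use_entry = -1;
  while (cur >= 0) {
    int prev, gene, entry;
    bool waived;
    if (use_entry >= 0) {
      const Entry &e = entries[cur][use_entry];
      prev = e.prev; gene = e.gene; waived = e.waived; entry = -1;
    } else if (use_entry == -2) {
      break;  // path started bare at this node
    } else {
      prev = bprev[cur]; gene = bgene[cur]; waived = bwaived[cur]; entry = bentry[cur];
    }
    if (gene >= 0) { sel.push_back(gene + 1); selw.push_back(waived); }
    if (prev < 0) break;
    use_entry = entry;  // -1 normal, >=0 entry of prev, -2 virtual start at prev
    cur = prev;
  }
  std::reverse(sel.begin(), sel.end());
  std::reverse(selw.begin(), selw.end());

  return List::create(_["genes"] = IntegerVector(sel.begin(), sel.end()),
                      _["waived"] = LogicalVector(selw.begin(), selw.end()),
                      _["total"] = val[jbest],
                      _["val"] = NumericVector(val.begin(), val.end()),
                      _["prev"] = IntegerVector(bprev.begin(), bprev.end()));
}
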