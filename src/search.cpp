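// Exhaustive attainment search for strictly simple profiles.
//
// State-space quotient of single-leaf binary network enumeration: a state
// is the multiset of root-to-arc path counts of the currently open arcs.
// Moves: duplicate one open count c -> {c, c} (tree vertex, free) or merge
// two open counts c1, c2 -> {c1 + c2} (hybrid vertex, cost 1; c1 = c2 on
// the same tail is a bead).  Start {1, 1}, target {m}.  Iterative
// deepening on the hybrid count with memoization of failed
// (state, merges-remaining) pairs; the memo is depth-independent because
// "remaining" is measured from the current node, so it is kept across
// deepening iterations.
//
// Invariants used for pruning (sum = sum of open counts):
//   * sum is invariant under merges and grows under duplicates, and the
//     final state has sum m, so sum <= m always;
//   * size - 1 <= merges remaining (each merge shrinks the state by 1);
//   * max * 2^r >= m (a merge at most doubles the maximum);
//   * duplicates remaining = r - (size - 1) because every duplicate must
//     eventually be matched by a merge; a duplicate at most doubles sum,
//     so sum * 2^{dups remaining} >= m;
//   * once sum == m the state is feasible iff size - 1 <= r (merge
//     everything, in any order).

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <set>
#include <vector>
using namespace Rcpp;

typedef std::vector<int> State; // kept sorted ascending

static std::set<State> memo_fail;                 // key: state ++ {r}
static std::vector<std::array<int, 3>> moves_buf; // (type 0=dup/1=merge, a, b)

static State remove_two(const State& st, int a, int b) {
  State nxt;
  nxt.reserve(st.size() - 1);
  bool rm_a = false, rm_b = false;
  for (int v : st) {
    if (!rm_a && v == a) { rm_a = true; continue; }
    if (!rm_b && v == b) { rm_b = true; continue; }
    nxt.push_back(v);
  }
  int s2 = a + b;
  nxt.insert(std::lower_bound(nxt.begin(), nxt.end(), s2), s2);
  return nxt;
}

static bool dfs(const State& st, int r, int m) {
  const int k = (int)st.size();
  long sum = 0;
  for (int v : st) sum += v;
  if (k == 1 && st[0] == m) return true;
  if (sum > m) return false;
  if (k - 1 > r) return false;
  {
    long cap = st[k - 1];
    for (int i = 0; i < r && cap < m; ++i) cap <<= 1;
    if (cap < m) return false;
  }
  if (sum == m) {
    // only merges remain; combine the two largest repeatedly
    State cur = st;
    while (cur.size() > 1) {
      int a = cur[cur.size() - 1], b = cur[cur.size() - 2];
      cur.pop_back();
      cur.pop_back();
      int s2 = a + b;
      cur.insert(std::lower_bound(cur.begin(), cur.end(), s2), s2);
      moves_buf.push_back({1, a, b});
    }
    return true;
  }
  const int dRem = r - (k - 1);
  if (dRem <= 0) return false; // sum < m needs at least one more duplicate
  {
    long g = sum;
    for (int i = 0; i < dRem && g < m; ++i) g <<= 1;
    if (g < m) return false;
  }

  State key = st;
  key.push_back(r);
  if (memo_fail.count(key)) return false;

  // unique values, ascending, with multiplicities
  std::vector<int> uniq;
  std::vector<int> cnt;
  for (int v : st) {
    if (uniq.empty() || uniq.back() != v) {
      uniq.push_back(v);
      cnt.push_back(1);
    } else {
      ++cnt.back();
    }
  }
  const int u = (int)uniq.size();

  // merges over unique value pairs, larger pairs first
  for (int i = u - 1; i >= 0; --i) {
    for (int j = i; j >= 0; --j) {
      if (j == i && cnt[i] < 2) continue;
      long s2 = (long)uniq[i] + uniq[j];
      if (s2 > m) continue;
      moves_buf.push_back({1, uniq[i], uniq[j]});
      if (dfs(remove_two(st, uniq[i], uniq[j]), r - 1, m)) return true;
      moves_buf.pop_back();
    }
  }
  // duplicates over unique values, larger first
  for (int i = u - 1; i >= 0; --i) {
    int c = uniq[i];
    if (sum + c > m) continue;
    State nxt = st;
    nxt.insert(std::lower_bound(nxt.begin(), nxt.end(), c), c);
    moves_buf.push_back({0, c, 0});
    if (dfs(nxt, r, m)) return true;
    moves_buf.pop_back();
  }

  memo_fail.insert(key);
  return false;
}

// [[Rcpp::export]]
List cpp_min_hybrids(int m, int lb, int budget) {
  memo_fail.clear();
  List out = List::create(_["h"] = R_NilValue, _["moves"] = R_NilValue);
  for (int depth = lb; depth <= budget; ++depth) {
    moves_buf.clear();
    State start = {1, 1};
    if (dfs(start, depth, m)) {
      IntegerMatrix mv((int)moves_buf.size(), 3);
      for (int i = 0; i < (int)moves_buf.size(); ++i) {
        mv(i, 0) = moves_buf[i][0];
        mv(i, 1) = moves_buf[i][1];
        mv(i, 2) = moves_buf[i][2];
      }
      out = List::create(_["h"] = depth, _["moves"] = mv);
      break;
    }
  }
  memo_fail.clear();
  moves_buf.clear();
  return out;
}
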