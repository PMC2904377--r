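#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// All randomness flows through R's RNG (unif_rand) so that runs are fully
// reproducible from set.seed() on the R side, whether iterations are drawn
// one at a time or in bulk.

static inline int rand_int(int n) {
  // uniform integer on 0..n-1
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

static void shuffle_vec(std::vector<int> &v) {
  // Fisher-Yates
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = rand_int(i + 1);
    std::swap(v[i], v[j]);
  }
}

// Greedy clique growth: shuffle the node list once; the first unassigned
// node seeds a block and the remaining unassigned nodes are scanned in
// shuffled order, each added iff adjacent to every current member.  The
// outcome is a deterministic function of the shuffle.
static void uv_iter(const IntegerMatrix &A, std::vector<int> &assign) {
  const int n = A.nrow();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  shuffle_vec(ord);
  std::fill(assign.begin(), assign.end(), 0);
  std::vector<int> members;
  int block = 0;
  for (int s = 0; s < n; ++s) {
    const int seed = ord[s];
    if (assign[seed]) continue;
    ++block;
    assign[seed] = block;
    members.assign(1, seed);
    for (int t = s + 1; t < n; ++t) {
      const int u = ord[t];
      if (assign[u]) continue;
      bool ok = true;
      for (size_t k = 0; k < members.size(); ++k)
        if (!A(u, members[k])) { ok = false; break; }
      if (ok) {
        assign[u] = block;
        members.push_back(u);
      }
    }
  }
}

static bool blocks_mergeable(const IntegerMatrix &A,
                             const std::vector<int> &bi,
                             const std::vector<int> &bj) {
  // union is a clique iff every cross pair is adjacent (members of each
  // block are already mutually adjacent)
  for (size_t a = 0; a < bi.size(); ++a)
    for (size_t b = 0; b < bj.size(); ++b)
      if (!A(bi[a], bj[b])) return false;
  return true;
}

// Random clique merging, two phases.  Phase 1: pick two distinct blocks
// uniformly and merge when their union is a clique; after n consecutive
// failed picks (counter reset on every success) switch to phase 2: maintain
// a block-level mergeability matrix, pick a 1-entry uniformly, merge, update
// incrementally; stop when no 1-entry remains.
static void r_iter(const IntegerMatrix &A, std::vector<int> &assign) {
  const int n = A.nrow();
  std::vector<std::vector<int> > blocks(n);
  for (int i = 0; i < n; ++i) blocks[i].assign(1, i);
  int nb = n;
  int fails = 0;
  while (nb >= 2 && fails < n) {
    int i = rand_int(nb);
    int j = rand_int(nb - 1);
    if (j >= i) ++j;
    if (blocks_mergeable(A, blocks[i], blocks[j])) {
      blocks[i].insert(blocks[i].end(), blocks[j].begin(), blocks[j].end());
      blocks[j].swap(blocks[nb - 1]);
      blocks[nb - 1].clear();
      --nb;
      fails = 0;
    } else {
      ++fails;
    }
  }
  if (nb >= 2) {
    // phase 2: mergeability matrix M (row-major nb x nb) + list of 1-entries
    std::vector<char> M((size_t)nb * nb, 0);
    std::vector<std::pair<int, int> > ones;
    for (int i = 0; i < nb; ++i)
      for (int j = i + 1; j < nb; ++j)
        if (blocks_mergeable(A, blocks[i], blocks[j])) {
          M[(size_t)i * nb + j] = M[(size_t)j * nb + i] = 1;
          ones.push_back(std::make_pair(i, j));
        }
    const int stride = nb;  // matrix stays allocated at initial width
    while (!ones.empty()) {
      const int pick = rand_int((int)ones.size());
      int i = ones[pick].first, j = ones[pick].second;
      // merge j into i: new block mergeable with k iff both were
      blocks[i].insert(blocks[i].end(), blocks[j].begin(), blocks[j].end());
      for (int k = 0; k < nb; ++k) {
        char v = M[(size_t)i * stride + k] && M[(size_t)j * stride + k];
        M[(size_t)i * stride + k] = v;
        M[(size_t)k * stride + i] = v;
      }
      M[(size_t)i * stride + i] = 0;
      // remove block j by swapping in the last block
      const int last = nb - 1;
      if (j != last) {
        blocks[j].swap(blocks[last]);
        for (int k = 0; k < nb; ++k) {
          M[(size_t)j * stride + k] = M[(size_t)last * stride + k];
          M[(size_t)k * stride + j] = M[(size_t)k * stride + last];
        }
        M[(size_t)j * stride + j] = 0;
      }
      blocks[last].clear();
      --nb;
      // rebuild the 1-entry list for rows touched; other entries unchanged
      std::vector<std::pair<int, int> > kept;
      kept.reserve(ones.size());
      for (size_t t = 0; t < ones.size(); ++t) {
        int a = ones[t].first, b = ones[t].second;
        if (a == i || b == i || a == j || b == j || a == last || b == last)
          continue;
        kept.push_back(ones[t]);
      }
      // re-add entries involving the merged block i and the relocated block j
      for (int k = 0; k < nb; ++k) {
        if (k != i && M[(size_t)i * stride + k])
          kept.push_back(std::make_pair(std::min(i, k), std::max(i, k)));
      }
      if (j < nb) {
        for (int k = 0; k < nb; ++k) {
          if (k == j || k == i) continue;  // (i,j) already added above
          if (M[(size_t)j * stride + k])
            kept.push_back(std::make_pair(std::min(j, k), std::max(j, k)));
        }
      }
      ones.swap(kept);
    }
  }
  std::fill(assign.begin(), assign.end(), 0);
  for (int b = 0; b < nb; ++b)
    for (size_t t = 0; t < blocks[b].size(); ++t)
      assign[blocks[b][t]] = b + 1;
}

// Star collapse: pick an unassigned node uniformly, cluster it with all its
// unassigned neighbors, remove, repeat.  Blocks are stars, not cliques.
static void s_iter(const IntegerMatrix &A, std::vector<int> &assign) {
  const int n = A.nrow();
  std::vector<int> avail(n);
  for (int i = 0; i < n; ++i) avail[i] = i;
  int na = n;
  std::fill(assign.begin(), assign.end(), 0);
  int block = 0;
  while (na > 0) {
    const int seed = avail[rand_int(na)];
    ++block;
    assign[seed] = block;
    int w = 0;
    for (int t = 0; t < na; ++t) {
      const int u = avail[t];
      if (u == seed) continue;
      if (A(u, seed)) {
        assign[u] = block;
      } else {
        avail[w++] = u;
      }
    }
    na = w;
  }
}

static void dispatch(const IntegerMatrix &A, int alg, std::vector<int> &assign) {
  switch (alg) {
    case 1: uv_iter(A, assign); break;
    case 2: r_iter(A, assign); break;
    case 3: s_iter(A, assign); break;
    default: stop("unknown algorithm code");
  }
}

// [[Rcpp::export]]
IntegerVector iter_partition_cpp(IntegerMatrix A, int alg) {
  const int n = A.nrow();
  if (n < 1) stop("graph is empty");
  std::vector<int> assign(n, 0);
  dispatch(A, alg, assign);
  return IntegerVector(assign.begin(), assign.end());
}

// Bulk driver: run `iterations` independent partitions and count, for each
// pair, how often it fell in the SAME block.  Separation counts are
// iterations - same (off-diagonal); dividing by iterations gives the
// secondary distance.
// [[Rcpp::export]]
IntegerMatrix cocluster_counts_cpp(IntegerMatrix A, int alg, int iterations) {
  const int n = A.nrow();
  if (n < 1) stop("graph is empty");
  if (iterations < 1) stop("iterations must be >= 1");
  IntegerMatrix same(n, n);
  std::vector<int> assign(n, 0);
  std::vector<std::vector<int> > members;
  for (int it = 0; it < iterations; ++it) {
    dispatch(A, alg, assign);
    int nb = 0;
    for (int i = 0; i < n; ++i) nb = std::max(nb, assign[i]);
    members.assign(nb, std::vector<int>());
    for (int i = 0; i < n; ++i) members[assign[i] - 1].push_back(i);
    for (int b = 0; b < nb; ++b) {
      const std::vector<int> &mb = members[b];
      for (size_t a = 0; a < mb.size(); ++a)
        for (size_t c = a + 1; c < mb.size(); ++c) {
          ++same(mb[a], mb[c]);
          ++same(mb[c], mb[a]);
        }
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return same;
}
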