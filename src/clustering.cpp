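#include <Rcpp.h>

using namespace Rcpp;

// All indices at this level are 0-based; the R wrappers translate.

// Neighbor counts for the radial algorithm: for each seed k in `avail`,
// the number of available frames j with D(k, j) < th (strict; includes k).
// [[Rcpp::export]]
IntegerVector rtc_counts_cpp(NumericMatrix D, IntegerVector avail, double th) {
  const int m = avail.size();
  IntegerVector cnt(m);
  for (int a = 0; a < m; ++a) {
    const int k = avail[a];
    int c = 0;
    for (int b = 0; b < m; ++b)
      if (D(k, avail[b]) < th) ++c;
    cnt[a] = c;
  }
  return cnt;
}

// Greedy diametral growth from `seed` over the pool `pool` (ascending,
// 0-based, must contain seed). Candidates are restricted to the seed's
// radial neighborhood: any frame at >= th from the seed can never join a
// set of diameter < th that contains the seed. At each step the candidate
// whose inclusion yields the smallest resulting diameter (strictly < th)
// is added; exact ties go to the lowest frame index. Members are returned
// in inclusion order, seed first.
static void grow_diametral(const NumericMatrix& D, int seed,
                           const std::vector<int>& pool, double th,
                           std::vector<int>& members, double& diam) {
  std::vector<int> cand;
  cand.reserve(pool.size());
  for (size_t p = 0; p < pool.size(); ++p) {
    const int j = pool[p];
    if (j != seed && D(seed, j) < th) cand.push_back(j);
  }
  const size_t nc = cand.size();
  std::vector<double> maxd(nc);   // max distance from candidate to current members
  std::vector<char> used(nc, 0);
  for (size_t c = 0; c < nc; ++c) maxd[c] = D(seed, cand[c]);

  members.clear();
  members.push_back(seed);
  diam = 0.0;
  for (;;) {
    int best = -1;
    double bestnd = th; // require resulting diameter < th
    for (size_t c = 0; c < nc; ++c) {
      if (used[c]) continue;
      const double nd = maxd[c] > diam ? maxd[c] : diam;
      if (nd < bestnd) { // strict: first (lowest-index) candidate wins ties
        bestnd = nd;
        best = static_cast<int>(c);
      }
    }
    if (best < 0) break;
    used[best] = 1;
    const int nb = cand[best];
    members.push_back(nb);
    if (maxd[best] > diam) diam = maxd[best];
    for (size_t c = 0; c < nc; ++c) {
      if (used[c]) continue;
      const double d = D(cand[c], nb);
      if (d > maxd[c]) maxd[c] = d;
    }
  }
}

// [[Rcpp::export]]
List qtc_grow_cpp(NumericMatrix D, int seed, IntegerVector avail, double th) {
  std::vector<int> pool(avail.begin(), avail.end());
  std::vector<int> members;
  double diam = 0.0;
  grow_diametral(D, seed, pool, th, members, diam);
  return List::create(_["members"] = wrap(members), _["diameter"] = diam);
}

// One full diametral iteration: grow a tentative cluster from every
// available seed, record the sizes, and return the winner (largest
// tentative cluster, ties to the lowest seed index).
// [[Rcpp::export]]
List qtc_iter_cpp(NumericMatrix D, IntegerVector avail, double th) {
  std::vector<int> pool(avail.begin(), avail.end());
  const size_t m = pool.size();
  IntegerVector sizes(m);
  std::vector<int> best_members;
  double best_diam = 0.0;
  int best_size = -1, best_seed = -1;
  std::vector<int> members;
  double diam;
  for (size_t a = 0; a < m; ++a) {
    grow_diametral(D, pool[a], pool, th, members, diam);
    const int sz = static_cast<int>(members.size());
    sizes[a] = sz;
    if (sz > best_size) { // strict: earliest (lowest) seed wins ties
      best_size = sz;
      best_seed = pool[a];
      best_members = members;
      best_diam = diam;
    }
  }
  return List::create(_["seed"] = best_seed,
                      _["members"] = wrap(best_members),
                      _["diameter"] = best_diam,
                      _["sizes"] = sizes);
}

// Complete clustering loop for either algorithm with f = min(index).
// Stops when no frames remain or the winning cluster falls below min_size
// (that cluster is not emitted). Returns per-cluster seeds and members.
// [[Rcpp::export]]
List cluster_full_cpp(NumericMatrix D, double th, bool radial, int min_size) {
  const int N = D.nrow();
  std::vector<int> avail(N);
  for (int i = 0; i < N; ++i) avail[i] = i;

  std::vector<int> seeds;
  std::vector<std::vector<int> > clusters;

  while (!avail.empty()) {
    int best_seed = -1, best_size = -1;
    std::vector<int> best_members, members;
    if (radial) {
      const size_t m = avail.size();
      for (size_t a = 0; a < m; ++a) {
        const int k = avail[a];
        int c = 0;
        for (size_t b = 0; b < m; ++b)
          if (D(k, avail[b]) < th) ++c;
        if (c > best_size) {
          best_size = c;
          best_seed = k;
        }
      }
      for (size_t b = 0; b < avail.size(); ++b)
        if (D(best_seed, avail[b]) < th) best_members.push_back(avail[b]);
    } else {
      double diam;
      for (size_t a = 0; a < avail.size(); ++a) {
        grow_diametral(D, avail[a], avail, th, members, diam);
        const int sz = static_cast<int>(members.size());
        if (sz > best_size) {
          best_size = sz;
          best_seed = avail[a];
          best_members = members;
        }
      }
    }
    if (best_size < min_size) break;
    seeds.push_back(best_seed);
    clusters.push_back(best_members);
    // remove members from avail, preserving ascending order
    std::vector<char> drop(N, 0);
    for (size_t i = 0; i < best_members.size(); ++i) drop[best_members[i]] = 1;
    std::vector<int> keep;
    keep.reserve(avail.size() - best_members.size());
    for (size_t i = 0; i < avail.size(); ++i)
      if (!drop[avail[i]]) keep.push_back(avail[i]);
    avail.swap(keep);
    Rcpp::checkUserInterrupt();
  }

  List out_members(clusters.size());
  for (size_t i = 0; i < clusters.size(); ++i) out_members[i] = wrap(clusters[i]);
  return List::create(_["seeds"] = wrap(seeds),
                      _["members"] = out_members,
                      _["unassigned"] = wrap(avail));
}
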