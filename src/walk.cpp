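#include <Rcpp.h>
using namespace Rcpp;

// Shared random-walk engine over a directed emission graph.
//
// Graph encoding (all indices 0-based):
//   ptr      : CSR pointer, length n_states + 1; out-edges of state s are
//              out_idx[ptr[s] .. ptr[s+1]-1] (global edge indices, graph order)
//   edge_to  : target state of each edge
//   prob     : transition probability of each edge (rows sum to 1)
//   emit     : per state, emission symbol index in 0..K-1, or -1 (silent)
//   start/fin: start and absorbing end state
//
// A walk tallies emission-symbol counts and (optionally) per-edge visit
// counts.  Return codes: 0 ok, 1 step guard exceeded, 2 per-symbol cap
// exceeded (only when a cap vector is supplied).

static int walk_once(const IntegerVector& ptr, const IntegerVector& out_idx,
                     const IntegerVector& edge_to, const NumericVector& prob,
                     const IntegerVector& emit, int start, int fin, int guard,
                     int* sym_counts, int* edge_counts, const int* cap) {
  int s = start;
  int steps = 0;
  while (s != fin) {
    if (++steps > guard) return 1;
    int lo = ptr[s], hi = ptr[s + 1];
    double u = unif_rand();
    double acc = 0.0;
    int e = out_idx[hi - 1];
    for (int k = lo; k < hi; ++k) {
      acc += prob[out_idx[k]];
      if (u <= acc) { e = out_idx[k]; break; }
    }
    if (edge_counts) edge_counts[e] += 1;
    s = edge_to[e];
    int sym = emit[s];
    if (sym >= 0) {
      sym_counts[sym] += 1;
      if (cap && cap[sym] >= 0 && sym_counts[sym] > cap[sym]) return 2;
    }
  }
  return 0;
}

// M independent haplotype walks: emission counts and optional edge counts.
// [[Rcpp::export]]
List cpp_sample_paths(IntegerVector ptr, IntegerVector out_idx,
                      IntegerVector edge_to, NumericVector prob,
                      IntegerVector emit, int start, int fin,
                      int K, int E, int M, int guard, bool want_edges) {
  IntegerMatrix emissions(M, K);
  IntegerMatrix edges(want_edges ? M : 0, want_edges ? E : 0);
  std::vector<int> sym(K), ec(E);
  for (int m = 0; m < M; ++m) {
    std::fill(sym.begin(), sym.end(), 0);
    if (want_edges) std::fill(ec.begin(), ec.end(), 0);
    int rc = walk_once(ptr, out_idx, edge_to, prob, emit, start, fin, guard,
                       sym.data(), want_edges ? ec.data() : nullptr, nullptr);
    if (rc == 1) stop("random walk exceeded the step guard (%d steps); a recursion loop has runaway probability", guard);
    for (int k = 0; k < K; ++k) emissions(m, k) = sym[k];
    if (want_edges) for (int e = 0; e < E; ++e) edges(m, e) = ec[e];
  }
  return List::create(_["emissions"] = emissions, _["edge_counts"] = edges);
}

// N diploid genotypes: element-wise sums of two independent walks.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_genotypes(IntegerVector ptr, IntegerVector out_idx,
                                   IntegerVector edge_to, NumericVector prob,
                                   IntegerVector emit, int start, int fin,
                                   int K, int N, int guard) {
  IntegerMatrix geno(N, K);
  std::vector<int> sym(K);
  for (int i = 0; i < N; ++i) {
    std::fill(sym.begin(), sym.end(), 0);
    for (int h = 0; h < 2; ++h) {
      int rc = walk_once(ptr, out_idx, edge_to, prob, emit, start, fin, guard,
                         sym.data(), nullptr, nullptr);
      if (rc == 1) stop("random walk exceeded the step guard (%d steps); a recursion loop has runaway probability", guard);
    }
    for (int k = 0; k < K; ++k) geno(i, k) = sym[k];
  }
  return geno;
}

// Incomplete-Gibbs pool refresh: for each individual draw up to `pool_size`
// prior path pairs at the current transition matrix and keep the first whose
// summed emissions match the observed genotype (exact conditional sampling
// by rejection).  Walks exceeding the genotype's per-symbol counts or the
// step guard are abandoned early and count as failed draws.
// [[Rcpp::export]]
List cpp_pool_update(IntegerVector ptr, IntegerVector out_idx,
                     IntegerVector edge_to, NumericVector prob,
                     IntegerVector emit, int start, int fin,
                     int K, int E, IntegerMatrix geno,
                     int pool_size, int guard) {
  int N = geno.nrow();
  IntegerMatrix counts(N, E);
  LogicalVector matched(N);
  IntegerVector draws(N);
  std::vector<int> sym(K), ec(E), cap(K);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < K; ++k) cap[k] = geno(i, k);
    bool hit = false;
    int d = 0;
    while (d < pool_size && !hit) {
      ++d;
      std::fill(sym.begin(), sym.end(), 0);
      std::fill(ec.begin(), ec.end(), 0);
      int rc = walk_once(ptr, out_idx, edge_to, prob, emit, start, fin, guard,
                         sym.data(), ec.data(), cap.data());
      if (rc != 0) continue;
      rc = walk_once(ptr, out_idx, edge_to, prob, emit, start, fin, guard,
                     sym.data(), ec.data(), cap.data());
      if (rc != 0) continue;
      hit = true;
      for (int k = 0; k < K; ++k) if (sym[k] != cap[k]) { hit = false; break; }
    }
    matched[i] = hit;
    draws[i] = d;
    if (hit) for (int e = 0; e < E; ++e) counts(i, e) = ec[e];
  }
  return List::create(_["counts"] = counts, _["matched"] = matched,
                      _["draws"] = draws);
}

// M path pairs with both the primary and the alternative (phased) emission
// tallies, used for genotype-phase translation.
// [[Rcpp::export]]
List cpp_walk_pairs_alt(IntegerVector ptr, IntegerVector out_idx,
                        IntegerVector edge_to, NumericVector prob,
                        IntegerVector emit, IntegerVector alt,
                        int start, int fin, int K, int Kalt,
                        int M, int guard) {
  IntegerMatrix primary(M, K);
  IntegerMatrix phased(M, Kalt);
  std::vector<int> sym(K), asym(Kalt);
  for (int m = 0; m < M; ++m) {
    std::fill(sym.begin(), sym.end(), 0);
    std::fill(asym.begin(), asym.end(), 0);
    for (int h = 0; h < 2; ++h) {
      int s = start;
      int steps = 0;
      while (s != fin) {
        if (++steps > guard) stop("random walk exceeded the step guard (%d steps)", guard);
        int lo = ptr[s], hi = ptr[s + 1];
        double u = unif_rand();
        double acc = 0.0;
        int e = out_idx[hi - 1];
        for (int k = lo; k < hi; ++k) {
          acc += prob[out_idx[k]];
          if (u <= acc) { e = out_idx[k]; break; }
        }
        s = edge_to[e];
        if (emit[s] >= 0) sym[emit[s]] += 1;
        if (alt[s] >= 0) asym[alt[s]] += 1;
      }
    }
    for (int k = 0; k < K; ++k) primary(m, k) = sym[k];
    for (int k = 0; k < Kalt; ++k) phased(m, k) = asym[k];
  }
  return List::create(_["primary"] = primary, _["phased"] = phased);
}

// Exhaustive bounded DFS over start-to-end paths with per-symbol emission
// caps.  Adjacency must arrive pre-sorted (by target id) so the output is
// lexicographic in the state sequence.  Budgets: max_paths recorded paths,
// max_expansions edge traversals; exceeding either stops the search and
// sets `truncated` (the caller decides whether that is an error).
// [[Rcpp::export]]
List cpp_enumerate_paths(IntegerVector ptr, IntegerVector out_idx,
                         IntegerVector edge_to, IntegerVector emit,
                         IntegerVector alt, int start, int fin,
                         int K, int Kalt, int E, IntegerVector cap,
                         int max_paths, double max_expansions) {
  std::vector<std::vector<int>> paths;
  std::vector<int> em_flat, alt_flat, ec_flat;
  std::vector<int> path(1, start), em(K, 0), al(Kalt, 0), ec(E, 0);
  // DFS stack of edge-slot iterators per depth
  std::vector<int> slot(1, ptr[start]);
  double expansions = 0;
  bool truncated = false;
  int n = 0;

  // handle degenerate start == fin (not a valid graph, but be safe)
  while (!slot.empty()) {
    int depth = slot.size() - 1;
    int s = path[depth];
    if (s == fin) {
      if (n >= max_paths) { truncated = true; break; }
      ++n;
      paths.push_back(path);
      em_flat.insert(em_flat.end(), em.begin(), em.end());
      alt_flat.insert(alt_flat.end(), al.begin(), al.end());
      ec_flat.insert(ec_flat.end(), ec.begin(), ec.end());
      // backtrack
      slot.pop_back();
      path.pop_back();
      if (!slot.empty()) {
        int pe = out_idx[slot.back() - 1];   // edge taken into this node
        int ps = edge_to[pe];
        if (emit[ps] >= 0) em[emit[ps]] -= 1;
        if (alt[ps] >= 0) al[alt[ps]] -= 1;
        ec[pe] -= 1;
        (void)ps;
      }
      continue;
    }
    if (slot[depth] >= ptr[s + 1]) {
      // exhausted this node's edges: backtrack
      slot.pop_back();
      path.pop_back();
      if (!slot.empty()) {
        int pe = out_idx[slot.back() - 1];
        int ps = edge_to[pe];
        if (emit[ps] >= 0) em[emit[ps]] -= 1;
        if (alt[ps] >= 0) al[alt[ps]] -= 1;
        ec[pe] -= 1;
      }
      continue;
    }
    int e = out_idx[slot[depth]];
    slot[depth] += 1;
    expansions += 1;
    if (expansions > max_expansions) { truncated = true; break; }
    int nxt = edge_to[e];
    int sym = emit[nxt];
    if (sym >= 0 && cap[sym] >= 0 && em[sym] + 1 > cap[sym]) continue;
    if (sym >= 0) em[sym] += 1;
    if (alt[nxt] >= 0) al[alt[nxt]] += 1;
    ec[e] += 1;
    path.push_back(nxt);
    slot.push_back(ptr[nxt]);
  }

  IntegerMatrix emissions(n, K), alts(n, Kalt), ecs(n, E);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) emissions(i, k) = em_flat[(size_t)i * K + k];
    for (int k = 0; k < Kalt; ++k) alts(i, k) = alt_flat[(size_t)i * Kalt + k];
    for (int e = 0; e < E; ++e) ecs(i, e) = ec_flat[(size_t)i * E + e];
  }
  List st(n);
  for (int i = 0; i < n; ++i) st[i] = wrap(paths[i]);
  return List::create(_["states"] = st, _["emissions"] = emissions,
                      _["alt_emissions"] = alts, _["edge_counts"] = ecs,
                      _["truncated"] = truncated);
}
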