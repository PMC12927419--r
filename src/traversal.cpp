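#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>

using namespace Rcpp;

// Graph encoding shared with the R side: nodes are 0-based ids 0..n_nodes-1,
// samples are ids 0..n_haploid-1 (leaves, no children). Down edges are stored
// in CSR form: edge_ptr has length n_nodes+1 and edge_child[edge_ptr[n] ..
// edge_ptr[n+1]-1] are the children of node n.

// Kahn topological sort. direction_up = false: parents before children
// (follow down edges); true: children before parents (reversed edges).
// Ties among simultaneously available nodes break by ascending node id
// (min-heap), so the order is fully deterministic.
// Returns list(order = 0-based ids, ok = bool, cycle_edge = c(parent, child)).
// [[Rcpp::export]]
List cpp_topo(int n_nodes, IntegerVector edge_ptr, IntegerVector edge_child,
              bool direction_up) {
  int n_edges = edge_child.size();
  // parent CSR (reversed edges), needed for the up direction
  std::vector<int> par_ptr, par_child;
  if (direction_up) {
    par_ptr.assign(n_nodes + 1, 0);
    for (int e = 0; e < n_edges; ++e) par_ptr[edge_child[e] + 1]++;
    for (int n = 0; n < n_nodes; ++n) par_ptr[n + 1] += par_ptr[n];
    par_child.assign(n_edges, 0);
    std::vector<int> fill(par_ptr.begin(), par_ptr.end() - 1);
    for (int n = 0; n < n_nodes; ++n)
      for (int e = edge_ptr[n]; e < edge_ptr[n + 1]; ++e)
        par_child[fill[edge_child[e]]++] = n;
  }
  const int *succ_ptr = direction_up ? par_ptr.data() : &edge_ptr[0];
  const int *succ = direction_up ? (par_child.empty() ? nullptr : par_child.data())
                                 : (n_edges ? &edge_child[0] : nullptr);

  std::vector<int> indeg(n_nodes, 0);
  if (direction_up) {
    for (int n = 0; n < n_nodes; ++n)
      indeg[n] = edge_ptr[n + 1] - edge_ptr[n];
  } else {
    for (int e = 0; e < n_edges; ++e) indeg[edge_child[e]]++;
  }

  std::priority_queue<int, std::vector<int>, std::greater<int> > heap;
  for (int n = 0; n < n_nodes; ++n)
    if (indeg[n] == 0) heap.push(n);

  std::vector<int> order;
  order.reserve(n_nodes);
  while (!heap.empty()) {
    int n = heap.top();
    heap.pop();
    order.push_back(n);
    for (int e = succ_ptr[n]; e < succ_ptr[n + 1]; ++e)
      if (--indeg[succ[e]] == 0) heap.push(succ[e]);
  }

  if ((int)order.size() != n_nodes) {
    // report one edge on a cycle: any down edge between two unprocessed nodes
    std::vector<bool> done(n_nodes, false);
    for (size_t k = 0; k < order.size(); ++k) done[order[k]] = true;
    for (int n = 0; n < n_nodes; ++n) {
      if (done[n]) continue;
      for (int e = edge_ptr[n]; e < edge_ptr[n + 1]; ++e) {
        if (!done[edge_child[e]]) {
          return List::create(_["order"] = IntegerVector(0),
                              _["ok"] = false,
                              _["cycle_edge"] = IntegerVector::create(n, edge_child[e]));
        }
      }
    }
    return List::create(_["order"] = IntegerVector(0), _["ok"] = false,
                        _["cycle_edge"] = IntegerVector::create(NA_INTEGER, NA_INTEGER));
  }
  return List::create(_["order"] = wrap(order), _["ok"] = true,
                      _["cycle_edge"] = IntegerVector(0));
}

// Downward accumulation: value(n) = sum of u over mutations attached to n
// plus sum of value(parent) over parents; equals G u at the sample nodes.
// topo_down must list every parent before all of its children.
// [[Rcpp::export]]
NumericVector cpp_dot_down(int n_nodes, int n_haploid,
                           IntegerVector edge_ptr, IntegerVector edge_child,
                           IntegerVector topo_down, IntegerVector mutation_node,
                           NumericVector u) {
  std::vector<double> val(n_nodes, 0.0);
  for (int i = 0; i < mutation_node.size(); ++i)
    val[mutation_node[i]] += u[i];
  for (int k = 0; k < n_nodes; ++k) {
    int n = topo_down[k];
    double v = val[n];
    for (int e = edge_ptr[n]; e < edge_ptr[n + 1]; ++e)
      val[edge_child[e]] += v;
  }
  NumericVector out(n_haploid);
  for (int j = 0; j < n_haploid; ++j) out[j] = val[j];
  return out;
}

// Upward accumulation: value(sample j) = v[j]; value(internal) = sum over
// children; output[i] = value at the node carrying mutation i. Equals G^T v.
// [[Rcpp::export]]
NumericVector cpp_dot_up(int n_nodes, int n_haploid,
                         IntegerVector edge_ptr, IntegerVector edge_child,
                         IntegerVector topo_down, IntegerVector mutation_node,
                         NumericVector v) {
  std::vector<double> val(n_nodes, 0.0);
  for (int j = 0; j < n_haploid; ++j) val[j] = v[j];
  // reverse down order = children before parents
  for (int k = n_nodes - 1; k >= 0; --k) {
    int n = topo_down[k];
    double s = val[n];
    for (int e = edge_ptr[n]; e < edge_ptr[n + 1]; ++e)
      s += val[edge_child[e]];
    val[n] = s;
  }
  NumericVector out(mutation_node.size());
  for (int i = 0; i < mutation_node.size(); ++i) out[i] = val[mutation_node[i]];
  return out;
}

// Direct reachability decode, independent of the accumulation traversals:
// per mutation, DFS from its node and mark every sample leaf reached.
// Returns the 2N-by-M 0/1 matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_decode(int n_nodes, int n_haploid,
                         IntegerVector edge_ptr, IntegerVector edge_child,
                         IntegerVector mutation_node) {
  int M = mutation_node.size();
  IntegerMatrix out(n_haploid, M);
  std::vector<int32_t> stamp(n_nodes, -1);
  std::vector<int> stack;
  for (int i = 0; i < M; ++i) {
    stack.clear();
    stack.push_back(mutation_node[i]);
    while (!stack.empty()) {
      int n = stack.back();
      stack.pop_back();
      if (stamp[n] == i) continue;
      stamp[n] = i;
      if (n < n_haploid) out(n, i) = 1;
      for (int e = edge_ptr[n]; e < edge_ptr[n + 1]; ++e)
        if (stamp[edge_child[e]] != i) stack.push_back(edge_child[e]);
    }
  }
  return out;
}
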