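// Felsenstein pruning over unique site patterns with discrete-gamma rate
// mixing, organised for MCMC: each non-root node caches its "contribution"
// matrix P(edge) * partial(node), so a proposal recomputes only the
// contributions on the changed edges and on the path from them to the root.
// No per-node rescaling: double range is ample at the tree sizes this
// package targets (tens of taxa).

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct PruneLik {
  int ntip, nnode, nstate, npat, ncat;
  imat edge;                       // (parent, child), 1-based node ids
  std::vector<int> parent;         // parent node id per node (0 = root)
  std::vector<std::vector<int>> children;
  std::vector<int> postorder;      // all non-root nodes, children-first
  imat tipstate;                   // npat x ntip, 0..nstate-1, -1 = unknown
  vec wts;
  vec pi, evals;
  mat A, Ainv;                     // P(t) = A diag(exp(evals t)) Ainv
  vec cat_rates;
  vec edge_len;                    // expected substitutions, by child node

  // contrib[(node-1)*ncat + cat]: nstate x npat
  std::vector<mat> contrib_cur, contrib_prop;
  std::vector<int> prop_nodes;
  vec prop_edge_len;
  mat tmp;                         // workspace partial
  double ll_cur;

  mat pmat(double t) const {
    return A * (Ainv.each_col() % exp(evals * t));
  }

  const mat& get_contrib(int node, int cat, const std::vector<bool>& dirty) const {
    return dirty[node - 1] ? contrib_prop[(node - 1) * ncat + cat]
                           : contrib_cur[(node - 1) * ncat + cat];
  }

  // recompute the contribution of `node` to its parent into contrib_prop
  void recompute(int node, double len, const std::vector<bool>& dirty) {
    for (int cat = 0; cat < ncat; ++cat) {
      mat P = pmat(len * cat_rates[cat]);
      mat& out = contrib_prop[(node - 1) * ncat + cat];
      if (node <= ntip) {
        for (int p = 0; p < npat; ++p) {
          int s = tipstate(p, node - 1);
          if (s < 0) out.col(p).ones();
          else out.col(p) = P.col(s);
        }
      } else {
        const std::vector<int>& kids = children[node - 1];
        tmp = get_contrib(kids[0], cat, dirty);
        for (size_t k = 1; k < kids.size(); ++k)
          tmp %= get_contrib(kids[k], cat, dirty);
        out = P * tmp;
      }
    }
  }

  double root_loglik(const std::vector<bool>& dirty) {
    int root = ntip + 1;
    const std::vector<int>& kids = children[root - 1];
    vec site(npat, fill::zeros);
    for (int cat = 0; cat < ncat; ++cat) {
      tmp = get_contrib(kids[0], cat, dirty);
      for (size_t k = 1; k < kids.size(); ++k)
        tmp %= get_contrib(kids[k], cat, dirty);
      site += tmp.t() * pi;
    }
    site /= ncat;
    return dot(wts, log(site));
  }

  double full_set(const vec& lens, const vec& rates) {
    cat_rates = rates;
    edge_len = lens;
    std::vector<bool> dirty(nnode, true);
    for (int v : postorder) recompute(v, lens[v - 1], dirty);
    std::swap(contrib_cur, contrib_prop);
    std::vector<bool> clean(nnode, false);
    ll_cur = root_loglik(clean);
    prop_nodes.clear();
    return ll_cur;
  }

  double propose(const vec& lens) {
    std::vector<bool> dirty(nnode, false);
    bool any = false;
    for (int e = 0; e < (int)edge.n_rows; ++e) {
      int c = edge(e, 1);
      if (lens[c - 1] != edge_len[c - 1]) {
        any = true;
        int v = c;   // the edge's own contribution and every ancestor's
        while (v != 0 && v != ntip + 1 && !dirty[v - 1]) {
          dirty[v - 1] = true;
          v = parent[v - 1];
        }
      }
    }
    prop_nodes.clear();
    if (!any) return ll_cur;
    for (int v : postorder)
      if (dirty[v - 1]) {
        recompute(v, lens[v - 1], dirty);
        prop_nodes.push_back(v);
      }
    prop_edge_len = lens;
    return root_loglik(dirty);
  }

  void accept(double ll) {
    for (int v : prop_nodes)
      for (int cat = 0; cat < ncat; ++cat)
        std::swap(contrib_cur[(v - 1) * ncat + cat],
                  contrib_prop[(v - 1) * ncat + cat]);
    if (!prop_nodes.empty()) edge_len = prop_edge_len;
    ll_cur = ll;
    prop_nodes.clear();
  }
};

// [[Rcpp::export]]
SEXP plik_build(Rcpp::IntegerMatrix edge, int ntip,
                Rcpp::IntegerMatrix tipstate, Rcpp::NumericVector wts,
                Rcpp::NumericVector pi, Rcpp::NumericVector evals,
                Rcpp::NumericMatrix A, Rcpp::NumericMatrix Ainv, int ncat) {
  PruneLik* L = new PruneLik();
  L->ntip = ntip;
  L->nstate = pi.size();
  L->npat = tipstate.nrow();
  L->ncat = ncat;
  L->edge = Rcpp::as<imat>(edge);
  L->nnode = ntip;
  for (int e = 0; e < edge.nrow(); ++e)
    L->nnode = std::max(L->nnode, std::max(edge(e, 0), edge(e, 1)));
  L->parent.assign(L->nnode, 0);
  L->children.assign(L->nnode, {});
  for (int e = 0; e < edge.nrow(); ++e) {
    L->parent[edge(e, 1) - 1] = edge(e, 0);
    L->children[edge(e, 0) - 1].push_back(edge(e, 1));
  }
  {
    // postorder over ALL non-root nodes (children before parents)
    std::vector<int> stack = {ntip + 1};
    std::vector<int> seen;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      if (v != ntip + 1) seen.push_back(v);
      for (int c : L->children[v - 1]) stack.push_back(c);
    }
    L->postorder.assign(seen.rbegin(), seen.rend());
  }
  L->tipstate = Rcpp::as<imat>(tipstate);
  L->wts = Rcpp::as<vec>(wts);
  L->pi = Rcpp::as<vec>(pi);
  L->evals = Rcpp::as<vec>(evals);
  L->A = Rcpp::as<mat>(A);
  L->Ainv = Rcpp::as<mat>(Ainv);
  L->cat_rates = vec(ncat, fill::ones);
  L->edge_len = vec(L->nnode, fill::zeros);
  L->contrib_cur.assign(L->nnode * ncat, mat());
  L->contrib_prop.assign(L->nnode * ncat, mat());
  for (int v : L->postorder)
    for (int cat = 0; cat < ncat; ++cat) {
      L->contrib_cur[(v - 1) * ncat + cat].set_size(L->nstate, L->npat);
      L->contrib_prop[(v - 1) * ncat + cat].set_size(L->nstate, L->npat);
    }
  L->tmp.set_size(L->nstate, L->npat);
  L->ll_cur = NA_REAL;
  Rcpp::XPtr<PruneLik> ptr(L, true);
  return ptr;
}

// [[Rcpp::export]]
double plik_set(SEXP ptr, Rcpp::NumericVector edge_len,
                Rcpp::NumericVector cat_rates) {
  Rcpp::XPtr<PruneLik> L(ptr);
  return L->full_set(Rcpp::as<vec>(edge_len), Rcpp::as<vec>(cat_rates));
}

// [[Rcpp::export]]
double plik_propose(SEXP ptr, Rcpp::NumericVector edge_len) {
  Rcpp::XPtr<PruneLik> L(ptr);
  return L->propose(Rcpp::as<vec>(edge_len));
}

// [[Rcpp::export]]
void plik_accept(SEXP ptr, double ll) {
  Rcpp::XPtr<PruneLik> L(ptr);
  L->accept(ll);
}

// [[Rcpp::export]]
double plik_current(SEXP ptr) {
  Rcpp::XPtr<PruneLik> L(ptr);
  return L->ll_cur;
}
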