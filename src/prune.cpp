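// Felsenstein pruning over compressed site patterns. Transition matrices
// are supplied per edge (the caller memoizes them per distinct branch
// length); tip partials are indicator matrices with few distinct columns,
// passed as a per-tip basis plus per-pattern column codes.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Persistent per-model context: eigendecomposition of Q plus a cache of
// P(t) per distinct branch length.
struct PruneCtx {
  cx_mat V, Vinv;
  cx_vec lam;
  std::map<double, mat> cache;
  int S;
};

// [[Rcpp::export]]
SEXP cpp_make_ctx(const arma::cx_mat& V, const arma::cx_mat& Vinv,
                  const arma::cx_vec& lam) {
  PruneCtx* ctx = new PruneCtx;
  ctx->V = V;
  ctx->Vinv = Vinv;
  ctx->lam = lam;
  ctx->S = V.n_rows;
  Rcpp::XPtr<PruneCtx> ptr(ctx, true);
  return ptr;
}

static const mat& ctx_pmat(PruneCtx* ctx, double t) {
  auto it = ctx->cache.find(t);
  if (it != ctx->cache.end()) return it->second;
  mat P;
  if (t <= 0) {
    P = eye(ctx->S, ctx->S);
  } else {
    cx_vec ex = exp(ctx->lam * t);
    P = real(ctx->V * diagmat(ex) * ctx->Vinv);
    P.transform([](double x) { return x < 0 ? 0.0 : x; });
  }
  auto ins = ctx->cache.emplace(t, std::move(P));
  return ins.first->second;
}

// Pruning with the per-model P cache.
// [[Rcpp::export]]
Rcpp::List cpp_prune_ctx(SEXP ctx_ptr, const arma::imat& edges,
                         const arma::vec& lens, double luca_len,
                         const Rcpp::List& tip_basis,
                         const Rcpp::List& tip_code, int normal,
                         const arma::vec& counts, int n_tip, int n_node) {
  Rcpp::XPtr<PruneCtx> ctx(ctx_ptr);
  const int K = edges.n_rows;
  const uvec code0 = Rcpp::as<uvec>(tip_code[0]);
  const int p = code0.n_elem;
  const int S = ctx->S;
  std::vector<mat> partial(n_tip + n_node + 1);
  vec logscale(p, fill::zeros);
  int k = 0;
  while (k < K) {
    int parent = edges(k, 0);
    mat Lp(S, p, fill::ones);
    while (k < K && edges(k, 0) == parent) {
      int child = edges(k, 1);
      const mat& P = ctx_pmat(ctx, lens(k));
      if (child <= n_tip) {
        const mat basis = Rcpp::as<mat>(tip_basis[child - 1]);
        const uvec code = Rcpp::as<uvec>(tip_code[child - 1]);
        mat U = P * basis;
        for (int j = 0; j < p; ++j) {
          Lp.col(j) %= U.col(code(j) - 1);
        }
      } else {
        Lp %= P * partial[child];
      }
      ++k;
    }
    rowvec cs = sum(Lp, 0);
    if (cs.min() < 1e-280) {
      rowvec mx = max(Lp, 0);
      mx.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
      Lp.each_row() /= mx;
      logscale += log(mx).t();
    }
    partial[parent] = Lp;
  }
  mat Lm = partial[n_tip + 1];
  const mat& Pl = ctx_pmat(ctx, luca_len);
  vec site = (Pl.row(normal - 1) * Lm).t();
  double ll;
  if (site.min() <= 0) {
    ll = -datum::inf;
  } else {
    ll = accu(counts % (log(site) + logscale));
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("mrca_partial") = Lm,
                            Rcpp::Named("logscale") = logscale,
                            Rcpp::Named("site_lik") = site);
}

// edges: postorder edge matrix (1-based parent, child), P_list aligned.
// tip_basis[i]: S x K_i indicator matrix over that tip's distinct
// observations; tip_code[i]: length-p 1-based column index per pattern.
// [[Rcpp::export]]
Rcpp::List cpp_prune(const arma::imat& edges, const Rcpp::List& P_list,
                     const arma::mat& P_luca, const Rcpp::List& tip_basis,
                     const Rcpp::List& tip_code, int normal,
                     const arma::vec& counts, int n_tip, int n_node) {
  const int K = edges.n_rows;
  const uvec code0 = Rcpp::as<uvec>(tip_code[0]);
  const int p = code0.n_elem;
  const int S = Rcpp::as<mat>(tip_basis[0]).n_rows;
  std::vector<mat> partial(n_tip + n_node + 1);
  vec logscale(p, fill::zeros);
  int k = 0;
  while (k < K) {
    int parent = edges(k, 0);
    mat Lp(S, p, fill::ones);
    while (k < K && edges(k, 0) == parent) {
      int child = edges(k, 1);
      const mat P = Rcpp::as<mat>(P_list[k]);
      if (child <= n_tip) {
        const mat basis = Rcpp::as<mat>(tip_basis[child - 1]);
        const uvec code = Rcpp::as<uvec>(tip_code[child - 1]);
        mat U = P * basis;                  // S x K_child
        for (int j = 0; j < p; ++j) {
          Lp.col(j) %= U.col(code(j) - 1);
        }
      } else {
        Lp %= P * partial[child];
      }
      ++k;
    }
    rowvec cs = sum(Lp, 0);
    if (cs.min() < 1e-280) {
      rowvec mx = max(Lp, 0);
      mx.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
      Lp.each_row() /= mx;
      logscale += log(mx).t();
    }
    partial[parent] = Lp;
  }
  mat Lm = partial[n_tip + 1];
  vec site = (P_luca.row(normal - 1) * Lm).t();
  double ll;
  if (site.min() <= 0) {
    ll = -datum::inf;
  } else {
    ll = accu(counts % (log(site) + logscale));
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("mrca_partial") = Lm,
                            Rcpp::Named("logscale") = logscale,
                            Rcpp::Named("site_lik") = site);
}
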