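// Felsenstein pruning over the 61 sense-codon states, with per-site
// scaling and an optional analytic branch-length derivative pass.
//
// The tree arrives as an ape-style edge matrix in postorder (children before
// parents), nodes numbered 1..n_tip for tips, root = n_tip + 1. Transition
// matrices come from the reversible eigendecomposition of each branch-class
// generator: P(t) = A diag(exp(lambda t)) B.
//
// The derivative pass returns r[e, s] = (d l_s / d t_e) / l_s for every edge
// and site pattern, computed with outside (upper) partial vectors, so the
// caller can assemble gradients for single-class models and for site-mixture
// models alike.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void rescale_cols(arma::mat& L, arma::rowvec& scale) {
  arma::rowvec m = arma::max(L, 0);
  for (arma::uword s = 0; s < L.n_cols; ++s) {
    double ms = m(s);
    if (ms > 0 && ms != 1.0) {
      L.col(s) /= ms;
      scale(s) += std::log(ms);
    }
  }
}

// [[Rcpp::export(name = ".codon_pruning")]]
List codon_pruning(IntegerMatrix edge, int n_tip,
                   NumericVector bl, IntegerVector class_idx,
                   List eigA, List eigB, List eigL, List Qs,
                   List dQomega, List dQkappa,
                   IntegerMatrix tip_states, NumericVector pi,
                   bool want_grad) {
  const int n_edge = edge.nrow();
  const int n_pat = tip_states.ncol();
  const int n_state = pi.size();
  const int n_node = n_tip + n_tip - 1; // rooted binary tree

  arma::vec piv(pi.begin(), n_state);

  // per-class eigensystems
  const int n_class = eigA.size();
  std::vector<arma::mat> A(n_class), B(n_class), Q(n_class), Dw(n_class), Dk(n_class);
  std::vector<arma::vec> lam(n_class);
  for (int k = 0; k < n_class; ++k) {
    A[k] = as<arma::mat>(eigA[k]);
    B[k] = as<arma::mat>(eigB[k]);
    lam[k] = as<arma::vec>(eigL[k]);
    if (want_grad) {
      Q[k] = as<arma::mat>(Qs[k]);
      // derivative generators projected into the eigenbasis: D = B dQ A
      Dw[k] = B[k] * as<arma::mat>(dQomega[k]) * A[k];
      Dk[k] = B[k] * as<arma::mat>(dQkappa[k]) * A[k];
    }
  }

  std::vector<arma::mat> L(n_node + 1);       // partials per node
  std::vector<arma::rowvec> S(n_node + 1);    // log-scale per node
  std::vector<arma::mat> M(n_edge);           // per-edge message P * L_child
  std::vector<arma::rowvec> MS(n_edge);       // scale carried by M (= S[child])
  std::vector<arma::mat> Pmat(n_edge);

  // forward (postorder) pass
  for (int e = 0; e < n_edge; ++e) {
    int parent = edge(e, 0), child = edge(e, 1);
    int k = class_idx[e] - 1;
    arma::mat P = A[k] * arma::diagmat(arma::exp(lam[k] * bl[e])) * B[k];
    P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    if (want_grad) Pmat[e] = P;

    arma::mat Me(n_state, n_pat);
    arma::rowvec Mscale(n_pat, arma::fill::zeros);
    if (child <= n_tip) {
      for (int s = 0; s < n_pat; ++s) {
        int st = tip_states(child - 1, s);
        if (st > 0) Me.col(s) = P.col(st - 1);
        else Me.col(s).ones();
      }
    } else {
      rescale_cols(L[child], S[child]);
      Me = P * L[child];
      Mscale = S[child];
    }
    if (want_grad) { M[e] = Me; MS[e] = Mscale; }

    if (L[parent].n_elem == 0) {
      L[parent] = Me;
      S[parent] = Mscale;
    } else {
      L[parent] %= Me;
      S[parent] += Mscale;
    }
  }

  int root = n_tip + 1;
  arma::rowvec lik_stored = piv.t() * L[root];
  arma::vec site_loglik(n_pat);
  for (int s = 0; s < n_pat; ++s) {
    double v = lik_stored(s);
    site_loglik(s) = (v > 0 ? std::log(v) : -1e10) + S[root](s);
  }

  List out = List::create(Named("site_loglik") = site_loglik);
  if (!want_grad) return out;

  // backward (preorder) pass: upper partials per node
  std::vector<arma::mat> U(n_node + 1);
  std::vector<arma::rowvec> US(n_node + 1);
  U[root] = arma::repmat(piv, 1, n_pat);
  US[root] = arma::rowvec(n_pat, arma::fill::zeros);

  // locate sibling edge for each edge (binary tree: each parent has 2 kids)
  std::vector<int> sib(n_edge, -1);
  {
    std::vector<int> first_edge(n_node + 1, -1);
    for (int e = 0; e < n_edge; ++e) {
      int p = edge(e, 0);
      if (first_edge[p] < 0) first_edge[p] = e;
      else { sib[e] = first_edge[p]; sib[first_edge[p]] = e; }
    }
  }

  arma::mat deriv(n_edge, n_pat, arma::fill::zeros);
  arma::mat deriv_w(n_edge, n_pat, arma::fill::zeros);
  arma::mat deriv_k(n_edge, n_pat, arma::fill::zeros);
  for (int e = n_edge - 1; e >= 0; --e) {
    int parent = edge(e, 0), child = edge(e, 1);
    int k = class_idx[e] - 1;
    double t = bl[e];

    arma::mat W;
    arma::rowvec Wscale;
    if (sib[e] >= 0) {
      W = U[parent] % M[sib[e]];
      Wscale = US[parent] + MS[sib[e]];
    } else {
      W = U[parent];
      Wscale = US[parent];
    }

    // Frechet derivative weights: V_ij = (e^{li t} - e^{lj t}) / (li - lj)
    const arma::vec& l = lam[k];
    arma::vec elt = arma::exp(l * t);
    arma::mat V(n_state, n_state);
    for (int i = 0; i < n_state; ++i) {
      for (int j = 0; j < n_state; ++j) {
        double d = l(i) - l(j);
        V(i, j) = (std::fabs(d) > 1e-9) ? (elt(i) - elt(j)) / d
                                        : t * std::exp(0.5 * (l(i) + l(j)) * t);
      }
    }
    arma::mat dPw = A[k] * (Dw[k] % V) * B[k];
    arma::mat dPk = A[k] * (Dk[k] % V) * B[k];
    arma::mat G = Q[k] * Pmat[e]; // dP/dt = Q P

    arma::mat GL(n_state, n_pat), GLw(n_state, n_pat), GLk(n_state, n_pat);
    arma::rowvec GLscale(n_pat, arma::fill::zeros);
    if (child <= n_tip) {
      for (int s = 0; s < n_pat; ++s) {
        int st = tip_states(child - 1, s);
        if (st > 0) {
          GL.col(s) = G.col(st - 1);
          GLw.col(s) = dPw.col(st - 1);
          GLk.col(s) = dPk.col(st - 1);
        } else {
          GL.col(s).zeros(); // rows of P sum to 1 -> Q P 1 = 0
          GLw.col(s).zeros();
          GLk.col(s).zeros();
        }
      }
    } else {
      GL = G * L[child];
      GLw = dPw * L[child];
      GLk = dPk * L[child];
      GLscale = S[child];
    }

    for (int s = 0; s < n_pat; ++s) {
      double delta = Wscale(s) + GLscale(s) - S[root](s);
      double denom = lik_stored(s);
      if (denom <= 0) continue;
      double fac = std::exp(delta) / denom;
      deriv(e, s) = arma::dot(W.col(s), GL.col(s)) * fac;
      deriv_w(e, s) = arma::dot(W.col(s), GLw.col(s)) * fac;
      deriv_k(e, s) = arma::dot(W.col(s), GLk.col(s)) * fac;
    }

    if (child > n_tip) { // descend
      U[child] = Pmat[e].t() * W;
      US[child] = Wscale;
      rescale_cols(U[child], US[child]);
    }
  }

  out["deriv_ratio"] = deriv;
  out["deriv_omega"] = deriv_w;
  out["deriv_kappa"] = deriv_k;
  return out;
}
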