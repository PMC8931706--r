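# R-side interface to the pruning core: data preparation, likelihood
# evaluation for single-class (per-branch omega) models and for site-mixture
# models, with analytic branch-length gradients.

# Prepare pruning inputs: postorder tree, compressed site patterns, integer
# tip states (0 = missing). Tip rows are ordered by tip index of the tree.
prepare_pruning <- function(aln, tree) {
  check_tree_alignment(tree, aln)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    stop("tree must be rooted and bifurcating", call. = FALSE)
  }
  tree_po <- ape::reorder.phylo(tree, "postorder")
  states <- aln$codon[tree_po$tip.label, , drop = FALSE]
  pat <- compress_patterns(states)
  tip_states <- pat$states
  tip_states[is.na(tip_states)] <- 0L
  storage.mode(tip_states) <- "integer"
  list(
    tree = tree_po,
    edge = tree_po$edge,
    n_tip = length(tree_po$tip.label),
    labels = branch_labels(tree_po),
    tip_states = tip_states,
    weights = pat$weights
  )
}

# Eigensystems (and, for gradients, derivative generators) for a set of
# omega values sharing kappa and pi.
class_eigensystems <- function(kappa, omegas, pi, want_Q = FALSE) {
  dummy <- matrix(0)
  sys <- lapply(omegas, function(w) {
    if (want_Q) {
      d <- rate_matrix_derivs(kappa, w, pi)
      ed <- eigen_rate_matrix(d$Q, pi)
      list(A = ed$A, B = ed$B, lambda = ed$lambda,
           Q = d$Q, dQw = d$dQ_omega, dQk = d$dQ_kappa)
    } else {
      Q <- build_rate_matrix(kappa, w, pi)
      ed <- eigen_rate_matrix(Q, pi)
      list(A = ed$A, B = ed$B, lambda = ed$lambda,
           Q = dummy, dQw = dummy, dQk = dummy)
    }
  })
  list(
    A = lapply(sys, `[[`, "A"),
    B = lapply(sys, `[[`, "B"),
    lambda = lapply(sys, `[[`, "lambda"),
    Q = lapply(sys, `[[`, "Q"),
    dQw = lapply(sys, `[[`, "dQw"),
    dQk = lapply(sys, `[[`, "dQk")
  )
}

# Core evaluation: per-pattern log-likelihood and, with `want_grad`, the
# per-edge per-pattern derivative ratios (d l/d t)/l, (d l/d omega_edge)/l,
# (d l/d kappa_edge)/l. `class_of_edge` indexes into `omegas`.
pruning_eval <- function(prep, bl, class_of_edge, kappa, omegas, pi,
                         want_grad = FALSE) {
  es <- class_eigensystems(kappa, omegas, pi, want_Q = want_grad)
  .codon_pruning(prep$edge, prep$n_tip, bl, as.integer(class_of_edge),
                 es$A, es$B, es$lambda, es$Q, es$dQw, es$dQk,
                 prep$tip_states, pi, want_grad)
}

#' Log-likelihood of a codon alignment under a branch model
#'
#' Evaluates the GY94 likelihood by Felsenstein pruning with site-pattern
#' compression and per-site scaling. Missing codons contribute a vector of
#' ones (so all-missing columns are harmless and the result is never NaN).
#'
#' @param aln A [codon_alignment].
#' @param tree Rooted bifurcating `ape::phylo`; tips must be alignment taxa.
#' @param params List with `kappa`, `omega` (named by branch class),
#'   `branch_classes` (named by branch label, see [branch_labels()]; omit for
#'   a single class), `branch_lengths` (named by branch label; defaults to
#'   the tree's edge lengths) and `pi` (61 codon frequencies; defaults to
#'   F3X4 from the alignment).
#' @return The log-likelihood (a single number).
#' @export
log_likelihood <- function(aln, tree, params) {
  prep <- prepare_pruning(aln, tree)
  pi <- params$pi %||% codon_frequencies(aln)
  bl <- params$branch_lengths
  if (is.null(bl)) {
    if (is.null(tree$edge.length)) stop("no branch lengths available", call. = FALSE)
    bl <- stats::setNames(prep$tree$edge.length, prep$labels)
  }
  if (!all(prep$labels %in% names(bl))) {
    stop("branch_lengths must be named by branch label", call. = FALSE)
  }
  omega <- params$omega
  if (is.null(names(omega))) names(omega) <- "all"
  classes <- params$branch_classes
  if (is.null(classes)) {
    class_of_edge <- rep(1L, nrow(prep$edge))
    omegas <- omega[[1]]
  } else {
    if (!all(prep$labels %in% names(classes))) {
      stop("branch_classes must cover every branch", call. = FALSE)
    }
    cls <- classes[prep$labels]
    levs <- names(omega)
    if (!all(cls %in% levs)) {
      stop("branch class without an omega: ",
           paste(setdiff(unique(cls), levs), collapse = ", "), call. = FALSE)
    }
    class_of_edge <- match(cls, levs)
    omegas <- as.numeric(omega)
  }
  out <- pruning_eval(prep, as.numeric(bl[prep$labels]), class_of_edge,
                      params$kappa, omegas, pi)
  sum(prep$weights * out$site_loglik)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
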