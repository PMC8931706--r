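# Maximum-likelihood fitting of branch models: kappa, free omegas, and all
# branch lengths are co-estimated by L-BFGS-B on log-transformed parameters.
# Branch-length gradients are analytic (outside-partial pass in the pruning
# core); kappa/omega gradients use central differences.

#' Count free parameters of a branch model
#'
#' Uses the rooted-tree convention: `2n - 2` branch lengths for `n` tips,
#' plus 1 for kappa, plus the number of free omega parameters. Equilibrium
#' codon frequencies are empirical and not counted.
#'
#' @param n_tips Number of tips.
#' @param n_free_omega Number of omega parameters estimated (0 when all are
#'   fixed, 1 for a one-ratio model, 2 for a two-ratio model, `2n - 2` for
#'   the free-ratio model).
#' @return Integer parameter count.
#' @export
count_parameters <- function(n_tips, n_free_omega) {
  as.integer(2L * n_tips - 2L + 1L + n_free_omega)
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

fit_control <- function(control = list()) {
  defaults <- list(
    kappa_init = 2, omega_init = 0.2, bl_init = 0.1,
    maxit = 300, factr = 1e7,
    max_restarts = 2, jitter_sd = 0.3, jitter_seed = 101,
    kappa_bounds = c(0.05, 50), omega_bounds = c(1e-4, 20),
    bl_bounds = c(1e-7, 10)
  )
  utils::modifyList(defaults, control)
}

#' Fit a GY94 branch model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over kappa, the free branch-class
#' omegas, and all branch lengths (log-transformed, box-bounded L-BFGS-B).
#' Any omega can be fixed (e.g. at 1 to test complete relaxation). On
#' non-convergence the optimizer restarts from jittered starting points
#' (deterministic jitter); a fit that still fails is returned with
#' `converged = FALSE`, never silently.
#'
#' @param aln A [codon_alignment].
#' @param tree Rooted bifurcating `ape::phylo`, tips in the alignment.
#' @param branch_classes Named character vector branch label -> class label
#'   (see [branch_labels()]); `NULL` for a single class `"all"`.
#' @param fixed_omega Named numeric vector of omegas to fix (names are class
#'   labels), e.g. `c(all = 1)`.
#' @param model_label Label stored on the fit (`"A"` .. `"E"` or custom).
#' @param pi Codon frequencies; default F3X4 from the alignment.
#' @param pi_method Frequency estimator when `pi` is `NULL`.
#' @param init Optional previous `codon_model_fit` used as a warm start.
#' @param control List of optimizer settings (see source for defaults).
#' @return A `codon_model_fit`: `lnL`, `np`, `kappa`, `omega` (named by
#'   class), `branch_lengths` (named by branch label), `converged`, etc.
#' @export
fit_model <- function(aln, tree, branch_classes = NULL, fixed_omega = NULL,
                      model_label = "custom", pi = NULL, pi_method = "F3X4",
                      init = NULL, control = list()) {
  ctl <- fit_control(control)
  prep <- prepare_pruning(aln, tree)
  if (is.null(pi)) pi <- codon_frequencies(aln, pi_method)

  labels <- prep$labels
  n_edge <- length(labels)
  if (is.null(branch_classes)) {
    branch_classes <- stats::setNames(rep("all", n_edge), labels)
  }
  if (!all(labels %in% names(branch_classes))) {
    stop("branch_classes must assign a class to every branch; missing: ",
         paste(utils::head(setdiff(labels, names(branch_classes)), 5), collapse = ", "),
         call. = FALSE)
  }
  cls <- branch_classes[labels]
  class_levels <- unique(cls)
  if (!is.null(fixed_omega)) {
    unknown <- setdiff(names(fixed_omega), class_levels)
    if (length(unknown) > 0) {
      stop("fixed_omega names not among branch classes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  free_classes <- setdiff(class_levels, names(fixed_omega))
  class_of_edge <- match(cls, class_levels)

  # starting values (warm start from a previous fit where available)
  kappa0 <- ctl$kappa_init
  omega0 <- stats::setNames(rep(ctl$omega_init, length(class_levels)), class_levels)
  bl0 <- if (!is.null(prep$tree$edge.length) && all(prep$tree$edge.length > 0)) {
    stats::setNames(pmax(prep$tree$edge.length, ctl$bl_bounds[1] * 10), labels)
  } else {
    stats::setNames(rep(ctl$bl_init, n_edge), labels)
  }
  if (!is.null(init) && inherits(init, "codon_model_fit")) {
    kappa0 <- init$kappa
    shared <- intersect(names(init$branch_lengths), labels)
    bl0[shared] <- init$branch_lengths[shared]
    for (cl in class_levels) {
      omega0[cl] <- if (cl %in% names(init$omega)) {
        init$omega[[cl]]
      } else if (length(init$omega) >= 1) {
        mean(init$omega)
      } else {
        ctl$omega_init
      }
    }
  }
  if (!is.null(fixed_omega)) omega0[names(fixed_omega)] <- fixed_omega
  omega0 <- pmin(pmax(omega0, ctl$omega_bounds[1]), ctl$omega_bounds[2])
  bl0 <- pmin(pmax(bl0, ctl$bl_bounds[1]), ctl$bl_bounds[2])
  kappa0 <- min(max(kappa0, ctl$kappa_bounds[1]), ctl$kappa_bounds[2])

  n_free <- length(free_classes)
  pack <- function(kappa, omega, bl) {
    c(log(kappa), if (n_free > 0) log(omega[free_classes]), log(bl[labels]))
  }
  unpack <- function(theta) {
    omega <- omega0
    if (n_free > 0) omega[free_classes] <- exp(theta[1L + seq_len(n_free)])
    if (!is.null(fixed_omega)) omega[names(fixed_omega)] <- fixed_omega
    list(kappa = exp(theta[1]), omega = omega,
         bl = exp(theta[(2L + n_free):length(theta)]))
  }

  negll <- function(theta) {
    p <- unpack(theta)
    out <- pruning_eval(prep, p$bl, class_of_edge, p$kappa,
                        as.numeric(p$omega), pi)
    v <- -sum(prep$weights * out$site_loglik)
    if (!is.finite(v)) v <- 1e12
    v
  }
  neggrad <- function(theta) {
    p <- unpack(theta)
    out <- pruning_eval(prep, p$bl, class_of_edge, p$kappa,
                        as.numeric(p$omega), pi, want_grad = TRUE)
    g_bl <- -as.numeric(out$deriv_ratio %*% prep$weights) * p$bl
    edge_w <- as.numeric(out$deriv_omega %*% prep$weights)
    edge_k <- as.numeric(out$deriv_kappa %*% prep$weights)
    g_kappa <- -sum(edge_k) * p$kappa
    g_omega <- vapply(free_classes, function(cl) {
      idx <- which(cls == cl)
      -sum(edge_w[idx]) * p$omega[[cl]]
    }, numeric(1))
    g <- c(g_kappa, g_omega, g_bl)
    if (any(!is.finite(g))) g[!is.finite(g)] <- 0
    g
  }

  lower <- c(log(ctl$kappa_bounds[1]), rep(log(ctl$omega_bounds[1]), n_free),
             rep(log(ctl$bl_bounds[1]), n_edge))
  upper <- c(log(ctl$kappa_bounds[2]), rep(log(ctl$omega_bounds[2]), n_free),
             rep(log(ctl$bl_bounds[2]), n_edge))

  theta0 <- pack(kappa0, omega0, bl0)
  best <- NULL
  for (attempt in 0:ctl$max_restarts) {
    th <- if (attempt == 0) theta0 else {
      with_preserved_seed(ctl$jitter_seed + attempt, {
        pmin(pmax(theta0 + stats::rnorm(length(theta0), 0, ctl$jitter_sd),
                  lower), upper)
      })
    }
    res <- tryCatch(
      stats::optim(th, negll, neggrad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = ctl$maxit, factr = ctl$factr)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    ok <- res$convergence %in% c(0L, 1L) && is.finite(res$value)
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$clean <- res$convergence == 0L && is.finite(res$value)
    }
    if (!is.null(best) && best$clean) break
  }
  if (is.null(best)) {
    stop("optimization failed on every restart", call. = FALSE)
  }
  if (!best$clean) {
    warning("model '", model_label, "' did not converge cleanly (code ",
            best$convergence, ")")
  }

  p <- unpack(best$par)
  fitted_tree <- prep$tree
  fitted_tree$edge.length <- as.numeric(p$bl)

  structure(list(
    lnL = -best$value,
    np = count_parameters(prep$n_tip, n_free),
    kappa = p$kappa,
    omega = p$omega,
    fixed_omega = fixed_omega,
    branch_lengths = stats::setNames(p$bl, labels),
    branch_classes = stats::setNames(cls, labels),
    pi = pi,
    converged = best$clean,
    model_label = model_label,
    n_tips = prep$n_tip,
    n_sites = ncol(aln$codon),
    tree = fitted_tree,
    optim = best[c("convergence", "counts", "message")]
  ), class = "codon_model_fit")
}

#' @export
print.codon_model_fit <- function(x, ...) {
  cat("<codon_model_fit> model ", x$model_label, ": lnL = ",
      formatC(x$lnL, format = "f", digits = 2), ", np = ", x$np,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  om <- x$omega
  show <- if (length(om) > 6) c(utils::head(om, 6)) else om
  cat("  kappa = ", formatC(x$kappa, digits = 4), "; omega: ",
      paste(sprintf("%s = %.4g", names(show), show), collapse = ", "),
      if (length(om) > 6) ", ...", "\n", sep = "")
  invisible(x)
}

#' Branch labels spanned by a clade
#'
#' Convenience for declaring foreground branch sets: all branches of the
#' clade defined by `tips` (its crown branches), optionally including the
#' stem branch above the MRCA.
#'
#' @param tree Rooted `ape::phylo`.
#' @param tips Tip labels whose MRCA defines the clade.
#' @param include_stem Include the branch above the MRCA (default `TRUE`).
#' @return Character vector of branch labels.
#' @export
clade_branches <- function(tree, tips, include_stem = TRUE) {
  stopifnot(all(tips %in% tree$tip.label))
  elab <- branch_labels(tree)
  if (length(tips) == 1L) {
    return(elab[tree$edge[, 2] == match(tips, tree$tip.label)])
  }
  mrca <- ape::getMRCA(tree, tips)
  # crown branches: every edge whose child lies within the mrca subtree
  in_clade <- integer(0)
  stack <- mrca
  while (length(stack) > 0) {
    v <- stack[1]; stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    in_clade <- c(in_clade, kids)
    stack <- c(stack, kids[kids > length(tree$tip.label)])
  }
  sel <- tree$edge[, 2] %in% in_clade
  if (include_stem) sel <- sel | tree$edge[, 2] == mrca
  elab[sel]
}
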