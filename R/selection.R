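# Nested likelihood-ratio tests over the branch-model suite (one-ratio,
# neutral-fixed, two-ratio, two-ratio-with-neutral-foreground, free-ratio)
# and a simplified selection-intensity (K) relaxation test.

#' Likelihood-ratio test from two log-likelihoods
#'
#' @param lnl_null,lnl_alt Log-likelihoods of the nested null and alternative
#'   models.
#' @param df Degrees of freedom (difference in free parameter counts), > 0.
#' @param null_label,alt_label Labels carried into the result.
#' @param tolerance A raw statistic in `(-tolerance, 0)` (optimizer noise) is
#'   clamped to 0 with a warning; more negative is an error.
#' @return One-row tibble: `null_label`, `alt_label`, `stat`, `df`,
#'   `p_value`, `p_formatted` (2-significant-digit scientific notation).
#' @export
lrt_from_loglik <- function(lnl_null, lnl_alt, df, null_label = "null",
                            alt_label = "alt", tolerance = 0.1) {
  if (df <= 0) stop("df must be positive (models must be nested)", call. = FALSE)
  stat <- 2 * (lnl_alt - lnl_null)
  if (stat < 0) {
    if (stat > -tolerance) {
      warning("negative LRT statistic (", formatC(stat, digits = 3),
              ") clamped to 0 (optimizer noise)")
      stat <- 0
    } else {
      stop("alternative log-likelihood is below the null by ",
           formatC(-stat / 2, digits = 6),
           "; models are mis-specified or unconverged", call. = FALSE)
    }
  }
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  tibble::tibble(
    null_label = null_label, alt_label = alt_label,
    stat = stat, df = as.integer(df), p_value = p,
    p_formatted = format_pvalue(p)
  )
}

format_pvalue <- function(p) {
  ifelse(p < 1e-300, "0", toupper(formatC(p, format = "e", digits = 2)))
}

#' Likelihood-ratio test between two fitted models
#'
#' @param fit_null,fit_alt Nested `codon_model_fit` objects
#'   (`fit_alt$np > fit_null$np`), both converged.
#' @param tolerance See [lrt_from_loglik()].
#' @return One-row tibble as in [lrt_from_loglik()].
#' @export
lrt <- function(fit_null, fit_alt, tolerance = 0.1) {
  stopifnot(inherits(fit_null, "codon_model_fit"),
            inherits(fit_alt, "codon_model_fit"))
  if (fit_alt$np <= fit_null$np) {
    stop("models are not nested: alternative np (", fit_alt$np,
         ") must exceed null np (", fit_null$np, ")", call. = FALSE)
  }
  if (!fit_null$converged || !fit_alt$converged) {
    stop("both fits must have converged", call. = FALSE)
  }
  lrt_from_loglik(fit_null$lnL, fit_alt$lnL, fit_alt$np - fit_null$np,
                  fit_null$model_label, fit_alt$model_label, tolerance)
}

#' Fit the branch-model suite and its nested comparisons
#'
#' Fits five branch models: A (one omega for all branches), B (omega fixed at
#' 1), C (foreground branches get their own omega2), D (foreground omega2
#' fixed at 1), E (free-ratio: every branch its own omega), sharing warm
#' starts along the nesting chain, and runs the comparisons B vs A, A vs C,
#' D vs C, C vs E. Optionally reports per-clade mean omega from Model E.
#'
#' @param aln A [codon_alignment].
#' @param tree Rooted bifurcating `ape::phylo`.
#' @param foreground_branches Branch labels (see [branch_labels()],
#'   [clade_branches()]) forming the foreground set for Models C/D.
#' @param clades Optional named list of tip-label vectors; for each, the mean
#'   Model E omega over the clade's branches is reported.
#' @param models Subset of `c("A","B","C","D","E")` to fit (default all).
#' @param pi,pi_method,control Passed to [fit_model()].
#' @return A `branch_model_suite`: list with `fits` (named list of fits),
#'   `table` (Table-style tibble of model rows), `comparisons` (LRT tibble),
#'   `clade_omega` (tibble or NULL).
#' @export
run_branch_model_suite <- function(aln, tree, foreground_branches,
                                   clades = NULL,
                                   models = c("A", "B", "C", "D", "E"),
                                   pi = NULL, pi_method = "F3X4",
                                   control = list()) {
  prep_labels <- branch_labels(ape::reorder.phylo(tree, "postorder"))
  need_fg <- any(c("C", "D") %in% models)
  if (need_fg) {
    if (length(foreground_branches) == 0) {
      stop("foreground branch set must be non-empty for Models C/D", call. = FALSE)
    }
    missing <- setdiff(foreground_branches, prep_labels)
    if (length(missing) > 0) {
      stop("foreground branches not in tree: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(pi)) pi <- codon_frequencies(aln, pi_method)
  two_ratio <- stats::setNames(
    ifelse(prep_labels %in% foreground_branches, "foreground", "background"),
    prep_labels
  )
  free_ratio <- stats::setNames(prep_labels, prep_labels)

  fits <- list()
  if ("A" %in% models) {
    fits$A <- fit_model(aln, tree, model_label = "A", pi = pi, control = control)
  }
  if ("B" %in% models) {
    fits$B <- fit_model(aln, tree, fixed_omega = c(all = 1), model_label = "B",
                        pi = pi, init = fits$A, control = control)
  }
  if ("C" %in% models) {
    fits$C <- fit_model(aln, tree, branch_classes = two_ratio, model_label = "C",
                        pi = pi, init = fits$A, control = control)
  }
  if ("D" %in% models) {
    fits$D <- fit_model(aln, tree, branch_classes = two_ratio,
                        fixed_omega = c(foreground = 1), model_label = "D",
                        pi = pi, init = fits$C %||% fits$A, control = control)
  }
  if ("E" %in% models) {
    fits$E <- fit_model(aln, tree, branch_classes = free_ratio, model_label = "E",
                        pi = pi, init = fits$C %||% fits$A, control = control)
  }

  describe <- c(
    A = "All branches have one omega",
    B = "All branches have omega = 1",
    C = "Foreground branches have omega2; others omega1",
    D = "Foreground branches have omega2 = 1; others omega1",
    E = "Each branch has its own omega"
  )
  table <- dplyr::bind_rows(lapply(names(fits), function(m) {
    f <- fits[[m]]
    om <- f$omega
    omega_txt <- if (m == "E") {
      "variable by branch"
    } else {
      paste(sprintf("%s = %.5f", names(om), om), collapse = ", ")
    }
    tibble::tibble(model = m, description = describe[[m]], omega = omega_txt,
                   lnL = f$lnL, np = f$np, converged = f$converged)
  }))

  pairs <- list(c("B", "A"), c("A", "C"), c("D", "C"), c("C", "E"))
  comparisons <- dplyr::bind_rows(lapply(pairs, function(pr) {
    if (!all(pr %in% names(fits))) return(NULL)
    lrt(fits[[pr[1]]], fits[[pr[2]]])
  }))

  clade_omega <- NULL
  if (!is.null(clades) && "E" %in% names(fits)) {
    clade_omega <- dplyr::bind_rows(lapply(names(clades), function(nm) {
      brs <- clade_branches(tree, clades[[nm]])
      tibble::tibble(
        clade = nm, n_branches = length(brs),
        mean_omega = mean(fits$E$omega[brs]),
        median_omega = stats::median(fits$E$omega[brs])
      )
    }))
  }

  structure(list(fits = fits, table = table, comparisons = comparisons,
                 clade_omega = clade_omega, foreground = foreground_branches),
            class = "branch_model_suite")
}

#' @export
print.branch_model_suite <- function(x, ...) {
  cat("<branch_model_suite>\n")
  print(as.data.frame(x$table[, c("model", "omega", "lnL", "np")]), row.names = FALSE)
  cat("\nComparisons:\n")
  print(as.data.frame(x$comparisons[, c("null_label", "alt_label", "stat", "df", "p_formatted")]),
        row.names = FALSE)
  invisible(x)
}

# ---- selection-intensity (K) relaxation test -------------------------------

relax_control <- function(control = list()) {
  defaults <- list(
    maxit = 200, factr = 1e7,
    k_bounds = c(0.02, 50), omega_bounds = c(1e-4, 5),
    kappa_bounds = c(0.05, 50), bl_bounds = c(1e-7, 10),
    omega_init = c(0.02, 0.2, 1.0)
  )
  utils::modifyList(defaults, control)
}

# mixture likelihood machinery shared by the null (K = 1) and alternative
relax_negll_factory <- function(prep, class_of_edge, pi, ctl, k_free,
                                weights) {
  n_edge <- nrow(prep$edge)
  # theta: log kappa | p_free (2, softmax) | log omega (3) | [log K] | log bl
  unpack <- function(theta) {
    kappa <- exp(theta[1])
    a <- c(0, theta[2:3])
    p <- exp(a) / sum(exp(a))
    omega <- exp(theta[4:6])
    K <- if (k_free) exp(theta[7]) else 1
    bl <- exp(theta[(if (k_free) 8 else 7):length(theta)])
    list(kappa = kappa, p = p, omega = omega, K = K, bl = bl)
  }
  eval_cats <- function(par, want_grad = FALSE) {
    lapply(1:3, function(k) {
      # class 1 = reference (omega_k), class 2 = test (omega_k^K)
      pruning_eval(prep, par$bl, class_of_edge, par$kappa,
                   c(par$omega[k], par$omega[k]^par$K), pi,
                   want_grad = want_grad)
    })
  }
  mix <- function(par, cats) {
    sll <- vapply(cats, `[[`, numeric(length(weights)), "site_loglik")
    m <- apply(sll, 1, max)
    lik <- exp(sll - m) %*% par$p
    list(site_loglik = m + log(lik), sll = sll, lik_rel = exp(sll - m),
         mix_rel = as.numeric(lik))
  }
  test_edges <- which(class_of_edge == 2L)
  ref_edges <- which(class_of_edge == 1L)
  negll <- function(theta) {
    par <- unpack(theta)
    v <- -sum(weights * mix(par, eval_cats(par))$site_loglik)
    if (!is.finite(v)) 1e12 else v
  }
  neggrad <- function(theta) {
    par <- unpack(theta)
    cats <- eval_cats(par, want_grad = TRUE)
    mx <- mix(par, cats)
    # posterior responsibility of category k per site pattern
    post <- sweep(mx$lik_rel, 2, par$p, `*`) / mx$mix_rel  # n_pat x 3
    wpost <- post * weights

    g_bl <- numeric(n_edge)
    g_kappa <- 0
    g_omega <- numeric(3)
    g_K <- 0
    for (k in 1:3) {
      g_bl <- g_bl + as.numeric(cats[[k]]$deriv_ratio %*% wpost[, k])
      g_kappa <- g_kappa + sum(colSums(cats[[k]]$deriv_kappa) * wpost[, k])
      rw_ref <- colSums(cats[[k]]$deriv_omega[ref_edges, , drop = FALSE])
      rw_test <- colSums(cats[[k]]$deriv_omega[test_edges, , drop = FALSE])
      # test-class omega is omega_k^K
      g_omega[k] <- sum((rw_ref + par$K * par$omega[k]^(par$K - 1) * rw_test) *
                          wpost[, k])
      g_K <- g_K + sum(rw_test * wpost[, k]) *
        par$omega[k]^par$K * log(par$omega[k])
    }
    # softmax proportions: d lnL / d a_m = sum_s w (post_m - p_m)
    g_p <- colSums(wpost[, 2:3, drop = FALSE]) -
      par$p[2:3] * sum(weights)
    g <- c(-g_kappa * par$kappa, -g_p,
           -g_omega * par$omega,
           if (k_free) -g_K * par$K,
           -g_bl * par$bl)
    if (any(!is.finite(g))) g[!is.finite(g)] <- 0
    g
  }
  list(unpack = unpack, negll = negll, neggrad = neggrad)
}

#' Selection-intensity (K) relaxation test
#'
#' A simplified three-category selection-intensity test: sites fall into
#' three omega categories shared across the tree; on the designated test
#' branches each category omega is raised to the power K. K < 1 drags every
#' category toward 1 (relaxation of both purifying and positive selection),
#' K > 1 intensifies selection. The null fixes K = 1; the LRT has one degree
#' of freedom. This is a deliberately reduced surrogate for full
#' random-effects selection-intensity machinery: it shares the K-exponent
#' idea but keeps a single shared site mixture.
#'
#' @param aln A [codon_alignment].
#' @param tree Rooted bifurcating `ape::phylo`.
#' @param test_branches Branch labels of the test set; must be a non-empty
#'   proper subset of the branches.
#' @param pi,pi_method Codon frequencies (default F3X4).
#' @param init Optional `codon_model_fit` supplying starting branch lengths
#'   and kappa (a one-ratio fit works well).
#' @param control Optimizer settings.
#' @return A `relax_fit`: `K`, `omega_categories` (tibble of proportion and
#'   reference omega per category), `lnL_null`, `lnL_alt`, `lrt` (tibble),
#'   `converged`.
#' @export
relaxation_k_test <- function(aln, tree, test_branches, pi = NULL,
                              pi_method = "F3X4", init = NULL,
                              control = list()) {
  ctl <- relax_control(control)
  prep <- prepare_pruning(aln, tree)
  labels <- prep$labels
  missing <- setdiff(test_branches, labels)
  if (length(missing) > 0) {
    stop("test branches not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(test_branches) == 0 || length(unique(test_branches)) >= length(labels)) {
    stop("test set must be a non-empty proper subset of branches", call. = FALSE)
  }
  if (is.null(pi)) pi <- codon_frequencies(aln, pi_method)
  class_of_edge <- ifelse(labels %in% test_branches, 2L, 1L)

  if (is.null(init)) {
    init <- fit_model(aln, tree, model_label = "one-ratio", pi = pi,
                      control = control)
  }
  bl0 <- pmin(pmax(init$branch_lengths[labels], ctl$bl_bounds[1]), ctl$bl_bounds[2])
  om0 <- pmin(pmax(ctl$omega_init, ctl$omega_bounds[1]), ctl$omega_bounds[2])

  run_one <- function(k_free, theta0 = NULL) {
    fac <- relax_negll_factory(prep, class_of_edge, pi, ctl, k_free, prep$weights)
    if (is.null(theta0)) {
      theta0 <- c(log(init$kappa), 0, 0, log(om0),
                  if (k_free) log(1), log(bl0))
    }
    n_edge <- length(labels)
    lower <- c(log(ctl$kappa_bounds[1]), -8, -8, rep(log(ctl$omega_bounds[1]), 3),
               if (k_free) log(ctl$k_bounds[1]), rep(log(ctl$bl_bounds[1]), n_edge))
    upper <- c(log(ctl$kappa_bounds[2]), 8, 8, rep(log(ctl$omega_bounds[2]), 3),
               if (k_free) log(ctl$k_bounds[2]), rep(log(ctl$bl_bounds[2]), n_edge))
    theta0 <- pmin(pmax(theta0, lower), upper)
    res <- stats::optim(theta0, fac$negll, fac$neggrad, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = ctl$maxit, factr = ctl$factr))
    list(res = res, par = fac$unpack(res$par))
  }

  # The mixture surface is multimodal, so null and alternative are chained:
  # the alternative warm-starts from the null solution (with K = 1), and the
  # null is then re-polished from the alternative's K = 1 projection; the
  # better of the two null runs is kept. This stops a poorly-optimized null
  # from masquerading as a relaxation signal.
  null_fit <- run_one(k_free = FALSE)
  th_null <- null_fit$res$par
  alt_fit <- run_one(k_free = TRUE,
                     theta0 = c(th_null[1:6], log(1), th_null[-(1:6)]))
  th_alt <- alt_fit$res$par
  null_fit2 <- run_one(k_free = FALSE, theta0 = th_alt[-7])
  if (null_fit2$res$value < null_fit$res$value) null_fit <- null_fit2

  lnL_null <- -null_fit$res$value
  lnL_alt <- -alt_fit$res$value
  # the null is nested in the alternative; guard against the alternative
  # optimizer landing marginally below it
  if (lnL_alt < lnL_null) lnL_alt <- lnL_null

  test <- lrt_from_loglik(lnL_null, lnL_alt, df = 1,
                          null_label = "K = 1", alt_label = "K free")
  structure(list(
    K = alt_fit$par$K,
    omega_categories = tibble::tibble(
      category = 1:3,
      proportion = alt_fit$par$p,
      omega_reference = alt_fit$par$omega,
      omega_test = alt_fit$par$omega^alt_fit$par$K
    ),
    lnL_null = lnL_null, lnL_alt = lnL_alt, lrt = test,
    kappa = alt_fit$par$kappa,
    test_branches = test_branches,
    converged = null_fit$res$convergence %in% c(0L, 1L) &&
      alt_fit$res$convergence %in% c(0L, 1L)
  ), class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  cat("<relax_fit> K = ", formatC(x$K, digits = 4),
      "  (K < 1: relaxation on test branches)\n", sep = "")
  cat("  LRT K=1 vs K free: stat = ", formatC(x$lrt$stat, digits = 4),
      ", p = ", x$lrt$p_formatted, "\n", sep = "")
  print(as.data.frame(x$omega_categories), row.names = FALSE)
  invisible(x)
}
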