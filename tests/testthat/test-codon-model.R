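equal_pi <- rep(1 / 61, 61)

test_that("the rate matrix is a scaled reversible generator", {
  Q <- build_rate_matrix(kappa = 2.5, omega = 0.3, pi = equal_pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(-sum(equal_pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance: diag(pi) Q symmetric
  PQ <- equal_pi * Q
  expect_lt(max(abs(PQ - t(PQ))), 1e-10)

  expect_error(build_rate_matrix(-1, 0.3, equal_pi), "kappa")
  expect_error(build_rate_matrix(2, -0.1, equal_pi), "omega")
})

test_that("omega = 0 removes every nonsynonymous rate", {
  Q <- build_rate_matrix(2, 0, equal_pi)
  aa <- codon_amino_acids()
  nonsyn <- outer(aa, aa, "!=")
  diag(nonsyn) <- FALSE
  expect_true(all(Q[nonsyn] == 0))
})

test_that("with equal pi, kappa = 1, omega = 1 all single-change rates agree", {
  # direct enumeration over the 61 x 61 entries
  Q <- build_rate_matrix(1, 1, equal_pi)
  codons <- sense_codons()
  nt <- do.call(rbind, strsplit(codons, ""))
  ndiff <- matrix(0L, 61, 61)
  for (p in 1:3) ndiff <- ndiff + outer(nt[, p], nt[, p], "!=")
  offdiag <- Q[ndiff == 1L]
  expect_equal(length(unique(round(offdiag, 14))), 1)
  expect_true(all(Q[ndiff > 1L] == 0))
})

test_that("transition probabilities are stochastic and match the series oracle", {
  Q <- build_rate_matrix(2, 0.2, equal_pi)
  P0 <- transition_probabilities(Q, 0, equal_pi)
  expect_equal(unname(P0), diag(61))
  P <- transition_probabilities(Q, 0.37, equal_pi)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  expect_true(all(P >= 0 & P <= 1))

  # truncated-series oracle on a 4-state reduction of the same generator:
  # collapse the problem by checking the full matrix against the series
  Pser <- genedecay:::expm_series(Q, 0.1)
  Peig <- transition_probabilities(Q, 0.1, equal_pi)
  expect_lt(max(abs(Pser - Peig)), 1e-10)

  expect_error(transition_probabilities(Q, -0.1, equal_pi), "nonnegative")
})

test_that("a single-tip likelihood reduces to the closed form", {
  seqs <- c(A = "ATGAAACCCGGGTTTACTTGGAAAGGGCAT",
            B = "ATGAAACCCGGGTTTACTTGGAAAGGGCAT")
  aln <- aln_from_strings(seqs)
  tree <- ape::read.tree(text = "(A:0.0,B:0.0);")
  pi <- codon_frequencies(aln, "F3X4")
  ll <- log_likelihood(aln, tree, list(kappa = 2, omega = c(all = 0.5), pi = pi))
  # zero-length branches: both tips must equal the root state, so the
  # likelihood is the product of root frequencies of the observed codons
  idx <- aln$codon["A", ]
  expect_equal(ll, sum(log(pi[idx])), tolerance = 1e-8)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  sim <- simulate_alignment(sim_config(n_taxa = 4, n_codons = 10, seed = 7,
                                       tree_depth = 0.3))
  pi <- codon_frequencies(sim$aln, "F3X4")
  for (om in c(0.1, 1)) {
    ll_prune <- log_likelihood(sim$aln, sim$tree,
                               list(kappa = 2, omega = c(all = om), pi = pi))
    ll_enum <- enumeration_loglik(sim$aln, sim$tree, 2, om, pi)
    expect_equal(ll_prune, unname(ll_enum), tolerance = 1e-8)
  }
})

test_that("missing data and pattern weighting behave exactly", {
  seqs <- c(A = "ATGAAACCCGGG", B = "ATGAAACCCGGG", C = "ATG---CCCGGG")
  aln <- aln_from_strings(seqs)
  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,C:0.2);")
  pi <- rep(1 / 61, 61)
  ll <- log_likelihood(aln, tree, list(kappa = 2, omega = c(all = 0.3), pi = pi))
  expect_true(is.finite(ll))

  # duplicating every column doubles the log-likelihood exactly
  seqs2 <- vapply(seqs, function(s) {
    paste(rep(substring(s, seq(1, 12, 3), seq(3, 12, 3)), each = 2), collapse = "")
  }, character(1))
  aln2 <- aln_from_strings(seqs2)
  ll2 <- log_likelihood(aln2, tree, list(kappa = 2, omega = c(all = 0.3), pi = pi))
  expect_equal(ll2, 2 * ll, tolerance = 1e-10)
})

test_that("likelihood is invariant to taxon order", {
  sim <- simulate_alignment(sim_config(n_taxa = 6, n_codons = 40, seed = 9))
  pi <- codon_frequencies(sim$aln)
  params <- list(kappa = 2, omega = c(all = 0.2), pi = pi)
  ll1 <- log_likelihood(sim$aln, sim$tree, params)
  perm <- rev(sim$aln$taxa)
  aln_perm <- codon_alignment(sim$aln$raw[perm, ], sim$aln$reference_taxon)
  ll2 <- log_likelihood(aln_perm, sim$tree, params)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences", {
  sim <- simulate_alignment(sim_config(n_taxa = 6, n_codons = 60, seed = 13))
  aln <- sim$aln
  pi <- codon_frequencies(aln)
  prep <- genedecay:::prepare_pruning(aln, sim$tree)
  bl <- prep$tree$edge.length
  cls <- rep(c(1L, 2L), length.out = nrow(prep$edge))
  om <- c(0.1, 0.7)
  out <- genedecay:::pruning_eval(prep, bl, cls, 2.3, om, pi, want_grad = TRUE)
  f <- function(kap, omv, blv) {
    o <- genedecay:::pruning_eval(prep, blv, cls, kap, omv, pi)
    sum(prep$weights * o$site_loglik)
  }
  h <- 1e-6
  for (e in c(1, 5, nrow(prep$edge))) {
    bp <- bl; bm <- bl; bp[e] <- bl[e] + h; bm[e] <- bl[e] - h
    expect_equal(sum(out$deriv_ratio[e, ] * prep$weights),
                 (f(2.3, om, bp) - f(2.3, om, bm)) / (2 * h), tolerance = 1e-4)
  }
  for (k in 1:2) {
    op <- om; omn <- om; op[k] <- om[k] + h; omn[k] <- om[k] - h
    expect_equal(sum(colSums(out$deriv_omega[cls == k, , drop = FALSE]) * prep$weights),
                 (f(2.3, op, bl) - f(2.3, omn, bl)) / (2 * h), tolerance = 1e-4)
  }
  expect_equal(sum(colSums(out$deriv_kappa) * prep$weights),
               (f(2.3 + h, om, bl) - f(2.3 - h, om, bl)) / (2 * h),
               tolerance = 1e-4)
})

test_that("the fitted model suite obeys the nesting chain", {
  sim <- miniature()
  st <- scan_all(sim$records, sim$aln)
  masked <- mask_lesions(sim$aln, all_events(st))
  fg <- clade_branches(sim$tree, sprintf("w%d", 1:6))
  suite <- run_branch_model_suite(masked, sim$tree, fg)
  ln <- stats::setNames(suite$table$lnL, suite$table$model)
  expect_true(ln[["E"]] >= ln[["C"]] - 1e-6)
  expect_true(ln[["C"]] >= ln[["A"]] - 1e-6)
  expect_true(ln[["A"]] >= ln[["B"]] - 1e-6)
  expect_true(ln[["C"]] >= ln[["D"]] - 1e-6)
  expect_true(all(suite$table$converged))
  # rooted parameter-count convention
  np <- stats::setNames(suite$table$np, suite$table$model)
  n <- length(sim$tree$tip.label)
  # 2n - 2 branch lengths + kappa + free omegas (1, 0, 2, 1, 2n - 2)
  expect_equal(unname(np[c("A", "B", "C", "D", "E")]),
               c(2 * n, 2 * n - 1, 2 * n + 1, 2 * n, 4 * n - 3))
})

test_that("one-ratio estimates recover the generating omega", {
  sim <- simulate_alignment(sim_config(n_taxa = 8, n_codons = 300, seed = 17,
                                       background_omega = 0.1))
  fit <- fit_model(sim$aln, sim$tree, model_label = "A")
  expect_true(fit$converged)
  expect_gt(fit$omega[["all"]], 0.05)
  expect_lt(fit$omega[["all"]], 0.2)
})

test_that("free-ratio parameter counts match the rooted convention at scale", {
  expect_equal(count_parameters(113, 2 * 113 - 2), 449L)
  expect_equal(count_parameters(119, 2 * 119 - 2), 473L)
})

test_that("tidiers expose parameters and fit summaries", {
  sim <- simulate_alignment(sim_config(n_taxa = 6, n_codons = 60, seed = 23))
  fit <- fit_model(sim$aln, sim$tree, model_label = "A",
                   control = list(maxit = 50))
  td <- tidy(fit)
  expect_setequal(unique(td$type), c("kappa", "omega", "branch_length"))
  expect_equal(nrow(td), 1 + 1 + 10) # kappa + omega + 2n-2 branches
  gl <- glance(fit)
  expect_equal(gl$np, 12)
  expect_equal(gl$logLik, fit$lnL)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
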