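test_that("LRT arithmetic from published log-likelihood pairs is exact", {
  tab <- utils::read.delim(
    system.file("extdata", "trpv3_published_lrt.tsv", package = "genedecay"),
    stringsAsFactors = FALSE
  )
  rows <- tab[!is.na(tab$published_stat), ]
  lnl_of <- function(ds, m) tab$lnL[tab$dataset == ds & tab$model == m]
  np_of <- function(ds, m) tab$np[tab$dataset == ds & tab$model == m]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    # the null is the member of the pair with fewer free parameters
    pair <- c(r$model, r$compared_to)
    nps <- vapply(pair, function(m) np_of(r$dataset, m), numeric(1))
    null_m <- pair[which.min(nps)]
    alt_m <- pair[which.max(nps)]
    res <- lrt_from_loglik(lnl_of(r$dataset, null_m), lnl_of(r$dataset, alt_m),
                           df = diff(range(nps)))
    expect_equal(res$stat, r$published_stat, tolerance = 1e-9,
                 info = paste(r$dataset, null_m, "vs", alt_m))
  }
})

test_that("LRT guards nesting, clamps optimizer noise, rejects real misfits", {
  res <- lrt_from_loglik(-100, -100, df = 1)
  expect_equal(res$stat, 0)
  expect_equal(res$p_value, 1)

  expect_warning(res2 <- lrt_from_loglik(-100, -100.01, df = 1), "clamped")
  expect_equal(res2$stat, 0)
  expect_error(lrt_from_loglik(-100, -110, df = 1), "below the null")
  expect_error(lrt_from_loglik(-100, -99, df = 0), "nested")

  # monotone: p decreases as the statistic grows, fixed df
  stats <- c(0.5, 2, 8, 30)
  ps <- vapply(stats, function(s) {
    lrt_from_loglik(-100, -100 + s / 2, df = 1)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  # p-value formatting mirrors 2-significant-digit scientific notation
  expect_match(lrt_from_loglik(-100, -92, df = 1)$p_formatted,
               "^[0-9]\\.[0-9]{2}E-[0-9]+$")
})

test_that("fitted-model LRT requires nesting and convergence", {
  sim <- simulate_alignment(sim_config(n_taxa = 6, n_codons = 80, seed = 31))
  fitA <- fit_model(sim$aln, sim$tree, model_label = "A")
  fitB <- fit_model(sim$aln, sim$tree, fixed_omega = c(all = 1),
                    model_label = "B", init = fitA)
  res <- lrt(fitB, fitA)
  expect_gt(res$stat, 0)
  expect_equal(res$df, 1L)
  expect_error(lrt(fitA, fitB), "not nested")
})

test_that("the model suite rejects bad foreground sets", {
  sim <- simulate_alignment(sim_config(n_taxa = 6, n_codons = 60, seed = 37))
  expect_error(
    run_branch_model_suite(sim$aln, sim$tree, character(0), models = c("A", "C")),
    "non-empty"
  )
  expect_error(
    run_branch_model_suite(sim$aln, sim$tree, "not_a_branch", models = c("A", "C")),
    "not in tree"
  )
})

test_that("relaxation K test validates its test set and finds no signal under the null", {
  sim <- simulate_alignment(sim_config(n_taxa = 8, n_codons = 200, seed = 41,
                                       background_omega = 0.15))
  labels <- branch_labels(ape::reorder.phylo(sim$tree, "postorder"))
  expect_error(relaxation_k_test(sim$aln, sim$tree, character(0)), "non-empty")
  expect_error(relaxation_k_test(sim$aln, sim$tree, labels), "proper subset")

  # test branches generated by the same process as the reference: no
  # systematic relaxation signal. Any single replicate can reject by chance,
  # so the assertion is on the median p over three replicates.
  ps <- vapply(c(41, 42, 43), function(seed) {
    simi <- simulate_alignment(sim_config(n_taxa = 8, n_codons = 200,
                                          seed = seed,
                                          background_omega = 0.15))
    lab <- branch_labels(ape::reorder.phylo(simi$tree, "postorder"))
    fit0 <- fit_model(simi$aln, simi$tree, model_label = "A")
    rx <- relaxation_k_test(simi$aln, simi$tree, lab[1:3], init = fit0)
    if (seed == 41) {
      expect_true(rx$converged)
      expect_equal(sum(rx$omega_categories$proportion), 1, tolerance = 1e-8)
      # test-branch omegas are the reference omegas raised to K
      expect_equal(rx$omega_categories$omega_test,
                   rx$omega_categories$omega_reference^rx$K, tolerance = 1e-12)
    }
    rx$lrt$p_value
  }, numeric(1))
  expect_gt(stats::median(ps), 0.05)
})

test_that("fixing K at 1 collapses test and reference branches exactly", {
  sim <- simulate_alignment(sim_config(n_taxa = 6, n_codons = 60, seed = 43))
  pi <- codon_frequencies(sim$aln)
  prep <- genedecay:::prepare_pruning(sim$aln, sim$tree)
  bl <- prep$tree$edge.length
  two_class <- rep(c(1L, 2L), length.out = nrow(prep$edge))
  for (w in c(0.05, 0.4, 1)) {
    split_ll <- genedecay:::pruning_eval(prep, bl, two_class, 2, c(w, w^1), pi)
    one_ll <- genedecay:::pruning_eval(prep, bl, rep(1L, nrow(prep$edge)), 2, w, pi)
    expect_equal(split_ll$site_loglik, one_ll$site_loglik, tolerance = 1e-12)
  }
})

test_that("relaxation is detected when test branches evolve neutrally", {
  whales <- c("w1", "w2")
  tree <- ape::read.tree(text = paste0(
    "(((w1:0.15,w2:0.15)wstem:0.1,(b1:0.1,b2:0.1)b12:0.1)i1:0.05,",
    "(b3:0.1,b4:0.1)b34:0.1)r;"
  ))
  fg <- clade_branches(tree, whales)
  sim <- simulate_alignment(sim_config(
    n_codons = 400, seed = 47, tree = tree, background_omega = 0.07,
    omega_by_branch = stats::setNames(rep(1, length(fg)), fg)
  ))
  rx <- relaxation_k_test(sim$aln, tree, fg)
  expect_lt(rx$K, 0.8)
  expect_lt(rx$lrt$p_value, 0.05)
})
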