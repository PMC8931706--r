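# Independent oracles used to cross-check the implementation. Everything in
# this file deliberately avoids the package's pruning / rate-matrix code
# paths wherever the quantity being checked is produced by them.

# Exhaustive-enumeration log-likelihood for small rooted binary trees:
# sums over every assignment of codon states to the internal nodes.
enumeration_loglik <- function(aln, tree, kappa, omega, pi,
                               branch_lengths = NULL) {
  tree_po <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree_po$tip.label)
  n_internal <- tree_po$Nnode
  stopifnot(n_internal <= 3) # 61^3 assignments is the practical ceiling
  Q <- build_rate_matrix(kappa, omega, pi)
  bl <- branch_lengths %||% tree_po$edge.length
  Plist <- lapply(bl, function(t) transition_probabilities(Q, t, pi))
  codmat <- aln$codon[tree_po$tip.label, , drop = FALSE]
  root <- n_tip + 1L
  # one row per joint assignment of codon states to the internal nodes
  grid <- as.matrix(expand.grid(rep(list(1:61), n_internal)))
  total_ll <- 0
  for (s in seq_len(ncol(codmat))) {
    tipstates <- codmat[, s]
    pr <- pi[grid[, 1]] # column 1 <-> root (node n_tip + 1)
    for (e in seq_len(nrow(tree_po$edge))) {
      pnode <- tree_po$edge[e, 1]
      cnode <- tree_po$edge[e, 2]
      pstates <- grid[, pnode - n_tip]
      if (cnode <= n_tip) {
        cs <- tipstates[cnode]
        if (is.na(cs)) next # missing tip: marginalised, P rows sum to 1
        pr <- pr * Plist[[e]][cbind(pstates, cs)]
      } else {
        pr <- pr * Plist[[e]][cbind(pstates, grid[, cnode - n_tip])]
      }
    }
    total_ll <- total_ll + log(sum(pr))
  }
  unname(total_ll)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Nei-Gojobori-style counting estimate of dN/dS between two ungapped,
# equal-length coding sequences (no correction for multiple hits beyond
# Jukes-Cantor; adequate as a sanity oracle on near-neutral simulations).
ng_dnds <- function(seq1, seq2) {
  gc_tab <- Biostrings::GENETIC_CODE
  codons1 <- substring(seq1, seq(1, nchar(seq1), 3), seq(3, nchar(seq1), 3))
  codons2 <- substring(seq2, seq(1, nchar(seq2), 3), seq(3, nchar(seq2), 3))
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(codon) {
    aa <- gc_tab[[codon]]
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, substr(codon, p, p))) {
        mut <- codon
        substr(mut, p, p) <- b
        if (!is.na(gc_tab[mut]) && gc_tab[[mut]] != "*" && gc_tab[[mut]] == aa) {
          s <- s + 1 / 3
        }
      }
    }
    s
  }
  count_diffs <- function(c1, c2) {
    # average over minimal mutation paths
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(pos) == 0) return(c(syn = 0, nonsyn = 0))
    paths <- combinat_permutations(pos)
    tallies <- matrix(0, nrow(paths), 2)
    for (r in seq_len(nrow(paths))) {
      cur <- c1
      for (p in paths[r, ]) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (is.na(gc_tab[cur]) || is.na(gc_tab[nxt]) ||
            gc_tab[[cur]] == "*" || gc_tab[[nxt]] == "*") {
          tallies[r, ] <- NA
          break
        }
        if (gc_tab[[cur]] == gc_tab[[nxt]]) tallies[r, 1] <- tallies[r, 1] + 1
        else tallies[r, 2] <- tallies[r, 2] + 1
        cur <- nxt
      }
    }
    tallies <- tallies[stats::complete.cases(tallies), , drop = FALSE]
    if (nrow(tallies) == 0) return(c(syn = 0, nonsyn = 0))
    c(syn = mean(tallies[, 1]), nonsyn = mean(tallies[, 2]))
  }
  S <- 0; N <- 0; sd_ <- 0; nd <- 0
  for (i in seq_along(codons1)) {
    c1 <- codons1[i]; c2 <- codons2[i]
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (is.na(gc_tab[c1]) || is.na(gc_tab[c2])) next
    if (gc_tab[[c1]] == "*" || gc_tab[[c2]] == "*") next
    s_sites <- (syn_sites(c1) + syn_sites(c2)) / 2
    S <- S + s_sites
    N <- N + 3 - s_sites
    d <- count_diffs(c1, c2)
    sd_ <- sd_ + d["syn"]
    nd <- nd + d["nonsyn"]
  }
  ps <- sd_ / S
  pn <- nd / N
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  unname(jc(pn) / jc(ps))
}

combinat_permutations <- function(x) {
  if (length(x) == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- combinat_permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

# Gillespie endpoint simulation of the codon CTMC: an independent check of
# transition-probability sampling.
gillespie_endpoint <- function(start_states, Q, t) {
  vapply(start_states, function(s0) {
    s <- s0
    time <- 0
    repeat {
      rate <- -Q[s, s]
      time <- time + stats::rexp(1, rate)
      if (time > t) break
      probs <- Q[s, ]
      probs[s] <- 0
      s <- sample.int(ncol(Q), 1, prob = probs)
    }
    s
  }, integer(1))
}

# Brute-force minimal Dollo gain set: smallest set of branches whose
# subtrees partition the carriers exactly (each gained subtree all-carrier).
brute_force_min_gains <- function(tree, carriers) {
  n_tip <- length(tree$tip.label)
  nodes <- seq_len(n_tip + tree$Nnode)
  desc <- lapply(nodes, function(v) {
    if (v <= n_tip) return(tree$tip.label[v])
    tree$tip.label[phangorn_descendants(tree, v)]
  })
  best <- Inf
  for (k in 1:min(4, length(carriers))) {
    combs <- utils::combn(nodes, k, simplify = FALSE)
    for (cmb in combs) {
      covered <- unlist(desc[cmb])
      if (length(covered) == length(unique(covered)) &&
          setequal(covered, carriers)) {
        best <- min(best, k)
      }
    }
    if (is.finite(best)) break
  }
  best
}

phangorn_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  out <- integer()
  stack <- node
  while (length(stack) > 0) {
    v <- stack[1]; stack <- stack[-1]
    if (v <= n_tip) out <- c(out, v)
    else stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
  }
  out
}
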