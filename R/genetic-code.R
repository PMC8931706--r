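# Codon-state machinery for the GY94-style substitution model.
# All model-facing matrices are indexed over the 61 sense codons of the
# standard (vertebrate nuclear) genetic code, in TCAG order as in
# Biostrings::GENETIC_CODE with the three stops removed.

.gd_cache <- new.env(parent = emptyenv())

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons, in a fixed order used by
#'   every model-facing matrix in the package.
#' @export
sense_codons <- function() {
  codon_structure()$codons
}

#' Amino-acid translation of the 61 sense codons
#' @return Named character vector, one-letter amino acids named by codon.
#' @export
codon_amino_acids <- function() {
  codon_structure()$aa
}

# Precomputed pair structure over sense codons: which ordered pairs differ at
# exactly one nucleotide, whether that change is a transition, and whether it
# is synonymous. Cached after first use.
codon_structure <- function() {
  if (!is.null(.gd_cache$structure)) {
    return(.gd_cache$structure)
  }
  gc_tab <- Biostrings::GENETIC_CODE
  stops <- names(gc_tab)[gc_tab == "*"]
  codons <- names(gc_tab)[gc_tab != "*"]
  aa <- gc_tab[codons]
  n <- length(codons)
  stopifnot(n == 61L)

  nt <- do.call(rbind, strsplit(codons, ""))
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)

  # n x n counts of differing positions; single-difference pairs only enter Q
  ndiff <- matrix(0L, n, n)
  pos_of_diff <- matrix(0L, n, n)
  for (p in 1:3) {
    d <- outer(nt[, p], nt[, p], "!=")
    ndiff <- ndiff + d
    pos_of_diff[d & pos_of_diff == 0L] <- p
  }
  single <- ndiff == 1L

  is_transition <- matrix(FALSE, n, n)
  for (p in 1:3) {
    same_class <- outer(purine[nt[, p]], purine[nt[, p]], "==")
    d <- outer(nt[, p], nt[, p], "!=")
    is_transition <- is_transition | (d & same_class & pos_of_diff == p)
  }
  is_synonymous <- outer(aa, aa, "==")

  .gd_cache$structure <- list(
    codons = codons, aa = unname(aa), stops = stops,
    nt = nt, single = single,
    transition = is_transition & single,
    synonymous = is_synonymous & single
  )
  .gd_cache$structure
}

#' Build the GY94 codon rate matrix
#'
#' Constructs the 61 x 61 generator of the Goldman--Yang codon model:
#' substitutions touching more than one codon position have rate 0; a single
#' nucleotide change i -> j has rate proportional to `pi[j]`, multiplied by
#' `kappa` if it is a transition and by `omega` if it is nonsynonymous.
#' Rows sum to zero and the matrix is rescaled so that branch lengths are in
#' expected substitutions per codon (-sum(pi * diag(Q)) == 1).
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega Nonsynonymous/synonymous rate ratio (dN/dS), >= 0.
#' @param pi Equilibrium frequencies of the 61 sense codons (summing to 1).
#' @return A 61 x 61 generator matrix with codon dimnames.
#' @export
build_rate_matrix <- function(kappa, omega, pi) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    stop("`kappa` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0) {
    stop("`omega` must be a single nonnegative number", call. = FALSE)
  }
  st <- codon_structure()
  n <- length(st$codons)
  if (length(pi) != n || any(pi <= 0) || abs(sum(pi) - 1) > 1e-6) {
    stop("`pi` must be 61 positive frequencies summing to 1", call. = FALSE)
  }
  pi <- pi / sum(pi)

  rate <- matrix(0, n, n, dimnames = list(st$codons, st$codons))
  rate[st$single] <- rep(pi, each = n)[st$single]
  rate[st$transition] <- rate[st$transition] * kappa
  nonsyn <- st$single & !st$synonymous
  rate[nonsyn] <- rate[nonsyn] * omega
  diag(rate) <- -rowSums(rate)
  scale <- -sum(pi * diag(rate))
  if (scale <= 0) {
    # omega = 0 with kappa tiny etc. can't actually reach here because
    # synonymous rates are always positive, but keep the guard honest
    stop("degenerate rate matrix: zero expected substitution rate", call. = FALSE)
  }
  rate / scale
}

# Q together with its partial derivatives wrt omega and kappa, all under the
# substitutions-per-codon scaling. With Q = Q0(kappa, omega) / c(kappa, omega)
# and c = -sum(pi * diag(Q0)):
#   dQ/dtheta = (dQ0/dtheta - (dc/dtheta) * Q) / c
# where dQ0/domega keeps only nonsynonymous entries (diag-corrected) and
# dQ0/dkappa only transition entries.
rate_matrix_derivs <- function(kappa, omega, pi) {
  st <- codon_structure()
  n <- length(st$codons)
  pi <- pi / sum(pi)
  base <- matrix(0, n, n)
  base[st$single] <- rep(pi, each = n)[st$single]
  nonsyn <- st$single & !st$synonymous
  ts <- st$transition

  Q0 <- base
  Q0[ts] <- Q0[ts] * kappa
  Q0[nonsyn] <- Q0[nonsyn] * omega
  diag(Q0) <- -rowSums(Q0)

  N0 <- base
  N0[ts] <- N0[ts] * kappa
  N0[!nonsyn] <- 0
  diag(N0) <- -rowSums(N0)

  T0 <- base
  T0[nonsyn] <- T0[nonsyn] * omega
  T0[!ts] <- 0
  diag(T0) <- -rowSums(T0)

  cc <- -sum(pi * diag(Q0))
  cN <- -sum(pi * diag(N0))
  cT <- -sum(pi * diag(T0))
  Q <- Q0 / cc
  list(
    Q = Q,
    dQ_omega = (N0 - cN * Q) / cc,
    dQ_kappa = (T0 - cT * Q) / cc
  )
}

# Equilibrium synonymous substitution flux of a generator: the expected
# number of synonymous substitutions per codon per unit branch length.
syn_flux <- function(Q, pi) {
  st <- codon_structure()
  sum((pi %o% rep(1, length(pi)))[st$synonymous] * Q[st$synonymous])
}

# Symmetric eigendecomposition of a reversible generator.
# Returns A, lambda, B with P(t) = A %*% diag(exp(lambda * t)) %*% B.
eigen_rate_matrix <- function(Q, pi) {
  sq <- sqrt(pi)
  S <- Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(
    A = (1 / sq) * e$vectors,       # diag(1/sqrt(pi)) %*% U
    B = t(e$vectors * sq),          # t(U) %*% diag(sqrt(pi))
    lambda = e$values
  )
}

#' Transition probabilities under a codon model
#'
#' Computes `P(t) = expm(Q t)` by symmetric eigendecomposition, exploiting the
#' reversibility of the GY94 generator. Falls back to scaling-and-squaring of
#' the series expansion if the decomposition is numerically unusable.
#'
#' @param Q Generator from [build_rate_matrix()].
#' @param t Branch length (expected substitutions per codon), >= 0.
#' @param pi Equilibrium frequencies used to build `Q`.
#' @return A 61 x 61 stochastic matrix.
#' @export
transition_probabilities <- function(Q, t, pi) {
  if (t < 0) stop("branch length `t` must be nonnegative", call. = FALSE)
  if (t == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  ed <- eigen_rate_matrix(Q, pi)
  P <- ed$A %*% (exp(ed$lambda * t) * ed$B)
  rs <- rowSums(P)
  if (any(!is.finite(P)) || any(abs(rs - 1) > 1e-6)) {
    warning("eigendecomposition unstable; falling back to scaling-and-squaring")
    P <- expm_series(Q, t)
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  P / rowSums(P)
}

# Scaling-and-squaring matrix exponential (fallback path only).
expm_series <- function(Q, t) {
  k <- max(0L, ceiling(log2(max(1, t * max(abs(diag(Q)))))))
  M <- Q * (t / 2^k)
  P <- diag(nrow(Q))
  term <- diag(nrow(Q))
  for (i in 1:30) {
    term <- term %*% M / i
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  dimnames(P) <- dimnames(Q)
  P
}

#' Codon equilibrium frequencies from an alignment
#'
#' @param aln A [codon_alignment].
#' @param method `"F3X4"` (position-specific nucleotide frequencies, the
#'   default), `"F1X4"` (pooled nucleotide frequencies), or `"EQUAL"`.
#' @param pseudocount Added to every nucleotide count so all codon frequencies
#'   stay strictly positive.
#' @return Numeric vector of 61 frequencies summing to 1, named by codon.
#' @export
codon_frequencies <- function(aln, method = c("F3X4", "F1X4", "EQUAL"),
                              pseudocount = 0.5) {
  method <- match.arg(method)
  st <- codon_structure()
  n <- length(st$codons)
  if (method == "EQUAL") {
    return(stats::setNames(rep(1 / n, n), st$codons))
  }
  obs <- st$codons[aln$codon[!is.na(aln$codon)]]
  ntm <- do.call(rbind, strsplit(obs, ""))
  bases <- c("T", "C", "A", "G")
  if (method == "F1X4") {
    f <- table(factor(ntm, levels = bases)) + 3 * pseudocount
    f <- as.numeric(f / sum(f))
    freq <- matrix(f, nrow = 3, ncol = 4, byrow = TRUE)
  } else {
    freq <- t(vapply(1:3, function(p) {
      f <- table(factor(ntm[, p], levels = bases)) + pseudocount
      as.numeric(f / sum(f))
    }, numeric(4)))
  }
  colnames(freq) <- bases
  pi <- freq[1, st$nt[, 1]] * freq[2, st$nt[, 2]] * freq[3, st$nt[, 3]]
  stats::setNames(pi / sum(pi), st$codons)
}
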