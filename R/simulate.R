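# Truth-labelled simulator: codon alignments evolved under per-branch omega
# (with optional mid-branch switches to neutral evolution), plus injected
# lesions of every scanned class, emitted with exon/splice tables, a time
# table, and an exact truth record so every pipeline stage can be tested
# offline.
#
# All randomness flows through one RNG stream keyed by the seed, consumed in
# a fixed order: (1) tree if random, (2) root codons, (3) per-edge
# substitutions in cladewise edge order (functional segment then neutral
# segment), (4) inserted nucleotides for insertion lesions in sorted group
# order, (5) random lesion positions.

#' Build and validate a simulation configuration
#'
#' @param n_taxa Number of tips (ignored when `tree` is supplied).
#' @param n_codons Number of evolving codon sites. The emitted CDS adds a
#'   start codon in front and a stop codon behind, so full CDS length is
#'   `3 * (n_codons + 2)` nt.
#' @param seed RNG seed (mandatory: simulations must be reproducible).
#' @param tree Optional rooted bifurcating `ape::phylo`; otherwise a random
#'   birth tree is drawn and rescaled to `tree_depth`.
#' @param tree_depth Root-to-tip height (expected substitutions per codon)
#'   for random trees.
#' @param kappa Transition/transversion ratio.
#' @param background_omega dN/dS on branches without an override.
#' @param omega_by_branch Named numeric vector of per-branch omega overrides
#'   (names are branch labels, see [branch_labels()]).
#' @param switchpoints Named numeric vector, branch label -> fraction f of
#'   the branch duration (at its recent end) evolved neutrally (omega = 1);
#'   the first (1 - f) of the branch uses the branch's functional omega.
#' @param lesions Tibble of lesions to inject, with columns `species`,
#'   `type` (START_LOSS, PREMATURE_STOP, STOP_LOSS, FRAMESHIFT_INDEL,
#'   INFRAME_INDEL, SPLICE_SITE), `codon_index` (full-CDS codon coordinate;
#'   NA = drawn at random for stops), `length` (signed nt for indels:
#'   positive insertion, negative deletion), `junction_index` and `site`
#'   ("donor"/"acceptor") for splice lesions, `obs_state` (optional observed
#'   state; sensible defaults per type).
#' @param n_exons Number of exons in the emitted annotation template.
#' @param pi Codon frequencies for the root draw and the model (default
#'   equal over the 61 sense codons).
#' @param time_scale Ma per unit branch length, used for the emitted
#'   divergence-time table.
#' @param time_jitter Half-width (as a fraction of T) of the emitted time
#'   intervals; 0 gives degenerate (exact) intervals.
#' @param reference_taxon Taxon used for indel polarity (defaults to the
#'   alphabetically first tip); it may not carry indel lesions.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_taxa = 16, n_codons = 500, seed,
                       tree = NULL, tree_depth = 0.4, kappa = 2,
                       background_omega = 0.07, omega_by_branch = NULL,
                       switchpoints = NULL, lesions = NULL, n_exons = 5,
                       pi = NULL, time_scale = 100, time_jitter = 0,
                       reference_taxon = NULL) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_codons >= 10, n_exons >= 1)
  if (!is.null(switchpoints)) {
    if (any(switchpoints < 0 | switchpoints > 1)) {
      stop("switchpoint fractions must lie in [0, 1]", call. = FALSE)
    }
  }
  n_cds_codons <- n_codons + 2L
  if (!is.null(lesions)) {
    lesions <- tibble::as_tibble(lesions)
    for (col in c("codon_index", "length", "junction_index", "site", "obs_state")) {
      if (!col %in% names(lesions)) {
        lesions[[col]] <- if (col %in% c("site", "obs_state")) NA_character_ else NA_integer_
      }
    }
    ok_types <- c("START_LOSS", "PREMATURE_STOP", "STOP_LOSS",
                  "FRAMESHIFT_INDEL", "INFRAME_INDEL", "SPLICE_SITE")
    if (!all(lesions$type %in% ok_types)) {
      stop("unknown lesion type(s): ",
           paste(setdiff(lesions$type, ok_types), collapse = ", "), call. = FALSE)
    }
    pos <- lesions$codon_index
    if (any(!is.na(pos) & (pos < 1 | pos > n_cds_codons))) {
      stop("lesion codon_index exceeds the CDS (1..", n_cds_codons, ")", call. = FALSE)
    }
    junc <- lesions$junction_index[lesions$type == "SPLICE_SITE"]
    if (any(is.na(junc)) || any(junc < 1 | junc > n_exons - 1)) {
      stop("splice lesions need junction_index in 1..", n_exons - 1, call. = FALSE)
    }
    idl <- lesions$length[lesions$type %in% c("FRAMESHIFT_INDEL", "INFRAME_INDEL")]
    if (any(is.na(idl) | idl == 0)) {
      stop("indel lesions need a nonzero signed `length`", call. = FALSE)
    }
    fs_ok <- abs(lesions$length) %% 3 != 0
    bad_fs <- lesions$type == "FRAMESHIFT_INDEL" & !is.na(lesions$length) & !fs_ok
    bad_if <- lesions$type == "INFRAME_INDEL" & !is.na(lesions$length) & fs_ok
    if (any(bad_fs) || any(bad_if)) {
      stop("indel type/length mismatch: frameshifts need length %% 3 != 0, ",
           "in-frame indels length %% 3 == 0", call. = FALSE)
    }
  }
  structure(list(
    n_taxa = n_taxa, n_codons = n_codons, seed = seed, tree = tree,
    tree_depth = tree_depth, kappa = kappa,
    background_omega = background_omega,
    omega_by_branch = omega_by_branch, switchpoints = switchpoints,
    lesions = lesions, n_exons = n_exons, pi = pi,
    time_scale = time_scale, time_jitter = time_jitter,
    reference_taxon = reference_taxon
  ), class = "sim_config")
}

sample_through <- function(states, P) {
  out <- integer(length(states))
  for (y in unique(states)) {
    idx <- which(states == y)
    out[idx] <- sample.int(ncol(P), length(idx), replace = TRUE, prob = P[y, ])
  }
  out
}

default_obs <- function(type, site) {
  switch(type,
    START_LOSS = "ATA", PREMATURE_STOP = "TAA", STOP_LOSS = "TGC",
    SPLICE_SITE = if (identical(site, "donor")) "GA" else "AA",
    NA_character_
  )
}

#' Simulate a truth-labelled dataset
#'
#' Evolves codon sequences along a tree under a GY94 model with per-branch
#' omega and optional mid-branch switches to neutral evolution, injects the
#' configured lesions post hoc (so truth labels are exact), and writes the
#' full file bundle: alignment FASTA, ungapped CDS FASTA, newick tree,
#' exon/splice TSV, divergence-time TSV, and a truth JSON.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list with the in-memory objects (`aln`, `records`,
#'   `tree`, `time_table`, `truth`) and `files` (paths, when written).
#' @export
simulate_alignment <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  # (1) tree
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rphylo(config$n_taxa, birth = 1, death = 0)
    tree$tip.label <- sprintf("sp%02d", seq_len(config$n_taxa))
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * config$tree_depth / depth
  }
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    stop("simulation tree must be rooted and bifurcating", call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  elab <- branch_labels(tree_cw)

  omega_edge <- stats::setNames(rep(config$background_omega, length(elab)), elab)
  if (!is.null(config$omega_by_branch)) {
    unknown <- setdiff(names(config$omega_by_branch), elab)
    if (length(unknown) > 0) {
      stop("omega override for unknown branch: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    omega_edge[names(config$omega_by_branch)] <- config$omega_by_branch
  }
  switch_edge <- stats::setNames(rep(0, length(elab)), elab)
  if (!is.null(config$switchpoints)) {
    unknown <- setdiff(names(config$switchpoints), elab)
    if (length(unknown) > 0) {
      stop("switchpoint for unknown branch: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    switch_edge[names(config$switchpoints)] <- config$switchpoints
  }

  st <- codon_structure()
  pi <- config$pi %||% rep(1 / 61, 61)

  # (2) root codons, (3) evolution in cladewise edge order
  n_sites <- config$n_codons
  seqs <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1L
  seqs[[root]] <- sample.int(61, n_sites, replace = TRUE, prob = pi)
  P_cache <- new.env(parent = emptyenv())
  get_P <- function(omega, t, rate = 1) {
    key <- paste(format(c(omega, t, rate), digits = 12), collapse = "_")
    if (is.null(P_cache[[key]])) {
      Q <- build_rate_matrix(config$kappa, omega, pi)
      P_cache[[key]] <- transition_probabilities(Q, rate * t, pi)
    }
    P_cache[[key]]
  }
  # On two-period branches the branch length stays calendar-proportional:
  # the neutral segment is rescaled so its synonymous flux matches the
  # functional segment's (dS ticks uniformly in time; dN scales with omega),
  # which is the regime the two-period dating equations describe.
  neutral_rate <- function(omega_f) {
    qf <- build_rate_matrix(config$kappa, omega_f, pi)
    qn <- build_rate_matrix(config$kappa, 1, pi)
    syn_flux(qf, pi) / syn_flux(qn, pi)
  }
  for (e in seq_len(nrow(tree_cw$edge))) {
    parent <- tree_cw$edge[e, 1]; child <- tree_cw$edge[e, 2]
    t_e <- tree_cw$edge.length[e]
    f <- switch_edge[elab[e]]
    om_e <- omega_edge[elab[e]]
    s <- seqs[[parent]]
    if (f < 1 && t_e > 0) s <- sample_through(s, get_P(om_e, (1 - f) * t_e))
    if (f > 0 && t_e > 0) {
      s <- sample_through(s, get_P(1, f * t_e, rate = neutral_rate(om_e)))
    }
    seqs[[child]] <- s
  }

  # assemble alignment rows: ATG + evolved codons + TAA
  codons <- st$codons
  taxa <- tree$tip.label
  n_cds_nt <- 3L * (n_sites + 2L)
  M <- matrix("-", n_tip, n_cds_nt, dimnames = list(taxa, NULL))
  for (i in seq_len(n_tip)) {
    cds <- paste0("ATG", paste(codons[seqs[[i]]], collapse = ""), "TAA")
    M[taxa[i], ] <- strsplit(cds, "")[[1]]
  }

  reference <- config$reference_taxon %||% sort(taxa)[1]
  if (!reference %in% taxa) stop("reference taxon not a tip", call. = FALSE)

  # exon template over the reference CDS
  bounds <- round(seq(0, n_cds_nt, length.out = config$n_exons + 1))
  exon_template <- diff(bounds)
  splice_template <- tibble::tibble(
    donor = rep("GT", max(0, config$n_exons - 1)),
    acceptor = rep("AG", max(0, config$n_exons - 1))
  )
  exon_lengths <- stats::setNames(rep(list(exon_template), n_tip), taxa)
  splice_tabs <- stats::setNames(rep(list(splice_template), n_tip), taxa)

  # (4, 5) lesion injection
  lesions <- config$lesions
  truth_lesions <- tibble::tibble()
  if (!is.null(lesions) && nrow(lesions) > 0) {
    bad_sp <- setdiff(lesions$species, taxa)
    if (length(bad_sp) > 0) {
      stop("lesion species not in tree: ", paste(bad_sp, collapse = ", "), call. = FALSE)
    }
    is_indel <- lesions$type %in% c("FRAMESHIFT_INDEL", "INFRAME_INDEL")
    if (any(is_indel & lesions$species == reference)) {
      stop("indel lesions may not target the reference taxon (", reference, ")",
           call. = FALSE)
    }
    # random positions for stops drawn now, in row order
    for (i in which(lesions$type == "PREMATURE_STOP" & is.na(lesions$codon_index))) {
      lesions$codon_index[i] <- sample(2:(n_sites + 1L), 1L)
    }
    lesions$obs_state <- ifelse(is.na(lesions$obs_state),
                                vapply(seq_len(nrow(lesions)), function(i) {
                                  default_obs(lesions$type[i], lesions$site[i])
                                }, character(1)),
                                lesions$obs_state)

    # point lesions (codon replacements)
    pts <- lesions[lesions$type %in% c("START_LOSS", "PREMATURE_STOP", "STOP_LOSS"), ]
    for (i in seq_len(nrow(pts))) {
      ci <- pts$codon_index[i]
      if (pts$type[i] == "START_LOSS") ci <- 1L
      if (pts$type[i] == "STOP_LOSS") ci <- n_sites + 2L
      cols <- (3L * (ci - 1L) + 1L):(3L * ci)
      M[pts$species[i], cols] <- strsplit(pts$obs_state[i], "")[[1]]
      pts$codon_index[i] <- ci
    }

    # deletions first (no column changes), then insertions (new columns,
    # applied right-to-left so positions stay valid)
    dels <- lesions[is_indel & lesions$length < 0, ]
    for (i in seq_len(nrow(dels))) {
      p <- 3L * (dels$codon_index[i] - 1L) + 1L
      len <- -dels$length[i]
      if (p + len - 1L > n_cds_nt) stop("deletion runs past the CDS", call. = FALSE)
      M[dels$species[i], p:(p + len - 1L)] <- "-"
    }
    ins <- lesions[is_indel & lesions$length > 0, ]
    ins_groups <- if (nrow(ins) > 0) {
      split(ins, paste(ins$codon_index, ins$length, sep = "_"))
    } else {
      list()
    }
    ref_coord <- seq_len(ncol(M)) # original coordinate of each current column
    for (gk in rev(names(sort(vapply(ins_groups, function(g) g$codon_index[1], numeric(1)))))) {
      g <- ins_groups[[gk]]
      p <- 3L * (g$codon_index[1] - 1L) # insert after original nt p
      len <- g$length[1]
      inserted <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      cur <- max(which(ref_coord <= p), 0L)
      newcols <- matrix("-", n_tip, len, dimnames = list(taxa, NULL))
      for (sp in g$species) newcols[sp, ] <- inserted
      M <- cbind(M[, seq_len(cur), drop = FALSE], newcols,
                 M[, setdiff(seq_len(ncol(M)), seq_len(cur)), drop = FALSE])
      ref_coord <- c(ref_coord[seq_len(cur)], rep(NA_integer_, len),
                     ref_coord[setdiff(seq_along(ref_coord), seq_len(cur))])
    }

    # splice lesions: rewrite annotation dinucleotides
    spl <- lesions[lesions$type == "SPLICE_SITE", ]
    for (i in seq_len(nrow(spl))) {
      tab <- splice_tabs[[spl$species[i]]]
      if (identical(spl$site[i], "donor")) {
        tab$donor[spl$junction_index[i]] <- spl$obs_state[i]
      } else {
        tab$acceptor[spl$junction_index[i]] <- spl$obs_state[i]
      }
      splice_tabs[[spl$species[i]]] <- tab
    }

    # per-species exon lengths absorb net indel length in the affected exon
    for (i in which(is_indel)) {
      sp <- lesions$species[i]
      p <- max(1L, 3L * (lesions$codon_index[i] - 1L))
      exon_of <- findInterval(p, bounds, left.open = TRUE, rightmost.closed = TRUE)
      exon_of <- min(max(exon_of, 1L), config$n_exons)
      lens <- exon_lengths[[sp]]
      lens[exon_of] <- lens[exon_of] + lesions$length[i]
      if (lens[exon_of] < 1) stop("indel erases exon ", exon_of, " of ", sp, call. = FALSE)
      exon_lengths[[sp]] <- lens
    }

    truth_lesions <- dplyr::bind_rows(pts, dels, ins, spl)
  }

  aln <- codon_alignment(M, reference)
  cds <- vapply(taxa, function(sp) {
    paste(M[sp, M[sp, ] != "-"], collapse = "")
  }, character(1))

  records <- tibble::tibble(
    species_id = taxa,
    cds = unname(cds),
    exon_lengths = unname(exon_lengths[taxa]),
    splice_sites = unname(splice_tabs[taxa]),
    coverage_fraction = pmin(1, nchar(unname(cds)) / n_cds_nt)
  )

  # time table: one interval per branch, T = length * time_scale
  tt <- tibble::tibble(
    label = elab,
    t_mid = tree_cw$edge.length * config$time_scale
  )
  tt$t_lower <- pmax(tt$t_mid * (1 - config$time_jitter), 1e-6)
  tt$t_upper <- tt$t_mid * (1 + config$time_jitter)
  time_table <- tt[, c("label", "t_lower", "t_upper")]

  truth <- list(
    seed = config$seed, kappa = config$kappa, pi = pi,
    background_omega = config$background_omega,
    branches = tibble::tibble(
      branch = elab, length = tree_cw$edge.length,
      omega = unname(omega_edge[elab]), switchpoint = unname(switch_edge[elab])
    ),
    lesions = truth_lesions,
    reference_taxon = reference,
    n_codons = config$n_codons
  )

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      alignment = file.path(dir, "alignment.fasta"),
      cds = file.path(dir, "cds.fasta"),
      tree = file.path(dir, "tree.nwk"),
      exons = file.path(dir, "exons.tsv"),
      times = file.path(dir, "times.tsv"),
      truth = file.path(dir, "truth.json")
    )
    write_codon_alignment(aln, files$alignment)
    write_fasta(cds, files$cds)
    ape::write.tree(tree, files$tree)
    write_exon_table(records, files$exons)
    utils::write.table(as.data.frame(time_table), files$times, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth_json <- truth
    truth_json$branches <- as.data.frame(truth$branches)
    truth_json$lesions <- as.data.frame(truth$lesions)
    truth_json$manifest <- basename(vapply(files, identity, character(1)))
    jsonlite::write_json(truth_json, files$truth, auto_unbox = TRUE, digits = NA)
  }

  invisible(list(aln = aln, records = records, tree = tree,
                 time_table = time_table, truth = truth, files = files))
}

#' Expected scanner events for a simulated dataset
#'
#' Translates the truth lesion list of a simulation into the exact event
#' table the scanner should report: point lesions in the species' own
#' ungapped-CDS codon coordinates (accounting for any upstream indels in
#' that species), indels in reference-frame coordinates with signed length,
#' splice lesions by junction and dinucleotide. A point lesion knocked out
#' of frame by an upstream frameshift in the same species is an error: such
#' a configuration has no well-defined truth label.
#'
#' @param sim Result of [simulate_alignment()].
#' @return An event tibble comparable with [scan_gene()] output (columns
#'   `species_id`, `event_type`, `codon_index`, `junction_index`,
#'   `obs_state`, `inactivating`).
#' @export
sim_expected_events <- function(sim) {
  les <- sim$truth$lesions
  if (is.null(les) || nrow(les) == 0) {
    return(event_tibble()[, c("species_id", "event_type", "codon_index",
                              "junction_index", "obs_state", "inactivating")])
  }
  aln <- sim$aln
  species_codon <- function(sp, ci) {
    cols <- aln$frame_cols[(3L * (ci - 1L) + 1L):(3L * ci)]
    row <- aln$raw[sp, ]
    offset <- if (cols[1] > 1) sum(row[seq_len(cols[1] - 1L)] != "-") else 0L
    if (offset %% 3L != 0L) {
      stop("point lesion at codon ", ci, " is out of frame in ", sp, call. = FALSE)
    }
    offset %/% 3L + 1L
  }
  rows <- lapply(seq_len(nrow(les)), function(i) {
    type <- les$type[i]; sp <- les$species[i]
    if (type %in% c("START_LOSS", "PREMATURE_STOP", "STOP_LOSS")) {
      ci <- if (type == "STOP_LOSS") {
        sum(aln$raw[sp, ] != "-") %/% 3L
      } else {
        species_codon(sp, les$codon_index[i])
      }
      tibble::tibble(species_id = sp, event_type = type,
                     codon_index = as.integer(ci), junction_index = NA_integer_,
                     obs_state = les$obs_state[i], inactivating = TRUE)
    } else if (type %in% c("FRAMESHIFT_INDEL", "INFRAME_INDEL")) {
      tibble::tibble(species_id = sp, event_type = type,
                     codon_index = as.integer(les$codon_index[i]),
                     junction_index = NA_integer_,
                     obs_state = sprintf("%+d", les$length[i]),
                     inactivating = type == "FRAMESHIFT_INDEL")
    } else {
      tibble::tibble(species_id = sp, event_type = "SPLICE_SITE",
                     codon_index = NA_integer_,
                     junction_index = as.integer(les$junction_index[i]),
                     obs_state = paste0(les$site[i], ":", les$obs_state[i]),
                     inactivating = TRUE)
    }
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$species_id, .data$event_type,
                 .data$codon_index, .data$junction_index)
}

#' The tutorial miniature dataset
#'
#' A fixed-seed 16-taxon, 500-codon dataset with the qualitative design of a
#' gene-loss study: a 6-tip "whale-like" clade under relaxed selection
#' (omega 0.5) carrying a premature stop shared by all six tips (so it maps
#' to the clade's stem) plus assorted private lesions; two intact
#' "manatee/hippo-like" tips with elevated omega and no lesions; and an
#' 8-tip purifying background at omega 0.07.
#'
#' @param dir Output directory for the file bundle; `NULL` keeps everything
#'   in memory.
#' @param n_codons Number of evolving codons (default 500).
#' @param seed RNG seed (fixed default so the fixture is stable).
#' @return As [simulate_alignment()], invisibly.
#' @export
preset_study_miniature <- function(dir = NULL, n_codons = 500, seed = 42) {
  whales <- sprintf("w%d", 1:6)
  others <- c("m1", "h1", sprintf("b%d", 1:8))
  nwk <- paste0(
    "(((((w1:0.02,w2:0.02)wAB:0.02,(w3:0.02,w4:0.02)wCD:0.02)wABCD:0.02,",
    "(w5:0.03,w6:0.03)wEF:0.03)whale:0.06,",
    "(m1:0.08,h1:0.08)relaxed:0.04)aquatic:0.05,",
    "(((b1:0.04,b2:0.04)bA:0.04,(b3:0.04,b4:0.04)bB:0.04)bAB:0.04,",
    "((b5:0.04,b6:0.04)bC:0.04,(b7:0.04,b8:0.04)bD:0.04)bCD:0.04)bg:0.05)root;"
  )
  tree <- ape::read.tree(text = nwk)
  whale_branches <- clade_branches(tree, whales)
  om <- stats::setNames(rep(0.5, length(whale_branches)), whale_branches)
  om[c("m1", "h1")] <- 0.5
  # lesion positions scale with the alignment so reduced-size fixtures stay
  # valid; all six scanned lesion classes are represented
  at <- function(f) as.integer(max(2, round(f * n_codons)))
  lesions <- tibble::tibble(
    species = c(whales,              # shared stop across the whale clade
                "w1", "w2", "w3", "w4", "w5", "w4", "w5"),
    type = c(rep("PREMATURE_STOP", 6),
             "SPLICE_SITE", "START_LOSS", "FRAMESHIFT_INDEL",
             "INFRAME_INDEL", "INFRAME_INDEL", "PREMATURE_STOP",
             "FRAMESHIFT_INDEL"),
    codon_index = c(rep(at(0.24), 6), NA, 1L, at(0.40), at(0.52), at(0.52),
                    at(0.62), at(0.80)),
    length = c(rep(NA, 6), NA, NA, 1L, -6L, -6L, NA, -2L),
    junction_index = c(rep(NA, 6), 2L, NA, NA, NA, NA, NA, NA),
    site = c(rep(NA, 6), "acceptor", NA, NA, NA, NA, NA, NA),
    obs_state = NA_character_
  )
  cfg <- sim_config(
    n_codons = n_codons, seed = seed, tree = tree,
    background_omega = 0.07, omega_by_branch = om,
    switchpoints = stats::setNames(rep(0.5, 6), whales),
    lesions = lesions, n_exons = 5, time_scale = 100
  )
  simulate_alignment(cfg, dir)
}
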