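# Shared fixtures, built in code. Expensive objects are cached once per test
# run.

# tiny codon alignment straight from sequence strings
aln_from_strings <- function(seqs, reference = names(seqs)[1]) {
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(mat) <- names(seqs)
  codon_alignment(mat, reference)
}

write_temp_fasta <- function(seqs) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}

balanced_tree8 <- function() {
  ape::read.tree(text = paste0(
    "(((A:0.05,B:0.05)ab:0.05,(C:0.05,D:0.05)cd:0.05)abcd:0.05,",
    "((E:0.05,F:0.05)ef:0.05,(G:0.05,H:0.05)gh:0.05)efgh:0.05)r;"
  ))
}

# one shared miniature per test run (reduced size keeps the suite quick)
miniature <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- preset_study_miniature(n_codons = 300)
    cache
  }
})

# scanner-vs-truth comparison honouring the reading-frame convention: events
# at or downstream of a species' first uncompensated frameshift are frame
# artifacts and excluded on both sides.
truth_recovery <- function(sim, statuses) {
  observed <- all_events(statuses)
  expected <- sim_expected_events(sim)
  horizon <- function(ev) {
    fs <- ev[ev$event_type == "FRAMESHIFT_INDEL" &
               !(ev$compensated %in% TRUE), , drop = FALSE]
    stats::setNames(
      vapply(unique(ev$species_id), function(sp) {
        f <- fs$codon_index[fs$species_id == sp]
        if (length(f) == 0) Inf else min(f)
      }, numeric(1)),
      unique(ev$species_id)
    )
  }
  h <- horizon(observed)
  keep <- function(ev) {
    lim <- h[ev$species_id]
    lim[is.na(lim)] <- Inf
    ev[is.na(ev$codon_index) | ev$codon_index <= lim, , drop = FALSE]
  }
  key <- function(ev) {
    paste(ev$species_id, ev$event_type,
          ifelse(is.na(ev$codon_index), ev$junction_index, ev$codon_index),
          ev$obs_state)
  }
  obs_keys <- key(keep(observed))
  exp_keys <- key(keep(expected))
  list(
    precision = mean(obs_keys %in% exp_keys),
    recall = mean(exp_keys %in% obs_keys),
    observed = obs_keys, expected = exp_keys
  )
}

event_tibble_empty <- function() {
  tibble::tibble(
    species_id = character(), event_type = character(),
    codon_index = integer(), junction_index = integer(),
    ref_state = character(), obs_state = character(),
    inactivating = logical(), compensated = logical()
  )
}

balanced_tree16 <- function() {
  clade <- "(((c1:0.03,c2:0.03)n1:0.03,(c3:0.03,c4:0.03)n2:0.03)n3:0.04,((c5:0.03,c6:0.03)n4:0.03,(c7:0.03,c8:0.03)n5:0.03)n6:0.04)clade8:0.06"
  bg <- "(((b1:0.04,b2:0.04)m1:0.04,(b3:0.04,b4:0.04)m2:0.04)m3:0.05,((b5:0.04,b6:0.04)m4:0.04,(b7:0.04,b8:0.04)m5:0.04)m6:0.05)bg8:0.04"
  ape::read.tree(text = paste0("(", clade, ",", bg, ")r;"))
}
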