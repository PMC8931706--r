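# The lesion catalogue cases here mirror classic gene-loss screens:
# start-codon mutations (ATG->ATA, ATG->GTG), an internal AAA->TAA stop, a
# non-canonical AG->AA acceptor, a 1-bp frameshift insertion, and 3/6-bp
# in-frame deletions.

test_that("start-codon scanning flags non-ATG first codons", {
  ev <- scan_start_codon("blue_whale", paste0("ATA", strrep("GCC", 20), "TAA"))
  expect_equal(ev$event_type, "START_LOSS")
  expect_equal(ev$ref_state, "ATG")
  expect_equal(ev$obs_state, "ATA")
  expect_true(ev$inactivating)

  ev2 <- scan_start_codon("indus_dolphin", paste0("GTG", strrep("GCC", 20), "TAA"))
  expect_equal(ev2$obs_state, "GTG")

  expect_equal(nrow(scan_start_codon("ok", "ATGGCCTAA")), 0)
  expect_equal(nrow(scan_start_codon("ambig", "NTGGCCTAA")), 0)
  expect_error(scan_start_codon("tiny", "AT"), "shorter than 3")
})

test_that("premature stops and stop loss are called in frame", {
  # internal AAA -> TAA at codon 3; terminal TGA is not an event
  ev <- scan_premature_stop("minke", "ATGGCCTAAGCCGCCTGA")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_type, "PREMATURE_STOP")
  expect_equal(ev$codon_index, 3L)
  expect_equal(ev$obs_state, "TAA")

  expect_equal(nrow(scan_premature_stop("clean", "ATGGCCAAAGCCTGA")), 0)

  # no terminal stop at all -> STOP_LOSS at the final codon
  ev3 <- scan_premature_stop("lost", "ATGGCCAAAGCCGCC")
  expect_equal(ev3$event_type, "STOP_LOSS")
  expect_equal(ev3$codon_index, 5L)

  # stops are still called arbitrarily close to the end by default
  near_end <- paste0("ATG", strrep("GCC", 96), "TAGTTTTGA")
  ev4 <- scan_premature_stop("late", near_end)
  expect_equal(ev4$event_type, "PREMATURE_STOP")
  expect_equal(ev4$codon_index, 98L)
  # ... but a terminal tolerance window can drop them
  expect_equal(nrow(scan_premature_stop("late", near_end,
                                        terminal_tolerance = 0.05)), 0)
})

test_that("an injected stop at a known codon is recovered exactly once", {
  n <- 150
  codons <- rep("GCC", n)
  codons[100] <- "TAG"
  cds <- paste0(paste(codons, collapse = ""), "TAA")
  ev <- scan_premature_stop("sim", cds)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$codon_index, 100L)
})

test_that("indels are polarised, classified by frame, and compensation-annotated", {
  seqs <- c(
    ref = "ATGAAACCCGGGTTTACTTGGAAAGGGCAT",
    ins1 = "ATGAAACCCGGGTTTACTTGGAAAGGGCAT",  # placeholder, replaced below
    del6 = "ATGAAA------TTTACTTGGAAAGGGCAT",  # 6-bp in-frame deletion
    del3 = "ATG---CCCGGGTTTACTTGGAAAGGGCAT",  # 3-bp in-frame deletion
    del1 = "ATGAAACCCGGGTT-ACTTGGAAAGGGCAT"   # 1-bp frameshift deletion
  )
  aln <- aln_from_strings(seqs, "ref")
  ev6 <- scan_indels(aln, "del6")
  expect_equal(ev6$event_type, "INFRAME_INDEL")
  expect_equal(ev6$obs_state, "-6")
  expect_false(ev6$inactivating)
  expect_true(scan_indels(aln, "del6", inframe_inactivating = TRUE)$inactivating)

  ev3 <- scan_indels(aln, "del3")
  expect_equal(ev3$event_type, "INFRAME_INDEL")
  expect_equal(ev3$codon_index, 2L)

  ev1 <- scan_indels(aln, "del1")
  expect_equal(ev1$event_type, "FRAMESHIFT_INDEL")
  expect_true(ev1$inactivating)
  expect_false(ev1$compensated)

  # 1-bp insertion relative to the reference
  seqs2 <- c(
    ref = "ATGAAACCC-GGGTTTACT",
    cam = "ATGAAACCCAGGGTTTACT"
  )
  aln2 <- aln_from_strings(seqs2, "ref")
  evi <- scan_indels(aln2, "cam")
  expect_equal(evi$event_type, "FRAMESHIFT_INDEL")
  expect_equal(evi$obs_state, "+1")
  expect_true(evi$inactivating)

  # +1 followed by -1 downstream: frame restored, both marked compensated,
  # both still inactivating events
  seqs3 <- c(
    ref = "ATGAAACCC-GGGTTTACTTGG",
    cmp = "ATGAAACCCAGGGTT-ACTTGG"
  )
  aln3 <- aln_from_strings(seqs3, "ref")
  evc <- scan_indels(aln3, "cmp")
  expect_equal(nrow(evc), 2)
  expect_true(all(evc$compensated))
  expect_true(all(evc$inactivating))

  expect_error(scan_indels(aln, "nope"), "not in alignment")
})

test_that("splice-site scanning flags non-canonical dinucleotides", {
  ss <- tibble::tibble(donor = c("GT", "GT"), acceptor = c("AG", "AA"))
  ev <- scan_splice_sites("baiji", ss)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$junction_index, 2L)
  expect_equal(ev$obs_state, "acceptor:AA")

  expect_equal(nrow(scan_splice_sites("clean",
    tibble::tibble(donor = "GT", acceptor = "AG"))), 0)

  gc_donor <- tibble::tibble(donor = "GC", acceptor = "AG")
  expect_equal(nrow(scan_splice_sites("gc", gc_donor)), 1)
  expect_equal(nrow(scan_splice_sites("gc", gc_donor, allow_gc_donor = TRUE)), 0)

  # injected donor lesion at a chosen junction
  ss5 <- tibble::tibble(donor = c(rep("GT", 4), "GA", "GT"),
                        acceptor = rep("AG", 6))
  ev5 <- scan_splice_sites("sim", ss5)
  expect_equal(ev5$junction_index, 5L)
  expect_equal(ev5$obs_state, "donor:GA")
})

test_that("gene classification follows coverage and inactivating events", {
  rec <- tibble::tibble(species_id = "nmr", cds = "ATGGCCTAA",
                        splice_sites = list(NULL), coverage_fraction = 0.78)
  st <- classify_gene(rec, event_tibble_empty(), 0.9)
  expect_equal(st$status, "INCOMPLETE")

  rec$coverage_fraction <- 1
  ev <- scan_premature_stop("nmr", "ATGGCCTAAGCCTGA")
  st2 <- classify_gene(rec, ev, 0.9)
  expect_equal(st2$status, "INACTIVATED")

  inframe <- tibble::tibble(
    species_id = "x", event_type = "INFRAME_INDEL", codon_index = 5L,
    junction_index = NA_integer_, ref_state = NA_character_,
    obs_state = "-6", inactivating = FALSE, compensated = NA
  )
  expect_equal(classify_gene(rec, inframe, 0.9)$status, "INTACT")
})

test_that("scanning is deterministic and order-independent", {
  sim <- miniature()
  st1 <- scan_all(sim$records, sim$aln)
  st2 <- scan_all(sim$records[rev(seq_len(nrow(sim$records))), ], sim$aln)
  ev1 <- dplyr::arrange(all_events(st1), species_id, event_type, codon_index)
  ev2 <- dplyr::arrange(all_events(st2), species_id, event_type, codon_index)
  expect_identical(ev1, ev2)
})
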