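test_that("CDS FASTA reading produces one validated record per sequence", {
  path <- write_temp_fasta(c(sp1 = "ATGGCCAAATAA", sp2 = "ATGGCCAAANNN"))
  recs <- read_cds_fasta(path)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$species_id, c("sp1", "sp2"))
  expect_equal(recs$coverage_fraction, c(1, 9 / 12))

  bad <- write_temp_fasta(c(sp1 = "ATGGXCAAATAA"))
  expect_error(read_cds_fasta(bad), "sp1")
})

test_that("exon tables parse, order, and reject malformed annotation", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "species\texon_index\texon_length\tdonor_dinuc\tacceptor_dinuc",
    "spA\t1\t100\tGT\t",
    "spA\t2\t80\tGT\tAG",
    "spA\t3\t60\t\tAA"  # non-canonical acceptor accepted at parse time
  ), tsv)
  tab <- read_exon_table(tsv)
  expect_equal(tab$exon_lengths[[1]], c(100L, 80L, 60L))
  expect_equal(tab$splice_sites[[1]]$donor, c("GT", "GT"))
  expect_equal(tab$splice_sites[[1]]$acceptor, c("AG", "AA"))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "species\texon_index\texon_length\tdonor_dinuc\tacceptor_dinuc",
    "spA\t1\t100\tGT\t", "spA\t1\t80\tGT\tAG"
  ), dup)
  expect_error(read_exon_table(dup), "duplicated")

  gap <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "species\texon_index\texon_length\tdonor_dinuc\tacceptor_dinuc",
    "spA\t1\t100\tGT\t", "spA\t3\t80\t\tAG"
  ), gap)
  expect_error(read_exon_table(gap), "without gaps")

  short <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "species\texon_index\texon_length\tdonor_dinuc\tacceptor_dinuc",
    "spA\t1\t100\tG\t", "spA\t2\t80\t\tAG"
  ), short)
  expect_error(read_exon_table(short), "2 nt")
})

test_that("exon structure attaches only when lengths sum to the CDS", {
  path <- write_temp_fasta(c(spA = strrep("ATG", 80), spB = strrep("GCC", 80)))
  recs <- read_cds_fasta(path)
  tab <- tibble::tibble(
    species_id = "spA", exon_lengths = list(c(140L, 100L)),
    splice_sites = list(tibble::tibble(donor = "GT", acceptor = "AG"))
  )
  out <- attach_exon_structure(recs, tab)
  expect_equal(out$exon_lengths[[1]], c(140L, 100L))
  expect_true(out$has_annotation[1])
  expect_false(out$has_annotation[2]) # spB keeps single-exon default

  tab$exon_lengths[[1]] <- c(140L, 90L)
  expect_error(attach_exon_structure(recs, tab), "sum to 230")
})

test_that("codon alignment parsing masks stops/gaps but keeps raw columns", {
  seqs <- c(
    ref = "ATGAAACCCGGGTTTACTGCTAAAGGGTAA",
    t2  = "ATGAAACCCGGGTTTACTGCTAAAGGGTAA",
    t3  = "ATGTAACCCGGG---ACTGCTAAAGGGTAA",  # internal stop + deletion
    t4  = "ATGAAACCCGGGTTTACTGCTAAAGGGTAA"
  )
  path <- write_temp_fasta(seqs)
  aln <- read_codon_alignment(path, "ref")
  expect_equal(dim(aln), c(4L, 10L))
  expect_true(is.na(aln$codon["t3", 2]))  # TAA masked for the model
  expect_true(is.na(aln$codon["t3", 5]))  # gapped codon masked
  expect_equal(paste(aln$raw["t3", 4:6], collapse = ""), "TAA") # raw kept
  # the model-facing matrix never contains a stop codon
  stops <- c("TAA", "TAG", "TGA")
  expect_false(any(sense_codons()[aln$codon[!is.na(aln$codon)]] %in% stops))

  expect_error(read_codon_alignment(path, "absent"), "reference")

  ragged <- write_temp_fasta(c(a = "ATGAAA", b = "ATG"))
  expect_error(read_codon_alignment(ragged, "a"), "ragged")

  nondiv <- write_temp_fasta(c(a = "ATGA", b = "ATGA"))
  expect_error(read_codon_alignment(nondiv, "a"), "divisible")
})

test_that("insertion columns are excluded from the reference frame", {
  seqs <- c(
    ref = "ATGAAA--CCCGGG",
    ins = "ATGAAATTCCCGGG"
  )
  aln <- aln_from_strings(seqs, "ref")
  expect_equal(ncol(aln$codon), 4L)
  expect_equal(length(aln$frame_cols), 12L)
  expect_equal(ncol(aln$raw), 14L)
})

test_that("newick reading enforces rooted binary trees and label checks", {
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", nwk)
  tree <- read_newick(nwk)
  expect_equal(nrow(tree$edge), 6) # 2n - 2 branches for rooted 4-tip tree

  poly <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1,C:1,D:1);", poly)
  expect_error(read_newick(poly), "polytomies")
  res <- read_newick(poly, resolve_polytomies = TRUE)
  expect_true(ape::is.binary(res))
  expect_equal(sort(res$tip.label), c("A", "B", "C", "D"))

  aln <- aln_from_strings(c(A = "ATG", B = "ATG", C = "ATG", D = "ATG"))
  expect_silent(check_tree_alignment(tree, aln))
  aln2 <- aln_from_strings(c(A = "ATG", B = "ATG", C = "ATG"))
  expect_error(check_tree_alignment(tree, aln2), "D")
})

test_that("time tables parse intervals and reject inverted bounds", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tt_lower\tt_upper", "Mysticeti\t25.9\t34"), tsv)
  tt <- read_time_table(tsv)
  expect_equal(tt$t_lower, 25.9)
  expect_equal(tt$t_upper, 34)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tt_lower\tt_upper", "X\t10\t5"), bad)
  expect_error(read_time_table(bad), "X")
})

test_that("alignment and exon-table writers round-trip", {
  sim <- simulate_alignment(sim_config(n_taxa = 6, n_codons = 20, seed = 11))
  dir <- withr::local_tempdir()
  sim2 <- simulate_alignment(sim_config(n_taxa = 6, n_codons = 20, seed = 11),
                             dir = dir)
  aln <- read_codon_alignment(file.path(dir, "alignment.fasta"),
                              sim2$truth$reference_taxon)
  expect_identical(aln$raw, sim2$aln$raw)
  expect_identical(aln$codon, sim2$aln$codon)

  tab <- read_exon_table(file.path(dir, "exons.tsv"))
  i <- match(sim2$records$species_id[1], tab$species_id)
  expect_equal(tab$exon_lengths[[i]], sim2$records$exon_lengths[[1]])
  expect_equal(tab$splice_sites[[i]], sim2$records$splice_sites[[1]])

  tt <- read_time_table(file.path(dir, "times.tsv"))
  expect_equal(tt$t_lower, sim2$time_table$t_lower, tolerance = 1e-9)
})
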