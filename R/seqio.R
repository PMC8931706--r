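# Readers and writers for the plain-text formats the pipeline consumes:
# CDS FASTA, aligned FASTA, exon/splice TSV, newick trees, divergence-time
# TSV. All tabular readers return tibbles.

read_fasta_matrix <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicated FASTA headers in ", path, call. = FALSE)
  chr <- toupper(as.character(seqs))
  names(chr) <- nm
  chr
}

#' Read per-species coding sequences from FASTA
#'
#' One record per sequence; the FASTA header (up to the first whitespace) is
#' the species id. Exon structure defaults to a single exon spanning the
#' whole CDS until [attach_exon_structure()] supplies an annotation table.
#' Coverage is measured against `reference_length` (the longest sequence in
#' the file by default): the fraction of the reference CDS represented by
#' unambiguous nucleotides.
#'
#' @param path FASTA file of coding sequences (gaps allowed only if the file
#'   is an alignment; they are ignored for coverage).
#' @param reference_length Length (nt) of the reference CDS used as the
#'   denominator for `coverage_fraction`.
#' @return A tibble with columns `species_id`, `cds` (ungapped, uppercase),
#'   `exon_lengths` (list), `splice_sites` (list of tibbles, one row per
#'   intron), `coverage_fraction`.
#' @export
read_cds_fasta <- function(path, reference_length = NULL) {
  chr <- read_fasta_matrix(path)
  allowed <- c("A", "C", "G", "T", "N", "-")
  for (i in seq_along(chr)) {
    bad <- setdiff(unique(strsplit(chr[[i]], "")[[1]]), allowed)
    if (length(bad) > 0) {
      stop("record '", names(chr)[i], "' contains non-nucleotide characters: ",
           paste(bad, collapse = " "), call. = FALSE)
    }
  }
  cds <- gsub("-", "", chr, fixed = TRUE)
  if (is.null(reference_length)) reference_length <- max(nchar(cds))
  covered <- vapply(strsplit(cds, ""), function(x) sum(x != "N"), integer(1))
  tibble::tibble(
    species_id = names(chr),
    cds = unname(cds),
    exon_lengths = lapply(nchar(cds), function(n) n),
    splice_sites = rep(list(tibble::tibble(donor = character(), acceptor = character())),
                       length(cds)),
    coverage_fraction = pmin(1, unname(covered) / reference_length)
  )
}

#' Read an exon/splice-junction annotation table
#'
#' Expects a TSV with columns `species`, `exon_index`, `exon_length`,
#' `donor_dinuc`, `acceptor_dinuc`. The donor dinucleotide belongs to the
#' intron following the exon (empty for the last exon) and the acceptor to
#' the intron preceding it (empty for the first exon). Non-canonical
#' dinucleotides (e.g. an AA acceptor) are accepted here: deciding whether
#' they are lesions is the scanner's job.
#'
#' @param path TSV file path.
#' @return A tibble with columns `species_id`, `exon_lengths` (list),
#'   `splice_sites` (list of tibbles with `donor`, `acceptor`, one row per
#'   intron, in order).
#' @export
read_exon_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(donor_dinuc = "character",
                                          acceptor_dinuc = "character"))
  need <- c("species", "exon_index", "exon_length", "donor_dinuc", "acceptor_dinuc")
  if (!all(need %in% names(tab))) {
    stop("exon table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tab$donor_dinuc <- toupper(trimws(tab$donor_dinuc))
  tab$acceptor_dinuc <- toupper(trimws(tab$acceptor_dinuc))
  out <- lapply(split(tab, tab$species), function(d) {
    d <- d[order(d$exon_index), , drop = FALSE]
    k <- nrow(d)
    if (anyDuplicated(d$exon_index)) {
      stop("duplicated (species, exon_index) rows for '", d$species[1], "'", call. = FALSE)
    }
    if (!identical(as.integer(d$exon_index), seq_len(k))) {
      stop("exon indices for '", d$species[1], "' must run 1..", k,
           " without gaps", call. = FALSE)
    }
    dinucs <- c(d$donor_dinuc[-k], d$acceptor_dinuc[-1])
    bad <- dinucs[dinucs != "" & nchar(dinucs) != 2L]
    if (length(bad) > 0) {
      stop("splice dinucleotides must be 2 nt (species '", d$species[1],
           "'): ", paste(bad, collapse = " "), call. = FALSE)
    }
    if (k > 1 && (any(d$donor_dinuc[-k] == "") || any(d$acceptor_dinuc[-1] == ""))) {
      stop("missing splice dinucleotide for an internal junction of '",
           d$species[1], "'", call. = FALSE)
    }
    tibble::tibble(
      species_id = d$species[1],
      exon_lengths = list(as.integer(d$exon_length)),
      splice_sites = list(tibble::tibble(
        donor = d$donor_dinuc[-k][seq_len(max(0, k - 1))],
        acceptor = d$acceptor_dinuc[-1][seq_len(max(0, k - 1))]
      ))
    )
  })
  dplyr::bind_rows(out)
}

#' Attach exon structure to CDS records
#'
#' Joins an exon table onto CDS records, checking that each species' exon
#' lengths sum to its ungapped CDS length. Species absent from the exon table
#' keep their single-exon default (their splice scanning is skipped, not
#' failed).
#'
#' @param records Tibble from [read_cds_fasta()].
#' @param exon_table Tibble from [read_exon_table()].
#' @return `records` with `exon_lengths` and `splice_sites` replaced where
#'   annotation is available, plus a logical `has_annotation` column.
#' @export
attach_exon_structure <- function(records, exon_table) {
  records$has_annotation <- records$species_id %in% exon_table$species_id
  for (i in seq_len(nrow(records))) {
    j <- match(records$species_id[i], exon_table$species_id)
    if (is.na(j)) next
    lens <- exon_table$exon_lengths[[j]]
    if (sum(lens) != nchar(records$cds[i])) {
      stop("exon lengths for '", records$species_id[i], "' sum to ",
           sum(lens), " but CDS length is ", nchar(records$cds[i]), call. = FALSE)
    }
    records$exon_lengths[[i]] <- lens
    records$splice_sites[[i]] <- exon_table$splice_sites[[j]]
  }
  records
}

#' Read a codon-aware alignment from FASTA
#'
#' @param path Aligned FASTA; all rows the same length.
#' @param reference_taxon Taxon defining the reading frame (see
#'   [codon_alignment()]).
#' @return A [codon_alignment].
#' @export
read_codon_alignment <- function(path, reference_taxon) {
  chr <- read_fasta_matrix(path)
  lens <- nchar(chr)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(chr, ""))
  rownames(mat) <- names(chr)
  codon_alignment(mat, reference_taxon)
}

#' Write a codon alignment (raw nucleotide matrix) to FASTA
#' @param aln A [codon_alignment].
#' @param path Output file.
#' @export
write_codon_alignment <- function(aln, path) {
  write_fasta(apply(aln$raw, 1, paste, collapse = ""), path)
}

write_fasta <- function(named_seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(named_seqs)) {
    writeLines(c(paste0(">", nm), named_seqs[[nm]]), con)
  }
  invisible(path)
}

#' Read a rooted species tree from newick
#'
#' @param path Newick file.
#' @param resolve_polytomies If `FALSE` (default) polytomies are an error; if
#'   `TRUE` they are resolved deterministically with zero-length branches.
#' @return An `ape::phylo` tree, rooted and bifurcating.
#' @export
read_newick <- function(path, resolve_polytomies = FALSE) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("duplicated tip labels", call. = FALSE)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    if (!resolve_polytomies) {
      stop("tree must be rooted and bifurcating but contains polytomies; set ",
           "resolve_polytomies = TRUE to resolve them deterministically with ",
           "zero-length branches", call. = FALSE)
    }
    tree <- ape::multi2di(ape::rotateConstr(tree, sort(tree$tip.label)),
                          random = FALSE)
    if (!ape::is.rooted(tree)) {
      stop("tree could not be rooted; supply a rooted newick", call. = FALSE)
    }
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths in tree", call. = FALSE)
  }
  tree
}

#' Check that tree tips and alignment taxa agree
#'
#' @param tree An `ape::phylo`.
#' @param aln A [codon_alignment].
#' @return Invisibly `TRUE`; errors listing the symmetric difference if the
#'   tip set is not a subset of the alignment taxa.
#' @export
check_tree_alignment <- function(tree, aln) {
  extra <- setdiff(tree$tip.label, aln$taxa)
  if (length(extra) > 0) {
    missing <- setdiff(aln$taxa, tree$tip.label)
    stop("tree/alignment mismatch; tips not in alignment: ",
         paste(extra, collapse = ", "),
         if (length(missing) > 0) paste0("; taxa not in tree: ",
                                         paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a divergence-time interval table
#'
#' TSV with columns `label` (tip or clade label), `t_lower`, `t_upper` in Ma.
#' @param path TSV file.
#' @return Tibble with columns `label`, `t_lower`, `t_upper`.
#' @export
read_time_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "t_lower", "t_upper")
  if (!all(need %in% names(tab))) {
    stop("time table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- tab$t_lower <= 0 | tab$t_lower > tab$t_upper
  if (any(bad)) {
    stop("invalid time interval for: ", paste(tab$label[bad], collapse = ", "),
         " (need 0 < t_lower <= t_upper)", call. = FALSE)
  }
  tibble::as_tibble(tab[, need])
}

#' Write an exon/splice table
#' @param records Tibble with `species_id`, `exon_lengths`, `splice_sites`.
#' @param path Output TSV.
#' @export
write_exon_table <- function(records, path) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    lens <- records$exon_lengths[[i]]
    ss <- records$splice_sites[[i]]
    k <- length(lens)
    data.frame(
      species = records$species_id[i],
      exon_index = seq_len(k),
      exon_length = lens,
      donor_dinuc = c(if (k > 1) ss$donor else character(), ""),
      acceptor_dinuc = c("", if (k > 1) ss$acceptor else character()),
      stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
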