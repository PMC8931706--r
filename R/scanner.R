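# Lesion scanning: call inactivating (and in-frame) mutations per species,
# classify gene status, and place shared lesions on ancestral branches.
#
# Event tibbles share one schema:
#   species_id, event_type, codon_index, junction_index, ref_state,
#   obs_state, inactivating, compensated
# `compensated` is only meaningful for frameshifts (does the cumulative frame
# offset return to 0 downstream); it never rescinds the event.

STOP_CODONS <- c("TAA", "TAG", "TGA")

event_tibble <- function(species_id = character(), event_type = character(),
                         codon_index = integer(), junction_index = integer(),
                         ref_state = character(), obs_state = character(),
                         inactivating = logical(), compensated = logical()) {
  tibble::tibble(
    species_id = species_id, event_type = event_type,
    codon_index = as.integer(codon_index),
    junction_index = as.integer(junction_index),
    ref_state = ref_state, obs_state = obs_state,
    inactivating = inactivating, compensated = compensated
  )
}

split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Scan the initiation codon
#'
#' Calls a start-codon loss when the first codon of the (ungapped) CDS is not
#' ATG. Codons containing ambiguity are never called.
#'
#' @param species_id Species label.
#' @param cds Ungapped coding sequence (length >= 3).
#' @return An event tibble with zero or one `START_LOSS` row.
#' @export
scan_start_codon <- function(species_id, cds) {
  cds <- toupper(gsub("-", "", cds, fixed = TRUE))
  if (nchar(cds) < 3L) stop("CDS of '", species_id, "' shorter than 3 nt", call. = FALSE)
  first <- substr(cds, 1L, 3L)
  if (first == "ATG" || grepl("N", first)) return(event_tibble())
  event_tibble(species_id, "START_LOSS", 1L, NA_integer_, "ATG", first, TRUE, NA)
}

#' Scan for premature and lost stop codons
#'
#' Reads the ungapped CDS in frame from position 1. Every in-frame stop codon
#' strictly before the final codon is a `PREMATURE_STOP`; a final codon that
#' is not a stop is a `STOP_LOSS`. Codons containing N are skipped.
#'
#' @param species_id Species label.
#' @param cds Ungapped coding sequence.
#' @param terminal_tolerance Fraction of terminal codons within which
#'   premature stops are not called (default 0: every internal stop counts).
#' @return An event tibble.
#' @export
scan_premature_stop <- function(species_id, cds, terminal_tolerance = 0) {
  cds <- toupper(gsub("-", "", cds, fixed = TRUE))
  codons <- split_codons(cds)
  n <- length(codons)
  if (n < 1L) return(event_tibble())
  out <- event_tibble()
  cutoff <- n - 1L - floor(terminal_tolerance * n)
  internal <- which(codons[seq_len(n - 1L)] %in% STOP_CODONS)
  internal <- internal[internal <= cutoff]
  if (length(internal) > 0) {
    out <- dplyr::bind_rows(out, event_tibble(
      rep(species_id, length(internal)), "PREMATURE_STOP",
      internal, NA_integer_, NA_character_, codons[internal], TRUE, NA
    ))
  }
  last <- codons[n]
  if (!last %in% STOP_CODONS && !grepl("N", last)) {
    out <- dplyr::bind_rows(out, event_tibble(
      species_id, "STOP_LOSS", n, NA_integer_, "stop", last, TRUE, NA
    ))
  }
  out
}

#' Scan alignment indels for one taxon
#'
#' Polarises indels against the alignment's reference taxon: a maximal run of
#' gap characters in the taxon (within the reference frame) is a deletion; a
#' maximal block of insertion columns (reference gapped) in which the taxon
#' carries nucleotides is an insertion. Indels whose length is not a multiple
#' of 3 are frameshifts (inactivating); in-frame indels are recorded but not
#' inactivating by default. Each frameshift is annotated with whether the
#' cumulative frame offset returns to 0 downstream (`compensated`), which
#' never rescinds the event.
#'
#' @param aln A [codon_alignment].
#' @param taxon Taxon to scan (must differ from the reference).
#' @param inframe_inactivating Treat in-frame indels as inactivating.
#' @return An event tibble with `FRAMESHIFT_INDEL` / `INFRAME_INDEL` rows;
#'   `codon_index` is the reference-frame codon where the indel starts and
#'   `obs_state` the indel length in nt, signed (+insertion / -deletion).
#' @export
scan_indels <- function(aln, taxon, inframe_inactivating = FALSE) {
  if (!taxon %in% aln$taxa) stop("taxon '", taxon, "' not in alignment", call. = FALSE)
  if (taxon == aln$reference_taxon) return(event_tibble())
  ref_row <- aln$raw[aln$reference_taxon, ]
  tax_row <- aln$raw[taxon, ]
  ncol_raw <- length(ref_row)
  # reference-frame position of each raw column (0 for insertion columns)
  ref_pos <- cumsum(ref_row != "-") * (ref_row != "-")

  runs <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  }

  ev <- list()
  # deletions: taxon gapped where reference has sequence
  del <- runs(ref_row != "-" & tax_row == "-")
  for (i in seq_len(nrow(del))) {
    len <- sum(ref_row[del[i, 1]:del[i, 2]] != "-")
    pos <- ref_pos[del[i, 1]]
    ev[[length(ev) + 1L]] <- list(start_nt = pos, len = -len)
  }
  # insertions: reference gapped, taxon carries nucleotides
  ins_block <- runs(ref_row == "-")
  for (i in seq_len(nrow(ins_block))) {
    len <- sum(tax_row[ins_block[i, 1]:ins_block[i, 2]] != "-")
    if (len == 0) next
    nxt <- if (ins_block[i, 2] < ncol_raw) ref_pos[ins_block[i, 2] + 1L] else max(ref_pos) + 1L
    ev[[length(ev) + 1L]] <- list(start_nt = nxt, len = len)
  }
  if (length(ev) == 0) return(event_tibble())

  ord <- order(vapply(ev, `[[`, numeric(1), "start_nt"))
  ev <- ev[ord]
  lens <- vapply(ev, `[[`, numeric(1), "len")
  offset_after <- cumsum(lens) %% 3L
  is_fs <- abs(lens) %% 3L != 0L
  compensated <- vapply(seq_along(ev), function(i) {
    if (!is_fs[i]) return(NA)
    any(offset_after[i:length(ev)] == 0L)
  }, logical(1))

  event_tibble(
    species_id = rep(taxon, length(ev)),
    event_type = ifelse(is_fs, "FRAMESHIFT_INDEL", "INFRAME_INDEL"),
    codon_index = pmax(1L, (vapply(ev, `[[`, numeric(1), "start_nt") - 1L) %/% 3L + 1L),
    junction_index = NA_integer_,
    ref_state = NA_character_,
    obs_state = sprintf("%+d", lens),
    inactivating = ifelse(is_fs, TRUE, inframe_inactivating),
    compensated = compensated
  )
}

#' Scan splice-junction dinucleotides
#'
#' Emits a `SPLICE_SITE` event for every donor dinucleotide that is not GT
#' (GC optionally whitelisted) and every acceptor that is not AG. Junctions
#' with missing or ambiguous dinucleotides are skipped.
#'
#' @param species_id Species label.
#' @param splice_sites Tibble with `donor`, `acceptor` columns, one row per
#'   intron in order.
#' @param allow_gc_donor Whitelist the minor GC donor.
#' @return An event tibble; `junction_index` is the 1-based intron index and
#'   `obs_state` is `"donor:XX"` or `"acceptor:XX"`.
#' @export
scan_splice_sites <- function(species_id, splice_sites, allow_gc_donor = FALSE) {
  out <- event_tibble()
  if (is.null(splice_sites) || nrow(splice_sites) == 0) return(out)
  donor_ok <- c("GT", if (allow_gc_donor) "GC")
  for (j in seq_len(nrow(splice_sites))) {
    d <- toupper(splice_sites$donor[j])
    a <- toupper(splice_sites$acceptor[j])
    if (nchar(d) == 2L && !grepl("N", d) && !d %in% donor_ok) {
      out <- dplyr::bind_rows(out, event_tibble(
        species_id, "SPLICE_SITE", NA_integer_, j, "GT", paste0("donor:", d), TRUE, NA
      ))
    }
    if (nchar(a) == 2L && !grepl("N", a) && a != "AG") {
      out <- dplyr::bind_rows(out, event_tibble(
        species_id, "SPLICE_SITE", NA_integer_, j, "AG", paste0("acceptor:", a), TRUE, NA
      ))
    }
  }
  out
}

#' Scan one species for all lesion classes
#'
#' Runs the start-codon, premature-stop/stop-loss, splice-site, and (if an
#' alignment is supplied) indel scanners and returns the combined,
#' deterministically ordered event table.
#'
#' @param record One row of a CDS record tibble ([read_cds_fasta()]).
#' @param aln Optional [codon_alignment] for indel scanning.
#' @param inframe_inactivating,allow_gc_donor,terminal_tolerance Scanner
#'   options, see the individual scanners.
#' @return An event tibble.
#' @export
scan_gene <- function(record, aln = NULL, inframe_inactivating = FALSE,
                      allow_gc_donor = FALSE, terminal_tolerance = 0) {
  sp <- record$species_id
  ev <- dplyr::bind_rows(
    scan_start_codon(sp, record$cds),
    scan_premature_stop(sp, record$cds, terminal_tolerance),
    scan_splice_sites(sp, record$splice_sites[[1]], allow_gc_donor),
    if (!is.null(aln) && sp %in% aln$taxa && sp != aln$reference_taxon) {
      scan_indels(aln, sp, inframe_inactivating)
    }
  )
  dplyr::arrange(ev, .data$event_type, .data$codon_index, .data$junction_index)
}

#' Classify a gene as intact, inactivated, or incomplete
#'
#' A gene is `INCOMPLETE` when its coverage of the reference CDS falls below
#' the completeness threshold (incomplete genes are still scanned, but their
#' lesion calls are not trusted as pseudogenization evidence); otherwise it
#' is `INACTIVATED` if it carries at least one inactivating event and
#' `INTACT` if not.
#'
#' @param record One row of a CDS record tibble.
#' @param events Event tibble for this species.
#' @param threshold Completeness threshold in (0, 1], default 0.9.
#' @return A one-row tibble: `species_id`, `status`, `n_inactivating`,
#'   `n_events`, `coverage_fraction`, `events` (list column).
#' @export
classify_gene <- function(record, events, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  n_inact <- sum(events$inactivating)
  status <- if (record$coverage_fraction < threshold) {
    "INCOMPLETE"
  } else if (n_inact > 0) {
    "INACTIVATED"
  } else {
    "INTACT"
  }
  tibble::tibble(
    species_id = record$species_id, status = status,
    n_inactivating = n_inact, n_events = nrow(events),
    coverage_fraction = record$coverage_fraction,
    events = list(events)
  )
}

#' Scan and classify every species
#'
#' @param records CDS record tibble ([read_cds_fasta()], optionally with
#'   exon structure attached).
#' @param aln Optional [codon_alignment] for indel scanning.
#' @param threshold Completeness threshold for [classify_gene()].
#' @param ... Passed to [scan_gene()].
#' @return A status tibble, one row per species.
#' @export
scan_all <- function(records, aln = NULL, threshold = 0.9, ...) {
  dplyr::bind_rows(lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    classify_gene(rec, scan_gene(rec, aln, ...), threshold)
  }))
}

#' Collect all events from a status table
#' @param statuses Tibble from [scan_all()].
#' @return A single event tibble across species.
#' @export
all_events <- function(statuses) {
  dplyr::bind_rows(statuses$events)
}
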