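# The codon_alignment container: a column-indexed codon matrix over taxa,
# kept alongside the raw nucleotide alignment so lesion scanning can see
# gaps, stops and insertion columns that the substitution model must not.

#' Construct a codon alignment
#'
#' Builds the model-facing codon matrix from a nucleotide alignment matrix.
#' Columns in which the reference taxon is gapped are insertion columns: they
#' are retained in the raw matrix (the mutation scanner consumes them) but
#' excluded from the codon matrix, which is laid out in the reading frame of
#' the reference. After removing insertion columns the alignment length must
#' be divisible by 3. Codons containing gaps, ambiguity codes, or stop codons
#' are stored as missing in the codon matrix; the raw matrix is untouched.
#'
#' @param mat Character matrix of single nucleotides (rows = taxa, named).
#' @param reference_taxon Taxon whose reading frame defines codon columns and
#'   against which indels are polarised.
#' @return An object of class `codon_alignment` with elements `taxa`, `codon`
#'   (integer matrix, indices into [sense_codons()], `NA` = missing), `raw`
#'   (the full nucleotide matrix), `frame_cols` (raw columns in the reference
#'   frame) and `reference_taxon`.
#' @export
codon_alignment <- function(mat, reference_taxon) {
  if (is.null(rownames(mat))) stop("alignment matrix must have taxon rownames", call. = FALSE)
  taxa <- rownames(mat)
  if (anyDuplicated(taxa)) stop("duplicated taxon labels in alignment", call. = FALSE)
  if (!reference_taxon %in% taxa) {
    stop("reference taxon '", reference_taxon, "' not present in alignment", call. = FALSE)
  }
  mat[] <- toupper(mat)
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V"))
  if (length(bad) > 0) {
    stop("non-nucleotide characters in alignment: ", paste(bad, collapse = " "), call. = FALSE)
  }
  frame_cols <- which(mat[reference_taxon, ] != "-")
  if (length(frame_cols) %% 3L != 0L) {
    stop("reference-frame alignment length (", length(frame_cols),
         ") is not divisible by 3", call. = FALSE)
  }
  fmat <- mat[, frame_cols, drop = FALSE]
  n_sites <- length(frame_cols) %/% 3L
  st <- codon_structure()
  idx <- stats::setNames(seq_along(st$codons), st$codons)

  codon_chr <- matrix(NA_character_, nrow(mat), n_sites,
                      dimnames = list(taxa, NULL))
  for (s in seq_len(n_sites)) {
    cols <- (3L * (s - 1L) + 1L):(3L * s)
    codon_chr[, s] <- paste0(fmat[, cols[1]], fmat[, cols[2]], fmat[, cols[3]])
  }
  codon <- matrix(idx[codon_chr], nrow(mat), n_sites, dimnames = list(taxa, NULL))

  structure(
    list(taxa = taxa, codon = codon, raw = mat, frame_cols = frame_cols,
         reference_taxon = reference_taxon),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x$taxa), " taxa x ", ncol(x$codon),
      " codon sites (reference: ", x$reference_taxon, ")\n", sep = "")
  miss <- mean(is.na(x$codon))
  cat(sprintf("  raw alignment: %d nt columns; missing codon cells: %.1f%%\n",
              ncol(x$raw), 100 * miss))
  invisible(x)
}

#' @export
dim.codon_alignment <- function(x) dim(x$codon)

# n_taxa x n_sites codon strings in reference frame (raw, unmasked).
codon_strings <- function(aln) {
  fmat <- aln$raw[, aln$frame_cols, drop = FALSE]
  n_sites <- ncol(fmat) %/% 3L
  out <- matrix(NA_character_, nrow(fmat), n_sites,
                dimnames = list(aln$taxa, NULL))
  for (s in seq_len(n_sites)) {
    cols <- (3L * (s - 1L) + 1L):(3L * s)
    out[, s] <- paste0(fmat[, cols[1]], fmat[, cols[2]], fmat[, cols[3]])
  }
  out
}

#' Restrict a codon alignment to a subset of taxa
#'
#' @param aln A [codon_alignment].
#' @param taxa Taxa to keep; must include the reference taxon.
#' @return A [codon_alignment] over the kept taxa.
#' @export
subset_alignment <- function(aln, taxa) {
  missing <- setdiff(taxa, aln$taxa)
  if (length(missing) > 0) {
    stop("taxa not in alignment: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!aln$reference_taxon %in% taxa) {
    stop("subset must retain the reference taxon", call. = FALSE)
  }
  codon_alignment(aln$raw[taxa, , drop = FALSE], aln$reference_taxon)
}

#' Mask pseudogene lesions ahead of model fitting
#'
#' The codon model has no stop states and assumes an intact reading frame, so
#' pseudogenized sequences must be partially masked before fitting: premature
#' stop codons are already missing in the model-facing matrix, and this
#' function additionally masks every codon from the first uncompensated
#' frameshift onward in each affected taxon.
#'
#' @param aln A [codon_alignment].
#' @param events Tibble of mutation events as returned by [scan_gene()] /
#'   [scan_indels()].
#' @return The alignment with additional codon cells set to missing.
#' @export
mask_lesions <- function(aln, events) {
  fs <- events[events$event_type == "FRAMESHIFT_INDEL" &
                 !is.na(events$codon_index) &
                 !isTRUE_vec(events$compensated), , drop = FALSE]
  if (nrow(fs) > 0) {
    for (sp in unique(fs$species_id)) {
      if (!sp %in% aln$taxa) next
      from <- min(fs$codon_index[fs$species_id == sp])
      if (from <= ncol(aln$codon)) {
        aln$codon[sp, from:ncol(aln$codon)] <- NA_integer_
      }
    }
  }
  aln
}

isTRUE_vec <- function(x) !is.na(x) & x

# Pattern compression: unique site patterns and their multiplicities.
# Missing cells participate in pattern identity.
compress_patterns <- function(codon_matrix) {
  key <- apply(codon_matrix, 2, paste, collapse = "\r")
  uq <- !duplicated(key)
  list(
    states = codon_matrix[, uq, drop = FALSE],
    weights = as.numeric(table(factor(key, levels = key[uq])))
  )
}
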