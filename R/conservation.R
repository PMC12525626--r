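#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and Clustal formats (via Biostrings). All
#' gapped sequences must share the same length.
#'
#' @param path File path.
#' @param format "fasta" or "clustal"; guessed from the extension when
#'   omitted (.aln/.clustal -> clustal).
#' @return An `msa_alignment`: list with `ids` (sequence identifiers,
#'   first whitespace-delimited header token) and `seqs` (named
#'   character vector of upper-case gapped sequences).
#' @export
read_alignment <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) %in%
                  c("aln", "clustal", "clu")) "clustal" else "fasta"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- toupper(as.character(aln))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  names(seqs) <- ids
  msa_alignment(seqs)
}

#' @rdname read_alignment
#' @param seqs Named character vector of gapped sequences.
#' @export
msa_alignment <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1) {
    stop_input("ragged alignment: sequences differ in length")
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop_input("alignment rows must carry unique ids")
  }
  structure(list(ids = names(seqs), seqs = seqs), class = "msa_alignment")
}

#' Per-residue percent identity relative to a reference sequence
#'
#' For each alignment column where the reference row is not gapped,
#' reports the percentage of other rows carrying the same residue.
#' Residue numbering is the cumulative non-gap count along the
#' reference, so the output maps directly onto reference coordinates
#' (and hence onto a structure via [conservation_to_structure()]).
#'
#' @param alignment An `msa_alignment`.
#' @param reference_id Row to use as reference.
#' @param exclude_reference Exclude the reference row from the
#'   denominator (default TRUE).
#' @param gap_as_mismatch Count gaps in other rows as mismatches
#'   (default TRUE); otherwise gapped rows are dropped from the column's
#'   denominator.
#' @return Data frame with columns `residue_number`, `residue`,
#'   `identity_pct`.
#' @export
percent_identity_per_reference_residue <- function(
    alignment, reference_id,
    exclude_reference = TRUE, gap_as_mismatch = TRUE) {
  stopifnot(inherits(alignment, "msa_alignment"))
  if (!reference_id %in% alignment$ids) {
    stop_input("reference '", reference_id, "' not in alignment")
  }
  mat <- do.call(rbind, strsplit(alignment$seqs, ""))
  rownames(mat) <- alignment$ids
  ref <- mat[reference_id, ]
  others <- if (exclude_reference) {
    mat[setdiff(alignment$ids, reference_id), , drop = FALSE]
  } else mat
  gap <- c("-", ".")
  cols <- which(!ref %in% gap)
  pct <- vapply(cols, function(j) {
    col <- others[, j]
    if (!gap_as_mismatch) col <- col[!col %in% gap]
    if (length(col) == 0) return(NA_real_)
    100 * mean(col == ref[j])
  }, numeric(1))
  data.frame(residue_number = seq_along(cols),
             residue = ref[cols],
             identity_pct = pct,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a per-residue conservation table to TSV
#'
#' @param identity Data frame from
#'   [percent_identity_per_reference_residue()].
#' @param path Output path.
#' @export
write_conservation <- function(identity, path) {
  write_tsv(identity, path)
}
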