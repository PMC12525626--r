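#' Construct a kinase position-specific scoring matrix
#'
#' Kinase substrate-preference matrices cover a window of relative
#' positions around the phosphoacceptor (position 0, excluded), here
#' -5..+4 by convention. All weights must be strictly positive; scoring
#' is additive in log2 of the weights.
#'
#' @param kinase_name Kinase identifier.
#' @param matrix Numeric matrix, rows named by relative position
#'   ("-5".."-1", "1".."4"), columns by amino acid.
#' @return A `kinase_pssm` object.
#' @export
kinase_pssm <- function(kinase_name, matrix) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  pos <- as.integer(rownames(matrix))
  if (any(is.na(pos)) || any(pos == 0L)) {
    stop_input("matrix rows must be non-zero relative positions")
  }
  rng <- sort(pos)
  expected <- setdiff(seq(min(rng), max(rng)), 0L)
  if (!identical(rng, as.integer(expected))) {
    stop_input("matrix positions must form a contiguous window ",
               "around the phosphoacceptor")
  }
  if (any(matrix <= 0)) stop_input("kinase PSSM weights must be > 0")
  structure(list(kinase_name = kinase_name, matrix = matrix),
            class = "kinase_pssm")
}

#' Read kinase PSSMs from a long-format TSV
#'
#' Expects columns `kinase`, `position` (relative, excluding 0), `aa`
#' and `weight`; one file can hold many kinases.
#'
#' @param path File path.
#' @return Named list of `kinase_pssm` objects.
#' @export
read_kinase_pssms <- function(path) {
  df <- read_tsv(path)
  need <- c("kinase", "position", "aa", "weight")
  if (!all(need %in% names(df))) {
    stop_input("kinase matrix file needs columns: ",
               paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$kinase), function(d) {
    pos <- sort(unique(d$position))
    aas <- sort(unique(d$aa))
    m <- matrix(NA_real_, length(pos), length(aas),
                dimnames = list(as.character(pos), aas))
    m[cbind(as.character(d$position), d$aa)] <- d$weight
    if (anyNA(m)) {
      stop_input("incomplete matrix for kinase ", d$kinase[1])
    }
    kinase_pssm(d$kinase[1], m)
  })
  out[order(names(out))]
}

#' Build a phosphoacceptor-centred sequence window
#'
#' Extracts the residues at relative positions -5..-1 and +1..+4 around
#' a serine/threonine phosphoacceptor; positions beyond the protein
#' termini are recorded as "-" and skipped during scoring (truncated
#' flanks are not padded with pseudo-residues).
#'
#' @param sequence Protein sequence.
#' @param center_residue 1-based index of the phosphoacceptor (S or T).
#' @param protein_id Optional identifier.
#' @return A `site_window` object with fields `protein_id`,
#'   `center_residue`, `center_aa` and `flank` (named character vector
#'   over relative positions).
#' @export
#' @examples
#' make_site_window("EPEGGSQDQKGQ", 6)   # MDC1 S955-centred window
make_site_window <- function(sequence, center_residue, protein_id = NA) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (center_residue < 1 || center_residue > L) {
    stop_input("center_residue out of range")
  }
  center_aa <- substring(sequence, center_residue, center_residue)
  if (!center_aa %in% c("S", "T")) {
    stop_input("phosphoacceptor must be serine or threonine, got ",
               center_aa)
  }
  rel <- setdiff(-5:4, 0L)
  idx <- center_residue + rel
  flank <- ifelse(idx >= 1 & idx <= L, substring(sequence, idx, idx), "-")
  names(flank) <- as.character(rel)
  structure(list(protein_id = protein_id,
                 center_residue = center_residue,
                 center_aa = center_aa,
                 flank = flank),
            class = "site_window")
}

#' Score a site window against one kinase PSSM
#'
#' The score is the sum, over in-range relative positions covered by the
#' matrix, of log2 of the matrix weight for the observed residue.
#' Out-of-range positions ("-") contribute 0. Phospho-residues in the
#' flank should be given as their unmodified letter unless the matrix
#' provides phospho columns.
#'
#' @param window A `site_window`.
#' @param pssm A `kinase_pssm`.
#' @return log2 score (numeric scalar).
#' @export
score_window <- function(window, pssm) {
  stopifnot(inherits(window, "site_window"), inherits(pssm, "kinase_pssm"))
  m <- pssm$matrix
  score <- 0
  for (pos in intersect(names(window$flank), rownames(m))) {
    aa <- window$flank[[pos]]
    if (aa == "-") next
    if (!aa %in% colnames(m)) {
      stop_input("residue ", aa, " absent from matrix alphabet of ",
                 pssm$kinase_name)
    }
    score <- score + log2(m[pos, aa])
  }
  score
}

#' Rank kinases for a phosphosite
#'
#' Scores the window against every matrix and ranks kinases by
#' descending log2 score. Ties share a dense 1-based rank and are listed
#' alphabetically by kinase name.
#'
#' @param window A `site_window`.
#' @param pssms Non-empty list of `kinase_pssm` objects.
#' @param top Number of kinases to return; default 10.
#' @return Data frame with columns `kinase`, `score`, `rank`.
#' @export
rank_kinases <- function(window, pssms, top = 10L) {
  if (length(pssms) == 0) stop_input("pssms must be non-empty")
  scores <- vapply(pssms, function(p) score_window(window, p), numeric(1))
  names(scores) <- vapply(pssms, `[[`, character(1), "kinase_name")
  ord <- order(-scores, names(scores))
  scores <- scores[ord]
  rank <- cumsum(!duplicated(round(-scores, 12)))   # dense ranks
  res <- data.frame(kinase = names(scores), score = unname(scores),
                    rank = rank, stringsAsFactors = FALSE)
  utils::head(res, top)
}
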