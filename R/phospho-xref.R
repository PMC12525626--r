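#' Read a phosphosite table
#'
#' Accepts a TSV in either of two dialects (mirroring a PhosphoSitePlus
#' export): a `residue` column holding tokens like "S955", or separate
#' `residue_type` and `residue_number` columns. A `modification` column
#' is optional and defaults to "phospho". Duplicate events (same
#' protein, residue and modification, e.g. aggregated from multiple
#' studies) are collapsed.
#'
#' @param path File path.
#' @return Data frame with columns `protein_id`, `residue_number`,
#'   `residue_type`, `modification`.
#' @export
read_phospho_table <- function(path) {
  df <- read_tsv(path)
  if (!"protein_id" %in% names(df)) {
    stop_input("phosphosite table needs a protein_id column")
  }
  if ("residue" %in% names(df)) {
    tok <- as.character(df$residue)
    ok <- grepl("^[STY][0-9]+$", tok)
    if (!all(ok)) {
      stop_input("unparseable residue token(s): ",
                 paste(unique(tok[!ok]), collapse = ", "))
    }
    df$residue_type <- substr(tok, 1, 1)
    df$residue_number <- as.integer(sub("^[STY]", "", tok))
  }
  if (!all(c("residue_type", "residue_number") %in% names(df))) {
    stop_input("phosphosite table needs residue or ",
               "residue_type/residue_number columns")
  }
  df$modification <- if ("modification" %in% names(df)) {
    as.character(df$modification)
  } else "phospho"
  out <- data.frame(protein_id = as.character(df$protein_id),
                    residue_number = as.integer(df$residue_number),
                    residue_type = as.character(df$residue_type),
                    modification = df$modification,
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Map phosphorylation events onto motif matches
#'
#' For every TBM match, collects the phosphorylation events that fall
#' inside the octapeptide and records their motif positions (1 to 8).
#' Matches with a position-8 event are assigned to the pS8, pT8 or pY8
#' arm according to the position-8 residue. Events whose reported
#' residue type disagrees with the octapeptide letter at the mapped
#' position raise a warning and are skipped. Events on proteins without
#' any motif match are ignored (the analysis runs motif -> modification).
#'
#' @param matches Data frame from [scan_proteome()].
#' @param events Data frame from [read_phospho_table()] (or with the
#'   same columns).
#' @return The matches with extra columns `phospho_positions`
#'   (comma-separated motif positions, "" when none) and `arm` (one of
#'   "pS8", "pT8", "pY8", "none").
#' @export
#' @examples
#' m <- data.frame(protein_id = "MDC1", start = 948L, end = 955L,
#'                 octapeptide = "RGEPEGGS", tts = 0.4, pos8_class = "S")
#' e <- data.frame(protein_id = "MDC1", residue_number = 955L,
#'                 residue_type = "S", modification = "phospho")
#' map_events_to_motifs(m, e)
map_events_to_motifs <- function(matches, events) {
  events <- unique(events[, c("protein_id", "residue_number",
                              "residue_type")])
  positions <- character(nrow(matches))
  arm <- rep("none", nrow(matches))
  for (i in seq_len(nrow(matches))) {
    ev <- events[events$protein_id == matches$protein_id[i], , drop = FALSE]
    if (nrow(ev) == 0) next
    off <- ev$residue_number - matches$start[i] + 1L
    inside <- off >= 1L & off <= 8L
    ev <- ev[inside, , drop = FALSE]
    off <- off[inside]
    if (nrow(ev) == 0) next
    motif_aa <- substring(matches$octapeptide[i], off, off)
    consistent <- motif_aa == ev$residue_type
    if (any(!consistent)) {
      warning("event residue type disagrees with motif sequence for ",
              matches$protein_id[i], " residue ",
              paste(ev$residue_number[!consistent], collapse = ","),
              "; event skipped", call. = FALSE)
    }
    off <- sort(unique(off[consistent]))
    positions[i] <- paste(off, collapse = ",")
    if (8L %in% off) {
      arm[i] <- paste0("p", substring(matches$octapeptide[i], 8, 8), "8")
    }
  }
  matches$phospho_positions <- positions
  matches$arm <- arm
  matches
}

#' Census of phospho-arms across motif matches
#'
#' Tallies position-8 phosphorylation by arm. Because a protein can host
#' several phosphorylated motifs, both tallies are reported: distinct
#' (protein, motif) hits per arm and distinct host proteins per arm.
#'
#' @param xrefs Data frame from [map_events_to_motifs()].
#' @return A list of class `arm_census` with elements `motif_counts`
#'   (named integer vector over pS8/pT8/pY8), `protein_counts` (distinct
#'   hosts per arm), `proteins_by_arm` (list of host-protein ids) and
#'   `proteins_pS8_pT8` (deduplicated hosts of the serine/threonine arm
#'   union, the study set for enrichment).
#' @export
census_by_arm <- function(xrefs) {
  arms <- c("pS8", "pT8", "pY8")
  motif_counts <- stats::setNames(integer(3), arms)
  proteins_by_arm <- stats::setNames(vector("list", 3), arms)
  for (a in arms) {
    sub <- xrefs[!is.na(xrefs$arm) & xrefs$arm == a, , drop = FALSE]
    key <- unique(paste(sub$protein_id, sub$start))
    motif_counts[a] <- length(key)
    proteins_by_arm[[a]] <- sort(unique(sub$protein_id))
  }
  structure(list(
    motif_counts = motif_counts,
    protein_counts = vapply(proteins_by_arm, length, integer(1)),
    proteins_by_arm = proteins_by_arm,
    proteins_pS8_pT8 = sort(unique(c(proteins_by_arm$pS8,
                                     proteins_by_arm$pT8)))),
    class = "arm_census")
}

#' @export
print.arm_census <- function(x, ...) {
  cat("Position-8 phospho-census\n")
  cat("  motifs:  ", paste(names(x$motif_counts), x$motif_counts,
                           sep = "=", collapse = "  "), "\n")
  cat("  proteins:", paste(names(x$protein_counts), x$protein_counts,
                           sep = "=", collapse = "  "), "\n")
  cat("  pS8 u pT8 host proteins:", length(x$proteins_pS8_pT8), "\n")
  invisible(x)
}

#' Write cross-referenced motif matches to TSV
#'
#' @param xrefs Data frame from [map_events_to_motifs()].
#' @param path Output path.
#' @export
write_xref <- function(xrefs, path) {
  write_tsv(xrefs, path)
}
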