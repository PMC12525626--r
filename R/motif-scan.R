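#' Build the default tankyrase-binding-motif PSSM
#'
#' Constructs the position weight matrix encoding the eight-position TBM
#' consensus R-x-x-[small hydrophobic or G]-[D/E]-G-[no P]-[D/E].
#' Positions 2 and 3 are wildcards ("x") and carry uniform weights;
#' they do not contribute to the tankyrase targeting score (TTS).
#'
#' Weight allocation at scored positions: 0.97 of the probability mass is
#' split evenly across the consensus residue(s) and 0.03 across the
#' remaining allowed residues. Absolute constraints get zero weight:
#' position 6 admits only glycine, position 7 excludes proline, and
#' position 8 excludes basic residues (H/K/R), which are the least
#' preferred there. Position 8 concentrates mass on the acidic residues
#' D/E, so that phospho-acceptor residues (S/T/Y) are tolerated but
#' score well below a perfect consensus.
#'
#' @return A `tbm_pssm` object: a list with elements `weights` (8 x 20
#'   matrix of per-position residue probabilities), `scored_positions`
#'   (integer vector; positions contributing to the TTS) and `name`.
#' @seealso [tts_score()], [scan_proteome()], [read_tbm_pssm()]
#' @export
#' @examples
#' pssm <- build_default_pssm()
#' pssm$weights["6", "G"]  # glycine is obligatory at position 6
build_default_pssm <- function() {
  w <- matrix(0, nrow = 8, ncol = 20,
              dimnames = list(as.character(1:8), AA_ALPHABET))
  split_mass <- function(consensus, excluded = character()) {
    row <- stats::setNames(numeric(20), AA_ALPHABET)
    rest <- setdiff(AA_ALPHABET, c(consensus, excluded))
    row[consensus] <- 0.97 / length(consensus)
    row[rest] <- 0.03 / length(rest)
    row
  }
  small_hydrophobic <- c("A", "C", "G", "I", "L", "M", "P", "S", "T", "V")
  w["1", ] <- split_mass("R")
  w["2", ] <- 1 / 20
  w["3", ] <- 1 / 20
  w["4", ] <- split_mass(small_hydrophobic)
  w["5", ] <- split_mass(ACIDIC_AA)
  w["6", "G"] <- 1                              # glycine is essential
  w["7", setdiff(AA_ALPHABET, "P")] <- 1 / 19   # proline forbidden
  w["8", ] <- split_mass(ACIDIC_AA, excluded = BASIC_AA)
  new_tbm_pssm(w, scored_positions = c(1L, 4L, 5L, 6L, 7L, 8L),
               name = "tbm_consensus_default")
}

new_tbm_pssm <- function(weights, scored_positions, name = "tbm_pssm") {
  stopifnot(is.matrix(weights), nrow(weights) == 8,
            identical(colnames(weights), AA_ALPHABET))
  scored_positions <- sort(as.integer(scored_positions))
  if (any(scored_positions < 1L | scored_positions > 8L)) {
    stop_input("scored positions must lie in 1..8")
  }
  sums <- rowSums(weights)
  if (any(abs(sums - 1) > 1e-9)) {
    stop_input("PSSM rows must sum to 1; off at position(s) ",
               paste(which(abs(sums - 1) > 1e-9), collapse = ", "))
  }
  if (any(weights < 0)) stop_input("PSSM weights must be >= 0")
  structure(list(weights = weights,
                 scored_positions = scored_positions,
                 name = name),
            class = "tbm_pssm")
}

#' @export
print.tbm_pssm <- function(x, ...) {
  cat("TBM PSSM '", x$name, "': scored positions ",
      paste(x$scored_positions, collapse = ","), "\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

#' Read or write a TBM PSSM as a TSV matrix
#'
#' The file has eight rows (motif positions 1 to 8) and twenty columns
#' (amino acids). On reading, positions whose weights are all equal are
#' treated as wildcards and excluded from scoring.
#'
#' @param path File path.
#' @param name Name to attach to the PSSM read.
#' @return `read_tbm_pssm()` returns a `tbm_pssm`; `write_tbm_pssm()`
#'   returns `path` invisibly.
#' @export
read_tbm_pssm <- function(path, name = basename(path)) {
  df <- read_tsv(path)
  first <- names(df)[1]
  if (!first %in% AA_ALPHABET) df[[first]] <- NULL   # position label column
  m <- as.matrix(df)
  if (!setequal(colnames(m), AA_ALPHABET) || nrow(m) != 8) {
    stop_input("PSSM file must have 8 rows and the 20 amino-acid columns")
  }
  m <- m[, AA_ALPHABET, drop = FALSE]
  dimnames(m) <- list(as.character(1:8), AA_ALPHABET)
  uniform <- apply(m, 1, function(r) diff(range(r)) < 1e-9)
  new_tbm_pssm(m, scored_positions = which(!uniform), name = name)
}

#' @rdname read_tbm_pssm
#' @param pssm A `tbm_pssm` object.
#' @export
write_tbm_pssm <- function(pssm, path) {
  df <- data.frame(position = 1:8, pssm$weights, check.names = FALSE)
  write_tsv(df, path)
}

#' Tankyrase targeting score of an octapeptide
#'
#' Scores an eight-residue window against a TBM PSSM. The score is the
#' geometric mean, over the scored positions, of the ratio between the
#' weight of the observed residue and the maximum weight at that
#' position. It equals 1 exactly when every scored position carries a
#' maximally weighted residue and 0 whenever any scored position holds a
#' zero-weight residue (including the ambiguity code X).
#'
#' @param octapeptide Character vector of 8-letter peptides.
#' @param pssm A `tbm_pssm`, default [build_default_pssm()].
#' @return Numeric vector of scores in \[0, 1\].
#' @export
#' @examples
#' tts_score("RGEPEGGS")            # MDC1 TBM1
#' tts_score("RGEPERGS")            # G6R variant scores 0
tts_score <- function(octapeptide, pssm = build_default_pssm()) {
  if (length(octapeptide) == 0) return(numeric(0))
  octapeptide <- toupper(octapeptide)
  bad_len <- nchar(octapeptide) != 8L
  if (any(bad_len)) stop_input("octapeptides must have length 8")
  chars <- matrix(unlist(strsplit(octapeptide, ""), use.names = FALSE),
                  ncol = 8, byrow = TRUE)
  bad <- setdiff(unique(as.vector(chars)), c(AA_ALPHABET, "X"))
  if (length(bad) > 0) {
    stop_input("invalid residue(s): ", paste(bad, collapse = ", "))
  }
  tts_score_matrix(chars, pssm)
}

# chars: n x 8 character matrix. Returns n scores.
tts_score_matrix <- function(chars, pssm) {
  pos <- pssm$scored_positions
  row_max <- apply(pssm$weights, 1, max)
  log_ratio <- matrix(0, nrow = nrow(chars), ncol = length(pos))
  for (j in seq_along(pos)) {
    p <- pos[j]
    aa <- chars[, p]
    w <- rep(0, length(aa))                 # X and unknowns score 0
    known <- aa %in% AA_ALPHABET
    w[known] <- pssm$weights[p, aa[known]]
    log_ratio[, j] <- log(w / row_max[p])   # -Inf where w == 0
  }
  score <- exp(rowMeans(log_ratio))
  score[!is.finite(rowSums(log_ratio))] <- 0
  score
}

classify_pos8 <- function(aa) {
  out <- rep("other", length(aa))
  out[aa %in% c("S", "T", "Y")] <- aa[aa %in% c("S", "T", "Y")]
  out[aa %in% ACIDIC_AA] <- "acidic"
  out[aa %in% BASIC_AA] <- "basic"
  out
}

#' Scan a proteome for tankyrase-binding motifs
#'
#' Slides an eight-residue window over every sequence, scores each window
#' with [tts_score()] and keeps windows at or above the threshold. The
#' default threshold 0.385 is the minimal consensus conformance used for
#' candidate selection.
#'
#' @param records Data frame with columns `id` and `sequence`
#'   (see [read_fasta()]).
#' @param pssm A `tbm_pssm`.
#' @param threshold TTS cutoff in \[0, 1\]; default 0.385.
#' @return Data frame with columns `protein_id`, `start`, `end`,
#'   `octapeptide`, `tts` and `pos8_class` (one of S, T, Y, acidic,
#'   basic, other), sorted by descending score, then protein id and
#'   start. Coordinates are 1-based and inclusive.
#' @export
#' @examples
#' recs <- data.frame(id = "MDC1", sequence = "AAAARGEPEGGSAAAA")
#' scan_proteome(recs)
scan_proteome <- function(records, pssm = build_default_pssm(),
                          threshold = 0.385) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  if (threshold < 0 || threshold > 1) {
    stop_input("threshold must lie in [0, 1]")
  }
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    seq <- toupper(records$sequence[i])
    L <- nchar(seq)
    if (L < 8L) next
    starts <- seq_len(L - 7L)
    wins <- substring(seq, starts, starts + 7L)
    chars <- matrix(unlist(strsplit(wins, ""), use.names = FALSE),
                    ncol = 8, byrow = TRUE)
    sc <- tts_score_matrix(chars, pssm)
    keep <- sc >= threshold
    if (!any(keep)) next
    out[[i]] <- data.frame(
      protein_id = records$id[i],
      start = starts[keep],
      end = starts[keep] + 7L,
      octapeptide = wins[keep],
      tts = sc[keep],
      pos8_class = classify_pos8(chars[keep, 8]),
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), octapeptide = character(),
                      tts = numeric(), pos8_class = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$tts, res$protein_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter motif matches by per-residue disorder
#'
#' Keeps matches whose mean disorder score over the eight motif residues
#' is at least `min_mean`. Disorder predictions are supplied by the user
#' (any per-residue score in \[0, 1\]); matches on proteins absent from
#' the disorder input are passed through unchanged and flagged as
#' unfiltered.
#'
#' @param matches Data frame from [scan_proteome()].
#' @param disorder Named list: protein id -> numeric vector of
#'   per-residue disorder scores covering the protein.
#' @param min_mean Minimum mean motif disorder; default 0.5.
#' @return The filtered matches with extra columns `mean_disorder`
#'   (NA when no disorder input was available) and `disorder_filtered`.
#' @export
filter_by_disorder <- function(matches, disorder, min_mean = 0.5) {
  stopifnot(is.list(disorder))
  mean_dis <- rep(NA_real_, nrow(matches))
  for (i in seq_len(nrow(matches))) {
    d <- disorder[[matches$protein_id[i]]]
    if (is.null(d)) next
    if (length(d) < matches$end[i]) {
      stop_input("disorder vector for ", matches$protein_id[i],
                 " is shorter than the protein")
    }
    mean_dis[i] <- mean(d[matches$start[i]:matches$end[i]])
  }
  matches$mean_disorder <- mean_dis
  matches$disorder_filtered <- !is.na(mean_dis)
  keep <- is.na(mean_dis) | mean_dis >= min_mean
  res <- matches[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read and write protein FASTA files
#'
#' Reading uses the first whitespace-delimited header token as the
#' protein id and upper-cases sequences.
#'
#' @param path File path.
#' @return `read_fasta()`: data frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  data.frame(id = ids, sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta
#' @param records Data frame with columns `id` and `sequence`.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}
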