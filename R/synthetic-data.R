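#' Specification for the synthetic-data generator
#'
#' Bundles the parameters of every synthetic fixture the package can
#' generate: a proteome with planted TBM octapeptides, a phosphosite
#' table with planted position-8 events and planted term enrichment, FP
#' titrations from the one-site total-binding model, and toy coordinate
#' sets for superposition. Defaults emulate the study conditions at
#' desk scale: the planted position-8 composition (31 S, 7 T, 5 Y) is a
#' one-tenth-scale version of the proteome-wide census, the 600-protein
#' population keeps the planted hosts a small fraction of the proteome
#' (as a real study set is, so genuine term enrichment can manifest),
#' titration
#' parameters use the MDC1 Kd pair with plate-reader-like noise, and
#' the planted term mimics a centrosome-biology annotation that is
#' strongly over-represented among phospho-position-8 host proteins.
#'
#' @param seed Mandatory RNG seed; every generator call derives its
#'   stream from it, so identical specs give byte-identical fixtures.
#' @param n_proteins,protein_length Proteome shape.
#' @param planted_pos8 Named integer vector over S/T/Y: how many motifs
#'   to plant with each position-8 residue.
#' @param planted_motifs Optional explicit data frame (`host`, `start`,
#'   `octapeptide`) overriding `planted_pos8`; `start` may be NA for
#'   random placement.
#' @param phospho_rate_background Per-residue background
#'   phosphorylation probability for S/T/Y residues.
#' @param planted_pos8_prob Probability that a planted motif's
#'   position-8 residue carries a phospho-event.
#' @param planted_term List describing the enriched term: `term_id`,
#'   `term_name`, `member_prob_phospho` (membership probability for
#'   phospho-position-8 host proteins), `member_prob_background`.
#' @param n_background_terms,background_term_prob Unenriched decoy
#'   terms and their uniform membership probability.
#' @param fp_specs Data frame (`name`, `kd`, `bmax`, `ns`, `noise_sd`)
#'   of titrations to simulate.
#' @param tts_threshold Scan threshold the background must stay below.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(
    seed,
    n_proteins = 600L,
    protein_length = 400L,
    planted_pos8 = c(S = 31L, T = 7L, Y = 5L),
    planted_motifs = NULL,
    phospho_rate_background = 0.01,
    planted_pos8_prob = 1,
    planted_term = list(term_id = "T0001",
                        term_name = "centrosome organization (synthetic)",
                        member_prob_phospho = 0.9,
                        member_prob_background = 0.05),
    n_background_terms = 10L,
    background_term_prob = 0.2,
    fp_specs = data.frame(
      name = c("MDC1_nonphospho", "MDC1_pS8"),
      kd = c(4.5, 1.7), bmax = 150, ns = 0.1, noise_sd = 3),
    tts_threshold = 0.385) {
  if (missing(seed)) stop_input("a seed is mandatory")
  probs <- c(phospho_rate_background, planted_pos8_prob,
             planted_term$member_prob_phospho,
             planted_term$member_prob_background, background_term_prob)
  if (any(probs < 0 | probs > 1)) {
    stop_input("probabilities must lie in [0, 1]")
  }
  structure(list(
    seed = seed, n_proteins = n_proteins,
    protein_length = protein_length, planted_pos8 = planted_pos8,
    planted_motifs = planted_motifs,
    phospho_rate_background = phospho_rate_background,
    planted_pos8_prob = planted_pos8_prob,
    planted_term = planted_term,
    n_background_terms = n_background_terms,
    background_term_prob = background_term_prob,
    fp_specs = fp_specs, tts_threshold = tts_threshold),
    class = "synthetic_spec")
}

random_consensus_octapeptide <- function(pos8) {
  small <- c("A", "C", "G", "I", "L", "M", "P", "S", "T", "V")
  paste0("R",
         sample(AA_ALPHABET, 1), sample(AA_ALPHABET, 1),
         sample(small, 1), sample(ACIDIC_AA, 1), "G",
         sample(setdiff(AA_ALPHABET, "P"), 1), pos8)
}

#' Generate a proteome with planted TBM octapeptides
#'
#' Draws i.i.d. uniform background residues and inserts the planted
#' octapeptides at their (possibly random) start positions. Each
#' protein's background is redrawn (rejection sampling) until scanning
#' it recovers exactly the planted motifs, so the ground truth is the
#' complete match set at the spec's threshold.
#'
#' @param spec A [synthetic_spec()].
#' @param pssm The scanning PSSM; default [build_default_pssm()].
#' @param max_tries Rejection-sampling cap per protein.
#' @return List with `records` (data frame `id`, `sequence`) and
#'   `truth` (the expected [scan_proteome()] output).
#' @export
make_proteome <- function(spec, pssm = build_default_pssm(),
                          max_tries = 100L) {
  set.seed(spec$seed)
  n <- spec$n_proteins
  L <- rep_len(spec$protein_length, n)
  ids <- sprintf("SYNP%04d", seq_len(n))
  planted <- spec$planted_motifs
  if (is.null(planted)) {
    pos8 <- rep(names(spec$planted_pos8), spec$planted_pos8)
    if (length(pos8) > n) {
      stop_input("more planted motifs than host proteins")
    }
    planted <- data.frame(
      host = seq_along(pos8),
      start = rep(NA_integer_, length(pos8)),
      octapeptide = vapply(pos8, random_consensus_octapeptide,
                           character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
  }
  if (any(planted$host < 1 | planted$host > n)) {
    stop_input("planted host index out of range")
  }
  planted$start <- as.integer(planted$start)
  for (i in seq_len(nrow(planted))) {
    if (is.na(planted$start[i])) {
      planted$start[i] <- sample.int(L[planted$host[i]] - 7L, 1)
    }
    if (planted$start[i] + 7L > L[planted$host[i]]) {
      stop_input("planted motif does not fit in host protein ",
                 planted$host[i])
    }
  }
  # non-overlapping placements within a host
  for (h in unique(planted$host)) {
    st <- sort(planted$start[planted$host == h])
    if (length(st) > 1 && any(diff(st) < 8L)) {
      stop_input("overlapping planted motifs in host ", h)
    }
  }
  seqs <- character(n)
  for (i in seq_len(n)) {
    mine <- planted[planted$host == i, , drop = FALSE]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- paste(sample(AA_ALPHABET, L[i], replace = TRUE),
                 collapse = "")
      for (j in seq_len(nrow(mine))) {
        substr(s, mine$start[j], mine$start[j] + 7L) <-
          mine$octapeptide[j]
      }
      hits <- scan_proteome(data.frame(id = ids[i], sequence = s),
                            pssm, spec$tts_threshold)
      if (nrow(hits) == nrow(mine) &&
          setequal(hits$start, mine$start)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop_input("could not place a TBM-free background for protein ",
                 ids[i], " in ", max_tries, " tries")
    }
    seqs[i] <- s
  }
  records <- data.frame(id = ids, sequence = seqs,
                        stringsAsFactors = FALSE)
  truth <- data.frame(
    protein_id = ids[planted$host],
    start = planted$start,
    end = planted$start + 7L,
    octapeptide = planted$octapeptide,
    tts = tts_score(planted$octapeptide, pssm),
    pos8_class = classify_pos8(substring(planted$octapeptide, 8, 8)),
    stringsAsFactors = FALSE)
  truth <- truth[order(-truth$tts, truth$protein_id, truth$start), ,
                 drop = FALSE]
  rownames(truth) <- NULL
  list(records = records, truth = truth)
}

#' Generate a phosphosite table with planted position-8 events
#'
#' Background S/T/Y residues are phosphorylated independently at the
#' spec's background rate; each planted motif's position-8 residue gets
#' an event with probability `planted_pos8_prob`. Ground-truth arm
#' counts are tallied from the events actually emitted, so they are
#' exact regardless of the probabilities chosen.
#'
#' @param spec A [synthetic_spec()].
#' @param proteome Result of [make_proteome()].
#' @return List with `events` (phosphosite data frame) and `truth`
#'   (list: `arm_motif_counts`, `arm_protein_counts`,
#'   `phospho8_hosts_st` — host proteins of the pS8/pT8 union).
#' @export
make_phospho_table <- function(spec, proteome) {
  set.seed(spec$seed + 1L)
  records <- proteome$records
  truth <- proteome$truth
  ev <- list()
  for (i in seq_len(nrow(records))) {
    chars <- strsplit(records$sequence[i], "")[[1]]
    sty <- which(chars %in% c("S", "T", "Y"))
    if (length(sty) > 0 && spec$phospho_rate_background > 0) {
      hit <- sty[stats::runif(length(sty)) < spec$phospho_rate_background]
      if (length(hit) > 0) {
        ev[[length(ev) + 1]] <- data.frame(
          protein_id = records$id[i], residue_number = hit,
          residue_type = chars[hit], modification = "phospho",
          stringsAsFactors = FALSE)
      }
    }
  }
  planted8 <- truth[substring(truth$octapeptide, 8, 8) %in%
                      c("S", "T", "Y"), , drop = FALSE]
  if (nrow(planted8) > 0) {
    take <- stats::runif(nrow(planted8)) < spec$planted_pos8_prob
    sel <- planted8[take, , drop = FALSE]
    if (nrow(sel) > 0) {
      ev[[length(ev) + 1]] <- data.frame(
        protein_id = sel$protein_id, residue_number = sel$end,
        residue_type = substring(sel$octapeptide, 8, 8),
        modification = "phospho", stringsAsFactors = FALSE)
    }
  }
  events <- if (length(ev) > 0) unique(do.call(rbind, ev)) else
    data.frame(protein_id = character(), residue_number = integer(),
               residue_type = character(), modification = character(),
               stringsAsFactors = FALSE)
  rownames(events) <- NULL
  # exact ground truth: motifs whose position-8 residue carries an event
  key_ev <- paste(events$protein_id, events$residue_number)
  has8 <- paste(truth$protein_id, truth$end) %in% key_ev &
    substring(truth$octapeptide, 8, 8) %in% c("S", "T", "Y")
  arm <- paste0("p", substring(truth$octapeptide, 8, 8), "8")
  arm[!has8] <- "none"
  counts <- vapply(c("pS8", "pT8", "pY8"),
                   function(a) sum(arm == a), integer(1))
  prot_counts <- vapply(c("pS8", "pT8", "pY8"), function(a)
    length(unique(truth$protein_id[arm == a])), integer(1))
  hosts_st <- sort(unique(truth$protein_id[arm %in% c("pS8", "pT8")]))
  list(events = events,
       truth = list(arm_motif_counts = counts,
                    arm_protein_counts = prot_counts,
                    phospho8_hosts_st = hosts_st))
}

#' Generate a term-annotation table with one planted enriched term
#'
#' The planted term preferentially annotates the host proteins of
#' phosphorylated position-8 motifs; decoy terms annotate proteins
#' uniformly at random, so only the planted term is enriched by
#' construction.
#'
#' @param spec A [synthetic_spec()].
#' @param proteome Result of [make_proteome()].
#' @param phospho Result of [make_phospho_table()].
#' @return List with `annotations` (data frame `protein_id`, `term_id`,
#'   `term_name`) and `truth` (list: `planted_term_id`).
#' @export
make_term_annotations <- function(spec, proteome, phospho) {
  set.seed(spec$seed + 2L)
  ids <- proteome$records$id
  hosts <- phospho$truth$phospho8_hosts_st
  pt <- spec$planted_term
  p_member <- ifelse(ids %in% hosts, pt$member_prob_phospho,
                     pt$member_prob_background)
  planted_members <- ids[stats::runif(length(ids)) < p_member]
  rows <- list(data.frame(protein_id = planted_members,
                          term_id = pt$term_id,
                          term_name = pt$term_name,
                          stringsAsFactors = FALSE))
  for (t in seq_len(spec$n_background_terms)) {
    members <- ids[stats::runif(length(ids)) < spec$background_term_prob]
    if (length(members) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      protein_id = members,
      term_id = sprintf("T%04d", t + 1L),
      term_name = sprintf("background process %d (synthetic)", t),
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  rownames(ann) <- NULL
  list(annotations = ann, truth = list(planted_term_id = pt$term_id))
}

random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Generate a toy structure pair with known transform and displacement
#'
#' Builds an idealised Calpha helix, then a copy in which one probe
#' residue is shifted by a controlled distance before a random rigid
#' transform is applied to the whole copy. Superposing the pair on all
#' non-probe residues therefore recovers the applied rotation exactly
#' and leaves the probe displaced by exactly `shift` Angstrom.
#'
#' @param seed RNG seed for the random transform and shift direction.
#' @param n_res Number of helix residues.
#' @param probe_res Residue index receiving the local shift.
#' @param shift Shift magnitude in Angstrom (default 1.3, the scale of
#'   a phosphate-accommodating backbone displacement).
#' @return List with `model_a`, `model_b` (`structure_model`s),
#'   `rotation`, `translation`, `probe_res`, `shift`.
#' @export
make_toy_structures <- function(seed = 1L, n_res = 12L, probe_res = 8L,
                                shift = 1.3) {
  stopifnot(probe_res >= 1, probe_res <= n_res, n_res >= 4)
  set.seed(seed)
  i <- seq_len(n_res)
  theta <- (i - 1) * 100 * pi / 180      # ideal alpha-helix geometry
  A <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
  R <- random_rotation_matrix()
  t_vec <- stats::runif(3, -10, 10)
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  B_local <- A
  B_local[probe_res, ] <- B_local[probe_res, ] + shift * u
  B <- sweep(B_local %*% t(R), 2, t_vec, `+`)
  as_model <- function(xyz, chain) structure_model(data.frame(
    chain = chain, resno = i, resid = "ALA", elety = "CA",
    elesy = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
  list(model_a = as_model(A, "A"), model_b = as_model(B, "A"),
       rotation = R, translation = t_vec,
       probe_res = probe_res, shift = shift)
}

#' Write a full synthetic dataset to disk
#'
#' Emits every fixture a pipeline run needs: proteome FASTA, phosphosite
#' and annotation TSVs, one plate CSV per titration (with no-protein
#' baseline wells), a toy structure pair as PDB, and a JSON ground-truth
#' file.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with file `paths` and the generator
#'   `truth`.
#' @export
simulate_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "plates"), showWarnings = FALSE)
  proteome <- make_proteome(spec)
  phospho <- make_phospho_table(spec, proteome)
  ann <- make_term_annotations(spec, proteome, phospho)
  paths <- list(
    fasta = file.path(dir, "proteome.fasta"),
    phospho = file.path(dir, "phospho.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    structures = file.path(dir, c("toy_a.pdb", "toy_b.pdb")),
    truth = file.path(dir, "truth.json"))
  write_fasta(proteome$records, paths$fasta)
  write_tsv(phospho$events, paths$phospho)
  write_tsv(ann$annotations, paths$annotations)
  plate_paths <- character(0)
  for (i in seq_len(nrow(spec$fp_specs))) {
    fs <- spec$fp_specs[i, ]
    tt <- simulate_titration(fs$kd, fs$bmax, fs$ns,
                             noise_sd = fs$noise_sd,
                             seed = spec$seed + 10L + i,
                             peptide_name = fs$name)
    wells <- data.frame(conc = c(0, 0, tt$conc),
                        fp = c(100, 100, tt$delta_fp + 100),
                        replicate_id = 1L,
                        is_baseline = c(TRUE, TRUE,
                                        rep(FALSE, nrow(tt))))
    p <- file.path(dir, "plates", paste0(fs$name, ".csv"))
    utils::write.csv(wells, p, row.names = FALSE)
    plate_paths <- c(plate_paths, p)
  }
  paths$plates <- plate_paths
  toys <- make_toy_structures(seed = spec$seed + 20L)
  write_structure(toys$model_a, paths$structures[1])
  write_structure(toys$model_b, paths$structures[2])
  truth <- list(
    n_planted_motifs = nrow(proteome$truth),
    arm_motif_counts = as.list(phospho$truth$arm_motif_counts),
    arm_protein_counts = as.list(phospho$truth$arm_protein_counts),
    n_phospho8_hosts_st = length(phospho$truth$phospho8_hosts_st),
    planted_term_id = ann$truth$planted_term_id,
    toy_shift = toys$shift)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(paths = paths,
                 truth = list(proteome = proteome$truth,
                              phospho = phospho$truth,
                              annotations = ann$truth,
                              toys = toys)))
}
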