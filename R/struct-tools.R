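#' Read a structure into an atom table
#'
#' Wraps bio3d's PDB/mmCIF readers and returns a flat atom table. For
#' atoms with alternate locations only the highest-occupancy conformer
#' is kept; hydrogens are dropped (all contact criteria in this package
#' are heavy-atom based).
#'
#' @param path PDB (.pdb/.ent) or mmCIF (.cif) file.
#' @param keep_hydrogens Logical, default FALSE.
#' @return A `structure_model`: data frame with columns `chain`,
#'   `resno`, `ins`, `resid`, `elety` (atom name), `elesy` (element),
#'   `x`, `y`, `z`, `b`, `o`.
#' @export
read_structure <- function(path, keep_hydrogens = FALSE) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  a <- pdb$atom
  elesy <- a$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == "")) {
    elesy <- substr(gsub("[^A-Za-z].*", "", trimws(a$elety)), 1, 1)
  }
  m <- data.frame(chain = a$chain, resno = a$resno,
                  ins = ifelse(is.na(a$insert), "", a$insert),
                  resid = a$resid, elety = trimws(a$elety),
                  elesy = toupper(trimws(elesy)),
                  x = a$x, y = a$y, z = a$z,
                  b = a$b %||% 0, o = a$o %||% 1,
                  stringsAsFactors = FALSE)
  if (!keep_hydrogens) m <- m[!m$elesy %in% c("H", "D"), , drop = FALSE]
  # keep highest-occupancy alternate conformer per atom
  key <- paste(m$chain, m$resno, m$ins, m$elety)
  m <- m[order(key, -m$o), , drop = FALSE]
  m <- m[!duplicated(paste(m$chain, m$resno, m$ins, m$elety)), ,
         drop = FALSE]
  m <- m[order(m$chain, m$resno, m$ins, m$elety), , drop = FALSE]
  rownames(m) <- NULL
  structure_model(m)
}

#' @rdname read_structure
#' @param atoms Data frame of atoms (columns as above; `ins`, `b`, `o`,
#'   `elesy` optional).
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop_input("atom table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!"b" %in% names(atoms)) atoms$b <- 0
  if (!"o" %in% names(atoms)) atoms$o <- 1
  if (!"elesy" %in% names(atoms)) {
    atoms$elesy <- substr(gsub("[0-9']", "", atoms$elety), 1, 1)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop_input("coordinates must be finite")
  }
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety)
  if (anyDuplicated(key)) {
    stop_input("duplicate (chain, residue, atom) entries")
  }
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

#' Write a structure model as PDB text
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @export
write_structure <- function(model, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(model)),
    ifelse(nchar(model$elety) < 4, paste0(" ", model$elety), model$elety),
    model$resid, model$chain, model$resno,
    ifelse(model$ins == "", " ", model$ins),
    model$x, model$y, model$z, model$o, model$b, model$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Select atoms from a structure model
#'
#' @param model A `structure_model`.
#' @param chain,resno,elety,resid Optional filters (vectors).
#' @return The matching atom rows, ordered by chain, residue, atom.
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL,
                         elety = NULL, resid = NULL) {
  keep <- rep(TRUE, nrow(model))
  if (!is.null(chain)) keep <- keep & model$chain %in% chain
  if (!is.null(resno)) keep <- keep & model$resno %in% resno
  if (!is.null(elety)) keep <- keep & model$elety %in% elety
  if (!is.null(resid)) keep <- keep & model$resid %in% resid
  out <- model[keep, , drop = FALSE]
  out <- out[order(out$chain, out$resno, out$ins, out$elety), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

coords_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  as.matrix(x[, c("x", "y", "z")])
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising the RMSD
#' between `R %*% mobile + t` and `fixed` over a paired atom list, via
#' singular value decomposition of the cross-covariance matrix with the
#' usual determinant sign correction.
#'
#' @param fixed,mobile n x 3 coordinate matrices (or atom tables with
#'   x/y/z columns) with paired rows; n >= 3.
#' @return A `superposition` list: `rotation` (3 x 3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom), `n_atoms`.
#' @export
kabsch_superpose <- function(fixed, mobile) {
  P <- coords_matrix(mobile)
  Q <- coords_matrix(fixed)
  if (nrow(P) != nrow(Q)) stop_input("coordinate lists must be paired")
  if (nrow(P) < 3) stop_input("need at least 3 atom pairs")
  cm_p <- colMeans(P); cm_q <- colMeans(Q)
  Pc <- sweep(P, 2, cm_p); Qc <- sweep(Q, 2, cm_q)
  H <- crossprod(Pc, Qc)                       # 3x3 cross-covariance
  if (qr(Pc)$rank < 2) stop_input("degenerate (rank-deficient) coordinates")
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Qc)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cm_q - R %*% cm_p),
                 rmsd = rmsd, n_atoms = nrow(P)),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sup A `superposition` from [kabsch_superpose()].
#' @param coords n x 3 matrix or atom table.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  X <- coords_matrix(coords)
  sweep(X %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms: rmsd %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Probe-atom displacement between two superposed structures
#'
#' Superposes structure `b` onto structure `a` using a shared alignment
#' selection (typically the ARC Calpha atoms) and returns the Euclidean
#' distance between a probe atom in the two frames — e.g. the Calpha of
#' the TBM position-8 residue to quantify the backbone shift that
#' accommodates the phosphate.
#'
#' Alignment atoms are paired in (chain, resno, atom) order, so the two
#' selections must describe corresponding residues (map peptide residues
#' to a common numbering, such as TBM position index, before calling if
#' the deposited numbering differs).
#'
#' @param model_a,model_b `structure_model` objects.
#' @param align_a,align_b Selection lists (arguments to
#'   [select_atoms()]) defining the paired alignment atoms in each
#'   model; `align_b` defaults to `align_a`.
#' @param probe_a,probe_b Selection lists that resolve to exactly one
#'   atom in each model; `probe_b` defaults to `probe_a`.
#' @return Distance in Angstrom, with the `superposition` attached as
#'   attribute "superposition".
#' @export
ca_displacement <- function(model_a, model_b, align_a,
                            align_b = align_a,
                            probe_a, probe_b = probe_a) {
  sel_a <- do.call(select_atoms, c(list(model_a), align_a))
  sel_b <- do.call(select_atoms, c(list(model_b), align_b))
  if (nrow(sel_a) == 0 || nrow(sel_b) == 0) {
    stop_input("alignment selection matched no atoms")
  }
  if (nrow(sel_a) != nrow(sel_b)) {
    stop_input("alignment selections differ in size (",
               nrow(sel_a), " vs ", nrow(sel_b), ")")
  }
  pa <- do.call(select_atoms, c(list(model_a), probe_a))
  pb <- do.call(select_atoms, c(list(model_b), probe_b))
  if (nrow(pa) != 1 || nrow(pb) != 1) {
    stop_input("probe selection must resolve to exactly one atom ",
               "(got ", nrow(pa), " and ", nrow(pb), ")")
  }
  sup <- kabsch_superpose(sel_a, sel_b)
  pb_aligned <- apply_superposition(sup, pb)
  d <- sqrt(sum((coords_matrix(pa) - pb_aligned)^2))
  attr(d, "superposition") <- sup
  d
}

# Atom-name sets defining charged groups for salt-bridge detection.
SALTBRIDGE_ATOMS <- list(
  LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2"),
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"))
PHOSPHATE_ATOMS <- c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3")

saltbridge_eligible <- function(model) {
  keep <- model$elety %in% PHOSPHATE_ATOMS
  for (res in names(SALTBRIDGE_ATOMS)) {
    keep <- keep | (model$resid == res &
                    model$elety %in% SALTBRIDGE_ATOMS[[res]])
  }
  model[keep, , drop = FALSE]
}

#' Census of polar contacts between two atom selections
#'
#' In `saltbridge` mode, pairs charged-group nitrogens/oxygens (Lys NZ;
#' Arg NE/NH1/NH2; His ND1/NE2; Asp/Glu carboxylate oxygens; phosphate
#' O1P/O2P/O3P) across the two selections within the cutoff (default
#' 4.0 Angstrom). In `hbond_heavy` mode, pairs any heavy N/O
#' donor/acceptor atoms within the cutoff (default 3.5 Angstrom).
#'
#' @param model A `structure_model`.
#' @param sel_a,sel_b Selection lists (arguments to [select_atoms()]).
#' @param cutoff Distance cutoff in Angstrom; defaults depend on mode.
#' @param mode "saltbridge" or "hbond_heavy".
#' @return Data frame of contacts (`chain_a`, `resno_a`, `resid_a`,
#'   `atom_a`, same for b, `distance`), sorted by distance, with the
#'   contact count as attribute "count".
#' @export
contact_census <- function(model, sel_a, sel_b, cutoff = NULL,
                           mode = c("saltbridge", "hbond_heavy")) {
  mode <- match.arg(mode)
  cutoff <- cutoff %||% if (mode == "saltbridge") 4.0 else 3.5
  a <- do.call(select_atoms, c(list(model), sel_a))
  b <- do.call(select_atoms, c(list(model), sel_b))
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop_input("empty atom selection")
  }
  if (mode == "saltbridge") {
    a <- saltbridge_eligible(a)
    b <- saltbridge_eligible(b)
  } else {
    a <- a[a$elesy %in% c("N", "O"), , drop = FALSE]
    b <- b[b$elesy %in% c("N", "O"), , drop = FALSE]
  }
  res <- data.frame(chain_a = character(), resno_a = integer(),
                    resid_a = character(), atom_a = character(),
                    chain_b = character(), resno_b = integer(),
                    resid_b = character(), atom_b = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(a) > 0 && nrow(b) > 0) {
    xa <- coords_matrix(a); xb <- coords_matrix(b)
    dist2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) -
      2 * xa %*% t(xb)
    dist2[dist2 < 0] <- 0
    idx <- which(dist2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      same <- paste(a$chain[idx[, 1]], a$resno[idx[, 1]],
                    a$elety[idx[, 1]]) ==
              paste(b$chain[idx[, 2]], b$resno[idx[, 2]],
                    b$elety[idx[, 2]])
      idx <- idx[!same, , drop = FALSE]
    }
    if (nrow(idx) > 0) {
      res <- data.frame(
        chain_a = a$chain[idx[, 1]], resno_a = a$resno[idx[, 1]],
        resid_a = a$resid[idx[, 1]], atom_a = a$elety[idx[, 1]],
        chain_b = b$chain[idx[, 2]], resno_b = b$resno[idx[, 2]],
        resid_b = b$resid[idx[, 2]], atom_b = b$elety[idx[, 2]],
        distance = sqrt(dist2[idx]), stringsAsFactors = FALSE)
      res <- res[order(res$distance), , drop = FALSE]
      rownames(res) <- NULL
    }
  }
  attr(res, "count") <- nrow(res)
  res
}

#' Conservation colour ramp
#'
#' Red for identity >= 95%, a linear red-to-white gradient over
#' (90, 95), and white for identity <= 90%.
#'
#' @param identity_pct Numeric vector of percent identities in
#'   \[0, 100\].
#' @return Data frame with columns `identity_pct`, `r`, `g`, `b` (0-255)
#'   and `hex`.
#' @export
conservation_colour <- function(identity_pct) {
  if (any(identity_pct < 0 | identity_pct > 100)) {
    stop_input("identity must lie in [0, 100]")
  }
  frac <- pmin(1, pmax(0, (95 - identity_pct) / 5))  # 0 = red, 1 = white
  g <- round(255 * frac)
  data.frame(identity_pct = identity_pct, r = 255L, g = as.integer(g),
             b = as.integer(g),
             hex = grDevices::rgb(255, g, g, maxColorValue = 255),
             stringsAsFactors = FALSE)
}

#' Map per-residue conservation onto a structure
#'
#' Writes percent identity into the B-factor column (the conventional
#' channel for colouring in molecular viewers) and returns the
#' accompanying colour table.
#'
#' @param model A `structure_model`.
#' @param identity Data frame with columns `residue_number` and
#'   `identity_pct` (as produced by
#'   [percent_identity_per_reference_residue()]), or a named numeric
#'   vector keyed by residue number.
#' @param chain Optional chain restriction for the mapping.
#' @return List with elements `model` (B-factors recoded; residues
#'   without an identity value get B = 0) and `colours` (per-residue
#'   colour table).
#' @export
conservation_to_structure <- function(model, identity, chain = NULL) {
  if (is.numeric(identity) && !is.null(names(identity))) {
    identity <- data.frame(residue_number = as.integer(names(identity)),
                           identity_pct = as.numeric(identity))
  }
  stopifnot(all(c("residue_number", "identity_pct") %in% names(identity)))
  if (any(identity$identity_pct < 0 | identity$identity_pct > 100)) {
    stop_input("identity must lie in [0, 100]")
  }
  idx <- match(model$resno, identity$residue_number)
  vals <- identity$identity_pct[idx]
  in_chain <- if (is.null(chain)) rep(TRUE, nrow(model))
              else model$chain %in% chain
  model$b <- ifelse(in_chain & !is.na(vals), vals, 0)
  cols <- cbind(residue_number = identity$residue_number,
                conservation_colour(identity$identity_pct))
  list(model = structure_model(as.data.frame(model)), colours = cols)
}
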