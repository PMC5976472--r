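AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

# First side-chain heavy atom beyond CB (the chi1 "gamma" atom).
GAMMA_ATOM <- c(ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG",
                GLU = "CG", HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG",
                MET = "CG", PHE = "CG", PRO = "CG", SER = "OG", THR = "OG1",
                TRP = "CG", TYR = "CG", VAL = "CG1")

RING_GROUPS <- list(
  TRP = c("CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PRO = c("N", "CA", "CB", "CG", "CD")
)

# Side-chain internal-coordinate templates beyond CB. Each row places one
# atom: refs are names of atoms already placed in the same residue (backbone
# included), tau_kind "chi1" uses the requested chi1, "chi1_off" adds the
# stated offset to chi1, "fixed" uses tau as given. Bond lengths/angles are
# ideal-geometry values; rings close only approximately, which is sufficient
# for centroid/contact/occupancy analyses.
sc_row <- function(name, element, r1, r2, r3, bond, angle, tau_kind, tau) {
  list(name = name, element = element, ref1 = r1, ref2 = r2, ref3 = r3,
       bond = bond, angle = angle, tau_kind = tau_kind, tau = tau)
}

SIDECHAIN_TEMPLATES <- list(
  GLY = list(),
  ALA = list(),
  SER = list(
    sc_row("OG", "O", "N", "CA", "CB", 1.417, 110.8, "chi1", 0),
    sc_row("HG", "H", "CA", "CB", "OG", 0.96, 109.5, "fixed", 180)),
  CYS = list(
    sc_row("SG", "S", "N", "CA", "CB", 1.808, 113.8, "chi1", 0),
    sc_row("HG", "H", "CA", "CB", "SG", 1.33, 96.0, "fixed", 180)),
  THR = list(
    sc_row("OG1", "O", "N", "CA", "CB", 1.433, 109.5, "chi1", 0),
    sc_row("CG2", "C", "N", "CA", "CB", 1.521, 110.5, "chi1_off", -120),
    sc_row("HG1", "H", "CA", "CB", "OG1", 0.96, 109.5, "fixed", 180)),
  VAL = list(
    sc_row("CG1", "C", "N", "CA", "CB", 1.527, 110.5, "chi1", 0),
    sc_row("CG2", "C", "N", "CA", "CB", 1.527, 110.5, "chi1_off", 122)),
  LEU = list(
    sc_row("CG", "C", "N", "CA", "CB", 1.530, 116.3, "chi1", 0),
    sc_row("CD1", "C", "CA", "CB", "CG", 1.521, 110.7, "fixed", 180),
    sc_row("CD2", "C", "CA", "CB", "CG", 1.521, 110.7, "fixed", 60)),
  ILE = list(
    sc_row("CG1", "C", "N", "CA", "CB", 1.530, 110.4, "chi1", 0),
    sc_row("CG2", "C", "N", "CA", "CB", 1.521, 110.5, "chi1_off", -122),
    sc_row("CD1", "C", "CA", "CB", "CG1", 1.513, 113.8, "fixed", 180)),
  MET = list(
    sc_row("CG", "C", "N", "CA", "CB", 1.520, 114.1, "chi1", 0),
    sc_row("SD", "S", "CA", "CB", "CG", 1.803, 112.7, "fixed", 180),
    sc_row("CE", "C", "CB", "CG", "SD", 1.791, 100.9, "fixed", 180)),
  ASP = list(
    sc_row("CG", "C", "N", "CA", "CB", 1.516, 112.6, "chi1", 0),
    sc_row("OD1", "O", "CA", "CB", "CG", 1.249, 118.4, "fixed", -10),
    sc_row("OD2", "O", "CA", "CB", "CG", 1.249, 118.4, "fixed", 170)),
  ASN = list(
    sc_row("CG", "C", "N", "CA", "CB", 1.516, 112.6, "chi1", 0),
    sc_row("OD1", "O", "CA", "CB", "CG", 1.231, 120.8, "fixed", -30),
    sc_row("ND2", "N", "CA", "CB", "CG", 1.328, 116.4, "fixed", 150),
    sc_row("HD21", "H", "CB", "CG", "ND2", 1.01, 120.0, "fixed", 0),
    sc_row("HD22", "H", "CB", "CG", "ND2", 1.01, 120.0, "fixed", 180)),
  GLU = list(
    sc_row("CG", "C", "N", "CA", "CB", 1.530, 114.1, "chi1", 0),
    sc_row("CD", "C", "CA", "CB", "CG", 1.516, 112.6, "fixed", 180),
    sc_row("OE1", "O", "CB", "CG", "CD", 1.249, 118.4, "fixed", -10),
    sc_row("OE2", "O", "CB", "CG", "CD", 1.249, 118.4, "fixed", 170)),
  GLN = list(
    sc_row("CG", "C", "N", "CA", "CB", 1.530, 114.1, "chi1", 0),
    sc_row("CD", "C", "CA", "CB", "CG", 1.516, 112.6, "fixed", 180),
    sc_row("OE1", "O", "CB", "CG", "CD", 1.231, 120.8, "fixed", -30),
    sc_row("NE2", "N", "CB", "CG", "CD", 1.328, 116.4, "fixed", 150),
    sc_row("HE21", "H", "CG", "CD", "NE2", 1.01, 120.0, "fixed", 0),
    sc_row("HE22", "H", "CG", "CD", "NE2", 1.01, 120.0, "fixed", 180)),
  LYS = list(
    sc_row("CG", "C", "N", "CA", "CB", 1.530, 114.1, "chi1", 0),
    sc_row("CD", "C", "CA", "CB", "CG", 1.520, 111.3, "fixed", 180),
    sc_row("CE", "C", "CB", "CG", "CD", 1.520, 111.3, "fixed", 180),
    sc_row("NZ", "N", "CG", "CD", "CE", 1.489, 111.9, "fixed", 180),
    sc_row("HZ1", "H", "CD", "CE", "NZ", 1.01, 109.5, "fixed", 180),
    sc_row("HZ2", "H", "CD", "CE", "NZ", 1.01, 109.5, "fixed", 60),
    sc_row("HZ3", "H", "CD", "CE", "NZ", 1.01, 109.5, "fixed", -60)),
  ARG = list(
    sc_row("CG", "C", "N", "CA", "CB", 1.530, 114.1, "chi1", 0),
    sc_row("CD", "C", "CA", "CB", "CG", 1.520, 111.3, "fixed", 180),
    sc_row("NE", "N", "CB", "CG", "CD", 1.461, 112.0, "fixed", 180),
    sc_row("CZ", "C", "CG", "CD", "NE", 1.330, 124.2, "fixed", 180),
    sc_row("HE", "H", "CG", "CD", "NE", 1.01, 118.0, "fixed", 0),
    sc_row("NH1", "N", "CD", "NE", "CZ", 1.326, 120.0, "fixed", 0),
    sc_row("NH2", "N", "CD", "NE", "CZ", 1.326, 120.0, "fixed", 180),
    sc_row("HH11", "H", "NE", "CZ", "NH1", 1.01, 120.0, "fixed", 0),
    sc_row("HH12", "H", "NE", "CZ", "NH1", 1.01, 120.0, "fixed", 180),
    sc_row("HH21", "H", "NE", "CZ", "NH2", 1.01, 120.0, "fixed", 0),
    sc_row("HH22", "H", "NE", "CZ", "NH2", 1.01, 120.0, "fixed", 180)),
  HIS = list(
    sc_row("CG", "C", "N", "CA", "CB", 1.497, 113.8, "chi1", 0),
    sc_row("ND1", "N", "CA", "CB", "CG", 1.378, 122.7, "fixed", -90),
    sc_row("CD2", "C", "CA", "CB", "CG", 1.356, 131.0, "fixed", 90),
    sc_row("CE1", "C", "CB", "CG", "ND1", 1.321, 109.3, "fixed", 180),
    sc_row("NE2", "N", "CB", "CG", "CD2", 1.374, 107.2, "fixed", 180),
    sc_row("HE2", "H", "CG", "CD2", "NE2", 1.01, 125.0, "fixed", 180)),
  PHE = list(
    sc_row("CG", "C", "N", "CA", "CB", 1.502, 113.8, "chi1", 0),
    sc_row("CD1", "C", "CA", "CB", "CG", 1.384, 120.8, "fixed", -90),
    sc_row("CD2", "C", "CA", "CB", "CG", 1.384, 120.8, "fixed", 90),
    sc_row("CE1", "C", "CB", "CG", "CD1", 1.382, 120.8, "fixed", 180),
    sc_row("CE2", "C", "CB", "CG", "CD2", 1.382, 120.8, "fixed", 180),
    sc_row("CZ", "C", "CG", "CD1", "CE1", 1.380, 120.0, "fixed", 0)),
  TYR = list(
    sc_row("CG", "C", "N", "CA", "CB", 1.502, 113.8, "chi1", 0),
    sc_row("CD1", "C", "CA", "CB", "CG", 1.384, 120.8, "fixed", -90),
    sc_row("CD2", "C", "CA", "CB", "CG", 1.384, 120.8, "fixed", 90),
    sc_row("CE1", "C", "CB", "CG", "CD1", 1.382, 120.8, "fixed", 180),
    sc_row("CE2", "C", "CB", "CG", "CD2", 1.382, 120.8, "fixed", 180),
    sc_row("CZ", "C", "CG", "CD1", "CE1", 1.380, 120.0, "fixed", 0),
    sc_row("OH", "O", "CD1", "CE1", "CZ", 1.376, 119.9, "fixed", 180),
    sc_row("HH", "H", "CE1", "CZ", "OH", 0.96, 109.5, "fixed", 180)),
  TRP = list(
    sc_row("CG", "C", "N", "CA", "CB", 1.498, 113.6, "chi1", 0),
    sc_row("CD1", "C", "CA", "CB", "CG", 1.365, 126.9, "fixed", -90),
    sc_row("CD2", "C", "CA", "CB", "CG", 1.433, 126.7, "fixed", 90),
    sc_row("NE1", "N", "CB", "CG", "CD1", 1.374, 110.2, "fixed", 180),
    sc_row("CE2", "C", "CB", "CG", "CD2", 1.409, 107.2, "fixed", 180),
    sc_row("CE3", "C", "CB", "CG", "CD2", 1.398, 133.9, "fixed", 0),
    sc_row("CZ2", "C", "CG", "CD2", "CE2", 1.394, 122.4, "fixed", 180),
    sc_row("CZ3", "C", "CG", "CD2", "CE3", 1.382, 118.6, "fixed", 180),
    sc_row("CH2", "C", "CD2", "CE2", "CZ2", 1.368, 117.5, "fixed", 0),
    sc_row("HE1", "H", "CG", "CD1", "NE1", 1.01, 125.0, "fixed", 180)),
  PRO = list(
    # ring torsions are fixed by an (approximate) C-gamma-endo pucker; the
    # requested global chi1 default is ignored for proline
    sc_row("CG", "C", "N", "CA", "CB", 1.492, 104.5, "fixed", 30),
    sc_row("CD", "C", "CA", "CB", "CG", 1.503, 106.1, "fixed", -35))
)

seq1_to_3 <- function(sequence) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(letters1, names(AA3))
  if (length(unknown) > 0) {
    abort(paste0("unknown residue letter(s): ", paste(unknown, collapse = ", ")))
  }
  unname(AA3[letters1])
}

#' Peptide topology
#'
#' A light catalogue of residues, atoms, aromatic/proline ring groups,
#' chi1-defining atom quadruplets and hydrogen attachments for a single
#' peptide chain. Built by [build_peptide()] / [realize_coordinates()] or
#' recovered from a PDB file by [read_ensemble()].
#'
#' @param sequence One-letter amino-acid string.
#' @param atoms Tibble with columns `serial`, `name`, `element`, `resno`,
#'   `resname`.
#' @param h_attach Tibble mapping each hydrogen to its heavy donor atom,
#'   columns `resno`, `h_name`, `heavy_name`.
#' @return An object of class `pep_topology`: a list with elements
#'   `sequence`, `residues` (tibble `resno`, `resname`), `atoms`,
#'   `ring_groups` (named by `resno`), `chi1_quads` (named by `resno`) and
#'   `h_attach`.
#' @export
pep_topology <- function(sequence, atoms, h_attach) {
  res3 <- seq1_to_3(sequence)
  n <- length(res3)
  residues <- tibble(resno = seq_len(n), resname = res3)
  stopifnot(all(atoms$resno %in% residues$resno))
  dup <- atoms |> dplyr::count(.data$resno, .data$name) |> filter(n > 1)
  if (nrow(dup) > 0) abort("duplicate atom names within a residue")
  ring_groups <- list()
  chi1_quads <- list()
  for (i in seq_len(n)) {
    rn <- res3[i]
    here <- atoms$name[atoms$resno == i]
    if (rn %in% names(RING_GROUPS) && all(RING_GROUPS[[rn]] %in% here)) {
      ring_groups[[as.character(i)]] <- RING_GROUPS[[rn]]
    }
    g <- GAMMA_ATOM[rn]
    if (!is.na(g) && all(c("N", "CA", "CB", g) %in% here)) {
      chi1_quads[[as.character(i)]] <- c("N", "CA", "CB", unname(g))
    }
  }
  structure(list(sequence = toupper(sequence), residues = residues,
                 atoms = atoms, ring_groups = ring_groups,
                 chi1_quads = chi1_quads, h_attach = h_attach),
            class = "pep_topology")
}

#' @export
print.pep_topology <- function(x, ...) {
  cat("<pep_topology> ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " atoms (", x$sequence, ")\n", sep = "")
  invisible(x)
}

n_residues <- function(topo) nrow(topo$residues)

# Resolve "Trp18" / 18 / "18" to a residue index, validating the name part.
resolve_residue <- function(topo, res) {
  if (is.numeric(res)) {
    idx <- as.integer(res)
  } else if (grepl("^[0-9]+$", res)) {
    idx <- as.integer(res)
  } else {
    m <- regmatches(res, regexec("^([A-Za-z]{3})([0-9]+)$", res))[[1]]
    if (length(m) != 3) abort(paste0("cannot parse residue label '", res, "'"))
    idx <- as.integer(m[3])
    if (idx < 1 || idx > n_residues(topo)) {
      abort(paste0("residue index ", idx, " out of range"))
    }
    want <- toupper(m[2])
    have <- topo$residues$resname[idx]
    if (want != have) {
      abort(paste0("residue ", idx, " is ", have, ", not ", want))
    }
  }
  if (idx < 1 || idx > n_residues(topo)) {
    abort(paste0("residue index ", idx, " out of range"))
  }
  idx
}

residue_label <- function(topo, idx) {
  rn <- topo$residues$resname[idx]
  paste0(substr(rn, 1, 1), tolower(substr(rn, 2, 3)), idx)
}

# Index of a named atom of a residue into the topology atom table.
atom_index <- function(topo, resno, name) {
  i <- which(topo$atoms$resno == resno & topo$atoms$name == name)
  if (length(i) != 1) {
    abort(paste0("atom ", name, " of residue ", resno, " not found"))
  }
  i
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3")

# Side-chain heavy atoms of a residue (indices into topo$atoms).
sidechain_heavy_idx <- function(topo, resno) {
  a <- topo$atoms
  which(a$resno == resno & a$element != "H" & !(a$name %in% BACKBONE_ATOMS))
}
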