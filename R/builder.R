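# Ideal backbone geometry (Angstrom / degrees). These are the conventional
# Engh-Huber-style values; analyses downstream depend only on torsions and
# coarse distances, not on the third decimal of a bond length.
BB <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231, b_NH = 1.01,
  b_OXT = 1.249,
  a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.8,
  a_CNH = 119.0,
  b_CACB = 1.530, a_CCACB = 110.1, imp_NC_CACB = 122.5
)

# Build coordinates for all frames at once. phi, psi: frames x n matrices in
# degrees (phi[,1] and psi[,n] are ignored for bonded geometry; psi[,n] is
# used to orient the terminal carboxylate when finite, else 180 is used).
# chi1: frames x n matrix. omega is fixed at 180 (trans) everywhere.
pep_build_core <- function(sequence, phi, psi, chi1) {
  res3 <- seq1_to_3(sequence)
  n <- length(res3)
  F <- nrow(phi)
  stopifnot(ncol(phi) == n, ncol(psi) == n, nrow(psi) == F)

  pos <- list()  # pos[[resno]][[atom]] = F x 3 matrix
  put <- function(i, name, m) pos[[i]][[name]] <<- m

  const3 <- function(v) matrix(v, nrow = F, ncol = 3, byrow = TRUE)
  # first residue: N at origin, CA on x, C in the xy-plane
  pos[[1]] <- list()
  put(1, "N", const3(c(0, 0, 0)))
  put(1, "CA", const3(c(BB$b_NCA, 0, 0)))
  a <- (180 - BB$a_NCAC) * pi / 180
  put(1, "C", const3(c(BB$b_NCA + BB$b_CAC * cos(a), BB$b_CAC * sin(a), 0)))

  for (i in seq_len(n)) {
    if (i < n) {
      pos[[i + 1]] <- list()
      put(i + 1, "N", nerf_place(pos[[i]]$N, pos[[i]]$CA, pos[[i]]$C,
                                 BB$b_CN, BB$a_CACN, psi[, i]))
      put(i + 1, "CA", nerf_place(pos[[i]]$CA, pos[[i]]$C, pos[[i + 1]]$N,
                                  BB$b_NCA, BB$a_CNCA, 180))
      put(i + 1, "C", nerf_place(pos[[i]]$C, pos[[i + 1]]$N, pos[[i + 1]]$CA,
                                 BB$b_CAC, BB$a_NCAC, phi[, i + 1]))
    }
    # carbonyl O (anti to the next N); terminal psi defaults to 180
    psi_i <- psi[, i]
    psi_i[!is.finite(psi_i)] <- 180
    put(i, "O", nerf_place(pos[[i]]$N, pos[[i]]$CA, pos[[i]]$C,
                           BB$b_CO, BB$a_CACO, wrap_angle(psi_i + 180)))
    if (i == n) {
      put(i, "OXT", nerf_place(pos[[i]]$N, pos[[i]]$CA, pos[[i]]$C,
                               BB$b_OXT, BB$a_CACO, psi_i))
    }
    # amide hydrogen (absent on proline); the N-terminal H is placed anti
    # to the carbonyl for completeness
    if (res3[i] != "PRO") {
      if (i == 1) {
        put(i, "H", nerf_place(pos[[1]]$C, pos[[1]]$CA, pos[[1]]$N,
                               BB$b_NH, 114, 180))
      } else {
        put(i, "H", nerf_place(pos[[i - 1]]$CA, pos[[i - 1]]$C, pos[[i]]$N,
                               BB$b_NH, BB$a_CNH, 0))
      }
    }
    # side chain
    if (res3[i] != "GLY") {
      put(i, "CB", nerf_place(pos[[i]]$N, pos[[i]]$C, pos[[i]]$CA,
                              BB$b_CACB, BB$a_CCACB, BB$imp_NC_CACB))
      for (row in SIDECHAIN_TEMPLATES[[res3[i]]]) {
        tau <- switch(row$tau_kind,
                      chi1 = chi1[, i],
                      chi1_off = wrap_angle(chi1[, i] + row$tau),
                      fixed = row$tau)
        put(i, row$name, nerf_place(pos[[i]][[row$ref1]], pos[[i]][[row$ref2]],
                                    pos[[i]][[row$ref3]],
                                    row$bond, row$angle, tau))
      }
    }
  }

  # assemble atom table in PDB-conventional order
  atoms <- list(); xyz <- list(); h_attach <- list(); serial <- 0
  for (i in seq_len(n)) {
    order_i <- c("N", "CA", "C", "O",
                 if (res3[i] != "PRO") "H",
                 if (res3[i] != "GLY") "CB",
                 vapply(SIDECHAIN_TEMPLATES[[res3[i]]], `[[`, "", "name"),
                 if (i == n) "OXT")
    for (nm in order_i) {
      serial <- serial + 1
      el <- if (nm %in% c("N", "O", "OXT")) substr(nm, 1, 1)
        else if (nm %in% c("CA", "C", "CB")) "C"
        else if (nm == "H") "H"
        else {
          tpl <- SIDECHAIN_TEMPLATES[[res3[i]]]
          tpl[[which(vapply(tpl, `[[`, "", "name") == nm)]]$element
        }
      atoms[[serial]] <- list(serial = serial, name = nm, element = el,
                              resno = i, resname = res3[i])
      xyz[[serial]] <- pos[[i]][[nm]]
      if (el == "H") {
        heavy <- if (nm == "H") "N" else {
          tpl <- SIDECHAIN_TEMPLATES[[res3[i]]]
          tpl[[which(vapply(tpl, `[[`, "", "name") == nm)]]$ref3
        }
        h_attach[[length(h_attach) + 1]] <-
          list(resno = i, h_name = nm, heavy_name = heavy)
      }
    }
  }
  atoms <- bind_rows(lapply(atoms, as_tibble))
  h_attach <- bind_rows(lapply(h_attach, as_tibble))
  coords <- array(0, dim = c(F, nrow(atoms), 3))
  for (k in seq_len(nrow(atoms))) coords[, k, ] <- xyz[[k]]
  list(topology = pep_topology(sequence, atoms, h_attach),
       coords = coords)
}

# Normalise a chi1 specification (scalar / per-residue vector / F x n matrix)
# into an F x n matrix.
expand_chi1 <- function(chi1, F, n) {
  if (is.matrix(chi1)) {
    stopifnot(nrow(chi1) == F, ncol(chi1) == n)
    return(chi1)
  }
  if (length(chi1) == 1) chi1 <- rep(chi1, n)
  stopifnot(length(chi1) == n)
  matrix(chi1, nrow = F, ncol = n, byrow = TRUE)
}

#' Build a peptide at given backbone torsions
#'
#' Constructs a single-frame, heavy-atom + polar-hydrogen model of a peptide
#' from ideal internal coordinates. Backbone phi/psi reproduce the request to
#' within builder round-off (< 0.5 degrees); all omega torsions are fixed at
#' 180 degrees (trans), including proline. Side chains are placed from
#' rotamer templates; `chi1` selects the first side-chain torsion (gauche-
#' minus, -60, by default; +60 or any other value may be requested, per
#' residue if desired). Proline's ring torsions come from a fixed ring
#' template and ignore `chi1`.
#'
#' @param sequence One-letter amino-acid string (standard 20 residues).
#' @param phi_psi Either a length-2 vector recycled to all residues or an
#'   n x 2 matrix / data frame of per-residue (phi, psi) in degrees. phi of
#'   residue 1 and psi of residue n do not correspond to real torsions; psi
#'   of residue n orients the C-terminal carboxylate.
#' @param chi1 Scalar or per-residue vector of chi1 targets in degrees.
#' @return List with elements `topology` ([pep_topology]) and `ensemble`
#'   (a 1-frame [pep_ensemble]).
#' @export
#' @examples
#' helix <- build_peptide("AAAA", c(-57, -47))
#' helix$topology
build_peptide <- function(sequence, phi_psi, chi1 = -60) {
  n <- nchar(sequence)
  if (n < 1) abort("sequence must be non-empty")
  if (is.null(dim(phi_psi))) {
    if (length(phi_psi) == 2) {
      phi_psi <- matrix(phi_psi, nrow = n, ncol = 2, byrow = TRUE)
    } else {
      abort("phi_psi must be a length-2 vector or an n x 2 matrix")
    }
  }
  phi_psi <- as.matrix(phi_psi)
  if (nrow(phi_psi) != n || ncol(phi_psi) != 2) {
    abort("phi_psi must have one (phi, psi) pair per residue")
  }
  phi <- matrix(phi_psi[, 1], nrow = 1)
  psi <- matrix(phi_psi[, 2], nrow = 1)
  built <- pep_build_core(sequence, phi, psi, expand_chi1(chi1, 1, n))
  list(topology = built$topology, ensemble = pep_ensemble(built$coords))
}

#' Realise coordinates for a torsion series
#'
#' Turns a per-frame phi/psi series (e.g. from [sample_two_state()]) into a
#' coordinate ensemble using the ideal-geometry builder, frame by frame.
#' Re-extracting backbone dihedrals from the result reproduces the input to
#' within 0.5 degrees.
#'
#' @param series A dihedral series as returned by [sample_two_state()] or
#'   [extract_backbone_dihedrals()]: a tibble with columns `frame`, `resno`,
#'   `kind` and `angle`. All non-terminal phi/psi must be present and finite.
#' @param sequence One-letter amino-acid string.
#' @param chi1 Scalar or per-residue chi1 in degrees (default -60).
#' @param frame_interval Time between frames in ps.
#' @return A [pep_ensemble] with one frame per frame of `series`, plus the
#'   topology, as a list `(topology, ensemble)`.
#' @export
realize_coordinates <- function(series, sequence, chi1 = -60,
                                frame_interval = 5) {
  n <- nchar(sequence)
  frames <- sort(unique(series$frame))
  F <- length(frames)
  phi <- matrix(NA_real_, F, n)
  psi <- matrix(NA_real_, F, n)
  s <- series[series$kind %in% c("phi", "psi"), ]
  fi <- match(s$frame, frames)
  ij <- cbind(fi, s$resno)
  phi[ij[s$kind == "phi", , drop = FALSE]] <- s$angle[s$kind == "phi"]
  psi[ij[s$kind == "psi", , drop = FALSE]] <- s$angle[s$kind == "psi"]
  core_phi <- phi[, -1, drop = FALSE]
  core_psi <- psi[, -n, drop = FALSE]
  if (anyNA(core_phi) || anyNA(core_psi)) {
    abort("series is missing non-terminal phi/psi angles (or contains NaN)")
  }
  phi[, 1] <- 0
  built <- pep_build_core(sequence, phi, psi, expand_chi1(chi1, F, n))
  list(topology = built$topology,
       ensemble = pep_ensemble(built$coords, frame_interval = frame_interval))
}
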