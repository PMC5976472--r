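#' Extract backbone phi/psi torsions from an ensemble
#'
#' phi_i is C(i-1)-N(i)-CA(i)-C(i); psi_i is N(i)-CA(i)-C(i)-N(i+1).
#' Terminal torsions that do not exist (phi of residue 1, psi of the last
#' residue) are reported as `NA` rows so the series keeps one row per
#' residue, frame and kind.
#'
#' @param ens A [pep_ensemble].
#' @param topo The matching [pep_topology].
#' @return A tibble of class `pep_dihedrals` with columns `frame`, `resno`,
#'   `resname`, `kind` ("phi"/"psi"), `angle` (degrees, (-180, 180]).
#' @export
extract_backbone_dihedrals <- function(ens, topo) {
  n <- n_residues(topo)
  F <- n_frames(ens)
  N <- lapply(seq_len(n), function(i) atom_xyz(ens, atom_index(topo, i, "N")))
  CA <- lapply(seq_len(n), function(i) atom_xyz(ens, atom_index(topo, i, "CA")))
  C <- lapply(seq_len(n), function(i) atom_xyz(ens, atom_index(topo, i, "C")))
  out <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    phi <- if (i == 1) rep(NA_real_, F) else
      dihedral(C[[i - 1]], N[[i]], CA[[i]], C[[i]])
    psi <- if (i == n) rep(NA_real_, F) else
      dihedral(N[[i]], CA[[i]], C[[i]], N[[i + 1]])
    out[[2 * i - 1]] <- tibble(frame = seq_len(F), resno = i, kind = "phi",
                               angle = phi)
    out[[2 * i]] <- tibble(frame = seq_len(F), resno = i, kind = "psi",
                           angle = psi)
  }
  series <- bind_rows(out)
  series$resname <- topo$residues$resname[series$resno]
  series <- series |>
    select("frame", "resno", "resname", "kind", "angle") |>
    arrange(.data$frame, .data$resno, .data$kind)
  class(series) <- c("pep_dihedrals", class(series))
  series
}

#' Per-frame chi1 torsion of one residue
#'
#' chi1 is the N-CA-CB-gamma torsion, where gamma is the first side-chain
#' heavy atom (OG for Ser, SG for Cys, CG1 for Val/Ile, CG otherwise).
#' Glycine and alanine have no gamma atom and raise an error. The summary
#' statistic is the circular mean, which is well behaved across the +/-180
#' seam (e.g. angles 179 and -179 average to 180, not 0).
#'
#' @param ens A [pep_ensemble].
#' @param topo The matching [pep_topology].
#' @param residue Residue index or "Trp18"-style label.
#' @return A tibble with columns `frame`, `resno`, `resname`, `kind`
#'   ("chi1"), `angle`; the circular mean is attached as attribute
#'   `circular_mean` and printed by `summary()`.
#' @export
chi1_series <- function(ens, topo, residue) {
  i <- resolve_residue(topo, residue)
  quad <- topo$chi1_quads[[as.character(i)]]
  if (is.null(quad)) {
    abort(paste0("residue ", i, " (", topo$residues$resname[i],
                 ") has no chi1 torsion"))
  }
  pts <- lapply(quad, function(nm) atom_xyz(ens, atom_index(topo, i, nm)))
  ang <- dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  out <- tibble(frame = seq_len(n_frames(ens)), resno = i,
                resname = topo$residues$resname[i], kind = "chi1",
                angle = ang)
  attr(out, "circular_mean") <- circular_mean(ang)
  out
}

#' Extract phi, psi and chi1 for a residue range
#'
#' Convenience wrapper used by dPCA: backbone torsions for all residues in
#' `residues` plus chi1 where defined (residues without a gamma atom
#' contribute no chi1 column, mirroring how Gly/Ala are dropped from
#' side-chain torsion analyses).
#'
#' @inheritParams extract_backbone_dihedrals
#' @param residues Integer vector of residue indices (default all).
#' @return A `pep_dihedrals` tibble with kinds phi, psi and chi1.
#' @export
extract_dihedrals <- function(ens, topo, residues = NULL) {
  if (is.null(residues)) residues <- seq_len(n_residues(topo))
  bb <- extract_backbone_dihedrals(ens, topo)
  bb <- bb[bb$resno %in% residues, ]
  chis <- lapply(residues, function(i) {
    if (is.null(topo$chi1_quads[[as.character(i)]])) return(NULL)
    chi1_series(ens, topo, i)
  })
  series <- bind_rows(bb, bind_rows(chis)) |>
    arrange(.data$frame, .data$resno, .data$kind)
  class(series) <- c("pep_dihedrals", class(series))
  series
}

new_interaction_series <- function(frame, dist, pair, kind) {
  out <- tibble(frame = frame, distance = dist, pair = pair, kind = kind)
  class(out) <- c("pep_interaction", class(out))
  out
}

#' Per-frame C-beta distance between two residues
#'
#' @param ens A [pep_ensemble].
#' @param topo The matching [pep_topology].
#' @param resA,resB Residue indices or "Trp18"-style labels; both residues
#'   must have a CB atom (glycine errors).
#' @return Tibble with `frame`, `distance` (Angstrom), `pair`, `kind`.
#' @export
cbeta_distance <- function(ens, topo, resA, resB) {
  ia <- resolve_residue(topo, resA)
  ib <- resolve_residue(topo, resB)
  for (i in c(ia, ib)) {
    if (topo$residues$resname[i] == "GLY") {
      abort(paste0("residue ", i, " is GLY and has no CB"))
    }
  }
  a <- atom_xyz(ens, atom_index(topo, ia, "CB"))
  b <- atom_xyz(ens, atom_index(topo, ib, "CB"))
  d <- sqrt(rowSums((a - b)^2))
  new_interaction_series(seq_len(n_frames(ens)), d,
                         paste0(residue_label(topo, ia), "-",
                                residue_label(topo, ib)), "cbeta")
}

ring_centroid <- function(ens, topo, i) {
  grp <- topo$ring_groups[[as.character(i)]]
  if (is.null(grp)) {
    abort(paste0("residue ", i, " (", topo$residues$resname[i],
                 ") has no ring group"))
  }
  idx <- vapply(grp, function(nm) atom_index(topo, i, nm), 1L)
  m <- ens$coords[, idx, , drop = FALSE]
  apply(m, c(1, 3), mean)
}

#' Per-frame ring-centroid distance between two ring-bearing residues
#'
#' The centroid is the unweighted mean of the residue's ring-group atoms
#' (indole 9 atoms for Trp, 6-ring for Tyr/Phe, imidazole for His, the
#' N-CA-CB-CG-CD ring for Pro). Used as the geometric proxy for CH-pi and
#' stacking interactions.
#'
#' @inheritParams cbeta_distance
#' @return Tibble with `frame`, `distance` (Angstrom), `pair`, `kind`.
#' @export
ring_centroid_distance <- function(ens, topo, resA, resB) {
  ia <- resolve_residue(topo, resA)
  ib <- resolve_residue(topo, resB)
  ca <- ring_centroid(ens, topo, ia)
  cb <- ring_centroid(ens, topo, ib)
  d <- sqrt(rowSums((ca - cb)^2))
  new_interaction_series(seq_len(n_frames(ens)), d,
                         paste0(residue_label(topo, ia), "-",
                                residue_label(topo, ib)), "ring_centroid")
}

#' Percentage of frames below a distance cutoff
#'
#' @param series An interaction series from [cbeta_distance()] or
#'   [ring_centroid_distance()] (any data frame with a `distance` column).
#' @param cutoff Distance cutoff in Angstrom; frames count when
#'   `distance < cutoff` (strict).
#' @return Percentage of frames, in `[0, 100]`.
#' @export
fraction_below <- function(series, cutoff) {
  100 * mean(series$distance < cutoff)
}

#' Side-chain contact occupancy between two residues
#'
#' A frame is a contact when the minimum distance over all pairs of
#' side-chain heavy atoms of the two residues is strictly below `cutoff`.
#'
#' @inheritParams cbeta_distance
#' @param cutoff Contact cutoff in Angstrom (default 6).
#' @return Percentage of frames in contact.
#' @export
sidechain_contact_fraction <- function(ens, topo, resA, resB, cutoff = 6.0) {
  ia <- resolve_residue(topo, resA)
  ib <- resolve_residue(topo, resB)
  sa <- sidechain_heavy_idx(topo, ia)
  sb <- sidechain_heavy_idx(topo, ib)
  if (length(sa) == 0 || length(sb) == 0) {
    abort("both residues need at least one side-chain heavy atom")
  }
  F <- n_frames(ens)
  mind2 <- rep(Inf, F)
  for (i in sa) {
    xi <- atom_xyz(ens, i)
    for (j in sb) {
      d2 <- rowSums((xi - atom_xyz(ens, j))^2)
      mind2 <- pmin(mind2, d2)
    }
  }
  100 * mean(sqrt(mind2) < cutoff)
}

#' Apply a random rigid motion to every frame (utility)
#'
#' Rotates and translates each frame by the same or per-frame random rigid
#' motion. Useful for testing rotation/translation invariance of analyses.
#'
#' @param ens A [pep_ensemble].
#' @param seed Integer seed.
#' @param per_frame Logical; draw an independent motion per frame.
#' @return A transformed [pep_ensemble].
#' @export
rigid_transform <- function(ens, seed = 1, per_frame = FALSE) {
  set.seed(seed)
  F <- n_frames(ens)
  coords <- ens$coords
  rand_rot <- function() {
    # QR of a Gaussian matrix, sign-fixed to a proper rotation
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  }
  if (per_frame) {
    for (f in seq_len(F)) {
      R <- rand_rot(); t <- rnorm(3, sd = 10)
      coords[f, , ] <- sweep(frame_xyz(ens, f) %*% t(R), 2, -t)
    }
  } else {
    R <- rand_rot(); t <- rnorm(3, sd = 10)
    for (f in seq_len(F)) {
      coords[f, , ] <- sweep(frame_xyz(ens, f) %*% t(R), 2, -t)
    }
  }
  pep_ensemble(coords, ens$frame_weights, ens$frame_interval)
}
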