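#' Write an ensemble as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, standard atom naming, coordinates at
#' PDB precision (1e-3 Angstrom). Uses bio3d's PDB writer underneath.
#'
#' @param ens A [pep_ensemble].
#' @param topo The matching [pep_topology].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, topo, path) {
  F <- n_frames(ens)
  natom <- dim(ens$coords)[2]
  if (natom != nrow(topo$atoms)) abort("topology does not match ensemble")
  xyz <- matrix(0, F, 3 * natom)
  for (f in seq_len(F)) {
    xyz[f, ] <- as.vector(t(frame_xyz(ens, f)))
  }
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = topo$atoms$resno,
                   resid = topo$atoms$resname,
                   eleno = topo$atoms$serial,
                   elety = topo$atoms$name,
                   elesy = topo$atoms$element,
                   chain = "A")
  invisible(path)
}

# Infer hydrogen attachments by nearest N/O/S heavy atom in the same
# residue (first frame); used when a topology is rebuilt from a PDB file.
infer_h_attach <- function(atoms, frame1) {
  hs <- which(atoms$element == "H")
  rows <- lapply(hs, function(h) {
    cand <- which(atoms$resno == atoms$resno[h] &
                    atoms$element %in% c("N", "O", "S"))
    if (length(cand) == 0) return(NULL)
    d2 <- colSums((t(frame1[cand, , drop = FALSE]) - frame1[h, ])^2)
    j <- cand[which.min(d2)]
    if (min(d2) > 1.6^2) return(NULL)  # not bonded to any N/O/S
    tibble(resno = atoms$resno[h], h_name = atoms$name[h],
           heavy_name = atoms$name[j])
  })
  bind_rows(rows)
}

#' Read a (multi-model) PDB file as an ensemble
#'
#' Parses MODEL/ENDMDL frame series (a single-model file yields a 1-frame
#' ensemble), rebuilds the residue/atom catalogue, ring groups and chi1
#' quadruplets from residue names, and infers hydrogen attachments
#' geometrically.
#'
#' @param path PDB file path.
#' @param frame_interval Time between frames in ps (default 5).
#' @return List with `topology` ([pep_topology]) and `ensemble`
#'   ([pep_ensemble]).
#' @export
read_ensemble <- function(path, frame_interval = 5) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) {
                    abort(paste0("failed to parse PDB file '", path, "': ",
                                 conditionMessage(e)))
                  })
  a <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (nrow(a) == 0) abort("no ATOM records found")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  natom <- nrow(pdb$atom)
  if (ncol(xyz) != 3 * natom) abort("inconsistent atom counts across models")
  res_index <- cumsum(!duplicated(paste(a$chain, a$resno)))
  aa1_rev <- setNames(names(AA3), AA3)
  resnames <- a$resid[!duplicated(res_index)]
  if (any(!resnames %in% AA3)) {
    abort(paste0("non-standard residue(s): ",
                 paste(setdiff(resnames, AA3), collapse = ", ")))
  }
  sequence <- paste(aa1_rev[resnames], collapse = "")
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[0-9]", "", a$elety), 1, 1)
  }
  atoms <- tibble(serial = seq_len(nrow(a)), name = a$elety,
                  element = elem, resno = res_index,
                  resname = a$resid)
  F <- nrow(xyz)
  coords <- array(0, dim = c(F, nrow(a), 3))
  keep <- pdb$atom$type == "ATOM"
  for (f in seq_len(F)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[f, , ] <- m[keep, , drop = FALSE]
  }
  h_attach <- infer_h_attach(atoms, coords[1, , ])
  topo <- pep_topology(sequence, atoms, h_attach)
  list(topology = topo,
       ensemble = pep_ensemble(coords, frame_interval = frame_interval))
}
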