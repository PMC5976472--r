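# Donor list: every N/O/S heavy atom with at least one attached hydrogen,
# from the topology's hydrogen attachment table.
hbond_donors <- function(topo) {
  if (is.null(topo$h_attach) || nrow(topo$h_attach) == 0) {
    abort("topology has no hydrogen atoms; hydrogen-bond analysis needs them")
  }
  d <- topo$h_attach
  d$heavy_idx <- mapply(function(r, nm) atom_index(topo, r, nm),
                        d$resno, d$heavy_name)
  d$h_idx <- mapply(function(r, nm) atom_index(topo, r, nm),
                    d$resno, d$h_name)
  el <- topo$atoms$element[d$heavy_idx]
  d[el %in% c("N", "O", "S"), ]
}

hbond_acceptors <- function(topo) {
  which(topo$atoms$element == "O")
}

#' Hydrogen-bond occupancy table
#'
#' Detects hydrogen bonds geometrically in every frame: a donor-H / acceptor
#' pair is bonded when the donor-heavy-atom to acceptor distance is strictly
#' below `d_cut` and the D-H...A angle deviates from linearity by strictly
#' less than `ang_dev_cut` (i.e. the angle at H exceeds 180 - `ang_dev_cut`).
#' Donors are N/O/S atoms carrying a hydrogen (backbone amides and side-chain
#' donors such as Arg HH/HE, Thr HG1, Ser HG); acceptors are all oxygen atoms
#' (backbone O, side-chain OD/OE/OG/OH, terminal OXT).
#'
#' @param ens A [pep_ensemble].
#' @param topo The matching [pep_topology] (must include hydrogens).
#' @param d_cut Donor-acceptor heavy-atom distance cutoff in Angstrom
#'   (default 3.5).
#' @param ang_dev_cut Allowed deviation from a linear D-H...A arrangement in
#'   degrees (default 35).
#' @param min_occupancy Report threshold in percent (default 5); rows below
#'   it are suppressed. Set to 0 to keep everything.
#' @return A tibble of class `pep_hbonds` with columns `donor` (e.g.
#'   "Arg27:HH21", the donor hydrogen), `acceptor` (e.g. "Asp26:OD1"),
#'   `occupancy` (percent of frames), sorted by donor residue then
#'   decreasing occupancy.
#' @export
hbond_occupancy <- function(ens, topo, d_cut = 3.5, ang_dev_cut = 35,
                            min_occupancy = 5) {
  don <- hbond_donors(topo)
  acc <- hbond_acceptors(topo)
  F <- n_frames(ens)
  ang_min <- 180 - ang_dev_cut
  rows <- list()
  for (k in seq_len(nrow(don))) {
    D <- atom_xyz(ens, don$heavy_idx[k])
    H <- atom_xyz(ens, don$h_idx[k])
    for (a in acc) {
      if (a == don$heavy_idx[k]) next
      A <- atom_xyz(ens, a)
      d2 <- rowSums((D - A)^2)
      near <- d2 < d_cut^2
      if (!any(near)) next
      # angle at H between D and A
      v1 <- D - H
      v2 <- A - H
      cosang <- rowSums(v1 * v2) /
        sqrt(rowSums(v1^2) * rowSums(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      occ <- 100 * sum(near & ang > ang_min) / F
      if (occ > 0) {
        rows[[length(rows) + 1]] <- tibble(
          donor = paste0(residue_label(topo, don$resno[k]), ":",
                         don$h_name[k]),
          donor_resno = don$resno[k],
          acceptor = paste0(
            residue_label(topo, topo$atoms$resno[a]), ":",
            topo$atoms$name[a]),
          occupancy = occ)
      }
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(donor = character(), donor_resno = integer(),
                  acceptor = character(), occupancy = numeric())
  }
  out <- out |>
    filter(.data$occupancy >= min_occupancy) |>
    arrange(.data$donor_resno, desc(.data$occupancy)) |>
    select("donor", "acceptor", "occupancy")
  class(out) <- c("pep_hbonds", class(out))
  out
}
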