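#' Aromatic / side-chain interaction occupancy summary
#'
#' Computes the percentage of frames in which each requested residue pair is
#' within its cutoff, using C-beta distances, ring-centroid distances or
#' minimum side-chain heavy-atom distances. Occupancies under 1% are
#' rendered "negligible" in the display column; the numeric value is always
#' kept.
#'
#' @param ens A [pep_ensemble].
#' @param topo The matching [pep_topology].
#' @param pairs Data frame with columns `resA`, `resB` (indices or
#'   "Trp18"-style labels) and `kind` (one of "cbeta", "ring_centroid",
#'   "contact").
#' @param cutoffs Named list of cutoffs in Angstrom; defaults 7.0 for
#'   C-beta pairs, 6.0 for ring centroids and 6.0 for side-chain contacts.
#' @return Tibble with columns `pair`, `kind`, `cutoff`, `occupancy`
#'   (percent) and `display` (formatted, "negligible" below 1%).
#' @export
interaction_summary <- function(ens, topo, pairs,
                                cutoffs = list(cbeta = 7.0,
                                               ring_centroid = 6.0,
                                               contact = 6.0)) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("resA", "resB", "kind") %in% names(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    kind <- pairs$kind[r]
    cut <- cutoffs[[kind]]
    if (is.null(cut)) abort(paste0("no cutoff for kind '", kind, "'"))
    occ <- switch(
      kind,
      cbeta = fraction_below(
        cbeta_distance(ens, topo, pairs$resA[r], pairs$resB[r]), cut),
      ring_centroid = fraction_below(
        ring_centroid_distance(ens, topo, pairs$resA[r], pairs$resB[r]), cut),
      contact = sidechain_contact_fraction(ens, topo, pairs$resA[r],
                                           pairs$resB[r], cutoff = cut),
      abort(paste0("unknown interaction kind '", kind, "'")))
    ia <- resolve_residue(topo, pairs$resA[r])
    ib <- resolve_residue(topo, pairs$resB[r])
    tibble(pair = paste0(residue_label(topo, ia), "-",
                         residue_label(topo, ib)),
           kind = kind, cutoff = cut, occupancy = occ)
  })
  out <- bind_rows(rows)
  out$display <- ifelse(out$occupancy < 1, "negligible",
                        sprintf("%.1f", out$occupancy))
  out
}
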