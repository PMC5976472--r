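#' Coordinate ensemble
#'
#' A frame series of 3-D coordinates in Angstrom, stored as a
#' frames x atoms x 3 array, with optional per-frame weights and the time
#' spacing between saved frames.
#'
#' @param coords Numeric array frames x atoms x 3 (Angstrom), all finite.
#' @param frame_weights Optional non-negative per-frame weights with positive
#'   sum; `NULL` means uniform.
#' @param frame_interval Time between frames in ps (default 5).
#' @return An object of class `pep_ensemble`.
#' @export
pep_ensemble <- function(coords, frame_weights = NULL, frame_interval = 5) {
  if (length(dim(coords)) == 2) {
    coords <- array(coords, dim = c(1, dim(coords)))
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (!all(is.finite(coords))) abort("ensemble coordinates must be finite")
  if (!is.null(frame_weights)) {
    if (length(frame_weights) != dim(coords)[1]) {
      abort("frame_weights length must match frame count")
    }
    if (any(frame_weights < 0) || sum(frame_weights) <= 0) {
      abort("frame_weights must be non-negative with positive sum")
    }
  }
  structure(list(coords = coords, frame_weights = frame_weights,
                 frame_interval = frame_interval),
            class = "pep_ensemble")
}

#' @export
print.pep_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat("<pep_ensemble> ", d[1], " frames x ", d[2], " atoms",
      if (!is.null(x$frame_weights)) ", weighted" else "",
      " (", x$frame_interval, " ps/frame)\n", sep = "")
  invisible(x)
}

n_frames <- function(ens) dim(ens$coords)[1]

# frames x 3 coordinate matrix of one atom across all frames
atom_xyz <- function(ens, idx) {
  m <- ens$coords[, idx, , drop = FALSE]
  dim(m) <- c(dim(ens$coords)[1], 3)
  m
}

# single frame as atoms x 3
frame_xyz <- function(ens, frame) {
  m <- ens$coords[frame, , , drop = FALSE]
  dim(m) <- dim(ens$coords)[2:3]
  m
}
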