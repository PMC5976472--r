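#' Optimal least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of mapping
#' `coordsB` onto `coordsA`, using the SVD construction with reflection
#' correction (the returned rotation always has determinant +1).
#'
#' @param coordsA,coordsB N x 3 coordinate matrices (Angstrom), N >= 3.
#' @param selection Optional integer vector of rows used to fit the
#'   superposition (the RMSD is also computed over this selection);
#'   default all.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   such that `B %*% t(rotation) + translation` superposes onto A, and
#'   `rmsd` (Angstrom, after superposition).
#' @export
kabsch_superpose <- function(coordsA, coordsB, selection = NULL) {
  A <- as_mat3(coordsA)
  B <- as_mat3(coordsB)
  if (!is.null(selection)) {
    A <- A[selection, , drop = FALSE]
    B <- B[selection, , drop = FALSE]
  }
  if (nrow(A) != nrow(B)) abort("coordinate sets must have equal atom counts")
  if (nrow(A) < 3) abort("need at least 3 atoms to superpose")
  ca <- colMeans(A)
  cb <- colMeans(B)
  Ac <- sweep(A, 2, ca)
  Bc <- sweep(B, 2, cb)
  H <- t(Bc) %*% Ac
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Ac - fitted)^2)))
  list(rotation = R, translation = as.numeric(ca - R %*% cb), rmsd = rmsd)
}

#' Root-mean-square deviation without superposition
#'
#' @inheritParams kabsch_superpose
#' @return RMSD in Angstrom between the two coordinate sets as given.
#' @export
rmsd_raw <- function(coordsA, coordsB) {
  A <- as_mat3(coordsA); B <- as_mat3(coordsB)
  sqrt(mean(rowSums((A - B)^2)))
}
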