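# Deterministic test structures and small independent oracles.

mkpp <- function(n, phi, psi) matrix(c(rep(phi, n), rep(psi, n)), ncol = 2)

# The DSSP cross-check suite: deterministic builds spanning helix, 3-10
# helix, an antiparallel hairpin with a real E ladder, random coils, a noisy
# helix and a mixed-sequence helix.
dssp_suite <- function() {
  s <- list()
  s$helix <- list(seq = strrep("A", 12), pp = mkpp(12, -57, -47))
  s$helix310 <- list(seq = strrep("A", 10), pp = mkpp(10, -49, -26))
  s$hairpin <- list(seq = strrep("A", 12),
                    pp = rbind(mkpp(5, -110, 100), c(60, -120), c(-80, 0),
                               mkpp(5, -110, 100)))
  set.seed(7)
  s$coil1 <- list(seq = strrep("A", 16),
                  pp = cbind(runif(16, -180, 180), runif(16, -180, 180)))
  set.seed(21)
  s$coil2 <- list(seq = strrep("A", 14),
                  pp = cbind(runif(14, -180, 180), runif(14, -180, 180)))
  set.seed(11)
  s$noisyhelix <- list(seq = strrep("A", 12),
                       pp = mkpp(12, -57, -47) + matrix(rnorm(24, 0, 10), 12, 2))
  s$mixedhelix <- list(seq = "KWPAWVYCTR", pp = mkpp(10, -60, -45))
  s
}

# Reference assignments for dssp_suite(), computed with an independent DSSP
# implementation (mdtraj 1.11.1 compute_dssp, simplified = FALSE, blanks
# mapped to C) on the exact coordinates the builds above produce.
DSSP_REFERENCE <- c(
  helix = "CHHHHHHHHHHC",
  helix310 = "CGGGGGGGGC",
  hairpin = "CEEEETTEEEEC",
  coil1 = "CCBSSSCBCSSSCCCC",
  coil2 = "CCBSSSSSSSSBCC",
  noisyhelix = "CHHHHHHHHHHC",
  mixedhelix = "CHHHHHHHHC"
)

# A hand-assembled micro topology: residues with only the atoms given in
# `atom_list` (list of tibbles-like rows), coordinates supplied directly.
micro_topology <- function(sequence, atom_rows, h_attach = NULL) {
  atoms <- dplyr::bind_rows(lapply(seq_along(atom_rows), function(k) {
    r <- atom_rows[[k]]
    tibble::tibble(serial = k, name = r$name, element = r$element,
                   resno = r$resno,
                   resname = pepscape:::seq1_to_3(sequence)[r$resno])
  }))
  if (is.null(h_attach)) {
    h_attach <- tibble::tibble(resno = integer(), h_name = character(),
                               heavy_name = character())
  }
  pep_topology(sequence, atoms, h_attach)
}

# Random-coil multi-frame ensemble of a real peptide, via the builder.
random_ensemble <- function(sequence, n_frames, seed, sigma = 60) {
  set.seed(seed)
  n <- nchar(sequence)
  spec <- two_state_spec(n, noise_sigma = sigma,
                         transition = matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2))
  tw <- sample_two_state(spec, sequence, n_frames, seed = seed)
  realize_coordinates(tw$series, sequence)
}

# Independent brute-force hydrogen-bond oracle: exhaustive double loop over
# every hydrogen-bearing N/O/S donor and every O acceptor, scalar arithmetic.
brute_force_hbonds <- function(ens, topo, d_cut = 3.5, ang_dev_cut = 35) {
  at <- topo$atoms
  ha <- topo$h_attach
  F <- dim(ens$coords)[1]
  res <- list()
  for (hrow in seq_len(nrow(ha))) {
    hi <- which(at$resno == ha$resno[hrow] & at$name == ha$h_name[hrow])
    di <- which(at$resno == ha$resno[hrow] & at$name == ha$heavy_name[hrow])
    if (!at$element[di] %in% c("N", "O", "S")) next
    for (ai in which(at$element == "O")) {
      if (ai == di) next
      nhit <- 0
      for (f in seq_len(F)) {
        D <- ens$coords[f, di, ]; H <- ens$coords[f, hi, ]
        A <- ens$coords[f, ai, ]
        d <- sqrt(sum((D - A)^2))
        if (d >= d_cut) next
        v1 <- D - H; v2 <- A - H
        ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang > 180 - ang_dev_cut) nhit <- nhit + 1
      }
      if (nhit > 0) {
        res[[length(res) + 1]] <- tibble::tibble(
          donor_idx = di, h_idx = hi, acceptor_idx = ai,
          occupancy = 100 * nhit / F)
      }
    }
  }
  dplyr::bind_rows(res)
}

# Numerical-optimiser RMSD oracle: minimise over an Euler-angle
# parameterisation of rotations after centroid removal, multi-start.
rmsd_optim_oracle <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) {
    R <- rotmat(ang)
    sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
  }
  best <- Inf
  set.seed(404)
  for (s in 1:12) {
    start <- runif(3, -pi, pi)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Angle-pair samples spread uniformly over every torsion bin: each bin gets
# an equal share of frames placed at jittered in-bin positions.
uniform_bin_angles <- function(n, width = 10, seed = 1) {
  nb <- 360 / width
  per <- ceiling(n / nb^2)
  grid <- expand.grid(x = seq_len(nb) - 1, y = seq_len(nb) - 1)
  set.seed(seed)
  idx <- rep(seq_len(nrow(grid)), length.out = n)
  x <- -180 + (grid$x[idx] + runif(n)) * width
  y <- -180 + (grid$y[idx] + runif(n)) * width
  list(x = pepscape::wrap_angle(x), y = pepscape::wrap_angle(y))
}
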