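#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic bond energy between a backbone carbonyl (C, O) and a
#' backbone amide (N, H):
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol.
#' A hydrogen bond is accepted when E < -0.5 kcal/mol. Very short contacts
#' (< 0.5 Angstrom) are clamped to -9.9 kcal/mol as in the reference
#' implementation; exactly coincident atoms are an error.
#'
#' @param C,O Acceptor carbonyl carbon and oxygen positions (length-3
#'   vectors or n x 3 matrices, Angstrom).
#' @param N,H Donor amide nitrogen and hydrogen positions.
#' @return Energy in kcal/mol (vectorised over rows).
#' @export
ks_hbond_energy <- function(C, O, N, H) {
  C <- as_mat3(C); O <- as_mat3(O); N <- as_mat3(N); H <- as_mat3(H)
  dist <- function(a, b) sqrt(rowSums((a - b)^2))
  rON <- dist(O, N); rCH <- dist(C, H); rOH <- dist(O, H); rCN <- dist(C, N)
  if (any(c(rON, rCH, rOH, rCN) == 0)) {
    abort("ks_hbond_energy(): coincident atoms")
  }
  e <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  e[pmin(rON, rCH, rOH, rCN) < 0.5] <- -9.9
  pmin(e, 9.9e3)
}

KS_ECUT <- -0.5
KS_CA_GATE <- 9.0

# Backbone coordinate bundle: list of F x 3 matrices per residue.
backbone_xyz <- function(ens, topo) {
  n <- n_residues(topo)
  get <- function(i, nm) atom_xyz(ens, atom_index(topo, i, nm))
  N <- lapply(seq_len(n), get, nm = "N")
  CA <- lapply(seq_len(n), get, nm = "CA")
  C <- lapply(seq_len(n), get, nm = "C")
  O <- lapply(seq_len(n), get, nm = "O")
  # amide H rebuilt the Kabsch-Sander way: 1 Angstrom from N along the
  # previous residue's C->O direction reversed (H = N + unit(C_prev - O_prev));
  # residue 1 and prolines keep H at N (they never donate anyway for PRO)
  H <- vector("list", n)
  H[[1]] <- N[[1]]
  for (i in seq_len(n)[-1]) {
    v <- C[[i - 1]] - O[[i - 1]]
    H[[i]] <- N[[i]] + v / sqrt(rowSums(v^2))
  }
  list(N = N, CA = CA, C = C, O = O, H = H,
       is_pro = topo$residues$resname == "PRO")
}

# HB[f, d, a] = TRUE when the amide of residue d donates to the carbonyl of
# residue a in frame f, following the DSSP pair conventions (donor d == a or
# d == a + 1 skipped, proline never donates, CA-CA gate of 9 Angstrom).
ks_hbond_array <- function(bb, F, n) {
  HB <- array(FALSE, dim = c(F, n, n))
  for (d in seq_len(n)) {
    if (bb$is_pro[d] || d == 1) next
    for (a in seq_len(n)) {
      if (d == a || d == a + 1) next
      ca_gate <- rowSums((bb$CA[[d]] - bb$CA[[a]])^2) < KS_CA_GATE^2
      if (!any(ca_gate)) next
      e <- ks_hbond_energy(bb$C[[a]], bb$O[[a]], bb$N[[d]], bb$H[[d]])
      HB[, d, a] <- ca_gate & (e < KS_ECUT)
    }
  }
  HB
}

# Single-frame pattern assignment from the donor->acceptor bond matrix.
ks_assign_codes <- function(hb, ca) {
  n <- nrow(hb)
  ss <- rep("C", n)
  turn <- function(stride, i) {
    # n-turn at i: CO(i) accepted by NH(i + stride)
    i + stride <= n && hb[i + stride, i]
  }
  seq2 <- function(a, b) if (b < a) integer(0) else a:b
  # beta bridges
  hbb <- function(d, a) d >= 1 && d <= n && a >= 1 && a <= n && hb[d, a]
  btype <- matrix(0L, n, n)  # 1 parallel, 2 antiparallel
  for (i in seq2(2, n - 1)) {
    for (j in seq2(2, n - 1)) {
      if (abs(i - j) < 3) next
      par <- (hbb(j, i - 1) && hbb(i + 1, j)) || (hbb(i, j - 1) && hbb(j + 1, i))
      anti <- (hbb(j, i) && hbb(i, j)) || (hbb(j + 1, i - 1) && hbb(i + 1, j - 1))
      if (par) btype[i, j] <- 1L else if (anti) btype[i, j] <- 2L
    }
  }
  bridged <- which(rowSums(btype > 0) > 0)
  if (length(bridged) > 0) {
    # ladders: bridge (i, j) extended by (i+1, j+1) (parallel) or
    # (i+1, j-1) (antiparallel)
    in_ladder <- rep(FALSE, n)
    for (i in seq_len(n)) {
      js <- which(btype[i, ] > 0)
      for (j in js) {
        ext <- if (btype[i, j] == 1L) {
          (i + 1 <= n && j + 1 <= n && btype[i + 1, j + 1] == 1L) ||
            (i - 1 >= 1 && j - 1 >= 1 && btype[i - 1, j - 1] == 1L)
        } else {
          (i + 1 <= n && j - 1 >= 1 && btype[i + 1, j - 1] == 2L) ||
            (i - 1 >= 1 && j + 1 <= n && btype[i - 1, j + 1] == 2L)
        }
        if (ext) in_ladder[i] <- TRUE
      }
    }
    ss[bridged] <- ifelse(in_ladder[bridged], "E", "B")
  }
  # alpha helix: two consecutive 4-turn starts
  for (i in seq2(2, n - 4)) {
    if (turn(4, i) && turn(4, i - 1)) ss[i:(i + 3)] <- "H"
  }
  # 3-10 helix into unassigned/loop stretches only
  for (i in seq2(2, n - 3)) {
    if (turn(3, i) && turn(3, i - 1) &&
        all(ss[i:(i + 2)] %in% c("C", "G"))) {
      ss[i:(i + 2)] <- "G"
    }
  }
  # pi helix
  for (i in seq2(2, n - 5)) {
    if (turn(5, i) && turn(5, i - 1) &&
        all(ss[i:(i + 4)] %in% c("C", "I"))) {
      ss[i:(i + 4)] <- "I"
    }
  }
  # turns
  for (stride in 3:5) {
    for (i in seq2(1, n - stride)) {
      if (turn(stride, i)) {
        span <- (i + 1):(i + stride - 1)
        ss[span][ss[span] == "C"] <- "T"
      }
    }
  }
  # bends: kappa > 70 degrees
  if (n >= 5) {
    for (i in seq2(3, n - 2)) {
      u <- ca[i, ] - ca[i - 2, ]
      v <- ca[i + 2, ] - ca[i, ]
      cosk <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      kappa <- acos(pmin(1, pmax(-1, cosk))) * 180 / pi
      if (kappa > 70 && ss[i] == "C") ss[i] <- "S"
    }
  }
  ss
}

#' Assign secondary structure to a single frame
#'
#' Kabsch-Sander assignment from backbone geometry: hydrogen bonds from the
#' electrostatic criterion ([ks_hbond_energy()] < -0.5 kcal/mol), then the
#' standard pattern rules (i to i+4 turns give H, i to i+3 give G, i to i+5
#' give I, bridges give E/B, remaining turn members T, C-alpha kinks over 70
#' degrees S, else C). Amide hydrogens are rebuilt geometrically from the
#' preceding carbonyl, so the assignment depends only on N, CA, C, O.
#'
#' @param ens A [pep_ensemble].
#' @param topo The matching [pep_topology].
#' @param frame Frame index (default 1).
#' @return Character vector of per-residue codes from H, G, I, E, B, T, S, C.
#' @export
assign_frame <- function(ens, topo, frame = 1) {
  ss_timeline(ens, topo, frames = frame)$codes[1, ]
}

#' Secondary-structure timeline
#'
#' Runs the Kabsch-Sander assignment on every frame.
#'
#' @inheritParams assign_frame
#' @param frames Optional integer vector restricting which frames to assign.
#' @return Object of class `pep_sstimeline`: list with `codes` (frames x
#'   residues character matrix), `frame_interval` (ps) and `residues`.
#'   Use [tidy()] for a long tibble or [autoplot()] for a timeline plot.
#' @export
ss_timeline <- function(ens, topo, frames = NULL) {
  n <- n_residues(topo)
  if (is.null(frames)) frames <- seq_len(n_frames(ens))
  sub <- pep_ensemble(ens$coords[frames, , , drop = FALSE],
                      frame_interval = ens$frame_interval)
  F <- length(frames)
  bb <- backbone_xyz(sub, topo)
  HB <- ks_hbond_array(bb, F, n)
  codes <- matrix("C", F, n)
  ca_all <- lapply(seq_len(n), function(i) bb$CA[[i]])
  for (f in seq_len(F)) {
    ca <- do.call(rbind, lapply(ca_all, function(m) m[f, ]))
    codes[f, ] <- ks_assign_codes(HB[f, , ], ca)
  }
  structure(list(codes = codes, frame_interval = ens$frame_interval,
                 residues = topo$residues, frames = frames),
            class = "pep_sstimeline")
}

#' @export
print.pep_sstimeline <- function(x, ...) {
  cat("<pep_sstimeline> ", nrow(x$codes), " frames x ", ncol(x$codes),
      " residues\n", sep = "")
  invisible(x)
}

#' @describeIn ss_timeline Long-format tibble (frame, resno, resname, code).
#' @param x A `pep_sstimeline`.
#' @param ... Unused.
#' @export
tidy.pep_sstimeline <- function(x, ...) {
  F <- nrow(x$codes); n <- ncol(x$codes)
  tibble(frame = rep(x$frames, n),
         resno = rep(seq_len(n), each = F),
         resname = rep(x$residues$resname, each = F),
         code = as.vector(x$codes))
}

#' Helical fraction of a timeline
#'
#' Percentage of (frame, residue) cells in `residue_range` assigned a
#' helical code (H, G or I).
#'
#' @param tl A `pep_sstimeline`.
#' @param residue_range Integer vector of residue indices (default all).
#' @return Percentage in `[0, 100]`.
#' @export
helical_fraction <- function(tl, residue_range = NULL) {
  if (is.null(residue_range)) residue_range <- seq_len(ncol(tl$codes))
  if (length(residue_range) == 0) abort("empty residue range")
  100 * mean(tl$codes[, residue_range, drop = FALSE] %in% c("H", "G", "I"))
}

#' Compact text rendering of a timeline
#'
#' One row per residue, one character per frame stride, suitable for eyeball
#' comparison of where helix (H/G/I) and strand (E/B) codes persist.
#'
#' @param tl A `pep_sstimeline`.
#' @param stride Sample every `stride`-th frame (default chosen to fit 80
#'   columns).
#' @return Invisibly, the character matrix printed.
#' @export
render_timeline <- function(tl, stride = NULL) {
  F <- nrow(tl$codes)
  if (is.null(stride)) stride <- max(1L, ceiling(F / 72))
  cols <- seq(1, F, by = stride)
  for (i in seq_len(ncol(tl$codes))) {
    lab <- sprintf("%4s%-3d", tl$residues$resname[i], i)
    cat(lab, paste(tl$codes[cols, i], collapse = ""), "\n")
  }
  invisible(tl$codes[cols, , drop = FALSE])
}
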