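test_that("dipeptide backbone series marks both terminal torsions missing", {
  b <- build_peptide("AA", c(-70, 140))
  s <- extract_backbone_dihedrals(b$ensemble, b$topology)
  expect_true(is.na(s$angle[s$resno == 1 & s$kind == "phi"]))
  expect_true(is.na(s$angle[s$resno == 2 & s$kind == "psi"]))
  expect_false(anyNA(s$angle[s$resno == 1 & s$kind == "psi"]))
})

test_that("series row count scales with frames", {
  e <- random_ensemble("AAAA", 100, seed = 5)
  s <- extract_backbone_dihedrals(e$ensemble, e$topology)
  expect_equal(nrow(s), 100 * 4 * 2)
  expect_equal(length(unique(s$frame)), 100)
})

test_that("chi1 circular mean survives the wrap and ALA errors out", {
  # constant series at the seam: equal mass at 179 and -179
  b1 <- build_peptide("AVA", c(-57, -47), chi1 = 179)
  b2 <- build_peptide("AVA", c(-57, -47), chi1 = -179)
  coords <- array(0, dim = c(2, nrow(b1$topology$atoms), 3))
  coords[1, , ] <- b1$ensemble$coords[1, , ]
  coords[2, , ] <- b2$ensemble$coords[1, , ]
  ens <- pep_ensemble(coords)
  cm <- attr(chi1_series(ens, b1$topology, 2), "circular_mean")
  expect_equal(abs(cm), 180, tolerance = 0.5)
  a <- build_peptide("AAA", c(-57, -47))
  expect_error(chi1_series(a$ensemble, a$topology, 2), "chi1")
})

test_that("cbeta_distance echoes constructed separations", {
  rows <- list(
    list(name = "N", element = "N", resno = 1),
    list(name = "CA", element = "C", resno = 1),
    list(name = "CB", element = "C", resno = 1),
    list(name = "N", element = "N", resno = 2),
    list(name = "CA", element = "C", resno = 2),
    list(name = "CB", element = "C", resno = 2))
  topo <- micro_topology("WW", rows)
  coords <- array(0, dim = c(3, 6, 3))
  for (f in 1:3) {
    coords[f, 1, ] <- c(-1, 0, 0); coords[f, 2, ] <- c(-0.5, 0, 0)
    coords[f, 4, ] <- c(7, 0, 0); coords[f, 5, ] <- c(6.5, 0, 0)
    coords[f, 3, ] <- c(0, 0, 0)
    coords[f, 6, ] <- c(5.87, 0, 0)
  }
  ens <- pep_ensemble(coords)
  d <- cbeta_distance(ens, topo, "Trp1", "Trp2")
  expect_equal(d$distance, rep(5.87, 3))
  expect_equal(nrow(d), 3)
})

test_that("cbeta_distance refuses glycine", {
  b <- build_peptide("GWG", c(-70, 150))
  expect_error(cbeta_distance(b$ensemble, b$topology, 1, 2), "GLY")
})

test_that("ring centroids and fraction_below behave on constructed input", {
  b <- build_peptide("WY", c(-120, 120))
  topo <- b$topology
  base <- b$ensemble$coords[1, , ]
  # translate the Tyr ring so centroid separations are exactly 4 and 8
  c1 <- pepscape:::ring_centroid(b$ensemble, topo, 1)[1, ]
  idx2 <- vapply(topo$ring_groups[["2"]],
                 function(nm) pepscape:::atom_index(topo, 2, nm), 1L)
  coords <- array(0, dim = c(4, nrow(topo$atoms), 3))
  for (f in 1:4) coords[f, , ] <- base
  for (f in 1:4) {
    tgt <- if (f <= 2) 4 else 8
    c2 <- colMeans(base[idx2, , drop = FALSE])
    shift <- (c1 + c(tgt, 0, 0)) - c2
    coords[f, idx2, ] <- sweep(base[idx2, , drop = FALSE], 2, -shift)
  }
  ens <- pep_ensemble(coords)
  d <- ring_centroid_distance(ens, topo, 1, 2)
  expect_equal(d$distance, c(4, 4, 8, 8), tolerance = 1e-9)
  expect_equal(fraction_below(d, 6), 50)
  expect_equal(fraction_below(d, 100), 100)
  # monotone in cutoff
  cuts <- seq(1, 12, by = 0.5)
  fb <- vapply(cuts, function(ct) fraction_below(d, ct), 1.0)
  expect_true(all(diff(fb) >= 0))
})

test_that("sidechain contacts use strict inequality and match brute force", {
  rows <- list(
    list(name = "N", element = "N", resno = 1),
    list(name = "CA", element = "C", resno = 1),
    list(name = "CB", element = "C", resno = 1),
    list(name = "N", element = "N", resno = 2),
    list(name = "CA", element = "C", resno = 2),
    list(name = "CB", element = "C", resno = 2))
  topo <- micro_topology("AA", rows)
  coords <- array(0, dim = c(1, 6, 3))
  coords[1, 1, ] <- c(-2, 0, 0); coords[1, 2, ] <- c(-1, 0, 0)
  coords[1, 3, ] <- c(0, 0, 0)
  coords[1, 4, ] <- c(8, 0, 0); coords[1, 5, ] <- c(7, 0, 0)
  coords[1, 6, ] <- c(6, 0, 0)   # exactly at the 6 A cutoff
  expect_equal(sidechain_contact_fraction(pep_ensemble(coords), topo, 1, 2),
               0)
  coords[1, 6, ] <- c(4, 0, 0)
  expect_equal(sidechain_contact_fraction(pep_ensemble(coords), topo, 1, 2),
               100)
  # brute-force all-pairs oracle on a real peptide
  e <- random_ensemble("KWPAWVYCTR", 10, seed = 31)
  for (pair in list(c(2, 5), c(5, 7), c(2, 7))) {
    sa <- pepscape:::sidechain_heavy_idx(e$topology, pair[1])
    sb <- pepscape:::sidechain_heavy_idx(e$topology, pair[2])
    hits <- 0
    for (f in 1:10) {
      dmin <- Inf
      for (i in sa) for (j in sb) {
        dmin <- min(dmin, sqrt(sum((e$ensemble$coords[f, i, ] -
                                      e$ensemble$coords[f, j, ])^2)))
      }
      if (dmin < 6) hits <- hits + 1
    }
    expect_equal(sidechain_contact_fraction(e$ensemble, e$topology,
                                            pair[1], pair[2]),
                 100 * hits / 10)
  }
})

test_that("distance and torsion measurements are rigid-motion invariant", {
  e <- random_ensemble("AWAVA", 5, seed = 17)
  moved <- rigid_transform(e$ensemble, seed = 99, per_frame = TRUE)
  d1 <- cbeta_distance(e$ensemble, e$topology, 2, 4)$distance
  d2 <- cbeta_distance(moved, e$topology, 2, 4)$distance
  expect_equal(d1, d2, tolerance = 1e-9)
  s1 <- extract_backbone_dihedrals(e$ensemble, e$topology)
  s2 <- extract_backbone_dihedrals(moved, e$topology)
  ok <- !is.na(s1$angle)
  expect_equal(wrap_angle(s1$angle[ok] - s2$angle[ok]),
               rep(0, sum(ok)), tolerance = 1e-9)
})

test_that("interaction_summary reproduces generator-controlled occupancy", {
  rows <- list(
    list(name = "N", element = "N", resno = 1),
    list(name = "CA", element = "C", resno = 1),
    list(name = "CB", element = "C", resno = 1),
    list(name = "N", element = "N", resno = 2),
    list(name = "CA", element = "C", resno = 2),
    list(name = "CB", element = "C", resno = 2))
  topo <- micro_topology("WW", rows)
  n <- 1000; hit <- 157
  coords <- array(0, dim = c(n, 6, 3))
  coords[, 1, 1] <- -2; coords[, 2, 1] <- -1
  coords[, 4, 1] <- 12; coords[, 5, 1] <- 11
  coords[, 6, 1] <- c(rep(5, hit), rep(10, n - hit))
  ens <- pep_ensemble(coords)
  out <- interaction_summary(ens, topo,
                             data.frame(resA = 1, resB = 2, kind = "cbeta"))
  expect_equal(out$occupancy, 15.7)
  expect_equal(out$display, "15.7")
  # never within cutoff -> 0; sub-1% -> negligible
  coords[, 6, 1] <- 10
  out0 <- interaction_summary(pep_ensemble(coords), topo,
                              data.frame(resA = 1, resB = 2, kind = "cbeta"))
  expect_equal(out0$occupancy, 0)
  coords[, 6, 1] <- c(rep(5, 5), rep(10, n - 5))
  outn <- interaction_summary(pep_ensemble(coords), topo,
                              data.frame(resA = 1, resB = 2, kind = "cbeta"))
  expect_equal(outn$occupancy, 0.5)
  expect_equal(outn$display, "negligible")
})
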