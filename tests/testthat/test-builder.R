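test_that("builder reproduces requested backbone torsions", {
  b <- build_peptide("AAAA", c(-57, -47))
  s <- extract_backbone_dihedrals(b$ensemble, b$topology)
  core <- s[!is.na(s$angle), ]
  expect_true(all(abs(core$angle[core$kind == "phi"] + 57) < 0.5))
  expect_true(all(abs(core$angle[core$kind == "psi"] + 47) < 0.5))
  # terminal torsions are flagged missing
  expect_true(is.na(s$angle[s$resno == 1 & s$kind == "phi"]))
  expect_true(is.na(s$angle[s$resno == 4 & s$kind == "psi"]))
})

test_that("builder/extractor round trip holds for random targets", {
  set.seed(1234)
  for (r in 1:20) {
    n <- sample(4:10, 1)
    pp <- cbind(runif(n, -175, 175), runif(n, -175, 175))
    b <- build_peptide(strrep("A", n), pp)
    s <- extract_backbone_dihedrals(b$ensemble, b$topology)
    for (i in 2:n) {
      got <- s$angle[s$resno == i & s$kind == "phi"]
      expect_lt(abs(wrap_angle(got - pp[i, 1])), 0.5)
    }
    for (i in 1:(n - 1)) {
      got <- s$angle[s$resno == i & s$kind == "psi"]
      expect_lt(abs(wrap_angle(got - pp[i, 2])), 0.5)
    }
  }
})

test_that("omega is trans everywhere, including proline", {
  b <- build_peptide("APGW", c(-70, 150))
  ens <- b$ensemble; topo <- b$topology
  xyz <- ens$coords[1, , ]
  at <- function(i, nm) xyz[pepscape:::atom_index(topo, i, nm), ]
  for (i in 1:3) {
    om <- dihedral(at(i, "CA"), at(i, "C"), at(i + 1, "N"), at(i + 1, "CA"))
    expect_equal(abs(om), 180, tolerance = 1e-6)
  }
})

test_that("glycine has no CB and no chi1 quad", {
  g <- build_peptide("G", matrix(c(-57, -47), 1))
  expect_false("CB" %in% g$topology$atoms$name)
  expect_length(g$topology$chi1_quads, 0)
  expect_error(chi1_series(g$ensemble, g$topology, 1), "chi1")
})

test_that("ring groups follow the residue catalogue", {
  b <- build_peptide("WPAWVY", mkpp(6, -120, 120))
  rg <- b$topology$ring_groups
  expect_setequal(names(rg), c("1", "2", "4", "6"))
  expect_length(rg[["1"]], 9)   # Trp indole
  expect_length(rg[["2"]], 5)   # Pro ring N-CA-CB-CG-CD
  expect_length(rg[["6"]], 6)   # Tyr six-ring
  expect_error(ring_centroid_distance(b$ensemble, b$topology, 3, 6), "ring")
})

test_that("chi1 is selectable and recovered exactly", {
  for (target in c(-60, 60, 61, 175)) {
    b <- build_peptide("AVA", c(-57, -47), chi1 = target)
    cs <- chi1_series(b$ensemble, b$topology, 2)
    expect_equal(attr(cs, "circular_mean"), target, tolerance = 0.5)
  }
  # per-residue chi1
  b <- build_peptide("VV", c(-120, 120), chi1 = c(-60, 60))
  expect_equal(attr(chi1_series(b$ensemble, b$topology, 1), "circular_mean"),
               -60, tolerance = 0.5)
  expect_equal(attr(chi1_series(b$ensemble, b$topology, 2), "circular_mean"),
               60, tolerance = 0.5)
})

test_that("builder rejects bad input", {
  expect_error(build_peptide("AXA", c(-57, -47)), "unknown residue")
  expect_error(build_peptide("AAA", matrix(c(-57, -47), 1)), "pair per residue")
  expect_error(build_peptide("", matrix(numeric(0), 0, 2)), "non-empty")
})

test_that("realize_coordinates round-trips a sampled series", {
  spec <- two_state_spec(5, noise_sigma = 20)
  tw <- sample_two_state(spec, "AAAAA", 25, seed = 77)
  real <- realize_coordinates(tw$series, "AAAAA")
  expect_equal(dim(real$ensemble$coords)[1], 25)
  back <- extract_backbone_dihedrals(real$ensemble, real$topology)
  merged <- merge(as.data.frame(tw$series), as.data.frame(back),
                  by = c("frame", "resno", "kind"))
  merged <- merged[!is.na(merged$angle.y), ]
  expect_true(all(abs(wrap_angle(merged$angle.x - merged$angle.y)) < 0.5))
})

test_that("realize_coordinates propagates one frame and rejects NaN", {
  spec <- two_state_spec(4, noise_sigma = 0)
  tw <- sample_two_state(spec, "AAAA", 1, seed = 1)
  one <- realize_coordinates(tw$series, "AAAA")
  expect_equal(dim(one$ensemble$coords)[1], 1)
  bad <- tw$series
  bad$angle[bad$resno == 2 & bad$kind == "phi"] <- NaN
  expect_error(realize_coordinates(bad, "AAAA"), "missing")
})

test_that("helix-state series yields mostly H in core residues", {
  spec <- two_state_spec(12, noise_sigma = 5,
                         transition = diag(2), p_init = c(1, 0))
  tw <- sample_two_state(spec, strrep("A", 12), 20, seed = 3)
  real <- realize_coordinates(tw$series, strrep("A", 12))
  tl <- ss_timeline(real$ensemble, real$topology)
  expect_gte(helical_fraction(tl, 3:10), 80)
})

test_that("multi-model PDB round trip preserves coordinates and names", {
  b <- random_ensemble("KWPAWVYCTR", 10, seed = 9)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(b$ensemble, b$topology, path)
  rt <- read_ensemble(path)
  expect_equal(dim(rt$ensemble$coords), dim(b$ensemble$coords))
  expect_lte(max(abs(rt$ensemble$coords - b$ensemble$coords)), 1e-3)
  expect_equal(rt$topology$atoms$name, b$topology$atoms$name)
  expect_equal(rt$topology$sequence, b$topology$sequence)
})

test_that("single-model PDB reads as a 1-frame ensemble", {
  b <- build_peptide("AWA", c(-57, -47))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(b$ensemble, b$topology, path)
  rt <- read_ensemble(path)
  expect_equal(dim(rt$ensemble$coords)[1], 1)
})

test_that("truncated PDB raises a parse error", {
  b <- build_peptide("AWA", c(-57, -47))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(b$ensemble, b$topology, path)
  lines <- readLines(path)
  writeLines(substr(head(lines, 5), 1, 20), path)
  expect_error(read_ensemble(path))
})
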