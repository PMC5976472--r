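test_that("discretize implements the stated edge conventions", {
  expect_equal(discretize(-180 + 1e-9, 10), 0L)
  expect_equal(discretize(-175, 10), 0L)
  expect_equal(discretize(180, 10), 35L)  # closed right edge wraps
  expect_equal(discretize(-180, 10), 35L) # -180 wraps onto +180
  expect_equal(discretize(0, 10), 18L)
  expect_error(discretize(10, width = 7), "divide")
  # uniform angles fill bins nearly uniformly
  set.seed(6)
  b <- discretize(runif(1e5, -180, 180), 10)
  cts <- tabulate(b + 1L, 36)
  expect_lt(max(abs(cts - mean(cts))) / mean(cts), 0.06)
})

test_that("reweight inverts closed-form cases", {
  # lambda = 1 is the identity
  rw <- reweight(c(3, 7), lam = 1)
  expect_equal(rw$p_unbiased, c(0.3, 0.7))
  # (750, 250) at lambda = 0.5: 0.75^2 / (0.75^2 + 0.25^2) = 0.9
  rw <- reweight(c(750, 250), lam = 0.5)
  expect_equal(rw$p_unbiased, c(0.9, 0.1))
  # (0.75, 0.25) at lambda = 0.7: x^(1/0.7) renormalised
  rw <- reweight(c(0.75, 0.25), lam = 0.7)
  u <- c(0.75, 0.25)^(1 / 0.7)
  expect_equal(rw$p_unbiased, u / sum(u))
  expect_equal(rw$p_unbiased, c(0.828, 0.172), tolerance = 1e-3)
  expect_error(reweight(c(0, 0), lam = 0.7), "zero")
  expect_error(reweight(c(1, 1), lam = 1.2), "lam")
})

test_that("applying reweight twice is not the identity", {
  rw1 <- reweight(c(750, 250), lam = 0.5)
  rw2 <- reweight(rw1$p_unbiased, lam = 0.5)
  expect_false(isTRUE(all.equal(rw2$p_unbiased, rw1$p_unbiased)))
})

test_that("reweighting recovers the truth from scaled sampling", {
  set.seed(8)
  for (r in 1:2) {
    p <- runif(36); p <- p / sum(p)
    for (lam in c(0.5, 0.7)) {
      cts <- sample_scaled_bins(p, lam, 1e5, seed = 300 + r)
      rw <- reweight(cts, lam)
      expect_lt(max(abs(rw$p_unbiased - p)), 0.02)
    }
  }
})

test_that("frame weights have mean one and follow the bin table", {
  cts <- c(600, 300, 100)
  rw <- reweight(cts, lam = 0.7)
  ids <- rep(0:2, times = cts)
  w <- frame_weights(ids, rw)
  expect_equal(mean(w), 1)
  expect_equal(length(unique(w)), 3)
  expect_error(frame_weights(c(0, 5), rw), "bin id")
})

test_that("fes2d reproduces the two-bin closed form", {
  x <- c(rep(15, 900), rep(105, 100))
  y <- rep(15, 1000)
  f <- fes2d(x, y, temperature = 298, width = 10)
  occ <- f$grid[f$grid$occupied, ]
  occ <- occ[order(occ$dG), ]
  expect_equal(occ$dG[1], 0)
  expect_equal(occ$dG[2], -0.0019872041 * 298 * log(1 / 9),
               tolerance = 1e-9)
  expect_equal(occ$dG[2], 1.301, tolerance = 1e-3)
})

test_that("every surface is anchored at zero and masks empty bins", {
  set.seed(9)
  x <- wrap_angle(rnorm(2000, 0, 40))
  y <- wrap_angle(rnorm(2000, -60, 40))
  f <- fes2d(x, y)
  occ <- f$grid[f$grid$occupied, ]
  expect_equal(min(occ$dG), 0)
  expect_true(all(is.na(f$grid$dG[!f$grid$occupied])))
  expect_true(all(occ$dG >= 0))
})

test_that("fes2d is invariant under uniform weight rescaling", {
  set.seed(10)
  x <- runif(500, -180, 180); y <- runif(500, -180, 180)
  w <- runif(500, 0.2, 2)
  f1 <- fes2d(x, y, weights = w)
  f2 <- fes2d(x, y, weights = 17 * w)
  expect_equal(f1$grid$dG, f2$grid$dG)
})

test_that("dG differences between bins are anchor-free", {
  set.seed(11)
  x <- wrap_angle(rnorm(5000, 30, 60)); y <- wrap_angle(rnorm(5000, 0, 60))
  f <- fes2d(x, y)
  occ <- f$grid[f$grid$occupied & f$grid$p > 0.002, ]
  i <- 1; j <- nrow(occ)
  lhs <- occ$dG[i] - occ$dG[j]
  rhs <- -0.0019872041 * 298 * log(occ$p[i] / occ$p[j])
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("uniform lattice input gives an essentially flat surface", {
  u <- uniform_bin_angles(1e5, width = 10, seed = 12)
  f <- fes2d(u$x, u$y, width = 10)
  occ <- f$grid[f$grid$occupied, ]
  expect_lt(max(occ$dG), 0.05)
})

test_that("reweight_series pools torsions and returns mean-1 weights", {
  mix <- sample_state_mixture(rbind(c(-57, -47), c(60, 45)), c(0.8, 0.2),
                              5000, noise_sigma = 10, seed = 14)
  rw <- reweight_series(mix$series, lam = 0.7, width = 30)
  expect_equal(mean(rw$weights), 1)
  expect_equal(length(rw$weights), 5000)
  expect_true(all(rw$table$p_unbiased >= 0))
  expect_equal(sum(rw$table$p_unbiased), 1)
})
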