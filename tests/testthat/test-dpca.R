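mini_series <- function(phi, psi = NULL) {
  n <- length(phi)
  rows <- tibble::tibble(frame = seq_len(n), resno = 1L, resname = "ALA",
                         kind = "phi", angle = phi)
  if (!is.null(psi)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      frame = seq_len(n), resno = 1L, resname = "ALA", kind = "psi",
      angle = psi))
  }
  class(rows) <- c("pep_dihedrals", class(rows))
  rows
}

test_that("to_metric implements the (cos, sin) embedding", {
  m <- to_metric(mini_series(c(0, 90, 180, -180)))
  expect_equal(ncol(m), 2)
  expect_equal(m[1, ], c(phi_1_cos = 1, phi_1_sin = 0))
  # +180 and -180 embed identically: the point of the transform
  expect_equal(m[3, ], m[4, ])
  expect_true(all(m >= -1 & m <= 1))
  # n angles -> 2n columns
  m2 <- to_metric(mini_series(c(10, 20), c(30, 40)))
  expect_equal(ncol(m2), 4)
})

test_that("to_metric is injective on (-180, 180] and wrap invariant", {
  a <- seq(-179, 180, by = 1)
  m <- to_metric(mini_series(a))
  expect_equal(nrow(unique(round(m, 12))), length(a))
  m2 <- to_metric(mini_series(wrap_angle(a + 360)))
  expect_equal(m, m2)
})

test_that("to_metric rejects partially missing columns", {
  s <- mini_series(c(10, NA, 30))
  expect_error(to_metric(s), "missing")
})

test_that("pca recovers rank and conserves variance", {
  set.seed(15)
  t_ <- runif(200)
  line4d <- cbind(t_, 2 * t_, -t_, 0.5 * t_)
  p <- pca_metric(line4d, k = 2)
  expect_lt(p$eigenvalues[2], 1e-10)
  expect_gt(p$eigenvalues[1], 0)
  X <- matrix(rnorm(1000 * 6), 1000, 6)
  p2 <- pca_metric(X, k = 6)
  expect_equal(sum(p2$eigenvalues), sum(apply(X, 2, stats::var)))
  # full-rank projections preserve pairwise distances
  i <- sample(1000, 50); j <- sample(1000, 50)
  d_orig <- sqrt(rowSums((X[i, ] - X[j, ])^2))
  d_proj <- sqrt(rowSums((p2$projections[i, ] - p2$projections[j, ])^2))
  expect_equal(d_proj, d_orig, tolerance = 1e-9)
  expect_error(pca_metric(X[1, , drop = FALSE]), "2 frames")
})

test_that("pca eigenvector signs are deterministic", {
  set.seed(16)
  X <- matrix(rnorm(500 * 4), 500, 4)
  p1 <- pca_metric(X)
  p2 <- pca_metric(X[nrow(X):1, ])  # same data, reversed order
  expect_equal(abs(p1$eigenvectors), abs(p2$eigenvectors), tolerance = 1e-9)
  for (j in 1:4) {
    expect_gt(p1$eigenvectors[which.max(abs(p1$eigenvectors[, j])), j], 0)
  }
})

test_that("two separated blobs recover their 60/40 split", {
  set.seed(17)
  n1 <- 6000; n2 <- 4000
  proj <- rbind(cbind(rnorm(n1, -2, 0.3), rnorm(n1, 0, 0.3)),
                cbind(rnorm(n2, 2, 0.3), rnorm(n2, 0, 0.3)))
  cl <- density_clusters(proj)
  expect_equal(length(cl$occupancies), 2)
  occ <- sort(as.numeric(cl$occupancies), decreasing = TRUE)
  expect_lt(abs(occ[1] - 60), 3)
  expect_lt(abs(occ[2] - 40), 3)
  # occupancies plus unassigned account for every frame
  expect_equal(sum(cl$occupancies) + 100 * mean(cl$labels == 0), 100,
               tolerance = 1e-9)
})

test_that("a single blob forms one near-total cluster", {
  set.seed(18)
  proj <- cbind(rnorm(5000, 0, 0.5), rnorm(5000, 0, 0.5))
  cl <- density_clusters(proj)
  expect_equal(length(cl$occupancies), 1)
  expect_gt(cl$occupancies[1], 95)
})

test_that("states straddling the +/-180 wrap stay single clusters", {
  mix <- sample_state_mixture(rbind(c(179, 0), c(-60, -45)), c(0.5, 0.5),
                              20000, noise_sigma = 15, seed = 5)
  dp <- dpca(mix$series, k = 2)
  expect_equal(length(dp$occupancies), 2)
  expect_lt(max(abs(sort(as.numeric(dp$occupancies)) - 50)), 3)
})

test_that("clustering is deterministic for identical projections", {
  set.seed(19)
  proj <- cbind(rnorm(3000), rnorm(3000))
  a <- density_clusters(proj)
  b <- density_clusters(proj)
  expect_identical(a$labels, b$labels)
  expect_identical(a$occupancies, b$occupancies)
})

test_that("three-state mixtures are recovered with correct occupancies", {
  centers <- rbind(c(-57, -47), c(-135, 135), c(60, 45))
  mix <- sample_state_mixture(centers, c(0.5, 0.3, 0.2), 20000,
                              noise_sigma = 15, seed = 123)
  dp <- dpca(mix$series, k = 2)
  expect_equal(length(dp$occupancies), 3)
  occ <- sort(as.numeric(dp$occupancies), decreasing = TRUE)
  expect_true(all(abs(occ - c(50, 30, 20)) < 3))
})

test_that("representative frames carry their cluster's label", {
  set.seed(20)
  proj <- rbind(cbind(rnorm(2000, -2, 0.3), rnorm(2000, 0, 0.3)),
                cbind(rnorm(1000, 2, 0.3), rnorm(1000, 0, 0.3)))
  cl <- density_clusters(proj)
  for (id in seq_along(cl$occupancies)) {
    f <- representative_frame(cl, id, proj)
    expect_equal(cl$labels[f], id)
    # within one grid cell of the blob center
    ctr <- as.numeric(cl$peaks[cl$peaks$cluster == id, c("PC1", "PC2")])
    expect_lt(sqrt(sum((proj[f, ] - ctr)^2)),
              2 * max(cl$grid$binw))
  }
  expect_error(representative_frame(cl, 99, proj), "unknown cluster")
})

test_that("a singleton far-out basin keeps its frame as representative", {
  set.seed(21)
  proj <- rbind(cbind(rnorm(3000, 0, 0.2), rnorm(3000, 0, 0.2)),
                c(8, 8))
  cl <- density_clusters(proj, min_density_fraction = 0,
                         min_cluster_fraction = 0)
  singleton <- cl$labels[3001]
  expect_gt(singleton, 0)
  expect_equal(representative_frame(cl, singleton, proj), 3001)
})

test_that("dpca tidy/glance expose frames and clusters", {
  mix <- sample_state_mixture(rbind(c(-57, -47), c(60, 45)), c(0.6, 0.4),
                              5000, noise_sigma = 12, seed = 22)
  dp <- dpca(mix$series, k = 2)
  td <- tidy(dp)
  expect_equal(nrow(td), 5000)
  expect_true(all(c("frame", "PC1", "PC2", "cluster") %in% names(td)))
  gl <- glance(dp)
  expect_equal(gl$n_frames, 5000)
  expect_equal(gl$n_clusters, length(dp$occupancies))
  expect_true(all(dp$eigenvalues >= 0))
  expect_equal(dp$eigenvalues, sort(dp$eigenvalues, decreasing = TRUE))
})
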