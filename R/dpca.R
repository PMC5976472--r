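#' Embed dihedral angles in metric (cos, sin) space
#'
#' Each angle a contributes the pair (cos a, sin a), removing the +/-180
#' periodicity artefact before PCA: +180 and -180 map to the same point, and
#' distances in the embedding are invariant to wrapping. Angles are taken
#' from a long dihedral series and spread to a frames x 2n matrix.
#'
#' @param series A `pep_dihedrals` tibble (columns `frame`, `resno`, `kind`,
#'   `angle`).
#' @param kinds Torsion kinds to include (default phi, psi, chi1).
#' @param residues Optional residue index filter.
#' @return Numeric matrix frames x (2 x angles), bounded in `[-1, 1]`, with
#'   column names like `phi_5_cos`. Errors if any selected angle is missing.
#' @export
to_metric <- function(series, kinds = c("phi", "psi", "chi1"),
                      residues = NULL) {
  s <- series[series$kind %in% kinds, ]
  if (!is.null(residues)) s <- s[s$resno %in% residues, ]
  # terminal phi/psi are structurally absent and dropped as whole columns;
  # a column that is only partially missing is an error
  s <- s |> mutate(label = paste0(.data$kind, "_", .data$resno))
  by_label <- s |> group_by(.data$label) |>
    summarise(n_na = sum(is.na(.data$angle)), n = n())
  partial <- by_label$label[by_label$n_na > 0 & by_label$n_na < by_label$n]
  if (length(partial) > 0) {
    abort(paste0("missing angles in selection: ",
                 paste(partial, collapse = ", ")))
  }
  keep <- by_label$label[by_label$n_na == 0]
  if (length(keep) == 0) abort("no complete angle columns in selection")
  s <- s[s$label %in% keep, ]
  wide <- s |> select("frame", "label", "angle") |>
    tidyr::pivot_wider(names_from = "label", values_from = "angle") |>
    arrange(.data$frame)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rad <- m * pi / 180
  out <- matrix(0, nrow(m), 2 * ncol(m))
  out[, seq(1, 2 * ncol(m), by = 2)] <- cos(rad)
  out[, seq(2, 2 * ncol(m), by = 2)] <- sin(rad)
  colnames(out) <- as.vector(rbind(paste0(colnames(m), "_cos"),
                                   paste0(colnames(m), "_sin")))
  out
}

#' Principal component analysis of metric coordinates
#'
#' Eigendecomposition of the covariance matrix of the (cos, sin) embedding
#' after column-mean centering. Eigenvector signs are fixed so the loading
#' of largest magnitude is positive, making results deterministic.
#'
#' @param metric Numeric matrix frames x d (from [to_metric()]).
#' @param k Number of components to keep for projections (default 2).
#' @return List with `eigenvalues` (all d, descending), `eigenvectors`
#'   (d x d, columns), `projections` (frames x k) and `variance_fraction`.
#' @export
pca_metric <- function(metric, k = 2) {
  if (nrow(metric) < 2) abort("need at least 2 frames for PCA")
  p <- prcomp(metric, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  vec <- p$rotation
  for (j in seq_len(ncol(vec))) {
    if (vec[which.max(abs(vec[, j])), j] < 0) {
      vec[, j] <- -vec[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  k <- min(k, ncol(vec))
  list(eigenvalues = ev, eigenvectors = vec,
       projections = p$x[, seq_len(k), drop = FALSE],
       variance_fraction = cumsum(ev) / sum(ev))
}

# ---- density peak clustering ------------------------------------------------

# smooth a k-dim count array with one pass of a (2w+1)^k boxcar
smooth_boxcar <- function(counts, w) {
  if (w <= 0) return(counts)
  d <- length(dim(counts))
  out <- counts
  for (axis in seq_len(d)) {
    shifted <- out * 0
    n <- dim(out)[axis]
    acc <- out * 0
    cnt <- 0
    for (s in (-w):w) {
      idx_from <- pmax(1, 1 - s):pmin(n, n - s)
      idx_to <- idx_from + s
      src <- slice_axis(out, axis, idx_from)
      acc <- acc + pad_axis(src, axis, idx_to, dim(out))
      cnt <- cnt + 1
    }
    out <- acc / cnt
  }
  out
}

slice_axis <- function(a, axis, idx) {
  d <- length(dim(a))
  args <- rep(list(quote(expr = )), d)
  args[[axis]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

pad_axis <- function(a, axis, idx, full_dim) {
  out <- array(0, dim = full_dim)
  d <- length(full_dim)
  args <- rep(list(quote(expr = )), d)
  args[[axis]] <- idx
  do.call(`[<-`, c(list(out), args, list(a)))
}

# face-adjacent neighbour offsets in k dimensions
face_neighbours <- function(k) {
  out <- matrix(0L, 2 * k, k)
  for (j in seq_len(k)) {
    out[2 * j - 1, j] <- -1L
    out[2 * j, j] <- 1L
  }
  out
}

#' Density peak-picking clustering of dPCA projections
#'
#' Histograms the top-k projections on a regular grid, finds density peaks
#' (local maxima over face-adjacent neighbours above a fraction of the
#' global maximum), and assigns every occupied bin to a peak by steepest-
#' ascent hill climbing; frames inherit their bin's peak. Basins whose local
#' maximum falls below the peak threshold are left unassigned (label 0).
#' Ties in the ascent are resolved toward the lexicographically smallest bin
#' index, so clustering is deterministic. A light boxcar smoothing pass and
#' a saddle-based peak merge step suppress Poisson noise in well-sampled
#' basins (both configurable).
#'
#' @param projections Numeric matrix frames x k with k = 2 or 3.
#' @param grid_bins Bins per axis (default 50 for k = 2, 30 for k = 3);
#'   at least 10.
#' @param min_density_fraction Peaks must exceed this fraction of the global
#'   density maximum (default 0.05).
#' @param floor_count Bins with fewer raw frames than this stay unassigned
#'   (default 1, i.e. every occupied bin is assigned).
#' @param smooth_window Half-width of the boxcar smoothing kernel in bins
#'   (default 1; 0 disables smoothing).
#' @param merge_saddle_fraction Two peaks are merged when the density at the
#'   saddle between their basins exceeds this fraction of the lower peak
#'   (default 0.75); guards against noise-split basins.
#' @param min_cluster_fraction Clusters holding less than this percentage of
#'   all frames are dissolved into the unassigned label (default 1); guards
#'   against stray tail bins forming spurious clusters.
#' @return Object of class `pep_dpca_clusters`: list with `labels` (per
#'   frame, 0 = unassigned), `occupancies` (percent per cluster, labelled by
#'   cluster id, sorted decreasing), `peaks` (tibble of peak bin centers and
#'   densities), `grid` metadata.
#' @export
density_clusters <- function(projections, grid_bins = NULL,
                             min_density_fraction = 0.05, floor_count = 1,
                             smooth_window = 1,
                             merge_saddle_fraction = 0.75,
                             min_cluster_fraction = 1) {
  proj <- as.matrix(projections)
  F <- nrow(proj)
  if (F == 0) abort("empty projections")
  k <- ncol(proj)
  if (!k %in% c(2, 3)) abort("projections must have 2 or 3 columns")
  if (is.null(grid_bins)) grid_bins <- if (k == 2) 50L else 30L
  if (grid_bins < 10) abort("grid_bins must be at least 10 per axis")
  nb <- as.integer(grid_bins)

  lo <- apply(proj, 2, min)
  hi <- apply(proj, 2, max)
  span <- pmax(hi - lo, 1e-12)
  binw <- span / nb
  bins <- matrix(0L, F, k)
  for (j in seq_len(k)) {
    b <- floor((proj[, j] - lo[j]) / binw[j])
    bins[, j] <- as.integer(pmin(pmax(b, 0), nb - 1))
  }
  idx_mat <- bins + 1L
  # column-major flat index into the k-dim count array
  flat <- idx_mat[, 1]
  mult <- 1L
  for (j in seq_len(k)[-1]) {
    mult <- mult * nb
    flat <- flat + (idx_mat[, j] - 1L) * mult
  }
  counts <- array(tabulate(flat, nbins = nb^k), dim = rep(nb, k))
  dens <- smooth_boxcar(counts, smooth_window)

  occupied <- which(counts > 0, arr.ind = TRUE)
  nbrs <- face_neighbours(k)
  dmax <- max(dens)
  get_d <- function(ix) {
    if (k == 2) dens[ix[1], ix[2]] else dens[ix[1], ix[2], ix[3]]
  }
  # steepest ascent with memoised paths; returns terminal bin key
  parent <- new.env(hash = TRUE)
  climb <- function(ix) {
    path <- character(0)
    cur <- ix
    repeat {
      key <- paste(cur, collapse = ",")
      hit <- parent[[key]]
      if (!is.null(hit)) {
        for (p in path) parent[[p]] <- hit
        return(hit)
      }
      path <- c(path, key)
      dcur <- get_d(cur)
      best <- cur
      dbest <- dcur
      cand <- sweep(nbrs, 2, cur, `+`)
      ok <- rowSums(cand >= 1 & cand <= nb) == k
      for (r in which(ok)) {
        dr <- get_d(cand[r, ])
        if (dr > dbest ||
            (dr == dbest && !identical(best, cur) &&
             lex_less(cand[r, ], best))) {
          best <- cand[r, ]
          dbest <- dr
        }
      }
      if (identical(best, cur)) {
        for (p in path) parent[[p]] <- key
        return(key)
      }
      cur <- best
    }
  }
  term <- character(nrow(occupied))
  for (r in seq_len(nrow(occupied))) term[r] <- climb(occupied[r, ])

  # peaks: terminal bins above the density threshold
  term_keys <- unique(term)
  term_ix <- do.call(rbind, lapply(strsplit(term_keys, ","), as.integer))
  term_d <- apply(term_ix, 1, get_d)
  is_peak <- term_d >= min_density_fraction * dmax

  # map each occupied bin to its terminal key
  bin_key <- apply(occupied, 1, paste, collapse = ",")
  bin_term <- term

  # merge peaks whose saddle is high relative to the lower peak
  peak_keys <- term_keys[is_peak]
  if (length(peak_keys) > 1 && merge_saddle_fraction < 1) {
    repeat {
      merged <- FALSE
      # saddle between basins a, b: highest density over face-adjacent
      # occupied bin pairs belonging to different basins
      basin <- setNames(bin_term, bin_key)
      occ_d <- apply(occupied, 1, get_d)
      peak_d <- setNames(apply(do.call(rbind, lapply(
        strsplit(peak_keys, ","), as.integer)), 1, get_d), peak_keys)
      saddles <- list()
      for (r in seq_len(nrow(occupied))) {
        ka <- bin_term[r]
        if (!(ka %in% peak_keys)) next
        cand <- sweep(nbrs, 2, occupied[r, ], `+`)
        ok <- rowSums(cand >= 1 & cand <= nb) == k
        for (q in which(ok)) {
          key2 <- paste(cand[q, ], collapse = ",")
          kb <- unname(basin[key2])
          if (is.na(kb) || kb == ka || !(kb %in% peak_keys)) next
          pr <- paste(sort(c(ka, kb)), collapse = "|")
          h <- min(occ_d[r], get_d(cand[q, ]))
          if (is.null(saddles[[pr]]) || saddles[[pr]] < h) saddles[[pr]] <- h
        }
      }
      if (length(saddles) > 0) {
        for (pr in names(saddles)) {
          ab <- strsplit(pr, "|", fixed = TRUE)[[1]]
          lowpk <- min(peak_d[ab[1]], peak_d[ab[2]])
          if (saddles[[pr]] >= merge_saddle_fraction * lowpk) {
            # absorb the lower peak into the higher one
            keep <- ab[which.max(peak_d[ab])]
            drop_ <- setdiff(ab, keep)
            bin_term[bin_term == drop_] <- keep
            peak_keys <- setdiff(peak_keys, drop_)
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) break
    }
  }

  # cluster ids by decreasing population
  lab_of_bin <- setNames(rep(0L, nrow(occupied)), bin_key)
  frame_key <- apply(idx_mat, 1, paste, collapse = ",")
  below_floor <- counts < floor_count
  basin_final <- setNames(bin_term, bin_key)
  frame_basin <- basin_final[frame_key]
  frame_basin[!(frame_basin %in% peak_keys)] <- NA
  # floor rule on the frame's own bin
  if (floor_count > 1) {
    raw <- counts[idx_mat]
    frame_basin[raw < floor_count] <- NA
  }
  pops <- sort(table(frame_basin), decreasing = TRUE)
  # dissolve clusters too small to be meaningful conformational states
  small <- 100 * as.numeric(pops) / F < min_cluster_fraction
  if (any(small)) {
    frame_basin[frame_basin %in% names(pops)[small]] <- NA
    pops <- pops[!small]
  }
  ids <- setNames(seq_along(pops), names(pops))
  labels <- ifelse(is.na(frame_basin), 0L, ids[frame_basin])
  labels[is.na(labels)] <- 0L
  occup <- 100 * as.numeric(pops) / F
  names(occup) <- seq_along(pops)

  centers <- function(keyv) {
    ix <- do.call(rbind, lapply(strsplit(keyv, ","), as.integer))
    sweep(sweep(ix - 0.5, 2, binw, `*`), 2, lo, `+`)
  }
  pk_ix <- names(pops)
  peaks <- as_tibble(as.data.frame(centers(pk_ix)))
  names(peaks) <- paste0("PC", seq_len(k))
  peaks$density <- vapply(strsplit(pk_ix, ","),
                          function(v) get_d(as.integer(v)), 1.0)
  peaks$cluster <- seq_len(nrow(peaks))
  structure(list(labels = as.integer(labels), occupancies = occup,
                 peaks = peaks,
                 grid = list(lo = lo, binw = binw, nb = nb, k = k)),
            class = "pep_dpca_clusters")
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Representative frame of a cluster
#'
#' The member frame whose projection lies closest (Euclidean, in the top-k
#' projection space) to the cluster's density-peak bin center.
#'
#' @param clusters A `pep_dpca_clusters` from [density_clusters()].
#' @param cluster_id Cluster id (1-based, 1 = most populated).
#' @param projections The projections the clustering was computed from.
#' @return Frame index.
#' @export
representative_frame <- function(clusters, cluster_id, projections) {
  pk <- clusters$peaks[clusters$peaks$cluster == cluster_id, ]
  if (nrow(pk) != 1) abort(paste0("unknown cluster id ", cluster_id))
  members <- which(clusters$labels == cluster_id)
  if (length(members) == 0) abort(paste0("cluster ", cluster_id, " is empty"))
  k <- clusters$grid$k
  ctr <- as.numeric(pk[1, paste0("PC", seq_len(k))])
  d2 <- rowSums((projections[members, seq_len(k), drop = FALSE] -
                   matrix(ctr, length(members), k, byrow = TRUE))^2)
  members[which.min(d2)]
}

#' Dihedral principal component analysis with density clustering
#'
#' End-to-end dPCA: (cos, sin) embedding of the selected torsions, PCA of
#' the embedding, density peak clustering of the top-k projections, and
#' representative-frame selection per cluster.
#'
#' @param series A `pep_dihedrals` tibble (phi/psi/chi1 of the residue range
#'   of interest; missing chi1 columns, e.g. Gly/Ala, are dropped).
#' @param residues Optional residue index filter.
#' @param kinds Torsion kinds entering the analysis.
#' @param k Number of principal components for clustering (2 or 3).
#' @param ... Passed to [density_clusters()].
#' @return Object of class `pep_dpca`: eigenstructure, projections, cluster
#'   labels, occupancies and representative frames. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
dpca <- function(series, residues = NULL, kinds = c("phi", "psi", "chi1"),
                 k = 2, ...) {
  metric <- to_metric(series, kinds = kinds, residues = residues)
  p <- pca_metric(metric, k = k)
  cl <- density_clusters(p$projections, ...)
  reps <- vapply(seq_along(cl$occupancies), function(id) {
    representative_frame(cl, id, p$projections)
  }, 1L)
  structure(list(eigenvalues = p$eigenvalues,
                 eigenvectors = p$eigenvectors,
                 projections = p$projections,
                 variance_fraction = p$variance_fraction,
                 labels = cl$labels,
                 occupancies = cl$occupancies,
                 peaks = cl$peaks,
                 representatives = reps,
                 clusters = cl),
            class = "pep_dpca")
}

#' @export
print.pep_dpca <- function(x, ...) {
  cat("<pep_dpca> ", nrow(x$projections), " frames, ",
      length(x$occupancies), " clusters; top-2 variance ",
      sprintf("%.1f%%", 100 * x$variance_fraction[2]), "\n", sep = "")
  for (i in seq_along(x$occupancies)) {
    cat(sprintf("  cluster %d: %.1f%% (representative frame %d)\n",
                i, x$occupancies[i], x$representatives[i]))
  }
  invisible(x)
}

#' @describeIn dpca Per-frame tibble of projections and cluster labels.
#' @param x A `pep_dpca`.
#' @param ... Unused.
#' @export
tidy.pep_dpca <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$projections))
  names(out) <- paste0("PC", seq_len(ncol(x$projections)))
  out$frame <- seq_len(nrow(out))
  out$cluster <- x$labels
  select(out, "frame", dplyr::everything())
}

#' @describeIn dpca One-row summary: frames, clusters, variance captured.
#' @export
glance.pep_dpca <- function(x, ...) {
  tibble(n_frames = nrow(x$projections),
         n_clusters = length(x$occupancies),
         top_occupancy = unname(x$occupancies[1]),
         unassigned_pct = 100 * mean(x$labels == 0),
         var_top2 = x$variance_fraction[2])
}
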