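#' Discretise angles into fixed-width bins
#'
#' Maps each angle to `floor((wrap(a) + 180) / width)` with left-closed,
#' right-open bins covering (-180, 180]; the closed right edge (+180) wraps
#' into the last bin's partner, bin 0's mirror: +180 maps to bin
#' `360/width - 1`'s wrap, i.e. `floor((180+180)/width) %% nbins`.
#'
#' @param a Numeric vector (or matrix) of angles in degrees.
#' @param width Bin width in degrees; must divide 360 (default 10).
#' @return Integer bin ids in `0 .. 360/width - 1`, same shape as `a`.
#' @export
#' @examples
#' discretize(c(-179.99, 0, 179.99, 180), width = 10)
discretize <- function(a, width = 10) {
  if (360 %% width != 0) abort("width must divide 360")
  nb <- as.integer(360 / width)
  b <- floor((wrap_angle(a) + 180) / width)
  # the closed right edge (+180, and -180 which wraps onto it) belongs to
  # the last bin
  b[b == nb] <- nb - 1
  storage.mode(b) <- "integer"
  b
}

# Combine per-dimension bin ids (matrix frames x d) into single multi-bin ids
multi_bin_id <- function(bins, nb) {
  d <- ncol(bins)
  id <- bins[, 1]
  if (d > 1) for (k in 2:d) id <- id * nb + bins[, k]
  id
}

#' Invert the population bias of a lambda-scaled simulation
#'
#' Scaled MD multiplies the potential by lambda < 1, so sampled bin
#' populations follow `q` proportional to `p^lambda`. Given biased counts
#' (or probabilities) per torsion bin, the unbiased populations are
#' recovered as `p` proportional to `q^(1/lambda)`, and each frame gets the
#' weight `p(bin)/q(bin)`, rescaled to mean 1.
#'
#' @param counts Non-negative counts (or unnormalised probabilities) per bin.
#' @param lam The scaling factor lambda used in the simulation, in (0, 1].
#' @return A tibble of class `pep_reweight` with columns `bin` (0-based),
#'   `p_biased`, `p_unbiased`, `weight` (the per-bin frame weight before the
#'   mean-1 rescale is applied by [frame_weights()]); `lam` is kept as an
#'   attribute.
#' @export
#' @examples
#' reweight(c(750, 250), lam = 0.5) # recovers p = (0.9, 0.1)
reweight <- function(counts, lam) {
  if (lam <= 0 || lam > 1) abort("lam must be in (0, 1]")
  if (any(counts < 0)) abort("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) abort("all counts are zero")
  p_b <- counts / tot
  p_u <- p_b^(1 / lam)
  p_u <- p_u / sum(p_u)
  w <- ifelse(p_b > 0, p_u / p_b, 0)
  out <- tibble(bin = seq_along(counts) - 1L, p_biased = p_b,
                p_unbiased = p_u, weight = w)
  attr(out, "lam") <- lam
  class(out) <- c("pep_reweight", class(out))
  out
}

#' Per-frame weights from a reweighted bin table
#'
#' @param bin_ids Integer vector of 0-based bin ids, one per frame.
#' @param rw A `pep_reweight` table from [reweight()].
#' @return Numeric weights with mean 1, one per frame.
#' @export
frame_weights <- function(bin_ids, rw) {
  w <- rw$weight[match(bin_ids, rw$bin)]
  if (anyNA(w)) abort("frame bin id not present in reweight table")
  w / mean(w)
}

#' Reweight a trajectory over discretised torsions
#'
#' Convenience wrapper: discretises the chosen torsions of a dihedral
#' series, pools frames into multi-bins, inverts the lambda bias and returns
#' per-frame weights (mean 1).
#'
#' @param series A `pep_dihedrals` tibble.
#' @param lam Scaling factor lambda in (0, 1].
#' @param width Bin width in degrees (default 10).
#' @param kinds Which torsion kinds enter the binning (default phi, psi and
#'   chi1 where present).
#' @return List with `weights` (per frame, mean 1) and `table` (the
#'   `pep_reweight` bin table).
#' @export
reweight_series <- function(series, lam, width = 10,
                            kinds = c("phi", "psi", "chi1")) {
  s <- series[series$kind %in% kinds & !is.na(series$angle), ]
  wide <- s |>
    mutate(label = paste0(.data$kind, "_", .data$resno)) |>
    select("frame", "label", "angle") |>
    tidyr::pivot_wider(names_from = "label", values_from = "angle") |>
    arrange(.data$frame)
  m <- as.matrix(wide[, -1, drop = FALSE])
  nb <- as.integer(360 / width)
  ids <- multi_bin_id(discretize(m, width), nb)
  counts <- table(factor(ids, levels = sort(unique(ids))))
  rw <- reweight(as.numeric(counts), lam)
  rw$bin <- as.numeric(names(counts))
  list(weights = frame_weights(ids, rw), table = rw)
}

BOLTZMANN_KCAL <- 0.0019872041  # kcal/(mol K)

#' Two-dimensional free-energy surface over torsion bins
#'
#' Weighted 2-D histogram of an angle pair converted to relative free energy
#' `dG = -kB T ln(p / p_max)` (kcal/mol), with the occupied minimum pinned
#' at exactly 0 and empty bins masked (`NA`), never reported as 0.
#'
#' @param x_angles,y_angles Angle vectors in degrees, same length; by
#'   convention the psi of residue i and the phi of residue i+1.
#' @param weights Optional non-negative per-frame weights (e.g. from
#'   [reweight_series()]); default uniform. Uniform rescaling of the weights
#'   does not change the surface.
#' @param temperature Temperature in Kelvin (default 298).
#' @param width Bin width in degrees (default 10).
#' @param axis_labels Character length-2 axis annotation, e.g.
#'   `c("Tyr20 psi", "Cys21 phi")`.
#' @return Object of class `pep_fes`: list with `grid` (tibble `x_center`,
#'   `y_center`, `p`, `dG`, `occupied`), `temperature`, `width`,
#'   `axis_labels`. `tidy()` returns the grid; `autoplot()` draws it.
#' @export
fes2d <- function(x_angles, y_angles, weights = NULL, temperature = 298,
                  width = 10, axis_labels = c("psi", "phi")) {
  if (length(x_angles) != length(y_angles)) abort("angle series lengths differ")
  if (length(x_angles) == 0) abort("empty input")
  if (is.null(weights)) weights <- rep(1, length(x_angles))
  if (any(weights < 0)) abort("weights must be non-negative")
  nb <- as.integer(360 / width)
  bx <- discretize(x_angles, width)
  by <- discretize(y_angles, width)
  w <- tapply(weights, list(factor(bx, levels = 0:(nb - 1)),
                            factor(by, levels = 0:(nb - 1))), sum)
  w[is.na(w)] <- 0
  p <- w / sum(w)
  occupied <- p > 0
  dG <- matrix(NA_real_, nb, nb)
  pmax_ <- max(p)
  dG[occupied] <- -BOLTZMANN_KCAL * temperature * log(p[occupied] / pmax_)
  centers <- -180 + width * (0:(nb - 1)) + width / 2
  grid <- tibble(
    x_center = rep(centers, nb),
    y_center = rep(centers, each = nb),
    p = as.vector(p),
    dG = as.vector(dG),
    occupied = as.vector(occupied))
  structure(list(grid = grid, temperature = temperature, width = width,
                 axis_labels = axis_labels),
            class = "pep_fes")
}

#' @export
print.pep_fes <- function(x, ...) {
  occ <- x$grid[x$grid$occupied, ]
  cat("<pep_fes> ", sum(x$grid$occupied), "/", nrow(x$grid),
      " occupied bins, dG range [0, ",
      sprintf("%.3f", max(occ$dG)), "] kcal/mol at ", x$temperature, " K\n",
      sep = "")
  invisible(x)
}

#' @describeIn fes2d Grid as a tibble.
#' @param x A `pep_fes`.
#' @param ... Unused.
#' @export
tidy.pep_fes <- function(x, ...) x$grid

#' @describeIn fes2d One-row summary (occupied bins, max dG, temperature).
#' @export
glance.pep_fes <- function(x, ...) {
  occ <- x$grid[x$grid$occupied, ]
  tibble(n_bins = nrow(x$grid), n_occupied = nrow(occ),
         dG_max = max(occ$dG), temperature = x$temperature,
         bin_width = x$width)
}
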