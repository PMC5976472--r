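#' Two-state torsion dynamics specification
#'
#' Defines a hidden two-state (helix H / coil C) Markov process over frames,
#' with per-residue mean (phi, psi) for each state and independent wrapped-
#' Gaussian angular noise. This is the synthetic stand-in used to emulate
#' helix/coil secondary-structure dynamics with known ground truth.
#'
#' @param n_res Number of residues.
#' @param helix_means,coil_means n x 2 matrices (or length-2 vectors recycled
#'   over residues) of per-residue (phi, psi) degrees for the H and C state.
#'   Defaults: (-57, -47) helix and (-120, 130) extended coil.
#' @param noise_sigma Wrapped-Gaussian standard deviation in degrees (>= 0).
#' @param transition 2 x 2 row-stochastic matrix, rows H then C.
#' @param p_init Initial state probabilities (H, C).
#' @param helix_propensity Optional per-residue multiplier in `[0, 1]` applied
#'   to the probability that a residue actually adopts the helix means when
#'   the chain is in state H (1 = always); models per-residue helical
#'   propensity.
#' @return Object of class `two_state_spec`.
#' @export
two_state_spec <- function(n_res,
                           helix_means = c(-57, -47),
                           coil_means = c(-120, 130),
                           noise_sigma = 10,
                           transition = matrix(c(0.995, 0.005,
                                                 0.005, 0.995), 2, 2,
                                               byrow = TRUE),
                           p_init = c(0.5, 0.5),
                           helix_propensity = NULL) {
  expand_means <- function(m) {
    if (is.null(dim(m))) m <- matrix(m, n_res, 2, byrow = TRUE)
    stopifnot(nrow(m) == n_res, ncol(m) == 2)
    m
  }
  helix_means <- expand_means(helix_means)
  coil_means <- expand_means(coil_means)
  if (any(abs(rowSums(transition) - 1) > 1e-12) || any(transition < 0)) {
    abort("transition must be a 2x2 row-stochastic matrix")
  }
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  if (abs(sum(p_init) - 1) > 1e-12 || any(p_init < 0)) {
    abort("p_init must be a probability vector of length 2")
  }
  if (is.null(helix_propensity)) helix_propensity <- rep(1, n_res)
  stopifnot(length(helix_propensity) == n_res,
            all(helix_propensity >= 0 & helix_propensity <= 1))
  structure(list(n_res = n_res, helix_means = wrap_angle(helix_means),
                 coil_means = wrap_angle(coil_means),
                 noise_sigma = noise_sigma, transition = transition,
                 p_init = p_init, helix_propensity = helix_propensity),
            class = "two_state_spec")
}

#' Sample a two-state torsion trajectory
#'
#' Draws a frame-wise Markov chain over states H and C and emits per-frame
#' per-residue phi/psi as the state mean plus wrapped-Gaussian noise. The
#' output is reproducible from `seed`.
#'
#' @param spec A [two_state_spec()].
#' @param sequence One-letter amino-acid string (length must equal
#'   `spec$n_res`).
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed for the single random stream.
#' @return A list with `series` (tibble `frame`, `resno`, `resname`, `kind`,
#'   `angle`, class `pep_dihedrals`) and `states` (character vector of "H" /
#'   "C" per frame).
#' @export
sample_two_state <- function(spec, sequence, n_frames, seed = 1) {
  stopifnot(inherits(spec, "two_state_spec"), n_frames >= 1)
  res3 <- seq1_to_3(sequence)
  if (length(res3) != spec$n_res) abort("sequence length must match spec$n_res")
  set.seed(seed)
  n <- spec$n_res
  # state path
  states <- integer(n_frames)
  states[1] <- sample.int(2, 1, prob = spec$p_init)
  if (n_frames > 1) {
    u <- runif(n_frames - 1)
    for (f in 2:n_frames) {
      states[f] <- if (u[f - 1] < spec$transition[states[f - 1], 1]) 1L else 2L
    }
  }
  # per-residue effective state: helix only with the residue's propensity
  eff_helix <- matrix(states == 1L, n_frames, n) &
    matrix(runif(n_frames * n) <
             matrix(spec$helix_propensity, n_frames, n, byrow = TRUE),
           n_frames, n)
  mean_phi <- ifelse(eff_helix,
                     matrix(spec$helix_means[, 1], n_frames, n, byrow = TRUE),
                     matrix(spec$coil_means[, 1], n_frames, n, byrow = TRUE))
  mean_psi <- ifelse(eff_helix,
                     matrix(spec$helix_means[, 2], n_frames, n, byrow = TRUE),
                     matrix(spec$coil_means[, 2], n_frames, n, byrow = TRUE))
  phi <- wrap_angle(mean_phi + rnorm(n_frames * n, sd = spec$noise_sigma))
  psi <- wrap_angle(mean_psi + rnorm(n_frames * n, sd = spec$noise_sigma))
  series <- bind_rows(
    tibble(frame = rep(seq_len(n_frames), n),
           resno = rep(seq_len(n), each = n_frames),
           kind = "phi", angle = as.vector(phi)),
    tibble(frame = rep(seq_len(n_frames), n),
           resno = rep(seq_len(n), each = n_frames),
           kind = "psi", angle = as.vector(psi)))
  series$resname <- res3[series$resno]
  series <- series |>
    select("frame", "resno", "resname", "kind", "angle") |>
    arrange(.data$frame, .data$resno, .data$kind)
  class(series) <- c("pep_dihedrals", class(series))
  list(series = series, states = c("H", "C")[states])
}

#' Sample categorical counts from a lambda-scaled distribution
#'
#' Emulates the population distortion of scaled molecular dynamics: when the
#' potential is multiplied by lambda < 1, bin populations follow
#' q proportional to p_true^lambda. Draws `n` categorical samples from q.
#'
#' @param p_true Probability vector over bins (sums to 1).
#' @param lam Scaling factor lambda, 0 < lam <= 1.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Integer vector of counts per bin, summing to `n`.
#' @export
#' @examples
#' sample_scaled_bins(c(0.9, 0.1), lam = 0.5, n = 1000, seed = 1)
sample_scaled_bins <- function(p_true, lam, n, seed = 1) {
  if (lam <= 0 || lam > 1) abort("lam must be in (0, 1]")
  if (any(p_true < 0) || abs(sum(p_true) - 1) > 1e-8) {
    abort("p_true must be a probability vector")
  }
  q <- p_true^lam
  q <- q / sum(q)
  set.seed(seed)
  as.integer(stats::rmultinom(1, size = n, prob = q))
}

#' Sample a categorical mixture of torsion states
#'
#' Draws frames from a set of (phi, psi) state centers with given mixing
#' fractions and independent wrapped-Gaussian noise; the ground truth used
#' to validate clustering. One row pair (phi, psi) per frame for a single
#' nominal residue.
#'
#' @param centers k x 2 matrix of state (phi, psi) centers in degrees.
#' @param fractions Length-k mixing fractions (sum to 1).
#' @param n Number of frames.
#' @param noise_sigma Wrapped-Gaussian standard deviation in degrees.
#' @param seed Integer seed.
#' @return List with `series` (a `pep_dihedrals` tibble for resno 1) and
#'   `states` (integer state index per frame).
#' @export
sample_state_mixture <- function(centers, fractions, n, noise_sigma = 15,
                                 seed = 1) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2, length(fractions) == nrow(centers),
            abs(sum(fractions) - 1) < 1e-8)
  set.seed(seed)
  st <- sample.int(nrow(centers), n, replace = TRUE, prob = fractions)
  phi <- wrap_angle(centers[st, 1] + rnorm(n, sd = noise_sigma))
  psi <- wrap_angle(centers[st, 2] + rnorm(n, sd = noise_sigma))
  series <- bind_rows(
    tibble(frame = seq_len(n), resno = 1L, resname = "ALA", kind = "phi",
           angle = phi),
    tibble(frame = seq_len(n), resno = 1L, resname = "ALA", kind = "psi",
           angle = psi)) |>
    arrange(.data$frame, .data$kind)
  class(series) <- c("pep_dihedrals", class(series))
  list(series = series, states = st)
}
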