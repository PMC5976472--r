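#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with validated
#' defaults. The default configuration generates a synthetic two-state
#' trajectory of the 22-residue peptide KKKRKVPLVWPAWVYCTRYSDR (a nuclear-
#' localisation sequence followed by the tryptophan-containing hexapeptide
#' motif region), with a disordered N-terminus and helix-prone core, and
#' analyses it end to end.
#'
#' @param sequence One-letter peptide sequence.
#' @param n_frames Frames to generate (default 5000).
#' @param lambda Potential scaling factor assumed for reweighting, in
#'   (0, 1]; values at or below 0.4 trigger a warning (sampling there is
#'   fast but conformations stop being physically meaningful) but the run
#'   proceeds.
#' @param temperature Temperature in K for free-energy conversion.
#' @param bin_width Torsion bin width in degrees.
#' @param hbond_dcut,hbond_angdev Hydrogen-bond cutoffs (Angstrom, degrees).
#' @param contact_cutoff Side-chain contact cutoff (Angstrom).
#' @param cbeta_cutoff,ring_cutoff Aromatic-pair cutoffs (Angstrom).
#' @param fes_residue Residue index i for the FES pair psi(i)/phi(i+1);
#'   default the tyrosine preceding the cysteine (residue 15 in the default
#'   sequence).
#' @param dpca_residues Residue range entering dPCA (default 7:22).
#' @param dpca_k Number of components used for clustering (2 or 3).
#' @param grid_bins Density grid bins per axis for clustering.
#' @param helix_propensity Per-residue helix propensity for the generator
#'   (default: low over the first six cell-penetrating residues, high over
#'   the motif core).
#' @param noise_sigma Angular noise of the generator (degrees).
#' @param seed Integer seed driving all randomness.
#' @return A validated list of class `pep_config`.
#' @export
pipeline_config <- function(sequence = "KKKRKVPLVWPAWVYCTRYSDR",
                            n_frames = 5000,
                            lambda = 0.7,
                            temperature = 298,
                            bin_width = 10,
                            hbond_dcut = 3.5,
                            hbond_angdev = 35,
                            contact_cutoff = 6.0,
                            cbeta_cutoff = 7.0,
                            ring_cutoff = 6.0,
                            fes_residue = NULL,
                            dpca_residues = NULL,
                            dpca_k = 2,
                            grid_bins = NULL,
                            helix_propensity = NULL,
                            noise_sigma = 18,
                            seed = 42) {
  n <- nchar(sequence)
  seq1_to_3(sequence)  # validates letters
  if (lambda <= 0 || lambda > 1) abort("lambda must be in (0, 1]")
  if (lambda <= 0.4) {
    warn(paste0("lambda = ", lambda, " is at or below 0.4; scaled sampling ",
                "this aggressive risks unphysical conformations"))
  }
  stopifnot(n_frames >= 1, temperature > 0, 360 %% bin_width == 0,
            hbond_dcut > 0, hbond_angdev > 0, hbond_angdev < 90,
            contact_cutoff > 0, cbeta_cutoff > 0, ring_cutoff > 0,
            dpca_k %in% c(2, 3))
  res3 <- seq1_to_3(sequence)
  if (is.null(fes_residue)) {
    cys_after <- which(res3[-1] == "CYS")
    fes_residue <- if (length(cys_after) > 0) cys_after[1] else max(1, n - 1)
  }
  if (fes_residue < 1 || fes_residue >= n) {
    abort("fes_residue must leave room for the following residue")
  }
  if (is.null(dpca_residues)) dpca_residues <- seq(min(7, n), n)
  if (is.null(helix_propensity)) {
    helix_propensity <- rep(0.85, n)
    helix_propensity[seq_len(min(6, n))] <- 0.05
  }
  stopifnot(length(helix_propensity) == n)
  structure(list(sequence = sequence, n_frames = n_frames, lambda = lambda,
                 temperature = temperature, bin_width = bin_width,
                 hbond_dcut = hbond_dcut, hbond_angdev = hbond_angdev,
                 contact_cutoff = contact_cutoff,
                 cbeta_cutoff = cbeta_cutoff, ring_cutoff = ring_cutoff,
                 fes_residue = fes_residue, dpca_residues = dpca_residues,
                 dpca_k = dpca_k, grid_bins = grid_bins,
                 helix_propensity = helix_propensity,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "pep_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @param config A `pep_config`.
#' @return `read_config()` returns a validated `pep_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  empty <- vapply(raw, function(x) {
    is.null(x) || (is.list(x) && length(x) == 0)
  }, TRUE)
  do.call(pipeline_config, raw[!empty])
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# default aromatic / proline interaction pairs for a topology: all pairs of
# ring-bearing aromatics (cbeta + ring), plus Pro-aromatic ring pairs
default_interaction_pairs <- function(topo) {
  res3 <- topo$residues$resname
  arom <- which(res3 %in% c("TRP", "TYR", "PHE", "HIS"))
  pro <- which(res3 == "PRO")
  rows <- list()
  if (length(arom) >= 2) {
    cmb <- utils::combn(arom, 2)
    for (c_ in seq_len(ncol(cmb))) {
      rows[[length(rows) + 1]] <- tibble(resA = cmb[1, c_], resB = cmb[2, c_],
                                         kind = "cbeta")
      rows[[length(rows) + 1]] <- tibble(resA = cmb[1, c_], resB = cmb[2, c_],
                                         kind = "ring_centroid")
    }
  }
  for (p in pro) {
    near <- arom[abs(arom - p) <= 4 & arom != p]
    for (a in near) {
      rows[[length(rows) + 1]] <- tibble(resA = p, resB = a,
                                         kind = "ring_centroid")
    }
  }
  bind_rows(rows)
}

stage_log <- function(quiet, stage, t0) {
  if (!quiet) {
    message(sprintf("[pepscape] %-16s %6.2f s", stage,
                    as.numeric(proc.time()[3] - t0)))
  }
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a trajectory and runs every analysis stage:
#' torsion extraction, secondary-structure timeline, hydrogen-bond /
#' contact / aromatic occupancy tables, lambda reweighting, free-energy
#' surface, dPCA clustering and representative conformers. All outputs are
#' written as TSV/JSON/PDB under `out_dir` together with a manifest;
#' rerunning with the same config and seed reproduces them byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param input Optional path to a multi-model PDB to analyse instead of
#'   generating a synthetic trajectory.
#' @param quiet Suppress stage timing messages (default FALSE).
#' @return Invisibly, a list with all intermediate results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, input = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pep_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path)
    files <<- c(files, name)
    path
  }
  t0 <- proc.time()[3]
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", stage, "' failed: ",
                   conditionMessage(e)))
    })
    stage_log(quiet, stage, t0)
    res
  }

  gen <- run_stage("generate", {
    if (!is.null(input)) {
      loaded <- read_ensemble(input)
      series <- extract_dihedrals(loaded$ensemble, loaded$topology)
      list(topology = loaded$topology, ensemble = loaded$ensemble,
           series = series, states = NULL)
    } else {
      spec <- two_state_spec(nchar(config$sequence),
                             noise_sigma = config$noise_sigma,
                             helix_propensity = config$helix_propensity)
      tw <- sample_two_state(spec, config$sequence, config$n_frames,
                             seed = config$seed)
      real <- realize_coordinates(tw$series, config$sequence)
      series <- extract_dihedrals(real$ensemble, real$topology)
      list(topology = real$topology, ensemble = real$ensemble,
           series = series, states = tw$states)
    }
  })
  topo <- gen$topology; ens <- gen$ensemble
  emit(gen$series, "dihedrals.tsv")

  tl <- run_stage("dssp", ss_timeline(ens, topo))
  emit(tidy(tl), "timeline.tsv")

  hb <- run_stage("hbonds", hbond_occupancy(
    ens, topo, d_cut = config$hbond_dcut, ang_dev_cut = config$hbond_angdev))
  emit(hb, "hbonds.tsv")

  pairs <- default_interaction_pairs(topo)
  aromatic <- run_stage("interactions", {
    if (nrow(pairs) > 0) {
      interaction_summary(ens, topo, pairs,
                          cutoffs = list(cbeta = config$cbeta_cutoff,
                                         ring_centroid = config$ring_cutoff,
                                         contact = config$contact_cutoff))
    } else {
      tibble(pair = character(), kind = character(), cutoff = numeric(),
             occupancy = numeric(), display = character())
    }
  })
  emit(aromatic, "aromatic.tsv")

  i <- config$fes_residue
  fes_series <- gen$series[(gen$series$resno == i & gen$series$kind == "psi") |
                           (gen$series$resno == i + 1 &
                              gen$series$kind == "phi"), ]
  rw <- run_stage("reweight", reweight_series(
    fes_series, lam = config$lambda, width = config$bin_width))
  emit(rw$table, "reweight.tsv")

  fes <- run_stage("fes", {
    x <- fes_series$angle[fes_series$kind == "psi"]
    y <- fes_series$angle[fes_series$kind == "phi"]
    fes2d(x, y, weights = rw$weights, temperature = config$temperature,
          width = config$bin_width,
          axis_labels = c(paste0(residue_label(topo, i), " psi"),
                          paste0(residue_label(topo, i + 1), " phi")))
  })
  emit(tidy(fes), "fes.tsv")

  dp <- run_stage("dpca", dpca(gen$series, residues = config$dpca_residues,
                               k = config$dpca_k,
                               grid_bins = config$grid_bins))
  emit(tidy(dp), "dpca_projections.tsv")
  emit(tibble(cluster = as.integer(names(dp$occupancies)),
              occupancy = as.numeric(dp$occupancies),
              representative_frame = dp$representatives),
       "dpca_clusters.tsv")

  files <- c(files, run_stage("representatives", {
    rep_frames <- dp$representatives
    sub <- pep_ensemble(ens$coords[rep_frames, , , drop = FALSE],
                        frame_interval = ens$frame_interval)
    write_ensemble(sub, topo, file.path(out_dir, "representatives.pdb"))
    "representatives.pdb"
  }))

  tables <- make_tables(list(hbonds = hb, aromatic = aromatic,
                             timeline = tl, dpca = dp))
  writeLines(tables, file.path(out_dir, "tables.md"))
  files <- c(files, "tables.md")

  manifest <- list(
    package = "pepscape",
    version = as.character(utils::packageVersion("pepscape")),
    config = unclass(config),
    input = if (is.null(input)) "synthetic" else input,
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log(quiet, "total", t0)
  invisible(list(topology = topo, ensemble = ens, series = gen$series,
                 states = gen$states, timeline = tl, hbonds = hb,
                 aromatic = aromatic, reweight = rw, fes = fes, dpca = dp,
                 manifest = manifest, out_dir = out_dir))
}

#' Render occupancy results as markdown tables
#'
#' Produces the hydrogen-bond and aromatic-interaction tables in the layout
#' used for trajectory reports: donor / acceptor / occupancy%, and pair /
#' occupancy%. Hydrogen-bond rows are already thresholded by
#' [hbond_occupancy()]; aromatic entries under 1% are shown as
#' "negligible".
#'
#' @param results Named list with elements `hbonds`, `aromatic` and
#'   optionally `timeline`, `dpca`.
#' @return Character vector of markdown lines.
#' @export
make_tables <- function(results) {
  out <- character(0)
  hb <- results$hbonds
  out <- c(out, "## Hydrogen bonds", "",
           "| donor | acceptor | occupancy (%) |",
           "|---|---|---|")
  if (!is.null(hb) && nrow(hb) > 0) {
    out <- c(out, sprintf("| %s | %s | %.1f |", hb$donor, hb$acceptor,
                          hb$occupancy))
  }
  out <- c(out, "")
  ar <- results$aromatic
  out <- c(out, "## Aromatic / proline interactions", "",
           "| pair | kind | occupancy (%) |", "|---|---|---|")
  if (!is.null(ar) && nrow(ar) > 0) {
    out <- c(out, sprintf("| %s | %s | %s |", ar$pair, ar$kind, ar$display))
  }
  out <- c(out, "")
  if (!is.null(results$timeline)) {
    hf <- helical_fraction(results$timeline)
    out <- c(out, sprintf("Overall helical fraction (H/G/I): %.1f%%", hf), "")
  }
  if (!is.null(results$dpca)) {
    dp <- results$dpca
    out <- c(out, "## dPCA clusters", "",
             "| cluster | occupancy (%) | representative frame |",
             "|---|---|---|",
             sprintf("| %d | %.1f | %d |",
                     seq_along(dp$occupancies),
                     as.numeric(dp$occupancies), dp$representatives), "")
  }
  out
}
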