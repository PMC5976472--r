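---
title: "Methods: peptide ensemble analysis in pepscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peptide ensemble analysis in pepscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscape)
```

pepscape summarises conformational ensembles of short peptides — frame
series of coordinates, typically from molecular dynamics — into the
standard ensemble observables: secondary-structure timelines, interaction
occupancies, reweighted torsion-space free-energy surfaces and dihedral-PCA
conformational states. This vignette documents the models, conventions and
numerical choices behind each stage, what the synthetic generator does and
does not emulate, and the package's known limitations.

## Torsions and circular statistics

All angles live on `(-180, 180]` degrees. Torsions follow the IUPAC sign
convention used by the mainstream trajectory tools (a right-handed
alpha-helix has phi near -57 deg); `dihedral()` agrees with independent
reference implementations on random geometry, and the tests assert the true
torsion symmetries — order reversal preserves a torsion, mirror reflection
negates it. Averages of angles are always circular means (`circular_mean()`);
arithmetic means are wrong across the +/-180 seam and are never used.

`discretize()` maps an angle to `floor((a + 180)/width)` with left-closed
bins; the closed right edge (+180, and -180 which wraps onto it) is placed
in the last bin so that the bin set tiles `(-180, 180]` exactly. The default
width of 10 deg (36 bins per torsion) balances resolution against empty-bin
noise at the frame counts this package targets (10^3-10^5 frames) and is
configurable everywhere it appears.

## Secondary structure (Kabsch-Sander)

`ss_timeline()` implements the original Kabsch-Sander assignment, the
common ancestor of the DSSP variants used by trajectory tools:

* Hydrogen bonds use the electrostatic model
  `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol with
  acceptance at `E < -0.5`. Amide hydrogens are always rebuilt 1 Angstrom
  from N along the preceding carbonyl C->O direction (the classic
  convention), so assignment depends only on N, CA, C, O and matches tools
  that ignore explicit hydrogens. Prolines never donate; adjacent-residue
  donation onto the preceding carbonyl is excluded; pairs are gated by a
  9 Angstrom CA-CA distance, as in the reference implementation.
* Patterns: two consecutive i->i+4 turns give H (residues i..i+3), i->i+3
  gives G and i->i+5 gives I (only into unassigned stretches), bridge
  patterns give E (ladders) or B (isolated bridges), remaining turn members
  T, CA kinks over 70 deg S, else C. Priority is H > E/B > G > I > T > S.

A seven-structure suite (ideal helix, 3-10 helix, an antiparallel hairpin
with a real E ladder, two random coils, a noisy helix, a mixed-sequence
helix) was assigned with an independent DSSP implementation and those code
strings are frozen in the tests; the package implementation agreed on 100%
of residues at freeze time and the acceptance check requires >= 90%.
Ladder-bulge merging and DSSP 4.x extensions (polyproline-II codes) are not
implemented.

## Hydrogen bonds, contacts, aromatic proxies

`hbond_occupancy()` is geometric: a donor hydrogen on an N/O/S heavy atom
bonds an oxygen acceptor in a frame when the donor-heavy to acceptor
distance is strictly below 3.5 Angstrom and the D-H...A angle deviates from
linearity by strictly less than 35 deg. Both cutoffs are parameters;
occupancy is the percentage of frames; rows under a 5% report threshold are
suppressed (configurable), mirroring how such tables are usually printed.
Donor inventories come from the topology's hydrogen-attachment table —
emitted exactly by the builder, or inferred from geometry (nearest N/O/S
within 1.6 Angstrom in frame 1) when reading a PDB.

Side-chain contacts count a frame when the minimum distance over all
side-chain heavy-atom pairs is strictly below 6 Angstrom. Aromatic
interactions are proxied by distances, as force-field studies do (explicit
pi-electron models are out of scope): C-beta pairs (default cutoff
7 Angstrom) and ring-centroid pairs (default 6 Angstrom; Trp uses all nine
indole atoms, Tyr/Phe the six-ring, His the imidazole, Pro the
N-CA-CB-CG-CD ring). The aromatic cutoffs are deliberately configurable
defaults rather than asserted constants: the literature typically selects
them from prior work rather than printing them.

## Scaled-MD reweighting and free-energy surfaces

Scaling a potential by lambda < 1 flattens barriers; sampled populations
over any discretised coordinate then follow `q ∝ p^lambda`. `reweight()`
inverts this population bias: `p ∝ q^(1/lambda)`, normalised, with
per-frame weights `p(bin)/q(bin)` rescaled to mean 1. This inversion is
exact for the sampler it models (`sample_scaled_bins()`), which is how the
tests close the loop: for random 36-bin distributions and lambda in
{0.5, 0.7}, n = 10^5 samples reweight back to the truth within 0.02
absolute per-bin probability. Applying the inversion twice is *not* the
identity, and a test guards against that misuse. lambda at or below 0.4
triggers a warning in the pipeline configuration (sampling that aggressive
stops being physically meaningful) but does not stop a run.

`fes2d()` converts a weighted 2-D torsion histogram to
`dG = -kB * T * ln(p / p_max)` with `kB = 0.0019872041` kcal/(mol K) and
T = 298 K by default. The occupied minimum is exactly 0 by construction;
empty bins are masked as `NA`, never reported as 0, so downstream renderers
cannot mistake unsampled for favourable. dG *differences* between bins are
anchor-free (independent of p_max), and uniform rescaling of the weights
leaves the surface unchanged; both are property-tested. In the bundled
pipeline the reweighting is performed over the same two torsions that span
the surface (psi of residue i, phi of residue i+1) — binning jointly over
all torsions of a 22-mer would put nearly every frame in its own bin and
degenerate the weights; the torsion selection is exposed through
`reweight_series()` for other choices.

## Dihedral PCA and density peak clustering

`to_metric()` embeds each angle as `(cos a, sin a)`, which identifies +180
with -180 and makes embedding distances wrap-invariant — the reason dPCA
works for disordered peptides where Cartesian PCA struggles. PCA is an
eigendecomposition of the covariance (not correlation) of the centred
embedding; eigenvector signs are fixed by making the largest-magnitude
loading positive, so results are deterministic. By default phi, psi and
chi1 of the analysed residue range enter the analysis; residues without a
chi1 (Gly, Ala) simply contribute no chi1 column.

Clustering is histogram peak-picking on the top k = 2 (or 3) projections:

* grid of 50 bins/axis in 2-D (30 in 3-D) over the data range;
* one boxcar smoothing pass (3^k window) over the counts;
* peaks = face-neighbour local maxima at or above 5% of the global maximum;
* every occupied bin is assigned by steepest-ascent hill climbing through
  face-adjacent neighbours, ties resolved toward the lexicographically
  smallest bin index (determinism over elegance); frames inherit their
  bin's peak, and basins terminating below the peak threshold are
  unassigned (label 0);
* two peaks are merged when the density at the saddle between their basins
  reaches 75% of the lower peak;
* clusters holding under 1% of frames are dissolved into the unassigned
  label.

The smoothing, saddle-merge and minimum-population steps are this package's
design choices, made because raw 50-bin histograms at n = 5 x 10^4 frames
split every well-sampled basin into several Poisson-noise local maxima and
let stray tail bins masquerade as states; with them, three-state torsion
mixtures at noise sigma = 15 deg are recovered with exactly three clusters
and occupancies within a fraction of a percent, and a state centred at phi
~ +/-180 stays one cluster. All five knobs are exposed as arguments of
`density_clusters()`. Representative conformers are the member frames
closest (Euclidean, in projection space) to their cluster's peak-bin
center. Cluster lifetimes and transition kinetics are deliberately out of
scope — occupancies say nothing about dwell times.

## Superposition

`kabsch_superpose()` is the SVD construction with determinant sign
correction, so the returned rotation is always proper (det = +1) even for
near-reflective inputs. It is cross-checked against a multi-start
Nelder-Mead optimiser over Euler angles on toy sets (agreement to 1e-6
Angstrom) and removes exact rigid motions to below 1e-9 Angstrom RMSD.

## The synthetic generator

The builder (`build_peptide()`, `realize_coordinates()`) places backbones
by natural-extension (NeRF) internal coordinates with conventional ideal
bond lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom),
reproducing requested phi/psi to well under 0.5 deg; all omega torsions are
fixed trans (180 deg), including prolines. Side chains come from rotamer
templates: chi1 is exact and selectable per residue (default -60 deg,
gauche-minus), later torsions are fixed template values, and rings close
only approximately — sufficient for centroid, contact and occupancy
analyses, but these are idealised conformers, not energy-minimised ones.
Polar hydrogens (backbone amides, Ser/Thr/Tyr/Cys hydroxyl/thiol, Lys/Arg/
Asn/Gln/His/Trp nitrogens) are emitted explicitly so hydrogen-bond tables
include side-chain donors; nonpolar hydrogens are not modelled. Proline's
ring torsions come from a fixed pucker template and ignore the global chi1
request.

The two-state simulator (`sample_two_state()`) drives a helix/coil Markov
chain over frames with per-residue helix propensities and independent
wrapped-Gaussian noise on every angle. The bundled pipeline configuration
emulates a 22-residue interference peptide: a disordered six-residue
cell-penetrating/nuclear-localisation N-terminus (propensity 0.05), a
helix-prone core (0.85), noise sigma 18 deg, 5000 frames at a nominal
5 ps/frame, lambda = 0.7. These are plausibility choices for a synthetic
stand-in, not fits to any particular system.

What the generator does *not* emulate: real force-field energetics,
solvent, side-chain rotamer dynamics (chi1 is static unless varied
explicitly), correlated backbone fluctuations, proline cis/trans
isomerisation (trans only, by design) and realistic transition kinetics.
Tests passing on synthetic trajectories therefore validate the *analysis
machinery* — extraction, assignment, counting, reweighting, clustering —
not the physics of any simulation; conclusions about a real peptide still
require real trajectories.

## Numerical conventions and degenerate inputs

* Wrapping is idempotent; bin edges are left-closed with the +180 edge
  clamped into the last bin.
* Strict inequalities at every cutoff (3.5 Angstrom, 35 deg, 6 Angstrom):
  a pair exactly at a cutoff does not count, and boundary tests pin this.
* `fes2d()` masks empty bins rather than assigning 0 or infinity.
* Coincident or collinear points in `dihedral()`/`ks_hbond_energy()` are
  errors, not NaNs; very short Kabsch-Sander contacts (< 0.5 Angstrom)
  clamp to -9.9 kcal/mol as in the reference implementation.
* All stochastic functions take an explicit integer seed and are
  reproducible; the pipeline writes byte-identical TSVs for a fixed config
  and seed, and its manifest lists every file it wrote.

## Problem sizes

The test suite and acceptance script run at the sizes the methods are
designed for: reweighting inversion and flat-surface checks at n = 10^5
samples, dPCA recovery at 5 x 10^4 frames, the bundled end-to-end pipeline
at 5000 frames of a 22-mer (a few tens of seconds on one CPU), and
structure-level checks on peptides of 2-16 residues. The crystal-structure
worked examples (an aromatic C-beta pair at 5.87 Angstrom; a tryptophan
chi1 of 61 deg) are reproduced on synthetic constructions built to those
geometries — clearly labelled as such — since no structure files ship with
the package.

## Known limitations

* The builder's rings and proline closure are approximate; do not use its
  output where sub-0.1-Angstrom ring geometry matters.
* Reweighting is population-based only; energetic reweighting requiring
  per-frame potentials is out of scope for coordinate-only input.
* DSSP bulge merging is simplified, so long irregular sheets may show
  E/B boundaries slightly differently from reference DSSP.
* Ring "interactions" are distance proxies; no electronic structure is
  implied.
* Multi-chain systems, insertion codes and alternate locations are not
  supported by the PDB reader; one peptide chain per file.
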