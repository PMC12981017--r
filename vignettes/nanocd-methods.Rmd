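---
title: "Methods: binding statistics, conformational sampling and CD sensing scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding statistics, conformational sampling and CD sensing scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanocd)
```

Ligand-protected gold nanoclusters (AuNCs) are candidate optical
biosensors for small chiral biomolecules: when an analyte adsorbs onto
the ligand shell, the cluster's circular-dichroism (CD) spectrum changes,
and if the two enantiomers of the analyte bind differently, the change is
enantiomer-specific. `nanocd` implements the *post-simulation* analysis
chain for this kind of study: binding statistics from molecular-dynamics
(MD) trajectories, representative-conformation selection, and
Boltzmann-weighted CD difference spectra with sensing scores. It does not
run MD or compute spectra from electronic structure — trajectories and
per-conformation spectra are inputs, read from multi-frame XYZ/PDB plus a
JSON role sidecar and from two-column CSV respectively.

Because raw MD trajectories of real nanocluster–analyte systems are large
and not generally redistributable, the package ships synthetic generators
with known ground truth for every stage. The generators are first-class,
tested code: they define the conditions under which the estimators are
validated.

## Binding statistics

**Contacts and adsorption probability.** For one analyte in one frame,
the number of contacts (NOC) is the number of heavy-atom pairs — analyte
heavy atoms versus nanocluster heavy atoms (gold, sulfur, ligand carbon,
nitrogen, oxygen; hydrogens and solvent excluded) — whose minimum-image
distance is at most the contact cutoff (default 0.6 nm, inclusive). A
frame is *bound* when NOC strictly exceeds the threshold (default 5).
Pooling all frames of all replicas,

$$P = 100 \cdot \frac{N_{\mathrm{NOC} > 5}}{N_\mathrm{total}}\ \%$$

is the adsorption probability; $P = 100$ means continuous adsorption.
The strict inequality and the inclusive distance cutoff are deliberate:
`adsorption_probability()` of a series in which every frame has exactly
NOC = 5 is 0, not 100. Replicas are pooled *before* the final rounding to
one decimal; per-replica values are also reported (`tidy()` on the
summary).

**Multi-analyte (concentration) systems** are summarised two ways: the
per-frame number of bound analytes (an analyte is bound when its backbone
C$_\alpha$ lies within a cutoff of any *inner* gold atom; the customary
range is 1.5–2.5 nm and the default is the midpoint 2.0 nm, because the
appropriate value grows with cluster and analyte size), and the
conversion of a mean bound count $\bar n$ of $n$ analytes to a percent
probability $100\,\bar n / n$, rounded to the nearest integer. Which gold
atoms count as "inner" is a labelling decision of the topology sidecar,
not something the package infers from geometry.

**Diagnostics.** Center-of-mass distances (mass-weighted, minimum-image
on the COM displacement), hydrogen bonds (donor–acceptor distance
≤ 0.35 nm and H–donor–acceptor angle ≤ 30°, the standard geometric
criterion of MD analysis suites; donor–hydrogen bonds must be declared in
the sidecar) and pairwise Coulomb/Lennard-Jones interaction energies.
The energies use a plain distance cutoff (default 1.0 nm), relative
permittivity 1 and the constant $f = 138.935$ kJ mol⁻¹ nm e⁻², with
Lorentz–Berthelot combination rules. They are qualitative diagnostics of
which interaction dominates; no claim of force-field accuracy (no Ewald
summation, no exclusions) is made, which is why they live behind an
explicitly diagnostic interface.

**The ligand-packing model.** For a spherical cluster at constant ligand
surface density the ligand count scales with the gold count to the power
2/3. `ligand_ratio_model()` and `actual_ligand_ratio()` report these
ratios truncated to two decimals (alongside the exact value), following
the truncation convention of the printed values they are compared
against: $(144/102)^{2/3} = 1.2585$ is reported as 1.25.

## Conformational sampling

The representative-structure chain is: rigid-body superposition → PCA →
free-energy landscape → minimum-region frame selection → RMSD clustering.

- **Superposition** (`superpose()`) is a Kabsch least-squares fit of each
  frame onto a reference over a selection (default: nanocluster heavy
  atoms), with a reflection guard and an explicit error on collinear
  selections. Periodic images are not unwrapped; molecules are assumed
  whole, which the readers guarantee for the shipped formats.
- **PCA** (`pca_trajectory()`) is a mean-centred eigendecomposition of
  the Cartesian coordinate covariance (via `prcomp`), by default
  unweighted; a `mass_weighted` flag exists because conventions differ.
  Eigenvalues are variances in nm².
- **The landscape** (`free_energy_landscape()`) bins the (PC1, PC2)
  projections into an $n \times n$ histogram (bounding box padded by 1%)
  and Boltzmann-inverts it: $\Delta G(\text{bin}) = -\ln(h/h_{\max})$ in
  units of $k_BT$, so the densest bin is the zero of free energy and
  unvisited bins are flagged rather than assigned infinities. Energies
  are kept in $k_BT$ internally; the temperature (default 300 K, the
  thermostat setting of the simulations this pipeline is meant for) only
  matters when exporting to kJ/mol.
- **Minimum regions** (`select_minimum_frames()`) are all frames whose
  bin lies within a depth (default 0.5 $k_BT$) of the minimum. The
  default is deliberately conservative: at 0.5 $k_BT$ a 70/30 two-basin
  system ($\Delta G = \ln(7/3) = 0.85\,k_BT$) selects only the dominant
  basin.
- **Clustering** (`rmsd_cluster()`) is gromos-style neighbour counting on
  the pairwise RMSD matrix (cutoffs conventionally 0.6–1.5 Å; default
  1.5 Å): the frame with the most neighbours within the cutoff seeds a
  cluster, the cluster is removed, and the procedure repeats. Ties break
  to the lowest frame index, which makes the output deterministic under
  frame reordering of ties. Each representative inherits the free energy
  $\Delta G_i$ of its landscape bin.

**Bin-count choice.** The histogram bin count trades resolution against
Poisson noise in the peak-bin counts, and the free-energy *difference*
between basin minima inherits that noise as roughly
$\sqrt{1/h_1 + 1/h_2}$ $k_BT$. The package default of 32×32 suits long
production trajectories (hundreds of thousands of frames). The validation
studies on the two-basin toy generator use 5,000 frames and 12×12 bins,
chosen so that the expected peak-bin counts (a few hundred per basin)
keep the Boltzmann-inversion error near 0.1 $k_BT$ — comfortably inside
the 0.2 $k_BT$ recovery check — rather than the ~0.25 $k_BT$ noise a
32×32 grid would produce at that sample size. Because the basin-minimum
difference is an extreme-value statistic (empirically, sd ≈ 0.13 $k_BT$
per 5,000-frame trajectory at this resolution), the reproduction script
averages it over three independent trajectories, the same replica-style
averaging the trajectory analyses use elsewhere.

## Boltzmann-weighted CD sensing

Per-conformation spectra are combined with weights
$w_i \propto e^{-\Delta G_i/k_BT}$ (computed shift-stably; adding a
constant to all $\Delta G_i$ changes nothing). Averaging happens on a
common wavelength grid: the union of sample points inside the
intersection of the spectral ranges, by linear interpolation —
extrapolation outside a spectrum's range is refused rather than guessed.
Which analytes belong in a hybrid spectrum is decided by the inclusion
rule: minimum any-atom distance (hydrogens included) to the nanocluster
strictly below 4.0 Å.

The sensing signal is the difference spectrum
$\Delta(\lambda) = \text{hybrid} - \text{bare}$. Sign regions are
annotated above a noise floor (default 5% of $\max|\Delta|$) to avoid
spurious micro-regions. Two scores summarise a pair of enantiomer
difference spectra over the band of interest (default 300–600 nm, where
ligand-protected gold clusters show their strongest analyte-induced CD
variations):

- *binding detectability*: $\int|\Delta|$ averaged over enantiomers,
  normalised by $\int|\text{bare}|$;
- *enantiodiscrimination*:
  $\int|\Delta_L - \Delta_D| \,/\, (\int|\Delta_L| + \int|\Delta_D|)$,
  which is 0 for identical responses and 1 for opposite or disjoint ones.

The scoring functionals are this package's own construction (the
qualitative Y/N sensing calls they feed are conventionally made by eye);
the Y/N thresholds (`detectability_threshold`, `enantio_threshold`) are
calibrated on the synthetic generator, not taken from any published
table.

## Synthetic generators: what they emulate, and what they do not

**Two-state binding** (`simulate_binding_trajectory()`): each analyte
follows an independent discrete-time bound/unbound chain with per-frame
transition probabilities $1 - e^{-k\,dt}$, so the stationary bound
fraction $k_\mathrm{on}/(k_\mathrm{on}+k_\mathrm{off})$ is analytic. The
chain is sampled at the frame interval rather than event-driven because
the analysis only ever sees frames. Geometry is constructed so the
estimators' classification rules have no grey zone: bound analytes sit
within 0.45 nm of a ligand atom (guaranteeing NOC > 5 for the 6-heavy-atom
analyte), unbound ones at least 1.2 nm clear of the ligand shell and
2.5 nm from the inner gold. A global seed splits into per-analyte
substreams, keeping analytes independent yet reproducible. What this
does *not* emulate: diffusive approach/departure (transitions are
instantaneous), analyte–analyte aggregation, ligand flexibility, water.
Passing recovery tests therefore shows the *estimator* is correct under
known kinetics, not that real binding kinetics are two-state.

**Validation conditions.** The estimator-recovery study uses a 3×3 grid
of $(k_\mathrm{on}, k_\mathrm{off})$ over $\{0.05, 0.1, 0.2\}$ ns⁻¹ at
$dt = 0.1$ ns and 20,000 frames per cell — mean dwell times of 5–20 ns,
the scale of the binding/desorption episodes such simulations actually
show — with 8 analytes per box for the aggregate error measure. Because
consecutive frames are strongly correlated, recovery is judged against
the autocorrelation-corrected standard error of the chain (lag-1
autocorrelation $\rho = e^{-(k_\mathrm{on}+k_\mathrm{off})dt}$, effective
sample size $n(1-\rho)/(1+\rho)$; `bound_fraction_se()`).

**Conformational basins** (`generate_basin_trajectory()`): Gaussian
blobs in configuration space at planted occupancies, basin centres
separated by a planted centre-to-centre RMSD (default study: 3 Å
separation, 0.3 Å per-coordinate thermal width, 70/30 occupancy). This
makes the PCA projection, the landscape gap
($-\ln(\text{occupancy ratio})$) and the expected cluster sizes all
analytic.

**Spectra** (`spectrum_model()` / `generate_spectra()`): sums of
Gaussian bands on a 200–800 nm grid (1 nm step) with an analyte-induced
per-band perturbation (centre shift + amplitude change), scaled by
$1+\varepsilon$ for the D enantiomer, plus independent noise. The RNG
stream depends only on the model seed, so at $\varepsilon = 0$ the L and
D ensembles are bitwise identical — the zero of the enantiodiscrimination
score is exact by construction. Real TDDFT spectra have far richer band
structure; the generator only emulates the *perturbation logic*, which is
all the averaging and scoring chain consumes.

## Numerical choices and degenerate inputs

- Internal units are nm and ns everywhere; Å appears only at interfaces
  where the field convention demands it (XYZ/PDB files, RMSD cutoffs,
  inclusion threshold), converted on the boundary.
- Orthorhombic boxes only; all distances minimum-image.
- Contact cutoff inclusive (≤), bound threshold strict (>), inclusion
  rule strict (<) — each matching its defining rule.
- Reported ratios are truncated (not rounded) to 2 decimals; $P$ is
  rounded to 1 decimal after pooling; mean-bound conversions round to
  integer percent.
- Degenerate inputs fail loudly with classed errors: collinear
  superposition selections, empty groups/series, all-frames-discarded
  equilibration cuts, non-overlapping spectral grids, duplicate
  wavelengths.
- Clustering tie-breaks, the FES zero, and generator substreams are all
  deterministic for fixed seeds; reports embed their full resolved
  configuration.

## Known limitations

- Interaction energies are cutoff-truncated diagnostics, not PME
  energies.
- The hydrogen-bond criterion is fixed geometry (0.35 nm / 30°); no
  donor/acceptor chemistry perception is attempted beyond the declared
  pairs.
- `P` from short trajectories of slow chains is dominated by
  autocorrelation; use `bound_fraction_se()` before reading differences
  as real.
- The Y/N sensing calls are threshold conventions on continuous scores;
  on real spectra the thresholds should be recalibrated against systems
  with known answers.
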