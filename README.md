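# nanocd

Analysis toolkit for chiral biosensing studies of ligand-protected gold
nanoclusters (AuNCs). When a small chiral biomolecule — an amino acid or
a short peptide — adsorbs onto a thiolate-protected gold nanocluster, the
cluster's circular-dichroism (CD) spectrum changes; if the L and D
enantiomers of the analyte bind differently, the change is
enantiomer-specific and the cluster can act as an enantioselective
optical sensor. `nanocd` implements the post-simulation analysis chain
such studies need, from molecular-dynamics (MD) trajectories and
per-conformation CD spectra to sensing calls:

1. **Binding statistics** — per-frame number of contacts (NOC: heavy-atom
   pairs within 0.6 nm between analyte and nanocluster, minimum-image)
   and the adsorption probability
   `P = 100 · N(NOC > 5) / N_total` % pooled over replicas; bound-analyte
   counts in multi-analyte boxes (Cα within a 1.5–2.5 nm cutoff of the
   inner gold); COM-distance, hydrogen-bond and Coulomb/Lennard-Jones
   diagnostics; the spherical ligand-packing model
   `(N/N')^(2/3)`.
2. **Conformational sampling** — Kabsch superposition, PCA over the
   nanocluster heavy atoms, a 2-D free-energy landscape
   `ΔG = −k_B T ln(h/h_max)` on the first two principal components,
   minimum-region frame selection, and gromos-style RMSD clustering
   (cutoffs 0.6–1.5 Å) to representative structures with per-structure
   free energies ΔG_i.
3. **Spectral sensing** — Boltzmann weighting `w_i ∝ exp(−ΔG_i/k_BT)` of
   per-conformation CD spectra, weighted-average and hybrid-minus-bare
   difference spectra with sign-region annotation, the 4.0 Å
   analyte-inclusion rule, and band-integrated (300–600 nm)
   binding-detectability and enantiodiscrimination scores with Y/N
   calls.
4. **Synthetic generators** with known ground truth for every stage:
   two-state adsorption kinetics with an analytic stationary bound
   fraction, planted conformational basins, and Gaussian-band CD
   ensembles with a tunable enantiomer asymmetry.

Everything tabular flows as tibbles (pipe-friendly, with `tidy()` /
`glance()` methods and ggplot2 `autoplot()`s); trajectories are a light
S3 object over a coordinate array with a `tidy()` accessor. Inputs are
plain formats: multi-frame XYZ or multi-model PDB plus a JSON sidecar
labelling atom roles (inner/core gold, sulfur, ligand, analyte, Cα), and
two-column CSV spectra.

MD itself and electronic-structure CD computation are out of scope:
trajectories and spectra are inputs.

## Worked example

```r
library(nanocd)

## --- binding: recover a planted adsorption probability -------------------
sys <- generate_nanocluster(n_gold = 25, n_ligands = 18, seed = 1)
replicas <- lapply(1:3, function(r)
  simulate_binding_trajectory(
    sys, n_analytes = 1,
    params = kinetic_parameters(k_on = 0.2, k_off = 0.1,
                                n_frames = 5000, seed = r),
    replica_id = r))
report <- run_binding(pipeline_config(equilibration_ns = 100), replicas)
report
#> <binding_report> pooled P = 65% over 12000 frames (1 analyte(s))
tidy(report$summary)
#> # A tibble: 3 × 4
#>   replica n_bound_frames n_total_frames P_percent
#>     <int>          <int>          <int>     <dbl>
#> 1       1           2788           4000      69.7
#> 2       2           2462           4000      61.5
#> 3       3           2547           4000      63.7
```

The planted stationary bound fraction is `0.2 / (0.2 + 0.1) = 66.7 %`;
the pooled estimate 65.0 % sits within the autocorrelation-corrected
standard error (`bound_fraction_se(2/3, 12000, 0.2, 0.1, 0.1)` ≈ 3.5 pp).
Per-replica scatter (61.5–69.7 %) is what 500 ns of a chain with ~7 ns
dwell times genuinely looks like.

```r
## --- sampling: representative structures from a two-basin trajectory ----
traj <- generate_basin_trajectory(5000, occupancies = c(0.7, 0.3),
                                  basin_separation = 3, seed = 17)
out <- run_sampling(pipeline_config(equilibration_ns = 0,
                                    pca_window_ns = Inf, fes_bins = 12),
                    traj)
tidy(out$representatives)
#> # A tibble: 1 × 5
#>   cluster center_frame  size mean_rmsd_A delta_g_kT
#>     <dbl>        <int> <int>       <dbl>      <dbl>
#> 1       1            1  2252       0.694          0
```

At the default 0.5 k_BT minimum-region depth only the dominant basin is
selected (the minor basin sits ln(7/3) ≈ 0.85 k_BT higher), so one
representative emerges — the intended behaviour for picking structures
for expensive downstream spectrum calculations. Clustering the full
trajectory instead recovers both basins at their 70/30 occupancies
(`rmsd_cluster(superpose(traj), 1:5000, ...)`).

```r
## --- sensing: enantiomer-specific spectral response ----------------------
model <- spectrum_model(enantiomer_asymmetry = 0.4, noise_sd = 0.005,
                        seed = 5)
dg <- c(0, 0.4, 1.1)   # representative-structure free energies, kT
sensing <- run_sensing(
  pipeline_config(),
  weighted_ensemble(generate_spectra(model, 3, TRUE,  "L"), dg),
  weighted_ensemble(generate_spectra(model, 3, TRUE,  "D"), dg),
  weighted_ensemble(generate_spectra(model, 3, FALSE, "L"), dg))
tidy(sensing)
#> # A tibble: 1 × 4
#>   binding_detectability enantiodiscrimination SB_call SE_call
#>                   <dbl>                 <dbl> <chr>   <chr>
#> 1                 0.152                 0.164 Y       Y
```

A planted enantiomer asymmetry of 0.4 yields a detectable binding
response (15 % of the bare band-integrated intensity) and an
enantiodiscrimination score of 0.16 — both above the configured call
thresholds, hence "Y"/"Y". With `enantiomer_asymmetry = 0` the
enantiodiscrimination score is exactly 0 and the SE call is "N".

`autoplot(out$fes)` and `autoplot(sensing$diff_L)` plot the free-energy
landscape and the annotated difference spectrum.

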