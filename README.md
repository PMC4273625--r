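# freqnet

Band-resolved functional connectivity analysis for ROI time-series panels.

Resting-state hemodynamic signals carry coupling on several time scales at
once. `freqnet` estimates, for narrow frequency bands, the network of
coherently fluctuating brain regions, and asks whether the topologies that
support information *segregation* (communities, modularity) and
*integration* (hubs, rich clubs, global efficiency) differ between bands.
It is written for analysts working with extracted ROI time series (e.g.
87-region parcellations of resting fMRI at TR = 2 s), and ships a synthetic
cohort generator with planted band-specific structure so that every stage
can be validated against ground truth.

## What it computes

- **Coherence spectra** for all ROI pairs by Welch's method:
  `C_xy(f) = |P_xy(f)|^2 / (P_xx(f) P_yy(f))`, averaged within narrow
  50%-overlapping bands (0.01–0.25 Hz, width 0.02 Hz → 23 bands).
- **Intra- vs inter-system coherence curves** over the band ladder, which
  localize connectivity to the very-low-frequency (VLF, 0.01–0.03 Hz) and
  low-frequency (LF, 0.07–0.09 Hz) bands.
- **Sparsity-matched binary networks**: the `floor(S·n(n−1)/2)` strongest
  pairs at sparsity `S`, with a bootstrap significance floor from
  circular-shift surrogates.
- **Group-level networks** via the consistent edge matrix `Ce` (fraction of
  subjects showing each edge) and consensus communities via the consistent
  assignment matrix `Ca` (fraction of subjects co-assigning each pair).
- **Louvain community detection** with restarts; partition similarity by
  normalized mutual information `NMI` with nulls from degree-preserving
  network rewiring.
- **Hubs** (degree and eigenvector centrality both ≥ mean + 1 SD),
  **rich-club curves** `Φ(k) = 2E_k/(N_k(N_k−1))` against 1000
  degree-preserving nulls with upper-1% regime detection, and
  **participation-coefficient roles** (provincial / connector / kinless).
- **Band-wise statistics**: paired two-tailed t-tests of subject-level
  modularity and global efficiency across the 5-threshold × 2-metric grid
  with Benjamini–Yekutieli FDR control.

The packaged 87-ROI table (`load_roi_table()`) carries MNI coordinates,
functional system labels (default mode, fronto-parietal, cingulo-opercular)
and the reference VLF/LF community assignments.

## Worked example

```r
library(freqnet)

roi <- load_roi_table()
nmi(roi$community_vlf, roi$community_lf)        # 0.5868… -> 0.59

cfg    <- generator_config(n_subjects = 12)     # planted 3-community cohort
panels <- generate_cohort(cfg)
bands  <- list(vlf = band(0.01, 0.03), lf = band(0.07, 0.09))

pl <- run_band_pipeline(panels, bands, S = 0.25, n_restarts = 20, seed = 1)
metrics <- subject_metrics(panels, bands, n_restarts = 10, seed = 2)
compare_bands(metrics)$table
```

which prints (group level, VLF band):

```
VLF: 3 communities, Q = 0.584 | group network connected: TRUE
recovery NMI (VLF) = 0.92
     metric sparsity      t        p significant
 efficiency     0.05  1.997 7.12e-02       FALSE
 efficiency     0.10  0.997 3.40e-01       FALSE
 efficiency     0.15  0.646 5.32e-01       FALSE
 efficiency     0.20 -0.989 3.44e-01       FALSE
 efficiency     0.25 -1.522 1.56e-01       FALSE
 modularity     0.05  9.828 8.79e-07        TRUE
 modularity     0.10  9.022 2.05e-06        TRUE
 modularity     0.15  8.545 3.47e-06        TRUE
 modularity     0.20  7.086 2.03e-05        TRUE
 modularity     0.25  4.397 1.07e-03        TRUE
```

Read: the pipeline recovers the planted three communities from the
consensus assignment matrix (NMI 0.92 against ground truth), the group
network is connected at sparsity 0.25, and across subjects the VLF band is
significantly more modular than the LF band at every threshold (positive t,
flagged after BY-FDR) while global efficiency shows no difference — the
planted segregation contrast without an integration contrast.

## The analysis workflow

The numbered scripts under `analysis/` run the full study chain on a
synthetic cohort and write tables under `results/`:

| script | stage | main outputs |
|---|---|---|
| `01_simulate.R` | cohort generation | panels (scratch), `cohort.json` |
| `02_spectra.R` | coherence + system curves | `system_curves.tsv` |
| `03_networks.R` | thresholding, bootstrap floor, `Ce`, `A^g` | `ce_*.tsv`, `ag_*.edges`, `network_build.json` |
| `04_communities.R` | consensus partitions, NMI + nulls | `partition_*.json`, `ca_*.tsv`, `nmi_report.json` |
| `05_hubs_richclub.R` | hubs, roles, rich-club regimes | `hubs_*.json`, `richclub_*.tsv` |
| `06_compare_bands.R` | paired tests + BY-FDR | `band_comparison.tsv/json` |

Run them from the repository root, e.g. `Rscript analysis/04_communities.R`.
The methods vignette (`vignettes/frequency-specific-networks.Rmd`) explains
the model, the estimator settings, the generator design and its limits.

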