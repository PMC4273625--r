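---
title: "Frequency-specific functional connectivity networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-specific functional connectivity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqnet)
```

## The analysis

Resting-state hemodynamic signals fluctuate on several time scales at once,
and the statistical dependence between brain regions is not uniform across
those scales. This package implements a band-resolved connectivity analysis
for panels of ROI time series: it asks, for each narrow frequency band,
what the network of coherent region pairs looks like, and whether the
topologies that support *segregation* (communities, modularity) and
*integration* (hubs, rich clubs, global efficiency) differ between bands.

The chain of computations is:

1. **Coherence spectra.** For every pair of ROI signals $x, y$, the
   magnitude-squared coherence
   $C_{xy}(\lambda) = |P_{xy}(\lambda)|^2 / (P_{xx}(\lambda) P_{yy}(\lambda))$
   is estimated on a frequency grid, where $P_{xy}$ is the cross-spectrum
   and $P_{xx}, P_{yy}$ are the auto-spectra.
2. **Band averaging.** The frequency axis from 0.01 to 0.25 Hz is divided
   into 23 narrow bands of width 0.02 Hz with 50% overlap, and coherence is
   averaged within each band, giving one ROI × ROI coherence matrix per
   band. Averaging coherence further within pairs of ROIs of the same
   functional system (intra-system) and of different systems (inter-system)
   produces two spectra whose peaks identify the bands that carry
   functional connectivity — with the packaged parcellation these are
   0.01–0.03 Hz (VLF) and 0.07–0.09 Hz (LF).
3. **Network construction.** Each band-averaged matrix is thresholded at a
   target *sparsity* $S$ (fraction of realized edges), keeping the
   $\lfloor S\,n(n-1)/2 \rfloor$ strongest pairs. A bootstrap null —
   band-averaged coherence of surrogate pairs built by circular time
   shifts — supplies a significance floor: a sparsity is admissible only if
   the weakest retained coherence exceeds the null's 95% point for every
   subject.
4. **Group level.** Individual binary networks are averaged into the
   consistent edge matrix $Ce$; thresholding $Ce$ gives the group network
   $A^g$, whose connectedness is reported. Individual community
   partitions (Louvain) are averaged as co-assignment indicators into the
   consistent assignment matrix $Ca$, and the group partition is detected
   on $Ca$.
5. **Comparison.** Partitions are compared with normalized mutual
   information (natural logarithms),
   $$NMI = \frac{-2 \sum_{ij} N_{ij}\,
   \log\!\big(N_{ij} N / N_i N_j\big)}{\sum_i N_i \log(N_i/N) +
   \sum_j N_j \log(N_j/N)},$$
   with permutation nulls from degree-preserving network rewiring. Hubs are
   nodes whose degree (in $A^g$) and eigenvector centrality (in the
   unthresholded $Ce$) both exceed the nodal mean by one standard
   deviation. Rich-club structure is quantified by the $k$-density
   $\Phi(k) = 2E_k / (N_k(N_k-1))$ over nodes of degree $> k$, compared
   per $k$ against the upper 1% of 1000 degree-preserving rewirings; the
   participation coefficient $P_i = 1 - \sum_s (\kappa_{is}/k_i)^2$
   classifies hubs as provincial ($P \le 0.30$), connector
   ($0.30 < P \le 0.75$) or kinless ($P > 0.75$). Subject-level modularity
   and global efficiency are compared between bands with paired two-tailed
   t-tests across the 2-metric × 5-threshold grid under
   Benjamini–Yekutieli FDR control (10 comparisons).

The numbered scripts under `analysis/` run these stages in order on a
synthetic cohort and write their tables under `results/`; every computation
they perform lives in the package's exported functions.

## Spectral estimation choices

The coherence estimator is Welch's method: overlapping segments,
per-segment linear detrend, Hann taper, cross- and auto-spectra averaged
across segments before forming the ratio. Defaults (all overridable via
`spectral_settings()`):

* **Segment length 128 samples.** At the default sampling interval of 2 s
  this gives a frequency resolution of $1/(128 \cdot 2) \approx 0.0039$ Hz,
  about 5 grid points per 0.02 Hz band, while still fitting 8 half-
  overlapping segments into a 610-sample panel. Averaging over segments is
  what keeps coherence estimates below 1 for unrelated signals; with $K$
  effective segments the no-coupling bias is roughly $1/K$ (about 0.13
  under the defaults — measured by simulation in the test suite).
* **50% segment overlap, Hann taper.** Standard variance/leakage trade-off.
* **Per-segment linear detrend.** Suppresses drift leakage into the lowest
  band; the DC bin is dropped from the grid for the same reason.
* **Band membership is half-open** $[lo, hi)$, with the final band of a
  ladder also including its upper edge — each grid point contributes to a
  band exactly once per 50%-overlap step while the range endpoint is kept.

The grid-point count per band, not the panel length alone, limits how
narrow a band can be: the synthetic-data generator refuses configurations
whose narrowest band holds fewer than 2 spectral bins under the default
settings.

## Network-construction choices

* **Sparsity → edge count uses floor**, so the realized density never
  exceeds the requested one, and the count is exact by construction.
* **Ties at the cutoff** are broken by ascending $(i, j)$ index pairs.
  This makes thresholding deterministic and monotone in $S$ (the edge set
  at a smaller $S$ is a subset of the edge set at a larger one), which the
  tests assert.
* **Surrogates for the coherence null** default to circular time shifts of
  one signal by at least one Welch segment: the surrogate keeps the
  signal's autocorrelation (hence the estimator's per-pair bias) but
  destroys its alignment with the partner. Phase randomization is
  available as an alternative. Nulls can be evaluated per pair or pooled
  over a sample of pairs for speed; the per-pair form is the reference.
* **Connectedness of $A^g$ is reported, not enforced.** Pipeline-level
  selection keeps the smallest grid sparsity at which all band networks
  are connected.

## Partitioning and statistics choices

* **Louvain with restarts.** The Louvain heuristic runs under `n_restarts`
  distinct random node orders (default 100) and the highest-modularity
  partition wins; results are deterministic given the seed. On graphs of
  5–8 nodes the test suite checks the returned modularity against
  exhaustive enumeration of all set partitions.
* **Modularity convention.** $Q = \sum_u [e_{uu} - (\sum_v e_{uv})^2]$
  with $e_{uv}$ the fraction of edges joining communities $u$ and $v$,
  each undirected edge counted once, so $\sum_v e_{uv}$ is community
  $u$'s degree share. This is the standard Newman definition and matches
  igraph's, which serves as an independent cross-check in the tests.
* **NMI degenerate cases.** Two single-community partitions give 1 (the
  identity limit); exactly one single-community partition gives 0 (no
  information). The natural logarithm is used throughout; the base cancels
  in the ratio.
* **Permutation p-values use the add-one estimator**
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{null})$, which never
  reports 0. When partition similarity is tested against an external
  reference partition (for which no generating network exists), two null
  families are built — degree-preserving rewirings of the observed network
  and density-matched random graphs — and the conservative (larger)
  p-value is reported, with both distributions returned.
* **Rich-club regime.** "Consistently within the upper 1%" is read per
  $k$: the regime is the maximal contiguous $k$-range whose observed
  $\Phi(k)$ exceeds the per-$k$ empirical $1-\alpha$ order statistic of
  the null; if several ranges qualify, the highest-$k$ range is the
  regime. $N_k$ counts nodes with degree *strictly* greater than $k$.
* **Degenerate hub rule.** If a nodal metric has zero spread (a regular
  graph's degrees), no node is one standard deviation above the mean and
  that criterion admits no hubs; population (divide-by-$n$) SDs are used.
* **Paired t-tests** treat the two bands as repeated measures on the same
  subjects. Cells with zero difference variance are flagged degenerate and
  reported at $p = 1$ rather than erroring, since metric grids routinely
  contain identical cells.
* **Efficiency convention.** Unreachable pairs contribute $1/d = 0$, so
  per-subject networks below the connectedness threshold still yield a
  defined global efficiency.

## The synthetic cohort generator

No public recordings accompany the analysis, so validation rests on a
generator whose cohorts carry known structure. Per frequency band, each
community owns one independent band-limited latent process (zero-phase
forward–backward Butterworth filtering of white noise, unit variance). ROI
$i$ of community $c$ receives
$$x_i = \textstyle\sum_b g_{s,b}\, \alpha_{b,c}\, w_i\, L_{b,c}
  \; + \; [\text{hub}]\; g_{s,b}\, \beta_b\, w_i\, L_{b,\mathrm{target}(i)}
  \; + \; \varepsilon_i,$$
with $\varepsilon_i$ white noise of unit SD. The defaults emulate the
study conditions the package targets: 87 ROIs, 28 subjects, 610 time
points at $dt = 2$ s, and elevated coherence in the two signature bands.

Design elements, and why they are there:

* **Per-ROI coupling weights** $w_i \sim U(0.7, 1.3)$ spread each class of
  ROI pair over a broad coherence range, as in real data where regions
  differ in signal-to-noise. Without them, all intra-community pairs sit
  at nearly the same coherence, and which pairs survive a sparsity cutoff
  is decided by estimation noise alone.
* **Per-subject, per-band gains** $g_{s,b}$ (log-normal, SD 0.2) give
  subjects individual band engagement, so across-subject variances of
  paired metric differences are realistic rather than degenerate.
* **Connector hubs bridge one target community each** (round-robin over
  community pairs, amplitude $\beta_b < \alpha$). An earlier design in
  which every hub mixed *all* other communities' latents made the hubs
  mutually coherent — community detection then carved the hub set out as
  its own module, which is an artifact, not connector behavior. With
  single-target bridges, hubs keep their community membership, their edges
  divide between home and target community, and their participation
  coefficients exceed those of degree-matched non-hubs.
* **The low-frequency band engages communities unevenly**
  ($\alpha_{LF} = 0.60/0.42/0.32$ against a uniform
  $\alpha_{VLF} = 0.55$; mean coupling still lower in LF). A uniformly
  weaker LF coupling turns out not to weaken segregation at the working
  sparsity range — nearly all retained edges are intra-community in both
  bands, and modularity differences vanish into fragmentation noise.
  Uneven engagement concentrates the LF edge budget on the strongly
  coupled community, which lowers modularity robustly at every threshold
  while leaving global efficiency nearly unchanged — the qualitative
  pattern the analysis is designed to detect.

What the generator does **not** emulate: hemodynamic response convolution,
scanner noise, non-stationary (state-dependent) dynamics, anti-correlations,
and degree-elevated hub nodes. The last point matters for interpretation:
planted hubs are *connectors* (high participation), not high-degree nodes,
so the mean+1SD hub detector typically reports no hubs on synthetic
cohorts — hub detection and the hub/rich-club cross-check are validated on
constructed graphs (stars, regular graphs, planted dense cores) instead.
Passing tests on these cohorts therefore show that the pipeline recovers
planted band-specific community structure and calibrated null behavior;
they do not certify performance on the full richness of real recordings.

## Problem sizes in the tests and scripts

The test suite validates the full pipeline on cohorts of 12 subjects at
the full panel geometry (87 ROIs × 610 samples), with permutation null
sizes of 100–1000 and Monte-Carlo oracles of 150–10000 replicates,
chosen so each property retains clear resolution at its tolerance. The
analysis scripts use 16 subjects and 1000-replicate nulls. All null sizes
are arguments; study-scale defaults (10000 for partition nulls, 1000 for
rich-club nulls) are the package defaults.

One numerical caveat found while validating: on Erdős–Rényi graphs the
normalized rich-club curve is centered on 1, but for $k$ where only
$N_k \approx 10$ nodes survive, $\Phi(k)$ itself is an average of ~45
Bernoulli edges and fluctuates with a relative SD near 0.25 — a per-$k$
band of ±0.1 cannot hold there for any estimator. The tests therefore
assert the tight envelope where $N_k \ge 40$ and calibration of the
curve's mean elsewhere.

## Worked example

```{r example, eval = FALSE}
library(freqnet)

cfg <- generator_config(n_subjects = 12)
panels <- generate_cohort(cfg)
bands <- list(vlf = band(0.01, 0.03), lf = band(0.07, 0.09))

pl <- run_band_pipeline(panels, bands, S = 0.25, seed = 1)
nmi(pl$vlf$group_partition, planted_truth(cfg)$partition$vlf)

metrics <- subject_metrics(panels, bands, seed = 1)
compare_bands(metrics)$table
```

## Known limitations

* Coherence is a linear, stationary coupling measure; time-varying
  connectivity is out of scope.
* The sparsity floor depends on the chosen surrogate family; circular
  shifts and phase randomization can disagree for strongly non-Gaussian
  signals.
* Weighted-network variants (weighted rich club, weighted modularity on
  coherence values) are not implemented; all graph analyses are on binary
  sparsity-matched networks, with the exception of eigenvector centrality,
  which is computed on the weighted consistent edge matrix by design.
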