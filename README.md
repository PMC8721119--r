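# allopath

Dynamical network analysis of allosteric pathways in protein trajectories.

Voltage-gated potassium channels such as Kv1.2 inactivate through a slow
rearrangement of the selectivity filter (SF), and the conformational signal
that triggers it originates far away — at the voltage-sensor domain (VSD) or
at the inner pore gate on helix S6.  `allopath` is an R package for tracing
such allosteric communication routes through the correlated equilibrium
fluctuations of a molecular-dynamics trajectory.  It is aimed at structural
bioinformaticians who have an equilibrium trajectory of an oligomeric protein
and want to know *which residues carry the coupling* between two sites.

## The method

The protein becomes a weighted residue graph:

* **Correlation.** After iterative Cα-mean superposition, each residue pair
  gets the normalized covariance of its Cα displacements,
  `Corr_ij = ⟨δr_i · δr_j⟩ / sqrt(⟨|δr_i|²⟩ ⟨|δr_j|²⟩) ∈ [−1, 1]`.
* **Edges.** Residue pairs whose side-chain heavy atoms come closer than
  5.0 Å in at least 75% of frames (persistent contacts) are joined with
  weight `d_ij = −ln |Corr_ij|` — zero only for perfect correlation.
* **Pathways.** Source and sink regions are 6 Å spheres around anchor
  residues held for ≥ 75% of frames.  Dijkstra's algorithm finds the
  minimum-weight path per subunit for two families — VSD→SF across the
  domain-swap interface to the *neighboring* subunit, and PD→SF within a
  subunit — and each family is summarised by its four-subunit mean length.
  Because the metric is logarithmic, a length difference of 2 between two
  runs means roughly an order of magnitude of correlation change; variants
  are flagged `hindered` (Δ ≥ 2) or `enhanced` (Δ ≤ −0.3) accordingly.
* **Hubs.** Per-residue source/sink-restricted betweenness (banded
  low/medium/high) and a centrality index — the fraction of near-optimal
  paths through the residue — identify the residues that act as relays.

A bead–spring synthetic generator with four-fold subunit symmetry and
analytically known correlations (Gaussian-network model: covariance ∝ the
Kirchhoff pseudo-inverse) makes every stage of the pipeline testable without
any external data; see the methods vignette
(`vignettes/allosteric-network-analysis.Rmd`).

## Worked example

Build the toy tetramer, plant a high-correlation sensor pathway, sample a
20 000-frame Gaussian trajectory with random rigid-body motion, and run the
full analysis:

```r
library(allopath)

topo   <- plant_pathway(build_toy_tetramer(), boost = 8)
traj   <- sample_frames(topo, n_frames = 20000, seed = 1, rigid_motion = TRUE)
cfg    <- toy_analysis_config(topo, label = "WT")
bundle <- run_pipeline(traj, cfg)
#> [input] 20000 frames, 48 residues
#> [superpose] iterative C-alpha mean fit
#> [contacts] 48 persistent contacts
#> [correlation] 48 x 48 matrix
#> [network] 48 edges
#> [regions] 8 source/sink region pairs
#> [paths] PD-SF mean length 4.279; VSD-SF mean length 1.120
#> [centrality] betweenness over 8 region pairs; CI per family

bundle
#> <analysis_bundle> 'WT'
#>   48 residues, 48 edges
#>   PD-SF mean path length: 4.2786
#>   VSD-SF mean path length: 1.1197

bundle$paths[["VSD-SF/A"]]
#> <path_result> VSD-SF, subunit A, length 1.1234: A:2 - A:3 - B:6
```

The recovered sensor pathway runs up subunit A's S4 segment and crosses the
swap interface onto subunit B's S5 top bead — exactly the planted chain
(`toy_expected_vsd_path(topo, "A")`), and its mean length ≈ 1.12 matches the
analytic (noise-free) value from `run_pipeline(topo, cfg)`.  The hub table
shows the planted-chain residues with centrality index 1 and high
betweenness:

```r
dplyr::filter(centrality_table(bundle), ci > 0)
#> # A tibble: 8 × 5
#>   residue betweenness    ci band  zero
#>     <int>       <dbl> <dbl> <chr> <lgl>
#> 1       1           0   0.5 low   TRUE
#> 2       2          20   1   high  FALSE
#> 3       3          40   1   high  FALSE
#> 4       6          32   1   high  FALSE
#> 5       7          48   0.5 high  FALSE
#> 6       9          32   1   high  FALSE
#> 7      10          40   1   high  FALSE
#> 8      11          20   1   high  FALSE
```

Weakening the planted springs (emulating a coupling-degrading mutation) and
comparing runs reproduces the wild-type-versus-variant report:

```r
weak  <- plant_pathway(topo, boost = 3)
wtraj <- sample_frames(weak, 20000, seed = 1, rigid_motion = TRUE)
compare_runs(bundle, run_pipeline(wtraj, toy_analysis_config(weak, label = "weakened"),
                                  quiet = TRUE))
#> # A tibble: 2 × 7
#>   label    family reference_length variant_length  delta ratio flag
#>   <chr>    <chr>             <dbl>          <dbl>  <dbl> <dbl> <chr>
#> 1 weakened PD-SF              4.28           3.97 -0.308 0.735 enhanced
#> 2 weakened VSD-SF             1.12           1.80  0.683 1.98  comparable
```

The sensor-family length grows (the route carries an ≈ 2× weaker correlation
product), while the pore family — whose springs were not weakened — shifts
only through the global redistribution of stiffness.

Real trajectories enter through `read_trajectory()` (multi-model PDB, or DCD
plus a PDB topology), followed by the same
`superpose() |> contact_map() / correlation_matrix() |> build_network()`
chain, or in one call via `run_pipeline(traj, analysis_config(...))`.  Every
result type has `tidy()`/`glance()`/`autoplot()` methods, and
`write_bundle()` exports TSV/JSON/GraphML/MatrixMarket files plus the
resolved YAML config that suffices to rerun the analysis.

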