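---
title: "Dynamical network analysis of allosteric pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical network analysis of allosteric pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Ion channels such as Kv1.2 are allosteric machines: conformational signals
generated at the voltage-sensor domain (VSD, helices S1–S4) or at the inner
pore gate (bottom of S6) propagate to the selectivity filter (SF), whose
constriction underlies slow C-type inactivation.  `allopath` reconstructs
these routes of motion propagation from an *equilibrium* trajectory of the
open state, on the premise that functional coupling shows up as correlated
fluctuations long before a full conformational transition is observed.

The protein is reduced to a weighted graph:

1. **Nodes** are residues, positioned at their Cα atoms.
2. **Correlations.** After superposing all frames on an iteratively refined
   Cα mean structure, the normalized covariance of the Cα displacement
   vectors is computed for every residue pair:
   $\mathrm{Corr}_{ij} =
   \langle \delta \vec r_i \cdot \delta \vec r_j\rangle /
   \sqrt{\langle|\delta \vec r_i|^2\rangle\langle|\delta \vec r_j|^2\rangle}
   \in [-1, 1]$, with $\delta \vec r = \vec r - \langle \vec r\rangle$ the
   deviation from the time mean.
3. **Edges** join residue pairs that are *persistent contacts*: a pair of
   side-chain heavy atoms closer than 5.0 Å in at least 75% of the frames
   (glycine is represented by its Cα).  Each edge carries the weight
   $d_{ij} = -\ln |\mathrm{Corr}_{ij}|$, which is zero only for perfect
   correlation and grows without bound as the motions decouple.
4. **Regions.** Source and sink regions are spheres of radius 6 Å centred on
   anchor residues (on S4 for the sensor pathway, on S6 for the pore pathway,
   on the SF for the sink); a residue is a member if its Cα stays inside the
   sphere in at least 75% of the frames.  Because the channel is
   domain-swapped, the sensor pathway of one subunit ends at the SF of the
   *neighboring* subunit, while the pore pathway stays within a subunit.
5. **Paths.**  The minimum-total-weight path over all source-member ×
   sink-member pairs is found with Dijkstra's algorithm, one path per subunit
   and family, and families are summarised by the arithmetic mean over the
   four subunits.  Because the metric is logarithmic, a *difference* of two
   units of path length between two runs corresponds to roughly one order of
   magnitude in the product of correlations along the route.
6. **Hubs.** Residue importance is measured two ways: *restricted
   betweenness* (the Brandes-style sum over source/sink member pairs of the
   fraction of shortest paths through a residue) and a *centrality index*,
   the fraction of near-optimal paths (within a slack of 1.0 of the optimum,
   enumerated with Yen's algorithm capped at 200 paths) that contain the
   residue.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `contact_cutoff` | 5.0 | Å | side-chain heavy-atom distance defining a contact (strict `<`) |
| `contact_occupancy` | 0.75 | fraction | persistence threshold (inclusive `>=`); pairs never in contact are never edges |
| `region_radius` | 6.0 | Å | source/sink sphere radius (strict `<`) |
| `region_occupancy` | 0.75 | fraction | membership persistence (inclusive) |
| `ci_epsilon` | 1.0 | path length | slack above the optimum defining "near-optimal" |
| `ci_k_max` | 200 | count | Yen enumeration cap; hitting it raises a warning |
| `superpose` | TRUE | — | iterative Cα-mean superposition before correlations |

The anchors have **no defaults**: they are a biological choice, not a
numerical one.  For Kv1.2-like channels the natural candidates are the
high-centrality residues of the two pathways (e.g. I304 on S4 and I402 on S6)
with Y377 anchoring the SF sink.

## Design choices on genuinely open points

* **Logarithm base.** Natural log: with it, a path-length difference of two
  units is $e^2 \approx 7.4$, i.e. about one order of magnitude of
  correlation, which matches how length differences between wild type and
  mutants are interpreted.  Base 10 would make two units a factor of 100.
* **Negative correlations.** $-\ln$ of a negative number is undefined, and
  anti-correlated motion transmits information just as correlated motion
  does, so weights use $|\mathrm{Corr}|$; the sign is kept as an edge
  attribute for reporting.
* **Edge gating.** Edges exist exactly for persistent contacts under the
  5.0 Å / 75% side-chain rule.  Sequential neighbours $(i, i\pm1)$ are *not*
  excluded: pathways legitimately run through consecutive helix residues.
* **Zero correlation** would give an infinite weight; such pairs are dropped
  from the edge set with a message rather than carried as infinities.
* **Restricted betweenness.** Betweenness is accumulated only over the
  source/sink member pairs of the analysis, not over all node pairs:
  all-pairs unnormalised betweenness on a protein-sized graph lives on a
  scale of thousands and could not fall into the low (≤ 1) / medium (≤ 4) /
  high bands used for reporting.
* **Centrality index.** The near-optimal-path definition (slack 1.0, cap
  200) is a reconstruction — the index is reported per residue *number*,
  aggregated across the four chains, so that a pathway plus its three
  symmetry mates gives its residues an index near 1.  The per-chain records
  remain available (`centrality_table(bundle, by = "key")`).
* **Comparison flags.** A variant run is flagged `hindered` when its family
  length grows by ≥ 2 (an order of magnitude of correlation) and `enhanced`
  when it shrinks by ≥ 0.3; the latter threshold is a reporting heuristic
  chosen so that a clearly faster-coupling mutant (length drop ≈ 0.35) is
  flagged, and is not derived from a rule of the method.
* **Boundary conventions.** "Closer than" is strict, "at least" is
  inclusive, everywhere.  Region membership uses Cα–Cα distance to the
  anchor Cα, consistent with the Cα-based network.

## Numerical choices

* Correlations are clamped to $[-1, 1]$ (tolerance $10^{-8}$) before taking
  logs; the diagonal is set to exactly 1; a residue with zero positional
  variance is a hard error naming the residue.
* Dijkstra ties are broken toward the lexicographically smallest residue-key
  sequence, making every output deterministic.
* Superposition iterates "fit all frames on the Cα mean, recompute the mean"
  until the mean moves less than `tol = 1e-4` Å (RMSD) or `max_iter = 10`;
  pure rigid-body motion is removed exactly (up to `tol`), and the total Cα
  variance never increases.
* The contact map prunes residue pairs with a per-frame Cα-distance bound
  (`d_CA - r_i - r_j >= cutoff` implies no side-chain contact); the result is
  identical to the exhaustive all-pairs scan, which the tests verify.

## The synthetic generator

`build_toy_tetramer()` constructs a bead–spring model of a domain-swapped
tetramer: four C4-symmetric subunits (chains A–D), each with an S4-like
sensor segment, S5/S6-like pore segments and an SF-like filter segment.  The
geometry is chosen so that (i) consecutive beads and the designed interfaces
(S4→neighbour-S5, S5→SF, SF→S6) sit at 3.5–4.7 Å, well inside the contact
cutoff, (ii) every other inter-segment approach stays above 6.5 Å, well
outside it, and (iii) the 6 Å source sphere around the S4 anchor contains
only sensor beads, so an inter-subunit pathway *must* cross the swap
interface.  An inner S6 ring joins the four pore domains within the spring
cutoff (7 Å) but beyond the contact cutoff, keeping the spring network
connected without adding contact shortcuts.

Displacements follow a Gaussian-network model: the per-axis covariance is the
temperature-scaled pseudo-inverse of the spring (Kirchhoff) matrix, so every
pairwise correlation is known in closed form (`analytic_correlations()`) and
serves as the oracle for the whole estimation pipeline.  Two refinements make
the oracle exact for the analysis actually performed:

* the rigid-body subspace (per-axis span of $\{1, x, y, z\}$) is projected
  out of the covariance, so the sampled frames carry no linearised net
  rotation or translation.  Without this, the soft collective modes of the
  spring network overlap global rotations, the least-squares fit absorbs part
  of them, and estimated correlations are biased away from the analytic
  values by far more than sampling noise;
* the pseudo-inverse is averaged over the cyclic subunit permutations that
  are exact symmetries of the spring network, so four-fold symmetry survives
  floating-point eigensolves and the noise-free pipeline returns four
  *identical* per-subunit path lengths (tested to $10^{-6}$, observed at
  $10^{-16}$).

`plant_pathway(topo, boost)` multiplies the spring constants along the
canonical sensor→interface→filter chain of every subunit, raising its
correlations and making it the dominant communication route; a smaller boost
emulates a mutation that weakens the coupling.  Default boost 8 and
temperature factor 0.04 were chosen once so that bonded-pair relative
fluctuations stay near 0.2 Å — designed contacts then persist in ≈ 99% of
frames and designed separations essentially never close — and so that the
planted sensor-pathway length lands near 1, the scale typical of a strongly
coupled route.  Frames are sampled independently (no autocorrelation): the
correlation estimator is static, so temporal correlation would only rescale
the effective sample size.  Each bead doubles as its own side-chain atom and
is written as a glycine Cα, exercising the glycine-surrogate contact rule
end to end.

What the generator does *not* emulate: anharmonicity, anisotropic per-bead
fluctuations, solvent and membrane coupling, conformational substates, and
autocorrelated dynamics.  Passing the planted-path and convergence tests
therefore validates the estimator and graph machinery, not the biological
realism of any particular trajectory.

## Problem sizes and validation scales

The packaged checks run the generator at 48 beads (4 × 12) with
$10^3$–$10^5$ frames for the correlation-convergence study (max absolute
error stays under $3/\sqrt{n}$ and shrinks by ≈ 2× per 4× frames), and
$2\times10^4$ frames × 10 seeds for planted-pathway recovery through the full
pipeline (superposition on, random rigid motion injected), with a
spring-weakened variant recomputed at the same seeds for a sign test on the
length increase.  Graph algorithms are checked against exhaustive
simple-path enumeration on 200 random graphs of up to 9 nodes.

## Limitations

* Correlation of Cα positions misses side-chain-only and lag-time coupling;
  mutual-information or time-lagged variants are out of scope.
* The contact-gated edge set is one defensible interaction rule; other
  gating choices (heavy-atom all-atom contacts, distance-weighted edges)
  would change path lengths, though typically not hub identities.
* Betweenness and the centrality index are computed from the supplied
  region pairs only; they are not global network centralities.
* Real mutant trajectories differ from the wild type by more than a scaled
  spring constant; the weakened-spring variant probes the *reporting*
  machinery, not mutational biophysics.
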