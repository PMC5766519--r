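---
title: "Classifying nuclear-receptor activation from trajectory correlations"
author: "h12assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying nuclear-receptor activation from trajectory correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The scientific problem

The estrogen receptor alpha ligand-binding domain (ER&alpha; LBD) is a
homodimer whose mobile helix 12 (H12) acts as a conformational switch:
packed against helices H3/H5-H6/H11 it forms the agonist (active) surface
that recruits coactivators; displaced into the H3-H5 groove it marks the
antagonist (inactive) state. Recurrent resistance mutations in the loop
between H11 and H12 (L536Q, Y537S, Y537N, D538G) shift this equilibrium
toward the active state even without hormone, and degrade the response to
endocrine drugs. Given molecular-dynamics trajectories of such systems,
the analysis questions are: *is a given isoform/ligand system in an
agonist-like state*, and *is a bound antagonist actually effective*?

`h12assay` implements the trajectory-side assay that answers both,
together with the supporting analyses (interaction persistence,
conformational clustering, fluctuations, helicity) and a synthetic
trajectory generator that supplies exact ground truth for testing.

## The activation metric

The core quantity is the dynamic cross-correlation matrix (DCCM) over
C&alpha; displacement vectors,

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
{\sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}},
\qquad \Delta r_i = r_i - \langle r_i \rangle,$$

computed after a single joint least-squares superposition of the whole
dimer C&alpha; set onto its iteratively refined mean. The joint fit
matters: correlations *between* monomers are only meaningful in a common
frame of reference, and anti-correlated monomer motion is one of the
assay's readouts.

Two aggregations are built on the DCCM, both using a coefficient
threshold $\tau = 0.6$ (inclusive; entries with $|C_{ij}| < \tau$ are
treated as noise):

* **Region score map.** The LBD sequence 303-552 is partitioned into 14
  regions (H1...H12 plus the H2-H3 coil and the beta hairpin;
  `default_region_scheme()`). The score of a region pair is the sum of
  thresholded coefficients over all residue pairs; for map displays it is
  divided by the number of pairs (`per_pair_mean`), for the activation
  metric it is the raw sum. Both normalizations are exposed because map
  values and activation scores live on different scales by construction.
* **H12 profile and activation score.** For each H12 residue $i$ and
  region $R$: $s_i(R) = \sum_{j\in R} C_{ij}\,[\,|C_{ij}|\ge\tau\,]$,
  raw sums. The per-monomer activation score is the larger of the H12-H3
  and H12-H5 totals. A score of **4** - the value the estrogen-bound wild
  type reaches - is the reference for activation: at or above 4 the
  monomer is classed `high` (agonist-like), in $[2, 4)$ `intermediate`
  (the band occupied by the most constitutively active apo variants),
  below 2 `low`. A bound antagonist is judged *effective* only when both
  monomers stay below 4, since monomers can and do behave differently.

Scores exactly at a boundary classify upward (4.0 is `high`); the
thresholds are inclusive because the underlying rule counts coefficients
"at or beyond" the cutoffs.

## Supporting analyses and their parameters

| quantity | rule | defaults |
|---|---|---|
| H-bond / salt bridge | $d(D,A) \le d_{max}$ and D-H&middot;&middot;&middot;A within $\theta_{max}$ of linear | 3.3 &Aring;, 35&deg; |
| hydrophobic contact | min cross-group heavy-atom distance $\le$ cutoff | 4.5 &Aring; |
| pi-stacking | centroid distance and acute inter-plane angle | 5.0 &Aring;, 30&deg; |
| clustering | GROMOS/Daura greedy neighbour counting at an RMSD cutoff | 2.75 &Aring;, C&alpha; |
| helicity | i&rarr;i+4 backbone H-bond, $d(O,N)\le 3.5$ &Aring;, deviation $\le 40°$ | &alpha;-only |
| analysis window | last fraction of frames, or absolute start time | final 60% |

Notes on the deliberately documented ambiguities:

* The 35&deg; H-bond cutoff is interpreted as the **maximum deviation of
  the D-H&middot;&middot;&middot;A angle from 180&deg;** (angle at the
  hydrogen $\ge 145°$), the acceptance convention of the common
  trajectory tools. `hbond_params(heavy_only = TRUE)` gives a
  distance-only fallback for hydrogen-free topologies, flagged in every
  output row.
* Multi-atom sites (carboxylate O&delta;1/O&delta;2, imidazole
  N&delta;1/N&epsilon;2) are OR-combined into one labelled interaction.
  Salt bridges use the same geometric rule as H-bonds.
* Daura clustering ties (equal neighbour counts) break to the lowest
  frame index, making results deterministic; cluster RMSDs are computed
  per monomer on C&alpha; atoms, matching the per-monomer populations the
  assay reports.
* The pi-stacking cutoffs are pragmatic defaults, exposed as arguments.
* The 14-region aggregation applies to author residue numbering 303-552,
  the only numbering the package exposes, because every mechanistic
  signature (E380, D351, K529, ...) is stated in it.
* The analysis window default is the *final 60% of frames* - the
  length-relative form of "discard the first 200 ns of a 500 ns run".
  `apply_window(traj, "absolute", 200)` reproduces the absolute form.
* `detect_equilibration()` additionally requires the plateau to span at
  least half the trajectory (`min_remaining = 0.5`). Without that floor,
  any monotonically drifting series would "converge" over a short enough
  tail; with it, a flat series converges at the start, a step at 40%
  converges at the step, and a steady drift is reported as not converged
  (`NA`), which is the behaviour a convergence check should have.

## The synthetic-data generator

Real microsecond-scale trajectories of this system are not distributed
with the package; the generator (`synthetic_spec()`,
`generate_trajectory()`) instead *plants* the statistical structure each
analysis stage is supposed to recover, so every stage can be validated
against exact ground truth:

* **Correlations.** Per frame, residue C&alpha; displacements are drawn
  from a zero-mean multivariate normal, independently and identically on
  x, y, z, so the expected DCCM entry of a planted region pair is exactly
  $\rho$. A plant sets every cross-region residue pair to $\rho$; to keep
  the covariance positive semi-definite this uses the single-factor
  (equicorrelated-block) construction, which also sets within-region
  off-diagonals to $|\rho|$ - the closed-form surface the recovery tests
  rely on. Incompatible plant combinations fail the Cholesky check with
  an instruction to reduce $|\rho|$.
* **H-bonds.** With the planted occupancy the acceptor atom is placed
  2.8-3.1 &Aring; from the donor on the D-H axis, otherwise 4.5-6.5
  &Aring; away; the per-frame labels are recorded, so persistence
  recovery can be compared frame-exactly, not only in expectation.
* **Conformer mixtures.** Frames draw a conformer label; conformers are
  the reference plus fixed displacement fields scaled to a prescribed
  C&alpha; RMSD separation (default 8 &Aring;, far above the 2.75
  &Aring; cluster cutoff), with isotropic noise on top.
* **Helicity.** A planted segment adopts an ideal-helix backbone in a
  Bernoulli fraction of frames and an extended template otherwise. The
  templates are built to satisfy (or cleanly violate) the i&rarr;i+4
  rule, and segment frames carry no extra noise so the planted labels
  are exact.
* The reference dimer is an idealised coil (residues 303-552 per chain,
  backbone N/H/C&alpha;/C/O plus named side-chain pseudo-atoms on the
  signature residues, 537-variant aware). Geometry is *metrically valid*
  (no two atoms closer than 1 &Aring;) but intentionally non-physical.

What passing tests on this generator do **not** show: behaviour under
real force-field anharmonicity, solvent effects, ligand chemistry, or
conformational transitions between the planted states. The generator
validates the *estimators*, not the simulations.

One master seed drives all draws in a fixed order, so a spec reproduces
its trajectory bit-identically, down to the bytes of the DCD it writes.

## Numerical choices

* Superposition uses the Kabsch SVD construction with the determinant
  correction (proper rotations only); collinear selections are rejected.
  The $O(n^2)$ pairwise RMSD used by clustering evaluates the
  Kabsch/Theobald identity on the 3&times;3 covariance instead of
  building rotations, and is tested for exact agreement with an
  independent quaternion-method oracle.
* DCCM entries for residues with (numerically) zero positional variance
  become NaN with a warning and are excluded from aggregation rather than
  silently biasing scores; a fully static trajectory is an error.
* Correlation-recovery tests compute the DCCM on the generator's output
  directly: the generator emits coordinates in a common laboratory frame,
  so no superposition is needed there. This is deliberate - a
  least-squares fit of ~500 correlated atoms removes six rigid degrees of
  freedom and measurably shrinks cross-region correlations (~0.01 at
  $\rho = 0.9$), which would be confounded with estimator error at
  3-standard-error tolerance. The end-to-end pipeline always superposes,
  and its classification margins are far wider than that bias.
* Windowed quantities at the stated problem sizes: correlation recovery
  uses 5000 frames (standard error $(1-\rho^2)/\sqrt{n} \approx 0.003$
  at $\rho = 0.9$), occupancy and helicity recovery 1000 frames
  (binomial 99% interval about &plusmn;4%), mixtures 500 frames, the
  end-to-end demonstration 240 frames per system. These sizes put
  sampling error well inside each test's tolerance while keeping the
  whole suite inexpensive.

## Running a study

A study is a declarative YAML config: global parameter overrides plus a
list of systems, each pointing at topology/trajectory files (`dt_ns`
required; DCD carries no trustworthy times) or at an inline synthetic
spec. `run_assay()` validates the schema first, then analyses each
system independently, marking failures without stopping the run, and
`write_report()` emits deterministic CSV tables plus a `summary.txt`
echoing every numeric parameter, because the verdicts hinge on them.

```{r, eval = FALSE}
library(h12assay)
cfg <- list(systems = list(list(
  id = "demo", isoform = "WT", ligand = "EST",
  synthetic = list(seed = 11, n_frames = 240, sigma = 1, isoform = "WT",
                   region_correlations = list(
                     list(region_a = "H12", chain_a = "A",
                          region_b = "H3", chain_b = "A", rho = 0.75),
                     list(region_a = "H12", chain_a = "B",
                          region_b = "H3", chain_b = "B", rho = 0.75))))))
report <- run_assay(cfg, out_dir = "results")
report
```

The default `system_design()` reproduces the full study matrix - 5
isoforms &times; (apo, estrogen, 3 antagonists) = 25 systems, 12.5 &mu;s
cumulative - and `enumerate_design()` is the bookkeeping the report is
checked against.

## Known limitations

* Ligand atoms are not modelled by the generator; ligand-mediated
  signatures (drug-K529 H-bonds and the like) can only be analysed on
  user-supplied trajectories via custom `interaction_spec()`s.
* Interaction energies are out of scope by design; the hydrophobic
  contact proxy is geometric.
* The helicity rule is two-state alpha/non-alpha; 3_10 and pi helices
  and beta structure are not classed.
* Correlation plants and helicity plants on overlapping residues are not
  supported (the helicity override discards the planted noise on those
  backbone atoms).
* PDB insertion codes and alternate locations beyond the first are not
  supported; PSF/GRO/XTC formats are not read.
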