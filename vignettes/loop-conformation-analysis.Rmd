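---
title: "Mapping the conformational repertoire of a protein loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the conformational repertoire of a protein loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Short loops on immunoglobulin-like receptor domains — the CC′-loop of an
immune checkpoint receptor is the motivating case — often carry a
disproportionate share of a binding interface, and ligands can act not by
reshaping the domain but by *selecting* one of several loop conformations
the free receptor already visits.  Molecular dynamics (MD) gives access to
this repertoire, but turning hundreds of thousands of stored frames from
several simulated systems (unbound receptor, natural ligand complex,
antibody complexes, ...) into a statement like "system X spends 80% of its
time in conformation A, which system Y never leaves" requires a chain of
analysis steps.  `loopscape` implements that chain:

1. framework-fitted loop RMSD between every pair of stored frames;
2. greedy RMSD-cutoff (neighbor-count) conformational clustering;
3. extraction of each cluster's central structure;
4. non-metric multidimensional scaling (MDS) of the central structures of
   the largest clusters into 2D for display;
5. meta-cluster delineation by average-linkage grouping of the central
   structures;
6. per-system occupancy / residence-time accounting;
7. a cluster-count convergence diagnostic over growing trajectory
   prefixes.

## Displacement statistics and the fit/compute split

All structural comparisons separate a **fit selection** (the *framework*:
the domain without the loop of interest) from a **compute selection** (the
loop, C-alpha atoms only).  For two frames the loop RMSD is

$$\mathrm{RMSD} = \sqrt{\tfrac{1}{N}\textstyle\sum_{i=1}^{N}
  \lVert x_i - y_i \rVert^2},$$

evaluated over the $N$ loop atoms *after* superposing the two frames by the
least-squares optimal proper rotation over the framework atoms.  Because
the fit minimises framework deviation, the residual loop deviation
measures loop motion relative to the molecular frame, not global tumbling.
Superposition is the Kabsch SVD solution with the determinant correction,
so a reflection is never returned even for near-planar atom sets.  Pairs
are always fitted directly onto each other — never through a common
reference — which keeps the statistic symmetric but means the resulting
dissimilarity need not satisfy the triangle inequality exactly; nothing
downstream assumes it does.

Per-atom flexibility is the root-mean-square fluctuation about the mean
position after fitting every frame to the first frame of its own
trajectory:

$$\mathrm{RMSF}(x) = \sqrt{\tfrac{1}{T}\textstyle\sum_{t=1}^{T}
  \lVert x(t) - \bar{x} \rVert^2}.$$

Replicate sub-simulations are combined per atom as the root of the mean of
squared per-run RMSFs (`aggregate = "rms"`), which preserves the second-
moment reading of the formula; plain averaging is available as
`aggregate = "mean"` since the literature is not unanimous.  No mass
weighting is applied anywhere: the analysis is C-alpha-only.

## Greedy cutoff clustering

Clustering follows the classic neighbor-count procedure: every remaining
structure is a candidate centre; its neighbors are the *other* remaining
structures at distance strictly below the cutoff (default **0.15 nm**);
the candidate with the most neighbors becomes a cluster together with its
neighbors, all of which leave the pool; repeat.  Three numerical rules
make the procedure fully deterministic:

* **strict inequality** — a pair exactly at the cutoff is not a neighbor
  pair;
* **tie-break** — equal neighbor counts are resolved towards the lowest
  global frame index;
* **recounting** — neighbor counts are recomputed on the shrinking pool,
  not frozen from the first pass.

Cluster sizes are consequently non-increasing along the rank order, and
the member count of a cluster, multiplied by the storage stride, is that
cluster's residence time (`occupancy_table()` keeps this arithmetic
exact: 16,500 frames at 10 ps are 165 ns, by construction).

Frames from all systems are concatenated *before* clustering and the
procedure sees no system labels; origins are re-attached afterwards,
which is what makes "mixed" clusters (conformations shared between
systems) meaningful.

## Non-metric MDS and meta-clusters

The central structures of the `top_n = 25` largest clusters are embedded
in 2D by stress majorization: alternate a Guttman transform of the
configuration with an isotonic (pool-adjacent-violators) regression of
the embedded distances on the dissimilarity rank order, and report
Kruskal's stress-1.  Ties use the primary approach (no constraint within
a tie block).  Eight starts are run: the first is the classical
(Torgerson) scaling solution, the rest are seeded random configurations;
the lowest-stress result wins, with sub-`1e-12` stress differences
treated as ties resolved towards the earliest start so that degenerate
inputs (e.g. all distances equal) return the symmetric classical layout.
Iteration stops at a relative stress change below `1e-6` or 500
iterations; a guard keeps the reported stress trace non-increasing.  The
embedding is defined only up to rotation and reflection, so tests and
downstream code compare embedded *distances*, never raw coordinates.

Grouping clusters into meta-clusters is done **on the central-structure
RMSD matrix, not on the 2D map**: the projection is a display proxy and
can place dissimilar points near each other at finite stress.  Average-
linkage agglomeration is cut at `linkage_threshold_nm = 0.30`, i.e. twice
the clustering cutoff — two clusters whose centres are within two cutoff
radii can share boundary structures and are therefore candidates for one
conformational family.  The cut is strict: a merge at exactly the
threshold does not happen.  Meta-clusters are labelled by decreasing
total member count.

## Convergence diagnostic

Sampling adequacy is judged by clustering concatenations of growing
per-system prefixes (default step: a 50 ns checkpoint,
expressed in frames; configurable) and recording the cluster count
$N_c$.  The curve is reported, not decided upon: a `plateau` attribute
flags a completed curve whose last two increments each add less than 5%
of the current count, computed on clusters of at least 3 structures
because late-appearing clusters typically hold one or two frames.  The
flag is advisory — a flat curve can equally mean the sampling is stuck.

## What the synthetic generator does and does not emulate

Because MD trajectories are large and study-specific, the package ships a
generator that reproduces only the *statistical* structure the analysis
consumes: a rigid framework (CA-like points on a helical sweep) with weak
isotropic jitter, and a 7-point loop that hops among template
conformations under a first-order Markov chain, with isotropic Gaussian
noise around the active template.  The templates are hinge rotations of a
semicircular arc (CA spacing 0.38 nm) by 0°, 90° and 180° about the axis
through the loop anchors — an idealisation of an outward-pointing, a
turned, and an overturned pose.  Useful closed forms:

* two same-state frames differ by an expected loop RMSD of
  $\sigma\sqrt{6}$ (about 0.073 nm at the default $\sigma = 0.03$ nm);
* a hinge rotation by $\varphi$ displaces an atom at distance $r$ from
  the axis by $2r\sin(\varphi/2)$, giving template separations of about
  0.68 nm (0°–90°, 90°–180°) and 0.96 nm (0°–180°).

The default 0.15 nm cutoff therefore sits comfortably between the noise
scale and the template separation, and recovery of the planted states is
well-posed — this is a *design property of the generator*, recorded in
`synth_config()` so tests can assert it.

The four-system study scenario (`make_study_scenario()`) plants, at
2,000 frames per system and a 10 ps stride: an unbound system mixing
open/turned at stationary occupancy 0.2/0.8; two systems confined to the
turned pose; and one mostly overturned with brief turned visits
(0.1/0.9).  For the unbound system the chain's rows equal its stationary
law, i.e. switching is fast relative to the storage stride and stored
frames are effectively independent draws; this matches how dwell times
far below the save interval appear in stored data and makes the
occupancy estimator's sampling error at $n = 2000$ the binomial
$\sqrt{0.2 \cdot 0.8 / n} \approx 0.9$ points.  Each system consumes its
own RNG stream derived from the master seed by a fixed offset, so
generating a subset of systems never changes the others.

What the generator deliberately does **not** reproduce: force-field
energetics, solvent, gradual (non-instantaneous) conformational
transitions, correlated framework motion, or any within-state
anisotropy.  Passing tests on this generator therefore demonstrate that
the *analysis chain* recovers planted structure under its own model
assumptions — not that those assumptions hold for any particular real
trajectory.

## Numerical choices and degenerate inputs

* Internal unit is nm everywhere; PDB readers/writers convert from/to Å
  on the boundary.  PDB fixed-width fields bound the round-trip error at
  1e-4 nm per coordinate.
* Superposition requires at least 3 fit atoms and refuses collinear
  configurations (second singular value below 1e-10).
* An all-zero distance matrix embeds as all points at the origin with
  stress 0; fewer than 3 points is an error.
* The all-pairs kernel (RcppArmadillo) evaluates the RMSD cross-term in
  the cancellation-prone form $|A|^2 + |B|^2 - 2\,\mathrm{tr}$; for
  *identical* frames the numerical floor is about 1e-7 nm, far below any
  physical scale in the analysis.
* A missing C-alpha inside a selected residue range is a hard error,
  never a silent skip; loop and framework selections must be disjoint.
* `run_pipeline()` output tables are written with fixed formatting so a
  rerun with the same seed is byte-identical; partial outputs are
  removed if a stage fails.

## Problem sizes

The shipped tests and the acceptance script run the full chain at 2,000
frames per system (8,000 frames, 32 million fitted pairs for the
four-system scenario) — the package's chosen desk scale, at which every
stage completes in minutes on one core while all planted-recovery
margins remain wide.  The dense all-pairs matrix at this scale occupies
about 0.5 GB; for substantially longer trajectories, subsample frames or
cluster per-system before pooling central structures.

## Known limitations

* Only multi-model PDB input is supported; GRO/XTC/DCD require prior
  conversion.
* Meta-cluster labels are structural groupings; naming them ("open",
  "closed", ...) remains a human, literature-facing step.
* The greedy clustering is quadratic in frames (dense matrix); ~10^5
  frames is the practical ceiling on a 8 GB machine.
* The plateau flag is a heuristic on the completed curve; it cannot
  distinguish converged sampling from trapped sampling.
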