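---
title: "De novo main-chain tracing from cryo-EM density maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo main-chain tracing from cryo-EM density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrace)
```

## The problem and the model

At resolutions around 4-5 Å, a cryo-EM map of a protein shows the main chain
as a connected tube of high density, decorated by side-chain bumps whose
mass scales with residue volume, but individual atoms are not resolved.
`catrace` builds C-alpha models directly from such maps, without template
structures or fragment libraries, in four stages:

1. **Local dense points (LDPs).** Grid points above a density threshold
   `phi_thr` seed a weighted mean shift: each point moves to the
   density-weighted mean of nearby grid positions under a Gaussian kernel
   `exp(-1.5 ||p||^2 / sigma^2)` with bandwidth `sigma = 1` Å. Points whose
   normalized kernel density falls below `theta_thr` are discarded, and
   points closer than 0.5 Å are clustered, keeping the densest member as
   representative. Update, filtering and clustering are interleaved and
   iterated; the surviving representatives (the LDPs) sample the density
   ridge of the molecule at roughly 0.5-1.5 Å spacing.

2. **Skeletonization.** LDPs whose seed voxels touch (26-neighborhood by
   default) are candidate neighbors. For every LDP a *local* minimum
   spanning tree is built over the LDPs within `r_local` of it; the union of
   local-MST edges is the admissible set, and the global MST over that set
   (Euclidean edge weights) is the initial skeleton. The two constraints
   keep the skeleton from shortcutting across density gaps.

3. **Tree refinement.** Each edge also carries a density cost
   `w' = w * min(Theta_endpoints)`. A tree is scored by
   `S(T) = sum_n (sum_{e in P_n} w'(e))^2` over its edge-disjoint longest
   paths `P_1, P_2, ...` (up to 100), so concentrating long, dense stretches
   into a single path is rewarded quadratically. A tabu search perturbs the
   tree: delete an edge longer than `d_keep`, reconnect across the cut with
   an admissible edge, subject to the total length staying within 1.01 of
   the initial MST length; 30 candidate moves are sampled per iteration, the
   best is applied if it improves `S`, and applied moves (with their
   reversals) are tabu for up to 100 subsequent moves.

4. **Threading.** The longest path's density profile `V` (per-LDP cluster
   density sums, Gaussian-smoothed with bandwidth `sigma_path`) is aligned
   to the sequence's expected-density profile `A_j = w_ss(ss_j) *
   d_table(aa_j)` by dynamic programming. A match earns the Z-score
   similarity `1 - |Z(V_k) - Z(A_j)|` minus a geometry penalty
   `w_ca * |d_std - d|`, where `d` is the distance along the path since the
   previous assigned residue; unassigned residues cost `gap` each; skipped
   LDPs are free (paths carry 1.6-3.5 times more LDPs than residues). Both
   sequence directions are threaded. Across a sweep of parameter
   combinations this yields a ranked pool of models; per-residue confidence
   is the fraction of other top models that place a C-alpha within 3.5 Å of
   the top model's position.

## Parameters that matter

| knob | meaning | default | rationale |
|---|---|---|---|
| `sigma` | mean-shift bandwidth (Å) | 1.0 | matches the grid spacing of near-atomic maps |
| `phi_thr` | seed density floor (map units) | preset | published absolute values for pdb2mrc-scaled maps; 5% of the map maximum in the fast preset |
| `theta_thr` | normalized density floor | 0-0.3 | prunes noise seeds in experimental maps; 0 on clean simulated maps, where pruning mainly severs the skeleton at thin regions |
| `merge_dist` | LDP cluster radius (Å) | 0.5 | sets the skeleton sampling density |
| `max_iter` | LDP iteration cap | 20 | see below: controls longitudinal collapse along the ridge |
| `r_local` | local-MST sphere (Å) | 5-10 | must exceed the typical LDP gap; 7.5 in the fast preset |
| `d_keep` | minimum deletable edge (Å) | 0.5-1.5 | avoids trivial tabu moves |
| `n_iter` | tabu iterations | 10-5000 | more iterations explore more branch rearrangements |
| `sigma_path` | profile smoothing (Å) | 0.8-1.4 | matches the LDP spacing along the path |
| `d_std` | expected per-residue advance (Å) | 3.0-3.8 | 3.8 for extended chains; smaller on paths that cut helix turns |
| `w_ca` | geometry penalty weight | 0.9 | balances profile match against spacing regularity |
| `gap` | per-residue gap penalty | -1 | strong enough to favor full-sequence tracing |

The iteration cap deserves a note. The mean-shift ridge along a protein
chain is nearly flat longitudinally, so running the interleaved loop to full
convergence makes representatives migrate along the chain into a handful of
density modes, leaving multi-Ångström gaps that disconnect the skeleton. The
cap is therefore a sampling-density control, not a numerical tolerance: the
default (20) reproduces, on the benchmark fixture, both an LDP:heavy-atom
ratio of about 0.25 (typical values for this family of methods are around
0.4) and a path-LDP:residue ratio of 1.6-3.5, and keeps the skeleton
connected. `converge_seeds()`, the standalone operation, retains a proper
convergence loop (`tol` = 0.01 Å on the step length, up to 100 sweeps) and
is what the single-blob mode-finding tests exercise.

Two further readings were fixed after the printed formulas proved
degenerate in practice:

* **Frozen normalization bounds.** Renormalizing the seed densities over
  survivors after each discard round strips the new minimum every sweep and
  collapses the seed set onto the global maximum. The bounds are therefore
  frozen at the first evaluation over all initial seeds; only the final LDP
  set is renormalized for downstream use.
* **Arc-length geometry in threading.** With straight-line distances, two
  path points a full helix turn apart are ~3.6 Å apart in space, so the
  alignment can satisfy the C-alpha spacing term while racing along the
  path, and the register is unconstrained. The default distance `d` is
  measured along the path polyline (`d_metric = "arc"`); the straight-line
  variant remains available and the two coincide on extended chains.
* **Score direction and penalty sign.** `S(T)` is maximized (long dense
  paths are good), and the C-alpha geometry term enters the match move as a
  subtracted penalty; a reward for deviating from the standard spacing
  would be meaningless.

## What the synthetic generator emulates — and what it does not

`make_synthetic_chain()` builds ideal C-alpha geometry (3.8 Å spacing;
helix rise 1.5 Å and twist 100°/residue; near-straight strands), and
`simulate_map()` blurs atoms with an isotropic Gaussian of width
`0.225 * resolution`, the common pdb2mrc-style convention, on a padded
grid. `add_sidechain_atoms()` adds the per-residue heavy-atom budget
(Gly 4 ... Trp 14) in one of two styles:

* `"compact"` (default): all pseudo-atoms within ~1.5 Å of the C-alpha,
  nudged along the local outward normal. Local density then directly
  realizes the per-residue average-density assumption behind the threading
  score, and the helix keeps a hollow core so the density ridge follows the
  C-alpha spiral.
* `"extended"`: backbone atoms along the chain segments and side-chain
  atoms marching outward to ~4 Å. This produces realistic side-chain
  branches in the skeleton — the structure the tabu refinement exists to
  handle — but on helices at 5 Å the volume signal around any path point is
  confounded by the adjacent turns (measured profile-to-sequence
  correlations drop to ~0.1-0.35), so sequence register cannot be recovered
  reliably in this regime. This mirrors the known behavior of
  density-threading methods, whose raw helical C-alpha models often need
  flexible-fitting refinement to recover the correct pitch.

Passing the end-to-end tests on the compact fixture therefore demonstrates
that the machinery — LDP detection, constrained skeletonization, tabu
refinement, directional threading, ranking, consensus — recovers a known
structure when the density-volume signal is present at the modeled
strength. It does not demonstrate register recovery on real side-chain
density of helical proteins at 5 Å, nor performance on experimental noise,
B-factor variation or multi-chain maps.

The canonical benchmark sequence (`GAWFGASGWYSTAGASGTAGASGRWHGSGL`) places
aromatic-rich clusters at unevenly spaced positions (3-4, 9-10, 24-26) on a
small-residue background: the landmarks pin the register, and their uneven
spacing makes the profile asymmetric under reversal, which is what the
direction test exploits. Evenly spaced landmarks would be nearly
palindromic and direction-blind.

## Numerical choices and degenerate inputs

* Kernel sums are truncated at 3 bandwidths (weights below `e^{-13.5}`).
* Cluster representatives break density ties lexicographically by position;
  Kruskal breaks weight ties by endpoint ids; traceback ties prefer the
  match move; the tabu search draws from a seeded, locally scoped RNG — the
  whole pipeline is reproducible bit-for-bit from one integer seed.
* Longest-path extraction breaks weight ties by hop count, then vertex id,
  so zero-cost forests still make progress.
* A disconnected admissible graph is traced on its largest component with a
  warning; empty seed sets and all-discarded seed sets raise errors that
  the sweep driver converts into skipped parameter combinations.
* Negative map values are clamped to zero on load; non-orthogonal cells are
  rejected; MRC axis permutations are normalized to x,y,z on read.
* Z-scores use population standard deviations; zero-variance profiles fall
  back to all-zero Z (the geometry term then drives the alignment).

## Problem sizes in the shipped tests

The test-suite and the acceptance script run desk-scale versions of the
method: a 30-residue helix benchmark (about 21,000 voxels, ~3,800 seeds,
~60 LDPs), oracle comparisons on instances of up to 8 LDPs (exhaustive
spanning-tree enumeration), 12-node trees (all-pairs path enumeration) and
4x7 threading problems (exhaustive monotone alignments), plus a fast sweep
preset (1 condition, 3 trees, 36 models). These sizes were chosen so every
oracle remains exhaustively enumerable and a full run stays interactive;
the same code paths scale to realistic maps by raising the preset values.

## Known limitations

* Single-chain maps only; multi-subunit maps must be segmented first
  (`zone_mask()` offers a distance-based stand-in for interactive tools).
* The final ranking is the threading score; molecular-dynamics-based
  rescoring and full-atom reconstruction are downstream of the exported
  C-alpha models and out of scope.
* The per-amino-acid density table defaults to normalized heavy-atom
  counts; on real maps a calibration of average residue densities from
  simulated maps of the same imaging model would be preferable.
* Helical regions at 5 Å blur toward rods; without external secondary
  structure weights the threading can misjudge the helical pitch, which is
  visible as low consensus confidence in those regions.
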