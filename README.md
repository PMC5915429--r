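# catrace

De novo main-chain tracing and C-alpha model building from near-atomic
(~4–5 Å) cryo-EM density maps, for structural biologists who have a map and
a sequence but no usable template structure.

At these resolutions the main chain appears as a connected tube of high
density whose local thickness scales with residue volume. `catrace` turns
that observation into models in four stages:

1. **Local dense points (LDPs)** — seeds above a density threshold Φ_thr are
   moved by weighted mean shift, `f(y) = Σ k(y−xₙ)Φ(xₙ)xₙ / Σ k(y−xₙ)Φ(xₙ)`
   with Gaussian kernel `k(p) = exp(−1.5‖p‖²/σ²)` (σ = 1 Å), filtered by
   normalized density θ_thr and clustered at 0.5 Å.
2. **Constrained minimum spanning tree** — LDPs are connected minimizing
   total Euclidean length `W(T) = Σ w(e)`, restricted to voxel-adjacent
   pairs and to the union of local MSTs within a radius r_local.
3. **Tabu-search refinement** — trees are rescored by
   `S(T) = Σₙ (Σ_{e∈Pₙ} w′(e))²` over edge-disjoint longest paths, with
   `w′(e) = w(e)·min(Θ_endpoints)`; edge swaps that keep
   `W(T) ≤ 1.01·W(T_MST)` are explored under a tabu list of capacity 100.
4. **Sequence threading** — the longest path's smoothed density profile V is
   aligned to the sequence's expected densities `A_j = W_SSj · D_Aj` by
   dynamic programming with score `1 − |Z(V_k) − Z(A_j)|`, a C-alpha
   spacing penalty `w_Cα·|d_std − d|` and per-residue gap penalties, in
   both chain directions.

A parameter sweep produces a pool of models ranked by threading score, with
per-residue consensus confidence (the fraction of alternative top models
placing a C-alpha within 3.5 Å) and standard metrics: C-alpha RMSD,
coverage and precision at distance cutoffs.

## Worked example

Build the 30-residue synthetic helix benchmark (5 Å map, 1 Å/voxel), run
the fast sweep preset, and evaluate the top-ranked model against the
generating trace:

```r
library(catrace)

fx <- synthetic_helix_fixture(seed = 1)
fx$map
#> density_grid: 19 x 19 x 55 voxels
#>   origin  (A): -9 -9 -5
#>   spacing (A): 1 1 1
#>   density    : min 0  max 9.337

pg <- sweep_preset("fast", map = fx$map)
pg
#> parameter_grid: 1 tree conditions x 3 trees x 12 threadings = 36 models

pool <- run_sweep(fx$map, fx$sequence, pg, seed = 1)
pool
#> model_pool: 36 C-alpha models, threading score 4.40715 (top) to -19.9025

top <- pool$models[[1]]
top
#> threaded_model: 30 residues, 30 assigned, direction forward , score 4.40715

ev <- evaluate_model(top, fx$trace, cutoffs = c(2, 3))
sprintf("C-alpha RMSD: %.2f A, coverage@2A: %.2f, precision@2A: %.2f",
        ev$ca_rmsd, ev$coverage[["2"]], ev$precision[["2"]])
#> "C-alpha RMSD: 0.45 A, coverage@2A: 1.00, precision@2A: 1.00"
```

All 30 residues are assigned in the correct chain direction; the top model
reproduces the generating C-alpha trace to 0.45 Å, and every native
C-alpha has a model C-alpha within 2 Å (coverage 1.00) and vice versa
(precision 1.00). `write_models(pool, "out", native = fx$trace)` writes one
C-alpha PDB per model, a ranked `manifest.tsv` and a `confidence.tsv` whose
consensus fractions also fill the top model's B-factor column.

Real maps enter through `read_mrc()` (MRC2014/CCP4) and `read_sequence()`
(FASTA); `sweep_preset("simulated")` and
`sweep_preset("experimental", contour = ...)` reproduce the full published
parameter grids (26,880 and 80,640 models). A thin command-line wrapper
lives in `inst/cli/catrace.R` (`trace`, `simulate`, `evaluate`).

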