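# topospect

Spectral template matching of topological signals in single-cell expression
data.

Single-cell expression matrices superimpose multiple structured biological
signals: cyclic processes (cell cycle, circadian rhythm), linear
trajectories (differentiation), discrete clusters (cell types), and spatial
organization (tissue zonation). `topospect` detects, reconstructs, enhances
and filters such signals **without low-dimensional embedding**, by matching
the data against the spectrum of a theoretical covariance matrix that
encodes the chosen topology.

For a cycle of `n` cells whose neighbors correlate at `α`, the expected
cell–cell covariance is the circulant matrix with first row
`α^min(j, n−j)`. Its eigenvalues are the discrete cosine transform of that
row, and its eigenvectors are fixed-phase real Fourier modes
`v_i(s) = √(2/n)·cos(2πis/n − π/4)`. A linear chain yields the
Kac–Murdock–Szegő matrix `α^|i−j|` with a closed-form eigenvalue
approximation; cluster, block-circulant and spatial heat-kernel templates
are decomposed numerically. Everything downstream is projection onto that
spectrum:

* **Reconstruction** — find the cell ordering maximizing
  `Σᵢ λᵢ‖(EA)ᵀvᵢ‖²`, relaxed from permutations to the Birkhoff polytope of
  doubly stochastic matrices, solved by projected gradient ascent with
  bi-stochastic projection, greedy rounding, and a deterministic 2-opt
  polish.
* **Gene inference** — score each gene's share of the template spectrum via
  a box-constrained diagonal mask with L1 control (solved exactly; the
  problem separates per gene).
* **Enhancement / filtering** — an elementwise mask `F ∈ [0,1]ⁿˣᵖ`
  maximizing (enhancement, stochastic ascent) or minimizing (filtering,
  convex descent) the same projection, so `A ⊙ F` keeps only — or
  everything but — the matching signal.
* **Evaluation** — circular mean/variance of gene activity along the
  ordering, projection proportion, adjusted Rand index helpers.
* **Simulation** — binary flip-process generators with planted cyclic,
  linear and composite (cycle + clusters) topologies and recorded ground
  truth.

## Worked example

Plant a cyclic signal, recover the ordering, and score genes:

```r
library(topospect)

sim <- simulate_cyclic(p = 500, k = 5, q = 60, seed = 3)   # 96 cells emerge
A   <- scale_unit(sim$matrix, "cells")

alpha <- as.numeric(estimate_alpha(A, "cyclic"))
spec  <- cyclic_template(nrow(A), alpha, drop_top = TRUE)

rec <- reconstruct_order(A, spec, optimizer_config(iterations = 400, seed = 3))
rec
#> <reconstruction> n=96 objective=192.5 (relaxed 190.546)

pos <- integer(nrow(A)); pos[rec$permutation] <- 0:(nrow(A) - 1)
circular_rank_correlation(pos, sim$true_order)
#> [1] 1  (perfect recovery up to circular shift/reflection)

gm <- infer_gene_mask(scale_unit(rec$ordered, "genes"), spec,
                      optimizer_config(gamma = "auto"))
gm
#> <gene_mask> genes=500 gamma=0.001376 retained (score >= 0.5): 229
```

Here `alpha` is estimated at 0.95 (the flip model implies
`exp(−2·5/500) ≈ 0.98`; the search grid tops out at 0.95), the polished
permutation's objective (192.5) even exceeds the relaxed iterate it was
rounded from (190.5), and the recovered ordering matches the planted cycle
exactly. The gene mask retains 229 of 500 genes — the flip
process leaves many genes constant, and constant genes carry no cyclic
information.

The same stages run from the shell via the thin CLI:

```sh
Rscript inst/cli/topospect.R simulate --topology cyclic --genes 500 \
        --flips 5 --steps 60 --seed 3 --output sim
Rscript inst/cli/topospect.R reconstruct --input sim_matrix.csv \
        --template cyclic --seed 3 --output rec/
```

`run_pipeline()` (CLI: `run`) chains preprocessing, alpha estimation,
reconstruction, gene inference and enhancement or filtering, and writes all
artifacts with a config-hash sidecar.

## Package layout

| Path | Contents |
| --- | --- |
| `R/templates.R` | covariance templates and their spectra |
| `R/simulate.R` | flip-process simulators with ground truth |
| `R/preprocess.R` | normalization, HVG selection, scaling, alpha estimation |
| `R/reconstruct.R` | Birkhoff-polytope optimization, projection, rounding |
| `R/masks.R` | gene inference, enhancement, filtering |
| `R/evaluate.R` | circular statistics, projection proportion, ARI |
| `R/io.R`, `R/pipeline.R` | matrix I/O, end-to-end workflow |
| `inst/cli/topospect.R` | command-line front end |
| `vignettes/` | methods vignette (model, algorithms, design choices) |
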