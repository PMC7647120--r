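# scipr — iterative point set registration for scRNA-seq batch alignment

`scipr` aligns single-cell RNA-seq batches by treating cells as points in
gene-expression space and registering one point cloud onto another, the
way iterative closest point (ICP) registers image or lidar scans. It is
for analysts who need a batch correction that (a) operates in the
original gene space, so the corrected values keep their gene semantics,
and (b) is a *fitted, reusable function*, so new cells arriving later can
be aligned with the same map instead of recomputing the integration.

## The method

Each iteration of the fit, with source batch A (cells × genes) and fixed
target batch B:

1. **Match.** Pair cells of the current A with cells of B by one of
   three strategies: classic closest point; a greedy partial assignment
   that scans all edges in ascending distance, matching at least a
   fraction α of source cells (default 0.5) while using no target cell
   more than β times (default 2); or mutual nearest neighbours
   (default, k = 10).
2. **Fit.** On the matched pair set S, learn an affine map
   f(x) = Wᵀx + b minimizing

   L = (1/|S|) Σ_{(i,j)∈S} (1/d) ‖Wᵀ Aᵢ + b − Bⱼ‖²₂

   by full-batch gradient descent on W from the identity, with b
   profiled out in closed form (b = mean(B_S) − mean(A_S)·W). A rigid
   (orthogonal Procrustes) variant exists as a baseline.
3. **Move.** Apply the map to *all* cells of A and repeat (default 5
   iterations, early stop when the mean matched distance stops
   improving).

Because affine maps compose into affine maps, the per-iteration fits
collapse into one composite transform: the model. Mixing quality is
scored with the local inverse Simpson's index (iLISI on batch labels,
higher is better; cLISI on cell-type labels, lower is better), and the
coefficients of the composite map rank genes by how much the correction
had to move them.

## A worked example

The package ships a ground-truth simulator, so the whole pipeline can be
exercised without any download: three cell types, 20 genes, 100 cells
per type per batch, and a hidden translation batch effect of norm 5 with
noise sd 0.5.

```r
library(scipr)

sim   <- simulate_batches(simulation_spec(seed = 7))
model <- scipr_fit(sim$source, sim$target, scipr_config(matching = "mnn"))
model
#> scipr_model: mnn/affine, 5 iteration(s), d = 20
#>  iteration n_pairs mean_distance final_loss
#>          1     468      4.365227  0.2983275
#>          2    1069      2.357353  0.2479883
#>          3    1359      2.220851  0.2422720
#>          4    1427      2.189681  0.2398895
#>          5    1440      2.178895  0.2387341
```

The mean matched-pair distance falls from 4.37 (the batch gap) to 2.18 —
the nearest-neighbour noise floor of the data (≈ σ√(2d)), i.e. the
batches now interleave. Scoring and ground-truth checks:

```r
aligned <- scipr_transform(model, sim$source)
ilisi_clisi(list(sim$source, sim$target))$ilisi$median  # 1        (unmixed)
ilisi_clisi(list(aligned, sim$target))$ilisi$median     # 1.945432 (mixed)
ilisi_clisi(list(aligned, sim$target))$clisi$median     # 1        (types intact)

# the composite offset recovers the simulated translation within 8%
sqrt(sum((model$composite$b - sim$truth$b)^2)) / sqrt(sum(sim$truth$b^2))
#> 0.07616457

head(rank_genes(model), 3)   # genes the correction moved most
#>     gene    score
#> 1 gene17 2.915058
#> 2  gene7 1.705231
#> 3 gene14 1.515341
```

An iLISI median of 1.95 out of a possible 2 means a typical neighbourhood
contains both batches in nearly equal proportion; cLISI staying at 1
means no cell-type mixing was introduced. `scipr_transform()` applies the
same fitted model to cells that never took part in fitting (e.g. a
held-out cell type), and `align_to_reference()` maps several batches onto
one reference with independent pairwise fits.

The same steps are available from a shell via the bundled launcher
(`system.file("exec", "scipr", package = "scipr")`) with subcommands
`simulate`, `fit`, `transform`, `evaluate` and `rank-genes`; every run
writes a `config.json` echo and a `log.txt` next to its outputs.

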