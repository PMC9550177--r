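# kappavelo

Scale-aware RNA velocity estimation from paired unspliced/spliced
single-cell count matrices.

## The problem

RNA velocity adds a temporal dimension to single-cell transcriptomics:
the balance of nascent (unspliced, *u*) and mature (spliced, *s*) mRNA
of a gene indicates whether its expression is rising or falling. Each
gene follows the splicing kinetics

    du/dt = α − βu
    ds/dt = βu − γs = v

with transcription rate α, splicing rate β and degradation rate γ.
Snapshot data only constrain the time-independent *u–s phase portrait*,
and the portrait is invariant to scaling all three rates by a factor κ:
per-gene time scales are unidentifiable from portraits alone. Summing
gene-wise velocity components with wrong relative scales changes the
*direction* of the high-dimensional cell velocity.

This package implements two complementary estimators for analysts of
single-cell spliced/unspliced data:

* **kappa-velo** — fits each gene's portrait (β ≡ 1) by EM, then
  recovers the gene's time scale κ from *cell densities*: for two
  same-phase cells i (earlier) and j, `f(i,j) = log((mu_i − α)/(mu_j −
  α)) = κ·Δt_ij`, and the number of cells ranked between i and j
  proxies Δt. Plotting f against that count gives a point cloud whose
  upper/left boundary slope is κ (steady-state dwell only depresses f);
  a minimal-area parallelogram fit extracts it. Scaled parameters
  `A = κα, B = κβ, Γ = κγ` then assemble the velocity field
  `V = B·M·U − Γ·S` (M upscales the undercounted unspliced reads).
* **eco-velo** — a heuristic that skips parameter fitting: over the
  interval Δt = 1/γ, `s(t + 1/γ) ≈ (β/γ)·u(t)`, so with shared rates a
  cell's future state is found by mutual-nearest-neighbour matching of
  its unspliced vector against other cells' spliced vectors.

Visualisation keeps the high-dimensional vectors honest: exact linear
PCA projection, and a Nyström out-of-sample projection
(`P′(i,j) ∝ exp(−‖x_i − x_j‖²/2σ_i²)`, row-normalised;
`Y_test = P′·Y_train`) that places velocity endpoints as convex
combinations of training coordinates on any existing embedding. The
correlation-kernel projection of earlier tools is included as a
baseline, together with its documented length-collapse defect.

A splicing-kinetics simulator with known rates, times and velocities
makes every stage testable without downloads.

## Worked example

```r
library(kappavelo)

# 50 genes sharing one base-rate triple, each scaled by kappa ~ U[1,15];
# 500 cells along an activation cascade; fit + kappa recovery
ex <- kappa_recovery_experiment(n_genes = 50, n_cells = 500,
                                noise_sd = 0, rng_seed = 11)
ag <- scale_agreement(ex$kappas$kappa_true, ex$kappas$kappa_hat)
round(c(r_squared = ag$r_squared, pearson_r = ag$pearson_r,
        constant = ag$constant), 4)
#> r_squared pearson_r  constant
#>    0.9996    0.9998    0.0053

ev  <- evaluate_velocities(ex$V, ex$V_true)       # kappa-velo
ev0 <- evaluate_velocities(ex$V_unit, ex$V_true)  # unit-kappa baseline
round(c(kvelo = median(ev$cosine, na.rm = TRUE),
        unit  = median(ev0$cosine, na.rm = TRUE)), 4)
#> kvelo  unit
#> 0.9999 0.9441
```

Reading: recovered κ is proportional to the true per-gene time scale
(R² of the through-origin fit 0.9996; the constant ≈ 0.005 is the
arbitrary per-cell time unit of the density proxy), and the
correctly-scaled velocity field points along the true one (median
cosine 0.9999 per cell), while assuming a common time scale for all
genes (the unit-κ baseline) visibly bends the field (0.9441).

The same machinery runs on real MTX/TSV exports:

```r
data <- read_dataset_mtx("path/with/spliced.mtx+unspliced.mtx")
res  <- run_workflow(data, run_config(mode = "kvelo", n_top = 2000))
res$kappas; res$velocity; res$arrows
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/kappavelo.R` (subcommands `simulate`, `run`).

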