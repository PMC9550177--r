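---
title: "Scale-aware RNA velocity: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-aware RNA velocity: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kappavelo)
```

## The problem

RNA velocity infers the direction and speed of transcriptional change of
single cells from the balance of nascent (unspliced, $u$) and mature
(spliced, $s$) mRNA. Each gene follows the two-stage kinetics

$$\frac{du}{dt} = \alpha - \beta u, \qquad
  \frac{ds}{dt} = \beta u - \gamma s = v,$$

with transcription rate $\alpha$, splicing rate $\beta$ and degradation
rate $\gamma$; transcription switches off ($\alpha = 0$) during
downregulation. Snapshot data only constrain the *time-independent*
relation between $u$ and $s$ (the phase portrait), and that portrait is
invariant under scaling all three rates by a factor $\kappa$: if
$(\alpha, \beta, \gamma)$ explains a gene's portrait, so does
$(\kappa\alpha, \kappa\beta, \kappa\gamma)$ for any $\kappa > 0$.
Gene-wise velocity components therefore carry unknown relative scales,
and summing them into a high-dimensional cell velocity without fixing
those scales distorts the direction of the resulting vector. This
package implements two estimation strategies around that problem — a
detailed one (kappa-velo) that recovers per-gene time scales from cell
densities, and a heuristic one (eco-velo) that avoids gene-wise
parameters entirely — plus projection machinery that visualises
high-dimensional velocities faithfully.

## The kappa-velo model

### Phase-portrait fitting

For each gene we fix $\beta = 1$ and fit the closed-form portrait

$$s(u) = \Big(s_0 - \tfrac{\alpha}{\gamma}
  + \tfrac{\alpha - m u_0}{\gamma - 1}\Big)
  \Big(\tfrac{m u - \alpha}{m u_0 - \alpha}\Big)^{\gamma}
  + \frac{m u - \alpha}{\gamma - 1} + \frac{\alpha}{\gamma},$$

with an upregulation branch from $(0, 0)$ and a downregulation branch
starting at the switch point. The factor $m$ upscales the measured
unspliced counts, which read-assignment pipelines systematically
undercount; it multiplies the same gene's counts identically in every
cell and is therefore not a per-cell normalisation. The removable
singularities $\gamma \to 1$ (portrait) and $\beta \to \gamma$ (time
solutions) are evaluated by their analytic limits whenever the
denominator is below $10^{-8}$.

`fit_gene_em()` estimates $(\alpha, \gamma, u_{switch}, m)$ by an
expectation–maximisation scheme: the E-step projects every cell onto
the nearest point of either branch (polyline projection onto curve
segments, so the discretisation error of the default 40 points per
branch is second order), the M-step improves the parameters by
Nelder–Mead on the summed squared distances. Distances are measured
after standardising $u$ and $s$ to unit variance so neither axis
dominates; a useful corollary is that the fit, its likelihood, and the
phase assignment are invariant under gene-wide rescaling of the data.
Initialisation is data driven: $m_0 = \mathrm{sd}(s)/\mathrm{sd}(u)$
(variance matching), $\alpha_0 = 1.05\,\max(m_0 u)$, $\gamma_0$ from
the steady-state slope of $s$ on $u$ over the extreme-total cells, and
the switch at the cell of maximal $u$. One jittered restart guards
against local minima; on simulated data additional restarts improve
the objective by well under one percent, so the default is 2 (the
count is configurable through `em_config()`). The EM objective is
non-increasing by construction and the trace is stored with each fit.

Genes whose cells form a single compact blob (coefficient of variation
below 5% in both coordinates) carry no transient information; such
fits are flagged `identifiable = FALSE`. After fitting, genes can be
filtered by likelihood (`filter_by_likelihood()`, default: keep the
top half) and — when a temporal ordering of cell types is known — by
agreement between the fitted curve positions and that ordering
(`filter_by_cluster_order()`, Spearman sign test). The likelihood is
the mean per-cell Gaussian log-density of the residual distances with
the fitted variance (floored at $10^{-12}$).

### Recovering the time scale from cell densities

With $\beta = 1$ and fitted $\alpha, m$, two cells $i$ (earlier) and
$j$ of the same transcriptional phase satisfy

$$f(i, j) \;=\; \log\frac{m u_i - \alpha}{m u_j - \alpha}
  \;=\; \kappa\,\Delta t_{ij},$$

so the unknown $\kappa$ is the slope of $f$ against elapsed time. True
times are unavailable; kappa-velo uses the number of cells $d(i, j)$
falling strictly between $i$ and $j$ in the phase ordering as a proxy,
on the assumption that sampling density along the trajectory is
proportional to residence time. Dwell at a fixed point breaks the
proxy — expression stops changing while time keeps passing — in two
ways that the implementation addresses separately:

* Cells within 5% of a phase's fixed points (the upregulated steady
  state and the silent state) are excluded from the ranking before
  pairs are drawn (`steady_exclude`), because gene speed is only
  measurable during transcriptional change; under noise the band
  widens to two residual standard deviations of the fit, and cells
  whose branch assignment margin is below twice the residual noise
  (per coordinate) are dropped as well — misassigned cells interleave
  ranks from the other phase's time window and would flatten the
  slope.
* Residual dwell can only depress $f$ below the line $\kappa d$, so
  `fit_parallelogram()` estimates the slope as the upper/left boundary
  of the $(d, f)$ cloud: it scans candidate slopes on a log grid
  around a robust initial slope (95th percentile of $f/(d+1)$),
  measures for each the shortest intercept band covering 95% of the
  points, and returns the slope minimising the band width (the
  parallelogram of minimal area at fixed coverage), refined on a
  second, finer grid. With fewer than 50 usable pairs it falls back to
  the robust quantile slope and says so.

Pairs from the downregulation branch are preferred when at least 50 of
them are usable: with $\alpha = 0$ the statistic collapses to
$\log(u_i/u_j)$, which involves *no* fitted parameters and has bounded
sensitivity over the kept range, whereas the induction statistic
inherits the error of $\hat\alpha, \hat m$ with sensitivity diverging
near the asymptote $m u \to \alpha$. This mirrors the reason the
unspliced inversion is preferred over the spliced one for the
cross-check (`source = "spliced"` inverts the fitted $s(\tau)$
numerically and depends on one more parameter). Genes without a usable
repression phase pool both phases.

The recovered $\kappa$ is expressed per in-between cell, i.e. across
genes it differs from the true value by one global constant (the
typical time gap between consecutively sampled cells); a global
constant leaves the *direction* of the assembled high-dimensional
velocity untouched. Velocities are assembled per cell as
$V = B M U - \Gamma S$ with $A = \kappa\alpha$, $B = \kappa$,
$\Gamma = \kappa\gamma$ on the processed counts of the retained genes.

## Eco-velo

Fixing the step to one degradation time, $\Delta t_g = 1/\gamma_g$,
turns the first-order expansion of the kinetics into
$s_g(t + \Delta t_g) \approx (\beta_g/\gamma_g)\,u_g(t)$ — a cell's
unspliced profile is proportional to its spliced profile one
degradation time later. If $\beta$ and $\gamma$ are shared across
genes, future states can be found without any parameter fitting by
matching $U$ against $S$: `mutual_nearest_neighbors()` keeps the cells
$j$ whose spliced profile is among the $k$ nearest to $u_i$ *and*
which reciprocally count $u_i$ among the $k$ nearest unspliced
profiles to $s_j$ (default $k = 5$; empty sets are legitimate). Arrows
go from a cell's embedding position toward the mean position of its
MNNs, shrunk by a global factor (default 0.5) for readability. A cell
may match itself; the default excludes self from the arrow target so
steady cells get empty sets and hence zero arrows — the interpretable
behaviour at a fixed point. When truncating, MNNs are ranked by the
U-to-S distance. `future_state_check()` quantifies how far a dataset
(or simulation truth) is from the shared-rate assumption; the identity
is exact post-transient and degrades with rate heterogeneity, which is
precisely the regime where eco-velo mis-orients arrows.

Processing differs deliberately between the methods. Kappa-velo:
variable genes by analytic Pearson residuals on the spliced counts
(overdispersion $\theta = 100$, residuals clipped at $\sqrt{n}$),
low-count gene removal (defaults: nonzero-u fraction $\ge 0.05$,
nonzero-s fraction $\ge 0.10$), then one shared size factor per cell
over $u + s$ — sharing the factor preserves every within-cell $u/s$
ratio exactly, whereas separate per-modality normalisation bends
portraits whenever the total-u/total-s ratio varies across cell types
(`normalisation_artefact_experiment()` reproduces this on a
constructed dataset where the truth is known) — and optional kNN
imputation in the PCA space of the z-scaled spliced counts (self
included, index tie-breaks). Eco-velo treats the modalities
separately on purpose: `log1p`, per-modality size factors, then L2 —
the standard preparation for cross-modal nearest-neighbour matching.

## Projection

PCA projection of velocity endpoints (`pca_project()`) is exactly
linear and serves as the reference: the projected arrow *is* the
projection of the high-dimensional vector. For nonlinear embeddings
the package uses the Nystrom extension: a row-stochastic Gaussian
kernel between displaced cells and the training cells
($P'_{ij} \propto \exp(-\lVert x_i - x_j\rVert^2/2\sigma_i^2)$, rows =
test points, normalised over the train set) places every endpoint at a
convex combination $P' Y_{train}$ of training coordinates. Bandwidths
are adaptive (distance to the 15th nearest training point, capped at
the largest training-side bandwidth so that far-out points cannot
widen their own kernel) unless the embedding provides its own. Because the extension is only valid near
the data support, all velocities are first downscaled by one global
factor so the largest displacement does not exceed the median
nearest-neighbour distance of the training cloud
(`downscale_quantile`); endpoints whose total kernel mass still
vanishes (below $10^{-12}$) are flagged and given a uniform fallback
over their nearest training points. Arrow starts are the Nystrom
*self-projection* of the cells rather than their raw embedding
coordinates: the kernel pulls every point slightly toward its
neighbourhood, and routing both ends of the arrow through the same map
cancels that shared displacement so the drawn arrow reflects the
velocity, not the smoothing. The correlation-kernel projection
used by earlier velocity tools is provided as
`baseline_projection()` — faithfully, including its documented
defects: correlations ignore vector length (two parallel velocities of
different magnitude visualise identically) and the neighbour
difference vectors are not an orthonormal basis. Embedding
*algorithms* are pluggable: PCA and a standard diffusion map are built
in, any other method's coordinates can be supplied precomputed; the
package owns only the projection mathematics.

## The simulator

`sample_gene_rates()` draws base rates log-normally (log-mean 0,
log-sd 0.5 — a modest spread that keeps noiseless fits identifiable)
and multiplies each gene's triple by $\kappa \sim U[1, 15]$.
`simulate_cells()` places cell times uniformly on $[0, t_{max}]$ and
activates genes in a cascade: the slowest gene switches on at time
zero and is exposed for `transient_span` (default 3) of its own time
constants — switching off before reaching steady state — while faster
genes activate later (activation time decreasing in $1/\text{speed}$)
and are exposed for $\sqrt{\text{speed ratio}}$-fold more of their own
constants, so they dwell at the upregulated steady state before
switching off, as real fast genes do. Each gene upregulates for
`switch_frac` (default 0.8) of its window. Consequences used by the
validation: early cells move slowly in few genes (high directional
variance), late cells are carried by fast genes (fast, deterministic),
the final mature state is never sampled, and the latest cells' true
velocities point outside the sampled cloud. Noise is additive
Gaussian with per-gene sd equal to `noise_sd` times the steady-state
amplitude, truncated at zero; the measured unspliced counts are the
model values divided by the gene's true $m$. The generator does not
emulate branching lineages, cell birth/death, or UMI depth noise — so
passing tests demonstrate correctness of the estimators under the
model's own assumptions, not robustness to everything real data do.

For time-scale *recovery* studies (`kappa_recovery_experiment()`) the
genes share one base triple (`shared_base = TRUE`), so "true kappa" is
well defined across genes; with per-gene log-normal base rates the
identifiable quantity is the product $\kappa\beta$ and comparisons
against $\kappa$ alone would conflate the base-rate spread with
estimator error.

## Validation scale and numerical choices

The packaged studies use 50 genes x 500 cells (recovery) and 20-30
genes x 300 cells (the cheaper property checks); at these sizes the
full suite and the acceptance script each run in minutes on one core
while leaving the estimators in the regime the methods target
(hundreds of cells per trajectory). Tie-breaks are deterministic
everywhere (cell index); every stochastic stage takes an explicit
seed; the curve discretisation (40 points/branch), kernel floors
($10^{-12}$), singular-limit switches ($10^{-8}$) and the variance
floor ($10^{-12}$) are stated above and in the function documentation.

Known limitations: kappa recovery inherits the sampling noise of the
cell-density proxy, so genes much faster than the trajectory (few
transient cells) are recovered with visibly more spread — more cells,
not more pairs, is the remedy; the density-time equivalence breaks
under non-uniform proliferation/death or enriched sorting; eco-velo is
only as good as the shared-rate assumption; and Nystrom projection
cannot extrapolate beyond the sampled expression region, which is
exactly where boundary-cell velocities point — PCA projection remains
the only fully faithful view there.
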