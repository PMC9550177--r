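#' Sample per-gene kinetic rates with gene-specific time scales
#'
#' Draws base rate triples (alpha, beta, gamma) log-normally and a
#' per-gene time-scale factor kappa uniformly in `kappa_range`; the
#' gene's true rates are the base triple multiplied by its kappa, so two
#' genes with the same base triple but different kappa trace identical
#' phase portraits at different speeds.
#'
#' With `shared_base = TRUE` a single base triple is drawn and shared by
#' all genes, so the per-gene speed differences come from kappa alone —
#' the design used for time-scale recovery experiments, where "true
#' kappa" must be meaningful across genes.
#'
#' @param n_genes number of genes, >= 1.
#' @param kappa_range length-2 numeric `(lo, hi)` with `0 < lo <= hi`.
#' @param meanlog,sdlog log-normal parameters for each base rate.
#' @param shared_base draw one base triple for all genes?
#' @param alpha,beta,gamma optional fixed base rates overriding sampling
#'   (recycled across genes); used e.g. for shared splicing/degradation
#'   rate scenarios.
#' @param m unspliced downscaling truth: measured u counts are the model
#'   values divided by `m` (recycled), emulating under-counted unspliced
#'   reads.
#' @param rng_seed integer seed; same seed gives an identical table.
#' @return data.frame with columns `gene_id`, base `alpha`, `beta`,
#'   `gamma`, `kappa`, `m`, and the scaled true rates `A = kappa*alpha`,
#'   `B = kappa*beta`, `G = kappa*gamma`.
#' @export
sample_gene_rates <- function(n_genes, kappa_range = c(1, 15),
                              meanlog = 0, sdlog = 0.5,
                              shared_base = FALSE,
                              alpha = NULL, beta = NULL, gamma = NULL,
                              m = 1, rng_seed = 0L) {
  stopifnot(n_genes >= 1, length(kappa_range) == 2,
            kappa_range[1] > 0, kappa_range[1] <= kappa_range[2])
  set.seed(rng_seed)
  draw <- function(fixed) {
    if (!is.null(fixed)) rep_len(fixed, n_genes)
    else if (shared_base) rep(stats::rlnorm(1, meanlog, sdlog), n_genes)
    else stats::rlnorm(n_genes, meanlog, sdlog)
  }
  a <- draw(alpha); b <- draw(beta); g <- draw(gamma)
  kappa <- stats::runif(n_genes, kappa_range[1], kappa_range[2])
  data.frame(gene_id = paste0("gene_", seq_len(n_genes)),
             alpha = a, beta = b, gamma = g,
             kappa = kappa, m = rep_len(m, n_genes),
             A = kappa * a, B = kappa * b, G = kappa * g,
             stringsAsFactors = FALSE)
}

#' Simulate cells along a splicing-kinetics trajectory
#'
#' Cells receive a true time drawn uniformly on `[0, t_max]`. Each gene
#' activates at a time inversely related to its speed (`kappa * beta`):
#' the slowest gene switches on at time 0 and the fastest genes only
#' towards the end of the trajectory, so early cells carry high
#' directional variance (few slow genes moving) while late cells move
#' fast and deterministically, with the final mature steady state never
#' sampled. Within its active window a gene follows the closed-form
#' solutions, upregulating for `switch_frac` of the window and then
#' switching transcription off. Counts are the noiseless solutions (u
#' divided by the gene's `m`) plus i.i.d. normal noise scaled to the
#' gene's steady-state amplitude, truncated at zero.
#'
#' @param rates rate table from [sample_gene_rates()].
#' @param n_cells number of cells, >= 2.
#' @param noise_sd noise level as a fraction of each gene's steady-state
#'   amplitude (0 = noiseless), >= 0.
#' @param t_max trajectory duration; default: the slowest gene's window
#'   `transient_span / min(speed)` so that the slowest gene is active
#'   from the start and never reaches steady state.
#' @param transient_span active-window length of the *slowest* gene in
#'   units of its own time constant `1/(kappa*beta)`; faster genes get
#'   proportionally (square-root of their speed ratio) longer exposure
#'   and hence dwell at the upregulated steady state before switching.
#' @param switch_frac fraction of the active window spent upregulating
#'   before transcriptional switch-off.
#' @param rng_seed integer seed.
#' @return list with components `data` (a [velocity_dataset()], raw
#'   counts) and `truth` (class `simulation_truth`): per-gene true rates,
#'   kappa, activation/switch times, per-cell true time, the noiseless
#'   `U0`/`S0` matrices (model units), per-cell phase matrix and the true
#'   velocity matrix.
#' @export
simulate_cells <- function(rates, n_cells = 500, noise_sd = 0.05,
                           t_max = NULL, transient_span = 3,
                           switch_frac = 0.8, rng_seed = 0L) {
  stopifnot(n_cells >= 2, noise_sd >= 0)
  set.seed(rng_seed + 1L)
  G <- nrow(rates)
  speed <- rates$B                       # true splicing rate kappa*beta
  # exposure in units of each gene's own time constant: the slowest gene
  # gets `transient_span` constants (switching off before reaching steady
  # state), faster genes proportionally more, so they dwell at their
  # upregulated steady state before switching off — the portrait shapes
  # seen in real fast genes
  tau_exposure <- transient_span * sqrt(speed / min(speed))
  window <- tau_exposure / speed         # active-window length per gene
  if (is.null(t_max)) t_max <- max(window)
  t_act <- pmax(0, t_max - window)       # fastest genes turn on last
  tau_sw <- switch_frac * pmin(window, t_max - t_act)

  t <- stats::runif(n_cells, 0, t_max)
  U0 <- S0 <- V <- matrix(0, n_cells, G)
  K <- matrix(1L, n_cells, G)
  for (g in seq_len(G)) {
    p <- gene_params(alpha = rates$A[g], beta = rates$B[g],
                     gamma = rates$G[g], t_switch = tau_sw[g], m = 1)
    tau <- pmax(0, t - t_act[g])
    tr <- kinetics_trajectory(p, tau)
    U0[, g] <- tr$u; S0[, g] <- tr$s; K[, g] <- tr$phase
    V[, g] <- gene_velocity(rates$B[g], rates$G[g], 1, tr$u, tr$s)
  }
  # measured u is downscaled by m; noise scaled to steady-state amplitude
  Um <- sweep(U0, 2, rates$m, "/")
  sd_u <- noise_sd * (rates$alpha / rates$beta) / rates$m
  sd_s <- noise_sd * (rates$alpha / rates$gamma)
  U <- Um; S <- S0
  if (noise_sd > 0) {
    U <- Um + sweep(matrix(stats::rnorm(n_cells * G), n_cells, G),
                    2, sd_u, "*")
    S <- S0 + sweep(matrix(stats::rnorm(n_cells * G), n_cells, G),
                    2, sd_s, "*")
    U[U < 0] <- 0; S[S < 0] <- 0    # counts truncated at zero
  }
  data <- velocity_dataset(U, S, gene_ids = rates$gene_id)
  truth <- structure(list(rates = rates, t = t, t_act = t_act,
                          tau_switch = tau_sw, t_max = t_max,
                          U0 = U0, S0 = S0, phase = K, velocity = V,
                          noise_sd = noise_sd),
                     class = "simulation_truth")
  list(data = data, truth = truth)
}

#' Ground-truth velocity matrix
#'
#' Recomputes the cells x genes true velocity from the noiseless
#' abundances and the true scaled rates:
#' `V[i, g] = B_g * u0[i, g] - G_g * s0[i, g]`.
#'
#' @param truth a `simulation_truth` object from [simulate_cells()].
#' @return cells x genes numeric matrix.
#' @export
true_velocities <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  sweep(truth$U0, 2, truth$rates$B, "*") -
    sweep(truth$S0, 2, truth$rates$G, "*")
}
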