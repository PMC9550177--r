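#' Order cells within each transcriptional phase
#'
#' Within upregulation (`k = 1`) cells are ranked by increasing unspliced
#' abundance, within downregulation (`k = 0`) by decreasing unspliced
#' abundance — both orders follow the direction of time along the
#' portrait. Ties are broken by cell index for determinism.
#'
#' @param u per-cell unspliced values.
#' @param phases per-cell phase labels (1 up, 0 down).
#' @return list with integer index vectors `up` and `down` (cell indices
#'   in phase order, earliest first).
#' @export
order_cells_in_phase <- function(u, phases) {
  stopifnot(length(u) == length(phases))
  idx_up <- which(phases == 1L)
  idx_dn <- which(phases == 0L)
  list(up = idx_up[order(u[idx_up], idx_up)],
       down = idx_dn[order(-u[idx_dn], idx_dn)])
}

#' Elapsed scaled time between two cells from unspliced counts
#'
#' Inverts the closed-form unspliced solution for a pair of cells in the
#' same phase (`i` earlier than `j`): with the splicing rate fixed at 1,
#' \deqn{f(i, j) = \kappa \Delta t_{ij}
#'   = \log\frac{m u_i - \alpha}{m u_j - \alpha}}
#' During downregulation the effective transcription rate is 0. Pairs
#' whose ratio is nonpositive (a cell pushed beyond the asymptote by
#' noise) give `NA` and are skipped by the estimator.
#'
#' @param u_i,u_j unspliced values of the earlier/later cell
#'   (vectorised).
#' @param fit a [fit_gene_em()] result (provides `alpha` and `m`).
#' @param phase phase of the pair (1 up, 0 down), recycled.
#' @return f values (elapsed time on the kappa-scaled clock), `NA` where
#'   undefined.
#' @export
pair_f <- function(u_i, u_j, fit, phase = 1L) {
  stopifnot(inherits(fit, "gene_kinetics_fit"))
  a <- ifelse(phase == 1L, fit$alpha, 0)
  ratio <- (fit$m * u_i - a) / (fit$m * u_j - a)
  ifelse(is.finite(ratio) & ratio > 0, log(ratio), NA_real_)
}

#' Sample random cell pairs within a phase ordering
#'
#' Draws ordered pairs (earlier, later) uniformly from one phase's
#' ranking and records `d`, the number of cells strictly between the two
#' in the ranking — the cell-density proxy for elapsed time. Requesting
#' at least as many pairs as exist returns all pairs exhaustively.
#'
#' @param ranking integer vector of cell indices in phase order (one
#'   element of [order_cells_in_phase()]).
#' @param n_pairs number of pairs to draw.
#' @param rng_seed integer seed.
#' @return data.frame with columns `i`, `j` (cell indices, `i` earlier)
#'   and `d` (strict in-between count; adjacent ranks give 0).
#' @export
sample_pairs <- function(ranking, n_pairs, rng_seed = 0L) {
  n <- length(ranking)
  if (n < 2) stop("need at least 2 cells in the phase")
  total <- n * (n - 1) / 2
  if (n_pairs >= total) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    a <- ij[, "row"]; b <- ij[, "col"]
  } else {
    set.seed(rng_seed)
    a <- sample.int(n, n_pairs, replace = TRUE)
    b <- sample.int(n - 1L, n_pairs, replace = TRUE)
    b <- b + (b >= a)                   # uniform over distinct pairs
    lo <- pmin(a, b); b <- pmax(a, b); a <- lo
  }
  data.frame(i = ranking[a], j = ranking[b], d = b - a - 1L)
}

#' Parallelogram estimator of the per-gene time scale kappa
#'
#' Pairs fully inside a transcriptional phase satisfy `f = kappa * dt`,
#' linear in the cell-count proxy `d` with slope proportional to kappa;
#' steady-state dwell can only depress `f` below that line. Plotting `f`
#' against `d` therefore produces a parallelogram whose upper/left
#' boundary slope equals kappa. The estimator scans candidate slopes on
#' a log grid around a robust initial slope (the 95th percentile of
#' `f/(d+1)`) and, for each slope, measures the shortest intercept band
#' of `f - slope * d` covering a `coverage` fraction of points; the
#' parallelogram area is band width times the d-range, so the returned
#' slope is the one minimising the band width subject to coverage.
#'
#' @param pairs data.frame with columns `d` and `f` (`NA` f dropped).
#' @param coverage fraction of points the parallelogram must cover
#'   (default 0.95).
#' @param min_pairs minimum usable pairs for the parallelogram; with
#'   fewer, the estimator falls back to the robust quantile slope with a
#'   warning.
#' @param n_grid number of candidate slopes.
#' @return list with `kappa` (the slope, in units of scaled time per
#'   in-between cell), `n_pairs` used, and the `estimator` tag
#'   (`"parallelogram"` or `"quantile_fallback"`).
#' @export
fit_parallelogram <- function(pairs, coverage = 0.95, min_pairs = 50,
                              n_grid = 150) {
  ok <- is.finite(pairs$f) & is.finite(pairs$d)
  d <- pairs$d[ok]; f <- pairs$f[ok]
  if (length(d) == 0 || all(d == 0))
    stop("no usable pairs with positive in-between counts")
  a1 <- stats::quantile(f / (d + 1), 0.95, names = FALSE)
  if (!is.finite(a1) || a1 <= 0)
    stop("no transient signal: nonpositive robust slope")
  if (length(d) < min_pairs) {
    warning("fewer than ", min_pairs,
            " usable pairs; falling back to quantile slope")
    return(list(kappa = a1, n_pairs = length(d),
                estimator = "quantile_fallback"))
  }
  shortest_width <- function(r) {
    r <- sort(r)
    k <- max(1L, ceiling(coverage * length(r)))
    if (k >= length(r)) return(r[length(r)] - r[1])
    min(r[seq(k, length(r))] - r[seq_len(length(r) - k + 1L)])
  }
  scan <- function(lo, hi, n) {
    grid <- exp(seq(log(lo), log(hi), length.out = n))
    widths <- vapply(grid, function(a) shortest_width(f - a * d),
                     numeric(1))
    list(grid = grid, best = which.min(widths))
  }
  coarse <- scan(0.1 * a1, 10 * a1, n_grid)
  step <- (10 / 0.1)^(1 / (n_grid - 1))
  centre <- coarse$grid[coarse$best]
  fine <- scan(centre / step, centre * step, 80)
  list(kappa = fine$grid[fine$best], n_pairs = length(d),
       estimator = "parallelogram")
}

# latent times of cells from the spliced counts by numerically inverting
# the fitted s(tau) on the monotone segment of the assigned branch;
# non-invertible cells get NA. Near the post-switch peak of s the
# derivative ds/dtau vanishes and the inversion amplifies any
# perturbation, so the usable segment starts where the decay rate
# reaches a fifth of its branch maximum.
.tau_from_spliced <- function(s, fit, phases, n_grid = 400) {
  cv <- .fit_curve(fit$alpha, fit$gamma, fit$sw_frac, fit$m, n_grid)
  inv_mono <- function(tau, sv, decreasing = FALSE) {
    if (decreasing) { tau <- rev(tau); sv <- rev(sv) }
    keep <- c(TRUE, diff(sv) > 0)
    function(x) stats::approx(sv[keep], tau[keep], xout = x,
                              rule = 1)$y
  }
  # up branch: s increases with tau; down branch: use the decaying,
  # well-conditioned segment after the post-switch peak of s
  f_up <- inv_mono(cv$tau_up, cv$up[, "s"])
  ds <- diff(cv$down[, "s"]) / diff(cv$tau_down)
  decay <- pmax(-ds, 0)
  pk <- which(decay >= 0.2 * max(decay))[1]
  if (is.na(pk)) pk <- which.max(cv$down[, "s"])
  f_dn <- inv_mono(cv$tau_down[pk:n_grid], cv$down[pk:n_grid, "s"],
                   decreasing = TRUE)
  tau <- rep(NA_real_, length(s))
  iu <- which(phases == 1L); id <- which(phases == 0L)
  tau[iu] <- f_up(s[iu])
  tau[id] <- f_dn(s[id])
  tau
}

#' Estimate a gene's time scale kappa from its cells
#'
#' End-to-end kappa recovery for one gene: phase assignment from the
#' fit, phase-order ranking, pair sampling, elapsed-time statistic `f`
#' (from the unspliced inversion by default, or from the spliced
#' solution as an independent cross-check) and the parallelogram fit.
#' The returned kappa is in units of scaled time per in-between cell —
#' across genes this differs from the true kappa by one global constant
#' (the typical time gap between consecutive cells).
#'
#' Pairs from the downregulation branch are preferred when the branch
#' yields enough of them: with transcription off, the elapsed-time
#' statistic reduces to `log(u_i/u_j)`, free of the fitted `alpha` and
#' `m`, and its sensitivity stays bounded over the kept range, whereas
#' the induction statistic inherits fit error with sensitivity growing
#' near the asymptote. Genes without a usable repression phase fall
#' back to pooling both phases.
#'
#' @param u,s per-cell unspliced/spliced values.
#' @param fit a [fit_gene_em()] result.
#' @param n_pairs pairs sampled per phase (default 2000).
#' @param coverage parallelogram coverage fraction.
#' @param source `"unspliced"` (default) or `"spliced"`.
#' @param times optional per-cell true/global times; when given, `d` is
#'   the absolute time difference `|t_i - t_j|` instead of the rank
#'   count (used to validate the density proxy).
#' @param steady_exclude cells whose upscaled u sits within this
#'   fraction of a phase's fixed points (the upregulated steady state
#'   `alpha` and the silent state 0) are left out of the ranking: gene
#'   speed is only measurable during transcriptional change, and dwell
#'   at either fixed point decouples expression distance from elapsed
#'   time (default 0.05).
#' @param rng_seed integer seed for pair sampling.
#' @return list as [fit_parallelogram()], plus the `source` used.
#' @export
estimate_kappa <- function(u, s, fit, n_pairs = 2000, coverage = 0.95,
                           source = c("unspliced", "spliced"),
                           times = NULL, steady_exclude = 0.05,
                           rng_seed = 0L) {
  source <- match.arg(source)
  phases <- rep(NA_integer_, length(u))
  w <- fit$m * u
  # widen the fixed-point exclusion to the fit's own noise level: cells
  # within two residual standard deviations of the silent state or the
  # asymptote are indistinguishable from dwell and carry no ordering
  # information
  rv <- if (is.null(fit$residual_var)) 0 else fit$residual_var
  noise_w <- 2 * sqrt(rv) * fit$sd_u * fit$m
  lo <- max(steady_exclude * fit$alpha, noise_w)
  hi <- fit$alpha - max(steady_exclude * fit$alpha, noise_w)
  lo_dn <- max(steady_exclude * fit$m * fit$u_switch, noise_w)
  # rank only cells whose branch assignment is confident at the fit's
  # noise level: where the two branches run close together (near the
  # switch, the origin, or for portraits that fold onto themselves)
  # noise scatters cells across the boundary, and misassigned cells
  # interleave ranks from the wrong time window
  confident <- rep(TRUE, length(u))
  if (rv > 0 && !is.null(fit$sw_frac)) {
    bd <- .branch_distances(u, s, fit$alpha, fit$gamma, fit$sw_frac,
                            fit$m, 1 / max(fit$sd_u, 1e-12),
                            1 / max(fit$sd_s, 1e-12), 60)
    confident <- abs(bd$d2_up - bd$d2_down) > 4 * rv
  }
  up_keep <- fit$k == 1L & w > lo & w < hi & confident
  dn_keep <- fit$k == 0L & w > lo_dn & confident
  phases[up_keep] <- 1L
  phases[dn_keep] <- 0L
  rk <- order_cells_in_phase(u, phases)
  tau_s <- if (source == "spliced")
    .tau_from_spliced(s, fit, phases) else NULL
  collect <- function(ranking, phase, seed_off) {
    if (length(ranking) < 2) return(NULL)
    pr <- sample_pairs(ranking, n_pairs, rng_seed = rng_seed + seed_off)
    pr$f <- if (source == "unspliced")
      pair_f(u[pr$i], u[pr$j], fit, phase = phase)
    else tau_s[pr$j] - tau_s[pr$i]
    if (!is.null(times)) pr$d <- abs(times[pr$j] - times[pr$i])
    pr
  }
  dn <- collect(rk$down, 0L, 1L)
  n_dn <- if (is.null(dn)) 0L else sum(is.finite(dn$f) & dn$d > 0)
  pairs <- if (n_dn >= 50) dn
           else rbind(collect(rk$up, 1L, 0L), dn)
  if (is.null(pairs)) stop("no phase with at least 2 cells")
  res <- fit_parallelogram(pairs, coverage = coverage)
  res$source <- source
  res$phase_used <- if (n_dn >= 50) "down" else "pooled"
  res
}

#' Recover kappa for every fitted gene of a dataset
#'
#' @param data processed [velocity_dataset()].
#' @param fits named list of per-gene [fit_gene_em()] results (same gene
#'   order as the dataset columns).
#' @param ... passed to [estimate_kappa()].
#' @return data.frame `gene_id`, `kappa`, `n_pairs`, `estimator`; genes
#'   whose estimate fails get `NA` kappa.
#' @export
recover_kappas <- function(data, fits, ...) {
  stopifnot(inherits(data, "velocity_dataset"),
            length(fits) == ncol(data$U))
  rows <- lapply(seq_along(fits), function(g) {
    res <- tryCatch(
      estimate_kappa(data$U[, g], data$S[, g], fits[[g]], ...),
      error = function(e) list(kappa = NA_real_, n_pairs = 0L,
                               estimator = paste("failed:",
                                                 conditionMessage(e))))
    data.frame(gene_id = data$gene_ids[g], kappa = res$kappa,
               n_pairs = res$n_pairs, estimator = res$estimator,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble correctly scaled kinetic parameters
#'
#' Combines per-gene fits (splicing rate 1) with recovered kappas into
#' the scaled parameter set `A = kappa * alpha`, `B = kappa`,
#' `G = kappa * gamma`, `M = m` used for high-dimensional velocities.
#' Genes with a missing kappa are dropped with a warning; the ratios
#' `B/G` are kappa-invariant by construction.
#'
#' @param fits named list of [fit_gene_em()] results.
#' @param kappas data.frame from [recover_kappas()] (or a numeric vector
#'   of per-gene kappas in the same order).
#' @return data.frame of class `scaled_kinetics`: `gene_id`, `kappa`,
#'   `A`, `B`, `G`, `M`.
#' @export
assemble_scaled <- function(fits, kappas) {
  kap <- if (is.data.frame(kappas)) kappas$kappa else kappas
  ids <- if (is.data.frame(kappas) && !is.null(kappas$gene_id))
    kappas$gene_id else names(fits)
  if (is.null(ids)) ids <- paste0("gene_", seq_along(fits))
  stopifnot(length(kap) == length(fits))
  ok <- is.finite(kap)
  if (any(!ok))
    warning(sprintf("dropping %d gene(s) without a kappa estimate",
                    sum(!ok)))
  out <- data.frame(
    gene_id = ids[ok],
    kappa = kap[ok],
    A = kap[ok] * vapply(fits[ok], `[[`, numeric(1), "alpha"),
    B = kap[ok],
    G = kap[ok] * vapply(fits[ok], `[[`, numeric(1), "gamma"),
    M = vapply(fits[ok], `[[`, numeric(1), "m"),
    stringsAsFactors = FALSE)
  class(out) <- c("scaled_kinetics", class(out))
  out
}

#' High-dimensional velocity field
#'
#' Elementwise per gene: `V[i, g] = B_g M_g U[i, g] - G_g S[i, g]` on the
#' processed (imputed, jointly normalised) counts restricted to the
#' retained genes.
#'
#' @param scaled a [assemble_scaled()] result.
#' @param data processed [velocity_dataset()] whose genes match
#'   `scaled$gene_id`.
#' @return cells x genes velocity matrix.
#' @export
velocity_field <- function(scaled, data) {
  stopifnot(inherits(data, "velocity_dataset"))
  idx <- match(scaled$gene_id, data$gene_ids)
  if (anyNA(idx)) stop("scaled genes missing from dataset")
  U <- data$U[, idx, drop = FALSE]
  S <- data$S[, idx, drop = FALSE]
  V <- sweep(U, 2, scaled$B * scaled$M, "*") -
       sweep(S, 2, scaled$G, "*")
  colnames(V) <- scaled$gene_id
  V
}
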