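#' EM settings for per-gene phase-portrait fitting
#'
#' @param max_iter maximum outer EM iterations.
#' @param inner_maxit Nelder-Mead iterations per M-step.
#' @param tol relative objective-change convergence tolerance.
#' @param n_restarts number of jittered restarts around the data-driven
#'   initialisation (the best final objective wins).
#' @param curve_points number of discretisation points per branch of the
#'   fitted curve (distances are computed to the polyline segments, so
#'   the discretisation error is second order).
#' @param rng_seed seed for the deterministic restart jitter.
#' @return list of class `em_config`.
#' @export
em_config <- function(max_iter = 10, inner_maxit = 200, tol = 1e-6,
                      n_restarts = 2, curve_points = 40, rng_seed = 0L) {
  structure(list(max_iter = max_iter, inner_maxit = inner_maxit, tol = tol,
                 n_restarts = n_restarts, curve_points = curve_points,
                 rng_seed = rng_seed),
            class = "em_config")
}

# build the fitted curve as polylines in measured (u, s) space.
# theta: alpha, gamma, sw_frac (fraction of the asymptote reached at the
# switch, in upscaled-u units), m. Returns per-branch point matrices and
# the latent time of each point (down-branch times offset by tau_switch).
.fit_curve <- function(alpha, gamma, sw_frac, m, n_pts) {
  sw_frac <- min(max(sw_frac, 1e-6), 1 - 1e-6)
  tau_sw <- -log(1 - sw_frac)
  p_up <- gene_params(alpha = alpha, beta = 1, gamma = gamma, m = 1)
  tau_u <- seq(0, tau_sw, length.out = n_pts)
  w_up <- unspliced_at(p_up, tau_u, 1L)
  s_up <- spliced_at(p_up, tau_u, 1L)
  # extreme gamma can cancel s to a tiny negative value numerically
  w_sw <- max(w_up[n_pts], 0); s_sw <- max(s_up[n_pts], 0)
  p_dn <- gene_params(alpha = alpha, beta = 1, gamma = gamma,
                      u0 = w_sw, s0 = s_sw, m = 1)
  tau_d <- seq(0, 8, length.out = n_pts)  # e^-8: decayed to ~0
  w_dn <- unspliced_at(p_dn, tau_d, 0L)
  s_dn <- spliced_at(p_dn, tau_d, 0L)
  list(up = cbind(u = w_up / m, s = s_up), tau_up = tau_u,
       down = cbind(u = w_dn / m, s = s_dn), tau_down = tau_sw + tau_d,
       tau_switch = tau_sw, u_switch = w_sw / m, s_switch = s_sw)
}

# squared distances from points X (n x 2, already standardised) to the
# segments of a standardised polyline P (m x 2); returns list(d2, seg, t)
# with the per-point minimum, its segment index and position on it.
.polyline_dist <- function(X, P) {
  m <- nrow(P) - 1L
  D <- P[-1, , drop = FALSE] - P[-(m + 1L), , drop = FALSE]
  len2 <- pmax(rowSums(D^2), 1e-300)
  # t[i,j] = ((X_i - P_j) . D_j) / len2_j, clamped to [0, 1]
  XD <- X %*% t(D)
  PD <- rowSums(P[-(m + 1L), , drop = FALSE] * D)
  Tm <- sweep(XD, 2, PD, "-")
  Tm <- sweep(Tm, 2, len2, "/")
  Tm[Tm < 0] <- 0; Tm[Tm > 1] <- 1
  px <- outer(rep(1, nrow(X)), P[-(m + 1L), 1]) + Tm * outer(rep(1, nrow(X)), D[, 1])
  py <- outer(rep(1, nrow(X)), P[-(m + 1L), 2]) + Tm * outer(rep(1, nrow(X)), D[, 2])
  d2 <- (X[, 1] - px)^2 + (X[, 2] - py)^2
  j <- max.col(-d2, ties.method = "first")
  idx <- cbind(seq_len(nrow(X)), j)
  list(d2 = d2[idx], seg = j, t = Tm[idx])
}

# E-step machinery shared by the objective and the final assignment:
# distances of standardised cells to both branches of the curve.
.branch_distances <- function(u, s, alpha, gamma, sw_frac, m, wu, ws, n_pts) {
  cv <- .fit_curve(alpha, gamma, sw_frac, m, n_pts)
  X <- cbind(u * wu, s * ws)
  std <- function(P) cbind(P[, 1] * wu, P[, 2] * ws)
  up <- .polyline_dist(X, std(cv$up))
  dn <- .polyline_dist(X, std(cv$down))
  tau_of <- function(br, tau) tau[br$seg] +
    br$t * (tau[br$seg + 1L] - tau[br$seg])
  list(curve = cv,
       d2_up = up$d2, d2_down = dn$d2,
       tau_up = tau_of(up, cv$tau_up), tau_down = tau_of(dn, cv$tau_down))
}

.em_objective <- function(par, u, s, wu, ws, n_pts) {
  alpha <- exp(par[1]); gamma <- exp(par[2])
  sw_frac <- stats::plogis(par[3]); m <- exp(par[4])
  if (!is.finite(alpha) || !is.finite(gamma) || !is.finite(m) ||
      alpha <= 0 || gamma <= 0) return(1e300)
  bd <- tryCatch(
    .branch_distances(u, s, alpha, gamma, sw_frac, m, wu, ws, n_pts),
    error = function(e) NULL)
  if (is.null(bd)) return(1e300)
  val <- sum(pmin(bd$d2_up, bd$d2_down))
  if (!is.finite(val)) 1e300 else val
}

#' Fit the phase-portrait parameters of one gene by EM
#'
#' Alternates (E) assigning every cell to its nearest point on the up- or
#' downregulation branch of the portrait curve with (M) updating the
#' parameters `(alpha, gamma, u_switch, m)` — splicing rate fixed at 1 —
#' to minimise the summed squared distances. Distances are measured
#' after standardising u and s to unit variance so neither axis
#' dominates. The routine runs several deterministically jittered
#' restarts around a data-driven initialisation (`m0 = sd(s)/sd(u)`,
#' `alpha0 = 1.05 max(m0 u)`, `gamma0` from the steady-state slope of s
#' on u over the extreme cells, switch at the cell of maximal u) and
#' returns the best.
#'
#' @param u,s per-cell unspliced/spliced vectors (imputed, jointly
#'   normalised); at least 20 cells recommended.
#' @param config an [em_config()].
#' @return object of class `gene_kinetics_fit`: parameters, switch point
#'   `(u_switch, s_switch)`, per-cell phase `k` (1 up / 0 down), per-cell
#'   latent curve position `tau` (down-branch offset by the switch time),
#'   residual variance, mean log-likelihood, the per-iteration objective
#'   trace and the flags `converged` / `identifiable`.
#' @export
fit_gene_em <- function(u, s, config = em_config()) {
  stopifnot(length(u) == length(s), length(u) >= 2)
  if (all(u == 0) || all(s == 0)) stop("all-zero gene cannot be fitted")
  if (length(u) < 20)
    warning("fewer than 20 cells; fit may be unreliable")
  sd_u <- stats::sd(u); sd_s <- stats::sd(s)
  identifiable <- !(sd_u / max(mean(u), 1e-300) < 0.05 &&
                    sd_s / max(mean(s), 1e-300) < 0.05)
  wu <- 1 / max(sd_u, 1e-12); ws <- 1 / max(sd_s, 1e-12)
  n_pts <- config$curve_points

  # data-driven initialisation
  m0 <- max(sd_s / max(sd_u, 1e-12), 1e-6)
  alpha0 <- max(m0 * max(u) * 1.05, 1e-6)
  tot <- u + s
  ext <- tot >= stats::quantile(tot, 0.90)
  slope <- sum(s[ext] * u[ext]) / max(sum(u[ext]^2), 1e-300)
  gamma0 <- m0 / max(slope, 1e-6)
  frac0 <- min(m0 * max(u) / alpha0, 0.95)
  par0 <- c(log(alpha0), log(gamma0), stats::qlogis(frac0), log(m0))

  set.seed(config$rng_seed)
  jitters <- rbind(0, matrix(stats::rnorm(4 * (config$n_restarts - 1),
                                          0, 0.3),
                             ncol = 4))
  best <- NULL
  for (r in seq_len(nrow(jitters))) {
    par <- par0 + jitters[r, ]
    obj <- .em_objective(par, u, s, wu, ws, n_pts)
    trace <- obj
    conv <- FALSE
    for (it in seq_len(config$max_iter)) {
      op <- stats::optim(par, .em_objective, u = u, s = s, wu = wu,
                         ws = ws, n_pts = n_pts, method = "Nelder-Mead",
                         control = list(maxit = config$inner_maxit))
      new_obj <- min(op$value, obj)      # never accept a worse objective
      if (op$value <= obj) par <- op$par
      trace <- c(trace, new_obj)
      if (obj - new_obj < config$tol * max(obj, 1e-300) ||
          new_obj <= 1e-12 * length(u)) {
        obj <- new_obj; conv <- TRUE; break
      }
      obj <- new_obj
    }
    if (is.null(best) || obj < best$obj)
      best <- list(par = par, obj = obj, trace = trace, converged = conv)
    # a near-interpolating fit cannot be improved by further restarts
    if (best$obj <= 1e-5 * length(u)) break
  }

  par <- best$par
  alpha <- exp(par[1]); gamma <- exp(par[2])
  sw_frac <- stats::plogis(par[3]); m <- exp(par[4])
  bd <- .branch_distances(u, s, alpha, gamma, sw_frac, m, wu, ws, n_pts)
  k <- ifelse(bd$d2_up <= bd$d2_down, 1L, 0L)   # tie-break: upregulation
  tau <- ifelse(k == 1L, bd$tau_up, bd$tau_down)
  d2 <- pmin(bd$d2_up, bd$d2_down)
  sigma2 <- max(mean(d2) / 2, 1e-12)            # per-coordinate variance
  loglik <- mean(-log(2 * pi * sigma2) - d2 / (2 * sigma2))
  structure(list(alpha = alpha, gamma = gamma, m = m,
                 u_switch = bd$curve$u_switch, s_switch = bd$curve$s_switch,
                 tau_switch = bd$curve$tau_switch, sw_frac = sw_frac,
                 k = k, tau = tau, percell_d2 = d2,
                 residual_var = sigma2, loglik = loglik,
                 objective = best$obj, objective_trace = best$trace,
                 converged = best$converged, identifiable = identifiable,
                 sd_u = sd_u, sd_s = sd_s, n_cells = length(u)),
            class = "gene_kinetics_fit")
}

#' @export
print.gene_kinetics_fit <- function(x, ...) {
  cat(sprintf(paste0("gene_kinetics_fit: alpha=%.4g gamma=%.4g m=%.4g ",
                     "u_switch=%.4g loglik=%.4g%s%s\n"),
              x$alpha, x$gamma, x$m, x$u_switch, x$loglik,
              if (x$converged) "" else " [not converged]",
              if (x$identifiable) "" else " [unidentifiable]"))
  invisible(x)
}

#' Assign each cell to the up- or downregulation branch
#'
#' Each cell goes to the branch whose fitted curve is nearer in the
#' standardised u-s space; exact ties go to upregulation (`k = 1`).
#'
#' @param u,s per-cell vectors.
#' @param fit a [fit_gene_em()] result.
#' @return integer vector of phase labels (1 up, 0 down).
#' @export
assign_phase <- function(u, s, fit) {
  stopifnot(inherits(fit, "gene_kinetics_fit"))
  bd <- .branch_distances(u, s, fit$alpha, fit$gamma, fit$sw_frac, fit$m,
                          1 / max(fit$sd_u, 1e-12),
                          1 / max(fit$sd_s, 1e-12), 60)
  ifelse(bd$d2_up <= bd$d2_down, 1L, 0L)
}

#' Mean per-cell Gaussian log-likelihood of a fit
#'
#' Computed from the fitted residual variance (floored at 1e-12) in
#' standardised space, so genes identical up to gene-wide scaling get
#' equal likelihoods and values are comparable across genes with equal
#' cell counts. Higher is better.
#'
#' @param fit a [fit_gene_em()] result.
#' @return scalar mean log-likelihood.
#' @export
gene_likelihood <- function(fit) {
  stopifnot(inherits(fit, "gene_kinetics_fit"))
  sigma2 <- max(fit$residual_var, 1e-12)
  mean(-log(2 * pi * sigma2) - fit$percell_d2 / (2 * sigma2))
}

#' Filter gene fits by likelihood
#'
#' @param fits named list of [fit_gene_em()] results.
#' @param threshold absolute likelihood threshold; genes with likelihood
#'   strictly above it survive. When `NULL`, the top `quantile` fraction
#'   of genes is retained.
#' @param quantile fraction of genes retained when no absolute threshold
#'   is given (default 0.5).
#' @return integer indices of surviving genes.
#' @export
filter_by_likelihood <- function(fits, threshold = NULL, quantile = 0.5) {
  ll <- vapply(fits, gene_likelihood, numeric(1))
  if (is.null(threshold))
    threshold <- stats::quantile(ll, 1 - quantile, names = FALSE)
  unname(which(ll >= threshold))
}

#' Filter genes whose fitted dynamics reverse the known cluster order
#'
#' For each gene, the mean fitted curve position (latent time along the
#' up-then-down trajectory) is computed per cell cluster and rank-
#' correlated (Spearman) against the user-supplied temporal hierarchy of
#' the clusters. Genes with negative correlation — fitted dynamics
#' running against the known direction of differentiation — are
#' rejected. With no hierarchy the filter is the identity.
#'
#' @param fits named list of [fit_gene_em()] results (per-cell `tau`).
#' @param cell_labels cluster label per cell.
#' @param hierarchy character vector of cluster labels in temporal
#'   order (earliest first), or `NULL` to disable.
#' @return integer indices of surviving genes.
#' @export
filter_by_cluster_order <- function(fits, cell_labels = NULL,
                                    hierarchy = NULL) {
  if (is.null(hierarchy)) return(seq_along(fits))
  stopifnot(!is.null(cell_labels))
  labs <- as.character(cell_labels)
  unknown <- setdiff(unique(labs), hierarchy)
  if (length(unknown)) {
    warning("labels absent from hierarchy ignored: ",
            paste(unknown, collapse = ", "))
  }
  keep_cells <- labs %in% hierarchy
  rank_of <- match(labs[keep_cells], hierarchy)
  ok <- vapply(fits, function(f) {
    pos <- f$tau[keep_cells]
    mean_pos <- tapply(pos, rank_of, mean)
    r <- suppressWarnings(
      stats::cor(as.numeric(names(mean_pos)), as.numeric(mean_pos),
                 method = "spearman"))
    is.na(r) || r >= 0
  }, logical(1))
  unname(which(ok))
}
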