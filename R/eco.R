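#' Mutual nearest neighbours between unspliced and spliced modalities
#'
#' Under shared splicing and degradation rates, a cell's unspliced vector
#' is proportional to its spliced vector one degradation time later, so
#' future states can be found by matching U against S directly. For each
#' cell `i`, the MNN set is
#' `{j : j in kNN_S(u_i) and i in kNN_U(s_j)}`: the cells whose spliced
#' profile is among the k nearest to `u_i` *and* which reciprocally count
#' `u_i` among the k nearest unspliced profiles to their own spliced
#' profile. Not every cell needs to have MNNs. Distances are Euclidean,
#' which on L2-normalised rows orders identically to cosine distance.
#' MNNs are returned ranked by the U-to-S distance.
#'
#' @param U_norm,S_norm eco-normalised matrices (see [eco_normalise()]):
#'   same cells and genes, L2-normalised rows.
#' @param k neighbour count (default 5), `< n_cells`.
#' @param include_self may a cell be its own mutual neighbour? Default
#'   `FALSE`: self is excluded so that steady cells (whose U profile
#'   matches their own S profile) get empty sets and hence zero arrows.
#' @return object of class `mnn_result`: list with `neighbors` (per-cell
#'   integer vectors, possibly empty) and `k`.
#' @export
mutual_nearest_neighbors <- function(U_norm, S_norm, k = 5,
                                     include_self = FALSE) {
  stopifnot(identical(dim(U_norm), dim(S_norm)), k >= 1)
  n <- nrow(U_norm)
  if (k >= n) stop("k must be smaller than the number of cells")
  # kNN of each u_i among spliced rows, and of each s_j among unspliced
  nn_us <- knn_index(S_norm, k, query = U_norm)  # rows: u_i -> S space
  nn_su <- knn_index(U_norm, k, query = S_norm)  # rows: s_j -> U space
  # in_su[j, i] is TRUE when cell i is among the k nearest unspliced
  # rows to s_j
  in_su <- matrix(FALSE, n, n)
  in_su[cbind(rep(seq_len(n), each = k), as.vector(t(nn_su)))] <- TRUE
  neighbors <- lapply(seq_len(n), function(i) {
    cand <- nn_us[i, ]                  # already ranked by U->S distance
    mnn <- cand[in_su[cand, i]]
    if (!include_self) mnn <- mnn[mnn != i]
    as.integer(mnn)
  })
  structure(list(neighbors = neighbors, k = k), class = "mnn_result")
}

#' Eco-velo velocity arrows on an embedding
#'
#' The arrow of cell `i` starts at its embedding position and points
#' towards the mean embedding position of its mutual nearest neighbours,
#' shrunk by a global factor so arrows indicate direction without
#' spanning the full displacement:
#' `end_i = Y_i + scale * (mean(Y[mnn_i]) - Y_i)`.
#' Cells with empty MNN sets get a zero-length arrow and are reported in
#' the `has_arrow` column.
#'
#' @param mnn a [mutual_nearest_neighbors()] result.
#' @param Y embedding coordinates (cells x K).
#' @param scale global shrink factor (default 0.5).
#' @return data.frame with start (`x0 ...`), end (`x1 ...`) coordinates
#'   per embedding dimension and logical `has_arrow`.
#' @export
eco_arrows <- function(mnn, Y, scale = 0.5) {
  stopifnot(inherits(mnn, "mnn_result"),
            nrow(Y) == length(mnn$neighbors))
  Y <- as.matrix(Y)
  K <- ncol(Y)
  end <- Y
  has <- lengths(mnn$neighbors) > 0
  for (i in which(has)) {
    target <- colMeans(Y[mnn$neighbors[[i]], , drop = FALSE])
    end[i, ] <- Y[i, ] + scale * (target - Y[i, ])
  }
  out <- data.frame(Y, end, has_arrow = has)
  names(out) <- c(paste0("x", seq_len(K), "_0"),
                  paste0("x", seq_len(K), "_1"), "has_arrow")
  out
}

#' Diagnostic for the eco-velo future-state assumption
#'
#' Eco-velo rests on the first-order identity
#' `s(t + 1/gamma) = (beta/gamma) u(t)` (exact at steady state), shared
#' across genes when beta and gamma are shared. The diagnostic evolves
#' the noiseless truth of a simulation forward by the *shared* interval
#' `dt = 1/median(gamma)` and compares the resulting spliced counts to
#' `median(beta/gamma) * u(t)` per gene. With heterogeneous rates the
#' shared clock is wrong for most genes and the check reports failure —
#' the documented failure mode of the heuristic.
#'
#' @param truth a `simulation_truth` from [simulate_cells()].
#' @param tol median relative-error threshold for the per-gene check
#'   (default 0.05).
#' @param steady_frac restrict the comparison to cells within this
#'   relative distance of the gene's steady state (`NULL`: all active
#'   cells); the identity is exact only post-transient.
#' @return list with `per_gene` (data.frame `gene_id`,
#'   `median_rel_error`, `n_cells`), `ok` (overall pass) and the shared
#'   `dt` and proportionality `factor` used.
#' @export
future_state_check <- function(truth, tol = 0.05, steady_frac = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  rates <- truth$rates
  dt <- 1 / stats::median(rates$G)
  fac <- stats::median(rates$B / rates$G)
  G <- nrow(rates)
  rows <- lapply(seq_len(G), function(g) {
    p <- gene_params(alpha = rates$A[g], beta = rates$B[g],
                     gamma = rates$G[g], t_switch = truth$tau_switch[g])
    tau <- pmax(0, truth$t - truth$t_act[g])
    active <- truth$t >= truth$t_act[g]
    s_fut <- kinetics_trajectory(p, tau + dt)$s
    pred <- fac * truth$U0[, g]
    keep <- active
    if (!is.null(steady_frac)) {
      ss <- steady_state(p)
      keep <- active &
        abs(truth$U0[, g] - ss["u_ss"]) <= steady_frac * ss["u_ss"] &
        abs(truth$S0[, g] - ss["s_ss"]) <= steady_frac * ss["s_ss"]
    }
    rel <- abs(s_fut[keep] - pred[keep]) /
      pmax(abs(pred[keep]), 1e-12)
    data.frame(gene_id = rates$gene_id[g],
               median_rel_error = if (any(keep)) stats::median(rel)
                                  else NA_real_,
               n_cells = sum(keep), stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  err <- per_gene$median_rel_error
  list(per_gene = per_gene,
       ok = stats::median(err, na.rm = TRUE) <= tol,
       dt = dt, factor = fac)
}
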