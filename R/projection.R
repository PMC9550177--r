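#' Fit an embedding model for Nystrom projection
#'
#' Wraps training features, training coordinates and per-point kernel
#' bandwidths into the reusable object that out-of-sample points are
#' projected onto. Embedding computation is delegated to a pluggable
#' provider keyed by the method tag: `"pca"` (prcomp scores) and
#' `"diffmap"` (Gaussian-kernel diffusion map, computed here) are built
#' in; for any other tag (`"tsne"`, `"umap"`, ...) precomputed
#' coordinates must be supplied via `Y` — this module owns only the
#' projection mathematics, not the embedding algorithms.
#'
#' @param X training feature matrix (cells x genes; the processed
#'   spliced counts of the retained genes).
#' @param method embedding tag; `"pca"`, `"diffmap"` or any tag with
#'   `Y` supplied.
#' @param K embedding dimensionality (ignored when `Y` is given).
#' @param Y optional precomputed coordinates (cells x K).
#' @param bandwidth_neighbor adaptive kernel bandwidth: distance to this
#'   nearest train neighbour (default 15).
#' @param sigma optional fixed kernel bandwidth overriding the adaptive
#'   rule (recycled per point).
#' @return object of class `embedding_model` with `X_train`, `Y_train`,
#'   `sigma` (per *test*-side evaluation the bandwidths are recomputed;
#'   these are the train-side defaults), `method`, and for `"pca"` the
#'   `center`/`rotation` of the linear map.
#' @export
embedding_model <- function(X, method = "pca", K = 2, Y = NULL,
                            bandwidth_neighbor = 15, sigma = NULL) {
  X <- as.matrix(X)
  pca <- NULL
  if (is.null(Y)) {
    if (method == "pca") {
      pca <- stats::prcomp(X, center = TRUE, rank. = K)
      Y <- pca$x[, seq_len(K), drop = FALSE]
    } else if (method == "diffmap") {
      Y <- .diffusion_map(X, K = K, bandwidth_neighbor = bandwidth_neighbor)
    } else {
      stop(sprintf(
        "method '%s' needs precomputed coordinates Y (provider not built in)",
        method))
    }
  } else {
    Y <- as.matrix(Y)
    if (nrow(Y) != nrow(X)) stop("X and Y row counts differ")
  }
  if (!is.null(sigma)) {
    sig <- rep_len(sigma, nrow(X))
    if (any(sig <= 0)) stop("sigma must be positive")
  } else if (nrow(X) < 2) {
    sig <- rep(1, nrow(X))     # single point: bandwidth is arbitrary
  } else {
    D <- sqrt(pairwise_sqdist(X, X))
    diag(D) <- Inf
    sig <- apply(D, 1, function(d)
      sort(d)[min(bandwidth_neighbor, nrow(X) - 1L)])
    sig[sig == 0] <- max(sig[sig > 0], 1e-12)
  }
  structure(list(X_train = X, Y_train = Y, sigma = sig, method = method,
                 bandwidth_neighbor = bandwidth_neighbor, pca = pca),
            class = "embedding_model")
}

# minimal diffusion map: Gaussian kernel with adaptive bandwidths,
# density-normalised transition operator, top nontrivial eigenvectors
.diffusion_map <- function(X, K = 2, bandwidth_neighbor = 15) {
  n <- nrow(X)
  D2 <- pairwise_sqdist(X, X)
  d <- sqrt(D2); diag(d) <- Inf
  sig <- apply(d, 1, function(r) sort(r)[min(bandwidth_neighbor, n - 1L)])
  sig[sig == 0] <- max(sig[sig > 0], 1e-12)
  W <- exp(-D2 / outer(sig, sig))       # symmetric adaptive kernel
  diag(W) <- 0
  q <- rowSums(W)
  W <- W / outer(q, q)                  # remove sampling-density bias
  dd <- rowSums(W)
  A <- W / sqrt(outer(dd, dd))          # symmetrised transition operator
  eig <- eigen(A, symmetric = TRUE)
  psi <- eig$vectors / sqrt(dd)
  Y <- psi[, seq(2, K + 1), drop = FALSE] *
    rep(eig$values[seq(2, K + 1)], each = n)
  colnames(Y) <- paste0("DC", seq_len(K))
  Y
}

#' Exact linear velocity projection by PCA
#'
#' Projects cells and their velocity endpoints with the same centred
#' linear map: starts are the PCA scores of `S`, ends are the scores of
#' `S + V` (a unit time step). The map is linear, so the visualised
#' arrow is exactly the projection of the high-dimensional velocity —
#' the reference every other visualisation is judged against.
#'
#' @param S processed spliced matrix (cells x genes).
#' @param V velocity matrix on the same genes.
#' @param K number of components.
#' @param fit optional existing `prcomp` fit to reuse.
#' @return list of class `projected_arrows`: `start`, `end` (cells x K)
#'   and the `prcomp` fit.
#' @export
pca_project <- function(S, V, K = 2, fit = NULL) {
  stopifnot(identical(dim(S), dim(V)))
  if (is.null(fit)) fit <- stats::prcomp(S, center = TRUE, rank. = K)
  K <- min(K, ncol(fit$rotation))
  rot <- fit$rotation[, seq_len(K), drop = FALSE]
  start <- sweep(as.matrix(S), 2, fit$center) %*% rot
  end <- sweep(as.matrix(S) + as.matrix(V), 2, fit$center) %*% rot
  structure(list(start = start, end = end, fit = fit,
                 flagged = logical(nrow(start))),
            class = "projected_arrows")
}

#' Nystrom transition matrix between test and train points
#'
#' Row-stochastic Gaussian kernel weights of each test point over the
#' training points:
#' \deqn{P'(i, j) = \exp(-\|x_i - x_j\|^2 / 2\sigma_i^2) / Z(i)}
#' with rows indexing test points, columns train points, and `Z(i)`
#' normalising over the train set. Bandwidths are adaptive per test
#' point (distance to its `bandwidth_neighbor`-th nearest train point)
#' unless the model carries fixed sigmas. Test points whose total
#' kernel mass vanishes (out of distribution) are flagged and given a
#' uniform fallback over their `bandwidth_neighbor` nearest train
#' points.
#'
#' @param model an [embedding_model()].
#' @param X_test test features in the same gene space as the training
#'   data.
#' @return list with `P` (n_test x n_train, rows sum to 1), logical
#'   `flagged` (out-of-distribution rows) and the per-row `sigma` used.
#' @export
nystrom_transition <- function(model, X_test) {
  stopifnot(inherits(model, "embedding_model"))
  X_test <- as.matrix(X_test)
  if (ncol(X_test) != ncol(model$X_train))
    stop("test points must live in the training gene space")
  D2 <- pairwise_sqdist(X_test, model$X_train)
  kb <- min(model$bandwidth_neighbor, nrow(model$X_train))
  sig <- apply(sqrt(D2), 1, function(d) sort(d)[kb])
  # adaptive per test point, but never wider than the largest train-side
  # bandwidth: otherwise far-out points would inflate their own sigma
  # and out-of-distribution detection would be impossible
  sig <- pmin(sig, max(model$sigma))
  sig[sig == 0] <- max(model$sigma)
  Wm <- exp(-D2 / (2 * sig^2))
  Z <- rowSums(Wm)
  flagged <- Z < 1e-12
  if (any(flagged)) {
    for (i in which(flagged)) {
      nn <- order(D2[i, ], seq_len(ncol(D2)))[seq_len(kb)]
      Wm[i, ] <- 0; Wm[i, nn] <- 1
    }
    Z <- rowSums(Wm)
  }
  list(P = Wm / Z, flagged = flagged, sigma = sig)
}

#' Nystrom out-of-sample coordinates
#'
#' `Y_test = P' %*% Y_train`: every projected point is a convex
#' combination of training coordinates, hence inside their convex hull.
#'
#' @param P row-stochastic transition matrix from [nystrom_transition()].
#' @param Y_train training coordinates (n_train x K).
#' @return n_test x K coordinate matrix.
#' @export
nystrom_project <- function(P, Y_train) {
  stopifnot(ncol(P) == nrow(Y_train))
  as.matrix(P) %*% as.matrix(Y_train)
}

#' Velocity arrows on an embedding via Nystrom projection
#'
#' Computes arrow endpoints as the Nystrom projection of the
#' velocity-displaced cells `S + delta V`. The global downscale factor
#' `delta` is chosen so that the largest displacement does not exceed
#' the `downscale_quantile` of nearest-neighbour distances among the
#' training points, keeping endpoints within the data support where the
#' Nystrom extension is valid; endpoints that still fall out of
#' distribution are flagged.
#'
#' @param model an [embedding_model()] fitted on the same retained-gene
#'   spliced counts.
#' @param S processed spliced matrix (usually `model$X_train`).
#' @param V velocity matrix on the same genes.
#' @param downscale_quantile quantile of train NN distances bounding the
#'   largest displacement (default 0.5, the median).
#' @return `projected_arrows` list: `start` (the Nystrom self-projection
#'   of `S`), `end`, `delta`, and per-cell `flagged`.
#' @details The arrow start is the Nystrom *self-projection* of `S`,
#'   not the raw training coordinates: the kernel projection smooths
#'   every point toward its neighbourhood, and taking both ends of the
#'   arrow through the same map cancels that shared displacement, so
#'   the arrow reflects the velocity rather than the smoothing.
#' @export
velocity_endpoints <- function(model, S, V, downscale_quantile = 0.5) {
  stopifnot(inherits(model, "embedding_model"),
            identical(dim(as.matrix(S)), dim(as.matrix(V))))
  S <- as.matrix(S); V <- as.matrix(V)
  Dtr <- sqrt(pairwise_sqdist(model$X_train, model$X_train))
  diag(Dtr) <- Inf
  nn_dist <- apply(Dtr, 1, min)
  target <- stats::quantile(nn_dist, downscale_quantile, names = FALSE)
  vmax <- max(sqrt(rowSums(V^2)))
  delta <- if (vmax > 0) target / vmax else 1
  start <- nystrom_project(nystrom_transition(model, S)$P,
                           model$Y_train)
  tr <- nystrom_transition(model, S + delta * V)
  structure(list(start = start,
                 end = nystrom_project(tr$P, model$Y_train),
                 delta = delta, flagged = tr$flagged),
            class = "projected_arrows")
}

#' Correlation-kernel projection baselines
#'
#' The neighbourhood-correlation velocity projection used by earlier
#' velocity tools, implemented faithfully *including its documented
#' defects* as a comparison baseline. Transition weights over the
#' neighbourhood of each cell are
#' `P_ij = exp(corr(rho(s_j - s_i), rho(v_i)) / sigma^2)` with
#' `rho(x) = sign(x) sqrt(|x|)` (variant `"rho"`) or
#' `P_ij = exp(cos(s_j - s_i, v_i) / sigma^2)` (variant `"cosine"`),
#' row-normalised; the visualised displacement is
#' \deqn{\Delta Y_i = \sum_j (P_{ij} - 1/n_i)
#'   \frac{Y_j - Y_i}{\|Y_j - Y_i\|}}
#' Because correlations ignore vector length, two velocities with equal
#' direction but different magnitude map to the same displacement.
#' Cells with zero velocity get `Delta Y = 0` by convention.
#'
#' @param S processed spliced matrix.
#' @param V velocity matrix.
#' @param Y embedding coordinates (cells x K).
#' @param sigma kernel width (default 0.1).
#' @param variant `"cosine"` (default) or `"rho"`.
#' @param n_neighbors neighbourhood size over which transitions are
#'   computed (default: all other cells).
#' @return cells x K matrix of displacements `Delta Y`.
#' @export
baseline_projection <- function(S, V, Y, sigma = 0.1,
                                variant = c("cosine", "rho"),
                                n_neighbors = NULL) {
  variant <- match.arg(variant)
  S <- as.matrix(S); V <- as.matrix(V); Y <- as.matrix(Y)
  n <- nrow(S)
  if (is.null(n_neighbors)) n_neighbors <- n - 1L
  nn <- knn_index(S, n_neighbors)
  rho <- function(x) sign(x) * sqrt(abs(x))
  dY <- matrix(0, n, ncol(Y))
  for (i in seq_len(n)) {
    vi <- V[i, ]
    if (all(vi == 0)) next
    js <- nn[i, ]
    dS <- S[js, , drop = FALSE] - rep(S[i, ], each = length(js))
    sim <- if (variant == "rho") {
      apply(dS, 1, function(x) {
        r <- suppressWarnings(stats::cor(rho(x), rho(vi)))
        if (is.na(r)) 0 else r
      })
    } else {
      den <- sqrt(rowSums(dS^2)) * sqrt(sum(vi^2))
      ifelse(den > 0, (dS %*% vi) / den, 0)
    }
    P <- exp(sim / sigma^2)
    P <- P / sum(P)
    dYe <- Y[js, , drop = FALSE] - rep(Y[i, ], each = length(js))
    len <- sqrt(rowSums(dYe^2))
    ok <- len > 0
    w <- (P - 1 / length(js))[ok] / len[ok]
    dY[i, ] <- colSums(dYe[ok, , drop = FALSE] * w)
  }
  dY
}
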