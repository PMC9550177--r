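#' Select highly variable genes by analytic Pearson residuals
#'
#' Ranks genes by the variance of their analytic Pearson residuals on the
#' spliced counts under the null model `mu_cg = rowsum_c * colsum_g /
#' grand_sum` with overdispersion `theta`:
#' \deqn{r_{cg} = (x_{cg} - \mu_{cg}) / \sqrt{\mu_{cg} + \mu_{cg}^2/\theta}}
#' Residuals are clipped at `sqrt(n_cells)`; genes with zero expected
#' counts get residual 0. Returns the indices of the `n_top` genes with
#' the largest residual variance, in decreasing order (ties broken by
#' gene index, so an exactly-null matrix falls back to input order).
#'
#' @param data a raw-count [velocity_dataset()].
#' @param n_top number of genes to keep; values exceeding the gene count
#'   return all genes with a warning.
#' @param theta overdispersion of the negative-binomial null (default
#'   100).
#' @return integer vector of selected gene indices, ordered.
#' @export
select_variable_genes <- function(data, n_top, theta = 100) {
  stopifnot(inherits(data, "velocity_dataset"), theta > 0)
  X <- data$S
  G <- ncol(X)
  if (n_top > G) {
    warning(sprintf("n_top (%d) exceeds gene count (%d); returning all genes",
                    n_top, G))
    n_top <- G
  }
  rs <- rowSums(X); cs <- colSums(X); tot <- sum(X)
  if (tot == 0) return(seq_len(n_top))
  mu <- outer(rs, cs) / tot
  r <- (X - mu) / sqrt(mu + mu^2 / theta)
  r[mu == 0] <- 0
  clip <- sqrt(nrow(X))
  r <- pmin(pmax(r, -clip), clip)
  v <- apply(r, 2, stats::var)
  order(v, decreasing = TRUE)[seq_len(n_top)]
}

#' Filter genes with insufficient unspliced or spliced counts
#'
#' Retains genes for which the fraction of cells with a nonzero unspliced
#' count is at least `min_u_frac` and the fraction with a nonzero spliced
#' count is at least `min_s_frac`. Velocity signal lives in genes
#' observed in both modalities; low-count genes produce unreliable
#' imputed portraits.
#'
#' @param data a [velocity_dataset()].
#' @param min_u_frac,min_s_frac thresholds in `[0, 1]` (defaults 0.05 and
#'   0.10).
#' @return integer vector of surviving gene indices.
#' @export
filter_low_count_genes <- function(data, min_u_frac = 0.05,
                                   min_s_frac = 0.10) {
  stopifnot(inherits(data, "velocity_dataset"),
            min_u_frac >= 0, min_u_frac <= 1,
            min_s_frac >= 0, min_s_frac <= 1)
  fu <- colMeans(data$U > 0)
  fs <- colMeans(data$S > 0)
  unname(which(fu >= min_u_frac & fs >= min_s_frac))
}

#' Joint size normalisation of unspliced and spliced counts
#'
#' The size of a cell is represented by its unspliced and spliced counts
#' together, so each cell's U row and S row are multiplied by the *same*
#' factor `target / (sum_g u + sum_g s)`. Sharing the factor preserves
#' every within-cell u:s ratio exactly — separate per-modality
#' normalisation distorts phase portraits whenever the total-u/total-s
#' ratio varies across cell types.
#'
#' @param data a raw [velocity_dataset()].
#' @param target post-normalisation per-cell total; default the median
#'   pre-normalisation total.
#' @return the normalised dataset (stage `"normalised"`); cells with zero
#'   total are removed with a warning.
#' @export
joint_size_normalise <- function(data, target = NULL) {
  stopifnot(inherits(data, "velocity_dataset"))
  tot <- rowSums(data$U) + rowSums(data$S)
  if (any(tot == 0)) {
    warning(sprintf("removing %d cell(s) with zero total counts",
                    sum(tot == 0)))
    data <- subset_dataset(data, cells = tot > 0)
    tot <- tot[tot > 0]
  }
  if (is.null(target)) target <- stats::median(tot)
  f <- target / tot
  out <- data
  out$U <- data$U * f
  out$S <- data$S * f
  .advance_stage(out, required = "raw", new = "normalised")
}

#' k-nearest-neighbour imputation of counts
#'
#' Replaces each cell's u and s vectors by the mean over the cell itself
#' and its `k` nearest neighbours (self weighted like a neighbour). The
#' neighbour graph is built in the space of the top `n_pcs` principal
#' components of the per-gene z-scaled spliced counts; neighbour ties are
#' broken by cell index for determinism. `k = 0` is the identity.
#'
#' @param data a normalised [velocity_dataset()].
#' @param k neighbour count, `0 <= k < n_cells`.
#' @param n_pcs number of principal components (capped at the data rank).
#' @return the imputed dataset (stage `"imputed"`).
#' @export
knn_impute <- function(data, k = 30, n_pcs = 30) {
  stopifnot(inherits(data, "velocity_dataset"), k >= 0)
  n <- nrow(data$S)
  if (k >= n) stop("k must be smaller than the number of cells")
  out <- data
  if (k > 0) {
    Z <- scale(data$S)
    Z[!is.finite(Z)] <- 0      # constant genes scale to NaN
    attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
    n_pcs <- min(n_pcs, n - 1, ncol(Z))
    P <- stats::prcomp(Z, center = FALSE, rank. = n_pcs)$x
    nn <- knn_index(P, k)
    U <- data$U; S <- data$S
    Ui <- Si <- matrix(0, n, ncol(U))
    for (i in seq_len(n)) {
      idx <- c(i, nn[i, ])
      Ui[i, ] <- colMeans(U[idx, , drop = FALSE])
      Si[i, ] <- colMeans(S[idx, , drop = FALSE])
    }
    dimnames(Ui) <- dimnames(Si) <- dimnames(U)
    out$U <- Ui; out$S <- Si
  }
  .advance_stage(out, required = "normalised", new = "imputed")
}

#' Eco-velo normalisation: log, separate size factors, L2
#'
#' The unspliced and spliced matrices are treated as two modalities to be
#' matched by nearest-neighbour search: nonzero counts are
#' log-transformed (`log1p`), each modality is size-normalised separately
#' to its own per-cell total (target: the modality's median total), and
#' finally every cell vector is scaled to unit Euclidean norm within each
#' modality, the standard preparation for mutual-nearest-neighbour
#' matching.
#'
#' @param data a raw (filtered) [velocity_dataset()].
#' @return list with matrices `U` and `S`, each with unit-norm rows;
#'   cells with a zero-norm vector in either modality are an error.
#' @export
eco_normalise <- function(data) {
  stopifnot(inherits(data, "velocity_dataset"))
  norm_one <- function(X) {
    X <- log1p(X)
    tot <- rowSums(X)
    if (any(tot == 0)) stop("cell with zero counts in one modality")
    X <- X * (stats::median(tot) / tot)
    l2 <- sqrt(rowSums(X^2))
    X / l2
  }
  list(U = norm_one(data$U), S = norm_one(data$S))
}

#' Run the kappa-velo processing pipeline
#'
#' Convenience chain: variable-gene selection (Pearson residuals on S),
#' low-count gene filtering, joint size normalisation and kNN imputation,
#' in that order, with per-stage gene/cell counts recorded in the
#' `"processing_log"` attribute.
#'
#' @param data a raw [velocity_dataset()].
#' @param n_top number of variable genes (default: all genes).
#' @param min_u_frac,min_s_frac low-count thresholds, see
#'   [filter_low_count_genes()].
#' @param k,n_pcs imputation parameters, see [knn_impute()]; `k = 0`
#'   skips imputation smoothing but still marks the data imputed.
#' @param theta Pearson-residual overdispersion.
#' @return processed [velocity_dataset()].
#' @export
process_kvelo <- function(data, n_top = ncol(data$U), min_u_frac = 0.05,
                          min_s_frac = 0.10, k = 30, n_pcs = 30,
                          theta = 100) {
  log <- list()
  g0 <- ncol(data$U)
  keep <- select_variable_genes(data, n_top = n_top, theta = theta)
  data <- subset_dataset(data, genes = sort(keep))
  log$variable_genes <- c(before = g0, after = ncol(data$U))
  g1 <- ncol(data$U)
  keep <- filter_low_count_genes(data, min_u_frac, min_s_frac)
  data <- subset_dataset(data, genes = keep)
  log$low_count <- c(before = g1, after = ncol(data$U))
  data <- joint_size_normalise(data)
  data <- knn_impute(data, k = k, n_pcs = n_pcs)
  attr(data, "processing_log") <- log
  data
}
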