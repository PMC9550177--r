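#' Workflow configuration
#'
#' All thresholds, neighbour counts and seeds used by the composite
#' workflows, with defaults matching the individual stage functions.
#' The config is a plain named list so it serialises cleanly (e.g. with
#' `jsonlite`) next to run outputs; re-running with the same config and
#' seed reproduces every deterministic stage bit for bit.
#'
#' @param mode `"kvelo"`, `"eco"` or `"simulate"`.
#' @param n_top,min_u_frac,min_s_frac,theta gene-selection/filter
#'   settings, see [select_variable_genes()] and
#'   [filter_low_count_genes()].
#' @param impute_k,impute_pcs imputation settings, see [knn_impute()].
#' @param likelihood_quantile post-fit likelihood filter, see
#'   [filter_by_likelihood()].
#' @param hierarchy optional cluster order, see
#'   [filter_by_cluster_order()].
#' @param n_pairs,coverage kappa-estimator settings, see
#'   [estimate_kappa()].
#' @param mnn_k,arrow_scale eco-velo settings.
#' @param embed_method,embed_dims embedding provider settings.
#' @param downscale_quantile Nystrom endpoint downscaling.
#' @param rng_seed integer seed for every stochastic stage.
#' @return named list of class `run_config`.
#' @export
run_config <- function(mode = c("kvelo", "eco", "simulate"),
                       n_top = NULL, min_u_frac = 0.05, min_s_frac = 0.10,
                       theta = 100, impute_k = 30, impute_pcs = 30,
                       likelihood_quantile = 0.5, hierarchy = NULL,
                       n_pairs = 2000, coverage = 0.95,
                       mnn_k = 5, arrow_scale = 0.5,
                       embed_method = "pca", embed_dims = 2,
                       downscale_quantile = 0.5, rng_seed = 0L) {
  structure(list(mode = match.arg(mode), n_top = n_top,
                 min_u_frac = min_u_frac, min_s_frac = min_s_frac,
                 theta = theta, impute_k = impute_k,
                 impute_pcs = impute_pcs,
                 likelihood_quantile = likelihood_quantile,
                 hierarchy = hierarchy, n_pairs = n_pairs,
                 coverage = coverage, mnn_k = mnn_k,
                 arrow_scale = arrow_scale, embed_method = embed_method,
                 embed_dims = embed_dims,
                 downscale_quantile = downscale_quantile,
                 rng_seed = as.integer(rng_seed)),
            class = c("run_config", "list"))
}

#' Run a complete velocity workflow
#'
#' Executes the staged pipeline on a raw dataset:
#' * `kvelo`: processing (variable genes, count filter, joint
#'   normalisation, kNN imputation) -> per-gene EM fits -> likelihood
#'   and cluster-order gene filters -> kappa recovery -> scaled
#'   parameters and velocity field -> embedding and Nystrom-projected
#'   arrows.
#' * `eco`: count filter -> eco normalisation -> mutual nearest
#'   neighbours -> embedding -> arrows.
#' Per-stage gene/cell counts are recorded in the returned `log` so the
#' full gene-attrition path can be reconstructed.
#'
#' @param data a raw [velocity_dataset()].
#' @param config a [run_config()].
#' @return named list of stage artefacts (contents depend on the mode)
#'   plus `log`, a data.frame of `(stage, n_before, n_after, rule)` rows.
#' @export
run_workflow <- function(data, config = run_config()) {
  stopifnot(inherits(data, "velocity_dataset"),
            inherits(config, "run_config"))
  log <- data.frame(stage = character(), n_before = integer(),
                    n_after = integer(), rule = character(),
                    stringsAsFactors = FALSE)
  note <- function(stage, before, after, rule) {
    log[nrow(log) + 1L, ] <<- list(stage, before, after, rule)
  }

  if (config$mode == "eco") {
    g0 <- ncol(data$U)
    keep <- filter_low_count_genes(data, config$min_u_frac,
                                   config$min_s_frac)
    data <- subset_dataset(data, genes = keep)
    note("filter_low_count", g0, ncol(data$U),
         sprintf("u_frac>=%g & s_frac>=%g", config$min_u_frac,
                 config$min_s_frac))
    norm <- eco_normalise(data)
    mnn <- mutual_nearest_neighbors(norm$U, norm$S, k = config$mnn_k)
    model <- embedding_model(norm$S, method = config$embed_method,
                             K = config$embed_dims)
    arrows <- eco_arrows(mnn, model$Y_train, scale = config$arrow_scale)
    note("mnn", nrow(data$U), sum(arrows$has_arrow), "cells with MNNs")
    return(list(data = data, normalised = norm, mnn = mnn,
                embedding = model, arrows = arrows, log = log,
                config = config))
  }

  # kvelo mode
  n_top <- if (is.null(config$n_top)) ncol(data$U) else config$n_top
  proc <- process_kvelo(data, n_top = n_top,
                        min_u_frac = config$min_u_frac,
                        min_s_frac = config$min_s_frac,
                        k = config$impute_k, n_pcs = config$impute_pcs,
                        theta = config$theta)
  plog <- attr(proc, "processing_log")
  note("variable_genes", plog$variable_genes["before"],
       plog$variable_genes["after"], "Pearson-residual variance")
  note("filter_low_count", plog$low_count["before"],
       plog$low_count["after"],
       sprintf("u_frac>=%g & s_frac>=%g", config$min_u_frac,
               config$min_s_frac))

  fits <- lapply(seq_len(ncol(proc$U)), function(g)
    fit_gene_em(proc$U[, g], proc$S[, g],
                config = em_config(rng_seed = config$rng_seed)))
  names(fits) <- proc$gene_ids

  g0 <- length(fits)
  keep <- filter_by_likelihood(fits, quantile = config$likelihood_quantile)
  note("filter_likelihood", g0, length(keep),
       sprintf("top %g by likelihood", config$likelihood_quantile))
  if (!is.null(config$hierarchy)) {
    keep2 <- filter_by_cluster_order(fits[keep], proc$cell_type,
                                     config$hierarchy)
    note("filter_cluster_order", length(keep), length(keep2),
         "fitted order matches hierarchy")
    keep <- keep[keep2]
  }
  proc <- subset_dataset(proc, genes = keep)
  fits <- fits[keep]

  kappas <- recover_kappas(proc, fits, n_pairs = config$n_pairs,
                           coverage = config$coverage,
                           rng_seed = config$rng_seed)
  note("kappa", length(fits), sum(is.finite(kappas$kappa)),
       "kappa estimate available")
  scaled <- assemble_scaled(fits, kappas)
  proc_v <- subset_dataset(proc,
                           genes = match(scaled$gene_id, proc$gene_ids))
  V <- velocity_field(scaled, proc_v)

  model <- embedding_model(proc_v$S, method = config$embed_method,
                           K = config$embed_dims)
  arrows <- velocity_endpoints(model, proc_v$S, V,
                               downscale_quantile =
                                 config$downscale_quantile)
  list(data = proc_v, fits = fits, kappas = kappas, scaled = scaled,
       velocity = V, embedding = model, arrows = arrows, log = log,
       config = config)
}
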