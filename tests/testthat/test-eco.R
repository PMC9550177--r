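# Mutual-nearest-neighbour velocity estimation and its theoretical basis.

l2_rows <- function(X) X / sqrt(rowSums(X^2))

brute_mnn <- function(U, S, k, include_self = FALSE) {
  n <- nrow(U)
  D <- as.matrix(stats::dist(rbind(U, S)))[seq_len(n),
                                           n + seq_len(n), drop = FALSE]
  knn_us <- lapply(seq_len(n), function(i)
    order(D[i, ], seq_len(n))[1:k])          # kNN of u_i among s_j
  knn_su <- lapply(seq_len(n), function(j)
    order(D[, j], seq_len(n))[1:k])          # kNN of s_j among u_i
  lapply(seq_len(n), function(i) {
    m <- knn_us[[i]][vapply(knn_us[[i]],
                            function(j) i %in% knn_su[[j]], logical(1))]
    if (!include_self) m <- m[m != i]
    as.integer(m)
  })
}

test_that("MNN sets equal brute-force double-kNN enumeration", {
  set.seed(31)
  for (n in c(30, 100)) {
    U <- l2_rows(matrix(runif(n * 6), n, 6))
    S <- l2_rows(matrix(runif(n * 6), n, 6))
    for (k in c(1, 5, 10)) {
      mnn <- mutual_nearest_neighbors(U, S, k = k)
      expect_identical(mnn$neighbors, brute_mnn(U, S, k))
    }
  }
})

test_that("MNN output is equivariant under cell permutation", {
  set.seed(32)
  n <- 40
  U <- l2_rows(matrix(runif(n * 5), n, 5))
  S <- l2_rows(matrix(runif(n * 5), n, 5))
  p <- sample(n)
  mnn <- mutual_nearest_neighbors(U, S, k = 5)
  mnn_p <- mutual_nearest_neighbors(U[p, ], S[p, ], k = 5)
  for (i in seq_len(n)) {
    q <- match(i, p)   # position of original cell i after permutation
    expect_identical(sort(p[mnn_p$neighbors[[q]]]),
                     sort(mnn$neighbors[[i]]))
  }
})

test_that("identical modalities self-match; saturation recovers plain kNN", {
  set.seed(33)
  n <- 25
  X <- l2_rows(matrix(runif(n * 4), n, 4))
  # with U == S each cell's nearest cross-neighbour is itself; the
  # default self-exclusion leaves no distance-zero matches
  mnn_self <- mutual_nearest_neighbors(X, X, k = 3, include_self = TRUE)
  expect_true(all(vapply(seq_len(n),
                         function(i) i %in% mnn_self$neighbors[[i]],
                         logical(1))))
  mnn_no <- mutual_nearest_neighbors(X, X, k = 3)
  expect_true(all(vapply(seq_len(n),
                         function(i) !(i %in% mnn_no$neighbors[[i]]),
                         logical(1))))
  # k = n - 1: every cross-NN is mutual
  U <- l2_rows(matrix(runif(n * 4), n, 4))
  S <- l2_rows(matrix(runif(n * 4), n, 4))
  mnn_sat <- mutual_nearest_neighbors(U, S, k = n - 1)
  expect_identical(mnn_sat$neighbors, brute_mnn(U, S, n - 1))
  expect_error(mutual_nearest_neighbors(U, S, k = n))
})

test_that("eco arrows point toward the MNN mean, shrunk by the scale", {
  Y <- rbind(c(0, 0), c(2, 0), c(0, 2), c(4, 4))
  mnn <- structure(list(neighbors = list(2L, integer(0), c(2L, 4L), 1L),
                        k = 2), class = "mnn_result")
  ar <- eco_arrows(mnn, Y, scale = 0.5)
  expect_equal(unlist(ar[1, 3:4]), c(1, 0), ignore_attr = TRUE)
  expect_false(ar$has_arrow[2])
  expect_equal(unlist(ar[2, 3:4]), Y[2, ], ignore_attr = TRUE)
  expect_equal(unlist(ar[3, 3:4]), c(0 + 0.5 * 3, 2 + 0.5 * 0),
               ignore_attr = TRUE)
  # two MNNs symmetric about the cell cancel to a zero-length arrow
  mnn2 <- structure(list(neighbors = list(c(2L, 3L), integer(0),
                                          integer(0)), k = 2),
                    class = "mnn_result")
  Y2 <- rbind(c(1, 1), c(0, 0), c(2, 2))
  ar2 <- eco_arrows(mnn2, Y2, scale = 1)
  expect_equal(unlist(ar2[1, 3:4]), Y2[1, ], ignore_attr = TRUE)
})

test_that("future-state identity holds for shared rates and fails for spread rates", {
  # the identity s(t + 1/gamma) = (beta/gamma) u(t) is a first-order
  # expansion, exact at steady state; long upregulation dwell provides
  # deeply equilibrated cells to verify it on
  rates <- sample_gene_rates(10, kappa_range = c(1, 1), beta = 1.2,
                             gamma = 1.2, rng_seed = 41L)
  sim <- simulate_cells(rates, n_cells = 400, noise_sd = 0,
                        transient_span = 25, switch_frac = 0.95,
                        rng_seed = 41L)
  chk <- future_state_check(sim$truth, steady_frac = 1e-6)
  expect_equal(chk$factor, 1)
  expect_true(chk$ok)
  expect_lt(median(chk$per_gene$median_rel_error, na.rm = TRUE), 1e-6)
  # beta = 2 gamma: proportionality constant 2
  # the splicing clock (beta) is twice the degradation clock (gamma):
  # equilibration follows the slower gamma clock, so dwell longer
  r2 <- sample_gene_rates(5, kappa_range = c(1, 1), beta = 2,
                          gamma = 1, rng_seed = 42L)
  s2 <- simulate_cells(r2, n_cells = 300, noise_sd = 0,
                       transient_span = 45, switch_frac = 0.95,
                       rng_seed = 42L)
  chk2 <- future_state_check(s2$truth, steady_frac = 1e-6)
  expect_equal(chk2$factor, 2)
  expect_true(chk2$ok)
  # heterogeneous rates break the shared clock and shared factor even
  # for fully equilibrated cells
  rh <- sample_gene_rates(20, kappa_range = c(1, 15), rng_seed = 43L)
  sh <- simulate_cells(rh, n_cells = 300, noise_sd = 0,
                       transient_span = 25, switch_frac = 0.95,
                       rng_seed = 43L)
  chk3 <- future_state_check(sh$truth, steady_frac = 1e-6)
  expect_false(chk3$ok)
})

test_that("eco arrows track true displacement on shared-rate simulation", {
  rates <- sample_gene_rates(30, kappa_range = c(1, 1), beta = 1,
                             gamma = 1, rng_seed = 44L)
  sim <- simulate_cells(rates, n_cells = 300, noise_sd = 0,
                        rng_seed = 44L)
  en <- eco_normalise(sim$data)
  mnn <- mutual_nearest_neighbors(en$U, en$S, k = 5)
  pc <- prcomp(sim$data$S, rank. = 2)
  Y <- pc$x
  ar <- eco_arrows(mnn, Y, scale = 1)
  # truth: the embedded displacement to each cell's state 1/gamma later
  dt <- 1 / median(sim$truth$rates$G)
  S_fut <- sapply(seq_len(nrow(rates)), function(g) {
    p <- gene_params(alpha = sim$truth$rates$A[g],
                     beta = sim$truth$rates$B[g],
                     gamma = sim$truth$rates$G[g],
                     t_switch = sim$truth$tau_switch[g])
    kinetics_trajectory(p, pmax(0, sim$truth$t - sim$truth$t_act[g]) +
                          dt)$s
  })
  dY_true <- (sweep(S_fut, 2, pc$center) %*% pc$rotation[, 1:2]) - Y
  dY_eco <- as.matrix(ar[, 3:4]) - Y
  has <- ar$has_arrow & sqrt(rowSums(dY_true^2)) > 1e-8
  expect_gt(sum(has), 50)
  A <- dY_true[has, , drop = FALSE]; B <- dY_eco[has, , drop = FALSE]
  cosines <- rowSums(A * B) /
    (sqrt(rowSums(A^2)) * sqrt(rowSums(B^2)))
  expect_gte(median(cosines), 0.9)
})
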