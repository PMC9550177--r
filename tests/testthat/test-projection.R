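# Velocity visualisation: exact PCA projection, Nystrom out-of-sample
# projection, the correlation-kernel baselines and evaluation metrics.

test_that("PCA projection equals the explicit centred linear map", {
  set.seed(51)
  S <- matrix(rnorm(40 * 6, 10), 40, 6)
  V <- matrix(rnorm(40 * 6, 0, 0.3), 40, 6)
  pr <- pca_project(S, V, K = 3)
  ctr <- colMeans(S)
  rot <- prcomp(S, center = TRUE)$rotation[, 1:3]
  # signs of principal axes are arbitrary; compare via the fitted map
  expect_equal(pr$start, sweep(S, 2, ctr) %*% pr$fit$rotation[, 1:3],
               tolerance = 1e-10)
  expect_equal(pr$end - pr$start, V %*% pr$fit$rotation[, 1:3],
               tolerance = 1e-10)
  expect_equal(abs(pr$fit$rotation[, 1:3]), abs(rot),
               tolerance = 1e-10, ignore_attr = TRUE)
  # exactly linear: projecting a*V scales arrows by a
  pr2 <- pca_project(S, 2.5 * V, K = 3, fit = pr$fit)
  expect_equal(pr2$end - pr2$start, 2.5 * (pr$end - pr$start),
               tolerance = 1e-12)
  # V = 0 gives zero-length arrows
  pr0 <- pca_project(S, V * 0, K = 2)
  expect_equal(pr0$end, pr0$start)
  # V along the first principal axis moves arrows on axis 1 only
  v1 <- matrix(rep(pr$fit$rotation[, 1], each = 40), 40, 6)
  pr1 <- pca_project(S, v1, K = 3, fit = pr$fit)
  d <- pr1$end - pr1$start
  expect_equal(d[, 2:3], matrix(0, 40, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(d[, 1], rep(1, 40), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("Nystrom transition rows are stochastic Gaussian weights", {
  set.seed(52)
  Xtr <- matrix(rnorm(30 * 4), 30, 4)
  model <- embedding_model(Xtr, method = "pca", K = 2)
  Xte <- matrix(rnorm(12 * 4), 12, 4)
  tr <- nystrom_transition(model, Xte)
  expect_true(all(tr$P >= 0))
  expect_equal(rowSums(tr$P), rep(1, 12), tolerance = 1e-12)
  # hand-computed Gaussian weights on a 5 x 3 toy with the sigma used
  Xtr2 <- matrix(c(0, 0, 1, 0, 0, 1, 2, 2, 3, 3), 5, 2)
  m2 <- embedding_model(Xtr2, method = "pca", K = 1,
                        bandwidth_neighbor = 2)
  Xte2 <- matrix(c(0.5, 1.5, 2.5, 0.5, 1.5, 2.5), 3, 2)
  tr2 <- nystrom_transition(m2, Xte2)
  for (i in 1:3) {
    w <- exp(-rowSums(sweep(Xtr2, 2, Xte2[i, ])^2) / (2 * tr2$sigma[i]^2))
    expect_equal(tr2$P[i, ], w / sum(w), tolerance = 1e-12)
  }
  # a test point equidistant from two train points splits evenly
  m1 <- embedding_model(rbind(c(0, 0), c(2, 0)), method = "pca", K = 1,
                        bandwidth_neighbor = 1)
  teq <- nystrom_transition(m1, rbind(c(1, 0)))
  expect_equal(as.numeric(teq$P), c(0.5, 0.5), tolerance = 1e-12)
  # n_train = 1 forces the whole row onto the single column
  ms <- embedding_model(matrix(c(0, 0), 1, 2), method = "pca", K = 1)
  expect_equal(as.numeric(nystrom_transition(ms, rbind(c(5, 5)))$P), 1)
})

test_that("Nystrom projection is a convex combination of train coordinates", {
  set.seed(53)
  Xtr <- matrix(rnorm(40 * 5), 40, 5)
  model <- embedding_model(Xtr, method = "pca", K = 2)
  # one-hot transition copies train coordinates
  P1 <- diag(40)[c(3, 7), ]
  expect_equal(nystrom_project(P1, model$Y_train),
               model$Y_train[c(3, 7), ], ignore_attr = TRUE)
  # uniform row lands on the centroid
  Pu <- matrix(1 / 40, 1, 40)
  expect_equal(as.numeric(nystrom_project(Pu, model$Y_train)),
               unname(colMeans(model$Y_train)))
  # projected points lie inside the convex hull: test via support
  # functions over random directions (max over hull >= projected value)
  tr <- nystrom_transition(model, Xtr + matrix(rnorm(200, 0, 0.1), 40, 5))
  Yt <- nystrom_project(tr$P, model$Y_train)
  for (rep in 1:25) {
    dir <- rnorm(2)
    expect_true(all(Yt %*% dir <= max(model$Y_train %*% dir) + 1e-10))
    expect_true(all(Yt %*% dir >= min(model$Y_train %*% dir) - 1e-10))
  }
  # self-projection with adaptive bandwidths stays local
  trs <- nystrom_transition(model, Xtr)
  Ys <- nystrom_project(trs$P, model$Y_train)
  D <- as.matrix(dist(model$Y_train)); diag(D) <- Inf
  med_nn <- median(apply(D, 1, min))
  displacement <- sqrt(rowSums((Ys - model$Y_train)^2))
  expect_lt(median(displacement), 3 * med_nn)
})

test_that("velocity endpoints are downscaled into the data support", {
  sim <- kv_small_sim(0)
  S <- sim$data$S
  V <- sim$truth$velocity
  model <- embedding_model(S, method = "pca", K = 2)
  ve <- velocity_endpoints(model, S, V, downscale_quantile = 0.5)
  # start is the self-projection, so both arrow ends share the kernel
  # smoothing and it cancels in the displacement
  self_proj <- nystrom_project(nystrom_transition(model, S)$P,
                               model$Y_train)
  expect_equal(ve$start, self_proj)
  Dtr <- as.matrix(dist(S)); diag(Dtr) <- Inf
  target <- median(apply(Dtr, 1, min))
  expect_lte(max(sqrt(rowSums((ve$delta * V)^2))), target + 1e-12)
  # V = 0: endpoints coincide with the starts exactly
  v0 <- velocity_endpoints(model, S, V * 0)
  expect_equal(v0$end, v0$start)
  # far out-of-distribution endpoints are flagged
  tr_far <- nystrom_transition(model, S + 1e6)
  expect_true(all(tr_far$flagged))
})

test_that("Nystrom arrows agree with exact PCA arrows on simulation", {
  sim <- kv_small_sim(0)
  S <- sim$data$S; V <- sim$truth$velocity
  model <- embedding_model(S, method = "pca", K = 2)
  ve <- velocity_endpoints(model, S, V)
  dY_nys <- ve$end - ve$start
  pr <- pca_project(S, ve$delta * V, K = 2, fit = model$pca)
  dY_pca <- pr$end - pr$start
  ok <- sqrt(rowSums(dY_pca^2)) > 1e-10 & !ve$flagged
  cosines <- rowSums(dY_nys[ok, ] * dY_pca[ok, ]) /
    (sqrt(rowSums(dY_nys[ok, ]^2)) * sqrt(rowSums(dY_pca[ok, ]^2)))
  expect_gte(median(cosines), 0.9)
})

test_that("baseline projection reproduces its length-collapse defect", {
  # two cells with velocities equal in direction, lengths 1 and 10,
  # identical neighbourhoods: identical displacements
  set.seed(54)
  S <- rbind(c(0, 0), c(0.1, 0), c(1, 0.5), c(0.4, 1), c(1, 1.4),
             c(0.2, 0.7))
  Y <- S[, 1:2]
  v <- c(1, 0.3)
  V1 <- rbind(v, v * 10, c(0, 1), c(1, 1), c(0.5, 0), c(0.2, 0.2))
  dY <- baseline_projection(S, V1, Y, sigma = 0.3, variant = "cosine")
  # cells 1 and 2 sit close together with parallel velocities of very
  # different length; the correlation kernel cannot tell them apart
  V2 <- V1; V2[1, ] <- v * 10
  dY2 <- baseline_projection(S, V2, Y, sigma = 0.3, variant = "cosine")
  expect_equal(dY[1, ], dY2[1, ], tolerance = 1e-12)
  # zero-velocity cells get zero displacement by convention
  V3 <- V1; V3[4, ] <- 0
  expect_equal(baseline_projection(S, V3, Y, sigma = 0.3)[4, ], c(0, 0))
})

test_that("baseline projection matches a hand-computed toy", {
  S <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 0), c(0, 2))
  Y <- S
  V <- rbind(c(1, 0), c(0, 1), c(1, 1), c(-1, 0), c(0, -1), c(1, -1))
  sigma <- 0.5
  for (variant in c("cosine", "rho")) {
    got <- baseline_projection(S, V, Y, sigma = sigma, variant = variant)
    rho <- function(x) sign(x) * sqrt(abs(x))
    for (i in 1:6) {
      js <- setdiff(1:6, i)
      sim <- sapply(js, function(j) {
        dS <- S[j, ] - S[i, ]
        if (variant == "rho") {
          r <- suppressWarnings(cor(rho(dS), rho(V[i, ])))
          if (is.na(r)) 0 else r
        } else {
          sum(dS * V[i, ]) / (sqrt(sum(dS^2)) * sqrt(sum(V[i, ]^2)))
        }
      })
      P <- exp(sim / sigma^2); P <- P / sum(P)
      dYe <- t(t(Y[js, ]) - Y[i, ])
      len <- sqrt(rowSums(dYe^2))
      expect_equal(got[i, ], colSums(dYe * (P - 1 / 5) / len),
                   tolerance = 1e-12)
    }
  }
  # a symmetric neighbourhood with uniform weights cancels exactly:
  # velocity orthogonal to every displacement gives sim = 0 uniformly
  Ssym <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0))
  Vz <- rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))
  Ysym <- rbind(c(0, 0), c(1, 0), c(-1, 0))
  dYs <- baseline_projection(Ssym, Vz, Ysym, sigma = 1)
  expect_equal(dYs[1, ], c(0, 0), tolerance = 1e-12)
})

test_that("velocity evaluation returns cosine and signed norm difference", {
  A <- rbind(c(1, 0), c(0, 2), c(1, 1))
  ev_same <- evaluate_velocities(A, A)
  expect_equal(ev_same$cosine, rep(1, 3))
  expect_equal(ev_same$norm_diff, rep(0, 3))
  ev_opp <- evaluate_velocities(-A, A)
  expect_equal(ev_opp$cosine, rep(-1, 3))
  expect_equal(ev_opp$norm_diff, rep(0, 3))
  # zero vectors give NA cosine
  B <- A; B[2, ] <- 0
  expect_true(is.na(evaluate_velocities(B, A)$cosine[2]))
  # orthogonal vectors: cosine 0 regardless of normalisation
  X <- rbind(c(1, 0), c(0, 1e-9))
  Yv <- rbind(c(0, 2), c(1e-9, 0))
  expect_equal(evaluate_velocities(X, Yv)$cosine, c(0, 0))
})

test_that("diffusion-map provider returns orthogonal-ish coordinates and projects", {
  sim <- kv_small_sim(0)
  S <- sim$data$S[1:100, ]
  model <- embedding_model(S, method = "diffmap", K = 2)
  expect_equal(dim(model$Y_train), c(100, 2))
  tr <- nystrom_transition(model, S)
  expect_equal(rowSums(tr$P), rep(1, 100), tolerance = 1e-12,
               ignore_attr = TRUE)
  # unsupported provider without coordinates is an explicit error
  expect_error(embedding_model(S, method = "tsne"), "precomputed")
  # precomputed coordinates are accepted for any tag
  m2 <- embedding_model(S, method = "tsne", Y = model$Y_train)
  expect_equal(m2$Y_train, model$Y_train)
})
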