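# Closed-form kinetics against an independent ODE integration and the
# model's structural identities.

test_that("closed-form solutions match numerical ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (rep in 1:20) {
    alpha <- runif(1, 0.5, 5); beta <- runif(1, 0.2, 3)
    gamma <- runif(1, 0.2, 3)
    u0 <- runif(1, 0, 2); s0 <- runif(1, 0, 2)
    phase <- sample(0:1, 1)
    a_eff <- if (phase == 1) alpha else 0
    p <- gene_params(alpha = alpha, beta = beta, gamma = gamma,
                     u0 = u0, s0 = s0)
    rhs <- function(t, y, parms)
      list(c(a_eff - beta * y[1], beta * y[1] - gamma * y[2]))
    out <- deSolve::ode(c(u = u0, s = s0), seq(0, 2, by = 0.5), rhs,
                        NULL, rtol = 1e-10, atol = 1e-12)
    expect_equal(unspliced_at(p, out[, "time"], phase), out[, "u"],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(spliced_at(p, out[, "time"], phase), out[, "s"],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("initial conditions and steady states are honoured", {
  p <- gene_params(alpha = 2, beta = 1, gamma = 0.5)
  expect_equal(unspliced_at(p, 0), 0)
  expect_equal(spliced_at(p, 0), 0)
  expect_equal(unspliced_at(p, 1e6), 2)
  expect_equal(spliced_at(p, 1e6), 4)
  expect_equal(unspliced_at(p, 1), 2 * (1 - exp(-1)))
  expect_equal(steady_state(p), c(u_ss = 2, s_ss = 4))
  # m rescales the measured unspliced steady state only
  pm <- gene_params(alpha = 2, beta = 1, gamma = 0.5, m = 2)
  expect_equal(steady_state(pm), c(u_ss = 1, s_ss = 4))
  p0 <- gene_params(alpha = 0, beta = 1, gamma = 0.5)
  expect_equal(steady_state(p0), c(u_ss = 0, s_ss = 0))
})

test_that("finite differences of the solutions satisfy the rate equations", {
  set.seed(1)
  h <- 1e-5
  for (rep in 1:100) {
    p <- gene_params(alpha = runif(1, 0, 4), beta = runif(1, 0.2, 3),
                     gamma = runif(1, 0.2, 3), u0 = runif(1, 0, 2),
                     s0 = runif(1, 0, 2))
    tau <- runif(1, h, 3)
    u <- unspliced_at(p, tau); s <- spliced_at(p, tau)
    dudt <- (unspliced_at(p, tau + h) - unspliced_at(p, tau - h)) / (2 * h)
    dsdt <- (spliced_at(p, tau + h) - spliced_at(p, tau - h)) / (2 * h)
    expect_equal(dudt, p$alpha - p$beta * u, tolerance = 1e-6)
    expect_equal(dsdt, p$beta * u - p$gamma * s, tolerance = 1e-6)
  }
})

test_that("scaling all rates by kappa rescales time exactly", {
  p <- gene_params(alpha = 2, beta = 1.3, gamma = 0.6, u0 = 0.2, s0 = 0.1)
  for (kappa in c(0.1, 1, 10)) {
    pk <- gene_params(alpha = kappa * 2, beta = kappa * 1.3,
                      gamma = kappa * 0.6, u0 = 0.2, s0 = 0.1)
    for (t in c(0.3, 1, 2.7)) {
      expect_equal(unspliced_at(pk, t / kappa), unspliced_at(p, t))
      expect_equal(spliced_at(pk, t / kappa), spliced_at(p, t))
    }
  }
})

test_that("phase portrait composed with u(t) reproduces s(t) on both branches", {
  p <- gene_params(alpha = 2, beta = 1, gamma = 0.5, t_switch = 1.5)
  tau_up <- seq(0.1, 1.4, by = 0.2)
  expect_equal(phase_portrait(p, unspliced_at(p, tau_up)),
               spliced_at(p, tau_up), tolerance = 1e-6)
  expect_equal(phase_portrait(p, 1.264241, phase = 1L),
               spliced_at(p, 1), tolerance = 1e-4)
  # down branch: initial conditions at the switch
  u_sw <- unspliced_at(p, 1.5); s_sw <- spliced_at(p, 1.5)
  pd <- gene_params(alpha = 2, beta = 1, gamma = 0.5,
                    u0 = u_sw, s0 = s_sw)
  tau_dn <- seq(0.1, 2, by = 0.3)
  expect_equal(phase_portrait(pd, unspliced_at(pd, tau_dn, 0L), phase = 0L),
               spliced_at(pd, tau_dn, 0L), tolerance = 1e-6)
  # the curve passes through the initial condition and the fixed point
  expect_equal(phase_portrait(pd, u_sw, phase = 0L), s_sw)
  # approach to the fixed point is O(r^gamma), slow for gamma < 1
  expect_equal(phase_portrait(p, 2 - 1e-12), 4, tolerance = 1e-4)
})

test_that("degenerate rate combinations use the analytic limit branches", {
  # beta == gamma in the time solution
  p_eq <- gene_params(alpha = 2, beta = 0.7, gamma = 0.7)
  p_near <- gene_params(alpha = 2, beta = 0.7, gamma = 0.7 + 1e-11)
  expect_equal(spliced_at(p_eq, 1.3), spliced_at(p_near, 1.3),
               tolerance = 1e-6)
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, parms) list(c(2 - 0.7 * y[1], 0.7 * y[1] - 0.7 * y[2]))
  out <- deSolve::ode(c(u = 0, s = 0), c(0, 1.3), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(spliced_at(p_eq, 1.3), out[2, "s"], tolerance = 1e-8,
               ignore_attr = TRUE)
  # gamma == 1 in the portrait (beta fixed at 1)
  pg <- gene_params(alpha = 2, beta = 1, gamma = 1)
  u <- unspliced_at(pg, 0.8)
  expect_equal(phase_portrait(pg, u), spliced_at(pg, 0.8),
               tolerance = 1e-6)
})

test_that("gene velocity is the scaled rate balance and vanishes at steady state", {
  expect_equal(gene_velocity(B = 1, Gamma = 0.5, M = 2, u = 1, s = 2), 1)
  p <- gene_params(alpha = 2, beta = 1, gamma = 0.5)
  ss <- steady_state(p)
  expect_equal(gene_velocity(1, 0.5, 1, ss["u_ss"], ss["s_ss"]),
               c(u_ss = 0))
  # velocity equals the analytic ds/dt along a trajectory
  tau <- c(0.2, 0.9, 2.1)
  h <- 1e-6
  dsdt <- (spliced_at(p, tau + h) - spliced_at(p, tau - h)) / (2 * h)
  expect_equal(gene_velocity(1, 0.5, 1, unspliced_at(p, tau),
                             spliced_at(p, tau)),
               dsdt, tolerance = 1e-6)
})

test_that("invalid parameters and inputs are rejected", {
  expect_error(gene_params(alpha = 2, beta = 0, gamma = 1))
  expect_error(gene_params(alpha = 2, beta = 1, gamma = -1))
  expect_error(unspliced_at(gene_params(alpha = 1, gamma = 1), -0.1))
  expect_error(phase_portrait(gene_params(alpha = 1, beta = 2, gamma = 1), 0.5),
               "beta")
  expect_error(phase_portrait(gene_params(alpha = 0, beta = 1, gamma = 1,
                                          u0 = 0), 0.1),
               "degenerate")
})
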