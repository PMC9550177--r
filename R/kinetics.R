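#' Per-gene splicing-kinetics parameters
#'
#' Container for the kinetic constants of the two-stage transcription /
#' splicing / degradation model
#' \deqn{du/dt = \alpha - \beta u, \qquad ds/dt = \beta u - \gamma s}
#' together with the initial conditions of the current transcriptional
#' phase, the switch time, and the unspliced upscaling factor `m` that
#' corrects the systematic under-counting of unspliced reads.
#'
#' During downregulation the transcription rate is treated as 0 and
#' `(u0, s0)` are the abundances at the switch time.
#'
#' @param alpha transcription rate (molecules per unit time), >= 0.
#' @param beta splicing rate (1/time), > 0.
#' @param gamma degradation rate of spliced mRNA (1/time), > 0.
#' @param u0,s0 unspliced/spliced abundance at the start of the phase, >= 0.
#' @param t_switch time of transcriptional switch-off (upregulation
#'   duration), > 0; `Inf` for a gene that never switches off.
#' @param m unspliced upscaling factor, > 0 (conceptually >= 1 for real
#'   data where unspliced counts are underestimated).
#' @return An object of class `gene_params`.
#' @export
gene_params <- function(alpha, beta = 1, gamma, u0 = 0, s0 = 0,
                        t_switch = Inf, m = 1) {
  stopifnot(is.numeric(alpha), alpha >= 0,
            is.numeric(beta), beta > 0,
            is.numeric(gamma), gamma > 0,
            u0 >= 0, s0 >= 0, m > 0, t_switch > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 u0 = u0, s0 = s0, t_switch = t_switch, m = m),
            class = "gene_params")
}

# tolerance below which beta ~ gamma (and gamma ~ beta in the portrait)
# are routed to the analytic-limit branch
.KINETICS_EPS <- 1e-8

#' Unspliced abundance at elapsed time tau
#'
#' Closed-form solution of the unspliced equation within one
#' transcriptional phase:
#' \deqn{u(\tau) = u_0 e^{-\beta\tau} + (\alpha/\beta)(1 - e^{-\beta\tau})}
#' In the downregulation phase (`phase = 0`) the effective transcription
#' rate is 0 and `(u0, s0)` must be the switch-time values.
#'
#' @param params a [gene_params()] object.
#' @param tau elapsed time since phase start (vectorised), >= 0.
#' @param phase 1 for upregulation, 0 for downregulation.
#' @return unspliced abundance, same length as `tau`.
#' @export
unspliced_at <- function(params, tau, phase = 1L) {
  stopifnot(inherits(params, "gene_params"), all(tau >= 0))
  a <- if (phase == 1L) params$alpha else 0
  e <- exp(-params$beta * tau)
  params$u0 * e + (a / params$beta) * (1 - e)
}

#' Spliced abundance at elapsed time tau
#'
#' Closed-form solution of the spliced equation within one phase:
#' \deqn{s(\tau) = s_0 e^{-\gamma\tau} + (\alpha/\gamma)(1 - e^{-\gamma\tau})
#'   + \frac{\alpha - \beta u_0}{\gamma - \beta}
#'     (e^{-\gamma\tau} - e^{-\beta\tau})}
#' The removable singularity at `beta == gamma` is handled by its
#' analytic limit.
#'
#' @inheritParams unspliced_at
#' @return spliced abundance, same length as `tau`.
#' @export
spliced_at <- function(params, tau, phase = 1L) {
  stopifnot(inherits(params, "gene_params"), all(tau >= 0))
  a <- if (phase == 1L) params$alpha else 0
  b <- params$beta; g <- params$gamma
  eg <- exp(-g * tau); eb <- exp(-b * tau)
  base <- params$s0 * eg + (a / g) * (1 - eg)
  if (abs(g - b) < .KINETICS_EPS) {
    # lim_{g->b} (e^{-g tau} - e^{-b tau})/(g - b) = -tau e^{-b tau}
    base + (b * params$u0 - a) * tau * eb
  } else {
    base + (a - b * params$u0) / (g - b) * (eg - eb)
  }
}

#' Time-independent phase portrait s(u)
#'
#' The spliced abundance as a function of the *measured* unspliced
#' abundance, eliminating time between the two closed-form solutions.
#' With the splicing rate fixed at 1 and the measured u upscaled by `m`:
#' \deqn{s(u) = \left(s_0 - \frac{\alpha}{\gamma}
#'   + \frac{\alpha - m u_0}{\gamma - 1}\right)
#'   \left(\frac{m u - \alpha}{m u_0 - \alpha}\right)^{\gamma}
#'   + \frac{m u - \alpha}{\gamma - 1} + \frac{\alpha}{\gamma}}
#' This is the curve fitted directly to u-s data. `gamma == 1` is a
#' removable singularity handled by its series limit. For the
#' downregulation branch pass `phase = 0` (effective `alpha` 0, initial
#' conditions at the switch).
#'
#' Consistency: `phase_portrait(params, unspliced_at(params, t))` equals
#' `spliced_at(params, t)` for every t within the phase.
#'
#' @param params a [gene_params()] object with `beta == 1`.
#' @param u measured unspliced abundance (vectorised); `m * u` must lie
#'   between `m * u0` and the phase asymptote.
#' @param phase 1 upregulation, 0 downregulation.
#' @return spliced abundance on the portrait curve.
#' @export
phase_portrait <- function(params, u, phase = 1L) {
  stopifnot(inherits(params, "gene_params"))
  if (abs(params$beta - 1) > .KINETICS_EPS)
    stop("phase_portrait requires beta == 1 (the fitting convention)")
  a <- if (phase == 1L) params$alpha else 0
  g <- params$gamma; m <- params$m
  w0 <- m * params$u0; w <- m * u; s0 <- params$s0
  if (abs(w0 - a) < .KINETICS_EPS)
    stop("degenerate portrait: m*u0 equals the phase asymptote alpha")
  r <- (w - a) / (w0 - a)
  if (any(r < -.KINETICS_EPS))
    stop("u outside the phase range: (m*u - alpha) changes sign")
  r <- pmax(r, 0)
  if (abs(g - 1) < .KINETICS_EPS) {
    # lim_{g->1}: (a - w0)/(g-1) (r^g - r) -> (a - w0) r log r
    rl <- ifelse(r > 0, r * log(r), 0)
    s0 * r + a * (1 - r) + (a - w0) * rl
  } else {
    (s0 - a / g + (a - w0) / (g - 1)) * r^g + (w - a) / (g - 1) + a / g
  }
}

#' Steady state of the kinetics
#'
#' Fixed point of the model in measured-u units: `u_ss = alpha/(m beta)`,
#' `s_ss = alpha/gamma`. The gene-wise velocity vanishes there.
#'
#' @param params a [gene_params()] object.
#' @return named numeric vector `c(u_ss, s_ss)`.
#' @export
steady_state <- function(params) {
  stopifnot(inherits(params, "gene_params"))
  c(u_ss = params$alpha / (params$m * params$beta),
    s_ss = params$alpha / params$gamma)
}

#' Gene-wise velocity component
#'
#' The rate of change of spliced abundance given scaled parameters
#' `(B, Gamma, M)` (splicing rate, degradation rate, unspliced upscale):
#' \deqn{v = B M u - \Gamma s}
#'
#' @param B scaled splicing rate(s).
#' @param Gamma scaled degradation rate(s).
#' @param M unspliced upscaling factor(s).
#' @param u,s measured unspliced/spliced abundances.
#' @return velocity component(s), recycled elementwise.
#' @export
gene_velocity <- function(B, Gamma, M, u, s) {
  stopifnot(is.finite(B), is.finite(Gamma), is.finite(M))
  B * M * u - Gamma * s
}

#' Evaluate u and s along a full up/down trajectory
#'
#' Convenience used by the simulator and the fitting module: evaluates the
#' closed-form solutions at global phase times `tau` (measured from
#' activation), switching to the downregulation branch at
#' `params$t_switch` with continuous initial conditions.
#'
#' @param params a [gene_params()] object (with finite or infinite
#'   `t_switch`).
#' @param tau times since activation, >= 0 (vectorised).
#' @return list with components `u`, `s` (measured-u units, i.e. divided
#'   by `m`) and integer `phase` (1 up, 0 down).
#' @export
kinetics_trajectory <- function(params, tau) {
  stopifnot(inherits(params, "gene_params"), all(tau >= 0))
  up <- tau <= params$t_switch
  u <- s <- numeric(length(tau))
  u[up] <- unspliced_at(params, tau[up], phase = 1L)
  s[up] <- spliced_at(params, tau[up], phase = 1L)
  if (any(!up)) {
    u_sw <- unspliced_at(params, params$t_switch, phase = 1L)
    s_sw <- spliced_at(params, params$t_switch, phase = 1L)
    down <- gene_params(alpha = 0, beta = params$beta, gamma = params$gamma,
                        u0 = u_sw, s0 = s_sw, m = params$m)
    u[!up] <- unspliced_at(down, tau[!up] - params$t_switch, phase = 0L)
    s[!up] <- spliced_at(down, tau[!up] - params$t_switch, phase = 0L)
  }
  list(u = u / params$m, s = s, phase = as.integer(up))
}
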