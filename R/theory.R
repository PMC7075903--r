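# Continuum active linear elasticity: closed-form Fourier and real-space
# velocity correlations, mean-square velocity, and the numerically integrated
# temporal velocity autocorrelation of Ornstein-Uhlenbeck-driven overdamped
# elastic modes.

#' Continuum theory parameters
#'
#' Collects the microscopic inputs `(v0, tau, zeta, B, mu, a)` and derives
#' the longitudinal and transverse correlation lengths
#' `xi_L = sqrt((B + mu) tau / zeta)`, `xi_T = sqrt(mu tau / zeta)`, the
#' effective temperature `T_eff = zeta v0^2 tau / 2` and the high-q cutoff
#' `q_m = 2 pi / a` (with `a` of the order of the cell size: the particle
#' radius in simulation units, about 11 micron for experiment-scale sets).
#'
#' @param v0 Active speed.
#' @param tau Persistence time.
#' @param zeta Substrate friction.
#' @param B,mu Bulk and shear moduli.
#' @param a Microscopic length (cell size / particle radius).
#' @return A `theory_params` object.
#' @export
theory_params <- function(v0, tau, zeta = 1, B, mu, a = 1) {
  for (nm in c("v0", "tau", "zeta", "B", "mu", "a"))
    check_scalar(get(nm), nm)
  xi <- correlation_lengths(B, mu, tau, zeta)
  structure(list(v0 = v0, tau = tau, zeta = zeta, B = B, mu = mu, a = a,
                 xi_L = xi[["xi_L"]], xi_T = xi[["xi_T"]],
                 T_eff = zeta * v0^2 * tau / 2, q_m = 2 * pi / a),
            class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat("Continuum active-elastic parameters:\n")
  cat(sprintf("  v0 = %.4g, tau = %.4g, zeta = %.4g, B = %.4g, mu = %.4g, a = %.4g\n",
              x$v0, x$tau, x$zeta, x$B, x$mu, x$a))
  cat(sprintf("  xi_L = %.4g, xi_T = %.4g, T_eff = %.4g, q_m = %.4g\n",
              x$xi_L, x$xi_T, x$T_eff, x$q_m))
  invisible(x)
}

#' Longitudinal and transverse velocity correlation lengths
#'
#' `xi_L = sqrt((B + mu) tau / zeta)` and `xi_T = sqrt(mu tau / zeta)`;
#' both scale as `sqrt(tau)`.
#'
#' @param B,mu Bulk and shear moduli.
#' @param tau Persistence time.
#' @param zeta Substrate friction.
#' @return Named vector `c(xi_L, xi_T)`.
#' @export
correlation_lengths <- function(B, mu, tau, zeta = 1) {
  if (mu <= 0 || tau <= 0 || zeta <= 0 || B + mu <= 0)
    stop_invalid("correlation lengths need mu, tau, zeta > 0 and B + mu > 0")
  c(xi_L = sqrt((B + mu) * tau / zeta), xi_T = sqrt(mu * tau / zeta))
}

#' Fourier-space velocity correlation (continuum prediction)
#'
#' `<|v(q)|^2> = (N v0^2 / 2) [1 / (1 + xi_L^2 q^2) + 1 / (1 + xi_T^2 q^2)]`.
#' The prefactor corresponds to the unnormalized discrete transform
#' `v(q) = sum_j exp(i q . r_j) v_j`; divide by `N^2` to compare with
#' spectra measured under the `1/N` convention used by [measure_vq()].
#'
#' @param params A `theory_params`.
#' @param q Wavenumber(s), >= 0.
#' @param n_particles N entering the prefactor.
#' @return Spectral density at each `q`.
#' @export
vq_theory <- function(params, q, n_particles) {
  stopifnot(inherits(params, "theory_params"))
  if (any(q < 0)) stop_invalid("q must be >= 0")
  n_particles * params$v0^2 / 2 *
    (1 / (1 + (params$xi_L * q)^2) + 1 / (1 + (params$xi_T * q)^2))
}

#' Normalized spectrum model for PIV fits
#'
#' The fit model for velocity fields normalized by their root-mean-square
#' speed: `(N/2) (v0 / vbar)^2 [1/(1 + xi_L^2 q^2) + 1/(1 + xi_T^2 q^2)]`.
#'
#' @param params A `theory_params`.
#' @param q Wavenumbers.
#' @param mean_speed Root-mean-square speed `vbar` (> 0).
#' @param n_particles N (grid points or cells) entering the prefactor.
#' @return Dimensionless spectral density.
#' @export
vq_normalized <- function(params, q, mean_speed, n_particles) {
  check_scalar(mean_speed, "mean_speed")
  vq_theory(params, q, n_particles) / mean_speed^2
}

#' Mean-square velocity (continuum prediction)
#'
#' `<|v|^2> = (v0^2 a^2 / 8 pi) [log(1 + xi_L^2 q_m^2)/xi_L^2 +
#' log(1 + xi_T^2 q_m^2)/xi_T^2]`, obtained by integrating the Fourier
#' correlation over the circular cutoff `|q| <= q_m`. The dominant scaling
#' at large correlation length is `1/xi^2` up to logarithms.
#'
#' @param params A `theory_params`.
#' @return Mean-square speed.
#' @export
mean_square_velocity <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  term <- function(xi) {
    x <- (xi * params$q_m)^2
    if (x < 1e-12) params$q_m^2 else log1p(x) / xi^2
  }
  params$v0^2 * params$a^2 / (8 * pi) * (term(params$xi_L) + term(params$xi_T))
}

#' Real-space velocity correlation (continuum prediction)
#'
#' `C_vv(r) = (a^2 v0^2 / 4 pi) [K0(r/xi_L)/xi_L^2 + K0(r/xi_T)/xi_T^2]`,
#' valid for `r > a`. With `asymptotic = TRUE` returns the large-distance
#' exponential form
#' `(a^2 v0^2 / 4 pi) sqrt(pi / 2 r) [exp(-r/xi_L)/xi_L^{3/2} +
#' exp(-r/xi_T)/xi_T^{3/2}]`.
#'
#' @param params A `theory_params`.
#' @param r Distance(s), > 0.
#' @param asymptotic Return the exponential asymptotic form instead.
#' @return Correlation value(s).
#' @export
cvv_theory <- function(params, r, asymptotic = FALSE) {
  stopifnot(inherits(params, "theory_params"))
  if (any(r <= 0)) stop_invalid("r must be > 0")
  pre <- params$a^2 * params$v0^2 / (4 * pi)
  if (asymptotic) {
    pre * sqrt(pi / (2 * r)) *
      (exp(-r / params$xi_L) / params$xi_L^1.5 +
       exp(-r / params$xi_T) / params$xi_T^1.5)
  } else {
    pre * (besselK(r / params$xi_L, 0) / params$xi_L^2 +
           besselK(r / params$xi_T, 0) / params$xi_T^2)
  }
}

# Per-mode velocity autocorrelation of an overdamped mode driven by
# exponentially correlated (OU) noise with correlation time tau:
#   C(t) = (v0^2/2) [exp(-t/tau) - u exp(-u t/tau)] / (1 - u^2),  u = omega tau,
# where omega = lambda/zeta is the mode relaxation rate. The u -> 1 pole is
# removable; its limit is (v0^2/4) exp(-t/tau) (1 - t/tau).
mode_vacf <- function(u, s, v0) {
  # s = t / tau, u = omega * tau (both vectorized)
  out <- numeric(length(u))
  reg <- abs(1 - u) > 1e-6
  out[reg] <- (exp(-s) - u[reg] * exp(-u[reg] * s)) / (1 - u[reg]^2)
  out[!reg] <- exp(-s) * (1 - s) / 2
  v0^2 / 2 * out
}

#' Temporal velocity autocorrelation (continuum prediction)
#'
#' `<v(t) . v(0)>` from the per-mode autocorrelation of overdamped elastic
#' modes driven by Ornstein-Uhlenbeck noise, integrated over the longitudinal
#' and transverse branches up to the circular cutoff `q_m`. At `t = 0` it
#' coincides with [mean_square_velocity()]. In the free limit (`B, mu -> 0`)
#' it reduces to `v0^2 exp(-t/tau)` times the cutoff-convention constant.
#'
#' @param params A `theory_params`.
#' @param t Lag time(s), >= 0.
#' @param rel_tol Quadrature relative tolerance.
#' @return Autocorrelation value(s).
#' @export
vacf_theory <- function(params, t, rel_tol = 1e-9) {
  stopifnot(inherits(params, "theory_params"))
  if (any(t < 0)) stop_invalid("t must be >= 0")
  one_lag <- function(tt) {
    s <- tt / params$tau
    branch <- function(xi) {
      f <- function(q) q * mode_vacf(xi^2 * q^2, s, params$v0)
      # split at the removable u = 1 point when it lies inside the range
      qs <- 1 / xi
      lims <- sort(unique(c(0, if (qs < params$q_m) qs, params$q_m)))
      tot <- 0
      for (i in seq_len(length(lims) - 1)) {
        iv <- tryCatch(
          integrate(f, lims[i], lims[i + 1], rel.tol = rel_tol,
                    subdivisions = 500L),
          error = function(e) stop("vacf quadrature failed: ", conditionMessage(e),
                                   call. = FALSE))
        tot <- tot + iv$value
      }
      tot
    }
    params$a^2 / (2 * pi) * (branch(params$xi_L) + branch(params$xi_T))
  }
  vapply(t, one_lag, numeric(1))
}
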