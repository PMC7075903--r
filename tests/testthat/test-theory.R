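# Continuum-elastic predictions and their internal consistency.

ref_params <- function(tau = 2, v0 = 1)
  theory_params(v0 = v0, tau = tau, zeta = 1, B = 1.684, mu = 0.510, a = 1)

test_that("correlation lengths follow sqrt(tau) scaling", {
  x1 <- correlation_lengths(1.684, 0.510, tau = 2.5)
  x4 <- correlation_lengths(1.684, 0.510, tau = 10)
  expect_equal(x4, 2 * x1, tolerance = 1e-12)

  # 100 micron at tau = 2.5 h maps to ~283 micron at tau = 20 h
  expect_equal(100 * sqrt(20 / 2.5), 282.8427, tolerance = 1e-6)
  mu_scale <- 100^2 / 2.5          # mu/zeta implied by xi_T = 100 at tau 2.5
  x20 <- correlation_lengths(3.3 * mu_scale, mu_scale, tau = 20)
  expect_equal(x20[["xi_T"]], 282.8427, tolerance = 1e-4)

  # moduli ratio 4.3 fixes xi_L / xi_T = sqrt(4.3)
  xr <- correlation_lengths(1.684, 0.510, tau = 7)
  expect_equal(xr[["xi_L"]] / xr[["xi_T"]], sqrt((1.684 + 0.510) / 0.510),
               tolerance = 1e-12)
  expect_error(correlation_lengths(1, -1, 1),
               class = "activesheet_invalid_parameter")
})

test_that("the Fourier spectrum model has the right intercept and tails", {
  p <- ref_params()
  n <- 500
  expect_equal(vq_theory(p, 0, n), n * p$v0^2)
  # degenerate B -> 0: equal lengths, half height at q = 1/xi
  pd <- theory_params(1, 2, 1, B = 1e-12, mu = 0.510, a = 1)
  expect_equal(vq_theory(pd, 1 / pd$xi_T, n), n * pd$v0^2 / 2,
               tolerance = 1e-6)
  # high-q decay ~ q^-2 with branch ratio mu / (B + mu)
  q <- 1e4
  term_L <- 1 / (1 + (p$xi_L * q)^2); term_T <- 1 / (1 + (p$xi_T * q)^2)
  expect_equal(term_L / term_T, p$xi_T^2 / p$xi_L^2, tolerance = 1e-6)
  expect_equal(vq_theory(p, q, n) * q^2,
               n * p$v0^2 / 2 * (1 / p$xi_L^2 + 1 / p$xi_T^2),
               tolerance = 1e-6)

  # normalized variant: intercept N (v0/vbar)^2
  expect_equal(vq_normalized(p, 0, mean_speed = 0.1, n), n * (p$v0 / 0.1)^2)
})

test_that("mean-square velocity matches its cutoff limits and scaling", {
  p0 <- theory_params(1, 2, 1, B = 1e-10, mu = 1e-10, a = 1)
  # xi -> 0: v0^2 a^2 q_m^2 / (4 pi)
  expect_equal(mean_square_velocity(p0), 1 * p0$q_m^2 / (4 * pi),
               tolerance = 1e-6)
  # large xi: <|v|^2> ~ 1/xi^2 up to logarithms
  msv <- vapply(c(1e3, 4e3), function(tau)
    mean_square_velocity(theory_params(1, tau, 1, 1.684, 0.510, a = 1)),
    numeric(1))
  ratio <- msv[1] / msv[2]
  expect_gt(ratio, 3)   # 1/xi^2 alone would give 4; logs soften it
  expect_lt(ratio, 4.2)
})

test_that("closed-form C_vv matches the numerically inverted spectrum", {
  p <- ref_params()
  for (r in c(2, 5, 10, 20)) {
    expect_equal(cvv_theory(p, r), cvv_hankel_oracle(p, r),
                 tolerance = 1e-3)
  }
  # large-distance exponential asymptote within 5% at r = 10 xi
  r_far <- 10 * p$xi_L
  expect_equal(cvv_theory(p, r_far, asymptotic = TRUE),
               cvv_theory(p, r_far), tolerance = 0.05)
  # strict monotone decay
  r <- seq(1.1, 40, length.out = 200)
  expect_true(all(diff(cvv_theory(p, r)) < 0))
})

test_that("the temporal autocorrelation is consistent at lag zero and in the free limit", {
  p <- ref_params()
  expect_equal(vacf_theory(p, 0), mean_square_velocity(p), tolerance = 1e-6)

  # vanishing moduli: per-mode relaxation rate -> 0, VACF = value(0) exp(-t/tau)
  pf <- theory_params(1, tau = 3, zeta = 1, B = 1e-14, mu = 1e-14, a = 1)
  tt <- c(0.5, 1, 3, 6)
  expect_equal(vacf_theory(pf, tt) / vacf_theory(pf, 0), exp(-tt / 3),
               tolerance = 1e-4)

  # inverse-S shape: monotone initial decay, then at most a weak elastic
  # recoil (small negative dip)
  vals <- vacf_theory(p, c(0, 0.25, 0.5, 1, 2))
  expect_true(all(diff(vals) < 0))
  dip <- vacf_theory(p, c(4, 8))
  expect_lt(max(abs(dip)), 0.1 * vals[1])
})

test_that("predictions are invariant under consistent rescaling", {
  # scaling (B, mu, zeta) -> (cB, cmu, czeta) leaves mu tau/zeta fixed,
  # hence all observable predictions unchanged
  p1 <- theory_params(0.7, 4, 1, 1.684, 0.510, a = 1)
  p2 <- theory_params(0.7, 4, 3, 3 * 1.684, 3 * 0.510, a = 1)
  expect_equal(p1$xi_L, p2$xi_L)
  expect_equal(vq_theory(p1, c(0.3, 1), 100), vq_theory(p2, c(0.3, 1), 100))
  expect_equal(cvv_theory(p1, 5), cvv_theory(p2, 5))
  expect_equal(vacf_theory(p1, 2), vacf_theory(p2, 2), tolerance = 1e-8)
})
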