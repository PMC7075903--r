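# Normal-mode machinery: Hessian assembly, spectra, mode energies, Fourier
# weights and elastic moduli.

test_that("the two-disk Hessian has the closed-form block structure", {
  two <- make_fixture_packing("two-disk")   # contact along x, delta = 0.1
  H <- assemble_hessian(two, force_tolerance = Inf)
  r <- 1.9; f <- 0.1
  # off-diagonal block: -k n n^T + (f/r) t t^T with n = x_hat
  expect_equal(H$matrix[1:2, 3:4],
               matrix(c(-1, 0, 0, f / r), 2, 2), tolerance = 1e-12)
  # closed form: one stiff pair mode 2k, two rigid motions, and one unstable
  # sliding direction -2f/r from the pre-stress of this non-equilibrium contact
  ev <- sort(eigen(H$matrix, symmetric = TRUE)$values)
  expect_equal(ev, sort(c(-2 * f / r, 0, 0, 2 * 1)), tolerance = 1e-12)
})

test_that("Hessian block rows sum to zero and match finite differences", {
  cfg <- generate_packing(64, 1, 0.3, seed = 4)
  H <- assemble_hessian(cfg)
  n <- 64
  # translation invariance: H . (uniform translation) = 0
  tx <- rep(c(1, 0), n); ty <- rep(c(0, 1), n)
  expect_lt(max(abs(H$matrix %*% tx)), 1e-10)
  expect_lt(max(abs(H$matrix %*% ty)), 1e-10)

  # finite-difference oracle on gradient columns
  h <- 1e-5
  scale <- max(abs(H$matrix))
  for (i in c(1, 17, 50)) for (d in 1:2) {
    cp <- cfg; cm <- cfg
    cp$positions[i, d] <- cp$positions[i, d] + h
    cm$positions[i, d] <- cm$positions[i, d] - h
    col_fd <- as.vector(t((-energy_and_forces(cp)$forces +
                            energy_and_forces(cm)$forces) / (2 * h)))
    expect_lt(max(abs(col_fd - H$matrix[, 2 * (i - 1) + d])) / scale, 1e-5)
  }

  # pre-stress warning on a non-equilibrated configuration
  loose <- generate_packing(20, 1, 0.3, seed = 6, relax = FALSE)
  expect_warning(assemble_hessian(loose), "not at mechanical equilibrium")
})

test_that("jammed periodic packings have exactly two zero modes", {
  cfg <- generate_packing(64, 1, 0.3, seed = 8)
  ms <- eigenmodes(assemble_hessian(cfg))
  expect_equal(sum(abs(ms$values) < 1e-8), 2L)
  expect_true(all(ms$values[-(1:2)] > 0))
  # orthonormality
  G <- crossprod(ms$vectors)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-10)
})

test_that("mode energies follow the driven-mode formula and its limits", {
  lambda <- c(0.5, 1, 2, 8)
  v0 <- 0.3; zeta <- 1
  # lambda tau / zeta = 1 gives zeta v0^2 tau / 8
  expect_equal(mode_energies(1, v0, tau = 1), v0^2 / 8)
  # small tau: equipartition at T_eff / 2 for every mode
  tau <- 1e-6
  expect_equal(mode_energies(lambda, v0, tau),
               rep(zeta * v0^2 * tau / 4, 4), tolerance = 1e-5)
  # large tau: E ~ zeta^2 v0^2 / (4 lambda)
  tau <- 1e9
  expect_equal(mode_energies(lambda, v0, tau),
               zeta^2 * v0^2 / (4 * lambda), tolerance = 1e-6)
  expect_error(mode_energies(c(-1, 1), v0, 1),
               class = "activesheet_invalid_parameter")
})

test_that("mode Fourier weights are complete", {
  cfg <- generate_packing(32, 1, 0.3, seed = 10)
  ms <- eigenmodes(assemble_hessian(cfg))
  qg <- q_grid(cfg$box_length, 2)
  q <- qg[c(1, 4, min(8, nrow(qg))), , drop = FALSE]
  W <- activesheet:::mode_fourier_weights(ms, q)
  # completeness: sum_nu |xi_nu(q)|^2 = 2/N for every q
  expect_equal(rowSums(W), rep(2 / 32, 3), tolerance = 1e-10)
})

test_that("the small-persistence mode sum is flat (thermal-like limit)", {
  cfg <- generate_packing(32, 1, 0.3, seed = 12)
  ms <- eigenmodes(assemble_hessian(cfg))
  v0 <- 0.1
  pred <- mode_velocity_correlation(ms, v0, tau = 1e-9, q_max = 2, bin = FALSE)
  # tau -> 0: <|v(q)|^2> -> v0^2/2 * sum |xi(q)|^2 = v0^2/N at every q
  expect_equal(pred$value, rep(v0^2 / 32, length(pred$value)),
               tolerance = 1e-6)
})

test_that("moduli estimates on a crystal agree with the strain oracle", {
  # weak uniform overlap keeps the pre-stress correction (which separates
  # wave moduli from static stress-strain moduli) below the tolerance
  hx <- hex_packing(40, 40, overlap = 0.002)
  oracle <- strain_oracle(hx, relax = FALSE, h = 2e-4)  # affine = exact here
  m <- estimate_moduli(hx, q_max_fit = 0.28, tangent = "dimensional")
  expect_equal(m$mu, oracle[["mu"]], tolerance = 0.02)
  expect_equal(m$B, oracle[["B"]], tolerance = 0.02)
  # the Green's-function branch agrees: no non-affinity in a perfect crystal
  g <- estimate_moduli(hx, q_max_fit = 0.28, method = "greens")
  expect_equal(g$mu, m$mu, tolerance = 1e-3)
  expect_equal(g$B, m$B, tolerance = 1e-3)
})

test_that("dynamical-matrix branches grow as q^2 at small q", {
  cfg <- generate_packing(128, 1, 0.3, seed = 14)
  m <- estimate_moduli(cfg)
  br <- m$branches
  low <- br[br$q < 1, ]
  # both branches consistent with lambda = c q^2, positive coefficients
  expect_true(all(low$lambda_L > 0) && all(low$lambda_T > 0))
  fitL <- lm(low$lambda_L ~ 0 + I(low$q^2))
  expect_gt(summary(fitL)$r.squared, 0.98)
  expect_gt(m$B, 0)
  expect_gt(m$mu, 0)
})
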