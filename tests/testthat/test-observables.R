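# Estimators on trajectories and gridded fields.

drift_trajectory <- function(n = 24, nf = 4, L = 10, vdrift = c(0.3, -0.1)) {
  set.seed(3)
  X <- matrix(runif(n * nf, 0, L), n, nf)
  Y <- matrix(runif(n * nf, 0, L), n, nf)
  fake_trajectory(times = seq_len(nf), X = X, Y = Y,
                  VX = matrix(vdrift[1], n, nf), VY = matrix(vdrift[2], n, nf),
                  radii = rep(1, n), L = L)
}

test_that("rigid drift puts no power at finite wavevectors", {
  # commensurate lattice positions so plane-wave orthogonality is exact
  g <- expand.grid(x = (0:4) * 2, y = (0:4) * 2)
  n <- nrow(g)
  tr <- fake_trajectory(1:2, matrix(rep(g$x, 2), n), matrix(rep(g$y, 2), n),
                        matrix(0.3, n, 2), matrix(-0.1, n, 2),
                        rep(1, n), 10)
  vq <- measure_vq(tr, q_max = 2)
  expect_lt(max(vq$value), 1e-25)
})

test_that("a single transverse plane wave concentrates at its wavevector", {
  L <- 10
  g <- expand.grid(x = (0:19) * 0.5, y = (0:19) * 0.5)
  n <- nrow(g)
  q0 <- 2 * pi / L * 3
  vx <- rep(0, n); vy <- cos(q0 * g$x)
  tr <- fake_trajectory(1, matrix(g$x), matrix(g$y), matrix(vx), matrix(vy),
                        rep(0.25, n), L)
  vq <- measure_vq(tr, q_max = 3)
  peak_bin <- which.max(vq$value)
  expect_lt(abs(vq$q[peak_bin] - q0), 2 * pi / L)   # peak bin contains q0
  expect_gt(vq$value[peak_bin] / (sum(vq$value) - vq$value[peak_bin]), 1e10)
})

test_that("Parseval holds on the complete grid of a gridded field", {
  set.seed(5)
  nx <- 8; ny <- 8; h <- 1
  U <- array(rnorm(nx * ny), c(nx, ny, 1))
  V <- array(rnorm(nx * ny), c(nx, ny, 1))
  flds <- grid_field_sequence((0:(nx - 1)) * h, (0:(ny - 1)) * h, U, V, h)
  # complete commensurate grid, including q = 0 and both half planes
  kx <- 2 * pi * (0:(nx - 1)) / (nx * h)
  ky <- 2 * pi * (0:(ny - 1)) / (ny * h)
  q <- as.matrix(expand.grid(kx, ky))
  pos <- as.matrix(expand.grid(x = flds$x, y = flds$y))
  vals <- activesheet:::.vq_frame(pos[, 1], pos[, 2],
                                  as.vector(U), as.vector(V), q[, 1], q[, 2])
  n <- nx * ny
  # sum over the complete grid of |v(q)|^2 equals (1/N) sum_j |v_j|^2
  expect_equal(sum(vals), mean(U^2 + V^2), tolerance = 1e-10)
})

test_that("real-space correlation estimator reproduces analytic cases", {
  tr <- drift_trajectory(n = 60, nf = 3)
  cv <- measure_cvv(tr, bin_width = 0.5)
  expect_true(all(abs(cv$value - (0.3^2 + 0.1^2)) < 1e-12))

  # independent isotropic velocities decorrelate
  set.seed(9)
  n <- 400; L <- 20
  tr2 <- fake_trajectory(1:8,
                         X = matrix(runif(n * 8, 0, L), n),
                         Y = matrix(runif(n * 8, 0, L), n),
                         VX = matrix(rnorm(n * 8), n),
                         VY = matrix(rnorm(n * 8), n),
                         radii = rep(1, n), L = L)
  cv2 <- measure_cvv(tr2, bin_width = 1)
  expect_lt(max(abs(cv2$value)), 6 / sqrt(min(cv2$counts)))
})

test_that("the scattering function satisfies its limits and censoring", {
  n <- 30; nf <- 12; L <- 12
  X <- matrix(runif(n), n, nf); Y <- matrix(runif(n), n, nf)
  frozen <- fake_trajectory(seq_len(nf), X, Y, X * 0, Y * 0,
                            rep(1, n), L, XU = X, YU = Y)
  s <- measure_sisf(frozen, q_magnitude = 2 * pi)
  expect_equal(s$value, rep(1, nf), tolerance = 1e-12)
  expect_true(s$censored)
  expect_equal(s$tau_alpha, max(s$times))

  # Brownian oracle: S(q, t) = exp(-q^2 D t)
  set.seed(11)
  D <- 0.05; dtf <- 0.5; nf2 <- 60; n2 <- 600
  steps_x <- matrix(rnorm(n2 * nf2, 0, sqrt(2 * D * dtf)), n2, nf2)
  steps_y <- matrix(rnorm(n2 * nf2, 0, sqrt(2 * D * dtf)), n2, nf2)
  XU <- t(apply(steps_x, 1, cumsum)); YU <- t(apply(steps_y, 1, cumsum))
  br <- fake_trajectory((1:nf2) * dtf, XU %% 10, YU %% 10, XU * 0, YU * 0,
                        rep(1, n2), 10, XU = XU, YU = YU)
  s2 <- measure_sisf(br, q_magnitude = 2)
  sel <- s2$times <= 10
  expect_equal(s2$value[sel], exp(-4 * D * s2$times[sel]), tolerance = 0.05)

  # wrapped-only trajectories are rejected
  nowrap <- frozen; nowrap$XU <- NULL
  expect_error(measure_sisf(nowrap), "unwrapped")
})

test_that("temporal autocorrelation starts at the mean-square velocity", {
  set.seed(13)
  n <- 50; nf <- 20
  VX <- matrix(rnorm(n * nf), n, nf); VY <- matrix(rnorm(n * nf), n, nf)
  tr <- fake_trajectory(seq_len(nf), matrix(0, n, nf), matrix(0, n, nf),
                        VX, VY, rep(1, n), 10)
  vf <- measure_vacf(tr)
  expect_equal(vf$value[1], mean(VX^2 + VY^2), tolerance = 1e-12)

  drift <- drift_trajectory(nf = 10)
  vd <- measure_vacf(drift)
  expect_true(all(abs(vd$value - vd$value[1]) < 1e-12))
})

test_that("speed statistics recover analytic distributions", {
  tr <- drift_trajectory(n = 100, nf = 2, vdrift = c(0.4, 0.3))
  st <- speed_stats(tr)
  expect_equal(st$mean_speed, 0.5, tolerance = 1e-12)
  expect_equal(st$mean_square_velocity, 0.25, tolerance = 1e-12)
  expect_equal(sum(st$distribution$density > 0), 1L)  # point mass at |v|/vbar = 1

  # isotropic 2D Gaussian velocities: normalized speeds are Rayleigh
  set.seed(15)
  n <- 4000
  g <- fake_trajectory(1, matrix(runif(n)), matrix(runif(n)),
                       matrix(rnorm(n)), matrix(rnorm(n)), rep(1, n), 1)
  sg <- speed_stats(g, breaks = seq(0, 5, 0.25))
  x <- sg$distribution$mid
  rayleigh <- 2 * x * exp(-x^2)          # Rayleigh in units of the rms speed
  sel <- sg$distribution$density > 0.05
  expect_equal(sg$distribution$density[sel], rayleigh[sel], tolerance = 0.15)
})
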