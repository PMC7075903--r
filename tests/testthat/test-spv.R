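# Self-propelled Voronoi model: tessellation, energetics, exact forces and
# overdamped active dynamics.

test_that("periodic tessellation partitions the box", {
  # four centers at the corners of a shifted unit square: equal quarter tiles
  sq <- spv_config(rbind(c(0.25, 0.25), c(0.75, 0.25),
                         c(0.25, 0.75), c(0.75, 0.75)), box = c(1, 1))
  ts <- tessellate(sq)
  expect_equal(ts$areas, rep(0.25, 4), tolerance = 1e-12)

  # hexagonal lattice: every tile a regular hexagon of equal area
  hx <- spv_hex_config(4, 4, spacing = 1)
  th <- tessellate(hx)
  expect_equal(th$areas, rep(sqrt(3) / 2, 16), tolerance = 1e-10)
  expect_equal(th$perimeters, rep(2 * sqrt(3) * 1 / sqrt(3) * sqrt(3), 16),
               tolerance = 1e-10)
  expect_true(all(vapply(th$neighbors, length, integer(1)) == 6))

  # random centers: areas sum to the box area
  set.seed(31)
  L <- 7
  cfg <- spv_config(cbind(runif(50, 0, L), runif(50, 0, L)), box = c(L, L))
  tr <- tessellate(cfg)
  expect_lt(abs(sum(tr$areas) - L^2) / L^2, 1e-10)

  # collinear centers cannot tessellate with open boundaries
  bad <- spv_config(cbind(1:5, rep(2, 5)), boundary_mode = "open",
                    preferred_areas = rep(1, 5))
  expect_error(tessellate(bad), "degenerac")
})

test_that("the zero-energy manifold has zero forces", {
  hx <- spv_hex_config(5, 4, spacing = 1,
                       shape_factor = hexagon_shape_index(),
                       preferred_areas = rep(sqrt(3) / 2, 20))
  ef <- spv_energy_forces(hx)
  expect_equal(ef$energy, 0, tolerance = 1e-20)
  expect_lt(max(abs(ef$forces)), 1e-12)
})

test_that("analytic SPV forces equal finite differences of the energy", {
  set.seed(41)
  L <- 6
  cfg <- spv_config(cbind(runif(30, 0, L), runif(30, 0, L)), box = c(L, L),
                    shape_factor = 3.6)
  ef <- spv_energy_forces(cfg)
  en_of <- function(centers) {
    c2 <- cfg; c2$centers <- centers
    spv_energy_forces(c2)$energy
  }
  rows <- c(2, 11, 23, 30)
  g <- fd_gradient(en_of, cfg$centers, rows)
  expect_lt(max(abs(-g - ef$forces[rows, ])) / max(abs(ef$forces)), 1e-5)
})

test_that("the passive tissue at shape factor 3.6 resists shear", {
  hx <- spv_hex_config(6, 6, spacing = 1, shape_factor = 3.6,
                       preferred_areas = rep(sqrt(3) / 2, 36))
  e0 <- spv_energy_forces(hx)$energy
  for (g in c(-0.02, 0.02)) {
    sheared <- hx
    sheared$centers <- cbind(hx$centers[, 1] * (1 + g),
                             hx$centers[, 2] / (1 + g))
    sheared$box <- hx$box * c(1 + g, 1 / (1 + g))
    es <- spv_energy_forces(sheared)$energy
    expect_gt(es, e0 + 1e-4)  # finite shear stiffness on the solid side
  }
})

test_that("open boundaries flag hull cells and pay line tension", {
  set.seed(43)
  ctr <- cbind(rnorm(25, 0, 1.5), rnorm(25, 0, 1.5))
  cfg0 <- spv_config(ctr, box = NULL, boundary_mode = "open",
                     preferred_areas = rep(1, 25), boundary_tension = 0)
  cfg1 <- spv_config(ctr, box = NULL, boundary_mode = "open",
                     preferred_areas = rep(1, 25), boundary_tension = 0.3)
  t0 <- tessellate(cfg0)
  expect_true(any(t0$boundary))
  expect_false(all(t0$boundary))
  hull <- ctr[grDevices::chull(ctr), ]
  hp <- sum(sqrt(rowSums((hull[c(2:nrow(hull), 1), ] - hull)^2)))
  e0 <- spv_energy_forces(cfg0)$energy
  e1 <- spv_energy_forces(cfg1)$energy
  expect_equal(e1 - e0, 0.3 * hp, tolerance = 1e-10)
})

test_that("SPV dynamics is deterministic and static without drive", {
  hx <- spv_hex_config(4, 4, spacing = 1, shape_factor = 3.6,
                       preferred_areas = rep(sqrt(3) / 2, 16))
  drv0 <- active_drive(16, 0, 1, angles = rep(0, 16))
  tr <- run_spv(hx, drv0, dt = 0.01, n_steps = 20, save_every = 20, seed = 3)
  expect_lt(max(abs(cbind(tr$X[, 1], tr$Y[, 1]) - hx$centers)), 1e-9)

  drv <- active_drive(16, 0.05, 1)
  a1 <- run_spv(hx, drv, dt = 0.01, n_steps = 40, save_every = 20, seed = 5)
  a2 <- run_spv(hx, drv, dt = 0.01, n_steps = 40, save_every = 20, seed = 5)
  expect_identical(a1$X, a2$X)
  expect_identical(a1$TH, a2$TH)
})

test_that("relaxation dynamics slows when persistence grows at fixed T_eff", {
  # scaled-down sweep: same effective temperature, two persistence times;
  # the more persistent system decorrelates more slowly (glassier)
  set.seed(47)
  n <- 25; L <- 5
  ctr <- cbind(runif(n, 0, L), runif(n, 0, L))
  cfg <- spv_config(ctr, box = c(L, L), shape_factor = 3.85,
                    preferred_areas = rep(1, n))
  teff <- 0.02
  taus <- c(0.5, 5)
  tau_alpha <- numeric(2)
  for (i in 1:2) {
    v0 <- sqrt(2 * teff / taus[i])
    drv <- active_drive(n, v0, taus[i], angles = runif(n, 0, 2 * pi))
    tr <- run_spv(cfg, drv, dt = 0.02, n_steps = 3000, save_every = 30,
                  seed = 11)
    s <- measure_sisf(tr, q_magnitude = 2 * pi / sqrt(1 / pi))
    tau_alpha[i] <- s$tau_alpha
  }
  expect_gte(tau_alpha[2], tau_alpha[1])
})
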