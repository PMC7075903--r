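# Soft harmonic disk model: packing generation, energetics, relaxation and
# active Brownian dynamics.

test_that("packing generation solves the packing-fraction constraint", {
  cfg <- generate_packing(4, packing_fraction = 1, polydispersity = 0,
                          seed = 1, relax = FALSE)
  expect_equal(cfg$box_length[1], sqrt(4 * pi), tolerance = 1e-12)
  expect_equal(sum(pi * cfg$radii^2) / prod(cfg$box_length), 1, tolerance = 1e-12)

  cfg2 <- generate_packing(50, packing_fraction = 0.8, polydispersity = 0.3,
                           seed = 2, relax = FALSE)
  expect_equal(sum(pi * cfg2$radii^2) / prod(cfg2$box_length), 0.8,
               tolerance = 1e-12)
  expect_true(all(cfg2$radii >= 0.7 & cfg2$radii <= 1.3))

  expect_error(generate_packing(0, 1), class = "activesheet_invalid_parameter")
  expect_error(generate_packing(10, -1), class = "activesheet_invalid_parameter")
  expect_error(generate_packing(10, 1, polydispersity = 1),
               class = "activesheet_invalid_parameter")
})

test_that("a two-disk confluent box still relaxes to a force-balanced minimum", {
  # at phi = 1 two disks cannot avoid overlap; the minimum has finite energy
  cfg <- generate_packing(2, packing_fraction = 1, polydispersity = 0, seed = 3)
  ef <- energy_and_forces(cfg)
  expect_true(is.finite(ef$energy))
  expect_lt(max(abs(ef$forces)), 1e-7)
})

test_that("pair energetics match the harmonic contact law", {
  # separated disks: no interaction
  far <- soft_disk_config(rbind(c(2, 2), c(8, 2)), c(1, 1), 20)
  expect_equal(energy_and_forces(far)$energy, 0)
  expect_equal(max(abs(energy_and_forces(far)$forces)), 0)

  # overlap delta = 0.1 at k = 1: energy k/2 delta^2, force k delta
  two <- make_fixture_packing("two-disk")
  ef <- energy_and_forces(two)
  expect_equal(ef$energy, 0.005, tolerance = 1e-14)
  expect_equal(sqrt(rowSums(ef$forces^2)), c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(ef$forces[1, ], -ef$forces[2, ], tolerance = 1e-14)

  # coincident centers: undefined contact normal
  bad <- soft_disk_config(rbind(c(5, 5), c(5, 5) + 1e-15), c(1, 1), 20)
  expect_error(energy_and_forces(bad), "coincident")
})

test_that("analytic forces equal finite differences of the energy", {
  for (eps in c(0, 0.15)) {
    set.seed(7)
    cfg <- generate_packing(20, 1, 0.3, seed = 7, relax = FALSE)
    cfg$attraction_eps <- eps
    ef <- energy_and_forces(cfg)
    en_of <- function(pos) {
      c2 <- cfg; c2$positions <- pos
      energy_and_forces(c2)$energy
    }
    rows <- c(1, 5, 13, 20)
    g <- fd_gradient(en_of, cfg$positions, rows)
    expect_lt(max(abs(-g - ef$forces[rows, ])) / max(abs(ef$forces)), 1e-6)
  }
})

test_that("internal forces carry no net momentum", {
  cfg <- generate_packing(80, 1, 0.3, seed = 5, relax = FALSE)
  ef <- energy_and_forces(cfg)
  expect_lt(max(abs(colSums(ef$forces))), 1e-10 * max(abs(ef$forces)))
})

test_that("relaxation descends to the requested force tolerance", {
  cfg <- generate_packing(100, 1, 0.3, seed = 9, relax = FALSE)
  e0 <- energy_and_forces(cfg)$energy
  rel <- relax_to_minimum(cfg, tolerance = 1e-8)
  expect_lte(attr(rel, "energy"), e0)
  expect_lt(attr(rel, "fmax"), 1e-8 * mean(cfg$radii))
  expect_true(attr(rel, "converged"))

  # fixed point: relaxing again changes nothing appreciable
  rel2 <- relax_to_minimum(rel, tolerance = 1e-8)
  expect_lt(max(abs(rel2$positions - rel$positions)), 1e-6)

  # two overlapping disks free to separate reach zero energy
  pair <- soft_disk_config(rbind(c(10, 10), c(11.5, 10)), c(1, 1), 40)
  done <- relax_to_minimum(pair, tolerance = 1e-10)
  expect_equal(attr(done, "energy"), 0, tolerance = 1e-12)

  # non-convergence raises a warning carrying the residual
  expect_warning(relax_to_minimum(cfg, tolerance = 1e-8, max_iter = 3L),
                 "did not reach tolerance")
})

test_that("the active step reproduces its analytic limits", {
  # force-free motion: displacement dt * v0 along the polarity
  lone <- soft_disk_config(rbind(c(5, 5), c(15, 15)), c(1, 1), 30)
  drv <- active_drive(2, speed = 1, persistence = 1e12,
                      angles = c(0, pi / 2))
  st <- step_active(lone, drv, dt = 0.05)
  expect_equal(st$config$positions[1, ], c(5.05, 5), tolerance = 1e-10)
  expect_equal(st$config$positions[2, ], c(15, 15.05), tolerance = 1e-10)

  # v0 = 0 at a minimum: static
  cfg <- generate_packing(30, 1, 0.3, seed = 13)
  drv0 <- active_drive(30, 0, 1, angles = rep(0, 30))
  st0 <- step_active(cfg, drv0, dt = 0.01)
  expect_lt(max(abs(st0$config$positions - cfg$positions)), 1e-9)

  # unstable step warning when dt * force exceeds a radius
  squeezed <- soft_disk_config(rbind(c(5, 5), c(5.05, 5)), c(1, 1), 20)
  expect_warning(step_active(squeezed, active_drive(2, 0, 1, angles = c(0, 0)),
                             dt = 10), "unstable")
})

test_that("polarity autocorrelation decays as exp(-t / (2 tau))", {
  # 2D rotational diffusion with <eta eta> = delta/tau gives theta variance
  # t/tau, hence <n(t).n(0)> = exp(-t/(2 tau))
  tau <- 5
  lone <- soft_disk_config(rbind(c(10, 10), c(30, 30)), c(0.5, 0.5), 60)
  drv <- active_drive(2, speed = 0, persistence = tau)
  traj <- run_trajectory(lone, drv, dt = 0.01, n_steps = 200000,
                         save_every = 20, seed = 42)
  nf <- n_frames(traj)
  lags <- c(5, 10, 20, 40)
  for (lag in lags) {
    idx <- seq_len(nf - lag)
    c_meas <- mean(cos(traj$TH[, idx + lag] - traj$TH[, idx]))
    t_lag <- lag * diff(traj$times[1:2])
    expect_equal(c_meas, exp(-t_lag / (2 * tau)), tolerance = 0.08)
  }
})

test_that("trajectories are deterministic and counted correctly", {
  cfg <- generate_packing(20, 1, 0.3, seed = 17)
  drv <- active_drive(20, 0.1, 1, angles = seq(0, 2 * pi, length.out = 20))
  t1 <- run_trajectory(cfg, drv, dt = 0.01, n_steps = 100, save_every = 50,
                       seed = 77)
  expect_equal(n_frames(t1), 2L)
  t2 <- run_trajectory(cfg, drv, dt = 0.01, n_steps = 100, save_every = 50,
                       seed = 77)
  expect_identical(t1$X, t2$X)
  expect_identical(t1$TH, t2$TH)

  t3 <- run_trajectory(cfg, drv, dt = 0.01, n_steps = 1000, save_every = 100,
                       seed = 78, discard = 5)
  expect_true(all(t3$times > 5))
  expect_error(run_trajectory(cfg, drv, dt = 0.01, n_steps = 10,
                              save_every = 50),
               class = "activesheet_invalid_parameter")
})

test_that("division and extrusion hold the population near its target", {
  cfg <- generate_packing(60, 1, 0.3, seed = 19)
  drv <- active_drive(60, 0.05, 1)
  # infinite cycle time: no division events at all
  res0 <- divide_and_extrude(cfg, drv, cycle_time = Inf, target_n = 60,
                             dt = 0.01, n_steps = 500, save_every = 100,
                             seed = 4)
  expect_equal(nrow(res0$config$positions), 60L)
  expect_equal(nrow(res0$n_history), 0L)

  # finite cycle time: steady state within +/- 5% of target
  res <- divide_and_extrude(cfg, drv, cycle_time = 50, target_n = 60,
                            dt = 0.01, n_steps = 10000, save_every = 1000,
                            seed = 4)
  expect_true(all(abs(res$n_history$n - 60) / 60 <= 0.05))
  expect_equal(nrow(res$config$positions), 60L)
})
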