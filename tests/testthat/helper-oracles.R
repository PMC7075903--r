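# Shared numerical oracles, independent of the implementation paths they test.

# Central finite-difference gradient of a scalar function of an N x 2
# coordinate matrix, evaluated at selected rows.
fd_gradient <- function(energy_fn, coords, rows, h = 1e-6) {
  g <- matrix(0, length(rows), 2)
  for (k in seq_along(rows)) for (d in 1:2) {
    cp <- coords; cm <- coords
    cp[rows[k], d] <- cp[rows[k], d] + h
    cm[rows[k], d] <- cm[rows[k], d] - h
    g[k, d] <- (energy_fn(cp) - energy_fn(cm)) / (2 * h)
  }
  g
}

# Hankel-transform oracle for the real-space velocity correlation: numerically
# inverts the two-Lorentzian Fourier spectrum by integrating between Bessel
# zeros and accelerating the alternating interval series by repeated
# partial-sum averaging (Euler transformation).
cvv_hankel_oracle <- function(params, r, n_zero = 120, levels = 8) {
  f <- function(q) q * besselJ(q * r, 0) *
    (1 / (1 + (params$xi_L * q)^2) + 1 / (1 + (params$xi_T * q)^2))
  zeros <- c(0, (seq_len(n_zero) - 0.25) * pi / r)
  terms <- vapply(seq_len(n_zero), function(i)
    integrate(f, zeros[i], zeros[i + 1], rel.tol = 1e-11)$value, numeric(1))
  ps <- cumsum(terms)
  tail_ps <- ps[(n_zero - 40):n_zero]
  for (l in seq_len(levels))
    tail_ps <- (tail_ps[-1] + tail_ps[-length(tail_ps)]) / 2
  params$a^2 * params$v0^2 / (4 * pi) * tail_ps[length(tail_ps)]
}

# Relaxed-strain oracle for elastic moduli in per-particle units: impose a
# small affine strain, re-minimize, differentiate the energy.
strain_oracle <- function(cfg, h = 1e-3, relax = TRUE) {
  A <- prod(cfg$box_length)
  acell <- A / nrow(cfg$positions)
  en <- function(exx, eyy) {
    c2 <- cfg
    c2$positions <- cbind(cfg$positions[, 1] * (1 + exx),
                          cfg$positions[, 2] * (1 + eyy))
    c2$box_length <- cfg$box_length * c(1 + exx, 1 + eyy)
    if (relax) attr(relax_to_minimum(c2, tolerance = 1e-10), "energy")
    else energy_and_forces(c2)$energy
  }
  e0 <- if (relax) attr(relax_to_minimum(cfg, tolerance = 1e-10), "energy")
        else energy_and_forces(cfg)$energy
  c(B = (en(h, h) - 2 * e0 + en(-h, -h)) / h^2 / (4 * A) * acell,
    mu = (en(h, -h) - 2 * e0 + en(-h, h)) / h^2 / (4 * A) * acell)
}

# Hand-built trajectory object (for estimator oracles that need synthetic
# kinematics rather than simulator output).
fake_trajectory <- function(times, X, Y, VX, VY, radii, L,
                            XU = X, YU = Y, TH = NULL) {
  if (is.null(TH)) TH <- matrix(0, nrow(X), ncol(X))
  activesheet:::new_trajectory(times, X, Y, XU, YU, VX, VY, TH, radii, L,
                               list(model = "synthetic"))
}
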