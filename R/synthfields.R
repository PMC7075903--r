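# Synthetic PIV-like velocity fields: Gaussian random vector fields whose
# longitudinal and transverse spectral components follow the Lorentzian
# mixture 1/(1 + xi_L^2 q^2), 1/(1 + xi_T^2 q^2), on a rectangular grid that
# emulates the experimental PIV output (54 x 40 nodes, 16 micron spacing,
# mean speed of order 12 micron/h).

#' Gridded velocity field sequence
#'
#' @param x,y Grid node coordinates (regular spacing).
#' @param U,V Arrays `nx x ny x n_frames` of velocity components.
#' @param spacing Grid spacing.
#' @param times Optional frame times.
#' @return A `grid_field_sequence`.
#' @export
grid_field_sequence <- function(x, y, U, V, spacing, times = NULL) {
  if (length(dim(U)) != 3 || !all(dim(U) == dim(V)))
    stop_invalid("U and V must be nx x ny x n_frames arrays of equal dimension")
  if (dim(U)[1] != length(x) || dim(U)[2] != length(y))
    stop_invalid("grid coordinate lengths must match the field arrays")
  if (any(!is.finite(U)) || any(!is.finite(V)))
    stop_invalid("velocity fields must be finite")
  if (length(x) > 1) {
    dx <- diff(x)
    if (max(abs(dx - spacing)) > 1e-9 * spacing)
      stop_invalid("irregular grid spacing in x")
  }
  if (length(y) > 1 && max(abs(diff(y) - spacing)) > 1e-9 * spacing)
    stop_invalid("irregular grid spacing in y")
  if (is.null(times)) times <- seq_len(dim(U)[3])
  structure(list(x = x, y = y, U = U, V = V, spacing = spacing, times = times),
            class = "grid_field_sequence")
}

#' @export
print.grid_field_sequence <- function(x, ...) {
  cat(sprintf("Gridded velocity fields: %d x %d nodes, spacing %.4g, %d frames\n",
              length(x$x), length(x$y), x$spacing, dim(x$U)[3]))
  invisible(x)
}

#' Generate synthetic velocity fields with a Lorentzian spectrum
#'
#' Draws statistically independent frames of a Gaussian random vector field
#' whose Fourier components along `q_hat` have variance proportional to
#' `1/(1 + xi_L^2 q^2)` and along the perpendicular direction
#' `1/(1 + xi_T^2 q^2)`; each frame is inverse-transformed from
#' Hermitian-symmetric coefficients (real white noise filtered in Fourier
#' space) and rescaled to the requested root-mean-square speed.
#'
#' @param nx,ny Grid size (>= 8 each).
#' @param spacing Grid spacing (e.g. microns).
#' @param xi_L,xi_T Longitudinal and transverse correlation lengths (0 gives
#'   a spatially white field).
#' @param v_rms Root-mean-square speed of each frame.
#' @param n_frames Number of independent frames.
#' @param seed Optional RNG seed.
#' @return A `grid_field_sequence`.
#' @export
generate_field <- function(nx = 54, ny = 40, spacing = 16, xi_L, xi_T,
                           v_rms = 1, n_frames = 1, seed = NULL) {
  if (nx < 8 || ny < 8) stop_invalid("nx and ny must be >= 8")
  check_scalar(spacing, "spacing")
  if (xi_L < 0 || xi_T < 0) stop_invalid("correlation lengths must be >= 0")
  check_scalar(v_rms, "v_rms")
  if (!is.null(seed)) set.seed(seed)
  qx <- 2 * pi * ifelse(0:(nx - 1) <= nx / 2, 0:(nx - 1), 0:(nx - 1) - nx) / (nx * spacing)
  qy <- 2 * pi * ifelse(0:(ny - 1) <= ny / 2, 0:(ny - 1), 0:(ny - 1) - ny) / (ny * spacing)
  QX <- matrix(qx, nx, ny); QY <- matrix(qy, nx, ny, byrow = TRUE)
  Q2 <- QX^2 + QY^2
  AL <- 1 / sqrt(1 + xi_L^2 * Q2)
  AT <- 1 / sqrt(1 + xi_T^2 * Q2)
  Qm <- sqrt(Q2); Qm[1, 1] <- 1
  ex <- QX / Qm; ey <- QY / Qm
  ex[1, 1] <- 1; ey[1, 1] <- 0          # q = 0: both amplitudes are 1 anyway
  U <- array(0, c(nx, ny, n_frames)); V <- array(0, c(nx, ny, n_frames))
  for (f in seq_len(n_frames)) {
    wx <- matrix(rnorm(nx * ny), nx, ny)
    wy <- matrix(rnorm(nx * ny), nx, ny)
    Wx <- stats::fft(wx); Wy <- stats::fft(wy)
    lon <- ex * Wx + ey * Wy            # component along q_hat
    trv <- -ey * Wx + ex * Wy           # component along q_hat_perp
    Fx <- AL * lon * ex - AT * trv * ey
    Fy <- AL * lon * ey + AT * trv * ex
    u <- Re(stats::fft(Fx, inverse = TRUE)) / (nx * ny)
    v <- Re(stats::fft(Fy, inverse = TRUE)) / (nx * ny)
    sc <- v_rms / sqrt(mean(u^2 + v^2))
    U[, , f] <- u * sc; V[, , f] <- v * sc
  }
  grid_field_sequence(x = (0:(nx - 1)) * spacing, y = (0:(ny - 1)) * spacing,
                      U = U, V = V, spacing = spacing)
}

#' Periodic hexagonal soft-disk crystal
#'
#' Monodisperse triangular lattice in a commensurate rectangular periodic box
#' with a uniform contact overlap; force-free by symmetry, and a convenient
#' reference crystal for elastic-moduli cross-checks.
#'
#' @param nx,ny Columns and rows (`ny` even).
#' @param overlap Relative lattice compression (0.02 = 2% overlap).
#' @param radius Disk radius.
#' @param stiffness Contact stiffness.
#' @return A `soft_disk_config` with a rectangular box.
#' @export
hex_packing <- function(nx, ny, overlap = 0.02, radius = 1, stiffness = 1) {
  if (ny %% 2 != 0) stop_invalid("ny must be even for periodicity")
  spacing <- 2 * radius * (1 - overlap)
  ay <- spacing * sqrt(3) / 2
  g <- expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1))
  xs <- (g$ix + ifelse(g$iy %% 2 == 1, 0.5, 0)) * spacing
  soft_disk_config(cbind(xs, g$iy * ay), radii = rep(radius, nx * ny),
                   box_length = c(nx * spacing, ny * ay), stiffness = stiffness)
}

#' Deterministic small fixture packings
#'
#' Named soft-disk configurations used as test fixtures: `"two-disk"` (two
#' unit disks with overlap 0.1 in a large box), `"hex-lattice-16"` (a 4 x 4
#' triangular lattice of monodisperse disks at 2% overlap, force-free by
#' symmetry) and `"random-64"` (a relaxed 64-particle packing at packing
#' fraction 1, 30% polydispersity, seed 7). Reference energies are attached
#' as the `reference_energy` attribute.
#'
#' @param name Fixture identifier.
#' @return A `soft_disk_config`.
#' @export
make_fixture_packing <- function(name = c("two-disk", "hex-lattice-16", "random-64")) {
  name <- match.arg(name)
  cfg <- switch(name,
    "two-disk" = {
      # centers 1.9 apart: overlap delta = 0.1, |force| = k * delta = 0.1
      soft_disk_config(rbind(c(5, 5), c(6.9, 5)), radii = c(1, 1),
                       box_length = 20, stiffness = 1)
    },
    "hex-lattice-16" = hex_packing(4, 4, overlap = 0.02),
    "random-64" = generate_packing(64, packing_fraction = 1,
                                   polydispersity = 0.3, seed = 7)
  )
  attr(cfg, "reference_energy") <- energy_and_forces(cfg)$energy
  cfg
}
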