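# Normal-mode linear response of jammed soft-disk packings: Hessian assembly,
# eigenmodes, mode energies, mode-resolved velocity correlations, the
# Fourier-space dynamical matrix D(q), and elastic moduli extraction.

#' Contact list of a soft-disk configuration
#'
#' All interacting pairs at the current positions with their minimum-image
#' separation vectors and the per-contact Hessian coefficients
#' `kn = V''(r)` and `kt = -V'(r)/r` (for a plain harmonic contact,
#' `kn = k` and `kt = f/r` with `f` the repulsive force magnitude).
#'
#' @param config A `soft_disk_config`.
#' @return A data frame with columns `i, j, dx, dy, r, kn, kt`.
#' @export
contact_list <- function(config) {
  stopifnot(inherits(config, "soft_disk_config"))
  as.data.frame(.sd_contacts(config$positions[, 1], config$positions[, 2],
                             config$radii, config$box_length[1],
                             config$box_length[2],
                             config$stiffness, config$attraction_eps))
}

#' Assemble the Hessian (dynamical matrix) of a packing
#'
#' Each contact contributes the 2 x 2 block
#' `K_ij = -kn n n^T + kt t t^T` to the off-diagonal `(i, j)` element and
#' `-K_ij` accumulates on the diagonal, so block rows sum to zero
#' (translation invariance). `kt = f/r` carries the dimensional `1/r`
#' restored relative to the bare-`|f|` convention; set
#' `dimensional_tangent = FALSE` to reproduce the latter.
#'
#' @param config A `soft_disk_config` at mechanical equilibrium (a warning is
#'   raised otherwise, since pre-stress shifts the spectrum).
#' @param dimensional_tangent Use `f/r` (default) rather than bare `|f|` in
#'   the tangential block.
#' @param force_tolerance Residual-force threshold for the equilibrium check,
#'   in units of `k * mean(radii)`.
#' @return A `hessian_matrix` object: the dense `2N x 2N` symmetric matrix
#'   with the reference configuration attached.
#' @export
assemble_hessian <- function(config, dimensional_tangent = TRUE,
                             force_tolerance = 1e-6) {
  stopifnot(inherits(config, "soft_disk_config"))
  ef <- energy_and_forces(config)
  fscale <- config$stiffness * mean(config$radii)
  if (max(sqrt(rowSums(ef$forces^2))) > force_tolerance * fscale)
    warning("configuration is not at mechanical equilibrium: pre-stress terms shift the spectrum",
            call. = FALSE)
  cl <- contact_list(config)
  n <- nrow(config$positions)
  H <- matrix(0, 2 * n, 2 * n)
  if (nrow(cl)) {
    nx <- cl$dx / cl$r; ny <- cl$dy / cl$r
    kt <- if (dimensional_tangent) cl$kt else cl$kt * cl$r
    # off-diagonal block K_ij = -kn n n^T + kt t t^T, t = (-ny, nx)
    kxx <- -cl$kn * nx * nx + kt * ny * ny
    kyy <- -cl$kn * ny * ny + kt * nx * nx
    kxy <- -(cl$kn + kt) * nx * ny
    for (c in seq_len(nrow(cl))) {
      i <- cl$i[c]; j <- cl$j[c]
      ix <- 2 * i - 1; jx <- 2 * j - 1
      blk <- matrix(c(kxx[c], kxy[c], kxy[c], kyy[c]), 2, 2)
      H[ix:(ix + 1), jx:(jx + 1)] <- H[ix:(ix + 1), jx:(jx + 1)] + blk
      H[jx:(jx + 1), ix:(ix + 1)] <- H[jx:(jx + 1), ix:(ix + 1)] + blk
      H[ix:(ix + 1), ix:(ix + 1)] <- H[ix:(ix + 1), ix:(ix + 1)] - blk
      H[jx:(jx + 1), jx:(jx + 1)] <- H[jx:(jx + 1), jx:(jx + 1)] - blk
    }
  }
  structure(list(matrix = H, reference = config$positions,
                 box_length = config$box_length, contacts = cl,
                 n_particles = n),
            class = "hessian_matrix")
}

#' @export
print.hessian_matrix <- function(x, ...) {
  cat(sprintf("Hessian: %d particles (%d x %d), %d contacts\n",
              x$n_particles, 2 * x$n_particles, 2 * x$n_particles,
              nrow(x$contacts)))
  invisible(x)
}

#' Normal modes of a Hessian
#'
#' Full symmetric eigendecomposition; eigenvalues ascending, eigenvectors
#' orthonormal. A jammed periodic packing has exactly two (numerically) zero
#' translation modes and otherwise positive eigenvalues.
#'
#' @param hessian A `hessian_matrix`.
#' @return A `mode_set`: `values` (ascending), `vectors` (columns matching
#'   `values`), reference positions and box length.
#' @export
eigenmodes <- function(hessian) {
  stopifnot(inherits(hessian, "hessian_matrix"))
  e <- eigen(hessian$matrix, symmetric = TRUE)
  idx <- order(e$values)
  structure(list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE],
                 reference = hessian$reference, box_length = hessian$box_length,
                 n_particles = hessian$n_particles),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("Mode set: %d modes, eigenvalues in [%.3g, %.3g], %d near-zero (<1e-8)\n",
              length(x$values), min(x$values), max(x$values),
              sum(abs(x$values) < 1e-8)))
  invisible(x)
}

#' Mean energy per normal mode under active driving
#'
#' `E_nu = zeta v0^2 tau / (4 (1 + lambda_nu tau / zeta))`. In the limit
#' `tau -> 0` every mode carries `T_eff / 2` with
#' `T_eff = zeta v0^2 tau / 2` (effective thermal equilibrium); for
#' `tau -> Inf` the lowest modes dominate as `zeta^2 v0^2 / (4 lambda)`.
#'
#' @param modes A `mode_set`, or a numeric vector of eigenvalues.
#' @param v0 Active speed.
#' @param tau Persistence time.
#' @param zeta Substrate friction.
#' @return Numeric vector of mode energies.
#' @export
mode_energies <- function(modes, v0, tau, zeta = 1) {
  lambda <- if (inherits(modes, "mode_set")) modes$values else as.numeric(modes)
  if (any(lambda < -1e-8)) stop_invalid("mode energies require lambda >= 0")
  zeta * v0^2 * tau / (4 * (1 + pmax(lambda, 0) * tau / zeta))
}

# Fourier transforms of all eigenvectors at the given wavevectors:
# |xi_nu(q)|^2 with xi_nu(q) = (1/N) sum_j exp(i q r_j) xi_nu^j.
mode_fourier_weights <- function(modes, q) {
  R <- modes$reference
  n <- nrow(R)
  phase <- R %*% t(q)              # N x Q
  C <- cos(phase); S <- sin(phase)
  ix <- seq(1, 2 * n, by = 2)
  Xx <- modes$vectors[ix, , drop = FALSE]      # N x 2N
  Xy <- modes$vectors[ix + 1, , drop = FALSE]
  (crossprod(C, Xx)^2 + crossprod(S, Xx)^2 +
   crossprod(C, Xy)^2 + crossprod(S, Xy)^2) / n^2   # Q x 2N
}

#' Mode-resolved prediction of the Fourier velocity correlation
#'
#' The normal-mode sum
#' `<|v(q)|^2> = sum_nu v0^2 / (2 (1 + lambda_nu tau / zeta)) |xi_nu(q)|^2`
#' with `xi_nu(q) = (1/N) sum_j exp(i q . r_j) xi_nu^j` evaluated at the
#' reference (equilibrium) positions, followed by a radial q average.
#'
#' @param modes A `mode_set`.
#' @param v0,tau Active speed and persistence time.
#' @param zeta Substrate friction.
#' @param q Optional matrix of wavevectors; defaults to the commensurate grid
#'   up to `q_max`.
#' @param q_max Largest wavenumber when `q` is not given.
#' @param bin If `TRUE` (default) radially average into bins of width
#'   `2 pi / L`; otherwise return per-wavevector values.
#' @return A `q_correlation` (binned) or a list with `q` and `value`.
#' @export
mode_velocity_correlation <- function(modes, v0, tau, zeta = 1, q = NULL,
                                      q_max = 2, bin = TRUE) {
  stopifnot(inherits(modes, "mode_set"))
  if (is.null(q)) q <- q_grid(modes$box_length, q_max)
  else {
    dq <- 2 * pi / modes$box_length
    off <- abs(sweep(q, 2, dq, "/") - round(sweep(q, 2, dq, "/")))
    if (any(off > 1e-8))
      warning("some wavevectors are incommensurate with the periodic box", call. = FALSE)
  }
  w <- v0^2 / (2 * (1 + modes$values * tau / zeta))
  vals <- as.numeric(mode_fourier_weights(modes, q) %*% w)
  if (!bin) return(list(q = q, value = vals))
  bw <- 2 * pi / max(modes$box_length)
  ra <- radial_average(q, vals, bw)
  new_q_correlation(ra$q, ra$value, ra$counts, normalization = "none",
                    bin_width = bw,
                    meta = list(source = "mode_sum", v0 = v0, tau = tau, zeta = zeta))
}

#' Fourier dynamical matrix branches
#'
#' Builds `D(q) = (1/N) sum_jl exp(i q . (r_j - r_l)) H_jl` on a set of
#' commensurate wavevectors, diagonalises each 2 x 2 matrix and labels the
#' eigenvector with the larger projection on `q_hat` as longitudinal.
#'
#' @param config A `soft_disk_config` at equilibrium.
#' @param q Matrix of wavevectors.
#' @param tangent `"printed"` uses the bare `|f|` tangential coefficient of
#'   the contact-Hessian recipe; `"dimensional"` uses `f/r` (the exact second
#'   derivative). See [estimate_moduli()] for the distinction.
#' @return Data frame with `qx, qy, qmag, lambda_L, lambda_T`.
#' @export
dq_branches <- function(config, q, tangent = c("printed", "dimensional")) {
  tangent <- match.arg(tangent)
  cl <- contact_list(config)
  kt <- if (tangent == "printed") cl$kt * cl$r else cl$kt
  comp <- .dq_components(cl$dx, cl$dy, cl$kn, kt, q[, 1], q[, 2],
                         nrow(config$positions))
  qmag <- sqrt(rowSums(q^2))
  lam_L <- lam_T <- numeric(nrow(q))
  for (iq in seq_len(nrow(q))) {
    D <- matrix(c(comp[iq, 1], comp[iq, 3], comp[iq, 3], comp[iq, 2]), 2, 2)
    e <- eigen(D, symmetric = TRUE)
    qhat <- q[iq, ] / qmag[iq]
    p1 <- abs(sum(e$vectors[, 1] * qhat))
    p2 <- abs(sum(e$vectors[, 2] * qhat))
    if (p1 >= p2) { lam_L[iq] <- e$values[1]; lam_T[iq] <- e$values[2] }
    else          { lam_L[iq] <- e$values[2]; lam_T[iq] <- e$values[1] }
  }
  data.frame(qx = q[, 1], qy = q[, 2], qmag = qmag,
             lambda_L = lam_L, lambda_T = lam_T)
}

# Radially average branch values using the mean |q| of each bin (bin centers
# distort the lowest shells).
bin_branch <- function(qmag, values, bw) {
  bin <- floor(qmag / bw)
  list(q = as.numeric(tapply(qmag, bin, mean)),
       value = as.numeric(tapply(values, bin, mean)),
       counts = as.integer(tapply(values, bin, length)))
}

#' Estimate elastic moduli of a packing
#'
#' The default (`method = "dq"`) follows the dynamical-matrix recipe: build
#' `D(q)` from the contact Hessian on the commensurate grid, radially average
#' the longitudinal and transverse eigenvalue branches, and fit `B + mu` as
#' the slope of `lambda_L(q)` vs `q^2` through the origin up to `q_max_fit`
#' (and `mu` from `lambda_T(q)`). Slopes are quoted in per-particle units
#' (physical modulus times area per particle), the convention in which the
#' reference soft-disk packing at packing fraction 1 has `B` near 1.68.
#'
#' Two cross-checking estimators are provided. `method = "greens"` measures
#' the branches of the inverse Hessian (Green's function),
#' `lambda_b(q) = 1 / (N e_b(q)^H H^+ e_b(q))`, which includes the
#' non-affine softening that the plane-wave quadratic form of `D(q)` leaves
#' out; `method = "strain"` imposes small affine strains, re-minimizes, and
#' differentiates the relaxed energy (the direct definition of the true
#' static moduli; slower).
#'
#' For `method = "dq"`, `tangent` selects the tangential coefficient of the
#' contact recipe: `"printed"` (bare `|f|`, the published form of the
#' contact Hessian used for this measurement) or `"dimensional"` (`f/r`, the
#' exact energy second derivative that [assemble_hessian()] uses). The two
#' differ by the contact-length factor and noticeably shift the transverse
#' slope; the methods vignette discusses the choice.
#'
#' @param config A relaxed `soft_disk_config`.
#' @param q_max_fit Upper end of the fit range (1.5 in natural units).
#' @param method `"dq"` (default), `"greens"` or `"strain"`.
#' @param tangent Tangential convention for `method = "dq"`.
#' @return A `moduli_estimate`: `B`, `mu`, slopes, and (for q-space methods)
#'   the binned branch table.
#' @export
estimate_moduli <- function(config, q_max_fit = 1.5,
                            method = c("dq", "greens", "strain"),
                            tangent = c("printed", "dimensional")) {
  stopifnot(inherits(config, "soft_disk_config"))
  method <- match.arg(method)
  tangent <- match.arg(tangent)
  if (method == "strain") return(strain_moduli(config))
  q <- q_grid(config$box_length, 2 * q_max_fit)
  qmag <- sqrt(rowSums(q^2))
  if (method == "dq") {
    br <- dq_branches(config, q, tangent = tangent)
    lam_L <- br$lambda_L; lam_T <- br$lambda_T
  } else {
    gb <- greens_branches(config, q)
    lam_L <- gb$lambda_L; lam_T <- gb$lambda_T
  }
  bw <- 2 * pi / max(config$box_length)
  ra_L <- bin_branch(qmag, lam_L, bw)
  ra_T <- bin_branch(qmag, lam_T, bw)
  sel <- ra_L$q <= q_max_fit
  if (sum(sel) < 3)
    stop_invalid("insufficient q resolution below q_max_fit: enlarge the system or the fit range")
  q2 <- ra_L$q[sel]^2
  fit_L <- stats::lm.fit(cbind(q2), ra_L$value[sel])
  fit_T <- stats::lm.fit(cbind(q2), ra_T$value[sel])
  slope_L <- fit_L$coefficients[[1]]
  slope_T <- fit_T$coefficients[[1]]
  structure(list(B = slope_L - slope_T, mu = slope_T,
                 slope_L = slope_L, slope_T = slope_T,
                 fit_range = c(0, q_max_fit), method = method,
                 tangent = if (method == "dq") tangent else "dimensional",
                 residuals = list(L = fit_L$residuals, T = fit_T$residuals),
                 branches = data.frame(q = ra_L$q, lambda_L = ra_L$value,
                                       lambda_T = ra_T$value,
                                       counts = ra_L$counts)),
            class = "moduli_estimate")
}

# Inverse-Hessian (Green's function) branches via sparse Cholesky: for each
# wavevector and polarization e, lambda = 1 / (N e^H H^+ e) with the
# translations projected out of the plane-wave vector.
greens_branches <- function(config, q) {
  cl <- contact_list(config)
  n <- nrow(config$positions)
  x <- config$positions[, 1]; y <- config$positions[, 2]
  nx <- cl$dx / cl$r; ny <- cl$dy / cl$r
  Kxx <- -cl$kn * nx * nx + cl$kt * ny * ny
  Kyy <- -cl$kn * ny * ny + cl$kt * nx * nx
  Kxy <- -(cl$kn + cl$kt) * nx * ny
  i2 <- 2 * cl$i - 1; j2 <- 2 * cl$j - 1
  ti <- c(i2, i2, i2 + 1, i2 + 1, j2, j2, j2 + 1, j2 + 1,
          i2, i2, i2 + 1, i2 + 1, j2, j2, j2 + 1, j2 + 1)
  tj <- c(j2, j2 + 1, j2, j2 + 1, i2, i2 + 1, i2, i2 + 1,
          i2, i2 + 1, i2, i2 + 1, j2, j2 + 1, j2, j2 + 1)
  tx <- c(Kxx, Kxy, Kxy, Kyy, Kxx, Kxy, Kxy, Kyy,
          -Kxx, -Kxy, -Kxy, -Kyy, -Kxx, -Kxy, -Kxy, -Kyy)
  H <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(2 * n, 2 * n))
  eps <- 1e-9 * mean(Matrix::diag(H))
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(H + Matrix::Diagonal(2 * n, eps)),
                         LDL = FALSE, super = TRUE)
  ix <- seq(1, 2 * n, 2); iy <- ix + 1
  qmag <- sqrt(rowSums(q^2))
  lam_L <- lam_T <- numeric(nrow(q))
  for (iq in seq_len(nrow(q))) {
    qh <- q[iq, ] / qmag[iq]; qp <- c(-qh[2], qh[1])
    ph <- q[iq, 1] * x + q[iq, 2] * y
    for (b in 1:2) {
      e <- if (b == 1) qh else qp
      G <- 0
      for (part in 1:2) {
        w <- if (part == 1) cos(ph) else sin(ph)
        rhs <- numeric(2 * n)
        rhs[ix] <- w * e[1] / n; rhs[iy] <- w * e[2] / n
        rhs[ix] <- rhs[ix] - mean(rhs[ix])
        rhs[iy] <- rhs[iy] - mean(rhs[iy])
        G <- G + sum(rhs * as.numeric(Matrix::solve(ch, rhs)))
      }
      if (b == 1) lam_L[iq] <- 1 / (n * G) else lam_T[iq] <- 1 / (n * G)
    }
  }
  list(lambda_L = lam_L, lambda_T = lam_T)
}

# True static moduli: strain, re-minimize, differentiate the relaxed energy.
# Quoted in the same per-particle units as the branch slopes.
strain_moduli <- function(config, h = 2e-3) {
  A <- prod(config$box_length)
  acell <- A / nrow(config$positions)
  strained <- function(exx, eyy) {
    c2 <- config
    c2$positions <- cbind(config$positions[, 1] * (1 + exx),
                          config$positions[, 2] * (1 + eyy))
    c2$box_length <- config$box_length * c(1 + exx, 1 + eyy)
    attr(relax_to_minimum(c2, tolerance = 1e-10), "energy")
  }
  e0 <- attr(relax_to_minimum(config, tolerance = 1e-10), "energy")
  B <- (strained(h, h) - 2 * e0 + strained(-h, -h)) / h^2 / (4 * A)
  mu <- (strained(h, -h) - 2 * e0 + strained(-h, h)) / h^2 / (4 * A)
  structure(list(B = B * acell, mu = mu * acell,
                 slope_L = (B + mu) * acell, slope_T = mu * acell,
                 fit_range = c(NA_real_, NA_real_), method = "strain",
                 tangent = "dimensional", residuals = NULL, branches = NULL),
            class = "moduli_estimate")
}

#' @export
print.moduli_estimate <- function(x, ...) {
  cat(sprintf("Elastic moduli (%s%s, per-particle units):\n", x$method,
              if (x$method == "dq") paste0(", ", x$tangent, " tangent") else ""))
  cat(sprintf("  B  = %.4g\n  mu = %.4g\n  (mu + B) / mu = %.4g\n",
              x$B, x$mu, (x$mu + x$B) / x$mu))
  invisible(x)
}
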