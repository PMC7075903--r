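# Self-propelled Voronoi (SPV) model: every cell is the Voronoi tile of its
# center and the tissue energy is V_i = K/2 (A_i - A0)^2 + Gamma/2 (P_i - P0)^2
# per cell. The tessellation is built by half-plane clipping (each tile vertex
# is the circumcenter of its generating triple), which makes exact analytic
# forces available through circumcenter derivatives.

#' SPV model configuration
#'
#' @param centers N x 2 matrix of cell centers.
#' @param box Periodic box sides `c(Lx, Ly)` (periodic mode).
#' @param preferred_areas Per-cell preferred areas `A0_i` (> 0); defaults to
#'   equal partition of the box.
#' @param area_stiffness Area stiffness `K` (energy / length^4).
#' @param perimeter_stiffness Perimeter stiffness `Gamma` (energy / length^2).
#' @param shape_factor Dimensionless preferred perimeter
#'   `p0_bar = P0 / sqrt(A0)`; the passive solid-fluid transition sits near
#'   3.812, and 3.6 places the passive tissue in the solid phase.
#' @param boundary_tension Line tension `lambda` applied to the outer contour
#'   in open mode.
#' @param boundary_mode `"periodic"` (reference-tested default) or `"open"`.
#' @param friction Substrate friction `zeta`.
#' @return An `spv_config`.
#' @export
spv_config <- function(centers, box, preferred_areas = NULL,
                       area_stiffness = 1, perimeter_stiffness = 1,
                       shape_factor = 3.6, boundary_tension = 0,
                       boundary_mode = c("periodic", "open"), friction = 1) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L || nrow(centers) < 3L)
    stop_invalid("need at least 3 cell centers (N x 2 matrix)")
  boundary_mode <- match.arg(boundary_mode)
  if (boundary_mode == "periodic") {
    if (length(box) == 1L) box <- c(box, box)
    if (any(box <= 0)) stop_invalid("box sides must be > 0")
    centers <- cbind(centers[, 1] %% box[1], centers[, 2] %% box[2])
  } else box <- c(NA_real_, NA_real_)
  if (anyDuplicated(centers)) stop_invalid("cell centers must be distinct")
  n <- nrow(centers)
  if (is.null(preferred_areas))
    preferred_areas <- rep(if (boundary_mode == "periodic") prod(box) / n else 1, n)
  if (length(preferred_areas) != n || any(preferred_areas <= 0))
    stop_invalid("preferred_areas must be positive, one per cell")
  if (area_stiffness < 0 || perimeter_stiffness < 0)
    stop_invalid("stiffnesses must be >= 0")
  structure(list(centers = centers, box = box,
                 preferred_areas = as.numeric(preferred_areas),
                 area_stiffness = area_stiffness,
                 perimeter_stiffness = perimeter_stiffness,
                 shape_factor = shape_factor,
                 preferred_perimeters = shape_factor * sqrt(preferred_areas),
                 boundary_tension = boundary_tension,
                 boundary_mode = boundary_mode, friction = friction),
            class = "spv_config")
}

#' @export
print.spv_config <- function(x, ...) {
  cat(sprintf("SPV configuration: N = %d cells, %s boundaries, K = %.3g, Gamma = %.3g, p0_bar = %.3g\n",
              nrow(x$centers), x$boundary_mode, x$area_stiffness,
              x$perimeter_stiffness, x$shape_factor))
  invisible(x)
}

#' Hexagonal SPV reference lattice
#'
#' A periodic triangular lattice of centers whose Voronoi tiles are regular
#' hexagons; useful as a zero-energy reference when `shape_factor` equals the
#' hexagon shape index (about 3.722) and `A0` the tile area.
#'
#' @param nx,ny Number of columns and rows (`ny` must be even).
#' @param spacing Lattice constant.
#' @param ... Passed to [spv_config()].
#' @return An `spv_config`.
#' @export
spv_hex_config <- function(nx, ny, spacing = 1, ...) {
  if (ny %% 2 != 0) stop_invalid("ny must be even for periodicity")
  ay <- spacing * sqrt(3) / 2
  g <- expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1))
  xs <- (g$ix + ifelse(g$iy %% 2 == 1, 0.5, 0)) * spacing
  ys <- g$iy * ay
  spv_config(cbind(xs, ys), box = c(nx * spacing, ny * ay), ...)
}

#' Shape index of a regular hexagon
#' @return `P / sqrt(A)` of a regular hexagon (about 3.722).
#' @export
hexagon_shape_index <- function() {
  s <- 1 / sqrt(3)                      # side for unit lattice constant
  6 * s / sqrt(3 * sqrt(3) / 2 * s^2)
}

# --- tessellation ------------------------------------------------------------

# Clip the convex polygon `poly` (CCW, list with matrix `v` and integer edge
# labels `lab`, lab[k] labels edge v[k] -> v[k+1]) by the half plane
# { x : x . d <= |d|^2 / 2 } (the bisector between the origin and point d).
clip_halfplane <- function(poly, d, label) {
  clip_halfplane_general(poly, d, 0.5 * sum(d * d), label)
}

# General half-plane clip: keep { x : x . nrm <= off }.
clip_halfplane_general <- function(poly, nrm, off, label) {
  v <- poly$v; lab <- poly$lab
  m <- nrow(v)
  f <- v %*% nrm - off                 # > 0 means outside
  if (all(f <= 0)) return(poly)
  if (all(f >= 0)) return(list(v = v[0, , drop = FALSE], lab = integer(0)))
  nv <- matrix(0, 0, 2); nl <- integer(0)
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    ins_k <- f[k] <= 0
    ins_k2 <- f[k2] <= 0
    if (ins_k) { nv <- rbind(nv, v[k, ]); nl <- c(nl, lab[k]) }
    if (xor(ins_k, ins_k2)) {
      t <- f[k] / (f[k] - f[k2])
      p <- v[k, ] + t * (v[k2, ] - v[k, ])
      if (ins_k) {
        # leaving: intersection starts the new (clipping) edge
        nv <- rbind(nv, p); nl <- c(nl, label)
      } else {
        # entering: intersection resumes the original edge k
        nv <- rbind(nv, p); nl <- c(nl, lab[k])
      }
    }
  }
  list(v = nv, lab = nl)
}

polygon_area <- function(v) {
  m <- nrow(v)
  k2 <- c(2:m, 1)
  0.5 * sum(v[, 1] * v[k2, 2] - v[k2, 1] * v[, 2])
}

polygon_perimeter <- function(v) {
  m <- nrow(v)
  k2 <- c(2:m, 1)
  sum(sqrt(rowSums((v[k2, , drop = FALSE] - v)^2)))
}

# Periodic tessellation of one cell. Returns local-frame polygon (relative to
# the cell center), candidate table (owner index, local position), and labels.
tessellate_cell <- function(i, centers, box, image_range) {
  n <- nrow(centers)
  sh <- expand.grid(mx = -image_range:image_range, my = -image_range:image_range)
  # candidate generators in the local frame of cell i
  px <- outer(centers[, 1] - centers[i, 1], sh$mx * box[1], `+`)
  py <- outer(centers[, 2] - centers[i, 2], sh$my * box[2], `+`)
  owner <- rep(seq_len(n), times = nrow(sh))
  P <- cbind(as.vector(px), as.vector(py))
  d2 <- rowSums(P^2)
  keep <- d2 > 1e-20
  P <- P[keep, , drop = FALSE]; owner <- owner[keep]; d2 <- d2[keep]
  ord <- order(d2)
  P <- P[ord, , drop = FALSE]; owner <- owner[ord]; d2 <- d2[ord]
  R0 <- 2 * max(box)
  poly <- list(v = rbind(c(-R0, -R0), c(R0, -R0), c(R0, R0), c(-R0, R0)),
               lab = rep(NA_integer_, 4))
  for (c in seq_len(nrow(P))) {
    rmax2 <- max(rowSums(poly$v^2))
    if (d2[c] > 4 * rmax2) break
    poly <- clip_halfplane(poly, P[c, ], c)
    if (nrow(poly$v) < 3)
      stop("tessellation degeneracy: empty cell (collinear or duplicate centers?)",
           call. = FALSE)
  }
  if (anyNA(poly$lab))
    stop("tessellation degeneracy: unbounded cell (too few neighbors)", call. = FALSE)
  list(v = poly$v, lab = poly$lab, cand = P, owner = owner)
}

#' Voronoi tessellation of an SPV configuration
#'
#' Exact Voronoi diagram of the cell centers. In periodic mode tiles are
#' computed with minimum-image replication and partition the box; in open
#' mode tiles are clipped to the convex hull of the centers and hull cells
#' are flagged as boundary cells.
#'
#' @param config An `spv_config`.
#' @return An `spv_tessellation`: per-cell polygon vertices (absolute
#'   coordinates), `areas`, `perimeters`, `neighbors`, `boundary` flags.
#' @export
tessellate <- function(config) {
  stopifnot(inherits(config, "spv_config"))
  n <- nrow(config$centers)
  if (config$boundary_mode == "periodic") {
    image_range <- if (n < 10) 2L else 1L
    cells <- lapply(seq_len(n), function(i)
      tessellate_cell(i, config$centers, config$box, image_range))
    areas <- vapply(cells, function(ce) polygon_area(ce$v), numeric(1))
    perims <- vapply(cells, function(ce) polygon_perimeter(ce$v), numeric(1))
    nbrs <- lapply(cells, function(ce) sort(unique(ce$owner[ce$lab])))
    verts <- lapply(seq_len(n), function(i)
      sweep(cells[[i]]$v, 2, config$centers[i, ], `+`))
    structure(list(vertices = verts, areas = areas, perimeters = perims,
                   neighbors = nbrs, boundary = rep(FALSE, n),
                   cells = cells, config = config),
              class = "spv_tessellation")
  } else {
    tessellate_open(config)
  }
}

# Open-boundary tessellation: clip tiles against the convex hull of the
# centers; cells on the hull are boundary cells.
tessellate_open <- function(config) {
  ctr <- config$centers
  n <- nrow(ctr)
  spread <- svd(sweep(ctr, 2, colMeans(ctr)))$d
  if (spread[2] < 1e-10 * spread[1])
    stop("tessellation degeneracy: collinear centers", call. = FALSE)
  hull <- grDevices::chull(ctr)              # clockwise indices
  hull <- rev(hull)                          # counter-clockwise
  hv <- ctr[hull, , drop = FALSE]
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    P <- sweep(ctr[-i, , drop = FALSE], 2, ctr[i, ])
    owner <- seq_len(n)[-i]
    ord <- order(rowSums(P^2))
    P <- P[ord, , drop = FALSE]; owner <- owner[ord]
    R0 <- 4 * max(sqrt(rowSums(sweep(ctr, 2, colMeans(ctr))^2))) + 1
    poly <- list(v = rbind(c(-R0, -R0), c(R0, -R0), c(R0, R0), c(-R0, R0)),
                 lab = rep(NA_integer_, 4))
    for (c in seq_len(nrow(P))) poly <- clip_halfplane(poly, P[c, ], c)
    # clip against hull edges (local frame); label NA marks boundary edges
    m <- nrow(hv)
    for (e in seq_len(m)) {
      aa <- hv[e, ] - ctr[i, ]; bb <- hv[if (e == m) 1 else e + 1, ] - ctr[i, ]
      ed <- bb - aa
      nrm <- c(ed[2], -ed[1])                # outward normal for CCW hull
      nrm <- nrm / sqrt(sum(nrm^2))
      poly <- clip_halfplane_general(poly, nrm, sum(aa * nrm), NA_integer_)
    }
    cells[[i]] <- list(v = poly$v, lab = poly$lab, cand = P, owner = owner)
  }
  areas <- vapply(cells, function(ce) polygon_area(ce$v), numeric(1))
  perims <- vapply(cells, function(ce) polygon_perimeter(ce$v), numeric(1))
  nbrs <- lapply(cells, function(ce) sort(unique(ce$owner[ce$lab[!is.na(ce$lab)]])))
  boundary <- vapply(cells, function(ce) anyNA(ce$lab), logical(1))
  verts <- lapply(seq_len(n), function(i) sweep(cells[[i]]$v, 2, ctr[i, ], `+`))
  structure(list(vertices = verts, areas = areas, perimeters = perims,
                 neighbors = nbrs, boundary = boundary,
                 cells = cells, config = config, hull = hull),
            class = "spv_tessellation")
}

#' @export
print.spv_tessellation <- function(x, ...) {
  cat(sprintf("Voronoi tessellation: %d tiles, total area %.6g, %d boundary cells\n",
              length(x$areas), sum(x$areas), sum(x$boundary)))
  invisible(x)
}

# --- energy and forces -------------------------------------------------------

spv_energy_from_tess <- function(config, tess) {
  e <- sum(config$area_stiffness / 2 * (tess$areas - config$preferred_areas)^2 +
           config$perimeter_stiffness / 2 *
             (tess$perimeters - config$preferred_perimeters)^2)
  if (config$boundary_mode == "open" && config$boundary_tension != 0) {
    hv <- config$centers[tess$hull, , drop = FALSE]
    m <- nrow(hv)
    hp <- sum(sqrt(rowSums((hv[c(2:m, 1), , drop = FALSE] - hv)^2)))
    e <- e + config$boundary_tension * hp
  }
  e
}

#' SPV energy and forces
#'
#' Total tissue energy `sum_i K/2 (A_i - A0_i)^2 + Gamma/2 (P_i - P0_i)^2`
#' (plus `lambda` times the outer contour length in open mode) and the
#' forces on the cell centers. In periodic mode forces are the exact analytic
#' gradients, obtained by chaining the polygon area/perimeter derivatives
#' through the circumcenter coordinates of each tile vertex; in open mode
#' they are central finite differences of the total energy.
#'
#' @param config An `spv_config`.
#' @param tess Optional precomputed tessellation.
#' @return List with `energy`, `forces` (N x 2), and the tessellation used.
#' @export
spv_energy_forces <- function(config, tess = NULL) {
  stopifnot(inherits(config, "spv_config"))
  if (is.null(tess)) tess <- tessellate(config)
  energy <- spv_energy_from_tess(config, tess)
  n <- nrow(config$centers)
  if (config$boundary_mode == "open") {
    grad <- matrix(0, n, 2)
    h <- 1e-6 * sqrt(mean(config$preferred_areas))
    for (i in seq_len(n)) for (dim in 1:2) {
      for (sgn in c(1, -1)) {
        cfg2 <- config
        cfg2$centers[i, dim] <- cfg2$centers[i, dim] + sgn * h
        e2 <- spv_energy_from_tess(cfg2, tessellate(cfg2))
        grad[i, dim] <- grad[i, dim] + sgn * e2 / (2 * h)
      }
    }
    return(list(energy = energy, forces = -grad, tessellation = tess))
  }
  grad <- matrix(0, n, 2)
  cA <- config$area_stiffness * (tess$areas - config$preferred_areas)
  cP <- config$perimeter_stiffness * (tess$perimeters - config$preferred_perimeters)
  for (i in seq_len(n)) {
    ce <- tess$cells[[i]]
    v <- ce$v
    m <- nrow(v)
    kp <- c(2:m, 1); km <- c(m, 1:(m - 1))
    # polygon derivatives dA/dh_k and dP/dh_k (CCW orientation)
    dA <- 0.5 * cbind(v[kp, 2] - v[km, 2], v[km, 1] - v[kp, 1])
    seg_m <- v - v[km, , drop = FALSE]
    seg_p <- v - v[kp, , drop = FALSE]
    len_m <- sqrt(rowSums(seg_m^2)); len_p <- sqrt(rowSums(seg_p^2))
    dP <- seg_m / pmax(len_m, 1e-14) + seg_p / pmax(len_p, 1e-14)
    G <- cA[i] * dA + cP[i] * dP          # m x 2: dE_i/dh_k
    for (k in seq_len(m)) {
      c1 <- ce$lab[km[k]]                 # incoming edge's generator
      c2 <- ce$lab[k]                     # outgoing edge's generator
      p1 <- ce$cand[c1, ]; p2 <- ce$cand[c2, ]
      M <- 2 * rbind(p1, p2 - p1)
      det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
      if (abs(det) < 1e-14) next          # collinear triple: measure-zero
      Minv <- matrix(c(M[2, 2], -M[2, 1], -M[1, 2], M[1, 1]), 2, 2) / det
      g <- G[k, ]
      h <- v[k, ]
      u_a <- 2 * Minv %*% c(1, 0)
      u_b <- 2 * Minv %*% c(1, -1)
      u_c <- 2 * Minv %*% c(0, 1)
      grad[i, ] <- grad[i, ] + sum(u_a * g) * h
      j1 <- ce$owner[c1]; j2 <- ce$owner[c2]
      grad[j1, ] <- grad[j1, ] + sum(u_b * g) * (p1 - h)
      grad[j2, ] <- grad[j2, ] + sum(u_c * g) * (p2 - h)
    }
  }
  list(energy = energy, forces = -grad, tessellation = tess)
}

#' Run SPV active Brownian dynamics
#'
#' Same first-order overdamped integrator as the soft-disk model, with the
#' tessellation refreshed every step. Exact cocircular degeneracies are
#' resolved by retrying with a deterministic jitter of relative size 1e-10.
#'
#' @param config An `spv_config` with a square periodic box.
#' @param drive An `active_drive`.
#' @param dt Time step.
#' @param n_steps Total steps (>= `save_every`).
#' @param save_every Snapshot interval in steps.
#' @param seed Optional RNG seed.
#' @return An `active_trajectory` (the cell radius slot holds
#'   `sqrt(A0 / pi)`).
#' @export
run_spv <- function(config, drive, dt = 0.01, n_steps, save_every, seed = NULL) {
  stopifnot(inherits(config, "spv_config"), inherits(drive, "active_drive"))
  if (config$boundary_mode != "periodic")
    stop_invalid("run_spv needs periodic boundaries")
  if (n_steps < save_every) stop_invalid("n_steps must be >= save_every")
  if (!is.null(seed)) set.seed(seed)
  L <- config$box
  n <- nrow(config$centers)
  n_saves <- n_steps %/% save_every
  X <- matrix(0, n, n_saves); Y <- matrix(0, n, n_saves)
  XU <- matrix(0, n, n_saves); YU <- matrix(0, n, n_saves)
  VX <- matrix(0, n, n_saves); VY <- matrix(0, n, n_saves)
  TH <- matrix(0, n, n_saves)
  times <- numeric(n_saves)
  ref <- config$centers
  pos_u <- config$centers
  theta <- drive$angles
  sig <- sqrt(dt / drive$persistence)
  isave <- 0L
  for (step in seq_len(n_steps)) {
    ef <- tryCatch(spv_energy_forces(config), error = function(e) NULL)
    if (is.null(ef)) {   # degenerate tessellation: deterministic jitter, retry
      jit <- 1e-10 * sqrt(mean(config$preferred_areas)) *
        matrix(rnorm(2 * n), n, 2)
      config$centers <- cbind((config$centers[, 1] + jit[, 1]) %% L[1],
                              (config$centers[, 2] + jit[, 2]) %% L[2])
      ef <- spv_energy_forces(config)
    }
    vel <- cbind(drive$speed * cos(theta), drive$speed * sin(theta)) +
      ef$forces / config$friction
    config$centers <- cbind((config$centers[, 1] + dt * vel[, 1]) %% L[1],
                            (config$centers[, 2] + dt * vel[, 2]) %% L[2])
    pos_u <- pos_u + dt * vel
    if (step %% save_every == 0) {
      isave <- isave + 1L
      X[, isave] <- config$centers[, 1]; Y[, isave] <- config$centers[, 2]
      XU[, isave] <- pos_u[, 1]; YU[, isave] <- pos_u[, 2]
      VX[, isave] <- vel[, 1]; VY[, isave] <- vel[, 2]
      TH[, isave] <- theta
      times[isave] <- step * dt
    }
    theta <- theta + sig * rnorm(n)
  }
  new_trajectory(times, X, Y, XU, YU, VX, VY, TH,
                 radii = sqrt(config$preferred_areas / pi),
                 box_length = config$box,
                 metadata = list(model = "spv", v0 = drive$speed,
                                 tau = drive$persistence, dt = dt,
                                 n_steps = n_steps, save_every = save_every,
                                 seed = seed, reference_positions = ref))
}
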