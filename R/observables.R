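# Estimators applied to simulated trajectories and PIV-style gridded velocity
# fields: Fourier and real-space velocity correlations, the self-intermediate
# scattering function with tau_alpha, temporal autocorrelation, and speed
# statistics.

# Internal: uniform view of a frame source. Returns list(kind, n_frames,
# frame(i) -> list(pos, vel), Lx, Ly, periodic, bin scale).
frame_source <- function(x) {
  if (inherits(x, "active_trajectory")) {
    ref <- x$metadata$reference_positions
    list(kind = "trajectory", n_frames = length(x$times),
         frame = function(i) list(pos = cbind(x$X[, i], x$Y[, i]),
                                  vel = cbind(x$VX[, i], x$VY[, i])),
         reference = ref, Lx = x$box_length[1],
         Ly = x$box_length[length(x$box_length)],
         periodic = TRUE, length_scale = mean(x$radii))
  } else if (inherits(x, "grid_field_sequence")) {
    pos <- as.matrix(expand.grid(x = x$x, y = x$y))
    nf <- dim(x$U)[3]
    list(kind = "grid", n_frames = nf,
         frame = function(i) list(pos = pos,
                                  vel = cbind(as.vector(x$U[, , i]),
                                              as.vector(x$V[, , i]))),
         reference = pos,
         Lx = length(x$x) * x$spacing, Ly = length(x$y) * x$spacing,
         periodic = TRUE, length_scale = x$spacing)
  } else stop_invalid("expected an active_trajectory or grid_field_sequence")
}

#' Fourier velocity correlation from frames
#'
#' Computes `v(q) = (1/N) sum_j exp(i q . r_j) v_j` per frame on the
#' commensurate wavevector grid, radially averages `|v(q)|^2` in bins of
#' width `2 pi / L` and then time-averages. For comparison against normal
#' mode predictions the transform is evaluated at the reference (equilibrium)
#' positions (`reference = "initial"`); for liquid or experimental data use
#' the instantaneous positions (`reference = "frame"`).
#'
#' @param x An `active_trajectory` or `grid_field_sequence`.
#' @param q_max Largest wavenumber (defaults to `pi / length_scale`).
#' @param reference `"frame"` (instantaneous positions, default) or
#'   `"initial"` (fixed reference positions).
#' @param normalization `"none"` or `"mean_square"` (each frame's velocities
#'   divided by their root-mean-square speed before transforming, the
#'   convention used for PIV fits).
#' @return A `q_correlation`.
#' @export
measure_vq <- function(x, q_max = NULL,
                       reference = c("frame", "initial"),
                       normalization = c("none", "mean_square")) {
  src <- frame_source(x)
  reference <- match.arg(reference)
  normalization <- match.arg(normalization)
  if (src$n_frames < 1) stop_invalid("no frames to analyse")
  if (is.null(q_max)) q_max <- pi / src$length_scale
  q <- q_grid(c(src$Lx, src$Ly), q_max)
  acc <- numeric(nrow(q))
  for (i in seq_len(src$n_frames)) {
    fr <- src$frame(i)
    pos <- if (reference == "initial") {
      if (is.null(src$reference)) stop_invalid("no reference positions stored")
      src$reference
    } else fr$pos
    vel <- fr$vel
    if (normalization == "mean_square") {
      vrms <- sqrt(mean(rowSums(vel^2)))
      if (vrms == 0) stop_invalid("zero velocities cannot be mean-square normalized")
      vel <- vel / vrms
    }
    acc <- acc + .vq_frame(pos[, 1], pos[, 2], vel[, 1], vel[, 2],
                           q[, 1], q[, 2])
  }
  vals <- acc / src$n_frames
  bw <- 2 * pi / max(src$Lx, src$Ly)
  ra <- radial_average(q, vals, bw)
  new_q_correlation(ra$q, ra$value, ra$counts, normalization = normalization,
                    bin_width = bw,
                    meta = list(n = nrow(src$frame(1)$pos),
                                n_frames = src$n_frames,
                                length_scale = src$length_scale,
                                reference = reference))
}

#' Real-space velocity correlation from frames
#'
#' Pair-averaged `<v(r0 + r) . v(r0)>` binned by separation (minimum image
#' in periodic geometry), averaged over frames.
#'
#' @param x An `active_trajectory` or `grid_field_sequence`.
#' @param bin_width Separation bin width (default: half the length scale).
#' @param r_max Largest separation (default: half the box).
#' @return An `r_correlation` with fields `r`, `value`, `counts`.
#' @export
measure_cvv <- function(x, bin_width = NULL, r_max = NULL) {
  src <- frame_source(x)
  if (src$n_frames < 1) stop_invalid("no frames to analyse")
  if (is.null(bin_width)) bin_width <- src$length_scale / 2
  if (is.null(r_max)) r_max <- min(src$Lx, src$Ly) / 2
  nb <- ceiling(r_max / bin_width)
  sums <- numeric(nb); counts <- numeric(nb)
  for (i in seq_len(src$n_frames)) {
    fr <- src$frame(i)
    res <- .cvv_frame(fr$pos[, 1], fr$pos[, 2], fr$vel[, 1], fr$vel[, 2],
                      src$Lx, src$Ly, src$periodic, bin_width, nb)
    sums <- sums + res$sums
    counts <- counts + res$counts
  }
  keep <- counts > 0
  structure(list(r = ((seq_len(nb) - 0.5) * bin_width)[keep],
                 value = (sums / pmax(counts, 1))[keep],
                 counts = counts[keep]),
            class = "r_correlation")
}

#' @export
print.r_correlation <- function(x, ...) {
  cat(sprintf("Real-space velocity correlation C_vv(r): %d bins, r in [%.4g, %.4g]\n",
              length(x$r), min(x$r), max(x$r)))
  invisible(x)
}

#' @export
plot.r_correlation <- function(x, ...) {
  plot(x$r, x$value, xlab = "r", ylab = "C_vv(r)", ...)
  invisible(x)
}

#' Self-intermediate scattering function and alpha-relaxation time
#'
#' `S(q, t)` from unwrapped displacements, averaged over time origins,
#' particles and `n_angles` directions at fixed `|q|`. The relaxation time
#' `tau_alpha` is the first saved lag where `S < 0.5`, censored at the
#' trajectory duration (flagged) when the decay is not reached.
#'
#' @param trajectory An `active_trajectory` with unwrapped coordinates.
#' @param q_magnitude Wavenumber (default `2 pi / mean(radii)`).
#' @param n_angles Number of q directions averaged.
#' @return A `sisf_result`: `times`, `value`, `tau_alpha`, `censored`.
#' @export
measure_sisf <- function(trajectory, q_magnitude = NULL, n_angles = 12L) {
  stopifnot(inherits(trajectory, "active_trajectory"))
  if (is.null(trajectory$XU))
    stop_invalid("need unwrapped coordinates for the scattering function")
  if (is.null(q_magnitude)) q_magnitude <- 2 * pi / mean(trajectory$radii)
  nf <- length(trajectory$times)
  if (nf < 2) stop_invalid("need at least 2 frames")
  lags <- 0:(nf - 1)
  S <- .sisf(trajectory$XU, trajectory$YU, q_magnitude, as.integer(n_angles),
             as.integer(lags))
  dtf <- trajectory$times[2] - trajectory$times[1]
  lag_times <- lags * dtf
  below <- which(S < 0.5)
  if (length(below)) {
    tau_alpha <- lag_times[below[1]]
    censored <- FALSE
  } else {
    tau_alpha <- max(lag_times)
    censored <- TRUE
  }
  structure(list(times = lag_times, value = S, q = q_magnitude,
                 tau_alpha = tau_alpha, censored = censored),
            class = "sisf_result")
}

#' @export
print.sisf_result <- function(x, ...) {
  cat(sprintf("S(q = %.4g, t): tau_alpha = %.4g%s\n", x$q, x$tau_alpha,
              if (x$censored) " (censored at trajectory length)" else ""))
  invisible(x)
}

#' Temporal velocity autocorrelation from a trajectory
#'
#' `<v(t) . v(0)>` averaged over particles and time origins; the lag-0 value
#' is the mean-square velocity.
#'
#' @param x An `active_trajectory` or `grid_field_sequence`.
#' @param normalize Divide by the lag-0 value.
#' @return A `vacf_estimate`: `times` (lags), `value`, `normalized`.
#' @export
measure_vacf <- function(x, normalize = FALSE) {
  src <- frame_source(x)
  nf <- src$n_frames
  if (nf < 2) stop_invalid("need at least 2 frames")
  fr1 <- src$frame(1)
  n <- nrow(fr1$vel)
  VX <- matrix(0, n, nf); VY <- matrix(0, n, nf)
  for (i in seq_len(nf)) {
    fr <- src$frame(i)
    VX[, i] <- fr$vel[, 1]; VY[, i] <- fr$vel[, 2]
  }
  M <- crossprod(VX) + crossprod(VY)   # frames x frames dot products
  vals <- vapply(0:(nf - 1), function(lag) {
    idx <- seq_len(nf - lag)
    mean(M[cbind(idx, idx + lag)]) / n
  }, numeric(1))
  tstep <- if (src$kind == "trajectory") diff(x$times[1:2]) else
    if (!is.null(x$times) && length(x$times) > 1) diff(x$times[1:2]) else 1
  if (normalize) vals <- vals / vals[1]
  structure(list(times = (0:(nf - 1)) * tstep, value = vals,
                 normalized = normalize),
            class = "vacf_estimate")
}

#' @export
print.vacf_estimate <- function(x, ...) {
  cat(sprintf("Velocity autocorrelation: %d lags, value(0) = %.4g%s\n",
              length(x$times), x$value[1],
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Speed statistics of frames
#'
#' Root-mean-square speed `vbar = sqrt(<|v|^2>)`, the mean-square velocity,
#' and the normalized speed distribution (histogram of `|v| / vbar`).
#'
#' @param x An `active_trajectory` or `grid_field_sequence`.
#' @param breaks Bin edges for the normalized speed histogram.
#' @return List with `mean_speed`, `mean_square_velocity` and `distribution`
#'   (data frame with `mid`, `density`).
#' @export
speed_stats <- function(x, breaks = seq(0, 5, by = 0.1)) {
  src <- frame_source(x)
  speeds <- unlist(lapply(seq_len(src$n_frames), function(i) {
    v <- src$frame(i)$vel
    sqrt(rowSums(v^2))
  }))
  msv <- mean(speeds^2)
  vbar <- sqrt(msv)
  sn <- pmin(speeds / vbar, max(breaks))
  h <- hist(sn, breaks = breaks, plot = FALSE)
  list(mean_speed = vbar, mean_square_velocity = msv,
       distribution = data.frame(mid = h$mids, density = h$density))
}
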