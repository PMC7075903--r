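#' @keywords internal
"_PACKAGE"

#' @useDynLib activesheet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm integrate optimize optim optimHess sd
#' @importFrom graphics plot points lines legend hist
NULL

# minimum-image separation in a periodic box
min_image <- function(d, L) d - L * round(d / L)

stop_invalid <- function(...) {
  stop(structure(class = c("activesheet_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_invalid(name, " must be > 0")
  invisible(x)
}

#' Commensurate wavevector grid for a periodic box
#'
#' All wavevectors `2*pi*(nx, ny)/L` with `0 < |q| <= q_max`, restricted to a
#' half plane (`q` and `-q` carry the same spectral information).
#'
#' @param box_length Box side(s): a scalar (square box) or `c(Lx, Ly)`.
#' @param q_max Largest wavenumber magnitude retained.
#' @return A two-column matrix of wavevectors (columns `qx`, `qy`).
#' @export
q_grid <- function(box_length, q_max) {
  if (length(box_length) == 1L) box_length <- rep(box_length, 2)
  check_scalar(q_max, "q_max")
  dqx <- 2 * pi / box_length[1]
  dqy <- 2 * pi / box_length[2]
  n <- expand.grid(nx = -ceiling(q_max / dqx):ceiling(q_max / dqx),
                   ny = 0:ceiling(q_max / dqy))
  # half plane: ny > 0, or ny == 0 and nx > 0 (q and -q are equivalent)
  n <- n[n$ny > 0 | (n$ny == 0 & n$nx > 0), , drop = FALSE]
  q <- cbind(qx = n$nx * dqx, qy = n$ny * dqy)
  q[sqrt(rowSums(q^2)) <= q_max + 1e-12, , drop = FALSE]
}

# Radial average of per-wavevector values into bins of fixed width; bins are
# labelled by the mean |q| of their members (bin centers distort the lowest
# shells).
radial_average <- function(q, values, bin_width) {
  qmag <- sqrt(rowSums(q^2))
  bin <- floor(qmag / bin_width)
  list(q = as.numeric(tapply(qmag, bin, mean)),
       value = as.numeric(tapply(values, bin, mean)),
       counts = as.integer(tapply(values, bin, length)))
}

new_q_correlation <- function(q, value, counts, normalization,
                              bin_width = NULL, meta = list()) {
  structure(list(q = q, value = value, counts = counts,
                 normalization = normalization, bin_width = bin_width,
                 meta = meta),
            class = "q_correlation")
}

#' @export
print.q_correlation <- function(x, ...) {
  cat("Radially averaged Fourier velocity correlation <|v(q)|^2>\n")
  cat(sprintf("  %d q-bins, q in [%.4g, %.4g], normalization: %s\n",
              length(x$q), min(x$q), max(x$q), x$normalization))
  invisible(x)
}

#' @export
plot.q_correlation <- function(x, ..., log = "xy") {
  plot(x$q, x$value, log = log, xlab = "q", ylab = "<|v(q)|^2>", ...)
  invisible(x)
}
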