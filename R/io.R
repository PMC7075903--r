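# Columnar plain-text interchange formats: trajectory snapshots, PIV-style
# velocity grids, and flat key-value run configurations. All writers emit a
# provenance block (package version, config hash, seed) and round-trip at
# full double precision.

fmt_g <- function(x) sprintf("%.17g", x)

provenance_lines <- function(meta = list()) {
  ver <- tryCatch(as.character(utils::packageVersion("activesheet")),
                  error = function(e) "dev")
  seed <- meta$seed
  hash <- sum(utf8ToInt(paste(names(meta), vapply(meta, function(m)
    paste(format(m), collapse = ","), character(1)), collapse = ";"))) %% 1e9
  c(sprintf("# activesheet_version=%s", ver),
    sprintf("# config_hash=%d", as.integer(hash)),
    if (!is.null(seed)) sprintf("# seed=%s", format(seed)))
}

#' Write a trajectory to a columnar snapshot file
#'
#' Leading metadata block (`# key=value`), then per frame a separator
#' `# t=<time>`, a header `# id x y vx vy theta radius xu yu` and one row per
#' particle. Lossless at full double precision.
#'
#' @param trajectory An `active_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "active_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  md <- trajectory$metadata
  writeLines(provenance_lines(md), con)
  writeLines(sprintf("# n=%d", nrow(trajectory$X)), con)
  writeLines(sprintf("# box=%s", paste(fmt_g(trajectory$box_length),
                                       collapse = " ")), con)
  for (key in c("model", "v0", "tau", "dt", "k", "zeta", "eps")) {
    if (!is.null(md[[key]]))
      writeLines(sprintf("# %s=%s", key, format(md[[key]], digits = 17)), con)
  }
  n <- nrow(trajectory$X)
  for (f in seq_along(trajectory$times)) {
    writeLines(sprintf("# t=%s", fmt_g(trajectory$times[f])), con)
    writeLines("# id x y vx vy theta radius xu yu", con)
    rows <- paste(seq_len(n),
                  fmt_g(trajectory$X[, f]), fmt_g(trajectory$Y[, f]),
                  fmt_g(trajectory$VX[, f]), fmt_g(trajectory$VY[, f]),
                  fmt_g(trajectory$TH[, f]), fmt_g(trajectory$radii),
                  fmt_g(trajectory$XU[, f]), fmt_g(trajectory$YU[, f]))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a trajectory written by [write_snapshots()]
#'
#' @param path Snapshot file.
#' @return An `active_trajectory`.
#' @export
read_snapshots <- function(path) {
  lines <- readLines(path)
  meta <- list()
  frame_starts <- grep("^# t=", lines)
  if (!length(frame_starts)) stop("no frames found in ", path, call. = FALSE)
  for (l in lines[seq_len(frame_starts[1] - 1)]) {
    kv <- sub("^# ", "", l)
    eq <- regexpr("=", kv)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  n <- as.integer(meta$n)
  if (is.na(n)) stop("missing particle count (n=) in header", call. = FALSE)
  nf <- length(frame_starts)
  times <- numeric(nf)
  mats <- replicate(8, matrix(NA_real_, n, nf), simplify = FALSE)
  names(mats) <- c("X", "Y", "VX", "VY", "TH", "R", "XU", "YU")
  required <- c("id", "x", "y", "vx", "vy", "theta", "radius")
  for (f in seq_len(nf)) {
    start <- frame_starts[f]
    times[f] <- as.numeric(sub("^# t=", "", lines[start]))
    hdr <- strsplit(sub("^# ", "", lines[start + 1]), "\\s+")[[1]]
    missing_cols <- setdiff(required, hdr)
    if (length(missing_cols))
      stop(sprintf("frame %d (line %d): missing column(s) %s", f, start + 1,
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    end <- if (f < nf) frame_starts[f + 1] - 1 else length(lines)
    body <- lines[(start + 2):end]
    body <- body[nzchar(body)]
    if (length(body) != n)
      stop(sprintf("frame %d has %d rows, expected n=%d", f, length(body), n),
           call. = FALSE)
    vals <- utils::read.table(text = body, col.names = hdr)
    mats$X[, f] <- vals$x; mats$Y[, f] <- vals$y
    mats$VX[, f] <- vals$vx; mats$VY[, f] <- vals$vy
    mats$TH[, f] <- vals$theta; mats$R[, f] <- vals$radius
    if ("xu" %in% hdr) { mats$XU[, f] <- vals$xu; mats$YU[, f] <- vals$yu }
  }
  md <- list(model = meta$model)
  for (key in c("v0", "tau", "dt", "k", "zeta", "eps", "seed"))
    if (!is.null(meta[[key]])) md[[key]] <- as.numeric(meta[[key]])
  new_trajectory(times, mats$X, mats$Y,
                 if (all(is.na(mats$XU))) NULL else mats$XU,
                 if (all(is.na(mats$YU))) NULL else mats$YU,
                 mats$VX, mats$VY, mats$TH, mats$R[, 1],
                 as.numeric(strsplit(meta$box, "\\s+")[[1]]), md)
}

#' Write a gridded velocity field sequence
#'
#' Metadata block (`# nx=, ny=, spacing=`), then rows `frame x y u v`.
#'
#' @param fields A `grid_field_sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_grid <- function(fields, path) {
  stopifnot(inherits(fields, "grid_field_sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(list(spacing = fields$spacing)), con)
  writeLines(c(sprintf("# nx=%d", length(fields$x)),
               sprintf("# ny=%d", length(fields$y)),
               sprintf("# spacing=%s", fmt_g(fields$spacing)),
               "# frame x y u v"), con)
  g <- expand.grid(x = fields$x, y = fields$y)
  for (f in seq_len(dim(fields$U)[3])) {
    rows <- paste(f, fmt_g(g$x), fmt_g(g$y),
                  fmt_g(as.vector(fields$U[, , f])),
                  fmt_g(as.vector(fields$V[, , f])))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a gridded velocity field sequence written by [write_grid()]
#'
#' @param path Grid file.
#' @return A `grid_field_sequence`.
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    l <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(l)) stop("missing header field ", key, call. = FALSE)
    as.numeric(sub(paste0("^# ", key, "="), "", l[1]))
  }
  nx <- as.integer(getv("nx")); ny <- as.integer(getv("ny"))
  spacing <- getv("spacing")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("empty frame list in ", path, call. = FALSE)
  d <- utils::read.table(text = body,
                         col.names = c("frame", "x", "y", "u", "v"))
  frames <- sort(unique(d$frame))
  U <- array(0, c(nx, ny, length(frames)))
  V <- array(0, c(nx, ny, length(frames)))
  xs <- sort(unique(d$x)); ys <- sort(unique(d$y))
  if (length(xs) != nx || length(ys) != ny)
    stop("grid dimensions do not match header", call. = FALSE)
  if (length(xs) > 1 && max(abs(diff(xs) - spacing)) > 1e-9 * spacing)
    stop("irregular grid spacing detected", call. = FALSE)
  for (f in seq_along(frames)) {
    sub <- d[d$frame == frames[f], ]
    if (nrow(sub) != nx * ny)
      stop(sprintf("frame %d has %d rows, expected %d", frames[f], nrow(sub),
                   nx * ny), call. = FALSE)
    ord <- order(sub$y, sub$x)
    U[, , f] <- matrix(sub$u[ord], nx, ny)
    V[, , f] <- matrix(sub$v[ord], nx, ny)
  }
  grid_field_sequence(xs, ys, U, V, spacing, times = frames)
}

#' Read a flat key-value run configuration
#'
#' Lines of the form `key=value`; blank lines and `#` comments are ignored.
#' Unknown keys are rejected.
#'
#' @param path Config file.
#' @param known Character vector of accepted keys.
#' @return Named list of values (numeric where possible).
#' @export
read_config <- function(path,
                        known = c("model", "n", "phi", "poly", "v0", "tau",
                                  "k", "zeta", "dt", "steps", "save_every",
                                  "seed", "eps", "p0", "K", "Gamma",
                                  "lambda", "discard", "tau_div")) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    eq <- regexpr("=", l)
    if (eq < 0) stop("malformed config line: ", l, call. = FALSE)
    key <- trimws(substr(l, 1, eq - 1))
    val <- trimws(substr(l, eq + 1, nchar(l)))
    if (!key %in% known) stop("unknown config key: ", key, call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}
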