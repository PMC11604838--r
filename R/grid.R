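#' Spin evaluation grid
#'
#' The set of points on which profiles are simulated. Each point carries a
#' position (m), a static frequency offset (Hz), a chemical shift (Hz) and a
#' dimensionless transmit scale; the equilibrium magnetization is 1.
#'
#' @param pos numeric matrix npts x 3 of positions in metres.
#' @param offset static offsets in Hz (frequency axis of 1D designs).
#' @param cs chemical shifts in Hz.
#' @param b1c dimensionless transmit scale, `>= 0`.
#' @param dims shape metadata (e.g. `512` or `c(32, 32)`); points are stored
#'   row-major with respect to `dims`.
#' @param axes optional named list of axis coordinate vectors (for printing
#'   and export).
#' @return an object of class `spin_grid`.
#' @export
spin_grid <- function(pos, offset = NULL, cs = NULL, b1c = NULL,
                      dims = NULL, axes = NULL) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 3L) stop("pos must be npts x 3")
  npts <- nrow(pos)
  if (npts < 1L) stop("a spin grid cannot be empty")
  if (is.null(offset)) offset <- numeric(npts)
  if (is.null(cs)) cs <- numeric(npts)
  if (is.null(b1c)) b1c <- rep(1, npts)
  stopifnot(length(offset) == npts, length(cs) == npts, length(b1c) == npts)
  if (any(b1c < 0)) stop("transmit scale c must be >= 0 at every point")
  if (is.null(dims)) dims <- npts
  if (prod(dims) != npts)
    stop("grid dims metadata inconsistent with point count")
  structure(list(pos = pos, offset = as.numeric(offset), cs = as.numeric(cs),
                 b1c = as.numeric(b1c), m0 = 1, npts = npts,
                 dims = as.integer(dims), axes = axes),
            class = "spin_grid")
}

#' @export
print.spin_grid <- function(x, ...) {
  cat(sprintf("<spin_grid> %s points (m0 = 1)\n",
              paste(x$dims, collapse = " x ")))
  invisible(x)
}

#' Uniform frequency-offset grid
#'
#' Endpoint-inclusive grid of `n` offsets spanning `[-fmax, fmax]` Hz, at the
#' isocenter, used for 1D frequency-selective and inversion designs.
#'
#' @param n number of points.
#' @param fmax half-range in Hz.
#' @export
grid_freq <- function(n, fmax) {
  f <- seq(-fmax, fmax, length.out = n)
  spin_grid(matrix(0, n, 3), offset = f, dims = n, axes = list(freq_hz = f))
}

#' Isocenter-centred 2D spatial grid (row-major)
#'
#' @param nx,ny points along x and y.
#' @param fov field of view in metres (isotropic).
#' @export
grid_spatial_2d <- function(nx, ny, fov) {
  x <- seq(-fov / 2, fov / 2, length.out = nx)
  y <- seq(-fov / 2, fov / 2, length.out = ny)
  # row-major: y (rows) outer, x (cols) inner
  pos <- cbind(x = rep(x, times = ny), y = rep(y, each = nx), z = 0)
  spin_grid(pos, dims = c(ny, nx), axes = list(y_m = y, x_m = x))
}

#' Spectral-spatial grid: position x chemical shift
#'
#' The spatial axis is specified as the frequency it maps to under a
#' reference slice gradient (`gref`, mT/m), matching how spectral-spatial
#' profiles are stated; positions are stored in metres.
#'
#' @param nf,ncs points along the spatial-frequency and chemical-shift axes.
#' @param fmax spatial half-range in Hz under `gref`.
#' @param csmax chemical-shift half-range in Hz.
#' @param gref reference gradient amplitude in mT/m.
#' @export
grid_spsp <- function(nf, ncs, fmax = 50e3, csmax = 750, gref = 20) {
  f <- seq(-fmax, fmax, length.out = nf)
  cs <- seq(-csmax, csmax, length.out = ncs)
  z <- f / (GAMMA_HZ_PER_MTM_M * gref)
  # spatial positions go on axis 1, which single-axis gradients pair with
  pos <- cbind(rep(z, each = ncs), 0, 0)
  spin_grid(pos, cs = rep(cs, times = nf), dims = c(nf, ncs),
            axes = list(freq_hz = f, cs_hz = cs, gref_mt_m = gref))
}

#' Magnetization profile over a spin grid
#'
#' @param M numeric matrix npts x 3 of (mx, my, mz) in units of m0.
#' @param grid the `spin_grid` the profile lives on.
#' @export
mag_profile <- function(M, grid) {
  M <- as.matrix(M)
  if (nrow(M) != grid$npts || ncol(M) != 3L)
    stop("profile shape does not match its grid")
  structure(list(M = M, grid = grid), class = "mag_profile")
}

#' Equilibrium profile (0, 0, m0) on a grid
#' @param grid a `spin_grid`.
#' @export
equilibrium_profile <- function(grid) {
  M <- cbind(mx = 0, my = 0, mz = rep(grid$m0, grid$npts))
  mag_profile(M, grid)
}

#' @export
print.mag_profile <- function(x, ...) {
  cat(sprintf("<mag_profile> %s points, |Mxy| in [%.3g, %.3g], Mz in [%.3g, %.3g]\n",
              paste(x$grid$dims, collapse = " x "),
              min(sqrt(x$M[, 1]^2 + x$M[, 2]^2)),
              max(sqrt(x$M[, 1]^2 + x$M[, 2]^2)),
              min(x$M[, 3]), max(x$M[, 3])))
  invisible(x)
}

#' Write / read a profile as delimited text
#' @param pf a `mag_profile`.
#' @param path file path.
#' @export
write_profile <- function(pf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims=%s", paste(pf$grid$dims, collapse = "x")), con)
  writeLines("# columns=mx my mz", con)
  writeLines(sprintf("%.12g %.12g %.12g", pf$M[, 1], pf$M[, 2], pf$M[, 3]), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  dims <- grep("^# dims=", lines, value = TRUE)
  dims <- as.integer(strsplit(sub("^# dims=", "", dims[1]), "x")[[1]])
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  M <- do.call(rbind, lapply(body, function(s)
    as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])))
  grid <- spin_grid(matrix(0, nrow(M), 3), dims = dims)
  mag_profile(M, grid)
}
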