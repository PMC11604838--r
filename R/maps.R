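# Synthetic system-imperfection maps: deterministic, seeded stand-ins for
# measured B0 (Hz) and B1+ (dimensionless scale) maps, used to exercise
# online adaptation without scanner data.

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing of a matrix (replicate-padded); degenerate
# single-row/column axes pass through untouched
smooth2d <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2L))[(r + 1L):(r + length(v))]
  }
  nr <- nrow(m); nc <- ncol(m)
  if (nr > 1L) m <- matrix(apply(m, 2L, pad_conv), nr, nc)
  if (nc > 1L) m <- t(matrix(apply(m, 1L, pad_conv), nc, nr))
  m
}

smooth_seeded_field <- function(dims, smoothness, seed) {
  set.seed(seed)
  if (length(dims) == 1L) dims <- c(dims, 1L)
  nr <- dims[1]; nc <- dims[2]
  noise <- matrix(rnorm(nr * nc), nr, nc)
  sigma <- max(1, smoothness * max(nr, nc))
  sm <- smooth2d(noise, sigma)
  # low-order polynomial component with seeded coefficients
  u <- if (nr > 1) seq(-1, 1, length.out = nr) else 0
  v <- if (nc > 1) seq(-1, 1, length.out = nc) else 0
  cf <- rnorm(5)
  poly <- outer(u, v, function(a, b)
    cf[1] * a + cf[2] * b + cf[3] * a * b + cf[4] * a^2 + cf[5] * b^2)
  fld <- sm / max(abs(sm)) + 0.7 * poly / max(abs(poly), 1e-12)
  fld <- fld - mean(fld)
  fld / max(abs(fld))
}

#' Synthetic smooth B0 map
#'
#' Zero-mean smooth off-resonance field: a seeded low-order polynomial plus
#' a Gaussian-smoothed random component, scaled so the extreme value is 85%
#' of `amplitude`. Pure function of its arguments.
#'
#' @param grid design `spin_grid` (its `dims` set the field shape).
#' @param amplitude bound on `|B0|` (Hz).
#' @param smoothness correlation length as a fraction of the grid extent.
#' @param seed RNG seed.
#' @return numeric vector of length `grid$npts` (row-major over `dims`), Hz.
#' @export
synth_b0_map <- function(grid, amplitude = 100, smoothness = 0.15, seed = 1L) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(numeric(grid$npts))
  fld <- smooth_seeded_field(grid$dims, smoothness, seed)
  as.vector(t(fld)) * 0.85 * amplitude
}

#' Synthetic smooth B1+ scale map
#'
#' Smooth positive field in `[center_scale - variation, center_scale +
#' variation]` with mean exactly `center_scale`.
#'
#' @param grid design `spin_grid`.
#' @param center_scale nominal transmit scale (> 0).
#' @param variation half-range of the variation (`0 <= variation <
#'   center_scale`).
#' @param smoothness correlation length fraction.
#' @param seed RNG seed.
#' @return numeric vector of length `grid$npts`, dimensionless.
#' @export
synth_b1_map <- function(grid, center_scale = 1, variation = 0.3,
                         smoothness = 0.15, seed = 1L) {
  if (center_scale <= 0) stop("center_scale must be positive")
  if (variation < 0 || variation >= center_scale)
    stop("need 0 <= variation < center_scale")
  if (variation == 0) return(rep(center_scale, grid$npts))
  fld <- smooth_seeded_field(grid$dims, smoothness, seed + 7L)
  center_scale + variation * as.vector(t(fld))
}

#' Deterministic "AI" glyph mask
#'
#' Renders the letters A and I as a binary bitmap with stroke width of at
#' least two pixels; the counter (enclosed triangle) of the A is open, a
#' feature 2D excitation experiments track. Identical across calls.
#'
#' @param rows,cols bitmap size, each `>= 32`.
#' @return a `rows x cols` 0/1 matrix.
#' @export
glyph_mask_ai <- function(rows = 64L, cols = 64L) {
  if (rows < 32L || cols < 32L)
    stop("glyph mask needs at least 32 x 32 pixels")
  seg_dist <- function(px, py, x1, y1, x2, y2) {
    vx <- x2 - x1; vy <- y2 - y1
    tt <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / (vx^2 + vy^2)))
    sqrt((px - (x1 + tt * vx))^2 + (py - (y1 + tt * vy))^2)
  }
  # letter geometry in the unit square (x right, y down)
  apex <- c(0.30, 0.14)
  footl <- c(0.08, 0.86); footr <- c(0.52, 0.86)
  ycb <- 0.62
  legx <- function(foot, y) apex[1] + (foot[1] - apex[1]) *
    (y - apex[2]) / (foot[2] - apex[2])
  segs <- rbind(
    c(apex, footl),                       # A left leg
    c(apex, footr),                       # A right leg
    c(legx(footl, ycb), ycb, legx(footr, ycb), ycb),  # A crossbar
    c(0.78, 0.14, 0.78, 0.86),            # I stem
    c(0.68, 0.14, 0.88, 0.14),            # I top serif
    c(0.68, 0.86, 0.88, 0.86)             # I bottom serif
  )
  # stroke half-width: >= 2 px, letters clear of the grid edge; strokes and
  # the A's counter both survive the packaged spirals' ~1.3-pixel resolution
  hw <- max(1.05 / min(rows, cols), 0.033)
  px <- (seq_len(cols) - 0.5) / cols
  py <- (seq_len(rows) - 0.5) / rows
  X <- matrix(rep(px, each = rows), rows, cols)
  Y <- matrix(rep(py, times = cols), rows, cols)
  mask <- matrix(0L, rows, cols)
  for (i in seq_len(nrow(segs))) {
    d <- seg_dist(X, Y, segs[i, 1], segs[i, 2], segs[i, 3], segs[i, 4])
    mask[d <= hw] <- 1L
  }
  mask
}

#' Write / read a scalar map as delimited text
#' @param map numeric vector (row-major over `dims`) or matrix.
#' @param dims field shape when `map` is a vector.
#' @param path file path.
#' @export
write_map <- function(map, path, dims = NULL) {
  if (is.matrix(map)) {
    dims <- dim(map)
    map <- as.vector(t(map))
  }
  if (is.null(dims)) dims <- length(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dims=%s", paste(dims, collapse = "x")), con)
  writeLines(sprintf("%.12g", map), con)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(sub("^# dims=", "",
                                  grep("^# dims=", lines, value = TRUE)[1]),
                              "x")[[1]])
  vals <- as.numeric(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  structure(vals, dims = dims)
}

#' Import a measured map from NIfTI
#'
#' Values are taken as-is (Hz for B0, dimensionless for B1+ scale);
#' orientation metadata is ignored and the voxel grid must match the design
#' grid.
#'
#' @param path NIfTI file.
#' @export
read_map_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required to read NIfTI maps")
  img <- RNifti::readNifti(path)
  v <- as.vector(aperm(as.array(img)))
  structure(as.numeric(v), dims = dim(as.array(img)))
}
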