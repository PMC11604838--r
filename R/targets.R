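#' Target profiles for pulse design
#'
#' A target bundles the full 3-component magnetization profile the designer
#' trains against, the flattened scalar vector fed to the network (length
#' `d`), the design mode, and, for B1-insensitive designs, the peak-amplitude
#' sweep. The network input channel is `mz` for inversion-type targets and
#' the transverse magnitude for excitation-type targets (so the input
#' dimension equals the grid point count, times the sweep length); `input = "all"` concatenates all
#' three components instead.
#'
#' @name target_profile
NULL

new_target <- function(profile, mode, input = "auto", sweep = NULL,
                       reference = NULL, dims = NULL) {
  M <- profile$M
  chan <- switch(input,
    auto = if (mode == "b1_sweep") M[, 3] else sqrt(M[, 1]^2 + M[, 2]^2),
    mz = M[, 3],
    xy = sqrt(M[, 1]^2 + M[, 2]^2),
    all = as.vector(M),
    stop("unknown input channel: ", input)
  )
  if (is.null(dims)) {
    dims <- profile$grid$dims
    if (!is.null(sweep)) dims <- c(dims, length(sweep))
  }
  structure(list(profile = profile, input_channel = as.numeric(chan),
                 d = length(chan), dims = dims, mode = mode, sweep = sweep,
                 reference = reference),
            class = "target_profile")
}

#' @export
print.target_profile <- function(x, ...) {
  cat(sprintf("<target_profile> mode %s, d = %d (%s)\n", x$mode, x$d,
              paste(x$dims, collapse = " x ")))
  invisible(x)
}

#' Target from a Bloch-simulated reference pulse
#'
#' Simulates a supplied reference pulse (any waveform, e.g. a packaged
#' adiabatic or spectral-spatial design) on the design grid and uses its
#' profile as the target.
#'
#' @param rf reference `rf_pulse`.
#' @param grad optional paired `grad_waveform`.
#' @param grid design `spin_grid`.
#' @param mode design mode the target is meant for.
#' @param rephase free-precession rewind passed to [simulate_pulse()].
#' @param input input-channel selection (see [target_profile]).
#' @return a `target_profile`.
#' @export
target_from_reference <- function(rf, grad = NULL, grid,
                                  mode = "selective_1d", rephase = 0,
                                  input = "auto") {
  pf <- simulate_pulse(rf, grad, grid, rephase = rephase)
  new_target(pf, mode = mode, input = input,
             reference = list(rf = rf, grad = grad, rephase = rephase))
}

#' Rectangle-function excitation target
#'
#' Inside the band the magnetization is tipped by `flip` toward +y; outside
#' it stays at equilibrium; an optional raised-cosine transition interpolates
#' the flip angle over `transition` Hz (keeping every target vector on the
#' unit sphere). The target is defined post-refocusing: pair it with
#' `rephase = -duration/2` in the physics model.
#'
#' @param band_halfwidth passband half-width (Hz).
#' @param flip flip angle (degrees).
#' @param grid a frequency `spin_grid` (from [grid_freq()]).
#' @param transition raised-cosine transition width (Hz); choose about
#'   `2 / duration` of the pulse that is to realize the target (the default
#'   800 Hz matches the package's canonical 2.56 ms raster). Narrower
#'   transitions are not representable by a time-limited pulse and leave an
#'   irreducible profile mismatch.
#' @param input input-channel selection.
#' @export
rect_target <- function(band_halfwidth, flip, grid, transition = 800,
                        input = "auto") {
  f <- abs(grid$offset)
  if (band_halfwidth + transition > max(f))
    stop("band (plus transition) is wider than the grid")
  w <- ifelse(f <= band_halfwidth, 1,
              ifelse(f >= band_halfwidth + transition, 0,
                     0.5 * (1 + cos(pi * (f - band_halfwidth) / transition))))
  a <- flip * pi / 180 * w
  M <- cbind(0, sin(a), cos(a))
  new_target(mag_profile(M, grid), mode = "selective_1d", input = input)
}

#' B1-insensitive sweep target
#'
#' Extends a 1D target across a second dimension of peak amplitudes. When
#' the base target was built from a reference pulse, the reference is
#' re-simulated with its peak scaled to each sweep value, so each sweep row
#' is the reference's own profile at that B1max (an adiabatic reference is
#' then insensitive above its adiabatic threshold and the design inherits
#' that behaviour). Without a reference the base profile is replicated.
#'
#' @param base a 1D `target_profile`.
#' @param b1max_list peak amplitudes in uT (e.g. `2.35 * (1:20)`).
#' @return a `target_profile` with mode `"b1_sweep"`; its grid is the base
#'   grid replicated per sweep value with the transmit scale `c` set to the
#'   sweep amplitude (the designed waveform is normalized to unit peak and
#'   scaled through `c`).
#' @export
sweep_target <- function(base, b1max_list) {
  if (length(base$profile$grid$dims) != 1L) stop("base target must be 1D")
  if (length(b1max_list) < 1L) stop("empty B1max sweep")
  g <- base$profile$grid
  S <- length(b1max_list)
  blocks <- vector("list", S)
  for (s in seq_len(S)) {
    if (!is.null(base$reference)) {
      ref <- base$reference
      rfs <- pulse_scale_to_peak(ref$rf, b1max_list[s])
      blocks[[s]] <- simulate_pulse(rfs, ref$grad, g, rephase = ref$rephase)$M
    } else {
      blocks[[s]] <- base$profile$M
    }
  }
  M <- do.call(rbind, blocks)
  grid_rep <- spin_grid(pos = g$pos[rep(seq_len(g$npts), S), , drop = FALSE],
                        offset = rep(g$offset, S), cs = rep(g$cs, S),
                        b1c = rep(b1max_list, each = g$npts),
                        dims = S * g$npts)
  grid_rep$sweep_dims <- c(g$npts, S)
  new_target(mag_profile(M, grid_rep), mode = "b1_sweep", input = "mz",
             sweep = b1max_list, reference = base$reference,
             dims = c(g$npts, S))
}

#' 2D binary-mask excitation target
#'
#' @param mask binary matrix (rows x cols) matching the grid shape.
#' @param flip flip angle (degrees) inside the mask.
#' @param grid a 2D `spin_grid` (from [grid_spatial_2d()]).
#' @export
mask2d_target <- function(mask, flip, grid, input = "auto") {
  mask <- as.matrix(mask)
  if (!all(dim(mask) == grid$dims))
    stop(sprintf("mask is %d x %d but grid is %s", nrow(mask), ncol(mask),
                 paste(grid$dims, collapse = " x ")))
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  m <- as.vector(t(mask))               # row-major flatten
  a <- flip * pi / 180 * m
  M <- cbind(0, sin(a), cos(a))
  new_target(mag_profile(M, grid), mode = "selective_2d", input = input)
}

#' Analytic spectral-spatial target
#'
#' Excites cells inside the spatial band and within the spectral passband
#' around `spectral_center`; every other cell stays at equilibrium.
#'
#' @param spatial_band full spatial band width (m).
#' @param spectral_center spectral passband centre (Hz).
#' @param flip flip angle (degrees).
#' @param grid a `spin_grid` from [grid_spsp()].
#' @param spectral_halfwidth spectral passband half-width (Hz).
#' @export
spsp_target <- function(spatial_band, spectral_center, flip, grid,
                        spectral_halfwidth = 220, input = "auto") {
  if (spectral_center < min(grid$cs) || spectral_center > max(grid$cs))
    stop("spectral_center lies outside the grid's chemical-shift range")
  z <- grid$pos[, 1]
  inside <- (abs(z) <= spatial_band / 2) &
    (abs(grid$cs - spectral_center) <= spectral_halfwidth)
  a <- flip * pi / 180 * inside
  M <- cbind(0, sin(a), cos(a))
  new_target(mag_profile(M, grid), mode = "spsp", input = input)
}
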