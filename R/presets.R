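# Packaged reference design problems. These fix the study conditions used
# throughout the documentation and the acceptance checks; every quantity is
# rebuilt from scratch at call time, nothing is cached.

#' Reference design problems
#'
#' Constructs the packaged design problems at their standard conditions:
#'
#' * `"selective_1d_scaled"`: rectangle 90-degree target (passband half-width
#'   1289 Hz, raised-cosine transition of `2/T` = 781.25 Hz, the transition a
#'   2.56 ms pulse supports) on a 512-point grid over +/-8.192 kHz;
#'   128-sample pulse at 20 us dwell, refocused by -T/2.
#' * `"selective_1d_full"`: target simulated from the packaged linear-phase
#'   selective reference (2.56 ms, time-bandwidth 6.6, 90 degrees) on a
#'   2048-point grid over +/-32.768 kHz; 256-sample pulse at 10 us dwell.
#' * `"b1_insensitive_scaled"`: inversion target simulated from an HS1 pulse
#'   (8 ms, 2 kHz bandwidth) on a 512-point grid over +/-8.192 kHz,
#'   replicated across the 10-value peak-amplitude sweep 4.7-47 uT (each row
#'   simulated at its own B1max); 128-sample pulse at 62.5 us dwell,
#'   normalized waveform scaled per sweep value.
#' * `"selective_2d_scaled"`: 32x32 "AI" glyph at 15 degrees over a 0.24 m
#'   field of view, excited along a 12-turn variable-density spiral-in of
#'   600 samples (10 us dwell) within 24 mT/m and 120 T/m/s.
#'
#' @param name preset name.
#' @param seed RNG seed for the network initialisation.
#' @param max_epochs optional epoch-cap override.
#' @return list with `target`, `physics`, `cfg` — pass to [design_pulse()].
#' @export
reference_problem <- function(name = c("selective_1d_scaled",
                                       "selective_1d_full",
                                       "b1_insensitive_scaled",
                                       "selective_2d_scaled"),
                              seed = 1L, max_epochs = NULL) {
  name <- match.arg(name)
  if (name %in% c("selective_1d_scaled", "selective_1d_full")) {
    full <- name == "selective_1d_full"
    n <- if (full) 2048L else 512L
    fmax <- if (full) 32768 else 8192
    t <- if (full) 256L else 128L
    dwell <- if (full) 1e-5 else 2e-5
    grid <- grid_freq(n, fmax)
    rephase <- -t * dwell / 2
    target <- if (full) {
      ref <- linear_phase_selective(t * dwell, 6.6, 90, t)
      target_from_reference(ref, NULL, grid, rephase = rephase)
    } else {
      rect_target(1289, 90, grid, transition = 2 / (t * dwell))
    }
    physics <- physics_for_target(target, dwell = dwell, rephase = rephase)
    cfg <- design_config(t = t, dwell = dwell, seed = seed,
                         edm_threshold = 0.999,
                         max_epochs = if (is.null(max_epochs)) 1500L else max_epochs)
  } else if (name == "b1_insensitive_scaled") {
    t <- 128L
    dwell <- 62.5e-6           # 8 ms pulse, matching the reference HS1 width
    grid <- grid_freq(512L, 8192)
    ref <- hs1(8e-3, 2000, b1max = 1, n = t)
    base <- target_from_reference(ref, NULL, grid, mode = "b1_sweep")
    target <- sweep_target(base, 4.7 * (1:10))
    physics <- physics_for_target(target, dwell = dwell)
    cfg <- design_config(t = t, dwell = dwell, seed = seed,
                         edm_threshold = 0.999, b1max_list = target$sweep,
                         max_epochs = if (is.null(max_epochs)) 800L else max_epochs)
  } else {
    t <- 600L
    dwell <- 1e-5
    fov <- 0.24
    grid <- grid_spatial_2d(32L, 32L, fov)
    target <- mask2d_target(glyph_mask_ai(32L, 32L), 15, grid)
    grad <- vd_spiral_in(spiral_spec(duration = t * dwell, turns = 12,
                                     fov = fov, density = 1.25, gmax = 24,
                                     smax = 120, samples = t))
    physics <- physics_for_target(target, grad = grad, dwell = dwell)
    cfg <- design_config(t = t, dwell = dwell, seed = seed,
                         edm_threshold = 0.98,
                         max_epochs = if (is.null(max_epochs)) 1500L else max_epochs)
  }
  list(target = target, physics = physics, cfg = cfg)
}

#' Synthetic adaptation maps for the 2D reference design
#'
#' B0 within +/-100 Hz and B1+ scale within 0.7 to 1.3, both smooth and
#' seeded — strong enough to visibly corrupt the unadapted profile while
#' remaining correctable.
#'
#' @param grid the design grid.
#' @param seed RNG seed.
#' @export
reference_maps <- function(grid, seed = 1L) {
  system_maps(db0 = synth_b0_map(grid, amplitude = 100, seed = seed),
              b1 = synth_b1_map(grid, center_scale = 1, variation = 0.3,
                                seed = seed),
              grid = grid)
}
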