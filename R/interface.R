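# Configuration-driven workflows. A run config is a YAML file (or list)
# validated against an explicit schema: unknown keys are rejected so typos
# fail loudly before any computation starts.

config_schema <- list(
  mode = "character",
  seed = "numeric",
  pulse = list(t = "numeric", dwell = "numeric"),
  # YAML 1.1 reads a bare key `n` as a boolean, so the point count is
  # `n_points`; plain `n` is still accepted from programmatic list configs
  grid = list(n_points = "numeric", n = "numeric", fmax_hz = "numeric",
              nx = "numeric", ny = "numeric", fov_m = "numeric"),
  target = list(kind = "character", band_halfwidth_hz = "numeric",
                flip_deg = "numeric", transition_hz = "numeric",
                pulse_file = "character", gradient_file = "character",
                mask_file = "character",
                hs1_duration_s = "numeric", hs1_bandwidth_hz = "numeric",
                b1max_list_ut = "numeric"),
  gradient = list(file = "character", spiral_turns = "numeric",
                  spiral_samples = "numeric", spiral_duration_s = "numeric",
                  density = "numeric", gmax_mt_m = "numeric",
                  smax_t_m_s = "numeric"),
  optimizer = list(lr_offline = "numeric", lr_adapt = "numeric",
                   edm_threshold = "numeric", adapt_threshold = "numeric",
                   patience = "numeric", plateau_tol = "numeric",
                   max_epochs = "numeric", max_adapt_epochs = "numeric",
                   reg_lambda = "numeric", reg_tau = "numeric",
                   compare = "character", lora_rank = "numeric"),
  maps = list(b0_file = "character", b1_file = "character",
              synth_b0_hz = "numeric", synth_b1_variation = "numeric",
              map_seed = "numeric"),
  checkpoint = "character",
  rephase_frac = "numeric",
  out_dir = "character",
  verbose = "numeric"
)

validate_block <- function(cfg, schema, path = "") {
  for (key in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(schema))
      stop(sprintf("unknown config key '%s'", full))
    spec <- schema[[key]]
    if (is.list(spec)) {
      if (!is.list(cfg[[key]]))
        stop(sprintf("config key '%s' must be a block", full))
      validate_block(cfg[[key]], spec, full)
    } else {
      ok <- switch(spec, numeric = is.numeric(cfg[[key]]),
                   character = is.character(cfg[[key]]), TRUE)
      if (!ok) stop(sprintf("config key '%s' must be %s", full, spec))
    }
  }
  invisible(TRUE)
}

#' Load and validate a run configuration
#'
#' @param x path to a YAML file, or a config list.
#' @return the validated config list.
#' @export
load_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  validate_block(cfg, config_schema)
  if (is.null(cfg$mode)) stop("config must set 'mode'")
  if (!cfg$mode %in% c("selective_1d", "b1_sweep", "spsp", "selective_2d"))
    stop("unknown mode: ", cfg$mode)
  t <- cfg$pulse$t
  if (is.null(t)) stop("config must set pulse.t")
  if (t > MLP_OUT_MAX)
    stop(sprintf("pulse.t = %d exceeds the designable maximum of %d samples",
                 t, MLP_OUT_MAX))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

cfg_get <- function(cfg, ..., default = NULL) {
  for (k in c(...)) {
    if (is.null(cfg)) return(default)
    cfg <- cfg[[k]]
  }
  if (is.null(cfg)) default else cfg
}

config_to_design <- function(cfg) {
  opt <- cfg$optimizer
  default_thr <- if (cfg$mode == "selective_2d") 0.98 else 0.999
  design_config(
    t = as.integer(cfg$pulse$t), dwell = cfg$pulse$dwell,
    lr_offline = cfg_get(opt, "lr_offline", default = 1e-3),
    lr_adapt = cfg_get(opt, "lr_adapt", default = 1e-2),
    edm_threshold = cfg_get(opt, "edm_threshold", default = default_thr),
    adapt_threshold = cfg_get(opt, "adapt_threshold", default = 0.98),
    patience = cfg_get(opt, "patience", default = 50L),
    plateau_tol = cfg_get(opt, "plateau_tol", default = 1e-5),
    max_epochs = cfg_get(opt, "max_epochs", default = 2000L),
    max_adapt_epochs = cfg_get(opt, "max_adapt_epochs", default = 40L),
    seed = as.integer(cfg$seed),
    reg_lambda = cfg_get(opt, "reg_lambda", default = 0),
    reg_tau = cfg_get(opt, "reg_tau", default = 2),
    compare = cfg_get(opt, "compare", default = "all"),
    lora_rank = as.integer(cfg_get(opt, "lora_rank", default = 4L)),
    b1max_list = cfg_get(cfg, "target", "b1max_list_ut"),
    verbose = as.integer(cfg_get(cfg, "verbose", default = 0L))
  )
}

# Build grid/target/gradient from a config. Covers the analytic target
# paths; reference pulses can be supplied as waveform files.
config_to_problem <- function(cfg) {
  dwell <- cfg$pulse$dwell
  t <- as.integer(cfg$pulse$t)
  mode <- cfg$mode
  grad <- NULL
  if (mode %in% c("selective_1d", "b1_sweep")) {
    npts <- cfg_get(cfg, "grid", "n_points",
                    default = cfg_get(cfg, "grid", "n", default = 512L))
    grid <- grid_freq(npts, cfg_get(cfg, "grid", "fmax_hz", default = 8192))
  } else if (mode == "selective_2d") {
    nx <- cfg_get(cfg, "grid", "nx", default = 32L)
    ny <- cfg_get(cfg, "grid", "ny", default = nx)
    grid <- grid_spatial_2d(nx, ny, cfg_get(cfg, "grid", "fov_m", default = 0.24))
  } else stop("spsp designs are configured programmatically; see spsp_spec()")

  kind <- cfg_get(cfg, "target", "kind",
                  default = if (mode == "b1_sweep") "hs1" else
                    if (mode == "selective_2d") "glyph" else "rect")
  rephase <- if (mode == "selective_1d")
    -cfg_get(cfg, "rephase_frac", default = 0.5) * t * dwell else 0

  if (kind == "rect") {
    target <- rect_target(cfg_get(cfg, "target", "band_halfwidth_hz", default = 1289),
                          cfg_get(cfg, "target", "flip_deg", default = 90),
                          grid,
                          transition = cfg_get(cfg, "target", "transition_hz",
                                               default = 400))
  } else if (kind == "reference") {
    rf <- read_pulse(cfg$target$pulse_file)
    gf <- cfg_get(cfg, "target", "gradient_file")
    gref <- if (is.null(gf)) NULL else read_gradient(gf)
    target <- target_from_reference(rf, gref, grid, mode = mode,
                                    rephase = rephase)
  } else if (kind == "hs1") {
    ref <- hs1(cfg_get(cfg, "target", "hs1_duration_s", default = 8e-3),
               cfg_get(cfg, "target", "hs1_bandwidth_hz", default = 2000),
               b1max = 1, n = t)
    base <- target_from_reference(ref, NULL, grid, mode = "b1_sweep")
    b1l <- cfg_get(cfg, "target", "b1max_list_ut", default = 4.7 * (1:10))
    target <- sweep_target(base, b1l)
  } else if (kind == "glyph") {
    mf <- cfg_get(cfg, "target", "mask_file")
    mask <- if (is.null(mf)) glyph_mask_ai(grid$dims[1], grid$dims[2]) else {
      m <- read_map(mf); matrix(m, grid$dims[1], grid$dims[2], byrow = TRUE)
    }
    target <- mask2d_target(mask, cfg_get(cfg, "target", "flip_deg", default = 15),
                            grid)
  } else stop("unknown target kind: ", kind)

  if (mode == "selective_2d") {
    gf <- cfg_get(cfg, "gradient", "file")
    grad <- if (!is.null(gf)) read_gradient(gf) else {
      sp <- spiral_spec(
        duration = cfg_get(cfg, "gradient", "spiral_duration_s", default = t * dwell),
        turns = cfg_get(cfg, "gradient", "spiral_turns", default = 12),
        fov = cfg_get(cfg, "grid", "fov_m", default = 0.24),
        density = cfg_get(cfg, "gradient", "density", default = 1.25),
        gmax = cfg_get(cfg, "gradient", "gmax_mt_m", default = 24),
        smax = cfg_get(cfg, "gradient", "smax_t_m_s", default = 120),
        samples = cfg_get(cfg, "gradient", "spiral_samples", default = t))
      vd_spiral_in(sp)
    }
  }
  physics <- physics_for_target(target, grad = grad, dwell = dwell,
                                rephase = rephase)
  list(target = target, physics = physics, grad = grad)
}

config_maps <- function(cfg, grid) {
  mp <- cfg$maps
  if (is.null(mp)) return(NULL)
  db0 <- if (!is.null(mp$b0_file)) as.numeric(read_map(mp$b0_file)) else
    synth_b0_map(grid, amplitude = cfg_get(mp, "synth_b0_hz", default = 100),
                 seed = as.integer(cfg_get(mp, "map_seed", default = cfg$seed)))
  b1 <- if (!is.null(mp$b1_file)) as.numeric(read_map(mp$b1_file)) else
    synth_b1_map(grid, center_scale = 1,
                 variation = cfg_get(mp, "synth_b1_variation", default = 0.3),
                 seed = as.integer(cfg_get(mp, "map_seed", default = cfg$seed)))
  system_maps(db0 = db0, b1 = b1, grid = grid)
}

write_run_artifacts <- function(state, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    pulse = file.path(out_dir, "pulse.txt"),
    checkpoint = file.path(out_dir, "checkpoint.rds"),
    history = file.path(out_dir, "history.csv"),
    profile = file.path(out_dir, "profile.txt"),
    config = file.path(out_dir, "config.yaml"))
  write_pulse(state$pulse, paths$pulse)
  save_checkpoint(state, paths$checkpoint)
  write_history(state, paths$history)
  write_profile(state$profile, paths$profile)
  cfg$warning <- if (state$converged) NULL else "did not reach the EDM threshold"
  yaml::write_yaml(cfg, paths$config)
  paths
}

#' Run an offline design from a configuration
#'
#' @param config YAML path or config list (see `load_config()`).
#' @return list with `state`, `edm`, `epochs`, `converged` and artifact
#'   `paths` (pulse, checkpoint, history CSV, profile, config copy).
#' @export
run_design <- function(config) {
  cfg <- load_config(config)
  prob <- config_to_problem(cfg)
  dcfg <- config_to_design(cfg)
  state <- design_pulse(prob$target, prob$physics, dcfg)
  out_dir <- cfg_get(cfg, "out_dir", default = file.path(tempdir(), "design_run"))
  paths <- write_run_artifacts(state, cfg, out_dir)
  message(sprintf("design finished: EDM %.5f after %d epochs (%s)",
                  state$edm, state$epochs,
                  if (state$converged) "converged" else "NOT converged"))
  invisible(list(state = state, edm = state$edm, epochs = state$epochs,
                 converged = state$converged, paths = paths))
}

#' Adapt a checkpointed design to system maps
#'
#' @param config YAML path or config list; must name `checkpoint` and a
#'   `maps` block (files or synthetic-map settings).
#' @return list with the adapted state, `edm_before`/`edm_after` report and
#'   artifact paths.
#' @export
run_adapt <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$checkpoint)) stop("adapt requires a 'checkpoint' entry")
  state <- load_checkpoint(cfg$checkpoint)
  grid <- state$target$profile$grid
  maps <- config_maps(cfg, grid)
  if (is.null(maps)) stop("adapt requires a 'maps' block")
  adapted <- adapt_pulse(state, maps, cfg = state$cfg)
  out_dir <- cfg_get(cfg, "out_dir", default = file.path(tempdir(), "adapt_run"))
  paths <- write_run_artifacts(adapted, cfg, out_dir)
  report <- data.frame(edm_before = adapted$edm_before, edm_after = adapted$edm)
  write.csv(report, file.path(out_dir, "adapt_report.csv"), row.names = FALSE)
  message(sprintf("adaptation: EDM %.5f -> %.5f in %d epochs",
                  adapted$edm_before, adapted$edm, adapted$epochs))
  invisible(list(state = adapted, edm_before = adapted$edm_before,
                 edm_after = adapted$edm, paths = paths))
}

#' Simulate a pulse file on a grid and export the profile
#'
#' @param pulse_file plain-text pulse file.
#' @param grid a `spin_grid`.
#' @param gradient_file optional gradient file.
#' @param maps optional `system_maps`.
#' @param rephase rewind (s).
#' @param out profile output path (optional).
#' @export
run_simulate <- function(pulse_file, grid, gradient_file = NULL, maps = NULL,
                         rephase = 0, out = NULL) {
  rf <- read_pulse(pulse_file)
  grad <- if (is.null(gradient_file)) NULL else read_gradient(gradient_file)
  pf <- simulate_pulse(rf, grad, grid, maps = maps, rephase = rephase)
  if (!is.null(out)) write_profile(pf, out)
  pf
}

#' Evaluate a simulated profile against a target
#'
#' @param profile a `mag_profile`.
#' @param target a `target_profile`.
#' @return list with the EDM, in-band mean flip angle (degrees) and
#'   out-of-band maximum transverse magnitude; "in band" means target
#'   transverse magnitude above half its maximum.
#' @export
run_evaluate <- function(profile, target) {
  Mt <- target$profile$M
  txy <- sqrt(Mt[, 1]^2 + Mt[, 2]^2)
  inband <- txy > max(txy) / 2
  sxy <- sqrt(profile$M[, 1]^2 + profile$M[, 2]^2)
  flip <- atan2(sxy, profile$M[, 3]) * 180 / pi
  list(edm = edm(profile$M, Mt),
       inband_mean_flip_deg = if (any(inband)) mean(flip[inband]) else NA_real_,
       outband_max_transverse = if (any(!inband)) max(sxy[!inband]) else NA_real_)
}
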