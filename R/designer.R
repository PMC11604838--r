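#' Design configuration
#'
#' Collects the optimizer and stopping settings of a design run. Learning
#' rates default to 1e-3 (offline) and 1e-2 (online adaptation); the EDM
#' stopping threshold is 0.999 for 1D-profile designs and 0.98 for 2D
#' spatially selective designs; adaptation stops at EDM 0.98. Training stops
#' once the loss has plateaued (relative improvement below `plateau_tol`
#' over `patience` epochs) while the EDM threshold is met, or at
#' `max_epochs`.
#'
#' @param t designed pulse length (samples, `<= 2560`).
#' @param dwell design raster (s).
#' @param lr_offline,lr_adapt AdamW learning rates.
#' @param edm_threshold,adapt_threshold EDM stopping thresholds.
#' @param patience plateau window (epochs).
#' @param plateau_tol relative loss-improvement tolerance defining a plateau.
#' @param max_epochs,max_adapt_epochs epoch caps.
#' @param seed RNG seed (network initialisation).
#' @param b1max_list peak-amplitude sweep (uT), B1-insensitive mode only.
#' @param reg_lambda peak-amplitude regularization weight (0 disables).
#' @param reg_tau sharpness (1/uT) of the log-sum-exp surrogate of
#'   `max |B1|` used by the regularizer.
#' @param compare which profile components enter the loss: all three
#'   (default, consistent with the 3-vector EDM), `mz` only, or transverse
#'   only.
#' @param beta1,beta2,eps,weight_decay AdamW constants.
#' @param lora_rank adapter rank for online adaptation.
#' @param verbose print a progress line every `verbose` epochs (0 silences).
#' @export
design_config <- function(t, dwell, lr_offline = 1e-3, lr_adapt = 1e-2,
                          edm_threshold = 0.999, adapt_threshold = 0.98,
                          patience = 50L, plateau_tol = 1e-5,
                          max_epochs = 2000L, max_adapt_epochs = 40L,
                          seed = 1L, b1max_list = NULL, reg_lambda = 0,
                          reg_tau = 2, compare = c("all", "mz", "xy"),
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          weight_decay = 0.01, lora_rank = 4L, verbose = 0L) {
  compare <- match.arg(compare)
  stopifnot(lr_offline > 0, lr_adapt > 0,
            edm_threshold > -1, edm_threshold <= 1,
            adapt_threshold > -1, adapt_threshold <= 1)
  if (t > MLP_OUT_MAX)
    stop(sprintf("pulse length t = %d exceeds the network output cap of %d samples",
                 t, MLP_OUT_MAX))
  structure(as.list(environment()), class = "design_config")
}

#' Physics model closure for the designer
#'
#' Bundles everything the Bloch supervision needs: the evaluation grid
#' (replicated across the sweep for B1-insensitive designs), optional
#' gradients, the rewind convention and optional system maps.
#'
#' @param grid design `spin_grid` (use `target$profile$grid`).
#' @param grad optional `grad_waveform`.
#' @param dwell RF raster (s).
#' @param rephase appended free-precession time (s); `-t*dwell/2` for 1D
#'   frequency-selective designs, 0 otherwise.
#' @param maps optional `system_maps` applied inside the simulator (online
#'   adaptation).
#' @export
physics_model <- function(grid, grad = NULL, dwell, rephase = 0, maps = NULL) {
  if (!is.null(grad) && !is.null(maps))
    NULL # both are allowed together; nothing to reconcile
  structure(list(grid = grid, grad = grad, dwell = dwell, rephase = rephase,
                 maps = maps), class = "physics_model")
}

#' Convenience: physics model matching a target
#' @param target a `target_profile`.
#' @param grad optional `grad_waveform`.
#' @param dwell RF raster (s).
#' @param rephase rewind (s).
#' @param maps optional `system_maps`.
#' @export
physics_for_target <- function(target, grad = NULL, dwell, rephase = 0,
                               maps = NULL) {
  physics_model(target$profile$grid, grad = grad, dwell = dwell,
                rephase = rephase, maps = maps)
}

#' Network forward pass to an RF pulse
#'
#' Runs the target's input channel through the MLP and interprets the two
#' branch outputs as the real and imaginary RF channels in uT. In
#' `b1_sweep` mode the complex waveform is normalized to unit peak
#' magnitude; the physics model then scales it per sweep amplitude through
#' the grid's transmit scale.
#'
#' @param net an `mlp_designer`.
#' @param target a `target_profile`.
#' @param dwell RF raster (s).
#' @param lora optional `lora_adapter`.
#' @return an `rf_pulse` (attribute `"normalized"` is TRUE in sweep mode).
#' @export
forward_design <- function(net, target, dwell, lora = NULL) {
  fw <- mlp_forward(net, target$input_channel, lora)
  re <- fw$re; im <- fw$im
  if (target$mode == "b1_sweep") {
    peak <- max(sqrt(re^2 + im^2))
    if (peak > 0) { re <- re / peak; im <- im / peak }
  }
  out <- rf_pulse(re, im, dwell)
  attr(out, "normalized") <- identical(target$mode, "b1_sweep")
  out
}

#' Self-supervised design loss
#'
#' Mean squared difference between the simulated and target profiles over
#' the compared components (averaged over every compared scalar entry, and
#' thus over all sweep amplitudes in `b1_sweep` mode), plus an optional
#' peak-amplitude penalty `reg_lambda * softmax_tau(|B1|)`.
#'
#' @param simulated,target `mag_profile` / `target_profile` (or plain
#'   matrices of matching shape).
#' @param pulse the designed `rf_pulse` (for the regularizer).
#' @param reg_lambda,reg_tau regularizer weight and sharpness.
#' @param compare component subset (see [design_config()]).
#' @return scalar loss.
#' @export
loss_offline <- function(simulated, target, pulse = NULL, reg_lambda = 0,
                         reg_tau = 2, compare = "all") {
  Ms <- if (inherits(simulated, "mag_profile")) simulated$M else simulated
  Mt <- if (inherits(target, "target_profile")) target$profile$M else
    if (inherits(target, "mag_profile")) target$M else target
  if (!all(dim(Ms) == dim(Mt))) stop("profile shapes do not match")
  cols <- switch(compare, all = 1:3, mz = 3L, xy = 1:2)
  D <- Ms[, cols, drop = FALSE] - Mt[, cols, drop = FALSE]
  loss <- mean(D^2)
  if (reg_lambda > 0 && !is.null(pulse))
    loss <- loss + reg_lambda * peak_surrogate(pulse$re, pulse$im, reg_tau)$value
  loss
}

# smooth surrogate of max|B1| (log-sum-exp with sharpness tau, in uT) and
# its gradient wrt the RF channels
peak_surrogate <- function(re, im, tau) {
  amp <- sqrt(re^2 + im^2 + 1e-12)
  a0 <- max(amp)
  w <- exp(tau * (amp - a0))
  value <- a0 + log(sum(w)) / tau
  sw <- w / sum(w)
  list(value = value, g_re = sw * re / amp, g_im = sw * im / amp)
}

#' Euclidean distance measure between two profiles
#'
#' `1 - mean_r ||M_a(r) - M_b(r)||`: 1 is a perfect match; for unit
#' magnetization vectors the score lies in `[-1, 1]`.
#'
#' @param a,b `mag_profile`s (or npts x 3 matrices) on the same grid.
#' @export
edm <- function(a, b) {
  Ma <- if (inherits(a, "mag_profile")) a$M else a
  Mb <- if (inherits(b, "mag_profile")) b$M else b
  if (!all(dim(Ma) == dim(Mb)))
    stop("EDM: profiles live on different grids")
  1 - mean(sqrt(rowSums((Ma - Mb)^2)))
}

#' Per-sweep-value EDM of a B1-insensitive design
#'
#' @param simulated npts x 3 matrix (stacked sweep blocks) or `mag_profile`.
#' @param target the `b1_sweep` `target_profile`.
#' @return named numeric vector, one EDM per B1max.
#' @export
edm_per_sweep <- function(simulated, target) {
  Ms <- if (inherits(simulated, "mag_profile")) simulated$M else simulated
  S <- length(target$sweep)
  npts <- nrow(Ms) / S
  vapply(seq_len(S), function(s) {
    idx <- (s - 1L) * npts + seq_len(npts)
    edm(Ms[idx, , drop = FALSE], target$profile$M[idx, , drop = FALSE])
  }, numeric(1)) |> setNames(sprintf("%.3g uT", target$sweep))
}

# one full forward pass (network -> pulse -> Bloch) with everything needed
# for the backward pass
design_forward_full <- function(net, target, physics, lora = NULL) {
  fw <- mlp_forward(net, target$input_channel, lora)
  re_raw <- fw$re; im_raw <- fw$im
  normalized <- identical(target$mode, "b1_sweep")
  if (normalized) {
    amp <- sqrt(re_raw^2 + im_raw^2)
    jpk <- which.max(amp)
    peak <- amp[jpk]
    re <- re_raw / peak; im <- im_raw / peak
  } else {
    re <- re_raw; im <- im_raw; peak <- NA_real_; jpk <- NA_integer_
  }
  rfp <- rf_pulse(re, im, physics$dwell)
  sim <- simulate_pulse(rfp, physics$grad, physics$grid, maps = physics$maps,
                        rephase = physics$rephase, keep_traj = TRUE)
  list(fw = fw, rfp = rfp, sim = sim, normalized = normalized,
       re_raw = re_raw, im_raw = im_raw, peak = peak, jpk = jpk)
}

# gradient of the loss wrt the raw branch outputs; returns g_re, g_im and the
# scalar loss
design_backward_full <- function(st, target, physics, cfg) {
  Ms <- st$sim$M
  Mt <- target$profile$M
  cols <- switch(cfg$compare, all = 1:3, mz = 3L, xy = 1:2)
  D <- Ms - Mt
  N <- nrow(Ms) * length(cols)
  loss <- sum(D[, cols]^2) / N
  gM <- matrix(0, nrow(Ms), 3L)
  gM[, cols] <- 2 * D[, cols] / N
  bk <- simulate_pulse_grad(st$rfp, physics$grad, physics$grid,
                            maps = physics$maps, rephase = physics$rephase,
                            traj = attr(st$sim, "traj"), gM = gM)
  g_re <- bk$g_re; g_im <- bk$g_im
  if (cfg$reg_lambda > 0) {
    ps <- peak_surrogate(st$rfp$re, st$rfp$im, cfg$reg_tau)
    loss <- loss + cfg$reg_lambda * ps$value
    g_re <- g_re + cfg$reg_lambda * ps$g_re
    g_im <- g_im + cfg$reg_lambda * ps$g_im
  }
  if (st$normalized) {
    # chain rule through w_norm = w / max|w| (argmax sample jpk)
    u <- st$re_raw; w <- st$im_raw; p <- st$peak; j <- st$jpk
    s <- sum(g_re * u + g_im * w) / p^2
    g_re_raw <- g_re / p
    g_im_raw <- g_im / p
    g_re_raw[j] <- g_re_raw[j] - s * u[j] / p
    g_im_raw[j] <- g_im_raw[j] - s * w[j] / p
    list(loss = loss, g_re = g_re_raw, g_im = g_im_raw)
  } else {
    list(loss = loss, g_re = g_re, g_im = g_im)
  }
}

plateaued <- function(losses, patience, tol) {
  e <- length(losses)
  if (e < 2L * patience) return(FALSE)
  past <- min(losses[seq_len(e - patience)])
  recent <- min(losses[(e - patience + 1L):e])
  (past - recent) <= tol * max(past, .Machine$double.xmin)
}

#' Offline self-supervised pulse design
#'
#' Iterates network forward pass, Bloch simulation, mean-squared profile
#' loss and AdamW update until the loss plateaus with the EDM threshold met
#' (or `max_epochs`). The whole run is deterministic given the seed.
#'
#' @param target a `target_profile`.
#' @param physics a `physics_model` on the target's grid.
#' @param cfg a `design_config`.
#' @return a `designer_state`: the trained network, per-epoch history
#'   (`epoch`, `loss`, `edm`), the final pulse and its simulated profile.
#' @export
design_pulse <- function(target, physics, cfg) {
  stopifnot(inherits(target, "target_profile"),
            inherits(physics, "physics_model"))
  if (!is.null(physics$grad) && physics$grad$n != cfg$t)
    stop(sprintf("raster mismatch: t = %d but gradient has %d samples",
                 cfg$t, physics$grad$n))
  net <- build_mlp(target$d, cfg$t, seed = cfg$seed)
  opt <- adamw_state(net)
  ocfg <- list(lr = cfg$lr_offline, beta1 = cfg$beta1, beta2 = cfg$beta2,
               eps = cfg$eps, weight_decay = cfg$weight_decay)
  history <- data.frame(epoch = integer(), loss = numeric(), edm = numeric())
  for (epoch in seq_len(cfg$max_epochs)) {
    st <- design_forward_full(net, target, physics)
    bk <- design_backward_full(st, target, physics, cfg)
    if (!is.finite(bk$loss))
      stop(sprintf("non-finite loss at epoch %d; aborting design", epoch))
    cur_edm <- edm(st$sim$M, target$profile$M)
    history[epoch, ] <- list(epoch, bk$loss, cur_edm)
    gys_re <- branch_backward(net$real, st$fw$cache_re, bk$g_re, net$t, net$slope)
    gys_im <- branch_backward(net$imag, st$fw$cache_im, bk$g_im, net$t, net$slope)
    opt <- adamw_step_net(net, opt, gys_re, st$fw$cache_re,
                          gys_im, st$fw$cache_im, ocfg)
    if (cfg$verbose > 0 && epoch %% cfg$verbose == 0)
      message(sprintf("epoch %d  loss %.3e  EDM %.5f", epoch, bk$loss, cur_edm))
    if (cur_edm >= cfg$edm_threshold &&
        plateaued(history$loss, cfg$patience, cfg$plateau_tol)) break
  }
  final <- design_forward_full(net, target, physics)
  final_edm <- edm(final$sim$M, target$profile$M)
  structure(list(net = net, lora = NULL, cfg = cfg, target = target,
                 physics = physics, history = history,
                 pulse = final$rfp, profile = final$sim,
                 edm = final_edm, epochs = nrow(history),
                 converged = final_edm >= cfg$edm_threshold),
            class = "designer_state")
}

#' @export
print.designer_state <- function(x, ...) {
  cat(sprintf("<designer_state> mode %s, %d epochs, final EDM %.5f (%s)\n",
              x$target$mode, x$epochs, x$edm,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Online adaptation to measured system maps
#'
#' Extends the physics model of a converged offline design with B0/B1+ maps,
#' freezes the base network, and trains rank-constrained LoRA factors (zero
#' initialised, so epoch 0 reproduces the offline pulse exactly) at the
#' adaptation learning rate until the EDM under the maps reaches the
#' adaptation threshold or `max_adapt_epochs`.
#'
#' @param state a converged `designer_state`.
#' @param maps a `system_maps` on the design grid.
#' @param cfg optional `design_config` override (defaults to the state's).
#' @return a `designer_state` with the adapter attached; `$edm_before` holds
#'   the EDM of the unadapted offline pulse simulated under the maps.
#' @export
adapt_pulse <- function(state, maps, cfg = NULL) {
  if (is.null(cfg)) cfg <- state$cfg
  target <- state$target
  grid <- target$profile$grid
  if (!is.null(maps$db0) && length(maps$db0) != grid$npts ||
      !is.null(maps$b1) && length(maps$b1) != grid$npts)
    stop("system maps do not match the design grid")
  physics <- state$physics
  physics$maps <- maps
  net <- state$net
  lora <- attach_lora(net, rank = cfg$lora_rank, seed = cfg$seed + 1000L)
  opt <- lora_opt_state(lora)
  acfg <- list(lr = cfg$lr_adapt, beta1 = cfg$beta1, beta2 = cfg$beta2,
               eps = cfg$eps, weight_decay = cfg$weight_decay)
  history <- data.frame(epoch = integer(), loss = numeric(), edm = numeric())
  edm_before <- NA_real_
  for (epoch in seq_len(cfg$max_adapt_epochs)) {
    st <- design_forward_full(net, target, physics, lora)
    bk <- design_backward_full(st, target, physics, cfg)
    if (!is.finite(bk$loss))
      stop(sprintf("non-finite adaptation loss at epoch %d", epoch))
    cur_edm <- edm(st$sim$M, target$profile$M)
    if (epoch == 1L) edm_before <- cur_edm   # zero-init adapter = offline pulse
    history[epoch, ] <- list(epoch, bk$loss, cur_edm)
    if (cur_edm >= cfg$adapt_threshold) break
    gys_re <- branch_backward(net$real, st$fw$cache_re, bk$g_re, net$t,
                              net$slope, lora$real)
    gys_im <- branch_backward(net$imag, st$fw$cache_im, bk$g_im, net$t,
                              net$slope, lora$imag)
    opt <- adamw_step_lora(lora, opt, gys_re, st$fw$cache_re,
                           gys_im, st$fw$cache_im, acfg)
    if (cfg$verbose > 0)
      message(sprintf("adapt epoch %d  loss %.3e  EDM %.5f", epoch, bk$loss, cur_edm))
  }
  final <- design_forward_full(net, target, physics, lora)
  final_edm <- edm(final$sim$M, target$profile$M)
  structure(list(net = net, lora = lora, cfg = cfg, target = target,
                 physics = physics, history = history,
                 pulse = final$rfp, profile = final$sim,
                 edm = final_edm, edm_before = edm_before,
                 epochs = nrow(history),
                 converged = final_edm >= cfg$adapt_threshold),
            class = "designer_state")
}

#' Drop the adapter from an adapted state
#'
#' Stripping the LoRA factors restores the frozen base network, hence the
#' offline pulse, exactly.
#'
#' @param state an adapted `designer_state`.
#' @export
strip_lora <- function(state) {
  state$lora <- NULL
  state
}

#' Save / load a designer checkpoint
#'
#' Single-file versioned archive (RDS) holding the network, adapter, config
#' and history.
#'
#' @param state a `designer_state`.
#' @param path file path.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(list(format = "blochdesign-checkpoint", version = 1L,
               state = state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "blochdesign-checkpoint"))
    stop("not a blochdesign checkpoint: ", path)
  x$state
}

#' Write the per-epoch training log as CSV
#' @param state a `designer_state`.
#' @param path file path.
#' @export
write_history <- function(state, path) {
  write.csv(state$history, path, row.names = FALSE)
  invisible(path)
}
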