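#' Single hard-pulse rotation step
#'
#' Applies the exact rotation a magnetization vector undergoes during one
#' dwell under constant fields: `R = Rz(phi) Ry(beta) Rx(alpha) Ry(-beta)
#' Rz(-phi)` with `phi` the RF phase, `beta = atan2(db0, omega1)` and
#' `alpha = 2*pi*sqrt(omega1^2 + db0^2)*dwell`, `omega1 = gamma*|b1|` in Hz.
#' Implemented as the equivalent Rodrigues rotation with rotation vector
#' `-2*pi*dwell*(gamma*b1x, gamma*b1y, db0)` (precession convention:
#' a real positive pulse tips equilibrium magnetization toward +y).
#'
#' @param m length-3 magnetization vector.
#' @param b1x,b1y RF field components (uT).
#' @param db0 off-resonance (Hz).
#' @param dwell step duration (s).
#' @return the rotated length-3 vector; `|R m| = |m|` to machine precision.
#' @export
rotation_step <- function(m, b1x, b1y, db0, dwell) {
  vals <- c(m, b1x, b1y, db0, dwell)
  if (!all(is.finite(vals))) stop("non-finite input rejected in rotation_step")
  if (dwell <= 0) stop("dwell must be positive")
  v <- -2 * pi * dwell * c(GAMMA_HZ_PER_UT * b1x, GAMMA_HZ_PER_UT * b1y, db0)
  th <- sqrt(sum(v^2))
  if (th == 0) return(m)
  u <- v / th
  cross <- c(u[2] * m[3] - u[3] * m[2],
             u[3] * m[1] - u[1] * m[3],
             u[1] * m[2] - u[2] * m[1])
  cos(th) * m + sin(th) * cross + (1 - cos(th)) * sum(u * m) * u
}

#' System-imperfection maps consumed by the simulator
#'
#' @param db0 off-resonance map in Hz (one value per grid point), or NULL.
#' @param b1 dimensionless transmit-scale map, or NULL.
#' @param grid the grid the maps are defined on (for shape checking).
#' @export
system_maps <- function(db0 = NULL, b1 = NULL, grid = NULL) {
  if (!is.null(grid)) {
    if (!is.null(db0) && length(db0) != grid$npts)
      stop("B0 map does not match the grid")
    if (!is.null(b1) && length(b1) != grid$npts)
      stop("B1+ map does not match the grid")
  }
  if (!is.null(b1) && any(b1 < 0)) stop("B1+ scale map must be >= 0")
  structure(list(db0 = if (is.null(db0)) NULL else as.numeric(db0),
                 b1 = if (is.null(b1)) NULL else as.numeric(b1)),
            class = "system_maps")
}

#' Hard-pulse Bloch simulation over a spin grid
#'
#' Propagates every grid point through the pulse one dwell at a time with
#' exact rotations; relaxation is neglected (pulse durations are much shorter
#' than T1/T2). The per-step offset at point r is
#' `db0(t, r) = gamma_G * G(t).r + offset(r) + cs(r) + db0_map(r)` and the RF
#' is scaled per point by `c(r) * b1_map(r)`.
#'
#' @param rf an `rf_pulse`.
#' @param grad optional `grad_waveform` on the same raster.
#' @param grid a `spin_grid`.
#' @param init optional `mag_profile` starting state (default equilibrium).
#' @param maps optional `system_maps` (B0 in Hz, B1+ scale).
#' @param rephase extra free-precession time (s) appended after the pulse and
#'   applied to the static offsets only; negative values rewind (the `-T/2`
#'   refocusing of 1D frequency-selective designs).
#' @param keep_traj keep the per-step trajectory (consumed by the
#'   reverse-mode pass that differentiates a loss through the simulator).
#' @return a `mag_profile` (with attribute `traj` when `keep_traj = TRUE`).
#' @export
simulate_pulse <- function(rf, grad = NULL, grid, init = NULL, maps = NULL,
                           rephase = 0, keep_traj = FALSE) {
  if (grid$npts < 1L) stop("grid is empty")
  gmat <- NULL
  if (!is.null(grad)) {
    if (grad$n != rf$n)
      stop(sprintf("raster mismatch: RF has %d samples but gradient has %d",
                   rf$n, grad$n))
    gmat <- cbind(grad$g, matrix(0, grad$n, 3L - ncol(grad$g)))
  }
  if (is.null(init)) init <- equilibrium_profile(grid)
  offs <- grid$offset + grid$cs
  cvec <- grid$b1c
  db0map <- numeric(grid$npts)
  if (!is.null(maps)) {
    if (!is.null(maps$db0)) {
      if (length(maps$db0) != grid$npts) stop("B0 map does not match the grid")
      db0map <- maps$db0
    }
    if (!is.null(maps$b1)) {
      if (length(maps$b1) != grid$npts) stop("B1+ map does not match the grid")
      cvec <- cvec * maps$b1
    }
  }
  res <- .bloch_forward_cpp(rf$re, rf$im, gmat, grid$pos, offs, cvec, db0map,
                            init$M, rf$dwell, rephase,
                            GAMMA_HZ_PER_UT, GAMMA_HZ_PER_MTM_M, keep_traj)
  out <- mag_profile(res$M, grid)
  if (keep_traj) attr(out, "traj") <- res$traj
  out
}

# Reverse-mode gradient of a scalar loss through the simulator: given the
# trajectory from simulate_pulse(..., keep_traj = TRUE) and dL/dM at the
# final state, returns dL/d(re) and dL/d(im) per RF sample. Exact (adjoint
# rotations + analytic Rodrigues derivative), not finite differences.
simulate_pulse_grad <- function(rf, grad = NULL, grid, maps = NULL,
                                rephase = 0, traj, gM) {
  gmat <- NULL
  if (!is.null(grad)) gmat <- cbind(grad$g, matrix(0, grad$n, 3L - ncol(grad$g)))
  offs <- grid$offset + grid$cs
  cvec <- grid$b1c
  db0map <- numeric(grid$npts)
  if (!is.null(maps)) {
    if (!is.null(maps$db0)) db0map <- maps$db0
    if (!is.null(maps$b1)) cvec <- cvec * maps$b1
  }
  .bloch_backward_cpp(rf$re, rf$im, gmat, grid$pos, offs, cvec, db0map,
                      rf$dwell, rephase, GAMMA_HZ_PER_UT, GAMMA_HZ_PER_MTM_M,
                      traj, gM)
}

#' Adiabaticity factor along a pulse
#'
#' `K(t) = 2*pi*beff(t) / |dpsi/dt|`, where `beff` is the effective-field
#' magnitude in Hz and `psi(t) = atan2(db0(t), omega1(t))` is the orientation
#' angle of the effective field in its sweep plane. `K > 1` means the
#' magnetization can follow the effective field (the adiabatic condition).
#' Steps where the orientation does not change report `K = Inf`.
#'
#' @param rf an `rf_pulse` (its magnitude supplies `omega1`).
#' @param db0_trajectory the z-component of the effective field per sample,
#'   in Hz, in the frame of the diagnostic (for a frequency-modulated pulse
#'   evaluated on resonance this is minus its instantaneous frequency sweep).
#' @return list with `K` (per-sample, endpoints NA), and
#'   `violation_fraction`, the fraction of interior samples with `K <= 1`.
#' @export
adiabaticity_k <- function(rf, db0_trajectory) {
  n <- rf$n
  stopifnot(length(db0_trajectory) == n)
  amp <- sqrt(rf$re^2 + rf$im^2)
  if (all(amp == 0)) stop("adiabaticity is undefined for an all-zero pulse")
  w1 <- GAMMA_HZ_PER_UT * amp
  beff <- sqrt(w1^2 + db0_trajectory^2)
  psi <- atan2(db0_trajectory, w1)
  K <- rep(NA_real_, n)
  if (n >= 3L) {
    dpsi <- abs(psi[3:n] - psi[1:(n - 2)]) / (2 * rf$dwell)
    idx <- 2:(n - 1)
    K[idx] <- ifelse(dpsi == 0, Inf, 2 * pi * beff[idx] / dpsi)
  }
  interior <- K[!is.na(K)]
  list(K = K,
       violation_fraction = if (length(interior)) mean(interior <= 1) else 0)
}

#' Small-tip-angle excitation prediction (diagnostic oracle)
#'
#' Predicts the transverse profile from the excitation k-space integral: RF
#' energy deposited at `k(t) = -gamma * integral_t^T G(s) ds` Fourier-encodes
#' space, and static offsets accrue phase over the remaining pulse time. Valid
#' for flips up to ~20 degrees; used as an independent cross-check of the
#' Bloch simulator, never inside training.
#'
#' @inheritParams simulate_pulse
#' @return a `mag_profile` with the predicted transverse components
#'   (`mz = sqrt(1 - |mxy|^2)`).
#' @export
small_tip_prediction <- function(rf, grad = NULL, grid, rephase = 0) {
  n <- rf$n
  b1 <- complex(real = rf$re, imaginary = rf$im)
  # residual time from the end of sample j to the end of the pulse (+rephase)
  tau <- (n - seq_len(n)) * rf$dwell + rephase
  if (!is.null(grad)) {
    g <- cbind(grad$g, matrix(0, grad$n, 3L - ncol(grad$g)))
    # k_j = -gamma * dwell * sum_{s > j} G_s  (cycles/m)
    ksuf <- apply(g, 2L, function(col) rev(cumsum(rev(col))) - col)
    kmat <- -GAMMA_HZ_PER_MTM_M * rf$dwell * ksuf
    spatial_phase <- kmat %*% t(grid$pos)      # n x npts, cycles
  } else {
    spatial_phase <- matrix(0, n, grid$npts)
  }
  offs <- grid$offset + grid$cs
  phase <- 2 * pi * (spatial_phase - tau %o% offs)
  mxy <- (2i * pi * GAMMA_HZ_PER_UT * rf$dwell) *
    colSums(b1 * exp(1i * phase) * 1)
  mxy <- mxy * grid$b1c
  M <- cbind(Re(mxy), Im(mxy), sqrt(pmax(0, 1 - Mod(mxy)^2)))
  mag_profile(M, grid)
}
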