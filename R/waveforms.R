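#' Hyperbolic-secant (HS1) adiabatic inversion pulse
#'
#' Amplitude `b1max * sech(beta*tau)` and frequency sweep
#' `-(bandwidth/2) * tanh(beta*tau) / tanh(beta)` for `tau` running over
#' `[-1, 1]`; the phase is the cumulative integral of the sweep. The
#' truncation parameter defaults to `asech(0.01)` (amplitude 1% of peak at
#' the endpoints).
#'
#' @param duration pulse width (s).
#' @param bandwidth sweep bandwidth (Hz).
#' @param b1max peak amplitude (uT).
#' @param n number of samples (endpoint-inclusive raster), `>= 16`.
#' @param beta truncation parameter.
#' @return an `rf_pulse`; attribute `"sweep_hz"` holds the instantaneous
#'   frequency per sample (used by adiabaticity diagnostics).
#' @export
hs1 <- function(duration, bandwidth, b1max, n = 512,
                beta = acosh(1 / 0.01)) {
  if (n < 16L) stop("HS1 needs at least 16 samples")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  dwell <- duration / n
  tau <- seq(-1, 1, length.out = n)
  amp <- b1max / cosh(beta * tau)
  sweep <- -(bandwidth / 2) * tanh(beta * tau) / tanh(beta)
  phase <- 2 * pi * cumsum(sweep) * dwell
  phase <- phase - phase[(n + 1L) %/% 2L]   # zero phase at pulse centre
  rfp <- rf_pulse(amp * cos(phase), amp * sin(phase), dwell)
  attr(rfp, "sweep_hz") <- sweep
  rfp
}

#' Linear-phase windowed-sinc selective excitation pulse
#'
#' Hamming-windowed sinc of the requested time-bandwidth, scaled to the
#' requested on-resonance flip. This is the package's reference 1D selective
#' pulse: a plain linear-phase least-squares-flavoured design whose
#' Bloch-simulated profile serves as a realizable 1D design target
#' (conceptually the role a Shinnar-Le Roux pulse plays in scanner practice).
#'
#' @param duration pulse width (s).
#' @param tbw time-bandwidth product (excited bandwidth = `tbw / duration`).
#' @param flip flip angle (degrees).
#' @param n number of samples.
#' @return an `rf_pulse` (purely real).
#' @export
linear_phase_selective <- function(duration, tbw, flip, n) {
  dwell <- duration / n
  s <- windowed_sinc(n, tbw)
  s <- s / (2 * pi * GAMMA_HZ_PER_UT * dwell * sum(s)) * (flip * pi / 180)
  rf_pulse(s, dwell = dwell)
}

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

windowed_sinc <- function(n, tbw) {
  x <- seq(-tbw / 2, tbw / 2, length.out = n)
  s <- ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  s * hamming_window(n)
}

#' Specification for a conventional spectral-spatial (SPSP) pulse
#'
#' @param n_sub number of spatial sub-pulses.
#' @param sub_duration duration of one sub-pulse (s).
#' @param spatial_tbw time-bandwidth of the windowed-sinc spatial sub-pulse.
#' @param spectral_tbw time-bandwidth of the spectral envelope.
#' @param flip target flip angle (degrees) at slice centre / spectral centre.
#' @param spectral_center spectral excitation frequency (Hz).
#' @param dwell raster (s).
#' @param g_plateau slice-gradient plateau amplitude (mT/m).
#' @param gmax,smax hardware limits (mT/m, T/m/s).
#' @export
spsp_spec <- function(n_sub = 20, sub_duration = 1.19e-3, spatial_tbw = 6,
                      spectral_tbw = 3, flip = 45, spectral_center = 0,
                      dwell = 1e-5, g_plateau = 20, gmax = 24, smax = 120) {
  if (g_plateau > gmax) stop("g_plateau exceeds gmax")
  structure(list(n_sub = n_sub, sub_duration = sub_duration,
                 spatial_tbw = spatial_tbw, spectral_tbw = spectral_tbw,
                 flip = flip, spectral_center = spectral_center, dwell = dwell,
                 g_plateau = g_plateau, gmax = gmax, smax = smax),
            class = "spsp_spec")
}

#' Conventional spectral-spatial reference pulse and gradient
#'
#' Builds the standard design: an oscillating slice gradient (one
#' alternating-polarity trapezoidal lobe per sub-pulse, slew-limited ramps),
#' windowed-sinc spatial sub-pulses confined to the gradient plateaus, and a
#' sampled windowed-sinc spectral envelope modulating the sub-pulse
#' amplitudes, phase-ramped to centre the spectral passband at
#' `spectral_center`. The amplitude is calibrated by Bloch simulation so the
#' flip at (slice centre, spectral centre) equals `flip`. The RF is exactly
#' zero on the gradient ramps, the signature feature of the conventional
#' design.
#'
#' @param spec an [spsp_spec()].
#' @return list with `rf` (`rf_pulse`), `grad` (`grad_waveform`, 1 axis) and
#'   `ramp_mask` (logical, TRUE on ramp samples).
#' @export
spsp_reference <- function(spec) {
  ns <- round(spec$sub_duration / spec$dwell)
  if (abs(ns * spec$dwell - spec$sub_duration) > 1e-12)
    stop("sub_duration must be a multiple of the dwell")
  # slew-limited ramp samples to reach the plateau
  nr <- ceiling(spec$g_plateau / (spec$smax * 1000 * spec$dwell))
  np <- ns - 2L * nr
  if (np < 2L * spec$spatial_tbw)
    stop(sprintf(paste0("infeasible gradient: plateau of %d samples cannot ",
                        "support a time-bandwidth %g sub-pulse at gmax %g mT/m"),
                 np, spec$spatial_tbw, spec$gmax))
  lobe <- c(spec$g_plateau * seq_len(nr) / nr,
            rep(spec$g_plateau, np),
            spec$g_plateau * rev(seq_len(nr) - 1) / nr)
  ramp_sub <- c(rep(TRUE, nr), rep(FALSE, np), rep(TRUE, nr))
  polarity <- (-1)^(seq_len(spec$n_sub) - 1)
  g <- as.vector(vapply(polarity, function(s) s * lobe, numeric(ns)))
  ramp_mask <- rep(ramp_sub, spec$n_sub)

  sub <- windowed_sinc(np, spec$spatial_tbw)
  env <- windowed_sinc(spec$n_sub, spec$spectral_tbw)
  tc <- (seq_len(spec$n_sub) - 0.5) * spec$sub_duration  # sub-pulse centres
  envc <- env * exp(-2i * pi * spec$spectral_center * tc)
  b1 <- complex(real = numeric(length(g)))
  for (i in seq_len(spec$n_sub)) {
    idx <- (i - 1L) * ns + nr + seq_len(np)
    b1[idx] <- envc[i] * sub
  }

  grad <- gradient_waveform(g, spec$dwell, gmax = spec$gmax, smax = spec$smax)
  # calibrate amplitude so the flip at (z = 0, cs = spectral_center) matches
  probe <- spin_grid(matrix(0, 1, 3), cs = spec$spectral_center)
  target_rad <- spec$flip * pi / 180
  scale <- target_rad / (2 * pi * GAMMA_HZ_PER_UT * spec$dwell *
                           Mod(sum(b1 * exp(2i * pi * spec$spectral_center *
                                              (seq_along(b1) - 0.5) * spec$dwell))))
  for (it in 1:4) {
    rfp <- rf_pulse(scale * Re(b1), scale * Im(b1), spec$dwell)
    pf <- simulate_pulse(rfp, grad, probe)
    achieved <- atan2(sqrt(pf$M[1, 1]^2 + pf$M[1, 2]^2), pf$M[1, 3])
    scale <- scale * target_rad / achieved
  }
  rfp <- rf_pulse(scale * Re(b1), scale * Im(b1), spec$dwell)
  list(rf = rfp, grad = grad, ramp_mask = ramp_mask)
}

#' Specification for a variable-density spiral-in trajectory
#'
#' @param duration total duration (s).
#' @param turns number of revolutions.
#' @param fov excitation field of view (m); the outermost k-space radius is
#'   `turns / fov`.
#' @param density radial density exponent (radius grows as `angle^density`).
#' @param gmax,smax hardware limits (mT/m, T/m/s).
#' @param samples number of gradient samples.
#' @export
spiral_spec <- function(duration, turns, fov, density = 2, gmax = 24,
                        smax = 120, samples) {
  structure(list(duration = duration, turns = turns, fov = fov,
                 density = density, gmax = gmax, smax = smax,
                 samples = samples, dwell = duration / samples),
            class = "spiral_spec")
}

#' Variable-density spiral-in excitation gradient
#'
#' Generates the k-space path `k(u) = kmax * u^density * exp(i*2*pi*turns*u)`
#' (spiral-out form), time-parameterises it under the slew and amplitude
#' limits (slower where the path curves harder), reverses it so the
#' trajectory terminates exactly at k = 0, and differentiates to gradients.
#' Errors if the requested duration cannot satisfy the limits.
#'
#' @param spec a [spiral_spec()].
#' @return a two-axis `grad_waveform`; attribute `"ktraj"` holds the
#'   `(samples+1) x 2` k-space path in cycles/m (last row is the origin).
#' @export
vd_spiral_in <- function(spec) {
  kmax <- spec$turns / spec$fov
  p <- spec$density
  nd <- max(4000L, 20L * spec$samples)
  u <- seq(1e-4, 1, length.out = nd)
  rho <- kmax * u^p
  phi <- 2 * pi * spec$turns * u
  kx <- rho * cos(phi); ky <- rho * sin(phi)
  # derivatives wrt u
  drho <- kmax * p * u^(p - 1); dphi <- 2 * pi * spec$turns
  dkx <- drho * cos(phi) - rho * dphi * sin(phi)
  dky <- drho * sin(phi) + rho * dphi * cos(phi)
  d2rho <- kmax * p * (p - 1) * u^(p - 2)
  d2kx <- d2rho * cos(phi) - 2 * drho * dphi * sin(phi) - rho * dphi^2 * cos(phi)
  d2ky <- d2rho * sin(phi) + 2 * drho * dphi * cos(phi) - rho * dphi^2 * sin(phi)
  speed_u <- sqrt(dkx^2 + dky^2)
  curv <- abs(dkx * d2ky - dky * d2kx) / pmax(speed_u, 1e-12)^3
  vmax <- 0.95 * GAMMA_HZ_PER_T * spec$gmax * 1e-3          # (1/m)/s
  amax <- 0.85 * GAMMA_HZ_PER_T * spec$smax                 # (1/m)/s^2
  vlim <- pmin(vmax, sqrt(amax / pmax(curv, 1e-12)))
  # minimal traversal time of each dense segment at the local speed limit
  ds <- speed_u * c(diff(u)[1], diff(u))
  tmin <- cumsum(ds / vlim)
  if (tmin[nd] > spec$duration)
    stop(sprintf(paste0("infeasible spiral: %g turns over %g ms need at least ",
                        "%.3g ms under gmax %g mT/m / smax %g T/m/s"),
                 spec$turns, spec$duration * 1e3, tmin[nd] * 1e3,
                 spec$gmax, spec$smax))
  tmap <- tmin * spec$duration / tmin[nd]    # uniform slow-down to fill T
  tj <- seq_len(spec$samples) * spec$dwell
  uj <- approx(tmap, u, xout = tj, rule = 2)$y
  kout <- cbind(kmax * uj^p * cos(2 * pi * spec$turns * uj),
                kmax * uj^p * sin(2 * pi * spec$turns * uj))
  kout <- rbind(c(0, 0), kout)               # path points 0..samples
  kin <- kout[rev(seq_len(nrow(kout))), , drop = FALSE]  # spiral-in, ends at 0
  g <- diff(kin) / (GAMMA_HZ_PER_MTM_M * spec$dwell)
  gw <- gradient_waveform(g, spec$dwell, gmax = spec$gmax, smax = spec$smax)
  attr(gw, "ktraj") <- kin
  # angular span of the generated geometric path, in revolutions (the
  # innermost fraction of a turn is traversed within the first dwell)
  attr(gw, "revolutions") <- spec$turns * (1 - u[1])
  attr(gw, "spec") <- spec
  gw
}

#' Prepend zero-net-area ramps to a gradient
#'
#' Inserts, per axis, a slew-limited ramp from zero up to the first gradient
#' sample preceded by a compensating lobe of opposite sign, so the summed
#' zeroth moment of the prepended span is zero (to better than 1e-12 of full
#' scale). Any RF paired with the prepended span is zero, so callers simply
#' left-pad their pulse.
#'
#' @param gw a `grad_waveform` with finite `smax`.
#' @return a `grad_waveform`; attribute `"n_prepended"` gives the number of
#'   samples added.
#' @export
prepend_balanced_ramp <- function(gw) {
  if (!is.finite(gw$smax)) stop("smax must be set to design ramps")
  dg <- gw$smax * 1000 * gw$dwell          # max per-sample step, mT/m
  segs <- lapply(seq_len(ncol(gw$g)), function(a) {
    g0 <- gw$g[1L, a]
    if (g0 == 0) return(numeric(0))
    nr <- ceiling(abs(g0) / dg)
    ramp <- g0 * seq_len(nr) / nr
    area <- sum(ramp)                      # in mT/m * samples
    # minimal slew-limited triangular lobe with |area| >= |area(ramp)|
    nt <- 1L
    lobe_area <- function(nt) {
      peak <- min(nt * dg, gw$gmax, na.rm = TRUE)
      up <- pmin(seq_len(nt) * dg, peak)
      sum(up) + sum(rev(up)[-1])
    }
    while (lobe_area(nt) < abs(area)) nt <- nt + 1L
    peak <- min(nt * dg, gw$gmax, na.rm = TRUE)
    up <- pmin(seq_len(nt) * dg, peak)
    lobe <- c(up, rev(up)[-1]) * (-sign(area))
    lobe <- lobe * abs(area) / abs(sum(lobe))   # exact discrete cancellation
    c(lobe, 0, ramp)                            # 0 keeps the junction slew-safe
  })
  nadd <- max(vapply(segs, length, integer(1)), 0L)
  if (nadd == 0L) {
    attr(gw, "n_prepended") <- 0L
    return(gw)
  }
  pre <- vapply(segs, function(s) c(numeric(nadd - length(s)), s),
                numeric(nadd))
  pre <- matrix(pre, nrow = nadd)
  out <- gradient_waveform(rbind(pre, gw$g), gw$dwell,
                           gmax = gw$gmax, smax = gw$smax)
  attr(out, "n_prepended") <- nadd
  out
}
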