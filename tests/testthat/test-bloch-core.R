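gam <- gyromagnetic_ratio("Hz/uT")

test_that("rotation_step handles the canonical single-step cases", {
  # zero field: identity
  expect_equal(rotation_step(c(0, 0, 1), 0, 0, 0, 1e-5), c(0, 0, 1))
  # amplitude giving a pi rotation about x inverts z
  dw <- 1e-3
  b1 <- 0.5 / (gam * dw)
  expect_equal(rotation_step(c(0, 0, 1), b1, 0, 0, dw), c(0, 0, -1),
               tolerance = 1e-12)
  # pure off-resonance: transverse vector precesses by exactly 2*pi*db0*dwell
  m <- rotation_step(c(1, 0, 0), 0, 0, 250, dw)
  expect_equal(m[3], 0)
  ang <- atan2(m[2], m[1])
  expect_equal(abs(ang), 2 * pi * 250 * dw, tolerance = 1e-12)
  # same step composed from an explicit 3x3 z-rotation (brute-force oracle)
  expect_equal(m, as.numeric(rot_z(ang) %*% c(1, 0, 0)), tolerance = 1e-12)
  # stated convention: a real pulse of small flip a maps z-hat to (0, sin a, cos a)
  a <- 0.3
  b1a <- a / (2 * pi * gam * dw)
  expect_equal(rotation_step(c(0, 0, 1), b1a, 0, 0, dw),
               c(0, sin(a), cos(a)), tolerance = 1e-12)
  expect_error(rotation_step(c(0, 0, NaN), 0, 0, 0, 1e-5), "non-finite")
  expect_error(rotation_step(c(0, 0, 1), 0, 0, 0, -1), "positive")
})

test_that("simulation preserves equilibrium, norm, composition and phase covariance", {
  set.seed(101)
  grid <- spin_grid(matrix(rnorm(12 * 3, sd = 0.05), 12, 3),
                    offset = runif(12, -4000, 4000),
                    b1c = runif(12, 0.5, 1.5))
  # zero RF leaves every point at equilibrium
  z <- simulate_pulse(rf_pulse(numeric(20), dwell = 1e-5), grid = grid)
  expect_equal(z$M, unname(cbind(0, 0, rep(1, 12))), ignore_attr = TRUE)

  for (k in 1:5) {
    n <- sample(16:64, 1)
    rf <- rf_pulse(runif(n, -15, 15), runif(n, -15, 15), 1e-5)
    pf <- simulate_pulse(rf, grid = grid)
    # norm conservation
    expect_lt(max(abs(sqrt(rowSums(pf$M^2)) - 1)), 1e-9)
    # composition: simulating the two halves sequentially is exact
    h <- n %/% 2
    rf1 <- rf_pulse(rf$re[1:h], rf$im[1:h], 1e-5)
    rf2 <- rf_pulse(rf$re[(h + 1):n], rf$im[(h + 1):n], 1e-5)
    p1 <- simulate_pulse(rf1, grid = grid)
    p12 <- simulate_pulse(rf2, grid = grid, init = p1)
    expect_identical(p12$M, pf$M)
    # phase covariance: a constant unit phase on the RF rotates the
    # transverse output by the same phase and leaves mz unchanged
    phi <- runif(1, -pi, pi)
    w <- complex(real = rf$re, imaginary = rf$im) * exp(1i * phi)
    pr <- simulate_pulse(rf_pulse(w, dwell = 1e-5), grid = grid)
    mxy <- complex(real = pf$M[, 1], imaginary = pf$M[, 2]) * exp(1i * phi)
    expect_lt(max(abs(pr$M[, 1] - Re(mxy))), 1e-9)
    expect_lt(max(abs(pr$M[, 2] - Im(mxy))), 1e-9)
    expect_lt(max(abs(pr$M[, 3] - pf$M[, 3])), 1e-9)
  }
})

test_that("hard-pulse propagation matches adaptive ODE integration", {
  set.seed(7)
  err <- 0
  for (k in 1:12) {
    n <- sample(8:48, 1)
    rf <- rf_pulse(runif(n, -20, 20), runif(n, -20, 20), 1e-5)
    offs <- runif(1, -5000, 5000)
    cs <- runif(1, 0.6, 1.4)
    mo <- ode_bloch(rf, offs, cs)
    ms <- simulate_pulse(rf, grid = spin_grid(matrix(0, 1, 3), offset = offs,
                                              b1c = cs))$M[1, ]
    err <- max(err, max(abs(mo - ms)))
  }
  expect_lt(err, 1e-4)
})

test_that("constant on-resonance pulses produce the closed-form flip angle", {
  n <- 100; dw <- 1e-5
  for (flip in c(pi / 6, pi / 2, pi)) {
    amp <- flip / (2 * pi * gam * n * dw)
    M <- simulate_pulse(rf_pulse(rep(amp, n), dwell = dw),
                        grid = spin_grid(matrix(0, 1, 3)))$M
    expect_equal(sqrt(M[1, 1]^2 + M[1, 2]^2), abs(sin(flip)), tolerance = 1e-9)
    expect_equal(M[1, 3], cos(flip), tolerance = 1e-9)
  }
})

test_that("reverse-mode RF gradients match central finite differences", {
  set.seed(42)
  n <- 12; npts <- 5; dw <- 1e-5
  rf <- rf_pulse(rnorm(n, sd = 5), rnorm(n, sd = 5), dw)
  grid <- spin_grid(matrix(rnorm(npts * 3, sd = 0.05), npts, 3),
                    offset = runif(npts, -3000, 3000),
                    b1c = runif(npts, 0.7, 1.3))
  grad <- gradient_waveform(cbind(rnorm(n, sd = 5), rnorm(n, sd = 5)), dw)
  tgt <- matrix(rnorm(npts * 3), npts, 3)
  lossfn <- function(re, im) {
    M <- simulate_pulse(rf_pulse(re, im, dw), grad, grid, rephase = -6e-5)$M
    sum((M - tgt)^2)
  }
  sim <- simulate_pulse(rf, grad, grid, rephase = -6e-5, keep_traj = TRUE)
  bk <- blochdesign:::simulate_pulse_grad(rf, grad, grid, rephase = -6e-5,
                                          traj = attr(sim, "traj"),
                                          gM = 2 * (sim$M - tgt))
  h <- 1e-6
  for (j in c(1, 5, n)) {
    rp <- rf$re; rp[j] <- rp[j] + h; rm <- rf$re; rm[j] <- rm[j] - h
    fd <- (lossfn(rp, rf$im) - lossfn(rm, rf$im)) / (2 * h)
    expect_lt(abs(bk$g_re[j] - fd) / max(abs(fd), 1e-8), 1e-4)
    ip <- rf$im; ip[j] <- ip[j] + h; im2 <- rf$im; im2[j] <- im2[j] - h
    fdi <- (lossfn(rf$re, ip) - lossfn(rf$re, im2)) / (2 * h)
    expect_lt(abs(bk$g_im[j] - fdi) / max(abs(fdi), 1e-8), 1e-4)
  }
})

test_that("simulate rejects inconsistent inputs with informative errors", {
  rf <- rf_pulse(rep(1, 10), dwell = 1e-5)
  grad <- gradient_waveform(matrix(0, 8, 1), 1e-5)
  grid <- grid_freq(4, 1000)
  expect_error(simulate_pulse(rf, grad, grid), "10.*8|raster")
  expect_error(spin_grid(matrix(0, 0, 3)), "empty")
  expect_error(rf_pulse(c(1, Inf), dwell = 1e-5), "non-finite")
})

test_that("adiabaticity factor flags sweep-rate violations", {
  # constant on-resonance pulse: orientation never changes
  rect <- rf_pulse(rep(10, 64), dwell = 1e-4)
  ak <- adiabaticity_k(rect, numeric(64))
  expect_true(all(is.infinite(ak$K[2:63])))
  expect_equal(ak$violation_fraction, 0)
  # HS1 at nominal amplitude satisfies K > 1 throughout
  h <- hs1(8e-3, 2000, 23.5, n = 512)
  ak <- adiabaticity_k(h, -attr(h, "sweep_hz"))
  expect_true(all(ak$K[!is.na(ak$K)] > 1))
  expect_equal(ak$violation_fraction, 0)
  # scaling the amplitude down 100x breaks the adiabatic condition
  hl <- hs1(8e-3, 2000, 0.235, n = 512)
  expect_gt(adiabaticity_k(hl, -attr(hl, "sweep_hz"))$violation_fraction, 0)
  expect_error(adiabaticity_k(rf_pulse(numeric(16), dwell = 1e-5), numeric(16)),
               "all-zero")
})

test_that("small-tip prediction agrees with full simulation at 15 degrees", {
  # trivial cases
  grid <- grid_freq(16, 2000)
  z <- small_tip_prediction(rf_pulse(numeric(10), dwell = 1e-5), grid = grid)
  expect_equal(z$M[, 1:2], matrix(0, 16, 2), ignore_attr = TRUE)
  # single RF sample at the trajectory end deposits at k = 0: uniform |mxy|
  g2 <- grid_spatial_2d(8, 8, 0.2)
  gw <- gradient_waveform(matrix(runif(20 * 2, -5, 5), 20, 2), 1e-5)
  rf1 <- rf_pulse(c(numeric(19), 2), dwell = 1e-5)
  stp <- small_tip_prediction(rf1, gw, g2)
  mag <- sqrt(stp$M[, 1]^2 + stp$M[, 2]^2)
  expect_lt(diff(range(mag)), 1e-12)
  # 2D spiral excitation at 15 degrees: Fourier prediction vs Bloch
  fov <- 0.24
  grid2 <- grid_spatial_2d(16, 16, fov)
  gsp <- vd_spiral_in(spiral_spec(3e-3, 6, fov, density = 1.25,
                                  gmax = 24, smax = 120, samples = 300))
  set.seed(5)
  # smooth low-pass RF so the excitation stays in the small-tip regime
  env <- exp(-((1:300) - 150)^2 / (2 * 60^2))
  rf2 <- rf_pulse(0.5 * env, 0.2 * env, dwell = 1e-5)
  pred <- small_tip_prediction(rf2, gsp, grid2)
  full <- simulate_pulse(rf2, gsp, grid2)
  dxy <- sqrt(rowSums((pred$M[, 1:2] - full$M[, 1:2])^2))
  expect_lt(max(flip_deg(full$M)), 25)  # regime guard
  expect_lt(mean(dxy), 0.02)
})

test_that("pulse and gradient text files round-trip to 12 significant digits", {
  set.seed(3)
  rf <- rf_pulse(rnorm(33, sd = 12), rnorm(33, sd = 12), 1.7e-5)
  f <- tempfile(fileext = ".txt")
  write_pulse(rf, f)
  rf2 <- read_pulse(f)
  expect_equal(rf2$re, rf$re, tolerance = 1e-11)
  expect_equal(rf2$im, rf$im, tolerance = 1e-11)
  expect_equal(rf2$dwell, rf$dwell, tolerance = 1e-11)
  gw <- gradient_waveform(matrix(rnorm(40, sd = 8), 20, 2), 1e-5,
                          gmax = 30, smax = 2000)
  fg <- tempfile(fileext = ".txt")
  write_gradient(gw, fg)
  gw2 <- read_gradient(fg)
  expect_equal(gw2$g, gw$g, tolerance = 1e-11)
  expect_equal(gw2$gmax, 30)
  # malformed file reports the offending line
  writeLines(c("# dwell_s=1e-5", "# units=uT", "1 2", "oops"), f)
  expect_error(read_pulse(f), "line 4")
})
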