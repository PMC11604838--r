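test_that("HS1 modulation functions follow the stated closed forms", {
  n <- 257  # odd: a sample sits exactly at the centre
  h <- hs1(8e-3, 2000, 23.5, n = n)
  amp <- sqrt(h$re^2 + h$im^2)
  expect_equal(amp[(n + 1) / 2], 23.5)                 # sech(0) = 1
  expect_equal(amp[1] / 23.5, 0.01, tolerance = 1e-10) # 1% truncation
  expect_equal(amp[n] / 23.5, 0.01, tolerance = 1e-10)
  # amplitude symmetric, sweep antisymmetric about the centre
  expect_lt(max(abs(amp - rev(amp))), 1e-12)
  sw <- attr(h, "sweep_hz")
  expect_lt(max(abs(sw + rev(sw))), 1e-12)
  expect_equal(max(abs(sw)), 1000, tolerance = 1e-10)  # bandwidth/2 at the ends
  expect_equal(pulse_duration(h), 8e-3)
  expect_error(hs1(8e-3, -5, 23.5), "positive")
})

test_that("HS1 inversion is B1-insensitive beyond its adiabatic threshold", {
  grid <- grid_freq(65, 3000)
  inband <- abs(grid$offset) <= 700
  mz_in <- vapply(c(9.4, 18.8, 23.5, 28.2, 47), function(b1) {
    mean(simulate_pulse(hs1(8e-3, 2000, b1, n = 256), grid = grid)$M[inband, 3])
  }, numeric(1))
  # below threshold: incomplete inversion; at/above 18.8 uT: deep plateau
  expect_gt(mz_in[1], -0.6)
  expect_true(all(mz_in[-1] < -0.95))
  expect_lt(max(abs(diff(mz_in[-1]))), 0.01)  # flat plateau
})

test_that("conventional SPSP construction meets its stated structure", {
  spec <- spsp_spec()  # 20 x 1.19 ms, spatial TBW 6, spectral TBW 3, 45 deg
  ref <- spsp_reference(spec)
  expect_equal(pulse_duration(ref$rf), 23.8e-3)
  # RF exactly zero on every gradient ramp
  amp <- sqrt(ref$rf$re^2 + ref$rf$im^2)
  expect_true(all(amp[ref$ramp_mask] == 0))
  expect_gt(max(amp[!ref$ramp_mask]), 0)
  # flip at (slice centre, spectral centre) equals sin(45 deg) within 2%
  probe <- spin_grid(matrix(0, 1, 3))
  M <- simulate_pulse(ref$rf, ref$grad, probe)$M
  expect_equal(sqrt(M[1, 1]^2 + M[1, 2]^2), sin(pi / 4), tolerance = 0.02)
  # spectral stopband: halfway to the first envelope replica
  # (replica spacing = 1/sub_duration = 840 Hz)
  null_cs <- 0.5 / spec$sub_duration
  pn <- spin_grid(matrix(0, 1, 3), cs = null_cs)
  Mn <- simulate_pulse(ref$rf, ref$grad, pn)$M
  expect_lt(sqrt(Mn[1, 1]^2 + Mn[1, 2]^2), 0.05)
  # infeasible plateau is rejected with the violated bound named
  expect_error(spsp_reference(spsp_spec(sub_duration = 0.4e-3, g_plateau = 24)),
               "plateau")
})

test_that("variable-density spiral-in honours its geometric contract", {
  sp <- spiral_spec(duration = 11.66e-3, turns = 24, fov = 0.24,
                    density = 2, gmax = 24, smax = 120, samples = 1166)
  gw <- vd_spiral_in(sp)
  k <- attr(gw, "ktraj")
  expect_equal(nrow(k), 1167)
  expect_equal(k[nrow(k), ], c(0, 0))                       # terminates at k = 0
  expect_equal(sqrt(sum(k[1, ]^2)), 24 / 0.24, tolerance = 1e-6)
  expect_equal(round(attr(gw, "revolutions")), 24)
  # hardware bounds on the emitted samples
  expect_lt(max(abs(gw$g)), 24)
  expect_lt(max(abs(diff(gw$g))) / gw$dwell / 1000, 120)
  # an infeasible duration is refused
  expect_error(vd_spiral_in(spiral_spec(0.5e-3, 24, 0.24, samples = 50)),
               "infeasible")
})

test_that("balanced pre-ramps cancel their zeroth moment exactly", {
  # zero gradient: unchanged
  gz <- gradient_waveform(matrix(0, 10, 2), 1e-5, gmax = 24, smax = 120)
  expect_identical(prepend_balanced_ramp(gz)$g, gz$g)
  # generic waveform: prepended area integrates to zero per axis
  set.seed(9)
  g <- matrix(cumsum(rnorm(30, sd = 0.3)), ncol = 1)
  g <- g / max(abs(g)) * 10
  gw <- gradient_waveform(g, 1e-5, gmax = 24, smax = 1200)
  out <- prepend_balanced_ramp(gw)
  nadd <- attr(out, "n_prepended")
  expect_gt(nadd, 0)
  pre_area <- sum(out$g[seq_len(nadd), 1])
  expect_lt(abs(pre_area) / max(abs(g)), 1e-12)
  # the joined waveform still meets the slew bound
  expect_lt(max(abs(diff(out$g))) / out$dwell / 1000, out$smax * (1 + 1e-9))
  # step-start at gmax: minimal slew-limited balanced ramp (closed form)
  dw <- 1e-5; gmax <- 24; smax <- 120
  gs <- gradient_waveform(matrix(gmax, 20, 1), dw, gmax = gmax, smax = smax)
  outs <- prepend_balanced_ramp(gs)
  dg <- smax * 1000 * dw                       # max step per sample, mT/m
  nr <- ceiling(gmax / dg)                     # rise samples to gmax
  area <- sum(gmax * seq_len(nr) / nr)
  # minimal triangular lobe (peak capped at gmax) with enough area
  nt <- 1
  lobe_area <- function(nt) {
    up <- pmin(seq_len(nt) * dg, gmax)
    sum(up) + sum(rev(up)[-1])
  }
  while (lobe_area(nt) < area) nt <- nt + 1
  expect_equal(attr(outs, "n_prepended"), (2 * nt - 1) + 1 + nr)
})
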