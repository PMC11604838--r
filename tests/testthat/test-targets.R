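test_that("rectangle targets encode the band geometry exactly", {
  grid <- grid_freq(2048, 32768)
  # zero flip: equilibrium everywhere
  t0 <- rect_target(1289, 0, grid)
  expect_equal(t0$profile$M, unname(cbind(0, 0, rep(1, 2048))),
               ignore_attr = TRUE)
  # 90 degrees: (0, 1, 0) in band, equilibrium far out of band
  t90 <- rect_target(1289, 90, grid, transition = 400)
  f <- grid$offset
  expect_true(all(abs(t90$profile$M[abs(f) <= 1289, 2] - 1) < 1e-12))
  expect_true(all(t90$profile$M[abs(f) >= 1689, 3] == 1))
  # in-band point count is fixed by the grid alignment
  expect_true(sum(abs(f) <= 1289) %in% c(80L, 81L))
  # every target vector stays on the unit sphere (raised-cosine acts on flip)
  expect_lt(max(abs(sqrt(rowSums(t90$profile$M^2)) - 1)), 1e-12)
  expect_equal(t90$d, 2048L)
  expect_error(rect_target(40000, 90, grid), "wider than the grid")
})

test_that("reference-simulated targets reproduce the reference profile", {
  grid <- grid_freq(256, 8192)
  # zero reference pulse: equilibrium target
  z <- target_from_reference(rf_pulse(numeric(32), dwell = 1e-4), NULL, grid)
  expect_equal(z$profile$M[, 3], rep(1, 256))
  # HS1 reference at 23.5 uT: deep inversion across the 2 kHz band centre
  h <- hs1(8e-3, 2000, 23.5, n = 128)
  th <- target_from_reference(h, NULL, grid, mode = "b1_sweep")
  centre <- abs(grid$offset) <= 700
  expect_true(all(th$profile$M[centre, 3] <= -0.95))
  expect_equal(th$d, 256L)
  # input channel for inversion-type targets is mz
  expect_equal(th$input_channel, th$profile$M[, 3])
})

test_that("sweep targets stack per-amplitude reference profiles", {
  grid <- grid_freq(128, 8192)
  ref <- hs1(8e-3, 2000, b1max = 1, n = 64)
  base <- target_from_reference(ref, NULL, grid, mode = "b1_sweep")
  # the canonical 20-step amplitude sweep is an arithmetic progression
  sweep20 <- 2.35 * (1:20)
  expect_equal(sweep20[1], 2.35)
  expect_equal(sweep20[20], 47)
  st <- sweep_target(base, sweep20)
  expect_equal(st$d, 128L * 20L)
  expect_equal(st$dims, c(128L, 20L))
  expect_equal(st$mode, "b1_sweep")
  # each block is the reference profile at that B1max
  b5 <- simulate_pulse(pulse_scale_to_peak(ref, sweep20[5]), NULL, grid)$M
  expect_equal(st$profile$M[(4 * 128 + 1):(5 * 128), ], b5)
  # grid transmit scale carries the sweep amplitudes
  expect_equal(st$profile$grid$b1c[1:128], rep(2.35, 128))
  # single-element sweep at the reference's own peak reproduces the base
  ref235 <- pulse_scale_to_peak(ref, 23.5)
  base235 <- target_from_reference(ref235, NULL, grid, mode = "b1_sweep")
  s1 <- sweep_target(base235, 23.5)
  expect_equal(s1$profile$M[1:128, ], base235$profile$M)
  expect_error(sweep_target(base, numeric(0)), "empty")
})

test_that("2D mask targets flatten row-major with the stated flip", {
  grid <- grid_spatial_2d(64, 64, 0.24)
  m0 <- mask2d_target(matrix(0, 64, 64), 15, grid)
  expect_equal(m0$profile$M[, 3], rep(1, 4096))
  mask <- glyph_mask_ai(64, 64)
  mt <- mask2d_target(mask, 15, grid)
  expect_equal(mt$d, 4096L)
  inm <- as.logical(as.vector(t(mask)))
  expect_true(all(abs(mt$profile$M[inm, 3] - cos(15 * pi / 180)) < 1e-12))
  expect_true(all(abs(mt$profile$M[inm, 2] - sin(15 * pi / 180)) < 1e-12))
  expect_error(mask2d_target(matrix(0, 32, 32), 15, grid), "32 x 32")
  expect_error(mask2d_target(matrix(0.5, 64, 64), 15, grid), "binary")
})

test_that("spectral-spatial targets select the stated spatial/spectral cell", {
  grid <- grid_spsp(192, 96)
  st <- spsp_target(5e-3, 440, 45, grid)
  expect_equal(st$d, 192L * 96L)
  # excited cell: |transverse| = sin(45 deg)
  z <- grid$pos[, 1]; cs <- grid$cs
  exc <- abs(z) <= 2.5e-3 & abs(cs - 440) <= 220
  expect_true(any(exc))
  txy <- sqrt(st$profile$M[, 1]^2 + st$profile$M[, 2]^2)
  expect_true(all(abs(txy[exc] - sin(pi / 4)) < 1e-12))
  # the 440 Hz target leaves water (0 Hz) at equilibrium in-slice
  water <- abs(z) <= 2.5e-3 & abs(cs) <= 100
  expect_true(all(st$profile$M[water, 3] == 1))
  expect_error(spsp_target(5e-3, 5000, 45, grid), "outside")
})

test_that("input channels are lossless reshapes of the recorded dimension", {
  grid <- grid_freq(512, 8192)
  tg <- rect_target(1289, 90, grid)
  expect_equal(length(tg$input_channel), tg$d)
  tall <- rect_target(1289, 90, grid, input = "all")
  expect_equal(tall$d, 3L * 512L)
  expect_equal(matrix(tall$input_channel, ncol = 3), tall$profile$M,
               ignore_attr = TRUE)
  # norm bound holds for every target type
  for (t in list(tg, tall)) {
    expect_true(all(sqrt(rowSums(t$profile$M^2)) <= 1 + 1e-6))
  }
})
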