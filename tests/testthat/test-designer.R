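test_that("the design network follows the halving layer scheme", {
  net <- build_mlp(2048, 256, seed = 1)
  dims <- vapply(net$real, function(l) nrow(l$W), integer(1))
  expect_equal(dims, c(1024L, 512L, 256L, 2560L))
  expect_equal(vapply(net$real, function(l) ncol(l$W), integer(1)),
               c(2048L, 1024L, 512L, 256L))
  # closed-form per-branch parameter count
  expect_equal(mlp_branch_params(net),
               2048 * 1024 + 1024 * 512 + 512 * 256 + 256 * 2560 +
                 (1024 + 512 + 256 + 2560))
  # determinism
  net2 <- build_mlp(2048, 256, seed = 1)
  expect_identical(net$real[[1]]$W, net2$real[[1]]$W)
  expect_identical(net$imag[[4]]$W, net2$imag[[4]]$W)
  # the two branches are independently initialised
  expect_false(identical(net$real[[1]]$W, net$imag[[1]]$W))
  expect_error(build_mlp(2048, 3000), "2560")
})

test_that("forward_design emits finite pulses with the stated normalization", {
  grid <- grid_freq(128, 8192)
  tg <- rect_target(1289, 90, grid)
  net <- build_mlp(tg$d, 64, seed = 3)
  rf <- forward_design(net, tg, dwell = 2e-5)
  expect_s3_class(rf, "rf_pulse")
  expect_equal(rf$n, 64L)
  expect_true(all(is.finite(c(rf$re, rf$im))))
  # a freshly initialised network produces a low-amplitude noise-like pulse
  expect_lt(pulse_peak(rf), 5)
  # sweep mode: unit peak magnitude by construction
  ref <- hs1(8e-3, 2000, 1, n = 64)
  base <- target_from_reference(ref, NULL, grid, mode = "b1_sweep")
  sw <- sweep_target(base, c(10, 20))
  netsw <- build_mlp(sw$d, 64, seed = 3)
  rfsw <- forward_design(netsw, sw, dwell = 62.5e-6)
  expect_equal(pulse_peak(rfsw), 1, tolerance = 1e-12)
  expect_true(attr(rfsw, "normalized"))
  expect_error(forward_design(net, sw, dwell = 2e-5), "dimension")
})

test_that("the self-supervised loss is the stated mean squared mismatch", {
  grid <- grid_freq(32, 4000)
  tg <- rect_target(1000, 90, grid)
  M <- tg$profile$M
  expect_equal(loss_offline(M, tg), 0)
  # mz +1 vs -1 everywhere, mz-only comparison: (2)^2 = 4 at every entry
  a <- cbind(0, 0, rep(1, 32)); b <- cbind(0, 0, rep(-1, 32))
  expect_equal(loss_offline(a, b, compare = "mz"), 4)
  # small perturbation: loss equals mean(eps^2) by direct arithmetic
  set.seed(8)
  eps <- matrix(rnorm(32 * 3, sd = 1e-3), 32, 3)
  expect_equal(loss_offline(M + eps, tg), mean(eps^2), tolerance = 1e-12)
  # peak regularizer adds a smooth upper bound on max |B1|
  rf <- rf_pulse(c(1, 5, 2), dwell = 1e-5)
  l0 <- loss_offline(M, tg)
  lr <- loss_offline(M, tg, pulse = rf, reg_lambda = 0.01, reg_tau = 2)
  expect_gte(lr - l0, 0.01 * 5)  # surrogate >= true peak
})

test_that("EDM behaves as a similarity score on 3-vector profiles", {
  grid <- grid_freq(16, 1000)
  a <- equilibrium_profile(grid)
  expect_equal(edm(a, a), 1)
  b <- mag_profile(cbind(0, 0, rep(-1, 16)), grid)
  expect_equal(edm(a, b), -1)
  expect_error(edm(a$M, matrix(0, 8, 3)), "different grids")
})

test_that("an equilibrium target drives the design to a silent pulse", {
  grid <- grid_freq(64, 8192)
  tg <- rect_target(1600, 0, grid)     # flip 0: nothing to excite
  physics <- physics_for_target(tg, dwell = 8e-5, rephase = -32 * 8e-5 / 2)
  cfg <- design_config(t = 32, dwell = 8e-5, seed = 5, max_epochs = 250)
  st <- design_pulse(tg, physics, cfg)
  expect_gt(st$edm, 0.9995)
  expect_lt(pulse_peak(st$pulse), 0.1)
})

test_that("designs are reproducible and loss/EDM histories anticorrelate", {
  prob <- tiny_rect_problem(max_epochs = 400L)
  s1 <- design_pulse(prob$target, prob$physics, prob$cfg)
  s2 <- design_pulse(prob$target, prob$physics, prob$cfg)
  expect_identical(s1$pulse$re, s2$pulse$re)
  expect_identical(s1$pulse$im, s2$pulse$im)
  expect_identical(s1$history, s2$history)
  # training improves the profile match as the loss decreases
  expect_lt(cor(s1$history$loss, s1$history$edm), 0)
  expect_gt(s1$edm, 0.95)
  # history is monotone in epoch and the final pulse has the design length
  expect_equal(s1$history$epoch, seq_len(nrow(s1$history)))
  expect_equal(s1$pulse$n, prob$cfg$t)
})

test_that("LoRA adaptation starts from the offline pulse and improves under maps", {
  prob <- tiny_rect_problem()
  st <- design_pulse(prob$target, prob$physics, prob$cfg)
  grid <- prob$target$profile$grid
  # identity maps: the zero-initialised adapter reproduces the offline pulse
  idm <- system_maps(db0 = numeric(grid$npts), b1 = rep(1, grid$npts))
  cfg0 <- st$cfg; cfg0$max_adapt_epochs <- 1L
  ad0 <- adapt_pulse(st, idm, cfg0)
  expect_equal(ad0$edm_before, st$edm, tolerance = 1e-12)
  # non-identity maps corrupt the profile; adaptation recovers it
  maps <- system_maps(db0 = synth_b0_map(grid, 60, seed = 3),
                      b1 = synth_b1_map(grid, 1, 0.2, seed = 3))
  cfga <- st$cfg; cfga$max_adapt_epochs <- 60L; cfga$adapt_threshold <- 0.995
  ad <- adapt_pulse(st, maps, cfga)
  expect_lt(ad$edm_before, st$edm)       # maps visibly corrupt the profile
  expect_gt(ad$edm, ad$edm_before)       # adaptation improves it
  # stripping the adapter restores the offline pulse exactly
  stripped <- strip_lora(ad)
  rf0 <- forward_design(stripped$net, prob$target, prob$cfg$dwell)
  expect_identical(rf0$re, st$pulse$re)
  expect_identical(rf0$im, st$pulse$im)
})

test_that("peak regularization exploits gradient ramps to lower B1max", {
  # scaled spectral-spatial problem with the ramps inside the design raster
  spec <- spsp_spec(n_sub = 6, sub_duration = 0.6e-3, spatial_tbw = 4,
                    spectral_tbw = 2, flip = 30, dwell = 2e-5, g_plateau = 18)
  ref <- spsp_reference(spec)
  grid <- grid_spsp(48, 16, fmax = 15e3, csmax = 900, gref = spec$g_plateau)
  target <- target_from_reference(ref$rf, ref$grad, grid, mode = "spsp")
  t <- ref$rf$n
  run <- function(lambda) {
    cfg <- design_config(t = t, dwell = spec$dwell, seed = 2,
                         max_epochs = 250, reg_lambda = lambda, reg_tau = 2)
    design_pulse(target, physics_for_target(target, grad = ref$grad,
                                            dwell = spec$dwell), cfg)
  }
  plain <- run(0)
  reg <- run(2e-4)
  ramp <- ref$ramp_mask
  amp_reg <- sqrt(reg$pulse$re^2 + reg$pulse$im^2)
  # unlike the conventional design, the learned pulse is active on the ramps
  expect_gt(max(amp_reg[ramp]), 0.02)
  # and the regularized design trades that freedom for a lower peak
  expect_lt(pulse_peak(reg$pulse), pulse_peak(plain$pulse))
  # while still exciting a comparable profile
  expect_gt(reg$edm, 0.9)
})
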