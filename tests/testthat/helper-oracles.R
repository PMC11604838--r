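# Independent oracles used across the suite.

# Adaptive-step integration of the rotating-frame Bloch equations with
# T1 = T2 = Inf: dM/dt = 2*pi * M x B, B = (gamma*c*b1x, gamma*c*b1y, db0) Hz.
# Integrates each dwell separately (the fields are piecewise constant).
ode_bloch <- function(rf, offs, c_scale = 1, m0 = c(0, 0, 1),
                      rtol = 1e-10, atol = 1e-12) {
  gam <- gyromagnetic_ratio("Hz/uT")
  m <- m0
  deriv <- function(t, y, B) {
    list(2 * pi * c(y[2] * B[3] - y[3] * B[2],
                    y[3] * B[1] - y[1] * B[3],
                    y[1] * B[2] - y[2] * B[1]))
  }
  for (j in seq_len(rf$n)) {
    B <- c(gam * c_scale * rf$re[j], gam * c_scale * rf$im[j], offs)
    sol <- deSolve::ode(m, c(0, rf$dwell), deriv, B, rtol = rtol, atol = atol)
    m <- as.numeric(sol[2, 2:4])
  }
  m
}

# 3x3 rotation matrices composed explicitly (right-handed, about fixed axes)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)

# flip angle (deg) of magnetization vectors
flip_deg <- function(M) atan2(sqrt(M[, 1]^2 + M[, 2]^2), M[, 3]) * 180 / pi

# deterministic tiny design problem used by several designer tests
tiny_rect_problem <- function(n = 64L, t = 32L, seed = 11L, flip = 90,
                              max_epochs = 400L) {
  grid <- grid_freq(n, 8192)
  target <- rect_target(1600, flip, grid, transition = 2 / (t * 8e-5))
  physics <- physics_for_target(target, dwell = 8e-5, rephase = -t * 8e-5 / 2)
  cfg <- design_config(t = t, dwell = 8e-5, seed = seed,
                       max_epochs = max_epochs)
  list(target = target, physics = physics, cfg = cfg)
}
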