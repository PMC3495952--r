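test_that("double-stance acceleration: pinned value and both EOM forms agree", {
  p <- tbl1()
  Tpk <- ankle_spring_torque(p$psi0, p)
  # hand evaluation at double-stance onset: (m g L sin(alpha) + T * (-4)) / (m L^2)
  expect_equal(accel_double_stance(p$alpha, p),
               (p$m * p$g * p$L * sin(p$alpha) - 4 * Tpk) / (p$m * p$L^2))
  expect_equal(accel_double_stance(p$alpha, p), -1.768, tolerance = 1e-3)
  # unactuated upright equilibrium of the reduced form
  expect_equal(accel_double_stance(0.2, p, torque = 0),
               p$g / p$L * sin(0.2) * 1) # gravity term only
  # Newton-Euler form equals the generalized-force form on a dense grid
  th <- seq(double_stance_end_angle(p), p$alpha, length.out = 101)
  lk <- ankle_angle(th, p)
  for (Tq in list(ankle_spring_torque(lk$psi, p), rep(50, length(th)))) {
    FA <- grf_trailing(th, p, Tq)
    ne <- (p$g * sin(th) - FA / p$m * cos(th - lk$phi)) / p$L
    gf <- accel_double_stance(th, p, Tq)
    expect_equal(gf, ne, tolerance = 1e-9)
    # two-force-member identity used by the reduced EOM
    expect_equal(FA * cos(th - lk$phi) / p$L, -Tq * lk$dpsi_dtheta / p$L^2,
                 tolerance = 1e-9)
  }
})

test_that("single-stance acceleration is the inverted pendulum", {
  p <- tbl1()
  expect_identical(accel_single_stance(0, p), 0)
  expect_equal(accel_single_stance(-p$alpha, p), 9.81 * sin(-pi / 6))
  expect_equal(accel_single_stance(-p$alpha, p), -4.905)
})

test_that("collision map scales speed by cos(2 alpha) exactly", {
  p <- tbl1()
  cm <- collision_map(-1.84410, p)
  expect_identical(cm$theta, p$alpha)
  expect_equal(cm$theta_dot, -0.92205) # cos(pi/3) = 1/2 algebraically
  expect_identical(collision_map(0, p)$theta_dot, 0)
  # rolling limit: no loss as alpha -> 0
  p0 <- walker_params(alpha = 1e-6, l = 1e-7, mu = pi / 2)
  expect_equal(collision_map(-1, p0)$theta_dot, -1, tolerance = 1e-10)
  # kinetic-energy ratio is cos^2(2 alpha) to machine precision
  expect_equal((cm$theta_dot / -1.84410)^2, cos(2 * p$alpha)^2)
})

test_that("ground reaction forces match pinned values and limits", {
  p <- tbl1()
  Tpk <- ankle_spring_torque(p$psi0, p)
  expect_equal(grf_trailing(p$alpha, p, Tpk), 706.2, tolerance = 1e-3)
  expect_identical(grf_trailing(p$alpha, p, 0), 0)
  # leading heel at the period-one double-stance onset
  td0 <- fixed_point(p)$theta_dot_star
  expect_equal(grf_leading(p$alpha, td0, p, Tpk), 149.5, tolerance = 2e-3)
  # static stand and centrifugal fly-off sign
  expect_equal(grf_leading(0, 0, p, 0), p$m * p$g)
  expect_lt(grf_leading(p$alpha, -10, p, Tpk), 0)
  # single stance: rest, pre-collision state, and the fly-off threshold
  expect_equal(grf_single_stance(0, 0, p), 784.8)
  v_C <- fixed_point(p)$v_C
  expect_equal(grf_single_stance(-p$alpha, -v_C / p$L, p), 407.6, tolerance = 1e-3)
  v_fly <- sqrt(p$g * p$L * cos(p$alpha))
  expect_equal(v_fly, 2.9149, tolerance = 1e-4)
  expect_equal(grf_single_stance(-p$alpha, v_fly / p$L, p), 0, tolerance = 1e-9)
})

test_that("a period-one step reproduces the printed period and GRF minimum", {
  p <- tbl1()
  w <- simulate_step(p)
  expect_equal(w$termination, "COMPLETED")
  s <- w$steps
  expect_equal(s$duration, 0.967, tolerance = 2.5e-3)
  expect_equal(s$min_grf_leading, 149.5, tolerance = 2e-3)
  expect_gt(s$min_grf_single_stance, 0)
  # minimum of the leading-heel force occurs at double-stance onset
  tr <- w$trajectory
  ds <- tr[tr$phase == "double_stance" & !is.na(tr$F_B), ]
  expect_equal(ds$F_B[which.min(ds$F_B)], ds$F_B[1])
  # fixed point maps to itself
  expect_equal(s$theta_dot_post, s$theta_dot_start, tolerance = 1e-8)
  # trajectory bookkeeping: monotone time, work only in double stance
  expect_true(all(diff(tr$t) >= 0))
  expect_true(all(tr$torque_spring[tr$phase == "single_stance"] == 0))
})

test_that("the compiled integrator agrees with an independent ODE solver", {
  p <- tbl1()
  for (td0 in c(fixed_point(p)$theta_dot_star, -1.2)) {
    ours <- simulate_step(p, td0, record = FALSE)$steps
    ref <- lsodar_step_oracle(p, td0)
    expect_equal(ours$duration, ref$duration, tolerance = 1e-7)
    expect_equal(ours$double_stance_duration, ref$toe_off, tolerance = 1e-7)
    expect_equal(ours$theta_dot_post, ref$theta_dot_post, tolerance = 1e-7)
  }
})

test_that("energy audit residuals vanish at tolerance on every step", {
  p <- tbl1()
  w <- simulate_walk(p, -1.2, n_steps = 8)
  expect_equal(w$termination, "COMPLETED")
  au <- energy_audit(w)
  expect_true(all(abs(au$residual_ds) < 1e-6))
  expect_true(all(abs(au$residual_ss) < 1e-6))
  expect_true(all(au$residual_collision == 0)) # algebraic map
  # spring work per step is the closed-form cocked-spring energy
  expect_equal(au$work_in, rep(0.5 * p$k * (p$mu - p$psi0)^2, 8),
               tolerance = 1e-9)
  expect_equal(au$work_in[1], 102.0, tolerance = 1e-3)
})

test_that("walk-level behavior: convergence, determinism, degenerate starts", {
  p <- tbl1()
  # all GRFs positive along the period-one gait
  w0 <- simulate_walk(p, n_steps = 5)
  expect_true(all(w0$steps$min_grf_leading > 0))
  expect_true(all(w0$steps$min_grf_single_stance > 0))
  expect_equal(max(w0$steps$duration) - min(w0$steps$duration), 0,
               tolerance = 1e-6)
  # below critical stiffness the walk falls back
  plow <- walker_params(k = 60)
  wl <- simulate_walk(plow, fixed_point(plow)$theta_dot_star, n_steps = 50)
  expect_equal(wl$termination, "FALL_BACK")
  # degenerate start terminates immediately as a fall-back
  wd <- simulate_walk(p, 0, n_steps = 2)
  expect_equal(wd$termination, "FALL_BACK")
  expect_equal(nrow(wd$steps), 0)
  # identical inputs give identical outputs (no hidden state)
  w1 <- simulate_walk(p, -1.1, n_steps = 4)
  w2 <- simulate_walk(p, -1.1, n_steps = 4)
  expect_identical(w1$steps, w2$steps)
})

test_that("results are robust to integrator settings", {
  p <- tbl1()
  d0 <- simulate_step(p, record = FALSE)$steps$duration
  tighter <- walker_numerics(rtol = 1e-12, atol = 1e-12)
  d1 <- simulate_step(p, numerics = tighter, record = FALSE)$steps$duration
  expect_equal(d0, d1, tolerance = 1e-8)
  fixed <- walker_numerics(fixed_step = 1e-4)
  d2 <- simulate_step(p, numerics = fixed, record = FALSE)$steps$duration
  expect_equal(d0, d2, tolerance = 1e-6)
})
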