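test_that("pulse gating: active window, swing nullification, leg parity", {
  p <- tbl1()
  A <- default_pulse_amplitude(p)
  expect_equal(A, 0.1 * p$k * (p$mu - p$psi0))
  expect_equal(A, 13.35, tolerance = 1e-3)
  pl <- pulse_train(A, width = 0.1, period = 2, offset = 0.5, leg = "A")
  # active window [offset + n*period, + width)
  expect_equal(pulse_torque(c(0.55, 2.55), "double_stance", "A", pl), c(A, A))
  expect_equal(pulse_torque(c(0.45, 0.61, 1.3), "double_stance", "A", pl),
               c(0, 0, 0))
  # nullified in swing and on the other leg's double stance
  expect_equal(pulse_torque(0.55, "single_stance", "A", pl), 0)
  expect_equal(pulse_torque(0.55, "double_stance", "B", pl), 0)
  expect_error(pulse_train(-1, period = 2), "amplitude")
  expect_error(pulse_train(1, width = 3, period = 2))
})

test_that("zero-amplitude pulse reproduces the unperturbed limit cycle exactly", {
  p <- tbl1()
  pl <- pulse_train(0, width = 0.1, period = 1.9, offset = 0.3)
  wp <- simulate_walk(p, n_steps = 10, pulse = pl)
  w0 <- simulate_walk(p, n_steps = 10)
  expect_equal(wp$steps$duration, w0$steps$duration, tolerance = 1e-12)
  expect_true(all(wp$steps$pulse_work == 0))
})

test_that("a pulse 50 ms faster than the stride entrains from any offset", {
  p <- tbl1()
  A <- default_pulse_amplitude(p)
  tau_p <- 1.8841
  locked <- vapply((0:3) / 4 * tau_p, function(d) {
    sim <- simulate_perturbed(p, pulse_train(A, 0.1, period = tau_p, offset = d),
                              n_strides = 300)
    expect_true(sim$entrained)
    expect_equal(sim$final_mean_stride_period, tau_p, tolerance = 1e-4)
    sim$locked_phase
  }, numeric(1))
  # the locked phase is a global attractor: identical across initial offsets,
  # slightly before toe-off (the pulse ends near spring release)
  expect_lt(diff(range(locked)), 0.01)
  expect_lt(mean(locked), 0)
  expect_gt(mean(locked), -0.15)
})

test_that("detuning outside the basin does not entrain", {
  p <- tbl1()
  A <- default_pulse_amplitude(p)
  tau_0 <- simulate_step(p, record = FALSE)$steps$duration
  for (det in c(0.05, -0.1)) { # slower than the gait, and 100 ms faster
    sim <- simulate_perturbed(
      p, pulse_train(A, 0.1, period = 2 * tau_0 + det, offset = 0.3),
      n_strides = 300)
    expect_false(sim$entrained)
  }
  # the pulse can only accelerate: no entrainment for any tau_p > 2 tau_0,
  # and stride periods never exceed the unperturbed stride
  for (det in c(0.02, 0.06)) {
    sim <- simulate_perturbed(
      p, pulse_train(A, 0.1, period = 2 * tau_0 + det, offset = 0),
      n_strides = 120)
    expect_false(sim$entrained)
    expect_lt(max(sim$strides$stride_period), 2 * tau_0 + 1e-6)
  }
})

test_that("locked phase drifts monotonically when not entrained", {
  p <- tbl1()
  A <- default_pulse_amplitude(p)
  tau_0 <- simulate_step(p, record = FALSE)$steps$duration
  tau_p <- 2 * tau_0 + 0.05
  sim <- simulate_perturbed(p, pulse_train(A, 0.1, period = tau_p, offset = 0),
                            n_strides = 80)
  ph <- phase_series(sim)
  # unwrap and check steady drift close to the detuning per stride
  d <- diff(ph)
  d <- d - round(d) # remove wrap jumps
  expect_gt(mean(d), 0.8 * 0.05 / tau_p)
  expect_lt(stats::sd(d), 0.02)
})

test_that("pulse work per stride is non-negative and geometrically bounded", {
  p <- tbl1()
  A <- default_pulse_amplitude(p)
  for (gat in c("truncate", "extend")) {
    sim <- simulate_perturbed(
      p, pulse_train(A, 0.1, period = 1.8841, offset = 0.7, gating = gat),
      n_strides = 60)
    expect_true(all(sim$strides$pulse_work >= 0))
    expect_true(all(sim$strides$pulse_work <= A * (pi - p$psi0) + 1e-9))
  }
})

test_that("entrainment detector on synthetic stride series", {
  tau_p <- 1.9
  mk <- function(periods, phases) {
    tibble::tibble(stride_index = seq_along(periods), stride_period = periods,
                   toe_off_time = cumsum(periods), pulse_onset_time = 0,
                   locked_phase = phases, pulse_work = 0,
                   capped = FALSE, extended = FALSE)
  }
  good <- mk(rep(tau_p, 40), rep(-0.03, 40))
  expect_true(detect_entrainment(good, tau_p))
  wobble <- mk(tau_p + rep(c(0.01, -0.01), 20), rep(-0.03, 40))
  expect_false(detect_entrainment(wobble, tau_p))
  sliding <- mk(rep(tau_p, 40), seq(0, 0.39, by = 0.01))
  expect_false(detect_entrainment(sliding, tau_p))
  expect_error(detect_entrainment(good[1:10, ], tau_p), "at least")
})

test_that("speed-vs-phase curve: bounds, extremes and terminal slope", {
  p <- tbl1()
  cv <- speed_vs_phase(p, n_phases = 120)
  v0 <- attr(cv, "v0")
  ds <- attr(cv, "ds_fraction")
  wf <- attr(cv, "width_fraction")
  expect_equal(v0, 1.03, tolerance = 5e-3)
  # a pulse never slows the gait; wholly-in-swing pulses leave it untouched
  expect_true(all(cv$speed >= v0 - 1e-9))
  swing <- cv$phase > ds & cv$phase < 1 - wf
  expect_equal(cv$speed[swing], rep(v0, sum(swing)), tolerance = 1e-9)
  expect_true(all(cv$pulse_work[swing] == 0))
  # maximum with the pulse wholly inside double stance
  expect_lt(cv$phase[which.max(cv$speed)], ds)
  # negative slope on the terminal double-stance branch
  terminal <- which(cv$phase > ds - wf & cv$phase <= ds)
  expect_true(all(diff(cv$speed[terminal]) < 0))
  # overall range is narrow: bounded energy per pulse
  expect_lt((max(cv$speed) - min(cv$speed)) / min(cv$speed), 0.09)
})

test_that("secondary basin is far narrower than the terminal branch", {
  p <- tbl1()
  cv <- speed_vs_phase(p, n_phases = 200)
  early <- secondary_basin_width(cv)
  term <- secondary_basin_width(cv, region = "terminal")
  expect_lt(early$width_pct, 0.2)
  expect_gt(term$width_pct, 10 * early$width_pct)
  # terminal branch width is commensurate with the measured basin (~3.9%)
  expect_gt(term$width_pct, 2)
  expect_lt(term$width_pct, 6)
})
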