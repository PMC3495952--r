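#' Periodic square torque pulse train
#'
#' A periodic square plantar-flexion torque pulse applied to one ankle:
#' active at absolute time `t` iff `((t - offset) mod period) < width`.
#' The pulse contributes to the dynamics only while its leg is the trailing
#' leg in double stance; a pulse arriving while its ankle is in swing does
#' no work (massless legs).
#'
#' Two gating policies resolve what happens when the pulse is still active
#' as the ankle angle reaches the spring-release angle `mu`:
#' * `"truncate"` (`TRUNCATE_AT_MU`, the default): double stance always
#'   ends at `psi = mu`; the rest of the pulse is nullified.
#' * `"extend"` (`EXTEND_WHILE_POSITIVE`): the trailing foot keeps pushing
#'   while the total ankle torque (then just the pulse amplitude) is
#'   positive, so double stance continues until the pulse switches off or
#'   the linkage approaches its singular configuration
#'   `psi = pi - eps_cap`, whichever comes first (the cap forces toe-off
#'   and flags the step).
#'
#' Truncation is the default because the four-bar linkage makes extension
#' degenerate: past `psi = mu` the moment-arm ratio `dpsi/dtheta` grows
#' without bound, so any extension runs away to the linkage cap and injects
#' a near-fixed, large work quantum; see the methods vignette for the
#' behavioral consequences of each policy.
#'
#' @param amplitude pulse amplitude \[N·m\] (>= 0; plantar direction only).
#'   See [default_pulse_amplitude()] for the standard 10%-of-peak-torque
#'   choice.
#' @param width pulse width \[s\] (default 0.1 s).
#' @param period pulse period `tau_p` \[s\].
#' @param offset initial phase `delta` \[s\], in `[0, period)`.
#' @param leg perturbed leg, `"A"` or `"B"`.
#' @param gating `"extend"` or `"truncate"` (see above).
#' @param eps_cap linkage-cap margin \[rad\] for the extension policy.
#' @return an object of class `pulse_train`.
#' @export
pulse_train <- function(amplitude, width = 0.1, period, offset = 0,
                        leg = c("A", "B"),
                        gating = c("truncate", "extend"), eps_cap = 0.01) {
  leg <- match.arg(leg)
  gating <- match.arg(gating)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1, amplitude >= 0,
            is.numeric(width), width > 0, is.numeric(period), period > width,
            is.numeric(offset), offset >= 0)
  structure(list(amplitude = amplitude, width = width, period = period,
                 offset = offset, leg = if (leg == "A") 0L else 1L,
                 leg_label = leg, gating = gating, eps_cap = eps_cap),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> A = %g N·m, width = %g s, period = %g s, offset = %g s\n",
              x$amplitude, x$width, x$period, x$offset))
  cat(sprintf("  leg %s, gating %s\n", x$leg_label, x$gating))
  invisible(x)
}

#' Standard pulse amplitude: a fraction of peak ankle torque
#'
#' The standard perturbation amplitude is 10% of the model's maximal ankle
#' torque `k*(mu - psi0)` (about 13.3 N·m with default parameters),
#' mirroring the torque pulses applied at the human ankle relative to peak
#' plantar-flexion torque in walking.
#'
#' @param params a [walker_params()] object.
#' @param fraction fraction of the peak spring torque.
#' @return amplitude \[N·m\].
#' @export
default_pulse_amplitude <- function(params, fraction = 0.1) {
  params <- as_walker_params(params)
  fraction * params$k * (params$mu - params$psi0)
}

#' Instantaneous gated pulse torque
#'
#' The torque the pulse train contributes at absolute time `t` given the
#' walker's phase and trailing-leg parity: the amplitude if the train is
#' active at `t`, the walker is in double stance, and the perturbed leg is
#' trailing; zero otherwise (in particular, a pulse to an ankle in swing is
#' nullified). The resolution of a pulse still active at spring release is
#' the gating policy of the train (see [pulse_train()]); this accessor
#' reports the gate for a given instantaneous state.
#'
#' @param t absolute time(s) \[s\].
#' @param phase `"double_stance"` or `"single_stance"` (recycled).
#' @param trailing_leg `"A"` or `"B"` (recycled).
#' @param pulse a [pulse_train()].
#' @return torque(s) \[N·m\], vectorized over `t`.
#' @export
pulse_torque <- function(t, phase, trailing_leg, pulse) {
  stopifnot(inherits(pulse, "pulse_train"))
  r <- (t - pulse$offset) %% pulse$period
  active <- r < pulse$width
  gate <- (phase == "double_stance") & (trailing_leg == pulse$leg_label)
  ifelse(active & gate, pulse$amplitude, 0)
}

wrap_half <- function(d, period) d - period * round(d / period)

strides_from_walk <- function(walk, pulse) {
  s <- walk$steps
  leg <- pulse$leg_label
  idx <- which(s$trailing_leg == leg)
  # a stride spans a perturbed step and the following step
  idx <- idx[idx + 1 <= nrow(s)]
  if (!length(idx)) return(tibble::tibble())
  period <- s$heel_strike_time[idx + 1] - s$t_start[idx]
  toe <- s$toe_off_time[idx]
  jj <- round((toe - pulse$offset) / pulse$period)
  onset <- pulse$offset + jj * pulse$period
  d <- wrap_half(onset - toe, pulse$period)
  tibble::tibble(
    stride_index = seq_along(idx),
    stride_period = period,
    toe_off_time = toe,
    pulse_onset_time = onset,
    locked_phase = d / period,
    pulse_work = s$pulse_work[idx] + s$pulse_work[idx + 1],
    capped = s$capped[idx] | s$capped[idx + 1],
    extended = s$extended[idx]
  )
}

#' Walk under a periodic torque pulse train
#'
#' Simulates `n_strides` strides (two steps each) starting on the
#' unperturbed period-one limit cycle at the double-stance onset of the
#' perturbed leg, with the pulse train superimposed on the trailing-ankle
#' spring torque, and evaluates the entrainment criterion.
#'
#' @param params a [walker_params()] object.
#' @param pulse a [pulse_train()].
#' @param n_strides number of strides to simulate (default 300).
#' @param theta_dot0 initial post-collision angular velocity; defaults to
#'   the unperturbed fixed point.
#' @param numerics a [walker_numerics()] object.
#' @param window,period_tol,phase_range_tol entrainment criterion, passed
#'   to [detect_entrainment()].
#' @return An object of class `entrainment_sim`: list with `strides`
#'   (tibble: `stride_index`, `stride_period`, `toe_off_time`,
#'   `pulse_onset_time`, `locked_phase` in \[-0.5, 0.5), `pulse_work`,
#'   gating flags), `entrained`, `final_mean_stride_period`,
#'   `locked_phase` (mean over the criterion window; `NA` if not
#'   entrained), `termination`, and the inputs.
#' @export
simulate_perturbed <- function(params, pulse, n_strides = 300,
                               theta_dot0 = NULL,
                               numerics = walker_numerics(),
                               window = 30, period_tol = 1e-3,
                               phase_range_tol = 0.01) {
  params <- as_walker_params(params)
  stopifnot(inherits(pulse, "pulse_train"))
  walk <- simulate_walk(params, theta_dot0, n_steps = 2 * n_strides,
                        pulse = pulse, numerics = numerics, record = FALSE,
                        t0 = 0, trailing_leg = pulse$leg_label)
  strides <- strides_from_walk(walk, pulse)
  entrained <- FALSE
  locked <- NA_real_
  final_mean <- NA_real_
  if (nrow(strides) >= window) {
    tail_idx <- seq(nrow(strides) - window + 1, nrow(strides))
    entrained <- detect_entrainment(strides, pulse$period, window = window,
                                    period_tol = period_tol,
                                    phase_range_tol = phase_range_tol)
    final_mean <- mean(strides$stride_period[tail_idx])
    if (entrained) locked <- mean(strides$locked_phase[tail_idx])
  }
  structure(list(strides = strides, entrained = entrained,
                 final_mean_stride_period = final_mean,
                 locked_phase = locked,
                 termination = walk$termination,
                 params = params, pulse = pulse, n_strides = n_strides),
            class = "entrainment_sim")
}

#' @export
print.entrainment_sim <- function(x, ...) {
  cat(sprintf("<entrainment_sim> tau_p = %g s, %d stride(s), %s\n",
              x$pulse$period, nrow(x$strides),
              if (x$entrained) "ENTRAINED" else "not entrained"))
  if (x$entrained) {
    cat(sprintf("  locked phase (re toe-off) = %.4f, final mean stride period = %.6f s\n",
                x$locked_phase, x$final_mean_stride_period))
  } else if (is.finite(x$final_mean_stride_period)) {
    cat(sprintf("  final mean stride period = %.6f s (target %.6f s)\n",
                x$final_mean_stride_period, x$pulse$period))
  }
  if (x$termination != "COMPLETED") cat("  termination:", x$termination, "\n")
  invisible(x)
}

#' Entrainment criterion on a stride series
#'
#' The gait counts as entrained to the pulse period `tau_p` when, over the
#' final `window` strides, every stride period is within `period_tol` of
#' `tau_p` and the locked phase varies by at most `phase_range_tol`
#' (a converged, phase-locked tail rather than a coincidental period
#' match).
#'
#' @param strides stride tibble (from an `entrainment_sim` or
#'   [simulate_perturbed()]).
#' @param tau_p pulse period \[s\].
#' @param window number of final strides inspected (default 30).
#' @param period_tol stride-period tolerance \[s\] (default 1 ms).
#' @param phase_range_tol maximal range of the locked phase over the window.
#' @return logical.
#' @export
detect_entrainment <- function(strides, tau_p, window = 30,
                               period_tol = 1e-3, phase_range_tol = 0.01) {
  if (inherits(strides, "entrainment_sim")) strides <- strides$strides
  if (nrow(strides) < window) {
    stop("detect_entrainment: need at least ", window, " strides, got ",
         nrow(strides), call. = FALSE)
  }
  tail_idx <- seq(nrow(strides) - window + 1, nrow(strides))
  periods <- strides$stride_period[tail_idx]
  phases <- strides$locked_phase[tail_idx]
  all(abs(periods - tau_p) <= period_tol) &&
    (diff(range(phases)) <= phase_range_tol)
}

#' Locked-phase series of a perturbed walk
#'
#' Per-stride phase difference between the pulse onset nearest the
#' perturbed leg's toe-off and that toe-off, as a fraction of the stride
#' period, wrapped to \[-0.5, 0.5). For entrained gaits the series
#' converges to a constant slightly below zero: the pulse ends at toe-off,
#' so its onset sits about one pulse width before toe-off.
#'
#' @param x an `entrainment_sim` or its stride tibble.
#' @return numeric vector of locked phases.
#' @export
phase_series <- function(x) {
  if (inherits(x, "entrainment_sim")) x <- x$strides
  x$locked_phase
}

#' Average speed versus pulse phase (single-probe curve)
#'
#' Starting on the unperturbed limit cycle, applies exactly one pulse with
#' onset at a prescribed phase of the stride (phase 0 = double-stance onset
#' of the perturbed leg; the stride is `2*tau_0` long) and reports the
#' average speed of the gait cycle containing the pulse's effective
#' portion. A pulse wholly inside the perturbed leg's swing phase leaves
#' the gait untouched (minimum, unperturbed speed); a pulse wholly inside
#' double stance maximizes the speed; the curve slopes down as the onset
#' approaches the end of double stance, the branch that stabilizes phase
#' locking, and has a much shallower negative-slope branch early in double
#' stance.
#'
#' `per` selects the averaging window. `"stride"` (default) uses the
#' perturbed stride — stride length over the duration of the perturbed
#' step plus its successor — which is the period the entrainment analysis
#' operates on (the pulse recurs once per stride) and accounts for the
#' work carried across the collision into the stride's second step.
#' `"step"` uses only the perturbed step.
#'
#' @param params a [walker_params()] object.
#' @param amplitude pulse amplitude \[N·m\]; default 10% of peak torque.
#' @param width pulse width \[s\].
#' @param n_phases grid size over one full stride of onset phases.
#' @param gating gating policy for the probe (default `"truncate"`; see
#'   [pulse_train()]).
#' @param per averaging window, `"stride"` (default) or `"step"`.
#' @param numerics a [walker_numerics()] object.
#' @return A tibble of class `speed_phase_curve`: `phase` (onset phase in
#'   \[0, 1)), `onset_time` \[s\], `speed` \[m/s\], `pulse_work` \[J\],
#'   with attributes `v0` (unperturbed speed), `tau_0`, `ds_fraction`
#'   (toe-off phase of the stride) and `width_fraction`.
#' @export
speed_vs_phase <- function(params, amplitude = NULL, width = 0.1,
                           n_phases = 200,
                           gating = c("truncate", "extend"),
                           per = c("stride", "step"),
                           numerics = walker_numerics()) {
  params <- as_walker_params(params)
  gating <- match.arg(gating)
  per <- match.arg(per)
  if (is.null(amplitude)) amplitude <- default_pulse_amplitude(params)
  base <- simulate_walk(params, n_steps = 1, numerics = numerics)
  stopifnot(base$termination == "COMPLETED")
  tau_0 <- base$steps$duration[1]
  tau_ds <- base$steps$double_stance_duration[1]
  step_len <- 2 * params$L * sin(params$alpha)
  v0 <- step_len / tau_0
  stride <- 2 * tau_0
  phases <- seq(0, 1, length.out = n_phases + 1)[seq_len(n_phases)]
  speed <- numeric(n_phases)
  work <- numeric(n_phases)
  for (i in seq_along(phases)) {
    onset <- phases[i] * stride
    pl <- pulse_train(amplitude, width, period = 1e6, offset = onset,
                      leg = "A", gating = gating)
    w <- simulate_walk(params, n_steps = 5, pulse = pl, numerics = numerics,
                       record = FALSE, trailing_leg = "A")
    hit <- which(w$steps$pulse_work > 1e-9)
    if (length(hit)) {
      hit <- hit[1] # the effective portion lies in a single double stance
      work[i] <- sum(w$steps$pulse_work)
      speed[i] <- if (per == "stride") {
        2 * step_len / sum(w$steps$duration[hit + 0:1])
      } else {
        step_len / w$steps$duration[hit]
      }
    } else {
      speed[i] <- v0
    }
  }
  out <- tibble::tibble(phase = phases, onset_time = phases * stride,
                        speed = speed, pulse_work = work)
  attr(out, "v0") <- v0
  attr(out, "tau_0") <- tau_0
  attr(out, "ds_fraction") <- tau_ds / stride
  attr(out, "width_fraction") <- width / stride
  attr(out, "step_length") <- step_len
  class(out) <- c("speed_phase_curve", class(out))
  out
}

# Maximal strictly-decreasing run of the curve restricted to a phase window.
decreasing_runs <- function(phase, speed, tol) {
  dec <- diff(speed) < -tol
  if (!any(dec)) return(NULL)
  r <- rle(dec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values] + 1)
  runs$span <- speed[runs$start] - speed[runs$end]
  runs
}

#' Width of the secondary (early-double-stance) basin of entrainment
#'
#' The speed-versus-phase curve can have a shallow negative-slope branch
#' early in double stance, in addition to the terminal branch at the end of
#' double stance that governs phase locking. Each negative-slope branch
#' admits entrainment over the stride periods it spans: converting its
#' speed span to periods via `period = stride length / speed` gives the
#' basin width attributable to that branch. This function isolates the
#' early branch (onset phases at which the whole pulse still fits inside
#' double stance, excluding the terminal roll-off) and returns its width as
#' a percentage of the unperturbed stride period `2*tau_0`; zero if no such
#' branch exists.
#'
#' @param curve a `speed_phase_curve` from [speed_vs_phase()].
#' @param region `"early"` (default) or `"terminal"`, the latter processing
#'   the end-of-double-stance branch identically (cross-check against the
#'   full basin).
#' @param tol minimal speed decrement \[m/s\] distinguishing a genuine
#'   negative slope from integrator noise.
#' @return one-row tibble: `width_pct` (% of `2*tau_0`), `phase_lo`,
#'   `phase_hi`, `v_hi`, `v_lo`.
#' @export
secondary_basin_width <- function(curve, region = c("early", "terminal"),
                                  tol = 1e-7) {
  stopifnot(inherits(curve, "speed_phase_curve"))
  region <- match.arg(region)
  ds_frac <- attr(curve, "ds_fraction")
  w_frac <- attr(curve, "width_fraction")
  tau_0 <- attr(curve, "tau_0")
  step_len <- attr(curve, "step_length")
  stride_len <- 2 * step_len
  cut <- ds_frac - w_frac # last onset with the whole pulse inside double stance
  sel <- if (region == "early") curve$phase <= cut else
    curve$phase > cut & curve$phase <= ds_frac
  ph <- curve$phase[sel]; sp <- curve$speed[sel]
  empty <- tibble::tibble(width_pct = 0, phase_lo = NA_real_,
                          phase_hi = NA_real_, v_hi = NA_real_, v_lo = NA_real_)
  if (sum(sel) < 3) return(empty)
  runs <- decreasing_runs(ph, sp, tol)
  if (is.null(runs)) return(empty)
  best <- runs[which.max(runs$span), ]
  v_hi <- sp[best$start]; v_lo <- sp[best$end]
  d_period <- stride_len / v_lo - stride_len / v_hi
  tibble::tibble(width_pct = 100 * d_period / (2 * tau_0),
                 phase_lo = ph[best$start], phase_hi = ph[best$end],
                 v_hi = v_hi, v_lo = v_lo)
}

#' Scan the basin of entrainment over pulse periods
#'
#' For each pulse period `tau_p` on a grid (default `2*tau_0 +/- 0.1` s at
#' 2 ms resolution) and each of several equispaced initial offsets `delta`,
#' runs [simulate_perturbed()] and marks `tau_p` as inside the basin iff
#' the gait entrains for every tested offset (the locked phase is a global
#' attractor, independent of the initial pulse phase). The basin width is
#' the measure of entrained grid points as a percentage of `2*tau_0`
#' ([basin_width_pct()]).
#'
#' @param params a [walker_params()] object.
#' @param amplitude pulse amplitude \[N·m\]; default 10% of peak torque.
#' @param width pulse width \[s\].
#' @param tau_p_grid pulse-period grid \[s\]; default `2*tau_0 +/- 0.1` s
#'   at `resolution`.
#' @param resolution grid spacing \[s\] when `tau_p_grid` is `NULL`.
#' @param offsets number of equispaced initial offsets per period.
#' @param n_strides strides per run.
#' @param gating gating policy (default `"truncate"`; see [pulse_train()]).
#' @param numerics a [walker_numerics()] object.
#' @param window,period_tol,phase_range_tol entrainment criterion.
#' @return A tibble of class `basin_scan`: `tau_p`, `detuning_ms`
#'   (`tau_p - 2*tau_0` in ms), `entrained`, `locked_phase` (mean over
#'   offsets when entrained), `period_err_ms` (worst final-period error
#'   across offsets), with attributes `tau_0` and `resolution`.
#' @export
basin_scan <- function(params, amplitude = NULL, width = 0.1,
                       tau_p_grid = NULL, resolution = 0.002, offsets = 8,
                       n_strides = 300, gating = c("truncate", "extend"),
                       numerics = walker_numerics(),
                       window = 30, period_tol = 1e-3,
                       phase_range_tol = 0.01) {
  params <- as_walker_params(params)
  gating <- match.arg(gating)
  if (is.null(amplitude)) amplitude <- default_pulse_amplitude(params)
  base <- simulate_walk(params, n_steps = 1, numerics = numerics)
  stopifnot(base$termination == "COMPLETED")
  tau_0 <- base$steps$duration[1]
  if (is.null(tau_p_grid)) {
    tau_p_grid <- seq(2 * tau_0 - 0.1, 2 * tau_0 + 0.1, by = resolution)
  } else {
    resolution <- if (length(tau_p_grid) > 1) stats::median(diff(tau_p_grid)) else NA_real_
  }
  x0 <- fixed_point(params)$theta_dot_star
  res <- purrr::map(tau_p_grid, function(tp) {
    deltas <- (seq_len(offsets) - 1) / offsets * tp
    ent <- TRUE; locked <- c(); per_err <- c()
    for (d in deltas) {
      pl <- pulse_train(amplitude, width, period = tp, offset = d,
                        leg = "A", gating = gating)
      sim <- simulate_perturbed(params, pl, n_strides = n_strides,
                                theta_dot0 = x0, numerics = numerics,
                                window = window, period_tol = period_tol,
                                phase_range_tol = phase_range_tol)
      per_err <- c(per_err, abs(sim$final_mean_stride_period - tp))
      if (!sim$entrained) { ent <- FALSE; break }
      locked <- c(locked, sim$locked_phase)
    }
    tibble::tibble(tau_p = tp, detuning_ms = 1000 * (tp - 2 * tau_0),
                   entrained = ent,
                   locked_phase = if (ent) mean(locked) else NA_real_,
                   period_err_ms = 1000 * max(per_err))
  })
  out <- dplyr::bind_rows(res)
  attr(out, "tau_0") <- tau_0
  attr(out, "resolution") <- resolution
  attr(out, "gating") <- gating
  class(out) <- c("basin_scan", class(out))
  out
}

#' Basin width from a scan
#'
#' Measure of pulse periods that entrain for all tested offsets, as a
#' percentage of the unperturbed stride period `2*tau_0`: number of
#' entrained grid points times the grid spacing.
#'
#' @param scan a `basin_scan` tibble.
#' @return width in % of `2*tau_0`.
#' @export
basin_width_pct <- function(scan) {
  stopifnot(inherits(scan, "basin_scan"))
  tau_0 <- attr(scan, "tau_0")
  res <- attr(scan, "resolution")
  100 * sum(scan$entrained) * res / (2 * tau_0)
}
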