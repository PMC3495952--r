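#' Numerical integration settings
#'
#' Settings for the event-driven hybrid integrator: an adaptive
#' Dormand-Prince Runge-Kutta 5(4) pair with bisection event localization.
#' Events (spring release `psi = mu`, heel strike `theta = -alpha`,
#' fall-back `theta_dot = 0`, pulse on/off instants, the linkage cap under
#' the extension gating policy) are located to an interval below 1e-13 s, so
#' the event-function residual is at the 1e-12 level. A fixed-step classic
#' RK4 mode is available for replication studies.
#'
#' @param rtol,atol relative/absolute local-error tolerances.
#' @param h_max maximal step \[s\]; also sets the trajectory sampling
#'   density and the resolution of the ground-reaction-force minima
#'   monitors.
#' @param h_init initial step \[s\].
#' @param fixed_step if positive, integrate with classic RK4 at this fixed
#'   step instead of the adaptive pair.
#' @param strict if `TRUE`, the fly-off monitors (leading-heel or
#'   single-stance ground reaction force crossing zero) and the linkage cap
#'   terminate the walk; by default they only flag the step record.
#' @return an object of class `walker_numerics`.
#' @export
walker_numerics <- function(rtol = 1e-10, atol = 1e-10, h_max = 0.01,
                            h_init = 1e-3, fixed_step = NULL, strict = FALSE) {
  structure(list(rtol = rtol, atol = atol, h_init = h_init, h_max = h_max,
                 fixed_step = if (is.null(fixed_step)) -1 else fixed_step,
                 strict = isTRUE(strict)),
            class = "walker_numerics")
}

as_walker_numerics <- function(x) {
  if (inherits(x, "walker_numerics")) return(x)
  if (is.null(x)) return(walker_numerics())
  do.call(walker_numerics, x)
}

#' Angular acceleration during double stance
#'
#' Generalized-force (energy-consistent) form of the double-stance equation
#' of motion:
#' `theta_ddot = (m*g*L*sin(theta) + T * dpsi/dtheta) / (m*L^2)`,
#' where `T` is the total plantar ankle torque (spring plus any gated
#' perturbation pulse). Identical, to rounding, to the Newton-Euler form
#' `theta_ddot = (g*sin(theta) - (F_A/m)*cos(theta - phi)) / L` with `F_A`
#' from [grf_trailing()]; the equality is a two-force-member identity of the
#' massless-leg linkage.
#'
#' @param theta hip angle(s) \[rad\].
#' @param params a [walker_params()] object.
#' @param torque total plantar ankle torque(s) \[N·m\]; defaults to the
#'   spring torque at `psi(theta)`.
#' @return angular acceleration(s) \[rad/s^2\], vectorized.
#' @export
accel_double_stance <- function(theta, params, torque = NULL) {
  params <- as_walker_params(params)
  lk <- ankle_angle(theta, params)
  if (is.null(torque)) torque <- ankle_spring_torque(lk$psi, params)
  (params$m * params$g * params$L * sin(theta) + torque * lk$dpsi_dtheta) /
    (params$m * params$L^2)
}

#' Angular acceleration during single stance
#'
#' Inverted pendulum about the stance ankle:
#' `theta_ddot = (g/L) * sin(theta)`.
#'
#' @inheritParams accel_double_stance
#' @return angular acceleration(s) \[rad/s^2\], vectorized.
#' @export
accel_single_stance <- function(theta, params) {
  params <- as_walker_params(params)
  params$g / params$L * sin(theta)
}

#' Heel-strike collision map
#'
#' The inelastic foot-ground collision redirects the mass velocity along the
#' new stance leg, scaling the angular speed by `cos(2*alpha)` (kinetic
#' energy by `cos^2(2*alpha)`), resetting `theta` to `+alpha` and swapping
#' the trailing leg. As `alpha -> 0` the loss vanishes and the behavior
#' approaches pure rolling.
#'
#' @param theta_dot_pre pre-collision angular velocity \[rad/s\].
#' @param params a [walker_params()] object.
#' @return list with `theta` (= `alpha`) and `theta_dot`
#'   (`= cos(2*alpha) * theta_dot_pre`).
#' @export
collision_map <- function(theta_dot_pre, params) {
  params <- as_walker_params(params)
  list(theta = params$alpha, theta_dot = cos(2 * params$alpha) * theta_dot_pre)
}

#' Ground reaction force at the trailing toe (double stance)
#'
#' The massless trailing foot transmits the ankle torque to the ground as a
#' force along the line from toe A to point mass C:
#' `F_A = T * AC / (l * L * sin(psi)) = T / (l * sin(angle DAC))`.
#' Non-negative whenever the total torque is.
#'
#' @inheritParams accel_double_stance
#' @return force magnitude(s) \[N\], vectorized.
#' @export
grf_trailing <- function(theta, params, torque = NULL) {
  params <- as_walker_params(params)
  if (is.null(torque)) {
    lk <- ankle_angle(theta, params)
    torque <- ankle_spring_torque(lk$psi, params)
    return(torque * lk$AC / (params$l * params$L * sin(lk$psi)))
  }
  n <- max(length(theta), length(torque))
  theta <- rep_len(theta, n); torque <- rep_len(torque, n)
  out <- numeric(n)
  nz <- torque != 0 # a torque-free foot transmits no force, any geometry
  if (any(nz)) {
    lk <- ankle_angle(theta[nz], params)
    out[nz] <- torque[nz] * lk$AC / (params$l * params$L * sin(lk$psi))
  }
  out
}

#' Ground reaction force at the leading heel (double stance)
#'
#' `F_B = m*g*cos(theta) - m*L*theta_dot^2 - F_A*sin(phi - theta)`, directed
#' from the heel contact B to the point mass. Negative values signal
#' fly-off: either an excessive trailing-ankle push (`F_A` term) or
#' excessive centripetal demand (`theta_dot^2` term).
#'
#' @inheritParams accel_double_stance
#' @param theta_dot angular velocity(ies) \[rad/s\].
#' @return force magnitude(s) \[N\], vectorized.
#' @export
grf_leading <- function(theta, theta_dot, params, torque = NULL) {
  params <- as_walker_params(params)
  FA <- grf_trailing(theta, params, torque)
  phi <- line_angle_phi(theta, params)
  FAterm <- ifelse(FA == 0, 0, FA * sin(phi - theta))
  params$m * params$g * cos(theta) - params$m * params$L * theta_dot^2 - FAterm
}

#' Ground reaction force during single stance
#'
#' `f = m * (g*cos(theta) - L*theta_dot^2)`; over a step its minimum occurs
#' at the end of single stance (`theta = -alpha`), where `cos(theta)` is
#' smallest and the speed largest, so the sign of `f(-alpha)` decides
#' whether the model flies off.
#'
#' @inheritParams grf_leading
#' @return force magnitude(s) \[N\], vectorized.
#' @export
grf_single_stance <- function(theta, theta_dot, params) {
  params <- as_walker_params(params)
  params$m * (params$g * cos(theta) - params$L * theta_dot^2)
}

pulse_to_cpp <- function(pulse) {
  if (is.null(pulse)) return(NULL)
  stopifnot(inherits(pulse, "pulse_train"))
  list(amplitude = pulse$amplitude, width = pulse$width, period = pulse$period,
       offset = pulse$offset, leg = pulse$leg,
       policy = if (pulse$gating == "extend") 1L else 0L,
       eps_cap = pulse$eps_cap)
}

steps_to_tibble <- function(sm) {
  df <- tibble::as_tibble(as.data.frame(sm))
  df$trailing_leg <- ifelse(df$trailing_leg == 0, "A", "B")
  df$capped <- df$capped > 0
  df$extended <- df$extended > 0
  df$ankle_work <- df$ankle_work # spring + pulse work over double stance [J]
  df
}

traj_to_tibble <- function(tm, params, pulse) {
  df <- tibble::as_tibble(as.data.frame(tm))
  p <- params
  ds <- df$phase == 0
  psi <- rep(NA_real_, nrow(df))
  T_spring <- numeric(nrow(df))
  T_pulse <- numeric(nrow(df))
  F_A <- rep(NA_real_, nrow(df))
  F_B <- rep(NA_real_, nrow(df))
  f_ss <- rep(NA_real_, nrow(df))
  if (any(ds)) {
    lk <- ankle_angle(df$theta[ds], p)
    psi[ds] <- lk$psi
    T_spring[ds] <- ankle_spring_torque(lk$psi, p)
    A <- if (is.null(pulse)) 0 else pulse$amplitude
    T_pulse[ds] <- ifelse(df$pulse_on[ds] > 0, A, 0)
    Ttot <- T_spring[ds] + T_pulse[ds]
    F_A[ds] <- Ttot * lk$AC / (p$l * p$L * sin(lk$psi))
    F_B[ds] <- p$m * p$g * cos(df$theta[ds]) -
      p$m * p$L * df$theta_dot[ds]^2 - F_A[ds] * sin(lk$phi - df$theta[ds])
  }
  if (any(!ds)) {
    f_ss[!ds] <- grf_single_stance(df$theta[!ds], df$theta_dot[!ds], p)
  }
  out <- tibble::tibble(
    t = df$t, theta = df$theta, theta_dot = df$theta_dot,
    phase = ifelse(ds, "double_stance", "single_stance"),
    psi = psi, torque_spring = T_spring, torque_pulse = T_pulse,
    F_A = F_A, F_B = F_B, f_ss = f_ss,
    KE = 0.5 * p$m * p$L^2 * df$theta_dot^2,
    PE = p$m * p$g * p$L * cos(df$theta),
    work_in = df$w_spring + df$w_pulse
  )
  class(out) <- c("walker_trajectory", class(out))
  out
}

#' Simulate a multi-step walk
#'
#' Chains step cycles of the hybrid dynamics from a post-collision start at
#' `theta = alpha`: double stance (actuated linkage, optionally perturbed by
#' a gated torque [pulse_train()]) to spring release, single stance
#' (inverted pendulum) to heel strike, inelastic collision, repeat.
#' Absolute time is maintained so the pulse train keeps its phase across
#' steps. The walk stops early on a fall-back (angular velocity reaching
#' zero before heel strike) or, in strict mode, on fly-off or linkage-cap
#' events.
#'
#' @param params a [walker_params()] object.
#' @param theta_dot0 initial (post-collision) angular velocity \[rad/s\],
#'   negative for forward progression. Defaults to the period-one fixed
#'   point.
#' @param n_steps number of step cycles to simulate.
#' @param pulse a [pulse_train()] or `NULL` for unperturbed walking.
#' @param numerics a [walker_numerics()] object.
#' @param record if `TRUE`, keep the dense trajectory.
#' @param t0 absolute start time \[s\] (pulse phasing).
#' @param trailing_leg leg ("A" or "B") that is trailing on the first step.
#' @return An object of class `walker_walk`: list with `steps` (tibble of
#'   per-step records: durations, toe-off and heel-strike times, pre/post
#'   collision velocities, ankle and pulse work, minimum ground reaction
#'   forces, gating flags), `termination` (`"COMPLETED"`, `"FALL_BACK"`,
#'   `"FLY_OFF"` or `"LINKAGE_SINGULARITY"`), `trajectory` (tibble or
#'   `NULL`), the final state, and the inputs.
#' @examples
#' p <- walker_params()
#' w <- simulate_walk(p, n_steps = 3)
#' w$steps$duration # about 0.967 s each
#' @export
simulate_walk <- function(params, theta_dot0 = NULL, n_steps = 10,
                          pulse = NULL, numerics = walker_numerics(),
                          record = FALSE, t0 = 0, trailing_leg = "A") {
  params <- as_walker_params(params)
  numerics <- as_walker_numerics(numerics)
  if (is.null(theta_dot0)) theta_dot0 <- fixed_point(params)$theta_dot_star
  stopifnot(n_steps >= 1)
  res <- .walk_cpp(unclass(params), theta_dot0, as.integer(n_steps),
                   pulse_to_cpp(pulse), unclass(numerics), record,
                   t0, if (identical(trailing_leg, "B")) 1L else 0L)
  steps <- steps_to_tibble(res$steps)
  traj <- if (record) traj_to_tibble(res$trajectory, params, pulse) else NULL
  structure(list(
    steps = steps,
    termination = res$termination,
    term_step = if (res$term_step >= 0) res$term_step + 1L else NA_integer_,
    t_final = res$t_final,
    state_final = list(theta = res$state_final[1], theta_dot = res$state_final[2],
                       trailing_leg = if (res$trailing_final == 0) "A" else "B"),
    trajectory = traj,
    params = params, pulse = pulse, numerics = numerics
  ), class = "walker_walk")
}

#' @export
print.walker_walk <- function(x, ...) {
  cat(sprintf("<walker_walk> %d step(s), termination: %s\n",
              nrow(x$steps), x$termination))
  if (nrow(x$steps)) {
    cat(sprintf("  step period %.6g s (last), average speed %.6g m/s\n",
                x$steps$duration[nrow(x$steps)],
                2 * x$params$L * sin(x$params$alpha) / mean(x$steps$duration)))
  }
  invisible(x)
}

#' Simulate a single step cycle
#'
#' One step of the hybrid dynamics (see [simulate_walk()]): from a
#' post-collision state at `theta = alpha` through toe-off and heel strike
#' to the next post-collision state.
#'
#' @inheritParams simulate_walk
#' @return A `walker_walk` object with a one-row `steps` tibble and (by
#'   default) the dense trajectory.
#' @export
simulate_step <- function(params, theta_dot0 = NULL, pulse = NULL,
                          numerics = walker_numerics(), record = TRUE,
                          t0 = 0, trailing_leg = "A") {
  simulate_walk(params, theta_dot0, n_steps = 1, pulse = pulse,
                numerics = numerics, record = record, t0 = t0,
                trailing_leg = trailing_leg)
}

#' Per-step energy audit
#'
#' For each completed step of a walk, three residuals that must vanish for a
#' correct simulation: over double stance,
#' `residual_ds = dKE + dPE - W_in` (work-energy balance with the ankle
#' work `W_in`, spring plus pulse); over single stance,
#' `residual_ss = dKE + dPE` (conservative pendulum); at the collision,
#' `residual_collision = KE_post/KE_pre - cos^2(2*alpha)` (algebraic energy
#' ratio of the inelastic impact). A period-one gait exists exactly when
#' the collision loss equals the ankle work injected per step.
#'
#' @param walk a `walker_walk` from [simulate_walk()].
#' @return tibble with one row per completed step and the three residuals
#'   \[J, J, dimensionless\].
#' @export
energy_audit <- function(walk) {
  stopifnot(inherits(walk, "walker_walk"))
  p <- walk$params
  s <- walk$steps
  KE <- function(td) 0.5 * p$m * p$L^2 * td^2
  PE <- function(th) p$m * p$g * p$L * cos(th)
  tibble::tibble(
    step_index = s$step_index,
    work_in = s$ankle_work,
    residual_ds = KE(s$theta_dot_toe_off) + PE(s$theta_toe_off) -
      KE(s$theta_dot_start) - PE(p$alpha) - s$ankle_work,
    residual_ss = KE(s$theta_dot_pre) + PE(-p$alpha) -
      KE(s$theta_dot_toe_off) - PE(s$theta_toe_off),
    residual_collision = (s$theta_dot_post / s$theta_dot_pre)^2 -
      cos(2 * p$alpha)^2
  )
}
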