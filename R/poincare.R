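#' Closed-form step-to-step (Poincare) map
#'
#' Work-energy form of the return map for the post-collision angular
#' velocity. Over one step the spring injects a fixed work
#' `W = k*(mu - psi0)^2 / 2` while potential energy returns to its
#' heel-strike value, so the pre-collision speed obeys
#' `theta_dot_pre^2 = x^2 + c` with `c = k*(mu - psi0)^2 / (m*L^2)`, and the
#' collision scales velocity by `cos(2*alpha)`:
#' `f(x) = -cos(2*alpha) * sqrt(x^2 + c)`.
#'
#' The closed form presumes the model vaults over the apex and that the
#' spring releases before the apex (`theta_f > 0`). The vault-over margin is
#' checked; inputs that would stall before the apex raise a domain error
#' mirroring the simulator's fall-back termination. Near the feasibility
#' boundary, or when `theta_f <= 0`, use [step_map_simulated()].
#'
#' @param theta_dot0 post-collision angular velocity(ies) \[rad/s\],
#'   negative for forward progression.
#' @param params a [walker_params()] object.
#' @param validate if `TRUE` (default), reject inputs whose vault-over
#'   margin is non-positive; `validate = FALSE` returns the algebraic value
#'   of the map (its analytic continuation) without the feasibility check,
#'   e.g. for studying the crawl limit `f(0-) = -cos(2*alpha)*sqrt(c)`.
#' @return mapped post-collision angular velocity(ies) \[rad/s\].
#' @export
step_map <- function(theta_dot0, params, validate = TRUE) {
  params <- as_walker_params(params)
  if (any(theta_dot0 >= 0)) {
    stop("step_map: theta_dot0 must be negative (forward progression)", call. = FALSE)
  }
  theta_f <- double_stance_end_angle(params)
  if (theta_f <= 0) {
    stop("step_map: spring not fully released before the apex (theta_f <= 0); ",
         "the closed form does not apply - use step_map_simulated()", call. = FALSE)
  }
  cc <- params$k * (params$mu - params$psi0)^2 / (params$m * params$L^2)
  if (validate) {
    # vault-over: KE at the apex with the full spring work released
    ke_apex <- 0.5 * params$m * params$L^2 * theta_dot0^2 +
      0.5 * params$k * (params$mu - params$psi0)^2 -
      params$m * params$g * params$L * (1 - cos(params$alpha))
    if (any(ke_apex <= 0)) {
      stop("step_map: insufficient kinetic energy to vault over the apex (fall-back)",
           call. = FALSE)
    }
  }
  -cos(2 * params$alpha) * sqrt(theta_dot0^2 + cc)
}

#' Simulated step-to-step map
#'
#' The return map evaluated by full hybrid simulation of one step
#' ([simulate_step()]); agrees with the closed-form [step_map()] to
#' integrator tolerance wherever the closed form applies.
#'
#' @inheritParams step_map
#' @param numerics a [walker_numerics()] object.
#' @return post-collision angular velocity after one simulated step
#'   \[rad/s\].
#' @export
step_map_simulated <- function(theta_dot0, params, numerics = walker_numerics()) {
  params <- as_walker_params(params)
  vapply(theta_dot0, function(x) {
    w <- simulate_walk(params, x, n_steps = 1, numerics = numerics, record = FALSE)
    if (w$termination != "COMPLETED" || nrow(w$steps) < 1) {
      stop("step_map_simulated: step did not complete (", w$termination, ")",
           call. = FALSE)
    }
    w$steps$theta_dot_post[1]
  }, numeric(1))
}

#' Period-one fixed point of the step map
#'
#' Solving `f(x) = x` for the closed-form map gives the pre-collision speed
#' `v_C = (mu - psi0) * sqrt(k/m) / sin(2*alpha)` and post-collision
#' angular velocity `theta_dot_star = -cos(2*alpha) * v_C / L`: the
#' collision loss `(1 - cos^2 2*alpha) * KE_pre` exactly equals the spring
#' work per step.
#'
#' @param params a [walker_params()] object.
#' @return list with `theta_dot_star` \[rad/s\] and `v_C` \[m/s\].
#' @export
fixed_point <- function(params) {
  params <- as_walker_params(params)
  v_C <- (params$mu - params$psi0) * sqrt(params$k / params$m) /
    sin(2 * params$alpha)
  list(theta_dot_star = -cos(2 * params$alpha) * v_C / params$L, v_C = v_C)
}

#' Analytic Floquet multiplier
#'
#' The derivative of the step-to-step map at its fixed point is
#' `cos^2(2*alpha)`: differentiation of `f(x) = -cos(2a)*sqrt(x^2 + c)`
#' gives `f'(x*) = cos(2a) * x*/sqrt(x*^2 + c) = cos^2(2a)`. Strictly
#' inside (0, 1) for `0 < alpha < pi/4`, so the period-one gait is locally
#' asymptotically stable; the multiplier tends to 1 (marginal stability) in
#' the rolling limit `alpha -> 0`.
#'
#' @param params a [walker_params()] object.
#' @return dimensionless multiplier.
#' @export
floquet_multiplier_analytic <- function(params) {
  params <- as_walker_params(params)
  cos(2 * params$alpha)^2
}

#' Floquet multiplier from simulation
#'
#' Central finite difference of the simulated return map at the fixed
#' point: `[f(x*(1+h)) - f(x*(1-h))] / (2*x**h)`. At default tolerances
#' this matches the analytic `cos^2(2*alpha)` to five decimals.
#'
#' @param params a [walker_params()] object.
#' @param offset_fraction relative offset `h` of the probes (default 0.5%).
#' @param numerics a [walker_numerics()] object.
#' @return dimensionless multiplier estimate.
#' @export
floquet_multiplier_numeric <- function(params, offset_fraction = 0.005,
                                       numerics = walker_numerics()) {
  params <- as_walker_params(params)
  x_star <- fixed_point(params)$theta_dot_star
  h <- offset_fraction
  fp <- step_map_simulated(x_star * (1 + h), params, numerics)
  fm <- step_map_simulated(x_star * (1 - h), params, numerics)
  (fp - fm) / (2 * x_star * h)
}

#' Critical ("just-vault-over") ankle stiffness
#'
#' Below this stiffness the spring cannot supply enough energy for the
#' period-one gait to carry the mass over the apex `theta = 0`. Setting the
#' apex kinetic energy of the fixed-point gait to zero gives
#' `k_C = 2*m*g*L*(1 - cos(alpha)) * sin^2(2*alpha) / (mu - psi0)^2`.
#' The derivation assumes the spring releases before the apex
#' (`theta_f > 0`), which is verified.
#'
#' @param params a [walker_params()] object.
#' @return stiffness \[N·m/rad\].
#' @export
critical_stiffness <- function(params) {
  params <- as_walker_params(params)
  if (double_stance_end_angle(params) <= 0) {
    stop("critical_stiffness: closed form assumes the spring releases before the apex (theta_f > 0)",
         call. = FALSE)
  }
  2 * params$m * params$g * params$L * (1 - cos(params$alpha)) *
    sin(2 * params$alpha)^2 / (params$mu - params$psi0)^2
}

#' Existence and feasibility of the period-one gait
#'
#' Checks the two feasibility conditions for the period-one gait:
#' (1) vault-over, `k > k_C` ([critical_stiffness()]); and (2) no fly-off,
#' the ground reaction forces at the leading heel (double stance) and the
#' stance foot (single stance) stay positive along the simulated
#' period-one step. Fills in the simulated step period `tau_0`, the average
#' forward speed `2*L*sin(alpha)/tau_0`, the minimum ground reaction
#' forces, and the Floquet multipliers.
#'
#' @param params a [walker_params()] object.
#' @param numerics a [walker_numerics()] object.
#' @param find_flyoff_k if `TRUE`, also bisect for the upper ("just-fly-off")
#'   stiffness at which the leading-heel force first touches zero
#'   (tolerance 0.1 N·m/rad).
#' @return An object of class `gait_analysis` with fields
#'   `feasible`, `reasons` (character, empty when feasible),
#'   `fixed_point_theta_dot`, `v_C`, `floquet_analytic`, `floquet_numeric`
#'   (NA unless computable), `tau_0`, `average_speed`, `k_critical`,
#'   `min_grf_leading`, `min_grf_single_stance`, and optionally
#'   `k_flyoff`. Use [generics::tidy()] / [generics::glance()] for tabular
#'   views.
#' @examples
#' g <- gait_existence_check(walker_params())
#' glance(g)
#' @export
gait_existence_check <- function(params, numerics = walker_numerics(),
                                 find_flyoff_k = FALSE) {
  params <- as_walker_params(params)
  kC <- critical_stiffness(params)
  fp <- fixed_point(params)
  reasons <- character(0)
  tau_0 <- NA_real_; v_avg <- NA_real_
  min_FB <- NA_real_; min_f <- NA_real_; flq_num <- NA_real_
  if (params$k <= kC) {
    reasons <- c(reasons, sprintf("vault-over fails: k = %g <= k_C = %g", params$k, kC))
  } else {
    w <- simulate_walk(params, fp$theta_dot_star, n_steps = 1,
                       numerics = numerics, record = FALSE)
    if (w$termination != "COMPLETED") {
      reasons <- c(reasons, paste0("period-one step terminated: ", w$termination))
    } else {
      tau_0 <- w$steps$duration[1]
      v_avg <- 2 * params$L * sin(params$alpha) / tau_0
      min_FB <- w$steps$min_grf_leading[1]
      min_f <- w$steps$min_grf_single_stance[1]
      if (min_FB <= 0) reasons <- c(reasons, sprintf("fly-off: min leading-heel GRF = %g N <= 0", min_FB))
      if (min_f <= 0) reasons <- c(reasons, sprintf("fly-off: min single-stance GRF = %g N <= 0", min_f))
    }
  }
  out <- list(
    feasible = length(reasons) == 0,
    reasons = reasons,
    fixed_point_theta_dot = fp$theta_dot_star,
    v_C = fp$v_C,
    floquet_analytic = floquet_multiplier_analytic(params),
    floquet_numeric = flq_num,
    tau_0 = tau_0,
    average_speed = v_avg,
    k_critical = kC,
    min_grf_leading = min_FB,
    min_grf_single_stance = min_f,
    params = params
  )
  if (find_flyoff_k) out$k_flyoff <- flyoff_stiffness(params, numerics)
  structure(out, class = "gait_analysis")
}

# Upper stiffness limit: bisection on k for min leading-heel GRF = 0 along
# the period-one step. No closed form; tolerance 0.1 N.m/rad.
flyoff_stiffness <- function(params, numerics = walker_numerics(),
                             k_hi = 50 * params$k, tol = 0.1) {
  params <- as_walker_params(params)
  min_FB_at <- function(k) {
    p <- walker_params(params$m, params$L, params$l, params$g,
                       params$alpha, params$mu, k)
    w <- simulate_walk(p, fixed_point(p)$theta_dot_star, n_steps = 1,
                       numerics = numerics, record = FALSE)
    if (w$termination != "COMPLETED") return(-Inf)
    w$steps$min_grf_leading[1]
  }
  lo <- params$k; hi <- k_hi
  if (min_FB_at(lo) <= 0) stop("flyoff_stiffness: reference k already flies off", call. = FALSE)
  while (min_FB_at(hi) > 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    if (min_FB_at(mid) > 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat("<gait_analysis>", if (x$feasible) "feasible period-one gait" else "INFEASIBLE", "\n")
  if (!x$feasible) for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  cat(sprintf("  fixed point: theta_dot* = %.6g rad/s (v_C = %.6g m/s)\n",
              x$fixed_point_theta_dot, x$v_C))
  cat(sprintf("  Floquet multiplier (analytic): %.6g\n", x$floquet_analytic))
  if (is.finite(x$tau_0)) {
    cat(sprintf("  step period tau_0 = %.6g s, average speed = %.6g m/s\n",
                x$tau_0, x$average_speed))
    cat(sprintf("  min GRF: leading heel %.6g N, single stance %.6g N\n",
                x$min_grf_leading, x$min_grf_single_stance))
  }
  cat(sprintf("  k = %.6g, k_critical = %.6g N·m/rad\n", x$params$k, x$k_critical))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gait analysis into one row per quantity
#'
#' @param x a `gait_analysis` from [gait_existence_check()].
#' @param ... unused.
#' @return tibble with columns `quantity`, `value`, `unit`.
#' @export
tidy.gait_analysis <- function(x, ...) {
  tibble::tibble(
    quantity = c("fixed_point_theta_dot", "v_C", "floquet_analytic",
                 "tau_0", "average_speed", "k_critical",
                 "min_grf_leading", "min_grf_single_stance"),
    value = c(x$fixed_point_theta_dot, x$v_C, x$floquet_analytic,
              x$tau_0, x$average_speed, x$k_critical,
              x$min_grf_leading, x$min_grf_single_stance),
    unit = c("rad/s", "m/s", "", "s", "m/s", "N·m/rad", "N", "N")
  )
}

#' One-row summary of a gait analysis
#'
#' @inheritParams tidy.gait_analysis
#' @return one-row tibble.
#' @export
glance.gait_analysis <- function(x, ...) {
  tibble::tibble(
    feasible = x$feasible,
    fixed_point_theta_dot = x$fixed_point_theta_dot,
    v_C = x$v_C,
    floquet_analytic = x$floquet_analytic,
    floquet_numeric = x$floquet_numeric,
    tau_0 = x$tau_0,
    average_speed = x$average_speed,
    k_critical = x$k_critical,
    min_grf_leading = x$min_grf_leading,
    min_grf_single_stance = x$min_grf_single_stance
  )
}
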