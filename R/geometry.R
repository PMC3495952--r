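#' Four-bar linkage kinematics of double stance
#'
#' During double stance the walker moves as four linked bars: trailing foot
#' (toe A to ankle D), trailing leg (D to point mass C), leading leg (C to
#' heel contact B) and the ground (B to A). All angles follow from the single
#' generalized coordinate `theta`, the angle of leg BC from vertical
#' (positive with the mass behind the leading contact B, which is the
#' origin). `ankle_angle()` returns the full linkage state on a grid of
#' `theta`: the ankle angle `psi` (interior angle at D between rays D->A and
#' D->C, positive towards plantar flexion), the angle `phi` of line AC above
#' horizontal, the distance `AC`, the derivative `dpsi_dtheta`, and the
#' ankle-point coordinates.
#'
#' With `a` the toe offset ([toe_offset()]),
#' `AC^2 = a^2 + L^2 - 2*a*L*sin(theta)` and the law of cosines in triangle
#' ADC (`|AD| = l`, `|DC| = L`) gives
#' `psi = acos((l^2 + L^2 - AC^2) / (2*l*L))`, the branch continuous with the
#' flat-foot configuration at `theta = alpha` (heel lifting, ankle above
#' ground). Differentiating the two expressions for `AC^2` yields
#' `dpsi/dtheta = -a*cos(theta) / (l*sin(psi))`.
#'
#' @param theta hip angle(s) \[rad\]. The double-stance range is
#'   `[theta_f, alpha]` (see [double_stance_end_angle()]); values beyond it
#'   are legitimate geometric queries (used when a torque pulse extends
#'   double stance past spring release) as long as the linkage stays away
#'   from its singularity `AC = l + L`.
#' @param params a [walker_params()] object.
#' @return A tibble with columns `theta`, `AC`, `psi`, `phi`, `dpsi_dtheta`,
#'   `D_x`, `D_y` — one row per element of `theta`.
#' @section Errors: a condition of class `anklewalker_singularity` is raised
#'   if any queried configuration reaches `AC >= l + L` (ankle angle at
#'   `pi`, linkage stretched flat).
#' @examples
#' p <- walker_params()
#' ankle_angle(p$alpha, p)$psi # pi/2 - alpha exactly
#' @export
ankle_angle <- function(theta, params) {
  params <- as_walker_params(params)
  a <- params$a; L <- params$L; l <- params$l
  AC2 <- a^2 + L^2 - 2 * a * L * sin(theta)
  AC <- sqrt(AC2)
  if (any(AC >= l + L - 1e-12)) {
    stop(errorCondition(
      sprintf("linkage singularity: AC = %.6g reaches l + L = %.6g (psi -> pi)",
              max(AC), l + L),
      class = c("anklewalker_singularity", "error")))
  }
  cpsi <- (l^2 + L^2 - AC2) / (2 * l * L)
  psi <- acos(pmin(pmax(cpsi, -1), 1))
  spsi <- sin(psi)
  # Ankle point D: on the circle of radius l about A, the intersection with
  # the circle of radius L about C that is continuous with the flat foot
  # (heel lifts; D stays on the non-reflected side of line AC).
  phi <- atan2(L * cos(theta), a - L * sin(theta))
  # interior angle at A between A->C and A->D; the heel-lift branch puts D
  # counter-clockwise from line AC (D on the ground at theta = alpha, above
  # it for smaller theta)
  cang_A <- (l^2 + AC2 - L^2) / (2 * l * AC)
  ang_A <- acos(pmin(pmax(cang_A, -1), 1))
  D_x <- -a + l * cos(phi + ang_A)
  D_y <- l * sin(phi + ang_A)
  tibble::tibble(
    theta = theta, AC = AC, psi = psi, phi = phi,
    dpsi_dtheta = -a * cos(theta) / (l * spsi),
    D_x = D_x, D_y = D_y
  )
}

#' Angle of the line from trailing toe to point mass
#'
#' `phi = atan2(L*cos(theta), a - L*sin(theta))`, the elevation above
#' horizontal of the line from the trailing toe A to the point mass C,
#' along which the trailing-leg ground reaction force acts (massless legs
#' transmit force straight to the mass).
#'
#' @inheritParams ankle_angle
#' @return angle(s) \[rad\], vectorized over `theta`.
#' @export
line_angle_phi <- function(theta, params) {
  params <- as_walker_params(params)
  atan2(params$L * cos(theta), params$a - params$L * sin(theta))
}

#' Derivative of the ankle angle with respect to the hip angle
#'
#' `dpsi/dtheta = -a*cos(theta) / (l*sin(psi(theta)))`; negative over the
#' double-stance range (plantar flexion increases as the body advances,
#' i.e. as `theta` decreases). This is the moment-arm ratio that converts
#' ankle torque into generalized force on `theta`.
#'
#' @inheritParams ankle_angle
#' @return dimensionless derivative(s), vectorized over `theta`.
#' @export
dpsi_dtheta <- function(theta, params) {
  ankle_angle(theta, params)$dpsi_dtheta
}

#' Hip angle at which double stance ends
#'
#' Double stance ends when the ankle torque reaches zero, i.e. when the
#' ankle angle `psi` reaches the maximal plantar-flexion angle `mu`.
#' Equating the two expressions for `AC^2` at `psi = mu` gives
#' `sin(theta_f) = (a^2 - l^2 + 2*l*L*cos(mu)) / (2*a*L)`, unique in
#' `(-alpha, alpha)`.
#'
#' @param params a [walker_params()] object.
#' @return `theta_f` \[rad\].
#' @export
double_stance_end_angle <- function(params) {
  params <- as_walker_params(params)
  s <- (params$a^2 - params$l^2 + 2 * params$l * params$L * cos(params$mu)) /
    (2 * params$a * params$L)
  if (!is.finite(s) || s < -1 || s > 1) {
    stop("double_stance_end_angle: no solution; parameters give sin(theta_f) = ",
         format(s), " outside [-1, 1]", call. = FALSE)
  }
  theta_f <- asin(s)
  if (theta_f > params$alpha + 1e-12) {
    stop("double_stance_end_angle: theta_f exceeds alpha; spring releases before heel strike",
         call. = FALSE)
  }
  theta_f
}

#' Tabulate the double-stance linkage over a hip-angle grid
#'
#' Convenience wrapper around [ankle_angle()] producing the linkage table
#' over an even grid spanning the double-stance range (or a user grid).
#'
#' @param params a [walker_params()] object.
#' @param theta optional vector of hip angles \[rad\]; defaults to an even
#'   grid of `n` points from `alpha` down to `theta_f`.
#' @param n grid size when `theta` is not supplied.
#' @return tibble as in [ankle_angle()].
#' @export
geometry_table <- function(params, theta = NULL, n = 201) {
  params <- as_walker_params(params)
  if (is.null(theta)) {
    theta <- seq(params$alpha, double_stance_end_angle(params), length.out = n)
  }
  ankle_angle(theta, params)
}
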