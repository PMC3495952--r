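#' Morphological and actuation parameters of the walker
#'
#' Constructs the parameter set of the ankle-actuated point-mass walker:
#' a point mass `m` on rigid massless legs of length `L`, feet of length `l`
#' (ankle to toe), half inter-leg angle `alpha` at heel strike, a torsional
#' ankle spring of stiffness `k` pre-loaded so that its torque vanishes when
#' the ankle angle reaches the maximal plantar-flexion angle `mu`.
#'
#' Defaults approximate an adult human: `m = 80` kg, `L = 1` m, `l = 0.2` m,
#' `g = 9.81` m/s^2, `alpha = pi/6` rad, `mu = 2.576` rad, and
#' `k = 87.3` N·m/rad (calibrated so that the peak plantar-flexion torque at
#' the start of double stance equals 17% of body weight times leg length;
#' see [calibrate_stiffness()]).
#'
#' @param m point mass \[kg\].
#' @param L leg length, hip (point mass) to ankle \[m\].
#' @param l foot length, ankle to toe \[m\].
#' @param g gravitational acceleration \[m/s^2\].
#' @param alpha half inter-leg angle at heel strike \[rad\]; the stance leg
#'   swings from `+alpha` to `-alpha` over one step.
#' @param mu maximal plantar-flexion angle of the ankle \[rad\]; the spring
#'   torque is `k * (mu - psi)` for ankle angle `psi <= mu` and zero beyond.
#' @param k ankle actuation stiffness \[N·m/rad\].
#'
#' @return An object of class `walker_params` (a named list of the seven
#'   constants plus derived quantities `a` (toe offset) and `psi0` (ankle
#'   angle at double-stance onset)).
#'
#' @details Validity requires `0 < alpha < pi/2`, `l < 2*L*sin(alpha)` (the
#'   trailing toe lies behind the leading heel), and
#'   `pi/2 - alpha < mu < pi` (the spring is cocked at double-stance onset
#'   and the linkage is non-degenerate at release).
#'
#' @examples
#' p <- walker_params()
#' toe_offset(p)
#' ankle_spring_torque(p$psi0, p) # peak torque, about 133.5 N·m
#' @export
walker_params <- function(m = 80, L = 1, l = 0.2, g = 9.81,
                          alpha = pi / 6, mu = 2.576, k = 87.3) {
  vals <- list(m = m, L = L, l = l, g = g, alpha = alpha, mu = mu, k = k)
  bad <- names(vals)[!vapply(vals, function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("walker_params: fields must be single positive finite numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (alpha >= pi / 2) stop("walker_params: alpha must be < pi/2", call. = FALSE)
  a <- 2 * L * sin(alpha) - l
  if (a <= 0) {
    stop("walker_params: foot too long; need l < 2*L*sin(alpha) so the trailing toe lies behind the leading heel",
         call. = FALSE)
  }
  psi0 <- pi / 2 - alpha
  if (mu <= psi0) {
    stop("walker_params: mu must exceed pi/2 - alpha (spring cocked at double-stance onset)",
         call. = FALSE)
  }
  if (mu >= pi) stop("walker_params: mu must be < pi (linkage degenerate at release)", call. = FALSE)
  structure(c(vals, list(a = a, psi0 = psi0)), class = "walker_params")
}

#' @export
print.walker_params <- function(x, ...) {
  cat("<walker_params>\n")
  cat(sprintf("  m = %g kg, L = %g m, l = %g m, g = %g m/s^2\n", x$m, x$L, x$l, x$g))
  cat(sprintf("  alpha = %.6g rad, mu = %.6g rad, k = %g N·m/rad\n", x$alpha, x$mu, x$k))
  cat(sprintf("  derived: toe offset a = %.6g m, psi0 = %.6g rad, peak torque = %.5g N·m\n",
              x$a, x$psi0, x$k * (x$mu - x$psi0)))
  invisible(x)
}

as_walker_params <- function(params) {
  if (inherits(params, "walker_params")) return(params)
  if (is.list(params)) return(do.call(walker_params, params[intersect(names(params), c("m", "L", "l", "g", "alpha", "mu", "k"))]))
  stop("expected a walker_params object", call. = FALSE)
}

#' Toe offset of the trailing foot
#'
#' Horizontal distance from the trailing toe to the leading heel at
#' heel strike, `a = 2*L*sin(alpha) - l`. With the previous stance foot flat
#' on the ground (ankle at its heel contact, toe `l` ahead) and step length
#' `2*L*sin(alpha)`, the trailing toe lies `a` behind the new contact.
#'
#' @param params a [walker_params()] object.
#' @return toe offset \[m\].
#' @export
toe_offset <- function(params) {
  params <- as_walker_params(params)
  params$a
}

#' Plantar ankle spring torque
#'
#' Torque of the pre-loaded torsional ankle spring as a function of the
#' ankle angle: `T = k * (mu - psi)` while `psi <= mu`, and exactly zero once
#' the spring has released (`psi > mu`); the released spring does not pull
#' back, so double stance ends when `psi` reaches `mu`.
#'
#' @param psi ankle angle(s) \[rad\], positive towards plantar flexion.
#' @param params a [walker_params()] object.
#' @return torque(s) \[N·m\], vectorized over `psi`.
#' @export
ankle_spring_torque <- function(psi, params) {
  params <- as_walker_params(params)
  params$k * pmax(params$mu - psi, 0)
}

#' Calibrate the ankle stiffness to a peak-torque target
#'
#' Returns the stiffness `k` for which the spring torque at double-stance
#' onset (ankle angle `psi0 = pi/2 - alpha`) equals a fraction of body
#' weight times leg length: `k = fraction * m * g * L / (mu - psi0)`.
#' Peak plantar-flexion torque in normal adult gait is about 17% of
#' `m * g * L`, the default target.
#'
#' @param params a [walker_params()] object (its `k` is ignored).
#' @param fraction peak-torque target as a fraction of `m * g * L`.
#' @return stiffness \[N·m/rad\].
#' @examples
#' calibrate_stiffness(walker_params()) # about 87.3
#' @export
calibrate_stiffness <- function(params, fraction = 0.17) {
  params <- as_walker_params(params)
  fraction * params$m * params$g * params$L / (params$mu - params$psi0)
}
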