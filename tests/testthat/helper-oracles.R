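# Independent brute-force oracles used across the suite. These deliberately
# avoid the closed forms and the compiled integrator they are used to check.

tbl1 <- function() walker_params() # default parameter set used throughout

# Ankle angle by explicit circle-circle intersection: the ankle D lies at
# distance l from the toe A = (-a, 0) and L from the mass C; the physical
# branch is continuous with the flat-foot configuration (cross product of
# (D - A) and (C - A) negative).
psi_oracle <- function(theta, p) {
  a <- 2 * p$L * sin(p$alpha) - p$l
  A <- c(-a, 0)
  C <- c(-p$L * sin(theta), p$L * cos(theta))
  d <- sqrt(sum((C - A)^2))
  x <- (p$l^2 - p$L^2 + d^2) / (2 * d)
  h <- sqrt(p$l^2 - x^2)
  u <- (C - A) / d
  n <- c(-u[2], u[1])
  for (s in c(1, -1)) {
    D <- A + x * u + s * h * n
    crossz <- (D[1] - A[1]) * (C[2] - A[2]) - (D[2] - A[2]) * (C[1] - A[1])
    if (crossz < 0) break
  }
  v1 <- A - D; v2 <- C - D
  acos(sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))
}

fd_central <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

bisect_root <- function(f, lo, hi, tol = 1e-13, it = 200) {
  flo <- f(lo)
  for (i in seq_len(it)) {
    mid <- 0.5 * (lo + hi)
    if (abs(hi - lo) < tol) break
    if ((f(mid) > 0) == (flo > 0)) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

# One full step integrated with deSolve::lsodar (independent of the
# package's compiled integrator): returns duration, toe-off time and
# post-collision angular velocity.
lsodar_step_oracle <- function(p, theta_dot0) {
  testthat::skip_if_not_installed("deSolve")
  a <- 2 * p$L * sin(p$alpha) - p$l
  psi_of <- function(th) {
    AC2 <- a^2 + p$L^2 - 2 * a * p$L * sin(th)
    acos((p$l^2 + p$L^2 - AC2) / (2 * p$l * p$L))
  }
  dpsi <- function(th) -a * cos(th) / (p$l * sin(psi_of(th)))
  rhs_ds <- function(t, y, parms) {
    Tq <- p$k * max(p$mu - psi_of(y[1]), 0)
    list(c(y[2], (p$m * p$g * p$L * sin(y[1]) + Tq * dpsi(y[1])) / (p$m * p$L^2)))
  }
  rhs_ss <- function(t, y, parms) list(c(y[2], p$g / p$L * sin(y[1])))
  o1 <- deSolve::lsodar(c(p$alpha, theta_dot0), seq(0, 3, 5e-4), rhs_ds,
                        rootfunc = function(t, y, parms) psi_of(y[1]) - p$mu,
                        rtol = 1e-12, atol = 1e-12)
  t1 <- attr(o1, "troot")
  y1 <- o1[nrow(o1), 2:3]
  o2 <- deSolve::lsodar(y1, seq(0, 5, 5e-4), rhs_ss,
                        rootfunc = function(t, y, parms) y[1] + p$alpha,
                        rtol = 1e-12, atol = 1e-12)
  t2 <- attr(o2, "troot")
  y2 <- o2[nrow(o2), 2:3]
  list(duration = unname(t1 + t2), toe_off = unname(t1),
       theta_dot_post = unname(cos(2 * p$alpha) * y2[2]))
}
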