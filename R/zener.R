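# Implicit time integration of the non-linear Maxwell (Zener branch) force.
#
# Backward-Euler update of the viscous force of one or several elements:
# given the force t0 at the beginning of the step and the total strain rate
# edot (held constant over the step), solve for x = t_ve(t + dt) from
#
#   (x - t0)/dt + E/eta(u) * x - (pi E d0^2/4) edot = 0,
#   u = edot - (x - t0)/(dt * pi E d0^2/4 * E/E)        (dashpot strain rate)
#
# with eta(u) the Carreau viscosity. The residual is continuous and tends
# to -Inf / +Inf as x -> -Inf / +Inf, so a bracket always exists; it is
# solved by a damped Newton iteration started from a linearised predictor,
# with a deterministic expanding-bracket bisection fallback. Where the
# strongly thinned regime admits several roots, starting from the predictor
# selects the root continuing the trajectory.

#' Backward-Euler update of viscous Zener forces
#'
#' Advances viscous force variables over one time step by solving the
#' implicit non-linear Maxwell equation with Carreau viscosity
#' (\code{\link{maxwellResidual}} with \eqn{\dot t \approx (x - t_0)/dt}).
#' Vectorised over elements (bundles or steric neighbours). The update is
#' accepted when the residual is below \code{1e-12 * (pi E d0^2/4) *
#' max(|edot|, edot0)}; on failure the step is halved recursively (at most
#' \code{maxHalvings} times).
#'
#' @param t0 viscous forces at the beginning of the step (N), vector.
#' @param edot total strain rates over the step (1/s), vector.
#' @param dt time step (s), positive.
#' @param E Maxwell spring modulus (Pa).
#' @param eta0 Newtonian plateau viscosity (Pa s).
#' @param edot0 Carreau transition strain rate (1/s).
#' @param n power-law index in [0, 1].
#' @param d0 fibril diameter (m).
#' @param maxHalvings maximum number of recursive step halvings.
#' @return Updated viscous forces (N), same length as \code{t0}.
#' @export
zenerStep <- function(t0, edot, dt, E, eta0, edot0, n, d0, maxHalvings = 20L) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  A <- pi * d0^2 / 4
  out <- .zenerSolve(t0, edot, dt, E, eta0, edot0, n, A)
  bad <- !is.finite(out)
  if (any(bad)) {
    if (maxHalvings <= 0L)
      stop("implicit Zener update failed to converge after step halving")
    half <- zenerStep(t0[bad], edot[bad], dt / 2, E, eta0, edot0, n, d0,
                      maxHalvings - 1L)
    out[bad] <- zenerStep(half, edot[bad], dt / 2, E, eta0, edot0, n, d0,
                          maxHalvings - 1L)
  }
  out
}

.zenerSolve <- function(t0, edot, dt, E, eta0, edot0, n, A) {
  AE <- A * E
  drive <- AE * edot
  resid <- function(x) {
    u <- edot - (x - t0) / (dt * AE)
    eta <- eta0 * (1 + (u / edot0)^2)^((n - 1) / 2)
    (x - t0) / dt + E / eta * x - drive
  }
  dresid <- function(x) {
    u <- edot - (x - t0) / (dt * AE)
    w <- 1 + (u / edot0)^2
    inv_eta <- w^((1 - n) / 2) / eta0
    dinv_eta_du <- ((1 - n) * u / edot0^2) * w^((1 - n) / 2 - 1) / eta0
    1 / dt + E * (inv_eta - x * dinv_eta_du / (dt * AE))
  }
  tol <- 1e-12 * AE * pmax(abs(edot), edot0)
  # predictor: linear Maxwell with the viscosity frozen at u = edot
  eta_p <- eta0 * (1 + (edot / edot0)^2)^((n - 1) / 2)
  x <- (t0 / dt + drive) / (1 / dt + E / eta_p)
  scale <- pmax(abs(x), abs(t0), AE * pmax(abs(edot), edot0) * dt, 1e-300)
  conv <- rep(FALSE, length(x))
  for (it in 1:80) {
    r <- resid(x)
    conv <- conv | (abs(r) <= tol & is.finite(x))
    if (all(conv)) break
    step <- r / dresid(x)
    step[conv | !is.finite(step)] <- 0
    step <- sign(step) * pmin(abs(step), 10 * scale)   # damp wild steps
    x <- x - step
  }
  if (!all(conv)) {
    for (k in which(!conv))
      x[k] <- .zenerBisect(t0[k], edot[k], dt, E, eta0, edot0, n, AE,
                           tol[k], scale[k])
  }
  x
}

.zenerBisect <- function(t0, edot, dt, E, eta0, edot0, n, AE, tol, scale) {
  f <- function(x) {
    u <- edot - (x - t0) / (dt * AE)
    eta <- eta0 * (1 + (u / edot0)^2)^((n - 1) / 2)
    (x - t0) / dt + E / eta * x - AE * edot
  }
  w <- scale
  lo <- t0 - w; hi <- t0 + w
  for (k in 1:200) {
    if (f(lo) <= 0) break
    w <- 2 * w; lo <- t0 - w
    if (!is.finite(lo)) return(NA_real_)
  }
  w <- scale
  for (k in 1:200) {
    if (f(hi) >= 0) break
    w <- 2 * w; hi <- t0 + w
    if (!is.finite(hi)) return(NA_real_)
  }
  if (!(f(lo) <= 0 && f(hi) >= 0)) return(NA_real_)
  r <- tryCatch(stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75,
                               maxiter = 2000L),
                error = function(e) NULL)
  if (is.null(r)) return(NA_real_)
  r$root
}
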