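#' Bundle kinematics under a macroscopic deformation
#'
#' Affine transport of the bundle directors: chord stretch
#' \eqn{\lambda_i = \|F E_i\|}, current direction
#' \eqn{e_i = F E_i / \lambda_i}, log-strain \eqn{\varepsilon_i =
#' \ln\lambda_i} and tensile strain rate \eqn{\dot\varepsilon_i = e_i
#' \cdot L \cdot e_i}.
#'
#' @param F 3 x 3 deformation gradient (unimodular).
#' @param L 3 x 3 velocity gradient (1/s).
#' @param directors m x 3 matrix of reference unit directors.
#' @return List with \code{lambda}, \code{eps}, \code{edot} (length-m
#'   vectors) and \code{e} (m x 3 matrix of current unit directions).
#' @export
bundleKinematics <- function(F, L, directors) {
  V <- directors %*% t(F)
  lambda <- sqrt(rowSums(V^2))
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("singular deformation gradient")
  e <- V / lambda
  list(lambda = lambda, eps = log(lambda),
       edot = rowSums((e %*% L) * e), e = e)
}

#' Steric neighbour kinematics
#'
#' Affine motion of the unconnected neighbour nodes: current distance
#' \eqn{\delta_q = \delta_q^0 \|F E_q\|}, direction \eqn{e_q}, contact
#' strain \eqn{\varepsilon_q = \ln(\delta_q/\delta_c)} and rate
#' \eqn{\dot\varepsilon_q = e_q \cdot L \cdot e_q}. Contact is active when
#' \eqn{\delta_q \le \delta_c}.
#'
#' @param F,L macroscopic deformation and velocity gradients.
#' @param neighbors neighbour set from \code{\link{buildNeighbors}} /
#'   \code{\link{revGeometry}}.
#' @param ell0 REV chord length (m), used for the normalised distance
#'   \eqn{\delta_q^* = \delta_q/\ell_0}.
#' @return List with \code{delta}, \code{delta_star}, \code{eps},
#'   \code{edot}, \code{contact}, \code{e}.
#' @export
neighborKinematics <- function(F, L, neighbors, ell0) {
  V <- neighbors$dirs %*% t(F)
  stretch <- sqrt(rowSums(V^2))
  e <- V / stretch
  delta <- neighbors$dists * stretch
  dc <- neighbors$delta_c
  eps <- if (is.finite(dc)) log(delta / dc) else rep(NA_real_, length(delta))
  list(delta = delta, delta_star = delta / ell0,
       eps = eps, edot = rowSums((e %*% L) * e),
       contact = if (is.finite(dc)) delta <= dc else rep(FALSE, length(delta)),
       e = e)
}

#' Fibril stress contribution
#'
#' Upscales the fibril forces of every family to the macroscopic Cauchy
#' contribution
#' \deqn{\sigma_f = \sum_{fam} \frac{\Phi}{(\pi d_0^2/4)\,\xi_0}
#'   \sum_{i=1}^4 t_i \lambda_i \; e_i \otimes e_i,}
#' i.e. force per fibril cross-section, weighted by volume fraction and
#' tortuosity (the reading of the network prefactor that yields stress
#' units and the correct dilute-limit modulus).
#'
#' @param model a \code{tissue_model}.
#' @param bk bundle kinematics from \code{\link{bundleKinematics}}.
#' @param forces list of per-family force vectors (length 4, N), named as
#'   \code{model$families}.
#' @return Symmetric 3 x 3 tensor (Pa).
#' @export
sigmaFibril <- function(model, bk, forces) {
  S <- matrix(0, 3, 3)
  for (nm in names(model$families)) {
    w <- model$prefactors[[nm]] * forces[[nm]] * bk$lambda
    S <- S + crossprod(bk$e, w * bk$e)
  }
  S
}

#' Steric stress contribution
#'
#' \deqn{\sigma_s = \Big(\sum_{fam}\frac{\Phi}{(\pi d_0^2/4)\,\xi_0}\Big)
#'   \sum_{q=1}^5 \frac{R_q}{\delta_q^*}\; e_q \otimes e_q,}
#' zero when no contact is active. Repulsive forces are negative scalars,
#' so an active contact along \eqn{e_x} contributes a negative (compressive)
#' \eqn{\sigma_{s,xx}}.
#'
#' @param model a \code{tissue_model}.
#' @param nk neighbour kinematics from \code{\link{neighborKinematics}}.
#' @param R per-neighbour total steric forces (length 5, N).
#' @return Symmetric 3 x 3 tensor (Pa).
#' @export
sigmaSteric <- function(model, nk, R) {
  if (is.null(model$steric) || all(R == 0)) return(matrix(0, 3, 3))
  w <- model$steric_prefactor * R / nk$delta_star
  crossprod(nk$e, w * nk$e)
}

#' Total Cauchy stress decomposition
#'
#' Assembles \eqn{\sigma = -p\delta + \sigma_m + \sigma_f + \sigma_s} from
#' the current kinematics and internal state, exposing each contribution.
#' The internal state carries the viscous forces; the neutral (hyperelastic)
#' forces are evaluated from the kinematics.
#'
#' @param model a \code{tissue_model}.
#' @param F,L macroscopic deformation and velocity gradients.
#' @param state list with \code{t_ve} (4 x n_families matrix, N) and
#'   \code{R_ve} (length-5 vector, N); \code{NULL} means virgin state.
#' @param p incompressibility pressure (Pa).
#' @return List of class \code{stress_decomposition} with \code{sigma},
#'   \code{sigma_m}, \code{sigma_f}, \code{sigma_s}, \code{p}.
#' @export
totalStress <- function(model, F, L, state = NULL, p = 0) {
  if (is.null(state)) state <- virginState(model)
  bk <- bundleKinematics(F, L, model$geometry$directors)
  forces <- list()
  for (k in seq_along(model$families)) {
    nm <- names(model$families)[k]
    f <- model$families[[nm]]
    forces[[nm]] <- neutralFibrilForce(bk$eps, f$geom, f$el) + state$t_ve[, k]
  }
  s_m <- matrixCauchy(F, model$matrix)
  s_f <- sigmaFibril(model, bk, forces)
  if (!is.null(model$steric)) {
    nk <- neighborKinematics(F, L, model$geometry$neighbors, model$geometry$ell0)
    Rq <- ifelse(nk$contact, neutralStericForce(nk$eps, model$steric), 0) + state$R_ve
    s_s <- sigmaSteric(model, nk, Rq)
  } else s_s <- matrix(0, 3, 3)
  sig <- -p * diag(3) + s_m + s_f + s_s
  structure(list(sigma = sig, sigma_m = s_m, sigma_f = s_f, sigma_s = s_s, p = p),
            class = "stress_decomposition")
}

#' Virgin internal state
#'
#' Zero viscous forces for every bundle, family and steric neighbour; every
#' simulation starts here.
#'
#' @param model a \code{tissue_model}.
#' @export
virginState <- function(model) {
  list(t_ve = matrix(0, 4, length(model$families),
                     dimnames = list(NULL, names(model$families))),
       R_ve = numeric(5))
}
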