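#' Neutral (hyperelastic) fibril force
#'
#' Relaxed, rate-independent tension of one fibril as a function of its
#' chord log-strain \eqn{\varepsilon_i = \ln\lambda_i}. In the stretched
#' branch,
#' \deqn{t_i^e = \frac{\pi d_0^2}{4}\Big\{E_{eq}^0\varepsilon_i +
#'   \frac{E_f - E_{eq}^0}{2}\big[\varepsilon_i +
#'   \sqrt{(\varepsilon_i - \ln\xi_0)^2 + \alpha^2} -
#'   \sqrt{\ln^2\xi_0 + \alpha^2}\big]\Big\},}
#' whose tangent modulus transitions smoothly from the folded apparent
#' modulus \eqn{E_{eq}^0} (bending-dominated unfolding) to the fibril
#' modulus \eqn{E_f} (taut stretching) around \eqn{\varepsilon_i =
#' \ln\xi_0}, with \eqn{\alpha} setting the sharpness of the transition.
#' Under compression only the linear folded term is kept,
#' \eqn{t_i^e = (\pi d_0^2/4) E_{eq}^0 \varepsilon_i}.
#'
#' @param eps chord log-strain (may be a vector).
#' @param geom a \code{\link{fibrilGeometry}} (uses \code{d0}, \code{xi0}).
#' @param el list with elastic parameters \code{Ef}, \code{alpha},
#'   \code{Eeq0} (see \code{\link{fibrilElastic}}).
#' @return Force (N), same length as \code{eps}.
#' @export
neutralFibrilForce <- function(eps, geom, el) {
  stopifnot(all(is.finite(eps)))
  A <- pi * geom$d0^2 / 4
  lx <- log(geom$xi0)
  taut <- A * (el$Eeq0 * eps + (el$Ef - el$Eeq0) / 2 *
                 (eps + sqrt((eps - lx)^2 + el$alpha^2) - sqrt(lx^2 + el$alpha^2)))
  folded <- A * el$Eeq0 * eps
  ifelse(eps >= 0, taut, folded)
}

#' Elastic parameter set of a fibril family
#'
#' Derives the initial apparent folded modulus \code{Eeq0} from the family
#' geometry and stores it with \code{Ef} and the transition parameter
#' \code{alpha}.
#'
#' @param Ef fibril Young modulus (Pa).
#' @param alpha dimensionless bending-to-stretching transition parameter.
#' @param geom a \code{\link{fibrilGeometry}}.
#' @export
fibrilElastic <- function(Ef, alpha, geom) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  list(Ef = Ef, alpha = alpha,
       Eeq0 = apparentModulus(Ef, geom$d0, geom$R0, geom$H0))
}

#' Carreau viscosity of the fibril Maxwell branch
#'
#' The Maxwell dashpot viscosity is a Carreau function of the viscous
#' (dashpot) strain rate \eqn{\dot\varepsilon_i - 4\dot t_i^{ve}/(\pi E
#' d_0^2)}: Newtonian plateau \eqn{\eta_0} at low rates, power-law thinning
#' with index \eqn{n} above the transition rate \eqn{\dot\varepsilon_0}.
#'
#' @param edot_total total bundle strain rate (1/s).
#' @param tdot_ve rate of the viscous force (N/s).
#' @param p list with \code{E}, \code{eta0}, \code{edot0}, \code{n}.
#' @param d0 fibril diameter (m).
#' @return Viscosity (Pa s), in \eqn{(0, \eta_0]}.
#' @export
carreauViscosity <- function(edot_total, tdot_ve, p, d0) {
  u <- edot_total - 4 * tdot_ve / (pi * p$E * d0^2)
  p$eta0 * (1 + (u / p$edot0)^2)^((p$n - 1) / 2)
}

#' Residual of the non-linear Maxwell evolution of the viscous fibril force
#'
#' \deqn{\dot t_i^{ve} + \frac{E}{\eta}\, t_i^{ve} -
#'   \frac{\pi E d_0^2}{4}\dot\varepsilon_i,}
#' with \eqn{\eta} the Carreau viscosity of
#' \code{\link{carreauViscosity}} evaluated at the same arguments. The
#' equation is implicit in \eqn{\dot t_i^{ve}}.
#'
#' @param tdot_ve trial viscous force rate (N/s).
#' @param t_ve current viscous force (N).
#' @param edot total bundle strain rate (1/s).
#' @param p bundle viscoelastic parameters (\code{E}, \code{eta0},
#'   \code{edot0}, \code{n}).
#' @param d0 fibril diameter (m).
#' @return Residual (N/s).
#' @export
maxwellResidual <- function(tdot_ve, t_ve, edot, p, d0) {
  eta <- carreauViscosity(edot, tdot_ve, p, d0)
  tdot_ve + p$E / eta * t_ve - pi * p$E * d0^2 / 4 * edot
}

#' Neutral (hyperelastic) steric force
#'
#' Repulsive contact force between the central node and an unconnected
#' neighbour, active once the distance \eqn{\delta_q} has dropped below the
#' critical contact distance \eqn{\delta_c}, i.e. for contact strain
#' \eqn{\varepsilon_q = \ln(\delta_q/\delta_c) \le 0}:
#' \eqn{R_q^e = -\beta |\varepsilon_q|^\kappa} (negative scalar along
#' \eqn{e_q}: the stress contribution resists further approach). Zero when
#' there is no contact.
#'
#' @param eps_q contact log-strain \eqn{\ln(\delta_q/\delta_c)} (vectorised).
#' @param s steric parameters (\code{beta}, \code{kappa}).
#' @return Force (N), non-positive.
#' @export
neutralStericForce <- function(eps_q, s) {
  ifelse(eps_q < 0, -s$beta * abs(eps_q)^s$kappa, 0)
}

#' Carreau viscosity of the steric Maxwell branch
#'
#' Same form as \code{\link{carreauViscosity}} with the steric parameters
#' \eqn{(\eta_0', \dot\varepsilon_0', E', n)} and the steric strain rate.
#'
#' @param edot_q steric strain rate (1/s).
#' @param Rdot_ve rate of the viscous steric force (N/s).
#' @param s steric parameters (\code{Eprime}, \code{eta0prime},
#'   \code{edot0prime}, \code{n}).
#' @param d0 diameter of the collagen family carrying the contact (m).
#' @export
stericViscosity <- function(edot_q, Rdot_ve, s, d0) {
  u <- edot_q - 4 * Rdot_ve / (pi * s$Eprime * d0^2)
  s$eta0prime * (1 + (u / s$edot0prime)^2)^((s$n - 1) / 2)
}

#' Residual of the viscous steric force evolution
#'
#' \deqn{\dot R_q^{ve} + \frac{E'}{\eta'} R_q^{ve} -
#'   \frac{\pi E' d_0^2}{4}\dot\varepsilon_q.}
#' The driving prefactor \eqn{\pi E' d_0^2/4} mirrors the fibril Maxwell
#' equation, the only form dimensionally consistent with the
#' \eqn{4\dot R_q^{ve}/(\pi E' d_0^2)} term inside the Carreau argument.
#' The viscous steric force evolves only while the contact is active and
#' resets to zero when contact is lost (the dashpot force has no carrier
#' without contact); that bookkeeping lives in the drivers.
#'
#' @inheritParams stericViscosity
#' @param R_ve current viscous steric force (N).
#' @return Residual (N/s).
#' @export
stericResidual <- function(Rdot_ve, R_ve, edot_q, s, d0) {
  eta <- stericViscosity(edot_q, Rdot_ve, s, d0)
  Rdot_ve + s$Eprime / eta * R_ve - pi * s$Eprime * d0^2 / 4 * edot_q
}

#' Cauchy stress of the incompressible neo-Hookean matrix
#'
#' The matrix strain energy is \eqn{W = \tfrac12 \mu (1-\Phi)
#' (\mathrm{tr}(F F^T) - 3)}, giving the (pressure-free) Cauchy
#' contribution \eqn{\sigma_m = \mu (1-\Phi) F F^T}. The incompressibility
#' pressure is handled separately in the total stress assembly.
#'
#' @param F 3 x 3 deformation gradient with \eqn{\det F = 1}.
#' @param m list with \code{mu} (matrix shear modulus, Pa) and
#'   \code{phi_total} (total fibril volume fraction).
#' @return Symmetric 3 x 3 stress tensor (Pa).
#' @export
matrixCauchy <- function(F, m) {
  stopifnot(is.matrix(F), all(dim(F) == c(3L, 3L)))
  if (abs(det(F) - 1) > 1e-9)
    stop("F violates incompressibility: |det F - 1| > 1e-9")
  m$mu * (1 - m$phi_total) * tcrossprod(F)
}
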