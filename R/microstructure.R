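#' Tortuosity of a sinusoidally wavy fibril
#'
#' Fibril bundles are idealised as monomodal sinusoids of wave amplitude
#' \code{R0} and spatial periodicity \code{H0}. The tortuosity \eqn{\xi_0}
#' is the curvilinear length of one period divided by its chord \code{H0},
#' i.e. the arc length of \eqn{u \mapsto R_0 \sin(2\pi u/H_0)} over one
#' period, normalised by \code{H0}. A straight fibril (\code{R0 = 0}) has
#' tortuosity 1.
#'
#' @param R0 wave amplitude (m), non-negative.
#' @param H0 spatial periodicity (m), positive.
#' @return Dimensionless tortuosity \eqn{\xi_0 \ge 1}.
#' @examples
#' tortuosity(0, 42e-6)        # 1: straight fibril
#' tortuosity(5e-6, 42e-6)     # ~1.13: lamina propria collagen
#' @export
tortuosity <- function(R0, H0) {
  stopifnot(is.numeric(R0), is.numeric(H0), length(R0) == 1L, length(H0) == 1L)
  if (!is.finite(H0) || H0 <= 0) stop("H0 must be positive")
  if (!is.finite(R0) || R0 < 0) stop("R0 must be non-negative")
  if (R0 == 0) return(1)
  k <- 2 * pi * R0 / H0
  arc <- stats::integrate(function(u) sqrt(1 + (k * cos(2 * pi * u / H0))^2),
                          lower = 0, upper = H0,
                          rel.tol = 1e-10, subdivisions = 500L)
  arc$value / H0
}

#' Apparent modulus of a folded fibril
#'
#' Initial apparent Young modulus of a wavy (folded) fibril,
#' \deqn{E_{eq}^0 = E_f \langle\cos\beta_0\rangle /
#'   (\langle\cos^2\beta_0\rangle + 16 v^2/d_0^2),}
#' where \eqn{\beta_0(u) = \arctan((2\pi R_0/H_0)\cos(2\pi u/H_0))} is the
#' local tangent angle of the sinusoid, \eqn{v^2 = R_0^2/2} its mean-square
#' transverse deviation, and \eqn{\langle\cdot\rangle} the average over one
#' period. It interpolates between the bending-dominated folded stiffness
#' and the fibril material modulus: \eqn{E_{eq}^0 \to E_f} as
#' \eqn{R_0 \to 0} and decreases monotonically with waviness.
#'
#' @param Ef fibril Young modulus (Pa).
#' @param d0 fibril diameter (m).
#' @param R0 wave amplitude (m).
#' @param H0 spatial periodicity (m).
#' @return Apparent modulus (Pa), in \eqn{(0, E_f]}.
#' @export
apparentModulus <- function(Ef, d0, R0, H0) {
  stopifnot(length(Ef) == 1L, length(d0) == 1L, length(R0) == 1L, length(H0) == 1L)
  if (!is.finite(d0) || d0 <= 0) stop("d0 must be positive")
  if (!is.finite(Ef) || Ef <= 0) stop("Ef must be positive")
  if (!is.finite(H0) || H0 <= 0) stop("H0 must be positive")
  if (!is.finite(R0) || R0 < 0) stop("R0 must be non-negative")
  if (R0 == 0) return(Ef)
  k <- 2 * pi * R0 / H0
  beta0 <- function(u) atan(k * cos(2 * pi * u / H0))
  avg <- function(f) stats::integrate(f, 0, H0, rel.tol = 1e-10,
                                      subdivisions = 500L)$value / H0
  c1 <- avg(function(u) cos(beta0(u)))
  c2 <- avg(function(u) cos(beta0(u))^2)
  v2 <- R0^2 / 2
  Ef * c1 / (c2 + 16 * v2 / d0^2)
}

#' Bundle orientation directors of the representative elementary volume
#'
#' The REV carries four fibril bundles whose mean orientations are obtained
#' from one generating unit vector
#' \eqn{E = (\sin\theta_0\cos\varphi_0, \sin\theta_0\sin\varphi_0,
#' \cos\theta_0)} and its images under sign flips of the x and y components.
#' \code{theta0} is the polar angle from the longitudinal axis \eqn{e_z}
#' (anterior-posterior), \code{phi0} the azimuth from \eqn{e_x} in the
#' \eqn{(e_x, e_y)} plane. The resulting set is closed under reflection in
#' the \eqn{(e_x,e_z)} and \eqn{(e_y,e_z)} planes (orthotropic symmetry).
#'
#' @param theta0 polar angle (degrees), in \eqn{[0, 90]}.
#' @param phi0 azimuth (degrees), in \eqn{[0, 90]}.
#' @return A 4 x 3 matrix; rows are unit directors.
#' @export
buildDirectors <- function(theta0, phi0) {
  stopifnot(length(theta0) == 1L, length(phi0) == 1L)
  if (!is.finite(theta0) || theta0 < 0 || theta0 > 90)
    stop("theta0 must be in [0, 90] degrees")
  if (!is.finite(phi0) || phi0 < 0 || phi0 > 90)
    stop("phi0 must be in [0, 90] degrees")
  th <- theta0 * pi / 180
  ph <- phi0 * pi / 180
  x <- sin(th) * cos(ph)
  y <- sin(th) * sin(ph)
  z <- cos(th)
  m <- rbind(c( x,  y, z),
             c(-x,  y, z),
             c( x, -y, z),
             c(-x, -y, z))
  dimnames(m) <- list(paste0("E", 1:4), c("x", "y", "z"))
  m
}

#' Steric neighbour set of the REV
#'
#' The unconnected neighbours of the central node are the nearest nodes of
#' the periodically repeated REV: the network tiles space by translations
#' along the bundle chords, so candidate neighbour positions are the
#' non-zero lattice vectors \eqn{\ell_0 (E_i - E_j)} and
#' \eqn{\ell_0 (E_i + E_j)}, \eqn{i \ne j}. The five candidates with the
#' smallest distinct distances are retained (lexicographic tie-break on the
#' direction components).
#'
#' @param directors 4 x 3 matrix of unit directors (see
#'   \code{\link{buildDirectors}}).
#' @param ell0 initial chord length between nodes (m).
#' @param delta_c critical contact distance (m); stored with the set, may be
#'   \code{NA} when the tissue has no steric interaction channel.
#' @return A list with \code{dirs} (5 x 3 unit directions), \code{dists}
#'   (5 ascending distances, m) and \code{delta_c}.
#' @export
buildNeighbors <- function(directors, ell0, delta_c = NA_real_) {
  stopifnot(is.matrix(directors), nrow(directors) == 4L, ncol(directors) == 3L)
  if (!is.finite(ell0) || ell0 <= 0) stop("ell0 must be positive")
  cand <- list()
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    cand[[length(cand) + 1L]] <- directors[i, ] - directors[j, ]
    cand[[length(cand) + 1L]] <- directors[i, ] + directors[j, ]
  }
  cand <- do.call(rbind, cand)
  len <- sqrt(rowSums(cand^2))
  keep <- len > 1e-12
  cand <- cand[keep, , drop = FALSE]
  len <- len[keep]
  # order by (distance, then lexicographic on direction components)
  dirs <- cand / len
  ord <- order(len, dirs[, 1], dirs[, 2], dirs[, 3])
  len <- len[ord]; dirs <- dirs[ord, , drop = FALSE]
  # distinct distances within a relative tolerance
  grp <- cumsum(c(TRUE, diff(len) > 1e-9 * len[-1]))
  first <- !duplicated(grp)
  len <- len[first]; dirs <- dirs[first, , drop = FALSE]
  if (nrow(dirs) < 5L)
    stop("degenerate director set: fewer than five distinct neighbour distances")
  out <- list(dirs = dirs[1:5, , drop = FALSE],
              dists = ell0 * len[1:5],
              delta_c = delta_c)
  dimnames(out$dirs) <- list(paste0("Eq", 1:5), c("x", "y", "z"))
  class(out) <- "rev_neighbors"
  out
}

#' Reference geometry of the representative elementary volume
#'
#' Assembles the four bundle directors and the five steric neighbour
#' directions/distances of the REV. When a steric interaction channel is
#' present (\code{delta_c} finite), the neighbour distances are rescaled so
#' that the nearest neighbour rests at \code{(1 + contactClearance) *
#' delta_c} while direction set and distance ratios are preserved
#' (near-contact packing: the fitted contact distance is only meaningful if
#' the rest gaps are of its order; the raw lattice distances are an
#' artefact of the affine node construction). With the default clearance of
#' 0.05 the first contact engages at about 5\% approach strain along the
#' nearest neighbour direction.
#'
#' @param theta0,phi0 bundle orientation angles (degrees).
#' @param ell0 initial chord length (m).
#' @param delta_c critical contact distance (m) or \code{NA}.
#' @param contactClearance relative rest clearance of the nearest neighbour
#'   above \code{delta_c}.
#' @return An object of class \code{rev_geometry} with elements
#'   \code{directors}, \code{neighbors}, \code{theta0}, \code{phi0},
#'   \code{ell0}.
#' @export
revGeometry <- function(theta0, phi0, ell0, delta_c = NA_real_,
                        contactClearance = 0.05) {
  directors <- buildDirectors(theta0, phi0)
  nb <- buildNeighbors(directors, ell0, delta_c)
  if (is.finite(delta_c)) {
    stopifnot(delta_c > 0, contactClearance > 0)
    nb$dists <- nb$dists * (1 + contactClearance) * delta_c / nb$dists[1]
  }
  structure(list(directors = directors, neighbors = nb,
                 theta0 = theta0, phi0 = phi0, ell0 = ell0),
            class = "rev_geometry")
}

#' Fibril family geometry
#'
#' Bundles the histological descriptors of one fibril family (collagen
#' fibrils of the lamina propria, or collagen/myofibrils of the vocalis)
#' with the derived quantities: chord length \code{ell0 = 10 * H0},
#' tortuosity \code{xi0}, and mean-square transverse deviation
#' \code{vsq = R0^2/2}.
#'
#' @param d0 fibril diameter (m).
#' @param R0 wave amplitude (m).
#' @param H0 spatial periodicity (m).
#' @param phi volume fraction of the family, in (0, 1).
#' @return An object of class \code{fibril_geometry}.
#' @export
fibrilGeometry <- function(d0, R0, H0, phi) {
  if (!is.finite(d0) || d0 <= 0) stop("d0 must be positive")
  if (!is.finite(H0) || H0 <= 0) stop("H0 must be positive")
  if (!is.finite(R0) || R0 < 0) stop("R0 must be non-negative")
  if (!is.finite(phi) || phi <= 0 || phi >= 1) stop("phi must be in (0, 1)")
  structure(list(d0 = d0, R0 = R0, H0 = H0, phi = phi,
                 ell0 = 10 * H0, xi0 = tortuosity(R0, H0), vsq = R0^2 / 2),
            class = "fibril_geometry")
}
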