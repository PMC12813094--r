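#' Assemble a tissue model
#'
#' Builds the full parameter bundle for one tissue sample: REV geometry,
#' per-family fibril geometry and elasticity, shared bundle viscoelasticity,
#' optional steric interaction channel, and matrix parameters. All inputs
#' are SI (m, Pa, s, N); use \code{\link{readTissueModel}} for configuration
#' files in micrometres and megapascals.
#'
#' The lamina propria carries a single collagen family; the vocalis carries
#' a myofibril family sheathed by a collagen family. Both families share
#' the bundle directors and the viscoelastic parameters \code{E},
#' \code{eta0}, \code{edot0}, \code{n}. The REV chord length is
#' \code{10 * H0} of the bundle-defining family (the myofibril family when
#' present, otherwise the collagen family); the steric channel uses the
#' collagen-family diameter.
#'
#' @param kind \code{"lamina_propria"} or \code{"vocalis"}.
#' @param theta0,phi0 bundle orientation angles (degrees).
#' @param families named list of families; each element a list with
#'   \code{d0}, \code{R0}, \code{H0}, \code{phi}, \code{Ef}, \code{alpha}.
#'   Names \code{"collagen"} and (for the vocalis) \code{"myofibril"}.
#' @param mu matrix shear modulus (Pa).
#' @param visco list with \code{E}, \code{eta0}, \code{edot0}, \code{n}
#'   (Pa, Pa s, 1/s, dimensionless).
#' @param steric optional list with \code{beta}, \code{kappa},
#'   \code{delta_c}, \code{Eprime}, \code{eta0prime}, \code{edot0prime}
#'   (N, -, m, Pa, Pa s, 1/s); \code{NULL} disables steric interactions.
#' @param contactClearance rest clearance of the nearest steric neighbour,
#'   see \code{\link{revGeometry}}.
#' @param sample optional sample label.
#' @return An object of class \code{tissue_model}.
#' @export
tissueModel <- function(kind = c("lamina_propria", "vocalis"),
                        theta0, phi0, families, mu, visco,
                        steric = NULL, contactClearance = 0.05,
                        sample = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.list(families), length(families) >= 1L)
  fam <- lapply(families, function(f) {
    geom <- fibrilGeometryZeroOk(f$d0, f$R0, f$H0, f$phi)
    list(geom = geom, el = fibrilElastic(f$Ef, f$alpha, geom))
  })
  phi_total <- sum(vapply(fam, function(f) f$geom$phi, 0))
  if (phi_total >= 1) stop("total fibril volume fraction must be < 1")
  if (!is.finite(mu) || mu <= 0) stop("mu must be positive")
  for (nm in c("E", "eta0", "edot0", "n"))
    if (length(visco[[nm]]) != 1L || !is.finite(visco[[nm]]))
      stop("viscoelastic parameter '", nm, "' must be a finite scalar")
  stopifnot(visco$E > 0, visco$eta0 > 0, visco$edot0 > 0,
            visco$n >= 0, visco$n <= 1)
  if (!is.null(steric)) {
    stopifnot(steric$beta > 0, steric$kappa >= 1, steric$delta_c > 0,
              steric$Eprime > 0, steric$eta0prime > 0, steric$edot0prime > 0)
    steric$n <- visco$n
  }
  chordFam <- if ("myofibril" %in% names(fam)) "myofibril" else names(fam)[1]
  ell0 <- fam[[chordFam]]$geom$ell0
  geometry <- revGeometry(theta0, phi0, ell0,
                          delta_c = if (is.null(steric)) NA_real_ else steric$delta_c,
                          contactClearance = contactClearance)
  # stress prefactors, Eqs. for sigma_f / sigma_s: Phi / ((pi d0^2/4) xi0)
  pref <- vapply(fam, function(f)
    4 * f$geom$phi / (pi * f$geom$d0^2 * f$geom$xi0), 0)
  collagenFam <- if ("collagen" %in% names(fam)) "collagen" else names(fam)[1]
  structure(list(kind = kind, sample = sample,
                 families = fam, visco = visco, steric = steric,
                 matrix = list(mu = mu, phi_total = phi_total),
                 geometry = geometry,
                 prefactors = pref,
                 steric_prefactor = sum(pref),
                 steric_d0 = fam[[collagenFam]]$geom$d0,
                 spec = list(kind = kind, theta0 = theta0, phi0 = phi0,
                             families = families, mu = mu, visco = visco,
                             steric = steric,
                             contactClearance = contactClearance,
                             sample = sample)),
            class = "tissue_model")
}

# like fibrilGeometry() but permits phi = 0 (fibril-free limit used by the
# neo-Hookean sanity checks)
fibrilGeometryZeroOk <- function(d0, R0, H0, phi) {
  if (identical(phi, 0) || identical(phi, 0L)) {
    g <- fibrilGeometry(d0, R0, H0, 0.5)
    g$phi <- 0
    g
  } else fibrilGeometry(d0, R0, H0, phi)
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("<tissue_model>", if (!is.null(x$sample)) paste0(" sample ", x$sample), "\n",
      sep = "")
  cat("  kind:      ", x$kind, "\n")
  cat("  families:  ", paste(names(x$families), collapse = ", "),
      " (phi total ", signif(x$matrix$phi_total, 3), ")\n", sep = "")
  for (nm in names(x$families)) {
    f <- x$families[[nm]]
    cat(sprintf("    %-10s d0 %.3g um, xi0 %.3f, Ef %.3g MPa, Eeq0 %.3g kPa\n",
                nm, f$geom$d0 * 1e6, f$geom$xi0, f$el$Ef / 1e6, f$el$Eeq0 / 1e3))
  }
  cat(sprintf("  matrix:     mu %.3g Pa\n", x$matrix$mu))
  v <- x$visco
  cat(sprintf("  bundle ve:  E %.3g MPa, eta0 %.3g MPa s, edot0 %.3g /s, n %.2f (tau %.3g s)\n",
              v$E / 1e6, v$eta0 / 1e6, v$edot0, v$n, v$eta0 / v$E))
  if (!is.null(x$steric)) {
    s <- x$steric
    cat(sprintf("  steric:     beta %.3g N, kappa %g, delta_c %.3g um, E' %.3g MPa, eta0' %.3g MPa s\n",
                s$beta, s$kappa, s$delta_c * 1e6, s$Eprime / 1e6, s$eta0prime / 1e6))
  } else cat("  steric:     none\n")
  cat(sprintf("  directors:  theta0 %g deg, phi0 %g deg, ell0 %.3g um\n",
              x$geometry$theta0, x$geometry$phi0, x$geometry$ell0 * 1e6))
  invisible(x)
}

#' Modify a tissue model
#'
#' Returns a rebuilt model with selected parameters replaced. Recognised
#' names: \code{phi}, \code{d0}, \code{R0}, \code{H0}, \code{Ef},
#' \code{alpha} (applied to \code{family}, default the first),
#' \code{mu}, \code{theta0}, \code{phi0}, the viscoelastic parameters
#' \code{E}, \code{eta0}, \code{edot0}, \code{n}, and the steric parameters
#' \code{beta}, \code{kappa}, \code{delta_c}, \code{Eprime},
#' \code{eta0prime}, \code{edot0prime}.
#'
#' @param model a \code{tissue_model}.
#' @param ... named replacements (SI units).
#' @param family family name the geometric/elastic replacements apply to.
#' @export
modifyTissue <- function(model, ..., family = NULL) {
  stopifnot(inherits(model, "tissue_model"))
  upd <- list(...)
  sp <- model$spec
  if (is.null(family)) family <- names(sp$families)[1]
  famKeys <- c("phi", "d0", "R0", "H0", "Ef", "alpha")
  viscoKeys <- c("E", "eta0", "edot0", "n")
  stericKeys <- c("beta", "kappa", "delta_c", "Eprime", "eta0prime", "edot0prime")
  for (nm in names(upd)) {
    if (nm %in% famKeys) sp$families[[family]][[nm]] <- upd[[nm]]
    else if (nm %in% viscoKeys) sp$visco[[nm]] <- upd[[nm]]
    else if (nm %in% stericKeys) {
      if (is.null(sp$steric)) stop("model has no steric channel")
      sp$steric[[nm]] <- upd[[nm]]
    }
    else if (nm %in% c("mu", "theta0", "phi0", "contactClearance", "sample"))
      sp[[nm]] <- upd[[nm]]
    else stop("unknown parameter: ", nm)
  }
  tissueModel(kind = sp$kind, theta0 = sp$theta0, phi0 = sp$phi0,
              families = sp$families, mu = sp$mu, visco = sp$visco,
              steric = sp$steric, contactClearance = sp$contactClearance,
              sample = sp$sample)
}

#' Disable the steric interaction channel
#'
#' Convenience for the "no steric interactions" ablation: returns the same
#' model with \eqn{\sigma_s \equiv 0}.
#'
#' @param model a \code{tissue_model}.
#' @export
disableSteric <- function(model) {
  stopifnot(inherits(model, "tissue_model"))
  sp <- model$spec
  tissueModel(kind = sp$kind, theta0 = sp$theta0, phi0 = sp$phi0,
              families = sp$families, mu = sp$mu, visco = sp$visco,
              steric = NULL, contactClearance = sp$contactClearance,
              sample = sp$sample)
}
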