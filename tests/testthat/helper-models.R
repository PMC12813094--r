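# Shared fixtures: models are built in code, never stored.

# fibril-free (matrix-only) model: exact incompressible neo-Hookean
toyMatrixModel <- function(mu = 31) {
  tissueModel("lamina_propria", 10.5, 83.7,
              families = list(collagen = list(d0 = 0.21e-6, R0 = 7.3e-6,
                                              H0 = 34.5e-6, phi = 0,
                                              Ef = 720e6, alpha = 1.6e-3)),
              mu = mu,
              visco = list(E = 3.68e6, eta0 = 1.56e6, edot0 = 2.1e-3, n = 0.27))
}

# wavy-fibril model with Newtonian dashpot (n = 1): a linear
# standard-linear-solid whose small-strain moduli have closed forms; a
# small d0 makes the folded (neutral) stiffness negligible against the
# Maxwell branch, approaching a pure Maxwell fluid
linearSLSModel <- function(E = 1e6, eta0 = 5e5, mu = 10, phi = 0.3,
                           theta0 = 45, phi0 = 20, d0 = 0.4e-6) {
  tissueModel("lamina_propria", theta0, phi0,
              families = list(collagen = list(d0 = d0, R0 = 7.3e-6,
                                              H0 = 34.5e-6, phi = phi,
                                              Ef = 720e6, alpha = 1e-3)),
              mu = mu,
              visco = list(E = E, eta0 = eta0, edot0 = 1e-3, n = 1))
}

# independent trapezoidal loop-area accounting used by energy tests
.loopAreaTest <- function(stress, strain) {
  n <- length(stress)
  sum((stress[-1] + stress[-n]) / 2 * diff(strain))
}

# analytic small-strain moduli of the linearised network: each bundle's
# Zener stiffness projected through (E_z E_x)^2 plus the matrix term.
# Independent closed-form oracle for gamma0 << 1 in the Newtonian regime.
slsModuliOracle <- function(model, f) {
  g <- model$geometry$directors
  v <- model$visco
  tau <- v$eta0 / v$E
  w <- 2 * pi * f
  Gp <- model$matrix$mu * (1 - model$matrix$phi_total)
  Gpp <- 0
  for (fam in model$families) {
    S <- sum((g[, "z"] * g[, "x"])^2)
    lx <- log(fam$geom$xi0); a <- fam$el$alpha
    Etan <- fam$el$Eeq0 + (fam$el$Ef - fam$el$Eeq0) / 2 *
      (1 - lx / sqrt(lx^2 + a^2))
    Ebar <- (Etan + fam$el$Eeq0) / 2    # mean of taut/folded branch tangents
    pref <- fam$geom$phi / fam$geom$xi0
    Gp <- Gp + pref * S * (Ebar + v$E * w^2 * tau^2 / (1 + w^2 * tau^2))
    Gpp <- Gpp + pref * S * v$E * w * tau / (1 + w^2 * tau^2)
  }
  c(G_storage = Gp, G_loss = Gpp)
}

# rotation matrix about an arbitrary axis (objectivity checks)
rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s0 * K + (1 - c0) * K %*% K
}
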