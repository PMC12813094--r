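geomCS <- fibrilGeometry(0.21e-6, 7.3e-6, 34.5e-6, 0.30)
elCS <- fibrilElastic(720e6, 1.6e-3, geomCS)

test_that("neutral fibril force vanishes at zero strain and is linear in compression", {
  expect_equal(neutralFibrilForce(0, geomCS, elCS), 0)
  A <- pi * geomCS$d0^2 / 4
  expect_equal(neutralFibrilForce(-0.1, geomCS, elCS), -A * elCS$Eeq0 * 0.1)
  # compression branch is exactly linear
  eps <- -c(0.01, 0.05, 0.2)
  expect_equal(neutralFibrilForce(eps, geomCS, elCS), A * elCS$Eeq0 * eps)
})

test_that("tangent stiffness transitions from Eeq0 to Ef", {
  A <- pi * geomCS$d0^2 / 4
  lx <- log(geomCS$xi0)
  fd <- function(e, h = 1e-7) {
    (neutralFibrilForce(e + h, geomCS, elCS) -
       neutralFibrilForce(e - h, geomCS, elCS)) / (2 * h)
  }
  # near the origin the stretched-branch tangent is Eeq0 plus the small
  # alpha-smoothed remainder of the taut term
  Etan0 <- elCS$Eeq0 + (elCS$Ef - elCS$Eeq0) / 2 *
    (1 - lx / sqrt(lx^2 + elCS$alpha^2))
  expect_equal(fd(1e-5, h = 1e-6) / (A * Etan0), 1, tolerance = 1e-2)
  # deep in the taut regime the tangent approaches Ef (alpha << ln xi0)
  expect_equal(fd(3 * lx) / (A * elCS$Ef), 1, tolerance = 0.02)
})

test_that("Carreau viscosity has plateau, half-power point and thinning slope", {
  p <- list(E = 3.68e6, eta0 = 1.56e6, edot0 = 2.1e-3, n = 0.27)
  d0 <- 0.21e-6
  A <- pi * d0^2 / 4
  # zero viscous rate (spring absorbs everything): Newtonian plateau
  edot <- 5e-3
  expect_equal(carreauViscosity(edot, A * p$E * edot, p, d0), p$eta0)
  # viscous rate exactly edot0
  expect_equal(carreauViscosity(p$edot0, 0, p, d0),
               p$eta0 * 2^((p$n - 1) / 2))
  # log-log slope at high viscous rates -> n - 1
  r1 <- 100 * p$edot0; r2 <- 1000 * p$edot0
  sl <- (log(carreauViscosity(r2, 0, p, d0)) -
           log(carreauViscosity(r1, 0, p, d0))) / (log(r2) - log(r1))
  expect_equal(sl, p$n - 1, tolerance = 0.01)
  # n = 1 collapses to the constant plateau
  p1 <- list(E = 1e6, eta0 = 2e5, edot0 = 1e-3, n = 1)
  expect_equal(carreauViscosity(10, 0, p1, d0), p1$eta0)
})

test_that("Maxwell residual has the stated equilibrium and steady state", {
  p <- list(E = 3.68e6, eta0 = 1.56e6, edot0 = 2.1e-3, n = 0.27)
  d0 <- 0.21e-6
  A <- pi * d0^2 / 4
  expect_equal(maxwellResidual(0, 0, 0, p, d0), 0)
  # steady state at constant rate: t_ve = A eta(edot) edot (tdot = 0)
  for (edot in c(1e-4, 5e-3, 0.3)) {
    t_inf <- A * p$eta0 * (1 + (edot / p$edot0)^2)^((p$n - 1) / 2) * edot
    expect_equal(maxwellResidual(0, t_inf, edot, p, d0), 0,
                 tolerance = 1e-12 * A * p$E * edot)
    # and the root-finder reaches it from a long constant-rate run
    ts <- zenerStep(rep(0, 1), edot, 1e5 / max(edot / 1e-3, 1), p$E, p$eta0,
                    p$edot0, p$n, d0)
    expect_equal(ts / t_inf, 1, tolerance = 1e-3)
  }
})

test_that("step strain then hold relaxes exponentially in the Newtonian regime", {
  p <- list(E = 3.68e6, eta0 = 1.56e6, edot0 = 2.1e-3, n = 0.27)
  d0 <- 0.21e-6
  A <- pi * d0^2 / 4
  # small ramp then hold: rates << edot0 so eta = eta0, tau = eta0/E
  tau <- p$eta0 / p$E
  t_ramp <- A * p$E * 1e-5           # viscous force right after a fast ramp
  tve <- t_ramp
  dt <- tau / 200
  for (k in 1:200) tve <- zenerStep(tve, 0, dt, p$E, p$eta0, p$edot0, p$n, d0)
  expect_equal(tve / (t_ramp * exp(-1)), 1, tolerance = 0.01)
})

test_that("neutral steric force is a one-sided power-law repulsion", {
  s <- list(beta = 2e-4, kappa = 3)
  expect_identical(neutralStericForce(log(2), s), 0)     # delta = 2 delta_c
  expect_identical(neutralStericForce(0, s), 0)          # contact onset
  expect_equal(neutralStericForce(-0.1, s), -2e-4 * 0.1^3)
  expect_true(all(neutralStericForce(seq(-1, 1, by = 0.1), s) <= 0))
})

test_that("steric viscosity and residual mirror the bundle laws", {
  s <- list(Eprime = 0.99e6, eta0prime = 8.3e6, edot0prime = 5.5e-3, n = 0.27,
            beta = 2e-4, kappa = 3)
  d0 <- 0.4e-6
  A <- pi * d0^2 / 4
  expect_equal(stericViscosity(1e-2, A * s$Eprime * 1e-2, s, d0), s$eta0prime)
  expect_equal(stericViscosity(s$edot0prime, 0, s, d0),
               s$eta0prime * 2^((s$n - 1) / 2))
  expect_equal(stericResidual(0, 0, 0, s, d0), 0)
  # steady state fixed point
  edot <- 2e-3
  R_inf <- A * s$eta0prime * (1 + (edot / s$edot0prime)^2)^((s$n - 1) / 2) * edot
  expect_equal(stericResidual(0, R_inf, edot, s, d0), 0,
               tolerance = 1e-12 * A * s$Eprime * edot)
  # relaxation time at small rates is eta0'/E' (= 8.3/0.99 s here)
  expect_equal(s$eta0prime / s$Eprime, 8.3 / 0.99)
})

test_that("matrix stress is neo-Hookean and enforces incompressibility", {
  m <- list(mu = 200, phi_total = 0.46)
  expect_equal(matrixCauchy(diag(3), m), m$mu * (1 - m$phi_total) * diag(3))
  F <- diag(3); F[3, 1] <- 0.1
  S <- matrixCauchy(F, m)
  expect_equal(S[3, 1], m$mu * (1 - m$phi_total) * 0.1)
  lam <- 1.1
  F <- diag(c(lam^-0.5, lam^-0.5, lam))
  S <- matrixCauchy(F, m)
  expect_equal(S[3, 3] - S[1, 1], m$mu * (1 - m$phi_total) * (lam^2 - 1 / lam))
  expect_error(matrixCauchy(diag(c(1.1, 1, 1)), m), "incompressibility")
})

test_that("quasi-static loading collapses the total force onto the neutral branch", {
  # at vanishing rate the viscous part (bounded by eta * edot) vanishes
  p <- list(E = 1.47e6, eta0 = 14.2e6, edot0 = 5e-4, n = 0.27)
  d0 <- 0.4e-6
  edot <- 1e-9
  tve <- 0
  for (k in 1:100) tve <- zenerStep(tve, edot, 1e6, p$E, p$eta0, p$edot0, p$n, d0)
  geom <- fibrilGeometry(d0, 5e-6, 42e-6, 0.46)
  el <- fibrilElastic(847e6, 4.4e-3, geom)
  peak <- abs(neutralFibrilForce(0.1, geom, el))
  expect_lt(abs(tve), 0.005 * peak)
})

test_that("viscous dissipation over a closed strain cycle is non-negative", {
  p <- list(E = 3.68e6, eta0 = 1.56e6, edot0 = 2.1e-3, n = 0.27)
  d0 <- 0.21e-6
  A <- pi * d0^2 / 4
  for (amp in c(1e-4, 5e-3, 5e-2)) {
    nstep <- 400
    eps <- amp * sin(2 * pi * (1:nstep) / nstep)
    dt <- 0.02 / nstep
    edot <- c(eps[1], diff(eps)) / dt
    tve <- numeric(nstep); x <- 0
    for (k in 1:nstep) {
      x <- zenerStep(x, edot[k], dt, p$E, p$eta0, p$edot0, p$n, d0)
      tve[k] <- x
    }
    # run a second cycle to a closed loop
    for (rep in 1:2) for (k in 1:nstep) {
      x <- zenerStep(x, edot[k], dt, p$E, p$eta0, p$edot0, p$n, d0)
      tve[k] <- x
    }
    work <- sum(tve * edot * dt)                 # = dissipation + d(spring)/cycle
    expect_gte(work, -1e-12 * A * p$E * amp)
  }
})
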