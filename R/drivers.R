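# Loading-program drivers: advance the coupled system (affine kinematics +
# internal viscous-force ODEs) through oscillatory shear, cyclic shear and
# cyclic uniaxial programs under strain control with incompressibility.
# Shear convention: F = I + gamma * ez (x) ex (displacement along ez,
# gradient along ex); only the symmetric sigma_zx is reported. Pressure is
# fixed per step by a traction-free condition (sigma_yy = 0 in shear; zero
# lateral normal stresses in uniaxial modes). All programs start from the
# virgin state (zero internal forces).

.IDX <- c(x = 1L, y = 2L, z = 3L)

.advanceState <- function(model, state, bk, nk, dt, viscous = TRUE) {
  if (!viscous) return(state)
  v <- model$visco
  for (k in seq_along(model$families)) {
    d0 <- model$families[[k]]$geom$d0
    state$t_ve[, k] <- zenerStep(state$t_ve[, k], bk$edot, dt,
                                 v$E, v$eta0, v$edot0, v$n, d0)
  }
  if (!is.null(model$steric) && !is.null(nk)) {
    s <- model$steric
    Rnew <- numeric(5)               # contact lost -> dashpot force reset
    act <- nk$contact
    if (any(act))
      Rnew[act] <- zenerStep(state$R_ve[act], nk$edot[act], dt,
                             s$Eprime, s$eta0prime, s$edot0prime, s$n,
                             model$steric_d0)
    state$R_ve <- Rnew
  }
  state
}

.stressParts <- function(model, F, L, state) {
  bk <- bundleKinematics(F, L, model$geometry$directors)
  forces <- list()
  for (k in seq_along(model$families)) {
    nm <- names(model$families)[k]
    f <- model$families[[nm]]
    forces[[nm]] <- neutralFibrilForce(bk$eps, f$geom, f$el) + state$t_ve[, k]
  }
  s_f <- sigmaFibril(model, bk, forces)
  s_m <- matrixCauchy(F, model$matrix)
  if (!is.null(model$steric)) {
    nk <- neighborKinematics(F, L, model$geometry$neighbors, model$geometry$ell0)
    Rq <- ifelse(nk$contact, neutralStericForce(nk$eps, model$steric), 0) +
      state$R_ve
    s_s <- sigmaSteric(model, nk, Rq)
  } else {
    nk <- NULL; Rq <- numeric(5); s_s <- matrix(0, 3, 3)
  }
  list(s = s_m + s_f + s_s, s_m = s_m, s_f = s_f, s_s = s_s,
       bk = bk, nk = nk, Rq = Rq)
}

.newTraj <- function(n, model, mode) {
  nfam <- length(model$families)
  list(mode = mode, model = model,
       time = numeric(n), strain = numeric(n),
       F = matrix(0, n, 4, dimnames = list(NULL, c("zz", "xx", "yy", "zx"))),
       sigma = matrix(0, n, 4, dimnames = list(NULL, c("zz", "xx", "yy", "zx"))),
       sigma_m = matrix(0, n, 4), sigma_f = matrix(0, n, 4),
       sigma_s = matrix(0, n, 4), p = numeric(n),
       eps_i = matrix(0, n, 4), lambda_i = matrix(0, n, 4),
       t_ve = matrix(0, n, 4 * nfam),
       R_ve = matrix(0, n, 5), contact = matrix(FALSE, n, 5),
       cycles = NULL, steadyCycle = NA_integer_)
}

.recordStep <- function(tr, i, t, strain, F, parts, state, p) {
  comp <- function(S) c(S[3, 3], S[1, 1], S[2, 2], S[3, 1])
  tr$time[i] <- t; tr$strain[i] <- strain
  tr$F[i, ] <- c(F[3, 3], F[1, 1], F[2, 2], F[3, 1])
  tr$sigma[i, ] <- comp(parts$s) - c(p, p, p, 0)
  tr$sigma_m[i, ] <- comp(parts$s_m)
  tr$sigma_f[i, ] <- comp(parts$s_f)
  tr$sigma_s[i, ] <- comp(parts$s_s)
  tr$p[i] <- p
  tr$eps_i[i, ] <- parts$bk$eps
  tr$lambda_i[i, ] <- parts$bk$lambda
  tr$t_ve[i, ] <- as.vector(state$t_ve)
  if (!is.null(parts$nk)) {
    tr$R_ve[i, ] <- state$R_ve
    tr$contact[i, ] <- parts$nk$contact
  }
  tr
}

.truncTraj <- function(tr, n) {
  for (nm in c("time", "strain", "p")) tr[[nm]] <- tr[[nm]][seq_len(n)]
  for (nm in c("F", "sigma", "sigma_m", "sigma_f", "sigma_s",
               "eps_i", "lambda_i", "t_ve", "R_ve", "contact"))
    tr[[nm]] <- tr[[nm]][seq_len(n), , drop = FALSE]
  tr
}

.loopArea <- function(stress, strain) {
  # signed area of the (strain, stress) loop; positive for clockwise
  # traversal under increasing-then-decreasing strain (dissipation > 0)
  n <- length(stress)
  sum((stress[-1] + stress[-n]) / 2 * diff(strain))
}

.shearF <- function(g) { F <- diag(3); F[3, 1] <- g; F }
.shearL <- function(gd) { L <- matrix(0, 3, 3); L[3, 1] <- gd; L }

# lean backward-Euler recursion of the Zener forces along a whole strain
# path: edotMat is steps x elements, returns the viscous-force matrix
.zenerSeries <- function(t0, edotMat, dt, E, eta0, edot0, n, A) {
  ns <- nrow(edotMat); k <- ncol(edotMat)
  out <- matrix(0, ns, k)
  AE <- A * E
  ex1 <- (n - 1) / 2; ex2 <- (1 - n) / 2
  x <- t0
  for (s in seq_len(ns)) {
    ed <- edotMat[s, ]
    xprev <- x
    drive <- AE * ed
    tol <- 1e-12 * AE * pmax(abs(ed), edot0)
    eta_p <- eta0 * (1 + (ed / edot0)^2)^ex1
    x <- (xprev / dt + drive) / (1 / dt + E / eta_p)
    scale <- pmax(abs(x), abs(xprev), AE * pmax(abs(ed), edot0) * dt, 1e-300)
    ok <- FALSE
    for (it in 1:40) {
      u <- ed - (x - xprev) / (dt * AE)
      w <- 1 + (u / edot0)^2
      inv_eta <- w^ex2 / eta0
      r <- (x - xprev) / dt + E * inv_eta * x - drive
      if (all(abs(r) <= tol)) { ok <- TRUE; break }
      dinv <- ((1 - n) * u / edot0^2) * w^(ex2 - 1) / eta0
      dr <- 1 / dt + E * (inv_eta - x * dinv / (dt * AE))
      stp <- r / dr
      stp[!is.finite(stp)] <- 0
      x <- x - sign(stp) * pmin(abs(stp), 10 * scale)
    }
    if (!ok) {
      u <- ed - (x - xprev) / (dt * AE)
      r <- (x - xprev) / dt + E * (1 + (u / edot0)^2)^ex2 / eta0 * x - drive
      for (j in which(abs(r) > tol | !is.finite(x)))
        x[j] <- .zenerBisect(xprev[j], ed[j], dt, E, eta0, edot0, n, AE,
                             tol[j], scale[j])
      if (any(!is.finite(x)))
        stop("implicit Zener update failed to converge")
    }
    out[s, ] <- x
  }
  out
}

# fast strain-controlled simple-shear integrator: kinematics and stress
# assembly vectorised per cycle; falls back to the generic per-step loop
# when a steric contact engages during shear (rare: simple shear barely
# shortens the neighbour gaps)
.runShearPath <- function(model, time, gamma, gammadot, cycleStarts,
                          mode, detectSteady = FALSE, steadyTol = 0.005,
                          viscous = TRUE) {
  dirs <- model$geometry$directors
  if (!is.null(model$steric)) {
    nb <- model$geometry$neighbors
    qz <- outer(gamma, nb$dirs[, "x"]) +
      matrix(nb$dirs[, "z"], length(gamma), 5, byrow = TRUE)
    stretch2 <- qz^2 + matrix(nb$dirs[, "x"]^2 + nb$dirs[, "y"]^2,
                              length(gamma), 5, byrow = TRUE)
    delta <- sqrt(stretch2) * matrix(nb$dists, length(gamma), 5, byrow = TRUE)
    if (any(delta <= nb$delta_c))
      return(.runShearPathGeneric(model, time, gamma, gammadot, cycleStarts,
                                  mode, detectSteady, steadyTol, viscous))
  }
  n <- length(time)
  nfam <- length(model$families)
  tr <- .newTraj(n, model, mode)
  Ex <- dirs[, "x"]; Ey <- dirs[, "y"]; Ez <- dirs[, "z"]
  muT <- model$matrix$mu * (1 - model$matrix$phi_total)
  state <- matrix(0, 4, nfam)          # running t_ve
  areas <- numeric(0)
  nCycles <- length(cycleStarts) - 1L
  lastRecorded <- 1L
  for (ic in seq_len(nCycles)) {
    idx <- if (ic == 1L) seq(cycleStarts[1], cycleStarts[2])
           else seq(cycleStarts[ic] + 1L, cycleStarts[ic + 1L])
    g <- gamma[idx]; gd <- gammadot[idx]
    Vz <- outer(g, Ex) + matrix(Ez, length(g), 4, byrow = TRUE)
    lam <- sqrt(Vz^2 + matrix(Ex^2 + Ey^2, length(g), 4, byrow = TRUE))
    ezc <- Vz / lam
    exc <- matrix(Ex, length(g), 4, byrow = TRUE) / lam
    eyc <- matrix(Ey, length(g), 4, byrow = TRUE) / lam
    eps <- log(lam)
    edot <- gd * ezc * exc
    sf <- matrix(0, length(g), 4)      # zz xx yy zx
    for (k in seq_len(nfam)) {
      f <- model$families[[k]]
      te <- neutralFibrilForce(eps, f$geom, f$el)
      if (viscous) {
        first <- if (ic == 1L) 2L else 1L   # row 1 of cycle 1 is t = 0
        tve <- matrix(0, length(g), 4)
        if (length(idx) >= first) {
          dt <- time[2L] - time[1L]    # uniform grid by construction
          v <- model$visco
          tve[first:length(g), ] <-
            .zenerSeries(state[, k], edot[first:length(g), , drop = FALSE],
                         dt, v$E, v$eta0, v$edot0, v$n,
                         pi * f$geom$d0^2 / 4)
          if (ic == 1L) tve[1L, ] <- 0
        }
        state[, k] <- tve[length(g), ]
      } else tve <- matrix(0, length(g), 4)
      ti <- te + tve
      w <- model$prefactors[[k]] * ti * lam
      sf[, 1] <- sf[, 1] + rowSums(w * ezc * ezc)
      sf[, 2] <- sf[, 2] + rowSums(w * exc * exc)
      sf[, 3] <- sf[, 3] + rowSums(w * eyc * eyc)
      sf[, 4] <- sf[, 4] + rowSums(w * ezc * exc)
      tr$t_ve[idx, (4 * k - 3):(4 * k)] <- tve
    }
    p <- muT + sf[, 3]                 # traction-free sigma_yy
    tr$time[idx] <- time[idx]; tr$strain[idx] <- g
    tr$F[idx, ] <- cbind(1, 1, 1, g)
    tr$sigma[idx, ] <- cbind(muT * (1 + g^2) + sf[, 1] - p,
                             muT + sf[, 2] - p, muT + sf[, 3] - p,
                             muT * g + sf[, 4])
    tr$sigma_m[idx, ] <- cbind(muT * (1 + g^2), muT, muT, muT * g)
    tr$sigma_f[idx, ] <- sf
    tr$p[idx] <- p
    tr$eps_i[idx, ] <- eps; tr$lambda_i[idx, ] <- lam
    lastRecorded <- idx[length(idx)]
    i0 <- cycleStarts[ic]; i1 <- cycleStarts[ic + 1L]
    areas[ic] <- .loopArea(tr$sigma[i0:i1, "zx"], tr$strain[i0:i1])
    if (detectSteady && ic >= 2L) {
      denom <- max(abs(areas[ic]), abs(areas[ic - 1L]))
      scl <- max(abs(tr$sigma[i0:i1, "zx"])) * max(abs(tr$strain[i0:i1]))
      if (denom <= 1e-10 * max(scl, 1e-300) ||
          abs(areas[ic] - areas[ic - 1L]) < steadyTol * denom) {
        tr$steadyCycle <- ic
        break
      }
    }
  }
  tr <- .truncTraj(tr, lastRecorded)
  nc <- length(areas)
  tr$cycles <- data.frame(cycle = seq_len(nc),
                          start = cycleStarts[seq_len(nc)],
                          end = pmin(cycleStarts[seq_len(nc) + 1L],
                                     lastRecorded),
                          area = areas)
  class(tr) <- "vf_trajectory"
  tr
}

# generic per-step integrator (handles steric contact during shear)
.runShearPathGeneric <- function(model, time, gamma, gammadot, cycleStarts,
                                 mode, detectSteady = FALSE, steadyTol = 0.005,
                                 viscous = TRUE) {
  n <- length(time)
  tr <- .newTraj(n, model, mode)
  state <- virginState(model)
  areas <- numeric(0)
  lastRecorded <- n
  i <- 1L
  while (i <= n) {
    if (i == 1L) {
      F <- .shearF(gamma[1]); L <- .shearL(gammadot[1])
      parts <- .stressParts(model, F, L, state)
    } else {
      dt <- time[i] - time[i - 1L]
      F <- .shearF(gamma[i]); L <- .shearL(gammadot[i])
      bk <- bundleKinematics(F, L, model$geometry$directors)
      nk <- if (!is.null(model$steric))
        neighborKinematics(F, L, model$geometry$neighbors, model$geometry$ell0)
      else NULL
      state <- .advanceState(model, state, bk, nk, dt, viscous)
      parts <- .stressParts(model, F, L, state)
    }
    p <- parts$s[2, 2]              # traction-free sigma_yy
    tr <- .recordStep(tr, i, time[i], gamma[i], F, parts, state, p)
    # end-of-cycle bookkeeping (a cycle closes where the next one starts)
    ic <- match(i, cycleStarts[-1])
    if (!is.na(ic)) {
      i0 <- cycleStarts[ic]; i1 <- i
      areas[ic] <- .loopArea(tr$sigma[i0:i1, "zx"], tr$strain[i0:i1])
      if (detectSteady && ic >= 2L) {
        denom <- max(abs(areas[ic]), abs(areas[ic - 1L]))
        scale <- max(abs(tr$sigma[i0:i1, "zx"])) * max(abs(tr$strain[i0:i1]))
        if (denom <= 1e-10 * max(scale, 1e-300) ||
            abs(areas[ic] - areas[ic - 1L]) < steadyTol * denom) {
          tr$steadyCycle <- ic
          lastRecorded <- i
          break
        }
      }
    }
    lastRecorded <- i
    i <- i + 1L
  }
  tr <- .truncTraj(tr, lastRecorded)
  nc <- length(areas)
  tr$cycles <- data.frame(cycle = seq_len(nc),
                          start = cycleStarts[seq_len(nc)],
                          end = pmin(cycleStarts[seq_len(nc) + 1L],
                                     lastRecorded),
                          area = areas)
  class(tr) <- "vf_trajectory"
  tr
}

#' Oscillatory simple-shear driver (SAOS / LAOS)
#'
#' Applies \eqn{\gamma_{zx}(t) = \gamma_0 \sin(2\pi f t)} in the
#' longitudinal plane \eqn{(e_z, e_x)} and integrates the internal viscous
#' forces by implicit (backward-Euler) time stepping. The run stops at
#' \code{nCycles} or as soon as two consecutive cycles have loop areas
#' within \code{steadyTol} (steady-cycle detection).
#'
#' @param model a \code{\link{tissueModel}}.
#' @param gamma0 shear strain amplitude (> 0).
#' @param f frequency (Hz).
#' @param nCycles maximum number of cycles.
#' @param stepsPerCycle time steps per cycle (default 200).
#' @param detectSteady stop once the cycle loop area has converged.
#' @param steadyTol relative loop-area tolerance for steadiness.
#' @param viscous set \code{FALSE} to evaluate the neutral (hyperelastic)
#'   response along the same strain path.
#' @return A \code{vf_trajectory}.
#' @export
runOscillatoryShear <- function(model, gamma0, f, nCycles = 30L,
                                stepsPerCycle = 200L, detectSteady = TRUE,
                                steadyTol = 0.005, viscous = TRUE) {
  stopifnot(gamma0 > 0, f > 0, nCycles >= 1, stepsPerCycle >= 16)
  T <- 1 / f
  dt <- T / stepsPerCycle
  time <- c(0, seq_len(nCycles * stepsPerCycle) * dt)
  w <- 2 * pi * f
  gamma <- gamma0 * sin(w * time)
  gammadot <- gamma0 * w * cos(w * time)
  cycleStarts <- 1L + (0:nCycles) * stepsPerCycle   # row 1 is t = 0
  tr <- .runShearPath(model, time, gamma, gammadot, cycleStarts,
                      mode = "oscillatory_shear_zx",
                      detectSteady = detectSteady, steadyTol = steadyTol,
                      viscous = viscous)
  tr$program <- list(gamma0 = gamma0, f = f, stepsPerCycle = stepsPerCycle)
  tr
}

.trianglePath <- function(target, rate, nCycles, stepsPerCycle) {
  stopifnot(stepsPerCycle %% 2 == 0)
  half <- stepsPerCycle / 2
  up <- seq(0, target, length.out = half + 1)[-1]
  one <- c(up, rev(seq(0, target, length.out = half + 1))[-1])
  path <- c(0, rep(one, nCycles))
  dt <- abs(target) / rate / half
  list(time = (seq_along(path) - 1) * dt, value = path, dt = dt)
}

#' Cyclic simple-shear driver
#'
#' Triangular shear cycles \eqn{0 \to \gamma_{max} \to 0} at constant
#' \eqn{|\dot\gamma|}.
#'
#' @inheritParams runOscillatoryShear
#' @param gammaMax peak shear strain.
#' @param rate shear strain rate magnitude (1/s).
#' @export
runCyclicShear <- function(model, gammaMax, rate, nCycles = 1L,
                           stepsPerCycle = 400L, viscous = TRUE) {
  stopifnot(gammaMax != 0, rate > 0, nCycles >= 1)
  pth <- .trianglePath(gammaMax, rate, nCycles, stepsPerCycle)
  gd <- c(0, diff(pth$value)) / pth$dt
  cycleStarts <- 1L + (0:nCycles) * stepsPerCycle
  tr <- .runShearPath(model, pth$time, pth$value, gd, cycleStarts,
                      mode = "shear_zx", detectSteady = FALSE,
                      viscous = viscous)
  tr$program <- list(gammaMax = gammaMax, rate = rate,
                     stepsPerCycle = stepsPerCycle)
  tr
}

#' Cyclic uniaxial driver (tension / compression)
#'
#' Triangular Hencky-strain cycles on one axis at constant strain-rate
#' magnitude. The two lateral stretches are solved at every step so that
#' both lateral normal stresses vanish while \eqn{\det F = 1} holds
#' exactly; anisotropy makes the two lateral stretches differ in general.
#' The pressure follows from the traction-free condition.
#'
#' @inheritParams runOscillatoryShear
#' @param axis loaded axis: \code{"z"} (longitudinal tension) or \code{"x"}
#'   (transverse compression).
#' @param epsTarget peak Hencky strain on the loaded axis (signed; e.g.
#'   0.1 for tension along z, -0.2 for compression along x).
#' @param rate strain-rate magnitude (1/s).
#' @param lateralTol residual tolerance of the lateral stress balance (Pa);
#'   defaults to \code{1e-9 * max(mu, 1)}.
#' @export
runCyclicUniaxial <- function(model, axis = c("z", "x"), epsTarget, rate,
                              nCycles = 1L, stepsPerCycle = 400L,
                              viscous = TRUE, lateralTol = NULL) {
  axis <- match.arg(axis)
  stopifnot(abs(epsTarget) > 0, rate > 0, nCycles >= 1)
  if (is.null(lateralTol)) lateralTol <- 1e-9 * max(model$matrix$mu, 1)
  pth <- .trianglePath(epsTarget, rate, nCycles, stepsPerCycle)
  n <- length(pth$time)
  ia <- .IDX[[axis]]
  ifree <- setdiff(1:3, ia)          # traction-free axes
  tr <- .newTraj(n, model, paste0(if (epsTarget >= 0) "tension_" else "compression_", axis))
  state <- virginState(model)
  epsFree <- matrix(0, n, 2)         # log lateral stretches
  areas <- numeric(0)
  cycleStarts <- 1L + (0:nCycles) * stepsPerCycle
  r <- 0                             # log ratio of lateral stretches
  for (i in seq_len(n)) {
    ea <- pth$value[i]
    dt <- if (i > 1L) pth$dt else 1
    prevFree <- if (i > 1L) epsFree[i - 1L, ] else c(0, 0)
    prevA <- if (i > 1L) pth$value[i - 1L] else 0
    trial <- function(r) {
      e1 <- -ea / 2 + r / 2
      e2 <- -ea / 2 - r / 2
      F <- diag(3); F[ia, ia] <- exp(ea)
      F[ifree[1], ifree[1]] <- exp(e1); F[ifree[2], ifree[2]] <- exp(e2)
      L <- diag(c(0, 0, 0))
      L[ia, ia] <- (ea - prevA) / dt
      L[ifree[1], ifree[1]] <- (e1 - prevFree[1]) / dt
      L[ifree[2], ifree[2]] <- (e2 - prevFree[2]) / dt
      bk <- bundleKinematics(F, L, model$geometry$directors)
      nk <- if (!is.null(model$steric))
        neighborKinematics(F, L, model$geometry$neighbors, model$geometry$ell0)
      else NULL
      st <- if (i > 1L) .advanceState(model, state, bk, nk, dt, viscous)
      else state
      parts <- .stressParts(model, F, L, st)
      list(h = parts$s[ifree[1], ifree[1]] - parts$s[ifree[2], ifree[2]],
           F = F, L = L, parts = parts, state = st, e1 = e1, e2 = e2)
    }
    # secant iteration on the lateral stretch ratio, bracketed fallback
    t1 <- trial(r)
    if (abs(t1$h) > lateralTol) {
      r2 <- r + 1e-4
      t2 <- trial(r2)
      for (it in 1:60) {
        if (abs(t2$h - t1$h) < .Machine$double.xmin) break
        rn <- r2 - t2$h * (r2 - r) / (t2$h - t1$h)
        if (!is.finite(rn)) break
        rn <- max(min(rn, r2 + 0.5), r2 - 0.5)
        r <- r2; t1 <- t2
        r2 <- rn; t2 <- trial(r2)
        if (abs(t2$h) <= lateralTol) break
      }
      if (abs(t2$h) <= lateralTol) { r <- r2; t1 <- t2 }
      else {
        h_of <- function(rr) trial(rr)$h
        w <- 0.05
        repeat {
          lo <- r - w; hi <- r + w
          if (h_of(lo) * h_of(hi) <= 0) break
          w <- w * 2
          if (w > 8) stop("lateral stress balance did not converge; last residual ",
                          signif(t2$h, 3), " Pa")
        }
        rt <- stats::uniroot(h_of, c(r - w, r + w), tol = 1e-13)
        r <- rt$root; t1 <- trial(r)
      }
    }
    state <- t1$state
    p <- t1$parts$s[ifree[1], ifree[1]]
    epsFree[i, ] <- c(t1$e1, t1$e2)
    tr <- .recordStep(tr, i, pth$time[i], ea, t1$F, t1$parts, state, p)
    ic <- match(i, cycleStarts[-1])
    if (!is.na(ic)) {
      i0 <- cycleStarts[ic]
      ax <- paste0(axis, axis)
      areas[ic] <- .loopArea(tr$sigma[i0:i, ax], tr$strain[i0:i])
    }
  }
  nc <- length(areas)
  tr$cycles <- data.frame(cycle = seq_len(nc), start = cycleStarts[seq_len(nc)],
                          end = cycleStarts[seq_len(nc) + 1L], area = areas)
  tr$program <- list(axis = axis, epsTarget = epsTarget, rate = rate,
                     stepsPerCycle = stepsPerCycle)
  class(tr) <- "vf_trajectory"
  tr
}

#' Detect the first steady cycle of a trajectory
#'
#' Returns the first cycle whose loop area differs from the previous one by
#' less than \code{tol} (relative), or \code{NA} if none. A trajectory with
#' (numerically) zero loop areas is steady from cycle 1.
#'
#' @param traj a \code{vf_trajectory} with at least 2 complete cycles
#'   (unless its areas are all zero).
#' @param tol relative loop-area tolerance.
#' @export
detectSteadyCycle <- function(traj, tol = 0.005) {
  stopifnot(inherits(traj, "vf_trajectory"))
  a <- traj$cycles$area
  scale <- max(abs(traj$sigma)) * max(abs(traj$strain))
  tiny <- 1e-10 * max(scale, 1e-300)
  if (length(a) >= 1L && all(abs(a) <= tiny)) return(1L)
  if (length(a) < 2L) stop("need at least two complete cycles")
  for (k in 2:length(a)) {
    denom <- max(abs(a[k]), abs(a[k - 1L]))
    if (denom <= tiny || abs(a[k] - a[k - 1L]) < tol * denom) return(k)
  }
  NA_integer_
}

#' @export
print.vf_trajectory <- function(x, ...) {
  cat("<vf_trajectory> mode:", x$mode, "\n")
  cat("  steps:", length(x$time), " cycles:", nrow(x$cycles),
      " steady cycle:", x$steadyCycle, "\n")
  cat("  peak |sigma_zx|:", signif(max(abs(x$sigma[, "zx"])), 4),
      "Pa  peak |sigma_zz|:", signif(max(abs(x$sigma[, "zz"])), 4),
      "Pa  peak |sigma_xx|:", signif(max(abs(x$sigma[, "xx"])), 4), "Pa\n")
  invisible(x)
}

#' @export
as.data.frame.vf_trajectory <- function(x, ...) {
  data.frame(time_s = x$time,
             Fzz = x$F[, "zz"], Fxx = x$F[, "xx"], Fyy = x$F[, "yy"],
             Fzx = x$F[, "zx"],
             sigma_zz = x$sigma[, "zz"], sigma_xx = x$sigma[, "xx"],
             sigma_zx = x$sigma[, "zx"],
             sigma_f_zz = x$sigma_f[, 1], sigma_s_xx = x$sigma_s[, 2],
             p = x$p)
}

#' Write a trajectory to CSV
#'
#' Fixed column order \code{time_s, Fzz, Fxx, Fyy, Fzx, sigma_zz,
#' sigma_xx, sigma_zx, sigma_f_zz, sigma_s_xx, p}; stresses in Pa, time in
#' seconds.
#'
#' @param traj a \code{vf_trajectory}.
#' @param path output file.
#' @export
exportTrajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
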