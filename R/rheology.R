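# Post-processing of trajectories into rheological observables: SAOS
# storage/loss moduli, loss factor, dynamic viscosity, cross-over
# frequency, Lissajous cycles, Pipkin grids and cyclic hysteresis metrics.

.lastCycleIdx <- function(traj) {
  cyc <- traj$cycles
  if (is.null(cyc) || nrow(cyc) < 1L) stop("trajectory holds no complete cycle")
  k <- nrow(cyc)
  seq(cyc$start[k], cyc$end[k])
}

#' First-harmonic storage and loss moduli of a steady cycle
#'
#' Fourier projection of the shear stress of one complete cycle driven by
#' \eqn{\gamma = \gamma_0\sin(2\pi f t)}:
#' \deqn{G' = \frac{2}{\gamma_0 T}\int_0^T \sigma(t)\sin(2\pi f t)\,dt,\quad
#'       G'' = \frac{2}{\gamma_0 T}\int_0^T \sigma(t)\cos(2\pi f t)\,dt.}
#'
#' @param traj an oscillatory-shear \code{vf_trajectory}.
#' @param cycle cycle number (default: the last recorded, i.e. the steady
#'   cycle when detection succeeded).
#' @return Named vector \code{c(G_storage, G_loss)} (Pa).
#' @export
firstHarmonicModuli <- function(traj, cycle = NULL) {
  stopifnot(inherits(traj, "vf_trajectory"),
            traj$mode == "oscillatory_shear_zx")
  cyc <- traj$cycles
  k <- if (is.null(cycle)) nrow(cyc) else cycle
  idx <- seq(cyc$start[k], cyc$end[k])
  t <- traj$time[idx]
  if (diff(range(t)) <= 0) stop("incomplete cycle")
  sig <- traj$sigma[idx, "zx"]
  g0 <- traj$program$gamma0
  f <- traj$program$f
  Tp <- 1 / f
  w <- 2 * pi * f
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(t))
  c(G_storage = 2 / (g0 * Tp) * trapz(sig * sin(w * t)),
    G_loss = 2 / (g0 * Tp) * trapz(sig * cos(w * t)))
}

#' SAOS frequency sweep
#'
#' Runs the oscillatory driver to its steady cycle at each frequency and
#' collects storage modulus, loss modulus, loss factor
#' \eqn{\zeta^\star = G''/G'} and dynamic viscosity
#' \eqn{\mu' = G''/(2\pi f)}.
#'
#' @param model a \code{\link{tissueModel}}.
#' @param frequencies ascending vector of frequencies (Hz).
#' @param gamma0 strain amplitude (default 0.01, the SAOS protocol).
#' @param nCycles,stepsPerCycle,steadyTol passed to
#'   \code{\link{runOscillatoryShear}}.
#' @return A data frame of class \code{saos_sweep} with columns \code{f},
#'   \code{G_storage}, \code{G_loss}, \code{loss_factor},
#'   \code{dyn_viscosity}, \code{cycles}.
#' @export
saosSweep <- function(model, frequencies, gamma0 = 0.01, nCycles = 30L,
                      stepsPerCycle = 200L, steadyTol = 0.005) {
  stopifnot(all(frequencies > 0), !is.unsorted(frequencies))
  rows <- lapply(frequencies, function(f) {
    tr <- runOscillatoryShear(model, gamma0, f, nCycles = nCycles,
                              stepsPerCycle = stepsPerCycle,
                              steadyTol = steadyTol)
    G <- firstHarmonicModuli(tr)
    data.frame(f = f, G_storage = G[["G_storage"]], G_loss = G[["G_loss"]],
               loss_factor = G[["G_loss"]] / G[["G_storage"]],
               dyn_viscosity = G[["G_loss"]] / (2 * pi * f),
               cycles = nrow(tr$cycles))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("saos_sweep", "data.frame")
  out
}

#' Cross-over frequency of a SAOS sweep
#'
#' Log-linear interpolation of the root of \eqn{G'(f) - G''(f)}. Returns
#' \code{NA} when the sweep does not bracket a sign change.
#'
#' @param sweep a \code{\link{saosSweep}} result (or any data frame with
#'   columns \code{f}, \code{G_storage}, \code{G_loss}).
#' @return Frequency (Hz) or \code{NA}.
#' @export
crossoverFrequency <- function(sweep) {
  d <- sweep$G_storage - sweep$G_loss
  s <- sign(d)
  k <- which(s[-1] * s[-length(s)] < 0)
  if (length(k) == 0L) {
    if (any(d == 0)) return(sweep$f[which(d == 0)[1]])
    return(NA_real_)
  }
  k <- k[1]
  lf <- log(sweep$f)
  exp(lf[k] - d[k] * (lf[k + 1] - lf[k]) / (d[k + 1] - d[k]))
}

#' Lissajous cycle at one frequency and amplitude
#'
#' Steady-cycle stress-strain loop \eqn{\sigma_{zx}(\gamma_{zx})} together
#' with the neutral (hyperelastic, viscous forces zeroed) stress evaluated
#' along the same strain path, plus hysteresis metrics.
#'
#' @inheritParams saosSweep
#' @param gamma0 strain amplitude.
#' @param f frequency (Hz).
#' @return Object of class \code{lissajous_cycle}: \code{gamma},
#'   \code{sigma}, \code{sigma_neutral}, \code{loop_area} (Pa),
#'   \code{peak_stress} (Pa), \code{eps_i_max}, \code{f}, \code{gamma0}.
#' @export
lissajous <- function(model, gamma0, f, nCycles = 30L, stepsPerCycle = 200L,
                      steadyTol = 0.005) {
  tr <- runOscillatoryShear(model, gamma0, f, nCycles = nCycles,
                            stepsPerCycle = stepsPerCycle, steadyTol = steadyTol)
  idx <- .lastCycleIdx(tr)
  gam <- tr$strain[idx]
  sig <- tr$sigma[idx, "zx"]
  # neutral stress: elastic evaluation along the same strain samples
  neu <- vapply(gam, function(g) {
    parts <- .stressParts(model, .shearF(g), .shearL(0), virginState(model))
    parts$s[3, 1]
  }, 0)
  structure(list(gamma = gam, sigma = sig, sigma_neutral = neu,
                 loop_area = .loopArea(sig, gam),
                 peak_stress = max(abs(sig)),
                 eps_i_max = max(tr$eps_i[idx, ]),
                 f = f, gamma0 = gamma0, steadyCycle = tr$steadyCycle),
            class = "lissajous_cycle")
}

#' Pipkin grid of Lissajous cycles
#'
#' Evaluates \code{\link{lissajous}} on the \eqn{\{f, \gamma_0\}} grid and
#' records, per cell, the cycle normalised by its peak stress and strain
#' and the maximal bundle tensile strain \eqn{\varepsilon_i^{max}} over the
#' steady cycle.
#'
#' @inheritParams lissajous
#' @param f_list,gamma0_list grid coordinates.
#' @return Object of class \code{pipkin_grid}: a list-matrix \code{cells}
#'   (rows: frequencies, columns: amplitudes) plus a summary data frame
#'   \code{summary} with \code{f}, \code{gamma0}, \code{loop_area},
#'   \code{peak_stress}, \code{eps_i_max}.
#' @export
pipkinGrid <- function(model, f_list, gamma0_list, nCycles = 30L,
                       stepsPerCycle = 200L) {
  stopifnot(length(f_list) >= 1L, length(gamma0_list) >= 1L)
  cells <- matrix(vector("list", length(f_list) * length(gamma0_list)),
                  nrow = length(f_list),
                  dimnames = list(paste0("f=", f_list),
                                  paste0("gamma0=", gamma0_list)))
  rows <- list()
  for (i in seq_along(f_list)) for (j in seq_along(gamma0_list)) {
    lc <- lissajous(model, gamma0_list[j], f_list[i], nCycles = nCycles,
                    stepsPerCycle = stepsPerCycle)
    lc$gamma_norm <- lc$gamma / max(abs(lc$gamma))
    lc$sigma_norm <- lc$sigma / max(abs(lc$sigma))
    cells[[i, j]] <- lc
    rows[[length(rows) + 1L]] <-
      data.frame(f = f_list[i], gamma0 = gamma0_list[j],
                 loop_area = lc$loop_area, peak_stress = lc$peak_stress,
                 eps_i_max = lc$eps_i_max)
  }
  structure(list(cells = cells, summary = do.call(rbind, rows)),
            class = "pipkin_grid")
}

#' Hysteresis metrics of one cycle
#'
#' Loop area by trapezoidal integration of \eqn{\sigma\,d\varepsilon};
#' peak stress as \eqn{\max|\sigma|} on the loading branch; residual strain
#' as the strain at the zero-stress crossing of the unloading branch
#' (linear interpolation).
#'
#' @param traj a cyclic \code{vf_trajectory} (triangular strain program).
#' @param cycle cycle number.
#' @return Named vector \code{c(loop_area, peak_stress, residual_strain)}.
#' @export
cycleMetrics <- function(traj, cycle = 1L) {
  stopifnot(inherits(traj, "vf_trajectory"))
  cyc <- traj$cycles
  if (is.null(cyc) || cycle > nrow(cyc)) stop("cycle not present in trajectory")
  idx <- seq(cyc$start[cycle], cyc$end[cycle])
  comp <- switch(traj$mode,
                 tension_z = "zz", compression_x = "xx",
                 shear_zx = "zx",
                 stop("cycleMetrics expects a triangular cyclic trajectory"))
  eps <- traj$strain[idx]
  sig <- traj$sigma[idx, comp]
  half <- which.max(abs(eps))          # end of the loading branch
  load <- seq_len(half)
  unload <- seq(half, length(idx))
  peak <- max(abs(sig[load]))
  # zero-stress crossing on the unloading branch
  su <- sig[unload]; eu <- eps[unload]
  cross <- which(su[-1] * su[-length(su)] <= 0 & su[-1] != su[-length(su)])
  residual <- if (length(cross) >= 1L) {
    k <- cross[1]
    eu[k] - su[k] * (eu[k + 1] - eu[k]) / (su[k + 1] - su[k])
  } else 0
  c(loop_area = .loopArea(sig, eps), peak_stress = peak,
    residual_strain = residual)
}

#' Write a SAOS sweep to CSV
#'
#' Columns \code{f_Hz, G_prime_Pa, G_dprime_Pa, loss_factor,
#' mu_prime_Pa_s}.
#'
#' @param sweep a \code{\link{saosSweep}} result.
#' @param path output file.
#' @export
exportSweep <- function(sweep, path) {
  utils::write.csv(data.frame(f_Hz = sweep$f, G_prime_Pa = sweep$G_storage,
                              G_dprime_Pa = sweep$G_loss,
                              loss_factor = sweep$loss_factor,
                              mu_prime_Pa_s = sweep$dyn_viscosity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a Lissajous cycle to CSV
#'
#' Columns \code{gamma, sigma_total_Pa, sigma_neutral_Pa}.
#'
#' @param cycle a \code{\link{lissajous}} result.
#' @param path output file.
#' @export
exportLissajous <- function(cycle, path) {
  utils::write.csv(data.frame(gamma = cycle$gamma,
                              sigma_total_Pa = cycle$sigma,
                              sigma_neutral_Pa = cycle$sigma_neutral),
                   path, row.names = FALSE)
  invisible(path)
}
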