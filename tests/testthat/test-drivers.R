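test_that("implicit Zener update has the dt -> 0 identity and O(dt^2) local accuracy", {
  E <- 1e6; eta0 <- 5e5; d0 <- 0.4e-6
  A <- pi * d0^2 / 4
  t0 <- 2e-10
  # dt -> 0: update -> identity
  expect_equal(zenerStep(t0, 1e-3, 1e-12, E, eta0, 1e-3, 0.27, d0), t0,
               tolerance = 1e-6)
  # n = 1 (linear Maxwell), zero rate: exact exponential decay; the
  # single-step backward-Euler error is O(dt^2): halving dt reduces it ~4x
  tau <- eta0 / E
  err <- function(dt) {
    abs(zenerStep(t0, 0, dt, E, eta0, 1e-3, 1, d0) - t0 * exp(-dt / tau))
  }
  dt <- tau / 50
  ratio <- err(dt) / err(dt / 2)
  expect_gt(ratio, 3.4); expect_lt(ratio, 4.6)
})

test_that("constant-rate integration converges to the algebraic steady state", {
  E <- 3.68e6; eta0 <- 1.56e6; edot0 <- 2.1e-3; n <- 0.27; d0 <- 0.21e-6
  A <- pi * d0^2 / 4
  for (edot in c(2e-4, 1e-2)) {
    x <- 0
    tau <- eta0 / E
    for (k in 1:4000) x <- zenerStep(x, edot, tau / 50, E, eta0, edot0, n, d0)
    t_inf <- A * eta0 * (1 + (edot / edot0)^2)^((n - 1) / 2) * edot
    expect_equal(x / t_inf, 1, tolerance = 1e-3)
  }
})

test_that("oscillatory driver is exact for the fibril-free neo-Hookean tissue", {
  toy <- toyMatrixModel(mu = 31)
  tr <- runOscillatoryShear(toy, 0.01, 75, nCycles = 4, detectSteady = FALSE)
  expect_equal(tr$sigma[, "zx"], 31 * tr$strain, tolerance = 1e-12)
  expect_lt(abs(tr$cycles$area[2]), 1e-12)
  expect_equal(unname(firstHarmonicModuli(tr)), c(31, 0), tolerance = 1e-9)
})

test_that("stress amplitude is linear in gamma0 in the small-strain limit", {
  m <- loadPreset("CSAOS")
  a1 <- max(abs(runOscillatoryShear(m, 1e-9, 10)$sigma[, "zx"]))
  a2 <- max(abs(runOscillatoryShear(m, 2e-9, 10)$sigma[, "zx"]))
  expect_equal(a2 / a1, 2, tolerance = 1e-3)
})

test_that("oscillatory runs reach a steady cycle with positive dissipation", {
  m <- loadPreset("CSAOS")
  tr <- runOscillatoryShear(m, 0.01, 75)
  expect_false(is.na(tr$steadyCycle))
  expect_lte(nrow(tr$cycles), 20)
  expect_gt(tr$cycles$area[nrow(tr$cycles)], 0)
})

test_that("uniaxial driver matches the neo-Hookean closed form for the isotropic toy", {
  toy <- toyMatrixModel(mu = 31)
  tr <- runCyclicUniaxial(toy, "z", 0.1, 1e-3, nCycles = 1, stepsPerCycle = 100)
  lam <- exp(tr$strain)
  expect_equal(tr$sigma[, "zz"], 31 * (lam^2 - 1 / lam), tolerance = 1e-9)
  expect_equal(tr$F[, "xx"], tr$F[, "yy"], tolerance = 1e-12)
  expect_equal(tr$F[, "xx"], lam^-0.5, tolerance = 1e-9)
  expect_true(all(abs(tr$sigma[, "xx"]) < 1e-7))
  expect_true(all(abs(tr$sigma[, "yy"]) < 1e-7))
})

test_that("lamina propria tension shows hysteresis and residual strain on cycle 1", {
  lp1 <- loadPreset("LP1")
  tr <- runCyclicUniaxial(lp1, "z", 0.1, 1e-3, nCycles = 1, stepsPerCycle = 200)
  mets <- cycleMetrics(tr, 1)
  expect_gt(mets[["loop_area"]], 0)
  expect_gt(mets[["residual_strain"]], 0)
  # unloading branch lies below loading branch at matched strains
  idx <- seq(tr$cycles$start[1], tr$cycles$end[1])
  half <- which.max(tr$strain[idx])
  eload <- tr$strain[idx][1:half]; sload <- tr$sigma[idx, "zz"][1:half]
  eun <- rev(tr$strain[idx][half:length(idx)])
  sun <- rev(tr$sigma[idx, "zz"][half:length(idx)])
  probe <- c(0.03, 0.05, 0.08)
  expect_true(all(stats::approx(eun, sun, probe)$y <
                    stats::approx(eload, sload, probe)$y))
})

test_that("steric ablation lowers the peak compression stress", {
  for (id in c("LP1", "V1")) {
    m <- loadPreset(id)
    a <- runCyclicUniaxial(m, "x", -0.2, 1e-3, nCycles = 1, stepsPerCycle = 120)
    b <- runCyclicUniaxial(disableSteric(m), "x", -0.2, 1e-3, nCycles = 1,
                           stepsPerCycle = 120)
    expect_gt(max(abs(a$sigma[, "xx"])), max(abs(b$sigma[, "xx"])))
    expect_true(any(a$contact))
  }
})

test_that("cyclic shear is odd under strain reversal and dissipative for LP1", {
  lp1 <- loadPreset("LP1")
  a <- runCyclicShear(lp1, 0.6, 1e-3, nCycles = 1, stepsPerCycle = 200)
  b <- runCyclicShear(lp1, -0.6, 1e-3, nCycles = 1, stepsPerCycle = 200)
  expect_equal(a$sigma[, "zx"], -b$sigma[, "zx"], tolerance = 1e-9)
  expect_gt(cycleMetrics(a, 1)[["loop_area"]], 0)
  # fibril-free toy: linear, no hysteresis
  toy <- toyMatrixModel()
  tr <- runCyclicShear(toy, 0.6, 1e-3, nCycles = 1, stepsPerCycle = 100)
  expect_equal(tr$sigma[, "zx"], 31 * tr$strain, tolerance = 1e-12)
})

test_that("steady-cycle detection classifies elastic, converging and drifting runs", {
  toy <- toyMatrixModel()
  tr <- runOscillatoryShear(toy, 0.01, 50, nCycles = 3, detectSteady = FALSE)
  expect_identical(detectSteadyCycle(tr), 1L)
  m <- loadPreset("CSAOS")
  tr <- runOscillatoryShear(m, 0.01, 75, nCycles = 20, detectSteady = FALSE)
  expect_lte(detectSteadyCycle(tr), 20L)
  # constructed drifting areas: 10% change per cycle -> none within 5 cycles
  fake <- tr
  fake$cycles <- data.frame(cycle = 1:5, start = 1, end = 2,
                            area = 1 * 1.1^(0:4))
  fake$sigma <- matrix(1, 2, 4, dimnames = list(NULL, c("zz", "xx", "yy", "zx")))
  fake$strain <- c(1, 1)
  expect_identical(detectSteadyCycle(fake), NA_integer_)
})

test_that("halving the time step changes the peak stress by less than 0.2%", {
  m <- loadPreset("CSAOS")
  steadyPeak <- function(spc) {
    tr <- runOscillatoryShear(m, 0.01, 75, nCycles = 300, stepsPerCycle = spc,
                              steadyTol = 1e-7)
    k <- nrow(tr$cycles)
    max(abs(tr$sigma[seq(tr$cycles$start[k], tr$cycles$end[k]), "zx"]))
  }
  p1 <- steadyPeak(200)
  p2 <- steadyPeak(400)
  expect_lt(abs(p1 / p2 - 1), 0.002)
  lp1 <- loadPreset("LP1")
  q1 <- max(abs(runCyclicUniaxial(lp1, "z", 0.1, 1e-3, stepsPerCycle = 200)$sigma[, "zz"]))
  q2 <- max(abs(runCyclicUniaxial(lp1, "z", 0.1, 1e-3, stepsPerCycle = 400)$sigma[, "zz"]))
  expect_lt(abs(q1 / q2 - 1), 0.002)
})

test_that("vectorised and per-step shear integrators agree", {
  lp1 <- loadPreset("LP1")
  T <- 1 / 20
  time <- c(0, seq_len(2 * 80)) * (T / 80)
  gamma <- 0.1 * sin(2 * pi * 20 * time)
  gammadot <- 0.1 * 2 * pi * 20 * cos(2 * pi * 20 * time)
  cs <- 1L + (0:2) * 80L
  fast <- vfrheo:::.runShearPath(lp1, time, gamma, gammadot, cs,
                                 "oscillatory_shear_zx")
  slow <- vfrheo:::.runShearPathGeneric(lp1, time, gamma, gammadot, cs,
                                        "oscillatory_shear_zx")
  expect_equal(fast$sigma[, "zx"], slow$sigma[, "zx"], tolerance = 1e-10)
  expect_equal(fast$t_ve, slow$t_ve, tolerance = 1e-8)
  expect_equal(fast$cycles$area, slow$cycles$area, tolerance = 1e-10)
})

test_that("trajectories export the documented CSV layout", {
  toy <- toyMatrixModel()
  tr <- runOscillatoryShear(toy, 0.01, 10, nCycles = 1, detectSteady = FALSE,
                            stepsPerCycle = 32)
  path <- tempfile(fileext = ".csv")
  exportTrajectory(tr, path)
  df <- utils::read.csv(path)
  expect_identical(names(df),
                   c("time_s", "Fzz", "Fxx", "Fyy", "Fzx", "sigma_zz",
                     "sigma_xx", "sigma_zx", "sigma_f_zz", "sigma_s_xx", "p"))
  expect_true(all(diff(df$time_s) > 0))
  unlink(path)
})
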