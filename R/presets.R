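# Parameter presets and configuration-file I/O. Configuration files are
# YAML with sections [histology], [hyperelastic], [viscoelastic]; lengths
# in micrometres, moduli in MPa (converted to SI at parse time). The
# shipped presets transcribe the optimised histo-mechanical parameter sets
# of the reference samples: CSAOS and CLAOS (vocal-fold cover under small-
# and large-amplitude oscillatory shear), LP1/LP2 (lamina propria) and
# V1/V2 (vocalis) under multi-axial cyclic loading.

#' Load a shipped tissue preset
#'
#' @param id one of \code{"CSAOS"}, \code{"CLAOS"}, \code{"LP1"},
#'   \code{"LP2"}, \code{"V1"}, \code{"V2"}.
#' @return A \code{\link{tissueModel}}.
#' @examples
#' loadPreset("CSAOS")
#' @export
loadPreset <- function(id) {
  path <- system.file("extdata", "presets", paste0(id, ".yaml"),
                      package = "vfrheo")
  if (!nzchar(path)) stop("unknown preset id: ", id)
  readTissueModel(path)
}

#' Read a tissue model from a YAML configuration file
#'
#' @param path file with sections \code{histology}, \code{hyperelastic},
#'   \code{viscoelastic} (micrometres / MPa units, see the shipped presets
#'   under \code{system.file("extdata", "presets", package = "vfrheo")}).
#' @return A \code{\link{tissueModel}}.
#' @export
readTissueModel <- function(path) {
  y <- yaml::read_yaml(path)
  h <- y$histology; e <- y$hyperelastic; v <- y$viscoelastic
  famNames <- names(h$families)
  families <- lapply(famNames, function(nm) {
    hf <- h$families[[nm]]; ef <- e$families[[nm]]
    list(d0 = hf$d0_um * 1e-6, R0 = hf$R0_um * 1e-6, H0 = hf$H0_um * 1e-6,
         phi = hf$phi, Ef = ef$Ef_MPa * 1e6, alpha = ef$alpha)
  })
  names(families) <- famNames
  steric <- NULL
  if (!is.null(e$steric)) {
    steric <- list(beta = e$steric$beta_N, kappa = e$steric$kappa,
                   delta_c = e$steric$delta_c_um * 1e-6,
                   Eprime = v$steric$Eprime_MPa * 1e6,
                   eta0prime = v$steric$eta0prime_MPa_s * 1e6,
                   edot0prime = v$steric$edot0prime_per_s)
  }
  tissueModel(kind = y$kind, theta0 = h$theta0_deg, phi0 = h$phi0_deg,
              families = families, mu = e$mu_Pa,
              visco = list(E = v$bundle$E_MPa * 1e6,
                           eta0 = v$bundle$eta0_MPa_s * 1e6,
                           edot0 = v$bundle$edot0_per_s,
                           n = v$bundle$n_index),
              steric = steric,
              contactClearance = if (is.null(y$contact_clearance)) 0.05
                                 else y$contact_clearance,
              sample = y$sample)
}

#' Write a tissue model to a YAML configuration file
#'
#' Inverse of \code{\link{readTissueModel}}; write-then-read reproduces
#' the model parameters.
#'
#' @param model a \code{\link{tissueModel}}.
#' @param path output file.
#' @export
writeTissueModel <- function(model, path) {
  sp <- model$spec
  famH <- lapply(sp$families, function(f)
    list(H0_um = f$H0 * 1e6, R0_um = f$R0 * 1e6, d0_um = f$d0 * 1e6,
         phi = f$phi))
  famE <- lapply(sp$families, function(f)
    list(Ef_MPa = f$Ef / 1e6, alpha = f$alpha))
  y <- list(sample = sp$sample, kind = sp$kind,
            contact_clearance = sp$contactClearance,
            histology = list(theta0_deg = sp$theta0, phi0_deg = sp$phi0,
                             families = famH),
            hyperelastic = c(list(mu_Pa = sp$mu, families = famE),
                             if (!is.null(sp$steric))
                               list(steric = list(beta_N = sp$steric$beta,
                                                  kappa = sp$steric$kappa,
                                                  delta_c_um = sp$steric$delta_c * 1e6))),
            viscoelastic = c(list(bundle = list(E_MPa = sp$visco$E / 1e6,
                                                eta0_MPa_s = sp$visco$eta0 / 1e6,
                                                edot0_per_s = sp$visco$edot0,
                                                n_index = sp$visco$n)),
                             if (!is.null(sp$steric))
                               list(steric = list(Eprime_MPa = sp$steric$Eprime / 1e6,
                                                  eta0prime_MPa_s = sp$steric$eta0prime / 1e6,
                                                  edot0prime_per_s = sp$steric$edot0prime))))
  writeLines(yaml::as.yaml(y, precision = 15), path)
  invisible(path)
}

.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded pseudo-experimental dataset
#'
#' Runs the forward model through one of the reference protocols and
#' applies seeded multiplicative log-normal noise
#' (\code{value * exp(sigma * Z)}) to the observables. The defaults are
#' the reference protocols: SAOS sweep at \eqn{\gamma_0 = 0.01} over 1-250
#' Hz; LAOS at 75 Hz with \eqn{\gamma_0 \in \{0.05, 0.1, 0.2, 0.5\}};
#' cyclic tension along z to a Hencky strain of 0.1 at \eqn{10^{-3}}
#' s\eqn{^{-1}}, 10 cycles (compression/shear via \code{protocol}).
#' Regeneration with the same seed is bit-identical.
#'
#' @param kind \code{"saos"}, \code{"laos"} or \code{"cyclic"}.
#' @param model a \code{\link{tissueModel}} (e.g. from
#'   \code{\link{loadPreset}}).
#' @param noiseSigma multiplicative noise level (0 = clean).
#' @param seed integer seed.
#' @param protocol optional list overriding protocol settings
#'   (\code{frequencies}, \code{gamma0}, \code{gamma0_list}, \code{f},
#'   \code{axis}, \code{epsTarget}, \code{rate}, \code{nCycles}).
#' @param sim optional list of simulation controls
#'   (\code{stepsPerCycle}, \code{maxCycles}) stored with the dataset so
#'   fits re-simulate on the same discretisation.
#' @return Object of class \code{vf_dataset} with elements \code{kind},
#'   \code{protocol}, \code{sim}, \code{clean}, \code{data},
#'   \code{noise_sigma}, \code{seed}.
#' @export
makeSynthetic <- function(kind = c("saos", "laos", "cyclic"), model,
                          noiseSigma = 0, seed = 1L, protocol = list(),
                          sim = list()) {
  kind <- match.arg(kind)
  stopifnot(noiseSigma >= 0)
  simDef <- list(stepsPerCycle = if (kind == "cyclic") 400L else 200L,
                 maxCycles = 30L)
  sim <- utils::modifyList(simDef, sim)
  if (kind == "saos") {
    prot <- utils::modifyList(
      list(frequencies = 10^seq(0, log10(250), length.out = 20),
           gamma0 = 0.01), protocol)
    sw <- saosSweep(model, prot$frequencies, gamma0 = prot$gamma0,
                    nCycles = sim$maxCycles, stepsPerCycle = sim$stepsPerCycle)
    clean <- data.frame(f = sw$f, G_storage = sw$G_storage, G_loss = sw$G_loss)
    noisy <- clean
    if (noiseSigma > 0) .withSeed(seed, {
      noisy$G_storage <- clean$G_storage * exp(noiseSigma * stats::rnorm(nrow(clean)))
      noisy$G_loss <- clean$G_loss * exp(noiseSigma * stats::rnorm(nrow(clean)))
    })
  } else if (kind == "laos") {
    prot <- utils::modifyList(
      list(f = 75, gamma0_list = c(0.05, 0.1, 0.2, 0.5)), protocol)
    rows <- lapply(prot$gamma0_list, function(g0) {
      lc <- lissajous(model, g0, prot$f, nCycles = sim$maxCycles,
                      stepsPerCycle = sim$stepsPerCycle)
      data.frame(gamma0 = g0, gamma = lc$gamma, sigma = lc$sigma)
    })
    clean <- do.call(rbind, rows)
    noisy <- clean
    if (noiseSigma > 0) .withSeed(seed, {
      noisy$sigma <- clean$sigma * exp(noiseSigma * stats::rnorm(nrow(clean)))
    })
  } else {
    prot <- utils::modifyList(
      list(axis = "z", epsTarget = 0.1, rate = 1e-3, nCycles = 10L), protocol)
    tr <- runCyclicUniaxial(model, axis = prot$axis, epsTarget = prot$epsTarget,
                            rate = prot$rate, nCycles = prot$nCycles,
                            stepsPerCycle = sim$stepsPerCycle)
    comp <- if (prot$axis == "z") "zz" else "xx"
    clean <- data.frame(time = tr$time, strain = tr$strain,
                        sigma = tr$sigma[, comp])
    noisy <- clean
    if (noiseSigma > 0) .withSeed(seed, {
      noisy$sigma <- clean$sigma * exp(noiseSigma * stats::rnorm(nrow(clean)))
    })
  }
  structure(list(kind = kind, protocol = prot, sim = sim, clean = clean,
                 data = noisy, noise_sigma = noiseSigma, seed = seed),
            class = "vf_dataset")
}
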