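# Parameter identification from rheometric datasets by bounded non-linear
# least squares (Levenberg-Marquardt via minpack.lm), with corridor
# constraints on the histological and hyperelastic parameters and
# seeded Latin-hypercube multi-start.

#' Admissible parameter corridors
#'
#' Literature-derived corridors for the histological and hyperelastic
#' parameters, plus finite search boxes for the positive viscoelastic
#' parameters (free in principle; the boxes bound the multi-start
#' sampling). All values SI.
#'
#' @return Data frame with columns \code{name}, \code{lower}, \code{upper},
#'   \code{log} (whether the parameter is searched on a log scale).
#' @export
parameterBounds <- function() {
  b <- rbind(
    data.frame(name = "theta0", lower = 0,      upper = 50,     log = FALSE),
    data.frame(name = "phi0",   lower = 20,     upper = 90,     log = FALSE),
    data.frame(name = "H0",     lower = 10e-6,  upper = 70e-6,  log = TRUE),
    data.frame(name = "R0",     lower = 1e-6,   upper = 10e-6,  log = TRUE),
    data.frame(name = "d0",     lower = 10e-9,  upper = 500e-9, log = TRUE),
    data.frame(name = "phi",    lower = 0.15,   upper = 0.55,   log = FALSE),
    data.frame(name = "Ef",     lower = 1e6,    upper = 1e9,    log = TRUE),
    data.frame(name = "mu",     lower = 1,      upper = 1.5e6,  log = TRUE),
    data.frame(name = "alpha",  lower = 1e-5,   upper = 1,      log = TRUE),
    data.frame(name = "E",      lower = 1e3,    upper = 1e9,    log = TRUE),
    data.frame(name = "eta0",   lower = 1e3,    upper = 1e9,    log = TRUE),
    data.frame(name = "edot0",  lower = 1e-6,   upper = 1,      log = TRUE),
    data.frame(name = "n",      lower = 0,      upper = 1,      log = FALSE),
    data.frame(name = "beta",   lower = 1e-6,   upper = 1e-2,   log = TRUE),
    data.frame(name = "kappa",  lower = 1,      upper = 5,      log = FALSE),
    data.frame(name = "delta_c", lower = 1e-6,  upper = 1e-3,   log = TRUE),
    data.frame(name = "Eprime", lower = 1e3,    upper = 1e9,    log = TRUE),
    data.frame(name = "eta0prime", lower = 1e3, upper = 1e9,    log = TRUE),
    data.frame(name = "edot0prime", lower = 1e-6, upper = 1,    log = TRUE))
  b
}

.modelPredict <- function(model, dataset) {
  prot <- dataset$protocol; sim <- dataset$sim
  if (dataset$kind == "saos") {
    sw <- saosSweep(model, prot$frequencies, gamma0 = prot$gamma0,
                    nCycles = sim$maxCycles, stepsPerCycle = sim$stepsPerCycle)
    data.frame(G_storage = sw$G_storage, G_loss = sw$G_loss)
  } else if (dataset$kind == "laos") {
    rows <- lapply(prot$gamma0_list, function(g0) {
      lc <- lissajous(model, g0, prot$f, nCycles = sim$maxCycles,
                      stepsPerCycle = sim$stepsPerCycle)
      data.frame(sigma = lc$sigma)
    })
    do.call(rbind, rows)
  } else {
    tr <- runCyclicUniaxial(model, axis = prot$axis,
                            epsTarget = prot$epsTarget, rate = prot$rate,
                            nCycles = prot$nCycles,
                            stepsPerCycle = sim$stepsPerCycle)
    comp <- if (prot$axis == "z") "zz" else "xx"
    data.frame(sigma = tr$sigma[, comp])
  }
}

#' Weighted residual vector of a parameter set against a dataset
#'
#' Re-simulates the dataset's protocol with the trial parameters and
#' returns \code{(model - data)/scale}, the scale being the per-dataset
#' root-mean-square of the data. SAOS residuals are computed on log-moduli
#' because the moduli span decades across a sweep. A failing forward model
#' yields a finite large-penalty residual.
#'
#' @param pars named numeric vector of trial parameters (SI), names as in
#'   \code{\link{parameterBounds}}.
#' @param dataset a \code{\link{makeSynthetic}}-style dataset.
#' @param model template \code{\link{tissueModel}}; parameters not in
#'   \code{pars} keep their template values.
#' @return Numeric residual vector (length = number of data points).
#' @export
residualVector <- function(pars, dataset, model) {
  m <- tryCatch(do.call(modifyTissue, c(list(model), as.list(pars))),
                error = function(e) NULL)
  npts <- if (dataset$kind == "saos") 2L * nrow(dataset$data)
          else nrow(dataset$data)
  if (is.null(m)) return(rep(1e3, npts))
  pred <- tryCatch(.modelPredict(m, dataset), error = function(e) NULL)
  if (is.null(pred) || anyNA(pred)) return(rep(1e3, npts))
  if (dataset$kind == "saos") {
    obs <- log10(c(dataset$data$G_storage, dataset$data$G_loss))
    fit <- log10(c(pred$G_storage, pred$G_loss))
    if (anyNA(fit) || any(!is.finite(fit))) return(rep(1e3, npts))
    sc <- sqrt(mean(obs^2))
    (fit - obs) / sc
  } else {
    obs <- dataset$data$sigma
    sc <- sqrt(mean(obs^2))
    (pred$sigma - obs) / sc
  }
}

.toInternal <- function(x, log) ifelse(log, log10(x), x)
.fromInternal <- function(x, log) ifelse(log, 10^x, x)

#' Fit model parameters to a dataset
#'
#' Bounded non-linear least squares (Levenberg-Marquardt) from a given
#' initial guess, with seeded Latin-hypercube multi-start inside the
#' parameter corridors; the best residual wins. Deterministic given
#' \code{seed}. Positive parameters are searched on a log scale.
#'
#' @param dataset a \code{\link{makeSynthetic}}-style dataset.
#' @param model template \code{\link{tissueModel}}.
#' @param free names of the free parameters (default: the bundle
#'   viscoelastic set).
#' @param init named initial values (default: the template model's values).
#' @param bounds bounds table, see \code{\link{parameterBounds}}.
#' @param nStarts number of seeded restarts (>= 1; the first start is
#'   \code{init}).
#' @param seed integer seed for the restart sampling.
#' @param control passed to \code{\link[minpack.lm]{nls.lm.control}}.
#' @return Object of class \code{vf_fit}: \code{par} (named, SI),
#'   \code{residual_norm}, \code{starts} (per-start summary),
#'   \code{converged}, \code{seed}.
#' @export
fitModel <- function(dataset, model, free = c("E", "eta0", "edot0", "n"),
                     init = NULL, bounds = parameterBounds(), nStarts = 5L,
                     seed = 1L,
                     control = minpack.lm::nls.lm.control(maxiter = 200)) {
  b <- bounds[match(free, bounds$name), ]
  if (anyNA(b$name)) stop("no bounds known for: ",
                          paste(setdiff(free, bounds$name), collapse = ", "))
  if (is.null(init)) init <- .currentValues(model)[free]
  init <- init[free]
  stopifnot(all(is.finite(unlist(init))))
  lo <- .toInternal(b$lower, b$log); hi <- .toInternal(b$upper, b$log)
  x0 <- .toInternal(as.numeric(init), b$log)
  x0 <- pmin(pmax(x0, lo), hi)
  objective <- function(x) {
    p <- .fromInternal(x, b$log); names(p) <- free
    residualVector(p, dataset, model)
  }
  starts <- matrix(x0, nrow = 1)
  if (nStarts > 1L) {
    u <- .withSeed(seed, lhs::randomLHS(nStarts - 1L, length(free)))
    starts <- rbind(starts, sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+"))
  }
  results <- vector("list", nrow(starts))
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], lower = lo, upper = hi,
                         fn = objective, control = control),
      error = function(e) NULL)
    results[[s]] <- fit
  }
  ok <- !vapply(results, is.null, TRUE)
  if (!any(ok)) stop("all restarts failed")
  dev <- vapply(results, function(r) if (is.null(r)) Inf else r$deviance, 0)
  best <- which.min(dev)
  par <- .fromInternal(results[[best]]$par, b$log)
  names(par) <- free
  structure(list(par = par,
                 residual_norm = sqrt(dev[best]),
                 starts = data.frame(start = seq_along(dev),
                                     deviance = dev,
                                     converged = ok),
                 converged = results[[best]]$info %in% 1:4,
                 info = results[[best]]$info,
                 seed = seed, free = free),
            class = "vf_fit")
}

.currentValues <- function(model) {
  sp <- model$spec
  f1 <- sp$families[[1]]
  v <- sp$visco
  out <- c(theta0 = sp$theta0, phi0 = sp$phi0,
           H0 = f1$H0, R0 = f1$R0, d0 = f1$d0, phi = f1$phi,
           Ef = f1$Ef, alpha = f1$alpha, mu = sp$mu,
           E = v$E, eta0 = v$eta0, edot0 = v$edot0, n = v$n)
  if (!is.null(sp$steric))
    out <- c(out, beta = sp$steric$beta, kappa = sp$steric$kappa,
             delta_c = sp$steric$delta_c, Eprime = sp$steric$Eprime,
             eta0prime = sp$steric$eta0prime,
             edot0prime = sp$steric$edot0prime)
  out
}

#' @export
print.vf_fit <- function(x, ...) {
  cat("<vf_fit> residual norm", signif(x$residual_norm, 4),
      if (x$converged) "(converged)" else "(not converged)", "\n")
  print(signif(x$par, 5))
  invisible(x)
}

#' Profile one parameter for identifiability
#'
#' Re-fits the remaining free parameters at each grid value of the profiled
#' parameter and reports the residual norm profile. A profile that is flat
#' within tolerance flags the parameter as unidentifiable from the dataset
#' (e.g. the power-law index from a single-rate cyclic test).
#'
#' @inheritParams fitModel
#' @param name parameter to profile.
#' @param values grid of values (SI).
#' @param free other parameters re-optimised at each grid point.
#' @param flatTol flatness tolerance on the residual-norm spread, relative
#'   to the number of data points.
#' @return Data frame with \code{value}, \code{rss}, and attribute
#'   \code{identifiable} (logical).
#' @export
profileParameter <- function(dataset, model, name, values,
                             free = c("E", "eta0", "edot0"),
                             bounds = parameterBounds(), seed = 1L,
                             flatTol = 1e-3) {
  rss <- vapply(values, function(v) {
    m <- do.call(modifyTissue, stats::setNames(list(model, v), c("model", name)))
    fit <- fitModel(dataset, m, free = free, bounds = bounds,
                    nStarts = 1L, seed = seed)
    fit$residual_norm^2
  }, 0)
  npts <- if (dataset$kind == "saos") 2L * nrow(dataset$data)
          else nrow(dataset$data)
  out <- data.frame(value = values, rss = rss)
  attr(out, "identifiable") <- (max(rss) - min(rss)) >= flatTol * npts
  out
}
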