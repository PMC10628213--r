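#' Create a fit configuration
#'
#' Defaults follow standard differential-evolution practice for
#' reflectometry-scale problems: rand/1/bin, population 15 per free
#' parameter, F = 0.7, CR = 0.9, at most 1000 generations, stopping when the
#' relative spread of population costs falls below \code{tol}. The default
#' cost is the unweighted mean squared residual of \eqn{\log_{10} R},
#' appropriate for curves spanning many decades without reliable point
#' weights; \code{"chi2_weighted"} uses the curve's dR.
#'
#' @param seed integer RNG seed (the search is reproducible given the seed).
#' @param populationSize population size; NA means 15 x free parameters.
#' @param maxGenerations generation cap.
#' @param mutationF,crossoverCR DE hyperparameters.
#' @param tol relative convergence tolerance on the population cost spread.
#' @param polish refine the best member by bounded local optimization
#'   (L-BFGS-B) after the evolutionary search; the cost can only decrease.
#' @param cost "log_unweighted" or "chi2_weighted".
#' @return A \linkS4class{FitConfig}.
#' @export
fitConfig <- function(seed = 1L, populationSize = NA_real_,
                      maxGenerations = 1000L, mutationF = 0.7,
                      crossoverCR = 0.9, tol = 1e-8, polish = TRUE,
                      cost = c("log_unweighted", "chi2_weighted")) {
  new("FitConfig", seed = as.integer(seed),
      populationSize = as.numeric(populationSize),
      maxGenerations = as.integer(maxGenerations),
      mutationF = as.numeric(mutationF), crossoverCR = as.numeric(crossoverCR),
      tol = as.numeric(tol), polish = isTRUE(polish), cost = match.arg(cost))
}

#' Fit cost between a curve and a model
#'
#' \code{"log_unweighted"}: mean over usable points of
#' \eqn{(\log_{10}(s R_{model} + b) - \log_{10} R_{data})^2}; points with
#' non-positive data are masked with a warning. \code{"chi2_weighted"}: mean
#' of squared linear residuals divided by dR^2 (requires dR).
#'
#' @param curve a \linkS4class{ReflectivityCurve}.
#' @param modelR model reflectivity on the curve's q grid.
#' @param scale,background intensity scale s and constant background b.
#' @param cost cost type.
#' @return a single non-negative number; 0 iff the scaled model matches the
#'   data exactly.
#' @export
fitCost <- function(curve, modelR,  scale = 1, background = 0,
                    cost = c("log_unweighted", "chi2_weighted")) {
  cost <- match.arg(cost)
  if (length(modelR) != length(curve@q))
    stop("modelR must match the curve in length")
  m <- scale * modelR + background
  if (cost == "log_unweighted") {
    ok <- curve@R > 0
    if (!all(ok)) warning(sum(!ok), " non-positive data point(s) masked")
    mean((log10(pmax(m[ok], 1e-30)) - log10(curve@R[ok]))^2)
  } else {
    if (!length(curve@dR)) stop("chi2_weighted cost requires dR on the curve")
    mean(((m - curve@R) / curve@dR)^2)
  }
}

#' Build a fit-parameter table for a stack
#'
#' One row per parameter, named \code{<slab>.d}, \code{<slab>.rho},
#' \code{<slab>.sigma} (slab names from [slabNames()]), plus
#' \code{backing.sigma}, \code{background} and \code{scale}. Default bounds
#' are the template value +- \code{frac} (densities and roughnesses floored
#' at 0); the background is free in [0, 1e-8] and the intensity scale free
#' in [0.95, 1.05] — beam normalization is only accurate to a few percent,
#' and pinning the scale forces the uniform log-offset that multiplicative
#' noise induces into the slab parameters. Edit rows with
#' [setParameter()] to fix values (e.g. a substrate oxide density) or to
#' impose published bounds (e.g. oxide thickness in [12, 25]).
#'
#' @param stack template \linkS4class{LayerStack}.
#' @param frac half-width of the default relative bounds.
#' @param backgroundBounds bounds for the additive background.
#' @return data.frame with columns name, value, lower, upper, fixed.
#' @export
defaultParameters <- function(stack, frac = 0.25,
                              backgroundBounds = c(0, 1e-8)) {
  nm <- slabNames(stack)
  d <- thicknesses(stack); rho <- densities(stack)
  sig <- roughnesses(stack)
  rows <- list()
  for (i in seq_along(nm)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(nm[i], c(".d", ".rho", ".sigma")),
      value = c(d[i], rho[i], sig[i]),
      lower = c(d[i] * (1 - frac), max(0, rho[i] * (1 - frac)),
                max(0, sig[i] * (1 - frac))),
      upper = c(d[i] * (1 + frac), rho[i] * (1 + frac),
                max(sig[i] * (1 + frac), 0.5)),
      fixed = FALSE)
  }
  bs <- stack@backingRoughness
  rows[[length(rows) + 1L]] <- data.frame(
    name = c("backing.sigma", "background", "scale"),
    value = c(bs, 0, 1),
    lower = c(max(0, bs * (1 - frac)), backgroundBounds[1], 0.95),
    upper = c(max(bs * (1 + frac), 0.5), backgroundBounds[2], 1.05),
    fixed = c(FALSE, FALSE, FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Edit one row of a fit-parameter table
#'
#' @param params table from [defaultParameters()].
#' @param name parameter name.
#' @param value,lower,upper,fixed fields to change (NULL leaves untouched).
#' @return the modified table.
#' @export
setParameter <- function(params, name, value = NULL, lower = NULL,
                         upper = NULL, fixed = NULL) {
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  if (!is.null(value)) params$value[i] <- value
  if (!is.null(lower)) params$lower[i] <- lower
  if (!is.null(upper)) params$upper[i] <- upper
  if (!is.null(fixed)) params$fixed[i] <- fixed
  if (params$lower[i] > params$upper[i]) stop("lower > upper for ", name)
  params$value[i] <- min(max(params$value[i], params$lower[i]),
                         params$upper[i])
  params
}

## map parameter names onto positions in the (d, rho, sigma) arrays;
## returns a function(fullValues) -> list(d, rho, sigma, scale, background)
.parameterMapper <- function(stack, params) {
  nm <- slabNames(stack)
  a <- .stackArrays(stack)
  n <- length(a$d)
  target <- character(nrow(params)); index <- integer(nrow(params))
  for (r in seq_len(nrow(params))) {
    p <- params$name[r]
    if (p == "background") { target[r] <- "background"; next }
    if (p == "scale") { target[r] <- "scale"; next }
    if (p == "backing.sigma") { target[r] <- "sigma"; index[r] <- n + 1L; next }
    dot <- regexpr("\\.[^.]*$", p)
    slab <- substr(p, 1L, dot - 1L); field <- substr(p, dot + 1L, nchar(p))
    i <- match(slab, nm)
    if (is.na(i) || !field %in% c("d", "rho", "sigma"))
      stop("parameter name does not address the template stack: ", p)
    target[r] <- switch(field, d = "d", rho = "rho", sigma = "sigma")
    index[r] <- if (field == "rho") i + 1L else i
  }
  function(values) {
    d <- a$d; rho <- a$rho; sigma <- a$sigma
    scale <- 1; background <- 0
    for (r in seq_along(values)) {
      switch(target[r],
             d = { d[index[r]] <- values[r] },
             rho = { rho[index[r]] <- values[r] },
             sigma = { sigma[index[r]] <- values[r] },
             background = { background <- values[r] },
             scale = { scale <- values[r] })
    }
    list(d = d, rho = rho, sigma = sigma, scale = scale,
         background = background)
  }
}

.curveChecksum <- function(curve)
  c(length(curve@q), sum(curve@q), sum(curve@R), sum(curve@q * curve@R))

## differential evolution, rand/1/bin with binomial crossover and bound
## clipping; the initial guess is injected as the first population member so
## the best cost can never exceed the cost of the starting point.
.deOptimize <- function(fn, lower, upper, init, popSize, maxGen, F, CR, tol,
                        seed) {
  set.seed(seed)
  npar <- length(lower)
  pop <- matrix(runif(popSize * npar), popSize, npar)
  pop <- sweep(sweep(pop, 2L, upper - lower, "*"), 2L, lower, "+")
  pop[1L, ] <- init
  costs <- numeric(popSize)
  neval <- 0L
  for (i in seq_len(popSize)) {
    costs[i] <- fn(pop[i, ]); neval <- neval + 1L
  }
  costs[!is.finite(costs)] <- Inf
  history <- numeric(0)
  for (g in seq_len(maxGen)) {
    for (i in seq_len(popSize)) {
      r <- sample.int(popSize - 1L, 3L)
      r <- ifelse(r >= i, r + 1L, r)
      mutant <- pop[r[1L], ] + F * (pop[r[2L], ] - pop[r[3L], ])
      cross <- runif(npar) < CR
      cross[sample.int(npar, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      ct <- fn(trial); neval <- neval + 1L
      if (is.finite(ct) && ct <= costs[i]) {
        pop[i, ] <- trial
        costs[i] <- ct
      }
    }
    history <- c(history, min(costs))
    finite <- costs[is.finite(costs)]
    if (length(finite) == popSize &&
        sd(finite) <= tol * abs(mean(finite)) + 1e-15) break
  }
  b <- which.min(costs)
  list(par = pop[b, ], value = costs[b], history = history, neval = neval)
}

#' Fit a slab stack to a reflectivity curve
#'
#' Global stochastic fit of the free parameters of a template
#' \linkS4class{LayerStack} by seeded differential evolution (a
#' genetic-type minimizer) under box constraints. Fixed parameters (e.g.
#' substrate and buffer densities) never move; the search is bit-reproducible
#' for a given seed and configuration.
#'
#' @param curve the data, a \linkS4class{ReflectivityCurve}.
#' @param template starting \linkS4class{LayerStack}; also defines slab names.
#' @param params parameter table (see [defaultParameters()]).
#' @param config a \linkS4class{FitConfig}.
#' @return A \linkS4class{FitResult}.
#' @examples
#' st <- presetStack(makePreset("dopc_monolayer_air"))
#' cu <- simulateCurve(st, noise = noiseModel(relativeSigma = 0.02, seed = 3))
#' pars <- defaultParameters(st, frac = 0.2)
#' pars <- setParameter(pars, "sio2.rho", fixed = TRUE)
#' \donttest{
#' fit <- fitStack(cu, st, pars, fitConfig(seed = 3, maxGenerations = 200))
#' }
#' @export
fitStack <- function(curve, template, params = defaultParameters(template),
                     config = fitConfig()) {
  stopifnot(is(curve, "ReflectivityCurve"), is(template, "LayerStack"))
  free <- !params$fixed
  if (!any(free)) stop("no free parameters to fit")
  if (any(!is.finite(params$lower[free])) || any(!is.finite(params$upper[free])))
    stop("bounds of free parameters must be finite")
  if (any(params$value < params$lower - 1e-12) ||
      any(params$value > params$upper + 1e-12))
    stop("parameter values must lie within their bounds")

  mapper <- .parameterMapper(template, params)
  q <- curve@q
  ok <- curve@R > 0
  if (!all(ok) && config@cost == "log_unweighted")
    warning(sum(!ok), " non-positive data point(s) masked during the fit")
  logR <- log10(curve@R[ok])
  dR <- curve@dR
  full <- params$value
  freeIdx <- which(free)

  costFn <- function(theta) {
    v <- full
    v[freeIdx] <- theta
    m <- mapper(v)
    Rm <- .abelesKernel(q, m$rho * .r_e, m$d, m$sigma)
    y <- m$scale * Rm + m$background
    if (config@cost == "log_unweighted")
      mean((log10(pmax(y[ok], 1e-30)) - logR)^2)
    else
      mean(((y - curve@R) / dR)^2)
  }

  npar <- length(freeIdx)
  popSize <- if (is.na(config@populationSize)) max(15L * npar, 20L)
             else as.integer(config@populationSize)
  de <- .deOptimize(costFn, params$lower[freeIdx], params$upper[freeIdx],
                    params$value[freeIdx], popSize, config@maxGenerations,
                    config@mutationF, config@crossoverCR, config@tol,
                    config@seed)
  if (config@polish) {
    rng <- params$upper[freeIdx] - params$lower[freeIdx]
    pol <- tryCatch(
      optim(de$par, costFn, method = "L-BFGS-B",
            lower = params$lower[freeIdx], upper = params$upper[freeIdx],
            control = list(maxit = 500, parscale = pmax(rng, 1e-12),
                           ndeps = pmax(rng * 1e-6, 1e-12))),
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value < de$value) {
      de$par <- pol$par
      de$value <- pol$value
      de$history <- c(de$history, pol$value)
      de$neval <- de$neval + pol$counts[[1L]]
    }
  }
  best <- params
  best$value[freeIdx] <- de$par
  m <- mapper(best$value)
  stack <- .rebuildStack(template, m)
  unc <- setNames(rep(NA_real_, nrow(best)), best$name)
  unc[!free] <- 0
  new("FitResult", stack = stack, parameters = best, costValue = de$value,
      costType = config@cost, scale = m$scale, background = m$background,
      uncertainty = unc, nFunctionEvals = as.integer(de$neval),
      seed = config@seed, history = de$history,
      curveChecksum = .curveChecksum(curve))
}

## rebuild a LayerStack from template + mapped arrays
.rebuildStack <- function(template, m) {
  slabs <- template@slabs
  for (i in seq_along(slabs))
    slabs[[i]] <- Slab(m$d[i], m$rho[i + 1L], m$sigma[i])
  names(slabs) <- names(template@slabs)
  suppressWarnings(
    LayerStack(template@fronting, slabs, template@backing,
               m$sigma[length(m$sigma)]))
}

#' Per-parameter uncertainty by residual bootstrap
#'
#' Resamples the fit residuals (in the cost's own space: log10 for the
#' unweighted log cost, linear for the weighted chi-square), regenerates
#' synthetic data around the best-fit model, and refits the free parameters
#' by bounded local optimization started from the global optimum. The
#' spread (sd) of each parameter over the resamples is its 1-sigma
#' uncertainty; fixed parameters report 0.
#'
#' @param result a \linkS4class{FitResult} from [fitStack()].
#' @param curve the curve that was fitted.
#' @param nBoot number of resamples (>= 10).
#' @param seed integer seed.
#' @return named numeric vector of 1-sigma uncertainties, one per parameter.
#' @export
parameterUncertainty <- function(result, curve, nBoot = 100L, seed = 1L) {
  if (nBoot < 10L) stop("nBoot must be >= 10")
  if (!isTRUE(all.equal(.curveChecksum(curve), result@curveChecksum)))
    stop("curve does not match the one the fit was run on")
  params <- result@parameters
  free <- which(!params$fixed)
  mapper <- .parameterMapper(result@stack, params)
  q <- curve@q
  m <- mapper(params$value)
  Rbest <- m$scale * .abelesKernel(q, m$rho * .r_e, m$d, m$sigma) +
    m$background
  logCost <- result@costType == "log_unweighted"
  ok <- if (logCost) curve@R > 0 & Rbest > 0 else rep(TRUE, length(q))
  resid <- if (logCost) log10(curve@R[ok]) - log10(Rbest[ok])
           else curve@R - Rbest
  set.seed(seed)
  draws <- matrix(NA_real_, nBoot, length(free))
  full <- params$value
  for (b in seq_len(nBoot)) {
    rs <- sample(resid, length(resid), replace = TRUE)
    yb <- if (logCost) 10^(log10(Rbest[ok]) + rs) else curve@R + rs
    fn <- function(theta) {
      v <- full
      v[free] <- theta
      mm <- mapper(v)
      Rm <- mm$scale * .abelesKernel(q, mm$rho * .r_e, mm$d, mm$sigma) +
        mm$background
      if (logCost) mean((log10(pmax(Rm[ok], 1e-30)) - log10(yb))^2)
      else mean(((Rm - yb) / curve@dR)^2)
    }
    fit <- tryCatch(
      optim(params$value[free], fn, method = "L-BFGS-B",
            lower = params$lower[free], upper = params$upper[free],
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) draws[b, ] <- fit$par
  }
  sig <- setNames(rep(0, nrow(params)), params$name)
  sig[params$name[free]] <- apply(draws, 2L, sd, na.rm = TRUE)
  sig
}

#' Compare nested slab models by cost improvement
#'
#' Implements the parsimony rule used to decide whether an extra slab is
#' warranted: the model with more slabs is selected only when it improves
#' the cost by more than \code{threshold} (relative, default 10 percent).
#' Equal costs select the smaller model. All fits must have been run on the
#' same data with the same cost functional.
#'
#' @param curve the data both models were fitted to.
#' @param fits list of \linkS4class{FitResult}s with different slab counts.
#' @param threshold relative cost improvement required to accept a larger
#'   model.
#' @return list with elements \code{selected} (a FitResult) and
#'   \code{report} (data.frame of slab counts, costs, improvements and
#'   acceptance).
#' @export
compareModels <- function(curve, fits, threshold = 0.1) {
  stopifnot(length(fits) >= 2L)
  cs <- .curveChecksum(curve)
  for (f in fits) {
    if (!isTRUE(all.equal(cs, f@curveChecksum)))
      stop("all fits must be on the same data as 'curve'")
    if (f@costType != fits[[1L]]@costType)
      stop("all fits must use the same cost functional")
  }
  k <- vapply(fits, function(f) nSlabs(f@stack), integer(1))
  ord <- order(k)
  fits <- fits[ord]; k <- k[ord]
  cost <- vapply(fits, costValue, numeric(1))
  sel <- 1L
  improvement <- rep(NA_real_, length(fits))
  accepted <- c(TRUE, rep(FALSE, length(fits) - 1L))
  for (i in seq_along(fits)[-1L]) {
    improvement[i] <- (cost[sel] - cost[i]) / cost[sel]
    if (is.finite(improvement[i]) && improvement[i] > threshold) {
      accepted[sel] <- FALSE
      sel <- i
      accepted[i] <- TRUE
    }
  }
  list(selected = fits[[sel]],
       report = data.frame(nSlabs = k, cost = cost,
                           improvement = improvement, accepted = accepted))
}
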