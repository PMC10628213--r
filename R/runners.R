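## Pipeline runners behind the command-line interface. Each writes its
## artifacts (with config hash + seed) into outDir and returns its result
## invisibly, so the same entry points serve scripts and interactive use.

.logmsg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
}

#' Simulate a preset curve to disk
#'
#' Writes the noisy curve (ASCII q/R/dR) plus a JSON sidecar recording the
#' stack, the noise model, the seed and the config hash.
#'
#' @param preset preset name (see [presetNames()]).
#' @param outDir output directory (created if needed).
#' @param seed integer seed for the noise draw.
#' @param relativeSigma relative noise level of the Gaussian noise model.
#' @param q q grid.
#' @return invisibly, the simulated \linkS4class{ReflectivityCurve}.
#' @export
runSimulate <- function(preset, outDir = ".", seed = 1L,
                        relativeSigma = 0.02, q = defaultQGrid()) {
  ps <- makePreset(preset)
  nm <- noiseModel("relative_gaussian", relativeSigma = relativeSigma,
                   seed = seed)
  curve <- simulateCurve(ps, q = q, noise = nm)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(command = "simulate", preset = preset, seed = seed,
              relativeSigma = relativeSigma,
              q = c(min(q), max(q), length(q)))
  hash <- .configHash(cfg)
  curveFile <- file.path(outDir, paste0(preset, "_curve.dat"))
  writeReflectivity(curve, curveFile,
                    header = list(preset = preset, seed = seed,
                                  config_md5 = hash))
  st <- ps@stack
  jsonlite::write_json(c(cfg, list(
    config_md5 = hash,
    stack = data.frame(name = slabNames(st), d = thicknesses(st),
                       rho = densities(st),
                       sigma = head(roughnesses(st), -1L)))),
    file.path(outDir, paste0(preset, "_meta.json")),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  .logmsg("simulate: wrote %s", curveFile)
  invisible(curve)
}

#' Fit a curve file against a preset template
#'
#' Reads the curve, builds the template and its parameter table (substrate
#' oxide density fixed at 0.660 e-/A^3 and oxide thickness bounded to
#' [12, 25] A; buffer/Si densities fixed through the media), runs the
#' differential-evolution fit and writes the fit report JSON plus the
#' implied density profile.
#'
#' @param curveFile ASCII curve file.
#' @param preset preset name providing the template stack.
#' @param outDir output directory.
#' @param seed integer seed for the search.
#' @param maxGenerations generation cap.
#' @param boundsFrac relative half-width of the default parameter bounds.
#' @param dialect column dialect for [readReflectivity()].
#' @return invisibly, the \linkS4class{FitResult}.
#' @export
runFit <- function(curveFile, preset, outDir = ".", seed = 1L,
                   maxGenerations = 400L, boundsFrac = 0.25,
                   dialect = "auto") {
  curve <- readReflectivity(curveFile, dialect = dialect)
  template <- presetStack(makePreset(preset))
  params <- presetFitParameters(template, frac = boundsFrac)
  cfg <- fitConfig(seed = seed, maxGenerations = maxGenerations)
  .logmsg("fit: %d free parameters, seed %d", sum(!params$fixed), seed)
  fit <- fitStack(curve, template, params, cfg)
  .logmsg("fit: cost %.6g after %d evaluations", fit@costValue,
          fit@nFunctionEvals)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(list(command = "fit", curveFile = curveFile,
                           preset = preset, seed = seed,
                           maxGenerations = maxGenerations,
                           boundsFrac = boundsFrac))
  writeFitReport(fit, file.path(outDir, paste0(preset, "_fit.json")),
                 extra = list(config_md5 = hash))
  writeProfile(profileFromStack(fit@stack),
               file.path(outDir, paste0(preset, "_profile.dat")),
               header = sprintf("config_md5: %s", hash))
  invisible(fit)
}

#' Default fit-parameter table for a preset-shaped template
#'
#' [defaultParameters()] with the conventions used throughout the package:
#' the slab named \code{sio2} has its density fixed (0.660) and its
#' thickness bounded to the published 12--25 \eqn{\AA} window.
#'
#' @param template a \linkS4class{LayerStack} whose oxide slab is named
#'   \code{sio2}.
#' @param frac relative half-width of the default bounds.
#' @return parameter table.
#' @export
presetFitParameters <- function(template, frac = 0.25) {
  params <- defaultParameters(template, frac = frac)
  if ("sio2.rho" %in% params$name)
    params <- setParameter(params, "sio2.rho", fixed = TRUE)
  if ("sio2.d" %in% params$name)
    params <- setParameter(params, "sio2.d", lower = 12, upper = 25)
  params
}

#' Write the density profile of a preset or fit report
#'
#' @param source preset name or path to a fit-report JSON.
#' @param outFile output two-column ASCII file.
#' @param dz grid spacing (\eqn{\AA}).
#' @return invisibly, the \linkS4class{DensityProfile}.
#' @export
runProfile <- function(source, outFile = "profile.dat", dz = 0.5) {
  stack <- if (file.exists(source)) readFitReport(source)$stack
           else presetStack(makePreset(source))
  pr <- profileFromStack(stack, dz = dz)
  writeProfile(pr, outFile)
  .logmsg("profile: wrote %s", outFile)
  invisible(pr)
}

#' Composition report from a fit report or explicit densities
#'
#' When given fit-report JSONs, pulls the outer head-group density (slab
#' named \code{outer_heads} or \code{heads}) and, when present, the
#' \code{protein} slab density.
#'
#' @param rhoHead dry head-group density.
#' @param rhoBefore,rhoAfter outer head-group densities, given directly or
#'   via \code{fitBefore}/\code{fitAfter} report paths.
#' @param phiWBefore pre-incubation hydration, when known directly.
#' @param fitBefore,fitAfter optional fit-report JSON paths.
#' @param rhoProtein anhydrous protein density (default: from the bundled
#'   Hsp70 sequence).
#' @param geometry a \linkS4class{LipidGeometry}.
#' @param outFile output JSON path, or NULL to skip writing.
#' @return invisibly, the \linkS4class{CompositionReport}.
#' @export
runCompose <- function(rhoHead, rhoBefore = NULL, rhoAfter = NULL,
                       phiWBefore = NULL, fitBefore = NULL, fitAfter = NULL,
                       rhoProtein = NULL, geometry = lipidGeometry(),
                       outFile = "composition.json") {
  pickHead <- function(path) {
    st <- readFitReport(path)$stack
    nm <- slabNames(st)
    i <- match(c("outer_heads", "heads"), nm)
    i <- i[!is.na(i)][1L]
    if (is.na(i)) stop("no head-group slab found in ", path)
    densities(st)[i]
  }
  if (!is.null(fitBefore)) rhoBefore <- pickHead(fitBefore)
  if (!is.null(fitAfter)) rhoAfter <- pickHead(fitAfter)
  rhoProteinLayer <- NA_real_
  if (!is.null(fitAfter)) {
    st <- readFitReport(fitAfter)$stack
    i <- match("protein", slabNames(st))
    if (!is.na(i)) rhoProteinLayer <- densities(st)[i]
  }
  if (is.null(rhoProtein))
    rhoProtein <- proteinElectronDensityFromSequence(hsp70Sequence())
  report <- compositionReport(
    rhoHead = rhoHead, rhoMeasuredBefore = rhoBefore,
    rhoMeasuredAfter = rhoAfter, phiWBefore = phiWBefore,
    geometry = geometry, rhoProteinLayer = rhoProteinLayer,
    rhoProtein = rhoProtein)
  if (!is.null(outFile)) {
    writeCompositionReport(report, outFile)
    .logmsg("compose: wrote %s", outFile)
  }
  invisible(report)
}

#' Synthetic parameter-recovery study
#'
#' Simulates \code{nReplicates} noisy curves from a preset, fits each with
#' the preset as template, and summarizes the recovery of every thickness
#' and density: median fitted value, median absolute error and median
#' relative error against the generating values.
#'
#' @param preset preset name.
#' @param nReplicates number of simulate-fit replicates.
#' @param seed base seed; replicate r uses seed + r for both noise and fit.
#' @param relativeSigma noise level.
#' @param maxGenerations DE generation cap per fit.
#' @param boundsFrac relative half-width of the fit bounds.
#' @param outFile optional TSV summary path.
#' @return data.frame summary (one row per d/rho parameter).
#' @export
runRecover <- function(preset, nReplicates = 20L, seed = 1L,
                       relativeSigma = 0.02, maxGenerations = 400L,
                       boundsFrac = 0.25, outFile = NULL) {
  template <- presetStack(makePreset(preset))
  params <- presetFitParameters(template, frac = boundsFrac)
  truth <- params$value
  names(truth) <- params$name
  keep <- grepl("\\.(d|rho)$", params$name) & !params$fixed
  fitted <- matrix(NA_real_, nReplicates, sum(keep),
                   dimnames = list(NULL, params$name[keep]))
  for (r in seq_len(nReplicates)) {
    s <- seed + r
    curve <- simulateCurve(template, noise = noiseModel(
      "relative_gaussian", relativeSigma = relativeSigma, seed = s))
    fit <- fitStack(curve, template, params,
                    fitConfig(seed = s, maxGenerations = maxGenerations))
    fitted[r, ] <- fit@parameters$value[keep]
  }
  tv <- truth[colnames(fitted)]
  summary <- data.frame(
    parameter = colnames(fitted),
    truth = tv,
    medianFit = apply(fitted, 2L, median),
    medianAbsError = apply(abs(sweep(fitted, 2L, tv)), 2L, median),
    medianRelError = apply(abs(sweep(fitted, 2L, tv) /
                                 rep(tv, each = nReplicates)), 2L, median))
  rownames(summary) <- NULL
  attr(summary, "fitted") <- fitted
  if (!is.null(outFile)) {
    write.table(summary, outFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
    .logmsg("recover: wrote %s", outFile)
  }
  summary
}
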