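#' Accessors for slab stacks and curves
#'
#' \code{thicknesses}, \code{densities} and \code{roughnesses} return the
#' per-slab vectors of a \linkS4class{LayerStack} (fronting to backing);
#' \code{roughnesses} appends the backing-interface roughness, so its length
#' is \code{nSlabs(x) + 1}. \code{densities} on a
#' \linkS4class{ReflectivityCurve} is not defined; use \code{qValues},
#' \code{reflectivity} and \code{uncertainties} there.
#'
#' @param x the object.
#' @return numeric vectors (see details); \code{nSlabs} an integer.
#' @name stack-accessors
#' @examples
#' st <- presetStack(makePreset("dopc_monolayer_air"))
#' thicknesses(st); densities(st); roughnesses(st)
NULL

#' @rdname stack-accessors
#' @export
setGeneric("thicknesses", function(x) standardGeneric("thicknesses"))

#' @rdname stack-accessors
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))

#' @rdname stack-accessors
#' @export
setGeneric("roughnesses", function(x) standardGeneric("roughnesses"))

#' @rdname stack-accessors
#' @export
setGeneric("nSlabs", function(x) standardGeneric("nSlabs"))

#' @rdname stack-accessors
#' @export
setGeneric("fronting", function(x) standardGeneric("fronting"))

#' @rdname stack-accessors
#' @export
setGeneric("backing", function(x) standardGeneric("backing"))

#' @rdname stack-accessors
#' @export
setGeneric("electronDensity", function(x) standardGeneric("electronDensity"))

setMethod("thicknesses", "LayerStack", function(x)
  vapply(x@slabs, slot, numeric(1), name = "thickness"))

setMethod("densities", "LayerStack", function(x)
  vapply(x@slabs, slot, numeric(1), name = "electronDensity"))

setMethod("roughnesses", "LayerStack", function(x)
  c(vapply(x@slabs, slot, numeric(1), name = "roughness"), x@backingRoughness))

setMethod("nSlabs", "LayerStack", function(x) length(x@slabs))

setMethod("fronting", "LayerStack", function(x) x@fronting)

setMethod("backing", "LayerStack", function(x) x@backing)

setMethod("electronDensity", "Medium", function(x) x@electronDensity)

setMethod("electronDensity", "Slab", function(x) x@electronDensity)

#' @rdname curve-accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname curve-accessors
#' @export
setGeneric("reflectivity", function(x) standardGeneric("reflectivity"))

#' @rdname curve-accessors
#' @export
setGeneric("uncertainties", function(x) standardGeneric("uncertainties"))

#' Accessors for reflectivity curves
#'
#' @param x a \linkS4class{ReflectivityCurve}.
#' @return numeric vectors; \code{uncertainties} has length 0 when the curve
#'   carries no error bars.
#' @name curve-accessors
setMethod("qValues", "ReflectivityCurve", function(x) x@q)

setMethod("reflectivity", "ReflectivityCurve", function(x) x@R)

setMethod("uncertainties", "ReflectivityCurve", function(x) x@dR)

#' Slab names of a stack
#'
#' @param x a \linkS4class{LayerStack}.
#' @return character vector (slab1..slabN where unnamed).
#' @export
slabNames <- function(x) {
  stopifnot(is(x, "LayerStack"))
  nm <- names(x@slabs)
  n <- nSlabs(x)
  if (is.null(nm)) nm <- rep("", n)
  empty <- !nzchar(nm)
  nm[empty] <- paste0("slab", seq_len(n))[empty]
  nm
}

#' Accessors for fit results
#'
#' @param x a \linkS4class{FitResult}.
#' @return \code{fittedStack}: the best-fit \linkS4class{LayerStack};
#'   \code{fitParameters}: the parameter table (with an \code{sigma} column
#'   of 1-sigma uncertainties once [parameterUncertainty()] has run);
#'   \code{costValue}: the achieved cost; \code{costHistory}: best cost per
#'   generation.
#' @name fit-accessors
#' @export
setGeneric("fittedStack", function(x) standardGeneric("fittedStack"))

#' @rdname fit-accessors
#' @export
setGeneric("fitParameters", function(x) standardGeneric("fitParameters"))

#' @rdname fit-accessors
#' @export
setGeneric("costValue", function(x) standardGeneric("costValue"))

#' @rdname fit-accessors
#' @export
setGeneric("costHistory", function(x) standardGeneric("costHistory"))

setMethod("fittedStack", "FitResult", function(x) x@stack)

setMethod("fitParameters", "FitResult", function(x) {
  p <- x@parameters
  if (length(x@uncertainty)) p$sigma <- x@uncertainty[p$name]
  p
})

setMethod("costValue", "FitResult", function(x) x@costValue)

setMethod("costHistory", "FitResult", function(x) x@history)

#' @rdname stack-accessors
#' @export
presetStack <- function(x) {
  stopifnot(is(x, "ScenarioPreset"))
  x@stack
}

setMethod("show", "Medium", function(object) {
  cat(sprintf("Medium '%s': rho = %.3f e-/A^3\n",
              object@name, object@electronDensity))
})

setMethod("show", "Slab", function(object) {
  cat(sprintf("Slab: d = %.2f A, rho = %.3f e-/A^3, sigma = %.2f A\n",
              object@thickness, object@electronDensity, object@roughness))
})

setMethod("show", "LayerStack", function(object) {
  cat(sprintf("LayerStack: %s | %d slab(s) | %s\n",
              object@fronting@name, nSlabs(object), object@backing@name))
  if (nSlabs(object)) {
    df <- data.frame(slab = slabNames(object),
                     d = thicknesses(object),
                     rho = densities(object),
                     sigma = head(roughnesses(object), -1L))
    print(df, row.names = FALSE)
  }
  cat(sprintf("backing interface roughness: %.2f A\n", object@backingRoughness))
})

setMethod("show", "ReflectivityCurve", function(object) {
  cat(sprintf(
    "ReflectivityCurve: %d points, q in [%.4g, %.4g] A^-1, R in [%.3g, %.3g]%s\n",
    length(object@q), min(object@q), max(object@q), min(object@R),
    max(object@R), if (length(object@dR)) ", with dR" else ""))
})

setMethod("show", "FitResult", function(object) {
  free <- sum(!object@parameters$fixed)
  cat(sprintf(
    "FitResult: cost (%s) = %.6g | %d free / %d parameters | %d evaluations | seed %d\n",
    object@costType, object@costValue, free, nrow(object@parameters),
    object@nFunctionEvals, object@seed))
  print(fitParameters(object), row.names = FALSE, digits = 4)
})

setMethod("show", "ScenarioPreset", function(object) {
  cat(sprintf("ScenarioPreset '%s'\n", object@name))
  show(object@stack)
})

setMethod("show", "CompositionReport", function(object) {
  pc <- function(x) if (is.na(x)) "NA" else sprintf("%.1f%%", 100 * x)
  cat("CompositionReport\n")
  cat(sprintf("  outer head-group hydration: %s -> %s (delta %.1f pp)\n",
              pc(object@phiWBefore), pc(object@phiWAfter),
              object@deltaHydration))
  cat(sprintf("  displaced waters per lipid: %.2f (~ %d)\n",
              object@displacedWatersExact, object@displacedWaters))
  if (!is.na(object@phiProtein))
    cat(sprintf("  protein volume fraction in adsorbed layer: %s\n",
                pc(object@phiProtein)))
  if (!is.na(object@deltaRho))
    cat(sprintf("  outer head-group density change: %.3f e-/A^3\n",
                object@deltaRho))
})
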