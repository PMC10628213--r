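#' @import methods
#' @importFrom stats median pnorm rnorm rpois runif sd setNames optim
#' @importFrom utils read.table write.table head tail
#' @useDynLib xrrfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Classical electron radius in Angstrom; converts electron density
## (e-/A^3) to X-ray scattering length density (A^-2).
.r_e <- 2.818e-5

.finite_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Semi-infinite medium bounding a slab stack
#'
#' A \code{Medium} is one of the two semi-infinite phases (fronting, through
#' which the beam arrives, or backing) bounding a \linkS4class{LayerStack}.
#' It carries a label and an electron density in e\eqn{^-}\,\eqn{\AA^{-3}}.
#'
#' @slot name character label.
#' @slot electronDensity electron density (e\eqn{^-}\,\eqn{\AA^{-3}}, >= 0).
#' @seealso [Medium()], [mediumAir()], [mediumBuffer()], [mediumSilicon()]
#' @exportClass Medium
setClass("Medium", representation(
  name = "character",
  electronDensity = "numeric"
), validity = function(object) {
  if (!.finite_scalar(object@electronDensity))
    return("electronDensity must be a finite scalar")
  if (object@electronDensity < 0)
    return("electronDensity must be >= 0")
  TRUE
})

#' A homogeneous slab of a layered interface model
#'
#' One layer of a slab model: thickness \code{d} (\eqn{\AA}), electron
#' density \code{rho} (e\eqn{^-}\,\eqn{\AA^{-3}}) and Gaussian roughness
#' \code{sigma} (\eqn{\AA}) of the interface on the *fronting* side of the
#' slab (the side the beam arrives from).
#'
#' @slot thickness slab thickness in \eqn{\AA} (> 0).
#' @slot electronDensity electron density in e\eqn{^-}\,\eqn{\AA^{-3}} (>= 0).
#' @slot roughness rms roughness of the fronting-side interface, \eqn{\AA} (>= 0).
#' @seealso [Slab()], [LayerStack()]
#' @exportClass Slab
setClass("Slab", representation(
  thickness = "numeric",
  electronDensity = "numeric",
  roughness = "numeric"
), validity = function(object) {
  if (!.finite_scalar(object@thickness) || object@thickness <= 0)
    return("thickness must be a finite scalar > 0")
  if (!.finite_scalar(object@electronDensity) || object@electronDensity < 0)
    return("electronDensity must be a finite scalar >= 0")
  if (!.finite_scalar(object@roughness) || object@roughness < 0)
    return("roughness must be a finite scalar >= 0")
  TRUE
})

#' Ordered slab stack between two semi-infinite media
#'
#' The full interfacial model the fitter optimizes: a fronting
#' \linkS4class{Medium}, an ordered list of \linkS4class{Slab}s (listed from
#' the fronting toward the backing, i.e. beam side first) and a backing
#' Medium. \code{backingRoughness} is the rms roughness of the last
#' slab/backing interface. An empty slab list is legal and describes a bare
#' interface.
#'
#' @slot fronting,backing \linkS4class{Medium} objects.
#' @slot slabs list of \linkS4class{Slab}, fronting to backing.
#' @slot backingRoughness roughness of the slab/backing interface (\eqn{\AA}).
#' @seealso [LayerStack()], [reflectivityAbeles()], [profileFromStack()]
#' @exportClass LayerStack
setClass("LayerStack", representation(
  fronting = "Medium",
  slabs = "list",
  backing = "Medium",
  backingRoughness = "numeric"
), validity = function(object) {
  if (!all(vapply(object@slabs, is, logical(1), class2 = "Slab")))
    return("slabs must all be Slab objects")
  for (s in object@slabs) {
    v <- validObject(s, test = TRUE)
    if (!isTRUE(v)) return(v)
  }
  if (!.finite_scalar(object@backingRoughness) || object@backingRoughness < 0)
    return("backingRoughness must be a finite scalar >= 0")
  TRUE
})

#' Specular reflectivity curve
#'
#' The observable: momentum transfer \code{q} (\eqn{\AA^{-1}}, strictly
#' increasing, > 0), reflectivity \code{R} (dimensionless, >= 0) and optional
#' 1-sigma uncertainties \code{dR} (length 0 when absent).
#'
#' @slot q momentum transfer grid, \eqn{\AA^{-1}}.
#' @slot R reflectivity values.
#' @slot dR optional 1-sigma uncertainties (> 0 where present).
#' @seealso [ReflectivityCurve()], [simulateCurve()], [readReflectivity()]
#' @exportClass ReflectivityCurve
setClass("ReflectivityCurve", representation(
  q = "numeric",
  R = "numeric",
  dR = "numeric"
), validity = function(object) {
  if (length(object@q) != length(object@R))
    return("q and R must have equal length")
  if (any(!is.finite(object@q)) || any(!is.finite(object@R)))
    return("q and R must be finite")
  if (any(object@q <= 0)) return("q must be > 0")
  if (any(diff(object@q) <= 0)) return("q must be strictly increasing")
  if (any(object@R < 0)) return("R must be >= 0")
  if (length(object@dR)) {
    if (length(object@dR) != length(object@q))
      return("dR must match q in length (or be absent)")
    if (any(!is.finite(object@dR)) || any(object@dR <= 0))
      return("dR must be finite and > 0 where present")
  }
  TRUE
})

#' Beamline instrument description
#'
#' Wavelength/energy of the monochromatic beam, used only to convert
#' incidence angles to momentum transfer. Defaults describe a 22 keV
#' high-energy reflectometer (\eqn{\lambda} = 0.56 \eqn{\AA}).
#'
#' @slot wavelength wavelength \eqn{\lambda} in \eqn{\AA} (> 0).
#' @slot energy photon energy in keV, consistent with \eqn{\lambda} =
#'   12.3984 / E within 1 percent.
#' @seealso [Instrument()], [qzFromAngle()]
#' @exportClass Instrument
setClass("Instrument", representation(
  wavelength = "numeric",
  energy = "numeric"
), validity = function(object) {
  if (!.finite_scalar(object@wavelength) || object@wavelength <= 0)
    return("wavelength must be a finite scalar > 0")
  if (length(object@energy)) {
    if (!.finite_scalar(object@energy) || object@energy <= 0)
      return("energy must be a finite scalar > 0")
    lam <- 12.3984 / object@energy
    if (abs(lam - object@wavelength) / object@wavelength > 0.01)
      return("wavelength and energy are inconsistent (lambda != 12.3984/E within 1%)")
  }
  TRUE
})

#' Continuous electron-density profile
#'
#' The laterally averaged profile rho(z) implied by a slab stack, with z in
#' \eqn{\AA} increasing from the fronting toward the backing and z = 0 at
#' the nominal fronting/first-slab interface.
#'
#' @slot z depth grid (\eqn{\AA}), strictly increasing.
#' @slot rho electron density (e\eqn{^-}\,\eqn{\AA^{-3}}).
#' @seealso [profileFromStack()], [integratedDensity()]
#' @exportClass DensityProfile
setClass("DensityProfile", representation(
  z = "numeric",
  rho = "numeric"
), validity = function(object) {
  if (length(object@z) != length(object@rho))
    return("z and rho must have equal length")
  if (any(!is.finite(object@z)) || any(!is.finite(object@rho)))
    return("z and rho must be finite")
  if (length(object@z) > 1 && any(diff(object@z) <= 0))
    return("z must be strictly increasing")
  TRUE
})

#' Result of a stochastic slab-stack fit
#'
#' Best-fit stack, the parameter table with bounds and fixed flags, the cost
#' achieved, per-parameter 1-sigma uncertainties (filled by
#' [parameterUncertainty()]), the best-cost-per-generation trace, and full
#' provenance (seed, cost type, number of function evaluations, a checksum
#' of the data fitted).
#'
#' @slot stack best-fit \linkS4class{LayerStack}.
#' @slot parameters data.frame with columns name, value, lower, upper, fixed.
#' @slot costValue achieved cost.
#' @slot costType "log_unweighted" or "chi2_weighted".
#' @slot scale,background intensity scale and constant background at the optimum.
#' @slot uncertainty named numeric, 1-sigma per parameter (NA until estimated).
#' @slot nFunctionEvals number of cost evaluations.
#' @slot seed RNG seed the search was run with.
#' @slot history best cost after each generation (non-increasing).
#' @slot curveChecksum checksum of (q, R) used, for compatibility checks.
#' @seealso [fitStack()], [compareModels()], [parameterUncertainty()]
#' @exportClass FitResult
setClass("FitResult", representation(
  stack = "LayerStack",
  parameters = "data.frame",
  costValue = "numeric",
  costType = "character",
  scale = "numeric",
  background = "numeric",
  uncertainty = "numeric",
  nFunctionEvals = "integer",
  seed = "integer",
  history = "numeric",
  curveChecksum = "numeric"
), validity = function(object) {
  need <- c("name", "value", "lower", "upper", "fixed")
  if (!all(need %in% names(object@parameters)))
    return("parameters must have columns name, value, lower, upper, fixed")
  p <- object@parameters
  if (any(p$value < p$lower - 1e-12) || any(p$value > p$upper + 1e-12))
    return("parameter values must lie within their bounds")
  if (length(object@history) > 1 && any(diff(object@history) > 1e-12))
    return("best-so-far cost history must be non-increasing")
  TRUE
})

#' Noise model for simulated reflectivity curves
#'
#' Either Poisson counting statistics at a given incident count rate
#' (\code{kind = "poisson_counts"}) or multiplicative Gaussian noise of
#' fixed relative width (\code{kind = "relative_gaussian"}).
#'
#' @slot kind "poisson_counts" or "relative_gaussian".
#' @slot incidentCounts incident counts I0 per point (Poisson mode).
#' @slot relativeSigma relative 1-sigma (Gaussian mode).
#' @slot backgroundRate mean background counts per point (Poisson mode).
#' @slot seed integer seed recorded in the simulated curve's metadata.
#' @seealso [noiseModel()], [simulateCurve()]
#' @exportClass NoiseModel
setClass("NoiseModel", representation(
  kind = "character",
  incidentCounts = "numeric",
  relativeSigma = "numeric",
  backgroundRate = "numeric",
  seed = "integer"
), validity = function(object) {
  if (!object@kind %in% c("poisson_counts", "relative_gaussian"))
    return("kind must be 'poisson_counts' or 'relative_gaussian'")
  if (object@kind == "poisson_counts" &&
      (!.finite_scalar(object@incidentCounts) || object@incidentCounts <= 0))
    return("incidentCounts must be > 0 for poisson_counts")
  if (object@kind == "relative_gaussian" &&
      (!.finite_scalar(object@relativeSigma) || object@relativeSigma < 0))
    return("relativeSigma must be >= 0 for relative_gaussian")
  if (!.finite_scalar(object@backgroundRate) || object@backgroundRate < 0)
    return("backgroundRate must be >= 0")
  TRUE
})

#' Named membrane scenario with its slab stack
#'
#' Couples a scenario name (e.g. \code{"dopc_monolayer_air"}) to the
#' published slab stack it denotes; see [makePreset()] for the catalogue.
#'
#' @slot name scenario name.
#' @slot stack the \linkS4class{LayerStack} for that scenario.
#' @exportClass ScenarioPreset
setClass("ScenarioPreset", representation(
  name = "character",
  stack = "LayerStack"
))

#' Membrane composition report
#'
#' Hydration of the outer head group before and after protein incubation,
#' the hydration change, the number of displaced water molecules per lipid,
#' and (when a protein layer is present) the protein volume fraction.
#' Fractions are stored as fractions in [0, 1]; \code{show()} prints
#' percentages.
#'
#' @slot phiWBefore,phiWAfter water volume fractions of the outer head group.
#' @slot deltaHydration hydration change, percentage points (before - after).
#' @slot displacedWatersExact displaced waters per lipid, unrounded.
#' @slot displacedWaters displaced waters per lipid, nearest integer.
#' @slot phiProtein protein volume fraction of the adsorbed layer (NA if none).
#' @slot deltaRho change of the outer-head-group electron density
#'   (e\eqn{^-}\,\eqn{\AA^{-3}}; NA when hydration was supplied directly).
#' @seealso [compositionReport()], [waterFraction()], [proteinFraction()]
#' @exportClass CompositionReport
setClass("CompositionReport", representation(
  phiWBefore = "numeric",
  phiWAfter = "numeric",
  deltaHydration = "numeric",
  displacedWatersExact = "numeric",
  displacedWaters = "integer",
  phiProtein = "numeric",
  deltaRho = "numeric"
), validity = function(object) {
  frac_ok <- function(x) length(x) == 1L && (is.na(x) || (x >= 0 && x <= 1))
  if (!frac_ok(object@phiWBefore) || !frac_ok(object@phiWAfter))
    return("hydration fractions must be in [0, 1]")
  if (!is.na(object@displacedWaters) && object@displacedWaters < 0)
    return("displacedWaters must be >= 0")
  if (!frac_ok(object@phiProtein))
    return("phiProtein must be in [0, 1] or NA")
  TRUE
})

#' Lipid head-group geometry
#'
#' Geometric constants used to convert a hydration change into displaced
#' water molecules per lipid: area per lipid (default 70 \eqn{\AA^2}),
#' head-group thickness (default 11.5 \eqn{\AA}, midrange of 11--12
#' \eqn{\AA}) and the volume of one water molecule (29 \eqn{\AA^3}).
#'
#' @slot areaPerLipid \eqn{\AA^2} (> 0).
#' @slot headgroupThickness \eqn{\AA} (> 0).
#' @slot waterVolume \eqn{\AA^3} (> 0).
#' @seealso [lipidGeometry()], [displacedWaters()]
#' @exportClass LipidGeometry
setClass("LipidGeometry", representation(
  areaPerLipid = "numeric",
  headgroupThickness = "numeric",
  waterVolume = "numeric"
), validity = function(object) {
  vals <- c(object@areaPerLipid, object@headgroupThickness, object@waterVolume)
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all geometry fields must be finite and > 0")
  TRUE
})

#' Configuration of the stochastic stack fit
#'
#' Settings of the differential-evolution (genetic-type) global search:
#' seed, population size (NA means 15 per free parameter), generation cap,
#' mutation weight F, crossover rate CR, relative convergence tolerance,
#' and the cost functional ("log_unweighted": mean squared residual of
#' log10 R; "chi2_weighted": squared residuals over dR^2).
#'
#' @slot seed integer RNG seed.
#' @slot populationSize population size; NA for 15 x free parameters.
#' @slot maxGenerations generation cap.
#' @slot mutationF DE mutation weight.
#' @slot crossoverCR DE crossover rate.
#' @slot tol relative spread of population costs at which to stop.
#' @slot polish run a bounded local refinement (L-BFGS-B) from the best
#'   population member after the evolutionary search.
#' @slot cost "log_unweighted" or "chi2_weighted".
#' @seealso [fitConfig()], [fitStack()]
#' @exportClass FitConfig
setClass("FitConfig", representation(
  seed = "integer",
  populationSize = "numeric",
  maxGenerations = "integer",
  mutationF = "numeric",
  crossoverCR = "numeric",
  tol = "numeric",
  polish = "logical",
  cost = "character"
), validity = function(object) {
  if (!is.na(object@populationSize) && object@populationSize < 4)
    return("populationSize must be >= 4")
  if (object@maxGenerations < 1) return("maxGenerations must be >= 1")
  if (!object@cost %in% c("log_unweighted", "chi2_weighted"))
    return("cost must be 'log_unweighted' or 'chi2_weighted'")
  if (object@mutationF <= 0 || object@crossoverCR < 0 || object@crossoverCR > 1)
    return("invalid DE hyperparameters")
  TRUE
})
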