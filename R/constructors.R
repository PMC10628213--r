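#' Create a semi-infinite medium
#'
#' @param name text label.
#' @param electronDensity electron density in e\eqn{^-}\,\eqn{\AA^{-3}}.
#' @return A \linkS4class{Medium}.
#' @examples
#' Medium("buffer", 0.335)
#' @export
Medium <- function(name, electronDensity) {
  new("Medium", name = as.character(name),
      electronDensity = as.numeric(electronDensity))
}

#' Standard media
#'
#' Convenience constructors for the media of a supported-membrane XRR
#' experiment: air (electron density 0), aqueous buffer (0.335
#' e\eqn{^-}\,\eqn{\AA^{-3}}), silicon (0.692) and silicon oxide (0.660).
#' The buffer, Si and SiO2 densities are the constants conventionally held
#' fixed during refinement.
#'
#' @return A \linkS4class{Medium}.
#' @examples
#' criticalQ(mediumBuffer(), mediumSilicon())
#' @export
mediumAir <- function() Medium("air", 0)

#' @rdname mediumAir
#' @export
mediumBuffer <- function() Medium("buffer", 0.335)

#' @rdname mediumAir
#' @export
mediumSilicon <- function() Medium("Si", 0.692)

#' @rdname mediumAir
#' @export
mediumSiliconOxide <- function() Medium("SiO2", 0.660)

#' Create a slab
#'
#' @param thickness slab thickness in \eqn{\AA} (> 0).
#' @param electronDensity electron density in e\eqn{^-}\,\eqn{\AA^{-3}} (>= 0).
#' @param roughness rms roughness (\eqn{\AA}) of the interface on the
#'   fronting side of the slab.
#' @return A \linkS4class{Slab}.
#' @examples
#' Slab(11.7, 0.318, 3.0)   # DOPC hydrocarbon chains in air
#' @export
Slab <- function(thickness, electronDensity, roughness = 0) {
  new("Slab", thickness = as.numeric(thickness),
      electronDensity = as.numeric(electronDensity),
      roughness = as.numeric(roughness))
}

#' Create a layer stack
#'
#' Slabs are listed from the fronting (beam) side toward the backing.
#' A roughness larger than twice the thickness of the thinner slab adjacent
#' to its interface smears the interface over more than the layer itself;
#' such stacks are legal but flagged with a warning.
#'
#' @param fronting,backing \linkS4class{Medium} objects.
#' @param slabs list of \linkS4class{Slab}s (possibly named), beam side first.
#' @param backingRoughness roughness of the last-slab/backing interface (\eqn{\AA}).
#' @return A \linkS4class{LayerStack}.
#' @examples
#' LayerStack(mediumAir(),
#'            list(chains = Slab(11.7, 0.318, 3.0),
#'                 heads  = Slab(7.4, 0.510, 4.7),
#'                 sio2   = Slab(18, 0.660, 3.0)),
#'            mediumSilicon(), backingRoughness = 3)
#' @export
LayerStack <- function(fronting, slabs = list(), backing, backingRoughness = 0) {
  if (is(slabs, "Slab")) slabs <- list(slabs)
  obj <- new("LayerStack", fronting = fronting, slabs = slabs,
             backing = backing, backingRoughness = as.numeric(backingRoughness))
  d <- thicknesses(obj)
  sig <- roughnesses(obj)           # length n+1: slab interfaces + backing
  n <- length(d)
  if (n) {
    ## thinner slab adjacent to each interface (media are semi-infinite)
    adj <- c(d[1L], if (n > 1) pmin(d[-n], d[-1L]), d[n])
    bad <- which(sig > 2 * adj)
    if (length(bad))
      warning("roughness exceeds twice the thickness of the thinner adjacent ",
              "slab at interface(s) ", paste(bad, collapse = ", "),
              "; the smeared profile may be unphysical")
  }
  obj
}

#' Create a reflectivity curve
#'
#' @param q momentum transfer grid (\eqn{\AA^{-1}}, strictly increasing, > 0).
#' @param R reflectivity.
#' @param dR optional 1-sigma uncertainties.
#' @return A \linkS4class{ReflectivityCurve}.
#' @export
ReflectivityCurve <- function(q, R, dR = numeric(0)) {
  new("ReflectivityCurve", q = as.numeric(q), R = as.numeric(R),
      dR = as.numeric(dR))
}

#' Create an instrument description
#'
#' @param wavelength beam wavelength \eqn{\lambda} in \eqn{\AA}.
#' @param energy photon energy in keV; optional, must agree with
#'   \eqn{\lambda} = 12.3984/E within 1 percent when given.
#' @return An \linkS4class{Instrument}.
#' @examples
#' Instrument()            # 22 keV, 0.56 Angstrom
#' @export
Instrument <- function(wavelength = 0.56, energy = 22) {
  new("Instrument", wavelength = as.numeric(wavelength),
      energy = as.numeric(energy))
}

#' Create a lipid head-group geometry
#'
#' @param areaPerLipid area per lipid molecule, \eqn{\AA^2}.
#' @param headgroupThickness head-group thickness, \eqn{\AA}.
#' @param waterVolume volume of one water molecule, \eqn{\AA^3}.
#' @return A \linkS4class{LipidGeometry}.
#' @export
lipidGeometry <- function(areaPerLipid = 70, headgroupThickness = 11.5,
                          waterVolume = 29) {
  new("LipidGeometry", areaPerLipid = as.numeric(areaPerLipid),
      headgroupThickness = as.numeric(headgroupThickness),
      waterVolume = as.numeric(waterVolume))
}

#' Create a noise model for curve simulation
#'
#' @param kind "relative_gaussian" (multiplicative Gaussian noise of fixed
#'   relative width) or "poisson_counts" (Poisson counting statistics).
#' @param relativeSigma relative 1-sigma for the Gaussian model.
#' @param incidentCounts incident counts per point for the Poisson model.
#' @param backgroundRate mean background counts per point (Poisson model).
#' @param seed integer seed; recorded with the simulated curve.
#' @return A \linkS4class{NoiseModel}.
#' @examples
#' noiseModel("relative_gaussian", relativeSigma = 0.02, seed = 1)
#' @export
noiseModel <- function(kind = c("relative_gaussian", "poisson_counts"),
                       relativeSigma = 0.02, incidentCounts = 1e8,
                       backgroundRate = 0, seed = 1L) {
  kind <- match.arg(kind)
  new("NoiseModel", kind = kind, relativeSigma = as.numeric(relativeSigma),
      incidentCounts = as.numeric(incidentCounts),
      backgroundRate = as.numeric(backgroundRate), seed = as.integer(seed))
}
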