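## published slab parameters for the membrane scenarios; SiO2 thickness
## defaults to 18 A (midpoint of the reported 12-25 A range) and substrate
## interfaces to 3 A rms (typical polished Si), neither being printed.
.presetCatalog <- function() {
  sio2 <- function() Slab(18, 0.660, 3)
  list(
    dopc_monolayer_air = LayerStack(
      mediumAir(),
      list(chains = Slab(11.7, 0.318, 3.0),
           heads = Slab(7.4, 0.510, 4.7),
           sio2 = sio2()),
      mediumSilicon(), backingRoughness = 3),
    dopc_hsp70_bilayer = LayerStack(
      mediumBuffer(),
      list(outer_heads = Slab(12.1, 0.394, 4.9),
           chains = Slab(22.5, 0.275, 5.6),
           inner_heads = Slab(9.1, 0.494, 7.8),
           sio2 = sio2()),
      mediumSilicon(), backingRoughness = 3),
    dopcdops_monolayer_air = LayerStack(
      mediumAir(),
      list(chains = Slab(13.0, 0.248, 5.5),
           heads = Slab(8.0, 0.504, 3.4),
           sio2 = sio2()),
      mediumSilicon(), backingRoughness = 3),
    dopcdops_hsp70_bilayer = LayerStack(
      mediumBuffer(),
      list(protein = Slab(22.6, 0.372, 11.9),
           outer_heads = Slab(10.8, 0.450, 4.7),
           chains = Slab(26.5, 0.284, 6.0),
           inner_heads = Slab(8.6, 0.406, 6.7),
           sio2 = sio2()),
      mediumSilicon(), backingRoughness = 3),
    disrupted_one_slab = LayerStack(
      mediumBuffer(),
      list(layer = Slab(40, 0.30, 10),
           sio2 = sio2()),
      mediumSilicon(), backingRoughness = 3)
  )
}

#' Scenario presets for supported DOPC / DOPC-DOPS membranes
#'
#' Named slab stacks for the membrane scenarios of the Hsp70 adsorption
#' study: DOPC and DOPC/20 mol\% DOPS monolayers in air (three slabs:
#' chains, head groups, SiO2), the corresponding bilayers after Hsp70
#' proteoliposome incubation in buffer (DOPC: outer heads / chains / inner
#' heads / SiO2; DOPC/DOPS: an additional Hsp70 protein layer on top), and
#' a degenerate single diffuse slab describing a disrupted bilayer. Slab
#' parameters are the published best-fit values; substrate details
#' (SiO2 thickness 18 \eqn{\AA}, interface roughness 3 \eqn{\AA}) are
#' conventional defaults.
#'
#' @param name one of \code{presetNames()}.
#' @return A \linkS4class{ScenarioPreset}.
#' @examples
#' makePreset("dopcdops_hsp70_bilayer")
#' @export
makePreset <- function(name) {
  cat <- .presetCatalog()
  if (!name %in% names(cat))
    stop("unknown preset '", name, "'; see presetNames()")
  new("ScenarioPreset", name = name, stack = cat[[name]])
}

#' @rdname makePreset
#' @export
presetNames <- function() names(.presetCatalog())

#' Simulate a reflectivity curve with noise
#'
#' Evaluates the exact slab-model reflectivity of \code{stack} on the q
#' grid and perturbs it with the chosen noise model. In Poisson mode the
#' expected counts at each point are \eqn{I_0 R + b}; the background is
#' subtracted again after drawing, so the simulated curve is an unbiased
#' estimate of the model. dR carries the 1-sigma uncertainty implied by the
#' noise model. The draw is reproducible through the noise model's seed.
#'
#' @param stack a \linkS4class{LayerStack} (or \linkS4class{ScenarioPreset}).
#' @param q q grid (\eqn{\AA^{-1}}, > 0); default [defaultQGrid()].
#' @param noise a \linkS4class{NoiseModel}; \code{NULL} for a noiseless
#'   curve.
#' @return A \linkS4class{ReflectivityCurve}.
#' @examples
#' cu <- simulateCurve(makePreset("dopc_monolayer_air"),
#'                     noise = noiseModel(relativeSigma = 0.02, seed = 1))
#' @export
simulateCurve <- function(stack, q = defaultQGrid(), noise = NULL) {
  if (is(stack, "ScenarioPreset")) stack <- stack@stack
  if (any(q <= 0)) stop("q grid must be > 0")
  R <- reflectivityAbeles(stack, q)
  if (is.null(noise)) return(ReflectivityCurve(q, R))
  set.seed(noise@seed)
  if (noise@kind == "relative_gaussian") {
    if (noise@relativeSigma == 0) return(ReflectivityCurve(q, R))
    Rs <- R * (1 + noise@relativeSigma * rnorm(length(q)))
    dR <- noise@relativeSigma * R
  } else {
    I0 <- noise@incidentCounts
    counts <- rpois(length(q), I0 * R + noise@backgroundRate)
    Rs <- (counts - noise@backgroundRate) / I0
    dR <- sqrt(pmax(counts, 1)) / I0
  }
  Rs <- pmax(Rs, 0)
  ReflectivityCurve(q, Rs, pmax(dR, 1e-300))
}
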