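#' Momentum transfer from incidence angle
#'
#' Converts grazing incidence angles to the specular momentum transfer
#' \eqn{q_z = 4\pi \sin(\alpha_i)/\lambda}.
#'
#' @param alphaDeg incidence angle(s) in degrees, in [0, 90).
#' @param instrument an \linkS4class{Instrument} supplying \eqn{\lambda}.
#' @return q in \eqn{\AA^{-1}}, same length as \code{alphaDeg}.
#' @examples
#' qzFromAngle(0.1)           # ~0.0392 A^-1 at 0.56 A
#' @export
qzFromAngle <- function(alphaDeg, instrument = Instrument()) {
  if (any(!is.finite(alphaDeg)) || any(alphaDeg < 0) || any(alphaDeg >= 90))
    stop("alphaDeg must be finite and in [0, 90)")
  4 * pi * sin(alphaDeg * pi / 180) / instrument@wavelength
}

#' Electron density to X-ray scattering length density
#'
#' \eqn{\mathrm{sld} = \rho\, r_e} with the classical electron radius
#' \eqn{r_e = 2.818\times10^{-5}} \eqn{\AA}.
#'
#' @param rho electron density in e\eqn{^-}\,\eqn{\AA^{-3}} (>= 0).
#' @return scattering length density in \eqn{\AA^{-2}}.
#' @examples
#' electronDensityToSld(0.335)    # buffer, ~9.44e-6 A^-2
#' @export
electronDensityToSld <- function(rho) {
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("rho must be finite and >= 0")
  rho * .r_e
}

#' Critical momentum transfer of an interface
#'
#' Total external reflection occurs below
#' \eqn{q_c = \sqrt{16\pi\,\Delta\mathrm{sld}}}. When the backing is less
#' dense than the fronting there is no total-reflection edge and 0 is
#' returned.
#'
#' @param fronting,backing \linkS4class{Medium} objects.
#' @return \eqn{q_c} in \eqn{\AA^{-1}}.
#' @examples
#' criticalQ(mediumAir(), mediumSilicon())     # ~0.0313
#' criticalQ(mediumBuffer(), mediumSilicon())  # ~0.0225
#' @export
criticalQ <- function(fronting, backing) {
  dsld <- electronDensityToSld(backing@electronDensity) -
    electronDensityToSld(fronting@electronDensity)
  if (dsld <= 0) return(0)
  sqrt(16 * pi * dsld)
}

## internal: stack -> arrays for the optical kernels
.stackArrays <- function(stack) {
  list(
    rho = unname(c(stack@fronting@electronDensity, densities(stack),
                   stack@backing@electronDensity)),
    d = unname(thicknesses(stack)),
    sigma = unname(roughnesses(stack))
  )
}

.checkStackQ <- function(stack, q) {
  a <- .stackArrays(stack)
  if (any(!is.finite(c(a$rho, a$d, a$sigma))))
    stop("stack parameters must be finite")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q must be finite and > 0")
  a
}

#' Specular reflectivity by the Abeles transfer matrix
#'
#' Exact specular reflectivity of a \linkS4class{LayerStack} on a q grid,
#' computed with the Abeles (transfer-matrix) formalism. Absorption is
#' neglected (real optical profile, appropriate for high-energy X-rays on
#' these materials). Gaussian interfacial roughness enters through the
#' Névot–Croce factor \eqn{\exp(-2 k_i k_{i+1} \sigma^2)} on each
#' interface's Fresnel coefficient, with \eqn{\sigma} taken from the slab
#' on the backing side of that interface.
#'
#' @param stack a \linkS4class{LayerStack}.
#' @param q momentum transfer grid (\eqn{\AA^{-1}}, > 0).
#' @param roughnessModel "nevot_croce" (default) or "none" (sharp interfaces).
#' @return reflectivity, same length as q.
#' @seealso [reflectivityParratt()] for the independent recursion,
#'   [simulateCurve()] to add noise.
#' @examples
#' st <- presetStack(makePreset("dopc_monolayer_air"))
#' R <- reflectivityAbeles(st, defaultQGrid())
#' @export
reflectivityAbeles <- function(stack, q,
                               roughnessModel = c("nevot_croce", "none")) {
  roughnessModel <- match.arg(roughnessModel)
  a <- .checkStackQ(stack, q)
  sigma <- if (roughnessModel == "none") numeric(length(a$sigma)) else a$sigma
  .abelesKernel(q, electronDensityToSld(a$rho), a$d, sigma)
}

#' Specular reflectivity by the Parratt recursion
#'
#' Same model as [reflectivityAbeles()] but evaluated with the Parratt
#' recursion, implemented independently in R. The two formalisms are exactly
#' equivalent; this routine exists as a cross-check of the transfer-matrix
#' kernel and is the slower path.
#'
#' @inheritParams reflectivityAbeles
#' @return reflectivity, same length as q.
#' @export
reflectivityParratt <- function(stack, q,
                                roughnessModel = c("nevot_croce", "none")) {
  roughnessModel <- match.arg(roughnessModel)
  a <- .checkStackQ(stack, q)
  sigma <- if (roughnessModel == "none") numeric(length(a$sigma)) else a$sigma
  sld <- electronDensityToSld(a$rho)
  n <- length(a$d)                     # internal slabs
  kz0 <- q / 2
  ## kz in each layer, complex below the local critical edge
  kz <- lapply(seq_along(sld), function(j)
    sqrt(as.complex(kz0^2 - 4 * pi * (sld[j] - sld[1L]))))
  ## recursion upward from the backing; X = reflected/incident amplitude
  ## just above each interface
  X <- rep(0 + 0i, length(q))
  for (i in (n + 1L):1L) {             # interface i between layer i and i+1
    ka <- kz[[i]]
    kb <- kz[[i + 1L]]
    r <- (ka - kb) / (ka + kb) * exp(-2 * ka * kb * sigma[i]^2)
    X <- (r + X) / (1 + r * X)
    if (i > 1L) X <- X * exp(2i * ka * a$d[i - 1L])
  }
  Mod(X)^2
}

#' Default simulation q grid
#'
#' 200 log-spaced points in [0.01, 0.7] \eqn{\AA^{-1}}, a typical range for
#' high-energy solid/liquid interface reflectometry.
#'
#' @param n number of points.
#' @param qmin,qmax grid limits in \eqn{\AA^{-1}}.
#' @return numeric vector of q values.
#' @export
defaultQGrid <- function(n = 200, qmin = 0.01, qmax = 0.7) {
  exp(seq(log(qmin), log(qmax), length.out = n))
}

#' Constant-dq/q Gaussian resolution smearing
#'
#' Smears a model reflectivity with a Gaussian resolution function of
#' constant relative width dq/q, by Gauss–Hermite quadrature. Off by
#' default everywhere in the package; provided as a hook because beamline
#' resolution, when significant, broadens the Kiessig minima.
#'
#' @inheritParams reflectivityAbeles
#' @param dqByQ relative FWHM-equivalent width dq/q (1-sigma).
#' @param nPoints quadrature points (odd).
#' @return smeared reflectivity, same length as q.
#' @export
reflectivitySmeared <- function(stack, q, dqByQ = 0.0, nPoints = 17L,
                                roughnessModel = c("nevot_croce", "none")) {
  roughnessModel <- match.arg(roughnessModel)
  if (dqByQ <= 0) return(reflectivityAbeles(stack, q, roughnessModel))
  ## simple Gauss quadrature over +-3 sigma of the Gaussian kernel
  u <- seq(-3, 3, length.out = nPoints)
  w <- exp(-u^2 / 2)
  w <- w / sum(w)
  out <- numeric(length(q))
  for (k in seq_along(u)) {
    qk <- pmax(q * (1 + u[k] * dqByQ), 1e-6)
    out <- out + w[k] * reflectivityAbeles(stack, qk, roughnessModel)
  }
  out
}
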