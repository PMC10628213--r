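#' Electron-density profile of a slab stack
#'
#' Reconstructs the continuous, laterally averaged electron-density profile
#' \eqn{\rho(z)} implied by a fitted stack: a sum of density steps at the
#' nominal interface positions, each smeared by an error function of width
#' \eqn{\sigma} of that interface,
#' \eqn{\rho(z) = \rho_f + \sum_i \Delta\rho_i\,\Phi((z - z_i)/\sigma_i)}.
#' z = 0 sits at the nominal fronting/first-slab interface and increases
#' toward the backing. With all \eqn{\sigma = 0} the profile is exactly
#' piecewise constant at the slab densities.
#'
#' @param stack a \linkS4class{LayerStack}.
#' @param zGrid increasing depth grid (\eqn{\AA}); the default spans
#'   5\eqn{\sigma_{max}} (at least 10 \eqn{\AA}) beyond the outer interfaces
#'   at 0.5 \eqn{\AA} spacing.
#' @param dz grid spacing used when \code{zGrid} is NULL.
#' @return A \linkS4class{DensityProfile}.
#' @examples
#' pr <- profileFromStack(presetStack(makePreset("dopc_monolayer_air")))
#' @export
profileFromStack <- function(stack, zGrid = NULL, dz = 0.5) {
  a <- .stackArrays(stack)
  zIface <- c(0, cumsum(a$d))          # nominal interface positions
  sigmax <- max(a$sigma, 0)
  if (is.null(zGrid)) {
    pad <- max(10, 5 * sigmax)
    zGrid <- seq(-pad, max(zIface) + pad, by = dz)
  }
  if (any(!is.finite(zGrid)) || (length(zGrid) > 1 && any(diff(zGrid) <= 0)))
    stop("zGrid must be finite and strictly increasing")
  rho <- rep(a$rho[1L], length(zGrid))
  for (i in seq_along(zIface)) {
    drho <- a$rho[i + 1L] - a$rho[i]
    s <- a$sigma[i]
    step <- if (s > 0) pnorm(zGrid, mean = zIface[i], sd = s)
            else as.numeric(zGrid >= zIface[i])
    rho <- rho + drho * step
  }
  new("DensityProfile", z = as.numeric(zGrid), rho = rho)
}

#' Integrated area density of a profile
#'
#' Trapezoidal integral of \eqn{\rho(z)} over [z1, z2], in
#' e\eqn{^-}\,\eqn{\AA^{-2}}. Invariant under splitting a slab into
#' equal-density sub-slabs, so it serves as a conservation check when
#' re-slabbing a model.
#'
#' @param profile a \linkS4class{DensityProfile}.
#' @param z1,z2 integration limits (\eqn{\AA}), inside the grid, z1 < z2.
#' @return integrated density, e\eqn{^-}\,\eqn{\AA^{-2}}.
#' @export
integratedDensity <- function(profile, z1, z2) {
  z <- profile@z
  if (!(z1 < z2)) stop("z1 must be < z2")
  if (z1 < min(z) || z2 > max(z)) stop("integration range outside the grid")
  rho1 <- stats::approx(z, profile@rho, xout = z1)$y
  rho2 <- stats::approx(z, profile@rho, xout = z2)$y
  inside <- z > z1 & z < z2
  zz <- c(z1, z[inside], z2)
  rr <- c(rho1, profile@rho[inside], rho2)
  sum(diff(zz) * (head(rr, -1L) + tail(rr, -1L)) / 2)
}

#' Write a density profile as two-column ASCII
#'
#' Columns are z (\eqn{\AA}) and rho (e\eqn{^-}\,\eqn{\AA^{-3}}); header
#' comment lines are prefixed with '#'.
#'
#' @param profile a \linkS4class{DensityProfile}.
#' @param path output file.
#' @param header optional extra comment lines (without the '#').
#' @return invisibly, the path.
#' @export
writeProfile <- function(profile, path, header = character(0)) {
  hdr <- header[nzchar(header)]
  writeLines(c("# electron density profile",
               "# columns: z [A]  rho [e-/A^3]",
               if (length(hdr)) paste0("# ", hdr),
               sprintf("%.6g %.8g", profile@z, profile@rho)), path)
  invisible(path)
}
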