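#' Read a reflectivity curve from ASCII columns
#'
#' Accepts whitespace- or comma-separated columns with '#' comment lines.
#' Dialects: \code{"q_R"} (q [\eqn{\AA^{-1}}], R), \code{"q_R_dR"} (plus
#' 1-sigma uncertainties), \code{"angle_R"} (incidence angle in degrees,
#' converted through the instrument wavelength), or \code{"auto"} (2
#' columns -> q_R, 3 -> q_R_dR). Non-monotonic q is sorted with a warning;
#' rows with R <= 0 are dropped with a message.
#'
#' @param path input file.
#' @param dialect column dialect (see above).
#' @param instrument \linkS4class{Instrument} for the angle dialect.
#' @return A \linkS4class{ReflectivityCurve}.
#' @export
readReflectivity <- function(path,
                             dialect = c("auto", "q_R", "q_R_dR", "angle_R"),
                             instrument = Instrument()) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(gsub(",", " ", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("fewer than 2 usable rows in ", path)
  fields <- strsplit(lines, "[ \t]+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L) stop("inconsistent column counts in ", path)
  mat <- matrix(as.numeric(unlist(fields)), ncol = ncol, byrow = TRUE)
  if (any(!is.finite(mat))) stop("non-numeric fields in ", path)
  if (dialect == "auto") dialect <- if (ncol >= 3L) "q_R_dR" else "q_R"
  q <- if (dialect == "angle_R") qzFromAngle(mat[, 1L], instrument)
       else mat[, 1L]
  R <- mat[, 2L]
  dR <- if (dialect == "q_R_dR" && ncol >= 3L) mat[, 3L] else numeric(0)
  keep <- R > 0
  if (!all(keep)) {
    message("dropped ", sum(!keep), " row(s) with R <= 0")
    q <- q[keep]; R <- R[keep]
    if (length(dR)) dR <- dR[keep]
  }
  if (length(q) < 2L) stop("fewer than 2 usable rows after filtering in ", path)
  if (any(diff(q) <= 0)) {
    warning("q not strictly increasing; rows sorted")
    o <- order(q)
    q <- q[o]; R <- R[o]
    if (length(dR)) dR <- dR[o]
    dup <- duplicated(q)
    if (any(dup)) {
      q <- q[!dup]; R <- R[!dup]
      if (length(dR)) dR <- dR[!dup]
    }
  }
  ReflectivityCurve(q, R, dR)
}

#' Write a reflectivity curve as ASCII columns
#'
#' Plain q / R / (dR) columns with ORSO-style '#' header comments recording
#' units, creation time and any extra metadata handed in.
#'
#' @param curve a \linkS4class{ReflectivityCurve}.
#' @param path output file.
#' @param header named list/character of extra header fields.
#' @return invisibly, the path.
#' @export
writeReflectivity <- function(curve, path, header = list()) {
  hdr <- c("# # reflectivity file",
           "# columns: Qz [1/angstrom] | R | sR",
           vapply(names(header), function(k)
             sprintf("# %s: %s", k, as.character(header[[k]])), character(1)))
  if (length(curve@dR))
    body <- sprintf("%.8g %.10g %.10g", curve@q, curve@R, curve@dR)
  else
    body <- sprintf("%.8g %.10g", curve@q, curve@R)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Records the parameter table (with uncertainties where estimated), the
#' media, cost, seed, cost history and evaluation count, so a fit is fully
#' reproducible and consumable by [runCompose()].
#'
#' @param result a \linkS4class{FitResult}.
#' @param path output JSON file.
#' @param extra named list merged into the report (e.g. config hash).
#' @return invisibly, the path.
#' @export
writeFitReport <- function(result, path, extra = list()) {
  st <- result@stack
  rep <- c(list(
    costType = result@costType,
    costValue = result@costValue,
    nFunctionEvals = result@nFunctionEvals,
    seed = result@seed,
    scale = result@scale,
    background = result@background,
    fronting = list(name = st@fronting@name,
                    rho = st@fronting@electronDensity),
    backing = list(name = st@backing@name,
                   rho = st@backing@electronDensity),
    backingRoughness = st@backingRoughness,
    slabs = data.frame(name = slabNames(st), d = thicknesses(st),
                       rho = densities(st),
                       sigma = head(roughnesses(st), -1L)),
    parameters = fitParameters(result),
    costHistory = result@history
  ), extra)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a fit report back into a stack
#'
#' @param path JSON file written by [writeFitReport()].
#' @return list with elements \code{stack} (\linkS4class{LayerStack}) and
#'   \code{report} (the raw parsed JSON).
#' @export
readFitReport <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  slabs <- mapply(function(d, rho, sigma) Slab(d, rho, sigma),
                  rep$slabs$d, rep$slabs$rho, rep$slabs$sigma,
                  SIMPLIFY = FALSE)
  names(slabs) <- rep$slabs$name
  stack <- suppressWarnings(LayerStack(
    Medium(rep$fronting$name, rep$fronting$rho), slabs,
    Medium(rep$backing$name, rep$backing$rho), rep$backingRoughness))
  list(stack = stack, report = rep)
}

#' Serialize a composition report to JSON
#'
#' @param report a \linkS4class{CompositionReport}.
#' @param path output JSON file.
#' @return invisibly, the path.
#' @export
writeCompositionReport <- function(report, path) {
  jsonlite::write_json(list(
    phi_w_before = report@phiWBefore,
    phi_w_after = report@phiWAfter,
    delta_hydration_pp = report@deltaHydration,
    displaced_waters_exact = report@displacedWatersExact,
    displaced_waters = report@displacedWaters,
    phi_protein = report@phiProtein,
    delta_rho = report@deltaRho
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Flat keys mirroring the package's types (preset, seed, noise settings,
#' fit settings, composition geometry, output directory); command-line
#' flags override file values.
#'
#' @param path YAML file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

## md5 of the serialized config, recorded in every written artifact
.configHash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
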