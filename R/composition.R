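#' Water volume fraction of a head-group slab
#'
#' Two-component mixing rule for a hydrated head-group layer: the measured
#' electron density is a volume-weighted average of the dry head-group
#' density and the water density,
#' \eqn{\rho_{meas} = \rho_H (1 - \varphi_w) + \rho_{water} \varphi_w},
#' inverted as
#' \eqn{\varphi_w = (\rho_H - \rho_{meas}) / (\rho_H - \rho_{water})}.
#' Measured densities outside [\eqn{\rho_{water}}, \eqn{\rho_H}] are clipped
#' to the nearest endpoint with a warning.
#'
#' @param rhoHead dry head-group electron density \eqn{\rho_H}
#'   (e\eqn{^-}\,\eqn{\AA^{-3}}).
#' @param rhoMeasured fitted slab density.
#' @param rhoWater water density (default 0.335).
#' @return water volume fraction in [0, 1].
#' @examples
#' waterFraction(0.510, 0.387)   # 0.703
#' waterFraction(0.510, 0.394)   # 0.663
#' @export
waterFraction <- function(rhoHead, rhoMeasured, rhoWater = 0.335) {
  if (any(c(rhoHead, rhoMeasured, rhoWater) < 0))
    stop("densities must be >= 0")
  if (abs(rhoHead - rhoWater) < 1e-12)
    stop("degenerate contrast: rhoHead equals rhoWater")
  phi <- (rhoHead - rhoMeasured) / (rhoHead - rhoWater)
  if (any(phi < 0) || any(phi > 1)) {
    warning("measured density outside [rhoWater, rhoHead]; fraction clipped")
    phi <- pmin(pmax(phi, 0), 1)
  }
  phi
}

#' Protein volume fraction of an adsorbed layer
#'
#' Mixing rule for a protein layer in water:
#' \eqn{\rho_{meas} = \rho_{prot}\varphi + \rho_{water}(1 - \varphi)},
#' inverted as
#' \eqn{\varphi = (\rho_{meas} - \rho_{water}) / (\rho_{prot} - \rho_{water})}.
#'
#' @param rhoMeasured fitted layer density (e\eqn{^-}\,\eqn{\AA^{-3}}).
#' @param rhoProtein anhydrous protein density (e.g. from
#'   [proteinElectronDensityFromSequence()]).
#' @param rhoWater water density (default 0.335).
#' @return protein volume fraction in [0, 1].
#' @examples
#' proteinFraction(0.372, 0.444)   # ~0.339
#' @export
proteinFraction <- function(rhoMeasured, rhoProtein, rhoWater = 0.335) {
  if (any(c(rhoMeasured, rhoProtein, rhoWater) < 0))
    stop("densities must be >= 0")
  if (abs(rhoProtein - rhoWater) < 1e-12)
    stop("degenerate contrast: rhoProtein equals rhoWater")
  phi <- (rhoMeasured - rhoWater) / (rhoProtein - rhoWater)
  if (any(phi < 0) || any(phi > 1)) {
    warning("measured density outside [rhoWater, rhoProtein]; fraction clipped")
    phi <- pmin(pmax(phi, 0), 1)
  }
  phi
}

#' Displaced water molecules per lipid
#'
#' Converts a hydration change of the head-group layer into water molecules
#' displaced per lipid:
#' \eqn{N = \Delta\varphi_w \cdot A\,t / V_w} with area per lipid A,
#' head-group thickness t and water volume \eqn{V_w}. Reported both exact
#' and rounded to the nearest integer.
#'
#' @param deltaPhiW hydration decrease, as a fraction in [0, 1].
#' @param geometry a \linkS4class{LipidGeometry}.
#' @return list with elements \code{exact} and \code{rounded}.
#' @examples
#' displacedWaters(0.04)$rounded    # 1
#' displacedWaters(0.296)$rounded   # 8
#' @export
displacedWaters <- function(deltaPhiW, geometry = lipidGeometry()) {
  if (any(deltaPhiW < 0) || any(deltaPhiW > 1))
    stop("deltaPhiW must be in [0, 1]")
  headVolume <- geometry@areaPerLipid * geometry@headgroupThickness
  exact <- deltaPhiW * headVolume / geometry@waterVolume
  list(exact = exact, rounded = as.integer(round(exact)))
}

#' Sphere diameter from volume
#'
#' \eqn{d = (6V/\pi)^{1/3}}, converted from \eqn{\AA} to nm — the size of a
#' compact globular protein of the given molecular volume.
#'
#' @param volume molecular volume in \eqn{\AA^3} (> 0).
#' @return diameter in nm.
#' @examples
#' sphereDiameter(84391)   # ~5.4 nm
#' @export
sphereDiameter <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be finite and > 0")
  (6 * volume / pi)^(1 / 3) / 10
}

#' Minimal anhydrous globular radius from mass
#'
#' \eqn{R_{min} = 0.066\,M^{1/3}} nm with M in Da — the radius of the
#' smallest sphere that can hold a protein of the given mass, from the
#' standard protein partial specific volume of ~0.73 cm\eqn{^3}/g.
#'
#' @param mass molecular mass in Da (> 0).
#' @return radius in nm.
#' @examples
#' rminFromMass(70000)   # ~2.7 nm for a 70 kDa globule
#' @export
rminFromMass <- function(mass) {
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("mass must be finite and > 0")
  0.066 * mass^(1 / 3)
}

## residue property table (volumes + elemental composition), cached
.residueTableEnv <- new.env(parent = emptyenv())

#' Amino-acid residue property table
#'
#' Per-residue mean volumes (\eqn{\AA^3}; Zamyatnin 1972 consensus values)
#' and residue elemental compositions (the amino acid minus one water), from
#' which electron counts follow as 6C + 1H + 7N + 8O + 16S. Bundled as
#' plain CSV under \code{extdata}.
#'
#' @return data.frame with one row per standard residue: columns
#'   \code{residue}, \code{volume}, \code{C}, \code{H}, \code{N}, \code{O},
#'   \code{S}, \code{electrons}.
#' @export
residueProperties <- function() {
  if (!is.null(.residueTableEnv$tab)) return(.residueTableEnv$tab)
  path <- system.file("extdata", "residue_properties.csv", package = "xrrfit",
                      mustWork = TRUE)
  tab <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                    stringsAsFactors = FALSE)
  tab$electrons <- 6 * tab$C + tab$H + 7 * tab$N + 8 * tab$O + 16 * tab$S
  .residueTableEnv$tab <- tab
  tab
}

.residueCounts <- function(sequence) {
  sequence <- toupper(gsub("[ \t\n*]", "", as.character(sequence)))
  if (!nchar(sequence)) return(integer(0))
  aa <- strsplit(sequence, "")[[1L]]
  tab <- residueProperties()
  bad <- setdiff(unique(aa), tab$residue)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  table(factor(aa, levels = tab$residue))
}

#' Protein volume from an amino-acid sequence
#'
#' Sum of mean residue volumes over the sequence. Additive under
#' concatenation; an empty sequence gives 0 with a warning.
#'
#' @param sequence amino-acid string (one-letter codes over the 20 standard
#'   residues), or an \code{AAString}/\code{AAStringSet} of length 1.
#' @param volumeTable optional named vector of residue volumes
#'   (\eqn{\AA^3}); defaults to the bundled table.
#' @return volume in \eqn{\AA^3}.
#' @examples
#' proteinVolumeFromSequence("GG")   # 2 x volume of glycine
#' @export
proteinVolumeFromSequence <- function(sequence, volumeTable = NULL) {
  sequence <- .asSequenceString(sequence)
  counts <- .residueCounts(sequence)
  if (!length(counts) || sum(counts) == 0L) {
    warning("empty sequence; volume is 0")
    return(0)
  }
  tab <- residueProperties()
  vol <- if (is.null(volumeTable)) setNames(tab$volume, tab$residue)
         else volumeTable
  sum(counts * vol[names(counts)])
}

#' Anhydrous protein electron density from a sequence
#'
#' Total electrons of the polypeptide (residue electrons summed over the
#' chain, plus one terminal water — equivalently the free amino acids minus
#' one water per peptide bond) divided by the summed residue volume.
#' Independent of residue order.
#'
#' @inheritParams proteinVolumeFromSequence
#' @param includeTerminalWater add the 10 electrons of the terminal H2O
#'   (default TRUE).
#' @return electron density in e\eqn{^-}\,\eqn{\AA^{-3}}.
#' @examples
#' proteinElectronDensityFromSequence("GGGG")
#' @export
proteinElectronDensityFromSequence <- function(sequence, volumeTable = NULL,
                                               includeTerminalWater = TRUE) {
  sequence <- .asSequenceString(sequence)
  counts <- .residueCounts(sequence)
  if (!length(counts) || sum(counts) == 0L)
    stop("cannot compute a density for an empty sequence")
  tab <- residueProperties()
  vol <- if (is.null(volumeTable)) setNames(tab$volume, tab$residue)
         else volumeTable
  el <- setNames(tab$electrons, tab$residue)
  electrons <- sum(counts * el[names(counts)]) +
    if (includeTerminalWater) 10 else 0
  electrons / sum(counts * vol[names(counts)])
}

.asSequenceString <- function(sequence) {
  if (is(sequence, "XStringSet")) {
    if (length(sequence) != 1L)
      stop("provide a single sequence")
    sequence <- sequence[[1L]]
  }
  as.character(sequence)
}

#' Read the bundled Hsp70 (HSPA1A) sequence
#'
#' The 641-residue human inducible Hsp70 (HSPA1A) sequence shipped with the
#' package, read with Biostrings.
#'
#' @return an \code{AAStringSet} of length 1.
#' @export
hsp70Sequence <- function() {
  path <- system.file("extdata", "HSPA1A_human.fasta", package = "xrrfit",
                      mustWork = TRUE)
  Biostrings::readAAStringSet(path)
}

#' Build a membrane composition report
#'
#' Combines the mixing rules into one report: outer head-group hydration
#' before and after protein incubation, the hydration change, displaced
#' waters per lipid, and (when a protein-layer density is supplied) the
#' protein volume fraction. For systems where the pre-incubation hydration
#' is known but the underlying density is not, pass \code{phiWBefore}
#' directly instead of \code{rhoMeasuredBefore}.
#'
#' @param rhoHead dry head-group density (e\eqn{^-}\,\eqn{\AA^{-3}}).
#' @param rhoMeasuredBefore,rhoMeasuredAfter fitted outer head-group
#'   densities before/after incubation (either before-value may be replaced
#'   by \code{phiWBefore}).
#' @param phiWBefore pre-incubation hydration fraction, if known directly.
#' @param rhoWater water density.
#' @param geometry a \linkS4class{LipidGeometry}.
#' @param rhoProteinLayer fitted density of the adsorbed protein layer
#'   (optional).
#' @param rhoProtein anhydrous protein density (required with
#'   \code{rhoProteinLayer}).
#' @return A \linkS4class{CompositionReport}.
#' @examples
#' compositionReport(rhoHead = 0.510, rhoMeasuredBefore = 0.387,
#'                   rhoMeasuredAfter = 0.394)
#' @export
compositionReport <- function(rhoHead, rhoMeasuredBefore = NULL,
                              rhoMeasuredAfter, phiWBefore = NULL,
                              rhoWater = 0.335, geometry = lipidGeometry(),
                              rhoProteinLayer = NA_real_,
                              rhoProtein = NA_real_) {
  if (is.null(phiWBefore)) {
    if (is.null(rhoMeasuredBefore))
      stop("supply either rhoMeasuredBefore or phiWBefore")
    phiWBefore <- waterFraction(rhoHead, rhoMeasuredBefore, rhoWater)
  }
  phiWAfter <- waterFraction(rhoHead, rhoMeasuredAfter, rhoWater)
  dphi <- phiWBefore - phiWAfter
  dw <- displacedWaters(max(dphi, 0), geometry)
  phiP <- if (is.na(rhoProteinLayer)) NA_real_
          else proteinFraction(rhoProteinLayer, rhoProtein, rhoWater)
  dRho <- if (is.null(rhoMeasuredBefore)) NA_real_
          else rhoMeasuredAfter - rhoMeasuredBefore
  new("CompositionReport", phiWBefore = phiWBefore, phiWAfter = phiWAfter,
      deltaHydration = 100 * dphi, displacedWatersExact = dw$exact,
      displacedWaters = dw$rounded, phiProtein = phiP, deltaRho = dRho)
}
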