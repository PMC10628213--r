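test_that("head-group hydration follows the mixing rule", {
  expect_equal(waterFraction(0.510, 0.387, 0.335), 0.703, tolerance = 1e-3)
  expect_equal(waterFraction(0.510, 0.394, 0.335), 0.663, tolerance = 1e-3)
  ## endpoints
  expect_equal(waterFraction(0.510, 0.510), 0)
  expect_equal(waterFraction(0.510, 0.335), 1)
  ## strictly decreasing in the measured density
  rho <- seq(0.34, 0.50, by = 0.01)
  expect_true(all(diff(waterFraction(0.510, rho)) < 0))
  expect_error(waterFraction(0.335, 0.335), "degenerate")
  expect_warning(waterFraction(0.510, 0.6), "clipped")
})

test_that("protein fraction inverts its mixing rule exactly", {
  expect_equal(proteinFraction(0.372, 0.444, 0.335), 0.037 / 0.109)
  expect_equal(proteinFraction(0.335, 0.444), 0)
  ## round trip phi -> rho -> phi
  for (phi in c(0, 0.17, 0.343, 0.9, 1)) {
    rho <- 0.444 * phi + 0.335 * (1 - phi)
    expect_equal(proteinFraction(rho, 0.444, 0.335), phi, tolerance = 1e-12)
  }
  ## water_fraction round trip as well
  for (phiw in c(0.05, 0.5, 0.95)) {
    rho <- 0.510 * (1 - phiw) + 0.335 * phiw
    expect_equal(waterFraction(0.510, rho, 0.335), phiw, tolerance = 1e-12)
  }
})

test_that("hydration changes convert to displaced waters per lipid", {
  dw <- displacedWaters(0.04)
  expect_equal(dw$exact, 0.04 * 70 * 11.5 / 29)
  expect_equal(dw$rounded, 1L)
  dw8 <- displacedWaters(0.296)
  expect_equal(dw8$exact, 8.2, tolerance = 0.01)
  expect_equal(dw8$rounded, 8L)
  expect_equal(displacedWaters(0)$exact, 0)
  ## linear in both the hydration change and the head-group volume
  expect_equal(displacedWaters(0.2)$exact, 2 * displacedWaters(0.1)$exact)
  g2 <- lipidGeometry(headgroupThickness = 23)
  expect_equal(displacedWaters(0.1, g2)$exact,
               2 * displacedWaters(0.1)$exact)
  expect_error(displacedWaters(1.5), "deltaPhiW")
  expect_error(lipidGeometry(areaPerLipid = -1), "> 0")
})

test_that("protein size estimates follow the closed forms", {
  expect_equal(sphereDiameter(84391), 5.4, tolerance = 0.01)
  ## inverse identity: unit sphere of volume pi/6 has diameter 1 A = 0.1 nm
  expect_equal(sphereDiameter(pi / 6), 0.1)
  expect_equal(sphereDiameter(2 * 84391) / sphereDiameter(84391), 2^(1 / 3))
  expect_equal(rminFromMass(70000), 2.7, tolerance = 0.02)
  expect_equal(rminFromMass(1000), 0.66)
  expect_equal(rminFromMass(8000) / rminFromMass(1000), 2)
  expect_error(sphereDiameter(-1), "volume")
  expect_error(rminFromMass(0), "mass")
})

test_that("sequence volume is additive and rejects unknown residues", {
  tab <- residueProperties()
  vG <- tab$volume[tab$residue == "G"]
  expect_equal(proteinVolumeFromSequence("GG"), 2 * vG)
  expect_equal(proteinVolumeFromSequence("GAVL"),
               proteinVolumeFromSequence("GA") +
                 proteinVolumeFromSequence("VL"))
  expect_warning(v0 <- proteinVolumeFromSequence(""), "empty")
  expect_equal(v0, 0)
  expect_error(proteinVolumeFromSequence("GAX"), "X")
})

test_that("the bundled Hsp70 sequence gives the published volume and size", {
  seq <- hsp70Sequence()
  expect_equal(length(seq), 1L)
  expect_equal(Biostrings::width(seq), 641L)
  vol <- proteinVolumeFromSequence(seq)
  expect_equal(vol, 84391, tolerance = 0.02)
  expect_equal(sphereDiameter(vol), 5.4, tolerance = 0.02)
})

test_that("sequence electron density matches the published protein value", {
  rho <- proteinElectronDensityFromSequence(hsp70Sequence())
  expect_equal(rho, 0.444, tolerance = 0.02)
  ## single-species chain: electrons/volume of that residue (+ terminal water)
  tab <- residueProperties()
  g <- tab[tab$residue == "G", ]
  n <- 50
  expect_equal(
    proteinElectronDensityFromSequence(strrep("G", n),
                                       includeTerminalWater = FALSE),
    g$electrons / g$volume)
  ## permutation invariance
  expect_equal(proteinElectronDensityFromSequence("ACDEFGHIKLMNPQRSTVWY"),
               proteinElectronDensityFromSequence("YWVTSRQPNMLKIHGFEDCA"))
})

test_that("composition reports assemble the published worked example", {
  rep <- compositionReport(rhoHead = 0.510, rhoMeasuredBefore = 0.387,
                           rhoMeasuredAfter = 0.394)
  expect_equal(rep@phiWBefore, 0.703, tolerance = 1e-3)
  expect_equal(rep@phiWAfter, 0.663, tolerance = 1e-3)
  expect_equal(rep@deltaHydration, 4.0, tolerance = 0.02)
  expect_equal(rep@displacedWaters, 1L)
  expect_equal(rep@deltaRho, 0.007)
  ## DOPC/DOPS case: pre-incubation hydration supplied directly
  rep2 <- compositionReport(rhoHead = 0.504, phiWBefore = 0.615,
                            rhoMeasuredAfter = 0.450,
                            rhoProteinLayer = 0.372, rhoProtein = 0.444)
  expect_equal(rep2@phiWAfter, 0.3195, tolerance = 1e-3)
  expect_equal(rep2@displacedWaters, 8L)
  expect_equal(rep2@phiProtein, 0.339, tolerance = 2e-3)
})
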