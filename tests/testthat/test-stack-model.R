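test_that("angle-to-q conversion follows 4*pi*sin(alpha)/lambda", {
  inst <- Instrument()
  expect_equal(qzFromAngle(0, inst), 0)
  expect_equal(qzFromAngle(0.1, inst), 4 * pi * sin(0.1 * pi / 180) / 0.56)
  expect_equal(qzFromAngle(0.1, inst), 0.03917, tolerance = 2e-4)
  ## small-angle linearity
  expect_equal(qzFromAngle(0.2, inst) / qzFromAngle(0.1, inst), 2,
               tolerance = 1e-3)
  ## strictly increasing in alpha
  a <- seq(0.01, 5, length.out = 50)
  expect_true(all(diff(qzFromAngle(a, inst)) > 0))
  expect_error(qzFromAngle(-1), "alphaDeg")
})

test_that("electron density converts linearly to SLD", {
  expect_equal(electronDensityToSld(0), 0)
  expect_equal(electronDensityToSld(0.335), 9.44e-6, tolerance = 1e-3)
  expect_equal(electronDensityToSld(0.692), 1.950e-5, tolerance = 1e-3)
  expect_equal(electronDensityToSld(2 * 0.335), 2 * electronDensityToSld(0.335))
  expect_error(electronDensityToSld(-0.1), "rho")
})

test_that("critical q matches the closed form and vanishes without contrast", {
  expect_equal(criticalQ(mediumAir(), mediumSilicon()), 0.0313,
               tolerance = 2e-3)
  expect_equal(criticalQ(mediumBuffer(), mediumSilicon()), 0.0225,
               tolerance = 2e-3)
  expect_equal(criticalQ(mediumBuffer(), mediumBuffer()), 0)
  ## inverted contrast has no total-reflection edge
  expect_equal(criticalQ(mediumSilicon(), mediumAir()), 0)
})

test_that("bare sharp interface reproduces the Fresnel closed form", {
  st <- bareInterface()
  qc <- criticalQ(mediumAir(), mediumSilicon())
  expect_equal(reflectivityAbeles(st, 2 * qc), 5.16e-3, tolerance = 2e-3)
  q <- seq(1.05 * qc, 30 * qc, length.out = 200)
  expect_equal(reflectivityAbeles(st, q), fresnelSharp(q, qc),
               tolerance = 1e-10)
  expect_equal(reflectivityParratt(st, q), fresnelSharp(q, qc),
               tolerance = 1e-12)
  ## total reflection below the edge
  expect_equal(reflectivityAbeles(st, qc * c(0.3, 0.6, 0.9)), rep(1, 3),
               tolerance = 1e-9)
})

test_that("Abeles and Parratt agree on random stacks", {
  set.seed(42)
  q <- defaultQGrid(120)
  for (i in 1:100) {
    st <- randomStack()
    Ra <- reflectivityAbeles(st, q)
    Rp <- reflectivityParratt(st, q)
    expect_lt(max(abs(Ra - Rp) / pmax(Rp, 1e-300)), 1e-8)
  }
})

test_that("reflectivity is bounded and deterministic", {
  set.seed(7)
  q <- defaultQGrid(100)
  for (i in 1:20) {
    st <- randomStack()
    R <- reflectivityAbeles(st, q)
    expect_true(all(R >= 0 & R <= 1 + 1e-9))
    expect_identical(R, reflectivityAbeles(st, q))
  }
})

test_that("zero-thickness and zero-contrast slabs are no-ops", {
  q <- defaultQGrid(80)
  st <- presetStack(makePreset("dopc_monolayer_air"))
  ## a vanishing slab inserted mid-stack is invisible between sharp
  ## interfaces (with roughness it would split one damped interface in two)
  base <- reflectivityAbeles(st, q, roughnessModel = "none")
  slabs <- append(st@slabs, list(Slab(1e-9, 0.5, 0)), after = 1L)
  stz <- suppressWarnings(LayerStack(st@fronting, slabs, st@backing,
                                     st@backingRoughness))
  expect_equal(reflectivityAbeles(stz, q, roughnessModel = "none"), base,
               tolerance = 1e-10)
  expect_equal(reflectivityParratt(stz, q, roughnessModel = "none"), base,
               tolerance = 1e-10)
  ## with roughness on, a vanishing slab at the density of its neighbour is
  ## a no-op (its own interface carries no contrast)
  baseNC <- reflectivityAbeles(st, q)
  rhoChains <- densities(st)[["chains"]]
  slabs2 <- append(st@slabs, list(Slab(1e-9, rhoChains, 0)), after = 1L)
  stz2 <- suppressWarnings(LayerStack(st@fronting, slabs2, st@backing,
                                      st@backingRoughness))
  expect_equal(reflectivityAbeles(stz2, q), baseNC, tolerance = 1e-10)
  expect_equal(reflectivityParratt(stz2, q), baseNC, tolerance = 1e-10)
  ## slabs with the density of both media leave the bare interface unchanged
  rho_si <- 0.692
  uni <- LayerStack(mediumSilicon(), list(Slab(20, rho_si, 0),
                                          Slab(35, rho_si, 0)),
                    mediumSilicon(), 0)
  expect_equal(reflectivityAbeles(uni, q), numeric(length(q)),
               tolerance = 1e-12)
})

test_that("splitting a slab at equal density leaves R unchanged", {
  q <- defaultQGrid(80)
  whole <- LayerStack(mediumAir(), list(Slab(30, 0.4, 2)), mediumSilicon(), 3)
  split <- LayerStack(mediumAir(), list(Slab(12, 0.4, 2), Slab(18, 0.4, 0)),
                      mediumSilicon(), 3)
  expect_equal(reflectivityParratt(split, q), reflectivityParratt(whole, q),
               tolerance = 1e-10)
  expect_equal(reflectivityAbeles(split, q), reflectivityAbeles(whole, q),
               tolerance = 1e-10)
})

test_that("R*q^4 approaches 16*pi^2*dSLD^2 far above the edge", {
  st <- bareInterface()
  qc <- criticalQ(mediumAir(), mediumSilicon())
  lim <- 16 * pi^2 * electronDensityToSld(0.692)^2
  expect_equal(reflectivityAbeles(st, 20 * qc) * (20 * qc)^4, lim,
               tolerance = 0.01)
})

test_that("Nevot-Croce roughness damps a single interface monotonically", {
  qc <- criticalQ(mediumAir(), mediumSilicon())
  q <- seq(2.1 * qc, 0.6, length.out = 60)
  sig <- seq(0, 8, by = 0.5)
  R <- sapply(sig, function(s)
    reflectivityAbeles(bareInterface(sigma = s), q))
  ## at every fixed q, R never increases with sigma
  expect_true(all(apply(R, 1L, function(row) all(diff(row) <= 1e-15))))
})

test_that("invalid stacks and grids are rejected", {
  st <- bareInterface()
  expect_error(reflectivityAbeles(st, c(-0.1, 0.2)), "q must be")
  expect_error(Slab(-1, 0.3, 0), "thickness")
  expect_error(Slab(10, -0.3, 0), "electronDensity")
  expect_error(Medium("x", -1), "electronDensity")
  expect_warning(
    LayerStack(mediumAir(), list(Slab(3, 0.3, 30)), mediumSilicon(), 0),
    "roughness exceeds")
})

test_that("resolution smearing reduces fringe contrast but preserves scale", {
  st <- presetStack(makePreset("dopc_monolayer_air"))
  q <- defaultQGrid(100)
  sharp <- reflectivityAbeles(st, q)
  smeared <- reflectivitySmeared(st, q, dqByQ = 0.05)
  expect_equal(reflectivitySmeared(st, q, dqByQ = 0), sharp)
  expect_equal(log10(smeared), log10(sharp), tolerance = 0.5)
  expect_false(isTRUE(all.equal(smeared, sharp)))
})

test_that("instrument validity couples wavelength and energy", {
  expect_silent(Instrument(0.56, 22))
  expect_error(Instrument(0.7, 22), "inconsistent")
  expect_error(Instrument(-1, numeric(0)), "wavelength")
})
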