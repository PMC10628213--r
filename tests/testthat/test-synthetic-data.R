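test_that("presets carry the published slab parameters", {
  st1 <- presetStack(makePreset("dopc_monolayer_air"))
  expect_equal(thicknesses(st1)[["chains"]], 11.7)
  expect_equal(densities(st1)[["chains"]], 0.318)
  expect_equal(roughnesses(st1)[["chains"]], 3.0)
  expect_equal(densities(st1)[["heads"]], 0.510)
  expect_equal(st1@fronting@electronDensity, 0)

  st2 <- presetStack(makePreset("dopcdops_monolayer_air"))
  expect_equal(thicknesses(st2)[["heads"]], 8.0)
  expect_equal(densities(st2)[["heads"]], 0.504)

  st4 <- presetStack(makePreset("dopcdops_hsp70_bilayer"))
  expect_equal(nSlabs(st4), 5L)   # protein + 3 lipid slabs + oxide
  expect_equal(thicknesses(st4)[["protein"]], 22.6)
  expect_equal(densities(st4)[["protein"]], 0.372)
  expect_equal(roughnesses(st4)[["protein"]], 11.9)
  expect_equal(st4@fronting@electronDensity, 0.335)
  expect_equal(st4@backing@electronDensity, 0.692)
  expect_equal(densities(st4)[["sio2"]], 0.660)

  ## every preset validates
  for (nm in presetNames())
    expect_s4_class(presetStack(makePreset(nm)), "LayerStack")
  expect_error(makePreset("no_such_membrane"), "unknown preset")
})

test_that("noiseless simulation reproduces the forward model exactly", {
  st <- presetStack(makePreset("dopc_monolayer_air"))
  q <- defaultQGrid(60)
  cu <- simulateCurve(st, q)
  expect_equal(reflectivity(cu), reflectivityAbeles(st, q))
  cu0 <- simulateCurve(st, q, noiseModel(relativeSigma = 0, seed = 1))
  expect_equal(reflectivity(cu0), reflectivityAbeles(st, q))
})

test_that("simulated curves are seeded and unbiased", {
  st <- presetStack(makePreset("dopc_monolayer_air"))
  q <- c(0.05, 0.1, 0.2, 0.4)
  R <- reflectivityAbeles(st, q)
  a <- simulateCurve(st, q, noiseModel(relativeSigma = 0.02, seed = 44))
  b <- simulateCurve(st, q, noiseModel(relativeSigma = 0.02, seed = 44))
  expect_identical(reflectivity(a), reflectivity(b))
  ## 500 seeded replicates: mean within 3 standard errors of the model
  reps <- sapply(1:500, function(s)
    reflectivity(simulateCurve(st, q,
                               noiseModel(relativeSigma = 0.02, seed = s))))
  se <- apply(reps, 1L, sd) / sqrt(ncol(reps))
  expect_true(all(abs(rowMeans(reps) - R) < 3 * se + 1e-12))
})

test_that("poisson mode has counting-statistics variance", {
  st <- presetStack(makePreset("dopc_monolayer_air"))
  q <- c(0.05, 0.1, 0.2)
  R <- reflectivityAbeles(st, q)
  I0 <- 1e7
  reps <- sapply(1:400, function(s)
    reflectivity(simulateCurve(st, q, noiseModel("poisson_counts",
                                                 incidentCounts = I0,
                                                 seed = s))))
  varCounts <- apply(reps * I0, 1L, var)
  expect_equal(varCounts, R * I0, tolerance = 0.2)
  ## dR reflects the counting error
  cu <- simulateCurve(st, q, noiseModel("poisson_counts",
                                        incidentCounts = I0, seed = 2))
  expect_equal(uncertainties(cu), sqrt(reflectivity(cu) * I0) / I0,
               tolerance = 0.2)
})

test_that("curves show a total-reflection plateau and multi-decade decay", {
  ## zero-roughness variant of the DOPC monolayer
  st <- presetStack(makePreset("dopc_monolayer_air"))
  slabs <- lapply(st@slabs, function(s) Slab(s@thickness, s@electronDensity, 0))
  st0 <- LayerStack(st@fronting, slabs, st@backing, 0)
  qc <- criticalQ(st0@fronting, st0@backing)
  qlow <- seq(0.005, 0.95 * qc, length.out = 20)
  expect_true(all(abs(reflectivityAbeles(st0, qlow) - 1) < 0.02))
  ## >= 4 decades down by q = 0.5 (roughness included)
  R <- reflectivityAbeles(st, c(0.5))
  expect_lt(R, 1e-4)
  expect_error(simulateCurve(st, c(-0.1, 0.2)), "q grid")
})
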