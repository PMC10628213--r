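quickCurve <- function(stack, seed = 1, noise = 0.02, n = 80) {
  simulateCurve(stack, q = defaultQGrid(n),
                noise = if (noise > 0)
                  noiseModel(relativeSigma = noise, seed = seed))
}

test_that("the cost functional behaves as specified", {
  st <- presetStack(makePreset("dopc_monolayer_air"))
  q <- defaultQGrid(50)
  R <- reflectivityAbeles(st, q)
  cu <- ReflectivityCurve(q, R, dR = 0.02 * R)
  expect_equal(fitCost(cu, R), 0)
  ## a constant factor of 10 in log10 space costs exactly 1
  expect_equal(fitCost(cu, 10 * R), 1)
  ## chi2 scales quadratically with the residuals
  c1 <- fitCost(cu, R * 1.01, cost = "chi2_weighted")
  c2 <- fitCost(cu, R * 1.02, cost = "chi2_weighted")
  expect_equal(c2 / c1, 4, tolerance = 1e-6)
  ## masked non-positive data
  cu0 <- ReflectivityCurve(q, c(0, R[-1]))
  expect_warning(v <- fitCost(cu0, R), "masked")
  expect_equal(v, 0)
  expect_error(fitCost(cu, R[-1]), "length")
  expect_error(fitCost(ReflectivityCurve(q, R), R, cost = "chi2_weighted"),
               "requires dR")
})

test_that("a single free parameter matches a brute-force grid search", {
  st <- presetStack(makePreset("dopc_monolayer_air"))
  cu <- quickCurve(st, seed = 21)
  pars <- defaultParameters(st)
  pars$fixed <- TRUE
  pars <- setParameter(pars, "chains.d", fixed = FALSE,
                       lower = 9, upper = 14, value = 11)
  fit <- fitStack(cu, st, pars, fitConfig(seed = 2, maxGenerations = 150,
                                          polish = FALSE))
  ## independent oracle: dense 1-D grid over the same objective
  grid <- seq(9, 14, by = 0.001)
  gcost <- vapply(grid, function(d) {
    s2 <- st
    s2@slabs$chains@thickness <- d
    fitCost(cu, reflectivityAbeles(s2, qValues(cu)))
  }, numeric(1))
  dstar <- grid[which.min(gcost)]
  dfit <- fit@parameters$value[fit@parameters$name == "chains.d"]
  expect_equal(dfit, dstar, tolerance = 0.002 / dstar)
  expect_lte(costValue(fit), min(gcost) + 1e-10)
})

test_that("fits are bit-reproducible for a fixed seed and config", {
  st <- presetStack(makePreset("dopc_monolayer_air"))
  cu <- quickCurve(st, seed = 5)
  ## start away from the generating values so the search has work to do
  pars <- presetFitParameters(st)
  pars <- setParameter(pars, "chains.d", value = 10.5)
  pars <- setParameter(pars, "heads.rho", value = 0.45)
  cfg <- fitConfig(seed = 9, maxGenerations = 40, polish = FALSE)
  f1 <- fitStack(cu, st, pars, cfg)
  f2 <- fitStack(cu, st, pars, cfg)
  expect_identical(f1@parameters$value, f2@parameters$value)
  expect_identical(costValue(f1), costValue(f2))
  expect_identical(costHistory(f1), costHistory(f2))
  ## a different seed explores differently
  f3 <- fitStack(cu, st, pars, fitConfig(seed = 10, maxGenerations = 40,
                                         polish = FALSE))
  expect_false(identical(costHistory(f1), costHistory(f3)))
})

test_that("bounds and fixed parameters are honoured", {
  st <- presetStack(makePreset("dopc_monolayer_air"))
  cu <- quickCurve(st, seed = 6)
  pars <- presetFitParameters(st)
  fit <- fitStack(cu, st, pars, fitConfig(seed = 1, maxGenerations = 30))
  p <- fit@parameters
  expect_true(all(p$value >= p$lower - 1e-12 & p$value <= p$upper + 1e-12))
  ## the oxide density stayed at its fixed published value
  expect_equal(p$value[p$name == "sio2.rho"], 0.660)
  expect_equal(densities(fittedStack(fit))[["sio2"]], 0.660)
  ## oxide thickness bounded to the published window
  expect_true(p$lower[p$name == "sio2.d"] == 12 &&
                p$upper[p$name == "sio2.d"] == 25)
  ## best-so-far cost trace is monotone non-increasing
  expect_true(all(diff(costHistory(fit)) <= 1e-15))
  ## no free parameters is a configuration error
  pars$fixed <- TRUE
  expect_error(fitStack(cu, st, pars), "free parameter")
})

test_that("the initial guess bounds the achieved cost from above", {
  st <- presetStack(makePreset("dopc_monolayer_air"))
  cu <- quickCurve(st, seed = 13)
  pars <- presetFitParameters(st)
  initCost <- fitCost(cu, reflectivityAbeles(st, qValues(cu)))
  fit <- fitStack(cu, st, pars, fitConfig(seed = 4, maxGenerations = 20))
  expect_lte(costValue(fit), initCost)
})

test_that("the degenerate one-slab scenario converges with its template", {
  st <- presetStack(makePreset("disrupted_one_slab"))
  cu <- quickCurve(st, seed = 31)
  pars <- presetFitParameters(st)
  fit <- fitStack(cu, st, pars, fitConfig(seed = 31, maxGenerations = 150))
  ## cost at the noise floor: log10(1 + 2%) ~ 0.0086, squared ~ 7e-5
  expect_lt(costValue(fit), 3e-4)
  expect_equal(thicknesses(fittedStack(fit))[["layer"]], 40, tolerance = 0.1)
})

test_that("bootstrap uncertainties scale with the noise level", {
  st <- presetStack(makePreset("dopc_monolayer_air"))
  pars <- defaultParameters(st)
  pars$fixed <- TRUE
  pars <- setParameter(pars, "chains.d", fixed = FALSE, lower = 10, upper = 13)
  pars <- setParameter(pars, "heads.rho", fixed = FALSE,
                       lower = 0.45, upper = 0.57)
  sig <- sapply(c(0.01, 0.02), function(nz) {
    cu <- quickCurve(st, seed = 8, noise = nz)
    fit <- fitStack(cu, st, pars, fitConfig(seed = 8, maxGenerations = 80))
    parameterUncertainty(fit, cu, nBoot = 40, seed = 99)
  })
  ## fixed parameters report exactly zero
  expect_true(all(sig[rownames(sig) %in% c("sio2.rho", "scale"), ] == 0))
  expect_true(all(sig[c("chains.d", "heads.rho"), ] > 0))
  ## doubling the noise roughly doubles the spread (within 50%)
  ratio <- sig["chains.d", 2] / sig["chains.d", 1]
  expect_gt(ratio, 1.0)
  expect_lt(ratio, 3.0)
  ## noiseless data give (near) zero uncertainty
  cu0 <- quickCurve(st, noise = 0)
  fit0 <- fitStack(cu0, st, pars, fitConfig(seed = 8, maxGenerations = 80))
  sig0 <- parameterUncertainty(fit0, cu0, nBoot = 12, seed = 1)
  expect_lt(sig0["chains.d"], 1e-3)
  expect_error(parameterUncertainty(fit0, cu0, nBoot = 5), "nBoot")
})

test_that("model comparison prefers parsimony unless cost improves enough", {
  st <- presetStack(makePreset("dopc_monolayer_air"))
  cu <- quickCurve(st, seed = 17)
  pars <- presetFitParameters(st)
  f3 <- fitStack(cu, st, pars, fitConfig(seed = 1, maxGenerations = 30))
  ## fabricate a 4-slab result with identical cost: the tie goes to 3 slabs
  st4 <- suppressWarnings(LayerStack(
    st@fronting, append(st@slabs, list(extra = Slab(10, 0.3, 2)), after = 0L),
    st@backing, st@backingRoughness))
  f4 <- f3
  f4@stack <- st4
  sel <- compareModels(cu, list(f4, f3))
  expect_equal(nSlabs(fittedStack(sel$selected)), 3L)
  expect_true(sel$report$accepted[sel$report$nSlabs == 3])
  ## mismatched data are rejected
  cu2 <- quickCurve(st, seed = 18)
  expect_error(compareModels(cu2, list(f3, f4)), "same data")
})
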