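cfgFast <- generatorConfig(runsPerModel = 1, samples = 1000, masterSeed = 1)

test_that("initial-condition randomization follows the uniform scaling rule", {
  set.seed(5)
  expect_equal(randomizeIC(c(0, 0)), c(0, 0))
  x0 <- c(10, 200, 10)
  for (i in 1:50) {
    r <- randomizeIC(x0)
    expect_true(all(abs(r) <= abs(x0)))
  }
  ## the scaling factors are uniform on (-1, 1)
  set.seed(99)
  draws <- replicate(10000, randomizeIC(10)[1] / 10)
  ks <- stats::ks.test(draws, "punif", -1, 1)
  expect_gt(ks$p.value, 0.01)
  expect_lt(max(abs(draws)), 1)
})

test_that("the integrator's baked-in derivatives agree with modelRHS", {
  reg <- modelRegistry()
  set.seed(21)
  for (m in reg) {
    if (m@form != "ode") next
    f <- chaosbench:::.desolveRHS(m)
    for (k in 1:5) {
      x <- rnorm(m@dim, sd = 3)
      t <- runif(1, 0, m@tMax)
      expect_equal(f(t, x, NULL)[[1]], modelRHS(m, t, x), info = m@symbol)
    }
  }
})

test_that("harmonic oscillator trajectory matches its closed form", {
  tr <- integrateModel(getModel("OSC_1"), c(1, 1), cfgFast)
  t <- trajectoryTimes(tr)
  expect_equal(t[1], 0)
  expect_equal(t[length(t)], 100)
  ## x1'' = -x1/4 with x1(0)=1, x1'(0)=1/2
  expect_lt(max(abs(trajectoryValues(tr)[, 1] - (cos(t / 2) + sin(t / 2)))),
            1e-2)
  expect_equal(trajectoryValues(tr)[1, ], c(1, 1), tolerance = 1e-10)
})

test_that("linear models match the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  for (sym in names(linearSystems())) {
    model <- getModel(sym)
    tr <- integrateModel(model, model@x0, cfgFast)
    idx <- seq(1, 1000, by = 25)
    ora <- linearSolution(linearSystems()[[sym]], model@x0,
                          trajectoryTimes(tr)[idx])
    expect_lt(max(abs(trajectoryValues(tr)[idx, ] - ora)), 1e-3,
              label = paste(sym, "max abs error vs matrix exponential"))
  }
})

test_that("undamped oscillators conserve energy along the flow", {
  for (sym in c("OSC_1", "OSC_2")) {
    model <- getModel(sym)
    tr <- integrateModel(model, model@x0, cfgFast)
    v <- trajectoryValues(tr)
    e0 <- sum(model@x0^2)
    expect_lt(max(abs(v[, 1]^2 + v[, 2]^2 - e0)), 1e-2 * e0, label = sym)
  }
})

test_that("damped systems decay", {
  for (sym in c("DS_1", "DS_2")) {
    model <- getModel(sym)
    v <- trajectoryValues(integrateModel(model, model@x0, cfgFast))
    expect_lt(sqrt(sum(v[1000, ]^2)), sqrt(sum(v[1, ]^2)), label = sym)
  }
})

test_that("chaotic models stay bounded and show sensitivity to initial conditions", {
  for (sym in paste0("CHA_", 1:5)) {
    model <- getModel(sym)
    tr <- integrateModel(model, model@x0, cfgFast)
    expect_true(all(is.finite(trajectoryValues(tr))), info = sym)
  }
  ## two Lorenz runs 1e-8 apart separate visibly before T_max
  lor <- getModel("CHA_2")
  a <- trajectoryValues(integrateModel(lor, lor@x0, cfgFast))
  b <- trajectoryValues(integrateModel(lor, lor@x0 + c(1e-8, 0, 0), cfgFast))
  expect_gt(max(abs(a[, 1] - b[, 1])), 1.0)
})

test_that("explicit trajectories match the formula on the grid", {
  model <- getModel("QPS_2")
  tr <- evaluateExplicit(model, phase = 0.37, cfgFast)
  expect_equal(ncol(trajectoryValues(tr)), 1L)
  t <- trajectoryTimes(tr)
  phi <- (1 + sqrt(5)) / 2
  expect_equal(trajectoryValues(tr)[, 1],
               sin(phi * t / 15 + 0.37) + sin(t / 15 + 0.37),
               tolerance = 1e-12)
  expect_true(all(abs(trajectoryValues(tr)) <= 2))
})

test_that("resampling interpolation modes agree closely on smooth systems", {
  model <- getModel("DOSC_1")
  dense <- trajectoryValues(integrateModel(model, model@x0, cfgFast))
  cub <- trajectoryValues(integrateModel(model, model@x0,
    generatorConfig(samples = 1000, interpolation = "cubic")))
  expect_lt(max(abs(dense - cub)), 1e-4)
})

test_that("dataset generation is deterministic and counts are honoured", {
  cfg <- generatorConfig(runsPerModel = 3, masterSeed = 42)
  m1 <- generateDataset("OSC_1", cfg)
  m2 <- generateDataset("OSC_1", cfg)
  expect_length(m1@trajectories, 3L)
  expect_equal(dim(trajectoryValues(m1@trajectories[[1]])), c(1000L, 2L))
  for (i in 1:3)
    expect_identical(trajectoryValues(m1@trajectories[[i]]),
                     trajectoryValues(m2@trajectories[[i]]))
  ## different master seed changes the draws
  m3 <- generateDataset("OSC_1", generatorConfig(runsPerModel = 3,
                                                 masterSeed = 43))
  expect_false(identical(trajectoryValues(m1@trajectories[[1]]),
                         trajectoryValues(m3@trajectories[[1]])))
  ## child seeds are unique across models and runs
  full <- generateDataset(dryRun = TRUE,
                          config = generatorConfig(masterSeed = 7))
  expect_false(anyDuplicated(full@runs$seed) > 0)
})

test_that("quasi-periodic phase randomization spans (-2 pi, 2 pi)", {
  man <- generateDataset("QPS_1", generatorConfig(runsPerModel = 50,
                                                  masterSeed = 2))
  phases <- vapply(man@trajectories, function(t) t@ic, 1)
  expect_true(all(abs(phases) < 2 * pi))
  expect_gt(max(phases), 2)      # actually spreads over the range
  expect_lt(min(phases), -2)
})

test_that("a dry-run manifest reports the full dataset arithmetic", {
  man <- generateDataset(dryRun = TRUE, config = generatorConfig())
  cnt <- datasetCounts(man)
  expect_equal(cnt$nModels, 15L)
  expect_equal(cnt$filesPerModel, 1000L)
  expect_equal(cnt$rowsPerFile, 1000L)
  expect_equal(cnt$nSeries, 33000L)
})
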