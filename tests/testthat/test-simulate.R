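test_that("genotype simulation respects map distances", {
  # distance 0: identical columns
  map0 <- LinkageMap(c("a", "b"), "LG1", c(5, 5))
  g0 <- simulateGenotypes(200, map0, seed = 1)
  v0 <- genoValues(g0)
  expect_identical(v0[, "a"], v0[, "b"])

  # huge distance: concordance -> 1/2
  mapInf <- LinkageMap(c("a", "b"), "LG1", c(0, 1e5))
  vI <- genoValues(simulateGenotypes(20000, mapInf, seed = 2))
  expect_lt(abs(mean(vI[, "a"] == vI[, "b"]) - 0.5), 3 * sqrt(0.25 / 20000))

  # d = 20 cM: empirical recombinant fraction near the Haldane value
  map20 <- LinkageMap(c("a", "b"), "LG1", c(0, 20))
  v20 <- genoValues(simulateGenotypes(50000, map20, seed = 3))
  r <- recombFraction(20)
  expect_lt(abs(mean(v20[, "a"] != v20[, "b"]) - r),
            3 * sqrt(r * (1 - r) / 50000))

  expect_error(simulateGenotypes(1, map20), "at least 2")
})

test_that("simulation is deterministic given the seed and columns balance", {
  map <- simulateMap(2, 6, 50)
  g1 <- simulateGenotypes(40, map, seed = 99)
  g2 <- simulateGenotypes(40, map, seed = 99)
  expect_identical(genoValues(g1), genoValues(g2))
  arch <- architecture(mean = 1, additive = c(LG1_M2 = 2), sigma = 1,
                       noise = "lognormal", nReps = 2)
  p1 <- simulatePhenotypes(g1, arch, seed = 7)
  p2 <- simulatePhenotypes(g2, arch, seed = 7)
  expect_identical(p1@records, p2@records)

  big <- genoValues(simulateGenotypes(20000, simulateMap(1, 4, 300), seed = 5))
  expect_true(all(abs(colMeans(big)) < 0.02))
  expect_true(all(abs(apply(big, 2, var) - 1) < 0.01))
})

test_that("phenotypes realize the generative model exactly in the noiseless limit", {
  map <- simulateMap(1, 5, 80)
  g <- simulateGenotypes(50, map, seed = 21)
  # all effects zero, no noise -> every observation equals the mean
  a0 <- architecture(mean = 12.5, sigma = 0, nReps = 3)
  ph0 <- simulatePhenotypes(g, a0, seed = 22)
  expect_true(all(ph0@records$value == 12.5))

  # single triple: line values in {mu - d, mu + d}
  mk <- markerIds(g)[c(1, 3, 5)]
  a1 <- architecture(mean = 10,
    triples = data.frame(m1 = mk[1], m2 = mk[2], m3 = mk[3], effect = 4),
    sigma = 0, nReps = 1)
  ph1 <- simulatePhenotypes(g, a1, seed = 23)
  expect_setequal(unique(ph1@records$value), c(6, 14))

  # and aaa_p then equals -delta * mean(triple product) identically
  w <- genoValues(g)[, mk[1]] * genoValues(g)[, mk[2]] * genoValues(g)[, mk[3]]
  expect_equal(estimateAaaP(lineMeans(ph1))@estimate, -4 * mean(w),
               tolerance = 1e-12)

  expect_error(geneticValues(g, architecture(additive = c(nope = 1))),
               "absent marker")
})

test_that("regressing simulated line means on the true design recovers the effects", {
  map <- simulateMap(3, 4, 90)
  g <- simulateGenotypes(250, map, seed = 31)
  qtl <- c("LG1_M2", "LG2_M3", "LG3_M1")
  arch <- architecture(mean = 5, additive = setNames(c(2, -1.5, 1), qtl),
    pairs = data.frame(m1 = qtl[1], m2 = qtl[2], effect = 0.8),
    triples = data.frame(m1 = qtl[1], m2 = qtl[2], m3 = qtl[3], effect = 1.2),
    sigma = 1, nReps = 4)
  ph <- simulatePhenotypes(g, arch, seed = 32)
  des <- dropAliased(buildDesign(g, qtl))
  fit <- fitUnweighted(unname(lineMeans(ph)), des)
  ct <- coefficientTests(fit)
  truth <- c("(Intercept)" = 5, setNames(c(2, -1.5, 1), qtl),
             setNames(0.8, paste(qtl[1], qtl[2], sep = ":")),
             setNames(1.2, paste(qtl, collapse = ":")))
  for (tm in names(truth)) {
    row <- ct[ct$term == tm, ]
    expect_lt(abs(row$estimate - truth[[tm]]), 3 * row$se)
  }
})

test_that("the Monte-Carlo harness recovers planted triples and its summaries are recomputable", {
  sc <- defaultScenario("recovery")
  mc <- monteCarloCompare(sc, nReps = 5, seed = 1234)
  expect_equal(mc$trueAaa, 5)
  expect_equal(mc$summary$recovery_rate, 1)
  # summaries derive from the per-replicate table
  expect_equal(mc$summary$recovery_rate, mean(mc$reps$recovered))
  expect_equal(mc$summary$mean_gw_true,
               mean(mc$reps$aaa_gw_true[mc$reps$recovered]))
  expect_equal(mc$summary$mse_gu,
               mean((mc$reps$aaa_gu_true[mc$reps$recovered] - 5)^2))
  # identical seed, identical output
  mc2 <- monteCarloCompare(sc, nReps = 5, seed = 1234)
  expect_identical(mc$reps, mc2$reps)
})

test_that("MCAR masking plus re-imputation still allows recovery at low noise", {
  sc <- defaultScenario("recovery")
  sc$maskRate <- 0.05
  mc <- monteCarloCompare(sc, nReps = 4, seed = 777)
  expect_gte(mean(mc$reps$recovered), 0.75)
})
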