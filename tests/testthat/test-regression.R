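# Independent normal-equations oracle: explicit matrix inversion.
neOracle <- function(G, y, w = rep(1, length(y))) {
  A <- t(G * w) %*% G
  drop(solve(A, t(G * w) %*% y))
}

# random full-rank +/-1 design with an intercept, p additive columns
randomDesign <- function(n, p, seed) {
  map <- simulateMap(1, max(p, 2), 1e4)  # far apart -> near-independent
  g <- simulateGenotypes(n, map, seed = seed)
  buildDesign(g, markerIds(g)[seq_len(p)], interactionMarkers = character())
}

test_that("intercept-only and orthogonal designs are solved exactly", {
  g1 <- GenotypeMatrix(matrix(c(1, -1, 1), 3, 1,
    dimnames = list(paste0("L", 1:3), "M1")))
  d0 <- buildDesign(g1, character())
  expect_equal(unname(coef(fitUnweighted(c(3, 3, 3), d0))), 3)

  x <- c(rep(1, 10), rep(-1, 10))
  g2 <- GenotypeMatrix(matrix(x, 20, 1,
    dimnames = list(paste0("L", 1:20), "M1")))
  d1 <- buildDesign(g2, "M1")
  f <- fitUnweighted(2 * x, d1)
  expect_equal(unname(coef(f)), c(0, 2), tolerance = 1e-12)
})

test_that("OLS and WLS match the explicit normal-equations oracle", {
  set.seed(71)
  for (i in 1:15) {
    des <- randomDesign(30, 5, seed = 300 + i)
    G <- designMatrix(des)
    y <- rnorm(30, sd = 3)
    fu <- fitUnweighted(y, des)
    expect_equal(unname(coef(fu)), unname(neOracle(G, y)), tolerance = 1e-8)
    # classical covariance sigma2 (G'G)^-1
    s2 <- sum(residuals(fu)^2) / (30 - ncol(G))
    expect_equal(unname(vcov(fu)), unname(s2 * solve(t(G) %*% G)),
                 tolerance = 1e-8)

    w <- exp(rnorm(30))
    fw <- fitWeighted(y, des, 1 / w)  # lineVariances = 1/w -> reg weights w
    expect_equal(unname(coef(fw)), unname(neOracle(G, y, w)), tolerance = 1e-8)
    # residuals orthogonal to the design in the weighted inner product
    expect_lt(max(abs(t(G) %*% (w * residuals(fw)))), 1e-8)
  }
})

test_that("equal weights reproduce the unweighted fit to 1e-10", {
  set.seed(72)
  for (i in 1:10) {
    des <- randomDesign(40, 6, seed = 400 + i)
    y <- rnorm(40)
    cu <- coef(fitUnweighted(y, des))
    cw <- coef(fitWeighted(y, des, rep(2.7, 40)))
    expect_equal(cu, cw, tolerance = 1e-10)
  }
})

test_that("a line with enormous variance is effectively excluded", {
  des <- randomDesign(35, 4, seed = 501)
  set.seed(73)
  y <- rnorm(35)
  v <- rep(1, 35); v[7] <- 1e9
  fw <- fitWeighted(y, des, v)
  # leave-one-out oracle
  G <- designMatrix(des)
  keep <- setdiff(1:35, 7)
  loo <- neOracle(G[keep, ], y[keep])
  expect_equal(unname(coef(fw)), unname(loo), tolerance = 1e-4)
})

test_that("totals are literal sums over triple coefficients", {
  # exact synthetic signal on a full-rank design: triple effects 2, -5, 7
  map <- simulateMap(1, 5, 2e4)
  g <- simulateGenotypes(120, map, seed = 601)
  mk <- markerIds(g)
  des <- dropAliased(buildDesign(g, mk))
  G <- designMatrix(des)
  ti <- termInfo(des)
  tr <- which(ti$type == "triple")[1:3]
  y <- drop(G[, tr] %*% c(2, -5, 7)) + 0.5
  fit <- fitUnweighted(y, des)
  tot <- totalAaa(fit, "allRetained")
  trip <- coef(fit)[ti$label[ti$type == "triple"]]
  expect_equal(tot$total, sum(trip), tolerance = 1e-10)
  expect_equal(totalAaa(fit)$total, 2 - 5 + 7, tolerance = 1e-6)
  expect_equal(totalAaa(fit)$min, -5, tolerance = 1e-6)
  expect_equal(totalAaa(fit)$max, 7, tolerance = 1e-6)
  expect_equal(totalAaa(fit)$count, 3L)

  # zero triples -> total 0, count 0
  des0 <- buildDesign(g, mk[1:2])
  f0 <- fitUnweighted(rnorm(120), des0)
  expect_equal(totalAaa(f0)$total, 0)
  expect_equal(totalAaa(f0)$count, 0L)
})

test_that("per-triple variance explained matches a two-refit oracle and saturates", {
  # saturation on an orthogonal (replicated 2^3 factorial) design:
  # y exactly mu + delta * triple column -> the triple accounts for
  # (essentially) everything
  gv <- as.matrix(expand.grid(A = c(-1, 1), B = c(-1, 1), C = c(-1, 1)))
  gv <- gv[rep(1:8, 5), ]
  rownames(gv) <- paste0("L", 1:40)
  gfac <- GenotypeMatrix(gv)
  desF <- buildDesign(gfac, c("A", "B", "C"))
  yF <- 10 + 4 * designMatrix(desF)[, "A:B:C"]
  fitF <- fitUnweighted(yF, desF)
  expect_gt(tripleVarianceExplained(yF, desF, fitF, "A:B:C"), 99)
  # an absent effect accounts for nothing
  y0 <- 10 + 2 * gv[, "A"]
  fit0 <- fitUnweighted(y0, desF)
  expect_equal(tripleVarianceExplained(y0, desF, fit0, "A:B:C"), 0,
               tolerance = 1e-10)

  map <- simulateMap(1, 4, 1e4)
  g <- simulateGenotypes(80, map, seed = 602)
  des <- dropAliased(buildDesign(g, markerIds(g)))
  ti <- termInfo(des)
  lab <- ti$label[ti$type == "triple"][1]
  G <- designMatrix(des)

  # random instance vs an oracle computing both RSS by independent refits
  set.seed(74)
  y2 <- rnorm(80)
  w <- runif(80, 0.5, 2)
  fw <- fitWeighted(y2, des, w)
  got <- tripleVarianceExplained(y2, des, fw, lab)
  rss <- function(M) {
    b <- neOracle(M, y2, 1 / w)
    sum((1 / w) * (y2 - M %*% b)^2)
  }
  tssW <- sum((1 / w) * (y2 - sum(y2 / w) / sum(1 / w))^2)
  want <- 100 * (rss(G[, colnames(G) != lab]) - rss(G)) / tssW
  expect_equal(got, want, tolerance = 1e-8)

  # marker-id addressing works too
  m3 <- unlist(ti[ti$label == lab, c("m1", "m2", "m3")])
  expect_equal(tripleVarianceExplained(y2, des, fw, unname(m3)), got)
})

test_that("coefficient t tests are exact in edge cases and calibrated under the null", {
  # a coefficient that is exactly zero: orthogonal design, y ignores x2
  gv <- as.matrix(expand.grid(A = c(-1, 1), B = c(-1, 1), C = c(-1, 1)))
  gv <- gv[rep(1:8, 3), ]
  rownames(gv) <- paste0("L", 1:24)
  g <- GenotypeMatrix(gv)
  des <- buildDesign(g, c("A", "B"), interactionMarkers = character())
  set.seed(75)
  e <- rnorm(24, 0, 1); e <- e - mean(e)
  e <- e - gv[1:24, "A"] * sum(e * gv[1:24, "A"]) / 24
  e <- e - gv[1:24, "B"] * sum(e * gv[1:24, "B"]) / 24
  y <- 3 * gv[1:24, "A"] + e   # exactly orthogonal noise
  ct <- coefficientTests(fitUnweighted(y, des))
  expect_equal(ct$t[ct$term == "B"], 0, tolerance = 1e-10)
  expect_equal(ct$p[ct$term == "B"], 1, tolerance = 1e-10)

  # null p-values uniform: KS test over replicated fits
  des2 <- randomDesign(30, 3, seed = 603)
  set.seed(76)
  ps <- vapply(1:400, function(i) {
    ctn <- coefficientTests(fitUnweighted(rnorm(30), des2))
    ctn$p[2]
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("rank-deficient designs are refused with guidance", {
  v <- matrix(c(1, -1, 1, -1, 1, -1, 1, -1), 4, 2,
              dimnames = list(paste0("L", 1:4), c("A", "B")))  # B == A
  des <- buildDesign(GenotypeMatrix(v), c("A", "B"),
                     interactionMarkers = character())
  expect_error(fitUnweighted(rnorm(4), des), "checkFullRank|rank deficient")
  expect_error(fitWeighted(rnorm(4), des, rep(-1, 4)), "> 0|rank")
})
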