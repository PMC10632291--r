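test_that("genotype CSV parsing is an identity on clean files and flags bad cells", {
  p <- writeGenoCSV(matrix(c("1", "-1", "-1", "1"), 2, 2),
                    c("L1", "L2"), c("M1", "M2"))
  g <- readGenotypes(p)
  expect_identical(genoValues(g), genoValues(tinyGeno()))
  expect_identical(lineIds(g), c("L1", "L2"))

  pm <- writeGenoCSV(matrix(c("1", "NA", "-1", "1"), 2, 2),
                     c("L1", "L2"), c("M1", "M2"))
  gm <- readGenotypes(pm, missingCode = "NA")
  expect_true(is.na(genoValues(gm)[2, 1]))
  expect_identical(genoValues(gm)[1, ], c(M1 = 1, M2 = -1))

  pb <- writeGenoCSV(matrix(c("1", "2", "-1", "1"), 2, 2),
                     c("L1", "L2"), c("M1", "M2"))
  expect_error(readGenotypes(pb), "L2.*M1|row 2, column 2")

  pd <- writeGenoCSV(matrix(c("1", "-1"), 2, 1), c("L1", "L1"), "M1")
  expect_error(readGenotypes(pd), "duplicate line")
})

test_that("genotype validity rejects out-of-range and unnamed grids", {
  expect_error(GenotypeMatrix(matrix(2, 1, 1,
    dimnames = list("L1", "M1"))), "\\[-1, \\+1\\]")
  expect_error(GenotypeMatrix(matrix(1, 2, 2)), "names")
  # imputed dosages inside [-1, 1] are fine
  expect_s4_class(GenotypeMatrix(matrix(c(0.4, -1), 1, 2,
    dimnames = list("L1", c("M1", "M2")))), "GenotypeMatrix")
})

test_that("linkage map reading validates and orders correctly", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("marker_id,group,position_cM", "m2,LG1,10", "m1,LG1,0",
               "m3,LG1,25"), p)
  m <- readLinkageMap(p)
  expect_equal(nrow(mapTable(m)), 3)
  expect_identical(mapTable(m)$marker_id, c("m1", "m2", "m3"))

  pd <- tempfile(fileext = ".csv")
  writeLines(c("marker_id,group,position_cM", "m1,LG1,0", "m1,LG2,5"), pd)
  expect_error(readLinkageMap(pd), "duplicate")

  pn <- tempfile(fileext = ".csv")
  writeLines(c("marker_id,group,position_cM", "m1,LG1,-3"), pn)
  expect_error(readLinkageMap(pn), "negative")

  pe <- tempfile(fileext = ".csv")
  writeLines("marker_id,group,position_cM", pe)
  expect_warning(me <- readLinkageMap(pe), "empty")
  expect_equal(nrow(mapTable(me)), 0)
})

test_that("phenotype sets yield line means, variances and replicate counts", {
  ph <- PhenotypeSet(c("A", "A", "B"), c(1, 2, 1), c(4, 6, 7))
  expect_equal(unname(lineMeans(ph)), c(5, 7))
  expect_equal(unname(lineVariances(ph, fallback = "none")), c(2, NA))
  # single-rep line gets the median of available variances
  expect_equal(unname(lineVariances(ph)), c(2, 2))
  expect_equal(unname(replicateCounts(ph)), c(2L, 1L))

  # no replicated line at all: unit weights with a warning
  ph1 <- PhenotypeSet(c("A", "B"), c(1, 1), c(1, 2))
  expect_warning(v1 <- lineVariances(ph1), "unit weights")
  expect_equal(unname(v1), c(1, 1))

  pbad <- tempfile(fileext = ".csv")
  writeLines(c("line_id,rep,value", "A,1,x"), pbad)
  expect_error(readPhenotypes(pbad), "non-numeric")
})

test_that("a 126-line single-rep file yields a 126-vector of means", {
  p <- tempfile(fileext = ".csv")
  set.seed(3)
  write.csv(data.frame(line_id = sprintf("L%03d", 1:126), rep = 1,
                       value = rnorm(126)), p, row.names = FALSE)
  expect_length(lineMeans(readPhenotypes(p)), 126)
})

test_that("all three formats round-trip exactly", {
  map <- simulateMap(2, 5, 40)
  g <- simulateGenotypes(8, map, seed = 4)
  v <- genoValues(g); v[2, 3] <- NA; v[5, 9] <- NA
  g <- GenotypeMatrix(v)
  arch <- architecture(mean = 10, additive = c(LG1_M2 = 1.5),
                       sigma = 0.7, nReps = 3)
  gi <- imputeFlanking(g, map)   # real-valued dosages exercise numerics
  ph <- simulatePhenotypes(gi, arch, seed = 5)

  pg <- tempfile(); writeGenotypes(g, pg)
  g2 <- readGenotypes(pg)
  expect_identical(dimnames(genoValues(g2)), dimnames(genoValues(g)))
  expect_equal(genoValues(g2), genoValues(g), tolerance = 1e-12)

  pm <- tempfile(); writeLinkageMap(map, pm)
  expect_equal(readLinkageMap(pm)@map, map@map, tolerance = 1e-12)

  pp <- tempfile(); writePhenotypes(ph, pp)
  ph2 <- readPhenotypes(pp)
  expect_identical(ph2@records$line_id, ph@records$line_id)
  expect_equal(ph2@records$value, ph@records$value, tolerance = 1e-12)
})

test_that("joining phenotypes to genotypes keeps genotype line order", {
  g <- GenotypeMatrix(matrix(c(1, -1, 1, -1, 1, 1), 3, 2,
    dimnames = list(c("L3", "L1", "L2"), c("M1", "M2"))))
  ph <- PhenotypeSet(c("L1", "L2", "L3"), c(1, 1, 1), c(10, 20, 30))
  j <- joinLines(ph, g)
  expect_identical(lineIds(j$geno), c("L3", "L1", "L2"))
  expect_equal(unname(lineMeans(j$pheno)), c(30, 10, 20))
  phx <- PhenotypeSet(c("L1", "LX"), c(1, 1), c(1, 2))
  expect_error(joinLines(phx, g), "absent")
})
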