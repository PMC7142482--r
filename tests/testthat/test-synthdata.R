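test_that("reference spectra are unit-intensity Lorentzian sums", {
  grid <- smallGrid()
  def <- metaboliteDef("probe", list(peakSpec(3.0, 1, 0.02)))
  s <- makeReferenceSpectrum(def, grid)
  expect_equal(sum(intensity(s)), 1.0, tolerance = 1e-12)

  # argmax falls on the grid point nearest the peak center (direct
  # evaluation of the Lorentzian on the grid as oracle)
  oracle <- (0.01^2) / ((grid - 3.0)^2 + 0.01^2)
  expect_equal(which.max(intensity(s)), which.max(oracle))
  expect_equal(which.max(intensity(s)), which.min(abs(grid - 3.0)))

  # two equal peaks symmetric about the grid midpoint give a symmetric shape
  gsym <- seq(-1, 1, length.out = 1001)
  dsym <- metaboliteDef("sym", list(peakSpec(-0.3, 1, 0.05),
                                    peakSpec(0.3, 1, 0.05)))
  ssym <- intensity(makeReferenceSpectrum(dsym, gsym))
  expect_equal(ssym, rev(ssym), tolerance = 1e-12)
})

test_that("empty or invalid metabolite definitions are rejected", {
  expect_error(metaboliteDef("empty", list()), "empty peak list")
  expect_error(peakSpec(3.0, amplitude = -1), "amplitude")
  expect_error(peakSpec(3.0, fwhm = 0))
})

test_that("mixtures are exactly linear in concentrations without noise", {
  grid <- smallGrid()
  defs <- smallDefs(2)
  refs <- lapply(defs, function(d)
    intensity(makeReferenceSpectrum(d, grid)))
  mx <- makeMixture(defs, c(2, 3), grid, seed = 1)
  expected <- 2 * refs[[1]] + 3 * refs[[2]]
  expect_equal(intensity(mx$spectrum), expected, tolerance = 1e-12)
  expect_equal(unname(mx$truth), c(2, 3))

  zero <- makeMixture(defs, c(0, 0), grid, seed = 1)
  expect_true(all(intensity(zero$spectrum) == 0))

  expect_error(makeMixture(defs, c(-1, 1), grid, seed = 1), "non-negative")
  expect_error(makeMixture(defs, c(1, 1, 1), grid, seed = 1), "length")
})

test_that("mixture generation is deterministic under a fixed seed", {
  grid <- smallGrid(512)
  defs <- smallDefs(3)
  a <- makeMixture(defs, c(1, 2, 3), grid, noiseSd = 0.01,
                   shiftJitterSd = 0.005, baselineAmp = 0.001, seed = 7)
  b <- makeMixture(defs, c(1, 2, 3), grid, noiseSd = 0.01,
                   shiftJitterSd = 0.005, baselineAmp = 0.001, seed = 7)
  expect_identical(intensity(a$spectrum), intensity(b$spectrum))
  c <- makeMixture(defs, c(1, 2, 3), grid, noiseSd = 0.01, seed = 8)
  expect_false(identical(intensity(a$spectrum), intensity(c$spectrum)))
})

test_that("cohorts carry metadata and exact ground truth", {
  design <- fourLineDesign(seed = 9)
  cohort <- makeCohort(design, smallDefs(5), smallGrid(512))
  expect_length(cohort$spectra, 12L)
  truth <- concentrations(cohort$truth)
  expect_equal(dim(truth), c(12L, 5L))
  # CV 0 and no effects: every replicate sits at the base level
  expect_true(all(truth == 1))
  cd <- SummarizedExperiment::colData(cohort$truth)
  expect_setequal(unique(cd$cellLine), c("LN18", "A172", "U118", "NHA"))
  expect_equal(unname(table(cd$cellLine))[1], 3L)
})

test_that("planted effects shift group means by the stated factor", {
  design <- fourLineDesign(effects = list("U118.cell" = c(lactate = 3)),
                           seed = 3)
  cohort <- makeCohort(design, smallDefs(5), smallGrid(512))
  truth <- concentrations(cohort$truth)
  cd <- SummarizedExperiment::colData(cohort$truth)
  inU <- cd$cellLine == "U118"
  expect_equal(mean(truth[inU, "lactate"]) / mean(truth[!inU, "lactate"]),
               3, tolerance = 1e-12)
  expect_equal(mean(truth[inU, "alanine"]), mean(truth[!inU, "alanine"]),
               tolerance = 1e-12)
})

test_that("cohort generation is reproducible byte for byte", {
  design <- fourLineDesign(seed = 5, cv = 0.1, noiseSd = 1e-4,
                           nMetabolites = 3L)
  a <- makeCohort(design, smallDefs(3), smallGrid(256))
  b <- makeCohort(design, smallDefs(3), smallGrid(256))
  expect_identical(lapply(a$spectra, intensity),
                   lapply(b$spectra, intensity))
  expect_identical(concentrations(a$truth), concentrations(b$truth))
})

test_that("toy networks are structurally sound", {
  for (kind in allToyKinds) {
    m <- makeToyNetwork(kind)
    expect_true(validateModel(m))
    S <- as.matrix(stoichiometry(m))
    expect_true(all(colSums(S != 0) > 0), info = kind)
    expect_true(all(rowSums(S != 0) > 0), info = kind)
    expect_true(objectiveReaction(m) %in% reactionIds(m), info = kind)
    expect_lte(length(reactionIds(m)), 8L)
  }
  expect_error(makeToyNetwork("nonsense"))
})

test_that("the TCA fragment carries succinate to fumarate to malate", {
  m <- makeToyNetwork("mini_tca")
  S <- as.matrix(stoichiometry(m))
  # some reaction consumes succ and produces fum
  expect_true(any(S["succ", ] < 0 & S["fum", ] > 0))
  # and fumarate feeds malate
  expect_true(any(S["fum", ] < 0 & S["mal", ] > 0))
  g <- makeToyNetwork("glutathione")
  expect_true(all(c("gthrd", "gthox", "x5oxpro") %in% metaboliteIds(g)))
})

test_that("expression profiles implement the boolean 100/0 scheme", {
  m <- makeToyNetwork("branched")
  all100 <- expressionValues(makeExpressionProfile(m, geneIds(m)))
  expect_true(all(all100 == 100))
  none <- expressionValues(makeExpressionProfile(m, character(0)))
  expect_true(all(none == 0))
  one <- expressionValues(makeExpressionProfile(m, "g1"))
  expect_equal(sum(one == 100), 1L)
  expect_equal(sum(one == 0), length(geneIds(m)) - 1L)
  expect_warning(makeExpressionProfile(m, c("g1", "ghost")), "ghost")
})
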