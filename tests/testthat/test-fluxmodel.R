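test_that("GPR rules parse into the expected trees", {
  expect_equal(parseGPR("g1"), list(op = "gene", id = "g1"))
  tree <- parseGPR("g1 and (g2 or g3)")
  expect_equal(tree$op, "and")
  expect_equal(tree$args[[1]], list(op = "gene", id = "g1"))
  expect_equal(tree$args[[2]]$op, "or")
  expect_null(parseGPR(""))
  expect_null(parseGPR("   "))
  expect_error(parseGPR("g1 and or g2"), "position")
  expect_error(parseGPR("(g1 and g2"), "\\)")
  expect_error(parseGPR("g1 g2"), "unexpected")
})

test_that("reaction expression agrees with truth-table evaluation", {
  rules <- c("gA", "gA and gB", "gA or gB", "(gA or gB) and gC",
             "gA and (gB or (gC and gD))", "gA or gB or gC and gD")
  genes <- c("gA", "gB", "gC", "gD")
  model1 <- function(rule) MetabolicModel(
    metabolites = "m", reactions = c("r", "ex"),
    S = matrix(c(1, -1), 1, 2), lb = c(0, 0), ub = c(1, 1),
    gpr = c(rule, ""), genes = genes, objective = "ex")
  boolOracle <- function(rule, vals) {
    expr <- gsub("\\band\\b", "&", gsub("\\bor\\b", "|", rule))
    for (g in genes)
      expr <- gsub(paste0("\\b", g, "\\b"),
                   as.character(vals[g] >= 50), expr)
    ifelse(eval(parse(text = expr)), 100, 0)
  }
  for (rule in rules) {
    m <- model1(rule)
    for (mask in 0:15) {
      vals <- setNames(100 * as.integer(intToBits(mask)[1:4]), genes)
      got <- reactionExpression(m, vals)
      expect_equal(unname(got["r"]), boolOracle(rule, vals),
                   info = sprintf("%s @ %d", rule, mask))
      expect_true(is.na(got["ex"]))   # empty rule: unconstrained marker
    }
  }
})

test_that("reaction expression follows the min/max convention", {
  m <- MetabolicModel(
    metabolites = "m", reactions = c("and2", "or2", "mix"),
    S = matrix(c(1, 1, -2), 1, 3), lb = rep(0, 3), ub = rep(1, 3),
    gpr = c("g1 and g2", "g1 or g2", "(g1 or g2) and g3"),
    genes = c("g1", "g2", "g3"), objective = "mix")
  e <- reactionExpression(m, c(g1 = 0, g2 = 100, g3 = 100))
  expect_equal(unname(e["and2"]), 0)
  expect_equal(unname(e["or2"]), 100)
  expect_equal(unname(e["mix"]), 100)
  # genes missing from the profile count as absent
  expect_message(e2 <- reactionExpression(m, c(g1 = 100)), "treated as 0")
  expect_equal(unname(e2["and2"]), 0)
})

test_that("model validation collects all failures", {
  err <- tryCatch(
    MetabolicModel(metabolites = "A", reactions = c("r1", "r2"),
                   S = matrix(c(1, -1), 1, 2), lb = c(0, 5), ub = c(10, 1),
                   gpr = c("gX", ""), genes = character(0),
                   objective = "missing"),
    error = conditionMessage)
  expect_match(err, "lb > ub")
  expect_match(err, "objective")
  expect_match(err, "undeclared")
})

test_that("FBA solves the textbook cases", {
  ch <- makeToyNetwork("chain")
  sol <- fba(ch)
  expect_equal(solverStatus(sol), "optimal")
  expect_equal(objectiveValue(sol), 10, tolerance = 1e-9)

  # closing the exchange kills the objective
  closed <- ch; closed@ub[1] <- 0
  expect_equal(objectiveValue(fba(closed)), 0, tolerance = 1e-9)

  # parallel routes of capacity 4 and 6 add up
  br <- makeToyNetwork("branched")
  br@ub[reactionIds(br) == "route1"] <- 4
  br@ub[reactionIds(br) == "route2"] <- 6
  solBr <- fba(br)
  expect_equal(objectiveValue(solBr), 10, tolerance = 1e-9)
  expect_equal(objectiveValue(solBr), fbaOracle(br)$value,
               tolerance = 1e-6)

  # infeasible: objective forced beyond the uptake capacity
  inf <- ch; inf@lb[3] <- 20
  expect_equal(solverStatus(fba(inf)), "infeasible")
})

test_that("FBA matches vertex enumeration and mass balance on all toys", {
  for (kind in allToyKinds) {
    m <- makeToyNetwork(kind)
    sol <- fba(m)
    expect_equal(solverStatus(sol), "optimal", info = kind)
    expect_equal(objectiveValue(sol), fbaOracle(m)$value,
                 tolerance = 1e-6, info = kind)
    resid <- as.numeric(stoichiometry(m) %*% fluxes(sol))
    expect_lt(max(abs(resid)), 1e-6)
    expect_true(all(fluxes(sol) >= m@lb - 1e-9 &
                    fluxes(sol) <= m@ub + 1e-9), info = kind)
  }
})

test_that("GIMME with all genes present has zero inconsistency", {
  for (kind in allToyKinds) {
    m <- makeToyNetwork(kind)
    prof <- makeExpressionProfile(m, geneIds(m))
    sol <- gimme(m, reactionExpression(m, prof))
    expect_equal(solverStatus(sol), "optimal", info = kind)
    expect_equal(inconsistencyScore(sol), 0, tolerance = 1e-9,
                 info = kind)
    expect_gte(objectiveValue(sol), 0.9 * objectiveValue(fba(m)) - 1e-9)
  }
})

test_that("GIMME routes flux through the expressed branch", {
  m <- makeToyNetwork("branched")
  rxnExpr <- reactionExpression(m, makeExpressionProfile(m, "g1"))
  sol <- gimme(m, rxnExpr)
  fl <- fluxes(sol)
  expect_equal(inconsistencyScore(sol), 0, tolerance = 1e-9)
  expect_gt(fl["route1"], 8)
  expect_equal(unname(fl["route2"]), 0, tolerance = 1e-9)
  expect_equal(inconsistencyScore(sol),
               gimmeOracle(m, rxnExpr), tolerance = 1e-6)
})

test_that("GIMME pays exactly the oracle penalty when forced low", {
  # choke the expressed route so the silent one must carry the rest
  m <- makeToyNetwork("branched")
  m@ub[reactionIds(m) == "route1"] <- 4
  rxnExpr <- reactionExpression(m, makeExpressionProfile(m, "g1"))
  sol <- gimme(m, rxnExpr, cutoff = 50, objectiveFraction = 0.9)
  # objective 9 needs route2 to carry 5 at weight (50 - 0)
  expect_equal(inconsistencyScore(sol), 50 * 5, tolerance = 1e-6)
  expect_equal(inconsistencyScore(sol), gimmeOracle(m, rxnExpr),
               tolerance = 1e-6)
})

test_that("GIMME matches brute-force enumeration across contexts", {
  profiles <- list(
    chain = list(character(0), "g1"),
    branched = list(character(0), "g1", "g2", c("g1", "g2")),
    mini_tca = list(c("aco", "idh", "ogdh"),
                    c("aco", "idh", "ogdh", "sdh", "fh"),
                    character(0)),
    glutathione = list("ggct", c("gpx", "ggct"), character(0)))
  for (kind in allToyKinds) {
    m <- makeToyNetwork(kind)
    for (present in profiles[[kind]]) {
      rxnExpr <- reactionExpression(m, makeExpressionProfile(m, present))
      sol <- gimme(m, rxnExpr)
      oracle <- gimmeOracle(m, rxnExpr)
      expect_equal(solverStatus(sol), "optimal",
                   info = paste(kind, paste(present, collapse = "+")))
      expect_equal(inconsistencyScore(sol), oracle, tolerance = 1e-6,
                   info = paste(kind, paste(present, collapse = "+")))
    }
  }
})

test_that("raising the objective fraction never lowers the score", {
  m <- makeToyNetwork("branched")
  m@ub[reactionIds(m) == "route1"] <- 4
  rxnExpr <- reactionExpression(m, makeExpressionProfile(m, "g1"))
  scores <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.9, 1.0), function(f)
    inconsistencyScore(gimme(m, rxnExpr, objectiveFraction = f)),
    numeric(1))
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("GIMME errors usefully when the objective cannot be held", {
  m <- makeToyNetwork("chain")
  m@ub[1] <- 0                     # no uptake: z* = 0
  rxnExpr <- reactionExpression(m, makeExpressionProfile(m, "g1"))
  expect_error(gimme(m, rxnExpr), "not positive")
})

test_that("subnetwork extraction keeps active reactions and flags dead ends", {
  ch <- makeToyNetwork("chain")
  sol <- fba(ch)
  sub <- contextSubnetwork(ch, sol)
  expect_setequal(reactionIds(sub$model), reactionIds(ch))
  expect_length(sub$deadEnds, 0L)

  zero <- new("FluxSolution",
              fluxes = setNames(rep(0, 3), reactionIds(ch)),
              objectiveValue = 0, status = "optimal",
              inconsistencyScore = NA_real_)
  subZero <- contextSubnetwork(ch, zero)
  expect_length(reactionIds(subZero$model), 0L)

  br <- makeToyNetwork("branched")
  rxnExpr <- reactionExpression(br, makeExpressionProfile(br, "g1"))
  subBr <- contextSubnetwork(br, gimme(br, rxnExpr))
  expect_false("route2" %in% reactionIds(subBr$model))
  expect_true("route1" %in% reactionIds(subBr$model))
})

test_that("models round-trip through JSON and SBML-FBC", {
  cmpModels <- function(a, b) {
    expect_equal(as.matrix(stoichiometry(a)), as.matrix(stoichiometry(b)))
    expect_identical(reactionIds(a), reactionIds(b))
    expect_identical(metaboliteIds(a), metaboliteIds(b))
    expect_equal(bounds(a), bounds(b))
    expect_identical(lapply(a@gpr, parseGPR), lapply(b@gpr, parseGPR))
    expect_setequal(geneIds(a), geneIds(b))
    expect_identical(objectiveReaction(a), objectiveReaction(b))
  }
  for (kind in allToyKinds) {
    m <- makeToyNetwork(kind)
    jf <- withr::local_tempfile(fileext = ".json")
    writeModel(m, jf, "json")
    cmpModels(m, readModel(jf))
    xf <- withr::local_tempfile(fileext = ".xml")
    writeModel(m, xf, "sbml")
    cmpModels(m, readModel(xf))
  }
})

test_that("model readers report schema violations", {
  tf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "A")),
    reactions = list(list(id = "r1", metabolites = list(A = 1))),
    genes = list(), objective = "r1"), tf, auto_unbox = TRUE)
  expect_error(readModel(tf), "missing bound")

  # lb > ub passes parsing but fails validation
  jsonlite::write_json(list(
    metabolites = list(list(id = "A")),
    reactions = list(list(id = "r1", metabolites = list(A = 1),
                          lb = 5, ub = 1)),
    genes = list(), objective = "r1"), tf, auto_unbox = TRUE)
  expect_error(readModel(tf), "lb > ub")

  # SBML reaction without FBC bound references is named in the error
  xf <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '<model id="m"><listOfSpecies><species id="A"/></listOfSpecies>',
    '<listOfReactions><reaction id="naked" reversible="false">',
    '<listOfProducts><speciesReference species="A" stoichiometry="1"/>',
    "</listOfProducts></reaction></listOfReactions></model></sbml>"), xf)
  expect_error(readModel(xf), "naked.*lowerFluxBound")
})
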