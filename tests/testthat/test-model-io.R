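test_that("model construction enforces the structural invariants", {
  expect_error(metabolic_model(
    metabolites = c("A"),
    reactions = list(list(id = "r1", stoich = c(A = -1), lb = 5, ub = 1))),
    "lower bound exceeds upper bound.*r1")
  expect_error(metabolic_model(
    metabolites = c("A"),
    reactions = list(list(id = "r1", stoich = c(B = -1), lb = 0, ub = 1))),
    "undeclared metabolite")
  expect_error(metabolic_model(
    metabolites = c("A"),
    reactions = list(list(id = "r1", stoich = c(A = -1)),
                     list(id = "r1", stoich = c(A = 1)))),
    "duplicate reaction ids")
  expect_error(metabolic_model(
    metabolites = c("A"),
    reactions = list(list(id = "r1", stoich = c(A = -1), gpr = "gX")),
    genes = "gY"),
    "not in gene list")
})

test_that("JSON round trip is the identity on all model fields", {
  m <- make_toy_network()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$metabolites, m$metabolites)
  expect_identical(names(m2$reactions), names(m$reactions))
  for (id in names(m$reactions)) {
    r1 <- m$reactions[[id]]; r2 <- m2$reactions[[id]]
    expect_equal(r2$lb, r1$lb)
    expect_equal(r2$ub, r1$ub)
    expect_equal(r2$stoich[order(names(r2$stoich))],
                 r1$stoich[order(names(r1$stoich))])
    expect_identical(serialize_gpr(r2$gpr), serialize_gpr(r1$gpr))
    expect_identical(r2$subsystem, r1$subsystem)
  }
  expect_identical(sort(m2$genes), sort(m$genes))
  expect_identical(m2$objective_id, m$objective_id)
})

test_that("SBML round trip preserves structure, bounds, GPRs and the objective", {
  m <- make_toy_network()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(unname(model_stats(m2)), unname(model_stats(m)))
  expect_identical(sort(names(m2$reactions)), sort(names(m$reactions)))
  for (id in names(m$reactions)) {
    expect_equal(m2$reactions[[id]]$lb, m$reactions[[id]]$lb)
    expect_equal(m2$reactions[[id]]$ub, m$reactions[[id]]$ub)
  }
  expect_identical(m2$objective_id, "biomass")
  # flux space identical
  expect_equal(fba(m2)$objective, fba(m)$objective, tolerance = 1e-9)
})

test_that("SBML without FBC falls back to reversibility bounds and notes GPRs", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">',
    '<model id="legacy">',
    '<listOfSpecies>',
    '<species id="A" compartment="c"/>',
    '<species id="B" compartment="c"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="r1" reversible="true">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: gA and gB</p>',
    '</body></notes>',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="r2" reversible="false">',
    '<listOfReactants><speciesReference species="B" stoichiometry="1"/></listOfReactants>',
    '</reaction>',
    '</listOfReactions>',
    '</model>',
    '</sbml>'), path)
  m <- read_model(path, format = "sbml")
  expect_equal(m$reactions$r1$lb, -1000)
  expect_equal(m$reactions$r1$ub, 1000)
  expect_equal(m$reactions$r2$lb, 0)
  expect_identical(serialize_gpr(m$reactions$r1$gpr), "gA and gB")
  expect_setequal(m$genes, c("gA", "gB"))
})

test_that("unparseable files raise format errors", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<not-sbml/>", bad)
  expect_error(read_model(bad), "format error")
  badj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": []}', badj)
  expect_error(read_model(badj), "missing top-level key 'reactions'")
  expect_error(read_model("/nonexistent/file.json"), "not found")
})

test_that("stoichiometric matrix matches the per-reaction dictionaries", {
  m <- make_toy_network()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(nrow(m$metabolites), length(m$reactions)))
  # entry-by-entry lookup
  for (id in names(m$reactions)) {
    st <- m$reactions[[id]]$stoich
    expect_equal(as.numeric(S[names(st), id]), unname(st))
  }
  # nonzero count equals total stoichiometry entries
  expect_equal(Matrix::nnzero(S),
               sum(vapply(m$reactions, function(r) length(r$stoich), integer(1))))
  # internal metabolites of a linear chain balance to zero across reactions
  ch <- chain_model()
  Sc <- as.matrix(stoichiometric_matrix(ch))
  expect_equal(unname(rowSums(Sc[c("A", "B", "C"), c("AB", "BC", "SINK_C", "EX_A")])),
               c(-2, 0, 0))
})

test_that("degenerate empty model yields 0x0 structures", {
  m <- metabolic_model(data.frame(id = character(0)), list())
  expect_equal(dim(stoichiometric_matrix(m)), c(0, 0))
  expect_equal(unname(model_stats(m)), c(0, 0, 0))
})

test_that("split_reversible produces an equivalent irreversible model", {
  m <- make_toy_network()
  ms <- split_reversible(m)
  expect_true(all(vapply(ms$reactions, function(r) r$lb >= 0, logical(1))))
  # reversible LDH (-1000, 1000) becomes forward/backward halves
  expect_equal(ms$reactions$LDH_f$ub, 1000)
  expect_equal(ms$reactions$LDH_b$ub, 1000)
  expect_equal(ms$reactions$LDH_b$stoich, -m$reactions$LDH$stoich)
  # irreversible-only models are unchanged
  ch <- chain_model()
  ch$reactions$EX_A$lb <- 0  # make fully irreversible
  expect_identical(names(split_reversible(ch)$reactions), names(ch$reactions))
  # FBA optimum is invariant under splitting
  ms$objective_id <- "biomass"
  expect_equal(fba(ms)$objective, fba(m)$objective, tolerance = 1e-8)
})
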