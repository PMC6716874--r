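# fixture: EX_A -> (NC transporter AB) -> B -> (HC reaction BC) -> sink
unique_support_model <- function() {
  metabolic_model(
    metabolites = c("A", "B", "C"),
    reactions = list(
      list(id = "EX_A", stoich = c(A = -1), lb = -10, ub = 0),
      list(id = "AB", stoich = c(A = -1, B = 1), lb = 0, ub = 1000,
           gpr = "g_ab"),
      list(id = "BC", stoich = c(B = -1, C = 1), lb = 0, ub = 1000,
           gpr = "g_bc"),
      list(id = "SINK_C", stoich = c(C = -1), lb = 0, ub = 1000)))
}

test_that("dependency assessment finds the reactions a target needs", {
  m <- split_reversible(unique_support_model())
  costs <- c(AB = 100, EX_A = 1, SINK_C = 1)
  sup <- dependency_assess(m, "BC", costs)
  expect_true("AB" %in% sup)
  # a target feasible through zero-cost reactions alone has empty support
  sup2 <- dependency_assess(m, "BC", c(AB = 0, EX_A = 0, SINK_C = 0))
  expect_length(sup2, 0)
  # a disconnected target is unsupportable, not an error
  m2 <- metabolic_model(
    metabolites = c("X", "Y"),
    reactions = list(
      list(id = "iso", stoich = c(X = -1, Y = 1), lb = 0, ub = 10)))
  expect_null(dependency_assess(m2, "iso", c(iso = 0)))
  expect_error(dependency_assess(m, "nope", c(AB = 1)), "unknown target")
})

test_that("flux thresholds clip to the target's maximum feasible flux", {
  m <- unique_support_model()
  m$reactions$EX_A$lb <- -0.5   # capacity far below the default threshold
  ms <- split_reversible(metabolic_model(m$metabolites, m$reactions))
  sup <- dependency_assess(ms, "BC", c(AB = 100), flux_threshold = 1.0)
  expect_true("AB" %in% sup)   # not declared unsupportable by scaling
})

test_that("extraction keeps high reactions flux-capable and prunes dead ends", {
  m <- make_toy_network()
  tiers <- stats::setNames(rep("high", length(m$reactions)),
                           names(m$reactions))
  res <- corda_extract(m, tiers)
  # all-high on a consistent fixture: identity
  expect_setequal(names(res$submodel$reactions), names(m$reactions))

  # tier the trp branch negative with an NAD-requiring biomass high:
  # the branch is essential and must be promoted
  tiers2 <- stats::setNames(rep("medium", length(m$reactions)),
                            names(m$reactions))
  tiers2[toy_trp_reactions()] <- "negative"
  tiers2["EX_trp"] <- "negative"
  tiers2["biomass"] <- "high"
  res2 <- corda_extract(m, tiers2)
  expect_true(all(toy_trp_reactions() %in% names(res2$submodel$reactions)))
  expect_gt(fba(res2$submodel)$objective, 0)

  # a dead-end negative reaction supporting nothing is excluded
  rx <- m$reactions
  rx$DEAD <- list(id = "DEAD", stoich = c(atp_c = -1, dead_c = 1),
                  lb = 0, ub = 1000,
                  gpr = parse_gpr("g_dead"))
  m3 <- metabolic_model(rbind(m$metabolites,
                              data.frame(id = "dead_c", name = "dead_c",
                                         compartment = "c")),
                        rx, c(m$genes, "g_dead"), m$objective_id)
  tiers3 <- stats::setNames(rep("medium", length(m3$reactions)),
                            names(m3$reactions))
  tiers3["biomass"] <- "high"
  tiers3["DEAD"] <- "negative"
  res3 <- corda_extract(m3, tiers3)
  expect_false("DEAD" %in% names(res3$submodel$reactions))

  # every included reaction can carry flux (FVA-based consistency)
  iv <- fva(res3$submodel, objective_fraction = 0)
  expect_true(all(pmax(abs(iv$vmin), abs(iv$vmax)) >= 1e-6))
})

test_that("a negative reaction that uniquely supports a high reaction is included", {
  m <- unique_support_model()
  tiers <- c(EX_A = "medium", AB = "negative", BC = "high", SINK_C = "medium")
  res <- corda_extract(m, tiers)
  expect_true("AB" %in% names(res$submodel$reactions))
  expect_true("BC" %in% names(res$submodel$reactions))
  # and the tally records the dependency
  expect_gte(res$dependency_tally[["AB"]], 1)
})

test_that("a high reaction infeasible in the generic model is reported, not fatal", {
  m <- unique_support_model()
  rx <- m$reactions
  rx$ISO <- list(id = "ISO", stoich = c(Z = -1, W = 1), lb = 0, ub = 10,
                 gpr = NULL)
  m2 <- metabolic_model(rbind(m$metabolites,
                              data.frame(id = c("Z", "W"),
                                         name = c("Z", "W"),
                                         compartment = "c")), rx)
  tiers <- c(EX_A = "medium", AB = "medium", BC = "high", SINK_C = "medium",
             ISO = "high")
  res <- corda_extract(m2, tiers)
  expect_identical(res$unsupportable, "ISO")
  expect_false("ISO" %in% names(res$submodel$reactions))
  expect_true("BC" %in% names(res$submodel$reactions))
})

test_that("growing the high tier never shrinks the included set", {
  m <- make_toy_network()
  base <- stats::setNames(rep("medium", length(m$reactions)),
                          names(m$reactions))
  base["biomass"] <- "high"
  r1 <- corda_extract(m, base)
  t2 <- base
  t2["OXPHOS"] <- "high"
  r2 <- corda_extract(m, t2)
  expect_true(all(names(r1$submodel$reactions) %in%
                    names(r2$submodel$reactions)))
})

test_that("extraction inputs are validated", {
  m <- unique_support_model()
  expect_error(corda_extract(m, c(EX_A = "medium")), "cover every")
  allmed <- stats::setNames(rep("medium", 4), names(m$reactions))
  expect_error(corda_extract(m, allmed), "high tier is empty")
  expect_error(extraction_params(mc_cost = 5, nc_cost = 2), "nc_cost > mc_cost")
  st <- model_stats(m)
  expect_equal(unname(st), c(3, 4, 2))
})
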