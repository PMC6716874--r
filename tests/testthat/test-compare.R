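mk_iv <- function(ids, vmin, vmax) {
  data.frame(reaction = ids, vmin = vmin, vmax = vmax,
             stringsAsFactors = FALSE)
}

test_that("status classification handles the canonical cases", {
  n <- mk_iv(c("r1", "r2", "r3", "r4"), c(2, 0, 0, 0), c(3, 5, 0, 1))
  p <- mk_iv(c("r1", "r2", "r3", "r5"), c(0, 0, 0, 2), c(1, 5, 0, 4))
  st <- classify_status(n, p)
  s <- stats::setNames(st$status, st$reaction)
  expect_identical(s[["r1"]], "A")  # disjoint, naive above
  expect_identical(s[["r2"]], "E")  # identical intervals
  expect_identical(s[["r3"]], "F")  # inactive in both
  expect_identical(s[["r4"]], "C")  # absent from primed -> (0,0), naive above
  expect_identical(s[["r5"]], "B")  # absent from naive -> (0,0), primed above
})

test_that("the classifier matches a decision-table oracle on an exhaustive grid", {
  vals <- c(0, 1e-9, 0.5, 1, 1.0000005, 2)  # includes ties and sub-tol gaps
  cases <- expand.grid(a_n = vals, b_n = vals, a_p = vals, b_p = vals)
  cases <- cases[cases$a_n <= cases$b_n & cases$a_p <= cases$b_p, ]
  got <- mapply(gemdiff:::classify_one, cases$a_n, cases$b_n, cases$a_p,
                cases$b_p)
  want <- mapply(status_oracle, cases$a_n, cases$b_n, cases$a_p, cases$b_p)
  expect_identical(unname(got), unname(want))
  # antisymmetry: swapping the models maps A<->B, C<->D, fixes E and F
  swapped <- mapply(gemdiff:::classify_one, cases$a_p, cases$b_p, cases$a_n,
                    cases$b_n)
  map <- c(A = "B", B = "A", C = "D", D = "C", E = "E", F = "F")
  expect_identical(unname(map[got]), unname(swapped))
  # every reaction receives exactly one status
  expect_true(all(got %in% c("A", "B", "C", "D", "E", "F")))
})

test_that("negative and signed intervals classify consistently", {
  vals <- c(-2, -1, 0, 1, 2)
  cases <- expand.grid(a_n = vals, b_n = vals, a_p = vals, b_p = vals)
  cases <- cases[cases$a_n <= cases$b_n & cases$a_p <= cases$b_p, ]
  got <- mapply(gemdiff:::classify_one, cases$a_n, cases$b_n, cases$a_p,
                cases$b_p)
  want <- mapply(status_oracle, cases$a_n, cases$b_n, cases$a_p, cases$b_p)
  expect_identical(unname(got), unname(want))
})

test_that("condition models silence genes through full GPR evaluation", {
  m <- metabolic_model(
    metabolites = "A",
    reactions = list(
      list(id = "r_or", stoich = c(A = 1), lb = 0, ub = 10,
           gpr = "g1 or g2"),
      list(id = "r_and", stoich = c(A = -1), lb = 0, ub = 10,
           gpr = "g1 and g2"),
      list(id = "r_free", stoich = c(A = -1), lb = 0, ub = 10)))
  # g1 strongly down in naive, g2 unchanged
  de <- make_de(c("g1", "g2"), p = c(1e-8, 0.9), logfc = c(-2, 0))
  mn <- derive_condition_model(m, de, "naive", logfc_threshold = 1)
  expect_equal(mn$reactions$r_or$ub, 10)    # OR redundancy keeps it
  expect_equal(mn$reactions$r_and$ub, 0)    # complex loses a subunit
  expect_equal(mn$reactions$r_free$ub, 10)  # no GPR, untouched
  expect_identical(attr(mn, "silenced_genes"), "g1")
  expect_identical(attr(mn, "zeroed_reactions"), "r_and")
  # any-association mode removes OR-redundant reactions too
  ma <- derive_condition_model(m, de, "naive", 1, mode = "any")
  expect_equal(ma$reactions$r_or$ub, 0)
  # primed model unaffected (g1 is down in naive, not primed)
  mp <- derive_condition_model(m, de, "primed", 1)
  expect_length(attr(mp, "silenced_genes"), 0)
  expect_message(derive_condition_model(m, de, "primed", 1), "no genes")
})

test_that("tightening the removal threshold never removes fewer genes", {
  set.seed(61)
  genes <- sprintf("g%03d", 1:100)
  de <- make_de(genes, p = runif(100, 0, 0.1),
                logfc = rnorm(100, 0, 1.2))
  m <- metabolic_model(
    metabolites = "A",
    reactions = lapply(seq_along(genes), function(i) {
      list(id = paste0("r", i), stoich = c(A = (-1)^i), lb = 0, ub = 10,
           gpr = genes[i])
    }))
  removed <- sapply(c(1.00, 0.85, 0.70), function(thr) {
    length(attr(derive_condition_model(m, de, "naive", thr), "silenced_genes"))
  })
  expect_true(all(diff(removed) >= 0))
})

test_that("consensus requires agreement at every threshold", {
  mk_call <- function(statuses) {
    out <- data.frame(reaction = names(statuses), status = unname(statuses),
                      stringsAsFactors = FALSE)
    class(out) <- c("status_calls", "data.frame")
    out
  }
  c1 <- mk_call(c(r1 = "A", r2 = "A", r3 = "B", r4 = "D"))
  c2 <- mk_call(c(r1 = "A", r2 = "A", r3 = "B", r4 = "B"))
  c3 <- mk_call(c(r1 = "C", r2 = "E", r3 = "D", r4 = "B"))
  cons <- consensus_status(list(c1, c2, c3))
  expect_identical(cons$up_naive, "r1")              # A, A, C -> robust
  expect_false("r2" %in% cons$up_naive)              # A, A, E -> not robust
  expect_setequal(cons$up_primed, c("r3", "r4"))     # B,B,D and D,B,B
  bad <- mk_call(c(rX = "A"))
  expect_error(consensus_status(list(c1, bad)), "different reaction universes")
})

test_that("gene sets are recovered from reaction GPRs", {
  m <- make_toy_network()
  expect_setequal(genes_from_reactions(m, toy_trp_reactions()),
                  toy_trp_genes())
  expect_setequal(genes_from_reactions(m, "GLY"), c("g_gly1", "g_gly2"))
  expect_identical(genes_from_reactions(m, "EX_glc"), character(0))
  expect_error(genes_from_reactions(m, "nope"), "unknown reaction")
})
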