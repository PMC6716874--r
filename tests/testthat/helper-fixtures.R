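# Small fixture models and random-structure generators shared across tests.

# linear chain: EX_A (uptake <= 10) -> A, A -> B, B -> C, C -> (sink),
# objective = sink; unique optimum 10, yield 1.
chain_model <- function() {
  metabolic_model(
    metabolites = c("A", "B", "C"),
    reactions = list(
      list(id = "EX_A", stoich = c(A = -1), lb = -10, ub = 0),
      list(id = "AB", stoich = c(A = -1, B = 1), lb = 0, ub = 1000,
           gpr = "g1"),
      list(id = "BC", stoich = c(B = -1, C = 1), lb = 0, ub = 1000,
           gpr = "g2"),
      list(id = "SINK_C", stoich = c(C = -1), lb = 0, ub = 1000)),
    objective_id = "SINK_C")
}

# parallel 2-path motif: source -> M via P1 (ub 10) or P2 (ub 10),
# M -> out via OUT (ub 15). Classic hand-enumerable FVA polytope.
two_path_model <- function(ub1 = 10, ub2 = 10, ub_out = 15) {
  metabolic_model(
    metabolites = c("S", "M"),
    reactions = list(
      list(id = "EX_S", stoich = c(S = -1), lb = -1000, ub = 0),
      list(id = "P1", stoich = c(S = -1, M = 1), lb = 0, ub = ub1),
      list(id = "P2", stoich = c(S = -1, M = 1), lb = 0, ub = ub2),
      list(id = "OUT", stoich = c(M = -1), lb = 0, ub = ub_out)),
    objective_id = "OUT")
}

# random well-formed GPR tree over the given genes; returns the tree in
# the package's own representation, built independently of parse_gpr
random_gpr_tree <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    return(sample(genes, 1))
  }
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  list(op = op, args = lapply(seq_len(k), function(i) {
    random_gpr_tree(genes, depth - 1)
  }))
}

# serialize a tree with full parenthesization (no precedence reliance)
serialize_tree_explicit <- function(tree) {
  if (is.character(tree)) return(tree)
  inner <- vapply(tree$args, serialize_tree_explicit, character(1))
  paste0("(", paste(inner, collapse = paste0(" ", tree$op, " ")), ")")
}

# independent recursive evaluators, coded in the tests
tree_eval_bool <- function(tree, on) {
  if (is.character(tree)) return(isTRUE(on[[tree]]))
  vals <- vapply(tree$args, tree_eval_bool, logical(1), on = on)
  if (tree$op == "and") all(vals) else any(vals)
}
tree_eval_score <- function(tree, expr) {
  if (is.character(tree)) {
    return(if (tree %in% names(expr)) expr[[tree]] else 0)
  }
  vals <- vapply(tree$args, tree_eval_score, numeric(1), expr = expr)
  if (tree$op == "and") min(vals) else max(vals)
}

# build a de_result directly from vectors (bypasses the expression stage)
make_de <- function(genes, p, logfc = rep(0, length(genes))) {
  out <- data.frame(gene = genes, logFC = logfc, p_value = p,
                    adj_p = stats::p.adjust(p, method = "BH"),
                    zero_variance = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}
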