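# Independent oracles used by the dual-route checks.

# FVA via an independently implemented LP route: the model is serialized
# to JSON and solved with scipy.optimize.linprog (HiGHS) through
# the system python. Returns data.frame(reaction, vmin, vmax) or NULL if
# python/scipy is unavailable (callers assert availability explicitly).
scipy_fva <- function(model, objective_fraction = 0.9) {
  mj <- tempfile(fileext = ".json")
  out <- tempfile(fileext = ".json")
  write_model(model, mj, format = "json")
  script <- sprintf('
import json, sys
import numpy as np
from scipy.optimize import linprog
mod = json.load(open("%s"))
mets = [m["id"] for m in mod["metabolites"]]
rxns = mod["reactions"]
mI = {m: i for i, m in enumerate(mets)}
n = len(rxns)
S = np.zeros((len(mets), n)); lb = np.zeros(n); ub = np.zeros(n)
ids = [r["id"] for r in rxns]
for j, r in enumerate(rxns):
    lb[j], ub[j] = r["lb"], r["ub"]
    for met, co in r["stoich"].items():
        S[mI[met], j] = co
bounds = list(zip(lb, ub))
iobj = ids.index(mod["objective"])
c = np.zeros(n); c[iobj] = -1.0
res = linprog(c, A_eq=S, b_eq=np.zeros(len(mets)), bounds=bounds, method="highs")
assert res.status == 0, res.message
opt = -res.fun
frac = %.17g
A_ub = np.zeros((1, n)); A_ub[0, iobj] = -1.0
b_ub = np.array([-frac * opt])
iv = {}
for j in range(n):
    c = np.zeros(n)
    c[j] = 1.0
    lo = linprog(c, A_ub=A_ub, b_ub=b_ub, A_eq=S, b_eq=np.zeros(len(mets)),
                 bounds=bounds, method="highs")
    c[j] = -1.0
    hi = linprog(c, A_ub=A_ub, b_ub=b_ub, A_eq=S, b_eq=np.zeros(len(mets)),
                 bounds=bounds, method="highs")
    assert lo.status == 0 and hi.status == 0
    iv[ids[j]] = [lo.fun, -hi.fun]
json.dump({"optimum": opt, "intervals": iv}, open("%s", "w"))
', mj, objective_fraction, out)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  if (!file.exists(out)) {
    stop("scipy oracle failed: ", paste(status, collapse = "\n"))
  }
  res <- jsonlite::read_json(out)
  iv <- res$intervals
  data.frame(reaction = names(iv),
             vmin = vapply(iv, function(v) v[[1]], numeric(1)),
             vmax = vapply(iv, function(v) v[[2]], numeric(1)),
             optimum = res$optimum,
             stringsAsFactors = FALSE)
}

# Benjamini-Hochberg step-up, coded from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# six-status decision table, transcribed independently from the interval
# semantics: F inactive both; A/B disjoint dominance; C/D componentwise
# shift with at least one strict; E otherwise
status_oracle <- function(a_n, b_n, a_p, b_p, tol = 1e-6) {
  near0 <- function(v) abs(v) < tol
  if (near0(a_n) && near0(b_n) && near0(a_p) && near0(b_p)) return("F")
  if (a_n - b_p > tol) return("A")
  if (a_p - b_n > tol) return("B")
  ge_n <- (a_n - a_p >= -tol) && (b_n - b_p >= -tol)
  strict_n <- (a_n - a_p > tol) || (b_n - b_p > tol)
  if (ge_n && strict_n) return("C")
  ge_p <- (a_p - a_n >= -tol) && (b_p - b_n >= -tol)
  strict_p <- (a_p - a_n > tol) || (b_p - b_n > tol)
  if (ge_p && strict_p) return("D")
  "E"
}

# exact hypergeometric upper tail by enumerating all draws (universe <= 30)
hyper_tail_enum <- function(overlap, set_size, universe_size, query_size) {
  total <- choose(universe_size, query_size)
  mass <- 0
  for (j in seq(overlap, min(set_size, query_size))) {
    mass <- mass + choose(set_size, j) *
      choose(universe_size - set_size, query_size - j)
  }
  mass / total
}
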