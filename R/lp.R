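# Linear programming layer.
#
# All flux computations reduce to LPs of the form
#   optimize  c'v   s.t.  S v = 0,  lb <= v <= ub,  A v <= b (optional).
# No LP package is assumed: the solver below is a dense bounded-variable
# two-phase simplex with Bland's anti-cycling rule, which is exact and
# robust at the problem sizes this package's models produce (tens to a
# few hundred variables). Basic solutions are refactorized from scratch
# every iteration, trading speed for numerical stability.

lp_problem <- function(S, lb, ub) {
  S <- as.matrix(S)
  n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)),
            all(is.finite(ub)), all(lb <= ub))
  list(S = S, lb = lb, ub = ub, n = n)
}

# obj: length-n objective over v; extra_A/extra_b: optional rows A v <= b.
# Returns list(status, objective, flux).
solve_lp <- function(prob, obj, maximize = TRUE,
                     extra_A = NULL, extra_b = NULL) {
  n <- prob$n
  A <- prob$S
  b <- rep(0, nrow(A))
  lb <- prob$lb
  ub <- prob$ub
  cc <- obj
  if (!is.null(extra_A)) {
    extra_A <- matrix(extra_A, ncol = n)
    ns <- nrow(extra_A)
    # slack per inequality row: A v + s = b, s >= 0
    A <- rbind(cbind(A, matrix(0, nrow(A), ns)),
               cbind(extra_A, diag(ns)))
    b <- c(b, as.numeric(extra_b))
    lb <- c(lb, rep(0, ns))
    ub <- c(ub, rep(Inf, ns))
    cc <- c(cc, rep(0, ns))
  }
  res <- simplex_bounded(cc, A, b, lb, ub, maximize = maximize)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, flux = NULL))
  }
  v <- res$x[seq_len(n)]
  list(status = "optimal", objective = sum(obj * v), flux = v)
}

# Two-phase bounded-variable simplex, Bland's rule.
#   minimize (or maximize) c'x  s.t.  A x = b,  l <= x <= u
# l/u may be +-Inf. Returns list(status, x, objective).
simplex_bounded <- function(cc, A, b, l, u, maximize = FALSE,
                            tol = 1e-9, maxiter = 20000L) {
  if (maximize) cc <- -cc
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cc) == n, length(l) == n, length(u) == n,
            all(l <= u))

  # initial nonbasic values at a finite bound (0 for free variables)
  x0 <- ifelse(is.finite(l), l, ifelse(is.finite(u), u, 0))
  r <- b - as.numeric(A %*% x0)
  sg <- ifelse(r >= 0, 1, -1)
  # artificials: columns sg_i * e_i, start at |r_i| >= 0
  Aext <- cbind(A, diag(sg, nrow = m))
  lext <- c(l, rep(0, m))
  uext <- c(u, rep(Inf, m))
  art <- n + seq_len(m)

  st <- list(A = Aext, b = b, l = lext, u = uext,
             basis = art,
             x = c(x0, abs(r)),
             at_upper = ifelse(!is.finite(l) & is.finite(u), TRUE, FALSE))
  st$at_upper <- c(st$at_upper, rep(FALSE, m))

  # phase I: drive artificials to zero
  c1 <- c(rep(0, n), rep(1, m))
  st <- simplex_iterate(st, c1, tol, maxiter)
  if (st$status == "iteration_limit") return(list(status = st$status))
  if (sum(st$x[art]) > 1e-7) return(list(status = "infeasible"))
  # fix artificials at zero for phase II
  st$u[art] <- 0
  st$x[art] <- 0

  c2 <- c(cc, rep(0, m))
  st <- simplex_iterate(st, c2, tol, maxiter)
  if (st$status != "optimal") return(list(status = st$status))
  obj <- sum(cc * st$x[seq_len(n)])
  list(status = "optimal", x = st$x[seq_len(n)],
       objective = if (maximize) -obj else obj)
}

simplex_iterate <- function(st, cc, tol, maxiter) {
  A <- st$A; b <- st$b; l <- st$l; u <- st$u
  m <- nrow(A); n <- ncol(A)
  basis <- st$basis
  x <- st$x
  at_upper <- st$at_upper

  for (iter in seq_len(maxiter)) {
    nonbasic <- setdiff(seq_len(n), basis)
    B <- A[, basis, drop = FALSE]
    # refactorize: recompute basic values from the nonbasic ones
    xN <- x[nonbasic]
    rhs <- b - as.numeric(A[, nonbasic, drop = FALSE] %*% xN)
    xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
    if (is.null(xB)) return(modifyList(st, list(status = "singular_basis")))
    x[basis] <- xB

    y <- tryCatch(solve(t(B), cc[basis]), error = function(e) NULL)
    if (is.null(y)) return(modifyList(st, list(status = "singular_basis")))
    d <- cc[nonbasic] - as.numeric(t(A[, nonbasic, drop = FALSE]) %*% y)

    up <- at_upper[nonbasic]
    eligible <- (!up & d < -tol & x[nonbasic] < u[nonbasic]) |
                (up & d > tol & x[nonbasic] > l[nonbasic])
    if (!any(eligible)) {
      return(modifyList(st, list(status = "optimal", basis = basis, x = x,
                                 at_upper = at_upper)))
    }
    j <- min(nonbasic[eligible])  # Bland: smallest eligible index enters
    dir <- if (at_upper[j]) -1 else 1
    w <- solve(B, A[, j])

    # ratio test: basic variables hitting a bound, and the entering
    # variable's own opposite bound
    ratios <- rep(Inf, m)
    for (i in seq_len(m)) {
      delta <- dir * w[i]
      if (delta > tol && is.finite(l[basis[i]])) {
        ratios[i] <- (x[basis[i]] - l[basis[i]]) / delta
      } else if (delta < -tol && is.finite(u[basis[i]])) {
        ratios[i] <- (u[basis[i]] - x[basis[i]]) / (-delta)
      }
    }
    t_bound <- if (is.finite(u[j]) && is.finite(l[j])) u[j] - l[j] else Inf
    t_star <- min(t_bound, ratios)
    if (!is.finite(t_star)) return(modifyList(st, list(status = "unbounded")))
    t_star <- max(t_star, 0)

    x[j] <- x[j] + dir * t_star
    x[basis] <- x[basis] - dir * t_star * w
    if (t_bound <= min(ratios)) {
      # entering variable travels to its opposite bound; basis unchanged
      at_upper[j] <- !at_upper[j]
      x[j] <- if (at_upper[j]) u[j] else l[j]
    } else {
      # among ties, leave the variable with the smallest index (Bland)
      cand <- which(ratios <= t_star + tol)
      leave <- cand[which.min(basis[cand])]
      lv <- basis[leave]
      at_upper[lv] <- dir * w[leave] < 0
      x[lv] <- if (at_upper[lv]) u[lv] else l[lv]
      basis[leave] <- j
      at_upper[j] <- FALSE
    }
  }
  modifyList(st, list(status = "iteration_limit", basis = basis, x = x,
                      at_upper = at_upper))
}

model_lp <- function(model) {
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  prob <- lp_problem(S, lb, ub)
  prob$rids <- reaction_ids(model)
  prob
}
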