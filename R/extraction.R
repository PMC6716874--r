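#' Parameters for context-specific extraction
#'
#' @param flux_threshold minimum flux each tested (core) reaction must
#'   support (mmol/gDW/h, default 1.0); clipped per target to its maximum
#'   feasible flux so low-capacity reactions are not declared
#'   unsupportable by scaling alone.
#' @param mc_cost,nc_cost per-unit-flux penalties on medium- and
#'   negative-confidence candidates in the dependency LPs (defaults 1 and
#'   100; \code{nc_cost > mc_cost} so low-evidence reactions are used
#'   only when nothing cheaper closes the balance).
#' @param nc_promotion_min minimum number of high-confidence reactions a
#'   negative candidate must support to be promoted into the submodel
#'   (default 2).
#' @param tol numeric tolerance for "carries flux" (default 1e-6).
#' @return An object of class \code{extraction_params}.
#' @export
extraction_params <- function(flux_threshold = 1.0, mc_cost = 1.0,
                              nc_cost = 100.0, nc_promotion_min = 2,
                              tol = 1e-6) {
  stopifnot(flux_threshold > 0, mc_cost > 0, nc_cost > 0,
            nc_promotion_min >= 1, tol > 0, nc_cost > mc_cost)
  structure(list(flux_threshold = flux_threshold, mc_cost = mc_cost,
                 nc_cost = nc_cost, nc_promotion_min = nc_promotion_min,
                 tol = tol),
            class = "extraction_params")
}

#' Dependency assessment of a target reaction
#'
#' Which penalized candidate reactions does a target reaction need to
#' carry flux? Solves \code{min sum(cost_i v_i)} over the candidates
#' subject to steady state, bounds, and \code{v_target >= flux_threshold}
#' (the threshold is clipped to the target's maximum feasible flux, found
#' by a pre-solve maximization). The model must be irreversible (see
#' [split_reversible()]).
#'
#' @param model_split an irreversible \code{metabolic_model}.
#' @param target reaction id to force on.
#' @param candidate_costs named nonnegative numeric vector, candidate
#'   reaction id -> cost; non-candidates cost 0.
#' @param flux_threshold minimum target flux before clipping.
#' @param tol flux tolerance.
#' @param disabled reaction ids forced to zero flux during the
#'   assessment; used to shut the reverse half of a split reversible
#'   target, whose futile two-cycle would otherwise satisfy the flux
#'   demand at zero net conversion.
#' @return Character vector of candidate ids with flux \code{> tol} at
#'   the optimum, or \code{NULL} if the target cannot carry flux at all
#'   (unsupportable; reported, not an error).
#' @export
dependency_assess <- function(model_split, target, candidate_costs,
                              flux_threshold = 1.0, tol = 1e-6,
                              disabled = character(0)) {
  for (d in intersect(disabled, names(model_split$reactions))) {
    model_split$reactions[[d]]$lb <- 0
    model_split$reactions[[d]]$ub <- 0
  }
  prob <- model_lp(model_split)
  if (!target %in% prob$rids) stop("unknown target reaction: ", target,
                                   call. = FALSE)
  stopifnot(all(candidate_costs >= 0))
  tsel <- as.numeric(prob$rids == target)
  pre <- solve_lp(prob, tsel, maximize = TRUE)
  if (pre$status != "optimal" || pre$objective < tol) return(NULL)
  thr <- min(flux_threshold, pre$objective)
  candidate_costs <- candidate_costs[names(candidate_costs) %in% prob$rids]
  cost <- stats::setNames(rep(0, length(prob$rids)), prob$rids)
  cost[names(candidate_costs)] <- candidate_costs
  res <- solve_lp(prob, as.numeric(cost), maximize = FALSE,
                  extra_A = matrix(-tsel, nrow = 1), extra_b = -thr)
  if (res$status != "optimal") return(NULL)
  v <- stats::setNames(res$flux, prob$rids)
  cand <- names(candidate_costs)[candidate_costs > 0]
  if (is.null(cand)) return(character(0))
  cand[v[cand] > tol]
}

#' Extract a context-specific model from confidence tiers
#'
#' Cost-penalized dependency assessment in three passes: (1) each
#' high-confidence reaction is forced on while medium and negative
#' candidates are penalized (\code{mc_cost}/\code{nc_cost}); candidates
#' used at the optimum are tallied. (2) Medium reactions that supported
#' any core reaction are promoted, as are negative reactions supporting
#' at least \code{nc_promotion_min} of them. (3) Each promoted medium
#' reaction is re-assessed against the remaining negative reactions (the
#' non-promoted mediums removed), promoting any further support. The
#' submodel is the high tier plus promotions. A rescue sweep then
#' re-assesses any high reaction left blocked, pulling in candidates that
#' are essential for it (e.g. a negative reaction that is the unique
#' support of one high reaction comes in regardless of its tally).
#' Finally the submodel is pruned of reactions that cannot carry
#' \code{|flux| >= tol} (repeated flux-consistency sweeps until stable).
#' High-tier reactions are never pruned: one going blocked is an
#' extraction failure. High reactions that cannot carry flux even in the
#' generic model are reported as \code{unsupportable} and excluded
#' rather than failing the extraction.
#'
#' @param model a \code{metabolic_model}.
#' @param tiers named character vector over all reactions
#'   (\code{"high"}/\code{"medium"}/\code{"negative"}), e.g. from
#'   [assign_tiers()].
#' @param params an \code{extraction_params}.
#' @return An object of class \code{extraction_result}: list with
#'   \code{submodel}, \code{included} (ids by tier of origin),
#'   \code{dependency_tally}, \code{unsupportable} (high reactions that
#'   could never carry flux in the generic model).
#' @export
corda_extract <- function(model, tiers, params = extraction_params()) {
  stopifnot(inherits(params, "extraction_params"))
  rids <- reaction_ids(model)
  if (!all(rids %in% names(tiers))) {
    stop("tiers must cover every model reaction", call. = FALSE)
  }
  tiers <- tiers[rids]
  if (!any(tiers == "high")) stop("high tier is empty", call. = FALSE)

  ms <- split_reversible(model)
  smap <- attr(ms, "split_map")
  stier <- stats::setNames(tiers[smap], names(smap))
  sids <- reaction_ids(ms)

  high_s <- sids[stier[sids] == "high"]
  med_s <- sids[stier[sids] == "medium"]
  neg_s <- sids[stier[sids] == "negative"]

  costs1 <- c(stats::setNames(rep(params$mc_cost, length(med_s)), med_s),
              stats::setNames(rep(params$nc_cost, length(neg_s)), neg_s))

  partner_of <- function(id, map) {
    setdiff(names(map)[map == map[[id]]], id)
  }

  tally <- stats::setNames(integer(length(sids)), sids)
  med_support <- character(0)
  unsupportable <- character(0)
  for (h in high_s) {
    sup <- dependency_assess(ms, h, costs1, params$flux_threshold, params$tol,
                             disabled = partner_of(h, smap))
    if (is.null(sup)) {
      unsupportable <- c(unsupportable, h)
      next
    }
    tally[sup] <- tally[sup] + 1L
    med_support <- union(med_support, intersect(sup, med_s))
  }

  neg_promoted <- names(tally)[tally >= params$nc_promotion_min &
                                 names(tally) %in% neg_s]
  neg_rest <- setdiff(neg_s, neg_promoted)

  # pass 3: promoted mediums re-checked with non-promoted mediums removed
  if (length(med_support) && length(neg_rest)) {
    keep3 <- c(high_s, med_support, neg_promoted, neg_rest)
    keep3_orig <- unique(unname(smap[keep3]))
    ms3 <- split_reversible(subset_model(model, keep3_orig))
    costs3 <- stats::setNames(rep(params$nc_cost, length(neg_rest)), neg_rest)
    costs3 <- costs3[names(costs3) %in% reaction_ids(ms3)]
    smap3 <- attr(ms3, "split_map")
    for (m in med_support) {
      if (!m %in% reaction_ids(ms3)) next
      sup <- dependency_assess(ms3, m, costs3, params$flux_threshold,
                               params$tol,
                               disabled = partner_of(m, smap3))
      if (is.null(sup)) next
      tally[sup] <- tally[sup] + 1L
      neg_promoted <- union(neg_promoted, sup)
    }
  }

  included_s <- c(high_s, med_support, neg_promoted)
  included_orig <- unique(unname(smap[included_s]))
  high_orig <- unique(unname(smap[high_s]))
  unsupportable_orig <- unique(unname(smap[unsupportable]))
  # high reactions infeasible even in the generic model can never be
  # rescued; they are reported, not fatal
  rescuable_high <- setdiff(high_orig, unsupportable_orig)
  included_orig <- setdiff(included_orig, unsupportable_orig)

  # rescue pass: an excluded candidate that is essential for a core
  # reaction (e.g. the unique negative-confidence support of a high
  # reaction) must come in regardless of its tally, or the core reaction
  # would be blocked
  repeat {
    sub <- subset_model(model, included_orig)
    blocked_high <- intersect(blocked_reactions(sub, tol = params$tol),
                              rescuable_high)
    if (!length(blocked_high)) break
    leftovers <- setdiff(rids, included_orig)
    ms_r <- split_reversible(subset_model(model,
                                          union(included_orig, leftovers)))
    cost_r <- stats::setNames(
      ifelse(tiers[leftovers] == "negative", params$nc_cost, params$mc_cost),
      leftovers)
    cost_rs <- stats::setNames(cost_r[smap[reaction_ids(ms_r)]],
                               reaction_ids(ms_r))
    cost_rs <- cost_rs[!is.na(cost_rs)]
    progress <- FALSE
    for (h in blocked_high) {
      hs <- intersect(reaction_ids(ms_r), c(h, paste0(h, "_f"), paste0(h, "_b")))
      smap_r <- attr(ms_r, "split_map")
      for (ht in hs) {
        sup <- dependency_assess(ms_r, ht, cost_rs, params$flux_threshold,
                                 params$tol,
                                 disabled = partner_of(ht, smap_r))
        if (is.null(sup) || !length(sup)) next
        sup_orig <- setdiff(unique(unname(smap[sup])), included_orig)
        if (length(sup_orig)) {
          tally[sup] <- tally[sup] + 1L
          included_orig <- union(included_orig, sup_orig)
          progress <- TRUE
        }
      }
    }
    if (!progress) {
      stop("extraction failure: high-confidence reaction(s) blocked in ",
           "the extracted model: ", paste(blocked_high, collapse = ", "),
           call. = FALSE)
    }
  }

  # prune flux-inconsistent reactions until stable
  repeat {
    blocked <- blocked_reactions(sub, tol = params$tol)
    if (!length(blocked)) break
    bad_high <- intersect(blocked, rescuable_high)
    if (length(bad_high)) {
      stop("extraction failure: high-confidence reaction(s) blocked in ",
           "the extracted model: ", paste(bad_high, collapse = ", "),
           call. = FALSE)
    }
    sub <- subset_model(sub, setdiff(reaction_ids(sub), blocked))
  }

  kept <- reaction_ids(sub)
  tally_orig <- tapply(tally, smap[names(tally)], sum)
  structure(list(
    submodel = sub,
    included = list(high = intersect(kept, high_orig),
                    medium = kept[tiers[kept] == "medium"],
                    negative = kept[tiers[kept] == "negative"]),
    dependency_tally = tally_orig[tally_orig > 0],
    unsupportable = unsupportable_orig),
    class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  st <- model_stats(x$submodel)
  cat(sprintf("extraction_result: submodel with %d reactions (%d high, %d medium, %d negative origin), %d metabolites, %d genes\n",
              st[["n_reactions"]], length(x$included$high),
              length(x$included$medium), length(x$included$negative),
              st[["n_metabolites"]], st[["n_genes"]]))
  if (length(x$unsupportable)) {
    cat("unsupportable high-tier reactions:",
        paste(x$unsupportable, collapse = ", "), "\n")
  }
  invisible(x)
}

# Reactions that cannot carry |flux| >= tol in any feasible steady state
# (no objective constraint).
blocked_reactions <- function(model, tol = 1e-6) {
  prob <- model_lp(model)
  out <- character(0)
  for (k in seq_along(prob$rids)) {
    obj <- as.numeric(seq_along(prob$rids) == k)
    hi <- solve_lp(prob, obj, maximize = TRUE)
    if (hi$status == "optimal" && hi$objective >= tol) next
    lo <- solve_lp(prob, obj, maximize = FALSE)
    if (lo$status == "optimal" && lo$objective <= -tol) next
    out <- c(out, prob$rids[k])
  }
  out
}

#' Write an extraction report as TSV
#'
#' @param result an \code{extraction_result}.
#' @param tiers the tier vector used for extraction.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_extraction_report <- function(result, tiers, path) {
  kept <- reaction_ids(result$submodel)
  df <- data.frame(reaction = names(tiers),
                   origin_tier = unname(tiers),
                   included = names(tiers) %in% kept,
                   tally = as.integer(result$dependency_tally[names(tiers)]),
                   stringsAsFactors = FALSE)
  df$tally[is.na(df$tally)] <- 0L
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
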