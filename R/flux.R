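#' Flux balance analysis (FBA)
#'
#' Maximizes the model's objective reaction subject to steady-state mass
#' balance (\code{S v = 0}) and flux bounds.
#'
#' @param model a \code{metabolic_model} with a non-empty
#'   \code{objective_id}.
#' @return List with \code{objective} (optimal value) and \code{flux}
#'   (named optimal flux vector). Errors with an infeasibility report if
#'   the constraints admit no solution.
#' @export
fba <- function(model) {
  if (!nzchar(model$objective_id)) {
    stop("model has no objective reaction", call. = FALSE)
  }
  prob <- model_lp(model)
  obj <- as.numeric(prob$rids == model$objective_id)
  res <- solve_lp(prob, obj, maximize = TRUE)
  if (res$status != "optimal") {
    stop("FBA infeasible: constraints admit no steady-state flux ",
         "distribution within bounds", call. = FALSE)
  }
  list(objective = res$objective,
       flux = stats::setNames(res$flux, prob$rids))
}

#' Flux variability analysis (FVA)
#'
#' For each reaction, minimizes and maximizes its flux subject to steady
#' state, bounds, and an objective floor
#' \code{c'v >= objective_fraction * FBA optimum} (2N LPs).
#'
#' @param model a \code{metabolic_model} with an objective.
#' @param objective_fraction fraction of the FBA optimum the objective
#'   must retain (default 0.9). Use 0 for unconstrained variability.
#' @param reactions reaction ids to analyze (default: all).
#' @return data.frame \code{(reaction, vmin, vmax)} of class
#'   \code{flux_intervals}.
#' @export
fva <- function(model, objective_fraction = 0.9, reactions = NULL) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  opt <- fba(model)$objective
  prob <- model_lp(model)
  if (is.null(reactions)) reactions <- prob$rids
  unknown <- setdiff(reactions, prob$rids)
  if (length(unknown)) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cobj <- as.numeric(prob$rids == model$objective_id)
  floor_val <- objective_fraction * opt
  # c'v >= floor  <=>  -c'v <= -floor
  eA <- matrix(-cobj, nrow = 1)
  eb <- -floor_val
  vmin <- vmax <- numeric(length(reactions))
  for (k in seq_along(reactions)) {
    obj <- as.numeric(prob$rids == reactions[k])
    lo <- solve_lp(prob, obj, maximize = FALSE, extra_A = eA, extra_b = eb)
    hi <- solve_lp(prob, obj, maximize = TRUE, extra_A = eA, extra_b = eb)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA infeasible at objective fraction ", objective_fraction,
           call. = FALSE)
    }
    vmin[k] <- lo$objective
    vmax[k] <- hi$objective
  }
  out <- data.frame(reaction = reactions, vmin = vmin, vmax = vmax,
                    stringsAsFactors = FALSE)
  class(out) <- c("flux_intervals", "data.frame")
  attr(out, "objective_fraction") <- objective_fraction
  attr(out, "fba_optimum") <- opt
  out
}

#' Add a biomass reaction and set it as the objective
#'
#' The biomass pseudo-reaction consumes precursors in fixed stoichiometry
#' and serves as the growth objective.
#'
#' @param model a \code{metabolic_model}.
#' @param biomass named numeric vector, metabolite id -> coefficient
#'   (negative = consumed); at least one coefficient must be negative.
#' @param id reaction id for the new reaction (default \code{"biomass"}).
#' @param ub upper flux bound of the biomass reaction.
#' @return The model with the biomass reaction appended and
#'   \code{objective_id} set.
#' @export
add_biomass <- function(model, biomass, id = "biomass", ub = 1000) {
  stopifnot(is.numeric(biomass), !is.null(names(biomass)))
  if (!any(biomass < 0)) {
    stop("biomass must consume at least one species (negative coefficient)",
         call. = FALSE)
  }
  unknown <- setdiff(names(biomass), model$metabolites$id)
  if (length(unknown)) {
    stop("biomass references unknown metabolite(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (id %in% reaction_ids(model)) {
    stop("reaction id '", id, "' already exists", call. = FALSE)
  }
  rx <- model$reactions
  rx[[id]] <- list(id = id, name = "biomass objective", subsystem = "biomass",
                   lb = 0, ub = ub, stoich = biomass, gpr = NULL)
  metabolic_model(model$metabolites, rx, model$genes, objective_id = id)
}

#' Constrain exchange reactions to a growth medium
#'
#' Listed exchange reactions get the given uptake lower bound (\code{<= 0},
#' uptake is negative flux). Under the default \code{"closed"} policy,
#' unlisted exchanges get lower bound 0 (no uptake); under \code{"open"}
#' they are left untouched. Secretion (upper) bounds are never modified.
#'
#' @param model a \code{metabolic_model}.
#' @param medium named numeric vector, exchange reaction id -> uptake
#'   lower bound (all \code{<= 0}). May be empty.
#' @param default_policy \code{"closed"} or \code{"open"}.
#' @return The constrained model.
#' @export
apply_medium <- function(model, medium = numeric(0),
                         default_policy = c("closed", "open")) {
  default_policy <- match.arg(default_policy)
  ex <- exchange_reactions(model)
  if (length(medium)) {
    stopifnot(is.numeric(medium), !is.null(names(medium)))
    not_ex <- setdiff(names(medium), ex)
    if (length(not_ex)) {
      stop("not exchange reaction(s): ", paste(not_ex, collapse = ", "),
           call. = FALSE)
    }
    if (any(medium > 0)) {
      stop("medium uptake bounds must be <= 0 (uptake is negative flux): ",
           paste(names(medium)[medium > 0], collapse = ", "), call. = FALSE)
    }
  }
  rx <- model$reactions
  for (e in ex) {
    if (e %in% names(medium)) {
      rx[[e]]$lb <- medium[[e]]
    } else if (default_policy == "closed") {
      rx[[e]]$lb <- max(0, rx[[e]]$lb)
    }
  }
  metabolic_model(model$metabolites, rx, model$genes, model$objective_id)
}
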