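#' Derive a condition-specific model by silencing downregulated genes
#'
#' Genes significantly downregulated in the target condition (beyond the
#' fold-change and adjusted-p thresholds) are switched off; every
#' reaction whose GPR then evaluates to false (all other genes on) has
#' both bounds set to zero, i.e. is practically removed. Reactions with
#' an empty GPR are untouched. Under \code{mode = "any"}, any reaction
#' touching a silenced gene is zeroed instead of evaluating the GPR
#' (so OR-redundant isozyme reactions are removed too).
#'
#' @param model a \code{metabolic_model}.
#' @param de a \code{de_result} (logFC = naive - primed, log2).
#' @param downregulated_in \code{"naive"} or \code{"primed"}: the
#'   condition whose downregulated genes are removed (yielding that
#'   condition's model).
#' @param logfc_threshold absolute log2 fold-change cutoff (the reference
#'   analysis sweeps 1.00, 0.85, 0.70).
#' @param padj_threshold BH-adjusted p cutoff (default 0.05).
#' @param mode \code{"gpr"} (default, full GPR evaluation) or
#'   \code{"any"}.
#' @return The condition model; attribute \code{"silenced_genes"} lists
#'   the genes switched off, \code{"zeroed_reactions"} the reactions
#'   removed.
#' @export
derive_condition_model <- function(model, de,
                                   downregulated_in = c("naive", "primed"),
                                   logfc_threshold = 1.0,
                                   padj_threshold = 0.05,
                                   mode = c("gpr", "any")) {
  downregulated_in <- match.arg(downregulated_in)
  mode <- match.arg(mode)
  stopifnot(inherits(de, "de_result"), logfc_threshold > 0)
  sig <- de$adj_p < padj_threshold
  down <- if (downregulated_in == "naive") de$logFC <= -logfc_threshold
          else de$logFC >= logfc_threshold
  off_genes <- intersect(de$gene[sig & down], model$genes)
  rx <- model$reactions
  zeroed <- character(0)
  if (length(off_genes)) {
    gene_on <- stats::setNames(rep(FALSE, length(off_genes)), off_genes)
    for (id in names(rx)) {
      gpr <- rx[[id]]$gpr
      if (is.null(gpr)) next
      kill <- if (mode == "gpr") !eval_gpr(gpr, gene_on, default = TRUE)
              else any(gpr_genes(gpr) %in% off_genes)
      if (kill) {
        rx[[id]]$lb <- 0; rx[[id]]$ub <- 0
        zeroed <- c(zeroed, id)
      }
    }
  } else {
    message("no genes pass the removal thresholds; model unchanged")
  }
  out <- metabolic_model(model$metabolites, rx, model$genes,
                         model$objective_id)
  attr(out, "silenced_genes") <- off_genes
  attr(out, "zeroed_reactions") <- zeroed
  out
}

#' Classify differential flux status between two condition models
#'
#' Compares the FVA interval of each reaction between the naive model
#' (\code{N = (a_n, b_n)}) and the primed model (\code{P = (a_p, b_p)}).
#' Statuses: \code{F} inactive in both (all endpoints within \code{tol}
#' of 0); \code{A} naive interval entirely above primed; \code{B} primed
#' entirely above naive; \code{C} naive shifted up (both endpoints at
#' least matching, one strictly above); \code{D} the symmetric
#' primed-shifted-up case; \code{E} otherwise (unchanged/overlapping).
#' \code{A}/\code{C} mark capacity up in naive, \code{B}/\code{D} up in
#' primed. A reaction absent from one model is treated as \code{(0, 0)}
#' there (removal is bound-zeroing, so this is exact).
#'
#' @param naive,primed \code{flux_intervals} data.frames
#'   (\code{reaction, vmin, vmax}).
#' @param tol comparison tolerance (default 1e-6).
#' @return data.frame of class \code{status_calls}: \code{reaction},
#'   \code{status}, plus the four endpoints.
#' @export
classify_status <- function(naive, primed, tol = 1e-6) {
  univ <- union(naive$reaction, primed$reaction)
  iv <- function(fv, ids) {
    i <- match(ids, fv$reaction)
    cbind(vmin = ifelse(is.na(i), 0, fv$vmin[i]),
          vmax = ifelse(is.na(i), 0, fv$vmax[i]))
  }
  N <- iv(naive, univ); P <- iv(primed, univ)
  status <- vapply(seq_along(univ), function(k) {
    classify_one(N[k, 1], N[k, 2], P[k, 1], P[k, 2], tol)
  }, character(1))
  out <- data.frame(reaction = univ, status = status,
                    naive_vmin = N[, 1], naive_vmax = N[, 2],
                    primed_vmin = P[, 1], primed_vmax = P[, 2],
                    stringsAsFactors = FALSE)
  class(out) <- c("status_calls", "data.frame")
  out
}

classify_one <- function(a_n, b_n, a_p, b_p, tol = 1e-6) {
  if (abs(a_n) < tol && abs(b_n) < tol && abs(a_p) < tol && abs(b_p) < tol) {
    return("F")
  }
  if (a_n > b_p + tol) return("A")
  if (a_p > b_n + tol) return("B")
  if (a_n >= a_p - tol && b_n >= b_p - tol &&
      (a_n > a_p + tol || b_n > b_p + tol)) return("C")
  if (a_p >= a_n - tol && b_p >= b_n - tol &&
      (a_p > a_n + tol || b_p > b_n + tol)) return("D")
  "E"
}

#' Consensus differential-flux calls across removal thresholds
#'
#' To avoid sensitivity to the fold-change removal threshold, a reaction
#' is called robustly up in naive only when its status is in \{A, C\} at
#' every threshold, and robustly up in primed only when in \{B, D\} at
#' every threshold.
#'
#' @param calls list of \code{status_calls} (one per threshold) over the
#'   same reaction universe.
#' @return List with \code{up_naive} and \code{up_primed} reaction id
#'   vectors.
#' @export
consensus_status <- function(calls) {
  stopifnot(length(calls) >= 1)
  univ <- sort(calls[[1]]$reaction)
  for (cl in calls) {
    if (!identical(sort(cl$reaction), univ)) {
      stop("status calls are over different reaction universes", call. = FALSE)
    }
  }
  stat <- sapply(calls, function(cl) cl$status[match(univ, cl$reaction)])
  stat <- matrix(stat, nrow = length(univ))
  up_n <- apply(stat, 1, function(s) all(s %in% c("A", "C")))
  up_p <- apply(stat, 1, function(s) all(s %in% c("B", "D")))
  list(up_naive = univ[up_n], up_primed = univ[up_p])
}

#' Genes associated with a set of reactions
#'
#' @param model a \code{metabolic_model}.
#' @param reactions reaction ids.
#' @return Union of the gene ids in the reactions' GPRs.
#' @export
genes_from_reactions <- function(model, reactions) {
  unknown <- setdiff(reactions, reaction_ids(model))
  if (length(unknown)) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  g <- unique(unlist(lapply(model$reactions[reactions],
                            function(r) gpr_genes(r$gpr))))
  if (is.null(g)) character(0) else g
}
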