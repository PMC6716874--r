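#' Construct a genome-scale metabolic model
#'
#' The central container of the package: metabolites linked by
#' stoichiometric reactions with flux bounds (mmol/gDW/h) and boolean
#' gene-protein-reaction (GPR) associations.
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment} (missing columns are filled from \code{id}).
#' @param reactions list of reaction records; each a list with \code{id},
#'   \code{lb}, \code{ub}, \code{stoich} (named numeric, metabolite id ->
#'   coefficient, negative = consumed), and optionally \code{name},
#'   \code{subsystem}, \code{gpr} (rule text or parsed tree).
#' @param genes character vector of gene ids; if \code{NULL}, the union
#'   of genes referenced by the GPRs.
#' @param objective_id reaction id of the objective, or \code{""}.
#' @return An object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL,
                            objective_id = "") {
  if (is.character(metabolites)) {
    metabolites <- data.frame(id = metabolites, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(metabolites), "id" %in% names(metabolites))
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) {
    metabolites$compartment <- sub("^.*_", "", metabolites$id)
  }
  metabolites <- metabolites[, c("id", "name", "compartment")]

  reactions <- lapply(reactions, function(r) {
    stopifnot(!is.null(r$id), !is.null(r$stoich))
    r$name <- if (is.null(r$name)) r$id else r$name
    r$subsystem <- if (is.null(r$subsystem)) "" else r$subsystem
    r$lb <- as.numeric(if (is.null(r$lb)) -1000 else r$lb)
    r$ub <- as.numeric(if (is.null(r$ub)) 1000 else r$ub)
    r$stoich <- unlist(r$stoich)
    if (is.null(r$gpr)) r$gpr <- NULL
    else if (is.character(r$gpr)) r$gpr <- parse_gpr(r$gpr)
    r[c("id", "name", "subsystem", "lb", "ub", "stoich", "gpr")]
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")

  gpr_all <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr))))
  if (is.null(genes)) genes <- gpr_all
  genes <- as.character(genes)

  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         genes = genes, objective_id = as.character(objective_id)),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks unique ids, stoichiometry referencing declared metabolites,
#' \code{lb <= ub} for every reaction, and GPR genes present in the gene
#' list.
#'
#' @param model a \code{metabolic_model}.
#' @return The model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mids <- model$metabolites$id
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(mids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "), call. = FALSE)
  }
  bad_lb <- rids[vapply(model$reactions, function(r) r$lb > r$ub, logical(1))]
  if (length(bad_lb)) {
    stop("validation error: lower bound exceeds upper bound for reaction(s): ",
         paste(bad_lb, collapse = ", "), call. = FALSE)
  }
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoich), mids)
    if (length(unknown)) {
      stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                   r$id, paste(unknown, collapse = ", ")), call. = FALSE)
    }
    missing_g <- setdiff(gpr_genes(r$gpr), model$genes)
    if (length(missing_g)) {
      stop(sprintf("reaction '%s' GPR references gene(s) not in gene list: %s",
                   r$id, paste(missing_g, collapse = ", ")), call. = FALSE)
    }
  }
  if (nzchar(model$objective_id) && !model$objective_id %in% rids) {
    stop("objective_id '", model$objective_id, "' is not a reaction id",
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites, %d reactions, %d genes\n",
              nrow(x$metabolites), length(x$reactions), length(x$genes)))
  if (nzchar(x$objective_id)) cat("objective:", x$objective_id, "\n")
  invisible(x)
}

reaction_ids <- function(model) names(model$reactions)

#' Stoichiometric matrix of a model
#'
#' @param model a \code{metabolic_model}.
#' @return A sparse metabolites x reactions matrix (dgCMatrix); entry
#'   (m, r) is the coefficient of metabolite m in reaction r.
#' @export
stoichiometric_matrix <- function(model) {
  validate_model(model)
  mids <- model$metabolites$id
  rids <- reaction_ids(model)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    if (!length(st)) next
    ii <- c(ii, match(names(st), mids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mids), length(rids)),
                       dimnames = list(mids, rids))
}

#' Model size statistics
#'
#' Counts metabolites, reactions, and genes after dropping orphans
#' (metabolites and genes referenced by no reaction).
#'
#' @param model a \code{metabolic_model}.
#' @return Named integer vector \code{(n_metabolites, n_reactions, n_genes)}.
#' @export
model_stats <- function(model) {
  used_m <- unique(unlist(lapply(model$reactions, function(r) names(r$stoich))))
  used_g <- unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr))))
  c(n_metabolites = sum(model$metabolites$id %in% used_m),
    n_reactions = length(model$reactions),
    n_genes = sum(model$genes %in% used_g))
}

#' Exchange (boundary) reactions of a model
#'
#' An exchange reaction imports/exports a single metabolite; its lower
#' bound encodes the maximal uptake from the medium.
#'
#' @param model a \code{metabolic_model}.
#' @return Character vector of reaction ids with single-entry stoichiometry.
#' @export
exchange_reactions <- function(model) {
  rids <- reaction_ids(model)
  rids[vapply(model$reactions, function(r) length(r$stoich) == 1L, logical(1))]
}

#' Restrict a model to a set of reactions
#'
#' Drops all other reactions, then orphan metabolites and genes.
#'
#' @param model a \code{metabolic_model}.
#' @param keep character vector of reaction ids to retain.
#' @return A \code{metabolic_model}.
#' @export
subset_model <- function(model, keep) {
  unknown <- setdiff(keep, reaction_ids(model))
  if (length(unknown)) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rx <- model$reactions[reaction_ids(model) %in% keep]
  used_m <- unique(unlist(lapply(rx, function(r) names(r$stoich))))
  used_g <- unique(unlist(lapply(rx, function(r) gpr_genes(r$gpr))))
  metabolic_model(
    metabolites = model$metabolites[model$metabolites$id %in% used_m, ,
                                    drop = FALSE],
    reactions = rx,
    genes = intersect(model$genes, used_g),
    objective_id = if (model$objective_id %in% names(rx)) model$objective_id else "")
}

#' Split reversible reactions into irreversible forward/backward pairs
#'
#' A reversible reaction \code{r} with bounds \code{(lb < 0, ub)} becomes
#' \code{r_f} with bounds \code{(0, ub)} and \code{r_b} (reversed
#' stoichiometry) with bounds \code{(0, -lb)}; merging
#' \code{v_r = v_f - v_b} recovers the original flux space.
#'
#' @param model a \code{metabolic_model}.
#' @return A \code{metabolic_model} whose reactions all have \code{lb >= 0};
#'   attribute \code{"split_map"} maps split ids back to original ids.
#' @export
split_reversible <- function(model) {
  out <- list()
  map <- character(0)
  for (r in model$reactions) {
    if (r$lb >= 0) {
      out[[r$id]] <- r
      map[r$id] <- r$id
    } else {
      rf <- r; rf$id <- paste0(r$id, "_f"); rf$lb <- max(0, r$lb); rf$lb <- 0
      rf$ub <- max(0, r$ub)
      rb <- r; rb$id <- paste0(r$id, "_b"); rb$stoich <- -r$stoich
      rb$lb <- 0; rb$ub <- -r$lb
      out[[rf$id]] <- rf; out[[rb$id]] <- rb
      map[rf$id] <- r$id; map[rb$id] <- r$id
    }
  }
  m2 <- metabolic_model(model$metabolites, out, model$genes,
                        objective_id = if (model$objective_id %in% names(out))
                          model$objective_id else "")
  attr(m2, "split_map") <- map
  m2
}

#' Read a metabolic model from SBML or JSON
#'
#' SBML Level 3 with the FBC v2 extension is the primary format; models
#' without FBC fall back to bounds from the \code{reversible} flag
#' ([-1000, 1000] reversible, [0, 1000] irreversible) and GPRs from
#' \code{GENE_ASSOCIATION} notes. The JSON dialect has top-level keys
#' \code{metabolites}/\code{reactions}/\code{genes}/\code{objective}.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"sbml"}, or
#'   \code{"json"}.
#' @return A validated \code{metabolic_model}.
#' @export
read_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

#' Write a metabolic model to SBML or JSON
#'
#' @param model a \code{metabolic_model}.
#' @param path output file path.
#' @param format \code{"auto"} (by extension), \code{"sbml"}, or
#'   \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  if (format == "json") write_model_json(model, path) else write_model_sbml(model, path)
  invisible(path)
}

read_model_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("format error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  for (key in c("metabolites", "reactions")) {
    if (is.null(obj[[key]])) {
      stop("format error: missing top-level key '", key, "'", call. = FALSE)
    }
  }
  mets <- do.call(rbind, lapply(obj$metabolites, function(m) {
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "" else m$compartment,
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(obj$reactions, function(r) {
    list(id = r$id, name = r$name, subsystem = r$subsystem,
         lb = r$lb, ub = r$ub, stoich = unlist(r$stoich),
         gpr = if (is.null(r$gpr)) "" else r$gpr)
  })
  metabolic_model(mets, rxns,
                  genes = if (is.null(obj$genes)) NULL else unlist(obj$genes),
                  objective_id = if (is.null(obj$objective)) "" else obj$objective)
}

write_model_json <- function(model, path) {
  obj <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      as.list(model$metabolites[i, , drop = FALSE])
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id, name = r$name, subsystem = r$subsystem,
           lb = r$lb, ub = r$ub, stoich = as.list(r$stoich),
           gpr = serialize_gpr(r$gpr))
    }),
    genes = as.list(model$genes),
    objective = model$objective_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mod_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mod_node, "xml_missing")) {
    # tolerate other SBML levels by ignoring the namespace
    mod_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  }
  if (inherits(mod_node, "xml_missing")) {
    stop("format error: no <model> element in '", path, "'", call. = FALSE)
  }

  ln <- function(node, name) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  }
  attr1 <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) "" else v
  }

  # flux-bound parameters (FBC)
  params <- ln(mod_node, "parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  met_nodes <- ln(xml2::xml_find_first(mod_node,
                    ".//*[local-name()='listOfSpecies']"), "species")
  mets <- data.frame(
    id = xml2::xml_attr(met_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(met_nodes, "name")),
                  xml2::xml_attr(met_nodes, "id"),
                  xml2::xml_attr(met_nodes, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(met_nodes, "compartment")), "",
                         xml2::xml_attr(met_nodes, "compartment")),
    stringsAsFactors = FALSE)
  boundary <- xml2::xml_attr(met_nodes, "boundaryCondition") %in% "true"
  boundary_ids <- mets$id[boundary]

  gp_nodes <- ln(mod_node, "geneProduct")
  gene_map <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gp_nodes, "label")),
           xml2::xml_attr(gp_nodes, "id"),
           xml2::xml_attr(gp_nodes, "label")),
    xml2::xml_attr(gp_nodes, "id"))

  rxn_list_node <- xml2::xml_find_first(mod_node,
                     ".//*[local-name()='listOfReactions']")
  rxn_nodes <- if (inherits(rxn_list_node, "xml_missing")) list()
               else xml2::xml_find_all(rxn_list_node,
                      "./*[local-name()='reaction']")

  parse_gpa <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr1(node, "geneProduct")
      g <- if (ref %in% names(gene_map)) gene_map[[ref]] else ref
      return(g)
    }
    kids <- xml2::xml_children(node)
    args <- lapply(kids, parse_gpa)
    args <- args[!vapply(args, is.null, logical(1))]
    if (nm == "and") return(list(op = "and", args = args))
    if (nm == "or") return(list(op = "or", args = args))
    if (length(args) == 1L) return(args[[1]])
    NULL
  }

  rxns <- lapply(rxn_nodes, function(rn) {
    rid <- attr1(rn, "id")
    rev_flag <- attr1(rn, "reversible") == "true"
    lb_ref <- attr1(rn, "lowerFluxBound"); ub_ref <- attr1(rn, "upperFluxBound")
    if (nzchar(lb_ref) && lb_ref %in% names(pvals)) {
      lb <- pvals[[lb_ref]]
    } else lb <- if (rev_flag) -1000 else 0
    if (nzchar(ub_ref) && ub_ref %in% names(pvals)) {
      ub <- pvals[[ub_ref]]
    } else ub <- 1000
    reac <- ln(rn, "listOfReactants")
    prod <- ln(rn, "listOfProducts")
    st <- numeric(0)
    grab <- function(list_nodes, sign) {
      for (lnode in list_nodes) {
        for (sr in xml2::xml_find_all(lnode, "./*[local-name()='speciesRef' or local-name()='speciesReference']")) {
          sp <- attr1(sr, "species")
          co <- suppressWarnings(as.numeric(attr1(sr, "stoichiometry")))
          if (is.na(co)) co <- 1
          st[sp] <<- (if (sp %in% names(st)) st[[sp]] else 0) + sign * co
        }
      }
    }
    grab(reac, -1); grab(prod, +1)
    st <- st[!names(st) %in% boundary_ids]

    gpa_node <- xml2::xml_find_first(rn,
      "./*[local-name()='geneProductAssociation']")
    gpr <- NULL
    if (!inherits(gpa_node, "xml_missing")) {
      kids <- xml2::xml_children(gpa_node)
      if (length(kids)) gpr <- parse_gpa(kids[[1]])
    } else {
      notes <- xml2::xml_find_first(rn, "./*[local-name()='notes']")
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt, regexpr("GENE_ASSOCIATION:[^\n<]*", txt))
        if (length(m)) {
          rule <- trimws(sub("GENE_ASSOCIATION:", "", m[1]))
          if (nzchar(rule)) gpr <- parse_gpr(rule)
        }
      }
    }
    list(id = rid, name = attr1(rn, "name"), subsystem = "",
         lb = lb, ub = ub, stoich = st, gpr = gpr)
  })

  objective_id <- ""
  obj_node <- xml2::xml_find_first(mod_node, ".//*[local-name()='fluxObjective']")
  if (!inherits(obj_node, "xml_missing")) {
    objective_id <- attr1(obj_node, "reaction")
  }

  mets <- mets[!boundary, , drop = FALSE]
  genes <- unique(unname(gene_map))
  if (!length(genes)) genes <- NULL
  metabolic_model(mets, rxns, genes = genes, objective_id = objective_id)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  gpa_xml <- function(gpr) {
    if (is.null(gpr)) return("")
    if (is.character(gpr)) {
      return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>', esc(gpr)))
    }
    inner <- paste(vapply(gpr$args, gpa_xml, character(1)), collapse = "")
    sprintf("<fbc:%s>%s</fbc:%s>", gpr$op, inner, gpr$op)
  }

  comps <- unique(model$metabolites$compartment)
  comps[!nzchar(comps)] <- "c"
  comps <- unique(comps)

  # unique flux-bound parameters
  bvals <- sort(unique(c(vapply(model$reactions, `[[`, numeric(1), "lb"),
                         vapply(model$reactions, `[[`, numeric(1), "ub"))))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(bvals)),
                         sprintf("%.17g", bvals))
  pref <- function(v) pid[[sprintf("%.17g", v)]]

  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w(sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS))
  w('<model id="model" fbc:strict="true">')
  w("<listOfCompartments>")
  for (cp in comps) w(sprintf('<compartment id="%s" constant="true"/>', esc(cp)))
  w("</listOfCompartments>")
  w("<listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    cp <- if (nzchar(m$compartment)) m$compartment else "c"
    w(sprintf('<species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
              esc(m$id), esc(m$name), esc(cp)))
  }
  w("</listOfSpecies>")
  w("<listOfParameters>")
  for (i in seq_along(bvals)) {
    w(sprintf('<parameter id="fb_%d" value="%s" constant="true"/>',
              i, format(bvals[i], digits = 17)))
  }
  w("</listOfParameters>")
  w("<listOfReactions>")
  for (r in model$reactions) {
    w(sprintf('<reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
              esc(r$id), esc(r$name), if (r$lb < 0) "true" else "false",
              pref(r$lb), pref(r$ub)))
    reac <- r$stoich[r$stoich < 0]; prod <- r$stoich[r$stoich > 0]
    if (length(reac)) {
      w("<listOfReactants>")
      for (k in seq_along(reac)) {
        w(sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                  esc(names(reac)[k]), format(-reac[[k]], digits = 17)))
      }
      w("</listOfReactants>")
    }
    if (length(prod)) {
      w("<listOfProducts>")
      for (k in seq_along(prod)) {
        w(sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                  esc(names(prod)[k]), format(prod[[k]], digits = 17)))
      }
      w("</listOfProducts>")
    }
    if (!is.null(r$gpr)) {
      w("<fbc:geneProductAssociation>")
      w(gpa_xml(r$gpr))
      w("</fbc:geneProductAssociation>")
    }
    w("</reaction>")
  }
  w("</listOfReactions>")
  if (length(model$genes)) {
    w("<fbc:listOfGeneProducts>")
    for (g in model$genes) {
      w(sprintf('<fbc:geneProduct fbc:id="%s" fbc:label="%s"/>', esc(g), esc(g)))
    }
    w("</fbc:listOfGeneProducts>")
  }
  if (nzchar(model$objective_id)) {
    w('<fbc:listOfObjectives fbc:activeObjective="obj">')
    w('<fbc:objective fbc:id="obj" fbc:type="maximize">')
    w("<fbc:listOfFluxObjectives>")
    w(sprintf('<fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
              esc(model$objective_id)))
    w("</fbc:listOfFluxObjectives>")
    w("</fbc:objective>")
    w("</fbc:listOfObjectives>")
  }
  w("</model>")
  w("</sbml>")
  invisible(path)
}
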