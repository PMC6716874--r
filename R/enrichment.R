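#' Read / write gene-set collections in GMT format
#'
#' GMT lines are tab-separated: set name, description, then gene ids.
#' Duplicate genes within a set are deduplicated; duplicate set names
#' are an error.
#'
#' @param path file path.
#' @return \code{read_gmt}: named list, set name -> character vector of
#'   gene ids, with per-set descriptions in attribute
#'   \code{"description"}.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); descr <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: need name, description, genes", i),
           call. = FALSE)
    }
    nm <- fields[1]
    if (nm %in% names(sets)) {
      stop(sprintf("duplicate set name '%s' at line %d", nm, i), call. = FALSE)
    }
    sets[[nm]] <- unique(fields[-(1:2)])
    descr[nm] <- fields[2]
  }
  attr(sets, "description") <- descr
  sets
}

#' @rdname read_gmt
#' @param collection named list of gene-id vectors.
#' @export
write_gmt <- function(collection, path) {
  descr <- attr(collection, "description")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(descr) && nm %in% names(descr)) descr[[nm]] else nm
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' drawing at least the observed overlap when sampling \code{|query|}
#' genes from a universe containing \code{|set ∩ universe|} set members;
#' BH adjustment across sets. Query genes outside the universe are
#' dropped with a message.
#'
#' @param query character vector of gene ids (e.g. a differential or
#'   flux-derived gene list).
#' @param collection named list of gene sets.
#' @param universe character vector of all testable gene ids.
#' @return data.frame \code{(set, set_size, overlap, p_value, adj_p)}
#'   sorted by p-value.
#' @export
enrich <- function(query, collection, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set_u <- intersect(collection[[nm]], universe)
    K <- length(set_u)
    ov <- length(intersect(query, set_u))
    p <- if (K == 0L) 1 else stats::phyper(ov - 1, K, N - K, n,
                                           lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = ov, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
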