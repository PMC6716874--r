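#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers stating which
#' gene products enable a reaction: \code{and} denotes an enzyme complex
#' (all subunits required), \code{or} denotes isozymes (any suffices).
#' When parentheses are absent, \code{and} binds tighter than \code{or},
#' following the COBRA community convention. Operators are matched
#' case-insensitively; any other token is a gene id.
#'
#' @param rule Character scalar. May be empty (\code{""} or \code{NA}),
#'   meaning "no gene constraint".
#' @return A GPR expression tree: \code{NULL} for the empty rule, a
#'   character scalar for a bare gene, or a list with elements \code{op}
#'   (\code{"and"}/\code{"or"}) and \code{args} (list of subtrees).
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' parse_gpr("")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1L)
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)

  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  tree <- gpr_parse_or(st)
  if (st$i <= nrow(st$toks)) {
    stop(sprintf("GPR parse error at character %d: unexpected token '%s'",
                 st$toks$pos[st$i], st$toks$text[st$i]), call. = FALSE)
  }
  tree
}

# Tokenizer: gene ids are maximal runs of non-space, non-paren characters.
gpr_tokenize <- function(rule) {
  chars <- strsplit(rule, "", fixed = TRUE)[[1]]
  text <- character(0); type <- character(0); pos <- integer(0)
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      text <- c(text, ch); type <- c(type, ch); pos <- c(pos, i)
      i <- i + 1L; next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()]$", chars[j], perl = TRUE)) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    lw <- tolower(word)
    ty <- if (lw %in% c("and", "&", "&&")) "and"
          else if (lw %in% c("or", "|", "||")) "or"
          else "gene"
    text <- c(text, word); type <- c(type, ty); pos <- c(pos, i)
    i <- j
  }
  data.frame(text = text, type = type, pos = pos, stringsAsFactors = FALSE)
}

gpr_peek <- function(st) if (st$i <= nrow(st$toks)) st$toks$type[st$i] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && gpr_peek(st) == "or") {
    st$i <- st$i + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && gpr_peek(st) == "and") {
    st$i <- st$i + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  ty <- gpr_peek(st)
  if (is.na(ty)) {
    last <- if (nrow(st$toks)) st$toks$pos[nrow(st$toks)] else 1L
    stop(sprintf("GPR parse error at character %d: dangling operator or empty expression",
                 last), call. = FALSE)
  }
  if (ty == "gene") {
    g <- st$toks$text[st$i]
    st$i <- st$i + 1L
    return(g)
  }
  if (ty == "(") {
    open_pos <- st$toks$pos[st$i]
    st$i <- st$i + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop(sprintf("GPR parse error at character %d: unbalanced parenthesis",
                   open_pos), call. = FALSE)
    }
    st$i <- st$i + 1L
    return(inner)
  }
  stop(sprintf("GPR parse error at character %d: unexpected '%s'",
               st$toks$pos[st$i], st$toks$text[st$i]), call. = FALSE)
}

#' Serialize a GPR expression tree back to rule text
#'
#' @param gpr A tree as returned by [parse_gpr()].
#' @return Character scalar; \code{""} for the empty rule.
#' @export
serialize_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  if (is.character(gpr)) return(gpr)
  parts <- vapply(gpr$args, function(a) {
    s <- serialize_gpr(a)
    # parenthesize an OR nested under AND to preserve precedence
    if (gpr$op == "and" && is.list(a) && a$op == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$op, " "))
}

#' Genes referenced by a GPR expression
#'
#' @param gpr A tree as returned by [parse_gpr()].
#' @return Character vector of unique gene ids (empty for the empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (is.character(gpr)) return(gpr)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}

#' Evaluate a GPR rule as a boolean over gene states
#'
#' @param gpr A tree as returned by [parse_gpr()].
#' @param gene_on Named logical vector; genes absent from it are taken
#'   as \code{default}.
#' @param default Logical state for unlisted genes (default \code{TRUE}).
#' @return \code{TRUE}/\code{FALSE}; the empty rule evaluates \code{TRUE}
#'   (no gene constraint).
#' @export
eval_gpr <- function(gpr, gene_on, default = TRUE) {
  if (is.null(gpr)) return(TRUE)
  if (is.character(gpr)) {
    if (!is.null(names(gene_on)) && gpr %in% names(gene_on)) return(isTRUE(unname(gene_on[gpr])))
    return(default)
  }
  vals <- vapply(gpr$args, eval_gpr, logical(1), gene_on = gene_on, default = default)
  if (gpr$op == "and") all(vals) else any(vals)
}

# Numeric GPR evaluation: AND -> min, OR -> max over operand scores.
# Genes without a value contribute `missing_value`.
eval_gpr_score <- function(gpr, gene_expr, missing_value = 0) {
  if (is.null(gpr)) return(NA_real_)
  if (is.character(gpr)) {
    if (!is.null(names(gene_expr)) && gpr %in% names(gene_expr)) {
      return(as.numeric(gene_expr[[gpr]]))
    }
    return(missing_value)
  }
  vals <- vapply(gpr$args, eval_gpr_score, numeric(1),
                 gene_expr = gene_expr, missing_value = missing_value)
  if (gpr$op == "and") min(vals) else max(vals)
}
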