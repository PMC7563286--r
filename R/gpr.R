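#' Parse a gene-protein-reaction (GPR) Boolean rule
#'
#' GPR rules link a reaction to the genes encoding its catalyst: `and`
#' joins subunits of an enzyme complex, `or` joins isoenzymes. The grammar
#' accepts gene identifiers, the case-insensitive operators `and`/`or`, and
#' parentheses; `and` binds tighter than `or`, so `"g1 and g2 or g3"`
#' parses as `(g1 and g2) or g3`.
#'
#' @param text GPR rule string, e.g. `"g1 and (g2 or g3)"`.
#' @return A `gpr_expression`: a tree of nodes with `kind` one of
#'   `"gene"` (field `gene`), `"and"` or `"or"` (field `children`, length
#'   >= 2).
#' @seealso [evaluate_gpr()], [unparse_gpr()], [gpr_genes()]
#' @export
#' @examples
#' parse_gpr("g1 and g2 or g3")
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty GPR string")
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st)
  if (st$pos <= nrow(st$toks))
    stop(sprintf("GPR parse error: unexpected '%s' at position %d",
                 st$toks$token[st$pos], st$toks$at[st$pos]))
  expr
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) stop("GPR parse error: no tokens in '", text, "'")
  tok <- regmatches(text, gregexpr(pat, text))[[1]]
  kind <- ifelse(tok == "(", "lpar",
          ifelse(tok == ")", "rpar",
          ifelse(tolower(tok) == "and", "and",
          ifelse(tolower(tok) == "or", "or", "gene"))))
  data.frame(token = tok, kind = kind, at = as.integer(m))
}

gpr_peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$kind[st$pos] else "eof"

gpr_node <- function(kind, children) {
  structure(list(kind = kind, children = children), class = "gpr_expression")
}

gpr_parse_or <- function(st) {
  children <- list(gpr_parse_and(st))
  while (gpr_peek(st) == "or") {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_and(st)))
  }
  if (length(children) == 1L) children[[1L]] else gpr_node("or", children)
}

gpr_parse_and <- function(st) {
  children <- list(gpr_parse_atom(st))
  while (gpr_peek(st) == "and") {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_atom(st)))
  }
  if (length(children) == 1L) children[[1L]] else gpr_node("and", children)
}

gpr_parse_atom <- function(st) {
  k <- gpr_peek(st)
  if (k == "gene") {
    g <- st$toks$token[st$pos]
    st$pos <- st$pos + 1L
    return(structure(list(kind = "gene", gene = g), class = "gpr_expression"))
  }
  if (k == "lpar") {
    at <- st$toks$at[st$pos]
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (gpr_peek(st) != "rpar")
      stop(sprintf("GPR parse error: unbalanced '(' at position %d", at))
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (k == "eof")
    stop("GPR parse error: unexpected end of expression (dangling operator?)")
  stop(sprintf("GPR parse error: unexpected '%s' at position %d",
               st$toks$token[st$pos], st$toks$at[st$pos]))
}

#' Serialize a GPR tree back to rule text
#'
#' `parse_gpr(unparse_gpr(x))` yields a tree equivalent to `x`.
#'
#' @param expr A `gpr_expression`.
#' @return A single GPR rule string with explicit parentheses.
#' @export
unparse_gpr <- function(expr) {
  stopifnot(inherits(expr, "gpr_expression"))
  if (expr$kind == "gene") return(expr$gene)
  parts <- vapply(expr$children, function(ch) {
    s <- unparse_gpr(ch)
    if (ch$kind == "gene") s else paste0("(", s, ")")
  }, "")
  paste(parts, collapse = paste0(" ", expr$kind, " "))
}

#' @export
print.gpr_expression <- function(x, ...) {
  cat("<gpr> ", unparse_gpr(x), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a GPR tree
#'
#' @param expr A `gpr_expression`.
#' @return Character vector of unique gene identifiers (tree leaves).
#' @export
gpr_genes <- function(expr) {
  stopifnot(inherits(expr, "gpr_expression"))
  if (expr$kind == "gene") return(expr$gene)
  unique(unlist(lapply(expr$children, gpr_genes)))
}

#' Evaluate a GPR rule to a numeric expression level
#'
#' Implements the min/max semantics for expression-constrained models:
#' an `and` node (enzyme complex) takes the minimum of its subunit levels
#' and an `or` node (isoenzymes) the maximum. Genes absent from `levels`
#' are unmeasured; the result for an (effectively) unmeasured rule is
#' `NA_real_`, signalling that the reaction's bound should not be
#' constrained by expression.
#'
#' @param expr A `gpr_expression` (or rule string, parsed on the fly).
#' @param levels Named non-negative numeric vector of expression levels
#'   (an expression map, see [to_expression_map()]).
#' @param missing_policy How unmeasured genes propagate:
#'   * `"unbounded"` (default): an unmeasured gene evaluates to unmeasured;
#'     under `or`, unmeasured branches are ignored when a measured sibling
#'     exists (isoenzyme evidence is kept); under `and`, any unmeasured
#'     subunit makes the whole complex unmeasured (the constraint is
#'     dropped).
#'   * `"zero"`: unmeasured genes count as level 0 (used e.g. for gene
#'     knockouts).
#'   * `"ignore"`: unmeasured genes are dropped from both `and` and `or`
#'     nodes; a rule with no measured gene at all is unmeasured.
#' @return A single non-negative numeric level, or `NA_real_` for
#'   unmeasured.
#' @export
#' @examples
#' evaluate_gpr(parse_gpr("g1 and g2"), c(g1 = 2, g2 = 5))  # min -> 2
#' evaluate_gpr(parse_gpr("g1 or g2"), c(g1 = 2, g2 = 5))   # max -> 5
evaluate_gpr <- function(expr, levels,
                         missing_policy = c("unbounded", "zero", "ignore")) {
  missing_policy <- match.arg(missing_policy)
  if (is.character(expr)) expr <- parse_gpr(expr)
  stopifnot(inherits(expr, "gpr_expression"))
  if (any(levels < 0, na.rm = TRUE)) stop("expression levels must be >= 0")
  gpr_eval(expr, levels, missing_policy)
}

gpr_eval <- function(node, levels, policy) {
  if (node$kind == "gene") {
    v <- unname(levels[node$gene])
    if (length(v) == 0 || is.na(v))
      return(if (policy == "zero") 0 else NA_real_)
    return(v)
  }
  vals <- vapply(node$children, gpr_eval, 0, levels = levels, policy = policy)
  if (node$kind == "or") {
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NA_real_)
    return(max(vals))
  }
  # and
  if (policy == "ignore") {
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NA_real_)
    return(min(vals))
  }
  if (anyNA(vals)) return(NA_real_)
  min(vals)
}
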