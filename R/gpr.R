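# Gene-protein-reaction rules: infix boolean text with "and"/"or"
# (case-insensitive) and parentheses over gene tokens. AND nodes model
# enzyme complexes (capacity limited by the scarcest subunit), OR nodes
# isozymes (capacities add).

#' Parse a GPR rule to an AND/OR tree
#'
#' @param text infix rule, e.g. `"(g1 and g2) or g3"`. Empty or `NA` text
#'   yields `NULL` (an unconstrained reaction).
#' @return A nested list with elements `op` (`"and"`, `"or"`, `"gene"`) and
#'   either `args` (subtrees) or `id` (gene token), or `NULL`.
#' @export
parse_gpr <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    return(NULL)
  toks <- gpr_tokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- gpr_parse_or(st)
  if (st$pos <= length(st$toks))
    stop("GPR grammar error near '", st$toks[st$pos], "' in: ", text)
  ast
}

gpr_tokens <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) stop("GPR grammar error in: ", text)
  regmatches(text, gregexpr(pat, text))[[1]]
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_atom(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("GPR grammar error: unexpected end of rule")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    node <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")")
      stop("GPR grammar error: unbalanced parenthesis")
    st$pos <- st$pos + 1L
    return(node)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or"))
    stop("GPR grammar error near '", tk, "'")
  st$pos <- st$pos + 1L
  list(op = "gene", id = tk)
}

#' Genes referenced by a GPR tree
#' @param ast result of [parse_gpr()].
#' @return character vector (empty for `NULL` rules).
#' @export
gpr_genes <- function(ast) {
  if (is.null(ast)) return(character(0))
  if (ast$op == "gene") return(ast$id)
  unique(unlist(lapply(ast$args, gpr_genes)))
}

#' Evaluate a GPR rule against gene abundances
#'
#' AND maps to the minimum of its children (complex limited by the scarcest
#' subunit), OR to the sum (isozyme capacities add). An empty rule evaluates
#' to `Inf`, the "unbounded" sentinel. Genes absent from `gene_levels` count
#' as abundance 0.
#'
#' @param gpr rule text or a tree from [parse_gpr()].
#' @param gene_levels named non-negative numeric vector of gene abundances.
#' @return single non-negative number (or `Inf`).
#' @export
evaluate_gpr <- function(gpr, gene_levels) {
  ast <- if (is.character(gpr)) parse_gpr(gpr) else gpr
  if (is.null(ast)) return(Inf)
  eval_gpr_ast(ast, gene_levels)
}

eval_gpr_ast <- function(ast, lv) {
  if (ast$op == "gene") {
    x <- lv[ast$id]
    return(if (is.na(x)) 0 else unname(x))
  }
  vals <- vapply(ast$args, eval_gpr_ast, numeric(1), lv = lv)
  if (ast$op == "and") min(vals) else sum(vals)
}

gpr_deparse <- function(ast) {
  if (is.null(ast)) return("")
  if (ast$op == "gene") return(ast$id)
  inner <- vapply(ast$args, gpr_deparse, character(1))
  paste0("(", paste(inner, collapse = paste0(" ", ast$op, " ")), ")")
}
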