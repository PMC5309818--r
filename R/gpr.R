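#' @title Boolean gene-protein-reaction (GPR) rules
#'
#' @description A GPR rule is a boolean expression over gene identifiers.
#' `OR` joins redundant isozymes (any one suffices), `AND` joins subunits of
#' an enzyme complex (all are required). Rules are stored as canonical trees:
#' nested nodes of the same operator are flattened, duplicate children are
#' merged, children are sorted lexicographically by their serialized form,
#' and no `AND`/`OR` node has fewer than two children. The empty rule
#' (`NULL`) marks a non-enzymatic reaction.
#'
#' @details `parse_gpr()` accepts case-insensitive `and`/`or` with
#' parentheses; `AND` binds tighter than `OR` when parentheses are omitted,
#' the conventional reading in constraint-based modelling. Parsing and
#' serialization (`deparse_gpr()`) are mutually inverse up to canonical
#' ordering.
#'
#' @param text GPR string, e.g. `"Gclc and Gclm"` or `"(A and B) or C"`.
#'   The empty string (or `NA`) yields the empty rule.
#' @return `parse_gpr()` returns an object of class `"gpr"` (or `NULL` for
#'   the empty rule).
#' @examples
#' r <- parse_gpr("A and B or C")
#' deparse_gpr(r)            # "(A and B) or C"
#' gpr_genes(r)              # "A" "B" "C"
#' gpr_eval(r, c(A = FALSE, B = TRUE, C = TRUE))
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(NULL)
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  rule <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error: unexpected token '", st$toks[st$pos],
         "' at position ", st$pos, " in: ", text)
  }
  gpr_canonicalize(rule)
}

# tokenizer: gene tokens, 'and'/'or' (case-insensitive), parentheses
gpr_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- grep("[^A-Za-z0-9_.:/()'[:space:]-]", chars)
  if (length(bad)) {
    stop("GPR parse error: illegal character '", chars[bad[1]],
         "' at position ", bad[1], " in: ", text)
  }
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    pos <- if (any(depth < 0)) which(depth < 0)[1] else length(chars)
    stop("GPR parse error: unbalanced parentheses at position ", pos,
         " in: ", text)
  }
  spaced <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_parse_or <- function(st) {
  children <- list(gpr_parse_and(st))
  while (st$pos <= length(st$toks) && tolower(st$toks[st$pos]) == "or") {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_and(st)))
  }
  if (length(children) == 1L) children[[1]] else list(op = "or", args = children)
}

gpr_parse_and <- function(st) {
  children <- list(gpr_parse_atom(st))
  while (st$pos <= length(st$toks) && tolower(st$toks[st$pos]) == "and") {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_atom(st)))
  }
  if (length(children) == 1L) children[[1]] else list(op = "and", args = children)
}

gpr_parse_atom <- function(st) {
  if (st$pos > length(st$toks)) stop("GPR parse error: unexpected end of rule")
  tok <- st$toks[st$pos]
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (st$pos > length(st$toks) || st$toks[st$pos] != ")") {
      stop("GPR parse error: expected ')' at position ", st$pos)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tolower(tok) %in% c("and", "or", ")")) {
    stop("GPR parse error: unexpected token '", tok, "' at position ", st$pos)
  }
  st$pos <- st$pos + 1L
  list(op = "gene", id = tok)
}

#' Canonicalize a GPR tree
#'
#' Flattens nested nodes of the same operator, removes duplicate children,
#' sorts children by serialized form, and collapses single-child nodes.
#' Idempotent; exported mainly for construction of rules by hand.
#'
#' @param rule a GPR tree (or `NULL`).
#' @return canonical `"gpr"` object or `NULL`.
#' @export
gpr_canonicalize <- function(rule) {
  if (is.null(rule)) return(NULL)
  node <- gpr_canon_rec(unclass(rule))
  class(node) <- "gpr"
  node
}

gpr_canon_rec <- function(node) {
  if (node$op == "gene") return(node)
  kids <- lapply(node$args, gpr_canon_rec)
  flat <- list()
  for (k in kids) {
    if (k$op == node$op) flat <- c(flat, k$args) else flat <- c(flat, list(k))
  }
  keys <- vapply(flat, gpr_deparse_rec, "", parent_op = node$op)
  flat <- flat[!duplicated(keys)]
  flat <- flat[order(keys[!duplicated(keys)], method = "radix")]
  if (length(flat) == 1L) return(flat[[1]])
  list(op = node$op, args = flat)
}

#' Serialize a GPR rule to text
#'
#' @param rule `"gpr"` object or `NULL`.
#' @return single string; `""` for the empty rule. Every nested operator
#'   node is parenthesized, so the text form is unambiguous without
#'   relying on precedence.
#' @export
deparse_gpr <- function(rule) {
  if (is.null(rule)) return("")
  gpr_deparse_rec(unclass(rule), parent_op = "top")
}

gpr_deparse_rec <- function(node, parent_op) {
  if (node$op == "gene") return(node$id)
  inner <- vapply(node$args, gpr_deparse_rec, "", parent_op = node$op)
  joined <- paste(inner, collapse = paste0(" ", node$op, " "))
  if (parent_op == "top") joined else paste0("(", joined, ")")
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", deparse_gpr(x), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a GPR rule
#'
#' @param rule `"gpr"` object or `NULL`.
#' @return character vector of distinct gene ids (sorted); empty for the
#'   empty rule.
#' @export
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character(0))
  leaves <- function(node) {
    if (node$op == "gene") return(node$id)
    unlist(lapply(node$args, leaves))
  }
  sort(unique(leaves(unclass(rule))))
}

#' Number of distinct genes in a GPR rule
#' @param rule `"gpr"` object or `NULL`.
#' @return integer count (0 for the empty rule).
#' @export
gpr_size <- function(rule) length(gpr_genes(rule))

#' Evaluate a GPR rule under a gene presence assignment
#'
#' @param rule `"gpr"` object or `NULL`.
#' @param present named logical vector of gene presence. Genes absent from
#'   the vector are governed by `default`.
#' @param default presence value for genes not named in `present`
#'   (default `TRUE`: an unannotated gene is assumed intact).
#' @return logical; the empty rule evaluates `TRUE` (non-enzymatic
#'   reactions are always active).
#' @export
gpr_eval <- function(rule, present = logical(0), default = TRUE) {
  if (is.null(rule)) return(TRUE)
  ev <- function(node) {
    if (node$op == "gene") {
      if (node$id %in% names(present)) return(isTRUE(present[[node$id]]))
      return(default)
    }
    vals <- vapply(node$args, ev, NA)
    if (node$op == "and") all(vals) else any(vals)
  }
  ev(unclass(rule))
}

gpr_has_op <- function(rule, op) {
  if (is.null(rule)) return(FALSE)
  rec <- function(node) {
    if (node$op == "gene") return(FALSE)
    node$op == op || any(vapply(node$args, rec, NA))
  }
  rec(unclass(rule))
}
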