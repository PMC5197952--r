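#' Variables available in screening formulas
#'
#' Single-profile variables: `pos`, `cov`, `mism`, `A`, `CSA`, `fA`,
#' `fC`, `fG`, `fT`, `nA`, `nC`, `nG`, `nT`, `p`, `p_adj`, `ref`.
#' Differential variables: `d_mism`, `d_A`, `d_CSA` plus the per-sample
#' pairs `cov1`/`cov2`, `mism1`/`mism2`, `A1`/`A2`, `CSA1`/`CSA2`.
#'
#' @return Character vector of recognised variable names.
#' @export
formula_variables <- function() {
  c("pos", "cov", "mism", "A", "CSA",
    "fA", "fC", "fG", "fT", "nA", "nC", "nG", "nT",
    "p", "p_adj", "ref",
    "d_mism", "d_A", "d_CSA",
    "cov1", "cov2", "mism1", "mism2", "A1", "A2", "CSA1", "CSA2")
}

# Variables only meaningful on differential rows.
.differential_only_variables <- function() {
  c("d_mism", "d_A", "d_CSA",
    "cov1", "cov2", "mism1", "mism2", "A1", "A2", "CSA1", "CSA2")
}

.CMP_OPS <- c("<", "<=", ">", ">=", "==", "!=")

# ---- tokenizer -------------------------------------------------------------

.tokenize_formula <- function(text) {
  pats <- c(
    ws     = "^[ \t\n]+",
    number = "^-?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?",
    op     = "^(<=|>=|==|!=|<|>)",
    lpar   = "^\\(",
    rpar   = "^\\)",
    string = "^(\"[^\"]*\"|'[^']*')",
    ident  = "^[A-Za-z_][A-Za-z0-9_]*"
  )
  toks <- list()
  offset <- 1L
  rest <- text
  while (nchar(rest) > 0L) {
    hit <- FALSE
    for (ty in names(pats)) {
      m <- regexpr(pats[[ty]], rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        val <- substr(rest, 1L, len)
        if (ty != "ws") {
          if (ty == "ident") {
            kw <- toupper(val)
            if (kw %in% c("AND", "OR", "XOR", "NOT")) {
              ty <- "keyword"
              val <- kw
            }
          }
          toks[[length(toks) + 1L]] <-
            list(type = ty, value = val, offset = offset)
        }
        rest <- substr(rest, len + 1L, nchar(rest))
        offset <- offset + len
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      stop("formula syntax error at character ", offset,
           ": unexpected '", substr(rest, 1L, 1L), "'")
    }
  }
  toks
}

# ---- recursive-descent parser ---------------------------------------------
# Precedence (tightest first): NOT > AND > XOR > OR; left-associative;
# parentheses override.  Same-operator chains are flattened into n-ary
# nodes, so the AST is canonical and serialisation round-trips.

parse_formula_tokens <- function(toks, variables) {
  st <- new.env(parent = emptyenv())
  st$i <- 1L

  peek <- function() if (st$i <= length(toks)) toks[[st$i]] else NULL
  advance <- function() { t <- toks[[st$i]]; st$i <- st$i + 1L; t }
  err <- function(msg) {
    t <- peek()
    at <- if (is.null(t)) "end of input" else
      paste0("character ", t$offset)
    stop("formula syntax error at ", at, ": ", msg)
  }
  at_keyword <- function(kw) {
    t <- peek()
    !is.null(t) && t$type == "keyword" && t$value == kw
  }

  parse_or <- function() {
    children <- list(parse_xor())
    while (at_keyword("OR")) {
      advance()
      children[[length(children) + 1L]] <- parse_xor()
    }
    if (length(children) == 1L) children[[1L]]
    else list(type = "logic", op = "OR", children = children)
  }
  parse_xor <- function() {
    children <- list(parse_and())
    while (at_keyword("XOR")) {
      advance()
      children[[length(children) + 1L]] <- parse_and()
    }
    if (length(children) == 1L) children[[1L]]
    else list(type = "logic", op = "XOR", children = children)
  }
  parse_and <- function() {
    children <- list(parse_not())
    while (at_keyword("AND")) {
      advance()
      children[[length(children) + 1L]] <- parse_not()
    }
    if (length(children) == 1L) children[[1L]]
    else list(type = "logic", op = "AND", children = children)
  }
  parse_not <- function() {
    if (at_keyword("NOT")) {
      advance()
      list(type = "not", child = parse_not())
    } else {
      parse_primary()
    }
  }
  parse_primary <- function() {
    t <- peek()
    if (is.null(t)) err("expected a condition")
    if (t$type == "lpar") {
      advance()
      node <- parse_or()
      if (is.null(peek()) || peek()$type != "rpar") err("expected ')'")
      advance()
      return(node)
    }
    parse_comparison()
  }
  parse_comparison <- function() {
    t <- peek()
    if (is.null(t) || t$type != "ident") err("expected a variable name")
    advance()
    if (!(t$value %in% variables)) {
      stop("unknown formula variable: ", t$value)
    }
    o <- peek()
    if (is.null(o) || o$type != "op") err("expected a comparison operator")
    advance()
    v <- peek()
    if (is.null(v) || !(v$type %in% c("number", "string"))) {
      err("expected a number or quoted string")
    }
    advance()
    value <- if (v$type == "number") as.numeric(v$value) else
      substr(v$value, 2L, nchar(v$value) - 1L)
    if (is.character(value) && !(o$value %in% c("==", "!="))) {
      stop("string comparisons support only == and != (variable ",
           t$value, ")")
    }
    list(type = "cmp", var = t$value, op = o$value, value = value)
  }

  node <- parse_or()
  if (!is.null(peek())) err("trailing input")
  node
}

#' Parse a Boolean threshold formula
#'
#' Comparison atoms (`variable op constant`, operators `<`, `<=`, `>`,
#' `>=`, `==`, `!=`) combined with `NOT`, `AND`, `XOR`, `OR` (precedence
#' in that order, tightest first, left-associative) and parentheses.
#' Reference-base comparisons use a quoted base: `ref == "A"`.
#'
#' @param text Formula text, e.g.
#'   `"mism >= 0.1 AND (A >= 0.2 OR CSA >= 10)"`.
#' @param variables Recognised variable names (default
#'   [formula_variables()]).
#' @return An object of class `rtsig_formula` (the AST).
#' @export
parse_formula <- function(text, variables = formula_variables()) {
  stopifnot(is.character(text), length(text) == 1L)
  ast <- parse_formula_tokens(.tokenize_formula(text), variables)
  structure(ast, class = "rtsig_formula", text = text)
}

.node_precedence <- function(node) {
  switch(node$type,
         cmp = 5L,
         not = 4L,
         logic = switch(node$op, AND = 3L, XOR = 2L, OR = 1L))
}

.format_node <- function(node, parent_prec = 0L) {
  s <- switch(node$type,
    cmp = {
      v <- if (is.character(node$value)) paste0("\"", node$value, "\"")
      else sprintf("%.17g", node$value)
      paste(node$var, node$op, v)
    },
    not = paste0("NOT ", .format_node(node$child, 4L)),
    logic = paste(vapply(node$children, .format_node, character(1),
                         parent_prec = .node_precedence(node)),
                  collapse = paste0(" ", node$op, " "))
  )
  if (.node_precedence(node) < parent_prec) paste0("(", s, ")") else s
}

#' Serialise a formula AST back to text
#'
#' Parenthesised only where precedence requires it; parsing the output
#' yields an identical AST.
#'
#' @param ast An `rtsig_formula` (or bare AST list).
#' @return Formula text.
#' @export
format_formula <- function(ast) {
  .format_node(unclass_ast(ast))
}

#' @export
print.rtsig_formula <- function(x, ...) {
  cat("<rtsig_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

unclass_ast <- function(ast) {
  if (inherits(ast, "rtsig_formula")) {
    attr(ast, "text") <- NULL
    class(ast) <- NULL
  }
  ast
}

#' Variables referenced by a formula
#'
#' @param ast Parsed formula.
#' @return Character vector of variable names used.
#' @export
formula_ast_variables <- function(ast) {
  node <- unclass_ast(ast)
  switch(node$type,
         cmp = node$var,
         not = formula_ast_variables(node$child),
         logic = unique(unlist(lapply(node$children,
                                      formula_ast_variables))))
}

#' Evaluate a formula over metric rows
#'
#' Comparisons on undefined (`NA`) metrics evaluate to `FALSE` —
#' uncovered positions are never flagged.  `XOR` of more than two terms
#' is the left-associative chain (parity).
#'
#' @param ast Parsed formula (or formula text, parsed on the fly).
#' @param rows Data frame whose columns include every variable the
#'   formula uses (see [call_candidates()] for the column layout).
#' @return Logical vector, one value per row.
#' @export
evaluate_formula <- function(ast, rows) {
  if (is.character(ast)) ast <- parse_formula(ast)
  eval_node(unclass_ast(ast), rows)
}

eval_node <- function(node, rows) {
  switch(node$type,
    cmp = {
      if (!(node$var %in% names(rows))) {
        stop("formula variable not available here: ", node$var)
      }
      x <- rows[[node$var]]
      res <- switch(node$op,
                    "<"  = x < node$value,
                    "<=" = x <= node$value,
                    ">"  = x > node$value,
                    ">=" = x >= node$value,
                    "==" = x == node$value,
                    "!=" = x != node$value)
      res[is.na(res)] <- FALSE
      res
    },
    not = !eval_node(node$child, rows),
    logic = {
      vals <- lapply(node$children, eval_node, rows = rows)
      op <- switch(node$op, AND = `&`, OR = `|`, XOR = xor)
      Reduce(op, vals)
    }
  )
}
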