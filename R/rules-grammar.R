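#' @title Boolean rule expressions over gene-family variables
#'
#' @description
#' Traits are mapped from gene content with a small Boolean rule language.
#' Every profile-HMM gene family is a Boolean variable (detected / not
#' detected) and rules combine variables -- or other rules -- with the
#' operators `&` (AND), `|` (OR) and `!` (NOT), plus parentheses.
#' Precedence is `!` > `&` > `|`; all operators associate left.
#'
#' An expression is parsed into an abstract syntax tree (AST) of nested
#' lists. Node types are `"ref"` (a leaf referencing a gene-family
#' variable or another rule by name), `"not"` (one operand in `$x`), and
#' `"and"` / `"or"` (n-ary, operands in `$args`). Identifiers are
#' case-sensitive: gene symbols can legitimately differ only by case.
#'
#' @param text Single character string containing one rule expression.
#' @return `parse_rule_expression()` returns an object of class
#'   `"rule_expr"`, the root node of the AST.
#' @examples
#' e <- parse_rule_expression("narG & narH & narI | napA & napB")
#' format(e)
#' rule_expr_vars(e)
#' @name rule_expressions
NULL

RULE_IDENT_RE <- "[A-Za-z0-9][A-Za-z0-9_.-]*"

rule_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (grepl("^[[:space:]]$", ch)) {
      pos <- pos + 1L
      next
    }
    if (ch %in% c("&", "|", "!", "(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, text = ch, pos = pos)
      pos <- pos + 1L
      next
    }
    m <- regmatches(
      substr(text, pos, n),
      regexpr(paste0("^", RULE_IDENT_RE), substr(text, pos, n))
    )
    if (length(m) == 1L && nzchar(m)) {
      tokens[[length(tokens) + 1L]] <- list(type = "ident", text = m, pos = pos)
      pos <- pos + nchar(m)
      next
    }
    stop(sprintf("rule syntax error at position %d: unexpected character '%s'",
                 pos, ch), call. = FALSE)
  }
  tokens
}

new_rule_ref <- function(name) {
  structure(list(type = "ref", name = name), class = "rule_expr")
}

new_rule_node <- function(type, args) {
  # splice children of the same associative operator so that
  # (a | b) | c and a | b | c build the identical (canonical) tree
  flat <- list()
  for (a in args) {
    if (a$type == type) flat <- c(flat, a$args) else
      flat[[length(flat) + 1L]] <- a
  }
  structure(list(type = type, args = flat), class = "rule_expr")
}

new_rule_not <- function(x) {
  structure(list(type = "not", x = x), class = "rule_expr")
}

#' @rdname rule_expressions
#' @export
parse_rule_expression <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    stop("empty rule expression", call. = FALSE)
  }
  tokens <- rule_tokenize(text)
  if (length(tokens) == 0L) stop("empty rule expression", call. = FALSE)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$i <- 1L

  peek <- function() {
    if (state$i <= length(state$tokens)) state$tokens[[state$i]] else NULL
  }
  advance <- function() {
    tok <- peek()
    state$i <- state$i + 1L
    tok
  }
  expect_fail <- function(what) {
    tok <- peek()
    if (is.null(tok)) {
      stop(sprintf("rule syntax error: unexpected end of expression, expected %s",
                   what), call. = FALSE)
    }
    stop(sprintf("rule syntax error at position %d: unexpected '%s', expected %s",
                 tok$pos, tok$text, what), call. = FALSE)
  }

  # expr := term ('|' term)* ; term := factor ('&' factor)* ;
  # factor := '!' factor | '(' expr ')' | ident
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else new_rule_node("or", args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else new_rule_node("and", args)
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.null(tok)) expect_fail("an identifier, '!' or '('")
    if (tok$type == "!") {
      advance()
      return(new_rule_not(parse_factor()))
    }
    if (tok$type == "(") {
      advance()
      inner <- parse_expr()
      close <- peek()
      if (is.null(close) || close$type != ")") expect_fail("')'")
      advance()
      return(inner)
    }
    if (tok$type == "ident") {
      advance()
      return(new_rule_ref(tok$text))
    }
    expect_fail("an identifier, '!' or '('")
  }

  out <- parse_expr()
  if (!is.null(peek())) expect_fail("end of expression")
  out
}

#' @rdname rule_expressions
#' @param x,e A `rule_expr` AST node.
#' @param ... Unused.
#' @export
format.rule_expr <- function(x, ...) {
  fmt <- function(node, parent_prec) {
    prec <- switch(node$type, ref = 4L, not = 3L, and = 2L, or = 1L)
    s <- switch(node$type,
      ref = node$name,
      not = paste0("!", fmt(node$x, 3L)),
      and = paste(vapply(node$args, fmt, "", 2L), collapse = " & "),
      or  = paste(vapply(node$args, fmt, "", 1L), collapse = " | ")
    )
    if (prec < parent_prec) paste0("(", s, ")") else s
  }
  fmt(x, 0L)
}

#' @export
print.rule_expr <- function(x, ...) {
  cat("<rule expression> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @rdname rule_expressions
#' @export
rule_expr_vars <- function(e) {
  switch(e$type,
    ref = e$name,
    not = rule_expr_vars(e$x),
    unique(unlist(lapply(e$args, rule_expr_vars)))
  )
}

# TRUE if the expression contains no NOT node (monotone in gene presence)
rule_expr_is_monotone <- function(e) {
  switch(e$type,
    ref = TRUE,
    not = FALSE,
    all(vapply(e$args, rule_expr_is_monotone, logical(1L)))
  )
}

# Evaluate an AST against a named logical environment (list or env)
rule_expr_eval <- function(e, values) {
  switch(e$type,
    ref = {
      v <- values[[e$name]]
      if (is.null(v) || is.na(v)) {
        stop(sprintf("unresolved reference '%s' during evaluation", e$name),
             call. = FALSE)
      }
      isTRUE(v)
    },
    not = !rule_expr_eval(e$x, values),
    and = all(vapply(e$args, rule_expr_eval, logical(1L), values)),
    or  = any(vapply(e$args, rule_expr_eval, logical(1L), values))
  )
}
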