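#' @keywords internal
"_PACKAGE"

## Boolean rule expressions ---------------------------------------------------
##
## A rule is a finite tree of operators over node identifiers:
##   var(name), const(0/1), not(arg), and(args), or(args)
## AND and OR are n-ary and always flattened, so associativity never
## distinguishes two trees and identical() is a sound equality test.

bool_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(type = "var", name = name), class = "bool_expr")
}

bool_const <- function(value) {
  value <- as.integer(value)
  stopifnot(value %in% c(0L, 1L))
  structure(list(type = "const", value = value), class = "bool_expr")
}

bool_not <- function(arg) {
  stopifnot(inherits(arg, "bool_expr"))
  structure(list(type = "not", arg = arg), class = "bool_expr")
}

bool_nary <- function(type, args) {
  stopifnot(type %in% c("and", "or"), length(args) >= 1L)
  flat <- list()
  for (a in args) {
    stopifnot(inherits(a, "bool_expr"))
    if (a$type == type) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  if (length(flat) == 1L) return(flat[[1L]])
  structure(list(type = type, args = flat), class = "bool_expr")
}

bool_and <- function(...) bool_nary("and", list(...))
bool_or <- function(...) bool_nary("or", list(...))

#' Free variables of a rule expression
#'
#' @param expr A `bool_expr` as returned by [parse_rule()].
#' @return Character vector of node identifiers referenced by `expr`,
#'   in first-appearance order.
#' @export
free_variables <- function(expr) {
  stopifnot(inherits(expr, "bool_expr"))
  out <- character(0)
  walk <- function(e) {
    switch(e$type,
      var = out[[length(out) + 1L]] <<- e$name,
      const = NULL,
      not = walk(e$arg),
      and = ,
      or = for (a in e$args) walk(a)
    )
    invisible(NULL)
  }
  walk(expr)
  unique(out)
}

## Convert an expression to an R language object (`!`, `&`, `|` over node
## names).  Evaluating the language object in an environment whose bindings
## are logical vectors gives vectorized rule evaluation for free.
expr_to_lang <- function(expr) {
  switch(expr$type,
    var = as.name(expr$name),
    const = expr$value == 1L,
    not = call("!", expr_to_lang(expr$arg)),
    and = ,
    or = {
      op <- if (expr$type == "and") "&" else "|"
      langs <- lapply(expr$args, expr_to_lang)
      out <- langs[[1L]]
      for (k in seq_along(langs)[-1L]) out <- call(op, out, langs[[k]])
      out
    }
  )
}

#' Evaluate a rule under a total assignment
#'
#' @param expr A `bool_expr`.
#' @param assignment Named vector (or list) of 0/1 values covering all free
#'   variables of `expr`.
#' @return A single bit, 0 or 1.
#' @export
evaluate_rule <- function(expr, assignment) {
  vars <- free_variables(expr)
  missing <- setdiff(vars, names(assignment))
  if (length(missing) > 0L) {
    stop("assignment is missing variable(s): ", paste(missing, collapse = ", "))
  }
  env <- lapply(as.list(assignment), function(v) as.logical(v))
  as.integer(eval(expr_to_lang(expr), envir = env))
}

## Tokenizer ------------------------------------------------------------------

tokenize_rule <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch %in% c("(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
    } else if (ch %in% c("&", "|", "!")) {
      type <- c("&" = "and", "|" = "or", "!" = "not")[[ch]]
      tokens[[length(tokens) + 1L]] <- list(type = type, pos = i)
      i <- i + 1L
    } else if (grepl("^[A-Za-z0-9_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_]$", substr(text, j, j))) j <- j + 1L
      word <- substr(text, i, j - 1L)
      lw <- tolower(word)
      type <- if (lw %in% c("and", "or", "not")) lw else "ident"
      tokens[[length(tokens) + 1L]] <- list(type = type, value = word, pos = i)
      i <- j
    } else {
      stop(sprintf("syntax error at position %d: unexpected character '%s'", i, ch))
    }
  }
  tokens
}

## Strip parenthetical annotations such as "(secreted)" or
## "(also known as CSF-1)".  A parenthesized group is an annotation exactly
## when it directly follows an identifier; operator-led groups like
## "not (FCGR)" and grouping parentheses at the start of a rule are kept.
strip_annotations <- function(text) {
  pat <- "([A-Za-z0-9_]+)[ \t]*\\([^()]*\\)"
  repeat {
    ms <- gregexpr(pat, text)[[1L]]
    if (ms[1L] == -1L) return(text)
    lens <- attr(ms, "match.length")
    changed <- FALSE
    for (k in rev(seq_along(ms))) {  # right-to-left keeps earlier offsets valid
      frag <- substr(text, ms[k], ms[k] + lens[k] - 1L)
      word <- sub("^([A-Za-z0-9_]+).*$", "\\1", frag)
      if (!(tolower(word) %in% c("and", "or", "not"))) {
        text <- paste0(substr(text, 1L, ms[k] - 1L), word,
                       substr(text, ms[k] + lens[k], nchar(text)))
        changed <- TRUE
      }
    }
    if (!changed) return(text)
  }
}

## Recursive-descent parser.
##
## standard dialect:  NOT > AND > OR (the BoolNet convention).
## grouped dialect:   AND and OR share one precedence level and associate to
##   the left, so an un-parenthesized chain "X1 or ... or Xk and not Y" groups
##   as (X1 | ... | Xk) & !Y.  Fully parenthesized rules parse identically in
##   both dialects.
parse_tokens <- function(tokens, dialect) {
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() {
    tk <- tokens[[pos]]
    pos <<- pos + 1L
    tk
  }
  expect <- function(type) {
    tk <- peek()
    if (is.null(tk) || tk$type != type) {
      at <- if (is.null(tk)) "end of input" else sprintf("position %d", tk$pos)
      stop(sprintf("syntax error at %s: expected '%s'", at, type))
    }
    advance()
  }

  parse_primary <- function() {
    tk <- peek()
    if (is.null(tk)) stop("syntax error at end of input: expected operand")
    if (tk$type == "ident") {
      advance()
      if (tk$value %in% c("0", "1")) return(bool_const(as.integer(tk$value)))
      if (grepl("^[0-9]+$", tk$value)) {
        stop(sprintf("syntax error at position %d: unknown constant '%s'",
                     tk$pos, tk$value))
      }
      return(bool_var(tk$value))
    }
    if (tk$type == "not") {
      advance()
      return(bool_not(parse_primary()))
    }
    if (tk$type == "(") {
      advance()
      e <- parse_expr()
      expect(")")
      return(e)
    }
    stop(sprintf("syntax error at position %d: unexpected '%s'", tk$pos, tk$type))
  }

  parse_and <- function() {
    e <- parse_primary()
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      e <- bool_nary("and", list(e, parse_primary()))
    }
    e
  }

  parse_expr_standard <- function() {
    e <- parse_and()
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      e <- bool_nary("or", list(e, parse_and()))
    }
    e
  }

  parse_expr_grouped <- function() {
    e <- parse_primary()
    while (!is.null(peek()) && peek()$type %in% c("and", "or")) {
      op <- advance()$type
      e <- bool_nary(op, list(e, parse_primary()))
    }
    e
  }

  parse_expr <- if (dialect == "grouped") parse_expr_grouped else parse_expr_standard

  e <- parse_expr()
  if (!is.null(peek())) {
    stop(sprintf("syntax error at position %d: unexpected trailing '%s'",
                 peek()$pos, peek()$type))
  }
  e
}

#' Parse a Boolean update rule
#'
#' Rules use the operators `and`, `or`, `not` (case-insensitive; `&`, `|`,
#' `!` are accepted synonyms), parentheses, the constants `0` and `1`, and
#' node identifiers.  Parenthetical annotations that directly follow an
#' identifier -- e.g. `"IL10s (secreted)"` -- are stripped before parsing.
#'
#' Published rule tables often leave chains such as
#' `"A or B and not (C)"` un-parenthesized, and two readings are defensible.
#' The `dialect` argument makes the choice explicit:
#' \describe{
#'   \item{`"standard"`}{`not` binds tighter than `and`, which binds tighter
#'     than `or` -- so `A or (B and not C)`.  This is the convention of the
#'     usual Boolean-network file formats.}
#'   \item{`"grouped"`}{`and` and `or` share one precedence level and
#'     associate left -- so `(A or B) and not C`, reading the trailing
#'     `and not (...)` as a guard on the whole disjunction.}
#' }
#' Fully parenthesized rules parse identically under both dialects.
#'
#' @param text Rule string.
#' @param dialect `"standard"` or `"grouped"`.
#' @return A `bool_expr` with attribute `ambiguous` (TRUE when the two
#'   dialects disagree on this rule).
#' @examples
#' parse_rule("LPS and not (FCGR)")
#' parse_rule("IL4RA or MCSFR or ERK and not (STAT6)", dialect = "grouped")
#' @export
parse_rule <- function(text, dialect = c("standard", "grouped")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- tokenize_rule(strip_annotations(text))
  if (length(tokens) == 0L) stop("syntax error: empty rule")
  e <- parse_tokens(tokens, dialect)
  other <- parse_tokens(tokens, setdiff(c("standard", "grouped"), dialect))
  attr(e, "ambiguous") <- !identical(strip_attr(e), strip_attr(other))
  e
}

strip_attr <- function(e) {
  attr(e, "ambiguous") <- NULL
  e
}

#' Do the two parsing dialects disagree on a rule?
#'
#' @inheritParams parse_rule
#' @return TRUE if `"standard"` and `"grouped"` yield different trees.
#' @export
dialect_divergent <- function(text) {
  isTRUE(attr(parse_rule(text, "standard"), "ambiguous"))
}

#' Serialize a rule to canonical, fully parenthesized text
#'
#' The canonical form round-trips: `parse_rule(serialize_rule(e), d)`
#' reproduces `e` under either dialect.
#'
#' @param expr A `bool_expr`.
#' @return A rule string such as `"(LPS and (not FCGR))"`.
#' @export
serialize_rule <- function(expr) {
  stopifnot(inherits(expr, "bool_expr"))
  switch(expr$type,
    var = expr$name,
    const = as.character(expr$value),
    not = paste0("(not ", serialize_rule(expr$arg), ")"),
    and = ,
    or = paste0("(", paste(vapply(expr$args, serialize_rule, character(1)),
                           collapse = paste0(" ", expr$type, " ")), ")")
  )
}

#' @export
print.bool_expr <- function(x, ...) {
  cat(serialize_rule(x), "\n")
  invisible(x)
}

## Simplify an expression under a partial assignment of constants.
## Returns a bool_expr; used by constant propagation in condition_network().
simplify_expr <- function(expr, known) {
  switch(expr$type,
    var = {
      if (expr$name %in% names(known)) bool_const(known[[expr$name]]) else expr
    },
    const = expr,
    not = {
      a <- simplify_expr(expr$arg, known)
      if (a$type == "const") bool_const(1L - a$value) else bool_not(a)
    },
    and = ,
    or = {
      absorbing <- if (expr$type == "and") 0L else 1L
      args <- list()
      for (a in expr$args) {
        s <- simplify_expr(a, known)
        if (s$type == "const") {
          if (s$value == absorbing) return(bool_const(absorbing))
          next  # identity element, drop
        }
        args[[length(args) + 1L]] <- s
      }
      if (length(args) == 0L) return(bool_const(1L - absorbing))
      bool_nary(expr$type, args)
    }
  )
}
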