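# Class expressions for logical definitions: the EL-style fragment of class
# atoms, existential restrictions (`relation some filler`) and intersections
# (`a and b and c`). This is the fragment every shipped design-pattern schema
# lives in; the classifier reasons over it structurally.

ex_atom <- function(curie) list(kind = "atom", curie = curie)
ex_slot <- function(var) list(kind = "slot", var = var)
ex_some <- function(relation, filler) list(kind = "some", relation = relation,
                                           filler = filler)
ex_and <- function(args) list(kind = "and", args = args)

# Tokenize a Manchester-like expression string: quoted names, bare names,
# CURIEs, %s slots, parentheses, keywords `some` and `and`.
tokenize_expression <- function(text) {
  pat <- "'[^']*'|%s|\\(|\\)|[A-Za-z_][A-Za-z0-9_:.-]*"
  m <- gregexpr(pat, text)[[1]]
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  rest <- gsub(pat, "", text)
  if (grepl("[^ \t\n]", rest))
    stop("unparseable characters in expression: ",
         gsub("[ \t\n]", "", rest), call. = FALSE)
  toks
}

#' Parse a logical-definition expression
#'
#' Grammar (Manchester-like, restricted to the EL fragment the pattern
#' schemas use):
#' `expr := primary ('and' primary)*`;
#' `primary := '(' expr ')' | relation 'some' primary | atom | '%s'`.
#' Quoted or bare names resolve to CURIEs through `classes`; names followed
#' by `some` must be declared in `relations` and are kept as relation names
#' (mapped to CURIEs only at serialization). `%s` slots consume entries of
#' `vars` in order.
#'
#' @param text expression string.
#' @param classes named character vector/list mapping class names to CURIEs.
#' @param relations named character vector/list of declared relation names.
#' @param vars character vector of variable names, one per `%s` slot in
#'   textual order.
#' @return an expression tree (nested lists with a `kind` field).
#' @export
parse_expression <- function(text, classes = list(), relations = list(),
                             vars = character(0)) {
  toks <- tokenize_expression(text)
  pos <- 1L
  slot_i <- 0L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  expect <- function(t) {
    if (!identical(peek(), t))
      stop("expected '", t, "' but found '", peek() %||% "<end>",
           "' in expression: ", text, call. = FALSE)
    advance()
  }
  unquote <- function(t) if (grepl("^'", t)) substr(t, 2L, nchar(t) - 1L) else t

  parse_primary <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of expression: ", text, call. = FALSE)
    if (t == "(") {
      advance()
      e <- parse_expr()
      expect(")")
      return(e)
    }
    if (t == "%s") {
      advance()
      slot_i <<- slot_i + 1L
      if (slot_i > length(vars))
        stop("more %s slots than variable references in expression: ", text,
             call. = FALSE)
      return(ex_slot(vars[slot_i]))
    }
    advance()
    name <- unquote(t)
    if (identical(peek(), "some")) {
      advance()
      if (!name %in% names(relations))
        stop("undeclared relation '", name, "' in expression", call. = FALSE)
      return(ex_some(name, parse_primary()))
    }
    if (is_curie(name)) return(ex_atom(name))
    if (!name %in% names(classes))
      stop("undeclared class '", name, "' in expression", call. = FALSE)
    ex_atom(as.character(classes[[name]]))
  }

  parse_expr <- function() {
    args <- list(parse_primary())
    while (identical(peek(), "and")) {
      advance()
      args[[length(args) + 1L]] <- parse_primary()
    }
    if (length(args) == 1L) args[[1L]] else ex_and(args)
  }

  e <- parse_expr()
  if (!is.na(peek()))
    stop("trailing tokens after expression: ", peek(), call. = FALSE)
  if (slot_i != length(vars))
    stop("expression has ", slot_i, " %s slot(s) but ", length(vars),
         " variable reference(s)", call. = FALSE)
  e
}

# Replace slots by bound CURIEs.
ground_expression <- function(expr, bindings) {
  switch(expr$kind,
    atom = expr,
    slot = {
      b <- bindings[[expr$var]]
      if (is.null(b)) stop("unbound variable '", expr$var, "'", call. = FALSE)
      ex_atom(as.character(b))
    },
    some = ex_some(expr$relation, ground_expression(expr$filler, bindings)),
    and = ex_and(lapply(expr$args, ground_expression, bindings = bindings)),
    stop("unknown expression kind: ", expr$kind, call. = FALSE))
}

expression_is_ground <- function(expr) {
  switch(expr$kind,
    atom = TRUE,
    slot = FALSE,
    some = expression_is_ground(expr$filler),
    and = all(vapply(expr$args, expression_is_ground, logical(1))))
}

expression_slots <- function(expr) {
  switch(expr$kind,
    atom = character(0),
    slot = expr$var,
    some = expression_slots(expr$filler),
    and = unlist(lapply(expr$args, expression_slots), use.names = FALSE))
}

expression_curies <- function(expr) {
  switch(expr$kind,
    atom = expr$curie,
    slot = character(0),
    some = expression_curies(expr$filler),
    and = unique(unlist(lapply(expr$args, expression_curies),
                        use.names = FALSE)))
}

#' Canonical string form of an expression
#'
#' Deterministic serialization: intersection conjuncts are sorted, so two
#' structurally identical ground expressions always render identically.
#' Used for duplicate-logical-definition detection and for the JSON release.
#'
#' @param expr an expression tree.
#' @param relations optional named map from relation names to CURIEs; when
#'   given, relation names are replaced by their CURIEs.
#' @return a single string.
#' @export
expression_string <- function(expr, relations = NULL) {
  rec <- function(e) {
    switch(e$kind,
      atom = e$curie,
      slot = paste0("?", e$var),
      some = {
        rel <- if (!is.null(relations) && e$relation %in% names(relations))
          as.character(relations[[e$relation]]) else e$relation
        f <- rec(e$filler)
        if (e$filler$kind %in% c("and", "some")) f <- paste0("(", f, ")")
        paste0(rel, " some ", f)
      },
      and = {
        parts <- sort_c(vapply(e$args, function(a) {
          s <- rec(a)
          if (a$kind == "and") paste0("(", s, ")") else s
        }, character(1)))
        paste(parts, collapse = " and ")
      })
  }
  rec(expr)
}
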