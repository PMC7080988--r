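# Boolean expression handling: parsing the .bnet dialect (!, &, | and
# parentheses, plus the literals 0 and 1), compilation to postfix programs,
# and evaluation over logical vectors.

# Postfix opcodes shared with the C++ engine. Non-negative integers push the
# value of the node with that 0-based index; negative integers are operators.
OP_NOT <- -1L
OP_AND <- -2L
OP_OR  <- -3L
OP_ZERO <- -4L
OP_ONE  <- -5L

#' @keywords internal
tokenize_bool_expr <- function(text) {
  # Accept both the ASCII .bnet operators and the word forms NOT/AND/OR.
  pattern <- "[A-Za-z_][A-Za-z0-9_]*|[01]|\\(|\\)|!|&|\\|"
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("empty Boolean expression", call. = FALSE)
  toks <- regmatches(text, gregexpr(pattern, text, perl = TRUE))[[1]]
  stripped <- gsub(pattern, "", text, perl = TRUE)
  if (grepl("[^[:space:]]", stripped)) {
    bad <- regmatches(stripped, regexpr("[^[:space:]]+", stripped))
    stop(sprintf("unexpected token '%s' in expression '%s'", bad, text),
         call. = FALSE)
  }
  # Map word operators onto symbols
  up <- toupper(toks)
  toks[up == "NOT"] <- "!"
  toks[up == "AND"] <- "&"
  toks[up == "OR"] <- "|"
  toks
}

# Recursive-descent parser: expr := term ('|' term)* ; term := factor
# ('&' factor)* ; factor := '!' factor | '(' expr ')' | name | 0 | 1.
# Returns an AST of nested lists: list(op = "var"/"not"/"and"/"or"/"const", ...)
#' @keywords internal
parse_bool_expr <- function(text) {
  toks <- tokenize_bool_expr(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop(sprintf("unexpected end of expression '%s'", text),
                       call. = FALSE)
    if (t == "!") {
      advance()
      return(list(op = "not", x = parse_factor()))
    }
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")"))
        stop(sprintf("missing ')' in expression '%s'", text), call. = FALSE)
      advance()
      return(e)
    }
    if (t %in% c("0", "1")) {
      advance()
      return(list(op = "const", value = as.integer(t)))
    }
    if (grepl("^[A-Za-z_]", t)) {
      advance()
      return(list(op = "var", name = t))
    }
    stop(sprintf("unexpected token '%s' in expression '%s'", t, text),
         call. = FALSE)
  }
  parse_term <- function() {
    e <- parse_factor()
    while (identical(peek(), "&")) {
      advance()
      e <- list(op = "and", x = e, y = parse_factor())
    }
    e
  }
  parse_expr <- function() {
    e <- parse_term()
    while (identical(peek(), "|")) {
      advance()
      e <- list(op = "or", x = e, y = parse_term())
    }
    e
  }
  e <- parse_expr()
  if (!is.na(peek()))
    stop(sprintf("trailing token '%s' in expression '%s'", peek(), text),
         call. = FALSE)
  e
}

#' @keywords internal
ast_vars <- function(ast) {
  switch(ast$op,
         var = ast$name,
         const = character(0),
         not = ast_vars(ast$x),
         unique(c(ast_vars(ast$x), ast_vars(ast$y))))
}

# Compile an AST into a postfix integer program against a node-name vector.
#' @keywords internal
ast_to_postfix <- function(ast, node_names) {
  rec <- function(a) {
    switch(a$op,
           var = {
             i <- match(a$name, node_names)
             if (is.na(i))
               stop(sprintf("unknown node '%s' in expression", a$name),
                    call. = FALSE)
             i - 1L
           },
           const = if (a$value == 1L) OP_ONE else OP_ZERO,
           not = c(rec(a$x), OP_NOT),
           and = c(rec(a$x), rec(a$y), OP_AND),
           or = c(rec(a$x), rec(a$y), OP_OR))
  }
  rec(ast)
}

# Evaluate a postfix program; `values` is a named list (or environment-like
# list) mapping node name -> logical vector. Used for truth-table construction
# and as the plain-R reference evaluator in tests.
#' @keywords internal
eval_postfix <- function(program, node_names, values) {
  stack <- vector("list", length(program))
  top <- 0L
  for (op in program) {
    if (op >= 0L) {
      top <- top + 1L
      stack[[top]] <- values[[node_names[op + 1L]]]
    } else if (op == OP_NOT) {
      stack[[top]] <- !stack[[top]]
    } else if (op == OP_AND) {
      stack[[top - 1L]] <- stack[[top - 1L]] & stack[[top]]
      top <- top - 1L
    } else if (op == OP_OR) {
      stack[[top - 1L]] <- stack[[top - 1L]] | stack[[top]]
      top <- top - 1L
    } else if (op == OP_ZERO) {
      top <- top + 1L
      stack[[top]] <- FALSE
    } else if (op == OP_ONE) {
      top <- top + 1L
      stack[[top]] <- TRUE
    }
  }
  stack[[1L]]
}

# Render an AST back to the .bnet dialect with minimal parentheses.
#' @keywords internal
ast_to_bnet <- function(ast) {
  prec <- c(or = 1L, and = 2L, not = 3L, var = 4L, const = 4L)
  wrap <- function(child, parent_prec) {
    txt <- rec(child)
    if (prec[[child$op]] < parent_prec) paste0("(", txt, ")") else txt
  }
  rec <- function(a) {
    switch(a$op,
           var = a$name,
           const = as.character(a$value),
           not = paste0("!", wrap(a$x, prec[["not"]])),
           and = paste(wrap(a$x, prec[["and"]]), "&", wrap(a$y, prec[["and"]])),
           or = paste(wrap(a$x, prec[["or"]]), "|", wrap(a$y, prec[["or"]])))
  }
  rec(ast)
}
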