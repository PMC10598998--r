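# displayif expressions ------------------------------------------------------
#
# Surface syntax (v1 dialect): <displayif=func(arg, ...)> where func is one of
# equals, notEquals, exists, greaterThan, lessThan, and, or. Arguments are
# question-id references (bare, e.g. DECON1), numeric literals, quoted string
# literals ('...' or "..."), or nested calls. Parsed into a small AST:
# list(func = <name>, args = <list>) of class "quest_displayif"; leaf args are
# list(ref = id) or list(lit = value).

QST_DISPLAYIF_FUNCS <- c(
  "equals", "notEquals", "exists", "greaterThan", "lessThan", "and", "or"
)

#' Parse a displayif expression
#'
#' @param src Expression source, e.g. `"and(equals(Q1, 2), exists(TEMP))"`.
#' @param line Source line used in parse-error messages.
#' @return A `quest_displayif` AST node.
#' @keywords internal
qst_parse_displayif <- function(src, line = NA_integer_) {
  cur <- new.env(parent = emptyenv())
  cur$s <- src
  cur$i <- 1L
  cur$line <- if (is.na(line)) 0L else line

  expr <- qdi_expr(cur)
  qdi_ws(cur)
  if (cur$i <= nchar(cur$s)) {
    qst_abort_parse(
      sprintf("trailing characters in displayif expression: '%s'",
              substr(cur$s, cur$i, nchar(cur$s))),
      cur$line
    )
  }
  expr
}

qdi_ws <- function(cur) {
  while (cur$i <= nchar(cur$s) && grepl("^\\s$", substr(cur$s, cur$i, cur$i))) {
    cur$i <- cur$i + 1L
  }
}

qdi_peek <- function(cur) {
  if (cur$i > nchar(cur$s)) "" else substr(cur$s, cur$i, cur$i)
}

qdi_take_while <- function(cur, pattern) {
  start <- cur$i
  while (cur$i <= nchar(cur$s) && grepl(pattern, substr(cur$s, cur$i, cur$i))) {
    cur$i <- cur$i + 1L
  }
  substr(cur$s, start, cur$i - 1L)
}

qdi_expr <- function(cur) {
  qdi_ws(cur)
  word <- qdi_take_while(cur, "^[A-Za-z0-9_#]$")
  if (!nzchar(word)) {
    qst_abort_parse(
      sprintf("expected a displayif function name in '%s'", cur$s), cur$line
    )
  }
  qdi_ws(cur)
  if (qdi_peek(cur) != "(") {
    qst_abort_parse(
      sprintf("expected '(' after displayif function '%s'", word), cur$line
    )
  }
  if (!word %in% QST_DISPLAYIF_FUNCS) {
    qst_abort_parse(sprintf("unknown displayif function '%s'", word), cur$line)
  }
  cur$i <- cur$i + 1L # consume '('
  args <- list()
  repeat {
    qdi_ws(cur)
    if (qdi_peek(cur) == ")" && length(args) == 0L) {
      break
    }
    args[[length(args) + 1L]] <- qdi_arg(cur)
    qdi_ws(cur)
    ch <- qdi_peek(cur)
    if (ch == ",") {
      cur$i <- cur$i + 1L
    } else if (ch == ")") {
      break
    } else {
      qst_abort_parse(
        sprintf("expected ',' or ')' in displayif arguments of '%s'", word),
        cur$line
      )
    }
  }
  if (qdi_peek(cur) != ")") {
    qst_abort_parse("unterminated displayif argument list", cur$line)
  }
  cur$i <- cur$i + 1L
  qdi_check_arity(word, length(args), cur$line)
  structure(list(func = word, args = args), class = "quest_displayif")
}

qdi_check_arity <- function(func, n, line) {
  ok <- switch(func,
    and = ,
    or = n >= 2L,
    exists = n == 1L,
    n == 2L
  )
  if (!ok) {
    qst_abort_parse(
      sprintf("displayif function '%s' does not take %d argument(s)", func, n),
      line
    )
  }
}

qdi_string <- function(cur, quote) {
  cur$i <- cur$i + 1L # opening quote
  start <- cur$i
  while (cur$i <= nchar(cur$s) && substr(cur$s, cur$i, cur$i) != quote) {
    cur$i <- cur$i + 1L
  }
  if (cur$i > nchar(cur$s)) {
    qst_abort_parse("unterminated string literal in displayif", cur$line)
  }
  out <- substr(cur$s, start, cur$i - 1L)
  cur$i <- cur$i + 1L # closing quote
  out
}

qdi_arg <- function(cur) {
  qdi_ws(cur)
  ch <- qdi_peek(cur)
  if (ch %in% c("'", '"')) {
    return(list(lit = qdi_string(cur, ch)))
  }
  if (grepl("^[-0-9.]$", ch)) {
    num <- qdi_take_while(cur, "^[-0-9.eE+]$")
    val <- suppressWarnings(as.numeric(num))
    if (is.na(val)) {
      qst_abort_parse(sprintf("malformed numeric literal '%s'", num), cur$line)
    }
    return(list(lit = val))
  }
  # bareword: either a nested call or a question-id reference
  save <- cur$i
  word <- qdi_take_while(cur, "^[A-Za-z0-9_#]$")
  if (!nzchar(word)) {
    qst_abort_parse("expected a displayif argument", cur$line)
  }
  qdi_ws(cur)
  if (qdi_peek(cur) == "(") {
    cur$i <- save
    return(qdi_expr(cur))
  }
  if (!qst_is_valid_id(word)) {
    qst_abort_parse(
      sprintf("'%s' is neither a question id nor a literal (quote strings)",
              word),
      cur$line
    )
  }
  list(ref = word)
}

# Canonical serialization of an AST back to the surface syntax.
qst_deparse_displayif <- function(expr) {
  args <- vapply(expr$args, function(a) {
    if (inherits(a, "quest_displayif")) {
      qst_deparse_displayif(a)
    } else if (!is.null(a$ref)) {
      a$ref
    } else if (is.character(a$lit)) {
      sprintf("'%s'", a$lit)
    } else {
      format(a$lit, scientific = FALSE)
    }
  }, character(1))
  sprintf("%s(%s)", expr$func, paste(args, collapse = ","))
}

# Question ids referenced anywhere in an expression (used by the validator's
# jump-graph only indirectly; references may also name prefill keys, so a
# reference to an id absent from the module is not an error).
qst_displayif_refs <- function(expr) {
  refs <- character(0)
  for (a in expr$args) {
    if (inherits(a, "quest_displayif")) {
      refs <- c(refs, qst_displayif_refs(a))
    } else if (!is.null(a$ref)) {
      refs <- c(refs, a$ref)
    }
  }
  unique(refs)
}
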