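# Independent brute-force oracle: a deliberately naive re-implementation of
# the navigation semantics, written directly from the stack rules and kept
# free of any engine code. Used to cross-check (path, payload) pairs by
# exhaustive enumeration of answer combinations on small modules.

oracle_eval_displayif <- function(expr, resp) {
  get_ref <- function(a) if (!is.null(a$ref)) resp[[a$ref]] else a$lit
  if (expr$func == "exists") {
    return(!is.null(get_ref(expr$args[[1]])))
  }
  a <- get_ref(expr$args[[1]])
  b <- get_ref(expr$args[[2]])
  if (is.null(a) || is.null(b)) return(FALSE)
  eq <- isTRUE(suppressWarnings(any(as.numeric(a) == as.numeric(b)))) ||
    any(as.character(a) == as.character(b))
  switch(expr$func,
    equals = eq,
    notEquals = !eq,
    greaterThan = as.numeric(a) > as.numeric(b),
    lessThan = as.numeric(a) < as.numeric(b),
    stop("oracle: unsupported displayif function ", expr$func)
  )
}

oracle_type <- function(s) {
  if (is.numeric(s)) return(s)
  if (grepl("^-?(0|[1-9][0-9]*)$", s)) as.numeric(s) else s
}

# answers: named list id -> value(s). Returns list(path=, payload=).
oracle_walk <- function(module, answers, max_steps = 1000L) {
  ids <- vapply(module$questions, `[[`, character(1), "id")
  q_at <- function(id) module$questions[[match(id, ids)]]
  succ <- function(id) {
    k <- match(id, ids) + 1L
    if (k > length(ids)) "END" else ids[k]
  }
  stack <- character(0)
  pop_or_next <- function(id) {
    if (length(stack) > 0L) {
      top <- stack[length(stack)]
      stack <<- stack[-length(stack)]
      top
    } else {
      succ(id)
    }
  }
  cur <- ids[1]
  path <- character(0)
  resp <- list()
  for (step in seq_len(max_steps)) {
    q <- q_at(cur)
    if (cur != "END" && !is.null(q$displayif) &&
        !oracle_eval_displayif(q$displayif, resp)) {
      cur <- pop_or_next(cur)
      next
    }
    path <- c(path, cur)
    if (cur == "END") {
      payload <- list()
      for (q2 in module$questions) {
        id <- q2$id
        if (is.null(resp[[id]])) next
        if (length(q2$options) > 0L && q2$options[[1]]$kind == "checkbox") {
          vals <- vapply(q2$options, `[[`, character(1), "value")
          payload[[id]] <- lapply(vals[vals %in% resp[[id]]], oracle_type)
        } else {
          payload[[id]] <- oracle_type(resp[[id]])
        }
      }
      if (length(payload) > 0L) {
        payload <- payload[sort(names(payload), method = "radix")]
      }
      return(list(path = path, payload = payload))
    }
    a <- answers[[cur]]
    has_spec <- length(q$options) > 0L || length(q$inputs) > 0L
    if (is.null(a) && has_spec) {
      # no response: #NR routing, else behave as an empty selection
      if (!is.null(q$nr_target)) {
        cur <- q$nr_target
        next
      }
      if (!is.null(q$default_next)) stack <- c(stack, q$default_next)
      cur <- pop_or_next(cur)
      next
    }
    if (has_spec) {
      if (length(q$options) > 0L && q$options[[1]]$kind == "checkbox") {
        resp[[cur]] <- as.character(unlist(a))
      } else if (length(q$inputs) > 0L && q$inputs[[1]]$kind == "numeric") {
        resp[[cur]] <- as.numeric(a)
      } else {
        resp[[cur]] <- as.character(a)
      }
    }
    if (!is.null(q$default_next)) stack <- c(stack, q$default_next)
    if (length(q$options) > 0L && q$options[[1]]$kind == "radio" &&
        !is.null(a)) {
      sel <- q$options[[match(as.character(a),
                              vapply(q$options, `[[`, character(1), "value"))]]
      if (!is.null(sel$jump_target)) {
        cur <- sel$jump_target
        next
      }
    }
    if (length(q$options) > 0L && q$options[[1]]$kind == "checkbox" &&
        !is.null(a)) {
      sel_vals <- as.character(unlist(a))
      for (o in rev(q$options)) {
        if (o$value %in% sel_vals && !is.null(o$jump_target)) {
          stack <- c(stack, o$jump_target)
        }
      }
    }
    cur <- pop_or_next(cur)
  }
  stop("oracle: step limit reached")
}

# All answer combinations for a small module: radio -> each value,
# checkbox -> every subset (incl. empty = skip-like NULL is separate),
# numeric -> bounds, text-ish -> one token, info -> nothing to choose.
oracle_answer_space <- function(module) {
  choices <- list()
  for (q in module$questions) {
    if (q$id == "END") next
    vals <- vapply(q$options, `[[`, character(1), "value")
    if (length(q$options) > 0L && q$options[[1]]$kind == "radio") {
      choices[[q$id]] <- as.list(vals)
    } else if (length(q$options) > 0L) {
      subsets <- list(character(0))
      for (v in vals) {
        subsets <- c(subsets, lapply(subsets, function(s) c(s, v)))
      }
      choices[[q$id]] <- subsets[-1] # non-empty selections
    } else if (length(q$inputs) > 0L && q$inputs[[1]]$kind == "numeric") {
      f <- q$inputs[[1]]
      choices[[q$id]] <- as.list(unique(c(f$min %||% 0, f$max %||% 1)))
    } else if (length(q$inputs) > 0L) {
      choices[[q$id]] <- list(switch(q$inputs[[1]]$kind,
        date = "2021-06-15", tel = "301-555-0142", ssn = "078-05-1120",
        "free text"
      ))
    }
  }
  choices
}

# Cartesian product of the answer space as a list of named answer lists.
oracle_enumerate <- function(module, limit = 20000L) {
  choices <- oracle_answer_space(module)
  n <- prod(vapply(choices, length, integer(1)))
  stopifnot(n <= limit)
  grid <- expand.grid(lapply(choices, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r) {
    ans <- list()
    for (id in names(choices)) {
      ans[[id]] <- choices[[id]][[grid[r, id]]]
    }
    ans
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
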