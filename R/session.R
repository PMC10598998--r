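# Session engine -------------------------------------------------------------
#
# Navigation model: answering a question may push pending question ids onto a
# LIFO stack. A declared default-next is always pushed first; a selected
# radio option with an arrow transfers control directly; selected checkbox
# options push their arrow targets in reverse declaration order (so they pop
# in declaration order, ahead of the default-next). When nothing routes
# explicitly the stack is popped; when the stack is empty the next question
# is the one immediately following in document order. Questions whose
# displayif condition is false at arrival are skipped transparently and
# recorded nowhere.

#' Session configuration
#'
#' @param step_cap Maximum number of answered/skipped steps before the
#'   engine aborts, guarding against non-terminating skip logic. Default
#'   (`NULL`) resolves to 10 times the question count at session start.
#' @param allow_skip May a participant skip a question that declares no
#'   `#NR` routing? Default `FALSE` (such questions are required).
#' @return A `quest_config` list.
#' @export
qst_config <- function(step_cap = NULL, allow_skip = FALSE) {
  if (!is.null(step_cap) &&
      (!is.numeric(step_cap) || length(step_cap) != 1L || step_cap < 1)) {
    qst_abort("step_cap must be a single positive number or NULL",
              "quest_config_error")
  }
  structure(list(step_cap = step_cap, allow_skip = isTRUE(allow_skip)),
            class = "quest_config")
}

#' Start a questionnaire session
#'
#' @param module A `quest_module` that validates with zero errors.
#' @param prefill Named list of externally supplied values (e.g. age from
#'   the study record), available to displayif conditions and text piping.
#' @param config A [qst_config()].
#' @param on_complete Optional completion hook: a function of one argument
#'   that receives the response payload when [qst_finalize()] runs. This is
#'   the callback contract by which a study collects results; the engine
#'   itself does not decide where responses are stored.
#' @return A `quest_session` positioned at the first question whose
#'   displayif (if any) evaluates true, with an empty stack and no
#'   responses. If that first question is END the session starts finished.
#' @export
qst_session <- function(module, prefill = list(), config = qst_config(),
                        on_complete = NULL) {
  stopifnot(inherits(module, "quest_module"))
  diag <- qst_validate(module)
  if (any(diag$severity == "error")) {
    qst_abort(
      sprintf("module has %d validation error(s); first: %s",
              sum(diag$severity == "error"),
              diag$message[diag$severity == "error"][1]),
      "quest_invalid_module", diagnostics = diag
    )
  }
  cap <- config$step_cap %||% (10L * length(module$questions))
  state <- structure(
    list(
      module = module,
      step_cap = as.integer(ceiling(cap)),
      allow_skip = config$allow_skip,
      prefill = prefill,
      current_id = NA_character_,
      stack = character(0),
      responses = list(),
      finished = FALSE,
      steps = 0L,
      trail = character(0),
      on_complete = on_complete
    ),
    class = "quest_session"
  )
  qst_advance(state, qst_ids(module)[1])
}

# Move to `next_id`, transparently skipping displayif-false questions
# (pop stack / document fallthrough, nothing recorded), and set the
# finished flag on arrival at an answer-free END.
qst_advance <- function(state, next_id) {
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > state$step_cap + length(state$module$questions) + 1L) {
      qst_abort("step cap exceeded while skipping displayif questions",
                "quest_step_cap")
    }
    if (is.na(next_id)) {
      # ran off the end of the document with an empty stack
      next_id <- "END"
    }
    q <- qst_question(state$module, next_id)
    if (is.null(q)) {
      qst_abort(sprintf("navigation reached undefined question '%s'", next_id),
                "quest_invalid_module")
    }
    if (q$id != "END" && !is.null(q$displayif) &&
        !qst_evaluate_displayif(q$displayif, state$responses, state$prefill)) {
      res <- qst_pop_or_fallthrough(state, q)
      next_id <- res$id
      state <- res$state
      next
    }
    break
  }
  state$current_id <- next_id
  state$trail <- c(state$trail, next_id)
  q <- qst_question(state$module, next_id)
  if (q$id == "END" && length(q$options) == 0L && length(q$inputs) == 0L) {
    state$finished <- TRUE
  }
  state
}

# Pop the stack when non-empty, else fall through in document order.
qst_pop_or_fallthrough <- function(state, question) {
  if (length(state$stack) > 0L) {
    id <- state$stack[length(state$stack)]
    state$stack <- state$stack[-length(state$stack)]
  } else {
    id <- qst_successor(state$module, question$id)
  }
  list(id = id, state = state)
}

#' Submit an answer for the current question
#'
#' Validates the answer against the current question's response
#' specification, records it, and advances to the next question under the
#' stack semantics. For a question with neither options nor input fields
#' (informational text), pass `answer = NULL` to continue; nothing is
#' recorded.
#'
#' @param state A running `quest_session`.
#' @param answer For radio questions a single option value; for checkbox
#'   questions a vector of option values (document order of the selection
#'   does not matter — the payload preserves option declaration order); for
#'   numeric inputs a number within the declared closed interval
#'   `[min, max]`; for date `YYYY-MM-DD`; for tel `ddd-ddd-dddd`; for SSN
#'   `ddd-dd-dddd`; for text any single string.
#' @return The updated session.
#' @export
qst_submit <- function(state, answer = NULL) {
  stopifnot(inherits(state, "quest_session"))
  if (state$finished) {
    qst_abort("session already finished", "quest_session_finished")
  }
  q <- qst_question(state$module, state$current_id)
  rec <- qst_coerce_answer(q, answer)
  if (!is.null(rec)) {
    state$responses[[q$id]] <- rec
  }
  state <- qst_count_step(state)
  next_id <- qst_route(state, q, rec)
  qst_advance(next_id$state, next_id$id)
}

qst_count_step <- function(state) {
  state$steps <- state$steps + 1L
  if (state$steps > state$step_cap) {
    qst_abort(
      sprintf("step cap of %d exceeded (possible skip-logic cycle)",
              state$step_cap),
      "quest_step_cap"
    )
  }
  state
}

# Next-question computation after answering `q` with recorded answer `rec`.
qst_route <- function(state, q, rec) {
  # the default next question, when declared, is always pushed
  if (!is.null(q$default_next)) {
    state$stack <- c(state$stack, q$default_next)
  }
  kind <- if (length(q$options) > 0L) q$options[[1]]$kind else "none"
  if (kind == "radio" && !is.null(rec)) {
    sel <- Filter(function(o) o$value == rec, q$options)[[1]]
    if (!is.null(sel$jump_target)) {
      return(list(id = sel$jump_target, state = state))
    }
  } else if (kind == "checkbox" && !is.null(rec)) {
    # push selected arrows in reverse declaration order -> pop in order
    targets <- character(0)
    for (o in q$options) {
      if (o$value %in% rec && !is.null(o$jump_target)) {
        targets <- c(targets, o$jump_target)
      }
    }
    state$stack <- c(state$stack, rev(targets))
  }
  qst_pop_or_fallthrough(state, q)
}

# Validate and canonicalize a raw answer for question `q`.
# Returns NULL (record nothing) for informational questions.
qst_coerce_answer <- function(q, answer) {
  values <- vapply(q$options, `[[`, character(1), "value")
  kind <- if (length(q$options) > 0L) q$options[[1]]$kind else NULL

  if (is.null(kind) && length(q$inputs) == 0L) {
    if (!is.null(answer)) {
      qst_abort_answer("question takes no answer; pass NULL to continue", q$id)
    }
    return(NULL)
  }
  if (is.null(answer)) {
    qst_abort_answer("an answer is required (use qst_skip() to skip)", q$id)
  }

  if (identical(kind, "radio")) {
    ans <- as.character(unlist(answer, use.names = FALSE))
    if (length(ans) != 1L) {
      qst_abort_answer("radio questions take exactly one value", q$id)
    }
    if (!(ans %in% values)) {
      qst_abort_answer(
        sprintf("'%s' is not among the option values (%s)",
                ans, paste(values, collapse = ", ")),
        q$id
      )
    }
    return(ans)
  }
  if (identical(kind, "checkbox")) {
    ans <- as.character(unlist(answer, use.names = FALSE))
    unknown <- setdiff(ans, values)
    if (length(unknown) > 0L) {
      qst_abort_answer(
        sprintf("unknown option value(s): %s", paste(unknown, collapse = ", ")),
        q$id
      )
    }
    return(unique(ans))
  }

  # input fields; v1 blocks carry options xor inputs, and multi-input blocks
  # accept a single scalar per field in declaration order
  f <- q$inputs[[1]]
  ans <- answer
  if (length(ans) != 1L) {
    qst_abort_answer("input fields take a single scalar answer", q$id)
  }
  switch(f$kind,
    numeric = {
      num <- suppressWarnings(as.numeric(ans))
      if (is.na(num)) {
        qst_abort_answer(sprintf("'%s' is not numeric", ans), q$id)
      }
      if (!is.null(f$min) && num < f$min) {
        qst_abort_answer(
          sprintf("%s is below the minimum of %s", num, f$min), q$id
        )
      }
      if (!is.null(f$max) && num > f$max) {
        qst_abort_answer(
          sprintf("%s is above the maximum of %s", num, f$max), q$id
        )
      }
      num
    },
    date = {
      ans <- as.character(ans)
      ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", ans) &&
        !is.na(as.Date(ans, format = "%Y-%m-%d"))
      if (!ok) qst_abort_answer("dates must be valid YYYY-MM-DD", q$id)
      ans
    },
    tel = {
      ans <- as.character(ans)
      if (!grepl("^\\d{3}-\\d{3}-\\d{4}$", ans)) {
        qst_abort_answer("telephone numbers must match ddd-ddd-dddd", q$id)
      }
      ans
    },
    ssn = {
      ans <- as.character(ans)
      if (!grepl("^\\d{3}-\\d{2}-\\d{4}$", ans)) {
        qst_abort_answer("SSN must match ddd-dd-dddd", q$id)
      }
      ans
    },
    as.character(ans)
  )
}

#' Skip the current question without answering
#'
#' Applies the question's `#NR` (no-response) routing when declared;
#' otherwise, when the session allows skipping, advances as if the question
#' had been answered with no selections (the default-next, if declared, is
#' still honoured via the stack). Nothing is recorded for the skipped
#' question.
#'
#' @param state A running `quest_session`.
#' @return The updated session.
#' @export
qst_skip <- function(state) {
  stopifnot(inherits(state, "quest_session"))
  if (state$finished) {
    qst_abort("session already finished", "quest_session_finished")
  }
  q <- qst_question(state$module, state$current_id)
  state <- qst_count_step(state)
  if (!is.null(q$nr_target)) {
    return(qst_advance(state, q$nr_target))
  }
  if (!state$allow_skip &&
      (length(q$options) > 0L || length(q$inputs) > 0L)) {
    qst_abort(
      sprintf("[%s] is required and declares no #NR routing", q$id),
      "quest_skip_not_allowed"
    )
  }
  nxt <- qst_route(state, q, NULL)
  qst_advance(nxt$state, nxt$id)
}

#' Evaluate a displayif condition
#'
#' `equals`/`notEquals` compare a referenced response (or prefill value)
#' with a literal, numerically when both sides are numeric; for a
#' multi-select response the comparison tests set membership. `exists` is
#' true iff the reference was answered or prefilled. `greaterThan`/
#' `lessThan` are numeric-only. `and`/`or` short-circuit. A reference to an
#' unanswered question makes every comparison false rather than raising —
#' participants legitimately skip questions.
#'
#' @param expr A `quest_displayif` AST (see `qst_parse_directive()`).
#' @param responses Named list of recorded responses.
#' @param prefill Named list of prefill values.
#' @return A single logical.
#' @export
qst_evaluate_displayif <- function(expr, responses = list(), prefill = list()) {
  stopifnot(inherits(expr, "quest_displayif"))
  resolve <- function(a) {
    if (inherits(a, "quest_displayif")) {
      return(qst_evaluate_displayif(a, responses, prefill))
    }
    if (!is.null(a$ref)) {
      if (a$ref %in% names(responses)) return(responses[[a$ref]])
      if (a$ref %in% names(prefill)) return(prefill[[a$ref]])
      return(NULL)
    }
    a$lit
  }
  cmp_equal <- function(a, b) {
    if (is.null(a) || is.null(b) || length(a) == 0L || length(b) == 0L) {
      return(FALSE)
    }
    an <- suppressWarnings(as.numeric(a))
    bn <- suppressWarnings(as.numeric(b))
    if (!anyNA(an) && !anyNA(bn)) {
      any(an %in% bn)
    } else {
      any(as.character(a) %in% as.character(b))
    }
  }
  switch(expr$func,
    equals = cmp_equal(resolve(expr$args[[1]]), resolve(expr$args[[2]])),
    notEquals = {
      a <- resolve(expr$args[[1]]); b <- resolve(expr$args[[2]])
      if (is.null(a) || is.null(b)) FALSE else !cmp_equal(a, b)
    },
    exists = {
      v <- resolve(expr$args[[1]])
      !is.null(v) && length(v) > 0L
    },
    greaterThan = qst_cmp_numeric(resolve(expr$args[[1]]),
                                  resolve(expr$args[[2]]), `>`),
    lessThan = qst_cmp_numeric(resolve(expr$args[[1]]),
                               resolve(expr$args[[2]]), `<`),
    and = {
      for (a in expr$args) {
        if (!isTRUE(qst_truthy(resolve(a)))) return(FALSE)
      }
      TRUE
    },
    or = {
      for (a in expr$args) {
        if (isTRUE(qst_truthy(resolve(a)))) return(TRUE)
      }
      FALSE
    }
  )
}

qst_truthy <- function(v) {
  if (is.logical(v) && length(v) == 1L) return(v)
  qst_abort("and/or arguments must be nested displayif expressions",
            "quest_expression_error")
}

qst_cmp_numeric <- function(a, b, op) {
  if (is.null(a) || is.null(b)) return(FALSE)
  if (length(a) != 1L || length(b) != 1L) {
    qst_abort("greaterThan/lessThan take scalar operands",
              "quest_expression_error")
  }
  an <- suppressWarnings(as.numeric(a))
  bn <- suppressWarnings(as.numeric(b))
  if (is.na(an) || is.na(bn)) {
    qst_abort("greaterThan/lessThan require numeric operands",
              "quest_expression_error")
  }
  op(an, bn)
}

#' Substitute piped placeholders into question text
#'
#' Each `{KEY}` placeholder is replaced by the recorded response for `KEY`
#' when present, else by the prefill value for `KEY`, else left verbatim.
#' Multi-select responses are joined with `", "`.
#'
#' @param text Question text possibly containing `{KEY}` placeholders.
#' @param responses Named list of recorded responses.
#' @param prefill Named list of prefill values.
#' @return The substituted string.
#' @examples
#' qst_resolve_piping("You are {AGE} years old", prefill = list(AGE = 63))
#' @export
qst_resolve_piping <- function(text, responses = list(), prefill = list()) {
  stopifnot(is.character(text), length(text) == 1L)
  matches <- gregexpr("\\{([A-Za-z0-9_#]+)\\}", text)[[1]]
  if (matches[1] == -1L) return(text)
  keys <- regmatches(text, gregexpr("\\{([A-Za-z0-9_#]+)\\}", text))[[1]]
  for (ph in unique(keys)) {
    key <- substr(ph, 2L, nchar(ph) - 1L)
    val <- if (key %in% names(responses)) {
      responses[[key]]
    } else if (key %in% names(prefill)) {
      prefill[[key]]
    } else {
      NULL
    }
    if (!is.null(val)) {
      text <- gsub(ph, paste(format(val, scientific = FALSE), collapse = ", "),
                   text, fixed = TRUE)
    }
  }
  text
}

#' @export
print.quest_session <- function(x, ...) {
  cat(sprintf(
    "<quest_session> at [%s]%s; %d answered, stack: %s\n",
    x$current_id, if (x$finished) " (finished)" else "",
    length(x$responses),
    if (length(x$stack) == 0L) "<empty>" else
      paste(rev(x$stack), collapse = " < ")
  ))
  invisible(x)
}
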