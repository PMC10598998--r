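# Condition constructors. Every user-facing failure is a classed condition so
# callers (and the CLI) can branch on class rather than message text.

qst_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "quest_error"), ...)
}

qst_abort_parse <- function(message, line) {
  qst_abort(
    sprintf("line %d: %s", as.integer(line), message),
    class = "quest_parse_error",
    line = as.integer(line)
  )
}

qst_abort_answer <- function(message, question_id) {
  qst_abort(
    sprintf("invalid answer for [%s]: %s", question_id, message),
    class = "quest_answer_error",
    question_id = question_id
  )
}
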