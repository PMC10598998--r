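#' Serialize a module back to canonical Quest markup
#'
#' Emits one block per question: the header line `[ID] text`, then options,
#' input fields and directives each on their own line, with blocks separated
#' by a blank line. The output is a parse fixed point:
#' `qst_parse(qst_serialize(m))` is structurally equal to `m` (source line
#' numbers aside).
#'
#' @param module A `quest_module`.
#' @return A single markup string (empty string for an empty module).
#' @export
qst_serialize <- function(module) {
  blocks <- vapply(module$questions, qst_serialize_question, character(1))
  if (length(blocks) == 0L) {
    return("")
  }
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}

qst_serialize_question <- function(q) {
  out <- sprintf("[%s]%s", q$id, if (nzchar(q$text)) paste0(" ", q$text) else "")
  for (o in q$options) {
    wrap <- if (o$kind == "radio") c("(", ")") else c("[", "]")
    line <- sprintf("%s%s%s%s", wrap[1], o$value, wrap[2],
                    if (nzchar(o$label)) paste0(" ", o$label) else "")
    if (!is.null(o$jump_target)) {
      line <- sprintf("%s -> %s", line, o$jump_target)
    }
    out <- c(out, line)
  }
  for (f in q$inputs) {
    tok <- switch(f$kind,
      text = "|__|", numeric = "|__|__|",
      date = "|date|", tel = "|tel|", ssn = "|SSN|"
    )
    ann <- character(0)
    if (!is.null(f$min)) ann <- c(ann, sprintf("min=%s", format(f$min, scientific = FALSE)))
    if (!is.null(f$max)) ann <- c(ann, sprintf("max=%s", format(f$max, scientific = FALSE)))
    out <- c(out, paste(c(tok, ann), collapse = " "))
  }
  if (!is.null(q$default_next)) {
    out <- c(out, sprintf("< -> %s>", q$default_next))
  }
  if (!is.null(q$nr_target)) {
    out <- c(out, sprintf("<#NR -> %s>", q$nr_target))
  }
  if (!is.null(q$displayif)) {
    out <- c(out, sprintf("<displayif=%s>", qst_deparse_displayif(q$displayif)))
  }
  paste(out, collapse = "\n")
}
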